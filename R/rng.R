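#' Evaluate an expression under a temporary RNG seed
#'
#' Saves and restores the global RNG state so that seeded package internals
#' never disturb the caller's random number stream. All stochastic behaviour
#' in camosim flows through this helper with an explicit integer seed, which
#' is what makes full-run replay exact.
#'
#' @param seed integer seed (must be < 2^31).
#' @param code expression to evaluate.
#' @return the value of `code`.
#' @keywords internal
with_seed <- function(seed, code) {
  seed <- as.integer(seed)
  stopifnot(is.finite(seed))
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      },
      add = TRUE
    )
  }
  set.seed(seed)
  code
}

#' Derive a stream of child seeds from one parent seed
#'
#' Used to give every generation / tray / operation its own independent,
#' reproducible seed. All derived seeds stay below 2^31 - 1.
#'
#' @param seed parent seed.
#' @param n number of child seeds.
#' @return integer vector of length `n`.
#' @keywords internal
derive_seeds <- function(seed, n) {
  with_seed(seed, sample.int(.Machine$integer.max - 1L, n))
}

# Deterministic, platform-stable hash of a gene vector onto a 31-bit seed.
# Genes are quantised to 1e-9 so that CSV round-trips (15 significant
# digits) hash identically. Plain modular accumulation in doubles: all
# intermediates stay far below 2^53 so arithmetic is exact.
hash_genes <- function(genes) {
  m <- 2147483647 # 2^31 - 1
  h <- 17
  q <- round(genes * 1e9)
  for (v in q) {
    h <- (h * 31 + (v %% m)) %% m
  }
  as.integer(h)
}
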