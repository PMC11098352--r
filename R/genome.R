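# Gene layout: 4 palette colours x 3 genes (L, a, b position inside the
# colour box) = 12, then 2 genes pattern scale (log-mapped to [4, 64] px),
# 3 genes colour proportions (softmax with a fixed fourth logit), 2 genes
# orientation / elongation, 1 gene edge softness. K = 20.
GENOME_LENGTH <- 20L
N_PALETTE <- 4L

#' Create a pattern genome
#'
#' A genome is a fixed-length vector of 20 genes, each in \[0, 1\],
#' decoded into palette colours and pattern parameters by
#' [decode_genome()]. Identifiers and parent identifiers carry lineage
#' through a run.
#'
#' @param genes numeric vector of length 20, all in \[0, 1\].
#' @param id character prey identifier.
#' @param parent_ids character vector of 0-2 parent identifiers.
#' @return an object of class `camo_genome`.
#' @export
camo_genome <- function(genes, id = "g0", parent_ids = character()) {
  genes <- as.numeric(genes)
  if (length(genes) != GENOME_LENGTH) {
    stop(sprintf("genome must have %d genes, got %d", GENOME_LENGTH,
                 length(genes)))
  }
  stopifnot(all(is.finite(genes)), all(genes >= 0), all(genes <= 1),
            length(parent_ids) <= 2)
  structure(
    list(genes = genes, id = as.character(id),
         parent_ids = as.character(parent_ids)),
    class = "camo_genome"
  )
}

#' @export
print.camo_genome <- function(x, ...) {
  cat(sprintf("camo_genome %s (%d genes, parents: %s)\n", x$id,
              length(x$genes),
              if (length(x$parent_ids)) paste(x$parent_ids, collapse = ", ")
              else "none"))
  invisible(x)
}

#' Draw a random genome
#'
#' Generation-0 genomes are i.i.d. Uniform(0, 1) on every gene; the colour
#' box only enters at decode time, so the same gene vector yields
#' background-biased colours under a narrow box and unrestricted colours
#' under the full box.
#'
#' @param seed integer seed.
#' @param id,parent_ids passed to [camo_genome()].
#' @return a `camo_genome`.
#' @export
random_genome <- function(seed, id = "g0", parent_ids = character()) {
  genes <- with_seed(seed, runif(GENOME_LENGTH))
  camo_genome(genes, id = id, parent_ids = parent_ids)
}

#' Decode a genome into phenotype parameters
#'
#' Colour genes map affinely onto the box intervals (gene 0 gives the lower
#' bound, 1 the upper). Pattern scale is log-mapped to \[4, 64\] px from the
#' mean of its two genes; coverage proportions are a softmax over three
#' logits plus a fixed fourth; orientation spans \[0, pi); elongation
#' \[1, 3\]; edge softness \[0, 2\] px of boundary blur.
#'
#' @param g a `camo_genome`.
#' @param space a [colour_space_box()].
#' @return a list of class `phenotype_params`: `palette` (4 x 3 Lab
#'   matrix), `pattern_scale`, `pattern_proportions`, `orientation`,
#'   `elongation`, `edge_softness`.
#' @export
decode_genome <- function(g, space = colour_space_box()) {
  stopifnot(inherits(g, "camo_genome"), inherits(space, "colour_space_box"))
  z <- g$genes
  affine <- function(u, iv) iv[1] + u * (iv[2] - iv[1])
  pal <- matrix(0, N_PALETTE, 3, dimnames = list(NULL, c("L", "a", "b")))
  for (i in seq_len(N_PALETTE)) {
    k <- (i - 1) * 3
    pal[i, ] <- c(affine(z[k + 1], space$L), affine(z[k + 2], space$a),
                  affine(z[k + 3], space$b))
  }
  scale_px <- 2^(2 + 4 * mean(z[13:14])) # [4, 64] px, log spaced
  logits <- c(z[15:17], 0.5) * 4
  prop <- exp(logits - max(logits))
  prop <- prop / sum(prop)
  structure(
    list(
      palette = pal,
      pattern_scale = scale_px,
      pattern_proportions = prop,
      orientation = z[18] * pi,
      elongation = 1 + 2 * z[19],
      edge_softness = 2 * z[20],
      genome_id = g$id
    ),
    class = "phenotype_params"
  )
}

#' Mutate a genome
#'
#' Each gene is independently perturbed with probability `rate` by a
#' Normal(0, `magnitude`) step, then reflected back into \[0, 1\].
#'
#' @param g a `camo_genome`.
#' @param rate per-gene mutation probability.
#' @param magnitude standard deviation of the perturbation.
#' @param seed integer seed.
#' @param id identifier for the mutant (defaults to the input's).
#' @return a mutated `camo_genome`.
#' @export
mutate_genome <- function(g, rate = 0.2, magnitude = 0.1, seed,
                          id = g$id) {
  stopifnot(inherits(g, "camo_genome"), rate >= 0, rate <= 1, magnitude > 0)
  genes <- with_seed(seed, {
    hit <- runif(GENOME_LENGTH) < rate
    step <- rnorm(GENOME_LENGTH, 0, magnitude)
    g$genes + ifelse(hit, step, 0)
  })
  camo_genome(reflect_unit(genes), id = id, parent_ids = g$parent_ids)
}

# reflect into [0,1] (handles arbitrarily large excursions)
reflect_unit <- function(x) {
  x <- x %% 2
  ifelse(x > 1, 2 - x, x)
}

#' Uniform crossover of two genomes
#'
#' Each child gene is copied from parent `a` or `b` with probability 1/2;
#' the child records both parent identifiers.
#'
#' @param a,b `camo_genome` objects with equal gene counts.
#' @param seed integer seed.
#' @param id identifier for the child.
#' @return a `camo_genome`.
#' @export
crossover_genomes <- function(a, b, seed, id = "child") {
  stopifnot(inherits(a, "camo_genome"), inherits(b, "camo_genome"))
  if (length(a$genes) != length(b$genes)) {
    stop("parent genomes have different lengths")
  }
  pick <- with_seed(seed, runif(length(a$genes)) < 0.5)
  camo_genome(ifelse(pick, a$genes, b$genes), id = id,
              parent_ids = c(a$id, b$id))
}

#' Genome list <-> data frame (CSV-ready)
#'
#' One row per genome: `id`, `generation`, `parent1`, `parent2`,
#' `gene_01` ... `gene_20`. Round-trips exactly at 15 significant digits.
#'
#' @param genomes list of `camo_genome`.
#' @param generation generation index recorded in the table.
#' @return `genomes_to_df`: a data.frame; `df_to_genomes`: a list of
#'   `camo_genome`.
#' @export
genomes_to_df <- function(genomes, generation = 0L) {
  gm <- t(vapply(genomes, function(g) g$genes, numeric(GENOME_LENGTH)))
  colnames(gm) <- sprintf("gene_%02d", seq_len(GENOME_LENGTH))
  p1 <- vapply(genomes, function(g) {
    if (length(g$parent_ids) >= 1) g$parent_ids[1] else ""
  }, character(1))
  p2 <- vapply(genomes, function(g) {
    if (length(g$parent_ids) >= 2) g$parent_ids[2] else ""
  }, character(1))
  data.frame(
    id = vapply(genomes, function(g) g$id, character(1)),
    generation = as.integer(generation), parent1 = p1, parent2 = p2,
    gm, stringsAsFactors = FALSE
  )
}

#' @rdname genomes_to_df
#' @param df a data.frame as produced by `genomes_to_df`.
#' @export
df_to_genomes <- function(df) {
  gcols <- sprintf("gene_%02d", seq_len(GENOME_LENGTH))
  lapply(seq_len(nrow(df)), function(i) {
    par <- c(df$parent1[i], df$parent2[i])
    camo_genome(as.numeric(df[i, gcols]), id = df$id[i],
                parent_ids = par[nzchar(par)])
  })
}
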