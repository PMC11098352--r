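# Fixtures built in code: tiny images, degenerate visual systems, and
# hand-rolled RNL closed forms used as independent oracles.

# uniform H x W x 3 image of one sRGB colour (0-1 triple)
uniform_image <- function(rgb01, h = 64, w = 64) {
  img <- array(0, c(h, w, 3))
  for (c in 1:3) img[, , c] <- rgb01[c]
  img
}

# a dichromatic visual system reading R and G channels directly
dichromat_vs <- function(weber = c(0.1, 0.1)) {
  visual_system(
    receptor_matrix = matrix(c(1, 0, 0, 0, 1, 0), 2, 3, byrow = TRUE),
    weber = weber, weber_lum = 0.1
  )
}

# independent oracle: dichromat RNL closed form
rnl_dichromat_oracle <- function(qA, qB, e) {
  df <- log(qA) - log(qB)
  abs(df[1] - df[2]) / sqrt(e[1]^2 + e[2]^2)
}

# independent oracle: trichromat RNL closed form
rnl_trichromat_oracle <- function(qA, qB, e) {
  f <- log(qA) - log(qB)
  num <- e[1]^2 * (f[2] - f[3])^2 + e[2]^2 * (f[1] - f[3])^2 +
    e[3]^2 * (f[1] - f[2])^2
  den <- (e[1] * e[2])^2 + (e[1] * e[3])^2 + (e[2] * e[3])^2
  sqrt(num / den)
}

# a solid-colour "target": uniform disc (ellipse) of one Lab colour
solid_target <- function(lab, size_px = c(64, 48), id = "solid") {
  rgb01 <- as.numeric(lab_to_srgb(lab)) / 255
  h <- size_px[2]
  w <- size_px[1]
  img <- uniform_image(rgb01, h, w)
  mask <- camosim:::mask_ellipse(h, w)
  for (c in 1:3) img[, , c][!mask] <- 0
  structure(list(rgb = img, alpha_mask = mask, genome_id = id),
            class = "target_image")
}

# a phenotype whose palette is n copies of the given Lab rows
palette_phenotype <- function(lab_matrix) {
  n <- camosim:::N_PALETTE
  pal <- lab_matrix[rep_len(seq_len(nrow(lab_matrix)), n), , drop = FALSE]
  structure(
    list(palette = pal, pattern_scale = 8,
         pattern_proportions = rep(1 / n, n), orientation = 0,
         elongation = 1, edge_softness = 0, genome_id = "fixture"),
    class = "phenotype_params"
  )
}

# random rank table over a population of n_groups x group_size prey
random_rank_table <- function(cfg, seed, ids = NULL) {
  if (is.null(ids)) {
    ids <- sprintf("p%02d", seq_len(cfg$population_size))
  }
  rk <- camosim:::with_seed(seed, {
    unlist(lapply(seq_len(cfg$n_groups), function(g) {
      sample(cfg$group_size)
    }))
  })
  tab <- data.frame(
    prey_id = ids,
    group = rep(seq_len(cfg$n_groups), each = cfg$group_size),
    slot = rep(seq_len(cfg$group_size), times = cfg$n_groups),
    attack_index = NA_integer_, fitness_rank = rk,
    stringsAsFactors = FALSE
  )
  class(tab) <- c("rank_table", "data.frame")
  tab
}
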