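#' Render a genome's phenotype as an oval target image
#'
#' The pattern is a band-limited noise field: white noise seeded from a
#' hash of the gene vector, smoothed by an anisotropic Gaussian whose
#' scale, elongation and orientation come from the phenotype, then
#' thresholded at the cumulative coverage proportions to assign each pixel
#' one of the four palette colours (quantised to 8-bit sRGB, as a printed
#' target would be). An optional boundary blur (edge softness) mixes
#' colours at patch borders. Rendering is a pure function of
#' (genome, size): repeated renders are bit-identical.
#'
#' @param p `phenotype_params` from [decode_genome()], or a `camo_genome`
#'   (decoded with `space`).
#' @param size_px `c(width, height)` in pixels, each >= 16. The default
#'   128 x 96 preserves the 18:14 physical shell aspect ratio
#'   approximately (4:3).
#' @param space colour box used when `p` is a genome.
#' @param shading if `TRUE`, apply a fixed multiplicative luminance dome
#'   (cosmetic 3D shading; off by default).
#' @return an object of class `target_image`: `rgb` (H x W x 3 in \[0,1\]),
#'   `alpha_mask` (H x W logical ellipse), `genome_id`.
#' @export
render_target <- function(p, size_px = c(128, 96),
                          space = colour_space_box(), shading = FALSE) {
  if (inherits(p, "camo_genome")) {
    seed <- hash_genes(p$genes)
    p <- decode_genome(p, space)
  } else {
    stopifnot(inherits(p, "phenotype_params"))
    seed <- hash_genes(c(
      as.numeric(p$palette), p$pattern_scale,
      p$pattern_proportions, p$orientation, p$elongation, p$edge_softness
    ))
  }
  w <- as.integer(size_px[1])
  h <- as.integer(size_px[2])
  stopifnot(w >= 16, h >= 16)

  field <- with_seed(seed, matrix(runif(h * w), h, w))
  sig <- p$pattern_scale / 4
  field <- gaussian_blur(field, sig * p$elongation, sig / p$elongation,
                         p$orientation)
  # threshold at coverage quantiles -> palette index per pixel
  cuts <- quantile(field, probs = cumsum(p$pattern_proportions)[-N_PALETTE],
                   names = FALSE)
  idx <- matrix(findInterval(field, cuts) + 1L, h, w)

  pal_rgb <- lab_to_srgb(p$palette) / 255
  img <- array(0, c(h, w, 3))
  for (c in 1:3) img[, , c] <- matrix(pal_rgb[idx, c], h, w)
  if (p$edge_softness > 0.05) {
    img <- map_channels(img, function(m) gaussian_blur(m, p$edge_softness))
  }
  if (shading) {
    dome <- shading_dome(h, w)
    img <- map_channels(img, function(m) pmin(pmax(m * dome, 0), 1))
  }
  mask <- mask_ellipse(h, w)
  for (c in 1:3) img[, , c][!mask] <- 0
  structure(list(rgb = img, alpha_mask = mask, genome_id = p$genome_id),
            class = "target_image")
}

# fixed luminance dome: brighter centre-top, darker rim
shading_dome <- function(h, w) {
  y <- matrix(seq_len(h) / h, h, w)
  x <- matrix(seq_len(w) / w, h, w, byrow = TRUE)
  r2 <- ((x - 0.5) * 2)^2 + ((y - 0.45) * 2)^2
  0.75 + 0.45 * exp(-r2 * 1.2)
}

#' @export
print.target_image <- function(x, ...) {
  cat(sprintf("target_image %s: %d x %d px, %d masked px\n",
              x$genome_id %||% "?", dim(x$rgb)[2], dim(x$rgb)[1],
              sum(x$alpha_mask)))
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Write a target as an RGBA PNG
#'
#' Pixels outside the oval mask get alpha 0.
#'
#' @param target a `target_image`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_target_png <- function(target, path) {
  d <- dim(target$rgb)
  out <- array(0, c(d[1], d[2], 4))
  out[, , 1:3] <- target$rgb
  out[, , 4] <- target$alpha_mask * 1
  png::writePNG(out, path)
  invisible(path)
}
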