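# Camouflage-efficacy metrics: mean-colour RNL distances, the
# frequency-weighted colour difference, granularity pattern difference and
# GabRat edge disruption. All are deterministic given (images, visual
# system, k-means seed).

#' Mean-colour RNL differences between a target and its background
#'
#' Averages linear RGB over the target's masked pixels and over all
#' background pixels, maps both means to receptor catches / luminance, and
#' returns the receptor-noise-limited chromatic and achromatic distances.
#'
#' @param target a `target_image`.
#' @param bg background image (H x W x 3 array) or a precomputed
#'   [background_stats()] object.
#' @param vs a [visual_system()].
#' @return named numeric: `delta_s`, `delta_l` (JND).
#' @export
mean_colour_difference <- function(target, bg, vs = visual_system()) {
  tpx <- image_to_rgb_rows(target$rgb, target$alpha_mask)
  if (nrow(tpx) == 0) stop("target mask is empty")
  tmean <- colMeans(srgb_linearise(tpx))
  bstat <- as_background_stats(bg, vs)
  qa <- linear_to_catches(matrix(tmean, 1), vs)
  ds <- rnl_chromatic(qa, bstat$mean_catch, vs)
  dl <- rnl_achromatic(linear_to_lum(matrix(tmean, 1), vs), bstat$mean_lum, vs)
  c(delta_s = as.numeric(ds), delta_l = as.numeric(dl))
}

#' Summarise a background for repeated metric evaluation
#'
#' Computes, once, the background's mean linear RGB (as catches and
#' luminance) and a seeded k-means palette of its pixel colours. All
#' metric functions accept this object in place of the raw image, which is
#' what makes whole-run metric evaluation cheap.
#'
#' @param bg H x W x 3 sRGB array.
#' @param vs a [visual_system()].
#' @param k number of k-means colour clusters (default 8).
#' @param seed k-means seed (default 1; fixed => deterministic metrics).
#' @param max_px subsample cap for k-means (default 20000 pixels).
#' @return an object of class `background_stats`.
#' @export
background_stats <- function(bg, vs = visual_system(), k = 8, seed = 1L,
                             max_px = 20000L) {
  stopifnot(k >= 1)
  px <- image_to_rgb_rows(bg)
  lin <- srgb_linearise(px)
  mean_lin <- matrix(colMeans(lin), 1)
  samp <- lin
  if (nrow(samp) > max_px) {
    idx <- with_seed(seed, sample.int(nrow(samp), max_px))
    samp <- samp[idx, , drop = FALSE]
  }
  km <- with_seed(seed, suppressWarnings(
    kmeans(samp, centers = min(k, nrow(unique(samp))), nstart = 10,
           iter.max = 50)
  ))
  centres <- km$centers
  structure(
    list(
      mean_catch = linear_to_catches(mean_lin, vs),
      mean_lum = linear_to_lum(mean_lin, vs),
      palette_catch = linear_to_catches(centres, vs),
      palette_lin = centres,
      lum = linear_to_lum(lin, vs),
      dim = dim(bg)[1:2]
    ),
    class = "background_stats"
  )
}

as_background_stats <- function(bg, vs, ...) {
  if (inherits(bg, "background_stats")) bg else background_stats(bg, vs, ...)
}

#' Frequency-weighted colour difference
#'
#' Pattern-aware colour matching: each of the target's palette colours is
#' compared with the most similar background colour (k-means centroid of
#' background pixels), and the per-colour minimum RNL distances are
#' averaged weighted by the palette colours' pixel frequencies on the
#' rendered target.
#'
#' @param target a `target_image` rendered from `phenotype`, or any target
#'   whose colours should be quantised to `phenotype$palette`.
#' @param phenotype the `phenotype_params` of the target (supplies the
#'   palette the pixels are assigned to).
#' @param bg background image or [background_stats()].
#' @param vs a [visual_system()].
#' @param n_bg_clusters clusters used if `bg` is a raw image.
#' @return weighted chromatic difference (JND).
#' @export
weighted_colour_difference <- function(target, phenotype, bg,
                                       vs = visual_system(),
                                       n_bg_clusters = 8) {
  if (n_bg_clusters < 1) stop("n_bg_clusters must be >= 1")
  bstat <- as_background_stats(bg, vs, k = n_bg_clusters)
  tpx <- image_to_rgb_rows(target$rgb, target$alpha_mask)
  if (nrow(tpx) == 0) stop("target mask is empty")
  pal_rgb <- lab_to_srgb(phenotype$palette) / 255
  pal_lin <- srgb_linearise(pal_rgb)
  tlin <- srgb_linearise(tpx)
  # nearest palette colour per pixel -> frequencies p_k
  d2 <- vapply(seq_len(nrow(pal_lin)), function(i) {
    rowSums(sweep(tlin, 2, pal_lin[i, ])^2)
  }, numeric(nrow(tlin)))
  assign <- max.col(-d2, ties.method = "first")
  p_k <- tabulate(assign, nbins = nrow(pal_lin)) / nrow(tlin)
  pal_catch <- linear_to_catches(pal_lin, vs)
  mins <- vapply(seq_len(nrow(pal_catch)), function(i) {
    min(rnl_chromatic(
      matrix(pal_catch[i, ], nrow(bstat$palette_catch),
             ncol(pal_catch), byrow = TRUE),
      bstat$palette_catch, vs
    ))
  }, numeric(1))
  sum(p_k * mins)
}

#' Granularity spectrum of an image
#'
#' Energy of the luminance channel in octave-spaced spatial-frequency
#' bands. Each band is a hard FFT annulus passing wavelengths within a
#' factor sqrt(2) of the band centre; band energy is the standard
#' deviation of the band-passed image (over the masked region if a mask is
#' given). Band-pass filters remove the DC component, so energies are
#' invariant to adding a constant to the image.
#'
#' @param img H x W x 3 array, H x W luminance matrix, or `target_image`.
#' @param mask optional logical matrix restricting the energy statistic.
#' @param scales band centres in px (default octaves 2-64).
#' @param vs visual system supplying luminance weights.
#' @return object of class `granularity_spectrum`: `scales`, `energy`.
#' @export
granularity_spectrum <- function(img, mask = NULL,
                                 scales = c(2, 4, 8, 16, 32, 64),
                                 vs = visual_system()) {
  if (inherits(img, "target_image")) {
    if (is.null(mask)) mask <- img$alpha_mask
    img <- img$rgb
  }
  lum <- if (length(dim(img)) == 3) {
    lin <- map_channels(img, srgb_linearise)
    lin[, , 1] * vs$lum_weights[1] + lin[, , 2] * vs$lum_weights[2] +
      lin[, , 3] * vs$lum_weights[3]
  } else {
    img
  }
  if (max(scales) > min(dim(lum))) {
    stop(sprintf("largest scale (%g px) exceeds image size (%d x %d)",
                 max(scales), nrow(lum), ncol(lum)))
  }
  energy <- vapply(scales, function(s) {
    band <- bandpass_annulus(lum, s)
    v <- if (is.null(mask)) as.vector(band) else band[mask]
    if (length(v) < 2) 0 else sd(v)
  }, numeric(1))
  structure(list(scales = scales, energy = energy),
            class = "granularity_spectrum")
}

#' Granularity pattern difference
#'
#' L1 distance between two granularity spectra taken over identical scale
#' lists: `sum_s |E_t(s) - E_b(s)|`. Being an L1 distance it is symmetric,
#' non-negative, zero only for identical spectra, and satisfies the
#' triangle inequality.
#'
#' @param t,b `granularity_spectrum` objects.
#' @return non-negative scalar.
#' @export
pattern_difference <- function(t, b) {
  if (length(t$scales) != length(b$scales) ||
        any(t$scales != b$scales)) {
    stop("granularity spectra use different scale lists")
  }
  sum(abs(t$energy - b$energy))
}

#' GabRat edge disruption of a composited target
#'
#' Measures how much "false" edge energy crosses the target outline
#' relative to the coherent outline itself. The target is composited onto
#' the background; even-symmetric Gabor filters at `n_orient` orientations
#' are applied to the luminance channel; for each outline pixel the energy
#' at the orientation parallel to the local outline tangent (`g_par`) is
#' compared with the maximum energy at clearly non-parallel orientations
#' (`g_false`), giving `g_false / (g_par + g_false)`. GabRat is the mean
#' over outline pixels and lies in \[0, 1\]; higher values mean more edge
#' disruption. Pixels with no response at all are skipped; if nothing
#' responds anywhere (target identical to a uniform background) the result
#' is 0 by convention.
#'
#' @param target a `target_image`.
#' @param bg background image array (at least as large as the target).
#' @param vs a [visual_system()].
#' @param sigma Gabor envelope sd across the edge, in px (default 3; the
#'   envelope is elongated 3:1 along the edge for sharp orientation
#'   tuning).
#' @param n_orient number of orientations (default 4: 0-135 deg by 45; a
#'   45 degree step keeps coherent-edge energy out of the false-edge
#'   maximum).
#' @param cy,cx composite centre (defaults: background centre).
#' @return scalar in \[0, 1\].
#' @export
gabrat_disruption <- function(target, bg, vs = visual_system(), sigma = 3,
                              n_orient = 4, cy = NULL, cx = NULL) {
  stopifnot(sigma > 0, n_orient >= 2)
  comp <- composite_target(bg, target, cy = cy, cx = cx)
  outline <- mask_outline(comp$mask)
  if (!any(outline)) stop("degenerate mask: no outline")
  lin <- map_channels(comp$img, srgb_linearise)
  lum <- lin[, , 1] * vs$lum_weights[1] + lin[, , 2] * vs$lum_weights[2] +
    lin[, , 3] * vs$lum_weights[3]

  thetas <- (seq_len(n_orient) - 1) * pi / n_orient
  oidx <- which(outline)
  energies <- vapply(thetas, function(th) {
    abs(gabor_even_response(lum, sigma, th))[oidx]
  }, numeric(length(oidx)))
  if (is.null(dim(energies))) energies <- matrix(energies, nrow = 1)

  tangent <- outline_tangents(comp$mask, sigma)[oidx]
  # orientation bin nearest each pixel's tangent
  ang_dist <- function(a, b) {
    d <- abs(a - b) %% pi
    pmin(d, pi - d)
  }
  ratios <- vapply(seq_along(oidx), function(i) {
    d <- ang_dist(tangent[i], thetas)
    par_bin <- which.min(d)
    g_par <- energies[i, par_bin]
    far <- d >= (pi / n_orient) - 1e-9
    g_false <- if (any(far)) max(energies[i, far]) else 0
    tot <- g_par + g_false
    if (tot <= 1e-12) NA_real_ else g_false / tot
  }, numeric(1))
  ratios <- ratios[!is.na(ratios)]
  if (length(ratios) == 0) return(0)
  mean(ratios)
}

# even (cosine) Gabor response via FFT; theta is the carrier direction
# normal to the edge orientation it detects, so an edge oriented at
# `theta` responds to the filter whose carrier is perpendicular. We index
# filters by the EDGE orientation they respond to.
gabor_even_response <- function(lum, sigma, edge_theta) {
  h <- nrow(lum)
  w <- ncol(lum)
  lambda <- 2 * sigma
  gam <- 1 / 3 # envelope aspect: elongated along the edge
  # carrier normal to the edge
  th <- edge_theta + pi / 2
  half <- ceiling(3 * sigma / gam)
  xs <- seq(-half, half)
  X <- matrix(xs, length(xs), length(xs), byrow = TRUE)
  Y <- matrix(xs, length(xs), length(xs))
  xr <- X * cos(th) + Y * sin(th)
  yr <- -X * sin(th) + Y * cos(th)
  g <- exp(-(xr^2 + (gam * yr)^2) / (2 * sigma^2)) * cos(2 * pi * xr / lambda)
  g <- g - mean(g) # zero DC so uniform regions give no response
  # embed kernel wrapped at origin for circular FFT convolution
  k <- matrix(0, h, w)
  for (i in seq_along(xs)) {
    for (j in seq_along(xs)) {
      k[(xs[i] %% h) + 1, (xs[j] %% w) + 1] <-
        k[(xs[i] %% h) + 1, (xs[j] %% w) + 1] + g[i, j]
    }
  }
  Re(fft(fft(lum) * Conj(fft(k)), inverse = TRUE)) / (h * w)
}

# boundary pixels: masked with at least one 4-neighbour outside
mask_outline <- function(mask) {
  h <- nrow(mask)
  w <- ncol(mask)
  pad <- rbind(FALSE, cbind(FALSE, mask, FALSE), FALSE)
  inner <- pad[1:h, 2:(w + 1)] & pad[3:(h + 2), 2:(w + 1)] &
    pad[2:(h + 1), 1:w] & pad[2:(h + 1), 3:(w + 2)]
  mask & !inner
}

# local outline tangent angle in [0, pi): perpendicular to the gradient of
# the Gaussian-smoothed mask
outline_tangents <- function(mask, sigma) {
  sm <- gaussian_blur(mask * 1, max(sigma, 1.5))
  h <- nrow(sm)
  w <- ncol(sm)
  gx <- matrix(0, h, w)
  gy <- matrix(0, h, w)
  gx[, 2:(w - 1)] <- (sm[, 3:w] - sm[, 1:(w - 2)]) / 2
  gy[2:(h - 1), ] <- (sm[3:h, ] - sm[1:(h - 2), ]) / 2
  (atan2(gy, gx) + pi / 2) %% pi
}

#' All camouflage metrics for one target against one background
#'
#' Convenience wrapper producing one row of a metrics table. Metrics can
#' be restricted (e.g. when the simulated observer only consumes colour
#' metrics) to keep closed-loop runs fast.
#'
#' @param target a `target_image`.
#' @param phenotype its `phenotype_params`.
#' @param bg background array.
#' @param bstat matching [background_stats()] (computed if missing).
#' @param vs a [visual_system()].
#' @param which character subset of
#'   `c("delta_s", "delta_l", "delta_s_weighted", "pattern_difference",
#'   "gabrat")`.
#' @param bg_spectrum optional precomputed background
#'   `granularity_spectrum`.
#' @param scales granularity band centres.
#' @return one-row data.frame of the requested metrics plus `target_id`.
#' @export
target_metrics <- function(target, phenotype, bg, bstat = NULL,
                           vs = visual_system(),
                           which = c("delta_s", "delta_l",
                                     "delta_s_weighted",
                                     "pattern_difference", "gabrat"),
                           bg_spectrum = NULL,
                           scales = c(2, 4, 8, 16, 32, 64)) {
  if (is.null(bstat)) bstat <- background_stats(bg, vs)
  out <- list(target_id = target$genome_id %||% NA_character_)
  if (any(c("delta_s", "delta_l") %in% which)) {
    md <- mean_colour_difference(target, bstat, vs)
    if ("delta_s" %in% which) out$delta_s <- md[["delta_s"]]
    if ("delta_l" %in% which) out$delta_l <- md[["delta_l"]]
  }
  if ("delta_s_weighted" %in% which) {
    out$delta_s_weighted <-
      weighted_colour_difference(target, phenotype, bstat, vs)
  }
  if ("pattern_difference" %in% which) {
    sc <- scales[scales <= min(dim(target$rgb)[1:2])]
    tsp <- granularity_spectrum(target, scales = sc, vs = vs)
    bsp <- if (!is.null(bg_spectrum)) {
      structure(list(scales = sc,
                     energy = bg_spectrum$energy[bg_spectrum$scales %in% sc]),
                class = "granularity_spectrum")
    } else {
      granularity_spectrum(bg, scales = sc, vs = vs)
    }
    out$pattern_difference <- pattern_difference(tsp, bsp)
  }
  if ("gabrat" %in% which) {
    out$gabrat <- gabrat_disruption(target, bg, vs)
  }
  as.data.frame(out, stringsAsFactors = FALSE)
}
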