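vs_default <- visual_system()

test_that("a target coloured as a uniform background scores zero", {
  lab <- c(55, 5, 15)
  bg <- uniform_image(as.numeric(lab_to_srgb(lab)) / 255, 96, 96)
  t <- solid_target(lab)
  md <- mean_colour_difference(t, bg, vs_default)
  expect_equal(unname(md), c(0, 0), tolerance = 1e-9)
  dsw <- weighted_colour_difference(t, palette_phenotype(matrix(lab, 1)),
                                    bg, vs_default)
  expect_equal(dsw, 0, tolerance = 1e-9)
})

test_that("mean colour difference matches a hand-computed two-patch average", {
  labA <- c(40, 10, 0)
  labB <- c(70, -10, 30)
  rgbA <- as.numeric(lab_to_srgb(labA)) / 255
  rgbB <- as.numeric(lab_to_srgb(labB)) / 255
  h <- 48; w <- 64
  img <- uniform_image(rgbA, h, w)
  for (c in 1:3) img[, (w / 2 + 1):w, c] <- rgbB[c]
  mask <- matrix(TRUE, h, w) # full-frame mask keeps areas exactly 50/50
  t <- structure(list(rgb = img, alpha_mask = mask, genome_id = "x"),
                 class = "target_image")
  bg_lab <- c(55, 0, 15)
  bg <- uniform_image(as.numeric(lab_to_srgb(bg_lab)) / 255, 32, 32)

  # oracle: average the two linearised colours by hand, closed-form RNL
  linA <- camosim:::srgb_linearise(rgbA)
  linB <- camosim:::srgb_linearise(rgbB)
  tmean <- (linA + linB) / 2
  bmean <- camosim:::srgb_linearise(as.numeric(lab_to_srgb(bg_lab)) / 255)
  e <- vs_default$weber
  want_ds <- rnl_trichromat_oracle(pmax(tmean, 1e-4), pmax(bmean, 1e-4), e)
  want_dl <- abs(log(mean(tmean) / mean(bmean))) / vs_default$weber_lum
  got <- mean_colour_difference(t, bg, vs_default)
  expect_equal(unname(got["delta_s"]), want_ds, tolerance = 1e-9)
  expect_equal(unname(got["delta_l"]), want_dl, tolerance = 1e-9)

  # permuting target pixels leaves the means unchanged
  perm <- camosim:::with_seed(1, sample(h * w))
  img2 <- img
  for (c in 1:3) img2[, , c] <- matrix(as.vector(img[, , c])[perm], h, w)
  t2 <- structure(list(rgb = img2, alpha_mask = mask, genome_id = "x"),
                  class = "target_image")
  expect_equal(mean_colour_difference(t2, bg, vs_default), got,
               tolerance = 1e-12)
})

test_that("weighted colour difference is the frequency-weighted minimum", {
  # two-colour target (75 / 25) against a two-colour background
  labT <- rbind(c(40, 5, 10), c(70, -5, 40))
  labB <- rbind(c(45, 5, 12), c(75, -8, 35))
  rgbT <- lab_to_srgb(labT) / 255
  rgbB <- lab_to_srgb(labB) / 255
  h <- 32; w <- 32
  img <- uniform_image(rgbT[1, ], h, w)
  for (c in 1:3) img[25:32, , c] <- rgbT[2, c] # bottom quarter
  t <- structure(list(rgb = img, alpha_mask = matrix(TRUE, h, w),
                      genome_id = "x"), class = "target_image")
  bgimg <- uniform_image(rgbB[1, ], 32, 32)
  for (c in 1:3) bgimg[, 17:32, c] <- rgbB[2, c]
  phe <- palette_phenotype(labT)

  dsw <- weighted_colour_difference(t, phe, bgimg, vs_default,
                                    n_bg_clusters = 2)

  # brute-force oracle over all colour pairs
  qT <- srgb_to_catches(rgbT * 255, vs_default)
  qB <- srgb_to_catches(rgbB * 255, vs_default)
  e <- vs_default$weber
  dmin <- vapply(1:2, function(i) {
    min(vapply(1:2, function(j) {
      rnl_trichromat_oracle(qT[i, ], qB[j, ], e)
    }, numeric(1)))
  }, numeric(1))
  want <- 0.75 * dmin[1] + 0.25 * dmin[2]
  expect_equal(dsw, want, tolerance = 1e-6)

  # reduction: monochrome target = min distance to any background colour
  t1 <- solid_target(labT[1, ])
  d1 <- weighted_colour_difference(t1, palette_phenotype(labT[1, , drop = FALSE]),
                                   bgimg, vs_default, n_bg_clusters = 2)
  expect_equal(d1, dmin[1], tolerance = 1e-6)
  expect_error(
    weighted_colour_difference(t1, phe, bgimg, vs_default,
                               n_bg_clusters = 0), "n_bg_clusters")
})

test_that("weighted difference never exceeds the worst single colour", {
  set.seed(11)
  bg <- generate_background(background_spec(size = c(96, 96), seed = 2))
  bstat <- background_stats(bg, vs_default)
  for (s in 1:10) {
    g <- random_genome(s)
    p <- decode_genome(g)
    t <- render_target(g, size_px = c(48, 36))
    dsw <- weighted_colour_difference(t, p, bstat, vs_default)
    worst <- max(vapply(seq_len(nrow(p$palette)), function(i) {
      q <- srgb_to_catches(lab_to_srgb(p$palette[i, ]), vs_default)
      min(rnl_chromatic(
        matrix(q, nrow(bstat$palette_catch), 3, byrow = TRUE),
        bstat$palette_catch, vs_default))
    }, numeric(1)))
    expect_lte(dsw, worst + 1e-9)
  }
})

test_that("granularity spectra behave like octave band-pass energies", {
  # uniform image: all energies zero
  u <- granularity_spectrum(matrix(0.5, 80, 80), scales = c(2, 4, 8, 16))
  expect_equal(u$energy, rep(0, 4), tolerance = 1e-12)

  # sinusoidal grating, period 16 px: arg-max energy in the 16 px band
  x <- matrix(seq_len(128), 128, 128, byrow = TRUE)
  grating <- 0.5 + 0.4 * sin(2 * pi * x / 16)
  sp <- granularity_spectrum(grating, scales = c(2, 4, 8, 16, 32, 64))
  expect_equal(sp$scales[which.max(sp$energy)], 16)

  # DC invariance
  sp2 <- granularity_spectrum(grating + 0.05,
                              scales = c(2, 4, 8, 16, 32, 64))
  expect_equal(sp$energy, sp2$energy, tolerance = 1e-9)

  expect_error(granularity_spectrum(matrix(0, 32, 32), scales = c(64)),
               "exceeds image size")
})

test_that("pattern difference is an L1 distance on spectra", {
  mk <- function(e) structure(list(scales = c(2, 4, 8), energy = e),
                              class = "granularity_spectrum")
  expect_equal(pattern_difference(mk(c(1, 0, 0)), mk(c(0, 1, 0))), 2)
  expect_equal(pattern_difference(mk(c(0.3, 0.2, 0.1)), mk(c(0.3, 0.2, 0.1))), 0)
  expect_equal(pattern_difference(mk(c(1, 2, 3)), mk(c(3, 2, 1))),
               pattern_difference(mk(c(3, 2, 1)), mk(c(1, 2, 3))))
  # triangle inequality on random spectra
  set.seed(5)
  for (i in 1:50) {
    a <- mk(runif(3)); b <- mk(runif(3)); c3 <- mk(runif(3))
    expect_lte(pattern_difference(a, c3),
               pattern_difference(a, b) + pattern_difference(b, c3) + 1e-12)
  }
  expect_error(
    pattern_difference(mk(c(1, 2, 3)),
                       structure(list(scales = c(2, 4), energy = c(1, 2)),
                                 class = "granularity_spectrum")),
    "different scale lists")
})

test_that("GabRat separates a coherent outline from a striped one", {
  lab_bg <- c(50, 0, 0)
  bg <- uniform_image(as.numeric(lab_to_srgb(lab_bg)) / 255, 96, 96)

  # target identical to the background: no responses, 0 by convention
  t_same <- solid_target(lab_bg)
  expect_equal(gabrat_disruption(t_same, bg, vs_default), 0)

  # high-contrast uniform disc: the coherent outline dominates
  t_disc <- solid_target(c(95, 0, 0), size_px = c(48, 48))
  g_disc <- gabrat_disruption(t_disc, bg, vs_default)
  expect_lt(g_disc, 0.3)

  # the same disc overlaid with high-contrast stripes crossing the outline
  t_str <- t_disc
  stripes <- (floor(matrix(seq_len(48), 48, 48, byrow = TRUE) / 4) %% 2) == 0
  for (c in 1:3) {
    ch <- t_str$rgb[, , c]
    ch[stripes & t_str$alpha_mask] <- 0.02
    t_str$rgb[, , c] <- ch
  }
  g_str <- gabrat_disruption(t_str, bg, vs_default)
  expect_gt(g_str, g_disc)

  expect_error(gabrat_disruption(
    structure(list(rgb = array(0, c(8, 8, 3)),
                   alpha_mask = matrix(FALSE, 8, 8), genome_id = "z"),
              class = "target_image"), bg, vs_default),
    "degenerate mask")
})

test_that("GabRat stays within [0, 1] across random fixtures", {
  bgs <- lapply(1:4, function(i) {
    generate_background(background_spec(size = c(72, 72), seed = i,
                                        texture_contrast = 12))
  })
  for (s in 1:40) {
    t <- render_target(random_genome(s + 300), size_px = c(40, 30))
    g <- gabrat_disruption(t, bgs[[(s %% 4) + 1]], vs_default)
    expect_gte(g, 0)
    expect_lte(g, 1)
  }
})

test_that("metrics are deterministic given images and seeds", {
  bg <- generate_background(background_spec(size = c(96, 96), seed = 9))
  g <- random_genome(15)
  t <- render_target(g, size_px = c(48, 36))
  p <- decode_genome(g)
  m1 <- target_metrics(t, p, bg, vs = vs_default)
  m2 <- target_metrics(t, p, bg, vs = vs_default)
  expect_identical(m1, m2)
  expect_true(all(vapply(m1[-1], is.finite, logical(1))))
})
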