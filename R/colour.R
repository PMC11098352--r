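#' @importFrom stats sd rnorm runif quantile kmeans fft dist setNames
#' @importFrom utils read.csv write.csv
NULL

# sRGB <-> XYZ matrices (D65 white, 2 degree observer), IEC 61966-2-1.
.M_XYZ2RGB <- matrix(c(
  3.2404542, -1.5371385, -0.4985314,
  -0.9692660, 1.8760108, 0.0415560,
  0.0556434, -0.2040259, 1.0572252
), nrow = 3, byrow = TRUE)
.M_RGB2XYZ <- matrix(c(
  0.4124564, 0.3575761, 0.1804375,
  0.2126729, 0.7151522, 0.0721750,
  0.0193339, 0.1191920, 0.9503041
), nrow = 3, byrow = TRUE)
.WHITE_D65 <- c(0.95047, 1.00000, 1.08883)

#' Construct a CIELAB colour-space box
#'
#' A box of permissible prey colours: closed intervals on L (lightness),
#' a (green-red) and b (blue-yellow). The default box spans L 0-100,
#' a -50 to 50 and b -10 to 70, the gamut used for printed prey targets.
#'
#' @param L,a,b length-2 numeric intervals `c(lo, hi)` with `lo <= hi`.
#' @return an object of class `colour_space_box`.
#' @export
#' @examples
#' box <- colour_space_box()
#' box$a
colour_space_box <- function(L = c(0, 100), a = c(-50, 50), b = c(-10, 70)) {
  for (iv in list(L, a, b)) {
    stopifnot(length(iv) == 2, is.finite(iv), iv[1] <= iv[2])
  }
  structure(list(L = as.numeric(L), a = as.numeric(a), b = as.numeric(b)),
    class = "colour_space_box"
  )
}

#' @export
print.colour_space_box <- function(x, ...) {
  cat(sprintf(
    "CIELAB colour box: L [%g, %g], a [%g, %g], b [%g, %g]\n",
    x$L[1], x$L[2], x$a[1], x$a[2], x$b[1], x$b[2]
  ))
  invisible(x)
}

#' Intersect two colour boxes
#' @param x,y `colour_space_box` objects.
#' @return their (non-empty) intersection.
#' @keywords internal
intersect_box <- function(x, y) {
  iv <- function(p, q) c(max(p[1], q[1]), min(p[2], q[2]))
  colour_space_box(iv(x$L, y$L), iv(x$a, y$a), iv(x$b, y$b))
}

#' Construct a receptor-noise-limited visual system
#'
#' Describes the observer used for all colour metrics: a linear map from
#' linear RGB to receptor quantum catches, per-receptor chromatic Weber
#' fractions, an achromatic Weber fraction, and the weights producing the
#' scalar luminance channel. The default is a self-contained stand-in
#' observer (identity receptor matrix, all Weber fractions 0.05); a mapping
#' calibrated for a real animal can be supplied instead, e.g. from JSON.
#'
#' @param receptor_matrix n x 3 non-negative matrix (n receptors, 2-4).
#' @param weber chromatic Weber fractions, length n, all > 0.
#' @param weber_lum achromatic Weber fraction, > 0.
#' @param lum_weights length-3 weights applied to linear RGB for luminance.
#' @param catch_floor smallest admissible quantum catch (keeps logs finite).
#' @return an object of class `visual_system`.
#' @export
visual_system <- function(receptor_matrix = diag(3),
                          weber = rep(0.05, 3),
                          weber_lum = 0.05,
                          lum_weights = rep(1 / 3, 3),
                          catch_floor = 1e-4) {
  receptor_matrix <- as.matrix(receptor_matrix)
  n <- nrow(receptor_matrix)
  stopifnot(
    ncol(receptor_matrix) == 3, n >= 2, n <= 4,
    all(receptor_matrix >= 0), all(rowSums(receptor_matrix) > 0),
    length(weber) == n, all(weber > 0), weber_lum > 0,
    length(lum_weights) == 3, catch_floor > 0
  )
  structure(
    list(
      receptor_matrix = receptor_matrix, weber = as.numeric(weber),
      weber_lum = as.numeric(weber_lum),
      lum_weights = as.numeric(lum_weights),
      catch_floor = as.numeric(catch_floor)
    ),
    class = "visual_system"
  )
}

#' @export
print.visual_system <- function(x, ...) {
  cat(sprintf(
    "visual_system: %d receptors, webers (%s), luminance weber %g\n",
    nrow(x$receptor_matrix), paste(x$weber, collapse = ", "), x$weber_lum
  ))
  invisible(x)
}

#' Read / write a visual system as JSON
#' @param path file path.
#' @return `visual_system_from_json` returns a `visual_system`.
#' @export
visual_system_from_json <- function(path) {
  j <- jsonlite::read_json(path, simplifyVector = TRUE)
  rm <- j$receptor_matrix
  if (!is.matrix(rm)) rm <- do.call(rbind, lapply(rm, as.numeric))
  visual_system(
    receptor_matrix = rm,
    weber = j$weber, weber_lum = j$weber_lum,
    lum_weights = j$lum_weights,
    catch_floor = if (is.null(j$catch_floor)) 1e-4 else j$catch_floor
  )
}

#' @rdname visual_system_from_json
#' @param vs a `visual_system`.
#' @export
visual_system_to_json <- function(vs, path) {
  j <- list(
    receptor_matrix = lapply(seq_len(nrow(vs$receptor_matrix)),
                             function(i) as.numeric(vs$receptor_matrix[i, ])),
    weber = vs$weber, weber_lum = vs$weber_lum,
    lum_weights = vs$lum_weights, catch_floor = vs$catch_floor
  )
  jsonlite::write_json(j, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

# sRGB electro-optical transfer: [0,1] companded <-> linear
srgb_linearise <- function(s) {
  ifelse(s <= 0.04045, s / 12.92, ((s + 0.055) / 1.055)^2.4)
}
srgb_delinearise <- function(v) {
  v <- pmax(v, 0)
  ifelse(v <= 0.0031308, 12.92 * v, 1.055 * v^(1 / 2.4) - 0.055)
}

#' Convert CIELAB colours to 8-bit sRGB
#'
#' Standard CIE Lab -> XYZ (D65, 2 degrees) -> linear RGB -> sRGB gamma.
#' Out-of-gamut channels are clipped to \[0, 255\]; the conversion is total
#' on finite inputs and never fails.
#'
#' @param lab numeric length-3 `c(L, a, b)` or an n x 3 matrix.
#' @return integer matrix n x 3 of sRGB values in \[0, 255\].
#' @export
#' @examples
#' lab_to_srgb(c(100, 0, 0)) # white
lab_to_srgb <- function(lab) {
  lab <- rbind_colour(lab)
  fy <- (lab[, 1] + 16) / 116
  fx <- fy + lab[, 2] / 500
  fz <- fy - lab[, 3] / 200
  finv <- function(t) {
    d <- 6 / 29
    ifelse(t > d, t^3, 3 * d^2 * (t - 4 / 29))
  }
  xyz <- cbind(finv(fx) * .WHITE_D65[1], finv(fy) * .WHITE_D65[2],
               finv(fz) * .WHITE_D65[3])
  lin <- xyz %*% t(.M_XYZ2RGB)
  srgb <- srgb_delinearise(pmin(pmax(lin, 0), 1e6))
  out <- round(pmin(pmax(srgb, 0), 1) * 255)
  storage.mode(out) <- "integer"
  colnames(out) <- c("R", "G", "B")
  out
}

#' Convert 8-bit sRGB colours to CIELAB
#'
#' Inverse companion of [lab_to_srgb()]; same D65 / 2 degree reference.
#'
#' @param rgb numeric length-3 in \[0, 255\] or an n x 3 matrix.
#' @return numeric matrix n x 3 with columns L, a, b.
#' @export
srgb_to_lab <- function(rgb) {
  rgb <- rbind_colour(rgb)
  lin <- srgb_linearise(rgb / 255)
  xyz <- lin %*% t(.M_RGB2XYZ)
  xr <- xyz[, 1] / .WHITE_D65[1]
  yr <- xyz[, 2] / .WHITE_D65[2]
  zr <- xyz[, 3] / .WHITE_D65[3]
  f <- function(t) {
    d <- 6 / 29
    ifelse(t > d^3, t^(1 / 3), t / (3 * d^2) + 4 / 29)
  }
  fx <- f(xr)
  fy <- f(yr)
  fz <- f(zr)
  out <- cbind(L = 116 * fy - 16, a = 500 * (fx - fy), b = 200 * (fy - fz))
  out
}

rbind_colour <- function(x) {
  if (is.null(dim(x))) {
    stopifnot(length(x) == 3)
    x <- matrix(as.numeric(x), nrow = 1)
  }
  stopifnot(ncol(x) == 3, all(is.finite(x)))
  x
}

#' Receptor quantum catches of an sRGB colour
#'
#' Linearises the sRGB triple and multiplies by the visual system's
#' receptor matrix; catches are floored at `vs$catch_floor` so log
#' contrasts stay defined. This stands in for camera-based cone-catch
#' estimation, which needs calibrated photography.
#'
#' @param rgb sRGB triple in \[0, 255\] or n x 3 matrix.
#' @param vs a [visual_system()].
#' @return numeric matrix n x n_receptors of catches.
#' @export
srgb_to_catches <- function(rgb, vs) {
  rgb <- rbind_colour(rgb)
  lin <- srgb_linearise(rgb / 255)
  linear_to_catches(lin, vs)
}

# catches from linear-RGB rows (internal: metrics average in linear RGB)
linear_to_catches <- function(lin, vs) {
  q <- lin %*% t(vs$receptor_matrix)
  pmax(q, vs$catch_floor)
}

# scalar luminance of linear-RGB rows
linear_to_lum <- function(lin, vs) {
  pmax(as.numeric(lin %*% vs$lum_weights), vs$catch_floor)
}

#' Receptor-noise-limited chromatic distance
#'
#' The general n-receptor receptor-noise-limited (RNL) distance between two
#' sets of quantum catches, in just-noticeable-difference (JND) units. Log
#' contrasts `df_i = ln(qA_i / qB_i)` are combined as
#' \deqn{\Delta S^2 = \frac{\sum_{i<j} \left(\prod_{k \ne i,j} e_k\right)^2
#'   (\Delta f_i - \Delta f_j)^2}{\sum_i \left(\prod_{k \ne i} e_k\right)^2}}
#' which reduces to the familiar dichromat and trichromat closed forms.
#'
#' @param qA,qB catch vectors (or matrices, row-wise) of the system's
#'   dimensionality.
#' @param vs a [visual_system()].
#' @return non-negative distance(s) in JND.
#' @export
#' @examples
#' vs <- visual_system(diag(3))
#' rnl_chromatic(c(1.1, 1, 1), c(1, 1, 1), vs)
rnl_chromatic <- function(qA, qB, vs) {
  n <- nrow(vs$receptor_matrix)
  qA <- rbind_catch(qA, n)
  qB <- rbind_catch(qB, n)
  stopifnot(nrow(qA) == nrow(qB))
  e <- vs$weber
  df <- log(pmax(qA, vs$catch_floor)) - log(pmax(qB, vs$catch_floor))
  num <- 0
  for (i in seq_len(n - 1)) {
    for (j in seq((i + 1), n)) {
      w <- prod(e[-c(i, j)])^2 # empty product = 1 for dichromats
      num <- num + w * (df[, i] - df[, j])^2
    }
  }
  den <- sum(vapply(seq_len(n), function(i) prod(e[-i])^2, numeric(1)))
  sqrt(num / den)
}

rbind_catch <- function(q, n) {
  if (is.null(dim(q))) {
    if (length(q) != n) stop("catch dimensionality does not match visual system")
    q <- matrix(as.numeric(q), nrow = 1)
  }
  if (ncol(q) != n) stop("catch dimensionality does not match visual system")
  q
}

#' Receptor-noise-limited achromatic distance
#'
#' `deltaL = |ln(lumA / lumB)| / weber_lum`, in JND units. Luminances are
#' floored at `vs$catch_floor` so the log is always defined.
#'
#' @param lumA,lumB positive scalar luminances (vectorised).
#' @param vs a [visual_system()].
#' @return non-negative distance(s) in JND.
#' @export
rnl_achromatic <- function(lumA, lumB, vs) {
  lumA <- pmax(lumA, vs$catch_floor)
  lumB <- pmax(lumB, vs$catch_floor)
  abs(log(lumA / lumB)) / vs$weber_lum
}

#' Narrow colour box derived from a background image
#'
#' Per CIELAB channel over all background pixels, the box spans
#' `mean - k * sd` to `mean + k * sd` (default k = 2), intersected with the
#' full box. Populations started from such a box are background-biased
#' from generation 0, which is the "narrow colour space" condition.
#'
#' @param bg background image: H x W x 3 sRGB array in \[0, 1\].
#' @param k half-width in standard deviations (default 2).
#' @param full_box the enclosing box (default [colour_space_box()]).
#' @return a `colour_space_box`.
#' @export
narrow_space_from_background <- function(bg, k = 2,
                                         full_box = colour_space_box()) {
  stopifnot(k > 0)
  px <- image_to_rgb_rows(bg)
  if (nrow(px) == 0) stop("empty background image")
  lab <- srgb_to_lab(px * 255)
  m <- colMeans(lab)
  s <- apply(lab, 2, sd)
  s[is.na(s)] <- 0 # single-pixel image
  box <- colour_space_box(
    L = c(m[1] - k * s[1], m[1] + k * s[1]),
    a = c(m[2] - k * s[2], m[2] + k * s[2]),
    b = c(m[3] - k * s[3], m[3] + k * s[3])
  )
  intersect_box(box, full_box)
}

# H x W x 3 array -> N x 3 matrix of sRGB [0,1] rows
image_to_rgb_rows <- function(img, mask = NULL) {
  stopifnot(length(dim(img)) == 3, dim(img)[3] >= 3)
  n <- dim(img)[1] * dim(img)[2]
  px <- cbind(
    as.vector(img[, , 1]), as.vector(img[, , 2]),
    as.vector(img[, , 3])
  )
  if (!is.null(mask)) px <- px[as.vector(mask), , drop = FALSE]
  px
}
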