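# Low-level image helpers. Images are H x W x 3 sRGB arrays in [0, 1]
# (the convention of png::readPNG); masks are H x W logicals; single
# channels are H x W matrices.

# Frequency grids for an H x W FFT, cycles per pixel in [-0.5, 0.5)
freq_grid <- function(h, w) {
  fy <- (seq_len(h) - 1) / h
  fy <- ifelse(fy >= 0.5, fy - 1, fy)
  fx <- (seq_len(w) - 1) / w
  fx <- ifelse(fx >= 0.5, fx - 1, fx)
  list(fy = matrix(fy, h, w), fx = matrix(fx, h, w, byrow = TRUE))
}

#' Gaussian blur of a matrix (FFT, circular boundary)
#'
#' Anisotropic Gaussian smoothing with axis standard deviations
#' `sigma_u`/`sigma_v` (px) rotated by `theta`. Implemented in the
#' frequency domain, so it is exact, fast, and deterministic.
#'
#' @param mat numeric matrix.
#' @param sigma_u,sigma_v standard deviations along the rotated axes (px).
#' @param theta rotation of the kernel axes (radians).
#' @return blurred matrix of the same size.
#' @keywords internal
gaussian_blur <- function(mat, sigma_u, sigma_v = sigma_u, theta = 0) {
  if (sigma_u <= 0 && sigma_v <= 0) return(mat)
  h <- nrow(mat)
  w <- ncol(mat)
  fg <- freq_grid(h, w)
  fu <- cos(theta) * fg$fx + sin(theta) * fg$fy
  fv <- -sin(theta) * fg$fx + cos(theta) * fg$fy
  resp <- exp(-2 * pi^2 * (sigma_u^2 * fu^2 + sigma_v^2 * fv^2))
  Re(fft(fft(mat) * resp, inverse = TRUE)) / (h * w)
}

# Hard annular octave band-pass: keeps wavelengths in [s/sqrt(2), s*sqrt(2))
bandpass_annulus <- function(mat, scale_px) {
  h <- nrow(mat)
  w <- ncol(mat)
  fg <- freq_grid(h, w)
  fr <- sqrt(fg$fx^2 + fg$fy^2)
  lam <- ifelse(fr > 0, 1 / fr, Inf)
  keep <- lam >= scale_px / sqrt(2) & lam < scale_px * sqrt(2)
  Re(fft(fft(mat) * keep, inverse = TRUE)) / (h * w)
}

#' Centred elliptical mask
#' @param h,w image size in px; the ellipse is inscribed in the full frame.
#' @return H x W logical matrix.
#' @keywords internal
mask_ellipse <- function(h, w) {
  cy <- (h + 1) / 2
  cx <- (w + 1) / 2
  y <- matrix(seq_len(h), h, w)
  x <- matrix(seq_len(w), h, w, byrow = TRUE)
  ((x - cx) / (w / 2))^2 + ((y - cy) / (h / 2))^2 <= 1
}

# apply fn to each channel of an H x W x 3 array
map_channels <- function(img, fn) {
  out <- img
  for (c in 1:3) out[, , c] <- fn(img[, , c])
  out
}

#' Composite a target onto a background image
#'
#' Places the target's masked pixels over the background with the target
#' centre at `(cy, cx)` (image row/column). Pixels falling outside the
#' background are dropped.
#'
#' @param bg H x W x 3 background array.
#' @param target a `target_image` (see [render_target()]).
#' @param cy,cx centre position (defaults: background centre).
#' @return list: `img` (composited array), `mask` (target mask in
#'   background coordinates).
#' @export
composite_target <- function(bg, target, cy = NULL, cx = NULL) {
  hb <- dim(bg)[1]; wb <- dim(bg)[2]
  ht <- dim(target$rgb)[1]; wt <- dim(target$rgb)[2]
  if (is.null(cy)) cy <- round(hb / 2)
  if (is.null(cx)) cx <- round(wb / 2)
  y0 <- round(cy - ht / 2)
  x0 <- round(cx - wt / 2)
  ys <- seq_len(ht) + y0
  xs <- seq_len(wt) + x0
  keep_y <- ys >= 1 & ys <= hb
  keep_x <- xs >= 1 & xs <= wb
  out <- bg
  full_mask <- matrix(FALSE, hb, wb)
  tm <- target$alpha_mask[keep_y, keep_x, drop = FALSE]
  full_mask[ys[keep_y], xs[keep_x]][tm] <- TRUE
  for (c in 1:3) {
    sub <- out[ys[keep_y], xs[keep_x], c]
    tc <- target$rgb[keep_y, keep_x, c]
    sub[tm] <- tc[tm]
    out[ys[keep_y], xs[keep_x], c] <- sub
  }
  list(img = out, mask = full_mask)
}

#' Write / read an image as PNG
#' @param img H x W x 3 array in \[0,1\] (write) / file path (read).
#' @param path output path.
#' @return `write_image` invisibly returns `path`; `read_image` an array.
#' @export
write_image <- function(img, path) {
  png::writePNG(img, path)
  invisible(path)
}

#' @rdname write_image
#' @export
read_image <- function(path) {
  img <- png::readPNG(path)
  if (length(dim(img)) == 2) img <- array(rep(img, 3), c(dim(img), 3))
  img[, , 1:3, drop = FALSE]
}
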