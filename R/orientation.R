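# Structure-tensor dominant orientation.
#
# Images are plain numeric matrices indexed [row, col] with row 1 displayed
# at the top. The biological display convention (viewed from the
# culture-medium side): theta = 0 along the horizontal long axis, theta > 0
# for left-down -> right-up texture (CCW), theta < 0 for left-up ->
# right-down (CW). Internally gradients use y = row (pointing down), so the
# display angle is the negated math angle; the synthetic stripe tests lock
# this sign once and the fiducial flip check guards it upstream.

gaussian_kernel <- function(sigma) {
  r <- max(1L, ceiling(3 * sigma))
  g <- exp(-((-r:r)^2) / (2 * sigma^2))
  g / sum(g)
}

# derivative-of-Gaussian kernel, normalised so that filtering a unit ramp
# returns exactly 1 (i.e. the kernel measures d/dindex)
gaussian_deriv_kernel <- function(sigma) {
  r <- max(1L, ceiling(3 * sigma))
  x <- -r:r
  d <- -x * exp(-(x^2) / (2 * sigma^2))
  ramp <- seq_len(6 * r + 9)
  resp <- stats::filter(ramp, d, method = "convolution", sides = 2)
  d / resp[3 * r + 4]
}

# convolve along the row index (vertical) with a centred kernel
conv_vert <- function(im, k) {
  out <- stats::filter(im, k, method = "convolution", sides = 2)
  matrix(out, nrow = nrow(im), ncol = ncol(im))
}

conv_horiz <- function(im, k) {
  t(conv_vert(t(im), k))
}

#' Structure tensor of an image region
#'
#' Gaussian-derivative gradients `fx` (along columns, display x) and `fy`
#' (along rows, display y), averaged with uniform weights over the interior
#' of the region (a border of 3 sigma, where the convolution is incomplete,
#' is excluded): `Jxx = <fx^2>`, `Jxy = <fx fy>`, `Jyy = <fy^2>`.
#'
#' @param image Numeric matrix, at least 8 x 8 pixels.
#' @param grad_sigma Gaussian derivative scale in pixels, default 1.
#' @return A list with elements `Jxx`, `Jxy`, `Jyy`.
#' @export
structure_tensor <- function(image, grad_sigma = 1) {
  g <- image_gradients(image, grad_sigma)
  list(Jxx = mean(g$fx^2), Jxy = mean(g$fx * g$fy), Jyy = mean(g$fy^2))
}

# shared gradient computation; returns interior-trimmed fx, fy
image_gradients <- function(image, grad_sigma = 1) {
  if (!is.matrix(image) || !is.numeric(image)) {
    stop("image must be a numeric matrix", call. = FALSE)
  }
  if (nrow(image) < 8 || ncol(image) < 8) {
    stop("image must be at least 8 x 8 pixels", call. = FALSE)
  }
  stopifnot(grad_sigma > 0)
  g <- gaussian_kernel(grad_sigma)
  d <- gaussian_deriv_kernel(grad_sigma)
  r <- (length(g) - 1L) / 2L
  fx <- conv_vert(conv_horiz(image, d), g)   # d/dcol, smoothed in rows
  fy <- conv_horiz(conv_vert(image, d), g)   # d/drow, smoothed in cols
  rows <- (r + 1):(nrow(image) - r)
  cols <- (r + 1):(ncol(image) - r)
  if (length(rows) < 1 || length(cols) < 1) {
    stop("image too small for this grad_sigma", call. = FALSE)
  }
  list(fx = fx[rows, cols], fy = fy[rows, cols], r = r)
}

#' Dominant orientation of an image region
#'
#' Eigen-analysis of the region-averaged structure tensor. The gradient-
#' dominant direction is `theta_raw = atan2(2 Jxy, Jxx - Jyy) / 2`; the
#' texture runs perpendicular to it, and the result is expressed in the
#' display convention (theta > 0 = left-down to right-up as displayed) on
#' (-90, 90]. Coherence is the normalised eigenvalue anisotropy
#' `sqrt((Jxx - Jyy)^2 + 4 Jxy^2) / (Jxx + Jyy)` in [0, 1]; `energy` is the
#' tensor trace. Regions with energy below a scale-free epsilon (blank
#' crops) are flagged indeterminate rather than raising an error.
#'
#' @inheritParams structure_tensor
#' @return A one-row tibble: `theta_deg`, `coherence`, `energy`,
#'   `indeterminate`.
#' @examples
#' im <- fiber_texture(64, 128, theta_deg = 30, scene_params(noise_sd = 0))
#' dominant_orientation(im)
#' @export
dominant_orientation <- function(image, grad_sigma = 1) {
  J <- structure_tensor(image, grad_sigma)
  energy <- J$Jxx + J$Jyy
  eps <- 1e-12 * (stats::var(as.vector(image)) + 1)
  if (!is.finite(energy) || energy < eps) {
    return(tibble::tibble(theta_deg = NA_real_, coherence = NA_real_,
                          energy = energy, indeterminate = TRUE))
  }
  theta_raw <- rad2deg(atan2(2 * J$Jxy, J$Jxx - J$Jyy) / 2)
  texture_math <- theta_raw + 90          # texture direction, y pointing down
  theta_deg <- wrap_axial(-texture_math)  # display convention, y up
  coherence <- sqrt((J$Jxx - J$Jyy)^2 + 4 * J$Jxy^2) / energy
  tibble::tibble(theta_deg = theta_deg,
                 coherence = min(1, coherence),
                 energy = energy, indeterminate = FALSE)
}

#' Per-pixel orientation map
#'
#' Local dominant orientation from the structure tensor smoothed with a
#' Gaussian window (`window_sigma`); intended for qualitative QC color maps
#' of fiber direction, not for the per-rectangle statistics.
#'
#' @inheritParams structure_tensor
#' @param window_sigma Tensor-averaging window scale in pixels.
#' @return A numeric matrix of display-convention angles in degrees
#'   ((-90, 90]); pixels with negligible local energy are `NA`.
#' @export
orientation_map <- function(image, grad_sigma = 1, window_sigma = 4) {
  stopifnot(window_sigma > 0)
  g <- image_gradients(image, grad_sigma)
  w <- gaussian_kernel(window_sigma)
  sm <- function(m) conv_vert(conv_horiz(m, w), w)
  Jxx <- sm(g$fx^2); Jxy <- sm(g$fx * g$fy); Jyy <- sm(g$fy^2)
  energy <- Jxx + Jyy
  eps <- 1e-12 * (stats::var(as.vector(image)) + 1)
  theta <- wrap_axial(-(rad2deg(atan2(2 * Jxy, Jxx - Jyy) / 2) + 90))
  theta[!is.finite(energy) | energy < eps] <- NA_real_
  theta
}
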