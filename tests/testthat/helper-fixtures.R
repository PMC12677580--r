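# Shared fixtures (built once per test run) and independent oracles.

.fixtures <- new.env(parent = emptyenv())

# Moderate synthetic scene reused across cropping/pipeline tests:
# 60 rectangles, default study-condition angle law (mu = -8, kappa = 6),
# mixed coverage straddling the 80% threshold.
test_scene <- function() {
  if (is.null(.fixtures$scene)) {
    g <- grid_spec(n_rectangles = 60, layout_diameter = 8200, um_per_px = 2)
    .fixtures$scene <- generate_scene(g, scene_params(seed = 11))
  }
  .fixtures$scene
}

# Oracle: axial circular mean by direct summation of doubled unit vectors,
# written independently of the package's estimator.
oracle_axial_mean <- function(theta_deg) {
  a <- 2 * theta_deg * pi / 180
  atan2(sum(sin(a)), sum(cos(a))) * 180 / pi / 2
}

# Oracle: rotate an image by delta degrees in the display convention
# (positive delta rotates texture direction from 0 towards +90, i.e.
# left-down -> right-up), by inverse-mapped bilinear interpolation.
rotate_display <- function(im, delta_deg) {
  nr <- nrow(im); nc <- ncol(im)
  cr <- (nr + 1) / 2; cc <- (nc + 1) / 2
  th <- delta_deg * pi / 180
  col_g <- matrix(rep(seq_len(nc), each = nr), nr, nc)
  row_g <- matrix(rep(seq_len(nr), times = nc), nr, nc)
  x <- col_g - cc
  yup <- -(row_g - cr)
  x0 <- cos(th) * x + sin(th) * yup     # inverse rotation R(-delta)
  y0 <- -sin(th) * x + cos(th) * yup
  in_col <- cc + x0
  in_row <- cr - y0
  r1 <- floor(in_row); c1 <- floor(in_col)
  fr <- in_row - r1; fc <- in_col - c1
  ok <- r1 >= 1 & c1 >= 1 & r1 + 1 <= nr & c1 + 1 <= nc
  out <- matrix(NA_real_, nr, nc)
  idx <- function(r, c) (c - 1) * nr + r
  out[ok] <- (1 - fr[ok]) * (1 - fc[ok]) * im[idx(r1[ok], c1[ok])] +
    (1 - fr[ok]) * fc[ok] * im[idx(r1[ok], c1[ok] + 1)] +
    fr[ok] * (1 - fc[ok]) * im[idx(r1[ok] + 1, c1[ok])] +
    fr[ok] * fc[ok] * im[idx(r1[ok] + 1, c1[ok] + 1)]
  out
}

# central square crop free of NA borders after rotation
central_crop <- function(im, frac = 0.5) {
  nr <- nrow(im); nc <- ncol(im)
  r <- floor(nr * frac / 2); c <- floor(nc * frac / 2)
  im[(floor(nr / 2) - r):(floor(nr / 2) + r),
     (floor(nc / 2) - c):(floor(nc / 2) + c)]
}
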