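# Synthetic micropattern scenes with known ground truth.

#' Synthetic scene parameters
#'
#' Parameters of the synthetic fibrous textures and of the per-rectangle
#' alignment-angle law. The texture is an oriented sinusoid (band-limited
#' stripe pattern, closed-form structure-tensor response) riding on a dim
#' uniform base that emulates diffuse cytoplasmic phalloidin signal, plus
#' optional additive Gaussian noise. Per-rectangle dominant angles are
#' drawn from the axial von Mises law of [sample_axial_angles()].
#'
#' @param mu_deg Axial mean alignment angle, degrees in (-90, 90]
#'   (default -8, a clockwise-aligned population).
#' @param kappa von Mises concentration on the doubled circle (default 6).
#' @param fiber_wavelength Stripe wavelength, um (default 20; the scale of
#'   aligned actin-bundle spacing).
#' @param fiber_contrast Stripe amplitude on the [0, 1] intensity scale
#'   (default 0.6).
#' @param noise_sd Additive Gaussian noise SD, intensity units
#'   (default 0.02).
#' @param coverage Per-rectangle cell-coverage fractions: a single number,
#'   a vector recycled over rectangles, or a `function(n)` returning `n`
#'   fractions in `[0, 1]`. The default mixture draws 80% of rectangles
#'   near-confluent (uniform on 0.88-1) and 20% sparse (uniform on
#'   0.40-0.70), straddling the 0.8 inclusion threshold while avoiding its
#'   immediate neighbourhood.
#' @param background_level Background intensity (default 0.05).
#' @param f_mark_mirrored Render the fiducial mirrored (test fixture for
#'   the flip detector), default `FALSE`.
#' @param seed Integer seed fixing the whole scene (default 1).
#' @return An object of class `scene_params` (a named list).
#' @export
scene_params <- function(mu_deg = -8, kappa = 6, fiber_wavelength = 20,
                         fiber_contrast = 0.6, noise_sd = 0.02,
                         coverage = coverage_mixture(),
                         background_level = 0.05,
                         f_mark_mirrored = FALSE, seed = 1L) {
  stopifnot(kappa >= 0, fiber_wavelength > 0,
            fiber_contrast >= 0, fiber_contrast <= 1,
            noise_sd >= 0, background_level >= 0, background_level < 1)
  structure(list(mu_deg = wrap_axial(mu_deg), kappa = kappa,
                 fiber_wavelength = fiber_wavelength,
                 fiber_contrast = fiber_contrast, noise_sd = noise_sd,
                 coverage = coverage, background_level = background_level,
                 f_mark_mirrored = isTRUE(f_mark_mirrored),
                 seed = as.integer(seed)),
            class = "scene_params")
}

#' Default coverage mixture straddling the 80% inclusion threshold
#'
#' @param p_confluent Fraction of near-confluent rectangles (default 0.8).
#' @param high,low Length-2 uniform ranges for confluent and sparse
#'   rectangles (defaults `c(0.88, 1)` and `c(0.40, 0.70)`).
#' @return A `function(n)` drawing `n` coverage fractions.
#' @export
coverage_mixture <- function(p_confluent = 0.8, high = c(0.88, 1),
                             low = c(0.40, 0.70)) {
  force(p_confluent); force(high); force(low)
  function(n) {
    conf <- stats::runif(n) < p_confluent
    ifelse(conf, stats::runif(n, high[1], high[2]),
           stats::runif(n, low[1], low[2]))
  }
}

#' Oriented fiber texture
#'
#' Grayscale stripe texture whose intensity ridges run along `theta_deg` in
#' the display convention (theta > 0 = left-down to right-up as displayed):
#' `I = bg + contrast * (0.65 + 0.35 cos(2 pi (x sin t + y cos t) / lambda))`
#' with `x` along columns, `y` along rows, plus Gaussian noise. With
#' `theta_deg = 0` every row is constant; with `theta_deg = 90` every
#' column is constant.
#'
#' @param height_px,width_px Image size in pixels (>= 16 each).
#' @param theta_deg Stripe direction, degrees in (-90, 90].
#' @param params A [scene_params()]; uses `fiber_wavelength` (um, converted
#'   with `um_per_px`), `fiber_contrast`, `background_level`, `noise_sd`.
#' @param um_per_px Image scale (default 2).
#' @param phase Stripe phase in radians (default 0; the scene generator
#'   randomises it per rectangle).
#' @return Numeric matrix in `[0, 1]`.
#' @export
fiber_texture <- function(height_px, width_px, theta_deg,
                          params = scene_params(), um_per_px = 2,
                          phase = 0) {
  if (height_px < 16 || width_px < 16) {
    stop("texture dimensions must be at least 16 px", call. = FALSE)
  }
  if (!is.numeric(theta_deg) || length(theta_deg) != 1 ||
      theta_deg <= -90 || theta_deg > 90) {
    stop("theta_deg must lie in (-90, 90]", call. = FALSE)
  }
  lam_px <- params$fiber_wavelength / um_per_px
  s <- sinpi(theta_deg / 180)   # exact at 0 and 90
  co <- cospi(theta_deg / 180)
  k <- 2 * pi / lam_px
  # phase varies perpendicular to the stripe direction (c*sin + r*cos)
  px <- k * s * seq_len(width_px)
  py <- k * co * seq_len(height_px)
  im <- params$background_level + params$fiber_contrast *
    (0.65 + 0.35 * cos(outer(py, px, `+`) + phase))
  if (params$noise_sd > 0) {
    im <- im + stats::rnorm(length(im), sd = params$noise_sd)
  }
  pmin(pmax(im, 0), 1)
}

#' Render the "F" fiducial glyph
#'
#' Binary mask of a non-mirrored (or mirrored) "F", 360 x 600 um with
#' 80 um strokes. The glyph is intrinsically chiral: a mirrored image of
#' the tape matches the mirrored template better than the original, which
#' is how accidental image flips (that would invert every chirality call)
#' are caught.
#'
#' @param um_per_px Image scale.
#' @param mirrored Mirror the glyph left-right.
#' @return Logical matrix (rows x cols = 600/um_per_px x 360/um_per_px).
#' @export
render_f_glyph <- function(um_per_px = 2, mirrored = FALSE) {
  h <- round(600 / um_per_px); w <- round(360 / um_per_px)
  stroke <- max(2L, round(80 / um_per_px))
  m <- matrix(FALSE, h, w)
  m[, seq_len(stroke)] <- TRUE                               # vertical bar
  m[seq_len(stroke), ] <- TRUE                               # top arm
  mid0 <- round(260 / um_per_px)
  m[(mid0 + 1):min(h, mid0 + stroke), seq_len(round(280 / um_per_px))] <- TRUE
  if (mirrored) m <- m[, rev(seq_len(ncol(m)))]
  m
}

#' Generate a synthetic stitched micropattern scene
#'
#' Renders the full tape: fiber-textured rectangles at the [grid_layout()]
#' positions, an "F" glyph at the tape center, background elsewhere, and
#' per-rectangle coverage (a centered sub-rectangle of equal aspect ratio
#' holding `sqrt(coverage)`-scaled sides carries texture). Each
#' rectangle's true dominant angle `theta_true_deg` is drawn from the
#' axial von Mises law in the tape frame; textures in vertical rectangles
#' are rotated +90 so that after the pipeline's 90-degree clockwise
#' rotation the recovered angle equals the tape-frame truth. The scene is
#' bit-reproducible for a fixed `params$seed`.
#'
#' @param grid A [grid_spec()].
#' @param params A [scene_params()].
#' @return An object of class `micropattern_scene`: list with `image`
#'   (numeric matrix in `[0, 1]`), `truth` (tibble: `rect_id`,
#'   `orientation`, `theta_true_deg`, `coverage`, `expected_included`,
#'   `center_row_px`, `center_col_px`), `grid` (with `f_mark_anchor`
#'   filled in), and `params`.
#' @export
generate_scene <- function(grid = grid_spec(), params = scene_params()) {
  stopifnot(inherits(grid, "grid_spec"), inherits(params, "scene_params"))
  set.seed(params$seed)
  upp <- grid$um_per_px
  lay <- grid_layout(grid)
  n <- nrow(lay)
  npx <- ceiling(grid$layout_diameter / upp)
  c0 <- (npx + 1) / 2  # tape center in (fractional) pixel coordinates
  theta_true <- sample_axial_angles(n, params$mu_deg, params$kappa)$theta_deg
  cov <- if (is.function(params$coverage)) params$coverage(n)
         else rep_len(params$coverage, n)
  if (any(cov < 0 | cov > 1)) stop("coverage fractions must be in [0, 1]", call. = FALSE)
  phases <- stats::runif(n, 0, 2 * pi)
  img <- matrix(params$background_level, npx, npx)
  noiseless <- params
  noiseless$noise_sd <- 0  # global noise added once at the end
  for (i in seq_len(n)) {
    o <- lay$orientation[i]
    rw <- if (o == "horizontal") grid$rect_length else grid$rect_width
    rh <- if (o == "horizontal") grid$rect_width else grid$rect_length
    # covered sub-rectangle: equal aspect, sides scaled by sqrt(coverage)
    sc <- sqrt(cov[i])
    cw_px <- max(16L, round(rw * sc / upp))
    ch_px <- max(16L, round(rh * sc / upp))
    r0 <- round(c0 + lay$cy_um[i] / upp - ch_px / 2)
    cl0 <- round(c0 + lay$cx_um[i] / upp - cw_px / 2)
    th_tex <- if (o == "horizontal") theta_true[i] else wrap_axial(theta_true[i] + 90)
    tex <- fiber_texture(ch_px, cw_px, th_tex, noiseless, upp, phase = phases[i])
    img[r0:(r0 + ch_px - 1), cl0:(cl0 + cw_px - 1)] <- tex
  }
  glyph <- render_f_glyph(upp, mirrored = params$f_mark_mirrored)
  g_r0 <- round(c0 - 300 / upp); g_c0 <- round(c0 - 180 / upp)
  patch <- img[g_r0:(g_r0 + nrow(glyph) - 1), g_c0:(g_c0 + ncol(glyph) - 1)]
  patch[glyph] <- 0.9
  img[g_r0:(g_r0 + nrow(glyph) - 1), g_c0:(g_c0 + ncol(glyph) - 1)] <- patch
  if (params$noise_sd > 0) {
    # chunked to bound peak memory on full-size canvases
    step <- max(1L, floor(2e7 / npx))
    for (r in seq(1L, npx, by = step)) {
      rr <- r:min(npx, r + step - 1L)
      img[rr, ] <- img[rr, ] + stats::rnorm(length(rr) * npx, sd = params$noise_sd)
    }
    img <- pmin(pmax(img, 0), 1)
  }
  grid$f_mark_anchor <- c(g_r0, g_c0)
  truth <- tibble::tibble(
    rect_id = lay$rect_id, orientation = lay$orientation,
    theta_true_deg = theta_true, coverage = cov,
    expected_included = cov >= 0.8,
    center_row_px = c0 + lay$cy_um / upp,
    center_col_px = c0 + lay$cx_um / upp)
  structure(list(image = img, truth = truth, grid = grid, params = params),
            class = "micropattern_scene")
}

#' @export
print.micropattern_scene <- function(x, ...) {
  cat(sprintf("Synthetic micropattern scene: %d x %d px, %d rectangles (%d expected included)\n",
              nrow(x$image), ncol(x$image), nrow(x$truth),
              sum(x$truth$expected_included)))
  invisible(x)
}

#' Write a scene to disk (16-bit TIFF + ground-truth CSV)
#'
#' @param scene A [generate_scene()] result.
#' @param dir Output directory (created if needed).
#' @return Invisibly, the paths written (`tiff`, `truth`, `grid`).
#' @export
write_scene <- function(scene, dir) {
  stopifnot(inherits(scene, "micropattern_scene"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  tif <- file.path(dir, "scene.tif")
  tiff::writeTIFF(scene$image, tif, bits.per.sample = 16)
  truth_csv <- file.path(dir, "ground_truth.csv")
  readr::write_csv(scene$truth, truth_csv)
  grid_yaml <- file.path(dir, "grid.yaml")
  g <- scene$grid
  g$f_mark_anchor <- as.integer(g$f_mark_anchor)
  yaml::write_yaml(unclass(g), grid_yaml)
  invisible(list(tiff = tif, truth = truth_csv, grid = grid_yaml))
}

#' Read a single-channel TIFF as a numeric matrix
#'
#' @param path TIFF file path.
#' @return Numeric matrix in `[0, 1]` (first channel if multi-channel).
#' @export
read_image_tiff <- function(path) {
  im <- tiff::readTIFF(path)
  if (length(dim(im)) == 3) im <- im[, , 1]
  im
}

#' Read a grid specification from YAML
#'
#' @param path YAML file with `grid_spec` fields.
#' @return A [grid_spec()].
#' @export
read_grid_yaml <- function(path) {
  y <- yaml::read_yaml(path)
  keep <- intersect(names(y), names(formals(grid_spec)))
  do.call(grid_spec, y[keep])
}
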