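test_that("angle sampler honours the concentration limit and rejects bad input", {
  s <- sample_axial_angles(5, mu_deg = 20, kappa = 1e8, seed = 1)$theta_deg
  expect_true(all(abs(s - 20) < 0.01))
  expect_error(sample_axial_angles(0, 0, 1, seed = 1), "positive count")
  expect_error(sample_axial_angles(5, 0, -1, seed = 1), "non-negative")
})

test_that("fiber textures have the stated separable structure", {
  p <- scene_params(noise_sd = 0)
  h <- fiber_texture(32, 48, 0, p)
  expect_equal(max(apply(h, 1, function(r) diff(range(r)))), 0)
  v <- fiber_texture(32, 48, 90, p)
  expect_equal(max(apply(v, 2, function(cc) diff(range(cc)))), 0)
  r30 <- dominant_orientation(fiber_texture(64, 64, 30, p))
  expect_lt(abs(axial_diff(r30$theta_deg, 30)), 0.5)
  expect_error(fiber_texture(32, 48, 135, p), "-90, 90")
  expect_error(fiber_texture(8, 48, 0, p), "16 px")
})

test_that("the default layout places the full rectangle count inside the circle", {
  lay <- grid_layout(grid_spec())
  expect_equal(nrow(lay), 453)
  expect_equal(lay$rect_id, seq_len(453))
  # every cell (rectangle plus half-gap margins) fits inside the circle
  half_diag <- sqrt((lay$cell_w_um / 2)^2 + (lay$cell_h_um / 2)^2)
  corner <- sqrt((abs(lay$cx_um) + lay$cell_w_um / 2)^2 +
                 (abs(lay$cy_um) + lay$cell_h_um / 2)^2)
  expect_true(all(corner <= 19000 / 2 + 1e-6))
  expect_true(all(c("horizontal", "vertical") %in% lay$orientation))
  # mixed orientations in roughly equal shares at the default mix
  expect_gt(mean(lay$orientation == "vertical"), 0.3)
  expect_lt(mean(lay$orientation == "vertical"), 0.7)
})

test_that("scene generation is bit-deterministic for a fixed seed", {
  g <- grid_spec(n_rectangles = 8, layout_diameter = 4000, um_per_px = 4)
  p <- scene_params(seed = 33)
  s1 <- generate_scene(g, p)
  s2 <- generate_scene(g, p)
  expect_identical(s1$image, s2$image)
  expect_identical(s1$truth, s2$truth)
  s3 <- generate_scene(g, scene_params(seed = 34))
  expect_false(identical(s1$image, s3$image))
})

test_that("ground truth marks sub-threshold coverage as expected-excluded", {
  g <- grid_spec(n_rectangles = 8, layout_diameter = 4000, um_per_px = 4)
  cov <- c(0.95, 0.5, 0.99, 0.3, 0.85, 0.79, 0.81, 1)
  s <- generate_scene(g, scene_params(coverage = cov, seed = 2))
  expect_equal(s$truth$expected_included, cov >= 0.8)
})

test_that("scene I/O round-trips through TIFF, CSV and YAML", {
  g <- grid_spec(n_rectangles = 8, layout_diameter = 4000, um_per_px = 4)
  s <- generate_scene(g, scene_params(seed = 3))
  dir <- withr::local_tempdir()
  paths <- write_scene(s, dir)
  im <- read_image_tiff(paths$tiff)
  expect_equal(dim(im), dim(s$image))
  expect_lt(max(abs(im - s$image)), 1 / 65535)  # 16-bit quantisation
  tr <- readr::read_csv(paths$truth, show_col_types = FALSE)
  expect_equal(nrow(tr), 8)
  g2 <- read_grid_yaml(paths$grid)
  expect_equal(g2$n_rectangles, 8L)
  expect_equal(g2$um_per_px, 4)
})
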