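test_that("locate_grid returns one ROI per rectangle, containing its centroid", {
  sc <- test_scene()
  rois <- locate_grid(sc$image, sc$grid)
  expect_equal(nrow(rois), nrow(sc$truth))
  expect_equal(rois$rect_id, sc$truth$rect_id)
  inside <- sc$truth$center_row_px > rois$row0 &
    sc$truth$center_row_px <= rois$row0 + rois$height &
    sc$truth$center_col_px > rois$col0 &
    sc$truth$center_col_px <= rois$col0 + rois$width
  expect_true(all(inside))
})

test_that("a mirrored image or a mirrored fiducial raises the flip error", {
  sc <- test_scene()
  mirrored <- sc$image[, rev(seq_len(ncol(sc$image)))]
  expect_error(locate_grid(mirrored, sc$grid), class = "chiralcell_flip_error")
  g <- grid_spec(n_rectangles = 8, layout_diameter = 4000, um_per_px = 4)
  scm <- generate_scene(g, scene_params(seed = 5, f_mark_mirrored = TRUE))
  expect_error(locate_grid(scm$image, scm$grid), class = "chiralcell_flip_error")
})

test_that("a scene without the fiducial raises fiducial-missing", {
  sc <- test_scene()
  img <- sc$image
  a <- sc$grid$f_mark_anchor
  img[a[1]:(a[1] + 320), a[2]:(a[2] + 200)] <- sc$params$background_level
  expect_error(locate_grid(img, sc$grid), class = "chiralcell_fiducial_error")
})

test_that("primary crops have the 900 x 600 um geometry and rotate verticals", {
  sc <- test_scene()
  upp <- sc$grid$um_per_px
  rois <- locate_grid(sc$image, sc$grid)
  ih <- which(rois$orientation == "horizontal")[1]
  iv <- which(rois$orientation == "vertical")[1]
  ch <- primary_crop(sc$image, as.list(rois[ih, ]))
  expect_equal(dim(ch), c(600 / upp, 900 / upp))
  expect_false(attr(ch, "rotated"))
  cv <- primary_crop(sc$image, as.list(rois[iv, ]))
  expect_equal(dim(cv), c(600 / upp, 900 / upp))  # long axis horizontal after rotation
  expect_true(attr(cv, "rotated"))
  # rotation bookkeeping: measured angle equals the tape-frame truth
  regv <- detect_cell_region(cv, sc$grid)
  angv <- dominant_orientation(secondary_crop(cv, regv, sc$grid))$theta_deg
  expect_lt(abs(axial_diff(angv, sc$truth$theta_true_deg[rois$rect_id[iv]])), 1)
})

test_that("out-of-bounds ROIs error and full-image crops are idempotent", {
  sc <- test_scene()
  bad <- list(rect_id = 999, orientation = "horizontal",
              row0 = nrow(sc$image) - 10, col0 = 0, height = 300, width = 450)
  expect_error(primary_crop(sc$image, bad), "out of image bounds")
  full <- list(rect_id = 1, orientation = "horizontal", row0 = 0, col0 = 0,
               height = nrow(sc$image), width = ncol(sc$image))
  once <- primary_crop(sc$image, full)
  twice <- primary_crop(once, full)
  expect_equal(unclass(twice), unclass(once), ignore_attr = TRUE)
})

test_that("cell-region detection tracks generator coverage through the 80% rule", {
  g <- grid_spec(n_rectangles = 8, layout_diameter = 4000, um_per_px = 2)
  cov <- c(1, 1, 0.5, 0.5, 0.9, 0.7, 0.95, 0.3)
  sc <- generate_scene(g, scene_params(coverage = cov, noise_sd = 0.02, seed = 7))
  rois <- locate_grid(sc$image, sc$grid)
  for (i in seq_len(nrow(rois))) {
    crop <- primary_crop(sc$image, as.list(rois[i, ]))
    reg <- detect_cell_region(crop, sc$grid)
    expect_equal(reg$included, sc$truth$expected_included[i])
    if (sc$truth$coverage[i] == 1) {
      expect_gt(reg$area_fraction, 0.95)
      expect_lt(reg$area_fraction, 1.05)
    }
  }
  blank <- matrix(0, 300, 450)
  regb <- detect_cell_region(blank, g)
  expect_equal(regb$area_fraction, 0)
  expect_false(regb$included)
})

test_that("secondary crop is 400 x 200 um, centred, clamped, and guarded", {
  sc <- test_scene()
  upp <- sc$grid$um_per_px
  rois <- locate_grid(sc$image, sc$grid)
  i <- which(sc$truth$expected_included)[1]
  crop <- primary_crop(sc$image, as.list(rois[i, ]))
  reg <- detect_cell_region(crop, sc$grid)
  out <- secondary_crop(crop, reg, sc$grid)
  expect_equal(dim(out), c(200 / upp, 400 / upp))
  # window centre follows the detected centroid
  reg2 <- reg
  reg2$center_row <- reg$center_row + 15  # +30 um at 2 um/px
  out2 <- secondary_crop(crop, reg2, sc$grid)
  expect_equal(out2, crop[(round(reg2$center_row - 50) + 1):(round(reg2$center_row - 50) + 100),
                          (round(reg2$center_col - 100) + 1):(round(reg2$center_col - 100) + 200)])
  excl <- reg; excl$included <- FALSE
  expect_error(secondary_crop(crop, excl, sc$grid), "excluded region")
})

test_that("inclusion decisions agree with ground truth across a mixed scene", {
  sc <- test_scene()
  res <- run_image_pipeline(sc)
  agree <- mean(res$manifest$included == sc$truth$expected_included)
  expect_gte(agree, 0.99)
})
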