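clean_params <- scene_params(noise_sd = 0)

test_that("structure tensor matches the separable-stripe closed form", {
  const <- matrix(0.5, 64, 64)
  J <- structure_tensor(const)
  expect_equal(unlist(J), c(Jxx = 0, Jxy = 0, Jyy = 0), tolerance = 1e-12)
  vert <- fiber_texture(64, 64, 90, clean_params)  # columns constant in rows
  Jv <- structure_tensor(vert)
  expect_gt(Jv$Jxx, 1e-4)
  expect_lt(abs(Jv$Jxy), 1e-8 * Jv$Jxx)
  expect_lt(Jv$Jyy, 1e-8 * Jv$Jxx)
})

test_that("noise-free stripes are recovered within 0.5 degrees with high coherence", {
  for (th in c(-60, -30, 0, 30, 60, 89)) {
    r <- dominant_orientation(fiber_texture(128, 256, th, clean_params, phase = 0.7))
    expect_false(r$indeterminate)
    expect_lt(abs(axial_diff(r$theta_deg, th)), 0.5)
    expect_gt(r$coherence, 0.95)
  }
})

test_that("blank regions are flagged indeterminate, not errors", {
  r <- dominant_orientation(matrix(0.3, 32, 32))
  expect_true(r$indeterminate)
  expect_true(is.na(r$theta_deg))
  expect_error(dominant_orientation(matrix(0, 4, 4)), "8 x 8")
})

test_that("orientation is equivariant under image rotation", {
  base <- fiber_texture(256, 256, 5, clean_params, phase = 1.1)
  for (delta in c(10, 25, 40)) {
    rot <- central_crop(rotate_display(base, delta), 0.5)
    r <- dominant_orientation(rot)
    expect_lt(abs(axial_diff(r$theta_deg, 5 + delta)), 1)
  }
})

test_that("orientation and coherence are invariant to affine intensity rescale", {
  im <- fiber_texture(96, 192, 37.3, clean_params, phase = 0.2)
  a <- dominant_orientation(im)
  b <- dominant_orientation(0.35 * im + 0.12)
  expect_equal(a$theta_deg, b$theta_deg, tolerance = 1e-9)
  expect_equal(a$coherence, b$coherence, tolerance = 1e-9)
})

test_that("a 180-degree image rotation leaves the axial angle unchanged", {
  im <- fiber_texture(96, 96, -23.4, clean_params, phase = 0.9)
  flip <- im[nrow(im):1, ncol(im):1]
  expect_equal(dominant_orientation(im)$theta_deg,
               dominant_orientation(flip)$theta_deg, tolerance = 1e-6)
})

test_that("coherence separates oriented texture from isotropic noise", {
  expect_gt(dominant_orientation(fiber_texture(128, 128, 45, clean_params))$coherence,
            0.95)
  set.seed(10)
  noise <- matrix(rnorm(256^2), 256, 256)
  expect_lt(dominant_orientation(noise)$coherence, 0.1)
})

test_that("orientation map reports local angles and flags blank pixels", {
  im <- fiber_texture(96, 96, 45, clean_params, phase = 0.4)
  m <- orientation_map(im, window_sigma = 4)
  vals <- m[!is.na(m)]
  expect_gt(length(vals), 1000)
  expect_true(all(abs(axial_diff(vals, 45)) < 2))
  # piecewise image: two plateaus at 0 and 90
  two <- cbind(fiber_texture(96, 96, 90, clean_params),
               fiber_texture(96, 96, 0, clean_params))
  m2 <- orientation_map(two, window_sigma = 3)
  left <- m2[, 20:70]; right <- m2[, 120:170]
  expect_true(mean(abs(axial_diff(left[!is.na(left)], 90)) < 3) > 0.9)
  expect_true(mean(abs(axial_diff(right[!is.na(right)], 0)) < 3) > 0.9)
  expect_true(all(is.na(orientation_map(matrix(0.2, 64, 64)))))
})
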