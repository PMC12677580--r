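test_that("axial circular mean matches direct vector-summation oracle", {
  expect_equal(circ_mean_axial(c(20, 20, 20)), 20)
  expect_equal(circ_mean_axial(c(10, 20, 30)), 20, tolerance = 1e-9)
  set.seed(3)
  for (i in 1:20) {
    th <- runif(50, -89, 90)
    expect_equal(circ_mean_axial(th), oracle_axial_mean(th), tolerance = 1e-9)
  }
  # perfectly balanced axial set: the mean direction does not exist
  expect_error(circ_mean_axial(c(-45, 45)), "undefined")
})

test_that("large axial von Mises samples recover mean and closed-form SD", {
  s <- sample_axial_angles(10000, mu_deg = -7.5, kappa = 5, seed = 7)$theta_deg
  expect_lt(abs(axial_diff(circ_mean_axial(s), -7.5)), 1)
  sd_hat <- circ_sd_axial(s)
  sd_true <- vm_axial_sd_deg(5)
  expect_lt(abs(sd_hat - sd_true) / sd_true, 0.02)
  expect_equal(circ_sd_axial(c(30, 30, 30, 30)), 0)
})

test_that("degenerate and near-degenerate confidence intervals behave", {
  # concentration limit: all mass at mu -> zero-width interval at mu
  s <- sample_axial_angles(40, mu_deg = 12, kappa = 1e8, seed = 1)$theta_deg
  ci <- ci_mean_axial(s)
  expect_lt(ci["high"] - ci["low"], 0.01)
  expect_lt(abs(mean(ci) - 12), 0.01)
  # constant sample vs mu0 = 0: zero-width CI excludes 0
  expect_true(one_sample_mean_test(rep(5, 30), mu0 = 0)$reject)
  # sample mean exactly at mu0 with a wide CI: not rejected
  s2 <- sample_axial_angles(100, 0, 2, seed = 4)$theta_deg
  s2 <- wrap_axial(s2 - circ_mean_axial(s2))  # recentre on 0
  expect_false(one_sample_mean_test(s2, mu0 = 0)$reject)
  expect_error(ci_mean_axial(rep(5, 5)), "at least 10")
})

test_that("reflection negates the mean and swaps chirality, leaving spread alone", {
  s <- sample_axial_angles(300, -8, 6, seed = 9)
  r <- dplyr::mutate(s, theta_deg = wrap_axial(-theta_deg))
  a <- summarize_angles(s); b <- summarize_angles(r)
  expect_equal(b$mean_deg, -a$mean_deg, tolerance = 1e-6)
  expect_equal(b$sd_deg, a$sd_deg, tolerance = 1e-9)
  expect_equal(b$rbar, a$rbar, tolerance = 1e-12)
  expect_equal(sort(c(b$ci_low, b$ci_high)), sort(-c(a$ci_high, a$ci_low)),
               tolerance = 1e-6)
  expect_equal(a$chirality, "CW")
  expect_equal(b$chirality, "CCW")
  u_ab <- watson_u2_test(s$theta_deg, r$theta_deg, n_perm = 199, seed = 1)$u2
  u_ba <- watson_u2_test(wrap_axial(-s$theta_deg), wrap_axial(-r$theta_deg),
                         n_perm = 199, seed = 1)$u2
  expect_equal(u_ab, u_ba, tolerance = 1e-12)
})

test_that("linear kurtosis of angles grows with concentration over the data range", {
  # sharper alignment -> more peaked histogram at low concentration; the
  # relation peaks near kappa ~ 2 and reverts to 0 (the Gaussian limit) for
  # large kappa, so monotonicity is asserted over the weakly-aligned range
  k <- vapply(c(0.25, 1, 2), function(kap) {
    angle_kurtosis(sample_axial_angles(600, 0, kap, seed = 21)$theta_deg)
  }, numeric(1))
  expect_true(all(diff(k) > 0))
})

test_that("frequency distribution conserves counts on half-open bins", {
  d4 <- tibble::tibble(theta_deg = rep(10, 4))
  f <- angle_frequency(d4, bin_width = 10)
  expect_equal(sum(f$count), 4)
  expect_equal(f$count[f$bin_low == 0 & f$bin_high == 10], 4)
  set.seed(6)
  d <- tibble::tibble(theta_deg = runif(5000, -90 + 1e-9, 90))
  f2 <- angle_frequency(d, bin_width = 15)
  expect_equal(sum(f2$count), 5000)
  expect_error(angle_frequency(d, bin_width = 7), "divide 180")
  # uniform axial sample: counts flat to within 3 sigma Poisson
  set.seed(8)
  du <- tibble::tibble(theta_deg = runif(18000, -90 + 1e-9, 90))
  fu <- angle_frequency(du, bin_width = 10)
  expect_true(all(abs(fu$count - 1000) <= 3 * sqrt(1000)))
})

test_that("group summaries: small groups warn, chirality calls follow the sign", {
  s <- dplyr::bind_rows(
    sample_axial_angles(200, -8, 6, seed = 2, label = "cw_group"),
    sample_axial_angles(200, 15, 6, seed = 3, label = "ccw_group"))
  out <- summarize_angles(s)
  expect_setequal(out$group, c("cw_group", "ccw_group"))
  expect_equal(out$chirality[out$group == "cw_group"], "CW")
  expect_equal(out$chirality[out$group == "ccw_group"], "CCW")
  expect_warning(one <- summarize_angles(tibble::tibble(theta_deg = 5)),
                 "fewer than 10")
  expect_equal(one$chirality, "indeterminate")
  expect_true(is.na(one$ci_low))
})
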