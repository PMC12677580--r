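# Axial circular statistics: all estimators work on the doubled circle
# (angles in (-90, 90] are doubled to [0, 360), analysed there, and results
# halved back), so every quantity is invariant under theta -> theta + 180.

#' Axial circular mean
#'
#' Mean direction of axial angles, computed on the doubled circle:
#' C = sum(cos 2\eqn{\theta}), S = sum(sin 2\eqn{\theta}),
#' mean = atan2(S, C) / 2, mapped back to (-90, 90].
#'
#' @param theta_deg Numeric vector of axial angles in degrees, (-90, 90].
#' @return Circular mean in degrees, (-90, 90].
#' @examples
#' circ_mean_axial(c(10, 20, 30))  # 20
#' @export
circ_mean_axial <- function(theta_deg) {
  theta_deg <- check_angles(theta_deg)
  phi <- deg2rad(double_angles(theta_deg))
  C <- sum(cos(phi)); S <- sum(sin(phi))
  R <- sqrt(C^2 + S^2) / length(phi)
  if (R < 1e-12) {
    stop("mean direction undefined: resultant length is (numerically) zero",
         call. = FALSE)
  }
  wrap_axial(rad2deg(atan2(S, C)) / 2)
}

#' Mean resultant length of the doubled angles
#'
#' Rbar in [0, 1] of the angles after doubling; 1 means perfect alignment,
#' 0 a balanced (e.g. uniform) axial distribution.
#'
#' @inheritParams circ_mean_axial
#' @return Mean resultant length in [0, 1].
#' @export
circ_rbar_axial <- function(theta_deg) {
  theta_deg <- check_angles(theta_deg)
  phi <- deg2rad(double_angles(theta_deg))
  min(1, sqrt(mean(cos(phi))^2 + mean(sin(phi))^2))
}

#' Axial circular standard deviation
#'
#' Circular SD of the doubled angles, `sqrt(-2 log Rbar)`, converted to
#' degrees and halved back to the half-circle scale (symmetric with the
#' mean's doubling treatment).
#'
#' @inheritParams circ_mean_axial
#' @return Circular SD in degrees (half-circle scale), >= 0.
#' @export
circ_sd_axial <- function(theta_deg) {
  rbar <- circ_rbar_axial(theta_deg)
  if (rbar == 0) stop("circular SD undefined: resultant length is zero", call. = FALSE)
  rad2deg(sqrt(-2 * log(rbar))) / 2
}

#' Closed-form axial SD of a von Mises population
#'
#' For axial data whose doubled angles follow von Mises(, kappa), the mean
#' resultant length is Rbar = I1(kappa)/I0(kappa) and the axial circular SD
#' is `(180/pi) sqrt(-2 log Rbar) / 2`. Used as the analytic reference in
#' parameter-recovery checks.
#'
#' @param kappa Non-negative concentration on the doubled circle.
#' @return Axial circular SD in degrees.
#' @export
vm_axial_sd_deg <- function(kappa) {
  stopifnot(kappa > 0)
  rbar <- besselI(kappa, 1, expon.scaled = TRUE) /
    besselI(kappa, 0, expon.scaled = TRUE)
  rad2deg(sqrt(-2 * log(rbar))) / 2
}

#' Confidence interval for the axial circular mean
#'
#' Large-sample CI for the mean direction of the doubled angles (Fisher's
#' circular-dispersion method): with rho2 the mean resultant length of the
#' twice-doubled angles, dispersion `delta = (1 - rho2) / (2 Rbar^2)` and
#' half-width `asin(z * sqrt(delta / n))` on the doubled circle. Endpoints
#' are halved back to (-90, 90] scale and returned centred on the mean
#' (they may extend past +/-90 rather than wrap, so `low <= mean <= high`).
#' When the asin argument reaches 1 or n < 25, a seeded percentile
#' bootstrap of the axial mean is used instead.
#'
#' @inheritParams circ_mean_axial
#' @param level Confidence level, default 0.95.
#' @param n_boot Bootstrap resamples for the fallback method, default 9999.
#' @return Named numeric `c(low, high)` in degrees with attribute
#'   `method` (`"dispersion"` or `"bootstrap"`).
#' @export
ci_mean_axial <- function(theta_deg, level = 0.95, n_boot = 9999) {
  theta_deg <- check_angles(theta_deg)
  n <- length(theta_deg)
  if (n < 10) stop("need at least 10 angles for a mean-direction CI", call. = FALSE)
  stopifnot(level > 0, level < 1)
  m <- circ_mean_axial(theta_deg)
  rbar <- circ_rbar_axial(theta_deg)
  if (rbar < 1e-12) stop("CI undefined: resultant length is zero", call. = FALSE)
  phi <- deg2rad(double_angles(theta_deg))
  rho2 <- sqrt(mean(cos(2 * phi))^2 + mean(sin(2 * phi))^2)
  delta <- (1 - rho2) / (2 * rbar^2)
  z <- stats::qnorm(1 - (1 - level) / 2)
  arg <- z * sqrt(delta / n)
  if (arg < 1 && n >= 25) {
    half <- rad2deg(asin(arg)) / 2
    method <- "dispersion"
  } else {
    dev <- replicate(n_boot, {
      idx <- sample.int(n, n, replace = TRUE)
      axial_diff(circ_mean_axial(theta_deg[idx]), m)
    })
    qs <- stats::quantile(dev, c((1 - level) / 2, 1 - (1 - level) / 2),
                          names = FALSE, type = 8)
    half <- max(abs(qs))  # symmetrised percentile half-width
    method <- "bootstrap"
  }
  structure(c(low = m - half, high = m + half), method = method)
}

#' One-sample test for the axial mean angle
#'
#' Rejects the null hypothesis that the population mean direction equals
#' `mu0` if and only if `mu0` (taken axially, modulo 180) lies outside the
#' confidence interval from [ci_mean_axial()]. This CI-inversion rule is the
#' standard large-sample one-sample mean-direction test for circular data.
#'
#' @inheritParams ci_mean_axial
#' @param mu0 Hypothesised axial mean, degrees.
#' @return A one-row tibble: `mu0`, `mean_deg`, `ci_low`, `ci_high`,
#'   `level`, `reject`.
#' @export
one_sample_mean_test <- function(theta_deg, mu0 = 0, level = 0.95) {
  ci <- ci_mean_axial(theta_deg, level = level)
  m <- circ_mean_axial(theta_deg)
  half <- unname(ci["high"] - ci["low"]) / 2
  reject <- abs(axial_diff(mu0, m)) > half
  tibble::tibble(mu0 = mu0, mean_deg = m,
                 ci_low = unname(ci["low"]), ci_high = unname(ci["high"]),
                 level = level, reject = reject)
}

#' Linear excess kurtosis of angle values
#'
#' Ordinary (linear) excess kurtosis `m4/m2^2 - 3` of the half-circle angle
#' values treated as real numbers; the conventional sharpness measure for
#' dominant-orientation histograms.
#'
#' @inheritParams circ_mean_axial
#' @return Excess kurtosis (0 for a normal distribution).
#' @export
angle_kurtosis <- function(theta_deg) {
  theta_deg <- check_angles(theta_deg)
  x <- theta_deg - mean(theta_deg)
  m2 <- mean(x^2)
  if (m2 == 0) return(NA_real_)
  mean(x^4) / m2^2 - 3
}

check_angles <- function(theta_deg) {
  if (!is.numeric(theta_deg) || length(theta_deg) < 1) {
    stop("angles must be a non-empty numeric vector", call. = FALSE)
  }
  if (anyNA(theta_deg)) {
    theta_deg <- theta_deg[!is.na(theta_deg)]
    if (length(theta_deg) < 1) stop("all angles are NA", call. = FALSE)
  }
  if (any(theta_deg <= -90 - 1e-9) || any(theta_deg > 90 + 1e-9)) {
    stop("angles must lie in (-90, 90]; use wrap_axial() first", call. = FALSE)
  }
  theta_deg
}
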