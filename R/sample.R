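# von Mises sampling (Best-Fisher rejection from a wrapped-Cauchy envelope).

# Draws n angles in radians from von Mises(mu, kappa) on the full circle.
# kappa ~ 0 degenerates to the uniform distribution.
rvonmises <- function(n, mu, kappa) {
  stopifnot(n >= 1, kappa >= 0)
  if (kappa < 1e-10) {
    return ((stats::runif(n, 0, 2 * pi) + mu) %% (2 * pi))
  }
  a <- 1 + sqrt(1 + 4 * kappa^2)
  b <- (a - sqrt(2 * a)) / (2 * kappa)
  r <- (1 + b^2) / (2 * b)
  out <- numeric(n)
  got <- 0L
  while (got < n) {
    todo <- n - got
    u1 <- stats::runif(todo); u2 <- stats::runif(todo); u3 <- stats::runif(todo)
    z <- cos(pi * u1)
    f <- (1 + r * z) / (r + z)
    cc <- kappa * (r - f)
    ok <- (cc * (2 - cc) - u2 > 0) | (log(cc / u2) + 1 - cc >= 0)
    f <- f[ok]; u3 <- u3[ok]
    k <- length(f)
    if (k > 0) {
      out[(got + 1):(got + k)] <-
        sign(u3 - 0.5) * acos(pmin(pmax(f, -1), 1))
      got <- got + k
    }
  }
  (out + mu) %% (2 * pi)
}

#' Sample axial angles from a von Mises law on the doubled circle
#'
#' Draws `n` dominant-orientation angles whose doubled values follow a
#' von Mises distribution with mean direction `2 * mu_deg` and concentration
#' `kappa`; each draw is halved back to the axial half-circle (-90, 90].
#' This is the generative model the synthetic scenes use for per-rectangle
#' alignment angles.
#'
#' @param n Number of angles (>= 1).
#' @param mu_deg Axial mean angle in degrees, (-90, 90] (values outside are
#'   wrapped axially).
#' @param kappa Concentration on the doubled circle, >= 0 (0 = uniform).
#' @param seed Optional integer seed; a fixed seed makes the sample
#'   reproducible.
#' @param label Group label stored in the output, default `"sample"`.
#' @return A tibble with columns `group` and `theta_deg`.
#' @examples
#' sample_axial_angles(5, mu_deg = -8, kappa = 6, seed = 1)
#' @export
sample_axial_angles <- function(n, mu_deg, kappa, seed = NULL, label = "sample") {
  if (!is.numeric(n) || length(n) != 1 || n < 1) {
    stop("n must be a positive count", call. = FALSE)
  }
  if (kappa < 0) stop("kappa must be non-negative", call. = FALSE)
  if (!is.null(seed)) set.seed(seed)
  mu_deg <- wrap_axial(mu_deg)
  phi <- rvonmises(as.integer(n), deg2rad(double_angles(mu_deg)), kappa)
  tibble::tibble(group = label, theta_deg = halve_angles(rad2deg(phi)))
}
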