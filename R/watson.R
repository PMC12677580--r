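# Watson's two-sample U2 test on the doubled circle.

# U2 statistic from two vectors of full-circle angles (degrees).
# d_k = ecdf_a - ecdf_b at each pooled order statistic;
# U2 = (n m / N^2) * (sum d^2 - (sum d)^2 / N), ties averaged per block.
watson_u2_stat <- function(phi_a, phi_b) {
  n <- length(phi_a); m <- length(phi_b); N <- n + m
  pooled <- c(phi_a, phi_b)
  ord <- order(pooled)
  lab <- c(rep(1L, n), rep(0L, m))[ord]
  d <- cumsum(lab) / n - cumsum(1L - lab) / m
  v <- pooled[ord]
  if (anyDuplicated(v)) {
    # within a block of tied values the ECDF step order is arbitrary:
    # replace d over each tied block by its block mean
    blk <- cumsum(c(TRUE, diff(v) != 0))
    d <- stats::ave(d, blk)
  }
  (n * m / N^2) * (sum(d^2) - sum(d)^2 / N)
}

#' Watson's two-sample U-squared test for axial angle samples
#'
#' Rotation-invariant two-sample test for a difference between two circular
#' (here axial, angle-doubled) distributions, based on squared differences
#' of the empirical CDFs at the pooled order statistics. The p-value comes
#' from random permutations of group labels by default (exact-level at any
#' sample size); the classical asymptotic series
#' \eqn{p = 2\sum_{k\ge1}(-1)^{k-1} e^{-2k^2\pi^2 U^2}} is also available.
#'
#' @param a,b Numeric vectors of axial angles in degrees, (-90, 90]. Both
#'   groups need at least 8 observations.
#' @param n_perm Number of label permutations (>= 99), default 9999.
#' @param method `"permutation"` (default) or `"asymptotic"`.
#' @param seed Optional integer seed for the permutation draw, making the
#'   p-value reproducible.
#' @return An object of class `watson_u2_test`: a list with `u2`, `p_value`,
#'   `method`, `n_perm`, `n`, `m`. Has [generics::tidy()] and
#'   [generics::glance()] methods.
#' @examples
#' a <- sample_axial_angles(50, mu_deg = -8, kappa = 6, seed = 1)$theta_deg
#' b <- sample_axial_angles(50, mu_deg = 20, kappa = 6, seed = 2)$theta_deg
#' watson_u2_test(a, b, n_perm = 199, seed = 1)
#' @export
watson_u2_test <- function(a, b, n_perm = 9999,
                           method = c("permutation", "asymptotic"),
                           seed = NULL) {
  method <- match.arg(method)
  a <- check_angles(a); b <- check_angles(b)
  n <- length(a); m <- length(b)
  if (n < 8 || m < 8) stop("Watson's U2 needs at least 8 angles per group", call. = FALSE)
  phi_a <- double_angles(a); phi_b <- double_angles(b)
  u2 <- watson_u2_stat(phi_a, phi_b)
  if (method == "permutation") {
    if (n_perm < 99) stop("n_perm must be at least 99", call. = FALSE)
    if (!is.null(seed)) set.seed(seed)
    pooled <- c(phi_a, phi_b)
    N <- n + m
    ord <- order(pooled)
    v <- pooled[ord]
    tied <- anyDuplicated(v) > 0
    blk <- if (tied) cumsum(c(TRUE, diff(v) != 0)) else NULL
    base_lab <- c(rep(1L, n), rep(0L, m))[ord]
    hits <- 0L
    scale <- n * m / N^2
    for (i in seq_len(n_perm)) {
      lab <- base_lab[sample.int(N)]
      d <- cumsum(lab) / n - cumsum(1L - lab) / m
      if (tied) d <- stats::ave(d, blk)
      u2p <- scale * (sum(d^2) - sum(d)^2 / N)
      if (u2p >= u2 - 1e-12) hits <- hits + 1L
    }
    p <- (1 + hits) / (n_perm + 1)
  } else {
    k <- seq_len(60)
    p <- 2 * sum((-1)^(k - 1) * exp(-2 * k^2 * pi^2 * u2))
    p <- min(max(p, 0), 1)
    n_perm <- NA_integer_
  }
  structure(list(u2 = u2, p_value = p, method = method,
                 n_perm = n_perm, n = n, m = m),
            class = "watson_u2_test")
}

#' @export
print.watson_u2_test <- function(x, ...) {
  cat("Watson's two-sample U2 test (axial, doubled angles)\n")
  cat(sprintf("  U2 = %.5f, p = %.4g (%s%s), n = %d, m = %d\n",
              x$u2, x$p_value, x$method,
              if (x$method == "permutation") sprintf(", %d permutations", x$n_perm) else "",
              x$n, x$m))
  invisible(x)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @exportS3Method generics::tidy
tidy.watson_u2_test <- function(x, ...) {
  tibble::tibble(statistic = x$u2, p.value = x$p_value,
                 method = paste0("Watson U2 (", x$method, ")"),
                 n = x$n, m = x$m, n_perm = x$n_perm)
}

#' @exportS3Method generics::glance
glance.watson_u2_test <- function(x, ...) tidy(x)
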