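# Group-level descriptive summaries and chirality calls.

#' Circular summary and chirality call per group of angles
#'
#' For each group of axial angles: circular mean and SD (doubled-angle
#' convention), mean resultant length, 95% CI for the mean direction,
#' linear excess kurtosis, and a chirality call. A population is called
#' clockwise (CW) when the one-sample mean-angle test rejects mu0 = 0 with
#' a negative mean (left-up to right-down alignment as displayed from the
#' culture-medium side), counterclockwise (CCW) with a positive mean, and
#' indeterminate otherwise. Groups with fewer than 10 angles get NA
#' intervals and an indeterminate call, with a warning.
#'
#' @param data A data frame with one angle per row (e.g. from
#'   [sample_axial_angles()] or [run_image_pipeline()]).
#' @param theta Column of axial angles in degrees, default `theta_deg`.
#' @param group Optional grouping column, default `group` if present.
#' @param mu0 Hypothesised mean for the chirality test, default 0 degrees.
#' @param level Confidence level, default 0.95.
#' @return A tibble with one row per group: `group`, `n`, `mean_deg`,
#'   `sd_deg`, `rbar`, `ci_low`, `ci_high`, `kurtosis`, `chirality`.
#' @examples
#' sample_axial_angles(200, -8, 6, seed = 1) |> summarize_angles()
#' @export
summarize_angles <- function(data, theta = theta_deg, group = NULL,
                             mu0 = 0, level = 0.95) {
  stopifnot(is.data.frame(data))
  theta <- rlang::enquo(theta)
  group <- rlang::enquo(group)
  if (rlang::quo_is_null(group) && "group" %in% names(data)) {
    group <- rlang::quo(group)
  }
  th <- dplyr::pull(data, !!theta)
  grp <- if (!rlang::quo_is_null(group)) {
    as.character(dplyr::pull(data, !!group))
  } else {
    rep("sample", length(th))
  }
  purrr::map_dfr(unique(grp), function(g) {
    dplyr::bind_cols(
      tibble::tibble(group = g),
      summarize_angle_vector(th[grp == g], mu0 = mu0, level = level))
  })
}

# One group: vector in, one-row tibble out.
summarize_angle_vector <- function(theta_deg, mu0 = 0, level = 0.95) {
  theta_deg <- check_angles(theta_deg)
  n <- length(theta_deg)
  m <- circ_mean_axial(theta_deg)
  base <- tibble::tibble(
    n = n,
    mean_deg = m,
    sd_deg = circ_sd_axial(theta_deg),
    rbar = circ_rbar_axial(theta_deg),
    kurtosis = angle_kurtosis(theta_deg)
  )
  if (n < 10) {
    warning("fewer than 10 angles: CI and chirality test skipped", call. = FALSE)
    return(dplyr::mutate(base, ci_low = NA_real_, ci_high = NA_real_,
                         chirality = "indeterminate"))
  }
  tst <- one_sample_mean_test(theta_deg, mu0 = mu0, level = level)
  chir <- if (!tst$reject) "indeterminate" else if (axial_diff(m, mu0) < 0) "CW" else "CCW"
  dplyr::mutate(base, ci_low = tst$ci_low, ci_high = tst$ci_high,
                chirality = chir)
}

#' Frequency distribution of axial angles
#'
#' Histogram table over half-open bins covering (-90, 90]; bin counts sum
#' to the number of angles.
#'
#' @inheritParams summarize_angles
#' @param bin_width Bin width in degrees; must divide 180 evenly.
#' @return A tibble with `group` (if grouped), `bin_low`, `bin_high`,
#'   `bin_mid`, `count`.
#' @export
angle_frequency <- function(data, theta = theta_deg, group = NULL,
                            bin_width = 10) {
  stopifnot(is.data.frame(data))
  if (!is.numeric(bin_width) || bin_width <= 0 ||
      abs(180 / bin_width - round(180 / bin_width)) > 1e-9) {
    stop("bin_width must divide 180 evenly", call. = FALSE)
  }
  theta <- rlang::enquo(theta)
  group <- rlang::enquo(group)
  if (rlang::quo_is_null(group) && "group" %in% names(data)) {
    group <- rlang::quo(group)
  }
  edges <- seq(-90, 90, by = bin_width)
  one <- function(th) {
    th <- check_angles(th)
    # half-open (low, high]: shift left edge infinitesimally via right-closed cut
    cnt <- hist(th, breaks = edges, plot = FALSE, right = TRUE)$counts
    # hist() right=TRUE gives (low, high] except the first bin is closed;
    # -90 itself cannot occur on (-90, 90]
    tibble::tibble(bin_low = edges[-length(edges)],
                   bin_high = edges[-1],
                   bin_mid = (edges[-1] + edges[-length(edges)]) / 2,
                   count = as.integer(cnt))
  }
  if (!rlang::quo_is_null(group)) {
    data |>
      dplyr::group_by(!!group) |>
      dplyr::summarise(res = list(one(!!theta)), .groups = "drop") |>
      (\(d) { names(d)[1] <- "group"; d })() |>
      tidyr::unnest("res")
  } else {
    one(dplyr::pull(data, !!theta))
  }
}
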