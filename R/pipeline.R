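# End-to-end orchestration: image -> per-rectangle angles -> chirality.

#' Run the full image-to-chirality pipeline
#'
#' Executes the semi-automated workflow on a stitched micropattern image:
#' fiducial-referenced grid location, primary cropping with rotation
#' normalisation, cell-region detection, the 80% coverage filter,
#' central secondary cropping, structure-tensor dominant orientation, and
#' the axial circular summary with chirality call. Every rectangle's
#' include/exclude decision and reason is recorded in the manifest.
#'
#' @param image A numeric matrix, a TIFF path, or a `micropattern_scene`.
#' @param grid A [grid_spec()]; taken from the scene when `image` is one.
#' @param group Group label for the resulting angle sample.
#' @param grad_sigma Gradient scale for the structure tensor, px.
#' @param coverage_threshold Inclusion threshold on cell-attached area
#'   fraction, default 0.8.
#' @param level Confidence level of the chirality test, default 0.95.
#' @param out_dir Optional output directory; when given, writes
#'   `manifest.csv`, `angles.csv`, `summary.json` and `histogram.png`.
#' @param bin_width Histogram bin width (degrees) for outputs, default 10.
#' @return An object of class `chirality_run`: list with `angles` (tibble:
#'   `rect_id`, `group`, `theta_deg`, `coherence`, `energy`), `manifest`
#'   (tibble: `rect_id`, `orientation`, `rotated`, `area_fraction`,
#'   `center_row`, `center_col`, `included`, `reason`), `summary` (the
#'   [summarize_angles()] row, or `NULL` when no rectangle survives),
#'   `grid`, `n_included`.
#' @export
run_image_pipeline <- function(image, grid = NULL, group = "sample",
                               grad_sigma = 1, coverage_threshold = 0.8,
                               level = 0.95, out_dir = NULL, bin_width = 10) {
  if (inherits(image, "micropattern_scene")) {
    if (is.null(grid)) grid <- image$grid
    image <- image$image
  } else if (is.character(image)) {
    image <- read_image_tiff(image)
  }
  stopifnot(is.matrix(image), inherits(grid, "grid_spec"))
  rois <- locate_grid(image, grid)
  rows <- purrr::pmap(rois, function(rect_id, orientation, row0, col0,
                                     height, width, rotated) {
    roi <- list(rect_id = rect_id, orientation = orientation, row0 = row0,
                col0 = col0, height = height, width = width)
    crop <- primary_crop(image, roi)
    region <- detect_cell_region(crop, grid, coverage_threshold)
    man <- tibble::tibble(rect_id = rect_id, orientation = orientation,
                          rotated = attr(crop, "rotated"),
                          area_fraction = region$area_fraction,
                          center_row = region$center_row,
                          center_col = region$center_col,
                          included = region$included,
                          reason = if (region$included) "ok" else "coverage_below_threshold")
    if (!region$included) return(list(manifest = man, angle = NULL))
    central <- secondary_crop(crop, region, grid)
    ori <- dominant_orientation(central, grad_sigma)
    if (ori$indeterminate) {
      man$included <- FALSE
      man$reason <- "indeterminate_orientation"
      return(list(manifest = man, angle = NULL))
    }
    list(manifest = man,
         angle = tibble::tibble(rect_id = rect_id, group = group,
                                theta_deg = ori$theta_deg,
                                coherence = ori$coherence,
                                energy = ori$energy))
  })
  manifest <- purrr::map_dfr(rows, "manifest")
  angles <- purrr::map_dfr(rows, "angle")
  summary <- NULL
  if (nrow(angles) > 0) {
    summary <- summarize_angles(angles, theta_deg, group, level = level)
  }
  res <- structure(list(angles = angles, manifest = manifest,
                        summary = summary, grid = grid,
                        n_included = nrow(angles)),
                   class = "chirality_run")
  if (!is.null(out_dir)) write_run_outputs(res, out_dir, bin_width)
  res
}

#' @export
print.chirality_run <- function(x, ...) {
  cat(sprintf("Micropattern chirality run: %d/%d rectangles included\n",
              x$n_included, nrow(x$manifest)))
  if (is.null(x$summary)) {
    cat("  no surviving rectangles: no chirality call\n")
  } else {
    print(x$summary)
  }
  invisible(x)
}

write_run_outputs <- function(res, out_dir, bin_width = 10) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  readr::write_csv(res$manifest, file.path(out_dir, "manifest.csv"))
  readr::write_csv(res$angles, file.path(out_dir, "angles.csv"))
  if (is.null(res$summary)) {
    jsonlite::write_json(list(status = "no data",
                              n_rectangles = nrow(res$manifest),
                              n_included = 0),
                         file.path(out_dir, "summary.json"), auto_unbox = TRUE)
  } else {
    jsonlite::write_json(as.list(res$summary),
                         file.path(out_dir, "summary.json"),
                         auto_unbox = TRUE, digits = NA)
    p <- autoplot.chirality_run(res, bin_width = bin_width)
    suppressMessages(ggplot2::ggsave(file.path(out_dir, "histogram.png"), p,
                                     width = 6, height = 4, dpi = 150))
  }
  invisible(out_dir)
}

#' Read an angle table (CSV/TSV or XLSX)
#'
#' Accepts the common layouts for per-rectangle dominant-orientation
#' tables: a long table with `group` and `theta_deg` (or `angle`) columns;
#' a wide table whose columns are one group each; or a multi-sheet XLSX
#' workbook with one sheet per group (sheet name = group; first numeric
#' column used), as in raw-angle supplementary workbooks.
#'
#' @param path File path (`.csv`, `.tsv`, `.txt`, or `.xlsx`).
#' @return A tibble with columns `group` and `theta_deg` (degrees,
#'   wrapped to (-90, 90]).
#' @export
read_angle_table <- function(path) {
  ext <- tolower(tools::file_ext(path))
  if (ext %in% c("xlsx", "xls")) {
    sheets <- readxl::excel_sheets(path)
    tabs <- purrr::map(sheets, function(s) {
      d <- suppressMessages(readxl::read_excel(path, sheet = s))
      tidy_angle_frame(d, default_group = s)
    })
    out <- dplyr::bind_rows(tabs)
  } else {
    delim <- if (ext %in% c("tsv", "txt")) "\t" else ","
    d <- suppressMessages(readr::read_delim(path, delim = delim,
                                            show_col_types = FALSE))
    out <- tidy_angle_frame(d, default_group = basename(path))
  }
  dplyr::mutate(out, theta_deg = wrap_axial(theta_deg))
}

tidy_angle_frame <- function(d, default_group) {
  nm <- tolower(names(d))
  ang_col <- which(nm %in% c("theta_deg", "theta", "angle", "angle_deg", "orientation_deg"))
  grp_col <- which(nm %in% c("group", "label", "condition", "sample"))
  if (length(ang_col)) {
    g <- if (length(grp_col)) as.character(d[[grp_col[1]]]) else default_group
    return(tibble::tibble(group = g, theta_deg = as.numeric(d[[ang_col[1]]])) |>
             tidyr::drop_na(theta_deg))
  }
  num <- vapply(d, is.numeric, logical(1))
  if (!any(num)) stop("no numeric angle column found", call. = FALSE)
  if (sum(num) == 1) {
    return(tibble::tibble(group = default_group,
                          theta_deg = as.numeric(d[[which(num)]])) |>
             tidyr::drop_na(theta_deg))
  }
  d[num] |>
    tidyr::pivot_longer(dplyr::everything(), names_to = "group",
                        values_to = "theta_deg") |>
    tidyr::drop_na(theta_deg) |>
    dplyr::arrange(group)
}

#' Statistics-only pipeline on pre-extracted angle tables
#'
#' Produces the circular summary (with chirality call) per group and
#' pairwise Watson's U2 tests, starting from angle tables rather than
#' images.
#'
#' @param tables A data frame with `group`/`theta_deg`, or a character
#'   vector of table paths for [read_angle_table()].
#' @param pairs Optional list of length-2 character vectors naming the
#'   group pairs to test; default: all pairs.
#' @param n_perm Permutations for the U2 p-value, default 9999.
#' @param level Confidence level, default 0.95.
#' @param seed Optional seed for the permutation p-values.
#' @return An object of class `chirality_stats`: list with `summary`
#'   (tibble) and `tests` (tibble, tidied U2 results with `group_a`,
#'   `group_b`).
#' @export
run_stats_only <- function(tables, pairs = NULL, n_perm = 9999,
                           level = 0.95, seed = NULL) {
  data <- if (is.character(tables)) {
    dplyr::bind_rows(purrr::map(tables, read_angle_table))
  } else {
    stopifnot(is.data.frame(tables))
    tables
  }
  stopifnot(all(c("group", "theta_deg") %in% names(data)))
  counts <- dplyr::count(data, group)
  empty <- counts$group[counts$n < 1]
  summary <- summarize_angles(data, theta_deg, group, level = level)
  groups <- unique(data$group)
  if (is.null(pairs) && length(groups) >= 2) {
    pairs <- utils::combn(groups, 2, simplify = FALSE)
  }
  tests <- NULL
  if (!is.null(pairs)) {
    tests <- purrr::map_dfr(pairs, function(p) {
      a <- data$theta_deg[data$group == p[1]]
      b <- data$theta_deg[data$group == p[2]]
      if (length(a) < 8 || length(b) < 8) {
        warning(sprintf("pair %s vs %s skipped: fewer than 8 angles", p[1], p[2]),
                call. = FALSE)
        return(NULL)
      }
      dplyr::bind_cols(tibble::tibble(group_a = p[1], group_b = p[2]),
                       tidy(watson_u2_test(a, b, n_perm = n_perm, seed = seed)))
    })
  }
  structure(list(summary = summary, tests = tests), class = "chirality_stats")
}

#' @export
print.chirality_stats <- function(x, ...) {
  cat("Circular summaries:\n"); print(x$summary)
  if (!is.null(x$tests) && nrow(x$tests)) {
    cat("\nPairwise Watson U2 tests:\n"); print(x$tests)
  }
  invisible(x)
}
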