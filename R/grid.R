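# Micropattern tape geometry.

#' Micropattern grid specification
#'
#' Geometry of the rectangular micropattern tape layout and the image
#' scale. Defaults describe the reference tape: 453 rectangles of
#' 600 x 300 um separated by 300 um gaps in both directions, mixed
#' horizontal/vertical orientations, arranged inside a 19 mm circle with an
#' "F" fiducial glyph at the center. The pixel coordinate of the left-top
#' corner of the "F" anchors the pixel-to-micrometer mapping.
#'
#' @param rect_length Rectangle long side, um (default 600).
#' @param rect_width Rectangle short side, um (default 300).
#' @param gap Gap between rectangles in both directions, um (default 300).
#' @param n_rectangles Number of rectangles to place (default 453).
#' @param layout_diameter Diameter of the circular layout, um (default 19000).
#' @param um_per_px Image scale, micrometers per pixel (default 2).
#' @param f_mark_anchor Optional pixel coordinate `c(row, col)` (1-based) of
#'   the left-top corner of the "F" glyph; filled in by [generate_scene()],
#'   or located by template matching in [locate_grid()] when `NULL`.
#' @param orientation_mix Fraction of rows holding vertical rectangles in
#'   `[0, 1]`, default 0.5 (alternating rows).
#' @return An object of class `grid_spec` (a named list).
#' @export
grid_spec <- function(rect_length = 600, rect_width = 300, gap = 300,
                      n_rectangles = 453, layout_diameter = 19000,
                      um_per_px = 2, f_mark_anchor = NULL,
                      orientation_mix = 0.5) {
  stopifnot(rect_length > 0, rect_width > 0, gap > 0, n_rectangles >= 1,
            layout_diameter > 0, um_per_px > 0,
            orientation_mix >= 0, orientation_mix <= 1)
  if (rect_length <= rect_width) stop("rect_length must exceed rect_width", call. = FALSE)
  if (rect_length + gap > layout_diameter) {
    stop("a single rectangle plus gap does not fit in the layout circle", call. = FALSE)
  }
  structure(list(rect_length = rect_length, rect_width = rect_width,
                 gap = gap, n_rectangles = as.integer(n_rectangles),
                 layout_diameter = layout_diameter, um_per_px = um_per_px,
                 f_mark_anchor = f_mark_anchor,
                 orientation_mix = orientation_mix),
            class = "grid_spec")
}

#' @export
print.grid_spec <- function(x, ...) {
  cat(sprintf(
    "Micropattern grid: %d rectangles %g x %g um, gap %g um,\n  circle %g um, %g um/px, orientation mix %g\n",
    x$n_rectangles, x$rect_length, x$rect_width, x$gap,
    x$layout_diameter, x$um_per_px, x$orientation_mix))
  invisible(x)
}

# Deterministic row-orientation sequence for ring index 0, 1, 2, ...:
# Bresenham-style accumulation of the vertical-row fraction.
row_orientations <- function(k_max, mix) {
  acc <- 0
  out <- character(k_max + 1)
  for (j in 0:k_max) {
    acc <- acc + mix
    if (acc >= 1 - 1e-9) { out[j + 1] <- "vertical"; acc <- acc - 1 }
    else out[j + 1] <- "horizontal"
  }
  out
}

#' Rectangle layout of a micropattern grid
#'
#' Deterministic placement of the rectangles inside the layout circle:
#' rows of cells alternate horizontal and vertical rectangle orientation
#' (per `orientation_mix`), each cell is the rectangle plus half-gap
#' margins (900 x 600 um at defaults), cells are kept only when the whole
#' cell fits inside the circle, and the `n_rectangles` cells closest to the
#' center are retained (the central cell is reserved for the "F" glyph).
#' Ids run row-major, top-to-bottom then left-to-right. Coordinates are in
#' micrometers in the tape frame: origin at the tape center, x to the
#' right, y downward (image display direction).
#'
#' @param grid A [grid_spec()].
#' @return A tibble: `rect_id`, `orientation`, `cx_um`, `cy_um` (cell and
#'   rectangle center), plus cell sizes `cell_w_um`, `cell_h_um`.
#' @export
grid_layout <- function(grid) {
  stopifnot(inherits(grid, "grid_spec"))
  R <- grid$layout_diameter / 2
  cellw <- function(o) if (o == "horizontal") grid$rect_length + grid$gap else grid$rect_width + grid$gap
  cellh <- function(o) if (o == "horizontal") grid$rect_width + grid$gap else grid$rect_length + grid$gap
  k_max <- ceiling(R / (grid$rect_width + grid$gap)) + 1
  orients <- row_orientations(k_max, grid$orientation_mix)
  rows <- list()
  # ring 0 is the row centred on y = 0; rings extend symmetrically up/down
  h0 <- cellh(orients[1])
  edge_dn <- h0 / 2
  rows[[1]] <- tibble::tibble(ring = 0, y0 = -h0 / 2, y1 = h0 / 2,
                              orientation = orients[1])
  edge_up <- -h0 / 2
  for (j in seq_len(k_max)) {
    h <- cellh(orients[j + 1])
    if (edge_dn + h > R && -edge_up + h > R) break
    rows[[length(rows) + 1]] <- tibble::tibble(
      ring = j, y0 = edge_dn, y1 = edge_dn + h, orientation = orients[j + 1])
    rows[[length(rows) + 1]] <- tibble::tibble(
      ring = -j, y0 = edge_up - h, y1 = edge_up, orientation = orients[j + 1])
    edge_dn <- edge_dn + h
    edge_up <- edge_up - h
  }
  rows <- dplyr::bind_rows(rows)
  cells <- purrr::pmap_dfr(rows, function(ring, y0, y1, orientation) {
    w <- cellw(orientation)
    ymax <- max(abs(y0), abs(y1))
    if (ymax >= R) return(NULL)
    half_x <- sqrt(R^2 - ymax^2)
    imax <- floor((half_x - w / 2) / w)
    if (imax < 0) return(NULL)
    i <- seq(-imax, imax)
    tibble::tibble(ring = ring, orientation = orientation,
                   cx_um = i * w, cy_um = (y0 + y1) / 2,
                   cell_w_um = w, cell_h_um = y1 - y0)
  })
  # reserve the central cell for the fiducial
  cells <- dplyr::filter(cells, !(ring == 0 & abs(cx_um) < 1e-9))
  if (nrow(cells) < grid$n_rectangles) {
    stop(sprintf("layout holds only %d rectangles inside the circle; %d requested",
                 nrow(cells), grid$n_rectangles), call. = FALSE)
  }
  cells |>
    dplyr::mutate(r2 = cx_um^2 + cy_um^2) |>
    dplyr::arrange(r2) |>
    dplyr::slice_head(n = grid$n_rectangles) |>
    dplyr::arrange(cy_um, cx_um) |>
    dplyr::mutate(rect_id = dplyr::row_number()) |>
    dplyr::select(rect_id, orientation, cx_um, cy_um, cell_w_um, cell_h_um)
}
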