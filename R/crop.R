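# F-mark-referenced grid cropping and the 80% coverage filter.
#
# Pixel boxes are 0-based and half-open (row0, col0, height, width), per
# the package-wide coordinate convention; R's 1-based slicing happens only
# at the moment of extraction.

ncc <- function(a, b) {
  a <- as.vector(a) - mean(a); b <- as.vector(b) - mean(b)
  da <- sqrt(sum(a^2)); db <- sqrt(sum(b^2))
  if (da == 0 || db == 0) return(0)
  sum(a * b) / (da * db)
}

# FFT cross-correlation search of a zero-mean template over a region;
# returns the 1-based (row, col) of the best left-top placement.
search_template <- function(image, tmpl, region = NULL) {
  if (is.null(region)) {
    nr <- nrow(image); nc <- ncol(image)
    # central third: the fiducial sits at the tape center by design
    region <- c(max(1, floor(nr / 3)), max(1, floor(nc / 3)),
                min(nr, ceiling(2 * nr / 3) + nrow(tmpl)),
                min(nc, ceiling(2 * nc / 3) + ncol(tmpl)))
  }
  sub <- image[region[1]:region[3], region[2]:region[4]]
  th <- nrow(tmpl); tw <- ncol(tmpl)
  if (nrow(sub) < th || ncol(sub) < tw) stop("search region smaller than template", call. = FALSE)
  tz <- tmpl - mean(tmpl)
  pad <- matrix(0, nrow(sub), ncol(sub))
  pad[1:th, 1:tw] <- tz
  cc <- Re(stats::fft(stats::fft(sub) * Conj(stats::fft(pad)), inverse = TRUE))
  valid <- cc[1:(nrow(sub) - th + 1), 1:(ncol(sub) - tw + 1), drop = FALSE]
  ij <- arrayInd(which.max(valid), dim(valid))
  c(region[1] + ij[1] - 1L, region[2] + ij[2] - 1L)
}

#' Locate the rectangle grid from the "F" fiducial
#'
#' Verifies the fiducial at its anchor (or finds it by template matching
#' when `grid$f_mark_anchor` is `NULL`), checks image chirality by
#' comparing the glyph against its mirror image, and returns one primary
#' crop window per expected rectangle: the rectangle plus half-gap margins
#' (900 x 600 um at defaults), positioned relative to the fiducial.
#'
#' @param image Numeric matrix (stitched scene).
#' @param grid A [grid_spec()].
#' @return A tibble of ROIs: `rect_id`, `orientation`, `row0`, `col0`,
#'   `height`, `width` (0-based, half-open), `rotated` (all `FALSE`).
#' @section Errors: condition class `chiralcell_fiducial_error` when no
#'   glyph matches; `chiralcell_flip_error` when the mirrored glyph
#'   matches better (the image is flipped and every chirality call would
#'   be inverted — re-export the image, do not analyse).
#' @export
locate_grid <- function(image, grid) {
  stopifnot(is.matrix(image), inherits(grid, "grid_spec"))
  upp <- grid$um_per_px
  tmpl <- matrix(0.05, nrow = round(600 / upp), ncol = round(360 / upp))
  glyph <- render_f_glyph(upp)
  tmpl[glyph] <- 0.9
  tmpl_m <- tmpl[, rev(seq_len(ncol(tmpl)))]
  anchor <- grid$f_mark_anchor
  if (is.null(anchor)) anchor <- search_template(image, tmpl)
  th <- nrow(tmpl); tw <- ncol(tmpl)
  if (anchor[1] < 1 || anchor[2] < 1 ||
      anchor[1] + th - 1 > nrow(image) || anchor[2] + tw - 1 > ncol(image)) {
    stop(fiducial_error("fiducial anchor outside the image"))
  }
  patch <- image[anchor[1]:(anchor[1] + th - 1), anchor[2]:(anchor[2] + tw - 1)]
  s_direct <- ncc(patch, tmpl)
  s_mirror <- ncc(patch, tmpl_m)
  if (max(s_direct, s_mirror) < 0.5) {
    stop(fiducial_error(sprintf(
      "no 'F' fiducial found at the anchor (best correlation %.2f)",
      max(s_direct, s_mirror))))
  }
  if (s_mirror > s_direct) {
    stop(flip_error(
      "the 'F' fiducial matches its mirror image: the image is flipped, so every CW/CCW chirality call would be inverted; re-export the image unflipped"))
  }
  # tape center from the glyph left-top corner (glyph box is centred there)
  c_row <- anchor[1] + 300 / upp
  c_col <- anchor[2] + 180 / upp
  lay <- grid_layout(grid)
  w <- round(lay$cell_w_um / upp)
  h <- round(lay$cell_h_um / upp)
  tibble::tibble(
    rect_id = lay$rect_id, orientation = lay$orientation,
    row0 = round(c_row + lay$cy_um / upp - h / 2) - 1L,
    col0 = round(c_col + lay$cx_um / upp - w / 2) - 1L,
    height = h, width = w, rotated = FALSE)
}

fiducial_error <- function(msg) {
  structure(class = c("chiralcell_fiducial_error", "error", "condition"),
            list(message = msg, call = NULL))
}

flip_error <- function(msg) {
  structure(class = c("chiralcell_flip_error", "error", "condition"),
            list(message = msg, call = NULL))
}

# rotate a matrix 90 degrees clockwise as displayed (top row -> right column)
rot90_cw <- function(m) t(m)[, nrow(m):1, drop = FALSE]

#' Primary crop of one rectangle window
#'
#' Extracts the 900 x 600 um window of one ROI; vertical rectangles are
#' rotated 90 degrees clockwise (display convention) so that the long axis
#' is horizontal for every downstream step.
#'
#' @param image Numeric matrix (stitched scene).
#' @param roi One ROI row from [locate_grid()] (or a list with the same
#'   fields).
#' @return Numeric matrix with attributes `rect_id`, `orientation`,
#'   `rotated`.
#' @export
primary_crop <- function(image, roi) {
  r0 <- roi$row0; c0 <- roi$col0; h <- roi$height; w <- roi$width
  if (r0 < 0 || c0 < 0 || r0 + h > nrow(image) || c0 + w > ncol(image)) {
    stop(sprintf("ROI %s out of image bounds", roi$rect_id), call. = FALSE)
  }
  m <- image[(r0 + 1):(r0 + h), (c0 + 1):(c0 + w), drop = FALSE]
  rotated <- FALSE
  if (identical(roi$orientation, "vertical")) {
    m <- rot90_cw(m)
    rotated <- TRUE
  }
  structure(m, rect_id = roi$rect_id, orientation = roi$orientation,
            rotated = rotated)
}

#' Detect the cell-attached region of a primary crop
#'
#' Segments foreground by Otsu's global threshold on a low-passed copy of
#' the crop (Gaussian blur, sigma 15 um, so that the texture's dark stripe
#' troughs do not fragment the cell-attached area), fills enclosed holes
#' smaller than (20 um)^2, and reports the foreground
#' centroid and the cell-attached area fraction relative to the nominal
#' rectangle area (`rect_length x rect_width`), with the inclusion flag
#' `area_fraction >= coverage_threshold`. A crop without usable
#' foreground/background contrast (blank or near-blank) gets area 0 and is
#' excluded — that is a data outcome, not an error.
#'
#' @param rect_image Primary-crop matrix (long axis horizontal).
#' @param grid A [grid_spec()] (for the nominal area and the scale).
#' @param coverage_threshold Inclusion threshold on the area fraction,
#'   default 0.8.
#' @return One-row tibble: `center_row`, `center_col`, `area_fraction`,
#'   `included`.
#' @export
detect_cell_region <- function(rect_image, grid, coverage_threshold = 0.8) {
  stopifnot(is.matrix(rect_image), inherits(grid, "grid_spec"))
  upp <- grid$um_per_px
  nominal_px <- grid$rect_length * grid$rect_width / upp^2
  none <- tibble::tibble(center_row = NA_real_, center_col = NA_real_,
                         area_fraction = 0, included = FALSE)
  if (diff(range(rect_image)) < 1e-6) return(none)
  sm <- EBImage::imageData(EBImage::gblur(EBImage::Image(rect_image),
                                          sigma = max(1, 15 / upp)))
  thr <- otsu_threshold(sm)
  mask <- sm > thr
  if (!any(mask) || all(mask)) return(none)
  # contrast floor: Otsu will split pure background noise too
  if (mean(sm[mask]) - mean(sm[!mask]) < 0.1) return(none)
  mask <- fill_small_holes(mask, max_area = (20 / upp)^2)
  idx <- which(mask, arr.ind = TRUE)
  area_fraction <- nrow(idx) / nominal_px
  tibble::tibble(center_row = mean(idx[, 1]), center_col = mean(idx[, 2]),
                 area_fraction = area_fraction,
                 included = area_fraction >= coverage_threshold)
}

# Otsu's threshold (EBImage's histogram implementation)
otsu_threshold <- function(im, levels = 256) {
  EBImage::otsu(EBImage::Image(im), range = range(im), levels = levels)
}

# fill background components fully enclosed by foreground and smaller
# than max_area px
fill_small_holes <- function(mask, max_area) {
  lab <- EBImage::imageData(EBImage::bwlabel(EBImage::Image(!mask)))
  mx <- max(lab)
  if (mx == 0) return(mask)
  border <- unique(c(lab[1, ], lab[nrow(lab), ], lab[, 1], lab[, ncol(lab)]))
  sizes <- tabulate(lab, nbins = mx)
  fill_ids <- setdiff(which(sizes < max_area), border)
  if (length(fill_ids)) mask[lab %in% fill_ids] <- TRUE
  mask
}

#' Secondary (central) crop of the cell-attached area
#'
#' The 400 x 200 um window centred on the detected cell centroid, clamped
#' so the window stays inside the primary crop (no intensity is ever
#' fabricated by padding).
#'
#' @param rect_image Primary-crop matrix.
#' @param region A [detect_cell_region()] row with `included = TRUE`.
#' @param grid A [grid_spec()].
#' @return Numeric matrix of size `200/um_per_px` x `400/um_per_px`.
#' @export
secondary_crop <- function(rect_image, region, grid) {
  if (!isTRUE(region$included)) {
    stop("secondary_crop called on an excluded region (area fraction below threshold)",
         call. = FALSE)
  }
  upp <- grid$um_per_px
  h <- round(200 / upp); w <- round(400 / upp)
  if (h > nrow(rect_image) || w > ncol(rect_image)) {
    stop("secondary window larger than the primary crop", call. = FALSE)
  }
  r0 <- round(region$center_row - h / 2)
  c0 <- round(region$center_col - w / 2)
  r0 <- min(max(r0, 0), nrow(rect_image) - h)
  c0 <- min(max(c0, 0), ncol(rect_image) - w)
  rect_image[(r0 + 1):(r0 + h), (c0 + 1):(c0 + w), drop = FALSE]
}
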