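#' Wrap angles to the axial half-circle (-90, 90]
#'
#' Axial (orientation) data are defined modulo 180 degrees: a fiber at +100
#' degrees is the same fiber as one at -80 degrees. All dominant-orientation
#' angles in this package live on the half-open interval (-90, 90].
#'
#' @param theta_deg Numeric vector of angles in degrees.
#' @return Numeric vector of the same length, wrapped to (-90, 90].
#' @examples
#' wrap_axial(c(-91, 90, 180, 270))
#' @export
wrap_axial <- function(theta_deg) {
  w <- ((theta_deg + 90) %% 180) - 90
  # %% maps to [-90, 90); the axial convention is half-open on the left
  w[w <= -90] <- 90
  w
}

#' Double axial angles onto the full circle
#'
#' Half-circle data in (-90, 90] are temporarily converted to full-circle
#' data in [0, 360) by doubling, so that ordinary circular statistics apply;
#' [halve_angles()] is the inverse.
#'
#' @param theta_deg Numeric vector of axial angles in degrees, (-90, 90].
#' @return Numeric vector of doubled angles in degrees, [0, 360).
#' @seealso [halve_angles()]
#' @examples
#' double_angles(c(-45, 0, 90))  # 270, 0, 180
#' @export
double_angles <- function(theta_deg) {
  stopifnot(is.numeric(theta_deg))
  (2 * theta_deg) %% 360
}

#' Halve full-circle angles back to the axial half-circle
#'
#' @param phi_deg Numeric vector of full-circle angles in degrees.
#' @return Numeric vector in (-90, 90].
#' @seealso [double_angles()]
#' @export
halve_angles <- function(phi_deg) {
  wrap_axial((phi_deg %% 360) / 2)
}

#' Signed axial difference a - b in (-90, 90]
#' @noRd
axial_diff <- function(a_deg, b_deg) {
  wrap_axial(a_deg - b_deg)
}

deg2rad <- function(x) x * pi / 180
rad2deg <- function(x) x * 180 / pi
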