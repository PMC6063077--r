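#' Cross-sectional geometry of a rectangular tracheid
#'
#' A differentiating tracheid is modelled as a rectangle in transverse
#' section: tangential diameter `CTD` (constant, the cell never grows
#' tangentially) by radial diameter `CRD = CA / CTD`.  The wall is a uniform
#' annulus of thickness `WT` lining the rectangle, so the wall area is
#'
#' \deqn{WA = 2\,CTD\,WT + 2\,WT\,(CRD - 2\,WT)}
#'
#' and conversely `WT` is the smaller root of the quadratic
#' \eqn{4 WT^2 - 2 (CTD + CRD) WT + WA = 0}.  The larger root would imply a
#' wall thicker than the half-cell and is geometrically meaningless.
#'
#' All lengths are in micrometres and all areas in square micrometres.
#'
#' @param CA Total cell cross-section area (um^2).
#' @param WA Wall area (um^2), `0 <= WA <= CA`.
#' @param CTD Cell tangential diameter (um).
#' @return `wall_thickness()` returns the wall thickness `WT` (um) as a
#'   numeric vector.
#' @examples
#' wall_thickness(CA = 327, WA = 40.55, CTD = 31)
#' derived_traits(CA = 327, WA = 40.55, CTD = 31)
#' initial_wall_area(CA0 = 327, CTD = 31, WT0 = 0.5)
#' @seealso [derived_traits()], [initial_wall_area()]
#' @export
wall_thickness <- function(CA, WA, CTD) {
  check_geometry_inputs(CA, WA, CTD)
  CRD <- CA / CTD
  # WA <= CA guarantees a non-negative discriminant analytically; floating
  # point jitter near the lumen-zero limit is clamped to 0.
  disc <- pmax(4 * (CTD + CRD)^2 - 16 * WA, 0)
  (2 * (CTD + CRD) - sqrt(disc)) / 8
}

#' @rdname wall_thickness
#' @return `derived_traits()` returns a tibble with one row per input state
#'   and columns `WT` (wall thickness, um), `CRD` (cell radial diameter, um),
#'   `LA` (lumen area, um^2) and `LRD` (lumen radial diameter, um).
#' @export
derived_traits <- function(CA, WA, CTD) {
  WT <- wall_thickness(CA, WA, CTD)
  CRD <- CA / CTD
  tibble(
    WT = WT,
    CRD = CRD,
    LA = CA - WA,
    LRD = pmax(CRD - 2 * WT, 0)
  )
}

#' @rdname wall_thickness
#' @param CA0 Initial cell area (um^2).
#' @param WT0 Primary wall thickness (um).
#' @return `initial_wall_area()` returns the primary wall area `WA0` (um^2):
#'   the area of a `WT0`-thick annulus inside a `CTD` by `CA0/CTD` rectangle.
#' @export
initial_wall_area <- function(CA0, CTD, WT0) {
  if (any(CTD <= 0)) {
    abort("`CTD` must be > 0.", class = "tracheidr_error_domain")
  }
  if (any(WT0 < 0)) {
    abort("`WT0` must be >= 0.", class = "tracheidr_error_domain")
  }
  CRD0 <- CA0 / CTD
  if (any(2 * WT0 >= CTD & WT0 > 0) || any(2 * WT0 >= CRD0 & WT0 > 0)) {
    abort(
      "Primary wall too thick: the lumen rectangle (CTD - 2 WT0) x (CRD0 - 2 WT0) must have positive sides.",
      class = "tracheidr_error_domain"
    )
  }
  2 * CTD * WT0 + 2 * WT0 * (CRD0 - 2 * WT0)
}

check_geometry_inputs <- function(CA, WA, CTD) {
  if (any(CA <= 0) || any(CTD <= 0)) {
    abort("`CA` and `CTD` must be > 0.", class = "tracheidr_error_domain")
  }
  if (any(WA < 0)) {
    abort("`WA` must be >= 0.", class = "tracheidr_error_domain")
  }
  if (any(WA > CA * (1 + 1e-9))) {
    abort("`WA` must not exceed `CA`.", class = "tracheidr_error_domain")
  }
  invisible(NULL)
}
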