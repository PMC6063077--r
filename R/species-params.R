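#' Species parameter sets
#'
#' `species_params()` bundles the fixed geometry of a cambial derivative
#' (initial cell area `CA0`, initial wall area `WA0`, tangential diameter
#' `CTD`, primary wall thickness `WT0`) with the calibrated kinetic constants
#' of the differentiation model:
#'
#' * `vc` -- specific enlargement rate (1/d),
#' * `CAmax` -- maximum cell area (um^2),
#' * `WTstar` -- wall-thickness threshold ending enlargement (um),
#' * `vw`, `WAmax`, `mw`, `sw` -- wall-deposition rate (um^2/d), wall-area
#'   ceiling (um^2) and the half-saturation scale / shape exponent of the
#'   lumen feedback on deposition,
#' * `vl`, `ml`, `sl` -- the analogous constants for lignification.
#'
#' All invariants are checked on construction and violations are reported by
#' name.
#'
#' @param name Species label.
#' @param CA0,WA0,CTD,WT0 Fixed initial geometry. `WA0 = NULL` computes the
#'   primary wall area from `CA0`, `CTD` and `WT0` via [initial_wall_area()].
#' @param vc,CAmax,WTstar,vw,WAmax,mw,sw,vl,ml,sl Kinetic constants (see
#'   Details).
#' @param LWA0 Initial lignified area; always 0 for a fresh derivative.
#' @return An object of class `species_params` (a named list).
#' @examples
#' p <- tracheid_species("Larix decidua")$params
#' p$WTstar
#' @seealso [tracheid_species()], [read_species_params()]
#' @export
species_params <- function(name, CA0, CTD, WT0, vc, CAmax, WTstar, vw, WAmax,
                           mw, sw, vl, ml, sl, WA0 = NULL, LWA0 = 0) {
  if (is.null(WA0)) WA0 <- initial_wall_area(CA0, CTD, WT0)
  p <- structure(
    list(
      name = as.character(name),
      CA0 = as.numeric(CA0), WA0 = as.numeric(WA0), LWA0 = as.numeric(LWA0),
      CTD = as.numeric(CTD), WT0 = as.numeric(WT0),
      vc = as.numeric(vc), CAmax = as.numeric(CAmax),
      WTstar = as.numeric(WTstar),
      vw = as.numeric(vw), WAmax = as.numeric(WAmax),
      mw = as.numeric(mw), sw = as.numeric(sw),
      vl = as.numeric(vl), ml = as.numeric(ml), sl = as.numeric(sl)
    ),
    class = "species_params"
  )
  validate_species_params(p)
}

#' @rdname species_params
#' @param x Object to validate or print.
#' @export
validate_species_params <- function(x) {
  stopifnot(is.list(x))
  num <- c(
    "CA0", "WA0", "LWA0", "CTD", "WT0", "vc", "CAmax", "WTstar",
    "vw", "WAmax", "mw", "sw", "vl", "ml", "sl"
  )
  missing <- setdiff(num, names(x))
  if (length(missing)) {
    abort(
      paste0("Missing parameter(s): ", paste(missing, collapse = ", "), "."),
      class = "tracheidr_error_params"
    )
  }
  bad <- num[!vapply(x[num], function(v) is.numeric(v) && length(v) == 1 && is.finite(v), TRUE)]
  if (length(bad)) {
    abort(
      paste0("Parameter(s) not a finite number: ", paste(bad, collapse = ", "), "."),
      class = "tracheidr_error_params"
    )
  }
  fail <- function(msg) abort(msg, class = "tracheidr_error_params")
  with(x, {
    if (CTD <= 0) fail("Invariant violated: CTD > 0.")
    if (WT0 < 0) fail("Invariant violated: WT0 >= 0.")
    if (LWA0 != 0) fail("Invariant violated: LWA0 = 0 (a fresh derivative has no lignified wall).")
    if (!(CA0 > WA0) || WA0 < 0) fail("Invariant violated: CA0 > WA0 >= 0.")
    if (2 * WT0 >= CTD || 2 * WT0 >= CA0 / CTD) {
      fail("Invariant violated: 2*WT0 < CTD and 2*WT0 < CA0/CTD (lumen must exist).")
    }
    for (pp in c("vc", "CAmax", "WTstar", "vw", "WAmax", "mw", "sw", "vl", "ml", "sl")) {
      if (get(pp) <= 0) fail(paste0("Invariant violated: ", pp, " > 0."))
    }
    if (WTstar <= WT0) fail("Invariant violated: WTstar > WT0 (enlargement must be possible).")
    if (WAmax <= WA0) fail("Invariant violated: WAmax > WA0.")
    if (CAmax <= CA0) fail("Invariant violated: CAmax > CA0.")
  })
  invisible(x)
}

#' @export
print.species_params <- function(x, ...) {
  cat("<species_params> ", x$name, "\n", sep = "")
  cat(
    sprintf(
      "  geometry: CA0 = %g um^2, WA0 = %g um^2, CTD = %g um, WT0 = %g um\n",
      x$CA0, x$WA0, x$CTD, x$WT0
    )
  )
  cat(
    sprintf(
      "  enlargement: vc = %g /d, CAmax = %g um^2, WT* = %g um\n",
      x$vc, x$CAmax, x$WTstar
    )
  )
  cat(
    sprintf(
      "  wall:        vw = %g um^2/d, WAmax = %g um^2, mw = %g, sw = %g\n",
      x$vw, x$WAmax, x$mw, x$sw
    )
  )
  cat(sprintf("  lignin:      vl = %g um^2/d, ml = %g, sl = %g\n", x$vl, x$ml, x$sl))
  invisible(x)
}

# Published parameter sets for the four study species.  WA0 is the printed
# (rounded) value; initial_wall_area() reproduces it to within 0.5 um^2.
.species_fixtures <- list(
  "Pinus cembra" = list(
    params = list(
      CA0 = 327, WA0 = 41, CTD = 31, WT0 = 0.5,
      vc = 0.39, CAmax = 3180, WTstar = 1.10,
      vw = 8.54, WAmax = 915, mw = 505, sw = 5.58,
      vl = 7.79, ml = 515, sl = 5.63
    ),
    curve = list(family = "quadratic", a = 1.77, b = -0.07, c = 1.60)
  ),
  "Picea abies" = list(
    params = list(
      CA0 = 248, WA0 = 35, CTD = 27, WT0 = 0.5,
      vc = 0.44, CAmax = 2206, WTstar = 1.02,
      vw = 8.18, WAmax = 1145, mw = 503, sw = 5.34,
      vl = 8.23, ml = 523, sl = 5.44
    ),
    curve = list(family = "quadratic", a = 1.46, b = -0.10, c = 1.81)
  ),
  "Larix decidua" = list(
    params = list(
      CA0 = 308, WA0 = 39, CTD = 30, WT0 = 0.5,
      vc = 0.39, CAmax = 2989, WTstar = 1.85,
      vw = 11.26, WAmax = 553, mw = 124, sw = 2.77,
      vl = 10.77, ml = 108, sl = 0.56
    ),
    curve = list(family = "quadratic", a = 2.78, b = -0.53, c = 1.83)
  ),
  "Picea mariana" = list(
    params = list(
      CA0 = 362, WA0 = 43, CTD = 33, WT0 = 0.5,
      vc = 0.41, CAmax = 1402, WTstar = 1.71,
      vw = 11.43, WAmax = 596, mw = 193, sw = 4.18,
      vl = 12.96, ml = 100, sl = 0.45
    ),
    curve = list(family = "exponential", a = 0.03, b = 4.15, c = 0.79)
  )
)

#' Bundled species fixtures
#'
#' Returns the published parameter set and seasonal sugar-availability curve
#' for one of the four study species.  `tracheid_species_names()` lists the
#' available species.
#'
#' @param species Species name, one of `tracheid_species_names()`
#'   (case-insensitive).
#' @return A list with elements `params` (a [species_params()] object) and
#'   `curve` (a [sugar_curve()] object).
#' @examples
#' fx <- tracheid_species("Picea mariana")
#' fx$curve
#' @export
tracheid_species <- function(species) {
  stopifnot(is.character(species), length(species) == 1)
  idx <- match(tolower(species), tolower(names(.species_fixtures)))
  if (is.na(idx)) {
    abort(
      paste0(
        "Unknown species '", species, "'. Available: ",
        paste(names(.species_fixtures), collapse = ", "), "."
      ),
      class = "tracheidr_error_species"
    )
  }
  fx <- .species_fixtures[[idx]]
  name <- names(.species_fixtures)[idx]
  list(
    params = do.call(species_params, c(list(name = name), fx$params)),
    curve = sugar_curve(fx$curve$family, fx$curve$a, fx$curve$b, fx$curve$c)
  )
}

#' @rdname tracheid_species
#' @export
tracheid_species_names <- function() names(.species_fixtures)
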