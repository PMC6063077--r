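#' Construct a tracheidogram
#'
#' A tracheidogram is the ordered series of anatomical traits (lumen area
#' `LA`, lumen radial diameter `LRD`, wall thickness `WT`) of consecutive
#' cells along a radial file of one tree ring, from the first (earlywood
#' side) to the last cell.  `as_tracheidogram()` validates a plain data frame
#' and attaches metadata; the `latewood` flag is recomputed from Mork's
#' formula when absent.
#'
#' @param x A data frame with columns `rel_position`, `LA`, `LRD`, `WT`
#'   (plus optional `cell`, `latewood` and any extra columns, which are
#'   kept).
#' @param species,source,curve Metadata: species label, data source
#'   (`"simulated"`, `"observed"` or `"synthetic"`) and the [sugar_curve()]
#'   used (or `NULL`).
#' @return A tibble of class `tracheidogram`.
#' @export
as_tracheidogram <- function(x, species = NA_character_,
                             source = c("observed", "simulated", "synthetic"),
                             curve = NULL) {
  source <- match.arg(source)
  x <- as_tibble(x)
  required <- c("rel_position", "LA", "LRD", "WT")
  missing <- setdiff(required, names(x))
  if (length(missing)) {
    abort(
      paste0("Missing tracheidogram column(s): ", paste(missing, collapse = ", "), "."),
      class = "tracheidr_error_missing_column"
    )
  }
  if (nrow(x) < 1) {
    abort("A tracheidogram needs at least one cell.", class = "tracheidr_error_empty")
  }
  pos <- x$rel_position
  if (any(!is.finite(pos)) || any(pos < 0 | pos > 1) || any(diff(pos) <= 0)) {
    abort(
      "`rel_position` must be strictly increasing within [0, 1].",
      class = "tracheidr_error_positions"
    )
  }
  for (tr in c("LA", "LRD", "WT")) {
    if (any(!is.finite(x[[tr]])) || any(x[[tr]] < 0)) {
      abort(
        paste0("Trait `", tr, "` must be finite and >= 0."),
        class = "tracheidr_error_negative_trait"
      )
    }
  }
  if (is.null(x[["cell"]])) x$cell <- seq_len(nrow(x))
  if (is.null(x[["latewood"]])) x$latewood <- mork_latewood(x$LRD, x$WT)
  x <- dplyr::relocate(x, "cell", "rel_position", "LA", "LRD", "WT", "latewood")
  structure(
    x,
    class = unique(c("tracheidogram", class(x))),
    species = species,
    n_cells = nrow(x),
    source = source,
    curve = curve
  )
}

#' Simulate a whole tree ring of tracheids
#'
#' Places `n_cells` cells at relative positions `x_i = (i - 1) / (n_cells -
#' 1)` across the ring, evaluates the sugar-availability curve at each
#' position, and develops every cell independently with [simulate_cell()]'s
#' dynamics (cells do not interact; the season enters only through `S`).
#' Each cell's terminal anatomy (at death) forms one row of the simulated
#' tracheidogram.
#'
#' @inheritParams simulate_cell
#' @param curve A [sugar_curve()] giving `S` as a function of ring position.
#' @param n_cells Number of cells across the ring (`>= 2`).
#' @return A tibble of class `tracheidogram` with columns `cell`,
#'   `rel_position`, `LA`, `LRD`, `WT`, `latewood`, `sugar`, `CA`, `WA`,
#'   `enl_days`, `thick_days`.
#' @examples
#' fx <- tracheid_species("Larix decidua")
#' ring <- simulate_ring(fx$params, fx$curve, n_cells = 20, dt = 0.05)
#' latewood_percentage(ring)
#' @seealso [latewood_percentage()], [write_tracheidogram()]
#' @export
simulate_ring <- function(params, curve, n_cells = 100, dt = 0.01, tmax = 200,
                          death_tol = 1e-8, saturation = "hill") {
  validate_species_params(params)
  stopifnot(inherits(curve, "sugar_curve"), n_cells >= 2)
  x <- (seq_len(n_cells) - 1) / (n_cells - 1)
  S <- sugar_at(curve, x)
  res <- rk4_cells(params, S, dt, tmax, death_tol, saturation, keep_path = FALSE)
  if (any(!res$died)) {
    bad <- which(!res$died)
    abort(
      sprintf(
        "%d cell(s) did not complete lignification by tmax = %g d (first: cell %d at x = %.3f, S = %.3f). Increase `tmax`.",
        length(bad), tmax, bad[1], x[bad[1]], S[bad[1]]
      ),
      class = "tracheidr_error_nontermination"
    )
  }
  traits <- derived_traits(res$CA, res$WA, params$CTD)
  out <- tibble(
    cell = seq_len(n_cells),
    rel_position = x,
    LA = traits$LA,
    LRD = traits$LRD,
    WT = traits$WT,
    latewood = mork_latewood(traits$LRD, traits$WT),
    sugar = S,
    CA = res$CA,
    WA = res$WA,
    enl_days = res$t_enl,
    thick_days = res$t_death - res$t_enl
  )
  structure(
    out,
    class = unique(c("tracheidogram", class(out))),
    species = params$name %||% NA_character_,
    n_cells = n_cells,
    source = "simulated",
    curve = curve,
    dt = dt,
    saturation = saturation
  )
}

#' Mork's earlywood/latewood classification
#'
#' A cell is latewood when its lumen radial diameter is no larger than twice
#' the double wall thickness, i.e. `LRD <= 4 * WT` (the tie is classified as
#' latewood).
#'
#' @param LRD Lumen radial diameter (um).
#' @param WT Wall thickness (um).
#' @return A logical vector, `TRUE` for latewood.
#' @examples
#' mork_latewood(LRD = c(13.0, 16.3), WT = c(3.9, 3.6))
#' @export
mork_latewood <- function(LRD, WT) {
  stopifnot(all(LRD >= 0), all(WT >= 0))
  LRD <= 4 * WT
}

#' @rdname mork_latewood
#' @param tr A `tracheidogram`.
#' @return `latewood_percentage()` returns the percentage (0--100) of
#'   latewood cells in the ring.
#' @export
latewood_percentage <- function(tr) {
  stopifnot(is.data.frame(tr))
  if (nrow(tr) == 0) {
    abort("Empty tracheidogram.", class = "tracheidr_error_empty")
  }
  lw <- tr[["latewood"]] %||% mork_latewood(tr$LRD, tr$WT)
  100 * mean(lw)
}

#' @export
print.tracheidogram <- function(x, ...) {
  cat(
    sprintf(
      "<tracheidogram> %s, %d cells, source: %s\n",
      attr(x, "species") %||% "?", nrow(x), attr(x, "source") %||% "?"
    )
  )
  if (!is.null(x[["latewood"]])) {
    cat(sprintf("  latewood: %.1f%%\n", latewood_percentage(x)))
  }
  NextMethod()
}
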