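#' Standardize a tracheidogram to a target cell count
#'
#' Observed radial files differ in cell number; before averaging or fitting
#' they are resampled onto a common count by linear interpolation of each
#' trait against normalized ring position.  End cells are preserved exactly.
#'
#' @param tr A `tracheidogram` (or data frame with `rel_position`, `LA`,
#'   `LRD`, `WT`).
#' @param n_target Number of cells after resampling (`>= 2`).
#' @return A `tracheidogram` with `n_target` cells at equidistant positions;
#'   the `latewood` flag is recomputed from the resampled traits.
#' @examples
#' fx <- tracheid_species("Picea abies")
#' ring <- simulate_ring(fx$params, fx$curve, n_cells = 30, dt = 0.05)
#' standardize_tracheidogram(ring, 10)
#' @export
standardize_tracheidogram <- function(tr, n_target) {
  stopifnot(is.data.frame(tr))
  if (nrow(tr) < 2) {
    abort("Standardization needs at least 2 cells.", class = "tracheidr_error_length")
  }
  if (n_target < 2) {
    abort("`n_target` must be >= 2.", class = "tracheidr_error_length")
  }
  x_in <- tr$rel_position
  # tolerate an un-normalized position column (e.g. raw cell index)
  x_in <- (x_in - min(x_in)) / (max(x_in) - min(x_in))
  x_out <- (seq_len(n_target) - 1) / (n_target - 1)
  out <- tibble(
    cell = seq_len(n_target),
    rel_position = x_out,
    LA = approx(x_in, tr$LA, x_out)$y,
    LRD = approx(x_in, tr$LRD, x_out)$y,
    WT = approx(x_in, tr$WT, x_out)$y
  )
  as_tracheidogram(
    out,
    species = attr(tr, "species") %||% NA_character_,
    source = (attr(tr, "source") %||% "observed"),
    curve = attr(tr, "curve")
  )
}

#' Sum-of-squares objective and goodness of fit
#'
#' The calibration objective is the unweighted sum of squared errors over the
#' three traits of aligned observed and simulated tracheidograms:
#' \deqn{SSE = \sum_i (WT_i - WT_i^*)^2 + \sum_i (LRD_i - LRD_i^*)^2 +
#'   \sum_i (LA_i - LA_i^*)^2}
#' in raw units (um and um^2 terms summed as such, so the lumen-area term
#' numerically dominates; see `weights` for an optional reweighting hook,
#' off by default).
#'
#' `sse_objective()` evaluates the objective at a candidate value of the free
#' parameters by running the forward ring model; invalid parameter sets and
#' non-terminating cells return a large finite penalty so a simplex search
#' can recover.  `fit_statistics()` reports the per-trait SSE components and
#' coefficients of determination for two aligned tracheidograms.
#'
#' @param values Numeric vector of candidate values, same length and order as
#'   `free`.
#' @param free Character vector naming the free parameters: any of `vc`,
#'   `CAmax`, `WTstar`, `vw`, `WAmax`, `mw`, `sw`, `vl`, `ml`, `sl` (kinetic,
#'   positive-constrained) and `a`, `b`, `c` (sugar-curve coefficients).
#' @param observed Observed (or synthetic) `tracheidogram`, already
#'   standardized to the forward model's cell count.
#' @param params Base [species_params()]; fixed parameters are taken from
#'   here.
#' @param curve Base [sugar_curve()]; fixed coefficients are taken from here.
#' @param dt,tmax,saturation Forward-model settings, as in [simulate_ring()].
#' @param weights Optional named per-trait weights `c(WT =, LRD =, LA =)`;
#'   `NULL` (default) is the plain unweighted objective.
#' @param penalty Value returned for infeasible parameter sets.
#' @return `sse_objective()`: a single number, the (penalised) SSE.
#' @export
sse_objective <- function(values, free, observed, params, curve,
                          dt = 0.01, tmax = 200, saturation = "hill",
                          weights = NULL, penalty = 1e12) {
  stopifnot(length(values) == length(free))
  unknown <- setdiff(free, c(.calib_kinetic, .calib_curve))
  if (length(unknown)) {
    abort(
      paste0("Unknown free parameter(s): ", paste(unknown, collapse = ", "), "."),
      class = "tracheidr_error_params"
    )
  }
  cand <- try(substitute_free(values, free, params, curve), silent = TRUE)
  if (inherits(cand, "try-error")) return(penalty)
  sim <- tryCatch(
    simulate_ring(cand$params, cand$curve,
      n_cells = nrow(observed),
      dt = dt, tmax = tmax, saturation = saturation
    ),
    error = function(e) NULL
  )
  if (is.null(sim)) return(penalty)
  comp <- sse_components(observed, sim)
  w <- weights %||% c(WT = 1, LRD = 1, LA = 1)
  sum(w[c("WT", "LRD", "LA")] * comp[c("WT", "LRD", "LA")])
}

.calib_kinetic <- c(
  "vc", "CAmax", "WTstar", "vw", "WAmax", "mw", "sw", "vl", "ml", "sl"
)
.calib_curve <- c("a", "b", "c")

substitute_free <- function(values, free, params, curve) {
  unknown <- setdiff(free, c(.calib_kinetic, .calib_curve))
  if (length(unknown)) {
    abort(
      paste0("Unknown free parameter(s): ", paste(unknown, collapse = ", "), "."),
      class = "tracheidr_error_params"
    )
  }
  p <- unclass(params)
  for (i in seq_along(free)) {
    if (free[i] %in% .calib_kinetic) p[[free[i]]] <- values[i]
  }
  p <- validate_species_params(structure(p, class = "species_params"))
  cc <- curve[c("a", "b", "c")]
  for (i in seq_along(free)) {
    if (free[i] %in% .calib_curve) cc[[free[i]]] <- values[i]
  }
  list(
    params = p,
    curve = sugar_curve(curve$family, cc$a, cc$b, cc$c)
  )
}

sse_components <- function(observed, simulated) {
  if (nrow(observed) != nrow(simulated)) {
    abort(
      sprintf(
        "Observed (%d cells) and simulated (%d cells) tracheidograms must be aligned; standardize first.",
        nrow(observed), nrow(simulated)
      ),
      class = "tracheidr_error_length"
    )
  }
  vapply(
    c(WT = "WT", LRD = "LRD", LA = "LA"),
    function(tr) sum((observed[[tr]] - simulated[[tr]])^2),
    numeric(1)
  )
}

#' @rdname sse_objective
#' @param simulated Simulated `tracheidogram`, same cell count as `observed`.
#' @return `fit_statistics()`: a tibble with columns `trait`, `sse`, `r2`.
#' @export
fit_statistics <- function(observed, simulated) {
  comp <- sse_components(observed, simulated)
  r2 <- vapply(
    c(WT = "WT", LRD = "LRD", LA = "LA"),
    function(tr) {
      ss_tot <- sum((observed[[tr]] - mean(observed[[tr]]))^2)
      if (ss_tot == 0) {
        return(NA_real_)
      }
      1 - comp[[tr]] / ss_tot
    },
    numeric(1)
  )
  tibble(trait = c("WT", "LRD", "LA"), sse = unname(comp), r2 = unname(r2))
}

#' Calibrate model parameters against an observed tracheidogram
#'
#' Minimizes the [sse_objective()] over a chosen set of free parameters with
#' the Nelder-Mead simplex (via [stats::optim()]).  Positive-constrained
#' kinetic parameters are searched in log space; sugar-curve coefficients
#' `a`, `b`, `c` may be negative and are searched untransformed.  The search
#' restarts from `n_starts` multiplicatively jittered copies of the initial
#' point (the first start is the unjittered initial point) and keeps the best
#' result; the jitter stream is seeded, so a calibration is deterministic
#' given its arguments.
#'
#' @inheritParams sse_objective
#' @param observed Observed `tracheidogram`; its cell count defines the
#'   forward model's grid (standardize first if needed).
#' @param free Names of the parameters to fit.
#' @param start Optional named list/vector of initial values for the free
#'   parameters; defaults to their values in `params` / `curve`.
#' @param maxit,reltol [stats::optim()] Nelder-Mead iteration cap and
#'   relative convergence tolerance.
#' @param n_starts Number of simplex starts (first one unjittered).
#' @param jitter Relative half-width of the multiplicative start jitter.
#' @param seed Integer seed for the jitter stream.
#' @return An object of class `tracheid_fit`; see [tidy.tracheid_fit()] and
#'   [glance.tracheid_fit()].
#' @examples
#' \donttest{
#' fx <- tracheid_species("Larix decidua")
#' obs <- generate_synthetic_tracheidogram(
#'   fx$params, fx$curve,
#'   n_cells = 15, cv = 0, dt = 0.1
#' )
#' fit <- calibrate_tracheids(
#'   obs, fx$params, fx$curve,
#'   free = "c",
#'   start = list(c = 2.1), dt = 0.1, n_starts = 1, maxit = 200
#' )
#' tidy(fit)
#' }
#' @export
calibrate_tracheids <- function(observed, params, curve,
                                free = c("a", "b", "c"), start = NULL,
                                dt = 0.01, tmax = 200, saturation = "hill",
                                weights = NULL, maxit = 2000, reltol = 1e-6,
                                n_starts = 5, jitter = 0.1, seed = 42L) {
  stopifnot(is.data.frame(observed), length(free) >= 1)
  for (tr in c("WT", "LRD", "LA")) {
    if (is.null(observed[[tr]])) {
      abort(
        paste0("Observed tracheidogram lacks trait `", tr, "`."),
        class = "tracheidr_error_missing_column"
      )
    }
  }
  validate_species_params(params)
  stopifnot(inherits(curve, "sugar_curve"))

  defaults <- c(unclass(params)[.calib_kinetic], curve[c("a", "b", "c")])
  x0 <- vapply(free, function(f) {
    s <- start[[f]] %||% defaults[[f]]
    as.numeric(s)
  }, numeric(1))
  names(x0) <- free
  logged <- free %in% .calib_kinetic # positive-constrained -> log space

  to_search <- function(x) ifelse(logged, log(x), x)
  from_search <- function(z) ifelse(logged, exp(z), z)
  obj <- function(z) {
    sse_objective(
      from_search(z), free, observed, params, curve,
      dt = dt, tmax = tmax, saturation = saturation, weights = weights
    )
  }

  starts <- with_preserved_rng(seed, {
    lapply(seq_len(n_starts), function(i) {
      if (i == 1) {
        return(x0)
      }
      x0 * (1 + runif(length(x0), -jitter, jitter))
    })
  })

  runs <- lapply(starts, function(s) {
    withCallingHandlers(
      optim(to_search(s), obj,
        method = "Nelder-Mead",
        control = list(maxit = maxit, reltol = reltol)
      ),
      # optim advises against Nelder-Mead for 1-D problems; the simplex is
      # the documented algorithm here and works, so silence the advisory
      warning = function(w) {
        if (grepl("Nelder-Mead", conditionMessage(w))) invokeRestart("muffleWarning")
      }
    )
  })
  best <- runs[[which.min(vapply(runs, `[[`, numeric(1), "value"))]]
  est <- from_search(best$par)
  names(est) <- free

  fitted <- substitute_free(est, free, params, curve)
  sim <- simulate_ring(fitted$params, fitted$curve,
    n_cells = nrow(observed),
    dt = dt, tmax = tmax, saturation = saturation
  )
  stats <- fit_statistics(observed, sim)

  structure(
    list(
      estimates = tibble(
        term = free,
        start = unname(x0),
        estimate = unname(est),
        log_scale = logged
      ),
      params = fitted$params,
      curve = fitted$curve,
      simulated = sim,
      observed = observed,
      sse = best$value,
      components = setNames(stats$sse, stats$trait),
      r2 = setNames(stats$r2, stats$trait),
      converged = best$convergence == 0,
      iterations = unname(best$counts["function"]),
      n_starts = n_starts,
      settings = list(
        dt = dt, tmax = tmax, saturation = saturation,
        maxit = maxit, reltol = reltol, jitter = jitter, seed = seed
      )
    ),
    class = "tracheid_fit"
  )
}

# Evaluate `expr` under a temporary RNG state seeded with `seed`, restoring
# the caller's stream afterwards.
with_preserved_rng <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  expr
}

#' @export
print.tracheid_fit <- function(x, ...) {
  cat(
    sprintf(
      "<tracheid_fit> %d free parameter(s), %d cells, %s\n",
      nrow(x$estimates), nrow(x$observed),
      if (x$converged) "converged" else "NOT converged"
    )
  )
  cat(sprintf(
    "  SSE = %.6g (WT %.4g + LRD %.4g + LA %.4g)\n",
    x$sse, x$components[["WT"]], x$components[["LRD"]], x$components[["LA"]]
  ))
  print(x$estimates)
  invisible(x)
}

#' Broom-style accessors for a calibration fit
#'
#' `tidy()` returns one row per fitted parameter; `glance()` returns a
#' one-row summary of the fit.
#'
#' @param x A `tracheid_fit` from [calibrate_tracheids()].
#' @param ... Unused.
#' @return A tibble.
#' @method tidy tracheid_fit
#' @export
tidy.tracheid_fit <- function(x, ...) {
  x$estimates[c("term", "estimate", "start")]
}

#' @rdname tidy.tracheid_fit
#' @method glance tracheid_fit
#' @export
glance.tracheid_fit <- function(x, ...) {
  tibble(
    sse = x$sse,
    sse_wt = x$components[["WT"]],
    sse_lrd = x$components[["LRD"]],
    sse_la = x$components[["LA"]],
    r2_wt = x$r2[["WT"]],
    r2_lrd = x$r2[["LRD"]],
    r2_la = x$r2[["LA"]],
    converged = x$converged,
    iterations = x$iterations,
    n_starts = x$n_starts
  )
}
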