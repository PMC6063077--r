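#' Instantaneous rates of the tracheid differentiation model
#'
#' The state of one differentiating tracheid is `(CA, WA, LWA)`: total cell
#' area, wall area and lignified wall area (um^2).  Three coupled ordinary
#' differential equations govern its development:
#'
#' * **Enlargement** -- logistic radial growth, braked by the thickening
#'   wall and halted once `WT` reaches the threshold `WT*`:
#'   \deqn{dCA/dt = v_c\, CA\, (1 - CA/CA_{max})\, (1 - \min(1, WT/WT^*))}
#' * **Wall deposition** -- driven by sugar availability `S`, limited by the
#'   wall-area ceiling and by a saturating feedback of the shrinking lumen:
#'   \deqn{dWA/dt = v_w\, S\, (1 - WA/WA_{max})\, f_w(CA - WA)\, D}
#' * **Lignification** -- driven by `S` with its own lumen feedback:
#'   \deqn{dLWA/dt = v_l\, S\, f_l(CA - WA)\, D}
#'
#' where `D` is the death indicator (1 while `LWA < WA`, 0 once the wall is
#' fully lignified) and the lumen feedback is, with `L = CA - WA` the lumen
#' area,
#' \deqn{f(L) = 1 - \frac{1}{1 + (L/m)^{s}} \quad (\code{saturation = "hill"})}
#' or, under the alternative reading,
#' \deqn{f(L) = 1 - (1 + L/m)^{-s} \quad (\code{saturation = "compound"}).}
#'
#' Under the Hill form `m` is the lumen area at which the rate reaches half
#' its ceiling and `s` controls the sharpness of the switch; this form is the
#' default (see the package vignette for why).  Wall thickness `WT` is a
#' state-dependent quantity, recomputed from `(CA, WA)` by
#' [wall_thickness()] at every evaluation.
#'
#' @param CA,WA,LWA State vectors (um^2).
#' @param S Sugar availability (dimensionless, `>= 0`).
#' @param params A [species_params()] object (or a named list with the same
#'   fields).
#' @param saturation Form of the lumen feedback term, `"hill"` (default) or
#'   `"compound"`.
#' @return The time derivative of `CA`, `WA` or `LWA` (um^2/d).
#' @examples
#' p <- tracheid_species("Larix decidua")$params
#' enlargement_rate(CA = 308, WA = 39, params = p)
#' wall_deposition_rate(CA = 308, WA = 39, LWA = 0, S = 1.58, params = p)
#' @name tracheid_rates
NULL

saturation_factor <- function(lumen, m, s, saturation = c("hill", "compound")) {
  saturation <- match.arg(saturation)
  lumen <- pmax(lumen, 0)
  switch(saturation,
    hill = 1 - 1 / (1 + (lumen / m)^s),
    compound = 1 - (1 + lumen / m)^(-s)
  )
}

#' @rdname tracheid_rates
#' @export
enlargement_rate <- function(CA, WA, params, saturation = "hill") {
  WT <- wall_thickness(CA, WA, params$CTD)
  params$vc * CA * (1 - CA / params$CAmax) * (1 - pmin(1, WT / params$WTstar))
}

#' @rdname tracheid_rates
#' @export
wall_deposition_rate <- function(CA, WA, LWA, S, params, saturation = "hill") {
  stopifnot(all(S >= 0))
  death <- as.numeric(LWA < WA)
  fw <- saturation_factor(CA - WA, params$mw, params$sw, saturation)
  params$vw * S * (1 - WA / params$WAmax) * fw * death
}

#' @rdname tracheid_rates
#' @export
lignification_rate <- function(CA, WA, LWA, S, params, saturation = "hill") {
  stopifnot(all(S >= 0))
  death <- as.numeric(LWA < WA)
  fl <- saturation_factor(CA - WA, params$ml, params$sl, saturation)
  params$vl * S * fl * death
}

# Right-hand side of the ODE system, vectorised over cells.  `alive` freezes
# every derivative of a dead cell (completed lignification ends all dynamics).
cell_rhs <- function(CA, WA, LWA, S, params, alive, saturation) {
  WT <- wall_thickness(CA, WA, params$CTD)
  lumen <- pmax(CA - WA, 0)
  growing <- as.numeric(alive)
  depositing <- as.numeric((LWA < WA) & alive)
  fw <- saturation_factor(lumen, params$mw, params$sw, saturation)
  fl <- saturation_factor(lumen, params$ml, params$sl, saturation)
  list(
    dCA = params$vc * CA * (1 - CA / params$CAmax) *
      (1 - pmin(1, WT / params$WTstar)) * growing,
    dWA = params$vw * S * (1 - WA / params$WAmax) * fw * depositing,
    dLWA = params$vl * S * fl * depositing
  )
}

# Fixed-step classical Runge-Kutta (RK4) integration of a cohort of cells,
# one sugar value per cell, vectorised over the cohort.  Cells are mutually
# independent; the cohort form exists purely for speed.
#
# Event handling per step k -> k+1:
#   * enlargement end: first crossing WT >= WTstar, linearly interpolated
#     between the bracketing steps;
#   * death: first crossing LWA >= WA - death_tol, linearly interpolated on
#     the gap WA - LWA; LWA is clamped to WA and the cell is frozen.
# Sub-step interpolation removes the O(dt) bias a step-quantised event time
# would put on reported phase durations.
rk4_cells <- function(params, S, dt = 0.01, tmax = 200, death_tol = 1e-8,
                      saturation = "hill", keep_path = FALSE) {
  stopifnot(dt > 0, tmax > 0, length(S) >= 1, all(is.finite(S)), all(S >= 0))
  n <- length(S)
  CA <- rep(params$CA0, n)
  WA <- rep(params$WA0, n)
  LWA <- rep(params$LWA0 %||% 0, n)
  alive <- rep(TRUE, n)
  t_enl <- rep(NA_real_, n)
  t_death <- rep(NA_real_, n)
  enl_censored <- rep(FALSE, n)

  WT_prev <- wall_thickness(CA, WA, params$CTD)
  # enlargement already over at t = 0 (degenerate threshold)
  t_enl[WT_prev >= params$WTstar] <- 0
  gap_prev <- WA - LWA
  n_steps <- ceiling(tmax / dt)

  path <- NULL
  if (keep_path) {
    path <- matrix(NA_real_, nrow = n_steps + 1, ncol = 3 * n)
    path[1, ] <- c(CA, WA, LWA)
  }
  last_step <- 0L

  for (step in seq_len(n_steps)) {
    if (!any(alive)) break
    k1 <- cell_rhs(CA, WA, LWA, S, params, alive, saturation)
    k2 <- cell_rhs(
      CA + dt / 2 * k1$dCA, WA + dt / 2 * k1$dWA, LWA + dt / 2 * k1$dLWA,
      S, params, alive, saturation
    )
    k3 <- cell_rhs(
      CA + dt / 2 * k2$dCA, WA + dt / 2 * k2$dWA, LWA + dt / 2 * k2$dLWA,
      S, params, alive, saturation
    )
    k4 <- cell_rhs(
      CA + dt * k3$dCA, WA + dt * k3$dWA, LWA + dt * k3$dLWA,
      S, params, alive, saturation
    )
    CA <- CA + dt / 6 * (k1$dCA + 2 * k2$dCA + 2 * k3$dCA + k4$dCA)
    WA <- WA + dt / 6 * (k1$dWA + 2 * k2$dWA + 2 * k3$dWA + k4$dWA)
    LWA <- LWA + dt / 6 * (k1$dLWA + 2 * k2$dLWA + 2 * k3$dLWA + k4$dLWA)
    t <- step * dt
    last_step <- step

    WT_now <- wall_thickness(CA, WA, params$CTD)
    crossed <- alive & is.na(t_enl) & WT_now >= params$WTstar
    if (any(crossed)) {
      frac <- (params$WTstar - WT_prev[crossed]) / (WT_now[crossed] - WT_prev[crossed])
      t_enl[crossed] <- t - dt + pmin(pmax(frac, 0), 1) * dt
    }

    gap_now <- WA - LWA
    dying <- alive & gap_now <= death_tol
    if (any(dying)) {
      denom <- gap_prev[dying] - gap_now[dying]
      frac <- ifelse(denom > 0, gap_prev[dying] / denom, 1)
      t_death[dying] <- t - dt + pmin(pmax(frac, 0), 1) * dt
      LWA[dying] <- WA[dying]
      alive[dying] <- FALSE
      # lignification completed before WT* was reached: enlargement is
      # censored at death (all dynamics stop)
      censored <- dying & is.na(t_enl)
      if (any(censored)) {
        t_enl[censored] <- t_death[censored]
        enl_censored[censored] <- TRUE
      }
    }
    if (keep_path) path[step + 1, ] <- c(CA, WA, LWA)
    WT_prev <- WT_now
    gap_prev <- WA - LWA
  }

  if (keep_path && last_step < n_steps) {
    path <- path[seq_len(last_step + 1), , drop = FALSE]
  }
  list(
    CA = CA, WA = WA, LWA = LWA,
    t_enl = t_enl, t_death = t_death,
    died = !alive, enl_censored = enl_censored,
    times = seq(0, by = dt, length.out = if (keep_path) nrow(path) else last_step + 1),
    path = path, n = n
  )
}

#' Simulate the development of a single tracheid
#'
#' Integrates the three-equation differentiation model (see
#' [tracheid_rates]) for one cell at constant sugar availability `S`, from
#' the initial state `(CA0, WA0, 0)` until the wall is fully lignified
#' (`LWA >= WA`, cell death) or until `tmax`.  Integration uses the classical
#' fixed-step fourth-order Runge-Kutta scheme; the end of enlargement (first
#' `WT >= WT*` crossing) and death are located by linear interpolation
#' between the bracketing steps.
#'
#' @param params A [species_params()] object.
#' @param S Sugar availability for this cell (constant over its development).
#' @param dt Integration step (days).
#' @param tmax Maximum simulated time (days); if the cell has not died by
#'   `tmax` (e.g. at `S = 0`) a warning is raised and the trajectory is
#'   flagged as non-terminated.
#' @param death_tol Tolerance (um^2) on `WA - LWA` for the death event.
#' @param saturation Lumen feedback form, see [tracheid_rates].
#' @return A tibble of class `tracheid_trajectory` with one row per time step
#'   and columns `time` (d), `CA`, `WA`, `LWA`, `LA` (um^2), `WT`, `LRD`
#'   (um), and `phase` (`"enlarging"`, `"thickening"` or `"dead"`).
#'   Attributes: `t_enl_end`, `t_death`, `died`, `enl_censored`, `S`,
#'   `species`, `dt`, `saturation`.
#' @examples
#' p <- tracheid_species("Larix decidua")$params
#' traj <- simulate_cell(p, S = 2.65, dt = 0.05)
#' phase_durations(traj)
#' @seealso [phase_durations()], [simulate_ring()], [write_trajectory()]
#' @export
simulate_cell <- function(params, S, dt = 0.01, tmax = 200, death_tol = 1e-8,
                          saturation = "hill") {
  validate_species_params(params)
  stopifnot(is.numeric(S), length(S) == 1, S >= 0)
  res <- rk4_cells(params, S, dt, tmax, death_tol, saturation, keep_path = TRUE)
  if (!res$died) {
    warn(
      sprintf(
        "Cell did not complete lignification by tmax = %g d (S = %g); trajectory flagged as non-terminated.",
        tmax, S
      ),
      class = "tracheidr_warning_nontermination"
    )
  }
  states <- res$path
  traits <- derived_traits(states[, 1], states[, 2], params$CTD)
  phase <- rep("thickening", length(res$times))
  if (!is.na(res$t_enl[1])) phase[res$times < res$t_enl[1]] <- "enlarging"
  if (!is.na(res$t_death[1])) phase[res$times >= res$t_death[1]] <- "dead"
  out <- tibble(
    time = res$times,
    CA = states[, 1], WA = states[, 2], LWA = states[, 3],
    LA = traits$LA, WT = traits$WT, LRD = traits$LRD,
    phase = phase
  )
  structure(
    out,
    class = c("tracheid_trajectory", class(out)),
    t_enl_end = res$t_enl[1],
    t_death = res$t_death[1],
    died = res$died[1],
    enl_censored = res$enl_censored[1],
    S = S,
    species = params$name %||% NA_character_,
    dt = dt,
    saturation = saturation
  )
}

#' Durations of the enlargement and wall-thickening phases
#'
#' The enlargement phase runs from cell birth to the first `WT >= WT*`
#' crossing; the thickening phase from there to death (completed
#' lignification).  Both end points are interpolated below the integration
#' step, so durations are not quantised to `dt`.
#'
#' @param traj A `tracheid_trajectory` from [simulate_cell()].
#' @return A tibble with columns `enlargement_days` and `thickening_days`.
#' @export
phase_durations <- function(traj) {
  stopifnot(inherits(traj, "tracheid_trajectory"))
  if (!isTRUE(attr(traj, "died"))) {
    abort(
      "Phase durations are undefined: the cell did not complete lignification within tmax.",
      class = "tracheidr_error_phase"
    )
  }
  t_enl <- attr(traj, "t_enl_end")
  t_death <- attr(traj, "t_death")
  tibble(
    enlargement_days = t_enl,
    thickening_days = t_death - t_enl
  )
}

#' @export
print.tracheid_trajectory <- function(x, ...) {
  cat(
    sprintf(
      "<tracheid_trajectory> %s, S = %g, dt = %g d, %d steps\n",
      attr(x, "species") %||% "?", attr(x, "S"), attr(x, "dt"), nrow(x) - 1L
    )
  )
  if (isTRUE(attr(x, "died"))) {
    cat(
      sprintf(
        "  enlargement %.2f d%s, thickening %.2f d, death at %.2f d\n",
        attr(x, "t_enl_end"),
        if (isTRUE(attr(x, "enl_censored"))) " (censored at death)" else "",
        attr(x, "t_death") - attr(x, "t_enl_end"),
        attr(x, "t_death")
      )
    )
  } else {
    cat("  non-terminated (no death by tmax)\n")
  }
  NextMethod()
}
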