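ld <- tracheid_species("Larix decidua")$params

test_that("instantaneous rates match direct arithmetic on the published constants", {
  # enlargement of a fresh Larix decidua derivative
  WT0 <- wall_thickness(308, 39, 30)
  expect_equal(
    enlargement_rate(CA = 308, WA = 39, params = ld),
    0.39 * 308 * (1 - 308 / 2989) * (1 - WT0 / 1.85)
  )
  expect_equal(enlargement_rate(CA = 308, WA = 39, params = ld),
    78.826,
    tolerance = 1e-4
  )

  # wall deposition at S = 1.58 (Hill-form lumen feedback, hand-expanded)
  lumen <- 308 - 39
  expect_equal(
    wall_deposition_rate(CA = 308, WA = 39, LWA = 0, S = 1.58, params = ld),
    11.26 * 1.58 * (1 - 39 / 553) * (1 - 1 / (1 + (lumen / 124)^2.77))
  )
  expect_equal(
    wall_deposition_rate(CA = 308, WA = 39, LWA = 0, S = 1.58, params = ld),
    14.8034,
    tolerance = 1e-4
  )

  # lignification in a large-lumen cell (lumen = 1200 um^2)
  expect_equal(
    lignification_rate(CA = 1500, WA = 300, LWA = 0, S = 1.58, params = ld),
    10.77 * 1.58 * (1 - 1 / (1 + (1200 / 108)^0.56))
  )
  expect_equal(
    lignification_rate(CA = 1500, WA = 300, LWA = 0, S = 1.58, params = ld),
    13.5091,
    tolerance = 1e-4
  )

  # the alternative compound-decay reading stays available
  expect_equal(
    wall_deposition_rate(
      CA = 308, WA = 39, LWA = 0, S = 1.58, params = ld,
      saturation = "compound"
    ),
    11.26 * 1.58 * (1 - 39 / 553) * (1 - (1 + lumen / 124)^(-2.77))
  )
})

test_that("rates vanish at their structural limits", {
  p <- toy_params()
  # wall at threshold thickness stops enlargement
  thick <- initial_wall_area(300, 30, 1.5) # WT = WTstar = 1.5
  expect_equal(enlargement_rate(CA = 300, WA = thick, params = p), 0)
  # logistic brake at CAmax
  expect_equal(enlargement_rate(CA = p$CAmax, WA = 10, params = p), 0)
  # wall-area ceiling
  expect_equal(wall_deposition_rate(p$WAmax + 100, p$WAmax, 0, 2, p), 0)
  # vanished lumen
  expect_equal(wall_deposition_rate(250, 250, 0, 2, p), 0)
  expect_equal(lignification_rate(250, 250, 0, 2, p), 0)
  # completed lignification (death) freezes both wall processes
  expect_equal(wall_deposition_rate(300, 100, 100, 2, p), 0)
  expect_equal(lignification_rate(300, 100, 100, 2, p), 0)
  # no sugar, no wall formation
  expect_equal(wall_deposition_rate(300, 50, 0, 0, p), 0)
  expect_equal(lignification_rate(300, 50, 0, 0, p), 0)
})

test_that("the fixed-step integrator agrees with deSolve's classical RK4", {
  skip_if_not_installed("deSolve")
  S <- 2
  rhs <- function(t, y, parms) {
    WT <- wall_thickness(y[1], y[2], ld$CTD)
    lumen <- max(y[1] - y[2], 0)
    death <- as.numeric(y[3] < y[2])
    list(c(
      ld$vc * y[1] * (1 - y[1] / ld$CAmax) * (1 - min(1, WT / ld$WTstar)),
      ld$vw * S * (1 - y[2] / ld$WAmax) * (1 - 1 / (1 + (lumen / ld$mw)^ld$sw)) * death,
      ld$vl * S * (1 - 1 / (1 + (lumen / ld$ml)^ld$sl)) * death
    ))
  }
  times <- seq(0, 10, by = 0.05)
  ref <- deSolve::ode(
    y = c(CA = ld$CA0, WA = ld$WA0, LWA = 0),
    times = times, func = rhs, parms = NULL, method = "rk4"
  )
  traj <- simulate_cell(ld, S = S, dt = 0.05, tmax = 30)
  idx <- match(round(times, 10), round(traj$time, 10))
  expect_equal(traj$CA[idx], unname(ref[, "CA"]), tolerance = 1e-10)
  expect_equal(traj$WA[idx], unname(ref[, "WA"]), tolerance = 1e-10)
  expect_equal(traj$LWA[idx], unname(ref[, "LWA"]), tolerance = 1e-10)
})

test_that("trajectories respect monotonicity and ordering invariants", {
  for (fx in all_fixtures()) {
    for (S in c(0.8, 1.6, 2.7)) {
      traj <- simulate_cell(fx$params, S = S, dt = 0.05, tmax = 300)
      expect_true(all(diff(traj$CA) >= -1e-9))
      expect_true(all(diff(traj$WA) >= -1e-9))
      expect_true(all(diff(traj$LWA) >= -1e-9))
      expect_true(all(traj$LWA <= traj$WA + 1e-6))
      expect_true(all(traj$WA <= traj$CA + 1e-6))
      expect_true(all(traj$WA <= fx$params$WAmax + 1e-6))
      expect_true(all(traj$CA <= fx$params$CAmax + 1e-6))
      expect_true(isTRUE(attr(traj, "died")))
      # wall keeps thickening once enlargement has stopped
      after <- traj$WT[traj$phase != "enlarging"]
      expect_true(all(diff(after) >= -1e-9))
    }
  }
})

test_that("halving the step changes durations and final state by far less than 0.1%", {
  for (S in c(1.9, 2.7)) {
    a <- simulate_cell(ld, S = S, dt = 0.02)
    b <- simulate_cell(ld, S = S, dt = 0.01)
    rel <- function(x, y) abs(x - y) / abs(y)
    expect_lt(rel(attr(a, "t_enl_end"), attr(b, "t_enl_end")), 1e-3)
    expect_lt(rel(attr(a, "t_death"), attr(b, "t_death")), 1e-3)
    expect_lt(rel(tail(a$CA, 1), tail(b$CA, 1)), 1e-3)
    expect_lt(rel(tail(a$WA, 1), tail(b$WA, 1)), 1e-3)
  }
})

test_that("more sugar means smaller cells with thicker walls", {
  S_grid <- c(1.9, 2.2, 2.6, 3.0, 3.6, 4.0)
  finals <- lapply(S_grid, function(S) {
    traj <- simulate_cell(ld, S = S, dt = 0.05)
    c(CA = tail(traj$CA, 1), WT = tail(traj$WT, 1))
  })
  CA <- vapply(finals, `[[`, numeric(1), "CA")
  WT <- vapply(finals, `[[`, numeric(1), "WT")
  expect_true(all(diff(CA) <= 1e-9))
  # the final wall thickens with S on the rising branch; at very high S the
  # shorter lignification window thins it again (as in the latewood tail)
  expect_true(all(diff(WT[S_grid <= 3.2]) >= -1e-9))
})

test_that("a starving cell never dies and is flagged as non-terminated", {
  expect_warning(
    traj <- simulate_cell(toy_params(), S = 0, dt = 0.1, tmax = 50),
    class = "tracheidr_warning_nontermination"
  )
  expect_false(attr(traj, "died"))
  expect_equal(tail(traj$WA, 1), toy_params()$WA0) # no wall growth at S = 0
  expect_error(phase_durations(traj), class = "tracheidr_error_phase")
})

test_that("phase durations split the lifetime at the WT* crossing", {
  traj <- simulate_cell(toy_params(), S = 2, dt = 0.05)
  pd <- phase_durations(traj)
  expect_equal(pd$enlargement_days, attr(traj, "t_enl_end"))
  expect_equal(
    pd$enlargement_days + pd$thickening_days,
    attr(traj, "t_death")
  )
  # WT at the interpolated crossing is the threshold (within step error)
  i <- findInterval(attr(traj, "t_enl_end"), traj$time)
  expect_equal(traj$WT[i + 1], toy_params()$WTstar, tolerance = 1e-2)

  # threshold barely above the primary wall: enlargement ends almost at birth
  p_thin <- toy_params(WTstar = 0.5001)
  traj2 <- simulate_cell(p_thin, S = 2, dt = 0.05)
  expect_lt(phase_durations(traj2)$enlargement_days, 0.1)
})
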