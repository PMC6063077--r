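test_that("standardization linearly resamples traits and preserves endpoints", {
  tr <- toy_tracheidogram(
    WT = seq(2, 4, length.out = 5),
    LRD = rep(20, 5),
    LA = seq(800, 400, length.out = 5)
  )
  # identity at the same cell count
  same <- standardize_tracheidogram(tr, 5)
  expect_equal(same$WT, tr$WT)
  expect_equal(same$LA, tr$LA)
  # constant series stays constant at any count
  expect_equal(standardize_tracheidogram(tr, 9)$LRD, rep(20, 9))
  # linear WT from 2 to 4 over 5 cells resampled to 3 -> (2, 3, 4)
  down <- standardize_tracheidogram(tr, 3)
  expect_equal(down$WT, c(2, 3, 4))
  expect_equal(down$rel_position, c(0, 0.5, 1))
  expect_error(standardize_tracheidogram(tr, 1), class = "tracheidr_error_length")
  expect_error(standardize_tracheidogram(tr[1, ], 3), class = "tracheidr_error_length")
})

test_that("the SSE objective is zero at truth and hand-summable on toys", {
  p <- toy_params()
  cur <- toy_curve(a = 0.5, b = 0.2, c = 1.5)
  obs <- simulate_ring(p, cur, n_cells = 6, dt = 0.1)
  expect_equal(
    sse_objective(c(0.5, 0.2, 1.5), c("a", "b", "c"), obs, p, cur, dt = 0.1),
    0
  )
  # single cell, WT off by 1, others exact -> SSE = 1
  obs1 <- toy_tracheidogram(WT = 3, LRD = 10, LA = 200)
  sim1 <- toy_tracheidogram(WT = 4, LRD = 10, LA = 200)
  expect_equal(sum(fit_statistics(obs1, sim1)$sse), 1)
  # two cells with per-cell offsets dWT=0.5, dLRD=2, dLA=10
  obs2 <- toy_tracheidogram(WT = c(3, 3), LRD = c(12, 12), LA = c(300, 300))
  sim2 <- toy_tracheidogram(WT = c(3.5, 3.5), LRD = c(14, 14), LA = c(310, 310))
  expect_equal(sum(fit_statistics(obs2, sim2)$sse), 2 * (0.25 + 4 + 100))
  # infeasible parameters earn the penalty, not an error
  expect_equal(
    sse_objective(-1, "vc", obs, p, cur, dt = 0.1),
    1e12
  )
  expect_error(
    sse_objective(1, "nope", obs, p, cur),
    class = "tracheidr_error_params"
  )
})

test_that("fit statistics recover the closed-form R-squared", {
  a <- toy_tracheidogram(WT = c(2, 3, 4), LRD = c(30, 20, 10), LA = c(9, 6, 3) * 100)
  expect_equal(fit_statistics(a, a)$r2, rep(1, 3))
  # simulated constant at the observed mean -> R2 = 0
  b <- toy_tracheidogram(WT = rep(3, 3), LRD = rep(20, 3), LA = rep(600, 3))
  expect_equal(fit_statistics(a, b)$r2, rep(0, 3))
  # one-unit error on the middle WT: R2 = 1 - 1/2
  c3 <- toy_tracheidogram(WT = c(2, 4, 4), LRD = c(30, 20, 10), LA = c(900, 600, 300))
  expect_equal(fit_statistics(a, c3)$r2[1], 1 - 1 / 2)
  expect_error(
    fit_statistics(a, toy_tracheidogram(WT = c(1, 2), LRD = c(1, 2), LA = c(1, 2))),
    class = "tracheidr_error_length"
  )
})

test_that("a single free parameter is recovered from noiseless synthetic data", {
  p <- toy_params()
  cur <- toy_curve(a = 0.5, b = 0.2, c = 1.5)
  obs <- generate_synthetic_tracheidogram(p, cur, n_cells = 10, cv = 0, dt = 0.1)
  fit <- calibrate_tracheids(
    obs, p, cur,
    free = "vc", start = list(vc = 0.65), # 30% off truth
    dt = 0.1, n_starts = 1, maxit = 400
  )
  expect_true(fit$converged)
  expect_equal(tidy(fit)$estimate, p$vc, tolerance = 0.01)
  expect_lt(fit$sse, 1e-4 * sum(obs$LA^2)) # tiny against the data scale
})

test_that("sugar-curve coefficients are recovered and the search descends", {
  p <- toy_params()
  cur <- toy_curve(a = 0.5, b = 0.2, c = 1.5)
  obs <- generate_synthetic_tracheidogram(p, cur, n_cells = 10, cv = 0, dt = 0.1)
  start <- list(a = 0.5 * 1.3, b = 0.2 * 0.7, c = 1.5 * 1.2)
  sse_at_start <- sse_objective(
    unlist(start), c("a", "b", "c"), obs, p, cur,
    dt = 0.1
  )
  fit <- calibrate_tracheids(
    obs, p, cur,
    free = c("a", "b", "c"), start = start,
    dt = 0.1, n_starts = 2, maxit = 1000
  )
  expect_lte(fit$sse, sse_at_start) # descent
  expect_equal(tidy(fit)$estimate, c(0.5, 0.2, 1.5), tolerance = 0.01)
  # perturbing any single coefficient away from truth raises the objective
  for (i in 1:3) {
    for (f in c(0.8, 1.2)) {
      v <- c(0.5, 0.2, 1.5)
      v[i] <- v[i] * f
      expect_gt(
        sse_objective(v, c("a", "b", "c"), obs, p, cur, dt = 0.1),
        fit$sse
      )
    }
  }
  # broom-style accessors
  td <- tidy(fit)
  expect_named(td, c("term", "estimate", "start"))
  gl <- glance(fit)
  expect_equal(gl$sse, fit$sse)
  expect_true(gl$converged)
})

test_that("calibration is deterministic given its seed and validates inputs", {
  p <- toy_params()
  cur <- toy_curve(a = 0.5, b = 0.2, c = 1.5)
  obs <- generate_synthetic_tracheidogram(p, cur, n_cells = 8, cv = 0.05, seed = 3, dt = 0.1)
  args <- list(
    observed = obs, params = p, curve = cur, free = "c",
    dt = 0.1, n_starts = 2, maxit = 150, seed = 11
  )
  f1 <- do.call(calibrate_tracheids, args)
  f2 <- do.call(calibrate_tracheids, args)
  expect_identical(tidy(f1)$estimate, tidy(f2)$estimate)
  expect_identical(f1$sse, f2$sse)
  # observed data must carry all three traits
  bad <- obs
  bad$WT <- NULL
  expect_error(
    calibrate_tracheids(bad, p, cur, free = "c"),
    class = "tracheidr_error_missing_column"
  )
})
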