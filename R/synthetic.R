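#' Generate a synthetic "observed" tracheidogram with known ground truth
#'
#' Runs the forward ring model and perturbs each trait of each cell with
#' independent multiplicative Gaussian noise: `trait * (1 + cv * z)`,
#' `z ~ N(0, 1)`, redrawn while the factor is not positive (traits span two
#' orders of magnitude, so additive noise would either drown the wall
#' thickness or leave the lumen area untouched).  The generating parameters,
#' curve, noise levels and seed are stored in the result's attributes so a
#' calibration run can be scored against its ground truth.  Output is
#' bit-reproducible for a fixed seed; the caller's RNG stream is left
#' untouched.
#'
#' @inheritParams simulate_ring
#' @param cv Per-trait coefficient of variation: a single number or a named
#'   vector/list with elements `WT`, `LRD`, `LA`.  `0` disables the noise.
#' @param seed Integer seed for the noise stream.
#' @return A tibble of class `tracheidogram` (`source = "synthetic"`) with
#'   the same columns as [simulate_ring()]; attributes `truth` (list with
#'   `params` and `curve`), `cv` and `seed`.
#' @examples
#' fx <- tracheid_species("Larix decidua")
#' syn <- generate_synthetic_tracheidogram(
#'   fx$params, fx$curve,
#'   n_cells = 12, cv = 0.02, seed = 7, dt = 0.1
#' )
#' attr(syn, "cv")
#' @export
generate_synthetic_tracheidogram <- function(params, curve, n_cells = 100,
                                             cv = 0.02, seed = 1L,
                                             dt = 0.01, tmax = 200,
                                             death_tol = 1e-8,
                                             saturation = "hill") {
  cv <- normalize_cv(cv)
  clean <- simulate_ring(params, curve,
    n_cells = n_cells, dt = dt, tmax = tmax,
    death_tol = death_tol, saturation = saturation
  )
  noisy <- clean
  with_preserved_rng(seed, {
    for (tr in c("WT", "LRD", "LA")) {
      noisy[[tr]] <- clean[[tr]] * positive_noise_factor(n_cells, cv[[tr]])
    }
  })
  noisy$latewood <- mork_latewood(noisy$LRD, noisy$WT)
  attr(noisy, "source") <- "synthetic"
  attr(noisy, "truth") <- list(params = params, curve = curve)
  attr(noisy, "cv") <- cv
  attr(noisy, "seed") <- as.integer(seed)
  noisy
}

normalize_cv <- function(cv) {
  if (length(cv) == 1 && is.null(names(cv))) {
    cv <- c(WT = cv, LRD = cv, LA = cv)
  }
  cv <- unlist(cv)
  missing <- setdiff(c("WT", "LRD", "LA"), names(cv))
  if (length(missing)) {
    abort(
      paste0("`cv` lacks element(s): ", paste(missing, collapse = ", "), "."),
      class = "tracheidr_error_params"
    )
  }
  if (any(cv < 0)) {
    abort("Coefficients of variation must be >= 0.", class = "tracheidr_error_params")
  }
  cv[c("WT", "LRD", "LA")]
}

# multiplicative 1 + cv*z factors, redrawn while non-positive so traits
# remain > 0 (truncation at zero)
positive_noise_factor <- function(n, cv) {
  if (cv == 0) {
    return(rep(1, n))
  }
  f <- 1 + cv * rnorm(n)
  while (any(bad <- f <= 0)) {
    f[bad] <- 1 + cv * rnorm(sum(bad))
  }
  f
}
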