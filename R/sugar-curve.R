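#' Seasonal sugar-availability curves
#'
#' Sugar availability `S` drives wall deposition and lignification.  It is
#' constant over the life of one cell but varies with the cell's relative
#' position `x` in the ring (`x = 0` first cell, `x = 1` last cell):
#'
#' * quadratic: `S(x) = a x^2 + b x + c`
#' * exponential: `S(x) = a exp(b x) + c`
#'
#' The curve must be non-negative on the whole of `[0, 1]`; this is checked on
#' a dense grid at construction time.
#'
#' @param family `"quadratic"` or `"exponential"`.
#' @param a,b,c Dimensionless coefficients.
#' @return An object of class `sugar_curve`.
#' @examples
#' cur <- sugar_curve("quadratic", a = 2.78, b = -0.53, c = 1.83)
#' sugar_at(cur, c(0, 0.5, 1))
#' @export
sugar_curve <- function(family = c("quadratic", "exponential"), a, b, c) {
  family <- match.arg(family)
  stopifnot(is.numeric(a), is.numeric(b), is.numeric(c))
  curve <- structure(
    list(family = family, a = as.numeric(a), b = as.numeric(b), c = as.numeric(c)),
    class = "sugar_curve"
  )
  grid <- seq(0, 1, length.out = 401)
  s <- sugar_at(curve, grid)
  if (any(s < 0)) {
    abort(
      sprintf(
        "Sugar curve is negative on [0, 1] (minimum %.4g at x = %.3f).",
        min(s), grid[which.min(s)]
      ),
      class = "tracheidr_error_curve"
    )
  }
  curve
}

#' @rdname sugar_curve
#' @param curve A `sugar_curve`.
#' @param x Relative ring positions in `[0, 1]`.
#' @return `sugar_at()` returns the sugar availability at each `x`.
#' @export
sugar_at <- function(curve, x) {
  stopifnot(inherits(curve, "sugar_curve"))
  if (any(x < 0 | x > 1)) {
    abort(
      "Relative ring position `x` must lie in [0, 1].",
      class = "tracheidr_error_domain"
    )
  }
  switch(curve$family,
    quadratic = curve$a * x^2 + curve$b * x + curve$c,
    exponential = curve$a * exp(curve$b * x) + curve$c
  )
}

#' @export
print.sugar_curve <- function(x, ...) {
  form <- switch(x$family,
    quadratic = sprintf("S(x) = %g x^2 + %g x + %g", x$a, x$b, x$c),
    exponential = sprintf("S(x) = %g exp(%g x) + %g", x$a, x$b, x$c)
  )
  cat("<sugar_curve> ", form, "\n", sep = "")
  cat(sprintf("  S(0) = %.3f, S(1) = %.3f\n", sugar_at(x, 0), sugar_at(x, 1)))
  invisible(x)
}
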