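# Small, fast parameter set for plumbing tests (dies in ~15 d at S = 2).
toy_params <- function(...) {
  args <- list(
    name = "toy", CA0 = 300, CTD = 30, WT0 = 0.5,
    vc = 0.5, CAmax = 1500, WTstar = 1.5,
    vw = 15, WAmax = 400, mw = 150, sw = 3,
    vl = 12, ml = 120, sl = 1
  )
  do.call(species_params, modifyList(args, list(...)))
}

toy_curve <- function(a = 0, b = 0, c = 2, family = "quadratic") {
  sugar_curve(family, a, b, c)
}

# hand-built tracheidogram from bare trait vectors
toy_tracheidogram <- function(WT, LRD, LA) {
  n <- length(WT)
  as_tracheidogram(
    tibble::tibble(
      cell = seq_len(n),
      rel_position = (seq_len(n) - 1) / max(n - 1, 1),
      LA = LA, LRD = LRD, WT = WT
    ),
    source = "observed"
  )
}

all_fixtures <- function() {
  lapply(tracheid_species_names(), tracheid_species)
}
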