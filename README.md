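# tracheidr

A process-based simulator of conifer tracheid differentiation, for wood
anatomists and tree-ring modellers who want to explore how the
earlywood-to-latewood transition can emerge from carbon allocation alone —
without a phenological switch, a hormonal gradient, or an explicit climate
driver.

## The model

Each xylem cell is a rectangle in cross-section (constant tangential
diameter *CTD*, radial growth only), described by three state variables:
total cell area *CA*, wall area *WA*, and lignified wall area *LWA*
(μm²). Three coupled ODEs govern its development at constant sugar
availability *S*:

```
dCA/dt  = vc · CA · (1 − CA/CAmax) · (1 − min(1, WT/WT*))
dWA/dt  = vw · S · (1 − WA/WAmax) · f(CA − WA; mw, sw) · D
dLWA/dt = vl · S · f(CA − WA; ml, sl) · D
```

where wall thickness *WT* is recovered from (*CA*, *WA*) by the annulus
quadratic, `f(L; m, s) = 1 − 1/(1 + (L/m)^s)` is a Hill-type saturation in
the lumen area, and `D` drops to 0 when the wall is fully lignified
(*LWA* ≥ *WA*) — programmed cell death, the end of the story for that cell.
Enlargement stops irreversibly once *WT* reaches the threshold *WT\**.

A tree ring is a file of such cells, each run independently with the sugar
availability of its relative position *x* ∈ [0, 1]
(quadratic `a·x² + b·x + c` or exponential `a·e^(b·x) + c`). Low spring
sugar means slow wall deposition, a late *WT\** crossing, and therefore
large thin-walled cells; high late-season sugar means a quick crossing and
small thick-walled cells. Cells with lumen no wider than twice the double
wall (*LRD* ≤ 4·*WT*, Mork's criterion) are latewood.

The system is integrated with fixed-step classical RK4 (default
`dt = 0.01` d), with the phase boundaries (enlargement end, death) located
by sub-step linear interpolation. Parameter sets for *Pinus cembra*,
*Picea abies*, *Larix decidua* and *Picea mariana* are bundled, as is a
Nelder–Mead least-squares calibrator and a synthetic-data generator for
testing it. See `vignette("xylogenesis-model")` for the full account,
including why the Hill reading of the saturation term is the default and
which published quantities do and do not reproduce.

## Worked example

```r
library(tracheidr)

fx <- tracheid_species("Larix decidua")   # Table-derived parameters + sugar curve

# one cell at high sugar availability
traj <- simulate_cell(fx$params, S = 2.65)
phase_durations(traj)
#> # A tibble: 1 × 2
#>   enlargement_days thickening_days
#>              <dbl>           <dbl>
#> 1             5.80            13.3

# a whole ring
ring <- simulate_ring(fx$params, fx$curve, n_cells = 100)
ring
#> <tracheidogram> Larix decidua, 100 cells, source: simulated
#>   latewood: 48.0%
#> # A tibble: 100 × 11
#>    cell rel_position    LA   LRD    WT latewood sugar    CA    WA enl_days
#> 1     1       0       703.  28.9  2.82 FALSE     1.83 1036.  332.     12.3
#> 2     2       0.0101  711.  29.2  2.80 FALSE     1.82 1043.  332.     12.4
#> ...
autoplot(ring)

# recover sugar-curve coefficients from noisy synthetic observations
syn <- generate_synthetic_tracheidogram(fx$params, fx$curve,
                                        n_cells = 25, cv = 0.02,
                                        seed = 7, dt = 0.1)
fit <- calibrate_tracheids(syn, fx$params, fx$curve, free = c("a", "b", "c"),
                           start = list(a = 3.3, b = -0.4, c = 2.0),
                           dt = 0.1, n_starts = 1)
tidy(fit)
#> # A tibble: 3 × 3
#>   term  estimate start
#> 1 a        2.77    3.3
#> 2 b       -0.522  -0.4
#> 3 c        1.83    2
```

The cell at `S = 2.65` enlarges for 5.8 days before its wall hits
*WT\** = 1.85 μm, then thickens and lignifies for another 13.3 days. The
simulated larch ring turns to latewood in its outer half (48% of cells),
and the calibrator recovers the generating coefficients
(a = 2.78, b = −0.53, c = 1.83) to within ~2% from 2%-noisy traits of 25
cells.

A command-line interface wrapping the same functions ships in `inst/cli/`:

```sh
inst/cli/tracheidr simulate-ring --species "Larix decidua" --n-cells 100 --out ring.csv
inst/cli/tracheidr calibrate --observed ring.csv --species "Larix decidua" \
    --free a,b,c --out fit.json
inst/cli/tracheidr fixtures list
```

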