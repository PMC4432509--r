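# phycoscreen

Design and analysis toolkit for high-throughput microalgae nutrient
screening in 96-well plates.

Media optimisation for microalgae production faces a combinatorial wall: the
21 commonly supplied macro- and microelements at just three levels each would
need 3^21 ≈ 1.05 × 10^10 full-factorial trials. The screening strategy this
package implements compresses that space in two steps. **Screen 1** is a
full factorial over the dominant nutrients — four nitrogen sources at five
concentrations crossed with three KH2PO4 levels (60 photoautotrophic
conditions + 3 mixotrophic TAP controls = 63 wells per strain). **Screen 2**
takes the best Screen 1 medium as its centre point and varies ten further
elements (Ca, Mg, Fe, Mn, Cu, Zn, B, Se, V, Si) at coded levels −1/0/+1 in a
Box–Behnken incomplete factorial: 160 runs in ten 4-factor blocks plus 20
centre replicates = 180 media, a 328-fold compression of the 3^10 = 59,049
full factorial. Tiled across eighteen 96-well plates (1,728 wells), a run
screens 24 species units in Screen 1 (1,512 wells) or 9 in Screen 2
(1,647 wells); 246 trials per strain in total.

For every well, growth is followed as OD750 (a light-scattering biomass
proxy) every 3 h for ≤ 75 h, and the curve is fitted with the variable-slope
sigmoid

    Y(t) = kt0 + (ktn − kt0) / (1 + 10^((t50 − t) · hill))

(`kt0` baseline OD, `ktn` plateau, `t50` inflection time, `hill` steepness).
Fits are quality-controlled (R² > 0.85, absolute sum of squares < 0.1,
convergence) and triaged into morphological classes (robust, no growth, low
plateau, death phase, circadian oscillation, long lag); excluded wells never
reach the statistics. The maximum specific growth rate is then the largest
two-point log slope on the fitted 3-h grid inside the 0–48 h window,

    μ = (ln OD(t2) − ln OD(t1)) / (t2 − t1),   μmax = max over consecutive points,

and per-condition rates feed the second-order response surface over the
coded factors,

    y = Xβ + ε,   x = (1, x1, …, xm, x1x2, …, x(m−1)xm, x1², …, xm²),

whose coefficient t-tests (or, alternatively, per-factor level-cluster
ANOVA) give main-effect and pairwise interaction p-values and a ranking of
media formulations against the centre-point baseline.

A calibrated simulator (`simulate_plate()`) generates synthetic plate
datasets whose true μmax values follow a known response surface, so the
whole pipeline is testable without plate-reader hardware.

## Worked example

Simulate a full Screen 2 in triplicate with a known Ca/Mg surface, fit and
QC every well, extract growth rates, and run the effects analysis:

```r
library(phycoscreen)

design <- generate_bbd(k = 10, n_center = 20)
design
#> Box-Behnken design: 10 factors, 180 runs (20 centre points)
#> Factors: Ca, Mg, Fe, Mn, Cu, Zn, B, Se, V, Si

surface <- true_surface(design, intercept = 0.1,
                        linear = c(Ca = 0.01, Mg = 0.006),
                        interactions = c("Ca:Mg" = 0.004))
sim <- simulate_plate(design, surface, sim_config(noise_sd = 0.01, seed = 42),
                      replicates = 3)
sim
#> plate_sim: 540 wells (180 conditions), 0 no-growth, noise_sd 0.01

fw <- fit_wells(sim$curves)
fw$fits[[1]]
#> Variable-slope sigmoid growth fit
#>   status: converged;  R2 = 0.9989;  abs SS = 0.003487
#>      kt0      ktn      t50     hill
#>  0.10072  0.99811 29.77163  0.07222

ok <- which(fw$table$qc_pass & !fw$table$excluded)
rates <- fw$table; rates$mu_max <- NA_real_
for (i in ok) rates$mu_max[i] <- mu_max(fw$fits[[i]])$mu_max
agg <- aggregate_replicates(rates)
y <- agg$mu_mean[match(design$condition_id, agg$condition_id)]

effects_report(design, y)
#> Effects report (rsm_t, alpha = 0.05)
#>   significant main effects: Ca, Mg
#>   significant interactions: Ca-Mg

rank_media(design, y)
#> Best medium: S2-012 [Ca (+1), Mg (+1), Cu (-1), B (+1)]
#>   response 0.1213 vs baseline 0.1001: improvement 21.2%
```

The analysis recovers exactly the effects that were injected: calcium and
magnesium main effects, their pairwise interaction, and a best medium that
raises both (the Cu/B deviations ride along in the winning block run because
their true effects are zero). The median replicate RSD of μmax in this run
is 1.7%, in line with automated-screen repeatability. `run_pipeline()`
performs the same steps end to end and writes a CSV report bundle;
`inst/cli/phycoscreen.R` exposes it from the shell.

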