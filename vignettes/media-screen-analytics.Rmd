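---
title: "Methods: two-step nutrient-screen design and growth-curve analytics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: two-step nutrient-screen design and growth-curve analytics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(phycoscreen)
```

# The screening problem

Nutrient requirements differ widely between microalgae strains, and a full
factorial over the commonly supplied elements is computationally and
practically impossible (ten micronutrients at three levels alone give
$3^{10} = 59{,}049$ combinations; twenty-one elements give $3^{21}$). The
package implements a two-step compression of that space:

1. **Screen 1** — a full factorial over the dominant nutrients only:
   nitrogen source (NaNO3, NH4Cl, urea, NH4NO3) $\times$ five
   concentrations $\times$ three KH2PO4 levels (0, 2, 10 mM), i.e. 60
   photoautotrophic media plus three TAP (Tris-acetate-phosphate) positive
   controls per strain. Nitrogen levels are expressed in mM of compound and
   are roughly halved for the two-nitrogen-atom sources so that N-atom
   supply is comparable across sources.
2. **Screen 2** — a ten-factor, three-level Box–Behnken incomplete
   factorial over Ca, Mg, Fe, Mn, Cu, Zn, B, Se, V and Si, centred on the
   best Screen 1 medium. Coded levels $-1/0/+1$ map to half/mid/twice the
   mid-point concentration (the twofold rule), configurable per factor.
   With the default 20 centre replicates the design has 180 runs — a
   328-fold compression of the full factorial while keeping every linear,
   pairwise-interaction and quadratic term of the second-order response
   surface estimable.

Background nutrients (Mo, Co, EDTA, Tris buffer, vitamins B1/B12) are
carried as metadata on every condition but are never design factors.

## The Box–Behnken block tables

For $k$ factors the design enumerates, for each block of a published
incomplete-block table, all $\pm1$ combinations of the blocked factors with
every other factor at 0, then appends the centre points. The block tables
are embedded as literal data in `bbd_block_table()`: paired blocks for
$k = 3,4,5$, cyclic triples for $k = 6,7$, a Steiner triple system plus one
repeated parallel class for $k = 9$ (15 blocks, 120 runs), and the cyclic
development of $\{1,2,5,7\} \bmod 10$ for $k = 10$ (10 blocks of 4, 160
runs). The $k = 10$ table was reconstructed to the classical catalogue's
structure and verified against every property the catalogue design has:
each factor non-zero in exactly 64 runs split 32/32 between $-1$ and $+1$,
every factor pair co-occurring in at least one block, mutually orthogonal
linear columns, and a full-rank 66-column second-order model matrix.
Row order is canonical (blocks in table order, within-block sign
combinations in binary counting order, centre points last) so outputs are
diffable.

```{r design}
d <- generate_bbd(k = 10, n_center = 20)
d
colSums(d$coded != 0)
qr(build_model_matrix(d))$rank
```

Screen 1 retains the four chemically identical zero-nitrogen rows (one per
source) as distinct conditions so the 60-condition layout is preserved;
all but the first are flagged `zero_n_duplicate`. Per-strain Screen 2
midpoint N/P media enter as condition metadata only, not as design factors:
nitrogen and phosphate are fixed at their Screen 1 optimum for the whole
Screen 2 run, so they carry no contrast to estimate.

# The growth model

Each well's OD750 series (3-h sampling, runs of at most 75 h) is fitted
with the variable-slope sigmoid

$$Y(t) = kt_0 + \frac{kt_n - kt_0}{1 + 10^{(t_{50} - t)\,\mathrm{hill}}}$$

with $kt_0$ the baseline OD (inoculation at OD750 $\approx 0.1$), $kt_n$
the plateau (light/nutrient-limited, $\approx 1.0$ under good conditions),
$t_{50}$ the inflection time in hours and $\mathrm{hill}$ the steepness.
The exponent is implemented on a linear time axis, which makes the printed
formula self-consistent; the dose–response convention of a $\log_{10}$ time
axis is available via `log_time = TRUE` for users who prefer the
half-time-on-log-scale interpretation.

**Fitting.** Levenberg–Marquardt least squares (`minpack.lm::nlsLM`) from
data-driven starts: $kt_0$ = first OD, $kt_n$ = max OD, $t_{50}$ = the
interpolated half-rise time, and $\mathrm{hill}$ from the steepest observed
slope via $dY/dt|_{t_{50}} = (kt_n - kt_0)\ln(10)\,\mathrm{hill}/4$. Up to
five jittered restarts are spent only while the incumbent fit's SSR
exceeds $10^{-4}$ of the series' total sum of squares, so clean wells cost
one optimiser call. Convergence failures and flat series are labelled
`not_converged`; fits whose parameters are effectively unidentified — any
standard error above $10\times$ its estimate, or a gradient condition
number above $10^8$ — are labelled `ambiguous`. Both labels exclude the
well downstream.

**Quality control.** A fit passes when it converged, $R^2 > 0.85$ and the
raw residual sum of squares is below 0.1 OD$^2$. $R^2$ is unadjusted
($1 - SS_{res}/SS_{tot}$) and the sum-of-squares cut is applied to the raw
per-curve SSR; both choices are exposed as config thresholds
(`r2_min`, `abs_ss_max`).

**Morphology triage.** A rule cascade mirrors the manual curation of
atypical plate curves, in this order: no growth (smoothed OD rise
< 0.05), death phase (smoothed post-peak decline > 20% of peak — the
smoothing is a 7-sample moving average, which keeps 24-h oscillations from
masquerading as death), strong/weak circadian oscillation, long lag
(fitted takeoff $t_{50} - 2/\mathrm{hill} > 15$ h; observed lags in
healthy media are 6–9 h), low plateau (max OD < 0.8, flagged for manual
review but not excluded), and robust otherwise. Wells that fail QC with no
morphological explanation are `ambiguous_excluded`.

The circadian score is the fraction of residual periodogram power in the
20–28 h band, with thresholds 0.2 (weak) and 0.5 (strong). Because the
band holds one Fourier bin of the 25-sample grid, pure measurement noise
occasionally concentrates there; an amplitude guard (dominant in-band
component $\ge 0.01$ OD, roughly $3.5\times$ the noise-only expectation at
the default noise level) keeps the false-positive rate on robust curves
negligible. On this grid the nearest bin to 24 h lies at $75/3 = 25$ h, so
the triage tests for dominant power in the band rather than at exactly
24 h.

# Growth rates

The specific growth rate between consecutive fitted grid points is
$\mu = (\ln OD_{t_2} - \ln OD_{t_1})/(t_2 - t_1)$ (h$^{-1}$), and
$\mu_{max}$ is the maximum over the analysis window, 0–48 h by default
(late-run evaporation biases longer windows; the window is configurable).
Rates are computed on fitted values — the fit filters measurement noise
and circadian ripple — with a raw-data option for diagnostics.
Non-positive fitted ODs are floored at $10^{-6}$ with a warning rather
than aborting a plate. Replicates are summarised by mean, SD and RSD per
condition, with QC-dropped wells counted; Cronbach's alpha across
replicate series quantifies run reliability.

At the default noise (SD 0.01 OD) a single well's fitted $\mu_{max}$ moves
by about 1.5% on average (so triplicate RSDs sit near 1–2%, comfortably
below the 5% screen-repeatability target, though the sample SD of three
replicates has a heavy right tail and individual conditions can exceed the
average severalfold).

# Effects analysis

Per-condition $\mu_{max}$ values are regressed on the full second-order
model matrix ($p = 1 + 2m + m(m-1)/2 = 66$ terms for $m = 10$) by QR-based
OLS, with t-tests on $n - p$ residual degrees of freedom. Two significance
methods are shipped because practice and description diverge in the field:
`rsm_t` (default) tests the linear and cross-product coefficients of the
surface fit, as response-surface software does; `cluster_anova` follows
the narrative procedure — cluster all runs by one factor's coded level
(centre points pool into the 0 cluster, which they are by construction)
and one-way-ANOVA the clusters, or for a pair, test the interaction
contrast of the $\pm1$ cell means. No multiple-testing correction is
applied by default across the 10 factors and 45 pairs, matching screening
practice where follow-up experiments arbitrate; a Benjamini–Hochberg
option is provided. QC-excluded runs are dropped row-wise and
estimability is re-checked — on the 180-run design all 66 terms remain
estimable under moderate exclusion, and the fit aborts with the
inestimable terms named otherwise.

Media are ranked by response; the best medium is reported as its non-zero
coded deviations from the centre point, with percentage improvement over
the centre-point mean (or an explicitly supplied baseline). Ties break by
design row order for determinism.

# The simulator

`simulate_curve()` builds the noiseless signal as the sigmoid shifted
right by a lag, multiplied by exponential decay beyond the post-midpoint
peak ($t_{50} + 2/\mathrm{hill}$) when a death rate is set, plus a
circadian sine and additive Gaussian noise, clipped at zero. The defaults
are the screen's study conditions: start OD 0.1, plateau 1.0, 3-h
sampling over 72 h, noise SD 0.01 (chosen to reproduce sub-5% replicate
RSD at plateau $\approx$ 1.0 — the instruments' noise model is not
documented, so additive Gaussian is the package's choice).

`simulate_plate()` draws each condition's true $\mu_{max}$ from a known
response surface $x'\beta + \varepsilon$ and calibrates the curve's
steepness by root finding so that the pipeline's own $\mu_{max}$ on the
noiseless 3-h grid equals the drawn value to $10^{-6}$ relative. Ground
truth is thus defined operationally — the quantity the pipeline estimates
— avoiding dependence on an analytic maximum the sampled grid never
attains. Calibrated rates between 0.02 and 0.25 h$^{-1}$ (the plausible
range for photoautotrophic microalgae in this format) round-trip through
simulate → fit → $\mu_{max}$ within $10^{-3}$ relative.

What the simulator does *not* emulate: evaporation (path-length loss and
concentration gain largely cancel in OD), plate edge effects, cell-size
drift in the OD–biomass relation, flocculation other than as a sine-like
artefact, and any mechanistic nutrient-uptake dynamics. Passing tests
demonstrate the *analytics* — fitting, QC, rate extraction, effect
recovery, design combinatorics — not biological realism of any particular
medium's response.

# Numerical choices and test problem sizes

- Optimiser tolerance $10^{-10}$ on SSR, 200 iterations max, 5 restarts.
- Degenerate inputs: constant series are rejected as unfittable
  (`not_converged`), not errors; curves need $\ge 6$ points.
- The acceptance-style suites run at desk scale: 50-curve oracle grids
  (grid search over $(t_{50}, \mathrm{hill})$ with profiled linear solves,
  then Nelder–Mead polish), 200 curves per morphology preset for label
  recovery, 2,000 pure-noise surface simulations for type-I calibration,
  200 seeds for power, and one 540-well triplicate screen for replicate
  statistics. These sizes keep the whole suite under a minute per block
  while leaving Monte-Carlo bands narrow relative to the asserted bounds.

# Known limitations

- The ten-factor block table reproduces the classical design's structure
  and estimability properties but may order or choose blocks differently
  from the original catalogue listing; any design with these properties
  yields identical inference for the second-order model.
- `ambiguous` is operationalised through standard-error ratios and
  Jacobian conditioning; commercial curve-fitting tools use their own
  undocumented heuristics, so borderline labels can differ.
- The weak/strong circadian distinction depends on the residual
  signal-to-noise ratio, not on oscillation amplitude alone; with
  25-sample series the two classes blur near the thresholds.
- Improvement percentages require an explicit baseline when centre points
  are absent; no attempt is made to parse composite improvement figures
  from legacy reports.
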