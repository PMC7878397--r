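---
title: "The two-step model of autophagic flux: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{The two-step model of autophagic flux: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(autoflux)
```

## The model

The LC3 turnover assay measures autophagy by Western blot: LC3-II, the
lipidated, membrane-bound form of LC3, scales with the number of
autophagosomes, and blocking lysosomal degradation (e.g. with bafilomycin,
BAF) makes autophagosomes accumulate. The conventional "autophagic flux"
is the LC3-II increment under the inhibitor, which only measures the
*degradation* side of the pathway. Yet most known regulatory genes act on
autophagosome *formation*, and the two stages can be controlled
independently.

autoflux treats the autophagosome pool as a black box with an input
(formation) and an output (degradation). Over the treatment window,

$$\mathrm{pool}_t = \mathrm{pool}_{ss} + \mathrm{formation} - \mathrm{degradation},$$

and in the basal (untreated) condition the pool is assumed to be at
equilibrium, so basal formation equals basal degradation. With the four
design cells of a standard assay — control (EXP−) and stimulus (EXP+),
each with and without the inhibitor — all quantities become differences of
measured, normalized LC3-II values, replicate-matched within a blot:

* basal flux = value(EXP−, BAF+) − value(EXP−, BAF−) — this is
  simultaneously the basal formation *and* the basal degradation;
* degradation(EXP+) = value(EXP+, BAF+) − value(EXP+, BAF−) — the
  conventional flux of the treated condition;
* formation(EXP+) = value(EXP+, BAF+) − value(EXP−, BAF−) — everything
  that accumulated under full blockade, minus the pre-existing pool.

Dividing by the basal rates gives the formation and degradation ratios,
and the net turnover ratio degradation/formation equals 1 at equilibrium,
rises above 1 when degradation dominates (shrinking pool) and falls below
1 when formation dominates (growing pool). Because the three estimators
are differences of the same four cells, the pool-balance equation above
is an algebraic identity of the fit: `pool_balance()` returns residuals
that are zero to machine precision for *any* input, and the package tests
treat that as the model's central self-consistency check, not as evidence
about the data.

### Assumptions and their limits

The model assumes (i) basal equilibrium — cells in a steady metabolic
state, which may fail in dense or stressed cultures; (ii) complete
inhibition of degradation under BAF+ during the window; (iii) LC3-II
proportional to autophagosome number, which chemiluminescent detection
makes only approximately linear (saturated bands are therefore flagged);
and (iv) formation and degradation acting independently within the
window. Violations show up as negative rates, which the package reports
and flags but never clamps, because clamping would bias the ratios.

## Fitting and inference

`flux_fit()` normalizes lanes (LC3-II over a loading control by default;
"% over control" rescaling and LC3-II/LC3-I are alternatives — the ratios
are invariant to the choice between the two loading-control schemes),
computes all rates per replicate, and only then summarizes. The
per-replicate-first order preserves the blot pairing, which the paired
tests and the ratio t-tests rely on; computing on cell means would
discard it. Whether published analyses of this design computed ratios per
replicate or on means is generally not stated; per replicate is this
package's choice, recorded here as an assumption.

`flux_stats()` reproduces the assay's decision sequence: a two-way ANOVA
(condition × inhibitor) on the raw normalized values screens for an
interaction at α = 0.05; if present, the treatment effect is re-examined
by one-way ANOVA within each inhibitor level. Flux, formation and
degradation are then compared against basal — by one-tailed pooled-variance
Student t-tests for a single treatment, or one-way ANOVA with a
Holm–Šidák step-down posthoc (each treatment vs control by default,
two-tailed on the pooled ANOVA error; all-pairwise behind a flag) for
dose series. The turnover ratios are tested against their equilibrium
value of 1 with one-tailed one-sample t-tests. Rates in arbitrary units
cannot meaningfully be compared "to one", so the vs-1 tests apply to the
dimensionless ratios; this reading is an interpretive choice of the
package. Every p is labeled significant (p < 0.05), tendency
(p < 0.1) or ns.

Two inferential rules are deliberately strict. The one-tailed direction
of every comparison must be stated in the call or config — inferring the
tail from the observed sign would double the type-I error. And zero
within-group variance raises an error instead of returning p = 0: real
densitometry always carries noise, so exact ties indicate a broken
pipeline upstream, not an infinitely significant effect. Shapiro–Wilk and
Brown–Forsythe (Levene) screens are reported as advisories only; no
automatic nonparametric fallback is taken because none is established
for this assay.

Undefined ratios (non-positive basal flux or formation in a replicate)
propagate as `NA`, are excluded from the vs-1 tests, and are counted in
the report — silent exclusion would make analyses irreproducible.

## The forward simulator

`simulate_flux()` inverts the estimators exactly: given a steady-state
pool, a basal flux and treatment multipliers $(f, d)$ on formation and
degradation, the noiseless cell expectations are

| cell | value |
|------|-------|
| EXP−/BAF− | pool |
| EXP−/BAF+ | pool + basal |
| EXP+/BAF− | pool + f·basal − d·basal |
| EXP+/BAF+ | pool + f·basal |

so `recover_rates()` returns the generating parameters exactly at zero
noise, for every feasible spec (the only constraint is that degradation
cannot exceed the available pool). Defaults are pool 100 au, basal flux
50 au, n = 3 replicates — a typical cultured-cell experiment where the
inhibitor roughly doubles basal LC3-II over a 6 h window. Noise is
multiplicative lognormal per lane with mean 1 and a chosen CV,
independent across the four cells, because densitometry error scales
with band intensity; the default CV of 0.1 matches well-behaved
replicate blots. Since the noise multiplier has mean exactly 1 and the
estimators are linear in the cell values, the rate estimators stay
unbiased under noise — a property the tests verify by Monte Carlo.
Bafilomycin is modeled as a complete degradation blockade; partial
inhibition is out of scope and would bias degradation estimates downward
in real data.

The seven presets (`flux_preset()`) encode the canonical regimes of
dissociated regulation — balanced proportional activation, formation up
or down alone, degradation up or down alone, and the two opposed
combinations — with multipliers 2× ("up") and 0.5× ("down"), arbitrary
but representative choices; each preset's analysis reproduces its
regime's direction triple (formation ratio, degradation ratio, net ratio
vs 1).

What the simulator does *not* emulate: loading-control variability (it
emits already-normalized values with `loading_control = 1`), blot-to-blot
transfer gradients, inter-day batch effects, partial inhibition, or
time-resolved dynamics. Passing recovery tests on simulated data
therefore demonstrates the estimators' correctness, not robustness to
every real-blot artifact.

## Densitometry

`quantify_gel()` re-implements the lane-profile workflow of interactive
gel analyzers without the manual steps: rectangular lane ROIs and band
intervals are explicit inputs (1-based inclusive row/column coordinates,
matrix-style), because band identity (LC3-I at ~16 kDa vs LC3-II at
~14 kDa vs actin at ~42 kDa) requires molecular-weight knowledge the
image does not contain — automatic peak detection is a non-goal.

Profiles are pixel sums across the lane width. Two automatic baselines
replace the hand-drawn one: a straight line interpolated through the
profile's local minima, and (the default) a grayscale morphological
opening with a flat structuring element of radius `window` px
(default 50). The opening tracks slowly varying background and passes
under any peak narrower than about twice its radius; the radius should be
at least ~4σ of the widest band. Its known failure mode is a background
slope steep relative to the band height, where the baseline can overshoot
by roughly slope × half-width of the peak on the uphill side; blot
backgrounds are faint and smooth relative to real bands, and the
synthetic-gel tests keep backgrounds and noise in that regime
(background and noise amplitudes bounded by a few percent of the
faintest band's peak height, the natural reading of "noise small
relative to peak" when bands differ in brightness). Net signal below the
baseline is clamped to zero at integration only — areas are physical
quantities — and any band containing pixels at ≥ 98% of the dynamic range
is flagged saturated, where detection is no longer linear.

`make_synthetic_gel()` generates Gaussian-profile bands whose total added
intensity is exact by construction, refuses layouts with band centers
closer than 3(σᵢ+σⱼ) (ambiguous ground truth), and returns the truth
table alongside the image, enabling exact conservation and 5% round-trip
checks.

## Numerical choices and problem sizes

Tolerances: the pool-balance identity is asserted at 10⁻⁹ relative;
conservation of synthetic band intensity at 10⁻⁶ relative (discrete
Gaussian tails beyond the integration interval account for ~10⁻⁹);
round-trip recovery at 5% under ≤ 2%-of-peak noise; ANOVA sums of squares
against an explicit projection oracle at 10⁻⁸. Degenerate inputs (empty
ROIs, exact-fit ANOVAs, zero-variance t-tests, infeasible scenarios)
raise classed errors — `autoflux_validation_error`,
`autoflux_config_error`, `autoflux_design_error`,
`autoflux_degenerate_error` — so callers can distinguish user error from
pipeline bugs.

The validation suites run at sizes chosen to exercise the asymptotics
while staying interactive: 1,000 randomized designs for the identity
check, 500 random scenarios for exact recovery, 10,000 replicates for
the unbiasedness check, 20,000 null draws for the type-I calibration of
the vs-1 test, and 100 random synthetic gels for the densitometry round
trip.

All randomness flows from explicit seeds; a fixed seed gives bit-identical
simulated datasets, band tables and reports. `flux_pipeline()` derives
stage sub-streams deterministically from the single top-level seed.

## A worked example

```{r example, fig.width = 7, fig.height = 5}
sim <- simulate_flux(flux_preset("formation_up", noise_cv = 0.1,
                                 n_replicates = 3, seed = 7))
fit <- flux_fit(sim$lanes)
summary(fit)
flux_stats(fit, direction = list(flux = "greater", formation = "greater",
                                 degradation = "greater",
                                 formation_ratio = "greater",
                                 degradation_ratio = "greater",
                                 net_ratio = "less"))
plot(fit)
```

A selective increase in formation leaves the conventional flux unchanged
— the scenario the two-step decomposition exists to catch: the formation
ratio rises while the net ratio falls below 1, flagging a growing
autophagosome pool that the flux alone would miss.

## Known limitations

Beyond the model assumptions above: the estimators are amounts per
treatment window, not per-hour rates (`duration_h` is carried as metadata
only, since the defining differences contain no time divisor); dose
series are compared each against the single control rather than modeled
as a dose–response curve; and the Holm–Šidák posthoc tails follow the
two-tailed convention of standard statistical software, while the
ratio-vs-1 tests are one-tailed by design.
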