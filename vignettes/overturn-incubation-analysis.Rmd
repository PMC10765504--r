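---
title: "Methods: growth, DOM diagenesis and community analysis for overturn incubations"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: growth, DOM diagenesis and community analysis for overturn incubations}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(overturnlab)
```

`overturnlab` analyzes transplant ("simulated overturn") incubations in
which surface and deep seawater microbial assemblages are diluted into
0.2 µm filtrate and followed for ~3 weeks. This vignette documents the
models the package implements, the tunable parameters and their defaults,
the synthetic-data generator's scope, and the numerical and design choices a
user or reviewer would want stated explicitly.

## Growth kinetics

### The logistic model and the stationary rule

Prokaryotic abundance per bottle is modeled as
$$N(t) = \frac{K}{1 + \frac{K - N_0}{N_0} e^{-rt}},$$
with carrying capacity $K$ (cells L^-1^), initial abundance $N_0$ and
intrinsic rate $r$ (d^-1^). The fit is nonlinear least squares
(Levenberg–Marquardt, `minpack.lm`) with a deterministic start — $K$ from
the largest observation, $N_0$ from the first, $r$ from the log-slope of the
first three points — and box bounds $K \in (\max N, 10\max N]$, so identical
data always give identical fits. The half-capacity time is
$t_{mid} = \ln((K-N_0)/N_0)/r$ and stationary phase is declared at
$t_{stat} = 2\,t_{mid}$, the symmetric-logistic convention: growth is
centered on $t_{mid}$, so by twice that time the curve has flattened to the
same degree it had steepened.

Assumptions worth noting: a single logistic phase (no diauxie, no grazing
mortality term), positive abundances, and enough observations (≥ 5) past
the minimum to identify all three parameters. A series that never rises
above its first observation is rejected as having no growth signal rather
than fitted.

### Exponential window, die-off handling and µ

The specific growth rate µ is the OLS slope of $\ln N$ vs. $t$ restricted
to the exponential window. The window ends at $t_{stat}$ (capped at the last
observation). It starts at the first timepoint unless a die-off is
detected: if the minimum abundance before $t_{mid}$ sits more than 10%
(`die_off_threshold`) below the first observation — as when a deep,
low-oxygen-adapted assemblage partially dies back on reoxygenation — the
window starts at that minimum, and the logistic is fit to the series from
the minimum onward (a three-parameter logistic absorbs the time shift
exactly, so this does not bias noiseless fits). The 10% margin exists so
that mere observation noise on a slow, near-flat start (µ ≈ 0.03 d^-1^
control bottles) is not mistaken for a die-off; without it, starting the
regression at a noise dip inflates µ systematically.

When a noisy fit places $2\,t_{mid}$ before the third sampled timepoint,
`fit_growth()` extends the window end to the earliest timepoint that gives
three observations; the lower-level `exponential_window()` keeps the strict
contract and errors instead, prompting a manual window.

### Bacterial growth efficiency

BGE is the ratio of time-integrated biomass-carbon increase to
time-integrated DOC drawdown over $[T_0, t_{stat}]$:
$$\mathrm{BGE} = \frac{\int_{T_0}^{t_{stat}} \Delta BC\,dt}
                      {\int_{T_0}^{t_{stat}} \Delta DOC\,dt},$$
where $\Delta$ means excess relative to the value at $T_0$ (windows start
at the die-off minimum when one exists). Biomass carbon uses 20 fg C
cell^-1^ (configurable, `fg_per_cell`) and a carbon molar mass of
12.011 g mol^-1^. Integrals are trapezoidal with window endpoints obtained
by linear interpolation, and both are normalized by the window length (the
normalization cancels in the ratio). This "excess above/below the T0 value"
reading makes BGE invariant to a constant DOC offset and reduces to the
familiar $\Delta BC/\Delta DOC$ for linear trajectories (e.g., a linear BC
rise of 1 µmol C L^-1^ against a 5 µmol C L^-1^ DOC drop gives exactly
20%). When the DOC integral is non-positive the result is flagged
`"no net DOC removal"` and BGE is NaN rather than a misleading number.

### DOC quality control

Within each (treatment, bottle) DOC series, values strictly above the 90th
percentile (sample quantile, linear interpolation between closest ranks,
`type = 7`) are flagged `contaminated`; flagged values are excluded from
fits and integrals but never deleted. Groups smaller than 5 observations
are skipped with a warning, and the grouping is configurable because a
per-series percentile screen necessarily suspects the maximum of any
declining series — which is its legitimate starting value. For that reason
the pipeline's BGE step holds the earliest unflagged DOC value constant
back to $T_0$ when the $T_0$ observation itself was flagged, and the
diagenesis step falls back to the flagged mean when QC suspected every
measurement at a timepoint.

## DOM diagenesis indices

Molar percentages $var_i$ are computed per sample from amino-acid
concentrations (nmol L^-1^). The degradation index is
$$DI = \sum_i \frac{var_i - \mathrm{AVG}var_i}{\mathrm{STD}var_i}
       \cdot fac.coef_i,$$
a factor-coefficient-weighted sum of standardized anomalies; DI depends
only on composition (not concentration scale), is zero at the reference
composition, and is linear in each acid's z-score. TDAA carbon is
$\sum_i c_i \times \mathrm{carbons}_i$ and the TDAA yield is TDAA-C as a
percent of DOC — both linear in concentrations.

The packaged reference table (`aa_reference_synthetic.csv`) is an explicitly
**synthetic stand-in** for the published degradation-index calibration: its
means sum to 100 mol% and its coefficient signs follow the published
fresh-vs-degraded pattern (protein amino acids such as leucine and
phenylalanine positive; glycine, serine, threonine negative), but the
numbers were not transcribed from the original source. Users computing DI
values for publication should supply a transcription of the published table
via `read_aa_reference(path)`; every property the package's tests rely on
(zero at reference, linearity, scale invariance) holds for any valid
reference, which is why the tests are property-based rather than
value-based. Amino acids present in a profile but absent from the
reference's DI set contribute to TDAA and mol% but not to DI.

## Molecular-formula indices and compound classes

For formula-assigned mzRT features:
$DBE = \tfrac12(2 + 2C - H + N + P)$ (half-integral DBE marks nitrogen-rule
parity violations and is flagged, not rejected), and the modified
aromaticity index
$$AI_{mod} = \frac{1 + C - \tfrac12 O - S - \tfrac12(N + P + H)}
                  {C - \tfrac12 O - N - S - P},$$
clamped to 0 when the numerator is negative or the denominator
non-positive; the unmodified AI (all oxygen counted) is available by flag.
Magnitude-weighted O/C, H/C and DBE are peak-magnitude-weighted means over
all assigned formulas (optionally only classified ones), so each lies
between the per-feature extremes and is invariant to uniform magnitude
rescaling.

Compound classes are assigned by a priority-ordered, editable rule table of
closed-interval bounds on H/C, O/C, AI~mod~, heteroatom counts and DBE
ratios, covering black carbon, condensed hydrocarbons, polyphenols, sugars,
carbohydrates, proteins/peptides/protein maya, saturated fatty acids,
lipids, unsaturated aliphatics, CRAM, lignin and highly unsaturated
compounds; anything matching no rule is `unassigned`. The shipped bounds
are literature-conventional defaults (e.g., AI~mod~ ≥ 0.66 for condensed
aromatics, with ≥ 15 carbons for black carbon; CRAM by DBE/C, DBE/H, DBE/O
ratio windows). Because such boundaries vary between laboratories, the
table is data, not code, and class-level checks in the test suite are
property-based (first-match semantics, agreement with an all-rules oracle,
fractions summing to 1) rather than tied to specific boundary values.

## qPCR quantification

Standard copies follow
$GCN = \mathrm{DNA(ng)} \times 6.0221\times10^{23} /
(\mathrm{length(bp)} \times 10^9 \times 660)$.
The standard curve is OLS of Cq on $\log_{10}$(copies) over a 10^6^–10^1^
dilution series; efficiency is $E = 10^{-1/\mathrm{slope}} - 1$ (a slope of
−3.3219 is perfect doubling, 100%; −2.93 gives 119%, matching the printed
efficiencies of the *cbbL*/*amoA* assays this models). Efficiencies above
100% are reported as such — they indicate inhibition/chemistry artifacts,
not an error. Unknowns are quantified by inverting the fitted line after
mean-Cq merging of replicates (configurable), normalized per ng of template
DNA; Cq values outside the standards' range are converted but flagged.
Amplification in a negative control raises a plate-level warning, not a
failure.

## Community summaries

ASVs present in fewer than 4 samples are removed (an ASV in exactly 4 is
kept), then samples are rarefied without replacement to exactly 10,000
reads (seeded; samples below depth are dropped with a notice, keeping all
retained samples comparable). The filter-then-rarefy order follows the
processing order the thresholds come from; the reverse order is available
in the options. Shannon ($-\sum p_i \ln p_i$, natural log) and Gini–Simpson
($1 - \sum p_i^2$) indices are computed per sample via `vegan`. Family
aggregation pools groups below 1% of the experiment-wide total into
`other`; the separate >0.15% per-ASV plotting threshold is an independent
option since the two act at different ranks.

Copy-number adjustment divides each taxon's percent of total ASVs by its
16S rRNA copy number. By default the result is reported **against the
original total** (a family at 75% with 3 copies becomes 25% of total ASVs),
which matches the reporting convention this arithmetic is usually quoted
in; `renormalize = TRUE` rescales the adjusted fractions to sum to 100% and
is the statistically preferable composition.

## Treatment comparisons

Per-analyte comparisons use one-way ANOVA across treatments (per timepoint
or pooled) with Tukey HSD pairwise contrasts. Replicate-bottle equivalence
pairs the two bottles of each treatment by timepoint and tests the pooled
differences against zero — by default a paired two-sided t test, with an
exhaustive sign-flip permutation alternative (exact for ≤ 20 pairs, Monte
Carlo beyond). The t test was chosen as the default because the pooled
paired-timepoint count it produces matches how such replicate checks are
conventionally reported; the permutation variant is assumption-free and the
two are cross-checked in the test suite. No multiple-testing correction is
applied across analytes by default (each analyte is reported as its own
family, with Tukey adjustment inside each ANOVA); a Benjamini–Hochberg
option exists in the pipeline options.

## The synthetic-data generator

`default_config()` encodes the study conditions the analysis assumes:

* three treatments (S/S, S/D, D/S) with 30%/70% inoculum/filtrate mixing,
  duplicate bottles, sampling days 0–6, 8, 9, 12, 21;
* initial abundances of 30% of 17.6×10^8^ (surface) and 70.0×10^8^ (deep)
  cells L^-1^; target specific growth rates 0.03, 0.19 and 0.11 d^-1^ and
  exponential durations 10.1, 4.9 and 2.8 d; a 25.5% one-day die-off for
  the deep inoculum;
* DOC starting at the conservative-mixing expectation of 94.8 (surface)
  and 110.1 (deep) µmol C L^-1^ end-members, with a 2-day lag then
  0.79 µmol C L^-1^ d^-1^ decline in the control, a fast (2.7 for 2 d) then
  slow (0.64) decline in S/D, a 0.68 decline in D/S with a ~5 µmol C L^-1^
  production pulse rising from day 9 to day 12 and relaxing by day 18;
* qPCR standards on a line with slope −2.93 Cq/log10 and intercept 38,
  duplicate wells with 0.15-cycle replicate noise;
* per-sample feature tables of 5,456 mzRT features with CHNOSP formulas
  whose H/C distribution rises by day 8 and partially relaxes by day 21;
* a 52-ASV community in which the deep inoculum is 75% a three-copy
  Chlorobiaceae stand-in that collapses to a surface-like assemblage within
  2 days, followed by a late shift toward SAR202/Nitrosopumilales-type
  families; library sizes are lognormal with a 12,000-read floor.

Because the downstream estimators measure µ as a window ln-slope and the
duration as $2\,t_{mid}$ — neither of which equals the logistic's $r$ or an
arbitrary duration — the generator **calibrates** $(r, K)$ jointly from the
configured (µ, duration, $N_0$) by root-finding on the window OLS slope at
the configured sampling days (`calibrate_logistic_growth()`). On noiseless
data the pipeline therefore recovers the configured µ and duration exactly,
which is the generator's defining contract. A consequence is that carrying
capacities (and hence cell yields and BGE) are implied by that calibration
rather than set independently; the generator targets rates and durations,
not yields.

Observation noise is multiplicative lognormal for abundances (positivity
without clipping the mean structure; the lognormal mean is bias-corrected)
and additive Gaussian truncated at zero for concentrations. Amino-acid
composition moves along a zero-sum direction in mol% space scaled so that
DI(t) = drift × t exactly, with total TDAA decaying exponentially.

What the generator does **not** emulate: mechanistic biogeochemistry (no
oxygen dynamics or nitrogen mass balance), within-day autocorrelation,
instrument drift, compositional coupling between the DOC block and the
growth block, chimeras/contamination in amplicon data, or realistic
phylogenetic structure. Passing tests on these bundles therefore
demonstrates that the estimators recover known statistical structure — not
that field data meet the models' assumptions.

## Numerical choices and degenerate inputs

* Quantiles: R type 7 (linear interpolation between closest ranks)
  everywhere a percentile is taken; "greater than" is strict.
* Logistic fit: `nls.lm` with `ftol = ptol = 1e-15`, ≤ 1024 iterations;
  calibration root-finding with `uniroot` at `tol = 1e-12`.
* Interpolation is linear, exact at knots, and never extrapolates; requests
  outside the observed range are errors.
* Trapezoidal integration with interpolated window endpoints; empty or
  inverted windows are errors.
* Identical ANOVA groups give F = 0, p = 1 (and Tukey p = 1) rather than
  NaN; identical replicate bottles give p = 1.
* Rarefaction and the pipeline are seeded through `withr::with_seed`, so a
  (config, seed) pair is reproducible across platforms; report equality is
  checked by a 128-bit content hash.
* All-zero amino-acid profiles, zero total magnitudes, non-positive DNA
  masses and copy numbers < 1 are rejected with named errors.

## Problem sizes

The shipped tests and the acceptance script run at the scale of the design
itself: 3 treatments × 2 bottles × 11 timepoints for kinetics, 5,456
features per metabolome sample, 30 × 52 ASV tables rarefied to 10,000
reads, 50-seed recovery sweeps for the µ property, and exhaustive
permutation oracles at ≤ 12 observations (34,650 relabelings) — sizes
chosen so every check is exact or tightly convergent while the whole suite
stays fast on a laptop.

## Known limitations

* The stationary rule $t_{stat} = 2 t_{mid}$ is a convention of the
  symmetric logistic; asymmetric growth (e.g., Gompertz-like) would bias
  both the window and µ.
* The BGE definition integrates excess over the window; other published
  BGE variants (instantaneous production/consumption ratios, leucine-based
  production) are not implemented and can differ substantially.
* The DI reference shipped is synthetic (see above); absolute DI values
  from the default table are not comparable to published DI values, though
  differences and trends are.
* Compound-class boundaries are laboratory conventions; class fractions
  should be compared only within a fixed rule table.
* The percentile DOC screen is a blunt instrument on short declining
  series; inspect flags before trusting automated exclusions.
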