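# overturnlab

Quantitative analysis of **simulated overturn incubation experiments** —
the transplant design used to ask whether dissolved organic matter (DOM)
that accumulates in a seasonally suboxic basin becomes bioavailable once the
water column mixes and reoxygenates. Surface and deep microbial assemblages
(30% whole water) are incubated in 0.2 µm filtrate from the same or the
opposite depth (70%), giving a surface control (S/S), surface cells in deep
filtrate (S/D), and deep cells in surface filtrate (D/S). The package is for
microbial ecologists and marine biogeochemists who have the resulting
time-series, amino-acid, mass-spectrometric, qPCR and amplicon tables and
want a reproducible, tested path from those tables to growth rates, growth
efficiencies, DOM diagenesis indices and community summaries.

## What it computes

**Growth kinetics.** Prokaryotic abundance `N(t)` per bottle is fit with a
logistic, `N(t) = K / (1 + ((K − N₀)/N₀) e^(−rt))`; the onset of stationary
phase is taken as twice the half-capacity time, `t_stat = 2·t_mid` with
`t_mid = ln((K − N₀)/N₀)/r`. The specific growth rate µ is the OLS slope of
`ln N` vs. `t` over the exponential window (window start moves to the bottom
of an initial die-off when one is detected). Bacterial growth efficiency is
the ratio of curve integrals over `[T₀, t_stat]`,

    BGE = ∫ ΔBC dt / ∫ ΔDOC dt,

with biomass carbon `BC` from a 20 fg C cell⁻¹ conversion and both
integrands measured as excess relative to their T₀ values.

**DOM diagenesis.** Per-sample amino-acid profiles give the TDAA carbon
yield (% of DOC) and the degradation index
`DI = Σᵢ [(varᵢ − AVGvarᵢ)/STDvarᵢ]·fac.coefᵢ` over standardized molar
percentages (lower DI = more degraded material).

**Molecular (mzRT) indices.** For formula-assigned features:
`DBE = ½(2 + 2C − H + N + P)`, the modified aromaticity index AI_mod,
magnitude-weighted O/C, H/C and DBE, CHO/CHON/CHOS counts, and peak-area
fractions over an editable van Krevelen compound-class rule table
(black carbon … CRAM).

**qPCR.** Standard copies from
`GCN = DNA(ng)·6.0221×10²³ / (length(bp)·10⁹·660)`, standard-curve fits with
efficiency `E = 10^(−1/slope) − 1`, inverse quantification and per-ng
normalization (used for *amoA* and *cbbL* marker genes).

**Community.** ASV prevalence filtering (< 4 samples removed), seeded
rarefaction to 10,000 reads, Shannon and Gini–Simpson diversity, family
aggregation with < 1% pooling into "other", and 16S copy-number adjustment
of relative abundances.

**Synthetic experiments.** `generate_experiment()` creates complete seeded
bundles (time series, amino acids, qPCR plate, feature tables, ASV counts)
with the statistical structure above, so the entire pipeline is testable
without any external data.

## Worked example

```r
library(overturnlab)

bundle <- generate_experiment(default_config(noise_scale = 0), seed = 1)
fits   <- fit_growth(bundle$timeseries)
fits[, c("treatment", "mu", "t_mid", "t_stationary", "exp_duration")]
#>   treatment   mu t_mid t_stationary exp_duration
#>         D/S 0.11  1.90          3.8          2.8
#>         S/D 0.19  2.45          4.9          4.9
#>         S/S 0.03  5.05         10.1         10.1

bge_table(bundle$timeseries, fits)[, c("treatment", "bge_percent")]
#>   treatment bge_percent
#>         D/S       47.04
#>         S/D       12.46
#>         S/S        5.96
```

The noiseless defaults reproduce the configured study conditions exactly:
µ of 0.03, 0.19 and 0.11 d⁻¹ and exponential durations of 10.1, 4.9 and
2.8 d for S/S, S/D and D/S. The BGE column is the integral ratio for the
generator's default trajectories (its DOC drawdown is configured
independently of the growth block, so these values characterize the
synthetic curves, not a field result).

```r
standards <- tibble::tibble(copies = 10^(6:1))
standards$cq <- 38 - 2.93 * log10(standards$copies)
fit_standard_curve(standards)
#> qPCR standard curve
#>   Cq = 38.0000 + -2.9300 x log10(copies)
#>   R^2 = 1.0000, efficiency = 119.4%

copy_number_adjust(
  tibble::tibble(taxon = c("Chlorobiales", "other families"),
                 fraction_pct = c(75, 25)),
  tibble::tibble(taxon = "Chlorobiales", copies = 3))
#>   taxon          fraction_pct copies adjusted_pct
#>   Chlorobiales             75      3           25
#>   other families           25      1           25
```

A dilution series with slope −2.93 Cq per log₁₀(copies) corresponds to 119%
amplification efficiency, and dividing a 75% ASV fraction by three 16S
copies yields 25% of total ASVs.

`run_pipeline(bundle)` chains every stage (QC → growth → diagenesis →
metabolome → qPCR → community → comparisons) into one tidy report whose
checksum is reproducible from (inputs, options, seed).

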