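---
title: "Monetizing disease burden and measuring its disparities"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Monetizing disease burden and measuring its disparities}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(vlwburden)
```

## The problem

Congenital heart disease concentrates its health loss in infancy and, in
lower- and middle-income settings, imposes an economic burden that national
planning rarely quantifies at subnational resolution. `vlwburden` turns
province-, sex- and age-disaggregated burden estimates — DALYs and YLLs in
the shape of a Global-Burden-of-Disease results export — into monetized
value-of-lost-welfare (VLW) figures, normalizes them by provincial GDP, and
summarizes how unevenly the burden falls across sexes and provinces.

## The valuation model

**Benefit transfer.** A value of a statistical life (VSL) estimated in a
reference economy is rescaled to the target economy through relative income:

$$VSL_{target} = VSL_{ref}\left(\frac{GDP^{pc}_{target}}{GDP^{pc}_{ref}}\right)^{\varepsilon}$$

with income elasticity $\varepsilon = 1$ by default, the conventional
assumption for transfers into lower- and middle-income economies
(`transfer_vsl()`). The three default benchmarks for Indonesia are a native
hedonic-wage VSL of US\$950,000 and two transferred values, US\$1.2 million
(OECD-based) and US\$1.77 million (US DOT-based); `default_benchmarks()`
stores all three.

**Value per life year.** Each benchmark's VSL is divided by a flat
sex-specific life expectancy — 60.67 years for males, 73.55 for females,
73.5 combined (2021 Indonesian values) — giving the VSLY used to price one
lost life year (`vsly()`). The published accounting is only reproducible
with these flat sex-specific divisors; an age-at-death-specific divisor
would be defensible in principle, and can be emulated by monetizing age
strata separately with different tables, but is not the default because the
flat divisors are what the published sex-stratified totals obey.

**Monetization.** For province $i$, sex $s$ and benchmark $m$,

$$VLW_{i,s,m} = \sum_{\alpha} B_{i,s,\alpha}\, VSLY_{m,s}$$

where $B$ is the absolute DALY or YLL count in age group $\alpha$
(`monetize()`, output in billion USD at full precision). Two consequences
are load-bearing and are enforced by tests:

* *Linearity*: replacing a benchmark's VSL by $c \times VSL$ scales every
  VLW and VLW-to-GDP ratio by exactly $c$, so all cross-benchmark columns
  are in the fixed ratio 1.77 : 1.2 : 0.95.
* *Combined-sex identity*: combined-sex rows are priced with the combined
  VSLY applied to summed counts, never as male + female. Hence
  $VLW_{both} \cdot LE_{both} = VLW_{m} LE_{m} + VLW_{f} LE_{f}$, and the
  combined value is smaller than the male + female sum
  (`combine_sex_vlw()` recovers one from the others).

**Normalization and the DALY–YLL gap.** `vlw_to_gdp()` expresses VLW as a
percentage of provincial GDP. `daly_yll_gap()` reports
$100\,(VLW_{DALY}-VLW_{YLL})/VLW_{DALY}$: the DALY-based figure is the
denominator, so the gap is the morbidity (YLD) share of the monetized
burden. Among the candidate denominators this is the only one that
reconciles the published provincial gap figures with the published tables.

## Disparity statistics

* `gender_disparity()`: $100\,(VLW_m - VLW_f)/VLW_f$, the proportional male
  excess. At full precision it is benchmark-invariant. A *rounded-input
  mode* (`rounded_inputs = TRUE` in the pipeline) recomputes it from values
  rounded to 3 decimals, because disparities quoted alongside published
  tables are typically computed from the rounded table entries.
* `location_quotient()`: a province's share of national VLW over its share
  of national population; the population-weighted mean over a full
  partition is exactly 1.
* `disparity_index()`: provincial VLW-to-GDP ratio over a national
  reference. The default reference is the national *aggregate* ratio; an
  unweighted mean of provincial ratios is available
  (`national_reference = "mean_provincial"`) since "national average" is
  genuinely ambiguous and published index values do not settle the reading.

**Clustering.** Disparity values are grouped by one-dimensional k-means
with $k = 4$. Because optimal 1-D clusters are contiguous in sorted order,
the package solves the problem *exactly* by dynamic programming over the
sorted values rather than by Lloyd iterations from a random or percentile
start: the result is deterministic, globally optimal in within-cluster sum
of squares, and verified in the test suite against a brute-force
enumeration of all contiguous partitions for small inputs. Clusters are
relabeled by ascending centroid onto ordered label sets (geographic:
*very low/low/high/very high*; gender: *low/moderate/high/very high*).
k-means clusters are generally not size-balanced quartiles; "quartile-like"
descriptions of such groupings should be read as ordered severity bands,
not as equal-count bins. Inputs with fewer distinct values than $k$ are
rejected rather than arbitrarily split.

## The synthetic country

`synthetic_config()` describes a country whose structure matches what the
analysis assumes: 34 province-like units on a west-east axis, GDP per
capita declining along the axis (`gdp_gradient`), burden rates co-varying
negatively with income (`burden_gdp_correlation`), five infancy-dominated
age strata, male rates exceeding female rates by `1 + male_excess`, and
YLL counts exactly `(1 - yld_share)` times DALY counts. Defaults were
fixed once from the study conditions: a national all-age DALY rate of 96.3
per 100,000 (the 2019 national rate for congenital heart disease in
Indonesia), `male_excess = 0.7` (the male/female count ratio implied by
the published national sex-specific totals and life expectancies),
`yld_share = 0.04` (the ~4% national DALY–YLL gap), populations between
0.7 and 50 million (the Indonesian provincial range), and a 10%
multiplicative lognormal noise CV on rates. Noise is mean-one lognormal
applied to rates only; populations are noise-free, so counts stay
non-negative and accounting identities stay exact. Combined-sex rows are
always derived from summed counts.

What the generator does *not* emulate: spatial autocorrelation beyond the
monotone axis, uncertainty intervals, year-over-year dynamics, and any
attempt to match real provincial values. Passing tests on synthetic data
therefore demonstrate the correctness of the accounting and the
statistics, not the realism of any particular province's figure.

## Numerical choices

* All internal computation is double-precision and unrounded; presentation
  rounding is half-away-from-zero (`round_half_up()`), to 3 decimals for
  billion-USD tables and 2 for percentages, matching how such tables are
  conventionally printed.
* The clustering DP breaks ties between equal-cost split points toward the
  smallest left boundary; a $10^{-12}$ slack guards against floating-point
  ties.
* Degenerate inputs fail loudly: zero female VLW (gender disparity), zero
  national ratio (disparity index), non-positive GDP or population, and
  all-equal cluster inputs each raise a classed error.
* Problem sizes in the test suite (34 provinces, 10 seeds for the
  population-weighted LQ property; brute-force clustering checks up to
  n = 12, k = 4) were chosen so the whole suite runs in seconds while the
  enumeration space stays exhaustive where it matters.

## Reproducibility

`run_pipeline()` emits a manifest (package version, config hash, seed)
alongside the result tables; re-running with the same config reproduces
the bundle bit-for-bit at full precision. Identical seeds give
byte-identical synthetic tables.

## Known limitations

* Point estimates only: no propagation of burden uncertainty intervals.
* Life expectancy enters as a flat sex-specific divisor; a conditional
  life-expectancy-at-age-of-death table would change the age weighting of
  the valuation.
* No discounting or age-weighting of life years is applied.
* The location quotient is the only spatial statistic; no smoothing or
  spatial autocorrelation measures are provided, and maps are left to
  external tools via the province join-key column.
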