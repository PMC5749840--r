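---
title: "Methods: quantifying lomas plant-community dynamics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: quantifying lomas plant-community dynamics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(lomaspulse)
```

# The setting and the data model

Lomas (fog oases) are isolated seasonal plant communities on coastal
desert hills, sustained by winter fog and episodically rewired by ENSO
precipitation extremes. The monitoring design this package targets is a
fixed panel: the same small plots (1 m²) surveyed in every campaign,
with campaigns identified by calendar month and grouped four per year
(one in each of Jan–Mar, Apr–Jun, Jul–Sep, Oct–Dec).

A `survey_table` keeps three things the analysis depends on and that a
bare data frame loses:

* the **plot roster** — plots with no individuals in a campaign are real
  ecological zeros, not missing data. All per-plot means and ranges run
  over the full roster, which is what makes printed ranges with zero
  minima and the campaign means mutually consistent;
* the ordered **campaign roster** with dates, used for pairing, joining
  to climate months, and deterministic output order;
* per-campaign **cover-overestimation flags**. A field protocol that
  measures each overlapping individual separately inflates absolute
  cover. Flagged campaigns are excluded from every statistic where cover
  enters in absolute units (campaign mean cover, cover seasonality,
  cover t-tests) and retained where only relative cover matters (the
  importance value index): a roughly multiplicative bias cancels in the
  ratio cᵢ/Cₜ.

Record-level invariants are enforced at construction: non-negative
integer counts, non-negative cover, cover zero whenever the count is
zero, one record per (campaign, plot, species). Cover above a physical
cap (default 10 000 cm² per 1 m² plot) is a warning, not an error,
because overlapping perpendicular projections legitimately exceed plot
area; `strict = TRUE` promotes it.

# Diversity, density, importance

Within a plot, density is the summed count (ind·m⁻²), cover the summed
species cover, and alpha diversity the Shannon index

H = −Σᵢ pᵢ log₂ pᵢ

on within-plot relative abundances. Base 2 (bits) is the default and
matches the magnitudes of published lomas campaign tables (gamma ≈ 1–3.3
for up to 41 species); a `base` argument provides nats. A plot with at
most one species has H = 0, and empty plots contribute alpha 0 — not
`NA` — to campaign means, consistent with the fixed-panel reading.

Gamma diversity applies the same index to abundances pooled over all
plots of a campaign; total richness counts species with pooled abundance
above zero. Alpha and gamma can move independently: a campaign where
dominant species swap between plots keeps plot-level evenness (alpha)
while changing landscape evenness (gamma), which is precisely why both
are tracked.

The importance value index weighs each species' regeneration (relative
abundance) and standing biomass proxy (relative cover) equally:

IVIᵢ = (nᵢ/Nₜ + cᵢ/Cₜ) / 2,

so each campaign column of the species × campaign IVI matrix sums to 1.
Degenerate campaigns (zero total abundance or zero total cover) raise an
error rather than emitting NaN; species with individuals but zero
measured cover contribute through the abundance term only, with a
warning.

# Seasonality index and stabilization

For each year with both a dry-window (Jan–Mar) and humid-window
(Jul–Sep) campaign,

SI = (value_humid − value_dry) / value_humid × 100.

SI ≤ 100 by construction; SI is undefined (recorded absent, never 0)
when the humid value is 0, and negative when the dry month beats the
humid one — the inversion signature of an El Niño summer. SI is exactly
invariant to rescaling both endpoints and deliberately not
translation-invariant. Cover SI is absent for years in which either
endpoint campaign carries the cover flag: an index built on a
known-biased endpoint would be misleading, even though the biased values
themselves are printed in the source tables.

Stabilization is read as the earliest year y whose SI is within `tol` of
year y + 1 (consecutive calendar years only). The published account is a
visual reading of a figure, so the tolerance is an explicit parameter,
default **10 percentage points**. On the transcribed published
summaries this detects 2000 for density (|Δ| = 0.49) and cover
(|Δ| = 8.27), matches the study's reading, and does *not* detect alpha
(|Δ| = 15.1): an honest disagreement between a numeric rule fixed in
advance and a visual judgement, not something the default was adjusted
to hide. Gamma keeps drifting and returns no year.

# Climate association

Spearman's rho is computed as the Pearson correlation of midranks, with
the two-sided t-approximation `t = ρ√((n−2)/(1−ρ²))` on n − 2 degrees of
freedom — the conventional default at n ≈ 15, where the exact null is
indistinguishable from it at the precision that matters here. An exact
permutation p (full enumeration) is available for n ≤ 10. Constant
series raise an error rather than returning 0.

Two separate Bonferroni families mirror the two published screens:

* **characteristics**: 5 responses × 2 climate variables, m = 10; the
  mean-cover pairs drop flagged campaigns (n = 13 instead of 15);
* **species**: the k = 20 most abundant species (total abundance over
  all campaigns, ties broken lexicographically) × 2 variables, m = 2k.
  Species density is pooled count divided by plot count; since that is a
  fixed rescaling, rho is identical under per-plot means.

`p_bonf = min(1, m·p)` exactly; the family size is emitted in every
output row for audit. Climate joins use the campaign's own calendar
month (a configurable lag exists, default 0). One consequence worth
stating plainly: on the published per-campaign summaries, mean cover vs
precipitation gives ρ = 0.698, p = 0.0080 at n = 13, hence
p_bonf = 0.080 — *not* significant under this family definition,
although the published account reports cover as significant. The
significance returns if the flagged campaigns are kept (n = 15) or if
each climate variable is corrected as its own family of 5. The package
keeps the stricter, pre-registered-style definition and documents the
discrepancy rather than selecting the family after seeing the result.

# Campaign and zone comparisons

All unordered campaign pairs are compared by paired t-tests on per-plot
values, pairing by plot. Values are transformed by **log10(x + 1)**
before differencing: a log is needed for the right-skewed densities and
covers, and the +1 offset is forced by exact zeros from empty plots
(`log1p` and identity are available). Fifteen campaigns give 105 pairs;
for cover, flagged campaigns are excluded first (13 campaigns, 78
pairs). Bonferroni runs within the pairs actually tested per
characteristic, not pooled across characteristics, mirroring per-panel
significance lettering. Two identical campaigns yield the degenerate
result t = 0, p = 1 (documented, not an exception); a constant nonzero
shift yields p = 0. A greedy compact-letter display is generated for
reporting only.

Zone effects use the Kruskal–Wallis H with midrank ties correction,
either within one campaign or pooling all campaigns ("all", each
plot × campaign value one observation — the pooled mode ignores
within-plot dependence and is the coarse screen the original design
used, not a mixed model).

# Detrended correspondence analysis

The DCA is authored from scratch. The CA core: with P = X/ΣX, row
masses r, column masses c, the standardized matrix
S = (P − rcᵀ)/√(rcᵀ) is SVD-ed; eigenvalues are squared singular
values, in (0, 1], invariant to positive rescaling of X. Site
(campaign) scores are principal coordinates — their c-weighted variance
on axis k equals the eigenvalue — and species scores are
profile-weighted means of the standard site coordinates (the reciprocal
averaging relation). All-zero rows/columns are dropped with a warning;
campaigns are never dropped by the pipeline itself.

Numerical choices:

* singular values below 1e-10 are treated as null rank;
* the sign of each axis is fixed by requiring a non-negative score for
  the lexicographically smallest site label, so permuting input columns
  permutes outputs identically;
* "variance represented" is reported as eigenvalue share of total
  inertia — the only reading that is reproducible across program
  dialects. Published two-axis percentages from other implementations
  (which rescale axes nonlinearly) are therefore comparable only
  loosely, and nonlinear rescaling is deliberately not implemented.

Rare-species downweighting follows Hill's classic rule on the
*effective frequency* fᵢ = (Σⱼxᵢⱼ)²/Σⱼxᵢⱼ² (equal to the number of
occurrences when a species' nonzero abundances are equal): species with
fᵢ below 1/5 of the maximum are scaled by fᵢ/threshold. Frequency, not
raw magnitude, drives the rule, which is what makes it meaningful on an
IVI matrix whose entries are already relative.

Detrending by segments: the axis-1 range is cut into 26 equal-width
segments (the classic default, configurable); axis-2 segment means —
empty segments filled by linear interpolation between neighbours, the
practical equivalent of merging them — are smoothed by a (¼, ½, ¼)
running average and subtracted. With `n_axes = 1` no detrending happens.

# The synthetic world

`simulate_survey()` generates the stated world of the monitoring design:
31 plots × 15 quarterly campaigns × 60 species. Monthly precipitation is
a smooth climatology peaking at ~30 mm in August with gamma-noise, plus
a 100 mm ENSO pulse in the months of designated campaigns (default: the
four campaigns of year 1 — ten times a typical month, about three times
the humid-season maximum). Temperature is an annual cycle between ~13.5
and ~22.5 °C.

Species base abundances are lognormal (rank-abundance `dominance`, sd
1.5); a `responder_fraction` (default 0.3) of species carries a
precipitation coefficient b (default 1) so that expected counts scale as
(1 + P)^b; counts are negative binomial (size 0.7 — the overdispersion
of clumped plant counts) around
exp(aᵢ + bᵢ·log(1 + Pₜ) + plot effect); cover is count × a lognormal
individual size (mean 150 cm², log-sd 0.6). Zero inflation in dry months
emerges from the collapsed seasonal mean, not from a separate mixture.
The base abundance scale (0.05 expected individuals per plot per species
at zero precipitation) was calibrated once so that dry-month plot
densities land in the single digits and humid/pulse campaigns in the
tens to hundreds — the magnitudes of published lomas campaign tables —
and was not revisited afterwards.

What the generator does **not** emulate: spatial structure among plots,
seed-bank dormancy and carry-over between campaigns (campaigns are
conditionally independent given climate), species interactions, and
observer error. A green test on synthetic data therefore establishes
that the statistical machinery recovers planted structure of the stated
kind — not that real lomas data satisfy the generative assumptions.
Ground truth (every bᵢ, plot effects, pulse months) is returned and
serialized so tests never re-derive it.

# Known limitations

* The species-screen power depends on responders being among the top-k
  abundance ranking; a rare strong responder is invisible by design,
  matching the screening protocol rather than fixing it.
* Per-campaign temperature for the shipped Lachay summaries was never
  published; `lachay_climate()` substitutes a clearly labelled
  climatological stand-in, so temperature-side conclusions drawn from it
  are stand-in results.
* The paired t-tests assume the log-transformed paired differences are
  approximately normal; with n = 31 plots this is a mild assumption but
  it is an assumption.
* The stabilization detector compares only consecutive years; a series
  that oscillates into agreement across a gap returns no year.
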