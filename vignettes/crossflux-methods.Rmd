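---
title: "Harmonizing cross-ecosystem carbon fluxes: models and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Harmonizing cross-ecosystem carbon fluxes: models and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(crossflux)
library(dplyr)
```

## The problem

Ecosystems exchange carbon: leaf litter falls into streams, emerging
aquatic insects deposit on land, particulate organic carbon sinks from the
pelagic zone to the sea floor, beach wrack piles up on desert shores.
Judging whether these *cross-ecosystem subsidies* matter for a recipient
ecosystem requires comparing them with the recipient's own local fluxes —
gross primary production (GPP), ecosystem respiration ($R_e$), net
ecosystem production (NEP), decomposition — on a single scale. The
literature reports all of these in wildly heterogeneous units: carbon, dry
or ash-free dry mass; per day, per growing season, or per year; per cubic
metre of water, per square metre of the *donor* system, or per metre of
shoreline. `crossflux` implements the full chain from such raw records to
a common currency, gC m⁻² yr⁻¹ of the *recipient* ecosystem, and the
statistics used to summarise the result.

## The harmonization model

Every record is a row of a flux table (see
`inst/extdata/column_dictionary.csv`) carrying its ecosystem (8 types:
forest, grassland, agro-ecosystem, desert, stream, lake, pelagic and
benthic ocean), climate zone (5 zones; marine records pooled into
Cold/Warm only at summary time), flux class, raw value and unit
descriptor, and optional geometry. `harmonize()` applies four
multiplicative steps in a fixed order; each multiplier is logged in a
per-record audit trail, so any harmonized value can be traced back to its
raw source (`audit_trail()`).

1. **Carbon conversion.** A study-reported carbon fraction takes
   precedence; otherwise the most specific entry of the conversion table
   (material class × mass basis) applies, falling back to a generic class.
   The shipped fractions — 0.5 gC/g for dry and ash-free dry mass, 0.1
   gC/g for wet mass — are deliberately parsimonious field defaults, kept
   in the configuration so that laboratory-specific factors can be dropped
   in without touching code. Decomposition *rates* are never
   carbon-converted: a first-order loss rate is taken to be the same in
   carbon as in the measured mass basis, the most parsimonious assumption
   and the only one that keeps rates comparable across sources.

2. **Volume-to-area integration.** Volumetric data are integrated over a
   water-column depth: the measured mean depth when given; volume/area in
   lakes; the hydraulic-geometry power law $depth = 0.2\,Q^{0.4}$ ($Q$ in
   m³ s⁻¹) in rivers, with a 5 cm floor for catchments under 1 km²; the
   euphotic (e.g. Secchi) depth in pelagic systems, or 100 m when only
   sampling depths are reported. The euphotic depth is used verbatim — no
   light-extinction transform is applied, since sources report "a
   meaningful depth" rather than a standardised optical quantity.

3. **Shoreline re-expression.** Lateral aquatic→terrestrial flows
   reported per m² of donor area cannot be compared directly with
   recipient-area fluxes: the flow reaching land depends on the donor's
   production area *and* its boundary length. Donor-area flows are first
   converted to a flow per metre of shoreline — in lakes by multiplying by
   lake area and dividing by the perimeter (measured, or approximated by
   $2 D_L \sqrt{\pi \cdot area}$ with shoreline development factor $D_L
   \ge 1$, assumed 1 and flagged in the audit when unknown); in streams by
   multiplying by width and dividing by two river sides — and then spread
   uniformly over the first 10 m inland (`band_width_m`), the distance
   within which most insect deposition and carcass transport falls. The
   100 m setting is a conservative sensitivity variant; because the band
   step is a plain division, it rescales every band-routed value by
   exactly 1/10 (`sensitivity_band()` verifies this and that nothing else
   moves). Whole-lake totals are first divided by lake area; vertical
   pelagic→benthic flows keep their area (donor and recipient coincide).
   This module deliberately uses a uniform band, not a distance-decay
   model of deposition.

4. **Annualization.** Per-day fluxes are multiplied by the growing-season
   length of the record's climate (temperate 181 d, boreal 155, arctic/
   alpine 116, arid 163, tropical 365 — tropical systems are assumed
   aseasonal). Fluxes integrated over a study period shorter than the GSL
   are rescaled by GSL/days; periods covering the GSL need no conversion;
   periods longer than a year are divided down by days/365, conserving the
   measured total (a choice this package makes where sources are silent).
   NEP is annualized like any other flux — there is no separate rule for
   sign-changing fluxes — and detritus stocks carry no time basis at all.

Two properties pin the implementation down: harmonization is *idempotent*
(a canonical record passes through unchanged with an empty audit) and
*homogeneous of degree one* (every step is linear in the value), which is
also what makes the shoreline step conserve carbon exactly:
$(\text{per-band flow}) \times perimeter \times band =
(\text{per-donor-m}^2\ \text{flow}) \times area$.

## Decomposition fluxes

Decomposition is rarely reported as a flux. `crossflux` derives it from
the one-pool exponential decay model: a stock $D_M$ decaying at rate $k$
releases $D_F = D_M (1 - e^{-kt})$ over horizon $t$. Rates come either
directly from the literature, from litter-bag mass pairs
($k = -\ln(D_t/D_{t_0})/t$, `k_from_massloss()`), or from a
production/export budget ($D_F = (D_P - E)(1 - e^{-kt})$,
`k_from_production()`; unknown export defaults to 0, which
under-estimates $k$ — the conservative direction). Per ecosystem ×
climate stratum, `stratum_decomposition_fluxes()` sets $D_M$ to the
*median* of that stratum's harmonized stocks (midpoint rule for even
counts) and turns every collected rate into one derived flux with $t = 1$
yr — the horizon forced by the annual canonical unit. Microbial-loop
parameterisations of $D_P$/$D_F$ in pelagic data are left to the user:
the functions expose those terms directly rather than guessing a mapping.

## NEP statistics

The metabolism identities $NEP = GPP - R_e$, $NEP = NPP - R_h$,
$NPP = GPP - R_a$ close any triplet with two known members
(`close_flux_triplet()`, iterated to a fixpoint; over-determined triplets
are checked to a $10^{-6}$ relative tolerance). Per ecosystem,
`nep_ttest()` runs the classical two-sided one-sample t test of mean NEP
against zero and reports $p_+$, the probability that a random NEP
observation is positive under a normal model of the data:
$\Phi(\bar{x}/s)$ with the *sample standard deviation*, not the standard
error — $p_+$ describes the data distribution (how often such an
ecosystem is net autotrophic), not the sampling distribution of the mean.

Across ecosystems the comparison is rank-based (Kruskal–Wallis with tie
correction — real flux data contain duplicated values), justified by
Bartlett's variance-homogeneity check, with Siegel–Castellan post-hoc
pairwise comparisons: groups $i, j$ differ when
$|\bar{R}_i - \bar{R}_j| \ge z_{1-\alpha/(K(K-1))}
\sqrt{\tfrac{N(N+1)}{12}\left(\tfrac{1}{n_i}+\tfrac{1}{n_j}\right)}$
at family alpha 0.05. The significance pattern is compressed into a
compact letter display by the insert-and-absorb algorithm; groups are
processed in the fixed ecosystem enumeration order so the letters are
reproducible. The critical-difference variance term deliberately omits a
tie correction, matching the classical formulation of this post-hoc test.

## The synthetic generator

No public accession exists for compiled cross-ecosystem flux datasets of
this kind, so the package carries a generator (`simulate_fluxes()`) whose
defaults emulate the composition of a global compilation: 2516 local-flux
records and 518 spatial flows (3034 records), allocated so that the
terrestrial–freshwater interface carries 347 spatial records (67.0%),
pelagic–benthic 93 (18.0%) and passive physical drivers 365 (70.5%).
Positive fluxes are log-normal around a target median — the median is the
natural invariant under log-normality and the quantity the synthesis
reports — with log-scale spreads back-computed from published
interquartile ranges where available (e.g. sdlog 1.23 for
terrestrial-plant subsidies from 148.7 [47.1–246.6]). NEP is modelled
directly as normal per ecosystem (matching the normality assumption
behind $p_+$) rather than as a GPP − $R_e$ difference; stream NEP uses
mean −114.1 and sd 281.4 = (−20.9 − (−400.5))/1.349, which implies
$p_+ = \Phi(-0.405) \approx 0.34$, i.e. roughly two-thirds to
three-quarters of stream observations net heterotrophic. Stratum medians
use published values where printed (forest GPP 1379.5, grassland 611.5,
stream 55.2 gC m⁻² yr⁻¹; invertebrate subsidies 1.51; beach-wrack
macroalgae 164) and realistic field magnitudes elsewhere; the
insect-deposition-to-forest stratum is centred low (0.2 gC m⁻² yr⁻¹,
sdlog 2.0) so that the generated spatial flows span the documented
milligram-to-ton range of more than six orders of magnitude.

Raw units are produced by *inversion*: each record receives a sampled
unit variant (about half the mass values already in carbon, 55% of time
bases already annual, volumetric bases for a third of aquatic local
fluxes, donor-area/shoreline/whole-lake bases for lateral flows) plus the
geometry needed to harmonize it, the record's multiplicative
harmonization factor is evaluated by running the harmonizer on a unit
value, and the raw value is the intended canonical value divided by that
factor. Harmonizing the generated data therefore recovers the ground
truth to floating-point rounding on every path — by construction, which
is exactly the point: the generator validates the plumbing, not the
science. What passing these tests does *not* show is robustness to
features of real compilations the generator omits: free-text units,
correlated measurement error, study-level clustering (the pipeline pools
measurements without random effects, as the synthesis design it follows
does), heavy tails beyond the log-normal, and transcription mistakes.

## Numerical and design notes

* Quartiles use the linear-interpolation convention
  (`stats::quantile()` type 7), stated here because published syntheses
  rarely say which convention they used; reproducing printed IQRs from a
  real supplement may require trying nearest-rank as well.
* Values are stored at full double precision; rounding to 0.1 happens
  only in percentage displays. Percentage tables sum to 100 before
  rounding.
* `decomposition_flux()` uses `expm1`, keeping the small-$kt$ limit
  $D_F \approx D_M k t$ accurate; complete litter-bag mass loss raises an
  infinite-rate condition rather than returning `Inf`.
* Degenerate inputs are defined, not crashed on: zero-variance NEP
  samples yield $p_+ \in \{0, 1\}$ by the sign of the mean; all-tied
  Kruskal–Wallis input gives $\chi^2 = 0$, $p = 1$; a single post-hoc
  group gets letter "a".
* Closed vocabularies: free-text ecosystem names ("prairie", "meadow")
  must be mapped before import — synonym pooling is a literature-search
  concern, not an analysis one.
* The `reach_length_m` geometry column backs the `per_stream_reach`
  basis; the column dictionary is this package's own layout.
* Problem sizes in the shipped tests: the property suites use 1000
  randomized records/geometries, statistical calibration uses 10,000
  simulated t tests (n = 20) and 1000–2000 rank/variance tests, and
  recovery checks run the full 3034-record default compilation or 200
  records per stratum — sizes chosen to make Monte-Carlo error small
  relative to the tolerances tested.

## Limitations

The package converts units; it does not judge data quality, weight
studies, model spatial decay of subsidies away from the boundary, fit
multi-pool decay models, or render maps. Isotope-only flow estimates and
nutrient (N/P) flows without a carbon equivalent are outside its scope,
as are flows lacking a defined recipient area. Where the configuration
ships a default (carbon fractions, $D_L = 1$, the 100 m pelagic depth),
the audit trail marks the assumption so downstream users can quantify its
leverage.
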