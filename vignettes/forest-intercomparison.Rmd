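---
title: "Comparing forest stands across regions: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Comparing forest stands across regions: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(standcompare)
```

## The problem

Managed and community forests are censused under heterogeneous protocols,
in climates ranging from temperate lowland to tropical montane. Raw
basal area or species counts are therefore not comparable across sites:
the same number can mean a thriving dry woodland or a degraded rainforest.
standcompare implements a family of comparison methods that put forests on
a common footing:

* **per-hectare basal area (BA)** from stratified circular plot
  inventories,
* **stem-based rarefied species richness (SR)** — the median number of
  unique species in repeated draws of 100 stems,
* **annualized change** between revisits of the same forest,
* **regional intercomparison** — a z-score of a forest's metric against
  the inverse-square-distance weighted mean and SD of nearby forests from
  the same dataset,
* **reference-forest comparison** — the same standardization against
  nearby old-growth transect plots, after harmonizing sampling effort,
* and the evaluation statistics used to relate these metrics to each
  other and to ordinal field ratings: major axis (model II) regression
  with a permutation test, and one-way ANOVA with Tukey HSD compact
  letter displays.

## Census dialects and basal area

Inventories arrive in three dialects (`plot_geometry()`). The standard
protocol censuses trees and palms ≥ 10 cm DBH within 10 m of each plot
center (area $\pi \cdot 10^2 \approx 314\,\mathrm{m}^2$) and saplings
(2.5–10 cm) plus shrubs and lianas ≥ 2.5 cm within 3 m
($\approx 28.3\,\mathrm{m}^2$). A variant used at some Indian sites
measures both strata in a single 5-m plot ($78.5\,\mathrm{m}^2$) and
records stem *circumference*; the reader converts to DBH as
$c/\pi$. Old-growth reference plots follow a 0.1-ha transect layout
— ten 100-m² subplots in which every stem ≥ 2.5 cm is measured.

Basal area per hectare is
$\sum_i \pi\,\mathrm{DBH}_i^2/4$ per stratum, divided by the stratum's
nominal area times the number of plots, with the per-hectare tree and
sapling components summed. The two strata must be scaled separately
because they sample very different areas. Shrubs and lianas are excluded
from BA (their measurement is inconsistent across crews) but **included**
in all biodiversity pools. Stratum areas are computed from the radii at
full double precision; the rounded areas sometimes quoted for the
protocol (314, 28.3 m²) are presentation values, not protocol.

Numerical/edge choices:

* Stems recorded outside their lifeform's size window (a 6-cm "tree")
  are field errors: flagged, kept in the table, excluded from structure
  metrics, never reassigned to another stratum.
* `apply_sanity_filter()` flags stems above `max_dbh` (default 1000 cm —
  an order of magnitude above the largest credible stem, so only unit
  errors are caught). The default scope excludes flagged stems from all
  metrics; `scope = "structure_only"` restricts the exclusion to basal
  area. A single giant stem cannot materially change a species count,
  so the simpler uniform rule is the default.
* Partial or edge plots are not supported; per-hectare scaling always
  uses the nominal plot area.

## Rarefied species richness

For each forest-visit all stems of every growth form are pooled across
plots. One repetition draws `n_draw = 100` stems *with replacement* and
counts the unique species; over `reps = 1000` repetitions the median is
the reported SR. One hundred stems is a compromise: enough draws to
separate forests, yet fewer stems than most forests contain. Pools
smaller than 100 stems remain computable — such forests (often heavily
harvested) are genuinely species-poor, and SR is then bounded by their
distinct species count.

Conventions worth stating because no authority fixes them:

* The median of an even number of repetitions is the mean of the two
  central order statistics, so half-integer values occur.
* Each estimate takes one root seed; repetition $r$ runs under its own
  deterministically derived sub-seed, so results do not depend on
  iteration order and a visit's estimate does not depend on which other
  visits share the table.
* Quantiles (q05/q25/q75/q95) are reported alongside the median.

### Harmonizing sampling effort against reference plots

A reference transect samples 0.1 ha; a typical focal census covers about
1 ha. Comparing their SR values directly would reward the larger effort.
`harmonized_richness()` therefore resamples each focal visit: every
repetition first draws 3 plots without replacement
($3 \times 314\,\mathrm{m}^2 = 0.0942$ ha, close to the reference
0.1 ha), pools their stems, then draws 100 stems as usual. Plot subsets
are drawn independently across repetitions — the most literal reading of
"resampled 1000 times, each time choosing 3 plots". India-dialect visits
use $4 \times 3 = 12$ of their smaller plots for trees and palms (exactly
the same tree-stratum area) and one independently drawn plot for other
lifeforms (78.5 m², close to the 84.8 m² of three standard understory
subplots). For the 4-plot bracketing variant the same $4\times$ rule
gives 16 plots; the understory stays at one plot (the nearest integer
match to four standard subplots at 113 m² would still be one-to-two
plots, and one keeps the rule simple).

Reference plots oversample small stems (every stem ≥ 2.5 cm over the
whole 0.1 ha versus 3-m subplots in focal forests).
`reference_richness()` therefore includes, per repetition, all stems
≥ 10 cm from the whole plot but small stems from only one uniformly
chosen subplot (100 m² of small-stem effort ≈ the 84.8 m² of three
standard subplots).

## Total distance and regional intercomparison

Geographic distance is the haversine great circle on a sphere of radius
6371 km. Elevation difference (m) and horizontal distance (km) are
combined as

$$\mathrm{TD} = \sqrt{d_{geo}^2 + d_{elev}^2},$$

equating 1 m of climb with 1 km of horizontal travel — a deliberate
mixed-unit construction (about the climatic equivalence of a 1-km climb
and a several-hundred-km poleward journey), so TD is a unitless
proximity index, not a distance.

A forest's neighborhood is every candidate with $0 < \mathrm{TD} \le
1000$ units (inclusive; the cutoff reflects the within-country clustering
of typical multi-site databases). Weights are $\mathrm{TD}^{-2}$,
normalized; because of the inverse-square decay, far neighbors contribute
little and the cutoff rarely binds. The z-score is

$$z = \frac{v_{focal} - \mu_w}{\sigma_w}, \qquad
  \sigma_w = \sqrt{\textstyle\sum_i w_i (v_i - \mu_w)^2}.$$

Design decisions, each genuinely open and settled here:

* **Weighted SD form**: the normalized-weight ("probability weight")
  population form. The purpose is a z-score, not an inferential standard
  error, and this form is exactly location- and scale-equivariant —
  adding a constant or rescaling all values leaves z unchanged.
* **Self-exclusion**: a forest is never its own neighbor, and when a
  forest has several visits only the latest enters the candidate pool,
  so a forest is not compared against itself across time.
* **Zero distances**: a candidate at TD = 0 would get infinite weight;
  distinct co-located candidates are excluded with a warning.
* **`min_neighbors = 2`**: an SD needs at least two points. Forests with
  smaller neighborhoods are reported with a missing z and a reason,
  never dropped. A degenerate neighborhood (σ = 0) yields z = 0 when the
  focal equals the mean and a missing z otherwise.
* Reference mode runs the identical code path with the candidate pool
  swapped for reference forests.

## Annualized change

The change in BA or SR between visits in years $y_1 < y_2$ is rescaled
per year. Two conventions satisfy all the defining properties (0 iff
unchanged, sign follows the difference): *simple*,
$((v_2-v_1)/v_1)/(y_2-y_1)$, and *compound*,
$(v_2/v_1)^{1/(y_2-y_1)}-1$. The package defaults to simple — matching
the "percent change per year" reading — and exposes compound via
`convention`; neither is presented as uniquely correct, since the
defining description is consistent with both.

## Evaluation statistics

**Major axis regression.** When two metrics both carry error (two
alternative measurements of forest condition), OLS is inappropriate and
asymmetric. The major axis is the leading eigenvector of the 2×2 sample
covariance matrix, in closed form
$\bigl(s_{yy}-s_{xx}+\sqrt{(s_{yy}-s_{xx})^2+4s_{xy}^2}\bigr)/(2s_{xy})$,
through the centroid; swapping the variables returns the reciprocal
slope. The slope's sign follows the covariance; at exactly zero
covariance the axis follows the larger-variance variable (vertical
handled by swap-and-invert). Significance is a two-tailed permutation
test of the Pearson correlation (999 permutations, observed statistic
included in the numerator) — assumption-light and self-contained, since
no distributional theory is needed for a z-scored, heavy-tailed metric.

**Ordinal ratings.** User change ratings are coded −1/0/1 and forester
level ratings −2…2. `anova_ordinal()` runs `stats::aov` plus
`stats::TukeyHSD` (Tukey–Kramer for unbalanced groups) and condenses the
pairwise matrix into a compact letter display by insert-and-absorb:
groups sharing no letter differ at α, groups sharing a letter do not.
For ordinal-vs-ordinal pairs the analysis is run both ways
(`response = "code"`).

## The synthetic landscape generator

Nothing in the package requires external data: `generate_landscape()`,
`generate_inventory()`, `generate_reference_set()` and
`generate_ratings()` produce a full synthetic study with known ground
truth. The generator emulates the structural features that matter to the
methods:

* **Clustered geography**: `n_clusters = 5` regions at widely separated
  longitudes (cross-cluster TD far above the 1000-unit cutoff), each
  with `cluster_spread_km = 50` of within-cluster scatter and 150 m of
  elevation scatter — so neighborhoods are dense within clusters and
  empty across them.
* **Regional fields**: stem density and species-pool size are multiplied
  by a smooth latitudinal trend times a lognormal cluster-level biome
  factor (SDs 0.7 and 1.0 on the log scale). The defaults were chosen so
  that generated basal areas span roughly 3–300 m²/ha and SR spans
  roughly 7–30 — the order-of-magnitude heterogeneity of real
  multi-biome databases, which is exactly what regional standardization
  exists to remove.
* **A latent condition effect** per forest (`effect_sd = 0.4`,
  lognormal): density × $e^{\mathrm{effect}}$, species pool ×
  $e^{0.5\,\mathrm{effect}}$. This is the recoverable ground truth.
* **Communities**: log-series species abundances
  ($p_k \propto x^k/k$, $x = 0.98$) over a baseline pool of 120 species;
  Poisson per-plot stem counts (15 tree-stratum and 8 understory stems
  per standard plot); exponential tree DBH (mean 10 cm above the 10-cm
  threshold) and truncated-exponential understory DBH on [2.5, 10) cm.
* **Reference plots**: the 10-subplot 0.1-ha layout with an `uplift`
  parameter making them old-growth analogues (density ×
  $e^{\mathrm{uplift}}$, larger trees, larger pool).
* **Ratings**: ordinal codes by thresholding
  `condition + halo × shared + noise × independent`, where the shared
  draw is a rater's overall impression; `halo` controls how strongly a
  rater's answers to different questions co-vary.

What the generator does *not* emulate: spatial autocorrelation of the
condition effect, temporal dynamics (succession, disturbance),
observer-specific measurement bias, and real taxonomic structure.
Passing tests therefore show that the estimators and the standardization
behave correctly under realistic heterogeneity — not that any particular
ecological conclusion transfers to real data.

## What the test suite establishes

The suite checks, among other properties: the protocol's plot-geometry
constants as computed from radii; haversine closed forms (antipodal and
pole-to-equator within 0.1 km); the equal-abundance rarefaction
expectation $S(1-(1-1/S)^{100})$ within three Monte-Carlo standard
errors at $10^5$ repetitions, and agreement of the median with an
independent brute-force simulation; exact agreement (1e−10) of the
weighted z with a from-scratch arithmetic oracle and of the major-axis
slope with an eigendecomposition oracle; reciprocal slope under variable
swap; translation/scale invariance of z; and letter displays consistent
with pairwise Tukey p-values.

On the default synthetic study (100 forests, 5 clusters, 10 plots each —
sizes chosen to exercise every code path while keeping the full suite
fast): ranking forests by the regional BA z-score recovers the latent
condition ranking with Spearman ρ ≈ 0.85–0.90; 3- versus 4-plot
harmonized richness agree after standardization with major-axis slope 1,
intercept 0 and R² ≈ 0.98; and with a positive old-growth uplift the
large majority (≈ 95%) of focal forests fall at or below their weighted
reference mean. The richness z responds to the condition effect in the
same direction but with a weaker correlation (ρ ≈ 0.6): fixed-draw
rarefaction is deliberately insensitive to stem density and compresses
pool-size differences, so structure is the sharper lens on the latent
condition — itself a finding about the estimator, not a defect. The
recovery benchmark is therefore stated on the structure metric.

`scripts/acceptance.R` recomputes all of these quantities from scratch
at a caller-supplied seed; the vignette states no number that script or
the tests do not themselves compute.

## Known limitations

* Species-label normalization is mechanical (whitespace and case only);
  distinguishing genuine taxa from misspellings requires the manual
  review that only a botanist can do.
* No biomass or allometric conversion: wood density varies enormously
  and allometric error would swamp the comparison; basal area is the
  structure proxy.
* No coverage-based rarefaction or richness extrapolation (Chao, Hill
  numbers): the fixed-draw median protocol is the method implemented.
* The mixed-unit total distance is a pragmatic proximity index; its
  1 m : 1 km equivalency is an assumption, not an estimate.
* No climate covariates: the standardization uses geography and
  elevation only.
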