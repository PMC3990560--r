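# standcompare

Tools for comparing the structure and biodiversity of forests censused
under heterogeneous protocols and environments — for quantitative
ecologists, forestry researchers and anyone analyzing multi-site
inventory databases where forests in different climates and biomes must
be put on a common footing.

Raw basal area or species counts are not comparable across sites: local
climate, species pools and land-use history set very different
potentials. standcompare implements a set of comparison methods around
one central idea, **regional intercomparison**: standardize each
forest's metric as a z-score against the inverse-square-distance
weighted mean and SD of its neighbors,

    TD = sqrt(d_geo² + d_elev²)          (1 m altitude ≡ 1 km distance)
    w_i ∝ TD_i⁻²,   neighbors: 0 < TD ≤ 1000 units
    z   = (v − Σ wᵢvᵢ) / sqrt(Σ wᵢ(vᵢ − Σ wⱼvⱼ)²)

together with the metrics it standardizes and the statistics used to
evaluate them:

- **Basal area per hectare** from stratified circular plots
  (`forest_basal_area()`): per-stem `π·DBH²/4`, summed per stratum and
  scaled by the stratum's sampled area — trees/palms ≥ 10 cm in the
  314-m² plot, saplings 2.5–10 cm plus shrubs/lianas in the 28.3-m²
  subplot (shrubs/lianas excluded from BA, included in biodiversity).
- **Rarefied species richness** (`rarefied_richness()`): the median
  number of unique species among 100 stems drawn with replacement from a
  visit's pooled stems, over 1000 repetitions.
- **Effort-harmonized richness** against 0.1-ha old-growth reference
  transects (`harmonized_richness()`, `reference_richness()`).
- **Annualized change** between revisits (`change_over_time()`).
- **Major axis (model II) regression** with permutation significance
  (`major_axis_fit()`) and **ANOVA + Tukey HSD compact letters** for
  ordinal field ratings (`anova_ordinal()`).
- A **synthetic-landscape generator** with known ground truth
  (`generate_landscape()` and friends), so the whole pipeline is testable
  without any external data.

Inventories are read from plain CSV (`read_inventory()`: stems, plots,
sites tables, with three census dialects including a
circumference-measuring variant); every user-facing function takes a data
frame and returns a tibble, so analyses chain with the pipe. Fitted
objects support `tidy()`, `glance()` and `autoplot()`.

## Worked example

Generate a 30-forest synthetic landscape, compute basal area and its
regional z-scores, and check that the z-scores recover the latent
per-forest condition:

```r
library(standcompare)

land <- generate_landscape(landscape_spec(n_forests = 30, n_clusters = 3, seed = 1))
inv  <- generate_inventory(land, community_spec(), n_plots = 10, seed = 2)
inv
#> <forest_inventory> 30 site(s), 300 plot(s), 16718 stem(s), 30 forest-visit(s)

ba <- forest_basal_area(inv)
head(ba, 3)
#> # A tibble: 3 × 7
#>   forest_id visit_year ba_per_ha tree_component sapling_component n_plots
#> 1 F001            2005      19.0           15.7              3.36      10
#> 2 F002            2005      22.6           19.4              3.15      10
#> 3 F003            2005      35.2           29.7              5.52      10
```

`ba_per_ha` is standing basal area in m²/ha — 19–35 m²/ha here, typical
of closed-canopy forest — split into its tree- and sapling-stratum
components. Standardize each forest against its distance-weighted
neighbors:

```r
tab <- dplyr::inner_join(visits(inv)[c("forest_id", "visit_year", "site_id")],
                         ba, by = c("forest_id", "visit_year")) |>
  dplyr::mutate(value = ba_per_ha)
ic <- intercompare(tab[c("forest_id", "visit_year", "site_id", "value")],
                   inv$sites, metric = "BA")
head(ic[c("forest_id", "focal_value", "n_neighbors", "weighted_mean",
          "weighted_sd", "z")], 4)
#> # A tibble: 4 × 6
#>   forest_id focal_value n_neighbors weighted_mean weighted_sd      z
#> 1 F001             19.0           9          46.5        19.9 -1.38
#> 2 F002             22.6           9          35.6        17.7 -0.733
#> 3 F003             35.2           9          42.3        20.5 -0.347
#> 4 F004             21.6           9          38.9        21.0 -0.826
```

Each forest is compared only with the 9 other forests of its own
cluster (the clusters are separated far beyond the 1000-unit cutoff);
F001 is 1.38 weighted standard deviations below its neighborhood.
Because the landscape carries a known condition effect, recovery can be
measured directly:

```r
round(cor(ic$z, land$true_effect, method = "spearman", use = "complete.obs"), 2)
#> [1] 0.86
f <- major_axis_fit(dplyr::inner_join(
  ic, tibble::tibble(forest_id = land$forest_id, eff = land$true_effect),
  by = "forest_id"), eff, z, seed = 4)
f
#> Major axis (model II) regression: z ~ eff
#>   slope 4.043  intercept 0.09018  R^2 0.701  p 0.001 (n = 30, 999 permutations)
```

The z-score ranks the latent condition with Spearman ρ = 0.86, and the
model II fit is strongly positive — the standardization sees through the
several-fold regional differences in density and diversity the generator
built in.

A thin command-line wrapper over the same functions is installed at
`inst/scripts/standcompare` (subcommands `simulate`, `validate`,
`structure`, `richness`, `change`, `intercompare`, `stats`, `all`,
driven by a YAML config; see `?run_pipeline`).

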