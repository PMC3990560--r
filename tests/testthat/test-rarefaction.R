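test_that("pooling gathers all lifeforms and ignores plot structure", {
  stems <- tibble::tibble(
    species = c("a", "b", "c", "d", "e"),
    lifeform = c("tree", "tree", "tree", "liana", "liana"),
    measure_cm = c(12, 15, 20, 5, 6), plot = c(1L, 1L, 2L, 1L, 2L))
  inv <- fixture_inventory(stems, n_plots = 2)
  pool <- pool_stems(inv)
  expect_equal(nrow(pool), 5)
  expect_setequal(pool$species, c("a", "b", "c", "d", "e"))
})

test_that("rarefied richness is deterministic and respects degenerate pools", {
  land <- generate_landscape(landscape_spec(n_forests = 3, n_clusters = 1,
                                            seed = 5))
  inv <- generate_inventory(land, community_spec(), n_plots = 3, seed = 6)
  r1 <- rarefied_richness(inv, reps = 200, seed = 42)
  r2 <- rarefied_richness(inv, reps = 200, seed = 42)
  expect_identical(r1, r2)
  r3 <- rarefied_richness(inv, reps = 200, seed = 43)
  expect_false(identical(r1$median_richness, r3$median_richness))

  # single species: median exactly 1
  inv1 <- fixture_inventory(simple_stems(7))
  expect_equal(rarefied_richness(inv1, reps = 100, seed = 1)$median_richness,
               1)
  # two abundant species: both essentially always seen in 100 draws
  inv2 <- fixture_inventory(dplyr::bind_rows(
    simple_stems(1, species = "a"), simple_stems(1, species = "b")))
  expect_equal(rarefied_richness(inv2, reps = 100, seed = 1)$median_richness,
               2)
  # empty pool: missing with reason
  inv0 <- fixture_inventory(simple_stems(1)[0, ])
  r0 <- rarefied_richness(inv0, reps = 100, seed = 1)
  expect_true(is.na(r0$median_richness))
  expect_identical(r0$missing_reason, "empty_pool")
})

test_that("equal-abundance pools match the closed-form expectation", {
  # S equally abundant species: E[unique in n draws] = S(1-(1-1/S)^n)
  stems <- tibble::tibble(species = sprintf("sp %03d", 1:50),
                          lifeform = "tree", measure_cm = 15, plot = 1L)
  inv <- fixture_inventory(stems)
  r <- rarefied_richness(inv, n_draw = 100, reps = 3000, seed = 9)
  expected <- 50 * (1 - (1 - 1 / 50)^100)
  # reconstruct the Monte-Carlo SE from the reported quantile spread
  counts_sd <- (r$q95 - r$q05) / (2 * qnorm(0.95))
  se <- counts_sd / sqrt(3000)
  expect_lt(abs(r$median_richness - expected), max(3 * se, 1))
  # sub-n pools stay computable and bounded by distinct species
  small <- fixture_inventory(tibble::tibble(
    species = rep(sprintf("s%d", 1:10), 3), lifeform = "tree",
    measure_cm = 15, plot = 1L))
  rs <- rarefied_richness(small, reps = 500, seed = 2)
  expect_lte(rs$median_richness, 10)
  expect_gte(rs$median_richness, 1)
})

test_that("adding a species never lowers expected rarefied richness", {
  base <- tibble::tibble(species = rep(c("a", "b", "c"), c(40, 30, 30)),
                         lifeform = "tree", measure_cm = 15, plot = 1L)
  extra <- dplyr::bind_rows(base, tibble::tibble(
    species = rep("d", 25), lifeform = "tree", measure_cm = 15, plot = 1L))
  r_base <- rarefied_richness(fixture_inventory(base), reps = 2000, seed = 3)
  r_extra <- rarefied_richness(fixture_inventory(extra), reps = 2000,
                               seed = 3)
  expect_gte(r_extra$median_richness, r_base$median_richness)
})

test_that("plot-subset harmonization is inert for identical plots", {
  one_plot <- tibble::tibble(
    species = rep(sprintf("sp %02d", 1:12), 3),
    lifeform = rep(c("tree", "sapling", "shrub"), each = 12),
    measure_cm = rep(c(15, 5, 4), each = 12))
  stems <- dplyr::bind_rows(lapply(1:6, function(p)
    dplyr::mutate(one_plot, plot = p)))
  inv <- fixture_inventory(stems, n_plots = 6)
  plain <- rarefied_richness(inv, reps = 1500, seed = 4)
  harm <- harmonized_richness(inv, 3, reps = 1500, seed = 4)
  expect_identical(harm$estimator, "sr100_3plot")
  expect_lt(abs(harm$median_richness - plain$median_richness), 1)
})

test_that("harmonization reports visits with too few plots as missing", {
  inv <- fixture_inventory(simple_stems(5), n_plots = 2)
  h <- harmonized_richness(inv, 3, reps = 50, seed = 1)
  expect_true(is.na(h$median_richness))
  expect_identical(h$missing_reason, "too_few_plots")
})

test_that("india-dialect harmonization uses 12 tree plots and 1 understory plot", {
  set.seed(10)
  per_plot <- function(p) tibble::tibble(
    species = c(sprintf("tree sp %d", sample(30, 4)),
                sprintf("under sp %d", sample(10, 2))),
    lifeform = c(rep("tree", 4), rep("shrub", 2)),
    measure_cm = c(runif(4, 12, 40) * pi, runif(2, 3, 8) * pi),
    plot = p)
  stems <- dplyr::bind_rows(lapply(1:20, per_plot))
  inv <- fixture_inventory(stems, n_plots = 20, dialect = "india_5m")
  h <- harmonized_richness(inv, 3, reps = 400, seed = 5)
  expect_true(is.finite(h$median_richness))
  # 4 * n_subset plots needed: 20 plots cannot support the 4-plot variant
  # (needs 16) but can support 3 (needs 12)
  inv_small <- fixture_inventory(dplyr::bind_rows(lapply(1:10, per_plot)),
                                 n_plots = 10, dialect = "india_5m")
  h2 <- harmonized_richness(inv_small, 3, reps = 50, seed = 5)
  expect_identical(h2$missing_reason, "too_few_plots")
})

test_that("reference sampling mixes one subplot of saplings per repetition", {
  # large stems: 5 species spread over subplots; small stems: 2 extra
  # species confined to subplot 1. The mean unique count must match the
  # closed-form mixture over the 10 equally likely subplot choices.
  big <- tibble::tibble(species = rep(sprintf("big %d", 1:5), each = 8),
                        lifeform = "tree", measure_cm = 30, plot = 1L,
                        subplot_index = rep(1:10, 4))
  small <- tibble::tibble(species = rep(c("tiny a", "tiny b"), each = 5),
                          lifeform = "sapling", measure_cm = 5, plot = 1L,
                          subplot_index = 1L)
  inv <- fixture_inventory(dplyr::bind_rows(big, small),
                           dialect = "gentry_reference")
  r <- reference_richness(inv, n_draw = 100, reps = 4000, seed = 6)

  # brute-force enumeration over the 10 equally likely subplot choices:
  # 9 subplots contribute a 5-species pool in which every species is
  # near-certain to appear in 100 draws (miss prob (1-8/40)^100 < 3e-8),
  # so the count is 5; subplot 1 adds both sapling-only species
  # (miss prob (1-5/50)^100 < 3e-5), giving 7. The rep distribution is
  # therefore 5 w.p. 0.9 and 7 w.p. 0.1: median and 75th percentile 5,
  # 95th percentile 7.
  expect_equal(r$median_richness, 5)
  expect_equal(r$q75, 5)
  expect_equal(r$q95, 7)

  # reference plot with only large stems reduces to plain rarefaction
  inv_big <- fixture_inventory(big, dialect = "gentry_reference")
  r_big <- reference_richness(inv_big, reps = 2000, seed = 7)
  plain <- rarefied_richness(inv_big, reps = 2000, seed = 8)
  expect_lt(abs(r_big$median_richness - plain$median_richness), 0.51)

  # all-one-species reference plot: median 1
  mono <- tibble::tibble(species = "only", lifeform = "tree",
                         measure_cm = rep(30, 10), plot = 1L,
                         subplot_index = 1:10)
  inv_mono <- fixture_inventory(mono, dialect = "gentry_reference")
  expect_equal(reference_richness(inv_mono, reps = 200,
                                  seed = 1)$median_richness, 1)

  # small stems without subplot_index are a validation error at read time
  expect_error(
    fixture_inventory(
      tibble::tibble(species = "x", lifeform = "sapling", measure_cm = 5,
                     plot = 1L, subplot_index = NA_integer_),
      dialect = "gentry_reference"),
    class = "standcompare_validation_error")
})
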