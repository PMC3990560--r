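test_that("stem basal area follows the circle-area formula", {
  expect_equal(stem_basal_area(10), 0.0078540, tolerance = 1e-5)
  expect_equal(stem_basal_area(20), 4 * stem_basal_area(10))
  # inverse: the DBH giving exactly 1 m^2
  expect_equal(stem_basal_area(112.8379), 1, tolerance = 1e-4)
  expect_error(stem_basal_area(0), class = "standcompare_domain_error")
  expect_error(stem_basal_area(-3), class = "standcompare_domain_error")
})

test_that("forest basal area scales by stratum area and excludes non-trees", {
  # one standard plot with a single 10-cm tree: 0.0078540 m^2 over
  # 0.0314159 ha = exactly 0.25 m^2/ha
  inv <- fixture_inventory(simple_stems(1, measure_cm = 10))
  ba <- forest_basal_area(inv)
  expect_equal(ba$ba_per_ha, 0.25, tolerance = 1e-12)
  expect_equal(ba$tree_component, 0.25)
  expect_equal(ba$sapling_component, 0)

  # adding lianas leaves basal area unchanged
  stems <- dplyr::bind_rows(
    simple_stems(1, measure_cm = 10),
    tibble::tibble(species = sprintf("liana %d", 1:5), lifeform = "liana",
                   measure_cm = 5, plot = 1L))
  ba2 <- forest_basal_area(fixture_inventory(stems))
  expect_equal(ba2$ba_per_ha, ba$ba_per_ha)
  expect_equal(ba2$n_stems_used, 1L)

  # zero stems: zero basal area, not an error
  inv0 <- fixture_inventory(simple_stems(1)[0, ])
  expect_equal(forest_basal_area(inv0)$ba_per_ha, 0)

  # components sum to the total
  land <- generate_landscape(landscape_spec(n_forests = 5, n_clusters = 2,
                                            seed = 8))
  bb <- forest_basal_area(generate_inventory(land, community_spec(),
                                             n_plots = 4, seed = 9))
  expect_equal(bb$ba_per_ha, bb$tree_component + bb$sapling_component,
               tolerance = 1e-9)
})

test_that("sapling stems use the understory plot area", {
  # one 5-cm sapling in the 3-m subplot: area / (pi * 9 m^2 in ha)
  inv <- fixture_inventory(
    tibble::tibble(species = "s", lifeform = "sapling", measure_cm = 5,
                   plot = 1L))
  ba <- forest_basal_area(inv)
  expect_equal(ba$sapling_component,
               stem_basal_area(5) / (pi * 9 / 1e4), tolerance = 1e-12)
  expect_equal(ba$tree_component, 0)
})

test_that("replicating plots leaves per-hectare basal area unchanged", {
  base <- tibble::tibble(
    species = c("a", "b", "c"), lifeform = c("tree", "tree", "sapling"),
    measure_cm = c(12, 30, 6), plot = 1L)
  reps <- dplyr::bind_rows(lapply(1:3, function(k)
    dplyr::mutate(base, plot = k)))
  ba1 <- forest_basal_area(fixture_inventory(base, n_plots = 1))
  ba3 <- forest_basal_area(fixture_inventory(reps, n_plots = 3))
  expect_equal(ba3$ba_per_ha, ba1$ba_per_ha, tolerance = 1e-12)
})

test_that("merging plot sets averages basal area by plot count", {
  a <- tibble::tibble(species = "a", lifeform = "tree", measure_cm = 25,
                      plot = 1L)
  b <- tibble::tibble(species = c("b", "b"), lifeform = "tree",
                      measure_cm = c(14, 18), plot = 1:2)
  ba_a <- forest_basal_area(fixture_inventory(a, n_plots = 1))$ba_per_ha
  ba_b <- forest_basal_area(fixture_inventory(b, n_plots = 2))$ba_per_ha
  merged <- dplyr::bind_rows(a, dplyr::mutate(b, plot = plot + 1L))
  ba_m <- forest_basal_area(fixture_inventory(merged, n_plots = 3))$ba_per_ha
  expect_equal(ba_m, (1 * ba_a + 2 * ba_b) / 3, tolerance = 1e-12)
})

test_that("reference-dialect basal area uses the whole 0.1 ha", {
  stems <- tibble::tibble(
    species = c("a", "b"), lifeform = c("tree", "sapling"),
    measure_cm = c(50, 5), plot = 1L, subplot_index = c(1L, 2L))
  ba <- forest_basal_area(fixture_inventory(stems,
                                            dialect = "gentry_reference"))
  expect_equal(ba$tree_component, stem_basal_area(50) / 0.1)
  expect_equal(ba$sapling_component, stem_basal_area(5) / 0.1)
})

test_that("annualized change satisfies its sign and zero properties", {
  expect_equal(annualized_change(10, 20, 2000, 2001), 1)
  expect_equal(annualized_change(10, 20, 2000, 2002, convention = "compound"),
               sqrt(2) - 1)
  # property: zero iff unchanged, sign follows the difference
  set.seed(7)
  for (i in 1:50) {
    v1 <- runif(1, 0.1, 50)
    v2 <- runif(1, 0, 50)
    y1 <- sample(1990:2000, 1)
    y2 <- y1 + sample(1:15, 1)
    for (cv in c("simple", "compound")) {
      d <- annualized_change(v1, v2, y1, y2, convention = cv)
      expect_equal(sign(d), sign(v2 - v1))
      expect_equal(annualized_change(v1, v1, y1, y2, convention = cv), 0)
    }
  }
  expect_error(annualized_change(10, 20, 2005, 2005),
               class = "standcompare_domain_error")
  expect_error(annualized_change(0, 20, 2000, 2005),
               class = "standcompare_domain_error")
})

test_that("change_over_time pairs consecutive visits per forest", {
  d <- tibble::tibble(forest_id = c("A", "A", "A", "B"),
                      visit_year = c(1995, 2000, 2010, 2001),
                      value = c(10, 20, 10, 5))
  ch <- change_over_time(d)
  expect_equal(nrow(ch), 2)  # B has a single visit
  expect_equal(ch$annualized[1], annualized_change(10, 20, 1995, 2000))
  expect_equal(ch$annualized[2], annualized_change(20, 10, 2000, 2010))
  # zero baseline flagged missing, not an error
  d0 <- tibble::tibble(forest_id = "C", visit_year = c(2000, 2005),
                       value = c(0, 3))
  ch0 <- change_over_time(d0)
  expect_true(is.na(ch0$annualized))
  expect_identical(ch0$missing_reason, "nonpositive_baseline")
})
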