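test_that("species normalization trims, collapses and case-folds", {
  expect_identical(normalize_species_label("  Cedrela  odorata "),
                   "cedrela odorata")
  expect_identical(normalize_species_label("CEDRELA ODORATA"),
                   normalize_species_label("Cedrela odorata"))
  # no fuzzy matching: different spellings stay distinct
  expect_false(normalize_species_label("Cedrella odorata") ==
                 normalize_species_label("Cedrela odorata"))
  # idempotent
  x <- c(" A  b ", "c\td", "E f")
  expect_identical(normalize_species_label(normalize_species_label(x)),
                   normalize_species_label(x))
  expect_error(normalize_species_label("   "),
               class = "standcompare_validation_error")
})

test_that("reader enforces schema and referential integrity", {
  inv <- fixture_inventory(simple_stems(3))
  expect_s3_class(inv, "forest_inventory")
  expect_equal(nrow(inv$stems), 3)

  # stem pointing at a plot absent from the plot table names the stem
  bad <- inv$stems
  bad$plot_id[2] <- "nowhere"
  expect_error(read_inventory(bad, inv$plots, inv$sites),
               regexp = "F1_T0002",
               class = "standcompare_validation_error")

  # missing column named in the error
  expect_error(read_inventory(inv$stems[-7], inv$plots, inv$sites),
               regexp = "measure_cm", class = "standcompare_schema_error")

  # unknown dialect is a config error
  p2 <- inv$plots
  p2$dialect <- "pentagon"
  expect_error(read_inventory(inv$stems, p2, inv$sites),
               class = "standcompare_config_error")

  # out-of-range coordinates rejected
  s2 <- inv$sites
  s2$latitude <- 123
  expect_error(read_inventory(inv$stems, inv$plots, s2),
               class = "standcompare_domain_error")

  # empty stem table with a valid header: no stems, no error
  empty <- inv$stems[0, ]
  inv0 <- read_inventory(empty, inv$plots, inv$sites)
  expect_equal(nrow(inv0$stems), 0)
  expect_equal(visits(inv0)$n_stems, 0L)
})

test_that("circumference dialect converts measure to DBH by pi", {
  inv <- fixture_inventory(
    simple_stems(1, measure_cm = 10 * pi), dialect = "india_5m")
  expect_equal(inv$stems$dbh, 10, tolerance = 1e-12)
  expect_identical(inv$stems$stratum, "tree")
  # hand calculation: 31.4 cm circumference -> 9.9949 cm DBH
  inv2 <- suppressWarnings(fixture_inventory(
    simple_stems(1, measure_cm = 31.4), dialect = "india_5m"))
  expect_equal(inv2$stems$dbh, 31.4 / pi, tolerance = 1e-12)
})

test_that("round-trip write/read preserves stem records", {
  land <- generate_landscape(landscape_spec(n_forests = 4, n_clusters = 2,
                                            seed = 3))
  inv <- generate_inventory(land, community_spec(), n_plots = 3, seed = 4)
  dir <- withr::local_tempdir()
  write_inventory(inv, dir)
  inv2 <- read_inventory(file.path(dir, "stems.csv"),
                         file.path(dir, "plots.csv"),
                         file.path(dir, "sites.csv"))
  cols <- c("stem_id", "plot_id", "species", "lifeform", "dbh")
  expect_equal(dplyr::arrange(inv$stems[cols], stem_id),
               dplyr::arrange(inv2$stems[cols], stem_id),
               tolerance = 1e-9)
})

test_that("stratum classification partitions valid stems", {
  # every lifeform/dbh combination lands in at most one stratum, and all
  # in-protocol stems land in exactly one
  set.seed(42)
  lifeform <- sample(c("tree", "palm", "sapling", "shrub", "liana"), 300,
                     replace = TRUE)
  dbh <- exp(runif(300, log(2.5), log(80)))
  strat <- classify_stratum(dbh, lifeform, "ifri_standard")
  expect_true(all(strat %in% c("tree", "sapling", NA)))
  in_protocol <- (lifeform %in% c("tree", "palm") & dbh >= 10) |
    (lifeform == "sapling" & dbh >= 2.5 & dbh < 10) |
    (lifeform %in% c("shrub", "liana") & dbh >= 2.5)
  expect_true(all(!is.na(strat[in_protocol])))
  expect_true(all(is.na(strat[!in_protocol])))
  # boundary: exactly 10 cm is tree stratum only
  expect_identical(classify_stratum(10, "tree", "ifri_standard"), "tree")
  expect_true(is.na(classify_stratum(10, "sapling", "ifri_standard")))
  # reference dialect: single stratum
  expect_identical(classify_stratum(c(3, 50), c("sapling", "tree"),
                                    "gentry_reference"), c("all", "all"))
})

test_that("out-of-stratum stems are flagged, kept, and excluded from structure", {
  stems <- tibble::tibble(species = c("a", "b"), lifeform = c("tree", "tree"),
                          measure_cm = c(15, 6), plot = 1L)
  expect_warning(inv <- fixture_inventory(stems), "outside")
  expect_equal(nrow(inv$stems), 2)
  expect_identical(inv$stems$exclusion_reason, c(NA, "out_of_stratum"))
  expect_identical(inv$stems$use_structure, c(TRUE, FALSE))
  expect_identical(inv$stems$use_biodiversity, c(TRUE, TRUE))
})

test_that("sanity filter flags oversize stems per scope", {
  stems <- tibble::tibble(species = c("a", "b", "c"), lifeform = "tree",
                          measure_cm = c(1837, 999, 15), plot = 1L)
  inv <- fixture_inventory(stems)
  f <- apply_sanity_filter(inv, max_dbh = 1000)
  expect_identical(sanity_report(f)$stem_id, "F1_T0001")
  expect_false(f$stems$use_structure[1])
  expect_false(f$stems$use_biodiversity[1])
  expect_true(all(f$stems$use_structure[2:3]))

  f2 <- apply_sanity_filter(inv, max_dbh = 1000, scope = "structure_only")
  expect_false(f2$stems$use_structure[1])
  expect_true(f2$stems$use_biodiversity[1])

  # Inf sentinel disables the filter
  f3 <- apply_sanity_filter(inv, max_dbh = Inf)
  expect_equal(nrow(sanity_report(f3)), 0)
  expect_true(all(f3$stems$use_structure))
})
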