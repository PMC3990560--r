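test_that("neighborhood standardization reproduces hand calculations", {
  # neighbors {0, 2} at equal distances, focal 2: mean 1, sd 1, z 1
  nb <- build_neighborhood(2, c(0, 2), c(10, 10))
  expect_equal(nb$weighted_mean, 1)
  expect_equal(nb$weighted_sd, 1)
  expect_equal(nb$z, 1)
  # all neighbors equal the focal value: z = 0 even though sd = 0
  nb0 <- build_neighborhood(5, c(5, 5, 5), c(3, 8, 12))
  expect_equal(nb0$z, 0)
  # sd = 0 with focal off the mean: missing with reason
  nbm <- build_neighborhood(6, c(5, 5), c(3, 8))
  expect_true(is.na(nbm$z))
  expect_identical(nbm$missing_reason, "zero_weighted_sd")
  # beyond the cutoff is not a neighbor
  nbc <- build_neighborhood(1, c(0, 2, 9), c(100, 200, 1500))
  expect_equal(nbc$n_neighbors, 2)
  expect_false("3" %in% nbc$neighbor_table$neighbor_id)
  # too-small neighborhood
  nb1 <- build_neighborhood(1, 5, 100, min_neighbors = 2)
  expect_identical(nb1$missing_reason, "insufficient_neighbors")
  # zero-distance candidates are excluded with a warning
  expect_warning(nbz <- build_neighborhood(1, c(4, 6, 8), c(0, 10, 20)))
  expect_equal(nbz$n_neighbors, 2)
})

test_that("weights normalize and match a from-scratch oracle", {
  # independent arithmetic oracle for <= 5 candidates
  oracle <- function(focal, v, td, cutoff) {
    keep <- td > 0 & td <= cutoff
    v <- v[keep]; td <- td[keep]
    w_raw <- 1 / td^2
    w <- w_raw / sum(w_raw)
    m <- 0; for (i in seq_along(v)) m <- m + w[i] * v[i]
    s2 <- 0; for (i in seq_along(v)) s2 <- s2 + w[i] * (v[i] - m)^2
    list(mean = m, sd = sqrt(s2), z = (focal - m) / sqrt(s2))
  }
  set.seed(11)
  for (i in 1:30) {
    k <- sample(2:5, 1)
    v <- rnorm(k, 10, 4)
    td <- runif(k, 1, 900)
    focal <- rnorm(1, 10, 4)
    nb <- build_neighborhood(focal, v, td)
    o <- oracle(focal, v, td, 1000)
    expect_equal(sum(nb$neighbor_table$weight), 1, tolerance = 1e-12)
    expect_equal(nb$weighted_mean, o$mean, tolerance = 1e-10)
    expect_equal(nb$weighted_sd, o$sd, tolerance = 1e-10)
    expect_equal(nb$z, o$z, tolerance = 1e-10)
  }
})

test_that("z-scores are location- and scale-equivariant", {
  set.seed(12)
  for (i in 1:20) {
    v <- rnorm(6); td <- runif(6, 10, 800); focal <- rnorm(1)
    a <- runif(1, -50, 50); k <- runif(1, 0.1, 20)
    z0 <- build_neighborhood(focal, v, td)$z
    expect_equal(build_neighborhood(focal + a, v + a, td)$z, z0,
                 tolerance = 1e-9)
    expect_equal(build_neighborhood(focal * k, v * k, td)$z, z0,
                 tolerance = 1e-9)
  }
})

test_that("batch intercomparison respects clusters and self-exclusion", {
  # two clusters separated far beyond the cutoff
  sites <- dplyr::bind_rows(grid_sites(4, lat0 = 5),
                            grid_sites(4, lat0 = 45))
  sites$site_id <- sprintf("S%03d", 1:8)
  tab <- tibble::tibble(forest_id = sprintf("F%d", 1:8),
                        site_id = sites$site_id,
                        value = c(1, 2, 3, 4, 101, 102, 103, 104))
  ic <- intercompare(tab, sites)
  expect_s3_class(ic, "sc_intercomparison")
  expect_equal(ic$n_neighbors, rep(3L, 8))  # own cluster only, minus self
  # neighborhood means stay within each cluster's value range
  expect_true(all(ic$weighted_mean[1:4] < 10))
  expect_true(all(ic$weighted_mean[5:8] > 100))

  # duplicated forest-visits rejected
  expect_error(intercompare(dplyr::bind_rows(tab, tab[1, ]), sites),
               class = "standcompare_validation_error")
  # reference mode needs a reference table
  expect_error(intercompare(tab, sites, mode = "reference"),
               class = "standcompare_config_error")
})

test_that("only a forest's latest visit enters the candidate pool", {
  sites <- grid_sites(3)
  tab <- tibble::tibble(
    forest_id = c("A", "A", "B", "C"),
    visit_year = c(2000, 2010, 2005, 2005),
    site_id = c("S001", "S001", "S002", "S003"),
    value = c(100, 10, 10, 10))
  ic <- intercompare(tab, sites, min_neighbors = 2)
  # B's neighborhood uses A's 2010 value (10), not the 2000 one (100)
  b <- ic[ic$forest_id == "B", ]
  expect_equal(b$weighted_mean, 10)
  # A's own visits are excluded from A's neighborhoods entirely
  a <- ic[ic$forest_id == "A" & ic$visit_year == 2000, ]
  expect_equal(a$n_neighbors, 2L)
})

test_that("null landscapes give approximately standard-normal z", {
  set.seed(99)
  n <- 200
  sites <- tibble::tibble(site_id = sprintf("S%03d", 1:n),
                          latitude = rnorm(n, 10, 0.5),
                          longitude = rnorm(n, 20, 0.5),
                          elevation_m = runif(n, 500, 700))
  tab <- tibble::tibble(forest_id = sites$site_id, site_id = sites$site_id,
                        value = rnorm(n))
  ic <- intercompare(tab, sites)
  expect_true(all(is.finite(ic$z)))
  expect_lt(abs(mean(ic$z)), 0.15)
  expect_gt(sd(ic$z), 0.8)
  expect_lt(sd(ic$z), 1.3)
})

test_that("reference-mode standardization uses the reference pool", {
  sites <- grid_sites(3)
  ref_sites <- grid_sites(2, lat0 = 5.002)
  ref_sites$site_id <- c("R001", "R002")
  tab <- tibble::tibble(forest_id = c("A", "B", "C"),
                        site_id = sites$site_id, value = c(5, 10, 15))
  ref <- tibble::tibble(forest_id = c("G1", "G2"),
                        site_id = ref_sites$site_id, value = c(20, 30))
  ic <- intercompare(tab, dplyr::bind_rows(sites, ref_sites),
                     mode = "reference", reference_table = ref)
  expect_equal(ic$n_neighbors, rep(2L, 3))
  expect_true(all(ic$z < 0))  # all focals sit below the reference mean
})
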