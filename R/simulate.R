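#' Specify a synthetic landscape
#'
#' Parameters for a synthetic set of forest sites with known ground truth,
#' emulating the spatial structure of multi-country forest-monitoring
#' databases: sites clustered in a few regions separated by thousands of
#' km, smooth latitudinal gradients in stem density and species-pool size,
#' and an independent per-forest "condition" deviation (`true_effect`) that
#' the regional-intercomparison z-score should recover.
#'
#' @param n_forests Number of forests/sites (default 100).
#' @param n_clusters Number of spatial clusters (default 5), placed with
#'   widely separated longitudes so cross-cluster pairs exceed any
#'   plausible neighborhood cutoff.
#' @param cluster_spread_km Within-cluster spatial SD in km (default 50).
#' @param elevation_range_m Range cluster base elevations are drawn from
#'   (default c(200, 2000)).
#' @param elevation_spread_m Within-cluster elevation SD in m (default 150).
#' @param effect_sd SD of the latent per-forest condition effect on the
#'   log scale (default 0.4): a forest's stem density is multiplied by
#'   `exp(effect)` and its species pool by `exp(0.5 * effect)`.
#' @param density_gradient,richness_gradient Strength of the regional
#'   fields multiplying stem density and species-pool size (defaults 0.7
#'   and 1.0). Each field is a smooth latitudinal trend times a
#'   cluster-level biome factor, lognormal with this SD on the log scale —
#'   biomes differ several-fold in density and richness, while forests
#'   within a cluster share almost the same field value.
#' @param visit_year Census year stamped on generated visits (default 2005).
#' @param seed Integer seed.
#' @return A list of class `landscape_spec`.
#' @export
landscape_spec <- function(n_forests = 100, n_clusters = 5,
                           cluster_spread_km = 50,
                           elevation_range_m = c(200, 2000),
                           elevation_spread_m = 150,
                           effect_sd = 0.4, density_gradient = 0.7,
                           richness_gradient = 1.0, visit_year = 2005,
                           seed = 1) {
  if (!(n_forests >= n_clusters && n_clusters >= 1)) {
    abort("need n_forests >= n_clusters >= 1",
          class = "standcompare_validation_error")
  }
  if (cluster_spread_km <= 0 || elevation_spread_m < 0 || effect_sd < 0) {
    abort("landscape scales must be positive",
          class = "standcompare_validation_error")
  }
  structure(as.list(environment()), class = "landscape_spec")
}

#' Specify a synthetic stem community
#'
#' Test-scaffolding generative model for stems within plots: species drawn
#' from a log-series abundance distribution (`p_k` proportional to
#' `x^k / k`) over a finite pool, per-plot stem counts Poisson, and DBH
#' from truncated exponentials per stratum. Not a calibrated ecological
#' simulator — no climate, soil or succession dynamics — but it produces
#' the skewed abundances and size distributions that make rarefaction and
#' basal-area estimates behave as they do on real inventories.
#'
#' @param species_pool Baseline species-pool size (default 120).
#' @param logseries_x Log-series parameter in (0, 1) (default 0.98;
#'   closer to 1 means more even abundances).
#' @param tree_stratum_density Expected tree/palm stems per standard
#'   (pi x 10^2 m^2) tree plot (default 15); rescaled by plot area for
#'   other dialects.
#' @param sapling_stratum_density Expected understory stems per standard
#'   (pi x 3^2 m^2) subplot (default 8).
#' @param lifeform_mix Named proportions over tree, palm, sapling, shrub,
#'   liana; must sum to 1.
#' @param tree_dbh_scale Mean DBH excess over 10 cm for tree-stratum stems
#'   (exponential, default 10 cm).
#' @param sapling_dbh_scale Scale of the truncated-exponential understory
#'   DBH distribution on \[2.5, 10) cm (default 2.5 cm).
#' @return A list of class `community_spec`.
#' @export
community_spec <- function(species_pool = 120, logseries_x = 0.98,
                           tree_stratum_density = 15,
                           sapling_stratum_density = 8,
                           lifeform_mix = c(tree = 0.50, palm = 0.05,
                                            sapling = 0.25, shrub = 0.12,
                                            liana = 0.08),
                           tree_dbh_scale = 10, sapling_dbh_scale = 2.5) {
  if (abs(sum(lifeform_mix) - 1) > 1e-8 ||
      !setequal(names(lifeform_mix), lifeform_levels())) {
    abort("lifeform_mix must be named over all five lifeforms and sum to 1",
          class = "standcompare_validation_error")
  }
  if (species_pool < 1 || logseries_x <= 0 || logseries_x >= 1 ||
      tree_stratum_density <= 0 || sapling_stratum_density <= 0 ||
      tree_dbh_scale <= 0 || sapling_dbh_scale <= 0) {
    abort("community rates must be positive (and 0 < logseries_x < 1)",
          class = "standcompare_validation_error")
  }
  structure(as.list(environment()), class = "community_spec")
}

#' Generate a clustered synthetic landscape
#'
#' @param spec A [landscape_spec()].
#' @return A tibble with one row per forest: `forest_id`, `site_id`,
#'   `latitude`, `longitude`, `elevation_m`, `cluster`, `density_field`
#'   and `richness_field` (the regional multipliers at that location), and
#'   `true_effect` (the latent condition deviation to be recovered by
#'   intercomparison). The spec is attached as attribute `"spec"`.
#'   Deterministic given `spec$seed`.
#' @export
generate_landscape <- function(spec) {
  stopifnot(inherits(spec, "landscape_spec"))
  with_seed(spec$seed, {
    k <- spec$n_clusters
    centers <- tibble::tibble(
      cluster = seq_len(k),
      lat = runif(k, -30, 40),
      lon = -180 + 360 * (seq_len(k) - 0.5) / k + runif(k, -10, 10),
      elev = runif(k, spec$elevation_range_m[1], spec$elevation_range_m[2]))
    assign <- sort(rep_len(seq_len(k), spec$n_forests))
    lat_sd <- spec$cluster_spread_km / 111.19
    lat <- centers$lat[assign] + rnorm(spec$n_forests, 0, lat_sd)
    lon_sd <- spec$cluster_spread_km /
      (111.19 * pmax(0.2, cos(centers$lat[assign] * pi / 180)))
    lon <- centers$lon[assign] + rnorm(spec$n_forests, 0, lon_sd)
    elev <- pmax(0, centers$elev[assign] +
                   rnorm(spec$n_forests, 0, spec$elevation_spread_m))
    # regional fields: cluster-level biome factor (lognormal) times a
    # smooth latitudinal trend — density/diversity decline away from the
    # tropics, and biomes differ several-fold
    biome_density <- exp(rnorm(k, 0, spec$density_gradient))
    biome_richness <- exp(rnorm(k, 0, spec$richness_gradient))
    latm <- pmin(89, pmax(-89, lat))
    trend <- cos(latm * pi / 180) - 0.5
    out <- tibble::tibble(
      forest_id = sprintf("F%03d", seq_len(spec$n_forests)),
      site_id = sprintf("S%03d", seq_len(spec$n_forests)),
      latitude = latm,
      longitude = ((lon + 180) %% 360) - 180,
      elevation_m = elev,
      cluster = assign,
      density_field = biome_density[assign] *
        exp(spec$density_gradient * trend),
      richness_field = biome_richness[assign] *
        exp(spec$richness_gradient * trend),
      true_effect = rnorm(spec$n_forests, 0, spec$effect_sd))
    attr(out, "spec") <- spec
    out
  })
}

empty_stem_table <- function() {
  tibble::tibble(stem_id = character(), plot_id = character(),
                 forest_id = character(), visit_year = integer(),
                 species = character(), lifeform = character(),
                 measure_cm = double(), subplot_index = integer())
}

logseries_probs <- function(s, x) {
  k <- seq_len(s)
  p <- x^k / k
  p / sum(p)
}

draw_dbh <- function(n, stratum, community) {
  if (stratum == "tree") {
    10 + rexp(n, rate = 1 / community$tree_dbh_scale)
  } else {
    # truncated exponential on [2.5, 10)
    sc <- community$sapling_dbh_scale
    u <- runif(n)
    2.5 - sc * log(1 - u * (1 - exp(-7.5 / sc)))
  }
}

draw_lifeforms <- function(n, stratum, mix) {
  if (n == 0) return(character(0))
  pool <- if (stratum == "tree") c("tree", "palm") else
    c("sapling", "shrub", "liana")
  p <- mix[pool] / sum(mix[pool])
  sample(pool, n, replace = TRUE, prob = p)
}

#' Generate the stems and plots of one forest-visit
#'
#' Draws a plot-based census of a synthetic community following the
#' stratum rules of the chosen dialect: tree/palm stems >= 10 cm DBH in
#' the tree stratum, saplings 2.5-10 cm plus shrubs/lianas in the
#' understory stratum, per-plot counts Poisson with area-scaled rates.
#' The latent `effect` multiplies stem density by `exp(effect)` and the
#' species pool by `exp(0.5 * effect)`, so downstream intercomparison
#' z-scores have known sign and ranking.
#'
#' @param site One-row site tibble (`forest_id`, `site_id`, coordinates).
#' @param community A [community_spec()].
#' @param n_plots Number of plots (default 10).
#' @param dialect Census dialect (default `"ifri_standard"`).
#' @param effect Latent condition deviation (default 0).
#' @param density_mult,pool_mult Extra multiplicative modifiers (regional
#'   fields), default 1.
#' @param visit_year Census year.
#' @param seed Integer seed.
#' @return A list with tibbles `plots` and `stems` in the raw CSV schema.
#' @export
generate_visit <- function(site, community, n_plots = 10,
                           dialect = c("ifri_standard", "india_5m"),
                           effect = 0, density_mult = 1, pool_mult = 1,
                           visit_year = 2005, seed = 1) {
  dialect <- match.arg(dialect)
  stopifnot(inherits(community, "community_spec"))
  geom <- plot_geometry(dialect)
  std <- plot_geometry("ifri_standard")
  lambda_tree <- community$tree_stratum_density *
    geom$tree_area_m2 / std$tree_area_m2 * density_mult * exp(effect)
  lambda_sap <- community$sapling_stratum_density *
    geom$sapling_area_m2 / std$sapling_area_m2 * density_mult * exp(effect)
  # a stratum with no lifeform mass produces no stems
  if (sum(community$lifeform_mix[c("tree", "palm")]) == 0) lambda_tree <- 0
  if (sum(community$lifeform_mix[c("sapling", "shrub", "liana")]) == 0) {
    lambda_sap <- 0
  }
  s_pool <- max(5L, as.integer(round(
    community$species_pool * pool_mult * exp(0.5 * effect))))
  sp_prob <- logseries_probs(s_pool, community$logseries_x)
  circumference <- geom$size_measure == "circumference"

  with_seed(seed, {
    plots <- tibble::tibble(
      plot_id = sprintf("%s_%d_P%03d", site$forest_id, visit_year,
                        seq_len(n_plots)),
      forest_id = site$forest_id, visit_year = visit_year,
      dialect = dialect, site_id = site$site_id)
    stems_by_plot <- lapply(seq_len(n_plots), function(p) {
      n_t <- rpois(1, lambda_tree)
      n_s <- rpois(1, lambda_sap)
      dbh <- c(draw_dbh(n_t, "tree", community),
               draw_dbh(n_s, "sapling", community))
      lf <- c(draw_lifeforms(n_t, "tree", community$lifeform_mix),
              draw_lifeforms(n_s, "sapling", community$lifeform_mix))
      n <- n_t + n_s
      if (n == 0) return(NULL)
      tibble::tibble(
        plot_id = plots$plot_id[p],
        species = sprintf("species %04d",
                          sample.int(s_pool, n, replace = TRUE,
                                     prob = sp_prob)),
        lifeform = lf,
        measure_cm = if (circumference) dbh * pi else dbh,
        subplot_index = NA_integer_)
    })
    stems <- dplyr::bind_rows(stems_by_plot)
    if (nrow(stems) == 0) stems <- empty_stem_table()
    if (nrow(stems) > 0) {
      stems <- dplyr::mutate(
        stems,
        stem_id = sprintf("%s_%d_T%05d", site$forest_id, visit_year,
                          dplyr::row_number()),
        forest_id = site$forest_id, visit_year = visit_year,
        .before = 1)
      stems <- stems[c("stem_id", "plot_id", "forest_id", "visit_year",
                       "species", "lifeform", "measure_cm",
                       "subplot_index")]
    }
    list(plots = plots, stems = stems)
  })
}

#' Generate a full inventory for a landscape
#'
#' One visit per landscape forest, with the landscape's latitudinal fields
#' and each forest's `true_effect` applied. Returns a validated
#' [read_inventory()] object ready for every downstream metric.
#'
#' @param landscape Output of [generate_landscape()].
#' @param community A [community_spec()].
#' @param n_plots Plots per forest (default 10).
#' @param dialect Census dialect for all forests.
#' @param seed Integer seed.
#' @return A `forest_inventory`.
#' @export
generate_inventory <- function(landscape, community, n_plots = 10,
                               dialect = "ifri_standard", seed = 1) {
  spec <- attr(landscape, "spec") %||% landscape_spec()
  seeds <- rep_seeds(seed, nrow(landscape))
  parts <- lapply(seq_len(nrow(landscape)), function(i) {
    generate_visit(landscape[i, ], community, n_plots = n_plots,
                   dialect = dialect, effect = landscape$true_effect[i],
                   density_mult = landscape$density_field[i],
                   pool_mult = landscape$richness_field[i],
                   visit_year = spec$visit_year, seed = seeds[i])
  })
  sites <- landscape[c("site_id", "latitude", "longitude", "elevation_m")]
  read_inventory(stems = dplyr::bind_rows(lapply(parts, `[[`, "stems")),
                 plots = dplyr::bind_rows(lapply(parts, `[[`, "plots")),
                 sites = sites)
}

#' Generate one old-growth reference plot
#'
#' A 0.1-ha reference transect plot: 10 subplots of 100 m^2, every stem
#' >= 2.5 cm DBH measured and tagged with its subplot. `uplift` makes the
#' reference an old-growth analogue of the focal community: stem density
#' is multiplied by `exp(uplift)`, the tree DBH scale by
#' `1 + 0.5 * uplift`, and the species pool by `exp(0.5 * uplift)`.
#'
#' @param community A [community_spec()].
#' @param uplift Old-growth uplift on the log scale (default 0.5; 0 means
#'   drawn from the same distribution as the focal forests).
#' @param forest_id,site_id Identifiers for the generated plot.
#' @param density_mult,pool_mult Regional-field modifiers, as in
#'   [generate_visit()].
#' @param visit_year Census year.
#' @param seed Integer seed.
#' @return A list with tibbles `plots` (a single plot) and `stems`.
#' @export
generate_reference_plot <- function(community, uplift = 0.5,
                                    forest_id = "REF001",
                                    site_id = "RS001", density_mult = 1,
                                    pool_mult = 1, visit_year = 2000,
                                    seed = 1) {
  stopifnot(inherits(community, "community_spec"))
  std <- plot_geometry("ifri_standard")
  geom <- plot_geometry("gentry_reference")
  lambda_big <- community$tree_stratum_density * exp(uplift) * density_mult *
    geom$subplot_area_m2 / std$tree_area_m2
  lambda_small <- community$sapling_stratum_density * exp(uplift) *
    density_mult * geom$subplot_area_m2 / std$sapling_area_m2
  s_pool <- max(5L, as.integer(round(
    community$species_pool * pool_mult * exp(0.5 * uplift))))
  sp_prob <- logseries_probs(s_pool, community$logseries_x)
  big_scale <- community$tree_dbh_scale * (1 + 0.5 * uplift)

  with_seed(seed, {
    rows <- lapply(1:10, function(sub) {
      n_b <- rpois(1, lambda_big)
      n_s <- rpois(1, lambda_small)
      dbh <- c(10 + rexp(n_b, rate = 1 / big_scale),
               draw_dbh(n_s, "sapling", community))
      lf <- c(draw_lifeforms(n_b, "tree", community$lifeform_mix),
              draw_lifeforms(n_s, "sapling", community$lifeform_mix))
      if (n_b + n_s == 0) return(NULL)
      tibble::tibble(species = sprintf("species %04d",
                                       sample.int(s_pool, n_b + n_s,
                                                  replace = TRUE,
                                                  prob = sp_prob)),
                     lifeform = lf, measure_cm = dbh,
                     subplot_index = sub)
    })
    stems <- dplyr::bind_rows(rows)
    if (nrow(stems) == 0) stems <- empty_stem_table()
    plot_id <- sprintf("%s_%d_G01", forest_id, visit_year)
    if (nrow(stems) > 0) {
      stems <- dplyr::mutate(
        stems,
        stem_id = sprintf("%s_%d_T%05d", forest_id, visit_year,
                          dplyr::row_number()),
        plot_id = plot_id, forest_id = forest_id, visit_year = visit_year,
        .before = 1)
      stems <- stems[c("stem_id", "plot_id", "forest_id", "visit_year",
                       "species", "lifeform", "measure_cm",
                       "subplot_index")]
    }
    plots <- tibble::tibble(plot_id = plot_id, forest_id = forest_id,
                            visit_year = visit_year,
                            dialect = "gentry_reference",
                            site_id = site_id)
    list(plots = plots, stems = stems)
  })
}

#' Generate a set of reference plots near a landscape's clusters
#'
#' Reference sites are placed by jittering randomly chosen focal sites by
#' about `jitter_km`, so every cluster has nearby old-growth analogues;
#' each gets one 0.1-ha reference plot via [generate_reference_plot()],
#' with the landscape's regional fields applied at the reference location.
#'
#' @param landscape Output of [generate_landscape()].
#' @param community A [community_spec()].
#' @param n_reference Number of reference plots (default 10).
#' @param uplift Old-growth uplift (see [generate_reference_plot()]).
#' @param jitter_km Spatial jitter of reference sites (default 30 km).
#' @param seed Integer seed.
#' @return A `forest_inventory` in the reference dialect (own sites).
#' @export
generate_reference_set <- function(landscape, community, n_reference = 10,
                                   uplift = 0.5, jitter_km = 30, seed = 1) {
  sites <- with_seed(seed, {
    anchor <- landscape[sample.int(nrow(landscape), n_reference,
                                   replace = n_reference > nrow(landscape)), ]
    tibble::tibble(
      forest_id = sprintf("REF%03d", seq_len(n_reference)),
      site_id = sprintf("RS%03d", seq_len(n_reference)),
      latitude = pmin(89, pmax(-89, anchor$latitude +
                                 rnorm(n_reference, 0, jitter_km / 111.19))),
      longitude = anchor$longitude + rnorm(n_reference, 0, jitter_km / 111.19),
      elevation_m = pmax(0, anchor$elevation_m + rnorm(n_reference, 0, 50)),
      density_field = anchor$density_field,
      richness_field = anchor$richness_field)
  })
  seeds <- rep_seeds(seed + 1L, n_reference)
  parts <- lapply(seq_len(n_reference), function(i) {
    generate_reference_plot(community, uplift = uplift,
                            forest_id = sites$forest_id[i],
                            site_id = sites$site_id[i],
                            density_mult = sites$density_field[i],
                            pool_mult = sites$richness_field[i],
                            seed = seeds[i])
  })
  read_inventory(stems = dplyr::bind_rows(lapply(parts, `[[`, "stems")),
                 plots = dplyr::bind_rows(lapply(parts, `[[`, "plots")),
                 sites = sites[c("site_id", "latitude", "longitude",
                                 "elevation_m")])
}

#' Generate ordinal ratings correlated with a latent condition
#'
#' Emulates user and forester questionnaire answers: each forest's four
#' ordinal codes are produced by thresholding a latent score
#' `condition_weight * effect + halo * shared + noise * independent`,
#' where `shared` is one draw per forest common to all four variables (the
#' rater's overall impression) and `independent` is drawn per variable.
#' `halo = 1, noise = 0` makes a rater's answers to different questions
#' identical; `halo = 0` leaves variables related only through the true
#' condition. User variables are cut at sample tertiles into codes
#' -1/0/1, forester variables at sample quintiles into -2..2.
#'
#' @param effects A data frame with `forest_id` and `true_effect` (e.g. a
#'   landscape), or a numeric vector of effects.
#' @param halo Weight of the shared rater component in \[0, 1\].
#' @param noise SD of the per-variable independent component.
#' @param condition_weight Weight of the true condition (default 1).
#' @param visit_year Year stamped on the ratings.
#' @param seed Integer seed.
#' @return A tibble: `forest_id`, `visit_year`, `variable`, `code`.
#' @export
generate_ratings <- function(effects, halo = 0.6, noise = 0.8,
                             condition_weight = 1, visit_year = 2005,
                             seed = 1) {
  if (is.numeric(effects)) {
    effects <- tibble::tibble(
      forest_id = sprintf("F%03d", seq_along(effects)),
      true_effect = effects)
  }
  stopifnot(halo >= 0, halo <= 1, noise >= 0)
  n <- nrow(effects)
  with_seed(seed, {
    shared <- rnorm(n)
    eff <- as.numeric(scale(effects$true_effect))
    if (any(!is.finite(eff))) eff <- rep(0, n)  # zero-variance effects
    latent <- function() {
      condition_weight * eff + halo * shared + noise * rnorm(n)
    }
    cut_codes <- function(l, codes) {
      qs <- quantile(l, probs = seq_len(length(codes) - 1) / length(codes),
                     names = FALSE)
      codes[findInterval(l, qs, left.open = TRUE) + 1L]
    }
    vars <- list(delta_density_user = -1:1, delta_area_user = -1:1,
                 density_forester = -2:2, diversity_forester = -2:2)
    purrr::imap_dfr(vars, function(codes, nm) {
      tibble::tibble(forest_id = effects$forest_id,
                     visit_year = visit_year, variable = nm,
                     code = cut_codes(latent(), codes))
    })
  })
}
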