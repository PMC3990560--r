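#' Run the full comparison pipeline
#'
#' Ties the stages together behind one reproducible entry point, as used
#' by the `standcompare` command-line script (installed under
#' `inst/scripts`). A run is driven by a config — a YAML file or an
#' equivalent nested list — validated up front and echoed into the output
#' directory alongside a metadata sidecar (package version, seed,
#' timestamp), so two runs with the same config and inputs produce
#' identical data files.
#'
#' Config layout (all `params` optional, defaults shown):
#' ```yaml
#' inputs:
#'   stems: stems.csv        # focal inventory
#'   plots: plots.csv
#'   sites: sites.csv
#'   ratings: ratings.csv    # optional, for the stats stage
#'   ref_stems: ...          # optional reference inventory (gentry dialect)
#'   ref_plots: ...
#'   ref_sites: ...
#' params:
#'   seed: 1
#'   n_draw: 100
#'   reps: 1000
#'   cutoff: 1000
#'   min_neighbors: 2
#'   convention: simple      # or compound
#'   max_dbh: 1000
#'   sanity_filter_scope: all
#' output_dir: out
#' ```
#'
#' @param config Path to a YAML config or a list.
#' @param stage One of `"validate"`, `"structure"`, `"richness"`,
#'   `"change"`, `"intercompare"`, `"stats"`, `"all"`.
#' @param mode Neighborhood mode for the intercompare stage.
#' @return Invisibly, a named list of output file paths.
#' @export
run_pipeline <- function(config,
                         stage = c("all", "validate", "structure",
                                   "richness", "change", "intercompare",
                                   "stats"),
                         mode = c("regional", "reference")) {
  stage <- match.arg(stage)
  mode <- match.arg(mode)
  cfg <- load_config(config)
  p <- cfg$params
  out_dir <- cfg$output_dir
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)

  log_line("reading inventory from %s", cfg$inputs$stems)
  inv <- read_inventory(cfg$inputs$stems, cfg$inputs$plots, cfg$inputs$sites)
  inv <- apply_sanity_filter(inv, p$max_dbh, p$sanity_filter_scope)
  v <- visits(inv)
  log_line("read %d stems in %d forest-visit(s); %d flagged",
           nrow(inv$stems), nrow(v),
           sum(!is.na(inv$stems$exclusion_reason)))
  if (stage == "validate") {
    n_bad <- sum(!is.na(inv$stems$exclusion_reason))
    if (n_bad > 0) {
      bad <- inv$stems$stem_id[!is.na(inv$stems$exclusion_reason)]
      abort(sprintf("validate: %d flagged stem(s): %s", n_bad,
                    paste(utils::head(bad, 20), collapse = ", ")),
            class = "standcompare_validation_error")
    }
    log_line("validate: clean")
    return(invisible(list()))
  }

  ref_inv <- NULL
  if (!is.null(cfg$inputs$ref_stems)) {
    ref_inv <- read_inventory(cfg$inputs$ref_stems, cfg$inputs$ref_plots,
                              cfg$inputs$ref_sites)
  }
  if (stage == "intercompare" && mode == "reference" && is.null(ref_inv)) {
    abort("intercompare --mode reference needs ref_stems/ref_plots/ref_sites",
          class = "standcompare_config_error")
  }

  paths <- list()
  emit <- function(df, name) {
    path <- file.path(out_dir, name)
    readr::write_csv(df, path)
    log_line("wrote %s (%d rows)", path, nrow(df))
    paths[[name]] <<- path
  }

  ba <- sr <- NULL
  if (stage %in% c("all", "structure", "change", "intercompare", "stats")) {
    ba <- forest_basal_area(inv)
    if (stage %in% c("all", "structure")) emit(ba, "basal_area.csv")
  }
  if (stage %in% c("all", "richness", "change", "intercompare", "stats")) {
    sr <- rarefied_richness(inv, n_draw = p$n_draw, reps = p$reps,
                            seed = p$seed)
    if (stage %in% c("all", "richness")) {
      harm <- harmonized_richness(inv, n_plots_subset = 3,
                                  n_draw = p$n_draw, reps = p$reps,
                                  seed = p$seed)
      rich <- dplyr::bind_rows(sr, harm)
      if (!is.null(ref_inv)) {
        rich <- dplyr::bind_rows(rich, reference_richness(
          ref_inv, n_draw = p$n_draw, reps = p$reps, seed = p$seed))
      }
      emit(rich, "richness.csv")
    }
  }
  if (stage %in% c("all", "change", "stats")) {
    ch <- dplyr::bind_rows(
      change_over_time(dplyr::rename(ba, value = "ba_per_ha"),
                       metric = "BA", convention = p$convention),
      change_over_time(dplyr::rename(sr, value = "median_richness"),
                       metric = "SR", convention = p$convention))
    if (stage %in% c("all", "change")) emit(ch, "change.csv")
  }
  ic <- NULL
  if (stage %in% c("all", "intercompare", "stats")) {
    key <- v[c("forest_id", "visit_year", "site_id")]
    ba_tab <- dplyr::inner_join(key, ba, by = c("forest_id", "visit_year")) |>
      dplyr::mutate(value = .data$ba_per_ha)
    sr_tab <- dplyr::inner_join(key, sr, by = c("forest_id", "visit_year")) |>
      dplyr::mutate(value = .data$median_richness)
    run_ic <- function(tab, metric, md) {
      ref_tab <- NULL
      if (md == "reference") {
        rv <- visits(ref_inv)[c("forest_id", "site_id")]
        ref_tab <- if (metric == "BA") {
          dplyr::inner_join(rv, forest_basal_area(ref_inv),
                            by = "forest_id") |>
            dplyr::mutate(value = .data$ba_per_ha)
        } else {
          dplyr::inner_join(rv, reference_richness(
            ref_inv, n_draw = p$n_draw, reps = p$reps, seed = p$seed),
            by = "forest_id") |>
            dplyr::mutate(value = .data$median_richness)
        }
      }
      sites <- dplyr::bind_rows(inv$sites,
                                if (md == "reference") ref_inv$sites)
      focal <- tab
      if (md == "reference" && metric == "SR") {
        harm3 <- harmonized_richness(inv, 3, p$n_draw, p$reps, p$seed)
        focal <- dplyr::inner_join(
          key, harm3, by = c("forest_id", "visit_year")) |>
          dplyr::mutate(value = .data$median_richness)
      }
      intercompare(focal[c("forest_id", "visit_year", "site_id", "value")],
                   sites, mode = md, reference_table = ref_tab,
                   metric = metric, cutoff = p$cutoff,
                   min_neighbors = p$min_neighbors)
    }
    modes <- if (stage %in% c("all", "stats")) {
      c("regional", if (!is.null(ref_inv)) "reference")
    } else {
      mode
    }
    ic <- dplyr::bind_rows(lapply(modes, function(md) {
      dplyr::bind_rows(run_ic(ba_tab, "BA", md), run_ic(sr_tab, "SR", md))
    }))
    if (stage %in% c("all", "intercompare")) emit(ic, "intercomparison.csv")
  }
  if (stage %in% c("all", "stats") && !is.null(cfg$inputs$ratings)) {
    st <- stats_stage(cfg$inputs$ratings, ic, ch, p)
    emit(st$fits, "fits.csv")
    emit(st$anova, "anova.csv")
  }

  meta <- list(package = "standcompare",
               version = as.character(packageVersion("standcompare")),
               seed = p$seed, stage = stage, config = cfg,
               timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"))
  jsonlite::write_json(meta, file.path(out_dir, "run_metadata.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(paths)
}

# pairwise model II fits among continuous metrics and ANOVAs of metrics
# across rating codes
stats_stage <- function(ratings_path, ic, ch, p) {
  ratings <- read_table_checked(ratings_path, "ratings",
    c("forest_id", "visit_year", "variable", "code"))
  zw <- ic |>
    dplyr::filter(is.finite(.data$z)) |>
    dplyr::mutate(var = paste(.data$metric, .data$mode, sep = "_")) |>
    dplyr::select("forest_id", "var", "z") |>
    tidyr::pivot_wider(names_from = "var", values_from = "z",
                       values_fn = dplyr::first)
  chw <- ch |>
    dplyr::filter(is.finite(.data$annualized)) |>
    dplyr::group_by(.data$forest_id, .data$metric) |>
    dplyr::summarise(annualized = dplyr::last(.data$annualized),
                     .groups = "drop") |>
    tidyr::pivot_wider(names_from = "metric", values_from = "annualized",
                       names_prefix = "delta_")
  cont <- dplyr::full_join(zw, chw, by = "forest_id")
  vars <- setdiff(names(cont), "forest_id")
  combos <- if (length(vars) >= 2) utils::combn(vars, 2, simplify = FALSE)
            else list()
  fits <- purrr::map_dfr(combos, function(pr) {
    d <- cont[is.finite(cont[[pr[1]]]) & is.finite(cont[[pr[2]]]), ]
    if (nrow(d) < 3 || var(d[[pr[1]]]) == 0 || var(d[[pr[2]]]) == 0) {
      return(NULL)
    }
    f <- major_axis_fit(d, !!rlang::sym(pr[1]), !!rlang::sym(pr[2]),
                        seed = p$seed)
    tibble::tibble(pair = paste(pr, collapse = " vs "), slope = f$slope,
                   intercept = f$intercept, r2 = f$r_squared,
                   p = f$p_value, n = f$n)
  })
  rt <- ratings |>
    dplyr::select("forest_id", "variable", "code") |>
    tidyr::pivot_wider(names_from = "variable", values_from = "code",
                       values_fn = dplyr::first)
  both <- dplyr::full_join(cont, rt, by = "forest_id")
  rat_vars <- intersect(names(rating_vocabularies()), names(both))
  anova_rows <- purrr::map_dfr(rat_vars, function(rv) {
    purrr::map_dfr(vars, function(cv) {
      d <- both[is.finite(both[[cv]]) & !is.na(both[[rv]]), ]
      res <- tryCatch(
        suppressWarnings(anova_ordinal(d, !!rlang::sym(cv),
                                       !!rlang::sym(rv))),
        error = function(e) NULL)
      if (is.null(res)) return(NULL)
      tibble::tibble(rating = rv, metric = cv,
                     f = res$f_statistic, p = res$p_value,
                     letters = paste(sprintf("%s:%s", res$groups$code,
                                             res$groups$letters),
                                     collapse = " "))
    })
  })
  list(fits = fits, anova = anova_rows)
}

load_config <- function(config) {
  if (is.character(config) && length(config) == 1L) {
    if (!file.exists(config)) {
      abort(sprintf("config file not found: %s", config),
            class = "standcompare_config_error")
    }
    config <- yaml::read_yaml(config)
  }
  stopifnot(is.list(config))
  defaults <- list(seed = 1L, n_draw = 100L, reps = 1000L, cutoff = 1000,
                   min_neighbors = 2L, convention = "simple",
                   max_dbh = 1000, sanity_filter_scope = "all")
  config$params <- utils::modifyList(defaults, config$params %||% list())
  if (is.null(config$output_dir)) config$output_dir <- "standcompare_out"
  need <- c("stems", "plots", "sites")
  missing <- setdiff(need, names(config$inputs %||% list()))
  if (length(missing) > 0) {
    abort(sprintf("config inputs missing: %s",
                  paste(missing, collapse = ", ")),
          class = "standcompare_config_error")
  }
  config
}

log_line <- function(fmt, ...) {
  message(sprintf("[%s] %s", format(Sys.time(), "%H:%M:%S"),
                  sprintf(fmt, ...)))
}

#' Simulate a full synthetic dataset to CSV
#'
#' Writes the complete input schema (sites, plots, stems, ratings, and a
#' reference inventory) for a synthetic landscape into `dir`, so the whole
#' pipeline can be exercised with zero external input. The latent
#' per-forest effects are saved too (`true_effects.csv`) for
#' parameter-recovery checks.
#'
#' @param dir Output directory.
#' @param landscape Optional [landscape_spec()] (defaults used otherwise).
#' @param community Optional [community_spec()].
#' @param n_plots Plots per forest.
#' @param n_reference Reference plots.
#' @param uplift Reference old-growth uplift.
#' @param seed Integer seed.
#' @return Invisibly, the directory.
#' @export
simulate_dataset <- function(dir, landscape = NULL, community = NULL,
                             n_plots = 10, n_reference = 10, uplift = 0.5,
                             seed = 1) {
  spec <- landscape %||% landscape_spec(seed = seed)
  comm <- community %||% community_spec()
  land <- generate_landscape(spec)
  inv <- generate_inventory(land, comm, n_plots = n_plots, seed = seed)
  refs <- generate_reference_set(land, comm, n_reference = n_reference,
                                 uplift = uplift, seed = seed + 1L)
  ratings <- generate_ratings(land, visit_year = spec$visit_year,
                              seed = seed + 2L)
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_inventory(inv, dir)
  ref_paths <- write_inventory(refs, file.path(dir, "reference"))
  file.copy(ref_paths, file.path(dir, paste0("ref_", basename(ref_paths))),
            overwrite = TRUE)
  unlink(file.path(dir, "reference"), recursive = TRUE)
  readr::write_csv(ratings, file.path(dir, "ratings.csv"))
  readr::write_csv(land[c("forest_id", "true_effect")],
                   file.path(dir, "true_effects.csv"))
  log_line("simulated dataset in %s (%d forests, %d reference plots)",
           dir, nrow(land), n_reference)
  invisible(dir)
}
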