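#' Read and validate a forest inventory
#'
#' Assembles a validated inventory from three headered CSV tables (or
#' in-memory data frames with the same columns):
#'
#' * `sites`: `site_id, latitude, longitude, elevation_m` — one row per
#'   site; coordinates in decimal degrees (WGS84 assumed, east/north
#'   positive), elevation in meters.
#' * `plots`: `plot_id, forest_id, visit_year, dialect, site_id` — one row
#'   per censused plot; `dialect` is one of the [plot_geometry()] dialects
#'   and must be constant within a forest-visit.
#' * `stems`: `stem_id, plot_id, forest_id, visit_year, species, lifeform,
#'   measure_cm, subplot_index` — one row per measured stem.
#'   `subplot_index` (1-10) is required for reference-dialect stems and
#'   must be blank otherwise.
#'
#' Validation is strict where the record is unusable (missing columns,
#' unknown dialects or plots, non-positive measurements, empty species
#' labels, out-of-range coordinates) and lenient where the stem is merely
#' inconsistent with the census protocol: stems whose DBH falls outside
#' their lifeform's stratum window are kept, flagged, and excluded from
#' structure metrics rather than silently dropped.
#'
#' Circumference-measured stems (the `india_5m` dialect) are converted to
#' DBH as `measure_cm / pi`; species labels are passed through
#' [normalize_species_label()].
#'
#' @param stems,plots,sites File paths or data frames (see above).
#' @return A `forest_inventory` object: a list with tibbles `$sites`,
#'   `$plots` and `$stems`, the latter carrying derived columns `dbh`,
#'   `stratum`, `use_structure`, `use_biodiversity`, `exclusion_reason`.
#' @seealso [visits()], [apply_sanity_filter()], [write_inventory()]
#' @export
read_inventory <- function(stems, plots, sites) {
  sites <- read_table_checked(sites, "sites",
    c("site_id", "latitude", "longitude", "elevation_m"))
  plots <- read_table_checked(plots, "plots",
    c("plot_id", "forest_id", "visit_year", "dialect", "site_id"))
  stems <- read_table_checked(stems, "stems",
    c("stem_id", "plot_id", "forest_id", "visit_year", "species",
      "lifeform", "measure_cm", "subplot_index"))

  validate_sites(sites)
  validate_plots(plots, sites)
  stems <- validate_stems(stems, plots)
  new_forest_inventory(sites, plots, stems)
}

read_table_checked <- function(x, what, required) {
  if (is.character(x) && length(x) == 1L) {
    if (!file.exists(x)) {
      abort(sprintf("%s file not found: %s", what, x),
            class = "standcompare_schema_error")
    }
    x <- readr::read_csv(x, show_col_types = FALSE, progress = FALSE)
  }
  x <- tibble::as_tibble(x)
  missing <- setdiff(required, names(x))
  if (length(missing) > 0) {
    abort(sprintf("`%s` table is missing required column(s): %s",
                  what, paste(missing, collapse = ", ")),
          class = "standcompare_schema_error")
  }
  x[required]
}

validate_sites <- function(sites) {
  if (anyDuplicated(sites$site_id)) {
    abort("duplicated site_id in sites table",
          class = "standcompare_validation_error")
  }
  check_number(sites$latitude, "latitude", -90, 90)
  check_number(sites$longitude, "longitude", -180, 180)
  check_number(sites$elevation_m, "elevation_m")
  invisible(sites)
}

validate_plots <- function(plots, sites) {
  if (anyDuplicated(plots$plot_id)) {
    abort("duplicated plot_id in plots table",
          class = "standcompare_validation_error")
  }
  bad_dialect <- setdiff(unique(plots$dialect), dialect_levels())
  if (length(bad_dialect) > 0) {
    abort(sprintf("unknown dialect(s): %s", paste(bad_dialect, collapse = ", ")),
          class = "standcompare_config_error")
  }
  orphan <- setdiff(plots$site_id, sites$site_id)
  if (length(orphan) > 0) {
    abort(sprintf("plots reference unknown site_id(s): %s",
                  paste(orphan, collapse = ", ")),
          class = "standcompare_validation_error")
  }
  check_number(plots$visit_year, "visit_year", 1900, 2100)
  mixed <- plots |>
    dplyr::distinct(.data$forest_id, .data$visit_year, .data$dialect) |>
    dplyr::count(.data$forest_id, .data$visit_year) |>
    dplyr::filter(.data$n > 1)
  if (nrow(mixed) > 0) {
    abort(sprintf("forest-visit(s) with mixed dialects: %s",
                  paste(mixed$forest_id, collapse = ", ")),
          class = "standcompare_validation_error")
  }
  invisible(plots)
}

validate_stems <- function(stems, plots) {
  orphan <- !stems$plot_id %in% plots$plot_id
  if (any(orphan)) {
    abort(sprintf("stem(s) reference unknown plot_id: %s",
                  paste(utils::head(stems$stem_id[orphan], 10), collapse = ", ")),
          class = "standcompare_validation_error")
  }
  if (anyDuplicated(stems$stem_id)) {
    abort("duplicated stem_id in stems table",
          class = "standcompare_validation_error")
  }
  plot_key <- plots |>
    dplyr::select("plot_id", plot_forest = "forest_id",
                  plot_year = "visit_year", "dialect")
  stems <- dplyr::left_join(stems, plot_key, by = "plot_id")
  mism <- stems$forest_id != stems$plot_forest |
    stems$visit_year != stems$plot_year
  if (any(mism)) {
    abort(sprintf(
      "stem(s) disagree with their plot's forest_id/visit_year: %s",
      paste(utils::head(stems$stem_id[mism], 10), collapse = ", ")),
      class = "standcompare_validation_error")
  }
  if (any(!is.finite(stems$measure_cm) | stems$measure_cm <= 0)) {
    bad <- !is.finite(stems$measure_cm) | stems$measure_cm <= 0
    abort(sprintf("non-positive measure_cm for stem(s): %s",
                  paste(utils::head(stems$stem_id[bad], 10), collapse = ", ")),
          class = "standcompare_validation_error")
  }
  bad_lf <- !stems$lifeform %in% lifeform_levels()
  if (any(bad_lf)) {
    abort(sprintf("unknown lifeform for stem(s): %s",
                  paste(utils::head(stems$stem_id[bad_lf], 10), collapse = ", ")),
          class = "standcompare_validation_error")
  }
  if (nrow(stems) > 0) stems$species <- normalize_species_label(stems$species)

  is_ref <- stems$dialect == "gentry_reference"
  bad_sub <- is_ref & (is.na(stems$subplot_index) |
                         !stems$subplot_index %in% 1:10)
  if (any(bad_sub)) {
    abort(sprintf("reference-dialect stem(s) need subplot_index 1-10: %s",
                  paste(utils::head(stems$stem_id[bad_sub], 10), collapse = ", ")),
          class = "standcompare_validation_error")
  }

  # circumference-recording dialects: DBH = recorded circumference / pi
  circumference <- vapply(stems$dialect, function(d)
    plot_geometry(d)$size_measure == "circumference", logical(1),
    USE.NAMES = FALSE)
  stems$dbh <- ifelse(circumference, stems$measure_cm / pi, stems$measure_cm)
  stems$stratum <- NA_character_
  for (d in unique(stems$dialect)) {
    i <- stems$dialect == d
    stems$stratum[i] <- classify_stratum(stems$dbh[i], stems$lifeform[i], d)
  }
  stems$use_structure <- !is.na(stems$stratum) &
    !stems$lifeform %in% c("shrub", "liana")
  stems$use_biodiversity <- TRUE
  stems$exclusion_reason <- ifelse(is.na(stems$stratum), "out_of_stratum",
                                   NA_character_)
  n_flag <- sum(is.na(stems$stratum))
  if (n_flag > 0) {
    warn(sprintf(
      "%d stem(s) fall outside their lifeform's stratum window; flagged and excluded from structure metrics (see exclusion_reason)",
      n_flag))
  }
  dplyr::select(stems, -"plot_forest", -"plot_year")
}

new_forest_inventory <- function(sites, plots, stems) {
  structure(list(sites = tibble::as_tibble(sites),
                 plots = tibble::as_tibble(plots),
                 stems = tibble::as_tibble(stems)),
            class = "forest_inventory")
}

#' @export
print.forest_inventory <- function(x, ...) {
  v <- visits(x)
  cat(sprintf(
    "<forest_inventory> %d site(s), %d plot(s), %d stem(s), %d forest-visit(s)\n",
    nrow(x$sites), nrow(x$plots), nrow(x$stems), nrow(v)))
  if (nrow(v) > 0) print(v, n = 5)
  invisible(x)
}

#' Summarize the forest-visits in an inventory
#'
#' A forest-visit (one forest censused in one year) is the unit of all
#' metric computation in this package.
#'
#' @param inventory A `forest_inventory`.
#' @return A tibble with one row per forest-visit: `forest_id`,
#'   `visit_year`, `site_id`, `dialect`, `n_plots`, `n_stems`.
#' @export
visits <- function(inventory) {
  stopifnot(inherits(inventory, "forest_inventory"))
  stem_n <- inventory$stems |>
    dplyr::count(.data$forest_id, .data$visit_year, name = "n_stems")
  inventory$plots |>
    dplyr::group_by(.data$forest_id, .data$visit_year) |>
    dplyr::summarise(site_id = .data$site_id[1], dialect = .data$dialect[1],
                     n_plots = dplyr::n(), .groups = "drop") |>
    dplyr::left_join(stem_n, by = c("forest_id", "visit_year")) |>
    dplyr::mutate(n_stems = dplyr::coalesce(.data$n_stems, 0L)) |>
    dplyr::arrange(.data$forest_id, .data$visit_year)
}

#' Write an inventory back to CSV
#'
#' Writes `sites.csv`, `plots.csv` and `stems.csv` (raw recorded measures,
#' not derived columns) into `dir`, so that [read_inventory()] on the
#' output reproduces the same stems.
#'
#' @param inventory A `forest_inventory`.
#' @param dir Output directory (created if needed).
#' @return Invisibly, the paths written.
#' @export
write_inventory <- function(inventory, dir) {
  stopifnot(inherits(inventory, "forest_inventory"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- file.path(dir, c("sites.csv", "plots.csv", "stems.csv"))
  readr::write_csv(inventory$sites, paths[1])
  readr::write_csv(inventory$plots, paths[2])
  stem_cols <- c("stem_id", "plot_id", "forest_id", "visit_year", "species",
                 "lifeform", "measure_cm", "subplot_index")
  readr::write_csv(inventory$stems[stem_cols], paths[3])
  invisible(paths)
}

#' Flag implausibly large stems
#'
#' Field databases occasionally contain order-of-magnitude recording errors
#' (a DBH of 18.37 m, say, where 18.37 cm was meant). Stems with DBH above
#' `max_dbh` are flagged and excluded from downstream metrics; they remain
#' in the stem table with an exclusion reason, never silently deleted.
#' `scope` controls whether the exclusion applies to structure metrics only
#' (basal area) or, the default, to biodiversity counts as well — one giant
#' stem cannot change a species count materially, and a single rule keeps
#' the invariants simple.
#'
#' @param inventory A `forest_inventory`.
#' @param max_dbh Threshold in cm (default 1000); `Inf` disables the filter.
#' @param scope `"all"` (default) or `"structure_only"`.
#' @return The inventory, with flags updated and a report attached;
#'   retrieve it with [sanity_report()].
#' @export
apply_sanity_filter <- function(inventory, max_dbh = 1000,
                                scope = c("all", "structure_only")) {
  stopifnot(inherits(inventory, "forest_inventory"))
  scope <- match.arg(scope)
  if (!(is.numeric(max_dbh) && length(max_dbh) == 1L && max_dbh > 0)) {
    abort("`max_dbh` must be a single positive number (Inf to disable)",
          class = "standcompare_domain_error")
  }
  flag <- inventory$stems$dbh > max_dbh
  inventory$stems$use_structure[flag] <- FALSE
  if (scope == "all") inventory$stems$use_biodiversity[flag] <- FALSE
  inventory$stems$exclusion_reason[flag] <- "oversize"
  report <- inventory$stems |>
    dplyr::filter(flag) |>
    dplyr::select("stem_id", "plot_id", "forest_id", "visit_year", "dbh") |>
    dplyr::mutate(reason = "oversize", max_dbh = max_dbh, scope = scope)
  attr(inventory, "sanity_report") <- report
  inventory
}

#' @rdname apply_sanity_filter
#' @export
sanity_report <- function(inventory) {
  attr(inventory, "sanity_report") %||%
    tibble::tibble(stem_id = character(), plot_id = character(),
                   forest_id = character(), visit_year = integer(),
                   dbh = double(), reason = character(),
                   max_dbh = double(), scope = character())
}
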