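#' Cross-sectional (basal) area of a stem
#'
#' The area of a circle applied to a stem's diameter at breast height:
#' `pi * DBH^2 / 4`, converted from cm^2 to m^2.
#'
#' @param dbh Numeric vector of DBH values in cm, all > 0.
#' @return Basal area(s) in m^2.
#' @examples
#' stem_basal_area(10)        # 0.007854 m^2
#' stem_basal_area(112.8379)  # ~1 m^2
#' @export
stem_basal_area <- function(dbh) {
  check_number(dbh, "dbh", lower = 1e-12)
  pi * (dbh / 100)^2 / 4
}

#' Basal area per hectare for each forest-visit
#'
#' Sums stem basal areas over a visit's plots and divides by the total
#' sampled area, separately by census stratum because the tree and sapling
#' strata cover different areas: the tree component uses the tree-stratum
#' plot area (e.g. pi * 10^2 m^2 per standard plot) and the sapling
#' component the understory subplot area (pi * 3^2 m^2); the per-hectare
#' components are then summed. Shrubs and lianas are never included in
#' basal area (measurement consistency), nor are stems flagged by
#' validation or [apply_sanity_filter()]. Reference-dialect visits have a
#' single stratum over the full 0.1-ha plot; their stems >= 10 cm are
#' reported in `tree_component` and smaller stems in `sapling_component`,
#' both scaled by the same 0.1 ha.
#'
#' Per-hectare scaling uses the nominal stratum area times the number of
#' plots; partial or edge plots are not supported.
#'
#' @param inventory A `forest_inventory`.
#' @return A tibble with one row per forest-visit: `forest_id`,
#'   `visit_year`, `ba_per_ha`, `tree_component`, `sapling_component`
#'   (all m^2/ha), `n_plots`, `n_stems_used`.
#' @examples
#' # one standard plot holding a single 10-cm tree:
#' # 0.0078540 m^2 / 0.0314159 ha = 0.25 m^2/ha
#' @export
forest_basal_area <- function(inventory) {
  stopifnot(inherits(inventory, "forest_inventory"))
  v <- visits(inventory)
  if (any(v$n_plots < 1)) {
    abort("every forest-visit needs at least one plot",
          class = "standcompare_domain_error")
  }
  stems <- dplyr::filter(inventory$stems, .data$use_structure)
  purrr::pmap_dfr(
    v[c("forest_id", "visit_year", "dialect", "n_plots")],
    function(forest_id, visit_year, dialect, n_plots) {
      geom <- plot_geometry(dialect)
      s <- stems[stems$forest_id == forest_id &
                   stems$visit_year == visit_year, ]
      if (dialect == "gentry_reference") {
        area_ha <- geom$plot_area_m2 / 1e4 * n_plots
        big <- s$dbh >= geom$tree_dbh_min
        tree_comp <- sum(stem_basal_area2(s$dbh[big])) / area_ha
        sap_comp <- sum(stem_basal_area2(s$dbh[!big])) / area_ha
      } else {
        tree_area_ha <- geom$tree_area_m2 / 1e4 * n_plots
        sap_area_ha <- geom$sapling_area_m2 / 1e4 * n_plots
        tree_comp <- sum(stem_basal_area2(s$dbh[s$stratum == "tree"])) /
          tree_area_ha
        sap_comp <- sum(stem_basal_area2(s$dbh[s$stratum == "sapling"])) /
          sap_area_ha
      }
      tibble::tibble(forest_id = forest_id, visit_year = visit_year,
                     ba_per_ha = tree_comp + sap_comp,
                     tree_component = tree_comp,
                     sapling_component = sap_comp,
                     n_plots = n_plots, n_stems_used = nrow(s))
    }
  )
}

# internal: stem_basal_area() without the domain check, tolerant of empty input
stem_basal_area2 <- function(dbh) {
  if (length(dbh) == 0) return(0)
  pi * (dbh / 100)^2 / 4
}
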