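#' Plot geometry dialects
#'
#' Forest inventories in this package come in three sampling "dialects".
#' The standard circular-plot protocol measures all trees and palms >= 10 cm
#' DBH within 10 m of the plot center and all saplings (2.5-10 cm DBH),
#' shrubs and lianas (>= 2.5 cm) within 3 m. A variant protocol used at some
#' Indian sites measures both strata in a single 5-m-radius plot and records
#' stem circumference instead of diameter. Old-growth reference plots follow
#' a 0.1-ha transect layout: 10 parallel 50 m x 2 m transects (here treated
#' as subplots 1-10 of 100 m^2 each) in which every stem >= 2.5 cm DBH is
#' measured, with no stratum distinction.
#'
#' @param dialect One of `"ifri_standard"`, `"india_5m"`, `"gentry_reference"`.
#'
#' @return A list of class `plot_geometry` with elements `dialect`,
#'   `size_measure` (`"diameter"` or `"circumference"`), `tree_dbh_min` and
#'   `sapling_dbh_min` (cm), and either `tree_radius_m`/`sapling_radius_m`
#'   plus the derived stratum areas in m^2 (circular dialects) or
#'   `plot_area_m2 = 1000` with `n_subplots = 10` (reference dialect).
#'   Areas are computed from the radii at full double precision.
#' @examples
#' plot_geometry("ifri_standard")$tree_area_m2   # pi * 10^2 = 314.159...
#' plot_geometry("india_5m")$size_measure        # "circumference"
#' @export
plot_geometry <- function(dialect) {
  dialect <- match.arg(dialect, dialect_levels())
  base <- list(dialect = dialect, tree_dbh_min = 10, sapling_dbh_min = 2.5)
  geom <- switch(dialect,
    ifri_standard = c(base, list(
      size_measure = "diameter",
      tree_radius_m = 10, sapling_radius_m = 3,
      tree_area_m2 = pi * 10^2, sapling_area_m2 = pi * 3^2
    )),
    india_5m = c(base, list(
      size_measure = "circumference",
      tree_radius_m = 5, sapling_radius_m = 5,
      tree_area_m2 = pi * 5^2, sapling_area_m2 = pi * 5^2
    )),
    gentry_reference = c(base, list(
      size_measure = "diameter",
      plot_area_m2 = 1000, n_subplots = 10L, subplot_area_m2 = 100
    ))
  )
  structure(geom, class = "plot_geometry")
}

dialect_levels <- function() c("ifri_standard", "india_5m", "gentry_reference")

lifeform_levels <- function() c("tree", "palm", "sapling", "shrub", "liana")

#' Assign stems to census strata
#'
#' Partitions stems into the size-defined census layers of their dialect:
#' trees and palms >= 10 cm DBH belong to the tree stratum; saplings
#' (2.5-10 cm) and shrubs/lianas >= 2.5 cm belong to the sapling
#' (understory) stratum. In the reference dialect every stem >= 2.5 cm falls
#' in a single stratum `"all"`. Stems violating their lifeform's size window
#' (field errors, e.g. a "tree" recorded at 6 cm) get stratum `NA` and are
#' excluded from structure metrics downstream rather than reassigned.
#'
#' @param dbh Numeric vector, diameter at breast height in cm.
#' @param lifeform Character vector, one of `"tree"`, `"palm"`, `"sapling"`,
#'   `"shrub"`, `"liana"`.
#' @param dialect A single dialect name (see [plot_geometry()]).
#' @return Character vector: `"tree"`, `"sapling"`, `"all"`, or `NA` for
#'   out-of-stratum stems.
#' @export
classify_stratum <- function(dbh, lifeform, dialect) {
  dialect <- match.arg(dialect, dialect_levels())
  geom <- plot_geometry(dialect)
  bad <- !lifeform %in% lifeform_levels()
  if (any(bad)) {
    abort(paste0("unknown lifeform(s): ",
                 paste(unique(lifeform[bad]), collapse = ", ")),
          class = "standcompare_validation_error")
  }
  if (dialect == "gentry_reference") {
    return(ifelse(dbh >= geom$sapling_dbh_min, "all", NA_character_))
  }
  out <- rep(NA_character_, length(dbh))
  woody_big <- lifeform %in% c("tree", "palm") & dbh >= geom$tree_dbh_min
  sap <- lifeform == "sapling" &
    dbh >= geom$sapling_dbh_min & dbh < geom$tree_dbh_min
  under <- lifeform %in% c("shrub", "liana") & dbh >= geom$sapling_dbh_min
  out[woody_big] <- "tree"
  out[sap | under] <- "sapling"
  out
}
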