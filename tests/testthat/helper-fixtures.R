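# in-code fixtures: tiny hand-built inventories

# Build a one-visit inventory from a compact stem description.
# `stems` needs columns species, lifeform, measure_cm and optionally
# plot (1-based plot index) and subplot_index.
fixture_inventory <- function(stems, n_plots = 1, dialect = "ifri_standard",
                              forest_id = "F1", visit_year = 2005,
                              latitude = 10, longitude = 20,
                              elevation_m = 500) {
  stems <- tibble::as_tibble(stems)
  if (!"plot" %in% names(stems)) stems$plot <- 1L
  if (!"subplot_index" %in% names(stems)) {
    stems$subplot_index <- NA_integer_
  }
  sites <- tibble::tibble(site_id = "S1", latitude = latitude,
                          longitude = longitude, elevation_m = elevation_m)
  plots <- tibble::tibble(
    plot_id = sprintf("%s_P%02d", forest_id, seq_len(n_plots)),
    forest_id = forest_id, visit_year = visit_year, dialect = dialect,
    site_id = "S1")
  stem_tbl <- tibble::tibble(
    stem_id = sprintf("%s_T%04d", forest_id, seq_len(nrow(stems))),
    plot_id = plots$plot_id[stems$plot],
    forest_id = forest_id, visit_year = visit_year,
    species = stems$species, lifeform = stems$lifeform,
    measure_cm = stems$measure_cm, subplot_index = stems$subplot_index)
  read_inventory(stem_tbl, plots, sites)
}

# n stems of one species, trees at 15 cm DBH unless overridden
simple_stems <- function(n, species = "sp a", lifeform = "tree",
                         measure_cm = 15, plot = 1L) {
  tibble::tibble(species = rep_len(species, n),
                 lifeform = rep_len(lifeform, n),
                 measure_cm = rep_len(measure_cm, n),
                 plot = rep_len(plot, n))
}

# site table laid out on a near-equatorial grid, all elevations equal
grid_sites <- function(n, lat0 = 5, spacing_deg = 0.05, elevation_m = 500) {
  tibble::tibble(site_id = sprintf("S%03d", seq_len(n)),
                 latitude = lat0 + spacing_deg * (seq_len(n) - 1),
                 longitude = 30,
                 elevation_m = elevation_m)
}
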