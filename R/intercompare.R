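#' Distance-weighted standardization against a neighborhood
#'
#' The core of regional intercomparison: a focal forest's metric value is
#' rescaled as a z-score against the inverse-square-distance weighted mean
#' and standard deviation of candidate forests within `cutoff` total
#' distance units ([total_distance()]). Weights are `total^-2`, normalized
#' to sum to 1; the weighted SD is the probability-weight population form
#' `sqrt(sum(w_i * (v_i - mean)^2))`, which makes the z-score exactly
#' location- and scale-equivariant.
#'
#' Candidates at total distance 0 would get infinite weight and are
#' excluded with a warning (the focal forest itself must never be a
#' candidate). A standard deviation needs at least two points, so
#' neighborhoods smaller than `min_neighbors` yield a missing z with reason
#' `"insufficient_neighbors"`; a degenerate neighborhood (weighted SD 0)
#' yields z = 0 if the focal value equals the weighted mean and a missing z
#' with reason `"zero_weighted_sd"` otherwise.
#'
#' @param focal_value Finite metric value of the focal forest.
#' @param values Candidate metric values.
#' @param totals Candidate total distances from the focal forest (same
#'   length as `values`).
#' @param ids Optional candidate identifiers for the neighbor table.
#' @param cutoff Neighborhood radius in total distance units (default 1000,
#'   inclusive).
#' @param min_neighbors Minimum neighborhood size (default 2).
#' @return A list: `z`, `weighted_mean`, `weighted_sd`, `n_neighbors`,
#'   `missing_reason`, and `neighbor_table` (tibble of `neighbor_id`,
#'   `total_distance`, `weight`, `value`).
#' @examples
#' # neighbors 0 and 2 at equal distances, focal 2: mean 1, sd 1, z = 1
#' build_neighborhood(2, c(0, 2), c(10, 10))$z
#' @export
build_neighborhood <- function(focal_value, values, totals, ids = NULL,
                               cutoff = 1000, min_neighbors = 2) {
  stopifnot(length(values) == length(totals))
  ids <- ids %||% as.character(seq_along(values))
  if (!is.finite(focal_value)) {
    abort("`focal_value` must be finite", class = "standcompare_domain_error")
  }
  at_zero <- totals == 0
  if (any(at_zero)) {
    warn(sprintf(
      "%d candidate(s) at total distance 0 excluded (undefined weight)",
      sum(at_zero)))
  }
  keep <- is.finite(values) & totals > 0 & totals <= cutoff
  empty_tbl <- tibble::tibble(neighbor_id = character(),
                              total_distance = double(),
                              weight = double(), value = double())
  res <- list(z = NA_real_, weighted_mean = NA_real_, weighted_sd = NA_real_,
              n_neighbors = sum(keep), missing_reason = NA_character_,
              neighbor_table = empty_tbl)
  if (sum(keep) < min_neighbors) {
    res$missing_reason <- "insufficient_neighbors"
    return(res)
  }
  v <- values[keep]
  td <- totals[keep]
  mom <- weighted_moments(v, td^-2)
  res$weighted_mean <- mom$mean
  res$weighted_sd <- mom$sd
  res$neighbor_table <- tibble::tibble(neighbor_id = ids[keep],
                                       total_distance = td,
                                       weight = mom$weights, value = v)
  tol <- 1e-12 * max(1, abs(mom$mean), abs(focal_value))
  if (mom$sd > 0) {
    res$z <- (focal_value - mom$mean) / mom$sd
  } else if (abs(focal_value - mom$mean) <= tol) {
    res$z <- 0
  } else {
    res$missing_reason <- "zero_weighted_sd"
  }
  res
}

#' Standardize forest metrics against nearby forests
#'
#' Batch application of [build_neighborhood()] to a table of per-forest
#' metric values. In `"regional"` mode each forest-visit is standardized
#' against the other forests of the same table (its regional peers); in
#' `"reference"` mode against a separate table of reference (old-growth)
#' forests. Either way the neighborhood is all candidates within `cutoff`
#' total distance units, weighted by inverse squared total distance.
#'
#' A forest is never its own neighbor: all visits of the focal forest are
#' excluded from its candidate pool, and when a forest has several visits
#' only the latest one enters the pool other forests are compared against.
#' Forests without a sufficient neighborhood are reported with a missing z
#' and a reason, never dropped.
#'
#' @param metric_table Tibble with columns `forest_id`, `site_id`, `value`,
#'   and optionally `visit_year` (one row per forest-visit).
#' @param sites Site table (`site_id`, `latitude`, `longitude`,
#'   `elevation_m`) covering every site referenced by `metric_table` and,
#'   in reference mode, `reference_table`.
#' @param mode `"regional"` or `"reference"`.
#' @param reference_table Required in reference mode: `forest_id`,
#'   `site_id`, `value` for the reference forests.
#' @param metric Label stored in the output (e.g. `"BA"`, `"SR"`).
#' @param cutoff,min_neighbors Passed to [build_neighborhood()].
#' @param keep_neighbors If `TRUE`, attach the full neighbor tables as the
#'   `"neighbors"` attribute (a long tibble).
#' @return A tibble of class `sc_intercomparison`: `forest_id`,
#'   `visit_year`, `metric`, `mode`, `focal_value`, `n_neighbors`,
#'   `weighted_mean`, `weighted_sd`, `z`, `missing_reason`.
#' @export
intercompare <- function(metric_table, sites,
                         mode = c("regional", "reference"),
                         reference_table = NULL, metric = "value",
                         cutoff = 1000, min_neighbors = 2,
                         keep_neighbors = FALSE) {
  mode <- match.arg(mode)
  metric_table <- tibble::as_tibble(metric_table)
  if (!"visit_year" %in% names(metric_table)) {
    metric_table$visit_year <- NA_integer_
  }
  stopifnot(all(c("forest_id", "site_id", "value") %in% names(metric_table)))
  if (anyDuplicated(metric_table[c("forest_id", "visit_year")])) {
    abort("duplicated (forest_id, visit_year) in metric_table",
          class = "standcompare_validation_error")
  }
  missing_site <- setdiff(metric_table$site_id, sites$site_id)
  if (length(missing_site) > 0) {
    abort(sprintf("metric_table references unknown site_id(s): %s",
                  paste(missing_site, collapse = ", ")),
          class = "standcompare_validation_error")
  }
  if (mode == "reference") {
    if (is.null(reference_table)) {
      abort("reference mode requires `reference_table`",
            class = "standcompare_config_error")
    }
    candidates <- tibble::as_tibble(reference_table)
    stopifnot(all(c("forest_id", "site_id", "value") %in% names(candidates)))
  } else {
    # latest visit per forest forms the candidate pool
    candidates <- metric_table |>
      dplyr::group_by(.data$forest_id) |>
      dplyr::slice_max(.data$visit_year, n = 1, with_ties = FALSE,
                       na_rm = FALSE) |>
      dplyr::ungroup()
  }
  cand_sites <- sites[match(candidates$site_id, sites$site_id), ]
  focal_sites <- sites[match(metric_table$site_id, sites$site_id), ]

  all_neighbors <- vector("list", nrow(metric_table))
  rows <- purrr::map_dfr(seq_len(nrow(metric_table)), function(i) {
    cand <- candidates
    csites <- cand_sites
    if (mode == "regional") {
      keep <- cand$forest_id != metric_table$forest_id[i]
      cand <- cand[keep, ]
      csites <- csites[keep, ]
    }
    td <- total_distance(
      focal_sites$latitude[i], focal_sites$longitude[i],
      focal_sites$elevation_m[i],
      csites$latitude, csites$longitude, csites$elevation_m)$total
    nb <- build_neighborhood(metric_table$value[i], cand$value, td,
                             ids = cand$forest_id, cutoff = cutoff,
                             min_neighbors = min_neighbors)
    if (keep_neighbors && nrow(nb$neighbor_table) > 0) {
      all_neighbors[[i]] <<- dplyr::mutate(
        nb$neighbor_table, focal_id = metric_table$forest_id[i],
        .before = 1)
    }
    tibble::tibble(forest_id = metric_table$forest_id[i],
                   visit_year = metric_table$visit_year[i],
                   metric = metric, mode = mode,
                   focal_value = metric_table$value[i],
                   n_neighbors = nb$n_neighbors,
                   weighted_mean = nb$weighted_mean,
                   weighted_sd = nb$weighted_sd,
                   z = nb$z, missing_reason = nb$missing_reason)
  })
  out <- structure(rows, class = c("sc_intercomparison", class(rows)))
  if (keep_neighbors) {
    attr(out, "neighbors") <- dplyr::bind_rows(all_neighbors)
  }
  out
}

#' @describeIn intercompare Histogram of the standardized z-scores, with
#'   reference lines at 0 and +/- 2.
#' @param object An `sc_intercomparison` tibble.
#' @param ... Unused.
#' @export
autoplot.sc_intercomparison <- function(object, ...) {
  dat <- dplyr::filter(object, is.finite(.data$z))
  ggplot2::ggplot(dat, ggplot2::aes(x = .data$z)) +
    ggplot2::geom_histogram(bins = 30, fill = "grey35", color = "white") +
    ggplot2::geom_vline(xintercept = 0, linetype = 2) +
    ggplot2::geom_vline(xintercept = c(-2, 2), linetype = 3) +
    ggplot2::labs(
      x = sprintf("%s (z, %s intercomparison)", dat$metric[1] %||% "value",
                  dat$mode[1] %||% ""),
      y = "forests") +
    ggplot2::theme_minimal()
}
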