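#' Annualized relative change between two measurements
#'
#' Rescales the change in a metric between two visit years to a per-year
#' proportion, so that forests re-measured after different intervals are
#' comparable. Two conventions are offered: `"simple"` (the default)
#' divides the relative change by the elapsed years,
#' `((v2 - v1) / v1) / (y2 - y1)`; `"compound"` is the equivalent constant
#' annual rate, `(v2 / v1)^(1 / (y2 - y1)) - 1`. Both are 0 exactly when
#' the metric is unchanged, positive for growth and negative for decline.
#'
#' @param value_1,value_2 Metric values at `year_1` and `year_2`;
#'   `value_1` must be > 0.
#' @param year_1,year_2 Calendar years with `year_2 > year_1`.
#' @param convention `"simple"` or `"compound"`.
#' @return Proportion per year (vectorized).
#' @examples
#' annualized_change(10, 20, 2000, 2001)               # 1.0 per year
#' annualized_change(10, 20, 2000, 2002, convention = "compound")  # sqrt(2)-1
#' @export
annualized_change <- function(value_1, value_2, year_1, year_2,
                              convention = c("simple", "compound")) {
  convention <- match.arg(convention)
  if (any(year_2 <= year_1)) {
    abort("`year_2` must be greater than `year_1`",
          class = "standcompare_domain_error")
  }
  if (any(!is.finite(value_1) | value_1 <= 0)) {
    abort("`value_1` must be finite and > 0",
          class = "standcompare_domain_error")
  }
  check_number(value_2, "value_2", lower = 0)
  dt <- year_2 - year_1
  switch(convention,
    simple = ((value_2 - value_1) / value_1) / dt,
    compound = (value_2 / value_1)^(1 / dt) - 1
  )
}

#' Annualized change between successive visits of each forest
#'
#' Pairs each forest's visits in chronological order and computes the
#' annualized change of a metric between consecutive visits. Visits whose
#' starting value is 0 (or missing) cannot be annualized relative to the
#' start and are reported with `annualized = NA` and a reason.
#'
#' @param data A data frame with columns `forest_id`, `visit_year`, and the
#'   metric column named by `value`.
#' @param value Name of the metric column (default `"value"`).
#' @param metric Label stored in the output (e.g. `"BA"` or `"SR"`).
#' @param convention Passed to [annualized_change()].
#' @return A tibble with one row per consecutive visit pair: `forest_id`,
#'   `metric`, `value_1`, `value_2`, `year_1`, `year_2`, `annualized`,
#'   `convention`, `missing_reason`.
#' @export
change_over_time <- function(data, value = "value", metric = "BA",
                             convention = c("simple", "compound")) {
  convention <- match.arg(convention)
  stopifnot(all(c("forest_id", "visit_year", value) %in% names(data)))
  out <- data |>
    dplyr::rename(.value = dplyr::all_of(value)) |>
    dplyr::arrange(.data$forest_id, .data$visit_year) |>
    dplyr::group_by(.data$forest_id) |>
    dplyr::mutate(value_1 = dplyr::lag(.data$.value),
                  year_1 = dplyr::lag(.data$visit_year)) |>
    dplyr::ungroup() |>
    dplyr::filter(!is.na(.data$year_1)) |>
    dplyr::transmute(.data$forest_id, metric = metric,
                     value_1 = .data$value_1, value_2 = .data$.value,
                     year_1 = .data$year_1, year_2 = .data$visit_year,
                     convention = convention)
  usable <- is.finite(out$value_1) & out$value_1 > 0 & is.finite(out$value_2)
  out$annualized <- NA_real_
  if (any(usable)) {
    out$annualized[usable] <- annualized_change(
      out$value_1[usable], out$value_2[usable],
      out$year_1[usable], out$year_2[usable], convention)
  }
  out$missing_reason <- ifelse(usable, NA_character_, "nonpositive_baseline")
  out
}
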