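#' Pool the stems of each forest-visit
#'
#' Biodiversity is estimated on a per-stem basis: for each forest-visit all
#' stems of every growth form (trees, palms, saplings, shrubs and lianas)
#' are pooled across plots and strata, discarding plot structure. Stems
#' excluded by the sanity filter (when its scope covers biodiversity) are
#' omitted.
#'
#' @param inventory A `forest_inventory`.
#' @return A tibble with one row per pooled stem: `forest_id`,
#'   `visit_year`, `plot_id`, `species`, `lifeform`, `dbh`,
#'   `subplot_index`.
#' @export
pool_stems <- function(inventory) {
  stopifnot(inherits(inventory, "forest_inventory"))
  inventory$stems |>
    dplyr::filter(.data$use_biodiversity) |>
    dplyr::select("forest_id", "visit_year", "plot_id", "species",
                  "lifeform", "dbh", "subplot_index")
}

# Monte-Carlo engine: `reps` unique-species counts, each from `n_draw`
# stems sampled with replacement from a pool built by `pool_fn(rep_index)`.
# Each rep runs under its own sub-seed so results do not depend on
# iteration order. Empty per-rep pools record 0 species and are flagged.
rarefy_counts <- function(pool_fn, n_draw, reps, seed) {
  seeds <- rep_seeds(seed, reps + 1L)
  counts <- integer(reps)
  empty <- 0L
  for (r in seq_len(reps)) {
    counts[r] <- with_seed(seeds[r], {
      pool <- pool_fn(r)
      if (length(pool) == 0) {
        empty <- empty + 1L
        0L
      } else {
        length(unique(pool[sample.int(length(pool), n_draw, replace = TRUE)]))
      }
    })
  }
  attr(counts, "n_empty_reps") <- empty
  counts
}

summarize_counts <- function(counts) {
  q <- quantile(counts, c(.05, .25, .75, .95), names = FALSE)
  tibble::tibble(median_richness = median(counts),
                 q05 = q[1], q25 = q[2], q75 = q[3], q95 = q[4])
}

richness_row <- function(forest_id, visit_year, estimator, counts, pool_size,
                         n_draw, reps, seed, missing_reason = NA_character_) {
  if (is.null(counts)) {
    summ <- tibble::tibble(median_richness = NA_real_, q05 = NA_real_,
                           q25 = NA_real_, q75 = NA_real_, q95 = NA_real_)
  } else {
    summ <- summarize_counts(counts)
  }
  dplyr::bind_cols(
    tibble::tibble(forest_id = forest_id, visit_year = visit_year,
                   estimator = estimator),
    summ,
    tibble::tibble(pool_size = pool_size, n_draw = n_draw, reps = reps,
                   seed = seed, missing_reason = missing_reason))
}

#' Rarefied species richness per forest-visit
#'
#' The stem-based richness estimator: from each visit's pooled stems,
#' `n_draw` stems (default 100) are sampled with replacement and the number
#' of unique species counted; repeated `reps` times (default 1000), the
#' median of the resulting distribution is the rarefied species richness
#' SR. Sampling 100 stems makes forests with very different census effort
#' and stem density comparable on a per-stem basis. Pools smaller than
#' `n_draw` remain computable (such forests are genuinely species-poor);
#' empty pools yield a missing estimate with a reason.
#'
#' The median of an even number of repetitions is the mean of the two
#' central order statistics, so half-integer values occur. Results are
#' deterministic given `seed`: each repetition runs under its own sub-seed
#' derived from the root seed.
#'
#' @param inventory A `forest_inventory` (or a pooled stem tibble from
#'   [pool_stems()]).
#' @param n_draw Stems per draw (default 100).
#' @param reps Number of repetitions (default 1000).
#' @param seed Integer root seed.
#' @param keep_counts If `TRUE`, attach the per-repetition unique-species
#'   counts as attribute `"counts"` (a list named by
#'   `forest_id.visit_year`), for diagnostics on the full distribution.
#' @return A tibble with one row per forest-visit: `estimator = "sr100"`,
#'   `median_richness`, quantiles `q05`, `q25`, `q75`, `q95`, `pool_size`,
#'   `n_draw`, `reps`, `seed`, `missing_reason`.
#' @export
rarefied_richness <- function(inventory, n_draw = 100, reps = 1000, seed = 1,
                              keep_counts = FALSE) {
  pooled <- if (inherits(inventory, "forest_inventory")) {
    pool_stems(inventory)
  } else {
    tibble::as_tibble(inventory)
  }
  keys <- dplyr::distinct(pooled, .data$forest_id, .data$visit_year)
  if (inherits(inventory, "forest_inventory")) {
    keys <- visits(inventory)[c("forest_id", "visit_year")]
  }
  all_counts <- list()
  out <- purrr::pmap_dfr(keys, function(forest_id, visit_year) {
    sp <- pooled$species[pooled$forest_id == forest_id &
                           pooled$visit_year == visit_year]
    if (length(sp) == 0) {
      return(richness_row(forest_id, visit_year, "sr100", NULL, 0L,
                          n_draw, reps, seed, "empty_pool"))
    }
    ids <- match(sp, unique(sp))
    counts <- rarefy_counts(function(r) ids, n_draw, reps,
                            visit_seed(seed, forest_id, visit_year))
    if (keep_counts) {
      all_counts[[paste(forest_id, visit_year, sep = ".")]] <<-
        as.integer(counts)
    }
    richness_row(forest_id, visit_year, "sr100", counts, length(sp),
                 n_draw, reps, seed)
  })
  if (keep_counts) attr(out, "counts") <- all_counts
  out
}

# Per-visit seed: stable hash of (root seed, forest_id, visit_year), so a
# visit's estimate does not depend on which other visits are in the table.
visit_seed <- function(seed, forest_id, visit_year) {
  key <- paste(forest_id, visit_year, sep = "\r")
  h <- sum(utf8ToInt(key) * (seq_len(nchar(key)) %% 97 + 1))
  (as.integer(seed) %% 100000L) * 20011L + (h %% 20011L) + 1L
}

#' Effort-harmonized richness for focal forests
#'
#' Old-growth reference transects sample only 0.1 ha, while a typical focal
#' forest's census covers about 1 ha, so richness must be re-estimated at a
#' matched effort before the two are compared. Each repetition first draws
#' a subset of plots without replacement — `n_plots_subset` (default 3,
#' giving 3 x pi x 10^2 m^2 = 0.0942 ha of tree-stratum area, close to the
#' 0.1-ha reference plot) — pools the subset's stems, then samples `n_draw`
#' stems with replacement and counts unique species; the median over
#' repetitions is reported.
#'
#' Visits in the `india_5m` dialect use `4 * n_plots_subset` of their
#' smaller plots for trees and palms (exactly the same tree-stratum area)
#' and one independently chosen plot for the other lifeforms (78.5 m^2,
#' close to the 84.8 m^2 of three standard understory subplots). Plot
#' subsets are drawn independently across repetitions.
#'
#' @inheritParams rarefied_richness
#' @param n_plots_subset Plots per subset for standard-dialect visits
#'   (default 3; 4 for the bracketing robustness check).
#' @return A tibble as in [rarefied_richness()], with
#'   `estimator = "sr100_<k>plot"`. Visits with too few plots get a missing
#'   estimate with reason `"too_few_plots"`; `pool_size` is the visit's
#'   full pool.
#' @export
harmonized_richness <- function(inventory, n_plots_subset = 3, n_draw = 100,
                                reps = 1000, seed = 1) {
  stopifnot(inherits(inventory, "forest_inventory"))
  v <- visits(inventory)
  v <- v[v$dialect != "gentry_reference", ]
  pooled <- pool_stems(inventory)
  estimator <- sprintf("sr100_%dplot", n_plots_subset)
  purrr::pmap_dfr(v[c("forest_id", "visit_year", "dialect")],
    function(forest_id, visit_year, dialect) {
      stems <- pooled[pooled$forest_id == forest_id &
                        pooled$visit_year == visit_year, ]
      plot_ids <- inventory$plots$plot_id[
        inventory$plots$forest_id == forest_id &
          inventory$plots$visit_year == visit_year]
      sp_ids <- match(stems$species, unique(stems$species))
      vseed <- visit_seed(seed, forest_id, visit_year)
      if (dialect == "india_5m") {
        n_tree_plots <- 4L * n_plots_subset
        if (length(plot_ids) < n_tree_plots) {
          return(richness_row(forest_id, visit_year, estimator, NULL,
                              nrow(stems), n_draw, reps, seed,
                              "too_few_plots"))
        }
        is_tree <- stems$lifeform %in% c("tree", "palm")
        tree_by_plot <- split(sp_ids[is_tree], stems$plot_id[is_tree])
        other_by_plot <- split(sp_ids[!is_tree], stems$plot_id[!is_tree])
        pool_fn <- function(r) {
          tp <- sample(plot_ids, n_tree_plots)
          op <- sample(plot_ids, 1L)
          c(unlist(tree_by_plot[tp], use.names = FALSE),
            unlist(other_by_plot[op], use.names = FALSE))
        }
      } else {
        if (length(plot_ids) < n_plots_subset) {
          return(richness_row(forest_id, visit_year, estimator, NULL,
                              nrow(stems), n_draw, reps, seed,
                              "too_few_plots"))
        }
        by_plot <- split(sp_ids, stems$plot_id)
        pool_fn <- function(r) {
          sel <- sample(plot_ids, n_plots_subset)
          unlist(by_plot[sel], use.names = FALSE)
        }
      }
      counts <- rarefy_counts(pool_fn, n_draw, reps, vseed)
      row <- richness_row(forest_id, visit_year, estimator, counts,
                          nrow(stems), n_draw, reps, seed)
      if ((attr(counts, "n_empty_reps") %||% 0L) > 0) {
        row$missing_reason <- sprintf("%d_empty_reps",
                                      attr(counts, "n_empty_reps"))
      }
      row
    })
}

#' Effort-harmonized richness for reference plots
#'
#' Reference transects census every stem >= 2.5 cm over the whole 0.1-ha
#' plot, a far greater small-stem effort than the 3-m understory subplots
#' of focal forests. To avoid inflating reference richness with saplings,
#' each repetition includes all stems >= 10 cm DBH from the whole plot but
#' small stems (< 10 cm) from only one of the ten 100-m^2 subplots, chosen
#' uniformly at random — 100 m^2 of small-stem effort, close to the
#' ~85 m^2 of three standard understory subplots. Then as usual `n_draw`
#' stems are sampled with replacement and unique species counted; the
#' median over `reps` repetitions is reported.
#'
#' @inheritParams rarefied_richness
#' @return A tibble as in [rarefied_richness()] with
#'   `estimator = "sr100_reference"`, one row per reference-dialect visit.
#' @export
reference_richness <- function(inventory, n_draw = 100, reps = 1000,
                               seed = 1) {
  stopifnot(inherits(inventory, "forest_inventory"))
  v <- visits(inventory)
  v <- v[v$dialect == "gentry_reference", ]
  pooled <- pool_stems(inventory)
  purrr::pmap_dfr(v[c("forest_id", "visit_year")],
    function(forest_id, visit_year) {
      stems <- pooled[pooled$forest_id == forest_id &
                        pooled$visit_year == visit_year, ]
      if (nrow(stems) == 0) {
        return(richness_row(forest_id, visit_year, "sr100_reference", NULL,
                            0L, n_draw, reps, seed, "empty_pool"))
      }
      small <- stems$dbh < 10
      if (any(small & is.na(stems$subplot_index))) {
        abort("reference stems < 10 cm DBH must carry subplot_index",
              class = "standcompare_validation_error")
      }
      sp_ids <- match(stems$species, unique(stems$species))
      big_pool <- sp_ids[!small]
      small_by_sub <- lapply(1:10, function(s)
        sp_ids[small & stems$subplot_index == s])
      pool_fn <- function(r) {
        c(big_pool, small_by_sub[[sample.int(10L, 1L)]])
      }
      counts <- rarefy_counts(pool_fn, n_draw, reps,
                              visit_seed(seed, forest_id, visit_year))
      richness_row(forest_id, visit_year, "sr100_reference", counts,
                   nrow(stems), n_draw, reps, seed)
    })
}
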