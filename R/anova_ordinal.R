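#' Ordinal rating vocabularies and codes
#'
#' Field assessments come as ordinal answers. User questions about
#' five-year change ("has the density of trees / the vegetated area
#' changed?") have three answers — decrease, no change, increase — coded
#' -1, 0, 1. Forester questions rating density and species diversity
#' relative to the local ecological zone have five answers — very low,
#' low, normal, high, very high — coded -2, -1, 0, 1, 2.
#'
#' @param variable Rating variable name: `"delta_density_user"`,
#'   `"delta_area_user"`, `"density_forester"`, or `"diversity_forester"`.
#' @param label Answer label(s) from that variable's vocabulary.
#' @return Integer code(s).
#' @examples
#' code_rating("delta_density_user", "decrease")   # -1
#' code_rating("diversity_forester", "very high")  # 2
#' @export
code_rating <- function(variable, label) {
  variable <- match.arg(variable, names(rating_vocabularies()))
  vocab <- rating_vocabularies()[[variable]]
  label <- tolower(trimws(label))
  unknown <- setdiff(unique(label), names(vocab))
  if (length(unknown) > 0) {
    abort(sprintf("unknown label(s) for %s: %s", variable,
                  paste(unknown, collapse = ", ")),
          class = "standcompare_validation_error")
  }
  unname(vocab[label])
}

rating_vocabularies <- function() {
  three <- c(decrease = -1L, `no change` = 0L, increase = 1L)
  five <- c(`very low` = -2L, low = -1L, normal = 0L, high = 1L,
            `very high` = 2L)
  list(delta_density_user = three, delta_area_user = three,
       density_forester = five, diversity_forester = five)
}

#' One-way ANOVA of a continuous metric across ordinal rating groups
#'
#' Tests whether a plot-derived continuous metric differs across the
#' levels of an ordinal field rating, using a fixed-effects one-way ANOVA
#' (`stats::aov`) followed by Tukey's honestly-significant-difference test
#' (`stats::TukeyHSD`, Tukey-Kramer for unbalanced groups). Pairwise
#' results are condensed into a compact letter display: groups sharing no
#' letter differ at level `alpha`; groups sharing a letter do not.
#'
#' Because an ANOVA needs a continuous response, comparisons between two
#' ordinal variables are run both ways; `response = "code"` swaps the
#' roles, treating the ordinal code as the (numeric) response and the
#' `value` column — then itself discrete — as the grouping factor.
#'
#' Groups with fewer than 2 observations are excluded with a warning; at
#' least two usable groups are required.
#'
#' @param data A data frame.
#' @param value Unquoted column with the continuous metric.
#' @param code Unquoted column with the ordinal codes.
#' @param alpha Significance level for the letter display (default 0.05).
#' @param response `"value"` (default) or `"code"` (the both-ways check).
#' @return An object of class `sc_group_comparison`: `$groups` (per-group
#'   `code`, `n`, `mean`, `sd`, `letters`), `$tukey` (pairwise tibble),
#'   `$f_statistic`, `$p_value`, `$df`, `$alpha`. Supports [tidy()],
#'   [glance()] and [autoplot()].
#' @export
anova_ordinal <- function(data, value, code, alpha = 0.05,
                          response = c("value", "code")) {
  response <- match.arg(response)
  v <- eval_tidy(enquo(value), data)
  g <- eval_tidy(enquo(code), data)
  if (response == "code") {
    tmp <- v
    v <- as.numeric(g)
    g <- tmp
  }
  ok <- is.finite(v) & !is.na(g)
  v <- v[ok]
  g <- g[ok]
  lev <- sort(unique(g))
  g <- factor(g, levels = lev)
  small <- names(which(table(g) < 2))
  if (length(small) > 0) {
    warn(sprintf("excluding group(s) with < 2 observations: %s",
                 paste(small, collapse = ", ")))
    keep <- !g %in% small
    v <- v[keep]
    g <- droplevels(g[keep])
  }
  if (nlevels(g) < 2) {
    abort("need at least two groups with >= 2 observations",
          class = "standcompare_domain_error")
  }
  fit <- aov(v ~ g)
  tab <- summary(fit)[[1]]
  tk <- TukeyHSD(fit, conf.level = 1 - alpha)$g
  # pairwise contrasts come in combn() order: (l2-l1), (l3-l1), ..., so the
  # pair identities are reconstructed positionally (level labels such as
  # "-1" make the rownames unparseable)
  cmb <- utils::combn(levels(g), 2)
  stopifnot(ncol(cmb) == nrow(tk))
  pairs <- tibble::tibble(
    contrast = rownames(tk), level_1 = cmb[2, ], level_2 = cmb[1, ],
    diff = unname(tk[, "diff"]), lwr = unname(tk[, "lwr"]),
    upr = unname(tk[, "upr"]), p_adj = unname(tk[, "p adj"]))
  letters <- cld_letters(levels(g), pairs, alpha)
  groups <- tibble::tibble(
    code = levels(g),
    n = as.integer(table(g)),
    mean = as.numeric(tapply(v, g, mean)),
    sd = as.numeric(tapply(v, g, sd)),
    letters = letters[levels(g)])
  structure(list(groups = groups, tukey = pairs,
                 f_statistic = tab[["F value"]][1],
                 p_value = tab[["Pr(>F)"]][1],
                 df = tab[["Df"]], alpha = alpha, response = response,
                 data = tibble::tibble(value = v, code = g)),
            class = "sc_group_comparison")
}

# Compact letter display by insert-and-absorb over the Tukey p matrix:
# start from one block holding every group; for each significantly
# different pair split every block containing both; drop blocks that are
# subsets of others; letter the blocks. Guarantees: significant pairs
# share no letter, non-significant pairs share at least one.
cld_letters <- function(levels, pairs, alpha) {
  k <- length(levels)
  blocks <- list(rep(TRUE, k))
  split_pair <- function(i, j) {
    out <- list()
    for (b in blocks) {
      if (b[i] && b[j]) {
        b1 <- b; b1[i] <- FALSE
        b2 <- b; b2[j] <- FALSE
        out <- c(out, list(b1, b2))
      } else {
        out <- c(out, list(b))
      }
    }
    # absorb: drop blocks contained in another block
    keep <- rep(TRUE, length(out))
    for (a in seq_along(out)) {
      for (b in seq_along(out)) {
        if (a != b && keep[b] && all(out[[a]] <= out[[b]]) &&
            !identical(out[[a]], out[[b]])) {
          keep[a] <- FALSE
          break
        }
      }
    }
    out[keep]
  }
  sig <- pairs[pairs$p_adj <= alpha, , drop = FALSE]
  for (r in seq_len(nrow(sig))) {
    blocks <- split_pair(match(sig$level_1[r], levels),
                         match(sig$level_2[r], levels))
  }
  # dedupe identical blocks
  blocks <- blocks[!duplicated(vapply(blocks, paste, character(1),
                                      collapse = ""))]
  lab <- letters[seq_along(blocks)]
  out <- vapply(seq_len(k), function(i)
    paste(lab[vapply(blocks, `[`, logical(1), i)], collapse = ""),
    character(1))
  setNames(out, levels)
}

#' @export
print.sc_group_comparison <- function(x, ...) {
  cat(sprintf("One-way ANOVA: F(%d, %d) = %.3f, p = %.4g\n",
              x$df[1], x$df[2], x$f_statistic, x$p_value))
  print(x$groups)
  invisible(x)
}

#' @export
tidy.sc_group_comparison <- function(x, ...) x$groups

#' @export
glance.sc_group_comparison <- function(x, ...) {
  tibble::tibble(statistic = x$f_statistic, p.value = x$p_value,
                 df = x$df[1], df.residual = x$df[2],
                 nobs = nrow(x$data), alpha = x$alpha)
}

#' @export
autoplot.sc_group_comparison <- function(object, ...) {
  ann <- object$groups
  ann$y <- tapply(object$data$value, object$data$code, max)[ann$code]
  ggplot2::ggplot(object$data,
                  ggplot2::aes(x = .data$code, y = .data$value)) +
    ggplot2::geom_boxplot(outlier.shape = NA, fill = "grey90") +
    ggplot2::geom_jitter(width = 0.15, alpha = 0.4, size = 1) +
    ggplot2::geom_text(data = ann,
                       ggplot2::aes(x = .data$code, y = .data$y,
                                    label = .data$letters),
                       vjust = -0.8, fontface = "italic") +
    ggplot2::labs(x = "ordinal rating", y = "metric") +
    ggplot2::theme_minimal()
}
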