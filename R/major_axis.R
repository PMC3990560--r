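#' Major axis (model II) regression
#'
#' When neither variable can be designated as the error-free predictor —
#' e.g. two alternative measurements of the same forest attribute —
#' ordinary least squares is inappropriate: it assumes error only in the
#' response and gives a different line when the variables are swapped.
#' Major axis regression fits the first principal axis of the bivariate
#' covariance ellipse instead; swapping x and y returns the reciprocal
#' slope, i.e. the same relationship.
#'
#' The slope is the direction of the leading eigenvector of the 2x2 sample
#' covariance matrix, in closed form
#' `(s_yy - s_xx + sqrt((s_yy - s_xx)^2 + 4 s_xy^2)) / (2 s_xy)`; the line
#' passes through the centroid. The slope's sign matches the sign of the
#' covariance; when the covariance is exactly 0 the axis follows whichever
#' variable has the larger variance (horizontal for x, vertical for y).
#' `r_squared` is the squared Pearson correlation. Significance comes from
#' a two-tailed permutation test of the correlation (the observed
#' statistic is included in the numerator), deterministic given `seed`.
#'
#' @param data A data frame.
#' @param x,y Unquoted column names of the two variables.
#' @param permutations Number of permutations (default 999).
#' @param seed Integer seed for the permutation test.
#' @return An object of class `sc_major_axis` with fields `slope`,
#'   `intercept`, `r_squared`, `p_value`, `n`, `permutations`, `seed`;
#'   supports [tidy()], [glance()], [autoplot()] and `predict()`.
#' @examples
#' d <- data.frame(a = 1:10, b = 2 * (1:10) + 1)
#' major_axis_fit(d, a, b)$slope  # 2
#' @export
major_axis_fit <- function(data, x, y, permutations = 999, seed = 1) {
  xv <- eval_tidy(enquo(x), data)
  yv <- eval_tidy(enquo(y), data)
  ok <- is.finite(xv) & is.finite(yv)
  xv <- xv[ok]
  yv <- yv[ok]
  n <- length(xv)
  if (n < 3) {
    abort("major axis regression needs at least 3 complete observations",
          class = "standcompare_domain_error")
  }
  sxx <- var(xv)
  syy <- var(yv)
  sxy <- cov(xv, yv)
  if (sxx == 0 || syy == 0) {
    abort("zero variance in x or y: major axis fit is degenerate",
          class = "standcompare_degenerate_error")
  }
  if (sxy == 0) {
    slope <- if (sxx >= syy) 0 else Inf
  } else {
    slope <- (syy - sxx + sqrt((syy - sxx)^2 + 4 * sxy^2)) / (2 * sxy)
  }
  intercept <- if (is.finite(slope)) mean(yv) - slope * mean(xv) else NA_real_
  r_obs <- cor(xv, yv)
  p <- with_seed(seed, {
    r_perm <- vapply(seq_len(permutations),
                     function(i) cor(xv, sample(yv)), numeric(1))
    (1 + sum(abs(r_perm) >= abs(r_obs) - 1e-12)) / (permutations + 1)
  })
  structure(list(slope = slope, intercept = intercept,
                 r_squared = r_obs^2, p_value = p, n = n,
                 permutations = permutations, seed = seed,
                 centroid = c(x = mean(xv), y = mean(yv)),
                 data = tibble::tibble(x = xv, y = yv),
                 labels = c(x = rlang::as_label(enquo(x)),
                            y = rlang::as_label(enquo(y)))),
            class = "sc_major_axis")
}

#' @export
print.sc_major_axis <- function(x, ...) {
  cat(sprintf("Major axis (model II) regression: %s ~ %s\n",
              x$labels["y"], x$labels["x"]))
  cat(sprintf("  slope %.4g  intercept %.4g  R^2 %.3f  p %.4g (n = %d, %d permutations)\n",
              x$slope, x$intercept, x$r_squared, x$p_value, x$n,
              x$permutations))
  invisible(x)
}

#' @export
tidy.sc_major_axis <- function(x, ...) {
  tibble::tibble(term = c("intercept", "slope"),
                 estimate = c(x$intercept, x$slope))
}

#' @export
glance.sc_major_axis <- function(x, ...) {
  tibble::tibble(r.squared = x$r_squared, p.value = x$p_value, nobs = x$n,
                 permutations = x$permutations, seed = x$seed)
}

#' @export
autoplot.sc_major_axis <- function(object, ...) {
  p <- ggplot2::ggplot(object$data,
                       ggplot2::aes(x = .data$x, y = .data$y)) +
    ggplot2::geom_point(alpha = 0.7) +
    ggplot2::labs(x = object$labels["x"], y = object$labels["y"],
                  subtitle = sprintf("major axis fit: R² = %.2f, p = %.3g",
                                     object$r_squared, object$p_value)) +
    ggplot2::theme_minimal()
  if (is.finite(object$slope)) {
    p <- p + ggplot2::geom_abline(intercept = object$intercept,
                                  slope = object$slope, linetype = 2)
  } else {
    p <- p + ggplot2::geom_vline(xintercept = object$centroid["x"],
                                 linetype = 2)
  }
  p
}
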