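#' Structure-property regression
#'
#' Ordinary least squares of `y` on `x`, with or without an intercept.
#' Adjusted R-squared is `1 - (1 - R2) * (n - 1) / (n - 2)` with an
#' intercept and `1 - (1 - R2) * n / (n - 1)` through the origin (the form
#' required for regressions on phylogenetic independent contrasts, which
#' are constrained through the origin); the p-value is the two-sided t-test
#' on the slope.
#'
#' @param data A data frame.
#' @param x,y Column names (tidy-select, e.g. bare names).
#' @param through_origin Fit without an intercept.
#' @return A `silk_regression` object; see [tidy()] and [glance()].
#' @export
silk_regress <- function(data, x, y, through_origin = FALSE) {
  xv <- dplyr::pull(data, {{ x }})
  yv <- dplyr::pull(data, {{ y }})
  keep <- stats::complete.cases(xv, yv)
  xv <- xv[keep]; yv <- yv[keep]
  n <- length(xv)
  min_n <- if (through_origin) 2L else 3L
  if (n < min_n) abort("too few complete observations to regress")
  fit <- if (through_origin) lm(yv ~ xv - 1) else lm(yv ~ xv)
  sm <- suppressWarnings(summary(fit))   # perfect fits warn harmlessly
  r2 <- sm$r.squared
  adj <- if (through_origin) 1 - (1 - r2) * n / (n - 1) else
    1 - (1 - r2) * (n - 1) / (n - 2)
  structure(
    list(slope = unname(coef(fit)[["xv"]]),
         intercept = if (through_origin) NA_real_ else
           unname(coef(fit)[["(Intercept)"]]),
         r_squared = r2,
         adjusted_r_squared = adj,
         p_value = unname(sm$coefficients["xv", "Pr(>|t|)"]),
         slope_se = unname(sm$coefficients["xv", "Std. Error"]),
         n = n,
         through_origin = through_origin,
         fit = fit,
         data = tibble(x = xv, y = yv)),
    class = "silk_regression")
}

#' @export
print.silk_regression <- function(x, ...) {
  cat("Linear fit", if (x$through_origin) "(through origin)" else "",
      "\n  slope =", signif(x$slope, 4))
  if (!is.na(x$intercept)) cat(", intercept =", signif(x$intercept, 4))
  cat("\n  adjusted R2 =", signif(x$adjusted_r_squared, 3),
      ", p =", signif(x$p_value, 3), ", n =", x$n, "\n")
  invisible(x)
}

#' @rdname silk_regress
#' @param x A `silk_regression` object.
#' @param ... Unused.
#' @export
tidy.silk_regression <- function(x, ...) {
  sm <- summary(x$fit)$coefficients
  tibble(term = ifelse(rownames(sm) == "xv", "x", "(Intercept)"),
         estimate = sm[, "Estimate"],
         std.error = sm[, "Std. Error"],
         statistic = sm[, "t value"],
         p.value = sm[, "Pr(>|t|)"])
}

#' @rdname silk_regress
#' @export
glance.silk_regression <- function(x, ...) {
  tibble(r.squared = x$r_squared,
         adj.r.squared = x$adjusted_r_squared,
         p.value = x$p_value,
         nobs = x$n,
         through.origin = x$through_origin)
}

#' Regression on phylogenetic independent contrasts
#'
#' Computes independent contrasts of `x` and `y` on the same tree (shared
#' pruning order) and regresses the `y` contrasts on the `x` contrasts
#' through the origin, the standard phylogenetically corrected
#' structure-property regression.
#'
#' @param tree A rooted binary `phylo` tree with branch lengths.
#' @param data A tibble with a tip-label column `id` and trait columns.
#' @param x,y Trait column names (tidy-select).
#' @return A `silk_regression` object with the contrast table in
#'   `$contrasts`.
#' @export
pic_regress <- function(tree, data, x, y) {
  stopifnot("id" %in% names(data))
  xv <- dplyr::pull(data, {{ x }})
  yv <- dplyr::pull(data, {{ y }})
  cx <- pic_contrasts(tree, tibble(id = data$id, value = xv))
  cy <- pic_contrasts(tree, tibble(id = data$id, value = yv))
  contrasts <- tibble(node = cx$node, x = cx$contrast, y = cy$contrast,
                      expected_variance = cx$expected_variance)
  fit <- silk_regress(contrasts, x, y, through_origin = TRUE)
  fit$contrasts <- contrasts
  fit
}
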