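# Robust summaries: medians with bootstrap percentile CIs, and agreement
# between the two overlap matrices.

#' Median with a bootstrap percentile confidence interval
#'
#' The median of `values` (even lengths: mean of the two central order
#' statistics) together with percentile bounds of the medians of `n_boot`
#' resamples drawn with replacement, each of the original size. The
#' resampling unit is whatever `values` holds — for overlap summaries,
#' the off-diagonal matrix cells.
#'
#' @param values Non-empty numeric vector.
#' @param n_boot Number of bootstrap resamples; default 1000.
#' @param level Confidence level in (0, 1); default 0.95.
#' @param seed Integer seed; recorded in the result. The global RNG state
#'   is left untouched.
#' @return A `median_ci` list: `median`, `ci_low`, `ci_high`, `level`,
#'   `n_boot`, `n`, `seed`.
#' @export
bootstrap_median_ci <- function(values, n_boot = 1000, level = 0.95,
                                seed = 1L) {
  values <- as.numeric(values)
  if (length(values) == 0) stop("empty input")
  stopifnot(level > 0, level < 1, n_boot >= 1)
  boots <- withr::with_seed(seed, {
    idx <- matrix(sample.int(length(values), length(values) * n_boot,
                             replace = TRUE),
                  nrow = n_boot)
    apply(idx, 1, function(i) median(values[i]))
  })
  alpha <- (1 - level) / 2
  ci <- unname(quantile(boots, c(alpha, 1 - alpha)))
  structure(list(median = median(values), ci_low = ci[1], ci_high = ci[2],
                 level = level, n_boot = as.integer(n_boot),
                 n = length(values), seed = as.integer(seed)),
            class = "median_ci")
}

#' @export
print.median_ci <- function(x, ...) {
  cat(sprintf("median %.3f [%g%% CI %.3f-%.3f] (n = %d, %d bootstrap resamples, seed %d)\n",
              x$median, 100 * x$level, x$ci_low, x$ci_high, x$n,
              x$n_boot, x$seed))
  invisible(x)
}

#' Agreement between two overlap matrices
#'
#' Pearson correlation (with two-sided p-value) over paired cells of two
#' overlap matrices with identical group ordering. By default the
#' conventionally-100 diagonal is excluded, leaving the 56 ordered
#' off-diagonal cells for eight groups. If either matrix has zero variance
#' over the used cells the correlation is reported as undefined rather
#' than propagating NaN.
#'
#' @param m1,m2 [overlap_matrix()] objects with the same groups in the
#'   same order.
#' @param include_diagonal Include the diagonal cells? Default `FALSE`.
#' @return A `matrix_agreement` list: `r`, `p`, `n_cells`, `undefined`.
#' @export
matrix_correlation <- function(m1, m2, include_diagonal = FALSE) {
  stopifnot(inherits(m1, "overlap_matrix"), inherits(m2, "overlap_matrix"))
  if (!identical(rownames(m1), rownames(m2))) {
    stop("matrices have mismatched group ordering")
  }
  if (include_diagonal) {
    v1 <- as.vector(unclass(m1)); v2 <- as.vector(unclass(m2))
  } else {
    v1 <- off_diagonal(m1); v2 <- off_diagonal(m2)
  }
  if (length(v1) < 3) stop("need at least 3 paired cells")
  if (sd(v1) == 0 || sd(v2) == 0) {
    return(structure(list(r = NA_real_, p = NA_real_, n_cells = length(v1),
                          undefined = TRUE),
                     class = "matrix_agreement"))
  }
  ct <- cor.test(v1, v2, method = "pearson")
  structure(list(r = unname(ct$estimate), p = ct$p.value,
                 n_cells = length(v1), undefined = FALSE),
            class = "matrix_agreement")
}

#' @export
print.matrix_agreement <- function(x, ...) {
  if (isTRUE(x$undefined)) {
    cat("matrix agreement: undefined (zero variance over",
        x$n_cells, "cells)\n")
  } else {
    cat(sprintf("matrix agreement: r = %.3f, p = %.3g (n = %d cells)\n",
                x$r, x$p, x$n_cells))
  }
  invisible(x)
}
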