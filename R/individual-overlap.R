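# Individual-level overlap: minimal delta E from each sample of a reference
# group to any sample of a comparison group, and the fraction of those
# minima below the perceptibility threshold.

#' Overlap matrix container
#'
#' A square matrix of percentages with rows as the reference group and
#' columns as the comparison group, tagged by the method that produced it
#' (`"individual"` or `"gamut"`).
#'
#' @param values Numeric square matrix of percentages in \[0, 100\].
#' @param groups Ordered character vector of group codes (row = column
#'   order).
#' @param method `"individual"` or `"gamut"`.
#' @return An `overlap_matrix`.
#' @export
overlap_matrix <- function(values, groups, method = c("individual", "gamut")) {
  method <- match.arg(method)
  values <- as.matrix(values)
  storage.mode(values) <- "double"
  if (nrow(values) != ncol(values)) stop("overlap matrix must be square")
  if (length(groups) != nrow(values)) stop("groups must match matrix size")
  if (anyDuplicated(groups)) stop("duplicate group codes")
  if (any(values < -1e-9 | values > 100 + 1e-9, na.rm = TRUE)) {
    stop("overlap percentages must lie in [0, 100]")
  }
  dimnames(values) <- list(groups, groups)
  structure(values, class = c("overlap_matrix", "matrix", "array"),
            method = method)
}

#' @export
print.overlap_matrix <- function(x, ...) {
  cat("<overlap_matrix> method:", attr(x, "method"),
      "| rows = reference group, columns = comparison group\n")
  print(round(unclass(x), 1))
  invisible(x)
}

#' Off-diagonal cells of an overlap matrix
#'
#' The diagonal is 100 by convention (a sample is indistinguishable from
#' itself) and is excluded from all medians and correlations; summaries run
#' over the ordered off-diagonal cells (56 for eight groups).
#'
#' @param m An `overlap_matrix`.
#' @return Numeric vector of off-diagonal values (row-major over ordered
#'   pairs).
#' @export
off_diagonal <- function(m) {
  stopifnot(inherits(m, "overlap_matrix"))
  v <- unclass(m)
  v[row(v) != col(v)]
}

#' Perceptibility threshold configuration
#'
#' The analysis threshold is a suprathreshold based on the perceptibility
#' threshold (just-noticeable difference), adopted at delta E*ab of about 2
#' so that differences at or above it are perceivable by a majority of
#' observers. (For context, maxillofacial skin replication studies report
#' PT around 1.1/1.6 and acceptability thresholds around 3.0/4.4 for
#' lighter/darker skin; those literature values are documentation constants
#' only and enter no computation here.)
#'
#' @param PT Threshold in delta E*ab units; must be > 0. Default 2.
#' @param strict If `TRUE` (default) a minimal difference counts as
#'   indistinguishable only when strictly below `PT`; set `FALSE` for a
#'   `<=` sensitivity analysis.
#' @return A `threshold_config` list.
#' @export
threshold_config <- function(PT = 2, strict = TRUE) {
  stopifnot(is.numeric(PT), length(PT) == 1, PT > 0)
  structure(list(PT = PT, strict = isTRUE(strict)),
            class = "threshold_config")
}

#' Minimal colour difference from each reference sample to a comparison set
#'
#' For every sample in the reference set, the exact minimum delta E*ab over
#' all samples of the comparison set (exhaustive scan in compiled code;
#' delta E*ab is Euclidean, so the minima are exact).
#'
#' @param reference,comparison n x 3 CIELAB matrices (or data frames with
#'   columns L, a, b).
#' @return A `min_distance_set`: list with `distances` (one minimum per
#'   reference sample) plus the set sizes.
#' @export
min_delta_e_profile <- function(reference, comparison) {
  ref <- .lab_matrix(reference, "reference")
  comp <- .lab_matrix(comparison, "comparison")
  if (nrow(ref) == 0) stop("reference group is empty")
  if (nrow(comp) == 0) stop("comparison group is empty")
  structure(list(distances = cpp_min_delta_e(ref, comp),
                 n_reference = nrow(ref), n_comparison = nrow(comp)),
            class = "min_distance_set")
}

.lab_matrix <- function(x, what) {
  if (inherits(x, "skin_dataset") || is.data.frame(x)) {
    x <- as.matrix(as.data.frame(x)[c("L", "a", "b")])
  }
  if (!is.matrix(x) || ncol(x) != 3) stop(what, " must be an n x 3 CIELAB matrix")
  storage.mode(x) <- "double"
  x
}

#' Fraction of minimal differences below the perceptibility threshold
#'
#' @param distances A [min_delta_e_profile()] result (or a bare numeric
#'   vector of minimal distances).
#' @param threshold A [threshold_config()].
#' @return Percentage in \[0, 100\]: 100 x (count below PT) / n.
#' @export
overlap_fraction <- function(distances, threshold = threshold_config()) {
  d <- if (inherits(distances, "min_distance_set")) distances$distances
       else as.numeric(distances)
  if (length(d) == 0) stop("no distances supplied")
  below <- if (threshold$strict) d < threshold$PT else d <= threshold$PT
  100 * mean(below)
}

#' Individual-level overlap matrix
#'
#' For every ordered pair of groups (reference rows, comparison columns),
#' the percentage of reference samples whose minimal delta E*ab to the
#' comparison group falls below the perceptibility threshold. The diagonal
#' is 100 by convention and excluded from downstream medians/correlations
#' (see [off_diagonal()]).
#'
#' @param dataset A [skin_dataset()] with at least two groups.
#' @param threshold A [threshold_config()].
#' @return An [overlap_matrix()] with `method = "individual"`.
#' @export
individual_overlap_matrix <- function(dataset,
                                      threshold = threshold_config()) {
  stopifnot(inherits(dataset, "skin_dataset"))
  groups <- levels(dataset$group)
  if (length(groups) < 2) stop("need at least two groups")
  labs <- lapply(groups, function(g) {
    .lab_matrix(dataset[dataset$group == g, ], g)
  })
  names(labs) <- groups
  k <- length(groups)
  vals <- matrix(100, k, k)
  for (i in seq_len(k)) {
    for (j in seq_len(k)) {
      if (i == j) next
      prof <- min_delta_e_profile(labs[[i]], labs[[j]])
      vals[i, j] <- overlap_fraction(prof, threshold)
    }
  }
  overlap_matrix(vals, groups, method = "individual")
}
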