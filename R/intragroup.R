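# Within-group variation: CIELAB moments per group, mean colour difference
# to the group centroid, and the ethnicity x gender ANOVA.

#' Per-group CIELAB summary
#'
#' For each group: sample count, mean and SD of L*, a*, b* and of
#' per-sample chroma C*, and the mean (with SD) delta E*ab between each
#' sample and the group's mean colour — a perceptually meaningful measure
#' of within-group variation. The centroid is the arithmetic mean of
#' (L*, a*, b*); chroma is summarised over per-sample values, not derived
#' from the mean colour.
#'
#' @param dataset A [skin_dataset()]; every group needs at least two
#'   samples.
#' @return Tibble with one row per group: `group`, `n`, `mean_L`, `sd_L`,
#'   `mean_a`, `sd_a`, `mean_b`, `sd_b`, `mean_C`, `sd_C`, `mean_dE`,
#'   `sd_dE`.
#' @export
summarize_groups <- function(dataset) {
  stopifnot(inherits(dataset, "skin_dataset"))
  groups <- levels(dataset$group)
  small <- groups[table(dataset$group)[groups] < 2]
  if (length(small)) {
    stop("group(s) with fewer than 2 samples: ",
         paste(small, collapse = ", "))
  }
  rows <- lapply(groups, function(g) {
    lab <- as.matrix(as.data.frame(dataset[dataset$group == g,
                                           c("L", "a", "b")]))
    centroid <- colMeans(lab)
    cstar <- chroma(lab)
    de <- delta_e_ab(lab, centroid)
    tibble::tibble(
      group = g, n = nrow(lab),
      mean_L = centroid[[1]], sd_L = sd(lab[, 1]),
      mean_a = centroid[[2]], sd_a = sd(lab[, 2]),
      mean_b = centroid[[3]], sd_b = sd(lab[, 3]),
      mean_C = mean(cstar), sd_C = sd(cstar),
      mean_dE = mean(de), sd_dE = sd(de)
    )
  })
  do.call(rbind, rows)
}

#' Two-way ethnicity x gender ANOVA for one CIELAB attribute
#'
#' Fixed-effects two-way ANOVA with interaction on a single attribute,
#' treating measurements as independent observations. Sums of squares are
#' Type II by default — main effects are not biased by the interaction
#' under the unbalanced designs typical of archive data — with Type III
#' available (fitted under sum-to-zero contrasts). The effect size is
#' partial eta-squared, `SS_effect / (SS_effect + SS_residual)`.
#'
#' @param dataset A [skin_dataset()] with at least two groups and both
#'   genders present in every group.
#' @param attribute One of `"L"`, `"a"`, `"b"` (also accepts `"C"` for
#'   per-sample chroma).
#' @param ss_type `2` (default) or `3`.
#' @return Tibble with one row per term (`group`, `gender`,
#'   `group:gender`, `Residuals`): `df`, `sumsq`, `statistic` (F),
#'   `p.value`, `partial_eta_sq`.
#' @export
anova_two_way <- function(dataset, attribute = c("L", "a", "b", "C"),
                          ss_type = 2) {
  stopifnot(inherits(dataset, "skin_dataset"))
  attribute <- match.arg(attribute)
  if (nlevels(dataset$group) < 2) stop("need at least two groups")
  tab <- table(dataset$group, dataset$gender)
  if (any(tab == 0)) {
    bad <- which(tab == 0, arr.ind = TRUE)
    stop("empty group x gender cell(s): ",
         paste(rownames(tab)[bad[, 1]], colnames(tab)[bad[, 2]],
               sep = "/", collapse = ", "))
  }
  df <- data.frame(
    value = if (attribute == "C") chroma(as.data.frame(dataset[c("L", "a", "b")]))
            else dataset[[attribute]],
    group = dataset$group,
    gender = droplevels(dataset$gender)
  )
  if (nrow(df) <= nlevels(df$group) * nlevels(df$gender)) {
    stop("more cells than observations")
  }
  contr <- if (ss_type == 3) {
    list(group = "contr.sum", gender = "contr.sum")
  } else NULL
  fit <- lm(value ~ group * gender, data = df, contrasts = contr)
  a <- car::Anova(fit, type = ss_type)
  a <- as.data.frame(a)
  ss_res <- a["Residuals", "Sum Sq"]
  terms_keep <- rownames(a)
  tibble::tibble(
    term = terms_keep,
    df = a$Df,
    sumsq = a$`Sum Sq`,
    statistic = a$`F value`,
    p.value = a$`Pr(>F)`,
    partial_eta_sq = ifelse(terms_keep == "Residuals", NA_real_,
                            a$`Sum Sq` / (a$`Sum Sq` + ss_res))
  )
}

#' Subject-aggregated view of a dataset
#'
#' Collapses measurements to one mean colour per subject, for sensitivity
#' analyses of the default per-measurement treatment (subjects contribute
#' about ten sites each, so measurements are not strictly independent).
#'
#' @param dataset A [skin_dataset()].
#' @return A [skin_dataset()] with one row per subject (body_site set to
#'   the first site observed; age averaged).
#' @export
aggregate_subjects <- function(dataset) {
  stopifnot(inherits(dataset, "skin_dataset"))
  sp <- split(as.data.frame(dataset), dataset$subject_id)
  rows <- lapply(sp, function(d) {
    data.frame(subject_id = d$subject_id[1],
               group = as.character(d$group[1]),
               gender = as.character(d$gender[1]),
               age = mean(d$age),
               body_site = as.character(d$body_site[1]),
               L = mean(d$L), a = mean(d$a), b = mean(d$b))
  })
  out <- do.call(rbind, rows)
  prov <- attr(dataset, "provenance")
  prov$aggregated <- "per subject"
  skin_dataset(out, provenance = prov)
}
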