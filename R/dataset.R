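# Reading, validating and filtering ISSA-style measurement tables.
#
# A skin_dataset is a tibble (one row per measurement) with columns
# subject_id, group, gender, age, body_site, L, a, b, carrying provenance
# (source path or generator config + seed) as an attribute. Colour always
# lives in CIELAB by the time a dataset exists; raw XYZ or spectra are
# converted on read.

#' Ethnic group codes, body sites and genders accepted by the schema
#'
#' `group_codes()` returns the eight self-identified ethnic group codes
#' (CA Caucasian, CN Chinese, JP Japanese, SA South Asian-Pakistani,
#' AF African, IQ Middle Eastern-Iraqi, TH Southeast Asian-Thai,
#' AB Middle Eastern-Arabian). `body_sites()` returns the controlled
#' vocabulary of measurement positions (the published list names thirteen
#' positions for "twelve body positions" because both forearm faces are
#' listed; the schema accepts every listed name). `genders()` returns the
#' recorded gender labels.
#'
#' @return Character vector.
#' @export
group_codes <- function() GROUP_CODES

#' @rdname group_codes
#' @export
body_sites <- function() BODY_SITES

#' @rdname group_codes
#' @export
genders <- function() GENDERS

#' Construct and validate a skin measurement dataset
#'
#' @param samples Data frame with columns `subject_id`, `group`, `gender`,
#'   `age` (years, may be NA), `body_site`, `L`, `a`, `b`.
#' @param provenance List describing where the samples came from (source
#'   path, or generator scenario + seed).
#' @return A `skin_dataset`: a tibble with the columns above, `group` and
#'   `gender` as factors over the controlled vocabularies.
#' @export
skin_dataset <- function(samples, provenance = list(source = "unknown")) {
  required <- c("subject_id", "group", "gender", "age", "body_site",
                "L", "a", "b")
  missing_cols <- setdiff(required, names(samples))
  if (length(missing_cols)) {
    stop("missing required column(s): ", paste(missing_cols, collapse = ", "))
  }
  samples <- tibble::as_tibble(samples)[required]
  if (nrow(samples) == 0) stop("dataset has no samples")

  bad_group <- !samples$group %in% GROUP_CODES
  if (any(bad_group)) {
    stop("unknown group code(s) at row(s) ",
         paste(head(which(bad_group), 5), collapse = ", "), ": ",
         paste(unique(samples$group[bad_group]), collapse = ", "))
  }
  bad_site <- !samples$body_site %in% BODY_SITES
  if (any(bad_site)) {
    stop("unknown body site(s) at row(s) ",
         paste(head(which(bad_site), 5), collapse = ", "), ": ",
         paste(unique(samples$body_site[bad_site]), collapse = ", "))
  }
  bad_gender <- !samples$gender %in% GENDERS
  if (any(bad_gender)) {
    stop("unknown gender label(s) at row(s) ",
         paste(head(which(bad_gender), 5), collapse = ", "), ": ",
         paste(unique(samples$gender[bad_gender]), collapse = ", "))
  }
  lab <- as.matrix(samples[c("L", "a", "b")])
  if (any(!is.finite(lab))) {
    stop("non-finite CIELAB value(s) at row(s) ",
         paste(head(which(rowSums(!is.finite(lab)) > 0), 5), collapse = ", "))
  }
  samples$group <- factor(samples$group,
                          levels = GROUP_CODES[GROUP_CODES %in% samples$group])
  samples$gender <- factor(samples$gender, levels = GENDERS)
  samples$age <- as.numeric(samples$age)
  structure(samples,
            class = c("skin_dataset", class(tibble::tibble())),
            provenance = provenance)
}

#' @export
print.skin_dataset <- function(x, ...) {
  cat("<skin_dataset> ", nrow(x), " measurements, ",
      nlevels(x$group), " group(s), ",
      length(unique(x$subject_id)), " subject(s)\n", sep = "")
  NextMethod()
}

#' Per-group measurement and subject tallies
#'
#' @param dataset A [skin_dataset()].
#' @return Tibble with columns `group`, `n_samples`, `n_subjects`.
#' @export
group_counts <- function(dataset) {
  stopifnot(inherits(dataset, "skin_dataset"))
  g <- levels(dataset$group)
  tibble::tibble(
    group = g,
    n_samples = as.integer(table(dataset$group)[g]),
    n_subjects = vapply(
      g, function(k) length(unique(dataset$subject_id[dataset$group == k])),
      integer(1), USE.NAMES = FALSE)
  )
}

# Apply a header-mapping config: `col_map` maps standard name -> file header.
.apply_col_map <- function(df, col_map) {
  if (is.null(col_map)) return(df)
  for (std in names(col_map)) {
    if (!col_map[[std]] %in% names(df)) {
      stop("column mapping refers to absent header '", col_map[[std]], "'")
    }
    names(df)[names(df) == col_map[[std]]] <- std
  }
  df
}

.meta_columns <- function(df, path) {
  meta <- c("subject_id", "group", "gender", "body_site")
  missing_cols <- setdiff(meta, names(df))
  if (length(missing_cols)) {
    stop("file ", path, " lacks required column(s): ",
         paste(missing_cols, collapse = ", "))
  }
  if (!"age" %in% names(df)) df$age <- NA_real_
  df
}

#' Read an ISSA-style measurement table
#'
#' Reads a CSV of skin colour measurements and returns a validated
#' [skin_dataset()]. Three dialects are supported:
#'
#' * `lab_csv` — columns `L`, `a`, `b` already in CIELAB;
#' * `xyz_csv` — columns `X`, `Y`, `Z` (Y = 100 scale), converted via
#'   [xyz_to_lab()];
#' * `spectra_csv` — wide form with one reflectance column per wavelength
#'   (headers like `nm_400` or `400`), or long form with columns
#'   `measurement_id`, `wavelength`, `reflectance`; converted via
#'   [spectrum_to_xyz()] and the matching [spectral_white_point()].
#'
#' All dialects also carry `subject_id`, `group`, `gender`, `body_site` and
#' optionally `age`. Unknown group/site/gender codes abort with the row
#' numbers and offending values.
#'
#' @param path CSV file path.
#' @param format One of `"lab_csv"`, `"xyz_csv"`, `"spectra_csv"`.
#' @param illuminant,observer Colorimetry settings for raw formats.
#' @param col_map Optional named character vector mapping standard column
#'   names to the file's headers, e.g. `c(group = "ethnicity")`.
#' @return A [skin_dataset()].
#' @export
read_dataset <- function(path,
                         format = c("lab_csv", "xyz_csv", "spectra_csv"),
                         illuminant = "D65", observer = "2deg",
                         col_map = NULL) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path)
  df <- utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  if (nrow(df) == 0) stop("empty file: ", path)
  df <- .apply_col_map(df, col_map)

  if (format == "lab_csv") {
    df <- .meta_columns(df, path)
    missing_cols <- setdiff(c("L", "a", "b"), names(df))
    if (length(missing_cols)) {
      stop("lab_csv requires columns L, a, b; missing: ",
           paste(missing_cols, collapse = ", "))
    }
  } else if (format == "xyz_csv") {
    df <- .meta_columns(df, path)
    missing_cols <- setdiff(c("X", "Y", "Z"), names(df))
    if (length(missing_cols)) {
      stop("xyz_csv requires columns X, Y, Z; missing: ",
           paste(missing_cols, collapse = ", "))
    }
    lab <- xyz_to_lab(as.matrix(df[c("X", "Y", "Z")]),
                      white = white_point(illuminant, observer),
                      ids = seq_len(nrow(df)))
    df$L <- lab[, "L"]; df$a <- lab[, "a"]; df$b <- lab[, "b"]
  } else {
    df <- .read_spectra(df, path, illuminant)
  }

  skin_dataset(df, provenance = list(source = normalizePath(path),
                                     format = format,
                                     illuminant = illuminant,
                                     observer = observer))
}

# Spectra dialects share the conversion: spectrum -> XYZ -> CIELAB under the
# computed spectral white point, so a unit reflector reads back as L* = 100.
.read_spectra <- function(df, path, illuminant) {
  white <- spectral_white_point(illuminant)
  if (all(c("wavelength", "reflectance") %in% names(df))) {
    if (!"measurement_id" %in% names(df)) {
      stop("long spectra_csv requires a measurement_id column")
    }
    meta_cols <- intersect(
      c("measurement_id", "subject_id", "group", "gender", "age",
        "body_site"), names(df))
    ids <- unique(df$measurement_id)
    rows <- lapply(ids, function(id) {
      block <- df[df$measurement_id == id, ]
      meta <- unique(block[setdiff(meta_cols, "measurement_id")])
      if (nrow(meta) != 1) {
        stop("inconsistent metadata within measurement_id '", id, "'")
      }
      sp <- reflectance_spectrum(block$wavelength, block$reflectance)
      lab <- xyz_to_lab(spectrum_to_xyz(sp, illuminant), white, ids = id)
      cbind(meta, L = lab[["L"]], a = lab[["a"]], b = lab[["b"]])
    })
    out <- do.call(rbind, rows)
  } else {
    wl_cols <- grep("^(nm_)?[0-9]+(\\.[0-9]+)?$", names(df), value = TRUE)
    if (length(wl_cols) < 2) {
      stop("wide spectra_csv needs wavelength columns (headers like ",
           "'nm_400' or '400'); none recognised in ", path)
    }
    wl <- as.numeric(sub("^nm_", "", wl_cols))
    ord <- order(wl)
    wl <- wl[ord]; wl_cols <- wl_cols[ord]
    refl <- as.matrix(df[wl_cols])
    lab <- t(vapply(seq_len(nrow(df)), function(i) {
      sp <- reflectance_spectrum(wl, refl[i, ])
      xyz_to_lab(spectrum_to_xyz(sp, illuminant), white, ids = i)
    }, numeric(3)))
    out <- df[setdiff(names(df), wl_cols)]
    out$L <- lab[, 1]; out$a <- lab[, 2]; out$b <- lab[, 3]
  }
  .meta_columns(out, path)
}

#' Drop measurements from excluded body sites
#'
#' The reference analysis excludes the ear lobe and ring finger positions,
#' whose coverage is incomplete across collection sites, reducing the
#' twelve measured positions to ten. The exclusion is a default, not a
#' hard-coded rule.
#'
#' @param dataset A [skin_dataset()].
#' @param excluded Character vector of body sites to drop (from the
#'   controlled vocabulary). Default `c("ear lobe", "ring finger")`.
#' @return The filtered [skin_dataset()]; retained records are unchanged.
#' @export
filter_sites <- function(dataset, excluded = c("ear lobe", "ring finger")) {
  stopifnot(inherits(dataset, "skin_dataset"))
  bad <- setdiff(excluded, BODY_SITES)
  if (length(bad)) {
    stop("excluded site(s) not in the controlled vocabulary: ",
         paste(bad, collapse = ", "))
  }
  drop <- dataset$body_site %in% excluded
  message("filter_sites: removed ", sum(drop), " of ", nrow(dataset),
          " measurements (excluded: ",
          if (length(excluded)) paste(excluded, collapse = ", ") else "none",
          ")")
  kept <- dataset[!drop, ]
  prov <- attr(dataset, "provenance")
  prov$excluded_sites <- excluded
  skin_dataset(kept, provenance = prov)
}

# ---- result serialisation --------------------------------------------------

.fmt_num <- function(x) {
  # 6 significant digits, plain (non-scientific) where possible
  ifelse(is.na(x), NA, format(signif(x, 6), trim = TRUE, scientific = FALSE))
}

#' Write an overlap matrix to CSV / read it back
#'
#' Rows are labelled by the reference group, columns by the comparison
#' group. Matrices are serialised at full precision (write/read
#' round-trips agree to 1e-12); `write_outputs()` additionally emits a
#' 1-decimal-place copy for reporting.
#'
#' @param m An `overlap_matrix`.
#' @param path Output CSV path.
#' @return `write_overlap_matrix` returns `path` invisibly;
#'   `read_overlap_matrix` returns an `overlap_matrix`.
#' @export
write_overlap_matrix <- function(m, path) {
  stopifnot(inherits(m, "overlap_matrix"))
  df <- data.frame(reference = rownames(m), unclass(m),
                   check.names = FALSE)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_overlap_matrix
#' @param method Overlap method tag to attach on read.
#' @export
read_overlap_matrix <- function(path, method = "individual") {
  df <- utils::read.csv(path, check.names = FALSE)
  vals <- as.matrix(df[, -1, drop = FALSE])
  rownames(vals) <- df[[1]]
  overlap_matrix(vals, groups = df[[1]], method = method)
}

#' Write the full result set of an analysis
#'
#' Deterministic CSV exports: the group summary table, both overlap
#' matrices, one ANOVA table per attribute, and the median/CI report.
#' Numbers carry 6 significant digits; percentage matrices are additionally
#' exported rounded to 1 decimal place (`*_1dp.csv`) to mirror the usual
#' reporting precision.
#'
#' @param results Named list with any of `group_summary`,
#'   `individual_matrix`, `gamut_matrix`, `anova` (named list of tables),
#'   `medians` (list of `median_ci`), `agreement`.
#' @param dir Output directory (created if needed).
#' @return Invisible character vector of files written.
#' @export
write_outputs <- function(results, dir) {
  if (!dir.exists(dir)) {
    ok <- dir.create(dir, recursive = TRUE, showWarnings = FALSE)
    if (!ok) stop("cannot create output directory: ", dir)
  }
  if (file.access(dir, 2) != 0) stop("output directory not writable: ", dir)
  files <- character(0)
  put <- function(df, name) {
    p <- file.path(dir, name)
    num <- vapply(df, is.numeric, logical(1))
    df[num] <- lapply(df[num], .fmt_num)
    utils::write.csv(df, p, row.names = FALSE, quote = FALSE)
    files <<- c(files, p)
  }
  if (!is.null(results$group_summary)) {
    put(as.data.frame(results$group_summary), "group_summary.csv")
  }
  for (nm in c("individual_matrix", "gamut_matrix")) {
    m <- results[[nm]]
    if (is.null(m)) next
    p <- file.path(dir, paste0(nm, ".csv"))
    write_overlap_matrix(m, p)
    files <- c(files, p)
    rounded <- overlap_matrix(round(unclass(m), 1), groups = rownames(m),
                              method = attr(m, "method"))
    p1 <- file.path(dir, paste0(nm, "_1dp.csv"))
    write_overlap_matrix(rounded, p1)
    files <- c(files, p1)
  }
  if (!is.null(results$anova)) {
    for (attr_name in names(results$anova)) {
      put(as.data.frame(results$anova[[attr_name]]),
          paste0("anova_", attr_name, ".csv"))
    }
  }
  if (!is.null(results$medians)) {
    rows <- lapply(names(results$medians), function(k) {
      ci <- results$medians[[k]]
      data.frame(statistic = k, median = ci$median, ci_low = ci$ci_low,
                 ci_high = ci$ci_high, level = ci$level,
                 n_boot = ci$n_boot, seed = ci$seed)
    })
    put(do.call(rbind, rows), "median_ci.csv")
  }
  if (!is.null(results$agreement)) {
    ag <- results$agreement
    put(data.frame(r = ag$r, p = ag$p, n_cells = ag$n_cells,
                   undefined = isTRUE(ag$undefined)),
        "matrix_agreement.csv")
  }
  invisible(files)
}
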