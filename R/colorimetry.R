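# Colorimetry: reflectance spectra -> XYZ -> CIELAB, chroma, delta E.
#
# All statistics downstream of this file live in CIELAB; colours are plain
# numeric length-3 vectors (L*, a*, b*) or n x 3 matrices with columns in
# that order, which keeps them trivially compatible with data frames.

# CIE standard illuminant white points (Y = 100), exact published constants.
.WHITE_POINTS <- list(
  D65 = list(`2deg` = c(X = 95.047, Y = 100, Z = 108.883),
             `10deg` = c(X = 94.811, Y = 100, Z = 107.304)),
  D50 = list(`2deg` = c(X = 96.422, Y = 100, Z = 82.521),
             `10deg` = c(X = 96.720, Y = 100, Z = 81.427)),
  A   = list(`2deg` = c(X = 109.850, Y = 100, Z = 35.585),
             `10deg` = c(X = 111.144, Y = 100, Z = 35.200)),
  E   = list(`2deg` = c(X = 100, Y = 100, Z = 100),
             `10deg` = c(X = 100, Y = 100, Z = 100))
)

# CIE standard illuminant D65 relative spectral power distribution,
# 400-700 nm at 10 nm (standard published table, normalised to 100 at 560 nm).
.D65_SPD <- c(
  `400` = 82.75, `410` = 91.49, `420` = 93.43, `430` = 86.68,
  `440` = 104.86, `450` = 117.01, `460` = 117.81, `470` = 114.86,
  `480` = 115.92, `490` = 108.81, `500` = 109.35, `510` = 107.80,
  `520` = 104.79, `530` = 107.69, `540` = 104.41, `550` = 104.05,
  `560` = 100.00, `570` = 96.33, `580` = 95.79, `590` = 88.69,
  `600` = 90.01, `610` = 89.60, `620` = 87.70, `630` = 83.29,
  `640` = 83.70, `650` = 80.03, `660` = 80.21, `670` = 82.28,
  `680` = 78.28, `690` = 69.72, `700` = 71.61
)

#' Reference white point for an illuminant/observer pair
#'
#' Returns the CIE tristimulus values of the reference white on the scale
#' where Y = 100, used by [xyz_to_lab()].
#'
#' @param illuminant Illuminant label: `"D65"` (default), `"D50"`, `"A"` or
#'   `"E"` (equal energy).
#' @param observer Standard observer label: `"2deg"` (CIE 1931, default) or
#'   `"10deg"` (CIE 1964).
#' @return Named numeric vector `c(X, Y, Z)` with `Y = 100`.
#' @examples
#' white_point()                 # D65, 2 degree
#' white_point("D65", "10deg")
#' @export
white_point <- function(illuminant = "D65", observer = c("2deg", "10deg")) {
  observer <- match.arg(observer)
  if (!illuminant %in% names(.WHITE_POINTS)) {
    stop("unknown illuminant '", illuminant, "'; available: ",
         paste(names(.WHITE_POINTS), collapse = ", "))
  }
  wp <- .WHITE_POINTS[[illuminant]][[observer]]
  structure(wp, illuminant = illuminant, observer = observer)
}

#' Construct a reflectance spectrum
#'
#' @param wavelengths Numeric vector of wavelengths in nm; strictly
#'   increasing on a uniform grid.
#' @param reflectance Numeric vector of spectral reflectance factors,
#'   nominally in \[0, 1\] (values up to 1.2 are tolerated, allowing for
#'   measurement noise at fluorescent edges).
#' @return A `reflectance_spectrum` object (list with `wavelengths` and
#'   `reflectance`).
#' @export
reflectance_spectrum <- function(wavelengths, reflectance) {
  wavelengths <- as.numeric(wavelengths)
  reflectance <- as.numeric(reflectance)
  if (length(wavelengths) < 2 || length(wavelengths) != length(reflectance)) {
    stop("wavelengths and reflectance must have equal length >= 2")
  }
  steps <- diff(wavelengths)
  if (any(steps <= 0)) stop("wavelengths must be strictly increasing")
  if (max(steps) - min(steps) > 1e-6) {
    stop("wavelength grid must be uniform; observed steps range from ",
         min(steps), " to ", max(steps), " nm")
  }
  if (any(!is.finite(reflectance)) || any(reflectance < 0)) {
    stop("reflectance must be finite and non-negative")
  }
  if (any(reflectance > 1.2)) {
    stop("reflectance above 1.2 is physically implausible (max observed ",
         signif(max(reflectance), 4), ")")
  }
  structure(list(wavelengths = wavelengths, reflectance = reflectance),
            class = "reflectance_spectrum")
}

# Piecewise-Gaussian lobe used by the analytic CIE 1931 colour-matching
# function fit (Wyman-Sloan-Shirley multi-lobe form).
.cmf_lobe <- function(x, mu, s1, s2) {
  s <- ifelse(x < mu, s1, s2)
  exp(-0.5 * ((x - mu) / s)^2)
}

#' CIE 1931 colour-matching functions (analytic approximation)
#'
#' Evaluates the 2-degree standard observer colour-matching functions at the
#' requested wavelengths using the published multi-lobe piecewise-Gaussian
#' analytic fit (accurate to about 1% of peak), avoiding bundled tables.
#'
#' @param wavelengths Numeric vector of wavelengths in nm.
#' @param observer Only `"2deg"` is available for spectral integration; the
#'   10-degree observer is supported at the white-point level only (see
#'   [white_point()]).
#' @return Matrix with columns `xbar`, `ybar`, `zbar`.
#' @export
cie_cmf <- function(wavelengths, observer = "2deg") {
  if (!identical(observer, "2deg")) {
    stop("colour-matching functions are available for the '2deg' observer ",
         "only; the '10deg' observer is supported at the white-point level")
  }
  x <- 1.056 * .cmf_lobe(wavelengths, 599.8, 37.9, 31.0) +
       0.362 * .cmf_lobe(wavelengths, 442.0, 16.0, 26.7) -
       0.065 * .cmf_lobe(wavelengths, 501.1, 20.4, 26.2)
  y <- 0.821 * .cmf_lobe(wavelengths, 568.8, 46.9, 40.5) +
       0.286 * .cmf_lobe(wavelengths, 530.9, 16.3, 31.1)
  z <- 1.217 * .cmf_lobe(wavelengths, 437.0, 11.8, 36.0) +
       0.681 * .cmf_lobe(wavelengths, 459.0, 26.0, 13.8)
  cbind(xbar = x, ybar = y, zbar = z)
}

# Relative spectral power of an illuminant on a wavelength grid.
.illuminant_spd <- function(illuminant, wavelengths) {
  if (illuminant == "D65") {
    key <- as.character(round(wavelengths))
    if (any(!key %in% names(.D65_SPD))) {
      stop("D65 table is tabulated on the 10 nm grid 400-700 nm; ",
           "requested wavelengths must align with it")
    }
    unname(.D65_SPD[key])
  } else if (illuminant == "A") {
    # Planckian radiator at T = 2848 K with c2 = 1.435e-2 m K (CIE definition)
    c2 <- 1.435e-2
    l <- wavelengths * 1e-9
    s <- 100 * (560e-9 / l)^5 *
      (exp(c2 / (2848 * 560e-9)) - 1) / (exp(c2 / (2848 * l)) - 1)
    s
  } else if (illuminant == "E") {
    rep(100, length(wavelengths))
  } else {
    stop("no spectral power distribution available for illuminant '",
         illuminant, "'; use D65, A or E for spectral integration")
  }
}

#' Integrate a reflectance spectrum to XYZ tristimulus values
#'
#' Standard tristimulus integration over 400-700 nm at a 10 nm step
#' (rectangular rule) with the normalisation chosen so that a perfect (unit)
#' reflector returns the illuminant white point with Y = 100. Finer input
#' grids are down-sampled by exact alignment to the 10 nm grid.
#'
#' @param spectrum A [reflectance_spectrum()].
#' @param illuminant Illuminant label (`"D65"`, `"A"` or `"E"`).
#' @param observer Observer label; `"2deg"` only for the spectral path.
#' @return Named numeric vector `c(X, Y, Z)` on the Y = 100 scale.
#' @export
spectrum_to_xyz <- function(spectrum, illuminant = "D65", observer = "2deg") {
  stopifnot(inherits(spectrum, "reflectance_spectrum"))
  grid <- seq(400, 700, by = 10)
  lo <- min(spectrum$wavelengths)
  hi <- max(spectrum$wavelengths)
  if (lo > 400 || hi < 700) {
    miss <- c(
      if (lo > 400) paste0("400-", min(hi, lo), " nm"),
      if (hi < 700) paste0(max(lo, hi), "-700 nm")
    )
    stop("spectrum must cover 400-700 nm; missing ",
         paste(miss, collapse = " and "))
  }
  idx <- match(grid, spectrum$wavelengths)
  if (any(is.na(idx))) {
    stop("spectrum grid does not align with the 10 nm integration grid ",
         "(first missing wavelength: ", grid[which(is.na(idx))[1]], " nm)")
  }
  refl <- spectrum$reflectance[idx]
  spd <- .illuminant_spd(illuminant, grid)
  cmf <- cie_cmf(grid, observer)
  k <- 100 / sum(spd * cmf[, "ybar"])
  c(
    X = k * sum(spd * refl * cmf[, "xbar"]),
    Y = k * sum(spd * refl * cmf[, "ybar"]),
    Z = k * sum(spd * refl * cmf[, "zbar"])
  )
}

#' White point of the spectral integration path
#'
#' The XYZ of a perfect reflector under [spectrum_to_xyz()]'s integration.
#' Use this (rather than the published constants of [white_point()]) as the
#' reference white when CIELAB values are derived from spectra, so that a
#' unit reflector maps exactly to L* = 100.
#'
#' @inheritParams spectrum_to_xyz
#' @return Named numeric vector `c(X, Y, Z)` with `Y = 100`.
#' @export
spectral_white_point <- function(illuminant = "D65", observer = "2deg") {
  grid <- seq(400, 700, by = 10)
  wp <- spectrum_to_xyz(reflectance_spectrum(grid, rep(1, length(grid))),
                        illuminant, observer)
  structure(wp, illuminant = illuminant, observer = observer)
}

# Accept a length-3 vector or an n x 3 matrix/data.frame; return n x 3 matrix
# plus a flag to restore vector shape.
.as_triplet_matrix <- function(x, what) {
  if (is.data.frame(x)) x <- as.matrix(x)
  if (is.matrix(x)) {
    if (ncol(x) != 3) stop(what, " must have exactly 3 columns")
    list(m = x, vec = FALSE)
  } else {
    if (length(x) != 3) stop(what, " must have length 3")
    list(m = matrix(as.numeric(x), 1, 3), vec = TRUE)
  }
}

# CIE 1976 nonlinearity: cube root above t0 = (6/29)^3, linear below.
.lab_f <- function(t) {
  delta <- 6 / 29
  ifelse(t > delta^3, t^(1 / 3), t / (3 * delta^2) + 4 / 29)
}

.lab_f_inv <- function(ft) {
  delta <- 6 / 29
  ifelse(ft > delta, ft^3, 3 * delta^2 * (ft - 4 / 29))
}

#' Convert XYZ tristimulus values to CIELAB
#'
#' Standard CIE 1976 L*a*b* transform with the linear segment below
#' t = (6/29)^3. Results are never clamped: L* outside \[0, 100\] (possible
#' only for non-reflective inputs) triggers a warning naming the offending
#' rows.
#'
#' @param xyz Length-3 vector `c(X, Y, Z)` or n x 3 matrix, on the scale
#'   where the reference white has Y = 100.
#' @param white Reference white, as returned by [white_point()] or
#'   [spectral_white_point()].
#' @param ids Optional identifiers used in the out-of-range warning.
#' @return `c(L, a, b)` vector or n x 3 matrix matching the input shape.
#' @examples
#' xyz_to_lab(white_point())              # L* = 100, neutral
#' xyz_to_lab(c(18, 18, 18) * white_point() / 100)
#' @export
xyz_to_lab <- function(xyz, white = white_point(), ids = NULL) {
  tri <- .as_triplet_matrix(xyz, "xyz")
  m <- tri$m
  if (any(!is.finite(m))) stop("tristimulus values must be finite")
  if (any(m < 0)) stop("negative tristimulus component")
  stopifnot(length(white) == 3, all(white > 0))
  fx <- .lab_f(m[, 1] / white[[1]])
  fy <- .lab_f(m[, 2] / white[[2]])
  fz <- .lab_f(m[, 3] / white[[3]])
  lab <- cbind(L = 116 * fy - 16, a = 500 * (fx - fy), b = 200 * (fy - fz))
  out <- lab[, 1] < 0 | lab[, 1] > 100
  if (any(out)) {
    bad <- if (is.null(ids)) which(out) else ids[out]
    warning("L* outside [0, 100] for record(s): ",
            paste(utils::head(bad, 5), collapse = ", "),
            if (sum(out) > 5) " ..." else "")
  }
  if (tri$vec) lab[1, ] else lab
}

#' Convert CIELAB to XYZ (inverse transform)
#'
#' @param lab `c(L, a, b)` vector or n x 3 matrix.
#' @inheritParams xyz_to_lab
#' @return `c(X, Y, Z)` vector or n x 3 matrix on the Y = 100 scale.
#' @export
lab_to_xyz <- function(lab, white = white_point()) {
  tri <- .as_triplet_matrix(lab, "lab")
  m <- tri$m
  fy <- (m[, 1] + 16) / 116
  fx <- fy + m[, 2] / 500
  fz <- fy - m[, 3] / 200
  xyz <- cbind(X = white[[1]] * .lab_f_inv(fx),
               Y = white[[2]] * .lab_f_inv(fy),
               Z = white[[3]] * .lab_f_inv(fz))
  if (tri$vec) xyz[1, ] else xyz
}

#' Chroma of a CIELAB colour
#'
#' C* = sqrt(a*^2 + b*^2), the distance from the neutral axis in the a*b*
#' plane; perceived colourfulness.
#'
#' @param lab `c(L, a, b)` vector or n x 3 matrix.
#' @return Non-negative numeric vector of chroma values.
#' @examples
#' chroma(c(50, 3, 4))  # 5
#' @export
chroma <- function(lab) {
  tri <- .as_triplet_matrix(lab, "lab")
  sqrt(tri$m[, 2]^2 + tri$m[, 3]^2)
}

#' Perceptual colour difference delta E*ab
#'
#' The classic CIE 1976 colour difference: Euclidean distance between two
#' colours in CIELAB. Symmetric, and zero exactly when the colours are
#' identical (to within 1e-12 absolute).
#'
#' @param c1,c2 `c(L, a, b)` vectors or n x 3 matrices (recycled rowwise if
#'   one argument is a single colour).
#' @return Numeric vector of distances.
#' @examples
#' delta_e_ab(c(50, 10, 15), c(53, 14, 27))  # 13
#' @export
delta_e_ab <- function(c1, c2) {
  m1 <- .as_triplet_matrix(c1, "c1")$m
  m2 <- .as_triplet_matrix(c2, "c2")$m
  if (nrow(m1) != nrow(m2)) {
    if (nrow(m1) == 1) m1 <- m1[rep(1, nrow(m2)), , drop = FALSE]
    else if (nrow(m2) == 1) m2 <- m2[rep(1, nrow(m1)), , drop = FALSE]
    else stop("c1 and c2 must have the same number of rows")
  }
  d <- sqrt(rowSums((m1 - m2)^2))
  d[d < 1e-12] <- 0
  d
}
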