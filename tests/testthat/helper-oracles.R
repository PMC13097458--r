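# Independent reference implementations and fixture builders used across
# the suite. Oracles deliberately avoid the package's own code paths.

# Exhaustive double-loop minimal-distance oracle (vectorised per row only).
oracle_min_dist <- function(ref, comp) {
  vapply(seq_len(nrow(ref)), function(i) {
    sqrt(min(colSums((t(comp) - ref[i, ])^2)))
  }, numeric(1))
}

# Dense-array reference for the gamut refinement: build a padded occupancy
# array, remove cubes with zero filled face neighbours (on the input
# snapshot), then fill empty cubes with six filled face neighbours (on the
# pass-1 snapshot).
oracle_refine <- function(cubes) {
  if (nrow(cubes) == 0) return(cubes)
  lo <- apply(cubes, 2, min) - 2L
  hi <- apply(cubes, 2, max) + 2L
  dims <- hi - lo + 1L
  occ <- array(FALSE, dims)
  occ[cbind(cubes[, 1] - lo[1] + 1L, cubes[, 2] - lo[2] + 1L,
            cubes[, 3] - lo[3] + 1L)] <- TRUE
  nbr_count <- function(a) {
    n <- array(0L, dim(a))
    d <- dim(a)
    n[-1, , ] <- n[-1, , ] + a[-d[1], , ]
    n[-d[1], , ] <- n[-d[1], , ] + a[-1, , ]
    n[, -1, ] <- n[, -1, ] + a[, -d[2], ]
    n[, -d[2], ] <- n[, -d[2], ] + a[, -1, ]
    n[, , -1] <- n[, , -1] + a[, , -d[3]]
    n[, , -d[3]] <- n[, , -d[3]] + a[, , -1]
    n
  }
  occ1 <- occ & nbr_count(occ) > 0L
  occ2 <- occ1 | (!occ1 & nbr_count(occ1) == 6L)
  idx <- which(occ2, arr.ind = TRUE)
  out <- cbind(idx[, 1] + lo[1] - 1L, idx[, 2] + lo[2] - 1L,
               idx[, 3] + lo[3] - 1L)
  colnames(out) <- c("iL", "ia", "ib")
  out
}

cube_sets_equal <- function(a, b) {
  key <- function(m) sort(paste(m[, 1], m[, 2], m[, 3], sep = ","))
  identical(key(a), key(b))
}

# Minimal valid dataset: one row per (group, colour) with boilerplate
# metadata.
make_lab_dataset <- function(lab_by_group, gender = "female",
                             site = "cheek") {
  rows <- lapply(names(lab_by_group), function(g) {
    lab <- lab_by_group[[g]]
    if (!is.matrix(lab)) lab <- matrix(lab, ncol = 3, byrow = TRUE)
    data.frame(subject_id = sprintf("%s_%03d", g, seq_len(nrow(lab))),
               group = g, gender = gender, age = NA_real_,
               body_site = site, L = lab[, 1], a = lab[, 2], b = lab[, 3])
  })
  skin_dataset(do.call(rbind, rows), provenance = list(source = "fixture"))
}

# Two-group, two-gender dataset from explicit per-cell values.
make_factorial_dataset <- function(values) {
  # values: list with names like CA.female -> numeric vector of L values
  rows <- lapply(names(values), function(k) {
    parts <- strsplit(k, ".", fixed = TRUE)[[1]]
    v <- values[[k]]
    data.frame(subject_id = sprintf("%s_%s_%03d", parts[1], parts[2],
                                    seq_along(v)),
               group = parts[1], gender = parts[2], age = NA_real_,
               body_site = "cheek", L = v, a = 0, b = 0)
  })
  skin_dataset(do.call(rbind, rows), provenance = list(source = "fixture"))
}

random_lab <- function(n, centre = c(55, 10, 16), spread = 8) {
  matrix(rnorm(3 * n, mean = rep(centre, each = n), sd = spread), n, 3)
}
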