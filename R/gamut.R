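# Group-level overlap via voxelized colour gamuts.
#
# Each group's CIELAB point cloud is segmented into cubes of edge 3 on a
# global grid anchored at the origin; at that edge the average distance
# between adjacent cubes exceeds the perceptibility threshold, so occupied
# cubes form perceptually meaningful clusters. Two morphological criteria
# refine each gamut before any intersection: isolated cubes (all six face
# neighbours empty) are removed, then cavities (empty cubes with all six
# face neighbours filled) are filled. Overlap is the share of the reference
# group's cubes also occupied by the comparison group.

.cube_key <- function(cubes) {
  paste(cubes[, 1], cubes[, 2], cubes[, 3], sep = ",")
}

.face_offsets <- rbind(
  c(1, 0, 0), c(-1, 0, 0), c(0, 1, 0), c(0, -1, 0), c(0, 0, 1), c(0, 0, -1)
)

# Count, for each row of `cubes`, how many of its 6 face neighbours are in
# the occupancy set `keys`.
.neighbour_counts <- function(cubes, keys) {
  counts <- integer(nrow(cubes))
  for (r in seq_len(6)) {
    shifted <- sweep(cubes, 2, .face_offsets[r, ], "+")
    counts <- counts + (.cube_key(shifted) %in% keys)
  }
  counts
}

#' Voxelize a CIELAB point cloud
#'
#' Assigns each colour to the cube `floor(coordinate / edge)` per axis on a
#' global grid anchored at the CIELAB origin (half-open cells
#' `[k*edge, (k+1)*edge)`; negative a*/b* coordinates floor downwards, so
#' cells stay uniform across zero). Duplicate cubes collapse to one.
#'
#' @param samples n x 3 CIELAB matrix, data frame with columns L, a, b, or
#'   a [skin_dataset()].
#' @param edge Cube edge length in CIELAB units; default 3.
#' @param group Optional group code carried along for reporting.
#' @return A `voxel_gamut`: list with `group`, `edge`, `cubes` (m x 3
#'   integer matrix of cube indices) and `refined = FALSE`.
#' @examples
#' voxelize(matrix(c(50, 10, 15), 1))  # single cube (16, 3, 5)
#' @export
voxelize <- function(samples, edge = 3, group = NA_character_) {
  stopifnot(is.numeric(edge), length(edge) == 1, edge > 0)
  lab <- .lab_matrix(samples, "samples")
  if (nrow(lab) == 0) stop("no samples to voxelize")
  cubes <- unique(floor(lab / edge))
  storage.mode(cubes) <- "integer"
  colnames(cubes) <- c("iL", "ia", "ib")
  structure(list(group = group, edge = edge, cubes = cubes, refined = FALSE),
            class = "voxel_gamut")
}

#' @export
print.voxel_gamut <- function(x, ...) {
  cat("<voxel_gamut>", if (!is.na(x$group)) paste0("group ", x$group),
      "edge", x$edge, "|", nrow(x$cubes), "cube(s),",
      if (x$refined) "refined" else "unrefined", "\n")
  invisible(x)
}

#' Refine a voxel gamut by the two morphological criteria
#'
#' Two passes, each evaluated on a snapshot of its input (no cascading),
#' applied once in this order:
#'
#' 1. remove every filled cube whose six face-adjacent neighbours are all
#'    empty (isolated outliers);
#' 2. add every empty cube whose six face-adjacent neighbours are all
#'    filled (cavities inconsistent with skin-colour continuity).
#'
#' Cubes with between 1 and 5 filled face neighbours are never touched.
#'
#' @param gamut An unrefined `voxel_gamut`.
#' @return The refined `voxel_gamut` (`refined = TRUE`).
#' @export
refine_gamut <- function(gamut) {
  stopifnot(inherits(gamut, "voxel_gamut"))
  cubes <- gamut$cubes
  keys <- .cube_key(cubes)

  # pass 1: drop isolated cubes, judged against the original occupancy
  isolated <- .neighbour_counts(cubes, keys) == 0L
  cubes <- cubes[!isolated, , drop = FALSE]
  keys <- .cube_key(cubes)

  # pass 2: fill cavities, judged against the pass-1 occupancy snapshot
  if (nrow(cubes) > 0) {
    cand <- unique(do.call(rbind, lapply(seq_len(6), function(r) {
      sweep(cubes, 2, .face_offsets[r, ], "+")
    })))
    cand <- cand[!.cube_key(cand) %in% keys, , drop = FALSE]
    fill <- .neighbour_counts(cand, keys) == 6L
    if (any(fill)) {
      cubes <- rbind(cubes, cand[fill, , drop = FALSE])
    }
  }
  storage.mode(cubes) <- "integer"
  colnames(cubes) <- c("iL", "ia", "ib")
  structure(list(group = gamut$group, edge = gamut$edge, cubes = cubes,
                 refined = TRUE),
            class = "voxel_gamut")
}

#' Gamut volume (number of occupied cubes)
#'
#' @param gamut A `voxel_gamut` (normally refined).
#' @return Integer cube count.
#' @export
gamut_volume <- function(gamut) {
  stopifnot(inherits(gamut, "voxel_gamut"))
  nrow(gamut$cubes)
}

#' Group-level shared-gamut overlap matrix
#'
#' Builds one refined gamut per group, then for each ordered pair
#' (reference row A, comparison column B) reports
#' `100 * |cubes(A) n cubes(B)| / |cubes(A)|`. The intersection is
#' symmetric, so `pct(A->B) * volume(A) == pct(B->A) * volume(B)` holds
#' exactly. The diagonal is 100 and excluded from downstream summaries.
#'
#' @param dataset A [skin_dataset()] with at least two groups.
#' @param edge Cube edge length; default 3.
#' @return An [overlap_matrix()] with `method = "gamut"`. The refined
#'   per-group volumes are attached as attribute `volumes`.
#' @export
gamut_overlap_matrix <- function(dataset, edge = 3) {
  stopifnot(inherits(dataset, "skin_dataset"))
  groups <- levels(dataset$group)
  if (length(groups) < 2) stop("need at least two groups")
  gamuts <- lapply(groups, function(g) {
    refine_gamut(voxelize(dataset[dataset$group == g, ], edge, group = g))
  })
  names(gamuts) <- groups
  vols <- vapply(gamuts, gamut_volume, integer(1))
  empty <- names(vols)[vols == 0]
  if (length(empty)) {
    stop("gamut empty after refinement for group(s): ",
         paste(empty, collapse = ", "))
  }
  keysets <- lapply(gamuts, function(g) .cube_key(g$cubes))
  k <- length(groups)
  vals <- matrix(100, k, k)
  for (i in seq_len(k)) {
    for (j in seq_len(k)) {
      if (i == j) next
      shared <- sum(keysets[[i]] %in% keysets[[j]])
      vals[i, j] <- 100 * shared / vols[[i]]
    }
  }
  m <- overlap_matrix(vals, groups, method = "gamut")
  attr(m, "volumes") <- vols
  m
}

#' Export a gamut's cube set as a data frame of integer triples
#'
#' @param gamut A `voxel_gamut`.
#' @return Tibble with columns `iL`, `ia`, `ib`.
#' @export
gamut_cubes <- function(gamut) {
  stopifnot(inherits(gamut, "voxel_gamut"))
  tibble::as_tibble(as.data.frame(gamut$cubes))
}
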