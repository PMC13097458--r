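# Voxelization, morphological refinement and the shared-gamut matrix.

block_cubes <- function(nx, ny, nz, origin = c(0, 0, 0)) {
  as.matrix(expand.grid(origin[1] + seq_len(nx) - 1,
                        origin[2] + seq_len(ny) - 1,
                        origin[3] + seq_len(nz) - 1))
}

gamut_from_cubes <- function(cubes, edge = 3) {
  # place one sample at each cube centre
  voxelize((cubes + 0.5) * edge, edge = edge)
}

test_that("voxelization floors onto the origin-anchored half-open grid", {
  g <- voxelize(matrix(c(50, 10, 15), 1))
  expect_equal(unname(g$cubes[1, ]), c(16L, 3L, 5L))
  # 100 samples inside one cube collapse to volume 1
  withr::with_seed(2, pts <- matrix(runif(300, 0, 2.999), 100, 3))
  expect_equal(gamut_volume(voxelize(pts)), 1)
  # half-open boundaries
  g2 <- voxelize(rbind(c(0, 0, 0), c(2.9, 2.9, 2.9), c(3, 0, 0)))
  expect_equal(gamut_volume(g2), 2)
  # negative coordinates floor downwards (uniform cells across zero)
  g3 <- voxelize(matrix(c(50, -0.5, 1), 1))
  expect_equal(unname(g3$cubes[1, ]), c(16L, -1L, 0L))
})

test_that("voxelizing cube centroids is idempotent at the cube level", {
  withr::with_seed(4, {
    cubes <- unique(matrix(sample(-5:10, 150, replace = TRUE), 50, 3))
  })
  g <- gamut_from_cubes(cubes)
  expect_true(cube_sets_equal(g$cubes, cubes))
})

test_that("refinement removes isolated cubes and fills enclosed gaps", {
  # a lone cube has six empty neighbours: removed, volume 0
  lone <- refine_gamut(gamut_from_cubes(matrix(c(5, 5, 5), 1)))
  expect_equal(gamut_volume(lone), 0)
  # a 3x3x3 solid block minus its centre: centre restored
  blk <- block_cubes(3, 3, 3)
  centre <- c(1, 1, 1)
  hollow <- blk[rowSums(sweep(blk, 2, centre, "==")) < 3, ]
  refined <- refine_gamut(gamut_from_cubes(hollow))
  expect_equal(gamut_volume(refined), 27)
  expect_true(cube_sets_equal(refined$cubes, blk))
  # refine on an already-solid block is the identity
  solid <- refine_gamut(gamut_from_cubes(blk))
  expect_true(cube_sets_equal(solid$cubes, blk))
})

test_that("cubes with 1-5 filled neighbours are never touched", {
  # a 2x1x1 domino: each cube has exactly one filled neighbour
  domino <- rbind(c(0, 0, 0), c(1, 0, 0))
  refined <- refine_gamut(gamut_from_cubes(domino))
  expect_true(cube_sets_equal(refined$cubes, domino))
})

test_that("refinement matches the dense-array oracle on random voxel sets", {
  for (seed in 1:20) {
    withr::with_seed(seed, {
      cubes <- unique(matrix(sample(0:7, 600, replace = TRUE), 200, 3))
    })
    refined <- refine_gamut(gamut_from_cubes(cubes))
    expect_true(cube_sets_equal(refined$cubes, oracle_refine(cubes)),
                info = paste("seed", seed))
  }
})

test_that("both passes use snapshot semantics (no cascading)", {
  # two diagonal cubes: both isolated w.r.t. the input snapshot, so both
  # are removed; cascading evaluation after removing one would still
  # remove the other here, but a plus-shape probes filling snapshots:
  # removing an isolated cube must not enable a fill in the same pass.
  diag2 <- rbind(c(0, 0, 0), c(1, 1, 0))
  expect_equal(gamut_volume(refine_gamut(gamut_from_cubes(diag2))), 0)
  # hollow 3x3x3 plus a far isolated cube: isolated cube removed AND the
  # centre filled, confirming pass-1 output feeds pass 2
  blk <- block_cubes(3, 3, 3)
  hollow <- blk[rowSums(sweep(blk, 2, c(1, 1, 1), "==")) < 3, ]
  with_outlier <- rbind(hollow, c(9, 9, 9))
  refined <- refine_gamut(gamut_from_cubes(with_outlier))
  expect_true(cube_sets_equal(refined$cubes, blk))
})

test_that("shared-count conservation holds exactly for every pair", {
  withr::with_seed(17, {
    d <- make_lab_dataset(list(CA = random_lab(500, spread = 6),
                               CN = random_lab(500, centre = c(50, 8, 14),
                                               spread = 5),
                               AF = random_lab(300, centre = c(42, 11, 13),
                                               spread = 7)))
  })
  m <- gamut_overlap_matrix(d)
  vols <- attr(m, "volumes")
  for (i in 1:3) for (j in 1:3) {
    expect_equal(m[i, j] * vols[[i]], m[j, i] * vols[[j]], tolerance = 1e-9)
  }
})

test_that("identical clouds share everything; translated clouds nothing", {
  withr::with_seed(6, lab <- random_lab(400, spread = 4))
  d_same <- make_lab_dataset(list(CA = lab, CN = lab))
  m_same <- gamut_overlap_matrix(d_same)
  expect_equal(unname(unclass(m_same)), matrix(100, 2, 2),
               ignore_attr = TRUE)
  d_far <- make_lab_dataset(list(CA = lab,
                                 CN = sweep(lab, 2, c(200, 0, 0), "+")))
  m_far <- gamut_overlap_matrix(d_far)
  expect_equal(off_diagonal(m_far), c(0, 0))
})

test_that("an empty refined reference gamut is an error naming the group", {
  # one isolated point per distinct far-apart cube: refinement empties CN
  scattered <- rbind(c(0, 0, 0), c(30, 30, 30), c(-30, -30, -30))
  withr::with_seed(9, dense <- random_lab(200, spread = 3))
  d <- make_lab_dataset(list(CA = dense, CN = scattered))
  expect_error(gamut_overlap_matrix(d), "CN")
})
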