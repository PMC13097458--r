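# Reading, validation, site filtering and result serialisation.

write_fixture_csv <- function(df) {
  path <- withr::local_tempfile(fileext = ".csv",
                                .local_envir = parent.frame())
  utils::write.csv(df, path, row.names = FALSE)
  path
}

lab_fixture <- function() {
  data.frame(subject_id = c("s1", "s1", "s2"),
             group = c("CA", "CA", "CN"),
             gender = c("female", "female", "male"),
             age = c(30, 30, 41),
             body_site = c("cheek", "forehead", "cheek"),
             L = c(61, 62, 59), a = c(11, 10, 10), b = c(15, 14, 17))
}

test_that("lab_csv round-trips three valid rows", {
  d <- read_dataset(write_fixture_csv(lab_fixture()), "lab_csv")
  expect_s3_class(d, "skin_dataset")
  expect_equal(nrow(d), 3)
  expect_equal(levels(d$group), c("CA", "CN"))
  counts <- group_counts(d)
  expect_equal(counts$n_samples, c(2L, 1L))
  expect_equal(counts$n_subjects, c(1L, 1L))
})

test_that("vocabulary violations name the row and value", {
  bad <- lab_fixture()
  bad$group[2] <- "XX"
  expect_error(read_dataset(write_fixture_csv(bad), "lab_csv"), "2.*XX")
  bad2 <- lab_fixture()
  bad2$body_site[3] <- "elbow"
  expect_error(read_dataset(write_fixture_csv(bad2), "lab_csv"),
               "3.*elbow")
  empty <- lab_fixture()[0, ]
  expect_error(read_dataset(write_fixture_csv(empty), "lab_csv"), "empty")
})

test_that("xyz_csv converts through the CIELAB transform", {
  wp <- white_point()
  df <- data.frame(subject_id = "s1", group = "CA", gender = "female",
                   age = 30, body_site = "cheek",
                   X = wp[["X"]], Y = wp[["Y"]], Z = wp[["Z"]])
  d <- read_dataset(write_fixture_csv(df), "xyz_csv")
  expect_equal(d$L, 100, tolerance = 1e-9)
  expect_equal(d$a, 0, tolerance = 1e-9)
})

test_that("wide spectra_csv converts flat grey reflectance", {
  grid <- seq(400, 700, 10)
  df <- data.frame(subject_id = "s1", group = "CA", gender = "female",
                   age = 30, body_site = "cheek")
  for (w in grid) df[[paste0("nm_", w)]] <- 0.5
  d <- read_dataset(write_fixture_csv(df), "spectra_csv")
  # L* of a 50% flat reflector: 116 * 0.5^(1/3) - 16
  expect_equal(d$L, 76.0693, tolerance = 1e-4)
  expect_equal(d$a, 0, tolerance = 1e-9)
})

test_that("long spectra_csv matches the wide reading", {
  grid <- seq(400, 700, 10)
  refl <- seq(0.3, 0.6, length.out = length(grid))
  long <- data.frame(measurement_id = "m1", subject_id = "s1",
                     group = "CA", gender = "female", age = 30,
                     body_site = "cheek", wavelength = grid,
                     reflectance = refl)
  wide <- data.frame(subject_id = "s1", group = "CA", gender = "female",
                     age = 30, body_site = "cheek")
  for (i in seq_along(grid)) wide[[as.character(grid[i])]] <- refl[i]
  dl <- read_dataset(write_fixture_csv(long), "spectra_csv")
  dw <- read_dataset(write_fixture_csv(wide), "spectra_csv")
  expect_equal(dl[c("L", "a", "b")], dw[c("L", "a", "b")],
               tolerance = 1e-12, ignore_attr = TRUE)
})

test_that("column mapping renames foreign headers", {
  df <- lab_fixture()
  names(df)[names(df) == "group"] <- "ethnicity"
  d <- read_dataset(write_fixture_csv(df), "lab_csv",
                    col_map = c(group = "ethnicity"))
  expect_equal(nrow(d), 3)
})

test_that("filter_sites drops excluded sites and leaves records untouched", {
  sites <- setdiff(body_sites(), "outer forearm")  # 12 positions
  lab <- cbind(50 + seq_along(sites), 10, 15)
  df <- data.frame(subject_id = "s1", group = "CA", gender = "female",
                   age = NA_real_, body_site = sites,
                   L = lab[, 1], a = lab[, 2], b = lab[, 3])
  d <- skin_dataset(df)
  expect_message(kept <- filter_sites(d), "removed 2 of 12")
  expect_equal(nrow(kept), 10)
  expect_false(any(kept$body_site %in% c("ear lobe", "ring finger")))
  retained <- d[!d$body_site %in% c("ear lobe", "ring finger"), ]
  expect_equal(as.data.frame(kept), as.data.frame(retained),
               ignore_attr = TRUE)
  # empty exclusion is the identity; absent sites are a logged no-op
  expect_message(same <- filter_sites(d, character(0)), "removed 0")
  expect_equal(nrow(same), 12)
  d10 <- filter_sites(d)
  expect_message(noop <- filter_sites(d10, "ear lobe"), "removed 0")
  expect_equal(nrow(noop), 10)
})

test_that("overlap matrices round-trip through CSV within 1e-12", {
  withr::with_seed(5, {
    vals <- matrix(runif(16, 0, 100), 4, 4)
    diag(vals) <- 100
  })
  m <- overlap_matrix(vals, c("CA", "CN", "JP", "AF"), "individual")
  path <- withr::local_tempfile(fileext = ".csv")
  write_overlap_matrix(m, path)
  back <- read_overlap_matrix(path, "individual")
  expect_equal(unclass(back), unclass(m), tolerance = 1e-12,
               ignore_attr = TRUE)
  expect_equal(rownames(back), rownames(m))
})

test_that("a single-group matrix serialises as a 1x1 CSV with 100 diagonal", {
  m <- overlap_matrix(matrix(100, 1, 1), "CA", "individual")
  path <- withr::local_tempfile(fileext = ".csv")
  write_overlap_matrix(m, path)
  txt <- readLines(path)
  expect_equal(length(txt), 2)
  expect_match(txt[2], "^CA,100")
})

test_that("write_outputs is deterministic across identical runs", {
  d <- generate_dataset(preset_scenarios(seed = 3)$two_group_partial)
  results <- list(
    group_summary = summarize_groups(d),
    individual_matrix = individual_overlap_matrix(d),
    medians = list(demo = bootstrap_median_ci(1:9, n_boot = 50, seed = 2))
  )
  dir1 <- withr::local_tempdir(); dir2 <- withr::local_tempdir()
  f1 <- write_outputs(results, dir1)
  f2 <- write_outputs(results, dir2)
  expect_equal(basename(f1), basename(f2))
  expect_equal(unname(tools::md5sum(f1)), unname(tools::md5sum(f2)))
})
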