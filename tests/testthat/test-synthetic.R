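# The synthetic cohort generator and its presets.

test_that("generation is reproducible from the seed and leaves the RNG alone", {
  cfg <- two_group_scenario(8, seed = 99, n_subjects = 20)
  set.seed(123); before <- runif(1)
  d1 <- generate_dataset(cfg)
  d2 <- generate_dataset(cfg)
  expect_identical(as.data.frame(d1), as.data.frame(d2))
  set.seed(123)
  expect_identical(runif(1), before)
  # different seed: same schema and counts, different values
  d3 <- generate_dataset(two_group_scenario(8, seed = 100, n_subjects = 20))
  expect_identical(dim(d3), dim(d1))
  expect_identical(group_counts(d3)$n_samples, group_counts(d1)$n_samples)
  expect_false(isTRUE(all.equal(d3$L, d1$L)))
})

test_that("degenerate spread collapses every sample onto the group mean", {
  gm <- group_model("CA", n_subjects = 5, mean = c(60, 10, 15),
                    covariance = matrix(0, 3, 3), noise_sd = 0)
  d <- generate_dataset(scenario_config(list(gm), seed = 1))
  expect_equal(unique(d$L), 60)
  expect_equal(unique(d$a), 10)
  expect_equal(unique(d$b), 15)
  expect_equal(nrow(d), 50)  # 5 subjects x 10 sites
})

test_that("invalid models are rejected", {
  expect_error(group_model("CA", 5, c(60, 10, 15),
                           covariance = matrix(c(1, 2, 0, 2, 1, 0, 0, 0, 1), 3)),
               "semidefinite")
  expect_error(group_model("CA", 5, c(60, 10, 15),
                           covariance = matrix(c(1, 2, 0, 0, 1, 0, 0, 0, 1), 3)),
               "symmetric")
  gm <- group_model("CA", 5, c(60, 10, 15))
  expect_error(scenario_config(list(gm, gm)), "duplicate")
})

test_that("gender labels, offsets and sites behave as configured", {
  gm <- group_model("CA", n_subjects = 40, mean = c(60, 10, 15),
                    covariance = matrix(0, 3, 3), noise_sd = 0,
                    gender_offset = c(-3, 0, 0),
                    gender_offset_target = "male",
                    female_fraction = 0.75)
  d <- generate_dataset(scenario_config(list(gm), seed = 4))
  expect_equal(sum(d$gender == "female"), 30 * 10)
  expect_equal(unique(d$L[d$gender == "male"]), 57)
  expect_equal(unique(d$L[d$gender == "female"]), 60)
  expect_equal(length(unique(d$body_site)), 10)
})

test_that("issa_like preset carries the configured group locations", {
  cfg <- issa_like_scenario(seed = 1)
  expect_equal(cfg$groups$CA$mean, c(61.2, 11.0, 14.7))
  expect_equal(cfg$groups$AF$mean, c(39.6, 10.2, 14.4))
  # marginal SD target: subject-level variance + within-subject noise
  expect_equal(sqrt(cfg$groups$CA$covariance[1, 1] + 0.5^2), 5.4)
  d <- generate_dataset(issa_like_scenario(seed = 2, n_subjects = 5))
  expect_equal(nlevels(d$group), 8)
  expect_equal(nrow(d), 8 * 5 * 10)
})

test_that("issa_like sample moments converge to the configured moments", {
  # reduced-size version of the acceptance check (SE-derived tolerances)
  d <- generate_dataset(issa_like_scenario(seed = 6, n_subjects = 250))
  tgt <- issa_like_moments()
  for (g in c("CA", "AF")) {
    sub <- d[d$group == g, ]
    row <- tgt[tgt$group == g, ]
    n <- nrow(sub)
    expect_equal(mean(sub$L), row$L, tolerance = 4 * row$sd_L / sqrt(n) / row$L)
    expect_equal(sd(sub$L), row$sd_L, tolerance = 0.15)
    expect_equal(mean(sub$b), row$b, tolerance = 4 * row$sd_b / sqrt(n) / row$b)
  }
})

test_that("the optional L*-b* coupling induces the configured correlation", {
  d <- generate_dataset(issa_like_scenario(seed = 9, n_subjects = 400,
                                           lb_correlation = 0.6))
  sub <- d[d$group == "CA", ]
  expect_gt(cor(sub$L, sub$b), 0.4)
  d0 <- generate_dataset(issa_like_scenario(seed = 9, n_subjects = 400))
  sub0 <- d0[d0$group == "CA", ]
  expect_lt(abs(cor(sub0$L, sub0$b)), 0.15)
})

test_that("presets cover the four required scenarios", {
  p <- preset_scenarios(seed = 1)
  expect_setequal(names(p),
                  c("issa_like", "identical", "disjoint",
                    "two_group_partial"))
  expect_equal(length(p$identical$groups), 8)
  expect_equal(length(unique(lapply(p$identical$groups, `[[`, "mean"))), 1)
  means_L <- vapply(p$disjoint$groups, function(g) g$mean[1], numeric(1))
  expect_true(all(diff(sort(means_L)) >= 30))
})
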