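test_that("cohort has the declared dimensions, split and determinism", {
  cfg <- synthetic_config(n_subjects = 114, n_regions = 148, n_modules = 4,
                          seed = 7)
  ch <- generate_cohort(cfg)
  expect_identical(dim(ch$thickness_t1), c(114L, 148L))
  expect_identical(dim(ch$thickness_t2), c(114L, 148L))
  expect_identical(rownames(ch$thickness_t1), rownames(ch$thickness_t2))
  expect_identical(colnames(ch$thickness_t1), colnames(ch$thickness_t2))
  expect_equal(unname(table(ch$truth$group_labels)[c("low", "high")]),
               c(57L, 57L), ignore_attr = TRUE)

  ch2 <- generate_cohort(cfg)
  expect_identical(ch, ch2)
})

test_that("population covariance matches the planted block structure", {
  cfg1 <- synthetic_config(n_subjects = 10, n_regions = 5, n_modules = 1,
                           within_module_corr = 0.5,
                           between_module_corr = 0.0)
  m1 <- population_covariance(cfg1)
  expect_equal(diag(m1), rep(1, 5))
  expect_equal(unique(m1[upper.tri(m1)]), 0.5)

  cfg2 <- synthetic_config(n_subjects = 10, n_regions = 6, n_modules = 3,
                           within_module_corr = 0.4,
                           between_module_corr = 0.0)
  m2 <- population_covariance(cfg2)
  mod <- rep(1:3, each = 2)
  expect_true(all(m2[outer(mod, mod, "!=")] == 0))

  cfg3 <- synthetic_config(n_subjects = 10, n_regions = 4, n_modules = 2,
                           within_module_corr = 0.6,
                           between_module_corr = 0.2)
  expected <- matrix(c(1, .6, .2, .2,
                       .6, 1, .2, .2,
                       .2, .2, 1, .6,
                       .2, .2, .6, 1), 4, 4)
  expect_equal(unname(population_covariance(cfg3)), expected)
})

test_that("invalid configurations are rejected with informative errors", {
  expect_error(synthetic_config(between_module_corr = 0.6,
                                within_module_corr = 0.4),
               "between_module_corr")
  expect_error(synthetic_config(within_module_corr = 1.0),
               "within_module_corr")
  expect_error(synthetic_config(timepoint_corr = 1), "timepoint_corr")
  # group effect pushing between-module correlation above within breaks
  # positive definiteness
  expect_error(synthetic_config(within_module_corr = 0.5,
                                between_module_corr = 0.45,
                                group_effect = 2.1),
               "positive definite")
})

test_that("generated data converge to the planted moments", {
  cfg <- synthetic_config(n_subjects = 5000, n_regions = 12, n_modules = 3,
                          within_module_corr = 0.5,
                          between_module_corr = 0.2,
                          timepoint_corr = 0.7, seed = 11)
  ch <- generate_cohort(cfg)
  pop <- population_covariance(cfg)
  emp <- cor(unclass(ch$thickness_t1))
  expect_lt(max(abs(emp - pop)), 0.05)

  tp <- vapply(seq_len(12), function(j)
    cor(ch$thickness_t1[, j], ch$thickness_t2[, j]), numeric(1))
  expect_lt(max(abs(tp - 0.7)), 0.05)

  sk <- vapply(c("negativity_epi", "warmth", "negativity_psi",
                 "communication"),
               function(cm) sample_skewness(ch$component_scores[[cm]]),
               numeric(1))
  expect_lt(max(abs(sk - c(1.98, 0.23, 0.89, -1.80))), 0.5)
})

test_that("null configurations leave the two label-defined groups exchangeable", {
  cfg <- synthetic_config(n_subjects = 5000, n_regions = 6, n_modules = 2,
                          within_module_corr = 0.5,
                          between_module_corr = 0.2,
                          group_effect = 1.0, seed = 21)
  ch <- generate_cohort(cfg)
  lab <- ch$truth$group_labels
  c_low <- cor(unclass(ch$thickness_t1[lab == "low", ]))
  c_high <- cor(unclass(ch$thickness_t1[lab == "high", ]))
  expect_lt(max(abs(c_low - c_high)), 0.05)
})

test_that("a planted group effect changes only the low group's between-module correlation", {
  cfg <- synthetic_config(n_subjects = 4000, n_regions = 6, n_modules = 2,
                          within_module_corr = 0.5,
                          between_module_corr = 0.4,
                          group_effect = 0.4, seed = 31)
  ch <- generate_cohort(cfg)
  lab <- ch$truth$group_labels
  mod <- ch$truth$module_assignment
  betw <- outer(mod, mod, "!=")
  c_low <- cor(unclass(ch$thickness_t1[lab == "low", ]))
  c_high <- cor(unclass(ch$thickness_t1[lab == "high", ]))
  expect_lt(abs(mean(c_low[betw]) - 0.4 * 0.4), 0.05)
  expect_lt(abs(mean(c_high[betw]) - 0.4), 0.05)
  # truth record recomputes the planted covariance exactly
  cfg_re <- do.call(synthetic_config, ch$truth$config)
  expect_identical(population_covariance(cfg_re),
                   population_covariance(cfg))
})

test_that("T2-only planting leaves Time 1 unaffected", {
  cfg <- synthetic_config(n_subjects = 4000, n_regions = 6, n_modules = 2,
                          within_module_corr = 0.5,
                          between_module_corr = 0.4,
                          group_effect = 0.3,
                          group_effect_timepoint = "T2", seed = 41)
  ch <- generate_cohort(cfg)
  lab <- ch$truth$group_labels
  mod <- ch$truth$module_assignment
  betw <- outer(mod, mod, "!=")
  c_low_t1 <- cor(unclass(ch$thickness_t1[lab == "low", ]))
  expect_lt(abs(mean(c_low_t1[betw]) - 0.4), 0.05)
})

test_that("cohorts round-trip through the on-disk representation", {
  dir <- withr::local_tempdir()
  cfg <- synthetic_config(n_subjects = 12, n_regions = 6, n_modules = 2,
                          seed = 5)
  ch <- generate_cohort(cfg)
  paths <- write_cohort(ch, dir)
  expect_true(all(file.exists(paths)))
  t1 <- read_thickness_table(paths[["thickness_t1"]], "T1")
  expect_equal(unclass(t1), unclass(ch$thickness_t1), ignore_attr = TRUE)
  expect_identical(rownames(t1), rownames(ch$thickness_t1))
  truth <- jsonlite::read_json(paths[["truth"]], simplifyVector = TRUE)
  expect_equal(truth$group_effect, 1)
})
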