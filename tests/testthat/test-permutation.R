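small_cohort <- function(seed = 1, n = 40, p = 10, effect = 1,
                         w = 0.55, b = 0.52) {
  cfg <- synthetic_config(n_subjects = n, n_regions = p, n_modules = 2,
                          within_module_corr = w, between_module_corr = b,
                          group_effect = effect, seed = seed)
  ch <- generate_cohort(cfg)
  list(groups = median_split(ch$component_scores, "warmth"),
       z1 = standardize_regions(ch$thickness_t1),
       z2 = standardize_regions(ch$thickness_t2))
}

test_that("a degenerate shuffle reproduces the observed difference exactly", {
  sc <- small_cohort(seed = 2)
  pt <- permutation_test(sc$z2, sc$groups, "global_efficiency", rho = 0.2,
                         n_perm = 100, seed = 5,
                         shuffle_fun = function(n) seq_len(n))
  expect_true(all(pt$null_diffs == pt$observed_diff))
  expect_equal(pt$p_raw, 1)
})

test_that("permutation p-values are valid and reproducible", {
  sc <- small_cohort(seed = 3)
  pt1 <- permutation_test(sc$z2, sc$groups, "global_efficiency", rho = 0.15,
                          n_perm = 200, seed = 11)
  pt2 <- permutation_test(sc$z2, sc$groups, "global_efficiency", rho = 0.15,
                          n_perm = 200, seed = 11)
  expect_identical(pt1, pt2)
  expect_gt(pt1$p_raw, 0)
  expect_lte(pt1$p_raw, 1)
  expect_length(pt1$null_diffs, 200)
  # equal group sizes: the permutation null is symmetric about 0
  se <- sd(pt1$null_diffs) / sqrt(200)
  expect_lt(abs(mean(pt1$null_diffs)), 3 * se + 1e-12)

  expect_error(permutation_test(sc$z2, sc$groups, "global_efficiency",
                                rho = 0.15, n_perm = 50), "at least 100")
})

test_that("p-values stabilize as permutations double", {
  sc <- small_cohort(seed = 4, n = 50, p = 8)
  p500 <- permutation_test(sc$z2, sc$groups, "global_efficiency",
                           rho = 0.15, n_perm = 500, seed = 21)$p_raw
  p1000 <- permutation_test(sc$z2, sc$groups, "global_efficiency",
                            rho = 0.15, n_perm = 1000, seed = 22)$p_raw
  expect_lt(abs(p500 - p1000), 2 / sqrt(500))
})

test_that("participation metric runs with a seeded partition per network", {
  sc <- small_cohort(seed = 6, n = 44, p = 12)
  pt <- permutation_test(sc$z2, sc$groups, "participation", rho = 0.2,
                         n_perm = 100, seed = 31)
  expect_true(is.finite(pt$observed_diff))
  expect_true(all(is.finite(pt$null_diffs)))
})

test_that("omnibus statistic is exactly zero when nothing changes", {
  sc <- small_cohort(seed = 7)
  pt <- omnibus_change_test(sc$z2, sc$z2, sc$groups, "global_efficiency",
                            rho = 0.2, n_perm = 100, seed = 41)
  expect_equal(pt$observed_diff, 0)
  expect_gte(pt$p_raw, 0.5)
  expect_identical(pt$contrast, "T2-T1")
})

test_that("omnibus test rejects unaligned inputs", {
  sc <- small_cohort(seed = 8)
  z2r <- sc$z2[rev(rownames(sc$z2)), ]
  expect_error(omnibus_change_test(sc$z1, z2r, sc$groups,
                                   "global_efficiency", 0.2, 100),
               "aligned")
})

test_that("an effect planted only at Time 2 drives the change statistic's sign", {
  signs <- vapply(1:12, function(s) {
    cfg <- synthetic_config(n_subjects = 80, n_regions = 20, n_modules = 4,
                            group_effect = 0.3,
                            group_effect_timepoint = "T2", seed = 600 + s)
    ch <- generate_cohort(cfg)
    g <- median_split(ch$component_scores, "warmth")
    z1 <- standardize_regions(ch$thickness_t1)
    z2 <- standardize_regions(ch$thickness_t2)
    pt <- omnibus_change_test(z1, z2, g, "participation", rho = 0.18,
                              n_perm = 100, seed = 700 + s)
    sign(pt$observed_diff)
  }, numeric(1))
  # low group becomes more segregated at T2 only -> negative diff-in-diff
  expect_gte(mean(signs < 0), 0.75)
})

test_that("Benjamini-Hochberg adjustment matches the step-up formula", {
  expect_equal(fdr_adjust(c(0.01, 0.02, 0.03, 0.04)),
               c(0.04, 0.04, 0.04, 0.04))
  expect_equal(fdr_adjust(1), 1)
  expect_equal(fdr_adjust(0.5), 0.5)
  expect_identical(fdr_adjust(numeric(0)), numeric(0))
  expect_error(fdr_adjust(c(0.5, 0)), "0, 1")

  set.seed(77)
  for (i in 1:20) {
    p <- runif(sample(2:30, 1))
    adj <- fdr_adjust(p)
    expect_true(all(adj <= 1 + 1e-15))
    expect_gte(min(adj - p), -1e-15)          # p_fdr >= p_raw
    ord <- order(p)
    expect_true(all(diff(adj[ord]) >= -1e-15))  # monotone in raw-p order
  }
})
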