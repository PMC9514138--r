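test_that("precision-to-partial-correlation follows the closed form", {
  p1 <- matrix(c(2, -1, -1, 2), 2, 2)
  pc1 <- precision_to_partial_correlation(p1)
  expect_equal(pc1[1, 2], 0.5)
  expect_equal(diag(pc1), c(0, 0))

  expect_equal(precision_to_partial_correlation(diag(c(1, 3, 5))),
               matrix(0, 3, 3))

  chain <- matrix(c(2, -0.8, 0, -0.8, 2, -0.8, 0, -0.8, 2), 3, 3)
  pcc <- precision_to_partial_correlation(chain)
  expect_equal(pcc[1, 2], 0.4)
  expect_equal(pcc[2, 3], 0.4)
  expect_equal(pcc[1, 3], 0)

  expect_error(precision_to_partial_correlation(matrix(c(1, 2, 2, 1), 2)),
               "positive definite")
})

test_that("partial correlations of random PD precisions stay in [-1, 1]", {
  set.seed(22)
  for (i in 1:50) {
    p <- sample(3:8, 1)
    a <- matrix(rnorm(p * p), p)
    prec <- crossprod(a) + diag(p) * 0.1
    pc <- precision_to_partial_correlation(prec)
    expect_true(all(abs(pc) <= 1 + 1e-12))
    expect_equal(pc, t(pc))
  }
})

test_that("solver output satisfies the penalized-likelihood KKT conditions", {
  set.seed(42)
  p <- 6
  a <- matrix(rnorm(p * p), p)
  s <- cov2cor(crossprod(a) / p + diag(p))
  for (rho in c(0.02, 0.1, 0.3)) {
    fit <- scnet:::glasso_cpp(s, rho, 500L, 1e-6)
    expect_true(fit$converged)
    res <- kkt_residuals(s, fit$precision, rho)
    expect_lt(res$bound, 1e-6)
    expect_lt(res$equality, 1e-5)
    expect_lt(res$diagonal, 1e-7)
  }
})

test_that("solver agrees with an independently computed reference solution", {
  # reference: scikit-learn graphical_lasso on the same input (alpha = 0.05,
  # duality gap < 1e-4), upper triangle including the diagonal
  set.seed(42)
  p <- 6
  a <- matrix(rnorm(p * p), p)
  s <- cov2cor(crossprod(a) / p + diag(p))
  ref_upper <- c(1.21615360, -0.20109217, 0.00000000, 0.44358399,
                 -0.07885952, 0.00000000, 1.30619359, 0.58506756,
                 0.00000000, 0.00000000, 0.00000000, 1.31945115,
                 0.06315906, 0.12713653, -0.21010672, 1.18523801,
                 0.09867291, 0.03389899, 1.06615586, -0.19398244,
                 1.07240386)
  ref <- matrix(0, 6, 6)
  k <- 1L
  for (i in 1:6) for (j in i:6) {
    ref[i, j] <- ref[j, i] <- ref_upper[k]
    k <- k + 1L
  }
  fit <- scnet:::glasso_cpp(s, 0.05, 1000L, 1e-7)
  expect_lt(max(abs(fit$precision - ref)), 2e-3)
})

test_that("penalties at or above the correlation ceiling give an empty network", {
  set.seed(5)
  x <- matrix(rnorm(50 * 6), 50, 6)
  colnames(x) <- paste0("r", 1:6)
  rownames(x) <- paste0("s", 1:50)
  s <- cor(scale(x))
  rho_max <- max(abs(s[upper.tri(s)]))
  net <- estimate_sparse_network(x, rho_max)
  expect_identical(net$n_edges, 0L)
  # the diagonal precision is the fixed point there
  expect_equal(unname(net$precision), diag(1 / diag(s)), tolerance = 1e-8)

  # independent columns at large n: no edges at rho = 0.1
  set.seed(6)
  x2 <- matrix(rnorm(10000 * 2), 10000, 2)
  colnames(x2) <- c("a", "b"); rownames(x2) <- paste0("s", 1:10000)
  expect_identical(estimate_sparse_network(x2, 0.1)$n_edges, 0L)
})

test_that("the adjacency contract holds on arbitrary data", {
  set.seed(7)
  for (i in 1:5) {
    x <- matrix(rnorm(40 * 10), 40, 10)
    dimnames(x) <- list(paste0("s", 1:40), paste0("r", 1:10))
    net <- estimate_sparse_network(x, runif(1, 0.05, 0.5))
    a <- net$adjacency
    expect_true(all(a %in% c(0L, 1L)))
    expect_identical(a, t(a))
    expect_identical(diag(a), setNames(rep(0L, 10), paste0("r", 1:10)))
  }
  expect_error(estimate_sparse_network(matrix(rnorm(15), 3, 5,
    dimnames = list(paste0("s", 1:3), paste0("r", 1:5))), 0),
    "singular")
})

test_that("chain-structured precision is recovered edge-exactly", {
  chain <- matrix(c(2, -0.8, 0, -0.8, 2, -0.8, 0, -0.8, 2), 3, 3)
  sigma <- solve(chain)
  ch <- chol(cov2cor(sigma))
  hits <- 0L
  for (s in 1:20) {
    set.seed(100 + s)
    x <- matrix(rnorm(5000 * 3), 5000, 3) %*% ch
    dimnames(x) <- list(paste0("s", 1:5000), paste0("r", 1:3))
    adj <- estimate_sparse_network(x, 0.1)$adjacency
    if (adj[1, 2] == 1L && adj[2, 3] == 1L && adj[1, 3] == 0L)
      hits <- hits + 1L
  }
  expect_gte(hits, 18L)
})

test_that("cross-validation selects a penalty by held-out likelihood, deterministically", {
  set.seed(33)
  prec <- diag(8)
  for (i in 1:7) prec[i, i + 1] <- prec[i + 1, i] <- -0.4
  ch <- chol(cov2cor(solve(prec)))
  x <- matrix(rnorm(150 * 8), 150, 8) %*% ch
  dimnames(x) <- list(paste0("s", 1:150), paste0("r", 1:8))
  z <- standardize_regions(x)

  expect_equal(select_regularization(z, rho_grid = 0.2, seed = 1)$rho, 0.2)

  cv1 <- select_regularization(z, k_folds = 5, seed = 9)
  cv2 <- select_regularization(z, k_folds = 5, seed = 9)
  expect_identical(cv1, cv2)

  # the argmax beats both grid extremes
  mll <- cv1$mean_loglik
  expect_gte(max(mll), mll[1])
  expect_gte(max(mll), mll[length(mll)])
  expect_equal(cv1$mean_loglik[cv1$rho_grid == cv1$rho], max(mll))
})
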