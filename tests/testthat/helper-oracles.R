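# Independent brute-force oracles used across the suite. These deliberately
# avoid the package's BFS/igraph code paths: distances come from boolean
# matrix powers, community ground truth from exhaustive partition search.

# shortest-path lengths via reachability of boolean matrix powers; Inf for
# disconnected pairs
oracle_distances <- function(adj) {
  n <- nrow(adj)
  d <- matrix(Inf, n, n)
  diag(d) <- 0
  reach <- diag(n) > 0
  step <- adj > 0
  cur <- reach
  for (k in seq_len(n - 1)) {
    cur <- (cur %*% step) > 0
    newly <- cur & !reach & !diag(n)
    d[newly & d == Inf] <- k
    reach <- reach | cur
  }
  d
}

oracle_global_efficiency <- function(adj) {
  n <- nrow(adj)
  if (n < 2) return(0)
  d <- oracle_distances(adj)
  inv <- 1 / d
  diag(inv) <- 0
  sum(inv) / (n * (n - 1))
}

oracle_local_efficiency <- function(adj) {
  n <- nrow(adj)
  vapply(seq_len(n), function(i) {
    nb <- which(adj[i, ] > 0)
    if (length(nb) < 2) return(0)
    oracle_global_efficiency(adj[nb, nb, drop = FALSE])
  }, numeric(1))
}

oracle_participation <- function(adj, memb) {
  n <- nrow(adj)
  vapply(seq_len(n), function(i) {
    k <- sum(adj[i, ])
    if (k == 0) return(0)
    kis <- tapply(adj[i, ], memb, sum)
    1 - sum((kis / k)^2)
  }, numeric(1))
}

# Newman-Girvan modularity with resolution gamma, computed from first
# principles
oracle_modularity <- function(adj, memb, gamma = 1) {
  m2 <- sum(adj)  # 2 * edge count
  if (m2 == 0) return(0)
  deg <- rowSums(adj)
  q <- 0
  for (s in unique(memb)) {
    idx <- memb == s
    q <- q + sum(adj[idx, idx]) / m2 - gamma * (sum(deg[idx]) / m2)^2
  }
  q
}

# all set partitions of 1..n (restricted growth strings); n <= 8 is cheap
all_partitions <- function(n) {
  out <- list()
  rec <- function(prefix, maxid) {
    if (length(prefix) == n) {
      out[[length(out) + 1L]] <<- prefix
      return()
    }
    for (v in seq_len(maxid + 1L))
      rec(c(prefix, v), max(maxid, v))
  }
  rec(integer(0), 0L)
  out
}

# exhaustive maximum-modularity partition
oracle_best_partition <- function(adj, gamma = 1) {
  parts <- all_partitions(nrow(adj))
  qs <- vapply(parts, function(p) oracle_modularity(adj, p, gamma),
               numeric(1))
  list(membership = parts[[which.max(qs)]], q = max(qs))
}

random_adjacency <- function(n, p_edge = 0.4) {
  a <- matrix(0L, n, n)
  up <- upper.tri(a)
  a[up] <- as.integer(runif(sum(up)) < p_edge)
  a + t(a)
}

# KKT stationarity residuals of the graphical-lasso solution: the estimate
# W = Theta^{-1} must satisfy |W - S| <= rho off-diagonally (with equality
# rho * sign(Theta) where Theta is nonzero) and W_ii = S_ii
kkt_residuals <- function(S, theta, rho) {
  W <- solve(theta)
  off <- row(S) != col(S)
  nz <- off & abs(theta) > 1e-7
  list(
    bound = max(abs(W - S)[off]) - rho,
    equality = if (any(nz))
      max(abs((W - S)[nz] - rho * sign(theta[nz]))) else 0,
    diagonal = max(abs(diag(W) - diag(S)))
  )
}

sample_skewness <- function(x) {
  m <- mean(x)
  mean((x - m)^3) / (mean((x - m)^2)^1.5)
}

# small labelled thickness-like matrix
toy_thickness <- function(n = 6, p = 4, seed = 1, mean = 2.5, sd = 0.1) {
  set.seed(seed)
  m <- matrix(rnorm(n * p, mean, sd), n, p,
              dimnames = list(sprintf("S%02d", seq_len(n)),
                              sprintf("region_%02d", seq_len(p))))
  thickness_matrix(m, timepoint = "T1")
}

make_complete <- function(n) {
  a <- matrix(1L, n, n)
  diag(a) <- 0L
  a
}
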