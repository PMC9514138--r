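# adjacency straight from data at a fixed penalty; lean path used inside
# permutation loops (cor() is scale-invariant, so no explicit
# standardization is needed here)
fit_adjacency <- function(x, rho, max_iter = 200L, tol = 1e-4) {
  s <- cor(x)
  fit <- glasso_cpp(s, rho, max_iter = max_iter, tol = tol)
  if (!fit$converged)
    stop(sprintf("graphical lasso did not converge at rho = %g", rho),
         call. = FALSE)
  th <- fit$precision
  d <- 1 / sqrt(diag(th))
  pc <- -(d * th) * rep(d, each = nrow(th))
  adj <- (abs(pc) > 1e-8) * 1L
  diag(adj) <- 0L
  storage.mode(adj) <- "integer"
  adj
}

# shared permutation engine: the label vector is permuted (group sizes
# preserved) and stat_fun(low_rows, high_rows) -> scalar diff is evaluated
# on the reallocated groups. The identity permutation reproduces the
# observed groups exactly. Failed evaluations (solver non-convergence)
# cause the permutation to be redrawn, within a redraw budget of 2 * n_perm.
perm_engine <- function(stat_fun, lab, n_perm, perm_seed,
                        shuffle_fun = NULL) {
  n <- length(lab)
  null_diffs <- numeric(n_perm)
  with_seed(perm_seed, {
    redraws <- 0L
    for (b in seq_len(n_perm)) {
      repeat {
        idx <- if (is.null(shuffle_fun)) sample.int(n) else shuffle_fun(n)
        labp <- lab[idx]
        val <- tryCatch(stat_fun(which(labp == "low"),
                                 which(labp == "high")),
                        error = function(e) NULL)
        if (!is.null(val)) break
        redraws <- redraws + 1L
        if (redraws > 2L * n_perm)
          stop("permutation redraw budget exhausted (", redraws,
               " failed solver fits)", call. = FALSE)
      }
      null_diffs[b] <- val
    }
  })
  null_diffs
}

new_permtest <- function(component_name, metric_name, contrast,
                         observed_low, observed_high, null_diffs, n_perm,
                         seed, rho) {
  observed_diff <- observed_low - observed_high
  p_raw <- (1 + sum(abs(null_diffs) >= abs(observed_diff))) / (1 + n_perm)
  out <- list(component_name = component_name, metric_name = metric_name,
              contrast = contrast, observed_low = observed_low,
              observed_high = observed_high, observed_diff = observed_diff,
              null_diffs = null_diffs, p_raw = p_raw, p_fdr = NA_real_,
              n_perm = n_perm, seed = seed, rho = rho)
  class(out) <- "scn_permtest"
  out
}

#' Permutation test of a group difference in a network metric
#'
#' Builds one sparse structural covariance network per group at a common
#' penalty, computes the chosen metric for each, and takes the observed
#' difference (low minus high). The null distribution comes from randomly
#' reallocating subjects to two groups of the original sizes and rebuilding
#' both networks at the same penalty, `n_perm` times. The two-tailed p-value
#' uses the add-one count,
#' `p = (1 + #\{|null| >= |observed|\}) / (1 + n_perm)`, the same decision
#' rule at level 0.05 as thresholding at the 95th percentile of `|null|`,
#' but yielding a usable p-value (never exactly 0). Fully reproducible given
#' `seed`.
#'
#' @param thickness subjects x regions matrix for the timepoint under test
#'   (row names are subject IDs).
#' @param group_assignment an [median_split()] result covering the subjects.
#' @param metric_name one of `"local_efficiency"`, `"global_efficiency"`,
#'   `"participation"`.
#' @param rho penalty shared by every network (the whole-group
#'   cross-validated value in the reference design).
#' @param n_perm number of permutations (>= 100; the reference design uses
#'   5,000).
#' @param resolution Louvain resolution for the participation metric.
#' @param seed integer seed; spawns independent streams for the shuffles and
#'   the community detection.
#' @param contrast label stored on the result (e.g. `"T2"`).
#' @param shuffle_fun optional replacement for the random shuffle (testing
#'   hook); must return a permutation of `1:n`, which is applied to the
#'   label vector. The identity permutation reproduces the observed
#'   allocation.
#' @return an object of class `scn_permtest` with the observed group values,
#'   the null differences, and the raw p-value (`p_fdr` is filled by
#'   [run_pipeline()] across components).
#' @export
permutation_test <- function(thickness, group_assignment, metric_name,
                             rho, n_perm = 5000L, resolution = 1,
                             seed = 1L, contrast = "T2",
                             shuffle_fun = NULL) {
  stopifnot(inherits(group_assignment, "scn_groups"))
  if (n_perm < 100L) stop("n_perm must be at least 100", call. = FALSE)
  x <- as.matrix(thickness)
  lab <- group_assignment$labels[rownames(x)]
  if (anyNA(lab))
    stop("group assignment does not cover all subjects in the thickness ",
         "matrix", call. = FALSE)
  seeds <- spawn_seeds(seed, 2L)
  low_rows <- which(lab == "low")
  high_rows <- which(lab == "high")

  eval_groups <- function(rows_low, rows_high) {
    a_low <- fit_adjacency(x[rows_low, , drop = FALSE], rho)
    a_high <- fit_adjacency(x[rows_high, , drop = FALSE], rho)
    c(metric_value(a_low, metric_name, resolution, seeds[2L]),
      metric_value(a_high, metric_name, resolution, seeds[2L]))
  }

  obs <- eval_groups(low_rows, high_rows)
  null_diffs <- perm_engine(
    function(rl, rh) { v <- eval_groups(rl, rh); v[1L] - v[2L] },
    lab = unname(lab), n_perm = n_perm,
    perm_seed = seeds[1L], shuffle_fun = shuffle_fun)

  new_permtest(group_assignment$component_name, metric_name, contrast,
               obs[1L], obs[2L], null_diffs, n_perm, seed, rho)
}

#' Permutation test of the group difference in metric change (omnibus)
#'
#' The omnibus change statistic is the difference in differences:
#' `(metric_low,T2 - metric_low,T1) - (metric_high,T2 - metric_high,T1)`.
#' Each permutation reallocates subjects — carrying both of their timepoints
#' together — to groups of the original sizes, rebuilds the four networks at
#' the common penalty, and recomputes the statistic. p-value as in
#' [permutation_test()].
#'
#' @param thickness_t1,thickness_t2 aligned subjects x regions matrices
#'   (identical subject and region order; see [align_timepoints()]).
#' @inheritParams permutation_test
#' @return an `scn_permtest` whose `observed_low` / `observed_high` are the
#'   per-group T2 - T1 changes.
#' @export
omnibus_change_test <- function(thickness_t1, thickness_t2,
                                group_assignment, metric_name, rho,
                                n_perm = 5000L, resolution = 1, seed = 1L,
                                shuffle_fun = NULL) {
  stopifnot(inherits(group_assignment, "scn_groups"))
  if (n_perm < 100L) stop("n_perm must be at least 100", call. = FALSE)
  x1 <- as.matrix(thickness_t1)
  x2 <- as.matrix(thickness_t2)
  if (!identical(rownames(x1), rownames(x2)) ||
      !identical(colnames(x1), colnames(x2)))
    stop("timepoints are not aligned; run align_timepoints() first",
         call. = FALSE)
  lab <- group_assignment$labels[rownames(x1)]
  if (anyNA(lab))
    stop("group assignment does not cover all subjects", call. = FALSE)
  seeds <- spawn_seeds(seed, 2L)
  low_rows <- which(lab == "low")

  eval_changes <- function(rl, rh) {
    m <- function(rows, x) metric_value(
      fit_adjacency(x[rows, , drop = FALSE], rho), metric_name, resolution,
      seeds[2L])
    c(m(rl, x2) - m(rl, x1), m(rh, x2) - m(rh, x1))
  }

  obs <- eval_changes(low_rows, which(lab == "high"))
  null_diffs <- perm_engine(
    function(rl, rh) { v <- eval_changes(rl, rh); v[1L] - v[2L] },
    lab = unname(lab), n_perm = n_perm,
    perm_seed = seeds[1L], shuffle_fun = shuffle_fun)

  new_permtest(group_assignment$component_name, metric_name, "T2-T1",
               obs[1L], obs[2L], null_diffs, n_perm, seed, rho)
}

#' @export
print.scn_permtest <- function(x, ...) {
  cat(sprintf("Permutation test: %s, %s (%s)\n", x$component_name,
              x$metric_name, x$contrast))
  cat(sprintf("  low = %.4f, high = %.4f, diff (low - high) = %+.4f\n",
              x$observed_low, x$observed_high, x$observed_diff))
  fdr <- if (is.na(x$p_fdr)) "" else sprintf(", p_fdr = %.4f", x$p_fdr)
  cat(sprintf("  p = %.4f (%d permutations, rho = %g)%s\n", x$p_raw,
              x$n_perm, x$rho, fdr))
  invisible(x)
}

#' Benjamini-Hochberg FDR adjustment
#'
#' Step-up adjusted p-values `p_(i) = min_{j >= i} (p_(j) * m / j)`, capped
#' at 1 and order-preserving (a thin, validated wrapper over
#' [stats::p.adjust()] with `method = "BH"`).
#'
#' @param p_values raw p-values in `(0, 1]`.
#' @return adjusted p-values in the input order; empty input gives empty
#'   output.
#' @export
fdr_adjust <- function(p_values) {
  if (!length(p_values)) return(numeric(0))
  if (any(is.na(p_values)) || any(p_values <= 0 | p_values > 1))
    stop("p-values must lie in (0, 1]", call. = FALSE)
  p.adjust(p_values, method = "BH")
}
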