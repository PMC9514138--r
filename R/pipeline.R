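#' Configuration for a full pipeline run
#'
#' Bundles the inputs and tuning parameters of the end-to-end analysis.
#' Either file paths to the two thickness tables (plus component scores and
#' optionally covariates) or a [synthetic_config()] must be supplied.
#'
#' @param thickness_t1,thickness_t2 paths to the per-timepoint thickness
#'   tables (ignored when `synthetic` is given).
#' @param component_scores path to the component-score table (CSV with
#'   `subject_id` plus one column per component).
#' @param covariates optional path to a covariate table for the confound
#'   screen.
#' @param synthetic optional [synthetic_config()]; when present the cohort
#'   is simulated instead of read.
#' @param rho `"cv"` to cross-validate the penalty on the whole sample, or
#'   a fixed non-negative number.
#' @param rho_grid,k_folds passed to [select_regularization()].
#' @param n_perm permutations per test (>= 100; default 5000 as in the
#'   reference design).
#' @param resolution Louvain resolution (default 1).
#' @param z_threshold QC flagging threshold (default 3).
#' @param fdr_q FDR level (default 0.05).
#' @param master_seed seed from which every random step derives a child
#'   seed.
#' @param output_dir directory for CSV/GraphML/JSON artifacts (`NULL` for
#'   none).
#' @param test_t1 also permutation-test the Time-1 cross-section (off by
#'   default: Time-1 values are reported descriptively only).
#' @return a validated list of class `scn_run_config`.
#' @export
run_config <- function(thickness_t1 = NULL, thickness_t2 = NULL,
                       component_scores = NULL, covariates = NULL,
                       synthetic = NULL, rho = "cv", rho_grid = NULL,
                       k_folds = 5L, n_perm = 5000L, resolution = 1,
                       z_threshold = 3, fdr_q = 0.05, master_seed = 1L,
                       output_dir = NULL, test_t1 = FALSE) {
  if (is.null(synthetic) &&
      (is.null(thickness_t1) || is.null(thickness_t2) ||
       is.null(component_scores)))
    stop("either 'synthetic' or the three input tables (thickness_t1, ",
         "thickness_t2, component_scores) must be given", call. = FALSE)
  if (!is.null(synthetic)) stopifnot(inherits(synthetic, "scn_config"))
  if (n_perm < 100L) stop("n_perm must be at least 100", call. = FALSE)
  if (fdr_q <= 0 || fdr_q >= 1) stop("fdr_q must be in (0, 1)", call. = FALSE)
  if (resolution <= 0) stop("resolution must be positive", call. = FALSE)
  if (!identical(rho, "cv")) stopifnot_scalar_number(rho, "rho")
  cfg <- list(thickness_t1 = thickness_t1, thickness_t2 = thickness_t2,
              component_scores = component_scores, covariates = covariates,
              synthetic = synthetic, rho = rho, rho_grid = rho_grid,
              k_folds = as.integer(k_folds), n_perm = as.integer(n_perm),
              resolution = resolution, z_threshold = z_threshold,
              fdr_q = fdr_q, master_seed = as.integer(master_seed),
              output_dir = output_dir, test_t1 = test_t1)
  class(cfg) <- "scn_run_config"
  cfg
}

#' Read a run configuration from JSON or YAML
#'
#' @param path configuration file; `.yaml`/`.yml` needs the `yaml` package,
#'   anything else is parsed as JSON. A `synthetic` block is converted via
#'   [synthetic_config()].
#' @return an [run_config()] object.
#' @export
read_run_config <- function(path) {
  raw <- if (grepl("\\.ya?ml$", path, ignore.case = TRUE)) {
    if (!requireNamespace("yaml", quietly = TRUE))
      stop("the 'yaml' package is needed for YAML configs", call. = FALSE)
    yaml::read_yaml(path)
  } else {
    jsonlite::read_json(path, simplifyVector = TRUE)
  }
  if (!is.null(raw$synthetic))
    raw$synthetic <- do.call(synthetic_config, raw$synthetic)
  do.call(run_config, raw)
}

metric_names <- c("local_efficiency", "global_efficiency", "participation")

# descriptive per-group metric values at a fixed penalty
group_metric_values <- function(x, labels, metric_name, rho, resolution,
                                seed) {
  v <- vapply(c("low", "high"), function(g) {
    adj <- fit_adjacency(x[names(labels)[labels == g], , drop = FALSE], rho)
    metric_value(adj, metric_name, resolution, seed)
  }, numeric(1L))
  stats::setNames(v, c("low", "high"))
}

#' Run the end-to-end structural covariance analysis
#'
#' Executes the full pipeline: read (or simulate) and validate the two
#' thickness tables, align timepoints, QC-screen for outliers, standardize
#' regions, choose the penalty by whole-sample cross-validation (one value,
#' reused by every comparison), form low/high groups per behavioural
#' component by median split, screen covariates for confounding, then for
#' each component x metric compute Time-1 descriptive group values, the
#' Time-2 cross-sectional permutation test, and the omnibus change test,
#' with Benjamini-Hochberg adjustment across the four components within
#' each metric x contrast family. Every random step is seeded from
#' `master_seed` via per-(component, metric, contrast) child seeds, so any
#' single cell can be reproduced in isolation.
#'
#' @param config an [run_config()] object.
#' @return an object of class `scn_run`: list with `rho` (and the CV curve
#'   if cross-validated), `qc` reports, `groups`, `covariate_screen`,
#'   `tests` (all `scn_permtest` objects), `tables` (one results data frame
#'   per metric, mirroring the reference layout), `whole_group` metrics per
#'   timepoint, and `seeds`.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "scn_run_config"))
  stage <- "load inputs"
  result <- tryCatch({
    if (!is.null(config$synthetic)) {
      cohort <- generate_cohort(config$synthetic)
      t1 <- cohort$thickness_t1
      t2 <- cohort$thickness_t2
      scores <- cohort$component_scores
      covars <- cohort$covariates
    } else {
      t1 <- read_thickness_table(config$thickness_t1, "T1")
      t2 <- read_thickness_table(config$thickness_t2, "T2")
      scores <- utils::read.csv(config$component_scores,
                                check.names = FALSE,
                                stringsAsFactors = FALSE)
      covars <- if (!is.null(config$covariates))
        utils::read.csv(config$covariates, check.names = FALSE,
                        stringsAsFactors = FALSE) else NULL
    }

    stage <- "align timepoints"
    al <- align_timepoints(t1, t2)
    t1 <- al$t1; t2 <- al$t2
    scores <- scores[match(rownames(t1), scores$subject_id), , drop = FALSE]
    if (anyNA(scores$subject_id))
      stop("component-score table is missing aligned subjects")
    components <- setdiff(names(scores), "subject_id")

    stage <- "quality control"
    qc <- list(T1 = detect_outliers(t1, config$z_threshold),
               T2 = detect_outliers(t2, config$z_threshold))

    stage <- "standardize regions"
    z1 <- standardize_regions(t1)
    z2 <- standardize_regions(t2)

    n_seeds <- 2L + length(components) * length(metric_names) * 3L
    seeds <- spawn_seeds(config$master_seed, n_seeds)

    stage <- "select regularization"
    # one penalty for every comparison, cross-validated on the whole
    # sample's baseline assessment
    cv <- NULL
    if (identical(config$rho, "cv")) {
      cv <- select_regularization(z1, rho_grid = config$rho_grid,
                                  k_folds = config$k_folds, seed = seeds[1L])
      rho <- cv$rho
    } else rho <- config$rho

    stage <- "whole-group networks"
    whole <- lapply(list(T1 = z1, T2 = z2), function(z) {
      compute_network_metrics(fit_adjacency(z, rho),
                              resolution = config$resolution,
                              seed = seeds[2L])
    })

    stage <- "median split"
    groups <- lapply(components, function(cm) median_split(scores, cm))
    names(groups) <- components

    stage <- "covariate screen"
    screen <- if (!is.null(covars))
      screen_covariates(groups, covars, fdr_q = config$fdr_q) else NULL

    stage <- "permutation tests"
    tests <- list()
    si <- 2L
    for (cm in components) {
      for (mt in metric_names) {
        key <- function(contrast) paste(cm, mt, contrast, sep = ".")
        s_t1 <- seeds[si <- si + 1L]
        s_t2 <- seeds[si <- si + 1L]
        s_om <- seeds[si <- si + 1L]
        if (config$test_t1) {
          tests[[key("T1")]] <- permutation_test(
            z1, groups[[cm]], mt, rho, n_perm = config$n_perm,
            resolution = config$resolution, seed = s_t1, contrast = "T1")
        } else {
          v <- group_metric_values(z1, groups[[cm]]$labels, mt, rho,
                                   config$resolution, s_t1)
          tests[[key("T1")]] <- new_permtest(cm, mt, "T1", v[["low"]],
                                             v[["high"]], numeric(0), 0L,
                                             s_t1, rho)
          tests[[key("T1")]]$p_raw <- NA_real_
        }
        tests[[key("T2")]] <- permutation_test(
          z2, groups[[cm]], mt, rho, n_perm = config$n_perm,
          resolution = config$resolution, seed = s_t2, contrast = "T2")
        tests[[key("T2-T1")]] <- omnibus_change_test(
          z1, z2, groups[[cm]], mt, rho, n_perm = config$n_perm,
          resolution = config$resolution, seed = s_om)
      }
    }

    stage <- "FDR adjustment"
    # family = the components within one metric x contrast
    for (mt in metric_names) {
      for (ct in c(if (config$test_t1) "T1", "T2", "T2-T1")) {
        keys <- paste(components, mt, ct, sep = ".")
        praw <- vapply(tests[keys], `[[`, numeric(1L), "p_raw")
        padj <- fdr_adjust(praw)
        for (i in seq_along(keys)) tests[[keys[i]]]$p_fdr <- padj[i]
      }
    }

    stage <- "result tables"
    tables <- lapply(metric_names, function(mt) {
      rows <- lapply(components, function(cm) {
        k <- function(ct) tests[[paste(cm, mt, ct, sep = ".")]]
        t1r <- k("T1"); t2r <- k("T2"); omr <- k("T2-T1")
        data.frame(
          component = cm,
          row = c("T1", "T2", "T2-T1", "omnibus"),
          low = c(t1r$observed_low, t2r$observed_low, omr$observed_low,
                  NA),
          high = c(t1r$observed_high, t2r$observed_high,
                   omr$observed_high, NA),
          diff = c(t1r$observed_diff, t2r$observed_diff,
                   omr$observed_diff, NA),
          p = c(t1r$p_raw, t2r$p_raw, NA, omr$p_raw),
          p_fdr = c(t1r$p_fdr, t2r$p_fdr, NA, omr$p_fdr),
          stringsAsFactors = FALSE)
      })
      do.call(rbind, rows)
    })
    names(tables) <- metric_names
    for (tb in tables) validate_results_table(tb, components)

    list(rho = rho, cv = cv, qc = qc, groups = groups,
         covariate_screen = screen, whole_group = whole, tests = tests,
         tables = tables, config = config,
         seeds = list(master = config$master_seed, children = seeds),
         aligned = list(t1 = t1, t2 = t2, dropped = al$dropped))
  }, error = function(e) {
    if (!is.null(config$output_dir)) {
      dir.create(config$output_dir, showWarnings = FALSE, recursive = TRUE)
      writeLines(c("status: incomplete", paste0("failed_stage: ", stage),
                   paste0("error: ", conditionMessage(e))),
                 file.path(config$output_dir, "MANIFEST"))
    }
    stop("pipeline failed at stage '", stage, "': ", conditionMessage(e),
         call. = FALSE)
  })
  class(result) <- "scn_run"
  if (!is.null(config$output_dir)) write_run_outputs(result)
  result
}

validate_results_table <- function(tb, components) {
  expected <- c("component", "row", "low", "high", "diff", "p", "p_fdr")
  if (!identical(names(tb), expected))
    stop("results table schema mismatch: got ",
         paste(names(tb), collapse = ", "), call. = FALSE)
  if (nrow(tb) != 4L * length(components))
    stop("results table has wrong number of rows", call. = FALSE)
  invisible(tb)
}

#' @export
print.scn_run <- function(x, ...) {
  cat("Structural covariance network analysis\n")
  cat(sprintf("  %d subjects, %d regions; rho = %.4g; n_perm = %d\n",
              nrow(x$aligned$t1), ncol(x$aligned$t1), x$rho,
              x$config$n_perm))
  for (tp in names(x$whole_group)) {
    m <- x$whole_group[[tp]]
    cat(sprintf(paste0("  whole group %s: local eff %.3f, global eff %.3f,",
                       " participation %.3f\n"), tp,
                m$mean_local_efficiency, m$global_efficiency,
                m$mean_participation))
  }
  sig <- Filter(function(t) !is.na(t$p_fdr) && t$p_fdr < x$config$fdr_q,
                x$tests)
  cat(sprintf("  %d of %d tested contrasts significant after FDR\n",
              length(sig), sum(!vapply(x$tests, function(t) is.na(t$p_raw),
                                       logical(1L)))))
  invisible(x)
}

write_run_outputs <- function(result) {
  dir <- result$config$output_dir
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  files <- character(0)
  for (mt in names(result$tables)) {
    f <- file.path(dir, paste0("results_", mt, ".csv"))
    write.csv(result$tables[[mt]], f, row.names = FALSE)
    files <- c(files, f)
  }
  for (tp in c("T1", "T2")) {
    f <- file.path(dir, paste0("qc_", tp, ".csv"))
    write.csv(as.data.frame(result$qc[[tp]]), f, row.names = FALSE)
    files <- c(files, f)
  }
  ga <- do.call(rbind, lapply(result$groups, function(g) data.frame(
    subject_id = names(g$labels), component = g$component_name,
    label = unname(g$labels), stringsAsFactors = FALSE)))
  f <- file.path(dir, "group_assignments.csv")
  write.csv(ga, f, row.names = FALSE)
  files <- c(files, f)
  if (!is.null(result$covariate_screen)) {
    f <- file.path(dir, "covariate_screen.csv")
    write.csv(as.data.frame(result$covariate_screen), f, row.names = FALSE)
    files <- c(files, f)
  }
  bundle <- list(
    rho = result$rho,
    n_perm = result$config$n_perm,
    resolution = result$config$resolution,
    fdr_q = result$config$fdr_q,
    seeds = result$seeds,
    cv_curve = if (!is.null(result$cv))
      list(rho_grid = result$cv$rho_grid,
           mean_loglik = result$cv$mean_loglik),
    whole_group = lapply(result$whole_group, function(m) list(
      mean_local_efficiency = m$mean_local_efficiency,
      global_efficiency = m$global_efficiency,
      mean_participation = m$mean_participation)),
    tests = lapply(result$tests, function(t) t[c(
      "component_name", "metric_name", "contrast", "observed_low",
      "observed_high", "observed_diff", "p_raw", "p_fdr", "n_perm",
      "seed", "rho")])
  )
  f <- file.path(dir, "results.json")
  jsonlite::write_json(bundle, f, auto_unbox = TRUE, digits = 12,
                       na = "null")
  files <- c(files, f)
  writeLines(c("status: complete", paste0("file: ", sort(basename(files)))),
             file.path(dir, "MANIFEST"))
  invisible(files)
}
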