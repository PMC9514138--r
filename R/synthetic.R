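#' Configuration for a synthetic longitudinal cohort
#'
#' Describes the statistical structure of a simulated two-timepoint cortical
#' thickness cohort: a block-structured inter-regional correlation matrix
#' (regions grouped into modules, higher correlation within modules than
#' between), per-region test-retest correlation across timepoints, and
#' skewed behavioural component scores. Defaults emulate the reference study
#' design: 114 subjects, 148 cortical regions, two assessments about 18
#' months apart, four parenting components with the published skewness
#' values, and a 57/57 median split on the warmth-like component.
#'
#' @param n_subjects number of subjects.
#' @param n_regions number of cortical regions (148 in the Destrieux atlas).
#' @param n_modules number of planted covariance modules; regions are
#'   assigned to modules in contiguous blocks sized as evenly as possible.
#' @param within_module_corr population correlation between regions of the
#'   same module, in `[0, 1)`.
#' @param between_module_corr population correlation between regions of
#'   different modules; must satisfy
#'   `0 <= between_module_corr <= within_module_corr < 1`.
#' @param group_effect multiplicative scaling applied to the between-module
#'   correlation of the low-scoring group (subjects below the median of the
#'   warmth-like component). `1` plants no group difference; values below 1
#'   make the low group's network more segregated.
#' @param group_effect_timepoint `"both"` (default) plants the group
#'   difference at both assessments; `"T2"` restricts it to the second
#'   timepoint (the Time-1 draw then follows the base model for everyone),
#'   for studying change contrasts.
#' @param timepoint_corr per-region test-retest correlation between the two
#'   timepoints, in `[0, 1)`.
#' @param mean_thickness mean cortical thickness in mm.
#' @param thickness_sd between-subject SD of thickness in mm.
#' @param score_skew target skewness of the four component scores; recycled
#'   to length 4. Defaults to the reference study's printed values.
#' @param seed integer RNG seed; the cohort is a deterministic function of
#'   the configuration.
#'
#' @return an object of class `scn_config` (a validated list).
#' @export
synthetic_config <- function(n_subjects = 114L,
                             n_regions = 148L,
                             n_modules = 4L,
                             within_module_corr = 0.55,
                             between_module_corr = 0.52,
                             group_effect = 1.0,
                             group_effect_timepoint = c("both", "T2"),
                             timepoint_corr = 0.7,
                             mean_thickness = 2.5,
                             thickness_sd = 0.1,
                             score_skew = c(1.98, 0.23, 0.89, -1.80),
                             seed = 1L) {
  cfg <- list(
    n_subjects = as.integer(n_subjects),
    n_regions = as.integer(n_regions),
    n_modules = as.integer(n_modules),
    within_module_corr = within_module_corr,
    between_module_corr = between_module_corr,
    group_effect = group_effect,
    group_effect_timepoint = match.arg(group_effect_timepoint),
    timepoint_corr = timepoint_corr,
    mean_thickness = mean_thickness,
    thickness_sd = thickness_sd,
    score_skew = rep_len(as.numeric(score_skew), 4L),
    seed = as.integer(seed)
  )
  class(cfg) <- "scn_config"
  validate_config(cfg)
  cfg
}

validate_config <- function(cfg) {
  with(cfg, {
    if (n_subjects < 4L) stop("n_subjects must be at least 4", call. = FALSE)
    if (n_regions < 2L) stop("n_regions must be at least 2", call. = FALSE)
    if (n_modules < 1L || n_modules > n_regions)
      stop("n_modules must be in [1, n_regions]", call. = FALSE)
    if (!(between_module_corr >= 0 && between_module_corr <= within_module_corr &&
          within_module_corr < 1))
      stop("require 0 <= between_module_corr <= within_module_corr < 1 ",
           "(got between_module_corr = ", between_module_corr,
           ", within_module_corr = ", within_module_corr, ")", call. = FALSE)
    if (timepoint_corr < 0 || timepoint_corr >= 1)
      stop("timepoint_corr must be in [0, 1)", call. = FALSE)
    if (thickness_sd <= 0) stop("thickness_sd must be positive", call. = FALSE)
    if (group_effect < 0)
      stop("group_effect must be non-negative", call. = FALSE)
  })
  # both implied correlation matrices (base, and low-group if an effect is
  # planted) must be positive definite
  check_pd <- function(mat, label) {
    ev <- min(eigen(mat, symmetric = TRUE, only.values = TRUE)$values)
    if (ev <= 1e-10)
      stop("implied population correlation matrix (", label, ") is not ",
           "positive definite (min eigenvalue ", signif(ev, 3),
           "); offending parameters: within_module_corr = ",
           cfg$within_module_corr, ", between_module_corr = ",
           cfg$between_module_corr, ", group_effect = ", cfg$group_effect,
           call. = FALSE)
  }
  check_pd(population_covariance(cfg), "group_effect not applied")
  if (cfg$group_effect != 1)
    check_pd(population_covariance(cfg, apply_group_effect = TRUE),
             "low group, group_effect applied")
  invisible(cfg)
}

#' @export
print.scn_config <- function(x, ...) {
  cat("Synthetic cohort configuration\n")
  cat(sprintf("  %d subjects x %d regions, %d modules\n",
              x$n_subjects, x$n_regions, x$n_modules))
  cat(sprintf("  correlation within/between modules: %.3f / %.3f\n",
              x$within_module_corr, x$between_module_corr))
  cat(sprintf("  test-retest correlation: %.3f; group effect: %.3f; seed: %d\n",
              x$timepoint_corr, x$group_effect, x$seed))
  invisible(x)
}

# contiguous module blocks, sized as evenly as possible
module_assignment <- function(n_regions, n_modules) {
  sizes <- rep(n_regions %/% n_modules, n_modules)
  extra <- n_regions %% n_modules
  if (extra > 0) sizes[seq_len(extra)] <- sizes[seq_len(extra)] + 1L
  rep(seq_len(n_modules), times = sizes)
}

#' Planted population correlation matrix
#'
#' The exact region-by-region correlation matrix implied by a synthetic
#' configuration: 1 on the diagonal, `within_module_corr` inside modules,
#' `between_module_corr` across modules (scaled by `group_effect` for the
#' low-scoring group when requested).
#'
#' @param config an [synthetic_config()] object.
#' @param apply_group_effect if `TRUE`, return the low group's matrix with
#'   the between-module correlation scaled by `config$group_effect`.
#' @return an `n_regions` x `n_regions` correlation matrix.
#' @export
population_covariance <- function(config, apply_group_effect = FALSE) {
  stopifnot(inherits(config, "scn_config"))
  mod <- module_assignment(config$n_regions, config$n_modules)
  same <- outer(mod, mod, "==")
  b <- config$between_module_corr
  if (apply_group_effect) b <- b * config$group_effect
  mat <- ifelse(same, config$within_module_corr, b)
  diag(mat) <- 1
  mat
}

# standardized (mean 0, sd 1) draws with a target skewness, via a
# sign-flipped log-normal; |skew| below 0.05 falls back to a normal
skewed_scores <- function(n, target_skew) {
  if (abs(target_skew) < 0.05) return(rnorm(n))
  skew_of_v <- function(v) (exp(v) + 2) * sqrt(exp(v) - 1)
  v <- uniroot(function(v) skew_of_v(v) - abs(target_skew),
               interval = c(1e-8, 10), tol = 1e-12)$root
  sig <- sqrt(v)
  y <- exp(sig * rnorm(n))
  y <- (y - exp(v / 2)) / sqrt((exp(v) - 1) * exp(v))
  sign(target_skew) * y
}

#' Generate a synthetic longitudinal cohort
#'
#' Draws a two-timepoint cortical-thickness cohort from the planted
#' block-structured multivariate normal model described by the
#' configuration. Thickness at Time 1 is multivariate normal with the
#' planted correlation; Time 2 is an equicorrelated redraw with per-region
#' test-retest correlation `timepoint_corr`. Component scores are drawn
#' from standardized skewed (log-normal) distributions; subjects below the
#' median of the warmth-like component form the "low" group, and when
#' `group_effect != 1` that group's between-module correlation is scaled
#' accordingly. The result is a deterministic function of the configuration
#' (including its seed).
#'
#' @param config an [synthetic_config()] object.
#' @return an object of class `scn_cohort`: a list with thickness matrices
#'   `thickness_t1` / `thickness_t2` (subjects x regions, with subject IDs as
#'   row names and region labels as column names), `component_scores`,
#'   `covariates`, and a `truth` record (module assignment, group labels and
#'   planted parameters) sufficient to recompute the population covariance.
#' @export
generate_cohort <- function(config) {
  stopifnot(inherits(config, "scn_config"))
  n <- config$n_subjects
  p <- config$n_regions
  subject_ids <- sprintf("S%04d", seq_len(n))
  half <- p - p %/% 2L
  region_labels <- c(sprintf("lh_region_%03d", seq_len(half)),
                     sprintf("rh_region_%03d", seq_len(p - half)))

  component_names <- c("negativity_epi", "warmth", "negativity_psi",
                       "communication")

  cohort <- with_seed(config$seed, {
    scores <- vapply(config$score_skew, function(s) skewed_scores(n, s),
                     numeric(n))
    colnames(scores) <- component_names
    rownames(scores) <- subject_ids

    # low/high labels from the warmth-like component (deterministic split)
    grp <- median_split_labels(scores[, "warmth"], subject_ids)

    C_high <- population_covariance(config)
    C_low <- if (config$group_effect != 1)
      population_covariance(config, apply_group_effect = TRUE) else C_high
    L_high <- chol(C_high)
    L_low <- chol(C_low)

    z1 <- matrix(rnorm(n * p), n, p)
    z2 <- matrix(rnorm(n * p), n, p)
    x1 <- matrix(0, n, p)
    x2 <- matrix(0, n, p)
    low <- grp == "low"
    tc <- config$timepoint_corr
    t2_only <- identical(config$group_effect_timepoint, "T2")
    L_low_t1 <- if (t2_only) L_high else L_low
    if (any(low)) {
      x1[low, ] <- z1[low, , drop = FALSE] %*% L_low_t1
      x2[low, ] <- tc * x1[low, , drop = FALSE] +
        sqrt(1 - tc^2) * (z2[low, , drop = FALSE] %*% L_low)
    }
    if (any(!low)) {
      x1[!low, ] <- z1[!low, , drop = FALSE] %*% L_high
      x2[!low, ] <- tc * x1[!low, , drop = FALSE] +
        sqrt(1 - tc^2) * (z2[!low, , drop = FALSE] %*% L_high)
    }

    t1 <- config$mean_thickness + config$thickness_sd * x1
    t2 <- config$mean_thickness + config$thickness_sd * x2
    dimnames(t1) <- dimnames(t2) <- list(subject_ids, region_labels)

    covariates <- data.frame(
      subject_id = subject_ids,
      age = rnorm(n, 8.42, 0.32),
      sex = rbinom(n, 1L, 0.535),
      depression = pmax(0, rnorm(n, 8.2, 6.0)),
      anxiety = pmax(0, rnorm(n, 26.1, 13.3)),
      traumatic_events = rpois(n, 3.8),
      maternal_occupation = pmin(100, pmax(0, rnorm(n, 61.5, 20.4))),
      stringsAsFactors = FALSE
    )

    list(
      thickness_t1 = thickness_matrix(t1, timepoint = "T1"),
      thickness_t2 = thickness_matrix(t2, timepoint = "T2"),
      component_scores = data.frame(subject_id = subject_ids, scores,
                                    stringsAsFactors = FALSE),
      covariates = covariates,
      truth = list(
        module_assignment = stats::setNames(
          module_assignment(p, config$n_modules), region_labels),
        group_labels = stats::setNames(grp, subject_ids),
        group_effect = config$group_effect,
        group_effect_timepoint = config$group_effect_timepoint,
        config = unclass(config)
      )
    )
  })
  class(cohort) <- "scn_cohort"
  cohort
}

#' @export
print.scn_cohort <- function(x, ...) {
  cat(sprintf("Synthetic cohort: %d subjects x %d regions, two timepoints\n",
              nrow(x$thickness_t1), ncol(x$thickness_t1)))
  tab <- table(x$truth$group_labels)
  cat(sprintf("  warmth median split: %d low / %d high; group effect %.3f\n",
              tab[["low"]], tab[["high"]], x$truth$group_effect))
  invisible(x)
}

#' Write a synthetic cohort to disk
#'
#' Writes the two thickness tables, the component-score table and the
#' covariate table as CSV (header row of region labels, first column the
#' subject ID), and the truth record as JSON.
#'
#' @param cohort an [generate_cohort()] result.
#' @param dir output directory (created if needed).
#' @return invisibly, the named vector of file paths written.
#' @export
write_cohort <- function(cohort, dir) {
  stopifnot(inherits(cohort, "scn_cohort"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- c(
    thickness_t1 = file.path(dir, "thickness_t1.csv"),
    thickness_t2 = file.path(dir, "thickness_t2.csv"),
    component_scores = file.path(dir, "component_scores.csv"),
    covariates = file.path(dir, "covariates.csv"),
    truth = file.path(dir, "truth.json")
  )
  write_thickness_table(cohort$thickness_t1, paths[["thickness_t1"]])
  write_thickness_table(cohort$thickness_t2, paths[["thickness_t2"]])
  write.csv(cohort$component_scores, paths[["component_scores"]],
            row.names = FALSE)
  write.csv(cohort$covariates, paths[["covariates"]], row.names = FALSE)
  jsonlite::write_json(cohort$truth, paths[["truth"]], auto_unbox = TRUE,
                       digits = NA)
  invisible(paths)
}
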