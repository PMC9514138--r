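# low/high labels from a median split; ties at the median are assigned in
# stable subject-ID order, each to the currently smaller group (low first on
# a size tie), guaranteeing determinism and |n_low - n_high| <= 1
median_split_labels <- function(scores, subject_ids) {
  med <- median(scores)
  lab <- ifelse(scores < med, "low", ifelse(scores > med, "high", NA))
  n_low <- sum(lab == "low", na.rm = TRUE)
  n_high <- sum(lab == "high", na.rm = TRUE)
  ties <- which(is.na(lab))
  for (i in ties[order(subject_ids[ties])]) {
    if (n_low <= n_high) {
      lab[i] <- "low"; n_low <- n_low + 1L
    } else {
      lab[i] <- "high"; n_high <- n_high + 1L
    }
  }
  lab
}

#' Split subjects into low/high groups at the component median
#'
#' Subjects scoring below the component's median go to the low group, above
#' it to the high group; scores exactly at the median are assigned
#' deterministically (stable subject-ID order, alternating toward the
#' smaller group) so that group sizes differ by at most one. With an even
#' number of distinct scores this reproduces the reference design's 57/57
#' split. The split depends only on score ranks, so it is invariant to any
#' strictly monotone transform of the scores.
#'
#' @param scores a data frame with a `subject_id` column and one numeric
#'   column per behavioural component (as produced by [generate_cohort()]).
#' @param component_name which component to split on.
#' @return an object of class `scn_groups`: list with `component_name`,
#'   `labels` (named character vector, `"low"`/`"high"` per subject) and
#'   `sizes`.
#' @export
median_split <- function(scores, component_name) {
  stopifnot(is.data.frame(scores), "subject_id" %in% names(scores))
  if (!component_name %in% names(scores))
    stop("unknown component: '", component_name, "' (available: ",
         paste(setdiff(names(scores), "subject_id"), collapse = ", "), ")",
         call. = FALSE)
  if (nrow(scores) < 4L)
    stop("median split needs at least 4 subjects", call. = FALSE)
  x <- scores[[component_name]]
  if (anyNA(x)) stop("missing scores for component '", component_name, "'",
                     call. = FALSE)
  lab <- median_split_labels(x, scores$subject_id)
  names(lab) <- scores$subject_id
  out <- list(component_name = component_name, labels = lab,
              sizes = c(n_low = sum(lab == "low"),
                        n_high = sum(lab == "high")))
  class(out) <- "scn_groups"
  out
}

#' @export
print.scn_groups <- function(x, ...) {
  cat(sprintf("Median split on '%s': %d low / %d high\n",
              x$component_name, x$sizes[["n_low"]], x$sizes[["n_high"]]))
  invisible(x)
}

#' Screen covariates for confounding across group splits
#'
#' For every (component split) x (covariate) pair, tests for a between-group
#' difference: one-way ANOVA for numeric covariates (with two groups this is
#' the squared two-sample pooled-variance t test) and a chi-squared test for
#' binary covariates such as sex. All tests are pooled into one
#' Benjamini-Hochberg FDR family (24 comparisons in the reference design:
#' 4 components x 6 covariates). Comparisons with zero within-group variance
#' are reported as `NA` with a warning and excluded from the FDR family.
#' The screen is a gate and report only — it never adjusts the downstream
#' analysis.
#'
#' @param groups a list of [median_split()] results (one per component).
#' @param covariates data frame with a `subject_id` column and one column
#'   per covariate; rows with a missing covariate value are dropped per
#'   test. Covariates with exactly two distinct values are treated as
#'   binary.
#' @param fdr_q FDR level used only to mark significance in the report.
#' @return a data frame (class `scn_screen`) with columns `component`,
#'   `covariate`, `test`, `statistic`, `p`, `p_fdr`, `significant`.
#' @export
screen_covariates <- function(groups, covariates, fdr_q = 0.05) {
  if (inherits(groups, "scn_groups")) groups <- list(groups)
  stopifnot(is.data.frame(covariates), "subject_id" %in% names(covariates))
  covs <- setdiff(names(covariates), "subject_id")
  rows <- list()
  for (g in groups) {
    lab <- g$labels[covariates$subject_id]
    if (anyNA(lab))
      stop("covariate table contains subjects outside the group assignment",
           call. = FALSE)
    for (v in covs) {
      x <- covariates[[v]]
      keep <- !is.na(x)
      xv <- x[keep]; lv <- factor(lab[keep], levels = c("low", "high"))
      if (min(table(lv)) < 2L)
        stop("fewer than 2 subjects per group for covariate '", v, "'",
             call. = FALSE)
      binary <- length(unique(xv)) == 2L
      if (binary) {
        tab <- table(lv, xv)
        ans <- suppressWarnings(chisq.test(tab, correct = FALSE))
        stat <- unname(ans$statistic); p <- ans$p.value; test <- "chisq"
      } else {
        within_var <- tapply(xv, lv, stats::var)
        if (any(within_var == 0, na.rm = TRUE) || stats::var(xv) == 0) {
          warning("zero within-group variance for covariate '", v,
                  "' in component '", g$component_name,
                  "'; comparison reported as NA", call. = FALSE)
          stat <- NA_real_; p <- NA_real_; test <- "anova"
        } else {
          fit <- aov(xv ~ lv)
          sm <- summary(fit)[[1L]]
          stat <- sm[["F value"]][1L]; p <- sm[["Pr(>F)"]][1L]; test <- "anova"
        }
      }
      rows[[length(rows) + 1L]] <- data.frame(
        component = g$component_name, covariate = v, test = test,
        statistic = stat, p = p, stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  out$p_fdr <- NA_real_
  ok <- !is.na(out$p)
  out$p_fdr[ok] <- fdr_adjust(out$p[ok])
  out$significant <- !is.na(out$p_fdr) & out$p_fdr < fdr_q
  class(out) <- c("scn_screen", class(out))
  out
}

#' @export
print.scn_screen <- function(x, ...) {
  cat(sprintf("Covariate screen: %d comparisons, %d significant after FDR\n",
              nrow(x), sum(x$significant)))
  print.data.frame(x, digits = 4)
  invisible(x)
}
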