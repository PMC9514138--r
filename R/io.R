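#' Construct and validate a thickness matrix
#'
#' A thickness matrix is a numeric subjects x regions matrix of regional
#' cortical thickness in mm, with unique subject IDs as row names, unique
#' region labels as column names, and a `timepoint` attribute. Validation
#' enforces no missing values and the physiological sanity bound
#' `0 < thickness < 10` mm.
#'
#' @param values numeric matrix, subjects in rows, regions in columns; row
#'   and column names are required unless given via `subject_ids` /
#'   `region_labels`.
#' @param subject_ids,region_labels optional dimension names, overriding any
#'   already on `values`.
#' @param timepoint timepoint label, e.g. `"T1"` or `"T2"`.
#' @return the validated matrix with class `thickness_matrix`.
#' @export
thickness_matrix <- function(values, subject_ids = rownames(values),
                             region_labels = colnames(values),
                             timepoint = "T1") {
  values <- as.matrix(values)
  if (is.null(subject_ids) || is.null(region_labels))
    stop("subject IDs and region labels are required", call. = FALSE)
  rownames(values) <- as.character(subject_ids)
  colnames(values) <- as.character(region_labels)
  attr(values, "timepoint") <- timepoint
  class(values) <- c("thickness_matrix", class(values))
  validate_thickness_matrix(values)
}

validate_thickness_matrix <- function(m) {
  if (!is.numeric(m)) stop("thickness values must be numeric", call. = FALSE)
  dup <- rownames(m)[duplicated(rownames(m))]
  if (length(dup))
    stop("duplicate subject IDs: ", paste(unique(dup), collapse = ", "),
         call. = FALSE)
  dup <- colnames(m)[duplicated(colnames(m))]
  if (length(dup))
    stop("duplicate region labels: ", paste(unique(dup), collapse = ", "),
         call. = FALSE)
  if (anyNA(m)) {
    idx <- which(is.na(m), arr.ind = TRUE)[1L, ]
    stop(sprintf("missing thickness value for subject '%s', region '%s'",
                 rownames(m)[idx[1L]], colnames(m)[idx[2L]]), call. = FALSE)
  }
  if (any(m <= 0 | m >= 10)) {
    idx <- which(m <= 0 | m >= 10, arr.ind = TRUE)[1L, ]
    stop(sprintf(paste0("thickness value %g for subject '%s', region '%s' is",
                        " outside the physiological range (0, 10) mm"),
                 m[idx[1L], idx[2L]], rownames(m)[idx[1L]],
                 colnames(m)[idx[2L]]), call. = FALSE)
  }
  m
}

#' Read a thickness table from delimited text
#'
#' Expects a header row of region labels and a subject-ID column (named
#' `subject_id`, or taken as the first column). The delimiter is sniffed
#' from the header line (comma vs tab) unless given. Duplicate subject IDs,
#' missing cells, non-numeric cells and physiologically impossible values
#' are hard errors naming the offending entry.
#'
#' @param path file path.
#' @param timepoint timepoint label to attach.
#' @param sep field delimiter; `NULL` (default) sniffs comma vs tab.
#' @return a [thickness_matrix()].
#' @export
read_thickness_table <- function(path, timepoint = "T1", sep = NULL) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  if (is.null(sep)) {
    header <- readLines(path, n = 1L)
    sep <- if (grepl("\t", header)) "\t" else ","
  }
  df <- read.table(path, header = TRUE, sep = sep, check.names = FALSE,
                   colClasses = "character", stringsAsFactors = FALSE)
  if (ncol(df) < 2L) stop("expected a subject-ID column plus at least one ",
                          "region column", call. = FALSE)
  id_col <- if ("subject_id" %in% names(df)) "subject_id" else names(df)[1L]
  ids <- df[[id_col]]
  vals <- df[, setdiff(names(df), id_col), drop = FALSE]
  raw <- as.matrix(vals)
  empty <- is.na(raw) | trimws(raw) == "" | raw == "NA"
  if (any(empty)) {
    idx <- which(empty, arr.ind = TRUE)[1L, ]
    stop(sprintf("missing thickness value for subject '%s', region '%s'",
                 ids[idx[1L]], colnames(raw)[idx[2L]]), call. = FALSE)
  }
  num <- suppressWarnings(
    vapply(vals, as.numeric, numeric(nrow(vals)), USE.NAMES = TRUE))
  num <- matrix(num, nrow = nrow(vals),
                dimnames = list(ids, colnames(vals)))
  bad <- which(is.na(num), arr.ind = TRUE)
  if (nrow(bad))
    stop(sprintf("non-numeric thickness cell '%s' at subject '%s', region '%s'",
                 raw[bad[1L, 1L], bad[1L, 2L]],
                 ids[bad[1L, 1L]], colnames(num)[bad[1L, 2L]]), call. = FALSE)
  thickness_matrix(num, timepoint = timepoint)
}

#' Write a thickness table as CSV
#'
#' Header row of region labels, first column `subject_id`. Values are
#' printed at full precision so that read -> write -> read round-trips
#' exactly.
#'
#' @param m a [thickness_matrix()].
#' @param path output path.
#' @return invisibly, `path`.
#' @export
write_thickness_table <- function(m, path) {
  # 17 significant digits guarantee exact double round-trip
  chr <- matrix(formatC(m, digits = 17, format = "g"), nrow(m),
                dimnames = dimnames(m))
  df <- data.frame(subject_id = rownames(m), chr, check.names = FALSE,
                   stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = ",", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Align two timepoints to a common subject set
#'
#' Restricts both matrices to the subjects present at both timepoints, in a
#' common (timepoint-1) order, and verifies that the region label sets are
#' identical (columns of the second matrix are reordered to match the first).
#'
#' @param t1,t2 validated [thickness_matrix()] objects.
#' @return a list with elements `t1`, `t2` (aligned matrices) and `dropped`
#'   (subject IDs present at only one timepoint).
#' @export
align_timepoints <- function(t1, t2) {
  diff1 <- setdiff(colnames(t1), colnames(t2))
  diff2 <- setdiff(colnames(t2), colnames(t1))
  if (length(diff1) || length(diff2))
    stop("region label sets differ between timepoints: ",
         paste(c(diff1, diff2), collapse = ", "), call. = FALSE)
  common <- intersect(rownames(t1), rownames(t2))
  if (length(common) == 0L)
    stop("no subjects shared between timepoints", call. = FALSE)
  dropped <- c(setdiff(rownames(t1), common), setdiff(rownames(t2), common))
  out1 <- t1[common, , drop = FALSE]
  out2 <- t2[common, colnames(t1), drop = FALSE]
  attr(out1, "timepoint") <- attr(t1, "timepoint")
  attr(out2, "timepoint") <- attr(t2, "timepoint")
  class(out1) <- class(out2) <- c("thickness_matrix", "matrix", "array")
  list(t1 = out1, t2 = out2, dropped = dropped)
}

#' Flag outlying thickness values by regional z-score
#'
#' Within each region, values are z-scored across subjects (sample SD,
#' n - 1 denominator) and entries with `|z| >= z_threshold` are flagged.
#' Constant regions (zero SD) produce no flags. Flags are reported, never
#' auto-removed; exclusion is an explicit downstream choice.
#'
#' @param m a validated [thickness_matrix()].
#' @param z_threshold positive flagging threshold (default 3).
#' @return a data frame of class `scn_qc` with columns `subject_id`,
#'   `region_label`, `value`, `z_score`, and attribute `threshold`.
#' @export
detect_outliers <- function(m, z_threshold = 3) {
  stopifnot_scalar_number(z_threshold, "z_threshold")
  if (z_threshold <= 0) stop("z_threshold must be positive", call. = FALSE)
  if (nrow(m) < 3L)
    stop("outlier detection needs at least 3 subjects", call. = FALSE)
  mu <- colMeans(m)
  sdev <- apply(m, 2L, sd)
  z <- sweep(sweep(m, 2L, mu, "-"), 2L, ifelse(sdev > 0, sdev, Inf), "/")
  hit <- which(abs(z) >= z_threshold, arr.ind = TRUE)
  out <- data.frame(
    subject_id = rownames(m)[hit[, 1L]],
    region_label = colnames(m)[hit[, 2L]],
    value = m[hit],
    z_score = z[hit],
    stringsAsFactors = FALSE
  )
  out <- out[order(out$region_label, out$subject_id), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "threshold") <- z_threshold
  class(out) <- c("scn_qc", class(out))
  out
}

#' @export
print.scn_qc <- function(x, ...) {
  cat(sprintf("QC report: %d flagged value(s) at |z| >= %g\n",
              nrow(x), attr(x, "threshold")))
  if (nrow(x)) print.data.frame(head(x, 20L))
  invisible(x)
}

#' Standardize regions to z-units
#'
#' Centers and scales each region (column) to mean 0 and SD 1, using the
#' sample SD (n - 1 denominator) — the same convention as
#' [detect_outliers()]. Covariance estimation consumes these standardized
#' columns, so the lasso penalty is on the correlation scale.
#'
#' @param m a validated [thickness_matrix()] (or any numeric matrix with
#'   dimnames).
#' @return a numeric matrix of the same shape in z-units.
#' @export
standardize_regions <- function(m) {
  sdev <- apply(m, 2L, sd)
  if (any(sdev == 0))
    stop("zero-variance region(s): ",
         paste(colnames(m)[sdev == 0], collapse = ", "), call. = FALSE)
  out <- sweep(sweep(m, 2L, colMeans(m), "-"), 2L, sdev, "/")
  out <- matrix(out, nrow(m), ncol(m), dimnames = dimnames(m))
  out
}
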