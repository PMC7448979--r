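# Molecular-descriptor preprocessing: the four removal criteria applied to a
# numeric entities x descriptors matrix before canonical correlation analysis.
# Stage order is fixed: missing values -> dominant value -> low RSD ->
# pairwise correlation.

#' Read a descriptor table
#'
#' First column is the entity id; all remaining columns are numeric
#' descriptors. Blank cells and `NA` are missing values.
#'
#' @param path CSV (comma) or TSV/other (tab) file with a header row.
#' @return numeric matrix with entity ids as row names.
#' @export
read_descriptors <- function(path) {
  df <- read_table_auto(path)
  if (ncol(df) < 2L) stop("descriptor table needs an id column plus data")
  ids <- as.character(df[[1L]])
  if (anyDuplicated(ids)) stop("duplicate entity ids in descriptor table")
  m <- as.matrix(df[, -1L, drop = FALSE])
  storage.mode(m) <- "double"
  rownames(m) <- ids
  m
}

check_dm <- function(dm) {
  if (!is.matrix(dm) || !is.numeric(dm)) {
    stop("descriptor matrix must be a numeric matrix")
  }
  if (ncol(dm) > 0L &&
        (is.null(colnames(dm)) || anyDuplicated(colnames(dm)))) {
    stop("descriptor matrix needs unique column names")
  }
  invisible(dm)
}

#' Drop descriptors with missing values
#'
#' Removes every column containing at least one `NA`/`NaN`.
#'
#' @param dm numeric matrix, rows = entities, columns = descriptors.
#' @return list with `matrix` (surviving columns) and `dropped` (names).
#' @export
drop_missing <- function(dm) {
  check_dm(dm)
  bad <- colSums(is.na(dm)) > 0L
  list(matrix = dm[, !bad, drop = FALSE], dropped = colnames(dm)[bad])
}

#' Drop near-constant descriptors (dominant modal value)
#'
#' A column is removed when its most frequent value occupies a strictly
#' greater fraction of rows than `max_mode_fraction`. Values are compared
#' after rounding to 6 significant digits, so floating-point copies of the
#' same underlying value count as equal.
#'
#' @param dm numeric matrix without missing values.
#' @param max_mode_fraction drop when mode fraction exceeds this (default
#'   0.80, strict inequality).
#' @return list with `matrix` and `dropped`.
#' @export
drop_dominant_value <- function(dm, max_mode_fraction = 0.80) {
  check_dm(dm)
  if (anyNA(dm)) stop("missing values present; run drop_missing first")
  n <- nrow(dm)
  frac <- vapply(seq_len(ncol(dm)), function(j) {
    if (n == 0L) return(0)
    max(table(signif(dm[, j], 6L))) / n
  }, numeric(1))
  bad <- frac > max_mode_fraction
  list(matrix = dm[, !bad, drop = FALSE], dropped = colnames(dm)[bad])
}

#' Drop descriptors with low relative standard deviation
#'
#' RSD is the sample standard deviation divided by the absolute mean. A
#' column is removed when RSD < `min_rsd` (strict). Columns with mean exactly
#' 0 and positive spread are kept (RSD treated as infinite); a column with
#' mean 0 and zero spread is dropped.
#'
#' @param dm numeric matrix without missing values.
#' @param min_rsd threshold (default 0.05).
#' @return list with `matrix` and `dropped`.
#' @export
drop_low_rsd <- function(dm, min_rsd = 0.05) {
  check_dm(dm)
  if (anyNA(dm)) stop("missing values present; run drop_missing first")
  mu <- colMeans(dm)
  sdv <- vapply(seq_len(ncol(dm)), function(j) stats::sd(dm[, j]),
                numeric(1))
  rsd <- ifelse(mu == 0, ifelse(sdv > 0, Inf, 0), sdv / abs(mu))
  bad <- rsd < min_rsd
  list(matrix = dm[, !bad, drop = FALSE], dropped = colnames(dm)[bad])
}

#' Drop one of each highly correlated descriptor pair
#'
#' Greedy removal: while any surviving pair has |Pearson r| above
#' `max_abs_r`, take the highest-|r| pair and drop whichever member has the
#' larger mean |r| against all other surviving columns (tie: the later
#' column). Correlations are recomputed on survivors after each removal.
#'
#' @param dm numeric matrix without missing values, at least 3 rows.
#' @param max_abs_r threshold (default 0.9, strict inequality).
#' @return list with `matrix` and `dropped` (in removal order).
#' @export
drop_correlated <- function(dm, max_abs_r = 0.9) {
  check_dm(dm)
  if (anyNA(dm)) stop("missing values present; run drop_missing first")
  if (nrow(dm) < 3L) {
    stop("correlation filter needs at least 3 rows")
  }
  dropped <- character()
  m <- dm
  while (ncol(m) >= 2L) {
    cm <- abs(suppressWarnings(stats::cor(m)))
    cm[is.na(cm)] <- 0
    diag(cm) <- 0
    top <- max(cm)
    if (top <= max_abs_r) break
    idx <- which(cm == top, arr.ind = TRUE)
    idx <- idx[idx[, 1L] < idx[, 2L], , drop = FALSE]
    idx <- idx[order(idx[, 1L], idx[, 2L]), , drop = FALSE]
    i <- idx[1L, 1L]; j <- idx[1L, 2L]
    mean_i <- mean(cm[i, -i])
    mean_j <- mean(cm[j, -j])
    drop_col <- if (mean_i > mean_j) i else if (mean_j > mean_i) j else
      max(i, j)
    dropped <- c(dropped, colnames(m)[drop_col])
    m <- m[, -drop_col, drop = FALSE]
  }
  list(matrix = m, dropped = dropped)
}

#' Preprocess a descriptor matrix
#'
#' Applies the four removal stages in fixed order (missing values ->
#' dominant value -> low RSD -> pairwise correlation) and returns the
#' surviving matrix together with an auditable report of what each stage
#' dropped. Rows (entities) are never altered.
#'
#' @param dm numeric matrix, rows = entities, columns = descriptors.
#' @param max_mode_fraction see [drop_dominant_value()].
#' @param min_rsd see [drop_low_rsd()].
#' @param max_abs_r see [drop_correlated()].
#' @return list of class `preprocess_result` with `matrix` and `report`
#'   (`dropped` per stage, `kept`, `stages`).
#' @export
preprocess_descriptors <- function(dm, max_mode_fraction = 0.80,
                                   min_rsd = 0.05, max_abs_r = 0.9) {
  check_dm(dm)
  s1 <- drop_missing(dm)
  s2 <- drop_dominant_value(s1$matrix, max_mode_fraction)
  s3 <- drop_low_rsd(s2$matrix, min_rsd)
  s4 <- drop_correlated(s3$matrix, max_abs_r)
  if (ncol(s4$matrix) == 0L) {
    stop("no descriptors survive preprocessing")
  }
  report <- list(
    dropped = list(missing = s1$dropped, dominant_value = s2$dropped,
                   low_rsd = s3$dropped, correlated = s4$dropped),
    kept = colnames(s4$matrix),
    stages = c("missing", "dominant_value", "low_rsd", "correlated")
  )
  structure(list(matrix = s4$matrix, report = report),
            class = "preprocess_result")
}

#' @export
print.preprocess_result <- function(x, ...) {
  d <- x$report$dropped
  cat("Descriptor preprocessing\n")
  cat(sprintf("  kept %d descriptor(s); dropped: missing %d, dominant %d, low-RSD %d, correlated %d\n",
              length(x$report$kept), length(d$missing),
              length(d$dominant_value), length(d$low_rsd),
              length(d$correlated)))
  invisible(x)
}
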