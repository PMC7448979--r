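# Canonical correlation analysis over interacting compound-protein descriptor
# pairs, Bartlett sequential significance, and loading-based selection of the
# feature descriptors that define the correlation space.

#' Build the paired descriptor sample from known compound-target edges
#'
#' Each known CT edge contributes one row: the compound's descriptors on the
#' X side and the protein's on the Y side. Edges whose endpoints are missing
#' from a descriptor matrix are dropped and counted. Rows are ordered by
#' (compound id, protein id) so the sample is deterministic.
#'
#' @param net a [tripartite_network()]; only `known` CT edges are used.
#' @param compound_dm,protein_dm numeric matrices with entity-id row names.
#' @return list of class `paired_sample`: `X` (n x p), `Y` (n x q), `pairs`
#'   (data.frame compound/protein), `n_dropped`.
#' @export
build_paired_sample <- function(net, compound_dm, protein_dm) {
  ct <- known_edges(net)
  ct <- ct[ct$pair_type == "CT", , drop = FALSE]
  usable <- ct$a %in% rownames(compound_dm) & ct$b %in% rownames(protein_dm)
  n_dropped <- sum(!usable)
  ct <- ct[usable, , drop = FALSE]
  if (nrow(ct) == 0L) {
    stop("no usable compound-target edges (all endpoints missing from the descriptor matrices)")
  }
  ct <- ct[order(ct$a, ct$b), , drop = FALSE]
  structure(list(X = compound_dm[ct$a, , drop = FALSE],
                 Y = protein_dm[ct$b, , drop = FALSE],
                 pairs = data.frame(compound = ct$a, protein = ct$b,
                                    stringsAsFactors = FALSE),
                 n_dropped = n_dropped),
            class = "paired_sample")
}

#' Fit a canonical correlation analysis
#'
#' Columns of both blocks are standardized to zero mean and unit (sample)
#' standard deviation; canonical correlations and weights are computed by
#' singular value decomposition of the whitened cross-covariance
#' (whitening by symmetric inverse square roots of the within-set
#' covariances, with an optional ridge added to their diagonals).
#' Weights are scaled so canonical variates have unit sample variance;
#' loadings are Pearson correlations between each original column and each
#' variate.
#'
#' @param x,y numeric matrices (or a `paired_sample` passed as `x`), n rows
#'   each, no missing values, no zero-variance columns.
#' @param ridge nonnegative regularizer added to the within-set covariance
#'   diagonals (as a fraction of their mean diagonal); default 0.
#' @return object of class `cca_fit`: canonical correlations `cor` (sorted
#'   descending, clipped to [0, 1]), `xcoef`/`ycoef` (weights for the
#'   standardized columns), `xloadings`/`yloadings`, standardization stats
#'   (`xcenter`, `xscale`, `ycenter`, `yscale`), `n`, `p`, `q`. Significance
#'   fields are filled by [canonical_significance()].
#' @export
fit_cca <- function(x, y = NULL, ridge = 0) {
  if (inherits(x, "paired_sample")) {
    y <- x$Y
    x <- x$X
  }
  stopifnot(is.matrix(x), is.matrix(y), nrow(x) == nrow(y), ridge >= 0)
  n <- nrow(x); p <- ncol(x); q <- ncol(y)
  if (n < 3L) stop("need at least 3 paired rows")
  if (p < 1L || q < 1L) stop("both blocks need at least one column")
  if (anyNA(x) || anyNA(y)) stop("missing values; preprocess first")
  if (n <= max(p, q) && ridge == 0) {
    stop("n <= max(p, q): within-set covariance is singular; ",
         "add a ridge or reduce the descriptor count")
  }
  if (is.null(colnames(x))) colnames(x) <- paste0("x", seq_len(p))
  if (is.null(colnames(y))) colnames(y) <- paste0("y", seq_len(q))

  xs <- scale(x)
  ys <- scale(y)
  if (any(attr(xs, "scaled:scale") == 0) || any(attr(ys, "scaled:scale") == 0)) {
    zv <- c(colnames(x)[attr(xs, "scaled:scale") == 0],
            colnames(y)[attr(ys, "scaled:scale") == 0])
    stop("zero-variance column(s): ", paste(zv, collapse = ", "),
         " (should have been removed by preprocessing)")
  }

  sxx <- crossprod(xs) / (n - 1)
  syy <- crossprod(ys) / (n - 1)
  sxy <- crossprod(xs, ys) / (n - 1)
  if (ridge > 0) {
    sxx <- sxx + ridge * mean(diag(sxx)) * diag(p)
    syy <- syy + ridge * mean(diag(syy)) * diag(q)
  }
  wx <- inv_sqrt_sym(sxx)
  wy <- inv_sqrt_sym(syy)
  sv <- svd(wx %*% sxy %*% wy)
  s <- min(p, q)
  r <- pmin(pmax(sv$d[seq_len(s)], 0), 1)
  xcoef <- wx %*% sv$u[, seq_len(s), drop = FALSE]
  ycoef <- wy %*% sv$v[, seq_len(s), drop = FALSE]
  u_scores <- xs %*% xcoef
  v_scores <- ys %*% ycoef
  # enforce unit sample variance of the variates (exact up to the ridge)
  su <- apply(u_scores, 2L, stats::sd)
  sv2 <- apply(v_scores, 2L, stats::sd)
  xcoef <- sweep(xcoef, 2L, ifelse(su > 0, su, 1), "/")
  ycoef <- sweep(ycoef, 2L, ifelse(sv2 > 0, sv2, 1), "/")
  u_scores <- sweep(u_scores, 2L, ifelse(su > 0, su, 1), "/")
  v_scores <- sweep(v_scores, 2L, ifelse(sv2 > 0, sv2, 1), "/")
  dimnames(xcoef) <- list(colnames(x), paste0("CV", seq_len(s)))
  dimnames(ycoef) <- list(colnames(y), paste0("CV", seq_len(s)))

  structure(list(
    cor = r,
    xcoef = xcoef, ycoef = ycoef,
    xloadings = stats::cor(xs, u_scores),
    yloadings = stats::cor(ys, v_scores),
    xcenter = attr(xs, "scaled:center"), xscale = attr(xs, "scaled:scale"),
    ycenter = attr(ys, "scaled:center"), yscale = attr(ys, "scaled:scale"),
    n = n, p = p, q = q, ridge = ridge,
    lambda = NULL, chisq = NULL, df = NULL, pvalue = NULL
  ), class = "cca_fit")
}

# symmetric inverse square root with a small eigenvalue floor
inv_sqrt_sym <- function(m) {
  e <- eigen(m, symmetric = TRUE)
  vals <- pmax(e$values, .Machine$double.eps * max(e$values, 1))
  e$vectors %*% (t(e$vectors) / sqrt(vals))
}

#' Bartlett sequential significance test for canonical correlations
#'
#' For each k, tests whether the k-th and all later canonical correlations
#' are zero: Wilks Lambda_k = prod_{i>=k} (1 - r_i^2), chi-square statistic
#' -(n - 1 - (p + q + 1)/2) log Lambda_k on (p - k + 1)(q - k + 1) degrees
#' of freedom.
#'
#' @param fit a [fit_cca()] object.
#' @param n sample size; defaults to the fit's own n.
#' @return The fit with `lambda`, `chisq`, `df` and `pvalue` filled in.
#' @export
canonical_significance <- function(fit, n = fit$n) {
  stopifnot(inherits(fit, "cca_fit"))
  s <- length(fit$cor)
  lambda <- rev(cumprod(rev(1 - fit$cor^2)))
  mult <- n - 1 - (fit$p + fit$q + 1) / 2
  k <- seq_len(s)
  df <- (fit$p - k + 1) * (fit$q - k + 1)
  if (mult <= 0) {
    warning("sample too small for the chi-square approximation; p-values set to 1")
    chisq <- rep(0, s)
    pval <- rep(1, s)
  } else {
    chisq <- -mult * log(pmax(lambda, .Machine$double.xmin))
    pval <- stats::pchisq(chisq, df, lower.tail = FALSE)
  }
  fit$lambda <- lambda
  fit$chisq <- chisq
  fit$df <- df
  fit$pvalue <- pval
  fit
}

#' Select feature descriptors from significant canonical variates
#'
#' Contributing variates are those with canonical correlation above `r_min`
#' and Bartlett p-value below `alpha`. A descriptor is selected when the
#' absolute value of its structure loading on at least one contributing
#' variate reaches `loading_cutoff`.
#'
#' @param fit a [fit_cca()] object with p-values
#'   (see [canonical_significance()]).
#' @param r_min minimum canonical correlation (default 0.8, strict).
#' @param alpha significance level (default 0.01, strict).
#' @param loading_cutoff minimum |loading| (default 0.3, inclusive).
#' @return object of class `ctcs_feature_selection`: `compound_descriptors`,
#'   `protein_descriptors`, `provenance` (thresholds and contributing variate
#'   indices).
#' @export
select_feature_descriptors <- function(fit, r_min = 0.8, alpha = 0.01,
                                       loading_cutoff = 0.3) {
  stopifnot(inherits(fit, "cca_fit"))
  if (is.null(fit$pvalue)) fit <- canonical_significance(fit)
  contributing <- which(fit$cor > r_min & fit$pvalue < alpha)
  if (!length(contributing)) {
    stop("no significant canonical variate (r > ", r_min, ", p < ", alpha,
         ")")
  }
  sel_x <- rownames(fit$xloadings)[
    apply(abs(fit$xloadings[, contributing, drop = FALSE]), 1L, max) >=
      loading_cutoff]
  sel_y <- rownames(fit$yloadings)[
    apply(abs(fit$yloadings[, contributing, drop = FALSE]), 1L, max) >=
      loading_cutoff]
  if (!length(sel_x) || !length(sel_y)) {
    stop("empty descriptor selection at loading cutoff ", loading_cutoff,
         "; lower the cutoff")
  }
  structure(list(compound_descriptors = sel_x,
                 protein_descriptors = sel_y,
                 provenance = list(r_min = r_min, alpha = alpha,
                                   loading_cutoff = loading_cutoff,
                                   variates = contributing,
                                   cor = fit$cor[contributing])),
            class = "ctcs_feature_selection")
}

#' @export
print.cca_fit <- function(x, digits = 3, ...) {
  cat("Canonical correlation analysis: n =", x$n, ", p =", x$p, ", q =",
      x$q, "\n")
  tab <- data.frame(cor = round(x$cor, digits))
  if (!is.null(x$pvalue)) {
    tab$wilks <- round(x$lambda, digits)
    tab$chisq <- round(x$chisq, digits)
    tab$df <- x$df
    tab$p <- signif(x$pvalue, digits)
  }
  print(tab)
  invisible(x)
}

#' @export
print.ctcs_feature_selection <- function(x, ...) {
  cat("Feature selection from", length(x$provenance$variates),
      "contributing canonical variate(s)\n")
  cat("  compound descriptors:", length(x$compound_descriptors), "\n")
  cat("  protein descriptors: ", length(x$protein_descriptors), "\n")
  invisible(x)
}
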