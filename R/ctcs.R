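# Compound-target correlation-space interaction prediction (CTCS-IPM).
#
# Compounds known to act on a target span the "compound space" of that target
# (symmetrically, the "target space" of a compound) in the standardized
# selected-descriptor space. Every anchor gets a distance threshold derived
# from the pairwise Euclidean distances among its members; a candidate is
# predicted to interact when its distances to the members satisfy the
# decision rule (default: every distance within the threshold).

#' Standardize selected feature columns
#'
#' @param dm numeric matrix with entity-id row names.
#' @param columns descriptor names to keep (must exist in `dm`).
#' @param stats optional list with `center` and `scale` (training statistics)
#'   to reuse; when NULL the statistics are computed from `dm` and returned.
#' @return list with `matrix` (z-scored) and `stats`.
#' @export
standardize_features <- function(dm, columns = colnames(dm), stats = NULL) {
  missing_cols <- setdiff(columns, colnames(dm))
  if (length(missing_cols)) {
    stop("columns absent from descriptor matrix: ",
         paste(missing_cols, collapse = ", "))
  }
  m <- dm[, columns, drop = FALSE]
  if (is.null(stats)) {
    center <- colMeans(m)
    scl <- vapply(seq_len(ncol(m)), function(j) stats::sd(m[, j]), numeric(1))
    names(scl) <- colnames(m)
    if (any(scl == 0)) {
      stop("zero-variance feature column(s): ",
           paste(colnames(m)[scl == 0], collapse = ", "))
    }
    stats <- list(center = center, scale = scl)
  } else {
    if (any(stats$scale[columns] == 0)) {
      stop("zero-sd column under reference statistics")
    }
  }
  z <- sweep(sweep(m, 2L, stats$center[columns]), 2L, stats$scale[columns],
             "/")
  list(matrix = z, stats = stats)
}

#' Euclidean distance between two feature vectors
#'
#' @param u,v numeric vectors of equal length.
#' @return sqrt(sum((u - v)^2)).
#' @export
euclidean_distance <- function(u, v) {
  if (length(u) != length(v)) stop("length mismatch")
  sqrt(sum((u - v)^2))
}

#' Distance threshold of an interaction space
#'
#' Three readings of "the upper limit of a 95% confidence interval of all
#' pairwise distances" are implemented:
#' \describe{
#'   \item{mean_plus_1p96sd}{mean + z_{(1+level)/2} * sd — a normal-
#'     approximation interval covering the distances themselves (default).}
#'   \item{ci_mean_t95}{mean + t_{(1+level)/2, m-1} * sd / sqrt(m) — the
#'     t-based upper confidence limit of the MEAN distance. Note that this
#'     limit converges to the mean pairwise distance as m grows, which makes
#'     it a very tight envelope for classification.}
#'   \item{percentile95}{the empirical `level` quantile (type-7
#'     interpolation).}
#' }
#' A single distance (m = 1) is returned unchanged, flagged degenerate.
#'
#' @param distances numeric vector of pairwise distances (length >= 1).
#' @param method threshold flavour, see above.
#' @param level confidence level (default 0.95).
#' @return the threshold, with attribute `degenerate` when m = 1.
#' @export
compute_threshold <- function(distances,
                              method = c("mean_plus_1p96sd", "ci_mean_t95",
                                         "percentile95"),
                              level = 0.95) {
  method <- match.arg(method)
  m <- length(distances)
  if (m == 0L) stop("no distances: threshold undefined")
  if (m == 1L) {
    return(structure(distances[[1L]], degenerate = TRUE))
  }
  mu <- mean(distances)
  sdv <- stats::sd(distances)
  switch(method,
    ci_mean_t95 = mu + stats::qt((1 + level) / 2, m - 1) * sdv / sqrt(m),
    mean_plus_1p96sd = mu + stats::qnorm((1 + level) / 2) * sdv,
    percentile95 = unname(stats::quantile(distances, level, type = 7))
  )
}

#' Build the interaction space of an anchor entity
#'
#' Members are the anchor's known partners present in the feature matrix.
#' With fewer than `min_members` members a skip marker is returned instead
#' of a space (a threshold from one or two points is not meaningful).
#'
#' @param anchor entity id the space belongs to (a target for a compound
#'   space, a compound for a target space).
#' @param member_ids ids of the anchor's known interaction partners.
#' @param features standardized feature matrix with entity-id row names.
#' @param min_members minimum member count (default 3).
#' @param threshold_method,level see [compute_threshold()].
#' @return object of class `entity_space` (anchor, member_ids, features,
#'   pairwise_distances, threshold, threshold_method) or a list with
#'   `skipped = TRUE` and a `reason`.
#' @export
build_space <- function(anchor, member_ids, features, min_members = 3L,
                        threshold_method = c("mean_plus_1p96sd",
                                             "ci_mean_t95", "percentile95"),
                        level = 0.95) {
  threshold_method <- match.arg(threshold_method)
  member_ids <- sort(unique(member_ids))
  member_ids <- member_ids[member_ids %in% rownames(features)]
  if (length(member_ids) < min_members) {
    return(list(anchor = anchor, skipped = TRUE,
                reason = sprintf("insufficient members (%d < %d)",
                                 length(member_ids), min_members)))
  }
  mf <- features[member_ids, , drop = FALSE]
  d <- as.vector(stats::dist(mf))
  structure(list(anchor = anchor, member_ids = member_ids, features = mf,
                 pairwise_distances = d,
                 threshold = compute_threshold(d, threshold_method, level),
                 threshold_method = threshold_method, level = level,
                 skipped = FALSE),
            class = "entity_space")
}

#' Score one candidate against an interaction space
#'
#' @param candidate numeric feature vector on the space's columns.
#' @param space an `entity_space` from [build_space()].
#' @param rule decision rule: `all` (every candidate-member distance within
#'   the threshold, the published criterion), `any` (at least one), or
#'   `mean` (mean distance within the threshold).
#' @return one-row data.frame: `anchor`, `candidate`, `n_members`, `d_max`,
#'   `d_mean`, `d_min`, `threshold`, `rule`, `decision` (logical).
#' @export
predict_pair <- function(candidate, space, rule = c("all", "any", "mean")) {
  rule <- match.arg(rule)
  stopifnot(inherits(space, "entity_space"))
  if (length(candidate) != ncol(space$features)) {
    stop("candidate length ", length(candidate),
         " does not match space dimension ", ncol(space$features))
  }
  d <- sqrt(colSums((t(space$features) - as.numeric(candidate))^2))
  thr <- as.numeric(space$threshold)
  decision <- switch(rule,
                     all = all(d <= thr),
                     any = any(d <= thr),
                     mean = mean(d) <= thr)
  data.frame(anchor = space$anchor,
             candidate = NA_character_,
             n_members = length(d),
             d_max = max(d), d_mean = mean(d), d_min = min(d),
             threshold = thr, rule = rule, decision = decision,
             stringsAsFactors = FALSE)
}

#' Fit the compound-target correlation-space prediction model
#'
#' Full pipeline on the known CT edges of a network: descriptor
#' preprocessing (fit on the interacting entities only), canonical
#' correlation analysis of the paired sample, Bartlett significance,
#' loading-based feature selection, feature standardization with training
#' statistics, and construction of the per-target compound spaces and
#' per-compound target spaces with their distance thresholds.
#'
#' @param net a [tripartite_network()] whose known CT edges are the training
#'   interactions.
#' @param compound_dm,protein_dm raw descriptor matrices (entity-id row
#'   names).
#' @param preprocess apply the four-stage descriptor cleaning first.
#' @param max_mode_fraction,min_rsd,max_abs_r see [preprocess_descriptors()].
#' @param r_min,alpha,loading_cutoff see [select_feature_descriptors()].
#' @param threshold_method,level see [compute_threshold()].
#' @param min_members minimum space size, see [build_space()].
#' @param ridge see [fit_cca()].
#' @return object of class `ctcs_ipm` with the fitted CCA, the feature
#'   selection, standardized feature matrices (all entities, training
#'   statistics), the target- and compound-anchored spaces, skip markers,
#'   and the training edges.
#' @export
ctcs_ipm <- function(net, compound_dm, protein_dm,
                     preprocess = TRUE,
                     max_mode_fraction = 0.80, min_rsd = 0.05,
                     max_abs_r = 0.9,
                     r_min = 0.8, alpha = 0.01, loading_cutoff = 0.3,
                     threshold_method = c("mean_plus_1p96sd", "ci_mean_t95",
                                          "percentile95"),
                     level = 0.95, min_members = 3L, ridge = 0) {
  threshold_method <- match.arg(threshold_method)
  stopifnot(inherits(net, "tripartite_network"))
  ct <- known_edges(net)
  ct <- ct[ct$pair_type == "CT", , drop = FALSE]
  if (nrow(ct) == 0L) stop("network has no known compound-target edges")
  train_compounds <- sort(unique(ct$a))
  train_proteins <- sort(unique(ct$b))

  if (preprocess) {
    cprep <- preprocess_descriptors(
      compound_dm[intersect(train_compounds, rownames(compound_dm)), ,
                  drop = FALSE],
      max_mode_fraction, min_rsd, max_abs_r)
    pprep <- preprocess_descriptors(
      protein_dm[intersect(train_proteins, rownames(protein_dm)), ,
                 drop = FALSE],
      max_mode_fraction, min_rsd, max_abs_r)
    compound_dm <- compound_dm[, cprep$report$kept, drop = FALSE]
    protein_dm <- protein_dm[, pprep$report$kept, drop = FALSE]
    prep_reports <- list(compound = cprep$report, protein = pprep$report)
  } else {
    prep_reports <- NULL
  }

  sample <- build_paired_sample(net, compound_dm, protein_dm)
  fit <- canonical_significance(fit_cca(sample, ridge = ridge))
  selection <- select_feature_descriptors(fit, r_min, alpha, loading_cutoff)

  cstd <- standardize_features(
    compound_dm[intersect(train_compounds, rownames(compound_dm)), ,
                drop = FALSE],
    selection$compound_descriptors)
  pstd <- standardize_features(
    protein_dm[intersect(train_proteins, rownames(protein_dm)), ,
               drop = FALSE],
    selection$protein_descriptors)
  compound_features <- standardize_features(
    compound_dm, selection$compound_descriptors, cstd$stats)$matrix
  protein_features <- standardize_features(
    protein_dm, selection$protein_descriptors, pstd$stats)$matrix

  build_all <- function(anchors, partners_of, features) {
    spaces <- lapply(anchors, function(anchor) {
      build_space(anchor, partners_of(anchor), features, min_members,
                  threshold_method, level)
    })
    names(spaces) <- anchors
    spaces
  }
  target_spaces <- build_all(
    train_proteins,
    function(t) ct$a[ct$b == t],
    compound_features)
  compound_spaces <- build_all(
    train_compounds,
    function(c) ct$b[ct$a == c],
    protein_features)

  structure(list(
    cca = fit, selection = selection,
    compound_features = compound_features,
    protein_features = protein_features,
    feature_stats = list(compound = cstd$stats, protein = pstd$stats),
    target_spaces = target_spaces, compound_spaces = compound_spaces,
    train_edges = ct[, c("a", "b")],
    prep_reports = prep_reports,
    config = list(threshold_method = threshold_method, level = level,
                  min_members = min_members, r_min = r_min, alpha = alpha,
                  loading_cutoff = loading_cutoff, ridge = ridge)
  ), class = "ctcs_ipm")
}

#' @export
print.ctcs_ipm <- function(x, ...) {
  built_t <- sum(vapply(x$target_spaces, function(s) !isTRUE(s$skipped),
                        logical(1)))
  built_c <- sum(vapply(x$compound_spaces, function(s) !isTRUE(s$skipped),
                        logical(1)))
  cat("Compound-target correlation-space interaction model\n")
  cat(sprintf("  training edges: %d (%d compounds, %d proteins)\n",
              nrow(x$train_edges), length(x$compound_spaces),
              length(x$target_spaces)))
  cat(sprintf("  selected descriptors: %d compound, %d protein (r1 = %.3f)\n",
              length(x$selection$compound_descriptors),
              length(x$selection$protein_descriptors), x$cca$cor[1L]))
  cat(sprintf("  spaces built: %d/%d targets, %d/%d compounds (threshold %s)\n",
              built_t, length(x$target_spaces), built_c,
              length(x$compound_spaces), x$config$threshold_method))
  invisible(x)
}

#' @export
summary.ctcs_ipm <- function(object, ...) {
  print(object)
  thr <- vapply(object$target_spaces, function(s)
    if (isTRUE(s$skipped)) NA_real_ else as.numeric(s$threshold), numeric(1))
  cat("  target-space thresholds: ",
      paste(round(stats::quantile(thr, na.rm = TRUE), 3), collapse = " "),
      " (min/q1/med/q3/max)\n", sep = "")
  invisible(object)
}

#' Predict candidate interactions from a fitted model
#'
#' Scores every (candidate, space) combination that is not already a
#' training edge. Direction `compound_to_target` scores compounds against
#' the per-target compound spaces, `target_to_compound` scores proteins
#' against the per-compound target spaces, and `union` runs both and merges
#' per pair (predicted when either direction predicts; the `agreement`
#' column records whether all scoring directions agreed).
#'
#' @param object a fitted [ctcs_ipm()] model.
#' @param rule decision rule, see [predict_pair()].
#' @param direction prediction direction (see above).
#' @param compounds,proteins optional candidate id subsets (default: every
#'   entity with features).
#' @param ... unused.
#' @return data.frame with one row per scored pair: `compound`, `protein`,
#'   `direction`, `n_members`, `d_max`, `d_mean`, `d_min`, `threshold`,
#'   `decision` (and `agreement` for union), ordered by compound then
#'   protein.
#' @export
predict.ctcs_ipm <- function(object,
                             direction = c("compound_to_target",
                                           "target_to_compound", "union"),
                             rule = c("all", "any", "mean"),
                             compounds = NULL, proteins = NULL, ...) {
  direction <- match.arg(direction)
  rule <- match.arg(rule)
  if (direction == "union") {
    a <- predict(object, "compound_to_target", rule, compounds, proteins)
    b <- predict(object, "target_to_compound", rule, compounds, proteins)
    both <- rbind(a, b)
    key <- paste(both$compound, both$protein, sep = "\r")
    merged <- do.call(rbind, lapply(split(seq_len(nrow(both)), key),
                                    function(idx) {
      row <- both[idx[1L], , drop = FALSE]
      row$direction <- "union"
      row$decision <- any(both$decision[idx])
      row$agreement <- length(unique(both$decision[idx])) == 1L
      row
    }))
    merged <- merged[order(merged$compound, merged$protein), , drop = FALSE]
    rownames(merged) <- NULL
    return(merged)
  }

  train_key <- paste(object$train_edges$a, object$train_edges$b, sep = "\r")
  if (direction == "compound_to_target") {
    spaces <- object$target_spaces
    features <- object$compound_features
    cands <- if (is.null(compounds)) rownames(features) else compounds
  } else {
    spaces <- object$compound_spaces
    features <- object$protein_features
    cands <- if (is.null(proteins)) rownames(features) else proteins
  }
  cands <- sort(intersect(cands, rownames(features)))
  out <- list()
  for (anchor in names(spaces)) {
    sp <- spaces[[anchor]]
    if (isTRUE(sp$skipped)) next
    for (cand in cands) {
      pair <- if (direction == "compound_to_target") {
        paste(cand, anchor, sep = "\r")
      } else {
        paste(anchor, cand, sep = "\r")
      }
      if (pair %in% train_key) next
      rec <- predict_pair(features[cand, ], sp, rule)
      rec$candidate <- cand
      out[[length(out) + 1L]] <- rec
    }
  }
  if (!length(out)) {
    return(data.frame(compound = character(), protein = character(),
                      direction = character(), n_members = integer(),
                      d_max = numeric(), d_mean = numeric(),
                      d_min = numeric(), threshold = numeric(),
                      decision = logical(), stringsAsFactors = FALSE))
  }
  recs <- do.call(rbind, out)
  res <- data.frame(
    compound = if (direction == "compound_to_target") recs$candidate else
      recs$anchor,
    protein = if (direction == "compound_to_target") recs$anchor else
      recs$candidate,
    direction = direction,
    n_members = recs$n_members, d_max = recs$d_max, d_mean = recs$d_mean,
    d_min = recs$d_min, threshold = recs$threshold,
    decision = recs$decision, stringsAsFactors = FALSE)
  res <- res[order(res$compound, res$protein), , drop = FALSE]
  rownames(res) <- NULL
  res
}

#' Stratified train/test split of compound-target edges
#'
#' Edges are split per target: each target's edges are shuffled and
#' `round(n / (train + test) * test)` of them go to the test set; a target
#' with a single edge keeps it in training.
#'
#' @param ct_edges data.frame with columns `a` (compound) and `b` (protein).
#' @param ratio `"4:1"` style string or numeric train fraction.
#' @param seed RNG seed for the per-target shuffles.
#' @return list with `train` and `test` data.frames (disjoint, union =
#'   input).
#' @export
stratified_split <- function(ct_edges, ratio = "4:1", seed = 1L) {
  if (is.character(ratio)) {
    parts <- as.numeric(strsplit(ratio, ":", fixed = TRUE)[[1L]])
    if (length(parts) != 2L || anyNA(parts)) stop("cannot parse ratio")
    test_frac <- parts[2L] / sum(parts)
  } else {
    test_frac <- 1 - ratio
  }
  ct_edges <- ct_edges[order(ct_edges$b, ct_edges$a), , drop = FALSE]
  set.seed(seed)
  test_idx <- integer()
  for (t in unique(ct_edges$b)) {
    idx <- which(ct_edges$b == t)
    n <- length(idx)
    if (n < 2L) next
    n_test <- round(n * test_frac)
    if (n_test >= 1L) {
      test_idx <- c(test_idx, sample(idx, n_test))
    }
  }
  test <- ct_edges[test_idx, , drop = FALSE]
  train <- ct_edges[setdiff(seq_len(nrow(ct_edges)), test_idx), ,
                    drop = FALSE]
  rownames(test) <- rownames(train) <- NULL
  list(train = train, test = test)
}

#' Cross-validated recall of the correlation-space predictor
#'
#' Per-target stratified k-fold partition of the known CT edges. For each
#' fold the full pipeline (preprocessing, CCA, selection, standardization,
#' space construction) is refit on the training edges only, and recall is
#' the fraction of held-out edges predicted to interact. Held-out edges
#' whose target space was skipped (too few training members) count as not
#' predicted; a fold on which no canonical variate passes the significance
#' gates contributes recall 0 with a warning (the model cannot be built).
#'
#' @inheritParams ctcs_ipm
#' @param k number of folds (default 10).
#' @param seed RNG seed for the fold assignment.
#' @param rule decision rule, see [predict_pair()].
#' @return object of class `sipa_recall_report`: per-fold table (`fold`,
#'   `n_train`, `n_test`, `n_recalled`, `recall`), `average_recall`, `seed`
#'   and the configuration.
#' @export
cross_validate <- function(net, compound_dm, protein_dm, k = 10L, seed = 1L,
                           rule = c("all", "any", "mean"),
                           preprocess = TRUE,
                           max_mode_fraction = 0.80, min_rsd = 0.05,
                           max_abs_r = 0.9,
                           r_min = 0.8, alpha = 0.01, loading_cutoff = 0.3,
                           threshold_method = c("mean_plus_1p96sd",
                                                "ci_mean_t95",
                                                "percentile95"),
                           level = 0.95, min_members = 3L, ridge = 0) {
  rule <- match.arg(rule)
  threshold_method <- match.arg(threshold_method)
  stopifnot(k >= 2L)
  ct <- known_edges(net)
  ct <- ct[ct$pair_type == "CT", c("a", "b")]
  if (nrow(ct) < k) stop("fewer edges than folds")
  ct <- ct[order(ct$b, ct$a), , drop = FALSE]

  set.seed(seed)
  fold <- integer(nrow(ct))
  for (t in unique(ct$b)) {
    idx <- which(ct$b == t)
    fold[idx] <- sample(rep_len(seq_len(k), length(idx)))
  }

  rows <- list()
  for (f in seq_len(k)) {
    test <- ct[fold == f, , drop = FALSE]
    train <- ct[fold != f, , drop = FALSE]
    if (nrow(test) == 0L) {
      warning("fold ", f, " has no test edges; skipped")
      next
    }
    train_net <- tripartite_network(
      net$entities,
      data.frame(a = train$a, b = train$b, pair_type = "CT",
                 provenance = "known", support = 0L,
                 stringsAsFactors = FALSE),
      warn_duplicates = FALSE)
    fit <- tryCatch(
      ctcs_ipm(train_net, compound_dm, protein_dm, preprocess = preprocess,
               max_mode_fraction = max_mode_fraction, min_rsd = min_rsd,
               max_abs_r = max_abs_r, r_min = r_min, alpha = alpha,
               loading_cutoff = loading_cutoff,
               threshold_method = threshold_method, level = level,
               min_members = min_members, ridge = ridge),
      error = function(e) {
        warning("fold ", f, ": model could not be fitted (",
                conditionMessage(e), "); recall 0")
        NULL
      })
    hits <- 0L
    if (!is.null(fit)) {
      for (i in seq_len(nrow(test))) {
        sp <- fit$target_spaces[[test$b[i]]]
        if (is.null(sp) || isTRUE(sp$skipped)) next
        if (!(test$a[i] %in% rownames(fit$compound_features))) next
        rec <- predict_pair(fit$compound_features[test$a[i], ], sp, rule)
        if (rec$decision) hits <- hits + 1L
      }
    }
    rows[[length(rows) + 1L]] <- data.frame(
      fold = f, n_train = nrow(train), n_test = nrow(test),
      n_recalled = hits, recall = hits / nrow(test))
  }
  folds <- do.call(rbind, rows)
  structure(list(folds = folds,
                 average_recall = mean(folds$recall),
                 seed = seed,
                 config = list(k = k, rule = rule,
                               threshold_method = threshold_method,
                               level = level, min_members = min_members,
                               r_min = r_min, alpha = alpha,
                               loading_cutoff = loading_cutoff)),
            class = "sipa_recall_report")
}

#' @export
print.sipa_recall_report <- function(x, ...) {
  cat(sprintf("Tenfold-style cross-validated recall (k = %d, rule = %s, threshold = %s)\n",
              x$config$k, x$config$rule, x$config$threshold_method))
  print(x$folds, row.names = FALSE)
  cat(sprintf("average recall: %.4f\n", x$average_recall))
  invisible(x)
}
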