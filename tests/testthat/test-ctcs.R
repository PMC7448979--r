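# Correlation-space predictor: thresholds, spaces, decisions, validation.

test_that("threshold closed forms match hand calculations", {
  d <- c(1, 2, 3)
  expect_equal(compute_threshold(d, "ci_mean_t95"),
               2 + qt(0.975, 2) * 1 / sqrt(3))
  expect_equal(compute_threshold(d, "ci_mean_t95"), 4.4842, tolerance = 1e-4)
  expect_equal(compute_threshold(d, "mean_plus_1p96sd"),
               2 + qnorm(0.975) * 1)
  expect_equal(compute_threshold(d, "mean_plus_1p96sd"), 3.96,
               tolerance = 1e-4)
  expect_equal(compute_threshold(d, "percentile95"), 2.9)

  # equal distances: every method returns that distance
  eq <- rep(1.7, 6)
  for (m in c("ci_mean_t95", "mean_plus_1p96sd", "percentile95")) {
    expect_equal(compute_threshold(eq, m), 1.7)
  }
  one <- compute_threshold(5, "ci_mean_t95")
  expect_equal(as.numeric(one), 5)
  expect_true(attr(one, "degenerate"))
  expect_error(compute_threshold(numeric()), "no distances")
})

test_that("spaces carry the pairwise distances and threshold", {
  feats <- dm(f1 = c(0, 3, 0, 1), f2 = c(0, 0, 4, 1),
              ids = c("C1", "C2", "C3", "C4"))
  sp <- build_space("T1", c("C1", "C2", "C3"), feats, min_members = 3L,
                    threshold_method = "ci_mean_t95")
  expect_s3_class(sp, "entity_space")
  expect_setequal(sp$pairwise_distances, c(3, 4, 5))
  expect_equal(sp$threshold, 4 + qt(0.975, 2) / sqrt(3))
  expect_equal(sp$threshold, 6.4842, tolerance = 1e-4)

  skip_marker <- build_space("T1", c("C1", "C2"), feats)
  expect_true(skip_marker$skipped)
  expect_match(skip_marker$reason, "insufficient members")
})

test_that("decision rules behave as documented on the hand example", {
  feats <- dm(f1 = c(0, 3, 0), f2 = c(0, 0, 4), ids = c("C1", "C2", "C3"))
  sp <- build_space("T1", c("C1", "C2", "C3"), feats,
                    threshold_method = "ci_mean_t95")
  near <- predict_pair(c(1, 1), sp, rule = "all")
  expect_equal(near$d_max, sqrt(10))
  expect_equal(near$d_min, sqrt(2))
  expect_true(near$decision)
  far <- predict_pair(c(100, 100), sp, rule = "all")
  expect_false(far$decision)
  # a candidate on top of a member always passes under rule any
  expect_true(predict_pair(c(3, 0), sp, rule = "any")$decision)
  expect_error(predict_pair(c(1, 1, 1), sp), "does not match")
})

test_that("decisions are scale-invariant and rules nest all < mean < any", {
  set.seed(31)
  feats <- matrix(rnorm(30), 10, 3,
                  dimnames = list(paste0("C", 1:10), paste0("f", 1:3)))
  sp1 <- build_space("T1", paste0("C", 1:6), feats)
  sp2 <- build_space("T1", paste0("C", 1:6), feats * 7)
  expect_equal(sp2$pairwise_distances, 7 * sp1$pairwise_distances)
  expect_equal(as.numeric(sp2$threshold), 7 * as.numeric(sp1$threshold))
  for (cand in paste0("C", 7:10)) {
    for (rule in c("all", "any", "mean")) {
      expect_equal(predict_pair(feats[cand, ] * 7, sp2, rule)$decision,
                   predict_pair(feats[cand, ], sp1, rule)$decision)
    }
    d_all <- predict_pair(feats[cand, ], sp1, "all")$decision
    d_mean <- predict_pair(feats[cand, ], sp1, "mean")$decision
    d_any <- predict_pair(feats[cand, ], sp1, "any")$decision
    expect_true(!d_all || d_mean)  # all implies mean
    expect_true(!d_mean || d_any)  # mean implies any
  }
})

test_that("feature standardization fits, reuses and validates statistics", {
  m <- dm(a = c(1, 2, 3, 10), b = c(5, 5.5, 6, 9))
  fit <- standardize_features(m)
  expect_equal(unname(colMeans(fit$matrix)), c(0, 0), tolerance = 1e-12)
  expect_equal(unname(apply(fit$matrix, 2, sd)), c(1, 1), tolerance = 1e-12)
  shifted <- standardize_features(m + 2, colnames(m), fit$stats)
  expect_equal(shifted$matrix - fit$matrix,
               sweep(matrix(2, 4, 2), 2, fit$stats$scale, "/"),
               ignore_attr = TRUE)
  expect_error(standardize_features(dm(a = rep(1, 3))), "zero-variance")
  expect_error(standardize_features(m, "zz"), "absent")
  expect_equal(euclidean_distance(c(0, 0), c(3, 4)), 5)
  expect_equal(euclidean_distance(1:7, 1:7), 0)
  expect_error(euclidean_distance(1:3, 1:4), "length mismatch")
})

test_that("stratified splitting is per-target, seeded and exhaustive", {
  edges <- data.frame(
    a = c(paste0("C", 1:5), paste0("C", 1:4), "C9"),
    b = c(rep("T1", 5), rep("T2", 4), "T3"))
  s1 <- stratified_split(edges, "4:1", seed = 4L)
  expect_equal(sum(s1$test$b == "T1"), 1L)  # round(5/5)
  expect_equal(sum(s1$test$b == "T2"), 1L)  # round(4/5)
  expect_equal(sum(s1$test$b == "T3"), 0L)  # singleton stays in training
  expect_equal(nrow(s1$train) + nrow(s1$test), nrow(edges))
  both <- rbind(s1$train, s1$test)
  expect_setequal(paste(both$a, both$b), paste(edges$a, edges$b))

  s2 <- stratified_split(edges, "4:1", seed = 4L)
  expect_identical(s1, s2)
  s3 <- stratified_split(edges, "4:1", seed = 99L)
  expect_equal(table(s3$test$b), table(s1$test$b))  # same per-target counts
})

test_that("fitted models never re-emit training edges and are deterministic", {
  st <- simulate_study(generator_config(seed = 11L))
  model <- ctcs_ipm(st$network, st$compounds, st$proteins)
  preds <- predict(model, rule = "all")
  train_key <- paste(model$train_edges$a, model$train_edges$b)
  expect_false(any(paste(preds$compound, preds$protein) %in% train_key))
  expect_false(is.unsorted(preds$compound))

  model2 <- ctcs_ipm(st$network, st$compounds, st$proteins)
  expect_identical(predict(model2, rule = "all"), preds)

  # rule nesting carries through to full prediction runs
  p_mean <- predict(model, rule = "mean")
  p_any <- predict(model, rule = "any")
  hits <- function(p) paste(p$compound, p$protein)[p$decision]
  expect_true(all(hits(preds) %in% hits(p_mean)))
  expect_true(all(hits(p_mean) %in% hits(p_any)))

  # union direction covers both single directions
  p_union <- predict(model, direction = "union", rule = "mean")
  p_t2c <- predict(model, direction = "target_to_compound", rule = "mean")
  expect_true(all(hits(p_mean) %in% hits(p_union)))
  expect_true(all(hits(p_t2c) %in% hits(p_union)))
  expect_true(all(c("decision", "agreement") %in% names(p_union)))
})

test_that("every training member is recovered by its own space under any", {
  st <- simulate_study(generator_config(seed = 12L))
  model <- ctcs_ipm(st$network, st$compounds, st$proteins)
  for (anchor in names(model$target_spaces)) {
    sp <- model$target_spaces[[anchor]]
    if (isTRUE(sp$skipped)) next
    for (member in sp$member_ids) {
      rec <- predict_pair(model$compound_features[member, ], sp, "any")
      expect_equal(rec$d_min, 0)
      expect_true(rec$decision)
    }
  }
})

test_that("only known edges inform the fit (no leakage from predictions)", {
  st <- simulate_study(generator_config(seed = 13L))
  base <- ctcs_ipm(st$network, st$compounds, st$proteins)
  # adding a non-known edge must not change the fitted model
  aug <- merge_interactions(
    st$network,
    data.frame(a = "C1", b = "T5", pair_type = "CT",
               provenance = "ctcs_predicted", support = 0L),
    dedupe_against_known = FALSE)$network
  refit <- ctcs_ipm(aug, st$compounds, st$proteins)
  expect_identical(refit$selection, base$selection)
  expect_identical(refit$target_spaces, base$target_spaces)
})

test_that("cross-validation is seeded and edge-order independent", {
  st <- simulate_study(generator_config(seed = 7L))
  rep1 <- suppressWarnings(
    cross_validate(st$network, st$compounds, st$proteins, seed = 7L,
                   rule = "mean"))
  expect_s3_class(rep1, "sipa_recall_report")
  expect_equal(nrow(rep1$folds), 10L)
  expect_true(all(rep1$folds$recall >= 0 & rep1$folds$recall <= 1))
  expect_equal(rep1$average_recall, mean(rep1$folds$recall))
  expect_equal(rep1$folds$n_train + rep1$folds$n_test,
               rep(nrow(st$network$interactions), 10L))

  # same seed: identical report, even from a shuffled edge table
  set.seed(1)
  perm <- sample(nrow(st$network$interactions))
  net_shuffled <- tripartite_network(st$network$entities,
                                     st$network$interactions[perm, ],
                                     warn_duplicates = FALSE)
  rep2 <- suppressWarnings(
    cross_validate(net_shuffled, st$compounds, st$proteins, seed = 7L,
                   rule = "mean"))
  expect_equal(rep1$folds, rep2$folds)

  # recall under rule any dominates rule all on identical folds
  rep_all <- suppressWarnings(
    cross_validate(st$network, st$compounds, st$proteins, seed = 7L,
                   rule = "all"))
  rep_any <- suppressWarnings(
    cross_validate(st$network, st$compounds, st$proteins, seed = 7L,
                   rule = "any"))
  expect_true(all(rep_any$folds$recall >= rep_all$folds$recall))
})
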