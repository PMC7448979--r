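# Canonical correlation analysis, significance testing, feature selection.

test_that("paired samples are built from known CT edges deterministically", {
  net <- table1_network()
  cdm <- dm(cd1 = 1:5, cd2 = (1:5)^2,
            ids = c("C10", "C17", "C18", "C29", "C40"))
  pdm <- dm(pd1 = c(1, 2), pd2 = c(3, 4), ids = c("T8", "T13"))
  s <- build_paired_sample(net, cdm, pdm)
  expect_equal(nrow(s$X), 8L)  # 8 known CT edges
  expect_equal(s$n_dropped, 0L)
  expect_equal(s$pairs$compound, sort(s$pairs$compound))
  # an edge endpoint missing from the compound matrix is dropped and counted
  s2 <- build_paired_sample(net, cdm[-1L, , drop = FALSE], pdm)
  expect_equal(nrow(s2$X), 7L)
  expect_equal(s2$n_dropped, 1L)
  expect_error(build_paired_sample(net, cdm[0L, , drop = FALSE], pdm),
               "no usable compound-target edges")
})

test_that("one-dimensional canonical correlation equals |Pearson r|", {
  x <- dm(x = c(1, 2, 3, 4, 5, 7, 9, 11, 13, 20))
  y <- dm(y = -2 * x[, 1])
  expect_equal(fit_cca(x, y)$cor, 1)

  x5 <- dm(x = c(1, 2, 3, 4, 5))
  y5 <- dm(y = c(2, 1, 4, 3, 5))
  expect_equal(fit_cca(x5, y5)$cor, 0.8)
  expect_equal(abs(cor(x5[, 1], y5[, 1])), 0.8)
})

test_that("canonical correlations match the eigen-decomposition oracle", {
  set.seed(21)
  for (dims in list(c(2L, 2L), c(3L, 2L), c(5L, 4L))) {
    n <- 40L
    x <- matrix(rnorm(n * dims[1L]), n)
    z <- rnorm(n)
    y <- matrix(rnorm(n * dims[2L]), n) + z
    x[, 1L] <- x[, 1L] + z
    colnames(x) <- paste0("x", seq_len(dims[1L]))
    colnames(y) <- paste0("y", seq_len(dims[2L]))
    fit <- fit_cca(x, y)
    expect_equal(fit$cor, oracle_cca_cor(x, y), tolerance = 1e-8)
    # cross-check against the base-R implementation on centered data
    cc <- cancor(scale(x, scale = FALSE), scale(y, scale = FALSE))
    expect_equal(fit$cor, cc$cor, tolerance = 1e-8)
    # canonical variates have unit sample variance
    scores <- scale(x, fit$xcenter, fit$xscale) %*% fit$xcoef
    expect_equal(unname(apply(scores, 2, sd)), rep(1, length(fit$cor)),
                 tolerance = 1e-8)
  }
})

test_that("correlations are invariant to affine recombination of a block", {
  set.seed(22)
  n <- 30L
  x <- matrix(rnorm(n * 2L), n, dimnames = list(NULL, c("a", "b")))
  y <- matrix(rnorm(n * 2L), n, dimnames = list(NULL, c("c", "d")))
  y[, 1L] <- y[, 1L] + x[, 1L]
  base <- fit_cca(x, y)$cor
  for (i in 1:5) {
    a <- matrix(rnorm(4), 2L)
    while (abs(det(a)) < 0.1) a <- matrix(rnorm(4), 2L)
    xt <- x %*% a + matrix(rnorm(2L), n, 2L, byrow = TRUE)  # mix and shift
    colnames(xt) <- c("a", "b")
    expect_equal(fit_cca(xt, y)$cor, base, tolerance = 1e-8)
  }
})

test_that("degenerate inputs are rejected with informative errors", {
  x <- dm(a = rnorm(4), b = rnorm(4), c = rnorm(4), d = rnorm(4))
  y <- dm(e = rnorm(4))
  expect_error(fit_cca(x, y), "n <= max")
  expect_silent(fit_cca(x, y, ridge = 1e-6))
  expect_error(fit_cca(dm(a = rep(1, 10)), dm(b = rnorm(10))),
               "zero-variance")
})

test_that("Bartlett statistics follow the sequential closed form", {
  fit <- structure(list(cor = c(0.9, 0.1), n = 50L, p = 2L, q = 2L),
                   class = "cca_fit")
  fit <- canonical_significance(fit)
  expect_equal(fit$lambda[1L], 0.19 * 0.99)
  expect_equal(fit$chisq[1L], -(50 - 1 - 2.5) * log(0.1881),
               tolerance = 1e-12)
  expect_equal(fit$chisq[1L], 77.70, tolerance = 1e-3)
  expect_equal(fit$df, c(4L, 1L))
  expect_equal(fit$pvalue[1L],
               pchisq(-(46.5) * log(0.1881), 4, lower.tail = FALSE))

  # zero correlations: Wilks 1, chi-square 0, p = 1 throughout
  null_fit <- structure(list(cor = c(0, 0), n = 30L, p = 2L, q = 2L),
                        class = "cca_fit")
  null_fit <- canonical_significance(null_fit)
  expect_equal(null_fit$lambda, c(1, 1))
  expect_equal(null_fit$chisq, c(0, 0))
  expect_equal(null_fit$pvalue, c(1, 1))

  tiny <- structure(list(cor = c(0.5), n = 3L, p = 2L, q = 2L),
                    class = "cca_fit")
  expect_warning(tiny <- canonical_significance(tiny), "sample too small")
  expect_equal(tiny$pvalue, 1)
})

test_that("a planted variate is detected and noise variates are not", {
  # note: p-values of the trailing pure-noise variates are NOT monotone in
  # the variate index (their statistics and degrees of freedom both shrink),
  # so the sequence is only anchored by the planted signal coming first
  set.seed(23)
  for (i in 1:10) {
    n <- 60L
    x <- matrix(rnorm(n * 3L), n, dimnames = list(NULL, paste0("x", 1:3)))
    y <- matrix(rnorm(n * 3L), n, dimnames = list(NULL, paste0("y", 1:3)))
    y[, 1L] <- y[, 1L] + 2 * x[, 1L]
    fit <- canonical_significance(fit_cca(x, y))
    expect_equal(which.min(fit$pvalue), 1L)
    expect_lt(fit$pvalue[1L], 1e-6)
    expect_true(all(fit$pvalue[-1L] > 0.01))
    # each statistic matches its own direct evaluation
    for (k in seq_along(fit$cor)) {
      expect_equal(fit$lambda[k], prod(1 - fit$cor[k:3]^2))
      expect_equal(fit$chisq[k], -(n - 1 - 3.5) * log(fit$lambda[k]))
    }
  }
})

test_that("feature selection follows loadings on significant variates", {
  fit <- structure(list(
    cor = c(0.95, 0.2), n = 100L, p = 2L, q = 2L,
    xloadings = matrix(c(0.9, 0.1, 0.2, 0.8), 2L,
                       dimnames = list(c("cd1", "cd2"), NULL)),
    yloadings = matrix(c(0.8, 0.05, 0.1, 0.9), 2L,
                       dimnames = list(c("pd1", "pd2"), NULL))),
    class = "cca_fit")
  fit <- canonical_significance(fit)
  sel <- select_feature_descriptors(fit)
  expect_equal(sel$compound_descriptors, "cd1")
  expect_equal(sel$protein_descriptors, "pd1")
  expect_equal(sel$provenance$variates, 1L)

  # loading cutoff 0 selects everything
  all_sel <- select_feature_descriptors(fit, loading_cutoff = 0)
  expect_setequal(all_sel$compound_descriptors, c("cd1", "cd2"))

  # no significant variate is a hard error
  dull <- structure(list(cor = c(0.3, 0.1), n = 100L, p = 2L, q = 2L,
                         xloadings = fit$xloadings,
                         yloadings = fit$yloadings),
                    class = "cca_fit")
  dull <- canonical_significance(dull)
  expect_error(select_feature_descriptors(dull),
               "no significant canonical variate")
  expect_error(select_feature_descriptors(fit, loading_cutoff = 0.99),
               "lower the cutoff")
})

test_that("planted canonical structure is recovered from paired data", {
  r1 <- vapply(1:20, function(seed) {
    s <- simulate_paired_descriptors(n = 500L, p = 6L, q = 6L, rho = 0.9,
                                     seed = seed)
    fit_cca(s$X, s$Y)$cor[1L]
  }, numeric(1))
  expect_true(all(abs(r1 - 0.9) <= 0.05))

  # independent blocks: the largest fitted correlation stays small
  s0 <- simulate_paired_descriptors(n = 1000L, p = 6L, q = 6L, rho = 0,
                                    rho2 = 0, seed = 5L)
  expect_lt(fit_cca(s0$X, s0$Y)$cor[1L], 0.2)

  # noise-free shared factor: the first correlation approaches 1
  s1 <- simulate_paired_descriptors(n = 1000L, p = 4L, q = 4L, rho = 0.999,
                                    noise_sd = 0, seed = 6L)
  expect_gt(fit_cca(s1$X, s1$Y)$cor[1L], 0.99)
})
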