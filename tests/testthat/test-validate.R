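test_that("Q2 rewards real class structure and punishes noise", {
  # strong signal: well separated rank-1 structure
  withr::with_seed(51, {
    y <- rep(c(-1, 1), each = 7)
    X <- outer(y, rnorm(20)) + matrix(rnorm(14 * 20, sd = 0.05), 14, 20)
    colnames(X) <- paste0("V", 1:20)
  })
  cls <- ifelse(y > 0, "B", "A")
  q2_strong <- q2_crossval(X, cls, ncomp = 1, folds = 7, seed = 1)
  expect_gte(q2_strong, 0.9)
  # pure noise response never looks predictive
  for (seed in 1:20) {
    withr::with_seed(200 + seed, {
      Xn <- matrix(rnorm(18 * 12), 18, 12,
                   dimnames = list(NULL, paste0("V", 1:12)))
      cln <- sample(rep(c("A", "B"), each = 9))
    })
    expect_lte(q2_crossval(Xn, cln, ncomp = 2, folds = 6, seed = seed), 0.2)
  }
})

test_that("Q2 never exceeds the training R2Y on these constructions", {
  for (seed in 1:5) {
    fx <- classed_matrix(per_class = 6, p = 10, n_signal = 2, delta = 2,
                         seed = 300 + seed)
    fit <- fit_plsda(fx$X, fx$classes, ncomp = 2)
    q2 <- q2_crossval(fx$X, fx$classes, ncomp = 2, folds = 6, seed = seed)
    expect_lte(q2, fit$R2Y[2] + 1e-9)
  }
})

test_that("venetian-blind folds are deterministic and class-guarded", {
  fx <- classed_matrix(per_class = 6, p = 8, seed = 52)
  a <- q2_crossval(fx$X, fx$classes, folds = 4, seed = 3)
  b <- q2_crossval(fx$X, fx$classes, folds = 4, seed = 3)
  expect_identical(a, b)
  expect_error(q2_crossval(fx$X, fx$classes, folds = 13, seed = 1),
               class = "fusemet_config_error")
  # a training fold losing a class is caught: with folds = 2 and alternating
  # labels, each training half holds only one class
  X <- classed_matrix(per_class = 2, p = 4, seed = 53)$X
  cls <- c("A", "B", "A", "B")
  expect_error(q2_crossval(X, cls, ncomp = 1, folds = 2, seed = 0),
               class = "fusemet_model_error")
})

test_that("permutation validation flags structure and reproduces identity labels", {
  fx <- classed_matrix(per_class = 6, p = 10, n_signal = 3, delta = 3, seed = 54)
  rep1 <- permutation_test(fx$X, fx$classes, ncomp = 2, n = 20, folds = 6,
                           seed = 2)
  expect_s3_class(rep1, "permutation_report")
  expect_equal(nrow(rep1$results), 21)
  # the original model is the correlation-1 point
  expect_equal(rep1$results$correlation[1], 1)
  refit <- fit_plsda(scale(fx$X, scale = FALSE), fx$classes, ncomp = 2)
  expect_equal(rep1$results$r2[1], refit$R2Y[2], tolerance = 1e-12)
  expect_equal(rep1$results$q2[1],
               q2_crossval(fx$X, fx$classes, ncomp = 2, folds = 6, seed = 2),
               tolerance = 1e-12)
  # determinism
  rep2 <- permutation_test(fx$X, fx$classes, ncomp = 2, n = 20, folds = 6,
                           seed = 2)
  expect_identical(rep1$results, rep2$results)
  expect_error(permutation_test(fx$X, fx$classes, n = 5),
               class = "fusemet_config_error")
  expect_s3_class(autoplot(rep1), "ggplot")
  expect_named(glance(rep1), c("n_permutations", "original_r2", "original_q2",
                               "r2_intercept", "q2_intercept", "valid"))
})

test_that("pure-noise data does not earn a validity flag", {
  flags <- vapply(1:5, function(seed) {
    withr::with_seed(400 + seed, {
      X <- matrix(rnorm(16 * 12), 16, 12,
                  dimnames = list(NULL, paste0("V", 1:12)))
      cls <- rep(c("A", "B"), each = 8)
    })
    p <- permutation_test(X, cls, ncomp = 2, n = 20, folds = 4, seed = seed)
    # original Q2 should sit inside the permuted distribution
    p$original_q2 > quantile(p$results$q2[p$results$permuted], 0.95, na.rm = TRUE)
  }, logical(1))
  expect_lte(sum(flags), 2)
})
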