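test_that("Pareto scaling centers and divides by the root standard deviation", {
  X <- matrix(c(1, 3, 5, 5), 2, 2, dimnames = list(NULL, c("a", "b")))
  out <- pareto_scale(X)
  expect_equal(unname(out[, "a"]), c(-1, 1) / 2^(1 / 4), tolerance = 1e-12)
  expect_equal(round(abs(out[1, "a"]), 4), 0.8409)
  # constant column: centered to zero, divisor 1, flagged
  expect_equal(unname(out[, "b"]), c(0, 0))
  expect_equal(attr(out, "zero_variance"), "b")
  # an already-centered unit-sd column is unchanged
  v <- c(-1, 0, 1) / sd(c(-1, 0, 1))
  expect_equal(unname(pareto_scale(cbind(x = v))[, 1]), v, tolerance = 1e-12)
  expect_error(pareto_scale(matrix(1:3, 1)), class = "fusemet_data_error")
})

test_that("first NIPALS weight is the dominant eigenvector of X'YY'X", {
  for (seed in 1:5) {
    fx <- classed_matrix(per_class = 5, p = 8, seed = seed)
    fit <- fit_plsda(fx$X, fx$classes, ncomp = 1)
    Y <- fusemet:::class_dummy(fx$classes)
    Yc <- sweep(Y, 2, colMeans(Y), "-")
    M <- crossprod(crossprod(Yc, fx$X))        # X'Yc Yc'X, 8 x 8
    ev <- eigen(M, symmetric = TRUE)$vectors[, 1]
    ev <- ev * sign(ev[which.max(abs(ev))])    # same sign convention
    expect_equal(unname(fit$W[, 1]), unname(ev), tolerance = 1e-8)
  }
})

test_that("scores are orthogonal and R2 statistics behave under deflation", {
  fx <- classed_matrix(per_class = 6, p = 12, n_signal = 3, seed = 3,
                       classes = c("A", "B", "C"))
  fit <- fit_plsda(fx$X, fx$classes, ncomp = 3)
  G <- crossprod(fit$T)
  expect_lt(max(abs(G[upper.tri(G)])), 1e-8 * max(diag(G)))
  expect_true(all(diff(fit$R2Y) >= -1e-12))    # R2Y non-decreasing
  expect_true(all(fit$R2X >= 0) && sum(fit$R2X) <= 1 + 1e-12)

  # rank-1 class-correlated data: one component explains nearly all of X
  withr::with_seed(4, {
    t <- rep(c(-1, 1), each = 6) + rnorm(12, sd = 0.05)
    p <- rnorm(10)
    X1 <- outer(t, p)
    colnames(X1) <- paste0("V", 1:10)
  })
  cls <- rep(c("A", "B"), each = 6)
  fit1 <- fit_plsda(scale(X1, scale = FALSE), cls, ncomp = 1)
  expect_gte(fit1$R2X[1], 0.999)
})

test_that("native scores agree with an established PLS-DA implementation", {
  skip_if_not_installed("mixOmics")
  fx <- classed_matrix(per_class = 7, p = 15, n_signal = 4, seed = 6,
                       classes = c("A", "B", "C"))
  fit <- fit_plsda(fx$X, fx$classes, ncomp = 2)
  ref <- mixOmics::plsda(fx$X, fx$classes, ncomp = 2, scale = FALSE)
  for (a in 1:2) {
    expect_gt(abs(cor(fit$T[, a], ref$variates$X[, a])), 1 - 1e-6)
  }
})

test_that("degenerate class designs are rejected", {
  fx <- classed_matrix(seed = 8)
  expect_error(fit_plsda(fx$X, rep("A", nrow(fx$X))),
               class = "fusemet_model_error")
  expect_error(fit_plsda(fx$X, fx$classes[-1]), class = "fusemet_data_error")
})

test_that("VIP scores obey the normalization identity and rank signal first", {
  fx <- classed_matrix(per_class = 6, p = 10, n_signal = 1, delta = 5, seed = 9)
  fit <- fit_plsda(fx$X, fx$classes, ncomp = 2)
  v <- vip_scores(fit)
  expect_equal(mean(v$vip^2), 1, tolerance = 1e-9)
  expect_equal(v$variable_id[which.max(v$vip)], "V1")
  # invariance of the ranking under positive rescaling of X
  fit2 <- fit_plsda(fx$X * 7.3, fx$classes, ncomp = 2)
  v2 <- vip_scores(fit2)
  expect_equal(order(-v$vip), order(-v2$vip))
  expect_equal(v$vip, v2$vip, tolerance = 1e-8)
})

test_that("the VIP identity holds on every fitted model in a seed sweep", {
  for (seed in 1:6) {
    fx <- classed_matrix(per_class = 4, p = 6 + seed, n_signal = 2,
                         seed = 40 + seed, classes = c("A", "B", "C"))
    fit <- fit_plsda(fx$X, fx$classes, ncomp = 2)
    expect_equal(mean(vip_scores(fit)$vip^2), 1, tolerance = 1e-9)
  }
})

test_that("inner relation recovers exact linear and orthogonal score pairs", {
  mock <- structure(list(
    T = cbind(t1 = c(-2, -1, 0, 1, 2)),
    U = cbind(u1 = 2 * c(-2, -1, 0, 1, 2)),
    sample_ids = paste0("S", 1:5),
    classes = factor(rep(c("A", "B"), c(2, 3)))
  ), class = c("plsda", "latent_model"))
  ir <- inner_relation(mock)
  expect_equal(ir$slope, 2, tolerance = 1e-12)
  expect_equal(ir$r_squared, 1, tolerance = 1e-12)
  # orthogonal u1: R2 = 0
  mock$U <- cbind(u1 = c(1, -1, 0, 1, -1) - mean(c(1, -1, 0, 1, -1)))
  mock$U[, 1] <- mock$U[, 1] - mock$T[, 1] *
    sum(mock$U[, 1] * mock$T[, 1]) / sum(mock$T[, 1]^2)
  expect_equal(inner_relation(mock)$r_squared, 0, tolerance = 1e-12)
  mock$T <- cbind(t1 = rep(1, 5))
  expect_error(inner_relation(mock), class = "fusemet_model_error")
})

test_that("biplot coordinates are max-abs normalized and block-tagged", {
  fx <- classed_matrix(per_class = 5, p = 9, seed = 10)
  fit <- fit_plsda(fx$X, fx$classes, ncomp = 2)
  blocks <- tibble::tibble(variable_id = paste0("V", 1:9),
                           block = rep(c("NMR", "MS"), c(5, 4)))
  bp <- biplot_data(fit, blocks)
  expect_equal(nrow(bp), 10 + 9)
  expect_true(all(abs(bp$x) <= 1 & abs(bp$y) <= 1))
  # sample coordinates are the scores up to one scalar per block
  s <- bp[bp$type == "sample", ]
  expect_equal(unname(s$x / fit$T[, 1]), rep(1 / max(abs(fit$T[, 1:2])), 10),
               tolerance = 1e-12)
  expect_equal(sort(unique(bp$class[bp$type == "variable"])), c("MS", "NMR"))
  fit1 <- fit_plsda(fx$X, fx$classes, ncomp = 1)
  expect_error(biplot_data(fit1), class = "fusemet_model_error")
})

test_that("tidiers expose loadings, weights and fit summaries", {
  fx <- classed_matrix(per_class = 4, p = 6, seed = 12)
  fit <- fit_plsda(fx$X, fx$classes, ncomp = 2)
  td <- tidy(fit)
  expect_equal(nrow(td), 12)
  expect_named(td, c("variable_id", "component", "weight", "loading", "vip"))
  gl <- glance(fit)
  expect_equal(gl$n_variables, 6)
  expect_s3_class(autoplot(fit), "ggplot")
})
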