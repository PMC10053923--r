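test_that("top-k VIP ranking is stable and complete", {
  fx <- classed_matrix(per_class = 5, p = 8, n_signal = 2, seed = 61)
  fit <- fit_plsda(fx$X, fx$classes, ncomp = 2)
  top <- rank_vip(fit, k = 3)
  expect_equal(nrow(top), 3)
  expect_true(all(diff(top$vip) <= 0))
  all_of_them <- rank_vip(fit, k = 100)
  expect_equal(nrow(all_of_them), 8)
  expect_error(rank_vip(fit, k = 0), class = "fusemet_config_error")
  # exact VIP ties order lexicographically by variable id, every run
  mock <- structure(list(
    W = matrix(rep(1, 4), 4, 1, dimnames = list(c("b", "a", "d", "c"), "w1")),
    SSY_expl = 1
  ), class = c("plsda", "latent_model"))
  expect_equal(rank_vip(mock, k = 4)$variable_id, c("a", "b", "c", "d"))
})

test_that("one-way ANOVA p-values match the two-sample t-test when k = 2", {
  withr::with_seed(62, {
    X <- matrix(rnorm(20 * 5), 20, 5, dimnames = list(NULL, paste0("V", 1:5)))
    X[1:10, 1] <- X[1:10, 1] + 1.5
  })
  cls <- rep(c("A", "B"), each = 10)
  got <- feature_pvalues(X, cls)
  for (j in 1:5) {
    tt <- t.test(X[cls == "A", j], X[cls == "B", j], var.equal = TRUE)
    expect_equal(got$p_value[j], tt$p.value, tolerance = 1e-12)
    expect_equal(got$f_statistic[j], unname(tt$statistic)^2, tolerance = 1e-9)
  }
  # identical group distributions: equal means give F = 0, p = 1
  Z <- matrix(rep(c(1, 2), 10), 20, 1, dimnames = list(NULL, "V1"))
  same <- feature_pvalues(Z, cls)
  expect_equal(same$f_statistic, 0)
  expect_equal(same$p_value, 1)
  expect_error(feature_pvalues(X, c(rep("A", 19), "B")),
               class = "fusemet_data_error")
})

test_that("null p-values are uniform under label shuffling", {
  withr::with_seed(63, {
    v <- rnorm(24)
    cls0 <- rep(c("A", "B", "C", "D"), each = 6)
    ps <- vapply(1:1000, function(i) {
      feature_pvalues(cbind(V1 = v), sample(cls0))$p_value
    }, numeric(1))
  })
  expect_gt(stats::ks.test(ps, "punif")$p.value, 0.01)
})

test_that("the rank FDR transform reproduces the published discriminant tables", {
  # fused-data table: 10 ranked p-values -> critical values 0.005 .. 0.050
  p1 <- c(0.00357, 0.00358, 0.01110, 0.01240, 0.01270, 0.01940, 0.02010,
          0.03480, 0.04150, 0.04400)
  t1 <- fdr_rank(setNames(p1, sprintf("d%02d", 1:10)))
  expect_equal(t1$fdr_reported, seq(0.005, 0.050, by = 0.005))
  expect_true(all(t1$retained))
  expect_equal(t1$rank, 1:10)
  # MS-data table: 9 ranked p-values; rank 3 reports 0.017
  p2 <- c(0.00005, 0.00047, 0.00581, 0.00661, 0.00896, 0.00898, 0.00976,
          0.01360, 0.01500)
  t2 <- fdr_rank(setNames(p2, sprintf("m%02d", 1:9)))
  expect_equal(t2$fdr_reported,
               c(0.006, 0.011, 0.017, 0.022, 0.028, 0.033, 0.039, 0.044, 0.050))
  # single p = 0.04: m = 1, FDR = 0.050
  t3 <- fdr_rank(c(x = 0.04))
  expect_equal(t3$m, 1L)
  expect_equal(t3$fdr, 0.05)
})

test_that("FDR table structure: monotone column ending at Q, monotone in Q", {
  withr::with_seed(64, {
    ps <- setNames(runif(40, 0, 0.2), paste0("V", 1:40))
  })
  tab <- fdr_rank(ps, Q = 0.05)
  expect_true(all(diff(tab$fdr) > 0))
  expect_equal(tab$fdr[nrow(tab)], 0.05)
  # increasing Q retains a superset
  lo <- fdr_rank(ps, Q = 0.01)
  hi <- fdr_rank(ps, Q = 0.05)
  expect_true(all(lo$variable_id[lo$retained] %in% hi$variable_id[hi$retained]))
  # no p <= cutoff: empty table, not an error
  expect_equal(nrow(fdr_rank(c(a = 0.9, b = 0.6))), 0L)
  expect_error(fdr_rank(c(a = 1.2)), class = "fusemet_data_error")
})

test_that("the BH step-up mode agrees with stats::p.adjust", {
  withr::with_seed(65, {
    ps <- setNames(c(runif(5, 0, 0.002), runif(45)), paste0("V", 1:50))
  })
  tab <- fdr_rank(ps, Q = 0.05, method = "bh")
  adj <- p.adjust(ps, method = "BH")
  expect_setequal(tab$variable_id[tab$retained], names(adj)[adj <= 0.05 & ps <= 0.05])
  # the reported rank-FDR column is the same in both modes
  expect_equal(tab$fdr, fdr_rank(ps, Q = 0.05, method = "rank")$fdr)
})

test_that("final selection is the ordered intersection of the two gates", {
  fx <- classed_matrix(per_class = 6, p = 10, n_signal = 2, delta = 4, seed = 66)
  fit <- fit_plsda(fx$X, fx$classes, ncomp = 2)
  top <- rank_vip(fit, k = 5)
  pv <- feature_pvalues(fx$X, fx$classes)
  tab <- fdr_rank(pv)
  sel <- select_discriminants(top, tab)
  expect_true(all(sel$variable_id %in% top$variable_id))
  expect_true(all(sel$variable_id %in% tab$variable_id[tab$retained]))
  expect_true(all(diff(sel$p_value) >= 0))
  expect_true(all(c("V1", "V2") %in% sel$variable_id))  # the planted signal
  # empty FDR table -> empty selection
  empty <- fdr_rank(c(z = 0.9))
  expect_equal(nrow(select_discriminants(top, empty)), 0L)
  # disjoint variable universes are an input error
  foreign <- fdr_rank(c(q1 = 0.01, q2 = 0.02))
  expect_error(select_discriminants(top, foreign), class = "fusemet_data_error")
})

test_that("group summaries match direct recomputation and Tukey behaves", {
  fx <- classed_matrix(per_class = 5, p = 4, n_signal = 1, delta = 3, seed = 67)
  gs <- group_summaries(fx$X, fx$classes)
  for (i in seq_len(nrow(gs$groups))) {
    r <- gs$groups[i, ]
    v <- fx$X[fx$classes == r$class, r$variable_id]
    expect_equal(r$mean, mean(v), tolerance = 1e-12)
    expect_equal(r$sd, sd(v), tolerance = 1e-12)
    expect_equal(r$n, length(v))
    expect_equal(unlist(r[c("min", "q1", "median", "q3", "max")]),
                 setNames(fivenum(v), c("min", "q1", "median", "q3", "max")),
                 tolerance = 1e-12)
  }
  # identical groups: all Tukey adjusted p ~ 1
  Z <- matrix(rep(rnorm(5), 4), 20, 1, dimnames = list(NULL, "V1"))
  cls4 <- rep(c("A", "B", "C", "D"), each = 5)
  tk <- group_summaries(Z, cls4)$tukey
  expect_true(all(tk$p_adj > 0.999))
  expect_error(group_summaries(fx$X, fx$classes, features = "nope"),
               class = "fusemet_data_error")
})

test_that("a seasonal 4-fold feature is declared WIN > SPR by Tukey", {
  mult <- c(SPR = 1, SUM = 4^(1 / 3), AUT = 4^(2 / 3), WIN = 4)
  hits <- vapply(1:20, function(seed) {
    withr::with_seed(500 + seed, {
      cls <- rep(names(mult), each = 9)
      sdlog <- sqrt(log(1 + 0.2^2))
      v <- mult[cls] * rlnorm(36, -sdlog^2 / 2, sdlog)
    })
    gs <- group_summaries(cbind(V1 = v), cls)
    row <- gs$tukey[gs$tukey$contrast == "WIN-SPR", ]
    row$diff > 0 && row$p_adj <= 0.05
  }, logical(1))
  expect_gte(mean(hits), 0.9)
})
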