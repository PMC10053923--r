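# Model validation: cross-validated predictive ability and permutation tests.

venetian_folds <- function(n, folds, seed) {
  shift <- as.integer(seed) %% folds
  ((seq_len(n) - 1L + shift) %% folds) + 1L
}

#' Cross-validated predictive ability Q2 of a PLS-DA configuration
#'
#' Seven-fold (by default) cross-validation with a deterministic
#' venetian-blind fold assignment: sample i goes to fold
#' `((i - 1 + seed mod folds) mod folds) + 1`.  Each fold is predicted from a
#' model fitted on the remaining samples (centering re-estimated on the
#' training part), and
#' \deqn{Q^2 = 1 - PRESS / SS_{tot}}
#' with PRESS the pooled squared prediction error of the dummy class matrix
#' and SS_tot its total centered sum of squares.
#'
#' @param x Samples x variables data frame or matrix (scaled as used for
#'   fitting).
#' @param classes Class labels.
#' @param ncomp Components per fold model.
#' @param folds Number of cross-validation segments (default 7).
#' @param seed Integer controlling the fold offset (default 0).
#' @return Q2 (a single number; can be negative for models with no
#'   predictive ability).
#' @export
q2_crossval <- function(x, classes, ncomp = 2, folds = 7, seed = 0) {
  m <- as_sample_matrix(x)
  classes <- factor(classes)
  n <- nrow(m)
  folds <- check_count(folds, "folds", min = 2L)
  if (folds > n) stop_config("folds (%d) exceeds number of samples (%d).", folds, n)
  fold_id <- venetian_folds(n, folds, seed)
  Y <- class_dummy(classes)
  press <- 0
  for (k in seq_len(folds)) {
    test <- fold_id == k
    cls_train <- classes[!test]
    if (nlevels(droplevels(cls_train)) < nlevels(classes)) {
      stop_model(paste0("training fold %d lost a class; ",
                        "use fewer folds than the smallest class allows."), k)
    }
    Xtr <- m[!test, , drop = FALSE]
    xc <- colMeans(Xtr)
    Xtr <- sweep(Xtr, 2L, xc, "-")
    fit <- fit_plsda(Xtr, cls_train, ncomp = ncomp)
    yc <- colMeans(Y[!test, , drop = FALSE])
    pred <- predict_dummy(fit, m[test, , drop = FALSE], xc, yc)
    press <- press + sum((pred - Y[test, , drop = FALSE])^2)
  }
  ss_tot <- sum(sweep(Y, 2L, colMeans(Y), "-")^2)
  1 - press / ss_tot
}

#' Permutation validation of a PLS-DA model
#'
#' Refits the model `n` times under randomly permuted class labels, records
#' each permuted model's cumulative R2Y and cross-validated Q2, and
#' regresses both against the absolute correlation between the permuted and
#' original dummy class matrices (the original model enters as the
#' correlation-1 point).  The model is flagged valid when the R2 regression
#' intercept exceeds the Q2 intercept and the Q2 intercept is negative --
#' i.e. label-scrambled data shows no residual predictive ability, so the
#' original fit is not explained by overfitting.
#'
#' @param x Samples x variables data frame or matrix (scaled).
#' @param classes Class labels.
#' @param ncomp Components (default 2).
#' @param n Number of permutations (default 100; at least 10 so the
#'   intercepts are stable).
#' @param folds,seed Passed to [q2_crossval()]; `seed` also drives the
#'   permutations.
#' @return A `permutation_report`: tibble of per-model `correlation`, `r2`,
#'   `q2` (`permuted` flag), plus `r2_intercept`, `q2_intercept`,
#'   `r2_slope`, `q2_slope`, `valid`.
#' @export
permutation_test <- function(x, classes, ncomp = 2, n = 100, folds = 7,
                             seed = 1) {
  if (n < 10) stop_config("n = %d permutations is too few for a stable intercept (need >= 10).", n)
  m <- as_sample_matrix(x)
  classes <- factor(classes)
  Y0 <- class_dummy(classes)
  y0v <- as.numeric(sweep(Y0, 2L, colMeans(Y0), "-"))

  eval_labels <- function(cls, sd) {
    fit <- fit_plsda(sweep(m, 2L, colMeans(m), "-"), cls, ncomp = ncomp)
    q2 <- tryCatch(q2_crossval(m, cls, ncomp = ncomp, folds = folds, seed = sd),
                   fusemet_model_error = function(e) NA_real_)
    Yp <- class_dummy(cls)
    r <- abs(cor(as.numeric(sweep(Yp, 2L, colMeans(Yp), "-")), y0v))
    c(correlation = r, r2 = fit$R2Y[ncomp], q2 = q2)
  }

  orig <- eval_labels(classes, seed)
  set.seed(seed)
  perms <- t(vapply(seq_len(n), function(i) {
    eval_labels(sample(classes), seed)
  }, numeric(3)))

  results <- bind_rows(
    tibble(correlation = orig[["correlation"]], r2 = orig[["r2"]],
           q2 = orig[["q2"]], permuted = FALSE),
    tibble(correlation = perms[, "correlation"], r2 = perms[, "r2"],
           q2 = perms[, "q2"], permuted = TRUE)
  )
  ok <- !is.na(results$q2)
  fit_r2 <- lm(r2 ~ correlation, data = results)
  fit_q2 <- lm(q2 ~ correlation, data = results[ok, , drop = FALSE])
  r2_int <- unname(coef(fit_r2)[1L]); q2_int <- unname(coef(fit_q2)[1L])
  structure(list(
    results = results,
    n_permutations = n,
    r2_intercept = r2_int, q2_intercept = q2_int,
    r2_slope = unname(coef(fit_r2)[2L]), q2_slope = unname(coef(fit_q2)[2L]),
    original_r2 = orig[["r2"]], original_q2 = orig[["q2"]],
    valid = (r2_int > q2_int) && (q2_int < 0)
  ), class = "permutation_report")
}

#' @export
print.permutation_report <- function(x, ...) {
  cat(sprintf("<permutation_report> n = %d permutations\n", x$n_permutations))
  cat(sprintf("  original R2Y = %.3f, Q2 = %.3f\n", x$original_r2, x$original_q2))
  cat(sprintf("  intercepts: R2 = %.3f, Q2 = %.3f -> %s\n",
              x$r2_intercept, x$q2_intercept,
              if (x$valid) "valid (not overfitted)" else "NOT valid"))
  invisible(x)
}

#' @export
tidy.permutation_report <- function(x, ...) x$results

#' @export
glance.permutation_report <- function(x, ...) {
  tibble(n_permutations = x$n_permutations,
         original_r2 = x$original_r2, original_q2 = x$original_q2,
         r2_intercept = x$r2_intercept, q2_intercept = x$q2_intercept,
         valid = x$valid)
}
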