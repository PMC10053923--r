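# Native NIPALS latent-variable modelling for class discrimination.
#
# PLS-DA is PLS2 regression of the data matrix X on a dummy class-membership
# matrix Y (one column per class).  Components are extracted one at a time by
# the NIPALS alternation (w <- X'u; t <- Xw; c <- Y't; u <- Yc) followed by
# rank-one deflation of X and Y.  The first weight vector of each component
# is the dominant eigenvector of X'YY'X of the deflated matrices.

#' Pareto scaling
#'
#' Centers every variable and divides it by the square root of its standard
#' deviation (sd with denominator n-1) -- the usual compromise between unit
#' variance and no scaling for spectroscopic/MS intensities, keeping large
#' peaks influential while boosting mid-intensity variables.
#'
#' Zero-variance variables are centered and left undivided (divisor 1), and
#' flagged in the `zero_variance` attribute.
#'
#' @param x Data frame (optional `sample_id` first column) or matrix with at
#'   least 2 samples.
#' @return Scaled matrix with attributes `center` (column means),
#'   `pareto_divisor` (sqrt of sd per column) and `zero_variance`.
#' @examples
#' pareto_scale(matrix(c(1, 3, 2, 6), 2))
#' @export
pareto_scale <- function(x) {
  m <- as_sample_matrix(x)
  if (nrow(m) < 2L) stop_data("Pareto scaling needs at least 2 samples.")
  mu <- colMeans(m)
  sds <- apply(m, 2L, sd)
  div <- sqrt(sds)
  zero <- sds == 0
  div[zero] <- 1
  out <- sweep(sweep(m, 2L, mu, "-"), 2L, div, "/")
  attr(out, "center") <- mu
  attr(out, "pareto_divisor") <- div
  attr(out, "zero_variance") <- colnames(m)[zero]
  out
}

# Dummy (one column per class) response matrix from a factor.
class_dummy <- function(classes) {
  f <- factor(classes)
  if (nlevels(f) < 2L) stop_model("need at least 2 classes, got %d.", nlevels(f))
  Y <- model.matrix(~ f - 1)
  colnames(Y) <- levels(f)
  rownames(Y) <- names(classes)
  attr(Y, "assign") <- NULL
  attr(Y, "contrasts") <- NULL
  Y
}

# Sign convention: orient each weight vector so its largest-magnitude entry
# is positive, for reproducible score/loading plots.
orient_sign <- function(w) {
  s <- sign(w[which.max(abs(w))])
  if (s == 0) 1 else s
}

# Convergence: stop when the relative change of the score vector drops below
# `tol`.  When two latent directions are nearly tied (typical for permuted
# class labels) the power iteration's linear rate leaves the change plateaued
# orders of magnitude above `tol` although any vector of the tied subspace is
# an acceptable component; a stagnated small change (< plateau_tol, not
# halved over the last 100 iterations) is therefore accepted.  Genuine
# non-convergence still errors with diagnostics.
nipals_component <- function(X, Y, tol = 1e-10, max_iter = 500L,
                             tol_soft = 1e-3, plateau_tol = 1e-2) {
  u <- Y[, which.max(apply(Y, 2L, var)), drop = TRUE]
  if (all(u == u[1L])) u <- Y[, 1L] + rnorm(nrow(Y), sd = 1e-8)
  t_old <- rep(Inf, nrow(X))
  delta <- Inf
  deltas <- numeric(max_iter)
  converged <- FALSE
  for (it in seq_len(max_iter)) {
    w <- crossprod(X, u)[, 1L]
    nw <- sqrt(sum(w^2))
    if (nw == 0) stop_model("NIPALS weight collapsed to zero (degenerate X'u).")
    w <- w / nw
    t <- X %*% w
    c <- crossprod(Y, t)[, 1L] / sum(t^2)
    u <- (Y %*% c)[, 1L] / sum(c^2)
    delta <- sqrt(sum((t - t_old)^2)) / max(sqrt(sum(t^2)), .Machine$double.eps)
    deltas[it] <- delta
    t_old <- t
    if (delta < tol) {
      converged <- TRUE
      break
    }
    if (it >= 200L && delta < plateau_tol && delta > 0.5 * deltas[it - 100L]) {
      converged <- TRUE  # stagnated in a near-tied subspace
      break
    }
  }
  if (!converged && delta >= tol_soft) {
    stop_model(paste0("NIPALS did not converge in %d iterations ",
                      "(last relative score change %.3g, tol %.1g)."),
               max_iter, delta, tol)
  }
  s <- orient_sign(w)
  list(w = s * w, t = s * t[, 1L], c = s * c, u = s * u, iter = it)
}

#' Fit a PLS-DA model by NIPALS
#'
#' Partial least squares discriminant analysis: NIPALS PLS2 of the (already
#' scaled) data matrix against the dummy class matrix.  Components are
#' extracted to maximal covariance with the class scores and removed by
#' rank-one deflation; X-scores are mutually orthogonal.
#'
#' @param x Samples x variables data frame (optional `sample_id` column) or
#'   matrix.  Supply Pareto-scaled data or set `scale = "pareto"`.
#' @param classes Factor/character vector of class labels, one per sample.
#' @param ncomp Number of components (default 2, the usual choice for score
#'   and loading plots).
#' @param scale `"none"` (default; `x` is used as given) or `"pareto"`.
#' @param tol,max_iter NIPALS convergence control: stop when the relative
#'   change of the score vector drops below `tol` (default 1e-10) or error
#'   after `max_iter` (default 500) iterations.
#' @return A `plsda` object: scores `T`, loadings `P`, weights `W`,
#'   y-loadings `C`, y-scores `U`, per-component `R2X`, cumulative `R2Y`,
#'   class labels, dummy `Y`, variable/sample ids, scaling record.
#' @export
fit_plsda <- function(x, classes, ncomp = 2, scale = c("none", "pareto"),
                      tol = 1e-10, max_iter = 500L) {
  scale <- match.arg(scale)
  m <- as_sample_matrix(x)
  if (length(classes) != nrow(m)) {
    stop_data("length(classes) (%d) != number of samples (%d).",
              length(classes), nrow(m))
  }
  ncomp <- check_count(ncomp, "ncomp")
  scaling <- NULL
  if (scale == "pareto") {
    m <- pareto_scale(m)
    scaling <- list(center = attr(m, "center"),
                    pareto_divisor = attr(m, "pareto_divisor"))
  }
  classes <- factor(classes)
  Y0 <- class_dummy(classes)
  Yc <- sweep(Y0, 2L, colMeans(Y0), "-")

  X <- m; Y <- Yc
  ssx0 <- sum(X^2); ssy0 <- sum(Y^2)
  p <- ncol(X); n <- nrow(X)
  Tm <- matrix(0, n, ncomp); U <- matrix(0, n, ncomp)
  W <- matrix(0, p, ncomp); P <- matrix(0, p, ncomp)
  C <- matrix(0, ncol(Y), ncomp)
  R2X <- numeric(ncomp); R2Ycum <- numeric(ncomp); SSY_expl <- numeric(ncomp)
  for (a in seq_len(ncomp)) {
    cmp <- nipals_component(X, Y, tol = tol, max_iter = max_iter)
    t <- cmp$t
    pload <- crossprod(X, t)[, 1L] / sum(t^2)
    Tm[, a] <- t; U[, a] <- cmp$u; W[, a] <- cmp$w
    P[, a] <- pload; C[, a] <- cmp$c
    X <- X - tcrossprod(t, pload)
    Yfit <- tcrossprod(t, cmp$c)
    SSY_expl[a] <- sum(Yfit^2)
    Y <- Y - Yfit
    R2X[a] <- sum(tcrossprod(t, pload)^2) / ssx0
    R2Ycum[a] <- 1 - sum(Y^2) / ssy0
  }
  dimnames(Tm) <- list(rownames(m), paste0("t", seq_len(ncomp)))
  dimnames(U) <- list(rownames(m), paste0("u", seq_len(ncomp)))
  dimnames(W) <- list(colnames(m), paste0("w", seq_len(ncomp)))
  dimnames(P) <- list(colnames(m), paste0("p", seq_len(ncomp)))
  dimnames(C) <- list(colnames(Y0), paste0("c", seq_len(ncomp)))
  structure(list(
    kind = "PLS-DA", ncomp = ncomp,
    T = Tm, U = U, W = W, P = P, C = C,
    R2X = R2X, R2Y = R2Ycum, SSY_expl = SSY_expl,
    classes = classes, Y = Y0, ssx0 = ssx0, ssy0 = ssy0,
    sample_ids = rownames(m), variable_ids = colnames(m),
    scaling = scaling
  ), class = c("plsda", "latent_model"))
}

#' Fit an OPLS-DA model (one predictive + orthogonal components)
#'
#' Orthogonal projections to latent structures for a binary contrast:
#' variation in X uncorrelated with the response is peeled off into
#' `n_ortho` orthogonal components, then a single predictive component is
#' fitted to the filtered matrix.  The summary splits explained X-variation
#' into a between-group share (`R2X_pred`, the predictive component) and a
#' within-group share (`R2X_ortho`, the orthogonal components).
#'
#' For more than two classes supply `positive_class`: the model contrasts
#' that class against all others (the usual "most distinct season versus the
#' rest" analysis).
#'
#' @param x Samples x variables data frame or matrix (scaled as desired, or
#'   `scale = "pareto"`).
#' @param classes Class labels (two classes, or any number together with
#'   `positive_class`).
#' @param n_ortho Number of orthogonal components (default 1).
#' @param positive_class Class treated as +1 in the one-vs-rest contrast.
#' @inheritParams fit_plsda
#' @return An `oplsda` object: predictive `t`, `p`, `w`, `c`; orthogonal
#'   `T_o`, `P_o`, `W_o`; `R2X_pred`, `R2X_ortho` (per component and total),
#'   `R2Y`, contrast coding, ids.
#' @export
fit_oplsda <- function(x, classes, n_ortho = 1, positive_class = NULL,
                       scale = c("none", "pareto")) {
  scale <- match.arg(scale)
  m <- as_sample_matrix(x)
  n_ortho <- check_count(n_ortho, "n_ortho")
  f <- factor(classes)
  if (nlevels(f) < 2L) stop_model("need at least 2 classes.")
  if (nlevels(f) > 2L && is.null(positive_class)) {
    stop_model(paste0("multiclass response: give `positive_class` for a ",
                      "one-vs-rest contrast (levels: %s)."),
               paste(levels(f), collapse = ", "))
  }
  positive_class <- positive_class %||% levels(f)[2L]
  if (!positive_class %in% levels(f)) {
    stop_config("`positive_class` '%s' is not a class label.", positive_class)
  }
  y <- ifelse(f == positive_class, 1, -1)
  scaling <- NULL
  if (scale == "pareto") {
    m <- pareto_scale(m)
    scaling <- list(center = attr(m, "center"),
                    pareto_divisor = attr(m, "pareto_divisor"))
  }
  X <- sweep(m, 2L, colMeans(m), "-")
  yc <- y - mean(y)
  ssx0 <- sum(X^2); ssy0 <- sum(yc^2)
  p <- ncol(X); n <- nrow(X)

  To <- matrix(0, n, n_ortho); Po <- matrix(0, p, n_ortho)
  Wo <- matrix(0, p, n_ortho)
  r2x_ortho <- numeric(n_ortho)
  for (k in seq_len(n_ortho)) {
    w <- crossprod(X, yc)[, 1L] / sum(yc^2)
    w <- w / sqrt(sum(w^2))
    t <- (X %*% w)[, 1L]
    pl <- crossprod(X, t)[, 1L] / sum(t^2)
    wo <- pl - sum(w * pl) * w
    nwo <- sqrt(sum(wo^2))
    if (nwo < 1e-12 * max(sqrt(sum(pl^2)), 1)) {
      # no y-orthogonal structure left; emit a null component
      next
    }
    wo <- wo / nwo
    s <- orient_sign(wo); wo <- s * wo
    to <- (X %*% wo)[, 1L]
    po <- crossprod(X, to)[, 1L] / sum(to^2)
    To[, k] <- to; Po[, k] <- po; Wo[, k] <- wo
    X <- X - tcrossprod(to, po)
    r2x_ortho[k] <- sum(tcrossprod(to, po)^2) / ssx0
  }
  # predictive component on the filtered matrix
  w <- crossprod(X, yc)[, 1L] / sum(yc^2)
  w <- w / sqrt(sum(w^2))
  s <- orient_sign(w); w <- s * w
  t <- (X %*% w)[, 1L]
  pl <- crossprod(X, t)[, 1L] / sum(t^2)
  cc <- sum(yc * t) / sum(t^2)
  r2x_pred <- sum(tcrossprod(t, pl)^2) / ssx0
  resid_y <- yc - t * cc
  dimnames(To) <- list(rownames(m), paste0("to", seq_len(n_ortho)))
  structure(list(
    kind = "OPLS-DA", n_ortho = n_ortho,
    t = setNames(t, rownames(m)), p = setNames(pl, colnames(m)),
    w = setNames(w, colnames(m)), c = cc,
    T_o = To, P_o = Po, W_o = Wo,
    R2X_pred = r2x_pred, R2X_ortho = r2x_ortho,
    R2X_ortho_total = sum(r2x_ortho),
    R2Y = 1 - sum(resid_y^2) / ssy0,
    y = y, positive_class = positive_class, classes = f,
    ssx0 = ssx0,
    sample_ids = rownames(m), variable_ids = colnames(m),
    scaling = scaling
  ), class = c("oplsda", "latent_model"))
}

#' Inner relation of a PLS model (u1 vs t1)
#'
#' Ordinary least squares of the first y-score on the first x-score.  A tight
#' linear inner relation indicates that the dominant latent direction of X
#' tracks the class structure; its R-squared is the squared Pearson
#' correlation of t1 and u1.
#'
#' @param model A fitted `plsda` model.
#' @return A list with `data` (tibble `sample_id`, `class`, `t1`, `u1`),
#'   `slope`, `intercept`, `r_squared`.
#' @export
inner_relation <- function(model) {
  stopifnot(inherits(model, "plsda"))
  t1 <- model$T[, 1L]; u1 <- model$U[, 1L]
  if (sd(t1) == 0) stop_model("constant first score vector t1.")
  fit <- lm(u1 ~ t1)
  list(
    data = tibble(sample_id = model$sample_ids,
                  class = as.character(model$classes), t1 = t1, u1 = u1),
    slope = unname(coef(fit)[2L]),
    intercept = unname(coef(fit)[1L]),
    r_squared = cor(t1, u1)^2
  )
}

#' Variable importance in projection (VIP)
#'
#' Per-variable summary of contribution to the explained class variance:
#' \deqn{VIP_j = \sqrt{p \sum_a (w_{ja}/\|w_a\|)^2 SSY_a / \sum_a SSY_a}}
#' where `p` is the number of variables and `SSY_a` the Y sum of squares
#' explained by component `a`.  The mean of squared VIPs is exactly 1, so
#' VIP > 1 marks above-average importance.
#'
#' @param model A fitted `plsda` or `oplsda` model (for OPLS-DA the
#'   predictive component is used).
#' @return Tibble `variable_id`, `vip`, sorted by input variable order.
#' @export
vip_scores <- function(model) {
  if (inherits(model, "oplsda")) {
    W <- matrix(model$w, ncol = 1L)
    ssy <- model$R2Y
  } else if (inherits(model, "plsda")) {
    W <- model$W
    ssy <- model$SSY_expl
  } else {
    stop_model("`model` must be a fitted plsda/oplsda object.")
  }
  if (sum(ssy) <= 0) stop_model("model explains zero Y variance; VIP undefined.")
  p <- nrow(W)
  wn2 <- sweep(W, 2L, sqrt(colSums(W^2)), "/")^2
  vip <- sqrt(p * as.numeric(wn2 %*% ssy) / sum(ssy))
  tibble(variable_id = rownames(W) %||% paste0("V", seq_len(p)), vip = vip)
}

#' Joint score/loading coordinates for a biplot
#'
#' Returns first-two-component coordinates for samples (scores) and
#' variables (loadings), each set normalized by its maximum absolute value
#' so both live on a common [-1, 1] square.
#'
#' @param model A fitted `plsda` model with >= 2 components.
#' @param blocks Optional tibble `variable_id`, `block` tagging each
#'   variable (e.g. NMR bucket vs m/z feature).
#' @return Tibble `id`, `type` (`"sample"`/`"variable"`), `class` (sample
#'   class or variable block), `x`, `y`.
#' @export
biplot_data <- function(model, blocks = NULL) {
  stopifnot(inherits(model, "plsda"))
  if (model$ncomp < 2L) stop_model("biplot needs at least 2 components.")
  norm_block <- function(m) m / max(abs(m), .Machine$double.eps)
  Tn <- norm_block(model$T[, 1:2, drop = FALSE])
  Pn <- norm_block(model$P[, 1:2, drop = FALSE])
  out <- bind_rows(
    tibble(id = model$sample_ids, type = "sample",
           class = as.character(model$classes),
           x = unname(Tn[, 1L]), y = unname(Tn[, 2L])),
    tibble(id = model$variable_ids, type = "variable",
           class = NA_character_,
           x = unname(Pn[, 1L]), y = unname(Pn[, 2L]))
  )
  if (!is.null(blocks)) {
    out <- out %>%
      left_join(rename(blocks, block_tag = "block"),
                by = c(id = "variable_id")) %>%
      mutate(class = ifelse(.data$type == "variable",
                            .data$block_tag, .data$class)) %>%
      select(-"block_tag")
  }
  out
}

#' @export
print.plsda <- function(x, ...) {
  cat(sprintf("<plsda> %d samples x %d variables, %d classes, %d component(s)\n",
              length(x$sample_ids), length(x$variable_ids),
              nlevels(x$classes), x$ncomp))
  cat(sprintf("  R2X per component: %s (cum %.3f)\n",
              paste(sprintf("%.3f", x$R2X), collapse = ", "), sum(x$R2X)))
  cat(sprintf("  R2Y cumulative:    %.3f\n", x$R2Y[x$ncomp]))
  invisible(x)
}

#' @export
print.oplsda <- function(x, ...) {
  cat(sprintf("<oplsda> %d samples x %d variables, contrast %s vs rest\n",
              length(x$sample_ids), length(x$variable_ids), x$positive_class))
  cat(sprintf("  R2X(pred) = %.3f, R2X(ortho) = %.3f (%d component(s)), R2Y = %.3f\n",
              x$R2X_pred, x$R2X_ortho_total, x$n_ortho, x$R2Y))
  invisible(x)
}

# Regression coefficients of a fitted PLS2 model: B = W (P'W)^-1 C'.
plsda_coefficients <- function(model) {
  WPW <- solve(crossprod(model$P, model$W))
  model$W %*% WPW %*% t(model$C)
}

# Predict the (centered-scale) dummy response for new samples.
predict_dummy <- function(model, newdata, xcenter, ycenter) {
  B <- plsda_coefficients(model)
  sweep(newdata, 2L, xcenter, "-") %*% B + rep(ycenter, each = nrow(newdata))
}
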