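# broom-style tidiers for fitted latent-variable models.

#' Tidy a PLS-DA model into a long variable table
#'
#' @param x A `plsda` object.
#' @param ... Unused.
#' @return Tibble `variable_id`, `component`, `weight`, `loading`, `vip`.
#' @export
tidy.plsda <- function(x, ...) {
  vip <- vip_scores(x)
  out <- bind_rows(lapply(seq_len(x$ncomp), function(a) {
    tibble(variable_id = x$variable_ids, component = a,
           weight = x$W[, a], loading = x$P[, a])
  }))
  left_join(out, vip, by = "variable_id")
}

#' One-row summary of a PLS-DA model
#'
#' @param x A `plsda` object.
#' @param ... Unused.
#' @return Tibble with `ncomp`, `r2x_cum`, `r2y`, `n_samples`,
#'   `n_variables`, `n_classes`.
#' @export
glance.plsda <- function(x, ...) {
  tibble(ncomp = x$ncomp, r2x_cum = sum(x$R2X), r2y = x$R2Y[x$ncomp],
         n_samples = length(x$sample_ids),
         n_variables = length(x$variable_ids),
         n_classes = nlevels(x$classes))
}

#' Tidy an OPLS-DA model
#'
#' @param x An `oplsda` object.
#' @param ... Unused.
#' @return Tibble `variable_id`, `weight`, `loading` (predictive component)
#'   and `loading_o1` (first orthogonal component).
#' @export
tidy.oplsda <- function(x, ...) {
  tibble(variable_id = x$variable_ids, weight = unname(x$w),
         loading = unname(x$p),
         loading_o1 = if (ncol(x$P_o)) x$P_o[, 1L] else NA_real_)
}

#' One-row summary of an OPLS-DA model
#'
#' @param x An `oplsda` object.
#' @param ... Unused.
#' @return Tibble with `r2x_pred`, `r2x_ortho`, `r2y`, `n_ortho`,
#'   `positive_class`.
#' @export
glance.oplsda <- function(x, ...) {
  tibble(r2x_pred = x$R2X_pred, r2x_ortho = x$R2X_ortho_total, r2y = x$R2Y,
         n_ortho = x$n_ortho, positive_class = x$positive_class)
}

#' Score table of a latent model
#'
#' @param model A `plsda` or `oplsda` object.
#' @return Tibble of per-sample scores: `sample_id`, `class`, score columns
#'   (`t1`, `t2`, ... for PLS-DA; `t_pred`, `t_ortho1`, ... for OPLS-DA).
#' @export
model_scores <- function(model) {
  if (inherits(model, "plsda")) {
    bind_cols(tibble(sample_id = model$sample_ids,
                     class = as.character(model$classes)),
              as_tibble(model$T))
  } else if (inherits(model, "oplsda")) {
    out <- tibble(sample_id = model$sample_ids,
                  class = as.character(model$classes),
                  t_pred = unname(model$t))
    if (ncol(model$T_o)) {
      To <- model$T_o
      colnames(To) <- paste0("t_ortho", seq_len(ncol(To)))
      out <- bind_cols(out, as_tibble(To))
    }
    out
  } else {
    stop_model("`model` must be a plsda/oplsda object.")
  }
}
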