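# ggplot2 autoplot methods for the main result types.  Plots are a viewing
# surface over the exported coordinate tables; all figures can be rebuilt
# from the tidied data.

#' Score plot of a PLS-DA model
#'
#' @param object A `plsda` object (>= 2 components for a 2D plot).
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.plsda <- function(object, ...) {
  s <- model_scores(object)
  if (object$ncomp >= 2) {
    ggplot(s, aes(x = .data$t1, y = .data$t2, colour = .data$class)) +
      geom_hline(yintercept = 0, colour = "grey80") +
      geom_vline(xintercept = 0, colour = "grey80") +
      geom_point(size = 2.5) +
      labs(x = sprintf("t[1] (R2X = %.1f%%)", 100 * object$R2X[1L]),
           y = sprintf("t[2] (R2X = %.1f%%)", 100 * object$R2X[2L]),
           colour = "class", title = "PLS-DA scores") +
      theme_minimal()
  } else {
    ggplot(s, aes(x = .data$class, y = .data$t1, colour = .data$class)) +
      geom_point(size = 2.5) + theme_minimal() +
      labs(y = "t[1]", title = "PLS-DA scores")
  }
}

#' Score plot of an OPLS-DA model (predictive vs first orthogonal)
#'
#' @param object An `oplsda` object.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.oplsda <- function(object, ...) {
  s <- model_scores(object)
  y <- if ("t_ortho1" %in% names(s)) "t_ortho1" else "t_pred"
  ggplot(s, aes(x = .data$t_pred, y = .data[[y]], colour = .data$class)) +
    geom_hline(yintercept = 0, colour = "grey80") +
    geom_vline(xintercept = 0, colour = "grey80") +
    geom_point(size = 2.5) +
    labs(x = sprintf("t[pred] (R2X = %.1f%%)", 100 * object$R2X_pred),
         y = sprintf("t[ortho] (R2X = %.1f%%)", 100 * object$R2X_ortho_total),
         title = sprintf("OPLS-DA: %s vs rest", object$positive_class)) +
    theme_minimal()
}

#' Permutation validation plot (R2/Q2 vs label correlation)
#'
#' @param object A `permutation_report`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.permutation_report <- function(object, ...) {
  d <- tidyr::pivot_longer(object$results, c("r2", "q2"),
                           names_to = "statistic", values_to = "value")
  ggplot(d, aes(x = .data$correlation, y = .data$value,
                colour = .data$statistic)) +
    geom_point(alpha = 0.6) +
    geom_smooth(method = "lm", formula = y ~ x, se = FALSE, linewidth = 0.5) +
    geom_hline(yintercept = 0, colour = "grey60", linetype = 2) +
    labs(x = "|correlation with original class labels|", y = NULL,
         title = sprintf("Permutation validation (intercepts: R2 %.2f, Q2 %.2f)",
                         object$r2_intercept, object$q2_intercept)) +
    theme_minimal()
}

#' Inner-relation plot (u1 vs t1)
#'
#' @param inner Result of [inner_relation()].
#' @return A ggplot object.
#' @export
plot_inner_relation <- function(inner) {
  ggplot(inner$data, aes(x = .data$t1, y = .data$u1, colour = .data$class)) +
    geom_abline(slope = inner$slope, intercept = inner$intercept,
                colour = "grey40") +
    geom_point(size = 2.5) +
    labs(title = sprintf("Inner relation: u1 = %.3f t1 %+.3f (R2 = %.4f)",
                         inner$slope, inner$intercept, inner$r_squared)) +
    theme_minimal()
}

#' Biplot of joint scores and loadings
#'
#' @param coords Tibble from [biplot_data()].
#' @return A ggplot object.
#' @export
plot_biplot <- function(coords) {
  ggplot(coords, aes(x = .data$x, y = .data$y)) +
    geom_hline(yintercept = 0, colour = "grey85") +
    geom_vline(xintercept = 0, colour = "grey85") +
    geom_point(data = coords[coords$type == "variable", ],
               aes(shape = .data$class), colour = "grey55", size = 1.5) +
    geom_point(data = coords[coords$type == "sample", ],
               aes(colour = .data$class), size = 2.5) +
    labs(x = "component 1", y = "component 2",
         colour = "sample class", shape = "variable block",
         title = "PLS-DA biplot (max-abs normalized)") +
    theme_minimal()
}

#' Box plots of selected discriminant features by group
#'
#' @param summaries Result of [group_summaries()].
#' @return A ggplot object built from the five-number summaries.
#' @export
plot_group_boxes <- function(summaries) {
  g <- summaries$groups
  ggplot(g, aes(x = .data$class, fill = .data$class)) +
    geom_boxplot(aes(ymin = .data$min, lower = .data$q1,
                     middle = .data$median, upper = .data$q3,
                     ymax = .data$max),
                 stat = "identity") +
    facet_wrap(~variable_id, scales = "free_y") +
    labs(x = NULL, y = "normalized intensity") +
    theme_minimal() + theme(legend.position = "none")
}
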