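# Discriminant feature selection: top-k VIP ranking, per-feature one-way
# ANOVA p-values, the rank-based FDR transform, and group summaries.

#' Top-k variables by VIP score
#'
#' @param model A fitted `plsda`/`oplsda` model.
#' @param k How many variables to keep (default 15, the usual short list
#'   examined on a loadings plot).
#' @return Tibble `variable_id`, `vip`, `vip_rank`, descending VIP; ties
#'   broken by variable id (lexicographic, stable across runs).
#' @export
rank_vip <- function(model, k = 15) {
  k <- check_count(k, "k")
  v <- vip_scores(model)
  v <- v[order(-v$vip, v$variable_id), , drop = FALSE]
  v$vip_rank <- seq_len(nrow(v))
  head(v, k)
}

#' Per-feature one-way ANOVA p-values across groups
#'
#' Classical fixed-effects one-way ANOVA F-test (equal-variance) applied to
#' every variable independently, on the normalized (not Pareto-scaled)
#' intensities.
#'
#' @param x Samples x variables data frame (optional `sample_id` column) or
#'   matrix.
#' @param classes Group labels; at least 2 groups with >= 2 samples each.
#' @return Tibble `variable_id`, `f_statistic`, `p_value`.
#' @export
feature_pvalues <- function(x, classes) {
  m <- as_sample_matrix(x)
  f <- factor(classes)
  if (nlevels(f) < 2L) stop_data("need at least 2 classes.")
  counts <- table(f)
  if (any(counts < 2L)) {
    stop_data("class(es) with fewer than 2 samples: %s",
              paste(names(counts)[counts < 2L], collapse = ", "))
  }
  res <- apply(m, 2L, function(v) {
    if (all(tapply(v, f, var) == 0)) {
      # no within-group variance: F degenerates; equal means mean no effect
      means <- tapply(v, f, mean)
      if (max(means) - min(means) == 0) return(c(0, 1)) else return(c(Inf, 0))
    }
    ht <- oneway.test(v ~ f, var.equal = TRUE)
    c(unname(ht$statistic), unname(ht$p.value))
  })
  tibble(variable_id = colnames(m), f_statistic = unname(res[1L, ]),
         p_value = unname(res[2L, ]))
}

#' Rank-based false-discovery-rate table
#'
#' Implements the reporting rule used for discriminant tables: features with
#' p <= `p_cutoff` are ranked ascending by p-value (rank `i` of `m` such
#' features) and each is assigned the Benjamini-Hochberg critical value
#' \deqn{FDR = (i/m) \times Q.}
#' With `method = "rank"` (the verbatim rule) a feature is retained when its
#' FDR value is at most `Q` -- which holds for every ranked feature, so the
#' p <= 0.05 filter is the effective gate.  `method = "bh"` instead applies
#' the standard BH step-up over *all* supplied p-values, which controls the
#' study-wise false discovery proportion at `Q`; the rank-FDR column is
#' still reported either way.
#'
#' @param pvalues Data frame with columns `variable_id` (or first column)
#'   and `p_value`, or a named numeric vector.
#' @param Q Acceptable FDR (default 0.05).
#' @param p_cutoff Ranking filter (default 0.05).
#' @param method `"rank"` (verbatim reporting rule, default) or `"bh"`
#'   (standard step-up over all tests).
#' @return Tibble (possibly empty): `variable_id`, `p_value`, `rank`, `m`,
#'   `fdr` (full precision), `fdr_reported` (3 decimals), `retained`.
#' @export
fdr_rank <- function(pvalues, Q = 0.05, p_cutoff = 0.05,
                     method = c("rank", "bh")) {
  method <- match.arg(method)
  Q <- check_number(Q, "Q", min = 0, strict = TRUE)
  tab <- normalize_pvalues(pvalues)
  if (any(tab$p_value < 0 | tab$p_value > 1, na.rm = TRUE)) {
    stop_data("p-values must lie in [0, 1].")
  }
  bh_adj <- p.adjust(tab$p_value, method = "BH")
  keep <- which(!is.na(tab$p_value) & tab$p_value <= p_cutoff)
  if (!length(keep)) {
    return(tibble(variable_id = character(), p_value = numeric(),
                  rank = integer(), m = integer(), fdr = numeric(),
                  fdr_reported = numeric(), retained = logical()))
  }
  sub <- tab[keep, , drop = FALSE]
  bh_sub <- bh_adj[keep]
  ord <- order(sub$p_value, sub$variable_id)
  sub <- sub[ord, , drop = FALSE]
  bh_sub <- bh_sub[ord]
  m <- nrow(sub)
  i <- seq_len(m)
  fdr <- (i / m) * Q
  retained <- switch(method, rank = fdr <= Q, bh = bh_sub <= Q)
  out <- tibble(variable_id = sub$variable_id, p_value = sub$p_value,
                rank = i, m = m, fdr = fdr, fdr_reported = round(fdr, 3),
                retained = retained)
  attr(out, "universe") <- tab$variable_id
  out
}

normalize_pvalues <- function(pvalues) {
  if (is.numeric(pvalues)) {
    ids <- names(pvalues) %||% paste0("V", seq_along(pvalues))
    return(tibble(variable_id = ids, p_value = as.numeric(pvalues)))
  }
  if (!is.data.frame(pvalues)) stop_data("`pvalues` must be a data frame or numeric vector.")
  df <- as.data.frame(pvalues)
  if (!"p_value" %in% names(df)) stop_data("`pvalues` needs a `p_value` column.")
  id_col <- if ("variable_id" %in% names(df)) "variable_id" else names(df)[1L]
  tibble(variable_id = as.character(df[[id_col]]), p_value = df$p_value)
}

#' Final discriminant list: top-VIP features that survive the FDR gate
#'
#' Intersects the top-k VIP set with the FDR-retained set, ordered by
#' ascending p-value.
#'
#' @param vip_top Tibble from [rank_vip()].
#' @param fdr_table Tibble from [fdr_rank()] computed over the same variable
#'   universe.
#' @return Tibble `variable_id`, `vip`, `vip_rank`, `p_value`, `rank`, `m`,
#'   `fdr`, `fdr_reported`.
#' @export
select_discriminants <- function(vip_top, fdr_table) {
  universe <- attr(fdr_table, "universe") %||% fdr_table$variable_id
  if (nrow(vip_top) && length(universe) &&
      !any(vip_top$variable_id %in% universe)) {
    # a fully disjoint variable universe means mismatched inputs,
    # not an empty selection
    stop_data("VIP table and FDR table share no variable ids; check inputs.")
  }
  if (nrow(fdr_table) == 0L) {
    return(tibble(variable_id = character(), vip = numeric(),
                  vip_rank = integer(), p_value = numeric(), rank = integer(),
                  m = integer(), fdr = numeric(), fdr_reported = numeric()))
  }
  retained <- fdr_table[fdr_table$retained, , drop = FALSE]
  out <- dplyr::inner_join(vip_top, retained, by = "variable_id")
  out <- arrange(out, .data$p_value)
  select(out, "variable_id", "vip", "vip_rank", "p_value", "rank", "m",
         "fdr", "fdr_reported")
}

#' Per-feature per-group summaries with ANOVA and Tukey HSD
#'
#' For each selected feature: group means, SDs and sizes (the usual
#' mean +/- SD reporting), box-plot five-number summaries, the one-way
#' ANOVA F and p, and Tukey honest-significant-difference adjusted p-values
#' for all group pairs (studentized-range based, via [stats::TukeyHSD()]).
#'
#' @param x Samples x variables data frame or matrix (normalized
#'   intensities).
#' @param classes Group labels (>= 2 per group).
#' @param features Character vector of variable ids to summarise (default:
#'   all columns).
#' @return A list with `groups` (tibble `variable_id`, `class`, `n`, `mean`,
#'   `sd`, `min`, `q1`, `median`, `q3`, `max`), `anova` (tibble
#'   `variable_id`, `f_statistic`, `p_value`) and `tukey` (tibble
#'   `variable_id`, `contrast`, `diff`, `p_adj`).
#' @export
group_summaries <- function(x, classes, features = NULL) {
  m <- as_sample_matrix(x)
  f <- factor(classes)
  features <- features %||% colnames(m)
  missing <- setdiff(features, colnames(m))
  if (length(missing)) {
    stop_data("unknown feature(s): %s", paste(head(missing, 5L), collapse = ", "))
  }
  counts <- table(f)
  if (any(counts < 2L)) stop_data("every class needs >= 2 samples for SD.")

  groups <- purrr::map(features, function(v) {
    vals <- m[, v]
    stats_by <- tapply(vals, f, function(g) {
      fn <- unname(fivenum(g))
      c(n = length(g), mean = mean(g), sd = sd(g),
        min = fn[1L], q1 = fn[2L], median = fn[3L], q3 = fn[4L], max = fn[5L])
    })
    bind_cols(tibble(variable_id = v, class = names(stats_by)),
              as_tibble(do.call(rbind, stats_by)))
  })
  groups <- bind_rows(groups)

  anova_tab <- feature_pvalues(m[, features, drop = FALSE], f)

  tukey <- purrr::map(features, function(v) {
    fit <- aov(m[, v] ~ f)
    th <- TukeyHSD(fit)$f
    tibble(variable_id = v, contrast = rownames(th),
           diff = th[, "diff"], p_adj = th[, "p adj"])
  })
  list(groups = groups, anova = anova_tab, tukey = bind_rows(tukey))
}
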