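#' Block-wise variance scaling of one data block
#'
#' Scales a samples x variables block by the sum of its per-variable sample
#' standard deviations: every entry is divided by
#' \eqn{\sum_j \sigma_j}{sum_j sd_j} (sd with denominator n-1).  After
#' scaling, the per-variable standard deviations of the block sum to 1, so
#' two blocks of very different size and intensity scale (e.g. 225 NMR
#' buckets vs tens-to-hundreds of LC-MS features) contribute comparable total
#' variance to a fused matrix.
#'
#' Zero-variance variables are retained (they divide like the rest) and
#' flagged in the `zero_variance` attribute of the result.
#'
#' @param x Data frame (optionally with a `sample_id` first column) or
#'   numeric matrix; at least 2 samples, no missing values.
#' @return A list with `values` (scaled tibble, `sample_id` first),
#'   `sigma_sum` (the divisor), and `zero_variance` (character vector of
#'   flagged variables).
#' @export
block_scale <- function(x) {
  m <- as_sample_matrix(x)
  if (nrow(m) < 2L) stop_data("block scaling needs at least 2 samples.")
  if (anyNA(m)) stop_data("NA/NaN in block; impute or remove before scaling.")
  sds <- apply(m, 2L, sd)
  sigma_sum <- sum(sds)
  if (sigma_sum <= 0) {
    stop_data("all-constant block (sum of standard deviations is 0); cannot scale.")
  }
  scaled <- m / sigma_sum
  list(values = matrix_to_tibble(scaled),
       sigma_sum = sigma_sum,
       zero_variance = colnames(m)[sds == 0])
}

#' Fuse a binned NMR block and an LC-MS block into one matrix
#'
#' Applies [block_scale()] to each block independently, then concatenates
#' them column-wise (NMR buckets first, then MS features) over the shared
#' samples.  Row order follows the NMR block.  The result records block
#' membership of every variable and the scaling divisors, so the fused
#' matrix can be unstacked exactly.
#'
#' @param nmr Binned NMR tibble (`sample_id` + one column per bucket), as
#'   from [stack_binned()].
#' @param ms Either a feature-table tibble (see [read_feature_table()]; the
#'   per-sample area columns are used) or a plain `sample_id` + variables
#'   table of MS intensities.
#' @return A `fused_matrix` object: list with `values` (tibble, `sample_id`
#'   first), `blocks` (tibble `variable_id`, `block`), `scaling` (tibble
#'   `block`, `sigma_sum`, `n_variables`), `zero_variance`.
#' @export
fuse_blocks <- function(nmr, ms) {
  ms_wide <- if (is.data.frame(ms) && all(feature_meta_cols %in% names(ms))) {
    feature_table_to_samples(ms)
  } else {
    ms
  }
  nmr_m <- as_sample_matrix(nmr)
  ms_m <- as_sample_matrix(ms_wide)

  only_nmr <- setdiff(rownames(nmr_m), rownames(ms_m))
  only_ms <- setdiff(rownames(ms_m), rownames(nmr_m))
  if (length(only_nmr) || length(only_ms)) {
    stop_data("sample sets differ between blocks. NMR-only: {%s}; MS-only: {%s}",
              paste(only_nmr, collapse = ", "), paste(only_ms, collapse = ", "))
  }
  ms_m <- ms_m[rownames(nmr_m), , drop = FALSE]
  dup <- intersect(colnames(nmr_m), colnames(ms_m))
  if (length(dup)) stop_data("variable ids shared across blocks: %s",
                             paste(head(dup, 5L), collapse = ", "))

  sn <- block_scale(nmr_m)
  sm <- block_scale(ms_m)
  fused <- cbind(as_sample_matrix(sn$values), as_sample_matrix(sm$values))

  structure(list(
    values = matrix_to_tibble(fused),
    blocks = tibble(
      variable_id = c(colnames(nmr_m), colnames(ms_m)),
      block = c(rep("NMR", ncol(nmr_m)), rep("MS", ncol(ms_m)))
    ),
    scaling = tibble(block = c("NMR", "MS"),
                     sigma_sum = c(sn$sigma_sum, sm$sigma_sum),
                     n_variables = c(ncol(nmr_m), ncol(ms_m))),
    zero_variance = c(sn$zero_variance, sm$zero_variance)
  ), class = "fused_matrix")
}

# Wide sample x feature intensity table from an MZmine-style feature table.
feature_table_to_samples <- function(features) {
  validate_feature_table(features)
  ids <- feature_sample_ids(features)
  m <- t(as.matrix(features[, ids, drop = FALSE]))
  colnames(m) <- features$feature_id
  rownames(m) <- ids
  m
}

#' Split a fused matrix back into its source blocks
#'
#' @param fused A `fused_matrix` object.
#' @return Named list of tibbles (`NMR`, `MS`), each `sample_id` + variables,
#'   exactly as scaled at fusion time.
#' @export
unstack_blocks <- function(fused) {
  stopifnot(inherits(fused, "fused_matrix"))
  m <- as_sample_matrix(fused$values)
  split_ids <- split(fused$blocks$variable_id, fused$blocks$block)
  lapply(split_ids[unique(fused$blocks$block)], function(v) {
    matrix_to_tibble(m[, v, drop = FALSE])
  })
}

#' @export
print.fused_matrix <- function(x, ...) {
  cat(sprintf("<fused_matrix> %d samples x %d variables\n",
              nrow(x$values), nrow(x$blocks)))
  s <- x$scaling
  for (i in seq_len(nrow(s))) {
    cat(sprintf("  block %-3s: %4d variables, sigma_sum = %.6g\n",
                s$block[i], s$n_variables[i], s$sigma_sum[i]))
  }
  if (length(x$zero_variance)) {
    cat(sprintf("  %d zero-variance variable(s) flagged\n",
                length(x$zero_variance)))
  }
  invisible(x)
}

#' Tidy a fused matrix into long form
#'
#' @param x A `fused_matrix`.
#' @param ... Unused.
#' @return Long tibble: `sample_id`, `variable_id`, `block`, `value`.
#' @export
tidy.fused_matrix <- function(x, ...) {
  long <- tidyr::pivot_longer(x$values, -"sample_id",
                              names_to = "variable_id", values_to = "value")
  left_join(long, x$blocks, by = "variable_id")[
    , c("sample_id", "variable_id", "block", "value")]
}

#' Write a fused matrix as delimited text with a block header
#'
#' Two header rows (variable id, block tag) followed by one row per sample;
#' [read_fused_matrix()] round-trips the format.
#'
#' @param fused A `fused_matrix`.
#' @param path Output path (tab-separated).
#' @return `path`, invisibly.
#' @export
write_fused_matrix <- function(fused, path) {
  stopifnot(inherits(fused, "fused_matrix"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste(c("sample_id", fused$blocks$variable_id), collapse = "\t"), con)
  writeLines(paste(c("block", fused$blocks$block), collapse = "\t"), con)
  m <- as_sample_matrix(fused$values)
  for (i in seq_len(nrow(m))) {
    writeLines(paste(c(rownames(m)[i], format(m[i, ], digits = 15)),
                     collapse = "\t"), con)
  }
  invisible(path)
}

#' Read a fused matrix written by [write_fused_matrix()]
#'
#' @param path File path.
#' @return A `fused_matrix` object (scaling record reconstructed as the
#'   identity: the stored values are already scaled).
#' @export
read_fused_matrix <- function(path) {
  lines <- readLines(path)
  hdr <- strsplit(lines[1L], "\t", fixed = TRUE)[[1L]]
  blk <- strsplit(lines[2L], "\t", fixed = TRUE)[[1L]]
  body <- strsplit(lines[-(1:2)], "\t", fixed = TRUE)
  ids <- vapply(body, `[[`, character(1), 1L)
  m <- do.call(rbind, lapply(body, function(r) as.numeric(r[-1L])))
  colnames(m) <- hdr[-1L]
  rownames(m) <- ids
  structure(list(
    values = matrix_to_tibble(m),
    blocks = tibble(variable_id = hdr[-1L], block = blk[-1L]),
    scaling = tibble(block = unique(blk[-1L]), sigma_sum = NA_real_,
                     n_variables = as.integer(table(blk[-1L])[unique(blk[-1L])])),
    zero_variance = character()
  ), class = "fused_matrix")
}
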