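#' Bin a 1D NMR projection spectrum into fixed-width buckets
#'
#' Divides the chemical-shift axis into consecutive buckets of `width` ppm
#' between `lo` and `hi` and summarises the intensity in each bucket.  This is
#' the classical bucketing step that turns a high-resolution 1D projection of
#' a 2D J-resolved experiment into a fixed-length variable vector comparable
#' across samples.  Defaults (0.0--9.0 ppm, 0.04 ppm buckets, mean intensity
#' per bucket) give 225 bins covering the full proton spectral window.
#'
#' Bucket `b` covers the half-open interval `[lo + b*width, lo + (b+1)*width)`;
#' the final bucket is closed on the right so the breakpoints partition
#' `[lo, hi]` without double counting.  Points outside `[lo, hi]` are ignored.
#' Empty buckets yield 0 so the output is always a complete vector.
#'
#' @param spec Data frame with numeric columns `ppm` and `intensity` (one
#'   sample), in either axis direction.
#' @param lo,hi Chemical-shift window in ppm.
#' @param width Bucket width in ppm.
#' @param agg `"mean"` (default) averages the points falling in each bucket;
#'   `"sum"` totals them instead.
#' @return A tibble with one row per bucket: `bin` (index), `ppm_lo`,
#'   `ppm_hi`, `bin_label` (e.g. `"6.52-6.56"`), `value`, `n_points`.
#' @examples
#' spec <- data.frame(ppm = seq(0, 9, by = 0.002), intensity = 1)
#' b <- bin_spectrum(spec)
#' nrow(b)  # 225
#' @export
bin_spectrum <- function(spec, lo = 0, hi = 9, width = 0.04,
                         agg = c("mean", "sum")) {
  agg <- match.arg(agg)
  width <- check_number(width, "width", min = 0, strict = TRUE)
  if (!(hi > lo)) stop_config("`hi` (%g) must exceed `lo` (%g).", hi, lo)
  if (!is.data.frame(spec) || !all(c("ppm", "intensity") %in% names(spec))) {
    stop_data("`spec` must be a data frame with columns `ppm` and `intensity`.")
  }
  ppm <- as.numeric(spec$ppm)
  y <- as.numeric(spec$intensity)
  if (length(ppm) == 0L) stop_data("empty spectrum: no points to bin.")
  if (anyNA(ppm) || anyNA(y)) stop_data("NaN/NA in spectrum axis or intensity.")

  edges <- bin_edges(lo, hi, width)
  nb <- length(edges) - 1L
  keep <- ppm >= lo & ppm <= hi
  ppm <- ppm[keep]; y <- y[keep]
  # half-open buckets, last one right-closed
  idx <- findInterval(ppm, edges, rightmost.closed = TRUE, left.open = FALSE)
  idx[idx > nb] <- nb
  counts <- tabulate(idx, nbins = nb)
  sums <- rep(0, nb)
  if (length(idx)) {
    agg_sum <- rowsum(y, group = idx)
    sums[as.integer(rownames(agg_sum))] <- agg_sum[, 1L]
  }
  value <- if (agg == "mean") ifelse(counts > 0L, sums / pmax(counts, 1L), 0) else sums
  tibble(
    bin = seq_len(nb),
    ppm_lo = edges[-length(edges)],
    ppm_hi = edges[-1L],
    bin_label = bin_labels(edges),
    value = as.numeric(value),
    n_points = counts
  )
}

# Bucket breakpoints; tolerant of floating-point jitter in (hi-lo)/width so
# that e.g. 9.0 / 0.04 yields exactly 225 buckets.
bin_edges <- function(lo, hi, width) {
  nb_real <- (hi - lo) / width
  nb <- if (abs(nb_real - round(nb_real)) < 1e-8) round(nb_real) else ceiling(nb_real)
  edges <- lo + width * seq.int(0L, nb)
  edges[length(edges)] <- max(edges[length(edges)], hi)
  edges
}

bin_labels <- function(edges) {
  sprintf("%.2f-%.2f", edges[-length(edges)], edges[-1L])
}

#' Stack binned spectra from several samples into one NMR data block
#'
#' Applies [bin_spectrum()] to each sample of a long spectrum table and
#' stacks the results row-wise into a samples x buckets matrix -- the NMR
#' variable block used downstream for fusion and modelling.
#'
#' @param spectra Long data frame with columns `sample_id`, `ppm`,
#'   `intensity` covering all samples.
#' @inheritParams bin_spectrum
#' @return A tibble with `sample_id` followed by one column per bucket
#'   (named by `bin_label`), rows in first-appearance order of `sample_id`.
#' @export
stack_binned <- function(spectra, lo = 0, hi = 9, width = 0.04,
                         agg = c("mean", "sum")) {
  agg <- match.arg(agg)
  if (!is.data.frame(spectra) ||
      !all(c("sample_id", "ppm", "intensity") %in% names(spectra))) {
    stop_data("`spectra` needs columns `sample_id`, `ppm`, `intensity`.")
  }
  runs <- rle(as.character(spectra$sample_id))
  ids <- runs$values
  if (anyDuplicated(ids)) {
    stop_data("duplicate sample_id in spectra: %s",
              paste(unique(ids[duplicated(ids)]), collapse = ", "))
  }
  if (length(ids) < 2L) stop_data("need at least 2 samples to stack.")
  stops <- cumsum(runs$lengths)
  starts <- c(1L, head(stops, -1L) + 1L)
  rows <- lapply(seq_along(ids), function(i) {
    one <- spectra[starts[i]:stops[i], c("ppm", "intensity")]
    bin_spectrum(one, lo = lo, hi = hi, width = width, agg = agg)
  })
  labels <- rows[[1L]]$bin_label
  values <- do.call(rbind, lapply(rows, function(b) b$value))
  colnames(values) <- labels
  bind_cols(tibble(sample_id = ids), as_tibble(values))
}

#' Read a per-sample projection spectrum from delimited text
#'
#' Two numeric columns (ppm, intensity); header optional; comma, tab or
#' whitespace separated.
#'
#' @param path File path.
#' @param sample_id Identifier attached to the returned rows; defaults to the
#'   file name without extension.
#' @return Tibble with `sample_id`, `ppm`, `intensity`.
#' @export
read_projection <- function(path, sample_id = NULL) {
  sample_id <- sample_id %||% sub("\\.[^.]*$", "", basename(path))
  first <- readLines(path, n = 1L)
  has_header <- grepl("[A-Za-z]", first)
  df <- utils::read.table(path, header = has_header, sep = "",
                          comment.char = "#",
                          col.names = c("ppm", "intensity"))
  tibble(sample_id = sample_id,
         ppm = as.numeric(df[[1L]]), intensity = as.numeric(df[[2L]]))
}

#' Read a manifest of projection spectra
#'
#' The manifest is delimited text with columns `sample_id` and `path`
#' (relative paths resolved against the manifest's directory).
#'
#' @param manifest Path to the manifest file.
#' @return Long tibble of all samples, ready for [stack_binned()].
#' @export
read_projection_manifest <- function(manifest) {
  df <- readr::read_delim(manifest, show_col_types = FALSE, trim_ws = TRUE)
  if (!all(c("sample_id", "path") %in% names(df))) {
    stop_data("manifest needs columns `sample_id` and `path`.")
  }
  base <- dirname(manifest)
  resolve <- function(p) if (file.exists(p)) p else file.path(base, p)
  bind_rows(purrr::map2(df$sample_id, df$path,
                        function(id, p) read_projection(resolve(p), id)))
}
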