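# Internal helpers: argument checking and error signalling.
#
# Errors carry a class taxonomy so callers (and the pipeline driver) can
# distinguish configuration mistakes, malformed data and modelling failures:
#   fusemet_config_error / fusemet_data_error / fusemet_model_error.

stop_config <- function(msg, ...) {
  abort(sprintf(msg, ...), class = c("fusemet_config_error", "fusemet_error"))
}

stop_data <- function(msg, ...) {
  abort(sprintf(msg, ...), class = c("fusemet_data_error", "fusemet_error"))
}

stop_model <- function(msg, ...) {
  abort(sprintf(msg, ...), class = c("fusemet_model_error", "fusemet_error"))
}

check_count <- function(x, name, min = 1L) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x != round(x) || x < min) {
    stop_config("`%s` must be a single integer >= %d (got %s).",
                name, min, deparse(substitute(x)) %||% format(x))
  }
  as.integer(x)
}

check_number <- function(x, name, min = -Inf, strict = FALSE) {
  ok <- is.numeric(x) && length(x) == 1L && !is.na(x) &&
    (if (strict) x > min else x >= min)
  if (!ok) stop_config("`%s` must be a single number %s %s.",
                       name, if (strict) ">" else ">=", format(min))
  as.numeric(x)
}

# Extract a samples x variables numeric matrix from a data frame whose first
# column may be a sample identifier, or pass a matrix through.  Returns the
# matrix with rownames set to the sample ids.
as_sample_matrix <- function(x, id_col = "sample_id") {
  if (is.matrix(x)) {
    if (is.null(rownames(x))) rownames(x) <- paste0("S", seq_len(nrow(x)))
    storage.mode(x) <- "double"
    return(x)
  }
  if (!is.data.frame(x)) stop_data("expected a data frame or matrix of intensities.")
  df <- as.data.frame(x)
  if (id_col %in% names(df)) {
    ids <- as.character(df[[id_col]])
    df[[id_col]] <- NULL
  } else if (!is.numeric(df[[1L]])) {
    ids <- as.character(df[[1L]])
    df[[1L]] <- NULL
  } else {
    ids <- paste0("S", seq_len(nrow(df)))
  }
  m <- as.matrix(df)
  if (!is.numeric(m)) stop_data("non-numeric variable columns in intensity table.")
  rownames(m) <- ids
  m
}

matrix_to_tibble <- function(m, id_col = "sample_id") {
  bind_cols(tibble(!!id_col := rownames(m)), as_tibble(m))
}
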