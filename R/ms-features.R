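#' Read an aligned LC-MS feature table
#'
#' Delimited text in the MZmine-export-like layout this pipeline consumes:
#' columns `feature_id`, `mz`, `rt_min`, `polarity`, then one numeric column
#' of peak areas per sample.  Feature ids carry a polarity prefix
#' (`P`/`N` for positive/negative ionization).
#'
#' @param path File path (comma- or tab-delimited, with header).
#' @return A feature-table tibble.
#' @export
read_feature_table <- function(path) {
  df <- readr::read_delim(path, show_col_types = FALSE, trim_ws = TRUE)
  validate_feature_table(df)
  df
}

#' Write a feature table back to delimited text
#'
#' @param features Feature-table tibble.
#' @param path Output path (`.csv` or `.tsv` by extension; default CSV).
#' @return `path`, invisibly.
#' @export
write_feature_table <- function(features, path) {
  validate_feature_table(features)
  if (grepl("\\.tsv$", path)) readr::write_tsv(features, path)
  else readr::write_csv(features, path)
  invisible(path)
}

feature_meta_cols <- c("feature_id", "mz", "rt_min", "polarity")

validate_feature_table <- function(features) {
  if (!is.data.frame(features) || !all(feature_meta_cols %in% names(features))) {
    stop_data("feature table needs columns %s plus one area column per sample.",
              paste(feature_meta_cols, collapse = ", "))
  }
  if (anyDuplicated(features$feature_id)) stop_data("duplicate feature_id values.")
  if (any(features$mz <= 0)) stop_data("all m/z values must be > 0.")
  if (any(features$rt_min < 0)) stop_data("retention times must be >= 0.")
  if (!all(features$polarity %in% c("positive", "negative", "P", "N"))) {
    stop_data("polarity must be 'positive'/'negative' (or 'P'/'N').")
  }
  invisible(features)
}

feature_sample_ids <- function(features) {
  setdiff(names(features), feature_meta_cols)
}

#' Remove features detected in solvent blanks
#'
#' Drops every feature whose peak area exceeds `threshold` in any of the
#' blank injections, then removes the blank columns themselves -- the
#' standard curation step applied after gap filling, before any statistics.
#'
#' @param features Feature-table tibble.
#' @param blank_ids Character vector of blank sample ids (columns of
#'   `features`). Empty vector leaves the table untouched.
#' @param threshold Area above which a blank detection counts (default 0:
#'   any signal in a blank removes the feature).
#' @return Curated feature-table tibble without the blank columns.
#' @export
remove_blank_features <- function(features, blank_ids, threshold = 0) {
  validate_feature_table(features)
  blank_ids <- as.character(blank_ids %||% character())
  if (!length(blank_ids)) return(features)
  missing <- setdiff(blank_ids, feature_sample_ids(features))
  if (length(missing)) {
    stop_data("unknown blank id(s): %s", paste(missing, collapse = ", "))
  }
  blank_area <- as.matrix(features[, blank_ids, drop = FALSE])
  keep <- apply(blank_area, 1L, function(a) all(a <= threshold))
  features[keep, setdiff(names(features), blank_ids), drop = FALSE]
}

#' QC check against an external standard
#'
#' Verifies that the feature table contains the external standard within a
#' retention-time window and an m/z tolerance.  Defaults are the reserpine
#' check used to quality-control retention-time migration (11.38 +/- 0.2 min,
#' m/z 609.2794 `[M+H]+`, 3 ppm).
#'
#' @param features Feature-table tibble.
#' @param expected_rt,rt_tol Retention window (min).
#' @param expected_mz Expected standard m/z (Th).
#' @param mz_tol_ppm m/z tolerance (ppm).
#' @return A one-row tibble report: `pass`, `n_matches`, plus the nearest
#'   candidate's `feature_id`, `mz`, `rt_min`, `ppm_error`, `rt_error` (NA
#'   when the table is empty).
#' @export
qc_check_standard <- function(features, expected_rt = 11.38, rt_tol = 0.2,
                              expected_mz = 609.2794, mz_tol_ppm = 3) {
  validate_feature_table(features)
  if (!nrow(features)) {
    return(tibble(pass = FALSE, n_matches = 0L, feature_id = NA_character_,
                  mz = NA_real_, rt_min = NA_real_, ppm_error = NA_real_,
                  rt_error = NA_real_))
  }
  dppm <- ppm_error(features$mz, expected_mz)
  drt <- features$rt_min - expected_rt
  hit <- abs(dppm) <= mz_tol_ppm & abs(drt) <= rt_tol
  # nearest candidate: normalized joint distance over both windows
  score <- sqrt((dppm / mz_tol_ppm)^2 + (drt / rt_tol)^2)
  i <- which.min(score)
  tibble(pass = any(hit), n_matches = sum(hit),
         feature_id = features$feature_id[i], mz = features$mz[i],
         rt_min = features$rt_min[i], ppm_error = dppm[i], rt_error = drt[i])
}

#' Read a compound library for dereplication
#'
#' Delimited text with columns `name`, `formula` (optional if `neutral_mass`
#' given), `neutral_mass` (optional if `formula` given) and `taxon` (tags
#' such as genus/family, `;`-separated).
#'
#' @param path File path.
#' @return Library tibble.
#' @export
read_compound_library <- function(path) {
  df <- readr::read_delim(path, show_col_types = FALSE, trim_ws = TRUE)
  if (!"name" %in% names(df)) stop_data("library needs a `name` column.")
  if (!"formula" %in% names(df)) df$formula <- NA_character_
  if (!"neutral_mass" %in% names(df)) df$neutral_mass <- NA_real_
  if (!"taxon" %in% names(df)) df$taxon <- NA_character_
  df
}

#' Dereplicate features against a compound library
#'
#' For every feature, computes the theoretical m/z of each library compound
#' under the feature's polarity's default adduct (`[M+H]+` for positive,
#' `[M-H]-` for negative) and emits all matches within `tol_ppm`.  Matching
#' by accurate mass against a database without orthogonal evidence is a
#' putative, class-level identification, so annotations are labelled
#' `"Level 3"`.
#'
#' @param features Feature-table tibble.
#' @param library Library tibble (see [read_compound_library()]); entries
#'   with a `formula` have their neutral mass computed, entries with neither
#'   formula nor `neutral_mass` are skipped with a warning.
#' @param tol_ppm Mass tolerance in ppm (default 3).
#' @param taxon_filter Optional character vector of taxon tags; restricts the
#'   candidate library to entries whose `taxon` field contains any tag.
#' @return Annotation tibble: `feature_id`, `mz`, `adduct`, `compound`,
#'   `formula`, `theoretical_mz`, `ppm_error`, `level`.
#' @export
dereplicate <- function(features, library, tol_ppm = 3, taxon_filter = NULL) {
  validate_feature_table(features)
  lib <- as_tibble(library)
  if (!nrow(lib)) return(empty_annotation_tibble())
  if (!"neutral_mass" %in% names(lib)) lib$neutral_mass <- NA_real_
  if (!"formula" %in% names(lib)) lib$formula <- NA_character_
  if (!is.null(taxon_filter) && "taxon" %in% names(lib)) {
    pat <- paste(taxon_filter, collapse = "|")
    lib <- lib[!is.na(lib$taxon) & grepl(pat, lib$taxon, ignore.case = TRUE), ,
               drop = FALSE]
  }
  if (!nrow(lib)) return(empty_annotation_tibble())

  mass <- lib$neutral_mass
  needs <- is.na(mass)
  mass[needs] <- vapply(lib$formula[needs], function(f) {
    if (is.na(f) || !nzchar(f)) NA_real_ else monoisotopic_mass(f)
  }, numeric(1))
  skipped <- is.na(mass)
  if (any(skipped)) {
    warn(sprintf("skipping %d library entr%s with neither mass nor formula: %s",
                 sum(skipped), if (sum(skipped) == 1) "y" else "ies",
                 paste(head(lib$name[skipped], 5L), collapse = ", ")))
    lib <- lib[!skipped, , drop = FALSE]
    mass <- mass[!skipped]
  }
  if (!nrow(lib) || !nrow(features)) return(empty_annotation_tibble())

  out <- lapply(seq_len(nrow(features)), function(i) {
    adduct <- default_adduct(features$polarity[i])
    theo <- mass + if (adduct == "[M+H]+") PROTON_MASS else -PROTON_MASS
    err <- ppm_error(features$mz[i], theo)
    hit <- which(abs(err) <= tol_ppm)
    if (!length(hit)) return(NULL)
    tibble(feature_id = features$feature_id[i], mz = features$mz[i],
           adduct = adduct, compound = lib$name[hit],
           formula = lib$formula[hit], theoretical_mz = theo[hit],
           ppm_error = err[hit], level = "Level 3")
  })
  out <- bind_rows(out)
  if (!nrow(out)) return(empty_annotation_tibble())
  arrange(out, .data$feature_id, abs(.data$ppm_error))
}

empty_annotation_tibble <- function() {
  tibble(feature_id = character(), mz = numeric(), adduct = character(),
         compound = character(), formula = character(),
         theoretical_mz = numeric(), ppm_error = numeric(), level = character())
}
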