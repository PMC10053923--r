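# Synthetic seasonal-study generator.
#
# Emulates a seasonal plant-harvest metabolomics design: samples from the
# four seasons (SPR/SUM/AUT/WIN), each yielding a 1D J-res NMR projection
# and a column of an aligned LC-MS feature table.  A configurable number of
# "planted" discriminant variables per block carry a monotone seasonal
# trend -- triterpene-like signals (aliphatic shifts, 0.5-3.1 ppm; heavy
# late-eluting MS features) rising from spring to winter, and C-glycosyl
# flavone-like signals (aromatic shifts, 6.5-8.0 ppm; flavone-mass MS
# features) rising from winter to spring.  All other variables are
# season-independent.  Ground truth is returned so downstream selection can
# be scored for recall and false positives.

SEASONS <- c("SPR", "SUM", "AUT", "WIN")

#' Define a synthetic seasonal-study design
#'
#' @param n_seasons Number of seasons (currently fixed at 4: SPR, SUM, AUT,
#'   WIN).
#' @param harvests_per_season Independent harvests per season (default 3).
#' @param replicates_per_harvest Replicate extracts per harvest (default 3).
#' @param n_nmr_points Points on the ppm axis of each projection
#'   (default 2700, i.e. 12 points per 0.04 ppm bucket over 0-9 ppm).
#' @param ppm_range Chemical-shift window, low then high (default c(0, 9)).
#' @param n_ms_features Number of aligned LC-MS features (default 90).
#' @param n_discriminant_features Planted discriminant variables per block
#'   (default 5; split as evenly as possible between the triterpene-like and
#'   flavone-like patterns).
#' @param effect_size Multiplicative fold change of a planted variable's
#'   mean between its lowest and highest season (default 4; 1 = null study).
#' @param noise_cv Coefficient of variation of the multiplicative log-normal
#'   intensity noise (default 0.2).
#' @param seed Integer RNG seed; a fixed seed makes the whole study
#'   bit-reproducible.
#' @return A `study_design` list, validated.
#' @export
study_design <- function(n_seasons = 4, harvests_per_season = 3,
                         replicates_per_harvest = 3, n_nmr_points = 2700,
                         ppm_range = c(0, 9), n_ms_features = 90,
                         n_discriminant_features = 5, effect_size = 4,
                         noise_cv = 0.2, seed = 1) {
  n_seasons <- check_count(n_seasons, "n_seasons")
  if (n_seasons != 4L) {
    stop_config("n_seasons must be 4 (SPR/SUM/AUT/WIN); got %d.", n_seasons)
  }
  design <- list(
    n_seasons = n_seasons,
    harvests_per_season = check_count(harvests_per_season, "harvests_per_season"),
    replicates_per_harvest = check_count(replicates_per_harvest,
                                         "replicates_per_harvest"),
    n_nmr_points = check_count(n_nmr_points, "n_nmr_points", min = 10L),
    ppm_range = ppm_range,
    n_ms_features = check_count(n_ms_features, "n_ms_features"),
    n_discriminant_features = check_count(n_discriminant_features,
                                          "n_discriminant_features", min = 0L),
    effect_size = check_number(effect_size, "effect_size", min = 1),
    noise_cv = check_number(noise_cv, "noise_cv", min = 0),
    seed = check_count(seed, "seed", min = 0L)
  )
  if (length(ppm_range) != 2L || !is.numeric(ppm_range) ||
      ppm_range[1L] >= ppm_range[2L]) {
    stop_config("`ppm_range` must be c(lo, hi) with lo < hi.")
  }
  structure(design, class = "study_design")
}

#' @export
print.study_design <- function(x, ...) {
  n <- x$n_seasons * x$harvests_per_season * x$replicates_per_harvest
  cat(sprintf(paste0("<study_design> %d seasons x %d harvests x %d replicates",
                     " = %d samples\n"),
              x$n_seasons, x$harvests_per_season, x$replicates_per_harvest, n))
  cat(sprintf("  NMR: %d points over %.1f-%.1f ppm; MS: %d features\n",
              x$n_nmr_points, x$ppm_range[1L], x$ppm_range[2L], x$n_ms_features))
  cat(sprintf("  planted: %d per block, effect size %.2g, noise CV %.2g, seed %d\n",
              x$n_discriminant_features, x$effect_size, x$noise_cv, x$seed))
  invisible(x)
}

# log-normal multiplicative noise with a given coefficient of variation and
# unit expectation
rlnorm_cv <- function(n, cv) {
  if (cv == 0) return(rep(1, n))
  sdlog <- sqrt(log(1 + cv^2))
  rlnorm(n, meanlog = -sdlog^2 / 2, sdlog = sdlog)
}

# Seasonal mean multiplier, geometric ramp across season order.
# direction +1: rises SPR -> WIN (triterpene-like); -1: rises WIN -> SPR
# (flavone-like).
season_multiplier <- function(effect_size, direction) {
  ramp <- effect_size^(seq(0, 1, length.out = length(SEASONS)))
  if (direction < 0) ramp <- rev(ramp)
  setNames(ramp, SEASONS)
}

#' Synthesize a 1D projection spectrum from a peak list
#'
#' Sums Lorentzian lines (the natural NMR line shape)
#' \eqn{h \gamma^2 / ((\delta - \delta_0)^2 + \gamma^2)} over a ppm grid and
#' adds non-negative baseline noise.
#'
#' @param peaks Data frame with columns `ppm` (center), `height`, `width`
#'   (half width at half maximum, ppm); may have zero rows.
#' @param axis Numeric ppm grid.
#' @param noise Standard deviation of the half-normal baseline noise
#'   (default 0 = noiseless).
#' @return Tibble `ppm`, `intensity`.
#' @export
generate_projection <- function(peaks, axis, noise = 0) {
  if (!is.numeric(axis) || !length(axis)) stop_config("`axis` must be a numeric grid.")
  if (is.null(peaks) || !nrow(as.data.frame(peaks))) {
    y <- rep(0, length(axis))
  } else {
    peaks <- as.data.frame(peaks)
    if (!all(c("ppm", "height", "width") %in% names(peaks))) {
      stop_config("`peaks` needs columns ppm, height, width.")
    }
    if (any(peaks$width <= 0)) stop_config("peak widths must be > 0.")
    rng <- range(axis)
    out <- peaks$ppm < rng[1L] | peaks$ppm > rng[2L]
    if (any(out)) {
      stop_config("peak center(s) outside the axis range: %s",
                  paste(format(peaks$ppm[out]), collapse = ", "))
    }
    y <- rep(0, length(axis))
    for (i in seq_len(nrow(peaks))) {
      g2 <- peaks$width[i]^2
      y <- y + peaks$height[i] * g2 / ((axis - peaks$ppm[i])^2 + g2)
    }
  }
  if (noise > 0) y <- y + abs(rnorm(length(axis), sd = noise))
  tibble(ppm = axis, intensity = y)
}

#' Generate a complete synthetic seasonal study
#'
#' Produces, from one seeded RNG stream, all inputs the analysis pipeline
#' consumes: per-sample NMR projections, an aligned LC-MS feature table
#' (positive and negative polarity features with accurate masses drawn from
#' a built-in compound list for the planted features), sample metadata with
#' season classes and seasonally varying climate covariates, and the ground
#' truth of planted discriminants.
#'
#' @param design A [study_design()].
#' @return A `synthetic_study` list: `projections` (long tibble `sample_id`,
#'   `ppm`, `intensity`), `features` (feature-table tibble), `metadata`
#'   (tibble `sample_id`, `season`, `harvest`, `replicate`, `temperature`,
#'   `radiation`, `humidity`, `rainfall`), `truth` (list with
#'   `discriminants` tibble and `season_profiles` tibble), `design`.
#' @export
generate_study <- function(design) {
  if (!inherits(design, "study_design")) design <- do.call(study_design, design)
  set.seed(design$seed)

  seasons <- SEASONS
  meta <- tidyr::expand_grid(season = factor(seasons, levels = seasons),
                             harvest = seq_len(design$harvests_per_season),
                             replicate = seq_len(design$replicates_per_harvest))
  meta <- mutate(meta,
                 sample_id = sprintf("%s_h%d_r%d", .data$season,
                                     .data$harvest, .data$replicate))
  n <- nrow(meta)
  climate <- list(  # season-typical values for a humid subtropical coast
    temperature = c(SPR = 22, SUM = 27, AUT = 21, WIN = 18),
    radiation = c(SPR = 15000, SUM = 18000, AUT = 12000, WIN = 10000),
    humidity = c(SPR = 82, SUM = 80, AUT = 78, WIN = 75),
    rainfall = c(SPR = 220, SUM = 240, AUT = 120, WIN = 60)
  )
  for (cv in names(climate)) {
    base <- climate[[cv]][as.character(meta$season)]
    meta[[cv]] <- round(base * rlnorm_cv(n, 0.05), 1)
  }
  meta <- meta[, c("sample_id", "season", "harvest", "replicate",
                   names(climate))]

  lo <- design$ppm_range[1L]; hi <- design$ppm_range[2L]
  axis <- seq(lo, hi, length.out = design$n_nmr_points)
  bwidth <- 0.04

  # candidate planted bucket centers inside each shift region
  planted_nmr <- plant_nmr_peaks(design, lo, hi, bwidth)
  background_nmr <- background_nmr_peaks(design, lo, hi)

  # MS block: planted features take accurate masses of real compound classes,
  # the rest are random masses over the acquisition range
  ms <- plant_ms_features(design)

  season_idx <- as.character(meta$season)
  mult_tri <- season_multiplier(design$effect_size, +1)
  mult_fla <- season_multiplier(design$effect_size, -1)
  mult_for <- function(direction) if (direction > 0) mult_tri else mult_fla

  # --- NMR projections -------------------------------------------------
  projections <- vector("list", n)
  for (i in seq_len(n)) {
    s <- season_idx[i]
    bg_heights <- background_nmr$height * rlnorm_cv(nrow(background_nmr),
                                                    design$noise_cv)
    pl_heights <- vapply(seq_len(nrow(planted_nmr)), function(j) {
      planted_nmr$height[j] * mult_for(planted_nmr$direction[j])[[s]]
    }, numeric(1)) * rlnorm_cv(nrow(planted_nmr), design$noise_cv)
    peaks <- rbind(
      data.frame(ppm = background_nmr$ppm, height = bg_heights,
                 width = background_nmr$width),
      data.frame(ppm = planted_nmr$ppm, height = pl_heights,
                 width = planted_nmr$width)
    )
    proj <- generate_projection(peaks, axis, noise = 0.002)
    projections[[i]] <- bind_cols(tibble(sample_id = meta$sample_id[i]), proj)
  }
  projections <- bind_rows(projections)

  # --- MS feature areas ------------------------------------------------
  areas <- matrix(0, nrow(ms), n,
                  dimnames = list(ms$feature_id, meta$sample_id))
  for (i in seq_len(n)) {
    s <- season_idx[i]
    mult <- ifelse(ms$direction == 0, 1,
                   vapply(ms$direction, function(d) {
                     if (d == 0) 1 else mult_for(d)[[s]]
                   }, numeric(1)))
    areas[, i] <- ms$base_area * mult * rlnorm_cv(nrow(ms), design$noise_cv)
  }
  features <- bind_cols(
    tibble(feature_id = ms$feature_id, mz = ms$mz, rt_min = ms$rt_min,
           polarity = ms$polarity),
    as_tibble(areas)
  )

  truth <- build_truth(design, planted_nmr, ms, lo, hi, bwidth)

  structure(list(projections = projections, features = features,
                 metadata = meta, truth = truth, design = design),
            class = "synthetic_study")
}

# Planted NMR peaks: one per discriminant, centered mid-bucket so each maps
# cleanly to a single 0.04 ppm bin.  Triterpene-like region 0.5-3.1 ppm
# (rising to winter), flavone-like region 6.5-8.0 ppm (rising to spring).
plant_nmr_peaks <- function(design, lo, hi, bwidth) {
  k <- design$n_discriminant_features
  if (k == 0L) {
    return(data.frame(ppm = numeric(), height = numeric(), width = numeric(),
                      direction = numeric(), bin_label = character()))
  }
  n_tri <- ceiling(k / 2); n_fla <- k - n_tri
  centers_in <- function(a, b) {
    idx <- which(bin_edges(lo, hi, bwidth) >= a &
                   bin_edges(lo, hi, bwidth) + bwidth <= b)
    lo + (idx - 1) * bwidth + bwidth / 2
  }
  tri_pool <- centers_in(0.5, 3.1)
  fla_pool <- centers_in(6.5, 8.0)
  tri <- sort(sample(tri_pool, n_tri))
  fla <- sort(sample(fla_pool, max(n_fla, 0)))
  edges <- bin_edges(lo, hi, bwidth)
  label_of <- function(p) {
    b <- findInterval(p, edges, rightmost.closed = TRUE)
    bin_labels(edges)[b]
  }
  data.frame(
    ppm = c(tri, fla),
    height = stats::runif(n_tri + n_fla, 0.8, 1.6),
    width = 0.006,
    direction = c(rep(1, n_tri), rep(-1, n_fla)),
    bin_label = vapply(c(tri, fla), label_of, character(1))
  )
}

# Season-independent background spectrum: aliphatic, carbohydrate and
# aromatic signals common to all samples.
background_nmr_peaks <- function(design, lo, hi) {
  n_bg <- 30L
  region <- sample(c("ali", "sug", "aro"), n_bg, replace = TRUE,
                   prob = c(0.3, 0.45, 0.25))
  ppm <- vapply(region, function(r) {
    switch(r, ali = stats::runif(1, 0.6, 2.9), sug = stats::runif(1, 3.1, 5.6),
           aro = stats::runif(1, 6.1, 8.6))
  }, numeric(1))
  data.frame(ppm = pmin(pmax(ppm, lo + 0.1), hi - 0.1),
             height = stats::runif(n_bg, 0.3, 2.5),
             width = stats::runif(n_bg, 0.004, 0.01))
}

# Built-in accurate masses for planted MS features (triterpene- and
# C-glycosyl-flavone-class formulas typical of tannin-rich leaf extracts).
PLANT_MS_FORMULAS <- list(
  triterpene = c("C30H48O4", "C30H48O5", "C30H48O6", "C30H46O5", "C30H44O3",
                 "C30H48O3"),
  flavone = c("C21H20O10", "C21H20O11", "C28H24O14", "C28H24O15", "C27H30O15",
              "C26H28O14")
)

plant_ms_features <- function(design) {
  p <- design$n_ms_features
  k <- min(design$n_discriminant_features, p)
  n_tri <- ceiling(k / 2); n_fla <- k - n_tri

  direction <- rep(0, p)
  if (k > 0) direction[seq_len(k)] <- c(rep(1, n_tri), rep(-1, n_fla))

  polarity <- character(p); mz <- numeric(p); rt <- numeric(p)
  for (i in seq_len(p)) {
    if (direction[i] > 0) {
      f <- sample(PLANT_MS_FORMULAS$triterpene, 1L)
      polarity[i] <- sample(c("positive", "negative"), 1L)
      rt[i] <- stats::runif(1, 15, 24)       # late-eluting apolar triterpenes
    } else if (direction[i] < 0) {
      f <- sample(PLANT_MS_FORMULAS$flavone, 1L)
      polarity[i] <- "positive"
      rt[i] <- stats::runif(1, 6, 9)
    } else {
      f <- NA_character_
      polarity[i] <- sample(c("positive", "negative"), 1L)
      rt[i] <- stats::runif(1, 1, 30)
    }
    if (is.na(f)) {
      mz[i] <- stats::runif(1, 150, 1200)
    } else {
      adduct <- default_adduct(polarity[i])
      # small instrument-like mass error, well inside the 3 ppm gate
      mz[i] <- adduct_mz(monoisotopic_mass(f), adduct) *
        (1 + rnorm(1, sd = 0.4) * 1e-6)
    }
  }
  # one non-discriminant slot carries the external standard (retention-time
  # QC expects it at 11.38 min, m/z 609.2794 [M+H]+)
  std <- which(direction == 0)
  if (length(std)) {
    i <- std[length(std)]
    polarity[i] <- "positive"; mz[i] <- 609.2794; rt[i] <- 11.38
  }
  prefix <- ifelse(polarity == "positive", "P", "N")
  data.frame(
    feature_id = sprintf("%s%04d", prefix, seq_len(p)),
    mz = round(mz, 4), rt_min = round(rt, 2), polarity = polarity,
    base_area = rlnorm(p, meanlog = log(1e6), sdlog = 1),
    direction = direction
  )
}

build_truth <- function(design, planted_nmr, ms, lo, hi, bwidth) {
  prof <- function(direction) {
    season_multiplier(design$effect_size, direction)
  }
  nmr_tr <- tibble(
    variable_id = planted_nmr$bin_label,
    block = "NMR",
    direction = ifelse(planted_nmr$direction > 0, "triterpene-like",
                       "flavone-like")
  )
  ms_planted <- ms[ms$direction != 0, , drop = FALSE]
  ms_tr <- tibble(
    variable_id = ms_planted$feature_id,
    block = "MS",
    direction = ifelse(ms_planted$direction > 0, "triterpene-like",
                       "flavone-like")
  )
  disc <- bind_rows(nmr_tr, ms_tr)
  profiles <- bind_rows(lapply(seq_len(nrow(disc)), function(i) {
    d <- if (disc$direction[i] == "triterpene-like") 1 else -1
    tibble(variable_id = disc$variable_id[i], season = SEASONS,
           multiplier = unname(prof(d)[SEASONS]))
  }))
  list(discriminants = disc, season_profiles = profiles)
}

#' @export
print.synthetic_study <- function(x, ...) {
  cat(sprintf("<synthetic_study> %d samples, %d MS features, %d planted discriminants\n",
              nrow(x$metadata), nrow(x$features),
              nrow(x$truth$discriminants)))
  invisible(x)
}

#' Write a synthetic study to disk in the pipeline's input formats
#'
#' Emits per-sample two-column projection files plus a manifest, the
#' feature-table CSV, the metadata CSV, and a JSON ground-truth sidecar.
#'
#' @param study A `synthetic_study`.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_study <- function(study, dir) {
  stopifnot(inherits(study, "synthetic_study"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  nmr_dir <- file.path(dir, "nmr")
  dir.create(nmr_dir, showWarnings = FALSE)
  ids <- unique(study$projections$sample_id)
  paths <- file.path("nmr", paste0(ids, ".tsv"))
  for (i in seq_along(ids)) {
    one <- study$projections[study$projections$sample_id == ids[i],
                             c("ppm", "intensity")]
    readr::write_tsv(one, file.path(dir, paths[i]))
  }
  readr::write_csv(tibble(sample_id = ids, path = paths),
                   file.path(dir, "nmr_manifest.csv"))
  write_feature_table(study$features, file.path(dir, "features.csv"))
  readr::write_csv(study$metadata, file.path(dir, "metadata.csv"))
  jsonlite::write_json(
    list(discriminants = study$truth$discriminants,
         season_profiles = study$truth$season_profiles),
    file.path(dir, "ground_truth.json"), dataframe = "rows", digits = NA
  )
  invisible(dir)
}
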