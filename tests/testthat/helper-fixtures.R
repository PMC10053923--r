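# Fixture builders shared across the suite.  Everything is generated in code
# under fixed seeds; no data files.

# Small two-block study used when the full default design would be overkill.
small_study <- function(seed = 1, effect_size = 4, noise_cv = 0.2,
                        harvests = 2, reps = 2, n_nmr_points = 1200,
                        n_ms_features = 30, n_disc = 3) {
  generate_study(study_design(
    harvests_per_season = harvests, replicates_per_harvest = reps,
    n_nmr_points = n_nmr_points, n_ms_features = n_ms_features,
    n_discriminant_features = n_disc, effect_size = effect_size,
    noise_cv = noise_cv, seed = seed
  ))
}

# Class-structured matrix: `per_class` samples per class, `p` variables of
# which the first `n_signal` carry a class-mean shift of size `delta`.
classed_matrix <- function(per_class = 5, p = 8, n_signal = 2, delta = 3,
                           classes = c("A", "B"), seed = 1) {
  withr::with_seed(seed, {
    n <- per_class * length(classes)
    cls <- factor(rep(classes, each = per_class))
    X <- matrix(rnorm(n * p), n, p,
                dimnames = list(paste0("S", 1:n), paste0("V", 1:p)))
    for (j in seq_len(n_signal)) {
      X[, j] <- X[, j] + delta * (as.integer(cls) - mean(as.integer(cls)))
    }
    list(X = scale(X, scale = FALSE), classes = cls)
  })
}

# Random sample_id-first intensity block, n samples x p variables.
matrix_block <- function(n, p, prefix = "v") {
  m <- matrix(rexp(n * p), n, p)
  colnames(m) <- paste0(prefix, seq_len(p))
  dplyr::bind_cols(tibble::tibble(sample_id = paste0("S", seq_len(n))),
                   tibble::as_tibble(m))
}

# Toy MZmine-style feature table with named sample area columns.
toy_feature_table <- function() {
  tibble::tibble(
    feature_id = c("P001", "P002", "N003", "N004", "P005"),
    mz = c(433.1129, 609.2794, 300.9996, 1083.0620, 489.3575),
    rt_min = c(7.67, 11.38, 3.2, 5.1, 17.41),
    polarity = c("positive", "positive", "negative", "negative", "positive"),
    S1 = c(10, 20, 30, 40, 50),
    S2 = c(11, 21, 31, 41, 51),
    blankA = c(0, 0, 5, 0, 0),
    blankB = c(0, 3, 0, 0, 0)
  )
}

# Independent brute-force bucketing oracle: per-point membership scan.
brute_force_bins <- function(ppm, intensity, lo, hi, width, agg = "mean") {
  nb_real <- (hi - lo) / width
  nb <- if (abs(nb_real - round(nb_real)) < 1e-8) round(nb_real) else ceiling(nb_real)
  vals <- numeric(nb)
  for (b in seq_len(nb)) {
    a <- lo + (b - 1) * width
    z <- lo + b * width
    inb <- if (b == nb) ppm >= a & ppm <= max(z, hi) else ppm >= a & ppm < z
    if (any(inb)) {
      vals[b] <- if (agg == "mean") mean(intensity[inb]) else sum(intensity[inb])
    }
  }
  vals
}
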