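test_that("the design arithmetic propagates to every output object", {
  st <- generate_study(study_design(harvests_per_season = 3,
                                    replicates_per_harvest = 3,
                                    n_nmr_points = 600, n_ms_features = 20,
                                    seed = 1))
  n <- 4 * 3 * 3
  expect_equal(nrow(st$metadata), n)
  expect_equal(length(unique(st$projections$sample_id)), n)
  expect_equal(length(fusemet:::feature_sample_ids(st$features)), n)
  expect_equal(nrow(st$features), 20)
  # planted ids exist in the generated data
  truth <- st$truth$discriminants
  binned <- stack_binned(st$projections, width = 0.04)
  expect_true(all(truth$variable_id[truth$block == "NMR"] %in% names(binned)))
  expect_true(all(truth$variable_id[truth$block == "MS"] %in%
                    st$features$feature_id))
})

test_that("a fixed seed makes the study bit-reproducible", {
  d <- study_design(n_nmr_points = 500, n_ms_features = 15, seed = 99)
  a <- generate_study(d)
  b <- generate_study(d)
  expect_identical(a$projections, b$projections)
  expect_identical(a$features, b$features)
  expect_identical(a$metadata, b$metadata)
  expect_identical(a$truth, b$truth)
  c <- generate_study(study_design(n_nmr_points = 500, n_ms_features = 15,
                                   seed = 100))
  expect_false(identical(a$features, c$features))
})

test_that("null designs are flat; planted effects hit the stated fold change", {
  null <- generate_study(study_design(effect_size = 1, n_nmr_points = 500,
                                      n_ms_features = 15, seed = 2))
  expect_true(all(null$truth$season_profiles$multiplier == 1))

  st <- generate_study(study_design(effect_size = 4, noise_cv = 0.2, seed = 1))
  truth <- st$truth
  # profiles strictly ordered between the extreme seasons
  prof <- tidyr::pivot_wider(truth$season_profiles, names_from = "season",
                             values_from = "multiplier")
  expect_true(all(prof$WIN / prof$SPR == 4 | prof$SPR / prof$WIN == 4))

  # oracle: recompute per-variable season means directly from emitted tables
  season_of <- setNames(as.character(st$metadata$season), st$metadata$sample_id)
  binned <- stack_binned(st$projections)
  for (i in seq_len(nrow(truth$discriminants))) {
    tr <- truth$discriminants[i, ]
    vals <- if (tr$block == "NMR") {
      setNames(binned[[tr$variable_id]], binned$sample_id)
    } else {
      row <- st$features[st$features$feature_id == tr$variable_id, ]
      unlist(row[fusemet:::feature_sample_ids(st$features)])
    }
    hi <- if (tr$direction == "triterpene-like") "WIN" else "SPR"
    lo <- if (hi == "WIN") "SPR" else "WIN"
    ratio <- mean(vals[season_of[names(vals)] == hi]) /
      mean(vals[season_of[names(vals)] == lo])
    expect_gte(ratio, 2)
    expect_lte(ratio, 8)
  }
})

test_that("projection synthesis is Lorentzian, additive and guarded", {
  axis <- seq(0, 9, by = 0.01)
  # no peaks, no noise: all zero
  expect_true(all(generate_projection(NULL, axis)$intensity == 0))
  # single on-grid peak: apex equals the height at the nearest grid point
  pk <- data.frame(ppm = 3.5, height = 7, width = 0.02)
  one <- generate_projection(pk, axis)
  expect_equal(max(one$intensity), 7)
  expect_equal(axis[which.max(one$intensity)], 3.5)
  # additivity of integrals of disjoint peaks
  skip_if_not_installed("pracma")
  p1 <- data.frame(ppm = 2, height = 3, width = 0.01)
  p2 <- data.frame(ppm = 7, height = 5, width = 0.02)
  both <- generate_projection(rbind(p1, p2), axis)
  a1 <- pracma::trapz(axis, generate_projection(p1, axis)$intensity)
  a2 <- pracma::trapz(axis, generate_projection(p2, axis)$intensity)
  expect_equal(pracma::trapz(axis, both$intensity), a1 + a2, tolerance = 1e-9)
  # peaks outside the axis are rejected
  expect_error(generate_projection(data.frame(ppm = 10, height = 1, width = 0.01),
                                   axis), class = "fusemet_config_error")
  expect_error(generate_projection(data.frame(ppm = 1, height = 1, width = 0),
                                   axis), class = "fusemet_config_error")
})

test_that("invalid designs name the offending field", {
  expect_error(study_design(effect_size = 0.5), "effect_size")
  expect_error(study_design(harvests_per_season = 0), "harvests_per_season")
  expect_error(study_design(ppm_range = c(9, 0)), "ppm_range")
  expect_error(study_design(noise_cv = -1), "noise_cv")
})

test_that("studies are written in the formats the loading path reads", {
  st <- small_study(seed = 5, n_nmr_points = 400, n_ms_features = 10)
  dir <- withr::local_tempdir()
  write_study(st, dir)
  spectra <- read_projection_manifest(file.path(dir, "nmr_manifest.csv"))
  expect_setequal(unique(spectra$sample_id), st$metadata$sample_id)
  feats <- read_feature_table(file.path(dir, "features.csv"))
  expect_equal(feats$feature_id, st$features$feature_id)
  truth <- jsonlite::read_json(file.path(dir, "ground_truth.json"),
                               simplifyVector = TRUE)
  expect_setequal(truth$discriminants$variable_id,
                  st$truth$discriminants$variable_id)
})
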