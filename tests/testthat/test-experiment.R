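# Small, fast experiment settings shared by the tests below: short records at
# a reduced sampling rate keep each full pipeline run in seconds.
tiny_subjects <- function() {
  ps <- subject_presets()[c("A", "B")]
  ps$A$heart_rate_bpm <- 72
  ps$B$heart_rate_bpm <- 75
  ps
}

tiny_config <- function(seed = 2) {
  experiment_config(subjects = tiny_subjects(), n_cal = 6, n_val = 3,
                    duration_s = 6, fs = 2000, seed = seed, k_max = 4)
}

test_that("data-set summaries reproduce per-subject and pooled statistics", {
  refs <- tibble::tibble(
    subject_id = rep(c("A", "B", "C"), each = 50),
    reference_bp_mmHg = c(111.3 + c(rep(-6, 25), rep(6, 25)),
                          123.1 + c(rep(-5, 25), rep(5, 25)),
                          100.9 + c(rep(-4, 25), rep(4, 25)))
  )
  s <- summarize_datasets(refs)
  expect_equal(s$subject, c("A", "B", "C", "Overall"))
  expect_equal(s$n, c(50, 50, 50, 150))
  expect_equal(s$mean_mmHg[1:3], c(111.3, 123.1, 100.9))
  # the pooled mean of the three balanced subjects, printed to one decimal
  expect_equal(round(s$mean_mmHg[4], 1), 111.8)
  # pooled extrema are the extrema of the per-subject extrema
  expect_equal(s$max_mmHg[4], max(s$max_mmHg[1:3]))
  expect_equal(s$min_mmHg[4], min(s$min_mmHg[1:3]))

  one <- summarize_datasets(refs[refs$subject_id == "A", ])
  expect_equal(one$n, c(50, 50))
  expect_equal(one$mean_mmHg[2], one$mean_mmHg[1])

  expect_error(summarize_datasets(refs[0, ]), class = "fbgbp_invalid_input")
})

test_that("individual curves produce one finite result row per subject", {
  bd <- simulate_beat_data(tiny_subjects(), n_cal = 6, n_val = 3,
                           duration_s = 6, fs = 2000, seed = 2)
  ind <- run_individual(bd, k_max = 3)
  expect_equal(nrow(ind$results), 2)
  expect_true(all(is.finite(ind$results$sep_mmHg)))
  expect_true(all(ind$results$sep_mmHg > 0))
  expect_true(all(ind$results$k >= 1))
  expect_equal(nrow(ind$predictions), 6)

  # permuting record order leaves the results unchanged
  bd_perm <- bd[withr::with_seed(1, sample(nrow(bd))), ]
  ind2 <- run_individual(bd_perm, k_max = 3)
  expect_equal(ind2$results, ind$results, tolerance = 1e-9)

  # a subject without a validation split is refused
  broken <- bd[!(bd$subject_id == "B" & bd$split == "validation"), ]
  expect_error(run_individual(broken), class = "fbgbp_missing_split")
})

test_that("a noiseless, exactly linear subject is recovered almost perfectly", {
  p <- quiet_subject(detector_noise_sd = 0, ref_noise_sd = 0)
  bd <- simulate_beat_data(p, n_cal = 8, n_val = 4, duration_s = 8, fs = 2000,
                           seed = 6)
  # probe the exact-recovery limit at an ample factor count: the remaining
  # error is the (small) nonlinearity of the anchor/min normalization plus
  # beat-interval jitter, well under half a mmHg
  fit <- fit_pls(bd[bd$split == "calibration", ], k = 4)
  ev <- evaluate_model(fit, bd[bd$split == "validation", ])
  expect_lt(ev$sep_mmHg, 0.5)
  expect_gt(ev$r, 0.99)
})

test_that("the overall curve pools subjects and degenerates gracefully to one", {
  bd <- simulate_beat_data(tiny_subjects(), n_cal = 6, n_val = 3,
                           duration_s = 6, fs = 2000, seed = 2)
  ov <- run_overall(bd, k_max = 3)
  pooled_row <- ov$results[ov$results$subject == "Overall", ]
  expect_equal(pooled_row$n, 6)            # pooled validation count
  expect_equal(ov$model$n, 12)             # pooled calibration count
  expect_equal(nrow(ov$results), 3)        # pooled + one row per subject

  # identical twin subjects: the pooled curve matches the individual curves
  twin <- list(A = quiet_subject("A"), A2 = quiet_subject("A2"))
  bd2 <- simulate_beat_data(twin, n_cal = 8, n_val = 4, duration_s = 8,
                            fs = 2000, seed = 3)
  ind2 <- run_individual(bd2, k_max = 3)
  ov2 <- run_overall(bd2, k_max = 3)
  merged <- dplyr::inner_join(
    ind2$predictions, ov2$predictions,
    by = c("subject_id", "record_id", "reference_bp_mmHg")
  )
  expect_lt(max(abs(merged$predicted_bp_mmHg.x - merged$predicted_bp_mmHg.y)), 1)

  one <- bd[bd$subject_id == "A", ]
  expect_error(run_overall(one), class = "fbgbp_invalid_input")
})

test_that("experiment reports are written deterministically and round-trip", {
  cfg <- tiny_config(seed = 2)
  rep1 <- run_experiment(cfg)
  rep2 <- run_experiment(cfg)

  d1 <- withr::local_tempdir()
  d2 <- withr::local_tempdir()
  p1 <- write_report(rep1, d1)
  p2 <- write_report(rep2, d2)
  for (f in names(p1)) {
    expect_identical(readBin(p1[[f]], "raw", file.size(p1[[f]])),
                     readBin(p2[[f]], "raw", file.size(p2[[f]])),
                     label = f)
  }

  # results CSV re-parses to the in-memory table
  res_back <- readr::read_csv(p1[["results"]], show_col_types = FALSE)
  expect_equal(as.data.frame(res_back), as.data.frame(rep1$results),
               tolerance = 1e-12)

  # manifest records the master seed
  manifest <- jsonlite::read_json(p1[["manifest"]])
  expect_equal(manifest$seed, 2)

  # every reported (R, SEP) is recomputable from the emitted predictions
  preds <- readr::read_csv(p1[["predictions"]], show_col_types = FALSE)
  for (i in seq_len(nrow(rep1$results))) {
    row <- rep1$results[i, ]
    sub <- preds[preds$curve == row$curve, ]
    if (row$subject != "Overall") sub <- sub[sub$subject_id == row$subject, ]
    err <- sub$predicted_bp_mmHg - sub$reference_bp_mmHg
    expect_equal(sqrt(sum(err^2) / (nrow(sub) - 1)), row$sep_mmHg,
                 tolerance = 1e-9)
    expect_equal(cor(sub$predicted_bp_mmHg, sub$reference_bp_mmHg), row$r,
                 tolerance = 1e-9)
  }
})

test_that("experiment configs are validated and read back from YAML", {
  expect_error(experiment_config(f_lo = 6, f_hi = 5),
               class = "fbgbp_domain_error")
  expect_error(experiment_config(n_cal = 2), class = "fbgbp_domain_error")

  path <- withr::local_tempfile(fileext = ".yaml")
  yaml::write_yaml(list(
    n_cal = 6, n_val = 3, duration_s = 6, fs = 2000, seed = 9,
    subjects = list(
      S1 = list(bp_mean = 105, bp_sd = 5, heart_rate_bpm = 70),
      S2 = list(bp_mean = 120, bp_sd = 5, heart_rate_bpm = 66)
    )
  ), path)
  cfg <- read_experiment_config(path)
  expect_s3_class(cfg, "experiment_config")
  expect_equal(names(cfg$subjects), c("S1", "S2"))
  expect_equal(cfg$subjects$S1$bp_mean, 105)
  expect_equal(cfg$seed, 9L)
})

test_that("autoplot methods return ggplot objects", {
  fs <- 500
  nb <- average_and_normalize(segment_beats(bump_train(fs, 20, 66), fs = fs))
  expect_s3_class(autoplot(nb), "ggplot")
  withr::with_seed(5, {
    X <- matrix(runif(60), 15, 4)
    y <- 100 + drop(X %*% c(5, -2, 1, 0)) + rnorm(15, 0.2)
    expect_s3_class(autoplot(fit_pls(X, y, k = 1)), "ggplot")
  })
})
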