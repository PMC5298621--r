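# The individual-vs-overall calibration experiment: build one calibration
# curve per subject and one pooled curve, evaluate each on held-out
# validation records, and emit summary/result/prediction tables.

#' Configuration of a calibration experiment
#'
#' Collects the generator settings (subjects, record counts, record length,
#' sampling rate), the beat-standardization settings and the PLS selection
#' settings under a single master seed. Defaults follow the study protocol:
#' 50 calibration and 25 validation records per subject, 20 s records at
#' 10 kHz, 0.5-5 Hz band, beat length 100.
#'
#' @param subjects Named list of [subject_params()]; default
#'   [subject_presets()].
#' @param n_cal,n_val Records per subject and split.
#' @param duration_s,fs Record length (s) and sampling rate (Hz).
#' @param L,anchor_frac Beat standardization, see [average_and_normalize()].
#' @param f_lo,f_hi Band edges, Hz (must satisfy `0 < f_lo < f_hi < fs / 2`).
#' @param alpha,k_max Factor-selection settings, see [select_factors()].
#' @param order Beat averaging order, see [average_and_normalize()].
#' @param seed Master seed for all randomness.
#' @return An object of class `experiment_config`.
#' @export
experiment_config <- function(subjects = subject_presets(),
                              n_cal = 50, n_val = 25,
                              duration_s = 20, fs = 10000,
                              L = 100, anchor_frac = 0.3,
                              f_lo = 0.5, f_hi = 5.0,
                              alpha = 0.05, k_max = 10,
                              order = "average_first",
                              seed = 1) {
  if (inherits(subjects, "subject_params")) subjects <- list(subjects)
  if (!length(subjects) ||
      !all(vapply(subjects, inherits, logical(1), "subject_params"))) {
    stop_fbg("'subjects' must be a list of subject_params", "fbgbp_invalid_input")
  }
  if (!(f_lo > 0 && f_lo < f_hi && f_hi < fs / 2)) {
    stop_fbg("band edges must satisfy 0 < f_lo < f_hi < fs/2", "fbgbp_domain_error")
  }
  if (n_cal < 4 || n_val < 2) {
    stop_fbg("need n_cal >= 4 and n_val >= 2", "fbgbp_domain_error")
  }
  names(subjects) <- vapply(subjects, function(s) s$subject_id, "")
  structure(
    list(subjects = subjects, n_cal = n_cal, n_val = n_val,
         duration_s = duration_s, fs = fs, L = L, anchor_frac = anchor_frac,
         f_lo = f_lo, f_hi = f_hi, alpha = alpha, k_max = k_max,
         order = order, seed = as.integer(seed)),
    class = "experiment_config"
  )
}

#' Read an experiment configuration from a YAML file
#'
#' Top-level keys mirror the arguments of [experiment_config()]; the
#' `subjects` key is a named map whose entries are passed to
#' [subject_params()] (a `morphology` entry, if present, must be a list of
#' columns `peak`, `center`, `width`, `amplitude`).
#'
#' @param path YAML file path.
#' @return An `experiment_config`.
#' @export
read_experiment_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  subjects <- if (is.null(cfg$subjects)) {
    subject_presets()
  } else {
    purrr::imap(cfg$subjects, function(s, id) {
      s$subject_id <- s$subject_id %||% id
      if (!is.null(s$morphology)) {
        s$morphology <- tibble::as_tibble(s$morphology)
      }
      if (!is.null(s$bp_sensitivity)) {
        s$bp_sensitivity <- unlist(s$bp_sensitivity)
      }
      do.call(subject_params, s)
    })
  }
  args <- cfg[setdiff(names(cfg), "subjects")]
  do.call(experiment_config, c(list(subjects = subjects), args))
}

#' Summarize reference-pressure data sets per subject and pooled
#'
#' Per subject and for the pooled ("Overall") data set: record count,
#' maximum, minimum and mean reference pressure. The pooled count is the sum
#' of the subject counts and the pooled extrema the elementwise extrema of
#' the subject extrema.
#'
#' @param references A data frame with columns `subject_id` and
#'   `reference_bp_mmHg` (or `bp_ref_mmHg`). Filter to one split before
#'   summarizing.
#' @return A tibble with columns `subject`, `n`, `max_mmHg`, `min_mmHg`,
#'   `mean_mmHg`; the final row is the pooled summary (only when more than
#'   one subject is present).
#' @export
summarize_datasets <- function(references) {
  ycol <- intersect(c("reference_bp_mmHg", "bp_ref_mmHg"), names(references))[1]
  if (is.na(ycol) || !"subject_id" %in% names(references)) {
    stop_fbg("need columns 'subject_id' and 'reference_bp_mmHg'",
             "fbgbp_invalid_input")
  }
  if (!nrow(references)) stop_fbg("empty data set", "fbgbp_invalid_input")
  y <- references[[ycol]]
  per <- references |>
    dplyr::group_by(subject = .data$subject_id) |>
    dplyr::summarise(n = dplyr::n(),
                     max_mmHg = max(.data[[ycol]]),
                     min_mmHg = min(.data[[ycol]]),
                     mean_mmHg = mean(.data[[ycol]]),
                     .groups = "drop") |>
    dplyr::arrange(.data$subject)
  pooled <- tibble::tibble(subject = "Overall", n = length(y),
                           max_mmHg = max(y), min_mmHg = min(y),
                           mean_mmHg = mean(y))
  dplyr::bind_rows(per, pooled)
}

# Fit + evaluate one curve; returns results row(s) and per-record predictions.
eval_curve <- function(curve, model, val_data, subject_label) {
  yhat <- predict(model, val_data)
  ev <- evaluate_model(model, val_data)
  list(
    result = tibble::tibble(curve = curve, subject = subject_label,
                            n = ev$n, k = ev$k, r = ev$r,
                            sep_mmHg = ev$sep_mmHg, bias_mmHg = ev$bias_mmHg),
    predictions = tibble::tibble(curve = curve,
                                 subject_id = val_data$subject_id,
                                 record_id = val_data$record_id,
                                 reference_bp_mmHg = val_data$bp_ref_mmHg,
                                 predicted_bp_mmHg = yhat)
  )
}

#' Build and evaluate individual calibration curves
#'
#' For each subject, a PLS calibration curve (with PRESS/F-test factor
#' selection) is fitted on that subject's calibration records only and
#' evaluated on that subject's validation records, so individual differences
#' cannot influence the result.
#'
#' @param beat_data Beat table from [simulate_beat_data()] (columns
#'   `subject_id`, `split`, `record_id`, `bp_ref_mmHg`, `beat`).
#' @param alpha,k_max Factor-selection settings.
#' @return A list with `results` (one row per subject: R, SEP, bias, k),
#'   `predictions` (per validation record) and `models` (named list of
#'   `fbg_pls`).
#' @export
run_individual <- function(beat_data, alpha = 0.05, k_max = 10) {
  check_splits(beat_data)
  subjects <- sort(unique(beat_data$subject_id))
  fits <- purrr::map(subjects, function(s) {
    cal <- beat_data[beat_data$subject_id == s & beat_data$split == "calibration", ]
    val <- beat_data[beat_data$subject_id == s & beat_data$split == "validation", ]
    model <- fit_pls_cv(cal, k_max = k_max, alpha = alpha)
    c(eval_curve(paste("Individual Subject", s), model, val, s), list(model = model))
  })
  list(
    results = dplyr::bind_rows(purrr::map(fits, "result")),
    predictions = dplyr::bind_rows(purrr::map(fits, "predictions")),
    models = stats::setNames(purrr::map(fits, "model"), subjects)
  )
}

#' Build and evaluate the overall (pooled) calibration curve
#'
#' A single curve is fitted on the pooled calibration records of all subjects
#' and evaluated both on the pooled validation set and on each subject's
#' validation set separately; the pooled curve includes every subject's data,
#' so individual differences can influence its predictions.
#'
#' @inheritParams run_individual
#' @return A list with `results` (pooled row first, then per-subject rows),
#'   `predictions` and `model`.
#' @export
run_overall <- function(beat_data, alpha = 0.05, k_max = 10) {
  check_splits(beat_data)
  subjects <- sort(unique(beat_data$subject_id))
  if (length(subjects) < 2) {
    stop_fbg("the overall curve needs at least 2 subjects", "fbgbp_invalid_input")
  }
  cal <- beat_data[beat_data$split == "calibration", ]
  val <- beat_data[beat_data$split == "validation", ]
  model <- fit_pls_cv(cal, k_max = k_max, alpha = alpha)
  pooled <- eval_curve("Overall", model, val, "Overall")
  per <- purrr::map(subjects, function(s) {
    eval_curve("Overall", model, val[val$subject_id == s, ], s)
  })
  list(
    results = dplyr::bind_rows(pooled$result, purrr::map(per, "result")),
    predictions = pooled$predictions,
    model = model
  )
}

check_splits <- function(beat_data) {
  need <- c("subject_id", "split", "record_id", "bp_ref_mmHg", "beat")
  missing_cols <- setdiff(need, names(beat_data))
  if (length(missing_cols)) {
    stop_fbg("beat data lacks column(s): %s", "fbgbp_invalid_input",
             paste(missing_cols, collapse = ", "))
  }
  splits <- split(beat_data$split, beat_data$subject_id)
  ok <- vapply(splits, function(s) {
    all(c("calibration", "validation") %in% s)
  }, logical(1))
  if (!all(ok)) {
    stop_fbg("subject(s) %s lack a calibration or validation split",
             "fbgbp_missing_split", paste(names(ok)[!ok], collapse = ", "))
  }
}

#' Run the full individual-vs-overall calibration experiment
#'
#' Generates beat data for every configured subject (streaming each record
#' through demodulation and beat processing), fits the individual calibration
#' curves and the pooled overall curve, and evaluates all of them on the
#' matching validation sets.
#'
#' @param config An [experiment_config()].
#' @return An object of class `experiment_report`: list with `config`,
#'   `references`, `summary_calibration`, `summary_validation`, `results`
#'   (curve, subject, n, k, R, SEP, bias), `predictions` and `models`.
#' @export
run_experiment <- function(config) {
  stopifnot(inherits(config, "experiment_config"))
  beat_data <- simulate_beat_data(
    config$subjects, n_cal = config$n_cal, n_val = config$n_val,
    duration_s = config$duration_s, fs = config$fs, seed = config$seed,
    L = config$L, anchor_frac = config$anchor_frac, order = config$order,
    f_lo = config$f_lo, f_hi = config$f_hi
  )
  ind <- run_individual(beat_data, alpha = config$alpha, k_max = config$k_max)
  multi <- length(config$subjects) > 1
  ov <- if (multi) run_overall(beat_data, alpha = config$alpha,
                               k_max = config$k_max)
  refs <- beat_data[, c("subject_id", "split", "record_id", "bp_ref_mmHg")]
  structure(
    list(
      config = config,
      references = refs,
      beat_data = beat_data,
      summary_calibration = summarize_datasets(refs[refs$split == "calibration", ]),
      summary_validation = summarize_datasets(refs[refs$split == "validation", ]),
      results = dplyr::bind_rows(ind$results, if (multi) ov$results),
      predictions = dplyr::bind_rows(ind$predictions, if (multi) ov$predictions),
      models = c(ind$models, if (multi) list(Overall = ov$model))
    ),
    class = "experiment_report"
  )
}

#' @export
print.experiment_report <- function(x, ...) {
  cat("<experiment_report>\n")
  cat(sprintf("  %d subject(s), seed %d\n", length(x$config$subjects),
              x$config$seed))
  cat("  calibration summary:\n")
  print(x$summary_calibration)
  cat("  results:\n")
  print(x$results)
  invisible(x)
}

#' Write an experiment report to disk
#'
#' Emits `summary_calibration.csv` and `summary_validation.csv` (per-subject
#' and pooled reference summaries), `results.csv` (curve, subject, R, SEP,
#' bias, k), `predictions.csv` (per validation record) and `manifest.json`
#' (seed, settings, package version). Output is deterministic given the same
#' report, byte for byte.
#'
#' @param report An `experiment_report`.
#' @param outdir Output directory (created if needed).
#' @return Named character vector of the files written, invisibly.
#' @export
write_report <- function(report, outdir) {
  stopifnot(inherits(report, "experiment_report"))
  ok <- dir.exists(outdir) || dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  if (!ok || !dir.exists(outdir)) {
    stop_fbg("cannot create output directory '%s'", "fbgbp_io_error", outdir)
  }
  cfg <- report$config
  paths <- c(
    summary_calibration = file.path(outdir, "summary_calibration.csv"),
    summary_validation = file.path(outdir, "summary_validation.csv"),
    results = file.path(outdir, "results.csv"),
    predictions = file.path(outdir, "predictions.csv"),
    manifest = file.path(outdir, "manifest.json")
  )
  readr::write_csv(report$summary_calibration, paths[["summary_calibration"]])
  readr::write_csv(report$summary_validation, paths[["summary_validation"]])
  readr::write_csv(report$results, paths[["results"]])
  readr::write_csv(report$predictions, paths[["predictions"]])
  manifest <- list(
    format = "fbgbp-experiment-manifest",
    version = as.character(packageVersion("fbgbp")),
    seed = cfg$seed,
    subjects = names(cfg$subjects),
    n_cal = cfg$n_cal, n_val = cfg$n_val,
    duration_s = cfg$duration_s, fs = cfg$fs,
    L = cfg$L, anchor_frac = cfg$anchor_frac,
    band_hz = c(cfg$f_lo, cfg$f_hi),
    alpha = cfg$alpha, k_max = cfg$k_max, order = cfg$order,
    selected_factors = lapply(report$models, function(m) m$k)
  )
  jsonlite::write_json(manifest, paths[["manifest"]], auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(paths)
}
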