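#!/usr/bin/env Rscript

# Thin command-line front end over the fbgbp package.
#
#   Rscript scripts/fbgbp.R <verb> [options]
#
# Verbs:
#   simulate    write synthetic three-phase records + references.csv
#   demodulate  three-phase CSV -> phase + wavelength-shift CSV
#   beats       three-phase CSV -> normalized averaged beat CSV
#   fit         beat-matrix CSV (with reference column) -> PLS model JSON
#   evaluate    model JSON + beat-matrix CSV -> R / SEP / bias
#   experiment  run the full individual-vs-overall design, write reports

suppressPackageStartupMessages({
  library(optparse)
  library(fbgbp)
})

args <- commandArgs(trailingOnly = TRUE)
verb <- if (length(args)) args[1] else ""
rest <- args[-1]

die <- function(msg) {
  message("error: ", msg)
  quit(status = 1)
}

opt <- function(option_list) {
  parse_args(OptionParser(option_list = option_list), args = rest)
}

log_stage <- function(fmt, ...) {
  message(sprintf("[fbgbp %s] %s", format(Sys.time(), "%H:%M:%S"),
                  sprintf(fmt, ...)))
}

result <- tryCatch(switch(
  verb,
  simulate = {
    o <- opt(list(
      make_option("--config", type = "character", default = NULL,
                  help = "experiment YAML (defaults to the preset subjects)"),
      make_option("--outdir", type = "character", default = "fbgbp_records"),
      make_option("--seed", type = "integer", default = 1L)
    ))
    cfg <- if (is.null(o$config)) experiment_config(seed = o$seed) else {
      read_experiment_config(o$config)
    }
    dir.create(o$outdir, recursive = TRUE, showWarnings = FALSE)
    refs <- dplyr::bind_rows(lapply(cfg$subjects, simulate_references,
                                    n_cal = cfg$n_cal, n_val = cfg$n_val,
                                    seed = cfg$seed))
    write_references(refs, file.path(o$outdir, "references.csv"))
    for (i in seq_len(nrow(refs))) {
      p <- cfg$subjects[[refs$subject_id[i]]]
      rec <- simulate_record(p, refs$bp_latent_mmHg[i], cfg$duration_s, cfg$fs,
                             seed = derive_seed(cfg$seed, p$subject_id,
                                                refs$split[i], "record",
                                                refs$record_id[i]))
      write_three_phase(rec, file.path(o$outdir,
                                       paste0(refs$record_id[i], ".csv")))
    }
    log_stage("wrote %d records to %s", nrow(refs), o$outdir)
  },
  demodulate = {
    o <- opt(list(
      make_option("--in", type = "character", dest = "input"),
      make_option("--out", type = "character", default = "phase.csv"),
      make_option("--bragg", type = "character", default = NULL,
                  help = "Bragg config YAML/JSON (default 1550 nm grating)")
    ))
    if (is.null(o$input)) die("demodulate needs --in <record.csv>")
    bragg <- if (is.null(o$bragg)) bragg_config(bragg_wavelength = 1550e-9) else {
      read_bragg_config(o$bragg)
    }
    rec <- read_three_phase(o$input)
    rec <- apply_channel_calibration(rec, estimate_channel_calibration(rec))
    phase <- demodulate_phase(rec)
    shift <- phase_to_wavelength_shift(phase, bragg)
    readr::write_csv(dplyr::mutate(phase, dlambda_m = shift$dlambda_m), o$out)
    log_stage("demodulated %s -> %s", o$input, o$out)
  },
  beats = {
    o <- opt(list(
      make_option("--in", type = "character", dest = "input"),
      make_option("--out", type = "character", default = "beat.csv"),
      make_option("--L", type = "integer", default = 100L)
    ))
    if (is.null(o$input)) die("beats needs --in <record.csv>")
    nb <- process_record(read_three_phase(o$input), L = o$L)
    write_beat_matrix(matrix(nb$amplitude, nrow = 1), o$out)
    log_stage("averaged %d beats -> %s", attr(nb, "n_beats"), o$out)
  },
  fit = {
    o <- opt(list(
      make_option("--in", type = "character", dest = "input",
                  help = "beat-matrix CSV with reference_bp_mmHg column"),
      make_option("--out", type = "character", default = "model.json"),
      make_option("--kmax", type = "integer", default = 10L),
      make_option("--alpha", type = "double", default = 0.05),
      make_option("--seed", type = "integer", default = 1L)
    ))
    if (is.null(o$input)) die("fit needs --in <beats.csv>")
    bd <- read_beat_matrix(o$input)
    model <- fit_pls_cv(bd, k_max = o$kmax, alpha = o$alpha)
    write_pls_model(model, o$out, seed = o$seed)
    log_stage("fitted %d-factor curve on %d beats -> %s", model$k, model$n,
              o$out)
  },
  evaluate = {
    o <- opt(list(
      make_option("--model", type = "character"),
      make_option("--in", type = "character", dest = "input"),
      make_option("--out", type = "character", default = NULL)
    ))
    if (is.null(o$model) || is.null(o$input)) {
      die("evaluate needs --model <model.json> --in <beats.csv>")
    }
    ev <- evaluate_model(read_pls_model(o$model), read_beat_matrix(o$input))
    if (!is.null(o$out)) readr::write_csv(ev, o$out)
    print(as.data.frame(ev))
  },
  experiment = {
    o <- opt(list(
      make_option("--config", type = "character", default = NULL),
      make_option("--outdir", type = "character", default = "fbgbp_results"),
      make_option("--seed", type = "integer", default = 1L)
    ))
    cfg <- if (is.null(o$config)) experiment_config(seed = o$seed) else {
      read_experiment_config(o$config)
    }
    t0 <- Sys.time()
    report <- run_experiment(cfg)
    log_stage("pipeline + calibration done in %.1f s",
              as.numeric(difftime(Sys.time(), t0, units = "secs")))
    write_report(report, o$outdir)
    log_stage("report written to %s", o$outdir)
    print(as.data.frame(report$results))
  },
  die(sprintf(paste0("unknown verb '%s'; use one of simulate, demodulate, ",
                     "beats, fit, evaluate, experiment"), verb))
), error = function(e) {
  message("error [", paste(class(e)[1]), "]: ", conditionMessage(e))
  quit(status = 1)
})
invisible(result)
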