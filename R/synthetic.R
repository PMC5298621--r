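# Synthetic subjects: acceleration-pulse-wave morphology whose component
# amplitudes covary linearly with a latent blood pressure, encoded through the
# three-phase interferometer with detector noise, plus cuff-reference error.

#' Parameters describing one synthetic subject
#'
#' The beat template is a sum of five Gaussian bumps standing in for the A-E
#' peaks of the acceleration pulse wave: A positive and dominant, B and D
#' negative, C and E positive. Each bump amplitude moves linearly with the
#' latent blood pressure around `bp_mean` at a per-component slope
#' (`bp_sensitivity`, amplitude units per mmHg), which is the minimal
#' structure under which a linear (PLS) calibration of beat shape on pressure
#' is actually correct.
#'
#' @param subject_id Label used in reports and seed streams.
#' @param bp_mean,bp_sd Mean and standard deviation of the latent systolic
#'   pressure across records, mmHg. The default spread (5.5 mmHg) makes a
#'   50-record draw span roughly +/- 12 mmHg around the mean, the spread a
#'   repeated-measurement protocol on a resting subject typically shows.
#' @param heart_rate_bpm Heart rate, beats per minute (40-180).
#' @param morphology Data frame with columns `peak` ("A".."E"), `center` and
#'   `width` (beat fractions in (0, 1), centers strictly increasing) and
#'   `amplitude` (signed, A positive and dominant).
#' @param bp_sensitivity Named numeric vector of amplitude slopes per mmHg
#'   for peaks A-E.
#' @param bp_anchor Pressure (mmHg) at which `morphology` amplitudes are
#'   defined; bump amplitudes at pressure `bp` are
#'   `amplitude + slope * (bp - bp_anchor)`. Defaults to `bp_mean`. Giving
#'   several subjects a common anchor places them on one shared
#'   pressure-morphology line, so a pooled calibration across them is
#'   coherent; per-subject deviations from that line are then genuine
#'   individual differences.
#' @param ref_noise_sd Standard deviation of the cuff-reference measurement
#'   error, mmHg.
#' @param detector_noise_sd Additive Gaussian noise on each detector channel,
#'   voltage units (channel amplitude is 1).
#' @param morph_noise_sd Record-level physiological variability: each record
#'   perturbs every bump amplitude by an independent `Normal(0, morph_noise_sd)`
#'   draw (amplitude units), modeling sensor coupling, posture and vasomotor
#'   state changes between repeated measurements that move beat shape without
#'   moving blood pressure. This, not detector noise, is what limits the
#'   accuracy of a real calibration.
#' @param phase_gain Interferometric phase excursion per unit of template
#'   amplitude, radians.
#' @param drift_amplitude_rad,drift_freq_hz Slow baseline phase drift
#'   (temperature etc.); must stay well below the 0.5 Hz band edge so the
#'   band-pass removes it. The default amplitude also guarantees the record
#'   sweeps more than a full fringe, so channel calibration can be estimated
#'   from the record itself.
#' @return An object of class `subject_params`.
#' @export
subject_params <- function(subject_id = "A",
                           bp_mean = 111.3,
                           bp_sd = 5.5,
                           heart_rate_bpm = 65,
                           morphology = default_morphology(),
                           bp_sensitivity = c(A = 0.002, B = -0.004, C = 0.005,
                                              D = -0.002, E = 0.002),
                           ref_noise_sd = 2,
                           detector_noise_sd = 0.01,
                           morph_noise_sd = 0.003,
                           bp_anchor = NULL,
                           phase_gain = 2,
                           drift_amplitude_rad = 3.5,
                           drift_freq_hz = 0.08) {
  morphology <- tibble::as_tibble(morphology)
  stopifnot(all(c("peak", "center", "width", "amplitude") %in% names(morphology)))
  if (bp_sd < 0 || ref_noise_sd < 0 || detector_noise_sd < 0) {
    stop_fbg("noise standard deviations must be >= 0", "fbgbp_domain_error")
  }
  if (heart_rate_bpm < 40 || heart_rate_bpm > 180) {
    stop_fbg("heart_rate_bpm must lie in [40, 180]", "fbgbp_domain_error")
  }
  ctr <- morphology$center
  if (any(ctr <= 0) || any(ctr >= 1) || any(diff(ctr) <= 0)) {
    stop_fbg("bump centers must be strictly increasing inside (0, 1)",
             "fbgbp_domain_error")
  }
  amp <- morphology$amplitude
  a_amp <- amp[morphology$peak == "A"]
  if (length(a_amp) != 1 || a_amp <= 0 || any(abs(amp[morphology$peak != "A"]) >= a_amp)) {
    stop_fbg("peak A amplitude must be positive and dominant", "fbgbp_domain_error")
  }
  if (drift_freq_hz >= 0.2) {
    stop_fbg("drift frequency must stay below 0.2 Hz", "fbgbp_domain_error")
  }
  sens <- bp_sensitivity[morphology$peak]
  sens[is.na(sens)] <- 0
  structure(
    list(subject_id = subject_id, bp_mean = bp_mean, bp_sd = bp_sd,
         bp_anchor = bp_anchor %||% bp_mean,
         heart_rate_bpm = heart_rate_bpm, morphology = morphology,
         bp_sensitivity = as.numeric(sens), ref_noise_sd = ref_noise_sd,
         detector_noise_sd = detector_noise_sd, morph_noise_sd = morph_noise_sd,
         phase_gain = phase_gain,
         drift_amplitude_rad = drift_amplitude_rad,
         drift_freq_hz = drift_freq_hz),
    class = "subject_params"
  )
}

#' @rdname subject_params
#' @export
default_morphology <- function() {
  tibble::tibble(
    peak = c("A", "B", "C", "D", "E"),
    center = c(0.30, 0.40, 0.52, 0.62, 0.72),
    width = c(0.035, 0.035, 0.045, 0.045, 0.050),
    amplitude = c(1.00, -0.55, 0.30, -0.20, 0.15)
  )
}

#' Three default synthetic subjects
#'
#' Subject mean pressures and spreads mimic the three-subject study design
#' (means about 111, 123 and 101 mmHg, per-subject ranges around +/- 10
#' mmHg). All three share one pressure-morphology line anchored at the pooled
#' mean (111.8 mmHg), so the pooled data are mutually consistent; individual
#' differences enter as small idiosyncratic bump-amplitude offsets off that
#' line, bump-width differences, and sensitivity scales of 1.0, 1.2 and 0.85
#' -- enough to cost a pooled calibration some accuracy without breaking it.
#'
#' @return Named list of three `subject_params` ("A", "B", "C").
#' @export
subject_presets <- function() {
  base <- default_morphology()
  shape <- c(A = 0.002, B = -0.004, C = 0.005, D = -0.002, E = 0.002)
  anchor <- 111.8
  morph_b <- base
  morph_b$amplitude <- base$amplitude + c(0, -0.007, 0, 0, 0.004)
  morph_b$width <- base$width * 1.05
  morph_c <- base
  morph_c$amplitude <- base$amplitude + c(0, 0.005, -0.006, 0, 0)
  morph_c$width <- base$width * 0.95
  list(
    A = subject_params("A", bp_mean = 111.3, bp_sd = 5.6, heart_rate_bpm = 65,
                       morphology = base, bp_sensitivity = shape,
                       bp_anchor = anchor, drift_freq_hz = 0.08),
    B = subject_params("B", bp_mean = 123.1, bp_sd = 5.1, heart_rate_bpm = 72,
                       morphology = morph_b, bp_sensitivity = shape * 1.2,
                       bp_anchor = anchor, drift_freq_hz = 0.10),
    C = subject_params("C", bp_mean = 100.9, bp_sd = 4.0, heart_rate_bpm = 58,
                       morphology = morph_c, bp_sensitivity = shape * 0.85,
                       bp_anchor = anchor, drift_freq_hz = 0.12)
  )
}

#' Render a subject's beat template at a given blood pressure
#'
#' Deterministic in `(params, bp)`: the sum of the five Gaussian bumps with
#' amplitudes `base + slope * (bp - bp_mean)`, evaluated on `n` points
#' spanning one beat.
#'
#' @param params A `subject_params`.
#' @param bp Latent blood pressure, mmHg.
#' @param n Number of samples.
#' @param amplitude_offset Extra additive offset per bump amplitude (length 5
#'   or scalar), used by [simulate_record()] to inject record-level
#'   physiological variability. Default 0.
#' @return Numeric waveform of length `n`.
#' @export
make_beat_template <- function(params, bp, n = 1024, amplitude_offset = 0) {
  u <- (seq_len(n) - 1) / (n - 1)
  m <- params$morphology
  amps <- m$amplitude + params$bp_sensitivity * (bp - params$bp_anchor) +
    amplitude_offset
  drop(exp(-outer(u, m$center, "-")^2 / (2 * rep(m$width, each = n)^2)) %*% amps)
}

#' Simulate one three-phase sensor record for a subject
#'
#' Beat templates are tiled at the subject's heart rate with a +/- 3 percent
#' uniform jitter on each beat interval, scaled by `phase_gain` to an
#' interferometric phase, superposed on a slow baseline drift (below 0.2 Hz,
#' removed later by the band-pass), and encoded into the three detector
#' channels with additive Gaussian noise.
#'
#' @param params A `subject_params`.
#' @param bp Latent blood pressure of this record, mmHg.
#' @param duration_s Record length in seconds (>= 5), default 20.
#' @param fs Sampling rate, Hz, default 10000.
#' @param seed Optional integer seed (jitter, drift phase, detector noise).
#' @param gains,offset Channel gains and offset of the encoder, defaults 1.
#' @return A three-phase record tibble.
#' @export
simulate_record <- function(params, bp, duration_s = 20, fs = 10000,
                            seed = NULL, gains = c(1, 1, 1), offset = 1) {
  if (duration_s < 5) {
    stop_fbg("duration_s must be >= 5 s", "fbgbp_domain_error")
  }
  n <- round(duration_s * fs)
  base_int <- 60 / params$heart_rate_bpm
  with_seed_maybe(seed, {
    amp_jit <- rnorm(nrow(params$morphology), 0, params$morph_noise_sd)
    tpl <- make_beat_template(params, bp, n = 2048, amplitude_offset = amp_jit)
    n_beats <- ceiling(duration_s / (base_int * 0.97)) + 2L
    ints <- base_int * (1 + runif(n_beats, -0.03, 0.03))
    wave <- unlist(lapply(ints, function(it) {
      resample_linear(tpl, max(8L, round(it * fs)))
    }), use.names = FALSE)
    wave <- wave[seq_len(n)]
    t <- (seq_len(n) - 1) / fs
    ph0 <- runif(2, 0, 2 * pi)
    drift <- params$drift_amplitude_rad *
      (sin(2 * pi * params$drift_freq_hz * t + ph0[1]) +
         0.35 * sin(2 * pi * 1.5 * params$drift_freq_hz * t + ph0[2]))
    phase <- params$phase_gain * wave + drift
    simulate_three_phase(phase, fs = fs, gains = gains, offset = offset,
                         noise_sd = params$detector_noise_sd)
  })
}

#' Simulate a full calibration/validation data set for one subject
#'
#' Latent pressures are drawn per record from
#' `Normal(bp_mean, bp_sd)`; the cuff reference reading adds
#' `Normal(0, ref_noise_sd)` measurement error. Calibration and validation
#' streams use disjoint sub-seeds of the master seed, so either split can be
#' regenerated independently.
#'
#' Holding 75 full-rate records in memory is heavy; for fitting calibrations
#' prefer [simulate_beat_data()], which processes each record to its
#' normalized beat as it is generated.
#'
#' @param params A `subject_params`.
#' @param n_cal,n_val Number of calibration / validation records (defaults
#'   50 and 25).
#' @param duration_s,fs Record length and sampling rate.
#' @param seed Master seed.
#' @return An object of class `subject_dataset`: list with `subject_id`,
#'   `params`, `seed` and `records`, a tibble with columns `split`,
#'   `record_id`, `bp_latent_mmHg`, `bp_ref_mmHg` and `record` (list column
#'   of three-phase tibbles).
#' @export
simulate_subject <- function(params, n_cal = 50, n_val = 25, duration_s = 20,
                             fs = 10000, seed = 1) {
  refs <- simulate_references(params, n_cal, n_val, seed)
  refs$record <- purrr::pmap(
    list(refs$split, refs$record_id, refs$bp_latent_mmHg),
    function(split, id, bp) {
      simulate_record(params, bp, duration_s, fs,
                      seed = derive_seed(seed, params$subject_id, split, "record", id))
    }
  )
  structure(list(subject_id = params$subject_id, params = params, seed = seed,
                 records = refs),
            class = "subject_dataset")
}

#' Draw latent and cuff-reference pressures for one subject
#'
#' Latent pressures come from `Normal(bp_mean, bp_sd)`; the cuff reading adds
#' `Normal(0, ref_noise_sd)` measurement error. Calibration and validation
#' use disjoint named sub-streams of the master seed, so regenerating one
#' split, or changing the size of the other, never changes these values.
#'
#' @param params A `subject_params`.
#' @param n_cal,n_val Records per split.
#' @param seed Master seed.
#' @return A tibble: `subject_id`, `split`, `record_id`, `bp_latent_mmHg`,
#'   `bp_ref_mmHg`.
#' @export
simulate_references <- function(params, n_cal, n_val, seed) {
  one_split <- function(split, n_rec) {
    latent <- with_seed_maybe(
      derive_seed(seed, params$subject_id, split, "bp"),
      rnorm(n_rec, params$bp_mean, params$bp_sd)
    )
    ref <- with_seed_maybe(
      derive_seed(seed, params$subject_id, split, "ref"),
      latent + rnorm(n_rec, 0, params$ref_noise_sd)
    )
    tibble::tibble(
      subject_id = params$subject_id,
      split = split,
      record_id = sprintf("%s_%s_%03d", params$subject_id, substr(split, 1, 3),
                          seq_len(n_rec)),
      bp_latent_mmHg = latent,
      bp_ref_mmHg = ref
    )
  }
  dplyr::bind_rows(one_split("calibration", n_cal), one_split("validation", n_val))
}

#' Run one record through the full demodulation and beat pipeline
#'
#' Channel calibration estimated from the record itself (the baseline drift
#' sweeps more than a full fringe), arctangent phase demodulation,
#' phase-to-wavelength conversion, band-pass, beat segmentation and
#' ensemble-average normalization.
#'
#' @param record A three-phase record tibble.
#' @param bragg A [bragg_config()]; default uses a 1550 nm grating.
#' @param L,anchor_frac,order Beat standardization settings, see
#'   [average_and_normalize()].
#' @param f_lo,f_hi Band edges, Hz.
#' @return A `normalized_beat` (attribute `n_beats` carries the number of
#'   beats averaged).
#' @export
process_record <- function(record, bragg = bragg_config(bragg_wavelength = 1550e-9),
                           L = 100, anchor_frac = 0.3,
                           order = "average_first", f_lo = 0.5, f_hi = 5.0) {
  calib <- estimate_channel_calibration(record)
  rec <- apply_channel_calibration(record, calib)
  phase <- demodulate_phase(rec)
  shift <- phase_to_wavelength_shift(phase, bragg)
  pulse <- bandpass(shift, f_lo = f_lo, f_hi = f_hi)
  beats <- segment_beats(pulse)
  average_and_normalize(beats, L = L, anchor_frac = anchor_frac, order = order)
}

#' Generate processed beat data for one or more synthetic subjects
#'
#' Streams record by record: each simulated three-phase record is immediately
#' demodulated and reduced to its normalized averaged beat, so memory stays
#' flat regardless of the record count. This is the input format consumed by
#' the calibration experiment.
#'
#' @param params A `subject_params` or (named) list of them.
#' @param n_cal,n_val Records per subject and split.
#' @param duration_s,fs Record length and sampling rate.
#' @param seed Master seed; every record derives its own sub-seed.
#' @param L,anchor_frac,order,f_lo,f_hi Pipeline settings, see
#'   [process_record()].
#' @param bragg A [bragg_config()].
#' @return A tibble with columns `subject_id`, `split`, `record_id`,
#'   `bp_latent_mmHg`, `bp_ref_mmHg`, `n_beats` and `beat` (list column of
#'   length-`L` numeric vectors).
#' @export
simulate_beat_data <- function(params, n_cal = 50, n_val = 25, duration_s = 20,
                               fs = 10000, seed = 1, L = 100, anchor_frac = 0.3,
                               order = "average_first", f_lo = 0.5, f_hi = 5.0,
                               bragg = bragg_config(bragg_wavelength = 1550e-9)) {
  if (inherits(params, "subject_params")) params <- list(params)
  out <- purrr::map(params, function(p) {
    refs <- simulate_references(p, n_cal, n_val, seed)
    beats <- purrr::pmap(
      list(refs$split, refs$record_id, refs$bp_latent_mmHg),
      function(split, id, bp) {
        rec <- simulate_record(p, bp, duration_s, fs,
                               seed = derive_seed(seed, p$subject_id, split,
                                                  "record", id))
        nb <- process_record(rec, bragg = bragg, L = L,
                             anchor_frac = anchor_frac, order = order,
                             f_lo = f_lo, f_hi = f_hi)
        list(beat = nb$amplitude, n_beats = attr(nb, "n_beats"))
      }
    )
    refs$n_beats <- vapply(beats, function(b) as.integer(b$n_beats), integer(1))
    refs$beat <- purrr::map(beats, "beat")
    refs
  })
  dplyr::bind_rows(out)
}
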