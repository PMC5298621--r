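# Interrogator physics: Bragg reflection, three-phase homodyne encoding and
# arctangent phase demodulation.

#' Bragg wavelength of a fiber grating
#'
#' The wavelength reflected by a fiber Bragg grating is `2 * n_eff * spacing`,
#' where `n_eff` is the effective refractive index of the fiber core and
#' `spacing` the grating pitch. Strain on the fiber changes the pitch and
#' therefore shifts the reflected wavelength; that shift is what the
#' interrogator measures.
#'
#' @param n_eff Effective refractive index of the fiber core (dimensionless).
#' @param grating_spacing Grating pitch in meters.
#' @return Bragg wavelength in meters.
#' @export
#' @examples
#' bragg_wavelength(1.45, 530e-9) # ~1537 nm
bragg_wavelength <- function(n_eff, grating_spacing) {
  check_scalar_positive(n_eff, "n_eff")
  check_scalar_positive(grating_spacing, "grating_spacing")
  2 * n_eff * grating_spacing
}

#' Optical configuration of the sensor and interrogator
#'
#' Bundles the constants needed to convert a demodulated interferometric phase
#' into a Bragg-wavelength shift: the effective refractive index, the grating
#' pitch and/or Bragg wavelength (either may be given; they are linked by
#' [bragg_wavelength()]), and the optical path difference of the two
#' Mach-Zehnder interferometer arms.
#'
#' Whether the path difference should be entered as a geometric length
#' difference or as optical path (index times length) depends on how the
#' instrument is specified; it is deliberately a plain user-supplied value.
#' The default, 3.33 mm, corresponds to a geometric arm-length difference of
#' about 3 mm read as optical path near that scale.
#'
#' @param n_eff Effective refractive index of the fiber core.
#' @param path_difference Optical path difference of the interferometer arms,
#'   meters.
#' @param grating_spacing Grating pitch in meters, or `NULL` to derive it from
#'   `bragg_wavelength`.
#' @param bragg_wavelength Bragg wavelength in meters, or `NULL` to derive it
#'   from `grating_spacing`. If both are supplied they must agree with
#'   `2 * n_eff * grating_spacing` to a relative 1e-12.
#' @return An object of class `bragg_config`.
#' @export
#' @examples
#' bragg_config(n_eff = 1.45, bragg_wavelength = 1550e-9)
bragg_config <- function(n_eff = 1.45,
                         path_difference = 3.33e-3,
                         grating_spacing = NULL,
                         bragg_wavelength = NULL) {
  check_scalar_positive(n_eff, "n_eff")
  check_scalar_positive(path_difference, "path_difference")
  if (is.null(grating_spacing) && is.null(bragg_wavelength)) {
    stop_fbg("supply 'grating_spacing' and/or 'bragg_wavelength'",
             "fbgbp_domain_error")
  }
  if (!is.null(grating_spacing)) {
    check_scalar_positive(grating_spacing, "grating_spacing")
  }
  if (!is.null(bragg_wavelength)) {
    check_scalar_positive(bragg_wavelength, "bragg_wavelength")
  }
  if (!is.null(grating_spacing) && !is.null(bragg_wavelength)) {
    implied <- 2 * n_eff * grating_spacing
    if (abs(implied - bragg_wavelength) > 1e-12 * bragg_wavelength) {
      stop_fbg("bragg_wavelength (%g m) inconsistent with 2 * n_eff * spacing (%g m)",
               "fbgbp_domain_error", bragg_wavelength, implied)
    }
  }
  if (is.null(bragg_wavelength)) {
    bragg_wavelength <- 2 * n_eff * grating_spacing
  }
  if (is.null(grating_spacing)) {
    grating_spacing <- bragg_wavelength / (2 * n_eff)
  }
  structure(
    list(n_eff = n_eff,
         grating_spacing = grating_spacing,
         bragg_wavelength = bragg_wavelength,
         path_difference = path_difference),
    class = "bragg_config"
  )
}

#' @export
print.bragg_config <- function(x, ...) {
  cat("<bragg_config>\n")
  cat(sprintf("  n_eff:            %.4f\n", x$n_eff))
  cat(sprintf("  grating spacing:  %.2f nm\n", x$grating_spacing * 1e9))
  cat(sprintf("  Bragg wavelength: %.2f nm\n", x$bragg_wavelength * 1e9))
  cat(sprintf("  path difference:  %.3f mm\n", x$path_difference * 1e3))
  invisible(x)
}

#' Read a Bragg/interrogator configuration from YAML or JSON
#'
#' Expects keys `n_eff`, `path_difference_m` and one or both of
#' `grating_spacing_m`, `bragg_wavelength_m`.
#'
#' @param path File path (extension `.json` is parsed as JSON, anything else
#'   as YAML).
#' @return A `bragg_config`.
#' @export
read_bragg_config <- function(path) {
  cfg <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else {
    yaml::read_yaml(path)
  }
  bragg_config(
    n_eff = cfg$n_eff,
    path_difference = cfg$path_difference_m,
    grating_spacing = cfg$grating_spacing_m,
    bragg_wavelength = cfg$bragg_wavelength_m
  )
}

#' Construct a three-phase detector record
#'
#' A record holds the voltages of the three interferometer detectors, whose
#' optical phases are offset by 0, 2*pi/3 and 4*pi/3, on a shared uniform time
#' grid.
#'
#' @param v1,v2,v3 Detector voltage traces (equal length).
#' @param fs Sampling rate, Hz.
#' @return A tibble with columns `time_s`, `v1`, `v2`, `v3`.
#' @export
three_phase_record <- function(v1, v2, v3, fs) {
  check_scalar_positive(fs, "fs")
  n <- length(v1)
  if (n < 1 || length(v2) != n || length(v3) != n) {
    stop_fbg("v1, v2, v3 must have equal length >= 1", "fbgbp_invalid_input")
  }
  if (!all(is.finite(v1)) || !all(is.finite(v2)) || !all(is.finite(v3))) {
    stop_fbg("detector traces must be finite", "fbgbp_invalid_input")
  }
  tibble::tibble(time_s = (seq_len(n) - 1) / fs, v1 = v1, v2 = v2, v3 = v3)
}

#' Simulate the three-phase Mach-Zehnder detector outputs
#'
#' Channel `n` (n = 1, 2, 3) is
#' `gains[n] * (offset + cos(phi + 2*pi*(n-1)/3))` plus independent zero-mean
#' Gaussian noise. This is the homodyne encoding the interrogator's arithmetic
#' circuit later inverts.
#'
#' @param phase Interferometric phase in radians: a numeric vector, or a data
#'   frame with columns `time_s` and `phi`.
#' @param fs Sampling rate in Hz (required for vector input; otherwise
#'   inferred from the time column).
#' @param gains Per-channel amplitudes, length 3, all positive.
#' @param offset Shared dimensionless offset of the cosine (1 for an ideal
#'   calibrated channel).
#' @param noise_sd Standard deviation of additive detector noise (voltage
#'   units); 0 for noiseless channels.
#' @param seed Optional integer seed making the noise reproducible; the global
#'   RNG state is restored afterwards.
#' @return A three-phase record tibble (see [three_phase_record()]).
#' @export
#' @examples
#' rec <- simulate_three_phase(rep(0, 4), fs = 10, offset = 1)
#' rec$v1 # all 2: cos(0) + 1
simulate_three_phase <- function(phase, fs = NULL, gains = c(1, 1, 1),
                                 offset = 1, noise_sd = 0, seed = NULL) {
  tr <- if (is.data.frame(phase)) as_trace(phase, fs, "phi") else as_trace(phase, fs)
  if (length(gains) != 3 || any(!is.finite(gains)) || any(gains <= 0)) {
    stop_fbg("'gains' must be three positive numbers", "fbgbp_invalid_input")
  }
  if (!is.finite(noise_sd) || noise_sd < 0) {
    stop_fbg("'noise_sd' must be >= 0", "fbgbp_invalid_input")
  }
  phi <- tr$x
  n <- length(phi)
  chans <- with_seed_maybe(seed, {
    lapply(1:3, function(ch) {
      v <- gains[ch] * (offset + cos(phi + 2 * pi * (ch - 1) / 3))
      if (noise_sd > 0) v <- v + rnorm(n, 0, noise_sd)
      v
    })
  })
  three_phase_record(chans[[1]], chans[[2]], chans[[3]], tr$fs)
}

#' Estimate per-channel gains and offset from a calibration record
#'
#' During the calibration measurement the sensor is held off the pulsation
#' point while temperature drift sweeps the interferometric phase through at
#' least a full fringe, so every channel traverses its full excursion
#' `gain * (offset - 1)` to `gain * (offset + 1)`. The gain estimate is then
#' half the peak-to-peak range per channel and the offset the (shared) mean of
#' mid-range over gain.
#'
#' @param record A three-phase record captured while the phase sweeps >= 2*pi.
#' @return An object of class `channel_calibration`: list with `gains`
#'   (length 3) and `offset` (scalar).
#' @export
estimate_channel_calibration <- function(record) {
  v <- as.matrix(record[, c("v1", "v2", "v3")])
  rngs <- apply(v, 2, range)
  ptp <- rngs[2, ] - rngs[1, ]
  scale_ref <- max(abs(v), 1e-300)
  if (any(ptp <= 1e-12 * scale_ref)) {
    stop_fbg("channel(s) %s have zero peak-to-peak range: calibration sweep is degenerate",
             "fbgbp_degenerate_calibration",
             paste(which(ptp <= 1e-12 * scale_ref), collapse = ", "))
  }
  gains <- as.numeric(ptp / 2)
  mid <- as.numeric((rngs[2, ] + rngs[1, ]) / 2)
  structure(list(gains = gains, offset = mean(mid / gains)),
            class = "channel_calibration")
}

#' Apply a channel calibration, normalizing a record to unit gain and offset
#'
#' Each channel is divided by its gain and shifted so the shared offset
#' becomes 1; a fully swept ideal record ends up in `[0, 2]` on every channel.
#'
#' @param record A three-phase record.
#' @param calibration A `channel_calibration` from
#'   [estimate_channel_calibration()].
#' @return The normalized record tibble.
#' @export
apply_channel_calibration <- function(record, calibration) {
  g <- calibration$gains
  shift <- calibration$offset - 1
  tibble::tibble(
    time_s = record$time_s,
    v1 = record$v1 / g[1] - shift,
    v2 = record$v2 / g[2] - shift,
    v3 = record$v3 / g[3] - shift
  )
}

#' Demodulate a normalized three-phase record into an unwrapped phase
#'
#' For calibrated channels `V_n = 1 + cos(phi + 2*pi*(n-1)/3)` the three-phase
#' combination obeys
#' `tan(phi) = sqrt(3) * (V2 - V3) / (V2 + V3 - 2 * V1)`.
#' The wrapped phase is recovered with the two-argument arctangent; since the
#' numerator and denominator above equal `-3 sin(phi)` and `-3 cos(phi)`, the
#' quadrant-correct form is `atan2(-num, -den)`. Successive samples are then
#' unwrapped by forcing phase differences into `(-pi, pi]`.
#'
#' Samples where numerator and denominator both vanish (all channels equal)
#' carry no phase information and are filled by linear interpolation from
#' their neighbors; a record that is degenerate throughout is an error.
#'
#' @param record A normalized three-phase record.
#' @return A tibble with columns `time_s` and `phi` (radians, unwrapped).
#' @export
demodulate_phase <- function(record) {
  fs <- infer_fs(record$time_s)
  num <- sqrt(3) * (record$v2 - record$v3)
  den <- record$v2 + record$v3 - 2 * record$v1
  tol <- 1e-9 * max(abs(c(num, den)), 1e-300)
  bad <- abs(num) < tol & abs(den) < tol
  if (all(bad)) {
    stop_fbg("all samples are degenerate (channels equal): no phase information",
             "fbgbp_degenerate_record")
  }
  wrapped <- atan2(-num, -den)
  if (any(bad)) {
    ok <- which(!bad)
    phi_ok <- unwrap_phase(wrapped[ok])
    phi <- approx(ok, phi_ok, xout = seq_along(wrapped), rule = 2)$y
  } else {
    phi <- unwrap_phase(wrapped)
  }
  tibble::tibble(time_s = record$time_s, phi = phi)
}

#' Convert a phase trace into a Bragg-wavelength shift
#'
#' The homodyne phase shift relates to the wavelength shift through
#' `dphi = 2 * pi * n_eff * d / lambda_Bragg^2 * dlambda`, so
#' `dlambda = phi * lambda_Bragg^2 / (2 * pi * n_eff * d)`. Because only
#' relative shifts are meaningful the trace mean is removed first (disable
#' with `demean = FALSE` to convert absolute phase values).
#'
#' @param phase A phase trace: tibble with `time_s`, `phi`, or a numeric
#'   vector of radians.
#' @param config A [bragg_config()].
#' @param demean Remove the trace mean before conversion? Default `TRUE`.
#' @param fs Sampling rate for vector input.
#' @return A tibble with columns `time_s` and `dlambda_m` (meters).
#' @export
#' @examples
#' cfg <- bragg_config(n_eff = 1.5, bragg_wavelength = 1550e-9,
#'                     path_difference = 3.33e-3)
#' phase_to_wavelength_shift(c(0, 2 * pi), cfg, demean = FALSE, fs = 1)
phase_to_wavelength_shift <- function(phase, config, demean = TRUE, fs = NULL) {
  stopifnot(inherits(config, "bragg_config"))
  tr <- if (is.data.frame(phase)) as_trace(phase, fs, "phi") else as_trace(phase, fs)
  phi <- tr$x
  if (!all(is.finite(phi))) {
    stop_fbg("phase trace contains non-finite values", "fbgbp_invalid_input")
  }
  if (demean) phi <- phi - mean(phi)
  k <- config$bragg_wavelength^2 / (2 * pi * config$n_eff * config$path_difference)
  tibble::tibble(time_s = tr$time, dlambda_m = phi * k)
}
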