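# From wavelength-shift trace to a normalized averaged beat and its
# acceleration-pulse-wave peaks.

#' Band-pass filter a raw pulse-wave trace
#'
#' Zero-phase Butterworth band-pass with 4th-order low and high corners,
#' applied forward-backward. Because the pass band (default 0.5-5 Hz) sits
#' orders of magnitude below typical interrogator sampling rates, the trace is
#' first decimated by block averaging to roughly `40 * f_hi` Hz, filtered at
#' the reduced rate where the recursive filter is well conditioned, and the
#' result interpolated back onto the original grid. DC and mains-frequency
#' components are strongly attenuated; pass-band gain is within a few percent
#' away from record edges.
#'
#' @param x Numeric trace, or a data frame with a `time_s` column plus one
#'   value column (e.g. the output of [phase_to_wavelength_shift()]).
#' @param fs Sampling rate in Hz (vector input only).
#' @param f_lo,f_hi Band edges in Hz; defaults 0.5 and 5.
#' @return A tibble with columns `time_s` and `pulse` (same units as the
#'   input, zero-mean).
#' @export
bandpass <- function(x, fs = NULL, f_lo = 0.5, f_hi = 5.0) {
  tr <- as_trace(x, fs)
  fs <- tr$fs
  if (!(f_lo > 0 && f_hi > f_lo)) {
    stop_fbg("need 0 < f_lo < f_hi", "fbgbp_domain_error")
  }
  if (fs <= 2 * f_hi) {
    stop_fbg("sampling rate (%g Hz) must exceed twice the upper band edge (%g Hz)",
             "fbgbp_domain_error", fs, f_hi)
  }
  n <- length(tr$x)
  min_len <- ceiling(3 * fs)
  if (n <= min_len) {
    stop_fbg("record too short for the filter transient: need more than 3 s (%d samples at %g Hz)",
             "fbgbp_record_too_short", min_len, fs)
  }
  m <- max(1L, as.integer(fs %/% (40 * f_hi)))
  xd <- decimate_block_mean(tr$x, m)
  fsd <- fs / m
  hp <- signal::butter(4, f_lo / (fsd / 2), type = "high")
  lp <- signal::butter(4, f_hi / (fsd / 2), type = "low")
  pad <- ceiling(3 * fsd / f_lo)
  y <- filtfilt_ic(lp$b, lp$a, filtfilt_ic(hp$b, hp$a, xd, pad), pad)
  if (!all(is.finite(y))) {
    stop_fbg("band-pass filter diverged; check band edges against fs",
             "fbgbp_numeric_error")
  }
  if (m > 1L) {
    # decimated samples live at block centers; interpolate back to full rate
    t_dec <- (seq_along(y) - 0.5) * m / fs - 0.5 / fs
    y <- approx(t_dec, y, xout = tr$time - tr$time[1], rule = 2)$y
  }
  tibble::tibble(time_s = tr$time, pulse = y)
}

#' Segment a pulse signal into individual beats
#'
#' Detects the dominant positive (systolic) peak of each beat: local maxima
#' with amplitude at least 30 percent of the signal's robust amplitude (the
#' 90th percentile of `|x|`), thinned greedily by height so that accepted
#' anchors are separated by at least `60 / max_bpm` seconds. Each beat window
#' spans from 30 percent of the median inter-anchor interval before its anchor
#' to 70 percent after; beats truncated by the record boundary are discarded.
#'
#' @param x Band-passed pulse signal: tibble from [bandpass()] or numeric
#'   vector plus `fs`.
#' @param fs Sampling rate (vector input only).
#' @param min_bpm,max_bpm Plausible heart-rate range; intervals implying a
#'   rate below `min_bpm` are excluded from the median interval estimate.
#' @return A tibble with one row per beat: `beat_id`, `anchor_time_s`,
#'   `anchor_index` (position of the anchor inside the window) and `samples`
#'   (list column of numeric windows). Sampling rate is kept in attribute
#'   `fs`.
#' @export
segment_beats <- function(x, fs = NULL, min_bpm = 40, max_bpm = 180) {
  tr <- as_trace(x, fs, if (is.data.frame(x)) "pulse" else NULL)
  fs <- tr$fs
  sig <- tr$x
  n <- length(sig)
  if (n / fs < 5) {
    stop_fbg("signal must be at least 5 s long for beat segmentation",
             "fbgbp_record_too_short")
  }
  thr <- 0.3 * quantile(abs(sig), 0.9, names = FALSE)
  if (!is.finite(thr) || thr <= 0) {
    stop_fbg("fewer than 3 beats detected (flat signal)", "fbgbp_insufficient_beats")
  }
  core <- sig[2:(n - 1)]
  cand <- which(core > sig[1:(n - 2)] & core >= sig[3:n] & core >= thr) + 1L
  # enforce minimum separation, keeping the taller peak
  min_sep <- 60 / max_bpm * fs
  cand <- cand[order(sig[cand], decreasing = TRUE)]
  keep <- integer(0)
  for (i in cand) {
    if (!length(keep) || all(abs(keep - i) >= min_sep)) keep <- c(keep, i)
  }
  anchors <- sort(keep)
  if (length(anchors) < 3) {
    stop_fbg("fewer than 3 beats detected", "fbgbp_insufficient_beats")
  }
  ints <- diff(anchors)
  ints <- ints[ints <= 60 / min_bpm * fs]
  if (!length(ints)) ints <- diff(anchors)
  med_int <- median(ints)
  w_pre <- round(0.3 * med_int)
  w_post <- round(0.7 * med_int)
  starts <- anchors - w_pre
  ends <- anchors + w_post
  ok <- starts >= 1 & ends <= n
  anchors <- anchors[ok]
  starts <- starts[ok]
  ends <- ends[ok]
  if (length(anchors) < 3) {
    stop_fbg("fewer than 3 complete beats inside the record",
             "fbgbp_insufficient_beats")
  }
  out <- tibble::tibble(
    beat_id = seq_along(anchors),
    anchor_time_s = tr$time[anchors],
    anchor_index = anchors - starts + 1L,
    samples = purrr::map2(starts, ends, function(s, e) sig[s:e])
  )
  attr(out, "fs") <- fs
  out
}

#' Ensemble-average beats and normalize to the unit interval
#'
#' Each beat is linearly resampled to a standard length `L` with its systolic
#' anchor pinned at the fixed fractional position `anchor_frac` (the stretch
#' is piecewise: pre-anchor and post-anchor segments are resampled
#' separately), the beats are averaged pointwise, and the average is affinely
#' rescaled so its minimum is exactly 0 and its anchor value exactly 1 -- the
#' "clipping position maps to 1, minimum to 0" normalization used for the
#' explanatory variables of the calibration.
#'
#' `order = "normalize_first"` instead rescales every beat before averaging
#' (the averaged beat is re-normalized afterwards so the output invariant
#' holds either way); the two readings of "averaged and normalized" differ
#' only at second order for well-aligned beats.
#'
#' @param beats Beat table from [segment_beats()], or a list of numeric beat
#'   windows together with `anchor_index` attribute per element.
#' @param L Standard beat length (number of samples), default 100.
#' @param anchor_frac Fractional position of the anchor in the standardized
#'   beat, default 0.3 (matching the 30/70 percent segmentation window).
#' @param order `"average_first"` (default) or `"normalize_first"`.
#' @return A `normalized_beat`: tibble with columns `position` (1..L), `frac`
#'   in `[0, 1]` and `amplitude` in `[0, 1]`; attributes `L`, `anchor_index`
#'   and `n_beats`.
#' @export
average_and_normalize <- function(beats, L = 100, anchor_frac = 0.3,
                                  order = c("average_first", "normalize_first")) {
  order <- match.arg(order)
  if (is.data.frame(beats)) {
    windows <- beats$samples
    anchors <- beats$anchor_index
  } else {
    windows <- beats
    anchors <- vapply(beats, function(b) attr(b, "anchor_index") %||% which.max(b),
                      integer(1))
  }
  if (length(windows) < 3) {
    stop_fbg("need at least 3 beats to average", "fbgbp_insufficient_beats")
  }
  if (L < 8) stop_fbg("standard beat length L must be >= 8", "fbgbp_domain_error")
  La <- max(2L, min(L - 1L, round(anchor_frac * L)))
  std <- vapply(seq_along(windows), function(i) {
    w <- as.numeric(windows[[i]])
    a <- anchors[i]
    pre <- resample_linear(w[seq_len(a)], La)
    post <- resample_linear(w[a:length(w)], L - La + 1L)
    c(pre, post[-1])
  }, numeric(L))
  rescale01 <- function(v) {
    lo <- min(v)
    denom <- v[La] - lo
    if (denom <= 0) {
      stop_fbg("anchor value equals the beat minimum: normalization degenerate",
               "fbgbp_degenerate_beat")
    }
    (v - lo) / denom
  }
  if (order == "normalize_first") std <- apply(std, 2, rescale01)
  avg <- rescale01(rowMeans(std))
  if (which.max(avg) != La) {
    rlang::warn("anchor is not the maximum of the averaged beat; values exceed 1")
  }
  out <- tibble::tibble(
    position = seq_len(L),
    frac = (seq_len(L) - 1) / (L - 1),
    amplitude = avg
  )
  class(out) <- c("normalized_beat", class(out))
  attr(out, "L") <- L
  attr(out, "anchor_index") <- La
  attr(out, "n_beats") <- length(windows)
  out
}

#' Discrete second derivative of a waveform
#'
#' Central second difference scaled by the squared sample interval; the two
#' endpoints use the adjacent one-sided estimate. Applied to a pulse waveform
#' this yields the acceleration pulse wave.
#'
#' @param x Numeric vector or a `normalized_beat`.
#' @param fs_effective Effective sampling rate of `x` (samples per second, or
#'   per beat-fraction unit for normalized beats). Default 1, i.e. unit
#'   sample spacing.
#' @return Numeric vector (vector input) or tibble with `position`, `frac`,
#'   `d2` (beat input).
#' @export
second_derivative <- function(x, fs_effective = 1) {
  beat_in <- inherits(x, "normalized_beat")
  v <- if (beat_in) x$amplitude else as.numeric(x)
  n <- length(v)
  if (n < 5) stop_fbg("need at least 5 samples", "fbgbp_invalid_input")
  dt2 <- (1 / fs_effective)^2
  d2 <- c(NA_real_, (v[1:(n - 2)] - 2 * v[2:(n - 1)] + v[3:n]) / dt2, NA_real_)
  d2[1] <- d2[2]
  d2[n] <- d2[n - 1]
  if (beat_in) tibble::tibble(position = x$position, frac = x$frac, d2 = d2) else d2
}

#' Locate the A-E peaks of an acceleration-pulse-wave beat
#'
#' On the normalized averaged beat, peak A is the global maximum (the early
#' systolic positive wave). B is the first local minimum after A (early
#' systolic negative wave), C the next local maximum (late systolic
#' re-increasing wave), D the next local minimum, and E the next local maximum
#' (early diastolic positive wave). Amplitudes are reported relative to the
#' diastolic baseline, estimated as the mean of the first and last 5 percent
#' of samples, so B and D come out negative for a healthy-pattern beat. An
#' extremum that does not exist in the waveform is reported as missing, never
#' fabricated.
#'
#' @param beat A `normalized_beat` (or plain numeric vector).
#' @return A tibble with one row per peak A-E: `peak`, `present`, `position`
#'   (sample index), `frac` and `amplitude` (baseline-relative).
#' @export
detect_peaks_abcde <- function(beat) {
  v <- if (inherits(beat, "normalized_beat") || is.data.frame(beat)) {
    beat$amplitude
  } else {
    as.numeric(beat)
  }
  n <- length(v)
  if (n < 8) stop_fbg("beat too short", "fbgbp_invalid_input")
  if (max(v) - min(v) <= 1e-12) {
    stop_fbg("flat beat: no distinguishable maximum", "fbgbp_degenerate_beat")
  }
  nb <- max(2L, round(0.05 * n))
  baseline <- mean(v[c(seq_len(nb), (n - nb + 1):n)])
  next_extremum <- function(from, type) {
    i <- from + 1L
    while (i < n) {
      if (type == "min" && v[i] < v[i - 1] && v[i] <= v[i + 1]) return(i)
      if (type == "max" && v[i] > v[i - 1] && v[i] >= v[i + 1]) return(i)
      i <- i + 1L
    }
    NA_integer_
  }
  idx <- c(A = which.max(v), B = NA_integer_, C = NA_integer_,
           D = NA_integer_, E = NA_integer_)
  types <- c(B = "min", C = "max", D = "min", E = "max")
  prev <- idx[["A"]]
  for (p in names(types)) {
    if (is.na(prev)) break
    idx[[p]] <- next_extremum(prev, types[[p]])
    prev <- idx[[p]]
  }
  tibble::tibble(
    peak = names(idx),
    present = !is.na(idx),
    position = as.integer(idx),
    frac = ifelse(is.na(idx), NA_real_, (idx - 1) / (n - 1)),
    amplitude = ifelse(is.na(idx), NA_real_, v[idx] - baseline)
  )
}
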