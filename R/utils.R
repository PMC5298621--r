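# Internal helpers shared across the pipeline.

stop_fbg <- function(msg, class, ...) {
  rlang::abort(sprintf(msg, ...), class = c(class, "fbgbp_error"))
}

#' Derive a reproducible sub-stream seed from a master seed
#'
#' All randomness in the package flows from one master seed through named
#' sub-streams (subject / record / channel), so that e.g. adding validation
#' records never perturbs the calibration stream. The derivation is a simple
#' polynomial string hash of the master seed plus the stream labels, reduced
#' modulo 2^31 - 1 so the result is always a valid R integer seed.
#'
#' @param seed Integer master seed.
#' @param ... Stream labels (coerced to character).
#' @return A single integer in `[0, 2^31 - 2]`.
#' @export
#' @examples
#' derive_seed(1, "subject_A", "record", 7)
derive_seed <- function(seed, ...) {
  key <- paste(c(as.character(seed), vapply(list(...), as.character, "")),
               collapse = "/")
  h <- 17
  for (b in utf8ToInt(key)) h <- (h * 31 + b) %% 2147483647
  as.integer(h)
}

# Evaluate code under a temporary RNG seed (restoring global RNG state);
# seed = NULL means "use the ambient RNG stream".
with_seed_maybe <- function(seed, code) {
  if (is.null(seed)) code else withr::with_seed(as.integer(seed), code)
}

# Infer a sampling rate from a time column, enforcing uniform spacing.
infer_fs <- function(time_s, tol = 1e-6) {
  if (length(time_s) < 2) {
    stop_fbg("need at least two samples to infer a sampling rate",
             "fbgbp_invalid_input")
  }
  dt <- diff(time_s)
  dt0 <- median(dt)
  if (dt0 <= 0 || any(abs(dt - dt0) > tol * dt0 + 1e-12)) {
    stop_fbg("time column is not uniformly sampled", "fbgbp_invalid_input")
  }
  1 / dt0
}

# Accept either (numeric vector, fs) or a data frame with a time column plus
# one value column; return list(x, fs, time).
as_trace <- function(x, fs = NULL, value_col = NULL) {
  if (is.data.frame(x)) {
    time_col <- intersect(c("time_s", "time"), names(x))[1]
    if (is.na(time_col)) {
      stop_fbg("data-frame input needs a 'time_s' column", "fbgbp_invalid_input")
    }
    value_col <- value_col %||% setdiff(names(x), time_col)[1]
    if (!value_col %in% names(x)) value_col <- setdiff(names(x), time_col)[1]
    fs <- fs %||% infer_fs(x[[time_col]])
    list(x = as.numeric(x[[value_col]]), fs = fs, time = x[[time_col]])
  } else {
    if (is.null(fs)) {
      stop_fbg("'fs' is required when the input is a bare numeric vector",
               "fbgbp_invalid_input")
    }
    x <- as.numeric(x)
    list(x = x, fs = fs, time = (seq_along(x) - 1) / fs)
  }
}

# Force successive phase differences into (-pi, pi] and integrate back.
unwrap_phase <- function(phi) {
  if (length(phi) < 2) return(phi)
  d <- diff(phi)
  d <- d - 2 * pi * ceiling((d - pi) / (2 * pi))
  phi[1] + cumsum(c(0, d))
}

# Linear resampling of a numeric vector onto L points spanning its support.
resample_linear <- function(x, L) {
  n <- length(x)
  if (n == 1L) return(rep(x, L))
  approx(seq_len(n), x, xout = seq(1, n, length.out = L))$y
}

check_scalar_positive <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1 || !is.finite(x) || x <= 0) {
    stop_fbg("'%s' must be a single positive finite number", "fbgbp_domain_error",
             name)
  }
  invisible(x)
}
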