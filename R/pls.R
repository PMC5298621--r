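# PLS1 calibration: NIPALS fit, leave-one-out PRESS, sequential F-test factor
# selection and SEP/R evaluation. The regression itself is implemented here
# from first principles -- it is the core of the calibration method.

# Resolve (X, y) from a beat-data tibble (list column `beat` + reference
# column) or a plain matrix / vector pair.
resolve_xy <- function(x, y = NULL) {
  if (is.data.frame(x) && "beat" %in% names(x)) {
    X <- do.call(rbind, lapply(x$beat, as.numeric))
    if (is.null(y)) {
      ycol <- intersect(c("bp_ref_mmHg", "reference_bp_mmHg", "y"), names(x))[1]
      if (is.na(ycol)) {
        stop_fbg("no reference pressure column found (expected 'bp_ref_mmHg')",
                 "fbgbp_invalid_input")
      }
      y <- x[[ycol]]
    }
  } else {
    X <- as.matrix(x)
    if (is.null(y)) stop_fbg("'y' is required", "fbgbp_invalid_input")
  }
  storage.mode(X) <- "double"
  y <- as.numeric(y)
  if (nrow(X) != length(y)) {
    stop_fbg("X has %d rows but y has %d values", "fbgbp_invalid_input",
             nrow(X), length(y))
  }
  if (anyNA(X) || anyNA(y) || !all(is.finite(X)) || !all(is.finite(y))) {
    stop_fbg("X and y must be finite with no missing values", "fbgbp_invalid_input")
  }
  list(X = X, y = y)
}

centered_rank <- function(X) {
  qr(scale(X, center = TRUE, scale = FALSE))$rank
}

#' Fit a PLS1 calibration model
#'
#' NIPALS partial least squares with a single response: on mean-centered
#' `X`, `y`, each factor takes the weight vector proportional to `X'y`
#' (normalized), scores `t = X w`, loadings `p = X't / t't`,
#' `q = y't / t't`, then deflates `X <- X - t p'` and `y <- y - q t`. The
#' regression vector is `b = W (P'W)^{-1} q`, giving predictions
#' `y_mean + (x - x_mean) b`. Columns are not variance-scaled: normalized
#' beats already share the `[0, 1]` scale.
#'
#' @param x Predictor matrix (rows = normalized beats), or a beat-data tibble
#'   with a `beat` list column and a `bp_ref_mmHg` column.
#' @param y Reference pressures in mmHg (omit for tibble input).
#' @param k Number of PLS factors, `1 <= k <= min(n - 1, rank of centered X)`.
#' @return An object of class `fbg_pls` with elements `x_mean`, `y_mean`,
#'   `weights`, `x_loadings`, `y_loadings`, `coefficients` (the regression
#'   vector, mmHg per unit beat amplitude), `k`, `n`, `fitted`, `residuals`.
#' @export
#' @examples
#' X <- matrix(rnorm(40), 10, 4)
#' y <- X %*% c(1, -1, 0.5, 0) + 100
#' fit <- fit_pls(X, as.numeric(y), k = 2)
#' glance(fit)
fit_pls <- function(x, y = NULL, k) {
  d <- resolve_xy(x, y)
  X <- d$X
  y <- d$y
  n <- nrow(X)
  p <- ncol(X)
  if (n < 3) stop_fbg("need at least 3 observations", "fbgbp_invalid_input")
  if (var(y) == 0) stop_fbg("y has zero variance", "fbgbp_domain_error")
  k <- as.integer(k)
  rk <- centered_rank(X)
  k_cap <- min(n - 1L, rk)
  if (k < 1 || k > k_cap) {
    stop_fbg("k = %d outside [1, %d] (n = %d, rank of centered X = %d)",
             "fbgbp_domain_error", k, k_cap, n, rk)
  }
  x_mean <- colMeans(X)
  y_mean <- mean(y)
  Xc <- sweep(X, 2, x_mean)
  yc <- y - y_mean
  W <- P <- matrix(0, p, k)
  qvec <- numeric(k)
  for (a in seq_len(k)) {
    w <- drop(crossprod(Xc, yc))
    nw <- sqrt(sum(w^2))
    if (nw < 1e-300) {
      stop_fbg("factor %d has a null weight vector: k exceeds usable rank",
               "fbgbp_domain_error", a)
    }
    w <- w / nw
    t_sc <- drop(Xc %*% w)
    tt <- sum(t_sc^2)
    if (tt < 1e-300) {
      stop_fbg("factor %d has a null score: k exceeds usable rank",
               "fbgbp_domain_error", a)
    }
    p_ld <- drop(crossprod(Xc, t_sc)) / tt
    q_ld <- sum(yc * t_sc) / tt
    Xc <- Xc - tcrossprod(t_sc, p_ld)
    yc <- yc - q_ld * t_sc
    W[, a] <- w
    P[, a] <- p_ld
    qvec[a] <- q_ld
  }
  b <- drop(W %*% solve(crossprod(P, W), qvec))
  fitted <- drop(y_mean + sweep(X, 2, x_mean) %*% b)
  structure(
    list(x_mean = x_mean, y_mean = y_mean, weights = W, x_loadings = P,
         y_loadings = qvec, coefficients = b, k = k, n = n, L = p,
         fitted = fitted, residuals = y - fitted),
    class = "fbg_pls"
  )
}

#' @export
print.fbg_pls <- function(x, ...) {
  cat(sprintf("<fbg_pls> PLS1 calibration: %d factor(s), n = %d beats of length %d\n",
              x$k, x$n, x$L))
  cat(sprintf("  training RMSE: %.3f mmHg\n", sqrt(mean(x$residuals^2))))
  invisible(x)
}

#' Predict blood pressure from normalized beats
#'
#' @param object A fitted `fbg_pls` model.
#' @param newdata A matrix with `L` columns, a beat-data tibble with a `beat`
#'   list column, a single `normalized_beat`, or a bare length-`L` vector.
#' @param ... Unused.
#' @return Numeric vector of predicted pressures, mmHg.
#' @export
predict.fbg_pls <- function(object, newdata, ...) {
  X <- if (inherits(newdata, "normalized_beat")) {
    matrix(newdata$amplitude, nrow = 1)
  } else if (is.data.frame(newdata) && "beat" %in% names(newdata)) {
    do.call(rbind, lapply(newdata$beat, as.numeric))
  } else if (is.matrix(newdata)) {
    newdata
  } else {
    matrix(as.numeric(newdata), nrow = 1)
  }
  if (ncol(X) != object$L) {
    stop_fbg("beat length %d does not match the model's L = %d",
             "fbgbp_invalid_input", ncol(X), object$L)
  }
  drop(object$y_mean + sweep(X, 2, object$x_mean) %*% object$coefficients)
}

#' Leave-one-out PRESS of a PLS1 model
#'
#' For each observation `i` the model is refitted with `k` factors on the
#' remaining rows and used to predict `y_i`; PRESS is the sum of the squared
#' prediction errors. `k = 0` uses the mean-only model (predicting each
#' held-out value by the mean of the others), which anchors the factor
#' selection sequence.
#'
#' @inheritParams fit_pls
#' @param k Number of factors, `0 <= k <= min(n - 2, rank)`.
#' @return PRESS in mmHg squared.
#' @export
loo_press <- function(x, y = NULL, k) {
  d <- resolve_xy(x, y)
  X <- d$X
  y <- d$y
  n <- nrow(X)
  if (n < 3) stop_fbg("need at least 3 observations for leave-one-out",
                      "fbgbp_invalid_input")
  k <- as.integer(k)
  if (k == 0L) {
    loo_mean <- (sum(y) - y) / (n - 1)
    return(sum((y - loo_mean)^2))
  }
  k_cap <- min(n - 2L, centered_rank(X))
  if (k < 0 || k > k_cap) {
    stop_fbg("k = %d outside [0, %d] for leave-one-out", "fbgbp_domain_error",
             k, k_cap)
  }
  press <- 0
  for (i in seq_len(n)) {
    fit <- fit_pls(X[-i, , drop = FALSE], y[-i], k)
    press <- press + (predict(fit, X[i, , drop = FALSE]) - y[i])^2
  }
  press
}

#' Choose the number of PLS factors by sequential PRESS F-tests
#'
#' Starting from the mean-only model (`k = 0`), the factor count is grown one
#' factor at a time. At each step the ratio `F = PRESS(k) / PRESS(k + 1)` is
#' compared with the upper critical value of the F distribution with
#' `(n, n)` degrees of freedom at level `alpha`: a significant reduction in
#' leave-one-out error admits the factor, the first non-significant step
#' stops the sequence and the smaller model is kept. At least one factor is
#' always returned -- a zero-factor model is not a calibration curve.
#'
#' @inheritParams fit_pls
#' @param k_max Largest factor count to consider (capped at `n - 2` and the
#'   rank of centered `X`).
#' @param alpha Significance level of each F-test, default 0.05.
#' @return A list of class `fbg_factor_selection`: `k` (selected count),
#'   `path` (tibble of tested steps with PRESS values, F statistics and
#'   critical values) and `alpha`.
#' @export
select_factors <- function(x, y = NULL, k_max = 10, alpha = 0.05) {
  d <- resolve_xy(x, y)
  X <- d$X
  y <- d$y
  n <- nrow(X)
  if (k_max < 1) stop_fbg("k_max must be >= 1", "fbgbp_domain_error")
  k_cap <- min(as.integer(k_max), n - 2L, centered_rank(X))
  f_crit <- qf(1 - alpha, n, n)
  k <- 0L
  press_k <- loo_press(X, y, 0L)
  steps <- list()
  while (k < k_cap) {
    press_next <- loo_press(X, y, k + 1L)
    f_stat <- if (press_next > 0) {
      press_k / press_next
    } else if (press_k > 0) Inf else 1  # both exactly zero: no improvement
    added <- f_stat > f_crit
    steps[[length(steps) + 1]] <- tibble::tibble(
      k_from = k, k_to = k + 1L, press_from = press_k, press_to = press_next,
      f = f_stat, f_crit = f_crit, added = added
    )
    if (!added) break
    k <- k + 1L
    press_k <- press_next
  }
  structure(
    list(k = max(k, 1L),
         path = if (length(steps)) dplyr::bind_rows(steps) else tibble::tibble(),
         alpha = alpha, n = n),
    class = "fbg_factor_selection"
  )
}

#' @export
print.fbg_factor_selection <- function(x, ...) {
  cat(sprintf("<fbg_factor_selection> k* = %d (alpha = %g, n = %d)\n",
              x$k, x$alpha, x$n))
  if (nrow(x$path)) print(x$path)
  invisible(x)
}

#' Fit a PLS1 calibration with automatic factor selection
#'
#' Convenience wrapper: [select_factors()] followed by [fit_pls()] at the
#' selected factor count. The selection path is attached as attribute
#' `selection`.
#'
#' @inheritParams select_factors
#' @return An `fbg_pls` model.
#' @export
fit_pls_cv <- function(x, y = NULL, k_max = 10, alpha = 0.05) {
  sel <- select_factors(x, y, k_max = k_max, alpha = alpha)
  fit <- fit_pls(x, y, k = sel$k)
  attr(fit, "selection") <- sel
  fit
}

#' Evaluate a calibration curve on a validation set
#'
#' Computes the standard error of prediction
#' `SEP = sqrt(sum((yhat - y)^2) / (n - 1))` (the "measurement accuracy" in
#' mmHg), the mean error (bias) and the Pearson correlation between predicted
#' and reference pressure. With a zero-variance reference the correlation is
#' undefined and reported as `NA`.
#'
#' @param model A fitted `fbg_pls`.
#' @param x_val Validation beats (matrix or beat-data tibble).
#' @param y_val Validation reference pressures (omit for tibble input).
#' @return A one-row tibble: `n`, `k`, `r`, `sep_mmHg`, `bias_mmHg`.
#' @export
evaluate_model <- function(model, x_val, y_val = NULL) {
  d <- resolve_xy(x_val, y_val)
  if (nrow(d$X) < 2) {
    stop_fbg("validation set needs at least 2 records", "fbgbp_invalid_input")
  }
  yhat <- predict(model, d$X)
  y <- d$y
  n <- length(y)
  r <- if (var(y) > 0 && var(yhat) > 0) cor(yhat, y) else NA_real_
  tibble::tibble(
    n = n,
    k = model$k,
    r = r,
    sep_mmHg = sqrt(sum((yhat - y)^2) / (n - 1)),
    bias_mmHg = mean(yhat - y)
  )
}

#' @describeIn fit_pls Tidy the regression vector: one row per beat position
#'   with the corresponding coefficient (mmHg per unit amplitude).
#' @export
tidy.fbg_pls <- function(x, ...) {
  tibble::tibble(
    position = seq_len(x$L),
    frac = (seq_len(x$L) - 1) / (x$L - 1),
    estimate = x$coefficients
  )
}

#' @describeIn fit_pls One-row model summary: factor count, training RMSE and
#'   training correlation.
#' @export
glance.fbg_pls <- function(x, ...) {
  y <- x$fitted + x$residuals
  tibble::tibble(
    n = x$n,
    L = x$L,
    k = x$k,
    rmse_train = sqrt(mean(x$residuals^2)),
    r_train = if (var(y) > 0 && var(x$fitted) > 0) cor(x$fitted, y) else NA_real_
  )
}

#' Serialize a PLS calibration model to JSON
#'
#' Stores centering parameters, weights, loadings, the factor count and
#' package version; [read_pls_model()] reconstitutes the model and recomputes
#' the regression vector from the stored weights and loadings.
#'
#' @param model An `fbg_pls`.
#' @param path Output file path.
#' @param seed Optional creation seed recorded as metadata.
#' @return `path`, invisibly.
#' @export
write_pls_model <- function(model, path, seed = NULL) {
  payload <- list(
    format = "fbgbp-pls-model",
    version = as.character(packageVersion("fbgbp")),
    L = model$L, n = model$n, k = model$k,
    seed = seed,
    x_mean = model$x_mean, y_mean = model$y_mean,
    weights = model$weights, x_loadings = model$x_loadings,
    y_loadings = model$y_loadings
  )
  jsonlite::write_json(payload, path, digits = NA, auto_unbox = TRUE)
  invisible(path)
}

#' @rdname write_pls_model
#' @export
read_pls_model <- function(path) {
  p <- jsonlite::read_json(path, simplifyVector = TRUE)
  W <- matrix(p$weights, ncol = p$k)
  P <- matrix(p$x_loadings, ncol = p$k)
  qvec <- as.numeric(p$y_loadings)
  b <- drop(W %*% solve(crossprod(P, W), qvec))
  structure(
    list(x_mean = as.numeric(p$x_mean), y_mean = p$y_mean, weights = W,
         x_loadings = P, y_loadings = qvec, coefficients = b,
         k = as.integer(p$k), n = as.integer(p$n), L = as.integer(p$L),
         fitted = NULL, residuals = NULL),
    class = "fbg_pls"
  )
}
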