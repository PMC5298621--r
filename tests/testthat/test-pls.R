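test_that("PLS reaches the exact-fit limit and matches least squares at full rank", {
  withr::with_seed(101, {
    for (dims in list(c(20, 5), c(16, 3), c(30, 8))) {
      n <- dims[1]
      p <- dims[2]
      X <- matrix(rnorm(n * p), n, p)
      b_true <- rnorm(p)
      y <- drop(X %*% b_true) + 110
      fit <- fit_pls(X, y, k = p)
      expect_lt(sqrt(mean(fit$residuals^2)), 1e-8)
      # and for noisy y, full-rank PLS equals the normal-equations solution
      y2 <- y + rnorm(n, 0, 3)
      fit2 <- fit_pls(X, y2, k = p)
      Xnew <- matrix(rnorm(5 * p), 5, p)
      expect_lt(max(abs(predict(fit2, Xnew) - ols_oracle_predict(X, y2, Xnew))),
                1e-8)
    }
  })
})

test_that("a single latent factor is captured by k = 1 at moderate SNR", {
  withr::with_seed(7, {
    n <- 60
    p <- 40
    t_sc <- rnorm(n)
    p_ld <- rnorm(p)
    p_ld <- p_ld / sqrt(sum(p_ld^2))
    signal <- tcrossprod(t_sc, p_ld)
    noise_sd <- sqrt(var(as.vector(signal)) / 10)  # SNR 10
    X <- signal + matrix(rnorm(n * p, 0, noise_sd), n, p)
    y <- 5 * t_sc + 100
    fit <- fit_pls(X, y, k = 1)
    r2 <- 1 - sum(fit$residuals^2) / sum((y - mean(y))^2)
    expect_gte(r2, 0.95)
  })
})

test_that("prediction is the centered affine map", {
  withr::with_seed(11, {
    X <- matrix(runif(48), 12, 4)
    y <- 100 + 20 * X[, 1] - 10 * X[, 3] + rnorm(12, 0, 0.5)
    fit <- fit_pls(X, y, k = 2)
    expect_equal(predict(fit, matrix(fit$x_mean, 1)), fit$y_mean)
    a <- X[1, , drop = FALSE]
    b <- X[2, , drop = FALSE]
    expect_equal(predict(fit, (a + b) / 2),
                 mean(predict(fit, rbind(a, b))), tolerance = 1e-12)
    expect_error(predict(fit, matrix(0, 1, 7)), class = "fbgbp_invalid_input")
    # adding a constant to y shifts predictions by exactly that constant
    fit2 <- fit_pls(X, y + 50, k = 2)
    expect_equal(predict(fit2, X), predict(fit, X) + 50, tolerance = 1e-9)
  })
})

test_that("fit_pls validates k, y variance and missing values", {
  X <- matrix(rnorm(40), 10, 4)
  expect_error(fit_pls(X, rep(5, 10), k = 1), class = "fbgbp_domain_error")
  expect_error(fit_pls(X, rnorm(10), k = 5), class = "fbgbp_domain_error")
  expect_error(fit_pls(X, rnorm(10), k = 0), class = "fbgbp_domain_error")
  Xna <- X
  Xna[2, 2] <- NA
  expect_error(fit_pls(Xna, rnorm(10), k = 1), class = "fbgbp_invalid_input")
  # rank-deficient X caps k at the rank
  Xdef <- cbind(X[, 1], X[, 1], X[, 2])
  expect_error(fit_pls(Xdef, rnorm(10), k = 3), class = "fbgbp_domain_error")
})

test_that("PRESS(0) equals hand arithmetic and PRESS matches the brute-force oracle", {
  X3 <- matrix(rnorm(6), 3, 2)
  expect_equal(loo_press(X3, c(1, 2, 3), k = 0), 4.5)

  fx <- press_fixture()
  expect_equal(loo_press(fx$X, fx$y, k = 1),
               loo_press_oracle(fx$X, fx$y, k = 1), tolerance = 1e-8)

  withr::with_seed(23, {
    X <- matrix(rnorm(10 * 4), 10, 4)
    y <- drop(X %*% c(2, -1, 0.5, 0)) + 110 + rnorm(10, 0, 0.3)
    for (k in 1:3) {
      expect_equal(loo_press(X, y, k), loo_press_oracle(X, y, k),
                   tolerance = 1e-8)
    }
  })
})

test_that("PRESS shows the overfitting pattern: drops to k*, rises beyond", {
  # exact-fit limit: PRESS bottoms out near zero at full rank and every
  # smaller model is no better
  withr::with_seed(29, {
    X <- matrix(rnorm(20 * 4), 20, 4)
    y <- 110 + drop(X %*% c(3, -2, 1, 0.5))
    press <- vapply(0:4, function(k) loo_press(X, y, k), numeric(1))
    expect_lt(press[5], 1e-10)
    expect_true(all(press[1:4] >= press[5]))
  })
  # noisy small-sample case: extra factors chase noise and LOO error rises
  withr::with_seed(33, {
    n <- 12
    p <- 8
    X <- matrix(rnorm(n * p), n, p)
    y <- drop(X %*% c(3, -2, rep(0, p - 2))) + 110 + rnorm(n, 0, 1.5)
    press <- vapply(0:6, function(k) loo_press(X, y, k), numeric(1))
    expect_lt(min(press[2:4]), press[1])   # real structure helps at first
    expect_gt(press[7], min(press[1:4]))   # far past k*, PRESS has risen
  })
})

test_that("factor selection keeps one factor for noise and stops on flat PRESS", {
  withr::with_seed(41, {
    X <- matrix(rnorm(30 * 10), 30, 10)
    y <- rnorm(30, 110, 5)   # independent of X
    sel <- select_factors(X, y, k_max = 4)
    expect_s3_class(sel, "fbg_factor_selection")
    expect_equal(sel$k, 1L)
    expect_false(sel$path$added[1])
  })
})

test_that("factor selection finds planted two-factor structure", {
  withr::with_seed(43, {
    n <- 40
    p <- 20
    q1 <- qr.Q(qr(matrix(rnorm(p * 2), p, 2)))
    t1 <- rnorm(n, 0, 3)   # dominates X variance
    t2 <- rnorm(n)
    signal <- tcrossprod(t1, q1[, 1]) + tcrossprod(t2, q1[, 2])
    noise_sd <- sqrt(var(as.vector(signal)) / 20)
    X <- signal + matrix(rnorm(n * p, 0, noise_sd), n, p)
    y <- t1 / 3 + t2       # both latents equally relevant for y
    y <- y + rnorm(n, 0, sqrt(var(y) / 20))
    sel <- select_factors(X, y, k_max = 5)
    expect_equal(sel$k, 2L)
  })
})

test_that("evaluation reports SEP, correlation and bias correctly", {
  withr::with_seed(53, {
    n <- 12
    X <- matrix(rnorm(n * 3), n, 3)
    y <- drop(X %*% c(4, -2, 1)) + 110
    fit <- fit_pls(X, y, k = 3)   # exact fit
    perfect <- evaluate_model(fit, X, y)
    expect_equal(perfect$sep_mmHg, 0, tolerance = 1e-7)
    expect_equal(perfect$r, 1, tolerance = 1e-7)
    expect_equal(perfect$bias_mmHg, 0, tolerance = 1e-7)

    # constant offset c: bias c, r = 1, sep = |c| * sqrt(n / (n - 1))
    cst <- 3.5
    off <- evaluate_model(fit, X, y - cst)
    expect_equal(off$bias_mmHg, cst, tolerance = 1e-7)
    expect_equal(off$r, 1, tolerance = 1e-7)
    expect_equal(off$sep_mmHg, cst * sqrt(n / (n - 1)), tolerance = 1e-7)

    # zero-variance reference: r is undefined
    flat <- evaluate_model(fit, X, rep(110, n))
    expect_true(is.na(flat$r))
    expect_gt(flat$sep_mmHg, 0)
  })
})

test_that("tidy and glance expose the regression vector and fit summary", {
  withr::with_seed(61, {
    X <- matrix(runif(60), 15, 4)
    y <- 100 + drop(X %*% c(5, 0, -3, 1)) + rnorm(15, 0, 0.2)
    fit <- fit_pls(X, y, k = 2)
    td <- tidy(fit)
    expect_equal(names(td), c("position", "frac", "estimate"))
    expect_equal(nrow(td), 4)
    expect_equal(td$estimate, fit$coefficients)
    gl <- glance(fit)
    expect_equal(gl$k, 2)
    expect_equal(gl$n, 15)
    expect_gt(gl$r_train, 0.9)
  })
})

test_that("models survive JSON serialization bit-faithfully", {
  withr::with_seed(71, {
    X <- matrix(rnorm(80), 20, 4)
    y <- 110 + drop(X %*% c(2, 1, -1, 0.5)) + rnorm(20, 0, 0.3)
    fit <- fit_pls(X, y, k = 3)
    path <- withr::local_tempfile(fileext = ".json")
    write_pls_model(fit, path, seed = 99)
    back <- read_pls_model(path)
    expect_equal(back$coefficients, fit$coefficients, tolerance = 1e-12)
    expect_equal(predict(back, X), predict(fit, X), tolerance = 1e-12)
    expect_equal(back$k, fit$k)
  })
})

test_that("beat-data tibbles are accepted directly by the fitting interface", {
  withr::with_seed(83, {
    X <- matrix(runif(60), 15, 4)
    y <- 100 + drop(X %*% c(5, -2, 1, 0)) + rnorm(15, 0, 0.2)
    bd <- tibble::tibble(beat = lapply(seq_len(15), function(i) X[i, ]),
                         bp_ref_mmHg = y)
    fit_a <- fit_pls(bd, k = 2)
    fit_b <- fit_pls(X, y, k = 2)
    expect_equal(fit_a$coefficients, fit_b$coefficients, tolerance = 1e-12)
    expect_equal(predict(fit_a, bd), predict(fit_b, X), tolerance = 1e-12)
  })
})
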