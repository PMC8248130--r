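test_that("goodness statistics match hand arithmetic", {
  cv <- survival_curve(c(0, 2, 4), mean = c(1, 0.5, 0.1))
  st <- goodness_stats(cv, fitted = c(1, 0.4, 0.12))
  expect_equal(st$rss, 0.0104)
  expect_equal(st$r, (0 + 0.2 + 0.2) / 3)
  expect_equal(st$sss, sum((c(1, 0.5, 0.1) - mean(c(1, 0.5, 0.1)))^2))
  expect_equal(st$r2, 1 - st$rss / st$sss)
  expect_true(is.na(st$e))  # no replicate SDs anywhere

  # perfect fit
  st0 <- goodness_stats(cv, fitted = cv$mean)
  expect_equal(st0$r2, 1)
  expect_identical(st0$rss, 0)
  expect_identical(st0$r, 0)
})

test_that("relative experimental error e averages sd/mean over points with SD", {
  cv <- survival_curve(c(0, 2, 4),
                       replicates = list(1, c(0.5, 0.6), c(0.10, 0.12)))
  st <- goodness_stats(cv, fitted = cv$mean)
  expect_equal(st$e, mean(c(sd(c(0.5, 0.6)) / 0.55, sd(c(0.1, 0.12)) / 0.11)))
})

test_that("R^2 is undefined when all means are equal", {
  cv <- survival_curve(c(1, 2, 3), mean = c(0.4, 0.4, 0.4), add_zero = FALSE)
  expect_true(is.na(goodness_stats(cv, fitted = cv$mean)$r2))
})

test_that("fit_uma recovers exact model parameters across the domain", {
  for (i in seq_len(nrow(param_grid))) {
    do <- param_grid$do[i]; n <- param_grid$n[i]
    cv <- exact_curve(uma_params(do, n), doses = seq(0, 6 * do, length.out = 13))
    f <- fit_uma(cv)
    expect_lt(abs(f$params$do - do) / do, 1e-6)
    expect_lt(abs(f$params$n - n) / n, 1e-6)
    expect_lt(f$r, 1e-8)
    expect_equal(f$r2, 1, tolerance = 1e-12)
  }
})

test_that("the linearization maps exact data onto the line y = D/Do", {
  p <- uma_params(1.5, 5)
  d <- 0:12
  s <- uma_survival(p, d)
  y <- log(p$n / s + 1 - p$n)
  expect_equal(y, d / p$do, tolerance = 1e-9)
})

test_that("single-exponential data yield n = 1 and the decay slope", {
  cv <- exact_curve(uma_params(2.8, 1), doses = 0:10)
  f <- fit_uma(cv)
  expect_lt(abs(f$params$n - 1), 1e-3)
  expect_lt(abs(f$params$do - 2.8), 1e-3 * 2.8)
})

test_that("fits are deterministic and self-consistent with goodness_stats", {
  cv <- generate_curve(uma_params(2.2, 2.8), doses = seq(0, 14, by = 2),
                       noise_sigma = 0.08, seed = 11)
  f1 <- fit_uma(cv); f2 <- fit_uma(cv)
  expect_identical(f1$params, f2$params)
  for (f in list(f1, fit_lq(cv), fit_mt(cv))) {
    st <- goodness_stats(cv, f$fitted)
    expect_equal(f$r2, st$r2)
    expect_equal(f$r, st$r)
    expect_equal(f$rss, st$rss)
  }
})

test_that("fit_lq recovers exact LQ coefficients and needs 3+ points", {
  d <- seq(0, 8, by = 1)
  cv <- survival_curve(d, mean = exp(-0.13 * d - 0.06 * d^2))
  f <- fit_lq(cv)
  expect_equal(f$params$alpha, 0.13, tolerance = 1e-9)
  expect_equal(f$params$beta, 0.06, tolerance = 1e-9)
  expect_error(fit_lq(cv, dose_range = c(7.5, 8.5)), ">= 3 points")
})

test_that("LQ alpha/beta is sensitive to the fitted dose range on curved data", {
  cv <- exact_curve(uma_params(2.20, 2.8), doses = seq(0, 14, by = 1))
  ab_low <- fit_lq(cv, dose_range = c(0, 10))$params$alpha_beta
  ab_full <- fit_lq(cv, dose_range = c(0, 14))$params$alpha_beta
  expect_gt(abs(ab_full - ab_low) / abs(ab_low), 0.05)
  expect_gt(ab_full, ab_low)  # widening the range raises the ratio
})

test_that("LQ and UMA agree inside the fitted range but LQ underestimates
           high-dose survival on shouldered data", {
  p <- uma_params(1.5, 5)
  cv <- exact_curve(p, doses = seq(0, 6, by = 0.5))
  lq <- fit_lq(cv)
  expect_lt(max(abs(lq$fitted - cv$mean)), 0.02)      # agreement in range
  expect_lt(predict(lq, 14), uma_survival(p, 14))     # divergence beyond
  expect_gt(uma_survival(p, 14) / predict(lq, 14), 2)
})

test_that("fit_mt recovers the multitarget asymptote and overestimates the
           shoulder", {
  d <- c(0, 4, 6, 8, 10)
  cv <- survival_curve(d, mean = pmin(5.4 * exp(-d / 1.35), 1))
  f <- fit_mt(cv, min_dose = 3)
  expect_equal(f$params$do, 1.35, tolerance = 1e-9)
  expect_equal(f$params$n, 5.4, tolerance = 1e-9)
  expect_gt(f$fitted[1], 1)  # back-extrapolated intercept exceeds S(0) = 1

  # on shouldered model data the tail fit overestimates low-dose survival
  p <- uma_params(1.5, 5)
  cvs <- exact_curve(p, doses = 0:12)
  fm <- fit_mt(cvs)
  expect_gt(predict(fm, 1), uma_survival(p, 1))

  # pure exponential: intercept ~ 0 so n ~ 1
  cve <- exact_curve(uma_params(2, 1), doses = 0:10)
  expect_equal(fit_mt(cve)$params$n, 1, tolerance = 1e-9)
  expect_error(fit_mt(cve, min_dose = 9.5), ">= 2 points")
})

test_that("two-population mixtures are recovered from exact data", {
  mix <- uma_mixture(list(uma_params(2.80, 1), uma_params(2.70, 58)))
  cv <- exact_curve(mix, doses = seq(0, 30, by = 2))
  f <- fit_uma_mixture(cv)
  expect_s3_class(f$params, "uma_mixture")
  dos <- vapply(f$params$components, `[[`, numeric(1), "do")
  ns <- vapply(f$params$components, `[[`, numeric(1), "n")
  expect_true(all(diff(dos) <= 0))  # sorted most radioresistant first
  expect_lt(abs(dos[1] - 2.80) / 2.80, 0.05)
  expect_lt(abs(dos[2] - 2.70) / 2.70, 0.05)
  expect_lt(abs(ns[2] - 58) / 58, 0.05)
  expect_lt(f$r, 1e-4)
  expect_identical(uma_survival(f$params, 0), 1)
})

test_that("degenerate mixture settings reduce sensibly", {
  cv <- exact_curve(uma_params(2, 4), doses = 0:10)
  f1 <- fit_uma_mixture(cv, k = 1)
  expect_identical(f1$model_kind, "UMA")
  expect_lt(abs(f1$params$do - 2) / 2, 1e-6)
  expect_error(fit_uma_mixture(survival_curve(c(0, 2, 4),
                                              mean = c(1, .5, .2)), k = 2),
               "2k \\+ 1")
})

test_that("fit results round-trip through JSON", {
  cv <- generate_curve(uma_params(1.5, 5), seed = 4)
  f <- fit_uma(cv)
  g <- fit_from_json(fit_to_json(f))
  expect_equal(g$params$do, f$params$do)
  expect_equal(g$params$n, f$params$n)
  expect_equal(g$fitted, f$fitted)
  expect_equal(g$r2, f$r2)
  expect_equal(g$model_kind, f$model_kind)
  lq <- fit_lq(cv)
  glq <- fit_from_json(fit_to_json(lq))
  expect_equal(glq$params$alpha, lq$params$alpha)
})
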