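test_that("survival is exactly 1 at zero dose, bounded, strictly decreasing", {
  for (i in seq_len(nrow(param_grid))) {
    p <- uma_params(param_grid$do[i], param_grid$n[i])
    expect_identical(uma_survival(p, 0), 1)
    s <- uma_survival(p, seq(0, 40, by = 0.5))
    expect_true(all(s > 0 & s <= 1))
    expect_true(all(diff(s) < 0))
  }
  mix <- uma_mixture(list(uma_params(2.8, 1), uma_params(2.7, 58)))
  expect_identical(uma_survival(mix, 0), 1)
  s <- uma_survival(mix, seq(0, 40, by = 0.5))
  expect_true(all(diff(s) < 0))
})

test_that("n = 1 gives the pure exponential and direct evaluation matches", {
  expect_equal(uma_survival(uma_params(2.8, 1), c(1, 7, 20)),
               exp(-c(1, 7, 20) / 2.8))
  # direct scalar evaluation of the closed form
  expect_equal(uma_survival(uma_params(1.73, 4.2), 20),
               4.2 / (exp(20 / 1.73) + 3.2), tolerance = 1e-12)
})

test_that("mixture survival is the weighted sum of component survivals", {
  p1 <- uma_params(2.80, 1); p2 <- uma_params(2.70, 58)
  mix <- uma_mixture(list(p1, p2), weights = c(0.3, 0.7))
  d <- c(0, 2, 7, 15, 30)
  expect_equal(uma_survival(mix, d),
               0.3 * uma_survival(p1, d) + 0.7 * uma_survival(p2, d),
               tolerance = 1e-12)
})

test_that("log-space evaluation survives extreme dose/do ratios", {
  s <- uma_log_survival(uma_params(1, 100), 700)
  expect_true(is.finite(s))
  expect_equal(s, log(100) - 700, tolerance = 1e-10)
  expect_gt(uma_survival(uma_params(2, 5), 500), 0) # underflows gracefully
})

test_that("high-dose straight portion: ln S approaches ln n - D/Do", {
  # deviation is log1p((n-1) exp(-D/Do)); below 1e-4 for n <= 16 at
  # D/Do >= 12, and for n up to 100 from D/Do >= 14
  for (n in c(0.2, 1, 5, 16)) {
    p <- uma_params(2, n)
    x <- c(12, 15, 20)
    expect_true(all(abs(uma_log_survival(p, x * 2) - (log(n) - x)) < 1e-4))
  }
  expect_lt(abs(uma_log_survival(uma_params(1, 100), 14) - (log(100) - 14)),
            1e-4)
})

test_that("alpha and beta match the derivatives of -ln S", {
  for (i in seq_len(nrow(param_grid))) {
    p <- uma_params(param_grid$do[i], param_grid$n[i])
    f <- function(d) uma_log_survival(p, d)
    for (D in p$do * c(0.5, 2, 5)) {
      h <- 0.01 * p$do
      beta_num <- -num_deriv2(f, D, h) / 2
      alpha_num <- -num_deriv1(f, D, h) + 2 * beta_num * D
      if (p$n == 1) {
        expect_identical(uma_beta(p, D), 0)
        expect_equal(uma_alpha(p, D), 1 / p$do, tolerance = 1e-12)
      } else {
        expect_equal(uma_beta(p, D), beta_num, tolerance = 1e-6)
        expect_equal(uma_alpha(p, D), alpha_num, tolerance = 1e-6)
      }
    }
  }
})

test_that("beta is negative for inverted shoulders and zero at n = 1", {
  expect_lt(uma_beta(uma_params(1.45, 0.9), 1.2), 0)
  expect_lt(uma_alpha_beta_ratio(uma_params(1.45, 0.9), 1.2), 0)
  expect_identical(uma_beta(uma_params(3.7, 1), 12), 0)
})

test_that("alpha/beta ratio equals alpha/beta and its closed form", {
  for (i in seq_len(nrow(param_grid))) {
    do <- param_grid$do[i]; n <- param_grid$n[i]
    if (n == 1) next
    p <- uma_params(do, n)
    for (D in c(0, 2, 7.4, 20)) {
      ratio <- uma_alpha_beta_ratio(p, D)
      expect_equal(ratio, uma_alpha(p, D) / uma_beta(p, D), tolerance = 1e-12)
      expect_equal(ratio, 2 * do * (exp(D / do) + n - 1) / (n - 1) + 2 * D,
                   tolerance = 1e-9)
    }
  }
  expect_true(is.na(uma_alpha_beta_ratio(uma_params(2.80, 1), 7)))
})

test_that("published dose-dependent alpha and alpha/beta values reproduce", {
  expect_equal(signif(uma_alpha(uma_params(6.50, 2.0), 20), 2), 0.17)
  expect_equal(signif(uma_alpha(uma_params(2.20, 2.8), 7.4), 2), 0.51)
  expect_equal(signif(uma_alpha_beta_ratio(uma_params(2.20, 2.8), 7.4), 2), 90)
  expect_equal(signif(uma_alpha_beta_ratio(uma_params(1.45, 0.9), 1.2), 2), -61)
})

test_that("mean inactivation dose matches quadrature of the survival curve", {
  for (do in c(0.5, 2, 7)) {
    for (n in c(0.2, 1 + 1e-6, 5, 60)) {
      p <- uma_params(do, n)
      quad <- integrate(function(d) uma_survival(p, d), 0, Inf,
                        rel.tol = 1e-10)$value
      expect_equal(mean_inactivation_dose(p), quad, tolerance = 1e-6)
    }
  }
})

test_that("MID closed form: known values and continuity at n = 1", {
  expect_identical(mean_inactivation_dose(uma_params(0.80, 1.0)), 0.80)
  expect_equal(round(mean_inactivation_dose(uma_params(1.49, 3.8)), 1), 2.7)
  for (do in c(0.5, 2, 7)) {
    expect_lt(abs(mean_inactivation_dose(uma_params(do, 1 + 1e-6)) - do),
              1e-4 * do)
    expect_lt(abs(mean_inactivation_dose(uma_params(do, 1 - 1e-6)) - do),
              1e-4 * do)
  }
})

test_that("invalid inputs are rejected", {
  expect_error(uma_params(0, 2), "do")
  expect_error(uma_params(2, -1), "n")
  expect_error(uma_survival(uma_params(2, 2), -1), "dose")
  expect_error(uma_mixture(list(uma_params(1, 1)), weights = 0.5), "sum to 1")
  expect_error(uma_mixture(list(uma_params(1, 1), uma_params(2, 2)),
                           weights = c(1.2, -0.2)), "> 0")
  expect_error(uma_alpha(uma_mixture(list(uma_params(1, 2))), 1),
               "single populations")
})
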