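# Noise-free curve evaluated exactly on the model: the fixture for all
# self-consistency / recovery tests.
exact_curve <- function(params, doses = 0:12) {
  survival_curve(doses, mean = uma_survival(params, doses), add_zero = TRUE)
}

# Richardson-extrapolated central differences of f, used as the
# independent derivative oracle for alpha/beta checks.
num_deriv1 <- function(f, x, h) {
  d <- function(h) (f(x + h) - f(x - h)) / (2 * h)
  (4 * d(h / 2) - d(h)) / 3
}
num_deriv2 <- function(f, x, h) {
  d <- function(h) (f(x + h) - 2 * f(x) + f(x - h)) / h^2
  (4 * d(h / 2) - d(h)) / 3
}

# Parameter grid spanning the package's intended domain, including the
# inverted-shoulder (n < 1) and pure-exponential regimes.
param_grid <- expand.grid(do = c(0.5, 1.08, 2.2, 7), n = c(0.2, 1, 5, 60))
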