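#' Log survival under the UMA model
#'
#' Natural logarithm of the survival fraction, evaluated in log space so
#' that very large `dose/do` (up to the double-precision exponent range)
#' does not overflow: \eqn{\ln S = \ln n - D/D_0 - \ln(1 + (n-1)e^{-D/D_0})}.
#'
#' @param params A [uma_params()] or [uma_mixture()] object.
#' @param dose Vector of doses in Gy, all >= 0.
#' @return Numeric vector of \eqn{\ln S}; exactly 0 at `dose = 0`.
#' @export
uma_log_survival <- function(params, dose) UseMethod("uma_log_survival")

#' @export
uma_log_survival.uma_params <- function(params, dose) {
  check_dose(dose)
  x <- dose / params$do
  out <- log(params$n) - x - log1p((params$n - 1) * exp(-x))
  out[dose == 0] <- 0
  out
}

#' @export
uma_log_survival.uma_mixture <- function(params, dose) {
  check_dose(dose)
  lw <- log(params$weights)
  lmat <- vapply(seq_along(params$components), function(k)
    lw[k] + uma_log_survival(params$components[[k]], dose),
    numeric(length(dose)))
  lmat <- matrix(lmat, nrow = length(dose))
  m <- apply(lmat, 1L, max)
  out <- m + log(rowSums(exp(lmat - m)))
  out[dose == 0] <- 0
  out
}

#' Survival fraction under the UMA model
#'
#' Evaluates \eqn{S(D) = n / (e^{D/D_0} + n - 1)} for a single population,
#' or the weighted sum over populations for a mixture.  The survival is
#' exactly 1 at zero dose, strictly decreasing in dose, and bounded in
#' (0, 1].
#'
#' @inheritParams uma_log_survival
#' @return Numeric vector of survival fractions in (0, 1].
#' @examples
#' uma_survival(uma_params(2.8, 1), 7)   # pure exponential: exp(-7/2.8)
#' @export
uma_survival <- function(params, dose) exp(uma_log_survival(params, dose))

#' Dose-dependent beta of the UMA model
#'
#' The quadratic LQ coefficient implied by the UMA curve at dose `dose`,
#' obtained from the second derivative of \eqn{-\ln S}:
#' \deqn{\beta(D) = \frac{(n-1)\,e^{D/D_0}}{2 D_0^2 (e^{D/D_0}+n-1)^2}.}
#' Zero when `n = 1`, negative when `n < 1` (inverted shoulder).
#'
#' @param params A [uma_params()] object (mixtures have no single
#'   well-defined curvature and are rejected).
#' @param dose Vector of doses in Gy, >= 0.
#' @return Numeric vector, Gy^-2.
#' @export
uma_beta <- function(params, dose) {
  check_single_population(params)
  check_dose(dose)
  x <- dose / params$do
  lng <- x + log1p((params$n - 1) * exp(-x))
  (params$n - 1) * exp(x - 2 * lng) / (2 * params$do^2)
}

#' Dose-dependent alpha of the UMA model
#'
#' The linear LQ coefficient implied by the UMA curve at dose `dose`:
#' \deqn{\alpha(D) = \frac{e^{D/D_0}}{D_0(e^{D/D_0}+n-1)} +
#'       \frac{D (n-1) e^{D/D_0}}{D_0^2 (e^{D/D_0}+n-1)^2},}
#' i.e. \eqn{-\partial \ln S/\partial D + 2\beta D}.  For `n = 1` this is
#' identically \eqn{1/D_0}.
#'
#' @inheritParams uma_beta
#' @return Numeric vector, Gy^-1.
#' @export
uma_alpha <- function(params, dose) {
  check_single_population(params)
  check_dose(dose)
  x <- dose / params$do
  lng <- x + log1p((params$n - 1) * exp(-x))
  exp(x - lng) / params$do +
    dose * (params$n - 1) * exp(x - 2 * lng) / params$do^2
}

#' Dose-dependent alpha/beta ratio of the UMA model
#'
#' The ratio of [uma_alpha()] to [uma_beta()], which simplifies to
#' \eqn{2 D_0 (e^{D/D_0}+n-1)/(n-1) + 2D}.  For `n = 1` the curvature
#' vanishes and the ratio is undefined: `NA` is returned (not an error),
#' matching the convention of reporting "N/A" for pure-exponential lines.
#' The ratio is negative when `n < 1`.
#'
#' @inheritParams uma_beta
#' @return Numeric vector in Gy, `NA` where undefined.
#' @export
uma_alpha_beta_ratio <- function(params, dose) {
  check_single_population(params)
  check_dose(dose)
  if (params$n == 1) return(rep(NA_real_, length(dose)))
  uma_alpha(params, dose) / uma_beta(params, dose)
}

#' Mean inactivation dose
#'
#' The integral of the survival curve over all doses,
#' \eqn{\mathrm{MID} = \int_0^\infty S(D)\,dD = n \ln(n) D_0/(n-1)},
#' a single-number radiosensitivity summary.  At `n = 1` the continuous
#' limit gives \eqn{\mathrm{MID} = D_0}.
#'
#' @param params A [uma_params()] object.
#' @return Mean inactivation dose in Gy.
#' @examples
#' mean_inactivation_dose(uma_params(1.49, 3.8))  # ~2.7 Gy
#' mean_inactivation_dose(uma_params(0.80, 1.0))  # exactly Do
#' @export
mean_inactivation_dose <- function(params) {
  check_single_population(params)
  n <- params$n
  if (n == 1) return(params$do)
  n * log(n) * params$do / (n - 1)
}

check_dose <- function(dose) {
  if (!is.numeric(dose) || any(!is.finite(dose)))
    stop("'dose' must be finite numeric", call. = FALSE)
  if (any(dose < 0))
    stop("'dose' must be >= 0 Gy", call. = FALSE)
  invisible(dose)
}

check_single_population <- function(params) {
  if (inherits(params, "uma_mixture"))
    stop("derivative quantities are defined for single populations only; ",
         "apply to each mixture component instead", call. = FALSE)
  if (!inherits(params, "uma_params"))
    stop("'params' must be a uma_params object", call. = FALSE)
  invisible(params)
}
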