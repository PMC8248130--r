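#' UMA model parameters
#'
#' Constructs the parameter pair of the unified multi-activation (UMA)
#' survival model, \eqn{S(D) = n / (e^{D/D_0} + n - 1)}.
#'
#' `do` is the characteristic dose slope \eqn{D_0} (Gy): the dose that
#' reduces survival e-fold on the straight, high-dose portion of the curve.
#' `n` is the activation (extrapolation) number: the back-extrapolated
#' zero-dose intercept of that straight portion, interpreted as the number
#' of radiation-activated cell-death pathways.  Values of `n` below 1 are
#' valid and describe inverted (negatively curved) shoulders; `n = 1`
#' collapses the model to the pure exponential \eqn{S = e^{-D/D_0}}.
#'
#' @param do Dose slope \eqn{D_0} in Gy; strictly positive scalar.
#' @param n Activation number; strictly positive scalar (values < 1 allowed).
#' @return An object of class `uma_params`.
#' @seealso [uma_survival()], [uma_mixture()]
#' @examples
#' p <- uma_params(do = 1.73, n = 4.2)
#' uma_survival(p, dose = c(0, 2, 20))
#' @export
uma_params <- function(do, n) {
  if (!is.numeric(do) || length(do) != 1L || !is.finite(do) || do <= 0)
    stop("'do' must be a single finite value > 0 (Gy)", call. = FALSE)
  if (!is.numeric(n) || length(n) != 1L || !is.finite(n) || n <= 0)
    stop("'n' must be a single finite value > 0", call. = FALSE)
  # e^(D/Do) + n - 1 >= n > 0 for all D >= 0, so the model is well defined
  # on the whole parameter domain, including 0 < n < 1.
  structure(list(do = as.numeric(do), n = as.numeric(n)),
            class = "uma_params")
}

#' Mixture of UMA cell populations
#'
#' A tumour containing several sub-populations with distinct
#' radiosensitivities (e.g. a hypoxic fraction) is modelled as a weighted
#' sum of single-population survival curves:
#' \eqn{S(D) = \sum_k w_k \, n_k / (e^{D/D_{0,k}} + n_k - 1)} with
#' \eqn{\sum_k w_k = 1}, so that \eqn{S(0) = 1} exactly.
#'
#' @param components List of [uma_params()] objects.
#' @param weights Numeric vector of positive population fractions, one per
#'   component, summing to 1.  Defaults to equal weights.
#' @return An object of class `uma_mixture`.
#' @examples
#' # irregular cervical-carcinoma curve resolved as two equal populations
#' mix <- uma_mixture(list(uma_params(2.80, 1), uma_params(2.70, 58)))
#' uma_survival(mix, dose = c(0, 7, 14))
#' @export
uma_mixture <- function(components, weights = NULL) {
  if (!is.list(components) || length(components) < 1L)
    stop("'components' must be a non-empty list of uma_params", call. = FALSE)
  if (!all(vapply(components, inherits, logical(1), "uma_params")))
    stop("every component must be a uma_params object", call. = FALSE)
  k <- length(components)
  if (is.null(weights)) weights <- rep(1 / k, k)
  if (!is.numeric(weights) || length(weights) != k || any(!is.finite(weights)))
    stop("'weights' must be a numeric vector, one value per component",
         call. = FALSE)
  if (any(weights <= 0))
    stop("all mixture weights must be > 0", call. = FALSE)
  if (abs(sum(weights) - 1) > 1e-8)
    stop("mixture weights must sum to 1 (got ", format(sum(weights)), ")",
         call. = FALSE)
  structure(list(components = components, weights = as.numeric(weights)),
            class = "uma_mixture")
}

#' Linear-quadratic model parameters
#'
#' Container for the coefficients of \eqn{\ln S = -\alpha D - \beta D^2}.
#' `beta` may be negative (inverted-shoulder curves).  The `alpha_beta`
#' ratio is `NA` when `beta` is zero, the pure-exponential case.
#'
#' @param alpha Linear coefficient, Gy^-1.
#' @param beta Quadratic coefficient, Gy^-2.
#' @return An object of class `lq_params` with fields `alpha`, `beta`,
#'   `alpha_beta`.
#' @export
lq_params <- function(alpha, beta) {
  stopifnot(is.numeric(alpha), length(alpha) == 1L, is.finite(alpha),
            is.numeric(beta), length(beta) == 1L, is.finite(beta))
  structure(list(alpha = as.numeric(alpha), beta = as.numeric(beta),
                 alpha_beta = if (beta == 0) NA_real_ else alpha / beta),
            class = "lq_params")
}

#' @export
print.uma_params <- function(x, ...) {
  cat(sprintf("UMA parameters: Do = %.4g Gy, n = %.4g\n", x$do, x$n))
  invisible(x)
}

#' @export
print.uma_mixture <- function(x, ...) {
  cat(sprintf("UMA mixture of %d populations:\n", length(x$components)))
  for (i in seq_along(x$components))
    cat(sprintf("  w = %.3f: Do = %.4g Gy, n = %.4g\n",
                x$weights[i], x$components[[i]]$do, x$components[[i]]$n))
  invisible(x)
}

#' @export
print.lq_params <- function(x, ...) {
  cat(sprintf("LQ parameters: alpha = %.4g /Gy, beta = %.4g /Gy^2, alpha/beta = %s\n",
              x$alpha, x$beta,
              if (is.na(x$alpha_beta)) "undefined" else
                sprintf("%.4g Gy", x$alpha_beta)))
  invisible(x)
}
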