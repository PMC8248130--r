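#' Survival ratio of two fractionation schemes
#'
#' Compares two ways of delivering (nominally) the same physical dose:
#' \eqn{S(D_a)^{N_a} / S(D_b)^{N_b}}, evaluated in log space.  Real-valued
#' exponents are allowed, as in the twice-daily hyperfractionation
#' comparison \eqn{(S_{1.2})^{2/1.2}/S_2} where the exponent matches the
#' physical dose per day rather than a whole fraction count.  Values below
#' 1 favour scheme A (more cell kill for the same physical dose); the
#' ratio is identically 1 when `n = 1` since the exponential model sees
#' only total dose.
#'
#' @param params [uma_params()] or [uma_mixture()].
#' @param dose_a,n_a Dose per fraction (Gy) and (real) fraction count of
#'   scheme A.
#' @param dose_b,n_b Same for scheme B.
#' @return Positive scalar ratio.
#' @examples
#' scheme_survival_ratio(uma_params(1, 5), 10, 1, 2, 5)   # < 1: hypo wins
#' @export
scheme_survival_ratio <- function(params, dose_a, n_a, dose_b, n_b) {
  stopifnot(is.numeric(dose_a), dose_a > 0, is.numeric(n_a), n_a > 0,
            is.numeric(dose_b), dose_b > 0, is.numeric(n_b), n_b > 0)
  if (abs(dose_a * n_a - dose_b * n_b) > 1e-8)
    warning(sprintf("schemes deliver unequal physical dose (%.4g vs %.4g Gy)",
                    dose_a * n_a, dose_b * n_b), call. = FALSE)
  exp(n_a * uma_log_survival(params, dose_a) -
        n_b * uma_log_survival(params, dose_b))
}

#' Scheme-comparison ratio surface over the (Do, n) plane
#'
#' Evaluates [scheme_survival_ratio()] on a rectangular grid of UMA
#' parameters, the surface used to pick a fractional dose for a cell line
#' of known radiosensitivity.  Two canonical comparisons are built in:
#' `"hypo_10v2"` (one 10-Gy fraction vs five 2-Gy fractions) and
#' `"hyper_1p2v2"` (1.2-Gy BID at equal daily physical dose, exponent
#' 2/1.2, vs one 2-Gy fraction); `"custom"` takes explicit schemes.
#'
#' @param ratio_kind `"hypo_10v2"`, `"hyper_1p2v2"` or `"custom"`.
#' @param do_range,n_range Axis ranges (Gy, dimensionless); defaults cover
#'   the span of the packaged tumour table.
#' @param resolution Grid points per axis.
#' @param dose_a,n_a,dose_b,n_b Schemes for `ratio_kind = "custom"`.
#' @return An object of class `ratio_grid`: list with `do`, `n` axis
#'   vectors and a `values` matrix (rows indexed by `do`).  Coerce with
#'   `as.data.frame()` for long-format export.
#' @examples
#' g <- ratio_grid("hypo_10v2", resolution = 21)
#' summary(g)
#' @export
ratio_grid <- function(ratio_kind = c("hypo_10v2", "hyper_1p2v2", "custom"),
                       do_range = c(0.5, 7), n_range = c(0.2, 20),
                       resolution = 60,
                       dose_a = NULL, n_a = NULL, dose_b = NULL, n_b = NULL) {
  ratio_kind <- match.arg(ratio_kind)
  if (any(do_range <= 0) || any(n_range <= 0))
    stop("'do_range' and 'n_range' must be positive", call. = FALSE)
  sch <- switch(ratio_kind,
    hypo_10v2 = list(da = 10, na = 1, db = 2, nb = 5),
    hyper_1p2v2 = list(da = 1.2, na = 2 / 1.2, db = 2, nb = 1),
    custom = {
      if (is.null(dose_a) || is.null(n_a) || is.null(dose_b) || is.null(n_b))
        stop("custom ratio needs dose_a, n_a, dose_b, n_b", call. = FALSE)
      list(da = dose_a, na = n_a, db = dose_b, nb = n_b)
    })
  do_axis <- seq(do_range[1], do_range[2], length.out = resolution)
  n_axis <- seq(n_range[1], n_range[2], length.out = resolution)
  values <- outer(do_axis, n_axis, function(d, n) {
    vapply(seq_along(d), function(i)
      scheme_survival_ratio(uma_params(d[i], n[i]),
                            sch$da, sch$na, sch$db, sch$nb), numeric(1))
  })
  structure(list(do = do_axis, n = n_axis, values = values,
                 ratio_kind = ratio_kind, scheme_a = c(sch$da, sch$na),
                 scheme_b = c(sch$db, sch$nb)),
            class = "ratio_grid")
}

#' @export
as.data.frame.ratio_grid <- function(x, ...) {
  data.frame(do = rep(x$do, times = length(x$n)),
             n = rep(x$n, each = length(x$do)),
             ratio = as.vector(x$values))
}

#' @export
print.ratio_grid <- function(x, ...) {
  cat(sprintf("Scheme survival ratio grid '%s': %gx%g vs %gx%g\n",
              x$ratio_kind, x$scheme_a[1], x$scheme_a[2],
              x$scheme_b[1], x$scheme_b[2]))
  cat(sprintf("  Do in [%.3g, %.3g] Gy, n in [%.3g, %.3g], %d x %d values in [%.3g, %.3g]\n",
              min(x$do), max(x$do), min(x$n), max(x$n),
              length(x$do), length(x$n), min(x$values), max(x$values)))
  invisible(x)
}

#' Monotonicity diagnostics of a ratio surface
#'
#' For each `n` column, whether the ratio is monotone nondecreasing along
#' increasing `Do`; for each `Do` row, the grid `n` at the interior
#' stationary point of the ratio across `n` (where
#' \eqn{\partial(\mathrm{ratio})/\partial n = 0}; for the
#' hypofractionation surface this is a minimum of the survival ratio,
#' i.e. the activation number at which the large-fraction scheme gains
#' the most tumour control), or `NA` when the ratio is monotone across
#' the grid's `n` range.
#'
#' @param object A [ratio_grid()].
#' @param ... Unused.
#' @return List with `increasing_in_do` (logical per `n` value) and
#'   `n_at_stationary` (per `Do` value).
#' @export
summary.ratio_grid <- function(object, ...) {
  inc <- apply(object$values, 2L, function(col) all(diff(col) >= -1e-12))
  stationary <- apply(object$values, 1L, function(row) {
    d <- diff(row)
    i <- which(d[-1] * d[-length(d)] < 0)
    if (length(i)) object$n[i[1] + 1L] else NA_real_
  })
  list(increasing_in_do = stats::setNames(inc, signif(object$n, 4)),
       n_at_stationary = stats::setNames(stationary, signif(object$do, 4)))
}
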