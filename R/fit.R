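#' Goodness statistics for a fitted survival curve
#'
#' Computed on the linear survival scale.  With observed means \eqn{S_i},
#' fitted values \eqn{S(D_i)} and \eqn{I} dose points:
#' \eqn{RSS = \sum_i (S(D_i)-S_i)^2}, \eqn{SSS = \sum_i (S_i-\bar S)^2},
#' \eqn{R^2 = 1 - RSS/SSS}, the mean relative residual
#' \eqn{r = I^{-1}\sum_i |S(D_i)-S_i|/S_i}, and the mean relative
#' experimental error \eqn{e = I'^{-1}\sum_i \Delta S_i/S_i} over the
#' \eqn{I'} points carrying a replicate SD.  `r` complements \eqn{R^2},
#' which is insensitive to discrepancies at high doses where survivals are
#' tiny; a good fit has \eqn{R^2 \in [0.9, 1]} and `r < e`.
#'
#' @param curve A [survival_curve()].
#' @param fitted Numeric vector of model survivals aligned with the curve's
#'   dose points.
#' @return List with elements `r2` (NA if all means are equal), `rss`,
#'   `sss`, `r`, `e` (NA when no point has an SD).
#' @examples
#' cv <- survival_curve(c(0, 2, 4), mean = c(1, 0.5, 0.1))
#' goodness_stats(cv, fitted = c(1, 0.4, 0.12))
#' @export
goodness_stats <- function(curve, fitted) {
  stopifnot(inherits(curve, "survival_curve"))
  if (length(fitted) != nrow(curve))
    stop("'fitted' must align with the curve's dose points", call. = FALSE)
  obs <- curve$mean
  rss <- sum((fitted - obs)^2)
  sss <- sum((obs - mean(obs))^2)
  r2 <- if (sss == 0) NA_real_ else 1 - rss / sss
  r <- mean(abs(fitted - obs) / obs)
  has_sd <- is.finite(curve$sd)
  e <- if (any(has_sd)) mean(curve$sd[has_sd] / obs[has_sd]) else NA_real_
  list(r2 = r2, rss = rss, sss = sss, r = r, e = e)
}

new_fit_result <- function(model_kind, params, curve, fitted,
                           dose_range = range(curve$dose), warnings = character()) {
  st <- goodness_stats(curve, fitted)
  good <- !is.na(st$r2) && st$r2 >= 0.9 && st$r2 <= 1 &&
    (is.na(st$e) || st$r < st$e)
  structure(list(
    model_kind = model_kind, params = params,
    r2 = st$r2, rss = st$rss, sss = st$sss, r = st$r, e = st$e,
    dose = curve$dose, observed = curve$mean, fitted = fitted,
    residuals = fitted - curve$mean,
    dose_range = as.numeric(dose_range), good_fit = good,
    warnings = warnings), class = "uma_fit")
}

#' @export
print.uma_fit <- function(x, ...) {
  cat(sprintf("%s fit over %d dose points (%.3g-%.3g Gy)\n",
              x$model_kind, length(x$dose), x$dose_range[1], x$dose_range[2]))
  print(x$params)
  cat(sprintf("  R^2 = %.4f, RSS = %.3g, r = %.4g%s\n",
              x$r2, x$rss, x$r,
              if (is.na(x$e)) "" else sprintf(", e = %.4g", x$e)))
  cat(sprintf("  good fit (R^2 in [0.9, 1] and r < e when available): %s\n",
              if (x$good_fit) "yes" else "no"))
  for (w in x$warnings) cat("  note: ", w, "\n", sep = "")
  invisible(x)
}

#' @export
predict.uma_fit <- function(object, dose = object$dose, ...) {
  p <- object$params
  switch(object$model_kind,
    "UMA" = , "UMA-mixture" = uma_survival(p, dose),
    "LQ" = exp(-p$alpha * dose - p$beta * dose^2),
    "MT" = p$n * exp(-dose / p$do),
    stop("unknown model kind: ", object$model_kind))
}

#' Fit the UMA model to a survival curve
#'
#' Uses the linearization of the model: for the true parameters,
#' \eqn{y_i = \ln(n/S_i + 1 - n) = D_i/D_0} exactly, so for any candidate
#' `n` the best \eqn{D_0} follows from a through-origin least-squares
#' regression of \eqn{y_i} on \eqn{D_i}.  Starting values come from the
#' two highest-dose points (\eqn{D_0^{(0)} =
#' -(D_I - D_{I-1})/(\ln S_I - \ln S_{I-1})},
#' \eqn{n^{(0)} = S_{I-1} e^{D_{I-1}/D_0^{(0)}}}); `n` is then adjusted
#' over a deterministic log-spaced grid refined by golden-section search to
#' minimize the mean relative residual `r`, restricted to candidates with
#' \eqn{R^2 \ge} `r2_min` when any exist (otherwise the constraint is
#' dropped with a warning).  Ties in `r` (within 1e-10) break to higher
#' \eqn{R^2}, then smaller `n`.  The zero-dose anchor participates in the
#' regression (contributing \eqn{y = 0} at \eqn{D = 0}) and in all
#' statistics except `e`.
#'
#' @param curve A [survival_curve()] with at least 3 points including the
#'   zero-dose anchor (at least 2 with positive dose).
#' @param n_range Search interval for the activation number `n`.
#' @param n_grid Number of log-spaced grid candidates.
#' @param r2_min Feasibility threshold on \eqn{R^2} (default 0.9).
#' @return A `uma_fit` object with `params` of class [uma_params()].
#' @examples
#' p <- uma_params(1.5, 5)
#' cv <- survival_curve(0:12, mean = uma_survival(p, 0:12))
#' fit_uma(cv)$params
#' @export
fit_uma <- function(curve, n_range = c(0.05, 200), n_grid = 160,
                    r2_min = 0.9) {
  stopifnot(inherits(curve, "survival_curve"))
  D <- curve$dose; S <- curve$mean
  if (nrow(curve) < 3L || sum(D > 0) < 2L)
    stop("fit_uma needs >= 3 dose points with >= 2 positive doses",
         call. = FALSE)

  ssd2 <- sum(D^2)
  eval_n <- function(n) {
    arg <- n / S + 1 - n
    if (any(arg <= 0)) return(NULL)       # infeasible candidate
    y <- log(arg)
    slope <- sum(D * y) / ssd2            # through-origin LS
    if (!is.finite(slope) || slope <= 0) return(NULL)
    do <- 1 / slope
    fit <- exp(uma_log_survival(uma_params(do, n), D))
    st <- goodness_stats(curve, fit)
    list(do = do, n = n, r = st$r, r2 = st$r2, fitted = fit)
  }

  # initialization from the two highest-dose points, then a log grid
  I <- length(D)
  do0 <- -(D[I] - D[I - 1]) / (log(S[I]) - log(S[I - 1]))
  n0 <- if (is.finite(do0) && do0 > 0) S[I - 1] * exp(D[I - 1] / do0) else NA
  cand <- exp(seq(log(n_range[1]), log(n_range[2]), length.out = n_grid))
  if (is.finite(n0) && n0 > n_range[1] && n0 < n_range[2])
    cand <- sort(c(cand, n0))
  evals <- lapply(cand, eval_n)
  ok <- !vapply(evals, is.null, logical(1))
  if (!any(ok)) stop("no feasible activation number in the search range",
                     call. = FALSE)
  cand <- cand[ok]; evals <- evals[ok]
  rr <- vapply(evals, `[[`, numeric(1), "r")
  r2 <- vapply(evals, `[[`, numeric(1), "r2")

  warnings <- character()
  feasible <- is.finite(r2) & r2 >= r2_min
  pool <- if (any(feasible)) which(feasible) else seq_along(cand)
  if (!any(feasible)) {
    warnings <- sprintf("no candidate reached R^2 >= %.2f; minimizing r unconstrained",
                        r2_min)
    warning(warnings, call. = FALSE)
  }
  best <- pool[pick_best(rr[pool], r2[pool], cand[pool])]

  # golden-section refinement of r(log n) between the neighbouring grid points
  lo <- if (best > 1L) cand[best - 1L] else cand[best]
  hi <- if (best < length(cand)) cand[best + 1L] else cand[best]
  res <- evals[[best]]
  if (hi > lo) {
    opt <- stats::optimize(function(ln) {
      ev <- eval_n(exp(ln))
      if (is.null(ev)) return(Inf)
      if (any(feasible) && (!is.finite(ev$r2) || ev$r2 < r2_min)) return(Inf)
      ev$r
    }, lower = log(lo), upper = log(hi), tol = 1e-12)
    refined <- eval_n(exp(opt$minimum))
    if (!is.null(refined) && refined$r <= res$r) res <- refined
  }

  out <- new_fit_result("UMA", uma_params(res$do, res$n), curve, res$fitted,
                        warnings = warnings)
  out
}

pick_best <- function(r, r2, n, tol = 1e-10) {
  o <- order(r, -r2, n)
  best <- o[1]
  near <- which(r - r[best] <= tol)
  near[order(-r2[near], n[near])][1]
}

#' Fit the linear-quadratic model
#'
#' Zero-intercept least squares of \eqn{\ln S_i = -\alpha D_i - \beta D_i^2}
#' over the points inside `dose_range` (default: all points).  Goodness
#' statistics are computed on the survival scale over *all* points, so the
#' characteristic high-dose underestimation of LQ extrapolation remains
#' visible even when the fit used only low doses.
#'
#' @param curve A [survival_curve()].
#' @param dose_range Optional `c(min, max)` restricting the doses entering
#'   the regression; at least 3 points must fall inside.
#' @return A `uma_fit` object with `params` of class [lq_params()].
#' @export
fit_lq <- function(curve, dose_range = NULL) {
  stopifnot(inherits(curve, "survival_curve"))
  D <- curve$dose
  sel <- if (is.null(dose_range)) rep(TRUE, length(D)) else
    D >= dose_range[1] & D <= dose_range[2]
  if (sum(sel) < 3L)
    stop("fit_lq needs >= 3 points inside the dose range", call. = FALSE)
  if (length(unique(D[sel])) < 2L)
    stop("degenerate design: all selected doses equal", call. = FALSE)
  y <- log(curve$mean[sel]); d <- D[sel]
  co <- stats::coef(stats::lm(y ~ 0 + d + I(d^2)))
  params <- lq_params(alpha = -co[[1]], beta = -co[[2]])
  fitted <- exp(-params$alpha * D - params$beta * D^2)
  new_fit_result("LQ", params, curve, fitted,
                 dose_range = if (is.null(dose_range)) range(D) else dose_range)
}

#' Fit the multitarget model to the high-dose tail
#'
#' Linear least squares of \eqn{\ln S} on dose over the points with
#' `dose > min_dose`, giving the multitarget asymptote
#' \eqn{S = n e^{-D/D_0}} with \eqn{D_0 = -1/\mathrm{slope}} and
#' \eqn{n = e^{\mathrm{intercept}}}.  Goodness statistics span *all*
#' points, exposing the model's overestimation of the low-dose shoulder.
#'
#' @param curve A [survival_curve()].
#' @param min_dose Points with dose strictly above this enter the
#'   regression (default 3 Gy).
#' @return A `uma_fit` object; `params` is a list with `do` and `n`
#'   (multitarget asymptote parameters, not a full UMA parameter set since
#'   the fitted survival may exceed 1 at low dose).
#' @export
fit_mt <- function(curve, min_dose = 3.0) {
  stopifnot(inherits(curve, "survival_curve"))
  D <- curve$dose
  sel <- D > min_dose
  if (sum(sel) < 2L)
    stop("fit_mt needs >= 2 points with dose > ", min_dose, " Gy",
         call. = FALSE)
  co <- stats::coef(stats::lm(log(curve$mean[sel]) ~ D[sel]))
  slope <- co[[2]]
  if (!is.finite(slope) || slope >= 0)
    stop("multitarget tail regression produced a non-decaying slope",
         call. = FALSE)
  params <- structure(list(do = -1 / slope, n = exp(co[[1]])),
                      class = "mt_params")
  fitted <- params$n * exp(-D / params$do)
  new_fit_result("MT", params, curve, fitted,
                 dose_range = c(min_dose, max(D)))
}

#' @export
print.mt_params <- function(x, ...) {
  cat(sprintf("Multitarget asymptote: Do = %.4g Gy, n = %.4g\n", x$do, x$n))
  invisible(x)
}
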