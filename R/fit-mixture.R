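#' Fit a mixture of UMA populations
#'
#' Resolves irregular survival curves (e.g. a tumour with a radioresistant
#' sub-population) as a weighted sum of `k` single-population UMA curves.
#' Weights default to fixed, equal fractions; set `free_weights = TRUE` to
#' estimate them.  The objective is the same mean relative residual `r`
#' minimized by [fit_uma()], optimized by Nelder-Mead in log-parameter
#' space from a deterministic set of starting points: a tail/shoulder
#' decomposition (multitarget regression on the upper half of the dose
#' range for the resistant component, initial-slope exponential for the
#' sensitive one) plus perturbations of the single-population fit.
#' Components are returned sorted by decreasing `do` (most radioresistant
#' first).
#'
#' @param curve A [survival_curve()] with at least `2k + 1` dose points.
#' @param k Number of components (default 2).
#' @param free_weights Estimate the weights instead of fixing them equal.
#' @param maxit Nelder-Mead iteration cap per start.
#' @return A `uma_fit` object with `params` of class [uma_mixture()]
#'   (or the [fit_uma()] result when `k = 1`).
#' @examples
#' mix <- uma_mixture(list(uma_params(2.80, 1), uma_params(2.70, 58)))
#' cv <- survival_curve(0:15 * 2, mean = uma_survival(mix, 0:15 * 2))
#' \donttest{fit_uma_mixture(cv)$params}
#' @export
fit_uma_mixture <- function(curve, k = 2L, free_weights = FALSE,
                            maxit = 4000L) {
  stopifnot(inherits(curve, "survival_curve"))
  if (k < 1L) stop("'k' must be >= 1", call. = FALSE)
  if (k == 1L) return(fit_uma(curve))
  if (nrow(curve) < 2L * k + 1L)
    stop("fit_uma_mixture needs >= 2k + 1 dose points", call. = FALSE)
  D <- curve$dose; S <- curve$mean

  unpack <- function(theta) {
    pars <- exp(theta[seq_len(2L * k)])
    comps <- lapply(seq_len(k), function(j)
      uma_params(pars[2L * j - 1L], pars[2L * j]))
    w <- if (free_weights) {
      z <- c(theta[-seq_len(2L * k)], 0)
      exp(z) / sum(exp(z))
    } else rep(1 / k, k)
    uma_mixture(comps, w)
  }
  objective <- function(theta) {
    mix <- tryCatch(unpack(theta), error = function(e) NULL)
    if (is.null(mix)) return(1e6)
    fit <- exp(uma_log_survival(mix, D))
    r <- mean(abs(fit - S) / S)
    if (!is.finite(r)) 1e6 else r
  }

  starts <- mixture_starts(curve, k, free_weights)
  best <- NULL
  converged <- FALSE
  for (th in starts) {
    opt <- stats::optim(th, objective, method = "Nelder-Mead",
                        control = list(maxit = maxit, reltol = 1e-14))
    # polish: restart once from the found optimum (Nelder-Mead stalls)
    opt <- stats::optim(opt$par, objective, method = "Nelder-Mead",
                        control = list(maxit = maxit, reltol = 1e-14))
    if (is.null(best) || opt$value < best$value) best <- opt
    if (opt$convergence == 0L) converged <- TRUE
  }
  if (is.null(best) || best$value >= 1e6)
    stop("mixture fit failed: no start produced a finite objective",
         call. = FALSE)
  warnings <- character()
  if (!converged) {
    warnings <- "Nelder-Mead iteration cap reached; returning best-so-far parameters"
    warning(warnings, call. = FALSE)
  }

  mix <- unpack(best$par)
  o <- order(vapply(mix$components, `[[`, numeric(1), "do"), decreasing = TRUE)
  mix <- uma_mixture(mix$components[o], mix$weights[o])
  fitted <- exp(uma_log_survival(mix, D))
  new_fit_result("UMA-mixture", mix, curve, fitted, warnings = warnings)
}

# Deterministic multi-start set in log space.
mixture_starts <- function(curve, k, free_weights) {
  D <- curve$dose; S <- curve$mean
  single <- tryCatch(fit_uma(curve), error = function(e) NULL,
                     warning = function(w) suppressWarnings(fit_uma(curve)))
  base <- if (is.null(single)) c(do = stats::median(D[D > 0]) / 2, n = 2)
          else c(do = single$params$do, n = single$params$n)

  # resistant tail: regression over the upper half of the dose range;
  # sensitive shoulder: pure exponential through the first positive point
  half <- max(D) / 2
  tail_par <- tryCatch({
    f <- fit_mt(curve, min_dose = half)
    c(do = f$params$do, n = max(f$params$n * k, 1.05))
  }, error = function(e) c(do = base[["do"]] * 1.5, n = max(base[["n"]], 2)))
  i1 <- which(D > 0)[1]
  do_low <- -D[i1] / log(S[i1])
  if (!is.finite(do_low) || do_low <= 0) do_low <- base[["do"]]

  two <- function(a, b) log(c(a[["do"]], a[["n"]], b[["do"]], b[["n"]]))
  starts2 <- list(
    two(tail_par, c(do = do_low, n = 1)),
    two(c(do = base[["do"]] * 1.25, n = base[["n"]]),
        c(do = base[["do"]] * 0.8, n = base[["n"]])),
    two(c(do = base[["do"]], n = base[["n"]] * 3),
        c(do = base[["do"]], n = max(base[["n"]] / 3, 0.3)))
  )
  starts <- if (k == 2L) starts2 else {
    # generic k: geometric spreads around the single-population fit
    lapply(c(0.6, 1, 1.6), function(f) {
      th <- as.numeric(vapply(seq_len(k), function(j)
        log(c(base[["do"]] * f^(j - (k + 1) / 2),
              base[["n"]] * (1 / f)^(j - (k + 1) / 2))), numeric(2)))
      th
    })
  }
  if (free_weights)
    starts <- lapply(starts, function(th) c(th, rep(0, k - 1L)))
  starts
}
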