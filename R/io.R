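#' Serialize a fit result to JSON
#'
#' Full-precision JSON round-trip of a `uma_fit` object, including the
#' model kind, parameters, goodness statistics and per-point values.
#'
#' @param fit A `uma_fit` object.
#' @param path Optional output path; when `NULL` the JSON string is
#'   returned.
#' @return The JSON string (invisibly when written to `path`).
#' @seealso [fit_from_json()]
#' @export
fit_to_json <- function(fit, path = NULL) {
  stopifnot(inherits(fit, "uma_fit"))
  p <- fit$params
  params <- if (inherits(p, "uma_mixture")) {
    list(type = "uma_mixture",
         do = vapply(p$components, `[[`, numeric(1), "do"),
         n = vapply(p$components, `[[`, numeric(1), "n"),
         weights = p$weights)
  } else if (inherits(p, "lq_params")) {
    list(type = "lq_params", alpha = p$alpha, beta = p$beta,
         alpha_beta = p$alpha_beta)
  } else {
    list(type = class(p)[1], do = p$do, n = p$n)
  }
  obj <- list(model_kind = fit$model_kind, params = params,
              r2 = fit$r2, rss = fit$rss, sss = fit$sss, r = fit$r, e = fit$e,
              dose = fit$dose, observed = fit$observed, fitted = fit$fitted,
              residuals = fit$residuals, dose_range = fit$dose_range,
              good_fit = fit$good_fit, warnings = fit$warnings)
  txt <- jsonlite::toJSON(obj, auto_unbox = TRUE, digits = NA, na = "null",
                          null = "null", pretty = TRUE)
  if (is.null(path)) return(txt)
  writeLines(txt, path)
  invisible(txt)
}

#' Deserialize a fit result from JSON
#'
#' @param json A JSON string or path produced by [fit_to_json()].
#' @return A `uma_fit` object.
#' @export
fit_from_json <- function(json) {
  obj <- jsonlite::fromJSON(json)
  p <- obj$params
  params <- switch(p$type,
    uma_params = uma_params(p$do, p$n),
    mt_params = structure(list(do = p$do, n = p$n), class = "mt_params"),
    lq_params = lq_params(p$alpha, p$beta),
    uma_mixture = uma_mixture(
      lapply(seq_along(p$do), function(i) uma_params(p$do[i], p$n[i])),
      p$weights),
    stop("unknown params type: ", p$type))
  null_na <- function(x) if (is.null(x)) NA_real_ else x
  structure(list(model_kind = obj$model_kind, params = params,
                 r2 = null_na(obj$r2), rss = obj$rss, sss = obj$sss,
                 r = obj$r, e = null_na(obj$e),
                 dose = obj$dose, observed = obj$observed,
                 fitted = obj$fitted, residuals = obj$residuals,
                 dose_range = obj$dose_range, good_fit = obj$good_fit,
                 warnings = as.character(obj$warnings)),
            class = "uma_fit")
}
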