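#' Generate a synthetic clonogenic survival curve
#'
#' Emulates a multi-replicate clonogenic assay: at each positive dose the
#' replicate survival fractions are the model mean times multiplicative
#' lognormal noise, \eqn{S_{ij} = S(D_i)\,e^{\varepsilon_{ij}}},
#' \eqn{\varepsilon \sim N(0, \sigma^2)}, clipped to (0, 1].  Lognormal
#' noise reflects the positivity and heteroscedasticity of colony-count
#' derived survival fractions.  The zero-dose point is emitted as exactly
#' (0, 1) with no replicate spread, matching the normalization convention.
#' Runs are reproducible: the same configuration and seed give an
#' identical curve, and the caller's RNG state is left untouched.
#'
#' @param params [uma_params()] or [uma_mixture()].
#' @param doses Positive doses in Gy (a zero dose may be included and is
#'   emitted noise-free); default 0-12 Gy in 1.5-Gy steps, a typical
#'   in-vitro assay grid.
#' @param replicates Replicates per positive dose point (default 3).
#' @param noise_sigma SD of the log-survival noise (default 0.1).
#' @param seed Integer seed; `NULL` uses the current RNG stream.
#' @return A [survival_curve()].
#' @examples
#' generate_curve(uma_params(1.5, 5), seed = 1)
#' @export
generate_curve <- function(params, doses = seq(0, 12, by = 1.5),
                           replicates = 3L, noise_sigma = 0.1, seed = NULL) {
  if (!inherits(params, "uma_params") && !inherits(params, "uma_mixture"))
    stop("'params' must be uma_params or uma_mixture", call. = FALSE)
  if (length(doses) == 0L) stop("empty dose list", call. = FALSE)
  check_dose(doses)
  if (is.unsorted(doses, strictly = TRUE))
    stop("'doses' must be strictly increasing", call. = FALSE)
  if (replicates < 1L) stop("'replicates' must be >= 1", call. = FALSE)
  if (noise_sigma < 0) stop("'noise_sigma' must be >= 0", call. = FALSE)

  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv())
    on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()), add = TRUE)
    set.seed(seed)
  }
  mu <- uma_survival(params, doses)
  reps <- lapply(seq_along(doses), function(i) {
    if (doses[i] == 0) return(1.0)
    pmin(mu[i] * exp(stats::rnorm(replicates, 0, noise_sigma)), 1.0)
  })
  survival_curve(doses, replicates = reps)
}
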