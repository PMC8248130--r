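#' Curated tumour cell-line parameter table
#'
#' A compilation of UMA parameters (`do_gy`, `n`) fitted to published
#' clonogenic survival curves of human tumour cell lines, together with
#' the clinically relevant fractionation scheme for each tumour type
#' (`dose_per_fraction_gy`, `fractions`), the reference values of the
#' dose-dependent `alpha`, `alpha/beta` and EQD2 derived from them
#' (`*_ref` columns; `alpha_beta_ref` is `NA` for pure-exponential lines),
#' the LQ-model EQD2 reported alongside (`lq_eqd2_ref`), and the clinical
#' \eqn{\alpha/\beta} conventionally used per tumour site
#' (`clinical_alpha_beta`: 3 Gy prostate, 8 Gy lung and colorectal,
#' 10 Gy otherwise).  The alpha-particle breast-cancer row carries
#' `ref_do_gy`/`ref_n`, the gamma-ray parameters of the same cells used
#' as the 2-Gy reference radiation in its EQD2.
#'
#' @return A data frame with 31 rows, one per cell line / condition.
#' @examples
#' tab <- tumor_parameter_table()
#' tab[tab$cell_line == "U373MG", c("do_gy", "n", "eqd2_ref")]
#' @export
tumor_parameter_table <- function() {
  path <- system.file("extdata", "tumor_parameters.csv", package = "umasurv",
                      mustWork = TRUE)
  utils::read.csv(path, check.names = TRUE, stringsAsFactors = FALSE)
}

#' Recompute model quantities for a parameter table
#'
#' For each row, evaluates the dose-dependent `alpha` and `alpha/beta` at
#' that row's dose per fraction, the UMA EQD2 of the row's scheme (using
#' `ref_do_gy`/`ref_n` as the reference radiation where present), and the
#' LQ EQD2 from the row's clinical \eqn{\alpha/\beta}.  When the table
#' carries `*_ref` columns, match flags are added: `alpha` and
#' `alpha_beta` at two-significant-figure tolerance (half a unit in the
#' last printed place), EQD2 within `eqd2_tol` Gy.
#'
#' @param table Data frame in the layout of [tumor_parameter_table()]
#'   (minimum columns: `cell_line`, `do_gy`, `n`, `dose_per_fraction_gy`,
#'   `fractions`; optional `clinical_alpha_beta`, `ref_do_gy`, `ref_n`,
#'   and `*_ref` reference columns).
#' @param eqd2_tol Absolute EQD2 tolerance in Gy for the match flag.
#' @return The table with columns `alpha`, `alpha_beta`, `eqd2`,
#'   `lq_eqd2` appended, plus `alpha_match`, `alpha_beta_match`,
#'   `eqd2_match` and `row_match` when reference columns exist.
#' @export
recompute_tumor_table <- function(table, eqd2_tol = 0.1) {
  need <- c("cell_line", "do_gy", "n", "dose_per_fraction_gy", "fractions")
  miss <- setdiff(need, names(table))
  if (length(miss))
    stop("missing columns: ", paste(miss, collapse = ", "), call. = FALSE)
  nr <- nrow(table)
  out <- table
  out$alpha <- out$alpha_beta <- out$eqd2 <- out$lq_eqd2 <- NA_real_
  for (i in seq_len(nr)) {
    p <- uma_params(table$do_gy[i], table$n[i])
    D <- table$dose_per_fraction_gy[i]; N <- table$fractions[i]
    scheme <- treatment_scheme(D, N)
    pref <- if (!is.null(table$ref_do_gy) && is.finite(table$ref_do_gy[i]))
      uma_params(table$ref_do_gy[i], table$ref_n[i]) else p
    out$alpha[i] <- uma_alpha(p, D)
    out$alpha_beta[i] <- uma_alpha_beta_ratio(p, D)
    out$eqd2[i] <- uma_eqd2(p, scheme, params_ref = pref)$eqd2
    if (!is.null(table$clinical_alpha_beta) &&
        is.finite(table$clinical_alpha_beta[i]))
      out$lq_eqd2[i] <- lq_eqd2(table$clinical_alpha_beta[i], scheme)
  }
  if (!is.null(table$alpha_ref)) {
    out$alpha_match <- two_sig_fig_match(out$alpha, table$alpha_ref)
    out$alpha_beta_match <- two_sig_fig_match(out$alpha_beta, table$alpha_beta_ref)
    out$eqd2_match <- abs(out$eqd2 - table$eqd2_ref) <= eqd2_tol + 1e-9
    out$row_match <- out$alpha_match & out$alpha_beta_match & out$eqd2_match
  }
  out
}

# TRUE when x agrees with a reference printed to two significant figures:
# within half a unit in the reference's last printed place.
two_sig_fig_match <- function(x, ref) {
  both_na <- is.na(x) & is.na(ref)
  tol <- 0.5 * 10^(floor(log10(abs(ref))) - 1)
  ok <- abs(x - ref) <= tol * (1 + 1e-9)
  ifelse(both_na, TRUE, !is.na(x) & !is.na(ref) & ok)
}
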