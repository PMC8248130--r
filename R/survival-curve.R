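#' Clonogenic survival curve
#'
#' Builds the container used by all fitting routines: an ordered set of
#' dose points, each carrying either raw replicate survival fractions or a
#' precomputed mean (with optional standard deviation).  Doses must be
#' strictly increasing and survivals in (0, 1].  Following clonogenic-assay
#' convention, survival is normalized to 1 at zero dose and the zero-dose
#' anchor carries no error bar; if the zero-dose point is missing it is
#' inserted as (0, 1) with a message.
#'
#' @param dose Numeric vector of doses in Gy, strictly increasing, >= 0.
#' @param replicates List of numeric vectors (one per dose point) of
#'   replicate survival fractions, or `NULL` if `mean` is given.
#' @param mean Numeric vector of mean survival fractions (used when raw
#'   replicates are unavailable).
#' @param sd Optional numeric vector of standard deviations matching `mean`.
#' @param add_zero Insert the (0, 1) anchor when absent (default `TRUE`).
#' @return A data frame of class `survival_curve` with columns `dose`,
#'   `mean`, `sd`, `n_rep` and a list column `replicates`.
#' @examples
#' survival_curve(dose = c(0, 2, 4), replicates = list(1, c(.5, .55), c(.2, .22)))
#' @export
survival_curve <- function(dose, replicates = NULL, mean = NULL, sd = NULL,
                           add_zero = TRUE) {
  if (!is.numeric(dose) || any(!is.finite(dose)) || any(dose < 0))
    stop("'dose' must be finite numeric >= 0", call. = FALSE)
  if (is.unsorted(dose, strictly = TRUE))
    stop("'dose' must be strictly increasing", call. = FALSE)
  if (is.null(replicates) == is.null(mean))
    stop("supply exactly one of 'replicates' or 'mean'", call. = FALSE)

  if (!is.null(replicates)) {
    if (!is.list(replicates) || length(replicates) != length(dose))
      stop("'replicates' must be a list with one vector per dose", call. = FALSE)
    m <- vapply(replicates, function(v) base::mean(v), numeric(1))
    s <- vapply(replicates, function(v)
      if (length(v) >= 2L) stats::sd(v) else NA_real_, numeric(1))
    nr <- lengths(replicates)
  } else {
    if (length(mean) != length(dose))
      stop("'mean' must match 'dose' in length", call. = FALSE)
    m <- as.numeric(mean)
    s <- if (is.null(sd)) rep(NA_real_, length(dose)) else as.numeric(sd)
    if (length(s) != length(dose))
      stop("'sd' must match 'dose' in length", call. = FALSE)
    nr <- rep(1L, length(dose))
    replicates <- lapply(m, identity)
  }
  vals <- unlist(replicates)
  if (any(!is.finite(vals)) || any(vals <= 0) || any(vals > 1 + 1e-12))
    stop("survival fractions must lie in (0, 1]", call. = FALSE)

  if (!any(dose == 0) && add_zero) {
    message("zero-dose anchor absent; inserting (dose = 0, survival = 1)")
    dose <- c(0, dose); m <- c(1, m); s <- c(NA_real_, s)
    nr <- c(1L, nr); replicates <- c(list(1), replicates)
  }
  if (any(dose == 0)) {
    i0 <- which(dose == 0)
    if (abs(m[i0] - 1) > 1e-9)
      stop("zero-dose survival must be 1 (normalization convention)",
           call. = FALSE)
    s[i0] <- NA_real_  # no error bar at the anchor
  }
  out <- data.frame(dose = dose, mean = m, sd = s, n_rep = nr)
  out$replicates <- replicates
  class(out) <- c("survival_curve", "data.frame")
  out
}

#' @export
print.survival_curve <- function(x, ...) {
  cat(sprintf("Survival curve: %d dose points, %s replicates\n",
              nrow(x), paste(range(x$n_rep), collapse = "-")))
  print(data.frame(dose = x$dose, mean = signif(x$mean, 4),
                   sd = signif(x$sd, 3), n_rep = x$n_rep), row.names = FALSE)
  invisible(x)
}

#' Read a survival curve from CSV
#'
#' Accepts the two dialects used throughout the package: a header
#' `dose_gy,rep1,rep2,...` with one replicate survival fraction per column,
#' or `dose_gy,mean[,sd]`.  Doses must be ascending; a zero-dose row
#' (0, 1) is inserted with a message when absent.  Empty replicate cells
#' are allowed (ragged replicate counts).
#'
#' @param path Path to a CSV file.
#' @return A [survival_curve()].
#' @export
read_survival_csv <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE)
  if (nrow(df) < 1L) stop("empty survival-curve file: ", path, call. = FALSE)
  nms <- tolower(names(df))
  if (nms[1] != "dose_gy")
    stop("first column must be 'dose_gy' (got '", names(df)[1], "')",
         call. = FALSE)
  dose <- as.numeric(df[[1]])
  if ("mean" %in% nms) {
    m <- as.numeric(df[[which(nms == "mean")]])
    s <- if ("sd" %in% nms) as.numeric(df[[which(nms == "sd")]]) else NULL
    survival_curve(dose, mean = m, sd = s)
  } else {
    repcols <- grep("^rep", nms)
    if (length(repcols) == 0L)
      stop("expected 'mean' or 'rep*' columns in ", path, call. = FALSE)
    reps <- lapply(seq_len(nrow(df)), function(i) {
      v <- as.numeric(unlist(df[i, repcols]))
      v <- v[is.finite(v)]
      if (length(v) == 0L)
        stop("row ", i, " of ", path, " has no replicate values", call. = FALSE)
      v
    })
    survival_curve(dose, replicates = reps)
  }
}

#' Write a survival curve to CSV
#'
#' Writes raw replicates (`dose_gy,rep1,...`) when the curve carries more
#' than one replicate anywhere, otherwise the `dose_gy,mean,sd` form.
#'
#' @param curve A [survival_curve()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_survival_csv <- function(curve, path) {
  stopifnot(inherits(curve, "survival_curve"))
  if (max(curve$n_rep) > 1L) {
    k <- max(curve$n_rep)
    mat <- t(vapply(curve$replicates, function(v) c(v, rep(NA_real_, k - length(v))),
                    numeric(k)))
    df <- data.frame(dose_gy = curve$dose, mat)
    names(df)[-1] <- paste0("rep", seq_len(k))
  } else {
    df <- data.frame(dose_gy = curve$dose, mean = curve$mean, sd = curve$sd)
  }
  utils::write.csv(df, path, row.names = FALSE, na = "")
  invisible(path)
}
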