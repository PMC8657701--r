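# TMM normalization of the Amp x line count matrix, per-line frequencies,
# and the presence threshold used throughout classification.
#
# The trimmed-mean-of-M-values estimator is coded here from its published
# definition (reference column by upper-quartile proximity; M/A computed on
# library-size-scaled proportions over features nonzero in both; 30% trim
# on M, 5% on A; precision-weighted mean; factors renormalized to geometric
# mean 1).  The edgeR implementation serves as an independent cross-check
# in the test suite, never as the implementation.

#' TMM scale factors and normalized matrix
#'
#' @param counts integer matrix (Amps x lines) with at least two columns,
#'   every column with a positive total.
#' @param logratio_trim,sum_trim trim fractions for M and A (defaults 0.3
#'   and 0.05).
#' @param units_constant multiplier applied to count / (library size x
#'   factor); the default 1e6 puts normalized values on a
#'   counts-per-million-like scale.
#' @return object of class `amp_abundance`: list with `counts`,
#'   `scale_factors` (geometric mean 1), `tmm` (normalized matrix), and the
#'   `units_constant` used.
#' @export
tmm_normalize <- function(counts, logratio_trim = 0.3, sum_trim = 0.05,
                          units_constant = 1e6) {
  counts <- as.matrix(counts)
  if (ncol(counts) < 2) stop("TMM needs at least two lines")
  lib <- colSums(counts)
  if (any(lib <= 0))
    stop("line(s) with zero total counts: ",
         paste(colnames(counts)[lib <= 0], collapse = ", "))

  x <- counts[rowSums(counts > 0) > 0, , drop = FALSE]
  # reference line: upper quartile (library-size scaled) closest to the mean
  f75 <- apply(x, 2, function(col) quantile(col, probs = 0.75)) / lib
  ref_col <- which.min(abs(f75 - mean(f75)))

  factors <- vapply(seq_len(ncol(x)), function(j) {
    tmm_pair_factor(x[, j], x[, ref_col], lib[j], lib[ref_col],
                    logratio_trim, sum_trim)
  }, numeric(1))
  factors <- factors / exp(mean(log(factors)))  # geometric mean 1
  names(factors) <- colnames(counts)

  tmm <- sweep(counts, 2, lib * factors, "/") * units_constant
  structure(list(counts = counts, scale_factors = factors, tmm = tmm,
                 units_constant = units_constant),
            class = "amp_abundance")
}

# Two-sample TMM factor (obs vs ref), the published estimator.
tmm_pair_factor <- function(obs, ref, n_obs, n_ref,
                            logratio_trim = 0.3, sum_trim = 0.05) {
  obs <- as.numeric(obs); ref <- as.numeric(ref)
  logR <- log2((obs / n_obs) / (ref / n_ref))           # M-values
  absE <- (log2(obs / n_obs) + log2(ref / n_ref)) / 2   # A-values
  v <- (n_obs - obs) / n_obs / obs + (n_ref - ref) / n_ref / ref
  fin <- is.finite(logR) & is.finite(absE)
  logR <- logR[fin]; absE <- absE[fin]; v <- v[fin]
  if (!length(logR) || max(abs(logR)) < 1e-6) return(1)
  n <- length(logR)
  lo_l <- floor(n * logratio_trim) + 1; hi_l <- n + 1 - lo_l
  lo_s <- floor(n * sum_trim) + 1; hi_s <- n + 1 - lo_s
  keep <- (rank(logR) >= lo_l & rank(logR) <= hi_l) &
    (rank(absE) >= lo_s & rank(absE) <= hi_s)
  f <- sum(logR[keep] / v[keep], na.rm = TRUE) / sum(1 / v[keep], na.rm = TRUE)
  if (is.na(f)) f <- 0
  2^f
}

#' @export
print.amp_abundance <- function(x, ...) {
  cat("Amp abundance matrix:", nrow(x$counts), "Amps x", ncol(x$counts),
      "lines\n")
  cat("  TMM scale factors:",
      paste(sprintf("%.3f", x$scale_factors), collapse = " "), "\n")
  invisible(x)
}

#' Per-line frequencies (%) of normalized abundances
#'
#' @param x an `amp_abundance` (frequencies computed on the TMM-normalized
#'   values) or a plain matrix (e.g. raw counts, via `use_raw` semantics).
#' @return matrix of per-line frequencies; each column sums to 100.
#' @export
amp_frequencies <- function(x) {
  m <- if (inherits(x, "amp_abundance")) x$tmm else as.matrix(x)
  cs <- colSums(m)
  if (any(cs <= 0))
    stop("all-zero column(s): ", paste(colnames(m)[cs <= 0], collapse = ", "))
  sweep(m, 2, cs, "/") * 100
}

#' Presence calls from a frequency matrix
#'
#' An Amp is present in a line iff its frequency strictly exceeds the
#' threshold (the published rule is "frequency higher than 0.3%", so
#' exactly 0.3% is absent).
#'
#' @param freq frequency matrix (%) from [amp_frequencies()].
#' @param threshold_pct presence threshold in percent (default 0.3).
#' @return logical matrix of the same shape.
#' @export
amp_presence <- function(freq, threshold_pct = 0.3) {
  stopifnot(threshold_pct >= 0)
  freq > threshold_pct
}
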