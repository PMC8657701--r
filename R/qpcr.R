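# qPCR relative copy-number estimation used to corroborate large deletions
# at a tandem locus: efficiency transform and target/reference ratio.

#' Amplification efficiency from instrument percent efficiency
#'
#' `E = E_cfx / 100 + 1`, so 100% efficiency gives the perfect doubling
#' E = 2.
#'
#' @param e_cfx percent efficiency reported by the instrument (> 0).
#' @return per-cycle amplification factor E.
#' @export
qpcr_efficiency <- function(e_cfx) {
  if (any(e_cfx <= 0)) stop("efficiency must be positive")
  e_cfx / 100 + 1
}

#' Describe one qPCR assay
#'
#' @param target_name assay label.
#' @param mcq mean quantification cycle (> 0).
#' @param e_cfx percent efficiency (alternative to `efficiency`).
#' @param efficiency per-cycle amplification factor E (alternative to
#'   `e_cfx`).
#' @param n_copies copies per haploid genome (reference genes; default 2).
#' @return object of class `qpcr_assay`.
#' @export
qpcr_assay <- function(target_name, mcq, e_cfx = NULL, efficiency = NULL,
                       n_copies = 2) {
  if (is.null(efficiency)) {
    if (is.null(e_cfx)) stop("supply e_cfx or efficiency")
    if (e_cfx <= 50 || e_cfx >= 150)
      warning("percent efficiency ", e_cfx, " outside the (50, 150) sanity range")
    efficiency <- qpcr_efficiency(e_cfx)
  }
  stopifnot(mcq > 0)
  structure(list(target_name = target_name, efficiency = efficiency,
                 mcq = mcq, n_copies = n_copies),
            class = "qpcr_assay")
}

#' Efficiency-corrected copy-number ratio of target vs reference
#'
#' `ratio = N * E_ref^MCq_ref / E_target^MCq_target`, with N the reference
#' gene's copies per haploid genome.  A lower target MCq (more template)
#' raises the ratio.
#'
#' @param ref,target [qpcr_assay()] objects (reference and target).
#' @return the copy-number ratio.
#' @export
copy_ratio <- function(ref, target) {
  stopifnot(inherits(ref, "qpcr_assay"), inherits(target, "qpcr_assay"))
  ref$n_copies * ref$efficiency^ref$mcq / target$efficiency^target$mcq
}

#' Fold change of amplicon copy number, CRISPR vs wild type
#'
#' Per reference gene, fold = mean ratio over CRISPR lines divided by mean
#' ratio over WT lines; reference genes are pooled on the ratio scale by
#' geometric mean.
#'
#' @param crispr_ratios,wt_ratios named numeric vectors (or named lists of
#'   per-line vectors) of [copy_ratio()] values keyed by reference gene;
#'   both must cover the same reference genes.
#' @return list with `per_reference` (named vector of folds) and `pooled`
#'   (geometric mean fold).
#' @export
crispr_vs_wt_ratio <- function(crispr_ratios, wt_ratios) {
  refs <- names(crispr_ratios)
  if (is.null(refs) || !setequal(refs, names(wt_ratios)))
    stop("CRISPR and WT ratios must cover the same reference genes")
  fold <- vapply(refs, function(r) {
    mean(unlist(crispr_ratios[[r]])) / mean(unlist(wt_ratios[[r]]))
  }, numeric(1))
  list(per_reference = fold, pooled = exp(mean(log(fold))))
}
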