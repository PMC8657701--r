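# Reporting artifacts: stage-statistics table, min-max scaled heatmap
# inputs, classical MDS coordinates.  The TSV/JSON data behind each figure
# is the tested contract; graphics are optional conveniences.

#' Stage-statistics table in the published layout
#'
#' Rows Pairs / Merged / Filtered / Denoised / Matched / Assigned.  Merged,
#' Filtered and Denoised are percentages of the previous stage; Matched is
#' the percentage of denoised-contained reads in database-matched Amps;
#' Assigned is the percentage of raw read pairs assigned to Amps.  The
#' Pairs row shows 100 with the raw count in parentheses.
#'
#' @param run an `amp_run` from [run_chain()], or its `stats` data.frame.
#' @return data.frame `step`, `pct` (numeric), `display` (formatted string,
#'   two decimals).
#' @export
stage_table <- function(run) {
  stats <- if (inherits(run, "amp_run")) run$stats else run
  tot <- function(col) sum(stats[[col]], na.rm = TRUE)
  pairs <- tot("pairs")
  pct <- c(
    Pairs = 100,
    Merged = 100 * tot("merged") / pairs,
    Filtered = 100 * tot("filtered") / tot("merged"),
    Denoised = 100 * tot("denoised") / tot("filtered"),
    Matched = if (all(is.na(stats$matched))) NA_real_ else
      100 * tot("matched") / tot("denoised"),
    Assigned = 100 * tot("assigned") / pairs)
  display <- sprintf("%.2f", pct)
  display[1] <- sprintf("100 (%s reads)", format(pairs, big.mark = ","))
  display[is.na(pct)] <- NA_character_
  data.frame(step = c("Pairs (raw reads)", "Merged", "Filtered", "Denoised",
                      "Matched to the amplicon database",
                      "Assigned to Amps"),
             pct = as.numeric(pct), display = display,
             stringsAsFactors = FALSE)
}

#' Min-max scaled heatmap matrix in dendrogram leaf order
#'
#' Each row is scaled to \[0, 1\] by `(x - min) / (max - min)`; constant
#' rows map to 0 (documented convention).  Rows are ordered by the tree's
#' leaf order when a tree is given.  Optional WT/CRISPR and Cas9 status
#' vectors are attached as side annotations.
#'
#' @param tmm normalized abundance matrix (Amps x lines).
#' @param tree optional `phylo` whose tip labels order the rows.
#' @param amp_status optional named vector (per Amp), e.g. "WT"/"CRISPR".
#' @param cas9_status optional named vector (per line).
#' @return list with `matrix` (scaled, ordered), `row_order`, and the
#'   annotations.
#' @export
minmax_heatmap_matrix <- function(tmm, tree = NULL, amp_status = NULL,
                                  cas9_status = NULL) {
  m <- as.matrix(tmm)
  rng <- apply(m, 1, range)
  span <- rng[2, ] - rng[1, ]
  scaled <- (m - rng[1, ]) / ifelse(span == 0, 1, span)
  scaled[span == 0, ] <- 0
  ord <- rownames(m)
  if (!is.null(tree)) {
    leaves <- tree$tip.label
    ord <- c(intersect(leaves, rownames(m)), setdiff(rownames(m), leaves))
  }
  scaled <- scaled[ord, , drop = FALSE]
  list(matrix = scaled, row_order = ord,
       amp_status = amp_status[ord], cas9_status = cas9_status)
}

#' Classical MDS coordinates of line abundance profiles
#'
#' Classical (metric) multidimensional scaling on Euclidean distances
#' between the lines' normalized abundance profiles.  Coordinates are
#' defined up to rotation and reflection.
#'
#' @param tmm normalized abundance matrix (Amps x lines) or an
#'   `amp_abundance`.
#' @param k number of dimensions (default 2).
#' @return list with `coords` (lines x k matrix) and `eigenvalues`.
#' @export
mds_coordinates <- function(tmm, k = 2) {
  if (inherits(tmm, "amp_abundance")) tmm <- tmm$tmm
  m <- t(as.matrix(tmm))
  if (nrow(m) < 3) stop("MDS needs at least 3 lines")
  fit <- cmdscale(dist(m), k = k, eig = TRUE)
  coords <- fit$points
  if (is.null(dim(coords)) || ncol(coords) < k) {
    # degenerate configurations can yield fewer axes; pad with zeros
    pad <- matrix(0, nrow(m), k - ncol(as.matrix(fit$points)))
    coords <- cbind(as.matrix(fit$points), pad)
  }
  rownames(coords) <- colnames(tmm)
  list(coords = coords, eigenvalues = fit$eig)
}
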