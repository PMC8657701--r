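# Read processing: merge pairs, expected-error filter, dereplicate,
# denoise into unique denoised amplicons (Amps), identity search.
# This mirrors the five-stage usearch amplicon chain
# (fastq_mergepairs / fastq_filter / fastx_uniques / unoise2 /
# search_global) with documented, reproducible semantics.

#' Merge-stage parameters
#'
#' @param maxdiffs maximum mismatches tolerated in the overlap (non-integer
#'   values, e.g. from the optimizer, are floored at use).
#' @param maxdiffpct maximum percent mismatches in the overlap.
#' @param min_overlap minimum ungapped overlap length (default 16).
#' @return object of class `merge_params`.
#' @export
merge_params <- function(maxdiffs = 5, maxdiffpct = 25, min_overlap = 16) {
  stopifnot(maxdiffs >= 0, maxdiffpct > 0, maxdiffpct <= 100, min_overlap >= 1)
  structure(list(maxdiffs = maxdiffs, maxdiffpct = maxdiffpct,
                 min_overlap = as.integer(min_overlap)),
            class = "merge_params")
}

#' Merge paired-end reads by their best ungapped overlap
#'
#' For each pair, R2 is reverse-complemented and the overlap with R1
#' maximizing (matches - mismatches), of length at least `min_overlap`, is
#' taken; the pair is rejected when the overlap has more than
#' `floor(maxdiffs)` mismatches or a higher mismatch percentage than
#' `maxdiffpct`.  In the overlap, agreeing bases get an increased posterior
#' quality and disagreeing bases take the higher-quality base with a reduced
#' posterior quality, computed from the exact Bayesian posterior error
#' probability (capped at Q41).
#'
#' @param r1,r2 FASTQ paths or data.frames (`id`, `seq`, `qual`).
#' @param p a [merge_params()].
#' @return list with `reads` (data.frame `id`, `seq`, `qual` of merged
#'   reads) and `stats` (`input`, `merged`, `merged_fraction`).
#' @export
merge_pairs <- function(r1, r2, p = merge_params()) {
  stopifnot(inherits(p, "merge_params"))
  if (is.character(r1)) r1 <- read_fastq(r1)
  if (is.character(r2)) r2 <- read_fastq(r2)
  if (nrow(r1) != nrow(r2))
    stop("R1 and R2 have different record counts (", nrow(r1), " vs ",
         nrow(r2), ")")
  if (!nrow(r1)) {
    return(list(reads = r1[0, ],
                stats = list(input = 0L, merged = 0L, merged_fraction = NaN)))
  }
  s2 <- revcomp(r2$seq)
  q2 <- cpp_reverse_strings(r2$qual)
  res <- cpp_merge_pairs(r1$seq, r1$qual, s2, q2,
                         min_overlap = p$min_overlap,
                         maxdiffs = p$maxdiffs, maxdiffpct = p$maxdiffpct)
  ok <- res$merged
  reads <- data.frame(id = r1$id[ok], seq = res$seq[ok], qual = res$qual[ok],
                      stringsAsFactors = FALSE)
  list(reads = reads,
       stats = list(input = nrow(r1), merged = sum(ok),
                    merged_fraction = mean(ok)))
}

#' Filter-stage parameters
#' @param maxee maximum expected errors per merged read.
#' @return object of class `filter_params`.
#' @export
filter_params <- function(maxee = 1) {
  stopifnot(maxee > 0)
  structure(list(maxee = maxee), class = "filter_params")
}

#' Expected-error filter
#'
#' A read is kept iff the sum of its per-base error probabilities
#' `sum(10^(-Q/10))` does not exceed `maxee`.  Output is sequence-only
#' (qualities are consumed by this stage).
#'
#' @param reads data.frame (`id`, `seq`, `qual`) or FASTQ path.
#' @param p a [filter_params()].
#' @return list with `reads` (data.frame `id`, `seq`), `ee` (expected
#'   errors of all inputs) and `stats` (`input`, `kept`).
#' @export
filter_maxee <- function(reads, p = filter_params()) {
  stopifnot(inherits(p, "filter_params"))
  if (is.character(reads)) reads <- read_fastq(reads)
  bad <- grepl("[^\x21-\x7e]", reads$qual) | nchar(reads$qual) != nchar(reads$seq)
  if (any(bad))
    stop("malformed quality string in record(s): ",
         paste(head(reads$id[bad], 5), collapse = ", "))
  ee <- cpp_expected_errors(reads$qual)
  keep <- ee <= p$maxee
  list(reads = data.frame(id = reads$id[keep], seq = reads$seq[keep],
                          stringsAsFactors = FALSE),
       ee = ee,
       stats = list(input = nrow(reads), kept = sum(keep)))
}

#' Dereplicate sequences into (unique sequence, abundance) pairs
#'
#' Exact-string dereplication, sorted by abundance descending; ties are
#' broken lexicographically by sequence so the ordering is deterministic.
#'
#' @param seqs character vector of sequences, or a data.frame with a `seq`
#'   column, or a FASTA path.
#' @return data.frame `seq`, `size` sorted by decreasing `size`.
#' @export
dereplicate <- function(seqs) {
  if (is.character(seqs) && length(seqs) == 1 && file.exists(seqs))
    seqs <- read_fasta(seqs)$seq
  if (is.data.frame(seqs)) seqs <- seqs$seq
  if (!length(seqs))
    return(data.frame(seq = character(), size = integer()))
  tab <- table(seqs)
  out <- data.frame(seq = names(tab), size = as.integer(tab),
                    stringsAsFactors = FALSE)
  out <- out[order(-out$size, out$seq), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Denoise-stage parameters
#'
#' @param minampsize minimum abundance for a unique sequence to found a new
#'   centroid (non-integer optimizer values are floored at use).
#' @param alpha steepness of the abundance-skew curve
#'   `beta(d) = 2^-(alpha*d + 1)` (UNOISE default 2).
#' @param chimera run the de novo chimera pass (default TRUE).
#' @return object of class `denoise_params`.
#' @export
denoise_params <- function(minampsize = 8, alpha = 2, chimera = TRUE) {
  stopifnot(minampsize >= 1, alpha > 0)
  structure(list(minampsize = minampsize, alpha = alpha, chimera = chimera),
            class = "denoise_params")
}

beta_skew <- function(d, alpha) 2^-(alpha * d + 1)

#' Denoise dereplicated sequences into Amp centroids
#'
#' Greedy centroid pass in abundance order: a unique sequence U with
#' abundance a_U joins an existing centroid C at edit distance d > 0 iff
#' `a_U / a_C <= beta(d) = 2^-(alpha*d + 1)`; among qualifying centroids the
#' closest one wins (ties: larger abundance, then earlier centroid).
#' Otherwise U founds a new centroid when `a_U >= floor(minampsize)`.
#' Joined abundances accumulate into the centroid size.  The optional de
#' novo chimera pass then removes centroids that are a perfect left/right
#' concatenation of two distinct higher-abundance centroids.
#'
#' @param uniques data.frame `seq`, `size` sorted by decreasing abundance
#'   (as from [dereplicate()]).
#' @param p a [denoise_params()].
#' @return data.frame `id`, `seq`, `size` (reads absorbed, including the
#'   centroid's own), class `amp_set`, with attribute `mapping`: integer
#'   vector, for each input unique the index of the centroid it joined (NA
#'   = discarded).
#' @export
denoise <- function(uniques, p = denoise_params()) {
  stopifnot(inherits(p, "denoise_params"))
  minsize <- floor(p$minampsize)
  n <- nrow(uniques)
  if (!n) {
    out <- data.frame(id = character(), seq = character(), size = integer())
    class(out) <- c("amp_set", "data.frame")
    return(out)
  }
  if (is.unsorted(rev(uniques$size)))
    stop("uniques must be sorted by abundance descending")
  cent_seq <- character(); cent_own <- integer(); cent_size <- numeric()
  mapping <- rep(NA_integer_, n)
  for (i in seq_len(n)) {
    u <- uniques$seq[i]; a <- uniques$size[i]
    joined <- FALSE
    if (length(cent_seq)) {
      # skew <= beta(d) bounds the useful edit distance from above
      best_d <- Inf; best_j <- 0L
      for (j in seq_along(cent_seq)) {
        skew <- a / cent_own[j]
        if (skew > beta_skew(1, p$alpha)) next
        dmax_j <- floor((-log2(skew) - 1) / p$alpha)
        dmax_try <- min(dmax_j, best_d - 1)
        if (dmax_try < 1) next
        d <- cpp_edit_distance_banded(u, cent_seq[j], as.integer(dmax_try))
        if (d > 0 && d < best_d) { best_d <- d; best_j <- j }
      }
      if (best_j > 0L) {
        cent_size[best_j] <- cent_size[best_j] + a
        mapping[i] <- best_j
        joined <- TRUE
      }
    }
    if (!joined && a >= minsize) {
      cent_seq <- c(cent_seq, u)
      cent_own <- c(cent_own, a)
      cent_size <- c(cent_size, a)
      mapping[i] <- length(cent_seq)
    }
  }
  keep <- rep(TRUE, length(cent_seq))
  if (p$chimera && length(cent_seq) >= 3) {
    for (x in seq_along(cent_seq)) {
      parents <- which(cent_own > cent_own[x])
      if (length(parents) < 2) next
      pl <- cpp_lcp_lcs(cent_seq[x], cent_seq[parents])
      nx <- nchar(cent_seq[x])
      # a single parent explaining x as its own prefix + suffix means x is
      # an indel relative of that parent, not a crossover product
      if (any(pl$lcp + pl$lcs >= nx)) next
      for (ai in seq_along(parents)) {
        hit <- which(pl$lcs + pl$lcp[ai] >= nx & seq_along(parents) != ai)
        if (length(hit)) { keep[x] <- FALSE; break }
      }
    }
  }
  out <- data.frame(id = sprintf("Amp%03d", seq_along(cent_seq)[keep]),
                    seq = cent_seq[keep],
                    size = as.integer(cent_size[keep]),
                    stringsAsFactors = FALSE)
  remap <- rep(NA_integer_, length(cent_seq))
  remap[keep] <- seq_len(sum(keep))
  attr(out, "mapping") <- remap[mapping]
  rownames(out) <- NULL
  class(out) <- c("amp_set", "data.frame")
  out
}

#' Search-stage parameters
#'
#' @param identity minimum global identity in (0, 1] for an assignment.
#' @param mode `"global"` (end-to-end alignment identity, terminal gaps
#'   excluded) or `"exact"` (string equality; forces identity 1).
#' @param top_candidates number of k-mer-ranked database candidates aligned
#'   per query (usearch-style accept heuristic).
#' @return object of class `search_params`.
#' @export
search_params <- function(identity = 0.99, mode = c("global", "exact"),
                          top_candidates = 8) {
  mode <- match.arg(mode)
  stopifnot(identity > 0, identity <= 1)
  if (mode == "exact") identity <- 1
  structure(list(identity = identity, mode = mode,
                 top_candidates = as.integer(top_candidates)),
            class = "search_params")
}

# identity of query vs target: global alignment with terminal gaps excluded
# from the column count.  Equal lengths take the Hamming shortcut (valid
# whenever the optimal alignment of equal-length near-identical sequences is
# gap-free, which holds at the identity thresholds used here).
glocal_identity <- function(query, target) {
  if (nchar(query) == nchar(target)) {
    mm <- cpp_hamming(query, target)
    return((nchar(query) - mm) / nchar(query))
  }
  aln <- cpp_align(query, target, free_ends = TRUE)
  st <- cpp_aln_stats(aln$a, aln$b)
  if (st$cols_internal == 0) return(0)
  st$matches / st$cols_internal
}

#' Assign query sequences to their best database hit by identity
#'
#' Global (end-to-end) alignment identity, defined as matches over
#' alignment columns with terminal gaps excluded.  Each query is assigned
#' to the highest-identity hit at or above the threshold; ties are broken
#' by longer hit, then lexicographic id.  `mode = "exact"` requires string
#' equality.  For speed, candidates are ranked by shared 8-mers and only the
#' top `top_candidates` are aligned (exact string matches short-circuit).
#'
#' @param queries character vector of sequences, or data.frame with `seq`
#'   (a `size` column, when present, weights the per-target read counts).
#' @param db data.frame `id`, `seq` (e.g. an `amplicon_db` or `amp_set`).
#' @param p a [search_params()].
#' @return list with `hits` (data.frame `query`, `hit`, `identity`; `hit`
#'   is NA below threshold) and `target_counts` (named vector of reads per
#'   target).
#' @export
search_assign <- function(queries, db, p = search_params()) {
  stopifnot(inherits(p, "search_params"))
  if (!nrow(db)) stop("empty search database")
  sizes <- NULL
  if (is.data.frame(queries)) { sizes <- queries$size; queries <- queries$seq }
  if (is.null(sizes)) sizes <- rep(1L, length(queries))
  nq <- length(queries)
  hit <- rep(NA_character_, nq)
  ident <- rep(NA_real_, nq)
  if (nq) {
    exact <- match(queries, db$seq)
    db_len <- nchar(db$seq)
    inexact <- which(is.na(exact))
    shared_mat <- if (length(inexact) && p$mode != "exact")
      cpp_shared_kmers_matrix(queries[inexact], db$seq, k = 8) else NULL
    shared_row <- setNames(seq_along(inexact), inexact)
    for (i in seq_len(nq)) {
      if (!is.na(exact[i])) { hit[i] <- db$id[exact[i]]; ident[i] <- 1; next }
      if (p$mode == "exact") next
      shared <- shared_mat[shared_row[[as.character(i)]], ]
      ord <- order(-shared, -db_len, db$id)
      cand <- head(ord, p$top_candidates)
      best_id <- -1; best_j <- 0L
      for (j in cand) {
        idj <- glocal_identity(queries[i], db$seq[j])
        better <- idj > best_id ||
          (idj == best_id && best_j > 0L &&
             (db_len[j] > db_len[best_j] ||
                (db_len[j] == db_len[best_j] && db$id[j] < db$id[best_j])))
        if (better) { best_id <- idj; best_j <- j }
        if (best_id >= 1) break
      }
      if (best_j > 0L && best_id >= p$identity) {
        hit[i] <- db$id[best_j]; ident[i] <- best_id
      }
    }
  }
  counts <- tapply(sizes[!is.na(hit)], hit[!is.na(hit)], sum)
  target_counts <- setNames(rep(0, nrow(db)), db$id)
  if (length(counts)) target_counts[names(counts)] <- as.numeric(counts)
  list(hits = data.frame(query = seq_len(nq), hit = hit, identity = ident,
                         stringsAsFactors = FALSE),
       target_counts = target_counts)
}
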