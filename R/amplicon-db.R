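# Non-redundant amplicon database: locate the primer pair in full-length
# family sequences, extract and trim the amplicon, drop exact duplicates
# while keeping provenance.

#' Define an amplicon primer pair
#'
#' Both primers are given 5'->3' as ordered for PCR: the reverse primer
#' anneals to the opposite strand, so its reverse complement is searched
#' downstream of the forward primer.  IUPAC ambiguity codes are honoured
#' (the default reverse primer carries an R).
#'
#' @param forward,reverse IUPAC DNA strings.
#' @return object of class `primer_pair`.
#' @export
primer_pair <- function(forward, reverse) {
  forward <- toupper(forward); reverse <- toupper(reverse)
  ok <- function(x) nzchar(x) && all(strsplit(x, "")[[1]] %in% names(IUPAC_MAP))
  if (!ok(forward) || !ok(reverse))
    stop("primers must be non-empty IUPAC DNA strings")
  structure(list(forward = forward, reverse = reverse), class = "primer_pair")
}

#' Default alpha-gliadin amplicon primers
#'
#' The primer pair spanning the alpha-gliadin amplicon:
#' aGli900F1 (forward) and 33mer1R2 (reverse, degenerate at one position).
#'
#' @return a [primer_pair()].
#' @export
default_primers <- function() {
  primer_pair(forward = "GTTAGAGTTCCAGTGCCACAA",
              reverse = "GGTTGTTGTGGTTGCGRATA")
}

# Best match of an IUPAC pattern in a plain DNA subject.
# Returns list(start, mismatches) of the best (fewest-mismatch, then
# leftmost) occurrence with mismatches <= max_mismatch, or NULL.
iupac_best_match <- function(subject, pattern, max_mismatch) {
  hits <- Biostrings::matchPattern(
    pattern, Biostrings::DNAString(subject),
    max.mismatch = max_mismatch, fixed = FALSE)
  if (!length(hits)) return(NULL)
  starts <- IRanges::start(hits)
  mm <- vapply(seq_along(hits), function(i) {
    sub <- as.character(hits[[i]])
    pat <- strsplit(pattern, "")[[1]]
    sum(vapply(seq_along(pat), function(k) {
      !(substr(sub, k, k) %in% IUPAC_MAP[[pat[k]]])
    }, logical(1)))
  }, integer(1))
  list(starts = starts, mismatches = mm)
}

#' Extract the amplicon delimited by a primer pair
#'
#' Finds the best forward-primer match and the best (reverse-complemented)
#' reverse-primer match downstream of it, allowing up to `max_mismatch`
#' mismatches per primer with IUPAC-aware comparison, and returns the
#' enclosed region.  When several primer matches exist, the combination
#' giving the longest amplicon is used (near-matches are common in
#' repeat-rich families).
#'
#' @param seq a DNA string (one full-length gene/pseudogene sequence).
#' @param primers a [primer_pair()].
#' @param max_mismatch mismatches tolerated per primer (default 1).
#' @param trim drop the primers from the returned amplicon (default TRUE).
#' @return the amplicon string, or `NULL` when either primer is absent (a
#'   forward match only downstream of every reverse match also yields
#'   `NULL`, with a warning).
#' @export
extract_amplicon <- function(seq, primers, max_mismatch = 1, trim = TRUE) {
  stopifnot(inherits(primers, "primer_pair"), max_mismatch >= 0)
  seq <- toupper(seq)
  fwd <- iupac_best_match(seq, primers$forward, max_mismatch)
  if (is.null(fwd)) return(NULL)
  rev_rc <- revcomp(primers$reverse)
  # reverse-complementing maps IUPAC codes too (R -> Y etc.)
  rev <- iupac_best_match(seq, rev_rc, max_mismatch)
  if (is.null(rev)) return(NULL)

  flen <- nchar(primers$forward); rlen <- nchar(primers$reverse)
  best <- NULL
  for (i in seq_along(fwd$starts)) {
    fs <- fwd$starts[i]
    after <- rev$starts > fs + flen - 1L
    if (!any(after)) next
    rs <- max(rev$starts[after])  # longest amplicon
    cand_len <- rs + rlen - fs + 1L
    if (is.null(best) || cand_len > best$len)
      best <- list(fs = fs, rs = rs, len = cand_len)
  }
  if (is.null(best)) {
    warning("forward primer matches only downstream of the reverse primer")
    return(NULL)
  }
  if (trim) substr(seq, best$fs + flen, best$rs - 1L)
  else substr(seq, best$fs, best$rs + rlen - 1L)
}

#' Build a non-redundant amplicon database
#'
#' Extracts the amplicon from every input sequence, uppercases, and removes
#' exact duplicates, recording which source sequences collapsed into each
#' record.  Sequences without both primer sites are skipped (counted in the
#' attribute `n_skipped`).
#'
#' @param fastas character vector of multi-FASTA paths, or a data.frame
#'   with columns `id`, `seq` (already-read sequences).
#' @param primers a [primer_pair()].
#' @param max_mismatch per-primer mismatch tolerance (default 1).
#' @return object of class `amplicon_db`: data.frame `id`, `seq` plus a
#'   `provenance` attribute (named list record id -> source ids).
#' @export
build_db <- function(fastas, primers = default_primers(), max_mismatch = 1) {
  if (is.character(fastas)) {
    if (!length(fastas)) stop("no input FASTA files")
    seqs <- do.call(rbind, lapply(fastas, read_fasta))
  } else {
    seqs <- fastas
  }
  if (is.null(seqs) || !nrow(seqs)) stop("no input sequences")
  amps <- vapply(seqs$seq, function(s) {
    a <- extract_amplicon(s, primers, max_mismatch)
    if (is.null(a)) NA_character_ else a
  }, character(1), USE.NAMES = FALSE)
  keep <- !is.na(amps)
  if (!any(keep)) stop("no sequence yielded an amplicon")
  amps <- toupper(amps[keep])
  src <- seqs$id[keep]

  uniq <- unique(amps)
  prov <- lapply(uniq, function(u) src[amps == u])
  ids <- sprintf("amp%03d", seq_along(uniq))
  names(prov) <- ids
  db <- data.frame(id = ids, seq = uniq, stringsAsFactors = FALSE)
  attr(db, "provenance") <- prov
  attr(db, "n_skipped") <- sum(!keep)
  class(db) <- c("amplicon_db", "data.frame")
  db
}

#' @export
print.amplicon_db <- function(x, ...) {
  cat("Non-redundant amplicon database:", nrow(x), "records\n")
  cat("  length range:", paste(range(nchar(x$seq)), collapse = "-"), "bp\n")
  ns <- attr(x, "n_skipped")
  if (!is.null(ns) && ns > 0) cat("  inputs without primer sites:", ns, "\n")
  invisible(x)
}

#' Write an amplicon database to FASTA plus a provenance TSV
#'
#' @param db an `amplicon_db`.
#' @param fasta,provenance_tsv output paths (`NULL` to skip either).
#' @export
write_db <- function(db, fasta, provenance_tsv = NULL) {
  stopifnot(inherits(db, "amplicon_db"))
  write_fasta(db$id, db$seq, fasta)
  if (!is.null(provenance_tsv)) {
    prov <- attr(db, "provenance")
    pv <- data.frame(id = names(prov),
                     sources = vapply(prov, paste, character(1), collapse = ","))
    write.table(pv, provenance_tsv, sep = "\t", quote = FALSE, row.names = FALSE)
  }
  invisible(db)
}
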