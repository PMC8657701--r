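# The end-to-end read-processing chain over multiple lines/samples:
# pooled Amp construction + per-line read assignment + stage statistics.

#' Bundle the five-stage pipeline parameters
#'
#' @param merge a [merge_params()].
#' @param filter a [filter_params()].
#' @param denoise a [denoise_params()].
#' @param search a [search_params()].
#' @return object of class `pipeline_params`.
#' @export
pipeline_params <- function(merge = merge_params(), filter = filter_params(),
                            denoise = denoise_params(), search = search_params()) {
  stopifnot(inherits(merge, "merge_params"), inherits(filter, "filter_params"),
            inherits(denoise, "denoise_params"), inherits(search, "search_params"))
  structure(list(merge = merge, filter = filter, denoise = denoise,
                 search = search),
            class = "pipeline_params")
}

#' Run the full read-processing chain over a set of lines
#'
#' Per line, read pairs are merged and expected-error filtered; the pooled
#' filtered reads are dereplicated and denoised into the Amp set.  Each
#' line's merged reads are then assigned to the pooled Amps by identity
#' search, giving the per-line count matrix.  When an amplicon database is
#' supplied, Amps are additionally matched against it and the fraction of
#' denoised reads contained in database-matched Amps is reported (the
#' pipeline's optimization score).
#'
#' @param samples list of samples, each a list with `line_id` and `r1`,
#'   `r2` (FASTQ paths or data.frames `id`/`seq`/`qual`).
#' @param params a [pipeline_params()].
#' @param db optional amplicon database (data.frame `id`, `seq`).
#' @return object of class `amp_run`: list with `amps` (the pooled
#'   `amp_set`, with per-line `sample_counts` columns attached), `counts`
#'   (integer matrix Amps x lines), `stats` (per-line + pooled stage
#'   counts), `db_hits` (Amp id -> db id or NA), `matched_reads` (total
#'   reads in db-matched Amps).
#' @export
run_chain <- function(samples, params = pipeline_params(), db = NULL) {
  stopifnot(inherits(params, "pipeline_params"), length(samples) >= 1)
  line_ids <- vapply(samples, function(s) s$line_id, character(1))
  if (anyDuplicated(line_ids)) stop("duplicate line ids")

  merged <- vector("list", length(samples))
  filtered <- vector("list", length(samples))
  pairs_n <- merged_n <- filtered_n <- integer(length(samples))
  for (i in seq_along(samples)) {
    s <- samples[[i]]
    m <- tryCatch(merge_pairs(s$r1, s$r2, params$merge),
                  error = function(e) stop("line ", s$line_id, ": ",
                                           conditionMessage(e), call. = FALSE))
    f <- filter_maxee(m$reads, params$filter)
    merged[[i]] <- m$reads
    filtered[[i]] <- f$reads
    pairs_n[i] <- m$stats$input
    merged_n[i] <- m$stats$merged
    filtered_n[i] <- f$stats$kept
  }

  pooled <- unlist(lapply(filtered, function(x) x$seq), use.names = FALSE)
  uniq <- dereplicate(pooled)
  amps <- denoise(uniq, params$denoise)
  if (!nrow(amps)) stop("denoising produced no Amps; inputs too sparse?")
  mapping <- attr(amps, "mapping")

  # reads contained in (absorbed by) retained centroids, per line
  denoised_n <- integer(length(samples))
  for (i in seq_along(samples)) {
    idx <- match(filtered[[i]]$seq, uniq$seq)
    denoised_n[i] <- sum(!is.na(mapping[idx]))
  }

  # per-line assignment of merged reads to the pooled Amp set
  counts <- matrix(0L, nrow = nrow(amps), ncol = length(samples),
                   dimnames = list(amps$id, line_ids))
  assigned_n <- integer(length(samples))
  for (i in seq_along(samples)) {
    du <- dereplicate(merged[[i]]$seq)
    if (nrow(du)) {
      res <- search_assign(du, amps, params$search)
      counts[, i] <- as.integer(round(res$target_counts[amps$id]))
    }
    assigned_n[i] <- sum(counts[, i])
  }

  db_hits <- NULL; matched_reads <- NA_real_; matched_n <- rep(NA_real_, length(samples))
  if (!is.null(db)) {
    res <- search_assign(amps, db, params$search)
    db_hits <- setNames(res$hits$hit, amps$id)
    ok_amp <- !is.na(db_hits)
    # reads contained in db-matched Amps, per line (of absorbed reads)
    for (i in seq_along(samples)) {
      idx <- match(filtered[[i]]$seq, uniq$seq)
      amp_of_read <- mapping[idx]
      matched_n[i] <- sum(!is.na(amp_of_read) & ok_amp[amp_of_read])
    }
    matched_reads <- sum(matched_n)
  }

  stats <- data.frame(line_id = line_ids, pairs = pairs_n, merged = merged_n,
                      filtered = filtered_n, denoised = denoised_n,
                      matched = matched_n, assigned = assigned_n,
                      stringsAsFactors = FALSE)
  # Amp size = reads assigned to it (sum over lines), per the Amp contract
  amps$size <- as.integer(rowSums(counts))
  amps$sample_counts <- I(lapply(seq_len(nrow(amps)), function(r)
    counts[r, , drop = TRUE]))

  structure(list(amps = amps, counts = counts, stats = stats,
                 db_hits = db_hits, matched_reads = matched_reads,
                 params = params),
            class = "amp_run")
}

#' @export
print.amp_run <- function(x, ...) {
  cat("Amplicon pipeline run:", nrow(x$amps), "Amps over",
      ncol(x$counts), "lines\n")
  cat("  raw pairs:", sum(x$stats$pairs),
      "| merged:", sum(x$stats$merged),
      "| filtered:", sum(x$stats$filtered),
      "| in Amps:", sum(x$stats$denoised), "\n")
  if (!all(is.na(x$stats$matched)))
    cat("  matched to database:", sum(x$stats$matched), "reads\n")
  invisible(x)
}
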