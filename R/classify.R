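# Classification of Amps into WT Amps and CRISPR Amps per genetic
# background, per-line offspring tables across generations, and subgenome
# assignment by translated-peptide motifs.

#' Line metadata table
#'
#' @param df data.frame with columns `line_id`, `background`, `generation`
#'   (one of `"WT"`, `"T0"`, `"T1"`, `"T2"`), optional `parent_id` (NA for
#'   WT and T0), optional `cas9` (`"present"`/`"absent"`/`"unknown"`).
#' @return validated data.frame of class `line_metadata`.
#' @export
line_metadata <- function(df) {
  need <- c("line_id", "background", "generation")
  stopifnot(all(need %in% names(df)))
  if (is.null(df$parent_id)) df$parent_id <- NA_character_
  if (is.null(df$cas9)) df$cas9 <- "unknown"
  stopifnot(all(df$generation %in% c("WT", "T0", "T1", "T2")))
  if (any(df$generation == "WT" & !is.na(df$parent_id)))
    stop("WT lines cannot have a parent")
  gen_rank <- c(WT = 0, T0 = 1, T1 = 2, T2 = 3)
  pr <- match(df$parent_id, df$line_id)
  bad <- !is.na(pr) & gen_rank[df$generation] <= gen_rank[df$generation[pr]]
  if (any(bad))
    stop("parent chain violates generation order for: ",
         paste(df$line_id[bad], collapse = ", "))
  class(df) <- c("line_metadata", "data.frame")
  df
}

#' The WT Amp set of a genetic background
#'
#' An Amp is a WT Amp iff it is present (above the presence threshold) in
#' at least one WT replicate of the background.  The WT count reported in
#' offspring tables is the mean of the per-replicate totals, rounded to the
#' nearest integer.
#'
#' @param presence logical matrix Amps x lines (from [amp_presence()]).
#' @param meta a [line_metadata()].
#' @param background background label to use.
#' @return character vector of Amp ids (the union over replicates), with
#'   attribute `wt_count` (rounded mean per-replicate total).
#' @export
wt_amp_set <- function(presence, meta, background) {
  wt_lines <- meta$line_id[meta$background == background &
                             meta$generation == "WT"]
  wt_lines <- intersect(wt_lines, colnames(presence))
  if (!length(wt_lines)) stop("no WT lines for background ", background)
  sub <- presence[, wt_lines, drop = FALSE]
  set <- rownames(presence)[rowSums(sub) > 0]
  attr(set, "wt_count") <- round(mean(colSums(sub)))
  set
}

#' Classify one edited line against its background's WT Amp set
#'
#' Partitions the line's present Amps into CRISPR Amps (absent from the WT
#' set) and non-targeted WT Amps (WT Amps still detected); WT Amps not
#' detected are the putative targeted WT Amps.  When a line has no CRISPR
#' Amps, WT-Amp presence is re-evaluated at a stricter (lower) secondary
#' threshold before any WT Amp is declared targeted -- a line without new
#' mutation products should not have WT Amps written off on a borderline
#' frequency.
#'
#' @param presence logical presence matrix at the primary threshold.
#' @param wt_set WT Amp id vector from [wt_amp_set()].
#' @param line line id (must be a column of `presence`).
#' @param freq frequency matrix (needed for the secondary re-evaluation;
#'   optional -- without it the primary presence stands).
#' @param secondary_threshold_pct stricter threshold (%) applied to WT Amps
#'   of zero-CRISPR-Amp lines (default 0.1).
#' @return data.frame row: `line_id`, `total_amps`, `crispr_amps`,
#'   `non_targeted_wt`, `putative_targeted_wt`, plus attribute `sets` (the
#'   underlying id sets).
#' @export
classify_line <- function(presence, wt_set, line, freq = NULL,
                          secondary_threshold_pct = 0.1) {
  if (!line %in% colnames(presence)) stop("line not in matrix: ", line)
  pres <- rownames(presence)[presence[, line]]
  crispr <- setdiff(pres, wt_set)
  non_targeted <- intersect(pres, wt_set)
  if (length(crispr) == 0 && !is.null(freq)) {
    sec <- rownames(freq)[freq[, line] > secondary_threshold_pct]
    non_targeted <- intersect(sec, wt_set)
  }
  targeted <- setdiff(wt_set, non_targeted)
  row <- data.frame(line_id = line,
                    total_amps = length(crispr) + length(non_targeted),
                    crispr_amps = length(crispr),
                    non_targeted_wt = length(non_targeted),
                    putative_targeted_wt = length(targeted),
                    stringsAsFactors = FALSE)
  attr(row, "sets") <- list(crispr = sort(crispr),
                            non_targeted = sort(non_targeted),
                            putative_targeted = sort(targeted))
  row
}

#' Offspring classification table for one background
#'
#' One row per non-WT line, ordered by pedigree: each T0 line is followed
#' by its T1 descendants, each T1 by its T2 descendants, then T1/T2 lines
#' attached directly to the T0.  A line whose non-targeted and putative
#' targeted WT Amp sets equal its parent's is flagged `non_segregating`.
#'
#' @param presence,freq presence and frequency matrices.
#' @param meta a [line_metadata()].
#' @param background background label.
#' @param secondary_threshold_pct see [classify_line()].
#' @return data.frame of classification rows with columns `line_id`,
#'   `generation`, `cas9`, `total_amps`, `crispr_amps`, `non_targeted_wt`,
#'   `putative_targeted_wt`, `non_segregating`, plus attribute `wt_count`.
#' @export
offspring_table <- function(presence, freq, meta, background,
                            secondary_threshold_pct = 0.1) {
  wt <- wt_amp_set(presence, meta, background)
  sub <- meta[meta$background == background & meta$generation != "WT", ,
              drop = FALSE]
  sub <- sub[sub$line_id %in% colnames(presence), , drop = FALSE]

  # pedigree ordering: depth-first from each T0 (roots = lines whose parent
  # is absent from the table), siblings in line_id order
  kids <- split(sub$line_id, factor(sub$parent_id, levels = sub$line_id))
  roots <- sub$line_id[is.na(sub$parent_id) | !(sub$parent_id %in% sub$line_id)]
  roots <- sort(roots)
  order_ids <- character(0)
  visit <- function(id, seen) {
    if (id %in% seen) stop("cycle in parent links at ", id)
    order_ids <<- c(order_ids, id)
    for (k in sort(kids[[id]] %||% character(0))) visit(k, c(seen, id))
  }
  for (r in roots) visit(r, character(0))
  if (length(order_ids) != nrow(sub))
    stop("cycle in parent links (unreachable lines: ",
         paste(setdiff(sub$line_id, order_ids), collapse = ","), ")")

  rows <- list(); sets <- list()
  for (id in order_ids) {
    row <- classify_line(presence, wt, id, freq, secondary_threshold_pct)
    sets[[id]] <- attr(row, "sets")
    m <- sub[sub$line_id == id, ]
    row$generation <- m$generation
    row$cas9 <- m$cas9
    parent <- m$parent_id
    row$non_segregating <- !is.na(parent) && !is.null(sets[[parent]]) &&
      identical(sets[[id]]$non_targeted, sets[[parent]]$non_targeted) &&
      identical(sets[[id]]$putative_targeted, sets[[parent]]$putative_targeted)
    rows[[id]] <- row
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out <- out[, c("line_id", "generation", "cas9", "total_amps", "crispr_amps",
                 "non_targeted_wt", "putative_targeted_wt", "non_segregating")]
  attr(out, "wt_count") <- attr(wt, "wt_count")
  attr(out, "wt_set") <- wt
  out
}

#' Assign an Amp to a subgenome by translated peptide motifs
#'
#' Translates the amplicon in the design reading frame and returns the
#' unique subgenome whose diagnostic motif(s) occur in the peptide; `NA`
#' when no motif or more than one subgenome matches.
#'
#' @param seq amplicon DNA sequence (primers trimmed; the design anchors
#'   frame 0 at the first base after the forward primer).
#' @param motif_table named list subgenome -> peptide motif(s); defaults to
#'   [default_subgenome_motifs()].
#' @param frame_offset 0-based offset into the amplicon where translation
#'   starts (default 0).
#' @return subgenome label or `NA_character_`.
#' @export
assign_subgenome <- function(seq, motif_table = default_subgenome_motifs(),
                             frame_offset = 0) {
  s <- substr(seq, frame_offset + 1, nchar(seq))
  s <- substr(s, 1, nchar(s) - nchar(s) %% 3)
  if (nchar(s) < 3) return(NA_character_)
  pep <- suppressWarnings(as.character(Biostrings::translate(
    Biostrings::DNAString(s), if.fuzzy.codon = "X")))
  hits <- vapply(names(motif_table), function(sg) {
    any(vapply(motif_table[[sg]], function(m) grepl(m, pep, fixed = TRUE),
               logical(1)))
  }, logical(1))
  if (sum(hits) == 1) names(motif_table)[hits] else NA_character_
}
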