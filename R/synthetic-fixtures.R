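# Synthetic fixture generator: multi-copy gene families with subgenome
# structure, CRISPR-edited descendants, and paired-end reads with a
# realistic error/quality model.  Everything is deterministic under one
# integer seed.

#' Specify a synthetic multi-copy gene family
#'
#' Describes a family of tandem paralogs split across subgenomes (A/B/D for
#' wheat), diverged from a common ancestral sequence.  Each subgenome can
#' carry a short in-frame peptide motif so that downstream subgenome
#' assignment by translated-motif matching is testable against truth.
#'
#' @param n_copies named integer vector, copies per subgenome, e.g.
#'   `c(A = 10, B = 10, D = 6)`.  Tetraploid families simply omit `D`.
#' @param ancestral_length length in bp of the ancestral gene; must exceed
#'   the amplicon primer span.
#' @param amplicon_span length in bp of the primer-to-primer amplicon
#'   (primers included, before motif insertion).  The default 440 keeps
#'   2 x 280 paired reads mergeable with a comfortable overlap.
#' @param divergence_within per-site substitution rate between paralogs, in
#'   \[0, 0.1\].
#' @param subgenome_motifs named list subgenome -> peptide motif (in-frame
#'   amino-acid string) inserted into all copies of that subgenome; defaults
#'   to the motifs shipped in [default_subgenome_motifs()].
#' @param primers a [primer_pair()]; primer binding sites are embedded in
#'   every copy so amplicons are extractable.
#' @param protospacers character vector of 20-mer protospacer sequences
#'   embedded (with an NGG PAM) between the primers of every copy, so that
#'   the family is targetable; defaults to the two alpha-gliadin guides.
#' @param seed integer master seed.
#' @return an object of class `family_spec`.
#' @export
family_spec <- function(n_copies = c(A = 10, B = 10, D = 6),
                        ancestral_length = 900,
                        amplicon_span = 440,
                        divergence_within = 0.02,
                        subgenome_motifs = default_subgenome_motifs(),
                        primers = default_primers(),
                        protospacers = default_target_sites()$protospacer,
                        seed = 1) {
  stopifnot(all(n_copies >= 1), ancestral_length >= 200,
            amplicon_span >= 150, ancestral_length >= amplicon_span + 40,
            divergence_within >= 0, divergence_within <= 0.1)
  if (is.null(names(n_copies)) || any(!nzchar(names(n_copies))))
    stop("n_copies must be named by subgenome label (e.g. A/B/D)")
  structure(list(n_copies = n_copies,
                 ancestral_length = as.integer(ancestral_length),
                 amplicon_span = as.integer(amplicon_span),
                 divergence_within = divergence_within,
                 subgenome_motifs = subgenome_motifs,
                 primers = primers,
                 protospacers = protospacers,
                 seed = as.integer(seed)),
            class = "family_spec")
}

#' Default subgenome diagnostic peptide motifs
#'
#' Synthetic stand-ins for subgenome-diagnostic peptide motifs of the
#' alpha-gliadin repetitive domain, shipped as editable data in
#' `extdata/subgenome_motifs.tsv` rather than hard-coded truth.  The true
#' published motifs are not redistributed here; these defaults are only
#' guaranteed to be consistent with [simulate_family()], which inserts
#' them in-frame.  Users analyzing real data should supply their own
#' motif table (TSV with columns `subgenome`, `motif`).
#'
#' @param path optional path to a motif TSV; defaults to the packaged one.
#' @return named list subgenome label -> peptide motif(s).
#' @export
default_subgenome_motifs <- function(path = NULL) {
  if (is.null(path))
    path <- system.file("extdata", "subgenome_motifs.tsv",
                        package = "amplindel")
  if (is.null(path) || !nzchar(path) || !file.exists(path))
    return(list(A = "QPFPQPQT", B = "QPYPQPQS", D = "QPIPQPQM"))
  tab <- read.delim(path, stringsAsFactors = FALSE)
  split(tab$motif, tab$subgenome)
}

random_dna <- function(n) paste(sample(DNA_BASES, n, replace = TRUE), collapse = "")

# Insert `insert` into `seq` at 1-based position pos (before pos).
str_insert <- function(seq, insert, pos) {
  paste0(substr(seq, 1, pos - 1), insert, substr(seq, pos, nchar(seq)))
}

peptide_to_dna <- function(pep) {
  # one deterministic codon per amino acid (standard code, arbitrary choice)
  codons <- c(A = "GCT", R = "CGT", N = "AAT", D = "GAT", C = "TGT",
              Q = "CAA", E = "GAA", G = "GGT", H = "CAT", I = "ATT",
              L = "CTT", K = "AAA", M = "ATG", F = "TTT", P = "CCA",
              S = "TCT", T = "ACT", W = "TGG", Y = "TAT", V = "GTT")
  aa <- strsplit(pep, "")[[1]]
  bad <- setdiff(aa, names(codons))
  if (length(bad)) stop("unknown amino acid(s) in motif: ", paste(bad, collapse = ","))
  paste(codons[aa], collapse = "")
}

#' Simulate a multi-copy gene family
#'
#' Builds an ancestral sequence containing both primer binding sites and the
#' protospacer + PAM target sites between them, then derives each paralog by
#' independent per-site substitution at rate `divergence_within` (primer
#' sites, target sites, and motif insertions are kept intact so that every
#' copy remains amplifiable and targetable).  Subgenome-specific peptide
#' motifs are inserted in-frame inside the amplicon region.
#'
#' @param spec a [family_spec()].
#' @return a data.frame (the truth table) with columns `copy_id`,
#'   `subgenome`, `seq`, of class `amp_family`.
#' @export
simulate_family <- function(spec) {
  stopifnot(inherits(spec, "family_spec"))
  with_seed(split_seed(spec$seed, 1L), {
    fwd <- toupper(spec$primers$forward)
    rev_site <- revcomp(toupper(gsub("R", "A", spec$primers$reverse)))
    # layout of the ancestral gene:
    # [pad1][FWD][core1][site1+PAM][core2][site2+PAM][core3][revcomp(REV)][pad2]
    pads <- (spec$ancestral_length - spec$amplicon_span) %/% 2L
    n_core <- length(spec$protospacers) + 1L
    inner <- spec$amplicon_span - nchar(fwd) - nchar(rev_site) -
      sum(nchar(spec$protospacers) + 3L)
    if (inner < 3L * n_core)
      stop("ancestral_length too short for the primer/target layout")
    core_len <- inner %/% n_core
    core_len <- core_len - core_len %% 3L  # keep frame stable
    cores <- vapply(seq_len(n_core), function(i) random_dna(core_len), character(1))
    sites <- paste0(spec$protospacers, "CGG")  # NGG PAM
    mid <- cores[1]
    if (length(sites)) {
      for (i in seq_along(sites)) mid <- paste0(mid, sites[i], cores[i + 1L])
    }
    anc <- paste0(random_dna(pads), fwd, mid, rev_site, random_dna(pads))

    # positions that must not mutate (primers + protospacer/PAM sites)
    prot <- rep(FALSE, nchar(anc))
    mark <- function(prot, start, len) { prot[start:(start + len - 1L)] <- TRUE; prot }
    fstart <- pads + 1L
    prot <- mark(prot, fstart, nchar(fwd))
    pos <- fstart + nchar(fwd) + nchar(cores[1]) - 1L  # last base of core1
    if (length(sites)) {
      for (i in seq_along(sites)) {
        prot <- mark(prot, pos + 1L, nchar(sites[i]))
        pos <- pos + nchar(sites[i]) + nchar(cores[i + 1L])
      }
    }
    prot <- mark(prot, pos + 1L, nchar(rev_site))

    anc_chars <- strsplit(anc, "")[[1]]
    free_idx <- which(!prot)

    out <- list()
    for (sg in names(spec$n_copies)) {
      motif_dna <- if (!is.null(spec$subgenome_motifs[[sg]]))
        peptide_to_dna(spec$subgenome_motifs[[sg]]) else ""
      for (k in seq_len(spec$n_copies[[sg]])) {
        chars <- anc_chars
        nmut <- rbinom(1, length(free_idx), spec$divergence_within)
        if (nmut > 0) {
          at <- sample(free_idx, nmut)
          chars[at] <- vapply(chars[at], function(b) {
            sample(setdiff(DNA_BASES, b), 1)
          }, character(1))
        }
        s <- paste(chars, collapse = "")
        if (nzchar(motif_dna)) {
          # in-frame insertion just after the forward primer (inside amplicon)
          ins_at <- fstart + nchar(fwd) + 3L  # codon boundary relative to primer end
          s <- str_insert(s, motif_dna, ins_at)
        }
        out[[length(out) + 1L]] <- data.frame(
          copy_id = sprintf("%s%02d", sg, k), subgenome = sg, seq = s,
          stringsAsFactors = FALSE)
      }
    }
    fam <- do.call(rbind, out)
    # sanity: primer sites survived
    ok <- vapply(fam$seq, function(s) {
      grepl(fwd, s, fixed = TRUE) && grepl(rev_site, s, fixed = TRUE)
    }, logical(1))
    if (!all(ok)) stop("divergence destroyed primer sites in some copies")
    class(fam) <- c("amp_family", "data.frame")
    fam
  })
}

#' Specify CRISPR edits to apply to a simulated family
#'
#' @param target_site a `target_site` (see [target_site()]) or the name of a
#'   default guide (`"sgAlpha1"`, `"sgAlpha2"`).
#' @param edits data.frame with columns `copy_id`, `indel_len` (signed:
#'   negative = deletion, positive = insertion), `offset` (bp from the cut
#'   site, 0 = at the cut).
#' @param large_deletion character vector of copy_ids removed entirely
#'   (emulating a chromosomal rearrangement at a tandem locus).
#' @param zygosity_fraction fraction (per edit) of molecules carrying the
#'   edit; 1 = homozygous, 0.5 = heterozygous mixtures.
#' @return object of class `edit_spec`.
#' @export
edit_spec <- function(target_site = "sgAlpha2",
                      edits = data.frame(copy_id = character(),
                                         indel_len = integer(),
                                         offset = integer()),
                      large_deletion = character(),
                      zygosity_fraction = 1) {
  if (is.character(target_site)) {
    ts <- default_target_sites()
    target_site <- as.list(ts[ts$name == target_site, ])
    if (!length(target_site$name)) stop("unknown default target site")
  }
  stopifnot(all(c("copy_id", "indel_len", "offset") %in% names(edits)),
            all(edits$indel_len != 0),
            zygosity_fraction >= 0, zygosity_fraction <= 1)
  structure(list(target_site = target_site, edits = edits,
                 large_deletion = large_deletion,
                 zygosity_fraction = zygosity_fraction),
            class = "edit_spec")
}

# Locate cut positions of a protospacer+NGG in `seq` (both strands).
# Returns 0-based cut positions: the break falls 3 bp 5' of the PAM,
# i.e. between protospacer positions 17 and 18.
find_cut_positions <- function(seq, protospacer, max_mismatch = 0) {
  hits <- integer()
  n <- nchar(seq)
  plen <- nchar(protospacer)
  if (n < plen + 3L) return(integer(0))
  scan <- function(s, proto) {
    res <- integer()
    starts <- seq_len(nchar(s) - plen - 2L)
    for (st in starts) {
      sub <- substr(s, st, st + plen - 1L)
      pam <- substr(s, st + plen, st + plen + 2L)
      if (substr(pam, 2, 3) != "GG") next
      mm <- cpp_hamming(sub, proto)
      if (mm >= 0 && mm <= max_mismatch) res <- c(res, st)
    }
    res
  }
  fw <- scan(seq, protospacer)
  # cut between positions (start+16) and (start+17) on forward strand
  if (length(fw)) hits <- c(hits, fw + 17L - 1L)
  rc <- scan(revcomp(seq), protospacer)
  if (length(rc)) {
    # map reverse-strand cut back to forward coordinates
    hits <- c(hits, n - (rc + 17L - 1L))
  }
  sort(unique(hits))
}

#' Apply CRISPR edits to a simulated family
#'
#' Edits are placed at the Cas9 cut site (the double-strand break 3 bp
#' upstream of the PAM) of the configured guide, shifted by each edit's
#' `offset`.  Deletions remove bases starting at the cut; insertions add
#' random bases at the cut.  Copies listed in `large_deletion` are dropped
#' from the output entirely.
#'
#' @param family an `amp_family` from [simulate_family()].
#' @param spec an [edit_spec()].
#' @param seed integer seed for inserted bases.
#' @return list with `molecules` (data.frame `copy_id`, `subgenome`, `seq`,
#'   `fraction`, `edited`) describing the molecular mixture, and `truth`
#'   (data.frame `copy_id`, `type`, `length`, `position` (0-based on the
#'   unedited copy), `offset`, `site`).
#' @export
apply_edits <- function(family, spec, seed = 1) {
  stopifnot(inherits(family, "amp_family"), inherits(spec, "edit_spec"))
  fam <- family[!(family$copy_id %in% spec$large_deletion), , drop = FALSE]
  truth <- list()
  molecules <- list()
  edited_seqs <- character()

  with_seed(split_seed(seed, 2L), {
    for (i in seq_len(nrow(fam))) {
      cid <- fam$copy_id[i]
      ed <- spec$edits[spec$edits$copy_id == cid, , drop = FALSE]
      if (!nrow(ed)) {
        molecules[[length(molecules) + 1L]] <- data.frame(
          copy_id = cid, subgenome = fam$subgenome[i], seq = fam$seq[i],
          fraction = 1, edited = FALSE, stringsAsFactors = FALSE)
        next
      }
      cuts <- find_cut_positions(fam$seq[i], spec$target_site$protospacer)
      if (!length(cuts))
        stop("copy ", cid, " does not contain the protospacer+PAM")
      cut <- cuts[1]
      for (j in seq_len(nrow(ed))) {
        pos0 <- cut + ed$offset[j]           # 0-based edit anchor
        len <- ed$indel_len[j]
        s <- fam$seq[i]
        if (pos0 < 0 || pos0 > nchar(s)) stop("edit offset outside sequence")
        if (len < 0) {
          if (pos0 - len > nchar(s)) stop("deletion runs off the sequence")
          new <- paste0(substr(s, 1, pos0), substr(s, pos0 - len + 1L, nchar(s)))
          type <- "deletion"
          # truth coordinates are left-normalized: a deletion in repeat
          # context is ambiguous, and callers report the leftmost placement
          norm <- pos0
          while (norm > 0 &&
                   substr(s, norm, norm) == substr(s, norm - len, norm - len))
            norm <- norm - 1L
        } else {
          ins <- random_dna(len)
          new <- paste0(substr(s, 1, pos0), ins, substr(s, pos0 + 1L, nchar(s)))
          type <- "insertion"
          norm <- pos0
          while (norm > 0 &&
                   substr(s, norm, norm) == substr(ins, len, len)) {
            ins <- paste0(substr(ins, len, len), substr(ins, 1, len - 1L))
            norm <- norm - 1L
          }
        }
        truth[[length(truth) + 1L]] <- data.frame(
          copy_id = cid, type = type, length = abs(len), indel_len = len,
          position = norm, offset = ed$offset[j],
          norm_offset = norm - cut,
          site = spec$target_site$name, seq = new, stringsAsFactors = FALSE)
        molecules[[length(molecules) + 1L]] <- data.frame(
          copy_id = cid, subgenome = fam$subgenome[i], seq = new,
          fraction = spec$zygosity_fraction / nrow(ed),
          edited = TRUE, stringsAsFactors = FALSE)
      }
      if (spec$zygosity_fraction < 1) {
        molecules[[length(molecules) + 1L]] <- data.frame(
          copy_id = cid, subgenome = fam$subgenome[i], seq = fam$seq[i],
          fraction = 1 - spec$zygosity_fraction, edited = FALSE,
          stringsAsFactors = FALSE)
      }
    }
  })
  list(molecules = do.call(rbind, molecules),
       truth = if (length(truth)) do.call(rbind, truth) else
         data.frame(copy_id = character(), type = character(),
                    length = integer(), indel_len = integer(),
                    position = integer(), offset = integer(),
                    norm_offset = integer(), site = character(),
                    seq = character()))
}

#' Specify the read simulator
#'
#' @param depth mean read pairs per molecule (scaled by molecule fractions).
#' @param read_length read length in bp (2 x 280 paired-end by default).
#' @param substitution_error_rate mean per-base substitution error rate;
#'   realized per-base error probabilities follow the drawn quality scores,
#'   whose profile is shifted so the read-average error equals this rate.
#' @param quality_sd standard deviation of the per-base quality draw.
#' @param quality_decay drop in mean Q from the first to the last cycle.
#' @param seed integer seed.
#' @return object of class `read_sim_spec`.
#' @export
read_sim_spec <- function(depth = 200, read_length = 280,
                          substitution_error_rate = 0.002,
                          quality_sd = 3, quality_decay = 10, seed = 1) {
  stopifnot(depth > 0, read_length > 30,
            substitution_error_rate >= 0, substitution_error_rate < 0.2)
  structure(list(depth = depth, read_length = as.integer(read_length),
                 substitution_error_rate = substitution_error_rate,
                 quality_sd = quality_sd, quality_decay = quality_decay,
                 seed = as.integer(seed)),
            class = "read_sim_spec")
}

# Mean quality per cycle: linear decay, shifted so that the expected error
# probability over the profile equals the requested substitution rate.
# The normal quality noise makes E[10^(-Q/10)] exceed 10^(-E[Q]/10) by the
# log-normal convexity factor, which the shift compensates for.
quality_profile <- function(sim) {
  base <- seq(38, 38 - sim$quality_decay, length.out = sim$read_length)
  if (sim$substitution_error_rate > 0) {
    conv <- exp((sim$quality_sd * log(10) / 10)^2 / 2)
    target <- sim$substitution_error_rate / conv
    # raising error probability by factor f lowers Q by 10*log10(f)
    base <- base + 10 * log10(mean(phred_to_error(base)) / target)
  }
  pmin(pmax(base, 5), 41)
}

#' Simulate paired-end reads from amplicon molecules
#'
#' Each molecule's amplicon (the region spanned by the primer pair,
#' primers included) is sequenced as an R1 (forward) / R2
#' (reverse-complement strand) pair.  Quality scores are drawn from a
#' truncated normal whose mean decays linearly along the read; substitution
#' errors are injected per base with probability `10^(-Q/10)`, so qualities
#' are consistent with the injected errors in expectation.  Read counts per
#' molecule are multinomial around `depth x fraction`.
#'
#' @param molecules data.frame with columns `copy_id`, `seq` and optionally
#'   `fraction` (defaults to 1), as produced by [apply_edits()]; sequences
#'   may be full-length genes, in which case `primers` delimits the
#'   amplicon.
#' @param sim a [read_sim_spec()].
#' @param primers a [primer_pair()] used to cut the amplicon out of each
#'   molecule; `NULL` to sequence the given sequences as-is.
#' @param r1,r2 output FASTQ paths; when `NULL`, reads are only returned.
#' @return invisible list with data.frames `r1`, `r2` (`id`, `seq`, `qual`)
#'   and `truth` (`read_id`, `copy_id`).
#' @export
simulate_reads <- function(molecules, sim, primers = default_primers(),
                           r1 = NULL, r2 = NULL) {
  stopifnot(inherits(sim, "read_sim_spec"), nrow(molecules) > 0)
  frac <- molecules$fraction %||% rep(1, nrow(molecules))
  if (is.null(molecules$fraction)) molecules$fraction <- frac

  amp <- vapply(molecules$seq, function(s) {
    if (is.null(primers)) return(s)
    a <- extract_amplicon(s, primers, max_mismatch = 1, trim = FALSE)
    if (is.null(a)) stop("molecule lacks primer sites; cannot amplify")
    a
  }, character(1), USE.NAMES = FALSE)

  with_seed(split_seed(sim$seed, 3L), {
    w <- molecules$fraction
    total <- round(sim$depth * sum(w))
    counts <- as.integer(rmultinom(1, total, prob = w))
    qmean <- quality_profile(sim)

    ids <- character(0); s1 <- character(0); q1 <- character(0)
    s2 <- character(0); q2 <- character(0); src <- character(0)
    ridx <- 0L
    for (m in seq_along(counts)) {
      n <- counts[m]
      if (n == 0) next
      a <- amp[m]
      alen <- nchar(a)
      rl <- min(sim$read_length, alen)
      fwd <- substr(a, 1, rl)
      rev <- revcomp(substr(a, alen - rl + 1L, alen))
      for (mate in 1:2) {
        tmpl <- if (mate == 1) fwd else rev
        chars <- matrix(strsplit(tmpl, "")[[1]], nrow = n, ncol = rl, byrow = TRUE)
        qm <- matrix(qmean[seq_len(rl)], nrow = n, ncol = rl, byrow = TRUE)
        q <- round(qm + matrix(rnorm(n * rl, sd = sim$quality_sd), n, rl))
        q <- pmin(pmax(q, 2), 41)
        if (sim$substitution_error_rate > 0) {
          perr <- phred_to_error(q)
          err <- matrix(runif(n * rl) < perr, n, rl)
          if (any(err)) {
            idx <- which(err)
            repl <- vapply(chars[idx], function(b) sample(setdiff(DNA_BASES, b), 1),
                           character(1))
            chars[idx] <- repl
          }
        } else {
          q[] <- 41L
        }
        seqs <- apply(chars, 1, paste, collapse = "")
        quals <- apply(q, 1, qual_string)
        if (mate == 1) { s1 <- c(s1, seqs); q1 <- c(q1, quals) }
        else { s2 <- c(s2, seqs); q2 <- c(q2, quals) }
      }
      new_ids <- sprintf("read%06d_%s", ridx + seq_len(n), molecules$copy_id[m])
      ids <- c(ids, new_ids)
      src <- c(src, rep(molecules$copy_id[m], n))
      ridx <- ridx + n
    }
    r1df <- data.frame(id = ids, seq = s1, qual = q1, stringsAsFactors = FALSE)
    r2df <- data.frame(id = ids, seq = s2, qual = q2, stringsAsFactors = FALSE)
    if (!is.null(r1)) write_fastq(r1df, r1)
    if (!is.null(r2)) write_fastq(r2df, r2)
    invisible(list(r1 = r1df, r2 = r2df,
                   truth = data.frame(read_id = ids, copy_id = src,
                                      stringsAsFactors = FALSE)))
  })
}
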