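# Internal helpers: seed splitting, FASTQ/FASTA I/O, small sequence utilities.

# All randomness in the package flows from one integer seed.  Sub-seeds for
# independent stages are derived deterministically so that fixing the master
# seed fixes every stage, and stages can be re-run in isolation.
split_seed <- function(seed, stream) {
  stopifnot(is.numeric(seed), length(seed) == 1)
  # keep derived seeds in the 32-bit integer range
  (as.integer(seed) * 7919L + as.integer(stream) * 104729L) %% 2147483587L
}

with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  code
}

DNA_BASES <- c("A", "C", "G", "T")

revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

# IUPAC code -> compatible bases (used for degenerate primer matching)
IUPAC_MAP <- list(
  A = "A", C = "C", G = "G", T = "T",
  R = c("A", "G"), Y = c("C", "T"), S = c("C", "G"), W = c("A", "T"),
  K = c("G", "T"), M = c("A", "C"),
  B = c("C", "G", "T"), D = c("A", "G", "T"), H = c("A", "C", "T"),
  V = c("A", "C", "G"), N = c("A", "C", "G", "T")
)

# FASTQ I/O on data.frame(id, seq, qual), qualities as Phred+33 strings.
# Plain-text readers keep fixtures inspectable and dependency-light.
read_fastq <- function(path) {
  lines <- readLines(path)
  if (length(lines) %% 4 != 0)
    stop("malformed FASTQ (record count not a multiple of 4): ", path)
  idx <- seq(1, length(lines), by = 4)
  data.frame(id = sub("^@", "", lines[idx]),
             seq = toupper(lines[idx + 1]),
             qual = lines[idx + 3],
             stringsAsFactors = FALSE)
}

write_fastq <- function(df, path) {
  stopifnot(all(c("id", "seq", "qual") %in% names(df)))
  con <- file(path, "w")
  on.exit(close(con))
  if (nrow(df)) writeLines(paste0("@", df$id, "\n", df$seq, "\n+\n", df$qual), con)
  invisible(path)
}

read_fasta <- function(path) {
  x <- Biostrings::readDNAStringSet(path)
  data.frame(id = names(x), seq = as.character(x), stringsAsFactors = FALSE)
}

write_fasta <- function(ids, seqs, path) {
  x <- Biostrings::DNAStringSet(stats::setNames(seqs, ids))
  Biostrings::writeXStringSet(x, path)
  invisible(path)
}

phred_to_error <- function(q) 10^(-q / 10)

qual_string <- function(q) rawToChar(as.raw(q + 33L))

qual_ints <- function(s) utf8ToInt(s) - 33L

`%||%` <- function(a, b) if (is.null(a)) b else a
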