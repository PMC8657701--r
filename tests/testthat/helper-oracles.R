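# Independent reference implementations used as oracles.  These stay
# deliberately naive and separate from the package code paths they check.

# Exhaustive IUPAC matcher: expand the degenerate pattern into all plain
# sequences and test each against the subject window.
iupac_expand <- function(pattern) {
  codes <- list(A = "A", C = "C", G = "G", T = "T",
                R = c("A", "G"), Y = c("C", "T"), S = c("C", "G"),
                W = c("A", "T"), K = c("G", "T"), M = c("A", "C"),
                B = c("C", "G", "T"), D = c("A", "G", "T"),
                H = c("A", "C", "T"), V = c("A", "C", "G"),
                N = c("A", "C", "G", "T"))
  chars <- strsplit(pattern, "")[[1]]
  grid <- expand.grid(lapply(chars, function(c) codes[[c]]),
                      stringsAsFactors = FALSE)
  apply(grid, 1, paste, collapse = "")
}

oracle_iupac_match <- function(window, pattern, max_mismatch = 0) {
  any(vapply(iupac_expand(pattern), function(p) {
    sum(strsplit(window, "")[[1]] != strsplit(p, "")[[1]]) <= max_mismatch
  }, logical(1)))
}

# Posterior error probability for two agreeing base calls: normalized
# P(true base != observed | both reads observed it), the p1*p2/3 model.
oracle_posterior_agree <- function(q1, q2) {
  p1 <- 10^(-q1 / 10); p2 <- 10^(-q2 / 10)
  num <- p1 * p2 / 3
  num / ((1 - p1) * (1 - p2) + num)
}

# Straightforward reference denoiser applying the documented greedy
# beta(d) rule, with base R's adist() as the (independent) edit distance.
oracle_denoise <- function(uniques, minampsize, alpha) {
  beta <- function(d) 2^-(alpha * d + 1)
  cent <- data.frame(seq = character(), own = integer(), size = integer(),
                     stringsAsFactors = FALSE)
  for (i in seq_len(nrow(uniques))) {
    u <- uniques$seq[i]; a <- uniques$size[i]
    joined <- FALSE
    if (nrow(cent)) {
      d <- as.integer(adist(u, cent$seq))
      ok <- d > 0 & (a / cent$own) <= beta(d)
      if (any(ok)) {
        cand <- which(ok)
        j <- cand[order(d[cand], -cent$own[cand], cand)][1]
        cent$size[j] <- cent$size[j] + a
        joined <- TRUE
      }
    }
    if (!joined && a >= floor(minampsize)) {
      cent <- rbind(cent, data.frame(seq = u, own = a, size = a,
                                     stringsAsFactors = FALSE))
    }
  }
  cent
}

# Random dereplicated input for denoiser equivalence trials: a few true
# templates with geometric abundances plus near-variants.
random_uniques <- function(n_max = 20, seq_len = 40) {
  bases <- c("A", "C", "G", "T")
  n_templates <- sample(1:3, 1)
  templates <- vapply(seq_len(n_templates), function(i)
    paste(sample(bases, seq_len, replace = TRUE), collapse = ""), character(1))
  n <- sample(2:n_max, 1)
  seqs <- character(n); sizes <- integer(n)
  for (i in seq_len(n)) {
    t <- sample(templates, 1)
    nmut <- sample(0:3, 1)
    ch <- strsplit(t, "")[[1]]
    if (nmut > 0) {
      at <- sample(seq_along(ch), nmut)
      ch[at] <- vapply(ch[at], function(b) sample(setdiff(bases, b), 1),
                       character(1))
    }
    seqs[i] <- paste(ch, collapse = "")
    sizes[i] <- max(1L, as.integer(round(rlnorm(1, log(20), 1.5))))
  }
  df <- aggregate(sizes, by = list(seq = seqs), FUN = sum)
  names(df)[2] <- "size"
  df <- df[order(-df$size, df$seq), ]
  rownames(df) <- NULL
  df
}

# Small error-free paired-read fixture from given amplicon sequences.
perfect_pairs <- function(amps, n_per = 5, read_len = NULL) {
  if (is.null(read_len)) read_len <- max(nchar(amps)) %/% 2 + 20
  r1 <- r2 <- list()
  k <- 0
  for (a in amps) {
    rl <- min(read_len, nchar(a))
    for (i in seq_len(n_per)) {
      k <- k + 1
      r1[[k]] <- data.frame(id = paste0("r", k),
                            seq = substr(a, 1, rl),
                            qual = strrep("I", rl))
      r2[[k]] <- data.frame(id = paste0("r", k),
                            seq = as.character(Biostrings::reverseComplement(
                              Biostrings::DNAString(substr(a, nchar(a) - rl + 1, nchar(a))))),
                            qual = strrep("I", rl))
    }
  }
  list(r1 = do.call(rbind, r1), r2 = do.call(rbind, r2))
}

# Presence/frequency fixture for classification: a matrix where the given
# Amp ids are present (1%) in the given lines and absent elsewhere.
presence_fixture <- function(amp_ids, lines, present) {
  freq <- matrix(0, length(amp_ids), length(lines),
                 dimnames = list(amp_ids, lines))
  for (ln in names(present)) freq[present[[ln]], ln] <- 1
  # renormalize columns to sum 100 (presence threshold is on %, entries
  # well above 0.3 as long as < 334 Amps are present per line)
  for (j in seq_len(ncol(freq))) {
    if (sum(freq[, j]) > 0) freq[, j] <- 100 * freq[, j] / sum(freq[, j])
  }
  freq
}
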