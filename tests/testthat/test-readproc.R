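# Read-processing stages: merging, expected-error filtering,
# dereplication, denoising, identity search.

q20 <- function(n) strrep("5", n)   # Phred+33: '5' = Q20
q40 <- function(n) strrep("I", n)
rcs <- function(x) as.character(Biostrings::reverseComplement(Biostrings::DNAString(x)))

test_that("overlap mismatches above the caps reject a pair", {
  a <- paste(sample(c("A","C","G","T"), 80, replace = TRUE), collapse = "")
  r1 <- substr(a, 1, 50)
  r2tmpl <- substr(a, 31, 80)
  # plant 3 mismatches inside the 20 bp overlap (positions 31..50)
  mut <- strsplit(r2tmpl, "")[[1]]
  for (k in c(2, 8, 14)) mut[k] <- setdiff(c("A","C","G","T"), mut[k])[1]
  r2 <- rcs(paste(mut, collapse = ""))
  df1 <- data.frame(id = "p", seq = r1, qual = q40(50))
  df2 <- data.frame(id = "p", seq = r2, qual = q40(50))
  res2 <- merge_pairs(df1, df2, merge_params(maxdiffs = 2, maxdiffpct = 90))
  expect_equal(res2$stats$merged, 0L)
  res3 <- merge_pairs(df1, df2, merge_params(maxdiffs = 3, maxdiffpct = 90))
  expect_equal(res3$stats$merged, 1L)
})

test_that("agreeing overlap bases get boosted posterior qualities", {
  set.seed(1)
  a <- paste(sample(c("A","C","G","T"), 60, replace = TRUE), collapse = "")
  r1 <- substr(a, 1, 40)
  r2 <- rcs(substr(a, 21, 60))
  m <- merge_pairs(data.frame(id = "p", seq = r1, qual = q20(40)),
                   data.frame(id = "p", seq = r2, qual = q20(40)),
                   merge_params(maxdiffs = 5))
  expect_equal(m$reads$seq, a)
  q <- utf8ToInt(m$reads$qual) - 33L
  overlap_q <- q[21:40]
  expect_true(all(overlap_q > 20))
  # oracle: direct posterior computation, capped at the configured Q41
  expected_q <- min(41, round(-10 * log10(oracle_posterior_agree(20, 20))))
  expect_true(all(overlap_q == expected_q))
})

test_that("merging rejects mismatched record counts", {
  df1 <- data.frame(id = c("a", "b"), seq = c("ACGT", "ACGT"),
                    qual = c("IIII", "IIII"))
  df2 <- df1[1, ]
  expect_error(merge_pairs(df1, df2), "different record counts")
})

test_that("expected-error filter applies the closed-form threshold", {
  reads <- data.frame(id = c("len100", "len150", "empty"),
                      seq = c(strrep("A", 100), strrep("A", 150), ""),
                      qual = c(q20(100), q20(150), ""))
  out <- filter_maxee(reads, filter_params(maxee = 1.13))
  # all-Q20: EE = n * 0.01 -> 1.00 kept, 1.50 discarded, empty read EE 0 kept
  expect_setequal(out$reads$id, c("len100", "empty"))
  expect_equal(unname(out$ee), c(1.0, 1.5, 0))
})

test_that("malformed quality strings are reported by record", {
  reads <- data.frame(id = "bad1", seq = "ACGT", qual = "II")
  expect_error(filter_maxee(reads), "bad1")
})

test_that("dereplication sums abundances with deterministic tie order", {
  out <- dereplicate(c("AAA", "AAA", "AAT"))
  expect_equal(out$seq, c("AAA", "AAT"))
  expect_equal(out$size, c(2L, 1L))
  expect_equal(nrow(dereplicate(character(0))), 0L)
  ties <- dereplicate(c("TTT", "AAA", "CCC"))
  expect_equal(ties$seq, c("AAA", "CCC", "TTT"))   # lexicographic at equal size
})

test_that("denoiser applies the abundance-skew rule beta(d) = 2^-(alpha d + 1)", {
  base <- strrep("ACGT", 10)
  variant <- paste0("T", substr(base, 2, 40))     # d = 1
  # skew 10/100 = 0.10 <= beta(1) = 0.125 -> absorbed
  u <- data.frame(seq = c(base, variant), size = c(100L, 10L))
  out <- denoise(u, denoise_params(minampsize = 4, alpha = 2))
  expect_equal(nrow(out), 1L)
  expect_equal(out$size, 110L)
  # skew 20/100 = 0.20 > 0.125 -> founds its own centroid
  u2 <- data.frame(seq = c(base, variant), size = c(100L, 20L))
  out2 <- denoise(u2, denoise_params(minampsize = 4, alpha = 2))
  expect_equal(nrow(out2), 2L)
  # same variant below minampsize is discarded entirely
  out3 <- denoise(u2, denoise_params(minampsize = 21, alpha = 2))
  expect_equal(nrow(out3), 1L)
  expect_equal(out3$size, 100L)
})

test_that("a single sufficiently abundant unique yields exactly one Amp", {
  u <- data.frame(seq = "ACGTACGT", size = 8L)
  expect_equal(nrow(denoise(u, denoise_params(minampsize = 8))), 1L)
  expect_equal(nrow(denoise(u, denoise_params(minampsize = 9))), 0L)
})

test_that("greedy denoiser matches the exhaustive reference on random instances", {
  set.seed(99)
  for (trial in 1:60) {
    u <- random_uniques()
    minamp <- sample(1:6, 1)
    ours <- denoise(u, denoise_params(minampsize = minamp, alpha = 2,
                                      chimera = FALSE))
    ref <- oracle_denoise(u, minamp, 2)
    expect_identical(ours$seq, ref$seq)
    expect_identical(ours$size, as.integer(ref$size))
  }
})

test_that("chimeric centroids are removed; indel relatives are kept", {
  left <- strrep("AC", 30); right <- strrep("GT", 30)
  parentA <- paste0(left, strrep("AAAC", 15))
  parentB <- paste0(strrep("TTTG", 15), right)
  chimera <- paste0(left, right)
  u <- data.frame(seq = c(parentA, parentB, chimera),
                  size = c(100L, 90L, 10L))
  u <- u[order(-u$size, u$seq), ]
  out <- denoise(u, denoise_params(minampsize = 2, alpha = 10))
  expect_false(chimera %in% out$seq)
  # a deletion product of one parent is explainable by that single parent
  # alone and must survive the chimera pass
  delprod <- paste0(substr(parentA, 1, 30), substr(parentA, 40, nchar(parentA)))
  u2 <- data.frame(seq = c(parentA, parentB, delprod),
                   size = c(100L, 90L, 30L))
  out2 <- denoise(u2, denoise_params(minampsize = 2, alpha = 10))
  expect_true(delprod %in% out2$seq)
})

test_that("identity search assigns at the threshold with documented ties", {
  db <- data.frame(id = c("t1", "t2"),
                   seq = c(strrep("ACGT", 25), strrep("TGCA", 25)))
  # exact hit
  res <- search_assign(db$seq[1], db, search_params(0.99))
  expect_equal(res$hits$hit, "t1")
  expect_equal(res$hits$identity, 1)
  # one substitution in 100 bp -> identity 0.99, assigned at threshold
  q <- paste0("T", substr(db$seq[1], 2, 100))
  res2 <- search_assign(q, db, search_params(0.99))
  expect_equal(res2$hits$hit, "t1")
  expect_equal(res2$hits$identity, 0.99)
  # nothing at ~25% identity passes a 0.99 threshold
  res3 <- search_assign(strrep("AAAA", 25), db, search_params(0.99))
  expect_true(is.na(res3$hits$hit))
  # exact mode rejects the 1-mismatch query
  res4 <- search_assign(q, db, search_params(mode = "exact"))
  expect_true(is.na(res4$hits$hit))
})

test_that("stage read-conservation and monotonicity invariants hold", {
  fs <- family_spec(n_copies = c(A = 3), divergence_within = 0.02, seed = 23)
  fam <- simulate_family(fs)
  rs <- simulate_reads(fam, read_sim_spec(depth = 60,
                                          substitution_error_rate = 0.004,
                                          seed = 23))
  m <- merge_pairs(rs$r1, rs$r2, merge_params(maxdiffs = 8))
  expect_equal(m$stats$merged + (m$stats$input - nrow(m$reads)),
               m$stats$input)
  kept <- vapply(c(0.5, 1, 2, 4), function(ee)
    filter_maxee(m$reads, filter_params(ee))$stats$kept, numeric(1))
  expect_true(all(diff(kept) >= 0))   # raising maxee never loses reads
  f <- filter_maxee(m$reads, filter_params(1))
  expect_equal(f$stats$kept + (f$stats$input - f$stats$kept), f$stats$input)
  u <- dereplicate(f$reads$seq)
  expect_equal(sum(u$size), nrow(f$reads))
  amps <- denoise(u, denoise_params(minampsize = 5))
  matched <- vapply(c(0.95, 0.99, 1), function(idy)
    sum(search_assign(u, amps, search_params(idy))$target_counts),
    numeric(1))
  expect_true(all(diff(matched) <= 0))  # raising identity never gains reads
})
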