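# Fixture generator: family construction, edit application, read simulation.

test_that("zero divergence gives identical amplicons within a subgenome", {
  fs <- family_spec(n_copies = c(A = 4), divergence_within = 0, seed = 3)
  fam <- simulate_family(fs)
  amps <- vapply(fam$seq, extract_amplicon, character(1),
                 primers = default_primers(), USE.NAMES = FALSE)
  expect_length(unique(amps), 1L)
})

test_that("family construction respects subgenome request and motifs", {
  fs <- family_spec(n_copies = c(A = 3, B = 3), divergence_within = 0.02,
                    seed = 5)
  fam <- simulate_family(fs)
  expect_setequal(unique(fam$subgenome), c("A", "B"))
  # no copy carries the D motif when D was not requested
  motifs <- default_subgenome_motifs()
  sg <- vapply(fam$seq, function(s) {
    a <- extract_amplicon(s, default_primers())
    assign_subgenome(a, motifs)
  }, character(1), USE.NAMES = FALSE)
  expect_false(any(sg == "D", na.rm = TRUE))
  expect_equal(sg, fam$subgenome, ignore_attr = TRUE)
})

test_that("family simulation is deterministic under a fixed seed", {
  fs <- family_spec(n_copies = c(A = 2, B = 2, D = 2), seed = 42)
  expect_identical(simulate_family(fs), simulate_family(fs))
})

test_that("edits are placed at the cut site with exact truth records", {
  fs <- family_spec(n_copies = c(A = 2), divergence_within = 0.01, seed = 9)
  fam <- simulate_family(fs)
  es <- edit_spec("sgAlpha2",
                  edits = data.frame(copy_id = c("A01", "A02"),
                                     indel_len = c(-3L, 1L), offset = 0L))
  ed <- apply_edits(fam, es, seed = 9)
  expect_equal(nrow(ed$truth), 2L)
  del <- ed$truth[ed$truth$copy_id == "A01", ]
  ins <- ed$truth[ed$truth$copy_id == "A02", ]
  expect_equal(nchar(del$seq), nchar(fam$seq[1]) - 3L)
  expect_equal(del$type, "deletion")
  expect_equal(nchar(ins$seq), nchar(fam$seq[2]) + 1L)
  expect_equal(ins$indel_len, 1L)
  # deletion removes bases exactly at the (normalized) cut position
  s <- fam$seq[1]
  expect_identical(del$seq,
                   paste0(substr(s, 1, del$position),
                          substr(s, del$position + 4L, nchar(s))))
})

test_that("large deletions drop whole copies from the molecule mix", {
  fs <- family_spec(n_copies = c(A = 3, B = 2), seed = 4)
  fam <- simulate_family(fs)
  es <- edit_spec("sgAlpha2", large_deletion = c("A01", "A02", "A03"))
  ed <- apply_edits(fam, es)
  expect_false(any(ed$molecules$subgenome == "A"))
  expect_setequal(ed$molecules$copy_id, c("B01", "B02"))
})

test_that("edit offsets outside the sequence are rejected", {
  fs <- family_spec(n_copies = c(A = 1), seed = 4)
  fam <- simulate_family(fs)
  es <- edit_spec("sgAlpha2",
                  edits = data.frame(copy_id = "A01", indel_len = -3L,
                                     offset = 10000L))
  expect_error(apply_edits(fam, es), "outside")
})

test_that("zygosity < 1 yields a WT/edited molecular mixture", {
  fs <- family_spec(n_copies = c(A = 1), seed = 6)
  fam <- simulate_family(fs)
  es <- edit_spec("sgAlpha2",
                  edits = data.frame(copy_id = "A01", indel_len = -2L,
                                     offset = 0L),
                  zygosity_fraction = 0.5)
  ed <- apply_edits(fam, es)
  expect_equal(sort(ed$molecules$fraction), c(0.5, 0.5))
  expect_setequal(ed$molecules$edited, c(TRUE, FALSE))
})

test_that("error-free reads merge back to the exact amplicon", {
  fs <- family_spec(n_copies = c(A = 2), divergence_within = 0.02, seed = 8)
  fam <- simulate_family(fs)
  rs <- simulate_reads(fam, read_sim_spec(depth = 10,
                                          substitution_error_rate = 0,
                                          seed = 8))
  m <- merge_pairs(rs$r1, rs$r2, merge_params(maxdiffs = 0))
  expect_equal(m$stats$merged_fraction, 1)
  truth_amps <- vapply(fam$seq, extract_amplicon, character(1),
                       primers = default_primers(), trim = FALSE,
                       USE.NAMES = FALSE)
  expect_true(all(m$reads$seq %in% truth_amps))
})

test_that("read counts follow the requested depth and seed determinism", {
  fs <- family_spec(n_copies = c(A = 5, B = 5), divergence_within = 0.01,
                    seed = 2)
  fam <- simulate_family(fs)
  sim <- read_sim_spec(depth = 100, seed = 31)
  rs <- simulate_reads(fam, sim)
  # oracle: direct count of emitted records (10 molecules x depth 100)
  expect_equal(nrow(rs$r1), 1000L)
  expect_equal(nrow(rs$r2), 1000L)
  rs2 <- simulate_reads(fam, sim)
  expect_identical(rs$r1, rs2$r1)
  expect_identical(rs$r2, rs2$r2)
})

test_that("injected qualities track injected error probabilities", {
  fs <- family_spec(n_copies = c(A = 1), seed = 12)
  fam <- simulate_family(fs)
  rate <- 0.005
  rs <- simulate_reads(fam, read_sim_spec(depth = 400,
                                          substitution_error_rate = rate,
                                          seed = 12))
  # realized mismatch rate vs the template should match the requested rate
  amp <- extract_amplicon(fam$seq[1], default_primers(), trim = FALSE)
  tmpl <- substr(amp, 1, nchar(rs$r1$seq[1]))
  mm <- vapply(rs$r1$seq, function(s) {
    sum(strsplit(s, "")[[1]] != strsplit(tmpl, "")[[1]])
  }, numeric(1))
  realized <- mean(mm) / nchar(tmpl)
  expect_lt(abs(realized - rate) / rate, 0.35)
})
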