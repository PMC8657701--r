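# Distances, neighbor joining, reference picking, InDel calling.

rand_seq <- function(n) paste(sample(c("A","C","G","T"), n, replace = TRUE),
                              collapse = "")

test_that("p-distances count mismatches and gap openings per column", {
  a <- strrep("ACGT", 25)
  b <- paste0("T", substr(a, 2, 100))
  d <- pairwise_distances(c(x = a, y = b))
  expect_equal(d["x", "y"], 0.01)
  expect_equal(d["x", "x"], 0)
  set.seed(5)
  s <- vapply(1:4, function(i) rand_seq(60), character(1))
  dm <- pairwise_distances(setNames(s, paste0("s", 1:4)))
  expect_equal(dm, t(dm), tolerance = 1e-12)
  expect_true(all(diag(dm) == 0) && all(dm >= 0))
})

test_that("neighbor joining recovers additive four-taxon trees", {
  # additive matrix from a known topology ((A,B),(C,D)) with internal
  # branch 3: the oracle is the exhaustive four-point check
  d <- matrix(0, 4, 4, dimnames = list(LETTERS[1:4], LETTERS[1:4]))
  bl <- c(A = 2, B = 5, C = 4, D = 1); internal <- 3
  d["A","B"] <- d["B","A"] <- bl["A"] + bl["B"]
  d["C","D"] <- d["D","C"] <- bl["C"] + bl["D"]
  for (i in c("A","B")) for (j in c("C","D"))
    d[i,j] <- d[j,i] <- bl[i] + bl[j] + internal
  # four-point condition: AB|CD is the split iff
  # d(A,B)+d(C,D) < d(A,C)+d(B,D) = d(A,D)+d(B,C)
  sums <- c(d["A","B"] + d["C","D"], d["A","C"] + d["B","D"],
            d["A","D"] + d["B","C"])
  expect_equal(which.min(sums), 1L)
  tree <- neighbor_joining(d)
  # NJ must place A,B on one side of the internal edge: the split is
  # recoverable as monophyly of {A,B} in the unrooted tree
  expect_true(ape::is.monophyletic(tree, c("A", "B")))
  expect_true(ape::is.monophyletic(tree, c("C", "D")))
  # Saitou-Nei branch lengths reproduce the generating additive lengths
  cop <- cophenetic(tree)
  expect_equal(cop[rownames(d), colnames(d)], d, tolerance = 1e-9)
})

test_that("three taxa get the closed-form star branch lengths", {
  d <- matrix(c(0, 3, 5,
                3, 0, 6,
                5, 6, 0), 3, 3, dimnames = list(c("a","b","c"), c("a","b","c")))
  tree <- neighbor_joining(d)
  # closed three-point formulas: la = (dab + dac - dbc)/2 etc.
  expect_equal(unname(cophenetic(tree)[c("a","b","c"), c("a","b","c")]),
               unname(d), tolerance = 1e-9)
  expect_error(neighbor_joining(d[1:2, 1:2]), "at least 3")
})

test_that("trees from tree-derived additive distances rebuild the topology", {
  set.seed(71)
  for (n in 5:8) {
    gen <- ape::rtree(n, br = function(k) runif(k, 0.5, 2))
    gen <- ape::unroot(gen)
    d <- cophenetic(gen)
    rec <- neighbor_joining(d)
    expect_equal(ape::dist.topo(ape::unroot(rec), gen), 0,
                 ignore_attr = TRUE)
    expect_equal(cophenetic(rec)[rownames(d), colnames(d)], d,
                 tolerance = 1e-8)
  }
})

test_that("the closest wild-type reference is picked, with total fallback", {
  set.seed(31)
  wt1 <- rand_seq(120)
  wt2 <- paste(rev(strsplit(rand_seq(120), "")[[1]]), collapse = "")
  # CRISPR Amp = wt1 with a 3 bp deletion
  cr <- paste0(substr(wt1, 1, 50), substr(wt1, 54, 120))
  amps <- data.frame(id = c("wtA", "wtB", "crX"), seq = c(wt1, wt2, cr))
  d <- pairwise_distances(amps)
  # random 3-taxon distances need not be additive: the clamp warning is fine
  tree <- suppressWarnings(neighbor_joining(d))
  pick <- pick_reference(tree, "crX", c("wtA", "wtB"), d)
  # oracle: argmin over brute-force distances
  expect_equal(pick, c("wtA", "wtB")[which.min(d["crX", c("wtA", "wtB")])])
  expect_equal(pick, "wtA")
  # single WT always wins; never a non-WT Amp
  expect_equal(pick_reference(tree, "crX", "wtB", d), "wtB")
  # distance ties break to the lexicographically smallest WT id
  d2 <- d; d2["crX", c("wtA", "wtB")] <- 0.05; d2[c("wtA", "wtB"), "crX"] <- 0.05
  expect_equal(pick_reference(tree, "crX", c("wtB", "wtA"), d2), "wtA")
})

test_that("InDel calls anchor to cut sites with window semantics", {
  fs <- family_spec(n_copies = c(A = 1), seed = 37)
  fam <- simulate_family(fs)
  ref <- extract_amplicon(fam$seq, default_primers(), trim = FALSE)
  expect_equal(nrow(call_indels(ref, ref)), 0L)
  cuts <- amplindel:::scan_cut_sites(ref, default_target_sites())
  cut2 <- cuts$cut[cuts$site == "sgAlpha2"]
  # 3 bp deletion exactly at the sgAlpha2 cut
  del <- paste0(substr(ref, 1, cut2), substr(ref, cut2 + 4, nchar(ref)))
  calls <- call_indels(del, ref)
  expect_equal(nrow(calls), 1L)
  expect_equal(calls$type, "deletion")
  expect_equal(calls$indel_len, -3L)
  expect_equal(calls$attributed_site, "sgAlpha2")
  expect_lte(abs(calls$distance_to_cut), 1L)  # repeat-context left shift only
  # +1 insertion 50 bp away from every site is left unattributed
  far <- cut2 + 50
  ins <- paste0(substr(ref, 1, far), "A", substr(ref, far + 1, nchar(ref)))
  calls2 <- call_indels(ins, ref, window = 10)
  expect_equal(nrow(calls2), 1L)
  expect_equal(calls2$type, "insertion")
  expect_equal(calls2$indel_len, 1L)
  expect_true(is.na(calls2$attributed_site))
})

test_that("gap placement is left-normalized in repeat context", {
  ref <- paste0("ACGTG", "AAAAA", "CTGCA")
  qry <- paste0("ACGTG", "AAA",   "CTGCA")   # 2 bp deletion in the A-run
  calls <- call_indels(qry, ref, sites = default_target_sites())
  expect_equal(nrow(calls), 1L)
  expect_equal(calls$indel_len, -2L)
  expect_equal(calls$position, 6L)  # leftmost placement in the homopolymer
})

test_that("simulated edits round-trip through the caller exactly", {
  fs <- family_spec(n_copies = c(A = 2, B = 2), divergence_within = 0.02,
                    seed = 53)
  fam <- simulate_family(fs)
  lens <- c(-5L, -1L, 2L, -9L)
  es <- edit_spec("sgAlpha2",
                  edits = data.frame(copy_id = fam$copy_id, indel_len = lens,
                                     offset = c(0L, 0L, 2L, -1L)))
  ed <- apply_edits(fam, es, seed = 53)
  for (k in seq_len(nrow(ed$truth))) {
    src <- fam$seq[fam$copy_id == ed$truth$copy_id[k]]
    calls <- call_indels(ed$truth$seq[k], src)
    expect_equal(nrow(calls), 1L)
    expect_equal(calls$indel_len, ed$truth$indel_len[k])
    expect_equal(calls$attributed_site, "sgAlpha2")
    expect_equal(calls$distance_to_cut, ed$truth$norm_offset[k])
  }
})
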