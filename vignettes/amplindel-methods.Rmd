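---
title: "Methods: amplicon denoising and closest-reference InDel calling in multi-copy gene families"
author: "amplindel authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: amplicon denoising and closest-reference InDel calling}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette is the package's own account of its methods: the models and
procedures, the tunable parameters and their defaults, what the synthetic
data generator emulates, and the numerical and design choices made where
the problem left them open.  It states no empirical result that the test
suite and `scripts/acceptance.R` do not themselves compute.

## 1. The analysis problem

CRISPR/Cas9 editing of a multi-copy, high-homology gene family — the
motivating case is the wheat α-gliadin family, tandem arrays of roughly a
hundred genes and pseudogenes on the group-6 chromosomes of the A, B and
(in hexaploids) D subgenomes — defeats reference-based InDel callers,
because each edited molecule descends from a *different* paralog.  The
workflow implemented here sidesteps the reference problem in two moves:

* amplicon sequencing reads are reduced, without any reference, to
  *unique denoised amplicons* (**Amps**) with per-line abundances;
* each putative mutation product (**CRISPR Amp**) is compared against the
  *closest wild-type Amp*, chosen per Amp via a neighbor-joining
  dendrogram over all Amps of the genetic background.

## 2. Read processing

### Pair merging

R2 is reverse-complemented and the best *ungapped* overlap with R1 of
length at least `min_overlap` is selected by maximizing
(matches − mismatches); ties go to the longer overlap.  A pair is rejected
when the overlap carries more than `floor(maxdiffs)` mismatches or a
mismatch percentage above `maxdiffpct`.  Within the overlap, posterior
base qualities are recomputed from the exact Bayesian posterior over the
four bases: for agreeing calls with error probabilities $p_1, p_2$,

$$p_\mathrm{err} = \frac{p_1 p_2 / 3}{(1-p_1)(1-p_2) + p_1 p_2/3},$$

and for disagreeing calls the higher-quality base is kept with its
posterior error probability.  Posterior qualities are capped at Q41
(`qmax`), floored at Q2.  Gapped overlaps are out of scope: indels inside
a 280 bp read pair of a PCR amplicon are vastly more likely to be real
mutations than merge artifacts.

*Defaults*: `min_overlap = 16` (a shorter overlap is indistinguishable
from chance at amplicon GC content), `maxdiffpct = 25`.

### Expected-error filter

A merged read is kept iff $\mathrm{EE} = \sum_i 10^{-Q_i/10} \le$
`maxee`.  This is the standard quality filter for amplicon work: it bounds
the expected number of wrong bases per read rather than thresholding
per-base quality.

### Dereplication and denoising

Exact-string dereplication produces (unique sequence, abundance) pairs
sorted by decreasing abundance, ties broken lexicographically so the
downstream pass is deterministic.  Denoising is the UNOISE centroid rule:
in abundance order, a unique $U$ joins an existing centroid $C$ at edit
distance $d > 0$ iff

$$\frac{a_U}{a_C} \le \beta(d) = 2^{-(\alpha d + 1)},$$

choosing the *closest* qualifying centroid (ties: larger abundance, then
earlier centroid); otherwise $U$ founds a new centroid if
$a_U \ge \lfloor\texttt{minampsize}\rfloor$.  $\alpha$ defaults to 2, the
published UNOISE default; the skew curve encodes the observation that
PCR/sequencing error abundance decays geometrically with distance from
the true template.  Implementation note: the skew inequality bounds the
useful edit distance from above, so distances are computed with a banded,
early-abandoning Levenshtein kernel; the greedy result is checked against
an exhaustive reference implementation in the test suite.

**Chimera pass.**  A centroid reconstructable as a perfect left/right
concatenation of two *distinct* higher-abundance centroids is removed.
One refinement proved necessary: a centroid explainable as prefix +
suffix of a *single* parent is an indel relative of that parent — exactly
the mutation products this package exists to find — and is exempted.
Without the exemption, a deletion product whose suffix happens to match a
second paralog (likely at percent-level paralog divergence) is falsely
flagged.  The pass is on by default and separable
(`denoise_params(chimera = FALSE)`).

### Identity search

Global (end-to-end) alignment identity = matches / alignment columns,
*terminal gaps excluded* — the common amplicon-search convention, and the
one that lets an Amp carrying primer flanks match a primer-trimmed
database record.  Queries are assigned to the highest-identity hit at or
above `identity`; ties break to the longer hit, then the lexicographic
id.  `mode = "exact"` requires string equality (both search modes are
provided; which to use for final per-line assignment is a user choice).
For speed, candidates are ranked by shared 8-mers and only the top few
are aligned; equal-length pairs take a Hamming shortcut, valid because at
the identity thresholds in use the optimal alignment of equal-length
near-identical sequences is gap-free.

### Per-line accounting

Amps are built from the pooled samples; per-line counts come from
assigning each line's *merged* reads to the pooled Amp set.  Raw pairs
cannot be assigned directly (each covers half the amplicon), so the
"assigned" percentage is reported relative to raw pairs with merging as
part of assignment — the stage table rows are: merged (of pairs),
filtered (of merged), denoised-contained (of filtered), matched to the
database (of denoised-contained), assigned (of raw pairs).

## 3. Parameter optimization

The five tunables are optimized by sequential model-based minimization of
−(reads contained in database-matched Amps), over the search box
maxdiffs (5–82), maxdiffpct (2–30), maxee (0.25–1.5), minampsize (2–30),
identity (0.99–1).  Choices made here:

* **Surrogate**: zero-mean Gaussian process with squared-exponential
  kernel on inputs rescaled to $[0,1]^d$; length-scale and noise chosen
  per refit by grid-search marginal likelihood.  Small, dependency-free,
  and adequate at desk-scale budgets.
* **Acquisition**: expected improvement, optimized over seeded uniform
  candidates (500 per iteration).
* **Initial design**: seeded Latin hypercube of $\max(5, 2d)$ points.
* **Budget**: default 50 evaluations (no published value exists; 50 is
  ample for a 5-dimensional box with a smooth objective).
* A seeded pure random search is selectable (`method = "random"`).
* `maxdiffs` and `minampsize` live on the real line during optimization
  and are floored at use — published optima are non-integer (58.94,
  22.47), so the continuous-relaxation-plus-floor convention is made
  explicit here.
* Optimization is meant to run on wild-type lines only (enforceable via
  `wt_only`), since the objective — matched reads against a wild-type
  database — would otherwise penalize real mutation products.
* Stage failures score as 0 matched reads (the worst value) with a
  warning, keeping the objective total for the optimizer.

Determinism: all randomness descends from one integer seed through a
documented splitting scheme (`split_seed`), and seeded runs reproduce
identical traces.

## 4. Abundance: TMM, frequencies, presence

Between-line count normalization uses the trimmed mean of M-values,
coded here from its published definition: reference line by
upper-quartile proximity to the mean; M- and A-values over Amps nonzero
in both lines; 30 % two-sided trim on M and 5 % on A; inverse-variance
(delta-method) weighting; factors renormalized to geometric mean 1.  The
edgeR implementation is used in the test suite as an independent
cross-check (agreement to 1e-6), never as the implementation.  Exact
invariance of the factors under rescaling one column holds for the
unweighted trimmed mean; the precision weights depend weakly on absolute
counts, so the property is asserted with a small tolerance.

Normalized values are `count / (library size × factor) × 1e6` — a
counts-per-million-style unit.  The published tables print TMM values
without defining their scale; the constant only affects display, never
frequencies or presence, and is recorded in the object.

Per-line frequencies are column percentages of the normalized matrix.
Presence uses a *strict* threshold (`freq > 0.3 %`): a frequency of
exactly 0.3 % is absent, matching the stated "higher than 0.3 %" rule.

## 5. Classification across generations

The WT Amp set of a background is the union of Amps present in any WT
replicate; the WT count *reported* in tables is the rounded mean of
per-replicate totals (union for membership, mean for the headline count —
the two conventions the published tables use).  For an edited line:
CRISPR Amps = present ∖ WT set; non-targeted WT Amps = present ∩ WT set;
putative targeted WT Amps = WT set ∖ present.  Two identities hold by
construction and are asserted property-style: total = CRISPR +
non-targeted, and non-targeted + putative-targeted = |WT set|.

When a line has *zero* CRISPR Amps, declaring WT Amps "targeted" on a
borderline frequency would be unsupported — there is no mutation product
to explain the loss.  Such lines re-evaluate WT-Amp presence at a
stricter (lower) secondary threshold before any WT Amp is counted as
targeted.  The rule is published; its value is not, and the package
defaults to 0.1 % (a third of the primary threshold — low enough to
rescue borderline detections, high enough to stay above the error floor
the 0.3 % threshold exists for).

Offspring tables order lines depth-first along the pedigree (each T0
followed by its T1s, each T1 by its T2s; siblings by id) and flag a line
as non-segregating when its non-targeted and putative-targeted *sets*
(not just counts) equal its parent's.

Subgenome assignment translates the amplicon in the design reading frame
(frame 0 at the first base after the forward primer, configurable
offset) and looks for subgenome-diagnostic peptide motifs; zero or
multiple matching subgenomes give NA.  The shipped motif table
(`extdata/subgenome_motifs.tsv`) contains *synthetic* defaults consistent
with the simulator, not the published wheat motifs, which are cited in
the literature rather than redistributed; users analyzing real data must
supply their own.

## 6. Dendrogram and InDel calling

* **Distances**: global pairwise alignment (match +1, mismatch −1, gap
  open −2, gap extend −0.5; one documented scheme replaces the
  interactive multi-aligner workflow, since pairwise alignment to a
  chosen reference fully determines InDel length and position and is
  reproducible); distance = (mismatches + gap openings) / alignment
  columns.
* **Tree**: classic neighbor joining via the standard implementation in
  `ape` (Q-matrix joins, Saitou–Nei branch lengths); negative branch
  lengths are clamped to zero with a warning.  NJ is bought, not built:
  it is a solved, standard step, and the package's contribution is how
  the tree is *used*.
* **Clusters**: the published dendrogram clusters were drawn manually; a
  reproducible default is needed.  The tree is midpoint-rooted, node
  depths measured from the root, and edges crossing a cut depth removed;
  hanging subtrees form clusters.  The default cut is the median
  internal-node depth, which at percent-level paralog divergence
  separates paralog groups while keeping mutation products with their
  sources.  The cut is configurable.
* **Reference choice**: the WT Amp in the CRISPR Amp's cluster with
  minimal distance; a cluster without WT Amps falls back to the nearest
  WT Amp over the whole background (the adjacent-cluster rule).
  Distance ties break to the lexicographically smallest WT id.
* **InDel calls**: each maximal gap run in the pairwise alignment is one
  InDel.  Gap runs are shifted maximally left (standard variant
  normalization) because repeat-rich sequence makes placement ambiguous;
  the simulator records its truth InDels in the same normalized
  coordinates, so round-trip tests compare like with like.  Cut sites
  are found by scanning the reference for protospacer + NGG on both
  strands (every occurrence indexed; up to 1 mismatch by default); the
  cut sits 3 bp 5′ of the PAM.  An InDel is attributed to the nearest
  cut within ±`window` (default 10 bp — wide enough for NHEJ resection,
  narrow enough to exclude unrelated polymorphism).

## 7. qPCR copy number

Efficiency transform $E = E_\mathrm{CFX}/100 + 1$; ratio
$N \cdot E_\mathrm{ref}^{MCq_\mathrm{ref}} / E_\mathrm{target}^{MCq_\mathrm{target}}$
with $N$ the reference gene's copies per haploid genome (default 2).
The CRISPR/WT fold change is the ratio of mean ratios per reference
gene; multiple reference genes are pooled by geometric mean — the natural
mean on a ratio scale, and symmetric under swapping numerator and
denominator conventions.  (The published fold changes pooled an
unstated way; geometric pooling is this package's choice.)

## 8. The synthetic-data generator: its stated world

`simulate_family()` builds an ancestral gene carrying both primer sites
and the guide target sites between them, then derives paralogs by
independent per-site substitution.  Defaults and what they emulate:

* `n_copies = c(A = 10, B = 10, D = 6)`: a subgenome-structured family,
  desk-scale stand-in for the ~100-copy real locus.
* `ancestral_length = 900`, `amplicon_span = 440`: a gene of realistic
  length whose primer-to-primer amplicon merges comfortably from 2 × 280
  paired reads.
* `divergence_within = 0.02`: percent-level paralog divergence, the
  regime in which closest-reference selection is non-trivial but
  denoising still separates paralogs.
* Primer sites, protospacer + PAM sites and motif insertions are
  mutation-protected so every copy stays amplifiable and targetable;
  divergence high enough to destroy primer sites raises an explicit
  error.
* Subgenome motifs are inserted in-frame at a fixed codon boundary after
  the forward primer.

`apply_edits()` places each edit at the Cas9 cut (3 bp 5′ of the PAM)
plus an offset; deletions remove downstream bases, insertions add random
bases.  Zygosity is a per-copy molecular mixture (fraction edited),
because heterozygous lines present mutation products *and* the full WT
Amp set.  `large_deletion` removes copies outright, emulating
rearrangement at a tandem locus.  Truth coordinates are left-normalized.

`simulate_reads()` draws per-base qualities from a truncated normal
whose mean decays linearly along the read (default Q38 → Q28 over
280 cycles, sd 3) — the simplest model with realistic maxEE behavior —
and injects substitutions with probability $10^{-Q/10}$, so qualities
are consistent with errors by construction.  The quality profile is
shifted so the *expectation* of the per-base error equals
`substitution_error_rate` (default 0.2 %), including the log-normal
convexity correction for the quality noise.  Read counts per molecule
are multinomial around `depth` × molecular fraction.

**What the simulator does not emulate** — hence what a green test does
not establish: PCR chimeras (the chimera filter is tested on constructed
cases, not on a chimera-generating PCR model), indel sequencing errors
(substitutions only), quality miscalibration, copy-number variation
among paralogs, primer-site polymorphism, and any property of the real
deposited sequencing runs.  Published real-data percentages and optima
are therefore not reproduction targets; the acceptance suite covers the
procedures with fixtures and closed forms instead.

## 9. Degenerate inputs and numerical conventions

* Empty FASTQ / zero extractable amplicons / zero-total count columns:
  explicit errors naming the offender.
* Constant heatmap rows map to 0 under min–max scaling (documented
  convention).
* MDS on fewer than 3 lines errors; identical lines simply coincide.
* Primer search tolerates ≤ 1 mismatch per primer by default
  (configurable); among multiple matches the longest amplicon wins.
* Duplicate removal in the database is exact-string after uppercasing;
  IUPAC codes are not expanded.
* All tie-breaks (dereplication order, search hits, reference choice,
  NJ label order) are deterministic and documented at the function
  level.

## 10. Known limitations

* The merge model assumes the amplicon is at least as long as one read;
  read-through into adapters is not modeled.
* The identity search's k-mer candidate filter is a heuristic: with very
  small databases all entries are examined, but for large databases an
  extremely distant best hit could in principle be missed (top-8
  candidates by shared 8-mers, configurable).
* Levenshtein distances in the denoiser treat all edits equally; no
  position- or homopolymer-aware error model.
* The cluster cut heuristic (median internal-node depth) is a
  reproducible default, not an inference; borderline cluster memberships
  are absorbed by the nearest-WT fallback, which is total.
* The classifier's secondary threshold (0.1 %) is a package default for
  a published-but-unquantified rule and should be treated as tunable.
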