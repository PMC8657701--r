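# Dendrogram-guided InDel calling: pairwise distances over all Amps of a
# background, neighbor-joining tree, closest-WT reference choice per CRISPR
# Amp (with adjacent-cluster fallback), and cut-site anchored InDel calls.

ALN_MATCH <- 1; ALN_MISMATCH <- -1; ALN_GAP_OPEN <- 2; ALN_GAP_EXT <- 0.5

#' Define a CRISPR target site
#'
#' @param name site label.
#' @param protospacer 20-mer protospacer (5'->3', PAM-proximal end last).
#' @param pam PAM motif (default NGG).
#' @param cut_offset bp upstream of the PAM where Cas9 cuts (default 3).
#' @return object of class `target_site`.
#' @export
target_site <- function(name, protospacer, pam = "NGG", cut_offset = 3) {
  protospacer <- toupper(protospacer)
  if (nchar(protospacer) != 20) stop("protospacer must be a 20-mer")
  structure(list(name = name, protospacer = protospacer, pam = pam,
                 cut_offset = as.integer(cut_offset)),
            class = "target_site")
}

#' The two default alpha-gliadin guides
#'
#' sgAlpha1 (GCCACAAGAGCAAGTTCCAT) and sgAlpha2 (GGTTGTGATGGAAATGGTTG).
#'
#' @return data.frame `name`, `protospacer`, `pam`, `cut_offset`.
#' @export
default_target_sites <- function() {
  data.frame(name = c("sgAlpha1", "sgAlpha2"),
             protospacer = c("GCCACAAGAGCAAGTTCCAT", "GGTTGTGATGGAAATGGTTG"),
             pam = "NGG", cut_offset = 3L, stringsAsFactors = FALSE)
}

align_pair <- function(a, b) {
  aln <- cpp_align(a, b, match = ALN_MATCH, mismatch = ALN_MISMATCH,
                   gap_open = ALN_GAP_OPEN, gap_ext = ALN_GAP_EXT,
                   free_ends = FALSE)
  la <- left_align_gaps(aln$a, aln$b)
  la
}

# Shift every gap run maximally left (standard variant normalization);
# repeat-rich sequence makes gap placement ambiguous otherwise.  A gap run
# in one row can move one column left whenever the other row's character
# entering the run equals the one leaving it, which preserves column-wise
# match status.
shift_gaps_left <- function(g, o) {
  i <- 1L; n <- length(g); moved <- FALSE
  while (i <= n) {
    if (g[i] != "-") { i <- i + 1L; next }
    j <- i
    while (j < n && g[j + 1L] == "-") j <- j + 1L
    while (i > 1L && g[i - 1L] != "-" && o[i - 1L] != "-" &&
             o[i - 1L] == o[j]) {
      g[j] <- g[i - 1L]; g[i - 1L] <- "-"
      i <- i - 1L; j <- j - 1L
      moved <- TRUE
    }
    i <- j + 1L
  }
  list(g = g, moved = moved)
}

left_align_gaps <- function(a, b) {
  av <- strsplit(a, "")[[1]]; bv <- strsplit(b, "")[[1]]
  repeat {
    r1 <- shift_gaps_left(av, bv); av <- r1$g
    r2 <- shift_gaps_left(bv, av); bv <- r2$g
    if (!r1$moved && !r2$moved) break
  }
  list(a = paste(av, collapse = ""), b = paste(bv, collapse = ""))
}

#' Pairwise p-distances between Amp sequences
#'
#' Global pairwise alignment (match +1, mismatch -1, gap open -2, gap
#' extend -0.5); distance = (mismatches + gap openings) / alignment
#' columns.
#'
#' @param amps data.frame `id`, `seq` (an `amp_set`), or named character
#'   vector of sequences.
#' @return symmetric distance matrix with Amp ids as dimnames.
#' @export
pairwise_distances <- function(amps) {
  if (is.character(amps)) amps <- data.frame(id = names(amps), seq = amps)
  n <- nrow(amps)
  if (n < 2) stop("need at least two Amps")
  d <- matrix(0, n, n, dimnames = list(amps$id, amps$id))
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      aln <- cpp_align(amps$seq[i], amps$seq[j],
                       match = ALN_MATCH, mismatch = ALN_MISMATCH,
                       gap_open = ALN_GAP_OPEN, gap_ext = ALN_GAP_EXT)
      st <- cpp_aln_stats(aln$a, aln$b)
      d[i, j] <- d[j, i] <- (st$mismatches + st$gap_opens +
                               (st$lead > 0) + (st$trail > 0)) / st$cols
    }
  }
  d
}

#' Neighbor-joining tree from a distance matrix
#'
#' Classic neighbor joining (Q-matrix joins, Saitou-Nei branch lengths) via
#' the standard implementation in \pkg{ape}; negative branch lengths are
#' clamped to zero with a warning.
#'
#' @param d symmetric distance matrix (>= 3 labels).
#' @return an unrooted `phylo` tree.
#' @export
neighbor_joining <- function(d) {
  d <- as.matrix(d)
  if (nrow(d) < 3) stop("neighbor joining needs at least 3 labels")
  if (max(abs(d - t(d))) > 1e-9) stop("distance matrix must be symmetric")
  tree <- ape::nj(as.dist(d))
  if (any(tree$edge.length < 0)) {
    warning("negative NJ branch lengths clamped to 0")
    tree$edge.length[tree$edge.length < 0] <- 0
  }
  tree
}

# Leaf clusters of an NJ tree under a height cut: the tree is midpoint
# rooted, node depths are measured from the root, edges crossing the cut
# are removed, and each hanging subtree's leaves form a cluster (leaves
# above the cut are singletons).  cut = NULL uses the median depth of
# internal nodes — a reproducible default where published workflows drew
# cluster bars by hand.
#' Leaf clusters from a tree height cut
#' @param tree an unrooted `phylo` (from [neighbor_joining()]).
#' @param cut cut depth from the (midpoint) root; `NULL` for the median
#'   internal-node depth.
#' @return named integer vector: cluster index per leaf label.
#' @export
tree_clusters <- function(tree, cut = NULL) {
  rooted <- phangorn::midpoint(tree)
  ntip <- length(rooted$tip.label)
  root <- ntip + 1L
  nnode <- ntip + rooted$Nnode
  depth <- rep(NA_real_, nnode)
  depth[root] <- 0
  eo <- ape::reorder.phylo(rooted, "cladewise")
  for (k in seq_len(nrow(eo$edge))) {
    p <- eo$edge[k, 1]; ch <- eo$edge[k, 2]
    depth[ch] <- depth[p] + eo$edge.length[k]
  }
  if (is.null(cut)) {
    internal <- setdiff((ntip + 1L):nnode, root)
    cut <- if (length(internal)) median(depth[internal]) else 0
  }
  # cluster root of node v: the first ancestor edge crossing `cut`
  parent <- rep(NA_integer_, nnode)
  parent[eo$edge[, 2]] <- eo$edge[, 1]
  cluster_of <- rep(NA_integer_, ntip)
  anchors <- integer(0)
  for (leaf in seq_len(ntip)) {
    v <- leaf
    anchor <- leaf  # deepest node on the path with depth >= cut
    while (!is.na(parent[v])) {
      p <- parent[v]
      if (depth[p] >= cut) anchor <- p
      v <- p
    }
    key <- match(anchor, anchors)
    if (is.na(key)) { anchors <- c(anchors, anchor); key <- length(anchors) }
    cluster_of[leaf] <- key
  }
  setNames(cluster_of, rooted$tip.label)
}

#' Pick the closest wild-type reference for a CRISPR Amp
#'
#' The reference is the WT Amp sharing the CRISPR Amp's dendrogram cluster
#' with minimal distance; when the cluster holds no WT Amp, the fallback is
#' the nearest WT Amp over the whole background (the adjacent-cluster
#' rule).  Distance ties go to the lexicographically smallest WT id.
#'
#' @param tree tree over all Amps of the background.
#' @param crispr_amp id of the CRISPR Amp.
#' @param wt_set character vector of WT Amp ids.
#' @param d distance matrix over the same labels.
#' @param cut see [tree_clusters()].
#' @return the chosen WT Amp id.
#' @export
pick_reference <- function(tree, crispr_amp, wt_set, d, cut = NULL) {
  if (!length(wt_set)) stop("empty WT set")
  stopifnot(crispr_amp %in% rownames(d))
  wt_set <- intersect(rownames(d), wt_set)
  cl <- tree_clusters(tree, cut)
  mine <- cl[[crispr_amp]]
  in_cluster <- intersect(wt_set, names(cl)[cl == mine])
  pool <- if (length(in_cluster)) in_cluster else wt_set
  dd <- d[crispr_amp, pool]
  pool[order(dd, pool)][1]
}

# Scan a reference sequence for protospacer+PAM occurrences on both
# strands; returns 0-based cut positions (3 bp 5' of the PAM).
scan_cut_sites <- function(ref, sites, max_mismatch = 1) {
  out <- list()
  for (k in seq_len(nrow(sites))) {
    cuts <- find_cut_positions(ref, sites$protospacer[k], max_mismatch)
    if (length(cuts))
      out[[length(out) + 1L]] <- data.frame(site = sites$name[k], cut = cuts)
  }
  if (!length(out)) return(data.frame(site = character(), cut = integer()))
  do.call(rbind, out)
}

#' Call InDels in a CRISPR Amp against its wild-type reference
#'
#' Globally aligns the two sequences (gaps left-normalized), reports each
#' maximal gap run as one InDel with its 1-based reference position, and
#' attributes it to the nearest Cas9 cut site within `window` bp.  Cut
#' sites are located by scanning the reference for protospacer + NGG on
#' both strands (every occurrence is indexed; repeat regions can carry a
#' site more than once, and the nearest occurrence wins).
#'
#' @param crispr_seq,ref_seq DNA strings (query and reference).
#' @param sites data.frame like [default_target_sites()], or a list of
#'   [target_site()] objects.
#' @param window attribution window around the cut in bp (default 10).
#' @param max_site_mismatch mismatches tolerated when locating protospacers
#'   (default 1).
#' @return data.frame of class `indel_calls`: `type`, `length`,
#'   `position` (1-based on the reference; for insertions the base after
#'   which the insertion occurs), `indel_len` (signed), `attributed_site`
#'   (NA outside the window), `distance_to_cut`.
#' @export
call_indels <- function(crispr_seq, ref_seq, sites = default_target_sites(),
                        window = 10, max_site_mismatch = 1) {
  stopifnot(nzchar(crispr_seq), nzchar(ref_seq))
  if (is.list(sites) && !is.data.frame(sites))
    sites <- do.call(rbind, lapply(sites, function(s)
      data.frame(name = s$name, protospacer = s$protospacer,
                 pam = s$pam, cut_offset = s$cut_offset)))
  aln <- align_pair(toupper(crispr_seq), toupper(ref_seq))
  q <- strsplit(aln$a, "")[[1]]; r <- strsplit(aln$b, "")[[1]]
  cuts <- scan_cut_sites(toupper(ref_seq), sites, max_site_mismatch)

  calls <- list()
  refpos <- 0L
  i <- 1L; L <- length(q)
  while (i <= L) {
    if (q[i] != "-" && r[i] != "-") { refpos <- refpos + 1L; i <- i + 1L; next }
    j <- i
    if (r[i] == "-") {                       # insertion (extra in query)
      while (j < L && r[j + 1L] == "-") j <- j + 1L
      len <- j - i + 1L
      boundary <- refpos                     # 0-based: inserted after refpos
      calls[[length(calls) + 1L]] <- data.frame(
        type = "insertion", length = len, position = refpos,
        indel_len = len, boundary = boundary, stringsAsFactors = FALSE)
    } else {                                 # deletion (gap in query)
      while (j < L && q[j + 1L] == "-") j <- j + 1L
      len <- j - i + 1L
      boundary <- refpos                     # 0-based left edge of the run
      calls[[length(calls) + 1L]] <- data.frame(
        type = "deletion", length = len, position = refpos + 1L,
        indel_len = -len, boundary = boundary, stringsAsFactors = FALSE)
      refpos <- refpos + len
    }
    i <- j + 1L
  }
  if (!length(calls)) {
    out <- data.frame(type = character(), length = integer(),
                      position = integer(), indel_len = integer(),
                      attributed_site = character(),
                      distance_to_cut = integer())
    class(out) <- c("indel_calls", "data.frame")
    return(out)
  }
  out <- do.call(rbind, calls)
  out$attributed_site <- NA_character_
  out$distance_to_cut <- NA_integer_
  if (nrow(cuts)) {
    for (k in seq_len(nrow(out))) {
      dist <- out$boundary[k] - cuts$cut
      pick <- which.min(abs(dist))
      if (abs(dist[pick]) <= window) {
        out$attributed_site[k] <- cuts$site[pick]
        out$distance_to_cut[k] <- dist[pick]
      }
    }
  }
  out$boundary <- NULL
  class(out) <- c("indel_calls", "data.frame")
  out
}

#' InDel calls for every CRISPR Amp of a background
#'
#' Builds the distance matrix and NJ tree over all Amps, picks each CRISPR
#' Amp's closest WT reference, and calls InDels against it.
#'
#' @param amps data.frame `id`, `seq` covering all Amps of the background.
#' @param crispr_ids,wt_ids id vectors partitioning (a subset of) the Amps.
#' @param sites,window,max_site_mismatch see [call_indels()].
#' @param cut see [tree_clusters()].
#' @return data.frame: `crispr_amp_id`, `reference_wt_amp_id` and the
#'   [call_indels()] columns, one row per InDel; attribute `tree` carries
#'   the NJ tree.
#' @export
characterize_indels <- function(amps, crispr_ids, wt_ids,
                                sites = default_target_sites(), window = 10,
                                max_site_mismatch = 1, cut = NULL) {
  stopifnot(length(wt_ids) >= 1)
  d <- pairwise_distances(amps)
  tree <- if (nrow(amps) >= 3) neighbor_joining(d) else NULL
  rows <- list()
  for (cid in crispr_ids) {
    ref <- if (is.null(tree)) {
      pool <- intersect(rownames(d), wt_ids)
      pool[order(d[cid, pool], pool)][1]
    } else pick_reference(tree, cid, wt_ids, d, cut)
    calls <- call_indels(amps$seq[amps$id == cid], amps$seq[amps$id == ref],
                         sites, window, max_site_mismatch)
    if (nrow(calls)) {
      calls$crispr_amp_id <- cid
      calls$reference_wt_amp_id <- ref
      rows[[cid]] <- calls
    }
  }
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(type = character(), length = integer(), position = integer(),
               indel_len = integer(), attributed_site = character(),
               distance_to_cut = integer(), crispr_amp_id = character(),
               reference_wt_amp_id = character())
  rownames(out) <- NULL
  out <- out[, c("crispr_amp_id", "reference_wt_amp_id", "type", "length",
                 "position", "indel_len", "attributed_site",
                 "distance_to_cut")]
  attr(out, "tree") <- tree
  out
}
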