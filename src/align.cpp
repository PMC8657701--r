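#include <Rcpp.h>
#include <cstring>
#include <climits>
#include <cmath>
#include <vector>
#include <string>
#include <algorithm>
#include <unordered_set>

using namespace Rcpp;

// Affine-gap (Gotoh) global alignment.  free_ends = true leaves terminal
// gaps in both sequences unpenalized (glocal / overlap alignment), which is
// the identity convention used for database searches where the query may
// carry primer flanks absent from the database record.
//
// Traceback preference (deterministic): diagonal > gap-in-b (deletion from
// a's point of view consumes a) > gap-in-a.  Gap runs are subsequently
// left-normalized at the R level, so tie-breaking here only needs to be
// deterministic, not canonical.

struct AlnResult {
    std::string a_aln, b_aln;
    double score;
};

static const double NEG_INF = -1e30;

static AlnResult gotoh_align(const std::string& a, const std::string& b,
                             double match, double mismatch,
                             double gap_open, double gap_ext,
                             bool free_ends) {
    const int n = a.size(), m = b.size();
    // M: a[i] aligned to b[j]; X: gap in b (consumes a); Y: gap in a (consumes b)
    std::vector<std::vector<double>> M(n + 1, std::vector<double>(m + 1, NEG_INF));
    std::vector<std::vector<double>> X(n + 1, std::vector<double>(m + 1, NEG_INF));
    std::vector<std::vector<double>> Y(n + 1, std::vector<double>(m + 1, NEG_INF));

    M[0][0] = 0.0;
    for (int i = 1; i <= n; ++i)
        X[i][0] = free_ends ? 0.0 : -gap_open - (i - 1) * gap_ext;
    for (int j = 1; j <= m; ++j)
        Y[0][j] = free_ends ? 0.0 : -gap_open - (j - 1) * gap_ext;

    for (int i = 1; i <= n; ++i) {
        for (int j = 1; j <= m; ++j) {
            double s = (a[i - 1] == b[j - 1]) ? match : mismatch;
            double prev = std::max(M[i - 1][j - 1],
                                   std::max(X[i - 1][j - 1], Y[i - 1][j - 1]));
            M[i][j] = prev + s;
            double xo = std::max(M[i - 1][j] - gap_open, X[i - 1][j] - gap_ext);
            double yo = std::max(M[i][j - 1] - gap_open, Y[i][j - 1] - gap_ext);
            // terminal gaps free on the last column/row
            if (free_ends && j == m)
                xo = std::max(xo, std::max(M[i - 1][j], X[i - 1][j]));
            if (free_ends && i == n)
                yo = std::max(yo, std::max(M[i][j - 1], Y[i][j - 1]));
            X[i][j] = xo;
            Y[i][j] = yo;
        }
    }

    // traceback
    std::string ra, rb;
    int i = n, j = m;
    double best = std::max(M[n][m], std::max(X[n][m], Y[n][m]));
    int state = (best == M[n][m]) ? 0 : (best == X[n][m] ? 1 : 2);
    while (i > 0 || j > 0) {
        if (i == 0) {
            ra.push_back('-'); rb.push_back(b[--j]);
            continue;
        }
        if (j == 0) {
            ra.push_back(a[--i]); rb.push_back('-');
            continue;
        }
        if (state == 0) {
            double s = (a[i - 1] == b[j - 1]) ? match : mismatch;
            double prev = M[i][j] - s;
            ra.push_back(a[i - 1]); rb.push_back(b[j - 1]);
            --i; --j;
            if (prev == M[i][j]) state = 0;
            else if (prev == X[i][j]) state = 1;
            else state = 2;
        } else if (state == 1) {
            bool freehere = free_ends && j == m;
            ra.push_back(a[i - 1]); rb.push_back('-');
            double cur = X[i][j];
            --i;
            if (cur == M[i][j] - gap_open || (freehere && cur == M[i][j])) state = 0;
            else state = 1;
        } else {
            bool freehere = free_ends && i == n;
            ra.push_back('-'); rb.push_back(b[j - 1]);
            double cur = Y[i][j];
            --j;
            if (cur == M[i][j] - gap_open || (freehere && cur == M[i][j])) state = 0;
            else state = 2;
        }
    }
    std::reverse(ra.begin(), ra.end());
    std::reverse(rb.begin(), rb.end());
    return AlnResult{ra, rb, best};
}

// [[Rcpp::export]]
List cpp_align(std::string a, std::string b,
               double match = 1.0, double mismatch = -1.0,
               double gap_open = 2.0, double gap_ext = 0.5,
               bool free_ends = false) {
    AlnResult r = gotoh_align(a, b, match, mismatch, gap_open, gap_ext, free_ends);
    return List::create(_["a"] = r.a_aln, _["b"] = r.b_aln, _["score"] = r.score);
}

// Alignment summary statistics from two aligned strings.
// Terminal-gap columns (leading/trailing columns gapped in either sequence)
// are reported so identity can exclude them.
// [[Rcpp::export]]
List cpp_aln_stats(std::string a, std::string b) {
    const int L = a.size();
    int lead = 0, trail = 0;
    while (lead < L && (a[lead] == '-' || b[lead] == '-')) ++lead;
    while (trail < L - lead &&
           (a[L - 1 - trail] == '-' || b[L - 1 - trail] == '-')) ++trail;
    int matches = 0, mismatches = 0, gapcols = 0, gapopens = 0;
    bool in_gap_a = false, in_gap_b = false;
    for (int i = lead; i < L - trail; ++i) {
        if (a[i] == '-') {
            ++gapcols;
            if (!in_gap_a) { ++gapopens; in_gap_a = true; }
            in_gap_b = false;
        } else if (b[i] == '-') {
            ++gapcols;
            if (!in_gap_b) { ++gapopens; in_gap_b = true; }
            in_gap_a = false;
        } else {
            in_gap_a = in_gap_b = false;
            if (a[i] == b[i]) ++matches; else ++mismatches;
        }
    }
    return List::create(_["cols"] = L,
                        _["cols_internal"] = L - lead - trail,
                        _["matches"] = matches,
                        _["mismatches"] = mismatches,
                        _["gap_cols"] = gapcols,
                        _["gap_opens"] = gapopens,
                        _["lead"] = lead,
                        _["trail"] = trail);
}

// Banded Levenshtein distance with early abandon; returns -1 when the
// distance exceeds dmax.  Unit costs; used by the denoiser where only
// distances small enough to satisfy the abundance-skew rule matter.
// [[Rcpp::export]]
int cpp_edit_distance_banded(std::string a, std::string b, int dmax) {
    int n = a.size(), m = b.size();
    if (std::abs(n - m) > dmax) return -1;
    if (n == 0) return m <= dmax ? m : -1;
    if (m == 0) return n <= dmax ? n : -1;
    const int BIG = INT_MAX / 4;
    std::vector<int> prev(m + 1, BIG), cur(m + 1, BIG);
    for (int j = 0; j <= std::min(m, dmax); ++j) prev[j] = j;
    for (int i = 1; i <= n; ++i) {
        int jlo = std::max(1, i - dmax), jhi = std::min(m, i + dmax);
        std::fill(cur.begin(), cur.end(), BIG);
        if (i <= dmax) cur[0] = i;
        int rowmin = BIG;
        for (int j = jlo; j <= jhi; ++j) {
            int sub = prev[j - 1] + (a[i - 1] == b[j - 1] ? 0 : 1);
            int del = prev[j] + 1;
            int ins = cur[j - 1] + 1;
            cur[j] = std::min(sub, std::min(del, ins));
            rowmin = std::min(rowmin, cur[j]);
        }
        if (i <= dmax && cur[0] < rowmin) rowmin = cur[0];
        if (rowmin > dmax) return -1;
        std::swap(prev, cur);
    }
    return prev[m] <= dmax ? prev[m] : -1;
}

// Hamming distance for equal-length sequences; -1 if lengths differ.
// [[Rcpp::export]]
int cpp_hamming(std::string a, std::string b) {
    if (a.size() != b.size()) return -1;
    int d = 0;
    for (size_t i = 0; i < a.size(); ++i)
        if (a[i] != b[i]) ++d;
    return d;
}

// Shared k-mer counts between one query and each database sequence,
// used to rank candidate targets before alignment (usearch-style filter).
// [[Rcpp::export]]
IntegerVector cpp_shared_kmers(std::string query, CharacterVector db, int k = 8) {
    std::unordered_set<uint64_t> qk;
    auto encode = [&](const std::string& s, std::unordered_set<uint64_t>& out) {
        if ((int)s.size() < k) return;
        uint64_t mask = (k >= 32) ? ~0ULL : ((1ULL << (2 * k)) - 1);
        uint64_t cur = 0; int run = 0;
        for (size_t i = 0; i < s.size(); ++i) {
            int c;
            switch (s[i]) {
                case 'A': case 'a': c = 0; break;
                case 'C': case 'c': c = 1; break;
                case 'G': case 'g': c = 2; break;
                case 'T': case 't': c = 3; break;
                default: c = -1;
            }
            if (c < 0) { run = 0; cur = 0; continue; }
            cur = ((cur << 2) | c) & mask;
            if (++run >= k) out.insert(cur);
        }
    };
    encode(query, qk);
    IntegerVector res(db.size());
    for (int i = 0; i < db.size(); ++i) {
        std::unordered_set<uint64_t> dk;
        encode(as<std::string>(db[i]), dk);
        int shared = 0;
        for (uint64_t km : dk) if (qk.count(km)) ++shared;
        res[i] = shared;
    }
    return res;
}

// Shared k-mer counts for many queries against one database, database
// profiles encoded once.  Rows = queries, cols = db entries.
// [[Rcpp::export]]
IntegerMatrix cpp_shared_kmers_matrix(CharacterVector queries,
                                      CharacterVector db, int k = 8) {
    auto encode = [&](const std::string& s, std::unordered_set<uint64_t>& out) {
        if ((int)s.size() < k) return;
        uint64_t mask = (k >= 32) ? ~0ULL : ((1ULL << (2 * k)) - 1);
        uint64_t cur = 0; int run = 0;
        for (size_t i = 0; i < s.size(); ++i) {
            int c;
            switch (s[i]) {
                case 'A': case 'a': c = 0; break;
                case 'C': case 'c': c = 1; break;
                case 'G': case 'g': c = 2; break;
                case 'T': case 't': c = 3; break;
                default: c = -1;
            }
            if (c < 0) { run = 0; cur = 0; continue; }
            cur = ((cur << 2) | c) & mask;
            if (++run >= k) out.insert(cur);
        }
    };
    int nd = db.size(), nq = queries.size();
    std::vector<std::unordered_set<uint64_t>> dbk(nd);
    for (int j = 0; j < nd; ++j) encode(as<std::string>(db[j]), dbk[j]);
    IntegerMatrix res(nq, nd);
    for (int i = 0; i < nq; ++i) {
        std::unordered_set<uint64_t> qk;
        encode(as<std::string>(queries[i]), qk);
        for (int j = 0; j < nd; ++j) {
            int shared = 0;
            const auto& small = (qk.size() < dbk[j].size()) ? qk : dbk[j];
            const auto& big = (qk.size() < dbk[j].size()) ? dbk[j] : qk;
            for (uint64_t km : small) if (big.count(km)) ++shared;
            res(i, j) = shared;
        }
    }
    return res;
}

// Longest common prefix / suffix lengths of x against each y.
// Used by the de novo chimera check (perfect left/right parent model).
// [[Rcpp::export]]
List cpp_lcp_lcs(std::string x, CharacterVector ys) {
    int n = ys.size();
    IntegerVector lcp(n), lcs(n);
    for (int i = 0; i < n; ++i) {
        std::string y = as<std::string>(ys[i]);
        size_t lim = std::min(x.size(), y.size());
        size_t p = 0;
        while (p < lim && x[p] == y[p]) ++p;
        lcp[i] = p;
        size_t s = 0;
        while (s < lim && x[x.size() - 1 - s] == y[y.size() - 1 - s]) ++s;
        lcs[i] = s;
    }
    return List::create(_["lcp"] = lcp, _["lcs"] = lcs);
}

// ---------------------------------------------------------------------------
// Paired-read merging: best ungapped overlap between R1 and revcomp(R2),
// posterior quality recomputation at overlap positions.
// seq2 / qual2 must already be reverse-complemented / reversed by the caller.
// Overlap model: R1 head, R2 tail; overlap length L in [min_overlap,
// min(n1, n2)]; merged = R1[1..n1] + R2[(L+1)..n2].  The chosen L maximizes
// (matches - mismatches) in the overlap; ties go to the longer overlap.
// ---------------------------------------------------------------------------

static inline double phred_to_p(int q) { return std::pow(10.0, -q / 10.0); }

// [[Rcpp::export]]
List cpp_merge_pairs(CharacterVector seq1, CharacterVector qual1,
                     CharacterVector seq2, CharacterVector qual2,
                     int min_overlap, double maxdiffs, double maxdiffpct,
                     int qmax = 41, int qmin = 2) {
    int nrec = seq1.size();
    CharacterVector mseq(nrec), mqual(nrec);
    IntegerVector overlap(nrec), ndiff(nrec);
    LogicalVector merged(nrec);
    int diffcap = (int)std::floor(maxdiffs);

    for (int r = 0; r < nrec; ++r) {
        std::string s1 = as<std::string>(seq1[r]);
        std::string s2 = as<std::string>(seq2[r]);
        std::string q1 = as<std::string>(qual1[r]);
        std::string q2 = as<std::string>(qual2[r]);
        int n1 = s1.size(), n2 = s2.size();
        int Lmax = std::min(n1, n2);
        int bestL = -1, bestScore = INT_MIN, bestMm = 0;
        for (int L = min_overlap; L <= Lmax; ++L) {
            // overlap: s1 tail of length L vs s2 head of length L
            int mm = 0;
            const char* p1 = s1.data() + (n1 - L);
            const char* p2 = s2.data();
            for (int i = 0; i < L; ++i)
                if (p1[i] != p2[i]) ++mm;
            int score = (L - mm) - mm;
            if (score > bestScore || (score == bestScore && L > bestL)) {
                bestScore = score; bestL = L; bestMm = mm;
            }
        }
        if (bestL < 0) { merged[r] = false; mseq[r] = NA_STRING; mqual[r] = NA_STRING; continue; }
        double pct = 100.0 * bestMm / bestL;
        overlap[r] = bestL; ndiff[r] = bestMm;
        if (bestMm > diffcap || pct > maxdiffpct) {
            merged[r] = false; mseq[r] = NA_STRING; mqual[r] = NA_STRING;
            continue;
        }
        // merged sequence: s1 prefix + consensus overlap + s2 suffix
        std::string ms; ms.reserve(n1 + n2 - bestL);
        std::string mq; mq.reserve(n1 + n2 - bestL);
        ms.append(s1, 0, n1 - bestL);
        mq.append(q1, 0, n1 - bestL);
        for (int i = 0; i < bestL; ++i) {
            char b1 = s1[n1 - bestL + i], b2 = s2[i];
            int Q1 = q1[n1 - bestL + i] - 33, Q2 = q2[i] - 33;
            double p1 = phred_to_p(Q1), p2 = phred_to_p(Q2);
            char base; double pe;
            if (b1 == b2) {
                base = b1;
                // posterior error: both reads agree
                double num = p1 * p2 / 3.0;
                double den = (1.0 - p1) * (1.0 - p2) + num;
                pe = num / den;
            } else {
                // keep the higher-quality base; exact posterior over 4 bases
                double pa = (1.0 - p1) * (p2 / 3.0);        // true = b1
                double pb = (p1 / 3.0) * (1.0 - p2);        // true = b2
                double pc = 2.0 * (p1 / 3.0) * (p2 / 3.0);  // true = other
                double tot = pa + pb + pc;
                if (Q1 >= Q2) { base = b1; pe = 1.0 - pa / tot; }
                else          { base = b2; pe = 1.0 - pb / tot; }
            }
            int Q;
            if (pe <= 0) Q = qmax;
            else Q = (int)std::lround(-10.0 * std::log10(pe));
            Q = std::max(qmin, std::min(qmax, Q));
            ms.push_back(base);
            mq.push_back((char)(Q + 33));
        }
        ms.append(s2, bestL, n2 - bestL);
        mq.append(q2, bestL, n2 - bestL);
        mseq[r] = ms; mqual[r] = mq;
        merged[r] = true;
    }
    return List::create(_["seq"] = mseq, _["qual"] = mqual,
                        _["merged"] = merged, _["overlap"] = overlap,
                        _["ndiff"] = ndiff);
}

// Reverse each string (used for reversing R2 quality strings).
// [[Rcpp::export]]
CharacterVector cpp_reverse_strings(CharacterVector x) {
    CharacterVector out(x.size());
    for (int i = 0; i < x.size(); ++i) {
        std::string s = as<std::string>(x[i]);
        std::reverse(s.begin(), s.end());
        out[i] = s;
    }
    return out;
}

// Expected errors per read from a Phred+33 quality string.
// [[Rcpp::export]]
NumericVector cpp_expected_errors(CharacterVector qual) {
    int n = qual.size();
    NumericVector ee(n);
    for (int i = 0; i < n; ++i) {
        if (qual[i] == NA_STRING) { ee[i] = NA_REAL; continue; }
        std::string q = as<std::string>(qual[i]);
        double s = 0;
        for (char c : q) s += std::pow(10.0, -(c - 33) / 10.0);
        ee[i] = s;
    }
    return ee;
}
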