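#include <Rcpp.h>
#include <random>
#include <vector>

using namespace Rcpp;

// Number of datasets in which gene i peaks strictly before gene j.
// tp is genes x datasets; NA marks a gene with no peak in that dataset.
// A dataset contributes to a pair only when both values are present; ties
// support neither direction.
// [[Rcpp::export]]
IntegerMatrix pair_support_cpp(NumericMatrix tp) {
    const int g = tp.nrow(), d = tp.ncol();
    IntegerMatrix supp(g, g);
    for (int c = 0; c < d; ++c) {
        for (int i = 0; i < g; ++i) {
            const double ti = tp(i, c);
            if (ISNAN(ti)) continue;
            for (int j = 0; j < g; ++j) {
                if (j == i) continue;
                const double tj = tp(j, c);
                if (ISNAN(tj)) continue;
                if (ti < tj) ++supp(i, j);
            }
        }
    }
    return supp;
}

static int count_edges(const std::vector<std::vector<double>> &cols,
                       const std::vector<std::vector<int>> &idx, int g,
                       int quorum) {
    // cols[c] holds the permuted values for the non-missing genes of column c
    // (in idx[c] order); tally pairwise precedence across columns.
    std::vector<int> supp(g * g, 0);
    const int d = cols.size();
    for (int c = 0; c < d; ++c) {
        const std::vector<int> &ix = idx[c];
        const std::vector<double> &v = cols[c];
        const int m = ix.size();
        for (int a = 0; a < m; ++a)
            for (int b = 0; b < m; ++b) {
                if (a == b) continue;
                if (v[a] < v[b]) ++supp[ix[a] * g + ix[b]];
            }
    }
    int edges = 0;
    for (int i = 0; i < g * g; ++i)
        if (supp[i] >= quorum) ++edges;
    return edges;
}

// Permutation null for the conserved-ordering edge count: each permutation
// independently shuffles the peak times within each dataset column across
// the genes present there (missing entries stay missing in place), then the
// conserved edges are recounted. Returns the edge count per permutation.
// [[Rcpp::export]]
IntegerVector perm_edge_counts_cpp(NumericMatrix tp, int quorum, int n_perm,
                                   int seed) {
    const int g = tp.nrow(), d = tp.ncol();
    std::mt19937_64 rng(static_cast<uint64_t>(seed) * 0x9E3779B97F4A7C15ULL + 17ULL);
    std::uniform_real_distribution<double> unif(0.0, 1.0);

    std::vector<std::vector<int>> idx(d);
    std::vector<std::vector<double>> base(d);
    for (int c = 0; c < d; ++c)
        for (int i = 0; i < g; ++i)
            if (!ISNAN(tp(i, c))) {
                idx[c].push_back(i);
                base[c].push_back(tp(i, c));
            }

    IntegerVector out(n_perm);
    std::vector<std::vector<double>> cols = base;
    for (int p = 0; p < n_perm; ++p) {
        for (int c = 0; c < d; ++c) {
            std::vector<double> &v = cols[c];
            v = base[c];
            for (int i = v.size() - 1; i > 0; --i) {
                int j = static_cast<int>(unif(rng) * (i + 1));
                if (j > i) j = i;
                std::swap(v[i], v[j]);
            }
        }
        out[p] = count_edges(cols, idx, g, quorum);
        if ((p & 255) == 0) Rcpp::checkUserInterrupt();
    }
    return out;
}
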