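#include <Rcpp.h>
#include <vector>
#include <algorithm>

using namespace Rcpp;

// Pearson chi-square on a (genotype combination) x (control, case) table.
// counts: ncell control cells followed by ncell case cells.
// Rows with zero total (unobserved combinations) are dropped, so df = K - 1
// with K the number of observed combinations.  Degenerate tables (one row,
// or an empty status column) score zero.
static void tableChi2(const int *counts, int ncell, double *chi2, int *df) {
    double n0 = 0.0, n1 = 0.0;
    int K = 0;
    for (int c = 0; c < ncell; ++c) {
        int tot = counts[c] + counts[ncell + c];
        if (tot > 0)
            ++K;
        n0 += counts[c];
        n1 += counts[ncell + c];
    }
    *df = (K > 1) ? K - 1 : 1;
    if (K < 2 || n0 == 0.0 || n1 == 0.0) {
        *chi2 = 0.0;
        return;
    }
    const double N = n0 + n1;
    double s = 0.0;
    for (int c = 0; c < ncell; ++c) {
        double tot = counts[c] + counts[ncell + c];
        if (tot == 0.0)
            continue;
        double e0 = tot * n0 / N;
        double e1 = tot * n1 / N;
        double d0 = counts[c] - e0;
        double d1 = counts[ncell + c] - e1;
        s += d0 * d0 / e0 + d1 * d1 / e1;
    }
    *chi2 = s;
}

//' @noRd
// [[Rcpp::export(name = ".pairScanCpp")]]
List pairScanCpp(IntegerMatrix geno, IntegerVector status) {
    const int N = geno.nrow();
    const int L = geno.ncol();
    const R_xlen_t M = (R_xlen_t)L * (L - 1) / 2;
    IntegerVector li(M), lj(M), df(M);
    NumericVector chi2(M);
    std::vector<int> st(N);
    for (int s = 0; s < N; ++s)
        st[s] = status[s] ? 9 : 0;
    const int *g = INTEGER(geno);
    R_xlen_t k = 0;
    int counts[18];
    for (int i = 0; i < L - 1; ++i) {
        const int *gi = g + (R_xlen_t)i * N;
        for (int j = i + 1; j < L; ++j) {
            const int *gj = g + (R_xlen_t)j * N;
            std::fill(counts, counts + 18, 0);
            for (int s = 0; s < N; ++s)
                ++counts[st[s] + gi[s] * 3 + gj[s]];
            double c2;
            int d;
            tableChi2(counts, 9, &c2, &d);
            li[k] = i + 1;
            lj[k] = j + 1;
            chi2[k] = c2;
            df[k] = d;
            ++k;
        }
        if ((i & 31) == 0)
            Rcpp::checkUserInterrupt();
    }
    return List::create(_["locus1"] = li, _["locus2"] = lj,
                        _["chi2"] = chi2, _["df"] = df);
}

//' @noRd
// [[Rcpp::export(name = ".scoreSetsCpp")]]
List scoreSetsCpp(IntegerMatrix geno, IntegerVector status, IntegerMatrix sets) {
    const int N = geno.nrow();
    const int m = sets.nrow();
    const int n = sets.ncol();
    int ncell = 1;
    for (int d = 0; d < n; ++d)
        ncell *= 3;
    NumericVector chi2(m);
    IntegerVector df(m);
    std::vector<int> counts(2 * ncell);
    std::vector<int> st(N);
    for (int s = 0; s < N; ++s)
        st[s] = status[s] ? ncell : 0;
    const int *g = INTEGER(geno);
    std::vector<const int *> cols(n);
    for (int a = 0; a < m; ++a) {
        std::fill(counts.begin(), counts.end(), 0);
        for (int d = 0; d < n; ++d)
            cols[d] = g + (R_xlen_t)(sets(a, d) - 1) * N;
        for (int s = 0; s < N; ++s) {
            int key = 0;
            for (int d = 0; d < n; ++d)
                key = key * 3 + cols[d][s];
            ++counts[st[s] + key];
        }
        double c2;
        int d;
        tableChi2(counts.data(), ncell, &c2, &d);
        chi2[a] = c2;
        df[a] = d;
        if ((a & 255) == 0)
            Rcpp::checkUserInterrupt();
    }
    return List::create(_["chi2"] = chi2, _["df"] = df);
}

// Fenwick (binary indexed) tree over locus weights, supporting prefix-sum
// inversion in O(log L).  Used for sequential weighted sampling without
// replacement: each draw inverts the CDF over the remaining weights in
// locus-index order, exactly as a linear renormalizing scan would.
struct Fenwick {
    int n, highbit;
    std::vector<double> t; // 1-based
    explicit Fenwick(const std::vector<double> &w) : n((int)w.size()),
                                                     t(w.size() + 1, 0.0) {
        for (int i = 1; i <= n; ++i) {
            t[i] += w[i - 1];
            int j = i + (i & -i);
            if (j <= n)
                t[j] += t[i];
        }
        highbit = 1;
        while ((highbit << 1) <= n)
            highbit <<= 1;
    }
    void add(int i, double d) { // 0-based index
        for (int j = i + 1; j <= n; j += j & -j)
            t[j] += d;
    }
    double total() const {
        double s = 0.0;
        for (int j = n; j > 0; j -= j & -j)
            s += t[j];
        return s;
    }
    // largest index whose prefix sum (exclusive) is <= u; 0-based
    int find(double u) const {
        int idx = 0;
        for (int k = highbit; k > 0; k >>= 1) {
            int nxt = idx + k;
            if (nxt <= n && t[nxt] <= u) {
                idx = nxt;
                u -= t[nxt];
            }
        }
        return idx < n ? idx : n - 1;
    }
};

// Sequential weighted sampling without replacement: each of the n draws picks
// a locus proportional to its weight among the loci not yet in the set
// (renormalization is implicit in drawing from the remaining total mass).
// Uses the R RNG so results are reproducible under set.seed().
//' @noRd
// [[Rcpp::export(name = ".sampleSetsCpp")]]
IntegerMatrix sampleSetsCpp(NumericVector prob, int n, int nSets) {
    const int L = prob.size();
    if (n > L)
        stop("cannot sample %d distinct loci from %d", n, L);
    IntegerMatrix out(nSets, n);
    std::vector<double> w(prob.begin(), prob.end());
    for (int k = 0; k < L; ++k)
        if (w[k] < 0.0 || !R_finite(w[k]))
            stop("probabilities must be finite and nonnegative");
    Fenwick tree(w);
    std::vector<int> chosen(n);
    for (int a = 0; a < nSets; ++a) {
        double total = tree.total();
        for (int d = 0; d < n; ++d) {
            double u = unif_rand() * total;
            int pick = tree.find(u);
            if (w[pick] <= 0.0) { // float round-off at a removed locus
                int alt = pick;
                while (alt < L - 1 && w[alt] <= 0.0)
                    ++alt;
                while (alt > 0 && w[alt] <= 0.0)
                    --alt;
                pick = alt;
            }
            chosen[d] = pick;
            total -= w[pick];
            tree.add(pick, -w[pick]);
            w[pick] = 0.0;
        }
        std::sort(chosen.begin(), chosen.end());
        for (int d = 0; d < n; ++d) {
            out(a, d) = chosen[d] + 1;
            w[chosen[d]] = prob[chosen[d]];
            tree.add(chosen[d], prob[chosen[d]]);
        }
        if ((a & 255) == 0)
            Rcpp::checkUserInterrupt();
    }
    return out;
}
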