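#include "aligntails.h"
#include <vector>
#include <algorithm>
using namespace Rcpp;

// Score-only affine-gap Smith-Waterman with a bipartite (per-query-row)
// matrix choice. x, y are 0-based symbol indices; xregion[i] selects the
// region matrix for query row i. Gap of length l costs openCost +
// extCost*(l-1), i.e. openCost already includes the first extended position
// under the open_plus_len convention (openCost = a + b) and equals the bare
// open penalty under open_plus_len_minus_1 (openCost = a).
int sw_score_core(const int *x, int lx, const int *y, int ly,
                  const IntegerMatrix &mdef, const IntegerMatrix &mreg,
                  const int *xregion, int openCost, int extCost) {
    if (lx == 0 || ly == 0) return 0;
    const int nsym = mdef.nrow();
    const int NEG = INT_MIN / 4;
    // subject profiles: prof[sym * ly + j] = m(sym, y[j]); sequential access
    // in the inner loop (R is single-threaded, static buffers are safe)
    static std::vector<int> profD, profR, H, E;
    profD.resize((size_t)nsym * ly);
    const int *md = mdef.begin();
    for (int j = 0; j < ly; ++j) {
        const int *col = md + (size_t)y[j] * nsym;
        for (int s = 0; s < nsym; ++s) profD[(size_t)s * ly + j] = col[s];
    }
    bool anyRegion = false;
    for (int i = 0; i < lx; ++i) if (xregion[i]) { anyRegion = true; break; }
    if (anyRegion) {
        profR.resize((size_t)nsym * ly);
        const int *mr = mreg.begin();
        for (int j = 0; j < ly; ++j) {
            const int *col = mr + (size_t)y[j] * nsym;
            for (int s = 0; s < nsym; ++s) profR[(size_t)s * ly + j] = col[s];
        }
    }
    H.assign(ly + 1, 0);
    E.assign(ly + 1, NEG);
    int best = 0;
    int *h = H.data(), *e = E.data();
    for (int i = 1; i <= lx; ++i) {
        const int *pr = (xregion[i - 1] ? profR.data() : profD.data())
                        + (size_t)x[i - 1] * ly;
        int diag = 0;      // H[i-1][j-1]
        int F = NEG;
        for (int j = 1; j <= ly; ++j) {
            const int up = h[j]; // H[i-1][j]
            int ej = std::max(e[j] - extCost, up - openCost);
            F = std::max(F - extCost, h[j - 1] - openCost);
            int v = diag + pr[j - 1];
            v = std::max(v, ej);
            v = std::max(v, F);
            v = std::max(v, 0);
            e[j] = ej;
            diag = up;
            h[j] = v;
            best = std::max(best, v);
        }
    }
    return best;
}

// [[Rcpp::export]]
int cpp_sw_score(IntegerVector x, IntegerVector y,
                 IntegerMatrix mdef, IntegerMatrix mreg,
                 IntegerVector xregion, int openCost, int extCost) {
    return sw_score_core(x.begin(), x.size(), y.begin(), y.size(),
                         mdef, mreg, xregion.begin(), openCost, extCost);
}

// Batch scoring of independently drawn pairs: X is LQ x n (or LQ x 1 for a
// fixed query recycled across subjects), Y is LS x n, column = one pair.
// [[Rcpp::export]]
IntegerVector cpp_sw_score_many(IntegerMatrix X, IntegerMatrix Y,
                                IntegerMatrix mdef, IntegerMatrix mreg,
                                IntegerVector xregion, int openCost,
                                int extCost) {
    const int n = Y.ncol(), lq = X.nrow(), ls = Y.nrow();
    IntegerVector out(n);
    for (int i = 0; i < n; ++i) {
        const int *x = &X[(size_t)(X.ncol() == 1 ? 0 : i) * lq];
        const int *y = &Y[(size_t)i * ls];
        out[i] = sw_score_core(x, lq, y, ls, mdef, mreg, xregion.begin(),
                               openCost, extCost);
    }
    return out;
}

// ---- HMM forward / Viterbi (log domain) --------------------------------

static double logsumexp(const std::vector<double> &v) {
    double m = R_NegInf;
    for (double a : v) if (a > m) m = a;
    if (!R_FINITE(m)) return R_NegInf;
    double s = 0.0;
    for (double a : v) s += std::exp(a - m);
    return m + std::log(s);
}

// [[Rcpp::export]]
List cpp_forward(IntegerVector x, NumericMatrix logEmis,
                 NumericMatrix logTrans, NumericVector logInit) {
    const int L = x.size(), K = logInit.size();
    NumericMatrix tab(K, L);
    std::vector<double> prev(K), tmp(K);
    for (int k = 0; k < K; ++k) {
        prev[k] = logInit[k] + logEmis(k, x[0]);
        tab(k, 0) = prev[k];
    }
    for (int i = 1; i < L; ++i) {
        for (int k = 0; k < K; ++k) {
            for (int t = 0; t < K; ++t) tmp[t] = prev[t] + logTrans(t, k);
            tab(k, i) = logEmis(k, x[i]) + logsumexp(tmp);
        }
        for (int k = 0; k < K; ++k) prev[k] = tab(k, i);
    }
    double lp = logsumexp(prev);
    return List::create(_["log_prob"] = lp, _["table"] = tab);
}

// [[Rcpp::export]]
List cpp_viterbi(IntegerVector x, NumericMatrix logEmis,
                 NumericMatrix logTrans, NumericVector logInit) {
    const int L = x.size(), K = logInit.size();
    NumericMatrix tab(K, L);
    IntegerMatrix back(K, L);
    for (int k = 0; k < K; ++k) {
        tab(k, 0) = logInit[k] + logEmis(k, x[0]);
        back(k, 0) = 0;
    }
    for (int i = 1; i < L; ++i) {
        for (int k = 0; k < K; ++k) {
            double bestv = R_NegInf;
            int bestt = 0;
            for (int t = 0; t < K; ++t) {
                double v = tab(t, i - 1) + logTrans(t, k);
                if (v > bestv) { bestv = v; bestt = t; } // ties: lowest index
            }
            tab(k, i) = logEmis(k, x[i]) + bestv;
            back(k, i) = bestt;
        }
    }
    double bestv = R_NegInf;
    int bestk = 0;
    for (int k = 0; k < K; ++k)
        if (tab(k, L - 1) > bestv) { bestv = tab(k, L - 1); bestk = k; }
    IntegerVector path(L);
    path[L - 1] = bestk;
    for (int i = L - 1; i > 0; --i) path[i - 1] = back[(size_t)i * K + path[i]];
    for (int i = 0; i < L; ++i) path[i] += 1; // 1-based state indices
    return List::create(_["path"] = path, _["log_prob"] = bestv,
                        _["table"] = tab);
}

// Number of maximal runs of helix-core states along a path (1-based states).
// [[Rcpp::export]]
int cpp_count_core_runs(IntegerVector path, LogicalVector isCore) {
    int n = 0;
    bool in = false;
    for (int i = 0; i < path.size(); ++i) {
        bool c = isCore[path[i] - 1];
        if (c && !in) ++n;
        in = c;
    }
    return n;
}
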