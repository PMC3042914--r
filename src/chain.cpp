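#include "aligntails.h"
#include <vector>
#include <cmath>
using namespace Rcpp;

// Sequence-space Metropolis-Hastings / Wang-Landau driver.
//
// Modes: 0 = RQGS (both sequences i.i.d.), 1 = FQPS (query fixed),
//        2 = HMM (query from a hidden Markov model, subject i.i.d.).
//
// Symbols are 0-based indices. The move set is length-preserving:
// substitution (prob 1/2) and four shift moves (prob 1/8 each); replacement
// symbols are drawn from the null frequencies (i.i.d. sequences, so the
// proposal ratio cancels the null-probability ratio exactly) or uniformly
// for HMM-generated queries (ratio 1, null ratio enters the acceptance).
// Proposals with a score or class outside the window are rejected and the
// current bin is re-counted.

enum { SUBSTITUTE = 0, INS_LEFT = 1, INS_RIGHT = 2, DEL_RIGHT = 3,
       DEL_LEFT = 4 };

static void apply_move_buf(const std::vector<int> &src, std::vector<int> &dst,
                           int kind, int pos, int sym, int &removed) {
    const int L = (int)src.size();
    dst = src;
    switch (kind) {
    case SUBSTITUTE:
        removed = dst[pos - 1];
        dst[pos - 1] = sym;
        break;
    case INS_LEFT:
        removed = dst[0];
        for (int i = 0; i < pos - 1; ++i) dst[i] = dst[i + 1];
        dst[pos - 1] = sym;
        break;
    case INS_RIGHT:
        removed = dst[L - 1];
        for (int i = L - 1; i >= pos; --i) dst[i] = dst[i - 1];
        dst[pos - 1] = sym;
        break;
    case DEL_RIGHT:
        removed = dst[pos - 1];
        for (int i = pos - 1; i >= 1; --i) dst[i] = dst[i - 1];
        dst[0] = sym;
        break;
    case DEL_LEFT:
        removed = dst[pos - 1];
        for (int i = pos - 1; i < L - 1; ++i) dst[i] = dst[i + 1];
        dst[L - 1] = sym;
        break;
    }
}

// [[Rcpp::export]]
IntegerVector cpp_apply_move(IntegerVector seq, int kind, int pos, int sym) {
    std::vector<int> src(seq.begin(), seq.end()), dst;
    int removed;
    apply_move_buf(src, dst, kind, pos, sym, removed);
    return wrap(dst);
}

static int sw_score_vec(const std::vector<int> &x, const std::vector<int> &y,
                        const IntegerMatrix &mdef, const IntegerMatrix &mreg,
                        const IntegerVector &xregion, int openCost,
                        int extCost) {
    return sw_score_core(x.data(), (int)x.size(), y.data(), (int)y.size(),
                         mdef, mreg, xregion.begin(), openCost, extCost);
}

static double forward_logprob(const std::vector<int> &x,
                              const NumericMatrix &logEmis,
                              const NumericMatrix &logTrans,
                              const NumericVector &logInit,
                              std::vector<double> &prev,
                              std::vector<double> &cur) {
    const int L = (int)x.size(), K = logInit.size();
    for (int k = 0; k < K; ++k) prev[k] = logInit[k] + logEmis(k, x[0]);
    for (int i = 1; i < L; ++i) {
        for (int k = 0; k < K; ++k) {
            double m = R_NegInf;
            for (int t = 0; t < K; ++t) {
                double v = prev[t] + logTrans(t, k);
                if (v > m) m = v;
            }
            double s = 0.0;
            if (R_FINITE(m))
                for (int t = 0; t < K; ++t)
                    s += std::exp(prev[t] + logTrans(t, k) - m);
            cur[k] = logEmis(k, x[i]) + (R_FINITE(m) ? m + std::log(s)
                                                     : R_NegInf);
        }
        prev.swap(cur);
    }
    double m = R_NegInf;
    for (int k = 0; k < K; ++k) if (prev[k] > m) m = prev[k];
    if (!R_FINITE(m)) return R_NegInf;
    double s = 0.0;
    for (int k = 0; k < K; ++k) s += std::exp(prev[k] - m);
    return m + std::log(s);
}

// Viterbi class count (number of maximal helix-core runs on the best path)
static int viterbi_class(const std::vector<int> &x,
                         const NumericMatrix &logEmis,
                         const NumericMatrix &logTrans,
                         const NumericVector &logInit,
                         const LogicalVector &isCore) {
    const int L = (int)x.size(), K = logInit.size();
    std::vector<double> prev(K), cur(K);
    std::vector<int> back((size_t)L * K);
    for (int k = 0; k < K; ++k) prev[k] = logInit[k] + logEmis(k, x[0]);
    for (int i = 1; i < L; ++i) {
        for (int k = 0; k < K; ++k) {
            double bestv = R_NegInf;
            int bestt = 0;
            for (int t = 0; t < K; ++t) {
                double v = prev[t] + logTrans(t, k);
                if (v > bestv) { bestv = v; bestt = t; }
            }
            cur[k] = logEmis(k, x[i]) + bestv;
            back[(size_t)i * K + k] = bestt;
        }
        prev.swap(cur);
    }
    double bestv = R_NegInf;
    int k = 0;
    for (int t = 0; t < K; ++t) if (prev[t] > bestv) { bestv = prev[t]; k = t; }
    int n = 0;
    bool in = false;
    // walk the path backwards; runs counted identically in either direction
    for (int i = L - 1; i >= 0; --i) {
        bool c = isCore[k];
        if (c && !in) ++n;
        in = c;
        if (i > 0) k = back[(size_t)i * K + k];
    }
    return n;
}

static int draw_from_cum(const std::vector<double> &cum) {
    double u = unif_rand();
    int lo = 0, hi = (int)cum.size() - 1;
    while (lo < hi) {
        int mid = (lo + hi) / 2;
        if (u <= cum[mid]) hi = mid; else lo = mid + 1;
    }
    return lo;
}

// [[Rcpp::export]]
List cpp_run_chain(List state, int nSteps, int mode,
                   NumericVector freqs, NumericVector logFreqs,
                   IntegerMatrix mdef, IntegerMatrix mreg,
                   IntegerVector xregion, int openCost, int extCost,
                   int smin, int smax, int nmin, int nmax,
                   NumericMatrix logW, NumericMatrix H, double logPhi,
                   int recordEvery,
                   NumericMatrix logEmis, NumericMatrix logTrans,
                   NumericVector logInit, LogicalVector isCore,
                   double stepOffset, int rtPhase, double rtCount) {
    std::vector<int> x = as<std::vector<int> >(state["x"]);
    std::vector<int> y = as<std::vector<int> >(state["y"]);
    int s = as<int>(state["score"]);
    int n = as<int>(state["n_tm"]);
    double logQ = as<double>(state["log_query"]); // log f^query(x) (HMM mode)
    double logNull = as<double>(state["log_null"]);
    const int LQ = (int)x.size(), LS = (int)y.size(), nsym = freqs.size();
    const int K = logInit.size();

    std::vector<double> cum(nsym);
    double acc = 0.0;
    for (int i = 0; i < nsym; ++i) { acc += freqs[i]; cum[i] = acc; }
    cum[nsym - 1] = 1.0;

    std::vector<double> fwdPrev(K > 0 ? K : 1), fwdCur(K > 0 ? K : 1);
    std::vector<int> cand;
    long accepted = 0;
    std::vector<int> recS, recN;
    if (recordEvery > 0) {
        recS.reserve(nSteps / recordEvery + 1);
        recN.reserve(nSteps / recordEvery + 1);
    }
    std::vector<double> rtStamps;

    for (int step = 1; step <= nSteps; ++step) {
        // ---- choose sequence, move, position, symbol -------------------
        bool moveQuery;
        if (mode == 1) moveQuery = false;
        else moveQuery = unif_rand() < 0.5;
        int L = moveQuery ? LQ : LS;
        double u = unif_rand();
        int kind = (u < 0.5) ? SUBSTITUTE : 1 + (int)(unif_rand() * 4.0);
        if (kind > 4) kind = 4;
        int pos = 1 + (int)(unif_rand() * L);
        if (pos > L) pos = L;
        bool uniformSym = (mode == 2 && moveQuery);
        int sym = uniformSym ? (int)(unif_rand() * nsym) : draw_from_cum(cum);
        if (sym >= nsym) sym = nsym - 1;

        // ---- build candidate, evaluate score/class/probability ---------
        int removed = 0;
        int s2, n2 = n;
        double logQ2 = logQ, dlogNull, dlog;
        if (moveQuery) {
            apply_move_buf(x, cand, kind, pos, sym, removed);
            s2 = sw_score_vec(cand, y, mdef, mreg, xregion, openCost, extCost);
            if (mode == 2) {
                logQ2 = forward_logprob(cand, logEmis, logTrans, logInit,
                                        fwdPrev, fwdCur);
                n2 = viterbi_class(cand, logEmis, logTrans, logInit, isCore);
                dlog = logQ2 - logQ; // uniform proposal: ratio 1
                dlogNull = logQ2 - logQ;
            } else {
                dlog = 0.0; // f-proposal cancels the null ratio
                dlogNull = logFreqs[sym] - logFreqs[removed];
            }
        } else {
            apply_move_buf(y, cand, kind, pos, sym, removed);
            s2 = sw_score_vec(x, cand, mdef, mreg, xregion, openCost, extCost);
            dlog = 0.0;
            dlogNull = logFreqs[sym] - logFreqs[removed];
        }

        // ---- accept / reject -------------------------------------------
        bool ok = (s2 >= smin && s2 <= smax && n2 >= nmin && n2 <= nmax);
        if (ok) {
            dlog += logW(s2 - smin, n2 - nmin) - logW(s - smin, n - nmin);
            if (dlog >= 0.0 || std::log(unif_rand()) < dlog) {
                if (moveQuery) { x = cand; logQ = logQ2; }
                else y = cand;
                s = s2;
                n = n2;
                logNull += dlogNull;
                ++accepted;
            }
        }

        // ---- flat-histogram bookkeeping on the resulting state ---------
        H(s - smin, n - nmin) += 1.0;
        if (logPhi > 0.0) logW(s - smin, n - nmin) -= logPhi;

        if (recordEvery > 0 && step % recordEvery == 0) {
            recS.push_back(s);
            recN.push_back(n);
        }

        // ---- round-trip tracking ---------------------------------------
        if (rtPhase == 0) {
            if (s == smin) rtPhase = 1;
        } else if (rtPhase == 1) {
            if (s == smax) rtPhase = 2;
        } else {
            if (s == smin) {
                rtPhase = 1;
                rtCount += 1.0;
                rtStamps.push_back(stepOffset + step);
            }
        }
    }

    return List::create(
        _["x"] = wrap(x), _["y"] = wrap(y), _["score"] = s, _["n_tm"] = n,
        _["log_query"] = logQ, _["log_null"] = logNull,
        _["accepted"] = (double)accepted, _["steps"] = (double)nSteps,
        _["rec_s"] = wrap(recS), _["rec_n"] = wrap(recN),
        _["rt_phase"] = rtPhase, _["rt_count"] = rtCount,
        _["rt_stamps"] = wrap(rtStamps));
}
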