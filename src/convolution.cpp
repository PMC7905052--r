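#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Per-slide similarity between the shorter row s (length L) and an aligned
// window w of the longer row. metric: 0 cosine, 1 euclidean, 2 pearson.
// Degenerate windows follow fixed conventions so every score lies in [0,1]:
// cosine with a zero vector is 1 iff both are zero; euclidean distance is
// scaled by sqrt(L), the maximum distance between binary vectors of length L;
// pearson with a zero-variance vector is 1 iff the windows are identical,
// and negative correlations clamp to 0.
static double slide_score(const double* s, const double* w, int L, int metric) {
    if (metric == 0) {  // cosine
        double dot = 0.0, ns = 0.0, nw = 0.0;
        for (int i = 0; i < L; ++i) {
            dot += s[i] * w[i];
            ns  += s[i] * s[i];
            nw  += w[i] * w[i];
        }
        if (ns == 0.0 && nw == 0.0) return 1.0;
        if (ns == 0.0 || nw == 0.0) return 0.0;
        double v = dot / std::sqrt(ns * nw);
        if (v < 0.0) v = 0.0;
        if (v > 1.0) v = 1.0;
        return v;
    } else if (metric == 1) {  // euclidean
        double ss = 0.0;
        for (int i = 0; i < L; ++i) {
            double d = s[i] - w[i];
            ss += d * d;
        }
        double v = 1.0 - std::sqrt(ss) / std::sqrt((double) L);
        if (v < 0.0) v = 0.0;
        return v;
    } else {  // pearson
        double ms = 0.0, mw = 0.0;
        for (int i = 0; i < L; ++i) { ms += s[i]; mw += w[i]; }
        ms /= L; mw /= L;
        double vs = 0.0, vw = 0.0, cov = 0.0;
        bool identical = true;
        for (int i = 0; i < L; ++i) {
            double ds = s[i] - ms, dw = w[i] - mw;
            vs += ds * ds; vw += dw * dw; cov += ds * dw;
            if (s[i] != w[i]) identical = false;
        }
        if (vs == 0.0 || vw == 0.0) return identical ? 1.0 : 0.0;
        double v = cov / std::sqrt(vs * vw);
        if (v < 0.0) v = 0.0;
        if (v > 1.0) v = 1.0;
        return v;
    }
}

// All nc = |lenA - lenB| + 1 slide scores of the shorter row over the longer.
// [[Rcpp::export(name = ".rowConvolutionCpp")]]
List row_convolution_cpp(NumericVector rowA, NumericVector rowB, int metric) {
    int la = rowA.size(), lb = rowB.size();
    if (la == 0 || lb == 0) stop("rows must be non-empty");
    const double* s;
    const double* g;
    int L, M;
    if (la <= lb) { s = REAL(rowA); L = la; g = REAL(rowB); M = lb; }
    else          { s = REAL(rowB); L = lb; g = REAL(rowA); M = la; }
    int nc = M - L + 1;
    NumericVector scores(nc);
    double best = 0.0;
    for (int off = 0; off < nc; ++off) {
        double v = slide_score(s, g + off, L, metric);
        scores[off] = v;
        if (off == 0 || v > best) best = v;
    }
    return List::create(_["nc"] = nc, _["scores"] = scores, _["best"] = best);
}

static double conv_best(const double* a, int la, const double* b, int lb,
                        int metric) {
    const double* s; const double* g; int L, M;
    if (la <= lb) { s = a; L = la; g = b; M = lb; }
    else          { s = b; L = lb; g = a; M = la; }
    int nc = M - L + 1;
    double best = 0.0;
    for (int off = 0; off < nc; ++off) {
        double v = slide_score(s, g + off, L, metric);
        if (off == 0 || v > best) best = v;
    }
    return best;
}

// One direction of the vectorial subgraph similarity: for every row k of A,
// the best convolution score against any row of B; returns the mean over k.
// [[Rcpp::export(name = ".vectorialDirectedCpp")]]
double vectorial_directed_cpp(NumericMatrix A, NumericMatrix B, int metric) {
    int na = A.nrow(), nb = B.nrow();
    if (na == 0 || nb == 0) stop("adjacency matrices must be non-empty");
    // copy rows to contiguous buffers (Rcpp matrices are column-major)
    std::vector<double> ra(na * A.ncol()), rb(nb * B.ncol());
    int ca = A.ncol(), cb = B.ncol();
    for (int k = 0; k < na; ++k)
        for (int j = 0; j < ca; ++j) ra[k * ca + j] = A(k, j);
    for (int l = 0; l < nb; ++l)
        for (int j = 0; j < cb; ++j) rb[l * cb + j] = B(l, j);
    double acc = 0.0;
    for (int k = 0; k < na; ++k) {
        double best = 0.0;
        for (int l = 0; l < nb; ++l) {
            double v = conv_best(&ra[k * ca], ca, &rb[l * cb], cb, metric);
            if (l == 0 || v > best) best = v;
            if (best >= 1.0) break;
        }
        acc += best;
    }
    return acc / na;
}
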