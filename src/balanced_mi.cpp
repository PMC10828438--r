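#include <Rcpp.h>
#include <algorithm>
#include <vector>
#include <cmath>

using namespace Rcpp;

// Type-7 (linear interpolation) quantile of a sorted vector.
static inline double quantile7(const std::vector<double>& s, double p) {
    const int n = (int)s.size();
    double h = (n - 1) * p;
    int lo = (int)std::floor(h);
    double f = h - lo;
    if (lo + 1 >= n) return s[n - 1];
    return s[lo] + f * (s[lo + 1] - s[lo]);
}

// Averaged class-balanced mutual information per protein.
//
// values:  proteins x samples matrix (complete).
// cls:     1-based class code per sample (1..n_classes).
// batches: n_sel x n_batches matrix of 1-based sample indices; each column
//          is one balanced batch.
// Per batch and protein, values are tercile-discretized within the batch
// (value <= q1/3 -> L, <= q2/3 -> M, else H; constant vectors collapse to
// L) and the plug-in MI (base 2, 0 log 0 = 0) with the class label is
// accumulated. Returns the per-protein mean over batches.
// [[Rcpp::export]]
NumericVector cpp_balanced_mi(NumericMatrix values, IntegerVector cls,
                              IntegerMatrix batches, int n_classes) {
    const int n_prot = values.nrow();
    const int n_sel = batches.nrow();
    const int n_batch = batches.ncol();
    if (n_sel < 3) stop("batches must contain >= 3 samples");
    NumericVector out(n_prot);
    std::vector<double> v(n_sel), s(n_sel);
    std::vector<int> cb(n_sel);
    std::vector<double> joint(3 * n_classes), px(n_classes), py(3);
    const double ln2 = std::log(2.0);

    for (int b = 0; b < n_batch; ++b) {
        for (int i = 0; i < n_sel; ++i) {
            int si = batches(i, b) - 1;
            if (si < 0 || si >= values.ncol())
                stop("batch index out of range");
            cb[i] = cls[si] - 1;
        }
        for (int p = 0; p < n_prot; ++p) {
            for (int i = 0; i < n_sel; ++i) v[i] = values(p, batches(i, b) - 1);
            s = v;
            std::sort(s.begin(), s.end());
            double q1 = quantile7(s, 1.0 / 3.0);
            double q2 = quantile7(s, 2.0 / 3.0);
            std::fill(joint.begin(), joint.end(), 0.0);
            std::fill(px.begin(), px.end(), 0.0);
            std::fill(py.begin(), py.end(), 0.0);
            for (int i = 0; i < n_sel; ++i) {
                int cat = v[i] <= q1 ? 0 : (v[i] <= q2 ? 1 : 2);
                joint[cb[i] * 3 + cat] += 1.0;
                px[cb[i]] += 1.0;
                py[cat] += 1.0;
            }
            double mi = 0.0;
            for (int x = 0; x < n_classes; ++x) {
                if (px[x] == 0.0) continue;
                for (int y = 0; y < 3; ++y) {
                    double j = joint[x * 3 + y];
                    if (j > 0.0)
                        mi += (j / n_sel) *
                              std::log(j * n_sel / (px[x] * py[y])) / ln2;
                }
            }
            out[p] += mi;
        }
    }
    for (int p = 0; p < n_prot; ++p) out[p] /= n_batch;
    return out;
}
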