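#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

// Adaptive-partitioning mutual information on rank-transformed data.
// A cell of the rank plane is split into quadrants at the midpoints of its
// rank ranges while a chi-square statistic over the four quadrant counts
// exceeds `crit` (default df=3, alpha=0.05 -> 7.815). The MI contribution of
// a terminal cell is (n_c/N) * ln(n_c * N / (w_x * w_y)) where w_x, w_y are
// the marginal rank widths of the cell (marginals are uniform after ranking).

static void mi_recurse(const std::vector<int>& xr, const std::vector<int>& yr,
                       std::vector<int>& idx,
                       int x1, int x2, int y1, int y2,
                       double crit, int N, double& mi) {
    const int nc = (int) idx.size();
    if (nc == 0) return;
    const double wx = (double) (x2 - x1 + 1);
    const double wy = (double) (y2 - y1 + 1);
    if (nc >= 8 && x2 > x1 && y2 > y1) {
        const int xm = (x1 + x2) / 2;
        const int ym = (y1 + y2) / 2;
        std::vector<int> q0, q1, q2, q3;
        for (int i : idx) {
            if (xr[i] <= xm) {
                if (yr[i] <= ym) q0.push_back(i); else q2.push_back(i);
            } else {
                if (yr[i] <= ym) q1.push_back(i); else q3.push_back(i);
            }
        }
        const double e = nc / 4.0;
        double chi2 = 0.0;
        const double d0 = q0.size() - e, d1 = q1.size() - e,
                     d2 = q2.size() - e, d3 = q3.size() - e;
        chi2 = (d0 * d0 + d1 * d1 + d2 * d2 + d3 * d3) / e;
        if (chi2 > crit) {
            mi_recurse(xr, yr, q0, x1, xm, y1, ym, crit, N, mi);
            mi_recurse(xr, yr, q1, xm + 1, x2, y1, ym, crit, N, mi);
            mi_recurse(xr, yr, q2, x1, xm, ym + 1, y2, crit, N, mi);
            mi_recurse(xr, yr, q3, xm + 1, x2, ym + 1, y2, crit, N, mi);
            return;
        }
    }
    mi += ((double) nc / N) * std::log((double) nc * N / (wx * wy));
}

// [[Rcpp::export]]
double mi_adaptive_cpp(IntegerVector xrank, IntegerVector yrank, double crit) {
    const int n = xrank.size();
    if (n != yrank.size()) stop("rank vectors differ in length");
    std::vector<int> xr(xrank.begin(), xrank.end());
    std::vector<int> yr(yrank.begin(), yrank.end());
    std::vector<int> idx(n);
    for (int i = 0; i < n; ++i) idx[i] = i;
    double mi = 0.0;
    mi_recurse(xr, yr, idx, 1, n, 1, n, crit, n, mi);
    return mi < 0.0 ? 0.0 : mi;
}

// Batch MI over a list of row pairs of a gene x sample rank matrix.
// `ranks` holds, per gene (row), the sample ranks 1..n. `ia`, `ib` are
// 1-based row indices of equal length.
// [[Rcpp::export]]
NumericVector mi_pairs_cpp(IntegerMatrix ranks, IntegerVector ia,
                           IntegerVector ib, double crit) {
    const int n = ranks.ncol();
    const int npair = ia.size();
    if (npair != ib.size()) stop("pair index vectors differ in length");
    NumericVector out(npair);
    std::vector<int> xr(n), yr(n), idx(n);
    for (int p = 0; p < npair; ++p) {
        const int a = ia[p] - 1, b = ib[p] - 1;
        for (int j = 0; j < n; ++j) {
            xr[j] = ranks(a, j);
            yr[j] = ranks(b, j);
            idx[j] = j;
        }
        double mi = 0.0;
        mi_recurse(xr, yr, idx, 1, n, 1, n, crit, n, mi);
        out[p] = mi < 0.0 ? 0.0 : mi;
    }
    return out;
}
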