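#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

// Plug-in mutual information (nats) from 1-based bin codes.
// Cells with zero joint count contribute nothing.
static double mi_from_codes(const int* xi, const int* yi, int n, int nx, int ny) {
    std::vector<int> jc(nx * ny, 0), mx(nx, 0), my(ny, 0);
    for (int k = 0; k < n; ++k) {
        int i = xi[k] - 1, j = yi[k] - 1;
        jc[i * ny + j]++;
        mx[i]++;
        my[j]++;
    }
    double mi = 0.0, N = (double)n;
    for (int i = 0; i < nx; ++i) {
        if (mx[i] == 0) continue;
        for (int j = 0; j < ny; ++j) {
            int nij = jc[i * ny + j];
            if (nij == 0) continue;
            mi += (nij / N) * std::log((nij * N) / ((double)mx[i] * (double)my[j]));
        }
    }
    return mi > 0.0 ? mi : 0.0;  // clamp tiny negative rounding
}

// [[Rcpp::export]]
double cpp_mi_nats(IntegerVector xi, IntegerVector yi, int nx, int ny) {
    if (xi.size() != yi.size()) stop("length mismatch");
    return mi_from_codes(xi.begin(), yi.begin(), xi.size(), nx, ny);
}

// Fisher-Yates shuffle driven by R's RNG stream (deterministic under set.seed).
static void shuffle_int(std::vector<int>& v) {
    int n = (int)v.size();
    for (int i = n - 1; i > 0; --i) {
        int j = (int)std::floor(unif_rand() * (i + 1));
        if (j > i) j = i;
        std::swap(v[i], v[j]);
    }
}

// Number of permuted MI values >= the observed MI (one-tailed).
// [[Rcpp::export]]
int cpp_perm_count_mi(IntegerVector xi, IntegerVector yi, int nx, int ny, int n_perm) {
    int n = xi.size();
    if (n != yi.size()) stop("length mismatch");
    double obs = mi_from_codes(xi.begin(), yi.begin(), n, nx, ny);
    std::vector<int> yp(yi.begin(), yi.end());
    int count = 0;
    for (int p = 0; p < n_perm; ++p) {
        shuffle_int(yp);
        if (mi_from_codes(xi.begin(), yp.data(), n, nx, ny) >= obs) count++;
    }
    return count;
}

// Number of permuted |r| >= observed |r| (two-tailed Pearson).
// Means and variances are permutation-invariant, so only the cross term
// sum(x * y_perm) varies; comparison done on |centered cross products|.
// [[Rcpp::export]]
int cpp_perm_count_pearson(NumericVector x, NumericVector y, int n_perm) {
    int n = x.size();
    if (n != y.size()) stop("length mismatch");
    double sx = 0, sy = 0;
    for (int k = 0; k < n; ++k) { sx += x[k]; sy += y[k]; }
    double mx = sx / n, my = sy / n;
    double obs = 0;
    for (int k = 0; k < n; ++k) obs += x[k] * y[k];
    obs = std::fabs(obs - n * mx * my);
    std::vector<double> yp(y.begin(), y.end());
    std::vector<int> idx(n);
    for (int k = 0; k < n; ++k) idx[k] = k;
    int count = 0;
    for (int p = 0; p < n_perm; ++p) {
        shuffle_int(idx);
        double s = 0;
        for (int k = 0; k < n; ++k) s += x[k] * yp[idx[k]];
        if (std::fabs(s - n * mx * my) >= obs) count++;
    }
    return count;
}
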