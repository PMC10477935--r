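#include <Rcpp.h>
using namespace Rcpp;

// Fused in-place Adam update: applies the (optionally clipped) gradient to
// parameters and first/second moment buffers in a single pass, avoiding the
// temporary allocations an R-level update would make. The caller guarantees
// exclusive ownership of w, m and v.
// [[Rcpp::export(".adamUpdateCpp")]]
void adamUpdateCpp(NumericVector w, NumericVector m, NumericVector v,
                   NumericVector g, double gscale, double beta1,
                   double beta2, double step, double eps) {
    R_xlen_t n = w.size();
    for (R_xlen_t i = 0; i < n; ++i) {
        double gi = g[i] * gscale;
        double mi = beta1 * m[i] + (1.0 - beta1) * gi;
        double vi = beta2 * v[i] + (1.0 - beta2) * gi * gi;
        m[i] = mi;
        v[i] = vi;
        w[i] -= step * mi / (std::sqrt(vi) + eps);
    }
}

// Squared sum of a numeric vector (for the global gradient-norm clip).
// [[Rcpp::export(".sumSquaresCpp")]]
double sumSquaresCpp(NumericVector x) {
    double s = 0.0;
    R_xlen_t n = x.size();
    for (R_xlen_t i = 0; i < n; ++i) s += x[i] * x[i];
    return s;
}

// In-place X = leakyrelu(X + b) over columns; b recycled per column.
// [[Rcpp::export(".addBiasLreluCpp")]]
void addBiasLreluCpp(NumericMatrix X, NumericVector b, double slope) {
    R_xlen_t nr = X.nrow(), nc = X.ncol();
    for (R_xlen_t j = 0; j < nc; ++j) {
        double bj = b[j];
        double *col = &X(0, j);
        for (R_xlen_t i = 0; i < nr; ++i) {
            double x = col[i] + bj;
            col[i] = x > 0 ? x : slope * x;
        }
    }
}

// In-place X = X + b over columns.
// [[Rcpp::export(".addBiasCpp")]]
void addBiasCpp(NumericMatrix X, NumericVector b) {
    R_xlen_t nr = X.nrow(), nc = X.ncol();
    for (R_xlen_t j = 0; j < nc; ++j) {
        double bj = b[j];
        double *col = &X(0, j);
        for (R_xlen_t i = 0; i < nr; ++i) col[i] += bj;
    }
}

// In-place dH *= lrelu'(pre-activation), using the post-activation H
// (same sign as the pre-activation; derivative at 0 takes the slope).
// [[Rcpp::export(".mulLreluGradCpp")]]
void mulLreluGradCpp(NumericVector dH, NumericVector H, double slope) {
    R_xlen_t n = dH.size();
    for (R_xlen_t i = 0; i < n; ++i)
        if (!(H[i] > 0)) dH[i] *= slope;
}

// Sum of numerically stable logits-form binary cross-entropies.
// [[Rcpp::export(".bceSumCpp")]]
double bceSumCpp(NumericVector x, NumericVector y) {
    R_xlen_t n = x.size();
    double s = 0.0;
    for (R_xlen_t i = 0; i < n; ++i) {
        double xi = x[i];
        double mx = xi > 0 ? xi : 0.0;
        double ax = xi > 0 ? xi : -xi;
        s += mx - xi * y[i] + std::log1p(std::exp(-ax));
    }
    return s;
}

// In-place O = scale * (sigmoid(O) - Y): the BCE gradient w.r.t. logits.
// [[Rcpp::export(".dLogitsCpp")]]
void dLogitsCpp(NumericVector O, NumericVector Y, double scale) {
    R_xlen_t n = O.size();
    for (R_xlen_t i = 0; i < n; ++i)
        O[i] = scale * (1.0 / (1.0 + std::exp(-O[i])) - Y[i]);
}
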