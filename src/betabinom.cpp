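#include <Rcpp.h>
using namespace Rcpp;

// log beta-binomial pmf with shape parameters (s*p, s*(1-p)), theta
// integrated out analytically. Returns -Inf outside the valid domain
// 0 < p < 1 (an invalid proposal, never silently clipped).
static inline double bb_term(double y, double n, double p, double s,
                             double lch) {
    if (!(p > 0.0 && p < 1.0) || !(s > 0.0))
        return R_NegInf;
    double a = s * p, b = s * (1.0 - p);
    return lch + Rf_lbeta(y + a, n - y + b) - Rf_lbeta(a, b);
}

// [[Rcpp::export]]
NumericVector bb_logpmf_cpp(NumericVector y, double n, NumericVector cm,
                            double s) {
    R_xlen_t L = y.size();
    if (cm.size() != L)
        stop("y and c*m must have equal length");
    NumericVector out(L);
    for (R_xlen_t l = 0; l < L; ++l)
        out[l] = bb_term(y[l], n, cm[l], s, Rf_lchoose(n, y[l]));
    return out;
}

// L x K matrix of log emission probabilities: entry (l, k) is the
// beta-binomial log pmf of count y[l] out of n at bias m[l] under
// copy number state value c[k] and inverse dispersion s.
// [[Rcpp::export]]
NumericMatrix emission_matrix_cpp(NumericVector y, double n, NumericVector m,
                                  NumericVector c, double s) {
    R_xlen_t L = y.size(), K = c.size();
    if (m.size() != L)
        stop("y and m must have equal length");
    NumericMatrix E(L, K);
    std::vector<double> lch(L);
    for (R_xlen_t l = 0; l < L; ++l)
        lch[l] = Rf_lchoose(n, y[l]);
    for (R_xlen_t k = 0; k < K; ++k)
        for (R_xlen_t l = 0; l < L; ++l)
            E(l, k) = bb_term(y[l], n, c[k] * m[l], s, lch[l]);
    return E;
}
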