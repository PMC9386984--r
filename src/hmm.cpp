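#include <Rcpp.h>
using namespace Rcpp;

// Joint draw of a hidden state path from its conditional posterior given
// log emissions, a (linear-scale) transition matrix and initial
// distribution: backward message pass followed by forward sampling.
// Emissions are exponentiated after a per-locus max shift and the
// backward messages renormalised at every step, so the recursion runs in
// scaled linear space without under/overflow. Returns 1-based states.
// [[Rcpp::export]]
IntegerVector fb_sample_cpp(NumericMatrix logE, NumericMatrix Pi,
                            NumericVector pi0) {
    int L = logE.nrow(), K = logE.ncol();
    if (Pi.nrow() != K || Pi.ncol() != K || pi0.size() != K)
        stop("dimension mismatch between emissions and transition model");

    // scaled emissions: exp(logE - rowmax)
    std::vector<double> E((size_t)L * K);
    for (int l = 0; l < L; ++l) {
        double mx = R_NegInf;
        for (int k = 0; k < K; ++k)
            if (logE(l, k) > mx) mx = logE(l, k);
        if (mx == R_NegInf)
            stop("all states have zero emission probability at locus %d",
                 l + 1);
        for (int k = 0; k < K; ++k)
            E[(size_t)l * K + k] = std::exp(logE(l, k) - mx);
    }

    // backward messages B(l, u) proportional to p(y_{l+1:L} | z_l = u)
    std::vector<double> B((size_t)L * K);
    for (int u = 0; u < K; ++u)
        B[(size_t)(L - 1) * K + u] = 1.0;
    std::vector<double> tmp(K);
    for (int l = L - 2; l >= 0; --l) {
        const double *En = &E[(size_t)(l + 1) * K];
        const double *Bn = &B[(size_t)(l + 1) * K];
        double *Bl = &B[(size_t)l * K];
        for (int v = 0; v < K; ++v)
            tmp[v] = En[v] * Bn[v];
        double mx = 0.0;
        for (int u = 0; u < K; ++u) {
            double acc = 0.0;
            for (int v = 0; v < K; ++v)
                acc += Pi(u, v) * tmp[v];
            Bl[u] = acc;
            if (acc > mx) mx = acc;
        }
        if (mx <= 0.0)
            stop("all states have zero posterior probability at locus %d",
                 l + 1);
        for (int u = 0; u < K; ++u)
            Bl[u] /= mx;
    }

    IntegerVector z(L);
    std::vector<double> w(K);
    for (int l = 0; l < L; ++l) {
        double sum = 0.0;
        const double *El = &E[(size_t)l * K];
        const double *Bl = &B[(size_t)l * K];
        for (int u = 0; u < K; ++u) {
            double base = (l == 0) ? pi0[u] : Pi(z[l - 1] - 1, u);
            w[u] = base * El[u] * Bl[u];
            sum += w[u];
        }
        if (!(sum > 0.0))
            stop("all states have zero posterior probability at locus %d",
                 l + 1);
        double r = unif_rand() * sum, acc = 0.0;
        int pick = K - 1;
        for (int u = 0; u < K; ++u) {
            acc += w[u];
            if (r <= acc) { pick = u; break; }
        }
        z[l] = pick + 1;
    }
    return z;
}
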