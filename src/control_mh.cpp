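#include <Rcpp.h>
using namespace Rcpp;

static inline double bb_ll(double y, double n, double p, double s) {
    if (!(p > 0.0 && p < 1.0) || !(s > 0.0))
        return R_NegInf;
    double a = s * p, b = s * (1.0 - p);
    // lchoose(n, y) omitted: constant in (m, s), cancels in every MH ratio
    return Rf_lbeta(y + a, n - y + b) - Rf_lbeta(a, b);
}

// Metropolis-Hastings sampler for the control-panel model: per-locus bias
// m_l with independent Beta(phi_c, phi_d) priors (logit random walk) and
// per-control inverse dispersion s_k with a Gamma(shape, scale) prior
// (log random walk). RCN is fixed at 1 for controls. Step sizes adapt
// towards ~30% acceptance during burn-in and are frozen afterwards.
// [[Rcpp::export]]
List control_mh_cpp(NumericMatrix x, NumericVector nk, NumericVector m0,
                    NumericVector s0, double phi_c, double phi_d,
                    double psi_shape, double psi_scale, int iters, int burn,
                    int thin) {
    int L = x.nrow(), K = x.ncol();
    if (nk.size() != K || m0.size() != L || s0.size() != K)
        stop("dimension mismatch in control sampler inputs");
    if (burn >= iters)
        stop("burn-in must be smaller than the iteration count");

    std::vector<double> m(m0.begin(), m0.end());
    std::vector<double> s(s0.begin(), s0.end());

    // cached log-likelihood per (locus, control)
    NumericMatrix ll(L, K);
    for (int k = 0; k < K; ++k)
        for (int l = 0; l < L; ++l)
            ll(l, k) = bb_ll(x(l, k), nk[k], m[l], s[k]);

    std::vector<double> step_m(L, 0.3), step_s(K, 0.3);
    std::vector<int> acc_m(L, 0), acc_s(K, 0), try_m(L, 0), try_s(K, 0);
    std::vector<long> acc_m_tot(L, 0), acc_s_tot(K, 0);
    const double target = 0.30;
    const int adapt_every = 50;

    int stored = (iters - burn) / thin;
    NumericMatrix m_trace(stored, L), s_trace(stored, K);
    int row = 0;

    std::vector<double> prop(K);
    for (int it = 1; it <= iters; ++it) {
        if (it % 200 == 0) checkUserInterrupt();

        // per-locus bias updates
        for (int l = 0; l < L; ++l) {
            double ml = m[l];
            double lo = std::log(ml) - std::log1p(-ml);
            double lo2 = lo + step_m[l] * norm_rand();
            double m2 = 1.0 / (1.0 + std::exp(-lo2));
            if (m2 <= 0.0 || m2 >= 1.0) { ++try_m[l]; continue; }
            double d = 0.0;
            bool ok = true;
            for (int k = 0; k < K; ++k) {
                prop[k] = bb_ll(x(l, k), nk[k], m2, s[k]);
                if (prop[k] == R_NegInf) { ok = false; break; }
                d += prop[k] - ll(l, k);
            }
            ++try_m[l];
            if (!ok) continue;
            d += (phi_c - 1.0) * (std::log(m2) - std::log(ml)) +
                 (phi_d - 1.0) * (std::log1p(-m2) - std::log1p(-ml));
            // Jacobian of the logit transform
            d += std::log(m2) + std::log1p(-m2) - std::log(ml) - std::log1p(-ml);
            if (d >= 0.0 || unif_rand() < std::exp(d)) {
                m[l] = m2;
                for (int k = 0; k < K; ++k) ll(l, k) = prop[k];
                ++acc_m[l];
                ++acc_m_tot[l];
            }
        }

        // per-control dispersion updates
        for (int k = 0; k < K; ++k) {
            double sk = s[k];
            double s2 = sk * std::exp(step_s[k] * norm_rand());
            double d = 0.0;
            bool ok = true;
            std::vector<double> col(L);
            for (int l = 0; l < L; ++l) {
                col[l] = bb_ll(x(l, k), nk[k], m[l], s2);
                if (col[l] == R_NegInf) { ok = false; break; }
                d += col[l] - ll(l, k);
            }
            ++try_s[k];
            if (!ok) continue;
            d += (psi_shape - 1.0) * (std::log(s2) - std::log(sk)) -
                 (s2 - sk) / psi_scale;
            d += std::log(s2) - std::log(sk); // log-scale Jacobian
            if (d >= 0.0 || unif_rand() < std::exp(d)) {
                s[k] = s2;
                for (int l = 0; l < L; ++l) ll(l, k) = col[l];
                ++acc_s[k];
                ++acc_s_tot[k];
            }
        }

        // step-size adaptation, frozen after burn-in
        if (it <= burn && it % adapt_every == 0) {
            for (int l = 0; l < L; ++l) {
                double rate = try_m[l] ? (double)acc_m[l] / try_m[l] : target;
                step_m[l] = std::min(10.0,
                    std::max(1e-3, step_m[l] * std::exp(rate - target)));
                acc_m[l] = try_m[l] = 0;
            }
            for (int k = 0; k < K; ++k) {
                double rate = try_s[k] ? (double)acc_s[k] / try_s[k] : target;
                step_s[k] = std::min(10.0,
                    std::max(1e-3, step_s[k] * std::exp(rate - target)));
                acc_s[k] = try_s[k] = 0;
            }
        }

        if (it > burn && (it - burn) % thin == 0) {
            for (int l = 0; l < L; ++l) m_trace(row, l) = m[l];
            for (int k = 0; k < K; ++k) s_trace(row, k) = s[k];
            ++row;
        }
    }

    NumericVector ar_m(L), ar_s(K);
    for (int l = 0; l < L; ++l) ar_m[l] = (double)acc_m_tot[l] / iters;
    for (int k = 0; k < K; ++k) ar_s[k] = (double)acc_s_tot[k] / iters;
    return List::create(_["m"] = m_trace, _["s"] = s_trace,
                        _["accept_m"] = ar_m, _["accept_s"] = ar_s);
}
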