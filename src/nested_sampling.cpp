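#include <Rcpp.h>
#include <random>
#include <vector>
#include "models.h"

using namespace Rcpp;

// [[Rcpp::export]]
NumericVector eval_model_cpp(int code, NumericVector params, NumericVector times) {
    const int n = times.size();
    NumericVector out(n);
    for (int i = 0; i < n; ++i) out[i] = model_value(code, params.begin(), times[i]);
    return out;
}

static double gauss_loglik(const int code, const double *p,
                           const NumericVector &times, const NumericMatrix &y,
                           const double sd) {
    const int nt = times.size(), nr = y.nrow();
    const double inv2v = 1.0 / (2.0 * sd * sd);
    const double lnorm = -0.918938533204672741780329736406 - std::log(sd); // -0.5*log(2*pi) - log(sd)
    double ll = 0.0;
    for (int j = 0; j < nt; ++j) {
        const double m = model_value(code, p, times[j]);
        for (int r = 0; r < nr; ++r) {
            const double d = y(r, j) - m;
            ll += lnorm - d * d * inv2v;
        }
    }
    return ll;
}

// [[Rcpp::export]]
double loglik_cpp(int code, NumericVector params, NumericVector times,
                  NumericMatrix y, double sd) {
    return gauss_loglik(code, params.begin(), times, y, sd);
}

static inline double logaddexp(double a, double b) {
    if (a == R_NegInf) return b;
    if (b == R_NegInf) return a;
    return (a > b) ? a + std::log1p(std::exp(b - a)) : b + std::log1p(std::exp(a - b));
}

// Classic nested sampling (Skilling) with uniform box priors and a
// constrained random-walk replacement step with stochastic step-size
// adaptation. Returns log-evidence, its information-based uncertainty
// sqrt(H/n_live), and posterior moments of the parameters (plus the derived
// peak time td+ts for the peak model).
// [[Rcpp::export]]
List ns_run_cpp(int code, NumericVector lower, NumericVector upper,
                NumericVector times, NumericMatrix y, double sd,
                int n_live, int seed, int max_iter = 100000,
                int n_steps = 30, double stop_tol = 1e-3) {
    const int dim = lower.size();
    std::mt19937_64 rng(static_cast<uint64_t>(seed) * 0x9E3779B97F4A7C15ULL + 1ULL);
    std::uniform_real_distribution<double> unif(0.0, 1.0);

    std::vector<std::vector<double>> live(n_live, std::vector<double>(dim));
    std::vector<double> liveL(n_live);
    for (int i = 0; i < n_live; ++i) {
        for (int d = 0; d < dim; ++d)
            live[i][d] = lower[d] + (upper[d] - lower[d]) * unif(rng);
        liveL[i] = gauss_loglik(code, live[i].data(), times, y, sd);
    }

    std::vector<double> scale(dim);
    for (int d = 0; d < dim; ++d) scale[d] = 0.1 * (upper[d] - lower[d]);

    std::vector<double> dead_logwt;
    std::vector<double> dead_par; // row-major dim-strided
    std::vector<double> dead_logL;
    dead_logwt.reserve(4096);

    double logZ = R_NegInf, H = 0.0;
    const double log_shrink = 1.0 / n_live;          // -log of per-iteration X ratio
    const double log_wfac = std::log(std::expm1(log_shrink)); // log(e^{1/n}-1)
    int iter = 0;
    bool converged = false;

    while (iter < max_iter) {
        // worst live point
        int worst = 0;
        double maxL = liveL[0];
        for (int i = 1; i < n_live; ++i) {
            if (liveL[i] < liveL[worst]) worst = i;
            if (liveL[i] > maxL) maxL = liveL[i];
        }
        const double Lstar = liveL[worst];
        ++iter;
        // X_{i-1} - X_i = e^{-i/n} (e^{1/n} - 1)
        const double logwt = Lstar - iter * log_shrink + log_wfac;

        const double logZnew = logaddexp(logZ, logwt);
        if (R_FINITE(logwt)) {
            H = std::exp(logwt - logZnew) * Lstar +
                std::exp(logZ - logZnew) * (H + logZ) - logZnew;
            if (!R_FINITE(H)) H = 0.0;
        }
        logZ = logZnew;

        dead_logwt.push_back(logwt);
        dead_logL.push_back(Lstar);
        for (int d = 0; d < dim; ++d) dead_par.push_back(live[worst][d]);

        // termination: remaining evidence bound maxL * X_i < stop_tol * Z
        if (maxL - iter * log_shrink < logZ + std::log(stop_tol)) {
            converged = true;
            // replace not needed; loop exits below
        }

        // replace worst by a constrained walk from a random surviving point
        int start = worst;
        if (n_live > 1) {
            do {
                start = static_cast<int>(unif(rng) * n_live);
                if (start >= n_live) start = n_live - 1;
            } while (start == worst);
        }
        std::vector<double> cur = live[start];
        double curL = liveL[start];
        int acc = 0, rej = 0;
        std::vector<double> prop(dim);
        for (int s = 0; s < n_steps; ++s) {
            bool inbox = true;
            // alternate axis-aligned walk steps with differential-evolution
            // moves along the difference of two random live points, which
            // follow the correlated ridges of the constrained region
            if (dim > 1 && n_live >= 4 && unif(rng) < 0.5) {
                int a = static_cast<int>(unif(rng) * n_live) % n_live;
                int b = static_cast<int>(unif(rng) * n_live) % n_live;
                while (b == a) b = static_cast<int>(unif(rng) * n_live) % n_live;
                const double g = 0.4 + 1.2 * unif(rng);
                for (int d = 0; d < dim; ++d) {
                    prop[d] = cur[d] + g * (live[a][d] - live[b][d]);
                    if (prop[d] < lower[d] || prop[d] > upper[d]) inbox = false;
                }
            } else {
                for (int d = 0; d < dim; ++d) {
                    prop[d] = cur[d] + scale[d] * (2.0 * unif(rng) - 1.0);
                    if (prop[d] < lower[d] || prop[d] > upper[d]) inbox = false;
                }
            }
            if (inbox) {
                const double pl = gauss_loglik(code, prop.data(), times, y, sd);
                if (pl > Lstar) {
                    cur = prop;
                    curL = pl;
                    ++acc;
                } else ++rej;
            } else ++rej;
        }
        // stochastic adaptation toward ~50% acceptance (Sivia & Skilling)
        if (acc > rej) {
            const double f = std::exp(1.0 / std::max(acc, 1));
            for (int d = 0; d < dim; ++d)
                scale[d] = std::min(scale[d] * f, upper[d] - lower[d]);
        } else {
            const double f = std::exp(1.0 / std::max(rej, 1));
            for (int d = 0; d < dim; ++d) scale[d] /= f;
        }
        live[worst] = cur;
        liveL[worst] = curL;

        if (converged) break;
        if ((iter & 1023) == 0) Rcpp::checkUserInterrupt();
    }

    // final live-point contribution: each carries weight X_final / n_live
    const double log_Xfinal = -static_cast<double>(iter) * log_shrink;
    for (int i = 0; i < n_live; ++i) {
        const double logwt = liveL[i] + log_Xfinal - std::log(static_cast<double>(n_live));
        const double logZnew = logaddexp(logZ, logwt);
        if (R_FINITE(logwt)) {
            H = std::exp(logwt - logZnew) * liveL[i] +
                std::exp(logZ - logZnew) * (H + logZ) - logZnew;
            if (!R_FINITE(H)) H = 0.0;
        }
        logZ = logZnew;
        dead_logwt.push_back(logwt);
        dead_logL.push_back(liveL[i]);
        for (int d = 0; d < dim; ++d) dead_par.push_back(live[i][d]);
    }

    // posterior moments from the weighted samples
    const size_t ns = dead_logwt.size();
    NumericVector pmean(dim), psd(dim);
    double tp_mean = NA_REAL, tp_sd = NA_REAL;
    {
        std::vector<double> w(ns);
        double wsum = 0.0;
        for (size_t i = 0; i < ns; ++i) {
            w[i] = std::exp(dead_logwt[i] - logZ);
            wsum += w[i];
        }
        if (wsum > 0) {
            for (int d = 0; d < dim; ++d) {
                double m = 0.0;
                for (size_t i = 0; i < ns; ++i) m += w[i] * dead_par[i * dim + d];
                m /= wsum;
                double v = 0.0;
                for (size_t i = 0; i < ns; ++i) {
                    const double dd = dead_par[i * dim + d] - m;
                    v += w[i] * dd * dd;
                }
                pmean[d] = m;
                psd[d] = std::sqrt(std::max(v / wsum, 0.0));
            }
            if (code == 4) {
                double m = 0.0;
                for (size_t i = 0; i < ns; ++i)
                    m += w[i] * (dead_par[i * dim + 2] + dead_par[i * dim + 3]);
                m /= wsum;
                double v = 0.0;
                for (size_t i = 0; i < ns; ++i) {
                    const double dd = dead_par[i * dim + 2] + dead_par[i * dim + 3] - m;
                    v += w[i] * dd * dd;
                }
                tp_mean = m;
                tp_sd = std::sqrt(std::max(v / wsum, 0.0));
            }
        }
    }

    double logZ_err = std::sqrt(std::max(H, 0.0) / n_live);
    return List::create(_["logZ"] = logZ, _["logZ_err"] = logZ_err,
                        _["H"] = H, _["n_iter"] = iter,
                        _["converged"] = converged,
                        _["post_mean"] = pmean, _["post_sd"] = psd,
                        _["tp_mean"] = tp_mean, _["tp_sd"] = tp_sd);
}
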