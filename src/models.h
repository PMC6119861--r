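#ifndef PROMKIN_MODELS_H
#define PROMKIN_MODELS_H

#include <cmath>

// Model codes shared between the sampler and the R-level model specs:
//   0 constant (evidence-validation model)
//   1 linear        a + b*t
//   2 decay         base + amp * exp(-k*t)
//   3 dip           base - depth * (exp(-k*r*t) - exp(-k*t)) / peak_h
//   4 delayed peak  p1 | rise to p1+p2 at t_p = td+ts | exponential fall
inline double model_value(const int code, const double *p, const double t) {
    switch (code) {
    case 0:
        return p[0];
    case 1:
        return p[0] + p[1] * t;
    case 2:
        return p[0] + p[1] * std::exp(-p[2] * t);
    case 3: {
        // p = (base, depth, k, ratio); recovery rate k*ratio < decline rate k,
        // so the curve falls to base - depth and then recovers toward base.
        const double k = p[2], kr = p[2] * p[3];
        const double dk = k - kr;
        double h, hmax;
        if (dk > 1e-12 * k) {
            const double tstar = std::log(k / kr) / dk;
            hmax = std::exp(-kr * tstar) - std::exp(-k * tstar);
            h = std::exp(-kr * t) - std::exp(-k * t);
        } else {
            // ratio -> 1 limit: h(t) proportional to t*exp(-k*t), max at 1/k
            hmax = std::exp(-1.0) / k;
            h = t * std::exp(-k * t);
        }
        return p[0] - p[1] * h / hmax;
    }
    case 4: {
        // p = (p1, p2, td, ts, r_rise, r_fall)
        const double p1 = p[0], p2 = p[1], td = p[2], ts = p[3];
        const double r1 = p[4], r2 = p[5];
        if (t <= td) return p1;
        const double tp = td + ts;
        if (t <= tp) return p1 + p2 * std::expm1(r1 * (t - td)) / std::expm1(r1 * ts);
        return p1 + p2 * std::exp(-r2 * (t - tp));
    }
    }
    return NA_REAL;
}

#endif
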