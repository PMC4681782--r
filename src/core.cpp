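#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

static inline double gain_fun(double x, double gamma, double theta) {
    double y = x + theta;
    return (y > 0.0) ? std::pow(y, gamma) : 0.0;
}

// Fast normal deviates for the noise term: xoshiro256++ with Box-Muller,
// seeded from R's RNG stream so that set.seed() fully determines the
// trajectory. R's own norm_rand() would dominate the step cost at the
// required draw volume (V draws per step).
struct FastNormal {
    uint64_t s[4];
    bool have_spare = false;
    double spare = 0.0;

    static uint64_t splitmix64(uint64_t& x) {
        x += 0x9e3779b97f4a7c15ULL;
        uint64_t z = x;
        z = (z ^ (z >> 30)) * 0xbf58476d1ce4e5b9ULL;
        z = (z ^ (z >> 27)) * 0x94d049bb133111ebULL;
        return z ^ (z >> 31);
    }
    explicit FastNormal() {
        // 53-bit draws from R's stream -> full 256-bit state
        uint64_t seed = (uint64_t)(unif_rand() * 9007199254740992.0);
        seed ^= (uint64_t)(unif_rand() * 9007199254740992.0) << 11;
        for (int i = 0; i < 4; ++i) s[i] = splitmix64(seed);
    }
    static inline uint64_t rotl(uint64_t x, int k) {
        return (x << k) | (x >> (64 - k));
    }
    inline uint64_t next() {
        uint64_t result = rotl(s[0] + s[3], 23) + s[0];
        uint64_t t = s[1] << 17;
        s[2] ^= s[0]; s[3] ^= s[1]; s[1] ^= s[2]; s[0] ^= s[3];
        s[2] ^= t; s[3] = rotl(s[3], 45);
        return result;
    }
    inline double uniform() { // in (0, 1)
        return ((next() >> 11) + 0.5) * (1.0 / 9007199254740992.0);
    }
    inline double normal() {
        if (have_spare) {
            have_spare = false;
            return spare;
        }
        double u1 = uniform(), u2 = uniform();
        double rad = std::sqrt(-2.0 * std::log(u1));
        double ang = 2.0 * M_PI * u2;
        spare = rad * std::sin(ang);
        have_spare = true;
        return rad * std::cos(ang);
    }
};

// Population-reduced stochastic rate dynamics.
//
// State: currents c_v for V identical-code populations. The recurrent drive
//   sum_w Jt_vw S_w g(c_w)
// is evaluated through its exact low-rank decomposition in the overlaps:
//   drive_v = kappa * (sum_mu (v_mu - f) m_mu - phi(t) m0)
//           + J+ * sum_{mu<=P-1} v_mu muhat_{mu+1}
//           + J- * sum_{mu>=2}  v_mu muhat_{mu-1}
// with muhat_mu = sum_w w_mu S_w g(c_w), m_mu = muhat_mu - f m0,
// m0 = sum_w S_w g(c_w). This is O(V*P) per step instead of O(V^2).
//
// Euler-Maruyama: c += dt/tau * (-c + drive) + noise_sd_v * sqrt(dt)/tau * z.
// Noise uses R's RNG stream (set.seed-reproducible).
// [[Rcpp::export]]
List reduced_core(NumericMatrix vmat, NumericVector sv,
                  double f, double kappa, double j_plus, double j_minus,
                  double phi_mid, double phi_amp, double period,
                  double phase0,
                  double gamma, double theta,
                  double tau, double dt, int n_steps,
                  NumericVector noise_sd, NumericVector c_init,
                  IntegerVector record_steps, bool record_pops) {
    const int V = vmat.nrow(), P = vmat.ncol();
    const int n_rec = record_steps.size();
    std::vector<double> c(c_init.begin(), c_init.end());
    std::vector<double> s(V), muhat(P), m(P), b(P), femp(P);

    for (int p = 0; p < P; ++p) {
        double acc = 0.0;
        for (int v = 0; v < V; ++v) acc += vmat(v, p) * sv[v];
        femp[p] = acc;
    }

    // membership lists (CSR): the 0/1 code vectors are sparse (mean
    // cardinality ~ P f), so iterating member bits beats dense V x P loops
    std::vector<int> mem_off(V + 1, 0), mem_idx;
    mem_idx.reserve(V * (int)(P * 0.2 + 2));
    for (int v = 0; v < V; ++v) {
        for (int p = 0; p < P; ++p)
            if (vmat(v, p) > 0.0) mem_idx.push_back(p);
        mem_off[v + 1] = (int)mem_idx.size();
    }

    NumericVector times(n_rec), phis(n_rec), m0_rec(n_rec);
    NumericMatrix mem_rates(n_rec, P), overlaps(n_rec, P);
    NumericMatrix pop_curr(record_pops ? V : 1, record_pops ? n_rec : 1);

    const double omega = 2.0 * M_PI / period;
    const double euler = dt / tau;
    const double nscale = std::sqrt(dt) / tau;
    bool any_noise = false;
    for (int v = 0; v < V; ++v) if (noise_sd[v] > 0.0) any_noise = true;

    RNGScope scope;
    FastNormal rng;
    int rec_pos = 0;
    for (int k = 0; k <= n_steps; ++k) {
        // overlap bookkeeping for current state
        double m0 = 0.0;
        std::fill(muhat.begin(), muhat.end(), 0.0);
        for (int v = 0; v < V; ++v) {
            double r = gain_fun(c[v], gamma, theta);
            double sval = sv[v] * r;
            s[v] = sval;
            if (sval != 0.0) {
                m0 += sval;
                for (int j = mem_off[v]; j < mem_off[v + 1]; ++j)
                    muhat[mem_idx[j]] += sval;
            }
        }
        for (int p = 0; p < P; ++p) m[p] = muhat[p] - f * m0;
        double t = k * dt;
        double phi = phi_mid - phi_amp * std::cos(omega * t + phase0);

        if (rec_pos < n_rec && record_steps[rec_pos] == k) {
            double cmax = 0.0;
            bool bad = false;
            for (int v = 0; v < V; ++v) {
                if (!std::isfinite(c[v])) bad = true;
                else if (std::fabs(c[v]) > cmax) cmax = std::fabs(c[v]);
            }
            if (bad)
                stop("state diverged (non-finite current) at step %d; max finite |c| = %g",
                     k, cmax);
            times[rec_pos] = t;
            phis[rec_pos] = phi;
            m0_rec[rec_pos] = m0;
            for (int p = 0; p < P; ++p) {
                overlaps(rec_pos, p) = m[p];
                mem_rates(rec_pos, p) = femp[p] > 0.0 ? muhat[p] / femp[p]
                                                      : 0.0;
            }
            if (record_pops)
                for (int v = 0; v < V; ++v) pop_curr(v, rec_pos) = c[v];
            ++rec_pos;
        }
        if (k == n_steps) break;

        double msum = 0.0;
        for (int p = 0; p < P; ++p) msum += m[p];
        for (int p = 0; p < P; ++p) {
            double acc = kappa * m[p];
            if (p + 1 < P) acc += j_plus * muhat[p + 1];
            if (p > 0) acc += j_minus * muhat[p - 1];
            b[p] = acc;
        }
        const double base = -kappa * (f * msum + phi * m0);
        for (int v = 0; v < V; ++v) {
            double drive = base;
            for (int j = mem_off[v]; j < mem_off[v + 1]; ++j)
                drive += b[mem_idx[j]];
            c[v] += euler * (drive - c[v]);
        }
        if (any_noise)
            for (int v = 0; v < V; ++v)
                if (noise_sd[v] > 0.0)
                    c[v] += nscale * noise_sd[v] * rng.normal();
    }

    List out = List::create(
        _["times"] = times, _["phi"] = phis, _["m0"] = m0_rec,
        _["memory_rates"] = mem_rates, _["overlaps"] = overlaps,
        _["final_currents"] = NumericVector(c.begin(), c.end()));
    if (record_pops) out["pop_currents"] = pop_curr;
    return out;
}

// Full single-neuron stochastic rate dynamics (validation scale).
// `j0` must be the connectivity with the inhibition part set to phi = 0;
// the time-varying inhibition enters as -kappa * phi(t) * mean(r).
// [[Rcpp::export]]
List full_core(NumericMatrix j0, IntegerMatrix eta,
               double f, double kappa,
               double phi_mid, double phi_amp, double period, double phase0,
               double gamma, double theta,
               double tau, double dt, int n_steps,
               double noise_sd, NumericVector c_init,
               IntegerVector record_steps, bool record_neurons) {
    const int N = j0.nrow(), P = eta.ncol();
    const int n_rec = record_steps.size();
    std::vector<double> c(c_init.begin(), c_init.end());
    std::vector<double> r(N);
    std::vector<double> sizes(P);
    for (int p = 0; p < P; ++p) {
        double acc = 0.0;
        for (int i = 0; i < N; ++i) acc += eta(i, p);
        sizes[p] = acc;
    }

    NumericVector times(n_rec), phis(n_rec), m0_rec(n_rec);
    NumericMatrix mem_rates(n_rec, P), overlaps(n_rec, P);
    NumericMatrix curr(record_neurons ? N : 1, record_neurons ? n_rec : 1);

    const double omega = 2.0 * M_PI / period;
    const double euler = dt / tau;
    const double nscale = std::sqrt(dt) / tau;

    RNGScope scope;
    int rec_pos = 0;
    for (int k = 0; k <= n_steps; ++k) {
        double rsum = 0.0;
        for (int i = 0; i < N; ++i) {
            r[i] = gain_fun(c[i], gamma, theta);
            rsum += r[i];
        }
        double m0 = rsum / N;
        double t = k * dt;
        double phi = phi_mid - phi_amp * std::cos(omega * t + phase0);

        if (rec_pos < n_rec && record_steps[rec_pos] == k) {
            double cmax = 0.0;
            bool bad = false;
            for (int i = 0; i < N; ++i) {
                if (!std::isfinite(c[i])) bad = true;
                else if (std::fabs(c[i]) > cmax) cmax = std::fabs(c[i]);
            }
            if (bad)
                stop("state diverged (non-finite current) at step %d; max finite |c| = %g",
                     k, cmax);
            times[rec_pos] = t;
            phis[rec_pos] = phi;
            m0_rec[rec_pos] = m0;
            for (int p = 0; p < P; ++p) {
                double acc = 0.0;
                for (int i = 0; i < N; ++i) acc += eta(i, p) * r[i];
                mem_rates(rec_pos, p) = sizes[p] > 0.0 ? acc / sizes[p] : 0.0;
                overlaps(rec_pos, p) = acc / N - f * m0;
            }
            if (record_neurons)
                for (int i = 0; i < N; ++i) curr(i, rec_pos) = c[i];
            ++rec_pos;
        }
        if (k == n_steps) break;

        // j0 arrives transposed from R so that column i holds row i of J
        // (contiguous access); drive_i = sum_j J_ij r_j - kappa phi(t) m0.
        const double inhib = kappa * phi * m0;
        for (int i = 0; i < N; ++i) {
            const double* jcol = &j0(0, i);
            double acc = 0.0;
            for (int j = 0; j < N; ++j) acc += jcol[j] * r[j];
            c[i] += euler * (acc - inhib - c[i]);
        }
        if (noise_sd > 0.0)
            for (int i = 0; i < N; ++i)
                c[i] += nscale * noise_sd * norm_rand();
    }

    List out = List::create(
        _["times"] = times, _["phi"] = phis, _["m0"] = m0_rec,
        _["memory_rates"] = mem_rates, _["overlaps"] = overlaps,
        _["final_currents"] = NumericVector(c.begin(), c.end()));
    if (record_neurons) out["currents"] = curr;
    return out;
}
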