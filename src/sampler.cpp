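// Hierarchical Bayesian sampler for the constrained diffusion-model lattice.
//
// Subject-level cell parameters are updated by adaptive random-walk
// Metropolis on transformed scales (log for boundary separation and
// non-decision time, identity for drift). Group-level means and variances
// (per design cell, normal population model on the transformed scale) are
// updated by conjugate Gibbs steps: normal for the mean, inverse-gamma for
// the variance.
//
// The likelihood is the 5%-contamination Wiener mixture; contaminant trials
// are uniform over the subject's observed RT range with chance responding.
//
// One call runs one chain; chains differ by initial values and R's RNG
// stream (seed on the R side).

#include <Rcpp.h>
using namespace Rcpp;

double wfpt_density_one(double t, double a, double v, double w, bool upper,
                        double err);

// [[Rcpp::export]]
List cpp_hddm_chain(NumericVector rt, IntegerVector upper,
                    IntegerVector combo_off,   // ncombo+1 CSR offsets into rt
                    IntegerVector combo_subj,  // 0-based subject of combo
                    IntegerVector combo_ia, IntegerVector combo_it0,
                    IntegerVector combo_iv,    // 0-based param slot (0..P-1)
                    int n_subj, int P,
                    IntegerVector ptype,       // 0 = a, 1 = t0, 2 = v
                    NumericVector cont_lo, NumericVector cont_hi,
                    double picont,
                    NumericMatrix eta_init,    // n_subj x P, transformed
                    int n_keep, int n_burn, int thin,
                    bool hierarchical,
                    NumericVector prior_m,     // by type: flat-prior mean
                    NumericVector prior_s,     // by type: flat-prior sd
                    NumericVector m0, NumericVector s0,  // group-mean hyper
                    double alpha0, double beta0,         // sigma^2 IG prior
                    double err) {
    int ncombo = combo_subj.size();

    // affected-combo lists per (subject, param slot)
    std::vector< std::vector<int> > aff((size_t)n_subj * P);
    for (int c = 0; c < ncombo; c++) {
        int j = combo_subj[c];
        aff[(size_t)j * P + combo_ia[c]].push_back(c);
        aff[(size_t)j * P + combo_it0[c]].push_back(c);
        aff[(size_t)j * P + combo_iv[c]].push_back(c);
    }

    std::vector<double> eta((size_t)n_subj * P);
    for (int j = 0; j < n_subj; j++)
        for (int p = 0; p < P; p++) eta[(size_t)j * P + p] = eta_init(j, p);

    std::vector<double> mu(P), sigma(P);
    for (int p = 0; p < P; p++) {
        // initialize group level at the subject mean / sd
        double m = 0.0;
        for (int j = 0; j < n_subj; j++) m += eta[(size_t)j * P + p];
        m /= n_subj;
        double ss = 0.0;
        for (int j = 0; j < n_subj; j++) {
            double d = eta[(size_t)j * P + p] - m;
            ss += d * d;
        }
        mu[p] = m;
        sigma[p] = std::sqrt(ss / std::max(1, n_subj - 1) + 0.01);
    }

    // combo log-likelihood given the current parameters of its subject
    std::vector<double> combo_ll(ncombo);
    std::vector<double> u_half(n_subj);
    for (int j = 0; j < n_subj; j++) {
        double width = cont_hi[j] - cont_lo[j];
        u_half[j] = (width > 0) ? 0.5 / width : 0.0;
    }

    // evaluate loglik of one combo with explicit parameter values
    auto eval_combo = [&](int c, double a, double v, double t0) {
        int j = combo_subj[c];
        double cterm = picont * u_half[j];
        double ll = 0.0;
        for (int i = combo_off[c]; i < combo_off[c + 1]; i++) {
            double td = rt[i] - t0;
            double dens = (td > 0.0)
                ? wfpt_density_one(td, a, v, 0.5, upper[i] == 1, err)
                : 0.0;
            double term = (1.0 - picont) * dens + cterm;
            if (term <= 0.0) return R_NegInf;
            ll += std::log(term);
        }
        return ll;
    };
    auto combo_par = [&](int c, int slot_override, double value, double* a,
                         double* v, double* t0) {
        int j = combo_subj[c];
        double ea = eta[(size_t)j * P + combo_ia[c]];
        double et = eta[(size_t)j * P + combo_it0[c]];
        double ev = eta[(size_t)j * P + combo_iv[c]];
        if (slot_override == combo_ia[c]) ea = value;
        if (slot_override == combo_it0[c]) et = value;
        if (slot_override == combo_iv[c]) ev = value;
        *a = std::exp(ea);
        *t0 = std::exp(et);
        *v = ev;
    };
    for (int c = 0; c < ncombo; c++) {
        double a, v, t0;
        combo_par(c, -1, 0.0, &a, &v, &t0);
        combo_ll[c] = eval_combo(c, a, v, t0);
    }

    // adaptive step sizes
    std::vector<double> step((size_t)n_subj * P);
    std::vector<int> n_try((size_t)n_subj * P, 0), n_acc((size_t)n_subj * P, 0);
    for (int j = 0; j < n_subj; j++)
        for (int p = 0; p < P; p++)
            step[(size_t)j * P + p] = (ptype[p] == 2) ? 0.25 : 0.08;

    int n_iter = n_burn + n_keep * thin;
    int ngroup = hierarchical ? 2 * P : 0;
    NumericMatrix out(n_keep, ngroup + n_subj * P);
    int row = 0;

    for (int it = 0; it < n_iter; it++) {
        // subject-level Metropolis updates
        for (int j = 0; j < n_subj; j++) {
            for (int p = 0; p < P; p++) {
                size_t idx = (size_t)j * P + p;
                double cur = eta[idx];
                double prop = cur + step[idx] * norm_rand();
                double dll = 0.0;
                const std::vector<int>& ac = aff[idx];
                std::vector<double> newll(ac.size());
                bool bad = false;
                for (size_t k = 0; k < ac.size(); k++) {
                    int c = ac[k];
                    double a, v, t0;
                    combo_par(c, p, prop, &a, &v, &t0);
                    newll[k] = eval_combo(c, a, v, t0);
                    if (!R_finite(newll[k])) { bad = true; break; }
                    dll += newll[k] - combo_ll[c];
                }
                double pm, ps;
                if (hierarchical) { pm = mu[p]; ps = sigma[p]; }
                else { pm = prior_m[ptype[p]]; ps = prior_s[ptype[p]]; }
                double dprior =
                    (-(prop - pm) * (prop - pm) + (cur - pm) * (cur - pm)) /
                    (2.0 * ps * ps);
                n_try[idx]++;
                if (!bad && std::log(unif_rand()) < dll + dprior) {
                    eta[idx] = prop;
                    for (size_t k = 0; k < ac.size(); k++)
                        combo_ll[ac[k]] = newll[k];
                    n_acc[idx]++;
                }
            }
        }

        // adapt proposal scales during burn-in
        if (it < n_burn && (it + 1) % 25 == 0) {
            for (size_t idx = 0; idx < step.size(); idx++) {
                if (n_try[idx] == 0) continue;
                double rate = (double)n_acc[idx] / n_try[idx];
                if (rate > 0.5) step[idx] *= 1.25;
                else if (rate < 0.3) step[idx] /= 1.25;
                if (step[idx] < 1e-3) step[idx] = 1e-3;
                if (step[idx] > 2.0) step[idx] = 2.0;
                n_try[idx] = 0;
                n_acc[idx] = 0;
            }
        }

        // group-level conjugate updates
        if (hierarchical) {
            for (int p = 0; p < P; p++) {
                int tp = ptype[p];
                double sum = 0.0;
                for (int j = 0; j < n_subj; j++) sum += eta[(size_t)j * P + p];
                double prec = n_subj / (sigma[p] * sigma[p]) +
                              1.0 / (s0[tp] * s0[tp]);
                double mean = (sum / (sigma[p] * sigma[p]) +
                               m0[tp] / (s0[tp] * s0[tp])) / prec;
                mu[p] = mean + norm_rand() / std::sqrt(prec);
                double ss = 0.0;
                for (int j = 0; j < n_subj; j++) {
                    double d = eta[(size_t)j * P + p] - mu[p];
                    ss += d * d;
                }
                double shape = alpha0 + n_subj / 2.0;
                double rate = beta0 + ss / 2.0;
                double g = R::rgamma(shape, 1.0 / rate);
                sigma[p] = std::sqrt(1.0 / g);
            }
        }

        // store
        if (it >= n_burn && (it - n_burn) % thin == thin - 1) {
            int col = 0;
            if (hierarchical) {
                for (int p = 0; p < P; p++) out(row, col++) = mu[p];
                for (int p = 0; p < P; p++) out(row, col++) = sigma[p];
            }
            for (int j = 0; j < n_subj; j++)
                for (int p = 0; p < P; p++) {
                    double e = eta[(size_t)j * P + p];
                    out(row, col++) = (ptype[p] == 2) ? e : std::exp(e);
                }
            row++;
        }
    }

    return List::create(_["draws"] = out);
}
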