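// Two-boundary Wiener first-passage-time numerics.
//
// Density evaluation uses the alternating-series representations with
// automatic small-time/large-time selection; the truncation rule bounds the
// absolute error of the scaled density, so with the default tolerance the
// two branches agree to well below 1e-9 at the switch point.
//
// Scale convention: within-trial diffusion coefficient s = 1.

#include <Rcpp.h>
using namespace Rcpp;

static const double PI_ = 3.14159265358979323846;

// Defective FPT density at the LOWER boundary for a Wiener process with
// drift v, boundary separation a, relative start w in (0,1), s = 1.
// t is decision time (> 0). err is the absolute truncation tolerance on the
// standardized density.
double wfpt_lower_raw(double t, double a, double v, double w, double err) {
    if (!(t > 0.0)) return 0.0;
    double tt = t / (a * a);  // standardized time

    // number of terms needed for the large-time representation
    double kl;
    if (PI_ * tt * err < 1.0) {
        kl = std::sqrt(-2.0 * std::log(PI_ * tt * err) / (PI_ * PI_ * tt));
        double kl_min = 1.0 / (PI_ * std::sqrt(tt));
        if (kl < kl_min) kl = kl_min;
    } else {
        kl = 1.0 / (PI_ * std::sqrt(tt));
    }

    // number of terms needed for the small-time representation
    double ks;
    if (2.0 * std::sqrt(2.0 * PI_ * tt) * err < 1.0) {
        ks = 2.0 + std::sqrt(-2.0 * tt * std::log(2.0 * std::sqrt(2.0 * PI_ * tt) * err));
        double ks_min = std::sqrt(tt) + 1.0;
        if (ks < ks_min) ks = ks_min;
    } else {
        ks = 2.0;
    }

    double p = 0.0;
    if (ks < kl) {  // small-time series
        int K = (int)std::ceil(ks);
        int lo = -(int)std::floor((K - 1) / 2.0);
        int hi = (int)std::ceil((K - 1) / 2.0);
        for (int k = lo; k <= hi; k++) {
            double z = w + 2.0 * k;
            p += z * std::exp(-z * z / (2.0 * tt));
        }
        p /= std::sqrt(2.0 * PI_ * tt * tt * tt);
    } else {        // large-time series
        int K = (int)std::ceil(kl);
        for (int k = 1; k <= K; k++) {
            p += k * std::exp(-k * k * PI_ * PI_ * tt / 2.0) *
                 std::sin(k * PI_ * w);
        }
        p *= PI_;
    }
    if (p < 0.0) p = 0.0;  // guard tiny negative truncation residue

    // unstandardize: drift/start-point factor and time scaling
    return p * std::exp(-v * a * w - v * v * t / 2.0) / (a * a);
}

// Density at either boundary: upper boundary is the lower boundary of the
// flipped process (v -> -v, w -> 1 - w).
double wfpt_density_one(double t, double a, double v, double w, bool upper,
                        double err) {
    if (upper) return wfpt_lower_raw(t, a, -v, 1.0 - w, err);
    return wfpt_lower_raw(t, a, v, w, err);
}

// [[Rcpp::export]]
NumericVector cpp_wfpt_density(NumericVector t, double a, double v, double w,
                               bool upper, double err) {
    int n = t.size();
    NumericVector out(n);
    for (int i = 0; i < n; i++)
        out[i] = wfpt_density_one(t[i], a, v, w, upper, err);
    return out;
}

// Absorption probability at the upper boundary (gambler's ruin), s = 1.
double prob_upper(double a, double v, double w) {
    if (std::fabs(v) < 1e-12) return w;
    double e1 = std::exp(-2.0 * v * a * w);
    double e2 = std::exp(-2.0 * v * a);
    return (1.0 - e1) / (1.0 - e2) * 1.0 -
           0.0;  // (1 - e^{-2vaw}) / (1 - e^{-2va})
}

// [[Rcpp::export]]
double cpp_prob_upper(double a, double v, double w) {
    return prob_upper(a, v, w);
}

// Contamination-mixture log-likelihood over trials.
// upper[i] = 1 if the response terminated at the upper (correct) boundary.
// Contaminants are uniform on [lo, hi] with chance responding.
// [[Rcpp::export]]
double cpp_mixture_loglik(NumericVector rt, IntegerVector upper, double a,
                          double v, double t0, double w, double picont,
                          double lo, double hi, double err) {
    int n = rt.size();
    double u = (hi > lo) ? 1.0 / (hi - lo) : 0.0;
    double ll = 0.0;
    for (int i = 0; i < n; i++) {
        double td = rt[i] - t0;
        double dens = (td > 0.0)
            ? wfpt_density_one(td, a, v, w, upper[i] == 1, err)
            : 0.0;
        double cont = (rt[i] >= lo && rt[i] <= hi) ? picont * u / 2.0 : 0.0;
        double term = (1.0 - picont) * dens + cont;
        if (term <= 0.0) return R_NegInf;
        ll += std::log(term);
    }
    return ll;
}

// ---------------------------------------------------------------------------
// Simulation
// ---------------------------------------------------------------------------

// Inverse-CDF sampling table for the decision-time distribution conditional
// on each boundary. The defective density is integrated on a uniform grid by
// the trapezoid rule out to a horizon where the residual tail mass is
// negligible (the slowest-decaying mode has rate pi^2/(2 a^2) + v^2/2).
struct IcdfTable {
    std::vector<double> grid;    // time nodes
    std::vector<double> cdf_lo;  // cumulative defective mass, lower boundary
    std::vector<double> cdf_up;
    double p_up;
    int n;
};

static IcdfTable build_icdf(double a, double v, double w, int ngrid) {
    IcdfTable tab;
    double lambda1 = PI_ * PI_ / (2.0 * a * a) + v * v / 2.0;
    double tmax = -std::log(1e-12) / lambda1 + 0.05;
    tab.n = ngrid;
    tab.grid.resize(ngrid + 1);
    tab.cdf_lo.resize(ngrid + 1);
    tab.cdf_up.resize(ngrid + 1);
    double h = tmax / ngrid;
    double err = 1e-11;
    double prev_lo = 0.0, prev_up = 0.0, c_lo = 0.0, c_up = 0.0;
    tab.grid[0] = 0.0;
    tab.cdf_lo[0] = 0.0;
    tab.cdf_up[0] = 0.0;
    for (int i = 1; i <= ngrid; i++) {
        double t = i * h;
        double flo = wfpt_density_one(t, a, v, w, false, err);
        double fup = wfpt_density_one(t, a, v, w, true, err);
        c_lo += 0.5 * h * (prev_lo + flo);
        c_up += 0.5 * h * (prev_up + fup);
        tab.grid[i] = t;
        tab.cdf_lo[i] = c_lo;
        tab.cdf_up[i] = c_up;
        prev_lo = flo;
        prev_up = fup;
    }
    tab.p_up = prob_upper(a, v, w);
    return tab;
}

// Draw one decision time from a (monotone) cumulative table by linear
// interpolation of the inverse.
static double icdf_draw(const std::vector<double>& grid,
                        const std::vector<double>& cdf, double target) {
    int lo = 0, hi = (int)cdf.size() - 1;
    if (target >= cdf[hi]) return grid[hi];
    while (hi - lo > 1) {
        int mid = (lo + hi) / 2;
        if (cdf[mid] < target) lo = mid; else hi = mid;
    }
    double c0 = cdf[lo], c1 = cdf[hi];
    double frac = (c1 > c0) ? (target - c0) / (c1 - c0) : 0.5;
    return grid[lo] + frac * (grid[hi] - grid[lo]);
}

// Euler-Maruyama path simulation to absorption (reference simulator,
// independent of the series density).
static void euler_trial(double a, double v, double w, double dt, double& t_out,
                        bool& upper_out) {
    double x = w * a;
    double t = 0.0;
    double sdt = std::sqrt(dt);
    while (x > 0.0 && x < a) {
        x += v * dt + sdt * norm_rand();
        t += dt;
    }
    t_out = t;
    upper_out = (x >= a);
}

// Simulate n trials with contamination mixture.
// method: 0 = inverse-CDF from the FPT distribution, 1 = Euler path.
// Returns rt (with t0 added), boundary (1 = upper), contaminant flag.
// Uses R's RNG: seed with set.seed() on the R side.
// [[Rcpp::export]]
List cpp_sim_wiener(int n, double a, double v, double t0, double w,
                    double picont, double lo, double hi, int method,
                    double dt) {
    NumericVector rt(n);
    IntegerVector up(n);
    IntegerVector cont(n);
    IcdfTable tab;
    if (method == 0) tab = build_icdf(a, v, w, 4096);
    double total = 0.0;
    if (method == 0) total = tab.cdf_lo[tab.n] + tab.cdf_up[tab.n];
    for (int i = 0; i < n; i++) {
        if (picont > 0.0 && unif_rand() < picont) {
            rt[i] = lo + (hi - lo) * unif_rand();
            up[i] = (unif_rand() < 0.5) ? 1 : 0;
            cont[i] = 1;
            continue;
        }
        cont[i] = 0;
        if (method == 0) {
            double u = unif_rand() * total;
            if (u <= tab.cdf_up[tab.n]) {
                up[i] = 1;
                rt[i] = t0 + icdf_draw(tab.grid, tab.cdf_up, u);
            } else {
                up[i] = 0;
                rt[i] = t0 + icdf_draw(tab.grid, tab.cdf_lo,
                                       u - tab.cdf_up[tab.n]);
            }
        } else {
            double td; bool bu;
            euler_trial(a, v, w, dt, td, bu);
            rt[i] = t0 + td;
            up[i] = bu ? 1 : 0;
        }
    }
    return List::create(_["rt"] = rt, _["upper"] = up,
                        _["contaminant"] = cont);
}

// Batch simulation over design cells: par has one row per cell with columns
// (a, v, t0); n_per_cell gives the trial count of each cell; lo/hi give the
// per-cell contaminant window. One inverse-CDF table is built per cell.
// Returns flat vectors plus the cell index of each trial. Uses R's RNG.
// [[Rcpp::export]]
List cpp_sim_cells(NumericMatrix par, IntegerVector n_per_cell, double w,
                   double picont, NumericVector lo, NumericVector hi,
                   int ngrid) {
    int ncell = par.nrow();
    int ntot = 0;
    for (int c = 0; c < ncell; c++) ntot += n_per_cell[c];
    NumericVector rt(ntot);
    IntegerVector up(ntot), cont(ntot), cell(ntot);
    int pos = 0;
    for (int c = 0; c < ncell; c++) {
        int nc = n_per_cell[c];
        if (nc == 0) continue;
        double a = par(c, 0), v = par(c, 1), t0 = par(c, 2);
        IcdfTable tab = build_icdf(a, v, w, ngrid);
        double total = tab.cdf_lo[tab.n] + tab.cdf_up[tab.n];
        for (int i = 0; i < nc; i++, pos++) {
            cell[pos] = c + 1;
            if (picont > 0.0 && unif_rand() < picont) {
                rt[pos] = lo[c] + (hi[c] - lo[c]) * unif_rand();
                up[pos] = (unif_rand() < 0.5) ? 1 : 0;
                cont[pos] = 1;
                continue;
            }
            cont[pos] = 0;
            double u = unif_rand() * total;
            if (u <= tab.cdf_up[tab.n]) {
                up[pos] = 1;
                rt[pos] = t0 + icdf_draw(tab.grid, tab.cdf_up, u);
            } else {
                up[pos] = 0;
                rt[pos] = t0 + icdf_draw(tab.grid, tab.cdf_lo,
                                         u - tab.cdf_up[tab.n]);
            }
        }
    }
    return List::create(_["rt"] = rt, _["upper"] = up,
                        _["contaminant"] = cont, _["cell"] = cell);
}
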