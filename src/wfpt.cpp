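#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// First-passage density of a unit-noise Wiener process at the LOWER boundary,
// for normalized time tt = t / a^2, zero drift, unit boundary, start fraction w.
// Two series expansions; the one needing fewer terms for truncation error <= eps
// is used (small-time is accurate for tt -> 0, large-time for tt -> Inf).
static double fpt_norm(double tt, double w, double eps) {
    if (tt <= 0.0) return 0.0;
    // number of terms required by each expansion
    double ks, kl;
    if (2.0 * eps * std::sqrt(2.0 * M_PI * tt) < 1.0) {
        ks = 2.0 + std::sqrt(-2.0 * tt * std::log(2.0 * eps * std::sqrt(2.0 * M_PI * tt)));
        ks = std::max(ks, std::sqrt(tt) + 1.0);
    } else {
        ks = 2.0;
    }
    if (M_PI * tt * eps < 1.0) {
        kl = std::sqrt(-2.0 * std::log(M_PI * tt * eps) / (M_PI * M_PI * tt));
        kl = std::max(kl, 1.0 / (M_PI * std::sqrt(tt)));
    } else {
        kl = 1.0 / (M_PI * std::sqrt(tt));
    }
    double p = 0.0;
    if (ks < kl) {               // small-time expansion
        int K = (int)std::ceil(ks);
        int lo = -((K - 1) / 2), hi = (K - 1) / 2 + ((K - 1) % 2);
        for (int k = lo; k <= hi; ++k) {
            double z = w + 2.0 * k;
            p += z * std::exp(-z * z / (2.0 * tt));
        }
        p /= std::sqrt(2.0 * M_PI * tt * tt * tt);
    } else {                     // large-time expansion
        int K = (int)std::ceil(kl);
        for (int k = 1; k <= K; ++k) {
            p += k * std::exp(-k * k * M_PI * M_PI * tt / 2.0) *
                 std::sin(k * M_PI * w);
        }
        p *= M_PI;
    }
    return p;
}

// log density of lower-boundary absorption at decision time t, drift v,
// boundary separation a, starting fraction w
static double wfpt_lower_log(double t, double v, double a, double w, double eps) {
    if (!(t > 0.0) || !(a > 0.0) || !(w > 0.0) || !(w < 1.0)) return R_NegInf;
    double tt = t / (a * a);
    double f = fpt_norm(tt, w, eps);
    if (f <= 0.0) return R_NegInf;
    return std::log(f) - 2.0 * std::log(a) - v * a * w - v * v * t / 2.0;
}

//' @noRd
// [[Rcpp::export(name = ".wfpt_logpdf_cpp")]]
NumericVector wfpt_logpdf_cpp(NumericVector t, NumericVector drift,
                              NumericVector boundary, NumericVector w,
                              LogicalVector upper, double eps) {
    R_xlen_t n = t.size();
    NumericVector out(n);
    for (R_xlen_t i = 0; i < n; ++i) {
        double v = drift[i % drift.size()];
        double a = boundary[i % boundary.size()];
        double ww = w[i % w.size()];
        bool up = upper[i % upper.size()];
        if (up) { v = -v; ww = 1.0 - ww; }  // upper boundary by reflection
        out[i] = wfpt_lower_log(t[i], v, a, ww, eps);
    }
    return out;
}

// summed log likelihood of (rt, accuracy) trials: upper boundary = correct
//' @noRd
// [[Rcpp::export(name = ".ddm_loglik_cpp")]]
double ddm_loglik_cpp(NumericVector rt, IntegerVector acc,
                      NumericVector drift, NumericVector ndt,
                      NumericVector boundary, double w, double eps) {
    R_xlen_t n = rt.size();
    double ll = 0.0;
    for (R_xlen_t i = 0; i < n; ++i) {
        double a = boundary[i];
        double tau = ndt[i];
        double t = rt[i] - tau;
        if (!(a > 0.0) || !(tau >= 0.0) || !(t > 0.0)) return R_NegInf;
        double v = drift[i];
        double ww = w;
        if (acc[i] == 1) { v = -v; ww = 1.0 - ww; }
        double l = wfpt_lower_log(t, v, a, ww, eps);
        if (l == R_NegInf) return R_NegInf;
        ll += l;
    }
    return ll;
}

// Euler-Maruyama first-passage simulation, unit diffusion coefficient.
// Returns matrix [choice (1 = upper), decision time] per path.
//' @noRd
// [[Rcpp::export(name = ".ddm_sim_cpp")]]
NumericMatrix ddm_sim_cpp(int n, double drift, double boundary, double w,
                          double dt, double tmax) {
    NumericMatrix out(n, 2);
    double sdt = std::sqrt(dt);
    for (int i = 0; i < n; ++i) {
        double x = w * boundary;
        double t = 0.0;
        int choice = NA_INTEGER;
        while (t < tmax) {
            x += drift * dt + sdt * norm_rand();
            t += dt;
            if (x >= boundary) { choice = 1; break; }
            if (x <= 0.0)      { choice = 0; break; }
        }
        out(i, 0) = (choice == NA_INTEGER) ? NA_REAL : (double)choice;
        out(i, 1) = t;
    }
    return out;
}

// One full Metropolis sweep over all participant-level coefficients.
// Cells are concatenated row-wise in rt/acc and the three design blocks;
// off[i]..off[i+1]-1 are cell i's trial rows. Uses R's RNG so runs are
// reproducible from set.seed().
//' @noRd
// [[Rcpp::export(name = ".ddm_sweep_cpp")]]
List ddm_sweep_cpp(NumericMatrix theta_in, NumericVector ll_in,
                   NumericVector rt, IntegerVector acc, IntegerVector off,
                   NumericMatrix Xd, NumericMatrix Xn, NumericMatrix Xb,
                   IntegerVector cond_of, NumericMatrix mu, NumericMatrix sig,
                   NumericVector lower, NumericVector upper,
                   NumericMatrix scales, IntegerVector block_id,
                   IntegerVector block_col, double w, double eps,
                   NumericMatrix scales2, IntegerVector int_idx,
                   NumericMatrix col_means) {
    int ncell = theta_in.nrow(), p = theta_in.ncol();
    NumericMatrix theta = clone(theta_in);
    NumericVector ll = clone(ll_in);
    IntegerMatrix accepts(ncell, p);
    int pd = Xd.ncol(), pn = Xn.ncol(), pb = Xb.ncol();

    for (int i = 0; i < ncell; ++i) {
        int r0 = off[i], r1 = off[i + 1];
        int n = r1 - r0;
        int ci = cond_of[i] - 1;
        std::vector<double> drift(n, 0.0), ndt(n, 0.0), bound(n, 0.0), tmp(n);
        for (int k = 0; k < n; ++k) {
            double d = 0.0, nn = 0.0, bb = 0.0;
            for (int c = 0; c < pd; ++c) d += Xd(r0 + k, c) * theta(i, c);
            for (int c = 0; c < pn; ++c) nn += Xn(r0 + k, c) * theta(i, pd + c);
            for (int c = 0; c < pb; ++c) bb += Xb(r0 + k, c) * theta(i, pd + pn + c);
            drift[k] = d; ndt[k] = nn; bound[k] = bb;
        }
        for (int j = 0; j < p; ++j) {
            double cur = theta(i, j);
            double prop = cur + scales(i, j) * norm_rand();
            if (prop < lower[j] || prop > upper[j]) continue;
            double delta = prop - cur;
            int b = block_id[j], c = block_col[j];
            double ll_new = 0.0;
            bool ok = true;
            for (int k = 0; k < n && ok; ++k) {
                double d = drift[k], nn = ndt[k], bb = bound[k];
                if (b == 0) d += delta * Xd(r0 + k, c);
                else if (b == 1) nn += delta * Xn(r0 + k, c);
                else bb += delta * Xb(r0 + k, c);
                double t = rt[r0 + k] - nn;
                if (!(bb > 0.0) || !(nn >= 0.0) || !(t > 0.0)) { ok = false; break; }
                double v = d, ww = w;
                if (acc[r0 + k] == 1) { v = -v; ww = 1.0 - ww; }
                double l = wfpt_lower_log(t, v, bb, ww, eps);
                if (l == R_NegInf) { ok = false; break; }
                ll_new += l;
            }
            if (!ok) continue;
            double pr = R::dnorm(prop, mu(ci, j), sig(ci, j), 1) -
                        R::dnorm(cur, mu(ci, j), sig(ci, j), 1);
            if (std::log(unif_rand()) < ll_new - ll[i] + pr) {
                theta(i, j) = prop;
                ll[i] = ll_new;
                accepts(i, j) = 1;
                for (int k = 0; k < n; ++k) {
                    if (b == 0) drift[k] += delta * Xd(r0 + k, c);
                    else if (b == 1) ndt[k] += delta * Xn(r0 + k, c);
                    else bound[k] += delta * Xb(r0 + k, c);
                }
            }
        }
    }
    // second pass: joint intercept-slope moves along the centred direction
    // (slope_j += d, intercept -= d * mean(covariate_j)), which leaves the
    // cell-average parameter value unchanged and so decorrelates the
    // otherwise collinear intercept-slope pairs
    IntegerMatrix accepts2(ncell, p);
    for (int i = 0; i < ncell; ++i) {
        int r0 = off[i], r1 = off[i + 1];
        int n = r1 - r0;
        int ci = cond_of[i] - 1;
        std::vector<double> drift(n, 0.0), ndt(n, 0.0), bound(n, 0.0);
        for (int k = 0; k < n; ++k) {
            double d = 0.0, nn = 0.0, bb = 0.0;
            for (int c = 0; c < pd; ++c) d += Xd(r0 + k, c) * theta(i, c);
            for (int c = 0; c < pn; ++c) nn += Xn(r0 + k, c) * theta(i, pd + c);
            for (int c = 0; c < pb; ++c) bb += Xb(r0 + k, c) * theta(i, pd + pn + c);
            drift[k] = d; ndt[k] = nn; bound[k] = bb;
        }
        for (int j = 0; j < p; ++j) {
            int b = block_id[j], c = block_col[j];
            int j0 = int_idx[b];             // intercept coefficient index
            if (j0 < 0 || j == j0) continue; // no intercept or j is one
            double d = scales2(i, j) * norm_rand();
            double prop_s = theta(i, j) + d;
            double prop_i = theta(i, j0) - d * col_means(i, j);
            if (prop_s < lower[j] || prop_s > upper[j] ||
                prop_i < lower[j0] || prop_i > upper[j0]) continue;
            double ll_new = 0.0;
            bool ok = true;
            for (int k = 0; k < n && ok; ++k) {
                double dd = drift[k], nn = ndt[k], bb = bound[k];
                double shift = d * ((b == 0 ? Xd(r0 + k, c)
                                    : b == 1 ? Xn(r0 + k, c)
                                             : Xb(r0 + k, c)) - col_means(i, j));
                if (b == 0) dd += shift;
                else if (b == 1) nn += shift;
                else bb += shift;
                double t = rt[r0 + k] - nn;
                if (!(bb > 0.0) || !(nn >= 0.0) || !(t > 0.0)) { ok = false; break; }
                double v = dd, ww = w;
                if (acc[r0 + k] == 1) { v = -v; ww = 1.0 - ww; }
                double l = wfpt_lower_log(t, v, bb, ww, eps);
                if (l == R_NegInf) { ok = false; break; }
                ll_new += l;
            }
            if (!ok) continue;
            double pr = R::dnorm(prop_s, mu(ci, j), sig(ci, j), 1) -
                        R::dnorm(theta(i, j), mu(ci, j), sig(ci, j), 1) +
                        R::dnorm(prop_i, mu(ci, j0), sig(ci, j0), 1) -
                        R::dnorm(theta(i, j0), mu(ci, j0), sig(ci, j0), 1);
            if (std::log(unif_rand()) < ll_new - ll[i] + pr) {
                for (int k = 0; k < n; ++k) {
                    double shift = d * ((b == 0 ? Xd(r0 + k, c)
                                        : b == 1 ? Xn(r0 + k, c)
                                                 : Xb(r0 + k, c)) - col_means(i, j));
                    if (b == 0) drift[k] += shift;
                    else if (b == 1) ndt[k] += shift;
                    else bound[k] += shift;
                }
                theta(i, j) = prop_s;
                theta(i, j0) = prop_i;
                ll[i] = ll_new;
                accepts2(i, j) = 1;
            }
        }
    }
    return List::create(_["theta"] = theta, _["ll"] = ll,
                        _["accepts"] = accepts, _["accepts2"] = accepts2);
}

// helper: summed log likelihood of cell i when coefficient j is shifted by
// delta (other coefficients unchanged)
static double cell_ll_shift(int i, int j, double delta,
                            const NumericMatrix &theta,
                            const NumericVector &rt, const IntegerVector &acc,
                            const IntegerVector &off,
                            const NumericMatrix &Xd, const NumericMatrix &Xn,
                            const NumericMatrix &Xb,
                            const IntegerVector &block_id,
                            const IntegerVector &block_col,
                            double w, double eps) {
    int r0 = off[i], r1 = off[i + 1];
    int pd = Xd.ncol(), pn = Xn.ncol(), pb = Xb.ncol();
    int b = block_id[j], c = block_col[j];
    double ll = 0.0;
    for (int k = r0; k < r1; ++k) {
        double d = 0.0, nn = 0.0, bb = 0.0;
        for (int cc = 0; cc < pd; ++cc) d += Xd(k, cc) * theta(i, cc);
        for (int cc = 0; cc < pn; ++cc) nn += Xn(k, cc) * theta(i, pd + cc);
        for (int cc = 0; cc < pb; ++cc) bb += Xb(k, cc) * theta(i, pd + pn + cc);
        double shift = delta * (b == 0 ? Xd(k, c) : b == 1 ? Xn(k, c) : Xb(k, c));
        if (b == 0) d += shift; else if (b == 1) nn += shift; else bb += shift;
        double t = rt[k] - nn;
        if (!(bb > 0.0) || !(nn >= 0.0) || !(t > 0.0)) return R_NegInf;
        double v = d, ww = w;
        if (acc[k] == 1) { v = -v; ww = 1.0 - ww; }
        double l = wfpt_lower_log(t, v, bb, ww, eps);
        if (l == R_NegInf) return R_NegInf;
        ll += l;
    }
    return ll;
}

// Interweaved (non-centred) group moves: with the standardised residuals
// eta_i = (theta_i - mu) / sigma held fixed, propose (a) a translation of mu
// and (b) a log-scale move of sigma, each carrying all participant
// coefficients of the condition along. Breaks the funnel-shaped coupling
// between group SDs and participant coefficients.
//' @noRd
// [[Rcpp::export(name = ".ddm_interweave_cpp")]]
List ddm_interweave_cpp(NumericMatrix theta_in, NumericVector ll_in,
                        NumericVector rt, IntegerVector acc,
                        IntegerVector off,
                        NumericMatrix Xd, NumericMatrix Xn, NumericMatrix Xb,
                        IntegerVector cond_of,
                        NumericMatrix mu_in, NumericMatrix sig_in,
                        NumericVector lower, NumericVector upper,
                        NumericMatrix mu_scale, NumericMatrix sig_scale,
                        IntegerVector block_id, IntegerVector block_col,
                        double w, double eps) {
    int ncell = theta_in.nrow(), p = theta_in.ncol();
    int nc = mu_in.nrow();
    NumericMatrix theta = clone(theta_in), mu = clone(mu_in),
                  sig = clone(sig_in);
    NumericVector ll = clone(ll_in);
    IntegerMatrix acc_mu(nc, p), acc_sig(nc, p);

    for (int ci = 0; ci < nc; ++ci) {
        for (int j = 0; j < p; ++j) {
            // (a) translation: mu' = mu + d, theta_i' = theta_i + d
            double d = mu_scale(ci, j) * norm_rand();
            double mu_new = mu(ci, j) + d;
            if (mu_new >= lower[j] && mu_new <= upper[j]) {
                double dll = 0.0;
                std::vector<double> lls(ncell, 0.0);
                bool ok = true;
                for (int i = 0; i < ncell && ok; ++i) {
                    if (cond_of[i] - 1 != ci) continue;
                    double th_new = theta(i, j) + d;
                    if (th_new < lower[j] || th_new > upper[j]) { ok = false; break; }
                    double l = cell_ll_shift(i, j, d, theta, rt, acc, off,
                                             Xd, Xn, Xb, block_id, block_col,
                                             w, eps);
                    if (l == R_NegInf) { ok = false; break; }
                    lls[i] = l;
                    dll += l - ll[i];
                }
                if (ok && std::log(unif_rand()) < dll) {
                    mu(ci, j) = mu_new;
                    for (int i = 0; i < ncell; ++i) {
                        if (cond_of[i] - 1 != ci) continue;
                        theta(i, j) += d;
                        ll[i] = lls[i];
                    }
                    acc_mu(ci, j) = 1;
                }
            }
            // (b) scale: sigma' = sigma * e^z, theta_i' = mu + r (theta_i - mu)
            double z = sig_scale(ci, j) * norm_rand();
            double s_old = sig(ci, j), s_new = s_old * std::exp(z);
            if (s_new > 0.005 && s_new < 5.0) {
                double r = s_new / s_old;
                double dll = 0.0;
                std::vector<double> lls(ncell, 0.0);
                bool ok = true;
                for (int i = 0; i < ncell && ok; ++i) {
                    if (cond_of[i] - 1 != ci) continue;
                    double delta = (r - 1.0) * (theta(i, j) - mu(ci, j));
                    double th_new = theta(i, j) + delta;
                    if (th_new < lower[j] || th_new > upper[j]) { ok = false; break; }
                    double l = cell_ll_shift(i, j, delta, theta, rt, acc, off,
                                             Xd, Xn, Xb, block_id, block_col,
                                             w, eps);
                    if (l == R_NegInf) { ok = false; break; }
                    lls[i] = l;
                    dll += l - ll[i];
                }
                // uniform prior on sigma; log-RW jacobian log(s'/s)
                if (ok && std::log(unif_rand()) < dll + std::log(r)) {
                    sig(ci, j) = s_new;
                    for (int i = 0; i < ncell; ++i) {
                        if (cond_of[i] - 1 != ci) continue;
                        theta(i, j) = mu(ci, j) + r * (theta(i, j) - mu(ci, j));
                        ll[i] = lls[i];
                    }
                    acc_sig(ci, j) = 1;
                }
            }
        }
    }
    return List::create(_["theta"] = theta, _["ll"] = ll, _["mu"] = mu,
                        _["sig"] = sig, _["acc_mu"] = acc_mu,
                        _["acc_sig"] = acc_sig);
}
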