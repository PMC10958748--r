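#include <Rcpp.h>
using namespace Rcpp;

// Crank-Nicolson solver for the first-passage problem of
//   dx = mu(t) dt + dW,  x(0) = 0,
// with symmetric absorbing boundaries +/- b(t). The drift is spatially
// uniform, so central differences need no upwinding. The boundary is
// absorbed at the nearest grid line; mass swept over by a collapsing
// boundary is credited to that side at the step where it happens.
//
// drift_t, bound_t: values at the nt+1 time nodes 0, dt, ..., nt*dt.
// Returns per-step absorbed-probability *densities* (mass / dt) at the
// upper (go) and lower (stay) boundary, plus undecided mass at t_max.
//
// The first `n_startup` steps use backward Euler (Rannacher smoothing of
// the delta initial condition); later steps are Crank-Nicolson.
// [[Rcpp::export]]
List fpt_solve_cpp(NumericVector drift_t, NumericVector bound_t,
                   double dt, double dx, double bmax, int n_startup = 8) {
  const int nt = drift_t.size() - 1;
  if (bound_t.size() != nt + 1) stop("drift_t and bound_t must share the time grid");
  const int Mh = (int)std::ceil(bmax / dx - 1e-9);  // half-width in cells
  const int M = 2 * Mh;                             // grid 0..M, x_j = (j-Mh)*dx

  std::vector<double> p(M + 1, 0.0), pn(M + 1, 0.0);
  std::vector<double> cl(M + 1), cd(M + 1), cu(M + 1), rhs(M + 1), gam(M + 1);
  p[Mh] = 1.0 / dx;  // delta at x = 0

  NumericVector go_flux(nt), stay_flux(nt);
  double p_go = 0.0, p_stay = 0.0;
  const double idx2 = 1.0 / (2.0 * dx * dx);

  for (int n = 0; n < nt; ++n) {
    const double theta = (n < n_startup) ? 1.0 : 0.5;
    const double mu0 = drift_t[n], mu1 = drift_t[n + 1];
    const double b_new = bound_t[n + 1];

    // boundary at nearest grid line, at least one cell from the start point
    int off = (int)std::lround(b_new / dx);
    if (off < 1) off = 1;
    if (off > Mh) off = Mh;
    const int klo = Mh - off, kup = Mh + off;

    // absorb mass the collapsing boundary has swept past (and boundary nodes)
    double swept_go = 0.0, swept_stay = 0.0;
    for (int j = 0; j <= klo; ++j) { swept_stay += p[j] * dx; p[j] = 0.0; }
    for (int j = kup; j <= M; ++j) { swept_go += p[j] * dx; p[j] = 0.0; }

    const int a = klo + 1, b = kup - 1;  // interior range

    // explicit part: rhs = (I + (1-theta) dt L(mu0)) p
    const double w = (1.0 - theta) * dt;
    const double elo = w * (mu0 / (2.0 * dx) + idx2);
    const double edi = 1.0 - w * 2.0 * idx2;
    const double eup = w * (-mu0 / (2.0 * dx) + idx2);
    for (int j = a; j <= b; ++j) {
      double lo = (j > a) ? p[j - 1] : 0.0;
      double up = (j < b) ? p[j + 1] : 0.0;
      rhs[j] = elo * lo + edi * p[j] + eup * up;
    }

    // implicit part: (I - theta dt L(mu1)) pn = rhs, Thomas algorithm
    const double v = theta * dt;
    const double ilo = -v * (mu1 / (2.0 * dx) + idx2);
    const double idi = 1.0 + v * 2.0 * idx2;
    const double iup = -v * (-mu1 / (2.0 * dx) + idx2);
    double beta = idi;
    pn[a] = rhs[a] / beta;
    for (int j = a + 1; j <= b; ++j) {
      gam[j] = iup / beta;
      beta = idi - ilo * gam[j];
      pn[j] = (rhs[j] - ilo * pn[j - 1]) / beta;
    }
    for (int j = b - 1; j >= a; --j) pn[j] -= gam[j + 1] * pn[j + 1];

    // discrete boundary fluxes (exact mass bookkeeping for this scheme):
    // R_up = p_b (1/(2dx) + mu/2), R_lo = p_a (1/(2dx) - mu/2)
    double loss_up = dt * ((1.0 - theta) * p[b] * (1.0 / (2.0 * dx) + mu0 / 2.0) +
                           theta * pn[b] * (1.0 / (2.0 * dx) + mu1 / 2.0));
    double loss_lo = dt * ((1.0 - theta) * p[a] * (1.0 / (2.0 * dx) - mu0 / 2.0) +
                           theta * pn[a] * (1.0 / (2.0 * dx) - mu1 / 2.0));
    if (loss_up < 0) loss_up = 0;
    if (loss_lo < 0) loss_lo = 0;

    for (int j = a; j <= b; ++j) p[j] = pn[j];

    go_flux[n] = (loss_up + swept_go) / dt;
    stay_flux[n] = (loss_lo + swept_stay) / dt;
    p_go += loss_up + swept_go;
    p_stay += loss_lo + swept_stay;
  }

  double p_undecided = 0.0;
  for (int j = 0; j <= M; ++j) p_undecided += p[j] * dx;

  return List::create(_["go_flux"] = go_flux, _["stay_flux"] = stay_flux,
                      _["p_go"] = p_go, _["p_stay_absorbed"] = p_stay,
                      _["p_undecided"] = p_undecided);
}

// Euler-Maruyama trial simulator on the same time grid as the solver.
// In addition to the post-step boundary check, a Brownian-bridge
// correction accounts for within-step excursions: given endpoints x0, x1
// strictly inside the boundaries, the bridge crosses a bound at distance
// (b - x0), (b - x1) with probability exp(-2 (b - x0)(b - x1) / dt).
// Without it, first passages are biased late by O(sqrt(dt)). Trials alive
// at the last node are censored (decision 0L = stay, decision time NA).
// Uses R's RNG, so results are reproducible under set.seed().
// [[Rcpp::export]]
List sim_trials_cpp(NumericVector drift_t, NumericVector bound_t,
                    double dt, int n) {
  const int nt = drift_t.size() - 1;
  if (bound_t.size() != nt + 1) stop("drift_t and bound_t must share the time grid");
  IntegerVector decision(n);
  NumericVector dtime(n);
  const double sd = std::sqrt(dt);
  for (int i = 0; i < n; ++i) {
    double x = 0.0;
    int dec = 0;
    double tdec = NA_REAL;
    for (int s = 0; s < nt; ++s) {
      const double x0 = x;
      x += drift_t[s] * dt + sd * norm_rand();
      const double bnd = bound_t[s + 1];
      if (x >= bnd) { dec = 1; tdec = (s + 1) * dt; break; }
      if (x <= -bnd) { dec = 0; tdec = (s + 1) * dt; break; }
      // within-step crossing of either bound (bridge approximation with
      // the boundary frozen at its end-of-step value)
      const double pu = std::exp(-2.0 * (bnd - x0) * (bnd - x) / dt);
      if (unif_rand() < pu) { dec = 1; tdec = (s + 1) * dt; break; }
      const double pl = std::exp(-2.0 * (x0 + bnd) * (x + bnd) / dt);
      if (unif_rand() < pl) { dec = 0; tdec = (s + 1) * dt; break; }
    }
    decision[i] = dec;
    dtime[i] = tdec;
  }
  return List::create(_["decision"] = decision, _["decision_time"] = dtime);
}

// Solve one condition and reduce straight to the fitting summary:
// go probability, observed-RT quantiles at `levels`, and mean observed RT.
// Mirrors solve_fpt() + convolve_nondecision() + predicted_summary() but
// avoids R-level glue; used by the weighted least-sum objective where it
// is evaluated thousands of times per fit.
// [[Rcpp::export]]
List solve_summary_cpp(NumericVector drift_t, NumericVector bound_t,
                       double dt, double dx, double bmax,
                       double mu_nd, double sigma_nd,
                       NumericVector levels, int n_startup = 8) {
  List sol = fpt_solve_cpp(drift_t, bound_t, dt, dx, bmax, n_startup);
  NumericVector go_flux = sol["go_flux"];
  const int nt = go_flux.size();
  double p_go = sol["p_go"];

  // non-decision kernel (zero-truncated normal discretized at dt)
  std::vector<double> dens;
  if (sigma_nd <= 0) {
    int shift = (int)std::lround(std::max(mu_nd, 0.0) / dt);
    dens.assign(nt + shift, 0.0);
    for (int i = 0; i < nt; ++i) {
      double g = go_flux[i];
      dens[i + shift] = g > 0 ? g : 0;
    }
  } else {
    const int K = (int)std::ceil((std::max(mu_nd, 0.0) + 6 * sigma_nd) / dt);
    std::vector<double> w(K + 1);
    double sw = 0;
    for (int i = 0; i <= K; ++i) {
      double t = i * dt, z = (t - mu_nd) / sigma_nd;
      w[i] = std::exp(-0.5 * z * z);
      sw += w[i];
    }
    for (int i = 0; i <= K; ++i) w[i] /= sw;
    dens.assign(nt + K, 0.0);
    for (int i = 0; i < nt; ++i) {
      double g = go_flux[i];
      if (g <= 0) continue;
      for (int j = 0; j <= K; ++j) dens[i + j] += g * w[j];
    }
  }
  const int m = dens.size();

  NumericVector q(levels.size(), NA_REAL);
  double mean_rt = NA_REAL;
  if (p_go > 1e-9) {
    // cdf over the extended grid t_i = (i+1) dt
    double acc = 0, tsum = 0;
    std::vector<double> cdf(m);
    for (int i = 0; i < m; ++i) {
      acc += dens[i] * dt;
      cdf[i] = acc / p_go;
      tsum += (i + 1) * dt * dens[i] * dt;
    }
    mean_rt = tsum / p_go;
    for (int l = 0; l < levels.size(); ++l) {
      double L = levels[l];
      if (L <= cdf[0]) { q[l] = dt; continue; }
      if (L >= cdf[m - 1]) { q[l] = m * dt; continue; }
      int lo = 0, hi = m - 1;
      while (hi - lo > 1) {
        int mid = (lo + hi) / 2;
        if (cdf[mid] < L) lo = mid; else hi = mid;
      }
      double t0 = (lo + 1) * dt, t1 = (hi + 1) * dt;
      double c0 = cdf[lo], c1 = cdf[hi];
      q[l] = c1 > c0 ? t0 + (t1 - t0) * (L - c0) / (c1 - c0) : t0;
    }
  }
  return List::create(_["p_go"] = p_go, _["rt_quantiles"] = q,
                      _["mean_rt"] = mean_rt);
}

// ---- allocation-free core used by the batched loss below ----------------

// Crank-Nicolson propagation identical to fpt_solve_cpp, writing the go
// first-passage density into go_flux (resized to nt) and returning p_go.
static double solve_core(const std::vector<double>& mu,
                         const std::vector<double>& bb,
                         double dt, double dx, double bmax, int n_startup,
                         std::vector<double>& go_flux) {
  const int nt = (int)mu.size() - 1;
  const int Mh = (int)std::ceil(bmax / dx - 1e-9);
  const int M = 2 * Mh;
  std::vector<double> p(M + 1, 0.0), pn(M + 1, 0.0), rhs(M + 1), gam(M + 1);
  p[Mh] = 1.0 / dx;
  go_flux.assign(nt, 0.0);
  double p_go = 0.0;
  const double idx2 = 1.0 / (2.0 * dx * dx);
  for (int n = 0; n < nt; ++n) {
    const double theta = (n < n_startup) ? 1.0 : 0.5;
    const double mu0 = mu[n], mu1 = mu[n + 1];
    int off = (int)std::lround(bb[n + 1] / dx);
    if (off < 1) off = 1;
    if (off > Mh) off = Mh;
    const int klo = Mh - off, kup = Mh + off;
    double swept_go = 0.0;
    for (int j = 0; j <= klo; ++j) p[j] = 0.0;
    for (int j = kup; j <= M; ++j) { swept_go += p[j] * dx; p[j] = 0.0; }
    const int a = klo + 1, b = kup - 1;
    const double w = (1.0 - theta) * dt;
    const double elo = w * (mu0 / (2.0 * dx) + idx2);
    const double edi = 1.0 - w * 2.0 * idx2;
    const double eup = w * (-mu0 / (2.0 * dx) + idx2);
    for (int j = a; j <= b; ++j) {
      double lo = (j > a) ? p[j - 1] : 0.0;
      double up = (j < b) ? p[j + 1] : 0.0;
      rhs[j] = elo * lo + edi * p[j] + eup * up;
    }
    const double v = theta * dt;
    const double ilo = -v * (mu1 / (2.0 * dx) + idx2);
    const double idi = 1.0 + v * 2.0 * idx2;
    const double iup = -v * (-mu1 / (2.0 * dx) + idx2);
    double beta = idi;
    pn[a] = rhs[a] / beta;
    for (int j = a + 1; j <= b; ++j) {
      gam[j] = iup / beta;
      beta = idi - ilo * gam[j];
      pn[j] = (rhs[j] - ilo * pn[j - 1]) / beta;
    }
    for (int j = b - 1; j >= a; --j) pn[j] -= gam[j + 1] * pn[j + 1];
    double loss_up = dt * ((1.0 - theta) * p[b] * (1.0 / (2.0 * dx) + mu0 / 2.0) +
                           theta * pn[b] * (1.0 / (2.0 * dx) + mu1 / 2.0));
    if (loss_up < 0) loss_up = 0;
    for (int j = a; j <= b; ++j) p[j] = pn[j];
    go_flux[n] = (loss_up + swept_go) / dt;
    p_go += loss_up + swept_go;
  }
  return p_go;
}

// Weighted least-sum score for one parameter vector across all
// conditions, entirely in compiled code (the optimization hot loop).
// variant: 0 = full, 1 = var_drift_const_bound, 2 = const_drift_const_bound.
// obs columns: n_trials, n_go, p_go, valid, then one column per level.
// Throws when the cell-Peclet guard |mu| dx < 2 is violated.
// [[Rcpp::export]]
double wls_loss_cpp(NumericVector tta0s, NumericVector d0s,
                    NumericMatrix obs, NumericVector levels,
                    double alpha, double beta_w, double theta_crit,
                    double b0, double kk, double tau,
                    double mu_nd, double sigma_nd, double drift_const,
                    int variant, double w_p, double w_q,
                    double dt, double dx, int n_startup = 8) {
  const int nl = levels.size();
  double loss = 0.0;
  std::vector<double> mu, bb, go_flux, dens, cdf;
  for (int c = 0; c < tta0s.size(); ++c) {
    const double tta0 = tta0s[c], d0 = d0s[c], v = d0 / tta0;
    const int nt = (int)std::ceil(tta0 / dt);
    mu.resize(nt + 1);
    bb.resize(nt + 1);
    for (int n = 0; n <= nt; ++n) {
      const double t = n * dt;
      if (variant == 2) {
        mu[n] = drift_const;
      } else {
        const double tta = std::max(tta0 - t, 0.0);
        const double d = std::max(d0 - v * t, 0.0);
        mu[n] = alpha * ((tta + beta_w * d) - theta_crit);
      }
      bb[n] = (variant == 0)
        ? b0 / (1.0 + std::exp(-kk * ((tta0 - t) - tau)))
        : b0;
      if (std::fabs(mu[n]) * dx >= 2.0)
        stop("grid resolution insufficient for this drift magnitude");
    }
    const double p_go = solve_core(mu, bb, dt, dx, b0, n_startup, go_flux);
    loss += w_p * obs(c, 0) * (obs(c, 2) - p_go) * (obs(c, 2) - p_go);
    if (obs(c, 3) > 0.5 && p_go >= 1e-4) {
      // observed-RT density: convolve with the zero-truncated normal kernel
      if (sigma_nd <= 0) {
        int shift = (int)std::lround(std::max(mu_nd, 0.0) / dt);
        dens.assign(nt + shift, 0.0);
        for (int i = 0; i < nt; ++i)
          dens[i + shift] = go_flux[i] > 0 ? go_flux[i] : 0;
      } else {
        const int K = (int)std::ceil((std::max(mu_nd, 0.0) + 6 * sigma_nd) / dt);
        std::vector<double> w(K + 1);
        double sw = 0;
        for (int i = 0; i <= K; ++i) {
          double z = (i * dt - mu_nd) / sigma_nd;
          w[i] = std::exp(-0.5 * z * z);
          sw += w[i];
        }
        for (int i = 0; i <= K; ++i) w[i] /= sw;
        dens.assign(nt + K, 0.0);
        for (int i = 0; i < nt; ++i) {
          const double g = go_flux[i];
          if (g <= 0) continue;
          for (int j = 0; j <= K; ++j) dens[i + j] += g * w[j];
        }
      }
      const int m = dens.size();
      cdf.resize(m);
      double acc = 0;
      for (int i = 0; i < m; ++i) { acc += dens[i] * dt; cdf[i] = acc / p_go; }
      double qsum = 0.0;
      for (int l = 0; l < nl; ++l) {
        const double L = levels[l];
        double q;
        if (L <= cdf[0]) q = dt;
        else if (L >= cdf[m - 1]) q = m * dt;
        else {
          int lo = 0, hi = m - 1;
          while (hi - lo > 1) {
            int mid = (lo + hi) / 2;
            if (cdf[mid] < L) lo = mid; else hi = mid;
          }
          const double t0 = (lo + 1) * dt, t1 = (hi + 1) * dt;
          q = cdf[hi] > cdf[lo]
            ? t0 + (t1 - t0) * (L - cdf[lo]) / (cdf[hi] - cdf[lo]) : t0;
        }
        const double d = obs(c, 4 + l) - q;
        qsum += d * d;
      }
      loss += w_q * obs(c, 1) * qsum;
    }
  }
  return loss;
}
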