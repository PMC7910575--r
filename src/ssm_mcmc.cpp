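// Metropolis-within-Gibbs sampler for the two-state (swimming/hidden)
// home-range state-space model.
//
// Latent structure: positions pos[n] and states S[n] (0 = swimming,
// 1 = hidden internally).  A hidden step keeps the previous position
// exactly, so the position path is piecewise constant over "segments"
// that start at step 0 and at every swimming step.  Moves:
//   * random-walk Metropolis on each continuous parameter
//     (centre x/y, log k, radius, d50, log(-slope), 8 logits of p/q);
//   * random-walk shifts of whole segments of the position path;
//   * joint state+position flips: hidden->swimming proposes the new
//     position from the BRW forward density (whose density then cancels
//     the new movement term in the acceptance ratio), swimming->hidden
//     collapses the segment onto the previous position (reverse proposal
//     cancels the removed movement term);
//   * an exact Gibbs draw for the first state, whose position is
//     unconstrained either way.
// Proposal scales adapt towards ~30% acceptance during burn-in only.
// All randomness comes from R's RNG, so set.seed() makes runs exact.

#include <Rcpp.h>
#include <cmath>
#include <vector>
using namespace Rcpp;

static const double CHI2_95_2 = 5.991464547107979; // qchisq(.95, 2)

struct Priors {
  double c0x, c0y, cr;       // centre disc
  double k_shape, k_scale;
  double r_lo, r_hi;         // radius
  double d_lo, d_hi;         // d50
  double ls_mu, ls_sd;       // log(-slope)
  double e_mu, e_sd, e_lo, e_hi; // eta (logit p/q)
};

struct Model {
  int N, R, m;
  double dt;
  const int *counts;         // N x R column-major
  std::vector<double> rx, ry;
  std::vector<int> cell;     // covariate cell per step (0..3)
  std::vector<double> lchoose_tab; // lchoose(m, counts), N x R
  bool prior_only;
  Priors pr;

  // current configuration
  double cx, cy, lk, radius, d50, ls;
  double eta[8];
  std::vector<double> px, py;
  std::vector<int> S;        // 0 swim, 1 hidden
  std::vector<double> obsll; // per-step detection loglik cache
  // derived
  double k, slope, kdt, stepvar, statvar;
  double lT[4][2][2];        // log transition probs per cell

  void refresh_movement() {
    k = std::exp(lk);
    kdt = k * dt;
    // discrete-time calibration: stationary per-axis variance is exactly
    // radius^2 / chisq, making radius the 95% stationary distance quantile
    stepvar = kdt * (2.0 - kdt) * radius * radius / CHI2_95_2;
    statvar = radius * radius / CHI2_95_2;
  }
  void refresh_detection() { slope = -std::exp(ls); }
  void refresh_transitions() {
    for (int c = 0; c < 4; ++c) {
      double ep = eta[2 * c], eq = eta[2 * c + 1];
      lT[c][0][0] = -std::log1p(std::exp(-ep));        // log p
      lT[c][0][1] = -ep - std::log1p(std::exp(-ep));   // log(1-p)
      lT[c][1][1] = -std::log1p(std::exp(-eq));        // log q
      lT[c][1][0] = -eq - std::log1p(std::exp(-eq));   // log(1-q)
    }
  }

  double obs_loglik_at(int n, double x, double y) const {
    if (prior_only) return 0.0;
    double ll = 0.0;
    for (int r = 0; r < R; ++r) {
      double dx = x - rx[r], dy = y - ry[r];
      double d = std::sqrt(dx * dx + dy * dy);
      double z = slope * (d - d50);
      // log plogis(z) and log(1 - plogis(z)), stable
      double lp = (z > 0) ? -std::log1p(std::exp(-z)) : z - std::log1p(std::exp(z));
      double lq = lp - z;
      int yobs = counts[n + (size_t)r * N];
      ll += lchoose_tab[n + (size_t)r * N] + yobs * lp + (m - yobs) * lq;
    }
    return ll;
  }

  double lnorm2(double x, double y, double mx, double my, double v) const {
    double dx = x - mx, dy = y - my;
    return -std::log(2.0 * M_PI * v) - (dx * dx + dy * dy) / (2.0 * v);
  }
  // BRW transition density of (x,y) from (fx,fy)
  double lmove(double fx, double fy, double x, double y) const {
    return lnorm2(x, y, fx + kdt * (cx - fx), fy + kdt * (cy - fy), stepvar);
  }
  double linit(double x, double y) const {
    return lnorm2(x, y, cx, cy, statvar);
  }

  double log_prior() const {
    const Priors &p = pr;
    if (radius < p.r_lo || radius > p.r_hi) return R_NegInf;
    if (d50 < p.d_lo || d50 > p.d_hi) return R_NegInf;
    if (!(k > 0) || kdt >= 1.0) return R_NegInf;
    double ddx = cx - p.c0x, ddy = cy - p.c0y;
    if (ddx * ddx + ddy * ddy > p.cr * p.cr) return R_NegInf;
    double lp = -std::log(M_PI * p.cr * p.cr)
              - std::log(p.r_hi - p.r_lo)
              - std::log(p.d_hi - p.d_lo);
    lp += R::dgamma(k, p.k_shape, p.k_scale, 1) + lk; // log-scale Jacobian
    lp += R::dnorm(ls, p.ls_mu, p.ls_sd, 1);
    double z = R::pnorm(p.e_hi, p.e_mu, p.e_sd, 1, 0)
             - R::pnorm(p.e_lo, p.e_mu, p.e_sd, 1, 0);
    for (int j = 0; j < 8; ++j) {
      if (eta[j] < p.e_lo || eta[j] > p.e_hi) return R_NegInf;
      lp += R::dnorm(eta[j], p.e_mu, p.e_sd, 1) - std::log(z);
    }
    return lp;
  }

  double chain_loglik() const {
    double ll = std::log(0.5);
    for (int n = 1; n < N; ++n) ll += lT[cell[n]][S[n - 1]][S[n]];
    return ll;
  }
  double movement_loglik() const {
    double ll = linit(px[0], py[0]);
    for (int n = 1; n < N; ++n)
      if (S[n] == 0) ll += lmove(px[n - 1], py[n - 1], px[n], py[n]);
    return ll;
  }
  double obs_total() const {
    double s = 0.0;
    for (int n = 0; n < N; ++n) s += obsll[n];
    return s;
  }
  double full_log_density() const {
    double lp = log_prior();
    if (!R_finite(lp)) return R_NegInf;
    return lp + chain_loglik() + movement_loglik() + obs_total();
  }
  void refresh_obs() {
    for (int n = 0; n < N; ++n) obsll[n] = obs_loglik_at(n, px[n], py[n]);
  }

  // two-step BRW transition density (hidden block of any length between
  // two swimming steps collapses the movement terms to entering/leaving,
  // and the bridge proposal integrates the entering position out)
  double lmove2(double fx, double fy, double x, double y) const {
    double g = 1.0 - kdt;
    double mx = g * g * fx + (1.0 - g * g) * cx;
    double my = g * g * fy + (1.0 - g * g) * cy;
    return lnorm2(x, y, mx, my, stepvar * (1.0 + g * g));
  }
};

// adaptive scale bookkeeping
struct Adapt {
  double scale;
  int tries = 0, acc = 0;
  void tune() {
    if (tries == 0) return;
    double rate = (double)acc / tries;
    if (rate > 0.3) scale *= 1.4; else scale /= 1.4;
    if (scale < 1e-8) scale = 1e-8;
    if (scale > 1e6) scale = 1e6;
    tries = acc = 0;
  }
};

// [[Rcpp::export]]
List ssm_mcmc_chain(IntegerMatrix counts, NumericVector rx, NumericVector ry,
                    IntegerVector cells, int m, double dt,
                    NumericVector priors, NumericVector init,
                    NumericMatrix pos0, IntegerVector states0,
                    int n_iter, int burn_in, int thin, bool prior_only) {
  Model mod;
  mod.N = counts.nrow();
  mod.R = counts.ncol();
  mod.m = m;
  mod.dt = dt;
  mod.counts = counts.begin();
  mod.rx.assign(rx.begin(), rx.end());
  mod.ry.assign(ry.begin(), ry.end());
  mod.cell.assign(cells.begin(), cells.end());
  mod.prior_only = prior_only;
  Priors &p = mod.pr;
  p.c0x = priors[0]; p.c0y = priors[1]; p.cr = priors[2];
  p.k_shape = priors[3]; p.k_scale = priors[4];
  p.r_lo = priors[5]; p.r_hi = priors[6];
  p.d_lo = priors[7]; p.d_hi = priors[8];
  p.ls_mu = priors[9]; p.ls_sd = priors[10];
  p.e_mu = priors[11]; p.e_sd = priors[12];
  p.e_lo = priors[13]; p.e_hi = priors[14];

  const int N = mod.N, R = mod.R;
  mod.lchoose_tab.resize((size_t)N * R);
  for (int r = 0; r < R; ++r)
    for (int n = 0; n < N; ++n)
      mod.lchoose_tab[n + (size_t)r * N] =
        R::lchoose(m, counts(n, r));

  mod.cx = init[0]; mod.cy = init[1]; mod.lk = init[2];
  mod.radius = init[3]; mod.d50 = init[4]; mod.ls = init[5];
  for (int j = 0; j < 8; ++j) mod.eta[j] = init[6 + j];
  mod.px.resize(N); mod.py.resize(N); mod.S.resize(N);
  for (int n = 0; n < N; ++n) {
    mod.px[n] = pos0(n, 0);
    mod.py[n] = pos0(n, 1);
    mod.S[n] = states0[n] - 1;  // public 1/2 -> internal 0/1
    if (n > 0 && mod.S[n] == 1 &&
        (mod.px[n] != mod.px[n - 1] || mod.py[n] != mod.py[n - 1])) {
      stop("initial hidden step with a position change");
    }
  }
  mod.obsll.resize(N);
  mod.refresh_movement();
  mod.refresh_detection();
  mod.refresh_transitions();
  mod.refresh_obs();

  if (!R_finite(mod.full_log_density())) {
    return List::create(_["ok"] = false);
  }

  // proposal scales: 0..1 centre, 2 log k, 3 radius, 4 d50, 5 log(-slope),
  // 6..13 eta, 14 segment position shift
  std::vector<Adapt> ad(18);
  ad[0].scale = ad[1].scale = 25.0;
  ad[2].scale = 0.3;
  ad[3].scale = 25.0;
  ad[4].scale = 25.0;
  ad[5].scale = 0.2;
  for (int j = 6; j < 14; ++j) ad[j].scale = 0.8;
  ad[14].scale = 20.0;
  ad[15].scale = 0.05;   // radius-path scaling (log scale)
  ad[16].scale = 10.0;   // centre-path translation (m)
  ad[17].scale = 0.1;    // k-displacement scaling (log-k scale)

  int n_keep = (n_iter - burn_in) / thin;
  NumericMatrix draws(n_keep, 14);
  NumericVector logdens(n_keep);
  int kept = 0;

  RNGScope rng;
  std::vector<double> newobs(N);

  for (int iter = 0; iter < n_iter; ++iter) {
    // --- continuous parameters ----------------------------------------
    // the detection parameters mix fastest and cost a full detection
    // pass, so they are updated on alternate iterations
    for (int j = 0; j < 14; ++j) {
      if ((j == 4 || j == 5) && iter % 2 == 1) continue;
      Adapt &a = ad[j];
      a.tries++;
      double step = a.scale * R::norm_rand();
      double lp_old = mod.log_prior();
      double delta;
      if (j <= 3) {           // movement block parameter
        double mv_old = mod.movement_loglik();
        double keep = (j == 0) ? mod.cx : (j == 1) ? mod.cy
                    : (j == 2) ? mod.lk : mod.radius;
        double *tgt = (j == 0) ? &mod.cx : (j == 1) ? &mod.cy
                    : (j == 2) ? &mod.lk : &mod.radius;
        *tgt = keep + step;
        mod.refresh_movement();
        double lp_new = mod.log_prior();
        delta = R_finite(lp_new)
              ? (lp_new - lp_old) + (mod.movement_loglik() - mv_old)
              : R_NegInf;
        if (R_finite(delta) && std::log(R::unif_rand()) < delta) {
          a.acc++;
        } else {
          *tgt = keep;
          mod.refresh_movement();
        }
      } else if (j == 4 || j == 5) { // detection parameter
        double keep = (j == 4) ? mod.d50 : mod.ls;
        double *tgt = (j == 4) ? &mod.d50 : &mod.ls;
        double obs_old = mod.obs_total();
        *tgt = keep + step;
        mod.refresh_detection();
        double lp_new = mod.log_prior();
        if (!R_finite(lp_new)) {
          *tgt = keep; mod.refresh_detection();
        } else {
          double obs_new = 0.0;
          for (int n = 0; n < N; ++n) {
            newobs[n] = mod.obs_loglik_at(n, mod.px[n], mod.py[n]);
            obs_new += newobs[n];
          }
          delta = (lp_new - lp_old) + (obs_new - obs_old);
          if (std::log(R::unif_rand()) < delta) {
            a.acc++;
            std::copy(newobs.begin(), newobs.end(), mod.obsll.begin());
          } else {
            *tgt = keep; mod.refresh_detection();
          }
        }
      } else {                 // eta (logit p or q)
        int e = j - 6;
        double keep = mod.eta[e];
        double ch_old = mod.chain_loglik();
        bool indep = R::unif_rand() < 0.5;
        if (indep) {
          // independence proposal from the truncated-normal prior; the
          // prior and proposal densities cancel in the ratio.  Essential
          // for weakly-informed cells whose posterior spans the whole
          // bathtub-shaped probability prior
          double plo = R::pnorm(p.e_lo, p.e_mu, p.e_sd, 1, 0);
          double phi = R::pnorm(p.e_hi, p.e_mu, p.e_sd, 1, 0);
          double u = plo + R::unif_rand() * (phi - plo);
          mod.eta[e] = R::qnorm(u, p.e_mu, p.e_sd, 1, 0);
          mod.refresh_transitions();
          delta = mod.chain_loglik() - ch_old;
        } else {
          mod.eta[e] = keep + step;
          mod.refresh_transitions();
          double lp_new = mod.log_prior();
          delta = R_finite(lp_new)
                ? (lp_new - lp_old) + (mod.chain_loglik() - ch_old)
                : R_NegInf;
        }
        if (indep) a.tries--;  // adapt the RW scale on RW proposals only
        if (R_finite(delta) && std::log(R::unif_rand()) < delta) {
          if (!indep) a.acc++;
        } else {
          mod.eta[e] = keep;
          mod.refresh_transitions();
        }
      }
    }

    // --- segment position shifts --------------------------------------
    {
      Adapt &a = ad[14];
      int start = 0;
      while (start < N) {
        int end = start;  // segment [start, end]
        while (end + 1 < N && mod.S[end + 1] == 1) ++end;
        a.tries++;
        double nx = mod.px[start] + a.scale * R::norm_rand();
        double ny = mod.py[start] + a.scale * R::norm_rand();
        double delta = 0.0;
        if (start == 0) {
          delta += mod.linit(nx, ny) - mod.linit(mod.px[0], mod.py[0]);
        } else {
          delta += mod.lmove(mod.px[start - 1], mod.py[start - 1], nx, ny)
                 - mod.lmove(mod.px[start - 1], mod.py[start - 1],
                             mod.px[start], mod.py[start]);
        }
        if (end + 1 < N) { // next step is a swimming step by construction
          delta += mod.lmove(nx, ny, mod.px[end + 1], mod.py[end + 1])
                 - mod.lmove(mod.px[start], mod.py[start],
                             mod.px[end + 1], mod.py[end + 1]);
        }
        double obs_new_tot = 0.0;
        for (int n2 = start; n2 <= end; ++n2) {
          newobs[n2] = mod.obs_loglik_at(n2, nx, ny);
          obs_new_tot += newobs[n2] - mod.obsll[n2];
        }
        delta += obs_new_tot;
        if (std::log(R::unif_rand()) < delta) {
          a.acc++;
          for (int n2 = start; n2 <= end; ++n2) {
            mod.px[n2] = nx; mod.py[n2] = ny; mod.obsll[n2] = newobs[n2];
          }
        }
        start = end + 1;
      }
    }

    // --- state updates -------------------------------------------------
    if (N > 1) {
      // Gibbs draw for the first state: only the first chain term depends
      // on it (its position is free either way)
      double l0 = mod.lT[mod.cell[1]][0][mod.S[1]];
      double l1 = mod.lT[mod.cell[1]][1][mod.S[1]];
      double p0 = 1.0 / (1.0 + std::exp(l1 - l0));
      mod.S[0] = (R::unif_rand() < p0) ? 0 : 1;

      for (int n = 1; n < N; ++n) {
        int s = mod.S[n], snew = 1 - s;
        // M: next position-change index after n (or N)
        int M = n + 1;
        while (M < N && mod.S[M] == 1) ++M;
        double delta = mod.lT[mod.cell[n]][mod.S[n - 1]][snew]
                     - mod.lT[mod.cell[n]][mod.S[n - 1]][s];
        if (n + 1 < N) {
          delta += mod.lT[mod.cell[n + 1]][snew][mod.S[n + 1]]
                 - mod.lT[mod.cell[n + 1]][s][mod.S[n + 1]];
        }
        double fx = mod.px[n - 1], fy = mod.py[n - 1];
        // movement part of the ratio: with the bridge proposal for the
        // inserted position, inserting a swimming step replaces the
        // one-step density to the next swimming position by the two-step
        // density (and vice versa when deleting)
        if (M < N) {
          double l2 = mod.lmove2(fx, fy, mod.px[M], mod.py[M]);
          double l1 = mod.lmove(fx, fy, mod.px[M], mod.py[M]);
          delta += (s == 1) ? (l2 - l1) : (l1 - l2);
        }
        if (s == 1) {
          // hidden -> swimming: propose the block position from the
          // Gaussian bridge given the neighbouring positions
          double nx, ny;
          double g = 1.0 - mod.kdt;
          if (M < N) {
            double tau = (1.0 + g * g);
            double v = mod.stepvar / tau;
            double ax = fx + mod.kdt * (mod.cx - fx);
            double ay = fy + mod.kdt * (mod.cy - fy);
            double mx = (ax + g * (mod.px[M] - mod.kdt * mod.cx)) / tau;
            double my = (ay + g * (mod.py[M] - mod.kdt * mod.cy)) / tau;
            nx = mx + std::sqrt(v) * R::norm_rand();
            ny = my + std::sqrt(v) * R::norm_rand();
          } else {
            double sd = std::sqrt(mod.stepvar);
            nx = fx + mod.kdt * (mod.cx - fx) + sd * R::norm_rand();
            ny = fy + mod.kdt * (mod.cy - fy) + sd * R::norm_rand();
          }
          double dobs = 0.0;
          for (int n2 = n; n2 < M; ++n2) {
            newobs[n2] = mod.obs_loglik_at(n2, nx, ny);
            dobs += newobs[n2] - mod.obsll[n2];
          }
          delta += dobs;
          if (std::log(R::unif_rand()) < delta) {
            mod.S[n] = 0;
            for (int n2 = n; n2 < M; ++n2) {
              mod.px[n2] = nx; mod.py[n2] = ny; mod.obsll[n2] = newobs[n2];
            }
          }
        } else {
          // swimming -> hidden: collapse the block onto the previous
          // position (deterministic down-move of the bridge pair)
          double dobs = 0.0;
          for (int n2 = n; n2 < M; ++n2) {
            newobs[n2] = mod.obs_loglik_at(n2, fx, fy);
            dobs += newobs[n2] - mod.obsll[n2];
          }
          delta += dobs;
          if (std::log(R::unif_rand()) < delta) {
            mod.S[n] = 1;
            for (int n2 = n; n2 < M; ++n2) {
              mod.px[n2] = fx; mod.py[n2] = fy; mod.obsll[n2] = newobs[n2];
            }
          }
        }
      }
    }

    // --- run-boundary shifts -------------------------------------------
    // swapping an adjacent (swim, hidden) pair slides the boundary of a
    // hidden run by one step; the block position is carried over, so the
    // movement densities cancel and only chain and detection terms remain
    for (int sweep = 0; sweep < 2 && N > 2; ++sweep) {
      for (int n = 1; n + 1 < N; ++n) {
        int s0 = mod.S[n], s1 = mod.S[n + 1];
        if (s0 == s1) continue;
        double delta = mod.lT[mod.cell[n]][mod.S[n - 1]][s1]
                     - mod.lT[mod.cell[n]][mod.S[n - 1]][s0]
                     + mod.lT[mod.cell[n + 1]][s1][s0]
                     - mod.lT[mod.cell[n + 1]][s0][s1];
        if (n + 2 < N) {
          delta += mod.lT[mod.cell[n + 2]][s0][mod.S[n + 2]]
                 - mod.lT[mod.cell[n + 2]][s1][mod.S[n + 2]];
        }
        // the step that changes position: swim->hidden joins the previous
        // block, hidden->swim adopts the next block's position
        double tx, ty;
        if (s0 == 0) { tx = mod.px[n - 1]; ty = mod.py[n - 1]; }
        else         { tx = mod.px[n + 1]; ty = mod.py[n + 1]; }
        double onew = mod.obs_loglik_at(n, tx, ty);
        delta += onew - mod.obsll[n];
        if (std::log(R::unif_rand()) < delta) {
          mod.S[n] = s1; mod.S[n + 1] = s0;
          mod.px[n] = tx; mod.py[n] = ty;
          mod.obsll[n] = onew;
        }
      }
    }

    // --- group moves (each costs a full detection pass; alternating
    // them halves that cost with little loss of mixing) -----------------
    if (iter % 2 == 0) {
    // (a) scale radius and the whole position path about the centre; the
    // movement-density change cancels the position Jacobian, so this
    // explores the (radius, path) ridge efficiently
    {
      Adapt &a = ad[15];
      a.tries++;
      double eps = a.scale * R::norm_rand();
      double f = std::exp(eps);
      double r_old = mod.radius, lp_old = mod.log_prior();
      double mv_old = mod.movement_loglik();
      std::vector<double> ox = mod.px, oy = mod.py;
      int n_seg = 1;
      for (int n = 1; n < N; ++n) if (mod.S[n] == 0) ++n_seg;
      mod.radius = f * r_old;
      mod.refresh_movement();
      double lp_new = mod.log_prior();
      bool acc = false;
      if (R_finite(lp_new)) {
        for (int n = 0; n < N; ++n) {
          mod.px[n] = mod.cx + f * (ox[n] - mod.cx);
          mod.py[n] = mod.cy + f * (oy[n] - mod.cy);
        }
        double dobs = 0.0;
        for (int n = 0; n < N; ++n) {
          newobs[n] = mod.obs_loglik_at(n, mod.px[n], mod.py[n]);
          dobs += newobs[n] - mod.obsll[n];
        }
        double delta = (lp_new - lp_old) + (mod.movement_loglik() - mv_old)
                     + dobs + (2.0 * n_seg + 1.0) * eps;
        if (std::log(R::unif_rand()) < delta) {
          acc = true;
          a.acc++;
          std::copy(newobs.begin(), newobs.end(), mod.obsll.begin());
        }
      }
      if (!acc) {
        mod.radius = r_old;
        mod.refresh_movement();
        mod.px = ox; mod.py = oy;
      }
    }
    // (b) scale k jointly with the swimming displacements: residuals are
    // carried over standardised, so the movement-density change cancels
    // the Jacobian and k can move without fighting the current path
    // roughness (k's conditional given the path is far narrower than its
    // marginal posterior)
    {
      Adapt &a = ad[17];
      a.tries++;
      double eps = a.scale * R::norm_rand();
      double lk_old = mod.lk, lp_old = mod.log_prior();
      double kdt_old = mod.kdt, sv_old = mod.stepvar;
      std::vector<double> ox = mod.px, oy = mod.py;
      mod.lk = lk_old + eps;
      mod.refresh_movement();
      double lp_new = mod.log_prior();
      bool acc = false;
      if (R_finite(lp_new)) {
        double ratio = std::sqrt(mod.stepvar / sv_old);
        double dobs = 0.0;
        for (int n = 1; n < N; ++n) {
          if (mod.S[n] == 0) {
            double ex = ox[n] - (ox[n - 1] + kdt_old * (mod.cx - ox[n - 1]));
            double ey = oy[n] - (oy[n - 1] + kdt_old * (mod.cy - oy[n - 1]));
            mod.px[n] = mod.px[n - 1] + mod.kdt * (mod.cx - mod.px[n - 1])
                      + ratio * ex;
            mod.py[n] = mod.py[n - 1] + mod.kdt * (mod.cy - mod.py[n - 1])
                      + ratio * ey;
          } else {
            mod.px[n] = mod.px[n - 1];
            mod.py[n] = mod.py[n - 1];
          }
        }
        for (int n = 0; n < N; ++n) {
          newobs[n] = mod.obs_loglik_at(n, mod.px[n], mod.py[n]);
          dobs += newobs[n] - mod.obsll[n];
        }
        double delta = (lp_new - lp_old) + dobs;
        if (std::log(R::unif_rand()) < delta) {
          acc = true;
          a.acc++;
          std::copy(newobs.begin(), newobs.end(), mod.obsll.begin());
        }
      }
      if (!acc) {
        mod.lk = lk_old;
        mod.refresh_movement();
        mod.px = ox; mod.py = oy;
      }
    }
    } else {
    // (c) translate the centre and the whole path together; the movement
    // density is translation-invariant
    {
      Adapt &a = ad[16];
      a.tries++;
      double dx = a.scale * R::norm_rand(), dy = a.scale * R::norm_rand();
      double lp_old = mod.log_prior();
      mod.cx += dx; mod.cy += dy;
      double lp_new = mod.log_prior();
      bool acc = false;
      if (R_finite(lp_new)) {
        double dobs = 0.0;
        for (int n = 0; n < N; ++n) {
          newobs[n] = mod.obs_loglik_at(n, mod.px[n] + dx, mod.py[n] + dy);
          dobs += newobs[n] - mod.obsll[n];
        }
        double delta = (lp_new - lp_old) + dobs;
        if (std::log(R::unif_rand()) < delta) {
          acc = true;
          a.acc++;
          for (int n = 0; n < N; ++n) {
            mod.px[n] += dx; mod.py[n] += dy; mod.obsll[n] = newobs[n];
          }
        }
      }
      if (!acc) { mod.cx -= dx; mod.cy -= dy; }
    }
    }

    // --- adaptation (burn-in only) ------------------------------------
    if (iter < burn_in && (iter + 1) % 50 == 0) {
      for (auto &a : ad) a.tune();
    }

    // --- record --------------------------------------------------------
    if (iter >= burn_in && (iter - burn_in + 1) % thin == 0 && kept < n_keep) {
      draws(kept, 0) = mod.cx;
      draws(kept, 1) = mod.cy;
      draws(kept, 2) = std::exp(mod.lk);
      draws(kept, 3) = mod.radius;
      draws(kept, 4) = mod.d50;
      draws(kept, 5) = -std::exp(mod.ls);
      for (int j = 0; j < 8; ++j)
        draws(kept, 6 + j) = 1.0 / (1.0 + std::exp(-mod.eta[j]));
      logdens[kept] = mod.full_log_density();
      ++kept;
    }
  }

  IntegerVector Sout(N);
  NumericMatrix posout(N, 2);
  for (int n = 0; n < N; ++n) {
    Sout[n] = mod.S[n] + 1;  // public 1/2 coding
    posout(n, 0) = mod.px[n];
    posout(n, 1) = mod.py[n];
  }
  return List::create(_["ok"] = true, _["draws"] = draws,
                      _["log_density"] = logdens,
                      _["final_states"] = Sout, _["final_positions"] = posout);
}

// Joint log density for an arbitrary configuration; mirrors the sampler's
// target so the R reference implementation can be checked against it.
// states use the public 1/2 coding.
// [[Rcpp::export]]
double ssm_joint_loglik_cpp(IntegerMatrix counts, NumericVector rx,
                            NumericVector ry, IntegerVector cells, int m,
                            double dt, NumericVector priors,
                            NumericVector params, NumericMatrix pos,
                            IntegerVector states, bool prior_only) {
  Model mod;
  mod.N = counts.nrow();
  mod.R = counts.ncol();
  mod.m = m;
  mod.dt = dt;
  mod.counts = counts.begin();
  mod.rx.assign(rx.begin(), rx.end());
  mod.ry.assign(ry.begin(), ry.end());
  mod.cell.assign(cells.begin(), cells.end());
  mod.prior_only = prior_only;
  Priors &p = mod.pr;
  p.c0x = priors[0]; p.c0y = priors[1]; p.cr = priors[2];
  p.k_shape = priors[3]; p.k_scale = priors[4];
  p.r_lo = priors[5]; p.r_hi = priors[6];
  p.d_lo = priors[7]; p.d_hi = priors[8];
  p.ls_mu = priors[9]; p.ls_sd = priors[10];
  p.e_mu = priors[11]; p.e_sd = priors[12];
  p.e_lo = priors[13]; p.e_hi = priors[14];
  const int N = mod.N, R = mod.R;
  mod.lchoose_tab.resize((size_t)N * R);
  for (int r = 0; r < R; ++r)
    for (int n = 0; n < N; ++n)
      mod.lchoose_tab[n + (size_t)r * N] = R::lchoose(m, counts(n, r));
  mod.cx = params[0]; mod.cy = params[1]; mod.lk = params[2];
  mod.radius = params[3]; mod.d50 = params[4]; mod.ls = params[5];
  for (int j = 0; j < 8; ++j) mod.eta[j] = params[6 + j];
  mod.px.resize(N); mod.py.resize(N); mod.S.resize(N);
  for (int n = 0; n < N; ++n) {
    mod.px[n] = pos(n, 0); mod.py[n] = pos(n, 1);
    mod.S[n] = states[n] - 1;
  }
  mod.refresh_movement();
  mod.refresh_detection();
  mod.refresh_transitions();
  // hidden steps must keep the previous position exactly
  for (int n = 1; n < N; ++n) {
    if (mod.S[n] == 1 &&
        (mod.px[n] != mod.px[n - 1] || mod.py[n] != mod.py[n - 1])) {
      return R_NegInf;
    }
  }
  mod.obsll.resize(N);
  mod.refresh_obs();
  return mod.full_log_density();
}
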