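#include <Rcpp.h>
#include <vector>
#include <cmath>
#include <algorithm>
using namespace Rcpp;

// Step-by-step Brownian dynamics of a reacting point-particle population.
// Units: positions nm, diffusion coefficients nm^2/s, time s.
//
// Each step of length dt displaces every molecule by an isotropic Gaussian
// (per-axis variance 2 D dt).  A pair reacts when it ends the step inside
// its encounter radius, or -- with the Brownian-bridge crossing probability
// exp(-(d0 - R)(d1 - R) / (D' dt)) -- when an encounter during the step went
// unobserved.  Nearest pairs win when partners are contested.  First-order
// channels (implicit-water reactions, scavengers) fire with probability
// 1 - exp(-lambda dt).

struct Cand {
  double d1;   // post-step distance
  double d0;   // pre-step distance
  int i, j, rx;
};

static inline double min_image(double d, double box) {
  if (box > 0.0) d -= box * std::round(d / box);
  return d;
}

static inline double wrap(double x, double box) {
  // floor-based wrap (avoids fmod, which needs a newer libm than some
  // runtime environments provide)
  if (box > 0.0) x -= box * std::floor(x / box);
  return x;
}

// [[Rcpp::export]]
List bd_engine_cpp(NumericMatrix pos0, IntegerVector spec0,
                   NumericVector D_nm2s, IntegerMatrix pair_rx,
                   NumericVector rx_radius, IntegerMatrix rx_prod,
                   List sp_unary_rx, List sp_unary_rate,
                   NumericVector sp_scav,
                   double t_start, double t_end,
                   double dt_min, double dt_max, double dt_growth,
                   double box, bool bridge,
                   bool adaptive, double adapt_factor,
                   NumericVector snap_times, bool record_positions) {
  const int ns = D_nm2s.size();
  const int nrx = rx_radius.size();
  int n = pos0.nrow();

  std::vector<double> X(n), Y(n), Z(n);
  std::vector<int> SP(n);
  std::vector<char> AL(n, 1);
  for (int i = 0; i < n; ++i) {
    X[i] = wrap(pos0(i, 0), box);
    Y[i] = wrap(pos0(i, 1), box);
    Z[i] = wrap(pos0(i, 2), box);
    SP[i] = spec0[i];
  }

  // per-species first-order channel bookkeeping
  std::vector<double> lam_tot(ns, 0.0);
  std::vector< std::vector<int> > ch_rx(ns);
  std::vector< std::vector<double> > ch_rate(ns);
  for (int s = 0; s < ns; ++s) {
    IntegerVector rxs = sp_unary_rx[s];
    NumericVector rts = sp_unary_rate[s];
    for (int k = 0; k < rxs.size(); ++k) {
      ch_rx[s].push_back(rxs[k]);
      ch_rate[s].push_back(rts[k]);
      lam_tot[s] += rts[k];
    }
    lam_tot[s] += sp_scav[s];
  }

  double Rmax = 0.0, Dmax = 0.0;
  for (int r = 0; r < nrx; ++r) Rmax = std::max(Rmax, rx_radius[r]);
  for (int s = 0; s < ns; ++s) Dmax = std::max(Dmax, D_nm2s[s]);
  bool any_pair = false;
  for (int a = 0; a < ns && !any_pair; ++a)
    for (int b = 0; b < ns; ++b)
      if (pair_rx(a, b) >= 0) { any_pair = true; break; }

  // cell list (periodic box only), sized from the worst-case reach
  double reach_max = Rmax +
    (bridge ? 6.0 * std::sqrt(4.0 * Dmax * dt_max) : 1e-6);
  int nc = 0;
  std::vector<int> head, nxt, cell_of, touched;
  bool use_cells = false;
  if (box > 0.0 && any_pair) {
    nc = (int)std::floor(box / std::max(reach_max, box / 80.0));
    if (nc > 80) nc = 80;
    if (nc >= 4) {
      use_cells = true;
      head.assign((size_t)nc * nc * nc, -1);
    }
  }

  std::vector<double> ev_t; std::vector<int> ev_rx;
  std::vector<double> sc_t; std::vector<int> sc_sp;
  std::vector<double> pX, pY, pZ;
  List snaps;
  int snap_i = 0;
  const int n_snap = snap_times.size();

  std::vector<Cand> cands;

  // dynamic step cap: no reactive pair may diffuse across its gap within
  // one step (keeps the per-step bridge approximation valid); updated from
  // each step's candidate scan, conservatively seeded
  double pair_cap = dt_min;
  const double Dp_max = 2.0 * Dmax;

  double t = t_start;
  while (t < t_end * (1.0 - 1e-12) && t < t_end) {
    double dt = std::min(dt_max, std::max(dt_min, dt_growth * t));
    if (adaptive && any_pair) dt = std::min(dt, std::max(dt_min, pair_cap));
    if (t + dt > t_end) dt = t_end - t;
    if (record_positions && snap_i < n_snap &&
        t + dt > snap_times[snap_i] && snap_times[snap_i] > t) {
      dt = snap_times[snap_i] - t;
    }
    const int n_step = (int)X.size();
    if (bridge) { pX = X; pY = Y; pZ = Z; }

    for (int i = 0; i < n_step; ++i) {
      if (!AL[i]) continue;
      double sd = std::sqrt(2.0 * D_nm2s[SP[i]] * dt);
      X[i] = wrap(X[i] + norm_rand() * sd, box);
      Y[i] = wrap(Y[i] + norm_rand() * sd, box);
      Z[i] = wrap(Z[i] + norm_rand() * sd, box);
    }
    double tn = t + dt;

    // --- pair reactions -------------------------------------------------
    if (any_pair) {
      double reach = Rmax +
        (bridge ? 6.0 * std::sqrt(4.0 * Dmax * dt) : 1e-9);
      if (adaptive) {
        double la = std::sqrt(adapt_factor * Dp_max *
                              std::min(dt_max, 18.0 * dt));
        if (la > reach - Rmax) reach = Rmax + la;
      }
      double reach2 = reach * reach;
      double min_gap = reach - Rmax;  // pairs beyond reach are at least here
      cands.clear();

      if (use_cells) {
        double cw = box / nc;
        touched.clear();
        if ((int)nxt.size() < n_step) nxt.resize(n_step);
        if ((int)cell_of.size() < n_step) cell_of.resize(n_step);
        for (int i = 0; i < n_step; ++i) {
          if (!AL[i]) continue;
          int cx = std::min(nc - 1, (int)(X[i] / cw));
          int cy = std::min(nc - 1, (int)(Y[i] / cw));
          int cz = std::min(nc - 1, (int)(Z[i] / cw));
          int cid = (cx * nc + cy) * nc + cz;
          cell_of[i] = cid;
          if (head[cid] == -1) touched.push_back(cid);
          nxt[i] = head[cid];
          head[cid] = i;
        }
        for (int i = 0; i < n_step; ++i) {
          if (!AL[i]) continue;
          int cid = cell_of[i];
          int cx = cid / (nc * nc), cy = (cid / nc) % nc, cz = cid % nc;
          for (int ox = -1; ox <= 1; ++ox)
          for (int oy = -1; oy <= 1; ++oy)
          for (int oz = -1; oz <= 1; ++oz) {
            int ncx = (cx + ox + nc) % nc;
            int ncy = (cy + oy + nc) % nc;
            int ncz = (cz + oz + nc) % nc;
            int nid = (ncx * nc + ncy) * nc + ncz;
            for (int j = head[nid]; j != -1; j = nxt[j]) {
              if (j <= i || !AL[j]) continue;
              int rx = pair_rx(SP[i], SP[j]);
              if (rx < 0) continue;
              double dx = min_image(X[j] - X[i], box);
              double dy = min_image(Y[j] - Y[i], box);
              double dz = min_image(Z[j] - Z[i], box);
              double d2 = dx * dx + dy * dy + dz * dz;
              if (d2 > reach2) continue;
              Cand c;
              c.d1 = std::sqrt(d2);
              c.d0 = 0.0;
              if (bridge) {
                double ex = min_image(pX[j] - pX[i], box);
                double ey = min_image(pY[j] - pY[i], box);
                double ez = min_image(pZ[j] - pZ[i], box);
                c.d0 = std::sqrt(ex * ex + ey * ey + ez * ez);
              }
              c.i = i; c.j = j; c.rx = rx;
              double gap = c.d1 - rx_radius[rx];
              if (gap < min_gap) min_gap = gap;
              cands.push_back(c);
            }
          }
        }
        for (size_t k = 0; k < touched.size(); ++k) head[touched[k]] = -1;
      } else {
        for (int i = 0; i < n_step; ++i) {
          if (!AL[i]) continue;
          for (int j = i + 1; j < n_step; ++j) {
            if (!AL[j]) continue;
            int rx = pair_rx(SP[i], SP[j]);
            if (rx < 0) continue;
            double dx = min_image(X[j] - X[i], box);
            if (std::fabs(dx) > reach) continue;
            double dy = min_image(Y[j] - Y[i], box);
            if (std::fabs(dy) > reach) continue;
            double dz = min_image(Z[j] - Z[i], box);
            double d2 = dx * dx + dy * dy + dz * dz;
            if (d2 > reach2) continue;
            Cand c;
            c.d1 = std::sqrt(d2);
            c.d0 = 0.0;
            if (bridge) {
              double ex = pX[j] - pX[i];
              double ey = pY[j] - pY[i];
              double ez = pZ[j] - pZ[i];
              c.d0 = std::sqrt(ex * ex + ey * ey + ez * ez);
            }
            c.i = i; c.j = j; c.rx = rx;
            double gap = c.d1 - rx_radius[rx];
            if (gap < min_gap) min_gap = gap;
            cands.push_back(c);
          }
        }
      }
      if (min_gap < 0.0) min_gap = 0.0;
      pair_cap = min_gap * min_gap / (adapt_factor * Dp_max);

      std::sort(cands.begin(), cands.end(),
                [](const Cand &a, const Cand &b) { return a.d1 < b.d1; });

      for (size_t k = 0; k < cands.size(); ++k) {
        const Cand &c = cands[k];
        if (!AL[c.i] || !AL[c.j]) continue;
        double R = rx_radius[c.rx];
        bool react = false;
        if (c.d1 <= R) {
          react = true;
        } else if (bridge) {
          double Dp = D_nm2s[SP[c.i]] + D_nm2s[SP[c.j]];
          double a0 = c.d0 - R, a1 = c.d1 - R;
          if (a0 <= 0.0) {
            react = true;  // started inside contact (fresh product)
          } else {
            double p = std::exp(-a0 * a1 / (Dp * dt));
            if (unif_rand() < p) react = true;
          }
        }
        if (!react) continue;
        // execute: kill both, place products at the pair midpoint
        AL[c.i] = 0; AL[c.j] = 0;
        double dx = min_image(X[c.j] - X[c.i], box);
        double dy = min_image(Y[c.j] - Y[c.i], box);
        double dz = min_image(Z[c.j] - Z[c.i], box);
        double mx = wrap(X[c.i] + 0.5 * dx, box);
        double my = wrap(Y[c.i] + 0.5 * dy, box);
        double mz = wrap(Z[c.i] + 0.5 * dz, box);
        for (int p = 0; p < 3; ++p) {
          int sp_new = rx_prod(c.rx, p);
          if (sp_new < 0) break;
          X.push_back(mx); Y.push_back(my); Z.push_back(mz);
          SP.push_back(sp_new); AL.push_back(1);
        }
        ev_t.push_back(tn); ev_rx.push_back(c.rx);
      }
    }

    // --- first-order channels ------------------------------------------
    for (int i = 0; i < n_step; ++i) {
      if (!AL[i]) continue;
      double lam = lam_tot[SP[i]];
      if (lam <= 0.0) continue;
      if (unif_rand() >= 1.0 - std::exp(-lam * dt)) continue;
      double u = unif_rand() * lam;
      double acc = 0.0;
      int chosen = -2;  // -1 = scavenger
      for (size_t k = 0; k < ch_rx[SP[i]].size(); ++k) {
        acc += ch_rate[SP[i]][k];
        if (u < acc) { chosen = ch_rx[SP[i]][k]; break; }
      }
      if (chosen == -2) chosen = -1;
      if (chosen == -1) {
        sc_t.push_back(tn); sc_sp.push_back(SP[i]);
        AL[i] = 0;
      } else {
        AL[i] = 0;
        for (int p = 0; p < 3; ++p) {
          int sp_new = rx_prod(chosen, p);
          if (sp_new < 0) break;
          X.push_back(X[i]); Y.push_back(Y[i]); Z.push_back(Z[i]);
          SP.push_back(sp_new); AL.push_back(1);
        }
        ev_t.push_back(tn); ev_rx.push_back(chosen);
      }
    }

    t = tn;
    if (record_positions && snap_i < n_snap &&
        t >= snap_times[snap_i] * (1.0 - 1e-12)) {
      int m = (int)X.size();
      NumericMatrix P(m, 3);
      IntegerVector sps(m); LogicalVector al(m);
      for (int i = 0; i < m; ++i) {
        P(i, 0) = X[i]; P(i, 1) = Y[i]; P(i, 2) = Z[i];
        sps[i] = SP[i]; al[i] = (bool)AL[i];
      }
      snaps.push_back(List::create(_["time"] = snap_times[snap_i],
                                   _["pos"] = P, _["species"] = sps,
                                   _["alive"] = al));
      snap_i++;
    }
    if (X.size() > 5000000) stop("population exploded; check configuration");
  }

  int m = (int)X.size();
  NumericMatrix P(m, 3);
  IntegerVector sps(m); LogicalVector al(m);
  for (int i = 0; i < m; ++i) {
    P(i, 0) = X[i]; P(i, 1) = Y[i]; P(i, 2) = Z[i];
    sps[i] = SP[i]; al[i] = (bool)AL[i];
  }
  return List::create(
    _["event_time"] = NumericVector(ev_t.begin(), ev_t.end()),
    _["event_rx"] = IntegerVector(ev_rx.begin(), ev_rx.end()),
    _["scav_time"] = NumericVector(sc_t.begin(), sc_t.end()),
    _["scav_species"] = IntegerVector(sc_sp.begin(), sc_sp.end()),
    _["pos"] = P, _["species"] = sps, _["alive"] = al,
    _["snapshots"] = snaps);
}
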