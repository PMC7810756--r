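#include <Rcpp.h>
#include <vector>
#include <queue>
#include <cmath>
using namespace Rcpp;

// Independent reaction times (IRT) chemistry engine.
//
// For every reactive pair a first-passage reaction time is drawn from the
// diffusion-controlled distribution
//   W(t | r0, R, D') = (R / r0) * erfc((r0 - R) / sqrt(4 D' t)),
// i.e. the pair ultimately reacts with probability R / r0, and conditional
// on reacting the time is obtained by inverting the erfc term.  First-order
// channels (implicit-water reactions, scavengers) draw exponential times.
// The earliest pending event fires; partners of consumed molecules are
// invalidated lazily.  When a reaction creates products, the positions of
// the molecules involved in resampling are first propagated to the event
// time by sampling their free-diffusion Green's function (lazy position
// updates); new pair times are then drawn from the updated geometry.
// Units: nm, nm^2/s, s.

struct Ev {
  double t;
  int kind;  // 0 = pair reaction, 1 = unary reaction, 2 = scavenging
  int i, j, rx;
};
struct EvCmp {
  bool operator()(const Ev &a, const Ev &b) const { return a.t > b.t; }
};

static inline double erfc_inv(double v) {
  // erfc(x) = v  =>  x = -qnorm(v/2)/sqrt(2)
  return -R::qnorm(v / 2.0, 0.0, 1.0, 1, 0) / M_SQRT2;
}

// [[Rcpp::export]]
List irt_engine_cpp(NumericMatrix pos0, IntegerVector spec0,
                    NumericVector D_nm2s, IntegerMatrix pair_rx,
                    NumericVector rx_radius, IntegerMatrix rx_prod,
                    List sp_unary_rx, List sp_unary_rate,
                    NumericVector sp_scav,
                    double t_start, double t_end) {
  const int ns = D_nm2s.size();
  int n = pos0.nrow();

  std::vector<double> X(n), Y(n), Z(n), TQ(n, t_start);
  std::vector<int> SP(n);
  std::vector<char> AL(n, 1);
  for (int i = 0; i < n; ++i) {
    X[i] = pos0(i, 0); Y[i] = pos0(i, 1); Z[i] = pos0(i, 2);
    SP[i] = spec0[i];
  }

  // lazily diffuse molecule q's stored position forward to time t
  auto propagate = [&](int q, double t) {
    if (t <= TQ[q]) return;
    double sd = std::sqrt(2.0 * D_nm2s[SP[q]] * (t - TQ[q]));
    X[q] += norm_rand() * sd;
    Y[q] += norm_rand() * sd;
    Z[q] += norm_rand() * sd;
    TQ[q] = t;
  };

  std::vector< std::vector<int> > ch_rx(ns);
  std::vector< std::vector<double> > ch_rate(ns);
  for (int s = 0; s < ns; ++s) {
    IntegerVector rxs = sp_unary_rx[s];
    NumericVector rts = sp_unary_rate[s];
    for (int k = 0; k < rxs.size(); ++k) {
      ch_rx[s].push_back(rxs[k]);
      ch_rate[s].push_back(rts[k]);
    }
  }
  bool any_pair = false;
  for (int a = 0; a < ns && !any_pair; ++a)
    for (int b = 0; b < ns; ++b)
      if (pair_rx(a, b) >= 0) { any_pair = true; break; }

  std::priority_queue<Ev, std::vector<Ev>, EvCmp> H;
  const double tiny = 1e-18;

  auto push_pair = [&](int i, int j, double t0) {
    int rx = pair_rx(SP[i], SP[j]);
    if (rx < 0) return;
    double R = rx_radius[rx];
    if (R <= 0.0) return;
    double dx = X[j] - X[i], dy = Y[j] - Y[i], dz = Z[j] - Z[i];
    double r0 = std::sqrt(dx * dx + dy * dy + dz * dz);
    Ev e; e.kind = 0; e.i = i; e.j = j; e.rx = rx;
    if (r0 <= R) {               // already in contact: immediate reaction
      e.t = t0 + tiny;
      H.push(e);
      return;
    }
    double Dp = D_nm2s[SP[i]] + D_nm2s[SP[j]];
    double horizon = t_end - t0;
    if (horizon <= 0.0) return;
    // W(t_end) <= (R/r0) erfc(6) ~ 0: unreachable partner
    double gap = r0 - R;
    if (gap > 6.0 * std::sqrt(4.0 * Dp * horizon)) return;
    double u = unif_rand();
    double winf = R / r0;
    if (u >= winf) return;       // pair escapes
    double x = erfc_inv(u / winf);
    if (x <= 0.0) return;
    double tt = t0 + gap * gap / (4.0 * Dp * x * x);
    if (tt <= t_end) { e.t = tt; H.push(e); }
  };

  auto push_unary = [&](int i, double t0) {
    int s = SP[i];
    for (size_t k = 0; k < ch_rx[s].size(); ++k) {
      double lam = ch_rate[s][k];
      if (lam <= 0.0) continue;
      double tt = t0 + exp_rand() / lam;
      if (tt <= t_end) {
        Ev e; e.t = tt; e.kind = 1; e.i = i; e.j = -1; e.rx = ch_rx[s][k];
        H.push(e);
      }
    }
    if (sp_scav[s] > 0.0) {
      double tt = t0 + exp_rand() / sp_scav[s];
      if (tt <= t_end) {
        Ev e; e.t = tt; e.kind = 2; e.i = i; e.j = -1; e.rx = -1;
        H.push(e);
      }
    }
  };

  if (any_pair) {
    for (int i = 0; i < n; ++i)
      for (int j = i + 1; j < n; ++j)
        push_pair(i, j, t_start);
  }
  for (int i = 0; i < n; ++i) push_unary(i, t_start);

  std::vector<double> ev_t; std::vector<int> ev_rx;
  std::vector<double> sc_t; std::vector<int> sc_sp;

  while (!H.empty()) {
    Ev e = H.top(); H.pop();
    if (e.t > t_end) break;
    if (!AL[e.i]) continue;
    if (e.kind == 0 && !AL[e.j]) continue;

    if (e.kind == 2) {
      AL[e.i] = 0;
      sc_t.push_back(e.t); sc_sp.push_back(SP[e.i]);
      continue;
    }

    double px, py, pz;
    if (e.kind == 0) {
      propagate(e.i, e.t); propagate(e.j, e.t);
      AL[e.i] = 0; AL[e.j] = 0;
      px = 0.5 * (X[e.i] + X[e.j]);
      py = 0.5 * (Y[e.i] + Y[e.j]);
      pz = 0.5 * (Z[e.i] + Z[e.j]);
    } else {
      propagate(e.i, e.t);
      AL[e.i] = 0;
      px = X[e.i]; py = Y[e.i]; pz = Z[e.i];
    }
    ev_t.push_back(e.t); ev_rx.push_back(e.rx);

    for (int p = 0; p < 3; ++p) {
      int sp_new = rx_prod(e.rx, p);
      if (sp_new < 0) break;
      X.push_back(px); Y.push_back(py); Z.push_back(pz);
      TQ.push_back(e.t);
      SP.push_back(sp_new); AL.push_back(1);
      int idx = (int)X.size() - 1;
      if (any_pair) {
        for (int q = 0; q < idx; ++q) {
          if (!AL[q]) continue;
          propagate(q, e.t);
          push_pair(q, idx, e.t);
        }
      }
      push_unary(idx, e.t);
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
    _["snapshots"] = List());
}
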