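#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Stochastic generation loop of the individual-based damage-repair model.
// Uses R's RNG (unif_rand / norm_rand) so that set.seed() on the R side
// yields bit-reproducible trajectories across platforms.

namespace {

struct Pars {
  double g_max, D_max, R_max, R_min, repair_slope, g_ref;
  double K, alpha, delta_t;
  double mutation_scale, mutation_prob, mutation_effect;
  double inheritance;
  int mutation_mode;  // 0 = gaussian every offspring, 1 = rare fixed effect
  bool K_finite;
};

inline double repair(double g, const Pars &p) {
  double r = p.R_max - p.repair_slope * (p.R_max - p.R_min) * (g / p.g_ref);
  if (r < p.R_min) r = p.R_min;
  if (r > p.R_max) r = p.R_max;
  return r;
}

inline double projected(double Dp, double g, const Pars &p) {
  double R = repair(g, p);
  double deq = p.D_max * g / R;
  return deq + (Dp - deq) * std::exp(-R * p.delta_t);
}

inline double mortality(double D, const Pars &p) {
  if (!p.K_finite || D <= 0.0) return 0.0;
  double r = std::pow(D / p.K, p.alpha);
  if (!std::isfinite(r)) return 1.0;
  return r / (1.0 + r);
}

inline double mutate(double g, const Pars &p) {
  double gc = g;
  if (p.mutation_mode == 0) {
    gc += norm_rand() * p.mutation_scale;
  } else if (unif_rand() < p.mutation_prob) {
    gc += (unif_rand() < 0.5 ? -1.0 : 1.0) * p.mutation_effect;
  }
  if (gc < 0.0) gc = 0.0;
  if (gc > p.g_max) gc = p.g_max;
  return gc;
}

// index of the parent drawn proportionally to growth rate, via binary
// search on the cumulative weight vector
inline int draw_parent(const std::vector<double> &cum, double total) {
  double u = unif_rand() * total;
  int lo = 0, hi = (int)cum.size() - 1;
  while (lo < hi) {
    int mid = (lo + hi) / 2;
    if (cum[mid] < u) lo = mid + 1; else hi = mid;
  }
  return lo;
}

}  // namespace

// [[Rcpp::export]]
List sim_generations_cpp(NumericVector g0, NumericVector D0, int n_gen,
                         double g_max, double D_max, double R_max,
                         double R_min, double repair_slope, double g_ref,
                         double K,
                         double alpha, double delta_t, double mutation_scale,
                         int mutation_mode, double mutation_prob,
                         double mutation_effect, double inheritance,
                         double deaths0, double max_attempts, bool record) {
  const int N = g0.size();
  if (N < 1) stop("population must contain at least one cell");
  if (D0.size() != N) stop("g and D must have the same length");

  Pars p;
  p.g_max = g_max; p.D_max = D_max; p.R_max = R_max; p.R_min = R_min;
  p.repair_slope = repair_slope; p.g_ref = g_ref; p.K = K; p.alpha = alpha;
  p.delta_t = delta_t; p.mutation_scale = mutation_scale;
  p.mutation_prob = mutation_prob; p.mutation_effect = mutation_effect;
  p.inheritance = inheritance; p.mutation_mode = mutation_mode;
  p.K_finite = std::isfinite(K);

  std::vector<double> g(g0.begin(), g0.end());
  std::vector<double> D(D0.begin(), D0.end());
  std::vector<double> g_new(N), D_new(N), cum(N);

  double deaths = deaths0;
  double attempts_total = 0.0;
  int status = 0;          // 0 ok, 1 extinction (attempt cap), 2 degenerate
  int failed_gen = NA_INTEGER;

  NumericMatrix traj;
  if (record) traj = NumericMatrix(n_gen, 6);

  RNGScope scope;

  int gen_done = 0;
  for (int gen = 0; gen < n_gen; ++gen) {
    double total = 0.0;
    for (int i = 0; i < N; ++i) {
      total += g[i];
      cum[i] = total;
    }
    if (total <= 0.0) { status = 2; failed_gen = gen + 1; break; }

    double gen_attempts = 0.0;
    bool capped = false;
    for (int slot = 0; slot < N; ++slot) {
      for (;;) {
        if (gen_attempts >= max_attempts) { capped = true; break; }
        gen_attempts += 1.0;
        int idx = draw_parent(cum, total);
        double gc = mutate(g[idx], p);
        double Dc = projected(p.inheritance * D[idx], gc, p);
        if (unif_rand() < mortality(Dc, p)) {
          deaths += 1.0;
        } else {
          g_new[slot] = gc;
          D_new[slot] = Dc;
          break;
        }
      }
      if (capped) break;
    }
    attempts_total += gen_attempts;
    if (capped) { status = 1; failed_gen = gen + 1; break; }

    g.swap(g_new);
    D.swap(D_new);
    ++gen_done;

    if (record) {
      double mg = 0.0, mD = 0.0;
      for (int i = 0; i < N; ++i) { mg += g[i]; mD += D[i]; }
      mg /= N; mD /= N;
      double vg = 0.0, vD = 0.0;
      for (int i = 0; i < N; ++i) {
        vg += (g[i] - mg) * (g[i] - mg);
        vD += (D[i] - mD) * (D[i] - mD);
      }
      if (N > 1) { vg /= (N - 1); vD /= (N - 1); }
      traj(gen, 0) = mg;
      traj(gen, 1) = vg;
      traj(gen, 2) = mD;
      traj(gen, 3) = vD;
      traj(gen, 4) = deaths;
      traj(gen, 5) = gen_attempts;
    }
  }

  List out = List::create(
      _["g"] = NumericVector(g.begin(), g.end()),
      _["D"] = NumericVector(D.begin(), D.end()),
      _["selective_deaths"] = deaths,
      _["attempts"] = attempts_total,
      _["generations_done"] = gen_done,
      _["status"] = status,
      _["failed_generation"] = failed_gen);
  if (record) {
    out["trajectory"] = traj(Range(0, std::max(gen_done - 1, 0)), _);
    if (gen_done == 0) out["trajectory"] = NumericMatrix(0, 6);
  }
  return out;
}
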