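// Core simulation loop: pollinators foraging on a continuous 2-D torus.
//
// All randomness is drawn from R's RNG (unif_rand/norm_rand under the RNGScope
// installed by Rcpp attributes), so a single set.seed() in the R wrapper makes
// the whole run bit-reproducible.
//
// Per-step schedule: pollinators act once each in a fresh uniform random
// permutation; afterwards every previously visited flower advances its
// time-since-visit clock and recomputes nectar/scent from the linear refill
// law. Never-visited flowers stay full and unmarked.

#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

static inline double wrap1(double v, double L) {
  double w = v - L * std::floor(v / L);
  if (w >= L) w -= L;   // floating-point guard: v/L can round so that w == L
  if (w < 0.0) w = 0.0;
  return w;
}

// squared minimum-image distance on the torus
static inline double tdist2(double x1, double y1, double x2, double y2, double L) {
  double dx = std::fabs(x1 - x2);
  if (dx > L * 0.5) dx = L - dx;
  double dy = std::fabs(y1 - y2);
  if (dy > L * 0.5) dy = L - dy;
  return dx * dx + dy * dy;
}

enum Mode { SEARCHING = 0, ASSESSING = 1, HANDLING = 2 };

// [[Rcpp::export]]
List run_sim_cpp(double size_map, int n_steps, int n_flowers, int n_pollinators,
                 double refill_coef, bool use_scent, int cost,
                 double detection_radius, double inertia, bool literal_scent,
                 Nullable<NumericVector> fx0 = R_NilValue,
                 Nullable<NumericVector> fy0 = R_NilValue,
                 Nullable<NumericVector> px0 = R_NilValue,
                 Nullable<NumericVector> py0 = R_NilValue,
                 Nullable<NumericVector> ph0 = R_NilValue) {
  if (n_flowers < 1) stop("a simulation needs at least one flower");
  if (n_pollinators < 0) stop("negative pollinator count");

  const double r2 = detection_radius * detection_radius;
  const double sigma = 2.0 * M_PI * inertia;

  // ---- flower state ----
  std::vector<double> fx(n_flowers), fy(n_flowers);
  std::vector<double> nectar(n_flowers, 1.0), scent(n_flowers, 0.0);
  std::vector<int> tsv(n_flowers, -1);          // -1 = never visited (sentinel)
  std::vector<int> visits(n_flowers, 0);
  std::vector<int> occupant(n_flowers, -1);     // pollinator index or -1

  // Draw order is fixed: flower positions (x,y per flower), then pollinator
  // positions, then headings. Optional fixed initial layouts for tests.
  if (fx0.isNotNull() && fy0.isNotNull()) {
    NumericVector ax(fx0), ay(fy0);
    if (ax.size() != n_flowers || ay.size() != n_flowers)
      stop("fixed flower layout has wrong length");
    for (int i = 0; i < n_flowers; ++i) { fx[i] = wrap1(ax[i], size_map); fy[i] = wrap1(ay[i], size_map); }
  } else {
    for (int i = 0; i < n_flowers; ++i) { fx[i] = unif_rand() * size_map; fy[i] = unif_rand() * size_map; }
  }

  // ---- pollinator state ----
  std::vector<double> px(n_pollinators), py(n_pollinators), heading(n_pollinators);
  std::vector<int> mode(n_pollinators, SEARCHING);
  std::vector<int> timer(n_pollinators, 0);
  std::vector<int> cur(n_pollinators, -1), last(n_pollinators, -1);
  std::vector<double> collected(n_pollinators, 0.0);
  std::vector<int> n_accepted(n_pollinators, 0);

  if (px0.isNotNull() && py0.isNotNull()) {
    NumericVector ax(px0), ay(py0);
    if (ax.size() != n_pollinators || ay.size() != n_pollinators)
      stop("fixed pollinator layout has wrong length");
    for (int i = 0; i < n_pollinators; ++i) { px[i] = wrap1(ax[i], size_map); py[i] = wrap1(ay[i], size_map); }
  } else {
    for (int i = 0; i < n_pollinators; ++i) { px[i] = unif_rand() * size_map; py[i] = unif_rand() * size_map; }
  }
  if (ph0.isNotNull()) {
    NumericVector ah(ph0);
    if (ah.size() != n_pollinators) stop("fixed heading vector has wrong length");
    for (int i = 0; i < n_pollinators; ++i) heading[i] = wrap1(ah[i], 2.0 * M_PI);
  } else {
    for (int i = 0; i < n_pollinators; ++i) heading[i] = unif_rand() * 2.0 * M_PI;
  }

  // ---- event log ----
  std::vector<int> ev_step, ev_p, ev_f, ev_acc;
  std::vector<double> ev_gain;
  ev_step.reserve(1024);

  std::vector<int> perm(n_pollinators);
  std::vector<int> cand; cand.reserve(32);
  double refill_total = 0.0;

  for (int s = 1; s <= n_steps; ++s) {
    // fresh uniform random permutation (Fisher-Yates)
    for (int i = 0; i < n_pollinators; ++i) perm[i] = i;
    for (int i = n_pollinators - 1; i > 0; --i) {
      int j = (int)(unif_rand() * (i + 1));
      if (j > i) j = i;
      std::swap(perm[i], perm[j]);
    }

    for (int k = 0; k < n_pollinators; ++k) {
      int p = perm[k];

      if (mode[p] == HANDLING) {
        if (--timer[p] == 0) {
          int f = cur[p];
          if (occupant[f] != p) stop("internal error: occupancy violated at release");
          occupant[f] = -1;
          last[p] = f;
          cur[p] = -1;
          mode[p] = SEARCHING;
        }
        continue;
      }

      if (mode[p] == ASSESSING) {
        int f = cur[p];
        if (occupant[f] != p) stop("internal error: occupancy violated at assessment");
        bool accept;
        if (!use_scent) {
          accept = true;                       // non-users never run the Bernoulli trial
        } else {
          double p_acc = literal_scent ? scent[f] : 1.0 - scent[f];
          accept = unif_rand() < p_acc;
        }
        if (accept) {
          double gain = nectar[f];
          nectar[f] = 0.0; scent[f] = 1.0; tsv[f] = 0; ++visits[f];
          collected[p] += gain; ++n_accepted[p];
          mode[p] = HANDLING; timer[p] = cost;
          ev_step.push_back(s); ev_p.push_back(p); ev_f.push_back(f);
          ev_acc.push_back(1); ev_gain.push_back(gain);
        } else {
          occupant[f] = -1;
          last[p] = f;
          cur[p] = -1;
          mode[p] = SEARCHING;
          ev_step.push_back(s); ev_p.push_back(p); ev_f.push_back(f);
          ev_acc.push_back(0); ev_gain.push_back(0.0);
        }
        continue;
      }

      // SEARCHING: novel (not the flower just left/rejected), free flowers in range
      cand.clear();
      for (int f = 0; f < n_flowers; ++f) {
        if (occupant[f] != -1 || f == last[p]) continue;
        if (tdist2(px[p], py[p], fx[f], fy[f], size_map) <= r2) cand.push_back(f);
      }
      if (!cand.empty()) {
        int j = (int)(unif_rand() * cand.size());
        if (j >= (int)cand.size()) j = (int)cand.size() - 1;
        int f = cand[j];
        occupant[f] = p;                       // claim: later movers this step skip it
        px[p] = fx[f]; py[p] = fy[f];
        cur[p] = f;
        mode[p] = ASSESSING;
      } else {
        heading[p] = wrap1(heading[p] + norm_rand() * sigma, 2.0 * M_PI);
        px[p] = wrap1(px[p] + std::cos(heading[p]), size_map);
        py[p] = wrap1(py[p] + std::sin(heading[p]), size_map);
      }
    }

    // flower update, after all pollinators have acted
    for (int f = 0; f < n_flowers; ++f) {
      if (tsv[f] < 0) continue;                // never visited: full, unmarked
      ++tsv[f];
      double t = refill_coef * (double)tsv[f];
      double newn = t < 1.0 ? t : 1.0;
      if (newn > nectar[f]) refill_total += newn - nectar[f];
      nectar[f] = newn;
      scent[f] = t < 1.0 ? 1.0 - t : 0.0;
    }
  }

  return List::create(
    _["flower_x"] = NumericVector(fx.begin(), fx.end()),
    _["flower_y"] = NumericVector(fy.begin(), fy.end()),
    _["nectar"] = NumericVector(nectar.begin(), nectar.end()),
    _["scent"] = NumericVector(scent.begin(), scent.end()),
    _["time_since_visit"] = IntegerVector(tsv.begin(), tsv.end()),
    _["visit_count"] = IntegerVector(visits.begin(), visits.end()),
    _["poll_x"] = NumericVector(px.begin(), px.end()),
    _["poll_y"] = NumericVector(py.begin(), py.end()),
    _["heading"] = NumericVector(heading.begin(), heading.end()),
    _["nectar_collected"] = NumericVector(collected.begin(), collected.end()),
    _["n_accepted"] = IntegerVector(n_accepted.begin(), n_accepted.end()),
    _["ev_step"] = IntegerVector(ev_step.begin(), ev_step.end()),
    _["ev_pollinator"] = IntegerVector(ev_p.begin(), ev_p.end()),
    _["ev_flower"] = IntegerVector(ev_f.begin(), ev_f.end()),
    _["ev_accepted"] = IntegerVector(ev_acc.begin(), ev_acc.end()),
    _["ev_gain"] = NumericVector(ev_gain.begin(), ev_gain.end()),
    _["refill_total"] = refill_total);
}
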