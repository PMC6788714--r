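#include <Rcpp.h>
#include <vector>
#include "rng.h"

using namespace Rcpp;

// Exact Gillespie simulation of the two-type well-mixed branching process.
// Events: type-0 division (b), type-0 death (d), type-0 -> type-1 mutation (u),
// type-1 division (b1), type-1 death (d1). Counts are aggregated (no per-cell
// state). Type-1 clones are tracked in founding order until the oldest
// surviving clone is "certain to survive" drift, i.e. its extinction
// probability (d1/b1)^n drops below survivor_threshold_prob; from then on
// only that first surviving lineage is followed and the mutation channel is
// dropped (further clones would not be tracked).
//
// A run is surviving if total population reaches M; total extinction rejects
// and restarts the run (rejection counts are reported). f_sub = Y/M at the
// first instant total >= M.
//
// Phase A (pre-designation, multiple nascent clones) is a tiny share of the
// events; phase B (two counts) carries almost all of them and is run
// branchless and interleaved across several replicate runs to hide the
// serial dependency chain of each run's state. Every attempt draws from its
// own (seed, attempt) RNG stream, so the interleaving cannot change results.

struct RunResult {
  double f_sub;
  double t;
  bool survivor;
  bool extinct;
  bool finished;   // decided already in phase A
};

struct BState {
  double x0, y, total, t;
  Xoshiro256 rng;
  BState() : x0(0), y(0), total(0), t(0), rng(0) {}
};

// Run until extinction, size M, or survivor designation. Returns the result
// (finished = true) or the phase-B start state (finished = false).
//
// Clones are kept in founding order and only the FRONT (oldest alive) clone
// can be designated: the first-founded clone that proves certain to survive
// is the first surviving lineage, which is the observable the analytic
// frequency distribution describes. Designating whichever clone first races
// to the size threshold instead selects for atypically fast growers and
// biases the final frequency upward when surviving clones are founded
// frequently (large u). Once the front clone has passed the threshold the
// other clones can never become the first surviving lineage, and clones do
// not interact, so dropping them is exact for this observable.
template <bool TrackTime>
static inline RunResult phase_a(Xoshiro256 &rng, double b, double d,
                                double b1, double d1, double u,
                                double M, double n_star, BState &bs) {
  RunResult out = {0.0, 0.0, false, false, true};
  double x0 = 1.0, ytot = 0.0, total = 1.0, t = 0.0;
  std::vector<double> clones;  // founding order; extinct clones removed
  double ucur = u;
  const double k1 = b1 + d1, bd = b + d;

  for (;;) {
    if (!clones.empty() && clones.front() >= n_star) {
      // designate the first surviving lineage; freeze the others out
      ytot = clones.front();
      total = x0 + ytot;
      break;
    }
    if (total >= M) {
      out.f_sub = ytot / total;
      out.t = t;
      return out;
    }
    if (total <= 0.0) { out.extinct = true; return out; }

    const double rate0 = x0 * (bd + ucur);
    const double R = rate0 + ytot * k1;
    if (TrackTime) t += rng.rexp() / R;
    const double v = rng.unif() * R;

    if (v < x0 * b) {
      x0 += 1.0; total += 1.0;
    } else if (v < x0 * bd) {
      x0 -= 1.0; total -= 1.0;
    } else if (v < rate0) {
      // mutation: one type-0 cell founds a new type-1 clone
      x0 -= 1.0;
      ytot += 1.0;
      clones.push_back(1.0);
    } else {
      double w = v - rate0;
      size_t k = 0;
      if (clones.size() > 1) {
        double cum = clones[0] * k1;
        while (w >= cum && k + 1 < clones.size()) {
          w -= cum;
          ++k;
          cum = clones[k] * k1;
        }
      }
      const double sz = clones[k];
      if (w < sz * b1) {
        clones[k] = sz + 1.0;
        ytot += 1.0; total += 1.0;
        if (clones[k] >= n_star) {
          // a certain survivor exists: younger clones can never be the
          // first surviving lineage, so drop them and stop new foundings;
          // only older (still uncertain) clones remain to be resolved
          if (k + 1 < clones.size()) {
            clones.resize(k + 1);
            ytot = 0.0;
            for (size_t j = 0; j < clones.size(); ++j) ytot += clones[j];
            total = x0 + ytot;
          }
          ucur = 0.0;
        }
      } else {
        clones[k] = sz - 1.0;
        ytot -= 1.0; total -= 1.0;
        if (clones[k] <= 0.0) clones.erase(clones.begin() + k);
      }
    }
  }

  out.finished = false;
  out.survivor = true;
  bs.x0 = x0;
  bs.y = ytot;
  bs.total = total;
  bs.t = t;
  bs.rng = rng;
  return out;
}

// One branchless phase-B event; returns +1 finished (size M), -1 extinct,
// 0 still running.
template <bool TrackTime>
static inline int phase_b_step(BState &s, double b, double bd, double b1,
                               double k1, double M) {
  const double xb = s.x0 * b, xbd = s.x0 * bd;
  const double R = xbd + s.y * k1;
  if (TrackTime) s.t += s.rng.rexp() / R;
  const double v = s.rng.unif() * R;
  const double e_xb = (double)(v < xb);               // type-0 division
  const double e_x = (double)(v < xbd);               // any type-0 event
  const double e_notyd = (double)(v < xbd + s.y * b1);// not a type-1 death
  const double dx = 2.0 * e_xb - e_x;
  const double dy = 2.0 * e_notyd - e_x - 1.0;
  s.x0 += dx;
  s.y += dy;
  s.total += dx + dy;
  if (s.total >= M) return 1;
  if (s.total <= 0.0) return -1;
  return 0;
}

// [[Rcpp::export]]
List branching_sim_cpp(double b, double d, double b1, double d1, double u,
                       double M, int n_runs, double seed,
                       double survivor_threshold_prob = 1e-6,
                       bool track_time = false,
                       double max_attempts = 1e9) {
  if (n_runs < 1) stop("n_runs must be >= 1");
  if (M < 2) stop("M must be >= 2");

  // clone size above which survival is 'certain'
  double n_star;
  if (d1 <= 0.0) {
    n_star = 1.0;
  } else {
    n_star = std::ceil(std::log(survivor_threshold_prob) / std::log(d1 / b1));
    if (n_star < 1.0) n_star = 1.0;
  }

  const double bd = b + d, k1 = b1 + d1;

  std::vector<double> f_sub_v, t_v;
  std::vector<int> rej_v;
  std::vector<int> surv_v;
  f_sub_v.reserve(n_runs);

  const uint64_t useed = (uint64_t)seed;
  double attempts = 0.0;
  int rejected_running = 0;
  int collected = 0;

  const int CHUNK = 64, LANES = 8;
  RunResult res[CHUNK];
  BState st[CHUNK];

  while (collected < n_runs) {
    if (attempts >= max_attempts)
      stop("max_attempts exceeded before collecting the requested surviving runs");
    int n_chunk = 0;
    int queue[CHUNK];
    int n_queue = 0;
    // phase A for a chunk of attempts
    for (; n_chunk < CHUNK && attempts + n_chunk < max_attempts; ++n_chunk) {
      Xoshiro256 rng = Xoshiro256::stream(useed, (uint64_t)(attempts + n_chunk));
      res[n_chunk] = track_time
        ? phase_a<true>(rng, b, d, b1, d1, u, M, n_star, st[n_chunk])
        : phase_a<false>(rng, b, d, b1, d1, u, M, n_star, st[n_chunk]);
      if (!res[n_chunk].finished) queue[n_queue++] = n_chunk;
    }
    attempts += n_chunk;

    // phase B, interleaved across lanes
    int lane_at[LANES];
    int n_active = 0, next_q = 0;
    for (int l = 0; l < LANES; ++l) {
      lane_at[l] = (next_q < n_queue) ? queue[next_q++] : -1;
      if (lane_at[l] >= 0) ++n_active;
    }
    while (n_active > 0) {
      for (int l = 0; l < LANES; ++l) {
        const int a = lane_at[l];
        if (a < 0) continue;
        const int outcome = track_time
          ? phase_b_step<true>(st[a], b, bd, b1, k1, M)
          : phase_b_step<false>(st[a], b, bd, b1, k1, M);
        if (outcome != 0) {
          if (outcome > 0) {
            res[a].f_sub = st[a].y / st[a].total;
            res[a].t = st[a].t;
          } else {
            res[a].extinct = true;
          }
          res[a].finished = true;
          lane_at[l] = (next_q < n_queue) ? queue[next_q++] : -1;
          if (lane_at[l] < 0) --n_active;
        }
      }
    }

    // collect results in attempt order
    for (int i = 0; i < n_chunk && collected < n_runs; ++i) {
      if (res[i].extinct) {
        ++rejected_running;
      } else {
        f_sub_v.push_back(res[i].f_sub);
        t_v.push_back(res[i].t);
        rej_v.push_back(rejected_running);
        surv_v.push_back(res[i].survivor ? 1 : 0);
        rejected_running = 0;
        ++collected;
      }
    }
    Rcpp::checkUserInterrupt();
  }

  const int n = n_runs;
  NumericVector f_sub(n), t_final(n);
  IntegerVector rejected_before(n);
  LogicalVector survivor_flag(n);
  for (int i = 0; i < n; ++i) {
    f_sub[i] = f_sub_v[i];
    t_final[i] = t_v[i];
    rejected_before[i] = rej_v[i];
    survivor_flag[i] = surv_v[i] != 0;
  }

  return List::create(_["f_sub"] = f_sub,
                      _["t_final"] = t_final,
                      _["rejected_before"] = rejected_before,
                      _["survivor_designated"] = survivor_flag,
                      _["attempts"] = attempts);
}

// Three-type process (wild type, first driver, second driver): the
// brute-force oracle for the two-sequential-driver detection formula. The
// bookkeeping mirrors the two-type simulation and the analytic convention:
// type-1 clones are tracked until one is certain to survive drift, after
// which only that clone is followed (type-0 mutation switches off) and
// second-driver mutations begin inside it at per-cell rate u; type-2 clones
// are then tracked the same way. f_first counts the tracked first-driver
// lineage including its second-driver cells.
//
// [[Rcpp::export]]
List three_type_sim_cpp(double b, double d, double b1, double d1,
                        double b2, double d2, double u, double M,
                        int n_runs, double seed,
                        double survivor_threshold_prob = 1e-6,
                        double max_attempts = 1e9) {
  if (n_runs < 1) stop("n_runs must be >= 1");
  NumericVector f1(n_runs), f2(n_runs);
  const uint64_t useed = (uint64_t)seed;
  double attempts = 0.0;
  int rejected = 0;

  const double thr = survivor_threshold_prob;
  const double n_star1 = (d1 <= 0) ? 1.0
    : std::max(1.0, std::ceil(std::log(thr) / std::log(d1 / b1)));
  const double n_star2 = (d2 <= 0) ? 1.0
    : std::max(1.0, std::ceil(std::log(thr) / std::log(d2 / b2)));

  for (int run = 0; run < n_runs; ++run) {
    bool done = false;
    while (!done) {
      if (attempts >= max_attempts) stop("max_attempts exceeded");
      Xoshiro256 rng = Xoshiro256::stream(useed, (uint64_t)attempts);
      attempts += 1.0;

      double x = 1.0, y1 = 0.0, y2 = 0.0, total = 1.0;
      std::vector<double> cl1, cl2;   // nascent clones pre-designation
      bool des1 = false, des2 = false;
      const double k1 = b1 + d1, k2 = b2 + d2;

      for (;;) {
        // first-founded surviving clone designation, per stage
        if (!des1 && !cl1.empty() && cl1.front() >= n_star1) {
          des1 = true;
          y1 = cl1.front();
          cl1.clear();
          total = x + y1 + y2;
        }
        if (des1 && !des2 && !cl2.empty() && cl2.front() >= n_star2) {
          des2 = true;
          y2 = cl2.front();
          cl2.clear();
          total = x + y1 + y2;
        }
        if (total >= M) {
          f1[run] = (y1 + y2) / total;
          f2[run] = y2 / total;
          done = true;
          break;
        }
        if (total <= 0.0) { ++rejected; break; }

        const double u0 = des1 ? 0.0 : u;       // type-0 -> type-1 channel
        const double u1 = (des1 && !des2) ? u : 0.0;  // type-1 -> type-2
        const double r0 = x * (b + d + u0);
        const double r1 = y1 * (k1 + u1);
        const double R = r0 + r1 + y2 * k2;
        const double v = rng.unif() * R;

        if (v < x * b) { x += 1.0; total += 1.0; }
        else if (v < x * (b + d)) {
          x -= 1.0; total -= 1.0;
        } else if (v < r0) {
          // new type-1 clone (founding order preserved)
          x -= 1.0;
          y1 += 1.0;
          cl1.push_back(1.0);
        } else if (v < r0 + r1) {
          double w = v - r0;
          if (des1) {
            // single tracked clone: divide, die, or mutate to type-2
            if (w < y1 * b1) { y1 += 1.0; total += 1.0; }
            else if (w < y1 * (b1 + d1)) { y1 -= 1.0; total -= 1.0; }
            else {
              y1 -= 1.0;
              y2 += 1.0;
              if (1.0 >= n_star2) {
                des2 = true; cl2.clear(); y2 = 1.0; total = x + y1 + 1.0;
              } else cl2.push_back(1.0);
            }
          } else {
            size_t k = 0;
            if (cl1.size() > 1) {
              double cum = cl1[0] * k1;
              while (w >= cum && k + 1 < cl1.size()) { w -= cum; ++k; cum = cl1[k] * k1; }
            }
            const double sz = cl1[k];
            if (w < sz * b1) {
              cl1[k] = sz + 1.0;
              y1 += 1.0; total += 1.0;
            } else {
              cl1[k] = sz - 1.0;
              y1 -= 1.0; total -= 1.0;
              if (cl1[k] <= 0.0) cl1.erase(cl1.begin() + k);
            }
          }
        } else {
          double w = v - r0 - r1;
          if (des2) {
            if (w < y2 * b2) { y2 += 1.0; total += 1.0; }
            else { y2 -= 1.0; total -= 1.0; }
          } else {
            size_t k = 0;
            if (cl2.size() > 1) {
              double cum = cl2[0] * k2;
              while (w >= cum && k + 1 < cl2.size()) { w -= cum; ++k; cum = cl2[k] * k2; }
            }
            const double sz = cl2[k];
            if (w < sz * b2) {
              cl2[k] = sz + 1.0;
              y2 += 1.0; total += 1.0;
            } else {
              cl2[k] = sz - 1.0;
              y2 -= 1.0; total -= 1.0;
              if (cl2[k] <= 0.0) cl2.erase(cl2.begin() + k);
            }
          }
        }
      }
    }
    if (run % 20 == 0) Rcpp::checkUserInterrupt();
  }
  return List::create(_["f_first"] = f1, _["f_second"] = f2,
                      _["n_rejected"] = rejected, _["attempts"] = attempts);
}

// Validation variant matching the analytic observable exactly: the full
// multi-clone process is simulated, but size is scored as the two-type
// subsystem (type-0 cells + the first surviving driver clone); the run stops
// when that subsystem reaches M and reports the clone's share of it. Clones
// do not interact in a branching process, so the subsystem is exactly the
// two-type model behind the frequency distribution.
//
// [[Rcpp::export]]
List branching_sim_eq1_cpp(double b, double d, double b1, double d1,
                           double u, double M, int n_runs, double seed,
                           double max_attempts = 1e9) {
  if (n_runs < 1) stop("n_runs must be >= 1");
  NumericVector f_sub(n_runs);
  const uint64_t useed = (uint64_t)seed;
  double attempts = 0.0;
  int rejected = 0;
  const double k0u = b + d + u, k1 = b1 + d1;

  for (int run = 0; run < n_runs; ++run) {
    bool done = false;
    while (!done) {
      if (attempts >= max_attempts) stop("max_attempts exceeded");
      Xoshiro256 rng = Xoshiro256::stream(useed, (uint64_t)attempts);
      attempts += 1.0;

      double x0 = 1.0, ytot = 0.0;
      std::vector<double> clones;  // founding order, alive clones only

      for (;;) {
        const double yfirst = clones.empty() ? 0.0 : clones.front();
        if (x0 + yfirst >= M) {
          f_sub[run] = yfirst / (x0 + yfirst);
          done = true;
          break;
        }
        if (x0 + ytot <= 0.0) { ++rejected; break; }

        const double rate0 = x0 * k0u;
        const double R = rate0 + ytot * k1;
        const double v = rng.unif() * R;

        if (v < x0 * b) {
          x0 += 1.0;
        } else if (v < x0 * (b + d)) {
          x0 -= 1.0;
        } else if (v < rate0) {
          x0 -= 1.0;
          ytot += 1.0;
          clones.push_back(1.0);
        } else {
          double w = v - rate0;
          size_t k = 0;
          if (clones.size() > 1) {
            double cum = clones[0] * k1;
            while (w >= cum && k + 1 < clones.size()) {
              w -= cum;
              ++k;
              cum = clones[k] * k1;
            }
          }
          const double sz = clones[k];
          if (w < sz * b1) {
            clones[k] = sz + 1.0;
            ytot += 1.0;
          } else {
            clones[k] = sz - 1.0;
            ytot -= 1.0;
            if (clones[k] <= 0.0) clones.erase(clones.begin() + k);
          }
        }
      }
    }
    if (run % 10 == 0) Rcpp::checkUserInterrupt();
  }
  return List::create(_["f_sub"] = f_sub,
                      _["n_rejected"] = rejected, _["attempts"] = attempts);
}
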