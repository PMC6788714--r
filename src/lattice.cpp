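#include <Rcpp.h>
#include <vector>
#include <cstdlib>
#include "rng.h"

using namespace Rcpp;

// Event-driven 3d lattice tumor growth with a single driver mutation.
//
// Cells occupy sites of a simple cubic lattice (Moore 26-neighborhood by
// default, von Neumann 6 optional). A cell dies with rate d (type 0) or d1
// (type 1) and replicates with rate b * (fraction of empty neighbors); a
// fully surrounded cell cannot replicate. A replication places the daughter
// on a uniformly chosen empty neighbor site; the daughter of a type-0 cell
// is a mutant with probability mut_prob, after which further mutations are
// forbidden. Runs whose population goes extinct are rejected and restarted;
// runs that never produce a mutant by the final size are rejected; runs
// whose mutant lineage dies out are accepted with f_sub = 0 unless
// reject_driver_extinct.
//
// Driver fraction is recorded at the first moment the population reaches
// each requested size (ascending), so one run yields the whole size sweep.
//
// Near the contact-process threshold (d/b close to the critical ratio) the
// population grows as a sparse cloud whose radius cannot be predicted from
// its size, so the bounding box is adaptive: when an attempt outgrows the
// box, the box is enlarged and the same attempt is re-run from its own RNG
// stream, which reproduces the identical trajectory. Results are therefore
// independent of the initial box size.

namespace {

struct Lattice {
  int L;
  long LL, L3, center;
  int nn;
  std::vector<long> offs;
  std::vector<uint8_t> type;     // 0 empty, 1 type-0, 2 type-1
  std::vector<uint8_t> emptyN;   // empty-neighbor count of each site
  std::vector<int> cellIdx;      // index into the per-type cell list
  std::vector<long> cells0, cells1;

  void build(int side, int neighborhood) {
    L = side;
    LL = (long)L * L;
    L3 = LL * L;
    center = (long)(L / 2) * (LL + L + 1);
    offs.clear();
    if (neighborhood == 6) {
      long o[6] = {1, -1, L, -L, LL, -LL};
      offs.assign(o, o + 6);
    } else {
      for (int dz = -1; dz <= 1; ++dz)
        for (int dy = -1; dy <= 1; ++dy)
          for (int dx = -1; dx <= 1; ++dx)
            if (dx || dy || dz) offs.push_back(dx + L * (long)dy + LL * (long)dz);
    }
    nn = (int)offs.size();
    type.assign(L3, 0);
    emptyN.assign(L3, (uint8_t)nn);
    cellIdx.assign(L3, 0);
    cells0.clear();
    cells1.clear();
  }

  // reset only the subcube touched by the last attempt
  void clear_region(long cheb) {
    const long h = L / 2;
    long lo = h - cheb - 2, hi = h + cheb + 2;
    if (lo < 0) lo = 0;
    if (hi > L - 1) hi = L - 1;
    for (long z = lo; z <= hi; ++z)
      for (long y = lo; y <= hi; ++y) {
        const long base = z * LL + y * L;
        std::fill(type.begin() + base + lo, type.begin() + base + hi + 1, (uint8_t)0);
        std::fill(emptyN.begin() + base + lo, emptyN.begin() + base + hi + 1, (uint8_t)nn);
      }
    cells0.clear();
    cells1.clear();
  }
};

struct AttemptOut {
  int status;  // 0 finished, 1 extinct, 2 overflow
  bool mutated;
  bool driver_alive;
  long cheb;   // touched radius (for clearing)
  std::vector<double> frec, trec;
};

template <bool TrackTime>
void one_attempt(Lattice &lat, Xoshiro256 rng, double b, double d, double d1,
                 double mut_prob, const IntegerVector &sizes, AttemptOut &out) {
  const int n_sizes = sizes.size();
  out.status = 0;
  out.mutated = false;
  out.cheb = 1;
  out.frec.assign(n_sizes, NA_REAL);
  out.trec.assign(n_sizes, NA_REAL);

  const int nn = lat.nn;
  const long h = lat.L / 2;

  lat.type[lat.center] = 1;
  lat.cellIdx[lat.center] = 0;
  lat.cells0.push_back(lat.center);
  for (int j = 0; j < nn; ++j) lat.emptyN[lat.center + lat.offs[j]]--;
  double S_empty = nn;

  double t = 0.0;
  int next_size = 0;

  while (next_size < n_sizes) {
    const long n0 = (long)lat.cells0.size(), n1 = (long)lat.cells1.size();
    const long n = n0 + n1;
    if (n == 0) { out.status = 1; return; }

    const double D = n0 * d + n1 * d1;
    const double B = b * S_empty / nn;
    const double R = D + B;
    if (!(R > 0.0) || S_empty < 0.0)
      stop("internal: non-positive event rate (bookkeeping corrupted)");
    if (TrackTime) t += rng.rexp() / R;

    const double v = rng.unif() * R;
    if (v < D) {
      // death; v is uniform on [0, D), so it also picks the victim
      long site;
      if (v < n0 * d) {
        long i = (long)(v / d);
        if (i >= n0) i = n0 - 1;  // guard the floating-point boundary
        if (i < 0) stop("internal: negative type-0 death index");
        site = lat.cells0[i];
        lat.cells0[i] = lat.cells0.back();
        lat.cellIdx[lat.cells0[i]] = (int)i;
        lat.cells0.pop_back();
      } else {
        long i = (long)((v - n0 * d) / d1);
        if (i >= n1) i = n1 - 1;
        if (i < 0) stop("internal: negative type-1 death index");
        site = lat.cells1[i];
        lat.cells1[i] = lat.cells1.back();
        lat.cellIdx[lat.cells1[i]] = (int)i;
        lat.cells1.pop_back();
      }
      if (lat.type[site] == 0) stop("internal: death at empty site");
      lat.type[site] = 0;
      S_empty -= lat.emptyN[site];
      for (int j = 0; j < nn; ++j) {
        const long nb = site + lat.offs[j];
        if (lat.emptyN[nb] >= nn) stop("internal: emptyN overflow on death");
        lat.emptyN[nb]++;
        if (lat.type[nb]) S_empty += 1.0;
      }
    } else {
      // replication: pick parent weighted by its empty-neighbor count
      long parent;
      for (;;) {
        const double v = rng.unif() * n * nn;
        const long i = (long)(v / nn);
        const long site = (i < n0) ? lat.cells0[i] : lat.cells1[i - n0];
        if (v - i * nn < lat.emptyN[site]) { parent = site; break; }
      }
      // uniform empty neighbor
      int pick = (int)(rng.unif() * lat.emptyN[parent]);
      long target = 0;
      for (int j = 0; j < nn; ++j) {
        const long nb = parent + lat.offs[j];
        if (!lat.type[nb] && pick-- == 0) { target = nb; break; }
      }
      // track extent; stop before touching a boundary neighborhood
      {
        const long z = target / lat.LL, rem = target % lat.LL;
        const long y = rem / lat.L, x = rem % lat.L;
        long cheb = std::labs(x - h);
        if (std::labs(y - h) > cheb) cheb = std::labs(y - h);
        if (std::labs(z - h) > cheb) cheb = std::labs(z - h);
        if (cheb > out.cheb) out.cheb = cheb;
        if (cheb >= h - 1) { out.status = 2; return; }
      }
      if (target < 0 || target >= lat.L3 || lat.type[target])
        stop("internal: invalid replication target");
      uint8_t child = lat.type[parent];
      if (child == 1 && !out.mutated && rng.unif() < mut_prob) {
        child = 2;
        out.mutated = true;
      }
      lat.type[target] = child;
      if (child == 1) {
        lat.cellIdx[target] = (int)lat.cells0.size();
        lat.cells0.push_back(target);
      } else {
        lat.cellIdx[target] = (int)lat.cells1.size();
        lat.cells1.push_back(target);
      }
      S_empty += lat.emptyN[target];
      for (int j = 0; j < nn; ++j) {
        const long nb = target + lat.offs[j];
        if (lat.emptyN[nb] == 0) stop("internal: emptyN underflow on birth");
        lat.emptyN[nb]--;
        if (lat.type[nb]) S_empty -= 1.0;
      }
      const long nnew = n + 1;
      if (nnew == sizes[next_size]) {
        out.frec[next_size] = (double)lat.cells1.size() / nnew;
        out.trec[next_size] = t;
        next_size++;
      }
    }
  }
  out.driver_alive = !lat.cells1.empty();
}

}  // namespace

// [[Rcpp::export]]
List lattice_sim_cpp(double b, double d, double d1, double mut_prob,
                     IntegerVector sizes, int n_runs, double seed,
                     int neighborhood = 26,
                     bool reject_driver_extinct = false,
                     bool reject_driverless = true,
                     bool track_time = true,
                     double max_attempts = 1e7,
                     double margin = 2.0) {
  if (n_runs < 1) stop("n_runs must be >= 1");
  if (sizes.size() < 1) stop("at least one target size required");
  for (int i = 1; i < sizes.size(); ++i)
    if (sizes[i] <= sizes[i - 1]) stop("sizes must be strictly increasing");
  if (neighborhood != 6 && neighborhood != 26) stop("neighborhood must be 6 or 26");

  const int n_sizes = sizes.size();
  const int max_n = sizes[n_sizes - 1];

  // initial box: compact-sphere radius over the mean-field bulk density
  // 1 - d/b (halved for near-critical depletion); enlarged on demand
  double rho = 0.5 * (1.0 - d / b);
  if (rho < 0.02) rho = 0.02;
  const double radius = std::cbrt(3.0 * max_n / (4.0 * M_PI * rho));
  int L = 2 * (int)std::ceil(margin * radius + 5.0) + 1;

  Lattice lat;
  lat.build(L, neighborhood);

  NumericMatrix f_at_size(n_runs, n_sizes);
  NumericMatrix t_at_size(n_runs, n_sizes);
  LogicalVector mutated_flag(n_runs), driver_alive_flag(n_runs);
  IntegerVector rejected_extinct(n_runs), rejected_driverless(n_runs);

  const uint64_t useed = (uint64_t)seed;
  double attempts = 0.0;
  int rej_ext = 0, rej_nodrv = 0;
  AttemptOut out;

  for (int run = 0; run < n_runs; ++run) {
    bool accepted = false;
    while (!accepted) {
      if (attempts >= max_attempts) stop("max_attempts exceeded");
      Rcpp::checkUserInterrupt();

      // run this attempt, enlarging the box until it fits; the RNG stream
      // restarts identically, so the trajectory is reproduced exactly
      for (;;) {
        if (track_time)
          one_attempt<true>(lat, Xoshiro256::stream(useed, (uint64_t)attempts),
                            b, d, d1, mut_prob, sizes, out);
        else
          one_attempt<false>(lat, Xoshiro256::stream(useed, (uint64_t)attempts),
                             b, d, d1, mut_prob, sizes, out);
        if (out.status != 2) break;
        if ((double)lat.L * lat.L * lat.L * 8.0 > 4e9)
          stop("lattice grew beyond the memory budget");
        lat.build((int)(lat.L * 1.6) | 1, neighborhood);
      }
      lat.clear_region(out.cheb);
      attempts += 1.0;

      if (out.status == 1) { ++rej_ext; continue; }
      if (reject_driverless && !out.mutated) { ++rej_nodrv; continue; }
      if (reject_driver_extinct && !out.driver_alive) { ++rej_nodrv; continue; }

      for (int k = 0; k < n_sizes; ++k) {
        f_at_size(run, k) = out.frec[k];
        t_at_size(run, k) = out.trec[k];
      }
      mutated_flag[run] = out.mutated;
      driver_alive_flag[run] = out.driver_alive;
      rejected_extinct[run] = rej_ext;
      rejected_driverless[run] = rej_nodrv;
      rej_ext = 0;
      rej_nodrv = 0;
      accepted = true;
    }
  }

  return List::create(_["f_at_size"] = f_at_size,
                      _["t_at_size"] = t_at_size,
                      _["mutated"] = mutated_flag,
                      _["driver_alive"] = driver_alive_flag,
                      _["rejected_extinct"] = rejected_extinct,
                      _["rejected_driverless"] = rejected_driverless,
                      _["attempts"] = attempts,
                      _["lattice_side"] = lat.L);
}
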