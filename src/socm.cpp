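// 3D Bak-Tang-Wiesenfeld sandpile with tunable propagation efficacy dE.
//
// Dynamics: each site carries a continuous energy E >= 0. When E reaches
// the threshold (6, the coordination number of the cubic lattice) the site
// topples: it loses exactly 6 units and each of its six nearest neighbours
// gains dE (energy sent across the lattice boundary is lost - open
// boundaries). Sweeps are synchronous: all super-threshold sites topple
// simultaneously, and the avalanche duration is the number of sweeps. The
// model is driven by single energy-unit grains at uniformly random sites,
// only when the lattice is quiescent (separation of timescales). dE = 1 is
// conservative in the bulk (critical); dE < 1 dissipates (subcritical);
// dE > 1 creates energy (supercritical, capped by max_sweeps).

#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

namespace {

struct RelaxScratch {
  std::vector<int> active, next, stamp;
  int stampval = 0;
  void init(int n) {
    stamp.assign(n, 0);
    stampval = 0;
    active.reserve(1024);
    next.reserve(1024);
  }
};

struct RelaxResult {
  long long size = 0;      // total topplings
  long long duration = 0;  // sweeps
  long long boundary_edges = 0;
  bool truncated = false;
};

// One relaxation starting from the current set of super-threshold sites.
// If sub_mask is non-null, per-sweep counts of topplings on marked sites
// are appended to *sub_counts; if sweep_sizes is non-null, per-sweep
// toppling counts are appended there.
RelaxResult relax(std::vector<double> &E, int L, double dE,
                  long long max_sweeps, RelaxScratch &sc,
                  const std::vector<char> *sub_mask,
                  std::vector<int> *sub_counts,
                  std::vector<int> *sweep_sizes) {
  const double THR = 6.0;
  const int N = L * L * L;
  RelaxResult res;
  sc.active.clear();
  for (int i = 0; i < N; ++i)
    if (E[i] >= THR) sc.active.push_back(i);
  const int LL = L * L;
  while (!sc.active.empty()) {
    if (res.duration >= max_sweeps) { res.truncated = true; break; }
    ++res.duration;
    const int ntop = (int)sc.active.size();
    res.size += ntop;
    int subc = 0;
    // apply all topplings of this sweep
    for (int k = 0; k < ntop; ++k) {
      const int site = sc.active[k];
      E[site] -= THR;
      if (sub_mask && (*sub_mask)[site]) ++subc;
      const int z = site / LL, r = site % LL, y = r / L, x = r % L;
      if (x > 0) E[site - 1] += dE; else ++res.boundary_edges;
      if (x < L - 1) E[site + 1] += dE; else ++res.boundary_edges;
      if (y > 0) E[site - L] += dE; else ++res.boundary_edges;
      if (y < L - 1) E[site + L] += dE; else ++res.boundary_edges;
      if (z > 0) E[site - LL] += dE; else ++res.boundary_edges;
      if (z < L - 1) E[site + LL] += dE; else ++res.boundary_edges;
    }
    if (sub_counts) sub_counts->push_back(subc);
    if (sweep_sizes) sweep_sizes->push_back(ntop);
    // collect the next sweep's super-threshold sites (toppled sites and
    // their neighbours are the only candidates)
    sc.next.clear();
    ++sc.stampval;
    for (int k = 0; k < ntop; ++k) {
      const int site = sc.active[k];
      const int z = site / LL, r = site % LL, y = r / L, x = r % L;
      const int cand[7] = {site,
                           x > 0 ? site - 1 : -1, x < L - 1 ? site + 1 : -1,
                           y > 0 ? site - L : -1, y < L - 1 ? site + L : -1,
                           z > 0 ? site - LL : -1,
                           z < L - 1 ? site + LL : -1};
      for (int c = 0; c < 7; ++c) {
        const int s2 = cand[c];
        if (s2 >= 0 && sc.stamp[s2] != sc.stampval && E[s2] >= THR) {
          sc.stamp[s2] = sc.stampval;
          sc.next.push_back(s2);
        }
      }
    }
    sc.active.swap(sc.next);
  }
  return res;
}

int draw_site(int N) {
  int s;
  do {
    s = (int)std::floor(unif_rand() * N);
  } while (s >= N);
  return s;
}

double mean_energy(const std::vector<double> &E) {
  double tot = 0;
  for (double e : E) tot += e;
  return tot / (double)E.size();
}

}  // namespace

// Relax a supplied energy configuration (no driving). Exposed for the
// single-avalanche contract and for exact energy bookkeeping checks.
// [[Rcpp::export]]
List socm_relax_cpp(NumericVector energies, int L, double dE,
                    double max_sweeps, IntegerVector sub_idx) {
  const int N = L * L * L;
  if ((int)energies.size() != N) stop("energies must have length L^3");
  std::vector<double> E(energies.begin(), energies.end());
  std::vector<char> mask;
  std::vector<int> sub_counts, sweep_sizes;
  const std::vector<char> *maskp = nullptr;
  if (sub_idx.size() > 0) {
    mask.assign(N, 0);
    for (int i = 0; i < sub_idx.size(); ++i) {
      int s = sub_idx[i];
      if (s < 0 || s >= N) stop("sub_idx out of range");
      mask[s] = 1;
    }
    maskp = &mask;
  }
  RelaxScratch sc;
  sc.init(N);
  RelaxResult r = relax(E, L, dE, (long long)max_sweeps, sc, maskp,
                        maskp ? &sub_counts : nullptr, &sweep_sizes);
  return List::create(
      _["energies"] = NumericVector(E.begin(), E.end()),
      _["size"] = (double)r.size, _["duration"] = (double)r.duration,
      _["boundary_edges"] = (double)r.boundary_edges,
      _["truncated"] = r.truncated,
      _["sweep_topplings"] = IntegerVector(sweep_sizes.begin(),
                                           sweep_sizes.end()),
      _["sub_counts"] = IntegerVector(sub_counts.begin(),
                                      sub_counts.end()));
}

// Drive-relax loop: burn-in followed by n_avalanches recorded avalanches.
// Uses R's RNG (seed with set.seed() on the R side). Subsampled events are
// reported on a concatenated sweep ("tick") axis where consecutive
// avalanches are separated by one empty tick.
// [[Rcpp::export]]
List socm_run_cpp(int L, double dE, int n_avalanches, int burn_in,
                  double max_sweeps, IntegerVector sub_idx,
                  double init_mean_energy, bool stationarity_stop) {
  const int N = L * L * L;
  std::vector<double> E(N);
  for (int i = 0; i < N; ++i) E[i] = unif_rand() * init_mean_energy * 2.0;
  std::vector<char> mask;
  const std::vector<char> *maskp = nullptr;
  if (sub_idx.size() > 0) {
    mask.assign(N, 0);
    for (int i = 0; i < sub_idx.size(); ++i) {
      int s = sub_idx[i];
      if (s < 0 || s >= N) stop("sub_idx out of range");
      mask[s] = 1;
    }
    maskp = &mask;
  }
  RelaxScratch sc;
  sc.init(N);

  // burn-in, with optional early stop once the running mean energy per
  // site drifts by < 0.1% between consecutive windows (three times in a
  // row)
  std::vector<double> etrace;
  const int check_every = 2000;
  int stable = 0;
  double prev_m = -1;
  long long burn_drives = 0;
  for (int i = 0; i < burn_in; ++i) {
    const int site = draw_site(N);
    E[site] += 1.0;
    if (E[site] >= 6.0)
      relax(E, L, dE, (long long)max_sweeps, sc, nullptr, nullptr, nullptr);
    ++burn_drives;
    if ((i + 1) % check_every == 0) {
      const double m = mean_energy(E);
      etrace.push_back(m);
      if (stationarity_stop && prev_m > 0 &&
          std::fabs(m - prev_m) / m < 1e-3) {
        if (++stable >= 3) break;
      } else {
        stable = 0;
      }
      prev_m = m;
    }
  }

  std::vector<double> sizes, durations;
  std::vector<int> truncated;
  std::vector<double> sub_tick;
  std::vector<int> sub_count, sub_counts_buf;
  sizes.reserve(n_avalanches);
  durations.reserve(n_avalanches);
  long long tick = 0, drives = 0;
  int recorded = 0;
  while (recorded < n_avalanches) {
    const int site = draw_site(N);
    E[site] += 1.0;
    ++drives;
    if (E[site] < 6.0) continue;
    sub_counts_buf.clear();
    RelaxResult r =
        relax(E, L, dE, (long long)max_sweeps, sc, maskp,
              maskp ? &sub_counts_buf : nullptr, nullptr);
    if (r.size == 0) continue;
    sizes.push_back((double)r.size);
    durations.push_back((double)r.duration);
    truncated.push_back(r.truncated ? 1 : 0);
    if (maskp) {
      for (size_t k = 0; k < sub_counts_buf.size(); ++k) {
        if (sub_counts_buf[k] > 0) {
          sub_tick.push_back((double)(tick + (long long)k));
          sub_count.push_back(sub_counts_buf[k]);
        }
      }
    }
    tick += r.duration + 1;  // one empty tick separates avalanches
    ++recorded;
    if (recorded % 4096 == 0) Rcpp::checkUserInterrupt();
  }
  return List::create(
      _["sizes"] = NumericVector(sizes.begin(), sizes.end()),
      _["durations"] = NumericVector(durations.begin(), durations.end()),
      _["truncated"] = IntegerVector(truncated.begin(), truncated.end()),
      _["sub_tick"] = NumericVector(sub_tick.begin(), sub_tick.end()),
      _["sub_count"] = IntegerVector(sub_count.begin(), sub_count.end()),
      _["total_ticks"] = (double)tick, _["n_drives"] = (double)drives,
      _["burn_drives"] = (double)burn_drives,
      _["energy_trace"] = NumericVector(etrace.begin(), etrace.end()),
      _["mean_energy"] = mean_energy(E));
}

// Virtual-LFP sampling: run the driven model and record, at every sweep,
// each electrode's Gaussian-kernel-weighted sum of topplings. Electrode
// tips are 0-based lattice coordinates (rows of `tips`). Runs until
// n_ticks sweeps (including the single empty tick after each avalanche)
// have been emitted.
// [[Rcpp::export]]
List socm_lfp_cpp(int L, double dE, double n_ticks, int burn_in,
                  double max_sweeps, NumericMatrix tips, double kernel_var,
                  double init_mean_energy, NumericVector init_energies) {
  const int N = L * L * L;
  const int ne = tips.nrow();
  const long long target = (long long)n_ticks;
  std::vector<double> E(N);
  if (init_energies.size() == N) {
    for (int i = 0; i < N; ++i) E[i] = init_energies[i];
  } else {
    for (int i = 0; i < N; ++i) E[i] = unif_rand() * init_mean_energy * 2.0;
  }
  RelaxScratch sc;
  sc.init(N);
  for (int i = 0; i < burn_in; ++i) {
    const int site = draw_site(N);
    E[site] += 1.0;
    if (E[site] >= 6.0)
      relax(E, L, dE, (long long)max_sweeps, sc, nullptr, nullptr, nullptr);
  }

  NumericMatrix sig(ne, (int)target);
  // weight cutoff: contributions below exp(-18) are dropped
  const double d2max = 2.0 * kernel_var * 18.0;
  const double inv2v = 1.0 / (2.0 * kernel_var);
  const int LL = L * L;
  long long tick = 0;
  long long n_aval = 0;
  const double THR = 6.0;
  // relax the current active set, accumulating electrode signals per sweep
  auto relax_record = [&]() {
    long long dur = 0;
    bool any = false;
    while (!sc.active.empty() && tick < target) {
      if (dur >= (long long)max_sweeps) break;
      ++dur;
      any = true;
      const int ntop = (int)sc.active.size();
      for (int k = 0; k < ntop; ++k) {
        const int site = sc.active[k];
        E[site] -= THR;
        const int z = site / LL, r = site % LL, y = r / L, x = r % L;
        for (int e = 0; e < ne; ++e) {
          const double dx = x - tips(e, 0), dy = y - tips(e, 1),
                       dz = z - tips(e, 2);
          const double d2 = dx * dx + dy * dy + dz * dz;
          if (d2 <= d2max) sig(e, (int)tick) += std::exp(-d2 * inv2v);
        }
        if (x > 0) E[site - 1] += dE;
        if (x < L - 1) E[site + 1] += dE;
        if (y > 0) E[site - L] += dE;
        if (y < L - 1) E[site + L] += dE;
        if (z > 0) E[site - LL] += dE;
        if (z < L - 1) E[site + LL] += dE;
      }
      sc.next.clear();
      ++sc.stampval;
      for (int k = 0; k < ntop; ++k) {
        const int site = sc.active[k];
        const int z = site / LL, r = site % LL, y = r / L, x = r % L;
        const int cand[7] = {site,
                             x > 0 ? site - 1 : -1,
                             x < L - 1 ? site + 1 : -1,
                             y > 0 ? site - L : -1,
                             y < L - 1 ? site + L : -1,
                             z > 0 ? site - LL : -1,
                             z < L - 1 ? site + LL : -1};
        for (int c = 0; c < 7; ++c) {
          const int s2 = cand[c];
          if (s2 >= 0 && sc.stamp[s2] != sc.stampval && E[s2] >= THR) {
            sc.stamp[s2] = sc.stampval;
            sc.next.push_back(s2);
          }
        }
      }
      sc.active.swap(sc.next);
      ++tick;
    }
    if (any) {
      ++n_aval;
      if (tick < target) ++tick;  // empty separator tick
    }
  };
  // sites already above threshold in the supplied configuration
  sc.active.clear();
  for (int i = 0; i < N; ++i)
    if (E[i] >= THR) sc.active.push_back(i);
  if (!sc.active.empty()) relax_record();
  while (tick < target) {
    const int site0 = draw_site(N);
    E[site0] += 1.0;
    if (E[site0] < THR) continue;
    sc.active.clear();
    sc.active.push_back(site0);
    relax_record();
    if (n_aval % 1024 == 0) Rcpp::checkUserInterrupt();
  }
  return List::create(_["signals"] = sig, _["n_avalanches"] = (double)n_aval,
                      _["mean_energy"] = mean_energy(E));
}
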