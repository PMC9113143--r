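#include <Rcpp.h>
#include <cmath>
#include <vector>
using namespace Rcpp;

// Wright-Fisher forward core for mtDNA heteroplasmy under a dilution
// bottleneck. Uses R's RNG throughout so set.seed() governs everything.
//
// State is the vector of copy counts of segregating mutations (infinite-sites
// bookkeeping: each mutation a unique entry; zero-count entries pruned).

static void evolve_once(std::vector<double> &counts, int n_cur, int n_next,
                        double u) {
  size_t keep = 0;
  for (size_t i = 0; i < counts.size(); ++i) {
    double c = R::rbinom((double)n_next, counts[i] / (double)n_cur);
    if (c > 0)
      counts[keep++] = c;
  }
  counts.resize(keep);
  int fresh = (int)R::rpois(u * (double)n_next);
  for (int k = 0; k < fresh; ++k)
    counts.push_back(1.0);
}

// One WF generation: resample existing mutation counts into a population of
// next_n copies, prune losses, add Poisson(u * next_n) new single-copy
// mutations.
// [[Rcpp::export]]
NumericVector cpp_evolve_generation(NumericVector counts, int cur_n,
                                    int next_n, double u) {
  if (next_n < 1)
    stop("mtDNA population extinct: next_N < 1");
  if (cur_n < 1)
    stop("current copy number must be >= 1");
  std::vector<double> st(counts.begin(), counts.end());
  for (double c : st)
    if (c < 0 || c > cur_n)
      stop("mutation count outside [0, N]");
  evolve_once(st, cur_n, next_n, u);
  return wrap(st);
}

static std::vector<double> lineage_vafs(int n0, double alpha, int td, int ta,
                                        double u) {
  int n = n0;
  std::vector<double> counts;
  int dil = td < ta ? td : ta;
  // Diluting divisions: only a fraction alpha of molecules replicates.
  for (int t = 0; t < dil; ++t) {
    int nn = (int)std::lround(alpha * (double)n);
    if (nn < 1)
      stop("mtDNA population extinct during dilution (Nb reached 0)");
    evolve_once(counts, n, nn, u);
    n = nn;
  }
  // Copy number stays at the bottleneck minimum through development; the
  // final (maturation) division rapidly restores the baseline.
  for (int t = dil; t < ta; ++t) {
    int nn = (t == ta - 1) ? n0 : n;
    evolve_once(counts, n, nn, u);
    n = nn;
  }
  std::vector<double> vafs(counts.size());
  for (size_t i = 0; i < counts.size(); ++i)
    vafs[i] = counts[i] / (double)n;
  return vafs;
}

// Final VAFs of one lineage run for ta generations: td diluting generations
// (N_{t+1} = round(alpha * N_t)), a sustained phase at the bottleneck
// minimum, and a final recovery generation back to n0.
// [[Rcpp::export]]
NumericVector cpp_simulate_lineage(int n0, double alpha, int td, int ta,
                                   double u) {
  return wrap(lineage_vafs(n0, alpha, td, ta, u));
}

// [[Rcpp::export]]
List cpp_simulate_cellset(int n_cells, int n0, double alpha, int td, int ta,
                          double u) {
  List out(n_cells);
  for (int i = 0; i < n_cells; ++i)
    out[i] = wrap(lineage_vafs(n0, alpha, td, ta, u));
  return out;
}

// Bin VAFs into the 19-bin spectrum with edges k * 0.05, k = 1..20;
// left-closed bins, last bin [0.95, 1] closed; VAF < 0.05 excluded.
static void add_to_spectrum(const std::vector<double> &vafs, double floor_vaf,
                            std::vector<double> &bins) {
  for (double v : vafs) {
    if (v < floor_vaf || v < 0.05 || v > 1.0)
      continue;
    int b = 0;
    for (int j = 1; j < 20; ++j)
      if (v >= j * 0.05)
        b = j;
    bins[b - 1] += 1.0;
  }
}

// Per-draw Euclidean distances between the observed spectrum and the
// spectrum of a freshly simulated cohort. obs must be on the same
// normalization scale as requested via per_cell_mean.
// [[Rcpp::export]]
NumericVector cpp_abc_distances(NumericVector alpha, IntegerVector td,
                                IntegerVector ta, int n0, double u,
                                int n_cells, NumericVector obs,
                                double detection_floor, bool per_cell_mean) {
  int k = alpha.size();
  if (td.size() != k || ta.size() != k)
    stop("parameter vectors must have equal length");
  if (obs.size() != 19)
    stop("observed spectrum must have 19 bins");
  NumericVector dist(k);
  for (int i = 0; i < k; ++i) {
    if (i % 512 == 0)
      Rcpp::checkUserInterrupt();
    std::vector<double> bins(19, 0.0);
    for (int c = 0; c < n_cells; ++c) {
      std::vector<double> vafs =
          lineage_vafs(n0, alpha[i], td[i], ta[i], u);
      add_to_spectrum(vafs, detection_floor, bins);
    }
    double d2 = 0.0;
    for (int j = 0; j < 19; ++j) {
      double s = bins[j];
      if (per_cell_mean)
        s /= (double)n_cells;
      double diff = s - obs[j];
      d2 += diff * diff;
    }
    dist[i] = std::sqrt(d2);
  }
  return dist;
}

// Constant-N drift replicates: evolve `reps` independent populations of size
// n starting from count0 copies of one allele for `generations` generations
// (no new mutations); returns the final copy count per replicate.
// [[Rcpp::export]]
NumericVector cpp_drift_replicates(int n, int count0, int generations,
                                   int reps) {
  if (count0 < 0 || count0 > n)
    stop("count0 must lie in [0, N]");
  NumericVector out(reps);
  for (int r = 0; r < reps; ++r) {
    double c = count0;
    for (int t = 0; t < generations; ++t) {
      c = R::rbinom((double)n, c / (double)n);
      if (c == 0 || c == n)
        break;
    }
    out[r] = c;
  }
  return out;
}

// Fraction of replicates in which a count0-copy neutral allele fixes before
// loss in a constant-N Wright-Fisher population.
// [[Rcpp::export]]
double cpp_fixation_probability(int n, int count0, int reps, int max_gen) {
  int fixed = 0;
  for (int r = 0; r < reps; ++r) {
    double c = count0;
    for (int t = 0; t < max_gen; ++t) {
      c = R::rbinom((double)n, c / (double)n);
      if (c == 0 || c == n)
        break;
    }
    if (c == n)
      ++fixed;
  }
  return (double)fixed / (double)reps;
}
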