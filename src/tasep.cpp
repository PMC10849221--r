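#include <Rcpp.h>
#include <random>
#include <vector>
#include <deque>
#include <string>
#include <algorithm>
using namespace Rcpp;

// Kinetic Monte Carlo (exact stochastic simulation) of an open-boundary
// TASEP with extended particles of size `footprint` on a lattice of
// L = hop_rates.size() codon sites.
//
// A ribosome is tracked by its leading-edge site i and covers sites
// max(1, i - footprint + 1) .. min(i, L); the decoded (A-site) codon is
// a(i) = max(1, i - footprint + 1).  Initiation at rate alpha requires
// sites 1..footprint vacant and places a ribosome with leading edge at
// `footprint`.  A ribosome hops i -> i+1 at rate hop_rates[a(i)] provided
// the ribosome ahead (leading edge p) satisfies p - i > footprint; the
// leading edge may overhang the lattice end (i > L) while the A-site
// finishes the last codons.  When a(i) == L the ribosome terminates at
// rate beta, freeing all its sites.
//
// Statistics are collected only on the time window [t_burn, t_burn +
// t_measure]; flux standard errors come from `n_batch` equal sub-windows.
// A "collision" is a hop after which the mover is immediately blocked by
// the ribosome ahead (a jamming contact).
// [[Rcpp::export]]
List tasep_kmc_cpp(NumericVector hop_rates, double alpha, double beta,
                   int footprint, double t_burn, double t_measure,
                   int n_batch, int seed) {
  const int L = hop_rates.size();
  if (L < 1) stop("empty hop_rates");
  if (footprint < 1) stop("footprint must be >= 1");
  std::mt19937_64 rng(static_cast<uint64_t>(seed) * 6364136223846793005ULL + 1442695040888963407ULL);
  std::uniform_real_distribution<double> unif(0.0, 1.0);

  std::deque<int> lead;  // leading edges, front() = most downstream
  double t = 0.0;
  const double t_end = t_burn + t_measure;
  const double batch_len = t_measure / n_batch;

  long terminations = 0, initiations = 0, collisions = 0;
  long ribo_at_window_start = -1;
  std::vector<double> occ_time(L, 0.0);
  std::vector<double> batch_term(n_batch, 0.0);
  std::vector<double> rates;  // event rates: [0]=init, then one per ribosome

  while (t < t_end) {
    // enumerate enabled events
    rates.clear();
    bool can_init = lead.empty() || (lead.back() >= 2 * footprint);
    rates.push_back(can_init ? alpha : 0.0);
    for (size_t k = 0; k < lead.size(); ++k) {
      int i = lead[k];
      int a = std::max(1, i - footprint + 1);
      double r = 0.0;
      if (a == L) {
        r = beta;  // termination (front ribosome by construction)
      } else {
        bool blocked = (k > 0) && (lead[k - 1] - i <= footprint);
        if (!blocked) r = hop_rates[a - 1];
      }
      rates.push_back(r);
    }
    double total = 0.0;
    for (double r : rates) total += r;
    if (total <= 0.0) break;  // absorbing (e.g. alpha = 0, empty lattice)

    double dt = -std::log(1.0 - unif(rng)) / total;
    double t_next = t + dt;

    // time-integrated occupancy over the overlap with the measure window
    double lo = std::max(t, t_burn), hi = std::min(t_next, t_end);
    if (hi > lo) {
      double w = hi - lo;
      for (size_t k = 0; k < lead.size(); ++k) {
        int i = lead[k];
        int from = std::max(1, i - footprint + 1);
        int to = std::min(i, L);
        for (int s = from; s <= to; ++s) occ_time[s - 1] += w;
      }
    }
    if (ribo_at_window_start < 0 && t_next >= t_burn)
      ribo_at_window_start = static_cast<long>(lead.size());
    t = t_next;
    if (t >= t_end) break;

    // pick the event
    double u = unif(rng) * total, acc = 0.0;
    int ev = -1;
    for (size_t j = 0; j < rates.size(); ++j) {
      acc += rates[j];
      if (u <= acc) { ev = static_cast<int>(j); break; }
    }
    if (ev < 0) ev = static_cast<int>(rates.size()) - 1;

    bool in_window = (t >= t_burn);
    if (ev == 0) {
      lead.push_back(footprint);
      if (in_window) ++initiations;
    } else {
      size_t k = static_cast<size_t>(ev - 1);
      int i = lead[k];
      int a = std::max(1, i - footprint + 1);
      if (a == L) {
        lead.pop_front();
        if (in_window) {
          ++terminations;
          int b = std::min(n_batch - 1, static_cast<int>((t - t_burn) / batch_len));
          batch_term[b] += 1.0;
        }
      } else {
        lead[k] = i + 1;
        if (in_window && k > 0 && lead[k - 1] - lead[k] <= footprint) ++collisions;
      }
    }
  }
  if (ribo_at_window_start < 0) ribo_at_window_start = static_cast<long>(lead.size());

  NumericVector density(L), batches(n_batch);
  for (int s = 0; s < L; ++s) density[s] = occ_time[s] / t_measure;
  double mean_flux = 0.0;
  for (int b = 0; b < n_batch; ++b) {
    batches[b] = batch_term[b] / batch_len;
    mean_flux += batches[b];
  }
  mean_flux /= n_batch;
  double ss = 0.0;
  for (int b = 0; b < n_batch; ++b) ss += (batches[b] - mean_flux) * (batches[b] - mean_flux);
  double flux_se = std::sqrt(ss / (n_batch - 1.0) / n_batch);

  return List::create(
    _["translation_rate"] = static_cast<double>(terminations) / t_measure,
    _["density"] = density,
    _["terminations"] = static_cast<double>(terminations),
    _["initiations"] = static_cast<double>(initiations),
    _["collisions"] = static_cast<double>(collisions),
    _["flux_se"] = flux_se,
    _["batch_flux"] = batches,
    _["ribosomes_initial"] = static_cast<double>(ribo_at_window_start),
    _["ribosomes_final"] = static_cast<double>(lead.size()));
}

static inline bool can_pair(char a, char b) {
  if (a == 'T') a = 'U';
  if (b == 'T') b = 'U';
  return (a == 'A' && b == 'U') || (a == 'U' && b == 'A') ||
         (a == 'G' && b == 'C') || (a == 'C' && b == 'G') ||
         (a == 'G' && b == 'U') || (a == 'U' && b == 'G');
}

// Nussinov base-pair maximization with a minimum hairpin loop of
// `min_loop` unpaired nucleotides; pairs allowed: AU, GC, GU.
// [[Rcpp::export]]
int nussinov_maxpairs_cpp(std::string seq, int min_loop) {
  int n = static_cast<int>(seq.size());
  if (n == 0) return 0;
  std::vector<std::vector<int> > dp(n, std::vector<int>(n, 0));
  for (int len = min_loop + 2; len <= n; ++len) {
    for (int i = 0; i + len - 1 < n; ++i) {
      int j = i + len - 1;
      int best = dp[i + 1][j];  // i unpaired
      for (int k = i + min_loop + 1; k <= j; ++k) {
        if (can_pair(seq[i], seq[k])) {
          int v = 1 + (k > i + 1 ? dp[i + 1][k - 1] : 0) +
                  (k < j ? dp[k + 1][j] : 0);
          if (v > best) best = v;
        }
      }
      dp[i][j] = best;
    }
  }
  return dp[0][n - 1];
}
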