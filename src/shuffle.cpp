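#include <Rcpp.h>
#include <unordered_map>
#include <vector>
using namespace Rcpp;

// Occurrence-preserving shuffle of a stub list.
//
// A network with per-protein report counts N_i is represented as a list of
// 2N "stubs" (protein index repeated N_i times). One realization:
//   1. Fisher-Yates permutation of the stubs; consecutive stubs form pairs.
//   2. Self-pair repair: while any pair (a,a) remains, swap its second stub
//      with a uniformly chosen stub elsewhere.
//   3. Metropolis mixing: mix_sweeps * 2N proposed stub transpositions,
//      each rejected if it would create a self-pair. The proposal is
//      symmetric, so the stationary distribution is uniform over all
//      self-pair-free stub pairings (the repair step alone is measurably
//      biased on small networks; mixing removes that).
// All randomness comes from R's RNG, so set.seed() upstream fixes the run.

static void one_shuffle(std::vector<int> &s, int mix_sweeps) {
  const int S = (int)s.size();
  const int nrec = S / 2;
  for (int i = S - 1; i > 0; i--) {
    int j = (int)(unif_rand() * (i + 1));
    if (j > i) j = i;
    std::swap(s[i], s[j]);
  }
  std::vector<int> selfs;
  for (int k = 0; k < nrec; k++)
    if (s[2 * k] == s[2 * k + 1]) selfs.push_back(k);
  long long guard = 0;
  while (!selfs.empty()) {
    int k = selfs.back();
    if (s[2 * k] != s[2 * k + 1]) { selfs.pop_back(); continue; }
    int t = (int)(unif_rand() * S);
    if (t >= S) t = S - 1;
    if (t == 2 * k || t == 2 * k + 1) continue;
    std::swap(s[2 * k + 1], s[t]);
    if (s[2 * k] != s[2 * k + 1]) selfs.pop_back();
    int k2 = t / 2;
    if (s[2 * k2] == s[2 * k2 + 1]) selfs.push_back(k2);
    if (++guard > 100000000LL)
      stop("self-pair repair did not converge; network close to infeasible");
  }
  const long long n_prop = (long long)mix_sweeps * S;
  for (long long m = 0; m < n_prop; m++) {
    int u = (int)(unif_rand() * S); if (u >= S) u = S - 1;
    int v = (int)(unif_rand() * S); if (v >= S) v = S - 1;
    if (u == v) continue;
    std::swap(s[u], s[v]);
    int ku = u / 2, kv = v / 2;
    if (s[2 * ku] == s[2 * ku + 1] || s[2 * kv] == s[2 * kv + 1])
      std::swap(s[u], s[v]);  // reject
  }
}

// [[Rcpp::export]]
IntegerVector shuffle_stubs_cpp(IntegerVector stubs, int mix_sweeps) {
  std::vector<int> s(stubs.begin(), stubs.end());
  one_shuffle(s, mix_sweeps);
  return wrap(s);
}

// Streaming ensemble statistics for the observed pairs over M realizations.
// pa/pb: 0-based protein indices of the observed pairs with pa < pb;
// obs: observed occurrences O_ij. Counts are small integers, so plain sums
// of x and x^2 are exact in double precision.
// [[Rcpp::export]]
List randomize_cpp(IntegerVector stubs, IntegerVector pa, IntegerVector pb,
                   IntegerVector obs, int M, int n_prot, int mix_sweeps) {
  const int npair = pa.size();
  std::vector<int> s(stubs.begin(), stubs.end());
  const int nrec = (int)s.size() / 2;
  std::unordered_map<long long, int> idx;
  idx.reserve((size_t)npair * 2);
  for (int i = 0; i < npair; i++)
    idx[(long long)pa[i] * n_prot + pb[i]] = i;
  std::vector<double> sumx(npair, 0.0), sumx2(npair, 0.0);
  std::vector<int> exceed(npair, 0), cnt(npair, 0);
  std::vector<int> touched;
  touched.reserve(nrec);
  for (int m = 0; m < M; m++) {
    one_shuffle(s, mix_sweeps);
    touched.clear();
    for (int k = 0; k < nrec; k++) {
      int a = s[2 * k], b = s[2 * k + 1];
      if (a > b) std::swap(a, b);
      auto it = idx.find((long long)a * n_prot + b);
      if (it != idx.end()) {
        if (cnt[it->second] == 0) touched.push_back(it->second);
        cnt[it->second]++;
      }
    }
    for (int i : touched) {
      double x = cnt[i];
      sumx[i] += x;
      sumx2[i] += x * x;
      if (cnt[i] >= obs[i]) exceed[i]++;
      cnt[i] = 0;
    }
    if (m % 4096 == 0) Rcpp::checkUserInterrupt();
  }
  return List::create(_["sum"] = wrap(sumx), _["sumsq"] = wrap(sumx2),
                      _["exceed"] = wrap(exceed));
}

// Empirical occurrence histograms for the observed pairs: row i gives the
// realization counts of R_ij = 0 .. max_count (last bin clamps).
// [[Rcpp::export]]
IntegerMatrix shuffle_pdf_cpp(IntegerVector stubs, IntegerVector pa,
                              IntegerVector pb, int M, int n_prot,
                              int mix_sweeps, int max_count) {
  const int npair = pa.size();
  std::vector<int> s(stubs.begin(), stubs.end());
  const int nrec = (int)s.size() / 2;
  std::unordered_map<long long, int> idx;
  for (int i = 0; i < npair; i++)
    idx[(long long)pa[i] * n_prot + pb[i]] = i;
  IntegerMatrix hist(npair, max_count + 1);
  std::vector<int> cnt(npair, 0);
  std::vector<int> touched;
  for (int m = 0; m < M; m++) {
    one_shuffle(s, mix_sweeps);
    touched.clear();
    for (int k = 0; k < nrec; k++) {
      int a = s[2 * k], b = s[2 * k + 1];
      if (a > b) std::swap(a, b);
      auto it = idx.find((long long)a * n_prot + b);
      if (it != idx.end()) {
        if (cnt[it->second] == 0) touched.push_back(it->second);
        cnt[it->second]++;
      }
    }
    for (int i = 0; i < npair; i++) {
      int c = cnt[i];
      if (c > max_count) c = max_count;
      hist(i, c)++;
    }
    for (int i : touched) cnt[i] = 0;
    if (m % 4096 == 0) Rcpp::checkUserInterrupt();
  }
  return hist;
}
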