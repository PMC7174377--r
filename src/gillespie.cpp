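#include <Rcpp.h>
using namespace Rcpp;

// Linear birth-death (Gillespie) final sizes for many independent lineages.
// Uses R's RNG stream so set.seed() on the R side makes runs reproducible.
// [[Rcpp::export]]
IntegerVector bd_final_sizes_cpp(int n_lineages, double b, double d,
                                 double t_end, int start_size) {
  IntegerVector out(n_lineages);
  const double rate_sum = b + d;
  for (int i = 0; i < n_lineages; ++i) {
    double t = 0.0;
    long n = start_size;
    if (rate_sum > 0.0) {
      const double p_birth = b / rate_sum;
      while (n > 0) {
        t += R::exp_rand() / (rate_sum * n);
        if (t > t_end) break;
        if (unif_rand() < p_birth) ++n; else --n;
      }
    }
    out[i] = (int) n;
  }
  return out;
}

// Single-lineage trajectory; stops at t_end, extinction, or size_cap
// (size_cap <= 0 disables the cap).
// [[Rcpp::export]]
List bd_trajectory_cpp(double b, double d, double t_end, int size_cap,
                       int start_size) {
  std::vector<double> times;
  std::vector<int> sizes;
  times.push_back(0.0);
  sizes.push_back(start_size);
  double t = 0.0;
  long n = start_size;
  const double rate_sum = b + d;
  if (rate_sum > 0.0) {
    const double p_birth = b / rate_sum;
    while (n > 0 && (size_cap <= 0 || n < size_cap)) {
      t += R::exp_rand() / (rate_sum * n);
      if (t > t_end) break;
      if (unif_rand() < p_birth) ++n; else --n;
      times.push_back(t);
      sizes.push_back((int) n);
    }
  }
  return List::create(_["time"] = wrap(times), _["size"] = wrap(sizes));
}

// For each query sequence, index (1-based) of the nearest reference within
// max_d mismatches, scanning refs in order so that ties resolve to the
// earliest (callers pre-sort refs by priority). Only the first ref_limit[i]
// references are searched for query i (lets callers restrict conforming
// queries to strictly more abundant representatives). 0 means no hit. All
// sequences must share one length; unequal-length queries never match.
// [[Rcpp::export]]
List hamming_nearest_cpp(CharacterVector queries, CharacterVector refs,
                         int max_d, IntegerVector ref_limit) {
  const int nq = queries.size(), nr = refs.size();
  IntegerVector idx(nq), dist(nq);
  std::vector<std::string> rs(nr);
  for (int j = 0; j < nr; ++j) rs[j] = as<std::string>(refs[j]);
  for (int i = 0; i < nq; ++i) {
    std::string q = as<std::string>(queries[i]);
    int best = -1, best_d = max_d + 1;
    const int lim = ref_limit[i] < nr ? ref_limit[i] : nr;
    for (int j = 0; j < lim; ++j) {
      if (rs[j].size() != q.size()) continue;
      int dct = 0;
      const size_t L = q.size();
      for (size_t p = 0; p < L; ++p) {
        if (q[p] != rs[j][p] && ++dct >= best_d) break;
      }
      if (dct < best_d) { best_d = dct; best = j; if (dct == 0) break; }
    }
    idx[i] = best < 0 ? 0 : best + 1;
    dist[i] = best < 0 ? NA_INTEGER : best_d;
  }
  return List::create(_["index"] = idx, _["distance"] = dist);
}
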