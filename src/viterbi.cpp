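#include <Rcpp.h>
using namespace Rcpp;

// Shared Viterbi core over one observation sequence laid out row-major in
// `obs` (T rows of D columns, column-major R matrix accessed via stride).
// Workspaces are supplied by the caller so batch decoding reuses them.
static void viterbi_core(const double* obs, int obs_stride, int T, int D,
                         int K, const double* mean, const double* norm,
                         const double* inv2v, const double* log_trans,
                         const double* log_init, std::vector<double>& delta,
                         std::vector<double>& delta_new,
                         std::vector<int>& back, int* path) {
  auto emit = [&](int t, int k) {
    double ll = 0.0;
    for (int d = 0; d < D; ++d) {
      double z = obs[t + (size_t)d * obs_stride] - mean[k + (size_t)d * K];
      ll += norm[k + (size_t)d * K] - z * z * inv2v[k + (size_t)d * K];
    }
    return ll;
  };
  for (int k = 0; k < K; ++k) delta[k] = log_init[k] + emit(0, k);
  for (int t = 1; t < T; ++t) {
    for (int j = 0; j < K; ++j) {
      int argmax = 0;
      double best = delta[0] + log_trans[0 + (size_t)j * K];
      for (int k = 1; k < K; ++k) {
        double cand = delta[k] + log_trans[k + (size_t)j * K];
        if (cand > best) { best = cand; argmax = k; }
      }
      back[(size_t)t * K + j] = argmax;
      delta_new[j] = best + emit(t, j);
    }
    std::swap(delta, delta_new);
  }
  int last = 0;
  double best = delta[0];
  for (int k = 1; k < K; ++k)
    if (delta[k] > best) { best = delta[k]; last = k; }
  path[T - 1] = last;
  for (int t = T - 1; t > 0; --t)
    path[t - 1] = back[(size_t)t * K + path[t]];
  for (int t = 0; t < T; ++t) path[t] += 1;  // 1-based states
}

static void check_emissions(const NumericMatrix& mean,
                            const NumericMatrix& var, int D, int K,
                            std::vector<double>& norm,
                            std::vector<double>& inv2v) {
  norm.resize((size_t)K * D);
  inv2v.resize((size_t)K * D);
  for (int d = 0; d < D; ++d)
    for (int k = 0; k < K; ++k) {
      double v = var(k, d);
      if (!(v > 0)) stop("non-positive emission variance");
      norm[k + (size_t)d * K] = -0.5 * std::log(2.0 * M_PI * v);
      inv2v[k + (size_t)d * K] = 0.5 / v;
    }
}

// Log-space Viterbi decoding with independent (diagonal) Gaussian
// emissions: obs is T x D, mean/var are K x D, log_trans is K x K,
// log_init length K. Returns the 1-based maximum-a-posteriori state path;
// ties break to the lowest state index.
// [[Rcpp::export]]
IntegerVector viterbi_gaussian(NumericMatrix obs, NumericMatrix mean,
                               NumericMatrix var, NumericMatrix log_trans,
                               NumericVector log_init) {
  const int T = obs.nrow(), D = obs.ncol(), K = mean.nrow();
  if (T == 0) stop("empty observation sequence");
  if (mean.ncol() != D || var.ncol() != D) stop("emission dimension mismatch");
  if (log_trans.nrow() != K || log_trans.ncol() != K ||
      log_init.size() != K)
    stop("state dimension mismatch");
  for (int i = 0; i < T * D; ++i)
    if (!R_finite(obs[i])) stop("non-finite observation");
  std::vector<double> norm, inv2v;
  check_emissions(mean, var, D, K, norm, inv2v);
  std::vector<double> delta(K), delta_new(K);
  std::vector<int> back((size_t)T * K);
  IntegerVector path(T);
  viterbi_core(REAL(obs), T, T, D, K, REAL(mean), norm.data(), inv2v.data(),
               REAL(log_trans), REAL(log_init), delta, delta_new, back,
               INTEGER(path));
  return path;
}

// Batch variant: `obs` stacks the observation rows of many sequences;
// `offsets` (length n+1, 0-based) delimits each sequence. All sequences
// share one emission model. Returns the concatenated 1-based paths.
// [[Rcpp::export]]
IntegerVector viterbi_gaussian_batch(NumericMatrix obs,
                                     IntegerVector offsets,
                                     NumericMatrix mean, NumericMatrix var,
                                     NumericMatrix log_trans,
                                     NumericVector log_init) {
  const int D = obs.ncol(), K = mean.nrow();
  const int n = offsets.size() - 1;
  const int N = obs.nrow();
  if (offsets[0] != 0 || offsets[n] != N) stop("bad offsets");
  if (mean.ncol() != D || var.ncol() != D) stop("emission dimension mismatch");
  for (int i = 0; i < N * D; ++i)
    if (!R_finite(obs[i])) stop("non-finite observation");
  std::vector<double> norm, inv2v;
  check_emissions(mean, var, D, K, norm, inv2v);
  int maxT = 0;
  for (int s = 0; s < n; ++s) {
    int T = offsets[s + 1] - offsets[s];
    if (T <= 0) stop("empty observation sequence in batch");
    if (T > maxT) maxT = T;
  }
  std::vector<double> delta(K), delta_new(K);
  std::vector<int> back((size_t)maxT * K);
  IntegerVector path(N);
  for (int s = 0; s < n; ++s) {
    int T = offsets[s + 1] - offsets[s];
    viterbi_core(REAL(obs) + offsets[s], N, T, D, K, REAL(mean),
                 norm.data(), inv2v.data(), REAL(log_trans), REAL(log_init),
                 delta, delta_new, back, INTEGER(path) + offsets[s]);
  }
  return path;
}
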