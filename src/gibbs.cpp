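#include <Rcpp.h>
using namespace Rcpp;

// Draw an index in 0..K-1 with unnormalized weights p (total = sum(p)).
// Uses R's RNG so set.seed() on the R side makes draws reproducible.
static inline int sample_categorical(const std::vector<double> &p, double tot) {
  const int K = (int)p.size();
  double u = unif_rand() * tot;
  double c = 0.0;
  for (int k = 0; k < K - 1; ++k) {
    c += p[k];
    if (u <= c) return k;
  }
  return K - 1;
}

// [[Rcpp::export]]
IntegerVector cpp_random_topics(int n, int K) {
  IntegerVector z(n);
  for (int i = 0; i < n; ++i) {
    int k = (int)(unif_rand() * K);
    if (k >= K) k = K - 1;  // guard against unif_rand() == 1.0
    z[i] = k;
  }
  return z;
}

// Count matrices consistent with an assignment vector.
// doc_of, word_of, z are 0-based, one entry per token occurrence.
// [[Rcpp::export]]
List cpp_count_state(IntegerVector z, IntegerVector doc_of, IntegerVector word_of,
                     int M, int V, int K) {
  IntegerMatrix n_dk(M, K), n_kw(K, V);
  IntegerVector n_k(K);
  const int T = z.size();
  for (int t = 0; t < T; ++t) {
    n_dk(doc_of[t], z[t])++;
    n_kw(z[t], word_of[t])++;
    n_k[z[t]]++;
  }
  return List::create(_["n_dk"] = n_dk, _["n_kw"] = n_kw, _["n_k"] = n_k);
}

// Collapsed Gibbs sweeps over every token occurrence, document order.
// The token's own assignment is removed from the counts, a new topic is
// drawn with probability proportional to
//   (n_dk[d,k] + alpha) * (n_kw[k,w] + eta) / (n_k[k] + V * eta),
// and the counts are restored with the new assignment.
// If average is true, per-sweep phi/theta point estimates are accumulated
// for sweeps s >= burn_in (0-based) and their means returned.
// [[Rcpp::export]]
List cpp_gibbs(IntegerVector z0, IntegerVector doc_of, IntegerVector word_of,
               IntegerMatrix n_dk0, IntegerMatrix n_kw0, IntegerVector n_k0,
               double alpha, double eta, int sweeps, int burn_in, bool average) {
  IntegerVector z = clone(z0);
  IntegerMatrix n_dk = clone(n_dk0);
  IntegerMatrix n_kw = clone(n_kw0);
  IntegerVector n_k = clone(n_k0);
  const int K = n_k.size();
  const int V = n_kw.ncol();
  const int M = n_dk.nrow();
  const int T = z.size();
  std::vector<double> p(K);
  std::vector<int> Nd(M, 0);
  for (int t = 0; t < T; ++t) Nd[doc_of[t]]++;

  NumericMatrix phi_sum(K, V), theta_sum(M, K);
  int n_avg = 0;

  for (int s = 0; s < sweeps; ++s) {
    for (int t = 0; t < T; ++t) {
      const int d = doc_of[t], w = word_of[t], k = z[t];
      n_dk(d, k)--; n_kw(k, w)--; n_k[k]--;
      double tot = 0.0;
      for (int j = 0; j < K; ++j) {
        p[j] = (n_dk(d, j) + alpha) * (n_kw(j, w) + eta) / (n_k[j] + V * eta);
        tot += p[j];
      }
      const int knew = sample_categorical(p, tot);
      z[t] = knew;
      n_dk(d, knew)++; n_kw(knew, w)++; n_k[knew]++;
    }
    if (average && s >= burn_in) {
      for (int k = 0; k < K; ++k) {
        const double den = n_k[k] + V * eta;
        for (int w = 0; w < V; ++w) phi_sum(k, w) += (n_kw(k, w) + eta) / den;
      }
      for (int d = 0; d < M; ++d) {
        const double den = Nd[d] + K * alpha;
        for (int k = 0; k < K; ++k) theta_sum(d, k) += (n_dk(d, k) + alpha) / den;
      }
      n_avg++;
    }
    if (s % 16 == 0) Rcpp::checkUserInterrupt();
  }

  List out = List::create(_["z"] = z, _["n_dk"] = n_dk, _["n_kw"] = n_kw,
                          _["n_k"] = n_k, _["n_avg"] = n_avg);
  if (average && n_avg > 0) {
    for (int i = 0; i < K * V; ++i) phi_sum[i] /= n_avg;
    for (int i = 0; i < M * K; ++i) theta_sum[i] /= n_avg;
    out["phi_avg"] = phi_sum;
    out["theta_avg"] = theta_sum;
  }
  return out;
}

// Fold-in inference for one unseen document: topic-word distributions are
// held fixed at the trained phi (phi[k,w] equals the smoothed count ratio,
// so sampling proportional to (c_k + alpha) * phi[k,w] is the collapsed
// conditional with trained counts frozen). Returns the smoothed theta row.
// [[Rcpp::export]]
NumericVector cpp_fold_in(IntegerVector word_of, NumericMatrix phi,
                          double alpha, int iters) {
  const int K = phi.nrow();
  const int N = word_of.size();
  std::vector<int> c(K, 0), z(N);
  std::vector<double> p(K);
  for (int t = 0; t < N; ++t) {
    int k = (int)(unif_rand() * K);
    if (k >= K) k = K - 1;
    z[t] = k;
    c[k]++;
  }
  for (int s = 0; s < iters; ++s) {
    for (int t = 0; t < N; ++t) {
      const int w = word_of[t];
      c[z[t]]--;
      double tot = 0.0;
      for (int k = 0; k < K; ++k) {
        p[k] = (c[k] + alpha) * phi(k, w);
        tot += p[k];
      }
      const int knew = sample_categorical(p, tot);
      z[t] = knew;
      c[knew]++;
    }
  }
  NumericVector theta(K);
  const double den = N + K * alpha;
  for (int k = 0; k < K; ++k) theta[k] = (c[k] + alpha) / den;
  return theta;
}
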