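#include <Rcpp.h>
using namespace Rcpp;

// Draws from R's RNG stream so everything is reproducible from set.seed().
static inline int unif_int(int n) {
  int v = (int)std::floor(unif_rand() * n);
  return v >= n ? n - 1 : v;
}

static double sq_dist(const NumericMatrix &X, int i, const std::vector<double> &c) {
  double d = 0.0;
  for (int j = 0; j < X.ncol(); ++j) {
    double t = X(i, j) - c[j];
    d += t * t;
  }
  return d;
}

// Lloyd k-means on the rows of X listed in idx, with greatest-distance
// ("farthest point") seeding from a random first item. Returns labels
// (1..k) aligned with idx and the total within-cluster sum of squares.
static double kmeans_once(const NumericMatrix &X, const std::vector<int> &idx,
                          int k, int maxit, std::vector<int> &labels) {
  int n = (int)idx.size(), d = X.ncol();
  std::vector<std::vector<double>> centers(k, std::vector<double>(d));

  // farthest-point seeding; ties resolved to the lowest item index
  std::vector<double> mind(n, R_PosInf);
  int first = unif_int(n);
  for (int j = 0; j < d; ++j) centers[0][j] = X(idx[first], j);
  for (int i = 0; i < n; ++i) mind[i] = sq_dist(X, idx[i], centers[0]);
  for (int c = 1; c < k; ++c) {
    int far = 0;
    for (int i = 1; i < n; ++i) if (mind[i] > mind[far]) far = i;
    for (int j = 0; j < d; ++j) centers[c][j] = X(idx[far], j);
    for (int i = 0; i < n; ++i) {
      double dd = sq_dist(X, idx[i], centers[c]);
      if (dd < mind[i]) mind[i] = dd;
    }
  }

  labels.assign(n, 0);
  std::vector<int> sizes(k);
  for (int it = 0; it < maxit; ++it) {
    bool moved = false;
    for (int i = 0; i < n; ++i) {
      int best = 0;
      double bd = sq_dist(X, idx[i], centers[0]);
      for (int c = 1; c < k; ++c) {
        double dd = sq_dist(X, idx[i], centers[c]);
        if (dd < bd) { bd = dd; best = c; }
      }
      if (labels[i] != best) { labels[i] = best; moved = true; }
    }
    std::fill(sizes.begin(), sizes.end(), 0);
    for (int c = 0; c < k; ++c) std::fill(centers[c].begin(), centers[c].end(), 0.0);
    for (int i = 0; i < n; ++i) {
      sizes[labels[i]]++;
      for (int j = 0; j < d; ++j) centers[labels[i]][j] += X(idx[i], j);
    }
    for (int c = 0; c < k; ++c) {
      if (sizes[c] == 0) {
        // re-seed an emptied cluster at the point farthest from its center
        int far = 0; double bd = -1.0;
        for (int i = 0; i < n; ++i) {
          double dd = sq_dist(X, idx[i], centers[labels[i]]);
          if (dd > bd) { bd = dd; far = i; }
        }
        for (int j = 0; j < d; ++j) centers[c][j] = X(idx[far], j);
        moved = true;
      } else {
        for (int j = 0; j < d; ++j) centers[c][j] /= sizes[c];
      }
    }
    if (!moved && it > 0) break;
  }

  double wss = 0.0;
  for (int i = 0; i < n; ++i) wss += sq_dist(X, idx[i], centers[labels[i]]);
  return wss;
}

static void kmeans_restarts(const NumericMatrix &X, const std::vector<int> &idx,
                            int k, int nstart, int maxit, std::vector<int> &best_labels) {
  std::vector<int> labels;
  double best = R_PosInf;
  for (int s = 0; s < nstart; ++s) {
    double wss = kmeans_once(X, idx, k, maxit, labels);
    if (wss < best) { best = wss; best_labels = labels; }
  }
}

// [[Rcpp::export]]
IntegerVector kmeans_fp_cpp(NumericMatrix X, int k, int nstart, int maxit) {
  std::vector<int> idx(X.nrow());
  for (int i = 0; i < X.nrow(); ++i) idx[i] = i;
  std::vector<int> labels;
  kmeans_restarts(X, idx, k, nstart, maxit, labels);
  IntegerVector out(X.nrow());
  for (int i = 0; i < X.nrow(); ++i) out[i] = labels[i] + 1;
  return out;
}

// Resampled co-membership accumulation: for each k and each resample, draw
// m of n items without replacement (partial Fisher-Yates on R's RNG),
// cluster the subset, and count co-clustered / co-sampled pairs.
// [[Rcpp::export]]
List consensus_counts_cpp(NumericMatrix X, IntegerVector ks, int n_resamples,
                          int m, int nstart, int maxit) {
  int n = X.nrow();
  List out(ks.size());
  std::vector<int> pool(n), sub(m), labels;
  for (int ki = 0; ki < ks.size(); ++ki) {
    int k = ks[ki];
    IntegerMatrix I(n, n), S(n, n);
    for (int r = 0; r < n_resamples; ++r) {
      for (int i = 0; i < n; ++i) pool[i] = i;
      for (int i = 0; i < m; ++i) {
        int j = i + unif_int(n - i);
        std::swap(pool[i], pool[j]);
        sub[i] = pool[i];
      }
      kmeans_restarts(X, sub, k, nstart, maxit, labels);
      for (int a = 0; a < m; ++a) {
        for (int b = a; b < m; ++b) {
          int ia = sub[a], ib = sub[b];
          S(ia, ib)++; S(ib, ia) += (ia == ib) ? 0 : 1;
          if (labels[a] == labels[b]) { I(ia, ib)++; if (ia != ib) I(ib, ia)++; }
        }
      }
    }
    out[ki] = List::create(Named("co_cluster") = I, Named("co_sample") = S);
  }
  out.names() = as<CharacterVector>(wrap(ks));
  return out;
}
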