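#include <Rcpp.h>
#include <queue>
using namespace Rcpp;

// Breadth-first all-pairs shortest path lengths on a binary undirected graph.
// Unreachable pairs are coded -1 (converted to Inf on the R side).
// [[Rcpp::export]]
IntegerMatrix bfs_distances_cpp(const IntegerMatrix& adj) {
  const int n = adj.nrow();
  IntegerMatrix dist(n, n);
  std::fill(dist.begin(), dist.end(), -1);
  // adjacency lists once, BFS from every source
  std::vector< std::vector<int> > nbr(n);
  for (int i = 0; i < n; ++i)
    for (int j = 0; j < n; ++j)
      if (i != j && adj(i, j) != 0) nbr[i].push_back(j);
  std::vector<int> q(n);
  for (int s = 0; s < n; ++s) {
    dist(s, s) = 0;
    int head = 0, tail = 0;
    q[tail++] = s;
    while (head < tail) {
      int u = q[head++];
      int du = dist(s, u);
      for (size_t k = 0; k < nbr[u].size(); ++k) {
        int v = nbr[u][k];
        if (dist(s, v) < 0) {
          dist(s, v) = du + 1;
          q[tail++] = v;
        }
      }
    }
  }
  return dist;
}

// Sample-entropy template-pair counts (Richman & Moorman convention):
// both template lengths use the same N - m start points, Chebyshev distance,
// self-matches excluded. Returns c(A, B) with A = (m+1)-matches, B = m-matches.
// [[Rcpp::export]]
NumericVector sampen_counts_cpp(const NumericVector& x, const int m,
                                const double r) {
  const int n = x.size();
  const int np = n - m;  // number of templates
  double A = 0.0, B = 0.0;
  for (int i = 0; i < np - 1; ++i) {
    for (int j = i + 1; j < np; ++j) {
      bool match = true;
      for (int k = 0; k < m; ++k) {
        if (std::abs(x[i + k] - x[j + k]) > r) { match = false; break; }
      }
      if (!match) continue;
      B += 1.0;
      if (std::abs(x[i + m] - x[j + m]) <= r) A += 1.0;
    }
  }
  return NumericVector::create(A, B);
}

// Periodic db2 DWT -> per-level quartile-fence thresholding of detail
// coefficients -> inverse transform, per row. N must be divisible by
// 2^levels. Levels with fewer than min_coeffs coefficients are left
// untouched. Mirrors the reference R implementation (dwt_periodic /
// idwt_periodic), which the test suite uses as its oracle.
// [[Rcpp::export]]
NumericMatrix wavelet_correct_cpp(const NumericMatrix& x, const int levels,
                                  const double iqr_factor,
                                  const int min_coeffs) {
  const int nr = x.nrow(), n0 = x.ncol();
  const double s3 = std::sqrt(3.0), s2 = std::sqrt(2.0);
  const double h[4] = {(1 + s3) / (4 * s2), (3 + s3) / (4 * s2),
                       (3 - s3) / (4 * s2), (1 - s3) / (4 * s2)};
  const double g[4] = {h[3], -h[2], h[1], -h[0]};
  NumericMatrix out(nr, n0);
  std::vector<double> a(n0), a2(n0), buf(n0);
  std::vector< std::vector<double> > dets(levels);
  for (int r = 0; r < nr; ++r) {
    int n = n0;
    for (int i = 0; i < n0; ++i) a[i] = x(r, i);
    for (int j = 0; j < levels; ++j) {
      const int half = n / 2;
      dets[j].assign(half, 0.0);
      for (int k = 0; k + 1 < half; ++k) {   // wrap-free main loop
        const double v0 = a[2 * k], v1 = a[2 * k + 1],
                     v2 = a[2 * k + 2], v3 = a[2 * k + 3];
        a2[k] = h[0] * v0 + h[1] * v1 + h[2] * v2 + h[3] * v3;
        dets[j][k] = g[0] * v0 + g[1] * v1 + g[2] * v2 + g[3] * v3;
      }
      if (half > 0) {                         // last position wraps
        const int k = half - 1;
        const double v0 = a[2 * k], v1 = a[(2 * k + 1) % n],
                     v2 = a[(2 * k + 2) % n], v3 = a[(2 * k + 3) % n];
        a2[k] = h[0] * v0 + h[1] * v1 + h[2] * v2 + h[3] * v3;
        dets[j][k] = g[0] * v0 + g[1] * v1 + g[2] * v2 + g[3] * v3;
      }
      // quartile fences (type-7 quantiles), skip short levels
      if (half >= min_coeffs) {
        buf.assign(dets[j].begin(), dets[j].end());
        std::sort(buf.begin(), buf.begin() + half);
        const double h1 = 0.25 * (half - 1), h3 = 0.75 * (half - 1);
        const int l1 = (int)h1, l3 = (int)h3;
        const double q1 = buf[l1] + (h1 - l1) * (buf[l1 + 1] - buf[l1]);
        const double q3 = buf[l3] + (h3 - l3) * (buf[l3 + 1] - buf[l3]);
        const double fence = iqr_factor * (q3 - q1);
        for (int k = 0; k < half; ++k)
          if (dets[j][k] < q1 - fence || dets[j][k] > q3 + fence)
            dets[j][k] = 0.0;
      }
      std::copy(a2.begin(), a2.begin() + half, a.begin());
      n = half;
    }
    // reconstruct
    for (int j = levels - 1; j >= 0; --j) {
      const int half = n, nn = 2 * n;
      std::fill(a2.begin(), a2.begin() + nn, 0.0);
      for (int k = 0; k + 1 < half; ++k) {   // wrap-free main loop
        const double av = a[k], dv = dets[j][k];
        a2[2 * k]     += h[0] * av + g[0] * dv;
        a2[2 * k + 1] += h[1] * av + g[1] * dv;
        a2[2 * k + 2] += h[2] * av + g[2] * dv;
        a2[2 * k + 3] += h[3] * av + g[3] * dv;
      }
      if (half > 0) {
        const int k = half - 1;
        const double av = a[k], dv = dets[j][k];
        for (int m = 0; m < 4; ++m)
          a2[(2 * k + m) % nn] += h[m] * av + g[m] * dv;
      }
      std::copy(a2.begin(), a2.begin() + nn, a.begin());
      n = nn;
    }
    for (int i = 0; i < n0; ++i) out(r, i) = a[i];
  }
  return out;
}

// All global metrics + nodal efficiency in one pass over a binary adjacency
// matrix: mean clustering coefficient (degree<2 nodes contribute 0),
// characteristic path length over connected pairs, global efficiency
// (1/Inf = 0), local efficiency (efficiency of each neighbor-induced
// subgraph), nodal efficiency. Definitions match the individual R functions,
// which are oracle-tested against brute-force enumeration.
// [[Rcpp::export]]
List graph_metrics_cpp(const IntegerMatrix& adj) {
  const int n = adj.nrow();
  std::vector< std::vector<int> > nbr(n);
  for (int i = 0; i < n; ++i)
    for (int j = 0; j < n; ++j)
      if (i != j && adj(i, j) != 0) nbr[i].push_back(j);
  // clustering
  double cp = 0.0;
  for (int i = 0; i < n; ++i) {
    const int k = nbr[i].size();
    if (k < 2) continue;
    int tri = 0;
    for (int a = 0; a < k; ++a)
      for (int b = a + 1; b < k; ++b)
        if (adj(nbr[i][a], nbr[i][b]) != 0) ++tri;
    cp += 2.0 * tri / (double)(k * (k - 1));
  }
  cp /= n;
  // BFS distances from every node
  std::vector<int> dist(n), q(n);
  double lp_sum = 0.0; long lp_cnt = 0; double eff_sum = 0.0;
  NumericVector enod(n);
  for (int s = 0; s < n; ++s) {
    std::fill(dist.begin(), dist.end(), -1);
    dist[s] = 0;
    int head = 0, tail = 0;
    q[tail++] = s;
    while (head < tail) {
      const int u = q[head++];
      for (size_t m = 0; m < nbr[u].size(); ++m) {
        const int v = nbr[u][m];
        if (dist[v] < 0) { dist[v] = dist[u] + 1; q[tail++] = v; }
      }
    }
    double einv = 0.0;
    for (int j = 0; j < n; ++j) {
      if (j == s || dist[j] < 0) continue;
      lp_sum += dist[j]; ++lp_cnt;
      einv += 1.0 / dist[j];
    }
    enod[s] = (n > 1) ? einv / (n - 1) : 0.0;
    eff_sum += einv;
  }
  const double lp = lp_cnt > 0 ? lp_sum / lp_cnt : R_PosInf;
  const double eglob = (n > 1) ? eff_sum / ((double)n * (n - 1)) : 0.0;
  // local efficiency: BFS inside each neighbor-induced subgraph
  double eloc = 0.0;
  std::vector<int> sub, pos(n, -1);
  for (int i = 0; i < n; ++i) {
    const int k = nbr[i].size();
    if (k < 2) continue;
    sub = nbr[i];
    for (int a = 0; a < k; ++a) pos[sub[a]] = a;
    double esub = 0.0;
    std::vector<int> sd(k), sq(k);
    for (int a = 0; a < k; ++a) {
      std::fill(sd.begin(), sd.end(), -1);
      sd[a] = 0;
      int h2 = 0, t2 = 0; sq[t2++] = a;
      while (h2 < t2) {
        const int u = sq[h2++];
        for (int b = 0; b < k; ++b)
          if (sd[b] < 0 && adj(sub[u], sub[b]) != 0) {
            sd[b] = sd[u] + 1; sq[t2++] = b;
          }
      }
      for (int b = 0; b < k; ++b)
        if (b != a && sd[b] > 0) esub += 1.0 / sd[b];
    }
    eloc += esub / ((double)k * (k - 1));
    for (int a = 0; a < k; ++a) pos[sub[a]] = -1;
  }
  eloc /= n;
  return List::create(_["cp"] = cp, _["lp"] = lp, _["eglob"] = eglob,
                      _["eloc"] = eloc, _["enod"] = enod);
}
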