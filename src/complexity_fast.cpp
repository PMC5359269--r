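// Hot loops of the complexity indices: bond-order-weighted all-pairs
// distances, topological symmetry classes, iterative neighborhood
// refinement ranks and the Bertz connection census. Molecules are small
// (tens of atoms), so simple dense algorithms are the right tool.

#include <Rcpp.h>
#include <algorithm>
#include <map>
#include <vector>
#include <cmath>

using namespace Rcpp;

// Floyd-Warshall with edge weight 1/order (1-based bond endpoints).
// [[Rcpp::export]]
NumericMatrix cpp_bo_dist(int n, IntegerVector bi, IntegerVector bj,
                          IntegerVector border) {
  NumericMatrix D(n, n);
  const double inf = R_PosInf;
  for (int i = 0; i < n; ++i)
    for (int j = 0; j < n; ++j) D(i, j) = (i == j) ? 0.0 : inf;
  for (int e = 0; e < bi.size(); ++e) {
    int a = bi[e] - 1, b = bj[e] - 1;
    double w = 1.0 / border[e];
    if (w < D(a, b)) { D(a, b) = w; D(b, a) = w; }
  }
  for (int k = 0; k < n; ++k)
    for (int i = 0; i < n; ++i) {
      double dik = D(i, k);
      if (dik == inf) continue;
      for (int j = 0; j < n; ++j) {
        double v = dik + D(k, j);
        if (v < D(i, j)) D(i, j) = v;
      }
    }
  return D;
}

// Atoms sharing an identical sorted distance profile (rounded to 4
// decimals, first `cutoff` entries) form one symmetry class.
// [[Rcpp::export]]
IntegerVector cpp_symmetry_classes(NumericMatrix D, int cutoff) {
  int n = D.nrow();
  int keep = std::min(cutoff, n);
  std::map<std::vector<long long>, int> seen;
  IntegerVector cls(n);
  for (int i = 0; i < n; ++i) {
    std::vector<long long> row(n);
    for (int j = 0; j < n; ++j)
      row[j] = (long long) std::llround(D(i, j) * 10000.0);
    std::sort(row.begin(), row.end());
    row.resize(keep);
    auto it = seen.find(row);
    if (it == seen.end()) {
      int id = (int) seen.size() + 1;
      seen[row] = id;
      cls[i] = id;
    } else cls[i] = it->second;
  }
  return cls;
}

// Morgan-style iterative refinement: classes only split, so iterate until
// the class count stops growing. init holds initial invariant classes.
// [[Rcpp::export]]
IntegerVector cpp_refine_ranks(IntegerVector init, IntegerVector bi,
                               IntegerVector bj, IntegerVector border) {
  int n = init.size();
  std::vector<std::vector<std::pair<int, int> > > nbr(n);
  for (int e = 0; e < bi.size(); ++e) {
    int a = bi[e] - 1, b = bj[e] - 1, o = border[e];
    nbr[a].push_back(std::make_pair(b, o));
    nbr[b].push_back(std::make_pair(a, o));
  }
  std::vector<int> rank(init.begin(), init.end());
  int nclass = 0;
  for (int v : rank) nclass = std::max(nclass, v);
  for (int sweep = 0; sweep < n + 1; ++sweep) {
    std::map<std::vector<int>, int> seen;
    std::vector<int> newrank(n);
    for (int i = 0; i < n; ++i) {
      std::vector<int> key;
      key.push_back(rank[i]);
      std::vector<int> codes;
      for (size_t k = 0; k < nbr[i].size(); ++k)
        codes.push_back(rank[nbr[i][k].first] * 4 + nbr[i][k].second);
      std::sort(codes.begin(), codes.end());
      key.insert(key.end(), codes.begin(), codes.end());
      auto it = seen.find(key);
      if (it == seen.end()) {
        int id = (int) seen.size() + 1;
        seen[key] = id;
        newrank[i] = id;
      } else newrank[i] = it->second;
    }
    int nc = (int) seen.size();
    rank = newrank;
    if (nc == nclass) break;
    nclass = nc;
  }
  return IntegerVector(rank.begin(), rank.end());
}

// Bertz connection census over symmetry classes: for every atom, count
// neighbor-pair connections (order_i * order_j) keyed by the class triple,
// and multiple-bond self connections order*(order-1)/2 keyed by the class
// pair. Returns the count multiset.
// [[Rcpp::export]]
NumericVector cpp_bertz_connections(int n, IntegerVector bi, IntegerVector bj,
                                    IntegerVector border, IntegerVector cls) {
  std::vector<std::vector<std::pair<int, int> > > nbr(n);
  for (int e = 0; e < bi.size(); ++e) {
    int a = bi[e] - 1, b = bj[e] - 1, o = border[e];
    nbr[a].push_back(std::make_pair(b, o));
    nbr[b].push_back(std::make_pair(a, o));
  }
  std::map<std::vector<int>, double> conn;
  for (int a = 0; a < n; ++a) {
    int ca = cls[a];
    for (size_t ii = 0; ii < nbr[a].size(); ++ii) {
      int ni = nbr[a][ii].first, oi = nbr[a][ii].second;
      if (oi > 1 && ni > a) {
        std::vector<int> key(2);
        key[0] = std::min(ca, cls[ni]);
        key[1] = std::max(ca, cls[ni]);
        conn[key] += oi * (oi - 1) / 2.0;
      }
      for (size_t jj = ii + 1; jj < nbr[a].size(); ++jj) {
        int nj = nbr[a][jj].first, oj = nbr[a][jj].second;
        std::vector<int> key(3);
        key[0] = std::min(cls[ni], cls[nj]);
        key[1] = ca;
        key[2] = std::max(cls[ni], cls[nj]);
        conn[key] += (double) oi * oj;
      }
    }
  }
  NumericVector out(conn.size());
  int k = 0;
  for (auto it = conn.begin(); it != conn.end(); ++it) out[k++] = it->second;
  return out;
}
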