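#include <Rcpp.h>
#include <vector>
#include <algorithm>
using namespace Rcpp;

// CART regression tree grown greedily on variance impurity, where the node
// impurity is the total sum of squared deviations from the node mean (a sum,
// not a mean, so child impurities add up against the parent's and every
// split's impurity decrease is directly the mean-decrease-Gini contribution).

struct TreeBuf {
  std::vector<int> var, left, right, n;
  std::vector<double> thr, imp, pred, dec;
  int add_node() {
    var.push_back(-1); left.push_back(-1); right.push_back(-1); n.push_back(0);
    thr.push_back(NA_REAL); imp.push_back(0.0); pred.push_back(0.0);
    dec.push_back(0.0);
    return (int)var.size() - 1;
  }
};

static double node_ss(double sum, double sum2, int n) {
  double ss = sum2 - sum * sum / n;
  return ss > 0 ? ss : 0.0; // clamp numerical negatives
}

// partial Fisher-Yates draw of m values from 0..p-1 using R's RNG stream
static std::vector<int> sample_features(int p, int m) {
  std::vector<int> idx(p);
  for (int i = 0; i < p; ++i) idx[i] = i;
  for (int i = 0; i < m; ++i) {
    int j = i + (int)(unif_rand() * (p - i));
    if (j >= p) j = p - 1;
    std::swap(idx[i], idx[j]);
  }
  idx.resize(m);
  std::sort(idx.begin(), idx.end()); // keeps the var-index tie-break stable
  return idx;
}

static void grow(const NumericMatrix& X, const NumericVector& y,
                 std::vector<int>& samples, int node, TreeBuf& buf,
                 int depth, int max_depth, int min_leaf, int mtry) {
  const int n = (int)samples.size();
  double sum = 0.0, sum2 = 0.0;
  for (int i = 0; i < n; ++i) {
    double v = y[samples[i]];
    sum += v; sum2 += v * v;
  }
  buf.n[node] = n;
  buf.pred[node] = sum / n;
  buf.imp[node] = node_ss(sum, sum2, n);

  if (n < 2 * min_leaf || buf.imp[node] <= 1e-12 ||
      (max_depth >= 0 && depth >= max_depth))
    return;

  const int p = X.ncol();
  std::vector<int> feats;
  if (mtry >= p) {
    feats.resize(p);
    for (int j = 0; j < p; ++j) feats[j] = j;
  } else {
    feats = sample_features(p, mtry);
  }

  double best_dec = 0.0, best_thr = NA_REAL;
  int best_var = -1;
  std::vector<std::pair<double, double> > xv(n); // (x, y) for sorting

  for (size_t f = 0; f < feats.size(); ++f) {
    int j = feats[f];
    for (int i = 0; i < n; ++i)
      xv[i] = std::make_pair(X(samples[i], j), y[samples[i]]);
    std::sort(xv.begin(), xv.end());
    if (xv[0].first == xv[n - 1].first) continue; // constant feature
    double lsum = 0.0, lsum2 = 0.0;
    for (int i = 0; i < n - 1; ++i) {
      double v = xv[i].second;
      lsum += v; lsum2 += v * v;
      if (xv[i].first == xv[i + 1].first) continue; // not a boundary
      int nl = i + 1, nr = n - nl;
      if (nl < min_leaf || nr < min_leaf) continue;
      double thr = xv[i].first + (xv[i + 1].first - xv[i].first) / 2.0;
      if (!(thr > xv[i].first)) continue; // midpoint underflow: unusable split
      double rsum = sum - lsum, rsum2 = sum2 - lsum2;
      double dec = buf.imp[node] - node_ss(lsum, lsum2, nl)
                                 - node_ss(rsum, rsum2, nr);
      // strict > keeps the first (lowest var index, lowest threshold) on ties
      if (dec > best_dec) {
        best_dec = dec; best_var = j; best_thr = thr;
      }
    }
  }

  if (best_var < 0 || best_dec <= 0.0) return; // no admissible strict decrease

  std::vector<int> left_s, right_s;
  left_s.reserve(n); right_s.reserve(n);
  for (int i = 0; i < n; ++i) {
    if (X(samples[i], best_var) <= best_thr) left_s.push_back(samples[i]);
    else right_s.push_back(samples[i]);
  }
  buf.var[node] = best_var;
  buf.thr[node] = best_thr;
  buf.dec[node] = best_dec;
  int li = buf.add_node(), ri = buf.add_node();
  buf.left[node] = li; buf.right[node] = ri;
  std::vector<int>().swap(samples); // free before recursing
  grow(X, y, left_s, li, buf, depth + 1, max_depth, min_leaf, mtry);
  grow(X, y, right_s, ri, buf, depth + 1, max_depth, min_leaf, mtry);
}

// [[Rcpp::export(name = ".cart_grow")]]
List cart_grow(NumericMatrix X, NumericVector y, IntegerVector sample_idx,
               int mtry, int min_leaf, int max_depth) {
  TreeBuf buf;
  std::vector<int> samples(sample_idx.size());
  for (int i = 0; i < sample_idx.size(); ++i) samples[i] = sample_idx[i] - 1;
  int root = buf.add_node();
  grow(X, y, samples, root, buf, 0, max_depth, min_leaf, mtry);
  return List::create(
    _["var"] = IntegerVector(buf.var.begin(), buf.var.end()),
    _["threshold"] = NumericVector(buf.thr.begin(), buf.thr.end()),
    _["left"] = IntegerVector(buf.left.begin(), buf.left.end()),
    _["right"] = IntegerVector(buf.right.begin(), buf.right.end()),
    _["n"] = IntegerVector(buf.n.begin(), buf.n.end()),
    _["impurity"] = NumericVector(buf.imp.begin(), buf.imp.end()),
    _["prediction"] = NumericVector(buf.pred.begin(), buf.pred.end()),
    _["decrease"] = NumericVector(buf.dec.begin(), buf.dec.end()));
}

// [[Rcpp::export(name = ".cart_predict")]]
NumericVector cart_predict(List tree, NumericMatrix X) {
  IntegerVector var = tree["var"], left = tree["left"], right = tree["right"];
  NumericVector thr = tree["threshold"], pred = tree["prediction"];
  int n = X.nrow();
  NumericVector out(n);
  for (int i = 0; i < n; ++i) {
    int node = 0;
    while (var[node] >= 0)
      node = (X(i, var[node]) <= thr[node]) ? left[node] : right[node];
    out[i] = pred[node];
  }
  return out;
}
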