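#include <Rcpp.h>
#include <algorithm>
#include <vector>
using namespace Rcpp;

// Classification random forest: CART trees grown to purity on bootstrap
// samples, Gini split criterion, mtry candidate features per node, majority
// vote with deterministic (lowest class index) tie-breaking. Uses R's RNG so
// set.seed() gives bit-identical forests.

namespace {

inline int runif_int(int n) {
  int k = static_cast<int>(unif_rand() * n);
  return k >= n ? n - 1 : k;
}

struct TreeArrays {
  std::vector<int> feature;  // split feature, -1 for leaf
  std::vector<double> thr;   // split threshold (go left if x <= thr)
  std::vector<int> left;
  std::vector<int> right;
  std::vector<int> pred;     // leaf class (majority, lowest index on ties)
};

int majority_class(const std::vector<int> &counts) {
  int best = 0;
  for (size_t k = 1; k < counts.size(); ++k)
    if (counts[k] > counts[best]) best = static_cast<int>(k);
  return best;
}

struct Builder {
  const NumericMatrix &X;
  const IntegerVector &y;
  int n_classes, mtry, p;
  TreeArrays &t;
  std::vector<int> feat_perm;
  // scratch for split search
  std::vector<std::pair<double, int> > vals;

  Builder(const NumericMatrix &X_, const IntegerVector &y_, int n_classes_,
          int mtry_, TreeArrays &t_)
      : X(X_), y(y_), n_classes(n_classes_), mtry(mtry_), p(X_.ncol()), t(t_) {
    feat_perm.resize(p);
    for (int j = 0; j < p; ++j) feat_perm[j] = j;
  }

  int new_node() {
    t.feature.push_back(-1);
    t.thr.push_back(0.0);
    t.left.push_back(-1);
    t.right.push_back(-1);
    t.pred.push_back(0);
    return static_cast<int>(t.feature.size()) - 1;
  }

  // idx: in-bag row indices at this node (with bootstrap repetitions)
  int build(std::vector<int> &idx) {
    int node = new_node();
    std::vector<int> counts(n_classes, 0);
    for (size_t i = 0; i < idx.size(); ++i) counts[y[idx[i]]]++;
    int maj = majority_class(counts);
    int n_here = static_cast<int>(idx.size());
    bool pure = counts[maj] == n_here;
    if (pure || n_here < 2) {
      t.pred[node] = maj;
      return node;
    }

    // sample mtry candidate features without replacement
    for (int j = 0; j < mtry; ++j) {
      int k = j + runif_int(p - j);
      std::swap(feat_perm[j], feat_perm[k]);
    }

    int best_f = -1;
    double best_thr = 0.0, best_score = -1.0;
    std::vector<int> lc(n_classes), rc(n_classes);
    for (int j = 0; j < mtry; ++j) {
      int f = feat_perm[j];
      vals.clear();
      for (size_t i = 0; i < idx.size(); ++i)
        vals.push_back(std::make_pair(X(idx[i], f), y[idx[i]]));
      std::sort(vals.begin(), vals.end());
      if (vals.front().first == vals.back().first) continue;  // constant
      std::fill(lc.begin(), lc.end(), 0);
      rc = counts;
      double sl = 0.0;  // sum of squared class counts, left
      double sr = 0.0;
      for (int k = 0; k < n_classes; ++k) sr += (double)rc[k] * rc[k];
      int nl = 0, nr = n_here;
      for (size_t i = 0; i + 1 < vals.size(); ++i) {
        int cls = vals[i].second;
        sl += 2.0 * lc[cls] + 1.0;
        sr -= 2.0 * rc[cls] - 1.0;
        lc[cls]++; rc[cls]--; nl++; nr--;
        if (vals[i].first == vals[i + 1].first) continue;
        double score = sl / nl + sr / nr;
        if (score > best_score) {
          best_score = score;
          best_f = f;
          best_thr = 0.5 * (vals[i].first + vals[i + 1].first);
        }
      }
    }

    if (best_f < 0) {  // all candidate features constant in this node
      t.pred[node] = maj;
      return node;
    }

    std::vector<int> lidx, ridx;
    for (size_t i = 0; i < idx.size(); ++i) {
      if (X(idx[i], best_f) <= best_thr) lidx.push_back(idx[i]);
      else ridx.push_back(idx[i]);
    }
    if (lidx.empty() || ridx.empty()) {  // numeric edge case
      t.pred[node] = maj;
      return node;
    }
    idx.clear(); idx.shrink_to_fit();
    t.feature[node] = best_f;
    t.thr[node] = best_thr;
    t.left[node] = build(lidx);
    t.right[node] = build(ridx);
    return node;
  }
};

int predict_row(const TreeArrays &t, int root, const NumericMatrix &X, int i) {
  int node = root;
  while (t.feature[node] >= 0)
    node = (X(i, t.feature[node]) <= t.thr[node]) ? t.left[node] : t.right[node];
  return t.pred[node];
}

}  // namespace

// [[Rcpp::export(name = ".rf_train_cpp")]]
List rf_train_cpp(NumericMatrix X, IntegerVector y, int n_classes, int n_trees,
                  int mtry, bool importance) {
  const int n = X.nrow(), p = X.ncol();
  TreeArrays t;
  std::vector<int> roots(n_trees);
  IntegerMatrix oob_votes(n, n_classes);
  NumericVector imp(p);
  std::vector<double> imp_sum(p, 0.0);
  std::vector<int> inbag(n);
  std::vector<int> oob;
  std::vector<double> xperm;
  int trees_with_oob = 0;

  for (int b = 0; b < n_trees; ++b) {
    std::fill(inbag.begin(), inbag.end(), 0);
    std::vector<int> idx(n);
    for (int i = 0; i < n; ++i) {
      int k = runif_int(n);
      idx[i] = k;
      inbag[k]++;
    }
    Builder builder(X, y, n_classes, mtry, t);
    roots[b] = builder.build(idx);

    oob.clear();
    for (int i = 0; i < n; ++i)
      if (inbag[i] == 0) oob.push_back(i);
    if (oob.empty()) continue;
    trees_with_oob++;

    int correct = 0;
    for (size_t i = 0; i < oob.size(); ++i) {
      int pr = predict_row(t, roots[b], X, oob[i]);
      oob_votes(oob[i], pr)++;
      if (pr == y[oob[i]]) correct++;
    }

    if (importance) {
      const int m = static_cast<int>(oob.size());
      xperm.resize(m);
      std::vector<int> perm(m);
      for (int f = 0; f < p; ++f) {
        for (int i = 0; i < m; ++i) perm[i] = i;
        for (int i = m - 1; i > 0; --i) std::swap(perm[i], perm[runif_int(i + 1)]);
        for (int i = 0; i < m; ++i) xperm[i] = X(oob[perm[i]], f);
        int correct_perm = 0;
        for (int i = 0; i < m; ++i) {
          int row = oob[i];
          // walk tree substituting permuted value for feature f
          int node = roots[b];
          while (t.feature[node] >= 0) {
            double v = (t.feature[node] == f) ? xperm[i] : X(row, t.feature[node]);
            node = (v <= t.thr[node]) ? t.left[node] : t.right[node];
          }
          if (t.pred[node] == y[row]) correct_perm++;
        }
        imp_sum[f] += static_cast<double>(correct - correct_perm) / m;
      }
    }
  }

  if (importance && trees_with_oob > 0)
    for (int f = 0; f < p; ++f) imp[f] = imp_sum[f] / trees_with_oob;

  return List::create(
      Named("feature") = wrap(t.feature), Named("thr") = wrap(t.thr),
      Named("left") = wrap(t.left), Named("right") = wrap(t.right),
      Named("pred") = wrap(t.pred), Named("roots") = wrap(roots),
      Named("oob_votes") = oob_votes, Named("importance") = imp,
      Named("n_classes") = n_classes);
}

// [[Rcpp::export(name = ".rf_predict_cpp")]]
IntegerVector rf_predict_cpp(List forest, NumericMatrix X) {
  TreeArrays t;
  t.feature = as<std::vector<int> >(forest["feature"]);
  t.thr = as<std::vector<double> >(forest["thr"]);
  t.left = as<std::vector<int> >(forest["left"]);
  t.right = as<std::vector<int> >(forest["right"]);
  t.pred = as<std::vector<int> >(forest["pred"]);
  std::vector<int> roots = as<std::vector<int> >(forest["roots"]);
  int n_classes = as<int>(forest["n_classes"]);
  const int n = X.nrow();
  IntegerVector out(n);
  std::vector<int> votes(n_classes);
  for (int i = 0; i < n; ++i) {
    std::fill(votes.begin(), votes.end(), 0);
    for (size_t b = 0; b < roots.size(); ++b)
      votes[predict_row(t, roots[b], X, i)]++;
    out[i] = majority_class(votes);
  }
  return out;
}

// Train on (Xtr, ytr) and predict Xte without materialising the forest in R;
// used per cross-validation split where only test predictions are needed.
// [[Rcpp::export(name = ".rf_train_predict_cpp")]]
IntegerVector rf_train_predict_cpp(NumericMatrix Xtr, IntegerVector ytr,
                                   int n_classes, NumericMatrix Xte,
                                   int n_trees, int mtry) {
  const int n = Xtr.nrow(), m = Xte.nrow();
  IntegerMatrix votes(m, n_classes);
  for (int b = 0; b < n_trees; ++b) {
    TreeArrays t;
    std::vector<int> idx(n);
    for (int i = 0; i < n; ++i) idx[i] = runif_int(n);
    Builder builder(Xtr, ytr, n_classes, mtry, t);
    int root = builder.build(idx);
    for (int i = 0; i < m; ++i) votes(i, predict_row(t, root, Xte, i))++;
  }
  IntegerVector out(m);
  for (int i = 0; i < m; ++i) {
    int best = 0;
    for (int k = 1; k < n_classes; ++k)
      if (votes(i, k) > votes(i, best)) best = k;
    out[i] = best;
  }
  return out;
}
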