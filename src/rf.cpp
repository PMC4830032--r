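// Random forest for binary classification: CART trees on bootstrap samples,
// Gini splits over mtry randomly drawn features, grown without pruning.
// Provides out-of-bag (OOB) error, OOB permutation importance (mean decrease
// in accuracy, MDA) and accumulated impurity decrease (mean decrease in
// Gini, MDG). All randomness flows through R's RNG so results are
// reproducible with set.seed().
#include <Rcpp.h>
#include <vector>
#include <algorithm>
using namespace Rcpp;

namespace {

struct Tree {
  std::vector<int> feature;      // split feature (0-based), -1 for leaf
  std::vector<double> threshold; // x <= threshold goes left
  std::vector<int> left, right;  // child node indices, -1 for leaf
  std::vector<double> pos_frac;  // training positive fraction in node
};

inline int rand_int(int n) {
  int k = (int)(unif_rand() * n);
  return k >= n ? n - 1 : k;
}

inline double gini(int n_pos, int n) {
  if (n == 0) return 0.0;
  double p = (double)n_pos / n;
  return 2.0 * p * (1.0 - p);
}

struct Builder {
  const NumericMatrix& X;
  const IntegerVector& y;  // 0/1
  int mtry, min_node, n_total, p;
  Tree tree;
  std::vector<double>& gini_dec;       // per-feature accumulated decrease
  std::vector<int> feat_pool;

  Builder(const NumericMatrix& X_, const IntegerVector& y_, int mtry_,
          int min_node_, std::vector<double>& gd)
    : X(X_), y(y_), mtry(mtry_), min_node(min_node_),
      n_total(X_.nrow()), p(X_.ncol()), gini_dec(gd), feat_pool(p) {
    for (int j = 0; j < p; ++j) feat_pool[j] = j;
  }

  int make_leaf(int n_pos, int n) {
    tree.feature.push_back(-1);
    tree.threshold.push_back(0.0);
    tree.left.push_back(-1);
    tree.right.push_back(-1);
    tree.pos_frac.push_back(n ? (double)n_pos / n : 0.0);
    return (int)tree.feature.size() - 1;
  }

  // samples: in-bag row indices reaching this node (may repeat)
  int grow(std::vector<int>& samples) {
    int n = (int)samples.size();
    int n_pos = 0;
    for (int i : samples) n_pos += y[i];
    if (n_pos == 0 || n_pos == n || n < 2 * min_node)
      return make_leaf(n_pos, n);

    double g_parent = gini(n_pos, n);
    double best_dec = 0.0, best_thr = 0.0;
    int best_f = -1;

    // sample mtry features without replacement (partial Fisher-Yates)
    for (int k = 0; k < mtry && k < p; ++k) {
      int r = k + rand_int(p - k);
      std::swap(feat_pool[k], feat_pool[r]);
      int f = feat_pool[k];

      static thread_local std::vector<std::pair<double, int>> vals;
      vals.clear();
      vals.reserve(n);
      for (int i : samples) vals.emplace_back(X(i, f), y[i]);
      std::sort(vals.begin(), vals.end());
      if (vals.front().first == vals.back().first) continue;

      int lp = 0;
      for (int i = 0; i < n - 1; ++i) {
        lp += vals[i].second;
        if (vals[i].first == vals[i + 1].first) continue;
        int nl = i + 1, nr = n - nl;
        double dec = g_parent -
          ((double)nl * gini(lp, nl) + (double)nr * gini(n_pos - lp, nr)) / n;
        if (dec > best_dec + 1e-12) {
          best_dec = dec;
          best_f = f;
          best_thr = 0.5 * (vals[i].first + vals[i + 1].first);
        }
      }
    }
    if (best_f < 0) return make_leaf(n_pos, n);

    gini_dec[best_f] += best_dec * n / n_total;

    std::vector<int> ls, rs;
    ls.reserve(n);
    rs.reserve(n);
    for (int i : samples) {
      if (X(i, best_f) <= best_thr) ls.push_back(i);
      else rs.push_back(i);
    }
    int node = make_leaf(n_pos, n);  // placeholder, converted to split node
    tree.feature[node] = best_f;
    tree.threshold[node] = best_thr;
    { std::vector<int>().swap(samples); }  // free before recursing
    int l = grow(ls), r = grow(rs);
    tree.left[node] = l;
    tree.right[node] = r;
    return node;
  }
};

inline double predict_row(const Tree& t, const NumericMatrix& X, int i,
                          int perm_feature = -1, int perm_row = -1) {
  int node = 0;
  while (t.feature[node] >= 0) {
    int f = t.feature[node];
    double v = (f == perm_feature) ? X(perm_row, f) : X(i, f);
    node = (v <= t.threshold[node]) ? t.left[node] : t.right[node];
  }
  return t.pos_frac[node];
}

List tree_to_list(const Tree& t) {
  return List::create(_["feature"] = wrap(t.feature),
                      _["threshold"] = wrap(t.threshold),
                      _["left"] = wrap(t.left),
                      _["right"] = wrap(t.right),
                      _["pos_frac"] = wrap(t.pos_frac));
}

Tree tree_from_list(const List& l) {
  Tree t;
  t.feature = as<std::vector<int>>(l["feature"]);
  t.threshold = as<std::vector<double>>(l["threshold"]);
  t.left = as<std::vector<int>>(l["left"]);
  t.right = as<std::vector<int>>(l["right"]);
  t.pos_frac = as<std::vector<double>>(l["pos_frac"]);
  return t;
}

}  // namespace

// [[Rcpp::export(rng = true)]]
List rf_train_cpp(NumericMatrix X, IntegerVector y, int ntree, int mtry,
                  int min_node, bool importance) {
  int n = X.nrow(), p = X.ncol();
  if (y.size() != n) stop("labels do not align with feature rows");
  if (mtry < 1 || mtry > p) stop("mtry out of range");

  std::vector<double> gini_dec(p, 0.0);
  std::vector<double> mda_sum(p, 0.0), mda_sq(p, 0.0);
  std::vector<int> oob_vote_pos(n, 0), oob_vote_tot(n, 0);
  List trees(ntree);
  std::vector<int> perm;

  for (int b = 0; b < ntree; ++b) {
    std::vector<int> inbag(n);
    std::vector<bool> in(n, false);
    for (int i = 0; i < n; ++i) {
      inbag[i] = rand_int(n);
      in[inbag[i]] = true;
    }
    Builder builder(X, y, mtry, min_node, gini_dec);
    builder.grow(inbag);
    const Tree& t = builder.tree;
    trees[b] = tree_to_list(t);

    std::vector<int> oob;
    for (int i = 0; i < n; ++i)
      if (!in[i]) oob.push_back(i);
    if (oob.empty()) continue;

    int correct = 0;
    for (int i : oob) {
      int vote = predict_row(t, X, i) > 0.5 ? 1 : 0;
      oob_vote_pos[i] += vote;
      oob_vote_tot[i] += 1;
      if (vote == y[i]) ++correct;
    }
    if (importance) {
      double acc0 = (double)correct / oob.size();
      perm.assign(oob.begin(), oob.end());
      for (int f = 0; f < p; ++f) {
        // permute feature f's values among this tree's OOB rows
        for (int k = (int)perm.size() - 1; k > 0; --k)
          std::swap(perm[k], perm[rand_int(k + 1)]);
        int corr = 0;
        for (size_t k = 0; k < oob.size(); ++k) {
          int vote = predict_row(t, X, oob[k], f, perm[k]) > 0.5 ? 1 : 0;
          if (vote == y[oob[k]]) ++corr;
        }
        double d = acc0 - (double)corr / oob.size();
        mda_sum[f] += d;
        mda_sq[f] += d * d;
      }
    }
  }

  int oob_wrong = 0, oob_n = 0;
  for (int i = 0; i < n; ++i) {
    if (oob_vote_tot[i] == 0) continue;
    ++oob_n;
    int pred = 2 * oob_vote_pos[i] > oob_vote_tot[i] ? 1 : 0;
    if (pred != y[i]) ++oob_wrong;
  }

  NumericVector mda(p), mda_sd(p), mdg(p);
  for (int f = 0; f < p; ++f) {
    mda[f] = mda_sum[f] / ntree;
    double var = mda_sq[f] / ntree - mda[f] * mda[f];
    mda_sd[f] = var > 0 ? std::sqrt(var) : 0.0;
    mdg[f] = gini_dec[f] / ntree;
  }
  return List::create(
    _["trees"] = trees,
    _["oob_error"] = oob_n ? (double)oob_wrong / oob_n : NA_REAL,
    _["mda"] = mda, _["mda_sd"] = mda_sd, _["mdg"] = mdg,
    _["ntree"] = ntree, _["mtry"] = mtry);
}

// Vote fraction of the ensemble: share of trees whose terminal node majority
// is the positive class.
// [[Rcpp::export(rng = false)]]
NumericVector rf_predict_cpp(List trees, NumericMatrix X) {
  int n = X.nrow(), ntree = trees.size();
  NumericVector out(n);
  for (int b = 0; b < ntree; ++b) {
    Tree t = tree_from_list(trees[b]);
    for (int i = 0; i < n; ++i)
      out[i] += predict_row(t, X, i) > 0.5 ? 1.0 : 0.0;
  }
  return out / (double)ntree;
}
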