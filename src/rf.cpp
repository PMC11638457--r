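// Random forest for binary classification with Gini (mean-decrease-impurity)
// importances, matching the usual scikit-learn conventions: bootstrap samples,
// mtry random candidate features per node, class-probability prediction as the
// mean over trees of the leaf class-1 fraction, and per-tree importances
// normalized to sum 1 before averaging across trees.

// [[Rcpp::depends(RcppArmadillo)]]
#include <RcppArmadillo.h>
#include <random>
#include <vector>

struct TreeNode {
  int feature = -1;          // -1 => leaf
  double threshold = 0.0;
  int left = -1, right = -1;
  double prob = 0.0;         // leaf class-1 fraction
};

struct Tree {
  std::vector<TreeNode> nodes;
};

struct Forest {
  std::vector<Tree> trees;
  arma::vec importance;      // averaged normalized MDI
  int p = 0;
};

struct Builder {
  const arma::mat& X;
  const arma::ivec& y;
  int mtry, max_depth, min_leaf;
  std::mt19937& rng;
  Tree& tree;
  arma::vec imp;             // raw impurity decreases for this tree
  double n_root;

  Builder(const arma::mat& X_, const arma::ivec& y_, int mtry_, int max_depth_,
          int min_leaf_, std::mt19937& rng_, Tree& t_)
      : X(X_), y(y_), mtry(mtry_), max_depth(max_depth_), min_leaf(min_leaf_),
        rng(rng_), tree(t_) {
    imp.zeros(X.n_cols);
  }

  static double gini(double n1, double n) {
    if (n <= 0) return 0.0;
    double p1 = n1 / n;
    return 2.0 * p1 * (1.0 - p1);
  }

  int build(std::vector<int>& idx, int depth) {
    double n = idx.size(), n1 = 0;
    for (int i : idx) n1 += y[i];
    TreeNode node;
    node.prob = n > 0 ? n1 / n : 0.0;
    double g0 = gini(n1, n);
    bool stop = (g0 <= 0.0) || (max_depth > 0 && depth >= max_depth) ||
                (n < 2.0 * min_leaf) || n < 2;
    if (!stop) {
      // sample mtry features without replacement
      int p = X.n_cols;
      std::vector<int> feats(p);
      for (int j = 0; j < p; ++j) feats[j] = j;
      for (int j = 0; j < mtry && j < p; ++j) {
        std::uniform_int_distribution<int> ud(j, p - 1);
        std::swap(feats[j], feats[ud(rng)]);
      }
      int best_f = -1;
      double best_gain = 1e-12, best_thr = 0.0;
      std::vector<std::pair<double, int>> vals(idx.size());
      for (int jj = 0; jj < mtry && jj < p; ++jj) {
        int f = feats[jj];
        for (size_t i = 0; i < idx.size(); ++i)
          vals[i] = {X(idx[i], f), y[idx[i]]};
        std::sort(vals.begin(), vals.end());
        double ln = 0, l1 = 0;
        for (size_t i = 0; i + 1 < vals.size(); ++i) {
          ln += 1; l1 += vals[i].second;
          if (vals[i].first == vals[i + 1].first) continue;
          double rn = n - ln, r1 = n1 - l1;
          if (ln < min_leaf || rn < min_leaf) continue;
          double gain = g0 - (ln / n) * gini(l1, ln) - (rn / n) * gini(r1, rn);
          if (gain > best_gain) {
            best_gain = gain; best_f = f;
            best_thr = 0.5 * (vals[i].first + vals[i + 1].first);
          }
        }
      }
      if (best_f >= 0) {
        std::vector<int> li, ri;
        for (int i : idx) (X(i, best_f) <= best_thr ? li : ri).push_back(i);
        node.feature = best_f; node.threshold = best_thr;
        imp[best_f] += (n / n_root) * best_gain;
        int me = int(tree.nodes.size());
        tree.nodes.push_back(node);
        int l = build(li, depth + 1);
        int r = build(ri, depth + 1);
        tree.nodes[me].left = l;
        tree.nodes[me].right = r;
        return me;
      }
    }
    int me = int(tree.nodes.size());
    tree.nodes.push_back(node);
    return me;
  }
};

static double tree_predict(const Tree& t, const arma::rowvec& x) {
  int ni = 0;
  while (t.nodes[ni].feature >= 0) {
    const TreeNode& nd = t.nodes[ni];
    ni = (x[nd.feature] <= nd.threshold) ? nd.left : nd.right;
  }
  return t.nodes[ni].prob;
}

// [[Rcpp::export]]
SEXP rf_fit(Rcpp::NumericMatrix Xr, Rcpp::IntegerVector yr, int ntree, int mtry,
            int max_depth, int min_leaf, int seed, bool bootstrap = true) {
  arma::mat X(Xr.begin(), Xr.nrow(), Xr.ncol(), false);
  arma::ivec y(Xr.nrow());
  for (int i = 0; i < Xr.nrow(); ++i) y[i] = yr[i];
  int n = X.n_rows, p = X.n_cols;
  if (mtry <= 0) mtry = std::max(1, int(std::floor(std::sqrt(double(p)))));

  Forest* f = new Forest();
  f->p = p;
  f->trees.resize(ntree);
  f->importance.zeros(p);
  std::mt19937 rng{static_cast<unsigned>(seed)};
  std::uniform_int_distribution<int> samp(0, n - 1);

  for (int t = 0; t < ntree; ++t) {
    std::vector<int> idx(n);
    if (bootstrap)
      for (int i = 0; i < n; ++i) idx[i] = samp(rng);
    else
      for (int i = 0; i < n; ++i) idx[i] = i;
    Builder b(X, y, mtry, max_depth, min_leaf, rng, f->trees[t]);
    b.n_root = double(n);
    b.build(idx, 0);
    double s = arma::accu(b.imp);
    if (s > 0) f->importance += b.imp / s;
  }
  f->importance /= double(ntree);
  return Rcpp::XPtr<Forest>(f, true);
}

// [[Rcpp::export]]
Rcpp::NumericVector rf_predict(SEXP fp, Rcpp::NumericMatrix Xr) {
  Rcpp::XPtr<Forest> f(fp);
  arma::mat X(Xr.begin(), Xr.nrow(), Xr.ncol(), false);
  int n = X.n_rows;
  Rcpp::NumericVector out(n);
  for (int i = 0; i < n; ++i) {
    double s = 0.0;
    for (const Tree& t : f->trees) s += tree_predict(t, X.row(i));
    out[i] = s / f->trees.size();
  }
  return out;
}

// [[Rcpp::export]]
Rcpp::NumericVector rf_importance(SEXP fp) {
  Rcpp::XPtr<Forest> f(fp);
  return Rcpp::NumericVector(f->importance.begin(), f->importance.end());
}

// [[Rcpp::export]]
Rcpp::List rf_export(SEXP fp) {
  Rcpp::XPtr<Forest> f(fp);
  Rcpp::List trees(f->trees.size());
  for (size_t t = 0; t < f->trees.size(); ++t) {
    const Tree& tr = f->trees[t];
    int m = int(tr.nodes.size());
    Rcpp::NumericMatrix nd(m, 5);
    for (int i = 0; i < m; ++i) {
      nd(i, 0) = tr.nodes[i].feature;
      nd(i, 1) = tr.nodes[i].threshold;
      nd(i, 2) = tr.nodes[i].left;
      nd(i, 3) = tr.nodes[i].right;
      nd(i, 4) = tr.nodes[i].prob;
    }
    trees[t] = nd;
  }
  return Rcpp::List::create(
      Rcpp::Named("trees") = trees,
      Rcpp::Named("importance") =
          Rcpp::NumericVector(f->importance.begin(), f->importance.end()),
      Rcpp::Named("p") = f->p);
}

// [[Rcpp::export]]
SEXP rf_import(Rcpp::List obj) {
  Forest* f = new Forest();
  Rcpp::List trees = obj["trees"];
  f->p = Rcpp::as<int>(obj["p"]);
  Rcpp::NumericVector imp = obj["importance"];
  f->importance = arma::vec(imp.begin(), imp.size());
  f->trees.resize(trees.size());
  for (int t = 0; t < trees.size(); ++t) {
    Rcpp::NumericMatrix nd = trees[t];
    Tree& tr = f->trees[t];
    tr.nodes.resize(nd.nrow());
    for (int i = 0; i < nd.nrow(); ++i) {
      tr.nodes[i].feature = int(nd(i, 0));
      tr.nodes[i].threshold = nd(i, 1);
      tr.nodes[i].left = int(nd(i, 2));
      tr.nodes[i].right = int(nd(i, 3));
      tr.nodes[i].prob = nd(i, 4);
    }
  }
  return Rcpp::XPtr<Forest>(f, true);
}
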