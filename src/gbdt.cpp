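// Gradient-boosted decision trees with logistic loss.
//
// Histogram-based exact greedy splitting on pre-binned features (up to 32
// quantile bins per feature), second-order (xgboost-style) gain with L2
// leaf regularization, shrinkage, per-tree row subsampling and per-tree
// feature subsampling. Small and CPU-friendly: the comparator contract is
// the printed hyperparameter grid, not a specific tree library.

// [[Rcpp::depends(RcppArmadillo)]]
#include <RcppArmadillo.h>
#include <random>
using namespace Rcpp;

struct Tree {
  std::vector<int> feat, left, right;
  std::vector<double> thr, val;  // leaf value in val when feat == -1
  int add_node() {
    feat.push_back(-1); left.push_back(-1); right.push_back(-1);
    thr.push_back(0); val.push_back(0);
    return (int)feat.size() - 1;
  }
};

struct Builder {
  const arma::umat& bins;          // n x p binned features
  const std::vector<std::vector<double>>& edges;  // split value per bin gap
  const arma::vec& g;
  const arma::vec& h;
  const std::vector<int>& feats;   // feature subset for this tree
  double lambda, min_child;
  int max_depth, max_bins;
  Tree tree;

  Builder(const arma::umat& b, const std::vector<std::vector<double>>& e,
          const arma::vec& g_, const arma::vec& h_,
          const std::vector<int>& f, double lam, double mc, int md, int mb)
    : bins(b), edges(e), g(g_), h(h_), feats(f), lambda(lam),
      min_child(mc), max_depth(md), max_bins(mb) {}

  int build(std::vector<int>& rows, int depth) {
    int node = tree.add_node();
    double G = 0, H = 0;
    for (int r : rows) { G += g[r]; H += h[r]; }
    double leaf = -G / (H + lambda);
    if (depth >= max_depth || rows.size() < 2) {
      tree.val[node] = leaf;
      return node;
    }
    double best_gain = 1e-12;
    int best_f = -1, best_bin = -1;
    std::vector<double> Gh(max_bins), Hh(max_bins);
    for (int f : feats) {
      if (edges[f].empty()) continue;
      std::fill(Gh.begin(), Gh.end(), 0.0);
      std::fill(Hh.begin(), Hh.end(), 0.0);
      for (int r : rows) {
        int b = (int)bins(r, f);
        Gh[b] += g[r]; Hh[b] += h[r];
      }
      double GL = 0, HL = 0;
      int nb = (int)edges[f].size();  // nb split points = nb+1 bins in use
      for (int b = 0; b < nb; ++b) {
        GL += Gh[b]; HL += Hh[b];
        double GR = G - GL, HR = H - HL;
        if (HL < min_child || HR < min_child) continue;
        double gain = 0.5 * (GL * GL / (HL + lambda) +
                             GR * GR / (HR + lambda) -
                             G * G / (H + lambda));
        if (gain > best_gain) { best_gain = gain; best_f = f; best_bin = b; }
      }
    }
    if (best_f < 0) {
      tree.val[node] = leaf;
      return node;
    }
    std::vector<int> lrows, rrows;
    for (int r : rows) {
      if ((int)bins(r, best_f) <= best_bin) lrows.push_back(r);
      else rrows.push_back(r);
    }
    if (lrows.empty() || rrows.empty()) {
      tree.val[node] = leaf;
      return node;
    }
    tree.feat[node] = best_f;
    tree.thr[node] = edges[best_f][best_bin];
    tree.left[node] = build(lrows, depth + 1);
    tree.right[node] = build(rrows, depth + 1);
    return node;
  }
};

static double tree_predict(const Tree& t, const arma::rowvec& x) {
  int node = 0;
  while (t.feat[node] >= 0) {
    node = (x[t.feat[node]] <= t.thr[node]) ? t.left[node] : t.right[node];
  }
  return t.val[node];
}

// [[Rcpp::export]]
List gbdt_train_cpp(const arma::mat& X, const arma::vec& y, List params) {
  double eta = as<double>(params["learning_rate"]);
  int max_depth = as<int>(params["max_depth"]);
  double subsample = as<double>(params["subsample"]);
  double colsample = as<double>(params["colsample"]);
  int nrounds = as<int>(params["nrounds"]);
  double lambda = params.containsElementNamed("lambda") ?
    as<double>(params["lambda"]) : 1.0;
  int seed = as<int>(params["seed"]);
  int max_bins = 32;
  int n = (int)X.n_rows, p = (int)X.n_cols;

  // quantile pre-binning; edges[f][b] = inclusive upper value of bin b
  arma::umat bins(n, p, arma::fill::zeros);
  std::vector<std::vector<double>> edges(p);
  for (int f = 0; f < p; ++f) {
    arma::vec col = X.col(f);
    arma::vec uq = arma::unique(col);
    arma::vec cand;
    if ((int)uq.n_elem <= max_bins) {
      cand = uq;
    } else {
      cand.set_size(max_bins);
      arma::vec sorted = arma::sort(col);
      for (int b = 0; b < max_bins; ++b) {
        double q = (b + 1.0) / max_bins;
        cand[b] = sorted[(arma::uword)std::min(
            (double)n - 1, std::floor(q * n))];
      }
      cand = arma::unique(cand);
    }
    // bin b holds values <= cand[b]; last bin catches the rest
    int nb = (int)cand.n_elem;
    for (int i = 0; i < n; ++i) {
      int b = 0;
      while (b < nb - 1 && col[i] > cand[b]) ++b;
      bins(i, f) = b;
    }
    edges[f].assign(cand.begin(), cand.end() - (nb ? 1 : 0));
  }

  std::mt19937 rng(seed);
  arma::vec margin(n, arma::fill::zeros);
  List trees(nrounds);
  std::vector<int> allrows(n), allfeat(p);
  for (int i = 0; i < n; ++i) allrows[i] = i;
  for (int f = 0; f < p; ++f) allfeat[f] = f;

  for (int round = 0; round < nrounds; ++round) {
    arma::vec prob = 1.0 / (1.0 + arma::exp(-margin));
    arma::vec g = prob - y;
    arma::vec h = prob % (1.0 - prob);
    std::vector<int> rows = allrows;
    if (subsample < 1.0) {
      std::shuffle(rows.begin(), rows.end(), rng);
      rows.resize(std::max(1, (int)std::floor(subsample * n)));
    }
    std::vector<int> feats = allfeat;
    if (colsample < 1.0) {
      std::shuffle(feats.begin(), feats.end(), rng);
      feats.resize(std::max(1, (int)std::floor(colsample * p)));
      std::sort(feats.begin(), feats.end());
    }
    Builder bld(bins, edges, g, h, feats, lambda, 1e-4, max_depth, max_bins);
    bld.build(rows, 0);
    for (int i = 0; i < n; ++i) {
      margin[i] += eta * tree_predict(bld.tree, X.row(i));
    }
    trees[round] = List::create(
      _["feat"] = wrap(bld.tree.feat), _["thr"] = wrap(bld.tree.thr),
      _["left"] = wrap(bld.tree.left), _["right"] = wrap(bld.tree.right),
      _["val"] = wrap(bld.tree.val));
  }
  return List::create(_["trees"] = trees, _["eta"] = eta);
}

// [[Rcpp::export]]
arma::vec gbdt_predict_cpp(List model, const arma::mat& X) {
  List trees = model["trees"];
  double eta = as<double>(model["eta"]);
  int n = (int)X.n_rows;
  arma::vec margin(n, arma::fill::zeros);
  for (int k = 0; k < trees.size(); ++k) {
    List tl = trees[k];
    Tree t;
    t.feat = as<std::vector<int>>(tl["feat"]);
    t.thr = as<std::vector<double>>(tl["thr"]);
    t.left = as<std::vector<int>>(tl["left"]);
    t.right = as<std::vector<int>>(tl["right"]);
    t.val = as<std::vector<double>>(tl["val"]);
    for (int i = 0; i < n; ++i) {
      margin[i] += eta * tree_predict(t, X.row(i));
    }
  }
  return 1.0 / (1.0 + arma::exp(-margin));
}
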