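// Gated recurrent risk model over ragged age-year code sequences.
//
// Architecture contract: per age-year step, the embeddings of that year's
// distinct codes are summed and concatenated with the standardized age at
// the step; a single GRU layer runs over the steps; dropout is applied to
// the final hidden state; the fixed-over-time vector is concatenated and an
// affine map with logistic output produces the 1-year death probability.
// Training: mean binary cross-entropy, Adam with L2 weight decay, early
// stopping on validation AUC with best-epoch weight restore.
//
// Sequences are ragged (persons differ in age years T). Batches are sorted
// by T descending so the active rows at step t form a prefix; inactive rows
// simply stop updating, which leaves each person's final hidden state in
// the running state matrix. The three gates' input and recurrent
// projections are fused into single (.,3H) GEMMs: with 200-row batches the
// wide products keep BLAS much closer to peak than three narrow ones.

// [[Rcpp::depends(RcppArmadillo)]]
#include <RcppArmadillo.h>
#include <random>
using namespace Rcpp;

typedef arma::fmat FM;
typedef arma::frowvec FRV;

struct RaggedData {
  arma::ivec codes;      // concatenated code indices (1 = UNK, >=2 vocab)
  arma::ivec code_ptr;   // 0-based, length total_rows + 1
  arma::ivec row_ptr;    // 0-based, length n + 1
  arma::fvec age;        // per global row, standardized
  FM fixed;              // n x F
  arma::fvec y;          // labels (may be empty for predict)
  int n() const { return (int)row_ptr.n_elem - 1; }
  int T(int i) const { return row_ptr[i + 1] - row_ptr[i]; }
};

static RaggedData unpack(const List& d) {
  RaggedData r;
  r.codes = as<arma::ivec>(d["codes"]);
  r.code_ptr = as<arma::ivec>(d["code_ptr"]);
  r.row_ptr = as<arma::ivec>(d["row_ptr"]);
  r.age = arma::conv_to<arma::fvec>::from(as<arma::vec>(d["age_std"]));
  r.fixed = arma::conv_to<FM>::from(as<arma::mat>(d["fixed"]));
  if (d.containsElementNamed("label") && !Rf_isNull(d["label"])) {
    r.y = arma::conv_to<arma::fvec>::from(as<arma::vec>(d["label"]));
  }
  return r;
}

// gate order within fused matrices: [z | r | n]
struct Weights {
  FM Emb;        // (V+2) x E
  FM W;          // (E+1) x 3H, input projection of all gates
  FM U;          // H x 3H, recurrent projection of all gates
  FRV b;         // 3H
  arma::fvec wout;
  float bout;
};

struct Grads {
  FM Emb, W, U;
  FRV b;
  arma::fvec wout;
  float bout;
  void zero_like(const Weights& w) {
    Emb.zeros(w.Emb.n_rows, w.Emb.n_cols);
    W.zeros(w.W.n_rows, w.W.n_cols);
    U.zeros(w.U.n_rows, w.U.n_cols);
    b.zeros(w.b.n_elem);
    wout.zeros(w.wout.n_elem);
    bout = 0.f;
  }
};

struct AdamState { FM m, v; };

static inline FM sigm(const FM& x) { return 1.0f / (1.0f + arma::exp(-x)); }

static Weights init_weights(int V2, int E, int H, int F, std::mt19937& rng) {
  std::uniform_real_distribution<float> u(-1.f, 1.f);
  float a = 1.f / std::sqrt((float)H);
  Weights w;
  auto fill = [&](FM& m, int r, int c, float s) {
    m.set_size(r, c);
    for (arma::uword j = 0; j < m.n_cols; ++j)
      for (arma::uword i = 0; i < m.n_rows; ++i) m(i, j) = u(rng) * s;
  };
  fill(w.Emb, V2, E, 0.1f);
  w.Emb.row(0).zeros();       // PAD row, never used
  fill(w.W, E + 1, 3 * H, a);
  fill(w.U, H, 3 * H, a);
  w.b.zeros(3 * H);
  // zero-init readout: the logit starts at the output bias (base rate)
  // and only learned structure ever enters the score
  w.wout.zeros(H + F);
  w.bout = 0.f;
  return w;
}

// per-batch activation cache for backprop
struct Cache {
  std::vector<FM> X, Hs, Z, R, N, A;  // Hs[t] = state AFTER step t; A = Hp*Un
  std::vector<int> act;
};

static void forward_batch(const Weights& w, const RaggedData& d,
                          const std::vector<int>& idx, Cache* cache,
                          FM& Hfinal) {
  int B = (int)idx.size();
  int E = w.Emb.n_cols, H = w.U.n_rows;
  int maxT = 0;
  for (int i = 0; i < B; ++i) maxT = std::max(maxT, d.T(idx[i]));
  FM Hcur(B, H, arma::fill::zeros);
  if (cache) {
    cache->X.resize(maxT); cache->Hs.resize(maxT + 1);
    cache->Z.resize(maxT); cache->R.resize(maxT); cache->N.resize(maxT);
    cache->A.resize(maxT); cache->act.resize(maxT);
    cache->Hs[0] = Hcur;
  }
  for (int t = 0; t < maxT; ++t) {
    int act = 0;
    while (act < B && d.T(idx[act]) > t) ++act;  // sorted desc -> prefix
    FM X(act, E + 1, arma::fill::zeros);
    for (int i = 0; i < act; ++i) {
      int g = d.row_ptr[idx[i]] + t;
      for (int c = d.code_ptr[g]; c < d.code_ptr[g + 1]; ++c) {
        X(i, arma::span(0, E - 1)) += w.Emb.row(d.codes[c]);
      }
      X(i, E) = d.age[g];
    }
    FM Hp = Hcur.rows(0, act - 1);
    FM G = X * w.W + arma::repmat(w.b, act, 1);   // act x 3H
    FM Grec = Hp * w.U;                            // act x 3H
    FM Z = sigm(G.cols(0, H - 1) + Grec.cols(0, H - 1));
    FM R = sigm(G.cols(H, 2 * H - 1) + Grec.cols(H, 2 * H - 1));
    FM A = Grec.cols(2 * H, 3 * H - 1);
    FM N = arma::tanh(G.cols(2 * H, 3 * H - 1) + R % A);
    Hcur.rows(0, act - 1) = (1.0f - Z) % N + Z % Hp;
    if (cache) {
      cache->X[t] = std::move(X); cache->Z[t] = std::move(Z);
      cache->R[t] = std::move(R); cache->N[t] = std::move(N);
      cache->A[t] = std::move(A); cache->act[t] = act;
      cache->Hs[t + 1] = Hcur;
    }
  }
  Hfinal = Hcur;  // logits computed by caller (dropout differs train/eval)
}

static void backward_batch(const Weights& w, const RaggedData& d,
                           const std::vector<int>& idx, const Cache& cache,
                           const FM& dHfinal, Grads& g) {
  int E = w.Emb.n_cols, H = w.U.n_rows;
  int maxT = (int)cache.X.size();
  FM dH = dHfinal;  // running dL/dh; a row activates at its last step
  for (int t = maxT - 1; t >= 0; --t) {
    int act = cache.act[t];
    FM dh = dH.rows(0, act - 1);
    const FM& Z = cache.Z[t];
    const FM& R = cache.R[t];
    const FM& N = cache.N[t];
    const FM& A = cache.A[t];
    const FM& X = cache.X[t];
    FM Hp = cache.Hs[t].rows(0, act - 1);
    FM dN = dh % (1.0f - Z) % (1.0f - N % N);
    FM dG(act, 3 * H);                       // fused pre-activation grads
    dG.cols(0, H - 1) = dh % (Hp - N) % Z % (1.0f - Z);          // dZ
    dG.cols(H, 2 * H - 1) = dN % A % R % (1.0f - R);             // dR
    dG.cols(2 * H, 3 * H - 1) = dN;                              // dNpre
    // recurrent-side pre-activations: z,r get dG directly; n-gate gets dN%R
    FM dGrec = dG;
    dGrec.cols(2 * H, 3 * H - 1) = dN % R;
    FM dHp = dh % Z + dGrec * w.U.t();
    g.U += Hp.t() * dGrec;
    g.W += X.t() * dG;
    g.b += arma::sum(dG, 0);
    FM dX = dG * w.W.t();
    for (int i = 0; i < act; ++i) {
      int gr = d.row_ptr[idx[i]] + t;
      for (int c = d.code_ptr[gr]; c < d.code_ptr[gr + 1]; ++c) {
        g.Emb.row(d.codes[c]) += dX.row(i).head(E);
      }
    }
    dH.rows(0, act - 1) = dHp;
  }
}

static void adam_update(FM& w, const FM& grad, AdamState& st, float lr,
                        float wd, float b1, float b2, float eps,
                        float b1t, float b2t) {
  FM gr = grad + wd * w;
  if (st.m.n_rows == 0) { st.m.zeros(arma::size(w)); st.v.zeros(arma::size(w)); }
  st.m = b1 * st.m + (1.f - b1) * gr;
  st.v = b2 * st.v + (1.f - b2) * (gr % gr);
  w -= lr * (st.m / (1.f - b1t)) / (arma::sqrt(st.v / (1.f - b2t)) + eps);
}

// Mann-Whitney AUC with average-rank tie handling
static double auc_cpp(const arma::fvec& y, const arma::fvec& s) {
  int n = (int)y.n_elem;
  arma::uvec ord = arma::stable_sort_index(
      arma::conv_to<arma::vec>::from(s));
  arma::vec rank(n);
  int i = 0;
  while (i < n) {
    int j = i;
    while (j + 1 < n && s[ord[j + 1]] == s[ord[i]]) ++j;
    double r = 0.5 * (i + j) + 1.0;
    for (int k = i; k <= j; ++k) rank[ord[k]] = r;
    i = j + 1;
  }
  double npos = arma::accu(y), sum_r = 0;
  for (int k = 0; k < n; ++k) if (y[k] > 0.5f) sum_r += rank[k];
  double nneg = n - npos;
  if (npos == 0 || nneg == 0) return NA_REAL;
  return (sum_r - npos * (npos + 1) / 2.0) / (npos * nneg);
}

static arma::fvec predict_all(const Weights& w, const RaggedData& d,
                              int chunk = 512) {
  int n = d.n(), H = w.U.n_rows;
  arma::fvec out(n);
  std::vector<int> order(n);
  for (int i = 0; i < n; ++i) order[i] = i;
  for (int s0 = 0; s0 < n; s0 += chunk) {
    int s1 = std::min(n, s0 + chunk);
    std::vector<int> idx(order.begin() + s0, order.begin() + s1);
    std::stable_sort(idx.begin(), idx.end(), [&](int a, int b) {
      return d.T(a) > d.T(b);
    });
    FM Hf;
    forward_batch(w, d, idx, nullptr, Hf);
    for (size_t i = 0; i < idx.size(); ++i) {
      float z = w.bout;
      for (int h = 0; h < H; ++h) z += Hf(i, h) * w.wout[h];
      for (arma::uword f = 0; f < d.fixed.n_cols; ++f)
        z += d.fixed(idx[i], f) * w.wout[H + f];
      out[idx[i]] = 1.f / (1.f + std::exp(-z));
    }
  }
  return out;
}

static List weights_to_list(const Weights& w) {
  return List::create(
    _["Emb"] = wrap(arma::conv_to<arma::mat>::from(w.Emb)),
    _["W"] = wrap(arma::conv_to<arma::mat>::from(w.W)),
    _["U"] = wrap(arma::conv_to<arma::mat>::from(w.U)),
    _["b"] = wrap(arma::conv_to<arma::rowvec>::from(w.b)),
    _["wout"] = wrap(arma::conv_to<arma::vec>::from(w.wout)),
    _["bout"] = (double)w.bout);
}

static Weights weights_from_list(const List& L) {
  Weights w;
  w.Emb = arma::conv_to<FM>::from(as<arma::mat>(L["Emb"]));
  w.W = arma::conv_to<FM>::from(as<arma::mat>(L["W"]));
  w.U = arma::conv_to<FM>::from(as<arma::mat>(L["U"]));
  w.b = arma::conv_to<FRV>::from(as<arma::rowvec>(L["b"]));
  w.wout = arma::conv_to<arma::fvec>::from(as<arma::vec>(L["wout"]));
  w.bout = (float)as<double>(L["bout"]);
  return w;
}

// [[Rcpp::export]]
List gru_train_cpp(List train, List valid, List params) {
  RaggedData dtr = unpack(train), dva = unpack(valid);
  int E = as<int>(params["embedding_dim"]);
  int H = as<int>(params["hidden_dim"]);
  float dropout = (float)as<double>(params["dropout"]);
  float lr = (float)as<double>(params["learning_rate"]);
  float wd = (float)as<double>(params["weight_decay"]);
  int bs = as<int>(params["batch_size"]);
  int max_epochs = as<int>(params["max_epochs"]);
  int patience = as<int>(params["patience"]);
  int seed = as<int>(params["seed"]);
  int V2 = as<int>(params["vocab_size"]) + 2;  // + PAD + UNK
  int F = dtr.fixed.n_cols;
  int n = dtr.n();
  bool verbose = params.containsElementNamed("verbose") ?
    as<bool>(params["verbose"]) : false;

  std::mt19937 rng(seed);
  Weights w = init_weights(V2, E, H, F, rng);
  {  // initialize the output bias at the training base rate
    double ybar = arma::mean(arma::conv_to<arma::vec>::from(dtr.y));
    ybar = std::min(std::max(ybar, 1e-6), 1.0 - 1e-6);
    w.bout = (float)std::log(ybar / (1.0 - ybar));
  }
  AdamState a_emb, a_w, a_u, a_b, a_wo, a_bo;
  float b1 = 0.9f, b2 = 0.999f, eps = 1e-8f;
  long step = 0;

  std::vector<int> order(n);
  for (int i = 0; i < n; ++i) order[i] = i;
  float keep = 1.f - dropout;
  std::uniform_real_distribution<float> unif(0.f, 1.f);

  double best_auc = -1;
  int best_epoch = -1, bad = 0;
  List best_weights;
  NumericVector log_epoch, log_loss, log_auc;

  for (int epoch = 0; epoch < max_epochs; ++epoch) {
    std::shuffle(order.begin(), order.end(), rng);
    double loss_sum = 0; long loss_n = 0;
    for (int s0 = 0; s0 < n; s0 += bs) {
      int s1 = std::min(n, s0 + bs);
      std::vector<int> idx(order.begin() + s0, order.begin() + s1);
      std::stable_sort(idx.begin(), idx.end(), [&](int a, int b) {
        return dtr.T(a) > dtr.T(b);
      });
      int B = (int)idx.size();
      Cache cache;
      FM Hf;
      forward_batch(w, dtr, idx, &cache, Hf);
      FM mask(B, H);
      for (int i = 0; i < B; ++i)
        for (int h = 0; h < H; ++h)
          mask(i, h) = (unif(rng) < keep) ? 1.f / keep : 0.f;
      FM Hd = Hf % mask;
      arma::fvec p(B), yv(B);
      for (int i = 0; i < B; ++i) {
        float zz = w.bout;
        for (int h = 0; h < H; ++h) zz += Hd(i, h) * w.wout[h];
        for (int f = 0; f < F; ++f)
          zz += dtr.fixed(idx[i], f) * w.wout[H + f];
        p[i] = 1.f / (1.f + std::exp(-zz));
        yv[i] = dtr.y[idx[i]];
        float pc = std::min(std::max(p[i], 1e-7f), 1.f - 1e-7f);
        loss_sum += -(yv[i] * std::log(pc) + (1 - yv[i]) * std::log(1 - pc));
      }
      loss_n += B;
      if (!std::isfinite(loss_sum)) {
        stop("NaN/Inf training loss at epoch %d (bad data or divergence)",
             epoch + 1);
      }
      arma::fvec dlogit = (p - yv) / (float)B;
      Grads g; g.zero_like(w);
      for (int i = 0; i < B; ++i) {
        for (int h = 0; h < H; ++h) g.wout[h] += dlogit[i] * Hd(i, h);
        for (int f = 0; f < F; ++f)
          g.wout[H + f] += dlogit[i] * dtr.fixed(idx[i], f);
        g.bout += dlogit[i];
      }
      FM dHf(B, H);
      for (int i = 0; i < B; ++i)
        for (int h = 0; h < H; ++h)
          dHf(i, h) = dlogit[i] * w.wout[h] * mask(i, h);
      backward_batch(w, dtr, idx, cache, dHf, g);
      ++step;
      float b1t = std::pow(b1, (float)step), b2t = std::pow(b2, (float)step);
      adam_update(w.Emb, g.Emb, a_emb, lr, wd, b1, b2, eps, b1t, b2t);
      adam_update(w.W, g.W, a_w, lr, wd, b1, b2, eps, b1t, b2t);
      adam_update(w.U, g.U, a_u, lr, wd, b1, b2, eps, b1t, b2t);
      {
        FM bv(w.b.t()), gv(g.b.t());
        adam_update(bv, gv, a_b, lr, wd, b1, b2, eps, b1t, b2t);
        w.b = bv.t();
        FM wov(w.wout), gov(g.wout);
        adam_update(wov, gov, a_wo, lr, wd, b1, b2, eps, b1t, b2t);
        w.wout = wov.col(0);
        FM bov(1, 1), gbo(1, 1);
        bov(0, 0) = w.bout; gbo(0, 0) = g.bout;
        adam_update(bov, gbo, a_bo, lr, wd, b1, b2, eps, b1t, b2t);
        w.bout = bov(0, 0);
      }
      w.Emb.row(0).zeros();  // PAD stays inert
    }
    arma::fvec pv = predict_all(w, dva);
    double vauc = auc_cpp(dva.y, pv);
    log_epoch.push_back(epoch + 1);
    log_loss.push_back(loss_sum / std::max(loss_n, 1L));
    log_auc.push_back(vauc);
    if (verbose) {
      Rcout << "epoch " << (epoch + 1) << " loss "
            << loss_sum / std::max(loss_n, 1L) << " valid AUC " << vauc
            << std::endl;
    }
    if (vauc > best_auc + 1e-6) {
      best_auc = vauc;
      best_epoch = epoch + 1;
      best_weights = weights_to_list(w);
      bad = 0;
    } else if (++bad >= patience) break;
    Rcpp::checkUserInterrupt();
  }
  if (best_epoch < 0) best_weights = weights_to_list(w);
  return List::create(
    _["weights"] = best_weights,
    _["best_epoch"] = best_epoch,
    _["best_valid_auc"] = best_auc,
    _["log"] = DataFrame::create(_["epoch"] = log_epoch,
                                 _["loss"] = log_loss,
                                 _["valid_auc"] = log_auc));
}

// [[Rcpp::export]]
NumericVector gru_predict_cpp(List weights, List data) {
  Weights w = weights_from_list(weights);
  RaggedData d = unpack(data);
  arma::fvec p = predict_all(w, d);
  return wrap(arma::conv_to<arma::vec>::from(p));
}
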