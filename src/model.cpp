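// Recurrent CRF sequence model.
//
// Architecture: a character-level bidirectional LSTM produces a
// morphological feature per token (concatenated final hidden states); that
// feature is concatenated with the token's word vector (trainable embedding
// or pretrained) and sense vector, passed through a token-level
// bidirectional LSTM, projected to unnormalized per-label emission scores,
// and decoded/trained with a linear-chain CRF (forward-backward gradients).
// Training is plain SGD, mini-batch of one sentence, inverted dropout on
// the concatenated token features and on the token-encoder output.
//
// All randomness (dropout masks) is drawn from R's RNG so a single R seed
// reproduces runs exactly.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace arma;

static const double NEG_INF = -std::numeric_limits<double>::infinity();

// ---------------------------------------------------------------- LSTM ----

struct LSTMCache {
  mat X;                  // d x T inputs
  mat I, F, G, O, C, TC;  // h x T gate activations, cell, tanh(cell)
  mat H;                  // h x T hidden states
};

static mat lstm_forward(const mat& Wx, const mat& Wh, const vec& b,
                        const mat& X, LSTMCache& cc) {
  const int h = Wh.n_cols, T = X.n_cols;
  cc.X = X;
  cc.I.set_size(h, T); cc.F.set_size(h, T); cc.G.set_size(h, T);
  cc.O.set_size(h, T); cc.C.set_size(h, T); cc.TC.set_size(h, T);
  cc.H.set_size(h, T);
  vec hprev(h, fill::zeros), cprev(h, fill::zeros);
  for (int t = 0; t < T; ++t) {
    vec a = Wx * X.col(t) + Wh * hprev + b;
    vec i = 1.0 / (1.0 + exp(-a.subvec(0, h - 1)));
    vec f = 1.0 / (1.0 + exp(-a.subvec(h, 2 * h - 1)));
    vec g = tanh(a.subvec(2 * h, 3 * h - 1));
    vec o = 1.0 / (1.0 + exp(-a.subvec(3 * h, 4 * h - 1)));
    vec c = f % cprev + i % g;
    vec tc = tanh(c);
    vec hh = o % tc;
    cc.I.col(t) = i; cc.F.col(t) = f; cc.G.col(t) = g; cc.O.col(t) = o;
    cc.C.col(t) = c; cc.TC.col(t) = tc; cc.H.col(t) = hh;
    hprev = hh; cprev = c;
  }
  return cc.H;
}

// dH: h x T upstream gradient; accumulates parameter grads, returns dX.
static mat lstm_backward(const mat& Wx, const mat& Wh, const LSTMCache& cc,
                         const mat& dH, mat& dWx, mat& dWh, vec& db) {
  const int h = Wh.n_cols, T = cc.X.n_cols;
  mat dX(cc.X.n_rows, T, fill::zeros);
  vec dh_rec(h, fill::zeros), dc(h, fill::zeros);
  for (int t = T - 1; t >= 0; --t) {
    vec dh = dH.col(t) + dh_rec;
    vec o = cc.O.col(t), tc = cc.TC.col(t);
    vec do_ = dh % tc;
    dc += dh % o % (1.0 - tc % tc);
    vec i = cc.I.col(t), f = cc.F.col(t), g = cc.G.col(t);
    vec cprev = (t > 0) ? vec(cc.C.col(t - 1)) : vec(h, fill::zeros);
    vec di = dc % g, dg = dc % i, df = dc % cprev;
    vec dc_prev = dc % f;
    vec da(4 * h);
    da.subvec(0, h - 1)         = di % i % (1.0 - i);
    da.subvec(h, 2 * h - 1)     = df % f % (1.0 - f);
    da.subvec(2 * h, 3 * h - 1) = dg % (1.0 - g % g);
    da.subvec(3 * h, 4 * h - 1) = do_ % o % (1.0 - o);
    vec hprev = (t > 0) ? vec(cc.H.col(t - 1)) : vec(h, fill::zeros);
    dWx += da * cc.X.col(t).t();
    dWh += da * hprev.t();
    db += da;
    dX.col(t) = Wx.t() * da;
    dh_rec = Wh.t() * da;
    dc = dc_prev;
  }
  return dX;
}

// ---------------------------------------------------------------- params --

struct Params {
  mat E_char, E_word;
  mat cf_Wx, cf_Wh; vec cf_b;
  mat cb_Wx, cb_Wh; vec cb_b;
  mat tf_Wx, tf_Wh; vec tf_b;
  mat tb_Wx, tb_Wh; vec tb_b;
  mat W_out; vec b_out;
  mat trans;
};

static Params params_from_list(const Rcpp::List& L) {
  Params p;
  p.E_char = Rcpp::as<mat>(L["E_char"]); p.E_word = Rcpp::as<mat>(L["E_word"]);
  p.cf_Wx = Rcpp::as<mat>(L["cf_Wx"]); p.cf_Wh = Rcpp::as<mat>(L["cf_Wh"]);
  p.cf_b = Rcpp::as<vec>(L["cf_b"]);
  p.cb_Wx = Rcpp::as<mat>(L["cb_Wx"]); p.cb_Wh = Rcpp::as<mat>(L["cb_Wh"]);
  p.cb_b = Rcpp::as<vec>(L["cb_b"]);
  p.tf_Wx = Rcpp::as<mat>(L["tf_Wx"]); p.tf_Wh = Rcpp::as<mat>(L["tf_Wh"]);
  p.tf_b = Rcpp::as<vec>(L["tf_b"]);
  p.tb_Wx = Rcpp::as<mat>(L["tb_Wx"]); p.tb_Wh = Rcpp::as<mat>(L["tb_Wh"]);
  p.tb_b = Rcpp::as<vec>(L["tb_b"]);
  p.W_out = Rcpp::as<mat>(L["W_out"]); p.b_out = Rcpp::as<vec>(L["b_out"]);
  p.trans = Rcpp::as<mat>(L["trans"]);
  return p;
}

static Rcpp::List params_to_list(const Params& p) {
  return Rcpp::List::create(
    Rcpp::Named("E_char") = p.E_char, Rcpp::Named("E_word") = p.E_word,
    Rcpp::Named("cf_Wx") = p.cf_Wx, Rcpp::Named("cf_Wh") = p.cf_Wh,
    Rcpp::Named("cf_b") = p.cf_b,
    Rcpp::Named("cb_Wx") = p.cb_Wx, Rcpp::Named("cb_Wh") = p.cb_Wh,
    Rcpp::Named("cb_b") = p.cb_b,
    Rcpp::Named("tf_Wx") = p.tf_Wx, Rcpp::Named("tf_Wh") = p.tf_Wh,
    Rcpp::Named("tf_b") = p.tf_b,
    Rcpp::Named("tb_Wx") = p.tb_Wx, Rcpp::Named("tb_Wh") = p.tb_Wh,
    Rcpp::Named("tb_b") = p.tb_b,
    Rcpp::Named("W_out") = p.W_out, Rcpp::Named("b_out") = p.b_out,
    Rcpp::Named("trans") = p.trans);
}

static Params zeros_like(const Params& p) {
  Params g;
  g.E_char = zeros<mat>(size(p.E_char)); g.E_word = zeros<mat>(size(p.E_word));
  g.cf_Wx = zeros<mat>(size(p.cf_Wx)); g.cf_Wh = zeros<mat>(size(p.cf_Wh));
  g.cf_b = zeros<vec>(p.cf_b.n_elem);
  g.cb_Wx = zeros<mat>(size(p.cb_Wx)); g.cb_Wh = zeros<mat>(size(p.cb_Wh));
  g.cb_b = zeros<vec>(p.cb_b.n_elem);
  g.tf_Wx = zeros<mat>(size(p.tf_Wx)); g.tf_Wh = zeros<mat>(size(p.tf_Wh));
  g.tf_b = zeros<vec>(p.tf_b.n_elem);
  g.tb_Wx = zeros<mat>(size(p.tb_Wx)); g.tb_Wh = zeros<mat>(size(p.tb_Wh));
  g.tb_b = zeros<vec>(p.tb_b.n_elem);
  g.W_out = zeros<mat>(size(p.W_out)); g.b_out = zeros<vec>(p.b_out.n_elem);
  g.trans = zeros<mat>(size(p.trans));
  return g;
}

// ------------------------------------------------------------- sentence ---

struct Sent {
  std::vector<uvec> chars;   // 0-based char indices per token
  uvec word_idx;             // 0-based rows of E_word
  mat word_vecs;             // n x d_w pretrained vectors (may be empty)
  mat sense;                 // n x d_s (d_s may be 0)
  int n;
};

static Sent sent_from_list(const Rcpp::List& L) {
  Sent s;
  Rcpp::List ch = L["char_idx"];
  s.n = ch.size();
  for (int i = 0; i < s.n; ++i) {
    Rcpp::IntegerVector v = ch[i];
    uvec u(v.size());
    for (int j = 0; j < v.size(); ++j) u[j] = v[j] - 1;
    s.chars.push_back(u);
  }
  Rcpp::IntegerVector wi = L["word_idx"];
  s.word_idx.set_size(wi.size());
  for (int j = 0; j < wi.size(); ++j) s.word_idx[j] = wi[j] - 1;
  s.sense = Rcpp::as<mat>(L["sense"]);
  if (L.containsElementNamed("word_vecs") &&
      !Rf_isNull(((SEXP)L["word_vecs"]))) {
    s.word_vecs = Rcpp::as<mat>(L["word_vecs"]);
  }
  return s;
}

struct SentCache {
  std::vector<LSTMCache> cf, cb;  // per-token char LSTM runs
  mat X, Xd, maskX;               // D x n token features
  LSTMCache tf, tb;
  mat Hcat, Hd, maskH;            // 2H x n
  mat em;                         // ny x n emissions
};

// forward pass; if dropout > 0, masks are drawn from R's RNG
static void forward_pass(const Params& p, const Sent& s, double dropout,
                         SentCache& cc) {
  const int hc = p.cf_Wh.n_cols;
  const int dw = p.E_word.n_cols;
  const int ds = s.sense.n_cols;
  const int D = 2 * hc + dw + ds;
  const int n = s.n;
  const bool pre = s.word_vecs.n_rows > 0;

  cc.X.set_size(D, n);
  cc.cf.resize(n); cc.cb.resize(n);
  for (int t = 0; t < n; ++t) {
    mat Xc = p.E_char.rows(s.chars[t]).t();       // d_c x m
    mat Hf = lstm_forward(p.cf_Wx, p.cf_Wh, p.cf_b, Xc, cc.cf[t]);
    mat Hb = lstm_forward(p.cb_Wx, p.cb_Wh, p.cb_b, fliplr(Xc), cc.cb[t]);
    cc.X.submat(0, t, hc - 1, t) = Hf.col(Hf.n_cols - 1);
    cc.X.submat(hc, t, 2 * hc - 1, t) = Hb.col(Hb.n_cols - 1);
    vec wv = pre ? vec(s.word_vecs.row(t).t())
                 : vec(p.E_word.row(s.word_idx[t]).t());
    cc.X.submat(2 * hc, t, 2 * hc + dw - 1, t) = wv;
    if (ds > 0) {
      cc.X.submat(2 * hc + dw, t, D - 1, t) = s.sense.row(t).t();
    }
  }
  if (dropout > 0) {
    cc.maskX.set_size(D, n);
    double keep = 1.0 - dropout;
    for (uword k = 0; k < cc.maskX.n_elem; ++k) {
      cc.maskX[k] = (R::unif_rand() < keep) ? 1.0 / keep : 0.0;
    }
    cc.Xd = cc.X % cc.maskX;
  } else {
    cc.Xd = cc.X;
  }
  mat Hf = lstm_forward(p.tf_Wx, p.tf_Wh, p.tf_b, cc.Xd, cc.tf);
  mat Hb = lstm_forward(p.tb_Wx, p.tb_Wh, p.tb_b, fliplr(cc.Xd), cc.tb);
  cc.Hcat = join_cols(Hf, fliplr(Hb));
  if (dropout > 0) {
    cc.maskH.set_size(size(cc.Hcat));
    double keep = 1.0 - dropout;
    for (uword k = 0; k < cc.maskH.n_elem; ++k) {
      cc.maskH[k] = (R::unif_rand() < keep) ? 1.0 / keep : 0.0;
    }
    cc.Hd = cc.Hcat % cc.maskH;
  } else {
    cc.Hd = cc.Hcat;
  }
  cc.em = p.W_out * cc.Hd;
  cc.em.each_col() += p.b_out;
}

// dEm: ny x n gradient on emissions; accumulate into g
static void backward_pass(const Params& p, const Sent& s, const SentCache& cc,
                          const mat& dEm, double dropout, Params& g) {
  const int hc = p.cf_Wh.n_cols;
  const int dw = p.E_word.n_cols;
  const int n = s.n;
  const int H = p.tf_Wh.n_cols;
  const bool pre = s.word_vecs.n_rows > 0;

  g.W_out += dEm * cc.Hd.t();
  g.b_out += sum(dEm, 1);
  mat dHd = p.W_out.t() * dEm;                  // 2H x n
  mat dHcat = (dropout > 0) ? mat(dHd % cc.maskH) : dHd;
  mat dHf = dHcat.rows(0, H - 1);
  mat dHb = fliplr(dHcat.rows(H, 2 * H - 1));
  mat dXf = lstm_backward(p.tf_Wx, p.tf_Wh, cc.tf, dHf,
                          g.tf_Wx, g.tf_Wh, g.tf_b);
  mat dXb = lstm_backward(p.tb_Wx, p.tb_Wh, cc.tb, dHb,
                          g.tb_Wx, g.tb_Wh, g.tb_b);
  mat dXd = dXf + fliplr(dXb);
  mat dX = (dropout > 0) ? mat(dXd % cc.maskX) : dXd;

  for (int t = 0; t < n; ++t) {
    if (!pre) {
      g.E_word.row(s.word_idx[t]) +=
        dX.submat(2 * hc, t, 2 * hc + dw - 1, t).t();
    }
    int m = cc.cf[t].X.n_cols;
    mat dHcf(hc, m, fill::zeros), dHcb(hc, m, fill::zeros);
    dHcf.col(m - 1) = dX.submat(0, t, hc - 1, t);
    dHcb.col(m - 1) = dX.submat(hc, t, 2 * hc - 1, t);
    mat dXcf = lstm_backward(p.cf_Wx, p.cf_Wh, cc.cf[t], dHcf,
                             g.cf_Wx, g.cf_Wh, g.cf_b);
    mat dXcb = lstm_backward(p.cb_Wx, p.cb_Wh, cc.cb[t], dHcb,
                             g.cb_Wx, g.cb_Wh, g.cb_b);
    mat dXc = dXcf + fliplr(dXcb);              // d_c x m
    for (int j = 0; j < m; ++j) {
      g.E_char.row(s.chars[t][j]) += dXc.col(j).t();
    }
  }
}

// ------------------------------------------------------------------ CRF ---

static double lse(const vec& x) {
  double m = x.max();
  if (!std::isfinite(m)) return m;
  return m + std::log(accu(exp(x - m)));
}

// forward-backward; fills dEm (ny x n) and dTrans with d NLL / d params,
// returns the NLL of the gold path.  -Inf transitions contribute nothing.
static double crf_nll_grad(const mat& em, const mat& trans, const uvec& gold,
                           mat& dEm, mat& dTrans) {
  const int ny = em.n_rows, n = em.n_cols;
  const int start = ny, stop = ny + 1;
  mat alpha(ny, n), beta(ny, n);
  alpha.col(0) = trans.submat(start, 0, start, ny - 1).t() + em.col(0);
  for (int t = 1; t < n; ++t) {
    for (int y = 0; y < ny; ++y) {
      alpha(y, t) = lse(alpha.col(t - 1) +
                        trans.submat(0, y, ny - 1, y)) + em(y, t);
    }
  }
  beta.col(n - 1) = trans.submat(0, stop, ny - 1, stop);
  for (int t = n - 2; t >= 0; --t) {
    for (int y = 0; y < ny; ++y) {
      beta(y, t) = lse(trans.submat(y, 0, y, ny - 1).t() +
                       em.col(t + 1) + beta.col(t + 1));
    }
  }
  double logZ = lse(alpha.col(n - 1) +
                    trans.submat(0, stop, ny - 1, stop));

  // gold score
  double gs = trans(start, gold[0]) + em(gold[0], 0);
  for (int t = 1; t < n; ++t) gs += trans(gold[t - 1], gold[t]) + em(gold[t], t);
  gs += trans(gold[n - 1], stop);

  // node marginals -> emission gradient
  for (int t = 0; t < n; ++t) {
    for (int y = 0; y < ny; ++y) {
      double lp = alpha(y, t) + beta(y, t) - logZ;
      dEm(y, t) += std::isfinite(lp) ? std::exp(lp)
                                     : (lp > 0 ? 1.0 : 0.0);
    }
    dEm(gold[t], t) -= 1.0;
  }
  // edge marginals -> transition gradient
  for (int t = 1; t < n; ++t) {
    for (int yp = 0; yp < ny; ++yp) {
      if (!std::isfinite(alpha(yp, t - 1))) continue;
      for (int y = 0; y < ny; ++y) {
        double tr = trans(yp, y);
        if (!std::isfinite(tr)) continue;
        double lp = alpha(yp, t - 1) + tr + em(y, t) + beta(y, t) - logZ;
        dTrans(yp, y) += std::exp(lp);
      }
    }
    dTrans(gold[t - 1], gold[t]) -= 1.0;
  }
  for (int y = 0; y < ny; ++y) {
    double lp0 = alpha(y, 0) + beta(y, 0) - logZ;
    if (std::isfinite(lp0)) dTrans(start, y) += std::exp(lp0);
    double lpn = alpha(y, n - 1) + trans(y, stop) - logZ;
    if (std::isfinite(lpn)) dTrans(y, stop) += std::exp(lpn);
  }
  dTrans(start, gold[0]) -= 1.0;
  dTrans(gold[n - 1], stop) -= 1.0;

  return logZ - gs;
}

// ------------------------------------------------------------- exports ----

// emission scores for one sentence (eval mode: no dropout); n x ny
// [[Rcpp::export]]
arma::mat cpp_emissions(Rcpp::List params, Rcpp::List sent) {
  Params p = params_from_list(params);
  Sent s = sent_from_list(sent);
  SentCache cc;
  forward_pass(p, s, 0.0, cc);
  return cc.em.t();
}

// NLL of the gold path for one sentence (eval mode)
// [[Rcpp::export]]
double cpp_sentence_loss(Rcpp::List params, Rcpp::List sent,
                         Rcpp::IntegerVector gold) {
  Params p = params_from_list(params);
  Sent s = sent_from_list(sent);
  SentCache cc;
  forward_pass(p, s, 0.0, cc);
  uvec g(gold.size());
  for (int i = 0; i < gold.size(); ++i) g[i] = gold[i] - 1;
  mat dEm(cc.em.n_rows, cc.em.n_cols, fill::zeros);
  mat dT(size(p.trans), fill::zeros);
  return crf_nll_grad(cc.em, p.trans, g, dEm, dT);
}

// analytic gradients for one sentence (eval mode); used by gradient checks
// [[Rcpp::export]]
Rcpp::List cpp_sentence_grads(Rcpp::List params, Rcpp::List sent,
                              Rcpp::IntegerVector gold) {
  Params p = params_from_list(params);
  Sent s = sent_from_list(sent);
  SentCache cc;
  forward_pass(p, s, 0.0, cc);
  uvec g(gold.size());
  for (int i = 0; i < gold.size(); ++i) g[i] = gold[i] - 1;
  Params gr = zeros_like(p);
  mat dEm(cc.em.n_rows, cc.em.n_cols, fill::zeros);
  double loss = crf_nll_grad(cc.em, p.trans, g, dEm, gr.trans);
  backward_pass(p, s, cc, dEm, 0.0, gr);
  Rcpp::List out = params_to_list(gr);
  out["loss"] = loss;
  return out;
}

static double grad_sq_norm(const Params& g) {
  return accu(square(g.E_char)) + accu(square(g.E_word)) +
    accu(square(g.cf_Wx)) + accu(square(g.cf_Wh)) + accu(square(g.cf_b)) +
    accu(square(g.cb_Wx)) + accu(square(g.cb_Wh)) + accu(square(g.cb_b)) +
    accu(square(g.tf_Wx)) + accu(square(g.tf_Wh)) + accu(square(g.tf_b)) +
    accu(square(g.tb_Wx)) + accu(square(g.tb_Wh)) + accu(square(g.tb_b)) +
    accu(square(g.W_out)) + accu(square(g.b_out)) + accu(square(g.trans));
}

static void sgd_step(Params& p, const Params& g, double lr) {
  p.E_char -= lr * g.E_char; p.E_word -= lr * g.E_word;
  p.cf_Wx -= lr * g.cf_Wx; p.cf_Wh -= lr * g.cf_Wh; p.cf_b -= lr * g.cf_b;
  p.cb_Wx -= lr * g.cb_Wx; p.cb_Wh -= lr * g.cb_Wh; p.cb_b -= lr * g.cb_b;
  p.tf_Wx -= lr * g.tf_Wx; p.tf_Wh -= lr * g.tf_Wh; p.tf_b -= lr * g.tf_b;
  p.tb_Wx -= lr * g.tb_Wx; p.tb_Wh -= lr * g.tb_Wh; p.tb_b -= lr * g.tb_b;
  p.W_out -= lr * g.W_out; p.b_out -= lr * g.b_out;
  // -Inf (forbidden) transition entries stay put: -Inf - 0 handled below
  for (uword k = 0; k < p.trans.n_elem; ++k) {
    if (std::isfinite(p.trans[k])) p.trans[k] -= lr * g.trans[k];
  }
}

// one SGD epoch over sentences (in the given order); returns updated
// parameters and the mean NLL
// [[Rcpp::export]]
Rcpp::List cpp_train_epoch(Rcpp::List params, Rcpp::List sents,
                           Rcpp::List golds, double lr, double dropout,
                           double clip) {
  Params p = params_from_list(params);
  const int ns = sents.size();
  double total = 0.0;
  Rcpp::RNGScope rngscope;
  for (int k = 0; k < ns; ++k) {
    Sent s = sent_from_list(sents[k]);
    Rcpp::IntegerVector gv = golds[k];
    uvec g(gv.size());
    for (int i = 0; i < gv.size(); ++i) g[i] = gv[i] - 1;
    SentCache cc;
    forward_pass(p, s, dropout, cc);
    Params gr = zeros_like(p);
    mat dEm(cc.em.n_rows, cc.em.n_cols, fill::zeros);
    total += crf_nll_grad(cc.em, p.trans, g, dEm, gr.trans);
    backward_pass(p, s, cc, dEm, dropout, gr);
    if (clip > 0) {
      double nrm = std::sqrt(grad_sq_norm(gr));
      if (nrm > clip) {
        double sc = clip / nrm;
        gr.E_char *= sc; gr.E_word *= sc;
        gr.cf_Wx *= sc; gr.cf_Wh *= sc; gr.cf_b *= sc;
        gr.cb_Wx *= sc; gr.cb_Wh *= sc; gr.cb_b *= sc;
        gr.tf_Wx *= sc; gr.tf_Wh *= sc; gr.tf_b *= sc;
        gr.tb_Wx *= sc; gr.tb_Wh *= sc; gr.tb_b *= sc;
        gr.W_out *= sc; gr.b_out *= sc; gr.trans *= sc;
      }
    }
    sgd_step(p, gr, lr);
  }
  Rcpp::List out = params_to_list(p);
  return Rcpp::List::create(Rcpp::Named("params") = out,
                            Rcpp::Named("mean_loss") = total / ns);
}

// batched eval-mode emissions for many sentences
// [[Rcpp::export]]
Rcpp::List cpp_emissions_batch(Rcpp::List params, Rcpp::List sents) {
  Params p = params_from_list(params);
  Rcpp::List out(sents.size());
  for (int k = 0; k < sents.size(); ++k) {
    Sent s = sent_from_list(sents[k]);
    SentCache cc;
    forward_pass(p, s, 0.0, cc);
    out[k] = cc.em.t();
  }
  return out;
}

// Viterbi decode on a (n x ny) emission matrix with (ny+2)^2 transitions;
// ties break to the lowest label index; returns 1-based label indices
// [[Rcpp::export]]
Rcpp::IntegerVector cpp_viterbi(arma::mat emissions, arma::mat trans) {
  const int n = emissions.n_rows, ny = emissions.n_cols;
  const int start = ny, stop = ny + 1;
  mat em = emissions.t();
  mat delta(ny, n);
  imat back(ny, n, fill::zeros);
  for (int y = 0; y < ny; ++y) delta(y, 0) = trans(start, y) + em(y, 0);
  for (int t = 1; t < n; ++t) {
    for (int y = 0; y < ny; ++y) {
      double best = NEG_INF; int bi = 0;
      for (int yp = 0; yp < ny; ++yp) {
        double v = delta(yp, t - 1) + trans(yp, y);
        if (v > best) { best = v; bi = yp; }
      }
      delta(y, t) = best + em(y, t);
      back(y, t) = bi;
    }
  }
  double best = NEG_INF; int bi = 0;
  for (int y = 0; y < ny; ++y) {
    double v = delta(y, n - 1) + trans(y, stop);
    if (v > best) { best = v; bi = y; }
  }
  Rcpp::IntegerVector out(n);
  out[n - 1] = bi + 1;
  for (int t = n - 1; t >= 1; --t) {
    bi = back(bi, t);
    out[t - 1] = bi + 1;
  }
  return out;
}
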