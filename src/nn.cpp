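// Bidirectional LSTM + LSTM + additive temporal attention + dense stack.
// Forward pass and full backpropagation-through-time, batched over
// sequences. Deterministic: all randomness (initial weights, dropout
// masks) is drawn on the R side and passed in.
//
// Layout conventions:
//   X            : cube n x d x T      (slice t = batch matrix at time t)
//   LSTM weights : W (d_in x 4H), U (H x 4H), b (4H); gate order i,f,g,o
//   hidden caches: cubes n x H x T
// [[Rcpp::depends(RcppArmadillo)]]
#include <RcppArmadillo.h>
using namespace arma;

static mat sigm(const mat& x) { return 1.0 / (1.0 + exp(-x)); }

struct LstmCache {
  cube i, f, g, o, c, h;   // each n x H x T
  void init(uword n, uword H, uword T) {
    i.set_size(n, H, T); f.set_size(n, H, T); g.set_size(n, H, T);
    o.set_size(n, H, T); c.set_size(n, H, T); h.set_size(n, H, T);
  }
};

// One LSTM direction over the whole sequence.
static void lstm_forward(const cube& X, const mat& W, const mat& U,
                         const rowvec& b, bool reverse, LstmCache& cc) {
  const uword n = X.n_rows, T = X.n_slices, H = U.n_rows;
  cc.init(n, H, T);
  mat h_prev(n, H, fill::zeros), c_prev(n, H, fill::zeros);
  for (uword s = 0; s < T; ++s) {
    const uword t = reverse ? (T - 1 - s) : s;
    mat Z = X.slice(t) * W + h_prev * U;
    Z.each_row() += b;
    mat gi = sigm(Z.cols(0, H - 1));
    mat gf = sigm(Z.cols(H, 2 * H - 1));
    mat gg = tanh(Z.cols(2 * H, 3 * H - 1));
    mat go = sigm(Z.cols(3 * H, 4 * H - 1));
    mat c = gf % c_prev + gi % gg;
    mat h = go % tanh(c);
    cc.i.slice(t) = gi; cc.f.slice(t) = gf; cc.g.slice(t) = gg;
    cc.o.slice(t) = go; cc.c.slice(t) = c;  cc.h.slice(t) = h;
    h_prev = h; c_prev = c;
  }
}

// BPTT for one direction. dH: gradient wrt this direction's hidden states
// (n x H x T). Accumulates dW,dU,db and (optionally) dX.
static void lstm_backward(const cube& X, const mat& W, const mat& U,
                          const LstmCache& cc, const cube& dH, bool reverse,
                          mat& dW, mat& dU, rowvec& db, cube* dX) {
  const uword n = X.n_rows, T = X.n_slices, H = U.n_rows;
  dW.zeros(W.n_rows, W.n_cols);
  dU.zeros(U.n_rows, U.n_cols);
  db.zeros(4 * H);
  mat dh_next(n, H, fill::zeros), dc_next(n, H, fill::zeros);
  for (uword s = 0; s < T; ++s) {
    // iterate processed timesteps last-to-first
    const uword t = reverse ? s : (T - 1 - s);
    const bool first_processed = reverse ? (t == T - 1) : (t == 0);
    mat c_prev = first_processed
        ? mat(n, H, fill::zeros)
        : cc.c.slice(reverse ? t + 1 : t - 1);
    mat h_prev = first_processed
        ? mat(n, H, fill::zeros)
        : cc.h.slice(reverse ? t + 1 : t - 1);
    mat tc = tanh(cc.c.slice(t));
    mat dh = dH.slice(t) + dh_next;
    mat dgo = dh % tc;
    mat dc = dc_next + dh % cc.o.slice(t) % (1.0 - tc % tc);
    mat dgi = dc % cc.g.slice(t);
    mat dgg = dc % cc.i.slice(t);
    mat dgf = dc % c_prev;
    mat dZ(n, 4 * H);
    dZ.cols(0, H - 1)         = dgi % cc.i.slice(t) % (1.0 - cc.i.slice(t));
    dZ.cols(H, 2 * H - 1)     = dgf % cc.f.slice(t) % (1.0 - cc.f.slice(t));
    dZ.cols(2 * H, 3 * H - 1) = dgg % (1.0 - cc.g.slice(t) % cc.g.slice(t));
    dZ.cols(3 * H, 4 * H - 1) = dgo % cc.o.slice(t) % (1.0 - cc.o.slice(t));
    dW += X.slice(t).t() * dZ;
    dU += h_prev.t() * dZ;
    db += sum(dZ, 0);
    if (dX) dX->slice(t) += dZ * W.t();
    dh_next = dZ * U.t();
    dc_next = dc % cc.f.slice(t);
  }
}

struct Params {
  mat Wf, Uf, Wb, Ub, W2, U2, Wa, Wd1, Wd2, Wo;
  rowvec bf, bb, b2, bd1, bd2, bo;
  vec ba, va;
};

static Params unpack(const Rcpp::List& p) {
  Params q;
  q.Wf = Rcpp::as<mat>(p["Wf"]); q.Uf = Rcpp::as<mat>(p["Uf"]);
  q.bf = Rcpp::as<rowvec>(p["bf"]);
  q.Wb = Rcpp::as<mat>(p["Wb"]); q.Ub = Rcpp::as<mat>(p["Ub"]);
  q.bb = Rcpp::as<rowvec>(p["bb"]);
  q.W2 = Rcpp::as<mat>(p["W2"]); q.U2 = Rcpp::as<mat>(p["U2"]);
  q.b2 = Rcpp::as<rowvec>(p["b2"]);
  q.Wa = Rcpp::as<mat>(p["Wa"]); q.ba = Rcpp::as<vec>(p["ba"]);
  q.va = Rcpp::as<vec>(p["va"]);
  q.Wd1 = Rcpp::as<mat>(p["Wd1"]); q.bd1 = Rcpp::as<rowvec>(p["bd1"]);
  q.Wd2 = Rcpp::as<mat>(p["Wd2"]); q.bd2 = Rcpp::as<rowvec>(p["bd2"]);
  q.Wo = Rcpp::as<mat>(p["Wo"]); q.bo = Rcpp::as<rowvec>(p["bo"]);
  return q;
}

static mat row_softmax(mat z) {
  z.each_col() -= max(z, 1);
  z = exp(z);
  z.each_col() /= sum(z, 1);
  return z;
}

struct ForwardState {
  LstmCache c1f, c1b, c2;
  cube H1;        // n x 2H1 x T, concatenated directions
  cube Ua;        // n x A x T, tanh scores cache
  mat E, Alpha;   // n x T
  mat Ctx, D1, D1d, D2, logits, P;
};

static void forward_all(const Params& q, const cube& X, const mat* mask,
                        ForwardState& st) {
  const uword n = X.n_rows, T = X.n_slices;
  const uword H1 = q.Uf.n_rows, H2 = q.U2.n_rows, A = q.Wa.n_cols;
  lstm_forward(X, q.Wf, q.Uf, q.bf, false, st.c1f);
  lstm_forward(X, q.Wb, q.Ub, q.bb, true, st.c1b);
  st.H1.set_size(n, 2 * H1, T);
  for (uword t = 0; t < T; ++t) {
    st.H1.slice(t).cols(0, H1 - 1) = st.c1f.h.slice(t);
    st.H1.slice(t).cols(H1, 2 * H1 - 1) = st.c1b.h.slice(t);
  }
  lstm_forward(st.H1, q.W2, q.U2, q.b2, false, st.c2);
  // additive attention over the second LSTM's sequence output
  st.Ua.set_size(n, A, T);
  st.E.set_size(n, T);
  for (uword t = 0; t < T; ++t) {
    mat u = st.c2.h.slice(t) * q.Wa;
    u.each_row() += q.ba.t();
    u = tanh(u);
    st.Ua.slice(t) = u;
    st.E.col(t) = u * q.va;
  }
  st.Alpha = row_softmax(st.E);
  st.Ctx.zeros(n, H2);
  for (uword t = 0; t < T; ++t) {
    st.Ctx += st.c2.h.slice(t).each_col() % st.Alpha.col(t);
  }
  mat d1 = st.Ctx * q.Wd1; d1.each_row() += q.bd1;
  d1.elem(find(d1 < 0)).zeros();
  st.D1 = d1;
  st.D1d = mask ? mat(st.D1 % (*mask)) : st.D1;
  mat d2 = st.D1d * q.Wd2; d2.each_row() += q.bd2;
  d2.elem(find(d2 < 0)).zeros();
  st.D2 = d2;
  st.logits = st.D2 * q.Wo;
  st.logits.each_row() += q.bo;
  st.P = row_softmax(st.logits);
}

// [[Rcpp::export]]
Rcpp::List nn_predict_cpp(Rcpp::List params, arma::cube X,
                          arma::mat dropout_mask, bool use_dropout) {
  Params q = unpack(params);
  ForwardState st;
  forward_all(q, X, use_dropout ? &dropout_mask : nullptr, st);
  return Rcpp::List::create(Rcpp::Named("probs") = st.P,
                            Rcpp::Named("attention") = st.Alpha);
}

// Cross-entropy loss and gradients for one (mini-)batch.
// y: 0-based class labels. dropout_mask: n x dense1 matrix of 0 or
// 1/(1-rate) values (inverted dropout), ignored unless use_dropout.
// [[Rcpp::export]]
Rcpp::List nn_loss_grad(Rcpp::List params, arma::cube X, arma::ivec y,
                        arma::mat dropout_mask, bool use_dropout) {
  Params q = unpack(params);
  const uword n = X.n_rows, T = X.n_slices;
  const uword H1 = q.Uf.n_rows, H2 = q.U2.n_rows;
  const uword K = q.Wo.n_cols;
  ForwardState st;
  forward_all(q, X, use_dropout ? &dropout_mask : nullptr, st);

  double loss = 0.0;
  mat dlogits = st.P;
  for (uword i = 0; i < n; ++i) {
    const uword k = static_cast<uword>(y(i));
    if (k >= K) Rcpp::stop("nn_loss_grad: label out of range");
    loss -= std::log(std::max(st.P(i, k), 1e-300));
    dlogits(i, k) -= 1.0;
  }
  loss /= n;
  dlogits /= n;

  // dense stack
  mat dWo = st.D2.t() * dlogits;
  rowvec dbo = sum(dlogits, 0);
  mat dD2 = dlogits * q.Wo.t();
  dD2 %= conv_to<mat>::from(st.D2 > 0);
  mat dWd2 = st.D1d.t() * dD2;
  rowvec dbd2 = sum(dD2, 0);
  mat dD1d = dD2 * q.Wd2.t();
  mat dD1 = use_dropout ? mat(dD1d % dropout_mask) : dD1d;
  dD1 %= conv_to<mat>::from(st.D1 > 0);
  mat dWd1 = st.Ctx.t() * dD1;
  rowvec dbd1 = sum(dD1, 0);
  mat dCtx = dD1 * q.Wd1.t();

  // attention backward
  cube dH2(n, H2, T, fill::zeros);
  mat dAlpha(n, T);
  for (uword t = 0; t < T; ++t) {
    dAlpha.col(t) = sum(dCtx % st.c2.h.slice(t), 1);
    dH2.slice(t) += dCtx.each_col() % st.Alpha.col(t);
  }
  vec s = sum(st.Alpha % dAlpha, 1);
  mat dE = st.Alpha % (dAlpha.each_col() - s);
  mat dWa(size(q.Wa), fill::zeros);
  vec dba(q.ba.n_elem, fill::zeros), dva(q.va.n_elem, fill::zeros);
  for (uword t = 0; t < T; ++t) {
    dva += st.Ua.slice(t).t() * dE.col(t);
    mat dU_t = dE.col(t) * q.va.t();                  // n x A
    mat dpre = dU_t % (1.0 - st.Ua.slice(t) % st.Ua.slice(t));
    dWa += st.c2.h.slice(t).t() * dpre;
    dba += sum(dpre, 0).t();
    dH2.slice(t) += dpre * q.Wa.t();
  }

  // second LSTM backward -> gradient wrt H1
  mat dW2, dU2; rowvec db2;
  cube dH1(n, 2 * H1, T, fill::zeros);
  lstm_backward(st.H1, q.W2, q.U2, st.c2, dH2, false, dW2, dU2, db2, &dH1);

  // split into the two first-layer directions
  cube dHf(n, H1, T), dHb(n, H1, T);
  for (uword t = 0; t < T; ++t) {
    dHf.slice(t) = dH1.slice(t).cols(0, H1 - 1);
    dHb.slice(t) = dH1.slice(t).cols(H1, 2 * H1 - 1);
  }
  mat dWf, dUf, dWb, dUb; rowvec dbf, dbb;
  lstm_backward(X, q.Wf, q.Uf, st.c1f, dHf, false, dWf, dUf, dbf, nullptr);
  lstm_backward(X, q.Wb, q.Ub, st.c1b, dHb, true, dWb, dUb, dbb, nullptr);

  Rcpp::List grads = Rcpp::List::create(
      Rcpp::Named("Wf") = dWf, Rcpp::Named("Uf") = dUf,
      Rcpp::Named("bf") = dbf, Rcpp::Named("Wb") = dWb,
      Rcpp::Named("Ub") = dUb, Rcpp::Named("bb") = dbb,
      Rcpp::Named("W2") = dW2, Rcpp::Named("U2") = dU2,
      Rcpp::Named("b2") = db2, Rcpp::Named("Wa") = dWa,
      Rcpp::Named("ba") = dba, Rcpp::Named("va") = dva,
      Rcpp::Named("Wd1") = dWd1, Rcpp::Named("bd1") = dbd1,
      Rcpp::Named("Wd2") = dWd2, Rcpp::Named("bd2") = dbd2,
      Rcpp::Named("Wo") = dWo, Rcpp::Named("bo") = dbo);
  return Rcpp::List::create(Rcpp::Named("loss") = loss,
                            Rcpp::Named("grads") = grads);
}

// Stand-alone additive attention over one sequence (T x d), used as the
// compiled counterpart of the R-level attention_pool for cross-checking.
// [[Rcpp::export]]
Rcpp::List cpp_attention(arma::mat H, arma::mat Wa, arma::vec ba,
                         arma::vec va) {
  mat u = H * Wa;
  u.each_row() += ba.t();
  u = tanh(u);
  vec e = u * va;
  e -= e.max();
  vec w = exp(e);
  w /= accu(w);
  vec ctx = H.t() * w;
  return Rcpp::List::create(Rcpp::Named("context") = ctx,
                            Rcpp::Named("weights") = w);
}
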