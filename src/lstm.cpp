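// Two-layer unidirectional LSTM sequence-to-sequence regressor.
//
// Layer stack: input -> LSTM(H) -> dropout -> LSTM(H) -> dropout ->
// dense(1) -> per-timestep MSE.  Gate rows in the 4H weight blocks are
// ordered [input; forget; cell; output].
//
// Variable-length minibatches are handled by per-sequence gradient
// accumulation with the loss normalised by the total timestep count of the
// batch; this is numerically identical to padding to the batch maximum and
// masking padded steps out of the mean.
//
// All randomness (shuffling, dropout masks) draws from R's RNG so that
// set.seed() on the R side makes training bit-reproducible.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;

namespace {

inline vec sigm(const vec& x) { return 1.0 / (1.0 + exp(-x)); }

struct Weights {
  mat W1, U1, b1;   // 4H x F, 4H x H, 4H x 1
  mat W2, U2, b2;   // 4H x H, 4H x H, 4H x 1
  mat Wd, bd;       // 1 x H, 1 x 1
  int H, F;
};

Weights unpack(const Rcpp::List& w) {
  Weights ws;
  ws.W1 = Rcpp::as<mat>(w["W1"]); ws.U1 = Rcpp::as<mat>(w["U1"]);
  ws.b1 = Rcpp::as<mat>(w["b1"]);
  ws.W2 = Rcpp::as<mat>(w["W2"]); ws.U2 = Rcpp::as<mat>(w["U2"]);
  ws.b2 = Rcpp::as<mat>(w["b2"]);
  ws.Wd = Rcpp::as<mat>(w["Wd"]); ws.bd = Rcpp::as<mat>(w["bd"]);
  ws.H = ws.U1.n_cols; ws.F = ws.W1.n_cols;
  return ws;
}

Rcpp::List pack(const Weights& ws) {
  return Rcpp::List::create(
      Rcpp::Named("W1") = ws.W1, Rcpp::Named("U1") = ws.U1,
      Rcpp::Named("b1") = ws.b1,
      Rcpp::Named("W2") = ws.W2, Rcpp::Named("U2") = ws.U2,
      Rcpp::Named("b2") = ws.b2,
      Rcpp::Named("Wd") = ws.Wd, Rcpp::Named("bd") = ws.bd);
}

// Per-sequence forward caches (one LSTM layer).
struct LayerCache {
  mat G;    // 4H x T activated gates [i; f; g; o]
  mat C;    // H x T cell states
  mat Tc;   // H x T tanh(cell)
  mat Hs;   // H x T hidden outputs (before dropout)
};

void lstm_layer_forward(const mat& X /* in x T */, const mat& W,
                        const mat& U, const mat& b, LayerCache& cc) {
  const int T = X.n_cols, H = U.n_cols;
  cc.G.set_size(4 * H, T); cc.C.set_size(H, T);
  cc.Tc.set_size(H, T); cc.Hs.set_size(H, T);
  // Input contribution for all timesteps in one GEMM; only the recurrent
  // term stays inside the loop.
  mat A = W * X;
  A.each_col() += b.col(0);
  vec h(H, fill::zeros), c(H, fill::zeros), a(4 * H);
  for (int t = 0; t < T; ++t) {
    a = A.col(t) + U * h;
    vec gi = sigm(a.subvec(0, H - 1));
    vec gf = sigm(a.subvec(H, 2 * H - 1));
    vec gg = tanh(a.subvec(2 * H, 3 * H - 1));
    vec go = sigm(a.subvec(3 * H, 4 * H - 1));
    c = gf % c + gi % gg;
    vec tc = tanh(c);
    h = go % tc;
    cc.G.col(t).subvec(0, H - 1) = gi;
    cc.G.col(t).subvec(H, 2 * H - 1) = gf;
    cc.G.col(t).subvec(2 * H, 3 * H - 1) = gg;
    cc.G.col(t).subvec(3 * H, 4 * H - 1) = go;
    cc.C.col(t) = c; cc.Tc.col(t) = tc; cc.Hs.col(t) = h;
  }
}

// Backward through one LSTM layer; returns gradient w.r.t. the layer input.
// dH: H x T gradient arriving at the layer's hidden outputs.  Only the
// hidden-state recursion runs per timestep; weight gradients are batched
// GEMMs over the stored pre-activation gradients.
mat lstm_layer_backward(const mat& X, const mat& W, const mat& U,
                        const LayerCache& cc, const mat& dH,
                        mat& dW, mat& dU, mat& db) {
  const int T = X.n_cols, H = U.n_cols;
  mat dA(4 * H, T);
  vec dh_next(H, fill::zeros), dc_next(H, fill::zeros);
  for (int t = T - 1; t >= 0; --t) {
    const double* g = cc.G.colptr(t);
    vec gi(const_cast<double*>(g), H, false, true);
    vec gf(const_cast<double*>(g + H), H, false, true);
    vec gg(const_cast<double*>(g + 2 * H), H, false, true);
    vec go(const_cast<double*>(g + 3 * H), H, false, true);
    vec tc = cc.Tc.col(t);
    vec dh = dH.col(t) + dh_next;
    vec dc = dc_next + dh % go % (1.0 - tc % tc);
    vec c_prev = (t > 0) ? vec(cc.C.col(t - 1)) : vec(H, fill::zeros);
    dA.col(t).subvec(0, H - 1) = dc % gg % gi % (1.0 - gi);
    dA.col(t).subvec(H, 2 * H - 1) = dc % c_prev % gf % (1.0 - gf);
    dA.col(t).subvec(2 * H, 3 * H - 1) = dc % gi % (1.0 - gg % gg);
    dA.col(t).subvec(3 * H, 4 * H - 1) = dh % tc % go % (1.0 - go);
    dh_next = U.t() * dA.col(t);
    dc_next = dc % gf;
  }
  dW += dA * X.t();
  if (T > 1)
    dU += dA.cols(1, T - 1) * cc.Hs.cols(0, T - 2).t();
  db += sum(dA, 1);
  return W.t() * dA;
}

// Full forward for one sequence.  X: F x T.  If training, dropout masks
// (inverted scaling) are sampled from R's RNG and applied after each LSTM.
vec net_forward(const mat& X, const Weights& ws, double dropout,
                bool training, LayerCache& c1, LayerCache& c2,
                mat& H1d, mat& M1, mat& M2) {
  const int T = X.n_cols, H = ws.H;
  lstm_layer_forward(X, ws.W1, ws.U1, ws.b1, c1);
  if (training && dropout > 0) {
    M1.set_size(H, T);
    for (uword j = 0; j < M1.n_elem; ++j)
      M1(j) = (R::unif_rand() < dropout) ? 0.0 : 1.0 / (1.0 - dropout);
    H1d = c1.Hs % M1;
  } else {
    H1d = c1.Hs;
  }
  lstm_layer_forward(H1d, ws.W2, ws.U2, ws.b2, c2);
  mat H2d;
  if (training && dropout > 0) {
    M2.set_size(H, T);
    for (uword j = 0; j < M2.n_elem; ++j)
      M2(j) = (R::unif_rand() < dropout) ? 0.0 : 1.0 / (1.0 - dropout);
    H2d = c2.Hs % M2;
  } else {
    H2d = c2.Hs;
  }
  vec yhat = (ws.Wd * H2d).t() + ws.bd(0, 0);
  return yhat;
}

struct Grads {
  mat W1, U1, b1, W2, U2, b2, Wd, bd;
  explicit Grads(const Weights& ws) {
    W1.zeros(size(ws.W1)); U1.zeros(size(ws.U1)); b1.zeros(size(ws.b1));
    W2.zeros(size(ws.W2)); U2.zeros(size(ws.U2)); b2.zeros(size(ws.b2));
    Wd.zeros(size(ws.Wd)); bd.zeros(size(ws.bd));
  }
  std::vector<mat*> all() { return {&W1, &U1, &b1, &W2, &U2, &b2, &Wd, &bd}; }
};

}  // namespace

// [[Rcpp::export]]
arma::vec lstm_forward_cpp(const arma::mat& X, const Rcpp::List& weights) {
  // X: T x F (rows = timesteps); inference pass, no dropout.
  Weights ws = unpack(weights);
  LayerCache c1, c2;
  mat H1d, M1, M2;
  return net_forward(X.t(), ws, 0.0, false, c1, c2, H1d, M1, M2);
}

// [[Rcpp::export]]
Rcpp::List lstm_train_cpp(const Rcpp::List& xs, const Rcpp::List& ys,
                          const Rcpp::List& weights, int epochs,
                          double lr0, double decay_factor, int decay_every,
                          int batch_size, double dropout, double clipnorm,
                          const Rcpp::List& val_xs, const Rcpp::List& val_ys) {
  Rcpp::RNGScope rngscope;
  Weights ws = unpack(weights);
  const int N = xs.size();
  std::vector<mat> X(N);      // F x T each
  std::vector<vec> Y(N);
  for (int i = 0; i < N; ++i) {
    X[i] = Rcpp::as<mat>(xs[i]).t();
    Y[i] = Rcpp::as<vec>(ys[i]);
  }
  const int Nv = val_xs.size();
  std::vector<mat> Xv(Nv);
  std::vector<vec> Yv(Nv);
  for (int i = 0; i < Nv; ++i) {
    Xv[i] = Rcpp::as<mat>(val_xs[i]).t();
    Yv[i] = Rcpp::as<vec>(val_ys[i]);
  }

  // Adam state
  Grads m(ws), v(ws);
  std::vector<mat*> wsl = {&ws.W1, &ws.U1, &ws.b1, &ws.W2, &ws.U2,
                           &ws.b2, &ws.Wd, &ws.bd};
  const double beta1 = 0.9, beta2 = 0.999, adam_eps = 1e-8;
  long adam_t = 0;

  vec train_rmse(epochs, fill::value(datum::nan));
  vec val_rmse(epochs, fill::value(datum::nan));
  int diverged_epoch = 0;
  std::vector<int> order(N);
  for (int i = 0; i < N; ++i) order[i] = i;

  for (int ep = 0; ep < epochs; ++ep) {
    const double lr =
        lr0 * std::pow(decay_factor, std::floor(ep / (double)decay_every));
    // Fisher-Yates shuffle from R's RNG (shuffling every epoch).
    for (int i = N - 1; i > 0; --i) {
      int j = (int)std::floor(R::unif_rand() * (i + 1));
      if (j > i) j = i;
      std::swap(order[i], order[j]);
    }
    double sse = 0.0; long nst = 0;
    for (int start = 0; start < N; start += batch_size) {
      const int stop = std::min(start + batch_size, N);
      long ntot = 0;
      for (int k = start; k < stop; ++k) ntot += Y[order[k]].n_elem;
      Grads g(ws);
      for (int k = start; k < stop; ++k) {
        const mat& Xi = X[order[k]];
        const vec& Yi = Y[order[k]];
        LayerCache c1, c2;
        mat H1d, M1, M2;
        vec yhat = net_forward(Xi, ws, dropout, true, c1, c2, H1d, M1, M2);
        vec resid = yhat - Yi;
        sse += dot(resid, resid); nst += Yi.n_elem;
        vec dy = 2.0 * resid / (double)ntot;
        // dense layer
        mat H2d = (dropout > 0) ? mat(c2.Hs % M2) : c2.Hs;
        g.Wd += dy.t() * H2d.t();
        g.bd(0, 0) += accu(dy);
        mat dH2 = ws.Wd.t() * dy.t();             // H x T
        if (dropout > 0) dH2 %= M2;
        mat dH1d = lstm_layer_backward(H1d, ws.W2, ws.U2, c2, dH2,
                                       g.W2, g.U2, g.b2);
        if (dropout > 0) dH1d %= M1;
        lstm_layer_backward(Xi, ws.W1, ws.U1, c1, dH1d, g.W1, g.U1, g.b1);
      }
      if (clipnorm > 0) {
        double nrm2 = 0;
        for (mat* gm : g.all()) nrm2 += accu(square(*gm));
        double nrm = std::sqrt(nrm2);
        if (nrm > clipnorm)
          for (mat* gm : g.all()) *gm *= clipnorm / nrm;
      }
      ++adam_t;
      const double bc1 = 1.0 - std::pow(beta1, (double)adam_t);
      const double bc2 = 1.0 - std::pow(beta2, (double)adam_t);
      std::vector<mat*> gl = g.all(), ml = m.all(), vl = v.all();
      for (size_t p = 0; p < wsl.size(); ++p) {
        *ml[p] = beta1 * (*ml[p]) + (1.0 - beta1) * (*gl[p]);
        *vl[p] = beta2 * (*vl[p]) + (1.0 - beta2) * square(*gl[p]);
        *wsl[p] -= lr * ((*ml[p]) / bc1) / (sqrt((*vl[p]) / bc2) + adam_eps);
      }
    }
    train_rmse(ep) = std::sqrt(sse / (double)nst);
    if (!std::isfinite(train_rmse(ep))) { diverged_epoch = ep + 1; break; }
    if (Nv > 0) {
      double vsse = 0.0; long vn = 0;
      LayerCache c1, c2; mat H1d, M1, M2;
      for (int i = 0; i < Nv; ++i) {
        vec yhat = net_forward(Xv[i], ws, 0.0, false, c1, c2, H1d, M1, M2);
        vec r = yhat - Yv[i];
        vsse += dot(r, r); vn += Yv[i].n_elem;
      }
      val_rmse(ep) = std::sqrt(vsse / (double)vn);
    }
    Rcpp::checkUserInterrupt();
  }
  return Rcpp::List::create(
      Rcpp::Named("weights") = pack(ws),
      Rcpp::Named("train_rmse") = train_rmse,
      Rcpp::Named("val_rmse") = val_rmse,
      Rcpp::Named("diverged_epoch") = diverged_epoch);
}
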