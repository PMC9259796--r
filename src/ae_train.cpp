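// Mini-batch Adam training loop of the penalized autoencoder.
// Layout: input -> tanh(500) -> tanh(h) -> tanh(500) -> sigmoid(input).
// Objective: mean per-sample cross-entropy + l1*|W|_1 + l2*|W|_F^2
// + aa * batch-mean squared activations (all four layers).
// All randomness (shuffling, dropout masks) comes from R's RNG so training
// is deterministic under set.seed().

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace arma;

static const double AE_EPS = 1e-7;

// Permutation of 0..n-1 obtained by sorting R-uniform keys.
static uvec r_permutation(int n) {
  vec keys(n);
  for (int i = 0; i < n; ++i) keys[i] = R::unif_rand();
  return sort_index(keys);
}

static fmat dropout_mask(int nr, int nc, double p) {
  fmat m(nr, nc);
  float scale = 1.0f / (float)(1.0 - p);
  for (uword j = 0; j < m.n_cols; ++j)
    for (uword i = 0; i < m.n_rows; ++i)
      m(i, j) = (R::unif_rand() >= p) ? scale : 0.0f;
  return m;
}

// The training loop runs in single precision: representation learning is
// insensitive to float32 rounding and the smaller operands roughly double
// BLAS and memory throughput. Weights are returned as doubles.
// [[Rcpp::export]]
Rcpp::List cpp_train_ae(Rcpp::List W_in, Rcpp::List b_in,
                        const arma::mat& V_in, int epochs, double dropout,
                        double l1_in, double l2_in, double aa_in,
                        double lr_in, int batch_size) {
  Rcpp::RNGScope rng;
  fmat V = conv_to<fmat>::from(V_in);
  std::vector<fmat> W(4);
  std::vector<frowvec> b(4);
  for (int i = 0; i < 4; ++i) {
    W[i] = conv_to<fmat>::from(Rcpp::as<mat>(W_in[i]));
    b[i] = conv_to<frowvec>::from(
      Rcpp::as<rowvec>(Rcpp::as<Rcpp::NumericVector>(b_in[i])));
  }
  std::vector<fmat> mW(4), vW(4);
  std::vector<frowvec> mB(4), vB(4);
  for (int i = 0; i < 4; ++i) {
    mW[i] = zeros<fmat>(size(W[i])); vW[i] = zeros<fmat>(size(W[i]));
    mB[i] = zeros<frowvec>(b[i].n_elem); vB[i] = zeros<frowvec>(b[i].n_elem);
  }
  const float b1 = 0.9f, b2 = 0.999f, eps = 1e-8f;
  const float l1 = l1_in, l2 = l2_in, aa = aa_in, lr = lr_in;
  const float feps = (float)AE_EPS;
  const int n = V.n_rows;
  long t_step = 0;
  std::vector<double> history;

  for (int ep = 0; ep < epochs; ++ep) {
    uvec ord = r_permutation(n);
    double ep_loss = 0.0;
    for (int s = 0; s < n; s += batch_size) {
      int e = std::min(s + batch_size, n) - 1;
      fmat B = V.rows(ord.subvec(s, e));
      int nb = B.n_rows;

      // forward with inverted dropout on the hidden layers
      std::vector<fmat> H(3), A(3), M(3);
      fmat Z = B * W[0]; Z.each_row() += b[0];
      H[0] = tanh(Z);
      std::vector<int> hdim = {(int)W[0].n_cols, (int)W[1].n_cols,
                               (int)W[2].n_cols};
      for (int i = 0; i < 3; ++i) {
        if (i > 0) {
          Z = A[i - 1] * W[i]; Z.each_row() += b[i];
          H[i] = tanh(Z);
        }
        if (dropout > 0) {
          M[i] = dropout_mask(nb, hdim[i], dropout);
          A[i] = H[i] % M[i];
        } else {
          A[i] = H[i];
        }
      }
      fmat Z4 = A[2] * W[3]; Z4.each_row() += b[3];
      fmat Xhat = 1.0f / (1.0f + exp(-Z4));

      // objective (for history / divergence check)
      fmat xh = clamp(Xhat, feps, 1.0f - feps);
      double ll = -accu(B % log(xh) + (1.0f - B) % log(1.0f - xh)) / nb;
      double wpen = 0.0;
      for (int i = 0; i < 4; ++i)
        wpen += l1 * accu(abs(W[i])) + l2 * accu(W[i] % W[i]);
      double act = (accu(A[0] % A[0]) + accu(A[1] % A[1]) +
                    accu(A[2] % A[2]) + accu(Xhat % Xhat)) / nb;
      double loss = ll + wpen + aa * act;
      if (!std::isfinite(loss))
        Rcpp::stop("training diverged (non-finite loss) at epoch %d", ep + 1);
      ep_loss += loss * nb;

      // backward
      fmat dZ4 = (Xhat - B) / nb +
        (2.0f * aa / nb) * (Xhat % Xhat % (1.0f - Xhat));
      std::vector<fmat> dW(4);
      std::vector<frowvec> db(4);
      dW[3] = A[2].t() * dZ4;
      db[3] = sum(dZ4, 0);
      fmat dA = dZ4 * W[3].t();
      for (int i = 2; i >= 0; --i) {
        dA += (2.0f * aa / nb) * A[i];
        if (dropout > 0) dA %= M[i];
        fmat dZi = dA % (1.0f - H[i] % H[i]);
        const fmat& Ain = (i == 0) ? B : A[i - 1];
        dW[i] = Ain.t() * dZi;
        db[i] = sum(dZi, 0);
        if (i > 0) dA = dZi * W[i].t();
      }

      // fused Adam step; weight penalties enter through the gradient
      ++t_step;
      float c1 = 1.0f - std::pow(b1, (float)t_step);
      float c2 = 1.0f - std::pow(b2, (float)t_step);
      for (int i = 0; i < 4; ++i) {
        float *w = W[i].memptr(), *g = dW[i].memptr();
        float *mw = mW[i].memptr(), *vw = vW[i].memptr();
        uword ne = W[i].n_elem;
        for (uword j = 0; j < ne; ++j) {
          float gj = g[j] + l1 * ((w[j] > 0) - (w[j] < 0)) + 2.0f * l2 * w[j];
          mw[j] = b1 * mw[j] + (1.0f - b1) * gj;
          vw[j] = b2 * vw[j] + (1.0f - b2) * gj * gj;
          w[j] -= lr * (mw[j] / c1) / (std::sqrt(vw[j] / c2) + eps);
        }
        float *bb = b[i].memptr(), *gb = db[i].memptr();
        float *mb = mB[i].memptr(), *vb = vB[i].memptr();
        for (uword j = 0; j < b[i].n_elem; ++j) {
          mb[j] = b1 * mb[j] + (1.0f - b1) * gb[j];
          vb[j] = b2 * vb[j] + (1.0f - b2) * gb[j] * gb[j];
          bb[j] -= lr * (mb[j] / c1) / (std::sqrt(vb[j] / c2) + eps);
        }
      }
    }
    history.push_back(ep_loss / n);
  }

  Rcpp::List W_out(4), b_out(4);
  for (int i = 0; i < 4; ++i) {
    W_out[i] = Rcpp::wrap(conv_to<mat>::from(W[i]));
    rowvec bd = conv_to<rowvec>::from(b[i]);
    b_out[i] = Rcpp::NumericVector(bd.begin(), bd.end());
  }
  return Rcpp::List::create(Rcpp::Named("W") = W_out,
                            Rcpp::Named("b") = b_out,
                            Rcpp::Named("history") = history);
}

// Analytic gradient of the full-data objective without dropout; used by the
// test suite to cross-check backpropagation against finite differences.
// [[Rcpp::export]]
Rcpp::List cpp_ae_grad(Rcpp::List W_in, Rcpp::List b_in, const arma::mat& V,
                       double l1, double l2, double aa) {
  std::vector<mat> W(4);
  std::vector<rowvec> b(4);
  for (int i = 0; i < 4; ++i) {
    W[i] = Rcpp::as<mat>(W_in[i]);
    b[i] = Rcpp::as<rowvec>(Rcpp::as<Rcpp::NumericVector>(b_in[i]));
  }
  int nb = V.n_rows;
  std::vector<mat> A(3);
  mat Z = V * W[0]; Z.each_row() += b[0];
  A[0] = tanh(Z);
  for (int i = 1; i < 3; ++i) {
    Z = A[i - 1] * W[i]; Z.each_row() += b[i];
    A[i] = tanh(Z);
  }
  mat Z4 = A[2] * W[3]; Z4.each_row() += b[3];
  mat Xhat = 1.0 / (1.0 + exp(-Z4));

  mat dZ4 = (Xhat - V) / nb + (2.0 * aa / nb) * (Xhat % Xhat % (1.0 - Xhat));
  std::vector<mat> dW(4);
  std::vector<rowvec> db(4);
  dW[3] = A[2].t() * dZ4 + l1 * sign(W[3]) + 2.0 * l2 * W[3];
  db[3] = sum(dZ4, 0);
  mat dA = dZ4 * W[3].t();
  for (int i = 2; i >= 0; --i) {
    dA += (2.0 * aa / nb) * A[i];
    mat dZi = dA % (1.0 - A[i] % A[i]);
    const mat& Ain = (i == 0) ? V : A[i - 1];
    dW[i] = Ain.t() * dZi + l1 * sign(W[i]) + 2.0 * l2 * W[i];
    db[i] = sum(dZi, 0);
    if (i > 0) dA = dZi * W[i].t();
  }
  Rcpp::List dW_out(4), db_out(4);
  for (int i = 0; i < 4; ++i) {
    dW_out[i] = dW[i];
    db_out[i] = Rcpp::NumericVector(db[i].begin(), db[i].end());
  }
  return Rcpp::List::create(Rcpp::Named("dW") = dW_out,
                            Rcpp::Named("db") = db_out);
}
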