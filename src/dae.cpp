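// [[Rcpp::depends(RcppArmadillo)]]
#include <RcppArmadillo.h>
using namespace Rcpp;

// Denoising-autoencoder training loop: a 3-layer fully connected network
// (p -> hidden -> p) with ReLU on hidden AND output layers, mean-squared-error
// loss against the clean profile, Adam minibatch updates. No RNG here:
// initial weights and the per-epoch row permutations are supplied by the
// caller, so training is bit-reproducible. The loop reuses buffers: profile
// matrices are small and the cost is otherwise dominated by allocation.

namespace {
inline void relu_inplace(arma::mat& z) {
  double* ptr = z.memptr();
  const arma::uword n = z.n_elem;
  for (arma::uword i = 0; i < n; ++i)
    if (ptr[i] < 0.0) ptr[i] = 0.0;
}

// zero entries of d where z <= 0 (ReLU backward)
inline void mask_inplace(arma::mat& d, const arma::mat& z) {
  double* dp = d.memptr();
  const double* zp = z.memptr();
  const arma::uword n = d.n_elem;
  for (arma::uword i = 0; i < n; ++i)
    if (zp[i] <= 0.0) dp[i] = 0.0;
}

double forward_mse(const arma::mat& X, const arma::mat& T, const arma::mat& W1,
                   const arma::rowvec& b1, const arma::mat& W2,
                   const arma::rowvec& b2) {
  arma::mat H = X * W1;
  H.each_row() += b1;
  relu_inplace(H);
  arma::mat Y = H * W2;
  Y.each_row() += b2;
  relu_inplace(Y);
  Y -= T;
  return arma::accu(Y % Y) / static_cast<double>(Y.n_elem);
}

struct Adam {
  arma::mat m, v;
  explicit Adam(arma::uword r, arma::uword c)
      : m(r, c, arma::fill::zeros), v(r, c, arma::fill::zeros) {}
  void step(arma::mat& w, const arma::mat& grad, double lr, double t) {
    const double b1 = 0.9, b2 = 0.999, eps = 1e-8;
    m *= b1;
    m += (1.0 - b1) * grad;
    v *= b2;
    v += (1.0 - b2) * (grad % grad);
    const double c1 = 1.0 / (1.0 - std::pow(b1, t));
    const double c2 = 1.0 / (1.0 - std::pow(b2, t));
    w -= lr * (c1 * m) / (arma::sqrt(c2 * v) + eps);
  }
};
}  // namespace

//' @noRd
// [[Rcpp::export(name = ".dae_train")]]
List dae_train(const arma::mat& Xnoisy, const arma::mat& Xclean,
               arma::mat W1, arma::rowvec b1v, arma::mat W2, arma::rowvec b2v,
               const arma::umat& perm,  // n_obs x n_epochs, 0-based row order
               int batch_size, double lr, const arma::mat& Xval,
               const arma::mat& Tval) {
  const arma::uword n = Xnoisy.n_rows, p = Xnoisy.n_cols;
  if (Xclean.n_rows != n || Xclean.n_cols != p) stop("noisy/clean shape mismatch");
  if (perm.n_rows != n) stop("perm rows must match data rows");
  const int n_epochs = static_cast<int>(perm.n_cols);
  const arma::uword bs = static_cast<arma::uword>(batch_size);

  arma::rowvec b1(b1v), b2(b2v);
  Adam aW1(W1.n_rows, W1.n_cols), ab1(1, b1.n_elem);
  Adam aW2(W2.n_rows, W2.n_cols), ab2(1, b2.n_elem);
  arma::mat b1m(b1), b2m(b2);  // 1 x k views for Adam

  arma::vec train_loss(n_epochs, arma::fill::zeros);
  arma::vec val_loss(n_epochs, arma::fill::zeros);
  double t = 0.0;

  arma::mat Xs, Ts, Z1, H, Z2, D, dZ1, gW1, gW2;
  arma::rowvec gb1, gb2;

  for (int e = 0; e < n_epochs; ++e) {
    // gather the epoch's shuffled copy once; batches are contiguous views
    const arma::uvec rows = perm.col(e);
    Xs = Xnoisy.rows(rows);
    Ts = Xclean.rows(rows);

    double acc_loss = 0.0;
    arma::uword n_batches = 0;
    for (arma::uword start = 0; start < n; start += bs) {
      const arma::uword stop_ = std::min(start + bs, n) - 1;
      const auto Xb = Xs.rows(start, stop_);
      const auto Tb = Ts.rows(start, stop_);
      const double B = static_cast<double>(stop_ - start + 1);

      Z1 = Xb * W1;
      Z1.each_row() += b1;
      H = Z1;
      relu_inplace(H);
      Z2 = H * W2;
      Z2.each_row() += b2;
      D = Z2;
      relu_inplace(D);  // D now holds Y
      D -= Tb;          // Y - T

      acc_loss += arma::accu(D % D) / (B * p);
      ++n_batches;

      D *= 2.0 / (B * p);
      mask_inplace(D, Z2);  // D now holds dZ2
      gW2 = H.t() * D;
      gb2 = arma::sum(D, 0);
      dZ1 = D * W2.t();
      mask_inplace(dZ1, Z1);
      gW1 = Xb.t() * dZ1;
      gb1 = arma::sum(dZ1, 0);

      t += 1.0;
      aW1.step(W1, gW1, lr, t);
      ab1.step(b1m, gb1, lr, t);
      aW2.step(W2, gW2, lr, t);
      ab2.step(b2m, gb2, lr, t);
      b1 = b1m.row(0);
      b2 = b2m.row(0);
    }
    train_loss(e) = acc_loss / std::max<arma::uword>(n_batches, 1);
    if (Xval.n_rows > 0)
      val_loss(e) = forward_mse(Xval, Tval, W1, b1, W2, b2);
    else
      val_loss(e) = NA_REAL;
  }

  return List::create(_["W1"] = W1, _["b1"] = b1, _["W2"] = W2, _["b2"] = b2,
                      _["train_loss"] = train_loss, _["val_loss"] = val_loss);
}

//' @noRd
// [[Rcpp::export(name = ".dae_forward")]]
arma::mat dae_forward(const arma::mat& X, const arma::mat& W1,
                      const arma::rowvec& b1, const arma::mat& W2,
                      const arma::rowvec& b2) {
  arma::mat H = X * W1;
  H.each_row() += b1;
  relu_inplace(H);
  arma::mat Y = H * W2;
  Y.each_row() += b2;
  relu_inplace(Y);
  return Y;
}
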