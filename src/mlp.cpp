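#include <RcppArmadillo.h>
#include <random>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;

// Two-hidden-layer ReLU regressor trained with Adam on half mean-squared
// error, templated on element type: float mirrors GPU-framework training
// defaults (used for the Fourier-feature network), double mirrors the
// reference CPU MLP regressor. batch_size <= 0 means full-batch gradient
// descent. Early stopping follows the usual "no training-loss improvement
// greater than tol for n_iter_no_change consecutive epochs" rule;
// n_iter_no_change <= 0 disables it.

template <typename T>
struct Adam {
  Mat<T> m, v;
  explicit Adam(const Mat<T>& p)
      : m(p.n_rows, p.n_cols, fill::zeros), v(p.n_rows, p.n_cols, fill::zeros) {}
  void step(Mat<T>& p, const Mat<T>& g, double lr, long t) {
    const T b1 = (T)0.9, b2 = (T)0.999, eps = (T)1e-8;
    m = b1 * m + ((T)1 - b1) * g;
    v = b2 * v + ((T)1 - b2) * square(g);
    T lr_t = (T)(lr * std::sqrt(1.0 - std::pow((double)b2, (double)t)) /
                 (1.0 - std::pow((double)b1, (double)t)));
    p -= lr_t * m / (sqrt(v) + eps);
  }
};

template <typename T>
static Rcpp::List train_net(const Mat<T>& X, const Mat<T>& Y,
                            Mat<T> W1, Mat<T> b1, Mat<T> W2, Mat<T> b2,
                            Mat<T> W3, Mat<T> b3,
                            double lr, int max_epochs, int batch_size,
                            double l2, double tol, int n_iter_no_change,
                            int shuffle_seed) {
  const uword N = X.n_rows;
  const bool full_batch = batch_size <= 0 || (uword)batch_size >= N;
  const uword bs = full_batch ? N : (uword)batch_size;

  Adam<T> sW1(W1), sb1(b1), sW2(W2), sb2(b2), sW3(W3), sb3(b3);

  std::mt19937 rng((unsigned)shuffle_seed);
  std::vector<uword> order(N);
  for (uword i = 0; i < N; ++i) order[i] = i;

  std::vector<double> loss_hist;
  double best_loss = datum::inf;
  int no_improve = 0;
  long t = 0;
  bool diverged = false;
  int epochs_run = 0;

  Mat<T> Xb, Yb;  // minibatch scratch
  for (int epoch = 1; epoch <= max_epochs && !diverged; ++epoch) {
    epochs_run = epoch;
    if (!full_batch) std::shuffle(order.begin(), order.end(), rng);
    double acc_loss = 0.0;

    for (uword start = 0; start < N; start += bs) {
      uword n = std::min(start + bs, N) - start;
      if (!full_batch) {
        uvec idx(n);
        for (uword i = 0; i < n; ++i) idx(i) = order[start + i];
        Xb = X.rows(idx);
        Yb = Y.rows(idx);
      }
      const Mat<T>& Xc = full_batch ? X : Xb;
      const Mat<T>& Yc = full_batch ? Y : Yb;

      Mat<T> A1 = Xc * W1; A1.each_row() += b1;
      Mat<T> H1 = clamp(A1, (T)0, std::numeric_limits<T>::max());
      Mat<T> A2 = H1 * W2; A2.each_row() += b2;
      Mat<T> H2 = clamp(A2, (T)0, std::numeric_limits<T>::max());
      Mat<T> P = H2 * W3; P.each_row() += b3;
      Mat<T>& E = P; E -= Yc;

      double sq = accu(conv_to<mat>::from(square(E)));
      double batch_loss = 0.5 * sq / (double)E.n_elem;
      if (l2 > 0)
        batch_loss += 0.5 * l2 *
          (accu(square(conv_to<mat>::from(W1))) +
           accu(square(conv_to<mat>::from(W2))) +
           accu(square(conv_to<mat>::from(W3)))) / (double)n;
      acc_loss += batch_loss * (double)n;

      Mat<T> d3 = E / (T)n;
      Mat<T> gW3 = H2.t() * d3;
      Mat<T> gb3 = sum(d3, 0);
      Mat<T> d2 = d3 * W3.t();
      d2 %= conv_to<Mat<T>>::from(A2 > (T)0);
      Mat<T> gW2 = H1.t() * d2;
      Mat<T> gb2 = sum(d2, 0);
      Mat<T> d1 = d2 * W2.t();
      d1 %= conv_to<Mat<T>>::from(A1 > (T)0);
      Mat<T> gW1 = Xc.t() * d1;
      Mat<T> gb1 = sum(d1, 0);
      if (l2 > 0) {
        gW1 += ((T)(l2 / (double)n)) * W1;
        gW2 += ((T)(l2 / (double)n)) * W2;
        gW3 += ((T)(l2 / (double)n)) * W3;
      }

      ++t;
      sW1.step(W1, gW1, lr, t); sb1.step(b1, gb1, lr, t);
      sW2.step(W2, gW2, lr, t); sb2.step(b2, gb2, lr, t);
      sW3.step(W3, gW3, lr, t); sb3.step(b3, gb3, lr, t);
    }

    double epoch_loss = acc_loss / (double)N;
    loss_hist.push_back(epoch_loss);
    if (!std::isfinite(epoch_loss)) { diverged = true; break; }

    if (n_iter_no_change > 0) {
      if (epoch_loss > best_loss - tol) ++no_improve; else no_improve = 0;
      if (epoch_loss < best_loss) best_loss = epoch_loss;
      if (no_improve >= n_iter_no_change) break;
    }
    Rcpp::checkUserInterrupt();
  }

  return Rcpp::List::create(
      Rcpp::Named("W1") = conv_to<mat>::from(W1),
      Rcpp::Named("b1") = conv_to<mat>::from(b1),
      Rcpp::Named("W2") = conv_to<mat>::from(W2),
      Rcpp::Named("b2") = conv_to<mat>::from(b2),
      Rcpp::Named("W3") = conv_to<mat>::from(W3),
      Rcpp::Named("b3") = conv_to<mat>::from(b3),
      Rcpp::Named("loss") = loss_hist,
      Rcpp::Named("n_epochs") = epochs_run,
      Rcpp::Named("diverged") = diverged);
}

// [[Rcpp::export]]
Rcpp::List cpp_train_mlp(const arma::mat& X, const arma::mat& Y,
                         const arma::mat& W1, const arma::mat& b1,
                         const arma::mat& W2, const arma::mat& b2,
                         const arma::mat& W3, const arma::mat& b3,
                         double lr, int max_epochs, int batch_size,
                         double l2, double tol, int n_iter_no_change,
                         int shuffle_seed, bool single_precision) {
  if (single_precision) {
    auto f = [](const mat& M) { return conv_to<fmat>::from(M); };
    return train_net<float>(f(X), f(Y), f(W1), f(b1), f(W2), f(b2), f(W3),
                            f(b3), lr, max_epochs, batch_size, l2, tol,
                            n_iter_no_change, shuffle_seed);
  }
  return train_net<double>(X, Y, W1, b1, W2, b2, W3, b3, lr, max_epochs,
                           batch_size, l2, tol, n_iter_no_change,
                           shuffle_seed);
}

// [[Rcpp::export]]
arma::mat cpp_mlp_forward(const arma::mat& X,
                          const arma::mat& W1, const arma::mat& b1,
                          const arma::mat& W2, const arma::mat& b2,
                          const arma::mat& W3, const arma::mat& b3) {
  mat A1 = X * W1; A1.each_row() += rowvec(b1.row(0));
  mat H1 = clamp(A1, 0.0, datum::inf);
  mat A2 = H1 * W2; A2.each_row() += rowvec(b2.row(0));
  mat H2 = clamp(A2, 0.0, datum::inf);
  mat P = H2 * W3; P.each_row() += rowvec(b3.row(0));
  return P;
}
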