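#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

static inline double sigmoid(double v) { return 1.0 / (1.0 + std::exp(-v)); }

namespace {
// Weights in flat row-per-unit layout: W1[j*p + i], W2[k*H + j]; inputs
// transposed to one contiguous block per sample.
struct Net {
  int p, H, K;
  std::vector<double> W1, b1, W2, b2;
};

void forward(const Net &net, const double *x, double *h, double *o) {
  for (int j = 0; j < net.H; ++j) {
    const double *w = &net.W1[(size_t)j * net.p];
    double a = net.b1[j];
    for (int i = 0; i < net.p; ++i) a += w[i] * x[i];
    h[j] = sigmoid(a);
  }
  for (int k = 0; k < net.K; ++k) {
    const double *w = &net.W2[(size_t)k * net.H];
    double a = net.b2[k];
    for (int j = 0; j < net.H; ++j) a += w[j] * h[j];
    o[k] = sigmoid(a);
  }
}

double mse(const Net &net, const std::vector<double> &Xt,
           const std::vector<double> &Tg, int n) {
  std::vector<double> h(net.H), o(net.K);
  double err = 0.0;
  for (int s = 0; s < n; ++s) {
    forward(net, &Xt[(size_t)s * net.p], h.data(), o.data());
    const double *t = &Tg[(size_t)s * net.K];
    for (int k = 0; k < net.K; ++k) {
      double e = o[k] - t[k];
      err += e * e;
    }
  }
  return err / ((double)n * net.K);
}

std::vector<double> transpose_rows(const NumericMatrix &M) {
  // rows of M become contiguous blocks
  const int n = M.nrow(), m = M.ncol();
  std::vector<double> out((size_t)n * m);
  for (int j = 0; j < m; ++j)
    for (int i = 0; i < n; ++i) out[(size_t)i * m + j] = M(i, j);
  return out;
}
} // namespace

// Online (per-sample, data-order) backpropagation for a one-hidden-layer
// sigmoid MLP on mean-squared error against one-hot targets, with test-set
// early stopping and best-snapshot restore. The per-sample gradient equals
// the R-level mlp_gradients() on a single row, so the two paths can be
// cross-checked exactly.
// [[Rcpp::export]]
List mlp_train_online_cpp(NumericMatrix X, NumericMatrix Tg,
                          NumericMatrix Xte, NumericMatrix Tte,
                          NumericMatrix W1_, NumericVector b1_,
                          NumericMatrix W2_, NumericVector b2_,
                          double lr, int max_epochs, int patience) {
  const int n = X.nrow(), p = X.ncol();
  const int H = W1_.nrow(), K = W2_.nrow();
  const int nte = Xte.nrow();

  Net net;
  net.p = p; net.H = H; net.K = K;
  net.W1.resize((size_t)H * p); net.b1.assign(b1_.begin(), b1_.end());
  net.W2.resize((size_t)K * H); net.b2.assign(b2_.begin(), b2_.end());
  for (int j = 0; j < H; ++j)
    for (int i = 0; i < p; ++i) net.W1[(size_t)j * p + i] = W1_(j, i);
  for (int k = 0; k < K; ++k)
    for (int j = 0; j < H; ++j) net.W2[(size_t)k * H + j] = W2_(k, j);

  std::vector<double> Xt = transpose_rows(X), Tt = transpose_rows(Tg);
  std::vector<double> Xet = transpose_rows(Xte), Tet = transpose_rows(Tte);

  Net best = net;
  double best_err = R_PosInf;
  int best_epoch = 0, wait = 0, epoch = 0;
  std::vector<double> hist_tr, hist_te;
  std::vector<double> h(H), o(K), dh(H), dk(K);

  while (epoch < max_epochs) {
    ++epoch;
    for (int s = 0; s < n; ++s) {
      const double *x = &Xt[(size_t)s * p];
      const double *t = &Tt[(size_t)s * K];
      forward(net, x, h.data(), o.data());
      for (int k = 0; k < K; ++k)
        dk[k] = (2.0 / K) * (o[k] - t[k]) * o[k] * (1.0 - o[k]);
      for (int j = 0; j < H; ++j) {
        double acc = 0.0;
        for (int k = 0; k < K; ++k) acc += net.W2[(size_t)k * H + j] * dk[k];
        dh[j] = acc * h[j] * (1.0 - h[j]);
      }
      for (int k = 0; k < K; ++k) {
        double *w = &net.W2[(size_t)k * H];
        const double step = lr * dk[k];
        for (int j = 0; j < H; ++j) w[j] -= step * h[j];
        net.b2[k] -= step;
      }
      for (int j = 0; j < H; ++j) {
        double *w = &net.W1[(size_t)j * p];
        const double step = lr * dh[j];
        for (int i = 0; i < p; ++i) w[i] -= step * x[i];
        net.b1[j] -= step;
      }
    }
    double etr = mse(net, Xt, Tt, n);
    double ete = mse(net, Xet, Tet, nte);
    hist_tr.push_back(etr);
    hist_te.push_back(ete);
    if (!std::isfinite(etr))
      stop("training aborted: loss became non-finite at epoch %d", epoch);
    if (ete < best_err) {
      best_err = ete;
      best_epoch = epoch;
      best = net;
      wait = 0;
    } else if (++wait >= patience) {
      break;
    }
  }
  if (best_epoch == 0) best = net;

  NumericMatrix W1o(H, p), W2o(K, H);
  for (int j = 0; j < H; ++j)
    for (int i = 0; i < p; ++i) W1o(j, i) = best.W1[(size_t)j * p + i];
  for (int k = 0; k < K; ++k)
    for (int j = 0; j < H; ++j) W2o(k, j) = best.W2[(size_t)k * H + j];
  return List::create(_["W1"] = W1o, _["b1"] = wrap(best.b1),
                      _["W2"] = W2o, _["b2"] = wrap(best.b2),
                      _["train_error"] = wrap(hist_tr),
                      _["test_error"] = wrap(hist_te),
                      _["stopped_epoch"] = epoch,
                      _["best_epoch"] = best_epoch);
}
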