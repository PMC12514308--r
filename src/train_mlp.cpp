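// Incremental (per-presentation) error back-propagation trainer for the
// one-hidden-layer nMVAR network: tanh hidden units, affine output,
// momentum, adaptive learning rate with rollback, early stopping on a
// validation split. Kept in C++ because the per-sample update loop over
// ~1e5 rows x hundreds of epochs x surrogate reruns dominates the whole
// pipeline's run time.

#include <Rcpp.h>
#include <random>
#include <vector>
#include <cmath>
using namespace Rcpp;

namespace {

struct Net {
  int D, H, M;
  std::vector<double> W1, b1, W2, b2;  // W1: H x D row-major, W2: M x H
  void init(int d, int h, int m, double initScale, std::mt19937 &rng) {
    D = d; H = h; M = m;
    W1.assign((size_t)H * D, 0.0); b1.assign(H, 0.0);
    W2.assign((size_t)M * H, 0.0); b2.assign(M, 0.0);
    double r1 = initScale / std::sqrt((double)D);
    double r2 = initScale / std::sqrt((double)H);
    std::uniform_real_distribution<double> u1(-r1, r1), u2(-r2, r2);
    for (auto &w : W1) w = u1(rng);
    for (auto &w : b1) w = u1(rng);
    for (auto &w : W2) w = u2(rng);
    for (auto &w : b2) w = u2(rng);
  }
};

// Mean squared error over samples and output dimensions for row set idx.
// X and Y are row-major copies (contiguous features per sample).
double setMse(const Net &net, const double *X, const double *Y,
              const std::vector<int> &idx) {
  if (idx.empty()) return NA_REAL;
  std::vector<double> h(net.H);
  double sse = 0.0;
  for (int r : idx) {
    const double *x = X + (size_t)r * net.D;
    for (int j = 0; j < net.H; ++j) {
      double a = net.b1[j];
      const double *w = &net.W1[(size_t)j * net.D];
      for (int d = 0; d < net.D; ++d) a += w[d] * x[d];
      h[j] = std::tanh(a);
    }
    const double *y0 = Y + (size_t)r * net.M;
    for (int m = 0; m < net.M; ++m) {
      double y = net.b2[m];
      const double *w = &net.W2[(size_t)m * net.H];
      for (int j = 0; j < net.H; ++j) y += w[j] * h[j];
      double e = y - y0[m];
      sse += e * e;
    }
  }
  return sse / ((double)idx.size() * net.M);
}

}  // namespace

// [[Rcpp::export]]
List cpp_train_mlp(NumericMatrix X, NumericMatrix Y,
                   IntegerVector trainIdx, IntegerVector valIdx,
                   int nHidden, double momentum, double eta0,
                   int maxEpochs, int patience,
                   double etaUp, double etaDown, double riseTol,
                   double initScale, int seed) {
  const int nrow = X.nrow(), D = X.ncol(), M = Y.ncol();
  // row-major copies: the per-sample loop touches one contiguous block
  std::vector<double> Xrm((size_t)nrow * D), Yrm((size_t)nrow * M);
  for (int r = 0; r < nrow; ++r) {
    for (int d = 0; d < D; ++d) Xrm[(size_t)r * D + d] = X(r, d);
    for (int m = 0; m < M; ++m) Yrm[(size_t)r * M + m] = Y(r, m);
  }
  std::mt19937 rng((unsigned)seed);
  Net net;
  net.init(D, nHidden, M, initScale, rng);
  const int H = nHidden;

  std::vector<int> tr(trainIdx.begin(), trainIdx.end());
  std::vector<int> va(valIdx.begin(), valIdx.end());
  for (auto &i : tr) --i;
  for (auto &i : va) --i;

  std::vector<double> dW1((size_t)H * D, 0.0), db1(H, 0.0);
  std::vector<double> dW2((size_t)M * H, 0.0), db2(M, 0.0);
  std::vector<double> h(H), delh(H), e(M);

  const double *Xp = Xrm.data(), *Yp = Yrm.data();
  double eta = eta0;
  double prevMse = R_PosInf;
  double bestVal = R_PosInf;
  Net bestNet = net;
  int bestEpoch = 0, badEpochs = 0;
  std::vector<double> trTrace, vaTrace, etaTrace;
  bool diverged = false;
  int divergedEpoch = -1;

  for (int epoch = 1; epoch <= maxEpochs; ++epoch) {
    Net snapshot = net;
    std::vector<double> sdW1 = dW1, sdb1 = db1, sdW2 = dW2, sdb2 = db2;
    std::shuffle(tr.begin(), tr.end(), rng);
    double sse = 0.0;
    for (int r : tr) {
      const double *x = Xp + (size_t)r * D;
      const double *y0 = Yp + (size_t)r * M;
      // forward
      for (int j = 0; j < H; ++j) {
        double a = net.b1[j];
        const double *w = &net.W1[(size_t)j * D];
        for (int d = 0; d < D; ++d) a += w[d] * x[d];
        h[j] = std::tanh(a);
      }
      for (int m = 0; m < M; ++m) {
        double y = net.b2[m];
        const double *w = &net.W2[(size_t)m * H];
        for (int j = 0; j < H; ++j) y += w[j] * h[j];
        e[m] = y - y0[m];
        sse += e[m] * e[m];
      }
      // backward
      for (int j = 0; j < H; ++j) {
        double s = 0.0;
        for (int m = 0; m < M; ++m) s += net.W2[(size_t)m * H + j] * e[m];
        delh[j] = s * (1.0 - h[j] * h[j]);
      }
      // momentum updates
      for (int m = 0; m < M; ++m) {
        double *w = &net.W2[(size_t)m * H];
        double *dw = &dW2[(size_t)m * H];
        for (int j = 0; j < H; ++j) {
          dw[j] = momentum * dw[j] - eta * e[m] * h[j];
          w[j] += dw[j];
        }
        db2[m] = momentum * db2[m] - eta * e[m];
        net.b2[m] += db2[m];
      }
      for (int j = 0; j < H; ++j) {
        double *w = &net.W1[(size_t)j * D];
        double *dw = &dW1[(size_t)j * D];
        for (int d = 0; d < D; ++d) {
          dw[d] = momentum * dw[d] - eta * delh[j] * x[d];
          w[d] += dw[d];
        }
        db1[j] = momentum * db1[j] - eta * delh[j];
        net.b1[j] += db1[j];
      }
    }
    double mse = sse / ((double)tr.size() * M);
    if (!std::isfinite(mse)) {
      diverged = true;
      divergedEpoch = epoch;
      break;
    }
    if (mse > prevMse * (1.0 + riseTol)) {
      // reject the epoch: roll weights back, damp the learning rate
      net = snapshot;
      dW1 = sdW1; db1 = sdb1; dW2 = sdW2; db2 = sdb2;
      eta *= etaDown;
      mse = prevMse;
    } else {
      if (mse < prevMse) eta *= etaUp;
      prevMse = mse;
    }
    double vmse = setMse(net, Xp, Yp, va);
    trTrace.push_back(mse);
    vaTrace.push_back(vmse);
    etaTrace.push_back(eta);
    double monitor = va.empty() ? mse : vmse;
    if (monitor < bestVal - 1e-12) {
      bestVal = monitor;
      bestNet = net;
      bestEpoch = epoch;
      badEpochs = 0;
    } else if (++badEpochs >= patience) {
      break;
    }
  }
  if (bestEpoch == 0) bestNet = net;

  NumericMatrix W1(H, D), W2(M, H);
  for (int j = 0; j < H; ++j)
    for (int d = 0; d < D; ++d) W1(j, d) = bestNet.W1[(size_t)j * D + d];
  for (int m = 0; m < M; ++m)
    for (int j = 0; j < H; ++j) W2(m, j) = bestNet.W2[(size_t)m * H + j];

  return List::create(
    _["W1"] = W1, _["b1"] = NumericVector(bestNet.b1.begin(), bestNet.b1.end()),
    _["W2"] = W2, _["b2"] = NumericVector(bestNet.b2.begin(), bestNet.b2.end()),
    _["trainMse"] = NumericVector(trTrace.begin(), trTrace.end()),
    _["valMse"] = NumericVector(vaTrace.begin(), vaTrace.end()),
    _["eta"] = NumericVector(etaTrace.begin(), etaTrace.end()),
    _["bestEpoch"] = bestEpoch,
    _["diverged"] = diverged,
    _["divergedEpoch"] = divergedEpoch,
    _["finalEta"] = eta
  );
}
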