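// Online training of the two small feed-forward networks used for the
// PRDIS-specific predictors: a single sigmoid output unit with no
// hidden layer, or one hidden layer of sigmoid units.  Training is
// plain stochastic gradient descent on squared error with a momentum
// term, one weight update per presented instance, mirroring the
// classic perceptron-style setup (learning rate L, momentum M, N
// epochs).  The presentation order is shuffled once from the given
// seed and then kept fixed across epochs, so training is fully
// deterministic for a given seed.

#include <Rcpp.h>
#include <random>
#include <vector>
using namespace Rcpp;

static inline double sigmoid(double z) { return 1.0 / (1.0 + std::exp(-z)); }

// [[Rcpp::export(name = ".mlp_train_cpp")]]
List mlp_train_cpp(NumericMatrix x, NumericVector y, int hidden,
                   double lr, double momentum, int epochs, int seed) {
  const int n = x.nrow(), p = x.ncol();
  if (n == 0) stop("no training rows");
  std::mt19937 rng(static_cast<std::uint32_t>(seed));
  std::uniform_real_distribution<double> unif(-0.5, 0.5);

  std::vector<int> order(n);
  for (int i = 0; i < n; ++i) order[i] = i;
  for (int i = n - 1; i > 0; --i) {  // Fisher-Yates, rng-stable across platforms
    std::uniform_int_distribution<int> d(0, i);
    std::swap(order[i], order[d(rng)]);
  }

  if (hidden <= 0) {
    std::vector<double> w(p), dw(p, 0.0);
    double b = unif(rng), db = 0.0;
    for (int j = 0; j < p; ++j) w[j] = unif(rng);
    for (int e = 0; e < epochs; ++e) {
      for (int ii = 0; ii < n; ++ii) {
        const int i = order[ii];
        double z = b;
        for (int j = 0; j < p; ++j) z += w[j] * x(i, j);
        const double o = sigmoid(z);
        const double g = (y[i] - o) * o * (1.0 - o);
        for (int j = 0; j < p; ++j) {
          dw[j] = lr * g * x(i, j) + momentum * dw[j];
          w[j] += dw[j];
        }
        db = lr * g + momentum * db;
        b += db;
      }
    }
    return List::create(_["w"] = NumericVector(w.begin(), w.end()),
                        _["b"] = b);
  }

  const int h = hidden;
  std::vector<double> W1(h * p), b1(h), w2(h), dW1(h * p, 0.0), db1(h, 0.0),
      dw2(h, 0.0);
  double b2 = 0.0, db2 = 0.0;
  for (int k = 0; k < h * p; ++k) W1[k] = unif(rng);
  for (int k = 0; k < h; ++k) b1[k] = unif(rng);
  for (int k = 0; k < h; ++k) w2[k] = unif(rng);
  b2 = unif(rng);

  std::vector<double> hid(h);
  for (int e = 0; e < epochs; ++e) {
    for (int ii = 0; ii < n; ++ii) {
      const int i = order[ii];
      for (int k = 0; k < h; ++k) {
        double z = b1[k];
        for (int j = 0; j < p; ++j) z += W1[k * p + j] * x(i, j);
        hid[k] = sigmoid(z);
      }
      double z2 = b2;
      for (int k = 0; k < h; ++k) z2 += w2[k] * hid[k];
      const double o = sigmoid(z2);
      const double g_out = (y[i] - o) * o * (1.0 - o);
      // output layer
      for (int k = 0; k < h; ++k) {
        const double upd = lr * g_out * hid[k] + momentum * dw2[k];
        dw2[k] = upd;
      }
      db2 = lr * g_out + momentum * db2;
      // hidden layer (uses pre-update output weights)
      for (int k = 0; k < h; ++k) {
        const double g_hid = hid[k] * (1.0 - hid[k]) * w2[k] * g_out;
        for (int j = 0; j < p; ++j) {
          dW1[k * p + j] = lr * g_hid * x(i, j) + momentum * dW1[k * p + j];
          W1[k * p + j] += dW1[k * p + j];
        }
        db1[k] = lr * g_hid + momentum * db1[k];
        b1[k] += db1[k];
      }
      for (int k = 0; k < h; ++k) w2[k] += dw2[k];
      b2 += db2;
    }
  }
  NumericMatrix W1m(h, p);
  for (int k = 0; k < h; ++k)
    for (int j = 0; j < p; ++j) W1m(k, j) = W1[k * p + j];
  return List::create(_["W1"] = W1m,
                      _["b1"] = NumericVector(b1.begin(), b1.end()),
                      _["w2"] = NumericVector(w2.begin(), w2.end()),
                      _["b2"] = b2);
}
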