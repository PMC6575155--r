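// Compact CNN engine: stride-1 "same" convolutions via im2col + GEMM,
// ReLU, window-stride max pooling, one hidden fully connected layer with
// inverted dropout, and a softmax read-out. Templated over the scalar type:
// float for training/inference speed, double for gradient checking.

// [[Rcpp::depends(RcppArmadillo)]]
#include <RcppArmadillo.h>
#include <random>

using namespace Rcpp;

namespace {

// Deterministic RNG independent of std::distribution implementations.
struct Rng {
  std::mt19937 eng;
  explicit Rng(uint32_t seed) : eng(seed) {}
  double unif() { return (eng() >> 5) * (1.0 / 134217728.0) / 32.0; } // [0,1)
  int below(int n) {
    return static_cast<int>((static_cast<uint64_t>(eng()) * n) >> 32);
  }
};

struct Config {
  std::vector<int> maps, kernels, pools;
  int inputSize = 0, nChannels = 3, fcWidth = 1024, nClasses = 3;
  double dropout = 0.5;
  int nLayers() const { return static_cast<int>(maps.size()); }
  // spatial side entering conv layer l (0-based)
  int sideIn(int l) const {
    int s = inputSize;
    for (int i = 0; i < l; ++i) s /= pools[i];
    return s;
  }
  int sideFinal() const { return sideIn(nLayers()); }
  int fanIn() const {
    int s = sideFinal();
    return s * s * maps[nLayers() - 1];
  }
};

Config parseConfig(const List& cfg) {
  Config c;
  IntegerVector m = cfg["maps"], k = cfg["kernels"], p = cfg["pools"];
  c.maps = std::vector<int>(m.begin(), m.end());
  c.kernels = std::vector<int>(k.begin(), k.end());
  c.pools = std::vector<int>(p.begin(), p.end());
  c.inputSize = as<int>(cfg["input_size"]);
  c.nChannels = as<int>(cfg["n_channels"]);
  c.fcWidth = as<int>(cfg["fc_width"]);
  c.nClasses = as<int>(cfg["n_classes"]);
  c.dropout = as<double>(cfg["dropout"]);
  if (c.maps.size() != c.kernels.size() || c.maps.size() != c.pools.size())
    stop("maps, kernels and pools must have equal length");
  int prod = 1;
  for (int w : c.pools) prod *= w;
  if (c.inputSize % prod != 0)
    stop("input_size must be divisible by the product of pool windows");
  for (int kk : c.kernels)
    if (kk % 2 == 0) stop("convolution kernels must be odd for same padding");
  return c;
}

template <typename T>
struct Weights {
  std::vector<arma::Mat<T>> convW;  // (k*k*Cin) x Cout
  std::vector<arma::Col<T>> convB;
  arma::Mat<T> W1, W2;  // fanIn x fcWidth, fcWidth x nClasses
  arma::Col<T> b1, b2;
};

template <typename T>
Weights<T> parseWeights(const List& w, const Config& c) {
  Weights<T> out;
  List conv = w["conv"];
  if (conv.size() != c.nLayers()) stop("weight/config layer count mismatch");
  int cin = c.nChannels;
  for (int l = 0; l < c.nLayers(); ++l) {
    List layer = conv[l];
    NumericMatrix W = layer["W"];
    NumericVector b = layer["b"];
    int k = c.kernels[l];
    if (W.nrow() != k * k * cin || W.ncol() != c.maps[l])
      stop("conv weight shape mismatch at layer %d", l + 1);
    out.convW.push_back(
        arma::conv_to<arma::Mat<T>>::from(as<arma::mat>(W)));
    out.convB.push_back(
        arma::conv_to<arma::Col<T>>::from(as<arma::vec>(b)));
    cin = c.maps[l];
  }
  List fc1 = w["fc1"], fc2 = w["fc2"];
  out.W1 = arma::conv_to<arma::Mat<T>>::from(as<arma::mat>(fc1["W"]));
  out.b1 = arma::conv_to<arma::Col<T>>::from(as<arma::vec>(fc1["b"]));
  out.W2 = arma::conv_to<arma::Mat<T>>::from(as<arma::mat>(fc2["W"]));
  out.b2 = arma::conv_to<arma::Col<T>>::from(as<arma::vec>(fc2["b"]));
  if (static_cast<int>(out.W1.n_rows) != c.fanIn() ||
      static_cast<int>(out.W1.n_cols) != c.fcWidth)
    stop("fc1 weight shape mismatch");
  if (static_cast<int>(out.W2.n_rows) != c.fcWidth ||
      static_cast<int>(out.W2.n_cols) != c.nClasses)
    stop("fc2 weight shape mismatch");
  return out;
}

template <typename T>
List exportWeights(const Weights<T>& w) {
  List conv(w.convW.size());
  for (size_t l = 0; l < w.convW.size(); ++l) {
    conv[l] = List::create(
        _["W"] = wrap(arma::conv_to<arma::mat>::from(w.convW[l])),
        _["b"] = wrap(arma::conv_to<arma::vec>::from(w.convB[l])));
  }
  return List::create(
      _["conv"] = conv,
      _["fc1"] = List::create(
          _["W"] = wrap(arma::conv_to<arma::mat>::from(w.W1)),
          _["b"] = wrap(arma::conv_to<arma::vec>::from(w.b1))),
      _["fc2"] = List::create(
          _["W"] = wrap(arma::conv_to<arma::mat>::from(w.W2)),
          _["b"] = wrap(arma::conv_to<arma::vec>::from(w.b2))));
}

// image array (H x W x C, 0..255 intensities) -> (H*W) x C matrix in [0,1]
template <typename T>
arma::Mat<T> imageToMat(const NumericVector& arr, int& H, int& W, int nCh) {
  IntegerVector dim = arr.attr("dim");
  if (dim.size() != 3 || dim[2] != nCh)
    stop("expected an H x W x %d image array", nCh);
  H = dim[0];
  W = dim[1];
  arma::Mat<T> X(H * W, nCh);
  const double* src = arr.begin();
  const double s = 1.0 / 255.0;
  for (size_t i = 0; i < X.n_elem; ++i) X(i) = static_cast<T>(src[i] * s);
  return X;
}

// The convolutions run strip-tiled: the im2col buffer covers only a band of
// image columns at a time so it stays cache-resident instead of streaming a
// multi-megabyte patch matrix through memory for every layer and pass.

// image columns per strip, aimed at a ~2 MB column buffer
template <typename T>
int stripCols(int H, int k, int Cin) {
  const double bytesPerImgCol =
      static_cast<double>(H) * k * k * Cin * sizeof(T);
  const int w = static_cast<int>(2.0e6 / std::max(1.0, bytesPerImgCol));
  return std::max(1, w);
}

// im2col restricted to output columns [c0, ce)
template <typename T>
void im2colStrip(const arma::Mat<T>& X, int H, int W, int k, int c0, int ce,
                 arma::Mat<T>& col) {
  const int p = (k - 1) / 2, Cin = X.n_cols, nCol = ce - c0;
  col.set_size(static_cast<size_t>(H) * nCol,
               static_cast<size_t>(k) * k * Cin);
  for (int ci = 0; ci < Cin; ++ci) {
    const T* xc = X.colptr(ci);
    for (int dc = 0; dc < k; ++dc) {
      for (int dr = 0; dr < k; ++dr) {
        T* cj = col.colptr(dr + k * (dc + k * ci));
        const int sr = dr - p, sc = dc - p;
        for (int cc = c0; cc < ce; ++cc) {
          T* dst = cj + static_cast<size_t>(H) * (cc - c0);
          const int srcCol = cc + sc;
          if (srcCol < 0 || srcCol >= W) {
            std::fill(dst, dst + H, static_cast<T>(0));
            continue;
          }
          const int rLo = std::max(0, -sr), rHi = std::min(H, H - sr);
          if (rLo > 0) std::fill(dst, dst + rLo, static_cast<T>(0));
          if (rHi < H) std::fill(dst + rHi, dst + H, static_cast<T>(0));
          const T* src = xc + static_cast<size_t>(H) * srcCol + sr;
          std::copy(src + rLo, src + rHi, dst + rLo);
        }
      }
    }
  }
}

// scatter-add inverse for output columns [c0, ce); dX must be pre-zeroed
template <typename T>
void col2imStripAdd(const arma::Mat<T>& col, int H, int W, int k, int c0,
                    int ce, arma::Mat<T>& dX) {
  const int p = (k - 1) / 2, Cin = dX.n_cols;
  for (int ci = 0; ci < Cin; ++ci) {
    T* xc = dX.colptr(ci);
    for (int dc = 0; dc < k; ++dc) {
      for (int dr = 0; dr < k; ++dr) {
        const T* cj = col.colptr(dr + k * (dc + k * ci));
        const int sr = dr - p, sc = dc - p;
        for (int cc = c0; cc < ce; ++cc) {
          const int srcCol = cc + sc;
          if (srcCol < 0 || srcCol >= W) continue;
          const int rLo = std::max(0, -sr), rHi = std::min(H, H - sr);
          T* xdst = xc + static_cast<size_t>(H) * srcCol + sr;
          const T* s = cj + static_cast<size_t>(H) * (cc - c0);
          for (int r = rLo; r < rHi; ++r) xdst[r] += s[r];
        }
      }
    }
  }
}

// same-padding convolution with fused bias + ReLU
template <typename T>
void convForward(const arma::Mat<T>& X, int H, int W, int k,
                 const arma::Mat<T>& Wt, const arma::Col<T>& b,
                 arma::Mat<T>& Y, arma::Mat<T>& colBuf,
                 arma::Mat<T>& stripBuf) {
  const int Cout = Wt.n_cols, sw = stripCols<T>(H, k, X.n_cols);
  Y.set_size(static_cast<size_t>(H) * W, Cout);
  for (int c0 = 0; c0 < W; c0 += sw) {
    const int ce = std::min(W, c0 + sw);
    im2colStrip(X, H, W, k, c0, ce, colBuf);
    stripBuf = colBuf * Wt;
    const int n = H * (ce - c0);
    for (int ch = 0; ch < Cout; ++ch) {
      const T bb = b(ch);
      T* y = Y.colptr(ch) + static_cast<size_t>(H) * c0;
      const T* s = stripBuf.colptr(ch);
      for (int i = 0; i < n; ++i) {
        const T v = s[i] + bb;
        y[i] = v > 0 ? v : static_cast<T>(0);
      }
    }
  }
}

// gradients of a same-padding convolution; dX (optional) accumulates the
// input gradient, gW/gb accumulate parameter gradients
template <typename T>
void convBackward(const arma::Mat<T>& X, int H, int W, int k,
                  const arma::Mat<T>& Wt, const arma::Mat<T>& dA,
                  arma::Mat<T>& gW, arma::Col<T>& gb, arma::Mat<T>* dX,
                  arma::Mat<T>& colBuf, arma::Mat<T>& stripBuf) {
  gb += arma::sum(dA, 0).t();
  if (dX) dX->zeros(static_cast<size_t>(H) * W, X.n_cols);
  const int sw = stripCols<T>(H, k, X.n_cols);
  for (int c0 = 0; c0 < W; c0 += sw) {
    const int ce = std::min(W, c0 + sw);
    im2colStrip(X, H, W, k, c0, ce, colBuf);
    const arma::Mat<T> dAs =
        dA.rows(static_cast<size_t>(H) * c0,
                static_cast<size_t>(H) * ce - 1);
    gW += colBuf.t() * dAs;
    if (dX) {
      stripBuf = dAs * Wt.t();
      col2imStripAdd(stripBuf, H, W, k, c0, ce, *dX);
    }
  }
}

template <typename T>
void maxpool(const arma::Mat<T>& A, int H, int W, int w, arma::Mat<T>& P,
             arma::umat& amax) {
  const int C = A.n_cols, Ho = H / w, Wo = W / w;
  P.set_size(static_cast<size_t>(Ho) * Wo, C);
  amax.set_size(static_cast<size_t>(Ho) * Wo, C);
  for (int ch = 0; ch < C; ++ch) {
    const T* a = A.colptr(ch);
    for (int co = 0; co < Wo; ++co) {
      for (int ro = 0; ro < Ho; ++ro) {
        T best = -std::numeric_limits<T>::infinity();
        size_t bidx = 0;
        for (int dc = 0; dc < w; ++dc) {
          const size_t base = static_cast<size_t>(H) * (co * w + dc) + ro * w;
          for (int dr = 0; dr < w; ++dr) {
            const T v = a[base + dr];
            if (v > best) {
              best = v;
              bidx = base + dr;
            }
          }
        }
        P(ro + static_cast<size_t>(Ho) * co, ch) = best;
        amax(ro + static_cast<size_t>(Ho) * co, ch) = bidx;
      }
    }
  }
}

template <typename T>
struct ForwardState {
  std::vector<arma::Mat<T>> relu;   // post-ReLU conv output per layer
  std::vector<arma::Mat<T>> pooled; // post-pool per layer
  std::vector<arma::umat> amax;
  std::vector<arma::Mat<T>> dA, dX;       // backward scratch
  arma::Mat<T> colBuf, stripBuf;          // strip-tile scratch
  arma::Col<T> fcIn, h1, h1drop, probs;
  arma::Col<T> dropMask; // empty when dropout off
  void ensure(int L) {
    if (static_cast<int>(relu.size()) == L) return;
    relu.resize(L);
    pooled.resize(L);
    amax.resize(L);
    dA.resize(L);
    dX.resize(L);
  }
};

template <typename T>
void forwardPass(const Weights<T>& w, const Config& c, const arma::Mat<T>& X0,
                 ForwardState<T>& st, bool dropoutOn, Rng* rng) {
  const int L = c.nLayers();
  st.ensure(L);
  const arma::Mat<T>* cur = &X0;
  int side = c.inputSize;
  for (int l = 0; l < L; ++l) {
    convForward(*cur, side, side, c.kernels[l], w.convW[l], w.convB[l],
                st.relu[l], st.colBuf, st.stripBuf);
    maxpool(st.relu[l], side, side, c.pools[l], st.pooled[l], st.amax[l]);
    side /= c.pools[l];
    cur = &st.pooled[l];
  }
  st.fcIn = arma::vectorise(st.pooled[L - 1]);
  st.h1 = w.W1.t() * st.fcIn + w.b1;
  st.h1.transform([](T v) { return v > 0 ? v : static_cast<T>(0); });
  if (dropoutOn) {
    const T keep = static_cast<T>(1.0 - c.dropout);
    st.dropMask.set_size(st.h1.n_elem);
    for (size_t i = 0; i < st.h1.n_elem; ++i)
      st.dropMask(i) = (rng->unif() < keep) ? static_cast<T>(1) / keep
                                            : static_cast<T>(0);
    st.h1drop = st.h1 % st.dropMask;
  } else {
    st.h1drop = st.h1;
    st.dropMask.reset();
  }
  arma::Col<T> logits = w.W2.t() * st.h1drop + w.b2;
  logits -= logits.max();
  st.probs = arma::exp(logits);
  st.probs /= arma::accu(st.probs);
}

template <typename T>
void backwardPass(const Weights<T>& w, const Config& c,
                  const arma::Mat<T>& X0, ForwardState<T>& st,
                  int y /*0-based*/, Weights<T>& g /*accumulated*/) {
  const int L = c.nLayers();
  arma::Col<T> dlog = st.probs;
  dlog(y) -= static_cast<T>(1);
  g.W2 += st.h1drop * dlog.t();
  g.b2 += dlog;
  arma::Col<T> dh1 = w.W2 * dlog;
  if (!st.dropMask.is_empty()) dh1 %= st.dropMask;
  for (size_t i = 0; i < dh1.n_elem; ++i)
    if (st.h1(i) <= 0) dh1(i) = 0;
  g.W1 += st.fcIn * dh1.t();
  g.b1 += dh1;
  arma::Col<T> dfcIn = w.W1 * dh1;

  // gradient w.r.t. the last pooled map
  arma::Mat<T> dPtop(const_cast<T*>(dfcIn.memptr()), st.pooled[L - 1].n_rows,
                     st.pooled[L - 1].n_cols, true);
  const arma::Mat<T>* dP = &dPtop;
  for (int l = L - 1; l >= 0; --l) {
    // unpool into scratch
    arma::Mat<T>& dA = st.dA[l];
    dA.zeros(st.relu[l].n_rows, st.relu[l].n_cols);
    const arma::umat& am = st.amax[l];
    for (size_t ch = 0; ch < dA.n_cols; ++ch)
      for (size_t i = 0; i < am.n_rows; ++i)
        dA(am(i, ch), ch) += (*dP)(i, ch);
    // ReLU mask
    const arma::Mat<T>& A = st.relu[l];
    for (size_t i = 0; i < dA.n_elem; ++i)
      if (A(i) <= 0) dA(i) = 0;
    const arma::Mat<T>& Xin = (l == 0) ? X0 : st.pooled[l - 1];
    const int side = c.sideIn(l);
    convBackward(Xin, side, side, c.kernels[l], w.convW[l], dA,
                 g.convW[l], g.convB[l],
                 l > 0 ? &st.dX[l - 1] : nullptr, st.colBuf, st.stripBuf);
    if (l > 0) dP = &st.dX[l - 1];
  }
}

template <typename T>
Weights<T> zeroLike(const Weights<T>& w) {
  Weights<T> g;
  for (size_t l = 0; l < w.convW.size(); ++l) {
    g.convW.push_back(
        arma::Mat<T>(w.convW[l].n_rows, w.convW[l].n_cols, arma::fill::zeros));
    g.convB.push_back(arma::Col<T>(w.convB[l].n_elem, arma::fill::zeros));
  }
  g.W1.zeros(w.W1.n_rows, w.W1.n_cols);
  g.b1.zeros(w.b1.n_elem);
  g.W2.zeros(w.W2.n_rows, w.W2.n_cols);
  g.b2.zeros(w.b2.n_elem);
  return g;
}

// Adam update over all parameter blocks.
template <typename T>
struct Adam {
  Weights<T> m, v;
  double lr, b1, b2, eps;
  long t = 0;
  Adam(const Weights<T>& w, double lr_, double beta1, double beta2,
       double eps_)
      : m(zeroLike(w)), v(zeroLike(w)), lr(lr_), b1(beta1), b2(beta2),
        eps(eps_) {}
  template <typename MatT>
  void stepBlock(MatT& w, MatT& g, MatT& m_, MatT& v_, double corr1,
                 double corr2) {
    for (size_t i = 0; i < w.n_elem; ++i) {
      const double gi = g(i);
      m_(i) = static_cast<T>(b1 * m_(i) + (1 - b1) * gi);
      v_(i) = static_cast<T>(b2 * v_(i) + (1 - b2) * gi * gi);
      const double mh = m_(i) / corr1, vh = v_(i) / corr2;
      w(i) -= static_cast<T>(lr * mh / (std::sqrt(vh) + eps));
    }
  }
  void step(Weights<T>& w, Weights<T>& g) {
    ++t;
    const double corr1 = 1 - std::pow(b1, t), corr2 = 1 - std::pow(b2, t);
    for (size_t l = 0; l < w.convW.size(); ++l) {
      stepBlock(w.convW[l], g.convW[l], m.convW[l], v.convW[l], corr1, corr2);
      stepBlock(w.convB[l], g.convB[l], m.convB[l], v.convB[l], corr1, corr2);
    }
    stepBlock(w.W1, g.W1, m.W1, v.W1, corr1, corr2);
    stepBlock(w.b1, g.b1, m.b1, v.b1, corr1, corr2);
    stepBlock(w.W2, g.W2, m.W2, v.W2, corr1, corr2);
    stepBlock(w.b2, g.b2, m.b2, v.b2, corr1, corr2);
  }
};

template <typename T>
void scaleWeights(Weights<T>& g, T s) {
  for (size_t l = 0; l < g.convW.size(); ++l) {
    g.convW[l] *= s;
    g.convB[l] *= s;
  }
  g.W1 *= s;
  g.b1 *= s;
  g.W2 *= s;
  g.b2 *= s;
}

template <typename T>
void zeroWeights(Weights<T>& g) {
  for (size_t l = 0; l < g.convW.size(); ++l) {
    g.convW[l].zeros();
    g.convB[l].zeros();
  }
  g.W1.zeros();
  g.b1.zeros();
  g.W2.zeros();
  g.b2.zeros();
}

}  // namespace

// [[Rcpp::export]]
List cpp_train(List weights, List config, List images, IntegerVector labels,
               int epochs, int batchSize, double learningRate, int seed) {
  Config c = parseConfig(config);
  Weights<float> w = parseWeights<float>(weights, c);
  const int n = images.size();
  if (labels.size() != n) stop("labels and images differ in length");
  std::vector<arma::fmat> X(n);
  std::vector<int> y(n);
  for (int i = 0; i < n; ++i) {
    int H, W;
    X[i] = imageToMat<float>(images[i], H, W, c.nChannels);
    if (H != c.inputSize || W != c.inputSize)
      stop("image %d is %dx%d but the network input is %dx%d", i + 1, H, W,
           c.inputSize, c.inputSize);
    y[i] = labels[i] - 1;
    if (y[i] < 0 || y[i] >= c.nClasses) stop("label out of range");
  }
  Rng rng(static_cast<uint32_t>(seed));
  Adam<float> opt(w, learningRate, 0.9, 0.999, 1e-8);
  Weights<float> g = zeroLike(w);
  NumericVector lossHist(epochs);
  std::vector<int> order(n);
  for (int i = 0; i < n; ++i) order[i] = i;
  ForwardState<float> st;
  for (int e = 0; e < epochs; ++e) {
    for (int i = n - 1; i > 0; --i)
      std::swap(order[i], order[rng.below(i + 1)]);
    double epochLoss = 0;
    for (int start = 0; start < n; start += batchSize) {
      const int stop_ = std::min(n, start + batchSize);
      zeroWeights(g);
      for (int b = start; b < stop_; ++b) {
        const int i = order[b];
        forwardPass(w, c, X[i], st, c.dropout > 0, &rng);
        const double p = std::max<double>(st.probs(y[i]), 1e-12);
        epochLoss += -std::log(p);
        backwardPass(w, c, X[i], st, y[i], g);
      }
      scaleWeights(g, 1.0f / static_cast<float>(stop_ - start));
      opt.step(w, g);
      Rcpp::checkUserInterrupt();
    }
    lossHist[e] = epochLoss / n;
  }
  return List::create(_["weights"] = exportWeights(w), _["loss"] = lossHist);
}

// [[Rcpp::export]]
NumericMatrix cpp_predict(List weights, List config, List images) {
  Config c = parseConfig(config);
  Weights<float> w = parseWeights<float>(weights, c);
  const int n = images.size();
  NumericMatrix out(n, c.nClasses);
  ForwardState<float> st;
  for (int i = 0; i < n; ++i) {
    int H, W;
    arma::fmat X = imageToMat<float>(images[i], H, W, c.nChannels);
    if (H != c.inputSize || W != c.inputSize)
      stop("image %d is %dx%d but the network input is %dx%d", i + 1, H, W,
           c.inputSize, c.inputSize);
    forwardPass(w, c, X, st, false, nullptr);
    for (int k = 0; k < c.nClasses; ++k) out(i, k) = st.probs(k);
  }
  return out;
}

// [[Rcpp::export]]
List cpp_activations(List weights, List config, NumericVector image) {
  Config c = parseConfig(config);
  Weights<float> w = parseWeights<float>(weights, c);
  int H, W;
  arma::fmat X = imageToMat<float>(image, H, W, c.nChannels);
  if (H != c.inputSize || W != c.inputSize)
    stop("image is %dx%d but the network input is %dx%d", H, W, c.inputSize,
         c.inputSize);
  ForwardState<float> st;
  forwardPass(w, c, X, st, false, nullptr);
  const int L = c.nLayers();
  List out;
  CharacterVector names;
  for (int l = 0; l < L; ++l) {
    const int side = c.sideIn(l), sideP = side / c.pools[l];
    NumericVector conv(wrap(arma::conv_to<arma::mat>::from(st.relu[l])));
    conv.attr("dim") = IntegerVector::create(side, side, c.maps[l]);
    NumericVector pool(wrap(arma::conv_to<arma::mat>::from(st.pooled[l])));
    pool.attr("dim") = IntegerVector::create(sideP, sideP, c.maps[l]);
    out.push_back(conv, "conv" + std::to_string(l + 1));
    out.push_back(pool, "pool" + std::to_string(l + 1));
  }
  NumericVector probs(wrap(arma::conv_to<arma::vec>::from(st.probs)));
  out.push_back(probs, "probs");
  return out;
}

// Double-precision loss and analytic gradients for one example; dropout off.
// [[Rcpp::export]]
List cpp_loss_grad(List weights, List config, NumericVector image, int label) {
  Config c = parseConfig(config);
  Weights<double> w = parseWeights<double>(weights, c);
  int H, W;
  arma::mat X = imageToMat<double>(image, H, W, c.nChannels);
  if (H != c.inputSize || W != c.inputSize) stop("image/network size mismatch");
  ForwardState<double> st;
  forwardPass(w, c, X, st, false, nullptr);
  const int y = label - 1;
  if (y < 0 || y >= c.nClasses) stop("label out of range");
  const double loss = -std::log(std::max(st.probs(y), 1e-300));
  Weights<double> g = zeroLike(w);
  backwardPass(w, c, X, st, y, g);
  return List::create(_["loss"] = loss, _["grads"] = exportWeights(g));
}

// Double-precision loss only (for numerical differentiation).
// [[Rcpp::export]]
double cpp_loss(List weights, List config, NumericVector image, int label) {
  Config c = parseConfig(config);
  Weights<double> w = parseWeights<double>(weights, c);
  int H, W;
  arma::mat X = imageToMat<double>(image, H, W, c.nChannels);
  ForwardState<double> st;
  forwardPass(w, c, X, st, false, nullptr);
  return -std::log(std::max(st.probs(label - 1), 1e-300));
}
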