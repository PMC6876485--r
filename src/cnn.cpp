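// Multi-view 2D convolutional network: one conv-pool-conv-pool-conv branch
// per view (weights not shared), feature concatenation, one hidden
// fully-connected layer with ReLU + dropout, 2-way softmax output.
// Implemented with im2col + BLAS sgemm in single precision; minibatch SGD
// with Nesterov momentum, L2 weight decay on weight matrices (not biases),
// balanced-class minibatch sampling and best-validation-accuracy early
// stopping. All randomness is drawn from R's RNG so set.seed() in R makes
// training reproducible.

// [[Rcpp::depends(RcppArmadillo)]]
#include <RcppArmadillo.h>
#include <vector>

using namespace Rcpp;
using arma::fmat;
using arma::fvec;
using arma::umat;
using arma::uword;

struct Weights {
  int n_views;
  std::vector<fmat> W1, W2, W3;  // [out_ch, in_ch*k*k] per view
  std::vector<fvec> b1, b2, b3;
  fmat fc1W, fc2W;  // [units, D], [2, units]
  fvec fc1b, fc2b;
};

static fmat as_fmat(SEXP s) {
  NumericMatrix m(s);
  fmat out(m.nrow(), m.ncol());
  for (int j = 0; j < m.ncol(); ++j)
    for (int i = 0; i < m.nrow(); ++i) out(i, j) = (float)m(i, j);
  return out;
}
static fvec as_fvec(SEXP s) {
  NumericVector v(s);
  fvec out(v.size());
  for (int i = 0; i < v.size(); ++i) out[i] = (float)v[i];
  return out;
}
static NumericMatrix to_rmat(const fmat& m) {
  NumericMatrix out(m.n_rows, m.n_cols);
  for (uword j = 0; j < m.n_cols; ++j)
    for (uword i = 0; i < m.n_rows; ++i) out(i, j) = m(i, j);
  return out;
}
static NumericVector to_rvec(const fvec& v) {
  NumericVector out(v.n_elem);
  for (uword i = 0; i < v.n_elem; ++i) out[i] = v[i];
  return out;
}

static Weights parse_weights(const List& wl) {
  Weights W;
  List views = wl["views"];
  W.n_views = views.size();
  for (int v = 0; v < W.n_views; ++v) {
    List br = views[v];
    W.W1.push_back(as_fmat(br["W1"]));
    W.b1.push_back(as_fvec(br["b1"]));
    W.W2.push_back(as_fmat(br["W2"]));
    W.b2.push_back(as_fvec(br["b2"]));
    W.W3.push_back(as_fmat(br["W3"]));
    W.b3.push_back(as_fvec(br["b3"]));
  }
  W.fc1W = as_fmat(wl["fc1W"]);
  W.fc1b = as_fvec(wl["fc1b"]);
  W.fc2W = as_fmat(wl["fc2W"]);
  W.fc2b = as_fvec(wl["fc2b"]);
  return W;
}

static List weights_to_list(const Weights& W) {
  List views(W.n_views);
  for (int v = 0; v < W.n_views; ++v) {
    views[v] = List::create(
        _["W1"] = to_rmat(W.W1[v]), _["b1"] = to_rvec(W.b1[v]),
        _["W2"] = to_rmat(W.W2[v]), _["b2"] = to_rvec(W.b2[v]),
        _["W3"] = to_rmat(W.W3[v]), _["b3"] = to_rvec(W.b3[v]));
  }
  return List::create(_["views"] = views, _["fc1W"] = to_rmat(W.fc1W),
                      _["fc1b"] = to_rvec(W.fc1b),
                      _["fc2W"] = to_rmat(W.fc2W),
                      _["fc2b"] = to_rvec(W.fc2b));
}

// Layout: activation tensors are fmat [channels, N*h*w] with column index
// n*(h*w) + j*w + i  (i fastest, matching R's column-major patch arrays).
static void im2col(const fmat& X, int ch, int N, int h, int w, int k,
                   fmat& C, int& oh, int& ow) {
  oh = h - k + 1;
  ow = w - k + 1;
  const long npos = (long)oh * ow;
  C.set_size((uword)ch * k * k, (uword)N * npos);
  for (int n = 0; n < N; ++n)
    for (int oj = 0; oj < oh; ++oj)
      for (int oi = 0; oi < ow; ++oi) {
        const uword col = (uword)n * npos + (uword)oj * ow + oi;
        float* dst = C.colptr(col);
        for (int c = 0; c < ch; ++c)
          for (int kj = 0; kj < k; ++kj) {
            const uword src = (uword)n * h * w + (uword)(oj + kj) * w + oi;
            const float* xp = X.colptr(src);  // contiguous over ki
            for (int ki = 0; ki < k; ++ki)
              dst[c * k * k + kj * k + ki] = X(c, src + ki);
            (void)xp;
          }
      }
}

static void col2im(const fmat& dC, int ch, int N, int h, int w, int k,
                   fmat& dX) {
  const int oh = h - k + 1, ow = w - k + 1;
  const long npos = (long)oh * ow;
  dX.zeros((uword)ch, (uword)N * h * w);
  for (int n = 0; n < N; ++n)
    for (int oj = 0; oj < oh; ++oj)
      for (int oi = 0; oi < ow; ++oi) {
        const uword col = (uword)n * npos + (uword)oj * ow + oi;
        const float* src = dC.colptr(col);
        for (int c = 0; c < ch; ++c)
          for (int kj = 0; kj < k; ++kj)
            for (int ki = 0; ki < k; ++ki)
              dX(c, (uword)n * h * w + (uword)(oj + kj) * w + oi + ki) +=
                  src[c * k * k + kj * k + ki];
      }
}

// 2x2 max pooling, stride 2, no padding; AR records the input column of the
// maximum for each (channel, output column); ties take the first element.
static void pool2(const fmat& A, int ch, int N, int h, int w, fmat& P,
                  umat& AR, int& ph, int& pw) {
  ph = (h - 2) / 2 + 1;
  pw = (w - 2) / 2 + 1;
  const long npos = (long)ph * pw;
  P.set_size((uword)ch, (uword)N * npos);
  AR.set_size((uword)ch, (uword)N * npos);
  for (int n = 0; n < N; ++n)
    for (int pj = 0; pj < ph; ++pj)
      for (int pi = 0; pi < pw; ++pi) {
        const uword oc = (uword)n * npos + (uword)pj * pw + pi;
        for (int c = 0; c < ch; ++c) {
          float best = -std::numeric_limits<float>::infinity();
          uword barg = 0;
          for (int dj = 0; dj < 2; ++dj)
            for (int di = 0; di < 2; ++di) {
              const uword ic = (uword)n * h * w + (uword)(2 * pj + dj) * w +
                               2 * pi + di;
              const float val = A(c, ic);
              if (val > best) { best = val; barg = ic; }
            }
          P(c, oc) = best;
          AR(c, oc) = barg;
        }
      }
}

struct BranchCache {
  fmat X, C1, A1, P1, C2, A2, P2, C3, A3;
  umat AR1, AR2;
  int s, o1, p1, o2, p2, o3;
  int ch1, ch2, ch3;
};

struct FCCache {
  fmat Xfc, Hrelu, H, logits, probs;
};

// Extract view v of the patch array [s, s, V, N] into fmat [1, N*s*s].
static fmat view_slice(const NumericVector& patches, int s, int V, int N,
                       int v) {
  fmat X(1, (uword)N * s * s);
  const long block = (long)s * s;
  for (int n = 0; n < N; ++n) {
    const double* src = &patches[0] + block * (v + (long)V * n);
    float* dst = X.colptr((uword)n * block);
    // row 0 of consecutive columns is not contiguous in arma; copy by column
    for (long p = 0; p < block; ++p) X(0, (uword)n * block + p) = (float)src[p];
    (void)dst;
  }
  return X;
}

static void branch_forward(const Weights& W, int v, BranchCache& B, int N) {
  const int k1 = (int)std::lround(std::sqrt((double)W.W1[v].n_cols));
  B.ch1 = W.W1[v].n_rows;
  B.ch2 = W.W2[v].n_rows;
  B.ch3 = W.W3[v].n_rows;
  const int k2 = (int)std::lround(std::sqrt((double)W.W2[v].n_cols / B.ch1));
  const int k3 = (int)std::lround(std::sqrt((double)W.W3[v].n_cols / B.ch2));
  int oh, ow, ph, pw;
  im2col(B.X, 1, N, B.s, B.s, k1, B.C1, oh, ow);
  B.o1 = oh;
  B.A1 = W.W1[v] * B.C1;
  B.A1.each_col() += W.b1[v];
  B.A1.transform([](float x) { return x > 0.0f ? x : 0.0f; });
  pool2(B.A1, B.ch1, N, B.o1, B.o1, B.P1, B.AR1, ph, pw);
  B.p1 = ph;
  im2col(B.P1, B.ch1, N, B.p1, B.p1, k2, B.C2, oh, ow);
  B.o2 = oh;
  B.A2 = W.W2[v] * B.C2;
  B.A2.each_col() += W.b2[v];
  B.A2.transform([](float x) { return x > 0.0f ? x : 0.0f; });
  pool2(B.A2, B.ch2, N, B.o2, B.o2, B.P2, B.AR2, ph, pw);
  B.p2 = ph;
  im2col(B.P2, B.ch2, N, B.p2, B.p2, k3, B.C3, oh, ow);
  B.o3 = oh;
  B.A3 = W.W3[v] * B.C3;
  B.A3.each_col() += W.b3[v];
  B.A3.transform([](float x) { return x > 0.0f ? x : 0.0f; });
}

// Full forward pass. If `dropout_mask` is non-null it is applied to the
// hidden FC activations (training mode); the mask is already scaled by
// 1/keep ("inverted" dropout).
static void forward(const Weights& W, const NumericVector& patches, int s,
                    int V, int N, std::vector<BranchCache>& BC, FCCache& FC,
                    const fmat* dropout_mask) {
  BC.resize(V);
  uword D = 0;
  for (int v = 0; v < V; ++v) {
    BC[v].s = s;
    BC[v].X = view_slice(patches, s, V, N, v);
    branch_forward(W, v, BC[v], N);
    D += (uword)BC[v].ch3 * BC[v].o3 * BC[v].o3;
  }
  FC.Xfc.set_size(D, (uword)N);
  uword off = 0;
  for (int v = 0; v < V; ++v) {
    const int hw = BC[v].o3 * BC[v].o3, ch = BC[v].ch3;
    for (int n = 0; n < N; ++n)
      for (int c = 0; c < ch; ++c)
        for (int p = 0; p < hw; ++p)
          FC.Xfc(off + (uword)c * hw + p, n) = BC[v].A3(c, (uword)n * hw + p);
    off += (uword)ch * hw;
  }
  FC.Hrelu = W.fc1W * FC.Xfc;
  FC.Hrelu.each_col() += W.fc1b;
  FC.Hrelu.transform([](float x) { return x > 0.0f ? x : 0.0f; });
  FC.H = dropout_mask ? (FC.Hrelu % (*dropout_mask)) : FC.Hrelu;
  FC.logits = W.fc2W * FC.H;
  FC.logits.each_col() += W.fc2b;
  FC.probs = FC.logits;
  for (uword n = 0; n < FC.probs.n_cols; ++n) {
    const float m = FC.probs.col(n).max();
    FC.probs.col(n) = arma::exp(FC.probs.col(n) - m);
    FC.probs.col(n) /= arma::accu(FC.probs.col(n));
  }
}

struct Grads {
  std::vector<fmat> W1, W2, W3;
  std::vector<fvec> b1, b2, b3;
  fmat fc1W, fc2W;
  fvec fc1b, fc2b;
};

static float l2_penalty(const Weights& W, float lambda) {
  float s = 0.0f;
  for (int v = 0; v < W.n_views; ++v)
    s += arma::accu(arma::square(W.W1[v])) +
         arma::accu(arma::square(W.W2[v])) +
         arma::accu(arma::square(W.W3[v]));
  s += arma::accu(arma::square(W.fc1W)) + arma::accu(arma::square(W.fc2W));
  return lambda * s;
}

// Backward pass for cross-entropy + L2; labels in {0,1}, class 1 = node.
static float backward(const Weights& W, std::vector<BranchCache>& BC,
                      FCCache& FC, const IntegerVector& labels,
                      const std::vector<int>& idx, float lambda,
                      const fmat* dropout_mask, Grads& G) {
  const int N = FC.probs.n_cols, V = W.n_views;
  fmat Y(2, N, arma::fill::zeros);
  float ce = 0.0f;
  for (int n = 0; n < N; ++n) {
    const int y = labels[idx[n]];
    Y(y, n) = 1.0f;
    ce -= std::log(std::max(FC.probs(y, n), 1e-12f));
  }
  ce /= N;
  fmat dL = (FC.probs - Y) / (float)N;
  G.fc2W = dL * FC.H.t() + 2.0f * lambda * W.fc2W;
  G.fc2b = arma::sum(dL, 1);
  fmat dH = W.fc2W.t() * dL;
  if (dropout_mask) dH %= (*dropout_mask);
  dH %= arma::conv_to<fmat>::from(FC.Hrelu > 0.0f);
  G.fc1W = dH * FC.Xfc.t() + 2.0f * lambda * W.fc1W;
  G.fc1b = arma::sum(dH, 1);
  fmat dXfc = W.fc1W.t() * dH;
  G.W1.assign(V, fmat());
  G.W2.assign(V, fmat());
  G.W3.assign(V, fmat());
  G.b1.assign(V, fvec());
  G.b2.assign(V, fvec());
  G.b3.assign(V, fvec());
  uword off = 0;
  for (int v = 0; v < V; ++v) {
    BranchCache& B = BC[v];
    const int hw = B.o3 * B.o3, ch = B.ch3;
    fmat dA3(ch, (uword)N * hw);
    for (int n = 0; n < N; ++n)
      for (int c = 0; c < ch; ++c)
        for (int p = 0; p < hw; ++p)
          dA3(c, (uword)n * hw + p) = dXfc(off + (uword)c * hw + p, n);
    off += (uword)ch * hw;
    dA3 %= arma::conv_to<fmat>::from(B.A3 > 0.0f);
    G.W3[v] = dA3 * B.C3.t() + 2.0f * lambda * W.W3[v];
    G.b3[v] = arma::sum(dA3, 1);
    const int k3 = (int)std::lround(std::sqrt((double)W.W3[v].n_cols / B.ch2));
    fmat dC3 = W.W3[v].t() * dA3;
    fmat dP2;
    col2im(dC3, B.ch2, N, B.p2, B.p2, k3, dP2);
    // pool backward
    fmat dA2(B.ch2, (uword)N * B.o2 * B.o2, arma::fill::zeros);
    for (uword oc = 0; oc < dP2.n_cols; ++oc)
      for (int c = 0; c < B.ch2; ++c)
        dA2(c, B.AR2(c, oc)) += dP2(c, oc);
    dA2 %= arma::conv_to<fmat>::from(B.A2 > 0.0f);
    G.W2[v] = dA2 * B.C2.t() + 2.0f * lambda * W.W2[v];
    G.b2[v] = arma::sum(dA2, 1);
    const int k2 = (int)std::lround(std::sqrt((double)W.W2[v].n_cols / B.ch1));
    fmat dC2 = W.W2[v].t() * dA2;
    fmat dP1;
    col2im(dC2, B.ch1, N, B.p1, B.p1, k2, dP1);
    fmat dA1(B.ch1, (uword)N * B.o1 * B.o1, arma::fill::zeros);
    for (uword oc = 0; oc < dP1.n_cols; ++oc)
      for (int c = 0; c < B.ch1; ++c)
        dA1(c, B.AR1(c, oc)) += dP1(c, oc);
    dA1 %= arma::conv_to<fmat>::from(B.A1 > 0.0f);
    G.W1[v] = dA1 * B.C1.t() + 2.0f * lambda * W.W1[v];
    G.b1[v] = arma::sum(dA1, 1);
  }
  return ce + l2_penalty(W, lambda);
}

// Gather samples `idx` (0-based) of patch array [s,s,V,N] into a contiguous
// sub-array [s,s,V,n].
static NumericVector gather_samples(const NumericVector& patches, int s,
                                    int V, const std::vector<int>& idx) {
  const long block = (long)s * s * V;
  NumericVector out(block * idx.size());
  for (size_t n = 0; n < idx.size(); ++n)
    std::copy(&patches[0] + block * idx[n], &patches[0] + block * (idx[n] + 1),
              &out[0] + block * n);
  return out;
}

// [[Rcpp::export(name = ".cnnPredict")]]
List cnn_predict(List weights, NumericVector patches, bool trace = false) {
  const Weights W = parse_weights(weights);
  IntegerVector dim = patches.attr("dim");
  const int s = dim[0], V = dim[2], N = dim[3];
  if (V != W.n_views) stop("patch view count does not match the network");
  std::vector<BranchCache> BC;
  FCCache FC;
  NumericMatrix probs(N, 2);
  const int chunk = 64;
  List tr;
  for (int start = 0; start < N; start += chunk) {
    const int n = std::min(chunk, N - start);
    std::vector<int> idx(n);
    for (int t = 0; t < n; ++t) idx[t] = start + t;
    NumericVector sub = gather_samples(patches, s, V, idx);
    forward(W, sub, s, V, n, BC, FC, nullptr);
    for (int t = 0; t < n; ++t) {
      probs(start + t, 0) = FC.probs(0, t);
      probs(start + t, 1) = FC.probs(1, t);
    }
    if (trace && start == 0) {
      const BranchCache& B = BC[0];
      tr = List::create(
          _["input"] = IntegerVector::create(s, s, 1),
          _["conv1"] = IntegerVector::create(B.o1, B.o1, B.ch1),
          _["pool1"] = IntegerVector::create(B.p1, B.p1, B.ch1),
          _["conv2"] = IntegerVector::create(B.o2, B.o2, B.ch2),
          _["pool2"] = IntegerVector::create(B.p2, B.p2, B.ch2),
          _["conv3"] = IntegerVector::create(B.o3, B.o3, B.ch3),
          _["concat"] = IntegerVector::create(1, 1, (int)FC.Xfc.n_rows),
          _["fc1"] = IntegerVector::create(1, 1, (int)W.fc1W.n_rows),
          _["fc2"] = IntegerVector::create(1, 1, (int)W.fc2W.n_rows));
    }
  }
  if (trace) return List::create(_["probs"] = probs, _["trace"] = tr);
  return List::create(_["probs"] = probs);
}

// Loss and exact gradients on a fixed batch, evaluation mode (no dropout).
// Used by finite-difference gradient verification and smoke properties.
// [[Rcpp::export(name = ".cnnLossGrads")]]
List cnn_loss_grads(List weights, NumericVector patches,
                    IntegerVector labels, double lambda2) {
  const Weights W = parse_weights(weights);
  IntegerVector dim = patches.attr("dim");
  const int s = dim[0], V = dim[2], N = dim[3];
  std::vector<BranchCache> BC;
  FCCache FC;
  forward(W, patches, s, V, N, BC, FC, nullptr);
  std::vector<int> idx(N);
  for (int t = 0; t < N; ++t) idx[t] = t;
  Grads G;
  const float loss = backward(W, BC, FC, labels, idx, (float)lambda2, nullptr, G);
  List views(V);
  for (int v = 0; v < V; ++v)
    views[v] = List::create(
        _["W1"] = to_rmat(G.W1[v]), _["b1"] = to_rvec(G.b1[v]),
        _["W2"] = to_rmat(G.W2[v]), _["b2"] = to_rvec(G.b2[v]),
        _["W3"] = to_rmat(G.W3[v]), _["b3"] = to_rvec(G.b3[v]));
  List grads = List::create(_["views"] = views, _["fc1W"] = to_rmat(G.fc1W),
                            _["fc1b"] = to_rvec(G.fc1b),
                            _["fc2W"] = to_rmat(G.fc2W),
                            _["fc2b"] = to_rvec(G.fc2b));
  return List::create(_["loss"] = (double)loss, _["grads"] = grads);
}

static void sgd_update(fmat& w, fmat& vel, const fmat& g, float lr, float mu) {
  // Nesterov momentum (Sutskever form): v <- mu*v - lr*g ; w <- w + mu*v - lr*g
  vel = mu * vel - lr * g;
  w += mu * vel - lr * g;
}
static void sgd_update_v(fvec& w, fvec& vel, const fvec& g, float lr, float mu) {
  vel = mu * vel - lr * g;
  w += mu * vel - lr * g;
}

static double val_accuracy(const Weights& W, const NumericVector& patches,
                           const IntegerVector& labels, int s, int V, int N) {
  std::vector<BranchCache> BC;
  FCCache FC;
  int correct = 0;
  const int chunk = 64;
  for (int start = 0; start < N; start += chunk) {
    const int n = std::min(chunk, N - start);
    std::vector<int> idx(n);
    for (int t = 0; t < n; ++t) idx[t] = start + t;
    NumericVector sub = gather_samples(patches, s, V, idx);
    forward(W, sub, s, V, n, BC, FC, nullptr);
    for (int t = 0; t < n; ++t) {
      const int pred = FC.probs(1, t) >= 0.5f ? 1 : 0;
      if (pred == labels[start + t]) ++correct;
    }
  }
  return (double)correct / N;
}

// [[Rcpp::export(name = ".cnnTrain")]]
List cnn_train(List weights, NumericVector train_patches,
               IntegerVector train_labels, NumericVector val_patches,
               IntegerVector val_labels, List cfg) {
  Weights W = parse_weights(weights);
  IntegerVector dim = train_patches.attr("dim");
  const int s = dim[0], V = dim[2], Ntr = dim[3];
  IntegerVector vdim = val_patches.attr("dim");
  const int Nval = vdim[3];
  const float lr = (float)as<double>(cfg["learning_rate"]);
  const float mu = (float)as<double>(cfg["nesterov_momentum"]);
  const float lambda = (float)as<double>(cfg["l2_lambda"]);
  const float p_drop = (float)as<double>(cfg["dropout_fc"]);
  const int batch = as<int>(cfg["batch_size"]);
  const int mb_per_epoch = as<int>(cfg["minibatches_per_epoch"]);
  const int max_epochs = as<int>(cfg["max_epochs"]);
  const int patience = as<int>(cfg["early_stop_patience_epochs"]);
  const bool log_batches = cfg.containsElementNamed("log_batch_classes")
                               ? as<bool>(cfg["log_batch_classes"])
                               : false;

  std::vector<int> pos, neg;
  for (int i = 0; i < Ntr; ++i)
    (train_labels[i] == 1 ? pos : neg).push_back(i);
  if (pos.empty() || neg.empty())
    stop("training set must contain both classes");

  // velocities
  Weights Vel = W;
  for (int v = 0; v < W.n_views; ++v) {
    Vel.W1[v].zeros(); Vel.W2[v].zeros(); Vel.W3[v].zeros();
    Vel.b1[v].zeros(); Vel.b2[v].zeros(); Vel.b3[v].zeros();
  }
  Vel.fc1W.zeros(); Vel.fc1b.zeros(); Vel.fc2W.zeros(); Vel.fc2b.zeros();

  Weights best = W;
  double best_acc = -1.0;
  int best_epoch = -1, since_best = 0;
  std::vector<double> ep_loss, ep_acc;
  std::vector<int> batch_pos_counts;
  std::vector<BranchCache> BC;
  FCCache FC;
  Grads G;
  const int half = batch / 2;

  int epoch = 0;
  for (; epoch < max_epochs; ++epoch) {
    double loss_sum = 0.0;
    for (int mb = 0; mb < mb_per_epoch; ++mb) {
      // balanced minibatch: half positives, half negatives, with replacement
      std::vector<int> idx(batch);
      for (int t = 0; t < half; ++t)
        idx[t] = pos[(int)(unif_rand() * pos.size()) % pos.size()];
      for (int t = half; t < batch; ++t)
        idx[t] = neg[(int)(unif_rand() * neg.size()) % neg.size()];
      if (log_batches) {
        int np = 0;
        for (int t = 0; t < batch; ++t) np += (train_labels[idx[t]] == 1);
        batch_pos_counts.push_back(np);
      }
      NumericVector sub = gather_samples(train_patches, s, V, idx);
      // dropout mask for the hidden FC layer (inverted scaling)
      fmat mask;
      fmat* maskp = nullptr;
      if (p_drop > 0.0f) {
        mask.set_size(W.fc1W.n_rows, (uword)batch);
        const float keep = 1.0f - p_drop;
        for (uword j = 0; j < mask.n_cols; ++j)
          for (uword i = 0; i < mask.n_rows; ++i)
            mask(i, j) = (unif_rand() < keep) ? 1.0f / keep : 0.0f;
        maskp = &mask;
      }
      forward(W, sub, s, V, batch, BC, FC, maskp);
      loss_sum += backward(W, BC, FC, train_labels, idx, lambda, maskp, G);
      for (int v = 0; v < W.n_views; ++v) {
        sgd_update(W.W1[v], Vel.W1[v], G.W1[v], lr, mu);
        sgd_update_v(W.b1[v], Vel.b1[v], G.b1[v], lr, mu);
        sgd_update(W.W2[v], Vel.W2[v], G.W2[v], lr, mu);
        sgd_update_v(W.b2[v], Vel.b2[v], G.b2[v], lr, mu);
        sgd_update(W.W3[v], Vel.W3[v], G.W3[v], lr, mu);
        sgd_update_v(W.b3[v], Vel.b3[v], G.b3[v], lr, mu);
      }
      sgd_update(W.fc1W, Vel.fc1W, G.fc1W, lr, mu);
      sgd_update_v(W.fc1b, Vel.fc1b, G.fc1b, lr, mu);
      sgd_update(W.fc2W, Vel.fc2W, G.fc2W, lr, mu);
      sgd_update_v(W.fc2b, Vel.fc2b, G.fc2b, lr, mu);
    }
    ep_loss.push_back(loss_sum / mb_per_epoch);
    const double acc = val_accuracy(W, val_patches, val_labels, s, V, Nval);
    ep_acc.push_back(acc);
    if (acc > best_acc) {
      best_acc = acc;
      best = W;
      best_epoch = epoch;
      since_best = 0;
    } else if (++since_best > patience) {
      ++epoch;
      break;
    }
    Rcpp::checkUserInterrupt();
  }

  List out = List::create(
      _["weights"] = weights_to_list(best),
      _["history"] = DataFrame::create(
          _["epoch"] = seq_len(ep_loss.size()),
          _["train_loss"] = NumericVector(ep_loss.begin(), ep_loss.end()),
          _["val_accuracy"] = NumericVector(ep_acc.begin(), ep_acc.end())),
      _["best_epoch"] = best_epoch + 1,
      _["best_val_accuracy"] = best_acc);
  if (log_batches)
    out["batch_pos_counts"] =
        IntegerVector(batch_pos_counts.begin(), batch_pos_counts.end());
  return out;
}
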