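// Minimal fully-convolutional network engine for the one-stage detector:
// 3x3/1x1 convolutions (im2col + GEMM), leaky-ReLU activations, and the
// matching backward pass. Layer topology is a DAG described from R as a
// list of layers, each naming the activation it consumes, so two detection
// heads can branch off one backbone.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;
using arma::mat;

struct LayerSpec {
  int in_ch, out_ch, k, stride, pad, input; // input: 0 = image, else layer id
  bool lrelu;
};

static std::vector<LayerSpec> parseLayers(const List& layers) {
  std::vector<LayerSpec> specs;
  for (int i = 0; i < layers.size(); ++i) {
    List l = layers[i];
    LayerSpec s;
    s.in_ch = as<int>(l["in"]);
    s.out_ch = as<int>(l["out"]);
    s.k = as<int>(l["k"]);
    s.stride = as<int>(l["stride"]);
    s.pad = s.k / 2;
    s.input = as<int>(l["input"]);
    s.lrelu = as<bool>(l["lrelu"]);
    specs.push_back(s);
  }
  return specs;
}

// Activation storage: (channels x H*W), pixel index q = y * W + x.
static mat im2col(const mat& X, int H, int W, int k, int stride, int pad,
                  int Ho, int Wo) {
  const int C = X.n_rows;
  mat col(C * k * k, Ho * Wo, arma::fill::zeros);
  double* cp = col.memptr();
  const double* xp = X.memptr();
  const int nrow = C * k * k;
  // fill column-major: output pixel q outer, patch entries inner
  for (int yo = 0; yo < Ho; ++yo)
    for (int xo = 0; xo < Wo; ++xo) {
      double* dst = cp + (size_t)(yo * Wo + xo) * nrow;
      for (int ky = 0; ky < k; ++ky) {
        const int y = yo * stride - pad + ky;
        if (y < 0 || y >= H) continue;
        for (int kx = 0; kx < k; ++kx) {
          const int x = xo * stride - pad + kx;
          if (x < 0 || x >= W) continue;
          const double* src = xp + (size_t)(y * W + x) * C;
          for (int c = 0; c < C; ++c)
            dst[c * k * k + ky * k + kx] = src[c];
        }
      }
    }
  return col;
}

static void col2im_add(const mat& col, mat& dX, int H, int W, int k,
                       int stride, int pad, int Ho, int Wo) {
  const int C = dX.n_rows;
  const int nrow = C * k * k;
  const double* cp = col.memptr();
  double* xp = dX.memptr();
  for (int yo = 0; yo < Ho; ++yo)
    for (int xo = 0; xo < Wo; ++xo) {
      const double* src = cp + (size_t)(yo * Wo + xo) * nrow;
      for (int ky = 0; ky < k; ++ky) {
        const int y = yo * stride - pad + ky;
        if (y < 0 || y >= H) continue;
        for (int kx = 0; kx < k; ++kx) {
          const int x = xo * stride - pad + kx;
          if (x < 0 || x >= W) continue;
          double* dst = xp + (size_t)(y * W + x) * C;
          for (int c = 0; c < C; ++c)
            dst[c] += src[c * k * k + ky * k + kx];
        }
      }
    }
}

struct ForwardState {
  std::vector<mat> acts;        // acts[0] = image, acts[i] = layer i output
  std::vector<int> Hs, Ws;      // spatial dims per activation
};

static ForwardState runForward(const List& weights, const List& layers,
                               const mat& image, int H, int W) {
  std::vector<LayerSpec> specs = parseLayers(layers);
  ForwardState st;
  st.acts.push_back(image);
  st.Hs.push_back(H);
  st.Ws.push_back(W);
  for (size_t i = 0; i < specs.size(); ++i) {
    const LayerSpec& s = specs[i];
    List wl = weights[i];
    mat Wm = as<mat>(wl["W"]);           // (out_ch x in_ch*k*k)
    arma::vec b = as<arma::vec>(wl["b"]);
    const mat& X = st.acts[s.input];
    const int Hi = st.Hs[s.input], Wi = st.Ws[s.input];
    const int Ho = (Hi + 2 * s.pad - s.k) / s.stride + 1;
    const int Wo = (Wi + 2 * s.pad - s.k) / s.stride + 1;
    mat col = im2col(X, Hi, Wi, s.k, s.stride, s.pad, Ho, Wo);
    mat Y = Wm * col;
    Y.each_col() += b;
    if (s.lrelu) Y = arma::max(Y, 0.1 * Y);
    st.acts.push_back(Y);
    st.Hs.push_back(Ho);
    st.Ws.push_back(Wo);
  }
  return st;
}

// Forward pass returning every activation (for training) or only the
// requested head layers (for inference).
// [[Rcpp::export]]
List net_forward(const List& weights, const List& layers,
                 const arma::mat& image, int H, int W, bool keepAll) {
  ForwardState st = runForward(weights, layers, image, H, W);
  int n = st.acts.size();
  List acts(keepAll ? n : 0);
  if (keepAll)
    for (int i = 0; i < n; ++i) acts[i] = wrap(st.acts[i]);
  return List::create(_["acts"] = acts,
                      _["H"] = wrap(st.Hs), _["W"] = wrap(st.Ws),
                      _["last"] = wrap(st.acts[n - 1]));
}

// Backward pass over activations previously returned by net_forward
// (keepAll = TRUE). headGrads: named list mapping layer index (1-based,
// as string) to a (channels x H*W) gradient matrix of the loss wrt that
// layer's output. Returns per-layer dW, db.
// [[Rcpp::export]]
List net_backward(const List& weights, const List& layers,
                  const List& acts, const IntegerVector& Hs,
                  const IntegerVector& Ws, const List& headGrads) {
  std::vector<LayerSpec> specs = parseLayers(layers);
  ForwardState st;
  for (int i = 0; i < acts.size(); ++i) {
    st.acts.push_back(as<mat>(acts[i]));
    st.Hs.push_back(Hs[i]);
    st.Ws.push_back(Ws[i]);
  }
  const int nL = specs.size();
  std::vector<mat> dacts(nL + 1);
  for (int i = 0; i <= nL; ++i)
    dacts[i] = mat(st.acts[i].n_rows, st.acts[i].n_cols, arma::fill::zeros);
  CharacterVector nms = headGrads.names();
  for (int i = 0; i < headGrads.size(); ++i) {
    std::string s(nms[i]);
    int idx = 0;                 // manual digit parse (layer index)
    for (char ch : s) if (ch >= '0' && ch <= '9') idx = idx * 10 + (ch - '0');
    dacts[idx] += as<mat>(headGrads[i]);
  }
  List grads(nL);
  for (int i = nL - 1; i >= 0; --i) {
    const LayerSpec& s = specs[i];
    mat dY = dacts[i + 1];
    if (arma::norm(dY, "fro") == 0.0) {   // nothing flows through this layer
      List wl = weights[i];
      mat Wm = as<mat>(wl["W"]);
      grads[i] = List::create(_["dW"] = wrap(mat(Wm.n_rows, Wm.n_cols,
                                                 arma::fill::zeros)),
                              _["db"] = wrap(arma::vec(s.out_ch,
                                                       arma::fill::zeros)));
      continue;
    }
    if (s.lrelu) {
      const mat& A = st.acts[i + 1];
      dY %= arma::conv_to<mat>::from(A > 0) * 0.9 + 0.1;
    }
    List wl = weights[i];
    mat Wm = as<mat>(wl["W"]);
    const int Hi = st.Hs[s.input], Wi = st.Ws[s.input];
    const int Ho = st.Hs[i + 1], Wo = st.Ws[i + 1];
    mat col = im2col(st.acts[s.input], Hi, Wi, s.k, s.stride, s.pad, Ho, Wo);
    mat dW = dY * col.t();
    arma::vec db = arma::sum(dY, 1);
    if (s.input > 0) {                    // no gradient wrt the input image
      mat dcol = Wm.t() * dY;
      col2im_add(dcol, dacts[s.input], Hi, Wi, s.k, s.stride, s.pad, Ho, Wo);
    }
    grads[i] = List::create(_["dW"] = wrap(dW), _["db"] = wrap(db));
  }
  return grads;
}
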