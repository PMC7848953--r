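#include <Rcpp.h>
#include "mlp_internal.h"
using namespace Rcpp;

// Activation codes: 0 = linear, 1 = sigmoid, 2 = leaky ReLU (slope alpha for z < 0).

double mlp_act_fun(double z, int code, double alpha) {
  switch (code) {
  case 1: return 1.0 / (1.0 + std::exp(-z));
  case 2: return z > 0 ? z : alpha * z;
  default: return z;
  }
}

// Derivative expressed through the post-activation value a.  Valid because
// sigmoid and leaky ReLU derivatives are recoverable from their outputs.
double mlp_act_deriv(double a, int code, double alpha) {
  switch (code) {
  case 1: return a * (1.0 - a);
  case 2: return a > 0 ? 1.0 : alpha;
  default: return 1.0;
  }
}

// Forward pass keeping all per-layer activations (cache for backprop).
// [[Rcpp::export]]
List mlp_forward_cpp(List Ws, List bs, IntegerVector act, NumericVector alpha,
                     NumericVector x) {
  int L = Ws.size();
  List cache(L + 1);
  cache[0] = x;
  NumericVector a = x;
  for (int l = 0; l < L; ++l) {
    NumericMatrix W = Ws[l];
    NumericVector b = bs[l];
    int nout = W.nrow(), nin = W.ncol();
    if (nin != a.size()) stop("layer %d: expected input length %d, got %d",
                              l + 1, nin, (int)a.size());
    NumericVector z = clone(b);
    double *zp = REAL(z);
    const double *Wp = REAL(W);
    const double *ap = REAL(a);
    for (int j = 0; j < nin; ++j) {
      double aj = ap[j];
      if (aj != 0.0) {
        const double *col = Wp + (size_t)j * nout;
        for (int i = 0; i < nout; ++i) zp[i] += col[i] * aj;
      }
    }
    int code = act[l]; double al = alpha[l];
    for (int i = 0; i < nout; ++i) zp[i] = mlp_act_fun(zp[i], code, al);
    cache[l + 1] = z;
    a = z;
  }
  return cache;
}

// Output values only (no cache); used for TD targets.
// [[Rcpp::export]]
NumericVector mlp_output_cpp(List Ws, List bs, IntegerVector act,
                             NumericVector alpha, NumericVector x) {
  int L = Ws.size();
  NumericVector a = x;
  for (int l = 0; l < L; ++l) {
    NumericMatrix W = Ws[l];
    NumericVector b = bs[l];
    int nout = W.nrow(), nin = W.ncol();
    if (nin != a.size()) stop("layer %d: expected input length %d, got %d",
                              l + 1, nin, (int)a.size());
    NumericVector z = clone(b);
    double *zp = REAL(z);
    const double *Wp = REAL(W);
    const double *ap = REAL(a);
    for (int j = 0; j < nin; ++j) {
      double aj = ap[j];
      if (aj != 0.0) {
        const double *col = Wp + (size_t)j * nout;
        for (int i = 0; i < nout; ++i) zp[i] += col[i] * aj;
      }
    }
    int code = act[l]; double al = alpha[l];
    for (int i = 0; i < nout; ++i) zp[i] = mlp_act_fun(zp[i], code, al);
    a = z;
  }
  return a;
}

// Semi-gradient TD update through a single selected output unit.  The TD
// error delta is treated as a constant: w <- w + lr * delta * dQ_k/dw.
// Mutates Ws/bs in place (reference semantics; callers needing a snapshot
// must clone first).  grad_scale lets minibatch code accumulate instead.
void mlp_backprop_selected(List Ws, List bs, IntegerVector act,
                           NumericVector alpha, List cache, int k,
                           double scale) {
  int L = Ws.size();
  NumericVector a_out = cache[L];
  int nout_last = a_out.size();
  if (k < 1 || k > nout_last) stop("selected output index out of range");
  // Gradient of output unit k w.r.t. its own pre-activation.
  std::vector<double> g(nout_last, 0.0);
  g[k - 1] = mlp_act_deriv(a_out[k - 1], act[L - 1], alpha[L - 1]);
  for (int l = L - 1; l >= 0; --l) {
    NumericMatrix W = Ws[l];
    NumericVector b = bs[l];
    NumericVector a_in = cache[l];
    int nout = W.nrow(), nin = W.ncol();
    double *Wp = REAL(W);
    double *bp = REAL(b);
    const double *ain = REAL(a_in);
    std::vector<double> g_prev;
    if (l > 0) {
      g_prev.assign(nin, 0.0);
      for (int j = 0; j < nin; ++j) {
        const double *col = Wp + (size_t)j * nout;
        double s = 0.0;
        for (int i = 0; i < nout; ++i) s += col[i] * g[i];
        g_prev[j] = s * mlp_act_deriv(ain[j], act[l - 1], alpha[l - 1]);
      }
    }
    for (int i = 0; i < nout; ++i) if (g[i] != 0.0) bp[i] += scale * g[i];
    for (int j = 0; j < nin; ++j) {
      double saj = scale * ain[j];
      if (saj != 0.0) {
        double *col = Wp + (size_t)j * nout;
        for (int i = 0; i < nout; ++i) col[i] += g[i] * saj;
      }
    }
    if (l > 0) g.swap(g_prev);
  }
}

// [[Rcpp::export]]
void mlp_update_selected_cpp(List Ws, List bs, IntegerVector act,
                             NumericVector alpha, List cache, int k,
                             double delta, double lr) {
  if (delta == 0.0) return;
  mlp_backprop_selected(Ws, bs, act, alpha, cache, k, lr * delta);
}

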