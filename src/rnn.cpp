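#include <Rcpp.h>
using namespace Rcpp;

// One TD(0) batch for the conditioning RNN: forward unroll of
// h_t = sigmoid(W_in x_t + W_rec h_{t-1}), v_t = w_out h_t, per-step TD
// errors delta_t = r_t + gamma v_{t+1} - v_t (v_{T+1} = 0), and the
// semi-gradient backward pass through time (delta constant, credit carried
// through the stored activations for `truncate` steps). Returns the batch
// gradient sums for w_out and w_rec; w_in stays frozen.
// cues/mots/rews are T x B; w_in is H x 2, w_rec H x H, w_out 1 x H.
// [[Rcpp::export]]
List rnn_td_batch_cpp(NumericMatrix w_in, NumericMatrix w_rec,
                      NumericMatrix w_out, NumericMatrix cues,
                      NumericMatrix mots, NumericMatrix rews,
                      double gamma, double truncate_steps) {
  const int T = cues.nrow(), B = cues.ncol(), H = w_rec.nrow();
  const double *Winp = REAL(w_in), *Wrecp = REAL(w_rec), *Woutp = REAL(w_out);
  std::vector<double> Hs((size_t)T * H * B);      // activations
  std::vector<double> V((size_t)T * B), delta((size_t)T * B);
  std::vector<double> hprev(H), z(H);
  // forward
  for (int b = 0; b < B; ++b) {
    std::fill(hprev.begin(), hprev.end(), 0.0);
    for (int t = 0; t < T; ++t) {
      double cue = cues(t, b), mot = mots(t, b);
      for (int i = 0; i < H; ++i)
        z[i] = Winp[i] * cue + Winp[H + i] * mot;
      for (int j = 0; j < H; ++j) {
        double hj = hprev[j];
        if (hj != 0.0) {
          const double *col = Wrecp + (size_t)j * H;
          for (int i = 0; i < H; ++i) z[i] += col[i] * hj;
        }
      }
      double v = 0.0;
      double *ht = &Hs[((size_t)t * B + b) * H];
      for (int i = 0; i < H; ++i) {
        double h = 1.0 / (1.0 + std::exp(-z[i]));
        ht[i] = h;
        v += Woutp[i] * h;
        hprev[i] = h;
      }
      V[(size_t)t * B + b] = v;
    }
    for (int t = 0; t < T; ++t) {
      double vnext = (t + 1 < T) ? V[(size_t)(t + 1) * B + b] : 0.0;
      delta[(size_t)t * B + b] =
        rews(t, b) + gamma * vnext - V[(size_t)t * B + b];
    }
  }
  // backward through time
  NumericMatrix dW_out(1, H), dW_rec(H, H);
  double *dWo = REAL(dW_out), *dWr = REAL(dW_rec);
  std::vector<double> Gpre(H), G(H);
  for (int b = 0; b < B; ++b) {
    std::fill(Gpre.begin(), Gpre.end(), 0.0);
    int age = 0;
    for (int t = T - 1; t >= 0; --t) {
      const double *ht = &Hs[((size_t)t * B + b) * H];
      double d = delta[(size_t)t * B + b];
      for (int i = 0; i < H; ++i) dWo[i] += d * ht[i];
      // G = w_out^T d + W_rec^T Gpre
      for (int j = 0; j < H; ++j) {
        double s = Woutp[j] * d;
        if (age > 0) {
          const double *col = Wrecp + (size_t)j * H;
          for (int i = 0; i < H; ++i) s += col[i] * Gpre[i];
        }
        G[j] = s;
      }
      for (int i = 0; i < H; ++i) Gpre[i] = G[i] * ht[i] * (1.0 - ht[i]);
      if (t > 0) {
        const double *hp = &Hs[((size_t)(t - 1) * B + b) * H];
        for (int j = 0; j < H; ++j) {
          double hj = hp[j];
          if (hj != 0.0) {
            double *col = dWr + (size_t)j * H;
            for (int i = 0; i < H; ++i) col[i] += Gpre[i] * hj;
          }
        }
      }
      ++age;
      if (age >= truncate_steps) {
        std::fill(Gpre.begin(), Gpre.end(), 0.0);
        age = 0;
      }
    }
  }
  NumericMatrix Vout(T, B);
  std::copy(V.begin(), V.end(), REAL(Vout));
  return List::create(_["dW_out"] = dW_out, _["dW_rec"] = dW_rec,
                      _["V"] = Vout);
}
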