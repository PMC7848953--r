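#include <Rcpp.h>
#include "mlp_internal.h"
using namespace Rcpp;

// Compiled inner loop for closed-loop (unsupervised) manager training on the
// transport task. Semantics mirror the R-level components: the manager
// (epsilon-greedy) edits the motivation estimate, the frozen trained agent
// (softmax over adjacent cities) acts on the edited estimate, and only the
// sign of the agent's reward returns to the manager (+5 positive, -2
// negative, -1 after "do nothing"). Episodes are capped at `max_steps`
// manager steps; semi-gradients are summed over minibatches of manager
// steps and applied in one step (minibatch = 1 gives per-step updates).
// All randomness uses R's RNG stream.
//
// The manager's Q(s') for the TD target equals the next iteration's policy
// forward pass (same input), so each step runs one manager forward, not two.

namespace {

// Flat-buffer network: weights viewed in place, activations preallocated.
struct FlatNet {
  int L;
  std::vector<double *> W, b;
  std::vector<int> nin, nout, code;
  std::vector<double> alpha;
  std::vector<std::vector<double>> a;  // a[0] = input, a[l] = layer output
  FlatNet(List Ws, List bs, IntegerVector act, NumericVector al) {
    L = Ws.size();
    for (int l = 0; l < L; ++l) {
      NumericMatrix Wl = Ws[l];
      NumericVector bl = bs[l];
      W.push_back(REAL(Wl));
      b.push_back(REAL(bl));
      nin.push_back(Wl.ncol());
      nout.push_back(Wl.nrow());
      code.push_back(act[l]);
      alpha.push_back(al[l]);
    }
    a.resize(L + 1);
    a[0].resize(nin[0]);
    for (int l = 0; l < L; ++l) a[l + 1].resize(nout[l]);
  }
  void forward() {
    for (int l = 0; l < L; ++l) {
      const double *Wl = W[l];
      double *out = a[l + 1].data();
      const double *in = a[l].data();
      std::copy(b[l], b[l] + nout[l], out);
      for (int j = 0; j < nin[l]; ++j) {
        double aj = in[j];
        if (aj != 0.0) {
          const double *col = Wl + (size_t)j * nout[l];
          for (int i = 0; i < nout[l]; ++i) out[i] += col[i] * aj;
        }
      }
      for (int i = 0; i < nout[l]; ++i)
        out[i] = mlp_act_fun(out[i], code[l], alpha[l]);
    }
  }
};

// Selected-output semi-gradient (delta constant) accumulated into flat
// buffers; `acts` is a snapshot of the activations of the transition.
struct GradBuf {
  std::vector<std::vector<double>> gW, gb;
  explicit GradBuf(const FlatNet &net) {
    for (int l = 0; l < net.L; ++l) {
      gW.emplace_back((size_t)net.nin[l] * net.nout[l], 0.0);
      gb.emplace_back(net.nout[l], 0.0);
    }
  }
  void accumulate(const FlatNet &net,
                  const std::vector<std::vector<double>> &acts, int k,
                  double delta) {
    int L = net.L;
    std::vector<double> g(net.nout[L - 1], 0.0);
    g[k] = delta * mlp_act_deriv(acts[L][k], net.code[L - 1],
                                 net.alpha[L - 1]);
    std::vector<double> g_prev;
    for (int l = L - 1; l >= 0; --l) {
      const double *Wl = net.W[l];
      const double *ain = acts[l].data();
      if (l > 0) {
        g_prev.assign(net.nin[l], 0.0);
        for (int j = 0; j < net.nin[l]; ++j) {
          const double *col = Wl + (size_t)j * net.nout[l];
          double s = 0.0;
          for (int i = 0; i < net.nout[l]; ++i) s += col[i] * g[i];
          g_prev[j] = s * mlp_act_deriv(ain[j], net.code[l - 1],
                                        net.alpha[l - 1]);
        }
      }
      double *gbl = gb[l].data();
      double *gWl = gW[l].data();
      for (int i = 0; i < net.nout[l]; ++i) gbl[i] += g[i];
      for (int j = 0; j < net.nin[l]; ++j) {
        double aj = ain[j];
        if (aj != 0.0) {
          double *col = gWl + (size_t)j * net.nout[l];
          for (int i = 0; i < net.nout[l]; ++i) col[i] += g[i] * aj;
        }
      }
      if (l > 0) g.swap(g_prev);
    }
  }
  void apply(FlatNet &net, double lr) {
    for (int l = 0; l < net.L; ++l) {
      size_t sz = gW[l].size();
      double *Wl = net.W[l];
      for (size_t i = 0; i < sz; ++i) {
        Wl[i] += lr * gW[l][i];
        gW[l][i] = 0.0;
      }
      for (int i = 0; i < net.nout[l]; ++i) {
        net.b[l][i] += lr * gb[l][i];
        gb[l][i] = 0.0;
      }
    }
  }
};

// Fused semi-gradient step: backpropagate the selected output's gradient
// (times scale = lr * delta) directly into the weights, layer by layer.
void update_selected_flat(FlatNet &net,
                          const std::vector<std::vector<double>> &acts,
                          int k, double scale) {
  int L = net.L;
  std::vector<double> g(net.nout[L - 1], 0.0);
  g[k] = mlp_act_deriv(acts[L][k], net.code[L - 1], net.alpha[L - 1]);
  std::vector<double> g_prev;
  for (int l = L - 1; l >= 0; --l) {
    double *Wl = net.W[l];
    const double *ain = acts[l].data();
    if (l > 0) {
      g_prev.assign(net.nin[l], 0.0);
      for (int j = 0; j < net.nin[l]; ++j) {
        const double *col = Wl + (size_t)j * net.nout[l];
        double s = 0.0;
        for (int i = 0; i < net.nout[l]; ++i) s += col[i] * g[i];
        g_prev[j] = s * mlp_act_deriv(ain[j], net.code[l - 1],
                                      net.alpha[l - 1]);
      }
    }
    for (int i = 0; i < net.nout[l]; ++i) net.b[l][i] += scale * g[i];
    for (int j = 0; j < net.nin[l]; ++j) {
      double saj = scale * ain[j];
      if (saj != 0.0) {
        double *col = Wl + (size_t)j * net.nout[l];
        for (int i = 0; i < net.nout[l]; ++i) col[i] += g[i] * saj;
      }
    }
    if (l > 0) g.swap(g_prev);
  }
}

}  // namespace

// [[Rcpp::export]]
void train_manager_loop_cpp(List mgrWs, List mgrbs, IntegerVector mgract,
                            NumericVector mgralpha, List agWs, List agbs,
                            IntegerVector agact, NumericVector agalpha,
                            List adj, NumericMatrix dist, int n_episodes,
                            int m, double gamma, double epsilon,
                            double agent_beta, int max_steps,
                            double lr_start, double lr_end, double lr_clip,
                            int minibatch) {
  RNGScope rng;
  int n = dist.nrow();
  FlatNet mgr(mgrWs, mgrbs, mgract, mgralpha);
  FlatNet ag(agWs, agbs, agact, agalpha);
  GradBuf grad(mgr);
  std::vector<IntegerVector> nbs;
  for (int i = 0; i < n; ++i) nbs.push_back(as<IntegerVector>(adj[i]));
  std::vector<double> mu_true(n), mu_est(n);
  std::vector<std::vector<double>> prev_acts;  // snapshot for the update
  int in_batch = 0;
  const double *dp = REAL(dist);
  for (int ep = 0; ep < n_episodes; ++ep) {
    double lr = lr_start * std::pow(lr_end / lr_start,
                                    (double)ep / n_episodes);
    if (lr > lr_clip) lr = lr_clip;
    int start = (int)(unif_rand() * n);
    if (start >= n) start = n - 1;
    std::fill(mu_true.begin(), mu_true.end(), 0.0);
    int placed = 0;
    while (placed < m) {
      int t = (int)(unif_rand() * n);
      if (t >= n || t == start || mu_true[t] > 0) continue;
      mu_true[t] = 1.0;
      ++placed;
    }
    mu_est = mu_true;
    int city = start;
    int remaining = m;
    bool have_prev = false;
    int prev_a = 0;
    double prev_r = 0.0, prev_q = 0.0;
    for (int t = 0; t < max_steps; ++t) {
      // manager observes (city, mu_est)
      std::fill(mgr.a[0].begin(), mgr.a[0].end(), 0.0);
      mgr.a[0][city] = 1.0;
      for (int i = 0; i < n; ++i) mgr.a[0][n + i] = mu_est[i];
      mgr.forward();
      const std::vector<double> &q = mgr.a[mgr.L];
      // this forward doubles as the previous transition's bootstrap
      if (have_prev) {
        double qnb = q[0];
        for (int i = 1; i <= n; ++i) qnb = std::max(qnb, q[i]);
        double delta = prev_r + gamma * qnb - prev_q;
        if (delta != 0.0) grad.accumulate(mgr, prev_acts, prev_a, delta);
        if (++in_batch >= minibatch) { grad.apply(mgr, lr); in_batch = 0; }
      }
      int a_mgr;
      if (unif_rand() < epsilon) {
        a_mgr = (int)(unif_rand() * (n + 1));
        if (a_mgr > n) a_mgr = n;
      } else {
        a_mgr = 0;
        for (int i = 1; i <= n; ++i) if (q[i] > q[a_mgr]) a_mgr = i;
      }
      if (a_mgr < n) mu_est[a_mgr] = 0.0;  // action n is "do nothing"
      // agent acts on the edited estimate
      std::fill(ag.a[0].begin(), ag.a[0].end(), 0.0);
      ag.a[0][city] = 1.0;
      for (int i = 0; i < n; ++i) ag.a[0][n + i] = mu_est[i];
      ag.forward();
      const std::vector<double> &qa = ag.a[ag.L];
      const IntegerVector &nb = nbs[city];
      int k = nb.size();
      double qmax = R_NegInf;
      for (int i = 0; i < k; ++i) qmax = std::max(qmax, qa[nb[i] - 1]);
      double ssum = 0.0;
      std::vector<double> p(k);
      for (int i = 0; i < k; ++i) {
        p[i] = std::exp(agent_beta * (qa[nb[i] - 1] - qmax));
        ssum += p[i];
      }
      double u = unif_rand() * ssum;
      int a_agent = nb[k - 1] - 1;
      for (int i = 0; i < k; ++i) {
        u -= p[i];
        if (u <= 0) { a_agent = nb[i] - 1; break; }
      }
      double reward_ag =
        5.0 * (mu_true[a_agent] > 0) - dp[(size_t)a_agent * n + city];
      if (mu_true[a_agent] > 0) { mu_true[a_agent] = 0.0; --remaining; }
      bool env_done = remaining == 0;
      double r = reward_ag > 0 ? 5.0 : (a_mgr == n ? -1.0 : -2.0);
      bool final_step = env_done || t == max_steps - 1;
      if (final_step) {
        double delta = r - q[a_mgr];  // terminal: no bootstrap
        prev_acts = mgr.a;
        if (delta != 0.0) grad.accumulate(mgr, prev_acts, a_mgr, delta);
        if (++in_batch >= minibatch) { grad.apply(mgr, lr); in_batch = 0; }
        have_prev = false;
      } else {
        prev_acts = mgr.a;
        prev_a = a_mgr;
        prev_r = r;
        prev_q = q[a_mgr];
        have_prev = true;
      }
      city = a_agent;
      if (env_done) break;
    }
  }
}

// Compiled supervised manager training: the trained agent runs under the
// true motivation dynamics (behavior softmax `agent_beta`); at each step
// the manager observes the city just entered together with the
// pre-transition motivation, takes an epsilon-greedy action, and is scored
// against the true transition (+2 correct, -2 incorrect, -1 for an
// incorrect "do nothing"). Per-step semi-gradient Q-updates, lr annealed
// geometrically per episode.
// [[Rcpp::export]]
void train_manager_supervised_cpp(List mgrWs, List mgrbs,
                                  IntegerVector mgract,
                                  NumericVector mgralpha, List agWs,
                                  List agbs, IntegerVector agact,
                                  NumericVector agalpha, List adj,
                                  NumericMatrix dist, int n_episodes, int m,
                                  double gamma, double epsilon,
                                  double agent_beta, int max_steps,
                                  double lr_start, double lr_end) {
  RNGScope rng;
  int n = dist.nrow();
  FlatNet mgr(mgrWs, mgrbs, mgract, mgralpha);
  FlatNet ag(agWs, agbs, agact, agalpha);
  std::vector<IntegerVector> nbs;
  for (int i = 0; i < n; ++i) nbs.push_back(as<IntegerVector>(adj[i]));
  std::vector<double> mu(n);
  std::vector<std::vector<double>> prev_acts;
  const double *dp = REAL(dist);
  for (int ep = 0; ep < n_episodes; ++ep) {
    double lr = lr_start * std::pow(lr_end / lr_start,
                                    (double)ep / n_episodes);
    int start = (int)(unif_rand() * n);
    if (start >= n) start = n - 1;
    std::fill(mu.begin(), mu.end(), 0.0);
    int placed = 0;
    while (placed < m) {
      int t = (int)(unif_rand() * n);
      if (t >= n || t == start || mu[t] > 0) continue;
      mu[t] = 1.0;
      ++placed;
    }
    int city = start;
    int remaining = m;
    bool have_prev = false;
    int prev_a = 0;
    double prev_r = 0.0, prev_q = 0.0;
    for (int t = 0; t < max_steps; ++t) {
      // agent acts on the true motivation
      std::fill(ag.a[0].begin(), ag.a[0].end(), 0.0);
      ag.a[0][city] = 1.0;
      for (int i = 0; i < n; ++i) ag.a[0][n + i] = mu[i];
      ag.forward();
      const std::vector<double> &qa = ag.a[ag.L];
      const IntegerVector &nb = nbs[city];
      int k = nb.size();
      double qmax = R_NegInf;
      for (int i = 0; i < k; ++i) qmax = std::max(qmax, qa[nb[i] - 1]);
      double ssum = 0.0;
      std::vector<double> p(k);
      for (int i = 0; i < k; ++i) {
        p[i] = std::exp(agent_beta * (qa[nb[i] - 1] - qmax));
        ssum += p[i];
      }
      double u = unif_rand() * ssum;
      int a_agent = nb[k - 1] - 1;
      for (int i = 0; i < k; ++i) {
        u -= p[i];
        if (u <= 0) { a_agent = nb[i] - 1; break; }
      }
      bool consumed = mu[a_agent] > 0;
      // manager observes (city entered, pre-transition motivation)
      std::fill(mgr.a[0].begin(), mgr.a[0].end(), 0.0);
      mgr.a[0][a_agent] = 1.0;
      for (int i = 0; i < n; ++i) mgr.a[0][n + i] = mu[i];
      mgr.forward();
      const std::vector<double> &q = mgr.a[mgr.L];
      if (have_prev) {
        double qnb = q[0];
        for (int i = 1; i <= n; ++i) qnb = std::max(qnb, q[i]);
        double delta = prev_r + gamma * qnb - prev_q;
        if (delta != 0.0)
          update_selected_flat(mgr, prev_acts, prev_a, lr * delta);
      }
      int a_mgr;
      if (unif_rand() < epsilon) {
        a_mgr = (int)(unif_rand() * (n + 1));
        if (a_mgr > n) a_mgr = n;
      } else {
        a_mgr = 0;
        for (int i = 1; i <= n; ++i) if (q[i] > q[a_mgr]) a_mgr = i;
      }
      // correct iff applying the action reproduces the true transition
      bool correct;
      if (consumed) correct = a_mgr == a_agent;
      else correct = a_mgr == n || (a_mgr < n && mu[a_mgr] == 0.0);
      double r = correct ? 2.0 : (a_mgr == n ? -1.0 : -2.0);
      if (consumed) { mu[a_agent] = 0.0; --remaining; }
      bool env_done = remaining == 0;
      bool final_step = env_done || t == max_steps - 1;
      if (final_step) {
        double delta = r - q[a_mgr];
        prev_acts = mgr.a;
        if (delta != 0.0)
          update_selected_flat(mgr, prev_acts, a_mgr, lr * delta);
        have_prev = false;
      } else {
        prev_acts = mgr.a;
        prev_a = a_mgr;
        prev_r = r;
        prev_q = q[a_mgr];
        have_prev = true;
      }
      city = a_agent;
      if (env_done) break;
    }
  }
}

// Compiled Q-learning loop for the flat transport agent: per-episode random
// start and m distinct targets (excluding the start), softmax behavior over
// adjacent cities, reward 5 on clearing a target minus the road length,
// semi-gradient TD with the max over the successor's adjacent cities, fused
// per-step updates, learning rate annealed geometrically per episode.
// [[Rcpp::export]]
void train_transport_loop_cpp(List agWs, List agbs, IntegerVector agact,
                              NumericVector agalpha, List adj,
                              NumericMatrix dist, int n_episodes, int m,
                              double gamma, double beta, double lr_start,
                              double lr_end) {
  RNGScope rng;
  int n = dist.nrow();
  FlatNet ag(agWs, agbs, agact, agalpha);
  std::vector<IntegerVector> nbs;
  for (int i = 0; i < n; ++i) nbs.push_back(as<IntegerVector>(adj[i]));
  std::vector<double> mu(n);
  std::vector<std::vector<double>> prev_acts;
  const double *dp = REAL(dist);
  for (int ep = 0; ep < n_episodes; ++ep) {
    double lr = lr_start * std::pow(lr_end / lr_start,
                                    (double)ep / n_episodes);
    int start = (int)(unif_rand() * n);
    if (start >= n) start = n - 1;
    std::fill(mu.begin(), mu.end(), 0.0);
    int placed = 0;
    while (placed < m) {
      int t = (int)(unif_rand() * n);
      if (t >= n || t == start || mu[t] > 0) continue;
      mu[t] = 1.0;
      ++placed;
    }
    int city = start;
    int remaining = m;
    bool done = false;
    while (!done) {
      std::fill(ag.a[0].begin(), ag.a[0].end(), 0.0);
      ag.a[0][city] = 1.0;
      for (int i = 0; i < n; ++i) ag.a[0][n + i] = mu[i];
      ag.forward();
      const std::vector<double> &q = ag.a[ag.L];
      const IntegerVector &nb = nbs[city];
      int k = nb.size();
      double qmax = R_NegInf;
      for (int i = 0; i < k; ++i) qmax = std::max(qmax, q[nb[i] - 1]);
      double ssum = 0.0;
      std::vector<double> p(k);
      for (int i = 0; i < k; ++i) {
        p[i] = std::exp(beta * (q[nb[i] - 1] - qmax));
        ssum += p[i];
      }
      double u = unif_rand() * ssum;
      int a = nb[k - 1] - 1;
      for (int i = 0; i < k; ++i) {
        u -= p[i];
        if (u <= 0) { a = nb[i] - 1; break; }
      }
      double q_sel = q[a];
      double reward = 5.0 * (mu[a] > 0) - dp[(size_t)a * n + city];
      if (mu[a] > 0) { mu[a] = 0.0; --remaining; }
      done = remaining == 0;
      prev_acts = ag.a;
      double q_next_best = 0.0;
      if (!done) {
        std::fill(ag.a[0].begin(), ag.a[0].end(), 0.0);
        ag.a[0][a] = 1.0;
        for (int i = 0; i < n; ++i) ag.a[0][n + i] = mu[i];
        ag.forward();
        const IntegerVector &nb2 = nbs[a];
        const std::vector<double> &q2 = ag.a[ag.L];
        q_next_best = R_NegInf;
        for (int i = 0; i < nb2.size(); ++i)
          q_next_best = std::max(q_next_best, q2[nb2[i] - 1]);
      }
      double delta = reward + gamma * q_next_best - q_sel;
      if (delta != 0.0)
        update_selected_flat(ag, prev_acts, a, lr * delta);
      city = a;
    }
  }
}
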