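// Stochastic simulation kernels: Gillespie direct, first reaction,
// Gibson-Bruck next reaction, and adaptive tau-leaping (Cao et al. 2006
// step-size selection with critical-reaction handling).
//
// All randomness goes through R's RNG (RNGScope), so trajectories are
// bit-reproducible under set.seed(). Expression rate laws arrive as RPN
// programs compiled in R (see compile_expr in R/model.R); opcodes must stay
// in sync with that file.

#include <Rcpp.h>
#include <vector>
#include <cmath>
#include <limits>
using namespace Rcpp;

static const double INF = std::numeric_limits<double>::infinity();

enum Op { OP_CONST = 1, OP_SPEC, OP_ADD, OP_SUB, OP_MUL, OP_DIV, OP_POW,
          OP_NEG, OP_MIN, OP_MAX, OP_EXP, OP_LOG };

struct Compiled {
  int nsp, nrx;
  std::vector<int> nu_net;   // nsp x nrx, column-major
  std::vector<int> nu_reac;
  std::vector<int> law_type; // 0 mass action, 1 expression
  std::vector<double> c;
  std::vector< std::vector<int> > code;
  std::vector< std::vector<double> > arg;
  mutable std::vector<double> stack;
  mutable bool clipped;

  void init(List cm) {
    IntegerMatrix nn = cm["nu_net"], nr = cm["nu_reac"];
    nsp = nn.nrow(); nrx = nn.ncol();
    nu_net.assign(nn.begin(), nn.end());
    nu_reac.assign(nr.begin(), nr.end());
    IntegerVector lt = cm["law_type"];
    law_type.assign(lt.begin(), lt.end());
    NumericVector cc = cm["c"];
    c.assign(cc.begin(), cc.end());
    List codeL = cm["code"], argL = cm["arg"];
    code.resize(nrx); arg.resize(nrx);
    size_t maxdepth = 4;
    for (int j = 0; j < nrx; ++j) {
      IntegerVector cj = codeL[j]; NumericVector aj = argL[j];
      code[j].assign(cj.begin(), cj.end());
      arg[j].assign(aj.begin(), aj.end());
      if (code[j].size() + 1 > maxdepth) maxdepth = code[j].size() + 1;
    }
    stack.resize(maxdepth);
    clipped = false;
  }

  inline double prop(int j, const std::vector<double>& x) const {
    if (law_type[j] == 0) {
      double a = c[j];
      const int* mr = &nu_reac[(size_t)j * nsp];
      for (int i = 0; i < nsp; ++i) {
        int m = mr[i];
        if (m == 0) continue;
        double n = x[i], f = 1.0;
        for (int k = 0; k < m; ++k) f *= (n - k > 0.0 ? n - k : 0.0);
        for (int k = 2; k <= m; ++k) f /= k;
        a *= f;
      }
      return a;
    }
    const std::vector<int>& cd = code[j];
    const std::vector<double>& ag = arg[j];
    int top = -1;
    for (size_t k = 0; k < cd.size(); ++k) {
      switch (cd[k]) {
      case OP_CONST: stack[++top] = ag[k]; break;
      case OP_SPEC:  stack[++top] = x[(int)ag[k] - 1]; break;
      case OP_ADD: --top; stack[top] += stack[top + 1]; break;
      case OP_SUB: --top; stack[top] -= stack[top + 1]; break;
      case OP_MUL: --top; stack[top] *= stack[top + 1]; break;
      case OP_DIV: --top; stack[top] /= stack[top + 1]; break;
      case OP_POW: --top; stack[top] = std::pow(stack[top], stack[top + 1]); break;
      case OP_NEG: stack[top] = -stack[top]; break;
      case OP_MIN: --top; stack[top] = std::min(stack[top], stack[top + 1]); break;
      case OP_MAX: --top; stack[top] = std::max(stack[top], stack[top + 1]); break;
      case OP_EXP: stack[top] = std::exp(stack[top]); break;
      case OP_LOG: stack[top] = std::log(stack[top]); break;
      }
    }
    double a = stack[0];
    if (!std::isfinite(a))
      stop("rate law of reaction %d evaluated to a non-finite value", j + 1);
    if (a < 0) { clipped = true; a = 0.0; }
    return a;
  }

  inline void all_props(const std::vector<double>& x,
                        std::vector<double>& a) const {
    for (int j = 0; j < nrx; ++j) a[j] = prop(j, x);
  }

  inline void apply(int j, std::vector<double>& x) const {
    const int* nc = &nu_net[(size_t)j * nsp];
    for (int i = 0; i < nsp; ++i) if (nc[i]) x[i] += nc[i];
  }
};

struct Recorder {
  int nsp, nrx;
  std::vector<double> times;
  std::vector<int> states;
  std::vector<double> props;
  std::vector<int> fired;
  std::vector<int> firings;   // tau-leap only
  bool leap;

  Recorder(int nsp_, int nrx_, bool leap_, R_xlen_t reserve)
    : nsp(nsp_), nrx(nrx_), leap(leap_) {
    if (reserve > 0 && reserve < 20000000) {
      times.reserve(reserve + 1);
      states.reserve((size_t)(reserve + 1) * nsp);
      props.reserve((size_t)(reserve + 1) * nrx);
      fired.reserve(reserve + 1);
    }
  }

  void row(double t, const std::vector<double>& x,
           const std::vector<double>& a, int mu,
           const std::vector<int>* k = 0) {
    times.push_back(t);
    for (int i = 0; i < nsp; ++i)
      states.push_back((int)std::llround(x[i]));
    for (int j = 0; j < nrx; ++j) props.push_back(a[j]);
    fired.push_back(mu);
    if (leap) {
      if (k) for (int j = 0; j < nrx; ++j) firings.push_back((*k)[j]);
      else for (int j = 0; j < nrx; ++j) firings.push_back(NA_INTEGER);
    }
  }

  List result(bool absorbing, bool clipped) {
    R_xlen_t n = times.size();
    NumericVector t(times.begin(), times.end());
    IntegerMatrix S(n, nsp);
    for (R_xlen_t r = 0; r < n; ++r)
      for (int i = 0; i < nsp; ++i) S(r, i) = states[(size_t)r * nsp + i];
    NumericMatrix A(n, nrx);
    for (R_xlen_t r = 0; r < n; ++r)
      for (int j = 0; j < nrx; ++j) A(r, j) = props[(size_t)r * nrx + j];
    IntegerVector f(fired.begin(), fired.end());
    List out = List::create(_["times"] = t, _["states"] = S,
                            _["propensities"] = A, _["fired"] = f,
                            _["absorbing"] = absorbing,
                            _["clipped"] = clipped);
    if (leap) {
      IntegerMatrix K(n, nrx);
      for (R_xlen_t r = 0; r < n; ++r)
        for (int j = 0; j < nrx; ++j) K(r, j) = firings[(size_t)r * nrx + j];
      out["firings"] = K;
    }
    return out;
  }
};

static void check_budget(R_xlen_t nrow, double max_events) {
  if ((double)nrow > max_events)
    stop("trajectory exceeded max_events = %.0f rows; raise max_events "
         "or shorten the run", max_events);
}

// ---- direct method --------------------------------------------------------

// [[Rcpp::export(name = ".ssa_direct")]]
List ssa_direct_cpp(IntegerVector x0, List cm, double end_value,
                    bool steps_mode, double max_events) {
  Compiled C; C.init(cm);
  std::vector<double> x(x0.begin(), x0.end());
  std::vector<double> a(C.nrx);
  Recorder rec(C.nsp, C.nrx, false, steps_mode ? (R_xlen_t)end_value : 1024);
  double t = 0.0;
  C.all_props(x, a);
  rec.row(t, x, a, NA_INTEGER);
  bool absorbing = false;
  long long nev = 0;
  while (true) {
    double a0 = 0.0;
    for (int j = 0; j < C.nrx; ++j) a0 += a[j];
    if (a0 <= 0.0) { absorbing = true; break; }
    t += R::rexp(1.0 / a0);
    if (!steps_mode && t > end_value) break;
    double u = unif_rand() * a0, cum = 0.0;
    int mu = C.nrx - 1;
    for (int j = 0; j < C.nrx; ++j) { cum += a[j]; if (u < cum) { mu = j; break; } }
    C.apply(mu, x);
    C.all_props(x, a);
    rec.row(t, x, a, mu + 1);
    check_budget(rec.times.size(), max_events);
    if (steps_mode && ++nev >= (long long)end_value) break;
  }
  if (!steps_mode) {
    // terminal non-event row at exactly t_end so occupancy weights span the
    // full interval
    rec.row(end_value, x, a, NA_INTEGER);
  }
  return rec.result(absorbing, C.clipped);
}

// ---- first reaction method ------------------------------------------------

// [[Rcpp::export(name = ".ssa_first")]]
List ssa_first_cpp(IntegerVector x0, List cm, double end_value,
                   bool steps_mode, double max_events) {
  Compiled C; C.init(cm);
  std::vector<double> x(x0.begin(), x0.end());
  std::vector<double> a(C.nrx);
  Recorder rec(C.nsp, C.nrx, false, steps_mode ? (R_xlen_t)end_value : 1024);
  double t = 0.0;
  C.all_props(x, a);
  rec.row(t, x, a, NA_INTEGER);
  bool absorbing = false;
  long long nev = 0;
  while (true) {
    int mu = -1;
    double tmin = INF;
    for (int j = 0; j < C.nrx; ++j) {
      if (a[j] <= 0.0) continue;
      double tj = R::rexp(1.0 / a[j]);
      if (tj < tmin) { tmin = tj; mu = j; }  // strict <: ties -> lowest index
    }
    if (mu < 0) { absorbing = true; break; }
    t += tmin;
    if (!steps_mode && t > end_value) break;
    C.apply(mu, x);
    C.all_props(x, a);
    rec.row(t, x, a, mu + 1);
    check_budget(rec.times.size(), max_events);
    if (steps_mode && ++nev >= (long long)end_value) break;
  }
  if (!steps_mode) rec.row(end_value, x, a, NA_INTEGER);
  return rec.result(absorbing, C.clipped);
}

// ---- next reaction method (Gibson-Bruck) ----------------------------------

struct IndexedHeap {
  std::vector<int> heap, pos;    // heap of reaction indices; pos[j] in heap
  std::vector<double>* key;
  void init(std::vector<double>* k, int n) {
    key = k; heap.resize(n); pos.resize(n);
    for (int j = 0; j < n; ++j) { heap[j] = j; pos[j] = j; }
    for (int j = n / 2 - 1; j >= 0; --j) down(j);
  }
  inline void swap_nodes(int i, int j) {
    std::swap(heap[i], heap[j]);
    pos[heap[i]] = i; pos[heap[j]] = j;
  }
  void up(int i) {
    while (i > 0) {
      int p = (i - 1) / 2;
      if ((*key)[heap[i]] < (*key)[heap[p]]) { swap_nodes(i, p); i = p; }
      else break;
    }
  }
  void down(int i) {
    int n = heap.size();
    while (true) {
      int l = 2 * i + 1, r = l + 1, m = i;
      if (l < n && (*key)[heap[l]] < (*key)[heap[m]]) m = l;
      if (r < n && (*key)[heap[r]] < (*key)[heap[m]]) m = r;
      if (m == i) break;
      swap_nodes(i, m); i = m;
    }
  }
  void update(int j) { int i = pos[j]; up(i); down(pos[j]); }
  int top() const { return heap[0]; }
};

// [[Rcpp::export(name = ".ssa_next")]]
List ssa_next_cpp(IntegerVector x0, List cm, List depends, double end_value,
                  bool steps_mode, double max_events) {
  Compiled C; C.init(cm);
  std::vector< std::vector<int> > dep(C.nrx);
  for (int j = 0; j < C.nrx; ++j) {
    IntegerVector dj = depends[j];
    dep[j].assign(dj.begin(), dj.end());
    for (size_t k = 0; k < dep[j].size(); ++k) dep[j][k] -= 1;  // 0-based
  }
  std::vector<double> x(x0.begin(), x0.end());
  std::vector<double> a(C.nrx), tau(C.nrx);
  Recorder rec(C.nsp, C.nrx, false, steps_mode ? (R_xlen_t)end_value : 1024);
  double t = 0.0;
  C.all_props(x, a);
  rec.row(t, x, a, NA_INTEGER);
  for (int j = 0; j < C.nrx; ++j)
    tau[j] = a[j] > 0.0 ? R::rexp(1.0 / a[j]) : INF;
  IndexedHeap H; H.init(&tau, C.nrx);
  bool absorbing = false;
  long long nev = 0;
  while (true) {
    int mu = H.top();
    double tnext = tau[mu];
    if (!std::isfinite(tnext)) { absorbing = true; break; }
    if (!steps_mode && tnext > end_value) break;
    t = tnext;
    C.apply(mu, x);
    for (size_t k = 0; k < dep[mu].size(); ++k) {
      int j = dep[mu][k];
      double aold = a[j], anew = C.prop(j, x);
      a[j] = anew;
      if (j == mu) {
        tau[j] = anew > 0.0 ? t + R::rexp(1.0 / anew) : INF;
      } else if (anew <= 0.0) {
        tau[j] = INF;
      } else if (aold > 0.0 && std::isfinite(tau[j])) {
        tau[j] = t + (aold / anew) * (tau[j] - t);   // scale pending clock
      } else {
        tau[j] = t + R::rexp(1.0 / anew);            // fresh clock on 0 -> +
      }
      H.update(j);
    }
    rec.row(t, x, a, mu + 1);
    check_budget(rec.times.size(), max_events);
    if (steps_mode && ++nev >= (long long)end_value) break;
  }
  if (!steps_mode) rec.row(end_value, x, a, NA_INTEGER);
  return rec.result(absorbing, C.clipped);
}

// ---- adaptive tau-leaping -------------------------------------------------

// [[Rcpp::export(name = ".ssa_tau")]]
List ssa_tau_cpp(IntegerVector x0, List cm, double end_value, bool steps_mode,
                 double epsilon, int nc, double max_events) {
  Compiled C; C.init(cm);
  std::vector<double> x(x0.begin(), x0.end());
  std::vector<double> a(C.nrx);
  std::vector<int> kfire(C.nrx);
  Recorder rec(C.nsp, C.nrx, true, 1024);
  double t = 0.0;
  C.all_props(x, a);
  rec.row(t, x, a, NA_INTEGER);

  // highest-order-reaction bookkeeping for the g_i factors
  std::vector<int> hor(C.nsp, 0), hmult(C.nsp, 0);
  for (int j = 0; j < C.nrx; ++j) {
    int order = 0;
    for (int i = 0; i < C.nsp; ++i) order += C.nu_reac[(size_t)j * C.nsp + i];
    for (int i = 0; i < C.nsp; ++i) {
      int m = C.nu_reac[(size_t)j * C.nsp + i];
      if (m == 0) continue;
      if (order > hor[i] || (order == hor[i] && m > hmult[i])) {
        hor[i] = order; hmult[i] = m;
      }
    }
  }
  std::vector<bool> crit(C.nrx);
  std::vector<double> mu_i(C.nsp), sig_i(C.nsp);
  bool absorbing = false;
  long long nrow_events = 0;

  while (true) {
    double a0 = 0.0;
    for (int j = 0; j < C.nrx; ++j) a0 += a[j];
    if (a0 <= 0.0) { absorbing = true; break; }

    // critical classification: fewer than nc firings possible before some
    // reactant is exhausted
    for (int j = 0; j < C.nrx; ++j) {
      crit[j] = false;
      if (a[j] <= 0.0) continue;
      double L = INF;
      const int* ncol = &C.nu_net[(size_t)j * C.nsp];
      for (int i = 0; i < C.nsp; ++i)
        if (ncol[i] < 0) L = std::min(L, std::floor(x[i] / (double)(-ncol[i])));
      if (L < (double)nc) crit[j] = true;
    }

    // Cao et al. 2006 candidate leap from the non-critical set
    std::fill(mu_i.begin(), mu_i.end(), 0.0);
    std::fill(sig_i.begin(), sig_i.end(), 0.0);
    bool any_noncrit = false;
    for (int j = 0; j < C.nrx; ++j) {
      if (crit[j] || a[j] <= 0.0) continue;
      any_noncrit = true;
      const int* ncol = &C.nu_net[(size_t)j * C.nsp];
      for (int i = 0; i < C.nsp; ++i) {
        if (!ncol[i]) continue;
        mu_i[i] += ncol[i] * a[j];
        sig_i[i] += (double)ncol[i] * ncol[i] * a[j];
      }
    }
    double tau1 = INF;
    if (any_noncrit) {
      for (int i = 0; i < C.nsp; ++i) {
        if (mu_i[i] == 0.0 && sig_i[i] == 0.0) continue;
        double g;
        if (hor[i] <= 1) g = 1.0;
        else if (hor[i] == 2 && hmult[i] == 1) g = 2.0;
        else if (hor[i] == 2) g = 2.0 + 1.0 / std::max(x[i] - 1.0, 1.0);
        else if (hor[i] == 3 && hmult[i] == 1) g = 3.0;
        else if (hor[i] == 3 && hmult[i] == 2)
          g = 1.5 * (2.0 + 1.0 / std::max(x[i] - 1.0, 1.0));
        else g = 3.0 + 1.0 / std::max(x[i] - 1.0, 1.0)
               + 2.0 / std::max(x[i] - 2.0, 1.0);
        double bound = std::max(epsilon * x[i] / g, 1.0);
        if (mu_i[i] != 0.0) tau1 = std::min(tau1, bound / std::fabs(mu_i[i]));
        if (sig_i[i] > 0.0) tau1 = std::min(tau1, bound * bound / sig_i[i]);
      }
    }

    if (tau1 < 10.0 / a0) {
      // leap not worthwhile: fall back to a burst of exact direct steps
      bool done = false;
      for (int s = 0; s < 10; ++s) {
        double a0b = 0.0;
        for (int j = 0; j < C.nrx; ++j) a0b += a[j];
        if (a0b <= 0.0) { absorbing = true; done = true; break; }
        double dt = R::rexp(1.0 / a0b);
        if (!steps_mode && t + dt > end_value) { done = true; break; }
        t += dt;
        double u = unif_rand() * a0b, cum = 0.0;
        int mu = C.nrx - 1;
        for (int j = 0; j < C.nrx; ++j) { cum += a[j]; if (u < cum) { mu = j; break; } }
        C.apply(mu, x);
        C.all_props(x, a);
        std::fill(kfire.begin(), kfire.end(), 0);
        kfire[mu] = 1;
        rec.row(t, x, a, mu + 1, &kfire);
        check_budget(rec.times.size(), max_events);
        if (steps_mode && ++nrow_events >= (long long)end_value) { done = true; break; }
      }
      if (done) break;
      continue;
    }

    double a0c = 0.0;
    for (int j = 0; j < C.nrx; ++j) if (crit[j]) a0c += a[j];
    double tau2 = a0c > 0.0 ? R::rexp(1.0 / a0c) : INF;
    double tau = std::min(tau1, tau2);
    bool hit_end = false;
    if (!steps_mode && t + tau > end_value) { tau = end_value - t; hit_end = true; }

    // draw firing counts; reject and halve the leap if a population would
    // go negative (negative copy numbers impossible by construction)
    std::vector<double> xnew(C.nsp);
    while (true) {
      bool fire_crit = !hit_end && std::isfinite(tau2) && tau2 <= tau;
      std::fill(kfire.begin(), kfire.end(), 0);
      for (int j = 0; j < C.nrx; ++j)
        if (!crit[j] && a[j] > 0.0)
          kfire[j] = (int)R::rpois(a[j] * tau);
      if (fire_crit) {
        double u = unif_rand() * a0c, cum = 0.0;
        int jc = -1;
        for (int j = 0; j < C.nrx; ++j)
          if (crit[j]) { cum += a[j]; if (u < cum) { jc = j; break; } }
        if (jc < 0) for (int j = C.nrx - 1; j >= 0; --j) if (crit[j]) { jc = j; break; }
        kfire[jc] = 1;
      }
      bool neg = false;
      for (int i = 0; i < C.nsp; ++i) {
        double xi = x[i];
        for (int j = 0; j < C.nrx; ++j)
          if (kfire[j]) xi += (double)C.nu_net[(size_t)j * C.nsp + i] * kfire[j];
        if (xi < 0.0) { neg = true; break; }
        xnew[i] = xi;
      }
      if (!neg) break;
      tau *= 0.5; hit_end = false;
    }
    t += tau;
    x = xnew;
    C.all_props(x, a);
    rec.row(t, x, a, NA_INTEGER, &kfire);
    check_budget(rec.times.size(), max_events);
    if (steps_mode && ++nrow_events >= (long long)end_value) break;
    if (!steps_mode && t >= end_value) break;
  }
  if (!steps_mode && (rec.times.empty() || rec.times.back() < end_value))
    rec.row(end_value, x, a, NA_INTEGER);
  return rec.result(absorbing, C.clipped);
}
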