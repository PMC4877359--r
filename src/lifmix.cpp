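// Numerical core: stimulus/current evaluation, Euler-Maruyama simulation,
// and the four first-passage-time solvers (Fokker-Planck PDF/CDF by
// Crank-Nicolson + Thomas, first- and second-kind Volterra integral
// equations) used for spike-train likelihoods.
#include <Rcpp.h>
#include <cmath>
#include <vector>
#include <numeric>
using namespace Rcpp;

static const double G_FLOOR = 1e-300; // density floor before taking logs

// ---------------------------------------------------------------------------
// Stimulus evaluation
//
// A stimulus is a list of additive terms, each with fields:
//   type: 1 = sinusoidal s1*sin(s2*t+s3)+s4
//         2 = piecewise constant (par = values, brk = breakpoints)
//         3 = sampled path held constant between sample points
//   coef: multiplicative coefficient of the term
// ---------------------------------------------------------------------------

struct StimTerm {
  int type;
  double coef;
  std::vector<double> par;   // sinusoidal params or piecewise values
  std::vector<double> brk;   // piecewise breakpoints
  double t0, dtp;            // path origin and sampling step
  std::vector<double> path;  // path values
};

static std::vector<StimTerm> parse_stim(const List& stim) {
  std::vector<StimTerm> terms;
  for (int l = 0; l < stim.size(); ++l) {
    List tl = stim[l];
    StimTerm tm;
    tm.type = as<int>(tl["type"]);
    tm.coef = as<double>(tl["coef"]);
    if (tm.type == 1) {
      tm.par = as<std::vector<double> >(tl["par"]);
    } else if (tm.type == 2) {
      tm.par = as<std::vector<double> >(tl["par"]);
      tm.brk = as<std::vector<double> >(tl["brk"]);
    } else if (tm.type == 3) {
      tm.t0 = as<double>(tl["t0"]);
      tm.dtp = as<double>(tl["dt"]);
      tm.path = as<std::vector<double> >(tl["path"]);
    } else {
      stop("unknown stimulus term type");
    }
    terms.push_back(tm);
  }
  return terms;
}

static double eval_term(const StimTerm& tm, double t) {
  if (tm.type == 1) {
    return tm.par[0] * std::sin(tm.par[1] * t + tm.par[2]) + tm.par[3];
  } else if (tm.type == 2) {
    const size_t n = tm.par.size();
    if (t < tm.brk[0] - 1e-12 || t > tm.brk[n] + 1e-12)
      stop("time %f outside piecewise-constant stimulus domain [%f, %f]",
           t, tm.brk[0], tm.brk[n]);
    // right-open segments [b_i, b_{i+1}); the right endpoint maps to the
    // last segment so that evaluation at the domain edge is defined
    size_t i = 0;
    while (i + 1 < n && t >= tm.brk[i + 1]) ++i;
    return tm.par[i];
  } else {
    double e = (t - tm.t0) / tm.dtp;
    if (e < -1e-9) stop("time %f before start of sampled stimulus path", t);
    long idx = (long)std::floor(e + 1e-12);
    if (idx < 0) idx = 0;
    if (idx >= (long)tm.path.size()) {
      if (e <= (double)tm.path.size() + 1e-6) idx = (long)tm.path.size() - 1;
      else stop("time %f beyond end of sampled stimulus path", t);
    }
    return tm.path[idx];
  }
}

static double eval_stim(const std::vector<StimTerm>& terms, double t) {
  double s = 0.0;
  for (size_t l = 0; l < terms.size(); ++l) s += terms[l].coef * eval_term(terms[l], t);
  return s;
}

// [[Rcpp::export]]
NumericVector cpp_stim_eval(List stim, NumericVector times) {
  std::vector<StimTerm> terms = parse_stim(stim);
  NumericVector out(times.size());
  for (int i = 0; i < times.size(); ++i) out[i] = eval_stim(terms, times[i]);
  return out;
}

// ---------------------------------------------------------------------------
// Post-spike current via a piecewise-constant kernel table
// table[j] approximates k_h on [j*dt_tab, (j+1)*dt_tab) by its midpoint value
// ---------------------------------------------------------------------------

// [[Rcpp::export]]
NumericVector cpp_post_spike_current(NumericVector history, NumericVector times,
                                     NumericVector table, double dt_tab) {
  const int nh = history.size();
  for (int k = 1; k < nh; ++k)
    if (history[k] <= history[k - 1]) stop("spike history must be strictly increasing");
  NumericVector out(times.size());
  for (int i = 0; i < times.size(); ++i) {
    double h = 0.0;
    for (int k = 0; k < nh; ++k) {
      double e = times[i] - history[k];
      if (e < 0) stop("post-spike current requested before a history spike");
      long idx = (long)std::floor(e / dt_tab);
      if (idx < table.size()) h += table[idx];
    }
    out[i] = h;
  }
  return out;
}

// ---------------------------------------------------------------------------
// Thomas algorithm for tridiagonal systems (in place on copies)
// ---------------------------------------------------------------------------

static void thomas(std::vector<double>& a, std::vector<double>& b,
                   std::vector<double>& c, std::vector<double>& d,
                   std::vector<double>& x) {
  const int n = (int)b.size();
  for (int i = 1; i < n; ++i) {
    double w = a[i] / b[i - 1];
    b[i] -= w * c[i - 1];
    d[i] -= w * d[i - 1];
  }
  x[n - 1] = d[n - 1] / b[n - 1];
  for (int i = n - 2; i >= 0; --i) x[i] = (d[i] - c[i] * x[i + 1]) / b[i];
}

// clamp density and cumulative values into a proper sub-distribution
static void postprocess(std::vector<double>& g, std::vector<double>& G) {
  double run = 0.0;
  for (size_t i = 0; i < g.size(); ++i) {
    if (g[i] < 0) g[i] = 0.0;
    if (G[i] < run) G[i] = run;
    if (G[i] > 1) G[i] = 1.0;
    run = G[i];
  }
}

// ---------------------------------------------------------------------------
// Fokker-Planck PDF equation: finite-volume Crank-Nicolson with absorbing
// boundary at x_th and reflecting (zero-flux) boundary at x_lower.
// itot[i] is the total current gamma*mu + I + H at grid time i*dt.
// drift b(x,t) = itot(t) - gamma*x; diffusion sigma^2/2 (OU) or
// sigma^2*x/2 (Feller, square-root noise).
// ---------------------------------------------------------------------------

static void fp_pdf_solve(const std::vector<double>& itot, double dt,
                         double gamma, double sigma, double x0, double xth,
                         double xlow, double dx, bool feller,
                         std::vector<double>& g, std::vector<double>& G,
                         std::vector<double>* field = 0) {
  const int n = (int)itot.size() - 1;       // time steps
  const int m = (int)std::round((xth - xlow) / dx); // cells 0..m-1, node m = threshold
  if (m < 3) stop("space grid too coarse");
  const double sig2 = sigma * sigma;
  std::vector<double> x(m + 1), D(m + 1);
  for (int i = 0; i <= m; ++i) {
    x[i] = xlow + i * dx;
    D[i] = feller ? 0.5 * sig2 * x[i] : 0.5 * sig2;
  }
  std::vector<double> f(m, 0.0);
  int i0 = (int)std::round((x0 - xlow) / dx);
  if (i0 <= 0 || i0 >= m) stop("reset potential x0 must lie strictly inside (x_lower, x_th)");
  f[i0] = 1.0 / dx;

  // A(t) rows: df_i/dt = lo_i f_{i-1} + di_i f_i + up_i f_{i+1}
  std::vector<double> lo(m), di(m), up(m);
  auto buildA = [&](double cur) {
    for (int i = 0; i < m; ++i) {
      double bhR = cur - gamma * (x[i] + 0.5 * dx);   // b at i+1/2
      double bhL = cur - gamma * (x[i] - 0.5 * dx);   // b at i-1/2
      double l = 0.0, d = 0.0, u = 0.0;
      // outgoing flux J_{i+1/2}
      d += -(0.5 * bhR + D[i] / dx) / dx;
      if (i + 1 < m) u += -(0.5 * bhR - D[i + 1] / dx) / dx; // f_m = 0 absorbed
      // incoming flux J_{i-1/2} (zero at the reflecting boundary)
      if (i > 0) {
        l += (0.5 * bhL + D[i - 1] / dx) / dx;
        d += (0.5 * bhL - D[i] / dx) / dx;
      }
      lo[i] = l; di[i] = d; up[i] = u;
    }
  };

  g.assign(n + 1, 0.0); G.assign(n + 1, 0.0);
  double mass_prev = dx * std::accumulate(f.begin(), f.end(), 0.0);
  if (field) { field->reserve((size_t)(n + 1) * m); field->insert(field->end(), f.begin(), f.end()); }
  std::vector<double> rhs(m), a(m), b(m), c(m), fn(m);
  for (int k = 1; k <= n; ++k) {
    // Rannacher startup: two implicit-Euler steps damp the oscillations
    // Crank-Nicolson would excite from the Dirac initial condition
    const double th = (k <= 2) ? 1.0 : 0.5;
    buildA(itot[k - 1]);
    for (int i = 0; i < m; ++i) {
      rhs[i] = f[i] + (1.0 - th) * dt * (di[i] * f[i]
                 + (i > 0 ? lo[i] * f[i - 1] : 0.0)
                 + (i + 1 < m ? up[i] * f[i + 1] : 0.0));
    }
    buildA(itot[k]);
    for (int i = 0; i < m; ++i) {
      a[i] = -th * dt * lo[i];
      b[i] = 1.0 - th * dt * di[i];
      c[i] = -th * dt * up[i];
    }
    thomas(a, b, c, rhs, fn);
    f = fn;
    if (field) field->insert(field->end(), f.begin(), f.end());
    double mass = 0.0;
    for (int i = 0; i < m; ++i) mass += f[i];
    mass *= dx;
    g[k] = (mass_prev - mass) / dt;
    G[k] = 1.0 - mass;
    mass_prev = mass;
  }
  postprocess(g, G);
}

// ---------------------------------------------------------------------------
// Fokker-Planck CDF equation: Crank-Nicolson for
//   dF/dt = -b(x,t) dF/dx + D(x) d2F/dx2
// with F(x_lower,t)=0, dF/dx(x_th,t)=0 (ghost node) and Heaviside initial
// condition at x0. Survival of the ISI is F(x_th, t).
// ---------------------------------------------------------------------------

static void fp_cdf_solve(const std::vector<double>& itot, double dt,
                         double gamma, double sigma, double x0, double xth,
                         double xlow, double dx, bool feller,
                         std::vector<double>& g, std::vector<double>& G,
                         std::vector<double>* field = 0) {
  const int n = (int)itot.size() - 1;
  const int m = (int)std::round((xth - xlow) / dx);
  if (m < 3) stop("space grid too coarse");
  if (x0 <= xlow || x0 >= xth) stop("reset potential x0 must lie strictly inside (x_lower, x_th)");
  const double sig2 = sigma * sigma;
  std::vector<double> x(m + 1), D(m + 1);
  for (int i = 0; i <= m; ++i) {
    x[i] = xlow + i * dx;
    D[i] = feller ? 0.5 * sig2 * x[i] : 0.5 * sig2;
  }
  // unknowns F_1..F_m stored at indices 0..m-1; F_0 = 0 fixed
  std::vector<double> F(m);
  for (int i = 1; i <= m; ++i) F[i - 1] = (x[i] >= x0 - 1e-12) ? 1.0 : 0.0;

  std::vector<double> lo(m), di(m), up(m);
  auto buildA = [&](double cur) {
    for (int i = 1; i <= m; ++i) {
      int r = i - 1;
      if (i < m) {
        double bi = cur - gamma * x[i];
        lo[r] = (0.5 * bi / dx + D[i] / (dx * dx));
        di[r] = -2.0 * D[i] / (dx * dx);
        up[r] = (-0.5 * bi / dx + D[i] / (dx * dx));
      } else { // ghost node: F_{m+1} = F_{m-1}, advection term vanishes
        lo[r] = 2.0 * D[m] / (dx * dx);
        di[r] = -2.0 * D[m] / (dx * dx);
        up[r] = 0.0;
      }
    }
  };

  g.assign(n + 1, 0.0); G.assign(n + 1, 0.0);
  double surv_prev = F[m - 1];
  if (field) { field->reserve((size_t)(n + 1) * m); field->insert(field->end(), F.begin(), F.end()); }
  std::vector<double> rhs(m), a(m), b(m), c(m), Fn(m);
  for (int k = 1; k <= n; ++k) {
    // Rannacher startup against the Heaviside initial condition
    const double th = (k <= 2) ? 1.0 : 0.5;
    buildA(itot[k - 1]);
    for (int r = 0; r < m; ++r) {
      rhs[r] = F[r] + (1.0 - th) * dt * (di[r] * F[r]
                 + (r > 0 ? lo[r] * F[r - 1] : 0.0)   // F_0 = 0
                 + (r + 1 < m ? up[r] * F[r + 1] : 0.0));
    }
    buildA(itot[k]);
    for (int r = 0; r < m; ++r) {
      a[r] = -th * dt * lo[r];
      b[r] = 1.0 - th * dt * di[r];
      c[r] = -th * dt * up[r];
    }
    thomas(a, b, c, rhs, Fn);
    F = Fn;
    if (field) field->insert(field->end(), F.begin(), F.end());
    double surv = F[m - 1];
    g[k] = (surv_prev - surv) / dt;
    G[k] = 1.0 - surv;
    surv_prev = surv;
  }
  postprocess(g, G);
}

// ---------------------------------------------------------------------------
// Threshold-free Gaussian transition moments for the OU membrane process,
// computed incrementally on the solver grid:
//   M(t_k | v, t_j) = v r^{k-j} + A0[k] - r^{k-j} A0[j]
//   V(t_k | t_j)    = sigma^2/(2 gamma) (1 - r^{2(k-j)}),  r = exp(-gamma dt)
// where A0[k] accumulates int_0^{t_k} itot(u) exp(-gamma (t_k - u)) du by
// the trapezoid rule.
// ---------------------------------------------------------------------------

struct OUMoments {
  std::vector<double> A0, powr;
  double r, vinf;
  void init(const std::vector<double>& itot, double dt, double gamma, double sigma) {
    const int n = (int)itot.size() - 1;
    r = std::exp(-gamma * dt);
    vinf = sigma * sigma / (2.0 * gamma);
    A0.assign(n + 1, 0.0);
    powr.assign(n + 1, 1.0);
    for (int k = 1; k <= n; ++k) {
      A0[k] = r * A0[k - 1] + 0.5 * dt * (itot[k] + r * itot[k - 1]);
      powr[k] = powr[k - 1] * r;
    }
  }
  inline double M(int k, double v, int j) const {
    return v * powr[k - j] + A0[k] - powr[k - j] * A0[j];
  }
  inline double V(int k, int j) const {
    double p = powr[k - j];
    return vinf * (1.0 - p * p);
  }
};

static inline double gauss(double x, double mean, double var) {
  double d = x - mean;
  return std::exp(-0.5 * d * d / var) / std::sqrt(2.0 * M_PI * var);
}

// First-kind Volterra (Fortet) equation solved by forward substitution
// with the product-midpoint rule: the unknown density is carried at the
// half-steps t_{j-1/2}, which keeps the weakly singular kernel
// f*(xth, t_k | xth, s) bounded (closest evaluation dt/2 off the
// diagonal). Node values are recovered by averaging adjacent half-steps;
// g(0) = 0.
static void volterra1_solve(const std::vector<double>& itot, double dt,
                            double gamma, double sigma, double x0, double xth,
                            std::vector<double>& g, std::vector<double>& G) {
  const int n = (int)itot.size() - 1;
  OUMoments mo;
  mo.init(itot, dt, gamma, sigma);
  const double rh = std::exp(-gamma * 0.5 * dt);
  // A(0, t_{j-1/2}) by a half-step trapezoid from node j-1
  std::vector<double> A0h(n + 1, 0.0);
  for (int j = 1; j <= n; ++j) {
    double imid = 0.5 * (itot[j - 1] + itot[j]);
    A0h[j] = rh * mo.A0[j - 1] + 0.25 * dt * (imid + rh * itot[j - 1]);
  }
  // product-integration weights: the kernel carries a 1/sqrt(t_k - s)
  // factor near the diagonal, so each subinterval uses the exact integral
  // of that factor times the midpoint value of the smooth remainder
  std::vector<double> sq(n + 2);
  for (int i = 0; i <= n + 1; ++i) sq[i] = std::sqrt(i * dt);
  std::vector<double> w(n + 1, 0.0);
  for (int d = 0; d <= n; ++d) // d = k - j
    w[d] = 2.0 * (sq[d + 1] - sq[d]) * std::sqrt((d + 0.5) * dt);
  std::vector<double> h(n + 1, 0.0); // h[j] = g(t_{j-1/2})
  for (int k = 1; k <= n; ++k) {
    double lhs = gauss(xth, mo.M(k, x0, 0), mo.V(k, 0));
    double s = 0.0, Kkk = 0.0;
    for (int j = 1; j <= k; ++j) {
      double p = mo.powr[k - j] * rh;               // exp(-gamma (t_k - t_{j-1/2}))
      double Mm = xth * p + mo.A0[k] - p * A0h[j];
      double Vv = mo.vinf * (1.0 - p * p);
      double K = gauss(xth, Mm, Vv);
      if (j == k) Kkk = K; else s += w[k - j] * K * h[j];
    }
    // clip at zero during the recursion: once the density touches zero
    // (deep refractory troughs) oscillating negatives would otherwise
    // propagate through the convolution and corrupt the tail
    h[k] = std::max((lhs - s) / (w[0] * Kkk), 0.0);
  }
  g.assign(n + 1, 0.0); G.assign(n + 1, 0.0);
  for (int k = 1; k <= n; ++k) {
    g[k] = (k < n) ? 0.5 * (h[k] + h[k + 1]) : h[n];
    G[k] = G[k - 1] + dt * std::max(h[k], 0.0); // midpoint rule mass
  }
  postprocess(g, G);
}

// Second-kind Volterra equation with the singularity-removed kernel phi:
//   g(t) = -2 phi(xth, t | x0, 0) + 2 int_0^t phi(xth, t | xth, s) g(s) ds
// phi(x,t|v,s) = f*(x,t|v,s)/2 [gamma x - itot(t) - sigma^2/V (x - M)];
// phi vanishes on the diagonal, so trapezoid forward substitution is explicit.
static void volterra2_solve(const std::vector<double>& itot, double dt,
                            double gamma, double sigma, double x0, double xth,
                            std::vector<double>& g, std::vector<double>& G) {
  const int n = (int)itot.size() - 1;
  OUMoments mo;
  mo.init(itot, dt, gamma, sigma);
  const double sig2 = sigma * sigma;
  auto phi = [&](int k, double v, int j) {
    double Vv = mo.V(k, j);
    double Mm = mo.M(k, v, j);
    double fs = gauss(xth, Mm, Vv);
    return 0.5 * fs * (gamma * xth - itot[k] - sig2 / Vv * (xth - Mm));
  };
  g.assign(n + 1, 0.0); G.assign(n + 1, 0.0);
  for (int k = 1; k <= n; ++k) {
    double s = 0.0;
    for (int j = 1; j <= k - 1; ++j) {
      // trapezoid in the interior; the final subinterval uses the exact
      // integral of the kernel's sqrt(t_k - s) vanishing law (2/3 dt)
      double wj = (j == k - 1) ? (0.5 * dt + 2.0 * dt / 3.0) : dt;
      s += wj * phi(k, xth, j) * g[j];
    }
    g[k] = -2.0 * phi(k, x0, 0) + 2.0 * s;
    G[k] = G[k - 1] + 0.5 * dt * (std::max(g[k], 0.0) + std::max(g[k - 1], 0.0));
  }
  postprocess(g, G);
}

// method codes: 1 fp_pdf, 2 fp_cdf, 3 volterra1, 4 volterra2
static void fpt_dispatch(int method, const std::vector<double>& itot, double dt,
                         double gamma, double sigma, double x0, double xth,
                         double xlow, double dx, bool feller,
                         std::vector<double>& g, std::vector<double>& G) {
  if (method == 1) fp_pdf_solve(itot, dt, gamma, sigma, x0, xth, xlow, dx, feller, g, G);
  else if (method == 2) fp_cdf_solve(itot, dt, gamma, sigma, x0, xth, xlow, dx, feller, g, G);
  else if (method == 3 || method == 4) {
    if (feller) stop("Volterra backends require additive (OU) noise; use a Fokker-Planck backend for Feller noise");
    if (method == 3) volterra1_solve(itot, dt, gamma, sigma, x0, xth, g, G);
    else volterra2_solve(itot, dt, gamma, sigma, x0, xth, g, G);
  } else stop("unknown solver method code");
}

// [[Rcpp::export]]
List cpp_fpt_solve(NumericVector itot, double dt, double gamma, double sigma,
                   double x0, double xth, double xlow, double dx,
                   bool feller, int method, bool return_field = false) {
  std::vector<double> it = as<std::vector<double> >(itot);
  std::vector<double> g, G;
  if (return_field && (method == 1 || method == 2)) {
    std::vector<double> field;
    if (method == 1)
      fp_pdf_solve(it, dt, gamma, sigma, x0, xth, xlow, dx, feller, g, G, &field);
    else
      fp_cdf_solve(it, dt, gamma, sigma, x0, xth, xlow, dx, feller, g, G, &field);
    const int m = (int)(field.size() / it.size());
    NumericMatrix fm((int)it.size(), m);
    for (int k = 0; k < (int)it.size(); ++k)
      for (int i = 0; i < m; ++i) fm(k, i) = field[(size_t)k * m + i];
    return List::create(_["g"] = wrap(g), _["G"] = wrap(G), _["field"] = fm);
  }
  fpt_dispatch(method, it, dt, gamma, sigma, x0, xth, xlow, dx, feller, g, G);
  return List::create(_["g"] = wrap(g), _["G"] = wrap(G));
}

// ---------------------------------------------------------------------------
// Per-train ISI likelihood: for every observed ISI build the total current
// on a local grid anchored at the previous spike, run the chosen solver and
// interpolate g and G at the observed ISI length.
// ---------------------------------------------------------------------------

// [[Rcpp::export]]
List cpp_train_isi_gG(NumericVector spikes, double gmu, double gamma,
                      double sigma, double x0, double xth, double xlow,
                      bool feller, NumericVector ktab, double ktab_dt,
                      List stim, double dt, double dx, int method) {
  const int N = spikes.size();
  std::vector<StimTerm> terms = parse_stim(stim);
  NumericVector gout(N), Gout(N);
  double ll = 0.0;
  std::vector<double> g, G;
  for (int j = 0; j < N; ++j) {
    double tprev = (j == 0) ? 0.0 : spikes[j - 1];
    double isi = spikes[j] - tprev;
    if (isi <= 0) stop("spike times must be strictly increasing");
    int n = (int)std::ceil(isi / dt - 1e-9) + 1;
    if (n < 2) n = 2;
    std::vector<double> itot(n + 1);
    for (int i = 0; i <= n; ++i) {
      double t = tprev + i * dt;
      double h = 0.0;
      for (int k = 0; k < j; ++k) {
        double e = t - spikes[k];
        long idx = (long)std::floor(e / ktab_dt);
        if (idx >= 0 && idx < ktab.size()) h += ktab[idx];
      }
      itot[i] = gmu + eval_stim(terms, t) + h;
    }
    fpt_dispatch(method, itot, dt, gamma, sigma, x0, xth, xlow, dx, feller, g, G);
    double pos = isi / dt;
    int i0 = (int)std::floor(pos);
    if (i0 >= n) i0 = n - 1;
    double frac = pos - i0;
    double gat = g[i0] + frac * (g[i0 + 1] - g[i0]);
    double Gat = G[i0] + frac * (G[i0 + 1] - G[i0]);
    gout[j] = gat;
    Gout[j] = Gat;
    ll += std::log(std::max(gat, G_FLOOR));
  }
  return List::create(_["loglik"] = ll, _["g"] = gout, _["G"] = Gout);
}

// ---------------------------------------------------------------------------
// Euler-Maruyama simulation of one spike train. The post-spike current is
// propagated exactly through two exponential filter states (one per kernel
// exponential), so no kernel truncation enters the simulator. Threshold
// crossings are detected at grid points; the membrane resets to x0 while
// stimulus time and spike history continue uninterrupted. Uses the R RNG.
// ---------------------------------------------------------------------------

// [[Rcpp::export]]
List cpp_simulate_train(double mu, double gamma, double sigma, double x0,
                        double xth, bool feller, NumericVector eta,
                        List stim, double T, double dt, bool record_voltage) {
  if (dt <= 0 || T <= 0) stop("dt_sim and T must be positive");
  std::vector<StimTerm> terms = parse_stim(stim);
  const long nstep = (long)std::round(T / dt);
  const double e1 = eta[0], e2 = eta[1], e3 = eta[2], e4 = eta[3];
  const double dA = std::exp(-e2 * dt), dB = std::exp(-e4 * dt);
  const double sqdt = std::sqrt(dt);
  double X = x0, A = 0.0, B = 0.0;
  std::vector<double> spikes;
  NumericVector volt;
  if (record_voltage) volt = NumericVector(nstep + 1);
  if (record_voltage) volt[0] = X;
  RNGScope scope;
  for (long i = 0; i < nstep; ++i) {
    double t = i * dt;
    double H = e1 * A - e3 * B;
    double drift = -gamma * (X - mu) + eval_stim(terms, t) + H;
    double noise = feller ? sigma * std::sqrt(std::max(X, 0.0)) : sigma;
    X += drift * dt + noise * sqdt * R::norm_rand();
    if (feller && X < 0) X = 0.0; // full truncation keeps sqrt defined
    A *= dA; B *= dB;
    if (X >= xth) {
      spikes.push_back((i + 1) * dt);
      X = x0;
      A += 1.0; B += 1.0;
    }
    if (record_voltage) volt[i + 1] = X;
  }
  List out = List::create(_["spikes"] = wrap(spikes));
  if (record_voltage) out["voltage"] = volt;
  return out;
}

// [[Rcpp::export]]
NumericVector cpp_simulate_ou_path(double s1, double s2, double dt, double T) {
  if (dt <= 0 || T <= 0) stop("dt and T must be positive");
  const long n = (long)std::round(T / dt);
  NumericVector S(n + 1);
  S[0] = s1; // start at the asymptotic mean
  const double sqdt = std::sqrt(dt);
  RNGScope scope;
  for (long i = 0; i < n; ++i)
    S[i + 1] = S[i] + (s1 - S[i]) * dt + s2 * sqdt * R::norm_rand();
  return S;
}
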