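// Batched forward / backward-through-time kernels for the three recurrent
// model families. States are n x batch matrices; input and target tensors
// are (channels x batch x time) cubes with one delay length per batch.
// Gradients are hand-derived; the single-step R functions in R/models.R
// define the same step semantics and the test suite checks the two paths
// against each other.
#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;
using arma::mat;
using arma::vec;
using arma::cube;
using arma::uword;

// Per-kernel-call noise stream: the generator is seeded once per call from
// R's RNG, so results are reproducible under set.seed() while the draws
// themselves come from a fast local Mersenne twister.
#include <random>
static std::mt19937_64 noise_rng;

static void seed_arma_from_r() {
  double u = R::unif_rand();
  noise_rng.seed((unsigned long long)(u * 9007199254740992.0));
}

static inline mat draw_noise(int n, int B, double sd) {
  if (sd <= 0.0) return arma::zeros<mat>(n, B);
  std::normal_distribution<double> nd(0.0, sd);
  mat Z(n, B);
  double* p = Z.memptr();
  for (int i = 0; i < n * B; ++i) p[i] = nd(noise_rng);
  return Z;
}

static inline mat relu(const mat& H) {
  return arma::clamp(H, 0.0, arma::datum::inf);
}

// training kernels for the two large-n families run in single precision:
// BPTT training tolerates fp32 well and the batched GEMMs double their
// throughput; the record kernels (analysis path) stay in double
typedef arma::fmat fmat_t;
typedef arma::fvec fvec_t;
typedef arma::fcube fcube_t;

// per-trial fraction of window timepoints where argmax over the first
// n_classes output channels matches the target class
static vec window_acc_init(int B) { return arma::zeros<vec>(B); }

static void acc_accumulate(vec& hits, const mat& Yhat, const mat& Ytgt,
                           int n_classes) {
  for (uword j = 0; j < Yhat.n_cols; ++j) {
    uword pred = arma::index_max(Yhat.col(j).head(n_classes));
    uword tru = arma::index_max(Ytgt.col(j).head(n_classes));
    if (pred == tru) hits(j) += 1.0;
  }
}

// ---------------------------------------------------------------------------
// Fixed-synapse network: x_t = (1-a) x_{t-1} + a phi(W x_{t-1} + I_t + b + xi)
// act: 0 = tanh, 1 = relu, 2 = identity
// ---------------------------------------------------------------------------

// [[Rcpp::export]]
List cpp_fs_batch(const arma::mat& W, const arma::mat& Win, const arma::vec& b,
                  const arma::mat& Wout, const arma::vec& cvec,
                  const arma::cube& M, const arma::cube& Y,
                  int win0, int win1, int n_classes,
                  double alpha, double noise_sd, int act,
                  double act_reg, bool grad) {
  const int n = W.n_rows, B = M.n_cols, T = M.n_slices;
  const int n_out = Wout.n_rows;
  if (noise_sd > 0) seed_arma_from_r();
  const int Twin = win1 - win0 + 1;
  const float al = (float)alpha;

  fmat_t Wf = arma::conv_to<fmat_t>::from(W);
  fmat_t Winf = arma::conv_to<fmat_t>::from(Win);
  fvec_t bf = arma::conv_to<fvec_t>::from(b);
  fmat_t Woutf = arma::conv_to<fmat_t>::from(Wout);
  fvec_t cf = arma::conv_to<fvec_t>::from(cvec);
  fcube_t Mf = arma::conv_to<fcube_t>::from(M);
  fcube_t Yf = arma::conv_to<fcube_t>::from(Y);

  fcube_t X(n, B, T + 1, arma::fill::zeros);
  fcube_t A(n, B, T);
  fmat_t H(n, B);
  std::normal_distribution<float> nd(0.0f, (float)(noise_sd > 0 ? noise_sd : 1.0));
  double mse = 0.0, reg = 0.0;
  vec hits = window_acc_init(B);

  for (int t = 1; t <= T; ++t) {
    H = Wf * X.slice(t - 1) + Winf * Mf.slice(t - 1);
    const float* xp = X.slice(t - 1).memptr();
    float* xn = X.slice(t).memptr();
    float* ac = A.slice(t - 1).memptr();
    float* h = H.memptr();
    double chk = 0.0;
    for (int e = 0; e < n * B; ++e) {
      const int i = e % n;
      float hv = h[e] + bf(i);
      if (noise_sd > 0) hv += nd(noise_rng);
      float ph;
      if (act == 0) ph = std::tanh(hv);
      else if (act == 1) ph = hv > 0 ? hv : 0;
      else ph = hv;
      const float x1 = (1.0f - al) * xp[e] + al * ph;
      ac[e] = ph;
      xn[e] = x1;
      chk += x1;
      if (act_reg > 0) reg += (double)x1 * x1;
    }
    if (!std::isfinite(chk))
      stop("non-finite state at step %d (fixed-synapse forward)", t);
    if (t >= win0 && t <= win1) {
      fmat_t Yhat = Woutf * X.slice(t);
      Yhat.each_col() += cf;
      mse += arma::accu(arma::square(
          arma::conv_to<mat>::from(Yhat - Yf.slice(t - 1))));
      for (int j = 0; j < B; ++j) {
        int pred = (int)arma::index_max(Yhat.col(j).head(n_classes));
        int tru = (int)arma::index_max(Yf.slice(t - 1).col(j).head(n_classes));
        if (pred == tru) hits(j) += 1.0;
      }
    }
  }
  mse /= (double)n_out * Twin * B;
  reg = act_reg * reg / ((double)n * T);
  vec acc = hits / (double)Twin;

  List out = List::create(_["loss"] = mse + reg, _["mse"] = mse,
                          _["reg"] = reg, _["acc"] = acc);
  if (!grad) return out;

  fmat_t dW(n, n, arma::fill::zeros), dWin(n, Win.n_cols, arma::fill::zeros);
  fvec_t db(n, arma::fill::zeros);
  fmat_t dWout(n_out, n, arma::fill::zeros);
  fvec_t dc(n_out, arma::fill::zeros);
  fmat_t dx(n, B, arma::fill::zeros), G(n, B);
  const float esc = (float)(2.0 / ((double)n_out * Twin * B));
  const float rsc = (float)(2.0 * act_reg / ((double)n * T));

  for (int t = T; t >= 1; --t) {
    if (t >= win0 && t <= win1) {
      fmat_t Yhat = Woutf * X.slice(t);
      Yhat.each_col() += cf;
      fmat_t E = esc * (Yhat - Yf.slice(t - 1));
      dWout += E * X.slice(t).t();
      dc += arma::sum(E, 1);
      dx += Woutf.t() * E;
    }
    {
      const float* xt = X.slice(t).memptr();
      const float* ac = A.slice(t - 1).memptr();
      float* dxp = dx.memptr();
      float* gp = G.memptr();
      for (int e = 0; e < n * B; ++e) {
        const int i = e % n;
        float d = dxp[e];
        if (act_reg > 0) d += rsc * xt[e];
        dxp[e] = d;
        float phip;
        if (act == 0) phip = 1.0f - ac[e] * ac[e];
        else if (act == 1) phip = ac[e] > 0 ? 1.0f : 0.0f;
        else phip = 1.0f;
        const float g = al * phip * d;
        gp[e] = g;
        db(i) += g;
      }
    }
    dW += G * X.slice(t - 1).t();
    dWin += G * Mf.slice(t - 1).t();
    dx = (1.0f - al) * dx + Wf.t() * G;
  }
  out["grads"] = List::create(
      _["W"] = arma::conv_to<mat>::from(dW),
      _["W_in"] = arma::conv_to<mat>::from(dWin),
      _["b"] = arma::conv_to<vec>::from(db),
      _["W_out"] = arma::conv_to<mat>::from(dWout),
      _["c"] = arma::conv_to<vec>::from(dc));
  return out;
}

// [[Rcpp::export]]
List cpp_fs_record(const arma::mat& W, const arma::mat& Win, const arma::vec& b,
                   const arma::cube& M, double alpha, double noise_sd, int act) {
  const int n = W.n_rows, B = M.n_cols, T = M.n_slices;
  if (noise_sd > 0) seed_arma_from_r();
  cube X(n, B, T, arma::fill::zeros);
  mat x(n, B, arma::fill::zeros);
  for (int t = 1; t <= T; ++t) {
    mat H = W * x + Win * M.slice(t - 1);
    H.each_col() += b;
    if (noise_sd > 0) H += draw_noise(n, B, noise_sd);
    mat Ph;
    if (act == 0) Ph = arma::tanh(H);
    else if (act == 1) Ph = relu(H);
    else Ph = H;
    x = (1.0 - alpha) * x + alpha * Ph;
    if (!x.is_finite()) stop("non-finite state at step %d", t);
    X.slice(t - 1) = x;
  }
  return List::create(_["rates"] = X);
}

// ---------------------------------------------------------------------------
// PS-pre: presynaptic facilitation/depression (utilization u, resources a)
// with Dale's-law signed effective weights W_eff = relu(W_raw) * diag(d).
//   x_t = (1-a) x + a relu(W_eff (u.a.x) + I + b [+ xi])
//   u_t = clip01(u + dt [(U-u)/tau_u + U (1-u) x])
//   a_t = clip01(a + dt [(1-a)/tau_a - u a x])
// tau in seconds, dt_s in seconds, rates dimensionless.
// ---------------------------------------------------------------------------

// [[Rcpp::export]]
List cpp_pspre_batch(const arma::mat& Wraw, const arma::vec& dsign, const arma::mat& Win,
                     const arma::vec& b, const arma::mat& Wout, const arma::vec& cvec,
                     const arma::vec& tau_a, const arma::vec& tau_u, const arma::vec& Uvec,
                     const arma::cube& M, const arma::cube& Y,
                     int win0, int win1, int n_classes,
                     double alpha, double dt_s, double noise_sd,
                     double act_reg, bool grad, bool freeze_syn) {
  const int n = Wraw.n_rows, B = M.n_cols, T = M.n_slices;
  const int n_out = Wout.n_rows;
  if (noise_sd > 0) seed_arma_from_r();
  const int Twin = win1 - win0 + 1;
  const float al = (float)alpha, dt = (float)dt_s;

  mat Weff_d = relu(Wraw);
  Weff_d.each_row() %= dsign.t(); // column j carries presynaptic sign d_j
  fmat_t Weff = arma::conv_to<fmat_t>::from(Weff_d);
  fmat_t Winf = arma::conv_to<fmat_t>::from(Win);
  fvec_t bf = arma::conv_to<fvec_t>::from(b);
  fmat_t Woutf = arma::conv_to<fmat_t>::from(Wout);
  fvec_t cf = arma::conv_to<fvec_t>::from(cvec);
  fcube_t Mf = arma::conv_to<fcube_t>::from(M);
  fcube_t Yf = arma::conv_to<fcube_t>::from(Y);
  fvec_t itu = arma::conv_to<fvec_t>::from(1.0 / tau_u);
  fvec_t ita = arma::conv_to<fvec_t>::from(1.0 / tau_a);
  fvec_t Uf = arma::conv_to<fvec_t>::from(Uvec);

  // state history for BPTT; elementwise arithmetic fused into single
  // passes per step so memory traffic stays at the arrays the gradient
  // actually needs
  fcube_t X(n, B, T + 1, arma::fill::zeros);
  fcube_t U(n, B, T + 1, arma::fill::zeros);
  if (freeze_syn) U.slice(0).ones(); // plasticity-off limit: u = a = 1
  fcube_t Aa(n, B, T + 1);
  Aa.slice(0).ones();
  fcube_t Act(n, B, T);
  fmat_t S(n, B, arma::fill::zeros); // u.a.x carried into the next drive
  fmat_t H(n, B);
  std::normal_distribution<float> nd(0.0f, (float)(noise_sd > 0 ? noise_sd : 1.0));

  double mse = 0.0, reg = 0.0;
  vec hits = window_acc_init(B);

  for (int t = 1; t <= T; ++t) {
    H = Weff * S + Winf * Mf.slice(t - 1);
    const float* xp = X.slice(t - 1).memptr();
    const float* up = U.slice(t - 1).memptr();
    const float* ap = Aa.slice(t - 1).memptr();
    float* xn = X.slice(t).memptr();
    float* un = U.slice(t).memptr();
    float* an = Aa.slice(t).memptr();
    float* ac = Act.slice(t - 1).memptr();
    float* h = H.memptr();
    float* sp = S.memptr();
    double chk = 0.0;
    for (int e = 0; e < n * B; ++e) {
      const int i = e % n;
      float hv = h[e] + bf(i);
      if (noise_sd > 0) hv += nd(noise_rng);
      const float ph = hv > 0 ? hv : 0;
      const float x1 = (1.0f - al) * xp[e] + al * ph;
      ac[e] = ph;
      xn[e] = x1;
      chk += x1;
      float u1, a1;
      if (freeze_syn) {
        u1 = up[e];
        a1 = ap[e];
      } else {
        u1 = up[e] + dt * ((Uf(i) - up[e]) * itu(i) +
                           Uf(i) * (1.0f - up[e]) * xp[e]);
        a1 = ap[e] + dt * ((1.0f - ap[e]) * ita(i) -
                           up[e] * ap[e] * xp[e]);
        u1 = u1 < 0 ? 0 : (u1 > 1 ? 1 : u1);
        a1 = a1 < 0 ? 0 : (a1 > 1 ? 1 : a1);
      }
      un[e] = u1;
      an[e] = a1;
      sp[e] = u1 * a1 * x1;
      if (act_reg > 0) reg += (double)x1 * x1;
    }
    if (!std::isfinite(chk))
      stop("non-finite state at step %d (PS-pre forward)", t);
    if (t >= win0 && t <= win1) {
      fmat_t Yhat = Woutf * X.slice(t);
      Yhat.each_col() += cf;
      mse += arma::accu(arma::square(
          arma::conv_to<mat>::from(Yhat - Yf.slice(t - 1))));
      for (int j = 0; j < B; ++j) {
        int pred = (int)arma::index_max(Yhat.col(j).head(n_classes));
        int tru = (int)arma::index_max(Yf.slice(t - 1).col(j).head(n_classes));
        if (pred == tru) hits(j) += 1.0;
      }
    }
  }
  mse /= (double)n_out * Twin * B;
  reg = act_reg * reg / ((double)n * T);
  vec acc = hits / (double)Twin;

  List out = List::create(_["loss"] = mse + reg, _["mse"] = mse,
                          _["reg"] = reg, _["acc"] = acc,
                          _["u_final"] = arma::conv_to<mat>::from(U.slice(T)),
                          _["a_final"] = arma::conv_to<mat>::from(Aa.slice(T)));
  if (!grad) return out;

  fmat_t dWeff(n, n, arma::fill::zeros), dWin(n, Win.n_cols, arma::fill::zeros);
  fvec_t db(n, arma::fill::zeros);
  fmat_t dWout(n_out, n, arma::fill::zeros);
  fvec_t dc(n_out, arma::fill::zeros);
  fmat_t dx(n, B, arma::fill::zeros), du(n, B, arma::fill::zeros),
      da(n, B, arma::fill::zeros);
  fmat_t dx2(n, B), du2(n, B), da2(n, B);
  fmat_t G(n, B), Sprev(n, B), dS(n, B);
  const float esc = (float)(2.0 / ((double)n_out * Twin * B));
  const float rsc = (float)(2.0 * act_reg / ((double)n * T));

  for (int t = T; t >= 1; --t) {
    if (t >= win0 && t <= win1) {
      fmat_t Yhat = Woutf * X.slice(t);
      Yhat.each_col() += cf;
      fmat_t E = esc * (Yhat - Yf.slice(t - 1));
      dWout += E * X.slice(t).t();
      dc += arma::sum(E, 1);
      dx += Woutf.t() * E;
    }
    {
      const float* xt = X.slice(t).memptr();
      const float* xp = X.slice(t - 1).memptr();
      const float* up = U.slice(t - 1).memptr();
      const float* ap = Aa.slice(t - 1).memptr();
      const float* ac = Act.slice(t - 1).memptr();
      float* dxp = dx.memptr();
      float* gp = G.memptr();
      float* spv = Sprev.memptr();
      for (int e = 0; e < n * B; ++e) {
        const int i = e % n;
        float d = dxp[e];
        if (act_reg > 0) d += rsc * xt[e];
        dxp[e] = d;
        const float g = ac[e] > 0 ? al * d : 0.0f;
        gp[e] = g;
        db(i) += g;
        spv[e] = up[e] * ap[e] * xp[e];
      }
    }
    dWeff += G * Sprev.t();
    dWin += G * Mf.slice(t - 1).t();
    dS = Weff.t() * G;
    {
      const float* xp = X.slice(t - 1).memptr();
      const float* up = U.slice(t - 1).memptr();
      const float* ap = Aa.slice(t - 1).memptr();
      const float* ut = U.slice(t).memptr();
      const float* at = Aa.slice(t).memptr();
      const float* dxp = dx.memptr();
      const float* dup = du.memptr();
      const float* dap = da.memptr();
      const float* dsp = dS.memptr();
      float* ndx = dx2.memptr();
      float* ndu = du2.memptr();
      float* nda = da2.memptr();
      for (int e = 0; e < n * B; ++e) {
        const int i = e % n;
        // clip subgradient: zero where u_t / a_t sit on a clamp boundary
        const float due = (ut[e] > 0.0f && ut[e] < 1.0f) ? dup[e] : 0.0f;
        const float dae = (at[e] > 0.0f && at[e] < 1.0f) ? dap[e] : 0.0f;
        const float uv = up[e], av = ap[e], xv = xp[e], ds = dsp[e];
        ndx[e] = (1.0f - al) * dxp[e] + ds * uv * av +
          due * dt * Uf(i) * (1.0f - uv) - dae * dt * uv * av;
        ndu[e] = ds * av * xv +
          due * (1.0f - dt * (itu(i) + Uf(i) * xv)) -
          dae * dt * av * xv;
        nda[e] = ds * uv * xv + dae * (1.0f - dt * (ita(i) + uv * xv));
      }
    }
    dx.swap(dx2);
    du.swap(du2);
    da.swap(da2);
  }
  mat dWeff_d = arma::conv_to<mat>::from(dWeff);
  dWeff_d.each_row() %= dsign.t();
  mat dWraw = dWeff_d % arma::conv_to<mat>::from(Wraw > 0);
  out["grads"] = List::create(
      _["W"] = dWraw,
      _["W_in"] = arma::conv_to<mat>::from(dWin),
      _["b"] = arma::conv_to<vec>::from(db),
      _["W_out"] = arma::conv_to<mat>::from(dWout),
      _["c"] = arma::conv_to<vec>::from(dc));
  return out;
}

// [[Rcpp::export]]
List cpp_pspre_record(const arma::mat& Wraw, const arma::vec& dsign, const arma::mat& Win,
                      const arma::vec& b, const arma::vec& tau_a, const arma::vec& tau_u,
                      const arma::vec& Uvec, const arma::cube& M, double alpha,
                      double dt_s, double noise_sd, bool freeze_syn) {
  const int n = Wraw.n_rows, B = M.n_cols, T = M.n_slices;
  if (noise_sd > 0) seed_arma_from_r();
  mat Weff = relu(Wraw);
  Weff.each_row() %= dsign.t();
  const vec itu = 1.0 / tau_u, ita = 1.0 / tau_a;
  cube X(n, B, T), U(n, B, T), Aa(n, B, T);
  mat x(n, B, arma::fill::zeros), u(n, B, arma::fill::zeros),
      a(n, B, arma::fill::ones);
  if (freeze_syn) u.ones(); // plasticity-off limit: u = a = 1
  for (int t = 1; t <= T; ++t) {
    mat H = Weff * (u % a % x) + Win * M.slice(t - 1);
    H.each_col() += b;
    if (noise_sd > 0) H += draw_noise(n, B, noise_sd);
    mat xn = (1.0 - alpha) * x + alpha * relu(H);
    if (!xn.is_finite()) stop("non-finite state at step %d", t);
    if (!freeze_syn) {
      mat rec = -u;
      rec.each_col() += Uvec;
      rec.each_col() %= itu;
      mat fac = (1.0 - u) % x;
      fac.each_col() %= Uvec;
      mat un = arma::clamp(u + dt_s * (rec + fac), 0.0, 1.0);
      mat ra = 1.0 - a;
      ra.each_col() %= ita;
      a = arma::clamp(a + dt_s * (ra - u % a % x), 0.0, 1.0);
      u = un;
    }
    x = xn;
    X.slice(t - 1) = x;
    U.slice(t - 1) = u;
    Aa.slice(t - 1) = a;
  }
  return List::create(_["rates"] = X, _["u"] = U, _["a"] = Aa);
}

// ---------------------------------------------------------------------------
// PS-hebb: anti-Hebbian plastic weights, identity activation.
//   x_t = (1-a) x + a (W x + I + b + xi)
//   W_t = lam W - a K o (x x^T),  lam = 1 - dt*gamma
// K = (C^2)^T (C^2) + 1e-2 O + 1e-2 I, elementwise square; trained via C.
// Per-trial weight state, so trials are looped (n is small by design).
// ---------------------------------------------------------------------------

// [[Rcpp::export]]
List cpp_pshebb_batch(const arma::mat& C, const arma::mat& Win, const arma::vec& b,
                      const arma::mat& Wout, const arma::vec& cvec,
                      const arma::cube& M, const arma::cube& Y,
                      int win0, int win1, int n_classes,
                      double alpha, double lam, double noise_sd,
                      double act_reg, bool grad, const arma::mat& Kmask) {
  const int n = C.n_rows, B = M.n_cols, T = M.n_slices;
  const int n_out = Wout.n_rows;
  if (noise_sd > 0) seed_arma_from_r();
  const int Twin = win1 - win0 + 1;

  mat Bm = arma::square(C);
  mat K = Bm.t() * Bm;
  K += 0.01;
  K.diag() += 0.01;
  K %= Kmask;
  const double* Kp = K.memptr();

  // per-step external drive for the whole batch, one gemm per step
  cube Drive(n, B, T);
  for (int t = 0; t < T; ++t) Drive.slice(t) = Win * M.slice(t);

  double mse = 0.0, reg = 0.0;
  vec hits = window_acc_init(B);
  mat dK(n, n, arma::fill::zeros), dWin(n, Win.n_cols, arma::fill::zeros);
  vec db(n, arma::fill::zeros);
  mat dWout(n_out, n, arma::fill::zeros);
  vec dc(n_out, arma::fill::zeros);
  const double esc = 2.0 / ((double)n_out * Twin * B);
  const double rsc = 2.0 * act_reg / ((double)n * T);

  // per-trial state history; preallocated, raw loops (n is small, so the
  // cost is dominated by loop overhead rather than BLAS)
  mat Xs(n, T + 1);
  cube Ws(n, n, T + 1);
  mat Noise(n, T);
  std::normal_distribution<double> nd(0.0, noise_sd > 0 ? noise_sd : 1.0);
  std::vector<double> hbuf(n), dxv(n), dx2v(n);
  mat dWt(n, n);
  vec yhat(n_out);

  int n_diverged = 0;
  for (int j = 0; j < B; ++j) {
    Xs.col(0).zeros();
    Ws.slice(0).zeros();
    bool diverged = false;
    if (noise_sd > 0) {
      double* np = Noise.memptr();
      for (int e = 0; e < n * T; ++e) np[e] = nd(noise_rng);
    }
    for (int t = 1; t <= T; ++t) {
      const double* x = Xs.colptr(t - 1);
      const double* Wp = Ws.slice(t - 1).memptr();
      double* xn = Xs.colptr(t);
      double* Wn = Ws.slice(t).memptr();
      const double* dr = Drive.slice(t - 1).colptr(j);
      double* h = hbuf.data();
      for (int i = 0; i < n; ++i) {
        h[i] = dr[i] + b(i);
        if (noise_sd > 0) h[i] += Noise(i, t - 1);
      }
      for (int k = 0; k < n; ++k) {
        const double xk = x[k];
        if (xk != 0.0) {
          const double* wc = Wp + (size_t)k * n;
          for (int i = 0; i < n; ++i) h[i] += wc[i] * xk;
        }
      }
      double amax = 0.0;
      for (int i = 0; i < n; ++i) {
        const double v = (1.0 - alpha) * x[i] + alpha * h[i];
        xn[i] = v;
        const double av = std::abs(v);
        if (av > amax) amax = av;
        if (act_reg > 0) reg += v * v;
      }
      if (!std::isfinite(amax) || amax > 1e6) {
        // divergent trial: abort training, but score it as a task failure
        // during evaluation (trials are independent here)
        if (grad)
          stop("PS-hebb state blow-up at step %d (||x||_inf > 1e6)", t);
        diverged = true;
        break;
      }
      for (int k = 0; k < n; ++k) {
        const double ck = alpha * x[k];
        const double* wc = Wp + (size_t)k * n;
        const double* kc = Kp + (size_t)k * n;
        double* nc = Wn + (size_t)k * n;
        for (int i = 0; i < n; ++i) nc[i] = lam * wc[i] - ck * kc[i] * x[i];
      }
      if (t >= win0 && t <= win1) {
        const double* ytgt = Y.slice(t - 1).colptr(j);
        for (int o = 0; o < n_out; ++o) {
          double s = cvec(o);
          for (int i = 0; i < n; ++i) s += Wout(o, i) * xn[i];
          yhat(o) = s;
          const double err = s - ytgt[o];
          mse += err * err;
        }
        int pred = 0, tru = 0;
        for (int o = 1; o < n_classes; ++o) {
          if (yhat(o) > yhat(pred)) pred = o;
          if (ytgt[o] > ytgt[tru]) tru = o;
        }
        if (pred == tru) hits(j) += 1.0;
      }
    }
    if (diverged) {
      hits(j) = 0.0;
      ++n_diverged;
      continue;
    }
    if (!grad) continue;
    std::fill(dxv.begin(), dxv.end(), 0.0);
    dWt.zeros();
    double* dWtp = dWt.memptr();
    for (int t = T; t >= 1; --t) {
      double* dx = dxv.data();
      double* dx2 = dx2v.data();
      const double* x = Xs.colptr(t);
      const double* xp = Xs.colptr(t - 1);
      if (t >= win0 && t <= win1) {
        const double* ytgt = Y.slice(t - 1).colptr(j);
        for (int o = 0; o < n_out; ++o) {
          double s = cvec(o);
          for (int i = 0; i < n; ++i) s += Wout(o, i) * x[i];
          const double e = esc * (s - ytgt[o]);
          dc(o) += e;
          for (int i = 0; i < n; ++i) {
            dWout(o, i) += e * x[i];
            dx[i] += Wout(o, i) * e;
          }
        }
      }
      if (act_reg > 0) for (int i = 0; i < n; ++i) dx[i] += rsc * x[i];
      // x_t equation
      const double* drr = M.slice(t - 1).colptr(j);
      for (int i = 0; i < n; ++i) db(i) += alpha * dx[i];
      for (int k = 0; k < (int)Win.n_cols; ++k) {
        const double mk = drr[k];
        if (mk != 0.0) {
          for (int i = 0; i < n; ++i) dWin(i, k) += alpha * dx[i] * mk;
        }
      }
      const double* Wp = Ws.slice(t - 1).memptr();
      for (int i = 0; i < n; ++i) dx2[i] = (1.0 - alpha) * dx[i];
      for (int k = 0; k < n; ++k) {
        const double* wc = Wp + (size_t)k * n;
        double s = 0.0;
        for (int i = 0; i < n; ++i) s += wc[i] * dx[i];
        dx2[k] += alpha * s; // (W^T dx)_k
      }
      // W_t equation, using dW_t before the rate-equation contribution
      for (int k = 0; k < n; ++k) {
        const double xk = xp[k];
        const double* kc = Kp + (size_t)k * n;
        double* dwc = dWtp + (size_t)k * n;
        for (int i = 0; i < n; ++i) {
          const double dw = dwc[i];
          dK(i, k) += -alpha * dw * xp[i] * xk;
          const double kd = dw * kc[i];
          dx2[i] += -alpha * kd * xk; // (dW o K) x
          dx2[k] += -alpha * kd * xp[i]; // (dW o K)^T x
          dwc[i] = lam * dw + alpha * dx[i] * xk;
        }
      }
      std::swap(dxv, dx2v);
      std::fill(dx2v.begin(), dx2v.end(), 0.0);
    }
  }
  mse /= (double)n_out * Twin * B;
  reg = act_reg * reg / ((double)n * T);
  vec acc = hits / (double)Twin;
  List out = List::create(_["loss"] = mse + reg, _["mse"] = mse,
                          _["reg"] = reg, _["acc"] = acc,
                          _["n_diverged"] = n_diverged);
  if (!grad) return out;
  dK %= Kmask;
  mat dB = Bm * (dK + dK.t());
  mat dC = 2.0 * (C % dB);
  out["grads"] = List::create(_["C"] = dC, _["W_in"] = dWin, _["b"] = db,
                              _["W_out"] = dWout, _["c"] = dc);
  return out;
}

// [[Rcpp::export]]
List cpp_pshebb_record(const arma::mat& C, const arma::mat& Win, const arma::vec& b,
                       const arma::cube& M, double alpha, double lam,
                       double noise_sd, bool record_w, const arma::mat& Kmask,
                       bool freeze_w, const arma::mat& W0) {
  const int n = C.n_rows, B = M.n_cols, T = M.n_slices;
  if (noise_sd > 0) seed_arma_from_r();
  mat Bm = arma::square(C);
  mat K = Bm.t() * Bm;
  K += 0.01;
  K.diag() += 0.01;
  K %= Kmask;

  cube X(n, B, T);
  cube Wt;
  if (record_w) Wt.set_size(n * n, B, T);
  mat Noise(n, T);
  for (int j = 0; j < B; ++j) {
    vec x(n, arma::fill::zeros);
    mat W = freeze_w ? W0 : arma::zeros<mat>(n, n);
    if (noise_sd > 0) Noise = draw_noise(n, T, noise_sd);
    for (int t = 1; t <= T; ++t) {
      vec h = W * x + Win * M.slice(t - 1).col(j) + b;
      if (noise_sd > 0) h += Noise.col(t - 1);
      vec xn = (1.0 - alpha) * x + alpha * h;
      if (!xn.is_finite() || arma::abs(xn).max() > 1e6)
        stop("PS-hebb state blow-up at step %d", t);
      if (!freeze_w) W = lam * W - alpha * (K % (x * x.t()));
      x = xn;
      X.slice(t - 1).col(j) = x;
      if (record_w) Wt.slice(t - 1).col(j) = arma::vectorise(W);
    }
  }
  List out = List::create(_["rates"] = X);
  if (record_w) out["weights"] = Wt;
  return out;
}
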