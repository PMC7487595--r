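// Core likelihood kernels for interval-censored outcomes observed through
// error-prone self-reports, plus the profile optimizer for the baseline
// interval probabilities theta.  theta is parameterized through a
// multinomial-logit map with the last interval as reference so the profile
// maximization is unconstrained.  The profile Newton solver is on the
// sampler's hot path (it runs at every Metropolis-Hastings proposal), so it
// works on preallocated flat buffers rather than allocating per call.
// [[Rcpp::depends(RcppArmadillo)]]
#include <RcppArmadillo.h>

using namespace Rcpp;

static const double NEG_INF = -std::numeric_limits<double>::infinity();

// softmax of c(eta, 0); returns vector of length J+1 summing to 1
static arma::vec softmax_full(const arma::vec& eta) {
  const int J = eta.n_elem;
  arma::vec v(J + 1);
  for (int a = 0; a < J; ++a) v[a] = eta[a];
  v[J] = 0.0;
  const double m = v.max();
  arma::vec w = arma::exp(v - m);
  return w / arma::accu(w);
}

// survival-style tail sums: G[j] = sum_{k >= j} theta_k (0-based), G[0] = 1
static arma::vec tail_sums(const arma::vec& theta, double eps) {
  const int Jp1 = theta.n_elem;
  arma::vec G(Jp1);
  double acc = 0.0;
  for (int j = Jp1 - 1; j >= 0; --j) {
    acc += theta[j];
    G[j] = acc;
  }
  G[0] = 1.0;  // guards accumulated rounding
  return arma::clamp(G, eps, 1.0);
}

// Subject likelihood from the raw observation matrix: every term is
// nonnegative, L_i = sum_j raw_ij * (G_j^h - G_{j+1}^h) with G_{J+2} := 0.
static double subject_lik_raw(const arma::mat& raw, int i,
                              const arma::vec& powg) {
  const int Jp1 = raw.n_cols;
  double L = 0.0;
  for (int j = 0; j < Jp1; ++j) {
    const double nxt = (j + 1 < Jp1) ? powg[j + 1] : 0.0;
    L += raw(i, j) * (powg[j] - nxt);
  }
  return L;
}

// [[Rcpp::export]]
List cpp_loglik(const arma::mat& raw, const arma::vec& h,
                const arma::vec& theta, double eps) {
  const int N = raw.n_rows, Jp1 = raw.n_cols;
  arma::vec G = tail_sums(theta, eps);
  arma::vec logG = arma::log(G);
  arma::vec li(N);
  std::vector<int> bad;
  double total = 0.0;
  arma::vec powg(Jp1);
  for (int i = 0; i < N; ++i) {
    for (int j = 0; j < Jp1; ++j) powg[j] = std::exp(h[i] * logG[j]);
    const double L = subject_lik_raw(raw, i, powg);
    if (L <= 0.0) {
      li[i] = NEG_INF;
      bad.push_back(i + 1);
      total = NEG_INF;
    } else {
      li[i] = std::log(L);
      if (std::isfinite(total)) total += li[i];
    }
  }
  return List::create(_["loglik"] = total, _["li"] = li,
                      _["bad_subjects"] = wrap(bad));
}

// Differenced dialect of the same log-likelihood: a second, independent
// algebraic route l = sum_i log( sum_j C_ij * G_j^{h_i} ), used to
// cross-check the raw form.
// [[Rcpp::export]]
double cpp_loglik_differenced(const arma::mat& Cm, const arma::vec& h,
                              const arma::vec& theta, double eps) {
  const int N = Cm.n_rows, Jp1 = Cm.n_cols;
  arma::vec G = tail_sums(theta, eps);
  arma::vec logG = arma::log(G);
  double total = 0.0;
  for (int i = 0; i < N; ++i) {
    double L = 0.0;
    for (int j = 0; j < Jp1; ++j) L += Cm(i, j) * std::exp(h[i] * logG[j]);
    if (L <= 0.0) return NEG_INF;
    total += std::log(L);
  }
  return total;
}

// ---------------------------------------------------------------------------
// profile optimizer on flat buffers

struct ProfileProblem {
  int N, Jp1, J;
  const double* raw;  // column-major N x (J+1)
  const double* Cm;
  std::vector<double> h;
  double eps;
  // workspaces (sized once)
  std::vector<double> theta, G, logG, powg, gth, U, vi, Hth, geta, Heta,
      Areg, d, chol, y, enew;

  ProfileProblem(const arma::mat& raw_, const arma::mat& Cm_, double eps_)
      : N(raw_.n_rows), Jp1(raw_.n_cols), J(Jp1 - 1),
        raw(raw_.memptr()), Cm(Cm_.memptr()), h(N), eps(eps_),
        theta(Jp1), G(Jp1), logG(Jp1), powg(Jp1), gth(Jp1), U(Jp1),
        vi(Jp1), Hth(Jp1 * Jp1), geta(J), Heta(J * J), Areg(J * J), d(J),
        chol(J * J), y(J), enew(J) {}

  void set_h(const double* lp) {  // h = exp(lp)
    for (int i = 0; i < N; ++i) h[i] = std::exp(lp[i]);
  }

  void softmax(const double* eta) {
    double m = 0.0;
    for (int a = 0; a < J; ++a) m = std::max(m, eta[a]);
    double s = std::exp(0.0 - m);
    theta[J] = s;
    for (int a = 0; a < J; ++a) {
      theta[a] = std::exp(eta[a] - m);
      s += theta[a];
    }
    for (int j = 0; j < Jp1; ++j) theta[j] /= s;
    double acc = 0.0;
    for (int j = Jp1 - 1; j >= 0; --j) {
      acc += theta[j];
      G[j] = std::min(std::max(acc, eps), 1.0);
    }
    G[0] = 1.0;
    for (int j = 0; j < Jp1; ++j) logG[j] = std::log(G[j]);
  }

  // log-likelihood value at eta (raw dialect, nonnegative terms)
  double value(const double* eta) {
    softmax(eta);
    double total = 0.0;
    for (int i = 0; i < N; ++i) {
      const double hi = h[i];
      for (int j = 0; j < Jp1; ++j) powg[j] = std::exp(hi * logG[j]);
      double L = 0.0;
      for (int j = 0; j < Jp1; ++j) {
        const double nxt = (j + 1 < Jp1) ? powg[j + 1] : 0.0;
        L += raw[i + (size_t)j * N] * (powg[j] - nxt);
      }
      if (L <= 0.0) return NEG_INF;
      total += std::log(L);
    }
    return total;
  }

  // value, gradient and Hessian in eta space; false when infeasible
  bool derivs(const double* eta, double& value_out) {
    softmax(eta);
    std::fill(gth.begin(), gth.end(), 0.0);
    std::fill(U.begin(), U.end(), 0.0);
    std::fill(Hth.begin(), Hth.end(), 0.0);
    double total = 0.0;
    for (int i = 0; i < N; ++i) {
      const double hi = h[i];
      for (int j = 0; j < Jp1; ++j) powg[j] = std::exp(hi * logG[j]);
      double L = 0.0;
      for (int j = 0; j < Jp1; ++j) {
        const double nxt = (j + 1 < Jp1) ? powg[j + 1] : 0.0;
        L += raw[i + (size_t)j * N] * (powg[j] - nxt);
      }
      if (L <= 0.0) return false;
      total += std::log(L);
      double Acum = 0.0, Bcum = 0.0;
      for (int m = 0; m < Jp1; ++m) {
        const double c = Cm[i + (size_t)m * N];
        const double pm1 = powg[m] / G[m];
        Acum += c * pm1;
        Bcum += c * pm1 / G[m];
        vi[m] = hi * Acum / L;
        gth[m] += vi[m];
        U[m] += hi * (hi - 1.0) * Bcum / L;
      }
      // rank-1 downdate Hth -= vi vi' (upper triangle, symmetrized later)
      for (int m = 0; m < Jp1; ++m)
        for (int n = m; n < Jp1; ++n)
          Hth[m + n * Jp1] -= vi[m] * vi[n];
    }
    for (int m = 0; m < Jp1; ++m)
      for (int n = m; n < Jp1; ++n) {
        Hth[m + n * Jp1] += U[m];  // U[min(m,n)]
        Hth[n + m * Jp1] = Hth[m + n * Jp1];
      }
    // chain rule to eta space
    double s = 0.0;
    for (int m = 0; m < Jp1; ++m) s += gth[m] * theta[m];
    for (int a = 0; a < J; ++a) geta[a] = theta[a] * (gth[a] - s);
    // Heta = Jm' Hth Jm + second-derivative term, Jm(m,a) = th_m (d_ma - th_a)
    for (int a = 0; a < J; ++a) {
      // w = Hth * Jm(., a): Jm col a = theta .* (e_a - theta[a])
      for (int m = 0; m < Jp1; ++m) {
        double w = 0.0;
        for (int n = 0; n < Jp1; ++n) {
          const double jna =
              theta[n] * ((n == a ? 1.0 : 0.0) - theta[a]);
          w += Hth[m + n * Jp1] * jna;
        }
        vi[m] = w;  // reuse vi as scratch
      }
      for (int bidx = 0; bidx <= a; ++bidx) {
        double hval = 0.0;
        for (int m = 0; m < Jp1; ++m) {
          const double jmb =
              theta[m] * ((m == bidx ? 1.0 : 0.0) - theta[bidx]);
          hval += jmb * vi[m];
        }
        double t2 = -gth[a] * theta[a] * theta[bidx] -
                    gth[bidx] * theta[bidx] * theta[a] +
                    2.0 * theta[a] * theta[bidx] * s;
        if (a == bidx) t2 += gth[a] * theta[a] - theta[a] * s;
        hval += t2;
        Heta[a + bidx * J] = hval;
        Heta[bidx + a * J] = hval;
      }
    }
    value_out = total;
    return true;
  }

  // Cholesky solve of A x = b for the J x J matrix in Areg; false if not PD
  bool chol_solve() {
    for (int k = 0; k < J * J; ++k) chol[k] = Areg[k];
    for (int c = 0; c < J; ++c) {
      double diag = chol[c + c * J];
      for (int k = 0; k < c; ++k) diag -= chol[c + k * J] * chol[c + k * J];
      if (diag <= 0.0) return false;
      diag = std::sqrt(diag);
      chol[c + c * J] = diag;
      for (int r = c + 1; r < J; ++r) {
        double v = chol[r + c * J];
        for (int k = 0; k < c; ++k) v -= chol[r + k * J] * chol[c + k * J];
        chol[r + c * J] = v / diag;
      }
    }
    for (int r = 0; r < J; ++r) {  // forward solve L y = g
      double v = geta[r];
      for (int k = 0; k < r; ++k) v -= chol[r + k * J] * y[k];
      y[r] = v / chol[r + r * J];
    }
    for (int r = J - 1; r >= 0; --r) {  // back solve L' d = y
      double v = y[r];
      for (int k = r + 1; k < J; ++k) v -= chol[k + r * J] * d[k];
      d[r] = v / chol[r + r * J];
    }
    return true;
  }
};

// Damped Newton ascent on the profiled log-likelihood in eta space;
// converges when the improvement drops below tol (at most maxit steps).
static bool newton_profile(ProfileProblem& pb, double* eta, double tol,
                           int maxit, double& f, int& iters) {
  const int J = pb.J;
  for (int a = 0; a < J; ++a)
    eta[a] = std::min(std::max(eta[a], -45.0), 45.0);
  if (!pb.derivs(eta, f)) {
    f = NEG_INF;
    iters = 0;
    return false;
  }
  bool converged = false;
  int it;
  for (it = 1; it <= maxit; ++it) {
    // solve (-H + lambda I) d = g, ramping lambda until positive definite
    double lambda = 0.0;
    bool solved = false;
    for (int k = 0; k < 40 && !solved; ++k) {
      for (int c = 0; c < J; ++c)
        for (int r = 0; r < J; ++r)
          pb.Areg[r + c * J] =
              -pb.Heta[r + c * J] + (r == c ? lambda : 0.0);
      solved = pb.chol_solve();
      if (solved) {
        double dg = 0.0;
        for (int a = 0; a < J; ++a) dg += pb.d[a] * pb.geta[a];
        if (dg <= 0.0) solved = false;
      }
      if (!solved) lambda = (lambda == 0.0) ? 1e-8 : lambda * 10.0;
    }
    if (!solved)
      for (int a = 0; a < J; ++a) pb.d[a] = pb.geta[a];  // steepest ascent
    double fnew = NEG_INF, step = 1.0;
    bool improved = false;
    for (int attempt = 0; attempt < 2 && !improved; ++attempt) {
      if (attempt == 1) {
        // the (quasi-)Newton direction found no ascent: retry along the
        // gradient before giving up
        for (int a = 0; a < J; ++a) pb.d[a] = pb.geta[a];
      }
      // trust-region style cap on the step length
      double dn = 0.0;
      for (int a = 0; a < J; ++a) dn += pb.d[a] * pb.d[a];
      dn = std::sqrt(dn);
      if (dn <= 0.0) break;
      if (dn > 30.0)
        for (int a = 0; a < J; ++a) pb.d[a] *= 30.0 / dn;
      double t = 1.0;
      for (int ls = 0; ls < 40; ++ls) {
        for (int a = 0; a < J; ++a)
          pb.enew[a] =
              std::min(std::max(eta[a] + t * pb.d[a], -45.0), 45.0);
        fnew = pb.value(pb.enew.data());
        if (std::isfinite(fnew) && fnew > f) {
          improved = true;
          step = t;
          break;
        }
        t *= 0.5;
        if (t * std::min(dn, 30.0) < 1e-13) break;  // step numerically nil
      }
      if (!solved) break;  // already searched along the gradient
    }
    if (!improved) { converged = true; break; }  // no ascent left
    const double gain = fnew - f;
    double ginf = 0.0;
    for (int a = 0; a < J; ++a) ginf = std::max(ginf, std::fabs(pb.geta[a]));
    for (int a = 0; a < J; ++a) eta[a] = pb.enew[a];
    f = fnew;
    // declare convergence on a sub-tol improvement only when the step was
    // untruncated or the gradient has vanished; a damped step with small
    // gain can sit far from the optimum
    if (gain < tol && (step == 1.0 || ginf < 1e-7 || gain < 1e-13)) {
      converged = true;
      break;
    }
    if (!pb.derivs(eta, f)) break;
  }
  iters = std::min(it, maxit);
  return converged;
}

// canonical theta for reporting: softmax(eta), floored at eps and
// renormalized; must stay in exact sync with cpp_eta_to_theta below
static arma::vec canonical_theta(const double* eta, int J, double eps) {
  arma::vec v(J + 1);
  for (int a = 0; a < J; ++a) v[a] = eta[a];
  v[J] = 0.0;
  const double m = v.max();
  arma::vec th = arma::exp(v - m);
  th /= arma::accu(th);
  for (int j = 0; j <= J; ++j) th[j] = std::max(th[j], eps);
  th /= arma::accu(th);
  // renormalization can push a floored entry a hair below eps; restore the
  // floor (the sum moves by O(J * eps^2), far inside the 1e-10 budget)
  for (int j = 0; j <= J; ++j) th[j] = std::max(th[j], eps);
  return th;
}

// log-likelihood at the canonical (floored) theta, computed with exactly
// the same arithmetic as cpp_loglik so cached values match recomputed ones
static double canonical_value(ProfileProblem& pb, const double* eta) {
  arma::vec th = canonical_theta(eta, pb.J, pb.eps);
  arma::vec G = tail_sums(th, pb.eps);
  arma::vec logG = arma::log(G);
  const int N = pb.N, Jp1 = pb.Jp1;
  double total = 0.0;
  for (int i = 0; i < N; ++i) {
    for (int j = 0; j < Jp1; ++j)
      pb.powg[j] = std::exp(pb.h[i] * logG[j]);
    double L = 0.0;
    for (int j = 0; j < Jp1; ++j) {
      const double nxt = (j + 1 < Jp1) ? pb.powg[j + 1] : 0.0;
      L += pb.raw[i + (size_t)j * N] * (pb.powg[j] - nxt);
    }
    if (L <= 0.0) return NEG_INF;
    total += std::log(L);
  }
  return total;
}

// [[Rcpp::export]]
arma::vec cpp_eta_to_theta(const arma::vec& eta, double eps) {
  return canonical_theta(eta.memptr(), eta.n_elem, eps);
}

// Boundary polish: when the profile optimum lies on the floor of the
// simplex, the logit-scale Newton ascent approaches it asymptotically;
// snapping near-floor coordinates to the clamp bound (and, for the
// reference coordinate, shifting the whole eta vector up) closes the
// remaining gap.  Only coordinates already close to the floor are tried,
// so the polish is free on non-degenerate problems.
static void polish_floor(ProfileProblem& pb, double* eta, double& f) {
  const int J = pb.J;
  pb.softmax(eta);  // fills pb.theta
  bool any_small = false;
  for (int j = 0; j <= J; ++j)
    if (pb.theta[j] < 1e-6) any_small = true;
  if (!any_small) return;
  bool improved = true;
  while (improved) {
    improved = false;
    for (int a = 0; a < J; ++a) {
      if (eta[a] <= -45.0) continue;
      pb.softmax(eta);
      if (pb.theta[a] >= 1e-6) continue;
      const double old = eta[a];
      eta[a] = -45.0;
      const double v = pb.value(eta);
      if (std::isfinite(v) && v > f) {
        f = v;
        improved = true;
      } else {
        eta[a] = old;
      }
    }
    // push the reference coordinate to the floor via a global shift
    pb.softmax(eta);
    if (pb.theta[J] < 1e-6) {
      double m = eta[0];
      for (int a = 1; a < J; ++a) m = std::max(m, eta[a]);
      if (m < 45.0) {
        std::vector<double> save(eta, eta + J);
        for (int a = 0; a < J; ++a)
          eta[a] = std::min(eta[a] + (45.0 - m), 45.0);
        const double v = pb.value(eta);
        if (std::isfinite(v) && v > f) {
          f = v;
          improved = true;
        } else {
          for (int a = 0; a < J; ++a) eta[a] = save[a];
        }
      }
    }
  }
}

// profile with warm start plus one restart from the uniform point; the
// reported value is evaluated at the canonical floored theta so that the
// cached log-likelihood equals a fresh evaluation at the returned theta
static bool run_profile(ProfileProblem& pb, double* eta, double tol,
                        int maxit, double& f, int& iters) {
  bool nonzero = false;
  for (int a = 0; a < pb.J; ++a)
    if (eta[a] != 0.0) nonzero = true;
  bool conv = newton_profile(pb, eta, tol, maxit, f, iters);
  if (!conv && nonzero) {
    for (int a = 0; a < pb.J; ++a) eta[a] = 0.0;
    int it2 = 0;
    conv = newton_profile(pb, eta, tol, maxit, f, it2);
    iters += it2;
  }
  if (conv && std::isfinite(f)) {
    polish_floor(pb, eta, f);
    f = canonical_value(pb, eta);
  }
  return conv;
}

// [[Rcpp::export]]
List cpp_profile_core(const arma::mat& raw, const arma::mat& Cm,
                      const arma::vec& h, arma::vec eta, double eps,
                      double tol, int maxit) {
  ProfileProblem pb(raw, Cm, eps);
  for (int i = 0; i < pb.N; ++i) pb.h[i] = h[i];
  double f;
  int iters;
  const bool converged =
      newton_profile(pb, eta.memptr(), tol, maxit, f, iters);
  if (converged && std::isfinite(f)) {
    polish_floor(pb, eta.memptr(), f);
    f = canonical_value(pb, eta.memptr());
  }
  return List::create(_["eta"] = eta, _["loglik"] = f,
                      _["converged"] = converged, _["iters"] = iters);
}

// Full Metropolis-Hastings-within-Gibbs iteration loop.  Uses R's RNG in a
// fixed draw order (flip: index uniform, optional slab normal, acceptance
// uniform; refine per included covariate in index order: gate uniform,
// proposal normal, acceptance uniform; then the conjugate Beta draw for
// omega), so a chain is reproducible from set.seed() and matches the
// R-level moves draw for draw.
// [[Rcpp::export]]
List cpp_run_chain(const arma::mat& raw, const arma::mat& Cm,
                   const arma::mat& Z, double b, double w1, double w2,
                   double p_main, int n_iter, int burn_in, double omega0,
                   arma::vec eta0, double loglik0, double eps, bool trace) {
  const int N = Z.n_rows, P = Z.n_cols, J = raw.n_cols - 1;
  ProfileProblem pb(raw, Cm, eps);
  arma::ivec gamma(P, arma::fill::zeros);
  arma::vec beta(P, arma::fill::zeros);
  std::vector<double> lp(N, 0.0), lp_new(N), eta(J), eta_prop(J);
  for (int a = 0; a < J; ++a) eta[a] = eta0[a];
  double loglik = loglik0, omega = omega0;
  int K = 0;
  arma::ivec counts(P, arma::fill::zeros);
  int kept = 0, flip_acc = 0, ref_acc = 0, ref_tot = 0, fail = 0;
  arma::ivec trK;
  arma::vec trL, trO;
  if (trace) {
    trK.set_size(n_iter);
    trL.set_size(n_iter);
    trO.set_size(n_iter);
  }
  const double tol = 1e-8;
  double ll_prop;
  int iters;
  for (int it = 0; it < n_iter; ++it) {
    // flip move
    const int p = std::min((int)(unif_rand() * P), P - 1);
    const int gnew = 1 - gamma[p];
    const double bnew = (gnew == 1) ? b * norm_rand() : 0.0;
    const double* zp = Z.colptr(p);
    const double db = bnew - beta[p];
    for (int i = 0; i < N; ++i) lp_new[i] = lp[i] + zp[i] * db;
    pb.set_h(lp_new.data());
    for (int a = 0; a < J; ++a) eta_prop[a] = eta[a];
    bool conv = run_profile(pb, eta_prop.data(), tol, 200, ll_prop, iters);
    if (!conv || !std::isfinite(ll_prop)) {
      unif_rand();
      ++fail;
    } else {
      const double delta = ll_prop - loglik +
          (2.0 * gnew - 1.0) * std::log(omega / (1.0 - omega));
      if (std::log(unif_rand()) < delta) {
        gamma[p] = gnew;
        beta[p] = bnew;
        lp.swap(lp_new);
        eta.swap(eta_prop);
        loglik = ll_prop;
        K += (gnew == 1) ? 1 : -1;
        ++flip_acc;
      }
    }
    // refine moves over included covariates, index order
    for (int q = 0; q < P; ++q) {
      if (gamma[q] != 1) continue;
      if (unif_rand() >= p_main) continue;
      ++ref_tot;
      const double bq = beta[q] + b * norm_rand();
      const double* zq = Z.colptr(q);
      const double dq = bq - beta[q];
      for (int i = 0; i < N; ++i) lp_new[i] = lp[i] + zq[i] * dq;
      pb.set_h(lp_new.data());
      for (int a = 0; a < J; ++a) eta_prop[a] = eta[a];
      conv = run_profile(pb, eta_prop.data(), tol, 200, ll_prop, iters);
      if (!conv || !std::isfinite(ll_prop)) {
        unif_rand();
        ++fail;
        continue;
      }
      const double delta = ll_prop - loglik +
          (beta[q] * beta[q] - bq * bq) / (2.0 * b * b);
      if (std::log(unif_rand()) < delta) {
        beta[q] = bq;
        lp.swap(lp_new);
        eta.swap(eta_prop);
        loglik = ll_prop;
        ++ref_acc;
      }
    }
    omega = R::rbeta(w1 + K, w2 + P - K);
    if (it + 1 > burn_in) {
      counts += gamma;
      ++kept;
    }
    if (trace) {
      trK[it] = K;
      trL[it] = loglik;
      trO[it] = omega;
    }
  }
  arma::vec eta_out(J);
  for (int a = 0; a < J; ++a) eta_out[a] = eta[a];
  List out = List::create(
      _["counts"] = counts, _["kept"] = kept, _["flip_acc"] = flip_acc,
      _["ref_acc"] = ref_acc, _["ref_tot"] = ref_tot, _["fail"] = fail,
      _["eta"] = eta_out, _["loglik"] = loglik);
  if (trace) {
    out["trace_K"] = trK;
    out["trace_loglik"] = trL;
    out["trace_omega"] = trO;
  }
  return out;
}

// log-likelihood with analytic gradient in (beta, eta), for joint ML fitting
// [[Rcpp::export]]
List cpp_ml_loglik_grad(const arma::mat& raw, const arma::mat& Cm,
                        const arma::mat& Z, const arma::vec& beta,
                        const arma::vec& eta, double eps) {
  const int N = raw.n_rows, Jp1 = raw.n_cols, J = Jp1 - 1,
            P = Z.n_cols;
  arma::vec theta = softmax_full(eta);
  arma::vec G = tail_sums(theta, eps);
  arma::vec logG = arma::log(G);
  arma::vec lp = Z * beta;
  arma::vec gth(Jp1, arma::fill::zeros);
  arma::vec q(N);  // per-subject weight for the beta gradient
  arma::vec powg(Jp1);
  double value = 0.0;
  for (int i = 0; i < N; ++i) {
    const double hi = std::exp(lp[i]);
    for (int j = 0; j < Jp1; ++j) powg[j] = std::exp(hi * logG[j]);
    const double L = subject_lik_raw(raw, i, powg);
    if (L <= 0.0) {
      return List::create(_["loglik"] = NEG_INF,
                          _["grad_beta"] = arma::vec(P, arma::fill::zeros),
                          _["grad_eta"] = arma::vec(J, arma::fill::zeros));
    }
    value += std::log(L);
    double dldh = 0.0, Acum = 0.0;
    for (int m = 0; m < Jp1; ++m) {
      dldh += Cm(i, m) * powg[m] * logG[m];
      Acum += Cm(i, m) * powg[m] / G[m];
      gth[m] += hi * Acum / L;
    }
    q[i] = hi * dldh / L;
  }
  arma::vec gbeta = Z.t() * q;
  const double s = arma::dot(gth, theta);
  arma::vec geta(J);
  for (int a = 0; a < J; ++a) geta[a] = theta[a] * (gth[a] - s);
  return List::create(_["loglik"] = value, _["grad_beta"] = gbeta,
                      _["grad_eta"] = geta);
}
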