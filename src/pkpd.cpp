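// Exact simulation of the linear three-compartment + effect-site system for
// piecewise-constant infusion input, and the FOCE-I inner (eta) problem for a
// single pharmacokinetic subject. Kept in C++ because the inner problem is
// re-solved thousands of times inside the outer likelihood optimisation.
#define ARMA_WARN_LEVEL 1
#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;

static const double MGL_TO_NGML = 1000.0; // mg/L -> ng/mL

// State order (A1, A2, A3, Ce): amounts mg in central/shallow/deep
// compartments, effect-site concentration in ng/mL.
// p = (V1, V2, V3, CL, Q2, Q3, ke0)
static mat system_matrix_c(const vec& p) {
  const double V1 = p(0), V2 = p(1), V3 = p(2);
  const double CL = p(3), Q2 = p(4), Q3 = p(5), ke0 = p(6);
  mat A(4, 4, fill::zeros);
  A(0, 0) = -(CL + Q2 + Q3) / V1;
  A(0, 1) = Q2 / V2;
  A(0, 2) = Q3 / V3;
  A(1, 0) = Q2 / V1;
  A(1, 1) = -Q2 / V2;
  A(2, 0) = Q3 / V1;
  A(2, 2) = -Q3 / V3;
  A(3, 0) = ke0 * MGL_TO_NGML / V1;
  A(3, 3) = -ke0;
  return A;
}

// Piecewise-constant input: on each segment x' = A x + b with b = (rate,0,0,0),
// so x(t0+dt) = e^{A dt} (x0 + A^{-1} b) - A^{-1} b. Propagation uses the
// eigendecomposition of A (block-triangular, eigenvalues real and negative for
// admissible parameters); if the eigenvector matrix is ill-conditioned
// (repeated-eigenvalue degeneracy) it falls back to a matrix exponential.
// events: m x 3 (start, rate mg/min, duration); times sorted, >= 0.
// [[Rcpp::export(name = ".sim_amounts_cpp")]]
arma::mat sim_amounts_cpp(const arma::vec& pars, const arma::mat& events,
                          const arma::vec& times) {
  const uword nt = times.n_elem;
  mat out(nt, 4, fill::zeros);
  mat A = system_matrix_c(pars);

  // segment breakpoints: 0 plus all event starts and ends
  std::vector<double> bps;
  bps.push_back(0.0);
  for (uword i = 0; i < events.n_rows; ++i) {
    bps.push_back(events(i, 0));
    bps.push_back(events(i, 0) + events(i, 2));
  }
  std::sort(bps.begin(), bps.end());
  bps.erase(std::unique(bps.begin(), bps.end(),
                        [](double a, double b) { return std::abs(a - b) < 1e-12; }),
            bps.end());

  cx_vec eval;
  cx_mat evec, evinv;
  bool eig_ok = eig_gen(eval, evec, A);
  if (eig_ok) {
    double rc = rcond(evec);
    eig_ok = std::isfinite(rc) && rc > 1e-10 && inv(evinv, evec);
  }
  vec e1 = {1.0, 0.0, 0.0, 0.0};
  vec ainv_e1 = solve(A, e1); // A^{-1} b for unit rate

  vec x(4, fill::zeros);
  uword ti = 0;
  // skip any output time earlier than the first breakpoint (t < 0 guarded in R)
  while (ti < nt && times(ti) < -1e-12) ++ti;

  for (size_t s = 0; s < bps.size(); ++s) {
    const double t0 = bps[s];
    const double t1 = (s + 1 < bps.size()) ? bps[s + 1] : datum::inf;
    double rate = 0.0;
    for (uword i = 0; i < events.n_rows; ++i) {
      if (events(i, 0) <= t0 + 1e-12 &&
          events(i, 0) + events(i, 2) > t0 + 1e-12)
        rate += events(i, 1);
    }
    const vec c = rate * ainv_e1;
    const vec v = x + c;
    cx_vec w;
    if (eig_ok) w = evinv * cx_vec(v, vec(4, fill::zeros));

    while (ti < nt && times(ti) < t1 - 1e-12) {
      double dt = times(ti) - t0;
      if (dt < 0.0) dt = 0.0;
      vec xt;
      if (eig_ok)
        xt = real(evec * (exp(eval * dt) % w)) - c;
      else
        xt = expmat(A * dt) * v - c;
      out.row(ti) = xt.t();
      ++ti;
    }
    if (s + 1 < bps.size()) {
      const double dt = t1 - t0;
      if (eig_ok)
        x = real(evec * (exp(eval * dt) % w)) - c;
      else
        x = expmat(A * dt) * v - c;
    }
    if (ti >= nt) break;
  }
  // exact solution can carry tiny negative round-off
  out.transform([](double z) { return (z < 0.0 && z > -1e-6) ? 0.0 : z; });
  return out;
}

// Fast path for the disposition block alone (central amount A1; the
// effect-site state is not needed during PK estimation). The mammillary
// 3x3 matrix is similar to a symmetric matrix under the volume scaling
// S = diag(V^-1/2), so a symmetric eigendecomposition (real, orthonormal,
// robust to repeated eigenvalues) gives the exact propagator.
// p6 = (V1, V2, V3, CL, Q2, Q3); returns A1 (mg) at each time.
// [[Rcpp::export(name = ".sim_a1_cpp")]]
arma::vec sim_a1_cpp(const arma::vec& p6, const arma::mat& events,
                     const arma::vec& times) {
  const double V1 = p6(0), V2 = p6(1), V3 = p6(2);
  const double CL = p6(3), Q2 = p6(4), Q3 = p6(5);
  const uword nt = times.n_elem;
  vec out(nt, fill::zeros);

  const vec s = {1.0 / std::sqrt(V1), 1.0 / std::sqrt(V2),
                 1.0 / std::sqrt(V3)};
  mat B(3, 3, fill::zeros); // B = S A S^{-1}, symmetric
  B(0, 0) = -(CL + Q2 + Q3) / V1;
  B(1, 1) = -Q2 / V2;
  B(2, 2) = -Q3 / V3;
  B(0, 1) = B(1, 0) = Q2 / std::sqrt(V1 * V2);
  B(0, 2) = B(2, 0) = Q3 / std::sqrt(V1 * V3);
  vec lam;
  mat U;
  eig_sym(lam, U, B);

  std::vector<double> bps;
  bps.push_back(0.0);
  for (uword i = 0; i < events.n_rows; ++i) {
    bps.push_back(events(i, 0));
    bps.push_back(events(i, 0) + events(i, 2));
  }
  std::sort(bps.begin(), bps.end());
  bps.erase(std::unique(bps.begin(), bps.end(),
                        [](double a, double b) { return std::abs(a - b) < 1e-12; }),
            bps.end());

  // A^{-1} b for unit rate: A^{-1} = S^{-1} U diag(1/lam) U' S; b = e1
  const vec u1 = U.row(0).t() * s(0);     // U' S e1
  const vec ainv_e1 = (U * (u1 / lam)) / s; // componentwise divide by s
  // first row of S^{-1} U, for reading off A1
  const rowvec r1 = U.row(0) / s(0);

  vec x(3, fill::zeros);
  uword ti = 0;
  while (ti < nt && times(ti) < -1e-12) ++ti;
  for (size_t seg = 0; seg < bps.size(); ++seg) {
    const double t0 = bps[seg];
    const double t1 = (seg + 1 < bps.size()) ? bps[seg + 1] : datum::inf;
    double rate = 0.0;
    for (uword i = 0; i < events.n_rows; ++i)
      if (events(i, 0) <= t0 + 1e-12 &&
          events(i, 0) + events(i, 2) > t0 + 1e-12)
        rate += events(i, 1);
    const vec c = rate * ainv_e1;
    const vec w = U.t() * ((x + c) % s); // U' S (x0 + c)
    while (ti < nt && times(ti) < t1 - 1e-12) {
      const double dt = std::max(times(ti) - t0, 0.0);
      out(ti) = dot(r1, exp(lam * dt) % w) - c(0);
      ++ti;
    }
    if (seg + 1 < bps.size())
      x = (U * (exp(lam * (t1 - t0)) % w)) / s - c;
    if (ti >= nt) break;
  }
  out.transform([](double z) { return (z < 0.0 && z > -1e-6) ? 0.0 : z; });
  return out;
}

struct FoceiResult {
  vec eta, pred, gvec;
  mat jac;
  double ofv, cond2ll;
  bool converged;
  int iter;
};

// FOCE-I inner problem for one PK subject under proportional residual error.
// Minimises over eta the conditional -2 log joint density
//   2h(eta) = sum_j [ log(2 pi g_j) + (y_j - f_j)^2 / g_j ]
//           + eta' Omega^{-1} eta + log |2 pi Omega|
// with f_j the model concentration and g_j = sigma2 * f_j^2 evaluated at eta
// (the "interaction"), then returns the subject's Laplace-type contribution
//   ofv_i = 2h(eta_hat) - d log(2 pi) + log |H2/2|
// where H2 is the Fisher-type approximation to the Hessian of 2h.
//
// theta_sub: subject-typical (V1,V2,V3,CL,Q2,Q3) with covariate factors applied
// eta_idx:   0-based indices of the parameters carrying eta
static FoceiResult focei_pk_subject_core(const vec& theta_sub,
                                         const uvec& eta_idx,
                                         const mat& events,
                                         const vec& obs_times,
                                         const vec& dv,
                                         const mat& Oinv, double ldO,
                                         double sigma2,
                                         const vec& eta0,
                                         int maxit, double tol) {
  const int d = eta_idx.n_elem;
  const uword n = dv.n_elem;
  const double log2pi = std::log(2.0 * datum::pi);

  auto predict = [&](const vec& eta) -> vec {
    vec p = theta_sub;
    for (int k = 0; k < d; ++k) p(eta_idx(k)) *= std::exp(eta(k));
    return MGL_TO_NGML * sim_a1_cpp(p, events, obs_times) / p(0);
  };
  auto objfun = [&](const vec& eta, const vec& f) -> double {
    vec g = clamp(sigma2 * square(f), 1e-12, datum::inf);
    vec r = dv - f;
    return accu(log(2.0 * datum::pi * g) + square(r) / g) +
           as_scalar(eta.t() * Oinv * eta) + d * log2pi + ldO;
  };
  auto jacobian = [&](const vec& eta, const vec& f, mat& F) {
    const double h = 1e-5;
    for (int k = 0; k < d; ++k) {
      vec e = eta;
      e(k) += h;
      F.col(k) = (predict(e) - f) / h;
    }
  };

  vec eta = eta0;
  vec f = predict(eta);
  double val = objfun(eta, f);
  mat F(n, d);
  bool conv = false;
  int it = 0;
  for (it = 0; it < maxit; ++it) {
    jacobian(eta, f, F);
    vec g = clamp(sigma2 * square(f), 1e-12, datum::inf);
    vec r = dv - f;
    mat Gd = 2.0 * sigma2 * (F.each_col() % f); // dg/deta, n x d
    vec w1 = (1.0 - square(r) / g) / g;
    vec grad = Gd.t() * w1 - 2.0 * (F.t() * (r / g)) + 2.0 * Oinv * eta;
    mat H2 = 2.0 * (F.t() * (F.each_col() / g)) +
             Gd.t() * (Gd.each_col() / square(g)) + 2.0 * Oinv;
    vec delta;
    if (!solve(delta, H2, grad, solve_opts::no_approx)) {
      delta = pinv(H2) * grad; // ill-conditioned curvature: least-norm step
      if (!delta.is_finite()) break;
    }
    double alpha = 1.0;
    bool ok = false;
    vec enew, fnew;
    double vnew = 0.0;
    for (int ls = 0; ls < 30; ++ls) {
      enew = eta - alpha * delta;
      fnew = predict(enew);
      vnew = objfun(enew, fnew);
      if (std::isfinite(vnew) && vnew <= val + 1e-12) {
        ok = true;
        break;
      }
      alpha *= 0.5;
    }
    if (!ok) { // no descent direction left: accept current point
      conv = true;
      break;
    }
    const double step = alpha * norm(delta, "inf");
    const double dec = val - vnew;
    eta = enew;
    f = fnew;
    val = vnew;
    if (step < tol || dec < 1e-12) {
      conv = true;
      break;
    }
  }

  jacobian(eta, f, F);
  vec g = clamp(sigma2 * square(f), 1e-12, datum::inf);
  mat Gd = 2.0 * sigma2 * (F.each_col() % f);
  mat H2 = 2.0 * (F.t() * (F.each_col() / g)) +
           Gd.t() * (Gd.each_col() / square(g)) + 2.0 * Oinv;
  double ldH, sgn;
  log_det(ldH, sgn, H2);

  FoceiResult res;
  res.eta = eta;
  res.pred = f;
  res.gvec = g;
  res.jac = F;
  res.cond2ll = val;
  res.ofv = val - d * log2pi + ldH - d * std::log(2.0);
  res.converged = conv;
  res.iter = it;
  return res;
}

// [[Rcpp::export(name = ".focei_pk_subject_cpp")]]
Rcpp::List focei_pk_subject_cpp(const arma::vec& theta_sub,
                                const arma::uvec& eta_idx,
                                const arma::mat& events,
                                const arma::vec& obs_times,
                                const arma::vec& dv,
                                const arma::mat& omega,
                                double sigma2,
                                const arma::vec& eta0,
                                int maxit, double tol) {
  mat Oinv;
  if (!inv_sympd(Oinv, omega))
    Rcpp::stop("omega matrix is not positive definite");
  double ldO, sgn;
  log_det(ldO, sgn, omega);
  FoceiResult r = focei_pk_subject_core(theta_sub, eta_idx, events, obs_times,
                                        dv, Oinv, ldO, sigma2, eta0, maxit,
                                        tol);
  return Rcpp::List::create(
      Rcpp::_["eta"] = r.eta, Rcpp::_["ofv"] = r.ofv,
      Rcpp::_["cond2ll"] = r.cond2ll, Rcpp::_["pred"] = r.pred,
      Rcpp::_["jac"] = r.jac, Rcpp::_["gvec"] = r.gvec,
      Rcpp::_["converged"] = r.converged, Rcpp::_["iter"] = r.iter);
}

// FOCE-I inner problem for one PD (BIS) subject: additive residual error,
// inhibitory sigmoid Emax prediction with analytic eta-Jacobian. The two
// random effects scale EC50 and gamma log-normally.
static FoceiResult focei_pd_subject_core(const vec& ce, const vec& dv,
                                         double E0, double Emax, double EC50,
                                         double gamma, const mat& Oinv,
                                         double ldO, double sigma2,
                                         const vec& eta0, int maxit,
                                         double tol) {
  const uword n = dv.n_elem;
  const int d = 2;
  const double log2pi = std::log(2.0 * datum::pi);

  auto predict = [&](const vec& eta, vec& f, mat& F) {
    const double ec = EC50 * std::exp(eta(0));
    const double ga = gamma * std::exp(eta(1));
    f.set_size(n);
    F.set_size(n, 2);
    for (uword j = 0; j < n; ++j) {
      if (ce(j) > 0.0) {
        const double lr = std::log(ce(j) / ec);
        const double u = std::exp(ga * lr);
        const double dEdu = -Emax / ((1.0 + u) * (1.0 + u));
        f(j) = E0 - Emax * u / (1.0 + u);
        F(j, 0) = dEdu * (-ga * u);
        F(j, 1) = dEdu * (ga * lr * u);
      } else {
        f(j) = E0;
        F(j, 0) = F(j, 1) = 0.0;
      }
    }
  };
  auto objfun = [&](const vec& eta, const vec& f) -> double {
    const vec r = dv - f;
    return n * std::log(2.0 * datum::pi * sigma2) + dot(r, r) / sigma2 +
           as_scalar(eta.t() * Oinv * eta) + d * log2pi + ldO;
  };

  vec eta = eta0, f;
  mat F;
  predict(eta, f, F);
  double val = objfun(eta, f);
  bool conv = false;
  int it = 0;
  for (it = 0; it < maxit; ++it) {
    vec r = dv - f;
    vec grad = -2.0 * (F.t() * r) / sigma2 + 2.0 * Oinv * eta;
    mat H2 = 2.0 * (F.t() * F) / sigma2 + 2.0 * Oinv;
    vec delta;
    if (!solve(delta, H2, grad, solve_opts::no_approx)) {
      delta = pinv(H2) * grad;
      if (!delta.is_finite()) break;
    }
    double alpha = 1.0;
    bool ok = false;
    vec enew, fnew;
    mat Fnew;
    double vnew = 0.0;
    for (int ls = 0; ls < 30; ++ls) {
      enew = eta - alpha * delta;
      predict(enew, fnew, Fnew);
      vnew = objfun(enew, fnew);
      if (std::isfinite(vnew) && vnew <= val + 1e-12) {
        ok = true;
        break;
      }
      alpha *= 0.5;
    }
    if (!ok) {
      conv = true;
      break;
    }
    const double step = alpha * norm(delta, "inf");
    const double dec = val - vnew;
    eta = enew;
    f = fnew;
    F = Fnew;
    val = vnew;
    if (step < tol || dec < 1e-12) {
      conv = true;
      break;
    }
  }
  mat H2 = 2.0 * (F.t() * F) / sigma2 + 2.0 * Oinv;
  double ldH, sgn;
  log_det(ldH, sgn, H2);

  FoceiResult res;
  res.eta = eta;
  res.pred = f;
  res.gvec = vec(n, fill::value(sigma2));
  res.jac = F;
  res.cond2ll = val;
  res.ofv = val - d * log2pi + ldH - d * std::log(2.0);
  res.converged = conv;
  res.iter = it;
  return res;
}

// Whole-dataset PD objective; ce_list holds each subject's effect-site
// concentrations at the BIS sampling times (already reflecting the current
// ke0).
// [[Rcpp::export(name = ".focei_pd_all_cpp")]]
Rcpp::List focei_pd_all_cpp(const Rcpp::List& ce_list,
                            const Rcpp::List& dv_list,
                            double E0, double Emax, double EC50, double gamma,
                            const arma::mat& omega, double sigma2,
                            const arma::mat& eta_warm,
                            int maxit, double tol) {
  const int nsub = ce_list.size();
  mat Oinv;
  if (!inv_sympd(Oinv, omega))
    Rcpp::stop("omega matrix is not positive definite");
  double ldO, sgn;
  log_det(ldO, sgn, omega);
  double total = 0.0;
  mat eta_out(nsub, 2);
  Rcpp::LogicalVector conv(nsub);
  for (int i = 0; i < nsub; ++i) {
    const vec ce = Rcpp::as<vec>(ce_list[i]);
    const vec dv = Rcpp::as<vec>(dv_list[i]);
    FoceiResult r = focei_pd_subject_core(ce, dv, E0, Emax, EC50, gamma,
                                          Oinv, ldO, sigma2,
                                          eta_warm.row(i).t(), maxit, tol);
    total += r.ofv;
    eta_out.row(i) = r.eta.t();
    conv[i] = r.converged;
  }
  return Rcpp::List::create(Rcpp::_["ofv"] = total,
                            Rcpp::_["eta"] = eta_out,
                            Rcpp::_["converged"] = conv);
}

// Whole-dataset FOCE-I objective: one call per outer evaluation. theta_mat is
// n_subjects x 6 (subject-typical parameters with covariate factors applied);
// eta_warm holds the warm-start conditional modes and is updated in place by
// returning the new modes.
// [[Rcpp::export(name = ".focei_pk_all_cpp")]]
Rcpp::List focei_pk_all_cpp(const arma::mat& theta_mat,
                            const arma::uvec& eta_idx,
                            const Rcpp::List& events_list,
                            const Rcpp::List& times_list,
                            const Rcpp::List& dv_list,
                            const arma::mat& omega,
                            double sigma2,
                            const arma::mat& eta_warm,
                            int maxit, double tol) {
  const int nsub = theta_mat.n_rows;
  const int d = eta_idx.n_elem;
  mat Oinv;
  if (!inv_sympd(Oinv, omega))
    Rcpp::stop("omega matrix is not positive definite");
  double ldO, sgn;
  log_det(ldO, sgn, omega);
  double total = 0.0;
  mat eta_out(nsub, d);
  Rcpp::LogicalVector conv(nsub);
  for (int i = 0; i < nsub; ++i) {
    const mat events = Rcpp::as<mat>(events_list[i]);
    const vec times = Rcpp::as<vec>(times_list[i]);
    const vec dv = Rcpp::as<vec>(dv_list[i]);
    FoceiResult r = focei_pk_subject_core(theta_mat.row(i).t(), eta_idx,
                                          events, times, dv, Oinv, ldO,
                                          sigma2, eta_warm.row(i).t(),
                                          maxit, tol);
    total += r.ofv;
    eta_out.row(i) = r.eta.t();
    conv[i] = r.converged;
  }
  return Rcpp::List::create(Rcpp::_["ofv"] = total,
                            Rcpp::_["eta"] = eta_out,
                            Rcpp::_["converged"] = conv);
}
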