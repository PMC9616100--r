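// Mass-action ODE core: right-hand side, analytic Jacobian and a linearly
// implicit Rosenbrock(2,3) integrator (Shampine-Reichelt ode23s scheme,
// L-stable) suitable for rate constants spanning ~10 orders of magnitude.
//
// Reactions are at most bimolecular on each side.  A reaction j is encoded by
// integer species indices re(j,0), re(j,1) (reactants) and pr(j,0), pr(j,1)
// (products), with -1 meaning "no molecule in this slot", and a rate constant
// k[j] (s^-1 if one reactant slot is used, M^-1 s^-1 if two).

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;

static void massaction_rhs(const vec& y, const imat& re, const imat& pr,
                           const vec& k, vec& dy) {
  dy.zeros();
  const int m = k.n_elem;
  for (int j = 0; j < m; ++j) {
    double f = k[j];
    const int r1 = re(j, 0), r2 = re(j, 1);
    if (r1 >= 0) f *= y[r1];
    if (r2 >= 0) f *= y[r2];
    if (r1 >= 0) dy[r1] -= f;
    if (r2 >= 0) dy[r2] -= f;
    const int p1 = pr(j, 0), p2 = pr(j, 1);
    if (p1 >= 0) dy[p1] += f;
    if (p2 >= 0) dy[p2] += f;
  }
}

static void massaction_jac(const vec& y, const imat& re, const imat& pr,
                           const vec& k, mat& J) {
  J.zeros();
  const int m = k.n_elem;
  for (int j = 0; j < m; ++j) {
    const int r1 = re(j, 0), r2 = re(j, 1);
    const int p1 = pr(j, 0), p2 = pr(j, 1);
    // derivative of the flux w.r.t. each reactant
    for (int which = 0; which < 2; ++which) {
      const int rs = (which == 0) ? r1 : r2;
      if (rs < 0) continue;
      double d = k[j];
      const int other = (which == 0) ? r2 : r1;
      if (other >= 0) d *= y[other];
      if (r1 >= 0) J(r1, rs) -= d;
      if (r2 >= 0) J(r2, rs) -= d;
      if (p1 >= 0) J(p1, rs) += d;
      if (p2 >= 0) J(p2, rs) += d;
    }
  }
}

// [[Rcpp::export]]
Rcpp::NumericVector massaction_rhs_cpp(Rcpp::NumericVector y0,
                                       Rcpp::IntegerMatrix re0,
                                       Rcpp::IntegerMatrix pr0,
                                       Rcpp::NumericVector k0) {
  vec y = Rcpp::as<vec>(y0), k = Rcpp::as<vec>(k0);
  imat re = Rcpp::as<imat>(re0), pr = Rcpp::as<imat>(pr0);
  vec dy(y.n_elem);
  massaction_rhs(y, re, pr, k, dy);
  return Rcpp::wrap(dy);
}

// Integrate dy/dt = f(y) by the ode23s Rosenbrock pair with analytic
// Jacobian, reporting the solution at the requested output times.
// `times` must be strictly increasing and non-negative; integration starts
// at t = 0.  Small negative excursions (integrator noise) are clipped to
// zero; excursions beyond the noise floor abort with an error.
// [[Rcpp::export]]
Rcpp::NumericMatrix ode23s_cpp(Rcpp::NumericVector y0_in,
                               Rcpp::IntegerMatrix re0,
                               Rcpp::IntegerMatrix pr0,
                               Rcpp::NumericVector k0,
                               Rcpp::NumericVector times_in,
                               double rtol, double atol) {
  vec y = Rcpp::as<vec>(y0_in), k = Rcpp::as<vec>(k0);
  imat re = Rcpp::as<imat>(re0), pr = Rcpp::as<imat>(pr0);
  vec times = Rcpp::as<vec>(times_in);
  const int n = y.n_elem, nt = times.n_elem;

  Rcpp::NumericMatrix out(nt, n);
  const double d = 1.0 / (2.0 + std::sqrt(2.0));
  const double e32 = 6.0 + std::sqrt(2.0);

  double t = 0.0;
  const double tend = times[nt - 1];
  double ymax = arma::abs(y).max();

  // initial step from the rhs magnitude
  vec f0(n), f1(n), f2(n), k1(n), k2(n), k3(n), ynew(n), err(n);
  mat J(n, n), W(n, n);
  massaction_rhs(y, re, pr, k, f0);
  double fn = norm(f0, "inf");
  double h = (fn > 0) ? 0.01 * (atol + rtol * std::max(ymax, 1e-300)) / fn
                      : tend * 1e-6;
  if (!(h > 0)) h = tend * 1e-6;
  h = std::min(h, tend > 0 ? tend : 1.0);

  int iout = 0;
  // emit any outputs at t == 0
  while (iout < nt && times[iout] <= 0.0) {
    for (int i = 0; i < n; ++i) out(iout, i) = y[i];
    ++iout;
  }

  const mat I = eye(n, n);
  long nstep = 0, nreject = 0;
  const long max_steps = 5000000;

  while (iout < nt) {
    const double tout = times[iout];
    bool hit = false;
    if (t + h >= tout) { h = tout - t; hit = true; }
    if (h <= 0) h = (tout - t);

    massaction_rhs(y, re, pr, k, f0);
    massaction_jac(y, re, pr, k, J);
    bool step_ok = false;
    double errnorm = 0.0;
    while (!step_ok) {
      if (++nstep > max_steps)
        Rcpp::stop("ode23s: step limit exceeded at t = %g s", t);
      W = I - (h * d) * J;
      bool solved = solve(k1, W, f0, solve_opts::no_approx + solve_opts::fast);
      if (!solved) Rcpp::stop("ode23s: singular stage matrix at t = %g s", t);
      ynew = y + (0.5 * h) * k1;
      massaction_rhs(ynew, re, pr, k, f1);
      solve(k2, W, vec(f1 - k1), solve_opts::no_approx + solve_opts::fast);
      k2 += k1;
      ynew = y + h * k2;
      massaction_rhs(ynew, re, pr, k, f2);
      solve(k3, W, vec(f2 - e32 * (k2 - f1) - 2.0 * (k1 - f0)),
            solve_opts::no_approx + solve_opts::fast);
      err = (h / 6.0) * (k1 - 2.0 * k2 + k3);
      errnorm = 0.0;
      for (int i = 0; i < n; ++i) {
        const double sk = atol + rtol * std::max(std::fabs(y[i]), std::fabs(ynew[i]));
        const double e = err[i] / sk;
        errnorm += e * e;
      }
      errnorm = std::sqrt(errnorm / n);
      if (errnorm <= 1.0 || h <= 16.0 * std::numeric_limits<double>::epsilon() * std::max(t, 1.0)) {
        step_ok = true;
      } else {
        ++nreject;
        hit = false;
        h *= std::max(0.2, 0.9 * std::pow(errnorm, -1.0 / 3.0));
      }
    }
    t = hit ? tout : (t + h);
    y = ynew;
    ymax = std::max(ymax, arma::abs(y).max());
    // clip integrator-noise negatives; abort on anything larger
    const double negtol = 100.0 * atol + 10.0 * rtol * ymax;
    for (int i = 0; i < n; ++i) {
      if (y[i] < 0) {
        if (y[i] < -negtol)
          Rcpp::stop("ode23s: concentration of species %d went negative (%g) at t = %g s",
                     i + 1, y[i], t);
        y[i] = 0.0;
      }
    }
    while (iout < nt && t >= times[iout] * (1.0 - 1e-14) && std::fabs(t - times[iout]) <= 1e-12 * std::max(1.0, times[iout])) {
      for (int i = 0; i < n; ++i) out(iout, i) = y[i];
      ++iout;
    }
    double fac = 0.9 * std::pow(std::max(errnorm, 1e-10), -1.0 / 3.0);
    h *= std::min(5.0, std::max(0.2, fac));
    if (iout < nt && t + h > times[nt - 1]) h = times[nt - 1] - t;
  }
  return out;
}
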