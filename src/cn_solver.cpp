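#include <Rcpp.h>
using namespace Rcpp;

// Time-stepper for the transformed frequency-spectrum equation.
//
// The forward equation for the density f(x, tau) of segregating sites,
//   df/dtau = 1/2 d2/dx2 [ x(1-x) f / rho(tau) ] - d/dx [ S x(1-x) f ],
// is solved in terms of g = x(1-x) f, which satisfies
//   dg/dtau = x(1-x) [ g'' / (2 rho) - S g' ]
// with Dirichlet boundaries g(0, tau) = theta * rho(tau) (mutational influx)
// and g(1, tau) = 0 (absorption into fixation).
//
// Crank-Nicolson on a nonuniform grid; the first `n_rannacher` steps of a run
// are fully implicit to damp oscillations from rough initial data.

// [[Rcpp::export]]
NumericVector cn_evolve_cpp(NumericVector g0, NumericVector x, double S,
                            double theta, NumericVector rho, NumericVector dt,
                            int n_rannacher = 4) {
  const int M = x.size();
  const int nstep = dt.size();
  if (g0.size() != M) stop("g0 and x lengths differ");
  if (rho.size() != nstep + 1) stop("rho must have length(dt) + 1");
  if (M < 5) stop("grid too small");

  NumericVector g = clone(g0);
  const int ni = M - 2;  // interior nodes

  // nonuniform-stencil coefficients for d2/dx2 and d/dx at interior nodes
  std::vector<double> d2l(ni), d2c(ni), d2u(ni), d1l(ni), d1c(ni), d1u(ni),
      b0(ni);
  for (int j = 0; j < ni; ++j) {
    const double hm = x[j + 1] - x[j];
    const double hp = x[j + 2] - x[j + 1];
    d2l[j] = 2.0 / (hm * (hm + hp));
    d2u[j] = 2.0 / (hp * (hm + hp));
    d2c[j] = -2.0 / (hm * hp);
    d1l[j] = -hp / (hm * (hm + hp));
    d1u[j] = hm / (hp * (hm + hp));
    d1c[j] = (hp - hm) / (hm * hp);
    const double xm = x[j + 1];
    b0[j] = xm * (1.0 - xm);
  }

  std::vector<double> lo(ni), di(ni), up(ni), rhs(ni), cp(ni), dp(ni);

  for (int k = 0; k < nstep; ++k) {
    const double w = (k < n_rannacher) ? 1.0 : 0.5;  // implicit weight
    const double dtk = dt[k];
    const double rho_old = rho[k], rho_new = rho[k + 1];
    const double bl_new = theta * rho_new;  // boundary value g(0) at new time

    // explicit part: rhs = g + (1-w) dt L(rho_old) g  (interior)
    for (int j = 0; j < ni; ++j) {
      const double gl = g[j], gc = g[j + 1], gu = g[j + 2];
      const double Lg =
          b0[j] * ((d2l[j] * gl + d2c[j] * gc + d2u[j] * gu) / (2.0 * rho_old) -
                   S * (d1l[j] * gl + d1c[j] * gc + d1u[j] * gu));
      rhs[j] = gc + (1.0 - w) * dtk * Lg;
    }

    // implicit matrix I - w dt L(rho_new)
    for (int j = 0; j < ni; ++j) {
      const double cdiff = w * dtk * b0[j];
      lo[j] = -cdiff * (d2l[j] / (2.0 * rho_new) - S * d1l[j]);
      di[j] = 1.0 - cdiff * (d2c[j] / (2.0 * rho_new) - S * d1c[j]);
      up[j] = -cdiff * (d2u[j] / (2.0 * rho_new) - S * d1u[j]);
    }
    // fold known Dirichlet boundary values into rhs
    rhs[0] -= lo[0] * bl_new;
    // g(1) = 0 so the last super-diagonal term vanishes

    // Thomas algorithm
    cp[0] = up[0] / di[0];
    dp[0] = rhs[0] / di[0];
    for (int j = 1; j < ni; ++j) {
      const double m = di[j] - lo[j] * cp[j - 1];
      cp[j] = up[j] / m;
      dp[j] = (rhs[j] - lo[j] * dp[j - 1]) / m;
    }
    g[ni] = dp[ni - 1];
    for (int j = ni - 2; j >= 0; --j) g[j + 1] = dp[j] - cp[j] * g[j + 2];

    g[0] = bl_new;
    g[M - 1] = 0.0;
  }
  return g;
}
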