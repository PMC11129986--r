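#include <Rcpp.h>
using namespace Rcpp;

// Forward-Euler / 3-point central-difference integrator for the 1-D
// reaction-diffusion system (diffusivities 1, 1, D; zero-flux boundaries
// via mirrored ghost nodes). Snapshots of all three fields are stored
// every save_every steps. Values in (-1e-8, 0) produced by the explicit
// update are clamped to zero and counted; anything more negative aborts.

// [[Rcpp::export]]
List rd_simulate_cpp(NumericVector c0, NumericVector u0, NumericVector v0,
                     List pars, double D, double dx, double dt,
                     int nsteps, int save_every) {
  const double A = pars["A"], B = pars["B"], sigma = pars["sigma"],
    c1 = pars["c1"], c2 = pars["c2"], c3 = pars["c3"], c4 = pars["c4"],
    eta = pars["eta"], delta = pars["delta"], nu = pars["nu"],
    h = pars["h"], mu1 = pars["mu1"], mu2 = pars["mu2"],
    eps = pars["epsilon"];
  const int n = c0.size();
  const double idx2 = 1.0 / (dx * dx);

  std::vector<double> c(c0.begin(), c0.end());
  std::vector<double> u(u0.begin(), u0.end());
  std::vector<double> v(v0.begin(), v0.end());
  std::vector<double> cn(n), un(n), vn(n);

  const int nsnap = nsteps / save_every + 1;
  NumericMatrix Cs(nsnap, n), Us(nsnap, n), Vs(nsnap, n);
  NumericVector times(nsnap);
  long clamped = 0;
  int isnap = 0;
  for (int j = 0; j < n; ++j) {
    Cs(0, j) = c[j]; Us(0, j) = u[j]; Vs(0, j) = v[j];
  }
  times[0] = 0.0;
  ++isnap;

  for (int step = 1; step <= nsteps; ++step) {
    for (int j = 0; j < n; ++j) {
      const int jm = (j == 0) ? 1 : j - 1;       // mirrored ghost nodes
      const int jp = (j == n - 1) ? n - 2 : j + 1;
      const double cc = c[j], uu = u[j], vv = v[j];
      const double lc = (c[jm] - 2.0 * cc + c[jp]) * idx2;
      const double lu = (u[jm] - 2.0 * uu + u[jp]) * idx2;
      const double lv = (v[jm] - 2.0 * vv + v[jp]) * idx2;
      const double Fr = A * uu / (cc + 1.0) - delta * uu * cc / (cc + c2)
        - nu * cc * vv / (cc + c3) - cc;
      const double Gr = (B * cc / (cc + c1) - uu) * uu
        - uu * vv / (uu + h) - sigma * uu;
      const double Hr = eta * cc * cc / (cc * cc + c4 * c4)
        * uu * vv / (uu + h) - mu1 * vv - mu2 * vv * vv;
      cn[j] = cc + dt * (lc + Fr);
      un[j] = uu + dt * (lu + Gr);
      vn[j] = vv + dt * (D * lv + eps * Hr);
    }
    for (int j = 0; j < n; ++j) {
      if (cn[j] < 0.0 || un[j] < 0.0 || vn[j] < 0.0) {
        if (cn[j] < -1e-8 || un[j] < -1e-8 || vn[j] < -1e-8)
          stop("numerical failure: field value below -1e-8 at step %d", step);
        if (cn[j] < 0.0) { cn[j] = 0.0; ++clamped; }
        if (un[j] < 0.0) { un[j] = 0.0; ++clamped; }
        if (vn[j] < 0.0) { vn[j] = 0.0; ++clamped; }
      }
      if (!std::isfinite(cn[j]) || !std::isfinite(un[j]) || !std::isfinite(vn[j]))
        stop("numerical failure: non-finite field value at step %d", step);
    }
    c.swap(cn); u.swap(un); v.swap(vn);
    if (step % save_every == 0) {
      for (int j = 0; j < n; ++j) {
        Cs(isnap, j) = c[j]; Us(isnap, j) = u[j]; Vs(isnap, j) = v[j];
      }
      times[isnap] = step * dt;
      ++isnap;
    }
  }
  return List::create(_["times"] = times, _["c"] = Cs, _["u"] = Us,
                      _["v"] = Vs, _["clamped"] = (double) clamped);
}
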