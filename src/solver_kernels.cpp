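#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Staggered MAC layout (0-based here; R wrappers are 1-based):
//   u: (nx+1) x ny, face i at x = i*h between cells i-1 and i
//   v: nx x (ny+1), face j at y = j*h between cells j-1 and j
//   lab: nx x ny cell labels (0 solid, 1 channel fluid, 2 sac fluid)
//   ustate: 0 fixed zero (wall/solid), 1 interior unknown, 2 inlet Dirichlet,
//           3 outlet (zero-gradient, pressure-corrected)
//   vstate: 0 fixed zero, 1 interior unknown
// Advection: second-order upwind with first-order fallback next to
// boundaries; tangential ghost values across a wall are mirrored (-u) so the
// no-slip wall sits exactly on the grid line.

// [[Rcpp::export]]
List predictor_step(NumericMatrix u, NumericMatrix v,
                    IntegerMatrix ustate, IntegerMatrix vstate,
                    IntegerMatrix lab,
                    NumericMatrix au_lin, NumericMatrix au_quad,
                    NumericMatrix av_lin, NumericMatrix av_quad,
                    double dt, double h, double nu) {
  const int nxp1 = u.nrow(), ny = u.ncol();
  const int nx = nxp1 - 1;
  NumericMatrix us(nxp1, ny), vs(nx, ny + 1);
  const double h2 = h * h;
  double maxvel = 0.0;
  bool bad = false;

  // ---- u momentum ----
  for (int j = 0; j < ny; ++j) {
    for (int i = 0; i <= nx; ++i) {
      int st = ustate(i, j);
      if (st == 2) { us(i, j) = u(i, j); continue; }      // inlet, prescribed
      if (st != 1) continue;                               // walls stay 0; outlet set below
      double uc = u(i, j);
      // advecting transverse velocity at the u face (corner average)
      double vbar = 0.25 * (v(i - 1, j) + v(i - 1, j + 1) + v(i, j) + v(i, j + 1));

      // du/dx, upwinded on the face row (stored neighbours are valid:
      // wall faces hold 0, inlet holds the profile)
      double dudx;
      if (uc >= 0.0) {
        if (i - 2 >= 0)
          dudx = (3.0 * uc - 4.0 * u(i - 1, j) + u(i - 2, j)) / (2.0 * h);
        else
          dudx = (uc - u(i - 1, j)) / h;
      } else {
        if (i + 2 <= nx)
          dudx = (-3.0 * uc + 4.0 * u(i + 1, j) - u(i + 2, j)) / (2.0 * h);
        else
          dudx = (u(i + 1, j) - uc) / h;
      }

      // du/dy, upwinded; linear mirror across walls
      bool haveN = (j + 1 < ny) && ustate(i, j + 1) != 0;
      bool haveS = (j - 1 >= 0) && ustate(i, j - 1) != 0;
      double uN = haveN ? u(i, j + 1) : -uc;
      double uS = haveS ? u(i, j - 1) : -uc;
      double dudy;
      if (vbar >= 0.0) {
        bool have2 = (j - 2 >= 0) && ustate(i, j - 1) != 0 && ustate(i, j - 2) != 0;
        dudy = have2 ? (3.0 * uc - 4.0 * u(i, j - 1) + u(i, j - 2)) / (2.0 * h)
                     : (uc - uS) / h;
      } else {
        bool have2 = (j + 2 < ny) && ustate(i, j + 1) != 0 && ustate(i, j + 2) != 0;
        dudy = have2 ? (-3.0 * uc + 4.0 * u(i, j + 1) - u(i, j + 2)) / (2.0 * h)
                     : (uN - uc) / h;
      }

      // diffusion: tangential ghosts across a wall use the quadratic
      // extrapolant through the no-slip interface (ghost = (far - 6c)/3),
      // exact for parabolic profiles; linear mirror when no far neighbour
      double uN_d = haveN ? uN : (haveS ? (uS - 6.0 * uc) / 3.0 : -uc);
      double uS_d = haveS ? uS : (haveN ? (uN - 6.0 * uc) / 3.0 : -uc);
      double lap = (u(i + 1, j) + u(i - 1, j) - 2.0 * uc) / h2
                 + (uN_d + uS_d - 2.0 * uc) / h2;

      double speed = std::sqrt(uc * uc + vbar * vbar);
      double denom = 1.0 + dt * (au_lin(i, j) + au_quad(i, j) * speed);
      double val = (uc + dt * (-(uc * dudx + vbar * dudy) + nu * lap)) / denom;
      if (!std::isfinite(val)) bad = true;
      us(i, j) = val;
      if (std::fabs(val) > maxvel) maxvel = std::fabs(val);
    }
  }
  // outlet faces: zero-gradient on the provisional field
  for (int j = 0; j < ny; ++j)
    if (ustate(nx, j) == 3) us(nx, j) = us(nx - 1, j);

  // ---- v momentum ----
  for (int j = 0; j <= ny; ++j) {
    for (int i = 0; i < nx; ++i) {
      if (vstate(i, j) != 1) continue;
      double vc = v(i, j);
      double ubar = 0.25 * (u(i, j - 1) + u(i + 1, j - 1) + u(i, j) + u(i + 1, j));

      double dvdy;
      if (vc >= 0.0) {
        if (j - 2 >= 0)
          dvdy = (3.0 * vc - 4.0 * v(i, j - 1) + v(i, j - 2)) / (2.0 * h);
        else
          dvdy = (vc - v(i, j - 1)) / h;
      } else {
        if (j + 2 <= ny)
          dvdy = (-3.0 * vc + 4.0 * v(i, j + 1) - v(i, j + 2)) / (2.0 * h);
        else
          dvdy = (v(i, j + 1) - vc) / h;
      }

      // tangential (x) neighbours: mirror at inlet/walls, zero-gradient at outlet
      bool haveE = (i + 1 < nx) && vstate(i + 1, j) != 0;
      bool haveW = (i - 1 >= 0) && vstate(i - 1, j) != 0;
      bool at_outlet = (i + 1 >= nx);
      double vE = at_outlet ? vc : (haveE ? v(i + 1, j) : -vc);
      double vW = haveW ? v(i - 1, j) : -vc;
      double dvdx;
      if (ubar >= 0.0) {
        bool have2 = (i - 2 >= 0) && vstate(i - 1, j) != 0 && vstate(i - 2, j) != 0;
        dvdx = have2 ? (3.0 * vc - 4.0 * v(i - 1, j) + v(i - 2, j)) / (2.0 * h)
                     : (vc - vW) / h;
      } else {
        bool have2 = (i + 2 < nx) && vstate(i + 1, j) != 0 && vstate(i + 2, j) != 0;
        dvdx = have2 ? (-3.0 * vc + 4.0 * v(i + 1, j) - v(i + 2, j)) / (2.0 * h)
                     : (vE - vc) / h;
      }

      // quadratic wall ghosts in x for diffusion (not at inlet/outlet planes)
      double vE_d = vE, vW_d = vW;
      if (!at_outlet && !haveE && haveW) vE_d = (vW - 6.0 * vc) / 3.0;
      if (i - 1 >= 0 && !haveW && haveE) vW_d = (vE - 6.0 * vc) / 3.0;
      double lap = (vE_d + vW_d - 2.0 * vc) / h2
                 + (v(i, j + 1) + v(i, j - 1) - 2.0 * vc) / h2;

      double speed = std::sqrt(vc * vc + ubar * ubar);
      double denom = 1.0 + dt * (av_lin(i, j) + av_quad(i, j) * speed);
      double val = (vc + dt * (-(ubar * dvdx + vc * dvdy) + nu * lap)) / denom;
      if (!std::isfinite(val)) bad = true;
      vs(i, j) = val;
      if (std::fabs(val) > maxvel) maxvel = std::fabs(val);
    }
  }

  // ---- divergence of the provisional field over fluid cells ----
  NumericMatrix div(nx, ny);
  for (int j = 0; j < ny; ++j)
    for (int i = 0; i < nx; ++i)
      if (lab(i, j) > 0)
        div(i, j) = (us(i + 1, j) - us(i, j) + vs(i, j + 1) - vs(i, j)) / h;

  return List::create(_["us"] = us, _["vs"] = vs, _["div"] = div,
                      _["maxvel"] = maxvel, _["bad"] = bad);
}

// [[Rcpp::export]]
List corrector_step(NumericMatrix us, NumericMatrix vs, NumericMatrix p,
                    IntegerMatrix ustate, IntegerMatrix vstate,
                    NumericMatrix bu, NumericMatrix bv,
                    double dtorh) {
  const int nxp1 = us.nrow(), ny = us.ncol();
  const int nx = nxp1 - 1;
  NumericMatrix un(clone(us)), vn(clone(vs));
  for (int j = 0; j < ny; ++j) {
    for (int i = 1; i < nx; ++i)
      if (ustate(i, j) == 1)
        un(i, j) = us(i, j) - bu(i, j) * dtorh * (p(i, j) - p(i - 1, j));
    if (ustate(nx, j) == 3)  // outlet face: ghost pressure = -p so p = 0 on the face
      un(nx, j) = us(nx, j) + dtorh * 2.0 * p(nx - 1, j);
  }
  for (int j = 1; j < ny; ++j)
    for (int i = 0; i < nx; ++i)
      if (vstate(i, j) == 1)
        vn(i, j) = vs(i, j) - bv(i, j) * dtorh * (p(i, j) - p(i, j - 1));
  return List::create(_["u"] = un, _["v"] = vn);
}

// Post-projection divergence (diagnostic)
// [[Rcpp::export]]
double max_divergence(NumericMatrix u, NumericMatrix v, IntegerMatrix lab,
                      double h) {
  const int nx = lab.nrow(), ny = lab.ncol();
  double m = 0.0;
  for (int j = 0; j < ny; ++j)
    for (int i = 0; i < nx; ++i)
      if (lab(i, j) > 0) {
        double d = std::fabs((u(i + 1, j) - u(i, j) + v(i, j + 1) - v(i, j)) / h);
        if (d > m) m = d;
      }
  return m;
}
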