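#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Linear interpolation on a uniform grid spanning [-L/2, +L/2] whose first
// and last values agree (periodic profile). z may be any real number; it is
// wrapped into the primary cell first.
static inline double interp_periodic(double z, double L, int ng,
                                     const double *grid) {
  double zw = z - L * std::floor(z / L + 0.5); // [-L/2, L/2)
  double h = L / (ng - 1);
  double u = (zw + 0.5 * L) / h;
  int i = (int)std::floor(u);
  if (i < 0) i = 0;
  if (i >= ng - 1) i = ng - 2;
  double f = u - i;
  return grid[i] * (1.0 - f) + grid[i + 1] * f;
}

// Overdamped Langevin (Ito) dynamics on a 1D periodic free-energy profile
// with position-dependent diffusivity:
//   z <- z + [ -D(z) F'(z)/kBT + D'(z) ] dt + sqrt(2 D(z) dt) N(0,1)
// The spurious-drift term D'(z) makes the stationary law Boltzmann in F
// regardless of D. Profiles are supplied as dense uniform grids over
// [-box_z/2, +box_z/2].
// [[Rcpp::export(name = ".langevin_1d_cpp")]]
List langevin_1d_cpp(NumericVector z0, int n_steps, int save_every,
                     double dt, double box_z,
                     NumericVector drift_grid, NumericVector D_grid) {
  const int np = z0.size();
  const int ng = drift_grid.size();
  if (D_grid.size() != ng) stop("grid size mismatch");
  const int n_saved = n_steps / save_every + 1;
  NumericMatrix zw(n_saved, np), zu(n_saved, np);
  const double *dg = REAL(drift_grid);
  const double *Dg = REAL(D_grid);
  for (int p = 0; p < np; ++p) {
    double z = z0[p];              // unwrapped running coordinate
    zw(0, p) = z - box_z * std::floor(z / box_z + 0.5);
    zu(0, p) = z;
    int isave = 1;
    for (int s = 1; s <= n_steps; ++s) {
      double drift = interp_periodic(z, box_z, ng, dg);
      double D = interp_periodic(z, box_z, ng, Dg);
      z += drift * dt + std::sqrt(2.0 * D * dt) * R::norm_rand();
      if (s % save_every == 0) {
        zw(isave, p) = z - box_z * std::floor(z / box_z + 0.5);
        zu(isave, p) = z;
        ++isave;
      }
    }
  }
  return List::create(_["z_wrapped"] = zw, _["z_unwrapped"] = zu);
}

static inline double min_image(double d, double L) {
  return d - L * std::floor(d / L + 0.5);
}

// Square-well potential energy of one particle: -depth inside the first
// containing well (wells are non-overlapping), 0 outside.
static inline double well_energy(double x, double y, double z,
                                 const NumericMatrix &centers,
                                 const NumericVector &radii,
                                 const NumericVector &depths,
                                 double L) {
  for (int w = 0; w < centers.nrow(); ++w) {
    double dx = min_image(x - centers(w, 0), L);
    double dy = min_image(y - centers(w, 1), L);
    double dz = min_image(z - centers(w, 2), L);
    double r2 = dx * dx + dy * dy + dz * dz;
    if (r2 <= radii[w] * radii[w]) return -depths[w];
  }
  return 0.0;
}

// Metropolis random walk in a cubic periodic box with spherical square
// wells: isotropic Gaussian proposals of scale step_size, acceptance
// min(1, exp(-dU/kBT)). Exact Boltzmann stationary law by construction.
// Returns wrapped and unwrapped coordinate arrays [frame, particle, axis].
// [[Rcpp::export(name = ".metropolis_3d_cpp")]]
List metropolis_3d_cpp(NumericMatrix x0, int n_steps, int save_every,
                       double box, double step_size,
                       NumericMatrix centers, NumericVector radii,
                       NumericVector depths, double kT) {
  const int np = x0.nrow();
  const int n_saved = n_steps / save_every + 1;
  NumericVector xyz_w(Dimension(n_saved, np, 3));
  NumericVector xyz_u(Dimension(n_saved, np, 3));
  const R_xlen_t fstride = n_saved;
  const R_xlen_t astride = (R_xlen_t)n_saved * np;
  for (int p = 0; p < np; ++p) {
    double x = x0(p, 0), y = x0(p, 1), z = x0(p, 2);
    double ux = x, uy = y, uz = z;
    double U = well_energy(x, y, z, centers, radii, depths, box);
    for (int a = 0; a < 3; ++a) {
      double w = (a == 0 ? x : (a == 1 ? y : z));
      double u = (a == 0 ? ux : (a == 1 ? uy : uz));
      xyz_w[0 + fstride * p + astride * a] = min_image(w, box);
      xyz_u[0 + fstride * p + astride * a] = u;
    }
    int isave = 1;
    for (int s = 1; s <= n_steps; ++s) {
      double dx = step_size * R::norm_rand();
      double dy = step_size * R::norm_rand();
      double dz = step_size * R::norm_rand();
      double Un = well_energy(x + dx, y + dy, z + dz,
                              centers, radii, depths, box);
      double dU = Un - U;
      bool accept = (dU <= 0.0) || (unif_rand() < std::exp(-dU / kT));
      if (accept) {
        x += dx; y += dy; z += dz;
        ux += dx; uy += dy; uz += dz;
        U = Un;
      }
      if (s % save_every == 0) {
        xyz_w[isave + fstride * p + astride * 0] = min_image(x, box);
        xyz_w[isave + fstride * p + astride * 1] = min_image(y, box);
        xyz_w[isave + fstride * p + astride * 2] = min_image(z, box);
        xyz_u[isave + fstride * p + astride * 0] = ux;
        xyz_u[isave + fstride * p + astride * 1] = uy;
        xyz_u[isave + fstride * p + astride * 2] = uz;
        ++isave;
      }
    }
  }
  return List::create(_["xyz_wrapped"] = xyz_w, _["xyz_unwrapped"] = xyz_u);
}

// Free 3D Brownian motion in a periodic cubic-or-orthorhombic box.
// [[Rcpp::export(name = ".free_3d_cpp")]]
List free_3d_cpp(NumericMatrix x0, int n_steps, int save_every,
                 double dt, NumericVector box, double D) {
  const int np = x0.nrow();
  const int n_saved = n_steps / save_every + 1;
  const double sigma = std::sqrt(2.0 * D * dt);
  NumericVector xyz_w(Dimension(n_saved, np, 3));
  NumericVector xyz_u(Dimension(n_saved, np, 3));
  const R_xlen_t fstride = n_saved;
  const R_xlen_t astride = (R_xlen_t)n_saved * np;
  for (int p = 0; p < np; ++p) {
    double u[3] = { x0(p, 0), x0(p, 1), x0(p, 2) };
    for (int a = 0; a < 3; ++a) {
      xyz_w[0 + fstride * p + astride * a] = min_image(u[a], box[a]);
      xyz_u[0 + fstride * p + astride * a] = u[a];
    }
    int isave = 1;
    for (int s = 1; s <= n_steps; ++s) {
      for (int a = 0; a < 3; ++a) u[a] += sigma * R::norm_rand();
      if (s % save_every == 0) {
        for (int a = 0; a < 3; ++a) {
          xyz_w[isave + fstride * p + astride * a] = min_image(u[a], box[a]);
          xyz_u[isave + fstride * p + astride * a] = u[a];
        }
        ++isave;
      }
    }
  }
  return List::create(_["xyz_wrapped"] = xyz_w, _["xyz_unwrapped"] = xyz_u);
}
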