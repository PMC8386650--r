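#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Linear interpolation on a uniform grid; clamped at the edges.
static inline double interp(const std::vector<double>& v, double x0,
                            double h, int n, double x) {
  double u = (x - x0) / h;
  if (u <= 0.0) return v[0];
  if (u >= n - 1) return v[n - 1];
  int i = (int)u;
  double f = u - i;
  return v[i] * (1.0 - f) + v[i + 1] * f;
}

// Overdamped Langevin dynamics with well-tempered multiple-walker
// metadynamics on a 1D tabulated potential.
//
// Units: length Angstrom, time ps, energy kcal/mol. The equation of
// motion is ds = -U'(s)/friction dt + sqrt(2 kT dt / friction) eta.
// Each walker deposits Gaussians into a private pending buffer that is
// merged into the shared bias every sync_stride_steps (the multiple-
// walker shared history-dependent bias); hill heights follow the
// well-tempered rule h = w0 exp(-V(s) / ((gamma - 1) kT)) evaluated on
// the walker's current view of the bias.
//
// Uses R's RNG so set.seed() in R makes runs reproducible.
// [[Rcpp::export]]
List run_metad_cpp(NumericVector s0, NumericVector grid_u,
                   double grid_x0, double grid_h,
                   double dt, int n_steps, double friction, double kT,
                   double w0, double sigma, double gamma_f,
                   int dep_stride_steps, int sync_stride_steps,
                   double wall_kappa, double wall_pos, double wall_lower,
                   int record_stride) {
  const int n_walk = s0.size();
  const int ng = grid_u.size();
  std::vector<double> U(grid_u.begin(), grid_u.end());
  const double xmin = grid_x0;
  const double xmax = grid_x0 + grid_h * (ng - 1);

  std::vector<double> shared(ng, 0.0);
  std::vector<std::vector<double> > pending(
      n_walk, std::vector<double>(ng, 0.0));
  std::vector<double> s(s0.begin(), s0.end());

  std::vector<double> hill_time, hill_center, hill_height;
  std::vector<int> hill_walker;

  const int n_rec = n_steps / record_stride + 1;
  NumericMatrix traj(n_rec, n_walk);
  NumericVector traj_t(n_rec);
  int i_rec = 0;

  const double noise_amp = std::sqrt(2.0 * kT * dt / friction);
  const double fd = 0.5 * grid_h;  // finite-difference half step
  const bool well_tempered = gamma_f > 1.0 && w0 > 0.0;

  RNGScope scope;

  for (int step = 0; step <= n_steps; ++step) {
    if (step % record_stride == 0 && i_rec < n_rec) {
      traj_t[i_rec] = step * dt;
      for (int w = 0; w < n_walk; ++w) traj(i_rec, w) = s[w];
      ++i_rec;
    }
    if (step == n_steps) break;

    for (int w = 0; w < n_walk; ++w) {
      double x = s[w];
      // potential force (finite difference on the tabulated grid)
      double f = -(interp(U, xmin, grid_h, ng, x + fd) -
                   interp(U, xmin, grid_h, ng, x - fd)) / (2.0 * fd);
      // bias force: shared + own pending
      if (w0 > 0.0) {
        double vp = interp(shared, xmin, grid_h, ng, x + fd) +
                    interp(pending[w], xmin, grid_h, ng, x + fd);
        double vm = interp(shared, xmin, grid_h, ng, x - fd) +
                    interp(pending[w], xmin, grid_h, ng, x - fd);
        f += -(vp - vm) / (2.0 * fd);
      }
      // one-sided harmonic walls
      if (x > wall_pos) f += -2.0 * wall_kappa * (x - wall_pos);
      if (x < wall_lower) f += 2.0 * wall_kappa * (wall_lower - x);

      x += f / friction * dt + noise_amp * norm_rand();
      // reflect at the grid boundary (outside any wall)
      if (x < xmin) x = 2.0 * xmin - x;
      if (x > xmax) x = 2.0 * xmax - x;
      s[w] = x;
    }

    int t1 = step + 1;
    if (w0 > 0.0 && dep_stride_steps > 0 && t1 % dep_stride_steps == 0) {
      for (int w = 0; w < n_walk; ++w) {
        double x = s[w];
        double h = w0;
        if (well_tempered) {
          double v = interp(shared, xmin, grid_h, ng, x) +
                     interp(pending[w], xmin, grid_h, ng, x);
          h = w0 * std::exp(-v / ((gamma_f - 1.0) * kT));
        }
        // add the Gaussian to the walker's pending buffer (6 sigma cut)
        int i_lo = std::max(0, (int)((x - 6.0 * sigma - xmin) / grid_h));
        int i_hi = std::min(ng - 1,
                            (int)((x + 6.0 * sigma - xmin) / grid_h) + 1);
        for (int i = i_lo; i <= i_hi; ++i) {
          double d = xmin + i * grid_h - x;
          pending[w][i] += h * std::exp(-d * d / (2.0 * sigma * sigma));
        }
        hill_time.push_back(t1 * dt);
        hill_center.push_back(x);
        hill_height.push_back(h);
        hill_walker.push_back(w + 1);
      }
    }
    if (w0 > 0.0 && sync_stride_steps > 0 && t1 % sync_stride_steps == 0) {
      for (int w = 0; w < n_walk; ++w) {
        for (int i = 0; i < ng; ++i) {
          shared[i] += pending[w][i];
          pending[w][i] = 0.0;
        }
      }
    }
  }

  // fold any unsynced pending bias into the final shared bias
  for (int w = 0; w < n_walk; ++w)
    for (int i = 0; i < ng; ++i) shared[i] += pending[w][i];

  return List::create(
      _["traj_time"] = traj_t, _["traj"] = traj,
      _["hill_time"] = wrap(hill_time), _["hill_center"] = wrap(hill_center),
      _["hill_height"] = wrap(hill_height),
      _["hill_walker"] = wrap(hill_walker),
      _["bias_grid"] = wrap(shared));
}
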