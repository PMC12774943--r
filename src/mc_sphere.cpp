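#include <Rcpp.h>
using namespace Rcpp;

// Monte-Carlo PGSE signal for reflecting random walks in an impermeable
// sphere. Units: um, ms; gamma_g in rad / (um * ms) so phase = gamma_g * z * dt.
// Gradient along z. Returns estimate |mean exp(i phi)| and its standard error.
// [[Rcpp::export(name = ".mc_sphere_walk")]]
List mc_sphere_walk(double R, double d, double delta, double Delta,
                    double gamma_g, int n_walkers, int n_steps) {
  const double T = Delta + delta;
  const double dt = T / n_steps;
  const double sigma = std::sqrt(2.0 * d * dt);   // per-axis step, um

  std::vector<double> x(n_walkers), y(n_walkers), z(n_walkers),
      phi(n_walkers, 0.0);

  // uniform initial positions in the sphere (rejection sampling)
  for (int i = 0; i < n_walkers; ++i) {
    double xi, yi, zi;
    do {
      xi = (2.0 * R_unif_index(1e9) / 1e9 - 1.0) * R;
      yi = (2.0 * R_unif_index(1e9) / 1e9 - 1.0) * R;
      zi = (2.0 * R_unif_index(1e9) / 1e9 - 1.0) * R;
    } while (xi * xi + yi * yi + zi * zi > R * R);
    x[i] = xi; y[i] = yi; z[i] = zi;
  }

  for (int s = 0; s < n_steps; ++s) {
    const double t_mid = (s + 0.5) * dt;
    double grad = 0.0;
    if (t_mid < delta) grad = 1.0;                     // first lobe
    else if (t_mid >= Delta && t_mid < Delta + delta) grad = -1.0;  // second lobe

    for (int i = 0; i < n_walkers; ++i) {
      double nx = x[i] + norm_rand() * sigma;
      double ny = y[i] + norm_rand() * sigma;
      double nz = z[i] + norm_rand() * sigma;
      double r2 = nx * nx + ny * ny + nz * nz;
      if (r2 > R * R) {
        // mirror the radial excess back inside (elastic reflection)
        double r = std::sqrt(r2);
        double fac = (2.0 * R - r) / r;
        if (fac < 0.0) fac = 0.0;   // pathological overshoot: clamp to centre side
        nx *= fac; ny *= fac; nz *= fac;
      }
      x[i] = nx; y[i] = ny; z[i] = nz;
      if (grad != 0.0) phi[i] += grad * gamma_g * z[i] * dt;
    }
  }

  double sc = 0.0, ss = 0.0, sc2 = 0.0;
  for (int i = 0; i < n_walkers; ++i) {
    const double c = std::cos(phi[i]);
    sc += c; ss += std::sin(phi[i]); sc2 += c * c;
  }
  const double mc = sc / n_walkers, ms = ss / n_walkers;
  const double est = std::sqrt(mc * mc + ms * ms);
  const double var_c = sc2 / n_walkers - mc * mc;
  const double se = std::sqrt(std::max(var_c, 0.0) / n_walkers);

  return List::create(_["estimate"] = est, _["se"] = se,
                      _["step_um"] = sigma);
}
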