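// Langevin (BAOAB) integrator with ratchet bias on either a projection CV
// or path collective variables over point milestones, on the analytic toy
// channel potentials. Normal deviates come from R's RNG so runs are
// reproducible via set.seed() and independent of the C++ stdlib.

#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

static const double ENERGY_TO_MD = 418.4; // kcal/mol -> amu A^2/ps^2

struct Toy {
  int dim;
  std::vector<double> gc, gh, gw; // Gaussian centres, heights, widths
  double k_perp, k_end, x_min, x_max;
};

// potential energy (kcal/mol) and gradient at x
static double toy_energy_grad(const Toy &t, const std::vector<double> &x,
                              std::vector<double> &grad) {
  double u = 0.0;
  std::fill(grad.begin(), grad.end(), 0.0);
  for (size_t j = 0; j < t.gc.size(); ++j) {
    double dx = x[0] - t.gc[j];
    double e = t.gh[j] * std::exp(-dx * dx / (2.0 * t.gw[j] * t.gw[j]));
    u += e;
    grad[0] += -e * dx / (t.gw[j] * t.gw[j]);
  }
  for (int d = 1; d < t.dim; ++d) {
    u += 0.5 * t.k_perp * x[d] * x[d];
    grad[d] += t.k_perp * x[d];
  }
  if (x[0] < t.x_min) {
    u += t.k_end * (x[0] - t.x_min) * (x[0] - t.x_min);
    grad[0] += 2.0 * t.k_end * (x[0] - t.x_min);
  }
  if (x[0] > t.x_max) {
    u += t.k_end * (x[0] - t.x_max) * (x[0] - t.x_max);
    grad[0] += 2.0 * t.k_end * (x[0] - t.x_max);
  }
  return u;
}

// Path CVs over point milestones (no alignment): d_i^2 = |x - node_i|^2.
// Returns S, Z and their gradients; log-sum-exp for numerical stability.
static void path_cv_grad(const NumericMatrix &nodes, double lambda,
                         const std::vector<double> &x, double &S, double &Z,
                         std::vector<double> &gS, std::vector<double> &gZ) {
  const int P = nodes.nrow(), dim = nodes.ncol();
  std::vector<double> d2(P);
  double amax = -1e300;
  for (int i = 0; i < P; ++i) {
    double s = 0.0;
    for (int d = 0; d < dim; ++d) {
      double dd = x[d] - nodes(i, d);
      s += dd * dd;
    }
    d2[i] = s;
    double a = -lambda * s;
    if (a > amax) amax = a;
  }
  double sw = 0.0, siw = 0.0;
  std::vector<double> w(P);
  for (int i = 0; i < P; ++i) {
    w[i] = std::exp(-lambda * d2[i] - amax);
    sw += w[i];
    siw += (i + 1.0) * w[i];
  }
  S = siw / sw;
  Z = -(amax + std::log(sw)) / lambda;
  // dS/dx_d = -lambda * sum_i (i+1 - S) * (w_i/sw) * dd2_i/dx_d
  // dZ/dx_d = sum_i (w_i/sw) * dd2_i/dx_d
  for (int d = 0; d < dim; ++d) { gS[d] = 0.0; gZ[d] = 0.0; }
  for (int i = 0; i < P; ++i) {
    double wi = w[i] / sw;
    for (int d = 0; d < dim; ++d) {
      double dd2 = 2.0 * (x[d] - nodes(i, d));
      gS[d] += -lambda * ((i + 1.0) - S) * wi * dd2;
      gZ[d] += wi * dd2;
    }
  }
}

// [[Rcpp::export(name = ".abmd_core")]]
List abmd_core(List toy, NumericVector x0, double dt, double max_time,
               double mass, double friction, double kbt,
               std::string cv_type,        // "proj" or "path"
               NumericVector proj_axis,    // unit axis for "proj"
               NumericMatrix path_nodes,   // P x dim for "path"
               double lambda,
               double ratchet_k, double cv_target, bool bias_enabled,
               double wall_z0, double wall_k,  // Z upper wall ("path" only)
               std::string stop_type,      // "cv_ge", "x_ge", "none"
               double stop_value,
               int record_stride) {
  Toy t;
  t.dim = as<int>(toy["dim"]);
  DataFrame g = as<DataFrame>(toy["gauss"]);
  NumericVector gc = g["centre"], gh = g["height"], gw = g["width"];
  t.gc.assign(gc.begin(), gc.end());
  t.gh.assign(gh.begin(), gh.end());
  t.gw.assign(gw.begin(), gw.end());
  t.k_perp = as<double>(toy["k_perp"]);
  t.k_end = as<double>(toy["k_end"]);
  t.x_min = as<double>(toy["x_min"]);
  t.x_max = as<double>(toy["x_max"]);
  const int dim = t.dim;
  if (ratchet_k < 0) stop("ratchet force constant must be non-negative");

  std::vector<double> x(x0.begin(), x0.end()), v(dim, 0.0);
  std::vector<double> grad(dim), gS(dim), gZ(dim), bias_grad(dim);

  RNGScope scope;
  const double c1 = std::exp(-friction * dt);
  const double c2 = std::sqrt((1.0 - c1 * c1) * kbt * ENERGY_TO_MD / mass);
  // initial velocities from Maxwell-Boltzmann
  for (int d = 0; d < dim; ++d)
    v[d] = std::sqrt(kbt * ENERGY_TO_MD / mass) * norm_rand();

  const long nsteps = (long)std::ceil(max_time / dt);
  long nrec = nsteps / record_stride + 2;
  NumericVector rec_t(nrec), rec_cv(nrec), rec_z(nrec), rec_bias(nrec),
      rec_rhom(nrec);
  NumericMatrix rec_x(nrec, dim);

  double rho_m = -1.0; // initialised from the first CV evaluation
  double S = 0.0, Z = 0.0, cv = 0.0;

  // evaluate CV, ratchet bias energy and total bias gradient at x
  auto eval_cv_bias = [&](double &bias_energy) {
    std::fill(bias_grad.begin(), bias_grad.end(), 0.0);
    bias_energy = 0.0;
    if (cv_type == "path") {
      path_cv_grad(path_nodes, lambda, x, S, Z, gS, gZ);
      cv = S;
      if (wall_k > 0 && Z > wall_z0) { // PLUMED convention: k (z-z0)^2
        bias_energy += wall_k * (Z - wall_z0) * (Z - wall_z0);
        for (int d = 0; d < dim; ++d)
          bias_grad[d] += 2.0 * wall_k * (Z - wall_z0) * gZ[d];
      }
    } else {
      cv = 0.0;
      for (int d = 0; d < dim; ++d) cv += x[d] * proj_axis[d];
      for (int d = 0; d < dim; ++d) gS[d] = proj_axis[d];
      Z = 0.0;
    }
    double rho = (cv - cv_target) * (cv - cv_target);
    if (rho_m < 0) rho_m = rho; // bias off at t = 0
    double ubias = 0.0;
    if (bias_enabled && rho > rho_m) {
      ubias = 0.5 * ratchet_k * (rho - rho_m) * (rho - rho_m);
      double dudrho = ratchet_k * (rho - rho_m);
      double dudcv = dudrho * 2.0 * (cv - cv_target);
      for (int d = 0; d < dim; ++d) bias_grad[d] += dudcv * gS[d];
    }
    bias_energy += ubias;
    if (rho < rho_m) rho_m = rho; // update after computing the bias
    return ubias;
  };

  double bias_e = 0.0;
  eval_cv_bias(bias_e);
  toy_energy_grad(t, x, grad);
  std::vector<double> force(dim);
  for (int d = 0; d < dim; ++d) force[d] = -(grad[d] + bias_grad[d]);

  bool event = false;
  double t_event = NA_REAL;
  long irec = 0;
  rec_t[irec] = 0.0; rec_cv[irec] = cv; rec_z[irec] = Z;
  rec_bias[irec] = bias_e; rec_rhom[irec] = rho_m;
  for (int d = 0; d < dim; ++d) rec_x(irec, d) = x[d];
  ++irec;

  auto stopped = [&]() {
    if (stop_type == "cv_ge") return cv >= stop_value;
    if (stop_type == "x_ge") return x[0] >= stop_value;
    return false;
  };
  if (stopped()) { event = true; t_event = 0.0; }

  long step = 0;
  while (!event && step < nsteps) {
    ++step;
    // BAOAB
    for (int d = 0; d < dim; ++d) {
      v[d] += 0.5 * dt * force[d] * ENERGY_TO_MD / mass;
      x[d] += 0.5 * dt * v[d];
    }
    for (int d = 0; d < dim; ++d) v[d] = c1 * v[d] + c2 * norm_rand();
    for (int d = 0; d < dim; ++d) x[d] += 0.5 * dt * v[d];
    double u = toy_energy_grad(t, x, grad);
    eval_cv_bias(bias_e);
    for (int d = 0; d < dim; ++d) {
      force[d] = -(grad[d] + bias_grad[d]);
      v[d] += 0.5 * dt * force[d] * ENERGY_TO_MD / mass;
    }
    if (!std::isfinite(u) || !std::isfinite(x[0]))
      stop("divergent energies at t = %f ps", step * dt);
    if (step % record_stride == 0 || step == nsteps) {
      rec_t[irec] = step * dt; rec_cv[irec] = cv; rec_z[irec] = Z;
      rec_bias[irec] = bias_e; rec_rhom[irec] = rho_m;
      for (int d = 0; d < dim; ++d) rec_x(irec, d) = x[d];
      ++irec;
    }
    if (stopped()) { event = true; t_event = step * dt; }
  }

  if (event && (step % record_stride != 0)) {
    rec_t[irec] = step * dt; rec_cv[irec] = cv; rec_z[irec] = Z;
    rec_bias[irec] = bias_e; rec_rhom[irec] = rho_m;
    for (int d = 0; d < dim; ++d) rec_x(irec, d) = x[d];
    ++irec;
  }

  IntegerVector keep = seq(0, (int)irec - 1);
  return List::create(
      _["event"] = event,
      _["time"] = event ? t_event : max_time,
      _["censored"] = !event,
      _["t"] = rec_t[keep], _["cv"] = rec_cv[keep], _["z"] = rec_z[keep],
      _["bias"] = rec_bias[keep], _["rho_m"] = rec_rhom[keep],
      _["coords"] = rec_x(Range(0, (int)irec - 1), _),
      _["n_steps"] = (double)step);
}
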