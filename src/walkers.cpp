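// Monte-Carlo cores for the standard and extended Boltzmann Walker.
//
// All randomness comes from R's own generator (unif_rand / exp_rand), so a
// set.seed() call on the R side makes every simulation reproducible.

#include <Rcpp.h>
#include <cmath>
#include <vector>

using namespace Rcpp;

namespace {

const double TWOPI = 2.0 * M_PI;

inline double wrap_pi(double a) {
  a = a - TWOPI * std::floor((a + M_PI) / TWOPI);
  if (a <= -M_PI) a = M_PI;
  return a;
}

// exact inverse-CDF draw from the elliptical phase function
// f(a) = sqrt(1-e^2) / (2 pi (1 - e cos a)),  e = 2 g / (1 + g^2)
inline double draw_elliptical(double g) {
  if (g <= 0.0) return M_PI * (2.0 * unif_rand() - 1.0);
  const double e = 2.0 * g / (1.0 + g * g);
  const double r = unif_rand();
  const double t = std::tan(M_PI * (r - 0.5));
  return 2.0 * std::atan(std::sqrt((1.0 - e) / (1.0 + e)) * t);
}

// distance along unit direction (ux, uy) from (x, y) to the circle of
// radius R centred at the origin; +Inf when the ray stays inside
inline double exit_distance(double x, double y, double ux, double uy,
                            double R) {
  const double b = x * ux + y * uy;
  const double c = x * x + y * y - R * R;
  const double disc = b * b - c;
  if (disc < 0.0) return R_PosInf;
  const double s = -b + std::sqrt(disc);
  return s > 0.0 ? s : R_PosInf;
}

// half-open heading sector, width 2*pi/S, sector 0 centred on `offset`
// (reduction via floor, not fmod, to avoid glibc >= 2.38 symbol versions)
inline int sector_index(double theta, int S, double offset) {
  const double w = TWOPI / S;
  double z = theta - offset + 0.5 * w;
  double phi = z - TWOPI * std::floor(z / TWOPI);
  int s = static_cast<int>(std::floor(phi / w));
  return s >= S ? s - S : (s < 0 ? 0 : s);
}

// inverse-interpolated draw from a discretised empirical CDF: lowest grid
// abscissa with F >= r, then linear interpolation with the previous one
inline double draw_ecdf(const double *a, const double *F, int m) {
  const double r = unif_rand();
  int lo = 0, hi = m - 1;
  if (r <= F[0]) return a[0];
  while (hi - lo > 1) {
    const int mid = (lo + hi) / 2;
    if (F[mid] >= r) hi = mid; else lo = mid;
  }
  return a[lo] + (r - F[lo]) / (F[hi] - F[lo]) * (a[hi] - a[lo]);
}

}  // namespace

// one standard BW trajectory of turning points: free paths ~ Exp(lambda),
// deviations ~ elliptical(g), constant speed v; stops at the first exit
// from the radius-R circle (R <= 0 or Inf disables the boundary) or after
// max_events events
// [[Rcpp::export]]
List cpp_simulate_bw(double v, double lambda, double g, double R,
                     int max_events) {
  if (v <= 0 || lambda <= 0) stop("v and lambda must be > 0");
  if (g < 0 || g >= 1) stop("g must be in [0, 1)");
  const bool bounded = std::isfinite(R) && R > 0;
  std::vector<double> xs{0.0}, ys{0.0};
  double x = 0.0, y = 0.0;
  double theta = M_PI * (2.0 * unif_rand() - 1.0);
  std::vector<double> headings;
  bool exited = false, capped = false;
  double cumlen = 0.0;
  std::vector<double> ts{0.0};
  for (int k = 0; k < max_events; ++k) {
    const double l = lambda * exp_rand();
    const double ux = -std::sin(theta), uy = std::cos(theta);
    headings.push_back(theta);
    if (bounded) {
      const double s = exit_distance(x, y, ux, uy, R);
      if (s <= l) {
        x += s * ux; y += s * uy; cumlen += s;
        xs.push_back(x); ys.push_back(y); ts.push_back(cumlen / v);
        exited = true;
        break;
      }
    }
    x += l * ux; y += l * uy; cumlen += l;
    xs.push_back(x); ys.push_back(y); ts.push_back(cumlen / v);
    theta = wrap_pi(theta + draw_elliptical(g));
  }
  if (!exited && bounded) capped = true;
  return List::create(
      _["x"] = xs, _["y"] = ys, _["t"] = ts, _["headings"] = headings,
      _["exited"] = exited, _["capped"] = capped,
      _["exit_heading"] = exited ? std::atan2(-x / std::sqrt(x * x + y * y),
                                              y / std::sqrt(x * x + y * y))
                                 : NA_REAL);
}

// mean square displacement after 1..n_events reorientation-free steps,
// averaged over n_walkers independent standard BWs (no boundary)
// [[Rcpp::export]]
NumericVector cpp_bw_msd_events(double lambda, double g, int n_walkers,
                                int n_events) {
  NumericVector msd(n_events);
  for (int w = 0; w < n_walkers; ++w) {
    double x = 0.0, y = 0.0;
    double theta = M_PI * (2.0 * unif_rand() - 1.0);
    for (int k = 0; k < n_events; ++k) {
      const double l = lambda * exp_rand();
      x += -l * std::sin(theta); y += l * std::cos(theta);
      msd[k] += x * x + y * y;
      theta = wrap_pi(theta + draw_elliptical(g));
    }
  }
  for (int k = 0; k < n_events; ++k) msd[k] /= n_walkers;
  return msd;
}

// mean square displacement at prescribed times (positions interpolated
// within free paths), averaged over n_walkers standard BWs
// [[Rcpp::export]]
NumericVector cpp_bw_msd_times(double v, double lambda, double g,
                               int n_walkers, NumericVector times) {
  const int nt = times.size();
  const double tmax = max(times);
  NumericVector msd(nt);
  for (int w = 0; w < n_walkers; ++w) {
    double x = 0.0, y = 0.0, t = 0.0;
    double theta = M_PI * (2.0 * unif_rand() - 1.0);
    int j = 0;
    while (t <= tmax && j < nt) {
      const double l = lambda * exp_rand();
      const double dt = l / v;
      const double ux = -std::sin(theta), uy = std::cos(theta);
      while (j < nt && times[j] <= t + dt) {
        const double s = (times[j] - t) * v;
        const double px = x + s * ux, py = y + s * uy;
        msd[j] += px * px + py * py;
        ++j;
      }
      x += l * ux; y += l * uy; t += dt;
      theta = wrap_pi(theta + draw_elliptical(g));
    }
  }
  for (int k = 0; k < nt; ++k) msd[k] /= n_walkers;
  return msd;
}

// one extended BW trajectory: per-sector ECDF draws for free-path length
// and deviation, sector chosen from the current heading; stops at the first
// exit from the radius-R circle or after max_events events
// [[Rcpp::export]]
List cpp_simulate_ext_bw(NumericMatrix len_a, NumericMatrix len_F,
                         NumericMatrix dev_a, NumericMatrix dev_F,
                         NumericVector speeds, double sector_offset,
                         double R, int max_events) {
  // one sector per column (column-major contiguity)
  const int S = len_a.ncol();
  const int mL = len_a.nrow(), mD = dev_a.nrow();
  const bool bounded = std::isfinite(R) && R > 0;
  std::vector<double> xs{0.0}, ys{0.0}, ts{0.0}, headings;
  double x = 0.0, y = 0.0, tcum = 0.0;
  double theta = M_PI * (2.0 * unif_rand() - 1.0);
  bool exited = false;
  for (int k = 0; k < max_events; ++k) {
    const int s = sector_index(theta, S, sector_offset);
    const double l = draw_ecdf(&len_a(0, s), &len_F(0, s), mL);
    const double ux = -std::sin(theta), uy = std::cos(theta);
    headings.push_back(theta);
    const double vs = speeds[s];
    if (bounded) {
      const double d = exit_distance(x, y, ux, uy, R);
      if (d <= l) {
        x += d * ux; y += d * uy; tcum += d / vs;
        xs.push_back(x); ys.push_back(y); ts.push_back(tcum);
        exited = true;
        break;
      }
    }
    x += l * ux; y += l * uy; tcum += l / vs;
    xs.push_back(x); ys.push_back(y); ts.push_back(tcum);
    theta = wrap_pi(theta + draw_ecdf(&dev_a(0, s), &dev_F(0, s), mD));
  }
  return List::create(
      _["x"] = xs, _["y"] = ys, _["t"] = ts, _["headings"] = headings,
      _["exited"] = exited, _["capped"] = (!exited && bounded),
      _["exit_heading"] = exited ? std::atan2(-x / std::sqrt(x * x + y * y),
                                              y / std::sqrt(x * x + y * y))
                                 : NA_REAL);
}

// exit headings (angle of the exact circle-crossing point, package heading
// convention) of n independent extended BW walkers started at the centre
// [[Rcpp::export]]
NumericVector cpp_ext_exit_headings(int n, NumericMatrix len_a,
                                    NumericMatrix len_F, NumericMatrix dev_a,
                                    NumericMatrix dev_F,
                                    double sector_offset, double R,
                                    int max_events) {
  // one sector per column (column-major contiguity)
  const int S = len_a.ncol();
  const int mL = len_a.nrow(), mD = dev_a.nrow();
  NumericVector out(n);
  for (int w = 0; w < n; ++w) {
    double x = 0.0, y = 0.0;
    double theta = M_PI * (2.0 * unif_rand() - 1.0);
    double h = NA_REAL;
    for (int k = 0; k < max_events; ++k) {
      const int s = sector_index(theta, S, sector_offset);
      const double l = draw_ecdf(&len_a(0, s), &len_F(0, s), mL);
      const double ux = -std::sin(theta), uy = std::cos(theta);
      const double d = exit_distance(x, y, ux, uy, R);
      if (d <= l) {
        x += d * ux; y += d * uy;
        h = std::atan2(-x / R, y / R);
        break;
      }
      x += l * ux; y += l * uy;
      theta = wrap_pi(theta + draw_ecdf(&dev_a(0, s), &dev_F(0, s), mD));
    }
    out[w] = h;
  }
  return out;
}

// exit headings of n standard BW walkers (used for isotropy checks)
// [[Rcpp::export]]
NumericVector cpp_bw_exit_headings(int n, double lambda, double g, double R,
                                   int max_events) {
  NumericVector out(n);
  for (int w = 0; w < n; ++w) {
    double x = 0.0, y = 0.0;
    double theta = M_PI * (2.0 * unif_rand() - 1.0);
    double h = NA_REAL;
    for (int k = 0; k < max_events; ++k) {
      const double l = lambda * exp_rand();
      const double ux = -std::sin(theta), uy = std::cos(theta);
      const double d = exit_distance(x, y, ux, uy, R);
      if (d <= l) {
        x += d * ux; y += d * uy;
        h = std::atan2(-x / R, y / R);
        break;
      }
      x += l * ux; y += l * uy;
      theta = wrap_pi(theta + draw_elliptical(g));
    }
    out[w] = h;
  }
  return out;
}
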