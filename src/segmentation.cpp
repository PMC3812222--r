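// Bottom-up piecewise-linear segmentation of a 2-D point series.
//
// Start from the finest partition (every pair of consecutive points is a
// segment), then greedily apply the merge -- either a pair merge (two
// adjacent segments -> one) or a triple merge (three adjacent segments ->
// two, split at the interior point minimising error) -- whose resulting
// maximum point-to-axis error is smallest, until no merge keeps that error
// within the accepted criterion eps. Each candidate is scored by refitting
// the merged point set: the fitted segment is the principal axis of the
// point cloud through its centroid, and the error is the largest
// perpendicular distance of a member point to that (infinite) axis line.

#include <Rcpp.h>
#include <queue>
#include <tuple>
#include <vector>

using namespace Rcpp;

namespace {

struct FitScratch {
  const double *x;
  const double *y;
  int n;
};

// max perpendicular distance of points a..b (inclusive) to the principal
// axis of their covariance through the centroid; ties between eigenvalues
// break toward the chord from point a to point b
double fit_error(const FitScratch &P, int a, int b) {
  const int m = b - a + 1;
  double mx = 0.0, my = 0.0;
  for (int i = a; i <= b; ++i) { mx += P.x[i]; my += P.y[i]; }
  mx /= m; my /= m;
  double sxx = 0.0, syy = 0.0, sxy = 0.0;
  for (int i = a; i <= b; ++i) {
    const double dx = P.x[i] - mx, dy = P.y[i] - my;
    sxx += dx * dx; syy += dy * dy; sxy += dx * dy;
  }
  double ux, uy;
  const double tr = sxx + syy;
  if (tr <= 0.0) return 0.0;  // all points identical: zero error by convention
  if (std::fabs(sxx - syy) + 2.0 * std::fabs(sxy) < 1e-14 * tr) {
    // isotropic cloud: use the chord direction
    ux = P.x[b] - P.x[a]; uy = P.y[b] - P.y[a];
    const double nrm = std::sqrt(ux * ux + uy * uy);
    if (nrm <= 0.0) { ux = 1.0; uy = 0.0; } else { ux /= nrm; uy /= nrm; }
  } else {
    const double th = 0.5 * std::atan2(2.0 * sxy, sxx - syy);
    ux = std::cos(th); uy = std::sin(th);
  }
  double err = 0.0;
  for (int i = a; i <= b; ++i) {
    const double d = std::fabs(ux * (P.y[i] - my) - uy * (P.x[i] - mx));
    if (d > err) err = d;
  }
  return err;
}

// best split of points a..b into two fitted segments sharing interior point
// j (a < j < b); returns the minimal max-error and the argmin j
double best_split(const FitScratch &P, int a, int b, int &bestj) {
  double best = R_PosInf;
  bestj = a + 1;
  for (int j = a + 1; j <= b - 1; ++j) {
    const double e1 = fit_error(P, a, j);
    if (e1 >= best) continue;  // max(e1, e2) >= e1
    const double e2 = fit_error(P, j, b);
    const double e = e1 > e2 ? e1 : e2;
    if (e < best) { best = e; bestj = j; }
  }
  return best;
}

// candidate in the merge queue; type 0 = pair (remove boundary k1),
// type 1 = triple (remove boundaries k1 and k2, insert the recorded split)
struct Cand {
  double cost;
  int type;
  int k1, k2;
  int splitj;
  long ver;
};
struct CandCmp {
  bool operator()(const Cand &a, const Cand &b) const {
    if (a.cost != b.cost) return a.cost > b.cost;
    if (a.type != b.type) return a.type > b.type;  // prefer pair merges
    return a.k1 > b.k1;                            // then lowest index
  }
};

}  // namespace

// [[Rcpp::export]]
IntegerVector cpp_segment_bottom_up(NumericVector x, NumericVector y,
                                    double eps) {
  const int n = x.size();
  if (n < 3) stop("need at least 3 points");
  if (eps <= 0) stop("epsilon must be > 0");
  FitScratch P{REAL(x), REAL(y), n};

  std::vector<int> nxt(n), prv(n);
  std::vector<char> active(n, 1);
  std::vector<long> ver(n, 0);
  for (int i = 0; i < n; ++i) { nxt[i] = i + 1; prv[i] = i - 1; }
  nxt[n - 1] = -1;

  std::priority_queue<Cand, std::vector<Cand>, CandCmp> pq;

  auto interior = [&](int k) { return k > 0 && k < n - 1 && active[k]; };

  auto push_pair = [&](int k) {
    if (!interior(k)) return;
    const int p = prv[k], q = nxt[k];
    pq.push(Cand{fit_error(P, p, q), 0, k, -1, -1, ver[k]});
  };
  auto push_triple = [&](int k1) {
    if (!interior(k1)) return;
    const int k2 = nxt[k1];
    if (!interior(k2)) return;
    const int p = prv[k1], q = nxt[k2];
    int j;
    const double c = best_split(P, p, q, j);
    pq.push(Cand{c, 1, k1, k2, j, ver[k1] + ver[k2]});
  };

  for (int k = 1; k < n - 1; ++k) push_pair(k);
  for (int k = 1; k < n - 2; ++k) push_triple(k);

  while (!pq.empty()) {
    Cand c = pq.top(); pq.pop();
    if (c.type == 0) {
      if (!interior(c.k1) || ver[c.k1] != c.ver) continue;
    } else {
      if (!interior(c.k1) || !active[c.k2] || nxt[c.k1] != c.k2 ||
          !interior(c.k2) || ver[c.k1] + ver[c.k2] != c.ver)
        continue;
    }
    if (c.cost > eps) break;

    if (c.type == 0) {
      const int k = c.k1, p = prv[k], q = nxt[k];
      active[k] = 0;
      nxt[p] = q; prv[q] = p;
      ++ver[p]; ++ver[q];
      // refresh candidates touching the new segment [p, q]
      push_pair(p); push_pair(q);
      if (p > 0) { push_triple(prv[p]); }
      push_triple(p);
      push_triple(q);
    } else {
      const int k1 = c.k1, k2 = c.k2, p = prv[k1], q = nxt[k2];
      const int j = c.splitj;
      active[k1] = 0; active[k2] = 0;
      active[j] = 1;
      nxt[p] = j; prv[j] = p; nxt[j] = q; prv[q] = j;
      ++ver[p]; ++ver[j]; ++ver[q];
      // refresh candidates touching the new segments [p, j] and [j, q]
      push_pair(p); push_pair(j); push_pair(q);
      if (p > 0) { push_triple(prv[p]); }
      push_triple(p);
      push_triple(j);
      push_triple(q);
    }
  }

  std::vector<int> out;
  for (int k = 0; k != -1; k = nxt[k]) out.push_back(k + 1);  // 1-based
  return wrap(out);
}
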