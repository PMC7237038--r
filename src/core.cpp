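#include <Rcpp.h>
#include <vector>
#include <algorithm>
#include <cmath>
using namespace Rcpp;

// Pili force kernel: sigmoidal, repulsive below contact (D < 2R),
// saturating to 1/m at long range.
static inline double kernelK(double D, double R, double k1, double k2,
                             double m) {
  return (1.0 + k1 * (std::tanh(k2 * (D - 2.0 * R)) - 1.0)) / m;
}

// Exact binned neighbour search: for every cell, the ascending indices of
// all other cells within centre-to-centre distance ell (inclusive).
static void build_neighbour_lists(const std::vector<double>& x,
                                  const std::vector<double>& y,
                                  double ell,
                                  std::vector<std::vector<int> >& nbr) {
  const int n = (int)x.size();
  for (int i = 0; i < n; ++i) nbr[i].clear();
  if (n < 2) return;
  double xmin = x[0], xmax = x[0], ymin = y[0], ymax = y[0];
  for (int i = 1; i < n; ++i) {
    if (x[i] < xmin) xmin = x[i];
    if (x[i] > xmax) xmax = x[i];
    if (y[i] < ymin) ymin = y[i];
    if (y[i] > ymax) ymax = y[i];
  }
  const double w = ell;
  const int nx = (int)std::floor((xmax - xmin) / w) + 1;
  const int ny = (int)std::floor((ymax - ymin) / w) + 1;
  std::vector<std::vector<int> > bins((size_t)nx * ny);
  std::vector<int> bx(n), by(n);
  for (int i = 0; i < n; ++i) {
    int cx = (int)std::floor((x[i] - xmin) / w);
    int cy = (int)std::floor((y[i] - ymin) / w);
    if (cx >= nx) cx = nx - 1;
    if (cy >= ny) cy = ny - 1;
    bx[i] = cx; by[i] = cy;
    bins[(size_t)cy * nx + cx].push_back(i);
  }
  const double ell2 = ell * ell;
  for (int i = 0; i < n; ++i) {
    for (int dy = -1; dy <= 1; ++dy) {
      int cy = by[i] + dy;
      if (cy < 0 || cy >= ny) continue;
      for (int dx = -1; dx <= 1; ++dx) {
        int cx = bx[i] + dx;
        if (cx < 0 || cx >= nx) continue;
        const std::vector<int>& b = bins[(size_t)cy * nx + cx];
        for (size_t k = 0; k < b.size(); ++k) {
          int j = b[k];
          if (j == i) continue;
          double ddx = x[j] - x[i], ddy = y[j] - y[i];
          if (ddx * ddx + ddy * ddy <= ell2) nbr[i].push_back(j);
        }
      }
    }
    std::sort(nbr[i].begin(), nbr[i].end());
  }
}

// [[Rcpp::export]]
List neighbour_lists_cpp(NumericMatrix positions, double ell) {
  const int n = positions.nrow();
  std::vector<double> x(n), y(n);
  for (int i = 0; i < n; ++i) { x[i] = positions(i, 0); y[i] = positions(i, 1); }
  std::vector<std::vector<int> > nbr(n);
  build_neighbour_lists(x, y, ell, nbr);
  List out(n);
  for (int i = 0; i < n; ++i) {
    IntegerVector v(nbr[i].size());
    for (size_t k = 0; k < nbr[i].size(); ++k) v[k] = nbr[i][k] + 1;
    out[i] = v;
  }
  return out;
}

// Choose min(m, n) targets uniformly without replacement from the sorted
// neighbour list of one puller, via partial Fisher-Yates. Consumes one
// uniform draw per selection only when n > m (all neighbours are taken,
// draw-free, otherwise). This draw discipline is mirrored exactly by the
// R reference step.
static void choose_targets(const std::vector<int>& nb, int m,
                           std::vector<int>& work, std::vector<int>& chosen) {
  const int n = (int)nb.size();
  chosen.clear();
  if (n == 0) return;
  if (n <= m) { chosen = nb; return; }
  work = nb;
  for (int t = 0; t < m; ++t) {
    int r = t + (int)(unif_rand() * (n - t));
    if (r >= n) r = n - 1;
    std::swap(work[t], work[r]);
    chosen.push_back(work[t]);
  }
}

// [[Rcpp::export]]
List sample_attachments_cpp(NumericMatrix positions, double ell, int m) {
  RNGScope scope;
  const int n = positions.nrow();
  std::vector<double> x(n), y(n);
  for (int i = 0; i < n; ++i) { x[i] = positions(i, 0); y[i] = positions(i, 1); }
  std::vector<std::vector<int> > nbr(n);
  build_neighbour_lists(x, y, ell, nbr);
  std::vector<int> puller, target, work, chosen;
  std::vector<double> dist, bear;
  for (int j = 0; j < n; ++j) {
    choose_targets(nbr[j], m, work, chosen);
    for (size_t k = 0; k < chosen.size(); ++k) {
      int i = chosen[k];
      double dx = x[j] - x[i], dy = y[j] - y[i];
      double D = std::sqrt(dx * dx + dy * dy);
      if (D <= 0.0) stop("degenerate geometry: coincident cells");
      puller.push_back(j + 1);
      target.push_back(i + 1);
      dist.push_back(D);
      double th = std::atan2(dy, dx);
      if (th < 0) th += 2.0 * M_PI;
      bear.push_back(th);
    }
  }
  return List::create(_["puller"] = wrap(puller), _["target"] = wrap(target),
                      _["distance"] = wrap(dist), _["bearing"] = wrap(bear));
}

// Full update loop for one colony. Per step, in documented draw order:
//   (1) per cell i (ascending): u_branch, u_angle -> heading, propulsion G_i
//   (2) per cell j (ascending): attachment selection draws -> forces F on
//       the chosen targets (positions read at time t only)
//   (3) X_i <- X_i + (G_i + F_i) * S(r,c) / (gamma0 * s0), S read at the
//       lattice point nearest the time-t position; zero motion where S = 0
//   (4) all positions commit in parallel
//   (5) every cell deposits s_rate (capped at s_max) at the lattice point
//       nearest its new position (old position when deposit_premove).
// [[Rcpp::export]]
List simulate_colony_cpp(NumericMatrix positions0, IntegerVector cell_class,
                         List class_cump, List class_theta,
                         NumericMatrix slime0, NumericVector grid_origin,
                         double grid_spacing, List par, int n_steps,
                         IntegerVector record_steps,
                         IntegerVector record_cells,
                         bool deposit_premove, bool reciprocal) {
  RNGScope scope;
  const int n = positions0.nrow();
  const double R = as<double>(par["radius"]);
  const double ell = as<double>(par["ell"]);
  const int m = as<int>(par["m"]);
  const double k1 = as<double>(par["k1"]);
  const double k2 = as<double>(par["k2"]);
  const double gamma0 = as<double>(par["gamma0"]);
  const double f0 = as<double>(par["f0"]);
  const double s_rate = as<double>(par["s_rate"]);
  const double s0 = as<double>(par["s0"]);
  const double s_max = as<double>(par["s_max"]);

  NumericMatrix slime = clone(slime0);
  const int nr = slime.nrow(), nc = slime.ncol();
  const double ox = grid_origin[0], oy = grid_origin[1];

  const int n_class = class_cump.size();
  std::vector<std::vector<double> > cump(n_class), ctheta(n_class);
  for (int c = 0; c < n_class; ++c) {
    cump[c] = as<std::vector<double> >(class_cump[c]);
    ctheta[c] = as<std::vector<double> >(class_theta[c]);
  }

  std::vector<double> x(n), y(n), xn(n), yn(n), Gx(n), Gy(n), Fx(n), Fy(n);
  for (int i = 0; i < n; ++i) { x[i] = positions0(i, 0); y[i] = positions0(i, 1); }

  const int n_rec = record_steps.size();
  const int n_rc = record_cells.size();
  NumericVector traj((R_xlen_t)n_rec * n_rc * 2);
  traj.attr("dim") = IntegerVector::create(n_rec, n_rc, 2);
  int rec_idx = 0;
  std::vector<std::vector<int> > nbr(n);
  std::vector<int> work, chosen;

  // nearest lattice indices (0-based); ties round toward +Inf
  #define GRID_RC(px, py, rr, cc)                                     \
    do {                                                              \
      cc = (int)std::floor((px - ox) / grid_spacing + 0.5);           \
      rr = (int)std::floor((py - oy) / grid_spacing + 0.5);           \
      if (rr < 0 || rr >= nr || cc < 0 || cc >= nc)                   \
        stop("cell left the slime lattice at step %d", t);            \
    } while (0)

  int t = 0;
  if (rec_idx < n_rec && record_steps[rec_idx] == 0) {
    for (int k = 0; k < n_rc; ++k) {
      int i = record_cells[k] - 1;
      traj[(R_xlen_t)0 + (R_xlen_t)n_rec * k] = x[i];
      traj[(R_xlen_t)0 + (R_xlen_t)n_rec * k + (R_xlen_t)n_rec * n_rc] = y[i];
    }
    ++rec_idx;
  }

  for (t = 1; t <= n_steps; ++t) {
    // (1) headings and propulsion
    for (int i = 0; i < n; ++i) {
      double u1 = unif_rand();
      double u2 = unif_rand();
      const std::vector<double>& cp = cump[cell_class[i] - 1];
      const std::vector<double>& th = ctheta[cell_class[i] - 1];
      double heading;
      int branch = -1;
      for (size_t k = 0; k < cp.size(); ++k)
        if (u1 < cp[k]) { branch = (int)k; break; }
      if (branch >= 0) heading = th[branch];
      else heading = 2.0 * M_PI * u2;
      Gx[i] = f0 * std::cos(heading);
      Gy[i] = f0 * std::sin(heading);
      Fx[i] = 0.0;
      Fy[i] = 0.0;
    }
    // (2) attachments and pili forces
    build_neighbour_lists(x, y, ell, nbr);
    for (int j = 0; j < n; ++j) {
      choose_targets(nbr[j], m, work, chosen);
      for (size_t k = 0; k < chosen.size(); ++k) {
        int i = chosen[k];
        double dx = x[j] - x[i], dy = y[j] - y[i];
        double D = std::sqrt(dx * dx + dy * dy);
        if (D <= 0.0) stop("degenerate geometry: coincident cells");
        double K = kernelK(D, R, k1, k2, (double)m);
        double fx = K * dx / D, fy = K * dy / D;
        Fx[i] += fx; Fy[i] += fy;
        if (reciprocal) { Fx[j] -= fx; Fy[j] -= fy; }
      }
    }
    // (3) overdamped move using slime at the time-t position
    for (int i = 0; i < n; ++i) {
      int rr, cc;
      GRID_RC(x[i], y[i], rr, cc);
      double S = slime(rr, cc);
      double mob = S / (gamma0 * s0);  // 1/gamma; 0 on bare substrate
      xn[i] = x[i] + (Gx[i] + Fx[i]) * mob;
      yn[i] = y[i] + (Gy[i] + Fy[i]) * mob;
      if (!std::isfinite(xn[i]) || !std::isfinite(yn[i]))
        stop("non-finite position at step %d", t);
    }
    // (5) deposition (pre-move variant uses the old positions)
    if (deposit_premove) {
      for (int i = 0; i < n; ++i) {
        int rr, cc;
        GRID_RC(x[i], y[i], rr, cc);
        double S = slime(rr, cc) + s_rate;
        slime(rr, cc) = S > s_max ? s_max : S;
      }
    }
    // (4) parallel commit
    for (int i = 0; i < n; ++i) { x[i] = xn[i]; y[i] = yn[i]; }
    if (!deposit_premove) {
      for (int i = 0; i < n; ++i) {
        int rr, cc;
        GRID_RC(x[i], y[i], rr, cc);
        double S = slime(rr, cc) + s_rate;
        slime(rr, cc) = S > s_max ? s_max : S;
      }
    }
    if (rec_idx < n_rec && record_steps[rec_idx] == t) {
      for (int k = 0; k < n_rc; ++k) {
        int i = record_cells[k] - 1;
        traj[(R_xlen_t)rec_idx + (R_xlen_t)n_rec * k] = x[i];
        traj[(R_xlen_t)rec_idx + (R_xlen_t)n_rec * k +
             (R_xlen_t)n_rec * n_rc] = y[i];
      }
      ++rec_idx;
    }
  }
  #undef GRID_RC

  NumericMatrix final_pos(n, 2);
  for (int i = 0; i < n; ++i) { final_pos(i, 0) = x[i]; final_pos(i, 1) = y[i]; }
  return List::create(_["traj"] = traj, _["final_positions"] = final_pos,
                      _["slime"] = slime);
}
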