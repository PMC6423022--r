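#include <Rcpp.h>
#include <cmath>
#include <vector>
using namespace Rcpp;

// Substrate as a single-valued height field z = f(x, y), periodic in x and y.
// Three kinds share one evaluator:
//   0  flat            f == 0
//   1  gaussian array  truncated Gaussians of signed height H on a square
//                      lattice with spacing dp (one peak per dp x dp cell,
//                      profile zero outside the inscribed circle r > dp/2)
//   2  height field    bilinear interpolation of a gridded scan; gradients
//                      are central differences at the nodes, themselves
//                      bilinearly interpolated
struct Surf {
  int type;
  double Lx, Ly;
  // gaussian array
  double H, v, dp, R2;
  // height field
  int nx, ny;
  double dx, dy;
  NumericMatrix z, gx, gy;   // nx x ny, node (i,j) at (i*dx, j*dy)

  Surf(List s) : z(0, 0), gx(0, 0), gy(0, 0) {
    type = as<int>(s["type_code"]);
    Lx = as<double>(s["Lx"]);
    Ly = as<double>(s["Ly"]);
    H = v = dp = R2 = 0.0;
    nx = ny = 0; dx = dy = 1.0;
    if (type == 1) {
      H  = as<double>(s["H"]);
      v  = as<double>(s["v"]);
      dp = as<double>(s["dp"]);
      R2 = 0.25 * dp * dp;
    } else if (type == 2) {
      z  = as<NumericMatrix>(s["z"]);
      gx = as<NumericMatrix>(s["gx"]);
      gy = as<NumericMatrix>(s["gy"]);
      nx = z.nrow(); ny = z.ncol();
      dx = as<double>(s["dx"]);
      dy = as<double>(s["dy"]);
    }
  }

  inline double wrapx(double x) const {
    x -= Lx * std::floor(x / Lx);
    if (x >= Lx) x = 0.0;
    return x;
  }
  inline double wrapy(double y) const {
    y -= Ly * std::floor(y / Ly);
    if (y >= Ly) y = 0.0;
    return y;
  }

  inline void eval(double x, double y, double &h, double &fx, double &fy) const {
    if (type == 0) { h = 0.0; fx = 0.0; fy = 0.0; return; }
    x = wrapx(x); y = wrapy(y);
    if (type == 1) {
      // nearest peak is always the one of the point's own lattice cell:
      // the truncation circle is inscribed in the cell
      double cx = (std::floor(x / dp) + 0.5) * dp;
      double cy = (std::floor(y / dp) + 0.5) * dp;
      double ax = x - cx, ay = y - cy;
      double r2 = ax * ax + ay * ay;
      if (r2 <= R2) {
        double e = H * std::exp(-r2 / (2.0 * v));
        h = e;
        fx = -ax / v * e;
        fy = -ay / v * e;
      } else {
        h = 0.0; fx = 0.0; fy = 0.0;
      }
    } else {
      double u = x / dx, t = y / dy;
      int i0 = (int)std::floor(u), j0 = (int)std::floor(t);
      double fu = u - i0, ft = t - j0;
      i0 %= nx; j0 %= ny;
      if (i0 < 0) i0 += nx;
      if (j0 < 0) j0 += ny;
      int i1 = (i0 + 1) % nx, j1 = (j0 + 1) % ny;
      double w00 = (1 - fu) * (1 - ft), w10 = fu * (1 - ft);
      double w01 = (1 - fu) * ft,       w11 = fu * ft;
      h  = w00 * z(i0, j0)  + w10 * z(i1, j0)  + w01 * z(i0, j1)  + w11 * z(i1, j1);
      fx = w00 * gx(i0, j0) + w10 * gx(i1, j0) + w01 * gx(i0, j1) + w11 * gx(i1, j1);
      fy = w00 * gy(i0, j0) + w10 * gy(i1, j0) + w01 * gy(i0, j1) + w11 * gy(i1, j1);
    }
  }

  inline double wfun(double x, double y) const {
    double h, fx, fy;
    eval(x, y, h, fx, fy);
    return std::sqrt(1.0 + fx * fx + fy * fy);
  }
};

// Evaluate height, gradient and area-element weight at given points.
// [[Rcpp::export]]
NumericMatrix surf_eval_cpp(List surf_spec, NumericVector x, NumericVector y) {
  Surf s(surf_spec);
  int n = x.size();
  NumericMatrix out(n, 4);
  for (int k = 0; k < n; ++k) {
    double h, fx, fy;
    s.eval(x[k], y[k], h, fx, fy);
    out(k, 0) = h;
    out(k, 1) = fx;
    out(k, 2) = fy;
    out(k, 3) = std::sqrt(1.0 + fx * fx + fy * fy);
  }
  return out;
}

// Midpoint-rule integral of the area element w = sqrt(1 + |grad f|^2)
// over the periodic cell.
// [[Rcpp::export]]
double surface_area_cpp(List surf_spec, double resolution) {
  Surf s(surf_spec);
  int nx = (int)std::ceil(s.Lx / resolution);
  int ny = (int)std::ceil(s.Ly / resolution);
  if (nx < 1) nx = 1;
  if (ny < 1) ny = 1;
  double hx = s.Lx / nx, hy = s.Ly / ny;
  double acc = 0.0;
  for (int i = 0; i < nx; ++i) {
    double x = (i + 0.5) * hx;
    double row = 0.0;
    for (int j = 0; j < ny; ++j)
      row += s.wfun(x, (j + 0.5) * hy);
    acc += row;
  }
  return acc * hx * hy;
}

// Area-weighted uniform sampling of surface anchor points via rejection:
// lateral proposals uniform on the cell, accepted w.p. w/wmax, so accepted
// density is proportional to the true area element dA = w dx dy.
// Columns: x, y, z, nhat_x, nhat_y, nhat_z.  Consumes R's RNG stream.
// [[Rcpp::export]]
NumericMatrix sample_surface_cpp(List surf_spec, int n, double wmax) {
  Surf s(surf_spec);
  if (!R_finite(wmax) || wmax <= 0.0)
    stop("invalid surface: area-element bound w_max is not finite");
  NumericMatrix out(n, 6);
  for (int k = 0; k < n; ++k) {
    double px, py, h, fx, fy, w;
    for (;;) {
      px = unif_rand() * s.Lx;
      py = unif_rand() * s.Ly;
      double u = unif_rand();
      s.eval(px, py, h, fx, fy);
      w = std::sqrt(1.0 + fx * fx + fy * fy);
      if (u * wmax <= w) break;
    }
    double inv = 1.0 / w;
    out(k, 0) = px; out(k, 1) = py; out(k, 2) = h;
    out(k, 3) = -fx * inv; out(k, 4) = -fy * inv; out(k, 5) = inv;
  }
  return out;
}

// Does a sphere of diameter D centred at (cx, cy, cz) dig into the substrate?
// Sampled on a lateral square grid of step D/10 inside the disk of radius
// D/2: penetration if the clearance cz - f drops below the sphere chord
// height sqrt((D/2)^2 - r^2) minus a tolerance of 1e-3 * D.
static inline bool penetrates_substrate(const Surf &s, double D,
                                        double cx, double cy, double cz) {
  const double R = 0.5 * D, step = 0.1 * D, tol = 1e-3 * D;
  const int m = 5;
  for (int oi = -m; oi <= m; ++oi) {
    double ox = oi * step;
    for (int oj = -m; oj <= m; ++oj) {
      double oy = oj * step;
      double r2 = ox * ox + oy * oy;
      if (r2 > R * R) continue;
      double chord = std::sqrt(R * R - r2);
      double h, fx, fy;
      s.eval(cx + ox, cy + oy, h, fx, fy);
      if (cz - h < chord - tol) return true;
    }
  }
  return false;
}

// [[Rcpp::export]]
int placement_check_cpp(List surf_spec, double D,
                        NumericMatrix centers,
                        double cx, double cy, double cz,
                        bool enforce_pen) {
  // 0 = ok, 1 = overlap, 2 = penetration
  Surf s(surf_spec);
  double D2 = D * D;
  for (int j = 0; j < centers.nrow(); ++j) {
    double ax = cx - centers(j, 0);
    double ay = cy - centers(j, 1);
    double az = cz - centers(j, 2);
    ax -= s.Lx * std::nearbyint(ax / s.Lx);
    ay -= s.Ly * std::nearbyint(ay / s.Ly);
    if (ax * ax + ay * ay + az * az < D2) return 1;
  }
  if (enforce_pen && s.type != 0 && penetrates_substrate(s, D, cx, cy, cz))
    return 2;
  return 0;
}

// One RSA deposition run.  Anchors are drawn area-weighted on the surface;
// the trial sphere centre sits at anchor + (D/2) * nhat (tangent sphere).
// A trial is rejected if any existing centre lies within D (3D Euclidean
// distance, minimum image in x and y), or -- optionally -- if the sphere
// penetrates the substrate.  The run stops after `stop_failures` consecutive
// rejections (jamming) or when `max_attempts` is exhausted (budget-limited).
//
// `brute = true` scans all deposited spheres per trial; otherwise a lateral
// cell list with cell size >= D restricts the scan to the 3x3 neighbourhood.
// Both paths make identical accept/reject decisions and consume the RNG
// stream identically.
// [[Rcpp::export]]
List run_rsa_cpp(List surf_spec, double D, double wmax,
                 double max_attempts, double stop_failures,
                 bool enforce_pen, bool brute) {
  Surf s(surf_spec);
  if (!R_finite(wmax) || wmax <= 0.0)
    stop("invalid surface: area-element bound w_max is not finite");
  const double D2 = D * D;

  int ncx = (int)std::floor(s.Lx / D);
  int ncy = (int)std::floor(s.Ly / D);
  bool use_grid = !brute && ncx >= 4 && ncy >= 4;
  double cwx = 1.0, cwy = 1.0;
  std::vector< std::vector<int> > cells;
  if (use_grid) {
    cwx = s.Lx / ncx;
    cwy = s.Ly / ncy;
    cells.assign((size_t)ncx * ncy, std::vector<int>());
  }

  std::vector<double> AX, AY, AZ, CX, CY, CZ;
  std::vector<double> used;   // attempts consumed per accepted deposit

  double n_att = 0.0, consec = 0.0, since_success = 0.0;
  bool budget_limited = false;

  for (;;) {
    if (consec >= stop_failures) break;
    if (n_att >= max_attempts) { budget_limited = true; break; }
    if (((long long)n_att & 0xFFFFF) == 0) Rcpp::checkUserInterrupt();
    n_att += 1.0; since_success += 1.0;

    double px, py, h, fx, fy, w;
    for (;;) {
      px = unif_rand() * s.Lx;
      py = unif_rand() * s.Ly;
      double u = unif_rand();
      s.eval(px, py, h, fx, fy);
      w = std::sqrt(1.0 + fx * fx + fy * fy);
      if (u * wmax <= w) break;
    }
    double inv = 1.0 / w;
    double cx = s.wrapx(px - 0.5 * D * fx * inv);
    double cy = s.wrapy(py - 0.5 * D * fy * inv);
    double cz = h + 0.5 * D * inv;

    bool overlap = false;
    if (use_grid) {
      int ic = (int)(cx / cwx); if (ic >= ncx) ic = ncx - 1;
      int jc = (int)(cy / cwy); if (jc >= ncy) jc = ncy - 1;
      for (int di = -1; di <= 1 && !overlap; ++di) {
        int ii = (ic + di + ncx) % ncx;
        for (int dj = -1; dj <= 1 && !overlap; ++dj) {
          int jj = (jc + dj + ncy) % ncy;
          const std::vector<int> &cell = cells[(size_t)ii * ncy + jj];
          for (size_t q = 0; q < cell.size(); ++q) {
            int j = cell[q];
            double ax = cx - CX[j], ay = cy - CY[j], az = cz - CZ[j];
            ax -= s.Lx * std::nearbyint(ax / s.Lx);
            ay -= s.Ly * std::nearbyint(ay / s.Ly);
            if (ax * ax + ay * ay + az * az < D2) { overlap = true; break; }
          }
        }
      }
    } else {
      for (size_t j = 0; j < CX.size(); ++j) {
        double ax = cx - CX[j], ay = cy - CY[j], az = cz - CZ[j];
        ax -= s.Lx * std::nearbyint(ax / s.Lx);
        ay -= s.Ly * std::nearbyint(ay / s.Ly);
        if (ax * ax + ay * ay + az * az < D2) { overlap = true; break; }
      }
    }
    if (overlap) { consec += 1.0; continue; }

    if (enforce_pen && s.type != 0 && penetrates_substrate(s, D, cx, cy, cz)) {
      consec += 1.0;
      continue;
    }

    AX.push_back(px); AY.push_back(py); AZ.push_back(h);
    CX.push_back(cx); CY.push_back(cy); CZ.push_back(cz);
    used.push_back(since_success);
    if (use_grid) {
      int ic = (int)(cx / cwx); if (ic >= ncx) ic = ncx - 1;
      int jc = (int)(cy / cwy); if (jc >= ncy) jc = ncy - 1;
      cells[(size_t)ic * ncy + jc].push_back((int)CX.size() - 1);
    }
    since_success = 0.0;
    consec = 0.0;
  }

  int N = (int)CX.size();
  NumericMatrix anchors(N, 3), centers(N, 3);
  NumericVector att(N);
  for (int i = 0; i < N; ++i) {
    anchors(i, 0) = AX[i]; anchors(i, 1) = AY[i]; anchors(i, 2) = AZ[i];
    centers(i, 0) = CX[i]; centers(i, 1) = CY[i]; centers(i, 2) = CZ[i];
    att[i] = used[i];
  }
  return List::create(_["anchors"] = anchors,
                      _["centers"] = centers,
                      _["attempts_used"] = att,
                      _["n_att"] = n_att,
                      _["budget_limited"] = budget_limited);
}

// Smallest minimum-image pairwise centre distance (exact brute force);
// used by the hard-core exclusion invariant tests.
// [[Rcpp::export]]
double min_pair_distance_cpp(NumericMatrix centers, double Lx, double Ly) {
  int n = centers.nrow();
  if (n < 2) return R_PosInf;
  double best = R_PosInf;
  for (int i = 0; i < n - 1; ++i)
    for (int j = i + 1; j < n; ++j) {
      double ax = centers(i, 0) - centers(j, 0);
      double ay = centers(i, 1) - centers(j, 1);
      double az = centers(i, 2) - centers(j, 2);
      ax -= Lx * std::nearbyint(ax / Lx);
      ay -= Ly * std::nearbyint(ay / Ly);
      double d2 = ax * ax + ay * ay + az * az;
      if (d2 < best) best = d2;
    }
  return std::sqrt(best);
}
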