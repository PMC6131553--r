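// Periodic Voronoi geometry, analytic shape-energy forces, and the
// self-propelled Voronoi / Vicsek time-stepping kernel.
//
// Geometry strategy: each cell's Voronoi polygon is obtained by clipping a
// large square with the perpendicular bisectors of nearby generators
// (minimum-image candidates, or all 3x3 periodic images when the search
// radius approaches L/2).  Candidates are processed nearest-first; clipping
// stops once the next candidate is farther than twice the current maximal
// vertex radius, which guarantees the polygon is exact.  Every polygon
// vertex is the circumcenter of the generator triple formed by the cell and
// the owners of its two adjacent edges, which is what the analytic force
// (gradient of the area/perimeter energy through the Voronoi vertices)
// needs.

#include <Rcpp.h>
#include <vector>
#include <algorithm>
#include <cmath>

using namespace Rcpp;

namespace {

constexpr int POLY_CAP = 160;

// minimum image for coordinates already wrapped into [0, L): dx in (-L, L)
inline double min_image(double dx, double L) {
  if (dx > 0.5 * L) return dx - L;
  if (dx < -0.5 * L) return dx + L;
  return dx;
}

struct CellPoly {
  // vertices CCW; edge k runs v[k] -> v[(k+1) % m]
  double vx[POLY_CAP], vy[POLY_CAP];
  int own[POLY_CAP];                   // generator owning edge k (-1 = box)
  double ox[POLY_CAP], oy[POLY_CAP];   // that generator image's displacement
  int m = 0;

  void clear() { m = 0; }
  int size() const { return m; }
  void push(double x, double y, int o, double odx, double ody) {
    vx[m] = x; vy[m] = y; own[m] = o; ox[m] = odx; oy[m] = ody; ++m;
  }
};

struct Cand {
  double dx, dy, d2;
  int idx;
};

// Clip polygon with half-plane {p : p . d <= |d|^2 / 2} (bisector between the
// cell at the origin and a generator displaced by d).  Writes the result into
// Q and returns true if the polygon changed (otherwise P is untouched).
bool clip_poly(const CellPoly &P, CellPoly &Q, double dx, double dy, int j) {
  const double b = 0.5 * (dx * dx + dy * dy);
  const int m = P.m;
  const double tol = 1e-12 * (1.0 + std::fabs(b));
  double s[POLY_CAP];
  bool any_out = false;
  for (int k = 0; k < m; ++k) {
    s[k] = dx * P.vx[k] + dy * P.vy[k] - b;
    if (s[k] > tol) any_out = true;
  }
  if (!any_out) return false;

  Q.clear();
  for (int k = 0; k < m; ++k) {
    const int k1 = (k + 1) % m;
    const bool ain = s[k] <= tol, bin = s[k1] <= tol;
    if (ain) {
      Q.push(P.vx[k], P.vy[k], P.own[k], P.ox[k], P.oy[k]);
      if (!bin) {  // leaving: intersection starts the new clip edge
        const double t = s[k] / (s[k] - s[k1]);
        Q.push(P.vx[k] + t * (P.vx[k1] - P.vx[k]),
               P.vy[k] + t * (P.vy[k1] - P.vy[k]), j, dx, dy);
      }
    } else if (bin) {  // entering: remainder of the old edge starts here
      const double t = s[k] / (s[k] - s[k1]);
      Q.push(P.vx[k] + t * (P.vx[k1] - P.vx[k]),
             P.vy[k] + t * (P.vy[k1] - P.vy[k]), P.own[k], P.ox[k], P.oy[k]);
    }
  }
  if (Q.m > POLY_CAP - 4) stop("voronoi polygon capacity exceeded");
  return true;
}

// Merge consecutive vertices closer than tol; the zero-length edge between
// them (degenerate, e.g. cocircular generators) is dropped.
void clean_poly(CellPoly &P, double tol = 1e-10) {
  const int m = P.m;
  if (m < 4) return;
  CellPoly Q;
  Q.clear();
  for (int k = 0; k < m; ++k) {
    if (Q.m > 0) {
      const double ddx = P.vx[k] - Q.vx[Q.m - 1], ddy = P.vy[k] - Q.vy[Q.m - 1];
      if (ddx * ddx + ddy * ddy < tol * tol) {
        // overwrite previous outgoing edge with this vertex's outgoing edge
        Q.own[Q.m - 1] = P.own[k]; Q.ox[Q.m - 1] = P.ox[k]; Q.oy[Q.m - 1] = P.oy[k];
        continue;
      }
    }
    Q.push(P.vx[k], P.vy[k], P.own[k], P.ox[k], P.oy[k]);
  }
  // wrap-around duplicate: drop the first vertex, its outgoing edge replaces
  // the zero-length closing edge
  if (Q.m >= 2) {
    const double ddx = Q.vx[0] - Q.vx[Q.m - 1], ddy = Q.vy[0] - Q.vy[Q.m - 1];
    if (ddx * ddx + ddy * ddy < tol * tol) {
      Q.own[Q.m - 1] = Q.own[0]; Q.ox[Q.m - 1] = Q.ox[0]; Q.oy[Q.m - 1] = Q.oy[0];
      for (int k = 0; k < Q.m - 1; ++k) {
        Q.vx[k] = Q.vx[k + 1]; Q.vy[k] = Q.vy[k + 1];
        Q.own[k] = Q.own[k + 1]; Q.ox[k] = Q.ox[k + 1]; Q.oy[k] = Q.oy[k + 1];
      }
      --Q.m;
    }
  }
  if (Q.m >= 3) P = Q;
}

bool build_cell(int i, const double *px, const double *py, int N, double L,
                double Rc, CellPoly *&P, double &maxrad) {
  static thread_local CellPoly bufA, bufB;
  CellPoly *cur = &bufA, *nxt = &bufB;
  const double H = Rc;
  cur->clear();
  // CCW initial box, edges owned by -1
  cur->push(-H, -H, -1, 0, 0);
  cur->push( H, -H, -1, 0, 0);
  cur->push( H,  H, -1, 0, 0);
  cur->push(-H,  H, -1, 0, 0);

  static thread_local std::vector<Cand> cand;
  cand.clear();
  const bool nine = (Rc >= 0.49 * L);
  if (!nine) {
    for (int j = 0; j < N; ++j) {
      if (j == i) continue;
      const double dx = min_image(px[j] - px[i], L);
      const double dy = min_image(py[j] - py[i], L);
      const double d2 = dx * dx + dy * dy;
      if (d2 <= Rc * Rc) cand.push_back({dx, dy, d2, j});
    }
  } else {
    for (int j = 0; j < N; ++j)
      for (int a = -1; a <= 1; ++a)
        for (int bb = -1; bb <= 1; ++bb) {
          if (j == i && a == 0 && bb == 0) continue;
          const double dx = px[j] - px[i] + a * L;
          const double dy = py[j] - py[i] + bb * L;
          const double d2 = dx * dx + dy * dy;
          if (d2 > 1e-24 && d2 <= Rc * Rc) cand.push_back({dx, dy, d2, j});
        }
  }
  std::sort(cand.begin(), cand.end(),
            [](const Cand &a, const Cand &b) { return a.d2 < b.d2; });

  maxrad = H * std::sqrt(2.0);
  for (const Cand &c : cand) {
    if (c.d2 >= 4.0 * maxrad * maxrad) break;  // cannot cut the polygon
    if (clip_poly(*cur, *nxt, c.dx, c.dy, c.idx)) {
      std::swap(cur, nxt);
      double mr2 = 0.0;
      for (int k = 0; k < cur->m; ++k) {
        const double r2 = cur->vx[k] * cur->vx[k] + cur->vy[k] * cur->vy[k];
        if (r2 > mr2) mr2 = r2;
      }
      maxrad = std::sqrt(mr2);
    }
  }
  P = cur;
  for (int k = 0; k < cur->m; ++k)
    if (cur->own[k] < 0) return false;         // still bounded by the box
  return 2.0 * maxrad <= Rc;                   // exactness guarantee
}

// Returns a pointer to a thread-local polygon buffer, valid until the next
// call.
const CellPoly *cell_polygon(int i, const double *px, const double *py,
                             int N, double L, double Rc0) {
  CellPoly *P = nullptr;
  double Rc = Rc0, maxrad;
  for (;;) {
    if (build_cell(i, px, py, N, L, Rc, P, maxrad)) break;
    Rc *= 2.0;
    if (Rc > 1.45 * L) {  // always sufficient on the torus
      build_cell(i, px, py, N, L, 1.45 * L, P, maxrad);
      break;
    }
  }
  clean_poly(*P);
  return P;
}

double shoelace(const CellPoly &P) {
  double a = 0.0;
  const int m = P.m;
  for (int k = 0; k < m; ++k) {
    const int k1 = (k + 1) % m;
    a += P.vx[k] * P.vy[k1] - P.vx[k1] * P.vy[k];
  }
  return 0.5 * a;
}

double perimeter(const CellPoly &P) {
  double p = 0.0;
  const int m = P.m;
  for (int k = 0; k < m; ++k) {
    const int k1 = (k + 1) % m;
    const double ex = P.vx[k1] - P.vx[k], ey = P.vy[k1] - P.vy[k];
    p += std::sqrt(ex * ex + ey * ey);
  }
  return p;
}

double default_rc(int N, double L) {
  const double spacing = std::sqrt(L * L / std::max(N, 1));
  return std::max(2.4 * spacing, 1e-3 * L);
}

// Analytic -grad E.  Accumulates, for every vertex of every cell, the chain
// rule through the circumcenter of the generating triple (i, a, b).
void accumulate_forces(const double *px, const double *py, int N, double L,
                       double KA, double Kp, double A0, double p0,
                       double Rc0, double *fx, double *fy,
                       double *area_out, double *perim_out) {
  std::fill(fx, fx + N, 0.0);
  std::fill(fy, fy + N, 0.0);
  for (int i = 0; i < N; ++i) {
    const CellPoly &P = *cell_polygon(i, px, py, N, L, Rc0);
    const int m = P.m;
    const double Ai = shoelace(P);
    const double pi_ = perimeter(P);
    if (area_out) area_out[i] = Ai;
    if (perim_out) perim_out[i] = pi_;
    const double cA = 2.0 * KA * (Ai - A0);
    const double cP = 2.0 * Kp * (pi_ - p0);
    for (int k = 0; k < m; ++k) {
      const int km = (k - 1 + m) % m, kp = (k + 1) % m;
      const double cx = P.vx[k], cy = P.vy[k];
      // dA_i/dv and dp_i/dv at vertex k (CCW shoelace / edge-length terms)
      const double dAx = 0.5 * (P.vy[kp] - P.vy[km]);
      const double dAy = 0.5 * (P.vx[km] - P.vx[kp]);
      double e1x = cx - P.vx[km], e1y = cy - P.vy[km];
      double e2x = cx - P.vx[kp], e2y = cy - P.vy[kp];
      const double l1 = std::sqrt(e1x * e1x + e1y * e1y);
      const double l2 = std::sqrt(e2x * e2x + e2y * e2y);
      if (l1 > 1e-14) { e1x /= l1; e1y /= l1; } else { e1x = e1y = 0.0; }
      if (l2 > 1e-14) { e2x /= l2; e2y /= l2; } else { e2x = e2y = 0.0; }
      const double gx = cA * dAx + cP * (e1x + e2x);
      const double gy = cA * dAy + cP * (e1y + e2y);
      // generators: cell i at origin, a = owner of incoming edge, b = outgoing
      const int a = P.own[km], b = P.own[k];
      const double ax = P.ox[km], ay = P.oy[km];
      const double bx = P.ox[k],  by = P.oy[k];
      const double det = ax * by - ay * bx;
      if (std::fabs(det) < 1e-13) continue;    // near-collinear triple
      const double u0x = (by - ay) / det, u0y = (ax - bx) / det;
      const double u1x =  by / det,       u1y = -bx / det;
      const double u2x = -ay / det,       u2y =  ax / det;
      const double s0 = gx * u0x + gy * u0y;
      const double s1 = gx * u1x + gy * u1y;
      const double s2 = gx * u2x + gy * u2y;
      fx[i] -= s0 * cx;            fy[i] -= s0 * cy;
      fx[a] -= s1 * (ax - cx);     fy[a] -= s1 * (ay - cy);
      fx[b] -= s2 * (bx - cx);     fy[b] -= s2 * (by - cy);
    }
  }
}

inline double wrap_pi(double a) {
  // wrap into (-pi, pi]
  a -= 2.0 * M_PI * std::floor(a / (2.0 * M_PI));  // [0, 2pi)
  if (a > M_PI) a -= 2.0 * M_PI;
  return a;
}

}  // namespace

// [[Rcpp::export]]
List cpp_voronoi_geometry(NumericMatrix pos, double L, bool polygons = false) {
  const int N = pos.nrow();
  const double *px = &pos(0, 0), *py = &pos(0, 1);
  const double Rc0 = default_rc(N, L);
  NumericVector areas(N), perims(N);
  List nbrs(N), polys(polygons ? N : 0);
  for (int i = 0; i < N; ++i) {
    const CellPoly &P = *cell_polygon(i, px, py, N, L, Rc0);
    areas[i] = shoelace(P);
    perims[i] = perimeter(P);
    std::vector<int> nb(P.own, P.own + P.m);
    std::sort(nb.begin(), nb.end());
    nb.erase(std::unique(nb.begin(), nb.end()), nb.end());
    IntegerVector nbv(nb.size());
    for (size_t k = 0; k < nb.size(); ++k) nbv[k] = nb[k] + 1;  // 1-based
    nbrs[i] = nbv;
    if (polygons) {
      NumericMatrix vv(P.m, 2);
      for (int k = 0; k < P.m; ++k) {
        vv(k, 0) = pos(i, 0) + P.vx[k];
        vv(k, 1) = pos(i, 1) + P.vy[k];
      }
      polys[i] = vv;
    }
  }
  List out = List::create(_["area"] = areas, _["perimeter"] = perims,
                          _["neighbors"] = nbrs);
  if (polygons) out["polygons"] = polys;
  return out;
}

// [[Rcpp::export]]
List cpp_sheet_forces(NumericMatrix pos, double L, double K_A, double K_p,
                      double A0, double p0) {
  const int N = pos.nrow();
  NumericMatrix F(N, 2);
  NumericVector areas(N), perims(N);
  std::vector<double> fx(N), fy(N);
  accumulate_forces(&pos(0, 0), &pos(0, 1), N, L, K_A, K_p, A0, p0,
                    default_rc(N, L), fx.data(), fy.data(),
                    &areas[0], &perims[0]);
  for (int i = 0; i < N; ++i) { F(i, 0) = fx[i]; F(i, 1) = fy[i]; }
  return List::create(_["force"] = F, _["area"] = areas,
                      _["perimeter"] = perims);
}

// Deterministic part of the Vicsek-like angle update: (dt/tau_V) times the
// mean wrapped difference between neighbour velocity angles and the cell's
// own polarization, neighbours taken within R_V (minimum image), self and
// zero-displacement cells excluded.
// [[Rcpp::export]]
NumericVector cpp_alignment_increment(NumericMatrix pos, NumericMatrix disp,
                                      NumericVector theta, double L,
                                      double R_V, double tau_V, double dt) {
  const int N = pos.nrow();
  NumericVector inc(N);
  if (R_V <= 0.0 || tau_V <= 0.0) return inc;
  std::vector<double> phi(N);
  std::vector<bool> valid(N);
  for (int j = 0; j < N; ++j) {
    const double d = std::hypot(disp(j, 0), disp(j, 1));
    valid[j] = d > 1e-15;
    phi[j] = valid[j] ? std::atan2(disp(j, 1), disp(j, 0)) : 0.0;
  }
  const double rv2 = R_V * R_V;
  for (int i = 0; i < N; ++i) {
    double s = 0.0;
    int n = 0;
    for (int j = 0; j < N; ++j) {
      if (j == i || !valid[j]) continue;
      const double dx = min_image(pos(j, 0) - pos(i, 0), L);
      const double dy = min_image(pos(j, 1) - pos(i, 1), L);
      if (dx * dx + dy * dy > rv2) continue;
      s += wrap_pi(phi[j] - theta[i]);
      ++n;
    }
    if (n > 0) inc[i] = (dt / tau_V) * (s / n);
  }
  return inc;
}

// Full time-stepping loop.  Angles are updated first (alignment from the
// previous step's displacements plus Gaussian rotational noise of variance
// 2 D_r dt), then positions advance with mu*F(t) + v0*n(t+dt).  Unwrapped
// positions are recorded every `stride` steps.
// [[Rcpp::export]]
List cpp_spv_run(NumericMatrix pos, NumericMatrix disp, NumericVector theta,
                 double L, double K_A, double K_p, double A0, double p0,
                 double mu, double v0, double tau_V, double R_V, double D_r,
                 double dt, int n_steps, int stride) {
  const int N = pos.nrow();
  std::vector<double> px(N), py(N), ux(N), uy(N), dx_(N), dy_(N), th(N);
  for (int i = 0; i < N; ++i) {
    px[i] = pos(i, 0); py[i] = pos(i, 1);
    ux[i] = pos(i, 0); uy[i] = pos(i, 1);
    dx_[i] = disp(i, 0); dy_[i] = disp(i, 1);
    th[i] = theta[i];
  }
  const int n_samples = (stride > 0) ? n_steps / stride : 0;
  NumericMatrix traj(n_samples, 2 * N);
  std::vector<double> fx(N), fy(N), phi(N), inc(N);
  std::vector<bool> valid(N);
  const double sigma = std::sqrt(2.0 * D_r * dt);
  const double rv2 = R_V * R_V;
  const double Rc0 = default_rc(N, L);
  int isample = 0;

  for (int step = 1; step <= n_steps; ++step) {
    // --- angle update (synchronous, from state at t) ---
    std::fill(inc.begin(), inc.end(), 0.0);
    if (R_V > 0.0 && tau_V > 0.0) {
      for (int j = 0; j < N; ++j) {
        const double d = std::hypot(dx_[j], dy_[j]);
        valid[j] = d > 1e-15;
        phi[j] = valid[j] ? std::atan2(dy_[j], dx_[j]) : 0.0;
      }
      for (int i = 0; i < N; ++i) {
        double s = 0.0;
        int n = 0;
        for (int j = 0; j < N; ++j) {
          if (j == i || !valid[j]) continue;
          const double ddx = min_image(px[j] - px[i], L);
          const double ddy = min_image(py[j] - py[i], L);
          if (ddx * ddx + ddy * ddy > rv2) continue;
          s += wrap_pi(phi[j] - th[i]);
          ++n;
        }
        if (n > 0) inc[i] = (dt / tau_V) * (s / n);
      }
    }
    for (int i = 0; i < N; ++i)
      th[i] = wrap_pi(th[i] + inc[i] + sigma * R::norm_rand());

    // --- forces at time t ---
    accumulate_forces(px.data(), py.data(), N, L, K_A, K_p, A0, p0, Rc0,
                      fx.data(), fy.data(), nullptr, nullptr);

    // --- position update ---
    for (int i = 0; i < N; ++i) {
      const double ddx = (mu * fx[i] + v0 * std::cos(th[i])) * dt;
      const double ddy = (mu * fy[i] + v0 * std::sin(th[i])) * dt;
      if (!std::isfinite(ddx) || !std::isfinite(ddy))
        stop("non-finite displacement at step %d, cell %d", step, i + 1);
      dx_[i] = ddx; dy_[i] = ddy;
      ux[i] += ddx; uy[i] += ddy;
      px[i] += ddx; py[i] += ddy;
      px[i] -= L * std::floor(px[i] / L);
      py[i] -= L * std::floor(py[i] / L);
    }

    if (stride > 0 && step % stride == 0) {
      for (int i = 0; i < N; ++i) {
        traj(isample, i) = ux[i];
        traj(isample, N + i) = uy[i];
      }
      ++isample;
    }
  }

  NumericMatrix pos_out(N, 2), disp_out(N, 2);
  NumericVector theta_out(N);
  for (int i = 0; i < N; ++i) {
    pos_out(i, 0) = px[i]; pos_out(i, 1) = py[i];
    disp_out(i, 0) = dx_[i]; disp_out(i, 1) = dy_[i];
    theta_out[i] = th[i];
  }
  return List::create(_["positions"] = pos_out, _["disp"] = disp_out,
                      _["theta"] = theta_out, _["traj"] = traj);
}
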