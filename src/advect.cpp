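#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Degrees of latitude per metre on a sphere of radius 6371 km.
static const double DEG_PER_M = 180.0 / (M_PI * 6371000.0);

// Gridded velocity field unpacked from the R side.
// Arrays are column-major with dim (nlon, nlat, ndep, nt); mask is
// (nlon, nlat, ndep) with 1 = water.
struct Grid {
  const double *u, *v, *w;
  const int *mask;
  const double *lon, *lat, *dep, *tim;
  int nlon, nlat, ndep, nt;
  bool has_w;

  inline int idx3(int i, int j, int k) const {
    return i + nlon * (j + nlat * k);
  }
  inline int idx4(int i, int j, int k, int l) const {
    return i + nlon * (j + nlat * (k + ndep * l));
  }
};

// Largest cell index i in [0, n-2] with coord[i] <= x, clamped into range.
// `hint` warm-starts the search (particle moves little per step).
static inline int find_cell(const double *coord, int n, double x, int hint) {
  if (n == 1) return 0;
  int i = hint;
  if (i < 0) i = 0;
  if (i > n - 2) i = n - 2;
  while (i > 0 && x < coord[i]) --i;
  while (i < n - 2 && x >= coord[i + 1]) ++i;
  return i;
}

// Trilinear in (lon, lat, depth), linear in time, with land nodes dropped
// and the remaining weights renormalized. Depth and time are clamped to the
// grid range; a horizontal query outside the grid sets *oob.
// Returns velocity through uvw[3]; (0,0,0) if all enclosing nodes are land.
static void interp_vel(const Grid &g, double qlon, double qlat, double qdep,
                       double qt, double uvw[3], bool *oob, int hint[4]) {
  uvw[0] = uvw[1] = uvw[2] = 0.0;
  if (qlon < g.lon[0] || qlon > g.lon[g.nlon - 1] ||
      qlat < g.lat[0] || qlat > g.lat[g.nlat - 1]) {
    *oob = true;
    return;
  }
  *oob = false;
  if (qdep < g.dep[0]) qdep = g.dep[0];
  if (qdep > g.dep[g.ndep - 1]) qdep = g.dep[g.ndep - 1];
  if (qt < g.tim[0]) qt = g.tim[0];
  if (qt > g.tim[g.nt - 1]) qt = g.tim[g.nt - 1];

  int i = find_cell(g.lon, g.nlon, qlon, hint[0]); hint[0] = i;
  int j = find_cell(g.lat, g.nlat, qlat, hint[1]); hint[1] = j;
  int k = find_cell(g.dep, g.ndep, qdep, hint[2]); hint[2] = k;
  int l = find_cell(g.tim, g.nt, qt, hint[3]); hint[3] = l;

  double fx = (g.nlon > 1) ? (qlon - g.lon[i]) / (g.lon[i + 1] - g.lon[i]) : 0.0;
  double fy = (g.nlat > 1) ? (qlat - g.lat[j]) / (g.lat[j + 1] - g.lat[j]) : 0.0;
  double fz = (g.ndep > 1) ? (qdep - g.dep[k]) / (g.dep[k + 1] - g.dep[k]) : 0.0;
  double ft = (g.nt > 1) ? (qt - g.tim[l]) / (g.tim[l + 1] - g.tim[l]) : 0.0;

  int di_max = (g.nlon > 1) ? 1 : 0;
  int dj_max = (g.nlat > 1) ? 1 : 0;
  int dk_max = (g.ndep > 1) ? 1 : 0;
  int dl_max = (g.nt > 1) ? 1 : 0;

  for (int dl = 0; dl <= dl_max; ++dl) {
    double wt = dl ? ft : (dl_max ? 1.0 - ft : 1.0);
    if (wt == 0.0) continue;
    double acc[3] = {0.0, 0.0, 0.0};
    double wsum = 0.0;
    for (int dk = 0; dk <= dk_max; ++dk) {
      double wz = dk ? fz : (dk_max ? 1.0 - fz : 1.0);
      for (int dj = 0; dj <= dj_max; ++dj) {
        double wy = dj ? fy : (dj_max ? 1.0 - fy : 1.0);
        for (int di = 0; di <= di_max; ++di) {
          double wx = di ? fx : (di_max ? 1.0 - fx : 1.0);
          double wgt = wx * wy * wz;
          if (wgt == 0.0) continue;
          if (!g.mask[g.idx3(i + di, j + dj, k + dk)]) continue;
          int id = g.idx4(i + di, j + dj, k + dk, l + dl);
          acc[0] += wgt * g.u[id];
          acc[1] += wgt * g.v[id];
          if (g.has_w) acc[2] += wgt * g.w[id];
          wsum += wgt;
        }
      }
    }
    if (wsum > 0.0) {
      uvw[0] += wt * acc[0] / wsum;
      uvw[1] += wt * acc[1] / wsum;
      uvw[2] += wt * acc[2] / wsum;
    }
  }
}

// 1 if the grid node nearest to (qlon, qlat, qdep) is land.
static inline int on_land(const Grid &g, double qlon, double qlat,
                          double qdep, int hint[4]) {
  if (qdep < g.dep[0]) qdep = g.dep[0];
  if (qdep > g.dep[g.ndep - 1]) qdep = g.dep[g.ndep - 1];
  int i = find_cell(g.lon, g.nlon, qlon, hint[0]);
  int j = find_cell(g.lat, g.nlat, qlat, hint[1]);
  int k = find_cell(g.dep, g.ndep, qdep, hint[2]);
  if (g.nlon > 1 && qlon - g.lon[i] > g.lon[i + 1] - qlon) ++i;
  if (g.nlat > 1 && qlat - g.lat[j] > g.lat[j + 1] - qlat) ++j;
  if (g.ndep > 1 && qdep - g.dep[k] > g.dep[k + 1] - qdep) ++k;
  return g.mask[g.idx3(i, j, k)] ? 0 : 1;
}

// Position derivative for Eq. dx/dt = u, dy/dt = v, dz/dt = w in grid
// coordinates: horizontal m/s -> deg/s (cos-latitude corrected), vertical
// positive-down depth advanced by -w (w positive up).
static inline bool deriv(const Grid &g, double qlon, double qlat, double qdep,
                         double qt, double out[3], int hint[4]) {
  bool oob = false;
  double uvw[3];
  interp_vel(g, qlon, qlat, qdep, qt, uvw, &oob, hint);
  if (oob) return false;
  double coslat = std::cos(qlat * M_PI / 180.0);
  out[0] = uvw[0] * DEG_PER_M / coslat;
  out[1] = uvw[1] * DEG_PER_M;
  out[2] = -uvw[2];
  return true;
}

// One classical RK4 step; returns false (position untouched) if any stage
// falls outside the horizontal domain.
static bool rk4(const Grid &g, double pos[3], double t, double dt,
                int hint[4]) {
  double k1[3], k2[3], k3[3], k4[3], p[3];
  if (!deriv(g, pos[0], pos[1], pos[2], t, k1, hint)) return false;
  for (int c = 0; c < 3; ++c) p[c] = pos[c] + 0.5 * dt * k1[c];
  if (!deriv(g, p[0], p[1], p[2], t + 0.5 * dt, k2, hint)) return false;
  for (int c = 0; c < 3; ++c) p[c] = pos[c] + 0.5 * dt * k2[c];
  if (!deriv(g, p[0], p[1], p[2], t + 0.5 * dt, k3, hint)) return false;
  for (int c = 0; c < 3; ++c) p[c] = pos[c] + dt * k3[c];
  if (!deriv(g, p[0], p[1], p[2], t + dt, k4, hint)) return false;
  for (int c = 0; c < 3; ++c)
    pos[c] += dt / 6.0 * (k1[c] + 2.0 * k2[c] + 2.0 * k3[c] + k4[c]);
  return true;
}

static Grid make_grid(NumericVector u, NumericVector v, NumericVector w,
                      IntegerVector mask, NumericVector lon, NumericVector lat,
                      NumericVector dep, NumericVector tim, bool has_w) {
  Grid g;
  g.u = u.begin(); g.v = v.begin(); g.w = w.begin();
  g.mask = mask.begin();
  g.lon = lon.begin(); g.lat = lat.begin();
  g.dep = dep.begin(); g.tim = tim.begin();
  g.nlon = lon.size(); g.nlat = lat.size();
  g.ndep = dep.size(); g.nt = tim.size();
  g.has_w = has_w;
  return g;
}

// [[Rcpp::export]]
List cpp_interp_velocity(NumericVector u, NumericVector v, NumericVector w,
                         IntegerVector mask, NumericVector lon,
                         NumericVector lat, NumericVector dep,
                         NumericVector tim, bool has_w, NumericVector qlon,
                         NumericVector qlat, NumericVector qdep,
                         NumericVector qt) {
  Grid g = make_grid(u, v, w, mask, lon, lat, dep, tim, has_w);
  int n = qlon.size();
  NumericVector out_u(n), out_v(n), out_w(n);
  LogicalVector oob(n);
  int hint[4] = {0, 0, 0, 0};
  for (int p = 0; p < n; ++p) {
    bool bad = false;
    double uvw[3];
    interp_vel(g, qlon[p], qlat[p], qdep[p], qt[p], uvw, &bad, hint);
    oob[p] = bad;
    out_u[p] = bad ? NA_REAL : uvw[0];
    out_v[p] = bad ? NA_REAL : uvw[1];
    out_w[p] = bad ? NA_REAL : uvw[2];
  }
  return List::create(_["u"] = out_u, _["v"] = out_v, _["w"] = out_w,
                      _["oob"] = oob);
}

// [[Rcpp::export]]
List cpp_rk4_step(NumericVector u, NumericVector v, NumericVector w,
                  IntegerVector mask, NumericVector lon, NumericVector lat,
                  NumericVector dep, NumericVector tim, bool has_w,
                  NumericVector plon, NumericVector plat, NumericVector pdep,
                  double t, double dt) {
  Grid g = make_grid(u, v, w, mask, lon, lat, dep, tim, has_w);
  int n = plon.size();
  NumericVector olon(n), olat(n), odep(n);
  LogicalVector oob(n);
  int hint[4] = {0, 0, 0, 0};
  for (int p = 0; p < n; ++p) {
    double pos[3] = {plon[p], plat[p], pdep[p]};
    bool ok = rk4(g, pos, t, dt, hint);
    oob[p] = !ok;
    olon[p] = pos[0];
    olat[p] = pos[1];
    odep[p] = pos[2];
  }
  return List::create(_["lon"] = olon, _["lat"] = olat, _["depth"] = odep,
                      _["oob"] = oob);
}

// Full particle integration. Status codes:
// 0 = pending (not yet released), 1 = active, 2 = beached, 3 = exited,
// 4 = finished (survived the full duration).
// Snapshots lie on a global clock t0 + s * out_every; dt must divide
// out_every and release times must sit on the snapshot grid (checked by the
// caller). beach_policy: 0 = absorb, 1 = reflect (revert and carry on).
// [[Rcpp::export]]
List cpp_advect(NumericVector u, NumericVector v, NumericVector w,
                IntegerVector mask, NumericVector lon, NumericVector lat,
                NumericVector dep, NumericVector tim, bool has_w,
                NumericVector plon, NumericVector plat, NumericVector pdep,
                NumericVector prel, double dt, double duration,
                double out_every, double t0, int nsnap, int beach_policy) {
  Grid g = make_grid(u, v, w, mask, lon, lat, dep, tim, has_w);
  int np = plon.size();
  NumericMatrix slon(np, nsnap), slat(np, nsnap), sdep(np, nsnap);
  IntegerMatrix sstat(np, nsnap);
  long nsteps = (long)std::lround(duration / dt);
  long steps_per_snap = (long)std::lround(out_every / dt);

  for (int p = 0; p < np; ++p) {
    double pos[3] = {plon[p], plat[p], pdep[p]};
    double prev[3] = {pos[0], pos[1], pos[2]};
    double t = prel[p];
    int hint[4] = {0, 0, 0, 0};
    long snap0 = (long)std::lround((prel[p] - t0) / out_every);
    for (long s = 0; s < snap0 && s < nsnap; ++s) {
      slon(p, s) = NA_REAL; slat(p, s) = NA_REAL; sdep(p, s) = NA_REAL;
      sstat(p, s) = 0;
    }
    int status = 1;
    long written = snap0 - 1;
    if (on_land(g, pos[0], pos[1], pos[2], hint)) status = 2;
    if (snap0 < nsnap) {
      slon(p, snap0) = pos[0]; slat(p, snap0) = pos[1]; sdep(p, snap0) = pos[2];
      sstat(p, snap0) = (status == 1) ? 1 : status;
      written = snap0;
    }
    long step = 0;
    while (status == 1 && step < nsteps) {
      prev[0] = pos[0]; prev[1] = pos[1]; prev[2] = pos[2];
      bool ok = rk4(g, pos, t, dt, hint);
      if (!ok) {
        status = 3;  // left the horizontal domain; freeze at last position
        pos[0] = prev[0]; pos[1] = prev[1]; pos[2] = prev[2];
        break;
      }
      if (pos[2] < g.dep[0]) pos[2] = g.dep[0];
      if (pos[2] > g.dep[g.ndep - 1]) pos[2] = g.dep[g.ndep - 1];
      ++step;
      t += dt;
      if (on_land(g, pos[0], pos[1], pos[2], hint)) {
        if (beach_policy == 1) {
          pos[0] = prev[0]; pos[1] = prev[1]; pos[2] = prev[2];
        } else {
          status = 2;  // absorb at the last water position
          pos[0] = prev[0]; pos[1] = prev[1]; pos[2] = prev[2];
        }
      }
      if (status == 1 && step % steps_per_snap == 0) {
        long s = snap0 + step / steps_per_snap;
        if (s < nsnap) {
          slon(p, s) = pos[0]; slat(p, s) = pos[1]; sdep(p, s) = pos[2];
          sstat(p, s) = (step == nsteps) ? 4 : 1;
          written = s;
        }
      }
    }
    if (status == 1) status = 4;
    // freeze terminal state into every remaining snapshot
    for (long s = written + 1; s < nsnap; ++s) {
      slon(p, s) = pos[0]; slat(p, s) = pos[1]; sdep(p, s) = pos[2];
      sstat(p, s) = status;
    }
  }
  return List::create(_["lon"] = slon, _["lat"] = slat, _["depth"] = sdep,
                      _["status"] = sstat);
}
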