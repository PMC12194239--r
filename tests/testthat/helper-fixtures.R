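# Shared fixtures, all built in code.

# Small all-water field with constant velocities.
const_field <- function(u = 0.1, v = 0, w = NULL,
                        lon = seq(-1, 1, by = 0.5),
                        lat = seq(-1, 1, by = 0.5),
                        depth = c(0, 50, 100), time = c(0, 2e7)) {
  dims <- c(length(lon), length(lat), length(depth), length(time))
  velocity_field(lon, lat, depth, time,
                 u = array(u, dims), v = array(v, dims),
                 w = if (is.null(w)) NULL else array(w, dims))
}

# Solid-body rotation about (0, 0) written directly in the integrator's
# metre<->degree convention, so trilinear interpolation is exact and the
# analytic orbit is a circle in degree space: lon = r cos(omega t),
# lat = r sin(omega t) (counterclockwise).
rotation_field <- function(omega, half_width = 0.02, spacing = 0.005,
                           t_max = 2e6) {
  m_per_deg <- pi / 180 * 6371000
  lon <- seq(-half_width, half_width, by = spacing)
  lat <- lon
  depth <- c(0, 50)
  time <- c(0, t_max)
  nl <- length(lon)
  u2 <- outer(lon, lat, function(x, y) -omega * y * m_per_deg)
  v2 <- outer(lon, lat, function(x, y) omega * x * m_per_deg)
  dims <- c(nl, nl, 2, 2)
  u <- array(rep(u2, 4), dims)
  v <- array(rep(v2, 4), dims)
  velocity_field(lon, lat, depth, time, u = u, v = v)
}

# Hand-built trajectory_set for recruitment tests: positions and statuses
# given per snapshot.
make_traj <- function(lon, lat, status, snap_time, release_zone,
                      release_time, depth = NULL, dt = 120,
                      duration = 122 * 86400) {
  np <- nrow(lon)
  if (is.null(depth)) depth <- matrix(10, np, ncol(lon))
  structure(
    list(lon = lon, lat = lat, depth = depth, status = status,
         snap_time = snap_time,
         particles = data.frame(id = seq_len(np),
                                release_zone = release_zone,
                                release_time = release_time,
                                lon = lon[, 1], lat = lat[, 1],
                                depth = depth[, 1]),
         dt = dt, duration = duration,
         output_every = if (length(snap_time) > 1)
           diff(snap_time[1:2]) else 21600,
         beaching = "absorb"),
    class = "trajectory_set")
}

# Two unit squares sharing the edge x = 1 (for boundary tie-break tests).
two_squares <- function() {
  zone_set(list(
    Z_A = list(lon = c(0, 1, 1, 0), lat = c(0, 0, 1, 1)),
    Z_B = list(lon = c(1, 2, 2, 1), lat = c(0, 0, 1, 1))
  ))
}

# Independent brute-force interpolation oracle: nested loops, land nodes
# dropped with weight renormalization, linear in time.
oracle_interp <- function(field, qlon, qlat, qdep, qt) {
  locate <- function(coord, x) {
    if (length(coord) == 1) return(list(i = 1L, f = 0))
    i <- max(which(coord <= x + 1e-12))
    i <- min(i, length(coord) - 1L)
    list(i = i, f = (x - coord[i]) / (coord[i + 1] - coord[i]))
  }
  ci <- locate(field$lon, qlon)
  cj <- locate(field$lat, qlat)
  ck <- locate(field$depth, min(max(qdep, field$depth[1]),
                                field$depth[length(field$depth)]))
  cl <- locate(field$time, min(max(qt, field$time[1]),
                               field$time[length(field$time)]))
  res <- c(u = 0, v = 0, w = 0)
  for (dl in 0:(length(field$time) > 1)) {
    wt <- if (length(field$time) > 1) (if (dl) cl$f else 1 - cl$f) else 1
    acc <- c(0, 0, 0); wsum <- 0
    for (dk in 0:(length(field$depth) > 1))
      for (dj in 0:(length(field$lat) > 1))
        for (di in 0:(length(field$lon) > 1)) {
          wx <- if (length(field$lon) > 1) (if (di) ci$f else 1 - ci$f) else 1
          wy <- if (length(field$lat) > 1) (if (dj) cj$f else 1 - cj$f) else 1
          wz <- if (length(field$depth) > 1)
            (if (dk) ck$f else 1 - ck$f) else 1
          wgt <- wx * wy * wz
          if (wgt == 0) next
          i <- ci$i + di; j <- cj$i + dj; k <- ck$i + dk; l <- cl$i + dl
          if (!field$mask[i, j, k]) next
          acc <- acc + wgt * c(field$u[i, j, k, l], field$v[i, j, k, l],
                               if (is.null(field$w)) 0
                               else field$w[i, j, k, l])
          wsum <- wsum + wgt
        }
    if (wsum > 0) res <- res + wt * acc / wsum
  }
  res
}

# Desk-scale pipeline config used by end-to-end tests.
tiny_config <- function(dir, seed = 1) {
  list(seed = seed, output_dir = dir,
       release = list(particles_per_day = 20, n_days = 2),
       connectivity = list(window_days = c(110, 120), density_bins = 10),
       abundance = list(scenario = list(n = 600, phi = 1.2, pi = 0.3),
                        family = "nb", ladder = "cumulative"))
}
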