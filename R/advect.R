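#' One fourth-order Runge-Kutta advection step
#'
#' Advances positions through the velocity field by one classical RK4 step:
#' stage velocities are evaluated at times `t`, `t + dt/2`, `t + dt/2`,
#' `t + dt`, horizontal velocities are converted from m/s to deg/s on a
#' 6371-km sphere with the cosine-latitude correction for longitude, and
#' depth (positive down) is advanced by `-w * dt`. With a spatially and
#' temporally constant velocity the step is exact.
#'
#' @param field A [velocity_field].
#' @param lon,lat,depth Current positions (vectors recycled to a common
#'   length).
#' @param t Current time (s, field time axis).
#' @param dt Step length (s).
#' @return data.frame with the new `lon`, `lat`, `depth`.
#' @export
rk4_step <- function(field, lon, lat, depth, t, dt = 120) {
  stopifnot(inherits(field, "velocity_field"))
  n <- max(length(lon), length(lat), length(depth))
  lon <- rep_len(as.numeric(lon), n); lat <- rep_len(as.numeric(lat), n)
  depth <- rep_len(as.numeric(depth), n)
  fp <- field_parts(field)
  res <- cpp_rk4_step(fp$u, fp$v, fp$w, fp$mask, fp$lon, fp$lat, fp$dep,
                      fp$tim, fp$has_w, lon, lat, depth, t, dt)
  if (any(res$oob))
    stop("RK4 stage evaluation left the horizontal domain (first at index ",
         which(res$oob)[1], "); last valid position returned in the error ",
         "condition is the input position")
  data.frame(lon = res$lon, lat = res$lat, depth = res$depth)
}

#' Particle status codes
#'
#' Integer codes used in trajectory status matrices: `pending` (not yet
#' released), `active`, and the absorbing terminal states `beached`,
#' `exited` and `finished`.
#' @format Named integer vector.
#' @export
STATUS_LEVELS <- c(pending = 0L, active = 1L, beached = 2L, exited = 3L,
                   finished = 4L)

#' Integrate particle trajectories through a velocity field
#'
#' The passive-larva transport model: every particle is integrated with RK4
#' steps of `dt` seconds from its release time for `duration_days` days or
#' until a terminal event. Particles advected into a land cell are frozen at
#' their last water position with status `beached` (or reverted and kept
#' active under the `reflect` policy); particles leaving the horizontal grid
#' become `exited`; survivors are `finished` at their full age. Positions and
#' statuses are recorded on a global clock every `output_hours` hours, so
#' snapshots are synoptic across staggered release days.
#'
#' @param particles A `release_set` from [build_release()] (or any data.frame
#'   with `id`, `release_zone`, `release_time`, `lon`, `lat`, `depth`).
#' @param field A [velocity_field] spanning every release time plus the full
#'   duration.
#' @param dt Integration step (s); must divide the output interval.
#' @param duration_days Per-particle integration horizon (days).
#' @param output_hours Snapshot interval (h).
#' @param beaching `"absorb"` (default) or `"reflect"`.
#' @return An object of class `trajectory_set`: matrices `lon`, `lat`,
#'   `depth`, `status` of dimension particles x snapshots, the snapshot
#'   times `snap_time`, and the release table.
#' @export
advect <- function(particles, field, dt = 120, duration_days = 122,
                   output_hours = 6, beaching = c("absorb", "reflect")) {
  beaching <- match.arg(beaching)
  stopifnot(inherits(field, "velocity_field"))
  req <- c("id", "release_zone", "release_time", "lon", "lat", "depth")
  if (!all(req %in% names(particles)))
    stop("particles must have columns: ", paste(req, collapse = ", "))
  duration <- duration_days * 86400
  out_every <- output_hours * 3600
  if (out_every %% dt != 0)
    stop("dt (", dt, " s) must divide the output interval (", out_every, " s)")
  if (duration %% out_every != 0)
    stop("duration must be a whole number of output intervals")
  t0 <- min(particles$release_time)
  t_end <- max(particles$release_time) + duration
  if (t0 < field$time[1] || (length(field$time) > 1 &&
                             t_end > field$time[length(field$time)]))
    stop("field time span [", field$time[1], ", ",
         field$time[length(field$time)],
         "] does not cover the simulation window [", t0, ", ", t_end, "]")
  offs <- (particles$release_time - t0) %% out_every
  if (any(offs != 0))
    stop("release times must lie on the global snapshot grid")
  nsnap <- as.integer((t_end - t0) / out_every) + 1L
  fp <- field_parts(field)
  res <- cpp_advect(fp$u, fp$v, fp$w, fp$mask, fp$lon, fp$lat, fp$dep,
                    fp$tim, fp$has_w,
                    particles$lon, particles$lat, particles$depth,
                    particles$release_time, dt, duration, out_every, t0,
                    nsnap, if (beaching == "reflect") 1L else 0L)
  structure(
    list(lon = res$lon, lat = res$lat, depth = res$depth,
         status = res$status,
         snap_time = t0 + (seq_len(nsnap) - 1L) * out_every,
         particles = particles, dt = dt, duration = duration,
         output_every = out_every, beaching = beaching),
    class = "trajectory_set"
  )
}

#' Particle status tallies per snapshot
#'
#' @param traj A `trajectory_set`.
#' @return Integer matrix (snapshots x status levels) counting particles in
#'   each state; rows always sum to the number of particles released.
#' @export
status_counts <- function(traj) {
  stopifnot(inherits(traj, "trajectory_set"))
  out <- sapply(STATUS_LEVELS, function(code)
    colSums(traj$status == code))
  if (is.null(dim(out))) out <- matrix(out, nrow = 1,
                                       dimnames = list(NULL,
                                                       names(STATUS_LEVELS)))
  out
}

#' @export
print.trajectory_set <- function(x, ...) {
  np <- nrow(x$status); ns <- ncol(x$status)
  cat("<trajectory_set>", np, "particles x", ns, "snapshots\n")
  cat(sprintf("  dt = %g s, duration = %g d, output every %g h, beaching: %s\n",
              x$dt, x$duration / 86400, x$output_every / 3600, x$beaching))
  fin <- x$status[, ns]
  tab <- table(factor(names(STATUS_LEVELS)[match(fin, STATUS_LEVELS)],
                      levels = names(STATUS_LEVELS)))
  cat("  final status:", paste(names(tab), tab, sep = "=", collapse = ", "),
      "\n")
  invisible(x)
}

#' @export
summary.trajectory_set <- function(object, ...) {
  sc <- status_counts(object)
  res <- list(n_particles = nrow(object$status),
              n_snapshots = ncol(object$status),
              final = sc[nrow(sc), ],
              span_days = diff(range(object$snap_time)) / 86400)
  class(res) <- "summary.trajectory_set"
  res
}

#' @export
print.summary.trajectory_set <- function(x, ...) {
  cat("Trajectory set:", x$n_particles, "particles,", x$n_snapshots,
      "snapshots over", x$span_days, "days\n")
  cat("Final statuses:\n")
  print(x$final)
  invisible(x)
}

#' Write trajectories to NetCDF
#'
#' Dimensions `(particle, snapshot)` with variables `lon`, `lat`, `depth`,
#' `status`, `release_zone` (integer index into a `zone_ids` attribute) and
#' `release_time`, shaped like common Lagrangian trajectory conventions.
#'
#' @param traj A `trajectory_set`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_trajectories_nc <- function(traj, path) {
  stopifnot(inherits(traj, "trajectory_set"))
  np <- nrow(traj$status); ns <- ncol(traj$status)
  dpart <- ncdf4::ncdim_def("particle", "1", seq_len(np))
  dsnap <- ncdf4::ncdim_def("snapshot", "seconds since 1970-01-01",
                            traj$snap_time)
  dims <- list(dpart, dsnap)
  fill <- 9.96921e36
  vlon <- ncdf4::ncvar_def("lon", "degrees_east", dims, missval = fill,
                           prec = "double")
  vlat <- ncdf4::ncvar_def("lat", "degrees_north", dims, missval = fill,
                           prec = "double")
  vdep <- ncdf4::ncvar_def("depth", "m", dims, missval = fill,
                           prec = "double")
  vst <- ncdf4::ncvar_def("status", "1", dims, prec = "integer")
  vrz <- ncdf4::ncvar_def("release_zone", "1", list(dpart), prec = "integer")
  vrt <- ncdf4::ncvar_def("release_time", "seconds since 1970-01-01",
                          list(dpart), prec = "double")
  nc <- ncdf4::nc_create(path, list(vlon, vlat, vdep, vst, vrz, vrt))
  on.exit(ncdf4::nc_close(nc), add = TRUE)
  zl <- sort(unique(traj$particles$release_zone))
  ncdf4::ncvar_put(nc, vlon, traj$lon)
  ncdf4::ncvar_put(nc, vlat, traj$lat)
  ncdf4::ncvar_put(nc, vdep, traj$depth)
  st <- traj$status; st[is.na(st)] <- 0L
  ncdf4::ncvar_put(nc, vst, st)
  ncdf4::ncvar_put(nc, vrz, match(traj$particles$release_zone, zl))
  ncdf4::ncvar_put(nc, vrt, traj$particles$release_time)
  ncdf4::ncatt_put(nc, 0, "zone_ids", paste(zl, collapse = ","))
  ncdf4::ncatt_put(nc, 0, "status_codes",
                   paste(names(STATUS_LEVELS), STATUS_LEVELS, sep = "=",
                         collapse = ","))
  invisible(path)
}
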