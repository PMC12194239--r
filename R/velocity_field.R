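#' Gridded ocean velocity field
#'
#' Container for zonal/meridional (and optionally vertical) velocity on a
#' regular lon x lat x depth x time grid, the physical forcing consumed by the
#' Lagrangian transport model. Arrays are stored in R's natural column-major
#' order with dimensions `(lon, lat, depth, time)`. Depth is positive-down
#' metres starting at the surface; time is seconds since 1970-01-01 UTC;
#' velocities are m/s with `w` positive up. The land/water mask has
#' dimensions `(lon, lat, depth)` with `TRUE` = water.
#'
#' @param lon,lat Strictly increasing coordinate vectors (degrees east/north).
#' @param depth Strictly increasing depth vector (m, positive down).
#' @param time Strictly increasing time vector (s since 1970-01-01 UTC).
#' @param u,v 4-D numeric arrays, dim `c(length(lon), length(lat),
#'   length(depth), length(time))`, in m/s. `NA` is allowed over land.
#' @param w Optional vertical velocity array (m/s, positive up); `NULL`
#'   (the default) is treated as identically zero.
#' @param mask Optional logical array `(lon, lat, depth)`, `TRUE` = water.
#'   Defaults to cells where `u` and `v` are finite at every time step.
#' @return An object of class `velocity_field`.
#' @examples
#' fld <- velocity_field(
#'   lon = 0:1, lat = 0:1, depth = c(0, 10), time = c(0, 86400),
#'   u = array(0.1, c(2, 2, 2, 2)), v = array(0, c(2, 2, 2, 2))
#' )
#' fld
#' @export
velocity_field <- function(lon, lat, depth, time, u, v, w = NULL, mask = NULL) {
  lon <- as.numeric(lon); lat <- as.numeric(lat)
  depth <- as.numeric(depth); time <- as.numeric(time)
  for (nm in c("lon", "lat", "depth", "time")) {
    x <- get(nm)
    if (length(x) < 1L || anyNA(x))
      stop("coordinate '", nm, "' must be non-empty and free of NA")
    if (length(x) > 1L && any(diff(x) <= 0))
      stop("coordinate '", nm, "' must be strictly increasing")
  }
  dims <- c(length(lon), length(lat), length(depth), length(time))
  for (nm in c("u", "v")) {
    a <- get(nm)
    if (!is.array(a) || !identical(dim(a), as.integer(dims)))
      stop("'", nm, "' must be an array with dim (lon, lat, depth, time) = (",
           paste(dims, collapse = ", "), ")")
  }
  if (!is.null(w) && (!is.array(w) || !identical(dim(w), as.integer(dims))))
    stop("'w' must be NULL or an array with the same dimensions as u")
  if (is.null(mask)) {
    ok <- is.finite(u) & is.finite(v)
    mask <- apply(ok, 1:3, all)
    dim(mask) <- dims[1:3]
  }
  if (!identical(dim(mask), as.integer(dims[1:3])))
    stop("'mask' must have dim (lon, lat, depth)")
  mask <- array(as.logical(mask), dims[1:3])
  wet <- array(rep(mask, dims[4]), dims)
  if (any(!is.finite(u[wet])) || any(!is.finite(v[wet])))
    stop("u and v must be finite wherever the mask is water")
  structure(
    list(lon = lon, lat = lat, depth = depth, time = time,
         u = u, v = v, w = w, mask = mask),
    class = "velocity_field"
  )
}

#' @export
print.velocity_field <- function(x, ...) {
  cat("<velocity_field>\n")
  cat(sprintf("  grid: %d lon x %d lat x %d depth x %d time\n",
              length(x$lon), length(x$lat), length(x$depth), length(x$time)))
  cat(sprintf("  lon [%.3f, %.3f] deg E, lat [%.3f, %.3f] deg N\n",
              min(x$lon), max(x$lon), min(x$lat), max(x$lat)))
  cat(sprintf("  depth [%g, %g] m (positive down), %d time steps\n",
              min(x$depth), max(x$depth), length(x$time)))
  cat(sprintf("  w: %s; water fraction: %.3f\n",
              if (is.null(x$w)) "absent (treated as zero)" else "present",
              mean(x$mask)))
  invisible(x)
}

# Internal: components in the layout the compiled kernels expect.
field_parts <- function(field) {
  list(
    u = as.numeric(field$u), v = as.numeric(field$v),
    w = if (is.null(field$w)) numeric(1) else as.numeric(field$w),
    mask = as.integer(field$mask),
    lon = field$lon, lat = field$lat, dep = field$depth, tim = field$time,
    has_w = !is.null(field$w)
  )
}

#' Read a gridded velocity field from NetCDF
#'
#' Reads a CF-style NetCDF file (CMEMS reanalysis dialect by default: velocity
#' variables `uo`/`vo`/`wo` on `longitude`/`latitude`/`depth`/`time`
#' dimensions). Fill values become masked land cells; a depth axis flagged
#' `positive = "up"` is converted to positive-down metres, negating `w`.
#'
#' @param path Path to a NetCDF file.
#' @param var_names Named character vector mapping roles `u`, `v` and
#'   optionally `w` to variable names in the file.
#' @return A [velocity_field].
#' @export
read_velocity_nc <- function(path,
                             var_names = c(u = "uo", v = "vo", w = "wo")) {
  if (!file.exists(path)) stop("file not found: ", path)
  nc <- ncdf4::nc_open(path)
  on.exit(ncdf4::nc_close(nc), add = TRUE)
  for (role in c("u", "v")) {
    if (is.na(var_names[role]) || !(var_names[[role]] %in% names(nc$var)))
      stop("velocity variable for role '", role, "' ('",
           var_names[role], "') not found in ", path)
  }
  getvar <- function(nm) ncdf4::ncvar_get(nc, nm, collapse_degen = FALSE)
  u <- getvar(var_names[["u"]])
  dimnms <- sapply(nc$var[[var_names[["u"]]]]$dim, function(d) d$name)
  pick <- function(cands, role) {
    hit <- dimnms[tolower(dimnms) %in% cands]
    if (length(hit) != 1L)
      stop("cannot identify the ", role, " coordinate among dimensions: ",
           paste(dimnms, collapse = ", "))
    hit
  }
  lon_nm <- pick(c("lon", "longitude", "x"), "longitude")
  lat_nm <- pick(c("lat", "latitude", "y"), "latitude")
  time_nm <- pick(c("time", "t"), "time")
  dep_nm <- dimnms[tolower(dimnms) %in% c("depth", "dep", "lev", "z")]
  lon <- as.numeric(ncdf4::ncvar_get(nc, lon_nm))
  lat <- as.numeric(ncdf4::ncvar_get(nc, lat_nm))
  time <- as.numeric(ncdf4::ncvar_get(nc, time_nm))
  has_dep <- length(dep_nm) == 1L
  flip_w <- FALSE
  if (has_dep) {
    depth <- as.numeric(ncdf4::ncvar_get(nc, dep_nm))
    pos <- tryCatch(ncdf4::ncatt_get(nc, dep_nm, "positive"),
                    error = function(e) list(hasatt = FALSE))
    if (isTRUE(pos$hasatt) && identical(tolower(pos$value), "up")) {
      depth <- -depth
      flip_w <- TRUE
    }
  } else {
    depth <- 0
  }
  target <- c(lon_nm, lat_nm, if (has_dep) dep_nm, time_nm)
  reshape <- function(a) {
    if (!has_dep) {
      a <- aperm(a, match(target, dimnms))
      dim(a) <- c(dim(a)[1:2], 1L, dim(a)[3])
    } else {
      a <- aperm(a, match(target, dimnms))
    }
    a
  }
  u <- reshape(u)
  v <- reshape(getvar(var_names[["v"]]))
  w <- NULL
  if (!is.na(var_names["w"]) && var_names[["w"]] %in% names(nc$var)) {
    w <- reshape(getvar(var_names[["w"]]))
    if (flip_w) w <- -w
  }
  if (has_dep && length(depth) > 1L && any(diff(depth) < 0)) {
    # positive-up files list depth from deep to shallow once negated; reorder
    ord <- order(depth)
    depth <- depth[ord]
    u <- u[, , ord, , drop = FALSE]
    v <- v[, , ord, , drop = FALSE]
    if (!is.null(w)) w <- w[, , ord, , drop = FALSE]
  }
  velocity_field(lon, lat, depth, time, u = u, v = v, w = w)
}

#' Write a velocity field to NetCDF
#'
#' Writes a CF-style file that [read_velocity_nc()] round-trips losslessly:
#' coordinates `longitude`/`latitude`/`depth`/`time` with units attributes and
#' velocities `uo`/`vo` (and `wo` when vertical velocity is present), with
#' land cells stored as fill values.
#'
#' @param field A [velocity_field].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_velocity_nc <- function(field, path) {
  stopifnot(inherits(field, "velocity_field"))
  dlon <- ncdf4::ncdim_def("longitude", "degrees_east", field$lon)
  dlat <- ncdf4::ncdim_def("latitude", "degrees_north", field$lat)
  ddep <- ncdf4::ncdim_def("depth", "m", field$depth)
  dtim <- ncdf4::ncdim_def("time", "seconds since 1970-01-01 00:00:00 UTC",
                           field$time)
  fill <- 9.96921e36
  dims <- list(dlon, dlat, ddep, dtim)
  vu <- ncdf4::ncvar_def("uo", "m s-1", dims, missval = fill, prec = "double")
  vv <- ncdf4::ncvar_def("vo", "m s-1", dims, missval = fill, prec = "double")
  vars <- list(vu, vv)
  if (!is.null(field$w)) {
    vars$vw <- ncdf4::ncvar_def("wo", "m s-1", dims, missval = fill,
                                prec = "double")
  }
  vmask <- ncdf4::ncvar_def("mask", "1", list(dlon, dlat, ddep),
                            prec = "integer")
  vars$vm <- vmask
  nc <- ncdf4::nc_create(path, vars)
  on.exit(ncdf4::nc_close(nc), add = TRUE)
  land <- array(rep(!field$mask, length(field$time)), dim(field$u))
  put <- function(var, a) {
    a[land] <- NA
    ncdf4::ncvar_put(nc, var, a)
  }
  put(vu, field$u)
  put(vv, field$v)
  if (!is.null(field$w)) put(vars$vw, field$w)
  ncdf4::ncvar_put(nc, vmask, array(as.integer(field$mask), dim(field$mask)))
  ncdf4::ncatt_put(nc, "depth", "positive", "down")
  invisible(path)
}

#' Interpolate velocity at arbitrary points
#'
#' Trilinear interpolation in lon/lat/depth and linear interpolation in time.
#' Land nodes contribute zero with the remaining weights renormalized over
#' water nodes, so velocity does not spuriously decay toward the coast;
#' a point fully enclosed by land yields `(0, 0, 0)`. Depth and time are
#' clamped to the grid range; a horizontal query outside the grid is an
#' error (the transport model decides the particle's fate instead).
#'
#' @param field A [velocity_field].
#' @param lon,lat,depth,t Query coordinates, recycled to a common length.
#' @return A data.frame with columns `u`, `v`, `w` (m/s), one row per query.
#' @export
interpolate_velocity <- function(field, lon, lat, depth, t) {
  stopifnot(inherits(field, "velocity_field"))
  n <- max(length(lon), length(lat), length(depth), length(t))
  lon <- rep_len(as.numeric(lon), n); lat <- rep_len(as.numeric(lat), n)
  depth <- rep_len(as.numeric(depth), n); t <- rep_len(as.numeric(t), n)
  fp <- field_parts(field)
  res <- cpp_interp_velocity(fp$u, fp$v, fp$w, fp$mask, fp$lon, fp$lat,
                             fp$dep, fp$tim, fp$has_w, lon, lat, depth, t)
  if (any(res$oob))
    stop("query point outside the horizontal grid bounds (first at index ",
         which(res$oob)[1], ")")
  data.frame(u = res$u, v = res$v, w = res$w)
}

#' Seasonal depth-averaged mean velocity maps
#'
#' Arithmetic mean of `u` and `v` over the time steps falling in the requested
#' calendar months and over all depth levels not exceeding `max_depth`,
#' water cells only. Land columns are `NA` in the output.
#'
#' @param field A [velocity_field] whose time axis is seconds since
#'   1970-01-01 UTC.
#' @param months Month numbers (1-12) or English month names.
#' @param max_depth Maximum depth (m) included in the vertical average.
#' @return A list with matrices `u` and `v` (lon x lat) and the coordinate
#'   vectors `lon`, `lat`.
#' @export
seasonal_mean_velocity <- function(field, months, max_depth = 100) {
  stopifnot(inherits(field, "velocity_field"))
  if (is.character(months))
    months <- match(tolower(substr(months, 1, 3)), tolower(month.abb))
  if (anyNA(months)) stop("unrecognized month label")
  tm <- as.POSIXlt(field$time, origin = "1970-01-01", tz = "UTC")
  sel_t <- which((tm$mon + 1L) %in% months)
  if (length(sel_t) == 0L)
    stop("field has no time steps in the requested months")
  sel_z <- which(field$depth <= max_depth)
  if (length(sel_z) == 0L) stop("no depth levels at or above ", max_depth, " m")
  avg <- function(a) {
    a <- a[, , sel_z, sel_t, drop = FALSE]
    land <- !field$mask[, , sel_z, drop = FALSE]
    a[array(rep(land, length(sel_t)), dim(a))] <- NA
    out <- apply(a, 1:2, function(x) if (all(is.na(x))) NA_real_ else
      mean(x, na.rm = TRUE))
    out
  }
  list(u = avg(field$u), v = avg(field$v), lon = field$lon, lat = field$lat)
}
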