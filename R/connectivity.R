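#' Per-particle recruitment assignment
#'
#' A particle recruits to the first zone it is found inside during its
#' recruitment age window: snapshots whose particle age (time since that
#' particle's release) lies in `[window_days[1], window_days[2]]`. The
#' default window, 110-120 days, is the 115-day (~4 month) larval duration
#' plus/minus the ~5 days settlement takes. Particles that beach or exit
#' before the window opens, or are never inside a zone during it, do not
#' recruit. With `max_depth` set, snapshots deeper than it are ignored.
#'
#' @param traj A `trajectory_set` whose duration covers the window.
#' @param zones A [zone_set].
#' @param window_days `c(min_age, max_age)` in days.
#' @param max_depth Optional maximum recruitment depth (m); default no
#'   screening.
#' @return Character vector, one element per particle: the recruitment zone
#'   id or `NA`.
#' @export
recruit <- function(traj, zones, window_days = c(110, 120), max_depth = NULL) {
  stopifnot(inherits(traj, "trajectory_set"), inherits(zones, "zone_set"),
            length(window_days) == 2, window_days[1] <= window_days[2])
  if (window_days[2] * 86400 > traj$duration)
    stop("recruitment window [", window_days[1], ", ", window_days[2],
         "] days exceeds the trajectory duration (",
         traj$duration / 86400, " days)")
  np <- nrow(traj$status)
  assigned <- rep(NA_character_, np)
  rel <- traj$particles$release_time
  lo <- window_days[1] * 86400
  hi <- window_days[2] * 86400
  for (s in seq_along(traj$snap_time)) {
    age <- traj$snap_time[s] - rel
    cand <- which(is.na(assigned) & age >= lo & age <= hi &
                    traj$status[, s] %in% c(1L, 4L))
    if (length(cand) == 0L) next
    if (!is.null(max_depth))
      cand <- cand[traj$depth[cand, s] <= max_depth]
    if (length(cand) == 0L) next
    z <- locate_zone(zones, traj$lon[cand, s], traj$lat[cand, s])
    hit <- !is.na(z)
    assigned[cand[hit]] <- z[hit]
  }
  assigned
}

#' Zone-to-zone connectivity matrix
#'
#' Tallies recruited particles by (release zone, recruitment zone). Rows are
#' release zones, columns recruitment zones; the diagonal is within-zone
#' retention, off-diagonal cells are between-zone connectivity. Unrecruited
#' particles (`NA` assignment) are excluded from the counts but included in
#' the released totals.
#'
#' @param recruits Per-particle recruitment zone ids (`NA` = none), as from
#'   [recruit()].
#' @param release_zones Per-particle release zone ids, aligned with
#'   `recruits`.
#' @param zone_ids Fixed zone ordering for rows/columns; defaults to the
#'   sorted union of ids seen.
#' @param window_days Recruitment window recorded as metadata.
#' @return An integer matrix of class `connectivity_matrix` with attributes
#'   `total_released`, `released_per_zone` and `window_days`.
#' @examples
#' m <- connectivity_matrix(c("RC_A", "RC_B", NA), c("RC_A", "RC_A", "RC_B"),
#'                          zone_ids = c("RC_A", "RC_B"))
#' retention_fraction(m)
#' @export
connectivity_matrix <- function(recruits, release_zones, zone_ids = NULL,
                                window_days = c(110, 120)) {
  if (length(recruits) != length(release_zones))
    stop("recruits and release_zones must be aligned by particle")
  if (is.null(zone_ids))
    zone_ids <- sort(unique(c(release_zones, recruits[!is.na(recruits)])))
  bad <- setdiff(c(release_zones, recruits[!is.na(recruits)]), zone_ids)
  if (length(bad))
    stop("unknown zone label(s): ", paste(unique(bad), collapse = ", "))
  rel <- factor(release_zones, levels = zone_ids)
  rec <- factor(recruits, levels = zone_ids)
  counts <- table(release = rel, recruitment = rec)
  m <- matrix(as.integer(counts), nrow = length(zone_ids),
              dimnames = list(release = zone_ids, recruitment = zone_ids))
  structure(m, class = c("connectivity_matrix", class(m)),
            total_released = length(release_zones),
            released_per_zone = as.integer(table(rel)),
            window_days = window_days)
}

#' @export
print.connectivity_matrix <- function(x, ...) {
  cat("<connectivity_matrix> (rows = release zone, cols = recruitment zone)\n")
  print(unclass_matrix(x))
  cat(sprintf("  recruited %d of %d released (%.2f%%); window %g-%g days\n",
              sum(x), attr(x, "total_released"),
              100 * sum(x) / attr(x, "total_released"),
              attr(x, "window_days")[1], attr(x, "window_days")[2]))
  invisible(x)
}

unclass_matrix <- function(x) {
  attributes(x) <- attributes(x)[c("dim", "dimnames")]
  x
}

#' Retention fraction of released larvae
#'
#' The share of released larvae recruited anywhere around the islands:
#' `100 * sum(counts) / total_released`. With `within_zone_only = TRUE` only
#' the diagonal (same-zone retention) is counted.
#'
#' @param m A `connectivity_matrix`.
#' @param total_released Denominator; defaults to the matrix's recorded
#'   released total.
#' @param within_zone_only Count only same-zone (diagonal) recruits.
#' @return Percentage (0-100).
#' @export
retention_fraction <- function(m, total_released = attr(m, "total_released"),
                               within_zone_only = FALSE) {
  if (is.null(total_released) || total_released <= 0)
    stop("total_released must be positive")
  num <- if (within_zone_only) sum(diag(unclass_matrix(m))) else sum(m)
  100 * num / total_released
}

#' Source contribution per release zone
#'
#' Percentage of all recruits contributed by each release zone
#' (`100 * rowSums / grand total`), reported to two decimals with halves
#' rounding up.
#'
#' @param m A `connectivity_matrix` (or plain counts matrix).
#' @return Named numeric vector summing to 100 up to rounding.
#' @export
source_contribution <- function(m) {
  tot <- sum(m)
  if (tot == 0) stop("no recruits: source contributions undefined")
  round_half_up(100 * rowSums(unclass_matrix(m)) / tot, 2)
}

#' Sink proportion per recruitment zone
#'
#' Percentage of all recruits received by each recruitment zone
#' (`100 * colSums / grand total`), reported to two decimals with halves
#' rounding up.
#'
#' @param m A `connectivity_matrix` (or plain counts matrix).
#' @return Named numeric vector summing to 100 up to rounding.
#' @export
sink_proportion <- function(m) {
  tot <- sum(m)
  if (tot == 0) stop("no recruits: sink proportions undefined")
  round_half_up(100 * colSums(unclass_matrix(m)) / tot, 2)
}

# Round to `digits` decimals with halves away from zero (the printed-report
# convention), rather than banker's rounding.
round_half_up <- function(x, digits = 2) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

#' Particle density map
#'
#' 2-D histogram of the positions of non-terminal (active or just-finished)
#' particles over the selected snapshots; darker cells in a rendered map are
#' sites of higher larval recurrence.
#'
#' @param traj A `trajectory_set`.
#' @param lon_breaks,lat_breaks Bin edges covering the domain.
#' @param window_days Optional `c(min_age, max_age)` restricting snapshots to
#'   a per-particle age window; default all snapshots.
#' @return List of class `density_map`: `counts` (lon bins x lat bins),
#'   `lon_breaks`, `lat_breaks`, `n_binned`.
#' @export
density_map <- function(traj, lon_breaks, lat_breaks, window_days = NULL) {
  stopifnot(inherits(traj, "trajectory_set"))
  if (length(lon_breaks) < 2 || length(lat_breaks) < 2)
    stop("bin specification must contain at least one bin per axis")
  keep <- traj$status %in% c(1L, 4L)
  dim(keep) <- dim(traj$status)
  if (!is.null(window_days)) {
    age <- outer(-traj$particles$release_time, traj$snap_time, `+`)
    keep <- keep & age >= window_days[1] * 86400 &
      age <= window_days[2] * 86400
  }
  lon <- traj$lon[keep]; lat <- traj$lat[keep]
  inside <- lon >= lon_breaks[1] & lon <= lon_breaks[length(lon_breaks)] &
    lat >= lat_breaks[1] & lat <= lat_breaks[length(lat_breaks)]
  lon <- lon[inside]; lat <- lat[inside]
  ii <- findInterval(lon, lon_breaks, rightmost.closed = TRUE)
  jj <- findInterval(lat, lat_breaks, rightmost.closed = TRUE)
  counts <- matrix(0L, length(lon_breaks) - 1L, length(lat_breaks) - 1L)
  tab <- table(factor(ii, levels = seq_len(nrow(counts))),
               factor(jj, levels = seq_len(ncol(counts))))
  counts[] <- as.integer(tab)
  structure(list(counts = counts, lon_breaks = lon_breaks,
                 lat_breaks = lat_breaks, n_binned = length(lon)),
            class = "density_map")
}

#' @export
print.density_map <- function(x, ...) {
  cat("<density_map>", nrow(x$counts), "x", ncol(x$counts), "bins,",
      x$n_binned, "(particle, snapshot) pairs binned\n")
  invisible(x)
}

#' Write a connectivity matrix to CSV with a JSON sidecar
#'
#' The CSV has labelled rows (release zones) and columns (recruitment
#' zones); the sidecar records the recruitment window, released totals and
#' summary percentages.
#'
#' @param m A `connectivity_matrix`.
#' @param csv_path,json_path Output paths (sidecar defaults to the CSV path
#'   with a `.json` extension).
#' @return `csv_path`, invisibly.
#' @export
write_connectivity <- function(m, csv_path,
                               json_path = sub("\\.csv$", ".json", csv_path)) {
  mm <- unclass_matrix(m)
  utils::write.csv(as.data.frame(mm), csv_path, row.names = TRUE)
  total <- attr(m, "total_released")
  side <- list(
    window_days = attr(m, "window_days"),
    total_released = total,
    released_per_zone = as.list(stats::setNames(attr(m, "released_per_zone"),
                                                rownames(mm))),
    recruited = sum(m),
    retention_fraction_pct = if (total > 0) retention_fraction(m) else NA,
    source_contribution_pct = if (sum(m) > 0)
      as.list(source_contribution(m)) else NULL,
    sink_proportion_pct = if (sum(m) > 0)
      as.list(sink_proportion(m)) else NULL
  )
  jsonlite::write_json(side, json_path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(csv_path)
}

#' Write a density map to NetCDF
#' @param dm A `density_map`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_density_nc <- function(dm, path) {
  mid <- function(b) (b[-1] + b[-length(b)]) / 2
  dlon <- ncdf4::ncdim_def("longitude", "degrees_east", mid(dm$lon_breaks))
  dlat <- ncdf4::ncdim_def("latitude", "degrees_north", mid(dm$lat_breaks))
  vc <- ncdf4::ncvar_def("count", "1", list(dlon, dlat), prec = "integer")
  nc <- ncdf4::nc_create(path, list(vc))
  on.exit(ncdf4::nc_close(nc), add = TRUE)
  ncdf4::ncvar_put(nc, vc, dm$counts)
  invisible(path)
}
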