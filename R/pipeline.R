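#' Run configuration for the dispersal pipeline
#'
#' Builds and validates the configuration that drives the four pipeline
#' stages (field, transport, connectivity, abundance). Accepts a YAML file
#' path or a nested list; unspecified entries take the desk-scale defaults
#' (the retention preset, the synthetic zone ring, a 100/day x 10-day
#' release, dt = 120 s, 122-day runs with 6-hourly output, the 110-120 day
#' recruitment window, and a synthetic ZINB catch table). Validation is
#' fail-fast: every stage's inputs must be resolvable before any stage runs.
#'
#' @param x Path to a YAML file, or a list with entries `seed`,
#'   `output_dir`, `field`, `zones`, `release`, `ibm`, `connectivity`,
#'   `abundance`.
#' @return A validated list of class `run_config`.
#' @export
run_config <- function(x = list()) {
  if (is.character(x)) {
    if (!file.exists(x)) stop("config file not found: ", x)
    x <- yaml::read_yaml(x)
  }
  def <- list(
    seed = 1L,
    output_dir = "larvconn_out",
    field = list(scenario = "retention", file = NULL, mean_flow_factor = 1),
    zones = list(geojson = NULL,
                 synthetic = list(center = c(-78.85, -33.65),
                                  island_radius = 5, ring_width = 14)),
    release = list(particles_per_day = 100, n_days = 10,
                   start_date = "2013-06-01", depth_range = c(0, 80),
                   mode = "union"),
    ibm = list(dt = 120, duration_days = 122, output_hours = 6,
               beaching = "absorb"),
    connectivity = list(window_days = c(110, 120), density_bins = 40),
    abundance = list(table = NULL,
                     scenario = list(n = 5000, phi = 1.2, pi = 0.35),
                     family = "zinb", ladder = "cumulative")
  )
  cfg <- utils::modifyList(def, x)
  # fail-fast validation of every stage before any stage runs
  if (!is.null(cfg$field$file) && !file.exists(cfg$field$file))
    stop("[field] input file not found: ", cfg$field$file)
  if (is.null(cfg$field$file) &&
      !identical(cfg$field$scenario, "retention"))
    stop("[field] unknown scenario '", cfg$field$scenario,
         "'; available presets: retention")
  if (!is.null(cfg$zones$geojson) && !file.exists(cfg$zones$geojson))
    stop("[zones] GeoJSON not found: ", cfg$zones$geojson)
  if (cfg$connectivity$window_days[2] > cfg$ibm$duration_days)
    stop("[connectivity] recruitment window (",
         cfg$connectivity$window_days[2],
         " d) exceeds the IBM duration (", cfg$ibm$duration_days, " d)")
  if ((cfg$ibm$output_hours * 3600) %% cfg$ibm$dt != 0)
    stop("[ibm] dt must divide the output interval")
  if (!is.null(cfg$abundance$table) && !file.exists(cfg$abundance$table))
    stop("[abundance] trap CSV not found: ", cfg$abundance$table)
  if (!cfg$abundance$family %in% c("poisson", "zip", "nb", "zinb"))
    stop("[abundance] unknown family: ", cfg$abundance$family)
  cfg$seed <- as.integer(cfg$seed)
  class(cfg) <- "run_config"
  cfg
}

# One global seed fanned out to fixed per-stage child seeds, so stages can
# be rerun independently yet reproducibly. Kept below 2^31.
derive_seed <- function(seed, stage) {
  idx <- match(stage, c("field", "release", "ibm", "connectivity",
                        "abundance"))
  as.integer((as.numeric(seed) * 48271 + idx * 9176) %% 2147483629)
}

# Tiny FNV-1a content hash for run manifests (hex string).
config_hash <- function(cfg) {
  bytes <- utf8ToInt(jsonlite::toJSON(unclass(cfg), auto_unbox = TRUE,
                                      digits = NA))
  h <- 2166136261
  for (b in bytes) {
    h <- bitwXor(as.integer(h %% 2^31), b)
    h <- (h * 16777619) %% 2^31
  }
  sprintf("%08x", as.integer(h))
}

write_manifest <- function(cfg, stage, extra, path) {
  jsonlite::write_json(
    c(list(stage = stage, config_hash = config_hash(cfg), seed = cfg$seed),
      extra),
    path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

cfg_zones <- function(cfg) {
  if (!is.null(cfg$zones$geojson)) read_zones_geojson(cfg$zones$geojson)
  else do.call(synthetic_zoneset,
               c(list(center = as.numeric(cfg$zones$synthetic$center)),
                 cfg$zones$synthetic[c("island_radius", "ring_width")]))
}

#' Pipeline stage: produce the velocity field
#'
#' Generates the configured synthetic scenario (or validates a supplied
#' NetCDF file) and writes `field.nc` plus a manifest into the output
#' directory.
#'
#' @param cfg A [run_config()] (or something coercible to one).
#' @return The [velocity_field], invisibly.
#' @export
cmd_make_field <- function(cfg) {
  cfg <- run_config(unclass_cfg(cfg))
  dir.create(cfg$output_dir, showWarnings = FALSE, recursive = TRUE)
  if (!is.null(cfg$field$file)) {
    fld <- read_velocity_nc(cfg$field$file)
  } else {
    sc <- retention_scenario(mean_flow_factor =
                               cfg$field$mean_flow_factor %||% 1)
    sc$seed <- derive_seed(cfg$seed, "field")
    span <- cfg$release$n_days + cfg$ibm$duration_days + 10
    fld <- make_flow_field(sc, retention_grid(cfg$release$start_date,
                                              span_days = span))
  }
  path <- file.path(cfg$output_dir, "field.nc")
  write_velocity_nc(fld, path)
  write_manifest(cfg, "make_field",
                 list(file = "field.nc",
                      grid = list(lon = length(fld$lon), lat = length(fld$lat),
                                  depth = length(fld$depth),
                                  time = length(fld$time))),
                 file.path(cfg$output_dir, "field_manifest.json"))
  invisible(fld)
}

unclass_cfg <- function(cfg) {
  if (inherits(cfg, "run_config")) unclass(cfg) else cfg
}

#' Pipeline stage: run the transport model
#'
#' Builds the release set, integrates every particle, and writes
#' `trajectories.nc` plus a manifest with particle-status tallies. Requires
#' `field.nc` in the output directory (run [cmd_make_field()] first) unless
#' `field` is supplied in memory.
#'
#' @param cfg A [run_config()].
#' @param field Optional in-memory [velocity_field], skipping the file read.
#' @return The `trajectory_set`, invisibly.
#' @export
cmd_run_ibm <- function(cfg, field = NULL) {
  cfg <- run_config(unclass_cfg(cfg))
  if (is.null(field)) {
    path <- file.path(cfg$output_dir, "field.nc")
    if (!file.exists(path))
      stop("[ibm] no field.nc in ", cfg$output_dir,
           "; run cmd_make_field() first")
    field <- read_velocity_nc(path)
  }
  zones <- cfg_zones(cfg)
  sched <- release_schedule(cfg$release$particles_per_day,
                            cfg$release$n_days, cfg$release$start_date,
                            as.numeric(cfg$release$depth_range),
                            seed = derive_seed(cfg$seed, "release"),
                            mode = cfg$release$mode)
  rel <- build_release(sched, zones)
  traj <- advect(rel, field, dt = cfg$ibm$dt,
                 duration_days = cfg$ibm$duration_days,
                 output_hours = cfg$ibm$output_hours,
                 beaching = cfg$ibm$beaching)
  dir.create(cfg$output_dir, showWarnings = FALSE, recursive = TRUE)
  write_trajectories_nc(traj, file.path(cfg$output_dir, "trajectories.nc"))
  fin <- traj$status[, ncol(traj$status)]
  tal <- as.list(table(factor(names(STATUS_LEVELS)[match(fin, STATUS_LEVELS)],
                              levels = names(STATUS_LEVELS))))
  write_manifest(cfg, "run_ibm",
                 list(released = nrow(rel), final_status = tal),
                 file.path(cfg$output_dir, "ibm_manifest.json"))
  invisible(traj)
}

#' Pipeline stage: connectivity and retention summaries
#'
#' Assigns recruits over the configured age window, writes the labelled
#' connectivity matrix CSV with its JSON sidecar, a particle density map,
#' and a summary JSON with the retention fraction and the top source and
#' sink zones.
#'
#' @param cfg A [run_config()].
#' @param traj Optional in-memory `trajectory_set`.
#' @return The `connectivity_matrix`, invisibly.
#' @export
cmd_connectivity <- function(cfg, traj = NULL) {
  cfg <- run_config(unclass_cfg(cfg))
  if (is.null(traj)) {
    path <- file.path(cfg$output_dir, "trajectories.nc")
    if (!file.exists(path))
      stop("[connectivity] no trajectories.nc in ", cfg$output_dir,
           "; run cmd_run_ibm() first")
    traj <- read_trajectories_nc(path)
  }
  zones <- cfg_zones(cfg)
  rec <- recruit(traj, zones,
                 window_days = as.numeric(cfg$connectivity$window_days))
  m <- connectivity_matrix(rec, traj$particles$release_zone,
                           zone_ids = sort(zones$ids),
                           window_days = cfg$connectivity$window_days)
  dir.create(cfg$output_dir, showWarnings = FALSE, recursive = TRUE)
  write_connectivity(m, file.path(cfg$output_dir, "connectivity.csv"))
  nb <- cfg$connectivity$density_bins
  dm <- density_map(traj,
                    seq(min(traj$particles$lon) - 0.3,
                        max(traj$particles$lon) + 0.3, length.out = nb + 1),
                    seq(min(traj$particles$lat) - 0.3,
                        max(traj$particles$lat) + 0.3, length.out = nb + 1),
                    window_days = as.numeric(cfg$connectivity$window_days))
  write_density_nc(dm, file.path(cfg$output_dir, "density.nc"))
  tot <- sum(m)
  if (tot == 0) {
    warning("no particles recruited in the window; empty matrix written")
    summ <- list(recruited = 0)
  } else {
    src <- source_contribution(m); snk <- sink_proportion(m)
    summ <- list(recruited = tot,
                 retention_fraction_pct = retention_fraction(m),
                 top_source = list(zone = names(which.max(src)),
                                   pct = max(src)),
                 top_sink = list(zone = names(which.max(snk)),
                                 pct = max(snk)))
  }
  write_manifest(cfg, "connectivity", summ,
                 file.path(cfg$output_dir, "connectivity_summary.json"))
  invisible(m)
}

#' Pipeline stage: abundance model ladders
#'
#' Fits the simple (m1-m5) and cumulative (M1-M5) predictor ladders for the
#' configured family on the configured trap table (a CSV or the synthetic
#' ZINB scenario) and writes the ranked selection CSV plus the best model's
#' coefficients CSV. A candidate that fails to fit is reported with its
#' error and does not abort the ladder.
#'
#' @param cfg A [run_config()].
#' @return The [model_selection()] table (both ladders combined), invisibly.
#' @export
cmd_fit_abundance <- function(cfg) {
  cfg <- run_config(unclass_cfg(cfg))
  if (!is.null(cfg$abundance$table)) {
    tab <- trap_haul_table(utils::read.csv(cfg$abundance$table,
                                           stringsAsFactors = FALSE))
  } else {
    sc <- do.call(catch_scenario,
                  c(cfg$abundance$scenario,
                    list(seed = derive_seed(cfg$seed, "abundance"))))
    tab <- make_trap_table(sc)
  }
  lad <- abundance_ladders()
  cands <- c(lad$simple, lad$cumulative)
  sel <- model_selection(tab, cands, family = cfg$abundance$family)
  dir.create(cfg$output_dir, showWarnings = FALSE, recursive = TRUE)
  write_model_selection(sel, file.path(cfg$output_dir, "model_selection.csv"),
                        file.path(cfg$output_dir, "coefficients.csv"))
  write_manifest(cfg, "fit_abundance",
                 list(n_records = nrow(tab),
                      best = sel$model[which.min(sel$aic)],
                      best_aic = min(sel$aic, na.rm = TRUE)),
                 file.path(cfg$output_dir, "abundance_manifest.json"))
  invisible(sel)
}

#' Run the whole pipeline
#'
#' Field generation, particle transport, connectivity, and the abundance
#' ladders, in order, with one global seed fanned out deterministically to
#' every stage. Each stage writes its artifacts and manifest into the
#' configured output directory.
#'
#' @param cfg A [run_config()], a YAML path, or a config list.
#' @return List with the `field`, `trajectories`, `connectivity` and
#'   `selection` results, invisibly.
#' @export
run_pipeline <- function(cfg = list()) {
  cfg <- run_config(if (is.character(cfg)) cfg else unclass_cfg(cfg))
  fld <- cmd_make_field(cfg)
  traj <- cmd_run_ibm(cfg, field = fld)
  m <- cmd_connectivity(cfg, traj = traj)
  sel <- cmd_fit_abundance(cfg)
  invisible(list(field = fld, trajectories = traj, connectivity = m,
                 selection = sel))
}

#' Read trajectories written by [write_trajectories_nc()]
#'
#' @param path NetCDF file path.
#' @return A `trajectory_set`.
#' @export
read_trajectories_nc <- function(path) {
  nc <- ncdf4::nc_open(path)
  on.exit(ncdf4::nc_close(nc), add = TRUE)
  g <- function(v) ncdf4::ncvar_get(nc, v, collapse_degen = FALSE)
  lon <- g("lon"); lat <- g("lat"); dep <- g("depth")
  status <- g("status")
  snap_time <- as.numeric(ncdf4::ncvar_get(nc, "snapshot"))
  zl <- strsplit(ncdf4::ncatt_get(nc, 0, "zone_ids")$value, ",")[[1]]
  particles <- data.frame(
    id = seq_len(nrow(lon)),
    release_zone = zl[as.integer(g("release_zone"))],
    release_time = as.numeric(g("release_time")),
    lon = NA_real_, lat = NA_real_, depth = NA_real_)
  status <- matrix(as.integer(status), nrow(lon), ncol(lon))
  dt_guess <- 120
  out_every <- if (length(snap_time) > 1) diff(snap_time[1:2]) else 21600
  first <- match(TRUE, status[1, ] != 0L)
  # duration: recover from the age at which the first particle finished
  fin <- which(status[1, ] == 4L)
  duration <- if (length(fin)) snap_time[fin[1]] - particles$release_time[1]
  else diff(range(snap_time))
  for (p in seq_len(nrow(lon))) {
    s0 <- match(TRUE, status[p, ] != 0L)
    if (!is.na(s0)) {
      particles$lon[p] <- lon[p, s0]
      particles$lat[p] <- lat[p, s0]
      particles$depth[p] <- dep[p, s0]
    }
  }
  structure(list(lon = lon, lat = lat, depth = dep, status = status,
                 snap_time = snap_time, particles = particles,
                 dt = dt_guess, duration = duration,
                 output_every = out_every, beaching = "absorb"),
            class = "trajectory_set")
}
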