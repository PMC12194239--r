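# A tiny zone set used throughout: two unit squares A and B.
square_zones <- function() {
  zone_set(list(
    RC_A = list(lon = c(0, 1, 1, 0), lat = c(0, 0, 1, 1)),
    RC_B = list(lon = c(2, 3, 3, 2), lat = c(0, 0, 1, 1)),
    RC_C = list(lon = c(4, 5, 5, 4), lat = c(0, 0, 1, 1))
  ))
}

test_that("recruit applies the age window and first-contact rule", {
  zs <- square_zones()
  day <- 86400
  snap_time <- c(0, 30, 111, 119, 121) * day
  # p1: stationary inside RC_C its whole life -> RC_C
  # p2: exits the grid on day 30 -> none
  # p3: inside RC_B at age 111 d, RC_C at age 119 d -> RC_B (first contact)
  # p4: offshore during the whole window -> none
  lon <- rbind(c(4.5, 4.5, 4.5, 4.5, 4.5),
               c(0.5, 0.5, 0.5, 0.5, 0.5),
               c(0.5, 9.0, 2.5, 4.5, 4.5),
               c(0.5, 9.0, 9.0, 9.0, 9.0))
  lat <- matrix(0.5, 4, 5)
  status <- rbind(c(1L, 1L, 1L, 1L, 1L),
                  c(1L, 3L, 3L, 3L, 3L),
                  c(1L, 1L, 1L, 1L, 1L),
                  c(1L, 1L, 1L, 1L, 1L))
  traj <- make_traj(lon, lat, status, snap_time,
                    release_zone = c("RC_C", "RC_A", "RC_A", "RC_A"),
                    release_time = rep(0, 4))
  got <- recruit(traj, zs, window_days = c(110, 120))
  expect_identical(got, c("RC_C", NA, "RC_B", NA))
  # window wider than the trajectory duration is refused
  expect_error(recruit(traj, zs, window_days = c(110, 130)), "window")
})

test_that("recruitment is invariant to snapshot permutation after re-sorting", {
  zs <- square_zones()
  day <- 86400
  snap_time <- c(0, 111, 115, 119) * day
  lon <- rbind(c(0.5, 2.5, 0.5, 4.5))
  lat <- matrix(0.5, 1, 4)
  status <- matrix(1L, 1, 4)
  traj <- make_traj(lon, lat, status, snap_time, "RC_A", 0)
  perm <- c(3, 1, 4, 2)
  ord <- order(snap_time[perm])
  traj_p <- make_traj(lon[, perm, drop = FALSE][, ord, drop = FALSE],
                      lat[, perm, drop = FALSE][, ord, drop = FALSE],
                      status, snap_time[perm][ord], "RC_A", 0)
  expect_identical(recruit(traj, zs), recruit(traj_p, zs))
  expect_identical(recruit(traj, zs), "RC_B")
})

test_that("connectivity_matrix tallies by hand and partitions recruits exactly", {
  ids <- c("RC_A", "RC_B", "RC_C")
  rel <- c("RC_A", "RC_A", "RC_B", "RC_B", "RC_C", "RC_C")
  rec <- c("RC_A", "RC_B", "RC_B", NA, "RC_A", "RC_C")
  m <- connectivity_matrix(rec, rel, zone_ids = ids)
  # by hand: A->A, A->B, B->B, (B unrecruited), C->A, C->C
  want <- matrix(c(1L, 1L, 0L,
                   0L, 1L, 0L,
                   1L, 0L, 1L), 3, 3, byrow = TRUE,
                 dimnames = list(release = ids, recruitment = ids))
  expect_equal(unclass(m)[, ], want, ignore_attr = TRUE)
  expect_equal(sum(m), sum(!is.na(rec)))
  # retention (diagonal) and cross-zone recruits partition the grand total
  retained <- sum(diag(unclass(m)[, ]))
  crossed <- sum(rec != rel, na.rm = TRUE)
  expect_equal(retained + crossed, sum(m))
  expect_equal(attr(m, "total_released"), 6L)
  # all-retained and no-recruit edge cases
  m10 <- connectivity_matrix(rep("RC_A", 10), rep("RC_A", 10),
                             zone_ids = ids)
  expect_equal(sum(diag(unclass(m10)[, ])), 10)
  m0 <- connectivity_matrix(rep(NA_character_, 5), rep("RC_B", 5),
                            zone_ids = ids)
  expect_true(all(m0 == 0L))
  expect_error(connectivity_matrix("RC_X", "RC_A", zone_ids = ids),
               "unknown zone")
})

test_that("retention fraction uses the released denominator", {
  ids <- c("RC_A", "RC_B")
  m <- connectivity_matrix(c(rep("RC_A", 5), rep(NA, 95)),
                           rep("RC_A", 100), zone_ids = ids)
  expect_equal(retention_fraction(m), 5.0)
  m0 <- connectivity_matrix(rep(NA_character_, 10), rep("RC_A", 10),
                            zone_ids = ids)
  expect_equal(retention_fraction(m0), 0.0)
  expect_error(retention_fraction(m, total_released = 0), "positive")
})

test_that("source and sink percentages reproduce printed worked examples", {
  # 2013: 699 of 2120 recruits from the top source; 768 of 2120 to the sink
  m13 <- matrix(0L, 6, 6, dimnames = list(ZONE_IDS, ZONE_IDS))
  m13["RC_B", "RC_A"] <- 699L
  m13["RC_A", "RC_C"] <- 768L
  m13["RC_D", "RC_E"] <- 2120L - 699L - 768L
  expect_equal(unname(source_contribution(m13)["RC_B"]), 32.97)
  expect_equal(unname(sink_proportion(m13)["RC_C"]), 36.23)
  expect_equal(round(unname(sink_proportion(m13)["RC_C"])), 36)
  # 2015: 5316 of 15403 contributed; 5076 of 15403 received
  m15 <- matrix(0L, 6, 6, dimnames = list(ZONE_IDS, ZONE_IDS))
  m15["RC_D", "RC_A"] <- 5316L
  m15["RC_A", "RC_F"] <- 5076L
  m15["RC_B", "RC_B"] <- 15403L - 5316L - 5076L
  expect_equal(unname(source_contribution(m15)["RC_D"]), 34.51)
  expect_equal(unname(sink_proportion(m15)["RC_F"]), 32.95)
  # each axis sums to 100 up to rounding
  expect_equal(sum(source_contribution(m15)), 100, tolerance = 0.02)
  expect_equal(sum(sink_proportion(m15)), 100, tolerance = 0.02)
  # degenerate single-zone matrix and uniform matrix
  m1 <- matrix(0L, 6, 6, dimnames = list(ZONE_IDS, ZONE_IDS))
  m1["RC_E", "RC_E"] <- 17L
  expect_equal(unname(source_contribution(m1)["RC_E"]), 100)
  mu <- matrix(1L, 6, 6, dimnames = list(ZONE_IDS, ZONE_IDS))
  expect_true(all(sink_proportion(mu) == 16.67))
  m0 <- matrix(0L, 2, 2)
  expect_error(source_contribution(m0), "no recruits")
  expect_error(sink_proportion(m0), "no recruits")
})

test_that("density map conserves mass and passes a uniformity check", {
  day <- 86400
  # one stationary particle, 9 snapshots -> one bin holds 9
  snap_time <- (0:8) * day
  traj1 <- make_traj(matrix(0.55, 1, 9), matrix(0.25, 1, 9),
                     matrix(1L, 1, 9), snap_time, "RC_A", 0)
  dm <- density_map(traj1, seq(0, 1, 0.1), seq(0, 1, 0.1))
  expect_equal(sum(dm$counts), 9)
  expect_equal(max(dm$counts), 9)
  expect_equal(dm$n_binned, 9)
  # uniform random positions: chi-square does not reject at alpha = 0.01
  set.seed(5)
  n <- 4000
  traju <- make_traj(matrix(runif(n), n, 1), matrix(runif(n), n, 1),
                     matrix(1L, n, 1), 0, rep("RC_A", n), rep(0, n))
  dmu <- density_map(traju, seq(0, 1, 0.25), seq(0, 1, 0.25))
  expect_equal(sum(dmu$counts), n)
  chi <- chisq.test(as.vector(dmu$counts))
  expect_gt(chi$p.value, 0.01)
  expect_error(density_map(traj1, numeric(1), seq(0, 1, 0.5)),
               "at least one bin")
})

test_that("pure retention flow recruits every in-zone particle", {
  # zero velocity: particles stay put, so everyone released inside a zone
  # recruits to its release zone
  zs <- synthetic_zoneset()
  fld <- const_field(u = 0, v = 0,
                     lon = seq(-79.2, -78.5, by = 0.05),
                     lat = seq(-34.0, -33.3, by = 0.05),
                     time = c(as.numeric(as.POSIXct("2013-06-01",
                                                    tz = "UTC")) - 86400,
                              as.numeric(as.POSIXct("2013-12-01",
                                                    tz = "UTC"))))
  rel <- build_release(release_schedule(15, 1, seed = 6), zs)
  traj <- advect(rel, fld)
  rec <- recruit(traj, zs)
  m <- connectivity_matrix(rec, rel$release_zone, zone_ids = zs$ids)
  expect_equal(retention_fraction(m), 100)
  expect_equal(sum(m), sum(diag(unclass(m)[, ])))
})

test_that("connectivity CSV + JSON sidecar round out the reporting surface", {
  ids <- c("RC_A", "RC_B")
  m <- connectivity_matrix(c("RC_A", "RC_B", NA), c("RC_A", "RC_A", "RC_B"),
                           zone_ids = ids)
  csv <- tempfile(fileext = ".csv")
  write_connectivity(m, csv)
  back <- utils::read.csv(csv, row.names = 1)
  expect_equal(as.matrix(back), unclass(m)[, ], ignore_attr = TRUE)
  side <- jsonlite::fromJSON(sub("\\.csv$", ".json", csv))
  expect_equal(side$recruited, 2)
  expect_equal(side$total_released, 3)
  unlink(c(csv, sub("\\.csv$", ".json", csv)))
})
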