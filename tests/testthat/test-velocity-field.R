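test_that("constructor enforces monotone coordinates and finite water values", {
  dims <- c(2, 2, 2, 2)
  u <- array(0.1, dims); v <- array(0, dims)
  expect_error(velocity_field(0:1, c(1, 0), c(0, 10), c(0, 1), u, v),
               "strictly increasing")
  expect_error(velocity_field(0:1, 0:1, c(10, 0), c(0, 1), u, v),
               "strictly increasing")
  ubad <- u; ubad[1, 1, 1, 1] <- Inf
  expect_error(velocity_field(0:1, 0:1, c(0, 10), c(0, 1), ubad, v,
                              mask = array(TRUE, dims[1:3])),
               "finite")
})

test_that("NetCDF round-trip is lossless, with and without w", {
  set.seed(11)
  dims <- c(4, 3, 3, 2)
  mask <- array(TRUE, dims[1:3]); mask[2, 2, ] <- FALSE
  mk <- function(with_w) {
    u <- array(rnorm(prod(dims)), dims)
    v <- array(rnorm(prod(dims)), dims)
    velocity_field(seq(-79, -78.4, length.out = 4),
                   seq(-34, -33.6, length.out = 3),
                   c(0, 50, 100), c(0, 86400),
                   u = u, v = v,
                   w = if (with_w) array(rnorm(prod(dims)) / 100, dims),
                   mask = mask)
  }
  for (with_w in c(TRUE, FALSE)) {
    fld <- mk(with_w)
    path <- tempfile(fileext = ".nc")
    write_velocity_nc(fld, path)
    back <- read_velocity_nc(path)
    expect_equal(back$lon, fld$lon)
    expect_equal(back$lat, fld$lat)
    expect_equal(back$depth, fld$depth)
    expect_equal(back$time, fld$time)
    expect_equal(back$mask, fld$mask)
    wet <- array(rep(fld$mask, dims[4]), dims)
    expect_equal(back$u[wet], fld$u[wet])
    expect_equal(back$v[wet], fld$v[wet])
    if (with_w) expect_equal(back$w[wet], fld$w[wet])
    else expect_null(back$w)
    unlink(path)
  }
})

test_that("reader flags missing velocity variables by role", {
  fld <- const_field()
  path <- tempfile(fileext = ".nc")
  write_velocity_nc(fld, path)
  expect_error(read_velocity_nc(path, var_names = c(u = "nope", v = "vo")),
               "role 'u'")
  unlink(path)
})

test_that("absent w is treated as zero by interpolation", {
  fld <- const_field(u = 0.3, v = -0.2, w = NULL)
  res <- interpolate_velocity(fld, 0.2, 0.1, 30, 1e5)
  expect_identical(res$w, 0)
  expect_equal(res$u, 0.3)
})

test_that("interpolation is exact at nodes and linear at midpoints", {
  lon <- c(0, 1); lat <- c(0, 1); depth <- c(0, 10); time <- c(0, 100)
  dims <- c(2, 2, 2, 2)
  u <- array(0.1, dims); u[2, , , ] <- 0.3
  fld <- velocity_field(lon, lat, depth, time, u, array(0, dims))
  expect_equal(interpolate_velocity(fld, 0, 0, 0, 0)$u, 0.1)
  expect_equal(interpolate_velocity(fld, 1, 1, 10, 100)$u, 0.3)
  expect_equal(interpolate_velocity(fld, 0.5, 0.2, 3, 40)$u, 0.2)
})

test_that("interpolation matches an independent brute-force oracle", {
  set.seed(42)
  dims <- c(3, 3, 3, 2)
  mask <- array(TRUE, dims[1:3])
  mask[2, 3, ] <- FALSE  # a land column to exercise renormalization
  fld <- velocity_field(c(0, 0.4, 1), c(-1, 0, 0.6), c(0, 20, 60),
                        c(0, 500),
                        u = array(rnorm(prod(dims)), dims),
                        v = array(rnorm(prod(dims)), dims),
                        w = array(rnorm(prod(dims)), dims), mask = mask)
  for (i in 1:25) {
    q <- c(runif(1, 0, 1), runif(1, -1, 0.6), runif(1, 0, 60),
           runif(1, 0, 500))
    got <- interpolate_velocity(fld, q[1], q[2], q[3], q[4])
    want <- oracle_interp(fld, q[1], q[2], q[3], q[4])
    expect_equal(unlist(got), want, tolerance = 1e-12,
                 ignore_attr = TRUE)
  }
})

test_that("a field linear in each coordinate is reproduced to machine precision", {
  lon <- c(0, 0.5, 1); lat <- c(0, 1, 2); depth <- c(0, 30, 60)
  time <- c(0, 1000)
  f <- function(x, y, z, t) 0.02 * x - 0.01 * y + 0.001 * z + 1e-5 * t + 0.1
  u <- array(0, c(3, 3, 3, 2))
  for (i in 1:3) for (j in 1:3) for (k in 1:3) for (l in 1:2)
    u[i, j, k, l] <- f(lon[i], lat[j], depth[k], time[l])
  fld <- velocity_field(lon, lat, depth, time, u, u)
  q <- list(lon = 0.37, lat = 1.21, depth = 41.7, t = 613)
  got <- interpolate_velocity(fld, q$lon, q$lat, q$depth, q$t)$u
  expect_equal(got, f(q$lon, q$lat, q$depth, q$t), tolerance = 1e-14)
})

test_that("interpolation is bounded by enclosing water-node values and errors out of bounds", {
  set.seed(7)
  fld <- velocity_field(c(0, 1), c(0, 1), c(0, 10), c(0, 1),
                        u = array(runif(16), c(2, 2, 2, 2)),
                        v = array(runif(16), c(2, 2, 2, 2)))
  got <- interpolate_velocity(fld, 0.3, 0.7, 4, 0.5)$u
  expect_gte(got, min(fld$u))
  expect_lte(got, max(fld$u))
  expect_error(interpolate_velocity(fld, 2, 0.5, 4, 0.5), "outside")
})

test_that("a point fully enclosed by land interpolates to zero", {
  dims <- c(2, 2, 1, 1)
  fld <- velocity_field(c(0, 1), c(0, 1), 0, 0,
                        u = array(1, dims), v = array(1, dims),
                        mask = array(FALSE, dims[1:3]))
  res <- interpolate_velocity(fld, 0.5, 0.5, 0, 0)
  expect_equal(unlist(res), c(u = 0, v = 0, w = 0))
})

test_that("seasonal mean velocity averages the right months, depths and cells", {
  jun1 <- as.numeric(as.POSIXct("2013-06-01", tz = "UTC"))
  jul1 <- as.numeric(as.POSIXct("2013-07-01", tz = "UTC"))
  sep1 <- as.numeric(as.POSIXct("2013-09-01", tz = "UTC"))
  dims <- c(2, 2, 3, 3)
  u <- array(0.05, dims)
  u[, , , 2] <- 0.2    # July
  u[, , , 3] <- 9      # September: must be excluded
  u[, , 3, ] <- 9      # 120 m: below the 100 m cut
  mask <- array(TRUE, dims[1:3]); mask[1, 2, ] <- FALSE
  fld <- velocity_field(0:1, 0:1, c(0, 50, 120), c(jun1, jul1, sep1),
                        u = u, v = u, mask = mask)
  mm <- seasonal_mean_velocity(fld, months = c("June", "July"),
                               max_depth = 100)
  expect_equal(mm$u[1, 1], mean(c(0.05, 0.2)))
  expect_true(is.na(mm$u[1, 2]))
  expect_error(seasonal_mean_velocity(fld, months = 1), "no time steps")
  # constant field sanity
  cf <- const_field(u = 0.05,
                    time = c(jun1, jul1))
  expect_true(all(seasonal_mean_velocity(cf, 6:7)$u == 0.05))
})
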