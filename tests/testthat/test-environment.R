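test_that("mixed-layer PAR matches its closed form and limits", {
  # vanishing mixed layer: the full PAR fraction of incoming radiation
  expect_equal(par_mixed_layer(100, 1e-9) / 100, 0.42)
  # no light in, no light out
  expect_identical(par_mixed_layer(0, 5), 0)
  # quadrature oracle: depth average of f*I0*exp(-k z) over [0, H]
  cases <- expand.grid(I0 = c(30, 100, 250), H = c(0.5, 10, 40),
                       k = c(0.1, 0.2, 0.5))
  for (r in seq_len(nrow(cases))) {
    num <- stats::integrate(function(z) {
      0.42 * cases$I0[r] * exp(-cases$k[r] * z)
    }, 0, cases$H[r], rel.tol = 1e-12)$value / cases$H[r]
    expect_equal(par_mixed_layer(cases$I0[r], cases$H[r],
                                 attenuation = cases$k[r]),
                 num, tolerance = 1e-9)
  }
  expect_error(par_mixed_layer(100, 0), "positive")
  expect_error(par_mixed_layer(100, -3), "positive")
})

test_that("PAR is monotone: decreasing in MLD, increasing in light, bounded", {
  H <- sort(runif(50, 0.01, 60))
  p <- par_mixed_layer(200, H)
  expect_true(all(diff(p) < 0))
  I0 <- sort(runif(50, 0, 400))
  p2 <- par_mixed_layer(I0, 12)
  expect_true(all(diff(p2) > 0))
  expect_true(all(p <= 0.42 * 200 + 1e-12))
  expect_true(all(p >= 0))
})

test_that("distance to coast matches the closed-form neighbour distance", {
  lon <- seq(10, 11, by = 0.05)
  lat <- seq(55, 55.5, by = 0.05)
  m <- matrix(FALSE, length(lat), length(lon))
  m[, 1] <- TRUE # single land column on the west edge
  grid <- bt_grid(lon, lat, m)
  d <- distance_to_coast(grid)
  # wet node adjacent to land at the same latitude, spacing 0.05 degrees
  j <- 3
  expected <- 6371000 * cos(lat[j] * pi / 180) * (0.05 * pi / 180) / 1852
  expect_equal(d[j, 2], expected, tolerance = 1e-5)
  expect_true(all(d[m] == 0))
})

test_that("distance field equals the brute-force oracle on a small grid", {
  set.seed(17)
  lon <- seq(12, 14, length.out = 20)
  lat <- seq(54, 56, length.out = 20)
  m <- matrix(runif(400) < 0.2, 20, 20)
  m[10, 10] <- FALSE
  m[1, 1] <- TRUE
  grid <- bt_grid(lon, lat, m)
  d <- distance_to_coast(grid)
  oracle <- brute_distance_to_coast(grid)
  expect_equal(d, oracle, tolerance = 1e-9)
  expect_true(all(d[!m] > 0))
  expect_error(distance_to_coast(wet_grid()), "no land")
})

test_that("distance field satisfies the great-circle Lipschitz bound", {
  grid <- gen_basin(n_lon = 24, n_lat = 18, peninsula = TRUE)
  d <- distance_to_coast(grid)
  wet <- which(!grid$land_mask, arr.ind = TRUE)
  set.seed(5)
  a <- wet[sample(nrow(wet), 100, replace = TRUE), , drop = FALSE]
  b <- wet[sample(nrow(wet), 100, replace = TRUE), , drop = FALSE]
  gc_nm <- ref_haversine(grid$lon[a[, 2]], grid$lat[a[, 1]],
                         grid$lon[b[, 2]], grid$lat[b[, 1]]) / 1852
  gap <- abs(d[a] - d[b])
  expect_true(all(gap <= gc_nm + 1e-6))
})

test_that("environmental sampling reproduces constants and node time series", {
  grid <- wet_grid(lon = seq(10, 14, length.out = 9),
                   lat = seq(54, 56, length.out = 5))
  times <- seq(0, 5 * 86400, by = 10800)
  ny <- 5; nx <- 9
  sst <- const_series(grid, times, matrix(16, ny, nx), "sst")
  mld <- const_series(grid, times, matrix(10, ny, nx), "mld")
  swr <- const_series(grid, times, matrix(200, ny, nx), "swr")
  dist <- matrix(25, ny, nx)
  vel <- uniform_velocity(grid, times, 0, 0)
  seeds <- tibble::tibble(drifter_id = 1:2, lon = c(11, 12), lat = c(55, 55.5),
                          label = factor(c("bloom", "no_bloom"),
                                         levels = c("bloom", "no_bloom",
                                                    "discarded")))
  traj <- advect_backward(seeds, vel$u, vel$v, times[length(times)],
                          window_days = 5, dt_hours = 3)
  env <- sample_environment(traj, sst, mld, swr, dist)
  expect_true(all(env$sst == 16))
  expect_true(all(env$mld == 10))
  expect_true(all(env$dist_coast_nm == 25))
  expect_equal(env$par, rep(par_mixed_layer(200, 10), nrow(env)))

  # a stationary drifter at a node samples exactly that node's time series
  vary <- array(rep(seq_along(times), ny * nx), c(length(times), ny, nx))
  for (k in seq_along(times)) vary[k, , ] <- k + 0.1 * row(matrix(0, ny, nx))
  sst2 <- bt_field_series(grid, times, vary, "sst")
  seeds2 <- tibble::tibble(drifter_id = 1L, lon = grid$lon[3],
                           lat = grid$lat[2])
  traj2 <- advect_backward(seeds2, vel$u, vel$v, times[length(times)],
                           window_days = 5, dt_hours = 3)
  env2 <- sample_environment(traj2, sst2, mld, swr, dist)
  node_series <- vary[, 2, 3]
  # trajectory offsets run from the event backwards: reverse the series
  expect_equal(env2$sst, rev(node_series))
})

test_that("PAR in a sampled history is consistent with its SWR and MLD columns", {
  sc <- simulate_scenario(n_lon = 24, n_lat = 18, days = 12, seed = 2)
  seeds <- classify_drifters(
    seed_drifters(sc$grid, 40, bbox = c(13, 24, 54, 60), seed = 2), sc$mask)
  traj <- advect_backward(seeds, sc$u, sc$v, sc$t_event,
                          window_days = 10, dt_hours = 3)
  env <- sample_environment(traj, sc$sst, sc$mld, sc$swr, sc$dist)
  # independently resample shortwave radiation onto the active points
  swr_sampled <- rep(NA_real_, nrow(env))
  for (tr in unique(env$time_rel_s)) {
    rows <- which(env$time_rel_s == tr & env$status == "active")
    if (!length(rows)) next
    swr_sampled[rows] <- interp_spacetime(sc$swr, env$lon[rows],
                                          env$lat[rows], sc$t_event + tr,
                                          "na")
  }
  ok <- !is.na(env$par)
  expect_true(any(ok))
  expect_equal(env$par[ok],
               par_mixed_layer(swr_sampled[ok], env$mld[ok]))
  # inactive points carry no environmental samples
  inactive <- env$status != "active"
  if (any(inactive)) {
    expect_true(all(is.na(env$sst[inactive])))
    expect_true(all(is.na(env$par[inactive])))
    expect_true(all(is.na(env$dist_coast_nm[inactive])))
  }
})
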