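test_that("a single Euler step matches the closed-form arithmetic", {
  # zero velocity: identity
  s <- step_euler_backward(15, 55, 0, 0, 10800)
  expect_identical(s$lon, 15)
  expect_identical(s$lat, 55)

  # u = 1 m/s, dt = 3 h at 55N, independently hand-computed
  s <- step_euler_backward(15, 55, 1, 0, 10800)
  expect_equal(s$lon, 15 - (1 * 10800) / (6371000 * cos(55 * pi / 180)) *
                 (180 / pi))
  expect_equal(s$lat, 55)

  # backward then forward with frozen velocity returns the start exactly
  # (zonal flow: the latitude, and with it the metric factor, is unchanged)
  b <- step_euler_backward(15.3, 56.7, 0.4, 0, 10800)
  f <- list(lon = b$lon + 0.4 * 10800 /
              (6371000 * cos(b$lat * pi / 180)) * (180 / pi),
            lat = b$lat)
  expect_equal(f$lon, 15.3)
  expect_equal(f$lat, 56.7)
  # the meridional update is linear, hence exactly invertible for any v
  b2 <- step_euler_backward(15.3, 56.7, 0, -0.2, 10800)
  expect_equal(b2$lat + (-0.2) * 10800 / 6371000 * (180 / pi), 56.7)
})

test_that("uniform steady flow back-traces to the closed-form displacement", {
  st <- small_tracking_setup(u = 0.05, v = 0, days = 10)
  traj <- advect_backward(st$seeds, st$u, st$v, st$t_event,
                          window_days = 10, dt_hours = 3)
  far <- traj[traj$time_rel_s == min(traj$time_rel_s), ]
  T_s <- 10 * 86400
  # back-traced position lies exactly U*T against the flow (west of the seed)
  expect_equal(far$lon, 16 - 0.05 * T_s / (6371000 * cos(57 * pi / 180)) *
                 (180 / pi), tolerance = 1e-12)
  expect_equal(far$lat, 57)
  expect_identical(as.character(far$status), "active")
})

test_that("zero velocity keeps every trajectory constant and unbeached", {
  st <- small_tracking_setup(u = 0, v = 0, days = 5)
  seeds <- tibble::tibble(drifter_id = 1:5,
                          lon = c(12, 14, 16, 18, 20),
                          lat = c(55, 56, 57, 58, 59))
  traj <- advect_backward(seeds, st$u, st$v, st$t_event,
                          window_days = 5, dt_hours = 3)
  expect_true(all(traj$status == "active"))
  per <- dplyr::group_by(traj, drifter_id)
  expect_true(all(dplyr::summarise(per, c = max(lon) - min(lon))$c == 0))
  expect_true(all(dplyr::summarise(per, c = max(lat) - min(lat))$c == 0))
})

test_that("solid-body rotation shows first-order convergence in dt", {
  # near-equatorial basin so the spherical metric is essentially flat and
  # the Euler radius drift dominates the error budget
  grid <- wet_grid(lon = seq(0, 8, length.out = 33),
                   lat = seq(-3, 3, length.out = 25))
  times <- seq(0, 60 * 86400, by = 10800)
  vel <- gen_velocity(grid, times, regime = "solid_rotation",
                      period_days = 30)
  seeds <- tibble::tibble(drifter_id = 1L, lon = 4.6, lat = 0)
  r_drift <- function(substeps) {
    traj <- advect_backward(seeds, vel$u, vel$v, times[length(times)],
                            window_days = 60, dt_hours = 3,
                            substeps = substeps)
    far <- traj[traj$time_rel_s == min(traj$time_rel_s), ]
    p0 <- metric_xy(grid, 4.6, 0)
    p1 <- metric_xy(grid, far$lon, far$lat)
    abs(sqrt(p1$x^2 + p1$y^2) - sqrt(p0$x^2 + p0$y^2))
  }
  e1 <- r_drift(1)
  e2 <- r_drift(2)
  expect_gt(e1, 0)
  # halving dt halves the radius error within 20 %
  expect_gt(e1 / e2, 2 * 0.8)
  expect_lt(e1 / e2, 2 * 1.2)
})

test_that("forward-then-backward inverts in steady flow and converges in unsteady flow", {
  # v = 0 keeps each drifter on its latitude circle, where the Euler step
  # is an exact step-wise involution
  st <- small_tracking_setup(u = 0.04, v = 0, days = 8)
  seeds <- tibble::tibble(drifter_id = 1:3, lon = c(15, 16, 17),
                          lat = c(56, 57, 57.5))
  fwd <- advect_forward(seeds, st$u, st$v, st$times[1],
                        window_days = 8, dt_hours = 3)
  ends <- fwd[fwd$time_rel_s == max(fwd$time_rel_s), ]
  back <- advect_backward(
    tibble::tibble(drifter_id = ends$drifter_id, lon = ends$lon,
                   lat = ends$lat),
    st$u, st$v, st$times[1] + 8 * 86400, window_days = 8, dt_hours = 3)
  rec <- back[back$time_rel_s == min(back$time_rel_s), ]
  expect_equal(rec$lon, seeds$lon, tolerance = 1e-9)
  expect_equal(rec$lat, seeds$lat, tolerance = 1e-9)

  # time-varying double gyre: forward/backward misfit shrinks as dt shrinks
  grid <- wet_grid(lon = seq(10, 20, length.out = 41),
                   lat = seq(54, 58, length.out = 25))
  times <- seq(0, 10 * 86400, by = 10800)
  vel <- gen_velocity(grid, times, regime = "double_gyre", amplitude = 0.05,
                      eps = 0.25, perturb_period_days = 5)
  sd0 <- tibble::tibble(drifter_id = 1L, lon = 13.4, lat = 55.9)
  misfit <- function(substeps) {
    fwd <- advect_forward(sd0, vel$u, vel$v, times[1], window_days = 10,
                          dt_hours = 3, substeps = substeps)
    e <- fwd[fwd$time_rel_s == max(fwd$time_rel_s), ]
    bwd <- advect_backward(tibble::tibble(drifter_id = 1L, lon = e$lon,
                                          lat = e$lat),
                           vel$u, vel$v, times[length(times)],
                           window_days = 10, dt_hours = 3,
                           substeps = substeps)
    r <- bwd[bwd$time_rel_s == min(bwd$time_rel_s), ]
    ref_haversine(r$lon, r$lat, 13.4, 55.9)
  }
  m1 <- misfit(1)
  m4 <- misfit(4)
  expect_lt(m4, m1)
})

test_that("beaching freezes drifters at their last wet position", {
  # thick land block on the western half: a west-flowing parcel must beach
  lon <- seq(10, 20, length.out = 21)
  lat <- seq(54, 58, length.out = 9)
  m <- matrix(FALSE, 9, 21)
  m[, 1:8] <- TRUE
  grid <- bt_grid(lon, lat, m)
  times <- seq(0, 20 * 86400, by = 10800)
  vel <- uniform_velocity(grid, times, u = 0.3, v = 0)
  seeds <- tibble::tibble(drifter_id = 1L, lon = 15, lat = 56)
  traj <- advect_backward(seeds, vel$u, vel$v, times[length(times)],
                          window_days = 20, dt_hours = 3)
  expect_true("beached" %in% traj$status)
  frozen <- traj[traj$status == "beached", ]
  expect_equal(length(unique(frozen$lon)), 1L)
  expect_equal(length(unique(frozen$lat)), 1L)
  # frozen west of the seed, still east of (or at) the land block interior
  expect_lt(unique(frozen$lon)[1], 15)
  # status never reverts: once beached, beached at all earlier offsets
  s <- traj$status[order(-traj$time_rel_s)]
  first <- match("beached", as.character(s))
  expect_true(all(s[first:length(s)] == "beached"))

  # seeds on land are beached immediately
  land_seed <- tibble::tibble(drifter_id = 1L, lon = 11, lat = 56)
  traj2 <- advect_backward(land_seed, vel$u, vel$v, times[length(times)],
                           window_days = 5, dt_hours = 3)
  expect_true(all(traj2$status == "beached"))
  expect_true(all(traj2$lon == 11))
})

test_that("ensemble bookkeeping: domain bounds, status conservation, determinism", {
  grid <- gen_basin(n_lon = 30, n_lat = 24)
  times <- gen_times(days = 20)
  vel <- gen_velocity(grid, times, regime = "double_gyre", amplitude = 0.3)
  seeds <- seed_drifters(grid, n_drifters = 60, bbox = c(13, 24, 54, 60),
                         seed = 5)
  t_event <- times[length(times)]
  traj <- advect_backward(seeds, vel$u, vel$v, t_event,
                          window_days = 18, dt_hours = 3)

  expect_true(all(traj$lon >= min(grid$lon) & traj$lon <= max(grid$lon)))
  expect_true(all(traj$lat >= min(grid$lat) & traj$lat <= max(grid$lat)))
  counts <- dplyr::count(traj, time_rel_s)
  expect_true(all(counts$n == 60))
  # seeded positions reproduced at offset zero
  at0 <- traj[traj$time_rel_s == 0, ]
  expect_equal(at0$lon, seeds$lon)
  expect_equal(at0$lat, seeds$lat)
  # bit-exact reproducibility: no hidden randomness in the tracker
  traj2 <- advect_backward(seeds, vel$u, vel$v, t_event,
                           window_days = 18, dt_hours = 3)
  expect_identical(traj, traj2)
})

test_that("insufficient temporal coverage fails before integrating", {
  st <- small_tracking_setup(days = 5)
  expect_error(advect_backward(st$seeds, st$u, st$v, st$t_event,
                               window_days = 6, dt_hours = 3),
               "does not cover")
  expect_error(advect_backward(st$seeds, st$u, st$v, st$t_event,
                               window_days = 5, dt_hours = 7),
               "integer multiple")
})
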