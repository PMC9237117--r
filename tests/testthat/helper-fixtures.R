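# Shared fixtures: tiny grids, analytic field builders, independent oracles.

# all-wet grid (no land): handy for pure-interpolation and tracker tests
wet_grid <- function(lon = seq(10, 20, length.out = 21),
                     lat = seq(54, 60, length.out = 13)) {
  bt_grid(lon, lat, matrix(FALSE, length(lat), length(lon)))
}

# field series with the same 2-D slice at every snapshot
const_series <- function(grid, times, slice, name = "f", units = "") {
  nt <- length(times)
  vals <- array(rep(as.vector(slice), each = nt),
                c(nt, nrow(slice), ncol(slice)))
  bt_field_series(grid, times, vals, name, units)
}

# spatially uniform velocity pair on an all-wet or masked grid
uniform_velocity <- function(grid, times, u = 0.1, v = 0) {
  ny <- length(grid$lat); nx <- length(grid$lon)
  list(u = const_series(grid, times, matrix(u, ny, nx), "u", "m s-1"),
       v = const_series(grid, times, matrix(v, ny, nx), "v", "m s-1"))
}

# independent haversine (not geosphere), radius 6371000 m, result in metres
ref_haversine <- function(lon1, lat1, lon2, lat2, r = 6371000) {
  d <- pi / 180
  a <- sin((lat2 - lat1) * d / 2)^2 +
    cos(lat1 * d) * cos(lat2 * d) * sin((lon2 - lon1) * d / 2)^2
  2 * r * asin(pmin(1, sqrt(a)))
}

# brute-force distance-to-coast oracle: explicit loop over wet x land nodes
brute_distance_to_coast <- function(grid) {
  m <- grid$land_mask
  out <- matrix(0, nrow(m), ncol(m))
  land <- which(m, arr.ind = TRUE)
  for (j in seq_along(grid$lat)) {
    for (i in seq_along(grid$lon)) {
      if (m[j, i]) next
      best <- Inf
      for (k in seq_len(nrow(land))) {
        dk <- ref_haversine(grid$lon[i], grid$lat[j],
                            grid$lon[land[k, 2]], grid$lat[land[k, 1]])
        if (dk < best) best <- dk
      }
      out[j, i] <- best / 1852
    }
  }
  out
}

# local metric coordinates (m) about the basin centre, matching gen_velocity
metric_xy <- function(grid, lon, lat, earth_radius = 6371000) {
  d <- pi / 180
  lon0 <- mean(range(grid$lon)); lat0 <- mean(range(grid$lat))
  list(x = earth_radius * cos(lat0 * d) * (lon - lon0) * d,
       y = earth_radius * (lat - lat0) * d)
}

# small ready-made back-tracing setup on an all-wet grid
small_tracking_setup <- function(u = 0.05, v = 0, days = 10,
                                 lon0 = 16, lat0 = 57) {
  grid <- wet_grid(lon = seq(10, 22, length.out = 25),
                   lat = seq(54, 60, length.out = 13))
  times <- seq(0, days * 86400, by = 3 * 3600)
  vel <- uniform_velocity(grid, times, u, v)
  seeds <- tibble::tibble(drifter_id = 1L, lon = lon0, lat = lat0)
  list(grid = grid, times = times, u = vel$u, v = vel$v, seeds = seeds,
       t_event = times[length(times)])
}
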