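#' Generate a rectangular basin grid with a land rim
#'
#' A regular lon/lat mesh whose outermost ring of nodes is land (the basin
#' is surrounded by solid walls, like the enclosed Baltic model domain) and
#' whose interior is wet. An optional peninsula — a one-node-wide land spur
#' reaching from the western wall a third of the way into the basin —
#' makes distance-to-coast fields non-trivial.
#'
#' @param n_lon,n_lat Node counts (each \eqn{\ge} 8).
#' @param lon_range,lat_range Extent in degrees; defaults cover the central
#'   Baltic study box with margin.
#' @param peninsula Add the land spur? Default `FALSE`.
#' @return A [bt_grid()].
#' @export
gen_basin <- function(n_lon = 80, n_lat = 60,
                      lon_range = c(12, 25), lat_range = c(53.5, 60.5),
                      peninsula = FALSE) {
  if (n_lon < 8 || n_lat < 8) {
    stop("basin needs at least 8 x 8 nodes", call. = FALSE)
  }
  lon <- seq(lon_range[1], lon_range[2], length.out = n_lon)
  lat <- seq(lat_range[1], lat_range[2], length.out = n_lat)
  m <- matrix(FALSE, n_lat, n_lon)
  m[c(1, n_lat), ] <- TRUE
  m[, c(1, n_lon)] <- TRUE
  if (peninsula) {
    m[round(n_lat / 2), 1:round(n_lon / 3)] <- TRUE
  }
  bt_grid(lon, lat, m)
}

# default synthetic event time: a mid-July bloom peak
default_event_time <- function() {
  as.numeric(as.POSIXct("2013-07-15 12:00:00", tz = "UTC"))
}

# snapshot time axis ending at t_end, 3-hourly by default
gen_times <- function(days = 63, dt_hours = 3, t_end = default_event_time()) {
  seq(t_end - days * 86400, t_end, by = dt_hours * 3600)
}

#' Generate an analytic surface-velocity field series
#'
#' Snapshot stack at a 3-hourly cadence over (at least) the tracing window,
#' in one of three regimes:
#' \describe{
#'   \item{`uniform`}{constant `(speed, 0)` everywhere wet;}
#'   \item{`solid_rotation`}{rigid rotation about the basin centre in local
#'     metric coordinates, `u = -omega * dy`, `v = omega * dx` with
#'     `omega = 2 * pi / period_days`;}
#'   \item{`double_gyre`}{the classic two-cell streamfunction flow on the
#'     basin rectangle (no normal flow through the walls), optionally
#'     time-periodic with perturbation strength `eps`.}
#' }
#'
#' @param grid A [bt_grid()].
#' @param times Snapshot times (seconds since epoch), e.g. from the
#'   default: 3-hourly over 63 days ending mid-July.
#' @param regime `"uniform"`, `"solid_rotation"` or `"double_gyre"`.
#' @param speed Uniform-flow speed (m s\eqn{^{-1}}, default 0.1).
#' @param period_days Solid-rotation period (default 120 days, giving
#'   basin-scale speeds of order 0.1 m s\eqn{^{-1}}).
#' @param amplitude Double-gyre velocity scale (m s\eqn{^{-1}}, default 0.1).
#' @param eps Double-gyre time-perturbation strength in `[0, 0.5)`
#'   (default 0 = steady).
#' @param perturb_period_days Period of the double-gyre perturbation
#'   (default 10 days).
#' @param earth_radius Sphere radius (m) for the local metric.
#' @return List with elements `u` and `v`, both [bt_field_series()].
#' @export
gen_velocity <- function(grid, times = gen_times(),
                         regime = c("uniform", "solid_rotation",
                                    "double_gyre"),
                         speed = 0.1, period_days = 120, amplitude = 0.1,
                         eps = 0, perturb_period_days = 10,
                         earth_radius = 6371000) {
  regime <- match.arg(regime)
  ny <- length(grid$lat); nx <- length(grid$lon)
  nt <- length(times)
  deg <- pi / 180
  lat0 <- mean(range(grid$lat)); lon0 <- mean(range(grid$lon))
  # local metric coordinates (m) about the basin centre
  x <- earth_radius * cos(lat0 * deg) * (grid$lon - lon0) * deg
  y <- earth_radius * (grid$lat - lat0) * deg
  xm <- matrix(x, ny, nx, byrow = TRUE)
  ym <- matrix(y, ny, nx)

  u <- array(NA_real_, c(nt, ny, nx))
  v <- array(NA_real_, c(nt, ny, nx))
  if (regime == "uniform") {
    u[] <- speed; v[] <- 0
  } else if (regime == "solid_rotation") {
    omega <- 2 * pi / (period_days * 86400)
    for (k in seq_len(nt)) {
      u[k, , ] <- -omega * ym
      v[k, , ] <- omega * xm
    }
  } else {
    # unit-square mapping: sx in [0, 2], sy in [0, 1] across the full extent
    sx <- 2 * (xm - min(x)) / (max(x) - min(x))
    sy <- (ym - min(y)) / (max(y) - min(y))
    for (k in seq_len(nt)) {
      tau <- times[k] - times[1]
      a <- eps * sin(2 * pi * tau / (perturb_period_days * 86400))
      b <- 1 - 2 * a
      f <- a * sx^2 + b * sx
      dfdx <- 2 * a * sx + b
      u[k, , ] <- -pi * amplitude * sin(pi * f) * cos(pi * sy)
      v[k, , ] <- pi * amplitude * cos(pi * f) * sin(pi * sy) * dfdx
    }
  }
  list(u = bt_field_series(grid, times, u, "u", "m s-1"),
       v = bt_field_series(grid, times, v, "v", "m s-1"))
}

#' Generate smooth synthetic forcing fields
#'
#' Sea surface temperature, mixed-layer depth and downward shortwave
#' radiation with simple large-scale structure: a meridional SST gradient,
#' a zonal MLD gradient, a diurnal cycle on the radiation, and optional
#' white noise per node and snapshot. Units and magnitudes emulate a
#' Baltic summer surface layer.
#'
#' @param grid A [bt_grid()].
#' @param times Snapshot times (seconds since epoch).
#' @param sst_mean Basin-mean SST (degC, default 16).
#' @param sst_lat_gradient SST change per degree latitude (default -0.3).
#' @param mld_mean Mean mixed-layer depth (m, default 10).
#' @param mld_lon_gradient MLD change per degree longitude (default 0.3).
#' @param swr_mean Daily-mean shortwave radiation (W m\eqn{^{-2}},
#'   default 250).
#' @param swr_diurnal_amplitude Amplitude of the diurnal cycle
#'   (default 150; the cycle is clipped at zero).
#' @param noise_sd Named-or-positional vector of white-noise standard
#'   deviations for `c(sst, mld, swr)` (defaults `c(0.2, 0.5, 5)`).
#' @param seed Optional RNG seed (applied locally).
#' @return List with [bt_field_series()] elements `sst`, `mld`, `swr`.
#' @export
gen_forcing <- function(grid, times = gen_times(),
                        sst_mean = 16, sst_lat_gradient = -0.3,
                        mld_mean = 10, mld_lon_gradient = 0.3,
                        swr_mean = 250, swr_diurnal_amplitude = 150,
                        noise_sd = c(0.2, 0.5, 5), seed = NULL) {
  ny <- length(grid$lat); nx <- length(grid$lon); nt <- length(times)
  lat0 <- mean(range(grid$lat)); lon0 <- mean(range(grid$lon))
  latm <- matrix(grid$lat, ny, nx)
  lonm <- matrix(grid$lon, ny, nx, byrow = TRUE)
  build <- function() {
    sst <- array(NA_real_, c(nt, ny, nx))
    mld <- array(NA_real_, c(nt, ny, nx))
    swr <- array(NA_real_, c(nt, ny, nx))
    for (k in seq_len(nt)) {
      hour <- (times[k] / 3600) %% 24
      diurnal <- swr_diurnal_amplitude * cos((hour - 12) / 24 * 2 * pi)
      sst[k, , ] <- sst_mean + sst_lat_gradient * (latm - lat0) +
        stats::rnorm(ny * nx, 0, noise_sd[1])
      mld[k, , ] <- pmax(0.5, mld_mean + mld_lon_gradient * (lonm - lon0) +
                           stats::rnorm(ny * nx, 0, noise_sd[2]))
      swr[k, , ] <- pmax(0, swr_mean + diurnal +
                           stats::rnorm(ny * nx, 0, noise_sd[3]))
    }
    list(sst = bt_field_series(grid, times, sst, "sst", "degC"),
         mld = bt_field_series(grid, times, mld, "mld", "m"),
         swr = bt_field_series(grid, times, swr, "swr", "W m-2"))
  }
  if (is.null(seed)) build() else withr::with_seed(seed, build())
}

#' Generate a synthetic bloom classification mask
#'
#' Emulates a satellite bloom map whose blooms sit offshore by design:
#' bloom cells are drawn only where the distance to coast is at least
#' `d_star_nm`, covering a fraction `coverage` of the eligible cells;
#' independently, every wet cell is clouded over (`inconclusive`) with
#' probability `inconclusive_frac`; the remaining wet cells are `no_bloom`.
#' Because placement respects `d_star_nm` by construction, the offshore
#' character of blooms is recoverable downstream.
#'
#' @param grid A [bt_grid()].
#' @param dist_field Distance-to-coast matrix from [distance_to_coast()].
#' @param event_time Event timestamp (default mid-July).
#' @param d_star_nm Minimum distance to coast of bloom cells (nm,
#'   default 15).
#' @param coverage Fraction of eligible cells receiving a bloom
#'   (default 0.3).
#' @param inconclusive_frac Per-cell cloud probability (default 0.2).
#' @param seed Optional RNG seed (applied locally).
#' @return A [bt_bloom_mask()].
#' @export
gen_bloom_mask <- function(grid, dist_field,
                           event_time = default_event_time(),
                           d_star_nm = 15, coverage = 0.3,
                           inconclusive_frac = 0.2, seed = NULL) {
  stopifnot(coverage >= 0, coverage <= 1,
            inconclusive_frac >= 0, inconclusive_frac <= 1)
  wet <- !grid$land_mask
  eligible <- which(wet & dist_field >= d_star_nm)
  if (!length(eligible)) {
    stop("no wet cells at least ", d_star_nm, " nm offshore", call. = FALSE)
  }
  build <- function() {
    states <- matrix(0L, nrow(dist_field), ncol(dist_field))
    n_bloom <- round(coverage * length(eligible))
    if (n_bloom > 0) {
      states[sample(eligible, n_bloom)] <- 1L
    }
    wet_idx <- which(wet)
    clouded <- wet_idx[stats::runif(length(wet_idx)) < inconclusive_frac]
    states[clouded] <- 2L
    bt_bloom_mask(grid, states, event_time)
  }
  if (is.null(seed)) build() else withr::with_seed(seed, build())
}

#' Generate a synthetic nutrient observation table
#'
#' Emulates a multi-decadal bottle-data extract with a designed coastal
#' enrichment: records at random wet positions on May–September dates,
#' concentrations drawn lognormally around a zone median (offshore
#' baseline, plus a coastal excess applied inshore of `zone_break_nm`) and
#' rounded to instrument precision (0.1 µmol L\eqn{^{-1}} for nitrate,
#' 0.01 for phosphate). Multiplicative noise preserves the designed
#' medians, so the coastal-minus-offshore median offsets are recoverable
#' by [monthly_whisker_stats()].
#'
#' @param grid A [bt_grid()].
#' @param dist_field Distance-to-coast matrix from [distance_to_coast()].
#' @param n_per_month Records per climatological month (default 200).
#' @param months Months sampled (default `5:9`).
#' @param years Calendar years sampled uniformly (default `1990:2017`).
#' @param no3_median,po4_median Offshore median concentrations
#'   (µmol L\eqn{^{-1}}; defaults 1.0 and 0.3).
#' @param no3_coastal_excess,po4_coastal_excess Designed coastal median
#'   excesses (defaults 0.5 and 0.1).
#' @param sdlog Lognormal noise scale (default 0.3).
#' @param zone_break_nm Distance separating the generator's enriched
#'   inshore regime from the offshore baseline (default 50 nm, the middle
#'   of the excluded 40–60 nm band).
#' @param seed Optional RNG seed (applied locally).
#' @return A tibble with columns `date`, `lon`, `lat`, `no3`, `po4`.
#' @export
gen_nutrient_table <- function(grid, dist_field, n_per_month = 200,
                               months = 5:9, years = 1990:2017,
                               no3_median = 1.0, po4_median = 0.3,
                               no3_coastal_excess = 0.5,
                               po4_coastal_excess = 0.1,
                               sdlog = 0.3, zone_break_nm = 50,
                               seed = NULL) {
  stopifnot(n_per_month > 0, sdlog >= 0)
  wet_idx <- which(!grid$land_mask)
  ny <- length(grid$lat)
  build <- function() {
    n <- n_per_month * length(months)
    cells <- sample(wet_idx, n, replace = TRUE)
    j <- (cells - 1L) %% ny + 1L
    i <- (cells - 1L) %/% ny + 1L
    lon <- grid$lon[i]
    lat <- grid$lat[j]
    dist <- dist_field[cells]
    coastal <- dist < zone_break_nm
    month <- rep(months, each = n_per_month)
    day <- sample(28L, n, replace = TRUE)
    year <- sample(years, n, replace = TRUE)
    no3 <- (no3_median + no3_coastal_excess * coastal) *
      exp(stats::rnorm(n, 0, sdlog))
    po4 <- (po4_median + po4_coastal_excess * coastal) *
      exp(stats::rnorm(n, 0, sdlog))
    tibble::tibble(
      date = as.Date(sprintf("%d-%02d-%02d", year, month, day)),
      lon = lon, lat = lat,
      no3 = pmax(0, round(no3, 1)),
      po4 = pmax(0, round(po4, 2)))
  }
  if (is.null(seed)) build() else withr::with_seed(seed, build())
}

#' Generate a complete synthetic study scenario
#'
#' Convenience wrapper tying the generators together: basin, distance
#' field, velocity and forcing series, an offshore bloom mask, and a
#' nutrient table, all reproducible from one seed. The result feeds the
#' full pipeline (seed, classify, back-trace, sample, summarise) without
#' any external data.
#'
#' @param regime Velocity regime (default `"double_gyre"`, the only regime
#'   whose streamlines respect the basin walls, giving a rim-hugging
#'   boundary current and closed interior circulation; `"uniform"` and
#'   `"solid_rotation"` are kept for integrator analytics).
#' @param days Length of the generated series (default 63, covering a
#'   60-day tracing window with margin).
#' @param n_lon,n_lat Basin node counts.
#' @param lon_range,lat_range Basin extent; the default spans a wide
#'   longitude band so each of the two gyre cells is metrically square,
#'   which keeps near-wall streamlines at a nearly constant distance to
#'   the coast.
#' @param d_star_nm,coverage,inconclusive_frac Bloom-mask design, see
#'   [gen_bloom_mask()].
#' @param n_per_month Nutrient records per month.
#' @param seed Integer seed controlling every random component.
#' @param ... Further arguments passed to [gen_velocity()].
#' @return List with elements `grid`, `dist`, `u`, `v`, `sst`, `mld`,
#'   `swr`, `mask`, `nutrients`, `t_event`.
#' @export
simulate_scenario <- function(regime = "double_gyre", days = 63,
                              n_lon = 120, n_lat = 60,
                              lon_range = c(5.5, 31.2),
                              lat_range = c(53.5, 60.5),
                              d_star_nm = 15, coverage = 0.3,
                              inconclusive_frac = 0.2,
                              n_per_month = 200, seed = 1, ...) {
  grid <- gen_basin(n_lon = n_lon, n_lat = n_lat,
                    lon_range = lon_range, lat_range = lat_range)
  dist <- distance_to_coast(grid)
  t_event <- default_event_time()
  times <- gen_times(days = days, t_end = t_event)
  vel <- gen_velocity(grid, times, regime = regime, ...)
  forcing <- gen_forcing(grid, times, seed = seed + 1L)
  mask <- gen_bloom_mask(grid, dist, event_time = t_event,
                         d_star_nm = d_star_nm, coverage = coverage,
                         inconclusive_frac = inconclusive_frac,
                         seed = seed + 2L)
  nutrients <- gen_nutrient_table(grid, dist, n_per_month = n_per_month,
                                  seed = seed + 3L)
  list(grid = grid, dist = dist, u = vel$u, v = vel$v,
       sst = forcing$sst, mld = forcing$mld, swr = forcing$swr,
       mask = mask, nutrients = nutrients, t_event = t_event)
}
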