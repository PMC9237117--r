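#' One explicit Euler step backward in time on the sphere
#'
#' Moves a position against the local velocity for a time step `dt_s`,
#' converting metres to degrees on a sphere of radius `earth_radius`:
#' \deqn{\Delta\lambda = -\,u\,dt / (R \cos\varphi) \cdot 180/\pi, \qquad
#'       \Delta\varphi = -\,v\,dt / R \cdot 180/\pi.}
#' A backward step followed by a forward step with the same frozen velocity
#' returns the start exactly.
#'
#' @param lon,lat Position (degrees), vectors of equal length.
#' @param u,v Surface velocity components (m s\eqn{^{-1}}), eastward and
#'   northward.
#' @param dt_s Time step in seconds (> 0).
#' @param earth_radius Sphere radius in metres (default 6 371 000).
#' @return A list with numeric elements `lon` and `lat`.
#' @export
#' @examples
#' step_euler_backward(15, 55, u = 0.1, v = 0, dt_s = 3 * 3600)
step_euler_backward <- function(lon, lat, u, v, dt_s,
                                earth_radius = 6371000) {
  deg <- 180 / pi
  list(lon = lon - u * dt_s / (earth_radius * cos(lat / deg)) * deg,
       lat = lat - v * dt_s / earth_radius * deg)
}

# forward counterpart (sign-flipped); kept internal, advect_forward wraps it
step_euler_forward <- function(lon, lat, u, v, dt_s,
                               earth_radius = 6371000) {
  step_euler_backward(lon, lat, u, v, -dt_s, earth_radius)
}

#' Back-trace drifters through a surface-velocity series
#'
#' Integrates each seeded drifter backward in time from `t_event` over the
#' tracing window with an explicit Euler scheme, the velocity bilinearly
#' interpolated in space and linearly in time onto the moving position.
#' A drifter whose next position falls outside the grid bounding box is
#' frozen at its last valid position with status `out_of_domain`; one whose
#' stencil is entirely land (no wet velocity available) freezes with status
#' `beached`. Frozen drifters stay in the ensemble so they remain countable.
#'
#' @param seeds Data frame of seed positions with columns `drifter_id`,
#'   `lon`, `lat` (e.g. from [seed_drifters()]); an optional `label` column
#'   is carried through to the output.
#' @param u_series,v_series Eastward / northward velocity
#'   [bt_field_series()] on a shared grid and time axis.
#' @param t_event Event timestamp (numeric seconds since epoch or
#'   `POSIXct`); positions are reported relative to it.
#' @param window_days Length of the tracing window in days (default 60).
#' @param dt_hours Reporting/integration step in hours (default 3, the
#'   cadence of the velocity output); `window_days` must be an integer
#'   multiple of it.
#' @param substeps Integer \eqn{\ge} 1: Euler substeps per `dt_hours`
#'   (velocities interpolated to substep times); positions are still
#'   recorded every `dt_hours`.
#' @param earth_radius Sphere radius in metres for the degree/metre
#'   conversion.
#' @return A tibble of class `bt_trajectories` in long format with columns
#'   `drifter_id`, `time_rel_s` (0 at the event, negative before it), `lon`,
#'   `lat`, `status` (factor `active`/`beached`/`out_of_domain`) and, if
#'   present in `seeds`, `label`. Attributes `t_event`, `dt_s`, `window_s`
#'   and `direction` record the configuration.
#' @export
advect_backward <- function(seeds, u_series, v_series, t_event,
                            window_days = 60, dt_hours = 3, substeps = 1L,
                            earth_radius = 6371000) {
  advect_engine(seeds, u_series, v_series, t_event, direction = -1,
                window_days, dt_hours, substeps, earth_radius)
}

#' Trace drifters forward in time
#'
#' Forward counterpart of [advect_backward()], mainly used to validate the
#' integrator (forward-then-backward inversion, convergence checks).
#' `time_rel_s` is 0 at `t_start` and positive afterwards.
#'
#' @inheritParams advect_backward
#' @param t_start Start timestamp of the forward integration.
#' @return A `bt_trajectories` tibble; see [advect_backward()].
#' @export
advect_forward <- function(seeds, u_series, v_series, t_start,
                           window_days = 60, dt_hours = 3, substeps = 1L,
                           earth_radius = 6371000) {
  advect_engine(seeds, u_series, v_series, t_start, direction = 1,
                window_days, dt_hours, substeps, earth_radius)
}

advect_engine <- function(seeds, u_series, v_series, t0, direction,
                          window_days, dt_hours, substeps, earth_radius) {
  stopifnot(is.data.frame(seeds),
            all(c("drifter_id", "lon", "lat") %in% names(seeds)),
            inherits(u_series, "bt_field_series"),
            inherits(v_series, "bt_field_series"))
  if (!isTRUE(all.equal(u_series$grid$lon, v_series$grid$lon)) ||
      !isTRUE(all.equal(u_series$grid$lat, v_series$grid$lat)) ||
      !identical(u_series$times, v_series$times)) {
    stop("u and v series must share grid and time axis", call. = FALSE)
  }
  if (window_days <= 0 || dt_hours <= 0) {
    stop("window and dt must be positive", call. = FALSE)
  }
  n_rec <- window_days * 24 / dt_hours
  if (abs(n_rec - round(n_rec)) > 1e-9) {
    stop("`window_days` must be an integer multiple of `dt_hours`",
         call. = FALSE)
  }
  n_rec <- as.integer(round(n_rec))
  substeps <- as.integer(substeps)
  stopifnot(substeps >= 1L)
  t0 <- as.numeric(t0)
  window_s <- window_days * 86400
  tt <- u_series$times
  t_far <- t0 + direction * window_s
  if (min(t0, t_far) < tt[1] || max(t0, t_far) > tt[length(tt)]) {
    stop("velocity series does not cover the tracing window", call. = FALSE)
  }

  grid <- u_series$grid
  n <- nrow(seeds)
  lon <- as.numeric(seeds$lon)
  lat <- as.numeric(seeds$lat)
  status <- rep(1L, n) # 1 active, 2 beached, 3 out_of_domain
  inside <- lon >= grid$lon[1] & lon <= grid$lon[length(grid$lon)] &
    lat >= grid$lat[1] & lat <= grid$lat[length(grid$lat)]
  status[!inside] <- 3L
  wet0 <- rep(FALSE, n)
  wet0[inside] <- nearest_node_wet(grid, lon[inside], lat[inside])
  status[inside & !wet0] <- 2L

  rec_lon <- matrix(NA_real_, n, n_rec + 1L)
  rec_lat <- matrix(NA_real_, n, n_rec + 1L)
  rec_status <- matrix(1L, n, n_rec + 1L)
  rec_lon[, 1L] <- lon; rec_lat[, 1L] <- lat; rec_status[, 1L] <- status

  dt_s <- dt_hours * 3600 / substeps
  lon_min <- grid$lon[1]; lon_max <- grid$lon[length(grid$lon)]
  lat_min <- grid$lat[1]; lat_max <- grid$lat[length(grid$lat)]

  for (rec in seq_len(n_rec)) {
    for (ss in seq_len(substeps)) {
      act <- which(status == 1L)
      if (!length(act)) break
      t_cur <- t0 + direction * ((rec - 1L) * substeps + ss - 1L) * dt_s
      uu <- interp_spacetime(u_series, lon[act], lat[act], t_cur, "na")
      vv <- interp_spacetime(v_series, lon[act], lat[act], t_cur, "na")
      dry <- is.na(uu) | is.na(vv)
      if (any(dry)) {
        status[act[dry]] <- 2L
        act <- act[!dry]; uu <- uu[!dry]; vv <- vv[!dry]
      }
      if (!length(act)) break
      stepped <- step_euler_backward(lon[act], lat[act], uu, vv,
                                     -direction * dt_s, earth_radius)
      nl <- normalize_lon(stepped$lon, lon_min)
      nphi <- stepped$lat
      out <- nl < lon_min | nl > lon_max | nphi < lat_min | nphi > lat_max
      status[act[out]] <- 3L
      keep <- act[!out]
      if (length(keep)) {
        nl <- nl[!out]; nphi <- nphi[!out]
        dryland <- !stencil_has_wet(grid, nl, nphi)
        status[keep[dryland]] <- 2L
        mv <- keep[!dryland]
        lon[mv] <- nl[!dryland]
        lat[mv] <- nphi[!dryland]
      }
    }
    rec_lon[, rec + 1L] <- lon
    rec_lat[, rec + 1L] <- lat
    rec_status[, rec + 1L] <- status
  }

  status_levels <- c("active", "beached", "out_of_domain")
  out <- tibble::tibble(
    drifter_id = rep(seeds$drifter_id, each = n_rec + 1L),
    time_rel_s = rep(direction * dt_hours * 3600 * (0:n_rec), times = n),
    lon = as.vector(t(rec_lon)),
    lat = as.vector(t(rec_lat)),
    status = factor(status_levels[as.vector(t(rec_status))],
                    levels = status_levels))
  if ("label" %in% names(seeds)) {
    out$label <- rep(seeds$label, each = n_rec + 1L)
  }
  structure(out,
            class = c("bt_trajectories", class(out)),
            t_event = t0, dt_s = dt_hours * 3600,
            window_s = window_s, direction = direction)
}

# wrap a longitude into [base, base + 360)
normalize_lon <- function(lon, base = -180) {
  ((lon - base) %% 360) + base
}

#' Write trajectories (or environmental histories) to CSV
#'
#' Long-format export: one row per drifter per time offset, matching the
#' tibble layout of [advect_backward()] / [sample_environment()].
#'
#' @param x A `bt_trajectories` or `bt_env_history` tibble.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_trajectories <- function(x, path) {
  readr::write_csv(as.data.frame(x), path)
  invisible(path)
}
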