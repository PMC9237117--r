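#' Mixed-layer averaged photosynthetically active radiation
#'
#' PAR experienced by a cell mixed through the surface layer: the fraction
#' `par_fraction` of incoming shortwave radiation, attenuated exponentially
#' with depth at rate `attenuation`, averaged over the mixed layer of depth
#' `mld`:
#' \deqn{\mathrm{PAR} = f\,I_0\,\frac{1 - e^{-kH}}{kH},}
#' the exact depth average of \eqn{f I_0 e^{-kz}} over \eqn{[0, H]}. As the
#' mixed layer vanishes the ratio PAR/\eqn{I_0} tends to `par_fraction`
#' (42 % by default); it decreases monotonically with deeper mixing.
#' Self-shading by the phytoplankton themselves is deliberately not
#' modelled.
#'
#' @param swr Incoming shortwave radiation \eqn{I_0} (W m\eqn{^{-2}},
#'   \eqn{\ge 0}).
#' @param mld Mixed-layer depth \eqn{H} (m, > 0).
#' @param par_fraction PAR fraction \eqn{f} of incoming shortwave
#'   (default 0.42).
#' @param attenuation Light attenuation \eqn{k} (m\eqn{^{-1}}, default 0.2).
#' @return PAR in W m\eqn{^{-2}}; vectorised with recycling, `NA` in gives
#'   `NA` out.
#' @export
#' @examples
#' par_mixed_layer(swr = 100, mld = 10)          # deep mixing dims the light
#' par_mixed_layer(swr = 100, mld = 1e-9) / 100  # surface limit: 0.42
par_mixed_layer <- function(swr, mld, par_fraction = 0.42,
                            attenuation = 0.2) {
  stopifnot(par_fraction > 0, par_fraction <= 1, attenuation > 0)
  if (any(mld <= 0, na.rm = TRUE)) {
    stop("`mld` must be positive", call. = FALSE)
  }
  x <- attenuation * mld
  par_fraction * swr * (-expm1(-x)) / x
}

#' Great-circle distance to the nearest coast, per grid node
#'
#' For every wet node, the minimum great-circle (haversine, sphere radius
#' `earth_radius`) distance to any land node, in nautical miles
#' (1 nm = 1852 m). Land nodes get 0. Computed node-to-node against the
#' grid's own land mask, which is adequate at the ~1 nm mesh spacing the
#' package targets.
#'
#' @param grid A [bt_grid()] with at least one land and one wet node.
#' @param earth_radius Sphere radius in metres (default 6 371 000).
#' @return Numeric matrix `(n_lat, n_lon)` of distances in nautical miles.
#' @export
distance_to_coast <- function(grid, earth_radius = 6371000) {
  stopifnot(inherits(grid, "bt_grid"))
  m <- grid$land_mask
  if (!any(m)) {
    stop("grid has no land nodes: distance to coast is undefined",
         call. = FALSE)
  }
  lonm <- matrix(grid$lon, nrow(m), ncol(m), byrow = TRUE)
  latm <- matrix(grid$lat, nrow(m), ncol(m))
  land_pts <- cbind(lonm[m], latm[m])
  wet_pts <- cbind(lonm[!m], latm[!m])
  out <- matrix(0, nrow(m), ncol(m))
  # chunk the wet points to bound the pairwise-distance matrix size
  chunk <- max(1L, floor(5e6 / nrow(land_pts)))
  idx <- which(!m)
  for (s in seq(1L, length(idx), by = chunk)) {
    e <- min(s + chunk - 1L, length(idx))
    d <- geosphere::distm(wet_pts[s:e, , drop = FALSE], land_pts,
                          fun = function(p1, p2) {
                            geosphere::distHaversine(p1, p2, r = earth_radius)
                          })
    out[idx[s:e]] <- apply(d, 1, min) / 1852
  }
  out
}

#' Attach environmental histories to trajectories
#'
#' Samples sea surface temperature, mixed-layer depth and shortwave
#' radiation onto every active trajectory point (bilinear in space, linear
#' in time), derives mixed-layer PAR via [par_mixed_layer()], and reads the
#' static distance-to-coast field at each position. Points where a drifter
#' is not active (beached / out of domain) get `NA` throughout, so frozen
#' parcels never contaminate ensemble statistics.
#'
#' @param traj A `bt_trajectories` tibble from [advect_backward()] /
#'   [advect_forward()].
#' @param sst,mld,swr [bt_field_series()] of sea surface temperature (degC),
#'   mixed-layer depth (m) and downward shortwave radiation (W m\eqn{^{-2}})
#'   covering the trajectory time span.
#' @param dist_field Static distance-to-coast matrix from
#'   [distance_to_coast()] on the same grid.
#' @param par_fraction,attenuation PAR parameters, see [par_mixed_layer()].
#' @return A tibble of class `bt_env_history`: `traj` plus columns `sst`,
#'   `mld`, `par` and `dist_coast_nm`.
#' @export
sample_environment <- function(traj, sst, mld, swr, dist_field,
                               par_fraction = 0.42, attenuation = 0.2) {
  stopifnot(inherits(traj, "bt_trajectories"),
            inherits(sst, "bt_field_series"),
            inherits(mld, "bt_field_series"),
            inherits(swr, "bt_field_series"))
  t_event <- attr(traj, "t_event")
  times_abs <- t_event + unique(traj$time_rel_s)
  for (s in list(sst, mld, swr)) {
    if (min(times_abs) < s$times[1] || max(times_abs) > s$times[length(s$times)]) {
      stop("'", s$name, "' series does not cover the trajectory time span",
           call. = FALSE)
    }
  }
  grid <- sst$grid
  n <- nrow(traj)
  v_sst <- rep(NA_real_, n)
  v_mld <- rep(NA_real_, n)
  v_swr <- rep(NA_real_, n)
  v_dst <- rep(NA_real_, n)
  act <- traj$status == "active"
  for (tr in unique(traj$time_rel_s)) {
    rows <- which(traj$time_rel_s == tr & act)
    if (!length(rows)) next
    t_abs <- t_event + tr
    v_sst[rows] <- interp_spacetime(sst, traj$lon[rows], traj$lat[rows],
                                    t_abs, "na")
    v_mld[rows] <- interp_spacetime(mld, traj$lon[rows], traj$lat[rows],
                                    t_abs, "na")
    v_swr[rows] <- interp_spacetime(swr, traj$lon[rows], traj$lat[rows],
                                    t_abs, "na")
  }
  w <- which(act)
  v_dst[w] <- interp_space(grid, dist_field, traj$lon[w], traj$lat[w], "na")
  out <- traj
  out$sst <- v_sst
  out$mld <- v_mld
  v_par <- rep(NA_real_, n)
  ok <- !is.na(v_swr) & !is.na(v_mld)
  v_par[ok] <- par_mixed_layer(v_swr[ok], v_mld[ok], par_fraction, attenuation)
  out$par <- v_par
  out$dist_coast_nm <- v_dst
  class(out) <- c("bt_env_history", setdiff(class(traj), "bt_env_history"))
  out
}
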