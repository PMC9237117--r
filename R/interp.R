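#' Masked bilinear interpolation of a gridded field
#'
#' Bilinear interpolation over the four grid nodes surrounding each query
#' point, aware of the land mask: land nodes (and nodes with missing values)
#' are dropped from the stencil and the remaining weights renormalised so
#' they sum to one. This prevents the zero/missing values on land from
#' biasing near-coastal interpolation. If all four stencil nodes are land
#' the result is `NA`.
#'
#' @param grid A [bt_grid()].
#' @param values Numeric matrix `(n_lat, n_lon)` — one 2-D field slice.
#' @param lon,lat Numeric vectors of query positions (degrees), equal length.
#' @param out_of_domain What to do with points outside the grid bounding
#'   box: `"error"` (default) or `"na"`.
#'
#' @return Numeric vector of interpolated values (`NA` where missing).
#' @export
#' @examples
#' g <- bt_grid(0:1, 0:1, matrix(FALSE, 2, 2))
#' vals <- matrix(c(1, 3, 2, 4), 2, 2) # rows = lat
#' interp_space(g, vals, lon = 0.5, lat = 0.5) # mean of the four corners
interp_space <- function(grid, values, lon, lat,
                         out_of_domain = c("error", "na")) {
  out_of_domain <- match.arg(out_of_domain)
  stopifnot(inherits(grid, "bt_grid"), length(lon) == length(lat))
  glon <- grid$lon; glat <- grid$lat
  nx <- length(glon); ny <- length(glat)
  inside <- !is.na(lon) & !is.na(lat) &
    lon >= glon[1] & lon <= glon[nx] & lat >= glat[1] & lat <= glat[ny]
  if (out_of_domain == "error" && !all(inside)) {
    stop("query point outside the grid bounding box", call. = FALSE)
  }
  res <- rep(NA_real_, length(lon))
  ok <- which(inside)
  if (!length(ok)) return(res)

  i <- pmin(pmax(findInterval(lon[ok], glon), 1L), nx - 1L)
  j <- pmin(pmax(findInterval(lat[ok], glat), 1L), ny - 1L)
  tx <- (lon[ok] - glon[i]) / (glon[i + 1L] - glon[i])
  ty <- (lat[ok] - glat[j]) / (glat[j + 1L] - glat[j])

  # linear index into an (n_lat, n_lon) matrix
  id <- function(jj, ii) (ii - 1L) * ny + jj
  idx <- cbind(id(j, i), id(j, i + 1L), id(j + 1L, i), id(j + 1L, i + 1L))
  w <- cbind((1 - tx) * (1 - ty), tx * (1 - ty), (1 - tx) * ty, tx * ty)

  v <- matrix(values[idx], ncol = 4L)
  dead <- matrix(grid$land_mask[idx], ncol = 4L) | is.na(v)
  w[dead] <- 0
  v[dead] <- 0
  wsum <- rowSums(w)
  val <- rowSums(w * v) / wsum
  val[wsum == 0] <- NA_real_
  res[ok] <- val
  res
}

#' Space-time interpolation into a field series
#'
#' Linear blend in time of [interp_space()] evaluated on the two snapshots
#' bracketing `t`; when `t` coincides with a stored snapshot exactly one
#' snapshot is used. No extrapolation: `t` outside the series span is an
#' error.
#'
#' @param series A [bt_field_series()].
#' @param lon,lat Query positions (degrees), equal-length vectors.
#' @param t Single timestamp (numeric seconds since epoch or `POSIXct`)
#'   within the series span.
#' @inheritParams interp_space
#' @return Numeric vector of interpolated values.
#' @export
interp_spacetime <- function(series, lon, lat, t,
                             out_of_domain = c("error", "na")) {
  out_of_domain <- match.arg(out_of_domain)
  stopifnot(inherits(series, "bt_field_series"), length(t) == 1L)
  t <- as.numeric(t)
  tt <- series$times
  n <- length(tt)
  if (is.na(t) || t < tt[1] || t > tt[n]) {
    stop(sprintf("time %s outside the '%s' series span", format(t),
                 series$name), call. = FALSE)
  }
  k <- findInterval(t, tt)
  if (t == tt[k]) {
    return(interp_space(series$grid, field_slice(series, k), lon, lat,
                        out_of_domain))
  }
  a <- (t - tt[k]) / (tt[k + 1L] - tt[k])
  v0 <- interp_space(series$grid, field_slice(series, k), lon, lat,
                     out_of_domain)
  v1 <- interp_space(series$grid, field_slice(series, k + 1L), lon, lat,
                     out_of_domain)
  (1 - a) * v0 + a * v1
}

# index of the grid node nearest to each coordinate (clamped to the range)
nearest_index <- function(coords, x) {
  k <- findInterval(x, coords, all.inside = TRUE)
  k + as.integer(x - coords[k] > coords[k + 1L] - x)
}

# TRUE where the nearest grid node to (lon, lat) is wet
nearest_node_wet <- function(grid, lon, lat) {
  i <- nearest_index(grid$lon, lon)
  j <- nearest_index(grid$lat, lat)
  !grid$land_mask[cbind(j, i)]
}

# TRUE where the 4-node bilinear stencil around (lon, lat) has >= 1 wet node
stencil_has_wet <- function(grid, lon, lat) {
  nx <- length(grid$lon); ny <- length(grid$lat)
  i <- pmin(pmax(findInterval(lon, grid$lon), 1L), nx - 1L)
  j <- pmin(pmax(findInterval(lat, grid$lat), 1L), ny - 1L)
  m <- grid$land_mask
  !(m[cbind(j, i)] & m[cbind(j, i + 1L)] &
      m[cbind(j + 1L, i)] & m[cbind(j + 1L, i + 1L)])
}
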