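#' Regular lon/lat grid with a land mask
#'
#' The spatial data model for every gridded quantity in the package: a
#' regular (rectilinear) longitude/latitude mesh with values registered at
#' the grid nodes, plus a logical land mask. All downstream machinery
#' (interpolation, tracking, distance to coast) assumes this layout.
#'
#' @param lon Numeric vector of node longitudes, degrees east, strictly
#'   increasing. Values in `[-180, 360)` are accepted; a grid must not mix
#'   the `[-180, 180)` and `[0, 360)` conventions.
#' @param lat Numeric vector of node latitudes, degrees north, strictly
#'   increasing.
#' @param land_mask Logical matrix of shape `(length(lat), length(lon))`;
#'   `TRUE` marks land nodes. At least one wet node is required.
#'
#' @return An object of class `bt_grid`: a list with elements `lon`, `lat`
#'   and `land_mask` (rows index latitude, columns longitude).
#' @export
#' @examples
#' g <- bt_grid(lon = 10:15, lat = 54:58,
#'              land_mask = matrix(FALSE, 5, 6))
#' g
bt_grid <- function(lon, lat, land_mask) {
  lon <- as.numeric(lon)
  lat <- as.numeric(lat)
  check_coord(lon, "lon")
  check_coord(lat, "lat")
  if (any(lon < -180) || any(lon >= 360)) {
    stop("`lon` must lie in [-180, 360)", call. = FALSE)
  }
  land_mask <- as.matrix(land_mask)
  storage.mode(land_mask) <- "logical"
  if (!identical(dim(land_mask), c(length(lat), length(lon)))) {
    stop("`land_mask` must have shape (length(lat), length(lon))",
         call. = FALSE)
  }
  if (anyNA(land_mask)) stop("`land_mask` must not contain NA", call. = FALSE)
  if (all(land_mask)) stop("grid has no wet cells", call. = FALSE)
  structure(list(lon = lon, lat = lat, land_mask = land_mask),
            class = "bt_grid")
}

check_coord <- function(x, name) {
  if (length(x) < 2 || anyNA(x) || any(diff(x) <= 0)) {
    stop("`", name, "` must be strictly increasing with no missing values",
         call. = FALSE)
  }
  invisible(x)
}

#' @export
print.bt_grid <- function(x, ...) {
  cat(sprintf(
    "<bt_grid> %d x %d nodes, lon [%g, %g], lat [%g, %g], %d wet / %d land\n",
    length(x$lat), length(x$lon),
    min(x$lon), max(x$lon), min(x$lat), max(x$lat),
    sum(!x$land_mask), sum(x$land_mask)))
  invisible(x)
}

#' Time-stamped stack of 2-D fields on a grid
#'
#' Container for an Eulerian surface field sampled at a sequence of times:
#' a velocity component, sea surface temperature, mixed-layer depth or
#' downward shortwave radiation. Values on land nodes are `NA` (missing),
#' never zero: zero is a legal physical value.
#'
#' @param grid A [bt_grid()].
#' @param times Numeric vector of timestamps (seconds since 1970-01-01 UTC)
#'   or a `POSIXct` vector; strictly increasing.
#' @param values Numeric array of shape `(n_time, n_lat, n_lon)`.
#' @param name Variable identifier, e.g. `"u"`, `"sst"`.
#' @param units Physical units string, e.g. `"m s-1"`, `"degC"`.
#'
#' @return An object of class `bt_field_series`.
#' @export
bt_field_series <- function(grid, times, values, name, units = "") {
  stopifnot(inherits(grid, "bt_grid"))
  times <- as.numeric(times)
  check_coord(times, "times")
  values <- unclass(values)
  dims <- c(length(times), length(grid$lat), length(grid$lon))
  if (!identical(dim(values), as.integer(dims)) &&
      !identical(dim(values), dims)) {
    stop("`values` must have shape (n_time, n_lat, n_lon)", call. = FALSE)
  }
  # enforce the missing-on-land convention
  land <- which(grid$land_mask)
  if (length(land)) {
    values <- matrix(values, nrow = length(times))
    values[, land] <- NA_real_
    dim(values) <- dims
  }
  structure(list(grid = grid, times = times, values = values,
                 name = as.character(name), units = as.character(units)),
            class = "bt_field_series")
}

#' @export
print.bt_field_series <- function(x, ...) {
  cat(sprintf("<bt_field_series> '%s' [%s], %d snapshots (%s to %s) on ",
              x$name, x$units, length(x$times),
              format(as.POSIXct(x$times[1], tz = "UTC", origin = "1970-01-01")),
              format(as.POSIXct(x$times[length(x$times)], tz = "UTC",
                                origin = "1970-01-01"))))
  print(x$grid)
  invisible(x)
}

#' Extract one time slice of a field series as a (lat, lon) matrix
#' @param series A [bt_field_series()].
#' @param i Snapshot index.
#' @return Numeric matrix `(n_lat, n_lon)`.
#' @export
field_slice <- function(series, i) {
  v <- series$values[i, , , drop = TRUE]
  dim(v) <- c(length(series$grid$lat), length(series$grid$lon))
  v
}
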