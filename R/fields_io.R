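#' Write a field series to a NetCDF file
#'
#' Stores the variable on `(lon, lat, time)` dimensions with coordinate
#' variables, a `units` attribute, a `land_mask` variable and the standard
#' missing-value convention (`NA` on land / missing cells maps to the
#' fill value).
#'
#' @param series A [bt_field_series()].
#' @param path Output file path (`.nc`).
#' @return `path`, invisibly.
#' @export
write_field_series <- function(series, path) {
  stopifnot(inherits(series, "bt_field_series"))
  g <- series$grid
  dim_lon <- ncdf4::ncdim_def("lon", "degrees_east", g$lon)
  dim_lat <- ncdf4::ncdim_def("lat", "degrees_north", g$lat)
  dim_time <- ncdf4::ncdim_def("time", "seconds since 1970-01-01 00:00:00",
                               series$times, unlim = TRUE)
  fill <- -1e30
  var <- ncdf4::ncvar_def(series$name, series$units,
                          list(dim_lon, dim_lat, dim_time),
                          missval = fill, prec = "double")
  var_mask <- ncdf4::ncvar_def("land_mask", "1", list(dim_lon, dim_lat),
                               prec = "integer")
  nc <- ncdf4::nc_create(path, list(var, var_mask))
  on.exit(ncdf4::nc_close(nc))
  # internal layout is (time, lat, lon); NetCDF wants (lon, lat, time)
  ncdf4::ncvar_put(nc, var, aperm(series$values, c(3, 2, 1)))
  ncdf4::ncvar_put(nc, var_mask, t(g$land_mask) * 1L)
  invisible(path)
}

#' Read a field series from a NetCDF file
#'
#' Expects a variable on `(lon, lat, time)`-style dimensions with strictly
#' increasing coordinate variables. The file's missing-value attribute is
#' honoured (such cells become `NA`); a `land_mask` variable, if present, is
#' used as the grid's mask, otherwise cells that are missing at every time
#' are treated as land.
#'
#' @param path NetCDF file path.
#' @param variable Name of the variable to read.
#' @return A [bt_field_series()].
#' @export
read_field_series <- function(path, variable) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  nc <- ncdf4::nc_open(path)
  on.exit(ncdf4::nc_close(nc))
  if (!variable %in% names(nc$var)) {
    stop("variable not found: '", variable, "'", call. = FALSE)
  }
  v <- nc$var[[variable]]
  dnames <- vapply(v$dim, function(d) d$name, character(1))
  lon_i <- match_dim(dnames, c("lon", "longitude", "x"))
  lat_i <- match_dim(dnames, c("lat", "latitude", "y"))
  time_i <- match_dim(dnames, c("time", "t"))
  if (is.na(time_i)) {
    stop("variable '", variable, "' has no time dimension", call. = FALSE)
  }
  if (is.na(lon_i) || is.na(lat_i)) {
    stop("variable '", variable, "' lacks lon/lat dimensions", call. = FALSE)
  }
  lon <- as.numeric(v$dim[[lon_i]]$vals)
  lat <- as.numeric(v$dim[[lat_i]]$vals)
  times <- as.numeric(v$dim[[time_i]]$vals)
  check_coord(lon, "lon"); check_coord(lat, "lat"); check_coord(times, "times")

  vals <- ncdf4::ncvar_get(nc, variable, collapse_degen = FALSE)
  vals <- aperm(vals, c(time_i, lat_i, lon_i)) # to (time, lat, lon)
  if ("land_mask" %in% names(nc$var)) {
    m <- ncdf4::ncvar_get(nc, "land_mask") # (lon, lat)
    mask <- t(matrix(m, length(lon), length(lat))) > 0
  } else {
    mask <- apply(is.na(vals), c(2, 3), all)
  }
  grid <- bt_grid(lon, lat, mask)
  bt_field_series(grid, times, vals, name = variable,
                  units = if (nzchar(v$units)) v$units else "")
}

match_dim <- function(dnames, candidates) {
  hit <- which(tolower(dnames) %in% candidates)
  if (length(hit)) hit[1] else NA_integer_
}

#' Write a bloom classification mask to a NetCDF file
#'
#' The three-state mask is stored as an integer-coded variable
#' (`0 = no_bloom`, `1 = bloom`, `2 = inconclusive`) with `flag_values` /
#' `flag_meanings` attributes and the event time as a variable attribute.
#'
#' @param mask A [bt_bloom_mask()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_bloom_mask <- function(mask, path) {
  stopifnot(inherits(mask, "bt_bloom_mask"))
  g <- mask$grid
  dim_lon <- ncdf4::ncdim_def("lon", "degrees_east", g$lon)
  dim_lat <- ncdf4::ncdim_def("lat", "degrees_north", g$lat)
  var <- ncdf4::ncvar_def("bloom_state", "1", list(dim_lon, dim_lat),
                          prec = "integer")
  var_mask <- ncdf4::ncvar_def("land_mask", "1", list(dim_lon, dim_lat),
                               prec = "integer")
  nc <- ncdf4::nc_create(path, list(var, var_mask))
  on.exit(ncdf4::nc_close(nc))
  ncdf4::ncvar_put(nc, var, t(mask$states))
  ncdf4::ncvar_put(nc, var_mask, t(g$land_mask) * 1L)
  ncdf4::ncatt_put(nc, var, "flag_values", "0 1 2")
  ncdf4::ncatt_put(nc, var, "flag_meanings", "no_bloom bloom inconclusive")
  ncdf4::ncatt_put(nc, var, "event_time", mask$event_time, prec = "double")
  invisible(path)
}

#' Read a bloom classification mask from a NetCDF file
#' @param path NetCDF file path written by [write_bloom_mask()].
#' @return A [bt_bloom_mask()].
#' @export
read_bloom_mask <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  nc <- ncdf4::nc_open(path)
  on.exit(ncdf4::nc_close(nc))
  if (!"bloom_state" %in% names(nc$var)) {
    stop("variable not found: 'bloom_state'", call. = FALSE)
  }
  v <- nc$var[["bloom_state"]]
  lon <- as.numeric(v$dim[[1]]$vals)
  lat <- as.numeric(v$dim[[2]]$vals)
  states <- t(matrix(ncdf4::ncvar_get(nc, "bloom_state"),
                     length(lon), length(lat)))
  m <- ncdf4::ncvar_get(nc, "land_mask")
  mask <- t(matrix(m, length(lon), length(lat))) > 0
  ev <- ncdf4::ncatt_get(nc, v, "event_time")
  bt_bloom_mask(bt_grid(lon, lat, mask), states,
                event_time = if (ev$hasatt) ev$value else NA_real_)
}
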