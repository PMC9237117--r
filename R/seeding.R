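#' Three-state bloom classification mask
#'
#' A per-event satellite-style classification of every grid cell as
#' `no_bloom` (0), `bloom` (1) or `inconclusive` (2, e.g. cloud cover or an
#' uncertain/sub-surface signal). Land cells carry `inconclusive` by
#' convention, so drifters mistakenly referred to land are discarded rather
#' than mislabelled.
#'
#' @param grid A [bt_grid()].
#' @param states Integer matrix `(n_lat, n_lon)` with codes 0/1/2.
#' @param event_time Event timestamp (numeric seconds since epoch or
#'   `POSIXct`).
#' @return An object of class `bt_bloom_mask`.
#' @export
bt_bloom_mask <- function(grid, states, event_time) {
  stopifnot(inherits(grid, "bt_grid"))
  states <- as.matrix(states)
  storage.mode(states) <- "integer"
  if (!identical(dim(states), dim(grid$land_mask))) {
    stop("`states` must match the grid shape", call. = FALSE)
  }
  if (anyNA(states) || !all(states %in% 0:2)) {
    stop("`states` codes must be 0 (no_bloom), 1 (bloom) or 2 (inconclusive)",
         call. = FALSE)
  }
  states[grid$land_mask] <- 2L
  structure(list(grid = grid, states = states,
                 event_time = as.numeric(event_time)),
            class = "bt_bloom_mask")
}

#' @export
print.bt_bloom_mask <- function(x, ...) {
  wet <- !x$grid$land_mask
  cat(sprintf(
    "<bt_bloom_mask> event %s: %d bloom, %d no-bloom, %d inconclusive wet cells\n",
    format(as.POSIXct(x$event_time, tz = "UTC", origin = "1970-01-01")),
    sum(x$states[wet] == 1L), sum(x$states[wet] == 0L),
    sum(x$states[wet] == 2L)))
  invisible(x)
}

#' Randomly seed virtual drifters in the study box
#'
#' Draws `n_drifters` positions uniformly over the bounding box; positions
#' whose nearest grid node is land are redrawn (rejection sampling), so the
#' returned count is exact and every seed starts on wet water. The default
#' box and count are the study configuration: 4000 drifters in
#' 13–24°E, 54–60°N.
#'
#' @param grid A [bt_grid()].
#' @param n_drifters Number of drifters (default 4000).
#' @param bbox Numeric `c(lon_min, lon_max, lat_min, lat_max)` in degrees
#'   (default `c(13, 24, 54, 60)`); must intersect wet cells of the grid.
#' @param seed Optional integer RNG seed; the generator is R's default
#'   Mersenne-Twister, applied locally so the global RNG state is untouched.
#' @return A tibble with columns `drifter_id`, `lon`, `lat`.
#' @export
seed_drifters <- function(grid, n_drifters = 4000,
                          bbox = c(13, 24, 54, 60), seed = NULL) {
  stopifnot(inherits(grid, "bt_grid"), length(bbox) == 4,
            n_drifters > 0)
  if (bbox[1] >= bbox[2] || bbox[3] >= bbox[4]) {
    stop("`bbox` must be c(lon_min, lon_max, lat_min, lat_max), nonempty",
         call. = FALSE)
  }
  # any wet node whose nearest-node cell can be hit from inside the box?
  half_dx <- max(diff(grid$lon)) / 2
  half_dy <- max(diff(grid$lat)) / 2
  cand <- outer(
    grid$lat >= bbox[3] - half_dy & grid$lat <= bbox[4] + half_dy,
    grid$lon >= bbox[1] - half_dx & grid$lon <= bbox[2] + half_dx)
  if (!any(cand & !grid$land_mask)) {
    stop("seeding box contains no wet cells", call. = FALSE)
  }
  draw <- function() {
    lon <- stats::runif(n_drifters, bbox[1], bbox[2])
    lat <- stats::runif(n_drifters, bbox[3], bbox[4])
    bad <- which(!nearest_node_wet(grid, lon, lat))
    tries <- 0L
    while (length(bad)) {
      lon[bad] <- stats::runif(length(bad), bbox[1], bbox[2])
      lat[bad] <- stats::runif(length(bad), bbox[3], bbox[4])
      bad <- bad[!nearest_node_wet(grid, lon[bad], lat[bad])]
      tries <- tries + 1L
      if (tries > 10000L) stop("rejection sampling failed to find wet water",
                               call. = FALSE)
    }
    tibble::tibble(drifter_id = seq_len(n_drifters), lon = lon, lat = lat)
  }
  if (is.null(seed)) draw() else withr::with_seed(seed, draw())
}

#' Attribute drifters to bloom / non-bloom patches
#'
#' Each drifter takes the classification state of its containing grid cell
#' (nearest-node assignment): `bloom`, `no_bloom`, or — for inconclusive
#' satellite information — `discarded`. Seeds outside the mask domain are
#' discarded with a warning. Labels always sum to the number of drifters.
#'
#' @param seeds Data frame with columns `drifter_id`, `lon`, `lat`.
#' @param mask A [bt_bloom_mask()].
#' @return `seeds` with an added factor column `label`
#'   (`bloom`/`no_bloom`/`discarded`).
#' @export
classify_drifters <- function(seeds, mask) {
  stopifnot(is.data.frame(seeds), inherits(mask, "bt_bloom_mask"))
  g <- mask$grid
  lon <- seeds$lon; lat <- seeds$lat
  inside <- lon >= g$lon[1] & lon <= g$lon[length(g$lon)] &
    lat >= g$lat[1] & lat <= g$lat[length(g$lat)]
  if (any(!inside)) {
    warning(sum(!inside), " seed(s) outside the mask domain were discarded",
            call. = FALSE)
  }
  code <- rep(2L, nrow(seeds))
  if (any(inside)) {
    i <- nearest_index(g$lon, lon[inside])
    j <- nearest_index(g$lat, lat[inside])
    code[inside] <- mask$states[cbind(j, i)]
  }
  label <- factor(c("no_bloom", "bloom", "discarded")[code + 1L],
                  levels = c("bloom", "no_bloom", "discarded"))
  out <- tibble::as_tibble(seeds)
  out$label <- label
  out
}
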