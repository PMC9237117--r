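#' Classify a coastal distance into nutrient-climatology zones
#'
#' Coastal water is everything closer than `coastal_max` nautical miles to
#' the coast, offshore everything beyond `offshore_min`; the band in
#' between is excluded so the offshore bin is not contaminated by recently
#' upwelled coastal water (Baltic upwelling reaches ~15 nm offshore).
#'
#' @param dist_nm Distance to coast in nautical miles (\eqn{\ge 0});
#'   vectorised, `NA` gives `NA`.
#' @param coastal_max Coastal threshold in nm (default 40; exclusive).
#' @param offshore_min Offshore threshold in nm (default 60; exclusive).
#' @return Factor with levels `coastal`, `offshore`, `excluded`.
#' @export
#' @examples
#' classify_zone(c(39, 50, 61))
classify_zone <- function(dist_nm, coastal_max = 40, offshore_min = 60) {
  stopifnot(coastal_max <= offshore_min)
  if (any(dist_nm < 0, na.rm = TRUE)) {
    stop("`dist_nm` must be non-negative", call. = FALSE)
  }
  out <- ifelse(dist_nm < coastal_max, "coastal",
                ifelse(dist_nm > offshore_min, "offshore", "excluded"))
  factor(out, levels = c("coastal", "offshore", "excluded"))
}

#' Excess phosphate relative to the Redfield ratio (P*)
#'
#' \deqn{P^{*} = \mathrm{PO_4} - \mathrm{NO_3}/16,} phosphate in excess of
#' the P:N Redfield ratio 1:16. Positive values mark nitrogen-depleted,
#' phosphorus-replete water — the niche of nitrogen-fixing cyanobacteria.
#'
#' @param po4 Phosphate (µmol L\eqn{^{-1}}).
#' @param no3 Nitrate (µmol L\eqn{^{-1}}).
#' @return P* in µmol L\eqn{^{-1}}; vectorised.
#' @export
#' @examples
#' pstar(po4 = 0.5, no3 = 8) # exactly Redfield-balanced: 0
pstar <- function(po4, no3) {
  po4 - no3 / 16
}

#' Read a nutrient observation table
#'
#' Delimited table in the shape of an ICES bottle-data extract: columns
#' `date` (parseable calendar date), `lon`, `lat` (degrees), `no3`, `po4`
#' (µmol L\eqn{^{-1}}).
#'
#' @param path CSV file path.
#' @return A tibble with `date` parsed to `Date`.
#' @export
read_nutrient_table <- function(path) {
  out <- readr::read_csv(path, show_col_types = FALSE)
  need <- c("date", "lon", "lat", "no3", "po4")
  if (!all(need %in% names(out))) {
    stop("nutrient table must have columns: ", paste(need, collapse = ", "),
         call. = FALSE)
  }
  out$date <- as.Date(out$date)
  if (anyNA(out$date)) stop("unparseable dates in nutrient table",
                            call. = FALSE)
  if (any(out$no3 < 0 | out$po4 < 0, na.rm = TRUE)) {
    stop("nutrient concentrations must be non-negative", call. = FALSE)
  }
  out
}

#' Monthly coastal/offshore nutrient climatology with whisker statistics
#'
#' Bins nutrient observations into climatological months and
#' coastal/offshore zones and computes box-whisker summaries per
#' (month, zone, variable) for nitrate, phosphate and P*: median and
#' quartiles of the full bin (quartiles by linear interpolation between
#' order statistics), outliers defined as exceeding 1.5 times the
#' interquartile range beyond the quartiles, and whiskers at the most
#' extreme retained data points. Records in the 40–60 nm band (or outside
#' the requested months) contribute to no bin; every record lands in
#' exactly one of coastal bin, offshore bin, or excluded.
#'
#' @param records Data frame with columns `date`, `lon`, `lat`, `no3`,
#'   `po4`; an optional `dist_coast_nm` column is used directly, otherwise
#'   `grid` and `dist_field` are required to look distances up.
#' @param grid A [bt_grid()] (only needed when `dist_coast_nm` is absent).
#' @param dist_field Distance-to-coast matrix from [distance_to_coast()].
#' @param months Integer months to bin (default `5:9`, May–September).
#' @param coastal_max,offshore_min Zone thresholds in nm, see
#'   [classify_zone()].
#' @param whisker_k Outlier fence multiplier on the IQR (default 1.5).
#' @return A tibble of class `bt_climatology` with columns `month`, `zone`,
#'   `variable` (`no3`/`po4`/`pstar`), `median`, `q25`, `q75`,
#'   `whisker_lo`, `whisker_hi`, `n_used`, `n_outliers`. Empty bins are
#'   reported with `n_used = 0` and `NA` statistics.
#' @export
monthly_whisker_stats <- function(records, grid = NULL, dist_field = NULL,
                                  months = 5:9, coastal_max = 40,
                                  offshore_min = 60, whisker_k = 1.5) {
  stopifnot(is.data.frame(records))
  records <- tibble::as_tibble(records)
  if (!nrow(records)) stop("`records` is empty", call. = FALSE)
  if (!"dist_coast_nm" %in% names(records)) {
    if (is.null(grid) || is.null(dist_field)) {
      stop("need `grid` and `dist_field` when records carry no distances",
           call. = FALSE)
    }
    records$dist_coast_nm <- interp_space(grid, dist_field,
                                          records$lon, records$lat, "na")
  }
  records$zone <- classify_zone(records$dist_coast_nm,
                                coastal_max, offshore_min)
  records$pstar <- pstar(records$po4, records$no3)
  records$month <- as.integer(format(as.Date(records$date), "%m"))

  long <- records |>
    tidyr::pivot_longer(cols = c("no3", "po4", "pstar"),
                        names_to = "variable", values_to = "value") |>
    dplyr::filter(.data$month %in% months,
                  .data$zone %in% c("coastal", "offshore"),
                  !is.na(.data$value))
  out <- long |>
    dplyr::group_by(month = .data$month,
                    zone = factor(.data$zone,
                                  levels = c("coastal", "offshore")),
                    variable = factor(.data$variable,
                                      levels = c("no3", "po4", "pstar"))) |>
    dplyr::summarise(whisker_stats(.data$value, whisker_k),
                     .groups = "drop") |>
    tidyr::complete(month = months,
                    zone = factor(c("coastal", "offshore"),
                                  levels = c("coastal", "offshore")),
                    variable = factor(c("no3", "po4", "pstar"),
                                      levels = c("no3", "po4", "pstar")),
                    fill = list(n_used = 0L, n_outliers = 0L)) |>
    dplyr::arrange(.data$month, .data$zone, .data$variable)
  class(out) <- c("bt_climatology", class(out))
  out
}

# box-whisker summary of one bin: quartiles on the full bin, whiskers at
# the most extreme points inside the k * IQR fences
whisker_stats <- function(x, k = 1.5) {
  q <- stats::quantile(x, c(0.25, 0.5, 0.75), names = FALSE, type = 7)
  iqr <- q[3] - q[1]
  keep <- x >= q[1] - k * iqr & x <= q[3] + k * iqr
  tibble::tibble(median = q[2], q25 = q[1], q75 = q[3],
                 whisker_lo = min(x[keep]), whisker_hi = max(x[keep]),
                 n_used = sum(keep), n_outliers = sum(!keep))
}
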