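#' Plot a trajectory ensemble
#'
#' Drifter paths coloured by bloom label (when present), drawn over the
#' basin outline.
#'
#' @param object A `bt_trajectories` or `bt_env_history` tibble.
#' @param max_drifters Cap on the number of drifters drawn (default 200,
#'   sampled deterministically by id order).
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.bt_trajectories <- function(object, max_drifters = 200, ...) {
  ids <- unique(object$drifter_id)
  if (length(ids) > max_drifters) {
    keep <- ids[round(seq(1, length(ids), length.out = max_drifters))]
    object <- object[object$drifter_id %in% keep, ]
  }
  aes_line <- if ("label" %in% names(object)) {
    ggplot2::aes(x = .data$lon, y = .data$lat, group = .data$drifter_id,
                 colour = .data$label)
  } else {
    ggplot2::aes(x = .data$lon, y = .data$lat, group = .data$drifter_id)
  }
  ggplot2::ggplot(tibble::as_tibble(object)) +
    ggplot2::geom_path(aes_line, alpha = 0.4, linewidth = 0.3) +
    ggplot2::scale_colour_manual(
      values = c(bloom = "#00a0a0", no_bloom = "grey30",
                 discarded = "grey80"), drop = TRUE) +
    ggplot2::labs(x = "Longitude (°E)", y = "Latitude (°N)",
                  colour = NULL) +
    ggplot2::theme_minimal()
}

#' @rdname autoplot.bt_trajectories
#' @export
autoplot.bt_env_history <- function(object, max_drifters = 200, ...) {
  autoplot.bt_trajectories(object, max_drifters = max_drifters, ...)
}

#' Plot time-aligned group statistics
#'
#' Mean curves with mean ± one standard deviation ribbons for the bloom
#' and non-bloom ensembles against days before the event.
#'
#' @param object A `bt_group_summary` from [group_statistics()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.bt_group_summary <- function(object, ...) {
  lab <- c(sst = "SST (°C)", mld = "MLD (m)",
           par = "PAR (W m⁻²)",
           dist_coast_nm = "Distance to coast (nm)")
  yl <- lab[object$variable[1]]
  if (is.na(yl)) yl <- object$variable[1]
  ggplot2::ggplot(tibble::as_tibble(object),
                  ggplot2::aes(x = .data$time_rel_days, y = .data$mean,
                               colour = .data$group, fill = .data$group)) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$mean - .data$sd,
                                      ymax = .data$mean + .data$sd),
                         alpha = 0.2, colour = NA) +
    ggplot2::geom_line(linewidth = 0.8) +
    ggplot2::scale_colour_manual(
      values = c(bloom = "#00a0a0", no_bloom = "grey20"),
      aesthetics = c("colour", "fill")) +
    ggplot2::labs(x = "Days relative to bloom event", y = yl,
                  colour = NULL, fill = NULL) +
    ggplot2::theme_minimal()
}

#' Plot a nutrient climatology as whisker panels
#'
#' Median, quartile box and whiskers per month, coastal and offshore side
#' by side, one facet per variable (nitrate, phosphate, P*).
#'
#' @param object A `bt_climatology` from [monthly_whisker_stats()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.bt_climatology <- function(object, ...) {
  d <- tibble::as_tibble(object)
  d <- d[d$n_used > 0, ]
  pos <- ggplot2::position_dodge(width = 0.6)
  ggplot2::ggplot(d, ggplot2::aes(x = factor(.data$month),
                                  colour = .data$zone)) +
    ggplot2::geom_linerange(ggplot2::aes(ymin = .data$whisker_lo,
                                         ymax = .data$whisker_hi),
                            position = pos) +
    ggplot2::geom_crossbar(ggplot2::aes(y = .data$median,
                                        ymin = .data$q25,
                                        ymax = .data$q75),
                           width = 0.4, position = pos, fatten = 1.5) +
    ggplot2::facet_wrap(~variable, scales = "free_y",
                        labeller = ggplot2::labeller(
                          variable = c(no3 = "Nitrate",
                                       po4 = "Phosphate",
                                       pstar = "P*"))) +
    ggplot2::scale_colour_manual(
      values = c(coastal = "#a0522d", offshore = "#4169e1")) +
    ggplot2::labs(x = "Month",
                  y = "Concentration (µmol L⁻¹)",
                  colour = NULL) +
    ggplot2::theme_minimal()
}

#' @export
#' @importFrom ggplot2 autoplot
ggplot2::autoplot
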