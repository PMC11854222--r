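#' Plot a release trajectory
#'
#' Two-panel view of a simulated run: per-phase protein amounts (mol) and
#' the cumulative release fraction over time. A dashed vertical line marks
#' the dissolution event where one is configured.
#'
#' @param object A `release_trajectory` from [simulate_release()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.release_trajectory <- function(object, ...) {
  long <- tidyr::pivot_longer(
    dplyr::select(tibble::as_tibble(object), "t_min", "n_s_mol",
                  "n_ads_mol", "n_b_mol"),
    -"t_min", names_to = "phase", values_to = "n_mol")
  long$phase <- factor(long$phase,
                       levels = c("n_s_mol", "n_ads_mol", "n_b_mol"),
                       labels = c("solid", "adsorbed", "bulk"))
  p <- ggplot2::ggplot(long, ggplot2::aes(x = .data$t_min, y = .data$n_mol,
                                          colour = .data$phase)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "time (min)", y = "protein amount (mol)",
                  colour = "phase") +
    ggplot2::theme_minimal()
  cfg <- attr(object, "config", exact = TRUE)
  if (!is.null(cfg) && !is.null(cfg$t_dissolve)) {
    p <- p + ggplot2::geom_vline(xintercept = cfg$t_dissolve,
                                 linetype = "dashed", colour = "red")
  }
  p
}

#' Plot a measurement time series
#'
#' Points with optional +/- 1 SD error bars.
#'
#' @param object A [release_timeseries()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.release_timeseries <- function(object, ...) {
  ylab <- switch(series_kind(object),
                 swelling_weight = "weight (g)",
                 bulk_concentration = "bulk concentration (mol/cm³)",
                 release_fraction = "release fraction")
  p <- ggplot2::ggplot(tibble::as_tibble(object),
                       ggplot2::aes(x = .data$t_min, y = .data$y)) +
    ggplot2::geom_point() +
    ggplot2::geom_line(alpha = 0.4) +
    ggplot2::labs(x = "time (min)", y = ylab) +
    ggplot2::theme_minimal()
  if ("sd" %in% names(object)) {
    p <- p + ggplot2::geom_errorbar(
      ggplot2::aes(ymin = .data$y - .data$sd, ymax = .data$y + .data$sd),
      width = 0)
  }
  p
}

#' Plot a fitted kinetic model against its data
#'
#' Observed values (points) with the fitted curve (line). For swelling fits
#' the y axis is adsorbed volume; for release fits it is the fitted
#' observable.
#'
#' @param object A `release_fit`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.release_fit <- function(object, ...) {
  series <- object$series
  if (is.null(series)) stop("fit carries no data to plot", call. = FALSE)
  if (startsWith(object$method, "fit_kv")) {
    obs <- (series$y - series$y[1]) / .rho_water
    ylab <- "adsorbed volume (cm³)"
  } else {
    obs <- series$y
    ylab <- series_kind(series)
  }
  df <- tibble::tibble(t_min = series$t_min, observed = obs,
                       fitted = object$fitted)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$t_min)) +
    ggplot2::geom_point(ggplot2::aes(y = .data$observed)) +
    ggplot2::geom_line(ggplot2::aes(y = .data$fitted), colour = "steelblue") +
    ggplot2::labs(x = "time (min)", y = ylab) +
    ggplot2::theme_minimal()
}
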