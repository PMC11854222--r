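#' Measurement time series
#'
#' Canonical container for the package's tabular measurements: particle
#' weights during swelling, bulk concentrations or cumulative release
#' fractions during a release run. A thin tibble with a `kind` attribute and
#' validated structure.
#'
#' @param t_min Sampling times, min; strictly increasing, `t_min[1] >= 0`.
#' @param y Measured values: g for `swelling_weight`, mol/cm^3 for
#'   `bulk_concentration`, dimensionless in `[0, 1]`-ish for
#'   `release_fraction`.
#' @param sd Optional per-point standard deviations (same unit as `y`);
#'   must be > 0 where present.
#' @param kind One of `"swelling_weight"`, `"bulk_concentration"`,
#'   `"release_fraction"`.
#' @return A tibble of class `release_timeseries` with columns `t_min`, `y`
#'   and (if given) `sd`.
#' @export
release_timeseries <- function(t_min, y, sd = NULL,
                               kind = c("swelling_weight",
                                        "bulk_concentration",
                                        "release_fraction")) {
  kind <- match.arg(kind)
  stopifnot(is.numeric(t_min), is.numeric(y))
  if (length(t_min) != length(y)) {
    stop("`t_min` and `y` must have equal length", call. = FALSE)
  }
  if (length(t_min) == 0L) stop("empty time series", call. = FALSE)
  if (t_min[1] < 0) stop("t_min[1] must be >= 0", call. = FALSE)
  if (any(diff(t_min) <= 0)) {
    stop("`t_min` must be strictly increasing", call. = FALSE)
  }
  if (!is.null(sd)) {
    stopifnot(is.numeric(sd), length(sd) == length(y))
    if (any(!is.na(sd) & sd <= 0)) {
      stop("`sd` must be > 0 where present", call. = FALSE)
    }
  }
  out <- tibble::tibble(t_min = as.numeric(t_min), y = as.numeric(y))
  if (!is.null(sd)) out$sd <- as.numeric(sd)
  class(out) <- c("release_timeseries", class(out))
  attr(out, "kind") <- kind
  out
}

#' Kind of a measurement series
#'
#' @param series A [release_timeseries()].
#' @return The kind string.
#' @export
series_kind <- function(series) {
  k <- attr(series, "kind", exact = TRUE)
  if (is.null(k)) stop("not a release_timeseries: missing kind", call. = FALSE)
  k
}

#' @export
print.release_timeseries <- function(x, ...) {
  cat(sprintf("<release_timeseries: %s, %d points>\n", series_kind(x), nrow(x)))
  NextMethod()
}
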