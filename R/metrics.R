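#' Swelling degree
#'
#' Percent mass gain of a dry particle after liquid uptake:
#' \eqn{Q = (M_{sw} - M_d) / M_d \times 100}.
#'
#' @param m_sw Swollen mass (any mass unit, shared with `m_d`); vectorized.
#' @param m_d Dry mass, > 0.
#' @return Swelling degree, percent.
#' @examples
#' swelling_degree(2, 1) # 100
#' @export
swelling_degree <- function(m_sw, m_d) {
  stopifnot(is.numeric(m_sw), is.numeric(m_d))
  if (any(m_d <= 0)) stop("dry mass `m_d` must be > 0", call. = FALSE)
  if (any(m_sw < m_d)) {
    stop("swollen mass `m_sw` must be >= dry mass `m_d`", call. = FALSE)
  }
  (m_sw - m_d) / m_d * 100
}

#' Encapsulation efficiency
#'
#' Percent of offered protein retained in the particles:
#' \eqn{EE = (m - m_f) / m \times 100}, with `m` the total protein offered
#' and `m_f` the free (unencapsulated) protein recovered from the supernatant.
#'
#' @param m_total Total protein offered, > 0; vectorized.
#' @param m_free Free protein, in `[0, m_total]`.
#' @return Encapsulation efficiency, percent.
#' @export
encapsulation_efficiency <- function(m_total, m_free) {
  stopifnot(is.numeric(m_total), is.numeric(m_free))
  if (any(m_total <= 0)) stop("`m_total` must be > 0", call. = FALSE)
  if (any(m_free < 0 | m_free > m_total)) {
    stop("`m_free` must lie in [0, m_total]", call. = FALSE)
  }
  (m_total - m_free) / m_total * 100
}

#' Summarize replicate batch metrics
#'
#' Mean and sample (n-1) standard deviation of replicate percent values,
#' e.g. encapsulation efficiencies across production batches. Values are
#' carried at full precision; `display` columns round to 1 decimal the way
#' such tables are conventionally reported.
#'
#' @param values Numeric vector of >= 2 values (percent).
#' @return A one-row tibble: `n`, `mean`, `sd`, `mean_display`, `sd_display`.
#' @examples
#' summarize_batches(c(55.4, 62.6, 78.1, 67.9, 64.8))
#' @export
summarize_batches <- function(values) {
  stopifnot(is.numeric(values))
  values <- values[!is.na(values)]
  if (length(values) < 2L) {
    stop("need at least 2 values to summarize (got ", length(values), ")",
         call. = FALSE)
  }
  m <- mean(values)
  s <- stats::sd(values)
  tibble::tibble(n = length(values), mean = m, sd = s,
                 mean_display = round(m, 1), sd_display = round(s, 1))
}

#' Cumulative release percent of a trajectory
#'
#' Converts a simulated trajectory into the cumulative-release curve
#' \eqn{C(t) = 100 \, n_b(t) / N} with `N` the total protein load; after a
#' dissolution event the curve sits at 100.
#'
#' @param trajectory A `release_trajectory` from [simulate_release()].
#' @return A [release_timeseries()] of kind `release_fraction` whose `y` is
#'   in percent.
#' @export
cumulative_release_percent <- function(trajectory) {
  stopifnot(inherits(trajectory, "release_trajectory"), nrow(trajectory) > 0)
  release_timeseries(t_min = trajectory$t_min,
                     y = 100 * trajectory$release_fraction,
                     kind = "release_fraction")
}
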