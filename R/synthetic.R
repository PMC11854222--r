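# density used to convert adsorbed liquid mass (g) to volume (cm^3)
.rho_water <- 1.0

#' Default release sampling grid
#'
#' Sampling times (min) typical of an in vitro release assay: dense over the
#' first minutes, where the film transfer plays out, then sparser out to
#' 10 h. Used as the default grid by the generator, the fitting helpers and
#' the sensitivity profile.
#'
#' @return Numeric vector of times, min, starting at 0.
#' @export
default_release_times <- function() {
  c(0, 1, 2, 3, 4, 5, 7.5, 10, 15, 20, 30, 45, 60,
    90, 120, 180, 240, 360, 480, 600)
}

#' Generate a synthetic swelling-weight series
#'
#' Forward-evaluates the analytic swelling law, converts adsorbed volume to
#' weight via the water density (1 g/cm^3), and adds seeded additive Gaussian
#' noise: `W(t) = dry_mass + rho * V_ads(t) + e`, `e ~ N(0, sd^2)`. The t = 0
#' point is left noise-free (it defines the dry reference every downstream
#' computation subtracts).
#'
#' @param params A [swelling_params()].
#' @param dry_mass Dry particle mass, g.
#' @param times Sampling times, min; sorted, starting at 0.
#' @param sd Measurement SD on the weights, g. `0` gives the exact curve.
#' @param seed Integer seed for the noise draw.
#' @return A [release_timeseries()] of kind `swelling_weight` with per-point
#'   `sd` attached.
#' @export
generate_swelling_series <- function(params, dry_mass, times, sd = 0,
                                     seed = 1L) {
  stopifnot(inherits(params, "swelling_params"),
            is.numeric(dry_mass), dry_mass > 0,
            is.numeric(times), is.numeric(sd), sd >= 0)
  if (times[1] != 0 || any(diff(times) <= 0)) {
    stop("`times` must be sorted, starting at 0", call. = FALSE)
  }
  w <- dry_mass + .rho_water * swelling_closed_form(times, params)
  if (sd > 0) {
    eps <- withr_rng(seed, stats::rnorm(length(times), 0, sd))
    eps[1] <- 0
    w <- w + eps
  }
  release_timeseries(t_min = times, y = w,
                     sd = if (sd > 0) rep(sd, length(times)) else NULL,
                     kind = "swelling_weight")
}

# evaluate expr under a local RNG state seeded with `seed`
withr_rng <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  expr
}

#' Generate a synthetic release series
#'
#' Forward-simulates the conservative-mode release trajectory for a batch,
#' samples the requested observable on the time grid, and adds seeded
#' additive Gaussian noise of standard deviation `sd` (homoscedastic in the
#' measured unit). Release fractions are clipped to `[0, 1]` after noise
#' (they are physical fractions). Per-point `sd` is attached; the relative
#' error `sd / y` — the convention used for error bars on release plots,
#' where uncertainty matters most at low concentration — is available via
#' `relative_error = TRUE`.
#'
#' @param config A [batch_config()].
#' @param times Sampling times, min. Defaults to [default_release_times()].
#' @param sd Noise SD in the unit of the observable. The release-fraction
#'   measurement SD of the emulated assay is 0.008.
#' @param seed Integer seed.
#' @param observable `"bulk_concentration"` (mol/cm^3) or
#'   `"release_fraction"`.
#' @param relative_error If `TRUE`, adds a `rel_err = sd / y` column
#'   (`NA` where `y` is 0).
#' @return A [release_timeseries()] of the requested kind.
#' @export
generate_release_series <- function(config, times = default_release_times(),
                                    sd = 0.008, seed = 1L,
                                    observable = c("bulk_concentration",
                                                   "release_fraction"),
                                    relative_error = FALSE) {
  observable <- match.arg(observable)
  stopifnot(inherits(config, "batch_config"), is.numeric(sd), sd >= 0)
  traj <- simulate_release(config, times = times, mode = "conservative")
  y <- if (observable == "bulk_concentration") {
    traj$C_b_mol_per_cm3
  } else {
    traj$release_fraction
  }
  if (sd > 0) {
    y <- y + withr_rng(seed, stats::rnorm(length(y), 0, sd))
  }
  if (observable == "release_fraction") y <- pmin(pmax(y, 0), 1)
  out <- release_timeseries(t_min = times, y = y,
                            sd = if (sd > 0) rep(sd, length(y)) else NULL,
                            kind = observable)
  if (relative_error) {
    out$rel_err <- ifelse(out$y > 0, sd / out$y, NA_real_)
  }
  out
}

#' Packaged batch configurations
#'
#' The three release experiments shipped with the package, as reported for
#' the lactoferrin-loaded alginate microparticle study the package models:
#' `batch1` (40 cm^3 stirred bulk), `batch2` (20 cm^3 stirred) and `batch3`
#' (20 cm^3 stagnant), each with its fitted transport parameters
#' (`H_Lf`, `beta_sl`, `beta_ll`).
#'
#' @return Named list of three [batch_config()] objects.
#' @examples
#' example_batches()$batch3$beta_ll
#' @export
example_batches <- function() {
  paths <- file.path("extdata", paste0("batch", 1:3, ".json"))
  cfgs <- lapply(paths, function(p) {
    read_batch_config(system.file(p, package = "microrelease", mustWork = TRUE))
  })
  names(cfgs) <- paste0("batch", 1:3)
  cfgs
}

#' Packaged swelling-weight measurements
#'
#' Mean particle weights (triplicate, with SD) of protein-loaded particles
#' during swelling, measured at 0, 1, 3, 5, 24 and 48 h. This is the series
#' the swelling constant `k_v` is fitted from.
#'
#' @return A [release_timeseries()] of kind `swelling_weight` (grams).
#' @export
example_swelling_weights <- function() {
  read_timeseries(system.file("extdata", "swelling_weights.csv",
                              package = "microrelease", mustWork = TRUE),
                  kind = "swelling_weight")
}

#' Packaged swelling-degree table
#'
#' Swelling degree Q (%) of plain (`ALG`) and protein-loaded (`ALG:Lf`)
#' particles over time, mean +/- SD of triplicates. An experiment distinct
#' from [example_swelling_weights()]; the two are not mutually consistent at
#' 48 h and are kept as separate fixtures.
#'
#' @return A tibble with columns `sample`, `t_h`, `Q_pct`, `sd`.
#' @export
example_swelling_degree <- function() {
  readr::read_csv(system.file("extdata", "swelling_degree.csv",
                              package = "microrelease", mustWork = TRUE),
                  show_col_types = FALSE)
}

#' Packaged encapsulation-efficiency table
#'
#' Encapsulation efficiency EE (%) of five production batches.
#'
#' @return A tibble with columns `batch`, `EE_pct`.
#' @export
example_encapsulation <- function() {
  readr::read_csv(system.file("extdata", "encapsulation.csv",
                              package = "microrelease", mustWork = FALSE),
                  show_col_types = FALSE)
}
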