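#' Swelling rate of a particle
#'
#' First-order swelling law: the uptake rate is proportional to the remaining
#' capacity, \eqn{dV_{ads}/dt = k_v (V_{max} - V_{ads})}. The rate vanishes
#' exactly at `V_ads = V_max`.
#'
#' @param V_ads Current adsorbed volume, cm^3. Must not exceed `V_max`.
#' @param params A [swelling_params()].
#' @return Uptake rate, cm^3/min (vectorized over `V_ads`).
#' @examples
#' p <- swelling_params(k_v = 0.00335, V_max = 1.27e-3, V_ads0 = 0)
#' swelling_rate(0, p)
#' @export
swelling_rate <- function(V_ads, params) {
  stopifnot(inherits(params, "swelling_params"), is.numeric(V_ads))
  if (any(V_ads > params$V_max)) {
    stop("V_ads exceeds V_max (", params$V_max, " cm^3): swelling law is ",
         "defined only up to the maximum swelling volume", call. = FALSE)
  }
  params$k_v * (params$V_max - V_ads)
}

#' Analytic solution of the swelling law
#'
#' Closed form of the first-order uptake equation:
#' \deqn{V_{ads}(t) = V_{max} - (V_{max} - V_{ads,0}) e^{-k_v t}.}
#' Used as the exact oracle against which the numerical integrator is checked,
#' and as the forward model when fitting `k_v` to weight--time data.
#'
#' @param t Time, min (vectorized; all values must be >= 0).
#' @param params A [swelling_params()].
#' @return Adsorbed volume at `t`, cm^3.
#' @export
swelling_closed_form <- function(t, params) {
  stopifnot(inherits(params, "swelling_params"), is.numeric(t))
  if (any(t < 0)) stop("t must be >= 0 min", call. = FALSE)
  params$V_max - (params$V_max - params$V_ads0) * exp(-params$k_v * t)
}

#' Phase concentrations of a release state
#'
#' Converts the per-phase amounts of a state into concentrations:
#' `C_s = n_s / V_s`, `C_ads = n_ads / V_ads`, `C_b = n_b / V_b`.
#'
#' @param state A named list or one-row data frame with `V_ads`, `V_b`,
#'   `n_s`, `n_ads`, `n_b` (volumes cm^3, amounts mol).
#' @param config A [batch_config()] supplying the constant solid volume `V_s`.
#' @return Named numeric vector `c(C_s, C_ads, C_b)`, mol/cm^3.
#' @export
concentrations <- function(state, config) {
  stopifnot(inherits(config, "batch_config"))
  s <- as.list(state)
  if (config$V_s <= 0 || s$V_ads <= 0 || s$V_b <= 0) {
    stop("degenerate state: all phase volumes must be > 0 to form ",
         "concentrations (V_s = ", config$V_s, ", V_ads = ", s$V_ads,
         ", V_b = ", s$V_b, ")", call. = FALSE)
  }
  c(C_s = s$n_s / config$V_s, C_ads = s$n_ads / s$V_ads, C_b = s$n_b / s$V_b)
}

#' Solid-to-liquid transfer flux
#'
#' Film flux across the stagnant liquid layer inside the particle:
#' \eqn{J_{sl} = \beta_{sl} (C_s / H - C_{ads})}. Positive values move protein
#' from the solid matrix into the adsorbed liquid; the driving force vanishes
#' at the partition equilibrium \eqn{C_s = H \, C_{ads}}.
#'
#' @param C Named numeric vector with `C_s` and `C_ads` (mol/cm^3), as
#'   returned by [concentrations()].
#' @param config A [batch_config()] supplying `beta_sl` and `H_Lf`.
#' @return Flux, mol cm^-3 min^-1.
#' @export
flux_sl <- function(C, config) {
  stopifnot(inherits(config, "batch_config"))
  C <- as.list(C)
  config$beta_sl * (C$C_s / config$H_Lf - C$C_ads)
}

#' Liquid-to-liquid transfer flux
#'
#' Single-film flux across the adsorbed-liquid / bulk interface:
#' \eqn{J_{ll} = \beta_{ll} (C_{ads} - C_b)}. Positive values move protein
#' from the particle's adsorbed liquid into the external bulk.
#'
#' @param C Named numeric vector with `C_ads` and `C_b` (mol/cm^3).
#' @param config A [batch_config()] supplying `beta_ll`.
#' @return Flux, mol cm^-3 min^-1.
#' @export
flux_ll <- function(C, config) {
  stopifnot(inherits(config, "batch_config"))
  C <- as.list(C)
  config$beta_ll * (C$C_ads - C$C_b)
}

#' Right-hand side of the release ODE system
#'
#' Time derivatives of the five dynamic states
#' `(V_ads, V_b, n_s, n_ads, n_b)`. The volume pair always satisfies
#' `dV_ads + dV_b = 0`. Two mole-balance conventions are available:
#'
#' * `"conservative"` (default): `dn_ads = (J_sl - J_ll) * V_ads`, so that
#'   `dn_s + dn_ads + dn_b = 0` identically — protein moves
#'   solid -> adsorbed liquid -> bulk without creation or loss.
#' * `"as_printed"`: `dn_ads = (J_ll - J_sl) * V_ads`. This variant is kept
#'   for documentation: its mole balance sums to
#'   `2 (J_ll - J_sl) * V_ads`, which is nonzero whenever the two fluxes
#'   differ, i.e. it does not conserve protein.
#'
#' @param t Time, min (unused by the autonomous system; kept for the
#'   integrator signature).
#' @param state Named list/vector with `V_ads`, `V_b`, `n_s`, `n_ads`, `n_b`.
#' @param config A [batch_config()].
#' @param mode `"conservative"` or `"as_printed"`.
#' @return Named numeric vector of the five derivatives
#'   `(dV_ads, dV_b, dn_s, dn_ads, dn_b)`.
#' @export
release_rhs <- function(t, state, config, mode = c("conservative", "as_printed")) {
  mode <- match.arg(mode)
  stopifnot(inherits(config, "batch_config"))
  s <- as.list(state)
  Vmax <- v_max(config)
  dV <- config$k_v * (Vmax - s$V_ads)
  C <- concentrations(s, config)
  Jsl <- flux_sl(C, config)
  Jll <- flux_ll(C, config)
  dn_s <- -Jsl * s$V_ads
  dn_b <- +Jll * s$V_ads
  dn_ads <- if (mode == "conservative") (Jsl - Jll) * s$V_ads else (Jll - Jsl) * s$V_ads
  c(dV_ads = dV, dV_b = -dV, dn_s = dn_s, dn_ads = dn_ads, dn_b = dn_b)
}

# deSolve-facing wrapper around release_rhs; parms carries config and mode.
.release_deriv <- function(t, y, parms) {
  cfg <- parms$config
  Vmax <- parms$Vmax
  V_ads <- y[[1L]]
  dV <- cfg$k_v * (Vmax - V_ads)
  C_s <- y[[3L]] / cfg$V_s
  C_ads <- y[[4L]] / V_ads
  C_b <- y[[5L]] / y[[2L]]
  Jsl <- cfg$beta_sl * (C_s / cfg$H_Lf - C_ads)
  Jll <- cfg$beta_ll * (C_ads - C_b)
  dn_s <- -Jsl * V_ads
  dn_b <- +Jll * V_ads
  dn_ads <- if (parms$conservative) (Jsl - Jll) * V_ads else (Jll - Jsl) * V_ads
  list(c(dV, -dV, dn_s, dn_ads, dn_b))
}

#' Simulate a release experiment
#'
#' Integrates the five-state swelling + two-film release system from the
#' batch initial condition over a time grid, with `lsoda` (stiff-capable,
#' relative tolerance `1e-9`, absolute tolerances scaled per component to the
#' initial magnitudes — the fast solid--liquid film makes the system stiff).
#'
#' If `config$t_dissolve` is set, the particle dissolves at that time: all
#' protein still in the solid and adsorbed phases is transferred to the bulk
#' instantaneously, and both transport and swelling stop, so every grid point
#' at `t >= t_dissolve` carries the frozen post-dissolution state and a
#' release fraction of 1.
#'
#' @param config A [batch_config()].
#' @param times Output time grid, min; strictly increasing, starting at 0.
#' @param mode Mole-balance convention, see [release_rhs()].
#' @param rtol,atol_scale Integrator tolerances. `atol_scale` multiplies the
#'   per-component magnitude scales `(V_max, V_b0, N, N, N)` to give the
#'   absolute tolerance vector.
#' @return A tibble of class `release_trajectory` with columns `t_min`,
#'   `V_ads_cm3`, `V_b_cm3`, `n_s_mol`, `n_ads_mol`, `n_b_mol`,
#'   `C_b_mol_per_cm3`, `release_fraction`, `dissolved`. The generating
#'   `config` and `mode` are attached as attributes.
#' @examples
#' cfg <- example_batches()$batch1
#' traj <- simulate_release(cfg, times = seq(0, 60, by = 5))
#' traj$release_fraction
#' @export
simulate_release <- function(config, times,
                             mode = c("conservative", "as_printed"),
                             rtol = 1e-9, atol_scale = 1e-9) {
  mode <- match.arg(mode)
  stopifnot(inherits(config, "batch_config"), is.numeric(times))
  if (length(times) < 2L || times[1] != 0 || any(diff(times) <= 0)) {
    stop("`times` must be a strictly increasing grid starting at 0 min",
         call. = FALSE)
  }
  Vmax <- v_max(config)
  N <- total_moles(config)
  y0 <- c(V_ads = config$V_ads0, V_b = config$V_b0,
          n_s = config$n_s0, n_ads = config$n_ads0, n_b = config$n_b0)
  atol <- pmax(atol_scale * c(Vmax, config$V_b0, N, N, N), 1e-300)
  parms <- list(config = config, Vmax = Vmax,
                conservative = (mode == "conservative"))

  td <- config$t_dissolve
  t_solve <- times
  if (!is.null(td)) t_solve <- sort(unique(c(times[times < td], td)))

  if (length(t_solve) >= 2L) {
    sol <- deSolve::lsoda(y = y0, times = t_solve, func = .release_deriv,
                          parms = parms, rtol = rtol, atol = atol)
    diagn <- attr(sol, "istate")
    if (!is.null(diagn) && diagn[1L] < 0) {
      stop("ODE integration failed (lsoda istate = ", diagn[1L],
           "); consider loosening tolerances or shortening the horizon",
           call. = FALSE)
    }
    sol <- as.data.frame(sol)
  } else {
    sol <- data.frame(time = t_solve, V_ads = y0[["V_ads"]], V_b = y0[["V_b"]],
                      n_s = y0[["n_s"]], n_ads = y0[["n_ads"]], n_b = y0[["n_b"]])
  }

  if (!is.null(td)) {
    # frozen post-dissolution state: all remaining protein to the bulk
    last <- sol[nrow(sol), ]
    frozen <- data.frame(time = times[times >= td],
                         V_ads = last$V_ads, V_b = last$V_b,
                         n_s = 0, n_ads = 0,
                         n_b = last$n_s + last$n_ads + last$n_b)
    sol <- rbind(sol[sol$time %in% times[times < td], , drop = FALSE], frozen)
  }

  out <- tibble::tibble(
    t_min = sol$time,
    V_ads_cm3 = sol$V_ads,
    V_b_cm3 = sol$V_b,
    n_s_mol = sol$n_s,
    n_ads_mol = sol$n_ads,
    n_b_mol = sol$n_b,
    C_b_mol_per_cm3 = sol$n_b / sol$V_b,
    release_fraction = if (N > 0) sol$n_b / N else 0,
    dissolved = if (is.null(td)) FALSE else sol$time >= td
  )
  class(out) <- c("release_trajectory", class(out))
  attr(out, "config") <- config
  attr(out, "mode") <- mode
  out
}

#' Analytic partition equilibrium of a release run
#'
#' Without dissolution the system relaxes to a state in which the two liquid
#' phases share one concentration `c` and the solid sits at `C_s = H c`.
#' Volume conservation fixes the final volumes
#' (`V_ads = V_max`, `V_b_inf = V_b0 + V_ads0 - V_max`) and mole conservation
#' gives
#' \deqn{c = \frac{N}{H V_s + V_{max} + V_{b\infty}},}
#' with `N` the total protein load. Serves as the closed-form oracle for
#' long-horizon simulations.
#'
#' @param config A [batch_config()]; its `t_dissolve` must be `NULL`.
#' @return A one-row tibble with the equilibrium state (`V_ads_cm3`,
#'   `V_b_cm3`, `n_s_mol`, `n_ads_mol`, `n_b_mol`), the common liquid
#'   concentration `c_eq_mol_per_cm3`, and `bulk_fraction` (= fraction of the
#'   load released at equilibrium).
#' @examples
#' equilibrium_state(example_batches()$batch1)$bulk_fraction
#' @export
equilibrium_state <- function(config) {
  stopifnot(inherits(config, "batch_config"))
  if (!is.null(config$t_dissolve)) {
    stop("equilibrium_state() describes the no-dissolution limit; ",
         "`t_dissolve` is set on this config", call. = FALSE)
  }
  Vmax <- v_max(config)
  V_b_inf <- config$V_b0 + config$V_ads0 - Vmax
  if (V_b_inf <= 0) {
    stop("bulk volume would be exhausted by swelling (V_b0 + V_ads0 <= V_max)",
         call. = FALSE)
  }
  N <- total_moles(config)
  c_eq <- N / (config$H_Lf * config$V_s + Vmax + V_b_inf)
  tibble::tibble(
    V_ads_cm3 = Vmax,
    V_b_cm3 = V_b_inf,
    n_s_mol = config$H_Lf * c_eq * config$V_s,
    n_ads_mol = c_eq * Vmax,
    n_b_mol = c_eq * V_b_inf,
    c_eq_mol_per_cm3 = c_eq,
    bulk_fraction = if (N > 0) c_eq * V_b_inf / N else 0
  )
}
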