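#' Swelling-law parameters
#'
#' Bundle of constants for the first-order swelling law
#' \eqn{dV_{ads}/dt = k_v (V_{max} - V_{ads})}: the particle takes up liquid
#' at a rate proportional to its remaining swelling capacity.
#'
#' @param k_v Swelling rate constant, 1/min. Must be > 0.
#' @param V_max Maximum adsorbed-liquid volume, cm^3. Must exceed `V_ads0`.
#' @param V_ads0 Initial adsorbed volume, cm^3. Defaults to the small
#'   positive sentinel `1e-8` so that the adsorbed-phase concentration
#'   `n_ads / V_ads` is defined from the first instant.
#'
#' @return An object of class `swelling_params` (a validated named list).
#' @examples
#' swelling_params(k_v = 0.00335, V_max = 1.27e-3)
#' @export
swelling_params <- function(k_v, V_max, V_ads0 = 1e-8) {
  stopifnot(is.numeric(k_v), length(k_v) == 1L,
            is.numeric(V_max), length(V_max) == 1L,
            is.numeric(V_ads0), length(V_ads0) == 1L)
  if (!is.finite(k_v) || k_v <= 0) {
    stop("`k_v` must be a finite positive rate (1/min), got ", k_v, call. = FALSE)
  }
  if (!is.finite(V_ads0) || V_ads0 < 0) {
    stop("`V_ads0` must be nonnegative (cm^3), got ", V_ads0, call. = FALSE)
  }
  if (!is.finite(V_max) || V_max <= V_ads0) {
    stop("`V_max` (cm^3) must exceed `V_ads0`; got V_max = ", V_max,
         ", V_ads0 = ", V_ads0, call. = FALSE)
  }
  structure(list(k_v = k_v, V_max = V_max, V_ads0 = V_ads0),
            class = "swelling_params")
}

#' @export
print.swelling_params <- function(x, ...) {
  cat("<swelling_params>\n")
  cat(sprintf("  k_v    = %g 1/min\n", x$k_v))
  cat(sprintf("  V_max  = %g cm^3\n", x$V_max))
  cat(sprintf("  V_ads0 = %g cm^3\n", x$V_ads0))
  invisible(x)
}

# field order used for JSON serialization (stable external interface)
.batch_fields <- c("W_s", "V_s", "V_ads0", "V_h", "V_b0", "k_v",
                   "n_s0", "n_ads0", "n_b0", "H_Lf", "beta_sl", "beta_ll",
                   "t_dissolve", "stirred", "mw_lf")

#' Batch configuration for a release experiment
#'
#' Full parameter set of one release run: geometry, phase volumes, initial
#' protein loads, the solid--liquid partition constant and the two film
#' mass-transfer coefficients. The maximum swelling volume is derived as
#' `V_max = V_h * W_s` (hydration capacity times dry charge), the only
#' dimensionally consistent combination of the listed quantities.
#'
#' @param W_s Dry particle charge, g.
#' @param V_s Solid-phase volume, cm^3; held constant over a run.
#' @param V_ads0 Initial adsorbed-liquid volume, cm^3 (small positive sentinel).
#' @param V_h Hydration capacity, cm^3 of liquid adsorbed per g of dry solid.
#' @param V_b0 Initial bulk (release-medium) volume, cm^3.
#' @param k_v Swelling rate constant, 1/min.
#' @param n_s0,n_ads0,n_b0 Initial protein amounts in the solid,
#'   adsorbed-liquid and bulk phases, mol.
#' @param H_Lf Solid/adsorbed-liquid partition constant
#'   \eqn{H = C_s / C_{ads}} at equilibrium, dimensionless.
#' @param beta_sl Solid--liquid film mass-transfer coefficient, 1/min.
#' @param beta_ll Liquid--liquid global mass-transfer coefficient, 1/min.
#' @param t_dissolve Optional dissolution time, min. `NULL` (default) means the
#'   particle never dissolves; otherwise at `t_dissolve` all protein remaining
#'   in the particle is assigned to the bulk and all fluxes stop.
#' @param stirred Logical annotation of whether the bulk was stirred
#'   (metadata only; it enters no equation).
#' @param mw_lf Molar mass used for gram/mole conversion, g/mol.
#'
#' @return An object of class `batch_config`.
#' @seealso [example_batches()] for the three packaged configurations.
#' @examples
#' cfg <- example_batches()$batch1
#' v_max(cfg)
#' @export
batch_config <- function(W_s, V_s, V_ads0 = 1e-8, V_h, V_b0, k_v,
                         n_s0, n_ads0 = 0, n_b0 = 0,
                         H_Lf, beta_sl, beta_ll,
                         t_dissolve = NULL, stirred = TRUE, mw_lf = 75000) {
  num1 <- function(x, nm) {
    if (!is.numeric(x) || length(x) != 1L || !is.finite(x)) {
      stop("`", nm, "` must be a single finite number", call. = FALSE)
    }
    as.numeric(x)
  }
  pos <- c(W_s = W_s, V_s = V_s, V_h = V_h, V_b0 = V_b0, k_v = k_v,
           H_Lf = H_Lf, beta_sl = beta_sl, beta_ll = beta_ll, mw_lf = mw_lf)
  for (nm in names(pos)) {
    v <- num1(pos[[nm]], nm)
    if (v <= 0) stop("`", nm, "` must be > 0, got ", v, call. = FALSE)
  }
  nonneg <- c(V_ads0 = V_ads0, n_s0 = n_s0, n_ads0 = n_ads0, n_b0 = n_b0)
  for (nm in names(nonneg)) {
    v <- num1(nonneg[[nm]], nm)
    if (v < 0) stop("`", nm, "` must be >= 0, got ", v, call. = FALSE)
  }
  if (V_h * W_s <= V_ads0) {
    stop("swelling capacity V_h * W_s (= ", V_h * W_s,
         " cm^3) must exceed V_ads0 (= ", V_ads0, " cm^3)", call. = FALSE)
  }
  if (!is.null(t_dissolve)) {
    t_dissolve <- num1(t_dissolve, "t_dissolve")
    if (t_dissolve <= 0) stop("`t_dissolve` must be > 0 min", call. = FALSE)
  }
  stopifnot(is.logical(stirred), length(stirred) == 1L)
  structure(list(W_s = as.numeric(W_s), V_s = as.numeric(V_s),
                 V_ads0 = as.numeric(V_ads0), V_h = as.numeric(V_h),
                 V_b0 = as.numeric(V_b0), k_v = as.numeric(k_v),
                 n_s0 = as.numeric(n_s0), n_ads0 = as.numeric(n_ads0),
                 n_b0 = as.numeric(n_b0), H_Lf = as.numeric(H_Lf),
                 beta_sl = as.numeric(beta_sl), beta_ll = as.numeric(beta_ll),
                 t_dissolve = t_dissolve, stirred = stirred,
                 mw_lf = as.numeric(mw_lf)),
            class = "batch_config")
}

#' Maximum swelling volume of a batch
#'
#' `V_max = V_h * W_s`: hydration capacity (cm^3/g) times the dry charge (g).
#'
#' @param config A [batch_config()].
#' @return Maximum adsorbed volume, cm^3.
#' @export
v_max <- function(config) {
  stopifnot(inherits(config, "batch_config"))
  config$V_h * config$W_s
}

#' Total protein load of a batch
#'
#' @param config A [batch_config()].
#' @return `n_s0 + n_ads0 + n_b0`, mol.
#' @export
total_moles <- function(config) {
  stopifnot(inherits(config, "batch_config"))
  config$n_s0 + config$n_ads0 + config$n_b0
}

#' Swelling parameters embedded in a batch configuration
#'
#' @param config A [batch_config()].
#' @return A [swelling_params()] with `V_max = V_h * W_s`.
#' @export
swelling_params_of <- function(config) {
  stopifnot(inherits(config, "batch_config"))
  swelling_params(k_v = config$k_v, V_max = v_max(config),
                  V_ads0 = config$V_ads0)
}

#' @export
print.batch_config <- function(x, ...) {
  cat("<batch_config>\n")
  cat(sprintf("  dry charge W_s      = %g g  (V_s = %g cm^3)\n", x$W_s, x$V_s))
  cat(sprintf("  swelling: k_v = %g 1/min, V_h = %g cm^3/g  (V_max = %g cm^3)\n",
              x$k_v, x$V_h, v_max(x)))
  cat(sprintf("  volumes:  V_ads0 = %g, V_b0 = %g cm^3  (%s)\n",
              x$V_ads0, x$V_b0, if (isTRUE(x$stirred)) "stirred" else "stagnant"))
  cat(sprintf("  load:     n_s0 = %g, n_ads0 = %g, n_b0 = %g mol (MW %g g/mol)\n",
              x$n_s0, x$n_ads0, x$n_b0, x$mw_lf))
  cat(sprintf("  transport: H_Lf = %g, beta_sl = %g, beta_ll = %g 1/min\n",
              x$H_Lf, x$beta_sl, x$beta_ll))
  if (!is.null(x$t_dissolve)) {
    cat(sprintf("  dissolution at t = %g min\n", x$t_dissolve))
  }
  invisible(x)
}

# Replace a subset of fields, re-running validation.
update_config <- function(config, ...) {
  stopifnot(inherits(config, "batch_config"))
  repl <- list(...)
  bad <- setdiff(names(repl), .batch_fields)
  if (length(bad)) {
    stop("unknown batch_config field(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  args <- unclass(config)
  args[names(repl)] <- repl
  do.call(batch_config, args)
}
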