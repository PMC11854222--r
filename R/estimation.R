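# bounds (natural scale) for the transport parameters; bracket the plausible
# values by at least two decades on either side
.release_bounds <- list(
  beta_sl = c(1e-8, 1e6),
  beta_ll = c(1e-8, 1e6),
  H_Lf    = c(1e-8, 1)
)

# L-BFGS-B stopping rule: relative objective change below 1e-10 (factr is in
# units of machine epsilon), or 500 iterations
.optim_control <- function() {
  list(factr = 1e-10 / .Machine$double.eps, maxit = 500)
}

new_release_fit <- function(estimates, transport = NULL, sse, residuals,
                            fitted, converged, n_evaluations, bounds_hit,
                            seed = NA_integer_, method, series = NULL,
                            config = NULL) {
  structure(list(estimates = estimates, transport = transport, sse = sse,
                 residuals = residuals, fitted = fitted,
                 converged = converged, n_evaluations = n_evaluations,
                 bounds_hit = bounds_hit, seed = seed, method = method,
                 series = series, config = config),
            class = "release_fit")
}

#' @export
print.release_fit <- function(x, ...) {
  cat("<release_fit:", x$method, ">\n")
  est <- vapply(x$estimates, identity, numeric(1))
  for (nm in names(est)) cat(sprintf("  %-8s = %.6g\n", nm, est[[nm]]))
  cat(sprintf("  sse = %.6g  (converged: %s, %d objective evaluations)\n",
              x$sse, x$converged, x$n_evaluations))
  invisible(x)
}

#' Tidy a fitted kinetic model
#'
#' @param x A `release_fit` from [fit_kv()] or [fit_release()].
#' @param ... Unused.
#' @return A tibble with one row per estimated parameter: `term`, `estimate`,
#'   `lower`, `upper` (search bounds where applicable) and `at_bound`.
#' @export
tidy.release_fit <- function(x, ...) {
  terms <- names(x$estimates)
  lower <- upper <- rep(NA_real_, length(terms))
  for (i in seq_along(terms)) {
    b <- .release_bounds[[terms[i]]]
    if (!is.null(b)) {
      lower[i] <- b[1]
      upper[i] <- b[2]
    }
  }
  tibble::tibble(term = terms,
                 estimate = unlist(x$estimates, use.names = FALSE),
                 lower = lower, upper = upper,
                 at_bound = unname(x$bounds_hit[terms]))
}

#' One-line summary of a fitted kinetic model
#'
#' @param x A `release_fit`.
#' @param ... Unused.
#' @return A one-row tibble: `sse`, `rmse`, `nobs`, `converged`,
#'   `n_evaluations`, `seed`.
#' @export
glance.release_fit <- function(x, ...) {
  nobs <- length(x$residuals)
  tibble::tibble(sse = x$sse,
                 rmse = sqrt(x$sse / max(nobs, 1L)),
                 nobs = nobs,
                 converged = x$converged,
                 n_evaluations = x$n_evaluations,
                 seed = x$seed)
}

#' Fit the swelling rate constant to weight--time data
#'
#' Converts particle weights to adsorbed volumes,
#' `V_ads(t) = (W(t) - W(0)) / rho_water`, and fits the analytic first-order
#' swelling curve by least squares over `k_v` (and optionally `V_max`).
#'
#' `v_max_policy` controls how the plateau volume enters:
#' * `"fixed_from_plateau"` (default): `V_max = (max W - W(0)) / rho` — the
#'   particle is taken to have reached its maximum swelling by the last
#'   sampled plateau;
#' * `"fixed_value"`: `V_max` supplied through `V_max_value`;
#' * `"co_fit"`: `V_max` estimated jointly with `k_v`.
#'
#' @param series A [release_timeseries()] of kind `swelling_weight`
#'   (weights in g); at least 3 points including t = 0.
#' @param dry_mass Dry particle mass, g. Defaults to the t = 0 weight.
#' @param v_max_policy See above.
#' @param V_max_value Plateau volume, cm^3, when `v_max_policy = "fixed_value"`.
#' @param weights `"none"` (unweighted SSE, default) or `"inverse_sd2"`
#'   (1/sd^2 weighting using the series' per-point SDs).
#' @return A `release_fit` with `k_v` (1/min) and, under `co_fit`, `V_max`
#'   (cm^3) in `estimates`.
#' @examples
#' fit <- fit_kv(example_swelling_weights())
#' tidy(fit)
#' @export
fit_kv <- function(series, dry_mass = NULL,
                   v_max_policy = c("fixed_from_plateau", "fixed_value",
                                    "co_fit"),
                   V_max_value = NULL,
                   weights = c("none", "inverse_sd2")) {
  v_max_policy <- match.arg(v_max_policy)
  weights <- match.arg(weights)
  stopifnot(inherits(series, "release_timeseries"))
  if (series_kind(series) != "swelling_weight") {
    stop("fit_kv() expects a swelling_weight series, got ",
         series_kind(series), call. = FALSE)
  }
  if (nrow(series) < 3L) {
    stop("insufficient data: need at least 3 time points to fit k_v (got ",
         nrow(series), ")", call. = FALSE)
  }
  if (series$t_min[1] != 0) {
    stop("series must include a t = 0 (dry reference) point", call. = FALSE)
  }
  if (is.null(dry_mass)) dry_mass <- series$y[1]
  stopifnot(is.numeric(dry_mass), dry_mass > 0)

  # gross non-monotonicity (drop of more than 3 sd) is flagged, not fatal:
  # swelling data plateau and jitter
  if (!is.null(series[["sd"]])) {
    drops <- diff(series$y)
    tol <- 3 * series[["sd"]][-1]
    if (any(drops < -tol, na.rm = TRUE)) {
      warning("swelling weights decrease by more than 3 SD between points; ",
              "check the series", call. = FALSE)
    }
  }

  v_obs <- (series$y - series$y[1]) / .rho_water
  w <- if (weights == "inverse_sd2") {
    if (is.null(series[["sd"]])) {
      stop("weights = \"inverse_sd2\" requires per-point `sd`", call. = FALSE)
    }
    1 / series[["sd"]]^2
  } else {
    rep(1, nrow(series))
  }

  vmax_fixed <- switch(v_max_policy,
    fixed_from_plateau = max(v_obs),
    fixed_value = {
      if (is.null(V_max_value) || V_max_value <= 0) {
        stop("v_max_policy = \"fixed_value\" needs a positive `V_max_value`",
             call. = FALSE)
      }
      V_max_value
    },
    co_fit = NA_real_
  )

  # objective is normalized to O(1): L-BFGS-B's stopping rule is effectively
  # absolute for objectives far below 1, and SSE in cm^6 is ~1e-7 here
  scale <- sum(w * v_obs^2)
  if (scale <= 0) scale <- 1
  obj <- function(theta) {
    k <- exp(theta[1])
    vm <- if (v_max_policy == "co_fit") exp(theta[2]) else vmax_fixed
    pred <- vm * (1 - exp(-k * series$t_min))
    sum(w * (v_obs - pred)^2) / scale
  }

  if (v_max_policy == "co_fit") {
    lower <- c(log(1e-7), log(1e-12))
    upper <- c(log(10), log(1e6))
    vm0 <- max(max(v_obs), 1e-12)
    starts <- lapply(c(1e-4, 1e-3, 1e-2), function(k0) c(log(k0), log(vm0)))
    fits <- lapply(starts, function(s) {
      stats::optim(s, obj, method = "L-BFGS-B", lower = lower, upper = upper,
                   control = .optim_control())
    })
    res <- fits[[which.min(vapply(fits, `[[`, numeric(1), "value"))]]
    est <- list(k_v = exp(res$par[1]), V_max = exp(res$par[2]))
    sse <- res$value * scale
    conv <- res$convergence == 0
    nev <- sum(vapply(fits, function(f) f$counts[["function"]], numeric(1)))
  } else {
    res <- stats::optimize(function(lk) obj(lk), lower = log(1e-7),
                           upper = log(10), tol = 1e-12)
    est <- list(k_v = exp(res$minimum), V_max = vmax_fixed)
    sse <- res$objective * scale
    conv <- TRUE
    nev <- NA_integer_
  }

  pred <- est$V_max * (1 - exp(-est$k_v * series$t_min))
  new_release_fit(
    estimates = est[if (v_max_policy == "co_fit") c("k_v", "V_max") else "k_v"],
    sse = sse, residuals = v_obs - pred, fitted = pred,
    converged = conv,
    n_evaluations = if (is.na(nev)) length(pred) else nev,
    bounds_hit = c(k_v = FALSE, V_max = FALSE),
    method = paste0("fit_kv/", v_max_policy), series = series
  )
}

# predict the observable of `kind` at series times under a config
.predict_release <- function(config, t_obs, kind) {
  grid <- t_obs
  prepend <- grid[1] > 0
  if (prepend) grid <- c(0, grid)
  traj <- simulate_release(config, times = grid, mode = "conservative")
  y <- if (kind == "bulk_concentration") {
    traj$C_b_mol_per_cm3
  } else {
    traj$release_fraction
  }
  if (prepend) y <- y[-1]
  y
}

#' Fit transport parameters to a release series
#'
#' Bounded least squares, in log-parameter space, of any subset of the three
#' transport parameters (`beta_sl`, `beta_ll`, `H_Lf`) to a measured release
#' series. Parameters are strictly positive and span several orders of
#' magnitude, hence the log parameterization; the search is multi-start from
#' a seeded Latin-hypercube over the log-bounds (plus one start at the
#' config's own values), and the best local optimum is returned. Starts whose
#' forward simulation fails are discarded with a warning.
#'
#' @param series A [release_timeseries()] of kind `bulk_concentration` or
#'   `release_fraction`, with at least 5 points.
#' @param config A [batch_config()]; parameters not in `free` are fixed at
#'   the config values.
#' @param free Character subset of `c("beta_sl", "beta_ll", "H_Lf")` to
#'   estimate. Empty ⇒ evaluation mode: the objective is computed at the
#'   config values with no optimization.
#' @param n_starts Number of multi-start points (>= 1; the first is always
#'   the config's own values).
#' @param seed Integer seed for the Latin-hypercube draw; makes the whole
#'   fit bit-reproducible.
#' @param weights `"none"` or `"inverse_sd2"`.
#' @return A `release_fit`; `estimates` holds the free parameters and
#'   `$transport` the complete `(beta_sl, beta_ll, H_Lf)` set with fixed
#'   entries taken from `config`.
#' @export
fit_release <- function(series, config,
                        free = c("beta_ll", "H_Lf"),
                        n_starts = 8L, seed = 1L,
                        weights = c("none", "inverse_sd2")) {
  weights <- match.arg(weights)
  stopifnot(inherits(series, "release_timeseries"),
            inherits(config, "batch_config"))
  kind <- series_kind(series)
  if (!kind %in% c("bulk_concentration", "release_fraction")) {
    stop("fit_release() expects a bulk_concentration or release_fraction ",
         "series", call. = FALSE)
  }
  if (nrow(series) < 5L) {
    stop("insufficient data: need at least 5 time points (got ",
         nrow(series), ")", call. = FALSE)
  }
  bad <- setdiff(free, names(.release_bounds))
  if (length(bad)) {
    stop("unknown free parameter(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  w <- if (weights == "inverse_sd2") {
    if (is.null(series[["sd"]])) {
      stop("weights = \"inverse_sd2\" requires per-point `sd`", call. = FALSE)
    }
    1 / series[["sd"]]^2
  } else {
    rep(1, nrow(series))
  }

  sse_at <- function(vals) {
    cfg <- do.call(update_config, c(list(config), as.list(vals)))
    pred <- .predict_release(cfg, series$t_min, kind)
    sum(w * (series$y - pred)^2)
  }

  if (length(free) == 0L) {
    vals <- numeric(0)
    sse <- sse_at(vals)
    pred <- .predict_release(config, series$t_min, kind)
    return(new_release_fit(
      estimates = list(), transport = config[c("beta_sl", "beta_ll", "H_Lf")],
      sse = sse, residuals = series$y - pred, fitted = pred,
      converged = TRUE, n_evaluations = 1L, bounds_hit = logical(0),
      seed = as.integer(seed), method = "fit_release/evaluate",
      series = series, config = config
    ))
  }

  lb <- log(vapply(.release_bounds[free], `[`, numeric(1), 1L))
  ub <- log(vapply(.release_bounds[free], `[`, numeric(1), 2L))
  # normalized objective: concentration SSE is ~1e-17 in natural units, far
  # below L-BFGS-B's effective absolute stopping scale
  scale <- sum(w * series$y^2)
  if (scale <= 0) scale <- 1
  obj <- function(theta) {
    vals <- stats::setNames(exp(theta), free)
    sse_at(vals) / scale
  }

  start0 <- pmin(pmax(log(unlist(config[free])), lb), ub)
  starts <- matrix(start0, nrow = 1)
  if (n_starts > 1L) {
    u <- withr_rng(seed, lhs::randomLHS(n_starts - 1L, length(free)))
    starts <- rbind(starts,
                    sweep(sweep(u, 2, ub - lb, `*`), 2, lb, `+`))
  }

  best <- NULL
  n_eval <- 0L
  for (i in seq_len(nrow(starts))) {
    res <- try(stats::optim(starts[i, ], obj, method = "L-BFGS-B",
                            lower = lb, upper = ub,
                            control = .optim_control()),
               silent = TRUE)
    if (inherits(res, "try-error")) {
      warning("fit_release: start ", i, " discarded (",
              conditionMessage(attr(res, "condition")), ")", call. = FALSE)
      next
    }
    n_eval <- n_eval + res$counts[["function"]]
    if (is.null(best) || res$value < best$value) best <- res
  }
  if (is.null(best)) {
    stop("estimation failed: every start's forward simulation failed",
         call. = FALSE)
  }

  est <- stats::setNames(as.list(exp(best$par)), free)
  transport <- config[c("beta_sl", "beta_ll", "H_Lf")]
  transport[free] <- est
  cfg_hat <- do.call(update_config, c(list(config), est))
  pred <- .predict_release(cfg_hat, series$t_min, kind)
  tol_edge <- 1e-6
  bounds_hit <- stats::setNames(
    (best$par - lb < tol_edge) | (ub - best$par < tol_edge), free)

  new_release_fit(
    estimates = est, transport = transport, sse = best$value * scale,
    residuals = series$y - pred, fitted = pred,
    converged = best$convergence == 0, n_evaluations = n_eval,
    bounds_hit = bounds_hit, seed = as.integer(seed),
    method = "fit_release", series = series, config = config
  )
}

#' Validate fitted transport parameters on another batch
#'
#' Transfers the full transport-parameter set of a fit (`beta_sl`,
#' `beta_ll`, `H_Lf`) onto another batch's configuration — batch-specific
#' quantities (dry charge, bulk volume, initial load) are retained — and
#' scores the forward simulation against that batch's measured series.
#'
#' @param fitted A `release_fit` from [fit_release()].
#' @param other_series A [release_timeseries()] of the batch to predict.
#' @param other_config The [batch_config()] of that batch.
#' @return A one-row tibble: `sse`, `rmse`, `max_abs_residual`, `nobs`.
#' @export
cross_validate <- function(fitted, other_series, other_config) {
  stopifnot(inherits(fitted, "release_fit"),
            inherits(other_config, "batch_config"))
  if (is.null(fitted$transport) ||
      !all(c("beta_sl", "beta_ll", "H_Lf") %in% names(fitted$transport))) {
    stop("`fitted` must carry the full transport set ",
         "(beta_sl, beta_ll, H_Lf)", call. = FALSE)
  }
  if (!inherits(other_series, "release_timeseries") ||
      nrow(other_series) == 0L) {
    stop("insufficient data: `other_series` is empty", call. = FALSE)
  }
  kind <- series_kind(other_series)
  cfg <- do.call(update_config,
                 c(list(other_config), fitted$transport))
  pred <- .predict_release(cfg, other_series$t_min, kind)
  resid <- other_series$y - pred
  tibble::tibble(sse = sum(resid^2),
                 rmse = sqrt(mean(resid^2)),
                 max_abs_residual = max(abs(resid)),
                 nobs = length(resid))
}

#' Sensitivity of the release curve to one parameter
#'
#' Perturbs a single model parameter by multiplicative factors and reports
#' the sum of squared deviations of the perturbed bulk-concentration curve
#' from the unperturbed reference, on a fixed time grid. Comparing profiles
#' across parameters ranks their leverage on the fit — under the shipped
#' batch conditions the liquid--liquid coefficient dominates, the partition
#' constant matters weakly, and the (very fast) solid--liquid coefficient is
#' practically invisible.
#'
#' @param config A [batch_config()].
#' @param parameter One of `"beta_sl"`, `"beta_ll"`, `"H_Lf"`, `"k_v"`.
#' @param factors Positive multipliers; `1` gives sse 0 by construction.
#' @param times Evaluation grid, min.
#' @param observable `"bulk_concentration"` (default) or `"release_fraction"`.
#' @return A tibble: `parameter`, `factor`, `value`, `sse`.
#' @examples
#' sensitivity_profile(example_batches()$batch1, "beta_ll", c(0.5, 2))
#' @export
sensitivity_profile <- function(config, parameter, factors = c(0.5, 2),
                                times = default_release_times(),
                                observable = c("bulk_concentration",
                                               "release_fraction")) {
  observable <- match.arg(observable)
  stopifnot(inherits(config, "batch_config"), is.numeric(factors))
  if (!parameter %in% c("beta_sl", "beta_ll", "H_Lf", "k_v")) {
    stop("unknown parameter \"", parameter, "\": sensitivity is defined for ",
         "beta_sl, beta_ll, H_Lf, k_v", call. = FALSE)
  }
  if (any(factors <= 0)) stop("`factors` must be > 0", call. = FALSE)
  ref <- .predict_release(config, times, observable)
  purrr::map_dfr(factors, function(f) {
    val <- config[[parameter]] * f
    cfg <- do.call(update_config,
                   stats::setNames(list(config, val), c("", parameter)))
    pert <- .predict_release(cfg, times, observable)
    tibble::tibble(parameter = parameter, factor = f, value = val,
                   sse = sum((pert - ref)^2))
  })
}
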