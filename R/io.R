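#' Read a measurement time series from CSV
#'
#' Expects the canonical header `t_min,y[,sd]`; a column `t_h` (hours) is
#' accepted in place of `t_min` and converted to minutes on ingest. Fails
#' fast, naming the offending row, on non-numeric cells or a non-increasing
#' time column.
#'
#' @param path CSV file path.
#' @param kind Measurement kind, see [release_timeseries()].
#' @return A [release_timeseries()].
#' @export
read_timeseries <- function(path, kind = c("swelling_weight",
                                           "bulk_concentration",
                                           "release_fraction")) {
  kind <- match.arg(kind)
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  df <- try(readr::read_csv(path, show_col_types = FALSE,
                            col_types = readr::cols(.default = "c")),
            silent = TRUE)
  if (inherits(df, "try-error") || nrow(df) == 0L) {
    stop("parse error: ", path, " is empty or not a readable CSV",
         call. = FALSE)
  }
  if ("t_h" %in% names(df) && !"t_min" %in% names(df)) {
    df$t_min <- as.numeric(df$t_h) * 60
    df$t_h <- NULL
  }
  need <- c("t_min", "y")
  miss <- setdiff(need, names(df))
  if (length(miss)) {
    stop("parse error in ", path, ": missing column(s) ",
         paste(miss, collapse = ", "), call. = FALSE)
  }
  to_num <- function(col, nm) {
    v <- suppressWarnings(as.numeric(df[[nm]]))
    bad <- which(is.na(v) & !is.na(df[[nm]]) & df[[nm]] != "NA")
    if (length(bad)) {
      stop("parse error in ", path, ": non-numeric `", nm, "` at data row ",
           bad[1], call. = FALSE)
    }
    v
  }
  t_min <- to_num(df$t_min, "t_min")
  y <- to_num(df$y, "y")
  if (any(diff(t_min) <= 0)) {
    stop("parse error in ", path, ": time must be strictly increasing ",
         "(violated at data row ", which(diff(t_min) <= 0)[1] + 1, ")",
         call. = FALSE)
  }
  sd <- if ("sd" %in% names(df)) to_num(df$sd, "sd") else NULL
  release_timeseries(t_min, y, sd = sd, kind = kind)
}

#' Write a measurement time series to CSV
#'
#' @param series A [release_timeseries()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_timeseries <- function(series, path) {
  stopifnot(inherits(series, "release_timeseries"))
  cols <- intersect(c("t_min", "y", "sd"), names(series))
  readr::write_csv(as.data.frame(series)[cols], path)
  invisible(path)
}

#' Read a batch configuration from JSON
#'
#' Strict reader for the JSON serialization of [batch_config()]: exactly the
#' documented field names; unknown keys are rejected rather than ignored —
#' the parameters span ten orders of magnitude and a silently dropped or
#' misspelled field is the main failure mode worth guarding against.
#'
#' @param path JSON file path.
#' @return A [batch_config()].
#' @export
read_batch_config <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!is.list(raw)) stop("parse error: ", path, " is not a JSON object",
                          call. = FALSE)
  unknown <- setdiff(names(raw), .batch_fields)
  if (length(unknown)) {
    stop("validation error in ", path, ": unknown field(s) ",
         paste(unknown, collapse = ", "), call. = FALSE)
  }
  required <- setdiff(.batch_fields, c("t_dissolve", "stirred", "mw_lf",
                                       "V_ads0", "n_ads0", "n_b0"))
  miss <- setdiff(required, names(raw))
  if (length(miss)) {
    stop("validation error in ", path, ": missing field(s) ",
         paste(miss, collapse = ", "), call. = FALSE)
  }
  if (!is.null(raw$t_dissolve) && all(is.na(raw$t_dissolve))) {
    raw$t_dissolve <- NULL
  }
  tryCatch(do.call(batch_config, raw),
           error = function(e) {
             stop("validation error in ", path, ": ", conditionMessage(e),
                  call. = FALSE)
           })
}

#' Write a batch configuration to JSON
#'
#' @param config A [batch_config()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_batch_config <- function(config, path) {
  stopifnot(inherits(config, "batch_config"))
  x <- unclass(config)
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA,
                       null = "null", pretty = TRUE)
  invisible(path)
}

#' Write a simulated trajectory to CSV
#'
#' Columns: `t_min`, `V_ads_cm3`, `V_b_cm3`, `n_s_mol`, `n_ads_mol`,
#' `n_b_mol`, `C_b_mol_per_cm3`, `release_fraction`, `dissolved`.
#'
#' @param trajectory A `release_trajectory`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_trajectory <- function(trajectory, path) {
  stopifnot(inherits(trajectory, "release_trajectory"))
  readr::write_csv(as.data.frame(trajectory), path)
  invisible(path)
}

# one manifest per CLI run: enough to re-execute the command
write_manifest <- function(dir, command, args, seed = NULL, outputs = character()) {
  manifest <- list(
    command = command,
    args = as.list(args),
    seed = seed,
    outputs = as.list(outputs),
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
    package = "microrelease",
    version = as.character(utils::packageVersion("microrelease"))
  )
  path <- file.path(dir, "run_manifest.json")
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, null = "null",
                       pretty = TRUE)
  invisible(path)
}

# minimal --flag value parser; flags without '--' are positional (unused)
.parse_flags <- function(args) {
  out <- list()
  i <- 1L
  while (i <= length(args)) {
    a <- args[[i]]
    if (!startsWith(a, "--")) {
      stop("usage error: unexpected argument '", a, "'", call. = FALSE)
    }
    key <- sub("^--", "", a)
    if (i == length(args) || startsWith(args[[i + 1L]], "--")) {
      out[[key]] <- TRUE
      i <- i + 1L
    } else {
      out[[key]] <- args[[i + 1L]]
      i <- i + 2L
    }
  }
  out
}

.cli_num <- function(flags, key, default = NULL) {
  if (is.null(flags[[key]])) return(default)
  v <- suppressWarnings(as.numeric(flags[[key]]))
  if (is.na(v)) stop("usage error: --", key, " must be numeric", call. = FALSE)
  v
}

#' Command-line interface
#'
#' A thin shell binding over the package functions, suitable for calling from
#' an `Rscript` wrapper (one ships at `inst/scripts/microrelease`). Every run
#' writes its outputs plus a `run_manifest.json` (command, arguments, seed,
#' package version, timestamp) into the output directory, so a run can be
#' re-executed from the manifest alone.
#'
#' Subcommands:
#' \describe{
#'   \item{`simulate-swelling`}{`--kv --vmax [--vads0] [--t-end] [--n] --out`}
#'   \item{`simulate-release`}{`--config batch.json [--t-end] [--n]
#'     [--mode conservative|as-printed] --out`}
#'   \item{`fit-swelling`}{`--data weights.csv [--policy] --out`}
#'   \item{`fit-release`}{`--data series.csv --config batch.json
#'     [--kind bulk_concentration|release_fraction] [--free a,b] [--seed]
#'     --out`}
#'   \item{`validate`}{`--fit-config batch.json --fit-data series.csv
#'     --config other.json --data other.csv [--kind ...] [--seed] --out`}
#'   \item{`generate`}{`--config batch.json [--sd] [--seed] [--kind] --out`}
#'   \item{`metrics`}{`--ee v1,v2,...` or `--q msw,md` — prints the result}
#' }
#'
#' @param args Character vector of command-line arguments (subcommand first),
#'   e.g. `commandArgs(trailingOnly = TRUE)`.
#' @return Integer exit code, invisibly: 0 on success, 2 on usage errors,
#'   1 on runtime failure.
#' @export
release_cli <- function(args = commandArgs(trailingOnly = TRUE)) {
  usage <- paste(
    "usage: microrelease <subcommand> [--flags]",
    "subcommands: simulate-swelling simulate-release fit-swelling",
    "             fit-release validate generate metrics", sep = "\n")
  if (length(args) == 0L) {
    message(usage)
    return(invisible(2L))
  }
  sub <- args[[1L]]
  known <- c("simulate-swelling", "simulate-release", "fit-swelling",
             "fit-release", "validate", "generate", "metrics")
  if (!sub %in% known) {
    message("unknown subcommand: ", sub, "\n", usage)
    return(invisible(2L))
  }
  flags <- try(.parse_flags(args[-1L]), silent = TRUE)
  if (inherits(flags, "try-error")) {
    message(conditionMessage(attr(flags, "condition")), "\n", usage)
    return(invisible(2L))
  }
  code <- tryCatch({
    .cli_dispatch(sub, flags)
    0L
  }, error = function(e) {
    message("error: ", conditionMessage(e))
    1L
  })
  invisible(code)
}

.cli_outdir <- function(flags) {
  out <- flags[["out"]]
  if (is.null(out) || isTRUE(out)) {
    stop("--out <dir> is required", call. = FALSE)
  }
  dir.create(out, recursive = TRUE, showWarnings = FALSE)
  out
}

.cli_times <- function(flags, default_end = 600) {
  t_end <- .cli_num(flags, "t-end", default_end)
  n <- .cli_num(flags, "n", 121)
  seq(0, t_end, length.out = max(2, round(n)))
}

.cli_dispatch <- function(sub, flags) {
  seed <- as.integer(.cli_num(flags, "seed", 1))
  switch(sub,
    "simulate-swelling" = {
      out <- .cli_outdir(flags)
      p <- swelling_params(k_v = .cli_num(flags, "kv"),
                           V_max = .cli_num(flags, "vmax"),
                           V_ads0 = .cli_num(flags, "vads0", 1e-8))
      times <- .cli_times(flags, 2880)
      df <- tibble::tibble(t_min = times,
                           V_ads_cm3 = swelling_closed_form(times, p))
      f <- file.path(out, "swelling.csv")
      readr::write_csv(df, f)
      write_manifest(out, sub, flags, seed, basename(f))
      message("wrote ", f)
    },
    "simulate-release" = {
      out <- .cli_outdir(flags)
      cfg <- read_batch_config(flags[["config"]])
      mode <- if (identical(flags[["mode"]], "as-printed")) "as_printed"
              else "conservative"
      traj <- simulate_release(cfg, times = .cli_times(flags), mode = mode)
      f <- file.path(out, "trajectory.csv")
      write_trajectory(traj, f)
      write_manifest(out, sub, flags, seed, basename(f))
      message("wrote ", f)
    },
    "fit-swelling" = {
      out <- .cli_outdir(flags)
      series <- read_timeseries(flags[["data"]], kind = "swelling_weight")
      policy <- flags[["policy"]] %||% "fixed_from_plateau"
      fit <- fit_kv(series, v_max_policy = policy)
      f <- file.path(out, "fit_swelling.json")
      jsonlite::write_json(list(estimates = fit$estimates, sse = fit$sse,
                                converged = fit$converged),
                           f, auto_unbox = TRUE, digits = NA)
      write_manifest(out, sub, flags, seed, basename(f))
      message("k_v = ", format(fit$estimates$k_v), " 1/min; wrote ", f)
    },
    "fit-release" = {
      out <- .cli_outdir(flags)
      kind <- flags[["kind"]] %||% "bulk_concentration"
      series <- read_timeseries(flags[["data"]], kind = kind)
      cfg <- read_batch_config(flags[["config"]])
      free <- strsplit(flags[["free"]] %||% "beta_ll,H_Lf", ",")[[1]]
      fit <- fit_release(series, cfg, free = free, seed = seed)
      f <- file.path(out, "fit_release.json")
      jsonlite::write_json(list(estimates = fit$estimates,
                                transport = fit$transport, sse = fit$sse,
                                converged = fit$converged, seed = fit$seed),
                           f, auto_unbox = TRUE, digits = NA)
      write_manifest(out, sub, flags, seed, basename(f))
      message("wrote ", f)
    },
    "validate" = {
      out <- .cli_outdir(flags)
      kind <- flags[["kind"]] %||% "bulk_concentration"
      fit_series <- read_timeseries(flags[["fit-data"]], kind = kind)
      fit_cfg <- read_batch_config(flags[["fit-config"]])
      fit <- fit_release(fit_series, fit_cfg, seed = seed)
      series <- read_timeseries(flags[["data"]], kind = kind)
      cfg <- read_batch_config(flags[["config"]])
      rep <- cross_validate(fit, series, cfg)
      f <- file.path(out, "validation.json")
      jsonlite::write_json(as.list(rep), f, auto_unbox = TRUE, digits = NA)
      write_manifest(out, sub, flags, seed, basename(f))
      message("rmse = ", format(rep$rmse), "; wrote ", f)
    },
    "generate" = {
      out <- .cli_outdir(flags)
      cfg <- read_batch_config(flags[["config"]])
      kind <- flags[["kind"]] %||% "bulk_concentration"
      series <- generate_release_series(cfg, sd = .cli_num(flags, "sd", 0.008),
                                        seed = seed, observable = kind)
      f <- file.path(out, "series.csv")
      write_timeseries(series, f)
      sidecar <- file.path(out, "series_params.json")
      jsonlite::write_json(list(config = unclass(cfg), sd = .cli_num(flags, "sd", 0.008),
                                seed = seed, observable = kind),
                           sidecar, auto_unbox = TRUE, digits = NA,
                           null = "null")
      write_manifest(out, sub, flags, seed, basename(c(f, sidecar)))
      message("wrote ", f)
    },
    "metrics" = {
      if (!is.null(flags[["ee"]])) {
        vals <- as.numeric(strsplit(flags[["ee"]], ",")[[1]])
        s <- summarize_batches(vals)
        cat(sprintf("EE mean %.1f sd %.1f (n = %d)\n",
                    s$mean_display, s$sd_display, s$n))
      } else if (!is.null(flags[["q"]])) {
        mm <- as.numeric(strsplit(flags[["q"]], ",")[[1]])
        if (length(mm) != 2L) stop("--q needs msw,md", call. = FALSE)
        cat(sprintf("Q = %.1f%%\n", swelling_degree(mm[1], mm[2])))
      } else {
        stop("metrics needs --ee or --q", call. = FALSE)
      }
    }
  )
  invisible(NULL)
}
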