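#' Declarative scenario configuration
#'
#' A scenario is one complete dose-response experiment: a model variant, a
#' set of parameter overrides (one of which may be a vector, producing one
#' curve per value), a dose axis with range and percent step, and the
#' readouts to score. Built-in scenarios covering the package's standard
#' experiments are available through [builtin_scenario()].
#'
#' @param name Scenario label (used in file names and metrics tables).
#' @param model `"mm"` or `"full"`.
#' @param overrides Named list of parameter overrides. At most one entry may
#'   be a vector; that entry generates one curve per value.
#' @param axis Dose-axis parameter name.
#' @param from,to,step_pct Dose grid specification (see [dose_grid()]).
#' @param readouts Readout columns to score; defaults to the substrate
#'   readouts of the model variant.
#' @param total Conserved total substrate (closed-cycle mode only).
#' @return A validated `scenario_config` object.
#' @export
scenario_config <- function(name, model = c("mm", "full"), overrides = list(),
                            axis = if (model == "mm") "X" else "Xtot",
                            from = 0.01, to = 100, step_pct = 1,
                            readouts = NULL, total = NULL) {
  model <- match.arg(model)
  base <- if (model == "mm") mm_params() else full_params()
  if (length(overrides) > 0L) {
    if (is.null(names(overrides)) || any(names(overrides) == "")) {
      stop("overrides must be a named list", call. = FALSE)
    }
    unknown <- setdiff(names(overrides), names(base))
    if (length(unknown) > 0L) {
      stop("overrides name unknown parameter(s): ",
           paste(unknown, collapse = ", "), call. = FALSE)
    }
    n_multi <- sum(lengths(overrides) > 1L)
    if (n_multi > 1L) {
      stop("at most one override may be vector-valued", call. = FALSE)
    }
  }
  if (!axis %in% names(base)) {
    stop("unknown dose axis '", axis, "' for model '", model, "'",
         call. = FALSE)
  }
  default_readouts <- c("R", "Rp", "Rtot_free",
                        if (model == "full") "total_substrate")
  readouts <- if (is.null(readouts)) default_readouts else readouts
  grid <- dose_grid(axis, from, to, step_pct)  # validates the range
  structure(list(name = name, model = model, overrides = overrides,
                 axis = axis, from = from, to = to, step_pct = step_pct,
                 readouts = readouts, total = total, grid = grid),
            class = "scenario_config")
}

#' @export
print.scenario_config <- function(x, ...) {
  cat("<scenario_config> ", x$name, ": model ", x$model, ", axis ", x$axis,
      " in [", format(x$from), ", ", format(x$to), "] @", x$step_pct, "%\n",
      sep = "")
  if (length(x$overrides)) {
    ov <- vapply(x$overrides, function(v) paste(format(v), collapse = ","), "")
    cat("  overrides:", paste(names(ov), "=", ov, collapse = "; "), "\n")
  }
  invisible(x)
}

builtin_scenario_list <- function() {
  list(
    # zero-order regime at defaults: strongly sigmoid Rp/R responses
    baseline = function() scenario_config("baseline", "mm"),
    # modified-form stability sweep: stabilization steepens, destabilization
    # flattens; Rtot response switches from rising to falling
    k4_sweep = function() scenario_config(
      "k4_sweep", "mm", overrides = list(k4 = c(1e-4, 1e-3, 1e-2, 1e-1, 1))),
    # comparable enzyme and substrate levels: titration weakens
    # ultrasensitivity; free Rtot can become nonmonotonic when stabilized
    full_ytot100 = function() scenario_config(
      "full_ytot100", "full",
      overrides = list(Ytot = 100, k4 = c(1e-4, 1e-3, 1e-2, 1e-1, 1))),
    # high-Km cycle with no basal ultrasensitivity: stabilization creates it
    emergence = function() scenario_config(
      "emergence", "mm",
      overrides = list(Km1 = 100, Km2 = 100, k4 = c(1e-4, 1e-3, 1e-2, 1e-1))),
    # same, in the mass-action variant (apparent Km raised to 100 through
    # the dissociation constants)
    emergence_full = function() scenario_config(
      "emergence_full", "full",
      overrides = list(k1b = 990, k2b = 990, k4 = c(1e-4, 1e-3, 1e-2, 1e-1))),
    # kinase Km sweep under destabilization; wide dose range so that the
    # shifted transitions still saturate
    km1_destab = function() scenario_config(
      "km1_destab", "mm", to = 1e4,
      overrides = list(k4 = 0.1, Km1 = c(0.1, 1, 10, 100, 1000))),
    # kinase Km sweep under strong stabilization
    km1_stab = function() scenario_config(
      "km1_stab", "mm", to = 1e4,
      overrides = list(k4 = 0.001, Km1 = c(0.1, 1, 10, 100, 1000))),
    # synthesis-rate-driven responses at fixed intermediate kinase level
    k0_sweep = function() scenario_config(
      "k0_sweep", "mm", axis = "k0",
      overrides = list(X = 1, k4 = c(1e-3, 1e-2, 1e-1, 1))),
    # synthesis-driven ultrasensitivity without a demodifying enzyme:
    # zero-order degradation variant
    k0_sweep_no_phosphatase = function() scenario_config(
      "k0_sweep_no_phosphatase", "mm", axis = "k0",
      overrides = list(X = 1, k2 = 0, k4 = 1)),
    # no synthesis or turnover: the classical conserved-total cycle
    closed_cycle = function() scenario_config(
      "closed_cycle", "mm", overrides = list(k0 = 0, k3 = 0, k4 = 0),
      total = 100),
    # strong-destabilization limit where the metrics settle
    large_k4_asymptote = function() scenario_config(
      "large_k4_asymptote", "mm", overrides = list(k4 = c(1, 10, 100)))
  )
}

#' Built-in scenarios
#'
#' @param name Scenario name; see [builtin_scenarios()] for the list.
#' @return A `scenario_config` object.
#' @export
builtin_scenario <- function(name) {
  lst <- builtin_scenario_list()
  if (!name %in% names(lst)) {
    stop("unknown scenario '", name, "'; available: ",
         paste(names(lst), collapse = ", "), call. = FALSE)
  }
  lst[[name]]()
}

#' @rdname builtin_scenario
#' @return For `builtin_scenarios()`, the character vector of names.
#' @export
builtin_scenarios <- function() names(builtin_scenario_list())

#' Run a scenario
#'
#' Executes every curve of a scenario (one per value of the vector-valued
#' override, if any), scores each configured readout with
#' [ultrasensitivity_metrics()], and optionally writes the curve CSVs, LRC
#' CSVs, metrics CSV and a JSON run manifest from which every output number
#' can be regenerated.
#'
#' @param config A `scenario_config`, or the name of a built-in scenario.
#' @param out_dir Output directory; created if missing. `NULL` (default)
#'   skips file output.
#' @return A `scenario_result`: list with `config`, `curves` (named list of
#'   `cmc_dr_curve`), `metrics` (tibble: scenario, readout, override_param,
#'   override_value, n_H, X_10, X_90, lrc_max_abs, lrc_max_location,
#'   saturated, monotone), and `files` (paths written, if any).
#' @examples
#' res <- run_scenario(builtin_scenario("closed_cycle"))
#' res$metrics
#' @export
run_scenario <- function(config, out_dir = NULL) {
  if (is.character(config)) config <- builtin_scenario(config)
  stopifnot(inherits(config, "scenario_config"))
  ov <- config$overrides
  multi <- names(ov)[lengths(ov) > 1L]
  fixed <- ov[setdiff(names(ov), multi)]
  values <- if (length(multi) == 1L) ov[[multi]] else NA
  base <- if (config$model == "mm") mm_params() else full_params()
  base <- set_params(base, fixed)

  curves <- list()
  metrics <- list()
  for (j in seq_along(values)) {
    p <- base
    label <- config$name
    ov_param <- NA_character_
    ov_value <- NA_real_
    if (length(multi) == 1L) {
      ov_param <- multi
      ov_value <- values[[j]]
      p <- set_params(p, stats::setNames(list(ov_value), multi))
      label <- paste0(multi, "=", format(ov_value))
    }
    curve <- scan_dose_response(p, config$grid, total = config$total)
    curves[[label]] <- curve
    for (rd in config$readouts) {
      m <- ultrasensitivity_metrics(curve, rd)
      metrics[[paste(label, rd)]] <- tibble::tibble(
        scenario = config$name, readout = rd, override_param = ov_param,
        override_value = ov_value, n_H = m$n_H, X_10 = m$X_10,
        X_90 = m$X_90, lrc_max_abs = m$lrc_max_abs,
        lrc_max_location = m$lrc_max_location, saturated = m$saturated,
        monotone = m$monotone)
    }
  }
  res <- structure(list(config = config, curves = curves,
                        metrics = dplyr::bind_rows(metrics),
                        files = character()),
                   class = "scenario_result")
  if (!is.null(out_dir)) res <- write_scenario_result(res, out_dir)
  res
}

#' @export
print.scenario_result <- function(x, ...) {
  cat("<scenario_result> ", x$config$name, ": ", length(x$curves),
      " curve(s)\n", sep = "")
  print(x$metrics)
  invisible(x)
}

#' @rdname tidiers
#' @export
tidy.scenario_result <- function(x, ...) x$metrics

#' Direction-of-change summary of ultrasensitivity modulators
#'
#' Recomputes, for the Michaelis-Menten model, how tenfold changes in each
#' kinetic parameter move the maximal amplification `|LRC|max` of the R, Rp
#' and free-Rtot readouts, under modified-form stabilization (`k3 > k4`,
#' baseline `k4 = 0.001`) and destabilization (`k3 < k4`, baseline
#' `k4 = 0.1`), for both the kinase-level dose axis and the synthesis-rate
#' dose axis. A change below `none_threshold` (relative) is reported as
#' `"none"`.
#'
#' @param none_threshold Relative change below which the direction is
#'   `"none"` (default 0.05).
#' @return Tibble: `change`, `condition`, `axis`, `readout`,
#'   `lrc_max_reference`, `lrc_max_varied`, `direction`.
#' @export
stability_effects_summary <- function(none_threshold = 0.05) {
  readouts <- c("R", "Rp", "Rtot_free")
  lrc_of <- function(overrides, axis = "X", to = 100) {
    p <- set_params(mm_params(), overrides)
    curve <- scan_dose_response(p, dose_grid(axis, 0.01, to))
    vapply(readouts, function(rd) {
      lrc_max(local_response_coefficients(curve, rd))$lrc_max_abs
    }, numeric(1))
  }
  stab <- list(k4 = 0.001)          # k3 > k4
  destab <- list(k4 = 0.1)          # k3 < k4
  k0_axis <- list(X = 1)
  rows <- list(
    list("k4 x0.1",  "k3 > k4", "X",  stab,   list(k4 = 1e-4)),
    list("k4 x10",   "k3 < k4", "X",  destab, list(k4 = 1)),
    list("Km1,Km2 x0.1", "k3 > k4", "X", stab,   list(Km1 = 1, Km2 = 1)),
    list("Km1,Km2 x0.1", "k3 < k4", "X", destab, list(Km1 = 1, Km2 = 1)),
    list("Km1,Km2 x10",  "k3 > k4", "X", stab,   list(Km1 = 100, Km2 = 100)),
    list("Km1,Km2 x10",  "k3 < k4", "X", destab, list(Km1 = 100, Km2 = 100)),
    list("k1 x10",   "k3 > k4", "X",  stab,   list(k1 = 100)),
    list("k1 x10",   "k3 < k4", "X",  destab, list(k1 = 100)),
    list("k1 x0.1",  "k3 > k4", "X",  stab,   list(k1 = 1)),
    list("k1 x0.1",  "k3 < k4", "X",  destab, list(k1 = 1)),
    list("k2 x10",   "k3 > k4", "X",  stab,   list(k2 = 100)),
    list("k2 x10",   "k3 < k4", "X",  destab, list(k2 = 100)),
    list("k4 x0.1",  "k3 > k4", "k0", c(k0_axis, stab),   list(k4 = 1e-4)),
    list("k4 x10",   "k3 < k4", "k0", c(k0_axis, destab), list(k4 = 1))
  )
  out <- lapply(rows, function(row) {
    base_ov <- row[[4]]
    varied_ov <- utils::modifyList(base_ov, row[[5]])
    ref <- lrc_of(base_ov, axis = row[[3]])
    var <- lrc_of(varied_ov, axis = row[[3]])
    rel <- unname((var - ref) / ref)
    tibble::tibble(change = row[[1]], condition = row[[2]], axis = row[[3]],
                   readout = readouts, lrc_max_reference = unname(ref),
                   lrc_max_varied = unname(var),
                   direction = ifelse(abs(rel) < none_threshold, "none",
                                      ifelse(rel > 0, "up", "down")))
  })
  dplyr::bind_rows(out)
}

#' Metric value at a parameter's asymptotic plateau
#'
#' Repeatedly multiplies one parameter by `factor`, rescanning the
#' dose-response and recomputing the metric, until the metric changes by
#' less than `change_tol` (relative) over one step; the value after that
#' final step is reported. Used for limits such as "very large k4" or
#' "very large Km1", where a printed metric refers to the asymptote.
#'
#' @param params Base `cmc_params`.
#' @param vary Parameter name to push toward its limit.
#' @param start Starting value of `vary`.
#' @param grid [dose_grid()] used for every scan, or a function of the
#'   varied parameter's current value returning one (for limits where the
#'   response transition shifts with the parameter, so the scan range must
#'   grow with it to keep the curve saturated).
#' @param readout Readout column to score.
#' @param metric `"n_H"` (absolute value) or `"lrc_max_abs"`.
#' @param factor Multiplier per step (default 2, i.e. doubling).
#' @param change_tol Relative-change stopping threshold (default 0.01).
#' @param max_steps Safety cap on the number of steps.
#' @return List: `value` (plateau metric), `at` (parameter value reached),
#'   `trace` (tibble of the visited values).
#' @export
metric_plateau <- function(params, vary, start, grid, readout,
                           metric = c("lrc_max_abs", "n_H"), factor = 2,
                           change_tol = 0.01, max_steps = 30L) {
  metric <- match.arg(metric)
  score <- function(val) {
    p <- set_params(params, stats::setNames(list(val), vary))
    g <- if (is.function(grid)) grid(val) else grid
    curve <- scan_dose_response(p, g)
    m <- ultrasensitivity_metrics(curve, readout)
    if (metric == "n_H") abs(m$n_H) else m$lrc_max_abs
  }
  x <- start
  v <- score(x)
  trace <- list(tibble::tibble(value = x, metric = v))
  for (i in seq_len(max_steps)) {
    x2 <- x * factor
    v2 <- score(x2)
    trace[[length(trace) + 1L]] <- tibble::tibble(value = x2, metric = v2)
    if (is.finite(v) && is.finite(v2) && abs(v2 - v) / abs(v) < change_tol) {
      return(list(value = v2, at = x2, trace = dplyr::bind_rows(trace)))
    }
    x <- x2
    v <- v2
  }
  stop("metric did not plateau within ", max_steps, " steps", call. = FALSE)
}
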