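# File input/output: curve CSVs (fixed column contract), metrics CSVs,
# LRC CSVs, JSON run manifests and YAML scenario configuration files.

# plain-decimal, full-precision, locale-independent number formatting so
# that two runs of the same scenario produce byte-identical CSV bodies
format_csv_num <- function(x) {
  vapply(x, function(v) {
    if (is.na(v)) return("NA")
    if (is.logical(v)) return(if (v) "TRUE" else "FALSE")
    format(v, digits = 17, scientific = FALSE, trim = TRUE)
  }, "")
}

write_table_csv <- function(df, path) {
  cols <- lapply(df, function(col) {
    if (is.numeric(col) || is.logical(col)) format_csv_num(col) else as.character(col)
  })
  m <- do.call(cbind, cols)
  lines <- c(paste(names(df), collapse = ","),
             apply(m, 1L, paste, collapse = ","))
  writeLines(lines, path)
  invisible(path)
}

#' Write a dose-response curve to CSV
#'
#' Writes the fixed column contract: `dose, R, Rp, Rtot_free,
#' total_substrate` (full model only), `flux_k1 .. flux_k4`, in plain
#' decimal notation at full double precision. A JSON manifest with the
#' parameters, grid and background needed to regenerate or re-score the
#' curve is written alongside unless `manifest = NULL`.
#'
#' @param curve A `cmc_dr_curve`.
#' @param path Output CSV path.
#' @param manifest Manifest path, or `NULL` to skip; default `<path>.json`.
#' @return `path`, invisibly.
#' @export
write_curve_csv <- function(curve, path, manifest = paste0(path, ".json")) {
  cols <- c("dose", "R", "Rp", "Rtot_free",
            if ("total_substrate" %in% names(curve)) "total_substrate",
            paste0("flux_k", 1:4))
  write_table_csv(curve[cols], path)
  if (!is.null(manifest)) write_curve_manifest(curve, manifest)
  invisible(path)
}

write_curve_manifest <- function(curve, path) {
  params <- attr(curve, "params")
  meta <- list(
    package = "cmcscan",
    version = as.character(utils::packageVersion("cmcscan")),
    model = attr(curve, "model"),
    params = as.list(unclass(params)),
    axis = attr(curve, "axis"),
    grid = list(from = min(curve$dose), to = max(curve$dose),
                step_pct = attr(curve, "step_pct"),
                increment = "multiplicative"),
    total = attr(curve, "total"),
    background = as.list(attr(curve, "background")),
    background_at = attr(curve, "background_at"),
    tolerances = list(steady_state_residual = 1e-8,
                      integration_rtol = 1e-9, integration_atol = 1e-12)
  )
  jsonlite::write_json(meta, path, auto_unbox = TRUE, digits = NA,
                       null = "null", pretty = TRUE)
  invisible(path)
}

#' Read a dose-response curve from CSV
#'
#' Restores a curve written by [write_curve_csv()]. If the JSON manifest is
#' present the parameters, axis and background are restored exactly;
#' otherwise the curve carries minimal metadata (background taken from the
#' first row), which is sufficient for LRC profiles but makes Hill
#' backgrounds approximate for kinase-axis scans.
#'
#' @param path CSV path.
#' @param manifest Manifest path; default `<path>.json`, ignored if missing.
#' @return A `cmc_dr_curve` tibble.
#' @export
read_curve_csv <- function(path, manifest = paste0(path, ".json")) {
  df <- tibble::as_tibble(utils::read.csv(path, check.names = FALSE))
  has_manifest <- !is.null(manifest) && file.exists(manifest)
  if (has_manifest) {
    meta <- jsonlite::read_json(manifest, simplifyVector = TRUE)
    params <- do.call(if (meta$model == "mm") mm_params else full_params,
                      as.list(meta$params))
    attr(df, "params") <- params
    attr(df, "model") <- meta$model
    attr(df, "axis") <- meta$axis
    attr(df, "step_pct") <- meta$grid$step_pct
    attr(df, "total") <- meta$total
    attr(df, "background") <- unlist(meta$background)
    attr(df, "background_at") <- meta$background_at
  } else {
    attr(df, "model") <- if ("total_substrate" %in% names(df)) "full" else "mm"
    attr(df, "axis") <- "dose"
    attr(df, "background") <- unlist(df[1L, setdiff(names(df), "dose")])
    attr(df, "background_at") <- df$dose[1L]
  }
  class(df) <- c("cmc_dr_curve", class(df))
  df
}

#' Write scenario outputs
#'
#' Writes, under `out_dir`: one curve CSV (+ JSON manifest) per curve, one
#' LRC CSV per curve and readout, the metrics CSV, and a run manifest tying
#' them together.
#'
#' @param result A `scenario_result` from [run_scenario()].
#' @param out_dir Output directory (created if missing).
#' @return The result with its `files` field filled in, invisibly.
#' @export
write_scenario_result <- function(result, out_dir) {
  stopifnot(inherits(result, "scenario_result"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  name <- result$config$name
  files <- character()
  slug <- function(x) gsub("[^A-Za-z0-9._-]+", "_", x)
  for (lbl in names(result$curves)) {
    curve <- result$curves[[lbl]]
    f <- file.path(out_dir, paste0(name, "_", slug(lbl), ".csv"))
    write_curve_csv(curve, f)
    files <- c(files, f, paste0(f, ".json"))
    for (rd in result$config$readouts) {
      lrc <- local_response_coefficients(curve, rd)
      fl <- file.path(out_dir, paste0(name, "_", slug(lbl), "_lrc_", rd, ".csv"))
      write_table_csv(lrc, fl)
      files <- c(files, fl)
    }
  }
  fm <- file.path(out_dir, paste0(name, "_metrics.csv"))
  write_table_csv(result$metrics, fm)
  files <- c(files, fm)
  frun <- file.path(out_dir, paste0(name, "_manifest.json"))
  cfg <- result$config
  run_meta <- list(
    package = "cmcscan",
    version = as.character(utils::packageVersion("cmcscan")),
    scenario = cfg$name, model = cfg$model,
    overrides = cfg$overrides,
    axis = cfg$axis,
    grid = list(from = cfg$from, to = cfg$to, step_pct = cfg$step_pct,
                increment = "multiplicative"),
    readouts = cfg$readouts, total = cfg$total,
    tolerances = list(steady_state_residual = 1e-8,
                      integration_rtol = 1e-9, integration_atol = 1e-12),
    files = basename(files)
  )
  jsonlite::write_json(run_meta, frun, auto_unbox = TRUE, digits = NA,
                       null = "null", pretty = TRUE)
  files <- c(files, frun)
  result$files <- files
  invisible(result)
}

#' Read a scenario configuration from a YAML file
#'
#' The file mirrors the [scenario_config()] fields by name (`name`, `model`,
#' `overrides`, `axis`, `from`, `to`, `step_pct`, `readouts`, `total`).
#' Example files for every built-in scenario ship under
#' `system.file("extdata", "scenarios", package = "cmcscan")`.
#'
#' @param path YAML file path.
#' @return A validated `scenario_config`.
#' @export
read_scenario_config <- function(path) {
  y <- yaml::read_yaml(path)
  allowed <- c("name", "model", "overrides", "axis", "from", "to",
               "step_pct", "readouts", "total")
  unknown <- setdiff(names(y), allowed)
  if (length(unknown) > 0L) {
    stop("unknown configuration field(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  if (is.null(y$name)) stop("configuration must set 'name'", call. = FALSE)
  do.call(scenario_config, y)
}

#' Write a scenario configuration to a YAML file
#'
#' @param config A `scenario_config`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_scenario_config <- function(config, path) {
  stopifnot(inherits(config, "scenario_config"))
  y <- unclass(config)
  y$grid <- NULL
  y <- y[!vapply(y, is.null, TRUE)]
  if (length(y$overrides) == 0L) y$overrides <- NULL
  yaml::write_yaml(y, path)
  invisible(path)
}
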