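#' Plot a dose-response curve
#'
#' Line plot of one or more readouts against dose, optionally on log scales
#' (log dose is the natural scale for geometric scan grids).
#'
#' @param object A `cmc_dr_curve`.
#' @param readouts Columns to draw; defaults to the substrate readouts.
#' @param log_dose,log_response Use log10 scales (default: log dose only).
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.cmc_dr_curve <- function(object, readouts = NULL, log_dose = TRUE,
                                  log_response = FALSE, ...) {
  if (is.null(readouts)) {
    readouts <- intersect(c("R", "Rp", "Rtot_free", "total_substrate"),
                          names(object))
  }
  long <- tidyr::pivot_longer(
    dplyr::select(tibble::as_tibble(object), dplyr::all_of(c("dose", readouts))),
    -"dose", names_to = "readout", values_to = "value")
  gg <- ggplot2::ggplot(long, ggplot2::aes(
    x = .data$dose, y = .data$value, colour = .data$readout)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = attr(object, "axis") %||% "dose",
                  y = "steady-state level", colour = NULL)
  if (log_dose) gg <- gg + ggplot2::scale_x_log10()
  if (log_response) gg <- gg + ggplot2::scale_y_log10()
  gg
}

#' Plot a time course
#'
#' @param object A `cmc_time_course` from [simulate_time_course()].
#' @param species Columns to draw; defaults to `R`, `Rp`, `Rtot_free`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.cmc_time_course <- function(object, species = NULL, ...) {
  if (is.null(species)) {
    species <- intersect(c("R", "Rp", "Rtot_free"), names(object))
  }
  long <- tidyr::pivot_longer(
    dplyr::select(tibble::as_tibble(object), dplyr::all_of(c("time", species))),
    -"time", names_to = "species", values_to = "concentration")
  ggplot2::ggplot(long, ggplot2::aes(
    x = .data$time, y = .data$concentration, colour = .data$species)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "time", y = "concentration", colour = NULL)
}

#' Plot an LRC profile
#'
#' Draws the local response coefficient against dose with the maximal-|LRC|
#' point marked and the |LRC| = 1 amplification threshold shown.
#'
#' @param object An `us_metrics` object.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.us_metrics <- function(object, ...) {
  lrc <- object$lrc
  ggplot2::ggplot(lrc, ggplot2::aes(x = .data$dose, y = .data$lrc)) +
    ggplot2::geom_hline(yintercept = c(-1, 1), linetype = "dotted") +
    ggplot2::geom_line() +
    ggplot2::annotate("point", x = object$lrc_max_location,
                      y = object$lrc_extremum, shape = 21) +
    ggplot2::scale_x_log10() +
    ggplot2::labs(x = "dose", y = "local response coefficient",
                  title = paste0(object$readout, ": |LRC|max = ",
                                 signif(object$lrc_max_abs, 3)))
}
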