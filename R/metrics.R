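#' Local response coefficients of a dose-response curve
#'
#' The local response coefficient (LRC) is the log-log slope of response
#' against dose, `d ln r / d ln D`: the ratio of the fractional change in
#' response to the fractional change in dose. Values above 1 in magnitude
#' mark amplification (ultrasensitivity), below 1 attenuation. On the
#' geometric scan grid the estimator is a centered finite difference of
#' `ln r` against `ln D` at interior points and a one-sided difference at the
#' endpoints; responses at or below `1e-12` are masked (log undefined at the
#' working precision).
#'
#' @param curve A `cmc_dr_curve` (or any tibble with a `dose` column).
#' @param readout Name of the response column, e.g. `"Rp"`.
#' @return Tibble `dose`, `lrc`.
#' @seealso [lrc_max()], [hill_coefficient()]
#' @export
local_response_coefficients <- function(curve, readout) {
  r <- pull_readout(curve, readout)
  d <- curve$dose
  n <- length(r)
  if (n < 3L) stop("need at least 3 grid points for LRC", call. = FALSE)
  r_mask <- ifelse(r <= 1e-12, NA_real_, r)
  lr <- log(r_mask)
  ld <- log(d)
  lrc <- rep(NA_real_, n)
  lrc[2:(n - 1)] <- (lr[3:n] - lr[1:(n - 2)]) / (ld[3:n] - ld[1:(n - 2)])
  lrc[1] <- (lr[2] - lr[1]) / (ld[2] - ld[1])
  lrc[n] <- (lr[n] - lr[n - 1]) / (ld[n] - ld[n - 1])
  tibble::tibble(dose = d, lrc = lrc)
}

#' Maximal amplification of an LRC profile
#'
#' Returns the maximal absolute local response coefficient, the signed value
#' there, and the dose at which it occurs (ties broken toward the lower
#' dose). This is the curve's maximal amplification capacity.
#'
#' @param lrc Tibble as returned by [local_response_coefficients()], or a
#'   numeric vector of LRC values (then `doses` must be given).
#' @param doses Dose vector when `lrc` is a bare numeric vector.
#' @return List with `lrc_max_abs`, `lrc_extremum` (signed), `location`.
#' @export
lrc_max <- function(lrc, doses = NULL) {
  if (is.data.frame(lrc)) {
    doses <- lrc$dose
    lrc <- lrc$lrc
  }
  if (length(lrc) == 0L) stop("empty LRC input", call. = FALSE)
  stopifnot(length(lrc) == length(doses))
  a <- abs(lrc)
  if (all(is.na(a))) stop("all LRC values undefined", call. = FALSE)
  i <- which(a == max(a, na.rm = TRUE))[1L]
  list(lrc_max_abs = a[i], lrc_extremum = lrc[i], location = doses[i])
}

#' Saturation (plateau) diagnostic of a dose-response curve
#'
#' A readout is considered saturated when its variation over the last
#' half-decade of doses, measured relative to the curve's overall scale
#' (its largest magnitude), falls below `tol`. Measuring against the curve
#' scale rather than the local value keeps the diagnostic meaningful for
#' inhibitory readouts that decay toward zero, where any residual decay is a
#' large fraction of the (tiny) local value but a negligible fraction of the
#' response. Non-saturating responses (e.g. substrate level versus synthesis
#' rate, which grows without bound) have no defined maximal response, so no
#' Hill coefficient.
#'
#' @param curve A `cmc_dr_curve`.
#' @param readout Response column name.
#' @param tol Scale-relative variation threshold (default `0.01`).
#' @return List with `saturated` flag and `plateau` (readout at the highest
#'   dose).
#' @export
plateau_check <- function(curve, readout, tol = 0.01) {
  r <- pull_readout(curve, readout)
  d <- curve$dose
  if (length(d) < 10L) stop("need at least 10 grid points", call. = FALSE)
  window <- d >= max(d) / sqrt(10)
  rw <- r[window]
  scale <- max(abs(r), 1e-300)
  saturated <- (max(rw) - min(rw)) / scale < tol
  list(saturated = saturated, plateau = r[length(r)])
}

#' Hill coefficient of a dose-response curve
#'
#' Estimates the global steepness of a saturating, monotone dose-response
#' curve from the dose ratio spanning 10% to 90% of the maximal response:
#' \deqn{n_H = \ln 81 / \ln(X_{0.9}/X_{0.1})}
#' The response is first normalized to the fractional level
#' `f(D) = (r(D) - r_bg) / (r_plateau - r_bg)`, where the background `r_bg`
#' is the zero-dose response stored on the curve and the plateau is the
#' high-dose end. For decreasing (inhibitory) responses the same formula
#' measures the fractional *decrease* from the basal level, and the returned
#' coefficient carries a negative sign. Crossings of 0.1 and 0.9 are located
#' by monotone piecewise-linear interpolation in log-dose.
#'
#' Curves that do not saturate at the high-dose end, or are not monotone
#' (beyond `1e-9` relative rounding noise), have no defined Hill coefficient:
#' the result is flagged (`defined = FALSE`, `n_H = NA`) rather than raised
#' as an error, so scenario tables can carry "not evaluated" cells.
#'
#' @param curve A `cmc_dr_curve`.
#' @param readout Response column name.
#' @param background Optional background override; defaults to the curve's
#'   recorded zero-dose readout.
#' @return List: `n_H` (signed), `X_10`, `X_90`, `saturated`, `monotone`,
#'   `defined`, `reason` (NA when defined).
#' @export
hill_coefficient <- function(curve, readout, background = NULL) {
  r <- pull_readout(curve, readout)
  d <- curve$dose
  if (is.null(background)) {
    bg <- attr(curve, "background")
    background <- if (!is.null(bg) && readout %in% names(bg)) bg[[readout]] else r[1L]
  }
  undefined <- function(reason, saturated = NA, monotone = NA) {
    list(n_H = NA_real_, X_10 = NA_real_, X_90 = NA_real_,
         saturated = saturated, monotone = monotone, defined = FALSE,
         reason = reason)
  }
  mono <- monotone_direction(r)
  sat <- plateau_check(curve, readout)$saturated
  if (is.na(mono)) return(undefined("nonmonotonic response", sat, FALSE))
  if (mono == 0) return(undefined("flat response", sat, TRUE))
  if (!sat) return(undefined("response does not saturate", FALSE, TRUE))
  plateau <- r[length(r)]
  span <- plateau - background
  if (abs(span) <= 1e-12 * max(abs(plateau), abs(background), 1)) {
    return(undefined("no response above background", TRUE, TRUE))
  }
  f <- (r - background) / span  # fractional response, increasing in dose
  X_10 <- cross_dose(d, f, 0.1)
  X_90 <- cross_dose(d, f, 0.9)
  if (is.na(X_10) || is.na(X_90)) {
    return(undefined("10%/90% levels not bracketed by the scan", TRUE, TRUE))
  }
  n_H <- sign(span) * log(81) / log(X_90 / X_10)
  list(n_H = n_H, X_10 = X_10, X_90 = X_90, saturated = TRUE, monotone = TRUE,
       defined = TRUE, reason = NA_character_)
}

# +1 increasing, -1 decreasing, 0 flat, NA nonmonotonic; tolerance 1e-9
# relative so solver noise does not flip the verdict.
monotone_direction <- function(r) {
  tol <- 1e-9 * max(abs(r), 1)
  dr <- diff(r)
  up <- any(dr > tol)
  down <- any(dr < -tol)
  if (up && down) return(NA_real_)
  if (up) 1 else if (down) -1 else 0
}

# first upward crossing of `level` by the monotone fractional response,
# linear interpolation in log-dose
cross_dose <- function(d, f, level) {
  n <- length(f)
  if (f[1L] >= level) return(if (abs(f[1L] - level) < 1e-9) d[1L] else NA_real_)
  i <- which(f[-n] < level & f[-1L] >= level)
  if (length(i) == 0L) return(NA_real_)
  i <- i[1L]
  ld <- log(d)
  w <- (level - f[i]) / (f[i + 1L] - f[i])
  exp(ld[i] + w * (ld[i + 1L] - ld[i]))
}

#' All ultrasensitivity metrics of one readout
#'
#' Bundles the Hill coefficient, the LRC profile, the maximal |LRC| with its
#' dose location, and the saturation/monotonicity diagnostics for one
#' readout of a dose-response curve.
#'
#' @inheritParams hill_coefficient
#' @return An `us_metrics` object; see [tidy.us_metrics()] for the one-row
#'   tabular form.
#' @examples
#' curve <- scan_dose_response(mm_params(), dose_grid("X", 0.01, 100))
#' m <- ultrasensitivity_metrics(curve, "Rp")
#' tidy(m)
#' @export
ultrasensitivity_metrics <- function(curve, readout, background = NULL) {
  lrc <- local_response_coefficients(curve, readout)
  pk <- lrc_max(lrc)
  hc <- hill_coefficient(curve, readout, background = background)
  pl <- plateau_check(curve, readout)
  structure(list(readout = readout, n_H = hc$n_H, X_10 = hc$X_10,
                 X_90 = hc$X_90, lrc = lrc, lrc_max_abs = pk$lrc_max_abs,
                 lrc_extremum = pk$lrc_extremum,
                 lrc_max_location = pk$location, saturated = hc$saturated,
                 monotone = hc$monotone, defined = hc$defined,
                 reason = hc$reason, plateau = pl$plateau),
            class = "us_metrics")
}

#' @export
print.us_metrics <- function(x, ...) {
  cat("<us_metrics> readout:", x$readout, "\n")
  if (x$defined) {
    cat("  n_H =", format(x$n_H, digits = 4),
        " (X_10 =", format(x$X_10, digits = 4),
        ", X_90 =", format(x$X_90, digits = 4), ")\n")
  } else {
    cat("  n_H = NA (", x$reason, ")\n", sep = "")
  }
  cat("  |LRC|max =", format(x$lrc_max_abs, digits = 4),
      "at dose", format(x$lrc_max_location, digits = 4), "\n")
  invisible(x)
}

#' Tidiers for cmcscan result objects
#'
#' [generics::tidy()] and [generics::glance()] methods returning tibbles, in
#' the style of broom: `tidy()` gives the per-component table, `glance()` a
#' one-row summary.
#'
#' @param x A cmcscan result object.
#' @param ... Unused.
#' @name tidiers
NULL

#' @rdname tidiers
#' @export
tidy.us_metrics <- function(x, ...) {
  tibble::tibble(readout = x$readout, n_H = x$n_H, X_10 = x$X_10,
                 X_90 = x$X_90, lrc_max_abs = x$lrc_max_abs,
                 lrc_extremum = x$lrc_extremum,
                 lrc_max_location = x$lrc_max_location,
                 saturated = x$saturated, monotone = x$monotone,
                 defined = x$defined, reason = x$reason)
}

#' @rdname tidiers
#' @export
glance.us_metrics <- function(x, ...) {
  tibble::tibble(n_H = x$n_H, lrc_max_abs = x$lrc_max_abs,
                 defined = x$defined)
}

pull_readout <- function(curve, readout) {
  stopifnot(is.character(readout), length(readout) == 1L)
  if (!"dose" %in% names(curve)) stop("not a dose-response curve", call. = FALSE)
  if (!readout %in% names(curve)) {
    stop("readout '", readout, "' not in curve (have: ",
         paste(setdiff(names(curve), "dose"), collapse = ", "), ")",
         call. = FALSE)
  }
  curve[[readout]]
}
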