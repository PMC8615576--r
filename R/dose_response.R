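#' Geometric dose grid with percent increments
#'
#' Builds the dose axis used by all scans: a geometric sequence
#' `from * (1 + step_pct/100)^i`, truncated at `to`. Percent increments on a
#' multiplicative grid keep the log-dose spacing uniform, which is what the
#' local response coefficient (a log-log slope) is differenced on.
#'
#' @param axis Name of the scanned parameter (e.g. `"X"`, `"Xtot"`, `"k0"`,
#'   `"Km1"`). Validated against the parameter set at scan time.
#' @param from,to Scan bounds, `0 < from < to`.
#' @param step_pct Relative increment in percent (default 1).
#' @return A `dose_grid` object with the realized `doses`.
#' @examples
#' dose_grid("X", 1, 1.0201)$doses  # 1.00 1.01 1.0201
#' @export
dose_grid <- function(axis, from, to, step_pct = 1) {
  stopifnot(is.character(axis), length(axis) == 1L)
  if (!(from > 0 && to > from)) stop("need 0 < from < to", call. = FALSE)
  if (step_pct <= 0) stop("step_pct must be > 0", call. = FALSE)
  r <- 1 + step_pct / 100
  n <- floor(log(to / from) / log(r) + 1e-9)
  structure(list(axis = axis, from = from, to = to, step_pct = step_pct,
                 doses = from * r^(0:n)),
            class = "dose_grid")
}

#' @export
print.dose_grid <- function(x, ...) {
  cat("<dose_grid> ", x$axis, " in [", format(x$from), ", ", format(x$to),
      "], ", x$step_pct, "% increments, ", length(x$doses), " points\n",
      sep = "")
  invisible(x)
}

#' Steady-state dose-response scan
#'
#' Computes one steady state per grid point, warm-starting each solve from
#' the previous point's solution, and assembles a tidy curve with all
#' readouts: the species, `Rtot_free = R + Rp`, `total_substrate` (full model
#' only) and the four fluxes. The background (zero-dose) response is taken at
#' axis value 0 when the axis is the kinase level (`X`/`Xtot`), else at the
#' grid's lower bound; which convention applied is recorded in the
#' `background_at` attribute.
#'
#' @param params A `cmc_params` object; the scanned axis value in it is
#'   ignored (replaced by each grid point).
#' @param grid A [dose_grid()]; its `axis` must name a parameter of `params`.
#' @param total Conserved total substrate for closed-cycle mode.
#' @return A tibble of class `cmc_dr_curve` with column `dose` followed by
#'   the readouts. Attributes: `params`, `axis`, `background` (named readout
#'   vector), `background_at`, `model`, `step_pct`, `total`.
#' @examples
#' curve <- scan_dose_response(mm_params(), dose_grid("X", 0.01, 100))
#' @export
scan_dose_response <- function(params, grid, total = NULL) {
  stopifnot(inherits(grid, "dose_grid"))
  if (!grid$axis %in% names(params)) {
    stop("unknown dose axis '", grid$axis, "' for ", class(params)[1L],
         call. = FALSE)
  }
  doses <- grid$doses
  nms <- state_names(params)
  warm <- NULL
  states <- matrix(NA_real_, length(doses), length(nms),
                   dimnames = list(NULL, nms))
  for (i in seq_along(doses)) {
    p_i <- set_params(params, stats::setNames(list(doses[i]), grid$axis))
    ss <- tryCatch(
      solve_steady_state(p_i, init = warm, total = total),
      error = function(e) {
        stop("steady state failed at ", grid$axis, " = ", format(doses[i]),
             ": ", conditionMessage(e), call. = FALSE)
      })
    if (!ss$converged) {
      stop("non-converged steady state at ", grid$axis, " = ",
           format(doses[i]), call. = FALSE)
    }
    states[i, ] <- ss$state
    warm <- ss$state
  }
  # background: basal (axis -> 0) for kinase axes, lower bound otherwise
  kinase_axis <- grid$axis %in% c("X", "Xtot")
  if (kinase_axis) {
    p_bg <- set_params(params, stats::setNames(list(0), grid$axis))
    bg_state <- solve_steady_state(p_bg, total = total)$state
    background_at <- 0
  } else {
    bg_state <- states[1L, ]
    background_at <- doses[1L]
  }
  curve <- assemble_curve(doses, states, params, grid$axis)
  attr(curve, "params") <- params
  attr(curve, "axis") <- grid$axis
  attr(curve, "step_pct") <- grid$step_pct
  attr(curve, "model") <- model_variant(params)
  attr(curve, "total") <- total
  attr(curve, "background") <- readouts_of(bg_state, params)
  attr(curve, "background_at") <- background_at
  class(curve) <- c("cmc_dr_curve", class(curve))
  curve
}

readouts_of <- function(state, params) {
  base <- c(state[c("R", "Rp")], Rtot_free = unname(state[["R"]] + state[["Rp"]]))
  if (model_variant(params) == "full") {
    base <- c(base,
              total_substrate = unname(sum(state[c("R", "Rp", "RX", "RpY")])),
              state[c("RX", "RpY")])
  }
  c(base, cmc_fluxes(state, params))
}

assemble_curve <- function(doses, states, params, axis) {
  rows <- lapply(seq_along(doses), function(i) {
    p_i <- set_params(params, stats::setNames(list(doses[i]), axis))
    readouts_of(states[i, ], p_i)
  })
  m <- do.call(rbind, rows)
  out <- tibble::as_tibble(as.data.frame(m))
  tibble::add_column(out, dose = doses, .before = 1L)
}

#' Readout names of a dose-response curve
#' @param curve A `cmc_dr_curve`.
#' @return Character vector of available readout columns.
#' @export
curve_readouts <- function(curve) setdiff(names(curve), "dose")

#' Per-dose flux table of a scan
#'
#' Extracts the four fluxes from a dose-response curve and, for the
#' Michaelis-Menten model, asserts the steady-state turnover balance
#' `flux_k3 + flux_k4 = k0` at every point.
#'
#' @param curve A `cmc_dr_curve` containing flux readouts.
#' @param tol Relative tolerance of the flux-balance assertion.
#' @return Tibble with `dose` and `flux_k1` .. `flux_k4`.
#' @export
flux_profile <- function(curve, tol = 1e-6) {
  fl <- paste0("flux_k", 1:4)
  if (!all(fl %in% names(curve))) {
    stop("curve has no flux readouts", call. = FALSE)
  }
  params <- attr(curve, "params")
  if (!is.null(params) && attr(curve, "model") == "mm" && params$k0 > 0 &&
      attr(curve, "axis") != "k0") {
    bal <- curve$flux_k3 + curve$flux_k4
    if (max(abs(bal - params$k0)) > tol * max(params$k0, 1)) {
      stop("turnover fluxes do not balance synthesis k0", call. = FALSE)
    }
  }
  dplyr::select(tibble::as_tibble(curve), dplyr::all_of(c("dose", fl)))
}

#' Linearity of total substrate in the modified / unmodified form
#'
#' At steady state the Michaelis-Menten model obeys two exact linear
#' relations derived from the turnover balance `k0 = k3 R + k4 Rp`:
#' `Rtot = k0/k3 + (1 - k4/k3) Rp` (requires `k3 > 0`) and
#' `Rtot = k0/k4 + (1 - k3/k4) R` (requires `k4 > 0`). This check recomputes
#' both residuals from solver output at every dose; they should vanish to
#' solver tolerance, and when `k3 = k4` the first relation collapses to the
#' constancy of `Rtot`.
#'
#' @param curve A Michaelis-Menten `cmc_dr_curve`.
#' @return Tibble `dose`, `resid_rp_form`, `resid_r_form` (NA where the
#'   corresponding rate constant is zero), with attributes `max_abs_rp_form`
#'   and `max_abs_r_form`.
#' @export
rtot_linearity_check <- function(curve) {
  if (!identical(attr(curve, "model"), "mm")) {
    stop("linearity relations apply to the Michaelis-Menten model", call. = FALSE)
  }
  p <- attr(curve, "params")
  rtot <- curve$R + curve$Rp
  r1 <- if (p$k3 > 0) rtot - (p$k0 / p$k3 + (1 - p$k4 / p$k3) * curve$Rp) else
    rep(NA_real_, nrow(curve))
  r2 <- if (p$k4 > 0) rtot - (p$k0 / p$k4 + (1 - p$k3 / p$k4) * curve$R) else
    rep(NA_real_, nrow(curve))
  out <- tibble::tibble(dose = curve$dose, resid_rp_form = r1, resid_r_form = r2)
  attr(out, "max_abs_rp_form") <- if (p$k3 > 0) max(abs(r1)) else NA_real_
  attr(out, "max_abs_r_form") <- if (p$k4 > 0) max(abs(r2)) else NA_real_
  out
}

#' @rdname tidiers
#' @export
glance.cmc_dr_curve <- function(x, ...) {
  tibble::tibble(model = attr(x, "model"), axis = attr(x, "axis"),
                 n_doses = nrow(x), from = min(x$dose), to = max(x$dose),
                 step_pct = attr(x, "step_pct"),
                 background_at = attr(x, "background_at"))
}
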