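#' Time derivatives of the Michaelis-Menten cycle model
#'
#' Evaluates the right-hand side of the two-equation model:
#' \deqn{dR/dt = k_0 - k_1 X R/(K_{m1}+R) + k_2 Y R_p/(K_{m2}+R_p) - k_3 R}
#' \deqn{dR_p/dt = k_1 X R/(K_{m1}+R) - k_2 Y R_p/(K_{m2}+R_p) - k_4 R_p}
#'
#' @param state Named numeric vector with elements `R` and `Rp`, both >= 0.
#' @param params An [mm_params()] object.
#' @return Named numeric vector `c(R = dR/dt, Rp = dRp/dt)`.
#' @seealso [mm_fluxes()], [solve_steady_state()]
#' @export
mm_rhs <- function(state, params) {
  check_state(state, c("R", "Rp"))
  p <- params
  v1 <- p$k1 * p$X * state[["R"]] / (p$Km1 + state[["R"]])
  v2 <- p$k2 * p$Y * state[["Rp"]] / (p$Km2 + state[["Rp"]])
  c(R  = p$k0 - v1 + v2 - p$k3 * state[["R"]],
    Rp = v1 - v2 - p$k4 * state[["Rp"]])
}

#' Reaction fluxes of the Michaelis-Menten cycle model
#'
#' The four fluxes named after their rate constants: phosphorylation
#' (`flux_k1`), dephosphorylation (`flux_k2`), degradation of R (`flux_k3`)
#' and degradation of Rp (`flux_k4`). At any steady state the turnover
#' fluxes balance synthesis: `flux_k3 + flux_k4 = k0`.
#'
#' @inheritParams mm_rhs
#' @return Named numeric vector `c(flux_k1, flux_k2, flux_k3, flux_k4)`.
#' @export
mm_fluxes <- function(state, params) {
  check_state(state, c("R", "Rp"))
  p <- params
  c(flux_k1 = p$k1 * p$X * state[["R"]] / (p$Km1 + state[["R"]]),
    flux_k2 = p$k2 * p$Y * state[["Rp"]] / (p$Km2 + state[["Rp"]]),
    flux_k3 = p$k3 * state[["R"]],
    flux_k4 = p$k4 * state[["Rp"]])
}

#' Time derivatives of the full mass-action cycle model
#'
#' Evaluates the right-hand side of the four-equation model with explicit
#' enzyme-substrate complexes. Free enzyme is an algebraic function of state
#' (`X = Xtot - RX`, `Y = Ytot - RpY`), so enzyme conservation holds by
#' construction. Degradation of a complex (rate `k3` for RX, `k4` for RpY)
#' removes the complex and releases the enzyme; no substrate is returned.
#'
#' \deqn{dR/dt = k_0 - k_{1f} R (X_{tot}-RX) + k_{1b} RX + k_{2c} RpY - k_3 R}
#' \deqn{dR_p/dt = k_{1c} RX - k_{2f} R_p (Y_{tot}-RpY) + k_{2b} RpY - k_4 R_p}
#' \deqn{dRX/dt = k_{1f} R (X_{tot}-RX) - (k_{1b}+k_{1c}+k_3) RX}
#' \deqn{dRpY/dt = k_{2f} R_p (Y_{tot}-RpY) - (k_{2b}+k_{2c}+k_4) RpY}
#'
#' @param state Named numeric vector with elements `R`, `Rp`, `RX`, `RpY`;
#'   all >= 0, `RX <= Xtot`, `RpY <= Ytot`.
#' @param params A [full_params()] object.
#' @return Named numeric vector of the four derivatives.
#' @export
full_rhs <- function(state, params) {
  check_state(state, c("R", "Rp", "RX", "RpY"))
  p <- params
  if (state[["RX"]] > p$Xtot + 1e-9 * max(1, p$Xtot)) {
    stop("'RX' exceeds total kinase Xtot", call. = FALSE)
  }
  if (state[["RpY"]] > p$Ytot + 1e-9 * max(1, p$Ytot)) {
    stop("'RpY' exceeds total phosphatase Ytot", call. = FALSE)
  }
  R <- state[["R"]]; Rp <- state[["Rp"]]
  RX <- state[["RX"]]; RpY <- state[["RpY"]]
  Xfree <- p$Xtot - RX
  Yfree <- p$Ytot - RpY
  c(R   = p$k0 - p$k1f * R * Xfree + p$k1b * RX + p$k2c * RpY - p$k3 * R,
    Rp  = p$k1c * RX - p$k2f * Rp * Yfree + p$k2b * RpY - p$k4 * Rp,
    RX  = p$k1f * R * Xfree - (p$k1b + p$k1c + p$k3) * RX,
    RpY = p$k2f * Rp * Yfree - (p$k2b + p$k2c + p$k4) * RpY)
}

#' Reaction fluxes of the full mass-action cycle model
#'
#' The analogues of [mm_fluxes()]: catalytic phosphorylation `k1c*RX`,
#' catalytic dephosphorylation `k2c*RpY`, and the total degradation fluxes
#' `k3*(R + RX)` and `k4*(Rp + RpY)`, which balance synthesis `k0` at any
#' steady state.
#'
#' @inheritParams full_rhs
#' @return Named numeric vector `c(flux_k1, flux_k2, flux_k3, flux_k4)`.
#' @export
full_fluxes <- function(state, params) {
  check_state(state, c("R", "Rp", "RX", "RpY"))
  p <- params
  c(flux_k1 = p$k1c * state[["RX"]],
    flux_k2 = p$k2c * state[["RpY"]],
    flux_k3 = p$k3 * (state[["R"]] + state[["RX"]]),
    flux_k4 = p$k4 * (state[["Rp"]] + state[["RpY"]]))
}

cmc_rhs <- function(state, params) {
  if (model_variant(params) == "mm") mm_rhs(state, params)
  else full_rhs(state, params)
}

cmc_fluxes <- function(state, params) {
  if (model_variant(params) == "mm") mm_fluxes(state, params)
  else full_fluxes(state, params)
}

state_names <- function(params) {
  if (model_variant(params) == "mm") c("R", "Rp") else c("R", "Rp", "RX", "RpY")
}

check_state <- function(state, nms) {
  if (!is.numeric(state) || !all(nms %in% names(state))) {
    stop("state must be a named numeric vector with elements ",
         paste(nms, collapse = ", "), call. = FALSE)
  }
  if (any(!is.finite(state[nms]))) {
    stop("state contains non-finite values", call. = FALSE)
  }
  if (any(state[nms] < 0)) {
    stop("negative concentrations in state", call. = FALSE)
  }
  invisible(state)
}

# Jacobian of the full model rhs, used by the damped Newton steady-state solver.
full_jacobian <- function(state, params) {
  p <- params
  R <- state[["R"]]; Rp <- state[["Rp"]]
  RX <- state[["RX"]]; RpY <- state[["RpY"]]
  Xfree <- p$Xtot - RX
  Yfree <- p$Ytot - RpY
  matrix(c(
    -p$k1f * Xfree - p$k3, 0,                     p$k1f * R + p$k1b,           p$k2c,
    0,                     -p$k2f * Yfree - p$k4, p$k1c,                       p$k2f * Rp + p$k2b,
    p$k1f * Xfree,         0,                     -p$k1f * R - (p$k1b + p$k1c + p$k3), 0,
    0,                     p$k2f * Yfree,         0,                           -p$k2f * Rp - (p$k2b + p$k2c + p$k4)
  ), nrow = 4L, byrow = TRUE,
  dimnames = list(c("R", "Rp", "RX", "RpY"), c("R", "Rp", "RX", "RpY")))
}
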