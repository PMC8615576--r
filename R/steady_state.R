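#' Basal initial condition of a cycle model
#'
#' The reference state from which all simulations start: the steady state
#' reached in the absence of kinase (`X = 0` or `Xtot = 0`), where all
#' modified species are zero and the unmodified substrate settles at the
#' synthesis/degradation balance `R = k0/k3`.
#'
#' @param params A `cmc_params` object.
#' @param total Conserved total substrate, required only in closed-cycle mode
#'   (`k0 = k3 = k4 = 0`), where no synthesis/degradation balance exists and
#'   the total is an input instead.
#' @return Named state vector (`R`, `Rp` and, for the full model, `RX`, `RpY`).
#' @export
initial_condition <- function(params, total = NULL) {
  nms <- state_names(params)
  if (is_conserved_cycle(params)) {
    if (is.null(total)) {
      stop("closed cycle (k0 = k3 = k4 = 0): supply the conserved total",
           call. = FALSE)
    }
    s <- stats::setNames(c(total, rep(0, length(nms) - 1L)), nms)
    return(s)
  }
  if (params$k3 == 0 && params$k0 > 0) {
    stop("k3 = 0 with k0 > 0: no finite basal steady state; ",
         "supply an explicit initial state", call. = FALSE)
  }
  R0 <- if (params$k3 > 0) params$k0 / params$k3 else 0
  stats::setNames(c(R0, rep(0, length(nms) - 1L)), nms)
}

is_conserved_cycle <- function(params) {
  params$k0 == 0 && params$k3 == 0 && params$k4 == 0
}

#' Steady state of a cycle model
#'
#' Finds the biologically relevant steady state, i.e. the one reachable from
#' [initial_condition()] (or from a caller-supplied warm start). For the
#' Michaelis-Menten model the algebraic system is reduced through the flux
#' balance `k0 = k3 R + k4 Rp` to a bracketed scalar root problem; for the
#' full model a damped Newton iteration with analytic Jacobian is used,
#' constrained to the physical box (`RX <= Xtot`, `RpY <= Ytot`). If root
#' finding fails, the solver falls back to long-time stiff integration with
#' convergence detection. Both models are monostable over the parameter
#' ranges explored here, so the warm start affects speed, not the answer.
#'
#' @param params A `cmc_params` object.
#' @param init Optional warm-start state (named numeric vector). Defaults to
#'   [initial_condition()].
#' @param total Conserved total substrate for closed-cycle mode.
#' @param tol Residual tolerance: maximum absolute time derivative at the
#'   returned state.
#' @return A `steady_state` object: list with elements `state`,
#'   `residual_norm`, `converged`, `method` (`"root"` or `"integrate"`),
#'   `params`, `total`.
#' @examples
#' solve_steady_state(mm_params(X = 1))
#' @export
solve_steady_state <- function(params, init = NULL, total = NULL, tol = 1e-8) {
  variant <- model_variant(params)
  if (is_conserved_cycle(params)) {
    if (is.null(total) && !is.null(init)) total <- sum(init[state_names(params)])
    if (is.null(total)) {
      stop("closed cycle (k0 = k3 = k4 = 0): supply the conserved total",
           call. = FALSE)
    }
  }
  res <- if (variant == "mm") {
    mm_steady_root(params, total = total)
  } else {
    full_steady_root(params, init = init, total = total)
  }
  if (!is.null(res)) {
    resid <- max(abs(cmc_rhs(res, params)))
    if (is.finite(resid) && resid <= tol && all(res >= 0)) {
      return(new_steady_state(res, resid, TRUE, "root", params, total))
    }
  }
  integrate_to_steady(params, init = init, total = total, tol = tol)
}

new_steady_state <- function(state, resid, converged, method, params, total) {
  structure(list(state = state, residual_norm = resid, converged = converged,
                 method = method, params = params, total = total),
            class = "steady_state")
}

# Scalar reduction of the MM steady-state system. Returns a state or NULL
# (NULL -> integration fallback).
mm_steady_root <- function(params, total = NULL) {
  p <- params
  v1 <- function(R) p$k1 * p$X * R / (p$Km1 + R)
  v2 <- function(Rp) p$k2 * p$Y * Rp / (p$Km2 + Rp)
  if (is_conserved_cycle(p)) {
    if (p$X == 0 || p$k1 == 0) return(c(R = total, Rp = 0))
    g <- function(Rp) v1(total - Rp) - v2(Rp)
    if (g(total) <= 0) {
      Rp <- stats::uniroot(g, c(0, total), tol = 1e-15)$root
    } else Rp <- total  # no phosphatase activity: fully converted
    return(c(R = total - Rp, Rp = Rp))
  }
  if (p$X == 0 || p$k1 == 0) {
    if (p$k3 == 0) {
      if (p$k0 == 0) return(c(R = 0, Rp = 0))
      return(NULL)  # unbounded accumulation of R
    }
    return(c(R = p$k0 / p$k3, Rp = 0))
  }
  if (p$k3 > 0 && p$k4 > 0) {
    # eliminate R via k0 = k3 R + k4 Rp; bisect the remaining balance in Rp
    g <- function(Rp) v1((p$k0 - p$k4 * Rp) / p$k3) - v2(Rp) - p$k4 * Rp
    upper <- p$k0 / p$k4
    if (p$k0 == 0) return(c(R = 0, Rp = 0))
    Rp <- stats::uniroot(g, c(0, upper), tol = 1e-15)$root
    return(c(R = (p$k0 - p$k4 * Rp) / p$k3, Rp = Rp))
  }
  if (p$k4 == 0 && p$k3 > 0) {
    # flux balance pins R = k0/k3; Rp from v2(Rp) = v1(R)
    R <- p$k0 / p$k3
    w <- v1(R)
    cap <- p$k2 * p$Y
    if (w >= cap) return(NULL)  # dephosphorylation saturates: Rp unbounded
    return(c(R = R, Rp = p$Km2 * w / (cap - w)))
  }
  if (p$k3 == 0 && p$k4 > 0) {
    Rp <- p$k0 / p$k4
    u <- p$k0 + v2(Rp)
    cap <- p$k1 * p$X
    if (u >= cap) return(NULL)
    return(c(R = p$Km1 * u / (cap - u), Rp = Rp))
  }
  NULL
}

# Damped Newton for the full model; box-constrained line search.
full_steady_root <- function(params, init = NULL, total = NULL,
                             tol = 1e-11, maxit = 200L) {
  p <- params
  if (is_conserved_cycle(p)) return(NULL)  # handled by integration
  s <- if (!is.null(init)) init[state_names(p)] else initial_condition(p)
  feasible <- function(x) {
    all(is.finite(x)) && all(x >= 0) &&
      x[["RX"]] <= p$Xtot + 1e-12 && x[["RpY"]] <= p$Ytot + 1e-12
  }
  s <- pmin(pmax(s, 0), c(Inf, Inf, p$Xtot, p$Ytot))
  f <- full_rhs(s, p)
  for (i in seq_len(maxit)) {
    if (max(abs(f)) < tol) return(s)
    step <- tryCatch(solve(full_jacobian(s, p), -f), error = function(e) NULL)
    if (is.null(step)) return(NULL)
    lam <- 1
    repeat {
      s2 <- s + lam * step
      if (feasible(s2)) {
        f2 <- full_rhs(s2, p)
        if (max(abs(f2)) < max(abs(f))) break
      }
      lam <- lam / 2
      if (lam < 1e-10) return(NULL)  # stalled: let integration take over
    }
    s <- s2
    f <- f2
  }
  if (max(abs(f)) < tol) s else NULL
}

# Long-time stiff integration fallback with convergence detection: the scaled
# residual max|dstate/dt| / max(state, 1) must stay below 1e-10 over a
# doubling of the integration time.
integrate_to_steady <- function(params, init = NULL, total = NULL, tol = 1e-8) {
  s <- if (!is.null(init)) init[state_names(params)] else {
    initial_condition(params, total = total)
  }
  t_end <- 1e3
  scaled_ok_prev <- FALSE
  repeat {
    tc <- integrate_model(params, s, times = c(0, t_end))
    s <- unlist(tc[nrow(tc), state_names(params)])
    s[s < 0 & s > -1e-12] <- 0
    f <- cmc_rhs(s, params)
    scaled <- max(abs(f)) / max(max(s), 1)
    if (scaled < 1e-10) {
      if (scaled_ok_prev) break
      scaled_ok_prev <- TRUE
    } else scaled_ok_prev <- FALSE
    t_end <- t_end * 2
    if (t_end > 1e9) {
      stop("steady-state integration did not converge; last residual ",
           format(max(abs(f))), call. = FALSE)
    }
  }
  resid <- max(abs(cmc_rhs(s, params)))
  new_steady_state(s, resid, resid <= tol, "integrate", params, total)
}

# deSolve wrapper shared by the fallback and by simulate_time_course().
integrate_model <- function(params, init, times, rtol = 1e-9, atol = 1e-12) {
  nms <- state_names(params)
  deriv <- function(t, y, parms) {
    y <- pmax(y, 0)
    names(y) <- nms
    list(unname(cmc_rhs(y, params)))
  }
  out <- deSolve::ode(y = unname(init[nms]), times = times, func = deriv,
                      parms = NULL, method = "lsoda", rtol = rtol, atol = atol)
  if (attr(out, "istate")[1L] < 0) {
    stop("stiff integrator failed (istate ", attr(out, "istate")[1L], ")",
         call. = FALSE)
  }
  m <- as.data.frame(out)
  names(m) <- c("time", nms)
  m
}

#' Simulate a time course of a cycle model
#'
#' Integrates the stiff ODE system from an initial state (by default the
#' basal state, emulating a step in kinase level applied at `t = 0`) and
#' reports the trajectory on a regular grid.
#'
#' @param params A `cmc_params` object describing the post-step conditions.
#' @param init Initial state; defaults to the basal state of the pre-step
#'   system (kinase set to zero), so the run represents a kinase step.
#' @param t_end End time (> 0).
#' @param n Number of reporting points (>= 2), evenly spaced on `[0, t_end]`.
#' @param total Conserved total for closed-cycle mode.
#' @return A tibble of class `cmc_time_course`: columns `time`, the species,
#'   `Rtot_free = R + Rp` and, for the full model, `total_substrate`.
#'   Attribute `settled` flags whether the final state is within tolerance of
#'   [solve_steady_state()].
#' @export
simulate_time_course <- function(params, init = NULL, t_end = 1000, n = 401L,
                                 total = NULL) {
  stopifnot(t_end > 0, n >= 2L)
  if (is.null(init)) {
    basal <- set_params(params,
                        if (model_variant(params) == "mm") list(X = 0)
                        else list(Xtot = 0))
    init <- initial_condition(basal, total = total)
  }
  check_state(init, state_names(params))
  times <- seq(0, t_end, length.out = n)
  m <- integrate_model(params, init, times)
  m$Rtot_free <- m$R + m$Rp
  if (model_variant(params) == "full") {
    m$total_substrate <- m$Rtot_free + m$RX + m$RpY
  }
  final <- unlist(m[nrow(m), state_names(params)])
  ss <- tryCatch(solve_steady_state(params, init = final, total = total),
                 error = function(e) NULL)
  settled <- !is.null(ss) && ss$converged &&
    max(abs(final - ss$state)) <= 1e-6 * max(1, max(abs(ss$state)))
  out <- tibble::as_tibble(m)
  attr(out, "params") <- params
  attr(out, "settled") <- settled
  class(out) <- c("cmc_time_course", class(out))
  out
}

#' @export
print.steady_state <- function(x, ...) {
  cat("<steady_state> [", x$method, "] converged:", x$converged,
      " residual:", format(x$residual_norm, digits = 3), "\n")
  print(round(x$state, 6))
  invisible(x)
}

#' @rdname tidiers
#' @export
tidy.steady_state <- function(x, ...) {
  tibble::tibble(species = names(x$state), concentration = unname(x$state))
}

#' @rdname tidiers
#' @export
glance.steady_state <- function(x, ...) {
  tibble::tibble(converged = x$converged, residual_norm = x$residual_norm,
                 method = x$method)
}
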