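#' Kinetic parameters of the Michaelis-Menten cycle model
#'
#' Constructs the parameter set of the two-equation covalent modification
#' cycle model in which phosphorylation and dephosphorylation follow
#' Michaelis-Menten rate laws and both substrate forms turn over by
#' first-order degradation. All units are arbitrary concentration/time units.
#'
#' The defaults place the cycle in the zero-order (ultrasensitive) regime:
#' the basal substrate level `k0/k3 = 100` exceeds both Michaelis constants
#' tenfold, and turnover (`k3`, `k4`) is two orders of magnitude slower than
#' the apparent first-order modification rates `k1/Km1` and `k2/Km2`.
#'
#' @param k0 Synthesis rate of the unmodified substrate R (concentration/time).
#' @param k1 Catalytic rate constant of the kinase (1/time).
#' @param Km1 Michaelis constant of the phosphorylation step (concentration).
#' @param X Kinase level (concentration); usually the dose axis.
#' @param k2 Catalytic rate constant of the phosphatase (1/time).
#' @param Km2 Michaelis constant of the dephosphorylation step (concentration).
#' @param k3 Degradation rate constant of R (1/time).
#' @param k4 Degradation rate constant of Rp (1/time). Setting `k4 < k3`
#'   models modification-induced stabilization, `k4 > k3` destabilization.
#' @param Y Phosphatase level (concentration).
#'
#' @return An immutable parameter object of class `mm_params`. Use
#'   [set_params()] to derive modified copies.
#' @seealso [full_params()], [set_params()], [mm_rhs()]
#' @examples
#' p <- mm_params()
#' set_params(p, X = 1, k4 = 0.001)
#' @export
mm_params <- function(k0 = 1, k1 = 10, Km1 = 10, X = 0,
                      k2 = 10, Km2 = 10, k3 = 0.01, k4 = 0.01, Y = 1) {
  p <- list(k0 = k0, k1 = k1, Km1 = Km1, X = X, k2 = k2, Km2 = Km2,
            k3 = k3, k4 = k4, Y = Y)
  validate_params(p, "mm_params")
}

#' Kinetic parameters of the full mass-action cycle model
#'
#' Constructs the parameter set of the four-equation model with explicit
#' kinase-substrate (`RX`) and phosphatase-substrate (`RpY`) complexes.
#' Binding (`k1f`, `k2f`), dissociation (`k1b`, `k2b`) and catalysis
#' (`k1c`, `k2c`) are resolved; complexed substrate is degraded at the same
#' rate constant as the corresponding free form (`k3` for R and RX, `k4` for
#' Rp and RpY), with the enzyme released intact.
#'
#' At the defaults the apparent Michaelis constants
#' `(k1b + k1c)/k1f` and `(k2b + k2c)/k2f` both equal 10, matching the
#' Michaelis-Menten variant ([mm_params()]).
#'
#' @param k0 Synthesis rate of free R (concentration/time).
#' @param k1f Association rate constant of R + X (1/concentration/time).
#' @param k1b Dissociation rate constant of the RX complex (1/time).
#' @param k1c Catalytic (phosphorylation) rate constant (1/time).
#' @param Xtot Total kinase (concentration); usually the dose axis.
#' @param k2f Association rate constant of Rp + Y (1/concentration/time).
#' @param k2b Dissociation rate constant of the RpY complex (1/time).
#' @param k2c Catalytic (dephosphorylation) rate constant (1/time).
#' @param k3 Degradation rate constant of R and RX (1/time).
#' @param k4 Degradation rate constant of Rp and RpY (1/time).
#' @param Ytot Total phosphatase (concentration).
#'
#' @return An immutable parameter object of class `full_params`.
#' @seealso [mm_params()], [apparent_km()], [full_rhs()]
#' @export
full_params <- function(k0 = 1, k1f = 10, k1b = 90, k1c = 10, Xtot = 0,
                        k2f = 10, k2b = 90, k2c = 10,
                        k3 = 0.01, k4 = 0.01, Ytot = 1) {
  p <- list(k0 = k0, k1f = k1f, k1b = k1b, k1c = k1c, Xtot = Xtot,
            k2f = k2f, k2b = k2b, k2c = k2c, k3 = k3, k4 = k4, Ytot = Ytot)
  validate_params(p, "full_params")
}

validate_params <- function(p, class) {
  vals <- unlist(p)
  if (any(!is.finite(vals))) {
    stop("all parameters must be finite numbers", call. = FALSE)
  }
  if (any(vals < 0)) {
    bad <- names(vals)[vals < 0]
    stop("parameters must be non-negative: ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  strict <- if (class == "mm_params") c("Km1", "Km2") else c("k1f", "k2f")
  for (nm in strict) {
    if (p[[nm]] <= 0) stop("'", nm, "' must be strictly positive", call. = FALSE)
  }
  structure(p, class = c(class, "cmc_params"))
}

#' Derive a modified copy of a parameter set
#'
#' Parameter objects are treated as immutable values: scans and scenario
#' overrides always produce fresh copies, so one scan can never contaminate
#' another.
#'
#' @param params An [mm_params()] or [full_params()] object.
#' @param ... Named parameter replacements, or a single named list.
#' @return A new, validated parameter object of the same class.
#' @export
set_params <- function(params, ...) {
  stopifnot(inherits(params, "cmc_params"))
  dots <- list(...)
  if (length(dots) == 1L && is.null(names(dots)) && is.list(dots[[1L]])) {
    dots <- dots[[1L]]
  }
  if (length(dots) == 0L) return(params)
  unknown <- setdiff(names(dots), names(params))
  if (length(unknown) > 0L || is.null(names(dots)) || any(names(dots) == "")) {
    stop("unknown parameter(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  p <- unclass(params)
  p[names(dots)] <- dots
  validate_params(p, class(params)[1L])
}

#' Model variant of a parameter set
#'
#' @param params A `cmc_params` object.
#' @return `"mm"` or `"full"`.
#' @export
model_variant <- function(params) {
  if (inherits(params, "mm_params")) return("mm")
  if (inherits(params, "full_params")) return("full")
  stop("not a cmc_params object", call. = FALSE)
}

#' Apparent Michaelis constant of a mass-action enzymatic step
#'
#' For an elementary binding/catalysis scheme with association rate `kf`,
#' dissociation rate `kb` and catalytic rate `kc`, the Michaelis constant of
#' the reduced rate law is `(kb + kc)/kf`. At the [full_params()] defaults
#' both cycle steps have an apparent Km of 10.
#'
#' @param kb Dissociation rate constant (1/time).
#' @param kc Catalytic rate constant (1/time).
#' @param kf Association rate constant (1/concentration/time); must be > 0.
#' @return The apparent Michaelis constant (concentration).
#' @examples
#' apparent_km(90, 10, 10)   # 10
#' apparent_km(990, 10, 10)  # 100
#' @export
apparent_km <- function(kb, kc, kf) {
  if (any(kf <= 0)) stop("'kf' must be strictly positive", call. = FALSE)
  (kb + kc) / kf
}

#' @export
print.cmc_params <- function(x, ...) {
  cat("<", class(x)[1L], "> ", sep = "")
  cat(paste0(names(x), " = ", format(unlist(x))), sep = ", ")
  cat("\n")
  invisible(x)
}

#' @export
format.cmc_params <- function(x, ...) {
  paste0(names(x), "=", vapply(x, format, ""), collapse = " ")
}

#' @rdname tidiers
#' @export
tidy.cmc_params <- function(x, ...) {
  tibble::tibble(parameter = names(x), value = unname(unlist(x)))
}
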