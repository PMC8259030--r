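#' Kinetic parameters for the tri-stable switch circuit
#'
#' Protein-level lumped Hill-kinetics model of the lambda-derived circuit:
#' five promoters (placm, patp2, pR, pRM, pRE), six gene products (cI, cro,
#' cII, cIII, beta-GAL from lacZ, L-LDH from ompA-lldD), first-order protein
#' degradation, and FtsH-mediated cII degradation inhibited by cIII.
#'
#' Each promoter entry is a list `v` (maximal rate, a.u./h), `v0` (leak,
#' a.u./h), `K` (half-saturation: mM lactose for placm, proton concentration
#' for patp2, a.u. regulator otherwise), `n` (Hill exponent >= 1). The shipped
#' defaults realize the circuit's two functional regimes: at neutral pH without
#' lactose the stable state is beta-GAL dominant, and at mouse-colon pH with
#' lactose present it is L-LDH dominant, with the switch midpoint of the
#' pH-sensing patp2 promoter at pH 6.
#'
#' @param ... named overrides, e.g. `placm = list(K = 2)`,
#'   `delta = c(cI = 2)`; partial lists are merged into the defaults.
#' @return validated parameter list of class `CircuitParams`
#' @examples
#' p <- circuitParams(placm = list(K = 2))
#' p$placm$K
#' @export
circuitParams <- function(...) {
  defaults <- list(
    placm = list(v = 10, v0 = 0.05, K = 5,     n = 2),  # lactose activation
    patp2 = list(v = 10, v0 = 0.1,  K = 1e-6,  n = 2),  # proton repression (pH 6 midpoint)
    pR    = list(v = 10, v0 = 0.1,  K = 1,     n = 2),  # repressed by cI
    pRM   = list(v = 10, v0 = 0.1,  K = 1,     n = 2),  # repressed by cro
    pRE   = list(v = 10, v0 = 0.1,  K = 1,     n = 2),  # activated by cII
    delta = c(cI = 1, cro = 1, cII = 1, cIII = 1, gal = 0.5, ldh = 0.5),
    ftsh  = list(deltaF = 9, Kiii = 1, m = 2))
  ov <- list(...)
  bad <- setdiff(names(ov), names(defaults))
  if (length(bad)) stop("unknown circuit parameter group(s): ",
                        paste(bad, collapse = ", "))
  for (nm in names(ov)) {
    defaults[[nm]] <- if (is.list(defaults[[nm]]))
      utils::modifyList(defaults[[nm]], as.list(ov[[nm]]))
    else { d <- defaults[[nm]]; d[names(ov[[nm]])] <- ov[[nm]]; d }
  }
  validateCircuitParams(defaults)
}

validateCircuitParams <- function(p) {
  for (pr in c("placm", "patp2", "pR", "pRM", "pRE")) {
    q <- p[[pr]]
    if (q$v0 < 0 || q$v < q$v0) stop(pr, ": need v >= v0 >= 0")
    if (q$K <= 0 || q$n < 1) stop(pr, ": need K > 0 and n >= 1")
  }
  if (any(p$delta <= 0)) stop("degradation rates must be positive")
  with(p$ftsh, if (deltaF <= 0 || Kiii <= 0 || m < 1)
    stop("FtsH parameters must be positive with m >= 1"))
  structure(p, class = "CircuitParams")
}

regulatorNames <- c("cI", "cro", "cII", "cIII", "l_ldh", "beta_gal")

hillUp <- function(x, v, v0, K, n) v0 + (v - v0) * x^n / (K^n + x^n)
hillDown <- function(x, v, v0, K, n) v0 + (v - v0) * K^n / (K^n + x^n)

#' Promoter activities of the circuit
#'
#' `activityPlacm` is Hill activation by lactose; `activityPatp2` is
#' repression by proton concentration `h = 10^(-pH)` (so activity increases
#' with pH); `activityPre` is Hill activation by cII; `hillRepression` is the
#' generic repression form used for pR (repressor cI) and pRM (repressor cro).
#'
#' @param lactose lactose concentration (mM), >= 0
#' @param pH pH in (0, 14)
#' @param cII cII concentration (a.u.), >= 0
#' @param params a [circuitParams()] list
#' @return transcription/production rate in a.u./h
#' @export
activityPlacm <- function(lactose, params) {
  if (any(lactose < 0) || any(!is.finite(lactose)))
    stop("lactose must be finite and >= 0")
  with(params$placm, hillUp(lactose, v, v0, K, n))
}

#' @rdname activityPlacm
#' @export
activityPatp2 <- function(pH, params) {
  if (any(pH <= 0) || any(pH >= 14) || any(!is.finite(pH)))
    stop("pH must lie strictly inside (0, 14)")
  h <- 10^(-pH)
  with(params$patp2, hillDown(h, v, v0, K, n))
}

#' @rdname activityPlacm
#' @param repressor repressor concentration (a.u.), >= 0
#' @param v,v0,K,n Hill parameters (see [circuitParams()])
#' @export
hillRepression <- function(repressor, v, v0, K, n) {
  if (any(repressor < 0) || any(!is.finite(repressor)))
    stop("repressor concentration must be finite and >= 0")
  hillDown(repressor, v, v0, K, n)
}

#' @rdname activityPlacm
#' @export
activityPre <- function(cII, params) {
  if (any(cII < 0) || any(!is.finite(cII)))
    stop("cII must be finite and >= 0")
  with(params$pRE, hillUp(cII, v, v0, K, n))
}

#' Effective first-order cII degradation rate
#'
#' FtsH degrades cII; cIII inhibits FtsH, so the rate falls from
#' `delta_cII + deltaF` (no cIII) to `delta_cII` (saturating cIII).
#'
#' @param cIII cIII concentration (a.u.), >= 0
#' @param params a [circuitParams()] list
#' @return degradation rate (1/h)
#' @export
ciiDegradationRate <- function(cIII, params) {
  if (any(cIII < 0) || any(!is.finite(cIII)))
    stop("cIII must be finite and >= 0")
  f <- params$ftsh
  unname(params$delta["cII"]) + f$deltaF * f$Kiii^f$m / (f$Kiii^f$m + cIII^f$m)
}

#' Right-hand side of the circuit ODEs
#'
#' Wiring: patp2(pH) -> cI; pR (repressed by cI) -> cIII and l_ldh;
#' placm(lactose) + pRE(cII) -> cro and cII (additive drives); pRM (repressed
#' by cro) -> beta_gal; first-order degradation everywhere, with the cII rate
#' modulated by cIII through FtsH.
#'
#' @param state named numeric vector with entries cI, cro, cII, cIII, l_ldh,
#'   beta_gal (a.u., >= 0)
#' @param signals list with `lactose` (mM) and `pH`
#' @param params a [circuitParams()] list
#' @return named derivative vector (a.u./h)
#' @export
circuitRhs <- function(state, signals, params) {
  if (any(!is.finite(state))) stop("non-finite circuit state")
  s <- state[regulatorNames]
  d <- params$delta
  pR_rate <- with(params$pR, hillRepression(s[["cI"]], v, v0, K, n))
  drive <- activityPlacm(signals$lactose, params) + activityPre(s[["cII"]], params)
  c(cI   = activityPatp2(signals$pH, params) - d[["cI"]] * s[["cI"]],
    cro  = drive - d[["cro"]] * s[["cro"]],
    cII  = drive - ciiDegradationRate(s[["cIII"]], params) * s[["cII"]],
    cIII = pR_rate - d[["cIII"]] * s[["cIII"]],
    l_ldh    = pR_rate - d[["ldh"]] * s[["l_ldh"]],
    beta_gal = with(params$pRM, hillRepression(s[["cro"]], v, v0, K, n)) -
      d[["gal"]] * s[["beta_gal"]])
}

#' Integrate the circuit ODEs
#'
#' Deterministic trajectory under a (possibly time-varying) signal protocol,
#' integrated with the stiff-capable `deSolve::lsoda` at relative tolerance
#' 1e-8 and absolute tolerance 1e-10. Values more negative than -1e-12 are an
#' integrator failure; tiny negative excursions are clipped to 0 with a
#' warning.
#'
#' @param initial named initial regulator state (see [circuitRhs()])
#' @param signalFn function of time (h) returning `list(lactose=, pH=)`, or a
#'   fixed `list(lactose=, pH=)` for constant signals
#' @param params a [circuitParams()] list
#' @param tGrid strictly increasing output times (h)
#' @return data.frame with column `time_h` and one column per regulator
#' @examples
#' tr <- simulateCircuit(rep(0, 6), list(lactose = 0, pH = 7),
#'                       circuitParams(), seq(0, 24, 0.5))
#' tail(tr, 1)
#' @export
simulateCircuit <- function(initial, signalFn, params, tGrid) {
  if (is.list(signalFn) && !is.function(signalFn)) {
    sig <- signalFn; signalFn <- function(t) sig
  }
  if (is.unsorted(tGrid, strictly = TRUE))
    stop("tGrid must be strictly increasing")
  y0 <- stats::setNames(as.numeric(initial), regulatorNames)
  if (any(y0 < 0) || any(!is.finite(y0))) stop("invalid initial state")
  rhs <- function(t, y, parms) list(circuitRhs(y, signalFn(t), parms))
  out <- deSolve::lsoda(y0, tGrid, rhs, params, rtol = 1e-8, atol = 1e-10)
  if (attr(out, "istate")[1] < 0)
    stop("circuit integration failed to converge at the requested tolerance")
  out <- as.data.frame(out)
  names(out)[1] <- "time_h"
  vals <- as.matrix(out[regulatorNames])
  if (any(!is.finite(vals)))
    stop("circuit integration produced non-finite values")
  if (any(vals < -1e-12))
    stop("circuit integration produced negative concentrations beyond tolerance")
  if (any(vals < 0)) {
    warning("clipping trace negative excursions (< 1e-12) to zero")
    out[regulatorNames] <- pmax(vals, 0)
  }
  out
}

# Finite-difference Jacobian of the circuit rhs (central differences,
# relative step 1e-6).
circuitJacobian <- function(state, signals, params) {
  n <- length(regulatorNames)
  J <- matrix(0, n, n, dimnames = list(regulatorNames, regulatorNames))
  for (j in seq_len(n)) {
    h <- 1e-6 * max(1, abs(state[j]))
    up <- dn <- state
    up[j] <- state[j] + h; dn[j] <- max(state[j] - h, 0)
    J[, j] <- (circuitRhs(up, signals, params) -
                 circuitRhs(dn, signals, params)) / (up[j] - dn[j])
  }
  J
}

#' Enumerate stable fixed points of the circuit
#'
#' Multi-start root finding (Levenberg-Marquardt on the rhs residuals) from
#' `nStarts` log-uniform initial states over [1e-3, 1e3] a.u.; roots are kept
#' when the residual infinity-norm is below `tol`, all components are
#' non-negative, and every eigenvalue of the finite-difference Jacobian has a
#' negative real part. Duplicates are removed at L-infinity distance 1e-6.
#'
#' @param signals list with `lactose` and `pH` (constant)
#' @param params a [circuitParams()] list
#' @param nStarts number of random starting states (>= 1)
#' @param seed integer seed making the start set reproducible
#' @param tol residual tolerance for accepting a fixed point
#' @return list of named stable states (possibly empty), each with attribute
#'   `eigenvalues`
#' @export
findStableStates <- function(signals, params, nStarts = 20, seed = 1,
                             tol = 1e-8) {
  stopifnot(nStarts >= 1)
  starts <- withSeed(seed, {
    m <- matrix(10^runif(nStarts * 6, -3, 3), nStarts, 6)
    colnames(m) <- regulatorNames
    m
  })
  found <- list()
  for (i in seq_len(nStarts)) {
    fit <- try(minpack.lm::nls.lm(
      par = starts[i, ],
      fn = function(x) circuitRhs(pmax(x, 0), signals, params),
      control = minpack.lm::nls.lm.control(maxiter = 500, ftol = 1e-15,
                                           ptol = 1e-15)), silent = TRUE)
    if (inherits(fit, "try-error")) next
    x <- pmax(fit$par, 0)
    res <- circuitRhs(x, signals, params)
    if (max(abs(res)) >= tol) next
    ev <- eigen(circuitJacobian(x, signals, params), only.values = TRUE)$values
    if (any(Re(ev) >= 0)) next
    dup <- any(vapply(found, function(f) max(abs(f - x)) < 1e-6, logical(1)))
    if (!dup) {
      st <- stats::setNames(x, regulatorNames)
      attr(st, "eigenvalues") <- ev
      found[[length(found) + 1L]] <- st
    }
  }
  found
}
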