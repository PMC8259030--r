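#' Lumen chemistry parameters
#'
#' Parameters of the extracellular (culture or colon-lumen) model: a
#' saturating lactate-to-pH map, Michaelis-Menten lactose hydrolysis by
#' beta-GAL, community fermentation of lactose to lactate, L-LDH oxidation of
#' lactate to pyruvate, baseline alkalinization by biomass metabolism,
#' pyruvate uptake, and logistic biomass growth with a Gaussian pH penalty.
#'
#' Three presets are shipped, differing where the biology differs:
#' \describe{
#'   \item{in_vitro}{pure BL21 culture in adjusted LB: no community
#'     fermentation (the lactic acid was pre-added to the medium), reference
#'     pH 7, inoculum OD 2.}
#'   \item{mouse_colon}{murine lumen: homeostatic reference pH 5, fast
#'     lactose clearance, modest community fermentation.}
#'   \item{human_colon}{neutral reference pH 7 with strong community
#'     fermentation; used for the lactose-pulse switching demonstration.}
#' }
#'
#' @param preset one of `"in_vitro"`, `"mouse_colon"`, `"human_colon"`
#' @param ... named scalar overrides (e.g. `V_ldh = 0.2`)
#' @return validated parameter list of class `EnvParams`
#' @export
envParams <- function(preset = c("in_vitro", "mouse_colon", "human_colon"),
                      ...) {
  preset <- match.arg(preset)
  base <- list(
    pH_ref = 7.4,  # acid-free reference pH (LB consumption plateau in vitro)
    eta = 3.4,     # max pH depression (pH units)
    kappa = 10,    # lactate half-depression constant (mM)
    V_gal = 0.4,   K_gal = 5,    # hydrolysis Vmax (per enzyme a.u. * biomass, 1/h), Km (mM)
    V_ferm = 0,    K_ferm = 10,  # community fermentation Vmax (mM/h per biomass), Km
    y_lac = 4,                   # mol lactate per mol lactose fermented (homolactic)
    V_ldh = 0.12,  K_ldh = 10,   # lactate oxidation Vmax (per enzyme * biomass), Km
    k_alk = 0.06,                # base production per biomass (mM/h)
    k_up = 1,                    # pyruvate uptake (1/h per biomass)
    mu_max = 0.6, B_max = 6, pH_opt = 7, sigma_pH = 1.5,
    Z_native = 1,                # native beta-GAL baseline (a.u.)
    B0 = 2)                      # initial biomass (OD equivalent)
  tweaks <- switch(preset,
    in_vitro = list(),
    mouse_colon = list(pH_ref = 5, eta = 3, V_gal = 25, V_ferm = 0.6,
                       V_ldh = 0.4, K_ldh = 5, k_alk = 1.2, mu_max = 0.2,
                       B_max = 2, pH_opt = 5, B0 = 1),
    human_colon = list(pH_ref = 7, eta = 3, V_gal = 0.03, V_ferm = 1.2,
                       V_ldh = 0.25, k_alk = 0.4, mu_max = 0.3, B_max = 3,
                       pH_opt = 6.5, sigma_pH = 2, B0 = 1))
  p <- utils::modifyList(base, tweaks)
  ov <- list(...)
  bad <- setdiff(names(ov), names(p))
  if (length(bad)) stop("unknown environment parameter(s): ",
                        paste(bad, collapse = ", "))
  p <- utils::modifyList(p, ov)
  if (p$y_lac < 1 || p$y_lac > 4) stop("y_lac must lie in [1, 4]")
  pos <- c("pH_ref", "eta", "kappa", "K_gal", "K_ferm", "K_ldh", "k_up",
           "mu_max", "B_max", "sigma_pH", "Z_native")
  for (nm in pos) assertScalarNumeric(p[[nm]], nm, lower = 0, strict_lower = TRUE)
  for (nm in c("V_gal", "V_ferm", "V_ldh", "k_alk", "B0", "pH_opt"))
    assertScalarNumeric(p[[nm]], nm, lower = 0)
  structure(p, class = "EnvParams")
}

#' Lactate-dependent pH and its inverse
#'
#' A single saturating depression of the reference pH:
#' `pH = pH_ref - eta * A / (kappa + A)` for lactate concentration `A`.
#' The map is strictly decreasing and bounded in `(pH_ref - eta, pH_ref]`, so
#' it is invertible; `lactateFromPh` errors when the requested pH lies outside
#' that band.
#'
#' @param lactate lactate concentration (mM), >= 0
#' @param pH a pH inside `(pH_ref - eta, pH_ref]`
#' @param params an [envParams()] list
#' @return pH (units) / lactate (mM)
#' @export
phFromLactate <- function(lactate, params) {
  if (any(lactate < 0) || any(!is.finite(lactate)))
    stop("lactate must be finite and >= 0")
  params$pH_ref - params$eta * lactate / (params$kappa + lactate)
}

#' @rdname phFromLactate
#' @export
lactateFromPh <- function(pH, params) {
  drop_ <- params$pH_ref - pH
  if (any(drop_ < 0) || any(drop_ >= params$eta))
    stop(sprintf("pH must lie in (%g, %g] to be invertible",
                 params$pH_ref - params$eta, params$pH_ref))
  params$kappa * drop_ / (params$eta - drop_)
}

lumenArms <- c("test", "control", "model", "untreated")

# Arm-effective enzyme levels: only the engineered (test) strain carries the
# circuit; BL21 keeps its native lacZ, so the test arm's beta-GAL adds the
# circuit product to the native baseline.
effectiveEnzymes <- function(regulators, arm, params) {
  if (!arm %in% lumenArms) stop("unknown arm label: ", arm)
  if (arm == "test")
    list(gal = params$Z_native + regulators[["beta_gal"]],
         ldh = regulators[["l_ldh"]])
  else list(gal = params$Z_native, ldh = 0)
}

#' Reaction fluxes in the lumen
#'
#' @param lumen named vector with `lactose`, `lactate`, `pyruvate`, `biomass`
#' @param regulators named regulator state (see [circuitRhs()])
#' @param arm one of `"test"`, `"control"`, `"model"`, `"untreated"`
#' @param params an [envParams()] list
#' @return named flux vector (mM/h): `hydrolysis`, `fermentation`,
#'   `ldh_oxidation`, `alkalinization`, `pyruvate_uptake`
#' @export
reactionFluxes <- function(lumen, regulators, arm, params) {
  enz <- effectiveEnzymes(regulators, arm, params)
  L <- lumen[["lactose"]]; A <- lumen[["lactate"]]
  P <- lumen[["pyruvate"]]; B <- lumen[["biomass"]]
  c(hydrolysis      = params$V_gal * enz$gal * B * L / (params$K_gal + L),
    fermentation    = params$V_ferm * B * L / (params$K_ferm + L),
    ldh_oxidation   = params$V_ldh * enz$ldh * B * A / (params$K_ldh + A),
    alkalinization  = params$k_alk * B,
    pyruvate_uptake = params$k_up * P * B)
}

#' Joint derivative of the coupled lumen + circuit system
#'
#' The circuit senses `(lactose, pH(lactate))`; the lumen consumes the circuit
#' enzymes. The lactate derivative is floored at zero lactate so base
#' production cannot drive the acid negative. Two bookkeeping states
#' (`cum_hydrolysis`, `cum_fermentation`) accumulate the consumed lactose.
#'
#' @inheritParams reactionFluxes
#' @param circuit a [circuitParams()] list
#' @return named derivative vector over
#'   `(lactose, lactate, pyruvate, biomass, regulators..., cum_*)`
#' @export
coupledRhs <- function(lumen, regulators, arm, params, circuit) {
  if (any(!is.finite(c(lumen, regulators)))) stop("non-finite joint state")
  lumen[] <- pmax(lumen, 0)   # guard vanishing-substrate integrator overshoot
  regulators[] <- pmax(regulators, 0)
  fl <- reactionFluxes(lumen, regulators, arm, params)
  A <- lumen[["lactate"]]
  dL <- -fl[["hydrolysis"]] - fl[["fermentation"]]
  # the alkalinization sink ramps off smoothly over the last ~1e-3 mM of
  # lactate so the A >= 0 floor is differentiable for the stiff integrator
  # (the LDH term already vanishes at A = 0 through its Michaelis factor)
  dA <- params$y_lac * fl[["fermentation"]] - fl[["ldh_oxidation"]] -
    fl[["alkalinization"]] * max(A, 0) / (max(A, 0) + 1e-3)
  if (A <= 0 && dA < 0) dA <- 0
  dP <- fl[["ldh_oxidation"]] - fl[["pyruvate_uptake"]]
  pH <- phFromLactate(max(A, 0), params)
  B <- lumen[["biomass"]]
  dB <- params$mu_max * exp(-(pH - params$pH_opt)^2 / (2 * params$sigma_pH^2)) *
    B * (1 - B / params$B_max)
  dreg <- circuitRhs(regulators, list(lactose = lumen[["lactose"]], pH = pH),
                     circuit)
  c(lactose = unname(dL), lactate = unname(dA), pyruvate = unname(dP),
    biomass = unname(dB), dreg,
    cum_hydrolysis = unname(fl[["hydrolysis"]]),
    cum_fermentation = unname(fl[["fermentation"]]))
}

#' Define a simulation scenario
#'
#' @param arm experimental arm; `"model"` and `"untreated"` exist only in
#'   vivo (no culture counterpart)
#' @param setting `"in_vitro"` or `"in_vivo"`
#' @param initial_pH starting pH; inverted to the starting lactate via
#'   [lactateFromPh()]
#' @param initial_lactose starting lactose (mM)
#' @param bolus data.frame with columns `time_h`, `lactose_mM`: instantaneous
#'   lactose additions
#' @param duration_h total simulated time (h, >= 0)
#' @param sampling_interval_h output spacing; must divide the duration
#' @param env_preset name of the [envParams()] preset used by default
#' @param preculture_pH pH at which the strain equilibrated before t = 0 (the
#'   circuit's initial state); defaults to 7 in vitro (neutral pre-culture)
#'   and to `initial_pH` in vivo (week-long colonization)
#' @param scenario_id label carried into outputs
#' @return validated list of class `Scenario`
#' @export
scenario <- function(arm, setting = c("in_vitro", "in_vivo"),
                     initial_pH, initial_lactose = 0,
                     bolus = NULL, duration_h = 12, sampling_interval_h = 0.5,
                     env_preset = NULL, preculture_pH = NULL,
                     scenario_id = NA_character_) {
  setting <- match.arg(setting)
  if (!arm %in% lumenArms) stop("unknown arm label: ", arm)
  if (setting == "in_vitro" && arm %in% c("model", "untreated"))
    stop("arms 'model' and 'untreated' exist only in vivo")
  assertScalarNumeric(duration_h, "duration_h", lower = 0)
  assertScalarNumeric(sampling_interval_h, "sampling_interval_h",
                      lower = 0, strict_lower = TRUE)
  if (duration_h > 0) {
    k <- duration_h / sampling_interval_h
    if (abs(k - round(k)) > 1e-8)
      stop("sampling_interval_h must divide duration_h")
  }
  assertScalarNumeric(initial_lactose, "initial_lactose", lower = 0)
  if (is.null(env_preset))
    env_preset <- if (setting == "in_vitro") "in_vitro" else "mouse_colon"
  if (is.null(preculture_pH))
    preculture_pH <- if (setting == "in_vitro") 7 else initial_pH
  if (!is.null(bolus)) {
    bolus <- as.data.frame(bolus)
    stopifnot(all(c("time_h", "lactose_mM") %in% names(bolus)))
  }
  structure(list(arm = arm, setting = setting, initial_pH = initial_pH,
                 initial_lactose = initial_lactose, bolus = bolus,
                 duration_h = duration_h,
                 sampling_interval_h = sampling_interval_h,
                 env_preset = env_preset, preculture_pH = preculture_pH,
                 scenario_id = scenario_id),
            class = "Scenario")
}

#' Load a shipped scenario preset
#'
#' Presets reproduce the study designs as simulations: the 12-h culture
#' experiment at three initial pH values (`pH_set_I`/`II`/`III`, 1% lactose,
#' arms `test`/`control`), the 6-h murine experiment
#' (`invivo_untreated`/`model`/`control`/`test`; the lactose gavage of 12 mg
#' per 20 g body weight maps to 87.6 mM over a 0.4 mL lumen volume), and a
#' 48-h neutral-colon lactose pulse (`human_pulse`) demonstrating the full
#' switch cycle.
#'
#' @param name preset name (file stem under `extdata/scenarios`)
#' @param arm arm to instantiate (defaults to the preset's first arm)
#' @return a [scenario()] object
#' @export
scenarioPreset <- function(name, arm = NULL) {
  path <- system.file("extdata", "scenarios", paste0(name, ".yaml"),
                      package = "lactoswitch")
  if (path == "") stop("unknown scenario preset: ", name)
  cfg <- yaml::read_yaml(path)
  if (is.null(arm)) arm <- cfg$arms[[1]]
  if (!arm %in% unlist(cfg$arms))
    stop("preset '", name, "' does not define arm '", arm, "'")
  bolus <- if (!is.null(cfg$bolus))
    data.frame(time_h = vapply(cfg$bolus, `[[`, 0, "time_h"),
               lactose_mM = vapply(cfg$bolus, `[[`, 0, "lactose_mM"))
  scenario(arm = arm, setting = cfg$setting, initial_pH = cfg$initial_pH,
           initial_lactose = cfg$initial_lactose %||% 0, bolus = bolus,
           duration_h = cfg$duration_h,
           sampling_interval_h = cfg$sampling_interval_h,
           env_preset = cfg$env_preset, preculture_pH = cfg$preculture_pH,
           scenario_id = paste(name, arm, sep = ":"))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Circuit state after long equilibration at constant signals; deterministic.
equilibratedCircuit <- function(lactose, pH, circuit, horizon = 400) {
  tr <- simulateCircuit(rep(0, 6), list(lactose = lactose, pH = pH),
                        circuit, c(0, horizon / 2, horizon))
  unlist(tr[nrow(tr), regulatorNames])
}

#' Run a scenario simulation
#'
#' Initial lactate is inverted from the initial pH; the circuit starts from
#' its equilibrated state at the pre-culture conditions; bolus events are
#' applied as instantaneous lactose increments; integration uses
#' `deSolve::lsoda` (rtol 1e-8, atol 1e-10).
#'
#' @param scn a [scenario()] or the name of a shipped preset
#' @param env an [envParams()] list (default: the preset named by the scenario)
#' @param circuit a [circuitParams()] list
#' @return data.frame of `(time_h, lactose, lactate, pyruvate, pH, biomass,
#'   regulators, beta_gal_eff, l_ldh_eff, cum_hydrolysis, cum_fermentation,
#'   arm, scenario_id)` at the sampling times
#' @examples
#' tr <- runScenario(scenarioPreset("invivo_untreated"))
#' range(tr$pH)
#' @export
runScenario <- function(scn, env = NULL, circuit = circuitParams()) {
  if (is.character(scn)) scn <- scenarioPreset(scn)
  stopifnot(inherits(scn, "Scenario"))
  if (is.null(env)) env <- envParams(scn$env_preset)
  A0 <- lactateFromPh(scn$initial_pH, env)
  regs0 <- equilibratedCircuit(0, scn$preculture_pH, circuit)
  y0 <- c(lactose = scn$initial_lactose, lactate = A0, pyruvate = 0,
          biomass = env$B0, regs0, cum_hydrolysis = 0, cum_fermentation = 0)
  times <- if (scn$duration_h == 0) 0 else
    seq(0, scn$duration_h, by = scn$sampling_interval_h)
  if (length(times) == 1L) {
    out <- as.data.frame(t(c(time_h = 0, y0)))
  } else {
    rhs <- function(t, y, parms)
      list(coupledRhs(y[1:4], y[regulatorNames], scn$arm, env, circuit))
    events <- NULL
    tms <- times
    if (!is.null(scn$bolus) && nrow(scn$bolus)) {
      events <- list(data = data.frame(
        var = "lactose", time = scn$bolus$time_h,
        value = scn$bolus$lactose_mM, method = "add"))
      tms <- sort(unique(c(times, scn$bolus$time_h)))
    }
    sol <- deSolve::lsoda(y0, tms, rhs, NULL, rtol = 1e-8, atol = 1e-10,
                          events = events)
    if (attr(sol, "istate")[1] < 0)
      stop("scenario integration failed to converge at the requested tolerance")
    out <- as.data.frame(sol)
    names(out)[1] <- "time_h"
    out <- out[out$time_h %in% times, , drop = FALSE]
    vals <- as.matrix(out[-1])
    if (any(!is.finite(vals))) stop("scenario integration produced non-finite values")
    if (any(vals < -1e-9))
      stop("scenario integration produced negative quantities beyond tolerance")
    out[-1] <- pmax(vals, 0)
  }
  out$pH <- phFromLactate(out$lactate, env)
  enzG <- if (scn$arm == "test") env$Z_native + out$beta_gal else
    rep(env$Z_native, nrow(out))
  enzL <- if (scn$arm == "test") out$l_ldh else rep(0, nrow(out))
  out$beta_gal_eff <- enzG
  out$l_ldh_eff <- enzL
  out$arm <- scn$arm
  out$scenario_id <- scn$scenario_id
  rownames(out) <- NULL
  out
}

#' Compare arms of a shared scenario
#'
#' @param trajectories named list of [runScenario()] outputs on the same time
#'   grid (names or `arm` columns identify the arms)
#' @return list with `differences` (per-time `test - control` and
#'   `model - untreated` differences of pH and effective enzymes, where both
#'   arms are present) and `trough` (per-arm pH trough time and depth)
#' @export
compareArms <- function(trajectories) {
  arms <- vapply(trajectories, function(d) d$arm[1], character(1))
  names(trajectories) <- arms
  tg <- trajectories[[1]]$time_h
  for (d in trajectories)
    if (!isTRUE(all.equal(d$time_h, tg)))
      stop("trajectories do not share a time grid")
  diffPair <- function(a, b) {
    if (!all(c(a, b) %in% arms)) return(NULL)
    da <- trajectories[[a]]; db <- trajectories[[b]]
    data.frame(time_h = tg, pair = paste0(a, "-", b),
               d_pH = da$pH - db$pH,
               d_beta_gal = da$beta_gal_eff - db$beta_gal_eff,
               d_l_ldh = da$l_ldh_eff - db$l_ldh_eff)
  }
  differences <- do.call(rbind, c(list(diffPair("test", "control")),
                                  list(diffPair("model", "untreated"))))
  trough <- do.call(rbind, lapply(arms, function(a) {
    d <- trajectories[[a]]
    i <- which.min(d$pH)
    data.frame(arm = a, trough_time_h = d$time_h[i],
               trough_depth = d$pH[1] - d$pH[i],
               max_abs_deviation = max(abs(d$pH - d$pH[1])))
  }))
  list(differences = differences, trough = trough)
}
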