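#' Dose events
#'
#' A dose event is one timed administration of a drug by a route.  Dose
#' lists are plain data frames so they can be built, concatenated and
#' serialized easily.
#'
#' @param t_dose Time of administration (min, >= 0).
#' @param drug `"fentanyl"`, `"carfentanil"` or `"naloxone"`.
#' @param route `"iv_bolus"` or `"intranasal"`.
#' @param amount Dose (mg, > 0).
#' @return A one-row data frame with columns `t_dose`, `drug`, `route`,
#'   `amount_mg`; combine with `rbind()`.
#' @export
dose_event <- function(t_dose, drug, route, amount) {
  drug <- match.arg(drug, c("fentanyl", "carfentanil", "naloxone"))
  route <- match.arg(route, c("iv_bolus", "intranasal"))
  stopifnot(t_dose >= 0, amount > 0)
  data.frame(t_dose = t_dose, drug = drug, route = route, amount_mg = amount)
}

#' Escalating intravenous naloxone protocol
#'
#' The stepped IV titration protocol used as the comparator dosing
#' strategy: 0.04 mg at 0 min, 0.5 mg at 2.5 min, 2 mg at 5 min and 4 mg
#' at 7.5 min (times relative to the first administration).
#'
#' @param n_steps Number of leading steps to keep (1-4); `n_steps = 2`
#'   gives the truncated variant (0.04 mg then 0.5 mg).
#' @return Data frame of [dose_event()] rows.
#' @export
boyer_iv_protocol <- function(n_steps = 4) {
  stopifnot(n_steps >= 1, n_steps <= 4)
  times <- c(0, 2.5, 5, 7.5)[seq_len(n_steps)]
  amounts <- c(0.04, 0.5, 2, 4)[seq_len(n_steps)]
  do.call(rbind, Map(function(t, a) dose_event(t, "naloxone", "iv_bolus", a),
                     times, amounts))
}

#' Pharmacokinetic parameter sets
#'
#' Two-compartment disposition for all three drugs; intranasal naloxone
#' adds first-order absorption (`ka`) with bioavailability `F`.  The
#' defaults are the package's typical-patient values: naloxone
#' disposition and absorption are set so a single 4-mg intranasal spray
#' peaks near 15 min at a few ng/mL, while fentanyl/carfentanil have the
#' rapid distribution typical of highly lipophilic synthetic opioids.
#' All values are configurable.
#'
#' @param drug `"fentanyl"`, `"carfentanil"` or `"naloxone"`.
#' @param route `"iv_bolus"` or `"intranasal"` (intranasal only for
#'   naloxone).
#' @param ... Overrides for any field (`V1`, `V2`, `CL`, `Q`, `ka`, `F`).
#' @return List of class `"pk_params"` with fields `drug`, `route`, `V1`,
#'   `V2` (L), `CL`, `Q` (L/min), `ka` (1/min), `F` (fraction).
#' @export
pk_params <- function(drug = c("fentanyl", "carfentanil", "naloxone"),
                      route = c("iv_bolus", "intranasal"), ...) {
  drug <- match.arg(drug)
  route <- match.arg(route)
  defaults <- switch(drug,
    fentanyl    = list(V1 = 13, V2 = 150, CL = 0.65, Q = 3.5, ka = NA, F = 1),
    carfentanil = list(V1 = 10, V2 = 120, CL = 0.50, Q = 3.0, ka = NA, F = 1),
    naloxone    = list(V1 = 25, V2 = 60, CL = 3.4, Q = 2.0,
                       ka = 0.02, F = 0.44))
  if (route == "intranasal" && drug != "naloxone") {
    stop("intranasal route is only parameterized for naloxone")
  }
  p <- utils::modifyList(defaults, list(...))
  if (route == "iv_bolus") { p$ka <- NA_real_; p$F <- 1 }
  with(p, stopifnot(V1 > 0, V2 > 0, CL > 0, Q > 0,
                    route == "iv_bolus" || (ka > 0 && F > 0 && F <= 1)))
  structure(c(list(drug = drug, route = route), p), class = "pk_params")
}

# Hybrid macro constants of the 2-compartment model.
.macro_2cmt <- function(pk) {
  k10 <- pk$CL / pk$V1; k12 <- pk$Q / pk$V1; k21 <- pk$Q / pk$V2
  s <- k10 + k12 + k21
  disc <- sqrt(s^2 - 4 * k10 * k21)
  list(alpha = (s + disc) / 2, beta = (s - disc) / 2, k21 = k21)
}

# Single unit-dose (1 mg) concentration curve, ng/mL, at times t >= 0.
.unit_conc <- function(pk, t) {
  m <- .macro_2cmt(pk)
  scale <- 1000 / pk$V1   # 1 mg in V1 litres -> ng/mL
  out <- numeric(length(t))
  pos <- t >= 0
  tt <- t[pos]
  if (pk$route == "iv_bolus") {
    A <- (m$alpha - m$k21) / (m$alpha - m$beta)
    B <- (m$k21 - m$beta) / (m$alpha - m$beta)
    out[pos] <- scale * (A * exp(-m$alpha * tt) + B * exp(-m$beta * tt))
  } else {
    ka <- pk$ka
    A <- (m$k21 - m$alpha) / ((ka - m$alpha) * (m$beta - m$alpha))
    B <- (m$k21 - m$beta) / ((ka - m$beta) * (m$alpha - m$beta))
    C <- (m$k21 - ka) / ((m$alpha - ka) * (m$beta - ka))
    out[pos] <- scale * pk$F * ka *
      (A * exp(-m$alpha * tt) + B * exp(-m$beta * tt) + C * exp(-ka * tt))
  }
  pmax(out, 0)
}

#' Plasma concentration under a dosing history
#'
#' Closed-form concentration of a linear two-compartment model (with
#' first-order absorption for the intranasal route) under superposition
#' over a list of dose events.  IV boluses are instantaneously maximal at
#' the dose time; intranasal doses start at zero and are unimodal.
#'
#' @param pk A [pk_params()] object.
#' @param doses Data frame of [dose_event()] rows; only rows whose
#'   `drug` matches `pk$drug` contribute.
#' @param t Times (min) at which to evaluate.
#' @return Concentrations (ng/mL) at `t`.
#' @export
plasma_concentration <- function(pk, doses, t) {
  stopifnot(inherits(pk, "pk_params"), all(t >= 0) || all(is.finite(t)))
  out <- numeric(length(t))
  if (is.null(doses) || nrow(doses) == 0) return(out)
  if (!all(doses$route %in% c("iv_bolus", "intranasal"))) {
    stop("unknown route in dose list")
  }
  doses <- doses[doses$drug == pk$drug & doses$route == pk$route, ,
                 drop = FALSE]
  for (i in seq_len(nrow(doses))) {
    out <- out + doses$amount_mg[i] * .unit_conc(pk, t - doses$t_dose[i])
  }
  out
}

#' Time and value of the maximal concentration
#'
#' @param pk A [pk_params()] object.
#' @param doses Dose events.
#' @param window Search window (min).
#' @param dt Grid resolution (min).
#' @return List with `tmax` (min) and `cmax` (ng/mL).
#' @export
pk_tmax <- function(pk, doses, window = c(0, 240), dt = 0.05) {
  grid <- seq(window[1], window[2], by = dt)
  cp <- plasma_concentration(pk, doses, grid)
  i <- which.max(cp)
  list(tmax = grid[i], cmax = cp[i])
}

#' Effect-site concentration from a plasma time series
#'
#' First-order plasma/effect-site equilibration `dCe/dt = ke0 (Cp - Ce)`
#' with `Ce(0) = 0`, solved exactly on the sampling grid assuming linear
#' interpolation of `Cp` between samples.  As `ke0` grows the effect
#' site tracks plasma.
#'
#' @param time Sampling times (min), increasing.
#' @param cp Plasma concentrations at `time`.
#' @param ke0 Equilibration rate (1/min, > 0).
#' @return Effect-site concentrations at `time` (same units as `cp`).
#' @export
effect_site_concentration <- function(time, cp, ke0) {
  stopifnot(ke0 > 0, length(time) == length(cp), !is.unsorted(time))
  ce <- numeric(length(cp))
  for (i in seq_along(cp)[-1]) {
    dt <- time[i] - time[i - 1]
    if (dt == 0) { ce[i] <- ce[i - 1]; next }
    slope <- (cp[i] - cp[i - 1]) / dt
    e <- exp(-ke0 * dt)
    ce[i] <- ce[i - 1] * e + cp[i - 1] * (1 - e) +
      slope * (dt - (1 - e) / ke0)
  }
  ce
}

#' Receptor binding parameter sets
#'
#' Association/dissociation rate constants at the mu-opioid receptor,
#' plasma-to-effect-site equilibration rate, and molecular weight for
#' mass-to-molar conversion.  Defaults encode the potency hierarchy
#' (carfentanil >> fentanyl ~ naloxone on affinity) and carfentanil's
#' characteristically slow dissociation; `Kd = koff/kon`.
#'
#' @param drug Drug name.
#' @param ... Overrides (`kon` 1/(nM min), `koff` 1/min, `ke0` 1/min,
#'   `mw` g/mol).
#' @return List of class `"binding_params"` with a derived `Kd` (nM).
#' @export
binding_params <- function(drug = c("fentanyl", "carfentanil", "naloxone"),
                           ...) {
  drug <- match.arg(drug)
  defaults <- switch(drug,
    fentanyl    = list(kon = 0.25 / 1.8, koff = 0.25, ke0 = 0.15, mw = 336.5),
    carfentanil = list(kon = 0.03 / 0.009, koff = 0.03, ke0 = 0.10, mw = 394.5),
    naloxone    = list(kon = 0.5 / 1.1, koff = 0.5, ke0 = 0.25, mw = 327.4))
  p <- utils::modifyList(defaults, list(...))
  with(p, stopifnot(kon > 0, koff > 0, ke0 > 0, mw > 0))
  p$Kd <- p$koff / p$kon
  structure(c(list(drug = drug), p), class = "binding_params")
}

#' Convert ng/mL to nM
#'
#' @param conc_ng_ml Concentration in ng/mL.
#' @param mw Molecular weight (g/mol).
#' @return Concentration in nmol/L.
#' @export
ng_ml_to_nM <- function(conc_ng_ml, mw) conc_ng_ml * 1000 / mw

#' Competitive receptor-occupancy kinetics
#'
#' Time derivatives of fractional mu-opioid receptor occupancy by an
#' agonist (`Ra`) and by naloxone (`Rn`) under competitive binding to a
#' single site:
#' `dRa/dt = kon_a Ca (1 - Ra - Rn) - koff_a Ra` and symmetrically for
#' `Rn`.  Integration preserves `Ra, Rn >= 0`, `Ra + Rn <= 1` for any
#' nonnegative concentration inputs.
#'
#' @param occ Numeric vector `c(Ra, Rn)`.
#' @param ce_agonist,ce_naloxone Effect-site concentrations (nM).
#' @param bp_agonist,bp_naloxone [binding_params()] objects.
#' @return Numeric vector `c(dRa, dRn)` (1/min).
#' @export
binding_derivatives <- function(occ, ce_agonist, ce_naloxone,
                                bp_agonist, bp_naloxone) {
  free <- 1 - occ[1] - occ[2]
  c(bp_agonist$kon * ce_agonist * free - bp_agonist$koff * occ[1],
    bp_naloxone$kon * ce_naloxone * free - bp_naloxone$koff * occ[2])
}

#' Equilibrium competitive occupancy
#'
#' Closed-form steady state of [binding_derivatives()] under constant
#' concentrations: `Ra = (Ca/Kda) / (1 + Ca/Kda + Cn/Kdn)` and
#' symmetrically for `Rn`.
#'
#' @inheritParams binding_derivatives
#' @return Named vector `c(Ra, Rn)`.
#' @export
equilibrium_occupancy <- function(ce_agonist, ce_naloxone,
                                  bp_agonist, bp_naloxone) {
  ra <- ce_agonist / bp_agonist$Kd
  rn <- ce_naloxone / bp_naloxone$Kd
  c(Ra = ra / (1 + ra + rn), Rn = rn / (1 + ra + rn))
}

#' Occupancy-to-ventilatory-depression map
#'
#' Maps agonist receptor occupancy to the multiplicative depression of
#' chemical ventilatory drive: 1 at zero occupancy (no opioid effect)
#' down to a configurable floor at full occupancy.  The default map is
#' linear, `1 - (1 - floor) * Ra`; an Emax form
#' `1 - (1 - floor) * Ra^gamma / (Ra^gamma + R50^gamma) * (1 + R50^gamma)`
#' normalised to reach the floor at `Ra = 1` is selectable.
#'
#' @param Ra Agonist occupancy in \[0, 1\].
#' @param pd A [pd_map()] parameter list.
#' @return Depression multiplier in \[floor, 1\], nonincreasing in `Ra`.
#' @export
ventilation_depression <- function(Ra, pd = pd_map()) {
  stopifnot(all(Ra >= 0 & Ra <= 1))
  eff <- if (pd$form == "linear") {
    Ra
  } else {
    (Ra^pd$gamma / (Ra^pd$gamma + pd$r50^pd$gamma)) * (1 + pd$r50^pd$gamma)
  }
  pd$floor + (1 - pd$floor) * (1 - eff)
}

#' Pharmacodynamic map parameters
#'
#' @param form `"linear"` (default) or `"emax"`.
#' @param floor Residual drive fraction at full occupancy (default 0:
#'   apnea is possible).
#' @param r50,gamma Emax-form parameters (ignored for linear).
#' @return List of class `"pd_map"`.
#' @export
pd_map <- function(form = c("linear", "emax"), floor = 0,
                   r50 = 0.5, gamma = 2) {
  form <- match.arg(form)
  stopifnot(floor >= 0, floor < 1, r50 > 0, gamma > 0)
  structure(list(form = form, floor = floor, r50 = r50, gamma = gamma),
            class = "pd_map")
}
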