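#' Naloxone dosing strategy
#'
#' A ventilation-triggered dosing template: the first administration
#' occurs `delay` minutes after minute ventilation first falls below the
#' trigger fraction of its baseline, and subsequent administrations
#' follow at the listed relative times.  An explicit dose-event table
#' (e.g. [boyer_iv_protocol()]) can override the template.
#'
#' @param sprays Sprays (or boluses) per administration time (>= 0; 0
#'   with empty `times` is the no-naloxone strategy).
#' @param times Administration times (min) relative to the first
#'   administration; strictly increasing, starting at 0.
#' @param route `"intranasal"` or `"iv"`.
#' @param spray_mg Amount per spray/bolus (mg; default 4, one nasal
#'   spray).
#' @param delay Minutes between the ventilation trigger and the first
#'   administration (default 1).
#' @param events Optional explicit data frame of [dose_event()] rows
#'   whose `t_dose` is relative to the first administration; overrides
#'   `sprays`/`times`/`spray_mg`.
#' @param name Label used in results tables.
#' @return List of class `"dosing_strategy"`.
#' @export
dosing_strategy <- function(sprays = 1, times = 0, route = c("intranasal", "iv"),
                            spray_mg = 4, delay = 1, events = NULL,
                            name = NULL) {
  route <- match.arg(route)
  stopifnot(sprays >= 0, delay >= 0, spray_mg > 0)
  if (length(times) > 1 && any(diff(times) <= 0)) {
    stop("administration times must be strictly increasing")
  }
  if (is.null(name)) {
    name <- if (!is.null(events)) "custom" else if (sprays == 0) "none" else
      sprintf("%s%d@%s", if (route == "intranasal") "IN" else "IV",
              sprays, paste(times, collapse = ","))
  }
  structure(list(sprays = sprays, times = times, route = route,
                 spray_mg = spray_mg, delay = delay, events = events,
                 name = name),
            class = "dosing_strategy")
}

#' Standard dosing strategies of the overdose experiment grid
#'
#' The six intranasal strategies of the outcome table (no naloxone; 1
#' spray at 0; 1 spray at 0 and 2.5; 1 spray at 0, 2.5, 5 and 7.5; 2
#' sprays at 0; 2 sprays at 0 and 2.5 -- all 4 mg per spray) plus the
#' escalating IV protocol.
#'
#' @return Named list of [dosing_strategy()] objects.
#' @export
standard_strategies <- function() {
  list(
    none        = dosing_strategy(0, numeric(0), name = "none"),
    in1_x1      = dosing_strategy(1, 0, name = "1 at 0"),
    in1_q2.5x2  = dosing_strategy(1, c(0, 2.5), name = "1 at 0,2.5"),
    in1_q2.5x4  = dosing_strategy(1, c(0, 2.5, 5, 7.5),
                                  name = "1 at 0,2.5,5,7.5"),
    in2_x1      = dosing_strategy(2, 0, name = "2 at 0"),
    in2_q2.5x2  = dosing_strategy(2, c(0, 2.5), name = "2 at 0,2.5"),
    boyer_iv    = dosing_strategy(route = "iv",
                                  events = boyer_iv_protocol(),
                                  name = "IV escalation"))
}

# Naloxone dose events (absolute time) implied by a strategy triggered
# at t_trigger; returns a deSolve events data frame (state additions).
.strategy_events <- function(strategy, t_trigger, patient, horizon) {
  t0 <- t_trigger + strategy$delay
  if (!is.null(strategy$events)) {
    ev <- strategy$events
    abs_t <- t0 + ev$t_dose
    routes <- ev$route
    amounts <- ev$amount_mg
  } else {
    if (strategy$sprays == 0 || !length(strategy$times)) return(NULL)
    abs_t <- t0 + strategy$times
    routes <- rep(if (strategy$route == "intranasal") "intranasal"
                  else "iv_bolus", length(abs_t))
    amounts <- rep(strategy$sprays * strategy$spray_mg, length(abs_t))
  }
  keep <- abs_t <= horizon
  if (!any(keep)) return(NULL)
  abs_t <- abs_t[keep]; routes <- routes[keep]; amounts <- amounts[keep]
  nasal <- routes == "intranasal"
  data.frame(
    var = ifelse(nasal, "And", "An1"),
    time = abs_t,
    value = ifelse(nasal, patient$pk$naloxone_in$F * amounts, amounts),
    method = "add")
}

.state_names <- c("Af1", "Af2", "Cef", "And", "An1", "An2", "Cen",
                  "Ra", "Rn", "pA_O2", "pA_CO2", "pt_O2", "pt_CO2",
                  "pbr_O2", "pbr_CO2", "VE", "CO")

.lsoda_overdose <- function(y, times, parms, events = NULL, root = FALSE) {
  args <- list(y = y, times = times, func = "overdose_derivs",
               parms = parms, dllname = "naloxsim",
               initfunc = "overdose_init", rtol = 1e-6, atol = 1e-8,
               maxsteps = 50000)
  if (root) { args$rootfunc <- "overdose_root"; args$nroot <- 1L }
  if (!is.null(events)) args$events <- list(data = events)
  out <- do.call(deSolve::lsoda, args)
  if (attr(out, "istate")[1] < 0) {
    stop("ODE solver failure (istate ", attr(out, "istate")[1], ")")
  }
  out
}

# Phase 1: drug-free-of-naloxone integration up to the ventilation
# trigger (or the horizon).  Shared by all strategies for one
# patient/opioid-dose combination.
.phase1 <- function(patient, drug, dose_mg, horizon, dt, trig_frac) {
  parms <- .overdose_parms(patient, agonist = drug, trig_frac = trig_frac)
  y0 <- setNames(numeric(17), .state_names)
  y0[names(patient$physio$baseline)] <- patient$physio$baseline
  y0["Af1"] <- dose_mg
  times <- seq(0, horizon, by = dt)
  out <- .lsoda_overdose(y0, times, parms, root = TRUE)
  troot <- attr(out, "troot")
  t_trigger <- if (length(troot) && is.finite(troot[1])) troot[1] else NA_real_
  list(out = out, t_trigger = t_trigger, parms = parms)
}

# Phase 2: continue from the trigger with naloxone events (or none).
.phase2 <- function(ph1, events, horizon, dt) {
  y1 <- ph1$out[nrow(ph1$out), -1]
  y1 <- setNames(as.numeric(y1), .state_names)
  t1 <- ph1$out[nrow(ph1$out), 1]
  times <- sort(c(seq(t1, horizon, by = dt), horizon,
                  if (!is.null(events)) events$time))
  times <- times[c(TRUE, diff(times) > 1e-7)]
  if (length(times) < 2) return(ph1$out)
  if (!is.null(events)) {
    # event times must coincide exactly with output times
    events$time <- times[vapply(events$time, function(tt)
      which.min(abs(times - tt)), integer(1))]
  }
  out <- .lsoda_overdose(y1, times, ph1$parms, events = events)
  rbind(ph1$out[-nrow(ph1$out), , drop = FALSE], out)
}

.finish_sim <- function(patient, drug, dose_mg, strategy, mat, t_trigger,
                        horizon, threshold = 20) {
  traj <- as.data.frame(mat)
  names(traj)[1] <- "t"
  det <- detect_cardiac_arrest(traj, patient$physio)
  if (det$arrest) {
    keep <- traj$t <= det$t_arrest + 1e-9
    if (any(!keep)) {
      # close the trajectory with the interpolated arrest state
      i <- which(!keep)[1]
      w <- (det$t_arrest - traj$t[i - 1]) / (traj$t[i] - traj$t[i - 1])
      cross <- traj[i - 1, ] * (1 - w) + traj[i, ] * w
      traj <- rbind(traj[keep, , drop = FALSE], cross)
    } else {
      traj <- traj[keep, , drop = FALSE]
    }
  }
  traj$pa_O2 <- traj$pA_O2
  traj$pa_CO2 <- traj$pA_CO2
  traj$SaO2 <- oxygen_saturation(pmax(traj$pA_O2, 0), patient$physio)
  traj$Qbr <- patient$physio$qbr_frac * traj$CO
  traj$Cp_agonist <- traj$Af1 * 1000 / patient$pk[[drug]]$V1
  traj$Cp_naloxone <- traj$An1 * 1000 / patient$pk$naloxone_iv$V1
  traj$depression <- ventilation_depression(pmin(pmax(traj$Ra, 0), 1),
                                            patient$pd)
  ht <- brain_hypoxia_time(traj, threshold = threshold, horizon = horizon,
                           arrest = det$arrest)
  structure(list(trajectory = traj, t_trigger = t_trigger,
                 arrest = det$arrest, t_arrest = det$t_arrest,
                 brain_hypoxia_time = ht,
                 scenario = list(drug = drug, dose_mg = dose_mg,
                                 strategy = strategy$name,
                                 delay = strategy$delay, horizon = horizon),
                 patient_id = patient$id),
            class = "overdose_sim")
}

#' Simulate one overdose-and-rescue scenario
#'
#' Integrates the coupled physiology + pharmacokinetic + receptor
#' binding system for one virtual patient: an IV opioid bolus at time 0,
#' ventilation-triggered naloxone per the dosing strategy (first dose
#' `strategy$delay` min after ventilation first falls below
#' `trig_frac` of the patient's baseline; if ventilation never crosses,
#' no naloxone is given), and extraction of the outcome measures.
#'
#' @param patient A [virtual_patient()].
#' @param opioid Either a [dose_event()] data frame (single IV bolus at
#'   t = 0) or a list with elements `drug` and `amount_mg`; `amount_mg`
#'   0 simulates the drug-free patient.
#' @param strategy A [dosing_strategy()].
#' @param horizon Simulation horizon (min; default 60, the acute
#'   recovery window).
#' @param dt Output grid step (min).
#' @param trig_frac Ventilation trigger as a fraction of baseline
#'   (default 0.4).
#' @param hypoxia_threshold Brain O2 threshold (mmHg) for the
#'   brain-hypoxia-time outcome.
#'
#' @return Object of class `"overdose_sim"`: `trajectory` (data frame:
#'   `t`, all model states, `pa_O2`, `SaO2`, `Qbr`, plasma
#'   concentrations, `depression`), `t_trigger`, `arrest`, `t_arrest`,
#'   `brain_hypoxia_time` (min; `Inf` on arrest or non-recovery), and a
#'   `scenario` echo.
#' @export
simulate_overdose <- function(patient, opioid, strategy = dosing_strategy(),
                              horizon = 60, dt = 0.1, trig_frac = 0.4,
                              hypoxia_threshold = 20) {
  if (is.data.frame(opioid)) {
    stopifnot(nrow(opioid) == 1, opioid$route == "iv_bolus",
              opioid$t_dose == 0)
    drug <- opioid$drug; dose_mg <- opioid$amount_mg
  } else {
    drug <- opioid$drug; dose_mg <- opioid$amount_mg
  }
  drug <- match.arg(drug, c("fentanyl", "carfentanil"))
  stopifnot(dose_mg >= 0, horizon > 0)
  ph1 <- .phase1(patient, drug, dose_mg, horizon, dt, trig_frac)
  if (is.na(ph1$t_trigger)) {
    mat <- ph1$out
  } else {
    ev <- .strategy_events(strategy, ph1$t_trigger, patient, horizon)
    mat <- .phase2(ph1, ev, horizon, dt)
  }
  .finish_sim(patient, drug, dose_mg, strategy, mat, ph1$t_trigger,
              horizon, hypoxia_threshold)
}

# All strategies for one patient/opioid dose, reusing the phase-1
# integration (the pre-trigger trajectory is strategy-independent).
.simulate_multi <- function(patient, drug, dose_mg, strategies, horizon = 60,
                            dt = 0.1, trig_frac = 0.4, threshold = 20) {
  ph1 <- .phase1(patient, drug, dose_mg, horizon, dt, trig_frac)
  lapply(strategies, function(s) {
    if (is.na(ph1$t_trigger)) {
      mat <- ph1$out
    } else {
      ev <- .strategy_events(s, ph1$t_trigger, patient, horizon)
      mat <- .phase2(ph1, ev, horizon, dt)
    }
    sim <- .finish_sim(patient, drug, dose_mg, s, mat, ph1$t_trigger,
                       horizon, threshold)
    list(arrest = sim$arrest, t_arrest = sim$t_arrest,
         brain_hypoxia_time = sim$brain_hypoxia_time,
         t_trigger = sim$t_trigger)
  })
}

#' @export
print.overdose_sim <- function(x, ...) {
  s <- x$scenario
  cat(sprintf("Overdose simulation: %s %.3g mg IV, strategy '%s' (delay %g min)\n",
              s$drug, s$dose_mg, s$strategy, s$delay))
  cat(sprintf("  ventilation trigger at %s min\n",
              if (is.na(x$t_trigger)) "never" else sprintf("%.2f", x$t_trigger)))
  cat(sprintf("  cardiac arrest: %s%s\n", x$arrest,
              if (x$arrest) sprintf(" (t = %.2f min)", x$t_arrest) else ""))
  cat(sprintf("  brain hypoxia time (<20 mmHg): %s min\n",
              if (is.infinite(x$brain_hypoxia_time)) "Inf"
              else sprintf("%.2f", x$brain_hypoxia_time)))
  invisible(x)
}

#' @export
plot.overdose_sim <- function(x, vars = c("VE", "SaO2", "pbr_O2", "CO"), ...) {
  tr <- x$trajectory
  old <- graphics::par(mfrow = c(length(vars), 1), mar = c(3, 4, 1, 1))
  on.exit(graphics::par(old))
  for (v in vars) {
    graphics::plot(tr$t, tr[[v]], type = "l", xlab = "time (min)",
                   ylab = v, ...)
  }
  invisible(x)
}

#' Brain-hypoxia time of a trajectory
#'
#' Total time (min) the brain-tissue oxygen partial pressure spends
#' below the threshold, measured with linear interpolation at the
#' crossings.  Returns `Inf` when the patient arrests or when the
#' trajectory has not recovered above threshold by the horizon end.
#'
#' @param trajectory Data frame with columns `t` and `pbr_O2`.
#' @param threshold Threshold (mmHg; default 20).
#' @param horizon Horizon (min); default the trajectory end.
#' @param arrest Whether the trajectory terminated in cardiac arrest.
#' @return Extended-real time in minutes (`Inf` allowed).
#' @export
brain_hypoxia_time <- function(trajectory, threshold = 20, horizon = NULL,
                               arrest = FALSE) {
  if (is.null(trajectory) || nrow(trajectory) == 0) stop("empty trajectory")
  if (arrest) return(Inf)
  t <- trajectory$t; x <- trajectory$pbr_O2
  n <- length(t)
  if (is.null(horizon)) horizon <- t[n]
  if (x[n] < threshold || t[n] < horizon - 1e-6) return(Inf)
  if (n == 1) return(0)
  x1 <- x[-n]; x2 <- x[-1]; dt <- diff(t)
  lo <- pmin(x1, x2); hi <- pmax(x1, x2)
  frac <- ifelse(hi < threshold, 1,
                 ifelse(lo >= threshold, 0,
                        (threshold - lo) / pmax(hi - lo, 1e-12)))
  sum(dt * frac)
}

#' Minimum opioid dose producing cardiac arrest
#'
#' Bisection on the (monotone) dose-arrest relation for one patient with
#' no naloxone: the smallest IV bolus dose whose simulation ends in
#' cardiac arrest, to within `tol` mg.
#'
#' @param patient A [virtual_patient()].
#' @param drug `"fentanyl"` or `"carfentanil"`.
#' @param tol Bracket width (mg) at which bisection stops.
#' @param d_max Upper search bound (mg); an error is raised if even
#'   `d_max` does not produce arrest.
#' @param horizon Simulation horizon (min).
#' @return Dose in mg.
#' @export
min_arrest_dose <- function(patient, drug = c("fentanyl", "carfentanil"),
                            tol = 1e-3, d_max = 50, horizon = 60) {
  drug <- match.arg(drug)
  none <- dosing_strategy(0, numeric(0), name = "none")
  arrests <- function(d) {
    simulate_overdose(patient, list(drug = drug, amount_mg = d),
                      strategy = none, horizon = horizon)$arrest
  }
  if (!arrests(d_max)) {
    stop(sprintf("no arrest for %s up to %g mg (bracket [0, %g])",
                 drug, d_max, d_max))
  }
  lo <- 0; hi <- d_max
  while (hi - lo > tol) {
    mid <- (lo + hi) / 2
    if (arrests(mid)) hi <- mid else lo <- mid
  }
  hi
}
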