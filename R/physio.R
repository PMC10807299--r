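#' Cardiorespiratory model parameters
#'
#' Constants of the lumped cardiorespiratory model: gas stores, blood gas
#' dissociation, metabolism, chemoreflex ventilatory control and
#' hypoxia-driven cardiovascular decompensation.  The chemoreflex gains
#' and thresholds are calibrated at construction so that the analytic
#' baseline (fixed `VE0`, `CO0`, Fick/alveolar balances) is an exact
#' fixed point of [physio_derivatives()] with no opioid effect.
#'
#' Units: pressures mmHg, flows and ventilation L/min, gas stores and
#' capacitances L and L/mmHg (gas volumes STPD), metabolic rates L/min.
#'
#' @param VE0 Baseline minute ventilation (L/min).
#' @param CO0 Baseline cardiac output (L/min).
#' @param fA Alveolar (non-dead-space) fraction of ventilation.
#' @param PI_O2 Inspired oxygen partial pressure (mmHg).
#' @param VL_O2,VL_CO2 Effective lung gas storage volumes (L).
#' @param beta_t_O2,beta_t_CO2,beta_br_O2,beta_br_CO2 Tissue and brain
#'   gas storage capacitances (L STPD per mmHg).
#' @param hb_cap Hemoglobin oxygen capacity (L O2 / L blood).
#' @param sol_O2 Dissolved O2 solubility (L/L/mmHg).
#' @param p50 Hemoglobin P50 (mmHg).
#' @param hill_n Hill coefficient of the O2 dissociation curve.
#' @param co2_slope,co2_int Linearized CO2 dissociation (L/L/mmHg, L/L).
#' @param MO2 Total O2 consumption (L/min); `MO2_br` is the brain share.
#' @param VCO2 Total CO2 production (L/min); `VCO2_br` the brain share.
#' @param MO2_br,VCO2_br Brain metabolic rates (L/min).
#' @param qbr_frac Brain fraction of cardiac output.
#' @param central_share Fraction of baseline drive from the central
#'   chemoreceptor.
#' @param delta_c,delta_p Baseline distance (mmHg) of brain and arterial
#'   CO2 above the central/peripheral thresholds; sets the gains.
#' @param hvr_amp,hvr_p0,hvr_tau Hypoxic amplification of the peripheral
#'   drive: factor `1 + hvr_amp * exp(-(paO2 - hvr_p0)/hvr_tau)`.
#' @param ve_floor Drug-independent residual ventilation (L/min).
#' @param tau_VE,tau_CO First-order time constants (min) of ventilation
#'   and cardiac output toward their control targets.
#' @param p_crit Arterial O2 threshold (mmHg) below which the cardiac
#'   output target collapses (hypoxic decompensation).
#' @param w_width Smoothing width (mmHg) of the decompensation switch.
#' @param tau_dec Decompensation time constant (min); CO decays toward 0
#'   with this constant under deep hypoxia.
#' @param arrest_frac Cardiac arrest threshold as a fraction of `CO0`.
#' @param p_m Partial pressure (mmHg) below which local metabolism is
#'   linearly reduced (prevents negative gas stores).
#' @param ... Ignored (future extensions).
#'
#' @return List of class `"physio_params"`; includes calibrated gains
#'   (`Gc`, `Bc`, `Gp`, `Bp`) and the analytic `baseline` state.
#' @export
physio_params <- function(VE0 = 6, CO0 = 5.5, fA = 0.7, PI_O2 = 150,
                          VL_O2 = 2.5, VL_CO2 = 3.2,
                          beta_t_O2 = 0.006, beta_t_CO2 = 0.06,
                          beta_br_O2 = 0.001, beta_br_CO2 = 0.003,
                          hb_cap = 0.197, sol_O2 = 3e-5,
                          p50 = 26.8, hill_n = 2.7,
                          co2_slope = 0.005, co2_int = 0.32,
                          MO2 = 0.24, MO2_br = 0.045,
                          VCO2 = 0.195, VCO2_br = 0.038,
                          qbr_frac = 0.136,
                          central_share = 0.75, delta_c = 3, delta_p = 5,
                          hvr_amp = 5, hvr_p0 = 30, hvr_tau = 20,
                          ve_floor = 0, tau_VE = 0.5, tau_CO = 0.5,
                          p_crit = 30, w_width = 0.5, tau_dec = 4,
                          arrest_frac = 0.3, p_m = 5, ...) {
  p <- list(VE0 = VE0, CO0 = CO0, fA = fA, PI_O2 = PI_O2,
            VL_O2 = VL_O2, VL_CO2 = VL_CO2,
            beta_t_O2 = beta_t_O2, beta_t_CO2 = beta_t_CO2,
            beta_br_O2 = beta_br_O2, beta_br_CO2 = beta_br_CO2,
            hb_cap = hb_cap, sol_O2 = sol_O2, p50 = p50, hill_n = hill_n,
            co2_slope = co2_slope, co2_int = co2_int,
            MO2 = MO2, MO2_br = MO2_br, VCO2 = VCO2, VCO2_br = VCO2_br,
            qbr_frac = qbr_frac, central_share = central_share,
            hvr_amp = hvr_amp, hvr_p0 = hvr_p0, hvr_tau = hvr_tau,
            ve_floor = ve_floor, tau_VE = tau_VE, tau_CO = tau_CO,
            p_crit = p_crit, w_width = w_width, tau_dec = tau_dec,
            arrest_frac = arrest_frac, p_m = p_m)
  stopifnot(VE0 > 0, CO0 > 0, fA > 0, fA <= 1, p50 > 0, hill_n > 0,
            arrest_frac > 0, arrest_frac < 1, qbr_frac > 0, qbr_frac < 1,
            MO2 > MO2_br, VCO2 > VCO2_br,
            all(unlist(p[c("VL_O2", "VL_CO2", "beta_t_O2", "beta_t_CO2",
                           "beta_br_O2", "beta_br_CO2", "tau_VE", "tau_CO",
                           "tau_dec")]) > 0))
  class(p) <- "physio_params"

  # analytic baseline at fixed VE0, CO0 -------------------------------
  VA0 <- fA * VE0
  pA_O2b <- PI_O2 - 863 * MO2 / VA0
  pA_CO2b <- 863 * VCO2 / VA0
  if (pA_O2b <= 0 || pA_CO2b <= 0) {
    stop("configuration gives nonpositive baseline alveolar pressures")
  }
  Qbr0 <- qbr_frac * CO0
  Qt0 <- CO0 - Qbr0
  CaO2 <- o2_content(pA_O2b, p)
  pt_O2b <- .invert_o2_content(CaO2 - (MO2 - MO2_br) / Qt0, p)
  pbr_O2b <- .invert_o2_content(CaO2 - MO2_br / Qbr0, p)
  pt_CO2b <- pA_CO2b + (VCO2 - VCO2_br) / (Qt0 * co2_slope)
  pbr_CO2b <- pA_CO2b + VCO2_br / (Qbr0 * co2_slope)

  # calibrate chemoreflex so drive(baseline) = VE0 exactly ------------
  p$Bc <- pbr_CO2b - delta_c
  p$Bp <- pA_CO2b - delta_p
  p$Gc <- central_share * VE0 / delta_c
  fb <- 1 + hvr_amp * exp(-(pA_O2b - hvr_p0) / hvr_tau)
  p$Gp <- (1 - central_share) * VE0 / (delta_p * fb)

  p$baseline <- c(pA_O2 = pA_O2b, pA_CO2 = pA_CO2b,
                  pt_O2 = pt_O2b, pt_CO2 = pt_CO2b,
                  pbr_O2 = pbr_O2b, pbr_CO2 = pbr_CO2b,
                  VE = VE0, CO = CO0)
  p
}

#' Hemoglobin oxygen saturation (Hill curve)
#'
#' @param pO2 Oxygen partial pressure (mmHg, >= 0).
#' @param params A [physio_params()] object (uses `p50`, `hill_n`).
#' @return Saturation fraction in \[0, 1\], monotone in `pO2`.
#' @export
oxygen_saturation <- function(pO2, params) {
  if (any(pO2 < 0)) stop("negative oxygen partial pressure")
  x <- (pO2 / params$p50)^params$hill_n
  x / (1 + x)
}

#' Blood oxygen content
#'
#' Hemoglobin-bound plus dissolved O2, L O2 (STPD) per L blood.
#' @inheritParams oxygen_saturation
#' @export
o2_content <- function(pO2, params) {
  pO2 <- pmax(pO2, 0)
  params$hb_cap * oxygen_saturation(pO2, params) + params$sol_O2 * pO2
}

#' Blood carbon dioxide content (linearized)
#' @param pCO2 CO2 partial pressure (mmHg).
#' @inheritParams oxygen_saturation
#' @export
co2_content <- function(pCO2, params) {
  params$co2_slope * pmax(pCO2, 0) + params$co2_int
}

.invert_o2_content <- function(content, params) {
  stopifnot(content > 0, content < o2_content(700, params))
  uniroot(function(p) o2_content(p, params) - content,
          interval = c(0, 700), tol = 1e-10)$root
}

#' Chemoreflex ventilatory drive
#'
#' Target minute ventilation: the sum of a central drive (brain CO2) and
#' a peripheral drive (arterial CO2, amplified under hypoxemia), scaled
#' by the opioid depression multiplier and floored at the residual
#' ventilation.  At the constructed baseline with `depression = 1` the
#' target equals `VE0` exactly.
#'
#' @param state Named state vector (uses `pA_O2`, `pA_CO2`, `pbr_CO2`;
#'   arterial pressures equal alveolar in this lumped model).
#' @param params A [physio_params()] object.
#' @param depression Multiplier in \[0, 1\] from
#'   [ventilation_depression()]; 1 = no opioid effect.
#' @return Target ventilation (L/min, >= 0).
#' @export
ventilatory_drive <- function(state, params, depression = 1) {
  stopifnot(depression >= 0, depression <= 1)
  pa_O2 <- state[["pA_O2"]]; pa_CO2 <- state[["pA_CO2"]]
  central <- params$Gc * max(state[["pbr_CO2"]] - params$Bc, 0)
  hyp <- 1 + params$hvr_amp * exp(-(pa_O2 - params$hvr_p0) / params$hvr_tau)
  peripheral <- params$Gp * max(pa_CO2 - params$Bp, 0) * hyp
  max(depression * (central + peripheral), params$ve_floor)
}

# metabolic down-regulation below p_m mmHg (linear shutoff; exact above)
.metab_scale <- function(p, p_m) pmin(pmax(p, 0) / p_m, 1)

#' Time derivatives of the cardiorespiratory state
#'
#' Mass balances for alveolar, non-brain tissue and brain O2/CO2 stores
#' (circulatory transport by cardiac output with a fixed brain flow
#' fraction; venous blood equilibrated with its tissue store; constant
#' metabolism, linearly down-regulated only at near-zero partial
#' pressures), with ventilation and cardiac output relaxing first-order
#' toward their control targets.  Below `p_crit` arterial O2 the cardiac
#' output target collapses toward zero with time constant `tau_dec`
#' (progressive hypoxic decompensation); the switch is a smooth logistic
#' in `pa_O2` of width `w_width`.
#'
#' @param state Named vector with elements `pA_O2`, `pA_CO2`, `pt_O2`,
#'   `pt_CO2`, `pbr_O2`, `pbr_CO2`, `VE`, `CO`.
#' @param params A [physio_params()] object.
#' @param depression Opioid depression multiplier in \[0, 1\].
#' @return Named vector of time derivatives (per min).
#' @export
physio_derivatives <- function(state, params, depression = 1) {
  if (!all(is.finite(unlist(state)))) {
    stop("non-finite physiologic state: ",
         paste(names(state), signif(unlist(state), 3), collapse = ", "))
  }
  s <- as.list(state)
  VE <- max(s$VE, 0); CO <- max(s$CO, 1e-9)
  VA <- params$fA * VE
  Qbr <- params$qbr_frac * CO
  Qt <- CO - Qbr

  CaO2 <- o2_content(s$pA_O2, params)
  CaCO2 <- co2_content(s$pA_CO2, params)
  CtO2 <- o2_content(s$pt_O2, params)
  CbrO2 <- o2_content(s$pbr_O2, params)
  CtCO2 <- co2_content(s$pt_CO2, params)
  CbrCO2 <- co2_content(s$pbr_CO2, params)
  CvO2 <- (Qbr * CbrO2 + Qt * CtO2) / CO
  CvCO2 <- (Qbr * CbrCO2 + Qt * CtCO2) / CO

  mt <- .metab_scale(s$pt_O2, params$p_m)
  mbr <- .metab_scale(s$pbr_O2, params$p_m)
  MO2_t <- (params$MO2 - params$MO2_br) * mt
  VCO2_t <- (params$VCO2 - params$VCO2_br) * mt

  dpA_O2 <- (VA * (params$PI_O2 - s$pA_O2) - 863 * CO * (CaO2 - CvO2)) /
    params$VL_O2
  dpA_CO2 <- (-VA * s$pA_CO2 + 863 * CO * (CvCO2 - CaCO2)) / params$VL_CO2
  dpt_O2 <- (Qt * (CaO2 - CtO2) - MO2_t) / params$beta_t_O2
  dpt_CO2 <- (Qt * (CaCO2 - CtCO2) + VCO2_t) / params$beta_t_CO2
  dpbr_O2 <- (Qbr * (CaO2 - CbrO2) - params$MO2_br * mbr) / params$beta_br_O2
  dpbr_CO2 <- (Qbr * (CaCO2 - CbrCO2) + params$VCO2_br * mbr) /
    params$beta_br_CO2

  ve_target <- ventilatory_drive(state, params, depression)
  dVE <- (ve_target - s$VE) / params$tau_VE
  w <- 1 / (1 + exp((params$p_crit - s$pA_O2) / params$w_width))
  dCO <- w * (params$CO0 - s$CO) / params$tau_CO -
    (1 - w) * s$CO / params$tau_dec

  # gas stores cannot go negative: freeze outflow at the floor
  if (s$pA_O2 <= 0 && dpA_O2 < 0) dpA_O2 <- 0
  if (s$pt_O2 <= 0 && dpt_O2 < 0) dpt_O2 <- 0
  if (s$pbr_O2 <= 0 && dpbr_O2 < 0) dpbr_O2 <- 0

  c(pA_O2 = dpA_O2, pA_CO2 = dpA_CO2, pt_O2 = dpt_O2, pt_CO2 = dpt_CO2,
    pbr_O2 = dpbr_O2, pbr_CO2 = dpbr_CO2, VE = dVE, CO = dCO)
}

#' Baseline steady state
#'
#' Returns the drug-free equilibrium of the cardiorespiratory model.
#' By construction ([physio_params()] calibrates the chemoreflex at
#' build time) the analytic baseline is an exact fixed point; the
#' residual is verified and an error raised if it exceeds `tol`.  With
#' `from` given, the state is instead found by integrating the model
#' from that start until it settles (basin-of-attraction checks).
#'
#' @param params A [physio_params()] object.
#' @param from Optional named start state; `NULL` uses the analytic
#'   baseline.
#' @param t_settle Integration time (min) when `from` is given.
#' @param tol Residual tolerance (per-min rate relative to state scale).
#' @param check_ranges Assert that baseline arterial gases are in the
#'   physiologically sensible ranges paO2 85-110 / paCO2 35-45 mmHg (a
#'   configuration sanity check; disable for deliberately extreme
#'   parameter studies).
#' @return Named baseline state vector.
#' @export
find_baseline_steady_state <- function(params, from = NULL, t_settle = 500,
                                       tol = 1e-6, check_ranges = TRUE) {
  state <- if (is.null(from)) {
    params$baseline
  } else {
    out <- deSolve::lsoda(
      y = from[names(params$baseline)],
      times = c(0, t_settle),
      func = function(t, y, p) list(physio_derivatives(y, p, 1)),
      parms = params, rtol = 1e-10, atol = 1e-10)
    st <- out[nrow(out), -1]
    setNames(as.numeric(st), names(params$baseline))
  }
  resid <- max(abs(physio_derivatives(state, params, 1)) /
                 pmax(abs(state), 1))
  if (resid > tol) {
    stop(sprintf("baseline did not converge: relative residual %.3g", resid))
  }
  if (check_ranges &&
      (state[["pA_O2"]] < 85 || state[["pA_O2"]] > 110 ||
       state[["pA_CO2"]] < 35 || state[["pA_CO2"]] > 45)) {
    stop(sprintf(paste0("baseline paO2 %.1f / paCO2 %.1f mmHg outside ",
                        "the physiologic ranges [85,110] / [35,45]"),
                 state[["pA_O2"]], state[["pA_CO2"]]))
  }
  state
}

#' Detect cardiac arrest in a trajectory
#'
#' Arrest occurs at the first time cardiac output falls below
#' `arrest_frac * CO0`; the event is absorbing (the simulator stops
#' there and reports ventilation and cardiac output as zero thereafter).
#'
#' @param trajectory Data frame with columns `t` and `CO` (from
#'   [simulate_overdose()] or constructed).
#' @param params A [physio_params()] object.
#' @return List with `arrest` (logical) and `t_arrest` (min, or `NA`).
#' @export
detect_cardiac_arrest <- function(trajectory, params) {
  if (is.null(trajectory) || nrow(trajectory) == 0) {
    stop("empty trajectory")
  }
  thr <- params$arrest_frac * params$CO0
  below <- which(trajectory$CO <= thr)
  if (!length(below)) return(list(arrest = FALSE, t_arrest = NA_real_))
  i <- below[1]
  t_arrest <- if (i == 1) trajectory$t[1] else {
    # linear interpolation of the crossing
    t0 <- trajectory$t[i - 1]; t1 <- trajectory$t[i]
    c0 <- trajectory$CO[i - 1]; c1 <- trajectory$CO[i]
    if (c0 == c1) t1 else t0 + (c0 - thr) / (c0 - c1) * (t1 - t0)
  }
  list(arrest = TRUE, t_arrest = t_arrest)
}
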