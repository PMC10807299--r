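#' Construct a virtual patient
#'
#' Bundles the physiologic, pharmacokinetic, receptor-binding and
#' pharmacodynamic parameter sets that define one simulated patient.
#' Called with no arguments it returns the typical patient; any
#' component can be replaced.
#'
#' @param id Identifier.
#' @param physio [physio_params()].
#' @param pk Named list of [pk_params()]: `fentanyl`, `carfentanil`,
#'   `naloxone_iv`, `naloxone_in`.
#' @param binding Named list of [binding_params()]: `fentanyl`,
#'   `carfentanil`, `naloxone`.
#' @param pd [pd_map()].
#' @return List of class `"virtual_patient"`.
#' @export
virtual_patient <- function(id = "typical",
                            physio = physio_params(),
                            pk = list(
                              fentanyl = pk_params("fentanyl"),
                              carfentanil = pk_params("carfentanil"),
                              naloxone_iv = pk_params("naloxone", "iv_bolus"),
                              naloxone_in = pk_params("naloxone", "intranasal")),
                            binding = list(
                              fentanyl = binding_params("fentanyl"),
                              carfentanil = binding_params("carfentanil"),
                              naloxone = binding_params("naloxone")),
                            pd = pd_map()) {
  stopifnot(inherits(physio, "physio_params"),
            all(c("fentanyl", "carfentanil", "naloxone_in", "naloxone_iv")
                %in% names(pk)),
            all(c("fentanyl", "carfentanil", "naloxone") %in% names(binding)))
  structure(list(id = id, physio = physio, pk = pk, binding = binding,
                 pd = pd),
            class = "virtual_patient")
}

#' @export
print.virtual_patient <- function(x, ...) {
  cat("Virtual patient", x$id, "\n")
  cat(sprintf("  naloxone IN: ka %.3g /min, F %.2f; CL %.2f L/min\n",
              x$pk$naloxone_in$ka, x$pk$naloxone_in$F, x$pk$naloxone_in$CL))
  cat(sprintf("  Kd (nM): fentanyl %.3g, carfentanil %.3g, naloxone %.3g\n",
              x$binding$fentanyl$Kd, x$binding$carfentanil$Kd,
              x$binding$naloxone$Kd))
  invisible(x)
}

# Parameter vector for the compiled RHS; order must match
# src/overdose_rhs.c exactly.
.overdose_parms <- function(patient, agonist = c("fentanyl", "carfentanil"),
                            trig_frac = 0.4) {
  agonist <- match.arg(agonist)
  pka <- patient$pk[[agonist]]
  pkn_iv <- patient$pk$naloxone_iv
  pkn_in <- patient$pk$naloxone_in
  bpa <- patient$binding[[agonist]]
  bpn <- patient$binding$naloxone
  ph <- patient$physio
  pd <- patient$pd
  c(V1a = pka$V1, V2a = pka$V2, CLa = pka$CL, Qa = pka$Q,
    # naloxone disposition from the IV set; nasal absorption rate from
    # the intranasal set (bioavailability is applied at the dose event)
    V1n = pkn_iv$V1, V2n = pkn_iv$V2, CLn = pkn_iv$CL, Qn = pkn_iv$Q,
    ka_n = pkn_in$ka,
    ke0a = bpa$ke0, ke0n = bpn$ke0,
    conv_a = 1e6 / (pka$V1 * bpa$mw), conv_n = 1e6 / (pkn_iv$V1 * bpn$mw),
    kon_a = bpa$kon, koff_a = bpa$koff, kon_n = bpn$kon, koff_n = bpn$koff,
    pd_form = as.numeric(pd$form == "emax"), pd_floor = pd$floor,
    pd_r50 = pd$r50, pd_gamma = pd$gamma,
    VE0 = ph$VE0, CO0 = ph$CO0, fA = ph$fA, PI_O2 = ph$PI_O2,
    VL_O2 = ph$VL_O2, VL_CO2 = ph$VL_CO2,
    beta_t_O2 = ph$beta_t_O2, beta_t_CO2 = ph$beta_t_CO2,
    beta_br_O2 = ph$beta_br_O2, beta_br_CO2 = ph$beta_br_CO2,
    hb_cap = ph$hb_cap, sol_O2 = ph$sol_O2, p50 = ph$p50,
    hill_n = ph$hill_n, co2_slope = ph$co2_slope, co2_int = ph$co2_int,
    MO2_t = ph$MO2 - ph$MO2_br, MO2_br = ph$MO2_br,
    VCO2_t = ph$VCO2 - ph$VCO2_br, VCO2_br = ph$VCO2_br,
    qbr_frac = ph$qbr_frac,
    Gc = ph$Gc, Bc = ph$Bc, Gp = ph$Gp, Bp = ph$Bp,
    hvr_amp = ph$hvr_amp, hvr_p0 = ph$hvr_p0, hvr_tau = ph$hvr_tau,
    ve_floor = ph$ve_floor, tau_VE = ph$tau_VE, tau_CO = ph$tau_CO,
    p_crit = ph$p_crit, w_width = ph$w_width, tau_dec = ph$tau_dec,
    p_m = ph$p_m, trig_level = trig_frac * ph$VE0)
}

# Parameters varied across the virtual population (lognormal).
.pop_varied <- list(
  pk = list(fentanyl = c("CL", "V1", "V2", "Q"),
            carfentanil = c("CL", "V1", "V2", "Q"),
            naloxone = c("CL", "V1", "V2", "Q", "ka", "F")),
  binding = c("kon", "koff", "ke0"))

#' Sample a virtual-patient population
#'
#' Draws `n` patients whose pharmacokinetic and receptor-binding
#' parameters vary lognormally around the typical patient.  By default
#' every clearance, volume, inter-compartment flow, the nasal absorption
#' rate and bioavailability, and the binding rate constants
#' (`kon`, `koff`, `ke0`) of each drug receive an independent lognormal
#' multiplier with the same coefficient of variation; bioavailability is
#' capped at 0.98.  Naloxone disposition perturbations are shared
#' between its IV and intranasal parameter sets (one body, two routes).
#'
#' @param n Number of patients.
#' @param cv Coefficient of variation (fraction) applied to each varied
#'   parameter; or a named list with elements `pk` and `binding` for
#'   different CVs per block.  The default 0.6 is of the magnitude of
#'   the between-subject spread seen in observed naloxone concentration
#'   data (arm-level CVs of roughly 70-250%).
#' @param typical Typical patient ([virtual_patient()]).
#' @param seed Integer seed; the draw is deterministic given the seed.
#' @return List of `n` `virtual_patient` objects (ids `pt0001`, ...).
#' @export
sample_population <- function(n = 2000, cv = 0.6,
                              typical = virtual_patient(), seed = 1) {
  if (is.list(cv)) {
    cv_pk <- cv$pk; cv_bind <- cv$binding
  } else {
    cv_pk <- cv_bind <- cv
  }
  stopifnot(cv_pk >= 0, cv_bind >= 0, n >= 1)
  sdl_pk <- sqrt(log(1 + cv_pk^2))
  sdl_b <- sqrt(log(1 + cv_bind^2))
  set.seed(as.integer(seed))
  lapply(seq_len(n), function(i) {
    pt <- typical
    pt$id <- sprintf("pt%04d", i)
    for (drug in c("fentanyl", "carfentanil")) {
      for (par in .pop_varied$pk[[drug]]) {
        pt$pk[[drug]][[par]] <- pt$pk[[drug]][[par]] * exp(rnorm(1, 0, sdl_pk))
      }
    }
    for (par in .pop_varied$pk$naloxone) {
      mult <- exp(rnorm(1, 0, sdl_pk))
      for (set in c("naloxone_iv", "naloxone_in")) {
        if (!is.na(pt$pk[[set]][[par]])) {
          pt$pk[[set]][[par]] <- pt$pk[[set]][[par]] * mult
        }
      }
      if (par == "F") {
        pt$pk$naloxone_in$F <- min(pt$pk$naloxone_in$F, 0.98)
      }
    }
    for (drug in names(pt$binding)) {
      for (par in .pop_varied$binding) {
        pt$binding[[drug]][[par]] <-
          pt$binding[[drug]][[par]] * exp(rnorm(1, 0, sdl_b))
      }
      pt$binding[[drug]]$Kd <-
        pt$binding[[drug]]$koff / pt$binding[[drug]]$kon
    }
    pt
  })
}
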