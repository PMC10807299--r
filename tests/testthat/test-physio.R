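test_that("the oxygen dissociation curve is a Hill function", {
  p <- physio_params()
  expect_equal(oxygen_saturation(0, p), 0)
  expect_equal(oxygen_saturation(p$p50, p), 0.5)
  # direct evaluation of the Hill form at 100 mmHg, P50 26.8, n 2.7
  x <- (100 / 26.8)^2.7
  expect_equal(oxygen_saturation(100, p), x / (1 + x))
  grid <- seq(0, 600, by = 0.5)
  s <- oxygen_saturation(grid, p)
  expect_true(all(diff(s) >= 0))
  expect_true(all(s >= 0 & s <= 1))
  expect_error(oxygen_saturation(-1, p), "negative")
})

test_that("ventilatory drive is calibrated to baseline and chemosensitive", {
  p <- physio_params()
  base <- p$baseline
  expect_equal(ventilatory_drive(base, p, 1), p$VE0, tolerance = 1e-10)
  expect_equal(ventilatory_drive(base, p, 0), 0)
  hyper <- base
  hyper["pA_CO2"] <- hyper["pA_CO2"] + 10
  expect_gt(ventilatory_drive(hyper, p, 1), p$VE0)
  # direct evaluation of the chemoreflex terms as oracle
  expected <- p$Gc * (base[["pbr_CO2"]] - p$Bc) +
    p$Gp * (hyper[["pA_CO2"]] - p$Bp) *
      (1 + p$hvr_amp * exp(-(base[["pA_O2"]] - p$hvr_p0) / p$hvr_tau))
  expect_equal(ventilatory_drive(hyper, p, 1), expected)
})

test_that("the analytic baseline is a fixed point and an attractor", {
  p <- physio_params()
  base <- find_baseline_steady_state(p)
  d <- physio_derivatives(base, p, 1)
  expect_lt(max(abs(d) / pmax(abs(base), 1)), 1e-6)
  expect_equal(base[["VE"]], p$VE0)

  # drug-free stability: 60 min of integration moves nothing by > 0.1%
  out <- deSolve::lsoda(base, c(0, 60),
                        function(t, y, pp) list(physio_derivatives(y, pp, 1)),
                        p, rtol = 1e-8, atol = 1e-8)
  final <- out[nrow(out), names(base)]
  expect_lt(max(abs(final - base) / pmax(abs(base), 1)), 1e-3)

  # basin: a perturbed start relaxes to the same fixed point
  pert <- base * c(1.2, 0.9, 1.1, 1.05, 0.9, 1.08, 1.5, 0.8)
  settled <- find_baseline_steady_state(p, from = pert, t_settle = 800,
                                        tol = 1e-4)
  expect_equal(unname(settled), unname(base), tolerance = 1e-3)
})

test_that("comparative statics: higher metabolism lowers baseline paO2", {
  base <- physio_params()$baseline
  hot <- physio_params(MO2 = 0.40, VCO2 = 0.32)$baseline
  expect_lt(hot[["pA_O2"]], base[["pA_O2"]])
  expect_gt(hot[["pA_CO2"]], base[["pA_CO2"]])
  # and the range sanity check rejects truly extreme configurations
  expect_error(find_baseline_steady_state(physio_params(MO2 = 0.48,
                                                        VCO2 = 0.39)),
               "outside")
})

test_that("conservation: no metabolism and equilibrated stores are static", {
  p <- physio_params(MO2 = 2e-8, MO2_br = 1e-8,
                     VCO2 = 2e-8, VCO2_br = 1e-8)
  st <- c(pA_O2 = p$PI_O2, pA_CO2 = 0, pt_O2 = p$PI_O2, pt_CO2 = 0,
          pbr_O2 = p$PI_O2, pbr_CO2 = 0, VE = p$VE0, CO = p$CO0)
  d <- physio_derivatives(st, p, 1)
  gas <- c("pA_O2", "pA_CO2", "pt_O2", "pt_CO2", "pbr_O2", "pbr_CO2")
  expect_true(all(abs(d[gas]) < 1e-4))
})

test_that("full suppression of drive produces monotone arterial O2 decline", {
  p <- physio_params()
  out <- deSolve::lsoda(p$baseline, seq(0, 12, by = 0.1),
                        function(t, y, pp) list(physio_derivatives(y, pp, 0)),
                        p, rtol = 1e-8, atol = 1e-8)
  pa <- out[, "pA_O2"]
  co <- out[, "CO"]
  before_collapse <- co > 0.9 * p$CO0
  expect_true(all(diff(pa[before_collapse]) < 1e-6))
  expect_error(physio_derivatives(replace(p$baseline, 1, NaN), p, 1),
               "non-finite")
})

test_that("cardiac arrest detection finds the crossing time", {
  p <- physio_params()
  flat <- data.frame(t = 0:60, CO = rep(p$CO0, 61))
  expect_false(detect_cardiac_arrest(flat, p)$arrest)
  forced <- data.frame(t = 0:10, CO = c(rep(p$CO0, 5), 0, rep(0, 5)))
  det <- detect_cardiac_arrest(forced, p)
  expect_true(det$arrest)
  expect_equal(det$t_arrest, 4 + (1 - p$arrest_frac), tolerance = 1e-9)
  expect_error(detect_cardiac_arrest(flat[0, ], p), "empty")
})

test_that("compiled and reference derivatives agree on random states", {
  set.seed(99)
  pt <- virtual_patient()
  parms <- naloxsim:::.overdose_parms(pt, "fentanyl")
  for (rep in 1:20) {
    y <- c(Af1 = runif(1, 0, 3), Af2 = runif(1, 0, 3),
           Cef = runif(1, 0, 300), And = runif(1, 0, 2),
           An1 = runif(1, 0, 2), An2 = runif(1, 0, 2),
           Cen = runif(1, 0, 30),
           Ra = runif(1, 0, 0.9), Rn = 0,
           pA_O2 = runif(1, 5, 120), pA_CO2 = runif(1, 20, 80),
           pt_O2 = runif(1, 5, 60), pt_CO2 = runif(1, 30, 80),
           pbr_O2 = runif(1, 2, 50), pbr_CO2 = runif(1, 30, 90),
           VE = runif(1, 0, 10), CO = runif(1, 0.5, 6))
    y["Rn"] <- runif(1, 0, 1 - y["Ra"])
    dc <- c_rhs(y, parms)
    # physiology block against the R reference
    dep <- ventilation_depression(unname(y["Ra"]), pt$pd)
    dr <- physio_derivatives(y[10:17], pt$physio, dep)
    expect_equal(unname(dc[10:17]), unname(dr), tolerance = 1e-10)
    # binding block against the R reference
    db <- binding_derivatives(y[c("Ra", "Rn")], y[["Cef"]], y[["Cen"]],
                              pt$binding$fentanyl, pt$binding$naloxone)
    expect_equal(unname(dc[8:9]), unname(db), tolerance = 1e-10)
  }
})
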