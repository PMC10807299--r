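test_that("no opioid means no trigger, no arrest, no hypoxia", {
  pt <- virtual_patient()
  sim <- simulate_overdose(pt, fentanyl_od(0), dosing_strategy(1, 0),
                           horizon = 20)
  expect_true(is.na(sim$t_trigger))
  expect_false(sim$arrest)
  expect_equal(sim$brain_hypoxia_time, 0)
  # baseline is held throughout
  expect_lt(max(abs(sim$trajectory$VE - pt$physio$VE0)), 0.01)
})

test_that("the typical patient arrests at the high fentanyl dose untreated", {
  pt <- virtual_patient()
  sim <- simulate_overdose(pt, fentanyl_od(2.97), no_naloxone())
  expect_true(sim$arrest)
  expect_equal(sim$brain_hypoxia_time, Inf)
  expect_false(is.na(sim$t_trigger))
  # trigger precedes arrest; arrest is where the trajectory stops
  expect_lt(sim$t_trigger, sim$t_arrest)
  expect_equal(max(sim$trajectory$t), sim$t_arrest, tolerance = 0.11)
  tail_co <- tail(sim$trajectory$CO, 1)
  expect_lte(tail_co, pt$physio$arrest_frac * pt$physio$CO0 + 1e-6)
})

test_that("arrest is absorbing: cardiac output never recovers after crossing", {
  pt <- virtual_patient()
  sim <- simulate_overdose(pt, fentanyl_od(2.97), no_naloxone())
  thr <- pt$physio$arrest_frac * pt$physio$CO0
  below <- which(sim$trajectory$CO <= thr)
  expect_true(all(sim$trajectory$t >= sim$t_arrest - 0.2 |
                    sim$trajectory$CO > thr))
  expect_true(all(diff(sim$trajectory$CO[below]) <= 1e-9))
})

test_that("more simultaneous naloxone can only help, on the same patient", {
  pt <- virtual_patient()
  one <- simulate_overdose(pt, fentanyl_od(2.97), dosing_strategy(1, 0))
  two <- simulate_overdose(pt, fentanyl_od(2.97), dosing_strategy(2, 0))
  expect_lte(as.numeric(two$arrest), as.numeric(one$arrest))
  expect_lte(two$brain_hypoxia_time, one$brain_hypoxia_time)
})

test_that("brain-hypoxia time measures the below-threshold set", {
  tr <- data.frame(t = 0:10,
                   pbr_O2 = c(30, 25, 15, 15, 15, 15, 25, 30, 30, 30, 30))
  # linearly crosses 20 inside (1,2) and (5,6): below on (1.5, 5.5) -> 4
  expect_equal(brain_hypoxia_time(tr, threshold = 20), 4)
  ok <- data.frame(t = 0:10, pbr_O2 = rep(35, 11))
  expect_equal(brain_hypoxia_time(ok), 0)
  # unrecovered at horizon end
  low <- data.frame(t = 0:10, pbr_O2 = c(rep(35, 5), rep(10, 6)))
  expect_equal(brain_hypoxia_time(low), Inf)
  expect_equal(brain_hypoxia_time(tr, arrest = TRUE), Inf)
  expect_error(brain_hypoxia_time(tr[0, ]), "empty")
})

test_that("the monotone dose-harm relation holds for the typical patient", {
  pt <- virtual_patient()
  doses <- c(0.25, 0.5, 1, 2, 3)
  ht <- vapply(doses, function(d) {
    simulate_overdose(pt, fentanyl_od(d), no_naloxone(),
                      horizon = 40)$brain_hypoxia_time
  }, numeric(1))
  expect_true(all(ht[-1] >= ht[-length(ht)]))   # extended-real monotone
})

test_that("minimum arrest dose scales inversely with potency", {
  pt <- virtual_patient()
  m1 <- min_arrest_dose(pt, "fentanyl", tol = 0.01, d_max = 10)
  # a synthetic agonist with doubled affinity (half Kd)
  pt2 <- pt
  pt2$binding$fentanyl$kon <- 2 * pt2$binding$fentanyl$kon
  pt2$binding$fentanyl$Kd <- pt2$binding$fentanyl$Kd / 2
  m2 <- min_arrest_dose(pt2, "fentanyl", tol = 0.01, d_max = 10)
  expect_equal(m2 / m1, 0.5, tolerance = 0.25)
  expect_lt(m2, m1)
  # no arrest below the bracket ceiling raises an informative error
  expect_error(min_arrest_dose(pt, "fentanyl", d_max = 0.05), "bracket")
})

test_that("the ventilation trigger honours the configured delay", {
  pt <- virtual_patient()
  s1 <- simulate_overdose(pt, fentanyl_od(2.97),
                          dosing_strategy(1, 0, delay = 1))
  s3 <- simulate_overdose(pt, fentanyl_od(2.97),
                          dosing_strategy(1, 0, delay = 3))
  expect_equal(s1$t_trigger, s3$t_trigger)      # trigger itself is fixed
  # later naloxone cannot reduce hypoxic burden
  expect_gte(s3$brain_hypoxia_time, s1$brain_hypoxia_time)
})
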