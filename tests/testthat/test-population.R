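test_that("population sampling is reproducible and respects CV = 0", {
  p0 <- sample_population(n = 4, cv = 0, seed = 5)
  expect_equal(p0[[1]]$pk, p0[[4]]$pk)
  expect_equal(p0[[1]]$binding, p0[[4]]$binding)
  a <- sample_population(n = 6, cv = 0.6, seed = 123)
  b <- sample_population(n = 6, cv = 0.6, seed = 123)
  expect_identical(a, b)
  expect_error(sample_population(3, cv = -0.1), "cv")
})

test_that("sampled parameter spread matches the requested CV", {
  pop <- sample_population(n = 2000, cv = 0.3, seed = 8)
  cl <- vapply(pop, function(p) p$pk$fentanyl$CL, numeric(1))
  cv_hat <- sd(cl) / mean(cl)
  expect_equal(cv_hat, 0.3, tolerance = 0.1)
  expect_true(abs(cv_hat - 0.3) < 0.03)
  # every draw satisfies the positivity invariants
  expect_true(all(vapply(pop, function(p)
    all(unlist(p$pk$fentanyl[c("V1", "V2", "CL", "Q")]) > 0), logical(1))))
  expect_true(all(vapply(pop, function(p)
    p$pk$naloxone_in$F <= 0.98, logical(1))))
})

test_that("degenerate bootstrap summaries are exact", {
  oc <- data.frame(arrest = rep(TRUE, 10),
                   brain_hypoxia_time = rep(Inf, 10))
  bs <- bootstrap_summary(oc, "arrest_pct", m = 5, B = 100, seed = 1)
  expect_equal(c(bs$median, bs$q1, bs$q3), c(100, 100, 100))
  bh <- bootstrap_summary(oc, "median_hypoxia_time", m = 5, B = 100, seed = 1)
  expect_equal(bh$median, Inf)
  expect_equal(bh$m, 5)
  expect_equal(bh$B, 100)
  expect_error(bootstrap_summary(oc, m = 0), "positive")
  expect_error(bootstrap_summary(oc[0, ]), "empty")
})

test_that("bootstrap replicate distribution matches brute-force enumeration", {
  # population of 4 with two arrests; draws of m = 2 have arrest_pct
  # 0/50/100 with enumeration probabilities 1/4, 1/2, 1/4
  oc <- data.frame(arrest = c(TRUE, TRUE, FALSE, FALSE),
                   brain_hypoxia_time = c(Inf, Inf, 0, 0))
  set.seed(31)
  stats <- replicate(8000, {
    idx <- sample.int(4, 2, replace = TRUE)
    mean(oc$arrest[idx]) * 100
  })
  emp <- table(factor(stats, levels = c(0, 50, 100))) / length(stats)
  expect_equal(as.numeric(emp), c(0.25, 0.5, 0.25), tolerance = 0.05)
  # the packaged summary of the same population lies inside that support
  bs <- bootstrap_summary(oc, "arrest_pct", m = 2, B = 2500, seed = 4)
  expect_true(all(c(bs$median, bs$q1, bs$q3) %in% c(0, 50, 100)))
  # seed reproducibility and order invariance
  bs2 <- bootstrap_summary(oc[c(3, 1, 4, 2), ], "arrest_pct", m = 2,
                           B = 2500, seed = 4)
  expect_equal(bs$median, bs2$median)
})

test_that("extended-real medians order infinity above all reals", {
  x <- c(1, 2, Inf, Inf, Inf)
  expect_equal(naloxsim:::ext_quantile(x, 0.5), Inf)
  expect_equal(naloxsim:::ext_quantile(x, 0.25), 2)
  expect_equal(naloxsim:::ext_quantile(c(3, 1, 2), c(0.25, 0.5, 0.75)),
               c(1, 2, 3))
})

test_that("the experiment grid returns one row per cell and outcome", {
  pop <- tiny_population()[1:3]
  grid <- expand.grid(drug = "fentanyl", dose_mg = c(1, 2.97),
                      strategy = c("none", "in1_x1"),
                      stringsAsFactors = FALSE)
  res <- run_experiment_grid(pop, grid, m = 3, B = 50, seed = 2,
                             horizon = 30)
  expect_equal(nrow(res), 2 * 2 * 2)
  expect_setequal(unique(res$outcome),
                  c("arrest_pct", "median_hypoxia_time"))
  expect_true(all(res$q1 <= res$median & res$median <= res$q3))
  expect_error(run_experiment_grid(pop,
                                   data.frame(drug = "fentanyl",
                                              dose_mg = 1,
                                              strategy = "nope")),
               "unknown strategies")
})

test_that("simulated outcomes table matches the single-scenario simulator", {
  pop <- tiny_population()[1:2]
  oc <- simulate_outcomes(pop, "fentanyl", 2.97, no_naloxone(),
                          horizon = 30)
  expect_equal(nrow(oc), 2)
  s1 <- simulate_overdose(pop[[1]], fentanyl_od(2.97), no_naloxone(),
                          horizon = 30)
  expect_equal(oc$arrest[1], s1$arrest)
  expect_equal(oc$brain_hypoxia_time[1], s1$brain_hypoxia_time)
})
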