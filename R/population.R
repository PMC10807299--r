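# Order-statistic (type 1) quantile, safe for extended reals (Inf).
ext_quantile <- function(x, probs) {
  x <- sort(x)          # Inf sorts above all reals
  n <- length(x)
  x[pmax(1L, ceiling(probs * n))]
}

#' Bootstrap summary of population outcomes
#'
#' For each of `B` replicates, draws `m` patients with replacement from
#' the simulated population, computes the outcome statistic (cardiac
#' arrest percentage, or the median brain-hypoxia time in extended reals
#' with `Inf` ordered above all finite values), and reports the median
#' and IQR of the statistic over replicates.  Order-statistic quantiles
#' are used throughout so infinite values propagate correctly.
#'
#' @param outcomes Data frame with columns `arrest` (logical) and
#'   `brain_hypoxia_time` (numeric, `Inf` allowed), one row per patient.
#' @param statistic `"arrest_pct"` or `"median_hypoxia_time"`.
#' @param m Patients drawn per replicate (default 200).
#' @param B Number of replicates (default 2500).
#' @param seed Integer seed (resampling is deterministic given it).
#' @return Object of class `"population_summary"`: list with `outcome`,
#'   `median`, `q1`, `q3`, `m`, `B`, `seed`, `n_population`.
#' @export
bootstrap_summary <- function(outcomes,
                              statistic = c("arrest_pct",
                                            "median_hypoxia_time"),
                              m = 200, B = 2500, seed = 1) {
  statistic <- match.arg(statistic)
  if (is.null(outcomes) || nrow(outcomes) == 0) stop("empty outcomes")
  if (m <= 0 || B <= 0) stop("m and B must be positive")
  n <- nrow(outcomes)
  val <- if (statistic == "arrest_pct") as.numeric(outcomes$arrest) * 100
         else outcomes$brain_hypoxia_time
  set.seed(as.integer(seed))
  stats <- vapply(seq_len(B), function(b) {
    idx <- sample.int(n, m, replace = TRUE)
    if (statistic == "arrest_pct") mean(val[idx])
    else ext_quantile(val[idx], 0.5)
  }, numeric(1))
  q <- ext_quantile(stats, c(0.25, 0.5, 0.75))
  structure(list(outcome = statistic, median = q[2], q1 = q[1], q3 = q[3],
                 m = m, B = B, seed = seed, n_population = n),
            class = "population_summary")
}

#' @export
print.population_summary <- function(x, ...) {
  fmt <- function(v) if (is.infinite(v)) "Inf" else sprintf("%.3g", v)
  cat(sprintf("%s: median %s (IQR %s-%s)  [m=%d, B=%d, n=%d, seed=%d]\n",
              x$outcome, fmt(x$median), fmt(x$q1), fmt(x$q3),
              x$m, x$B, x$n_population, x$seed))
  invisible(x)
}

#' Simulate outcomes for a population under one scenario
#'
#' Runs [simulate_overdose()] for every patient and collects the outcome
#' fields.
#'
#' @param patients List of [virtual_patient()] objects.
#' @param drug Opioid.
#' @param dose_mg IV bolus dose (mg).
#' @param strategy A [dosing_strategy()].
#' @param horizon,dt,trig_frac Passed to the simulator.
#' @return Data frame: `patient`, `arrest`, `brain_hypoxia_time`,
#'   `t_trigger`.
#' @export
simulate_outcomes <- function(patients, drug, dose_mg, strategy,
                              horizon = 60, dt = 0.1, trig_frac = 0.4) {
  res <- lapply(patients, function(pt) {
    sim <- simulate_overdose(pt, list(drug = drug, amount_mg = dose_mg),
                             strategy = strategy, horizon = horizon,
                             dt = dt, trig_frac = trig_frac)
    data.frame(patient = pt$id, arrest = sim$arrest,
               brain_hypoxia_time = sim$brain_hypoxia_time,
               t_trigger = sim$t_trigger)
  })
  do.call(rbind, res)
}

#' Run an overdose experiment grid
#'
#' Simulates every cell of an opioid-dose x dosing-strategy (x trigger
#' delay) grid over a shared virtual-patient population and summarises
#' each cell's outcomes by bootstrap.  Within one opioid/dose
#' combination the pre-trigger portion of every patient's trajectory is
#' computed once and shared across strategies.
#'
#' @param patients List of [virtual_patient()] objects.
#' @param grid Data frame with columns `drug`, `dose_mg`, `strategy`
#'   (names into `strategies`) and optionally `delay_min` (overrides the
#'   strategy's trigger delay).
#' @param strategies Named list of [dosing_strategy()] objects (default
#'   [standard_strategies()]).
#' @param horizon,dt,trig_frac Simulator settings.
#' @param m,B,seed Bootstrap settings (see [bootstrap_summary()]).
#'
#' @return Data frame with one row per cell and outcome: `drug`,
#'   `dose_mg`, `strategy`, `delay_min`, `outcome`, `median`, `q1`, `q3`.
#' @export
run_experiment_grid <- function(patients, grid,
                                strategies = standard_strategies(),
                                horizon = 60, dt = 0.1, trig_frac = 0.4,
                                m = 200, B = 2500, seed = 1) {
  stopifnot(all(c("drug", "dose_mg", "strategy") %in% names(grid)))
  if (is.null(grid$delay_min)) grid$delay_min <- NA_real_
  unknown <- setdiff(unique(grid$strategy), names(strategies))
  if (length(unknown)) {
    stop("unknown strategies in grid: ", paste(unknown, collapse = ", "))
  }
  out <- list()
  for (combo in split(grid, list(grid$drug, grid$dose_mg), drop = TRUE)) {
    drug <- combo$drug[1]; dose <- combo$dose_mg[1]
    strat_list <- lapply(seq_len(nrow(combo)), function(i) {
      s <- strategies[[combo$strategy[i]]]
      if (is.finite(combo$delay_min[i])) s$delay <- combo$delay_min[i]
      s
    })
    sims <- lapply(patients, function(pt) {
      tryCatch(
        .simulate_multi(pt, drug, dose, strat_list, horizon = horizon,
                        dt = dt, trig_frac = trig_frac),
        error = function(e) {
          stop(sprintf("cell %s %.3g mg, patient %s: %s",
                       drug, dose, pt$id, conditionMessage(e)))
        })
    })
    for (i in seq_len(nrow(combo))) {
      oc <- data.frame(
        arrest = vapply(sims, function(s) s[[i]]$arrest, logical(1)),
        brain_hypoxia_time = vapply(sims, function(s)
          s[[i]]$brain_hypoxia_time, numeric(1)))
      for (stat in c("arrest_pct", "median_hypoxia_time")) {
        bs <- bootstrap_summary(oc, stat, m = m, B = B, seed = seed)
        out[[length(out) + 1L]] <- data.frame(
          drug = drug, dose_mg = dose, strategy = combo$strategy[i],
          delay_min = if (is.finite(combo$delay_min[i]))
            combo$delay_min[i] else strat_list[[i]]$delay,
          outcome = stat, median = bs$median, q1 = bs$q1, q3 = bs$q3)
      }
    }
  }
  do.call(rbind, out)
}
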