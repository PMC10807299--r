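#' Block randomization of crossover sequences
#'
#' Assigns each participant one of the 6 orderings of the three arms.
#' Within each complete block of `block_size` every sequence appears
#' exactly once; the remainder is drawn without replacement from the 6.
#'
#' @param n Number of participants.
#' @param block_size Block size (default 6).
#' @param seed Integer seed.
#' @return Integer vector of sequence indices (1-6), length `n`.
#' @export
randomize_sequences <- function(n, block_size = 6, seed = 1) {
  stopifnot(n >= 1, block_size == 6)
  set.seed(as.integer(seed))
  full <- n %/% block_size
  rem <- n %% block_size
  out <- unlist(lapply(seq_len(full), function(b) sample.int(6)))
  if (rem > 0) out <- c(out, sample.int(6)[seq_len(rem)])
  out[seq_len(n)]
}

# The 6 arm orderings (rows) over the 3 periods (columns).
.sequence_table <- function() {
  arms <- trial_arms()
  perms <- rbind(c(1, 2, 3), c(1, 3, 2), c(2, 1, 3),
                 c(2, 3, 1), c(3, 1, 2), c(3, 2, 1))
  matrix(arms[perms], nrow = 6)
}

# Dosing schedule (dose events) of each trial arm; 4 mg per spray.
.arm_doses <- function(arm) {
  sched <- switch(arm,
    "IN1_q2.5x2" = list(times = c(0, 2.5), mg = 4),
    "IN2_q2.5x2" = list(times = c(0, 2.5), mg = 8),
    "IN1_q2.5x4" = list(times = c(0, 2.5, 5, 7.5), mg = 4),
    stop("unknown arm: ", arm))
  do.call(rbind, lapply(sched$times, function(t)
    dose_event(t, "naloxone", "intranasal", sched$mg)))
}

#' Total administered naloxone dose per arm (mg)
#' @param arm Arm label.
#' @export
arm_total_dose <- function(arm) {
  sum(.arm_doses(arm)$amount_mg)
}

#' Specification for a synthetic crossover trial
#'
#' Settings of the trial-table generator: design size, variability
#' components, quantification limit and dropout.  The typical
#' concentration curve of each arm comes from the package's intranasal
#' naloxone model with superposed doses, so the generator and the
#' overdose simulator share one pharmacokinetic truth; `arm_scale` can
#' multiply selected arms' typical curves to bake a known concentration
#' ratio into the data for recovery tests.
#'
#' Observed concentrations are
#' `typical(t) * exp(eta_participant) * exp(eta_period) * (1 + eps) + eps_add`,
#' floored at zero: lognormal between-subject and within-subject
#' (period) variability, a proportional residual, and an additive
#' residual that dominates at low concentrations (inflating the
#' coefficient of variation at early times, as seen in observed data).
#'
#' @param n_participants Default 21.
#' @param bsv_cv Between-subject CV (fraction, default 0.6).
#' @param wsv_cv Within-subject (period) CV (default 0.3).
#' @param prop_cv Proportional residual CV (default 0.25).
#' @param add_sd Additive residual SD (ng/mL, default 0.3).
#' @param lloq Lower limit of quantification (ng/mL, default 0.04).
#' @param dropout Named list, participants discontinuing during periods
#'   1 and 2 (defaults 2 and 1: 18 completers out of 21).
#' @param arm_scale Named numeric multipliers on arms' typical curves
#'   (default all 1).
#' @param pk Intranasal naloxone [pk_params()] used for the typical
#'   curves.
#' @param seed Integer seed.
#' @return List of class `"trial_sim_spec"`.
#' @export
trial_sim_spec <- function(n_participants = 21, bsv_cv = 0.6, wsv_cv = 0.3,
                           prop_cv = 0.25, add_sd = 0.3, lloq = 0.04,
                           dropout = list(period1 = 2, period2 = 1),
                           arm_scale = NULL,
                           pk = pk_params("naloxone", "intranasal"),
                           seed = 1) {
  stopifnot(n_participants >= 1, bsv_cv >= 0, wsv_cv >= 0, prop_cv >= 0,
            add_sd >= 0, lloq >= 0)
  scale <- setNames(rep(1, 3), trial_arms())
  if (!is.null(arm_scale)) scale[names(arm_scale)] <- arm_scale
  structure(list(n_participants = n_participants, bsv_cv = bsv_cv,
                 wsv_cv = wsv_cv, prop_cv = prop_cv, add_sd = add_sd,
                 lloq = lloq, dropout = dropout, arm_scale = scale,
                 pk = pk, seed = seed),
            class = "trial_sim_spec")
}

#' Typical concentration curve of a trial arm
#'
#' @param arm Arm label.
#' @param t Times (min).
#' @param spec A [trial_sim_spec()] (uses its PK set and arm scaling).
#' @return Concentrations (ng/mL).
#' @export
arm_typical_curve <- function(arm, t, spec = trial_sim_spec()) {
  spec$arm_scale[[arm]] *
    plasma_concentration(spec$pk, .arm_doses(arm), t)
}

#' Generate a synthetic crossover concentration table
#'
#' Emulates the deposited trial dataset's structure: 21 participants
#' randomized in blocks of 6 to the 6 arm orderings, 3 periods, 16
#' nominal sampling times per period, lognormal between/within-subject
#' variability, additive-plus-proportional residual error, LLOQ
#' censoring and dropout.  Deterministic given `spec$seed`.
#'
#' @param spec A [trial_sim_spec()].
#' @return Validated trial table (see [read_trial_table()]).
#' @export
generate_trial <- function(spec = trial_sim_spec()) {
  stopifnot(inherits(spec, "trial_sim_spec"))
  seqs <- randomize_sequences(spec$n_participants, seed = spec$seed)
  # randomize_sequences seeds the stream; continue it for the noise
  stab <- .sequence_table()
  times <- protocol_times()
  sdl_b <- sqrt(log(1 + spec$bsv_cv^2))
  sdl_w <- sqrt(log(1 + spec$wsv_cv^2))

  n_drop1 <- spec$dropout$period1 %||% 0
  n_drop2 <- spec$dropout$period2 %||% 0
  dropped <- sample.int(spec$n_participants, n_drop1 + n_drop2)
  drop_period <- setNames(rep(Inf, spec$n_participants),
                          seq_len(spec$n_participants))
  if (n_drop1 > 0) drop_period[dropped[seq_len(n_drop1)]] <- 1
  if (n_drop2 > 0) drop_period[dropped[n_drop1 + seq_len(n_drop2)]] <- 2

  rows <- list()
  for (i in seq_len(spec$n_participants)) {
    eta_i <- rnorm(1, 0, sdl_b)
    for (period in 1:3) {
      if (period >= drop_period[i]) next
      arm <- stab[seqs[i], period]
      eta_ip <- rnorm(1, 0, sdl_w)
      typ <- arm_typical_curve(arm, times, spec)
      eps_p <- rnorm(length(times), 0, spec$prop_cv)
      eps_a <- rnorm(length(times), 0, spec$add_sd)
      conc <- pmax(typ * exp(eta_i + eta_ip) * (1 + eps_p) + eps_a, 0)
      conc[times == 0] <- 0          # predose: no carryover
      blq <- conc < spec$lloq
      conc[blq] <- 0
      rows[[length(rows) + 1L]] <- data.frame(
        participant = sprintf("p%02d", i), sequence = seqs[i],
        period = period, arm = arm, nominal_time = times,
        concentration = conc, blq = blq)
    }
  }
  validate_trial_table(do.call(rbind, rows))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Generate a virtual population with recorded ground truth
#'
#' Wraps [sample_population()] and retains the generating settings and
#' typical parameter values so recovery tests can compare sample moments
#' against the truth.
#'
#' @param n Population size.
#' @param cv Coefficient of variation (see [sample_population()]).
#' @param typical Typical patient.
#' @param seed Integer seed.
#' @return List with `patients` and `truth` (list: `n`, `cv`, `seed`,
#'   `typical`).
#' @export
generate_population_truth <- function(n = 2000, cv = 0.6,
                                      typical = virtual_patient(),
                                      seed = 1) {
  patients <- sample_population(n = n, cv = cv, typical = typical,
                                seed = seed)
  list(patients = patients,
       truth = list(n = n, cv = cv, seed = seed, typical = typical))
}
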