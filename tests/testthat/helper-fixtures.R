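# Shared fixtures: built in code, small enough for quick tests.

# A deterministic noise-free trial spec (every profile equals the arm's
# typical curve).
noise_free_spec <- function(...) {
  trial_sim_spec(bsv_cv = 0, wsv_cv = 0, prop_cv = 0, add_sd = 0,
                 dropout = list(period1 = 0, period2 = 0), ...)
}

# Small virtual population shared across simulator tests (computed once
# per test run).
tiny_population <- local({
  cache <- NULL
  function(n = 40, cv = 0.6, seed = 2024) {
    if (is.null(cache)) cache <<- sample_population(n = n, cv = cv,
                                                    seed = seed)
    cache
  }
})

# Direct evaluation of the compiled RHS at a state (C/R lockstep checks).
c_rhs <- function(y, parms) {
  out <- deSolve::DLLfunc(func = "overdose_derivs", times = 0, y = y,
                          parms = parms, dllname = "naloxsim",
                          initfunc = "overdose_init")
  out$dy
}

fentanyl_od <- function(dose = 2.97) list(drug = "fentanyl", amount_mg = dose)
no_naloxone <- function() dosing_strategy(0, numeric(0), name = "none")
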