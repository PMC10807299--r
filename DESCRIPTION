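Package: naloxsim
Title: Mechanistic Simulation of Naloxone Rescue of Synthetic-Opioid
    Overdose and Crossover Pharmacokinetic Trial Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: A lumped cardiorespiratory pharmacokinetic-pharmacodynamic
    simulator of fentanyl and carfentanil overdose and naloxone rescue,
    coupling oxygen and carbon dioxide storage and exchange, chemoreflex
    ventilatory control and hypoxic cardiovascular decompensation to
    competitive mu-opioid receptor binding kinetics.  Supports
    ventilation-triggered intranasal and intravenous naloxone dosing
    strategies, virtual-patient populations and bootstrap outcome
    summaries (brain-hypoxia time, cardiac arrest).  Also implements the
    statistical pipeline of a randomized crossover comparison of repeat
    intranasal naloxone dosing: noncompartmental analysis, paired
    log-scale comparisons with Pocock-adjusted sequential testing,
    geometric mean ratios and dose-proportionality assessment, together
    with synthetic-data generators emulating the trial's concentration
    tables.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    deSolve,
    mvtnorm,
    jsonlite,
    yaml,
    stats,
    utils,
    graphics
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
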