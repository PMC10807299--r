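---
title: "Models and methods in naloxsim"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods in naloxsim}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(naloxsim)
```

naloxsim addresses a practical question in overdose response: when a
bystander treats a fentanyl or carfentanil overdose with intranasal
naloxone and no ventilatory support, how do different dosing
strategies — more sprays at once, repeated sprays every 2.5 minutes,
longer delays before the first dose, or titrated intravenous dosing —
change the time the brain spends hypoxic and the chance of cardiac
arrest?  The package couples a mechanistic cardiorespiratory model to
opioid and naloxone pharmacology and runs the race between receptor
occupancy and cardiovascular collapse over virtual-patient populations.
It also implements the statistical pipeline used to compare repeat
intranasal naloxone regimens in a randomized crossover study of healthy
adults, together with a synthetic-data generator that emulates such a
trial so that every stage is testable without any external data.

## The cardiorespiratory model

The physiologic engine is a self-contained lumped model in the style of
Ursino's respiratory-control models, with every coefficient exposed in
`physio_params()` so the model can be re-parameterized.  The state
comprises alveolar, non-brain-tissue and brain partial pressures of
oxygen and carbon dioxide, minute ventilation `VE`, and cardiac output
`CO`.  Arterial gases equal alveolar gases (no shunt is modeled);
venous blood leaving each tissue compartment is equilibrated with that
compartment's store.

Gas exchange and storage follow standard mass balances.  For alveolar
oxygen,

$$V_{L,O_2}\,\dot p_{A,O_2} = V_A (P_{I,O_2} - p_{A,O_2})
  - 863\, \mathrm{CO}\,(C_a - C_v),$$

where $V_A$ is alveolar ventilation (a fixed 70% of `VE`), the factor
863 converts blood gas content (L STPD per L) times flow into
mmHg·L/min, and $C_a$, $C_v$ are arterial and flow-weighted mixed
venous contents.  Oxygen content uses a Hill dissociation curve with
`P50 = 26.8` mmHg and coefficient `n = 2.7` plus dissolved oxygen;
carbon dioxide content is linearized.  Tissue and brain stores use
constant capacitances (L per mmHg); metabolism is constant except below
`p_m = 5` mmHg, where it shuts off linearly so stores cannot go
negative.

Ventilatory control is a two-component chemoreflex.  The central drive
is proportional to brain CO2 above a threshold; the peripheral drive is
proportional to arterial CO2 above a threshold and is amplified under
hypoxemia by the factor $1 + 5\,e^{-(p_{a,O_2}-30)/20}$.  Opioid effect
multiplies the total chemical drive by the depression factor described
below, and `VE` relaxes toward the resulting target with a 0.5-min time
constant.  Crucially, the gains and thresholds are calibrated at
construction so that the analytic baseline — obtained by fixing
`VE = VE0`, `CO = CO0` and solving the Fick and alveolar balances in
closed form — is an *exact* fixed point.  This gives a well-defined
"baseline ventilation" for the 40%-of-baseline naloxone trigger rule
and makes drug-free stability a testable identity rather than an
approximation.  `find_baseline_steady_state()` verifies the residual
and (by default) that baseline arterial gases are physiologically
sensible (paO2 85–110, paCO2 35–45 mmHg).

Cardiovascular decompensation is deliberately simple: while arterial
oxygen stays above `p_crit = 30` mmHg the cardiac-output target is
`CO0`; below it the target collapses and `CO` decays toward zero with
time constant `tau_dec = 4` min (a smooth logistic switch of width 0.5
mmHg joins the regimes).  Cardiac arrest is declared when `CO` falls
below 30% of `CO0`; the event is absorbing — the simulation stops at
the interpolated crossing.  With these defaults the untreated typical
patient at the high fentanyl dose arrests roughly 7 minutes after the
ventilation trigger, which leaves a realistic window in which slowly
absorbed intranasal naloxone can win or lose the race.

## Pharmacology

All three drugs use linear two-compartment disposition; intranasal
naloxone adds first-order absorption from a nasal depot with
bioavailability `F`.  Plasma concentrations outside the simulator are
evaluated in closed form with superposition over dose events
(`plasma_concentration()`); inside the simulator the same kinetics are
integrated as ODEs so doses can be scheduled by the ventilation
trigger.  The naloxone absorption parameters (`ka = 0.02`/min,
`F = 0.44`, `CL = 3.4` L/min, the high systemic clearance
characteristic of naloxone) were chosen so that a single 4-mg spray
peaks near 15 minutes at about 5 ng/mL, matching the well-established
observation that intranasal naloxone reaches its maximal concentration
only after roughly a quarter of an hour — the mechanistic heart of the
repeat-dosing question.  Intravenous naloxone uses the same disposition
with instantaneous input, so IV concentrations peak immediately.

Each drug reaches its receptor through a first-order effect-site lag
(`ke0`), and binding at the mu-opioid receptor is competitive and
kinetic:

$$\dot R_a = k_{on,a} C_a (1 - R_a - R_n) - k_{off,a} R_a,$$

and symmetrically for naloxone occupancy $R_n$.  At constant
concentrations the equilibrium is the standard competitive-binding
expression, which the tests use as an oracle at $10^{-4}$ tolerance.
Affinities encode the potency hierarchy — fentanyl `Kd` 1.8 nM,
naloxone 1.1 nM, carfentanil 0.009 nM with a slow dissociation
(`koff = 0.03`/min) that makes it much harder to displace.  The
carfentanil affinity was set so that the minimum-arrest-dose ratio of
carfentanil to fentanyl for the typical patient is about 0.007, which
maps the two fentanyl study doses (1.63 and 2.97 mg) onto carfentanil
doses near the 0.012 and 0.022 mg used in the study design.

The pharmacodynamic map is linear by default: chemical ventilatory
drive is multiplied by $1 - R_a$, with a configurable floor (default 0,
so apnea is possible) and an optional Emax form.  Linearity is the
simplest monotone choice; the qualitative rescue behaviour is driven by
the competition kinetics and the CO2 reserve (hypercapnia accumulated
during apnea multiplies the drive once occupancy falls), not by the
shape of this map.

## The overdose scenario engine

`simulate_overdose()` integrates the 17-state coupled system (lsoda,
`rtol 1e-6`, `atol 1e-8`, 0.1-min output grid) in two phases.  Phase 1
runs from the opioid bolus with root-finding on `VE - 0.4 VE0`, so the
trigger time is located by the solver rather than read off a grid.  If
ventilation never crosses, no naloxone is ever given.  Phase 2 restarts
at the trigger with naloxone dose events scheduled at
`t_trigger + delay + administration times` (intranasal events add
`F × dose` to the depot; IV events add to the central compartment); the
right-hand side is compiled C for speed, and unit tests hold it in
lockstep with the R reference implementation.  Outcomes are the
brain-hypoxia time — the measure of time brain oxygen spends below 20
mmHg, with linear interpolation at threshold crossings — and the
cardiac-arrest indicator.  Following the convention of the outcome
tables this package emulates, arrest records a hypoxia time of
infinity, as does failure to recover above threshold by the end of the
60-minute horizon; medians and IQRs are computed in the extended reals
using order-statistic quantiles so infinities propagate correctly.

The population layer draws virtual patients by multiplying every
clearance, volume, inter-compartment flow, the nasal absorption rate
and bioavailability, and each drug's `kon`, `koff` and `ke0` by
independent lognormal factors.  The default coefficient of variation is
0.6 per parameter.  That value was chosen once, on two grounds: it is
the magnitude of spread implied by observed arm-level concentration CVs
of roughly 70–250% in crossover naloxone data, and it produces a
no-naloxone arrest fraction in the low 80s of percent at the high
fentanyl dose — i.e., a meaningful minority of untreated patients
survive, as a population model of real overdoses should allow.
Summaries follow the 200-of-population bootstrap: each of `B = 2500`
replicates draws `m = 200` patients with replacement, computes the
arrest percentage or extended-real median hypoxia time, and the
replicate distribution is summarised by its median and IQR.  Of the two
readings the bootstrap description admits, the per-replicate-resampling
one is implemented, because it is the only reading that uses the
replicate count, the subsample size and the population size together.
`run_experiment_grid()` evaluates an opioid-dose × strategy × delay
grid over a shared population, reusing each patient's pre-trigger
trajectory across strategies (it is strategy-independent by
construction).

What the defaults reproduce, and what they do not: with the package's
own coefficients the simulator reproduces the qualitative pattern of
the study's outcome table — arrest percentage falls steeply with
simultaneous sprays but barely at all with q2.5-min repeats, grows with
trigger delay, and falls sharply under early IV titration — and lands
numerically close to several of its cells (46%/34–35% for one/two
sprays at the high fentanyl dose).  This closeness is not a validation:
the published model's calibrated coefficients live in its companion
publication and are not built in here, so exact percentages should be
read as the behaviour of *this* model, not a replication of that one.

## The crossover trial pipeline

The statistical half is independent of the simulator.
Noncompartmental analysis uses linear-up/log-down trapezoids (plain
linear selectable), a terminal slope fitted on the last three
quantifiable points after `Tmax` and extended earlier while adjusted
R² improves, and `AUC_inf = AUC_last + C_last/lambda_z`.
Below-quantification values are excluded, except predose BLQ which
contributes zero to the AUC; profiles with no negative terminal slope
return `AUC_inf` as missing and flagged.  The quantification limit is a
configuration field because deposited tables differ in it.

Paired comparisons are t tests of within-participant log-concentration
differences at single nominal times, reported as geometric mean ratios
with a one-sided lower confidence bound; pairs with a BLQ member are
excluded.  Multiplicity over the three prespecified times uses a Pocock
boundary: `pocock_nominal_level(K, alpha)` solves for the constant
per-look level by deterministic numeric integration (Miwa) of the
equal-information group-sequential multivariate normal with correlation
$\sqrt{i/j}$.  Two points deserve note.  First, the default is the
standard two-sided boundary, which for three looks at overall 0.05
gives 0.0220 — the conventional published value — while the strictly
one-sided crossing problem gives 0.0232; the package reproduces the
conventional value by default and exposes `sided = 1`.  Second, the
three comparison times are correlated repeated measures on the same
participants, not accumulating interim looks, so the equal-information
correlation $\sqrt{i/j}$ is an approximation the original analysis also
adopted.  The acceptance simulation verifies familywise control under a
null whose between-look correlation (0.70) matches the mean of the
equal-information correlations the boundary is designed for; under
weaker repeated-measures correlation the same procedure is mildly
anticonservative (simulated familywise error about 0.054 at a
between-look correlation of 0.6), which is the cost of applying a
group-sequential boundary to repeated-measures looks and is inherited
here deliberately, since the package reproduces the trial's analysis as
specified.
`sequential_test()` applies the looks in order and stops at the first
one-sided p below the nominal level, and the one-sided 97.8% bound is
implemented exactly as $1 - 0.022$ with the t quantile (n−1 degrees of
freedom); whether t or normal quantiles were used originally is not
stated, and t is the conservative choice.  Dose proportionality divides
AUC or Cmax by each arm's total administered dose and reports the
paired GMR with a two-sided 90% CI.

## The synthetic trial generator

`generate_trial()` emulates the deposited table's structure exactly: 21
participants block-randomized (blocks of 6) over the 6 orderings of the
three arms, 3 periods, the 16 protocol sampling times, and dropout of
two participants during period 1 and one during period 2, leaving 18
completers.  Observed concentrations are the arm's typical curve times
lognormal between-subject and within-subject (period) factors, times a
proportional residual, plus an additive residual that dominates at low
concentrations — that additive term is what inflates early-time CVs
toward the large values seen in observed data.  Values below the LLOQ
are flagged and zeroed; predose samples are zero by construction (no
carryover across the long washout).  The typical curves come from the
package's own intranasal PK model with superposed doses, so the
generator and the simulator share one pharmacokinetic truth; a
convenient consequence is that the two-sprays arm is exactly twice the
one-spray arm under these linear kinetics, giving the pipeline a free
built-in true ratio of 2 for recovery tests.  `arm_scale` can impose
any other truth.  The generator does not emulate assay drift,
sub-proportional bioavailability at repeated dosing (the simulator
offers a per-dose bioavailability multiplier separately, off by
default so the simulator stays linear), or realistic
actual-vs-nominal sampling-time deviations beyond flagging support in
the reader — so pipeline tests demonstrate statistical correctness on
data of the right shape, not assay realism.

## Numerical choices and problem sizes

Solver tolerances are `rtol 1e-6` / `atol 1e-8` with event times forced
onto the output grid; trigger location uses the solver's root finder;
arrest times are interpolated between grid points.  Ties in
order-statistic quantiles resolve downward (type 1), which is what
makes extended-real medians well defined.  Bisection for the minimum
arrest dose assumes dose-monotonicity of arrest, which is itself a
tested property.  The shipped tests and the acceptance script use a
200-patient population with the full `m = 200`, `B = 2500` bootstrap —
at that size every reported ordering is stable across seeds — and
10,000 simulated null trials for the familywise-error check; the
vignette-scale examples in the README use the same sizes.  Populations
of 2000, as in the study design, run in a few minutes with the compiled
right-hand side.

## Known limitations

The physiologic coefficients are the package's own, not the companion
model's; absolute arrest percentages therefore carry no clinical
authority.  Renarcotization beyond the 60-minute horizon, rescue
breathing and chest compressions are excluded by design.  The
cardiovascular model is a single decompensation pathway with no
baroreflex detail; acid–base chemistry beyond CO2 stores, pediatric
scaling and nonlinear protein binding are out of scope.  The trial
pipeline treats nominal sampling times as analysis times and flags,
rather than models, out-of-window samples.
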