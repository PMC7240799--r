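---
title: "Methods: a finite MDP for stroke-convalescence treatment comparison"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: a finite MDP for stroke-convalescence treatment comparison}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(strokemdp)
library(data.table)
```

## The model

Longitudinal visit records of stroke patients in the convalescence stage
are encoded as a finite Markov decision process.

**States** are six-digit codes, one digit per patient attribute: age band
(i1: 18–45 / 46–65 / ≥66 years), count of prior diseases (i2: 0 / 1 / ≥2),
complications (i3: none / any), Western diagnosis (i4: ischaemic /
haemorrhagic), TCM syndrome type (i5: five categories), and the
neurological-function-impairment level (i6). The impairment score lives on
a 0–29 scale and is graded into five levels — 0–2, 3–5, 6–12, 13–19,
20–29 — the last digit of the state. Levels 1–2 form the *mild* severity
band, levels 3–5 the *moderate-to-severe* band. A patient who dies is
recorded with the scale maximum, 29, hence level 5. Attributes i1–i5 are
admission characteristics, fixed over a stay; i6 is re-graded from the
score at every decision epoch (without re-grading, transitions between
severity levels could not exist).

**Actions** are the eight on/off combinations of three treatments applied
over one epoch: rehabilitation therapy (a1), Chinese herbal decoction
(a2), acupuncture (a3), written as three-bit codes (`"101"` =
rehabilitation plus acupuncture).

**Rewards** are impairment-score decreases across one epoch,
`score_before - score_after`: positive is improvement, negative is
deterioration, and the episodic return is the undiscounted sum.

**Decision epochs** fall on day 1 and every 7 days thereafter; decision
times beyond day 147 (21 epochs) are discarded. A transition is retained
when it *starts* at or before day 147, so a long stay contributes at most
21 transitions. Off-grid visit days are an error, not silently snapped:
snapping would silently corrupt rewards. Consecutive on-grid visits more
than one epoch apart do not form a transition (no interpolation).

## Estimation

The empirical model is pure frequency estimation:
`P(s'|s,a) = n(s,a,s') / n(s,a)` and `R(s,a,s')` the arithmetic mean of
observed rewards, over exactly the observed states and actions. There is
no smoothing or shrinkage; unobserved pairs carry no estimate and are
excluded from optimisation, because the method derives everything from
observed frequencies and smoothing would invent support.

Two probability views are exposed. The solver consumes *conditional*
probabilities per (state, action). The outcome-table report
(`joint_outcome_table()`) prints *joint* frequencies of (action, next
state) given the pretreatment state, the only reading under which a
printed per-state column sums to 1 (0.5151 + 0.0303 + 0.3333 + 0.1212 ≈
1). Displayed frequencies are **truncated**, not rounded, to 4 decimals
(17/33 = 0.51515… prints as 0.5151), and displayed mean rewards are
rounded to the nearest integer; full precision is kept internally.

## Solving

`run_mc_control()` is tabular Monte Carlo control with exploring starts on
the estimated model: each episode starts at a uniformly drawn supported
(state, action) pair, then follows the current greedy policy; the return
from a visit is the undiscounted reward sum to episode end; Q(s, a) is the
mean of all collected returns and the policy is updated to the
Q-maximising action (ties to the lexicographically smallest action code)
after every episode. The default budget is 500,000 episodes. Episodes
terminate on reaching a state with no supported actions or after 21 steps
— the number of 7-day epochs in 147 days — which guarantees termination
where the empirical chain has cycles without introducing an uncited
discount factor.

`exact_q()` is the verification oracle: finite-horizon backward induction
on the same model, sharing no code with the Monte Carlo path. On
acyclic ("layered") models, where every episode ends within the horizon,
the two must agree; the test suite checks max-norm agreement within 0.1
at 200,000 episodes over ten seeded random models.

**First-visit averaging is the default.** For a pair visited several
times within one cyclic episode, every-visit averaging mixes suffix
returns of many different remaining horizons into one mean. On the cyclic
empirical chain this systematically distorts Q at high-severity states:
the incumbent greedy action accumulates many short-suffix mid-episode
visits while rival actions are reached almost only through full-horizon
exploring starts, so the two are estimated on different effective
horizons. The classical exploring-starts algorithm is the first-visit
variant, and the acceptance suite shows it recovers the exact-oracle
optimum reliably where every-visit falls short; every-visit remains
available as `visit_mode = "every_visit"`. Note that even first-visit
Monte Carlo on a cyclic chain does not estimate exactly the horizon-21
action value (mid-episode visits still carry shorter suffixes), so near
ties can resolve differently from `exact_q()`; when a seed-independent
answer is wanted, `extract_policy(exact_q(model))` is the reference
route.

Q initialisation is zero by default; the "random function" initialisation
is available (`q_init = "random"`, uniform on [-1, 1]) and is
asymptotically irrelevant, but zero-init makes small-model tests exact.

## The synthetic cohort

The reference hospital cohort is not deposited anywhere public, so the generator
stands in for the hospital EHR extraction. It emulates:

* admission attribute marginals matching the reference cohort table
  (N = 835; e.g. 63.83% aged ≥66, 59.64% phlegm-blocking syndrome) and an
  admission severity distribution from the reference level counts;
* 7-day visit grids capped at day 147, death recorded as a terminal visit
  with score 29;
* a configurable fraction of missing attribute/score cells, to exercise
  the cleaning and uniform random-fill stages (the reference cohort has 31 of
  835 patients with partially missing data, randomly filled by computer);
* a uniform logging policy over the eight actions by default — Monte
  Carlo control needs support on every pair, and the real cohort's
  physician-driven assignment mechanism is unknown — with a
  frequency-weighted alternative.

Score dynamics are rounded Gaussian increments clipped to 0–29: per epoch
the score improves by a baseline drift plus the assigned action's effect
plus noise. **The defaults state one fixed world** (they are not tuned per
test): untreated deterioration of 2.5 points/epoch (sd 0.5), effects of
+0.5 for single therapies, +1 for dual, +4 for the triple combination
`"111"`, noise sd 1, a 0.005/epoch death hazard, and deterioration past
the scale ceiling is fatal and absorbing. The planted optimum is `"111"`
everywhere, with a 3-point gap to the runner-up.

The shape of this world is forced by an identifiability argument, not by
clinical realism. Score-differential rewards are *potential-shaped*: the
return telescopes to first score minus last score. In any world where
every first action is followed by an optimal continuation that reaches
the same terminal score well inside the horizon, action values at a state
differ only through binning artefacts, and no solver — Monte Carlo or
exact — could recover a planted optimum. The generator therefore makes
the horizon bind: non-planted actions carry net deterioration, the
planted action net recovery, so a first-step choice leaves a permanent
trace in the terminal score. A per-severity-band multiplier on the action
effects (scalar or per-action) lets the planted optimum differ between
mild and moderate-to-severe states.

What a green recovery test establishes is therefore: *given* a world
whose optimal action is identifiable from finite-horizon returns at the
configured cohort size, the pipeline identifies it. It does not establish
that the reference cohort's decision tables are correct, that real
treatment effects have this structure, or that 5,000 patients suffice for
real data. The generator also deliberately omits inter-attribute
correlations, time-varying effects, informative treatment assignment and
informative dropout.

## Numerical and degenerate-input choices

* All codes are serialized as digit strings; leading zeros survive I/O.
* The five grading intervals partition 0–29 exactly; scores outside the
  range are errors, never clamped.
* Duplicate (patient, day) rows and blank identifier/day/treatment cells
  are integrity errors; abnormal values are dropped with a logged count;
  blanks are filled uniformly at random under a caller-supplied seed.
* Empty inputs: an empty step list is a valid input to the state
  inventory (empty table) but an error for model estimation; a tie in the
  planted optimum is a configuration error.
* Every stochastic component (generator, fill, solver) consumes a single
  user-visible seed; repeated runs are bit-identical.

## Known limitations

* Severity binning loses within-level score information; the empirical
  chain can subsidise transitions that enter a wide level near its
  favourable edge. This is a property of the reference state design,
  inherited faithfully.
* Monte Carlo control on cyclic empirical chains estimates a
  depth-mixed action value (see above); `exact_q()` is provided as the
  deterministic reference.
* The stratified decision tables count *states* (each observed state
  contributes one optimal decision), matching the reference table logic;
  weighting by patient counts is available via `weights =
  state_inventory(steps)`.
* The reference cohort's 236-state inventory and decision-table cell counts
  derive from undeposited hospital records and are out of reach by
  construction; the package reproduces the reconstructed worked example and
  all structural conventions instead.
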