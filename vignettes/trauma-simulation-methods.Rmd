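---
title: "Methods: the virtual trauma patient, the reference grammar, and the evaluation stack"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: the virtual trauma patient, the reference grammar, and the evaluation stack}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(traumasim)
```

`traumasim` is a scriptable re-creation of a web-based trauma training
simulator together with the analytics used to evaluate trainees on it. It
targets the primary survey of an isolated pelvic trauma case: a virtual
patient deteriorates toward death unless the trainee applies the right
interventions in the right order, every action and its effect on the vital
signs is logged, and performance is scored against the set of treatment
sequences consistent with ATLS (Advanced Trauma Life Support) priorities.
This vignette explains the models, the tunable parameters, and the design
choices made where the design was genuinely open.

## The virtual patient

### State and deterioration model

The patient state is a seven-vital panel -- heart rate (bpm), systolic and
diastolic blood pressure (mmHg), SpO2 (%), respiratory rate (breaths/min),
body temperature (°C) and a GCS-like consciousness ordinal (3--15) -- plus
a blood volume expressed as a fraction of normal. Time advances in integer
simulated minutes (`engine_config(tick = 1)`); all timings in the package
are simulated minutes.

The scenario contract is the *remaining lifetime*: the time until death if
no action is taken. The original simulator's update rules are not public,
so the engine uses the minimal dynamics that honor this contract: linear
per-vital deterioration, calibrated at initialization so that the first
lethal-bound crossing happens at exactly the remaining lifetime
(`engine_init()`):

* **Hemorrhage** is the lethal mechanism of the pelvic case. The bleeding
  rate is set so that systolic pressure, which falls linearly with volume
  lost (`sbp_per_volume`, default 100 mmHg per unit fraction), reaches its
  lethal bound (60 mmHg) at the remaining lifetime. Diastolic pressure and
  heart rate follow volume through their own couplings
  (`dbp_per_volume` = 50, `hr_per_volume` = 60), clamped per scenario so
  that systolic collapse is always the first crossing.
* **SpO2, temperature and respiratory rate** deteriorate independently,
  each calibrated to reach its bound (70 %, 30 °C, 40 breaths/min) at the
  same time. This means an untreated patient dies of whichever is checked
  first on the death tick, all by design at the same minute, and every one
  of these failure routes must be treated for the patient to survive a
  full session.
* **Consciousness** declines at half pace
  (`consciousness_lifetime_factor = 2`) and never reaches a lethal level
  within a session: a confused patient stays assessable but does not die
  of the confusion.

Death is declared the first tick any vital reaches or exits its lethal
interval, and is absorbing. Because each deteriorating vital keeps a
strictly positive margin of `(initial - bound)/lifetime` per tick until
the final minute, floating-point accumulation can shift the death tick by
at most one; the contract is therefore stated (and property-tested over
randomized scenarios) as death at the remaining lifetime ± 1 tick.

### Action effects

Actions apply additive deltas instantly, with physiological clipping
(SpO2 caps at 100 %, temperature at 37.5 °C, and so on), and may register
persistent multipliers on a vital's deterioration rate (oxygen delivery
stops the SpO2 decline; warming stops heat loss). Two mechanisms deserve
detail:

* **Pelvic binder**: multiplies the bleeding rate by
  `binder_bleeding_factor` (default 0.1). Placing it earlier is never
  worse: blood volume under an earlier binder dominates the later-binder
  trajectory at every common time point (property-tested).
* **Fluids before hemorrhage control are mostly futile**: while the
  bleeding rate exceeds `controlled_fraction` (default 0.5) of its initial
  calibrated value, only `uncontrolled_fluid_efficiency` (default 0.2) of
  any infused volume is retained -- the rest is lost through the
  hemorrhage. After binder placement the bleed is controlled and fluids
  are fully retained. Both constants are configurable.

When an action and a tick coincide, the action applies first: trainee
input precedes passive deterioration at the same timestamp. Action
durations occupy the timeline but do not pause the deterioration clock;
this keeps the replay a pure function of (scenario, script, config),
which the determinism tests rely on.

The default scenario (`default_scenario()`) is a 34-year-old with an
isolated pelvic injury: HR 110, BP 100/65, SpO2 93 %, RR 22, T 34.5 °C
(hypothermic: the threshold is ≤ 35 °C), consciousness 13, remaining
lifetime 240 minutes. The 240-minute window was chosen to accommodate the
treatment times around 230 minutes that the evaluation layer is designed
to analyze.

## The reference grammar and its 432 sequences

Guideline-consistent treatment is encoded as a phase-ordered slot grammar
(`reference_model()`): phases A → B → C → D → E never interleave, and each
slot is *mandatory*, an *alternative* (choose exactly one of m actions),
*optional*, or *repeatable* (one base occurrence plus up to r extras).

The published description of the pelvic case gives only the enumeration's
summary: 432 valid sequences with a specific length distribution over
8--14 actions. That distribution factors exactly as

$$12 \cdot (1+x)^2 \cdot (1+x+x^2)^2,$$

which pins down the grammar's *shape*: an 8-action backbone, a
length-preserving multiplicity of 12 from alternative slots, two optional
single actions, and two repeatable slots with up to two extras each. The
clinical labeling of that shape is not published, so the default model is
a reconstruction choosing the most natural assignment:

| slot | type |
|---|---|
| airway inspection | mandatory (A) |
| airway clearing | optional (A) |
| intubation | optional (A) |
| oxygen delivery: mask / nasal cannula / bag-valve | alternative of 3 (B) |
| vascular access: peripheral / central | alternative of 2 (C) |
| pelvic binder | mandatory (C) |
| blood transfusion | repeatable, ≤ 2 extra (C) |
| crystalloids | repeatable, ≤ 2 extra (C) |
| talk to the patient | mandatory (D) |
| warming: thermal blanket / hot liquids | alternative of 2 (E) |

Any other labeling with the same shape would enumerate identically; the
model ships as an ordinary constructor argument and can be edited. The
enumeration is deterministic (lexicographic), duplicate-free, and tested
against a brute-force product-expansion oracle on random toy grammars.
Membership (`is_reference()`) is decided by grammar matching with
backtracking, not by set lookup, and the two are cross-checked.

## Scoring

"Correct" and "sequential" actions are not formally defined in the
source material; the package operationalizes them as:

* `n_correct`: the maximum, over all 432 reference sequences, of the
  longest-common-subsequence length with the session's action sequence --
  right actions in the right relative order;
* `n_sequential`: the longest contiguous block of the session that occurs
  as a contiguous block of some reference sequence -- the longest run of
  uninterrupted guideline adherence.

Both equal the session length on a perfect session and 0 on an empty one,
and `n_sequential ≤ n_correct ≤ n_actions` always. Scoring is validated
against exhaustive subsequence/substring oracles on short logs. Cohort
summaries report mean ± SD (sample SD, n − 1) for numeric metrics and
"p% (k/n)" per action with p rounded half-up to an integer (so 20/28
prints as 71 %); a derived row reports the union of the two warming
measures.

## Statistics

`rank_sum_test()` is implemented from first principles. Midranks handle
ties; for pooled sizes ≤ 12 without ties the p-value is exact by full
enumeration of rank splits; otherwise a normal approximation with
tie-corrected variance and a 0.5 continuity correction is used, and
significance is declared at 0.05. Exact p-values are verified to equal a
permutation oracle exhaustively for all tie-free instances with pooled
size ≤ 10, and against `stats::wilcox.test`. For the approximation, full
enumeration of the n1 = n2 = 8 null distribution shows a worst-case
two-sided error of 0.0109 with the continuity correction (versus 0.046
without), with typical errors around 0.003 -- the correction stays on.

`describe_sample()` uses quartiles by linear interpolation between order
statistics (`quantile(type = 7)`; `{1,2,3,4}` has Q1 = 1.75), matching
the fractional quartiles the evaluation layer is meant to report. Likert
questionnaire ratings (fifteen questions, 7-point scale) are ordinal, so
`summarize_likert()` reports medians only, per group and overall.

## The synthetic trainee cohorts

Human sessions are not available, so `generate_cohort()` emulates the two
pilot groups (28 students, 13 doctors). Each synthetic trainee walks the
grammar:

* a slot with per-branch performance probabilities $p_i$ fires with
  probability $\min(1, \sum p_i)$ and picks branch $i$ proportionally to
  $p_i$. When $\sum p_i \le 1$ every action's marginal performance
  probability is exactly its profile value -- this is what makes
  large-cohort parameter recovery exact (tested within 3 binomial SEs at
  n = 10⁴) and makes mutually exclusive alternatives (the two warming
  measures) sum to the observed union proportions (64 % students, 77 %
  doctors);
* ordering: at each step the trainee takes the next reference action with
  probability `adherence` (defaults 0.7 students, 0.85 doctors), otherwise
  a uniformly random remaining one;
* timing: one log-normal time is sampled per included action from that
  action's `(t_median, t_sigma)`, the time multiset is sorted, and the
  sorted times are assigned to the adherence-perturbed order. Sampling
  times per action and then ordering *by time* would erase the adherence
  structure, so the perturbed order is authoritative and the sampled times
  serve as its order statistics. Medians are anchored to published
  response times where available (airway inspection ~5 min students vs
  ~1.5 min doctors; pelvic binder 72 vs 157 min) and are package defaults
  elsewhere.

Default per-action probabilities equal the pilot cohorts' observed
fractions (students 20/28 airway inspection, doctors 13/13 oxygenation,
0 for talking to the patient in both groups, and so on). Per-trainee
inclusions are sampled independently -- only marginal proportions are
published, so no correlation structure is imposed. With
`stratified = TRUE`, per-action counts are pinned to
`round_half_up(p · n)` with disjoint branch assignments, so a (28, 13)
cohort reproduces the expected k/n table exactly through the whole
pipeline; scripts are clamped one tick inside the session horizon, and
since untreated lethal crossings cannot occur before the horizon, every
scheduled action is replayed and pinned counts survive scoring.

What the generator does *not* emulate: inter-action correlations within a
trainee, learning effects, reaction to the evolving vitals, or wrong /
harmful actions outside the catalog. Passing pipeline tests therefore
demonstrates that the machinery measures what it should on behaviorally
plausible inputs, not that it reproduces human cohort dynamics.

## Numerical choices and limitations

* Integer 1-minute ticks; action times falling between ticks are applied
  at the next grid point, before that tick's deterioration.
* Validation is total: malformed scenarios, scripts, logs and responses
  raise structured condition classes listing every violation; no partially
  constructed object escapes.
* Serialization is canonical (fixed key order, YAML primary / JSON
  accepted), so saving twice is byte-identical and round-trips are exact.
* Problem sizes in the test suite -- 432-sequence enumerations, cohorts of
  41, 10⁴-trainee recovery runs, exhaustive rank-sum grids to pooled size
  10 -- were chosen so the whole suite runs in about a minute on one CPU.
* The engine is a reconstruction honoring every stated constraint of the
  original tool, not a disclosure of its update rules; conclusions about
  the original system should rest on the contracts tested here (death
  timing, monotonicity, determinism), not on the specific linear form.
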