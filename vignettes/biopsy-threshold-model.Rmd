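---
title: "A finite-horizon MDP for the breast-biopsy threshold: model and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{A finite-horizon MDP for the breast-biopsy threshold: model and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(biopsyMDP)
```

## The decision problem

A radiologist reading a mammographic finding must choose annually between
recommending an image-guided **biopsy (BX)** or continuing with **annual
mammography (AM)**. The finding carries an estimated probability of
malignancy — an integer *risk score* 0–100, i.e. the percent probability of
breast cancer produced by an upstream risk model (out of scope here; this
package consumes scores). Biopsy resolves the uncertainty at a quality-of-life
cost; waiting preserves quality of life but exposes a patient whose lesion is
malignant to another year of untreated disease. The package casts this
trade-off as a finite-horizon, discrete-time Markov decision process (MDP)
and asks: *at which risk score does biopsy become optimal, and how does that
threshold depend on age?*

## States, actions, horizon

The state space has **104 states**: the 101 risk-score states 0..100, a
benign-biopsy state (Biopsy-B), an absorbing malignant-biopsy state
(Biopsy-M) and an absorbing Death state. Decisions are made annually from age
40 through age 99 (the last decision age); at age 100 every alive state
receives a terminal reward equal to the remaining life expectancy at 100,
irrespective of the final action. Both actions are available in every
risk-score state; absorbing states admit none.

Biopsy is assumed perfect: a patient in risk state $s$ who is biopsied moves
to Biopsy-M with probability $s/100$ and to Biopsy-B otherwise
(`biopsy_branch()`). After a benign biopsy the record of the biopsy is not
retained; her next-year score is drawn from the same transition row as if she
had been under surveillance.

## Rewards (QALYs)

Rewards are quality-adjusted life years; the model deliberately includes
*only* the disutility of biopsy (no disease-, treatment- or age-related
quality weights), isolating the trade-off between biopsy harm and life-years
gained by early diagnosis.

* **Intermediate reward.** A year under AM is worth 1 QALY if survived and
  1/2 QALY if the patient dies during it (half-cycle correction:
  `intermediate_reward()`). The death probability combines other-cause
  mortality $q_o(a)$ and risk-weighted untreated breast-cancer mortality as
  independent competing risks:
  $p(a,s) = 1 - (1 - q_o(a))\,(1 - \tfrac{s}{100}\, m_u(a))$,
  with $m_u(a) = \min(1, \tau\, m_t(a))$, where $m_t$ is treated
  breast-cancer mortality and $\tau$ the treatment-effectiveness factor
  (untreated-to-treated mortality ratio; base case 1.6).
* **Biopsy disutility.** A time penalty of `d40` weeks at age 40 (base
  case 2) growing linearly to `factor × d40` weeks at age 100 (base case
  factor 2, i.e. 4 weeks), converted at 52 weeks/year. It is subtracted in
  the benign-biopsy year and — by default — also from the malignant lump sum
  (`malignant_disutility = TRUE`): the procedure's discomfort does not
  depend on its pathology. Whether the malignant branch should carry the
  penalty is genuinely open; the switch makes the benign-only reading
  available.
* **Lump sum.** Entering Biopsy-M grants the post-treatment expected
  remaining life: a `pct_invasive` (base 0.75) mixture of the invasive and
  DCIS expected-life tables at the diagnosis age. Death grants 0.

The Bellman recursion solved by `backward_induction()` is, for each decision
age $a$ (from 99 down) and score $s$, with $K$ the transition kernel and
$C(a,s)=\sum_{s'}K(s'|s)V(a{+}1,s')$:

$$V_{AM}(a,s) = 1 - \tfrac{p(a,s)}{2} + (1-p(a,s))\,C(a,s)$$
$$V_{BX}(a,s) = \tfrac{s}{100}\big(L(a) - d(a)\big) +
  \big(1-\tfrac{s}{100}\big)\Big[1 - \tfrac{q_o(a)}{2} - d(a) +
  (1-q_o(a))\,C(a,s)\Big]$$
$$V(a,s) = \max\{V_{AM}, V_{BX}\}$$

Ties (within $10^{-12}$) resolve to AM, so the reported threshold is the
smallest score at which biopsy is *strictly* better. Death preempts the
score transition within a year (continuation weight $1-p$), keeping the
transition measure normalized; the ordering of death and score change within
a year is not otherwise identified. QALYs are summed undiscounted;
`build_instance()` exposes a discount factor, default 1, for exploration
only.

## Transition-kernel estimation

`estimate_kernel()` implements the empirical pipeline:

1. **Exclusion** — findings observed once carry no transition information
   and are dropped.
2. **Annualization** — exam gaps longer than a year are filled by linear
   interpolation of the risk score at (approximately) annual spacing,
   rounding half-up to the integer grid: scores 1 at age 40 and 5 at 42
   impute 3 at 41. A gap of $g$ years is split into $\max(1,\text{round}(g))$
   equal steps so observed points are preserved exactly. Interpolation is
   performed on the integer score scale (not the probability scale); on a
   0–100 grid the two differ only through rounding.
3. **Counting** — every consecutive annual pair $(s_t, s_{t+1})$, observed
   or imputed, adds one count to cell $(s_t \to s_{t+1})$; rows are
   normalized to empirical distributions.

"Average change in risk per year" admits two readings. The default
(`mode = "empirical"`) keeps the full empirical next-score distribution —
the stochastic structure the Bellman expectation needs. A `"mean-drift"`
mode (all mass on the rounded mean next score) is provided for comparison;
it collapses the expectation to a deterministic drift and is not used by the
pipeline. Rows with no observed departures are imputed as self-transitions
and flagged (`imputed`), never silently smoothed; no other smoothing is
applied.

## Synthetic cohort and fixture tables

The clinical dataset the model was originally estimated from is not
deposited, so `generate_cohort()` produces a synthetic stand-in with the
documented summary shape: entry ages Normal(56.5, 12.7) clipped to the
horizon (the clinical cohort extends below 40; the decision model starts at
40, so younger entries are clipped — configurable via `age_range`); risk
scores heavily concentrated below 5 (geometric baseline, ratio 0.55 — the
empirical marginal is unpublished, so this is a modelling choice); about 2.7
exams per patient with 25% of mass at a single exam (exercising the
exclusion rule); inter-exam gaps of 2–3 years with probability 0.25
(exercising interpolation); and a per-exam cancer indicator
$P(\text{cancer}\mid s) = \min(1, \beta s/100)$ with $\beta$ calibrated by
root-finding so the marginal rate is 9.7/1000 exams. Outcomes are generated
for calibration and reporting only — the MDP consumes risk scores, not
outcomes, mirroring the separation between the risk model and the decision
model. Everything is reproducible from one integer seed.

The ground-truth kernel (`synthetic_base_kernel()`) is deterministic: row
$s$ is a discretized normal over 0..100 with mean $s + 0.05 + 0.015s$ and
standard deviation $1 + 0.05s$ — a mild upward drift at low scores and a
heavier, wider upward tail at high scores. This choice makes base-case
solves produce non-trivial threshold curves while keeping most of the
population at low risk. What the generator does **not** emulate: reader
variability, BI-RADS descriptor structure, breast/quadrant matching,
registry linkage error, or secular drift in imaging practice — so green
tests certify the estimation and optimization machinery, not clinical
transferability.

The parameter tables in `inst/extdata` are synthetic stand-ins generated by
`make_fixture_tables()` (a test keeps files and generator identical):
Gompertz other-cause mortality ($0.002\,e^{0.0778(a-40)}$, capped at 0.6 —
about 0.2% at 40 and 4.5% at 80, US-life-table shape); treated invasive
breast-cancer mortality rising from 0.14/yr at 40 ($+0.0013$/yr of age);
and post-diagnosis expected life equal to 85% (invasive) and 97% (DCIS) of
the remaining life expectancy implied by the mortality curve itself
(extended to age 120, half-cycle credited). The treated-mortality table is
the *conditional* annual hazard used only to derive untreated mortality via
$\tau$; the lump-sum tables are cure-inclusive (SEER-like) and deliberately
not the integral of that hazard — the same simplification the decision
model's framing makes.

### Invasive fraction enters the hazard, not just the lump sum

In `base_reward_spec()` the effective treated breast-cancer mortality is the
stage mixture `pct_invasive × treated_bc_invasive(age)`, taking the
short-term mortality of in-situ disease as zero. This is the package's
resolution of a genuine modelling fork: if `pct_invasive` scaled only the
lump sum, a higher invasive fraction would make biopsy *less* attractive
(smaller reward, unchanged hazard), whereas clinically — and in the model's
reported behavior — more invasive disease makes *waiting* more dangerous and
lowers the threshold. Mixing the hazard achieves that with one table and no
extra parameters; `annual_death_prob()` itself is agnostic and uses whatever
table it is given.

## Numerical choices and edge cases

* Half-up rounding everywhere a value meets the integer score grid
  (probability-to-score conversion, interpolation, mean-drift mode);
  banker's rounding would map 2.5% to 2 and 12.5% to 12, making the grid
  mapping non-monotone in places.
* Kernel rows must sum to 1 within $10^{-9}$; instances are validated on
  construction and rejected, never repaired.
* The threshold sentinel is 101 ("biopsy never optimal at this age");
  control-limit structure (BX for *all* scores above the threshold) is
  checked per age and reported, not imposed.
* Duplicate exam ages within a finding are an error (no implicit averaging).
* Unachievable cancer-rate calibrations (target above what the score
  distribution can support) are an error, not a silent cap.
* Serialization writes doubles with 17 significant digits, so instances
  round-trip to $10^{-12}$.

## Problem sizes

The default pipeline uses 10,000 patients (~27,000 exams); kernel-recovery
checks use 10,000 annual transitions per row; the solver handles the
101-state, 60-epoch instance in milliseconds, so sweeps are cheap. The test
suite uses smaller cohorts (hundreds to a few thousand patients), chosen so
each statistical check retains clear power at its stated tolerance.

## Known limitations

* Thresholds on synthetic inputs reproduce the *qualitative* structure
  (rising with age; monotone responses to disutility, invasive fraction and
  treatment effect), not any clinically estimated curve: absolute values
  depend on the non-public clinical transition kernel and on survival
  inputs folded into lump-sum tables.
* The kernel estimated from a realistic cohort is well supported only at
  low scores (most exams are low-risk); high-score rows fall back to
  flagged self-transition imputation, exactly as sparse clinical data
  would.
* No short-interval follow-up, ultrasound or MRI arms; no biopsy memory; no
  non-adherence; no costs; risk neutrality throughout.
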