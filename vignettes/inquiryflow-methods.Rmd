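---
title: "Multi-level process mining of simulation-based inquiry logs: models and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Multi-level process mining of simulation-based inquiry logs}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(inquiryflow)
```

## The problem and the data

Simulation-based science assessments log every interface action a student
takes — adjusting experimental variables, running trials, editing an answer,
deleting a data row — as a timestamped event stream. `inquiryflow` analyses
such streams for a structured experimentation task (the *Hydroelectric Power
Plant* task): students manipulate a gate position (Low/Medium/High) and an
inlet inlet diameter (40/80/120 cm), observe the water wheel's rotation
speed per trial, and must submit the single condition that maximises
rotation speed while staying under a 400 rpm safety limit, together with
that condition's exact speed. Correctness is dichotomous: all three answer
elements must be right.

The package implements the full analysis chain:

1. **Task model** — the 9-cell outcome table, its structural requirements
   (a unique constrained optimum; rotation speed strictly increasing in
   both factors), and the scoring rule.
2. **Behavior coding** — raw events are recoded into two parallel
   sequences per student: eight *micro* codes (Adjust Gate, Adjust
   Diameter, Run Trial, Initial Answer, Revise Answer, Remove Record,
   Start Task, End Task) and six *macro* inquiry phases (START, DESIGN,
   CONDUCT, ANSWER, MANAGE, END).
3. **Performance subgroups** — effectiveness (task correctness) crossed
   with a latent efficiency profile from a Gaussian mixture on completion
   time, giving the 2 x 2 design the group analyses condition on.
4. **Macro analytics** — offset Poisson rate models with HC3 robust
   intervals, positionwise state-distribution plots, and gap-tolerant
   frequent-subsequence mining with Wilson intervals, two-proportion z
   tests and Benjamini–Hochberg control.
5. **Micro analytics** — normalized Shannon entropy of behavioral
   repertoires, Dirichlet–multinomial smoothed first-order transition
   models, bootstrap delta probability maps, and thresholded process
   graphs.

Because classroom log files of this kind are generally not shareable, the
package also ships an agent-based simulator that generates raw event logs
with known ground truth, so every stage is exercisable and testable without
access to real data.

## Behavior coding

Interface events map one-to-one onto micro codes except for answer edits:
a maximal run of consecutive `edit_answer` events collapses into a single
*answer episode*. The first episode is coded Initial Answer; every later
episode is Revise Answer. Two choices deserve note:

* **Episode boundary.** An episode is a contiguous run of edit events
  uninterrupted by any other event. Contiguity is the minimal assumption
  consistent with "returning to the item later"; a pause without an
  intervening event does not split an episode.
* **Revision without change.** A later edit run counts as Revise Answer
  whether or not the stored value actually changed, since logs need not
  record prior values.

Completion time is the difference between the first and last event
timestamps; sequence length is the number of micro codes. `cohens_kappa()`
is provided as a utility for validating alternative coder implementations
against fixtures.

## The agent simulator and what it does (and does not) emulate

Each synthetic student follows a **stationary first-order Markov chain**
over the eight micro codes — deliberately the same model family the
micro-level estimator assumes. A behavioral profile bundles the chain, a
dwell-time model, and an answer policy (the probability that the final
submitted triple is the optimum; otherwise a random non-optimal safe
condition is submitted). Four built-in profiles span the 2 x 2 performance
design with the qualitative signatures reported for this task family: the
quick-but-wrong preset opens with an answer from the start state with the
largest probability in its row; the effective presets iterate
design–trial cycles and carry high answer policies; inefficient presets
take longer than efficient ones within each effectiveness level.

Three constraints of the task grammar are honoured *by construction* rather
than by rejection sampling:

* the first answer episode is Initial Answer and later ones Revise Answer,
  whatever label the chain drew (answer identity is positional, exactly as
  in the coding scheme);
* record deletion only ever targets an existing data row (built-in
  profiles place Remove Record mass only in the Run Trial row, and a row
  always exists immediately after a trial);
* an End Task drawn before any answer forces a completing answer episode
  first, mirroring the interface prompt.

These repairs would ordinarily make the realized coded transition
frequencies differ from the chain matrix. The built-in matrices were
therefore fixed, once, at the **self-consistent point**: the matrix each
preset carries is the long-run conditional transition frequency of its own
grammar-constrained process (computed by iterated large-sample simulation
during design). Consequently the empirical coded matrix of a simulated
cohort converges to the declared ground truth as the cohort grows, which is
what the parameter-recovery tests assert (sup-norm below 0.05 by n = 500
for the long-sequence preset). The Initial/Revise split of each row's
answer mass matches the realized first/later-answer shares; only the
row totals are behaviorally meaningful.

**Dwell times and completion time.** Per-behavior dwell times are
log-normal (positive, right-skewed, like human response latencies). Summing
10–20 such draws, with geometric-tailed sequence lengths, yields completion
times far more dispersed and skewed than the approximately normal,
well-separated subgroup times this task family reports (means/SDs of about
81/28, 197/46, 62/20 and 144/43 seconds). Each profile therefore also
carries an explicit completion-time distribution — a positive-truncated
normal with exactly those values — and the log-normal draws are rescaled
within student to the drawn total, acting as relative pacing weights. This
models students pacing themselves to a time budget and makes mixed cohorts
genuinely bimodal, so the mixture model can resolve them; it is the
package's own design choice.

What the simulator does **not** emulate: learning or drift within a student
(the chain is stationary by design, matching the analysis model), payload
realism beyond the outcome table (tentative answers are random table
cells), or any dependence of dwell time on the evolving task state. Tests
that pass on simulated cohorts therefore certify the *estimators* under
the model's own assumptions — first-order dynamics, mixture-distributed
times — not the behavior of real students, whose dynamics may be
higher-order or non-stationary.

The default demonstration cohort is 260 students split 72 / 14 / 152 / 22
across the four presets, which reproduces the reported group proportions
(roughly one third effective; 84/16 and 87/13 efficient/inefficient splits
within the effectiveness groups).

## Efficiency profiles

`fit_efficiency_profiles()` fits univariate Gaussian mixtures with
K = 1..4 components to completion time **in raw seconds** (not log
seconds — the log transform appears only in the PDR validation
regression, and the two are kept distinct deliberately), by EM:

* initialisation: component means at the (k − 0.5)/K quantiles, pooled SD,
  equal weights; for K > 1 a *nested* initialisation (the K − 1 solution
  with its heaviest component split) is also run and the better optimum
  kept, which keeps the log-likelihood monotone in K;
* degeneracy: a variance floor at 1e-4 of the sample SD; collapsing
  components trigger seeded jittered restarts (5 attempts) before a hard
  error;
* selection: minimum BIC with parameter count 3K − 1 (K means, K SDs,
  K − 1 free weights);
* labelling: components are ordered by mean; with K = 2 the smaller-mean
  component is *Efficient*, the other *Inefficient*. Students are assigned
  by maximum posterior responsibility, and the mean maximum posterior is
  reported as classification certainty.

Because EM operates on affine-equivariant quantities, the labels are
invariant to rescaling time (seconds vs minutes), which a test asserts.
Robustness utilities: `sensitivity_split()` (median and tertile splits;
ties go to the faster side, deterministically) and the PDR proxy — the
proportion of a student's consecutive micro pairs that are Adjust
Diameter -> Run Trial. The PDR denominator is **all** consecutive pairs,
the plainest reading of "proportion of transitions"; an alternative
(pairs leaving Adjust Diameter only) exists but is not implemented.
`pdr_regression()` regresses PDR on standardized log completion time and a
correctness indicator by OLS.

## Macro-level analytics

**Rate models.** For each macro behavior, a Poisson GLM with log link
models per-student counts on a group indicator with log sequence length as
exposure offset, so groups are compared on rates per step. Robust Wald
inference uses the HC3 sandwich estimator (squared working residuals
inflated by (1 − h)^−2 with leverages from the IRLS design). In the
two-group saturated case the IRR reduces to the ratio of pooled rates,
which the tests verify against hand computation. Behaviors with zero count
variance (START and END are structurally one per student) are skipped;
a behavior absent from one group is reported as a boundary estimate with a
warning. p-values are BH-adjusted across the modeled behaviors.

**Pattern mining.** Candidate patterns are order-preserving subsequences
with unlimited gaps (no maxgap/mingap constraints; items are single
events), length 2–4 by default, enumerated levelwise with anti-monotone
support pruning — with a 6-state alphabet and length cap 4 the candidate
space is small enough that no lattice or ID-list machinery is needed.
Support counts students (present/absent), never occurrences. The candidate
set is the union of patterns reaching support 0.30 in at least one group;
each gets per-group Wilson 95% intervals, a pooled two-proportion z test
(no continuity correction), and BH adjustment **across the candidate
set**; retention requires both the support rule and adjusted p < 0.05.
Single-state patterns are excluded from results but seed the levelwise
growth.

**State distributions.** Sequences are right-padded with a BLANK filler
state to the cohort maximum length and tabulated positionwise;
`autoplot()` renders the stacked-area distribution plot.

## Micro-level analytics

**Entropy.** For each student, the relative frequencies of the distinct
micro behaviors are treated as probabilities and Shannon entropy
H = −Σ p log2 p (bits, 0 log 0 = 0) is normalized by log2 8 = 3, the
maximum over the closed alphabet, giving an index in [0, 1]. Subgroup
means carry percentile bootstrap 95% intervals (2000 resamples of students
within subgroup), and a two-way ANOVA with effectiveness, efficiency and
their interaction reports partial eta squared per term. Type II sums of
squares are used because the 2 x 2 design is unbalanced in realistic
cohorts; with balanced cells Type II coincides with the classical
decomposition, which a test exploits as an oracle.

**Transition models.** Transition counts run over consecutive micro pairs,
with End Task excluded as a source and Start Task as a target (structural
zeros of the grammar). The unsmoothed estimate is the conditional relative
frequency. For subgroup models, a hierarchical Dirichlet–multinomial
scheme shrinks each row toward the *global* matrix pooled over the full
sample: with concentration α = 0.5 (read as the **total prior mass per
row**, split proportionally to the global row — not a per-cell
pseudo-count), the smoothed row is the posterior mean
(count + α · prior) / (n + α). α → 0 recovers the raw estimate; α → ∞
converges to the prior; rows with no data and no prior are flagged
undefined rather than invented.

**Delta probability maps.** Students are resampled with replacement
independently within each subgroup (1000 resamples); smoothed matrices and
their difference are recomputed per resample with the **global prior held
fixed** — the texts this follows are silent on whether the prior should be
re-derived per resample, and fixing it isolates subgroup variability,
which is the quantity of interest. Percentile 95% intervals (not BCa; no
stronger claim than "bootstrap confidence intervals" is warranted) flag a
cell significant when its delta interval excludes zero. Process graphs
display only edges with probability at or above 0.30, optionally coloured
green/red by which subgroup a significant delta favours, and serialise to
DOT and JSON.

## Pipeline, seeding and reproducibility

`run_pipeline()` executes simulate → code → profile → macro → micro →
report and writes every artifact as fixed-format text (CSV, JSONL, JSON,
DOT). A single mandatory seed fans out to per-stage child seeds through a
fixed affine map, so stages are individually reproducible; identical
config and seed give byte-identical artifacts, which a test asserts
file-by-file. Configuration is YAML with the documented defaults (support
0.30, pattern length cap 4, α = 0.5, 1000/2000 bootstrap resamples, edge
threshold 0.30, FDR 0.05, K up to 4, seed 0); unknown keys and
out-of-range values are rejected with the offenders named, and a support
threshold of zero is refused outright because the candidate space is no
longer usefully bounded.

## Problem sizes used in tests

The shipped tests run cohorts of 20–1000 simulated students, mixture
recovery at n = 86–200, transition recovery at n = 200–1000, bootstrap
checks at 200–1000 resamples with subgroups of 150, and an end-to-end
pipeline of 76 students at 60 resamples. These sizes were chosen so every
statistical check retains comfortable power while the whole suite stays
quick on a single CPU.

## Known limitations

* The miner targets a small closed alphabet; it enumerates rather than
  maintains ID-lists, so very long alphabets or pattern lengths would need
  a different engine.
* Transition models are strictly first-order and time-homogeneous; no
  semi-Markov or hidden-state structure.
* Efficiency profiling is univariate by design (completion time only); no
  covariance-structured mixtures.
* The simulator certifies estimators under the analysis model's own
  assumptions; conclusions about real student populations require real
  logs, which the pipeline ingests through the same `code_events()` entry
  point.

## A worked micro-example

```{r example}
task <- hpp_task()
rotation_speed(task, "Medium", "120")

cohort <- generate_cohort(builtin_profiles(), n = c(14, 3, 29, 4), seed = 0)
coded <- code_events(cohort$events)
sg <- performance_subgroups(coded, final_answers(cohort$events), seed = 0)
dplyr::count(sg$assignments, effectiveness, efficiency)

est <- estimate_transitions(coded)
round(est$probs["Adjust Diameter", ], 2)
```
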