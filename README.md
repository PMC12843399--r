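# inquiryflow

Multi-level process mining of event logs from simulation-based
scientific-inquiry tasks, for researchers in learning analytics and
psychometrics who work with interface-level process data.

In a structured experimentation task (the *Hydroelectric Power Plant*
task), students manipulate a gate position (Low/Medium/High) and an inlet
diameter (40/80/120 cm), run trials that return the water wheel's rotation
speed, and must submit the unique condition that maximises speed below a
400 rpm safety limit, together with its exact speed. Every interface
action is logged. `inquiryflow` takes such logs from raw events to
reported statistics:

* **Coding.** Events become parallel micro-level (8 codes: Adjust Gate,
  Adjust Diameter, Run Trial, Initial Answer, Revise Answer, Remove
  Record, Start Task, End Task) and macro-level (START, DESIGN, CONDUCT,
  ANSWER, MANAGE, END) behavior sequences; consecutive answer edits
  collapse into answer episodes.
* **Performance subgroups.** Effectiveness is dichotomous task
  correctness; efficiency is a latent profile from a univariate Gaussian
  mixture on completion time (EM; K chosen by minimum BIC with 3K − 1
  parameters; the faster component is *Efficient*), validated by
  median/tertile sensitivity splits and the PDR behavioral proxy (the
  share of Adjust Diameter → Run Trial transitions).
* **Macro analytics.** Per-behavior Poisson rate models
  `count ~ group + offset(log length)` with HC3-robust Wald intervals
  (incidence rate ratios), positionwise state-distribution plots, and
  frequent-subsequence mining (order-preserving, gap-tolerant, lengths
  2–4, support ≥ 0.30 in at least one group) with Wilson 95% intervals,
  pooled two-proportion z tests and Benjamini–Hochberg adjustment.
* **Micro analytics.** Normalized Shannon entropy
  H/log2(8) = −Σ p·log2 p / 3 with 2000-resample bootstrap intervals and a
  two-way ANOVA (partial η²); first-order Markov transition models
  P(t|s) = count(s,t)/Σ count(s,·) smoothed toward the pooled matrix by a
  Dirichlet–multinomial posterior mean with per-row concentration α = 0.5;
  1000-resample bootstrap delta probability maps between subgroups; and
  process graphs keeping edges with Pr ≥ 0.30 (DOT/JSON serialisation,
  ggplot rendering).
* **Simulator.** An agent-based generator produces raw event logs from
  parameterised first-order behavioral profiles with known ground truth
  (four built-in presets spanning the 2 × 2 performance design), so every
  stage can be exercised and tested without classroom data.

## Worked example

```r
library(inquiryflow)

task <- hpp_task()
rotation_speed(task, "Medium", "120")
#> [1] 309     # the optimal condition's speed; 438 at High/120 breaks the limit

cohort <- generate_cohort(builtin_profiles(), n = c(72, 14, 152, 22), seed = 0)
coded  <- code_events(cohort$events)
sg     <- performance_subgroups(coded, final_answers(cohort$events), seed = 0)
dplyr::count(sg$assignments, effectiveness, efficiency)
#>   effectiveness efficiency      n
#> 1 Effective     Efficient      69
#> 2 Effective     Inefficient    15
#> 3 Ineffective   Efficient     157
#> 4 Ineffective   Inefficient    19
```

84 of 260 simulated students (32%) submit the correct triple, and within
each effectiveness group the mixture model resolves the two seeded pacing
profiles. The selected Effective-group model:

```r
glance(sg$gmm[["Effective"]])
#>       K logLik   AIC   BIC mean_max_posterior     n
#> 1     2  -434.  878.  890.              0.927    84
```

K = 2 wins on BIC and students are assigned with mean maximum posterior
0.93 — high classification certainty. Entropy, in contrast, barely
separates the subgroups (means 0.74–0.78 on the 0–1 normalized scale, all
partial η² < 0.003), the expected behavior when groups differ in how they
*order* behaviors rather than in which behaviors they use:

```r
ent <- dplyr::left_join(entropy_by_student(coded),
                        sg$assignments[, c("student_id", "effectiveness", "efficiency")],
                        by = "student_id")
entropy_group_comparison(ent, B = 2000, seed = 0)$anova
#>   term                     statistic p.value partial_eta_sq
#> 1 effectiveness              0.00972   0.922      0.0000380
#> 2 efficiency                 0.706     0.402      0.00275
#> 3 effectiveness:efficiency   0.482     0.488      0.00188
```

The ordering differences show up in the transition models and delta maps
instead (`estimate_transitions()`, `bootstrap_deltas()`,
`build_process_graph()`), and `run_pipeline(load_config())` writes the
whole artifact set — assignments, model-selection table, rate models,
pattern table, state distributions, entropy summary, smoothed transition
matrices, delta maps and DOT process graphs — from one seeded
configuration. A thin command-line wrapper lives at
`inst/scripts/inquiryflow-pipeline.R`.

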