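---
title: "Modelling stake-dependent arbitration between model-based and model-free control"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling stake-dependent arbitration between model-based and model-free control}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(stakerl)
```

## The scientific question

People can solve sequential decision problems in two ways: a cheap,
habit-like *model-free* strategy that caches action values learned from
reward history, and a costly, deliberate *model-based* strategy that
plans through the structure of the task. Healthy adults shift toward
model-based control when more reward is at stake; a failure to make that
shift — impaired *metacontrol* — is a candidate mechanism for maladaptive
decision making in populations such as frequent alcohol users. `stakerl`
provides the full computational tool-chain for studying this question
with a stakes-modulated two-step task: a generative task environment, two
behavioural models with their fitting machinery, a synthetic-cohort
generator with known ground truth, and the group-level statistics.

## The task environment

`task_config()` describes the task. Each trial:

1. A cue announces the stake. With probability `p_high_stake` (default
   0.5) the trial is *high stakes* and second-stage points are multiplied
   by `stake_multiplier` (default 5); otherwise they are paid unchanged.
2. The trial starts in one of two first-stage states (fair coin by
   default), each showing two spaceships.
3. The chosen spaceship flies *deterministically* to the red or the
   purple planet. Both start states offer the same red/purple choice —
   this equivalence is what lets a model-based learner transfer
   experience across states. A stochastic transition matrix can be
   supplied for generality (`deterministic_transitions = FALSE`), but the
   deployed task is deterministic.
4. The planet pays `payoff` points. Each planet's payoff follows an
   independent Gaussian random walk (step SD `drift_sd = 2` points) with
   reflecting boundaries on `[0, 9]`, rounded to whole points; initial
   payoffs are uniform within the bounds. The walk keeps the planets'
   relative worth changing so that neither system can stop learning.

Values the task description fixes (200 trials, 50/50 stakes, the ×5
multiplier, the 0–9 point range) are defaults; values it leaves open
(drift SD, start-state probability, initial payoffs, key layout) are
configurable with the defaults above, chosen to match the task lineage
this design comes from. The response key is tied to screen position;
by default action A sits on the left key, with `randomize_keys = TRUE`
shuffling positions per trial.

```{r walks, fig.width = 6, fig.height = 3}
plot_reward_walks(generate_reward_walks(task_config(), seed = 1))
```

## The dual-system model

The model-free system is SARSA(λ) over four first-stage state–action
pairs and the two planets (one forced action each). Eligibility traces
are zeroed at trial start; the chosen pair's trace is incremented before
each update and all traces decay by λ after each update. The first-stage
prediction error is purely bootstrapped, δ₁ = Q(planet) − Q(s₁,a₁)
(no reward arrives at stage 1), and the second-stage error is purely
reward-driven, δ₂ = r − Q(planet). With λ = 0 only the planet value
moves; with λ = 1 the first-stage pair receives the full second-stage
error.

The model-based system computes Q_MB(s₁,a) by propagating planet values
through the transition structure — with deterministic transitions, a
lookup shared by both start states. Choice mixes the two systems,
Q_net = ω·Q_MB + (1−ω)·Q_MF, with ω = ω_low on low-stakes and ω_high on
high-stakes trials; Δω = ω_high − ω_low indexes arbitration flexibility.
The softmax adds perseveration terms: `rep(a)` marks the action leading
to the previously chosen planet (choice identity travels with the
destination, because the start states are equivalent), `resp(a)` marks
the previously pressed key, and the logit is β·(Q_net + π·rep + ρ·resp).
Only the first-stage choice enters the likelihood — the planet stage has
a single forced action.

Two conventions deserve note, both configurable:

* **Learning signal.** The model equations contain a single reward `r`
  with no multiplier, and stake effects enter through ω alone, so by
  default the learner sees the *base* (unmultiplied) points;
  `task_config(learning_reward = "delivered")` switches to the ×5 signal
  for sensitivity analyses.
* **ρ's prior.** The parameter list assigns ρ both to the unit-interval
  Beta(2,2) family and to the N(0,1) stickiness family; the stickiness
  reading (unbounded, N(0,1)) is the default, and
  `hybrid_priors(rho_prior = "beta")` selects the bounded reading.

### MAP estimation

`fit_hybrid_map()` maximises likelihood × prior with Beta(2,2) priors on
α, λ, ω_low, ω_high, a Gamma(3, 0.2) prior on β and N(0,1) priors on π
and ρ. The Gamma hyperparameters are read as shape–scale (prior mode
(3−1)·0.2 = 0.4), the convention of the fitting toolbox this prior set
comes from; `gamma_parameterisation = "rate"` gives the shape–rate
reading. Optimisation is bounded L-BFGS-B restarted from `n_restarts`
prior draws (default 100), keeping the best posterior; ties go to the
first occurrence. Because the Beta densities vanish at 0 and 1, the box
bounds are pulled 10⁻⁶ inside the support so the objective stays finite;
β is capped at 30 and the stickiness box at ±10, far beyond any mass of
their priors. On an empty session the fit returns the analytic prior
modes (0.5, 0.4 and 0), a useful end-to-end check of the machinery.

`fit_exhaustive_map()` fits the 12-parameter variant in which every
parameter has a low- and a high-stakes value, evaluated over a single
shared value table with the trial's stake selecting the parameter set;
with tied values it reproduces the 7-parameter likelihood bit for bit.

## The risk-sensitive utility model

The utility model asks a different question of the same choices: how
much does estimated outcome *variance* deter (or attract) the subject?
Expected returns R(s,a) for first-stage pairs and planets are learned by
temporal-difference updates whose errors are clipped to
±δ_limit, with the planet value backed up to stage 1 through the
discount Γ. The risk table h(s,a) — first-stage pairs only, as the
forced second stage carries no risk trade-off — moves toward the squared
clipped first-stage error with the same learning rate (a convex
combination, so h never goes negative). Choice is a softmax over
U = R − μ·sign(R)·√h, with sign(0) defined as 0. Positive μ penalises
variance on gains (risk aversion); negative μ rewards it.

No canonical equation set pins down the R and h updates for this task
variant; the implementation follows the established utility-formulation
lineage this model descends from (clipped TD errors, risk
prediction error ξ = δ² − h, shared η) and isolates every piece inside
`utility_update()` so an alternative rule can be swapped in. Whether Γ
acts between stages or across trials is likewise unstated; it is applied
between stages here. The utility learner sees the *delivered* points by
default — stake-dependent risk is the phenomenon of interest, and the
×5 trials genuinely carry larger variance — with `reward_signal =
"base"` available.

`fit_utility_ga()` estimates (μ, β, η, Γ, δ_limit) by maximising the
choice log-likelihood with a real-valued genetic algorithm (population
1000, 100 generations by default). Hyperparameters the description
leaves open are set to standard values and exposed in `ga_config()`:
tournament size 3, uniform crossover at rate 0.5, Gaussian mutation with
SD 10% of each bound width at per-gene rate 0.2, elitism of 5. Fits are
produced separately for low- and high-stakes trials: the learning
dynamics always run over *all* trials in order (experience is
continuous), and only the likelihood sum is filtered, so the low and
high log-likelihoods add up to the unfiltered one. Fitting on a frozen
discontinuous subset instead would break that additivity and is not the
default. μ is bounded to [−2, 2] by default, admitting both risk-averse
and risk-seeking subjects.

## The synthetic cohort

`generate_cohort()` produces two-group cohorts of simulated subjects
with known ground truth, the package's substitute for participant data.
Per-subject parameters are independent truncated-Gaussian draws from
group presets stored in `inst/extdata/cohort_presets.json`:

* **Hybrid preset.** Non-users: ω_low ≈ 0.35, ω_high ≈ 0.55 (flexible
  arbitration, Δω ≈ 0.2); users: ω_low ≈ ω_high ≈ 0.45 (no
  arbitration). Shared: α ≈ 0.5, β ≈ 1.0, λ ≈ 0.5, small stickiness.
* **Utility preset.** Both groups more risk-sensitive on high stakes,
  with a smaller user-group high-stakes μ (non-users 0.2 → 0.8, users
  0.3 → 0.5).

The ω means encode the qualitative group contrast under study; the
remaining locations and scales were fixed once so that the full pipeline
(simulate → fit → mixed ANOVA) detects the stakes-by-group interaction
on ω with roughly 80% power at 40 subjects per group, which is the
calibration the cohort design targets. Subject-level seeds derive from
the group seed and subject index by a fixed splitting rule, so any
subject can be regenerated alone.

What the generator does *not* emulate: reaction times, attention or
motivation lapses, questionnaire-driven heterogeneity beyond an optional
group-shifted `severity` covariate, and any within-session
non-stationarity of parameters. Passing recovery and power checks on
these agents therefore shows the estimation and inference machinery is
sound — not that real subjects satisfy the models.

## The statistical layer

`mixed_anova_2x2()` treats stakes as within-subject and group as
between-subject: each subject contributes one low- and one high-stakes
estimate, so every effect is tested on (1, n − 2) degrees of freedom
(via `stats::aov` with a subject error stratum); partial η² is each
effect's share of its error stratum. `rank_tests()` reports the
Mann-Whitney and Wilcoxon signed-rank batteries with tie-corrected,
continuity-corrected normal z statistics (`stats::wilcox.test` serves as
the cross-check oracle in the tests, and all-tied inputs yield a
degenerate flag, never a crash).
`spearman_with_bonferroni()` always reports the family size next to the
adjusted p, since Bonferroni families are analysis choices.
`fisher_z_compare()` implements the atanh-based comparison of two
independent correlations. `split_session_halves()` /`split_half_refit()`
implement the two standard split schemes — first/second hundred trials
and odd/even trials, the first half taking the extra trial at odd counts.

## Numerical choices and scale of the shipped experiments

Softmaxes are evaluated with max-subtraction; the likelihood core is
compiled (C++) and shared by both the hybrid and exhaustive variants, so
per-subject MAP fits take a fraction of a second and cohort-scale
experiments run on one CPU. Q values initialise at 0 and payoffs stay on
the raw 0–9 point scale. The test suite exercises the pipeline at the
sizes the analyses use: 50 prior-drawn agents for hybrid recovery
(Spearman ≥ 0.5 required for α, ω_low, ω_high), 20 agents at μ = ±0.8
with a reduced genetic algorithm (population 100, 30 generations) for
sign recovery, 20 seeded end-to-end runs at 40 subjects per group for
the interaction power check (5 restarts per subject fit), and 40
subjects for split-half reliability.

Two experiment-design notes. First, the power check's null arm (Δω = 0 in
both groups) verifies calibration: its detection rate must stay at the
nominal 5% within binomial error. Second, split-half reliability of ω is
measured on agents whose mixing weights span the unit interval with
nuisance parameters at moderate consistent-responder values (β = 1.5):
reliability of a specific parameter is a property of the estimator along
that parameter's axis, and a population whose ω barely varies (or whose
choices are near-random under a prior-typical β ≈ 0.6) has almost no
between-subject ω signal for halves to agree on — with 100-trial halves
of this deterministic-transition task, between-half correlations are then
structurally low, a genuine limitation worth knowing about rather than a
fault of the refitting machinery.

## Known limitations

* The deterministic-transition design makes model-based and model-free
  values similar once learning settles, so ω is weakly identified in
  short sessions; estimates shrink visibly toward the Beta(2,2) prior
  mode at 100 trials.
* λ recovers poorly at 200 trials (its likelihood contribution is
  subtle); group analyses here rest on ω and μ, which recover well.
* The utility model's update rule follows its lineage, not a fixed
  canonical equation set; conclusions tied to its internals (rather than
  to μ's ordering) should be drawn cautiously. Verbal glosses of the
  sign(R) term sometimes describe it as shrinking the estimate for
  positive R, which disagrees with the formula's arithmetic for μ > 0;
  the formula is what is implemented.
* No hierarchical (group-level) Bayesian fitting and no model-evidence
  comparison are provided; fits are per subject, as in the analysis this
  package supports.
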