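---
title: "Methods: design, simulation and estimation in vaxdce"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: design, simulation and estimation in vaxdce}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

## Scope

`vaxdce` implements a complete discrete choice experiment (DCE) pipeline for
vaccine-preference studies: a seven-attribute vaccine grid (effectiveness,
duration of protection, number of injections, common side effects, risk of
serious side effects, origin, cost per injection in INR), D-optimal paired
choice-set construction, a synthetic respondent generator, conditional-logit
estimation, willingness-to-pay (WTP) and relative attribute importance
(RAI) post-estimation metrics, and opt-out-based vaccine-hesitancy
analysis. The default parameterisation emulates a large nationwide Indian
COVID-19 vaccine DCE (10,000 respondents, 8 design blocks of 5 tasks plus a
trap task); no real survey data ships with or is needed by the package.

## The choice model

Within a choice set of alternatives with coded attribute rows $x_j$, a
respondent picks alternative $j$ with conditional-logit probability

$$P(j) = \frac{\exp(x_j^\top\beta)}{\sum_k \exp(x_k^\top\beta)}.$$

Categorical attributes are dummy-coded against reference levels (50%
protection, 6 months, three injections, no common side effects,
1-in-one-crore risk, imported product); cost is continuous in INR with
"Free" = 0. The opt-out ("neither vaccine") alternative has all attribute
columns zero plus, by default, an alternative-specific constant (ASC)
column. The study being emulated never states how the opt-out entered its
model; the ASC default is the standard treatment, and
`code_dataset(include_optout_asc = FALSE)` and `drop_optout = TRUE` expose
the two plausible alternatives so the ambiguity can be explored rather
than silently resolved.

Estimation (`fit_clogit`) is a from-scratch Newton-Raphson on the grouped
log-likelihood with log-sum-exp stabilisation, step-halving, convergence at
gradient max-norm $< 10^{-8}$, and covariance from the inverse observed
information. Standard errors are classical (the emulated study reports
plain conditional-logit SEs); a cluster-robust sandwich by respondent is
available via `vcov_cluster` but is not the default. Trap tasks are
excluded from estimation: each respondent contributes their five
experimental tasks only.

## Design construction

The full factorial over the grid has $3\times4\times3\times3\times2\times2
\times6 = 2592$ profiles and $2592\cdot2591/2 = 3{,}357{,}936$ unordered
pairs. Enumerating that pair space per exchange step is infeasible, so
`candidate_pairs` draws a seeded uniform sample of distinct pairs (default
budget 100,000 in the pipeline) and `d_optimal_select` runs a modified
Fedorov exchange on it: start from a seeded random subset of `n_sets`
pairs, and repeatedly replace one included task by the excluded candidate
that most increases $\log\det M(\beta_0)$, where $M$ is the accumulated
conditional-logit Fisher information, stopping after a full pass with no
improvement above $10^{-10}$ (ties rejected to guarantee termination).

Construction uses $\beta_0 = 0$ (a utility-neutral design, as in the
emulated study). At $\beta_0 = 0$ a two-alternative task contributes the
rank-one information $\tfrac14\,\Delta x\,\Delta x^\top$ with $\Delta x$
the coded difference of its profiles, so swaps are evaluated with exact
rank-two determinant-update formulas rather than refactorisations. The
design-stage model deliberately uses the two vaccine alternatives only
(the opt-out row carries no attribute contrast at $\beta_0=0$ beyond a
probability rescaling, and the emulated study's sample-size arithmetic
also treats tasks as two-alternative). A ridge of $10^{-8}$ on the
information diagonal is used inside the search only, so the exchange can
pass through singular intermediate designs; the returned
`criterion_value` is ridge-free and an error is raised if the final design
is singular. The exchange is a reconstruction: the original study states
only that a D-optimality algorithm with zero coefficients produced 40
random pairwise choice sets, not which algorithm variant.

The 40 selected sets are randomly partitioned into 8 blocks of 5
(`assign_blocks`), checked by a Pearson goodness-of-fit test
(`block_balance_test`). A fixed trap task (`trap_task`) is appended,
unblocked, and shown to every respondent: vaccine A dominates vaccine B on
every attribute with a stated preference direction, with origin held equal
on both sides. Dominance (`is_dominant_pair`) uses per-attribute partial
orders: effectiveness and duration increasing, injections, serious risk
and cost decreasing, "no common side effects" strictly preferred to
either side-effect profile (local vs systemic incomparable), and origin
incomparable a priori. Incomparable attributes must be *equal* for a pair
to count as dominant. Whether the original survey used one fixed trap pair
for all respondents or block-specific traps is not stated; a single fixed
pair is the simpler reading and is what the package builds.

## The synthetic world

`sim_config()` fixes the stated world; its defaults are the published
conditions, not tuning knobs:

* **True part-worths** default to the published main-effects coefficients
  (`published_part_worths()`). The cost slope is $-0.000649$ per INR, the
  value implied by the published WTP ratios; the printed $-0.0006$ is a
  rounded display value and would distort every WTP by ~8%.
* **Covariates** are sampled independently at the published marginal
  prevalences (61.03% male, 58.23% city, 14.8% healthcare workers, SES
  upper/middle/lower 3.56/53.69/42.74%, comorbidity rates of a few
  percent, age normal (36.32, 12.61) truncated at 18). Only marginals were
  published, so no dependence structure (copula) is imposed.
* **Hesitancy.** Each respondent gets a propensity
  $\pi_i = \mathrm{logit}^{-1}(c + z_i^\top\gamma)$ with $\gamma$ the
  published adjusted log odds-ratios (hypertension, which had no reported
  adjusted estimate, defaults to null) and the intercept $c$ calibrated by
  root-finding so that $\bar\pi$ equals the published hesitant fraction
  15.92%. A latent hesitancy-prone class is drawn as
  $H_i \sim \mathrm{Bernoulli}(\pi_i)$ and class members receive an
  opt-out utility increment (`hesitant_optout_shift`, default 4). The
  shift multiplies the class indicator, not the propensity itself: with a
  continuous $\mathrm{shift}\cdot\pi_i$ bump the realised hesitant
  fraction lands near 3% instead of ~16% and the covariate-hesitancy
  association is irrecoverably attenuated, defeating both stated
  calibration targets. The default shift of 4 makes a class member's
  per-task opt-out probability roughly 0.5-0.8 against typical task
  utilities, which reproduces a realistic spread of opt-out counts (few
  all-six opt-outs) rather than an all-or-nothing pattern.
* **Opt-out ASC.** With `optout_asc = NULL` (default), the ASC is
  calibrated at simulation time (`calibrate_optout_asc`) so the expected
  population share of opt-out task responses equals 15.78%, averaging over
  tasks, respondents, the latent class, and the inattentive mixture.
* **Inattention.** With probability `p_inattentive` (default 0.10) a
  respondent answers *every* task uniformly at random over the three
  alternatives, and thus fails the trap with probability 2/3. Attentive
  respondents are probabilistic logit choosers everywhere, including the
  trap, so attentive trap failures occur at the rate the model implies;
  `deterministic_trap = TRUE` forces attentive respondents to pass.

Choices are drawn via the Gumbel-argmax representation of the logit, all
randomness flows from the config seed (sub-streams use fixed offsets), and
the caller's RNG state is restored afterwards.

**Trap rule.** `apply_trap_filter` by default counts an opt-out answer on
the trap as a failure, alongside choosing the dominated vaccine. The
emulated study's own tally of respondents opting out on all six pairs
among the trap-passed sample implies the opposite convention (an opt-out
on the trap was evidently not an exclusion there); the package keeps the
strict rule as the documented default and exposes the permissive variant
as `optout_fails = FALSE`. A consequence of the strict rule plus the
hesitancy class is that the simulated failure rate (~19% at default
settings) exceeds the study's reported 12.41%: hesitancy-prone respondents
legitimately choose the opt-out on the trap and are filtered. This is a
property of the stated world and is left as-is rather than re-tuned.

**What a green test does not establish.** The generator emulates marginal
prevalences, a logistic hesitancy structure, and logit choice behaviour.
It does not emulate covariate dependence, nonresponse, language arms,
block-demographic interactions, or any behavioural pattern beyond
inattention and opt-out shifting, so recovery tests validate the
estimation machinery against the stated model, not the published
coefficients themselves - those are not reproducible without the real
data.

## Post-estimation metrics

**WTP.** For a level with coefficient $\beta_\ell$,
$\mathrm{WTP} = -\beta_\ell/\beta_{cost}$ in INR. Intervals use the delta
method over the $2\times2$ sub-covariance with gradient
$(-1/\beta_{cost},\ \beta_\ell/\beta_{cost}^2)$; the study does not name
its interval method, so a parametric bootstrap (multivariate-normal
coefficient draws) is offered as a cross-check and agrees with the delta
method to a few percent at realistic covariance scales. USD figures use
the fixed study-period rate of 77 INR/USD (configurable).

**RAI.** Each categorical attribute's utility range is
$\max(0, \beta_{\ell_1}, \dots) - \min(0, \beta_{\ell_1}, \dots)$ (the
reference level contributes 0); RAI is the range as a share of the summed
ranges. Cost is excluded by default: a "range" for a continuous attribute
is ill-defined without an arbitrary span, and exclusion exactly reproduces
all six published RAI percentages from the published coefficients (54.2,
20.6, 12.6, 6.6, 3.4, 2.6) - which pins down that the original
computation excluded cost too.

**Hesitancy.** `score_optout` counts opt-out answers per respondent over
all six tasks (trap included, matching the published "six vaccine pairs"
denominator; configurable to 5) and flags respondents at $\ge 3$ as
hesitant. Univariate analysis uses $2\times2$ odds ratios with Woolf
intervals; the multivariate analysis is a from-scratch IRLS logistic
regression with age continuous and SES as two dummies against the lower
class. In `run_study`, binary predictors with an empty outcome cross-cell
(whose MLE diverges) are dropped with a warning - mirroring the emulated
study, which entered hypertension but reported no adjusted estimate for
it.

## Numerical choices and degenerate inputs

* Newton step-halving triggers on any non-improving step; coefficients
  drifting beyond $10^3$ (clogit) or 30 (logistic) raise a separation
  error naming the offending column.
* `clogit_loglik` is finite for all finite coefficients (log-sum-exp).
* Exchange ties ($\Delta\log\det < 10^{-10}$) are rejected; the criterion
  trace is strictly increasing across accepted swaps.
* `two_by_two_or` errors on zero cells unless the Haldane-Anscombe 0.5
  correction is requested.
* All seeded operations restore the caller's RNG state; rerunning any
  stage with the same seed is byte-reproducible.

## Scaled-down checks

The test suite keeps runtime within CI budgets by scaling simulations
down, never by weakening assertions: the Wald-coverage study uses 100
replicates at n = 500 (pooled coverage bounded in [90%, 99%]); the
cross-check against `survival::clogit` uses 20 seeded datasets of 60
respondents; design-search tests use candidate samples of 600-2000 pairs
instead of the pipeline default 100,000. The full-size pipeline
(`cli_run_all` at n = 10,000 with 100,000 candidates) runs in well under
five minutes on one CPU.

## Known limitations

* The Fedorov exchange optimises over a sampled candidate set; the
  resulting design is near-optimal for the sample, with no global
  optimality claim over all 3.36M pairs.
* Bayesian/nonzero-prior efficient designs, level-balance constraints,
  mixed logit, nested logit and latent-class models are out of scope.
* The univariate odds ratio for continuous age requires a logistic fit on
  respondent-level data and has no closed 2x2 form; `univariate_or_table`
  therefore covers binary predictors only.
* Hesitancy burden estimated from repeated opt-outs is design-dependent
  and not comparable to survey-scale hesitancy instruments.
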