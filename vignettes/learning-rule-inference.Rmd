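---
title: "Inferring learning rules from trial-by-trial choice data"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Inferring learning rules from trial-by-trial choice data}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(pgrule)
```

## The problem

When an animal learns a two-alternative forced-choice task from scratch, its
trial-by-trial choices carry information not only about *what* it has
learned but about *how* it learns: which feedback events move its internal
policy, by how much, and in which direction. `pgrule` treats the learning
rule itself as the estimand. Given a trial table (stimulus contrasts,
choices, rewards, session boundaries), it fits a parametric family of
reinforcement-learning rules to a single animal's trajectory and asks which
member of the family — and which parameter values — best explain the
observed choice sequence.

## Model

**Policy.** The per-trial decision is Bernoulli with logistic link,
$p(y_t = R \mid w_t, x_t) = \sigma(w_t^\top x_t)$, over five covariates:
a constant bias, left and right stimulus contrast (raw fractions in
$[0, 1]$; a monotone transform hook exists but the default is identity —
nothing in our validation suggested a transform is needed for synthetic
data), the previous choice and the previous correct side, both coded
$L = -1$, $R = +1$ and reset to 0 at session starts so the trial count is
preserved. The $L/R \mapsto \mp 1$ coding makes $\mathrm{sign}(y_t) = y_t$
a literal factor in the update below.

**Learning rule.** The weights evolve by a REINFORCE-style policy-gradient
step with per-regressor parameters (products elementwise):

$$
w_{t+1} = w_t
  + \alpha \odot (r_t - \beta)\,(1 - p(y_t \mid w_t, x_t))\, y_t\, x_t
  - Q \odot w_t + \epsilon_t,
\qquad \epsilon_t \sim \mathcal N(0, \mathrm{diag}(\sigma_t^2)),
$$

with $\sigma_t = \sigma_{day}$ on the transition from a session's last trial
into the next session's first trial and $\sigma$ otherwise. The REINFORCE
term is an unbiased single-sample estimate of the gradient of expected
reward; subtracting any baseline $\beta$ leaves its expectation unchanged
(a variance-reduction device), but a *negative* baseline changes the
trial-by-trial dynamics qualitatively — incorrect trials then reinforce the
erroneous choice, producing consecutive errors and a measurable drop in
expected reward after an error (`reward_after_error()`). Weight decay $Q$
models forgetting. The `dynamic_rate` variant multiplies the learning term
by a latent scalar gate $\alpha_t$ with Gaussian random-walk prior
($\alpha_1 \sim \mathcal N(\alpha_0, \sigma_\alpha^2)$, innovations
$\sigma_\alpha$), inferred jointly with the weights; `dynamic_baseline`
does the analogous thing for $\beta_t$.

**The TDRL alternative.** The contrasting action-value model receives a
noisy percept $m_t \sim \mathcal N(s_t, \sigma_m^2)$ of the signed contrast
$s_t = c_R - c_L$ and chooses right when $m_t$ exceeds the value-determined
criterion $\sigma_m \Phi^{-1}(V_L / (V_L + V_R))$. Marginalizing the percept
gives the probit choice rule
$p(R \mid V, s) = \Phi(s/\sigma_m - \Phi^{-1}(V_L/(V_L+V_R)))$ — a GLM in
$s/\sigma_m$, so the two model classes are policy-equivalent and differ
only in their latent update rules. The chosen value updates with a
belief-weighted prediction error
$V_y \mathrel{+}= \eta\,[r - V_y \Phi(s/(2\sigma_m))] + V_y\,
\varphi_{\sigma_m}(s)\,\epsilon$: percept noise induces a fluctuation that
grows with the current value and shrinks with contrast, unlike the
trial-independent additive noise of the PG model. The percept-level
stochastic choice mechanism beyond the threshold rule is not fully pinned
down by the sources we model from; we implement a symmetric lapse mixing
the threshold rule with an unbiased coin (`stochasticity`, default 0) and
flag this as an assumption.

## Inference

The weights (and any latent gate/baseline) are integrated out with a
bootstrap particle filter: particles are propagated through the learning
rule *conditioned on the animal's realized choice and reward* — the animal
experienced the trial whether or not we score it, so held-out trials still
drive the dynamics; they are simply not reweighted, and their predictive
probability under the particle mixture is recorded separately. Systematic
resampling triggers at ESS $< n/2$; genealogies are stored so
`smooth_posterior()` can return smoothed trajectories by ancestral-lineage
tracing (a warning fires when fewer than 1% of lineages remain distinct at
the first trial — increase the particle count if smoothed uncertainties at
early trials matter). With all dynamics noise at zero and a point-mass
initial weight the filter is exact and particle-count-independent, which
the test suite exploits as an anchor.

**Maximum likelihood.** The filter's log-likelihood estimate is noisy, so
the optimiser works on a common-random-numbers objective: the filter seeds
are frozen within an optimisation, making the objective deterministic in
the parameters (optionally averaged over `n_rep` seed replicates).
Positivity of $\alpha, \sigma, \sigma_{day}, Q, \sigma_\alpha$ is enforced
by softplus; $\beta$ and $\alpha_0$ are unconstrained. Learning rates are
constrained nonnegative by default (`alpha_positive = FALSE` lifts this).
Nelder–Mead is the default search (BFGS with finite differences is
available), run as a chain of restarts from the incumbent (`n_chain`)
because a single simplex tends to contract prematurely on the jagged CRN
surface; one-dimensional problems switch to Brent automatically.
Multi-start jitters the initial point. `free`, `tie` and `free_idx` allow
profile fits — optimising a subset of parameters with the rest pinned —
which is how the expensive recovery checks are run.

**Posteriors.** `pmmh_sample()` runs particle-marginal Metropolis–Hastings:
Gaussian random-walk proposals in the unconstrained coordinates, a fresh
filter randomisation per proposal, and the likelihood estimate carried with
the chain state (the pseudo-marginal construction that targets the exact
posterior under a flat prior on the unconstrained coordinates — note the
softplus transform therefore implies a non-flat induced prior on the
constrained scale). The proposal scale adapts toward ~25% acceptance during
burn-in, then freezes.

## Learning/noise decomposition

`learning_rollout()` replays the fitted rule through the animal's actual
choices with the noise omitted (using the posterior-mean $\hat\alpha_t$ per
trial for dynamic fits); `update_residuals()` evaluates the rule's update at
the *inferred* weights $\hat w_t$ and defines the residual
$\hat\epsilon_t = (\hat w_{t+1} - \hat w_t) - \Delta^{\text{learn}}_t$. The
**learning fraction** averages the bounded per-trial ratio
$f_t = \lVert\Delta^{\text{learn}}_t\rVert /
(\lVert\Delta^{\text{learn}}_t\rVert + \lVert\hat\epsilon_t\rVert)$.
Two design choices deserve note:

* The per-trial-ratio form is used (rather than a ratio of summed norms,
  available via `method = "ratio_of_sums"`) because it is bounded per trial
  and reproduces the analytic endpoints — exactly 0 for a noise-only model,
  exactly 1 for a noiseless deterministic learner.
* Trials on which *both* norms vanish (below `zero_tol = 1e-12`) are
  excluded from the average rather than scored 0: such trials carry no
  information about the update, and scoring them 0 would make the
  deterministic-learner endpoint depend on how many exactly-zero updates
  (e.g. unrewarded trials under $\beta = 0$) a trajectory happens to
  contain. A trajectory with no informative trials has fraction 0. The
  `zero_tol` floor also absorbs float cancellation when a trajectory is
  reconstructed from its own increments.

$\Delta^{\text{learn}}_t$ is evaluated at the inferred weights for the
fraction (matching its definition against the inferred update), while the
rollout trajectory serves visual decomposition; the projection fraction and
mean cosine similarity are reported alongside as alternates. Cohort
summaries — preferred/non-preferred relabeling by the larger stimulus
learning rate with a parameter-shuffled control, residual-norm versus
$\lVert\sigma\rVert$ consistency, and trial-warped learning-rate trends
with cumulative accuracy — operate on lists of per-animal results;
trial warping is linear time-normalisation to $[0,1]$ plus linear
interpolation (the simplest warp consistent with its purpose of averaging
across animals with different training lengths). Reported
$\Delta\log\hat\alpha_t$ uses a $10^{-6}$ floor before logs, and the
log-difference is invariant to the static rate scale.

## The synthetic-data generator

`simulate_pg()` / `simulate_tdrl()` / `simulate_cohort()` generate the
study conditions: sessions of a few hundred trials; a staged curriculum
that unlocks contrast levels $\{1, 0.5, 0.25, 0.125, 0.0625, 0\}$ at
sessions $\{1, 1, 6, 9, 12, 15\}$ by default (a documented placeholder for
shaping protocols whose exact unlock days vary by lab) or a uniform
schedule with all levels from session 1; stimulus side Bernoulli(0.5) by
default. On zero-contrast trials the correct side is the drawn side, so
reward labels are always defined. Master seeds split into per-animal
streams by a counter scheme, so enlarging a cohort never perturbs earlier
animals.

**Noise scales.** The recovery and acceptance simulations use
$\sigma = 0.05$ per trial, $\sigma_{day} = 0.2$, $w_1 \sim \mathcal N(0,
0.5^2)$. The reasoning: psychometric weights of behaving mice stay of order
one to a few units; a random walk with per-trial SD much larger than
$\approx 0.05$ drifts over $10^4$ trials to $|w| \sim 15$, a saturated
regime where the policy is effectively deterministic, single surprising
choices cost dozens of nats, and the marginal likelihood becomes
pathological — not a regime real training data occupies. Session-boundary
noise is set several-fold larger than within-session noise, reflecting the
overnight resets that motivate a separate $\sigma_{day}$.

**What the generator does not emulate.** Satiety/engagement states,
reaction times, wheel kinematics, block-structured reward probabilities,
and lab-specific curricula. Passing recovery tests on these synthetic
conditions shows the estimator works when the model class is correct; it
does not certify the model class against real mice.

## Problem sizes and numerical choices

The validation battery runs at sizes chosen to keep the full suite
comfortably interactive:

* Filter-versus-quadrature: $T = 8$–$10$, $M = 1$, 200–500 filter
  replicates at 1,000 particles against a 1,200–2,000-point grid
  integration (the oracle shares no code with the filter).
* Noise-scale recovery: $T = 10{,}000$, 1,000 particles, profile fit of
  $(\sigma, \sigma_{day})$ tied across regressors.
* Sign recoveries (side asymmetry, negative baseline) and the dynamic-rate
  step direction: $T = 2{,}000$–$3{,}000$, 250–300 particles, profile fits
  with 30–50 Nelder–Mead iterations (Brent for one-dimensional profiles),
  3–10 replicates. The asymmetry experiment plants its effect in a learner
  with modest weight decay ($Q = 0.01$): without decay the asymmetry is
  expressed only during initial acquisition (weights saturate and the
  $(1-p)$ factor kills the gradient), and the sign of the planted effect is
  genuinely unidentifiable in a substantial fraction of realisations;
  with decay, steady-state stimulus weights scale with $\alpha / Q$ and the
  asymmetry remains identifiable throughout training. The baseline's
  *sign* is recoverable at these sizes but its magnitude is noisy — $\beta$
  is the family's most weakly identified parameter.
* Model-comparison ordering: $T = 2{,}000$, three replicates, 10% held-out
  masks shared across the compared fits; full-trajectory log-likelihood is
  the comparison metric (held-out trials included), as in the fitting
  protocol.

Probabilities are clamped to $[10^{-12}, 1 - 10^{-12}]$ before logs.
Degenerate inputs fail loudly: all-zero particle weights raise an error
suggesting more particles; a trial table whose rewards contradict its
choice/correct-side columns is rejected with the offending row; series of
length one cannot be warped; a cohort of one cannot be shuffled. ESS is
clipped to $[1, n]$ against float round-off. TDRL values are floored at
$10^{-8}$ so the value-ratio criterion stays defined.

## Known limitations

* The bootstrap proposal makes the filter simple and honest but
  Monte-Carlo-hungry in weakly identified regimes; a locally optimal
  proposal would cut likelihood variance substantially.
* Ancestral-lineage smoothing degenerates at early trials for long series;
  smoothed SDs there are flagged, and a backward-simulation pass would be
  the next improvement.
* The full 25-parameter vector-PG MLE is expensive at realistic particle
  counts; profile fits are the intended workflow, mirroring how the
  recovery checks are run.
* Cohort significance helpers are plain one-sample/paired t statistics —
  reporting aids, not a multiple-comparison-corrected inference pipeline.
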