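---
title: "Shaping curricula: models, teachers, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Shaping curricula: models, teachers, and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

This vignette is the package's account of its science: the student and
teacher models, the parameters that matter and why their defaults are what
they are, the places where the design was genuinely open and what we chose,
and what the simulations do and do not establish.

## The shaping problem

A learner that must execute a long chain of actions before any reward is
delivered almost never stumbles on the full chain by chance: the naive
success probability decays exponentially with chain length. Trainers solve
this by *shaping* — rewarding ever-longer prefixes of the behavior. We
study the closed-loop version of this problem: a teacher that observes only
a transcript of successes and failures must choose, interaction by
interaction, which prefix length (difficulty level) to reward, so that the
learner reaches a criterion success rate on the full task as quickly as
possible.

## The student

```{r, eval = FALSE}
student_params(n_steps = 10, eps = -1.5, alpha = 0.1)
```

At step $i$ of an episode the student takes the correct action with
probability $\sigma(q_i + \varepsilon_i)$, where $\sigma$ is the logistic
function. The innate bias $\varepsilon_i$ (log-odds units) encodes how
likely a naive learner is to act correctly: $\varepsilon = -\log(K-1)$ for
a uniform choice among $K$ actions. Only the correct action carries a
learned value $q_i$ (all incorrect actions are pinned at 0, so
$\sigma(q_i+\varepsilon_i)$ is the complete per-step description). An
episode at level $k$ terminates at the first error or after $k$ correct
steps; only full completion is rewarded.

**TD rule.** Values update online, in temporal order, at every correctly
executed step: $q_i \leftarrow q_i + \alpha\,(r_i + V_{i+1} - q_i)$, with
$r_i = r$ at the rewarded step and $V_{i+1}$ the value of the next state
($q_{i+1}$ while the episode is alive, 0 past termination). This is the
minimal tabular rule that produces both waves seen in shaping:

* *reinforcement wave* — value flows backward from the rewarded step, so
  later steps cross any threshold before earlier ones;
* *extinction wave* — immediately after an increment from $k$ to $k+1$,
  the previously rewarded step bootstraps on the untrained $q_{k+1} = 0$
  and loses exactly $\alpha q_k$ on every episode that reaches it,
  regardless of the new step's outcome.

Failed steps update nothing; whether a learner punishes incorrect choices
is left out of the model, and values beyond the assigned level are never
touched.

**Reward magnitude.** Under TD learning $q_i$ can never exceed the
terminal reward $r$, so the trained per-step success probability is capped
at $\sigma(r + \varepsilon)$. A unit reward therefore caps the trained
*full-task* success at $\sigma(1+\varepsilon)^N$ — below any practical
criterion for $N = 10$ even at $\varepsilon = 0$. The reward magnitude is
thus a real model parameter, not a convention. We calibrated the default
once, jointly with the default curriculum settings below, so that the
incremental teacher's failure boundary sits at $\varepsilon \approx -1.7$
(a naive per-step success rate of about 15%): `default_reward()` returns
5.5, whose measured 50% completion crossing is at $\varepsilon \approx
-1.73$. Larger rewards shift the boundary to lower biases (6 gives
$\approx -1.83$), smaller ones to higher; nothing else in the package is
sensitive to the exact value.

## The transcript estimator

The teacher never sees $q$. Each level keeps an exponential moving average
$\hat{s} \leftarrow (1-\beta)\hat{s} + \beta x$ folded outcome by outcome
(default $\beta = 0.1$), plus the per-interaction change
$\Delta\hat{s}$ — the observable proxy for learning progress. Choices made
here, and why:

* **Per-level estimates persist across level changes.** Decrement decisions
  rely on remembered competence at easier levels; forgetting them on every
  move would make every revisit look like a fresh start.
* **First visits start at $\hat{s} = 0$.** The first $\Delta\hat{s}$ at a
  new level is then usually positive, which biases the adaptive teacher
  toward "stay" on fresh levels — the desired behavior while a student is
  still learning.
* $\Delta\hat{s}$ is per-interaction, not smoothed further; smoothing is
  the estimator's job ($\beta$), not the feature's.

With $T = 10$ episodes per interaction and $\beta = 0.1$, the stationary
estimator fluctuates around the true rate with standard deviation
$\approx 0.23\sqrt{p(1-p)}$; the threshold comparisons below are made
against that noise level.

## Teachers

**Incremental (INC).** Increment when $\hat{s} \ge \tau$ at the current
level; never decrement. Ties resolve upward throughout the package
($\ge$ triggers the more aggressive branch). INC is the experimenter's
default and the baseline every other teacher is judged against. Its
failure is abrupt: below a critical bias, post-increment extinction
outruns reinforcement, earlier steps unlearn, and the curriculum stalls —
the completion rate collapses from near 1 to near 0 within ~0.3 log-odds
units.

**Adaptive (ADP).** A two-feature decision tree: increment when
$\hat{s} \ge \theta_{inc}$; otherwise stay while $\Delta\hat{s} \ge \mu$;
otherwise decrement. The two thresholds are tuned by differential
evolution (below) and then frozen; all benchmarks use the shipped defaults
with no re-tuning. The evolved optimum ($\theta_{inc} = 0.54$,
$\mu = 0.1$) is more aggressive than one might hand-design: $\mu$ sits at
the top of its search range, so the teacher drops back whenever visible
progress stalls, producing near-constant alternation between adjacent
levels. That alternation is the mechanism that defeats extinction: a
single interaction at the easier level re-inflates the decayed value, at
the cost of one interaction, which is cheap compared to a stall.

**POMCP.** The teacher's problem is a POMDP: hidden state $(q,
\varepsilon, \alpha)$, observations are outcome blocks, actions are
decrement/stay/increment, unit reward on reaching criterion at the full
task, discount $\gamma = 0.98$. We solve it online:

* *Belief*: a particle filter (default 1000 particles) over
  $(q, \varepsilon, \alpha)$, with uniform priors $\varepsilon \sim
  U(-3, 0)$, $\alpha \sim U(0.01, 0.5)$, constant $\varepsilon$ within a
  particle, and $q = 0$ known at the start of training. Each observed
  outcome multiplies a particle's weight by its predicted probability and
  advances the particle's $q$ along one sampled trace consistent with the
  outcome (failure steps drawn from their exact conditional
  distribution) — unbiased in the particle limit and far cheaper than
  exact trace marginalization. Systematic resampling with Gaussian
  reinvigoration (scales 0.05 on $\varepsilon$, 0.01 on $\alpha$, clipped
  to the prior box) triggers when the effective sample size falls below
  half the particle count.
* *Planning*: Monte Carlo tree search with UCB1 ($c = \sqrt{2}$).
  Observation nodes branch on the block's *success count* ($T+1$
  branches) rather than the $2^T$ ordered sequences — the tree stays
  tractable while the particle filter still consumes the full ordered
  block. The simulated planning state carries the tracker estimate, so
  termination inside the tree mirrors the real loop. Leaves are evaluated
  by a rollout that follows the incremental rule on the simulated
  tracker.

Planning cost grows steeply as success gets rarer; at biases around $-3$
the planner is not expected to be tractable, which is exactly the regime
the cheap adaptive heuristic is for.

**Learning-progress baselines.** Four variants (online, naive, window,
sampling) that assign the level with the steepest estimated slope of its
success curve, re-implemented best-effort from the published
teacher–student curriculum learning heuristics and marked experimental:
the available descriptions leave estimator details open, and our versions
make the simplest choices (EMA'd or regression slopes, $\epsilon$-greedy
or proportional sampling, unvisited levels first).

## Evolving the adaptive thresholds

`evolve_adp_policy()` tunes $(\theta_{inc}, \mu)$ — optionally $\beta$ —
by DE/rand/1/bin (population 16, 40 generations, $F = 0.7$, $CR = 0.9$)
against the mean completion time over a training grid
$\varepsilon \in \{-1, -1.5, -2\}$ × 5 fixed seeds (common random
numbers), with incomplete runs charged twice the budget. The grid spans
the incremental failure boundary on purpose: the optimum must work both
where INC works and where it fails. The initial population contains the
incremental-rule vertex ($\theta_{inc} = \tau$, $\mu$ at its lower bound,
where the decrement branch cannot fire), so with elitist selection the
evolved policy can only match or beat INC on the training grid. The
search bounds are $\theta_{inc} \in (0.5, 0.99)$ and $\mu \in (-1, 0.1)$;
$\mu = -1$ is unreachable by the tracker in one interaction, making the
lower edge a true "never decrement". The winning policy was validated on
held-out seeds before being frozen as the package default. The continuous
teacher's four thresholds are evolved the same way
(`evolve_cont_policy()`).

## The continuous extension

Real curricula can often be subdivided further when a student hits a wall.
The continuous task realizes difficulty $d \in (0, D]$ as a chain of
$\lceil d/\Delta \rceil$ micro-steps (default $\Delta = 0.1$). The
per-micro-step innate success probability is $\sigma(\varepsilon)^\Delta$,
so the naive success probability at difficulty $d$ is exactly
$\sigma(\varepsilon)^d$ on the grid: difficulty is an *intensive* scale,
invariant to how finely the chain is discretized, and $\Delta = 1$
recovers the discrete task bit-for-bit (a property the tests assert under
shared seeds). The alternative of scaling the bias itself by $\Delta$
fails: each extra micro-step contributes $\approx \log 2$ of difficulty
regardless of bias, so refining the grid would make the same nominal
difficulty arbitrarily harder.

The student bootstraps $K$ micro-steps ahead ($K$-step TD); the default
$K = \mathrm{round}(1/\Delta)$ makes the lookahead one difficulty unit,
commensurate with the discrete dynamics. The teacher chooses among nine
actions — {decrement, stay, increment} × {shrink, keep, grow} on the
increment $\delta$, which starts from the experimenter's rough guess
$\delta_0 = 1$, multiplies or divides by $g = 2$, and is clamped to
$[\Delta, 2]$. The tree uses two $\hat{s}$ thresholds and two
$\Delta\hat{s}$ thresholds: increment when $\hat{s} \ge \theta_{hi}$, grow
when $\hat{s} \ge \theta_{grow}$, decrement when $\Delta\hat{s} < \mu$,
shrink when $\Delta\hat{s} < \nu_{lo}$; the operation applies before the
move. After a too-large jump the observed pattern is
decrement-and-shrink, then a smooth climb at the finer increment.

## Numerical and reproducibility choices

* Thresholds compare with $\ge$; level moves clamp to $[1, N]$ and
  out-of-range teacher proposals are clamped and logged.
* Termination is judged on the observable $\hat{s}_N \ge \tau$, never on
  the hidden true success probability; the log records the true
  probability alongside for honest evaluation.
* All randomness flows through R's RNG, including the C++ kernels, so a
  single `set.seed()` makes entire curricula bit-reproducible; benchmark
  sub-seeds are derived from the cell's content (teacher name, bias,
  repeat), so reordering a sweep never changes any individual run.
* Completion time is counted in teacher–student interactions (each is
  $T$ episodes).
* Degenerate inputs: a zero learning rate freezes the student (used by
  calibration tests); belief collapse (all particle weights zero) resamples
  from the prior with a warning; an empty outcome block is an error.

## What the simulations do and do not show

The generator emulates the study conditions: tabular students with
logistic action selection, constant innate bias per student, stationary
parameters, and i.i.d. step noise. It does not emulate real learners'
non-stationarity (fatigue, motivation drift), generalization across
levels, structured errors, or deep-RL function approximation — the teacher
interface is deliberately agnostic to all of these, but passing tests here
demonstrates correctness of the algorithms under the model, not efficacy
on any particular animal or agent.

Problem sizes used by the test suite are chosen to exercise the claims at
meaningful scale while staying quick: the failure-boundary sweep uses the
full 13-point bias grid with 10 seeds (130 curricula); planner–oracle
agreement uses a two-level task where exhaustive expectimax is feasible;
parameter recovery uses 20 seeds of 50 interactions with 1000 particles.

## Known limitations

* The learning-progress baselines are approximations of their published
  descriptions; comparisons against them are indicative, not exact.
* POMCP's observation aggregation (success counts) discards outcome order
  inside a block; the belief update does not. For small $T$ the induced
  value differences are below the planner's Monte Carlo noise.
* The evolved thresholds are optimal only for the conditions they were
  trained on; changing $T$, $\beta$, $\tau$ or the reward magnitude calls
  for re-running the evolution (one function call, about two minutes).
* Single difficulty axis only; multi-skill curricula are out of scope.
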