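# oclr — outcome-based curriculum learning for behavioral shaping

Animal trainers and machine-learning practitioners alike "shape" complex
behavior by walking a learner through a curriculum of progressively harder
tasks. When is that safe, when does it fail catastrophically, and how should
the curriculum react to the learner's record of successes and failures?

`oclr` is a simulation and algorithm library for **outcome-based curriculum
learning (OCL)**: a teacher agent chooses the next task difficulty using
*only* the transcript of binary outcomes — never the learner's internal
state. It is aimed at computational neuroscientists and RL researchers
studying shaping protocols, and at anyone designing closed-loop training
procedures for animals or artificial agents.

## The model

**Student.** A sequence-learning reinforcement learner must execute N
correct actions in order. At step *i* the correct action is taken with
probability σ(qᵢ + εᵢ), where σ is the logistic function, εᵢ is a fixed
innate bias (log-odds of guessing correctly before learning; for a uniform
choice among K actions, ε = −log(K − 1)), and qᵢ is an action value,
initially 0, updated by an online TD(0) rule with learning rate α. The
terminal reward magnitude r bounds the attainable q values (see
`default_reward()`); difficulty level k rewards k correct steps.

Two opposed waves govern the dynamics: a **reinforcement wave** propagating
value backward from the rewarded step, and an **extinction wave** — after a
difficulty increment, the step just mastered bootstraps on the new,
untrained step and decays by αqₖ per completed episode. Shaping succeeds
when reinforcement outruns extinction.

**Teachers.** Each interaction the teacher assigns a level, the student
attempts it for T episodes, and a per-level exponential moving average ŝ
(decay β) tracks the success rate:

* `teacher_inc()` — *incremental*: increment when ŝ ≥ τ; never retreat.
  Collapses catastrophically once ε drops below ≈ −1.7 (a naive per-step
  success rate of ~15%).
* `teacher_adp()` — *adaptive*: a decision tree on (ŝ, Δŝ): increment when
  ŝ ≥ θ_inc, stay while Δŝ ≥ μ, otherwise decrement. Thresholds are tuned
  by differential evolution (`evolve_adp_policy()`) and shipped frozen.
* `teacher_pomcp()` — near-optimal planning: a particle filter infers the
  hidden (q, ε, α) from the transcript and Monte Carlo tree search plans
  over increment/stay/decrement with a unit terminal reward and discount.
* `teacher_rand()` and `teacher_lp()` — random and learning-progress
  baselines (the latter experimental re-implementations of published
  teacher–student curriculum heuristics).

A continuous-difficulty extension (`run_continuous_curriculum()`) replaces
the level grid with a fine micro-step chain, a K-step TD student, and a
nine-action teacher that also grows or shrinks its difficulty increment.

## Worked example

A hard student (ε = −2, below the incremental teacher's failure boundary):

```r
library(oclr)
spec    <- curriculum_spec(n_levels = 10)   # N=10, T=10, tau=0.85, budget 1500
student <- student_params(n_steps = 10, eps = -2, alpha = 0.1)

set.seed(11)
fit_adp <- run_curriculum(teacher_adp(), student, spec)
set.seed(11)
fit_inc <- run_curriculum(teacher_inc(), student, spec)

fit_adp
#> <ocl_curriculum> teacher: adp completed in 241 interactions (N = 10 )
fit_inc
#> <ocl_curriculum> teacher: inc DNF after 1500 interactions (N = 10 )

glance(fit_adp)
#> # A tibble: 1 × 7
#>   teacher completed interactions_used final_level final_s_hat true_p_full
#> 1 adp     TRUE                    241          10       0.872       0.740

table(fit_adp$log$action)
#> DECREMENT INCREMENT      STAY
#>       101       116        24
```

The adaptive teacher finishes in 241 interactions where the incremental
teacher exhausts its whole budget of 1500: `final_s_hat` is the tracked
success estimate on the full task at termination (0.872 ≥ τ = 0.85), and
the action table shows the constant alternation between adjacent levels
(101 decrements) that keeps extinction in check. `autoplot(fit_adp)` draws
the grayscale q-value heatmap with the level trajectory overlaid;
`run_benchmark()` sweeps teachers × biases × seeds into a tidy table.

A thin command-line front end is installed with the package
(`exec/ocl`: `simulate`, `benchmark`, `evolve` subcommands; see
`inst/extdata/benchmark-example.yaml` for the config format).

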