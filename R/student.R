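#' Hidden parameters of the sequence-learning student
#'
#' The student must execute a chain of `n_steps` correct actions to obtain
#' reward. At step `i` the correct action is taken with probability
#' `sigma(q_i + eps_i)`, where `q_i` is a learned action value (initially 0)
#' and `eps_i` is a fixed innate bias in log-odds units: the log-odds that a
#' naive student picks the correct action at that step. Action values are
#' updated by a temporal-difference rule with learning rate `alpha`.
#'
#' @param n_steps Number of steps `N` in the full task (positive integer).
#' @param eps Innate bias. Either a single value, recycled to all steps, or a
#'   vector of length `n_steps`. For a naive student choosing uniformly among
#'   `K` actions, `eps = -log(K - 1)` (see [bias_from_action_count()]).
#' @param alpha Learning rate in `(0, 1]`; `alpha = 0` is allowed and freezes
#'   learning (useful for calibration checks).
#' @param reward Magnitude of the terminal reward, the TD target of the
#'   final step (default [default_reward()]). Because action values cannot
#'   exceed the reward under TD learning, the reward magnitude sets the
#'   ceiling `sigma(reward + eps)` of the trained per-step success
#'   probability and must comfortably exceed `-eps` for the task to be
#'   learnable to criterion.
#'
#' @return An object of class `ocl_student_params`.
#' @seealso [student_state()], [run_episode()], [run_interaction()]
#' @examples
#' student_params(n_steps = 10, eps = -1.5, alpha = 0.1)
#' @export
student_params <- function(n_steps, eps, alpha, reward = default_reward()) {
  if (!is.numeric(n_steps) || length(n_steps) != 1L || n_steps < 1 ||
      n_steps != round(n_steps)) {
    abort("`n_steps` must be a single positive integer.")
  }
  n_steps <- as.integer(n_steps)
  if (!is.numeric(eps) || !all(is.finite(eps))) {
    abort("`eps` must be finite numeric.")
  }
  if (length(eps) == 1L) eps <- rep(as.numeric(eps), n_steps)
  if (length(eps) != n_steps) {
    abort("`eps` must have length 1 or `n_steps`.")
  }
  if (!is.numeric(alpha) || length(alpha) != 1L || !is.finite(alpha) ||
      alpha < 0 || alpha > 1) {
    abort("`alpha` must be a single value in [0, 1].")
  }
  if (!is.numeric(reward) || length(reward) != 1L || !is.finite(reward) ||
      reward <= 0) {
    abort("`reward` must be a single positive value.")
  }
  structure(
    list(n_steps = n_steps, eps = as.numeric(eps), alpha = as.numeric(alpha),
         reward = as.numeric(reward)),
    class = "ocl_student_params"
  )
}

#' @export
print.ocl_student_params <- function(x, ...) {
  eps_txt <- if (length(unique(x$eps)) == 1L) {
    format(x$eps[1])
  } else {
    paste0("[", paste(format(x$eps, digits = 3), collapse = ", "), "]")
  }
  cat("<ocl_student_params> N =", x$n_steps, " eps =", eps_txt,
      " alpha =", x$alpha, " reward =", x$reward, "\n")
  invisible(x)
}

#' Action-value state of the student
#'
#' Holds the learned action values `q_1..q_N` (log-odds units). A fresh
#' student starts with all values at zero.
#'
#' @param n_steps Number of steps in the full task.
#' @param q Optional initial values (defaults to zeros).
#' @return An object of class `ocl_student_state`.
#' @examples
#' student_state(5)
#' @export
student_state <- function(n_steps, q = rep(0, n_steps)) {
  n_steps <- as.integer(n_steps)
  if (length(q) != n_steps || !is.numeric(q) || !all(is.finite(q))) {
    abort("`q` must be finite numeric of length `n_steps`.")
  }
  structure(list(q = as.numeric(q)), class = "ocl_student_state")
}

#' @export
print.ocl_student_state <- function(x, ...) {
  cat("<ocl_student_state> q = [",
      paste(format(x$q, digits = 3), collapse = ", "), "]\n")
  invisible(x)
}

#' Per-step success probability of the logistic action rule
#'
#' Probability that the student takes the correct action at a step with
#' action value `q_i` and innate bias `eps_i`: `1 / (1 + exp(-(q_i + eps_i)))`.
#'
#' @param q_i Action value (log-odds units).
#' @param eps_i Innate bias (log-odds units).
#' @return Probability strictly in (0, 1). Vectorized over both arguments.
#' @examples
#' logistic_success_prob(0, 0)      # 0.5
#' logistic_success_prob(0, -1.7)   # ~0.15, a hard naive step
#' @export
logistic_success_prob <- function(q_i, eps_i) {
  if (!is.numeric(q_i) || !is.numeric(eps_i) ||
      !all(is.finite(q_i)) || !all(is.finite(eps_i))) {
    abort("`q_i` and `eps_i` must be finite numeric.")
  }
  stats::plogis(q_i + eps_i)
}

#' Innate bias implied by a uniform choice among K actions
#'
#' A naive student choosing uniformly among `K` actions, exactly one of which
#' is correct, succeeds with probability `1/K`; on the log-odds scale this is
#' a bias of `-log(K - 1)`.
#'
#' @param K Number of available actions per step (integer, at least 2).
#' @return The innate bias `-log(K - 1)`.
#' @examples
#' bias_from_action_count(2)  # 0: coin flip
#' bias_from_action_count(5)  # -log(4)
#' @export
bias_from_action_count <- function(K) {
  if (!is.numeric(K) || any(K < 2) || any(K != round(K))) {
    abort("`K` must be an integer >= 2 (otherwise no incorrect action exists).")
  }
  -log(K - 1)
}

#' Probability of completing an episode at difficulty level k
#'
#' Exact success probability of one episode at level `k`: the product of the
#' per-step probabilities `sigma(q_i + eps_i)` over steps `1..k`. This is the
#' analytic counterpart of [run_episode()] at `alpha = 0`, and the likelihood
#' kernel used by the POMCP teacher's particle filter.
#'
#' @param state An [student_state()] object.
#' @param params An [student_params()] object.
#' @param k Difficulty level (reward delivered after `k` correct steps).
#' @return Probability in (0, 1); non-increasing in `k` for a fixed state.
#' @examples
#' p <- student_params(5, eps = -1, alpha = 0.1)
#' episode_success_prob(student_state(5), p, k = 3)  # plogis(-1)^3
#' @export
episode_success_prob <- function(state, params, k) {
  check_level(k, params$n_steps)
  cpp_episode_success_prob(state$q, params$eps, as.integer(k))
}

check_level <- function(k, n_steps) {
  if (!is.numeric(k) || length(k) != 1L || k < 1 || k > n_steps ||
      k != round(k)) {
    abort(sprintf("level `k` must be an integer in [1, %d].", n_steps))
  }
  invisible(as.integer(k))
}

#' Simulate one episode and apply the TD update
#'
#' Runs a single episode at level `k`: steps are attempted in order, each
#' succeeding with probability `sigma(q_i + eps_i)`; the episode terminates
#' at the first incorrect action or after step `k`, and the terminal reward
#' is delivered only on full completion. Action values of correct steps are updated online
#' in temporal order by TD(0) (or, for the continuous-task student, a K-step
#' TD rule): `q_i <- q_i + alpha * (target_i - q_i)` where the target is the
#' reward plus the value of the state K steps ahead (0 past termination).
#' Values of steps beyond `k` and of incorrect actions are never touched.
#'
#' @inheritParams episode_success_prob
#' @param td_k Lookahead of the TD rule in steps (default 1, i.e. TD(0)).
#' @return A list with `result` (an `ocl_episode_result`: `outcome` 0/1,
#'   `steps_taken`, per-step `trace`) and `state` (updated [student_state()]).
#' @examples
#' set.seed(1)
#' p <- student_params(3, eps = 0, alpha = 0.2)
#' run_episode(student_state(3), p, k = 2)
#' @export
run_episode <- function(state, params, k, td_k = 1L) {
  check_level(k, params$n_steps)
  out <- cpp_run_episode(state$q, params$eps, params$alpha,
                         as.integer(k), as.integer(td_k), params$reward)
  res <- structure(
    list(outcome = out$outcome, steps_taken = out$steps, trace = out$trace),
    class = "ocl_episode_result"
  )
  list(result = res, state = student_state(params$n_steps, out$q))
}

#' Simulate an interaction block of T episodes at one level
#'
#' One teacher-student interaction: the student attempts the level-`k` task
#' for `T` consecutive episodes, learning between episodes. The ordered 0/1
#' outcome block is what the teacher observes.
#'
#' @inheritParams run_episode
#' @param T_attempts Number of episodes in the block.
#' @return A list with `outcomes` (integer vector of length `T_attempts`)
#'   and `state` (updated [student_state()]).
#' @examples
#' set.seed(1)
#' p <- student_params(4, eps = -0.5, alpha = 0.1)
#' run_interaction(student_state(4), p, k = 2, T_attempts = 10)$outcomes
#' @export
run_interaction <- function(state, params, k, T_attempts, td_k = 1L) {
  check_level(k, params$n_steps)
  if (!is.numeric(T_attempts) || length(T_attempts) != 1L || T_attempts < 1) {
    abort("`T_attempts` must be a positive integer.")
  }
  out <- cpp_run_interaction(state$q, params$eps, params$alpha,
                             as.integer(k), as.integer(T_attempts),
                             as.integer(td_k), params$reward)
  list(outcomes = out$outcomes, state = student_state(params$n_steps, out$q))
}

#' Serialize / deserialize student parameters
#'
#' Student parameters round-trip through plain lists suitable for YAML or
#' JSON configuration files, with keys `n_steps`, `eps` (scalar or list) and
#' `alpha`.
#'
#' @param params An [student_params()] object.
#' @return `student_params_to_list()`: a plain list;
#'   `student_params_from_list()`: an `ocl_student_params`.
#' @examples
#' p <- student_params(5, eps = -1.5, alpha = 0.1)
#' student_params_from_list(student_params_to_list(p))
#' @export
student_params_to_list <- function(params) {
  eps <- params$eps
  if (length(unique(eps)) == 1L) eps <- eps[1]
  list(n_steps = params$n_steps, eps = eps, alpha = params$alpha,
       reward = params$reward)
}

#' @rdname student_params_to_list
#' @param x A plain list with fields `n_steps`, `eps`, `alpha`.
#' @export
student_params_from_list <- function(x) {
  student_params(n_steps = x$n_steps, eps = unlist(x$eps), alpha = x$alpha,
                 reward = x$reward %||% default_reward())
}

#' Default terminal reward magnitude
#'
#' The TD target of the rewarded final step. The default of 5.5 was
#' calibrated once, together with the default curriculum settings
#' (`T = 10`, `tau = 0.85`, `beta = 0.1`, budget 1500), so that the
#' incremental teacher's failure boundary on the ten-step task sits at an
#' innate bias near -1.7 (a naive per-step success rate of about 15%);
#' see `vignette("shaping-curricula")`.
#'
#' @return A single number.
#' @export
default_reward <- function() 5.5
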