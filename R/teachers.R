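#' Discrete curriculum specification
#'
#' Defines the shaping problem the teacher faces: `n_levels` tasks on a
#' monotone difficulty scale (level `k` rewards `k` correct steps, level `N`
#' is the full task), `T_attempts` episodes per teacher-student interaction,
#' a target success threshold `tau` on the full task, and a budget of
#' interactions after which training is abandoned.
#'
#' @param n_levels Number of difficulty levels `N`.
#' @param T_attempts Episodes per interaction (default 10).
#' @param tau Target success threshold on the full task, in (0, 1)
#'   (default 0.85).
#' @param budget Maximum number of interactions (default 1500).
#' @param beta EMA decay for the success-rate tracker (default 0.1).
#' @return An object of class `ocl_curriculum_spec`.
#' @examples
#' curriculum_spec(n_levels = 10)
#' @export
curriculum_spec <- function(n_levels, T_attempts = 10, tau = 0.85,
                            budget = 1500, beta = 0.1) {
  stopifnot(n_levels >= 1, T_attempts >= 1, tau > 0, tau < 1, budget >= 1,
            beta > 0, beta < 1)
  structure(
    list(n_levels = as.integer(n_levels), T_attempts = as.integer(T_attempts),
         tau = tau, budget = as.integer(budget), beta = beta),
    class = "ocl_curriculum_spec"
  )
}

#' @export
print.ocl_curriculum_spec <- function(x, ...) {
  cat("<ocl_curriculum_spec> N =", x$n_levels, " T =", x$T_attempts,
      " tau =", x$tau, " budget =", x$budget, " beta =", x$beta, "\n")
  invisible(x)
}

#' Decision thresholds of the adaptive (ADP) teacher
#'
#' The adaptive teacher is a two-feature decision tree over the estimated
#' success rate `s_hat` and its per-interaction change `delta_s_hat`:
#' increment when the student looks competent (`s_hat >= theta_inc`), stay
#' while learning progresses (`delta_s_hat >= mu`), and decrement on signs
#' of significant extinction (`delta_s_hat < mu`). The default thresholds
#' are the ones found by [evolve_adp_policy()] under the package's default
#' benchmark conditions; the evolved optimum sits at the aggressive end
#' (a moderate increment threshold with `mu` high enough that the teacher
#' drops back whenever visible progress stalls), which yields the
#' characteristic alternation between adjacent difficulty levels. See
#' `vignette("shaping-curricula")`.
#'
#' @param theta_inc Success-rate threshold for incrementing, in (0, 1).
#' @param mu Learning-progress threshold separating stay from decrement.
#' @param beta Optional tracker decay override carried with the policy.
#' @return An object of class `ocl_adp_policy`.
#' @examples
#' adp_policy()
#' adp_policy(theta_inc = 0.9, mu = -0.05)
#' @export
adp_policy <- function(theta_inc = 0.54, mu = 0.1, beta = NULL) {
  stopifnot(theta_inc > 0, theta_inc < 1, is.numeric(mu))
  structure(list(theta_inc = theta_inc, mu = mu, beta = beta),
            class = "ocl_adp_policy")
}

#' @export
print.ocl_adp_policy <- function(x, ...) {
  cat("<ocl_adp_policy> theta_inc =", x$theta_inc, " mu =", x$mu,
      if (!is.null(x$beta)) paste(" beta =", x$beta) else "", "\n")
  invisible(x)
}

#' Teacher decision rules
#'
#' `inc_decide()` is the incremental (INC) rule: increment when the
#' estimated success rate reaches `tau`, otherwise stay; it never
#' decrements. `adp_decide()` is the adaptive (ADP) decision tree described
#' in [adp_policy()]. `rand_decide()` picks a level uniformly at random.
#' Threshold ties resolve upward (`>=` triggers the increment / stay
#' branch).
#'
#' @param s_hat Estimated success rate at the current level.
#' @param delta_s_hat Change of `s_hat` over the last interaction.
#' @param spec A [curriculum_spec()].
#' @param policy An [adp_policy()].
#' @return For `inc_decide()`/`adp_decide()`: one of `"DECREMENT"`,
#'   `"STAY"`, `"INCREMENT"`. For `rand_decide()`: a level in `1..N`.
#' @examples
#' sp <- curriculum_spec(10)
#' inc_decide(0.9, sp)
#' adp_decide(0.3, -0.2, adp_policy(0.85, -0.01))
#' @export
inc_decide <- function(s_hat, spec) {
  if (s_hat >= spec$tau) "INCREMENT" else "STAY"
}

#' @rdname inc_decide
#' @export
adp_decide <- function(s_hat, delta_s_hat, policy) {
  if (s_hat >= policy$theta_inc) {
    "INCREMENT"
  } else if (delta_s_hat >= policy$mu) {
    "STAY"
  } else {
    "DECREMENT"
  }
}

#' @rdname inc_decide
#' @export
rand_decide <- function(spec) {
  sample.int(spec$n_levels, 1L)
}

apply_move <- function(level, move, n_levels) {
  switch(move,
    INCREMENT = min(level + 1L, n_levels),
    DECREMENT = max(level - 1L, 1L),
    STAY = level,
    abort(paste("unknown move", move))
  )
}

# --- teacher objects ---------------------------------------------------------
# A teacher is a list(name, init, propose):
#   init(spec)  -> teacher state
#   propose(tstate, level, tracker, spec, last_block) -> list(level, action, tstate)
# `level` is the level of the previous interaction (1 before the first) and
# `last_block` its outcome block (NULL before the first).
# State is passed functionally so identical seeds give identical runs.

new_teacher <- function(name, init, propose) {
  structure(list(name = name, init = init, propose = propose),
            class = "ocl_teacher")
}

#' @export
print.ocl_teacher <- function(x, ...) {
  cat("<ocl_teacher>", x$name, "\n")
  invisible(x)
}

#' Construct curriculum teachers
#'
#' * `teacher_inc()` — incremental: raise difficulty once the estimated
#'   success rate at the current level reaches `tau`; never lower it.
#' * `teacher_adp()` — adaptive decision tree over `(s_hat, delta_s_hat)`;
#'   see [adp_policy()].
#' * `teacher_rand()` — assigns a uniformly random level each interaction.
#' * `teacher_lp()` — learning-progress baselines: assign the level with the
#'   greatest (estimated) absolute slope of its success-rate curve. Four
#'   variants differ in how the slope is estimated and how levels are
#'   picked; these are best-effort re-implementations of published
#'   teacher-student curriculum heuristics and are marked experimental.
#' * `teacher_pomcp()` is documented separately (see [pomcp_search()]).
#'
#' @param policy An [adp_policy()] for `teacher_adp()`.
#' @param variant One of `"online"`, `"naive"`, `"window"`, `"sampling"`.
#' @param explore Exploration rate of the greedy variants (default 0.1).
#' @param window Window length of the `"window"` variant (default 5).
#' @return An `ocl_teacher` usable with [run_curriculum()].
#' @examples
#' set.seed(1)
#' sp <- curriculum_spec(4, budget = 50)
#' st <- student_params(4, eps = 0.5, alpha = 0.2)
#' run_curriculum(teacher_inc(), st, sp)
#' @export
teacher_inc <- function() {
  new_teacher(
    "inc",
    init = function(spec) NULL,
    propose = function(tstate, level, tracker, spec, last_block) {
      move <- inc_decide(tracker$s_hat[level], spec)
      list(level = apply_move(level, move, spec$n_levels), action = move,
           tstate = tstate)
    }
  )
}

#' @rdname teacher_inc
#' @export
teacher_adp <- function(policy = adp_policy()) {
  new_teacher(
    "adp",
    init = function(spec) NULL,
    propose = function(tstate, level, tracker, spec, last_block) {
      move <- adp_decide(tracker$s_hat[level], tracker$last_delta, policy)
      list(level = apply_move(level, move, spec$n_levels), action = move,
           tstate = tstate)
    }
  )
}

#' @rdname teacher_inc
#' @export
teacher_rand <- function() {
  new_teacher(
    "rand",
    init = function(spec) NULL,
    propose = function(tstate, level, tracker, spec, last_block) {
      list(level = rand_decide(spec), action = "JUMP", tstate = tstate)
    }
  )
}

#' @rdname teacher_inc
#' @export
teacher_lp <- function(variant = c("online", "naive", "window", "sampling"),
                       explore = 0.1, window = 5L) {
  variant <- match.arg(variant)
  new_teacher(
    paste0("lp-", variant),
    init = function(spec) {
      list(scores = vector("list", spec$n_levels),
           slope_ema = rep(0, spec$n_levels))
    },
    propose = function(tstate, level, tracker, spec, last_block) {
      # fold in the last interaction's block mean for the level just taught
      if (tracker$visited[level]) {
        sc <- tstate$scores[[level]]
        m <- tracker$s_hat[level]
        if (length(sc) > 0) {
          d <- m - tail(sc, 1)
          tstate$slope_ema[level] <- 0.7 * tstate$slope_ema[level] + 0.3 * d
        }
        tstate$scores[[level]] <- c(sc, m)
      }
      nxt <- lp_baseline_decide(tstate, variant, spec, explore, window)
      list(level = nxt, action = "JUMP", tstate = tstate)
    }
  )
}

#' Level choice of the learning-progress baselines
#'
#' Given per-level score histories, choose the next level. Unvisited levels
#' are sampled first; thereafter the greedy variants pick the level with the
#' largest absolute progress slope (epsilon-greedy), and the `"sampling"`
#' variant samples levels with probability proportional to absolute slope.
#'
#' @param tstate Internal state of a [teacher_lp()] (fields `scores`,
#'   `slope_ema`).
#' @param variant Slope estimator variant.
#' @param spec A [curriculum_spec()].
#' @param explore Exploration rate.
#' @param window Window length for the `"window"` variant.
#' @return A level in `1..N`.
#' @keywords internal
#' @export
lp_baseline_decide <- function(tstate, variant, spec, explore = 0.1,
                               window = 5L) {
  N <- spec$n_levels
  unvisited <- which(lengths(tstate$scores) == 0)
  if (length(unvisited) > 0) {
    return(unvisited[sample.int(length(unvisited), 1L)])
  }
  slope <- switch(variant,
    online = tstate$slope_ema,
    naive = vapply(tstate$scores, function(sc) {
      if (length(sc) < 2) 0 else diff(tail(sc, 2))
    }, numeric(1)),
    window = vapply(tstate$scores, function(sc) {
      sc <- tail(sc, window)
      if (length(sc) < 2) return(0)
      unname(stats::lm.fit(cbind(1, seq_along(sc)), sc)$coefficients[2])
    }, numeric(1)),
    sampling = tstate$slope_ema
  )
  w <- abs(slope)
  if (variant == "sampling") {
    p <- w + 1e-6
    return(sample.int(N, 1L, prob = p / sum(p)))
  }
  if (runif(1) < explore) return(sample.int(N, 1L))
  best <- which(w == max(w))
  best[sample.int(length(best), 1L)]
}

#' Run the teacher-student interaction loop
#'
#' The central loop of outcome-based curriculum learning: each interaction,
#' the teacher proposes a difficulty level from the transcript so far, the
#' student attempts that level for `T_attempts` episodes (learning between
#' episodes), and the success-rate tracker absorbs the outcome block.
#' Training terminates successfully when the assigned level is the full task
#' and its estimated success rate reaches `tau`, or unsuccessfully when the
#' interaction budget is exhausted. The first interaction is always at
#' level 1, the simplest version of the task.
#'
#' Termination is judged on the observable estimate `s_hat`, never on the
#' student's hidden state; the true episode success probability is recorded
#' alongside for honest evaluation.
#'
#' @param teacher An `ocl_teacher` (see [teacher_inc()], [teacher_pomcp()]).
#' @param params The hidden [student_params()] of the simulated student.
#' @param spec A [curriculum_spec()].
#' @param record_q Record the full action-value history (default `TRUE`)?
#' @param td_k TD lookahead of the student (default 1).
#' @return An object of class `ocl_curriculum`: a list with `completed`,
#'   `interactions_used`, a tidy `log` tibble (one row per interaction with
#'   columns `t`, `level`, `action`, `outcomes`, `successes`, `s_hat`,
#'   `delta_s_hat`, `true_p_level`, `true_p_full`), the final `state`, and
#'   (optionally) `q_history`, an interactions-by-N matrix. Use [tidy()] /
#'   [glance()] / [autoplot()] on the result.
#' @examples
#' set.seed(7)
#' sp <- curriculum_spec(n_levels = 5, budget = 400)
#' st <- student_params(5, eps = -1, alpha = 0.1)
#' fit <- run_curriculum(teacher_inc(), st, sp)
#' glance(fit)
#' @export
run_curriculum <- function(teacher, params, spec, record_q = TRUE,
                           td_k = 1L) {
  stopifnot(inherits(teacher, "ocl_teacher"),
            inherits(params, "ocl_student_params"),
            inherits(spec, "ocl_curriculum_spec"))
  if (params$n_steps != spec$n_levels) {
    abort("student `n_steps` must equal spec `n_levels`.")
  }
  N <- spec$n_levels
  Tt <- spec$T_attempts
  budget <- spec$budget
  q <- rep(0, N)
  tracker <- rate_tracker(N, beta = spec$beta)
  tstate <- teacher$init(spec)
  level <- 1L

  lev_v <- integer(budget); act_v <- character(budget)
  succ_v <- integer(budget); sh_v <- numeric(budget); ds_v <- numeric(budget)
  tp_lev <- numeric(budget); tp_full <- numeric(budget)
  out_m <- matrix(NA_integer_, budget, Tt)
  qh <- if (record_q) matrix(NA_real_, budget, N) else NULL

  completed <- FALSE
  used <- 0L
  last_block <- NULL
  for (t in seq_len(budget)) {
    prop <- teacher$propose(tstate, level, tracker, spec, last_block)
    tstate <- prop$tstate
    level <- min(max(as.integer(prop$level), 1L), N)
    tp_lev[t] <- cpp_episode_success_prob(q, params$eps, level)
    out <- cpp_run_interaction(q, params$eps, params$alpha, level, Tt,
                               as.integer(td_k), params$reward)
    q <- out$q
    obs <- observe_interaction(tracker, level, out$outcomes)
    tracker <- obs$tracker
    lev_v[t] <- level; act_v[t] <- prop$action
    out_m[t, ] <- out$outcomes
    succ_v[t] <- sum(out$outcomes)
    sh_v[t] <- obs$s_hat; ds_v[t] <- obs$delta_s_hat
    tp_full[t] <- cpp_episode_success_prob(q, params$eps, N)
    if (record_q) qh[t, ] <- q
    last_block <- out$outcomes
    used <- t
    if (level == N && obs$s_hat >= spec$tau) { completed <- TRUE; break }
  }
  idx <- seq_len(used)
  log <- tibble::tibble(
    t = idx, level = lev_v[idx], action = act_v[idx],
    outcomes = lapply(idx, function(i) out_m[i, ]),
    successes = succ_v[idx], s_hat = sh_v[idx], delta_s_hat = ds_v[idx],
    true_p_level = tp_lev[idx], true_p_full = tp_full[idx]
  )
  structure(
    list(teacher = teacher$name, completed = completed,
         interactions_used = used, log = log,
         state = student_state(N, q), tracker = tracker, spec = spec,
         teacher_state = tstate,
         q_history = if (record_q) qh[idx, , drop = FALSE] else NULL),
    class = "ocl_curriculum"
  )
}

#' @export
print.ocl_curriculum <- function(x, ...) {
  cat("<ocl_curriculum> teacher:", x$teacher,
      if (x$completed) "completed in" else "DNF after",
      x$interactions_used, "interactions (N =", x$spec$n_levels, ")\n")
  invisible(x)
}
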