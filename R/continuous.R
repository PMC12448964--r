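#' Continuous curriculum specification
#'
#' Continuous-difficulty extension of the sequence task. Difficulty `d` is
#' realized as a chain of `ceiling(d / grid_resolution)` micro-steps whose
#' innate per-step success probability is `sigma(eps)^grid_resolution`
#' (bias `logit(sigma(eps)^grid_resolution)` in log-odds units), so the
#' naive success probability of difficulty `d` is `sigma(eps)^d` on the
#' grid: difficulty is an intensive scale, independent of how finely the
#' chain is discretized, and a grid of 1 recovers the discrete task
#' exactly. The teacher starts from the experimenter's rough guess
#' `initial_increment` for the difficulty step and may grow or shrink it by
#' the factor `growth` within `increment_bounds`.
#'
#' The student learns with a K-step TD rule (`td_k` micro-steps of
#' lookahead); the default `td_k = round(1 / grid_resolution)` makes the
#' bootstrap horizon one difficulty unit, commensurate with the discrete
#' task.
#'
#' @param max_difficulty Full-task difficulty `D`.
#' @param grid_resolution Micro-step size (default 0.1).
#' @param initial_increment Starting difficulty increment (default 1).
#' @param growth Multiplicative grow/shrink factor for the increment
#'   (default 2).
#' @param increment_bounds `c(min, max)` clamp for the increment
#'   (default `c(grid_resolution, 2)`).
#' @param tau,T_attempts,budget,beta As in [curriculum_spec()].
#' @param td_k TD lookahead in micro-steps.
#' @return An object of class `ocl_continuous_spec`.
#' @examples
#' continuous_spec(max_difficulty = 10)
#' @export
continuous_spec <- function(max_difficulty, grid_resolution = 0.1,
                            initial_increment = 1, growth = 2,
                            increment_bounds = c(grid_resolution, 2),
                            tau = 0.85, T_attempts = 10, budget = 1500,
                            beta = 0.1,
                            td_k = max(1L, round(1 / grid_resolution))) {
  stopifnot(max_difficulty > 0, grid_resolution > 0,
            grid_resolution <= increment_bounds[1],
            increment_bounds[1] <= initial_increment,
            initial_increment <= increment_bounds[2],
            growth > 1, tau > 0, tau < 1, T_attempts >= 1, budget >= 1)
  structure(
    list(max_difficulty = max_difficulty, grid_resolution = grid_resolution,
         initial_increment = initial_increment, growth = growth,
         increment_bounds = increment_bounds, tau = tau,
         T_attempts = as.integer(T_attempts), budget = as.integer(budget),
         beta = beta, td_k = as.integer(td_k),
         n_micro = as.integer(ceiling(round(max_difficulty / grid_resolution,
                                            9)))),
    class = "ocl_continuous_spec"
  )
}

#' @export
print.ocl_continuous_spec <- function(x, ...) {
  cat("<ocl_continuous_spec> D =", x$max_difficulty, " delta =",
      x$grid_resolution, " micro-steps =", x$n_micro, " K =", x$td_k, "\n")
  invisible(x)
}

micro_level <- function(d, cspec) {
  if (!is.numeric(d) || length(d) != 1L || d <= 0 ||
      d > cspec$max_difficulty + 1e-9) {
    abort("difficulty `d` must lie in (0, max_difficulty].")
  }
  max(1L, as.integer(ceiling(round(d / cspec$grid_resolution, 9))))
}

# per-micro-step bias preserving sigma(eps)^d naive success on the grid
micro_bias <- function(eps, grid_resolution) {
  stats::qlogis(stats::plogis(eps)^grid_resolution)
}

cont_student <- function(cspec, eps, alpha, reward = default_reward()) {
  student_params(cspec$n_micro,
                 eps = micro_bias(eps, cspec$grid_resolution),
                 alpha = alpha, reward = reward)
}

#' One interaction block on the continuous task
#'
#' Runs `T_attempts` episodes of the micro-step chain of length
#' `ceiling(d / grid_resolution)`, with K-step TD updates between episodes.
#' With `td_k = 1` and `grid_resolution = 1` this is exactly the discrete
#' sequence task.
#'
#' @param state An [student_state()] over the `n_micro` micro-steps.
#' @param cspec A [continuous_spec()].
#' @param eps Innate bias per unit difficulty.
#' @param alpha Learning rate.
#' @param d Assigned difficulty, in `(0, max_difficulty]`.
#' @param T_attempts Episodes in the block (defaults to the spec's).
#' @return A list with `outcomes` and the updated `state`.
#' @examples
#' set.seed(1)
#' cs <- continuous_spec(5, grid_resolution = 0.5)
#' cont_run_interaction(student_state(cs$n_micro), cs, eps = -2,
#'                      alpha = 0.1, d = 1.5)
#' @export
cont_run_interaction <- function(state, cspec, eps, alpha, d,
                                 T_attempts = cspec$T_attempts) {
  m <- micro_level(d, cspec)
  params <- cont_student(cspec, eps, alpha)
  run_interaction(state, params, m, T_attempts, td_k = cspec$td_k)
}

#' Decision tree of the continuous adaptive teacher
#'
#' Nine actions: a difficulty move (decrement / stay / increment) crossed
#' with an increment operation (shrink / keep / grow). The move follows the
#' discrete adaptive logic with thresholds `theta_hi` (success rate to
#' increment) and `mu` (progress below which to decrement). The increment
#' operation shrinks the step after strong extinction
#' (`delta_s_hat < nu_lo`) and grows it when the student is comfortably
#' above the increment threshold (`s_hat >= theta_grow`), otherwise keeps
#' it. Defaults are the thresholds found by [evolve_cont_policy()] under
#' the package's default conditions.
#'
#' @param theta_hi Success-rate threshold for incrementing.
#' @param theta_grow Success-rate threshold for growing the increment
#'   (normally `>= theta_hi`).
#' @param mu Progress threshold separating stay from decrement.
#' @param nu_lo Progress threshold below which the increment shrinks
#'   (normally `<= mu`).
#' @return An object of class `ocl_cont_adp_policy`.
#' @examples
#' cont_adp_decide(0.95, 0.01, cont_adp_policy())
#' cont_adp_decide(0.4, -0.3, cont_adp_policy())
#' @export
cont_adp_policy <- function(theta_hi = 0.5, theta_grow = 0.842,
                            mu = 0.052, nu_lo = -0.089) {
  stopifnot(theta_hi > 0, theta_hi < 1, theta_grow > 0, theta_grow <= 1)
  structure(list(theta_hi = theta_hi, theta_grow = theta_grow, mu = mu,
                 nu_lo = nu_lo),
            class = c("ocl_cont_adp_policy", "ocl_adp_policy"))
}

#' @export
print.ocl_cont_adp_policy <- function(x, ...) {
  cat("<ocl_cont_adp_policy> theta_hi =", x$theta_hi, " theta_grow =",
      x$theta_grow, " mu =", x$mu, " nu_lo =", x$nu_lo, "\n")
  invisible(x)
}

#' @rdname cont_adp_policy
#' @param s_hat,delta_s_hat Tracker features at the current difficulty.
#' @param policy An `ocl_cont_adp_policy`.
#' @return `cont_adp_decide()`: a list with `move` (DECREMENT / STAY /
#'   INCREMENT) and `increment_op` (SHRINK / KEEP / GROW).
#' @export
cont_adp_decide <- function(s_hat, delta_s_hat, policy) {
  move <- if (s_hat >= policy$theta_hi) {
    "INCREMENT"
  } else if (delta_s_hat >= policy$mu) {
    "STAY"
  } else {
    "DECREMENT"
  }
  op <- if (delta_s_hat < policy$nu_lo) {
    "SHRINK"
  } else if (s_hat >= policy$theta_grow) {
    "GROW"
  } else {
    "KEEP"
  }
  list(move = move, increment_op = op)
}

#' Continuous-curriculum teachers
#'
#' `cont_teacher_inc()` is the fixed-increment incremental baseline: raise
#' difficulty by `initial_increment` once the estimated success rate
#' reaches `tau`, never lower it, never change the increment.
#' `cont_teacher_adp()` applies the nine-action decision tree of
#' [cont_adp_policy()]: the increment operation is applied first, then the
#' move is taken with the updated increment.
#'
#' @param policy An [cont_adp_policy()].
#' @return An object of class `ocl_cont_teacher`.
#' @export
cont_teacher_inc <- function() {
  structure(
    list(name = "cont-inc",
         decide = function(s_hat, delta_s_hat, delta_inc, cspec) {
           move <- if (s_hat >= cspec$tau) "INCREMENT" else "STAY"
           list(move = move, increment_op = "KEEP")
         }),
    class = "ocl_cont_teacher"
  )
}

#' @rdname cont_teacher_inc
#' @export
cont_teacher_adp <- function(policy = cont_adp_policy()) {
  structure(
    list(name = "cont-adp",
         decide = function(s_hat, delta_s_hat, delta_inc, cspec) {
           cont_adp_decide(s_hat, delta_s_hat, policy)
         }),
    class = "ocl_cont_teacher"
  )
}

#' @export
print.ocl_cont_teacher <- function(x, ...) {
  cat("<ocl_cont_teacher>", x$name, "\n")
  invisible(x)
}

#' Run a continuous-difficulty curriculum
#'
#' Interaction loop for the continuous task: the teacher picks one of nine
#' actions from the tracker features at the current difficulty, difficulty
#' moves by the (possibly grown or shrunk) increment, clamped to
#' `(0, max_difficulty]` and snapped to the micro-step grid, and the
#' student attempts the assigned chain for a block of episodes. Terminates
#' when the full difficulty is assigned and its success estimate reaches
#' `tau`, or at budget. The success-rate tracker is indexed by micro-level,
#' so revisiting a difficulty resumes its estimate.
#'
#' @param teacher A [cont_teacher_inc()] or [cont_teacher_adp()].
#' @param eps Student innate bias per unit difficulty.
#' @param alpha Student learning rate.
#' @param cspec A [continuous_spec()].
#' @param record_q Record the micro-step action-value history?
#' @return An `ocl_cont_curriculum`: `completed`, `interactions_used`, a
#'   `log` tibble (with `difficulty` and `increment` columns), final
#'   `state`, and optional `q_history`.
#' @examples
#' set.seed(1)
#' cs <- continuous_spec(3, grid_resolution = 0.5, budget = 200)
#' run_continuous_curriculum(cont_teacher_adp(), eps = -1, alpha = 0.1, cs)
#' @export
run_continuous_curriculum <- function(teacher, eps, alpha, cspec,
                                      record_q = FALSE) {
  stopifnot(inherits(teacher, "ocl_cont_teacher"),
            inherits(cspec, "ocl_continuous_spec"))
  M <- cspec$n_micro
  grid <- cspec$grid_resolution
  params <- cont_student(cspec, eps, alpha)
  q <- rep(0, M)
  tracker <- rate_tracker(M, beta = cspec$beta)
  budget <- cspec$budget
  d <- min(cspec$initial_increment, cspec$max_difficulty)
  delta_inc <- cspec$initial_increment

  dif_v <- numeric(budget); inc_v <- numeric(budget)
  mv_v <- character(budget); op_v <- character(budget)
  succ_v <- integer(budget); sh_v <- numeric(budget); ds_v <- numeric(budget)
  out_m <- matrix(NA_integer_, budget, cspec$T_attempts)
  qh <- if (record_q) matrix(NA_real_, budget, M) else NULL
  completed <- FALSE; used <- 0L
  for (t in seq_len(budget)) {
    m <- micro_level(d, cspec)
    if (t > 1) {
      dec <- teacher$decide(tracker$s_hat[m], tracker$last_delta,
                            delta_inc, cspec)
      delta_inc <- switch(dec$increment_op,
        SHRINK = max(delta_inc / cspec$growth, cspec$increment_bounds[1]),
        GROW = min(delta_inc * cspec$growth, cspec$increment_bounds[2]),
        KEEP = delta_inc
      )
      d2 <- switch(dec$move,
        INCREMENT = d + delta_inc,
        DECREMENT = d - delta_inc,
        STAY = d
      )
      d2 <- min(max(d2, grid), cspec$max_difficulty)
      d <- round(d2 / grid) * grid
      m <- micro_level(d, cspec)
      mv_v[t] <- dec$move; op_v[t] <- dec$increment_op
    } else {
      mv_v[t] <- "START"; op_v[t] <- "KEEP"
    }
    out <- cpp_run_interaction(q, params$eps, params$alpha, m,
                               cspec$T_attempts, cspec$td_k, params$reward)
    q <- out$q
    obs <- observe_interaction(tracker, m, out$outcomes)
    tracker <- obs$tracker
    dif_v[t] <- d; inc_v[t] <- delta_inc
    out_m[t, ] <- out$outcomes; succ_v[t] <- sum(out$outcomes)
    sh_v[t] <- obs$s_hat; ds_v[t] <- obs$delta_s_hat
    if (record_q) qh[t, ] <- q
    used <- t
    if (m == M && obs$s_hat >= cspec$tau) { completed <- TRUE; break }
  }
  idx <- seq_len(used)
  log <- tibble::tibble(
    t = idx, difficulty = dif_v[idx], increment = inc_v[idx],
    action = mv_v[idx], increment_op = op_v[idx],
    outcomes = lapply(idx, function(i) out_m[i, ]),
    successes = succ_v[idx], s_hat = sh_v[idx], delta_s_hat = ds_v[idx]
  )
  structure(
    list(teacher = teacher$name, completed = completed,
         interactions_used = used, log = log,
         state = student_state(M, q), tracker = tracker, cspec = cspec,
         q_history = if (record_q) qh[idx, , drop = FALSE] else NULL),
    class = "ocl_cont_curriculum"
  )
}

#' @export
print.ocl_cont_curriculum <- function(x, ...) {
  cat("<ocl_cont_curriculum> teacher:", x$teacher,
      if (x$completed) "completed in" else "DNF after",
      x$interactions_used, "interactions (D =", x$cspec$max_difficulty,
      ")\n")
  invisible(x)
}

#' Evolve the continuous adaptive teacher's thresholds
#'
#' Differential evolution of the four thresholds of [cont_adp_policy()]
#' against simulated continuous curricula, mirroring [evolve_adp_policy()].
#'
#' @param cspec A [continuous_spec()].
#' @param eval_eps_grid Training biases (default `c(-1, -1.5, -2)`).
#' @param eval_seeds Evaluation seeds (default `1:3`).
#' @param alpha Student learning rate (default 0.1).
#' @param dnf_penalty Cost for incomplete runs (default `2 * budget`).
#' @param population,generations,F,CR DE settings.
#' @return A list with `policy`, `cost` and the `de` fit.
#' @export
evolve_cont_policy <- function(cspec, eval_eps_grid = c(-1, -1.5, -2),
                               eval_seeds = 1:3, alpha = 0.1,
                               dnf_penalty = 2 * cspec$budget,
                               population = 16, generations = 20,
                               F = 0.7, CR = 0.9) {
  lower <- c(theta_hi = 0.5, theta_grow = 0.5, mu = -1, nu_lo = -1)
  upper <- c(theta_hi = 0.99, theta_grow = 1, mu = 0.1, nu_lo = 0.1)
  objective <- function(x) {
    pol <- cont_adp_policy(x[1], x[2], x[3], x[4])
    teach <- cont_teacher_adp(pol)
    mean(vapply(eval_eps_grid, function(eps) {
      mean(vapply(eval_seeds, function(seed) {
        set.seed(seed)
        res <- run_continuous_curriculum(teach, eps, alpha, cspec)
        if (res$completed) res$interactions_used else dnf_penalty
      }, numeric(1)))
    }, numeric(1)))
  }
  fit <- de_optimize(objective, lower, upper, population = population,
                     generations = generations, F = F, CR = CR)
  list(policy = cont_adp_policy(fit$par[1], fit$par[2], fit$par[3],
                                fit$par[4]),
       cost = fit$value, de = fit)
}
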