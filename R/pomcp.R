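#' Prior over the hidden student parameters
#'
#' The planning teacher is not told the student's innate bias or learning
#' rate; it starts from independent uniform priors over both. A single
#' constant bias per particle is assumed (the common simplification that all
#' per-step biases are equal).
#'
#' @param eps_range Support of the uniform prior over the innate bias
#'   (default `c(-3, 0)`).
#' @param alpha_range Support of the uniform prior over the learning rate;
#'   must lie in (0, 1] (default `c(0.01, 0.5)`).
#' @return An object of class `ocl_prior_spec`.
#' @examples
#' prior_spec()
#' @export
prior_spec <- function(eps_range = c(-3, 0), alpha_range = c(0.01, 0.5)) {
  stopifnot(length(eps_range) == 2, eps_range[1] < eps_range[2],
            length(alpha_range) == 2, alpha_range[1] < alpha_range[2],
            alpha_range[1] > 0, alpha_range[2] <= 1)
  structure(list(eps_range = eps_range, alpha_range = alpha_range),
            class = "ocl_prior_spec")
}

#' POMCP planner configuration
#'
#' @param n_particles Belief particles (default 1000).
#' @param n_simulations Tree-search iterations per decision (default 500).
#' @param ucb_c UCB1 exploration constant (default `sqrt(2)`).
#' @param gamma_teacher Teacher discount in (0, 1) (default 0.98); this is
#'   what makes faster curricula more valuable.
#' @param max_depth Planning horizon in interactions (default 30).
#' @return An object of class `ocl_pomcp_config`.
#' @examples
#' pomcp_config(n_simulations = 200)
#' @export
pomcp_config <- function(n_particles = 1000, n_simulations = 500,
                         ucb_c = sqrt(2), gamma_teacher = 0.98,
                         max_depth = 30) {
  stopifnot(n_particles >= 1, n_simulations >= 0, ucb_c >= 0,
            gamma_teacher > 0, gamma_teacher < 1, max_depth >= 1)
  structure(
    list(n_particles = as.integer(n_particles),
         n_simulations = as.integer(n_simulations), ucb_c = ucb_c,
         gamma_teacher = gamma_teacher, max_depth = as.integer(max_depth)),
    class = "ocl_pomcp_config"
  )
}

#' Draw an initial particle belief from the prior
#'
#' Each particle is one hypothesis about the student: an action-value vector
#' `q` (known to be all zeros at the start of training), a constant innate
#' bias `eps` and a learning rate `alpha`, with uniform weights.
#'
#' @param prior An [prior_spec()].
#' @param n Number of particles.
#' @param n_steps Length of the student's action chain.
#' @param reward Terminal reward magnitude, treated as known to the teacher
#'   (the experimenter sets it); default [default_reward()].
#' @return An object of class `ocl_belief` with fields `q` (n-by-N matrix),
#'   `eps`, `alpha`, `w` (normalized weights) and the `prior`.
#' @examples
#' set.seed(1)
#' b <- sample_prior(prior_spec(), n = 100, n_steps = 5)
#' effective_sample_size(b)
#' @export
sample_prior <- function(prior, n, n_steps, reward = default_reward()) {
  stopifnot(inherits(prior, "ocl_prior_spec"), n >= 1, n_steps >= 1)
  structure(
    list(
      q = matrix(0, n, n_steps),
      eps = runif(n, prior$eps_range[1], prior$eps_range[2]),
      alpha = runif(n, prior$alpha_range[1], prior$alpha_range[2]),
      w = rep(1 / n, n),
      prior = prior, n_steps = as.integer(n_steps), reward = reward
    ),
    class = "ocl_belief"
  )
}

#' @export
print.ocl_belief <- function(x, ...) {
  cat("<ocl_belief>", length(x$w), "particles, ESS =",
      format(effective_sample_size(x), digits = 4),
      "\n  E[eps] =", format(belief_mean(x)["eps"], digits = 3),
      " E[alpha] =", format(belief_mean(x)["alpha"], digits = 3), "\n")
  invisible(x)
}

#' Belief summaries
#'
#' `effective_sample_size()` returns `1 / sum(w^2)`; `belief_mean()` the
#' weighted posterior means of `eps` and `alpha`.
#'
#' @param belief An `ocl_belief`.
#' @return A number, or a named vector `c(eps = , alpha = )`.
#' @export
effective_sample_size <- function(belief) 1 / sum(belief$w^2)

#' @rdname effective_sample_size
#' @export
belief_mean <- function(belief) {
  c(eps = sum(belief$w * belief$eps), alpha = sum(belief$w * belief$alpha))
}

#' Particle-filter update of the belief from one interaction block
#'
#' Bayes' rule over the hidden student, implemented as a particle filter:
#' for each particle, the weight is multiplied by the particle's predicted
#' probability of each observed outcome in order, and the particle's action
#' values are advanced by simulating the student's TD update along one
#' sampled step-trace consistent with that outcome (failure steps drawn from
#' their exact conditional distribution). Weights are renormalized;
#' systematic resampling with Gaussian reinvigoration of `(eps, alpha)`
#' (scales 0.05 and 0.01, clipped to the prior support) is triggered when
#' the effective sample size drops below half the particle count. If every
#' particle assigns the block zero probability the belief has collapsed; it
#' is re-drawn from the prior with a warning.
#'
#' @param belief An `ocl_belief` from [sample_prior()].
#' @param level Difficulty level of the observed block.
#' @param block Integer 0/1 outcomes of the block, in order.
#' @return The updated `ocl_belief`.
#' @export
belief_update <- function(belief, level, block) {
  n <- length(belief$w)
  up <- cpp_belief_update(belief$q, matrix(belief$eps, n, belief$n_steps),
                          belief$alpha, log(belief$w), as.integer(level),
                          as.integer(block), 1L, belief$reward)
  lw <- up$logw
  belief$q <- up$q
  if (all(!is.finite(lw))) {
    warning("belief collapse: all particle weights vanished; resampling prior")
    fresh <- sample_prior(belief$prior, n, belief$n_steps, belief$reward)
    fresh$q <- belief$q # keep advanced q hypotheses
    return(fresh)
  }
  lw <- lw - max(lw)
  w <- exp(lw)
  belief$w <- w / sum(w)
  if (effective_sample_size(belief) < n / 2) {
    belief <- resample_belief(belief)
  }
  belief
}

# systematic resampling + reinvigoration jitter on (eps, alpha)
resample_belief <- function(belief) {
  n <- length(belief$w)
  u <- (runif(1) + seq_len(n) - 1) / n
  idx <- findInterval(u, cumsum(belief$w)) + 1L
  idx[idx > n] <- n
  belief$q <- belief$q[idx, , drop = FALSE]
  pr <- belief$prior
  belief$eps <- pmin(pmax(belief$eps[idx] + stats::rnorm(n, 0, 0.05),
                          pr$eps_range[1]), pr$eps_range[2])
  belief$alpha <- pmin(pmax(belief$alpha[idx] + stats::rnorm(n, 0, 0.01),
                            pr$alpha_range[1]), pr$alpha_range[2])
  belief$w <- rep(1 / n, n)
  belief
}

#' Unit terminal reward of the teacher's POMDP
#'
#' The teacher earns reward 1 on the interaction at which the student is
#' assigned the full task and the success estimate crosses the target
#' threshold, and 0 otherwise. Under the teacher discount, a curriculum
#' finishing at interaction `t` (counting from 0) is worth
#' `gamma_teacher^t`.
#'
#' @param level Assigned level this interaction.
#' @param s_full Post-block success estimate at the full task.
#' @param spec A [curriculum_spec()].
#' @return 0 or 1.
#' @examples
#' sp <- curriculum_spec(10)
#' teacher_reward(10, 0.9, sp)
#' teacher_reward(3, 0.9, sp)
#' @export
teacher_reward <- function(level, s_full, spec) {
  as.numeric(level == spec$n_levels && s_full >= spec$tau)
}

#' Monte Carlo tree search over curriculum actions
#'
#' One POMCP planning step. Each of `n_simulations` iterations samples a
#' particle as the hidden student, then descends a search tree whose nodes
#' alternate between teacher actions (decrement / stay / increment, chosen
#' by UCB1) and observation branches keyed by the block's success count.
#' Along the descent the student and the success-rate tracker are simulated
#' forward one interaction per action; termination yields the unit reward.
#' Leaves are expanded and evaluated by a rollout that follows the
#' incremental rule on the simulated tracker. Returns are discounted by
#' `gamma_teacher` and backed up; the root action with the most visits is
#' returned.
#'
#' The simulated planning state carries the tracker estimate so termination
#' inside the tree mirrors the real interaction loop.
#'
#' @param belief An `ocl_belief`.
#' @param level Current difficulty level.
#' @param tracker The real [rate_tracker()] (its estimates seed the
#'   simulated tracker).
#' @param spec A [curriculum_spec()].
#' @param config A [pomcp_config()].
#' @return A list with `action` (the chosen move), `visits` and `values`
#'   (named per root action diagnostics).
#' @export
pomcp_search <- function(belief, level, tracker, spec, config) {
  if (config$n_simulations < 1) abort("`n_simulations` must be >= 1.")
  moves <- c("DECREMENT", "STAY", "INCREMENT")
  N <- spec$n_levels
  tree <- new.env(parent = emptyenv(), size = 4L * config$n_simulations)
  node <- function(key) {
    nd <- tree[[key]]
    if (is.null(nd)) {
      nd <- list(n = 0, an = c(0, 0, 0), aq = c(0, 0, 0))
      tree[[key]] <- nd
    }
    nd
  }
  gamma <- config$gamma_teacher
  ucb_c <- config$ucb_c
  tau <- spec$tau
  Tt <- spec$T_attempts
  beta <- spec$beta
  rew <- belief$reward %||% default_reward()

  simulate <- function(q, eps, alpha, lev, shat, key, depth) {
    if (depth > config$max_depth) return(0)
    nd <- node(key)
    fresh <- nd$n == 0
    # UCB1 over the three moves; unvisited moves first
    if (any(nd$an == 0)) {
      a <- which(nd$an == 0)[1]
    } else {
      a <- which.max(nd$aq + ucb_c * sqrt(log(nd$n) / nd$an))
    }
    lev2 <- apply_move(lev, moves[a], N)
    sim <- cpp_run_interaction(q, eps, alpha, lev2, Tt, 1L, rew)
    o <- sum(sim$outcomes)
    shat[lev2] <- ema_update(shat[lev2], sim$outcomes, beta)
    r <- teacher_reward(lev2, shat[N], spec)
    if (r >= 1) {
      ret <- 1
    } else if (fresh) {
      # expand this node and evaluate the continuation by rollout
      ret <- gamma * cpp_rollout(sim$q, eps, alpha, lev2, shat, N, Tt, tau,
                                 beta, gamma, config$max_depth - depth, 1L,
                                 rew)
    } else {
      ret <- gamma * simulate(sim$q, eps, alpha, lev2, shat,
                              paste0(key, "a", a, "o", o), depth + 1L)
    }
    nd <- tree[[key]]
    nd$n <- nd$n + 1
    nd$an[a] <- nd$an[a] + 1
    nd$aq[a] <- nd$aq[a] + (ret - nd$aq[a]) / nd$an[a]
    tree[[key]] <- nd
    ret
  }

  nP <- length(belief$w)
  for (i in seq_len(config$n_simulations)) {
    p <- if (nP == 1) 1L else sample.int(nP, 1L, prob = belief$w)
    simulate(belief$q[p, ], belief$eps[p], belief$alpha[p], level,
             tracker$s_hat, "R", 1L)
  }
  root <- tree[["R"]]
  best <- which.max(root$an)
  list(action = moves[best],
       visits = setNames(root$an, moves),
       values = setNames(root$aq, moves))
}

#' POMCP planning teacher
#'
#' Combines the particle-filter belief over the hidden student
#' ([belief_update()]) with Monte Carlo tree search over curriculum moves
#' ([pomcp_search()]). Before each decision the belief absorbs the previous
#' interaction's outcome block; the search then plans from the updated
#' belief. Per-decision diagnostics (posterior means, effective sample size,
#' root action statistics) are kept in the teacher state and returned in the
#' curriculum log via `run_curriculum()`.
#'
#' Planning cost grows quickly as the task gets harder (more interactions,
#' deeper trees); at strongly negative biases (around -3) planning is not
#' expected to be tractable.
#'
#' @param config A [pomcp_config()].
#' @param prior A [prior_spec()].
#' @return An `ocl_teacher`.
#' @examples
#' set.seed(1)
#' sp <- curriculum_spec(3, budget = 30)
#' st <- student_params(3, eps = -0.5, alpha = 0.2)
#' tch <- teacher_pomcp(pomcp_config(n_particles = 100, n_simulations = 50,
#'                                   max_depth = 10))
#' run_curriculum(tch, st, sp)
#' @export
teacher_pomcp <- function(config = pomcp_config(), prior = prior_spec()) {
  new_teacher(
    "pomcp",
    init = function(spec) {
      list(belief = sample_prior(prior, config$n_particles, spec$n_levels),
           diagnostics = list())
    },
    propose = function(tstate, level, tracker, spec, last_block) {
      if (!is.null(last_block)) {
        tstate$belief <- belief_update(tstate$belief, level, last_block)
      }
      res <- pomcp_search(tstate$belief, level, tracker, spec, config)
      tstate$diagnostics[[length(tstate$diagnostics) + 1L]] <-
        c(belief_mean(tstate$belief),
          ess = effective_sample_size(tstate$belief), res$values)
      list(level = apply_move(level, res$action, spec$n_levels),
           action = res$action, tstate = tstate)
    }
  )
}
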