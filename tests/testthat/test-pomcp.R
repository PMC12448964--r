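point_mass_belief <- function(q, eps, alpha, reward = default_reward()) {
  structure(
    list(q = matrix(q, 1), eps = eps, alpha = alpha, w = 1,
         prior = prior_spec(), n_steps = length(q), reward = reward),
    class = "ocl_belief"
  )
}

test_that("prior sampling produces uniform particles with the stated
           moments", {
  set.seed(1)
  b1 <- sample_prior(prior_spec(), 1, 5)
  expect_equal(b1$w, 1)
  expect_equal(dim(b1$q), c(1, 5))
  expect_true(all(b1$q == 0))
  # near-point-mass prior collapses all particles
  pm <- prior_spec(eps_range = c(-1.5 - 1e-9, -1.5),
                   alpha_range = c(0.1, 0.1 + 1e-9))
  bp <- sample_prior(pm, 50, 3)
  expect_equal(bp$eps, rep(-1.5, 50), tolerance = 1e-6)
  expect_equal(bp$alpha, rep(0.1, 50), tolerance = 1e-6)
  # moment check on the default eps prior U(-3, 0)
  set.seed(2)
  b <- sample_prior(prior_spec(), 1e4, 2)
  se <- sqrt(9 / 12 / 1e4)
  expect_lt(abs(mean(b$eps) + 1.5), 3 * se)
  expect_equal(effective_sample_size(b), 1e4)
  expect_error(prior_spec(eps_range = c(0, -3)))
})

test_that("belief updates multiply weights by the exact block likelihood", {
  # two frozen particles predicting success 0.9 vs 0.1 at level 1
  q <- rbind(stats::qlogis(0.9), stats::qlogis(0.1))
  b <- structure(
    list(q = q, eps = c(0, 0), alpha = c(0, 0), w = c(0.5, 0.5),
         prior = prior_spec(), n_steps = 1L, reward = default_reward()),
    class = "ocl_belief"
  )
  set.seed(1)
  up <- belief_update(b, 1, rep(1L, 5))
  expect_equal(up$w[1] / up$w[2], (0.9 / 0.1)^5, tolerance = 1e-6)
  # frozen particles never advance their q
  expect_equal(up$q, q)
})

test_that("with frozen particles the posterior over eps concentrates at
           the empirical success logit", {
  set.seed(3)
  n <- 500
  # an effectively zero learning-rate prior keeps resampled particles
  # frozen too
  frozen <- prior_spec(alpha_range = c(1e-9, 2e-9))
  b <- structure(
    list(q = matrix(0, n, 1), eps = seq(-3, 0, length.out = n),
         alpha = rep(0, n), w = rep(1 / n, n),
         prior = frozen, n_steps = 1L, reward = default_reward()),
    class = "ocl_belief"
  )
  p_true <- ref_sigma(-1.2)
  obs <- stats::rbinom(200, 1, p_true)
  for (i in seq(1, 200, by = 10)) {
    b <- belief_update(b, 1, obs[i:(i + 9)])
  }
  post_eps <- sum(b$w * b$eps)
  expect_lt(abs(post_eps - stats::qlogis(mean(obs))), 0.25)
})

test_that("resampling keeps the belief normalized and inside the prior
           support", {
  set.seed(4)
  b <- sample_prior(prior_spec(), 200, 3)
  st <- student_params(3, eps = -1, alpha = 0.1)
  q <- rep(0, 3)
  for (t in 1:15) {
    out <- cpp_run_interaction(q, st$eps, st$alpha, 2L, 10L, 1L, st$reward)
    q <- out$q
    b <- belief_update(b, 2, out$outcomes)
    expect_equal(sum(b$w), 1, tolerance = 1e-12)
    expect_true(all(b$eps >= -3 & b$eps <= 0))
    expect_true(all(b$alpha >= 0.01 & b$alpha <= 0.5))
  }
  expect_gte(effective_sample_size(b), 1)
})

test_that("the particle filter recovers a known student from an
           incremental curriculum", {
  recover <- function(seed, n_inter = 50) {
    set.seed(seed)
    sp <- curriculum_spec(10)
    st <- student_params(10, eps = -1.5, alpha = 0.1)
    b <- sample_prior(prior_spec(), 500, 10)
    q <- rep(0, 10)
    tracker <- rate_tracker(10)
    level <- 1L
    tch <- teacher_inc()
    for (t in seq_len(n_inter)) {
      level <- tch$propose(NULL, level, tracker, sp, NULL)$level
      out <- cpp_run_interaction(q, st$eps, st$alpha, level, 10L, 1L,
                                 st$reward)
      q <- out$q
      tracker <- observe_interaction(tracker, level, out$outcomes)$tracker
      b <- belief_update(b, level, out$outcomes)
    }
    belief_mean(b)
  }
  m <- t(vapply(1:5, recover, c(eps = 0, alpha = 0)))
  ok <- abs(m[, "eps"] + 1.5) <= 0.3 & abs(m[, "alpha"] - 0.1) <= 0.05
  expect_gte(sum(ok), 4)
})

test_that("teacher reward fires only on full-task threshold crossing", {
  sp <- curriculum_spec(10)
  expect_equal(teacher_reward(3, 0.99, sp), 0)
  expect_equal(teacher_reward(10, 0.84, sp), 0)
  expect_equal(teacher_reward(10, 0.85, sp), 1)
})

test_that("planning prefers to collect an imminent reward", {
  # the belief is certain the student already masters the full task and
  # the tracker already sits above tau: staying at N pays immediately,
  # dropping a level cannot
  sp <- curriculum_spec(2, T_attempts = 2)
  b <- point_mass_belief(c(50, 50), eps = 0, alpha = 0.1)
  tr <- rate_tracker(2)
  tr$s_hat <- c(0.9, 0.9)
  tr$visited <- c(TRUE, TRUE)
  set.seed(5)
  res <- pomcp_search(b, 2, tr, sp, pomcp_config(n_simulations = 300,
                                                 max_depth = 5))
  expect_true(res$action %in% c("STAY", "INCREMENT")) # both land on N
  expect_gt(max(res$values[c("STAY", "INCREMENT")]),
            res$values["DECREMENT"])
  expect_error(
    pomcp_search(b, 2, tr, sp, pomcp_config(n_simulations = 0)),
    "n_simulations"
  )
})

test_that("tree search matches exhaustive depth-2 expectimax on a small
           task", {
  sp <- curriculum_spec(2, T_attempts = 2, tau = 0.6, beta = 0.3)
  cfg <- pomcp_config(n_simulations = 2000, max_depth = 2,
                      gamma_teacher = 0.98)
  set.seed(6)
  agree <- 0
  n_cases <- 12
  for (i in seq_len(n_cases)) {
    q <- runif(2, 0, default_reward())
    eps <- runif(1, -2, 0)
    alpha <- runif(1, 0.05, 0.4)
    shat <- runif(2, 0.2, 0.9)
    level <- sample(2, 1)
    oracle <- expectimax_root(q, rep(eps, 2), alpha, level, shat, sp,
                              cfg$gamma_teacher, default_reward())
    tr <- rate_tracker(2, beta = sp$beta)
    tr$s_hat <- shat
    tr$visited <- c(TRUE, TRUE)
    b <- point_mass_belief(q, eps, alpha)
    got <- pomcp_search(b, level, tr, sp, cfg)
    best <- expectimax_best_levels(oracle$values, level, 2)
    agree <- agree + (move_level(got$action, level, 2) %in% best)
  }
  expect_gte(agree, 8)
})

test_that("the full POMCP teacher completes an easy curriculum", {
  set.seed(7)
  sp <- curriculum_spec(3, budget = 60)
  st <- student_params(3, eps = -0.5, alpha = 0.2)
  tch <- teacher_pomcp(pomcp_config(n_particles = 200, n_simulations = 60,
                                    max_depth = 10))
  fit <- run_curriculum(tch, st, sp, record_q = FALSE)
  expect_true(fit$completed)
  expect_true(all(fit$log$level >= 1 & fit$log$level <= 3))
  # per-decision diagnostics were collected
  expect_equal(length(fit$teacher_state$diagnostics), fit$interactions_used)
})

test_that("spending more planning simulations never hurts completion
           time beyond noise", {
  mean_t <- function(ns, seeds = 1:4) {
    mean(vapply(seeds, function(s) {
      set.seed(s)
      sp <- curriculum_spec(3, budget = 80)
      st <- student_params(3, eps = -1, alpha = 0.15)
      tch <- teacher_pomcp(pomcp_config(n_particles = 150,
                                        n_simulations = ns,
                                        max_depth = 10))
      run_curriculum(tch, st, sp, record_q = FALSE)$interactions_used
    }, numeric(1)))
  }
  t8 <- mean_t(8); t50 <- mean_t(50); t200 <- mean_t(200)
  expect_lt(t50, t8)
  expect_lte(t200, t50 + 3)
})
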