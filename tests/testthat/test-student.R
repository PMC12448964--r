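test_that("logistic action rule and action-count bias follow closed forms", {
  expect_equal(logistic_success_prob(0, 0), 0.5)
  # a bias of -1.7 is the ~15% naive success rate at the INC boundary
  expect_equal(logistic_success_prob(0, -1.7), 1 / (1 + exp(1.7)))
  expect_equal(round(logistic_success_prob(0, -1.7), 4), 0.1545)
  expect_equal(bias_from_action_count(2), 0)
  expect_equal(bias_from_action_count(5), -log(4))
  for (K in 2:10) {
    expect_equal(logistic_success_prob(0, bias_from_action_count(K)), 1 / K)
  }
  expect_true(all(diff(logistic_success_prob(seq(-3, 3, 0.5), 0)) > 0))
  expect_error(bias_from_action_count(1), "K")
  expect_error(logistic_success_prob(NA_real_, 0))
  expect_error(logistic_success_prob(0, Inf))
})

test_that("episode success probability is the per-step product", {
  p <- student_params(6, eps = -0.8, alpha = 0.1)
  s0 <- student_state(6)
  for (k in 1:6) {
    expect_equal(episode_success_prob(s0, p, k), ref_sigma(-0.8)^k)
  }
  probs <- vapply(1:6, function(k) episode_success_prob(s0, p, k),
                  numeric(1))
  expect_true(all(diff(probs) < 0))
  # heterogeneous biases
  ph <- student_params(3, eps = c(0, -1, -2), alpha = 0.1)
  expect_equal(episode_success_prob(student_state(3), ph, 3),
               prod(ref_sigma(c(0, -1, -2))))
  # trained values push the probability to 1
  expect_gt(episode_success_prob(student_state(6, rep(50, 6)), p, 6), 0.999)
  expect_error(episode_success_prob(s0, p, 0))
  expect_error(episode_success_prob(s0, p, 7))
})

test_that("TD updates match the hand-applied rule on forced traces", {
  big <- 50
  # one-step task, unit reward: q_1 <- alpha * 1 after one success
  p1 <- student_params(1, eps = big, alpha = 0.3, reward = 1)
  set.seed(1)
  out <- run_episode(student_state(1), p1, 1)
  expect_equal(out$result$outcome, 1L)
  expect_equal(out$state$q, 0.3)

  # forced success through a 3-chain, arbitrary starting q and reward
  q0 <- c(1.2, 0.4, 2.0)
  p3 <- student_params(3, eps = big, alpha = 0.25, reward = 6)
  set.seed(1)
  out <- run_episode(student_state(3, q0), p3, 3)
  expect_equal(out$result$outcome, 1L)
  expect_equal(out$state$q, ref_td_update(q0, 0.25, 3, 0, 6))

  # forced failure at step 3: correct steps bootstrap on current values,
  # including the failing step's value
  pf <- student_params(3, eps = c(big, big, -big), alpha = 0.25, reward = 6)
  set.seed(1)
  out <- run_episode(student_state(3, q0), pf, 3)
  expect_equal(out$result$outcome, 0L)
  expect_equal(out$result$steps_taken, 3L)
  expect_equal(out$state$q, ref_td_update(q0, 0.25, 3, 3, 6))
  # hand check: q1 -> q1 + a(q2 - q1), q2 -> q2 + a(q3 - q2), q3 untouched
  expect_equal(out$state$q[1], 1.2 + 0.25 * (0.4 - 1.2))
  expect_equal(out$state$q[2], 0.4 + 0.25 * (2.0 - 0.4))
  expect_equal(out$state$q[3], 2.0)

  # zero learning rate never moves the state
  pz <- student_params(3, eps = -0.5, alpha = 0)
  set.seed(42)
  for (i in 1:20) {
    out <- run_episode(student_state(3, q0), pz, 3)
    expect_equal(out$state$q, q0)
  }
})

test_that("extinction: after an increment, q_k drops by alpha * q_k on a
           correct-through-k episode regardless of the new step's outcome", {
  big <- 50
  k <- 4
  q0 <- c(3, 2.5, 2, 1.5, 0) # freshly incremented: q_{k+1} = 0
  for (eps_last in c(big, -big)) { # new step succeeds or fails
    p <- student_params(5, eps = c(rep(big, 4), eps_last), alpha = 0.1)
    set.seed(1)
    out <- run_episode(student_state(5, q0), p, 5)
    expect_equal(out$state$q[k] - q0[k], -0.1 * q0[k])
  }
})

test_that("values beyond the assigned level are never updated", {
  p <- student_params(5, eps = 0.5, alpha = 0.2)
  st <- student_state(5)
  set.seed(3)
  for (i in 1:50) st <- run_interaction(st, p, k = 2, T_attempts = 5)$state
  expect_true(st$q[1] > 0 && st$q[2] > 0)
  expect_equal(st$q[3:5], rep(0, 3))
})

test_that("with a frozen student, episode outcomes match the analytic
           success probability", {
  p <- student_params(3, eps = -0.5, alpha = 0)
  st <- student_state(3, c(0.3, 0, -0.2))
  truth <- episode_success_prob(st, p, 3)
  set.seed(11)
  n <- 2e4
  hits <- sum(run_interaction(st, p, 3, T_attempts = n)$outcomes)
  se <- sqrt(truth * (1 - truth) / n)
  expect_lt(abs(hits / n - truth), 3 * se)
})

test_that("interaction blocks have length T and learn between episodes", {
  p <- student_params(2, eps = 50, alpha = 0)
  out <- run_interaction(student_state(2), p, 1, T_attempts = 3)
  expect_equal(out$outcomes, rep(1L, 3))
  expect_equal(out$state$q, c(0, 0))
  for (Tt in c(1, 7, 25)) {
    expect_length(run_interaction(student_state(2), p, 2, Tt)$outcomes, Tt)
  }
  # naive success rate at eps = -1.7 is ~15%
  pn <- student_params(1, eps = -1.7, alpha = 0)
  set.seed(5)
  m <- mean(run_interaction(student_state(1), pn, 1, 2e4)$outcomes)
  expect_lt(abs(m - 0.1545), 3 * sqrt(0.1545 * 0.8455 / 2e4))
})

test_that("reinforcement propagates backward from the rewarded step", {
  crossing <- function(seed, n_max = 2000) {
    set.seed(seed)
    p <- student_params(5, eps = -1, alpha = 0.1)
    st <- student_state(5)
    cross <- rep(NA_integer_, 5)
    for (t in seq_len(n_max)) {
      st <- run_interaction(st, p, k = 5, T_attempts = 10)$state
      cross[is.na(cross) & st$q > 0.5] <- t
      if (!anyNA(cross)) break
    }
    cross
  }
  w <- t(vapply(1:3, crossing, integer(5)))
  expect_true(all(!is.na(w)))
  # later steps cross the threshold no later than earlier ones
  for (r in seq_len(nrow(w))) expect_true(all(diff(w[r, ]) <= 0))
})

test_that("student parameters validate and round-trip through plain lists", {
  expect_error(student_params(0, 0, 0.1), "n_steps")
  expect_error(student_params(3, c(0, 1), 0.1), "length")
  expect_error(student_params(3, 0, 1.5), "alpha")
  expect_error(student_params(3, 0, 0.1, reward = -1), "reward")
  expect_error(student_state(3, c(0, 0)), "length")
  p <- student_params(4, eps = c(0, -1, -2, 0.5), alpha = 0.2, reward = 3)
  expect_equal(student_params_from_list(student_params_to_list(p)), p)
  pc <- student_params(4, eps = -1, alpha = 0.2)
  lst <- student_params_to_list(pc)
  expect_length(lst$eps, 1) # constant bias collapses to a scalar
  expect_equal(student_params_from_list(lst), pc)
})
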