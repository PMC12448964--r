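test_that("incremental and adaptive decision rules apply their thresholds,
           with ties resolving upward", {
  sp <- curriculum_spec(10, tau = 0.85)
  expect_equal(inc_decide(0.95, sp), "INCREMENT")
  expect_equal(inc_decide(0.5, sp), "STAY")
  expect_equal(inc_decide(0.85, sp), "INCREMENT") # tie
  pol <- adp_policy(theta_inc = 0.85, mu = -0.01)
  expect_equal(adp_decide(0.9, -0.5, pol), "INCREMENT")
  expect_equal(adp_decide(0.3, 0.05, pol), "STAY")
  expect_equal(adp_decide(0.3, -0.2, pol), "DECREMENT")
  expect_equal(adp_decide(0.85, -0.2, pol), "INCREMENT") # tie
  expect_equal(adp_decide(0.3, -0.01, pol), "STAY")      # tie
})

test_that("random teacher draws levels uniformly and reproducibly", {
  sp1 <- curriculum_spec(1)
  expect_true(all(replicate(20, rand_decide(sp1)) == 1))
  sp6 <- curriculum_spec(6)
  set.seed(10)
  draws <- replicate(1e4, rand_decide(sp6))
  freq <- tabulate(draws, 6) / 1e4
  se <- sqrt((1 / 6) * (5 / 6) / 1e4)
  expect_true(all(abs(freq - 1 / 6) < 3 * se))
  set.seed(99)
  a <- replicate(50, rand_decide(sp6))
  set.seed(99)
  expect_identical(a, replicate(50, rand_decide(sp6)))
})

test_that("learning-progress baselines pick the level with the steepest
           score slope", {
  sp <- curriculum_spec(2)
  # one level: always that level
  sp1 <- curriculum_spec(1)
  st1 <- list(scores = list(c(0.1, 0.2)), slope_ema = 0.1)
  expect_equal(lp_baseline_decide(st1, "naive", sp1, explore = 0), 1L)
  # flat vs improving
  st <- list(scores = list(c(0.4, 0.4, 0.4), c(0.1, 0.3, 0.5)),
             slope_ema = c(0, 0.2))
  for (v in c("online", "naive", "window")) {
    expect_equal(lp_baseline_decide(st, v, sp, explore = 0), 2L)
  }
  # sampling with equal progress is asymptotically uniform
  st_eq <- list(scores = list(c(0.1, 0.2), c(0.3, 0.4)),
                slope_ema = c(0.1, 0.1))
  set.seed(12)
  draws <- replicate(4000, lp_baseline_decide(st_eq, "sampling", sp))
  expect_lt(abs(mean(draws == 1) - 0.5), 3 * sqrt(0.25 / 4000))
  # unvisited levels are sampled first
  st_new <- list(scores = list(numeric(0), c(0.5)), slope_ema = c(0, 0))
  expect_equal(lp_baseline_decide(st_new, "online", sp, explore = 0), 1L)
})

test_that("a deterministic-success student completes under INC exactly as
           the EMA walkthrough predicts", {
  N <- 5
  sp <- curriculum_spec(N, T_attempts = 10, tau = 0.85, budget = 200)
  st <- student_params(N, eps = 50, alpha = 0) # always succeeds
  set.seed(1)
  fit <- run_curriculum(teacher_inc(), st, sp)
  expect_true(fit$completed)
  expect_true(all(diff(fit$log$level) >= 0)) # INC never decrements
  # oracle walkthrough: all outcomes are 1, so each level's estimate is
  # 1 - 0.9^(10 * visits); count interactions until each crosses tau
  per_level <- which(1 - 0.9^(10 * (1:10)) >= sp$tau)[1]
  expect_equal(fit$interactions_used, N * per_level)
  expect_false("DECREMENT" %in% fit$log$action)
})

test_that("budget exhaustion reports an incomplete curriculum", {
  sp <- curriculum_spec(10, budget = 1)
  set.seed(2)
  fit <- run_curriculum(teacher_inc(), student_params(10, -2, 0.1), sp)
  expect_false(fit$completed)
  expect_equal(fit$interactions_used, 1L)
  expect_equal(nrow(fit$log), 1L)
})

test_that("identical seed and configuration give bit-identical runs", {
  sp <- curriculum_spec(6, budget = 120)
  st <- student_params(6, eps = -1.2, alpha = 0.1)
  for (tch in list(teacher_inc(), teacher_adp(), teacher_rand(),
                   teacher_lp("online"))) {
    set.seed(77)
    a <- run_curriculum(tch, st, sp)
    set.seed(77)
    b <- run_curriculum(tch, st, sp)
    expect_identical(a$log, b$log)
    expect_identical(a$q_history, b$q_history)
    expect_identical(a$completed, b$completed)
  }
})

test_that("levels stay within bounds and out-of-range teacher proposals
           are clamped", {
  rogue <- structure(list(
    name = "rogue",
    init = function(spec) NULL,
    propose = function(tstate, level, tracker, spec, last_block) {
      list(level = 99L, action = "JUMP", tstate = tstate)
    }
  ), class = "ocl_teacher")
  sp <- curriculum_spec(4, budget = 10)
  set.seed(3)
  fit <- run_curriculum(rogue, student_params(4, 0, 0.1), sp)
  expect_true(all(fit$log$level >= 1 & fit$log$level <= 4))
  expect_true(all(fit$log$level == 4))
})

test_that("the adaptive teacher survives and alternates where the
           incremental teacher collapses", {
  sp <- curriculum_spec(10)
  seeds <- 1:5
  runs <- lapply(seeds, function(s) {
    set.seed(s)
    st <- student_params(10, eps = -2, alpha = 0.1)
    run_curriculum(teacher_adp(), st, sp, record_q = FALSE)
  })
  n_dec <- vapply(runs, function(r) sum(r$log$action == "DECREMENT"),
                  numeric(1))
  expect_gte(sum(n_dec >= 1), 4) # alternation in nearly all seeds
  expect_gte(sum(vapply(runs, `[[`, logical(1), "completed")), 3)
  # INC, by construction, never decrements
  set.seed(1)
  inc <- run_curriculum(teacher_inc(), student_params(10, -2, 0.1), sp,
                        record_q = FALSE)
  expect_false("DECREMENT" %in% inc$log$action)
})

test_that("tidy and glance summarize curriculum fits", {
  set.seed(8)
  fit <- run_curriculum(teacher_inc(), student_params(3, 0.5, 0.2),
                        curriculum_spec(3, budget = 80))
  td <- tidy(fit)
  expect_s3_class(td, "tbl_df")
  expect_equal(nrow(td), fit$interactions_used)
  expect_equal(td$teacher[1], "inc")
  gl <- glance(fit)
  expect_equal(nrow(gl), 1L)
  expect_true(gl$completed)
  expect_equal(gl$final_level, 3)
})
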