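#' Teacher registry
#'
#' Build a teacher by name, as used in benchmark configurations and the
#' command-line interface. Known names: `inc`, `rand`, `adp`, `pomcp`,
#' `lp-online`, `lp-naive`, `lp-window`, `lp-sampling`.
#'
#' @param name Teacher id.
#' @param policy [adp_policy()] for `adp` (default: the package's evolved
#'   policy).
#' @param pomcp [pomcp_config()] for `pomcp`.
#' @param prior [prior_spec()] for `pomcp`.
#' @return An `ocl_teacher`.
#' @examples
#' make_teacher("inc")
#' make_teacher("lp-online")
#' @export
make_teacher <- function(name, policy = adp_policy(),
                         pomcp = pomcp_config(), prior = prior_spec()) {
  switch(name,
    inc = teacher_inc(),
    rand = teacher_rand(),
    adp = teacher_adp(policy),
    pomcp = teacher_pomcp(pomcp, prior),
    `lp-online` = teacher_lp("online"),
    `lp-naive` = teacher_lp("naive"),
    `lp-window` = teacher_lp("window"),
    `lp-sampling` = teacher_lp("sampling"),
    abort(paste0("unknown teacher id `", name, "`"))
  )
}

#' Benchmark configuration
#'
#' A sweep over teachers, student biases and seeded repeats under one
#' curriculum specification, mirroring the standard completion-time
#' benchmark (means over repeats per teacher and bias).
#'
#' @param teachers Character vector of teacher ids (see [make_teacher()]).
#' @param eps_grid Student biases to sweep.
#' @param repeats Seeded repeats per cell (default 10).
#' @param spec A [curriculum_spec()].
#' @param alpha Student learning rate (default 0.1).
#' @param master_seed Master seed; per-run sub-seeds derive from it
#'   deterministically and order-insensitively.
#' @param policy [adp_policy()] used for the `adp` teacher.
#' @return An object of class `ocl_benchmark_config`.
#' @export
benchmark_config <- function(teachers, eps_grid, repeats = 10,
                             spec = curriculum_spec(10), alpha = 0.1,
                             master_seed = 1, policy = adp_policy()) {
  stopifnot(length(teachers) >= 1, length(eps_grid) >= 1, repeats >= 1)
  unknown <- setdiff(teachers, c("inc", "rand", "adp", "pomcp", "lp-online",
                                 "lp-naive", "lp-window", "lp-sampling"))
  if (length(unknown) > 0) {
    abort(paste("unknown teacher id(s):", paste(unknown, collapse = ", ")))
  }
  structure(
    list(teachers = teachers, eps_grid = eps_grid,
         repeats = as.integer(repeats), spec = spec, alpha = alpha,
         master_seed = as.integer(master_seed), policy = policy),
    class = "ocl_benchmark_config"
  )
}

# deterministic sub-seed per (teacher, eps, repeat); depends only on the
# cell's content, never on its position in the sweep, so reordering or
# subsetting a config leaves each run's seed unchanged
derive_seed <- function(master_seed, teacher, eps, rep_idx) {
  th <- sum(utf8ToInt(teacher) * (seq_len(nchar(teacher)) + 13))
  (master_seed * 48271 + th * 40503 + round(eps * 1000) * 9973 +
     rep_idx * 7919) %% 2147483629
}

#' Run a benchmark sweep
#'
#' Executes [run_curriculum()] for every (teacher, bias, repeat) cell of
#' the configuration and returns a tidy results table with one row per
#' run. Optionally writes a CSV summary and per-run JSONL transcript logs.
#'
#' @param cfg A [benchmark_config()].
#' @param out_dir Optional output directory; created if missing.
#' @param record_q Keep action-value histories (memory-heavy for large
#'   sweeps; default `FALSE`).
#' @return A tibble with columns `teacher`, `eps`, `seed`, `sub_seed`,
#'   `completed`, `interactions_used`, `final_level`, `final_s_hat`,
#'   `true_p_full`. When `record_q = TRUE` the `ocl_curriculum` objects are
#'   attached as a list attribute `"runs"`.
#' @examples
#' cfg <- benchmark_config(c("inc", "adp"), eps_grid = -1, repeats = 2,
#'                         spec = curriculum_spec(4, budget = 150))
#' run_benchmark(cfg)
#' @export
run_benchmark <- function(cfg, out_dir = NULL, record_q = FALSE) {
  stopifnot(inherits(cfg, "ocl_benchmark_config"))
  if (!is.null(out_dir) && !dir.exists(out_dir)) {
    dir.create(out_dir, recursive = TRUE)
  }
  cells <- tidyr::expand_grid(
    teacher = cfg$teachers,
    eps = cfg$eps_grid,
    seed = seq_len(cfg$repeats)
  )
  runs <- vector("list", nrow(cells))
  rows <- purrr::pmap(cells, function(teacher, eps, seed) {
    sub <- derive_seed(cfg$master_seed, teacher, eps, seed)
    set.seed(sub)
    st <- student_params(cfg$spec$n_levels, eps = eps, alpha = cfg$alpha)
    res <- run_curriculum(make_teacher(teacher, policy = cfg$policy), st,
                          cfg$spec, record_q = record_q)
    if (!is.null(out_dir)) {
      write_transcript_jsonl(
        res$log,
        file.path(out_dir, sprintf("run_%s_eps%s_seed%d.jsonl",
                                   teacher, format(eps), seed))
      )
    }
    list(res = if (record_q) res else NULL,
         row = tibble::tibble(
           teacher = teacher, eps = eps, seed = seed, sub_seed = sub,
           completed = res$completed,
           interactions_used = res$interactions_used,
           final_level = tail(res$log$level, 1),
           final_s_hat = tail(res$log$s_hat, 1),
           true_p_full = tail(res$log$true_p_full, 1)
         ))
  })
  out <- dplyr::bind_rows(purrr::map(rows, "row"))
  if (!is.null(out_dir)) {
    utils::write.csv(out, file.path(out_dir, "benchmark.csv"),
                     row.names = FALSE)
  }
  if (record_q) attr(out, "runs") <- purrr::map(rows, "res")
  out
}

#' Export the action-value history of a run
#'
#' The striped reinforcement/extinction dynamics of a curriculum are read
#' from the matrix of action values over interactions together with the
#' assigned-level trajectory; this exports both, sufficient to regenerate
#' the grayscale q-value figure.
#'
#' @param result An `ocl_curriculum` from [run_curriculum()] with
#'   `record_q = TRUE`.
#' @param path Optional CSV path.
#' @return A tibble with columns `t`, `level` and `q1..qN`, invisibly if
#'   written to `path`.
#' @export
export_q_history <- function(result, path = NULL) {
  if (is.null(result$q_history)) {
    abort("q history was not recorded; rerun with `record_q = TRUE`.")
  }
  qh <- result$q_history
  colnames(qh) <- paste0("q", seq_len(ncol(qh)))
  out <- dplyr::bind_cols(
    tibble::tibble(t = result$log$t, level = result$log$level),
    tibble::as_tibble(qh)
  )
  if (!is.null(path)) {
    utils::write.csv(out, path, row.names = FALSE)
    return(invisible(out))
  }
  out
}

#' Detect reinforcement/extinction stripes in a curriculum log
#'
#' A "stripe" is the signature of an increment followed by transient
#' extinction and eventual recovery: an INCREMENT action followed within
#' `within` interactions by a success-estimate drop below `drop`, with the
#' estimate at that level later reaching `tau`. Thresholds are heuristic
#' and intended for diagnostics and tests, not inference.
#'
#' @param result An `ocl_curriculum`.
#' @param drop Drop threshold on `delta_s_hat` (default -0.1).
#' @param within Window after the increment, in interactions (default 3).
#' @return A tibble with one row per detected stripe (`t_increment`,
#'   `level`, `t_drop`, `t_recover`).
#' @export
detect_stripes <- function(result, drop = -0.1, within = 3) {
  log <- result$log
  tau <- result$spec$tau
  incs <- which(log$action == "INCREMENT")
  out <- purrr::map(incs, function(t0) {
    lev <- log$level[t0]
    win <- log[log$t > t0 & log$t <= t0 + within & log$level == lev, ]
    if (nrow(win) == 0 && log$delta_s_hat[t0] >= drop) return(NULL)
    t_drop <- if (log$delta_s_hat[t0] < drop) {
      log$t[t0]
    } else {
      cand <- win$t[win$delta_s_hat < drop]
      if (length(cand) == 0) return(NULL) else cand[1]
    }
    later <- log[log$t >= t_drop & log$level == lev & log$s_hat >= tau, ]
    if (nrow(later) == 0) return(NULL)
    tibble::tibble(t_increment = log$t[t0], level = lev, t_drop = t_drop,
                   t_recover = later$t[1])
  })
  dplyr::bind_rows(out)
}

#' Estimate the incremental teacher's failure boundary
#'
#' Sweeps the student's innate bias over a grid, runs seeded repeats of the
#' incremental teacher at each value, and locates the collapse of the
#' completion rate: scanning from the easiest bias downward, the boundary
#' is the midpoint between the last bias with a majority of completions
#' and the first with a minority. This is the critical bias below which
#' incremental shaping fails; under the default conditions it sits near
#' -1.7, where the naive per-step success rate is about 15%.
#'
#' @param eps_grid Bias grid, default `seq(-1, -2.2, by = -0.1)`.
#' @param repeats Seeded repeats per grid point (default 10).
#' @param spec A [curriculum_spec()].
#' @param alpha Student learning rate (default 0.1).
#' @param master_seed Master seed for the sweep.
#' @return A list with `midpoint` (the estimated critical bias), `table`
#'   (a tibble of per-bias completion rates, easiest first) and `n_runs`.
#' @examples
#' \donttest{
#' inc_failure_boundary(eps_grid = c(-1, -2.2), repeats = 2)
#' }
#' @export
inc_failure_boundary <- function(eps_grid = seq(-1, -2.2, by = -0.1),
                                 repeats = 10,
                                 spec = curriculum_spec(10), alpha = 0.1,
                                 master_seed = 1) {
  cfg <- benchmark_config("inc", eps_grid = eps_grid, repeats = repeats,
                          spec = spec, alpha = alpha,
                          master_seed = master_seed)
  runs <- run_benchmark(cfg)
  tbl <- dplyr::arrange(
    dplyr::summarise(dplyr::group_by(runs, .data$eps),
                     completion_rate = mean(.data$completed),
                     .groups = "drop"),
    dplyr::desc(.data$eps)
  )
  below <- which(tbl$completion_rate < 0.5)
  midpoint <- if (length(below) == 0) {
    min(tbl$eps) # no collapse inside the grid
  } else if (below[1] == 1) {
    max(tbl$eps) # collapse before the grid starts
  } else {
    mean(tbl$eps[c(below[1] - 1, below[1])])
  }
  list(midpoint = midpoint, table = tbl, n_runs = nrow(runs))
}
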