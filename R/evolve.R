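#' Configuration for evolving teacher policies
#'
#' Settings for tuning the adaptive teacher's decision thresholds by
#' differential evolution against simulated curricula. A candidate policy's
#' cost is its mean completion time over a grid of student biases and a
#' fixed set of evaluation seeds, with a penalty substituted for runs that
#' do not finish within budget.
#'
#' @param population DE population size (at least 4; default 16).
#' @param generations DE generations (default 40).
#' @param F Differential weight (default 0.7).
#' @param CR Crossover rate in (0, 1] (default 0.9).
#' @param bounds Named list of `c(lower, upper)` per parameter. Defaults to
#'   `theta_inc` in (0.5, 0.99) and `mu` in (-1, 0.1); note a `mu` at -1 can
#'   never trigger (the tracker cannot drop that fast), so the incremental
#'   rule lies inside the search space. Add a `beta` entry to co-evolve the
#'   tracker decay.
#' @param eval_eps_grid Training grid of student biases (default
#'   `c(-1, -1.5, -2)`, spanning the incremental teacher's failure
#'   boundary).
#' @param eval_seeds Integer seeds reused for every candidate (common random
#'   numbers; default `1:5`).
#' @param spec The [curriculum_spec()] evaluated against.
#' @param alpha Student learning rate used in evaluation (default 0.1).
#' @param dnf_penalty Cost charged for a run that does not finish
#'   (default `2 * spec$budget`).
#' @param aggregate `"mean"` (default) or `"median"` across grid and seeds.
#' @return An object of class `ocl_evolve_config`.
#' @export
evolve_config <- function(population = 16, generations = 40, F = 0.7,
                          CR = 0.9,
                          bounds = list(theta_inc = c(0.5, 0.99),
                                        mu = c(-1, 0.1)),
                          eval_eps_grid = c(-1, -1.5, -2),
                          eval_seeds = 1:5,
                          spec = curriculum_spec(10),
                          alpha = 0.1,
                          dnf_penalty = 2 * spec$budget,
                          aggregate = c("mean", "median")) {
  stopifnot(population >= 4, generations >= 1, F > 0, CR > 0, CR <= 1,
            length(eval_eps_grid) >= 1, length(eval_seeds) >= 1)
  aggregate <- match.arg(aggregate)
  structure(
    list(population = as.integer(population),
         generations = as.integer(generations), F = F, CR = CR,
         bounds = bounds, eval_eps_grid = eval_eps_grid,
         eval_seeds = as.integer(eval_seeds), spec = spec, alpha = alpha,
         dnf_penalty = dnf_penalty, aggregate = aggregate),
    class = "ocl_evolve_config"
  )
}

#' Cost of an adaptive policy on simulated curricula
#'
#' Runs the adaptive teacher with the given thresholds on every
#' (bias, seed) pair in the configuration and aggregates the number of
#' interactions used, substituting `dnf_penalty` for runs that fail to
#' complete. Lower is better. Evaluation seeds are fixed in the
#' configuration, so the cost of a given policy is deterministic.
#'
#' @param policy An [adp_policy()].
#' @param cfg An [evolve_config()].
#' @return A single cost value.
#' @examples
#' cfg <- evolve_config(eval_eps_grid = -1, eval_seeds = 1,
#'                      spec = curriculum_spec(4, budget = 200))
#' evaluate_policy(adp_policy(0.85, -0.05), cfg)
#' @export
evaluate_policy <- function(policy, cfg) {
  spec <- cfg$spec
  if (!is.null(policy$beta)) {
    spec <- curriculum_spec(spec$n_levels, spec$T_attempts, spec$tau,
                            spec$budget, beta = policy$beta)
  }
  teach <- teacher_adp(policy)
  costs <- vapply(cfg$eval_eps_grid, function(eps) {
    vapply(cfg$eval_seeds, function(seed) {
      set.seed(seed)
      st <- student_params(spec$n_levels, eps = eps, alpha = cfg$alpha)
      res <- run_curriculum(teach, st, spec, record_q = FALSE)
      if (res$completed) res$interactions_used else cfg$dnf_penalty
    }, numeric(1))
  }, numeric(length(cfg$eval_seeds)))
  if (cfg$aggregate == "mean") mean(costs) else stats::median(costs)
}

#' Differential evolution (DE/rand/1/bin)
#'
#' Plain global optimizer over a box: mutation by scaled vector differences
#' of three distinct population members, binomial crossover, greedy
#' one-to-one selection. Used to tune teacher decision trees, and usable on
#' any objective.
#'
#' @param fn Objective, taking a numeric vector, returning a single cost.
#' @param lower,upper Numeric bounds (equal length).
#' @param population Population size (default 16).
#' @param generations Number of generations (default 40).
#' @param F Differential weight (default 0.7).
#' @param CR Crossover rate (default 0.9).
#' @param init Optional matrix (rows = members) of initial population
#'   members; remaining members are drawn uniformly in the box.
#' @return A list with `par` (best vector), `value` (its cost), `history`
#'   (best cost after each generation; non-increasing) and `n_evals`.
#' @examples
#' set.seed(1)
#' fit <- de_optimize(function(x) sum((x - 0.3)^2), c(-1, -1), c(1, 1),
#'                    population = 12, generations = 30)
#' fit$par
#' @export
de_optimize <- function(fn, lower, upper, population = 16, generations = 40,
                        F = 0.7, CR = 0.9, init = NULL) {
  d <- length(lower)
  stopifnot(length(upper) == d, all(lower < upper), population >= 4)
  pop <- matrix(runif(population * d, rep(lower, each = population),
                      rep(upper, each = population)),
                population, d)
  if (!is.null(init)) {
    k <- min(nrow(init), population)
    pop[seq_len(k), ] <- init[seq_len(k), , drop = FALSE]
  }
  cost <- apply(pop, 1, fn)
  n_evals <- population
  history <- numeric(generations)
  for (g in seq_len(generations)) {
    for (i in seq_len(population)) {
      r <- sample(setdiff(seq_len(population), i), 3L)
      v <- pop[r[1], ] + F * (pop[r[2], ] - pop[r[3], ])
      v <- pmin(pmax(v, lower), upper)
      jrand <- sample.int(d, 1L)
      cross <- runif(d) < CR
      cross[jrand] <- TRUE
      trial <- ifelse(cross, v, pop[i, ])
      tc <- fn(trial)
      n_evals <- n_evals + 1L
      if (tc <= cost[i]) {
        pop[i, ] <- trial
        cost[i] <- tc
      }
    }
    history[g] <- min(cost)
  }
  best <- which.min(cost)
  structure(
    list(par = pop[best, ], value = cost[best], history = history,
         n_evals = n_evals, population = pop, cost = cost),
    class = "ocl_de"
  )
}

#' @export
print.ocl_de <- function(x, ...) {
  cat("<ocl_de> best cost", format(x$value, digits = 5), "at [",
      paste(format(x$par, digits = 4), collapse = ", "), "] after",
      x$n_evals, "evaluations\n")
  invisible(x)
}

#' Evolve the adaptive teacher's thresholds
#'
#' Tunes [adp_policy()] parameters by [de_optimize()] against
#' [evaluate_policy()]. The initial population is seeded with the
#' incremental-rule vertex (`theta_inc = tau`, `mu` at its lower bound,
#' where the decrement branch never fires), so the evolved policy can only
#' match or beat the incremental teacher on the training grid. The evolved
#' policy is meant to be frozen and reused for all benchmarks without
#' re-tuning.
#'
#' @param cfg An [evolve_config()].
#' @return A list with `policy` (the best [adp_policy()]), `cost`, and the
#'   full `de` fit (history, final population).
#' @examples
#' \donttest{
#' set.seed(1)
#' cfg <- evolve_config(population = 8, generations = 4,
#'                      eval_eps_grid = c(-1, -1.5), eval_seeds = 1:2,
#'                      spec = curriculum_spec(6, budget = 400))
#' evolve_adp_policy(cfg)$policy
#' }
#' @export
evolve_adp_policy <- function(cfg) {
  nm <- names(cfg$bounds)
  lower <- vapply(cfg$bounds, `[`, numeric(1), 1)
  upper <- vapply(cfg$bounds, `[`, numeric(1), 2)
  as_policy <- function(x) {
    x <- setNames(as.list(x), nm)
    adp_policy(theta_inc = x$theta_inc, mu = x$mu, beta = x$beta)
  }
  inc_vertex <- setNames(numeric(length(nm)), nm)
  inc_vertex["theta_inc"] <- min(max(cfg$spec$tau, lower["theta_inc"]),
                                 upper["theta_inc"])
  inc_vertex["mu"] <- lower["mu"]
  if ("beta" %in% nm) inc_vertex["beta"] <- cfg$spec$beta
  fit <- de_optimize(function(x) evaluate_policy(as_policy(x), cfg),
                     lower, upper,
                     population = cfg$population,
                     generations = cfg$generations,
                     F = cfg$F, CR = cfg$CR,
                     init = matrix(inc_vertex, 1))
  list(policy = as_policy(fit$par), cost = fit$value, de = fit)
}

#' Read and write adaptive policies as JSON
#'
#' The JSON written by `write_policy_json()` is the exact input format
#' accepted by the command-line `simulate` entry point for the adaptive
#' teacher.
#'
#' @param policy An [adp_policy()] or [cont_adp_policy()].
#' @param path File path.
#' @return `write_policy_json()`: the path, invisibly;
#'   `read_policy_json()`: the policy object.
#' @export
write_policy_json <- function(policy, path) {
  x <- unclass(policy)
  x$kind <- if (inherits(policy, "ocl_cont_adp_policy")) "continuous" else
    "discrete"
  jsonlite::write_json(x[!vapply(x, is.null, logical(1))], path,
                       auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_policy_json
#' @export
read_policy_json <- function(path) {
  x <- jsonlite::fromJSON(path)
  if (identical(x$kind, "continuous")) {
    cont_adp_policy(theta_hi = x$theta_hi, theta_grow = x$theta_grow,
                    mu = x$mu, nu_lo = x$nu_lo)
  } else {
    adp_policy(theta_inc = x$theta_inc, mu = x$mu, beta = x$beta)
  }
}
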