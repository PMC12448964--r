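#' Tidy curriculum results
#'
#' `tidy()` returns the per-interaction log as a tibble; `glance()` a
#' one-row summary.
#'
#' @param x An `ocl_curriculum` or `ocl_cont_curriculum`.
#' @param ... Unused.
#' @return A tibble.
#' @examples
#' set.seed(1)
#' fit <- run_curriculum(teacher_inc(), student_params(3, 0, 0.2),
#'                       curriculum_spec(3, budget = 100))
#' tidy(fit)
#' glance(fit)
#' @export
tidy.ocl_curriculum <- function(x, ...) {
  dplyr::mutate(x$log, teacher = x$teacher, .before = 1)
}

#' @rdname tidy.ocl_curriculum
#' @export
glance.ocl_curriculum <- function(x, ...) {
  tibble::tibble(
    teacher = x$teacher,
    completed = x$completed,
    interactions_used = x$interactions_used,
    final_level = tail(x$log$level, 1),
    final_s_hat = tail(x$log$s_hat, 1),
    true_p_full = tail(x$log$true_p_full, 1),
    n_levels = x$spec$n_levels
  )
}

#' @rdname tidy.ocl_curriculum
#' @export
tidy.ocl_cont_curriculum <- function(x, ...) {
  dplyr::mutate(x$log, teacher = x$teacher, .before = 1)
}

#' @rdname tidy.ocl_curriculum
#' @export
glance.ocl_cont_curriculum <- function(x, ...) {
  tibble::tibble(
    teacher = x$teacher,
    completed = x$completed,
    interactions_used = x$interactions_used,
    final_difficulty = tail(x$log$difficulty, 1),
    final_s_hat = tail(x$log$s_hat, 1),
    max_difficulty = x$cspec$max_difficulty
  )
}

#' Tidy differential-evolution fits
#'
#' @param x An `ocl_de` from [de_optimize()].
#' @param ... Unused.
#' @return `tidy()`: a tibble of per-generation best costs; `glance()`:
#'   a one-row summary.
#' @export
tidy.ocl_de <- function(x, ...) {
  tibble::tibble(generation = seq_along(x$history), best_cost = x$history)
}

#' @rdname tidy.ocl_de
#' @export
glance.ocl_de <- function(x, ...) {
  tibble::tibble(best_cost = x$value, n_evals = x$n_evals,
                 generations = length(x$history))
}

#' Plot the striped action-value dynamics of a curriculum
#'
#' Grayscale heatmap of the action values `q_i` over interactions with the
#' assigned difficulty overlaid in red — the standard visualization of
#' alternating reinforcement and extinction waves along a curriculum.
#'
#' @param object An `ocl_curriculum` run with `record_q = TRUE`, or an
#'   `ocl_cont_curriculum`.
#' @param ... Unused.
#' @return A ggplot.
#' @examples
#' set.seed(1)
#' fit <- run_curriculum(teacher_inc(), student_params(5, -1, 0.1),
#'                       curriculum_spec(5, budget = 500))
#' autoplot(fit)
#' @export
autoplot.ocl_curriculum <- function(object, ...) {
  if (is.null(object$q_history)) {
    abort("q history was not recorded; rerun with `record_q = TRUE`.")
  }
  qh <- export_q_history(object)
  long <- tidyr::pivot_longer(qh, dplyr::starts_with("q"),
                              names_to = "step", names_prefix = "q",
                              values_to = "value")
  long$step <- as.integer(long$step)
  ggplot2::ggplot(long, ggplot2::aes(x = .data$t, y = .data$step)) +
    ggplot2::geom_raster(ggplot2::aes(fill = .data$value)) +
    ggplot2::geom_step(
      data = qh, ggplot2::aes(x = .data$t, y = .data$level),
      color = "red", linewidth = 0.4
    ) +
    ggplot2::scale_fill_gradient(low = "white", high = "black",
                                 name = "q value") +
    ggplot2::labs(x = "interaction", y = "sequence step / level") +
    ggplot2::theme_minimal()
}

#' @rdname autoplot.ocl_curriculum
#' @export
autoplot.ocl_cont_curriculum <- function(object, ...) {
  log <- object$log
  ggplot2::ggplot(log, ggplot2::aes(x = .data$t)) +
    ggplot2::geom_step(ggplot2::aes(y = .data$difficulty),
                       color = "red") +
    ggplot2::geom_line(ggplot2::aes(y = .data$s_hat *
                                      object$cspec$max_difficulty),
                       color = "grey40", linetype = 2) +
    ggplot2::scale_y_continuous(
      name = "difficulty",
      sec.axis = ggplot2::sec_axis(~ . / object$cspec$max_difficulty,
                                   name = "estimated success rate")
    ) +
    ggplot2::labs(x = "interaction") +
    ggplot2::theme_minimal()
}

#' Plot benchmark results
#'
#' Completion rate and mean completion time per teacher and student bias
#' from a [run_benchmark()] table.
#'
#' @param df A tibble from [run_benchmark()].
#' @return A ggplot.
#' @export
plot_benchmark <- function(df) {
  summ <- dplyr::summarise(
    dplyr::group_by(df, .data$teacher, .data$eps),
    completion_rate = mean(.data$completed),
    mean_interactions = mean(.data$interactions_used),
    .groups = "drop"
  )
  ggplot2::ggplot(summ,
                  ggplot2::aes(x = factor(.data$eps),
                               y = .data$mean_interactions,
                               fill = .data$teacher)) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::geom_text(ggplot2::aes(label = scales_percent(
      .data$completion_rate)),
      position = ggplot2::position_dodge(width = 0.9), vjust = -0.3,
      size = 2.8) +
    ggplot2::labs(x = "innate bias", y = "mean interactions used",
                  caption = "labels: completion rate") +
    ggplot2::theme_minimal()
}

# tiny percent formatter; avoids a scales dependency
scales_percent <- function(x) paste0(round(100 * x), "%")
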