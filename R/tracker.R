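#' One step of the exponential-moving-average success estimator
#'
#' The teacher never sees the student's action values; it estimates the
#' success rate at each difficulty level from the outcome transcript with an
#' exponential moving average, `s <- (1 - beta) * s + beta * x`.
#'
#' @param s Current estimate in `[0, 1]`.
#' @param x Observed outcome, 0 or 1 (vectorized: a block of outcomes is
#'   folded in order).
#' @param beta Decay in `(0, 1)`; larger values weight recent outcomes more.
#' @return Updated estimate after folding in all of `x`.
#' @examples
#' ema_update(0.5, 1, 0.2)        # 0.6
#' ema_update(0, c(1, 1, 1), 0.2) # 1 - 0.8^3
#' @export
ema_update <- function(s, x, beta) {
  if (!is.numeric(s) || length(s) != 1L || s < 0 || s > 1) {
    abort("`s` must be a single probability.")
  }
  if (!is.numeric(x) || !all(x %in% c(0, 1))) {
    abort("`x` must be binary outcomes (0/1).")
  }
  if (!is.numeric(beta) || length(beta) != 1L || beta <= 0 || beta >= 1) {
    abort("`beta` must lie strictly in (0, 1).")
  }
  for (xi in x) s <- (1 - beta) * s + beta * xi
  s
}

#' Per-level success-rate tracker
#'
#' Maintains one EMA estimate per difficulty level. Estimates persist across
#' level changes, so revisiting a level resumes its estimate; a level's
#' estimate starts at 0 on first visit.
#'
#' @param n_levels Number of difficulty levels.
#' @param beta EMA decay (default 0.1).
#' @return An object of class `ocl_rate_tracker` with fields `s_hat`
#'   (numeric, length `n_levels`), `visited` (logical), `last_delta`, `beta`.
#' @examples
#' tr <- rate_tracker(5)
#' observe_interaction(tr, level = 1, block = c(1, 1, 0, 1))
#' @export
rate_tracker <- function(n_levels, beta = 0.1) {
  if (!is.numeric(beta) || beta <= 0 || beta >= 1) {
    abort("`beta` must lie strictly in (0, 1).")
  }
  structure(
    list(s_hat = rep(0, n_levels), visited = rep(FALSE, n_levels),
         last_delta = 0, beta = beta),
    class = "ocl_rate_tracker"
  )
}

#' @export
print.ocl_rate_tracker <- function(x, ...) {
  cat("<ocl_rate_tracker> beta =", x$beta, "\n  s_hat:",
      paste(format(x$s_hat, digits = 3), collapse = " "), "\n")
  invisible(x)
}

#' Fold an interaction block into the tracker
#'
#' Applies [ema_update()] outcome-by-outcome to the assigned level's
#' estimate and records the per-interaction change
#' `delta_s_hat = s_hat(after) - s_hat(before)` — the learning-progress
#' feature used by the adaptive teacher. Other levels' estimates are
#' untouched.
#'
#' @param tracker An [rate_tracker()].
#' @param level Difficulty level of the block.
#' @param block Integer vector of 0/1 outcomes (nonempty).
#' @return A list with `tracker` (updated), `s_hat` (post-block estimate at
#'   `level`) and `delta_s_hat`.
#' @export
observe_interaction <- function(tracker, level, block) {
  if (length(block) == 0) abort("`block` must be nonempty.")
  before <- tracker$s_hat[level]
  after <- ema_update(before, block, tracker$beta)
  tracker$s_hat[level] <- after
  tracker$visited[level] <- TRUE
  tracker$last_delta <- after - before
  list(tracker = tracker, s_hat = after, delta_s_hat = after - before)
}

#' Write / read a transcript log as JSONL
#'
#' The transcript — the ordered record of (interaction, level, outcomes) —
#' is the teacher's only observable. One JSON object per line with fields
#' `t`, `level`, `outcomes`, `s_hat`, `delta_s_hat`, `action`.
#'
#' @param transcript A tibble as produced by [run_curriculum()] (`$log`).
#' @param path File path.
#' @return `write_transcript_jsonl()`: the path, invisibly.
#'   `read_transcript_jsonl()`: the transcript tibble.
#' @export
write_transcript_jsonl <- function(transcript, path) {
  lines <- purrr::pmap_chr(transcript, function(t, level, outcomes, s_hat,
                                                delta_s_hat, action, ...) {
    jsonlite::toJSON(
      list(t = t, level = level, outcomes = as.integer(outcomes),
           s_hat = s_hat, delta_s_hat = delta_s_hat, action = action),
      auto_unbox = TRUE, digits = NA
    )
  })
  writeLines(lines, path)
  invisible(path)
}

#' @rdname write_transcript_jsonl
#' @export
read_transcript_jsonl <- function(path) {
  rows <- lapply(readLines(path), jsonlite::fromJSON)
  tibble::tibble(
    t = purrr::map_int(rows, "t"),
    level = purrr::map_dbl(rows, "level"),
    outcomes = purrr::map(rows, ~ as.integer(.x$outcomes)),
    s_hat = purrr::map_dbl(rows, "s_hat"),
    delta_s_hat = purrr::map_dbl(rows, "delta_s_hat"),
    action = purrr::map_chr(rows, "action")
  )
}
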