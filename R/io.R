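#' Read an experiment configuration file
#'
#' YAML or JSON (by extension) with blocks `spec` (fields of
#' [curriculum_spec()]), `student` (fields of [student_params()]; `eps`
#' scalar or list) and optionally `teachers`, `eps_grid`, `repeats`,
#' `policy` (fields of [adp_policy()]). Missing fields fall back to package
#' defaults. See `inst/extdata/benchmark-example.yaml` for a commented
#' example.
#'
#' @param path Config file path.
#' @return A list with elements `spec` (an `ocl_curriculum_spec`),
#'   `student` (an `ocl_student_params` or `NULL`), `policy`, and the raw
#'   remaining fields.
#' @export
read_curriculum_config <- function(path) {
  ext <- tolower(tools::file_ext(path))
  raw <- switch(ext,
    yaml = , yml = yaml::read_yaml(path),
    json = jsonlite::fromJSON(path, simplifyVector = TRUE),
    abort("config must be .yaml, .yml or .json")
  )
  sp <- raw$spec %||% list()
  spec <- curriculum_spec(
    n_levels = sp$n_levels %||% 10,
    T_attempts = sp$T_attempts %||% 10,
    tau = sp$tau %||% 0.85,
    budget = sp$budget %||% 1500,
    beta = sp$beta %||% 0.1
  )
  student <- if (!is.null(raw$student)) {
    student_params(
      n_steps = raw$student$n_steps %||% spec$n_levels,
      eps = unlist(raw$student$eps),
      alpha = raw$student$alpha %||% 0.1
    )
  }
  policy <- if (!is.null(raw$policy)) {
    adp_policy(theta_inc = raw$policy$theta_inc,
               mu = raw$policy$mu, beta = raw$policy$beta)
  } else {
    adp_policy()
  }
  c(list(spec = spec, student = student, policy = policy),
    raw[setdiff(names(raw), c("spec", "student", "policy"))])
}
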