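#' Fit the full iterative decomposition to a task dataset
#'
#' Runs the complete pipeline on a preprocessed trial dataset: (1) the
#' difficulty fixed point ([estimate_difficulty()]); (2) the ability/delay
#' fixed point ([estimate_ability_delay()]); (3) specific-ability rescoring
#' ([compute_specific_ability()]); (4) ability-scaled difficulty
#' ([compute_scaled_difficulty()]). The result carries the four estimates
#' the decomposition is built to deliver: a difficulty D and scaled
#' difficulty DS per trial label, and a specific ability AS and delay time
#' DT per participant. Deterministic given the dataset (including its
#' presentation order) and control settings.
#'
#' @param dataset a [task_dataset()].
#' @param control an [idoct_control()].
#' @return Object of class `idoct_fit`: list with `difficulty` (an
#'   `idoct_difficulty` with `ds` populated), `participants` (data.frame:
#'   `participant_id`, `a`, `as`, `dt`, `dt_max`, `q`), `at_max`, `traces`
#'   (per-stage iteration traces), `converged` (per-stage flags), `control`,
#'   `mode`, `rt_max`.
#' @examples
#' sim <- simulate_task(sim_params(n_participants = 50, n_labels = 8, seed = 1))
#' fit <- idoct(sim$dataset)
#' fit
#' head(participant_estimates(fit))
#' @export
idoct <- function(dataset, control = idoct_control()) {
  if (!inherits(dataset, "task_dataset")) {
    stop("dataset must be a task_dataset", call. = FALSE)
  }
  difficulty <- estimate_difficulty(dataset, control)
  ability <- estimate_ability_delay(dataset, difficulty, control)
  as_ <- compute_specific_ability(dataset, ability, difficulty)
  difficulty$ds <- suppressWarnings(
    compute_scaled_difficulty(dataset, difficulty, as_)
  )
  participants <- ability$participants
  participants$as <- unname(as_[participants$participant_id])
  participants <- participants[, c("participant_id", "a", "as", "dt",
                                   "dt_max", "q")]
  structure(
    list(
      difficulty = difficulty,
      participants = participants,
      at_max = ability$at_max,
      traces = list(difficulty = difficulty$trace, ability = ability$trace),
      converged = c(difficulty = difficulty$converged,
                    ability = ability$converged),
      n_iter = c(difficulty = difficulty$n_iter, ability = ability$n_iter),
      control = control,
      mode = dataset$mode,
      rt_max = dataset$rt_max
    ),
    class = "idoct_fit"
  )
}

#' @export
print.idoct_fit <- function(x, ...) {
  cat("idoct_fit (", x$mode, " accuracy)\n", sep = "")
  cat("  participants:", nrow(x$participants),
      " trial labels:", length(x$difficulty$d), "\n")
  cat("  iterations: difficulty", x$n_iter["difficulty"],
      if (x$converged["difficulty"]) "(converged)," else "(flagged),",
      "ability", x$n_iter["ability"],
      if (x$converged["ability"]) "(converged)" else "(flagged)", "\n")
  cat("  mean D  =", signif(mean(x$difficulty$d), 4),
      "  mean DS =", signif(mean(x$difficulty$ds), 4), "\n")
  cat("  mean AS =", signif(mean(x$participants$as), 4),
      "  mean DT =", signif(mean(x$participants$dt), 4), "ms\n")
  invisible(x)
}

#' Per-participant estimates of a fit
#'
#' @param fit an [idoct()] result.
#' @return data.frame with `participant_id`, `a` (ability), `as` (specific
#'   ability), `dt` and `dt_max` (ms), `q` (trial count).
#' @export
participant_estimates <- function(fit) {
  stopifnot(inherits(fit, "idoct_fit"))
  fit$participants
}

#' Per-label difficulty scale of a fit
#'
#' @param fit an [idoct()] result.
#' @return data.frame with `trial_label`, `d`, `ds`, `n_presentations`.
#' @export
difficulty_scale <- function(fit) {
  stopifnot(inherits(fit, "idoct_fit"))
  as.data.frame(fit$difficulty)
}

#' Write a fit to disk
#'
#' Writes `participants.csv`, `difficulty.csv`, `trace.csv` (per-stage
#' iteration traces) and `config.json` (control settings and convergence
#' flags, for provenance) into `outdir`, creating it if needed. Column order
#' is fixed, so identical fits produce byte-identical files.
#'
#' @param fit an [idoct()] result.
#' @param outdir output directory.
#' @return `outdir`, invisibly.
#' @export
write_fit <- function(fit, outdir) {
  stopifnot(inherits(fit, "idoct_fit"))
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  utils::write.csv(participant_estimates(fit),
                   file.path(outdir, "participants.csv"),
                   row.names = FALSE, quote = FALSE)
  utils::write.csv(difficulty_scale(fit),
                   file.path(outdir, "difficulty.csv"),
                   row.names = FALSE, quote = FALSE)
  traces <- rbind(
    data.frame(stage = "difficulty",
               iteration = seq_along(fit$traces$difficulty),
               mean_abs_change = fit$traces$difficulty),
    data.frame(stage = "ability",
               iteration = seq_along(fit$traces$ability),
               mean_abs_change = fit$traces$ability)
  )
  utils::write.csv(traces, file.path(outdir, "trace.csv"),
                   row.names = FALSE, quote = FALSE)
  config <- list(
    tol = fit$control$tol,
    max_iter = fit$control$max_iter,
    mode = fit$mode,
    rt_max = fit$rt_max,
    at_max = fit$at_max,
    converged = as.list(fit$converged),
    n_iter = as.list(fit$n_iter)
  )
  jsonlite::write_json(config, file.path(outdir, "config.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(outdir)
}

#' Read a fit's estimate tables back from disk
#'
#' @param outdir directory written by [write_fit()].
#' @return list with `participants` and `difficulty` data.frames and
#'   `config`.
#' @export
read_fit <- function(outdir) {
  list(
    participants = utils::read.csv(file.path(outdir, "participants.csv"),
                                   stringsAsFactors = FALSE),
    difficulty = utils::read.csv(file.path(outdir, "difficulty.csv"),
                                 stringsAsFactors = FALSE),
    config = jsonlite::read_json(file.path(outdir, "config.json"),
                                 simplifyVector = TRUE)
  )
}
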