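#' Control parameters for the fixed-point iterations
#'
#' Both estimation stages iterate until the mean absolute between-iteration
#' change of the stage's parameter vector (difficulty D, then ability A)
#' drops below `tol`, or `max_iter` iterations have been run. With the
#' defaults the iterations reproduce the fixed-depth behaviour observed in
#' practice (both stages contract geometrically and are close to their fixed
#' points within ten iterations); a non-converged stage is flagged on the
#' result, with its residual change recorded, rather than raising an error.
#'
#' @param tol convergence tolerance on the mean absolute parameter change.
#' @param max_iter maximum number of iterations per stage.
#' @return list of class `idoct_control`.
#' @export
idoct_control <- function(tol = 1e-6, max_iter = 10L) {
  stopifnot(tol >= 0, max_iter >= 1)
  structure(list(tol = tol, max_iter = as.integer(max_iter)),
            class = "idoct_control")
}

#' Per-trial performance score
#'
#' The elementary performance measure combining speed, accuracy and trial
#' difficulty: 0 for a wrong answer (an RT on a failed trial carries no
#' ability information), otherwise `(1 - rt/rt_max) * d`; in continuous mode
#' the graded accuracy multiplies the speed term instead of gating it.
#' Clamped to \[0, 1\].
#'
#' @param rt reaction time(s), ms.
#' @param score correctness indicator (binary mode) or graded accuracy in
#'   \[0,1\] (continuous mode); vectorised.
#' @param d difficulty value(s) in (0, 1\].
#' @param rt_max global RT scaling constant; must be `>= max(rt)`.
#' @return numeric vector of performances in \[0, 1\].
#' @export
compute_performance <- function(rt, score, d, rt_max) {
  if (any(rt > rt_max)) {
    stop("rt exceeds rt_max: scaling-constant inconsistency", call. = FALSE)
  }
  if (anyNA(score)) stop("missing accuracy score", call. = FALSE)
  pmin(1, pmax(0, (1 - rt / rt_max) * score * d))
}

# per-label mean of score * (1 - rt/rt_max): the contraction slope m_t of the
# difficulty iteration D_{n+1} = 1 - m_t * D_n
label_slopes <- function(dataset) {
  s <- trial_score(dataset) * (1 - dataset$records$rt / dataset$rt_max)
  m <- tapply(s, dataset$records$trial_label, mean)
  m <- m[sort(names(m))]
  stats::setNames(as.numeric(m), names(m))
}

#' Analytic fixed point of the difficulty iteration
#'
#' The difficulty update is affine per label, `D <- 1 - m_t * D`, with slope
#' `m_t` the mean over the label's presentations of
#' `score * (1 - rt/rt_max)`. Its fixed point is `1 / (1 + m_t)`. Used as an
#' independent oracle for [estimate_difficulty()].
#'
#' @param dataset a [task_dataset()].
#' @return named numeric vector of fixed-point difficulties per trial label.
#' @export
closed_form_difficulty <- function(dataset) {
  m <- label_slopes(dataset)
  1 / (1 + m)
}

#' Estimate the data-driven trial difficulty scale D
#'
#' First fixed-point stage. Every label starts at maximum difficulty
#' `D(t,0) = 1`; each iteration scores every presentation by
#' [compute_performance()] at the current difficulty and resets each label's
#' difficulty to the mean of `1 - P` over all its presentations (repeats by
#' the same participant count as separate presentations). Difficulty and
#' group performance converge on mutually consistent values; the converged D
#' lies in \[0.5, 1\] since the contraction slope `m_t` is in \[0, 1\].
#'
#' If a label's slope is exactly 1 (every presentation correct at rt = 0)
#' the iteration oscillates between 0 and 1; the analytic fixed point 0.5 is
#' returned for such labels with a warning.
#'
#' @param dataset a [task_dataset()].
#' @param control an [idoct_control()].
#' @return An object of class `idoct_difficulty`: list with `d` (named
#'   vector, trial label -> difficulty), `ds` (NA until scaled, see
#'   [compute_scaled_difficulty()]), `presentation_counts`, `trace` (mean
#'   |change in D| per iteration), `n_iter`, `converged` and `residual`.
#' @export
estimate_difficulty <- function(dataset, control = idoct_control()) {
  m <- label_slopes(dataset)
  degenerate <- abs(m - 1) < 1e-12
  if (any(degenerate)) {
    warning("label(s) with all-correct zero-RT presentations oscillate; ",
            "returning the analytic fixed point 0.5 for: ",
            paste(names(m)[degenerate], collapse = ", "), call. = FALSE)
  }
  d <- rep(1, length(m))
  names(d) <- names(m)
  trace <- numeric(0)
  converged <- FALSE
  n_iter <- 0L
  for (n in seq_len(control$max_iter)) {
    d_new <- ifelse(degenerate, 0.5, 1 - m * d)
    delta <- mean(abs(d_new - d))
    trace <- c(trace, delta)
    d <- d_new
    n_iter <- n
    if (delta < control$tol) {
      converged <- TRUE
      break
    }
  }
  if (!converged) {
    warning("difficulty stage did not reach tol = ", control$tol, " within ",
            control$max_iter, " iterations (residual mean |dD| = ",
            signif(trace[length(trace)], 3), ")", call. = FALSE)
  }
  counts <- table(dataset$records$trial_label)[names(d)]
  structure(
    list(
      d = d, ds = rep(NA_real_, length(d)) |> stats::setNames(names(d)),
      presentation_counts = as.integer(counts) |> stats::setNames(names(d)),
      trace = trace, n_iter = n_iter, converged = converged,
      residual = trace[length(trace)]
    ),
    class = "idoct_difficulty"
  )
}

#' @export
print.idoct_difficulty <- function(x, ...) {
  cat("idoct_difficulty:", length(x$d), "trial labels\n")
  cat("  D  range: [", signif(min(x$d), 4), ",", signif(max(x$d), 4), "]\n")
  if (!anyNA(x$ds)) {
    cat("  DS range: [", signif(min(x$ds), 4), ",", signif(max(x$ds), 4), "]\n")
  }
  cat("  iterations:", x$n_iter,
      if (x$converged) "(converged)" else "(NOT converged)", "\n")
  invisible(x)
}

#' @export
as.data.frame.idoct_difficulty <- function(x, ...) {
  data.frame(
    trial_label = names(x$d),
    d = unname(x$d),
    ds = unname(x$ds),
    n_presentations = unname(x$presentation_counts),
    row.names = NULL
  )
}
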