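#' @title Ability, delay-time and scaled-difficulty estimation
#'
#' @description Second fixed-point stage of the model. Reaction time is
#' decomposed as `RT(i,t) = AT(i,t) + DT(i)`: the answer time AT is the
#' portion attributable to the targeted cognitive process, while the delay
#' time DT collects device latency, visuomotor processing and
#' task-unspecific cognition. AT scales with trial difficulty and shrinks as
#' ability grows, `AT(i,t) = (1 - A(i)) * D(t) * (RT(i,t) - DTmax(i))`,
#' where `DTmax(i)` is the participant's smallest retained RT (an upper
#' bound on the delay at initialisation). Ability A is the running mean of
#' cumulative mean performance in presentation order, which makes the
#' estimate depend on the recorded presentation order (early trials carry
#' more weight); performance P combines speed, accuracy and difficulty as in
#' the first stage but with RT replaced by its decomposition. A and P are
#' mutually recursive, so a fixed-point iteration is run from A = 1
#' ("ability is maximum", equivalently AT initialised at its ceiling
#' `ATmin(i,t) = RT(i,t) - DTmax(i)` and DT at `DTmax(i)`).
#'
#' At the fixed point `DT(i)` is the mean of `RT - AT` over the
#' participant's trials and lies in `[DTmax(i), mean RT(i)]` by
#' construction.
#' @name ability_stage
NULL

# Precompute per-record structures for the ability iteration. Records are
# put in (participant, presentation-order) order; results are independent of
# participant processing order because every reduction is a per-participant
# sum over a factor with sorted levels.
prepare_ability_inputs <- function(dataset, d) {
  r <- dataset$records
  missing_labels <- setdiff(unique(r$trial_label), names(d))
  if (length(missing_labels) > 0L) {
    stop("difficulty scale lacks label(s): ",
         paste(missing_labels, collapse = ", "), call. = FALSE)
  }
  pid <- factor(r$participant_id, levels = sort(unique(r$participant_id)))
  perm <- order(as.integer(pid), r$order)
  pid <- pid[perm]
  q <- tabulate(pid, nbins = nlevels(pid))
  rt <- r$rt[perm]
  dtmax <- as.numeric(tapply(rt, pid, min))
  # weights of the mean-of-cumulative-means: A(i) = sum_k P_k * w_k with
  # w_k = (H_Q - H_{k-1}) / Q, H the harmonic numbers (H_0 = 0)
  H <- c(0, cumsum(1 / seq_len(max(q))))
  k <- sequence(q)
  ip <- as.integer(pid)
  w <- (H[q[ip] + 1L] - H[k]) / q[ip]
  sc <- trial_score(dataset)[perm]
  list(
    pid = pid, ip = ip, q = q, rt = rt, dtmax = dtmax, w = w,
    score = sc, dvec = unname(d[r$trial_label[perm]]),
    rt_max = dataset$rt_max,
    participant_id = levels(pid), perm = perm
  )
}

# one evaluation of AT, DT(i), P and the resulting A given current abilities;
# `first` uses the initial ATN = 1 (AT at its ceiling RT - DTmax)
ability_step <- function(st, a, first = FALSE) {
  atn <- if (first) 1 else (1 - a[st$ip]) * st$dvec
  at <- atn * (st$rt - st$dtmax[st$ip])
  dt_i <- as.numeric(rowsum(st$rt - at, st$ip)) / st$q
  p <- st$score * (1 - at / st$rt_max - dt_i[st$ip] / st$rt_max) * st$dvec
  p <- pmin(1, pmax(0, p))
  a_new <- as.numeric(rowsum(p * st$w, st$ip))
  list(a = a_new, at = at, dt = dt_i, p = p)
}

#' Estimate participant ability A and delay time DT
#'
#' Runs the answer-time/delay-time fixed-point iteration (see
#' [ability_stage]) for a fitted difficulty scale. Iterates until the mean
#' absolute change in A across participants falls below `control$tol` or
#' `control$max_iter` is reached (flagged, not an error).
#'
#' @param dataset a [task_dataset()].
#' @param difficulty an [estimate_difficulty()] result, or a named difficulty
#'   vector covering every trial label in the dataset.
#' @param control an [idoct_control()].
#' @return list with `participants` (data.frame: `participant_id`, `a`,
#'   `dt`, `dt_max`, `q`), `at_max` (max answer time over all retained
#'   presentations), `at` (per-record answer times, in the row order of
#'   `dataset$records`), `trace` (mean |change in A| per iteration),
#'   `n_iter`, `converged`, `residual`.
#' @export
estimate_ability_delay <- function(dataset, difficulty,
                                   control = idoct_control()) {
  d <- if (inherits(difficulty, "idoct_difficulty")) difficulty$d else difficulty
  st <- prepare_ability_inputs(dataset, d)
  a <- rep(1, length(st$q))
  trace <- numeric(0)
  converged <- FALSE
  n_iter <- 0L
  for (n in seq_len(control$max_iter)) {
    step <- ability_step(st, a, first = (n == 1L))
    delta <- mean(abs(step$a - a))
    trace <- c(trace, delta)
    a <- step$a
    n_iter <- n
    if (delta < control$tol) {
      converged <- TRUE
      break
    }
  }
  if (!converged) {
    warning("ability stage did not reach tol = ", control$tol, " within ",
            control$max_iter, " iterations (residual mean |dA| = ",
            signif(trace[length(trace)], 3), ")", call. = FALSE)
  }
  # final AT/DT self-consistent with the converged abilities
  final <- ability_step(st, a, first = FALSE)
  at_out <- numeric(length(st$rt))
  at_out[st$perm] <- final$at
  participants <- data.frame(
    participant_id = st$participant_id,
    a = a,
    dt = final$dt,
    dt_max = st$dtmax,
    q = st$q,
    row.names = NULL
  )
  list(
    participants = participants,
    at_max = max(final$at),
    at = at_out,
    trace = trace, n_iter = n_iter, converged = converged,
    residual = trace[length(trace)]
  )
}

#' Compute specific ability AS
#'
#' Once RT is decomposed, the specific performance `PA(i,t)` rescores each
#' presentation using only the answer-time component:
#' `PA = score * (1 - AT/ATmax) * D(t)` clamped to \[0,1\], with `ATmax` the
#' maximum answer time across all retained presentations. The specific
#' ability AS is the mean of cumulative means of PA in presentation order,
#' exactly as A is built from P.
#'
#' @param dataset a [task_dataset()].
#' @param ability result of [estimate_ability_delay()].
#' @param difficulty an [estimate_difficulty()] result or named vector.
#' @return named numeric vector of AS per participant (names =
#'   `participant_id`).
#' @export
compute_specific_ability <- function(dataset, ability, difficulty) {
  d <- if (inherits(difficulty, "idoct_difficulty")) difficulty$d else difficulty
  st <- prepare_ability_inputs(dataset, d)
  at <- ability$at[st$perm]
  at_max <- ability$at_max
  if (at_max <= 0) {
    warning("all answer times are zero (degenerate decomposition); ",
            "AS computed with the AT term set to 0", call. = FALSE)
    at_term <- 0
  } else {
    at_term <- at / at_max
  }
  pa <- pmin(1, pmax(0, st$score * (1 - at_term) * st$dvec))
  as_ <- as.numeric(rowsum(pa * st$w, st$ip))
  stats::setNames(as_, st$participant_id)
}

#' Compute the ability-scaled difficulty DS
#'
#' Corrects the difficulty scale for who actually saw each trial. A label's
#' pre-scale value is `D(t)` times the mean AS of the distinct participants
#' presented that label; under adaptive (staircase) sampling the hardest
#' trials are seen only by high-ability participants, so their raw D
#' understates their difficulty and the AS weighting restores it. The
#' pre-scale values are then mapped affinely onto the range of the original
#' D scale, so a task with uniform abilities recovers D exactly.
#'
#' @param dataset a [task_dataset()].
#' @param difficulty an [estimate_difficulty()] result.
#' @param as_ named AS vector from [compute_specific_ability()].
#' @return named numeric vector DS over trial labels (same order as
#'   `difficulty$d`), with the unrescaled per-label values attached as
#'   attribute `"pre_scale"`.
#' @export
compute_scaled_difficulty <- function(dataset, difficulty, as_) {
  d <- difficulty$d
  r <- dataset$records
  pairs <- unique(data.frame(trial_label = r$trial_label,
                             participant_id = r$participant_id))
  mean_as <- tapply(as_[pairs$participant_id], pairs$trial_label, mean)
  pre <- d * as.numeric(mean_as[names(d)])
  if (length(d) < 2L || diff(range(pre)) == 0) {
    warning("DS rescaling undefined (single label or constant pre-scale ",
            "values); returning pre-scale values", call. = FALSE)
    return(structure(pre, pre_scale = pre))
  }
  # affine min-max map of the pre-scale values onto [min D, max D]
  lo <- min(d); hi <- max(d)
  ds <- lo + (pre - min(pre)) * (hi - lo) / (max(pre) - min(pre))
  structure(stats::setNames(as.numeric(ds), names(d)),
            pre_scale = stats::setNames(as.numeric(pre), names(d)))
}
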