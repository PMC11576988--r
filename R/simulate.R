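#' Parameters for the synthetic task-data generator
#'
#' Defines a generative model that is the structural inverse of the fitted
#' decomposition: each participant carries a latent ability in (0,1) and a
#' delay time in ms; each trial label carries a latent difficulty in (0,1).
#' The answer time of a presentation is
#' `AT = (1 - ability) * difficulty * tau * noise` with multiplicative
#' lognormal noise (unit mean), and `RT = AT + delay`. Correctness follows a
#' logistic link, `Pr(correct) = plogis(kappa * (ability - difficulty))`;
#' in continuous mode a graded score in \{0, 1/3, 2/3, 1\} is drawn from a
#' discretised version of the same link (three rubric points, emulating
#' 3/2/1/0 scoring normalised to \[0,1\]).
#'
#' Default distributions are chosen to emulate large online task batteries:
#' abilities Beta(4,2) (centred near 0.67 with a negative skew), delays
#' Gamma(shape 16, scale 50) ms (mean 800 ms, positively skewed), and
#' difficulties evenly spaced on \[0.2, 0.95\]. Jointly these place the
#' difficulty iteration in its typical operating regime (contraction slopes
#' m_t averaging about 0.35 across labels) while keeping the qualitative
#' shapes seen in large online batteries: a positively skewed delay-time
#' distribution and a negatively skewed specific-ability distribution.
#'
#' @param n_participants,n_labels problem size.
#' @param ability_shape length-2 Beta shape pair for latent abilities.
#' @param delay_shape,delay_scale Gamma parameters of the latent delay (ms).
#' @param difficulty_range range over which the `n_labels` true difficulties
#'   are evenly spaced (within (0, 1\]).
#' @param tau answer-time scale in ms.
#' @param rt_sigma lognormal sigma of the multiplicative RT noise (0 = none).
#' @param kappa steepness of the logistic correctness link.
#' @param mode `"binary"` or `"continuous"` scoring.
#' @param sampling `"balanced"` (every participant sees every label once, in
#'   random order) or `"staircase"` (adaptive span-style assignment, see
#'   [simulate_staircase_task()]).
#' @param fail_limit staircase termination rule: the task ends after this
#'   many consecutive failures (default 3, the digit-span convention).
#' @param seed mandatory RNG seed.
#' @return list of class `sim_params`.
#' @export
sim_params <- function(n_participants = 1000, n_labels = 50,
                       ability_shape = c(4, 2),
                       delay_shape = 16, delay_scale = 50,
                       difficulty_range = c(0.2, 0.95),
                       tau = 800, rt_sigma = 0.15, kappa = 6,
                       mode = c("binary", "continuous"),
                       sampling = c("balanced", "staircase"),
                       fail_limit = 3L, seed = NULL) {
  mode <- match.arg(mode)
  sampling <- match.arg(sampling)
  if (is.null(seed)) stop("seed is mandatory", call. = FALSE)
  stopifnot(
    n_participants >= 1, n_labels >= 1,
    length(ability_shape) == 2, all(ability_shape > 0),
    delay_shape > 0, delay_scale > 0,
    length(difficulty_range) == 2,
    difficulty_range[1] > 0, difficulty_range[2] <= 1,
    difficulty_range[1] <= difficulty_range[2],
    tau > 0, rt_sigma >= 0, kappa > 0, fail_limit >= 1
  )
  structure(
    list(
      n_participants = as.integer(n_participants),
      n_labels = as.integer(n_labels),
      ability_shape = ability_shape,
      delay_shape = delay_shape, delay_scale = delay_scale,
      difficulty_range = difficulty_range,
      tau = tau, rt_sigma = rt_sigma, kappa = kappa,
      mode = mode, sampling = sampling,
      fail_limit = as.integer(fail_limit),
      seed = as.integer(seed)
    ),
    class = "sim_params"
  )
}

sim_latents <- function(params) {
  n <- params$n_participants
  L <- params$n_labels
  pid <- sprintf("P%05d", seq_len(n))
  labels <- sprintf("%02d", seq_len(L))
  ability <- stats::setNames(
    stats::rbeta(n, params$ability_shape[1], params$ability_shape[2]), pid)
  delay <- stats::setNames(
    stats::rgamma(n, shape = params$delay_shape, scale = params$delay_scale),
    pid)
  difficulty <- stats::setNames(
    if (L == 1L) mean(params$difficulty_range) else
      seq(params$difficulty_range[1], params$difficulty_range[2],
          length.out = L),
    labels)
  list(pid = pid, labels = labels, ability = ability, delay = delay,
       difficulty = difficulty)
}

# lognormal noise with unit mean so rt_sigma = 0 is the exact noiseless limit
rt_noise <- function(n, sigma) {
  if (sigma == 0) rep(1, n) else exp(stats::rnorm(n, -sigma^2 / 2, sigma))
}

sim_scores <- function(p_correct, mode) {
  n <- length(p_correct)
  if (mode == "binary") {
    list(correct = stats::runif(n) < p_correct, acc = NULL)
  } else {
    # graded rubric: three independent rubric points under the same link
    acc <- stats::rbinom(n, size = 3L, prob = p_correct) / 3
    list(correct = NULL, acc = acc)
  }
}

sim_assemble <- function(params, lat, pid_idx, lab_idx, ord) {
  a <- lat$ability[pid_idx]
  d <- lat$difficulty[lab_idx]
  p_correct <- stats::plogis(params$kappa * (a - d))
  scores <- sim_scores(p_correct, params$mode)
  at_true <- (1 - a) * d * params$tau * rt_noise(length(a), params$rt_sigma)
  rt <- at_true + lat$delay[pid_idx]
  records <- data.frame(
    participant_id = lat$pid[pid_idx],
    trial_label = lat$labels[lab_idx],
    rt = as.numeric(rt),
    order = ord,
    timepoint = 1L
  )
  if (params$mode == "binary") records$correct <- scores$correct
  else records$acc <- scores$acc
  dataset <- task_dataset(records, mode = params$mode)
  truth <- structure(
    list(
      ability = lat$ability, delay = lat$delay, difficulty = lat$difficulty,
      assignment = data.frame(participant_id = records$participant_id,
                              trial_label = records$trial_label),
      params = params
    ),
    class = "sim_truth"
  )
  list(dataset = dataset, truth = truth)
}

#' Simulate a balanced task dataset with known ground truth
#'
#' Every participant sees every trial label exactly once, in an independent
#' random order. Regeneration with the same parameters and seed is
#' bit-identical.
#'
#' @param params a [sim_params()] (with `sampling = "balanced"`).
#' @return list with `dataset` (a [task_dataset()]) and `truth` (class
#'   `sim_truth`: `ability`, `delay`, `difficulty`, `assignment`, `params`).
#' @export
simulate_task <- function(params) {
  stopifnot(inherits(params, "sim_params"))
  if (params$sampling != "balanced") {
    return(simulate_staircase_task(params))
  }
  set.seed(params$seed)
  lat <- sim_latents(params)
  n <- params$n_participants
  L <- params$n_labels
  # per-participant random presentation order of the full label set
  lab_idx <- as.vector(vapply(seq_len(n), function(i) sample.int(L),
                              integer(L)))
  pid_idx <- rep(seq_len(n), each = L)
  ord <- rep(seq_len(L), times = n)
  sim_assemble(params, lat, pid_idx, lab_idx, ord)
}

#' Simulate an adaptive staircase (span-style) task
#'
#' Trial labels are ordered by true difficulty and treated as span levels.
#' Each participant starts at the lowest level; a correct response moves
#' them up one level (a correct response at the top level ends the task), an
#' incorrect response repeats the level, and the task terminates after
#' `fail_limit` consecutive failures. The hardest levels are therefore seen
#' almost exclusively by high-ability participants — the sampling bias the
#' DS scaling is designed to correct.
#'
#' @param params a [sim_params()]; must use binary mode.
#' @return As [simulate_task()].
#' @export
simulate_staircase_task <- function(params) {
  stopifnot(inherits(params, "sim_params"))
  if (params$mode != "binary") {
    stop("staircase sampling requires binary mode (span semantics)",
         call. = FALSE)
  }
  set.seed(params$seed)
  lat <- sim_latents(params)
  n <- params$n_participants
  L <- params$n_labels
  pid_idx <- integer(0); lab_idx <- integer(0); ord <- integer(0)
  correct_all <- logical(0)
  for (i in seq_len(n)) {
    level <- 1L
    fails <- 0L
    k <- 0L
    lv <- integer(0); cr <- logical(0)
    repeat {
      k <- k + 1L
      p <- stats::plogis(params$kappa * (lat$ability[i] -
                                           lat$difficulty[level]))
      ok <- stats::runif(1) < p
      lv <- c(lv, level); cr <- c(cr, ok)
      if (ok) {
        fails <- 0L
        if (level == L) break
        level <- level + 1L
      } else {
        fails <- fails + 1L
        if (fails >= params$fail_limit) break
      }
    }
    pid_idx <- c(pid_idx, rep(i, k))
    lab_idx <- c(lab_idx, lv)
    ord <- c(ord, seq_len(k))
    correct_all <- c(correct_all, cr)
  }
  out <- sim_assemble(params, lat, pid_idx, lab_idx, ord)
  # keep the correctness draws that drove the staircase path
  out$dataset$records$correct <- correct_all
  out
}

#' @export
print.sim_truth <- function(x, ...) {
  cat("sim_truth:", length(x$ability), "participants,",
      length(x$difficulty), "labels,", nrow(x$assignment),
      "presentations (", x$params$sampling, "sampling )\n")
  invisible(x)
}

cor_or_na <- function(x, y, method) {
  if (length(x) < 3L || stats::sd(x) == 0 || stats::sd(y) == 0) {
    return(NA_real_)
  }
  stats::cor(x, y, method = method)
}

#' Truth-vs-estimate recovery metrics
#'
#' Pearson and Spearman correlations between the generator's ground truth
#' and the fitted estimates: ability vs AS (and vs A), delay vs DT,
#' difficulty vs D and vs DS. Degenerate constant vectors yield NA.
#'
#' @param truth a `sim_truth` from the generators.
#' @param fit an [idoct()] result on the simulated dataset.
#' @return data.frame with columns `quantity`, `estimate`, `pearson`,
#'   `spearman`, `n`.
#' @export
recovery_metrics <- function(truth, fit) {
  stopifnot(inherits(truth, "sim_truth"), inherits(fit, "idoct_fit"))
  p <- fit$participants
  true_ab <- unname(truth$ability[p$participant_id])
  true_dl <- unname(truth$delay[p$participant_id])
  lab <- names(fit$difficulty$d)
  true_d <- unname(truth$difficulty[lab])
  rows <- list(
    c("ability", "as"), c("ability", "a"), c("delay", "dt"),
    c("difficulty", "d"), c("difficulty", "ds")
  )
  est <- list(p$as, p$a, p$dt, unname(fit$difficulty$d),
              unname(fit$difficulty$ds))
  tru <- list(true_ab, true_ab, true_dl, true_d, true_d)
  data.frame(
    quantity = vapply(rows, `[`, "", 1),
    estimate = vapply(rows, `[`, "", 2),
    pearson = mapply(function(t, e) cor_or_na(t, e, "pearson"), tru, est),
    spearman = mapply(function(t, e) cor_or_na(t, e, "spearman"), tru, est),
    n = vapply(tru, length, 1L),
    row.names = NULL
  )
}

#' Subsample stability of the estimates
#'
#' Refits the model on random participant subsamples and correlates the
#' subsample estimates against the full-sample fit: AS and DT over the
#' subsampled participants, D and DS over the labels present in the
#' subsample (labels missing from a subsample are omitted and counted).
#'
#' @param dataset a [task_dataset()].
#' @param sizes integer vector of subsample sizes (each at most the number
#'   of participants).
#' @param n_repeats random subsamples per size.
#' @param seed RNG seed.
#' @param control an [idoct_control()] used for every fit.
#' @return data.frame with columns `size`, `rep`, `metric` (`as`, `dt`,
#'   `d`, `ds`), `pearson`, `n_items`, `n_missing_labels`.
#' @export
subsample_stability <- function(dataset, sizes, n_repeats = 30, seed = 1,
                                control = idoct_control()) {
  stopifnot(inherits(dataset, "task_dataset"))
  ids <- unique(dataset$records$participant_id)
  if (any(sizes > length(ids))) {
    stop("subsample size exceeds the number of participants", call. = FALSE)
  }
  full <- suppressWarnings(idoct(dataset, control))
  fp <- full$participants
  set.seed(seed)
  out <- list()
  for (size in sizes) {
    for (r in seq_len(n_repeats)) {
      sub_ids <- if (size == length(ids)) ids else sample(ids, size)
      keep <- dataset$records$participant_id %in% sub_ids
      sub <- task_dataset(dataset$records[keep, , drop = FALSE],
                          mode = dataset$mode)
      sfit <- suppressWarnings(idoct(sub, control))
      sp <- sfit$participants
      idx <- match(sp$participant_id, fp$participant_id)
      lab <- names(sfit$difficulty$d)
      lidx <- match(lab, names(full$difficulty$d))
      n_missing <- length(full$difficulty$d) - length(lab)
      out[[length(out) + 1L]] <- data.frame(
        size = size, rep = r,
        metric = c("as", "dt", "d", "ds"),
        pearson = c(
          cor_or_na(sp$as, fp$as[idx], "pearson"),
          cor_or_na(sp$dt, fp$dt[idx], "pearson"),
          cor_or_na(unname(sfit$difficulty$d),
                    unname(full$difficulty$d[lidx]), "pearson"),
          cor_or_na(unname(sfit$difficulty$ds),
                    unname(full$difficulty$ds[lidx]), "pearson")
        ),
        n_items = c(nrow(sp), nrow(sp), length(lab), length(lab)),
        n_missing_labels = c(0L, 0L, n_missing, n_missing)
      )
    }
  }
  do.call(rbind, out)
}

#' Write simulation ground truth to CSV
#'
#' Emits two plain-text tables alongside a simulated dataset: per-participant
#' truth (`participant_id`, `true_ability`, `true_delay_ms`) and per-label
#' truth (`trial_label`, `true_difficulty`).
#'
#' @param truth a `sim_truth`.
#' @param participants_path,labels_path output CSV paths.
#' @return invisibly, the two paths.
#' @export
write_truth_csv <- function(truth, participants_path, labels_path) {
  utils::write.csv(
    data.frame(participant_id = names(truth$ability),
               true_ability = unname(truth$ability),
               true_delay_ms = unname(truth$delay)),
    participants_path, row.names = FALSE, quote = FALSE)
  utils::write.csv(
    data.frame(trial_label = names(truth$difficulty),
               true_difficulty = unname(truth$difficulty)),
    labels_path, row.names = FALSE, quote = FALSE)
  invisible(c(participants_path, labels_path))
}
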