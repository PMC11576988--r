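# Independent brute-force oracle: a literal, loop-based transliteration of
# the two fixed-point stages, kept deliberately naive (per-participant,
# per-trial loops; no shared code with the package internals).

bf_score <- function(dataset) {
  if (dataset$mode == "binary") as.numeric(dataset$records$correct)
  else dataset$records$acc
}

# difficulty stage: D(t,0) = 1; P = score * (1 - rt/rt_max) * D; D <- mean(1-P)
bf_difficulty <- function(dataset, n_iter = 50) {
  r <- dataset$records
  sc <- bf_score(dataset)
  labels <- sort(unique(r$trial_label))
  d <- stats::setNames(rep(1, length(labels)), labels)
  for (n in seq_len(n_iter)) {
    d_new <- d
    for (t in labels) {
      idx <- which(r$trial_label == t)
      p <- numeric(length(idx))
      for (j in seq_along(idx)) {
        i <- idx[j]
        p[j] <- sc[i] * (1 - r$rt[i] / dataset$rt_max) * d[[t]]
        p[j] <- min(1, max(0, p[j]))
      }
      d_new[[t]] <- mean(1 - p)
    }
    d <- d_new
  }
  d
}

# ability stage: per-participant loops over trials in presentation order;
# first iteration uses ATN = 1 (AT at its ceiling), later ones (1 - A) * D
bf_ability <- function(dataset, d, n_iter = 50) {
  r <- dataset$records
  sc <- bf_score(dataset)
  ids <- sort(unique(r$participant_id))
  rt_max <- dataset$rt_max
  trials <- lapply(ids, function(id) {
    idx <- which(r$participant_id == id)
    idx[order(r$order[idx])]
  })
  names(trials) <- ids
  a <- stats::setNames(rep(1, length(ids)), ids)
  compute_one <- function(id, a_i, first) {
    idx <- trials[[id]]
    dtmax <- min(r$rt[idx])
    at <- numeric(length(idx))
    for (j in seq_along(idx)) {
      i <- idx[j]
      atn <- if (first) 1 else (1 - a_i) * d[[r$trial_label[i]]]
      at[j] <- atn * (r$rt[i] - dtmax)
    }
    dt_i <- mean(r$rt[idx] - at)
    p <- numeric(length(idx))
    for (j in seq_along(idx)) {
      i <- idx[j]
      p[j] <- sc[i] * (1 - at[j] / rt_max - dt_i / rt_max) *
        d[[r$trial_label[i]]]
      p[j] <- min(1, max(0, p[j]))
    }
    # ability: mean over trials of the running cumulative mean of P
    b <- cumsum(p)
    cummeans <- b / seq_along(p)
    list(a = mean(cummeans), at = at, dt = dt_i, p = p)
  }
  for (n in seq_len(n_iter)) {
    a_new <- a
    for (id in ids) {
      a_new[[id]] <- compute_one(id, a[[id]], first = (n == 1))$a
    }
    a <- a_new
  }
  # final self-consistent AT/DT at the converged abilities
  at_all <- list(); dt <- stats::setNames(numeric(length(ids)), ids)
  for (id in ids) {
    res <- compute_one(id, a[[id]], first = FALSE)
    at_all[[id]] <- res$at
    dt[[id]] <- res$dt
  }
  list(a = a, dt = dt, at = at_all, at_max = max(unlist(at_all)),
       dt_max = stats::setNames(
         vapply(ids, function(id) min(r$rt[trials[[id]]]), 0), ids),
       trials = trials)
}

bf_specific <- function(dataset, d, ab) {
  r <- dataset$records
  sc <- bf_score(dataset)
  at_max <- ab$at_max
  out <- stats::setNames(numeric(length(ab$a)), names(ab$a))
  for (id in names(ab$a)) {
    idx <- ab$trials[[id]]
    at <- ab$at[[id]]
    pa <- numeric(length(idx))
    for (j in seq_along(idx)) {
      i <- idx[j]
      term <- if (at_max > 0) at[j] / at_max else 0
      pa[j] <- sc[i] * (1 - term) * d[[r$trial_label[i]]]
      pa[j] <- min(1, max(0, pa[j]))
    }
    out[[id]] <- mean(cumsum(pa) / seq_along(pa))
  }
  out
}

# random small dataset with repeats allowed and per-participant order
rand_small_dataset <- function(n_participants, n_labels, n_trials_each,
                               mode = "binary", seed = 1) {
  set.seed(seed)
  labels <- sprintf("L%02d", seq_len(n_labels))
  rows <- list()
  for (i in seq_len(n_participants)) {
    q <- n_trials_each
    rows[[i]] <- data.frame(
      participant_id = sprintf("p%02d", i),
      trial_label = sample(labels, q, replace = TRUE),
      rt = round(stats::runif(q, 300, 4000), 1),
      order = seq_len(q),
      timepoint = 1L,
      correct = stats::runif(q) < 0.6,
      acc = round(stats::runif(q), 3)
    )
  }
  records <- do.call(rbind, rows)
  if (mode == "binary") records$acc <- NULL else records$correct <- NULL
  task_dataset(records, mode = mode)
}

sample_skewness <- function(x) {
  mean((x - mean(x))^3) / stats::sd(x)^3
}
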