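test_that("a single-trial participant reduces to the hand-computed case", {
  ds <- task_dataset(data.frame(
    participant_id = c("solo", "other", "other", "other"),
    trial_label = c("t1", "t1", "t2", "t2"),
    rt = c(600, 900, 1000, 800),
    correct = c(TRUE, TRUE, FALSE, TRUE),
    order = c(1L, 1L, 2L, 3L)
  ), mode = "binary")
  diff <- estimate_difficulty(ds, idoct_control(tol = 1e-12, max_iter = 300))
  ab <- estimate_ability_delay(ds, diff,
                               idoct_control(tol = 1e-12, max_iter = 300))
  p <- ab$participants
  solo <- p[p$participant_id == "solo", ]
  # DTmax is the only rt, so AT = 0, DT = rt and A is the single performance
  expect_equal(solo$dt_max, 600)
  expect_equal(solo$dt, 600)
  expect_equal(solo$a, (1 - 600 / ds$rt_max) * diff$d[["t1"]],
               tolerance = 1e-9)
})

test_that("all-incorrect responding collapses ability to zero", {
  ds <- task_dataset(data.frame(
    participant_id = rep(c("a", "b"), each = 3),
    trial_label = rep(c("t1", "t2", "t3"), 2),
    rt = c(400, 800, 1200, 500, 900, 700),
    correct = FALSE
  ), mode = "binary")
  fit <- idoct(ds)
  expect_equal(fit$participants$a, c(0, 0))
  expect_equal(fit$participants$as, c(0, 0))
  expect_equal(unname(fit$difficulty$d), rep(1, 3))
  # at A = 0 and D = 1 the decomposition assigns AT = RT - DTmax, so the
  # delay estimate sits at its lower bound, the participant's smallest RT
  expect_equal(fit$participants$dt, fit$participants$dt_max)
  expect_equal(fit$participants$dt_max, c(400, 500))
})

test_that("optimized stages match the literal brute-force transliteration", {
  for (seed in 1:10) {
    mode <- if (seed %% 2) "binary" else "continuous"
    ds <- rand_small_dataset(n_participants = 5, n_labels = 4,
                             n_trials_each = 5, mode = mode, seed = seed)
    d <- closed_form_difficulty(ds)
    ab <- suppressWarnings(
      estimate_ability_delay(ds, d, idoct_control(tol = 0, max_iter = 50)))
    oracle <- bf_ability(ds, d, n_iter = 50)
    p <- ab$participants
    expect_equal(p$a, unname(oracle$a[p$participant_id]), tolerance = 1e-9)
    expect_equal(p$dt, unname(oracle$dt[p$participant_id]), tolerance = 1e-9)
    expect_equal(p$dt_max, unname(oracle$dt_max[p$participant_id]))
    expect_equal(ab$at_max, oracle$at_max, tolerance = 1e-9)
    as_ <- compute_specific_ability(ds, ab, d)
    expect_equal(unname(as_[p$participant_id]),
                 unname(bf_specific(ds, d, oracle)[p$participant_id]),
                 tolerance = 1e-9)
  }
})

test_that("estimates respect their structural ranges on fuzzed inputs", {
  for (seed in 1:8) {
    ds <- rand_small_dataset(6, 5, 7,
                             mode = if (seed %% 2) "binary" else "continuous",
                             seed = 100 + seed)
    fit <- suppressWarnings(idoct(ds, idoct_control(max_iter = 30)))
    p <- fit$participants
    expect_true(all(p$a >= 0 & p$a <= 1))
    expect_true(all(p$as >= 0 & p$as <= 1))
    expect_true(all(fit$difficulty$d >= 0.5 & fit$difficulty$d <= 1))
    mean_rt <- tapply(ds$records$rt, ds$records$participant_id, mean)
    expect_true(all(p$dt >= p$dt_max - 1e-9))
    expect_true(all(p$dt <= unname(mean_rt[p$participant_id]) + 1e-9))
    expect_gte(fit$at_max, 0)
  }
})

test_that("a flat-RT correct participant scores the cumulative-mean of D", {
  # identical RTs make AT vanish for that participant; with all answers
  # correct the specific performance is exactly D(t) per trial
  ds <- task_dataset(data.frame(
    participant_id = c(rep("flat", 3), rep("other", 3)),
    trial_label = rep(c("t1", "t2", "t3"), 2),
    rt = c(500, 500, 500, 400, 900, 1000),
    correct = c(TRUE, TRUE, TRUE, TRUE, FALSE, TRUE)
  ), mode = "binary")
  ctl <- idoct_control(tol = 1e-12, max_iter = 300)
  diff <- estimate_difficulty(ds, ctl)
  ab <- estimate_ability_delay(ds, diff, ctl)
  as_ <- compute_specific_ability(ds, ab, diff)
  dseq <- diff$d[c("t1", "t2", "t3")]
  expect_equal(as_[["flat"]], mean(cumsum(dseq) / seq_along(dseq)),
               tolerance = 1e-9)
})

test_that("a fully degenerate answer-time decomposition warns and falls back", {
  ds <- task_dataset(data.frame(
    participant_id = rep(c("a", "b"), each = 2),
    trial_label = rep(c("t1", "t2"), 2),
    rt = c(500, 500, 700, 700),
    correct = TRUE
  ), mode = "binary")
  ctl <- idoct_control(tol = 1e-10, max_iter = 200)
  diff <- estimate_difficulty(ds, ctl)
  ab <- estimate_ability_delay(ds, diff, ctl)
  expect_equal(ab$at_max, 0)
  expect_warning(as_ <- compute_specific_ability(ds, ab, diff),
                 "answer times are zero")
  expect_true(all(as_ > 0))
})

test_that("scaling leaves a uniform-ability difficulty scale unchanged", {
  # identical behaviour means identical AS; DS must then reproduce D
  ds <- task_dataset(data.frame(
    participant_id = rep(c("a", "b", "c"), each = 3),
    trial_label = rep(c("t1", "t2", "t3"), 3),
    rt = rep(c(400, 700, 1000), 3),
    correct = rep(c(TRUE, TRUE, FALSE), 3)
  ), mode = "binary")
  ctl <- idoct_control(tol = 1e-12, max_iter = 300)
  fit <- idoct(ds, ctl)
  expect_equal(unname(fit$difficulty$ds), unname(fit$difficulty$d),
               tolerance = 1e-9, ignore_attr = TRUE)
})

test_that("low-ability cohorts depress the pre-scale DS of their labels", {
  # direct evaluation of the scaling rule: two labels with equal D seen by
  # disjoint cohorts whose specific abilities average 0.2 vs 0.8
  ds <- task_dataset(data.frame(
    participant_id = c("lo1", "lo2", "hi1", "hi2", "lo1", "hi1"),
    trial_label = c("x", "x", "y", "y", "easy", "easy"),
    rt = c(500, 700, 500, 700, 400, 400),
    correct = TRUE
  ), mode = "binary")
  difficulty <- structure(
    list(d = c(easy = 0.6, x = 0.8, y = 0.8)), class = "idoct_difficulty")
  as_ <- c(lo1 = 0.15, lo2 = 0.25, hi1 = 0.75, hi2 = 0.85)
  ds_vec <- compute_scaled_difficulty(ds, difficulty, as_)
  pre <- attr(ds_vec, "pre_scale")
  # pre-scale value is D(t) times the mean AS of the label's cohort
  expect_equal(pre[["x"]], 0.8 * 0.2)
  expect_equal(pre[["y"]], 0.8 * 0.8)
  expect_equal(pre[["easy"]], 0.6 * mean(c(0.15, 0.75)))
  expect_lt(pre[["x"]], pre[["y"]])
  # the affine rescale spans exactly the original D range
  expect_equal(min(ds_vec), min(difficulty$d))
  expect_equal(max(ds_vec), max(difficulty$d))
  # and a fitted low-ability cohort does carry lower specific ability
  ds2 <- task_dataset(data.frame(
    participant_id = rep(c("slow1", "slow2", "fast1", "fast2"), each = 3),
    trial_label = rep(c("a", "b", "c"), 4),
    rt = c(900, 950, 980, 920, 960, 940, 300, 320, 310, 330, 305, 315),
    correct = c(TRUE, FALSE, FALSE, FALSE, TRUE, FALSE,
                TRUE, TRUE, TRUE, TRUE, TRUE, TRUE)
  ), mode = "binary")
  fit2 <- idoct(ds2, idoct_control(tol = 1e-12, max_iter = 300))
  p2 <- fit2$participants
  expect_lt(mean(p2$as[p2$participant_id %in% c("slow1", "slow2")]),
            mean(p2$as[p2$participant_id %in% c("fast1", "fast2")]))
})
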