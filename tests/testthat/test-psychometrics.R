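# planted-structure builders -------------------------------------------------

block_corr <- function(n_blocks, per_block, within, between = 0) {
  p <- n_blocks * per_block
  r <- matrix(between, p, p)
  for (b in seq_len(n_blocks)) {
    idx <- ((b - 1) * per_block + 1):(b * per_block)
    r[idx, idx] <- within
  }
  diag(r) <- 1
  colnames(r) <- rownames(r) <- sprintf("task%02d", seq_len(p))
  r
}

hierarchical_corr <- function(lambda = 0.7, phi_off = 0.6,
                              n_blocks = 4, per_block = 3) {
  p <- n_blocks * per_block
  L <- matrix(0, p, n_blocks)
  for (b in seq_len(n_blocks)) {
    L[((b - 1) * per_block + 1):(b * per_block), b] <- lambda
  }
  phi <- matrix(phi_off, n_blocks, n_blocks)
  diag(phi) <- 1
  r <- L %*% phi %*% t(L)
  diag(r) <- 1
  colnames(r) <- rownames(r) <- sprintf("task%02d", seq_len(p))
  list(corr = r, loadings = L, phi = phi,
       g_true = L %*% rep(sqrt(phi_off), n_blocks))
}

test_that("pairwise correlation honours sparsity and overlap thresholds", {
  set.seed(1)
  x <- matrix(rnorm(200), 50, 4,
              dimnames = list(NULL, paste0("t", 1:4)))
  # complete data reproduce the dense correlation matrix
  expect_equal(unclass(pairwise_correlation(x))[1:4, 1:4],
               cor(x), ignore_attr = TRUE)
  # duplicated and negated columns hit the boundary values
  y <- cbind(a = x[, 1], b = x[, 1], c = -x[, 1], d = x[, 2])
  r <- pairwise_correlation(y)
  expect_equal(r["a", "b"], 1)
  expect_equal(r["a", "c"], -1)
  # a pair with too little overlap is reported missing, not fatal
  z <- x
  z[1:48, 1] <- NA
  z[3:50, 2] <- NA
  r2 <- pairwise_correlation(z, min_overlap = 3)
  expect_true(is.na(r2["t1", "t2"]))
  expect_equal(diag(r2), rep(1, 4), ignore_attr = TRUE)
  expect_error(pairwise_correlation(x[, 1, drop = FALSE]), "2 tasks")
})

test_that("independent columns show only sampling-level correlation", {
  set.seed(2)
  x <- matrix(rnorm(2 * 10000), 10000, 2)
  r <- pairwise_correlation(x)
  expect_lt(abs(r[1, 2]), 0.05)
})

test_that("complete-linkage clustering recovers planted blocks", {
  r <- block_corr(2, 3, within = 0.9, between = 0.05)
  cl <- hierarchical_clusters(r, k = 2)
  expect_equal(length(unique(cl$labels[1:3])), 1)
  expect_equal(length(unique(cl$labels[4:6])), 1)
  expect_false(cl$labels[1] == cl$labels[4])

  # 12 tasks, 4 planted domains
  r4 <- block_corr(4, 3, within = 0.75, between = 0.1)
  cl4 <- hierarchical_clusters(r4, k = 4)
  truth <- rep(1:4, each = 3)
  expect_equal(length(unique(paste(cl4$labels, truth))), 4)

  # degenerate all-equal correlations still cut deterministically
  flat <- block_corr(1, 4, within = 0.5)
  c1 <- hierarchical_clusters(flat, k = 2)$labels
  c2 <- hierarchical_clusters(flat, k = 2)$labels
  expect_identical(c1, c2)
  expect_equal(length(unique(c1)), 2)

  bad <- r
  bad[1, 2] <- bad[2, 1] <- NA
  expect_error(hierarchical_clusters(bad, k = 2), "missing")
  expect_error(hierarchical_clusters(r), "exactly one")
})

test_that("the Kaiser criterion counts eigenvalues strictly above one", {
  expect_equal(kaiser_nfactors(diag(5)), 0)
  r2 <- matrix(c(1, 0.5, 0.5, 1), 2)  # eigenvalues 1.5 and 0.5
  expect_equal(kaiser_nfactors(r2), 1)
  expect_equal(kaiser_nfactors(block_corr(4, 3, within = 0.8,
                                          between = 0.05)), 4)
})

test_that("factor extraction recovers a planted single factor", {
  lam <- seq(0.45, 0.85, length.out = 12)
  r <- tcrossprod(lam)
  diag(r) <- 1
  colnames(r) <- rownames(r) <- sprintf("task%02d", 1:12)
  for (method in c("minres", "pa")) {
    sol <- factor_analysis_varimax(r, 1, method = method)
    expect_lt(max(abs(as.numeric(sol$loadings) - lam)), 0.05)
  }
  # independent oracle: maximum-likelihood factanal on the same matrix
  ml <- stats::factanal(covmat = r, factors = 1, n.obs = 1000)
  sol <- factor_analysis_varimax(r, 1)
  expect_lt(max(abs(abs(as.numeric(ml$loadings)) -
                      abs(as.numeric(sol$loadings)))), 0.05)
  expect_error(factor_analysis_varimax(r, 12), "n_factors")
})

test_that("varimax solutions separate orthogonal planted blocks", {
  r <- block_corr(2, 4, within = 0.7, between = 0)
  sol <- factor_analysis_varimax(r, 2)
  L <- sol$loadings
  own <- c(apply(abs(L[1:4, , drop = FALSE]), 1, max),
           apply(abs(L[5:8, , drop = FALSE]), 1, max))
  other <- c(apply(abs(L[1:4, , drop = FALSE]), 1, min),
             apply(abs(L[5:8, , drop = FALSE]), 1, min))
  expect_true(all(own > 0.4))
  expect_true(all(other < 0.2))
  # deterministic: repeated runs agree exactly
  expect_identical(L, factor_analysis_varimax(r, 2)$loadings)
})

test_that("orthogonal group factors carry no general factor", {
  r <- block_corr(3, 4, within = 0.7, between = 0)
  sol <- schmid_leiman_g(r, 3)
  expect_lt(sol$pct_g, 3)
  expect_lt(max(abs(sol$g_loadings)), 0.25)
})

test_that("a planted hierarchical model yields the analytic g share", {
  h <- hierarchical_corr(lambda = 0.7, phi_off = 0.6)
  pct_true <- 100 * sum(h$g_true^2) / ncol(h$corr)
  sol <- schmid_leiman_g(h$corr, 4)
  expect_lt(abs(sol$pct_g - pct_true), 2)
  expect_equal(sol$ss_g, sum(sol$g_loadings^2), tolerance = 1e-12)
  # task order invariance of the g share
  perm <- c(7, 1, 12, 3, 9, 5, 11, 2, 8, 4, 10, 6)
  sol_p <- schmid_leiman_g(h$corr[perm, perm], 4)
  expect_equal(sol_p$pct_g, sol$pct_g, tolerance = 0.5)
  expect_error(schmid_leiman_g(h$corr, 1), "at least 2")
})

test_that("g variance share follows the sum-of-squares convention", {
  expect_equal(g_variance_pct(2.88, 12), 24)
  expect_equal(g_variance_pct(0, 12), 0)
  expect_equal(g_variance_pct(1.35, 12), 11.25)
  expect_equal(round(g_variance_pct(1.35, 12)), 11)
})

test_that("effect-size helpers follow their printed formulas", {
  expect_equal(cohens_f2(0.5), 1)
  expect_equal(cohens_f2(1), 0)
  # just above the 0.02 negligibility threshold
  expect_equal(cohens_f2(0.98), (1 - 0.98) / 0.98)
  expect_gt(cohens_f2(0.98), 0.02)
  expect_equal(cohens_f2(0.5, conventional = TRUE), 1)
  expect_equal(cohens_f2(0.2, conventional = TRUE), 0.25)
  expect_error(cohens_f2(0), "\\(0, 1\\]")

  expect_equal(effect_size_sd(1, 2), 0.5)
  expect_equal(effect_size_sd(0, 5), 0)
  expect_equal(effect_size_sd(-0.3, 0.1), -3)
  expect_error(effect_size_sd(1, 0), "positive")
})

test_that("a stronger shared component inflates the g share", {
  weak <- hierarchical_corr(lambda = 0.7, phi_off = 0.2)
  strong <- hierarchical_corr(lambda = 0.7, phi_off = 0.7)
  expect_lt(schmid_leiman_g(weak$corr, 4)$pct_g,
            schmid_leiman_g(strong$corr, 4)$pct_g)
})

test_that("score matrices assemble sparsely across fitted tasks", {
  shared <- simulate_task(sim_params(n_participants = 30, n_labels = 5,
                                     seed = 71))
  other <- simulate_task(sim_params(n_participants = 20, n_labels = 5,
                                    seed = 72))
  fits <- list(task_a = suppressWarnings(idoct(shared$dataset)),
               task_b = suppressWarnings(idoct(other$dataset)))
  m <- score_matrix(fits, "as")
  expect_equal(dim(m), c(30, 2))
  expect_equal(sum(is.na(m[, "task_b"])), 10)
  expect_equal(unname(m[fits$task_a$participants$participant_id, "task_a"]),
               fits$task_a$participants$as)
  expect_error(score_matrix(unname(fits)), "named")
})
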