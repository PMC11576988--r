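#' @title Psychometric validation layer
#'
#' @description Analytics applied to participant-by-task score matrices
#' (e.g. AS or DT collected across several fitted tasks): sparse pairwise
#' correlation, complete-linkage hierarchical clustering, exploratory factor
#' analysis with varimax rotation under the Kaiser criterion, a
#' Schmid-Leiman second-order (bifactor-style) general-factor summary, and
#' regression effect-size helpers. The share of score variance captured by
#' the general factor quantifies how non-specific a battery's measures are:
#' the smaller it is, the more discretely the battery fractionates
#' cognitive abilities.
#' @name psychometrics
NULL

#' Pairwise-complete correlation matrix
#'
#' Pearson correlation per task pair using only participants observed on
#' both tasks, which accommodates the sparsity of batteries where each
#' participant completes a subset of tasks. Pairs with fewer than
#' `min_overlap` common observations are set to NA.
#'
#' @param scores numeric matrix or data.frame, participants x tasks, NAs
#'   allowed.
#' @param min_overlap minimum number of common observations per pair
#'   (at least 3).
#' @return correlation matrix with unit diagonal; the pairwise sample sizes
#'   are attached as attribute `"n_overlap"`.
#' @export
pairwise_correlation <- function(scores, min_overlap = 3) {
  stopifnot(min_overlap >= 3)
  scores <- as.matrix(scores)
  if (ncol(scores) < 2L) stop("need at least 2 tasks", call. = FALSE)
  n_ok <- colSums(!is.na(scores))
  if (any(n_ok < 2L)) {
    stop("each task column needs at least 2 non-missing values",
         call. = FALSE)
  }
  r <- suppressWarnings(
    stats::cor(scores, use = "pairwise.complete.obs", method = "pearson"))
  overlap <- crossprod(!is.na(scores))
  low <- overlap < min_overlap
  diag(low) <- FALSE
  if (any(low)) r[low] <- NA_real_
  diag(r) <- 1
  attr(r, "n_overlap") <- overlap
  r
}

#' Complete-linkage clustering of a task correlation matrix
#'
#' Agglomerative clustering on the dissimilarity `1 - r` with complete
#' linkage. Ties are broken deterministically by task order in the matrix
#' (the ordering `hclust` inherits from the input).
#'
#' @param corr correlation matrix without missing entries (impute or
#'   restrict first).
#' @param k number of clusters to cut, or NULL.
#' @param h cut height on `1 - r`, or NULL (exactly one of `k`, `h`).
#' @return list with `labels` (named cluster memberships) and `tree`
#'   (the `hclust` object).
#' @export
hierarchical_clusters <- function(corr, k = NULL, h = NULL) {
  if (anyNA(corr)) {
    stop("correlation matrix has missing entries; impute or restrict first",
         call. = FALSE)
  }
  if (is.null(k) == is.null(h)) {
    stop("supply exactly one of k or h", call. = FALSE)
  }
  tree <- stats::hclust(stats::as.dist(1 - corr), method = "complete")
  labels <- stats::cutree(tree, k = k, h = h)
  list(labels = labels, tree = tree)
}

#' Number of factors by the Kaiser criterion
#'
#' Counts the eigenvalues of the correlation matrix strictly greater than 1.
#' The inequality is strict, so an identity matrix retains zero factors.
#'
#' @param corr symmetric correlation matrix.
#' @return integer factor count.
#' @export
kaiser_nfactors <- function(corr) {
  ev <- eigen(corr, symmetric = TRUE, only.values = TRUE)$values
  sum(ev > 1)
}

# squared multiple correlations; communality starting values
smc <- function(corr) {
  inv <- tryCatch(solve(corr), error = function(e) NULL)
  if (is.null(inv)) return(rep(0.5, ncol(corr)))
  pmin(0.995, pmax(0.005, 1 - 1 / diag(inv)))
}

loadings_from_psi <- function(corr, psi, n_factors) {
  e <- eigen(corr - diag(psi, ncol(corr)), symmetric = TRUE)
  lam <- e$values[seq_len(n_factors)]
  L <- e$vectors[, seq_len(n_factors), drop = FALSE] %*%
    diag(sqrt(pmax(lam, 0)), n_factors)
  rownames(L) <- colnames(corr)
  L
}

# common-factor extraction: minimum residual (default) or principal axis
extract_factors <- function(corr, n_factors, method = c("minres", "pa"),
                            max_iter = 100, tol = 1e-6) {
  method <- match.arg(method)
  p <- ncol(corr)
  if (n_factors < 1 || n_factors >= p) {
    stop("n_factors must be in [1, n_tasks)", call. = FALSE)
  }
  if (method == "minres") {
    offdiag <- row(corr) != col(corr)
    objective <- function(psi) {
      L <- loadings_from_psi(corr, psi, n_factors)
      res <- corr - tcrossprod(L)
      sum(res[offdiag]^2)
    }
    start <- 1 - smc(corr)
    fit <- stats::optim(start, objective, method = "L-BFGS-B",
                        lower = 0.005, upper = 1,
                        control = list(maxit = 1000))
    # a line-search stall (code 52) on an already-flat objective is benign
    stalled_ok <- fit$convergence == 52 && fit$value <= objective(start)
    if (fit$convergence != 0 && !stalled_ok) {
      warning("minres extraction did not fully converge (code ",
              fit$convergence, ")", call. = FALSE)
    }
    L <- loadings_from_psi(corr, fit$par, n_factors)
  } else {
    h2 <- smc(corr)
    L <- NULL
    for (i in seq_len(max_iter)) {
      R_star <- corr
      diag(R_star) <- h2
      e <- eigen(R_star, symmetric = TRUE)
      L <- e$vectors[, seq_len(n_factors), drop = FALSE] %*%
        diag(sqrt(pmax(e$values[seq_len(n_factors)], 0)), n_factors)
      h2_new <- pmin(0.995, rowSums(L^2))
      if (max(abs(h2_new - h2)) < tol) {
        h2 <- h2_new
        break
      }
      h2 <- h2_new
    }
    rownames(L) <- colnames(corr)
  }
  L
}

# fix each column's sign so its largest-magnitude loading is positive
fix_signs <- function(L) {
  for (j in seq_len(ncol(L))) {
    if (L[which.max(abs(L[, j])), j] < 0) L[, j] <- -L[, j]
  }
  L
}

new_factor_solution <- function(loadings, rotation, eigenvalues, n_factors,
                                g_loadings = NULL, ss_g = NA_real_,
                                pct_g = NA_real_, phi = NULL) {
  structure(
    list(loadings = loadings, rotation = rotation,
         eigenvalues = eigenvalues, n_factors = n_factors,
         g_loadings = g_loadings, ss_g = ss_g, pct_g = pct_g, phi = phi),
    class = "factor_solution"
  )
}

#' @export
print.factor_solution <- function(x, digits = 3, ...) {
  cat("factor_solution:", x$n_factors, "factor(s),", x$rotation,
      "rotation\n")
  print(round(x$loadings, digits))
  if (!is.na(x$ss_g)) {
    cat("g-factor: sum-of-squares loading =", signif(x$ss_g, 4),
        "->", signif(x$pct_g, 4), "% of variance\n")
  }
  invisible(x)
}

#' Exploratory factor analysis with varimax rotation
#'
#' Common-factor extraction (minimum-residual by default, principal-axis
#' optionally) followed by varimax rotation. Column signs are fixed so each
#' factor's largest-magnitude loading is positive, making the solution
#' deterministic up to column order.
#'
#' @param corr correlation matrix (no missing entries).
#' @param n_factors number of factors, `1 <= n_factors < n_tasks`
#'   (see [kaiser_nfactors()]).
#' @param method extraction method, `"minres"` or `"pa"`.
#' @return a `factor_solution` (g-factor fields empty).
#' @export
factor_analysis_varimax <- function(corr, n_factors,
                                    method = c("minres", "pa")) {
  method <- match.arg(method)
  L <- extract_factors(corr, n_factors, method)
  if (n_factors > 1L) {
    L <- stats::varimax(L, normalize = TRUE)$loadings
    L <- matrix(as.numeric(L), nrow = nrow(L),
                dimnames = list(colnames(corr),
                                paste0("F", seq_len(n_factors))))
  } else {
    colnames(L) <- "F1"
  }
  L <- fix_signs(L)
  ev <- eigen(corr, symmetric = TRUE, only.values = TRUE)$values
  new_factor_solution(L, "varimax", ev, n_factors)
}

# single-factor loadings of a factor correlation matrix (second order)
second_order_loadings <- function(phi, method) {
  k <- ncol(phi)
  if (k == 2L) {
    # one factor on two variables is underidentified; the standard
    # resolution assigns equal loadings sqrt(r12)
    r <- max(phi[1, 2], 0)
    return(matrix(sqrt(r), nrow = 2))
  }
  g <- extract_factors(phi, 1L, method)
  if (sum(g) < 0) g <- -g
  g
}

#' Schmid-Leiman general-factor solution
#'
#' Orthogonalises a higher-order factor model into a general factor plus
#' group factors. The first-order solution uses an oblique (promax)
#' rotation, the inter-factor correlation matrix is factored by a single
#' second-order factor, and each task's general-factor loading is the
#' product of its first-order pattern loadings with the second-order
#' loadings. The sum of squared g loadings (`ss_g`) divided by the number
#' of tasks gives the share of total variance carried by the general
#' factor (`pct_g`, in percent).
#'
#' @param corr correlation matrix (no missing entries).
#' @param n_factors number of first-order factors (at least 2).
#' @param method extraction method for both orders.
#' @return a `factor_solution` with `loadings` (first-order promax pattern),
#'   `phi` (factor correlations), `g_loadings`, `ss_g` and `pct_g`.
#' @export
schmid_leiman_g <- function(corr, n_factors, method = c("minres", "pa")) {
  method <- match.arg(method)
  if (n_factors < 2L) {
    stop("the Schmid-Leiman decomposition needs at least 2 first-order ",
         "factors", call. = FALSE)
  }
  L <- extract_factors(corr, n_factors, method)
  vm <- stats::varimax(L, normalize = TRUE)
  pm <- stats::promax(fix_signs(
    matrix(as.numeric(vm$loadings), nrow = nrow(L))), m = 4)
  pattern <- matrix(as.numeric(pm$loadings), nrow = nrow(L),
                    dimnames = list(colnames(corr),
                                    paste0("F", seq_len(n_factors))))
  ui <- solve(pm$rotmat)
  phi <- ui %*% t(ui)
  phi <- stats::cov2cor((phi + t(phi)) / 2)
  if (abs(det(phi)) < 1e-12) {
    warning("singular factor correlation matrix; g loadings unreliable",
            call. = FALSE)
  }
  gamma <- second_order_loadings(phi, method)
  g <- as.numeric(pattern %*% gamma)
  names(g) <- colnames(corr)
  ss_g <- sum(g^2)
  ev <- eigen(corr, symmetric = TRUE, only.values = TRUE)$values
  new_factor_solution(pattern, "promax (Schmid-Leiman)", ev, n_factors,
                      g_loadings = g, ss_g = ss_g,
                      pct_g = g_variance_pct(ss_g, ncol(corr)), phi = phi)
}

#' Percentage of variance explained by the general factor
#'
#' `100 * ss_g / n_tasks`, the general factor's sum-of-squares loading as a
#' share of the total (unit) variance of the task measures.
#'
#' @param ss_g sum of squared general-factor loadings.
#' @param n_tasks number of task measures.
#' @return percentage (full precision; round for reporting).
#' @export
g_variance_pct <- function(ss_g, n_tasks) {
  stopifnot(ss_g >= 0, n_tasks >= 1)
  100 * ss_g / n_tasks
}

#' Effect size f2 from a regression R-squared
#'
#' Computed as `(1 - R^2) / R^2`; values at or below 0.02 are conventionally
#' treated as negligible device effects. Set `conventional = TRUE` for the
#' textbook Cohen's f2 `R^2 / (1 - R^2)` (the reciprocal).
#'
#' @param r_squared coefficient of determination, in (0, 1\].
#' @param conventional use the textbook form instead.
#' @return numeric effect size.
#' @export
cohens_f2 <- function(r_squared, conventional = FALSE) {
  if (any(r_squared <= 0) || any(r_squared > 1)) {
    stop("r_squared must lie in (0, 1]", call. = FALSE)
  }
  if (conventional) {
    if (any(r_squared == 1)) stop("conventional f2 undefined at R^2 = 1",
                                  call. = FALSE)
    r_squared / (1 - r_squared)
  } else {
    (1 - r_squared) / r_squared
  }
}

#' Regression effect size in standard-deviation units
#'
#' A regression coefficient divided by the standard deviation of the
#' outcome, putting effects on a common SD scale across tasks.
#'
#' @param beta regression coefficient(s).
#' @param outcome_sd standard deviation of the outcome (positive).
#' @return effect size(s) in SD units.
#' @export
effect_size_sd <- function(beta, outcome_sd) {
  if (any(outcome_sd <= 0)) stop("outcome_sd must be positive", call. = FALSE)
  beta / outcome_sd
}

#' Assemble a participant-by-task score matrix from several fits
#'
#' Joins per-participant estimates from multiple fitted tasks on
#' participant id, producing the (possibly sparse) score matrix consumed by
#' [pairwise_correlation()]. Participants missing from a task get NA.
#'
#' @param fits named list of [idoct()] results, or of data.frames with
#'   `participant_id` and the measure column (e.g. read back from
#'   [write_fit()] output); names become task names.
#' @param measure which estimate to extract: `"as"`, `"dt"` or `"a"`.
#' @return numeric matrix, participants x tasks, with dimnames.
#' @export
score_matrix <- function(fits, measure = c("as", "dt", "a")) {
  measure <- match.arg(measure)
  if (is.null(names(fits)) || any(!nzchar(names(fits)))) {
    stop("fits must be a named list (names are task names)", call. = FALSE)
  }
  tabs <- lapply(fits, function(f) {
    if (inherits(f, "idoct_fit")) f <- participant_estimates(f)
    if (!all(c("participant_id", measure) %in% names(f))) {
      stop("each element needs participant_id and '", measure, "' columns",
           call. = FALSE)
    }
    f[, c("participant_id", measure)]
  })
  ids <- sort(unique(unlist(lapply(tabs, `[[`, "participant_id"))))
  out <- matrix(NA_real_, length(ids), length(tabs),
                dimnames = list(ids, names(tabs)))
  for (task in names(tabs)) {
    t <- tabs[[task]]
    out[t$participant_id, task] <- t[[measure]]
  }
  out
}
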