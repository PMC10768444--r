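# Group classification on relational (distance) data with the Potential
# Support Vector Machine (P-SVM), leave-one-out cross-validation,
# label-permutation significance testing and Bonferroni family correction.
#
# The P-SVM operates directly on a rectangular relational matrix K whose
# rows are samples and whose columns are reference samples -- here the
# profile-distance matrix restricted to the two groups being compared. K
# need not be square, symmetric, or positive semi-definite: distances are
# not kernels, which is precisely why a relational-data classifier is used.
# Each column of K is treated as a feature, standardised, and fitted with a
# box-constrained l1-penalised least-squares margin model (sparse in the
# reference samples); prediction is sign(sum_j alpha_j K(x, j) + b).

#' Train a P-SVM on a relational data matrix
#'
#' Solves `min 0.5*||X a + b - y||^2 + eps*||a||_1` subject to
#' `|a_j| <= C`, where `X` is `K` with columns standardised to zero mean and
#' unit variance (constant columns are inert). The l1 term selects a sparse
#' set of reference samples (the "support" columns); the box constraint
#' bounds each coefficient. The offset `b` is unpenalised.
#'
#' When `epsilon` is `NULL` it defaults to
#' `epsilon_scale * max_j |X_j'(y - mean(y))|`, the scale at which the first
#' coefficient becomes active; this keeps the default meaningful across
#' datasets without using any test-fold information.
#'
#' The box-constrained l1 problem is a small convex QP; it is solved either
#' by the package's own cyclic coordinate-descent routine (soft-threshold
#' and clip; the reference implementation) or by [glmnet::glmnet()] as a
#' generic penalised-least-squares backend, which is substantially faster
#' on larger, strongly correlated instances. The default `"auto"` picks by
#' problem size; both backends solve the identical objective and are
#' cross-checked against each other and against a generic QP oracle in the
#' package tests.
#'
#' @param K numeric matrix, rows = samples, columns = reference samples.
#' @param y labels in `{-1, +1}`, one per row of `K`.
#' @param C positive box constraint on each coefficient.
#' @param epsilon non-negative l1 penalty; `NULL` for the relative default.
#' @param epsilon_scale relative penalty used when `epsilon` is `NULL`.
#' @param solver `"auto"`, `"cd"` (own coordinate descent) or `"glmnet"`.
#' @return object of class `psvm`: coefficients `alpha`, offset `b`, column
#'   scalings, hyperparameters, and the attained objective value.
#' @export
train_psvm <- function(K, y, C = 100, epsilon = NULL, epsilon_scale = 0.1,
                       solver = c("auto", "cd", "glmnet")) {
  solver <- match.arg(solver)
  K <- as.matrix(K)
  y <- as.numeric(y)
  if (nrow(K) != length(y)) stop("nrow(K) != length(y)")
  if (!all(y %in% c(-1, 1))) stop("labels must be -1/+1")
  if (length(unique(y)) < 2L) stop("both label classes are required")
  if (all(K == 0)) stop("degenerate relational matrix (all zero)")
  if (C <= 0) stop("C must be positive")
  mu <- colMeans(K)
  sdv <- apply(K, 2, stats::sd)
  sdv[!is.finite(sdv) | sdv < 1e-12] <- Inf   # constant columns contribute 0
  X <- sweep(sweep(K, 2, mu, "-"), 2, sdv, "/")
  if (is.null(epsilon)) {
    epsilon <- epsilon_scale * max(abs(crossprod(X, y - mean(y))))
  }
  fit <- solve_psvm(X, y, epsilon, C, solver, tol = 1e-10)
  obj <- 0.5 * sum((y - X %*% fit$alpha - fit$b)^2) +
    epsilon * sum(abs(fit$alpha))
  structure(list(alpha = fit$alpha, b = fit$b,
                 mu = mu, sd = sdv, C = C, epsilon = epsilon,
                 objective = obj, solver = fit$solver),
            class = "psvm")
}

# dispatch the inner box-constrained l1 least-squares solve
solve_psvm <- function(X, y, epsilon, C, solver = "auto", tol = 1e-8,
                       a_init = NULL, b_init = 0) {
  if (solver == "auto") solver <- if (ncol(X) > 20L) "glmnet" else "cd"
  if (solver == "cd") {
    fit <- psvm_cd(X, y, epsilon, C, max_sweeps = 5000L, tol = tol,
                   a_init = a_init, b_init = b_init)
    list(alpha = as.numeric(fit$alpha), b = fit$b, solver = "cd")
  } else {
    # glmnet gaussian objective is (1/2n)*RSS + lambda*||a||_1
    n <- length(y)
    g <- glmnet::glmnet(X, y, family = "gaussian", lambda = epsilon / n,
                        standardize = FALSE, intercept = TRUE,
                        lower.limits = -C, upper.limits = C,
                        thresh = min(tol, 1e-9))
    cf <- as.numeric(stats::coef(g))
    list(alpha = cf[-1], b = cf[1], solver = "glmnet")
  }
}

#' @export
print.psvm <- function(x, ...) {
  cat(sprintf("<psvm> %d reference columns, %d active, C=%g, epsilon=%.4g\n",
              length(x$alpha), sum(x$alpha != 0), x$C, x$epsilon))
  invisible(x)
}

#' Decision values and class predictions for new relational rows
#'
#' @param object a fitted [train_psvm()] model.
#' @param K_new matrix (or vector) of relational values to the same
#'   reference columns used in training.
#' @param ... unused.
#' @return list with `decision` (numeric) and `label` (`+1`/`-1`;
#'   `decision >= 0` maps to `+1`).
#' @export
predict.psvm <- function(object, K_new, ...) {
  if (is.null(dim(K_new))) K_new <- matrix(K_new, nrow = 1L)
  X <- sweep(sweep(as.matrix(K_new), 2, object$mu, "-"), 2, object$sd, "/")
  f <- as.numeric(X %*% object$alpha + object$b)
  list(decision = f, label = ifelse(f >= 0, 1, -1))
}

#' Balanced accuracy (mean of per-class recalls)
#' @keywords internal
balanced_accuracy <- function(truth, predicted) {
  mean(vapply(c(-1, 1), function(cl)
    mean(predicted[truth == cl] == cl), numeric(1)))
}

# Precompute per-fold standardised training matrices for LOOCV on a square
# relational matrix D. The held-out sample is excluded both as a row and as
# a reference column. Label-independent, so reusable across permutations.
loocv_folds <- function(D) {
  D <- as.matrix(D)
  n <- nrow(D)
  if (n < 4L) stop("need at least 4 samples for LOOCV")
  folds <- lapply(seq_len(n), function(i) {
    tr <- setdiff(seq_len(n), i)
    Ktr <- D[tr, tr, drop = FALSE]
    mu <- colMeans(Ktr)
    sdv <- apply(Ktr, 2, stats::sd)
    sdv[!is.finite(sdv) | sdv < 1e-12] <- Inf
    Xtr <- sweep(sweep(Ktr, 2, mu, "-"), 2, sdv, "/")
    xte <- (D[i, tr] - mu) / sdv
    list(i = i, tr = tr, X = Xtr, x_new = xte)
  })
  mu <- colMeans(D)
  sdv <- apply(D, 2, stats::sd)
  sdv[!is.finite(sdv) | sdv < 1e-12] <- Inf
  attr(folds, "X_full") <- sweep(sweep(D, 2, mu, "-"), 2, sdv, "/")
  folds
}

# LOOCV score for a given label vector on precomputed folds. Scoring uses
# a lighter convergence tolerance than [train_psvm()] (decision values are
# stable well beyond the scale that could affect a prediction); on the
# coordinate-descent path each fold is warm-started from the full-data
# solution, which the folds differ from by a single sample.
loocv_score <- function(folds, y, C = 100, epsilon_scale = 0.1,
                        solver = "auto") {
  n <- length(y)
  dec <- numeric(n)
  backend <- if (solver == "auto") {
    if (ncol(attr(folds, "X_full")) > 20L) "glmnet" else "cd"
  } else solver
  a_full <- NULL; b_full <- 0
  if (backend == "cd") {
    full <- attr(folds, "X_full")
    eps_full <- epsilon_scale * max(abs(crossprod(full, y - mean(y))))
    warm <- solve_psvm(full, y, eps_full, C, "cd", tol = 1e-6)
    a_full <- warm$alpha; b_full <- warm$b
  }
  for (f in folds) {
    ytr <- y[f$tr]
    eps <- epsilon_scale * max(abs(crossprod(f$X, ytr - mean(ytr))))
    fit <- solve_psvm(f$X, ytr, eps, C, backend, tol = 1e-6,
                      a_init = if (is.null(a_full)) NULL else a_full[f$tr],
                      b_init = b_full)
    dec[f$i] <- sum(f$x_new * fit$alpha) + fit$b
  }
  pred <- ifelse(dec >= 0, 1, -1)
  list(decision = dec, predicted = pred,
       score = balanced_accuracy(y, pred),
       margin = mean(y * dec))
}

#' Leave-one-out cross-validation of the P-SVM
#'
#' For each sample the model is retrained on the remaining `n - 1` samples
#' (excluding the held-out sample both as a row and as a reference column)
#' and the held-out sample is predicted. The observed score is balanced
#' accuracy (mean of per-class recalls), robust to unequal group sizes.
#'
#' @param D square relational matrix (e.g. profile-distance matrix
#'   restricted to two groups), with one row/column per sample.
#' @param y labels in `{-1, +1}`.
#' @param C,epsilon_scale hyperparameters passed to [train_psvm()].
#' @return list with per-sample `decision` and `predicted`, the balanced
#'   accuracy `score`, and the mean margin `margin = mean(y * decision)`.
#' @export
psvm_loocv <- function(D, y, C = 100, epsilon_scale = 0.1,
                       solver = "auto") {
  y <- as.numeric(y)
  if (!all(y %in% c(-1, 1))) stop("labels must be -1/+1")
  if (length(unique(y)) < 2L) stop("both label classes are required")
  loocv_score(loocv_folds(D), y, C, epsilon_scale, solver)
}

#' Label-permutation significance test of P-SVM group separation
#'
#' Re-runs the full LOOCV under label permutations that preserve class
#' sizes and reports the add-one empirical p-value
#' `p = (1 + #permutations scoring >= observed) / (1 + n_perm)`. A
#' permutation counts as scoring at least the observed run if its balanced
#' accuracy exceeds the observed one, or ties it with at least the observed
#' mean margin -- the margin tie-break makes the comparison effectively
#' continuous, so the null p-value distribution is close to uniform instead
#' of conservatively lumpy.
#'
#' @param D square relational matrix over the compared samples.
#' @param y labels in `{-1, +1}`.
#' @param n_perm requested number of permutations (study convention: up to
#'   1000).
#' @param seed integer seed; permutations are deterministic given it.
#' @param C,epsilon_scale P-SVM hyperparameters.
#' @param comparison label carried into the result.
#' @param max_seconds optional wall-clock budget; if exceeded the test stops
#'   early, computes p over the completed shuffles and sets the `truncated`
#'   flag.
#' @return object of class `classification_result`.
#' @export
permutation_test <- function(D, y, n_perm = 1000L, seed = 1L, C = 100,
                             epsilon_scale = 0.1, comparison = "comparison",
                             max_seconds = Inf, solver = "auto") {
  if (n_perm < 1L) stop("n_perm must be >= 1")
  folds <- loocv_folds(D)
  y <- as.numeric(y)
  if (!all(y %in% c(-1, 1))) stop("labels must be -1/+1")
  obs <- loocv_score(folds, y, C, epsilon_scale, solver)
  t0 <- Sys.time()
  perm_scores <- numeric(0)
  perm_margins <- numeric(0)
  completed <- 0L
  for (k in seq_len(n_perm)) {
    yp <- with_seed(derive_seed(seed, "perm", k), sample(y))
    sc <- loocv_score(folds, yp, C, epsilon_scale, solver)
    perm_scores <- c(perm_scores, sc$score)
    perm_margins <- c(perm_margins, sc$margin)
    completed <- completed + 1L
    if (as.numeric(difftime(Sys.time(), t0, units = "secs")) > max_seconds)
      break
  }
  beats <- perm_scores > obs$score |
    (perm_scores == obs$score & perm_margins >= obs$margin)
  p <- (1 + sum(beats)) / (1 + completed)
  structure(list(comparison = comparison,
                 predictions = obs$predicted,
                 decision = obs$decision,
                 observed = obs$score,
                 margin = obs$margin,
                 perm_scores = perm_scores,
                 perm_margins = perm_margins,
                 n_perm = completed,
                 requested = as.integer(n_perm),
                 p_value = p,
                 truncated = completed < n_perm,
                 seed = seed),
            class = "classification_result")
}

#' @export
print.classification_result <- function(x, ...) {
  cat(sprintf(
    "<classification_result> %s: balanced accuracy %.3f, p = %.4g (%d%s permutations)\n",
    x$comparison, x$observed, x$p_value, x$n_perm,
    if (x$truncated) sprintf(" of %d requested", x$requested) else ""))
  invisible(x)
}

#' Bonferroni per-test significance threshold
#'
#' @param m number of tests in the family, or a [hypothesis_family()].
#' @param alpha_family family-wise error rate (default 0.05).
#' @return per-test threshold `alpha_family / m`.
#' @export
bonferroni_threshold <- function(m, alpha_family = 0.05) {
  if (inherits(m, "hypothesis_family")) m <- attr(m, "m")
  m <- as.integer(m)
  if (is.na(m) || m < 1L) stop("m must be >= 1")
  alpha_family / m
}

#' Enumerate a hypothesis family of group comparisons
#'
#' Each comparison is tested for both cell types (CD4, CD8) and each of the
#' three TCR chains (alpha, beta, gamma), i.e. six tests per hypothesis.
#' The primary family holds the three primary hypotheses (ME vs HC, ME vs
#' MS, MEsa vs MEmm; 18 tests); the secondary family holds six further
#' pairings (36 tests); `combined` is both (54 tests, the denominator of
#' the secondary Bonferroni threshold).
#'
#' The "Cases" group-set of the secondary family is configurable: the
#' default pools all disease cases (MEsa, MEmm, MS); pass
#' `cases = c("MEsa", "MEmm")` for the ME-only reading.
#'
#' @param name one of `"primary"`, `"secondary"`, `"combined"`.
#' @param cell_types,chains the test grid per hypothesis.
#' @param cases group labels pooled as "Cases" in the secondary family.
#' @param alpha_family family-wise error rate.
#' @return tibble of comparisons (classed `hypothesis_family`) with columns
#'   `hypothesis`, `groups_a`, `groups_b` (list-columns of group labels),
#'   `cell_type`, `chain`; attributes `m`, `alpha_family`, `threshold`.
#' @export
hypothesis_family <- function(name = c("primary", "secondary", "combined"),
                              cell_types = c("CD4", "CD8"),
                              chains = c("alpha", "beta", "gamma"),
                              cases = c("MEsa", "MEmm", "MS"),
                              alpha_family = 0.05) {
  name <- match.arg(name)
  prim <- list(
    "ME vs HC"      = list(a = c("MEsa", "MEmm"), b = "HC"),
    "ME vs MS"      = list(a = c("MEsa", "MEmm"), b = "MS"),
    "MEsa vs MEmm"  = list(a = "MEsa",            b = "MEmm"))
  seco <- list(
    "Cases vs HC"   = list(a = cases,             b = "HC"),
    "MS vs HC"      = list(a = "MS",              b = "HC"),
    "MEmm vs HC"    = list(a = "MEmm",            b = "HC"),
    "MEsa vs HC"    = list(a = "MEsa",            b = "HC"),
    "MEmm vs MS"    = list(a = "MEmm",            b = "MS"),
    "MEsa vs MS"    = list(a = "MEsa",            b = "MS"))
  hyps <- switch(name, primary = prim, secondary = seco,
                 combined = c(prim, seco))
  grid <- expand.grid(hypothesis = names(hyps), cell_type = cell_types,
                      chain = chains, stringsAsFactors = FALSE,
                      KEEP.OUT.ATTRS = FALSE)
  out <- tibble::tibble(
    hypothesis = grid$hypothesis,
    groups_a = lapply(grid$hypothesis, function(h) hyps[[h]]$a),
    groups_b = lapply(grid$hypothesis, function(h) hyps[[h]]$b),
    cell_type = grid$cell_type,
    chain = grid$chain)
  # secondary aims are corrected against all tests run (primary +
  # secondary), so their Bonferroni denominator is the combined count
  denom <- if (name == "secondary")
    nrow(out) + length(prim) * length(cell_types) * length(chains)
  else nrow(out)
  structure(out, class = c("hypothesis_family", class(out)),
            family = name, m = nrow(out), alpha_family = alpha_family,
            threshold = alpha_family / denom)
}

#' Run a hypothesis family over per-(cell type, chain) distance matrices
#'
#' For each enumerated comparison, restricts the relevant distance matrix to
#' the samples of the two group-sets, labels them +1/-1, and runs the P-SVM
#' permutation test. Comparisons whose groups are missing from the metadata
#' are skipped with a warning.
#'
#' @param dist_matrices named list of square distance matrices, names
#'   `"<cell_type>_<chain>"` (e.g. `"CD8_alpha"`), dimnames = sample ids.
#' @param metadata data frame with columns `sample_id`, `group`,
#'   `cell_type`.
#' @param family a [hypothesis_family()].
#' @param n_perm,seed,C,epsilon_scale,max_seconds passed to
#'   [permutation_test()]; each comparison gets a seed derived from `seed`
#'   and its description.
#' @return tibble report: one row per comparison with the observed score,
#'   raw p-value, truncation flag, raw `p < 0.05` marker and whether the
#'   comparison survives the family threshold.
#' @export
run_comparison_grid <- function(dist_matrices, metadata, family,
                                n_perm = 1000L, seed = 1L, C = 100,
                                epsilon_scale = 0.1, max_seconds = Inf) {
  stopifnot(inherits(family, "hypothesis_family"))
  thr <- attr(family, "threshold")
  rows <- lapply(seq_len(nrow(family)), function(r) {
    h <- family$hypothesis[r]
    ct <- family$cell_type[r]
    ch <- family$chain[r]
    key <- paste(ct, ch, sep = "_")
    D <- dist_matrices[[key]]
    if (is.null(D)) {
      warning(sprintf("no distance matrix for %s; skipping %s", key, h))
      return(NULL)
    }
    md <- metadata[metadata$cell_type == ct, , drop = FALSE]
    ids_a <- md$sample_id[md$group %in% family$groups_a[[r]]]
    ids_b <- md$sample_id[md$group %in% family$groups_b[[r]]]
    ids_a <- intersect(ids_a, rownames(D))
    ids_b <- intersect(ids_b, rownames(D))
    if (length(ids_a) < 2L || length(ids_b) < 2L) {
      warning(sprintf("missing group for %s (%s): skipped", h, key))
      return(NULL)
    }
    ids <- c(ids_a, ids_b)
    y <- c(rep(1, length(ids_a)), rep(-1, length(ids_b)))
    res <- permutation_test(D[ids, ids], y, n_perm = n_perm,
                            seed = derive_seed(seed, h, ct, ch),
                            C = C, epsilon_scale = epsilon_scale,
                            comparison = sprintf("%s [%s %s]", h, ct, ch),
                            max_seconds = max_seconds)
    tibble::tibble(hypothesis = h, cell_type = ct, chain = ch,
                   n_a = length(ids_a), n_b = length(ids_b),
                   observed = res$observed, p_value = res$p_value,
                   n_perm = res$n_perm, truncated = res$truncated,
                   raw_significant = res$p_value < 0.05,
                   family_significant = res$p_value < thr)
  })
  out <- dplyr::bind_rows(rows)
  attr(out, "family") <- attr(family, "family")
  attr(out, "threshold") <- thr
  out
}
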