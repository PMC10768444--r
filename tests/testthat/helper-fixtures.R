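# Shared fixtures and independent oracles for the test suite. Fixtures are
# generated in code under fixed seeds; oracles are deliberately naive
# implementations kept independent of the package code paths they check.

# cached germline references (generation is cheap but repeated a lot)
.fixture_env <- new.env(parent = emptyenv())

trb_segments <- function() {
  if (is.null(.fixture_env$trb))
    .fixture_env$trb <- make_germline_reference(8, 2, 4, "TRB", seed = 7)
  .fixture_env$trb
}

trg_segments <- function() {
  if (is.null(.fixture_env$trg))
    .fixture_env$trg <- make_germline_reference(4, 0, 3, "TRG", seed = 5)
  .fixture_env$trg
}

# brute-force connected components of the <= max_mm mismatch graph
bf_umi_components <- function(umis, max_mm = 2L) {
  uniq <- unique(umis)
  n <- length(uniq)
  if (n == 0L) return(0L)
  adj <- matrix(FALSE, n, n)
  for (i in seq_len(n)) {
    for (k in seq_len(n)) {
      d <- sum(utf8ToInt(uniq[i]) != utf8ToInt(uniq[k]))
      adj[i, k] <- d <= max_mm
    }
  }
  seen <- rep(FALSE, n)
  comps <- 0L
  for (s in seq_len(n)) {
    if (seen[s]) next
    comps <- comps + 1L
    queue <- s
    while (length(queue) > 0L) {
      v <- queue[1]; queue <- queue[-1]
      if (seen[v]) next
      seen[v] <- TRUE
      queue <- c(queue, which(adj[v, ] & !seen))
    }
  }
  comps
}

# the P-SVM objective on standardised features
psvm_objective <- function(X, y, a, b, eps) {
  0.5 * sum((y - X %*% a - b)^2) + eps * sum(abs(a))
}

# generic QP oracle: L-BFGS-B on the positive/negative split
# a = u - v, u, v in [0, C]; the l1 term becomes linear
qp_oracle <- function(X, y, eps, C) {
  m <- ncol(X); n <- nrow(X)
  fn <- function(par) {
    u <- par[1:m]; v <- par[(m + 1):(2 * m)]; b <- par[2 * m + 1]
    r <- y - X %*% (u - v) - b
    0.5 * sum(r^2) + eps * sum(u + v)
  }
  gr <- function(par) {
    u <- par[1:m]; v <- par[(m + 1):(2 * m)]; b <- par[2 * m + 1]
    r <- as.numeric(y - X %*% (u - v) - b)
    g <- -as.numeric(crossprod(X, r))
    c(g + eps, -g + eps, -sum(r))
  }
  fit <- stats::optim(rep(0, 2 * m + 1), fn, gr, method = "L-BFGS-B",
                      lower = c(rep(0, 2 * m), -Inf),
                      upper = c(rep(C, 2 * m), Inf),
                      control = list(maxit = 5000, factr = 10))
  u <- fit$par[1:m]; v <- fit$par[(m + 1):(2 * m)]
  list(alpha = u - v, b = fit$par[2 * m + 1], objective = fit$value)
}

# distance matrix of two well-separated 1-d clusters (labels +1 then -1)
separable_instance <- function(n_per_class = 6, gap = 8, seed = 1) {
  set.seed(seed)
  x <- c(rnorm(n_per_class, 0, 0.5), rnorm(n_per_class, gap, 0.5))
  D <- as.matrix(dist(x))
  ids <- paste0("s", seq_len(2 * n_per_class))
  dimnames(D) <- list(ids, ids)
  list(D = D, y = rep(c(1, -1), each = n_per_class))
}

# simulate a null or effect cohort and return its permutation p-value
pipeline_p_value <- function(rep_index, n_per_group, effect_delta,
                             depth_range, n_perm, seed_base) {
  cs <- cohort_spec(groups = c(A = n_per_group, B = n_per_group),
                    base_expansion = 0.05, effect_delta = effect_delta,
                    effect_groups = "B", depth_range = depth_range,
                    seed = tcrdiv:::derive_seed(seed_base, "cohort", rep_index))
  co <- simulate_cohort(cs)
  D <- distance_matrix(cohort_counts(co),
                       seed = tcrdiv:::derive_seed(seed_base, "dist", rep_index))
  y <- ifelse(co$group == "A", 1, -1)
  permutation_test(D, y, n_perm = n_perm,
                   seed = tcrdiv:::derive_seed(seed_base, "perm", rep_index))$p_value
}
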