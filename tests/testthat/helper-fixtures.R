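# Shared fixtures, built in code and memoized for the session.

.fixture_env <- new.env(parent = emptyenv())

memo <- function(key, expr) {
  if (!exists(key, envir = .fixture_env)) {
    assign(key, expr, envir = .fixture_env)
  }
  get(key, envir = .fixture_env)
}

# Small M = 2 labeled datasets for fast end-to-end checks.
tiny_noiseless <- function() {
  memo("tiny_noiseless",
       generate_dataset(M = 2, p = 3, N = 600, trials_per_graph = 16,
                        noise_mode = "none", seed = 42))
}

tiny_noisy <- function() {
  memo("tiny_noisy",
       generate_dataset(M = 2, p = 3, N = 600, trials_per_graph = 16,
                        noise_mode = "uniform", seed = 43))
}

# One moderate M = 3 trial for feature/Geweke equivalence checks.
one_trial_m3 <- function() {
  memo("one_trial_m3", {
    ds <- generate_dataset(M = 3, p = 10, N = 800, trials_per_graph = 1,
                           noise_mode = "uniform", seed = 7)
    ds$trials[[5]]$X
  })
}

# Exhaustive concordant-pair-counting AUC oracle (ties get half credit).
auc_pair_oracle <- function(scores, truths) {
  s <- as.vector(scores)
  y <- as.vector(truths)
  pos <- s[y == 1]
  neg <- s[y == 0]
  cmp <- outer(pos, neg, ">") + 0.5 * outer(pos, neg, "==")
  mean(cmp)
}

# Brute-force normal-equations OLS oracle.
ols_normal_eq_oracle <- function(design, target) {
  Z <- cbind(1, design)
  beta <- solve(crossprod(Z), crossprod(Z, target))
  res <- target - Z %*% beta
  list(coefficients = drop(beta), mse = mean(res^2))
}

tiny_m3_stub <- function() {
  memo("tiny_m3_stub",
       generate_dataset(M = 3, p = 2, N = 60, trials_per_graph = 1,
                        noise_mode = "none", seed = 77))
}

subset_one_class <- function(fe) {
  keep <- fe$graph_index == 0
  fe$X <- fe$X[keep, , drop = FALSE]
  fe$graph_index <- fe$graph_index[keep]
  fe
}
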