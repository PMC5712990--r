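## MAR(p) generative model. Each trial is X = (1 - gamma) * Xs + gamma * Xn,
## where Xs is a stationary MAR(p) process whose lag coefficients follow a
## binary causal graph and Xn is an independent MAR(p) noise process with
## diagonal (channel-wise) lag coefficients. Innovations are i.i.d.
## M-dimensional standard normal.

check_coeffs <- function(coeffs) {
  if (!is.list(coeffs) || length(coeffs) < 1L) {
    stop_invalid("`coeffs` must be a non-empty list of square matrices")
  }
  M <- nrow(coeffs[[1]])
  ok <- vapply(coeffs, function(a) {
    is.matrix(a) && is.numeric(a) && nrow(a) == M && ncol(a) == M &&
      all(is.finite(a))
  }, logical(1))
  if (is.null(M) || !all(ok)) {
    stop_invalid("`coeffs` must be a list of equally sized square numeric matrices")
  }
  invisible(coeffs)
}

#' Companion-matrix stationarity test for MAR(p) coefficients
#'
#' An MAR(p) process is (covariance-)stationary iff the spectral radius of
#' the `(Mp) x (Mp)` companion matrix of its lag coefficients is below 1.
#'
#' @param coeffs list of `p` square `M x M` coefficient matrices
#'   `A(1), ..., A(p)` (the orientation is immaterial: a matrix set and its
#'   transposes have the same companion spectrum).
#' @return `is_stationary()` returns `TRUE`/`FALSE`; `spectral_radius()`
#'   returns the modulus of the leading companion eigenvalue.
#' @examples
#' is_stationary(list(matrix(0.5)))        # AR(1), a = 0.5
#' is_stationary(list(matrix(1.1)))        # explosive
#' @export
is_stationary <- function(coeffs) {
  spectral_radius(coeffs) < 1
}

#' @rdname is_stationary
#' @export
spectral_radius <- function(coeffs) {
  check_coeffs(coeffs)
  p <- length(coeffs)
  M <- nrow(coeffs[[1]])
  comp <- matrix(0, M * p, M * p)
  for (tau in seq_len(p)) {
    comp[seq_len(M), (tau - 1) * M + seq_len(M)] <- coeffs[[tau]]
  }
  if (p > 1) {
    idx <- seq_len(M * (p - 1))
    comp[cbind(M + idx, idx)] <- 1
  }
  max(Mod(eigen(comp, only.values = TRUE)$values))
}

## Shrink a coefficient set until stationary: scale the whole tensor by
## target/rho and re-check (the companion spectrum is not homogeneous in a
## uniform coefficient scale, hence the loop).
shrink_to_stationary <- function(coeffs, target = 0.95, max_iter = 100L) {
  for (it in seq_len(max_iter)) {
    rho <- spectral_radius(coeffs)
    if (rho < 1) return(coeffs)
    coeffs <- lapply(coeffs, function(a) a * (target / rho))
  }
  stop_invalid("failed to reach a stationary coefficient set")  # nocov
}

#' Sample MAR coefficient tensors for a causal graph
#'
#' `sample_signal_coeffs()` draws the signal coefficients `A_s(1..p)`:
#' entries allowed by the binary graph (including the diagonal, which is
#' fixed to 1 in the graph convention) are Uniform(-1, 1) draws, all other
#' entries are exactly zero at every lag. `sample_noise_coeffs()` draws the
#' noise coefficients `A_n(1..p)` as diagonal matrices with Uniform(-1, 1)
#' diagonals, so the noise process is M independent univariate AR(p)
#' channels. Both are rescaled, if necessary, by a shrinkage loop
#' (multiply the whole tensor by `0.95 / rho` until the companion spectral
#' radius `rho` drops below 1), which preserves the zero pattern and
#' guarantees termination.
#'
#' Draws are consumed from the current R random stream; seed beforehand
#' for reproducibility.
#'
#' @param graph binary `M x M` causal configuration matrix.
#' @param p lag order.
#' @param M number of channels.
#' @return A list of `p` matrices passing [is_stationary()].
#' @examples
#' set.seed(1)
#' cs <- sample_signal_coeffs(index_to_graph(5, 3), p = 4)
#' is_stationary(cs)
#' @export
sample_signal_coeffs <- function(graph, p) {
  check_graph(graph)
  p <- check_count(p, "p")
  M <- nrow(graph)
  mask <- graph
  diag(mask) <- 1
  coeffs <- lapply(seq_len(p), function(tau) {
    mask * matrix(runif(M * M, -1, 1), M, M)
  })
  shrink_to_stationary(coeffs)
}

#' @rdname sample_signal_coeffs
#' @export
sample_noise_coeffs <- function(M, p) {
  M <- check_count(M, "M")
  p <- check_count(p, "p")
  coeffs <- lapply(seq_len(p), function(tau) diag(runif(M, -1, 1), M, M))
  shrink_to_stationary(coeffs)
}

#' Simulate one component of the MAR model
#'
#' Runs the recursion
#' `x(t) = sum_tau t(A(tau)) x(t - tau) + e(t)` with innovations `e(t)`
#' i.i.d. M-dimensional standard normal, starting from a zero state, and
#' discards the first `burn_in` samples. Entry `(i, j)` of each `A(tau)`
#' controls the lagged influence of channel `i` on channel `j` (hence the
#' transpose in the recursion).
#'
#' @param coeffs list of `p` coefficient matrices; must be stationary.
#' @param N number of retained time points.
#' @param burn_in number of initial samples discarded to wash out the zero
#'   initial state.
#' @return An `N x M` numeric matrix.
#' @examples
#' set.seed(1)
#' x <- simulate_component(list(matrix(0.9)), N = 200, burn_in = 100)
#' @export
simulate_component <- function(coeffs, N, burn_in = 500L) {
  check_coeffs(coeffs)
  N <- check_count(N, "N")
  burn_in <- check_count(burn_in, "burn_in", min = 0L)
  p <- length(coeffs)
  if (N <= p) stop_invalid("`N` must exceed the lag order p")
  if (!is_stationary(coeffs)) {
    stop_invalid("`coeffs` are non-stationary; simulation would diverge")
  }
  M <- nrow(coeffs[[1]])
  total <- N + burn_in
  innov <- matrix(rnorm(total * M), total, M)
  coef_t <- do.call(cbind, lapply(coeffs, t))
  X <- mar_recurse_cpp(coef_t, innov, p)
  X[(burn_in + 1):total, , drop = FALSE]
}

#' Mix signal and noise components
#'
#' Elementwise convex combination `X = (1 - gamma) * Xs + gamma * Xn`.
#' `gamma` tunes the signal-to-noise ratio: 0 keeps the causal component
#' only, 1 keeps the noise only.
#'
#' @param X_s,X_n equally shaped numeric matrices.
#' @param gamma mixing weight in `[0, 1]`.
#' @return Matrix of the same shape.
#' @export
mix_series <- function(X_s, X_n, gamma) {
  gamma <- check_prob(gamma, "gamma")
  if (!is.matrix(X_s) || !is.matrix(X_n) ||
      !identical(dim(X_s), dim(X_n))) {
    stop_invalid("`X_s` and `X_n` must be matrices of identical shape")
  }
  (1 - gamma) * X_s + gamma * X_n
}

## One labeled trial: fresh coefficients, fresh innovations, fixed gamma.
simulate_trial <- function(graph, p, N, gamma, burn_in) {
  cs <- sample_signal_coeffs(graph, p)
  cn <- sample_noise_coeffs(nrow(graph), p)
  Xs <- simulate_component(cs, N, burn_in)
  Xn <- simulate_component(cn, N, burn_in)
  list(X = mix_series(Xs, Xn, gamma), signal_coeffs = cs, noise_coeffs = cn)
}

#' Generate a balanced labeled MAR dataset
#'
#' Simulates `trials_per_graph` trials for each of the `2^(M(M-1))`
#' enumerated causal graphs. Each trial draws fresh signal and noise
#' coefficient tensors, a fresh mixing weight gamma (0 for
#' `noise_mode = "none"`, Uniform(0, 1) for `noise_mode = "uniform"`) and
#' fresh innovations. Every trial has its own random stream derived
#' deterministically from `(seed, graph index, replicate index)` via
#' [mix_seed()], so datasets are bitwise reproducible.
#'
#' @param M number of channels.
#' @param p MAR lag order.
#' @param N time points per trial.
#' @param trials_per_graph trials simulated for each graph.
#' @param noise_mode `"none"` (gamma = 0 for every trial; the noiseless
#'   dataset) or `"uniform"` (gamma ~ Uniform(0, 1) per trial; the noisy
#'   dataset).
#' @param seed master seed.
#' @param burn_in discarded initial samples per component; default
#'   `max(500, 10 * p)`.
#' @param max_trials resource guard on the total trial count.
#' @return A `mar_dataset`: list with `trials` (each a list with `X`,
#'   `graph_index`, `gamma`, `seed`), plus `M`, `p`, `N`,
#'   `trials_per_graph`, `noise_mode`, `seed`, `burn_in`.
#' @examples
#' ds <- generate_dataset(M = 2, p = 2, N = 80, trials_per_graph = 2,
#'                        noise_mode = "none", seed = 1)
#' length(ds$trials)  # 8 = 2^2 graphs x 2 trials
#' @export
generate_dataset <- function(M, p, N, trials_per_graph,
                             noise_mode = c("uniform", "none"),
                             seed = 1L,
                             burn_in = max(500L, 10L * p),
                             max_trials = 1e6) {
  M <- check_count(M, "M")
  p <- check_count(p, "p")
  N <- check_count(N, "N")
  trials_per_graph <- check_count(trials_per_graph, "trials_per_graph")
  noise_mode <- match.arg(noise_mode)
  n_g <- n_graphs(M)
  if (n_g * trials_per_graph > max_trials) {
    stop_invalid(sprintf(
      "requested %g trials exceeds `max_trials` (%g); raise the cap explicitly",
      n_g * trials_per_graph, max_trials))
  }
  graphs <- enumerate_graphs(M)
  trials <- vector("list", n_g * trials_per_graph)
  k <- 0L
  for (gi in seq_len(n_g) - 1L) {
    graph <- graphs[[gi + 1L]]
    for (r in seq_len(trials_per_graph)) {
      trial_seed <- mix_seed(seed, gi, r)
      tr <- with_seed(trial_seed, {
        gamma <- if (noise_mode == "uniform") runif(1) else 0
        sim <- simulate_trial(graph, p, N, gamma, burn_in)
        list(X = sim$X, graph_index = gi, gamma = gamma, seed = trial_seed)
      })
      k <- k + 1L
      trials[[k]] <- tr
    }
  }
  structure(
    list(trials = trials, M = M, p = p, N = N,
         trials_per_graph = trials_per_graph, noise_mode = noise_mode,
         seed = as.integer(seed), burn_in = burn_in),
    class = "mar_dataset")
}

#' @exportS3Method base::print
print.mar_dataset <- function(x, ...) {
  cat(sprintf(
    "MAR dataset: %d trials (%d graphs x %d), M = %d, p = %d, N = %d, noise = %s, seed = %d\n",
    length(x$trials), n_graphs(x$M), x$trials_per_graph, x$M, x$p, x$N,
    x$noise_mode, x$seed))
  invisible(x)
}

#' Ground-truth cell labels of a labeled dataset
#'
#' @param dataset a `mar_dataset` (or anything with `trials` carrying
#'   `graph_index`).
#' @return A binary matrix, trials x off-diagonal cells, columns in the
#'   canonical cell order of [off_diag_cells()].
#' @export
dataset_truth <- function(dataset) {
  idx <- vapply(dataset$trials, function(tr) {
    if (is.null(tr$graph_index) || is.na(tr$graph_index)) NA_real_
    else as.numeric(tr$graph_index)
  }, numeric(1))
  if (anyNA(idx)) stop_invalid("dataset has trials without ground-truth labels")
  graph_bits(idx, dataset$M)
}
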