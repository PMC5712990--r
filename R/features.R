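## Feature-space mapping: one trial -> regression scores over causality
## scenarios, Geweke-style log-variance-ratio features, and optional
## engineered expansions.

#' Map one trial into the causality-scenario feature space
#'
#' Fits the lagged regression problem of every scenario in the selected
#' family (in-sample OLS with intercept) and assembles, in canonical
#' scenario order, the pair (MSE, r^2) per scenario, followed by a block
#' of `M(M-1)` Granger-causality coefficients: for each ordered channel
#' pair `(i, j)` the conditional Geweke log variance ratio
#' `ln(rv[(all \\ i) -> j] / rv[all -> j])` (complete and c-pw modes) or
#' its bivariate analogue `ln(rv[{j} -> j] / rv[{i, j} -> j])` (pw mode).
#' The ratios reuse the already-fitted scenarios; no extra regressions
#' are run.
#'
#' @param X `N x M` numeric matrix (one trial).
#' @param p lag order of the regression problems.
#' @param mode scenario family: `"complete"`, `"pw"` or `"c-pw"`.
#' @return A named numeric vector of length
#'   `2 * n_scenarios + M(M-1)` (48 for M = 3 complete), with attributes
#'   `M`, `p`, `mode`.
#' @examples
#' set.seed(1)
#' x <- matrix(rnorm(300), 100, 3)
#' length(compute_features(x, p = 2))  # 48
#' @export
compute_features <- function(X, p, mode = c("complete", "pw", "c-pw")) {
  mode <- match.arg(mode)
  p <- check_count(p, "p")
  if (!is.matrix(X) || nrow(X) <= p) {
    stop_invalid("`X` must be a matrix with more than p rows")
  }
  M <- ncol(X)
  scs <- reduce_scenarios(enumerate_scenarios(M), mode, M)
  labels <- vapply(scs, scenario_label, character(1))
  L <- cbind(1, lag_matrix(X, p))
  targets <- X[(p + 1):nrow(X), , drop = FALSE]
  fits <- lapply(scs, function(sc) {
    cols <- c(1L, 1L + lag_columns(sc$causes, p))
    ols_score(L[, cols, drop = FALSE], targets[, sc$effect])
  })
  names(fits) <- labels

  base <- numeric(2L * length(fits))
  base_names <- character(length(base))
  for (k in seq_along(fits)) {
    base[2 * k - 1] <- fits[[k]]$mse
    base[2 * k] <- fits[[k]]$r2
    base_names[2 * k - 1] <- paste0("mse[", labels[k], "]")
    base_names[2 * k] <- paste0("r2[", labels[k], "]")
  }

  rv <- vapply(fits, `[[`, numeric(1), "rv")
  cells <- off_diag_cells(M)
  gc <- numeric(nrow(cells))
  for (k in seq_len(nrow(cells))) {
    i <- cells[k, 1]; j <- cells[k, 2]
    if (mode == "pw") {
      num <- scenario_label(list(causes = j, effect = j))
      den <- scenario_label(list(causes = sort(c(i, j)), effect = j))
    } else {
      num <- scenario_label(list(causes = setdiff(seq_len(M), i), effect = j))
      den <- scenario_label(list(causes = seq_len(M), effect = j))
    }
    gc[k] <- log(rv[[num]] / rv[[den]])
  }

  out <- c(base, gc)
  names(out) <- c(base_names, paste0("gc[", cell_names(M), "]"))
  structure(out, M = M, p = p, mode = mode)
}

#' Engineered feature expansion
#'
#' Appends, for every input feature `x`: its square, its cube and its
#' signed square root `sign(x) * sqrt(|x|)` (the Geweke-ratio features can
#' be marginally negative numerically), followed by every unordered
#' pairwise product of the input features. A vector of `k` features
#' expands to `4k + choose(k, 2)` (1320 for the 48 complete-mode
#' features). Names are derived deterministically from the input names.
#'
#' @param v named numeric vector of raw features.
#' @return The expanded named numeric vector (original features first).
#' @examples
#' engineer_features(c(a = 4, b = 9))
#' @export
engineer_features <- function(v) {
  if (!is.numeric(v) || is.null(names(v)) || any(!is.finite(v))) {
    stop_invalid("`v` must be a named numeric vector of finite features")
  }
  n <- names(v)
  k <- length(v)
  pairs <- if (k >= 2) combn(k, 2) else matrix(integer(0), 2, 0)
  prods <- v[pairs[1, ]] * v[pairs[2, ]]
  out <- c(v, v^2, v^3, sign(v) * sqrt(abs(v)), prods)
  names(out) <- c(
    n,
    paste0("(", n, ")^2"),
    paste0("(", n, ")^3"),
    paste0("sqrt(", n, ")"),
    paste0(n[pairs[1, ]], "*", n[pairs[2, ]]))
  at <- attributes(v)
  structure(out, M = at$M, p = at$p, mode = at$mode, engineered = TRUE)
}

#' Featurize every trial of a dataset
#'
#' @param dataset a `mar_dataset` (or compatible list of trials).
#' @param mode scenario family passed to [compute_features()].
#' @param engineered apply [engineer_features()] to every trial's vector.
#' @param p lag order; defaults to the dataset's generating order.
#' @return A `trial_features` object: list with `X` (trials x features
#'   matrix with stable column names), `graph_index` (per-trial label, NA
#'   if absent), `M`, `p`, `mode`, `engineered`.
#' @export
featurize_dataset <- function(dataset, mode = c("complete", "pw", "c-pw"),
                              engineered = TRUE, p = dataset$p) {
  mode <- match.arg(mode)
  trials <- dataset$trials
  if (length(trials) == 0L) stop_invalid("dataset has no trials")
  one <- function(tr) {
    v <- compute_features(tr$X, p, mode)
    if (engineered) v <- engineer_features(v)
    v
  }
  first <- one(trials[[1]])
  X <- matrix(0, length(trials), length(first),
              dimnames = list(NULL, names(first)))
  X[1, ] <- first
  if (length(trials) > 1) {
    for (k in 2:length(trials)) X[k, ] <- one(trials[[k]])
  }
  gi <- vapply(trials, function(tr) {
    if (is.null(tr$graph_index)) NA_real_ else as.numeric(tr$graph_index)
  }, numeric(1))
  structure(
    list(X = X, graph_index = gi, M = dataset$M, p = p, mode = mode,
         engineered = engineered),
    class = "trial_features")
}

#' @exportS3Method base::print
print.trial_features <- function(x, ...) {
  cat(sprintf(
    "Trial features: %d trials x %d features (mode = %s, engineered = %s, p = %d)\n",
    nrow(x$X), ncol(x$X), x$mode, x$engineered, x$p))
  invisible(x)
}
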