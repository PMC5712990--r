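## Conditional Geweke measure of Granger causality in the time domain,
## with the large-sample chi-square significance test. This is the
## unsupervised baseline (GCA) against which the supervised classifiers
## are compared.

#' Conditional Geweke measure in the time domain
#'
#' Tests whether channel `i` Granger-causes channel `j` conditional on all
#' remaining channels: fits two lagged OLS models for `x_j(t)` over
#' `t = p..N-1` -- the reduced model on the lags of every channel except
#' `i`, and the full model on the lags of all channels -- and returns the
#' natural log of the ratio of their (maximum-likelihood) residual
#' variances, `ln(rv_reduced / rv_full)`. The models are nested and fitted
#' in sample, so the value is non-negative up to solver tolerance.
#'
#' @param X `N x M` numeric matrix (one trial).
#' @param i candidate cause channel (1-based).
#' @param j effect channel, `j != i`.
#' @param p lag order of both models.
#' @return The F value in nats (a single non-negative number).
#' @examples
#' set.seed(1)
#' x <- matrix(rnorm(600), 200, 3)
#' conditional_geweke(x, 1, 2, p = 3)
#' @export
conditional_geweke <- function(X, i, j, p) {
  p <- check_count(p, "p")
  M <- ncol(X)
  i <- check_count(i, "i")
  j <- check_count(j, "j")
  if (i > M || j > M || i == j) {
    stop_invalid("`i` and `j` must be distinct channel indices")
  }
  if (nrow(X) <= p * M + 1) {
    stop_invalid("too few time points for the full conditional model")
  }
  L <- cbind(1, lag_matrix(X, p))
  y <- X[(p + 1):nrow(X), j]
  full <- ols_score(L, y)
  red_cols <- c(1L, 1L + lag_columns(setdiff(seq_len(M), i), p))
  reduced <- ols_score(L[, red_cols, drop = FALSE], y)
  f <- log(reduced$rv / full$rv)
  if (!is.finite(f)) {
    stop_invalid(sprintf(
      "non-finite Geweke ratio for pair (%d, %d): rv_reduced = %g, rv_full = %g",
      i, j, reduced$rv, full$rv))
  }
  f
}

#' Asymptotic significance of a Geweke F value
#'
#' Under the null of no Granger causality, the likelihood-ratio statistic
#' `(N - p) * F` is asymptotically chi-square with `p` degrees of freedom
#' (`N - p` is the number of regression rows, `p` the number of excluded
#' lag coefficients).
#'
#' @param F_value Geweke log variance ratio (nats).
#' @param N trial length in time points.
#' @param p lag order.
#' @return The p-value in `[0, 1]` (`1` at `F = 0`).
#' @export
gca_significance <- function(F_value, N, p) {
  N <- check_count(N, "N")
  p <- check_count(p, "p")
  if (!is.numeric(F_value) || any(!is.finite(F_value))) {
    stop_invalid("`F_value` must be finite")
  }
  pchisq(pmax(F_value, 0) * (N - p), df = p, lower.tail = FALSE)
}

#' Per-cell GCA score matrix of one trial
#'
#' Computes `1 - p_value` of the conditional Geweke test for every ordered
#' channel pair and places it at cell `(i, j)`; the diagonal is `NA`.
#' Higher scores mean stronger evidence for a causal link, so the matrix
#' is directly comparable with the classifiers' posterior cell scores.
#'
#' @inheritParams conditional_geweke
#' @return An `M x M` numeric matrix with `NA` diagonal.
#' @export
gca_score_matrix <- function(X, p) {
  M <- ncol(X)
  out <- matrix(NA_real_, M, M)
  cells <- off_diag_cells(M)
  fv <- gca_trial_F(X, p)
  out[cells] <- 1 - gca_significance(fv, nrow(X), p)
  out
}

## All M(M-1) conditional Geweke F values of one trial, in canonical cell
## order, sharing one lag matrix and one full fit per effect.
gca_trial_F <- function(X, p) {
  M <- ncol(X)
  L <- cbind(1, lag_matrix(X, p))
  targets <- X[(p + 1):nrow(X), , drop = FALSE]
  rv_full <- vapply(seq_len(M), function(j) {
    ols_score(L, targets[, j])$rv
  }, numeric(1))
  cells <- off_diag_cells(M)
  vapply(seq_len(nrow(cells)), function(k) {
    i <- cells[k, 1]; j <- cells[k, 2]
    red_cols <- c(1L, 1L + lag_columns(setdiff(seq_len(M), i), p))
    rv_red <- ols_score(L[, red_cols, drop = FALSE], targets[, j])$rv
    log(rv_red / rv_full[j])
  }, numeric(1))
}

#' GCA cell scores for every trial of a dataset
#'
#' @param dataset a `mar_dataset`.
#' @param p lag order; defaults to the dataset's generating order.
#' @return A numeric matrix, trials x off-diagonal cells (canonical cell
#'   order), of `1 - p_value` scores.
#' @export
gca_scores <- function(dataset, p = dataset$p) {
  p <- check_count(p, "p")
  n <- length(dataset$trials)
  out <- matrix(NA_real_, n, dataset$M * (dataset$M - 1),
                dimnames = list(NULL, cell_names(dataset$M)))
  for (k in seq_len(n)) {
    X <- dataset$trials[[k]]$X
    out[k, ] <- 1 - gca_significance(gca_trial_F(X, p), nrow(X), p)
  }
  out
}
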