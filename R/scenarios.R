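## Causality scenarios and their lagged regression problems. A scenario
## pairs a non-empty cause subset with an effect channel; its regression
## problem predicts x_effect(t) from the p previous samples of every cause
## channel, for every admissible t.

#' Enumerate causality scenarios
#'
#' A causality scenario is a pair (cause subset, effect): one lagged
#' regression problem predicting the effect channel from the past of the
#' cause channels. For `M` channels there are `(2^M - 1) * M` scenarios
#' (every non-empty subset, for every effect). The canonical order is
#' effect-major; within an effect, cause subsets are ordered by size and
#' then lexicographically (singletons ascending, then pairs, ..., up to
#' the full set).
#'
#' @param M number of channels.
#' @return A list of scenarios, each a list with integer fields `causes`
#'   (sorted, 1-based) and `effect`.
#' @examples
#' length(enumerate_scenarios(3))  # 21
#' @export
enumerate_scenarios <- function(M) {
  M <- check_count(M, "M")
  subsets <- ordered_subsets(M)
  out <- vector("list", (2^M - 1) * M)
  k <- 0L
  for (effect in seq_len(M)) {
    for (s in subsets) {
      k <- k + 1L
      out[[k]] <- list(causes = s, effect = effect)
    }
  }
  out
}

## Non-empty subsets of 1..M ordered by size then lexicographically.
ordered_subsets <- function(M) {
  out <- list()
  for (size in seq_len(M)) {
    cols <- combn(M, size)
    out <- c(out, lapply(seq_len(ncol(cols)), function(j) cols[, j]))
  }
  out
}

scenario_label <- function(sc) {
  sprintf("{%s}->x%d", paste0("x", sc$causes, collapse = ","), sc$effect)
}

#' Reduce the scenario family to its pairwise or conditional-pairwise subset
#'
#' The reduced families mimic bivariate and conditional-bivariate Geweke
#' testing. For each effect `j`, mode `"pw"` keeps the self-scenario
#' `{j} -> j` plus the pairs `{i, j} -> j` for every `i != j`; mode
#' `"c-pw"` keeps the full-set scenario plus all leave-one-out scenarios
#' `(all \\ i) -> j` for every `i != j`. Both reduced families have `M^2`
#' scenarios (they coincide when `M = 2`); `"complete"` returns the input
#' unchanged.
#'
#' @param scenarios output of [enumerate_scenarios()].
#' @param mode `"complete"`, `"pw"` or `"c-pw"`.
#' @param M number of channels.
#' @return The ordered sub-family, in the canonical order inherited from
#'   the complete enumeration.
#' @export
reduce_scenarios <- function(scenarios, mode = c("complete", "pw", "c-pw"),
                             M) {
  mode <- match.arg(mode)
  M <- check_count(M, "M")
  if (mode == "complete") return(scenarios)
  keep <- vapply(scenarios, function(sc) {
    j <- sc$effect
    cs <- sc$causes
    if (mode == "pw") {
      # self-scenario {j} -> j, or a pair containing the effect
      identical(cs, j) || (length(cs) == 2L && j %in% cs)
    } else {
      # full set, or a leave-one-out set dropping a channel other than j
      missing_ch <- setdiff(seq_len(M), cs)
      length(missing_ch) == 0L ||
        (length(missing_ch) == 1L && missing_ch != j)
    }
  }, logical(1))
  scenarios[keep]
}

#' Build the lagged regression problem of a scenario
#'
#' For every admissible time point `t` in `{p, ..., N - 1}` (0-based), the
#' design row concatenates, cause by cause, the `p` previous samples
#' `[x_c(t - p), ..., x_c(t - 1)]`; the target is `x_effect(t)`. No value
#' at time `>= t` ever enters the row for `t`, so features computed from
#' the problem respect temporal precedence.
#'
#' @param X `N x M` numeric matrix (one trial).
#' @param scenario a scenario from [enumerate_scenarios()].
#' @param p lag order.
#' @return A list with `design` (`(N - p) x (p * |causes|)` matrix) and
#'   `target` (length `N - p` vector).
#' @export
build_lagged_problem <- function(X, scenario, p) {
  p <- check_count(p, "p")
  if (!is.matrix(X) || nrow(X) <= p) {
    stop_invalid("`X` must be a matrix with more than p rows")
  }
  L <- lag_matrix(X, p)
  cols <- lag_columns(scenario$causes, p)
  list(design = L[, cols, drop = FALSE],
       target = X[(p + 1):nrow(X), scenario$effect])
}

## Full lag matrix: column block for channel c holds
## [x_c(t-p), ..., x_c(t-1)] aligned with targets x(t), t = p..N-1.
lag_matrix <- function(X, p) {
  n <- nrow(X)
  M <- ncol(X)
  out <- matrix(0, n - p, M * p)
  for (ch in seq_len(M)) {
    em <- embed(X[, ch], p + 1)          # cols: x(t), x(t-1), ..., x(t-p)
    out[, (ch - 1) * p + seq_len(p)] <- em[, (p + 1):2, drop = FALSE]
  }
  out
}

lag_columns <- function(causes, p) {
  p <- as.integer(p)
  as.vector(vapply(as.integer(causes), function(ch) (ch - 1L) * p + seq_len(p),
                   integer(p)))
}

#' Ordinary least squares with intercept, rank tolerant
#'
#' Fits `target ~ 1 + design` by QR; on rank deficiency it falls back to
#' the minimum-norm solution via the pseudoinverse. Returns in-sample
#' scores: `mse` (mean squared residual), `r2` (coefficient of
#' determination, 0 by convention for a zero-variance target, flagged via
#' `zero_variance`) and `rv` (maximum-likelihood residual variance,
#' identical to `mse`; retained under its own name because it feeds the
#' Geweke log-variance ratios).
#'
#' @param problem list with `design` and `target`
#'   (see [build_lagged_problem()]).
#' @return List with `coefficients` (intercept first), `mse`, `r2`, `rv`,
#'   `rank`, `zero_variance`.
#' @export
fit_and_score <- function(problem) {
  ols_score(cbind(1, problem$design), problem$target)
}

## Core OLS on an explicit design (first column typically the intercept).
ols_score <- function(Z, y) {
  n <- length(y)
  if (!is.matrix(Z) || nrow(Z) != n || n < 1L) {
    stop_invalid("design and target are inconsistent")
  }
  fit <- .lm.fit(Z, y)
  if (fit$rank < ncol(Z)) {
    # minimum-norm solution via SVD pseudoinverse
    s <- svd(Z)
    tol <- max(dim(Z)) * .Machine$double.eps * s$d[1]
    pos <- s$d > tol
    coef <- s$v[, pos, drop = FALSE] %*%
      (crossprod(s$u[, pos, drop = FALSE], y) / s$d[pos])
    res <- y - Z %*% coef
    coef <- drop(coef)
    rank <- sum(pos)
  } else {
    coef <- numeric(ncol(Z))
    coef[fit$pivot] <- fit$coefficients
    res <- fit$residuals
    rank <- fit$rank
  }
  sse <- sum(res^2)
  sst <- sum((y - mean(y))^2)
  zero_var <- sst <= 0
  r2 <- if (zero_var) 0 else 1 - sse / sst
  mse <- sse / n
  list(coefficients = coef, mse = mse, r2 = r2, rv = mse, rank = rank,
       zero_variance = zero_var)
}
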