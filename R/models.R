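## Supervised causal-graph predictors: cell-based classification (CBC,
## one l2-regularized binary logistic model per off-diagonal graph cell)
## and matrix-based classification (MBC, one multinomial model over all
## 2^(M(M-1)) graph indices). Both consume the identical feature matrix.
##
## Both model families are fitted in-package by direct penalized maximum
## likelihood (L-BFGS with analytic gradients; stable log1p-exp /
## log-softmax losses). At the small ridge penalties used here,
## coordinate-descent fits are not numerically reliable on these heavily
## collinear engineered features (diverging multinomial deviance; stalls
## on separable binomial problems), whereas the direct optimizer with a
## fixed iteration budget is deterministic and has bounded cost. The
## tests cross-check the core against an independent coordinate-descent
## fit on well-conditioned data. Models are stored as plain coefficient
## arrays.

## Training-set standardizer; zero-variance columns get scale 1.
fit_standardizer <- function(X) {
  center <- colMeans(X)
  scale <- apply(X, 2, sd)
  scale[!is.finite(scale) | scale <= 0] <- 1
  list(center = center, scale = scale)
}

apply_standardizer <- function(std, X) {
  sweep(sweep(X, 2, std$center, "-"), 2, std$scale, "/")
}

## reg_strength is the conventional inverse-regularization parameter C;
## the ridge objective is mean(-loglik) + lambda/2 * ||B||^2 with
## lambda = 1 / (C * n_train).
reg_lambda <- function(reg_strength, n) {
  if (!is.numeric(reg_strength) || length(reg_strength) != 1L ||
      !is.finite(reg_strength) || reg_strength <= 0) {
    stop_invalid("`reg_strength` must be a single positive number")
  }
  1 / (reg_strength * n)
}

check_features <- function(features) {
  if (!inherits(features, "trial_features")) {
    stop_invalid("`features` must be a `trial_features` object (see featurize_dataset)")
  }
  invisible(features)
}

check_feature_layout <- function(model, features) {
  check_features(features)
  if (!identical(colnames(features$X), model$feature_names)) {
    stop_invalid("feature layout does not match the one the model was trained on")
  }
  invisible(features)
}

## Multinomial ridge logistic regression by direct penalized ML.
## X: n x d (standardized), Y: n x K class indicator. Intercepts are
## unpenalized. Returns list(a0 = K intercepts, beta = d x K matrix).
ridge_multinomial <- function(X, Y, lambda, maxit = 500L, factr = 1e7) {
  n <- nrow(X)
  d <- ncol(X)
  K <- ncol(Y)
  obj <- function(par) {
    a0 <- par[seq_len(K)]
    B <- matrix(par[-seq_len(K)], d, K)
    lin <- sweep(X %*% B, 2, a0, "+")
    m <- apply(lin, 1, max)
    lse <- m + log(rowSums(exp(lin - m)))
    -(sum(lin * Y) - sum(lse)) / n + lambda / 2 * sum(B^2)
  }
  grad <- function(par) {
    a0 <- par[seq_len(K)]
    B <- matrix(par[-seq_len(K)], d, K)
    lin <- sweep(X %*% B, 2, a0, "+")
    P <- exp(lin - apply(lin, 1, max))
    P <- P / rowSums(P)
    D <- P - Y
    c(colSums(D) / n, as.vector(crossprod(X, D) / n + lambda * B))
  }
  o <- stats::optim(numeric(K + d * K), obj, grad, method = "L-BFGS-B",
                    control = list(maxit = maxit, factr = factr))
  list(a0 = o$par[seq_len(K)],
       beta = matrix(o$par[-seq_len(K)], d, K),
       value = o$value, convergence = o$convergence)
}

softmax_rows <- function(lin) {
  P <- exp(lin - apply(lin, 1, max))
  P / rowSums(P)
}

## Binomial ridge logistic regression, same objective as the multinomial
## core with K = 2 but cheaper: one linear score per trial.
ridge_binomial <- function(X, y, lambda, maxit = 300L, factr = 1e7) {
  n <- nrow(X)
  d <- ncol(X)
  obj <- function(par) {
    lin <- drop(X %*% par[-1]) + par[1]
    # log(1 + exp(lin)) - y * lin, evaluated stably for large |lin|
    nll <- sum(pmax(lin, 0) - y * lin + log1p(exp(-abs(lin))))
    nll / n + lambda / 2 * sum(par[-1]^2)
  }
  grad <- function(par) {
    lin <- drop(X %*% par[-1]) + par[1]
    d1 <- stats::plogis(lin) - y
    c(sum(d1) / n, drop(crossprod(X, d1)) / n + lambda * par[-1])
  }
  o <- stats::optim(numeric(1 + d), obj, grad, method = "L-BFGS-B",
                    control = list(maxit = maxit, factr = factr))
  list(a0 = o$par[1], beta = o$par[-1], value = o$value,
       convergence = o$convergence)
}

#' Train the cell-based classifier (CBC)
#'
#' Fits one l2-regularized binary logistic regression per off-diagonal
#' cell of the causal graph; the target of cell `(i, j)` is that entry of
#' each trial's label graph. Features are standardized with statistics of
#' the training data only. A cell whose training labels are single-class
#' is replaced by a constant-probability predictor (with a warning).
#'
#' @param features labeled `trial_features` (see [featurize_dataset()]).
#' @param reg_strength inverse regularization strength C (> 0); the ridge
#'   penalty weight is `1 / (C * n_train)`.
#' @param seed stored for provenance; the fit itself is deterministic.
#' @return A `trained_cbc` object.
#' @export
train_cbc <- function(features, reg_strength = 1, seed = 1L) {
  check_features(features)
  if (anyNA(features$graph_index)) stop_invalid("training features must be labeled")
  X <- features$X
  std <- fit_standardizer(X)
  Xs <- apply_standardizer(std, X)
  bits <- graph_bits(features$graph_index, features$M)
  lam <- reg_lambda(reg_strength, nrow(Xs))
  models <- vector("list", ncol(bits))
  names(models) <- colnames(bits)
  for (k in seq_len(ncol(bits))) {
    y <- bits[, k]
    if (length(unique(y)) < 2L) {
      warning(sprintf("cell %s has a single training class; using a constant predictor",
                      colnames(bits)[k]))
      models[[k]] <- list(constant = mean(y))
    } else {
      fit <- ridge_binomial(Xs, y, lam)
      models[[k]] <- list(a0 = fit$a0, beta = fit$beta)
    }
  }
  structure(
    list(models = models, standardizer = std,
         feature_names = colnames(X), M = features$M,
         config = list(method = "cbc", reg_strength = reg_strength,
                       mode = features$mode,
                       engineered = features$engineered, seed = seed)),
    class = "trained_cbc")
}

#' Train the matrix-based classifier (MBC)
#'
#' Fits one multinomial l2-regularized logistic regression whose classes
#' are the `2^(M(M-1))` graph indices, by direct penalized maximum
#' likelihood. Classes absent from the training data are kept in the
#' class map with zero posterior (a warning is emitted).
#'
#' @inheritParams train_cbc
#' @return A `trained_mbc` object.
#' @export
train_mbc <- function(features, reg_strength = 1, seed = 1L) {
  check_features(features)
  if (anyNA(features$graph_index)) stop_invalid("training features must be labeled")
  X <- features$X
  std <- fit_standardizer(X)
  Xs <- apply_standardizer(std, X)
  gi <- features$graph_index
  present <- sort(unique(gi))
  if (length(present) < 2L) {
    stop_invalid("MBC needs at least two distinct graph classes in training data")
  }
  if (length(present) < n_graphs(features$M)) {
    warning(sprintf("%d of %d graph classes absent from training data; they get zero posterior",
                    n_graphs(features$M) - length(present), n_graphs(features$M)))
  }
  Y <- 1 * outer(gi, present, "==")
  fit <- ridge_multinomial(Xs, Y, reg_lambda(reg_strength, nrow(Xs)))
  structure(
    list(a0 = fit$a0, beta = fit$beta, classes = present,
         standardizer = std, feature_names = colnames(X), M = features$M,
         config = list(method = "mbc", reg_strength = reg_strength,
                       mode = features$mode,
                       engineered = features$engineered, seed = seed)),
    class = "trained_mbc")
}

#' Per-cell causal scores from a trained model
#'
#' For CBC, the score of cell `(i, j)` is that cell model's posterior
#' probability of class 1. For MBC, all cells are predicted jointly: the
#' score of cell `(i, j)` is the marginal cell posterior, i.e. the sum of
#' class posteriors of every graph whose entry `(i, j)` is 1. Both yield
#' scores in `[0, 1]` on which a classification threshold can be swept.
#'
#' @param model a `trained_cbc` or `trained_mbc`.
#' @param features `trial_features` with the same feature layout as the
#'   training data.
#' @return A numeric matrix, trials x off-diagonal cells (canonical cell
#'   order of [off_diag_cells()]).
#' @export
predict_cell_scores <- function(model, features) {
  UseMethod("predict_cell_scores")
}

#' @export
predict_cell_scores.trained_cbc <- function(model, features) {
  check_feature_layout(model, features)
  Xs <- apply_standardizer(model$standardizer, features$X)
  out <- matrix(NA_real_, nrow(Xs), length(model$models),
                dimnames = list(NULL, names(model$models)))
  for (k in seq_along(model$models)) {
    mk <- model$models[[k]]
    out[, k] <- if (!is.null(mk$constant)) {
      rep(mk$constant, nrow(Xs))
    } else {
      stats::plogis(drop(Xs %*% mk$beta) + mk$a0)
    }
  }
  out
}

#' @export
predict_cell_scores.trained_mbc <- function(model, features) {
  post <- predict_class_posteriors(model, features)
  bits <- graph_bits(model$classes, model$M)
  scores <- post %*% bits
  colnames(scores) <- cell_names(model$M)
  scores
}

#' Class posteriors of the matrix-based classifier
#'
#' @param model a `trained_mbc`.
#' @inheritParams predict_cell_scores
#' @return A matrix, trials x training classes, of softmax posteriors
#'   (rows sum to 1); column names are the graph indices.
#' @export
predict_class_posteriors <- function(model, features) {
  check_feature_layout(model, features)
  Xs <- apply_standardizer(model$standardizer, features$X)
  lin <- sweep(Xs %*% model$beta, 2, model$a0, "+")
  post <- softmax_rows(lin)
  colnames(post) <- model$classes
  post
}

#' Threshold cell scores into a predicted causal graph
#'
#' Sets off-diagonal entry `(i, j)` to 1 iff its cell score exceeds the
#' threshold; the diagonal is fixed to 1 by convention. The default 0.75
#' is the utility-indifference point of a cost model rewarding true
#' positives (+1) and penalizing false positives (-3): predict 1 iff
#' `p * 1 > (1 - p) * 3`.
#'
#' @param model a trained CBC or MBC model.
#' @param features `trial_features` for the trials to predict.
#' @param threshold decision threshold in `[0, 1]`.
#' @return A list of binary `M x M` matrices, one per trial.
#' @export
predict_graph <- function(model, features, threshold = 0.75) {
  threshold <- check_prob(threshold, "threshold")
  scores <- predict_cell_scores(model, features)
  cells <- off_diag_cells(model$M)
  lapply(seq_len(nrow(scores)), function(t) {
    A <- diag(1, model$M)
    A[cells] <- as.numeric(scores[t, ] > threshold)
    A
  })
}

#' @exportS3Method base::print
print.trained_cbc <- function(x, ...) {
  cat(sprintf("CBC model: %d cell classifiers, %d features (mode = %s, C = %g)\n",
              length(x$models), length(x$feature_names), x$config$mode,
              x$config$reg_strength))
  invisible(x)
}

#' @exportS3Method base::print
print.trained_mbc <- function(x, ...) {
  cat(sprintf("MBC model: %d classes, %d features (mode = %s, C = %g)\n",
              length(x$classes), length(x$feature_names), x$config$mode,
              x$config$reg_strength))
  invisible(x)
}

#' Serialize / restore a trained model as JSON
#'
#' Stores the coefficient arrays, standardizer, feature names and
#' configuration in a single version-stamped JSON file, so trained models
#' can be archived and reloaded without any binary format.
#'
#' @param model a `trained_cbc` or `trained_mbc`.
#' @param path JSON file path.
#' @return `write_model()` returns `path` invisibly; `read_model()` the
#'   restored model.
#' @export
write_model <- function(model, path) {
  stopifnot(inherits(model, c("trained_cbc", "trained_mbc")))
  payload <- unclass(model)
  payload$container_version <- 1L
  payload$class <- class(model)
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_model
#' @export
read_model <- function(path) {
  payload <- jsonlite::read_json(path, simplifyVector = TRUE)
  cls <- payload$class
  payload$class <- NULL
  payload$container_version <- NULL
  if (identical(cls, "trained_mbc")) {
    payload$beta <- matrix(payload$beta, ncol = length(payload$classes))
  } else {
    payload$models <- lapply(payload$models, as.list)
  }
  payload$standardizer <- as.list(payload$standardizer)
  payload$config <- as.list(payload$config)
  structure(payload, class = cls)
}
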