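#' Off-diagonal cells of an M x M causal graph in canonical order
#'
#' The `M(M-1)` off-diagonal entries of a causal configuration matrix are
#' the free parameters of a causal graph. Their canonical order is
#' row-major: cell k runs over `(1,2), (1,3), ..., (2,1), (2,3), ...`.
#' This order defines both the bit order of [graph_to_index()] (least
#' significant bit first) and the column order of every per-cell score
#' matrix in the package.
#'
#' @param M number of channels.
#' @return A two-column integer matrix with columns `from` and `to`, one
#'   row per off-diagonal cell.
#' @examples
#' off_diag_cells(3)
#' @export
off_diag_cells <- function(M) {
  M <- check_count(M, "M")
  from <- rep(seq_len(M), each = M)
  to <- rep(seq_len(M), times = M)
  keep <- from != to
  cbind(from = from[keep], to = to[keep])
}

n_graphs <- function(M) 2^(M * (M - 1))

#' Convert between causal graphs and integer indices
#'
#' A causal configuration matrix is a binary `M x M` matrix whose entry
#' `(i, j)` declares a lagged influence of channel `i` on channel `j`;
#' the diagonal is fixed to 1 (every channel has its own autoregressive
#' dynamics). The `M(M-1)` off-diagonal entries, read in the canonical
#' order of [off_diag_cells()] with the least significant bit first, map
#' each graph bijectively onto an index in `[0, 2^(M(M-1)) - 1]`. The
#' index is the class label used by matrix-based classification.
#'
#' @param graph binary `M x M` matrix.
#' @param index integer in `[0, 2^(M(M-1)) - 1]`.
#' @param M number of channels.
#' @return `graph_to_index()` returns the integer index; `index_to_graph()`
#'   returns the binary matrix (diagonal 1).
#' @examples
#' index_to_graph(0, 3)              # empty off-diagonal
#' graph_to_index(index_to_graph(37, 3))
#' @export
graph_to_index <- function(graph) {
  check_graph(graph)
  M <- nrow(graph)
  cells <- off_diag_cells(M)
  bits <- graph[cells]
  idx <- sum(bits * 2^(seq_along(bits) - 1))
  if (idx <= .Machine$integer.max) as.integer(idx) else idx
}

#' @rdname graph_to_index
#' @export
index_to_graph <- function(index, M) {
  M <- check_count(M, "M")
  if (!is.numeric(index) || length(index) != 1L || !is.finite(index) ||
      index != round(index) || index < 0 || index >= n_graphs(M)) {
    stop_invalid(sprintf("`index` must be an integer in [0, %d]",
                         n_graphs(M) - 1))
  }
  cells <- off_diag_cells(M)
  k <- nrow(cells)
  bits <- (index %/% 2^(seq_len(k) - 1)) %% 2
  A <- diag(1, M)
  A[cells] <- bits
  A
}

check_graph <- function(graph) {
  if (!is.matrix(graph) || nrow(graph) != ncol(graph) ||
      !all(graph %in% c(0, 1))) {
    stop_invalid("`graph` must be a square binary (0/1) matrix")
  }
  invisible(graph)
}

#' Enumerate all causal configuration matrices for M channels
#'
#' Returns the `2^(M(M-1))` binary causal graphs in index order
#' (see [graph_to_index()]). A balanced labeled training set contains the
#' same number of simulated trials for every graph in this enumeration.
#'
#' @param M number of channels. The count grows as `2^(M(M-1))`
#'   (64 for M = 3, 4096 for M = 4), so full enumeration is only practical
#'   for small M.
#' @return A list of binary `M x M` matrices, element `k` having index
#'   `k - 1`.
#' @examples
#' length(enumerate_graphs(3))  # 64
#' @export
enumerate_graphs <- function(M) {
  M <- check_count(M, "M")
  if (M * (M - 1) > 24) {
    stop_invalid("enumeration of 2^(M(M-1)) graphs is infeasible for this M")
  }
  lapply(seq_len(n_graphs(M)) - 1, index_to_graph, M = M)
}

## Bits of each graph index as a matrix: rows = indices, cols = cells.
graph_bits <- function(index, M) {
  k <- M * (M - 1)
  out <- outer(index, 2^(seq_len(k) - 1), function(i, b) (i %/% b) %% 2)
  colnames(out) <- cell_names(M)
  out
}

cell_names <- function(M) {
  cells <- off_diag_cells(M)
  sprintf("x%d->x%d", cells[, 1], cells[, 2])
}
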