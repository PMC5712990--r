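## Plain-text dataset and feature containers: a directory holding a JSON
## manifest plus tab-delimited numeric files, chosen for inspectability
## and language neutrality.

fmt_num_rows <- function(X) {
  apply(X, 1, function(r) paste(sprintf("%.17g", r), collapse = "\t"))
}

#' Write / read a labeled dataset container
#'
#' The container is one directory per dataset: `manifest.json` records
#' `M`, `p`, `N`, `noise_mode`, `seed` and per-trial entries
#' `{trial_id, graph_index, gamma, file}`; each trial is an `N`-row,
#' `M`-column tab-separated text file without header, written at full
#' double precision so the round-trip is lossless. Trials without a
#' ground-truth label carry `graph_index = null` and load back as `NA`.
#'
#' @param dataset a `mar_dataset`.
#' @param path container directory (created if missing).
#' @return `write_dataset()` returns `path` invisibly; `read_dataset()`
#'   returns the `mar_dataset`.
#' @export
write_dataset <- function(dataset, path) {
  dir.create(path, showWarnings = FALSE, recursive = TRUE)
  n <- length(dataset$trials)
  files <- sprintf("trial_%06d.tsv", seq_len(n))
  records <- lapply(seq_len(n), function(k) {
    tr <- dataset$trials[[k]]
    writeLines(fmt_num_rows(tr$X), file.path(path, files[k]))
    rec <- list(trial_id = k, gamma = tr$gamma, file = files[k])
    gi <- tr$graph_index
    if (!is.null(gi) && length(gi) == 1 && !is.na(gi)) rec$graph_index <- gi
    if (!is.null(tr$seed)) rec$seed <- tr$seed
    rec
  })
  manifest <- list(
    M = dataset$M, p = dataset$p, N = dataset$N,
    trials_per_graph = dataset$trials_per_graph,
    noise_mode = dataset$noise_mode, seed = dataset$seed,
    burn_in = dataset$burn_in, trials = records)
  jsonlite::write_json(manifest, file.path(path, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' @rdname write_dataset
#' @export
read_dataset <- function(path) {
  mf_path <- file.path(path, "manifest.json")
  if (!file.exists(mf_path)) stop_invalid("no manifest.json in container")
  mf <- jsonlite::read_json(mf_path)
  M <- check_count(mf$M, "M")
  N <- check_count(mf$N, "N")
  trials <- lapply(mf$trials, function(rec) {
    f <- file.path(path, rec$file)
    if (!file.exists(f)) stop_invalid(sprintf("missing trial file %s", rec$file))
    vals <- scan(f, sep = "\t", quiet = TRUE)
    if (length(vals) != N * M) {
      stop_invalid(sprintf(
        "trial %s: expected %d x %d values, found %d", rec$file, N, M,
        length(vals)))
    }
    gi <- rec$graph_index
    gi <- if (is.null(gi) || length(gi) != 1) NA_real_ else as.numeric(gi)
    if (!is.na(gi) && (gi < 0 || gi >= n_graphs(M))) {
      stop_invalid(sprintf("trial %s: graph index %g out of range", rec$file, gi))
    }
    list(X = matrix(vals, nrow = N, ncol = M, byrow = TRUE),
         graph_index = gi, gamma = rec$gamma,
         seed = if (is.null(rec$seed)) NA_integer_ else rec$seed)
  })
  structure(
    list(trials = trials, M = M, p = mf$p, N = N,
         trials_per_graph = mf$trials_per_graph,
         noise_mode = mf$noise_mode, seed = mf$seed, burn_in = mf$burn_in),
    class = "mar_dataset")
}

#' Write / read a feature container
#'
#' A tab-delimited matrix with a header row of stable feature names,
#' next to a JSON sidecar recording the feature configuration
#' (`mode`, `engineered`, `p`, `M`) and the per-trial labels.
#'
#' @param features a `trial_features` object.
#' @param path container directory.
#' @return `write_features()` returns `path` invisibly; `read_features()`
#'   the `trial_features`.
#' @export
write_features <- function(features, path) {
  check_features(features)
  dir.create(path, showWarnings = FALSE, recursive = TRUE)
  con <- file.path(path, "features.tsv")
  writeLines(c(paste(colnames(features$X), collapse = "\t"),
               fmt_num_rows(features$X)), con)
  jsonlite::write_json(
    list(M = features$M, p = features$p, mode = features$mode,
         engineered = features$engineered,
         graph_index = features$graph_index),
    file.path(path, "features.json"), auto_unbox = TRUE, digits = NA,
    pretty = TRUE, na = "null")
  invisible(path)
}

#' @rdname write_features
#' @export
read_features <- function(path) {
  side <- jsonlite::read_json(file.path(path, "features.json"),
                              simplifyVector = TRUE)
  lines <- readLines(file.path(path, "features.tsv"))
  nms <- strsplit(lines[1], "\t", fixed = TRUE)[[1]]
  vals <- strsplit(lines[-1], "\t", fixed = TRUE)
  X <- do.call(rbind, lapply(vals, as.numeric))
  colnames(X) <- nms
  gi <- as.numeric(side$graph_index)
  if (length(gi) != nrow(X)) {
    stop_invalid("feature sidecar labels do not match the matrix rows")
  }
  structure(
    list(X = X, graph_index = gi, M = side$M, p = side$p, mode = side$mode,
         engineered = side$engineered),
    class = "trial_features")
}
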