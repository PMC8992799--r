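#' Euclidean representational dissimilarity matrix
#'
#' @param patterns A condition-by-unit numeric matrix (>= 2 rows).
#' @param labels Optional tibble of condition labels (one row per condition).
#' @return An object of class \code{"rdm"}: a list with \code{matrix}
#'   (symmetric, zero diagonal), \code{labels} and \code{metric}.
#' @examples
#' euclidean_rdm(rbind(c(0, 0), c(3, 4)))$matrix[1, 2] # 5
#' @export
euclidean_rdm <- function(patterns, labels = NULL) {
  patterns <- as.matrix(patterns)
  if (nrow(patterns) < 2) abort("need at least two conditions")
  if (!all(is.finite(patterns))) abort("`patterns` contains non-finite values")
  m <- as.matrix(dist(patterns, method = "euclidean"))
  dimnames(m) <- NULL
  structure(list(matrix = m, labels = labels, metric = "euclidean"),
            class = "rdm")
}

#' @export
print.rdm <- function(x, ...) {
  cat(sprintf("<rdm> %d x %d, metric = %s\n", nrow(x$matrix), ncol(x$matrix), x$metric))
  invisible(x)
}

#' Cross-validated Pearson-distance RDM over runs
#'
#' Builds the (n_runs * n_conditions) square RDM whose entry for condition i
#' in run r and condition j in run s is one minus the Pearson correlation of
#' the two mean-centred patterns. Within-run blocks (r = s) are set to
#' \code{NA} and are dropped from all downstream fits; constant (zero
#' variance) patterns also produce \code{NA} with a warning.
#'
#' @param patterns Run-by-condition-by-unit array, or a list of
#'   condition-by-unit matrices (one per run), or a \code{"pattern_set"}.
#' @param labels Optional tibble of per-condition labels (recycled over runs).
#' @return An object of class \code{"rdm"} with \code{metric =
#'   "crossval_pearson"}, plus \code{run} and \code{condition} index vectors.
#' @export
crossval_pearson_rdm <- function(patterns, labels = NULL) {
  if (inherits(patterns, "pattern_set")) {
    labels <- labels %||% patterns$condition_labels
    patterns <- patterns$patterns
  }
  runs <- if (is.array(patterns) && length(dim(patterns)) == 3) {
    lapply(seq_len(dim(patterns)[1]), function(r) patterns[r, , ])
  } else if (is.list(patterns)) {
    patterns
  } else {
    abort("`patterns` must be a 3-d array, list of matrices, or pattern_set")
  }
  if (length(runs) < 2) abort("need at least two runs")
  n_cond <- nrow(runs[[1]])
  centred <- lapply(runs, function(m) {
    m <- as.matrix(m)
    if (nrow(m) != n_cond) abort("all runs must contain the same conditions")
    sweep(m, 1, rowMeans(m))
  })
  stacked <- do.call(rbind, centred)
  norms <- sqrt(rowSums(stacked^2))
  if (any(norms == 0)) {
    warn("constant patterns found; their dissimilarities are set to NA")
  }
  cors <- tcrossprod(stacked / ifelse(norms == 0, NA, norms))
  m <- 1 - cors
  run_idx <- rep(seq_along(runs), each = n_cond)
  within <- outer(run_idx, run_idx, "==")
  m[within] <- NA
  structure(
    list(matrix = m, labels = labels, metric = "crossval_pearson",
         run = run_idx, condition = rep(seq_len(n_cond), length(runs))),
    class = "rdm"
  )
}
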