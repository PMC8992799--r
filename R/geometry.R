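#' Singular-value spectrum and embedding dimensionality
#'
#' Applies SVD to a condition-by-unit activity matrix and reports the
#' cumulative variance explained by the leading components (from the squared
#' singular values), together with the number of components needed to reach
#' each requested variance threshold. By default the matrix is not centred
#' (the raw stimulus-by-unit response matrix is decomposed); column
#' centring is available via \code{center}.
#'
#' @param patterns Condition-by-unit numeric matrix.
#' @param center Centre columns before the SVD? Default \code{FALSE}.
#' @param thresholds Variance thresholds (default 0.95).
#' @return An object of class \code{"svd_spectrum"}: list with
#'   \code{singular_values}, \code{cumulative_variance},
#'   \code{n_for_threshold} (named integer vector).
#' @export
svd_spectrum <- function(patterns, center = FALSE, thresholds = 0.95) {
  patterns <- as.matrix(patterns)
  if (nrow(patterns) < 2) abort("need at least two conditions")
  if (!all(is.finite(patterns))) abort("`patterns` contains non-finite values")
  if (center) patterns <- scale(patterns, center = TRUE, scale = FALSE)
  d <- svd(patterns, nu = 0, nv = 0)$d
  cum <- cumsum(d^2) / sum(d^2)
  n_thr <- vapply(thresholds, function(t) {
    # tiny numerical slack so that exact-rank matrices report their rank
    as.integer(which(cum >= t - 1e-12)[1])
  }, integer(1))
  names(n_thr) <- paste0(thresholds * 100, "%")
  structure(list(singular_values = d, cumulative_variance = cum,
                 n_for_threshold = n_thr),
            class = "svd_spectrum")
}

#' @export
print.svd_spectrum <- function(x, ...) {
  cat("<svd_spectrum>", length(x$singular_values), "components;",
      paste(names(x$n_for_threshold), "at", x$n_for_threshold, collapse = ", "), "\n")
  invisible(x)
}

#' Readout accuracy after rank-k truncation of the hidden layer
#'
#' Reconstructs the 50-condition hidden activity matrix from its top
#' \code{k} singular triplets, passes the reconstruction through the trained
#' readout and scores sign accuracy against the targets.
#'
#' @param params Trained [init_mlp()] parameters.
#' @param grid A [make_condition_grid()] tibble.
#' @param k Number of singular components kept (1 to min(n conditions,
#'   n units)).
#' @return Sign accuracy, a fraction in [0, 1].
#' @export
truncated_readout_accuracy <- function(params, grid, k) {
  H <- forward(params, grid)$hidden
  kmax <- min(dim(H))
  if (k < 1 || k > kmax) abort("`k` out of range")
  s <- svd(H)
  idx <- seq_len(k)
  Hk <- s$u[, idx, drop = FALSE] %*% (s$d[idx] * t(s$v[, idx, drop = FALSE]))
  out <- drop(Hk %*% params$w_out) + params$b_out
  sign_accuracy(out, grid$target)
}

#' Minimal rank maintaining ceiling accuracy
#'
#' Smallest \code{k} for which [truncated_readout_accuracy()] stays within
#' \code{tol} of the untruncated accuracy. "Ceiling" is operationalised as a
#' 0.1-percentage-point tolerance by default.
#'
#' @inheritParams truncated_readout_accuracy
#' @param tol Accuracy tolerance (default 0.001 = 0.1 percentage points).
#' @return The minimal k (integer).
#' @export
min_rank_for_ceiling <- function(params, grid, tol = 0.001) {
  full <- sign_accuracy(forward(params, grid)$output, grid$target)
  kmax <- min(nrow(grid), length(params$w_out))
  for (k in seq_len(kmax)) {
    if (truncated_readout_accuracy(params, grid, k) >= full - tol) {
      return(k)
    }
  }
  kmax
}

binary_label <- function(levels) {
  mid <- mean(range(levels))
  out <- ifelse(levels > mid, "high", ifelse(levels < mid, "low", NA))
  out
}

#' Cross-task linear decoding
#'
#' Trains a linear maximum-margin classifier (SVM) on the binary high/low
#' label of one task's relevant dimension using that task's trials, and
#' evaluates on held-out folds both for the same task and for the same
#' dimension in the other task (where it is irrelevant). Patterns are
#' standardised and PCA-denoised (components up to \code{var_threshold}
#' cumulative variance) inside each training fold. For the 72-condition
#' pseudo-population design the two data halves form the folds; supplying
#' run labels switches to leave-one-run-out.
#'
#' @param trials Trial-by-unit matrix or a \code{"pseudo_population"}.
#' @param labels Tibble with columns \code{motion}, \code{color},
#'   \code{context}, and \code{half} (or \code{run}).
#' @param train_context Context whose relevant dimension the decoder is
#'   trained on (default "motion").
#' @param var_threshold PCA denoising threshold (default 0.95).
#' @param cost SVM regularisation constant (fixed at 1).
#' @param seed Integer seed (used only for label permutation via
#'   \code{shuffle}).
#' @param shuffle Permute training labels (chance calibration)?
#' @return A tibble of class \code{"decoding_report"} with columns
#'   \code{condition} ("same_task" / "other_task"), \code{accuracy}, and
#'   \code{chance} = 0.5.
#' @export
cross_task_decode <- function(trials, labels = NULL, train_context = "motion",
                              var_threshold = 0.95, cost = 1, seed = NULL,
                              shuffle = FALSE) {
  if (!requireNamespace("e1071", quietly = TRUE)) {
    abort("cross_task_decode requires the e1071 package")
  }
  if (inherits(trials, "pseudo_population")) {
    labels <- trials$trial_labels
    trials <- trials$trials
  }
  labels <- tibble::as_tibble(labels)
  fold_var <- if ("run" %in% names(labels)) "run" else "half"
  folds <- unique(labels[[fold_var]])
  if (length(folds) < 2) abort("need at least two folds")
  rel_dim <- if (train_context == "motion") "motion" else "color"
  other_context <- setdiff(unique(labels$context), train_context)
  lab <- binary_label(labels[[rel_dim]])
  res <- list()
  with_seed(seed, {
    for (f in folds) {
      tr <- labels[[fold_var]] != f & labels$context == train_context & !is.na(lab)
      if (length(unique(lab[tr])) < 2) abort("training fold contains a single class")
      mu <- colMeans(trials[tr, , drop = FALSE])
      sdv <- apply(trials[tr, , drop = FALSE], 2, sd)
      sdv[sdv == 0] <- 1
      std <- function(m) sweep(sweep(m, 2, mu), 2, sdv, "/")
      Xtr <- std(trials[tr, , drop = FALSE])
      pc <- svd(Xtr, nu = 0)
      cum <- cumsum(pc$d^2) / sum(pc$d^2)
      ncomp <- which(cum >= var_threshold - 1e-12)[1]
      proj <- pc$v[, seq_len(ncomp), drop = FALSE]
      ytr <- factor(lab[tr], levels = c("low", "high"))
      if (shuffle) ytr <- sample(ytr)
      fit <- e1071::svm(Xtr %*% proj, ytr, kernel = "linear", cost = cost,
                        scale = FALSE)
      for (ctx in c(train_context, other_context)) {
        te <- labels[[fold_var]] == f & labels$context == ctx & !is.na(lab)
        pred <- stats::predict(fit, std(trials[te, , drop = FALSE]) %*% proj)
        res[[length(res) + 1]] <- tibble::tibble(
          condition = if (ctx == train_context) "same_task" else "other_task",
          fold = f, accuracy = mean(pred == lab[te])
        )
      }
    }
  })
  out <- dplyr::summarise(dplyr::group_by(dplyr::bind_rows(res), .data$condition),
                          accuracy = mean(.data$accuracy), .groups = "drop")
  out$chance <- 0.5
  class(out) <- c("decoding_report", class(out))
  out
}
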