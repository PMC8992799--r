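as_rdm_matrix <- function(x) {
  if (inherits(x, "rdm")) x$matrix else as.matrix(x)
}

# tile a condition-level model RDM over runs to match a run-structured
# neural RDM (within-run blocks end up NA in the neural RDM and are dropped)
tile_model <- function(model_m, n_total) {
  n <- nrow(model_m)
  if (n_total == n) return(model_m)
  if (n_total %% n != 0) {
    abort("model RDM size does not divide the neural RDM size")
  }
  reps <- n_total / n
  kronecker(matrix(1, reps, reps), model_m)
}

#' Regress a neural RDM onto model RDMs
#'
#' Ordinary least squares of the z-scored vectorised lower triangle of the
#' neural RDM on the z-scored lower triangles of the model RDMs (plus an
#' intercept). Entries that are \code{NA} in the neural RDM (e.g. within-run
#' blocks of a cross-validated RDM) are dropped before z-scoring.
#' z-scoring uses the population (n) standard deviation. Condition-level
#' model RDMs are tiled over runs automatically when the neural RDM is
#' run-structured.
#'
#' @param neural An [euclidean_rdm()]/[crossval_pearson_rdm()] result or a
#'   square matrix.
#' @param models A named list of model RDMs (or matrices).
#' @return An object of class \code{"rdm_fit"}: list with \code{betas}
#'   (named numeric), \code{intercept}, \code{rss}, \code{r_squared},
#'   \code{n_pairs}.
#' @export
rdm_regression <- function(neural, models) {
  nm <- as_rdm_matrix(neural)
  if (is.null(names(models))) {
    names(models) <- paste0("model", seq_along(models))
  }
  y <- lower_tri_vec(nm)
  X <- vapply(models, function(m) {
    lower_tri_vec(tile_model(as_rdm_matrix(m), nrow(nm)))
  }, numeric(length(y)))
  keep <- is.finite(y)
  y <- y[keep]
  X <- X[keep, , drop = FALSE]
  qrX <- qr(cbind(1, scale_cols_pop(X)))
  if (qrX$rank < ncol(X) + 1) {
    bad <- names(models)[qrX$pivot[seq(qrX$rank + 1, ncol(X) + 1)] - 1]
    abort(paste0("model RDMs are collinear: ", paste(bad, collapse = ", ")))
  }
  yz <- zscore_pop(y)
  fit <- qr.coef(qrX, yz)
  res <- qr.resid(qrX, yz)
  structure(
    list(betas = stats::setNames(fit[-1], names(models)), intercept = fit[1],
         rss = sum(res^2), r_squared = 1 - sum(res^2) / sum((yz - mean(yz))^2),
         n_pairs = length(y)),
    class = "rdm_fit"
  )
}

scale_cols_pop <- function(X) {
  apply(X, 2, zscore_pop)
}

#' @export
print.rdm_fit <- function(x, ...) {
  cat("<rdm_fit>\n")
  print(round(x$betas, 4))
  cat(sprintf("  RSS %.4f over %d pairs\n", x$rss, x$n_pairs))
  invisible(x)
}

#' Permutation test for regression-based RSA on trial data
#'
#' Computes per-condition mean patterns from trial-wise data, fits the model
#' RDMs with [rdm_regression()], then builds a null distribution by randomly
#' permuting the trial labels and refitting. The p value for each model is
#' the proportion of permutations whose beta is at least as large as the
#' observed one (with the +1 small-sample correction, so p is never exactly
#' zero).
#'
#' @param trials Trial-by-unit matrix (or a \code{"pseudo_population"}).
#' @param labels Tibble of trial labels with columns \code{motion},
#'   \code{color}, \code{context} (ignored when \code{trials} is a
#'   pseudo-population).
#' @param models Named list of condition-level model RDMs matching the
#'   condition ordering of [condition_means()] (context, then motion, then
#'   color).
#' @param n_perm Number of permutations (>= 100).
#' @param seed Integer seed.
#' @return A tibble with columns \code{model}, \code{beta_observed},
#'   \code{p_value}.
#' @export
permutation_test_rsa <- function(trials, labels = NULL, models, n_perm = 1000,
                                 seed = NULL) {
  if (n_perm < 100) abort("`n_perm` must be at least 100")
  if (inherits(trials, "pseudo_population")) {
    labels <- trials$trial_labels
    trials <- trials$trials
  }
  pop <- structure(list(trials = trials,
                        trial_labels = tibble::as_tibble(labels)),
                   class = "pseudo_population")
  observed <- rdm_regression(euclidean_rdm(condition_means(pop)$means), models)$betas
  with_seed(seed, {
    exceed <- numeric(length(observed))
    for (i in seq_len(n_perm)) {
      idx <- sample.int(nrow(trials))
      perm <- structure(list(trials = trials[idx, , drop = FALSE],
                             trial_labels = pop$trial_labels),
                        class = "pseudo_population")
      b <- rdm_regression(euclidean_rdm(condition_means(perm)$means), models)$betas
      exceed <- exceed + (b >= observed)
    }
    tibble::tibble(model = names(observed), beta_observed = unname(observed),
                   p_value = unname((exceed + 1) / (n_perm + 1)))
  })
}
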