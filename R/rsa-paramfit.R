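param_to_vec <- function(g) {
  c(g$compr_rel_A, g$compr_irrel_A, g$compr_rel_B, g$compr_irrel_B,
    g$rotation, g$context_offset)
}

vec_to_param <- function(v) {
  v <- unname(v)
  param_geometry(v[1], v[2], v[3], v[4], v[5], v[6])
}

param_lower <- c(0, 0, 0, 0, -90, 0)
param_upper <- function(offset_max) c(1, 1, 1, 1, 90, offset_max)

#' Fit the six-parameter geometry model to a neural RDM
#'
#' Bounded least squares between the lower triangles of the neural RDM and
#' the RDM generated by [param_feature_matrix()], minimised with L-BFGS-B
#' from \code{n_restarts} random starting points drawn uniformly within the
#' parameter bounds from a seeded stream. Both the average of the per-start
#' optima (weighted interpretation of multi-start averaging) and the single
#' best start are returned; per-start optima are retained for inspection.
#'
#' The objective compares raw distances, so the neural RDM must live on the
#' unit-grid scale of the model family. For RDMs of arbitrary scale (e.g.
#' Euclidean RDMs of trained hidden layers), \code{normalize = "rms"}
#' rescales the neural RDM to the root-mean-square distance of the grid
#' model before fitting.
#'
#' @param neural An RDM (object or square matrix) on the full two-context
#'   factorial design, ordered context-major.
#' @param n_restarts Number of random restarts (default 1000, as in the
#'   reference procedure; smaller values are fine for well-conditioned
#'   problems).
#' @param seed Integer seed for the starting points.
#' @param normalize \code{"none"} (default) or \code{"rms"}.
#' @param offset_max Upper bound for the context-offset parameter.
#' @param relevant_A,b_levels,l_levels Passed to [param_feature_matrix()].
#' @return An object of class \code{"param_geometry_fit"}: list with
#'   \code{estimate} (average of per-start optima, a [param_geometry()]),
#'   \code{best} (lowest-cost start), \code{cost_best}, \code{starts}
#'   (tibble of per-start optima and costs) and \code{normalize}.
#' @export
fit_param_geometry <- function(neural, n_restarts = 1000, seed = NULL,
                               normalize = c("none", "rms"), offset_max = 10,
                               relevant_A = "b", b_levels = -2:2,
                               l_levels = -2:2) {
  normalize <- match.arg(normalize)
  nm <- as_rdm_matrix(neural)
  y <- lower_tri_vec(nm)
  keep <- is.finite(y)
  y <- y[keep]
  if (normalize == "rms") {
    grid_d <- lower_tri_vec(model_rdm("grid", relevant_A = relevant_A,
                                      b_levels = b_levels,
                                      l_levels = l_levels)$matrix)[keep]
    y <- y * sqrt(mean(grid_d^2)) / sqrt(mean(y^2))
  }
  objective <- function(v) {
    g <- vec_to_param(v)
    d <- lower_tri_vec(model_rdm(g, relevant_A = relevant_A,
                                 b_levels = b_levels,
                                 l_levels = l_levels)$matrix)[keep]
    sum((y - d)^2)
  }
  lo <- param_lower
  hi <- param_upper(offset_max)
  starts <- with_seed(seed, {
    matrix(runif(n_restarts * 6, rep(lo, each = n_restarts),
                 rep(hi, each = n_restarts)), n_restarts, 6)
  })
  fits <- vector("list", n_restarts)
  ok <- logical(n_restarts)
  for (i in seq_len(n_restarts)) {
    f <- tryCatch(
      optim(starts[i, ], objective, method = "L-BFGS-B", lower = lo, upper = hi),
      error = function(e) NULL
    )
    if (!is.null(f)) {
      fits[[i]] <- f
      ok[i] <- TRUE
    }
  }
  if (!any(ok)) abort("optimisation failed on every start")
  fits <- fits[ok]
  pars <- t(vapply(fits, `[[`, numeric(6), "par"))
  costs <- vapply(fits, `[[`, numeric(1), "value")
  colnames(pars) <- c("compr_rel_A", "compr_irrel_A", "compr_rel_B",
                      "compr_irrel_B", "rotation", "context_offset")
  starts_tbl <- tibble::as_tibble(pars)
  starts_tbl$cost <- costs
  structure(
    list(estimate = vec_to_param(colMeans(pars)),
         best = vec_to_param(pars[which.min(costs), ]),
         cost_best = min(costs),
         cost_mean = mean(costs),
         starts = starts_tbl,
         normalize = normalize),
    class = "param_geometry_fit"
  )
}

#' @export
print.param_geometry_fit <- function(x, ...) {
  cat("<param_geometry_fit> best-of-", nrow(x$starts), " starts, cost ",
      signif(x$cost_best, 4), "\n", sep = "")
  print(x$best)
  invisible(x)
}

#' Compression index of a fitted geometry
#'
#' Signed log-ratio of the irrelevant to the relevant compression, averaged
#' over the two contexts. Positive values mean the irrelevant feature
#' dimension is more compressed than the relevant one (the signature of the
#' rich regime); zero means equal compression. Compressions at zero are
#' clipped to \code{eps} with a warning, so the index is always finite.
#'
#' @param g A [param_geometry()] (or a fit, in which case the best-start
#'   parameters are used).
#' @param eps Clipping floor for zero compressions.
#' @return A single number.
#' @export
compression_index <- function(g, eps = 1e-6) {
  if (inherits(g, "param_geometry_fit")) g <- g$best
  v <- c(g$compr_irrel_A, g$compr_rel_A, g$compr_irrel_B, g$compr_rel_B)
  if (any(v < eps)) {
    warn("near-zero compressions clipped for the log-ratio")
    v <- pmax(v, eps)
  }
  (log(v[1] / v[2]) + log(v[3] / v[4])) / 2
}
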