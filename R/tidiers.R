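#' @importFrom generics tidy glance
#' @export
generics::tidy

#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Tidy an RDM regression fit
#'
#' @param x An [rdm_regression()] fit.
#' @param ... Unused.
#' @return A tibble with one row per model RDM (term, estimate).
#' @export
tidy.rdm_fit <- function(x, ...) {
  tibble::tibble(term = names(x$betas), estimate = unname(x$betas))
}

#' @rdname tidy.rdm_fit
#' @export
glance.rdm_fit <- function(x, ...) {
  tibble::tibble(r_squared = x$r_squared, rss = x$rss, n_pairs = x$n_pairs)
}

#' Tidy a parameterised-geometry fit
#'
#' @param x A [fit_param_geometry()] result.
#' @param ... Unused.
#' @return A tibble with one row per parameter and columns for the
#'   best-start and start-averaged estimates.
#' @export
tidy.param_geometry_fit <- function(x, ...) {
  nm <- c("compr_rel_A", "compr_irrel_A", "compr_rel_B", "compr_irrel_B",
          "rotation", "context_offset")
  tibble::tibble(
    term = nm,
    estimate = unlist(x$best[nm]),
    estimate_mean = unlist(x$estimate[nm])
  )
}

#' @rdname tidy.param_geometry_fit
#' @export
glance.param_geometry_fit <- function(x, ...) {
  tibble::tibble(cost_best = x$cost_best, cost_mean = x$cost_mean,
                 n_starts = nrow(x$starts), normalize = x$normalize)
}

#' Tidy a psychophysical fit
#'
#' @param x A [fit_psychophysics()] result.
#' @param ... Unused.
#' @return A tibble with one row per context.
#' @export
tidy.psycho_fit <- function(x, ...) {
  dplyr::bind_rows(purrr::imap(x$params, function(p, ctx) {
    tibble::tibble(context = ctx, angle = p$angle, offset = p$offset,
                   slope = p$slope, lapse = p$lapse,
                   angular_bias = x$angular_bias[[ctx]])
  }))
}

#' @rdname tidy.psycho_fit
#' @export
glance.psycho_fit <- function(x, ...) {
  tibble::tibble(mean_angular_bias = x$mean_angular_bias, cost = x$cost)
}

#' Tidy a unit classification
#'
#' @param x A [classify_units()] result.
#' @param ... Unused.
#' @return The per-class proportion tibble.
#' @export
tidy.unit_classes <- function(x, ...) {
  x$proportions
}

#' Tidy an SVD spectrum
#'
#' @param x A [svd_spectrum()] result.
#' @param ... Unused.
#' @return A tibble with component index, singular value and cumulative
#'   variance.
#' @export
tidy.svd_spectrum <- function(x, ...) {
  tibble::tibble(component = seq_along(x$singular_values),
                 singular_value = x$singular_values,
                 cumulative_variance = x$cumulative_variance)
}

#' Plot an RDM as a heat map
#'
#' @param object An [euclidean_rdm()] / [crossval_pearson_rdm()] result.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.rdm <- function(object, ...) {
  m <- object$matrix
  df <- tidyr::expand_grid(row = seq_len(nrow(m)), col = seq_len(ncol(m)))
  df$dissimilarity <- as.vector(t(m))
  ggplot2::ggplot(df, ggplot2::aes(.data$col, .data$row,
                                   fill = .data$dissimilarity)) +
    ggplot2::geom_raster() +
    ggplot2::scale_y_reverse() +
    ggplot2::coord_fixed() +
    ggplot2::labs(x = NULL, y = NULL,
                  title = paste0("RDM (", object$metric, ")")) +
    ggplot2::theme_minimal()
}

#' Plot a training trace
#'
#' @param object A [train()] trace.
#' @param ... Unused.
#' @return A ggplot object (loss and hidden-weight norm over iterations).
#' @export
autoplot.train_trace <- function(object, ...) {
  df <- tidyr::pivot_longer(
    object[, c("iteration", "loss", "norm_W_hidden")],
    -"iteration", names_to = "metric", values_to = "value"
  )
  ggplot2::ggplot(df, ggplot2::aes(.data$iteration, .data$value)) +
    ggplot2::geom_line() +
    ggplot2::facet_wrap(~metric, scales = "free_y", ncol = 1) +
    ggplot2::labs(x = "iteration", y = NULL) +
    ggplot2::theme_minimal()
}

#' Scree plot of a spectrum
#'
#' @param object A [svd_spectrum()] result.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.svd_spectrum <- function(object, ...) {
  df <- tidy.svd_spectrum(object)
  ggplot2::ggplot(df, ggplot2::aes(.data$component, .data$cumulative_variance)) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::geom_hline(yintercept = 0.95, linetype = "dashed") +
    ggplot2::labs(y = "cumulative explained variance") +
    ggplot2::theme_minimal()
}

#' Plot a gating-network trajectory
#'
#' @param object A [simulate_gating_rnn()] trajectory.
#' @param ... Unused.
#' @return A ggplot object of the four unit rates over time.
#' @export
autoplot.rnn_trajectory <- function(object, ...) {
  df <- tidyr::pivot_longer(object[, c("t", "h1", "h2", "h3", "h4")],
                            -"t", names_to = "unit", values_to = "rate")
  df$unit <- factor(df$unit, levels = paste0("h", 1:4),
                    labels = c("motion +", "motion -", "color +", "color -"))
  ggplot2::ggplot(df, ggplot2::aes(.data$t, .data$rate, colour = .data$unit)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "time", y = "rate") +
    ggplot2::theme_minimal()
}

#' Plot a choice matrix
#'
#' @param object A [choice_matrix()].
#' @param ... Unused.
#' @return A ggplot object: p(plant) per feature cell, one panel per context.
#' @export
autoplot.choice_matrix <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(.data$b, .data$l, fill = .data$p_plant)) +
    ggplot2::geom_raster() +
    ggplot2::facet_wrap(~context) +
    ggplot2::scale_fill_gradient2(midpoint = 0.5) +
    ggplot2::coord_fixed() +
    ggplot2::theme_minimal()
}
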