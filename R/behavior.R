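#' Psychophysical choice-model parameters
#'
#' The model categorises a stimulus (b, l) against a linear boundary through
#' the origin of the feature plane: the signed distance is
#' \code{d = cos(angle) * b + sin(angle) * l} (the angle parameterises the
#' boundary normal, in degrees), and the probability of responding "plant"
#' is \code{lapse / 2 + (1 - lapse) * logistic(slope * (d - offset))} — a
#' logistic choice function with an inflection offset and a symmetric lapse
#' floor/ceiling.
#'
#' @param angle Boundary-normal angle in degrees. The ground-truth boundary
#'   is 0 in context A (only b matters) and 90 in context B.
#' @param offset Decision bias: shift of the logistic inflection point.
#' @param slope Logistic slope (> 0).
#' @param lapse Lapse rate in [0, 1].
#' @return An object of class \code{"psycho_params"}.
#' @export
psycho_params <- function(angle = 0, offset = 0, slope = 1, lapse = 0) {
  if (lapse < 0 || lapse > 1) abort("`lapse` must lie in [0, 1]")
  if (slope <= 0) abort("`slope` must be positive")
  structure(list(angle = angle, offset = offset, slope = slope, lapse = lapse),
            class = "psycho_params")
}

#' @export
print.psycho_params <- function(x, ...) {
  cat(sprintf("<psycho_params> angle %.1f deg, offset %.3f, slope %.3f, lapse %.3f\n",
              x$angle, x$offset, x$slope, x$lapse))
  invisible(x)
}

ground_truth_angle <- function(context) {
  if (context == "A") 0 else 90
}

#' Choice probability of the psychophysical model
#'
#' @param params A [psycho_params()].
#' @param b,l Feature levels.
#' @param context "A" or "B" (unused by the probability itself, which is
#'   fully determined by \code{params}; kept for interface symmetry).
#' @return p(plant) in [0, 1].
#' @examples
#' choice_probability(psycho_params(lapse = 1), 2, 2, "A") # 0.5
#' @export
choice_probability <- function(params, b, l, context = "A") {
  th <- params$angle * pi / 180
  d <- cos(th) * b + sin(th) * l
  params$lapse / 2 +
    (1 - params$lapse) / (1 + exp(-params$slope * (d - params$offset)))
}

#' Empirical choice matrix from a choice set
#'
#' @param choices A [gen_synthetic_choices()] tibble (or any tibble with
#'   columns context, b, l, response).
#' @return A tibble of class \code{"choice_matrix"} with one row per design
#'   cell: \code{context}, \code{b}, \code{l}, \code{n_plant},
#'   \code{n_total}, \code{p_plant}.
#' @export
choice_matrix <- function(choices) {
  out <- dplyr::summarise(
    dplyr::group_by(choices, .data$context, .data$b, .data$l),
    n_plant = sum(.data$response == "plant"), n_total = dplyr::n(),
    .groups = "drop"
  )
  out$p_plant <- out$n_plant / out$n_total
  class(out) <- c("choice_matrix", class(out))
  out
}

# squared-error mismatch between empirical and predicted per-cell p(plant)
psycho_objective <- function(par, cells) {
  p <- choice_probability(
    structure(list(angle = par[1], offset = par[2], slope = par[3],
                   lapse = par[4]), class = "psycho_params"),
    cells$b, cells$l
  )
  sum((cells$p_plant - p)^2)
}

angular_difference <- function(a, b) {
  d <- abs(a - b) %% 360
  pmin(d, 360 - d)
}

#' Fit the psychophysical model to choices
#'
#' Per-context bounded least squares between the empirical and predicted
#' per-cell probabilities of responding "plant", minimised with multi-start
#' L-BFGS-B (starts drawn uniformly within the bounds from a seeded stream).
#' The angular bias is the absolute angular disparity between each fitted
#' boundary and the context's ground truth (0 degrees in context A, 90 in
#' context B).
#'
#' @param choices A choice set or [choice_matrix()].
#' @param n_starts Number of random restarts per context (default 20).
#' @param seed Integer seed.
#' @param slope_max,offset_max Bounds for slope and |offset|.
#' @return An object of class \code{"psycho_fit"}: list with \code{params}
#'   (named list of per-context [psycho_params()]), \code{angular_bias}
#'   (named per-context, degrees), \code{mean_angular_bias}, \code{cost}.
#' @export
fit_psychophysics <- function(choices, n_starts = 20, seed = NULL,
                              slope_max = 20, offset_max = 3) {
  cm <- if (inherits(choices, "choice_matrix")) choices else choice_matrix(choices)
  if (any(cm$n_total < 1)) abort("every design cell needs at least one trial")
  lo <- c(-180, -offset_max, 1e-3, 0)
  hi <- c(180, offset_max, slope_max, 1)
  seeds <- child_seeds(seed, 2)
  fit_ctx <- function(ctx, s) {
    cells <- cm[cm$context == ctx, ]
    if (length(unique(cells$p_plant)) == 1) {
      warn(paste0("context ", ctx, ": all-constant responses; boundary unidentifiable"))
    }
    starts <- with_seed(s, matrix(runif(n_starts * 4, rep(lo, each = n_starts),
                                        rep(hi, each = n_starts)), n_starts, 4))
    best <- NULL
    for (i in seq_len(n_starts)) {
      f <- tryCatch(
        optim(starts[i, ], psycho_objective, cells = cells,
              method = "L-BFGS-B", lower = lo, upper = hi),
        error = function(e) NULL
      )
      if (!is.null(f) && (is.null(best) || f$value < best$value)) best <- f
    }
    if (is.null(best)) abort("psychophysical fit failed on every start")
    best
  }
  fits <- list(A = fit_ctx("A", seeds[1]), B = fit_ctx("B", seeds[2]))
  params <- purrr::map(fits, function(f) {
    psycho_params(f$par[1], f$par[2], max(f$par[3], 1e-3), f$par[4])
  })
  bias <- purrr::imap_dbl(params, function(p, ctx) {
    angular_difference(p$angle, ground_truth_angle(ctx))
  })
  structure(
    list(params = params, angular_bias = bias,
         mean_angular_bias = mean(bias),
         cost = sum(purrr::map_dbl(fits, "value"))),
    class = "psycho_fit"
  )
}

#' @export
print.psycho_fit <- function(x, ...) {
  cat("<psycho_fit>\n")
  for (ctx in names(x$params)) {
    p <- x$params[[ctx]]
    cat(sprintf("  context %s: angle %.1f deg (bias %.1f), offset %.2f, slope %.2f, lapse %.3f\n",
                ctx, p$angle, x$angular_bias[[ctx]], p$offset, p$slope, p$lapse))
  }
  invisible(x)
}

#' Factorised versus linear fit of a choice matrix
#'
#' Builds a behavioral RDM from the per-cell probabilities of responding
#' "plant" (absolute differences across the full two-context design) and
#' regresses it on two model RDMs: the \emph{factorised} model, in which
#' choices follow the ground-truth context-specific boundaries, and the
#' \emph{linear} model, in which a single diagonal boundary is applied in
#' both contexts. The factorised beta is the \emph{axis-alignment score}.
#'
#' @param cm A [choice_matrix()] (or choice set).
#' @return A list of class \code{"behavior_geometry_fit"} with
#'   \code{axis_alignment} (factorised beta), \code{linear_beta}, and the
#'   underlying [rdm_regression()] \code{fit}.
#' @export
fit_factorised_linear <- function(cm) {
  if (!inherits(cm, "choice_matrix")) cm <- choice_matrix(cm)
  cm <- dplyr::arrange(cm, .data$context, .data$b, .data$l)
  if (sd(cm$p_plant) == 0) abort("constant choice matrix cannot be fit")
  mag_rdm <- function(v) abs(outer(v, v, "-"))
  rel <- ifelse(cm$context == "A", cm$b, cm$l)
  lin <- cm$b + cm$l
  fit <- rdm_regression(mag_rdm(cm$p_plant),
                        list(factorised = mag_rdm(rel), linear = mag_rdm(lin)))
  structure(
    list(axis_alignment = unname(fit$betas["factorised"]),
         linear_beta = unname(fit$betas["linear"]), fit = fit),
    class = "behavior_geometry_fit"
  )
}

#' @export
print.behavior_geometry_fit <- function(x, ...) {
  cat(sprintf("<behavior_geometry_fit> axis alignment %.3f, linear beta %.3f\n",
              x$axis_alignment, x$linear_beta))
  invisible(x)
}

#' Accuracy of the context-blind diagonal strategy
#'
#' Enumerates the full 2 x 5 x 5 design, takes the diagonal score
#' \code{b + l} as the context-blind prediction, and scores a condition
#' correct when the prediction's sign equals the sign of the
#' context-relevant feature (a zero score, on anti-diagonal stimuli, never
#' counts as correct). Conditions whose relevant feature is zero (undefined
#' correct answer) are excluded from the denominator, leaving 40 scored
#' conditions of which the diagonal rule gets 28 right.
#'
#' @return The fraction correct (exactly 0.70).
#' @examples
#' diagonal_strategy_accuracy()
#' @export
diagonal_strategy_accuracy <- function() {
  des <- design_tbl()
  rel <- ifelse(des$context == "A", des$b, des$l)
  sign_accuracy(des$b + des$l, rel)
}
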