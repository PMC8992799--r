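#' Classify hidden units by context gating
#'
#' Units are labelled from their activations on the full 50-condition grid:
#' \emph{dead} units respond (at most \code{tol}) to no stimulus,
#' \emph{task-specific} units respond to at least one stimulus in exactly one
#' context and to none in the other (the ReLU gating signature), and
#' \emph{task-agnostic} units respond in both contexts.
#'
#' @param hidden Condition-by-unit activation matrix from the full grid.
#' @param grid The [make_condition_grid()] the activations came from (used
#'   for the context labels).
#' @param tol Absolute activation treated as zero (default 1e-8; ReLU
#'   returns exact zeros up to float error).
#' @return An object of class \code{"unit_classes"}: list with \code{label}
#'   (per-unit factor: dead / task_specific_A / task_specific_B /
#'   task_agnostic) and \code{proportions} (tibble; task_specific pools A
#'   and B).
#' @export
classify_units <- function(hidden, grid, tol = 1e-8) {
  a_rows <- grid$context == "A"
  active_A <- colSums(abs(hidden[a_rows, , drop = FALSE]) > tol) > 0
  active_B <- colSums(abs(hidden[!a_rows, , drop = FALSE]) > tol) > 0
  label <- dplyr::case_when(
    !active_A & !active_B ~ "dead",
    active_A & !active_B ~ "task_specific_A",
    !active_A & active_B ~ "task_specific_B",
    TRUE ~ "task_agnostic"
  )
  label <- factor(label, levels = c("dead", "task_specific_A",
                                    "task_specific_B", "task_agnostic"))
  counts <- table(label)
  props <- tibble::tibble(
    class = c("dead", "task_specific", "task_agnostic"),
    proportion = c(counts[["dead"]],
                   counts[["task_specific_A"]] + counts[["task_specific_B"]],
                   counts[["task_agnostic"]]) / length(label)
  )
  structure(list(label = label, proportions = props), class = "unit_classes")
}

#' @export
print.unit_classes <- function(x, ...) {
  cat("<unit_classes>\n")
  print(x$proportions)
  invisible(x)
}

units_in_class <- function(classes, unit_class) {
  which(switch(unit_class,
    task_specific = classes$label %in% c("task_specific_A", "task_specific_B"),
    task_specific_A = classes$label == "task_specific_A",
    task_specific_B = classes$label == "task_specific_B",
    task_agnostic = classes$label == "task_agnostic",
    dead = classes$label == "dead",
    abort("unknown unit class")
  ))
}

#' Correlation between the two context input weights
#'
#' Pearson correlation between the weights from the two context units into a
#' subset of hidden units. Anticorrelated context weights are the wiring
#' signature of the gating scheme: units pushed below the ReLU threshold in
#' one context are pushed above it in the other.
#'
#' @param params An [init_mlp()] parameter set (the last two input columns
#'   are the context weights).
#' @param unit_subset Integer indices of hidden units (default all).
#' @return Pearson r.
#' @export
context_weight_correlation <- function(params, unit_subset = NULL) {
  n_in <- ncol(params$W_hidden)
  w_A <- params$W_hidden[, n_in - 1]
  w_B <- params$W_hidden[, n_in]
  if (!is.null(unit_subset)) {
    w_A <- w_A[unit_subset]
    w_B <- w_B[unit_subset]
  }
  if (length(w_A) < 2) abort("`unit_subset` must contain at least two units")
  cor(w_A, w_B)
}

#' Ablate a unit class and re-evaluate
#'
#' Clamps the activations of the named sub-population to zero during the
#' forward pass over the full condition grid and returns the resulting sign
#' accuracy. Pass \code{context} to score a single task only.
#'
#' @param params Trained [init_mlp()] parameters.
#' @param grid A [make_condition_grid()] tibble.
#' @param unit_class One of "task_specific", "task_specific_A",
#'   "task_specific_B", "task_agnostic", "dead", or an integer vector of
#'   unit indices.
#' @param classes Optional precomputed [classify_units()] result.
#' @param context Optional "A" or "B" to restrict scoring to one context.
#' @param tol Passed to [classify_units()].
#' @return Sign accuracy after ablation.
#' @export
ablate_and_eval <- function(params, grid, unit_class, classes = NULL,
                            context = NULL, tol = 1e-8) {
  fw <- forward(params, grid)
  idx <- if (is.numeric(unit_class)) {
    unit_class
  } else {
    classes <- classes %||% classify_units(fw$hidden, grid, tol)
    units_in_class(classes, unit_class)
  }
  H <- fw$hidden
  H[, idx] <- 0
  out <- drop(H %*% params$w_out) + params$b_out
  keep <- if (is.null(context)) rep(TRUE, nrow(grid)) else grid$context == context
  sign_accuracy(out[keep], grid$target[keep])
}

#' Accuracy split by stimulus congruency
#'
#' A condition is congruent when its two feature levels have the same sign
#' (both would map to the same response under either context) and
#' incongruent when the signs are opposite; conditions with a zero on either
#' feature are excluded.
#'
#' @param outputs Network outputs for every row of \code{grid}.
#' @param grid A [make_condition_grid()] tibble.
#' @return A tibble with columns \code{congruency} and \code{accuracy}.
#' @export
congruency_accuracy <- function(outputs, grid) {
  cong <- sign(grid$x) == sign(grid$y) & grid$x != 0 & grid$y != 0
  incong <- sign(grid$x) == -sign(grid$y) & grid$x != 0 & grid$y != 0
  tibble::tibble(
    congruency = c("congruent", "incongruent"),
    accuracy = c(sign_accuracy(outputs[cong], grid$target[cong]),
                 sign_accuracy(outputs[incong], grid$target[incong]))
  )
}

#' Regression-based selectivity of rate units
#'
#' Regresses each unit's trial-wise rate on four predictors (color level in
#' the color task, motion level in the color task, color level in the motion
#' task, motion level in the motion task; the level enters only on trials of
#' the corresponding context and is zero elsewhere). Two-sided t tests on
#' the coefficients are corrected with Benjamini-Hochberg FDR across all
#' unit-by-coefficient tests, and each unit is categorised from its
#' significant coefficients: \emph{task_selective} (relevant dimensions
#' only), \emph{color_only} / \emph{motion_only} (one dimension in both
#' contexts), \emph{task_agnostic} (both dimensions), \emph{nonspecific}
#' (any other significant pattern) or \emph{none}.
#'
#' @param rates Trial-by-unit rate matrix or a \code{"pseudo_population"}.
#' @param labels Tibble with columns \code{motion}, \code{color},
#'   \code{context} (levels "motion"/"color").
#' @param alpha Significance level after correction (default 0.05).
#' @param fdr Apply Benjamini-Hochberg correction (default TRUE)?
#' @return A tibble of class \code{"selectivity_report"}: one row per unit
#'   with the four coefficients, their adjusted p values and the
#'   \code{category}.
#' @export
unit_selectivity_regression <- function(rates, labels = NULL, alpha = 0.05,
                                        fdr = TRUE) {
  if (inherits(rates, "pseudo_population")) {
    labels <- rates$trial_labels
    rates <- rates$trials
  }
  labels <- tibble::as_tibble(labels)
  rates <- as.matrix(rates)
  if (length(unique(labels$context)) < 2) {
    abort("labels must span both contexts")
  }
  ctr <- function(x) x - mean(x)
  in_color <- labels$context == "color"
  X <- cbind(
    colour_colourtask = ctr(labels$color) * in_color,
    motion_colourtask = ctr(labels$motion) * in_color,
    colour_motiontask = ctr(labels$color) * !in_color,
    motion_motiontask = ctr(labels$motion) * !in_color
  )
  design <- cbind(1, X)
  if (qr(design)$rank < ncol(design)) abort("rank-deficient selectivity design")
  fit <- lm(rates ~ X)
  cf <- as.matrix(coef(fit))[-1, , drop = FALSE]
  sm <- summary(fit)
  if (inherits(sm, "summary.lm")) sm <- list(sm)
  pmat <- vapply(sm, function(s) s$coefficients[-1, "Pr(>|t|)"],
                 numeric(ncol(X)))
  padj <- matrix(if (fdr) p.adjust(pmat, method = "BH") else pmat,
                 nrow = nrow(pmat))
  sig <- padj <= alpha
  coef_names <- c("colour_colourtask", "motion_colourtask",
                  "colour_motiontask", "motion_motiontask")
  categorise <- function(s) {
    names(s) <- coef_names
    if (!any(s)) return("none")
    on <- coef_names[s]
    relevant <- c("colour_colourtask", "motion_motiontask")
    colour <- c("colour_colourtask", "colour_motiontask")
    motion <- c("motion_colourtask", "motion_motiontask")
    if (all(on %in% relevant)) return("task_selective")
    if (all(on %in% colour)) return("color_only")
    if (all(on %in% motion)) return("motion_only")
    if (any(on %in% colour) && any(on %in% motion)) return("task_agnostic")
    "nonspecific"
  }
  out <- tibble::as_tibble(t(cf))
  names(out) <- coef_names
  out$unit <- seq_len(ncol(rates))
  for (i in seq_along(coef_names)) {
    out[[paste0("p_", coef_names[i])]] <- padj[i, ]
  }
  out$category <- apply(sig, 2, categorise)
  out <- out[, c("unit", coef_names, paste0("p_", coef_names), "category")]
  class(out) <- c("selectivity_report", class(out))
  out
}

#' Factorised versus linear fit of sub-population response profiles
#'
#' Builds a magnitude-difference RDM (absolute differences of the mean
#' responses across the full design) and regresses it on two model RDMs: the
#' \emph{factorised} model, in which responses scale with the
#' context-relevant feature, and the \emph{linear} model, in which responses
#' scale with the sum of both features irrespective of context.
#'
#' @param responses Mean response per condition (length = rows of the
#'   design, ordered context-major).
#' @param design Tibble with columns \code{context} ("A"/"B"), \code{b},
#'   \code{l} (defaults to the 50-condition grid); context A's relevant
#'   feature is b.
#' @return An [rdm_regression()] fit with betas \code{factorised} and
#'   \code{linear}.
#' @export
unit_response_model_fit <- function(responses, design = design_tbl()) {
  if (length(responses) != nrow(design)) {
    abort("`responses` must have one value per design row")
  }
  if (sd(responses) == 0) abort("constant responses cannot be fit")
  mag_rdm <- function(v) abs(outer(v, v, "-"))
  rel <- ifelse(design$context == "A", design$b, design$l)
  lin <- design$b + design$l
  rdm_regression(mag_rdm(responses),
                 list(factorised = mag_rdm(rel), linear = mag_rdm(lin)))
}
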