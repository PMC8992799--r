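#' Render a Gaussian-blob stimulus image
#'
#' Builds the 5x5 pixel image of an isotropic Gaussian blob centred on one of
#' the 25 grid positions of the stimulus space. Pixel coordinates and blob
#' centres live on the same grid, with levels \code{-2..2} in steps of one;
#' \code{blob_sd} is expressed in grid steps. Neighbouring blobs overlap
#' partially so the input code carries similarity structure.
#'
#' @param x_level,y_level Integer grid levels in \code{-2..2} giving the blob
#'   centre.
#' @param blob_sd Standard deviation of the blob in grid steps. The default
#'   (0.8) makes adjacent-centre images overlap strongly while images at
#'   opposite corners are nearly orthogonal.
#' @param normalize Either \code{"max"} (default; peak pixel scaled to 1) or
#'   \code{"sum"} (pixels sum to 1).
#' @return A 5x5 numeric matrix of non-negative pixel intensities; rows index
#'   y levels (from -2 to 2), columns x levels.
#' @examples
#' img <- make_blob_image(0, 0)
#' which(img == max(img)) # central pixel
#' @export
make_blob_image <- function(x_level, y_level, blob_sd = 0.8,
                            normalize = c("max", "sum")) {
  normalize <- match.arg(normalize)
  levels <- -2:2
  if (!(x_level %in% levels) || !(y_level %in% levels)) {
    abort("blob centre levels must lie on the grid -2..2")
  }
  stopifnot_scalar_number(blob_sd, "blob_sd")
  if (blob_sd <= 0) {
    abort("`blob_sd` must be positive")
  }
  img <- outer(levels, levels, function(y, x) {
    exp(-((x - x_level)^2 + (y - y_level)^2) / (2 * blob_sd^2))
  })
  img <- switch(normalize, max = img / max(img), sum = img / sum(img))
  dimnames(img) <- list(y = levels, x = levels)
  img
}

#' Build the 50-condition two-context task grid
#'
#' Enumerates the full factorial design: 2 contexts x 5 x-levels x 5
#' y-levels. Each condition carries a 27-length input vector (25 vectorised
#' blob pixels plus a one-hot context pair) and a signed target reward in
#' \code{-2..2}: the x level in context A and the y level in context B.
#' Ordering is context-major, then x, then y; downstream RDM indices follow
#' this convention.
#'
#' @inheritParams make_blob_image
#' @return A tibble with 50 rows and columns \code{context} ("A"/"B"),
#'   \code{x}, \code{y}, \code{target}, and \code{input} (list column of
#'   27-length numeric vectors).
#' @examples
#' grid <- make_condition_grid()
#' dplyr::filter(grid, context == "B", x == 2, y == -1)$target # -1
#' @export
make_condition_grid <- function(blob_sd = 0.8, normalize = c("max", "sum")) {
  normalize <- match.arg(normalize)
  levels <- -2:2
  design <- tidyr::expand_grid(context = c("A", "B"), x = levels, y = levels)
  design$target <- ifelse(design$context == "A", design$x, design$y)
  design$input <- purrr::pmap(design[c("context", "x", "y")], function(context, x, y) {
    pixels <- as.vector(make_blob_image(x, y, blob_sd, normalize))
    ctx <- if (context == "A") c(1, 0) else c(0, 1)
    c(pixels, ctx)
  })
  structure(tibble::as_tibble(design), class = c("condition_grid", class(design)))
}

#' Stack condition inputs into a matrix
#'
#' @param grid A condition grid from [make_condition_grid()].
#' @return A 50x27 numeric matrix, one row per condition.
#' @export
input_matrix <- function(grid) {
  do.call(rbind, grid$input)
}

# coordinates used when planting geometry into synthetic patterns
planted_coordinates <- function(geometry, ...) {
  if (inherits(geometry, "param_geometry")) {
    param_feature_matrix(geometry)
  } else if (is.character(geometry) && length(geometry) == 1L) {
    model_feature_matrix(geometry, ...)
  } else {
    abort("`geometry` must be a model name or a `param_geometry` object")
  }
}

#' Generate condition-by-unit patterns with planted geometry
#'
#' Embeds the coordinates of a named model geometry (or a parameterised
#' geometry) into \code{n_units} dimensions through a seeded random
#' orthonormal map (QR of a Gaussian matrix), then adds independent Gaussian
#' noise per run. Because the embedding is an isometry, the noiseless
#' Euclidean RDM of every run equals the planted model RDM exactly.
#'
#' @param geometry A model name accepted by [model_feature_matrix()] or a
#'   [param_geometry()] object.
#' @param n_units Number of units (>= the intrinsic dimensionality of the
#'   geometry's coordinates).
#' @param n_runs Number of independent runs (noise redrawn per run).
#' @param noise_sd Standard deviation of the additive Gaussian noise.
#' @param seed Integer seed; fixed seeds give bit-identical patterns.
#' @param ... Passed to [model_feature_matrix()] for named geometries.
#' @return A list of class \code{"pattern_set"} with elements
#'   \code{patterns} (run x condition x unit array), \code{run_labels},
#'   \code{condition_labels} (tibble: context, b, l), \code{noise_sd} and
#'   \code{planted_geometry}.
#' @export
gen_planted_patterns <- function(geometry, n_units = 20, n_runs = 1,
                                 noise_sd = 0, seed = NULL, ...) {
  if (n_units < 3) abort("`n_units` must be at least 3")
  if (n_runs < 1) abort("`n_runs` must be at least 1")
  if (noise_sd < 0) abort("`noise_sd` must be non-negative")
  fm <- planted_coordinates(geometry, ...)
  coords <- fm$coordinates
  d <- ncol(coords)
  if (n_units < d) {
    abort("`n_units` is smaller than the intrinsic dimensionality of the geometry")
  }
  with_seed(seed, {
    q <- qr.Q(qr(matrix(rnorm(n_units * n_units), n_units, n_units)))[, seq_len(d), drop = FALSE]
    base <- coords %*% t(q)
    patterns <- array(0, dim = c(n_runs, nrow(coords), n_units))
    for (r in seq_len(n_runs)) {
      patterns[r, , ] <- base + matrix(rnorm(length(base), sd = noise_sd),
                                       nrow(base), ncol(base))
    }
    structure(
      list(patterns = patterns, run_labels = seq_len(n_runs),
           condition_labels = fm$labels, noise_sd = noise_sd,
           planted_geometry = geometry),
      class = "pattern_set"
    )
  })
}

#' Simulate binary choices from the psychophysical model
#'
#' Draws plant/reject responses independently per trial with the choice
#' probabilities of [choice_probability()] on the full 2 x 5 x 5 design.
#'
#' @param params A [psycho_params()] object (or a list of two, named "A" and
#'   "B", for context-specific parameters).
#' @param n_per_cell Trials per design cell (>= 1).
#' @param seed Integer seed.
#' @return A tibble of class \code{"choice_set"} with columns
#'   \code{context}, \code{b}, \code{l}, \code{response} ("plant"/"reject"),
#'   and attributes \code{params} and \code{seed}.
#' @export
gen_synthetic_choices <- function(params, n_per_cell, seed = NULL) {
  if (n_per_cell < 1) abort("`n_per_cell` must be at least 1")
  par_list <- if (inherits(params, "psycho_params")) list(A = params, B = params) else params
  stopifnot(all(c("A", "B") %in% names(par_list)))
  design <- tidyr::expand_grid(context = c("A", "B"), b = -2:2, l = -2:2)
  design$p <- purrr::pmap_dbl(design, function(context, b, l) {
    choice_probability(par_list[[context]], b, l, context)
  })
  trials <- tidyr::uncount(design, weights = n_per_cell)
  with_seed(seed, {
    trials$response <- ifelse(rbinom(nrow(trials), 1, trials$p) == 1, "plant", "reject")
  })
  trials$p <- NULL
  out <- tibble::as_tibble(trials)
  attr(out, "params") <- par_list
  attr(out, "seed") <- seed
  class(out) <- c("choice_set", class(out))
  out
}

#' Generate an NHP-style pseudo-population
#'
#' Simulates trial-wise rates for the 72-condition design (6 motion x 6 color
#' x 2 contexts) from a population of units whose tuning follows
#' \code{effect_spec}: a mixture of task-specific units (responding to the
#' relevant feature in their preferred context only), task-agnostic units
#' (responding to the sum of both features in both contexts) and color-only
#' units, plus i.i.d. Gaussian trial noise.
#'
#' @param effect_spec A list with elements \code{p_task_specific},
#'   \code{p_task_agnostic}, \code{p_color_only}, \code{p_motion_only}
#'   (mixture weights summing to at most 1; the remainder are untuned),
#'   \code{gain} (tuning gain, default 1) and \code{noise_sd}. Shortcut
#'   strings \code{"orthogonal"} (all task-specific), \code{"agnostic"},
#'   \code{"color_only"} and \code{"grid"} (half motion-tuned, half
#'   color-tuned, context-blind) are accepted.
#' @param n_units Number of units.
#' @param n_trials Total number of pseudo-trials; must be divisible by 72.
#' @param seed Integer seed.
#' @return A list of class \code{"pseudo_population"} with \code{trials}
#'   (trial x unit matrix), \code{trial_labels} (tibble: motion 1..6, color
#'   1..6, context "motion"/"color", half "train"/"test") and \code{unit_type}.
#' @export
gen_pseudo_population <- function(effect_spec = "orthogonal", n_units = 50,
                                  n_trials = 1440, seed = NULL) {
  if (n_trials %% 72 != 0) abort("`n_trials` must be divisible by 72")
  spec <- if (is.character(effect_spec)) {
    switch(effect_spec,
      orthogonal = list(p_task_specific = 1),
      agnostic = list(p_task_agnostic = 1),
      color_only = list(p_color_only = 1),
      grid = list(p_color_only = 0.5, p_motion_only = 0.5),
      abort("unknown effect_spec shortcut")
    )
  } else {
    effect_spec
  }
  for (f in c("p_task_specific", "p_task_agnostic", "p_color_only",
              "p_motion_only")) {
    spec[[f]] <- spec[[f]] %||% 0
  }
  spec$gain <- spec$gain %||% 1
  spec$noise_sd <- spec$noise_sd %||% 0
  per_cond <- n_trials / 72
  # signed feature coordinates for levels 1..6
  coord <- function(level) (level - 3.5) / 2.5
  labels <- tidyr::expand_grid(motion = 1:6, color = 1:6,
                               context = c("motion", "color"))
  labels <- tidyr::uncount(labels, weights = per_cond)
  labels$half <- rep(c("train", "test"), length.out = nrow(labels))
  with_seed(seed, {
    n_ts <- round(spec$p_task_specific * n_units)
    n_ta <- round(spec$p_task_agnostic * n_units)
    n_co <- round(spec$p_color_only * n_units)
    n_mo <- round(spec$p_motion_only * n_units)
    if (n_ts + n_ta + n_co + n_mo > n_units) abort("mixture weights exceed 1")
    unit_type <- c(rep("task_specific", n_ts), rep("task_agnostic", n_ta),
                   rep("color_only", n_co), rep("motion_only", n_mo),
                   rep("untuned", n_units - n_ts - n_ta - n_co - n_mo))
    # task-specific units split evenly between motion- and color-preferring,
    # with balanced +/- tuning slopes and a fixed context baseline of
    # 1/sqrt(2): the noiseless condition means are then an isometric
    # embedding of the orthogonal model geometry (unit context separation)
    pref <- rep_len(c("motion", "color"), n_ts)
    tune_sign <- rep_len(c(1, 1, -1, -1), n_ts) # balanced within each pref group
    m <- coord(labels$motion)
    cl <- coord(labels$color)
    rel <- ifelse(labels$context == "motion", m, cl)
    rates <- matrix(0, nrow(labels), n_units)
    g <- spec$gain * sample(c(-1, 1), n_units, replace = TRUE)
    for (u in seq_len(n_units)) {
      rates[, u] <- switch(unit_type[u],
        task_specific = spec$gain * (labels$context == pref[u]) *
          (1 / sqrt(2) + tune_sign[u] * rel),
        task_agnostic = g[u] * (m + cl),
        color_only = g[u] * cl,
        motion_only = g[u] * m,
        untuned = 0
      )
    }
    rates <- rates + matrix(rnorm(length(rates), sd = spec$noise_sd),
                            nrow(rates), ncol(rates))
    structure(
      list(trials = rates, trial_labels = tibble::as_tibble(labels),
           unit_type = unit_type, effect_spec = spec),
      class = "pseudo_population"
    )
  })
}

#' Per-condition mean rates of a pseudo-population
#'
#' Conditions are ordered motion context first, then motion level, then
#' color level, matching the default model-RDM convention (the motion
#' context maps onto context A with the motion level on the b axis).
#'
#' @param pop A [gen_pseudo_population()] result.
#' @param half Optionally restrict to the \code{"train"} or \code{"test"} half.
#' @return A list with \code{means} (72 x unit matrix) and \code{labels}.
#' @export
condition_means <- function(pop, half = NULL) {
  keep <- if (is.null(half)) rep(TRUE, nrow(pop$trial_labels)) else pop$trial_labels$half == half
  lab <- pop$trial_labels[keep, c("motion", "color", "context")]
  key <- paste(lab$context, lab$motion, lab$color, sep = ".")
  sums <- rowsum(pop$trials[keep, , drop = FALSE], key)
  counts <- as.vector(table(key)[rownames(sums)])
  means <- sums / counts
  ulab <- lab[match(rownames(sums), key), ]
  ctx_levels <- if (all(unique(ulab$context) %in% c("motion", "color"))) {
    c("motion", "color")
  } else {
    sort(unique(ulab$context))
  }
  ord <- order(match(ulab$context, ctx_levels), ulab$motion, ulab$color)
  list(means = means[ord, , drop = FALSE], labels = tibble::as_tibble(ulab[ord, ]))
}
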