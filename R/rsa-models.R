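#' Parameterised representational geometry
#'
#' Container for the six-parameter geometry model: four compression factors
#' (relevant/irrelevant dimension per context, each in [0, 1]; 0 = no
#' compression, 1 = dimension collapsed), a rotation of the context-A
#' manifold in the feature plane (degrees, -90..90; 0 keeps the input frame,
#' 90 rotates context A's relevant axis onto context B's, yielding parallel
#' manifolds) and a non-negative context offset scaling the separation
#' between contexts.
#'
#' @param compr_rel_A,compr_irrel_A,compr_rel_B,compr_irrel_B Compression in
#'   [0, 1] of each context's relevant/irrelevant feature dimension.
#' @param rotation Rotation angle theta of the context-A block, degrees in
#'   [-90, 90].
#' @param context_offset Non-negative multiplier on the context separation.
#' @return An object of class \code{"param_geometry"}.
#' @examples
#' param_geometry() # the grid geometry
#' param_geometry(compr_irrel_A = 1, compr_irrel_B = 1) # orthogonal manifolds
#' @export
param_geometry <- function(compr_rel_A = 0, compr_irrel_A = 0,
                           compr_rel_B = 0, compr_irrel_B = 0,
                           rotation = 0, context_offset = 1) {
  compr <- c(compr_rel_A, compr_irrel_A, compr_rel_B, compr_irrel_B)
  if (any(compr < 0 | compr > 1)) {
    abort("compression parameters must lie in [0, 1]")
  }
  if (rotation < -90 || rotation > 90) {
    abort("`rotation` must lie in [-90, 90] degrees")
  }
  if (context_offset < 0) {
    abort("`context_offset` must be non-negative")
  }
  structure(
    list(compr_rel_A = compr_rel_A, compr_irrel_A = compr_irrel_A,
         compr_rel_B = compr_rel_B, compr_irrel_B = compr_irrel_B,
         rotation = rotation, context_offset = context_offset),
    class = "param_geometry"
  )
}

#' @export
print.param_geometry <- function(x, ...) {
  cat("<param_geometry>\n")
  cat(sprintf("  compression A (rel/irrel): %.3f / %.3f\n", x$compr_rel_A, x$compr_irrel_A))
  cat(sprintf("  compression B (rel/irrel): %.3f / %.3f\n", x$compr_rel_B, x$compr_irrel_B))
  cat(sprintf("  rotation: %.1f deg, context offset: %.3f\n", x$rotation, x$context_offset))
  invisible(x)
}

# full factorial (t, b, l) design, context-major then b then l
design_tbl <- function(b_levels = -2:2, l_levels = -2:2) {
  tidyr::expand_grid(context = c("A", "B"), b = b_levels, l = l_levels)
}

rotation_block <- function(theta_deg, direction = 1) {
  th <- direction * theta_deg * pi / 180
  # acts on (b, l) coordinates; the context coordinate is untouched
  matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2, 2, byrow = TRUE)
}

#' Coordinates of the candidate geometry models
#'
#' Builds the condition-by-coordinate matrix whose pairwise Euclidean
#' distances define each model RDM. All models place the two contexts on
#' parallel sheets separated by unit distance along a context coordinate
#' (t = 0 for context A, 1 for context B) and differ in how the two feature
#' dimensions b and l are retained:
#' \describe{
#'   \item{grid}{both features retained at unit spacing in both contexts;}
#'   \item{orthogonal}{each context keeps only its relevant feature
#'     (b in context A, l in context B by default), so the two task
#'     manifolds span perpendicular axes;}
#'   \item{parallel}{the orthogonal model with context A's manifold rotated
#'     by 90 degrees onto context B's axis (a context-blind magnitude code);}
#'   \item{rotated_grid}{the grid model with context A's sheet rotated by 90
#'     degrees;}
#'   \item{branchiness, leafiness}{both contexts keep only b (respectively
#'     l);}
#'   \item{diagonal}{both contexts keep the diagonal coordinate
#'     (b + l) / sqrt(2).}
#' }
#'
#' @param kind Model name (see above).
#' @param reward_direction +1 or -1; sign of the 90-degree rotation used by
#'   the parallel and rotated-grid models (which feature ends map onto the
#'   same response).
#' @param relevant_A Which feature ("b" or "l") is relevant in context A; the
#'   other is relevant in context B.
#' @param b_levels,l_levels Feature levels of the design (default the 5x5
#'   grid -2..2; pass 6-level coordinates for the 6 x 6 x 2 design).
#' @return A list of class \code{"feature_matrix"} with \code{coordinates}
#'   (condition x 3 matrix: t, b, l), \code{labels} (tibble) and \code{kind}.
#' @export
model_feature_matrix <- function(kind = c("grid", "orthogonal", "parallel",
                                          "rotated_grid", "branchiness",
                                          "leafiness", "diagonal"),
                                 reward_direction = 1,
                                 relevant_A = c("b", "l"),
                                 b_levels = -2:2, l_levels = -2:2) {
  kind <- match.arg(kind)
  relevant_A <- match.arg(relevant_A)
  if (!reward_direction %in% c(-1, 1)) abort("`reward_direction` must be +1 or -1")
  des <- design_tbl(b_levels, l_levels)
  t_coord <- ifelse(des$context == "A", 0, 1)
  b <- des$b
  l <- des$l
  rel <- if (relevant_A == "b") list(A = b, B = l) else list(A = l, B = b)
  a_rows <- des$context == "A"
  X <- switch(kind,
    grid = cbind(t_coord, b, l),
    orthogonal = {
      out <- cbind(t_coord, 0, 0)
      # context A's relevant feature on the b axis, context B's on the l axis
      out[a_rows, 2] <- rel$A[a_rows]
      out[!a_rows, 3] <- rel$B[!a_rows]
      out
    },
    parallel = {
      out <- cbind(t_coord, 0, 0)
      out[a_rows, 2] <- rel$A[a_rows]
      out[!a_rows, 3] <- rel$B[!a_rows]
      R <- rotation_block(90, reward_direction)
      out[a_rows, 2:3] <- out[a_rows, 2:3] %*% R
      out
    },
    rotated_grid = {
      out <- cbind(t_coord, b, l)
      R <- rotation_block(90, reward_direction)
      out[a_rows, 2:3] <- out[a_rows, 2:3] %*% R
      out
    },
    branchiness = cbind(t_coord, b, 0),
    leafiness = cbind(t_coord, 0, l),
    diagonal = cbind(t_coord, (b + l) / sqrt(2), 0)
  )
  colnames(X) <- c("t", "b", "l")
  structure(list(coordinates = X, labels = des, kind = kind),
            class = "feature_matrix")
}

#' Coordinates of the parameterised geometry model
#'
#' Builds the condition coordinates for a [param_geometry()]: context A's
#' block is \code{(t = 0, (1 - compr_rel_A) * rel_A, (1 - compr_irrel_A) *
#' irrel_A)} rotated by theta in the feature plane; context B's block is
#' \code{(context_offset * 1, (1 - compr_irrel_B) * irrel_B,
#' (1 - compr_rel_B) * rel_B)} with its relevant feature on the second
#' feature axis. At the parameter limits this family reproduces the grid
#' (no compression, theta = 0, offset = 1), orthogonal (irrelevant
#' dimensions fully compressed) and parallel (orthogonal plus theta = 90)
#' models exactly.
#'
#' @param g A [param_geometry()].
#' @inheritParams model_feature_matrix
#' @return A \code{"feature_matrix"} list, as [model_feature_matrix()].
#' @export
param_feature_matrix <- function(g, relevant_A = c("b", "l"),
                                 b_levels = -2:2, l_levels = -2:2) {
  if (!inherits(g, "param_geometry")) abort("`g` must be a `param_geometry`")
  relevant_A <- match.arg(relevant_A)
  des <- design_tbl(b_levels, l_levels)
  a_rows <- des$context == "A"
  rel <- if (relevant_A == "b") list(A = des$b, B = des$l) else list(A = des$l, B = des$b)
  irrel <- if (relevant_A == "b") list(A = des$l, B = des$b) else list(A = des$b, B = des$l)
  X <- cbind(t = 0, b = 0, l = 0)[rep(1, nrow(des)), ]
  # context A: relevant on axis 2, irrelevant on axis 3, then rotated
  X[a_rows, 2] <- (1 - g$compr_rel_A) * rel$A[a_rows]
  X[a_rows, 3] <- (1 - g$compr_irrel_A) * irrel$A[a_rows]
  R <- rotation_block(g$rotation)
  X[a_rows, 2:3] <- X[a_rows, 2:3] %*% R
  # context B: irrelevant on axis 2, relevant on axis 3
  X[!a_rows, 1] <- g$context_offset
  X[!a_rows, 2] <- (1 - g$compr_irrel_B) * irrel$B[!a_rows]
  X[!a_rows, 3] <- (1 - g$compr_rel_B) * rel$B[!a_rows]
  colnames(X) <- c("t", "b", "l")
  structure(list(coordinates = X, labels = des, kind = "parameterised"),
            class = "feature_matrix")
}

#' Model RDM from a geometry
#'
#' Convenience wrapper: coordinates of a named model or parameterised
#' geometry passed through [euclidean_rdm()].
#'
#' @param geometry A model name, \code{"feature_matrix"} or
#'   [param_geometry()].
#' @param ... Passed to [model_feature_matrix()] / [param_feature_matrix()].
#' @return An [euclidean_rdm()] result.
#' @export
model_rdm <- function(geometry, ...) {
  fm <- if (inherits(geometry, "feature_matrix")) {
    geometry
  } else if (inherits(geometry, "param_geometry")) {
    param_feature_matrix(geometry, ...)
  } else {
    model_feature_matrix(geometry, ...)
  }
  euclidean_rdm(fm$coordinates, labels = fm$labels)
}
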