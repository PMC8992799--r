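#' Configuration of the four-unit recurrent gating model
#'
#' A hand-wired firing-rate network with four neuron classes — preferred /
#' anti-preferred motion and preferred / anti-preferred color — that
#' receives a transient stimulus (signed motion coherence m and color level
#' c) and a sustained context signal. Context acts purely by inhibition:
#' motion units are inhibited in the color task and color units in the
#' motion task, with strength \code{w}. Each unit has unit-weight self
#' recurrence (an autapse), so activity persists through the delay, and the
#' dynamics are \code{dh/dt = -h + relu(h + Wx x(t) + Wu u(t))}, integrated
#' by forward Euler from \code{h(0) = 0}. The readout subtracts each
#' anti-preferred unit from its preferred partner.
#'
#' The stimulus profile is \code{p_x(t) = a * exp(-t / tau) + b_profile} for
#' \code{0 < t <= t_x} (a sharp onset transient decaying to a plateau) and 0
#' afterwards; the context pulse \code{p_u(t)} is 1 for \code{0 < t <= t_u}.
#' Defaults realise the grid-to-orthogonal transition: the onset transient
#' exceeds the inhibition (irrelevant stimuli drive their units early),
#' while the plateau falls below it (the inhibition wins later and the
#' irrelevant units decay to zero by the end of the delay).
#'
#' @param w Context inhibition strength (> 0; \code{w = 0} switches the
#'   gating off).
#' @param a Onset amplitude of the stimulus profile.
#' @param b_profile Plateau of the stimulus profile (named to disambiguate
#'   from the branchiness feature).
#' @param tau Decay time constant of the onset transient.
#' @param t_x Stimulus duration; \code{t_u} context/delay duration
#'   (\code{t_u > t_x}).
#' @param t_u See \code{t_x}.
#' @param dt Euler integration step.
#' @param m Signed motion coherence in [-1, 1]; \code{c_level} signed color
#'   level in [-1, 1].
#' @param c_level See \code{m}.
#' @param context "motion" or "color".
#' @return A list of class \code{"rnn_config"}.
#' @export
rnn_config <- function(w = 0.5, a = 2, b_profile = 0.2, tau = 0.3,
                       t_x = 1, t_u = 2, dt = 0.005, m = 1, c_level = 1,
                       context = c("motion", "color")) {
  context <- match.arg(context)
  if (w < 0) abort("`w` must be non-negative")
  if (!(t_u > t_x && t_x > 0)) abort("need t_u > t_x > 0")
  if (dt <= 0) abort("`dt` must be positive")
  if (abs(m) > 1 || abs(c_level) > 1) abort("m and c_level must lie in [-1, 1]")
  structure(list(w = w, a = a, b_profile = b_profile, tau = tau, t_x = t_x,
                 t_u = t_u, dt = dt, m = m, c_level = c_level,
                 context = context),
            class = "rnn_config")
}

#' Stimulus and context input profiles
#'
#' @param t Time (scalar or vector, >= 0).
#' @param cfg An [rnn_config()].
#' @return A list with \code{x} (length-2 rows: m * p_x, c * p_x) and
#'   \code{u} (length-2 rows: motion-context and color-context pulses);
#'   vectors when \code{t} is scalar.
#' @export
input_profiles <- function(t, cfg) {
  if (any(t < 0)) abort("`t` must be non-negative")
  p_x <- ifelse(t > 0 & t <= cfg$t_x, cfg$a * exp(-t / cfg$tau) + cfg$b_profile, 0)
  p_u <- as.numeric(t > 0 & t <= cfg$t_u)
  z <- as.numeric(cfg$context == "motion")
  x <- rbind(cfg$m * p_x, cfg$c_level * p_x)
  u <- rbind(z * p_u, (1 - z) * p_u)
  if (length(t) == 1) {
    list(x = drop(x), u = drop(u))
  } else {
    list(x = x, u = u)
  }
}

rnn_weights <- function(w) {
  list(
    # rows: motion+, motion-, color+, color-
    Wx = matrix(c(1, 0, -1, 0, 0, 1, 0, -1), 4, 2, byrow = TRUE),
    # motion units inhibited by the color context, color units by motion
    Wu = matrix(c(0, -w, 0, -w, -w, 0, -w, 0), 4, 2, byrow = TRUE),
    Wo = matrix(c(1, -1, 0, 0, 0, 0, 1, -1), 2, 4, byrow = TRUE)
  )
}

#' Simulate the gating network
#'
#' Forward-Euler integration of the firing-rate dynamics from
#' \code{h(0) = 0} to \code{t_u}.
#'
#' @param cfg An [rnn_config()].
#' @return A tibble of class \code{"rnn_trajectory"} with columns \code{t},
#'   \code{h1..h4} (motion+/-, color+/- rates) and \code{r_motion},
#'   \code{r_color} (readouts).
#' @export
simulate_gating_rnn <- function(cfg) {
  W <- rnn_weights(cfg$w)
  n_steps <- ceiling(cfg$t_u / cfg$dt)
  ts <- seq_len(n_steps) * cfg$dt
  H <- matrix(0, n_steps + 1, 4)
  h <- numeric(4)
  for (i in seq_len(n_steps)) {
    inp <- input_profiles(ts[i], cfg)
    dh <- -h + relu(h + drop(W$Wx %*% inp$x) + drop(W$Wu %*% inp$u))
    h <- h + cfg$dt * dh
    if (any(!is.finite(h))) {
      abort(paste0("non-finite state at step ", i))
    }
    H[i + 1, ] <- h
  }
  R <- H %*% t(W$Wo)
  out <- tibble::tibble(
    t = c(0, ts), h1 = H[, 1], h2 = H[, 2], h3 = H[, 3], h4 = H[, 4],
    r_motion = R[, 1], r_color = R[, 2]
  )
  class(out) <- c("rnn_trajectory", class(out))
  out
}

#' Time-resolved geometry of the gating network
#'
#' Simulates the network over a factorial stimulus grid (6 motion x 6 color
#' x 2 contexts by default), time-averages the four-unit state within each
#' window, and regresses the per-window Euclidean RDM on the grid and
#' orthogonal model RDMs. With the default inhibition the geometry
#' transitions from grid-like in the early window to orthogonal in the late
#' window; with \code{w = 0} no orthogonalisation occurs.
#'
#' @param cfg An [rnn_config()] (its m / c_level / context are overridden by
#'   the grid).
#' @param levels Signed coherence levels (default 6 values in [-1, 1]).
#' @param windows Named list of \code{c(start, end)} time windows; default
#'   thirds of the trial.
#' @return A tibble with columns \code{window}, \code{model}, \code{beta}.
#' @export
windowed_geometry <- function(cfg = rnn_config(), levels = NULL,
                              windows = NULL) {
  levels <- levels %||% c(-1, -0.6, -0.2, 0.2, 0.6, 1)
  windows <- windows %||% list(
    early = c(0, cfg$t_u / 3),
    middle = c(cfg$t_u / 3, 2 * cfg$t_u / 3),
    late = c(2 * cfg$t_u / 3, cfg$t_u)
  )
  if (any(vapply(windows, function(w) w[2] <= w[1], logical(1)))) {
    abort("empty time window")
  }
  design <- tidyr::expand_grid(context = c("motion", "color"),
                               m = levels, c_level = levels)
  trajs <- purrr::pmap(design, function(context, m, c_level) {
    cfg2 <- cfg
    cfg2$m <- m
    cfg2$c_level <- c_level
    cfg2$context <- context
    simulate_gating_rnn(cfg2)
  })
  mods <- list(
    grid = model_rdm("grid", b_levels = levels, l_levels = levels),
    orthogonal = model_rdm("orthogonal", b_levels = levels, l_levels = levels)
  )
  # model design is context-major with b = m, l = c; match it: context
  # "motion" (relevant = m) maps to context A with relevant_A = "b"
  design_order <- order(match(design$context, c("motion", "color")),
                        design$m, design$c_level)
  out <- purrr::imap(windows, function(win, nm) {
    states <- t(vapply(trajs, function(tr) {
      rows <- tr$t >= win[1] & tr$t <= win[2]
      colMeans(as.matrix(tr[rows, c("h1", "h2", "h3", "h4")]))
    }, numeric(4)))
    states <- states[design_order, ]
    fit <- rdm_regression(euclidean_rdm(states), mods)
    tibble::tibble(window = nm, model = names(fit$betas),
                   beta = unname(fit$betas))
  })
  dplyr::bind_rows(out)
}
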