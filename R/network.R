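#' Initialise the single-hidden-layer ReLU network
#'
#' Weights are drawn from zero-mean Gaussians: input-to-hidden weights with
#' standard deviation \code{sigma0} (the initial weight scale that selects
#' the learning regime — small values such as 0.01 put the network in the
#' rich regime, large values such as 3 in the lazy regime), hidden-to-output
#' weights with variance \code{1 / n_hidden}. All biases start at zero.
#'
#' @param sigma0 Initial weight scale (> 0).
#' @param n_hidden Number of hidden units (default 100).
#' @param n_input Number of inputs (default 27 = 25 pixels + 2 context units).
#' @param n_hidden2 Optional size of a second hidden layer (used only for the
#'   auxiliary RDM-loss experiments); \code{NULL} for the standard
#'   architecture.
#' @param seed Integer seed; same seed, same parameters.
#' @return An object of class \code{"mlp_params"}: list with \code{W_hidden}
#'   (n_hidden x n_input), \code{b_hidden}, optionally \code{W_hidden2} /
#'   \code{b_hidden2}, \code{w_out}, \code{b_out}, \code{sigma0}.
#' @export
init_mlp <- function(sigma0, n_hidden = 100, n_input = 27, n_hidden2 = NULL,
                     seed = NULL) {
  stopifnot_scalar_number(sigma0, "sigma0")
  if (sigma0 <= 0) abort("`sigma0` must be positive")
  with_seed(seed, {
    params <- list(
      W_hidden = matrix(rnorm(n_hidden * n_input, sd = sigma0), n_hidden, n_input),
      b_hidden = numeric(n_hidden),
      sigma0 = sigma0
    )
    n_top <- n_hidden
    if (!is.null(n_hidden2)) {
      params$W_hidden2 <- matrix(rnorm(n_hidden2 * n_hidden, sd = sigma0),
                                 n_hidden2, n_hidden)
      params$b_hidden2 <- numeric(n_hidden2)
      n_top <- n_hidden2
    }
    params$w_out <- rnorm(n_top, sd = sqrt(1 / n_top))
    params$b_out <- 0
    structure(params, class = "mlp_params")
  })
}

#' @export
print.mlp_params <- function(x, ...) {
  cat(sprintf("<mlp_params> %d -> %d%s -> 1, sigma0 = %g\n",
              ncol(x$W_hidden), nrow(x$W_hidden),
              if (is.null(x$W_hidden2)) "" else paste0(" -> ", nrow(x$W_hidden2)),
              x$sigma0))
  invisible(x)
}

#' Forward pass
#'
#' @param params An [init_mlp()] parameter set.
#' @param inputs Input matrix, one row per item (27 columns), or a
#'   condition grid (its input vectors are stacked).
#' @return A list with \code{hidden} (item x unit ReLU activations; for the
#'   two-layer variant, the top layer, with the first layer in
#'   \code{hidden1}) and \code{output} (numeric vector).
#' @export
forward <- function(params, inputs) {
  if (inherits(inputs, "condition_grid")) inputs <- input_matrix(inputs)
  inputs <- if (is.matrix(inputs)) inputs else matrix(inputs, nrow = 1)
  if (ncol(inputs) != ncol(params$W_hidden)) {
    abort("input width does not match the network's input layer")
  }
  h <- relu(tcrossprod(inputs, params$W_hidden) +
              rep(params$b_hidden, each = nrow(inputs)))
  out <- list()
  if (!is.null(params$W_hidden2)) {
    out$hidden1 <- h
    h <- relu(tcrossprod(h, params$W_hidden2) +
                rep(params$b_hidden2, each = nrow(inputs)))
  }
  out$hidden <- h
  out$output <- drop(h %*% params$w_out) + params$b_out
  out
}

#' Training configuration
#'
#' @param learning_rate SGD learning rate (default 0.001).
#' @param batch_size Minibatch size (default 50); batches are drawn uniformly
#'   with replacement, half from each context (interleaved contexts).
#' @param n_iterations Number of SGD iterations (default 10000).
#' @param l2_lambda L2 penalty weight on all weight matrices (default 0).
#' @param rdm_beta Weight of the auxiliary RDM loss (default 0); when
#'   positive, \code{rdm_target} must be a 50 x 50 RDM.
#' @param rdm_target Target RDM for the auxiliary loss ([euclidean_rdm()]
#'   object or matrix), or \code{NULL}.
#' @param checkpoint_every Trace recording interval in iterations (default
#'   100).
#' @param seed Integer seed for batch sampling.
#' @return A list of class \code{"train_config"}.
#' @export
train_config <- function(learning_rate = 0.001, batch_size = 50,
                         n_iterations = 10000, l2_lambda = 0, rdm_beta = 0,
                         rdm_target = NULL, checkpoint_every = 100,
                         seed = NULL) {
  if (learning_rate <= 0 || batch_size <= 0 || n_iterations <= 0) {
    abort("learning rate, batch size and iteration count must be positive")
  }
  if (l2_lambda < 0 || rdm_beta < 0) abort("penalty weights must be non-negative")
  if (rdm_beta > 0 && is.null(rdm_target)) {
    abort("`rdm_target` is required when `rdm_beta` > 0")
  }
  structure(list(learning_rate = learning_rate, batch_size = batch_size,
                 n_iterations = n_iterations, l2_lambda = l2_lambda,
                 rdm_beta = rdm_beta, rdm_target = rdm_target,
                 checkpoint_every = checkpoint_every, seed = seed),
            class = "train_config")
}

frob <- function(m) sqrt(sum(m^2))

# analytic gradients of MSE + l2 + RDM-loss for the 1- or 2-hidden-layer MLP
mlp_gradients <- function(params, X, y, cfg, rdm_target_m) {
  n <- nrow(X)
  two_layer <- !is.null(params$W_hidden2)
  Z1 <- tcrossprod(X, params$W_hidden) + rep(params$b_hidden, each = n)
  H1 <- relu(Z1)
  if (two_layer) {
    Z2 <- tcrossprod(H1, params$W_hidden2) + rep(params$b_hidden2, each = n)
    Htop <- relu(Z2)
  } else {
    Htop <- H1
  }
  yhat <- drop(Htop %*% params$w_out) + params$b_out
  err <- yhat - y
  loss <- mean(err^2)
  d_yhat <- 2 * err / n
  g <- list(
    w_out = drop(crossprod(Htop, d_yhat)),
    b_out = sum(d_yhat)
  )
  d_Htop <- tcrossprod(d_yhat, params$w_out)
  # auxiliary RDM loss on the top hidden layer
  if (cfg$rdm_beta > 0) {
    G <- tcrossprod(Htop) # n x n Gram of condition patterns
    rdm <- outer(diag(G), diag(G), "+") - 2 * G
    D <- cfg$rdm_beta * (rdm - rdm_target_m) # dL/dRDM
    dG <- diag(rowSums(D) + colSums(D)) - (D + t(D))
    d_Htop <- d_Htop + (dG + t(dG)) %*% Htop
    loss <- loss + (cfg$rdm_beta / 2) * sum((rdm_target_m - rdm)^2)
  }
  if (two_layer) {
    d_Z2 <- d_Htop * (Z2 > 0)
    g$W_hidden2 <- crossprod(d_Z2, H1)
    g$b_hidden2 <- colSums(d_Z2)
    d_H1 <- d_Z2 %*% params$W_hidden2
  } else {
    d_H1 <- d_Htop
  }
  d_Z1 <- d_H1 * (Z1 > 0)
  g$W_hidden <- crossprod(d_Z1, X)
  g$b_hidden <- colSums(d_Z1)
  if (cfg$l2_lambda > 0) {
    loss <- loss + cfg$l2_lambda *
      (sum(params$W_hidden^2) + sum(params$w_out^2) +
         if (two_layer) sum(params$W_hidden2^2) else 0)
    g$W_hidden <- g$W_hidden + 2 * cfg$l2_lambda * params$W_hidden
    g$w_out <- g$w_out + 2 * cfg$l2_lambda * params$w_out
    if (two_layer) {
      g$W_hidden2 <- g$W_hidden2 + 2 * cfg$l2_lambda * params$W_hidden2
    }
  }
  list(loss = loss, grads = g)
}

#' Train the network with minibatch SGD
#'
#' Plain SGD on the mean-squared error between predicted and true signed
#' rewards, with optional L2 regularisation and an optional auxiliary loss
#' penalising the squared difference between the hidden layer's Euclidean
#' RDM (computed from the Gram matrix of the activity patterns) and a target
#' RDM. When the auxiliary loss is active, every iteration passes the full
#' 50-condition set through the network; otherwise minibatches are sampled
#' uniformly with replacement, half from each context. Gradients are
#' analytic. Every \code{checkpoint_every} iterations the loss, Frobenius
#' weight norms and log relative weight change are recorded.
#'
#' @param params An [init_mlp()] parameter set.
#' @param grid A [make_condition_grid()] tibble.
#' @param cfg A [train_config()].
#' @return A list with \code{params} (trained \code{"mlp_params"}) and
#'   \code{trace} (tibble of class \code{"train_trace"} with columns
#'   \code{iteration}, \code{loss}, \code{norm_W_hidden}, \code{norm_w_out},
#'   \code{log_dnorm_W_hidden}, \code{log_dnorm_w_out}); the initial
#'   parameters are kept as attribute \code{"params_init"} of the trace.
#' @export
train <- function(params, grid, cfg = train_config()) {
  X <- input_matrix(grid)
  y <- grid$target
  a_idx <- which(grid$context == "A")
  b_idx <- which(grid$context == "B")
  rdm_target_m <- if (cfg$rdm_beta > 0) as_rdm_matrix(cfg$rdm_target) else NULL
  full_batch <- cfg$rdm_beta > 0
  init <- params
  n_checks <- floor(cfg$n_iterations / cfg$checkpoint_every)
  trace <- vector("list", n_checks + 1)
  record <- function(iter, loss) {
    tibble::tibble(
      iteration = iter, loss = loss,
      norm_W_hidden = frob(params$W_hidden),
      norm_w_out = frob(params$w_out),
      log_dnorm_W_hidden = log(frob(params$W_hidden - init$W_hidden)),
      log_dnorm_w_out = log(frob(params$w_out - init$w_out))
    )
  }
  with_seed(cfg$seed, {
    loss0 <- mlp_gradients(params, X, y, cfg, rdm_target_m)$loss
    trace[[1]] <- record(0L, loss0)
    k <- 1L
    half <- ceiling(cfg$batch_size / 2)
    for (iter in seq_len(cfg$n_iterations)) {
      idx <- if (full_batch) {
        seq_len(nrow(X))
      } else {
        # interleaved contexts: alternate A and B draws within the batch
        as.vector(rbind(sample(a_idx, half, replace = TRUE),
                        sample(b_idx, half, replace = TRUE)))[seq_len(cfg$batch_size)]
      }
      step <- mlp_gradients(params, X[idx, , drop = FALSE], y[idx], cfg,
                            rdm_target_m)
      if (!is.finite(step$loss)) {
        trace <- dplyr::bind_rows(trace[!vapply(trace, is.null, logical(1))])
        abort("training diverged (non-finite loss)",
              class = "richlazy_divergence", trace = trace)
      }
      for (nm in names(step$grads)) {
        params[[nm]] <- params[[nm]] - cfg$learning_rate * step$grads[[nm]]
      }
      if (iter %% cfg$checkpoint_every == 0) {
        k <- k + 1L
        trace[[k]] <- record(iter, step$loss)
      }
    }
  })
  trace <- dplyr::bind_rows(trace)
  attr(trace, "params_init") <- init
  class(trace) <- c("train_trace", class(trace))
  list(params = params, trace = trace)
}

#' Sign accuracy of predictions
#'
#' Fraction of items whose prediction has the same sign as the target.
#' Items with a zero target (stimuli on the category boundary, for which
#' the sign is undefined) are excluded from the denominator; a prediction
#' of exactly zero never matches a nonzero target. For continuous network
#' outputs the zero-prediction case has measure zero, but for rule-based
#' predictors (e.g. the diagonal rule, whose output ties at zero on
#' anti-diagonal stimuli) this convention matters: it is what scores the
#' diagonal strategy at 28 of 40.
#'
#' @param outputs Numeric predictions.
#' @param targets Numeric targets of the same length.
#' @return A fraction in [0, 1].
#' @examples
#' sign_accuracy(c(1, -2, 3), c(2, -1, -1)) # 2/3
#' @export
sign_accuracy <- function(outputs, targets) {
  if (length(outputs) == 0 || length(outputs) != length(targets)) {
    abort("`outputs` and `targets` must be non-empty and of equal length")
  }
  keep <- targets != 0
  if (!any(keep)) abort("no items with nonzero target")
  mean(sign(outputs[keep]) == sign(targets[keep]))
}

#' Accuracy under additive input noise
#'
#' Adds i.i.d. Gaussian noise to the 25 stimulus inputs (context inputs are
#' left intact) at evaluation and averages sign accuracy over repetitions.
#'
#' @param params Trained [init_mlp()] parameters.
#' @param grid A [make_condition_grid()] tibble.
#' @param noise_sds Vector of noise standard deviations (>= 0).
#' @param n_reps Noise draws per level.
#' @param seed Integer seed.
#' @return A tibble with columns \code{noise_sd} and \code{accuracy}.
#' @export
noise_robustness <- function(params, grid, noise_sds, n_reps = 10,
                             seed = NULL) {
  if (any(noise_sds < 0)) abort("`noise_sds` must be non-negative")
  X <- input_matrix(grid)
  stim_cols <- seq_len(ncol(X) - 2)
  with_seed(seed, {
    acc <- vapply(noise_sds, function(s) {
      mean(vapply(seq_len(n_reps), function(r) {
        Xn <- X
        Xn[, stim_cols] <- Xn[, stim_cols] +
          matrix(rnorm(nrow(X) * length(stim_cols), sd = s),
                 nrow(X), length(stim_cols))
        sign_accuracy(forward(params, Xn)$output, grid$target)
      }, numeric(1)))
    }, numeric(1))
    tibble::tibble(noise_sd = noise_sds, accuracy = acc)
  })
}

#' Endpoint weight norms and log relative weight change
#'
#' @param trace A training trace from [train()].
#' @return A tibble with one row: endpoint Frobenius norms of the hidden and
#'   output weights and the log Frobenius norm of their change from
#'   initialisation.
#' @export
weight_change_metrics <- function(trace) {
  if (nrow(trace) < 1) abort("empty trace")
  last <- trace[nrow(trace), ]
  tibble::tibble(
    norm_W_hidden = last$norm_W_hidden,
    norm_w_out = last$norm_w_out,
    log_dnorm_W_hidden = last$log_dnorm_W_hidden,
    log_dnorm_w_out = last$log_dnorm_w_out
  )
}

#' Iterations to convergence
#'
#' First checkpoint at which the running mean of the loss (over the
#' \code{patience} most recent checkpoints, including the current one) has
#' been below \code{threshold} for \code{patience} consecutive checkpoints.
#' Returns \code{Inf} when the criterion is never met.
#'
#' @param trace A training trace from [train()].
#' @param threshold Loss threshold (default 0.01).
#' @param patience Number of consecutive sub-threshold checkpoints required
#'   (default 5).
#' @return The iteration at the start of the first sustained sub-threshold
#'   streak (0 if the trace is below threshold from its first checkpoint), or
#'   \code{Inf} if the criterion is never met.
#' @export
episodes_to_convergence <- function(trace, threshold = 0.01, patience = 5) {
  below <- trace$loss < threshold
  r <- rle(below)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  hit <- which(r$values & r$lengths >= patience)
  # a trace that ends below threshold but is too short for the full patience
  # window still counts if the streak runs to the final checkpoint
  tail_hit <- which(r$values & ends == length(below) &
                      starts == 1L & length(below) < patience)
  hit <- sort(unique(c(hit, tail_hit)))
  if (length(hit) == 0) return(Inf)
  trace$iteration[starts[hit[1]]]
}
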