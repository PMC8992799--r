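# Config-driven experiment pipelines. Each experiment trains/generates per
# seed from independent child seeds and returns one tibble row (or a few)
# per seed; run_experiment() aggregates and optionally writes a results
# directory.

regime_models <- function() {
  list(grid = model_rdm("grid"), orthogonal = model_rdm("orthogonal"),
       parallel = model_rdm("parallel"))
}

# Per-regime operating points: every network is analysed at convergence.
# Lazy-regime networks meet the convergence criterion within the standard
# budget; rich-regime networks need a larger one (methods vignette,
# "Training regimes").
regime_train_config <- function(sigma0, params, seed) {
  rich <- sigma0 < 1
  train_config(
    learning_rate = params$learning_rate %||% if (rich) 0.002 else 0.001,
    batch_size = params$batch_size %||% 50,
    n_iterations = params$n_iterations %||% if (rich) 20000 else 10000,
    l2_lambda = params$l2_lambda %||% 0,
    seed = seed
  )
}

train_one <- function(sigma0, grid, params, seed) {
  seeds <- with_seed(seed, sample.int(.Machine$integer.max - 1L, 2))
  net <- init_mlp(sigma0, seed = seeds[1])
  train(net, grid, regime_train_config(sigma0, params, seeds[2]))
}

exp_regime_sweep <- function(params, seed) {
  grid <- make_condition_grid(params$blob_sd %||% 0.8,
                              params$normalize %||% "max")
  mods <- regime_models()
  rows <- lapply(params$sigma0s %||% c(0.01, 3), function(s0) {
    tr <- train_one(s0, grid, params, seed)
    fw <- forward(tr$params, grid)
    cl <- classify_units(fw$hidden, grid)
    betas <- rdm_regression(euclidean_rdm(fw$hidden), mods)$betas
    wm <- weight_change_metrics(tr$trace)
    tibble::tibble(
      sigma0 = s0,
      accuracy = sign_accuracy(fw$output, grid$target),
      final_loss = tail(tr$trace$loss, 1),
      norm_W_hidden = wm$norm_W_hidden,
      log_dnorm_W_hidden = wm$log_dnorm_W_hidden,
      episodes_to_convergence = episodes_to_convergence(tr$trace),
      beta_grid = unname(betas["grid"]),
      beta_orthogonal = unname(betas["orthogonal"]),
      beta_parallel = unname(betas["parallel"]),
      prop_task_specific = cl$proportions$proportion[2],
      prop_task_agnostic = cl$proportions$proportion[3],
      prop_dead = cl$proportions$proportion[1],
      ablate_task_specific = ablate_and_eval(tr$params, grid, "task_specific",
                                            classes = cl),
      ablate_task_agnostic = ablate_and_eval(tr$params, grid, "task_agnostic",
                                             classes = cl),
      n_components_95 = unname(svd_spectrum(fw$hidden)$n_for_threshold[1]),
      k_ceiling = min_rank_for_ceiling(tr$params, grid)
    )
  })
  dplyr::bind_rows(rows)
}

exp_robustness <- function(params, seed) {
  grid <- make_condition_grid(params$blob_sd %||% 0.8,
                              params$normalize %||% "max")
  noise_sds <- params$noise_sds %||% c(0, 0.5, 1, 2)
  rows <- lapply(params$sigma0s %||% c(0.01, 3), function(s0) {
    tr <- train_one(s0, grid, params, seed)
    nr <- noise_robustness(tr$params, grid, noise_sds,
                           n_reps = params$n_reps %||% 10, seed = seed)
    nr$sigma0 <- s0
    nr
  })
  dplyr::bind_rows(rows)
}

exp_geometry_rsa <- function(params, seed) {
  grid <- make_condition_grid(params$blob_sd %||% 0.8,
                              params$normalize %||% "max")
  mods <- regime_models()
  rows <- lapply(params$sigma0s %||% c(0.01, 3), function(s0) {
    tr <- train_one(s0, grid, params, seed)
    H <- forward(tr$params, grid)$hidden
    fit <- rdm_regression(euclidean_rdm(H), mods)
    g <- suppressWarnings(fit_param_geometry(
      euclidean_rdm(H), n_restarts = params$n_restarts %||% 20,
      seed = seed, normalize = "rms"
    ))
    tibble::tibble(
      sigma0 = s0, model = names(fit$betas), beta = unname(fit$betas),
      compression_index = suppressWarnings(compression_index(g)),
      rotation = g$best$rotation, context_offset = g$best$context_offset
    )
  })
  dplyr::bind_rows(rows)
}

exp_dimensionality <- function(params, seed) {
  grid <- make_condition_grid(params$blob_sd %||% 0.8,
                              params$normalize %||% "max")
  rows <- lapply(params$sigma0s %||% c(0.01, 3), function(s0) {
    tr <- train_one(s0, grid, params, seed)
    H <- forward(tr$params, grid)$hidden
    tibble::tibble(
      sigma0 = s0,
      n_components_95 = unname(svd_spectrum(H)$n_for_threshold[1]),
      k_ceiling = min_rank_for_ceiling(tr$params, grid)
    )
  })
  dplyr::bind_rows(rows)
}

exp_selectivity_ablation <- function(params, seed) {
  grid <- make_condition_grid(params$blob_sd %||% 0.8,
                              params$normalize %||% "max")
  rows <- lapply(params$sigma0s %||% c(0.01, 3), function(s0) {
    tr <- train_one(s0, grid, params, seed)
    fw <- forward(tr$params, grid)
    cl <- classify_units(fw$hidden, grid)
    ts_idx <- units_in_class(cl, "task_specific")
    ta_idx <- units_in_class(cl, "task_agnostic")
    H_abl <- fw$hidden
    H_abl[, ts_idx] <- 0
    out_abl <- drop(H_abl %*% tr$params$w_out) + tr$params$b_out
    cong <- congruency_accuracy(out_abl, grid)
    tibble::tibble(
      sigma0 = s0,
      prop_task_specific = cl$proportions$proportion[2],
      prop_task_agnostic = cl$proportions$proportion[3],
      prop_dead = cl$proportions$proportion[1],
      ctx_cor_task_specific = if (length(ts_idx) >= 2) {
        context_weight_correlation(tr$params, ts_idx)
      } else NA_real_,
      ctx_cor_task_agnostic = if (length(ta_idx) >= 2) {
        context_weight_correlation(tr$params, ta_idx)
      } else NA_real_,
      ablate_task_specific = ablate_and_eval(tr$params, grid, "task_specific",
                                             classes = cl),
      ablate_task_agnostic = ablate_and_eval(tr$params, grid, "task_agnostic",
                                             classes = cl),
      congruent_after_ts_ablation = cong$accuracy[1],
      incongruent_after_ts_ablation = cong$accuracy[2]
    )
  })
  dplyr::bind_rows(rows)
}

exp_behavior_recovery <- function(params, seed) {
  truth <- params$truth %||% list(
    A = psycho_params(angle = 10, offset = 0.2, slope = 2, lapse = 0.05),
    B = psycho_params(angle = 80, offset = -0.1, slope = 2, lapse = 0.05)
  )
  ch <- gen_synthetic_choices(truth, params$n_per_cell %||% 200, seed = seed)
  fit <- fit_psychophysics(ch, n_starts = params$n_starts %||% 20, seed = seed)
  bg <- fit_factorised_linear(ch)
  tibble::tibble(
    context = c("A", "B"),
    angle_true = c(truth$A$angle, truth$B$angle),
    angle_est = c(fit$params$A$angle, fit$params$B$angle),
    angular_bias = unname(fit$angular_bias),
    axis_alignment = bg$axis_alignment,
    linear_beta = bg$linear_beta,
    diagonal_benchmark = diagonal_strategy_accuracy()
  )
}

exp_gating_rnn <- function(params, seed) {
  cfg <- rnn_config(w = params$w %||% 0.5)
  cfg0 <- rnn_config(w = 0)
  wg <- windowed_geometry(cfg)
  wg$inhibition <- "default"
  wg0 <- windowed_geometry(cfg0)
  wg0$inhibition <- "none"
  dplyr::bind_rows(wg, wg0)
}

exp_pseudo_population <- function(params, seed) {
  pop <- gen_pseudo_population(params$effect_spec %||% "orthogonal",
                               n_units = params$n_units %||% 50,
                               n_trials = params$n_trials %||% 1440,
                               seed = seed)
  mods <- list(
    grid = model_rdm("grid", b_levels = (1:6 - 3.5) / 2.5,
                     l_levels = (1:6 - 3.5) / 2.5),
    orthogonal = model_rdm("orthogonal", b_levels = (1:6 - 3.5) / 2.5,
                           l_levels = (1:6 - 3.5) / 2.5)
  )
  perm <- permutation_test_rsa(pop, models = mods,
                               n_perm = params$n_perm %||% 200, seed = seed)
  dec <- cross_task_decode(pop, seed = seed)
  tibble::tibble(
    model = perm$model, beta = perm$beta_observed, p_value = perm$p_value,
    decode_same_task = dec$accuracy[dec$condition == "same_task"],
    decode_other_task = dec$accuracy[dec$condition == "other_task"]
  )
}

experiment_registry <- function() {
  list(
    regime_sweep = exp_regime_sweep,
    robustness = exp_robustness,
    geometry_rsa = exp_geometry_rsa,
    dimensionality = exp_dimensionality,
    selectivity_ablation = exp_selectivity_ablation,
    behavior_recovery = exp_behavior_recovery,
    gating_rnn = exp_gating_rnn,
    pseudo_population = exp_pseudo_population
  )
}

#' Run a named experiment over seeds
#'
#' Executes one of the package's experiment pipelines end to end. All
#' randomness is drawn from per-seed streams derived from the master seed,
#' so a config reproduces bit-identically.
#'
#' @param config A list (or path to a YAML/JSON file) with elements
#'   \code{experiment} (one of regime_sweep, robustness, geometry_rsa,
#'   dimensionality, selectivity_ablation, behavior_recovery, gating_rnn,
#'   pseudo_population), \code{params} (experiment parameters; see the
#'   corresponding \code{exp_*} defaults), \code{n_seeds}, \code{seed}, and
#'   optionally \code{out_dir}.
#' @return An object of class \code{"result_bundle"}: list with
#'   \code{results} (per-seed tibble), \code{summary} (mean/sd per numeric
#'   column), \code{provenance} (config, seed list, package version).
#' @export
run_experiment <- function(config) {
  if (is.character(config)) config <- read_experiment_config(config)
  known <- names(experiment_registry())
  if (is.null(config$experiment) || !config$experiment %in% known) {
    abort(paste0("unknown experiment; valid names: ",
                 paste(known, collapse = ", ")))
  }
  n_seeds <- config$n_seeds %||% 1
  master <- config$seed %||% 1
  seeds <- child_seeds(master, n_seeds)
  fn <- experiment_registry()[[config$experiment]]
  params <- config$params %||% list()
  results <- dplyr::bind_rows(lapply(seq_len(n_seeds), function(i) {
    out <- fn(params, seeds[i])
    out$seed_index <- i
    out
  }))
  bundle <- structure(
    list(results = results,
         summary = summarize_bundle_results(results),
         provenance = list(experiment = config$experiment, params = params,
                           master_seed = master, seeds = seeds,
                           n_seeds = n_seeds,
                           version = as.character(utils::packageVersion("richlazy")))),
    class = "result_bundle"
  )
  if (!is.null(config$out_dir)) write_result_bundle(bundle, config$out_dir)
  bundle
}

group_cols <- function(results) {
  intersect(c("sigma0", "model", "window", "inhibition", "context",
              "condition", "noise_sd", "congruency"), names(results))
}

summarize_bundle_results <- function(results) {
  gc <- group_cols(results)
  num <- setdiff(names(results)[vapply(results, is.numeric, logical(1))],
                 c(gc, "seed_index"))
  grouped <- dplyr::group_by(results, dplyr::across(dplyr::all_of(gc)))
  dplyr::summarise(
    grouped,
    dplyr::across(dplyr::all_of(num),
                  list(mean = ~mean(.x[is.finite(.x)]),
                       sd = ~sd(.x[is.finite(.x)]),
                       mode = ~modal_value(.x))),
    n_seeds = dplyr::n_distinct(.data$seed_index),
    .groups = "drop"
  )
}

modal_value <- function(x) {
  x <- x[is.finite(x)]
  if (length(x) == 0) return(NA_real_)
  tab <- table(x)
  as.numeric(names(tab)[which.max(tab)])
}

#' Summary tables of a result bundle
#'
#' Recomputes the aggregate table (mean, sd and modal value of every
#' numeric result, grouped by the experiment's condition columns) from the
#' per-seed records.
#'
#' @param bundle A [run_experiment()] result.
#' @return A tibble.
#' @export
summarize_experiment <- function(bundle) {
  if (!inherits(bundle, "result_bundle") || nrow(bundle$results) == 0) {
    abort("`bundle` must be a non-empty result_bundle")
  }
  summarize_bundle_results(bundle$results)
}

#' @export
print.result_bundle <- function(x, ...) {
  cat(sprintf("<result_bundle> %s, %d seeds\n", x$provenance$experiment,
              x$provenance$n_seeds))
  print(x$summary)
  invisible(x)
}

read_experiment_config <- function(path) {
  if (grepl("\\.json$", path)) {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else {
    yaml::read_yaml(path)
  }
}

write_result_bundle <- function(bundle, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  jsonlite::write_json(bundle$provenance, file.path(dir, "config.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  utils::write.csv(bundle$results, file.path(dir, "results.csv"),
                   row.names = FALSE)
  jsonlite::write_json(bundle$summary, file.path(dir, "summary.json"),
                       auto_unbox = TRUE, digits = NA, dataframe = "rows")
  writeLines(c(paste("experiment:", bundle$provenance$experiment),
               paste("seeds:", paste(bundle$provenance$seeds, collapse = " ")),
               paste("written:", format(Sys.time(), "%Y-%m-%dT%H:%M:%S"))),
             file.path(dir, "log.txt"))
  invisible(dir)
}
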