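# Shared fixtures built in code at test time. Trained networks are cached in
# this environment so that expensive cohorts are trained once per test run.
.fixture_cache <- new.env(parent = emptyenv())

fixture <- function(name, builder) {
  if (!exists(name, envir = .fixture_cache)) {
    assign(name, builder(), envir = .fixture_cache)
  }
  get(name, envir = .fixture_cache)
}

default_grid <- function() {
  fixture("grid", function() make_condition_grid())
}

# per-regime operating points at which the convergence criterion is met
# (see the methods vignette); used for all regime-level analyses
regime_cfg <- function(sigma0, seed) {
  if (sigma0 < 1) {
    train_config(learning_rate = 0.002, n_iterations = 20000, seed = seed)
  } else {
    train_config(n_iterations = 10000, seed = seed)
  }
}

# a small cohort of converged networks per regime, shared across acceptance
# and property tests
trained_cohort <- function(sigma0, n = 20) {
  key <- paste0("cohort_", sigma0, "_", n)
  fixture(key, function() {
    grid <- default_grid()
    lapply(seq_len(n), function(s) {
      net <- init_mlp(sigma0, seed = 1000 * sigma0 + s)
      train(net, grid, regime_cfg(sigma0, seed = 2000 + s))
    })
  })
}

# single quickly-trained rich network for unit tests that only need a
# trained object, not a converged one
quick_rich_net <- function() {
  fixture("quick_rich", function() {
    grid <- default_grid()
    train(init_mlp(0.01, seed = 7), grid,
          train_config(learning_rate = 0.005, n_iterations = 4000, seed = 7))
  })
}

network_models <- function() {
  fixture("network_models", function() {
    list(grid = model_rdm("grid"), orthogonal = model_rdm("orthogonal"),
         parallel = model_rdm("parallel"))
  })
}

# finite-difference gradient of the training loss, used as the oracle for
# the analytic backward pass
numeric_grad <- function(params, X, y, cfg, rdm_target_m, field, eps = 1e-6) {
  loss_at <- function(p) {
    richlazy:::mlp_gradients(p, X, y, cfg, rdm_target_m)$loss
  }
  g <- array(0, dim = dim(params[[field]]) %||% length(params[[field]]))
  for (i in seq_along(params[[field]])) {
    up <- params
    up[[field]][i] <- up[[field]][i] + eps
    dn <- params
    dn[[field]][i] <- dn[[field]][i] - eps
    g[i] <- (loss_at(up) - loss_at(dn)) / (2 * eps)
  }
  g
}

`%||%` <- function(x, y) if (is.null(x)) y else x
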