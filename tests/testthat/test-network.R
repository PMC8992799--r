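test_that("initialisation respects the weight-scale and bias conventions", {
  p <- init_mlp(0.01, seed = 1)
  expect_equal(dim(p$W_hidden), c(100, 27))
  expect_true(all(p$b_hidden == 0))
  expect_identical(p$b_out, 0)
  expect_equal(sd(p$W_hidden), 0.01, tolerance = 0.05) # 2700 draws
  expect_equal(sd(p$w_out), sqrt(1 / 100), tolerance = 0.3)
  expect_identical(init_mlp(0.5, seed = 9), init_mlp(0.5, seed = 9))
  expect_error(init_mlp(0), "positive")
})

test_that("the forward pass is a ReLU network with a linear readout", {
  grid <- default_grid()
  p <- init_mlp(1, seed = 2)
  fw <- forward(p, grid)
  expect_true(all(fw$hidden >= 0))
  expect_length(fw$output, 50)

  zero <- p
  zero$W_hidden[] <- 0
  zero$w_out[] <- 0
  expect_true(all(forward(zero, grid)$output == 0))

  doubled <- p
  doubled$w_out <- 2 * p$w_out
  expect_equal(forward(doubled, grid)$output - doubled$b_out,
               2 * (fw$output - p$b_out))
  expect_error(forward(p, matrix(0, 2, 5)), "width")
})

test_that("analytic gradients match finite differences for all loss terms", {
  grid <- default_grid()
  X <- input_matrix(grid)[1:10, ]
  y <- grid$target[1:10]
  p <- init_mlp(0.5, n_hidden = 8, seed = 3)
  tgt <- model_rdm("orthogonal")$matrix[1:10, 1:10]^2
  cases <- list(
    plain = train_config(seed = 1),
    l2 = train_config(l2_lambda = 0.01, seed = 1),
    rdm = train_config(rdm_beta = 0.05, rdm_target = tgt, seed = 1)
  )
  for (nm in names(cases)) {
    cfg <- cases[[nm]]
    tm <- if (cfg$rdm_beta > 0) tgt else NULL
    got <- richlazy:::mlp_gradients(p, X, y, cfg, tm)$grads
    for (field in c("W_hidden", "w_out", "b_hidden", "b_out")) {
      want <- numeric_grad(p, X, y, cfg, tm, field)
      expect_equal(as.vector(got[[field]]), as.vector(want),
                   tolerance = 1e-5,
                   label = paste(nm, field, "analytic gradient"))
    }
  }
})

test_that("two-layer gradients match finite differences", {
  grid <- default_grid()
  X <- input_matrix(grid)[1:8, ]
  y <- grid$target[1:8]
  p <- init_mlp(0.5, n_hidden = 6, n_hidden2 = 5, seed = 4)
  cfg <- train_config(rdm_beta = 0.02,
                      rdm_target = model_rdm("grid")$matrix[1:8, 1:8]^2,
                      seed = 1)
  got <- richlazy:::mlp_gradients(p, X, y, cfg, cfg$rdm_target)$grads
  for (field in c("W_hidden", "W_hidden2", "w_out")) {
    want <- numeric_grad(p, X, y, cfg, cfg$rdm_target, field)
    expect_equal(as.vector(got[[field]]), as.vector(want), tolerance = 1e-5,
                 label = paste("two-layer", field))
  }
})

test_that("sign accuracy matches its definition and the diagonal-rule benchmark", {
  expect_equal(sign_accuracy(c(1, -2, 3), c(1, -2, 3)), 1)
  expect_equal(sign_accuracy(c(-1, 2), c(1, -2)), 0)
  # zero targets excluded from the denominator
  expect_equal(sign_accuracy(c(1, -5, 2), c(1, 0, -3)), 0.5)
  expect_error(sign_accuracy(numeric(0), numeric(0)))

  grid <- default_grid()
  diag_out <- grid$x + grid$y
  expect_equal(sign_accuracy(diag_out, grid$target), 0.70)
})

test_that("training reduces the loss, reaches ceiling accuracy, and is reproducible", {
  grid <- default_grid()
  tr <- quick_rich_net()
  expect_lt(tail(tr$trace$loss, 1), tr$trace$loss[1])
  expect_equal(sign_accuracy(forward(tr$params, grid)$output, grid$target), 1)
  # trace recorded at the configured interval
  expect_equal(diff(tr$trace$iteration)[1], 100)

  cfg <- train_config(n_iterations = 300, seed = 5)
  a <- train(init_mlp(0.1, seed = 6), grid, cfg)
  b <- train(init_mlp(0.1, seed = 6), grid, cfg)
  expect_identical(a$params, b$params)
  expect_identical(a$trace$loss, b$trace$loss)
})

test_that("an L2 penalty shrinks the lazy endpoint weight norm", {
  grid <- default_grid()
  plain <- train(init_mlp(3, seed = 11), grid,
                 train_config(learning_rate = 0.002, n_iterations = 5000,
                              seed = 12))
  reg <- train(init_mlp(3, seed = 11), grid,
               train_config(learning_rate = 0.002, n_iterations = 5000,
                            l2_lambda = 0.05, seed = 12))
  expect_lt(weight_change_metrics(reg$trace)$norm_W_hidden,
            0.5 * weight_change_metrics(plain$trace)$norm_W_hidden)
})

test_that("weight-change metrics and convergence detection behave at the boundaries", {
  grid <- default_grid()
  tr0 <- train(init_mlp(1, seed = 13), grid,
               train_config(n_iterations = 100, seed = 13))
  expect_equal(exp(tr0$trace$log_dnorm_W_hidden[1]), 0) # untrained checkpoint

  flat_low <- tibble::tibble(iteration = seq(0, 900, 100), loss = rep(1e-4, 10))
  expect_equal(episodes_to_convergence(flat_low), 0)
  never <- tibble::tibble(iteration = seq(0, 900, 100), loss = rep(1, 10))
  expect_identical(episodes_to_convergence(never), Inf)
  mid <- tibble::tibble(iteration = seq(0, 900, 100),
                        loss = c(1, 1, 1, rep(0.001, 7)))
  expect_equal(episodes_to_convergence(mid), 300)
})

test_that("evaluation noise degrades accuracy monotonically up to Monte-Carlo error", {
  grid <- default_grid()
  tr <- quick_rich_net()
  nr <- noise_robustness(tr$params, grid, c(0, 0.5, 1, 2, 4), n_reps = 8,
                         seed = 14)
  expect_equal(nr$accuracy[1],
               sign_accuracy(forward(tr$params, grid)$output, grid$target))
  expect_true(all(diff(nr$accuracy) < 0.1)) # non-increasing within MC error
  expect_lt(nr$accuracy[5], nr$accuracy[1])
})

test_that("auxiliary RDM-loss training shapes the hidden geometry as targeted", {
  grid <- default_grid()
  norm_rdm_loss <- function(params, tm) {
    H <- forward(params, grid)$hidden
    G <- tcrossprod(H)
    rdm <- outer(diag(G), diag(G), "+") - 2 * G
    mean((rdm - tm)^2) / mean(tm^2)
  }
  run <- function(target_kind) {
    tm <- model_rdm(target_kind)$matrix^2
    tr <- train(init_mlp(0.1, seed = 2), grid,
                train_config(learning_rate = 0.005, n_iterations = 12000,
                             rdm_beta = 0.005, rdm_target = tm, seed = 2))
    c(acc = sign_accuracy(forward(tr$params, grid)$output, grid$target),
      rdm = norm_rdm_loss(tr$params, tm))
  }
  orth <- run("orthogonal")
  grd <- run("grid")
  par <- run("parallel")
  # orthogonal and grid targets: ceiling accuracy and a close RDM fit
  expect_gte(orth["acc"], 0.95)
  expect_lt(orth["rdm"], 0.1)
  expect_gte(grd["acc"], 0.95)
  expect_lt(grd["rdm"], 0.1)
  # a single hidden layer cannot jointly satisfy the task and a parallel
  # geometry: the RDM misfit stays several times larger
  expect_gt(par["rdm"], 2 * max(orth["rdm"], grd["rdm"]))
})
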