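test_that("choice probabilities follow the boundary-logistic-lapse form", {
  expect_equal(choice_probability(psycho_params(lapse = 1), 2, -1), 0.5)
  expect_equal(choice_probability(psycho_params(), 0, 5), 0.5) # on-boundary
  sharp <- psycho_params(slope = 500)
  expect_equal(choice_probability(sharp, 2, 0), 1, tolerance = 1e-6)
  expect_equal(choice_probability(sharp, -2, 0), 0, tolerance = 1e-6)
  # monotone in the signed distance for lapse < 1
  p <- psycho_params(angle = 30, slope = 1.5, lapse = 0.1)
  d_grid <- seq(-3, 3, 0.5)
  probs <- sapply(d_grid, function(b) choice_probability(p, b, 0))
  expect_true(all(diff(probs) > 0))
})

test_that("psychophysical fitting recovers planted parameters and is consistent", {
  truth <- list(A = psycho_params(angle = 15, offset = 0.3, slope = 2, lapse = 0.08),
                B = psycho_params(angle = 75, offset = -0.2, slope = 3, lapse = 0.05))
  biases <- sapply(1:4, function(s) {
    ch <- gen_synthetic_choices(truth, n_per_cell = 300, seed = s)
    fit <- fit_psychophysics(ch, n_starts = 15, seed = s)
    c(abs(fit$params$A$angle - 15), abs(fit$params$B$angle - 75),
      abs(fit$params$A$lapse - 0.08))
  })
  expect_lt(median(biases[1, ]), 5)
  expect_lt(median(biases[2, ]), 5)
  expect_lt(median(biases[3, ]), 0.05)

  # consistency: error shrinks with trial count
  err_at <- function(n) {
    median(sapply(1:3, function(s) {
      ch <- gen_synthetic_choices(truth, n_per_cell = n, seed = 100 + s)
      fit <- fit_psychophysics(ch, n_starts = 15, seed = s)
      abs(fit$params$A$angle - 15)
    }))
  }
  expect_lt(err_at(1000), err_at(50) + 2)

  # a deterministic factorized chooser has zero angular bias
  exact <- list(A = psycho_params(0, 0, 400, 0), B = psycho_params(90, 0, 400, 0))
  ch <- gen_synthetic_choices(exact, 50, seed = 5)
  fit <- fit_psychophysics(ch, n_starts = 15, seed = 5)
  expect_lt(fit$mean_angular_bias, 2)

  # a diagonal-rule chooser is 45 degrees off in each context
  diagc <- list(A = psycho_params(45, 0, 400, 0), B = psycho_params(45, 0, 400, 0))
  chd <- gen_synthetic_choices(diagc, 50, seed = 6)
  fitd <- fit_psychophysics(chd, n_starts = 15, seed = 6)
  expect_equal(unname(fitd$angular_bias), c(45, 45), tolerance = 3)
})

test_that("behavioral geometry fits rank factorised and linear choosers correctly", {
  gt <- list(A = psycho_params(0, 0, 5, 0), B = psycho_params(90, 0, 5, 0))
  ff <- fit_factorised_linear(gen_synthetic_choices(gt, 200, seed = 1))
  expect_gt(ff$axis_alignment, ff$linear_beta)

  diagp <- list(A = psycho_params(45, 0, 5, 0), B = psycho_params(45, 0, 5, 0))
  fd <- fit_factorised_linear(gen_synthetic_choices(diagp, 200, seed = 2))
  expect_gt(fd$linear_beta, fd$axis_alignment)

  # axis alignment rises monotonically from diagonal to factorized choosers
  scores <- sapply(c(45, 30, 15, 0), function(ang) {
    pars <- list(A = psycho_params(ang, 0, 5, 0),
                 B = psycho_params(90 - ang, 0, 5, 0))
    fit_factorised_linear(gen_synthetic_choices(pars, 400, seed = 3))$axis_alignment
  })
  expect_true(all(diff(scores) > 0))
})

test_that("axis alignment tracks planted neural orthogonality across agents", {
  # agents share one compression parameter between their neural geometry and
  # their choice boundaries: more compression of the irrelevant feature means
  # more orthogonal neural patterns and more factorized choices
  compr <- seq(0, 1, length.out = 6)
  scores <- sapply(seq_along(compr), function(i) {
    cg <- compr[i]
    g <- param_geometry(compr_irrel_A = cg, compr_irrel_B = cg)
    ps <- gen_planted_patterns(g, n_units = 15, noise_sd = 0.1, seed = i)
    orth_beta <- rdm_regression(
      euclidean_rdm(ps$patterns[1, , ]),
      list(orthogonal = model_rdm("orthogonal"), grid = model_rdm("grid"))
    )$betas["orthogonal"]
    ang <- 45 * (1 - cg)
    pars <- list(A = psycho_params(ang, 0, 5, 0.05),
                 B = psycho_params(90 - ang, 0, 5, 0.05))
    axis <- fit_factorised_linear(
      gen_synthetic_choices(pars, 150, seed = i)
    )$axis_alignment
    c(orth = unname(orth_beta), axis = axis)
  })
  expect_gt(cor(scores["orth", ], scores["axis", ]), 0.8)
})

test_that("the context-blind diagonal strategy scores exactly 70 percent", {
  expect_identical(diagonal_strategy_accuracy(), 0.7)
  expect_equal(diagonal_strategy_accuracy() * 40, 28)
  # symmetric across contexts
  des <- richlazy:::design_tbl()
  rel <- ifelse(des$context == "A", des$b, des$l)
  keep <- rel != 0
  ok <- (des$b + des$l > 0)[keep] == (rel[keep] > 0)
  expect_equal(mean(ok[des$context[keep] == "A"]),
               mean(ok[des$context[keep] == "B"]))
})
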