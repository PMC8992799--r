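test_that("blob images are grid-centred Gaussians with the expected overlap structure", {
  img <- make_blob_image(0, 0)
  expect_equal(dim(img), c(5, 5))
  expect_true(all(img >= 0))
  expect_equal(which(img == max(img)), 13) # central pixel
  expect_equal(max(img), 1) # unit-max normalization

  adjacent <- sum(make_blob_image(0, 0) * make_blob_image(1, 0))
  expect_gt(adjacent, 0) # neighbouring blobs overlap
  corners <- sum(make_blob_image(-2, -2) * make_blob_image(2, 2))
  expect_lt(corners, adjacent)

  # deterministic: no RNG involved
  expect_identical(make_blob_image(1, -2), make_blob_image(1, -2))
  expect_error(make_blob_image(3, 0), "grid")
  expect_error(make_blob_image(0, 0, blob_sd = -1), "positive")

  img_sum <- make_blob_image(0, 0, normalize = "sum")
  expect_equal(sum(img_sum), 1)
})

test_that("the condition grid enumerates the full two-context design", {
  grid <- make_condition_grid()
  expect_equal(nrow(grid), 50)
  expect_true(all(lengths(grid$input) == 27))
  # one-hot context channels
  ctx <- t(sapply(grid$input, function(v) v[26:27]))
  expect_true(all(rowSums(ctx) == 1))
  expect_true(all(ctx[grid$context == "A", 1] == 1))
  # target is the relevant feature
  expect_equal(grid$target[grid$context == "A"], grid$x[grid$context == "A"])
  expect_equal(grid$target[grid$context == "B"], grid$y[grid$context == "B"])
  expect_equal(grid$target[grid$context == "A" & grid$x == 2 & grid$y == -1], 2)
  expect_equal(grid$target[grid$context == "B" & grid$x == 2 & grid$y == -1], -1)
  # pixel block identical for the same (x, y) across contexts
  a <- grid[grid$context == "A", ]
  b <- grid[grid$context == "B", ]
  for (i in c(1, 13, 25)) {
    expect_equal(a$input[[i]][1:25], b$input[[i]][1:25])
  }
})

test_that("planted-geometry patterns are isometric embeddings plus noise", {
  ps <- gen_planted_patterns("orthogonal", n_units = 12, n_runs = 2,
                             noise_sd = 0, seed = 3)
  target <- model_rdm("orthogonal")$matrix
  for (r in 1:2) {
    got <- euclidean_rdm(ps$patterns[r, , ])$matrix
    expect_equal(got, target, tolerance = 1e-10)
  }
  # grid geometry regresses onto the grid model with zero residual
  ps_grid <- gen_planted_patterns("grid", n_units = 10, seed = 4)
  fit <- rdm_regression(euclidean_rdm(ps_grid$patterns[1, , ]),
                        list(grid = model_rdm("grid")))
  expect_equal(fit$rss, 0, tolerance = 1e-16)
  expect_equal(unname(fit$betas), 1, tolerance = 1e-8)

  # bit-identical under the same seed, different under another
  again <- gen_planted_patterns("orthogonal", n_units = 12, n_runs = 2,
                                noise_sd = 0, seed = 3)
  expect_identical(ps$patterns, again$patterns)
  expect_error(gen_planted_patterns("grid", n_units = 2, seed = 1), "at least 3")
  expect_error(gen_planted_patterns("grid", n_units = 10, n_runs = 0, seed = 1))
})

test_that("synthetic choices follow the generating psychophysical model", {
  # lapse-dominated: p(plant) near 0.5 everywhere
  lapsey <- gen_synthetic_choices(psycho_params(lapse = 1), 400, seed = 1)
  cm <- choice_matrix(lapsey)
  expect_true(all(abs(cm$p_plant - 0.5) < 0.12))
  expect_true(all(cm$n_total == 400))

  # near-deterministic chooser off the boundary
  sharp <- gen_synthetic_choices(psycho_params(angle = 0, slope = 50), 50, seed = 2)
  cm2 <- choice_matrix(sharp)
  off <- cm2[cm2$b != 0, ]
  expect_true(all(off$p_plant[off$b > 0] == 1))
  expect_true(all(off$p_plant[off$b < 0] == 0))

  expect_error(gen_synthetic_choices(psycho_params(), 0, seed = 1), "at least 1")
  expect_error(psycho_params(lapse = 1.5), "lapse")
})

test_that("pseudo-populations are balanced and carry the planted geometry", {
  pop <- gen_pseudo_population("orthogonal", n_units = 40, n_trials = 1440,
                               seed = 5)
  counts <- table(pop$trial_labels$motion, pop$trial_labels$color,
                  pop$trial_labels$context)
  expect_true(all(counts == 20)) # 1440 / 72
  expect_equal(nrow(pop$trials), 1440)

  lv <- (1:6 - 3.5) / 2.5
  mods <- list(grid = model_rdm("grid", b_levels = lv, l_levels = lv),
               orthogonal = model_rdm("orthogonal", b_levels = lv, l_levels = lv))
  cm <- condition_means(pop)
  # noiseless orthogonal tuning is an isometric embedding: residual zero
  fit <- rdm_regression(euclidean_rdm(cm$means), mods["orthogonal"])
  expect_lt(fit$rss / fit$n_pairs, 1e-10)
  expect_equal(unname(fit$betas), 1, tolerance = 1e-8)

  # color-only tuning: the color-only model beats the orthogonal model
  pop_c <- gen_pseudo_population("color_only", n_units = 30, n_trials = 720,
                                 seed = 6)
  mods_c <- c(mods, list(color_only = model_rdm("leafiness", b_levels = lv,
                                                l_levels = lv)))
  fit_c <- rdm_regression(euclidean_rdm(condition_means(pop_c)$means), mods_c)
  expect_gt(fit_c$betas["color_only"], fit_c$betas["orthogonal"])

  expect_error(gen_pseudo_population("orthogonal", n_trials = 100, seed = 1),
               "divisible")
})
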