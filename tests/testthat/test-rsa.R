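test_that("Euclidean RDMs are metric and unit-permutation invariant", {
  m <- euclidean_rdm(rbind(c(0, 0), c(3, 4), c(0, 0)))$matrix
  expect_equal(m[1, 2], 5)
  expect_equal(m[1, 3], 0)
  expect_equal(m, t(m))
  expect_true(all(diag(m) == 0))

  pat <- matrix(rnorm(40), 8, 5)
  expect_equal(euclidean_rdm(pat)$matrix,
               euclidean_rdm(pat[, c(3, 1, 5, 2, 4)])$matrix)
  expect_error(euclidean_rdm(rbind(c(1, NA), c(0, 0))), "finite")
})

test_that("cross-validated Pearson RDMs exclude within-run blocks", {
  pat <- matrix(rnorm(30), 5, 6)
  rdm <- crossval_pearson_rdm(list(pat, pat))
  expect_equal(rdm$matrix[6, 1], 0, tolerance = 1e-12) # identical across runs
  neg <- crossval_pearson_rdm(list(pat, -pat))
  expect_equal(neg$matrix[6, 1], 2, tolerance = 1e-12) # anti-correlated
  # within-run entries are missing and never reach the regression
  expect_true(all(is.na(rdm$matrix[1:5, 1:5])))
  fit <- rdm_regression(rdm, list(model = euclidean_rdm(pat)))
  expect_equal(fit$n_pairs, 25) # only the 5x5 cross-run block
  expect_warning(crossval_pearson_rdm(list(rbind(pat, 1), rbind(pat, 1))),
                 "constant")
})

test_that("model feature matrices encode the seven candidate geometries", {
  grid <- model_rdm("grid")$matrix
  des <- richlazy:::design_tbl()
  # adjacent on one feature: unit distance
  i <- which(des$context == "A" & des$b == 0 & des$l == 0)
  j <- which(des$context == "A" & des$b == 1 & des$l == 0)
  expect_equal(grid[i, j], 1)
  # grid RDM invariant to swapping the two features
  perm <- order(des$context, des$l, des$b)
  expect_equal(grid, grid[perm, perm])

  orth <- model_rdm("orthogonal")$matrix
  # same-context pair differing only on the irrelevant feature collapses
  k <- which(des$context == "A" & des$b == 0 & des$l == 2)
  expect_equal(orth[i, k], 0)
  # cross-context pair with relevant coordinates 2 and 2
  a2 <- which(des$context == "A" & des$b == 2 & des$l == 0)
  b2 <- which(des$context == "B" & des$b == 0 & des$l == 2)
  expect_equal(orth[a2, b2], 3)

  # the parallel rotation is an isometry within each task
  par <- model_rdm("parallel")$matrix
  a_rows <- which(des$context == "A")
  expect_equal(par[a_rows, a_rows], orth[a_rows, a_rows])
  # and maps context A's relevant axis onto context B's
  a_same <- which(des$context == "A" & des$b == 2 & des$l == 0)
  b_same <- which(des$context == "B" & des$b == 0 & des$l == 2)
  expect_equal(par[a_same, b_same], 1) # only the context offset remains

  for (kind in c("grid", "orthogonal", "parallel", "rotated_grid",
                 "branchiness", "leafiness", "diagonal")) {
    m <- model_rdm(kind)$matrix
    expect_equal(m, t(m), label = paste(kind, "symmetric"))
    expect_true(all(diag(m) == 0), label = paste(kind, "zero diagonal"))
  }
  expect_error(model_feature_matrix("bogus"))
})

test_that("the parameterised geometry reproduces the named models at its limits", {
  expect_equal(model_rdm(param_geometry())$matrix,
               model_rdm("grid")$matrix, tolerance = 1e-12)
  orth_g <- param_geometry(compr_irrel_A = 1, compr_irrel_B = 1)
  expect_equal(model_rdm(orth_g)$matrix, model_rdm("orthogonal")$matrix,
               tolerance = 1e-12)
  par_g <- param_geometry(compr_irrel_A = 1, compr_irrel_B = 1, rotation = 90)
  expect_equal(model_rdm(par_g)$matrix, model_rdm("parallel")$matrix,
               tolerance = 1e-12)
  expect_error(param_geometry(compr_rel_A = 2), "0, 1")
  expect_error(param_geometry(rotation = 120), "-90")
})

test_that("RDM regression equals the closed-form normal-equations oracle", {
  zs <- function(v) (v - mean(v)) / sqrt(mean((v - mean(v))^2))
  mods <- lapply(c("grid", "orthogonal", "parallel", "rotated_grid",
                   "branchiness", "leafiness", "diagonal"), model_rdm)
  names(mods) <- paste0("m", 1:7)
  Xz <- sapply(mods, function(m) zs(m$matrix[lower.tri(m$matrix)]))
  set.seed(42)
  for (rep in 1:5) {
    w <- rnorm(7)
    neural <- Reduce(`+`, Map(function(m, wi) wi * m$matrix, mods, w))
    neural <- neural + 3 # constant offsets must not matter
    fit <- rdm_regression(neural, mods)
    y <- zs(neural[lower.tri(neural)])
    oracle <- solve(crossprod(cbind(1, Xz)), crossprod(cbind(1, Xz), y))
    expect_equal(unname(fit$betas), unname(oracle[-1]), tolerance = 1e-8)
  }
  # single-model identity: beta 1, zero residual
  one <- rdm_regression(mods$m1$matrix, mods["m1"])
  expect_equal(unname(one$betas), 1, tolerance = 1e-12)
  expect_lt(one$rss, 1e-16)
  # shift invariance
  shifted <- rdm_regression(mods$m1$matrix + 10, mods)
  base <- rdm_regression(mods$m1$matrix, mods)
  expect_equal(shifted$betas, base$betas, tolerance = 1e-8)
  # collinear design is refused with the culprits named
  expect_error(rdm_regression(mods$m1$matrix,
                              list(a = mods$m2, b = mods$m2)), "collinear")
})

test_that("the parameterised fit recovers planted geometries", {
  orth <- model_rdm("orthogonal")
  fit <- fit_param_geometry(orth, n_restarts = 12, seed = 1)
  expect_lt(fit$cost_best, 1e-6)
  expect_equal(fit$best$compr_irrel_A, 1, tolerance = 0.02)
  expect_equal(fit$best$compr_irrel_B, 1, tolerance = 0.02)
  expect_lt(fit$best$compr_rel_A, 0.02)
  expect_lt(fit$best$compr_rel_B, 0.02)
  expect_lt(abs(fit$best$rotation), 2)

  grd <- fit_param_geometry(model_rdm("grid"), n_restarts = 12, seed = 2)
  expect_lt(grd$cost_best, 1e-6)
  expect_lt(max(grd$best$compr_rel_A, grd$best$compr_irrel_A,
                grd$best$compr_rel_B, grd$best$compr_irrel_B), 0.02)

  # planted compression with moderate noise recovers within tolerance
  g0 <- param_geometry(compr_rel_A = 0.2, compr_irrel_A = 0.8,
                       compr_rel_B = 0.1, compr_irrel_B = 0.7,
                       rotation = 0, context_offset = 1.5)
  errs <- sapply(1:5, function(s) {
    ps <- gen_planted_patterns(g0, n_units = 15, noise_sd = 0.05, seed = s)
    f <- fit_param_geometry(euclidean_rdm(ps$patterns[1, , ]),
                            n_restarts = 8, seed = s)
    max(abs(unlist(f$best[1:4]) - unlist(g0[1:4])))
  })
  expect_lt(median(errs), 0.1)

  # best-of-n objective is non-increasing in the number of restarts
  f4 <- fit_param_geometry(orth, n_restarts = 4, seed = 9)
  f12 <- fit_param_geometry(orth, n_restarts = 12, seed = 9)
  expect_lte(f12$cost_best, f4$cost_best)
})

test_that("the compression index is a signed log-ratio", {
  expect_equal(compression_index(param_geometry(compr_rel_A = 0.3,
                                                compr_irrel_A = 0.3,
                                                compr_rel_B = 0.3,
                                                compr_irrel_B = 0.3)), 0)
  g <- param_geometry(compr_rel_A = 0.2, compr_irrel_A = 0.2 * exp(1),
                      compr_rel_B = 0.2, compr_irrel_B = 0.2 * exp(1))
  expect_equal(compression_index(g), 1, tolerance = 1e-12)
  expect_warning(compression_index(param_geometry()), "clipped")
})

test_that("the permutation test detects planted geometry and respects its bounds", {
  lv <- (1:6 - 3.5) / 2.5
  mods <- list(grid = model_rdm("grid", b_levels = lv, l_levels = lv),
               orthogonal = model_rdm("orthogonal", b_levels = lv, l_levels = lv))
  pop <- gen_pseudo_population(
    list(p_task_specific = 1, noise_sd = 0.3), n_units = 30, n_trials = 720,
    seed = 8
  )
  res <- permutation_test_rsa(pop, models = mods, n_perm = 199, seed = 8)
  expect_lt(res$p_value[res$model == "orthogonal"], 0.05)
  expect_true(all(res$p_value >= 1 / 200 & res$p_value <= 1))
  expect_error(permutation_test_rsa(pop, models = mods, n_perm = 10, seed = 1),
               "at least 100")
})
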