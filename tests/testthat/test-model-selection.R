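test_that("fold assignment is balanced, complete and deterministic", {
  f <- make_folds(10, 5, seed = 4)
  expect_equal(sort(unique(f$assignment)), 1:5)
  expect_true(all(table(f$assignment) == 2))
  expect_identical(make_folds(10, 5, seed = 4)$assignment, f$assignment)
  expect_false(identical(make_folds(10, 5, seed = 5)$assignment,
                         f$assignment))
  f2 <- make_folds(23, 5, seed = 1)
  expect_lte(diff(range(table(f2$assignment))), 1)
  expect_error(make_folds(3, 5), "cannot make")
})

test_that("stratified folds balance the stratification variable", {
  z <- sort(rnorm(60, mean = 60, sd = 10))
  devs <- c()
  for (s in 1:100) {
    f <- make_folds(60, 5, seed = s, stratify_on = z)
    expect_lte(diff(range(table(f$assignment))), 1)
    devs <- c(devs, vapply(1:5, function(k)
      abs(mean(z[f$assignment == k]) - mean(z)), numeric(1)))
  }
  expect_true(all(devs < sd(z)))
})

test_that("cv score is 1 for perfectly aligned blocks and 0 when shrunk away", {
  # X column, Y column and Z are affine copies of one 0/1/2 pattern, so
  # all three held-out correlations are exactly 1 in every fold
  set.seed(12)
  g <- sample(rep(c(0, 1, 2), 10))
  d <- oscca_dataset(X = matrix(g * 0.1 + 0.4,
                                dimnames = list(NULL, "x1")),
                     Y = matrix(g), Z = g * 10 + 50)
  folds <- make_folds(30, 5, seed = 2)
  s <- cv_score(d, 0, 0, folds = folds)
  expect_equal(s, 1, tolerance = 1e-10)

  s0 <- cv_score(d, 1e6, 1e6, folds = folds)
  expect_equal(s0, 0)
})

test_that("cv score equals an independently assembled correlation average", {
  sim <- sim_dataset(sim_config(n = 40, p = 5, q = 4, s_x = 2, s_y = 2,
                                seed = 6))
  d <- sim$dataset
  folds <- make_folds(d$n, 5, seed = 3)
  lu <- 2; lv <- 2
  s <- cv_score(d, lu, lv, folds = folds)

  # independent reassembly: refit per fold and average the 15 correlations
  scores <- c()
  for (i in 1:5) {
    tr <- dataset_rows(d, folds$assignment != i)
    te <- dataset_rows(d, folds$assignment == i)
    fit <- oscca(tr, lambda_u = lu, lambda_v = lv)
    st <- impute_and_standardize(tr$X)
    Xte <- impute_and_standardize(te$X, st$stats)$M
    st_y <- impute_and_standardize(tr$Y)
    Yte <- impute_and_standardize(te$Y, st_y$stats)$M
    st_z <- impute_and_standardize(matrix(tr$Z))
    zte <- impute_and_standardize(matrix(te$Z), st_z$stats)$M[, 1]
    xu <- drop(Xte %*% fit$u); yv <- drop(Yte %*% fit$v)
    cors <- c(if (sd(xu) > 0 && sd(yv) > 0) cor(xu, yv) else 0,
              if (sd(xu) > 0) cor(xu, zte) else 0,
              if (sd(yv) > 0) cor(yv, zte) else 0)
    scores <- c(scores, mean(cors))
  }
  expect_equal(s, mean(scores), tolerance = 1e-8)
  expect_true(abs(s) <= 1)
})

test_that("tuning returns the only pair of a singleton grid, is deterministic, and never picks loading-killing penalties", {
  sim <- sim_dataset(sim_config(n = 50, p = 8, q = 6, s_x = 3, s_y = 3,
                                seed = 9))
  d <- sim$dataset
  g1 <- list(lambda_u = 1, lambda_v = 1)
  t1 <- tune_lambdas(d, grid = g1, seed = 2)
  expect_equal(unname(t1$best), c(1, 1))

  grid <- list(lambda_u = c(0.01, 3, 1e5), lambda_v = c(0.01, 3, 1e5))
  t2 <- tune_lambdas(d, grid = grid, seed = 2)
  expect_lt(t2$best[["lambda_u"]], 1e5)
  expect_lt(t2$best[["lambda_v"]], 1e5)
  t3 <- tune_lambdas(d, grid = grid, seed = 2)
  expect_identical(t2$table, t3$table)
  expect_identical(t2$best, t3$best)

  expect_error(tune_lambdas(d, grid = list(lambda_u = 1e7,
                                           lambda_v = 1e7), seed = 2),
               "zero loadings")
})

test_that("feature selection reads non-zero loadings and consensus intersects", {
  sol <- structure(list(u = c(0, 0.3, 0), v = c(0.1, 0)), class = "oscca")
  sel <- selected_features(sol)
  expect_equal(sel$imaging, 2L)
  expect_equal(sel$genetic, 1L)
  sol0 <- structure(list(u = c(0, 0), v = c(0, 0)), class = "oscca")
  expect_length(selected_features(sol0)$imaging, 0)

  expect_equal(consensus_features(list(c(1, 2, 3), c(2, 3, 4), c(2, 3))),
               c(2, 3))
  expect_equal(consensus_features(list(c(1, 2), c(1, 2))), c(1, 2))
  expect_length(consensus_features(list(1:2, 3:4)), 0)
  # adding a selection never grows the consensus
  sels <- list(c(1, 2, 5), c(2, 5, 7))
  expect_true(all(consensus_features(c(sels, list(c(2, 9)))) %in%
                    consensus_features(sels)))
})

test_that("nested CV is reproducible and leaks nothing from test folds", {
  sim <- sim_dataset(sim_config(n = 60, p = 10, q = 8, s_x = 3, s_y = 3,
                                seed = 14))
  d <- sim$dataset
  r1 <- oscca_nested_cv(d, seed = 7)
  r2 <- oscca_nested_cv(d, seed = 7)
  expect_identical(r1$fold_metrics, r2$fold_metrics)
  expect_identical(r1$consensus, r2$consensus)
  expect_identical(lapply(r1$folds, `[[`, "fit"),
                   lapply(r2$folds, `[[`, "fit"))

  # mutation test: perturbing a held-out subject must not change that
  # fold's fitted loadings or selection
  fold1_test <- r1$folds[[1]]$test_idx
  d_mut <- d
  d_mut$X[fold1_test[1], ] <- d_mut$X[fold1_test[1], ] + 100
  d_mut$Z[fold1_test[1]] <- d_mut$Z[fold1_test[1]] + 50
  r_mut <- oscca_nested_cv(d_mut, seed = 7)
  expect_identical(r_mut$folds[[1]]$fit$u, r1$folds[[1]]$fit$u)
  expect_identical(r_mut$folds[[1]]$fit$v, r1$folds[[1]]$fit$v)
  expect_identical(r_mut$folds[[1]]$selected, r1$folds[[1]]$selected)
})

test_that("nested CV recovers planted imaging structure and stays honest on noise", {
  # strong planted signal: consensus imaging set overlaps the truth
  sim <- sim_dataset(sim_config(seed = 31))
  r <- oscca_nested_cv(sim$dataset, seed = 31)
  jac <- length(intersect(r$consensus$imaging, sim$support_x)) /
    length(union(r$consensus$imaging, sim$support_x))
  expect_gte(jac, 0.5)
  expect_gt(r$metrics$r[r$metrics$kind == "oscca_combined"], 0.5)

  # pure-noise target: small average test correlation (a few seeds)
  rs <- vapply(1:4, function(s) {
    simn <- sim_dataset(sim_config(n = 60, p = 10, q = 8, s_x = 3,
                                   s_y = 3, delta_z = 0, seed = s))
    rn <- oscca_nested_cv(simn$dataset, seed = s)
    rn$metrics$r[rn$metrics$kind == "oscca_combined"]
  }, numeric(1))
  expect_lt(abs(mean(rs, na.rm = TRUE)), 0.35)
})
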