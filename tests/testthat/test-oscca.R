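test_that("soft-thresholding implements the l1 proximal operator", {
  expect_equal(soft_threshold(c(3, -1, 0.5), 1), c(2, 0, 0))
  a <- c(-2.5, 0.1, 4)
  expect_equal(soft_threshold(a, 0), a)
  expect_equal(soft_threshold(a, 4), c(0, 0, 0))
  expect_error(soft_threshold(a, -1), "non-negative")
})

test_that("penalized objective matches independent term-by-term arithmetic", {
  expect_equal(oscca_objective(0, 0, matrix(1, 2), matrix(1, 2), c(1, 1)),
               0)
  # hand-computable 2x1x1 instance
  X <- matrix(c(1, -1), 2)
  Y <- matrix(c(1, -1), 2)
  Z <- c(1, -1)
  expect_equal(oscca_objective(1, 1, X, Y, Z, w = 1), -6)

  set.seed(5)
  for (rep in 1:10) {
    n <- sample(4:12, 1); p <- sample(1:4, 1); q <- sample(1:4, 1)
    X <- matrix(rnorm(n * p), n); Y <- matrix(rnorm(n * q), n)
    Z <- rnorm(n); u <- rnorm(p); v <- rnorm(q)
    w <- runif(1, 0, 2); lu <- runif(1); lv <- runif(1)
    expect_equal(oscca_objective(u, v, X, Y, Z, w, lu, lv),
                 objective_by_hand(u, v, X, Y, Z, w, lu, lv),
                 tolerance = 1e-10)
  }
  expect_error(oscca_objective(c(1, 2), 1, matrix(1, 2), matrix(1, 2),
                               c(1, 1)), "dimension")
})

test_that("block update soft-thresholds then normalizes", {
  g <- c(3, 1)
  expect_equal(update_loading(g, 0), g / sqrt(10))
  expect_equal(update_loading(g, 5), c(0, 0))
  expect_equal(update_loading(g, 1), c(1, 0))
})

test_that("solver recovers trivial optima", {
  # perfectly aligned one-dimensional blocks
  z <- as.vector(scale(c(1, 3, -2, 0.5, 4, -1)))
  fit <- oscca(matrix(z), matrix(z), z, standardize = FALSE)
  expect_equal(unname(fit$u), 1, tolerance = 1e-8)
  expect_equal(unname(fit$v), 1, tolerance = 1e-8)

  # penalties above every gradient force the zero solution
  b <- random_blocks(12, 3, 3, seed = 2)
  fit0 <- oscca(b$X, b$Y, b$Z, lambda_u = 1e4, lambda_v = 1e4,
                standardize = FALSE)
  expect_equal(unname(fit0$u), rep(0, 3))
  expect_equal(unname(fit0$v), rep(0, 3))
  expect_equal(fit0$objective, 0)

  expect_error(oscca(matrix(c(1, NA), 2), matrix(c(1, 2), 2), c(1, 2),
                     standardize = FALSE), "non-finite")
})

test_that("solver finds a planted rank-1 support at moderate penalties", {
  set.seed(21)
  n <- 30
  L <- rnorm(n)
  X <- cbind(L + rnorm(n, sd = 0.2), matrix(rnorm(2 * n), n))
  Y <- cbind(L + rnorm(n, sd = 0.2), matrix(rnorm(2 * n), n))
  Z <- L + rnorm(n, sd = 0.2)
  fit <- oscca(scale(X), scale(Y), as.vector(scale(Z)),
               lambda_u = 15, lambda_v = 15, standardize = FALSE)
  expect_equal(which(fit$u != 0), 1)
  expect_equal(which(fit$v != 0), 1)
  # and it matches the derivative-free reference search
  o <- oscca_oracle(scale(X), scale(Y), as.vector(scale(Z)),
                    lambda_u = 15, lambda_v = 15, n_restarts = 3000,
                    seed = 4)
  expect_lt(abs(fit$objective - o$value), 1e-3)
})

test_that("objective trajectory is non-increasing on random instances", {
  set.seed(33)
  for (rep in 1:100) {
    n <- sample(6:25, 1); p <- sample(2:8, 1); q <- sample(2:8, 1)
    b <- random_blocks(n, p, q, seed = rep + 500)
    fit <- oscca(b$X, b$Y, b$Z, lambda_u = runif(1, 0, 3),
                 lambda_v = runif(1, 0, 3), w = runif(1, 0, 2),
                 standardize = FALSE)
    tr <- fit$objective_trajectory
    if (length(tr) > 1) expect_true(all(diff(tr) <= 1e-9))
  }
})

test_that("with w = 0 the solver reduces to two-way PMD sparse CCA", {
  set.seed(8)
  for (rep in 1:20) {
    n <- sample(10:30, 1); p <- sample(2:6, 1); q <- sample(2:6, 1)
    b <- random_blocks(n, p, q, seed = rep + 900)
    lu <- runif(1, 0, 2); lv <- runif(1, 0, 2)
    fit <- oscca(b$X, b$Y, b$Z, lambda_u = lu, lambda_v = lv, w = 0,
                 standardize = FALSE)
    ref <- pmd_rank1(b$X, b$Y, lu, lv)
    # align the joint sign (indeterminate at w = 0)
    if (sum(ref$u * fit$u) < 0) {
      ref$u <- -ref$u; ref$v <- -ref$v
    }
    expect_equal(unname(fit$u), ref$u, tolerance = 1e-6)
    expect_equal(unname(fit$v), ref$v, tolerance = 1e-6)
    expect_equal(fit$objective, ref$objective, tolerance = 1e-6)
  }
})

test_that("column permutations permute the matching loading vector", {
  b <- random_blocks(15, 4, 3, seed = 77)
  fit <- oscca(b$X, b$Y, b$Z, lambda_u = 0.5, lambda_v = 0.5,
               standardize = FALSE)
  perm <- c(3, 1, 4, 2)
  fit_p <- oscca(b$X[, perm], b$Y, b$Z, lambda_u = 0.5, lambda_v = 0.5,
                 standardize = FALSE)
  expect_equal(unname(fit_p$u), unname(fit$u[perm]), tolerance = 1e-8)
  expect_equal(unname(fit_p$v), unname(fit$v), tolerance = 1e-8)
  permq <- c(2, 3, 1)
  fit_q <- oscca(b$X, b$Y[, permq], b$Z, lambda_u = 0.5, lambda_v = 0.5,
                 standardize = FALSE)
  expect_equal(unname(fit_q$v), unname(fit$v[permq]), tolerance = 1e-8)
})

test_that("sign is indeterminate at w = 0 and fixed by the convention", {
  b <- random_blocks(15, 3, 3, seed = 101)
  fit <- oscca(b$X, b$Y, b$Z, w = 0, standardize = FALSE)
  # flipping both loadings leaves the unpenalized two-block objective
  # unchanged
  expect_equal(
    oscca_objective(fit$u, fit$v, b$X, b$Y, b$Z, w = 0),
    oscca_objective(-fit$u, -fit$v, b$X, b$Y, b$Z, w = 0))
  # the reported solution follows corr(Xu, Z) >= 0
  expect_gte(cor(drop(b$X %*% fit$u), b$Z), 0)
})

test_that("support size of u is non-increasing in its penalty", {
  b <- random_blocks(25, 6, 4, seed = 55)
  sizes <- vapply(c(0, 0.5, 1, 2, 4, 8, 16), function(l) {
    sum(oscca(b$X, b$Y, b$Z, lambda_u = l, lambda_v = 0.5,
              standardize = FALSE)$u != 0)
  }, numeric(1))
  expect_true(all(diff(sizes) <= 0))
})

test_that("reference search lower-bounds feasible pairs and hits zero", {
  b <- random_blocks(10, 3, 3, seed = 13)
  o <- oscca_oracle(b$X, b$Y, b$Z, lambda_u = 100, lambda_v = 100,
                    n_restarts = 500, seed = 1)
  expect_equal(o$value, 0)   # heavy shrinkage: zero loadings optimal
  o2 <- oscca_oracle(b$X, b$Y, b$Z, lambda_u = 0.3, lambda_v = 0.3,
                     n_restarts = 2000, seed = 2)
  set.seed(99)
  for (rep in 1:20) {
    u <- rnorm(3); u <- u / sqrt(sum(u^2))
    v <- rnorm(3); v <- v / sqrt(sum(v^2))
    expect_lte(o2$value,
               oscca_objective(u, v, b$X, b$Y, b$Z, 1, 0.3, 0.3) + 1e-12)
  }
})

test_that("fit is deterministic and serializes to JSON", {
  b <- random_blocks(20, 4, 4, seed = 3)
  f1 <- oscca(b$X, b$Y, b$Z, lambda_u = 1, lambda_v = 1,
              standardize = FALSE)
  f2 <- oscca(b$X, b$Y, b$Z, lambda_u = 1, lambda_v = 1,
              standardize = FALSE)
  expect_identical(f1$u, f2$u)
  expect_identical(f1$objective_trajectory, f2$objective_trajectory)
  f <- withr::local_tempfile(fileext = ".json")
  write_oscca_json(f1, f)
  back <- jsonlite::read_json(f, simplifyVector = TRUE)
  expect_equal(unlist(back$u), f1$u, tolerance = 1e-12)
  expect_equal(back$objective, f1$objective, tolerance = 1e-12)
})
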