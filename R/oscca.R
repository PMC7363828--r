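#' Elementwise soft-thresholding
#'
#' The proximal operator of the l1 penalty:
#' \code{sign(a) * pmax(abs(a) - t, 0)}.
#'
#' @param a numeric vector.
#' @param t non-negative threshold.
#' @return Shrunken vector of the same length.
#' @export
soft_threshold <- function(a, t) {
  if (t < 0) stop("threshold must be non-negative")
  sign(a) * pmax(abs(a) - t, 0)
}

#' Penalized objective of objective-specific sparse CCA
#'
#' Evaluates the minimized criterion
#' \deqn{-u' X' Y v - w\, v' Y' Z - w\, Z' X u
#'       + \lambda_u \|u\|_1 + \lambda_v \|v\|_1}
#' for given loading vectors on (column-standardized) data blocks.
#'
#' @param u,v loading vectors of length \code{ncol(X)} and \code{ncol(Y)}.
#' @param X,Y,Z standardized data blocks sharing rows.
#' @param w positive scalar weight on the two target terms.
#' @param lambda_u,lambda_v non-negative l1 penalties.
#' @return The scalar objective value.
#' @export
oscca_objective <- function(u, v, X, Y, Z, w = 1,
                            lambda_u = 0, lambda_v = 0) {
  if (length(u) != ncol(X) || length(v) != ncol(Y) ||
      nrow(X) != nrow(Y) || nrow(X) != length(Z))
    stop("dimension mismatch between loadings and data blocks")
  obj_core(u, v, crossprod(X, Y), w * crossprod(X, Z)[, 1],
           w * crossprod(Y, Z)[, 1], lambda_u, lambda_v)
}

# Objective from precomputed cross-products: C = X'Y, a = w X'Z, b = w Y'Z.
obj_core <- function(u, v, C, a, b, lambda_u, lambda_v) {
  -drop(u %*% C %*% v) - sum(b * v) - sum(a * u) +
    lambda_u * sum(abs(u)) + lambda_v * sum(abs(v))
}

#' Closed-form block update of one loading vector
#'
#' Minimizing the penalized objective over one loading with the other block
#' fixed, subject to the unit l2 ball, gives soft-threshold-then-normalize:
#' \code{S(g, lambda) / ||S(g, lambda)||} (the zero vector if everything is
#' shrunk away).
#'
#' @param g gradient vector of the bilinear terms with respect to this
#'   block (\code{X'Yv + w X'Z} for u, \code{Y'Xu + w Y'Z} for v).
#' @param lambda non-negative l1 penalty.
#' @return A vector with l2 norm 1 or 0.
#' @export
update_loading <- function(g, lambda) {
  s <- soft_threshold(g, lambda)
  nrm <- sqrt(sum(s^2))
  if (nrm == 0) s else s / nrm
}

#' Fit objective-specific sparse canonical correlation analysis
#'
#' Finds sparse loading vectors \code{u} (imaging) and \code{v} (genetics)
#' that jointly maximize the imaging-genetic, imaging-target and
#' genetic-target associations of three aligned data blocks, by alternating
#' the closed-form soft-threshold block updates of the penalized objective
#' (see \code{\link{oscca_objective}}).  The target block is a single
#' column, so its loading reduces to the fixed scalar weight \code{w}.
#'
#' @param X an \code{\link{oscca_dataset}}, or the imaging matrix
#'   (subjects x features).
#' @param Y genotype matrix (ignored when \code{X} is a dataset).
#' @param Z target vector (ignored when \code{X} is a dataset).
#' @param lambda_u,lambda_v non-negative l1 penalties on the imaging and
#'   genetic loadings; larger values give sparser loadings.
#' @param w positive weight on the two target terms.
#' @param standardize impute and column-standardize the blocks before
#'   fitting (default TRUE; set FALSE when the caller already standardized,
#'   e.g. with training-fold statistics).
#' @param max_iter maximum number of alternating sweeps.
#' @param tol convergence tolerance on the sup-norm change of the loadings.
#' @param init \code{"svd"} (leading right singular vector of X'Y;
#'   deterministic) or \code{"random"} (unit Gaussian direction drawn under
#'   \code{seed}).
#' @param seed integer seed used only by random initialization.
#' @return An object of class \code{"oscca"}: list with loading vectors
#'   \code{u}, \code{v} (named by feature), the penalties, \code{w},
#'   \code{objective}, \code{objective_trajectory}, \code{n_iter},
#'   \code{converged}, and the three in-sample canonical correlations
#'   \code{cors}.
#' @examples
#' set.seed(1)
#' n <- 40; L <- rnorm(n)
#' X <- cbind(L + rnorm(n, sd = .3), matrix(rnorm(2 * n), n))
#' Y <- cbind(L + rnorm(n, sd = .3), matrix(rnorm(2 * n), n))
#' fit <- oscca(X, Y, Z = L + rnorm(n, sd = .3),
#'              lambda_u = 0.3, lambda_v = 0.3)
#' coef(fit)
#' @export
oscca <- function(X, Y = NULL, Z = NULL, lambda_u = 0, lambda_v = 0,
                  w = 1, standardize = TRUE, max_iter = 100L, tol = 1e-6,
                  init = c("svd", "random"), seed = 1L) {
  cl <- match.call()
  init <- match.arg(init)
  if (inherits(X, "oscca_dataset")) {
    d <- X; X <- d$X; Y <- d$Y; Z <- d$Z
  }
  X <- as.matrix(X); Y <- as.matrix(Y); Z <- as.numeric(Z)
  if (standardize) {
    X <- impute_and_standardize(X)$M
    Y <- impute_and_standardize(Y)$M
    Z <- as.vector(impute_and_standardize(matrix(Z, ncol = 1))$M)
  }
  if (!all(is.finite(X)) || !all(is.finite(Y)) || !all(is.finite(Z)))
    stop("non-finite values in the data blocks (standardize them first?)")
  stopifnot(lambda_u >= 0, lambda_v >= 0, w > 0 || w == 0,
            tol > 0, max_iter >= 1)

  C <- crossprod(X, Y)
  xtz <- crossprod(X, Z)[, 1]
  ytz <- crossprod(Y, Z)[, 1]
  fit <- oscca_core(C, w * xtz, w * ytz, lambda_u, lambda_v,
                    max_iter = max_iter, tol = tol, init = init,
                    seed = seed)
  u <- fit$u; v <- fit$v
  # sign convention: imaging variate positively associated with the target
  cu <- sum(u * xtz)
  if (cu < 0) {
    flip_obj <- obj_core(-u, -v, C, w * xtz, w * ytz, lambda_u, lambda_v)
    if (flip_obj <= fit$objective + 1e-12) {
      u <- -u; v <- -v
      fit$objective <- flip_obj
    }
  }
  names(u) <- colnames(X); names(v) <- colnames(Y)
  xu <- drop(X %*% u); yv <- drop(Y %*% v)
  structure(
    list(u = u, v = v, lambda_u = lambda_u, lambda_v = lambda_v, w = w,
         objective = fit$objective,
         objective_trajectory = fit$trajectory,
         n_iter = fit$n_iter, converged = fit$converged, init = init,
         cors = c(xy = safe_cor(xu, yv), xz = safe_cor(xu, Z),
                  yz = safe_cor(yv, Z)),
         n = nrow(X), call = cl),
    class = "oscca")
}

# Alternating minimization on precomputed cross-products.  The objective is
# bi-convex, so a single start can settle in a block-wise fixed point; the
# deterministic default therefore runs a small fixed set of starts (the
# leading singular direction with both signs, two target-driven directions,
# and the zero corner) and keeps the best converged run.
oscca_core <- function(C, a, b, lambda_u, lambda_v,
                       max_iter = 100L, tol = 1e-6,
                       init = "svd", seed = 1L, sv = NULL) {
  p <- nrow(C); q <- ncol(C)
  starts <- list()
  if (init == "svd") {
    v0 <- sv %||% svd(C, nu = 0, nv = 1)$v[, 1]
    if (v0[which.max(abs(v0))] < 0) v0 <- -v0  # fix SVD sign ambiguity
    starts <- list(v0, -v0)
    if (any(b != 0)) {
      vb <- b / sqrt(sum(b^2))
      starts <- c(starts, list(vb))
    }
    if (any(a != 0)) {
      u0 <- a / sqrt(sum(a^2))
      g <- drop(crossprod(C, u0)) + b
      if (any(g != 0)) starts <- c(starts, list(g / sqrt(sum(g^2))))
    }
  } else {
    v0 <- withr_seed(seed, stats::rnorm(q))
    starts <- list(v0 / sqrt(sum(v0^2)))
  }
  best <- NULL
  for (v0 in starts) {
    run <- oscca_sweep(C, a, b, lambda_u, lambda_v, v0, max_iter, tol)
    if (is.null(best) || run$objective < best$objective - 1e-12)
      best <- run
  }
  if (best$objective > 0) {
    # the zero pair is feasible with objective 0
    best <- list(u = numeric(p), v = numeric(q), objective = 0,
                 trajectory = 0, n_iter = 1L, converged = TRUE)
  }
  best
}

oscca_sweep <- function(C, a, b, lambda_u, lambda_v, v,
                        max_iter, tol) {
  u <- numeric(nrow(C))
  trajectory <- numeric(0)
  converged <- FALSE
  it <- 0L
  repeat {
    it <- it + 1L
    u_new <- update_loading(drop(C %*% v) + a, lambda_u)
    v_new <- update_loading(drop(crossprod(C, u_new)) + b, lambda_v)
    trajectory <- c(trajectory,
                    obj_core(u_new, v_new, C, a, b, lambda_u, lambda_v))
    delta <- max(max(abs(u_new - u)), max(abs(v_new - v)))
    u <- u_new; v <- v_new
    if (delta < tol) { converged <- TRUE; break }
    if (it >= max_iter) break
  }
  list(u = u, v = v, objective = trajectory[length(trajectory)],
       trajectory = trajectory, n_iter = it, converged = converged)
}

# Pearson correlation that returns NA for zero-variance inputs instead of
# warning.
safe_cor <- function(x, y) {
  if (stats::sd(x) == 0 || stats::sd(y) == 0) return(NA_real_)
  stats::cor(x, y)
}

# Evaluate an expression under a temporary RNG state.
withr_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  on.exit(if (is.null(old)) {
    if (exists(".Random.seed", globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  } else assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  expr
}

#' Derivative-free reference search for the penalized objective
#'
#' Independent check of the alternating solver on small problems: samples
#' loading pairs on the unit spheres (plus the zero loadings), evaluates the
#' penalized objective in bulk, and polishes the best candidates with
#' Nelder-Mead on a ball-projected parameterization.  Intended for
#' \code{p*q} up to around 16.
#'
#' @inheritParams oscca_objective
#' @param n_restarts number of random candidate pairs.
#' @param seed RNG seed.
#' @param polish number of top candidates refined by Nelder-Mead.
#' @return List with \code{value} (best objective found), \code{u},
#'   \code{v}.
#' @export
oscca_oracle <- function(X, Y, Z, w = 1, lambda_u = 0, lambda_v = 0,
                         n_restarts = 20000L, seed = 1L, polish = 10L) {
  X <- as.matrix(X); Y <- as.matrix(Y); Z <- as.numeric(Z)
  p <- ncol(X); q <- ncol(Y)
  C <- crossprod(X, Y)
  a <- w * crossprod(X, Z)[, 1]
  b <- w * crossprod(Y, Z)[, 1]
  obj_batch <- function(U, V) {
    -rowSums((U %*% C) * V) - drop(V %*% b) - drop(U %*% a) +
      lambda_u * rowSums(abs(U)) + lambda_v * rowSums(abs(V))
  }
  res <- withr_seed(seed, {
    U <- matrix(stats::rnorm(n_restarts * p), n_restarts, p)
    V <- matrix(stats::rnorm(n_restarts * q), n_restarts, q)
    U <- U / sqrt(rowSums(U^2))
    V <- V / sqrt(rowSums(V^2))
    # include zero loadings (feasible and optimal under heavy shrinkage)
    U <- rbind(U, matrix(0, 1, p), U[1, , drop = FALSE], matrix(0, 1, p))
    V <- rbind(V, V[1, , drop = FALSE], matrix(0, 1, q), matrix(0, 1, q))
    vals <- obj_batch(U, V)
    ord <- order(vals)[seq_len(min(polish, length(vals)))]
    best <- vals[ord[1]]
    best_u <- U[ord[1], ]; best_v <- V[ord[1], ]
    proj <- function(x) {
      nrm <- sqrt(sum(x^2)); if (nrm > 1) x / nrm else x
    }
    f <- function(par) {
      u <- proj(par[seq_len(p)]); v <- proj(par[p + seq_len(q)])
      obj_core(u, v, C, a, b, lambda_u, lambda_v)
    }
    for (i in ord) {
      opt <- stats::optim(c(U[i, ], V[i, ]), f, method = "Nelder-Mead",
                          control = list(maxit = 2000, reltol = 1e-12))
      if (opt$value < best) {
        best <- opt$value
        best_u <- proj(opt$par[seq_len(p)])
        best_v <- proj(opt$par[p + seq_len(q)])
      }
    }
    list(value = best, u = best_u, v = best_v)
  })
  res
}
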