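#' Build cross-validation folds
#'
#' Seeded, balanced fold assignment (sizes differ by at most one).  When a
#' stratification vector is given, subjects are first binned into quartiles
#' of that vector and folds are filled bin by bin, keeping each fold's
#' distribution close to the global one.
#'
#' @param n number of subjects.
#' @param k number of folds (default 5).
#' @param seed RNG seed; the assignment is deterministic per seed.
#' @param stratify_on optional numeric vector of length \code{n}.
#' @return List of class \code{"fold_split"} with \code{k},
#'   \code{assignment} (fold index per subject) and \code{seed}.
#' @export
make_folds <- function(n, k = 5L, seed = 1L, stratify_on = NULL) {
  if (n < k) stop("cannot make ", k, " folds from ", n, " subjects")
  if (k < 2L) stop("k must be at least 2")
  assignment <- withr_seed(seed, {
    if (is.null(stratify_on)) {
      sample(rep_len(seq_len(k), n))
    } else {
      stopifnot(length(stratify_on) == n)
      bins <- cut(rank(stratify_on, ties.method = "first"),
                  breaks = 4, labels = FALSE)
      out <- integer(n)
      offset <- sample.int(k, 1L) - 1L
      pos <- 0L
      for (b in sort(unique(bins))) {
        idx <- sample(which(bins == b))
        out[idx] <- ((pos + seq_along(idx) - 1L + offset) %% k) + 1L
        pos <- pos + length(idx)
      }
      out
    }
  })
  structure(list(k = as.integer(k), assignment = assignment,
                 seed = as.integer(seed)),
            class = "fold_split")
}

# Precompute, per inner fold: training-set cross-products (for fitting) and
# the standardized validation blocks (training statistics applied), so a
# whole penalty grid can be scored from one pass over the folds.
inner_fold_data <- function(dataset, folds) {
  lapply(seq_len(folds$k), function(i) {
    val <- folds$assignment == i
    if (sum(val) < 3L)
      stop("validation fold with fewer than 3 subjects")
    tr <- dataset_rows(dataset, !val)
    te <- dataset_rows(dataset, val)
    s_tr <- standardize_blocks(tr)
    s_te <- standardize_blocks(te, stats = s_tr$stats)
    C <- crossprod(s_tr$X, s_tr$Y)
    list(C = C, sv = svd(C, nu = 0, nv = 1)$v[, 1],
         xtz = crossprod(s_tr$X, s_tr$Z)[, 1],
         ytz = crossprod(s_tr$Y, s_tr$Z)[, 1],
         X_val = s_te$X, Y_val = s_te$Y, Z_val = s_te$Z)
  })
}

score_one_fold <- function(fd, lambda_u, lambda_v, w, max_iter, tol) {
  fit <- oscca_core(fd$C, w * fd$xtz, w * fd$ytz, lambda_u, lambda_v,
                    max_iter = max_iter, tol = tol, sv = fd$sv)
  xu <- drop(fd$X_val %*% fit$u)
  yv <- drop(fd$Y_val %*% fit$v)
  r1 <- safe_cor(xu, yv)
  r2 <- safe_cor(xu, fd$Z_val)
  r3 <- safe_cor(yv, fd$Z_val)
  # zero-variance projections (over-shrunk loadings) contribute 0
  mean(ifelse(is.na(c(r1, r2, r3)), 0, c(r1, r2, r3)))
}

#' Cross-validated association score for one penalty pair
#'
#' The tuning criterion: fit the model on each training subset, project the
#' held-out subjects, and average the three held-out Pearson correlations
#' (imaging-genetic, imaging-target, genetic-target) over folds.  A
#' zero-variance projection (all loadings shrunk to zero) contributes 0 to
#' its term.
#'
#' @param dataset an \code{\link{oscca_dataset}} (raw; each training subset
#'   is standardized with its own statistics).
#' @param lambda_u,lambda_v penalty pair to score.
#' @param w target-term weight.
#' @param folds a \code{\link{make_folds}} split (default: 5 folds, seed 1).
#' @param max_iter,tol solver controls.
#' @return Mean held-out score in [-1, 1].
#' @export
cv_score <- function(dataset, lambda_u, lambda_v, w = 1, folds = NULL,
                     max_iter = 100L, tol = 1e-6) {
  folds <- folds %||% make_folds(dataset$n, 5L, seed = 1L)
  fd <- inner_fold_data(dataset, folds)
  mean(vapply(fd, score_one_fold, numeric(1),
              lambda_u = lambda_u, lambda_v = lambda_v, w = w,
              max_iter = max_iter, tol = tol))
}

# Data-adaptive default penalty grid: log-spaced below the sup-norm of the
# initial block gradients (at which the first update is fully shrunk).
default_grid <- function(dataset, w = 1, n_points = 10L, lower_frac = 0.05) {
  s <- standardize_blocks(dataset)
  C <- crossprod(s$X, s$Y)
  xtz <- crossprod(s$X, s$Z)[, 1]
  ytz <- crossprod(s$Y, s$Z)[, 1]
  v0 <- svd(C, nu = 0, nv = 1)$v[, 1]
  # orient the singular vector so the bilinear and target terms add up
  # rather than cancel (the sign of an SVD vector is arbitrary)
  if (max(abs(drop(C %*% -v0) + w * xtz)) >
      max(abs(drop(C %*% v0) + w * xtz))) v0 <- -v0
  gu <- drop(C %*% v0) + w * xtz
  u1 <- update_loading(gu, 0)
  gv <- drop(crossprod(C, u1)) + w * ytz
  list(lambda_u = exp(seq(log(lower_frac * max(abs(gu))),
                          log(max(abs(gu))), length.out = n_points)),
       lambda_v = exp(seq(log(lower_frac * max(abs(gv))),
                          log(max(abs(gv))), length.out = n_points)))
}

#' Tune the sparsity penalties by internal cross-validation
#'
#' Scores every \code{(lambda_u, lambda_v)} pair of a grid with
#' \code{\link{cv_score}} on shared folds and returns the pair with the
#' best mean held-out score.  Ties are broken toward the larger
#' \code{lambda_u + lambda_v}, i.e. the sparser model.
#'
#' @param dataset an \code{\link{oscca_dataset}}.
#' @param grid list with numeric vectors \code{lambda_u} and
#'   \code{lambda_v}; default is a data-adaptive 8 x 8 log-spaced grid.
#' @param w target-term weight.
#' @param k inner fold count.
#' @param seed fold seed.
#' @param rule \code{"max_mean_1se"} (default): among pairs whose mean
#'   score is within one standard error of the best, take the sparsest
#'   (largest \code{lambda_u + lambda_v}) — the usual one-standard-error
#'   guard against the over-selection of cross-validation maxima in l1
#'   problems; \code{"max_mean"}: the plain maximizer;
#'   \code{"mean_best"}: average each fold's best pair (an alternative
#'   reading of per-fold tuning).
#' @param max_iter,tol solver controls.
#' @return List of class \code{"oscca_tuning"}: \code{best} (named vector
#'   lambda_u, lambda_v), \code{table} (grid with mean scores),
#'   \code{fold_scores} (pairs x folds matrix), \code{rule}.
#' @export
tune_lambdas <- function(dataset, grid = NULL, w = 1, k = 5L, seed = 1L,
                         rule = c("max_mean_1se", "max_mean", "mean_best"),
                         max_iter = 100L, tol = 1e-6) {
  rule <- match.arg(rule)
  grid <- grid %||% default_grid(dataset, w = w)
  pairs <- expand.grid(lambda_u = grid$lambda_u,
                       lambda_v = grid$lambda_v,
                       KEEP.OUT.ATTRS = FALSE)
  if (nrow(pairs) == 0L) stop("empty penalty grid")
  folds <- make_folds(dataset$n, k, seed = seed)
  fd <- inner_fold_data(dataset, folds)
  fold_scores <- t(vapply(seq_len(nrow(pairs)), function(i) {
    vapply(fd, score_one_fold, numeric(1),
           lambda_u = pairs$lambda_u[i], lambda_v = pairs$lambda_v[i],
           w = w, max_iter = max_iter, tol = tol)
  }, numeric(length(fd))))
  fold_scores <- matrix(fold_scores, nrow = nrow(pairs))
  mean_score <- rowMeans(fold_scores)
  if (all(mean_score == 0))
    stop("every grid pair yields zero loadings; use a grid with smaller penalties")
  if (rule %in% c("max_mean", "max_mean_1se")) {
    margin <- 1e-12
    if (rule == "max_mean_1se") {
      bi <- which.max(mean_score)
      margin <- stats::sd(fold_scores[bi, ]) / sqrt(ncol(fold_scores))
    }
    top <- which(mean_score >= max(mean_score) - margin)
    best_i <- top[which.max(pairs$lambda_u[top] + pairs$lambda_v[top])]
    best <- c(lambda_u = pairs$lambda_u[best_i],
              lambda_v = pairs$lambda_v[best_i])
  } else {
    per_fold <- apply(fold_scores, 2, function(s) {
      top <- which(s >= max(s) - 1e-12)
      top[which.max(pairs$lambda_u[top] + pairs$lambda_v[top])]
    })
    best <- c(lambda_u = mean(pairs$lambda_u[per_fold]),
              lambda_v = mean(pairs$lambda_v[per_fold]))
  }
  structure(list(best = best,
                 table = cbind(pairs, mean_score = mean_score),
                 fold_scores = fold_scores, rule = rule, seed = seed),
            class = "oscca_tuning")
}

#' Indices of the selected (non-zero loading) features
#'
#' @param solution a fitted \code{\link{oscca}} model.
#' @return List with integer vectors \code{imaging} and \code{genetic}.
#' @export
selected_features <- function(solution) {
  list(imaging = which(solution$u != 0),
       genetic = which(solution$v != 0))
}

#' Features selected in every fold
#'
#' @param selections list of integer index vectors (one per fold).
#' @return The intersection, ordered by original feature index.
#' @export
consensus_features <- function(selections) {
  if (length(selections) == 0L) stop("at least one selection required")
  sort(Reduce(intersect, selections))
}
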