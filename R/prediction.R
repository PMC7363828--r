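#' Pearson correlation with a two-sided p-value
#'
#' @param x,y numeric vectors of equal length (at least 3).
#' @return List with \code{r} and two-sided \code{p} (t transform with
#'   \code{n - 2} df); both \code{NA} when either input is constant.
#' @export
pearson <- function(x, y) {
  if (length(x) != length(y)) stop("length mismatch")
  if (length(x) < 3L) stop("need at least 3 observations")
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    return(list(r = NA_real_, p = NA_real_, degenerate = TRUE))
  ct <- stats::cor.test(x, y, method = "pearson", alternative = "two.sided")
  list(r = unname(ct$estimate), p = ct$p.value, degenerate = FALSE)
}

#' Root mean square error
#'
#' @param actual,predicted numeric vectors of equal length.
#' @return \code{sqrt(mean((actual - predicted)^2))}, in target units.
#' @export
rmse <- function(actual, predicted) {
  if (length(actual) != length(predicted)) stop("length mismatch")
  sqrt(mean((actual - predicted)^2))
}

#' Train a random-forest regressor on selected features
#'
#' @param features numeric matrix (rows = subjects).
#' @param targets numeric target vector (e.g. age at onset in years).
#' @param n_trees number of regression trees (default 500).
#' @param seed RNG seed; predictions are deterministic per seed.
#' @return A fitted \code{randomForest} object.
#' @export
train_rf <- function(features, targets, n_trees = 500L, seed = 1L) {
  features <- as.matrix(features)
  if (ncol(features) < 1L) stop("empty feature set")
  if (nrow(features) < 2L) stop("need at least 2 training rows")
  withr_seed(seed,
             randomForest::randomForest(x = features, y = targets,
                                        ntree = n_trees))
}

#' Constant mean-of-target baseline predictor
#'
#' @param train_targets training target values.
#' @return A function that predicts the training mean for any number of
#'   rows; its mean is stored in attribute \code{"mean"}.
#' @export
mean_baseline <- function(train_targets) {
  if (length(train_targets) == 0L) stop("empty training targets")
  m <- mean(train_targets)
  structure(function(newdata) rep(m, NROW(newdata)), mean = m)
}

#' Average per-fold model metrics
#'
#' Arithmetic mean of r, p and RMSE across folds for each model kind, the
#' reporting convention of fold-wise evaluation (the averaged p is a
#' summary, not a combined test).  Folds with undefined metrics are
#' excluded and counted.
#'
#' @param fold_metrics data.frame with columns \code{fold}, \code{kind},
#'   \code{r}, \code{p}, \code{rmse}, \code{n_test}.
#' @return data.frame with one row per kind: mean \code{r}, \code{p},
#'   \code{rmse}, \code{n_folds} used and \code{n_undefined}.
#' @export
evaluate_models <- function(fold_metrics) {
  kinds <- unique(fold_metrics$kind)
  rows <- lapply(kinds, function(kd) {
    fm <- fold_metrics[fold_metrics$kind == kd, , drop = FALSE]
    ok <- !is.na(fm$rmse)
    okr <- ok & !is.na(fm$r)
    data.frame(kind = kd,
               r = if (any(okr)) mean(fm$r[okr]) else NA_real_,
               p = if (any(okr)) mean(fm$p[okr]) else NA_real_,
               rmse = if (any(ok)) mean(fm$rmse[ok]) else NA_real_,
               n_folds = sum(ok), n_undefined = sum(!ok),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

# Fit an RF on training columns and score the held-out fold.  Empty
# feature sets give undefined metrics (NA) rather than an error.
fold_model_metrics <- function(kind, cols_tr, cols_te, z_tr, z_te,
                               n_trees, seed) {
  if (is.null(cols_tr) || ncol(cols_tr) == 0L) {
    return(list(metrics = data.frame(kind = kind, r = NA_real_,
                                     p = NA_real_, rmse = NA_real_,
                                     n_test = length(z_te),
                                     stringsAsFactors = FALSE),
                predicted = rep(NA_real_, length(z_te))))
  }
  rf <- train_rf(cols_tr, z_tr, n_trees = n_trees, seed = seed)
  pred <- unname(stats::predict(rf, cols_te))
  pr <- pearson(z_te, pred)
  list(metrics = data.frame(kind = kind, r = pr$r, p = pr$p,
                            rmse = rmse(z_te, pred),
                            n_test = length(z_te),
                            stringsAsFactors = FALSE),
       predicted = pred)
}
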