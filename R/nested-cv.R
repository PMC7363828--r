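#' Nested cross-validated feature selection and target prediction
#'
#' The full evaluation pipeline: for each outer fold, standardize on the
#' training rows, tune the sparsity penalties by internal cross-validation
#' (see \code{\link{tune_lambdas}}), fit the objective-specific sparse CCA,
#' take the non-zero loadings as selected features, train random-forest
#' regressors on the imaging, genetic and combined selections plus a
#' mean-of-target baseline, and score predictions on the held-out fold by
#' Pearson correlation and RMSE.  Metrics are averaged over folds and the
#' features selected in every fold are reported as the consensus.
#' Optionally, LASSO and mRMR selectors (with the feature count matched to
#' the main model's selection) are run through the identical prediction
#' protocol for comparison.
#'
#' @param dataset an \code{\link{oscca_dataset}}.
#' @param k_outer,k_inner outer and inner fold counts (default 5/5).
#' @param grid penalty grid for \code{\link{tune_lambdas}} (default:
#'   data-adaptive per training set).
#' @param w target-term weight.
#' @param n_trees random-forest size (default 500).
#' @param seed master seed; folds, tuning folds and forests all derive
#'   their seeds from it.
#' @param baselines also run the LASSO and mRMR comparison selectors.
#' @param tune_rule hyperparameter reading passed to
#'   \code{\link{tune_lambdas}}.
#' @param max_iter,tol solver controls.
#' @return Object of class \code{"oscca_cv"}: per-fold results
#'   (\code{folds}), averaged \code{metrics}, \code{pooled} correlations
#'   (predictions pooled across folds; reported separately, never
#'   substituted for the averaged r), \code{consensus} feature names and
#'   indices, \code{predictions} (long table of actual/predicted), and the
#'   configuration.
#' @export
oscca_nested_cv <- function(dataset, k_outer = 5L, k_inner = 5L,
                            grid = NULL, w = 1, n_trees = 500L, seed = 1L,
                            baselines = FALSE,
                            tune_rule = "max_mean",
                            max_iter = 100L, tol = 1e-6) {
  stopifnot(inherits(dataset, "oscca_dataset"))
  outer <- make_folds(dataset$n, k_outer, seed = seed)
  folds_out <- vector("list", k_outer)
  all_metrics <- list()
  all_preds <- list()

  for (f in seq_len(k_outer)) {
    te <- outer$assignment == f
    d_tr <- dataset_rows(dataset, !te)
    d_te <- dataset_rows(dataset, te)
    s_tr <- standardize_blocks(d_tr)
    s_te <- standardize_blocks(d_te, stats = s_tr$stats)

    tuning <- tune_lambdas(d_tr, grid = grid, w = w, k = k_inner,
                           seed = seed + 1000L + f, rule = tune_rule,
                           max_iter = max_iter, tol = tol)
    fit <- oscca(s_tr$X, s_tr$Y, s_tr$Z,
                 lambda_u = tuning$best[["lambda_u"]],
                 lambda_v = tuning$best[["lambda_v"]],
                 w = w, standardize = FALSE,
                 max_iter = max_iter, tol = tol)
    sel <- selected_features(fit)
    if (length(sel$imaging) == 0L && length(sel$genetic) == 0L)
      warning("fold ", f, ": empty combined feature set; ",
              "metrics recorded as undefined")

    fm <- run_fold_models(
      sel_img = sel$imaging, sel_gen = sel$genetic,
      X_tr = s_tr$X, Y_tr = s_tr$Y, X_te = s_te$X, Y_te = s_te$Y,
      z_tr = d_tr$Z, z_te = d_te$Z,
      n_trees = n_trees, seed = seed + 2000L + f, method = "oscca")
    metrics <- fm$metrics
    preds <- fm$preds

    extra <- NULL
    if (baselines) {
      extra <- run_baseline_models(
        X_tr = s_tr$X, Y_tr = s_tr$Y, X_te = s_te$X, Y_te = s_te$Y,
        z_tr = d_tr$Z, z_te = d_te$Z,
        k_img = length(sel$imaging), k_gen = length(sel$genetic),
        n_trees = n_trees, seed = seed + 3000L + f)
      metrics <- rbind(metrics, extra$metrics)
      preds <- rbind(preds, extra$preds)
    }

    metrics$fold <- f
    preds$fold <- f
    all_metrics[[f]] <- metrics
    all_preds[[f]] <- preds
    folds_out[[f]] <- list(
      fold = f, test_idx = which(te),
      lambda_u = unname(tuning$best[["lambda_u"]]),
      lambda_v = unname(tuning$best[["lambda_v"]]),
      tuning_table = tuning$table,
      fit = fit, selected = sel,
      baseline_selected = extra$selected)
  }

  fold_metrics <- do.call(rbind, all_metrics)
  predictions <- do.call(rbind, all_preds)
  metrics <- evaluate_models(fold_metrics)

  pooled <- do.call(rbind, lapply(split(predictions, predictions$kind),
    function(df) {
      ok <- !is.na(df$predicted)
      if (sum(ok) >= 3L && stats::sd(df$predicted[ok]) > 0) {
        pr <- pearson(df$actual[ok], df$predicted[ok])
        data.frame(kind = df$kind[1], r = pr$r, p = pr$p,
                   rmse = rmse(df$actual[ok], df$predicted[ok]),
                   stringsAsFactors = FALSE)
      } else {
        data.frame(kind = df$kind[1], r = NA_real_, p = NA_real_,
                   rmse = NA_real_, stringsAsFactors = FALSE)
      }
    }))
  rownames(pooled) <- NULL

  cons_img <- consensus_features(lapply(folds_out,
                                        function(x) x$selected$imaging))
  cons_gen <- consensus_features(lapply(folds_out,
                                        function(x) x$selected$genetic))
  structure(
    list(folds = folds_out,
         fold_metrics = fold_metrics,
         metrics = metrics,
         pooled = pooled,
         predictions = predictions,
         consensus = list(
           imaging = cons_img, genetic = cons_gen,
           imaging_names = dataset$imaging_names[cons_img],
           genetic_names = dataset$variant_names[cons_gen]),
         config = list(k_outer = k_outer, k_inner = k_inner, w = w,
                       n_trees = n_trees, seed = seed,
                       baselines = baselines, tune_rule = tune_rule,
                       rf_defaults = "mtry = floor(p/3), nodesize = 5")),
    class = "oscca_cv")
}

# The three RF models (imaging / genetic / combined) plus the mean
# baseline for one method's selection on one outer fold.
run_fold_models <- function(sel_img, sel_gen, X_tr, Y_tr, X_te, Y_te,
                            z_tr, z_te, n_trees, seed, method) {
  blocks <- list(
    imaging = list(tr = X_tr[, sel_img, drop = FALSE],
                   te = X_te[, sel_img, drop = FALSE]),
    genetic = list(tr = Y_tr[, sel_gen, drop = FALSE],
                   te = Y_te[, sel_gen, drop = FALSE]),
    combined = list(
      tr = cbind(X_tr[, sel_img, drop = FALSE],
                 Y_tr[, sel_gen, drop = FALSE]),
      te = cbind(X_te[, sel_img, drop = FALSE],
                 Y_te[, sel_gen, drop = FALSE])))
  out_m <- list(); out_p <- list()
  for (kd in names(blocks)) {
    b <- blocks[[kd]]
    res <- fold_model_metrics(paste(method, kd, sep = "_"),
                              b$tr, b$te, z_tr, z_te, n_trees, seed)
    out_m[[kd]] <- res$metrics
    out_p[[kd]] <- data.frame(kind = res$metrics$kind, actual = z_te,
                              predicted = res$predicted,
                              stringsAsFactors = FALSE)
  }
  if (method == "oscca") {
    bl <- mean_baseline(z_tr)
    pred <- bl(z_te)
    out_m$baseline <- data.frame(kind = "mean_baseline", r = NA_real_,
                                 p = NA_real_, rmse = rmse(z_te, pred),
                                 n_test = length(z_te),
                                 stringsAsFactors = FALSE)
    out_p$baseline <- data.frame(kind = "mean_baseline", actual = z_te,
                                 predicted = pred, stringsAsFactors = FALSE)
  }
  list(metrics = do.call(rbind, out_m), preds = do.call(rbind, out_p))
}

# LASSO and mRMR comparison selectors run through the identical
# prediction protocol; the mRMR feature count is matched per block to the
# main model's selection size.
run_baseline_models <- function(X_tr, Y_tr, X_te, Y_te, z_tr, z_te,
                                k_img, k_gen, n_trees, seed) {
  las_img <- lasso_select(X_tr, z_tr, seed = seed)
  las_gen <- lasso_select(Y_tr, z_tr, seed = seed + 1L)
  m <- list(); p <- list(); sel <- list()
  fm <- run_fold_models(las_img, las_gen, X_tr, Y_tr, X_te, Y_te,
                        z_tr, z_te, n_trees, seed + 2L, method = "lasso")
  m$lasso <- fm$metrics; p$lasso <- fm$preds
  sel$lasso <- list(imaging = las_img, genetic = las_gen)

  mr_img <- if (k_img > 0)
    mrmr_rank(X_tr, z_tr, k = k_img)$index else integer(0)
  mr_gen <- if (k_gen > 0)
    mrmr_rank(Y_tr, z_tr, k = k_gen)$index else integer(0)
  fm <- run_fold_models(mr_img, mr_gen, X_tr, Y_tr, X_te, Y_te,
                        z_tr, z_te, n_trees, seed + 3L, method = "mrmr")
  m$mrmr <- fm$metrics; p$mrmr <- fm$preds
  sel$mrmr <- list(imaging = mr_img, genetic = mr_gen)
  list(metrics = do.call(rbind, m), preds = do.call(rbind, p),
       selected = sel)
}

#' @export
print.oscca_cv <- function(x, ...) {
  cat("Nested cross-validated os-SCCA pipeline\n")
  cat(sprintf("  %d outer / %d inner folds, %d subjects\n",
              x$config$k_outer, x$config$k_inner,
              length(unlist(lapply(x$folds, `[[`, "test_idx")))))
  cat(sprintf("  consensus features: %d imaging, %d genetic\n",
              length(x$consensus$imaging), length(x$consensus$genetic)))
  cat("\nAveraged test-fold metrics:\n")
  print(x$metrics, row.names = FALSE, digits = 4)
  invisible(x)
}

#' @export
summary.oscca_cv <- function(object, ...) {
  cat("Per-fold penalties and selection sizes:\n")
  df <- do.call(rbind, lapply(object$folds, function(f)
    data.frame(fold = f$fold, lambda_u = f$lambda_u,
               lambda_v = f$lambda_v,
               n_imaging = length(f$selected$imaging),
               n_genetic = length(f$selected$genetic))))
  print(df, row.names = FALSE, digits = 4)
  cat("\nConsensus imaging features:\n ",
      paste(object$consensus$imaging_names, collapse = ", "), "\n")
  cat("Consensus genetic features:\n ",
      paste(object$consensus$genetic_names, collapse = ", "), "\n")
  print(object)
  invisible(object)
}

#' Write nested-CV results to disk
#'
#' Writes the full result as JSON plus per-fold CSV tables of metrics,
#' selected features and prediction scatter data.
#'
#' @param result an \code{oscca_cv} object.
#' @param dir output directory (created if needed).
#' @export
write_nested_cv <- function(result, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  utils::write.csv(result$fold_metrics,
                   file.path(dir, "fold_metrics.csv"), row.names = FALSE)
  utils::write.csv(result$metrics,
                   file.path(dir, "metrics_averaged.csv"),
                   row.names = FALSE)
  utils::write.csv(result$predictions,
                   file.path(dir, "predictions.csv"), row.names = FALSE)
  sel <- do.call(rbind, lapply(result$folds, function(f)
    rbind(data.frame(fold = f$fold, block = "imaging",
                     index = f$selected$imaging),
          data.frame(fold = f$fold, block = "genetic",
                     index = f$selected$genetic))))
  utils::write.csv(sel, file.path(dir, "selected_features.csv"),
                   row.names = FALSE)
  jsonlite::write_json(
    list(metrics = result$metrics, pooled = result$pooled,
         consensus = result$consensus,
         per_fold = lapply(result$folds, function(f)
           list(fold = f$fold, lambda_u = f$lambda_u,
                lambda_v = f$lambda_v,
                imaging = f$selected$imaging,
                genetic = f$selected$genetic)),
         config = result$config),
    file.path(dir, "nested_cv.json"), auto_unbox = TRUE, digits = NA,
    na = "null")
  invisible(dir)
}
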