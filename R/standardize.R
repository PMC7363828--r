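#' Mean-impute missing entries and standardize columns
#'
#' Replaces missing entries by the column mean and scales every column to
#' mean 0 and unit sample (n-1) standard deviation.  When \code{stats} from
#' a previous call are supplied (held-out folds), those training means and
#' standard deviations are applied unchanged, so no information leaks from
#' held-out rows.  Zero-variance columns are centered, divided by 1 and
#' flagged.
#'
#' @param M numeric matrix, possibly with \code{NA} entries.
#' @param stats optional result of a previous call: a list with
#'   \code{center}, \code{scale} and \code{degenerate}.
#' @return List with \code{M} (transformed matrix) and \code{stats}.
#' @export
impute_and_standardize <- function(M, stats = NULL) {
  M <- as.matrix(M)
  if (is.null(stats)) {
    center <- colMeans(M, na.rm = TRUE)
    if (anyNA(center))
      stop("column(s) with no observed values cannot be imputed")
    for (j in seq_len(ncol(M))) {
      mj <- is.na(M[, j])
      if (any(mj)) M[mj, j] <- center[j]
    }
    sds <- apply(M, 2, stats::sd)
    degenerate <- !is.finite(sds) | sds == 0
    scale <- ifelse(degenerate, 1, sds)
    stats <- list(center = center, scale = scale, degenerate = degenerate)
  } else {
    for (j in seq_len(ncol(M))) {
      mj <- is.na(M[, j])
      if (any(mj)) M[mj, j] <- stats$center[j]
    }
  }
  M <- sweep(M, 2, stats$center, "-")
  M <- sweep(M, 2, stats$scale, "/")
  list(M = M, stats = stats)
}

# Standardize all three blocks of a dataset on its own statistics (or on
# supplied training statistics), returning plain matrices/vector plus the
# statistics for reuse on held-out rows.
standardize_blocks <- function(dataset, stats = NULL) {
  sx <- impute_and_standardize(dataset$X, stats$X)
  sy <- impute_and_standardize(dataset$Y, stats$Y)
  sz <- impute_and_standardize(matrix(dataset$Z, ncol = 1), stats$Z)
  list(X = sx$M, Y = sy$M, Z = as.vector(sz$M),
       stats = list(X = sx$stats, Y = sy$stats, Z = sz$stats))
}
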