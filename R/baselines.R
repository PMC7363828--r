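#' LASSO feature selection against the target
#'
#' l1-penalized linear regression of the target on one feature block, with
#' the penalty chosen by internal 5-fold cross-validation over a log-spaced
#' path (50 values down from the smallest penalty that zeroes every
#' coefficient; CV-minimum rule).  The selected features are the non-zero
#' coefficients; an empty selection is legal and simply returned empty.
#'
#' @param F standardized feature matrix (at least two columns).
#' @param Z target vector.
#' @param seed seed controlling the CV fold assignment.
#' @param lambda optional fixed penalty overriding cross-validation.
#' @return Integer vector of selected column indices (possibly empty).
#' @export
lasso_select <- function(F, Z, seed = 1L, lambda = NULL) {
  F <- as.matrix(F)
  if (ncol(F) < 2L) stop("LASSO selection needs at least two features")
  if (is.null(lambda)) {
    cvfit <- withr_seed(seed,
      glmnet::cv.glmnet(F, Z, alpha = 1, nfolds = 5, nlambda = 50))
    lambda <- cvfit$lambda.min
    fit <- cvfit$glmnet.fit
  } else {
    fit <- glmnet::glmnet(F, Z, alpha = 1)
  }
  co <- as.matrix(stats::coef(fit, s = lambda))[-1, 1]
  which(co != 0)
}

# 3-level discretization of a continuous vector at mean +/- 0.5 sd;
# vectors that are already low-cardinality (e.g. 0/1/2 genotypes) are used
# as-is.
discretize3 <- function(v) {
  u <- unique(v)
  if (length(u) <= 5L) return(match(v, sort(u)))
  m <- mean(v); s <- stats::sd(v)
  if (s == 0) return(rep(1L, length(v)))
  findInterval(v, c(m - 0.5 * s, m + 0.5 * s)) + 1L
}

#' Plug-in mutual information of two discretized vectors
#'
#' Empirical mutual information (nats) of the joint distribution after
#' discretization: continuous inputs are binned into 3 levels at
#' mean +/- 0.5 sd, low-cardinality inputs (such as 0/1/2 genotype counts)
#' are kept as-is.
#'
#' @param x,y numeric vectors of equal length.
#' @return Non-negative scalar, symmetric in its arguments.
#' @export
mutual_information <- function(x, y) {
  if (length(x) != length(y)) stop("length mismatch")
  tab <- table(discretize3(x), discretize3(y))
  pj <- tab / sum(tab)
  px <- rowSums(pj); py <- colSums(pj)
  idx <- pj > 0
  sum(pj[idx] * log(pj[idx] / outer(px, py)[idx]))
}

#' Greedy minimum-redundancy maximum-relevance feature ranking
#'
#' Classic mutual-information-difference (MID) variant: the first feature
#' maximizes relevance \code{MI(f, Z)}; each subsequent feature maximizes
#' the feature-selection score \code{MI(f, Z) - mean MI(f, s)} over the
#' already-selected set \code{s}.  Ties break toward the lower feature
#' index.
#'
#' @param F feature matrix.
#' @param Z target vector.
#' @param k number of features to rank (truncated with a warning when it
#'   exceeds the number of features).
#' @return List of class \code{"mrmr_ranking"}: \code{index} (ordered
#'   selected columns), \code{score} (FS score at selection time),
#'   \code{method}, \code{k}.
#' @export
mrmr_rank <- function(F, Z, k) {
  F <- as.matrix(F)
  if (k < 1L) stop("k must be at least 1")
  if (k > ncol(F)) {
    warning("k exceeds the number of features; truncating to ", ncol(F))
    k <- ncol(F)
  }
  disc <- lapply(seq_len(ncol(F)), function(j) discretize3(F[, j]))
  zd <- discretize3(Z)
  mi_pair <- function(a, b) {
    tab <- table(a, b)
    pj <- tab / sum(tab)
    px <- rowSums(pj); py <- colSums(pj)
    idx <- pj > 0
    sum(pj[idx] * log(pj[idx] / outer(px, py)[idx]))
  }
  relevance <- vapply(disc, mi_pair, numeric(1), b = zd)
  selected <- integer(0)
  scores <- numeric(0)
  red_sum <- numeric(ncol(F))
  for (step in seq_len(k)) {
    cand <- setdiff(seq_len(ncol(F)), selected)
    fs <- relevance[cand] -
      if (step == 1L) 0 else red_sum[cand] / length(selected)
    best <- cand[which.max(fs)]          # which.max breaks ties low
    selected <- c(selected, best)
    scores <- c(scores, max(fs))
    if (step < k)
      for (j in setdiff(seq_len(ncol(F)), selected))
        red_sum[j] <- red_sum[j] + mi_pair(disc[[j]], disc[[best]])
  }
  structure(list(index = selected, score = scores,
                 method = "mrmr_mid", k = k),
            class = "mrmr_ranking")
}

#' @export
print.mrmr_ranking <- function(x, ...) {
  cat("mRMR (MID) ranking, k =", x$k, "\n")
  print(data.frame(rank = seq_along(x$index), index = x$index,
                   fs_score = x$score), row.names = FALSE, digits = 4)
  invisible(x)
}

#' Write a ranked selection as CSV
#'
#' @param ranking an \code{mrmr_ranking}.
#' @param path output CSV path.
#' @param names optional feature names indexed by \code{ranking$index}.
#' @export
write_ranking <- function(ranking, path, names = NULL) {
  df <- data.frame(rank = seq_along(ranking$index),
                   index = ranking$index,
                   name = if (is.null(names)) NA else names[ranking$index],
                   fs_score = ranking$score)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}
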