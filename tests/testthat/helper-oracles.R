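# Independent reference implementations used as test oracles.  These are
# deliberately written along different code paths from the package
# internals they check.

# Term-by-term evaluation of the penalized three-block objective using
# explicit scalar loops.
objective_by_hand <- function(u, v, X, Y, Z, w, lambda_u, lambda_v) {
  t1 <- 0
  for (i in seq_len(ncol(X)))
    for (j in seq_len(ncol(Y)))
      t1 <- t1 + u[i] * sum(X[, i] * Y[, j]) * v[j]
  t2 <- 0
  for (j in seq_len(ncol(Y))) t2 <- t2 + v[j] * sum(Y[, j] * Z)
  t3 <- 0
  for (i in seq_len(ncol(X))) t3 <- t3 + u[i] * sum(X[, i] * Z)
  -t1 - w * t2 - w * t3 + lambda_u * sum(abs(u)) + lambda_v * sum(abs(v))
}

# Rank-1 penalized matrix decomposition (two-way sparse CCA) transcribed
# independently: soft-threshold/normalize power iteration on the
# cross-product matrix.
pmd_rank1 <- function(X, Y, lambda_u, lambda_v, max_iter = 100,
                      tol = 1e-6) {
  C <- crossprod(as.matrix(X), as.matrix(Y))
  v <- svd(C)$v[, 1]
  if (v[which.max(abs(v))] < 0) v <- -v
  u <- rep(0, nrow(C))
  for (it in seq_len(max_iter)) {
    su <- drop(C %*% v)
    su <- sign(su) * pmax(abs(su) - lambda_u, 0)
    u_new <- if (sum(su^2) > 0) su / sqrt(sum(su^2)) else su
    sv <- drop(t(C) %*% u_new)
    sv <- sign(sv) * pmax(abs(sv) - lambda_v, 0)
    v_new <- if (sum(sv^2) > 0) sv / sqrt(sum(sv^2)) else sv
    done <- max(max(abs(u_new - u)), max(abs(v_new - v))) < tol
    u <- u_new; v <- v_new
    if (done) break
  }
  list(u = u, v = v,
       objective = -drop(u %*% C %*% v) + lambda_u * sum(abs(u)) +
         lambda_v * sum(abs(v)))
}

# Exact conditional heterozygote distribution by the classic upward
# recurrence (unnormalized, then normalized); p-value by summing
# configurations no more probable than the observed one.
hwe_enum <- function(n_hom_ref, n_het, n_hom_alt) {
  n <- n_hom_ref + n_het + n_hom_alt
  nm <- min(2 * n_hom_ref + n_het, 2 * n_hom_alt + n_het)
  if (nm == 0) return(1)
  hets <- seq(nm %% 2, nm, by = 2)
  probs <- numeric(length(hets))
  probs[1] <- 1
  if (length(hets) > 1) {
    for (i in seq_len(length(hets) - 1)) {
      h <- hets[i]
      hom_minor <- (nm - h) / 2
      hom_major <- n - h - hom_minor
      probs[i + 1] <- probs[i] * 4 * hom_minor * hom_major /
        ((h + 2) * (h + 1))
    }
  }
  probs <- probs / sum(probs)
  obs <- probs[match(n_het, hets)]
  min(1, sum(probs[probs <= obs * (1 + 1e-12)]))
}

# Upper-tail hypergeometric probability by explicit combinatorial sum.
hyper_tail_enum <- function(k, K, n, N) {
  js <- k:min(K, n)
  sum(choose(K, js) * choose(N - K, n - js)) / choose(N, n)
}

# F1 of a selected index set against a true support.
f1_score <- function(sel, truth) {
  tp <- length(intersect(sel, truth))
  if (length(sel) == 0 || tp == 0) return(0)
  prec <- tp / length(sel)
  rec <- tp / length(truth)
  2 * prec * rec / (prec + rec)
}

# Small standardized random blocks for solver tests.
random_blocks <- function(n, p, q, seed) {
  set.seed(seed)
  list(X = scale(matrix(rnorm(n * p), n)),
       Y = scale(matrix(rnorm(n * q), n)),
       Z = as.vector(scale(rnorm(n))))
}
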