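#' @export
print.oscca <- function(x, ...) {
  cat("Objective-specific sparse CCA fit\n")
  cat(sprintf("  lambda_u = %.4g, lambda_v = %.4g, w = %.4g\n",
              x$lambda_u, x$lambda_v, x$w))
  cat(sprintf("  non-zero loadings: %d/%d imaging, %d/%d genetic\n",
              sum(x$u != 0), length(x$u), sum(x$v != 0), length(x$v)))
  cat(sprintf("  converged in %d iterations (objective %.6g)\n",
              x$n_iter, x$objective))
  cat(sprintf("  canonical correlations: XY %.3f, XZ %.3f, YZ %.3f\n",
              x$cors["xy"], x$cors["xz"], x$cors["yz"]))
  invisible(x)
}

#' @export
coef.oscca <- function(object, ...) {
  list(u = object$u, v = object$v)
}

#' @export
summary.oscca <- function(object, ...) {
  sel <- selected_features(object)
  out <- list(fit = object,
              imaging = data.frame(feature = names(object$u)[sel$imaging],
                                   loading = unname(object$u[sel$imaging])),
              genetic = data.frame(feature = names(object$v)[sel$genetic],
                                   loading = unname(object$v[sel$genetic])))
  class(out) <- "summary.oscca"
  out
}

#' @export
print.summary.oscca <- function(x, ...) {
  print(x$fit)
  cat("\nSelected imaging features (non-zero u):\n")
  if (nrow(x$imaging)) print(x$imaging, row.names = FALSE) else cat("  none\n")
  cat("\nSelected genetic features (non-zero v):\n")
  if (nrow(x$genetic)) print(x$genetic, row.names = FALSE) else cat("  none\n")
  invisible(x)
}

#' @export
plot.oscca <- function(x, ...) {
  plot(seq_along(x$objective_trajectory), x$objective_trajectory,
       type = "b", xlab = "iteration", ylab = "penalized objective",
       main = "os-SCCA objective trajectory", ...)
  invisible(x)
}

#' Canonical variate scores for new data
#'
#' Projects (already standardized, or raw comparable) imaging and genotype
#' blocks onto the fitted loadings.
#'
#' @param object a fitted \code{\link{oscca}} model.
#' @param X,Y new imaging / genotype blocks with the training columns.
#' @param ... unused.
#' @return A two-column matrix of imaging and genetic variate scores.
#' @export
predict.oscca <- function(object, X, Y, ...) {
  cbind(imaging = drop(as.matrix(X) %*% object$u),
        genetic = drop(as.matrix(Y) %*% object$v))
}

#' Serialize a fitted os-SCCA solution to JSON
#'
#' @param fit a fitted \code{\link{oscca}} model.
#' @param path output path.
#' @export
write_oscca_json <- function(fit, path) {
  jsonlite::write_json(
    list(u = as.list(fit$u), v = as.list(fit$v),
         lambda_u = fit$lambda_u, lambda_v = fit$lambda_v, w = fit$w,
         objective = fit$objective,
         objective_trajectory = fit$objective_trajectory,
         n_iter = fit$n_iter, converged = fit$converged,
         cors = as.list(fit$cors)),
    path, auto_unbox = TRUE, digits = NA, na = "null")
  invisible(path)
}
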