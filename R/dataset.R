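#' Assemble an aligned imaging-genetics dataset
#'
#' Bundles the three data blocks used throughout the package: an imaging
#' feature matrix \code{X} (subjects x regions, e.g. mean fractional
#' anisotropy per atlas region), a genotype matrix \code{Y} of minor-allele
#' counts (subjects x variants, entries 0/1/2 or \code{NA}), and a target
#' vector \code{Z} (one continuous value per subject, e.g. age at onset in
#' years).  All three blocks must share the same subjects in the same order.
#'
#' @param X numeric matrix, subjects x imaging features.
#' @param Y numeric matrix, subjects x variants; non-missing entries must be
#'   0, 1 or 2.
#' @param Z numeric vector, one target value per subject.
#' @param subject_ids character vector of subject identifiers; defaults to
#'   the rownames of \code{X} or \code{"s1"..."sn"}.
#' @param imaging_names,variant_names feature labels; default to the column
#'   names of \code{X} and \code{Y}.
#' @return An object of class \code{"oscca_dataset"}: a list with elements
#'   \code{X}, \code{Y}, \code{Z}, \code{subject_ids}, \code{imaging_names},
#'   \code{variant_names}, \code{n}, \code{p}, \code{q}.
#' @examples
#' d <- oscca_dataset(X = matrix(rnorm(6), 3), Y = matrix(0:1, 3, 2),
#'                    Z = c(55, 61, 70))
#' d$n
#' @export
oscca_dataset <- function(X, Y, Z, subject_ids = NULL,
                          imaging_names = NULL, variant_names = NULL) {
  X <- as.matrix(X)
  Y <- as.matrix(Y)
  storage.mode(X) <- "double"
  storage.mode(Y) <- "double"
  Z <- as.numeric(Z)
  n <- nrow(X)
  if (n < 2L)
    stop("dataset needs at least 2 subjects")
  if (nrow(Y) != n || length(Z) != n)
    stop("X, Y and Z must describe the same subjects: nrow(X) = ", n,
         ", nrow(Y) = ", nrow(Y), ", length(Z) = ", length(Z))
  bad <- !is.na(Y) & !(Y %in% c(0, 1, 2))
  if (any(bad))
    stop("genotype matrix has ", sum(bad),
         " entries outside {0, 1, 2, NA}")
  if (!is.numeric(X) || anyNA(Z))
    stop("imaging block must be numeric and the target must have no missing values")

  subject_ids <- subject_ids %||% rownames(X) %||% paste0("s", seq_len(n))
  imaging_names <- imaging_names %||% colnames(X) %||%
    paste0("img", seq_len(ncol(X)))
  variant_names <- variant_names %||% colnames(Y) %||%
    paste0("snp", seq_len(ncol(Y)))
  if (anyDuplicated(subject_ids))
    stop("duplicate subject ids")
  if (anyDuplicated(imaging_names))
    stop("duplicate imaging feature labels")
  if (anyDuplicated(variant_names))
    stop("duplicate variant labels")
  if (length(imaging_names) != ncol(X) || length(variant_names) != ncol(Y))
    stop("feature label lengths do not match block dimensions")

  dimnames(X) <- list(subject_ids, imaging_names)
  dimnames(Y) <- list(subject_ids, variant_names)
  structure(
    list(X = X, Y = Y, Z = Z, subject_ids = as.character(subject_ids),
         imaging_names = as.character(imaging_names),
         variant_names = as.character(variant_names),
         n = n, p = ncol(X), q = ncol(Y)),
    class = "oscca_dataset")
}

#' @export
print.oscca_dataset <- function(x, ...) {
  cat("Aligned imaging-genetics dataset\n")
  cat(sprintf("  subjects: %d\n  imaging features: %d\n  variants: %d\n",
              x$n, x$p, x$q))
  miss <- mean(is.na(x$Y))
  cat(sprintf("  genotype missingness: %.2f%%\n", 100 * miss))
  cat(sprintf("  target: mean %.2f, sd %.2f\n",
              mean(x$Z), stats::sd(x$Z)))
  invisible(x)
}

#' Subset a dataset by subject rows
#'
#' @param dataset an \code{oscca_dataset}.
#' @param rows integer or logical index of subjects to keep.
#' @return A new \code{oscca_dataset} with the selected subjects.
#' @export
dataset_rows <- function(dataset, rows) {
  oscca_dataset(dataset$X[rows, , drop = FALSE],
                dataset$Y[rows, , drop = FALSE],
                dataset$Z[rows],
                subject_ids = dataset$subject_ids[rows],
                imaging_names = dataset$imaging_names,
                variant_names = dataset$variant_names)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
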