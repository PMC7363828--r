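#' Variant quality-control thresholds
#'
#' Standard panel filters applied to a minor-allele-count genotype matrix:
#' minor allele frequency, genotype call rate, exact Hardy-Weinberg
#' equilibrium p-value, and the per-call genotype-quality score below which
#' calls are set missing.
#'
#' @param maf_min drop variants with MAF below this fraction.
#' @param call_rate_min drop variants with call rate below this fraction.
#' @param hwe_p_min drop variants with exact HWE p below this value.
#' @param gq_min calls with genotype quality below this score are masked.
#' @return A list of class \code{"qc_thresholds"}.
#' @export
qc_thresholds <- function(maf_min = 0.01, call_rate_min = 0.95,
                          hwe_p_min = 1e-6, gq_min = 20L) {
  stopifnot(maf_min >= 0, maf_min <= 1,
            call_rate_min >= 0, call_rate_min <= 1,
            hwe_p_min >= 0, hwe_p_min <= 1,
            gq_min >= 0)
  structure(list(maf_min = maf_min, call_rate_min = call_rate_min,
                 hwe_p_min = hwe_p_min, gq_min = as.integer(gq_min)),
            class = "qc_thresholds")
}

#' Mask genotype calls with low genotyping quality
#'
#' @param genotypes matrix of 0/1/2/NA.
#' @param gq matrix of per-call quality scores, same shape.
#' @param gq_min calls with \code{gq < gq_min} become \code{NA}.
#' @return The genotype matrix with low-quality calls set missing.
#' @export
mask_low_gq <- function(genotypes, gq, gq_min = 20L) {
  if (!identical(dim(genotypes), dim(gq)))
    stop("genotype and GQ matrices must have the same shape")
  genotypes[gq < gq_min] <- NA_real_
  genotypes
}

#' Per-variant allele-frequency and call-rate summary
#'
#' @param column genotype vector with entries in \{0, 1, 2, NA\}.
#' @return List with \code{maf} (minor allele frequency, \code{NA} when the
#'   column is all-missing), \code{call_rate}, and \code{freq} (frequency of
#'   the counted allele).
#' @export
variant_stats <- function(column) {
  obs <- column[!is.na(column)]
  call_rate <- length(obs) / length(column)
  if (length(obs) == 0L)
    return(list(maf = NA_real_, call_rate = 0, freq = NA_real_))
  f <- sum(obs) / (2 * length(obs))
  list(maf = min(f, 1 - f), call_rate = call_rate, freq = f)
}

#' Exact Hardy-Weinberg equilibrium test
#'
#' Exact conditional test on the genotype counts of a biallelic variant:
#' given the observed allele counts, the p-value is the sum of the
#' probabilities of all heterozygote counts whose conditional probability
#' does not exceed that of the observed count (the convention used by the
#' standard genotype-QC toolchain; no mid-p correction).  Monomorphic sites
#' return 1.
#'
#' @param n_hom_ref,n_het,n_hom_alt non-negative genotype counts.
#' @return Exact p-value in (0, 1].
#' @export
hwe_exact_test <- function(n_hom_ref, n_het, n_hom_alt) {
  stopifnot(n_hom_ref >= 0, n_het >= 0, n_hom_alt >= 0)
  n <- n_hom_ref + n_het + n_hom_alt
  if (n < 1L) stop("at least one genotype required")
  n_minor <- min(2 * n_hom_ref + n_het, 2 * n_hom_alt + n_het)
  if (n_minor == 0L) return(1)
  # heterozygote count has the parity of the minor-allele count
  hets <- seq.int(n_minor %% 2L, n_minor, by = 2L)
  # P(het = h | allele counts) = n! 2^h / (hr! h! ha!) / [ (2n)! / (nm! nM!) ]
  logp <- vapply(hets, function(h) {
    hr <- (n_minor - h) / 2          # minor-allele homozygotes
    ha <- n - h - hr
    lgamma(n + 1) - lgamma(hr + 1) - lgamma(h + 1) - lgamma(ha + 1) +
      h * log(2) +
      lgamma(n_minor + 1) + lgamma(2 * n - n_minor + 1) - lgamma(2 * n + 1)
  }, numeric(1))
  prob <- exp(logp - max(logp))
  prob <- prob / sum(prob)
  obs <- prob[match(n_het, hets)]
  if (is.na(obs)) stop("heterozygote count incompatible with allele counts")
  min(1, sum(prob[prob <= obs * (1 + 1e-12)]))
}

hwe_p_column <- function(column) {
  obs <- column[!is.na(column)]
  if (length(obs) == 0L) return(NA_real_)
  hwe_exact_test(sum(obs == 0), sum(obs == 1), sum(obs == 2))
}

#' Apply variant quality control to a genotype matrix
#'
#' Drops variants whose minor allele frequency, call rate, or exact
#' Hardy-Weinberg p-value falls below the configured thresholds, preserving
#' the column order of survivors, and records every decision.
#'
#' @param Y genotype matrix (subjects x variants) of 0/1/2/NA.
#' @param thresholds a \code{\link{qc_thresholds}} object.
#' @return List with \code{Y} (filtered matrix) and \code{report}, a
#'   data.frame of class \code{"qc_report"} with one row per input variant:
#'   \code{variant}, \code{maf}, \code{call_rate}, \code{hwe_p},
#'   \code{kept}, \code{reasons} (semicolon-separated failure reasons).
#' @export
apply_qc <- function(Y, thresholds = qc_thresholds()) {
  stopifnot(inherits(thresholds, "qc_thresholds"))
  vn <- colnames(Y) %||% paste0("snp", seq_len(ncol(Y)))
  rows <- lapply(seq_len(ncol(Y)), function(j) {
    st <- variant_stats(Y[, j])
    hp <- hwe_p_column(Y[, j])
    reasons <- character(0)
    if (is.na(st$maf) || st$maf < thresholds$maf_min)
      reasons <- c(reasons, "maf")
    if (st$call_rate < thresholds$call_rate_min)
      reasons <- c(reasons, "call_rate")
    if (!is.na(hp) && hp < thresholds$hwe_p_min)
      reasons <- c(reasons, "hwe")
    data.frame(variant = vn[j], maf = st$maf, call_rate = st$call_rate,
               hwe_p = hp, kept = length(reasons) == 0L,
               reasons = paste(reasons, collapse = ";"),
               stringsAsFactors = FALSE)
  })
  report <- do.call(rbind, rows)
  attr(report, "thresholds") <- thresholds
  class(report) <- c("qc_report", class(report))
  if (!any(report$kept))
    stop("empty panel: no variant survives quality control")
  list(Y = Y[, report$kept, drop = FALSE], report = report)
}

#' Write a QC report to disk
#'
#' @param report a \code{qc_report}.
#' @param path output path; \code{.json} writes JSON, anything else CSV.
#' @export
write_qc_report <- function(report, path) {
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::write_json(
      list(thresholds = unclass(attr(report, "thresholds")),
           variants = as.data.frame(report)),
      path, auto_unbox = TRUE, digits = NA, na = "null")
  } else {
    utils::write.csv(as.data.frame(report), path, row.names = FALSE)
  }
  invisible(path)
}
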