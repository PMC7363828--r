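#' Configuration for the synthetic imaging-genetics generator
#'
#' Defaults reproduce the shape of the study cohort the package is designed
#' around: 146 subjects, 90 imaging regions, a 72-variant disease panel,
#' with 14 imaging and 24 genetic features carrying the planted signal.
#' The generative model is genotype-driven: a latent factor L is the
#' standardized allele-count score of the causal variants, the imaging
#' support loads on L, and the target is L plus noise — so the
#' imaging-genetic, imaging-target and genetic-target associations are all
#' positive simultaneously, the regime the three-term model assumes.
#'
#' @param n,p,q subjects, imaging features, variants.
#' @param s_x,s_y imaging / genetic support sizes.
#' @param maf_range minor-allele-frequency range of the panel (common
#'   variants by default, as in a curated disease panel).
#' @param beta_g per-variant effect on the latent factor.
#' @param gamma_x loading of support imaging features on L (off-support
#'   features are unit-variance noise).
#' @param delta_z effect of L on the target, in target units (years);
#'   0 gives a pure-noise target.
#' @param sd_x,sd_z noise standard deviations of imaging features and the
#'   target.
#' @param mu_z target mean (years).
#' @param dropout uniform genotype missingness rate.
#' @param seed RNG seed.
#' @return Validated list of class \code{"sim_config"}.
#' @export
sim_config <- function(n = 146L, p = 90L, q = 72L, s_x = 14L, s_y = 24L,
                       maf_range = c(0.2, 0.5), beta_g = 1,
                       gamma_x = 1, delta_z = 9, sd_x = 0.5, sd_z = 4,
                       mu_z = 61, dropout = 0, seed = 1L) {
  stopifnot(n >= 2, p >= 1, q >= 1, s_x <= p, s_y <= q, s_x >= 1,
            s_y >= 1, length(maf_range) == 2,
            maf_range[1] > 0, maf_range[2] <= 0.5,
            maf_range[1] <= maf_range[2],
            sd_x > 0, sd_z > 0, delta_z >= 0, gamma_x >= 0,
            dropout >= 0, dropout < 1)
  structure(list(n = as.integer(n), p = as.integer(p), q = as.integer(q),
                 s_x = as.integer(s_x), s_y = as.integer(s_y),
                 maf_range = maf_range, beta_g = beta_g,
                 gamma_x = gamma_x, delta_z = delta_z,
                 sd_x = sd_x, sd_z = sd_z, mu_z = mu_z,
                 dropout = dropout, seed = as.integer(seed)),
            class = "sim_config")
}

#' Simulate a genotype matrix of minor-allele counts
#'
#' Independent draws: entry (i, j) ~ Binomial(2, maf_j).  No linkage
#' disequilibrium is modelled.
#'
#' @param n subjects.
#' @param q variants.
#' @param mafs vector of allele frequencies in (0, 0.5], length \code{q}.
#' @param seed RNG seed.
#' @return n x q matrix with entries in \{0, 1, 2\} and rsID-style
#'   colnames.
#' @export
sim_genotypes <- function(n, q, mafs, seed = 1L) {
  stopifnot(length(mafs) == q)
  if (any(mafs <= 0 | mafs > 0.5))
    stop("allele frequencies must lie in (0, 0.5]")
  Y <- withr_seed(seed, {
    matrix(stats::rbinom(n * q, 2L, rep(mafs, each = n)), nrow = n)
  })
  dimnames(Y) <- list(paste0("s", seq_len(n)),
                      paste0("rs", 100000L + seq_len(q), "_A"))
  Y
}

#' Simulate an aligned dataset with planted sparse cross-modal structure
#'
#' @param config a \code{\link{sim_config}}.
#' @return List of class \code{"sim_dataset"}: \code{dataset} (an
#'   \code{\link{oscca_dataset}}), \code{support_x}, \code{support_y}
#'   (true support indices), \code{latent} (the factor values), and the
#'   \code{config}.
#' @export
sim_dataset <- function(config = sim_config()) {
  stopifnot(inherits(config, "sim_config"))
  cf <- config
  out <- withr_seed(cf$seed, {
    mafs <- stats::runif(cf$q, cf$maf_range[1], cf$maf_range[2])
    Y <- matrix(stats::rbinom(cf$n * cf$q, 2L, rep(mafs, each = cf$n)),
                nrow = cf$n)
    support_y <- sort(sample.int(cf$q, cf$s_y))
    support_x <- sort(sample.int(cf$p, cf$s_x))
    score <- drop(Y[, support_y, drop = FALSE] %*%
                    rep(cf$beta_g, cf$s_y))
    L <- if (stats::sd(score) > 0) as.vector(scale(score)) else score
    X <- matrix(stats::rnorm(cf$n * cf$p), nrow = cf$n)
    X[, support_x] <- cf$gamma_x * L +
      matrix(stats::rnorm(cf$n * cf$s_x, sd = cf$sd_x), nrow = cf$n)
    Z <- cf$mu_z + cf$delta_z * L + stats::rnorm(cf$n, sd = cf$sd_z)
    if (cf$dropout > 0)
      Y[matrix(stats::runif(cf$n * cf$q) < cf$dropout,
               nrow = cf$n)] <- NA_real_
    list(Y = Y, X = X, Z = Z, L = L,
         support_x = support_x, support_y = support_y)
  })
  dimnames(out$Y) <- list(paste0("s", seq_len(cf$n)),
                          paste0("rs", 100000L + seq_len(cf$q), "_A"))
  dimnames(out$X) <- list(paste0("s", seq_len(cf$n)),
                          paste0("roi", seq_len(cf$p)))
  structure(
    list(dataset = oscca_dataset(out$X, out$Y, out$Z),
         support_x = out$support_x, support_y = out$support_y,
         latent = out$L, config = cf),
    class = "sim_dataset")
}

#' @export
print.sim_dataset <- function(x, ...) {
  cat("Synthetic imaging-genetics dataset (planted sparse structure)\n")
  print(x$dataset)
  cat(sprintf("  true supports: %d imaging, %d genetic; delta_z = %.3g\n",
              length(x$support_x), length(x$support_y),
              x$config$delta_z))
  invisible(x)
}

#' Synthetic variant annotation and gene-set collection
#'
#' Builds an rsID-to-gene table for \code{q} variants and a collection of
#' gene sets in which one planted set preferentially contains the genes of
#' the true-support variants, so over-representation analysis of a correct
#' selection should rank the planted set first.  All names are synthetic.
#'
#' @param variant_names character vector of variant labels (a trailing
#'   allele suffix like \code{"_A"} is stripped for the rsID column).
#' @param support_y indices of the true-support variants.
#' @param n_genes size of the gene universe.
#' @param set_size size of every gene set, including the planted one.
#' @param n_decoys number of decoy sets drawn uniformly from the universe.
#' @param seed RNG seed.
#' @return List: \code{annotation} (data.frame rsid/gene), \code{sets}
#'   (named list, first element \code{"planted"}), \code{universe},
#'   \code{planted} (name of the planted set).
#' @export
sim_annotation <- function(variant_names, support_y, n_genes = 200L,
                           set_size = 25L, n_decoys = 19L, seed = 1L) {
  stopifnot(n_genes >= set_size, set_size >= 1)
  q <- length(variant_names)
  rsids <- sub("_[ACGT]$", "", variant_names)
  withr_seed(seed, {
    universe <- paste0("GENE", seq_len(n_genes))
    planted_genes <- universe[seq_len(set_size)]
    gene_of <- character(q)
    # support variants map into the planted set, the rest map uniformly
    gene_of[support_y] <- sample(planted_genes, length(support_y),
                                 replace = length(support_y) > set_size)
    rest <- setdiff(seq_len(q), support_y)
    gene_of[rest] <- sample(universe, length(rest), replace = TRUE)
    sets <- c(list(planted = planted_genes),
              stats::setNames(
                lapply(seq_len(n_decoys),
                       function(i) sample(universe, set_size)),
                paste0("decoy", seq_len(n_decoys))))
    list(annotation = data.frame(rsid = rsids, gene = gene_of,
                                 stringsAsFactors = FALSE),
         sets = sets, universe = universe, planted = "planted")
  })
}

#' Write all pipeline input files for a synthetic dataset
#'
#' Emits the imaging CSV, the additive-recode genotype text file, the
#' target CSV, the rsID-to-gene TSV, the GMT gene-set collection, and the
#' ground truth as JSON.
#'
#' @param sim a \code{\link{sim_dataset}}.
#' @param dir output directory (created if needed).
#' @param annotation optional result of \code{\link{sim_annotation}};
#'   generated from the simulation's truth by default.
#' @return The directory, invisibly; files: \code{imaging.csv},
#'   \code{genotypes.raw}, \code{target.csv}, \code{annotation.tsv},
#'   \code{gene_sets.gmt}, \code{truth.json}.
#' @export
write_sim_inputs <- function(sim, dir, annotation = NULL) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  d <- sim$dataset
  write_imaging_table(d$X, file.path(dir, "imaging.csv"))
  write_plink_raw(d$Y, file.path(dir, "genotypes.raw"))
  write_target(stats::setNames(d$Z, d$subject_ids),
               file.path(dir, "target.csv"), value_name = "aao")
  ann <- annotation %||% sim_annotation(d$variant_names, sim$support_y,
                                        seed = sim$config$seed)
  utils::write.table(ann$annotation, file.path(dir, "annotation.tsv"),
                     sep = "\t", row.names = FALSE, quote = FALSE)
  write_gmt(ann$sets, file.path(dir, "gene_sets.gmt"))
  writeLines(ann$universe, file.path(dir, "universe.txt"))
  jsonlite::write_json(
    list(support_x = sim$support_x, support_y = sim$support_y,
         latent = sim$latent, config = unclass(sim$config),
         planted_set = ann$planted),
    file.path(dir, "truth.json"), auto_unbox = TRUE, digits = NA)
  invisible(dir)
}
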