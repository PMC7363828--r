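#' Validate and fill a pipeline configuration
#'
#' Checks a parsed configuration (usually from a YAML file), fills every
#' missing field with its default, and reports all violations together,
#' each naming the offending field.  Defaults follow the study protocol:
#' five outer and five inner folds, 500 regression trees, QC thresholds
#' MAF 0.01 / call rate 0.95 / HWE 1e-6 / GQ 20, target-term weight 1.
#'
#' @param cfg a named list (possibly empty).
#' @param base_dir directory against which relative input paths are
#'   resolved.
#' @param require_inputs character vector of input fields that must name
#'   existing files for the intended subcommand.
#' @return The fully-resolved configuration, class \code{"run_config"}.
#' @export
validate_config <- function(cfg = list(), base_dir = ".",
                            require_inputs = character(0)) {
  errs <- character(0)
  cfg$inputs <- cfg$inputs %||% list()
  cfg$qc <- cfg$qc %||% list()
  defaults <- list(
    k_outer = 5L, k_inner = 5L, n_trees = 500L, w = 1,
    seed = 1L, baselines = FALSE, tune_rule = "max_mean",
    fs_threshold = 0.2, max_iter = 100L, tol = 1e-6,
    output_dir = "oscca_output", grid = NULL, sim = list())
  for (nm in names(defaults))
    if (is.null(cfg[[nm]])) cfg[[nm]] <- defaults[[nm]]
  qc_def <- list(maf_min = 0.01, call_rate_min = 0.95,
                 hwe_p_min = 1e-6, gq_min = 20L)
  for (nm in names(qc_def))
    if (is.null(cfg$qc[[nm]])) cfg$qc[[nm]] <- qc_def[[nm]]

  if (cfg$k_outer < 2) errs <- c(errs, "k_outer: must be at least 2")
  if (cfg$k_inner < 2) errs <- c(errs, "k_inner: must be at least 2")
  if (cfg$n_trees < 1) errs <- c(errs, "n_trees: must be positive")
  if (cfg$w < 0) errs <- c(errs, "w: must be non-negative")
  if (cfg$tol <= 0) errs <- c(errs, "tol: must be positive")
  if (!cfg$tune_rule %in% c("max_mean", "mean_best"))
    errs <- c(errs, "tune_rule: must be 'max_mean' or 'mean_best'")
  for (nm in c("maf_min", "call_rate_min")) {
    v <- cfg$qc[[nm]]
    if (!is.numeric(v) || v < 0 || v > 1)
      errs <- c(errs, paste0("qc.", nm, ": must lie in [0, 1]"))
  }
  if (cfg$qc$gq_min < 0) errs <- c(errs, "qc.gq_min: must be non-negative")

  for (nm in names(cfg$inputs)) {
    pth <- cfg$inputs[[nm]]
    if (!is.null(pth) && !file.exists(pth))
      cfg$inputs[[nm]] <- file.path(base_dir, pth)
  }
  for (nm in require_inputs) {
    pth <- cfg$inputs[[nm]]
    if (is.null(pth))
      errs <- c(errs, paste0("inputs.", nm, ": missing path"))
    else if (!file.exists(pth))
      errs <- c(errs, paste0("inputs.", nm, ": file not found (", pth, ")"))
  }
  if (length(errs))
    stop("invalid configuration:\n  ", paste(errs, collapse = "\n  "),
         call. = FALSE)
  class(cfg) <- "run_config"
  cfg
}

# Read the three input tables and align them on shared subject IDs, in the
# imaging table's order.
load_dataset <- function(cfg) {
  X <- read_imaging_table(cfg$inputs$imaging)
  Y <- read_plink_raw(cfg$inputs$genotype)
  z <- read_target(cfg$inputs$target)
  ids <- intersect(intersect(rownames(X), rownames(Y)), names(z))
  if (length(ids) < 2L)
    stop("fewer than 2 subjects shared by the three input files")
  ids <- rownames(X)[rownames(X) %in% ids]
  oscca_dataset(X[ids, , drop = FALSE], Y[ids, , drop = FALSE], z[ids],
                subject_ids = ids)
}

stage_dir <- function(cfg, stage, force = FALSE) {
  dir <- file.path(cfg$output_dir, stage)
  if (dir.exists(dir) && length(list.files(dir)) > 0 && !force)
    stop("output directory ", dir,
         " already contains results; use --force to overwrite")
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  dir
}

log_run <- function(dir, cfg, stage) {
  writeLines(c(
    paste0("stage: ", stage),
    paste0("package: oscca ",
           as.character(utils::packageVersion("oscca"))),
    paste0("R: ", R.version.string),
    "config:",
    utils::capture.output(utils::str(unclass(cfg)))),
    file.path(dir, "run_log.txt"))
}

#' Run one pipeline stage from command-line style arguments
#'
#' Subcommands: \code{simulate} (write synthetic input files), \code{qc}
#' (variant quality control), \code{fit} (tune and fit the sparse CCA on
#' the full data), \code{nested-cv} (the full nested evaluation;
#' \code{baselines: true} adds the LASSO/mRMR comparisons with the mRMR
#' feature count matched to the main selection), \code{baselines}
#' (standalone full-data comparison selectors), \code{enrich}
#' (over-representation analysis of the consensus variants), and
#' \code{report} (recompute the averaged metrics table from per-fold
#' files).  Each stage writes its outputs plus a run log under
#' \code{output_dir/<stage>}.
#'
#' @param argv character vector: subcommand, then \code{--config path},
#'   optionally \code{--force}.
#' @return 0 on success (invisibly); errors propagate as conditions.
#' @export
run_pipeline_command <- function(argv) {
  if (length(argv) < 1L)
    stop("usage: <subcommand> --config <file> [--force]")
  sub <- argv[[1L]]
  force <- "--force" %in% argv
  ci <- which(argv == "--config")
  cfg_raw <- if (length(ci))
    yaml::read_yaml(argv[[ci + 1L]]) else list()
  base_dir <- if (length(ci)) dirname(argv[[ci + 1L]]) else "."

  need <- switch(sub,
    "simulate" = character(0),
    "qc" = "genotype",
    "fit" = ,
    "nested-cv" = ,
    "baselines" = c("imaging", "genotype", "target"),
    "enrich" = c("annotation", "gene_sets"),
    "report" = character(0),
    stop("unknown subcommand '", sub, "'"))
  cfg <- validate_config(cfg_raw, base_dir = base_dir,
                         require_inputs = need)

  if (sub == "simulate") {
    dir <- stage_dir(cfg, "inputs", force)
    sim_args <- cfg$sim %||% list()
    sim_args$seed <- sim_args$seed %||% cfg$seed
    sim <- sim_dataset(do.call(sim_config, sim_args))
    write_sim_inputs(sim, dir)
    log_run(dir, cfg, sub)
  } else if (sub == "qc") {
    dir <- stage_dir(cfg, "qc", force)
    Y <- read_plink_raw(cfg$inputs$genotype)
    thr <- qc_thresholds(cfg$qc$maf_min, cfg$qc$call_rate_min,
                         cfg$qc$hwe_p_min, cfg$qc$gq_min)
    res <- apply_qc(Y, thr)
    write_plink_raw(res$Y, file.path(dir, "genotypes_qc.raw"))
    write_qc_report(res$report, file.path(dir, "qc_report.csv"))
    write_qc_report(res$report, file.path(dir, "qc_report.json"))
    log_run(dir, cfg, sub)
  } else if (sub == "fit") {
    dir <- stage_dir(cfg, "fit", force)
    d <- load_dataset(cfg)
    tuning <- tune_lambdas(d, grid = cfg$grid, w = cfg$w,
                           k = cfg$k_inner, seed = cfg$seed,
                           rule = cfg$tune_rule)
    s <- standardize_blocks(d)
    fit <- oscca(s$X, s$Y, s$Z,
                 lambda_u = tuning$best[["lambda_u"]],
                 lambda_v = tuning$best[["lambda_v"]],
                 w = cfg$w, standardize = FALSE,
                 max_iter = cfg$max_iter, tol = cfg$tol)
    write_oscca_json(fit, file.path(dir, "fit.json"))
    utils::write.csv(tuning$table, file.path(dir, "tuning.csv"),
                     row.names = FALSE)
    log_run(dir, cfg, sub)
  } else if (sub == "nested-cv") {
    dir <- stage_dir(cfg, "nested_cv", force)
    d <- load_dataset(cfg)
    res <- oscca_nested_cv(d, k_outer = cfg$k_outer,
                           k_inner = cfg$k_inner, grid = cfg$grid,
                           w = cfg$w, n_trees = cfg$n_trees,
                           seed = cfg$seed, baselines = cfg$baselines,
                           tune_rule = cfg$tune_rule,
                           max_iter = cfg$max_iter, tol = cfg$tol)
    write_nested_cv(res, dir)
    log_run(dir, cfg, sub)
  } else if (sub == "baselines") {
    dir <- stage_dir(cfg, "baselines", force)
    d <- load_dataset(cfg)
    s <- standardize_blocks(d)
    tuning <- tune_lambdas(d, grid = cfg$grid, w = cfg$w,
                           k = cfg$k_inner, seed = cfg$seed)
    fit <- oscca(s$X, s$Y, s$Z,
                 lambda_u = tuning$best[["lambda_u"]],
                 lambda_v = tuning$best[["lambda_v"]],
                 w = cfg$w, standardize = FALSE)
    sel <- selected_features(fit)
    k_img <- max(1L, length(sel$imaging))
    k_gen <- max(1L, length(sel$genetic))
    write_ranking(mrmr_rank(s$X, d$Z, k_img),
                  file.path(dir, "mrmr_imaging.csv"), d$imaging_names)
    write_ranking(mrmr_rank(s$Y, d$Z, k_gen),
                  file.path(dir, "mrmr_genetic.csv"), d$variant_names)
    li <- lasso_select(s$X, d$Z, seed = cfg$seed)
    lg <- lasso_select(s$Y, d$Z, seed = cfg$seed + 1L)
    utils::write.csv(
      rbind(data.frame(block = "imaging", index = li,
                       name = d$imaging_names[li]),
            data.frame(block = "genetic", index = lg,
                       name = d$variant_names[lg])),
      file.path(dir, "lasso_selected.csv"), row.names = FALSE)
    log_run(dir, cfg, sub)
  } else if (sub == "enrich") {
    dir <- stage_dir(cfg, "enrichment", force)
    sel_file <- cfg$inputs$selection %||%
      file.path(cfg$output_dir, "nested_cv", "nested_cv.json")
    if (!file.exists(sel_file))
      stop("no variant selection found; run nested-cv first or set inputs.selection")
    rsids <- if (grepl("\\.json$", sel_file)) {
      res <- jsonlite::read_json(sel_file, simplifyVector = TRUE)
      sub("_[ACGT]$", "", res$consensus$genetic_names)
    } else sub("_[ACGT]$", "", readLines(sel_file))
    ann <- read_annotation(cfg$inputs$annotation)
    sets <- read_gmt(cfg$inputs$gene_sets)
    universe <- if (!is.null(cfg$inputs$universe))
      readLines(cfg$inputs$universe) else NULL
    genes <- map_snps_to_genes(rsids, ann)
    ora <- run_ora(genes, sets, universe = universe)
    utils::write.csv(as.data.frame(ora), file.path(dir, "ora.csv"),
                     row.names = FALSE)
    writeLines(genes, file.path(dir, "mapped_genes.txt"))
    log_run(dir, cfg, sub)
  } else if (sub == "report") {
    dir <- stage_dir(cfg, "report", force)
    fm <- utils::read.csv(file.path(cfg$output_dir, "nested_cv",
                                    "fold_metrics.csv"))
    metrics <- evaluate_models(fm)
    utils::write.csv(metrics, file.path(dir, "metrics_report.csv"),
                     row.names = FALSE)
    print(metrics, row.names = FALSE, digits = 4)
    log_run(dir, cfg, sub)
  }
  invisible(0L)
}
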