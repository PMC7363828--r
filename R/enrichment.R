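#' Map selected variants to genes
#'
#' Looks selected rsIDs up in an annotation table and returns the
#' deduplicated union of mapped genes in order of first appearance.
#' Annotation cells may carry several genes separated by \code{/} (a
#' variant between or tagging two genes maps to both).
#'
#' @param rsids character vector of variant identifiers.
#' @param annotation data.frame with columns \code{rsid} and \code{gene}
#'   (see \code{\link{read_annotation}}).
#' @return Character vector of gene names; uncovered rsIDs are reported in
#'   attribute \code{"unmapped"} and a warning.
#' @export
map_snps_to_genes <- function(rsids, annotation) {
  hit <- match(rsids, annotation$rsid)
  unmapped <- rsids[is.na(hit)]
  if (length(unmapped) == length(rsids))
    stop("none of the rsIDs are covered by the annotation")
  if (length(unmapped))
    warning(length(unmapped), " rsID(s) without annotation: ",
            paste(utils::head(unmapped, 5), collapse = ", "))
  genes <- unlist(strsplit(annotation$gene[hit[!is.na(hit)]], "/",
                           fixed = TRUE))
  genes <- trimws(genes)
  genes <- genes[nzchar(genes)]
  out <- genes[!duplicated(genes)]
  attr(out, "unmapped") <- unmapped
  out
}

#' Upper-tail hypergeometric probability
#'
#' \eqn{P(X \ge k)} for \eqn{X \sim} Hypergeometric(population \code{N},
#' \code{K} successes, \code{n} draws) — the over-representation p-value
#' for observing \code{k} or more genes of a size-\code{K} set in a
#' selection of \code{n} genes from a universe of \code{N}.
#'
#' @param k observed overlap.
#' @param K gene-set size in the universe.
#' @param n number of selected genes.
#' @param N universe size.
#' @return p-value in (0, 1].
#' @export
hypergeom_tail <- function(k, K, n, N) {
  if (k < 0 || K < 0 || n < 0 || N < 1 || k > min(K, n) ||
      K > N || n > N)
    stop("inconsistent hypergeometric counts")
  if (k == 0) return(1)
  stats::phyper(k - 1, K, N - K, n, lower.tail = FALSE)
}

#' Benjamini-Hochberg false-discovery-rate adjustment
#'
#' Step-up adjustment with monotonicity enforcement.
#'
#' @param pvals vector of p-values in [0, 1].
#' @return Adjusted values (same order as the input).
#' @export
bh_fdr <- function(pvals) {
  if (any(pvals < 0 | pvals > 1, na.rm = TRUE))
    stop("p-values must lie in [0, 1]")
  stats::p.adjust(pvals, method = "BH")
}

#' Over-representation analysis of a gene selection
#'
#' One upper-tail hypergeometric test per gene set against the collection's
#' reference universe, with Benjamini-Hochberg adjustment across the tested
#' sets.  Selected genes outside the universe are dropped (and counted),
#' mirroring the usual annotation loss between a variant-derived gene list
#' and a curated reference.
#'
#' @param genes character vector of selected gene names.
#' @param sets named list of character vectors (e.g. from
#'   \code{\link{read_gmt}}).
#' @param universe reference gene list; defaults to the union of the sets.
#' @return data.frame of class \code{"ora_result"}, sorted by ascending p:
#'   \code{set}, \code{overlap}, \code{set_size}, \code{n_selected},
#'   \code{universe_size}, \code{p}, \code{fdr}.  Attribute
#'   \code{"n_dropped"} counts selected genes outside the universe.
#' @export
run_ora <- function(genes, sets, universe = NULL) {
  universe <- unique(universe %||% unlist(sets, use.names = FALSE))
  sets <- lapply(sets, function(s) intersect(unique(s), universe))
  if (any(lengths(sets) == 0L))
    stop("gene set(s) with no members inside the universe")
  genes <- unique(genes)
  eff <- intersect(genes, universe)
  if (length(eff) == 0L)
    stop("no selected gene lies in the reference universe")
  n_dropped <- length(genes) - length(eff)
  N <- length(universe); n <- length(eff)
  rows <- lapply(names(sets), function(nm) {
    K <- length(sets[[nm]])
    k <- length(intersect(eff, sets[[nm]]))
    data.frame(set = nm, overlap = k, set_size = K, n_selected = n,
               universe_size = N, p = hypergeom_tail(k, K, n, N),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$fdr <- bh_fdr(out$p)
  out <- out[order(out$p, out$set), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "n_dropped") <- n_dropped
  class(out) <- c("ora_result", class(out))
  out
}
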