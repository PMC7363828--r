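#' Read a delimited imaging feature table
#'
#' Reads a CSV/TSV table of continuous imaging features (e.g. mean FA per
#' atlas region) with one ID column and one header label per feature.
#'
#' @param path file path; the delimiter is inferred from the extension
#'   (\code{.tsv}/\code{.txt} = tab, otherwise comma) unless given.
#' @param id_col name or index of the subject-ID column (default: first).
#' @param sep field separator, overriding the inferred one.
#' @return A numeric matrix with subject IDs as rownames and feature labels
#'   as colnames, in file order.
#' @export
read_imaging_table <- function(path, id_col = 1L, sep = NULL) {
  sep <- sep %||% if (grepl("\\.(tsv|txt)$", path, ignore.case = TRUE)) "\t" else ","
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          check.names = FALSE, stringsAsFactors = FALSE,
                          colClasses = NA)
  if (is.character(id_col)) {
    id_idx <- match(id_col, names(df))
    if (is.na(id_idx)) stop("ID column '", id_col, "' not found")
  } else id_idx <- as.integer(id_col)
  if (anyDuplicated(names(df)))   # before subsetting, which uniquifies
    stop("duplicate feature labels in ", path)
  ids <- as.character(df[[id_idx]])
  vals <- df[-id_idx]
  if (anyDuplicated(ids))
    stop("duplicate subject IDs in ", path)
  num <- lapply(vals, function(col) {
    if (is.character(col) || is.factor(col)) {
      out <- suppressWarnings(as.numeric(as.character(col)))
      if (anyNA(out) && !all(is.na(col)))
        stop("non-numeric cell in feature table ", path)
      out
    } else as.numeric(col)
  })
  m <- do.call(cbind, num)
  dimnames(m) <- list(ids, names(vals))
  m
}

#' Write an imaging feature table
#'
#' @param m numeric matrix with rownames (IDs) and colnames (labels).
#' @param path output CSV path.
#' @export
write_imaging_table <- function(m, path) {
  # %.17g so doubles survive the text round trip exactly
  body <- apply(m, 1, function(r)
    paste(sprintf("%.17g", r), collapse = ","))
  writeLines(c(paste(c("ID", colnames(m)), collapse = ","),
               paste(rownames(m), body, sep = ",")), path)
  invisible(path)
}

#' Read a PLINK additive-recoded genotype file
#'
#' Parses the whitespace-delimited \code{.raw} dialect produced by
#' \code{plink --recode A}: six leading columns (FID IID PAT MAT SEX
#' PHENOTYPE) followed by one column per variant holding the count of the
#' counted allele (0, 1, 2) or \code{NA} for a missing call.
#'
#' @param path file path.
#' @return A numeric matrix (subjects x variants) with IID rownames and the
#'   header variant tokens (rsID plus counted-allele suffix) as colnames.
#' @export
read_plink_raw <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) < 1L) stop("empty .raw file ", path)
  toks <- strsplit(trimws(lines), "[ \t]+")
  header <- toks[[1L]]
  std <- c("FID", "IID", "PAT", "MAT", "SEX", "PHENOTYPE")
  if (length(header) < 6L || !identical(toupper(header[1:6]), std))
    stop(".raw header must start with the six standard columns FID IID PAT MAT SEX PHENOTYPE")
  vn <- header[-(1:6)]
  body <- toks[-1L]
  ncol_exp <- length(header)
  ids <- character(length(body))
  m <- matrix(NA_real_, nrow = length(body), ncol = length(vn))
  for (i in seq_along(body)) {
    row <- body[[i]]
    if (length(row) != ncol_exp)
      stop("ragged row ", i, " in ", path)
    ids[i] <- row[2L]
    cell <- row[-(1:6)]
    g <- ifelse(cell == "NA", NA_real_,
                suppressWarnings(as.numeric(cell)))
    bad <- !is.na(cell) & cell != "NA" & (is.na(g) | !(g %in% c(0, 1, 2)))
    if (any(bad))
      stop("genotype cell outside {0,1,2,NA} in row ", i, " of ", path)
    m[i, ] <- g
  }
  dimnames(m) <- list(ids, vn)
  m
}

#' Write a genotype matrix in PLINK additive-recoded dialect
#'
#' @param Y genotype matrix of 0/1/2/NA with IDs as rownames and variant
#'   tokens as colnames.
#' @param path output path.
#' @export
write_plink_raw <- function(Y, path) {
  ids <- rownames(Y) %||% paste0("s", seq_len(nrow(Y)))
  header <- c("FID", "IID", "PAT", "MAT", "SEX", "PHENOTYPE",
              colnames(Y) %||% paste0("snp", seq_len(ncol(Y))))
  rows <- vapply(seq_len(nrow(Y)), function(i) {
    g <- Y[i, ]
    cells <- ifelse(is.na(g), "NA", format(g, trim = TRUE))
    paste(c(ids[i], ids[i], "0", "0", "0", "-9", cells), collapse = " ")
  }, character(1))
  writeLines(c(paste(header, collapse = " "), rows), path)
  invisible(path)
}

#' Read a per-subject target table
#'
#' @param path CSV with columns ID and value (header required).
#' @return Named numeric vector of target values.
#' @export
read_target <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
  if (ncol(df) < 2L) stop("target file needs an ID column and a value column")
  z <- as.numeric(df[[2L]])
  if (anyNA(z)) stop("non-numeric or missing target values in ", path)
  names(z) <- as.character(df[[1L]])
  z
}

#' @rdname read_target
#' @param z named numeric vector.
#' @param value_name header used for the value column.
#' @export
write_target <- function(z, path, value_name = "target") {
  ids <- names(z) %||% paste0("s", seq_along(z))
  writeLines(c(paste0("ID,", value_name),
               paste(ids, sprintf("%.17g", z), sep = ",")), path)
  invisible(path)
}

#' Read a gene-set collection in GMT format
#'
#' One set per line: name, description, then member genes, tab-separated.
#'
#' @param path GMT file path.
#' @return Named list of character vectors.
#' @export
read_gmt <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  toks <- strsplit(lines, "\t", fixed = TRUE)
  sets <- lapply(toks, function(t) unique(t[-(1:2)]))
  names(sets) <- vapply(toks, `[[`, character(1), 1L)
  if (anyDuplicated(names(sets))) stop("duplicate set names in ", path)
  sets
}

#' @rdname read_gmt
#' @param sets named list of character vectors.
#' @export
write_gmt <- function(sets, path) {
  lines <- vapply(names(sets), function(nm) {
    paste(c(nm, "na", sets[[nm]]), collapse = "\t")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

#' Read an rsID-to-gene annotation table
#'
#' @param path TSV/CSV with columns \code{rsid} and \code{gene}; a cell may
#'   list several genes separated by \code{/}.
#' @return data.frame with columns \code{rsid}, \code{gene}.
#' @export
read_annotation <- function(path) {
  sep <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          stringsAsFactors = FALSE, check.names = FALSE)
  names(df) <- tolower(names(df))
  if (!all(c("rsid", "gene") %in% names(df)))
    stop("annotation table needs 'rsid' and 'gene' columns")
  df[c("rsid", "gene")]
}
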