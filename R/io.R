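#' Read a gene x sample count table
#'
#' Accepts either a TSV (first column the gene id, remaining columns
#' integer counts per sample, header row mandatory) or a MatrixMarket
#' triplet file with `genes.tsv` / `samples.tsv` index files alongside
#' (one id per line, no header). Malformed input is reported with the
#' offending line number.
#'
#' @param path TSV file, or an `.mtx` file with sibling index files
#' @return a [count_matrix()]
#' @export
read_counts <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  if (grepl("\\.mtx$", path)) return(.read_counts_mtx(path))
  nf <- utils::count.fields(path, sep = "\t", quote = "")
  if (length(unique(nf)) != 1)
    stop("ragged rows in ", path, " at line(s): ",
         paste(which(nf != nf[1]), collapse = ", "))
  tab <- utils::read.delim(path, stringsAsFactors = FALSE, quote = "",
                           check.names = FALSE,
                           colClasses = c("character", rep(NA, nf[1] - 1)))
  genes <- tab[[1]]
  if (anyDuplicated(genes)) {
    dup <- which(duplicated(genes))[1]
    stop("duplicate gene id '", genes[dup], "' at line ", dup + 1)
  }
  raw <- as.matrix(tab[, -1, drop = FALSE])
  m <- suppressWarnings(matrix(as.numeric(raw), nrow(raw), ncol(raw),
                               dimnames = dimnames(raw)))
  bad_row <- apply(m, 1, function(r)
    any(is.na(r)) || any(r != round(r)) || any(r < 0))
  if (any(bad_row))
    stop("non-integer or negative count at line ", which(bad_row)[1] + 1)
  rownames(m) <- genes
  count_matrix(m)
}

.read_counts_mtx <- function(path) {
  base <- sub("\\.mtx$", "", path)
  gene_file <- paste0(base, "_genes.tsv")
  sample_file <- paste0(base, "_samples.tsv")
  for (f in c(gene_file, sample_file))
    if (!file.exists(f)) stop("missing MTX index file: ", f)
  m <- as.matrix(Matrix::readMM(path))
  rownames(m) <- readLines(gene_file)
  colnames(m) <- readLines(sample_file)
  count_matrix(m)
}

#' Write a count matrix
#'
#' `format = "tsv"` writes the gene-id + counts table; `format = "mtx"`
#' writes a MatrixMarket triplet plus `<base>_genes.tsv` and
#' `<base>_samples.tsv` index files.
#'
#' @param x a [count_matrix()]
#' @param path output path (`.mtx` extension for MTX)
#' @param format "tsv" or "mtx"
#' @export
write_counts <- function(x, path, format = c("tsv", "mtx")) {
  stopifnot(inherits(x, "count_matrix"))
  format <- match.arg(format)
  if (format == "tsv") {
    tab <- data.frame(gene = rownames(x$counts), x$counts,
                      check.names = FALSE, stringsAsFactors = FALSE)
    utils::write.table(tab, path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  } else {
    base <- sub("\\.mtx$", "", path)
    Matrix::writeMM(Matrix::Matrix(x$counts, sparse = TRUE),
                    paste0(base, ".mtx"))
    writeLines(rownames(x$counts), paste0(base, "_genes.tsv"))
    writeLines(colnames(x$counts), paste0(base, "_samples.tsv"))
  }
  invisible(path)
}

#' Read / write the sample sheet
#'
#' TSV with columns sample, line_type, treatment, timepoint (and
#' optionally replicate); levels are validated against the closed
#' vocabularies by [sample_design()].
#'
#' @param path TSV path
#' @return a [sample_design()]
#' @export
read_samples <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  sample_design(utils::read.delim(path, stringsAsFactors = FALSE, quote = ""))
}

#' @rdname read_samples
#' @param design a [sample_design()]
#' @export
write_samples <- function(design, path) {
  stopifnot(inherits(design, "sample_design"))
  utils::write.table(design$samples, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Read / write TMM normalization factors (two-column TSV)
#' @param factors a [tmm_factors()] result
#' @param path TSV path
#' @export
write_norm_factors <- function(factors, path) {
  utils::write.table(
    data.frame(sample = names(factors), factor = as.numeric(factors)),
    path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_norm_factors
#' @export
read_norm_factors <- function(path) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  stats::setNames(tab$factor, tab$sample)
}

#' Write / read a differential-expression result table
#'
#' Columns gene, logFC, AveExpr, t, P.Value, adj.P.Val in the common
#' topTable order; values rounded to 6 significant digits.
#'
#' @param res a `dge_result`
#' @param path TSV path
#' @export
write_dge_result <- function(res, path) {
  stopifnot(inherits(res, "dge_result"))
  tab <- data.frame(gene = res$gene,
                    logFC = signif(res$log2_fc, 6),
                    AveExpr = signif(res$ave_expr, 6),
                    t = signif(res$t, 6),
                    P.Value = signif(res$p_value, 6),
                    adj.P.Val = signif(res$fdr, 6),
                    stringsAsFactors = FALSE)
  utils::write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_dge_result
#' @param contrast optional contrast name to attach as metadata
#' @export
read_dge_result <- function(path, contrast = NULL) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE,
                           colClasses = c(gene = "character"))
  out <- data.frame(gene = tab$gene, log2_fc = tab$logFC,
                    ave_expr = tab$AveExpr, t = tab$t,
                    p_value = tab$P.Value, fdr = tab$adj.P.Val,
                    stringsAsFactors = FALSE)
  structure(out, class = c("dge_result", "data.frame"), contrast = contrast)
}

#' Write the per-gene plasticity calls table
#' @param calls a `plasticity_calls` table
#' @param path TSV path
#' @export
write_calls <- function(calls, path) {
  stopifnot(inherits(calls, "plasticity_calls"))
  tab <- calls
  num <- vapply(tab, is.numeric, logical(1))
  tab[num] <- lapply(tab[num], signif, digits = 6)
  utils::write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
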