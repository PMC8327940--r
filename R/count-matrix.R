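#' Construct a gene x sample count matrix
#'
#' Light container for bulk RNA-seq digital gene expression: an integer
#' matrix with genes in rows and samples in columns, plus per-sample
#' library sizes. Library sizes default to the column sums; after
#' expression filtering they deliberately retain the pre-filter totals
#' (see [filter_by_expression()]), which is why they are stored rather
#' than recomputed on the fly.
#'
#' @param counts numeric matrix of non-negative integers with unique
#'   rownames (gene ids) and colnames (sample ids).
#' @param lib_sizes optional numeric vector of per-sample library sizes
#'   (total reads); defaults to `colSums(counts)`. Must be positive.
#' @return An object of class `count_matrix`: a list with elements
#'   `counts` (the matrix) and `lib_sizes` (named numeric).
#' @examples
#' m <- matrix(rpois(20, 50), 5, 4,
#'             dimnames = list(paste0("g", 1:5), paste0("s", 1:4)))
#' cm <- count_matrix(m)
#' dim(cm)
#' @export
count_matrix <- function(counts, lib_sizes = NULL) {
  counts <- as.matrix(counts)
  if (is.null(rownames(counts)) || is.null(colnames(counts)))
    stop("counts must have gene rownames and sample colnames")
  if (anyDuplicated(rownames(counts)))
    stop("duplicate gene id: ",
         paste(unique(rownames(counts)[duplicated(rownames(counts))]), collapse = ", "))
  if (anyDuplicated(colnames(counts)))
    stop("duplicate sample id: ",
         paste(unique(colnames(counts)[duplicated(colnames(counts))]), collapse = ", "))
  if (!is.numeric(counts) || any(counts < 0) || any(counts != round(counts)))
    stop("counts must be non-negative integers")
  storage.mode(counts) <- "double"  # keeps counts > .Machine$integer.max safe
  if (is.null(lib_sizes)) {
    lib_sizes <- colSums(counts)
  } else {
    if (length(lib_sizes) != ncol(counts))
      stop("lib_sizes length must match the number of samples")
    lib_sizes <- as.numeric(lib_sizes)
    names(lib_sizes) <- colnames(counts)
  }
  if (any(lib_sizes <= 0))
    stop("zero or negative library size for sample: ",
         paste(colnames(counts)[lib_sizes <= 0], collapse = ", "))
  structure(list(counts = counts, lib_sizes = lib_sizes),
            class = "count_matrix")
}

#' @export
dim.count_matrix <- function(x) dim(x$counts)

#' @export
dimnames.count_matrix <- function(x) dimnames(x$counts)

#' @export
print.count_matrix <- function(x, ...) {
  cat("count_matrix:", nrow(x$counts), "genes x", ncol(x$counts), "samples\n")
  cat("library sizes:", format(min(x$lib_sizes), big.mark = ","), "-",
      format(max(x$lib_sizes), big.mark = ","), "\n")
  invisible(x)
}

#' Subset a count matrix by gene and/or sample
#'
#' Library sizes follow the selected samples but are NOT recomputed from
#' the remaining genes, so gene subsetting preserves the original
#' sequencing depths.
#' @param x a `count_matrix`
#' @param i,j gene / sample indices
#' @param ... ignored
#' @export
`[.count_matrix` <- function(x, i, j, ...) {
  if (missing(i)) i <- seq_len(nrow(x$counts))
  if (missing(j)) j <- seq_len(ncol(x$counts))
  sub <- x$counts[i, j, drop = FALSE]
  structure(list(counts = sub, lib_sizes = x$lib_sizes[j]),
            class = "count_matrix")
}
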