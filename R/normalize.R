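#' Counts per million, optionally log2-transformed
#'
#' Unlogged CPM is `count / (lib_size * factor) * 1e6`. The logged form
#' follows the precision-weighting convention:
#' `log2((count + prior_count) / (lib_size * factor + 2 * prior_count) * 1e6)`,
#' so with the default `prior_count = 0.5` the effective library size is
#' offset by 1 and an all-zero gene in a 1e6-read library maps to
#' about -1.
#'
#' @param x a [count_matrix()]
#' @param log logical; return log2 values?
#' @param prior_count offset added to counts before logging (ignored when
#'   `log = FALSE`)
#' @param norm_factors optional per-sample scaling factors from
#'   [tmm_factors()]; defaults to 1.
#' @return numeric matrix, genes x samples
#' @export
cpm <- function(x, log = FALSE, prior_count = 0.5, norm_factors = NULL) {
  stopifnot(inherits(x, "count_matrix"))
  lib <- .effective_lib_sizes(x, norm_factors)
  if (log) {
    log2(sweep(x$counts + prior_count, 2, lib + 2 * prior_count, "/") * 1e6)
  } else {
    sweep(x$counts, 2, lib, "/") * 1e6
  }
}

.effective_lib_sizes <- function(x, norm_factors) {
  lib <- x$lib_sizes
  if (any(lib <= 0))
    stop("zero library size for sample: ",
         paste(names(lib)[lib <= 0], collapse = ", "))
  if (!is.null(norm_factors)) {
    f <- stats::setNames(as.numeric(norm_factors), names(norm_factors))
    if (length(f) == 1) f <- rep(f, length(lib))
    if (length(f) != length(lib))
      stop("norm_factors length must match the number of samples")
    if (!is.null(names(f))) {
      if (!setequal(names(f), names(lib)))
        stop("norm_factors names do not match the sample ids")
      f <- f[names(lib)]
    }
    lib <- lib * unname(f)
  }
  lib
}

#' Remove genes below a counts-per-million expression floor
#'
#' Keeps genes whose CPM (raw library sizes, no normalization factors)
#' reaches `cpm_min` in at least k samples, where k is the size of the
#' smallest occupied design cell scaled by `min_prop`. The boundary is
#' inclusive: CPM exactly equal to `cpm_min` counts. The returned matrix
#' retains the pre-filter library sizes, so downstream CPM values are
#' unchanged for the surviving genes.
#'
#' @param x a [count_matrix()]
#' @param design a [sample_design()] whose samples match the columns of `x`
#' @param cpm_min minimum CPM (default 10)
#' @param min_prop proportion of the smallest cell that must reach the
#'   floor (default 1 = the whole smallest cell)
#' @return filtered `count_matrix`
#' @export
filter_by_expression <- function(x, design, cpm_min = 10, min_prop = 1) {
  stopifnot(inherits(x, "count_matrix"), inherits(design, "sample_design"))
  if (cpm_min < 0) stop("cpm_min must be non-negative")
  if (min_prop <= 0 || min_prop > 1) stop("min_prop must be in (0, 1]")
  if (!identical(colnames(x$counts), as.character(design$samples$sample)))
    stop("sample sheet does not match the count matrix columns")
  k <- max(1L, floor(min(design$cell_sizes) * min_prop))
  v <- cpm(x, log = FALSE)
  keep <- rowSums(v >= cpm_min) >= k
  x[keep, ]
}

#' Trimmed mean of M-values (TMM) normalization factors
#'
#' Between-sample scaling factors from doubly trimmed, precision-weighted
#' log-ratios against a reference sample. The reference is the sample
#' whose 75th-percentile CPM is closest to the mean of those percentiles
#' (lowest index on ties). For each sample, genes with nonzero counts in
#' both the sample and the reference contribute a log-ratio M, an average
#' log-abundance A and a precision weight (the reciprocal of the
#' delta-method variance of M); genes in the upper or
#' lower `trim_m` tails of M or `trim_a` tails of A are discarded (ranks
#' tie-broken by gene order) and the factor is 2^(weighted mean of the
#' surviving M). Factors are finally scaled to unit geometric mean.
#'
#' @param x a [count_matrix()] with at least two samples
#' @param trim_m tail fraction trimmed on the log-ratios (default 0.30)
#' @param trim_a tail fraction trimmed on the log-abundances (default 0.05)
#' @return object of class `norm_factors`: named numeric vector of
#'   per-sample factors (unit geometric mean) with attribute
#'   `reference_sample`.
#' @export
tmm_factors <- function(x, trim_m = 0.30, trim_a = 0.05) {
  stopifnot(inherits(x, "count_matrix"))
  counts <- x$counts
  lib <- x$lib_sizes
  if (ncol(counts) < 2) stop("TMM needs at least two samples")
  if (any(colSums(counts > 0) == 0))
    stop("sample with no nonzero gene: ",
         paste(colnames(counts)[colSums(counts > 0) == 0], collapse = ", "))
  f75 <- apply(counts, 2, stats::quantile, probs = 0.75, names = FALSE) / lib
  ref <- which.min(abs(f75 - mean(f75)))  # which.min takes the first tie
  f <- vapply(seq_len(ncol(counts)), function(k) {
    .tmm_pair(counts[, k], counts[, ref], lib[k], lib[ref], trim_m, trim_a,
              sample_id = colnames(counts)[k])
  }, numeric(1))
  f <- f / exp(mean(log(f)))
  names(f) <- colnames(counts)
  structure(f, class = "norm_factors",
            reference_sample = colnames(counts)[ref])
}

# One sample against the reference: doubly trimmed weighted mean of M.
.tmm_pair <- function(obs, ref, n_obs, n_ref, trim_m, trim_a, sample_id) {
  ok <- obs > 0 & ref > 0
  if (!any(ok))
    stop("sample ", sample_id, " shares no nonzero genes with the reference")
  p_o <- obs[ok] / n_obs
  p_r <- ref[ok] / n_ref
  M <- log2(p_o / p_r)
  A <- (log2(p_o) + log2(p_r)) / 2
  # delta-method variance of M; precision weights are its reciprocal
  v <- (n_obs - obs[ok]) / (n_obs * obs[ok]) + (n_ref - ref[ok]) / (n_ref * ref[ok])
  if (max(abs(M)) < 1e-6) return(1)
  n <- length(M)
  lo_m <- floor(n * trim_m) + 1; hi_m <- n + 1 - lo_m
  lo_a <- floor(n * trim_a) + 1; hi_a <- n + 1 - lo_a
  r_m <- rank(M, ties.method = "first")
  r_a <- rank(A, ties.method = "first")
  keep <- r_m >= lo_m & r_m <= hi_m & r_a >= lo_a & r_a <= hi_a
  if (!any(keep))
    stop("sample ", sample_id, ": no genes survive trimming; lower trim_m/trim_a")
  2^(sum(M[keep] / v[keep]) / sum(1 / v[keep]))
}

#' @export
print.norm_factors <- function(x, ...) {
  cat("TMM normalization factors (reference:",
      attr(x, "reference_sample"), ")\n")
  print(round(unclass(x), 4))
  invisible(x)
}
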