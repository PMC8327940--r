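#' Classify genes as adaptive or maladaptive plasticity
#'
#' Intersects a plastic differential-expression result (sprayed vs
#' unsprayed within the control lines) with an evolved result (resistant
#' vs control lines, unsprayed) and labels every shared gene:
#'
#' * `adaptive`: both FDRs below `alpha` and the two log2 fold changes
#'   share a nonzero sign (the plastic response anticipates the evolved
#'   one);
#' * `maladaptive`: both significant, opposite signs;
#' * `plastic_only` / `evolved_only`: significant in one result;
#' * `none`: significant in neither;
#' * `unclassifiable`: both significant but one log2 fold change is
#'   exactly zero (sign undefined; excluded from the binomial test with a
#'   warning).
#'
#' The evolved result must come from the unsprayed comparison: measuring
#' the selection response in the spray environment would confound the
#' evolved difference with plasticity itself. When the result carries
#' contrast metadata naming the sprayed evolved comparison the function
#' refuses unless `allow_sprayed_evolved = TRUE`.
#'
#' @param plastic,evolved `dge_result` tables sharing a gene universe
#' @param alpha FDR threshold (default 0.1)
#' @param allow_sprayed_evolved override the unsprayed-evolved guard
#' @return data.frame of class `plasticity_calls` with columns gene,
#'   plastic_lfc, plastic_fdr, evolved_lfc, evolved_fdr, call
#' @export
classify_genes <- function(plastic, evolved, alpha = 0.1,
                           allow_sprayed_evolved = FALSE) {
  stopifnot(is.data.frame(plastic), is.data.frame(evolved))
  if (alpha <= 0 || alpha >= 1) stop("alpha must be in (0, 1)")
  ev_name <- attr(evolved, "contrast")
  if (!is.null(ev_name) && identical(ev_name, "evolved_sprayed") &&
      !allow_sprayed_evolved)
    stop("the evolved result is the sprayed-conditions contrast; ",
         "selection must be measured in unsprayed conditions to avoid ",
         "confounding the evolved response with plasticity itself ",
         "(set allow_sprayed_evolved = TRUE to override)")
  shared <- intersect(plastic$gene, evolved$gene)
  if (!length(shared))
    stop("the plastic and evolved results share no genes")
  ip <- match(shared, plastic$gene)
  ie <- match(shared, evolved$gene)
  pl <- plastic$log2_fc[ip]; pf <- plastic$fdr[ip]
  el <- evolved$log2_fc[ie]; ef <- evolved$fdr[ie]
  both <- pf < alpha & ef < alpha
  s <- sign(pl) * sign(el)
  call <- ifelse(both & s > 0, "adaptive",
           ifelse(both & s < 0, "maladaptive",
            ifelse(both, "unclassifiable",
             ifelse(pf < alpha, "plastic_only",
              ifelse(ef < alpha, "evolved_only", "none")))))
  n_zero <- sum(call == "unclassifiable")
  if (n_zero > 0)
    warning(n_zero, " doubly significant gene(s) with an exactly zero ",
            "log2 fold change are unclassifiable and excluded from the ",
            "concordance test")
  structure(data.frame(gene = shared, plastic_lfc = pl, plastic_fdr = pf,
                       evolved_lfc = el, evolved_fdr = ef, call = call,
                       row.names = NULL, stringsAsFactors = FALSE),
            class = c("plasticity_calls", "data.frame"), alpha = alpha)
}

#' Exact two-sided binomial test (minimum-likelihood method)
#'
#' Sums the probabilities of all outcomes whose point probability does
#' not exceed that of the observed count; for `p0 = 0.5` this equals
#' doubling the smaller tail. Computed in log space, so it is stable for
#' n up to about one million trials.
#'
#' @param k number of successes
#' @param n number of trials
#' @param p0 null success probability (default 0.5)
#' @return two-sided p-value in (0, 1]
#' @export
exact_binomial_two_sided <- function(k, n, p0 = 0.5) {
  if (k != round(k) || n != round(n) || k < 0 || n < 1)
    stop("k and n must be non-negative integers with n >= 1")
  if (k > n) stop("k must not exceed n")
  if (p0 <= 0 || p0 >= 1) stop("p0 must lie strictly between 0 and 1")
  ld <- stats::dbinom(0:n, n, p0, log = TRUE)
  # relative slack guards against ties lost to floating-point rounding
  min(1, sum(exp(ld[ld <= ld[k + 1] + 1e-7])))
}

#' Binomial sign-concordance test on a calls table
#'
#' Among genes significant in both the plastic and the evolved result,
#' tests whether the adaptive (sign-concordant) fraction departs from the
#' 50:50 split expected if plastic and evolved directions were unrelated.
#'
#' @param calls a `plasticity_calls` table from [classify_genes()]
#' @return list of class `concordance_test`: n_both, n_concordant,
#'   p_two_sided (NA when n_both = 0) and direction
#'   (adaptive-biased / maladaptive-biased / balanced).
#' @export
concordance_test <- function(calls) {
  stopifnot(inherits(calls, "plasticity_calls"))
  n_ad <- sum(calls$call == "adaptive")
  n_mal <- sum(calls$call == "maladaptive")
  n_both <- n_ad + n_mal
  if (n_both == 0) {
    message("no doubly significant genes; concordance p-value undefined")
    p <- NA_real_
  } else {
    p <- exact_binomial_two_sided(n_ad, n_both, 0.5)
  }
  direction <- if (n_both == 0 || n_ad * 2 == n_both) "balanced"
    else if (n_ad * 2 > n_both) "adaptive-biased" else "maladaptive-biased"
  structure(list(n_both = n_both, n_concordant = n_ad,
                 p_two_sided = p, direction = direction),
            class = "concordance_test")
}

#' @export
print.concordance_test <- function(x, ...) {
  cat("Sign concordance:", x$n_concordant, "adaptive of", x$n_both,
      "doubly significant genes (", x$direction, ")\n")
  cat("two-sided exact binomial p =", format(x$p_two_sided, digits = 3), "\n")
  invisible(x)
}

#' Consistency of the plastic response across timepoints
#'
#' Pearson correlation of the log2 fold changes at the two sampling
#' timepoints over all shared genes, plus the number of genes significant
#' at both timepoints whose response direction differs.
#'
#' @param plastic_8h,plastic_32h per-timepoint `dge_result` tables
#' @param alpha FDR threshold for the direction-change count
#' @return list with `pearson_r`, `n_direction_changed`, `n_genes`
#' @export
timepoint_concordance <- function(plastic_8h, plastic_32h, alpha = 0.1) {
  shared <- intersect(plastic_8h$gene, plastic_32h$gene)
  if (length(shared) < 3)
    stop("need at least 3 shared genes to correlate timepoints")
  i8 <- match(shared, plastic_8h$gene)
  i32 <- match(shared, plastic_32h$gene)
  l8 <- plastic_8h$log2_fc[i8]; l32 <- plastic_32h$log2_fc[i32]
  sig <- plastic_8h$fdr[i8] < alpha & plastic_32h$fdr[i32] < alpha
  list(pearson_r = stats::cor(l8, l32),
       n_direction_changed = sum(sig & sign(l8) * sign(l32) < 0),
       n_genes = length(shared))
}

#' Did selection for resistance amplify the plastic response?
#'
#' Compares the magnitude of the herbicide response gene by gene between
#' control and resistance-selected lines. `fraction_greater` is the share
#' of all shared genes whose |log2 fold change| is strictly greater in
#' the resistant lines (exact ties count as not greater, which is
#' conservative for a "majority amplified" claim).
#'
#' @param plastic_control,plastic_resistant per-line plastic `dge_result`
#'   tables
#' @param alpha FDR threshold for the per-line significant-gene counts
#' @return list of class `plasticity_comparison`: `per_gene` data.frame
#'   (gene, abs_lfc_control, abs_lfc_resistant, greater_in_resistant) and
#'   summary fields fraction_greater, n_sig_control, n_sig_resistant,
#'   lfc_correlation.
#' @export
plasticity_amplification <- function(plastic_control, plastic_resistant,
                                     alpha = 0.1) {
  shared <- intersect(plastic_control$gene, plastic_resistant$gene)
  if (!length(shared)) stop("the two plastic results share no genes")
  ic <- match(shared, plastic_control$gene)
  ir <- match(shared, plastic_resistant$gene)
  ac <- abs(plastic_control$log2_fc[ic])
  ar <- abs(plastic_resistant$log2_fc[ir])
  greater <- ar > ac
  structure(list(
    per_gene = data.frame(gene = shared, abs_lfc_control = ac,
                          abs_lfc_resistant = ar,
                          greater_in_resistant = greater,
                          row.names = NULL, stringsAsFactors = FALSE),
    fraction_greater = mean(greater),
    n_sig_control = sum(plastic_control$fdr[ic] < alpha),
    n_sig_resistant = sum(plastic_resistant$fdr[ir] < alpha),
    lfc_correlation = stats::cor(plastic_control$log2_fc[ic],
                                 plastic_resistant$log2_fc[ir])),
    class = "plasticity_comparison")
}

#' @export
print.plasticity_comparison <- function(x, ...) {
  cat(sprintf("%.1f%% of %d genes respond more strongly in resistant lines\n",
              100 * x$fraction_greater, nrow(x$per_gene)))
  cat("significant plastic genes:", x$n_sig_control, "(control) vs",
      x$n_sig_resistant, "(resistant); LFC correlation",
      format(x$lfc_correlation, digits = 3), "\n")
  invisible(x)
}

#' Fisher exact term enrichment
#'
#' Per annotation term, a 2x2 exact test of foreground membership against
#' term membership over the background universe, with Benjamini-Hochberg
#' adjustment across terms. Terms annotating no background gene are
#' skipped with a warning.
#'
#' @param foreground character vector of genes of interest (must be a
#'   subset of `background`)
#' @param background character vector: the tested gene universe
#' @param annotation data.frame with columns `gene`, `term`
#' @return data.frame: term, n_term, n_overlap, odds_ratio, p_value, fdr
#' @export
fisher_enrichment <- function(foreground, background, annotation) {
  stopifnot(is.data.frame(annotation),
            all(c("gene", "term") %in% names(annotation)))
  foreground <- unique(foreground)
  background <- unique(background)
  if (!all(foreground %in% background))
    stop("foreground must be a subset of the background universe")
  terms <- unique(annotation$term)
  annotation <- annotation[annotation$gene %in% background, , drop = FALSE]
  if (!nrow(annotation))
    stop("annotation covers no background gene")
  in_fg <- background %in% foreground
  rows <- lapply(terms, function(tm) {
    genes_t <- unique(annotation$gene[annotation$term == tm])
    if (!length(genes_t)) return(NULL)
    in_t <- background %in% genes_t
    tab <- matrix(c(sum(in_fg & in_t),  sum(in_fg & !in_t),
                    sum(!in_fg & in_t), sum(!in_fg & !in_t)),
                  2, 2, byrow = TRUE)
    ft <- stats::fisher.test(tab)
    data.frame(term = tm, n_term = sum(in_t), n_overlap = tab[1, 1],
               odds_ratio = unname(ft$estimate), p_value = ft$p.value,
               stringsAsFactors = FALSE)
  })
  empty <- lengths(rows) == 0
  if (any(empty))
    warning("skipped ", sum(empty), " term(s) with no annotated background gene")
  out <- do.call(rbind, rows)
  if (is.null(out)) stop("no term annotates any background gene")
  out$fdr <- bh_fdr(out$p_value)
  out[order(out$p_value), , drop = FALSE]
}
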