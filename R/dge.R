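#' Precision weights from the mean-variance trend of log-CPM
#'
#' Computes log2-CPM (prior count 0.5, library sizes scaled by the TMM
#' factors and offset by 1) and observation-level inverse-variance
#' weights. Per gene, an ordinary least-squares fit on the design gives a
#' residual standard deviation; the square root of that standard deviation
#' is smoothed against mean log2 count with locally weighted regression
#' (tricube weights, 2 robustness iterations, `span` as given). Each
#' observation's weight is the trend value at its fitted log2 count,
#' raised to the power -4. The trend is extrapolated flat beyond the
#' fitted range.
#'
#' @param x filtered [count_matrix()]
#' @param norm_factors factors from [tmm_factors()] (or 1s)
#' @param design a [sample_design()]
#' @param span lowess span (default 0.5)
#' @return object of class `voom_fit`: list with `E` (log2-CPM matrix),
#'   `weights` (same dimension, all positive), `trend` (list x, y of the
#'   lowess curve), `design`, `span`.
#' @export
voom_weights <- function(x, norm_factors, design, span = 0.5) {
  stopifnot(inherits(x, "count_matrix"), inherits(design, "sample_design"))
  X <- design$matrix
  n <- ncol(x$counts)
  if (n != nrow(X)) stop("design rows must match count matrix columns")
  df_resid <- n - ncol(X)
  if (df_resid <= 0)
    stop("no residual degrees of freedom: ", n, " samples for ",
         ncol(X), " coefficients")
  eff_lib <- .effective_lib_sizes(x, norm_factors)
  E <- log2(sweep(x$counts + 0.5, 2, eff_lib + 1, "/") * 1e6)

  qrX <- qr(X)
  fitted <- t(qr.fitted(qrX, t(E)))
  sigma <- sqrt(rowSums((E - fitted)^2) / df_resid)

  amean <- rowMeans(E)
  sx <- amean + mean(log2(eff_lib + 1)) - log2(1e6)   # mean log2 count
  sy <- sqrt(sigma)                                    # sqrt of residual sd
  lo <- stats::lowess(sx, sy, f = span, iter = 2)
  trend_fun <- stats::approxfun(lo$x, lo$y, rule = 2,
                                ties = list("ordered", mean))

  fitted_logcount <- sweep(fitted, 2, log2(eff_lib + 1), "+") - log2(1e6)
  pred <- trend_fun(fitted_logcount)
  if (any(!is.finite(pred)) || any(pred <= 0))
    stop("mean-variance trend is non-positive; weights undefined")
  W <- matrix(pred^-4, nrow(E), ncol(E), dimnames = dimnames(E))
  structure(list(E = E, weights = W, trend = list(x = lo$x, y = lo$y),
                 design = design, span = span),
            class = "voom_fit")
}

# Gene-wise weighted least squares on the group-means design.
# Returns coefficients, unscaled covariance per gene, residual variance.
.fit_gene_models <- function(E, weights, design) {
  X <- design$matrix
  n <- nrow(X); p <- ncol(X)
  df_resid <- n - p
  if (df_resid <= 0) stop("no residual degrees of freedom")
  G <- nrow(E)
  beta <- matrix(NA_real_, G, p, dimnames = list(rownames(E), colnames(X)))
  cov_unscaled <- array(NA_real_, c(p, p, G))
  sigma2 <- numeric(G)
  for (g in seq_len(G)) {
    wg <- weights[g, ]
    Xw <- X * wg
    XtWX <- crossprod(X, Xw)
    inv <- tryCatch(chol2inv(chol(XtWX)),
                    error = function(e)
                      stop("singular weighted design for gene ",
                           rownames(E)[g], call. = FALSE))
    b <- inv %*% crossprod(Xw, E[g, ])
    r <- E[g, ] - drop(X %*% b)
    beta[g, ] <- b
    cov_unscaled[, , g] <- inv
    sigma2[g] <- sum(wg * r^2) / df_resid
  }
  list(coefficients = beta, cov_unscaled = cov_unscaled, sigma2 = sigma2,
       df_residual = df_resid, amean = rowMeans(E), genes = rownames(E))
}

#' Gene-wise weighted least-squares estimates for one contrast
#'
#' Fits each gene's expression on the group-means design with its
#' observation weights and evaluates the contrast: the estimate
#' `log2_fc = c'theta`, its unscaled variance `v = c'(X'WX)^-1 c`, the
#' residual variance `s2` and residual degrees of freedom.
#'
#' @param E log2-CPM matrix (as from [voom_weights()])
#' @param weights positive weight matrix of the same dimension
#' @param design a [sample_design()]
#' @param contrast a [make_contrast()] vector over design columns
#' @return data.frame (class `contrast_fit`) with columns gene, log2_fc,
#'   ave_expr, s2, v, df; attribute `contrast` carries the name.
#' @export
fit_contrast <- function(E, weights, design, contrast) {
  fit <- .fit_gene_models(E, weights, design)
  .contrast_stats(fit, contrast)
}

.contrast_stats <- function(fit, contrast) {
  cvec <- as.numeric(contrast)
  if (abs(sum(cvec)) > 1e-8) stop("contrast weights must sum to zero")
  if (sum(cvec != 0) < 2) stop("contrast must involve at least two coefficients")
  G <- length(fit$genes)
  lfc <- drop(fit$coefficients %*% cvec)
  v <- vapply(seq_len(G), function(g)
    drop(crossprod(cvec, fit$cov_unscaled[, , g] %*% cvec)), numeric(1))
  out <- data.frame(gene = fit$genes, log2_fc = lfc, ave_expr = fit$amean,
                    s2 = fit$sigma2, v = v, df = fit$df_residual,
                    row.names = NULL, stringsAsFactors = FALSE)
  structure(out, class = c("contrast_fit", "data.frame"),
            contrast = attr(contrast, "contrast"))
}

#' Inverse of the trigamma function
#'
#' Monotone Newton iteration on `trigamma(y) = x`; used when matching
#' moments of log residual variances to a scaled inverse-chi-squared
#' prior. `trigamma_inverse(pi^2/6)` is 1.
#'
#' @param x positive value(s)
#' @return y with `trigamma(y) = x`
#' @export
trigamma_inverse <- function(x) {
  vapply(x, function(xi) {
    if (!is.finite(xi) || xi <= 0) return(NaN)
    if (xi > 1e7) return(1 / sqrt(xi))
    if (xi < 1e-6) return(1 / xi)
    y <- 0.5 + 1 / xi
    for (i in 1:50) {
      tri <- trigamma(y)
      dif <- tri * (1 - tri / xi) / psigamma(y, deriv = 2)
      y <- y + dif
      if (-dif / y < 1e-8) break
    }
    y
  }, numeric(1))
}

# Moment-matching of gene-wise variances to a scaled inverse-chi-squared
# prior (prior df d0, prior variance s20), on the log scale.
.estimate_variance_prior <- function(s2, df) {
  use <- s2 > 0
  if (sum(use) < 10)
    stop("need at least 10 genes with positive residual variance")
  z <- log(s2[use])
  e <- z - digamma(df / 2) + log(df / 2)
  emean <- mean(e)
  evar <- sum((e - emean)^2) / (length(e) - 1) - trigamma(df / 2)
  if (evar > 0) {
    d0 <- 2 * trigamma_inverse(evar)
    s20 <- exp(emean + digamma(d0 / 2) - log(d0 / 2))
  } else {
    d0 <- Inf
    s20 <- exp(emean)
  }
  list(prior_df = d0, prior_var = s20)
}

#' Empirical-Bayes moderated t-statistics for a fitted contrast
#'
#' Shrinks gene-wise residual variances toward a prior estimated across
#' genes: with prior degrees of freedom d0 and prior variance s0^2, the
#' posterior variance is `(d0 s0^2 + d s2) / (d0 + d)` and the moderated
#' t-statistic `log2_fc / sqrt(s2_post * v)` is referred to a Student-t
#' distribution with d0 + d degrees of freedom (standard normal when d0
#' is infinite). Two-sided p-values are adjusted with [bh_fdr()].
#'
#' @param cfit a `contrast_fit` from [fit_contrast()]
#' @return data.frame of class `dge_result` with columns gene, log2_fc,
#'   ave_expr, t, p_value, fdr, residual_df; attributes `prior_df`,
#'   `prior_var`, `contrast`.
#' @export
ebayes_moderate <- function(cfit) {
  stopifnot(inherits(cfit, "contrast_fit"))
  if (all(cfit$s2 == 0))
    stop("all residual variances are zero; variance landscape degenerate")
  df <- cfit$df[1]
  prior <- .estimate_variance_prior(cfit$s2, df)
  d0 <- prior$prior_df; s20 <- prior$prior_var
  s2_post <- if (is.infinite(d0)) rep(s20, nrow(cfit)) else
    (d0 * s20 + df * cfit$s2) / (d0 + df)
  t_mod <- cfit$log2_fc / sqrt(s2_post * cfit$v)
  df_total <- d0 + df
  p <- 2 * stats::pt(-abs(t_mod), df = df_total)
  out <- data.frame(gene = cfit$gene, log2_fc = cfit$log2_fc,
                    ave_expr = cfit$ave_expr, t = t_mod, p_value = p,
                    fdr = bh_fdr(p), residual_df = df,
                    row.names = NULL, stringsAsFactors = FALSE)
  structure(out, class = c("dge_result", "data.frame"),
            prior_df = d0, prior_var = s20,
            contrast = attr(cfit, "contrast"))
}

#' Benjamini-Hochberg step-up adjusted p-values
#'
#' `q_(i) = min over j >= i of p_(j) * m / j`, capped at 1 and returned in
#' the input order.
#'
#' @param p numeric vector of p-values in \[0, 1\]
#' @return adjusted values, same length and order
#' @export
bh_fdr <- function(p) {
  if (any(is.na(p)) || any(p < 0) || any(p > 1))
    stop("p-values must lie in [0, 1]")
  m <- length(p)
  if (m <= 1) return(p)
  o <- order(p, decreasing = TRUE)
  ro <- order(o)
  pmin(1, cummin(p[o] * m / (m:1)))[ro]
}

#' Run the standard plastic and evolved contrasts end to end
#'
#' Computes TMM factors (unless supplied), the mean-variance trend and
#' precision weights on the full group-means design, fits every gene once,
#' then evaluates and moderates each requested contrast. FDR adjustment is
#' applied within each contrast separately. Sign conventions: positive
#' log2 fold change means higher expression in sprayed samples (plastic
#' contrasts) or in resistance-selected lines (evolved contrasts).
#'
#' @param x filtered [count_matrix()]
#' @param design a [sample_design()]
#' @param norm_factors optional precomputed [tmm_factors()]
#' @param contrasts character vector of standard contrast names (default
#'   [standard_contrast_names()])
#' @param span lowess span passed to [voom_weights()]
#' @return named list of `dge_result` tables, plus attributes
#'   `norm_factors` and `voom` for reuse.
#' @export
run_standard_contrasts <- function(x, design, norm_factors = NULL,
                                   contrasts = standard_contrast_names(),
                                   span = 0.5) {
  stopifnot(inherits(x, "count_matrix"), inherits(design, "sample_design"))
  lt <- unique(design$samples$line_type)
  tr <- unique(design$samples$treatment)
  if (length(lt) < 2 || length(tr) < 2)
    stop("design must contain both line types and both treatments")
  if (is.null(norm_factors)) norm_factors <- tmm_factors(x)
  cons <- lapply(contrasts, make_contrast, design = design)
  names(cons) <- contrasts
  vm <- voom_weights(x, norm_factors, design, span = span)
  fit <- .fit_gene_models(vm$E, vm$weights, design)
  res <- lapply(cons, function(cw) ebayes_moderate(.contrast_stats(fit, cw)))
  attr(res, "norm_factors") <- norm_factors
  attr(res, "voom") <- vm
  res
}
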