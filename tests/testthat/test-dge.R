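# -- precision weights ------------------------------------------------------

test_that("flat mean-variance data yields a flat trend and near-equal weights", {
  # constant variance on the log scale: high, narrow baseline + tiny
  # dispersion, so sqrt-sd does not depend on abundance
  sim <- simulate_experiment(sim_config(
    n_genes = 2000, samples_per_cell = 4, frac_plastic = 0,
    frac_evolved = 0, frac_both = 0, baseline_log2cpm_mean = 7,
    baseline_log2cpm_sd = 0.3, dispersion_a0 = 0, dispersion_a1 = 0.05,
    seed = 13))
  f <- filter_by_expression(sim$counts, sim$design)
  vm <- voom_weights(f, tmm_factors(f), sim$design)
  expect_true(all(vm$weights > 0))
  expect_lt(max(vm$weights) / min(vm$weights), 1.2)
})

test_that("weights are invariant to a common library-size scale factor", {
  sim <- simulate_experiment(sim_config(n_genes = 300, samples_per_cell = 2,
                                        seed = 17))
  x <- sim$counts
  vm1 <- voom_weights(x, rep(1, ncol(x$counts)), sim$design)
  x2 <- count_matrix(x$counts, lib_sizes = x$lib_sizes * 10)
  vm2 <- voom_weights(x2, rep(1, ncol(x$counts)), sim$design)
  # CPM shifts by -log2(10) but the sqrt-sd trend shifts with it, so the
  # weight surface is unchanged up to the +1 library offset
  expect_equal(vm2$weights, vm1$weights, tolerance = 0.02)
})

test_that("a zero-residual-variance gene still gets a finite trend weight", {
  design <- toy_design(per_cell = 2)
  n <- nrow(design$samples)
  set.seed(5)
  m <- matrix(rnbinom(50 * n, mu = 300, size = 10), 50, n,
              dimnames = list(paste0("g", 1:50), design$samples$sample))
  m[1, ] <- 400  # identical in every sample: within-cell residual sd = 0
  vm <- voom_weights(count_matrix(m), rep(1, n), design)
  expect_true(is.finite(vm$weights[1, 1]) && vm$weights[1, 1] > 0)
})

test_that("voom agrees with the limma implementation on simulated data", {
  skip_if_not_installed("limma")
  skip_if_not_installed("edgeR")
  sim <- simulate_experiment(sim_config(n_genes = 1500, seed = 3))
  f <- filter_by_expression(sim$counts, sim$design)
  tf <- tmm_factors(f)
  vm <- voom_weights(f, tf, sim$design)
  dge <- edgeR::DGEList(f$counts, lib.size = unname(f$lib_sizes),
                        norm.factors = unname(as.numeric(tf)))
  ref <- limma::voom(dge, sim$design$matrix)
  expect_equal(vm$E, ref$E, tolerance = 1e-12, ignore_attr = TRUE)
  # the lowess robustness-iteration count differs by one; weights agree
  # to a few percent
  expect_lt(max(abs(vm$weights / ref$weights - 1)), 0.1)
  expect_lt(median(abs(vm$weights / ref$weights - 1)), 0.01)
})

test_that("too few samples for the design is an explicit error", {
  design <- toy_design(per_cell = 2)
  keep <- !duplicated(design$cell)           # one sample per cell
  small <- sample_design(design$samples[keep, ])
  m <- matrix(rpois(10 * sum(keep), 100), 10, sum(keep),
              dimnames = list(paste0("g", 1:10),
                              small$samples$sample))
  expect_error(voom_weights(count_matrix(m), rep(1, sum(keep)), small),
               "residual degrees of freedom")
})

# -- gene-wise weighted fits ------------------------------------------------

test_that("unit-weight fits reduce to ordinary normal-equations OLS", {
  design <- toy_design(per_cell = 2)
  n <- nrow(design$samples)
  set.seed(23)
  E <- matrix(rnorm(5 * n, mean = 8), 5, n,
              dimnames = list(paste0("g", 1:5), design$samples$sample))
  W <- matrix(1, 5, n)
  cw <- make_contrast(design, "plastic_control_pooled")
  fit <- fit_contrast(E, W, design, cw)
  for (g in 1:5) {
    o <- oracle_wls(E[g, ], design$matrix, rep(1, n), as.numeric(cw))
    expect_equal(fit$log2_fc[g], o$estimate, tolerance = 1e-10)
    expect_equal(fit$s2[g], o$s2, tolerance = 1e-10)
    expect_equal(fit$v[g], o$v, tolerance = 1e-10)
  }
  # two-group reading: estimate equals difference of cell means
  cells <- design$cell
  manual <- mean(E[1, cells %in% c("control.sprayed.8", "control.sprayed.32")]) -
            mean(E[1, cells %in% c("control.unsprayed.8", "control.unsprayed.32")])
  expect_equal(fit$log2_fc[1], manual, tolerance = 1e-10)
})

test_that("non-unit weights match the weighted normal equations", {
  design <- toy_design(per_cell = 3)
  n <- nrow(design$samples)
  set.seed(29)
  E <- matrix(rnorm(4 * n), 4, n,
              dimnames = list(paste0("g", 1:4), design$samples$sample))
  W <- matrix(rgamma(4 * n, 5, 1), 4, n)
  cw <- make_contrast(design, "evolved_unsprayed")
  fit <- fit_contrast(E, W, design, cw)
  for (g in 1:4) {
    o <- oracle_wls(E[g, ], design$matrix, W[g, ], as.numeric(cw))
    expect_equal(fit$log2_fc[g], o$estimate, tolerance = 1e-10)
    expect_equal(fit$s2[g], o$s2, tolerance = 1e-10)
    expect_equal(fit$v[g], o$v, tolerance = 1e-10)
  }
})

test_that("a planted fold change is estimated accurately at low noise", {
  sim <- simulate_experiment(sim_config(
    n_genes = 500, samples_per_cell = 3, dispersion_a0 = 0.05,
    dispersion_a1 = 0.002, effect_lfc_mean = 2, effect_lfc_sd = 0.01,
    frac_plastic = 0.3, frac_evolved = 0, frac_both = 0, amplification = 1,
    seed = 37))
  f <- filter_by_expression(sim$counts, sim$design, cpm_min = 1)
  vm <- voom_weights(f, tmm_factors(f), sim$design)
  fit <- fit_contrast(vm$E, vm$weights, sim$design,
                      make_contrast(sim$design, "plastic_control_pooled"))
  truth <- sim$truth$true_plastic_lfc[match(fit$gene, sim$truth$gene)]
  expect_lt(median(abs(fit$log2_fc - truth)), 0.05)
})

# -- moderation and FDR -----------------------------------------------------

test_that("trigamma_inverse inverts trigamma", {
  expect_equal(trigamma_inverse(pi^2 / 6), 1, tolerance = 1e-6)
  for (y in c(0.2, 1, 3.7, 25))
    expect_equal(trigamma_inverse(trigamma(y)), y, tolerance = 1e-6)
})

test_that("variance-prior recovery under the exact scaled-inverse-chi2 model", {
  set.seed(53)
  d0 <- 4; s20 <- 2; dg <- 10; G <- 20000
  s2 <- s20 * d0 / rchisq(G, d0) * (rchisq(G, dg) / dg)
  prior <- adaplast:::.estimate_variance_prior(s2, dg)
  expect_lt(abs(prior$prior_df - d0), 0.5)
  expect_lt(abs(prior$prior_var - s20), 0.1)
})

test_that("moderated statistics match limma's empirical Bayes", {
  skip_if_not_installed("limma")
  design <- toy_design(per_cell = 3)
  n <- nrow(design$samples)
  set.seed(61)
  E <- matrix(rnorm(200 * n, 8, 1), 200, n,
              dimnames = list(paste0("g", 1:200), design$samples$sample))
  W <- matrix(1, 200, n)
  cw <- make_contrast(design, "plastic_control_pooled")
  mine <- ebayes_moderate(fit_contrast(E, W, design, cw))
  fit <- limma::lmFit(E, design$matrix)
  fit2 <- limma::eBayes(limma::contrasts.fit(fit, as.numeric(cw)))
  expect_equal(attr(mine, "prior_df"), fit2$df.prior, tolerance = 1e-8)
  expect_equal(attr(mine, "prior_var"), fit2$s2.prior, tolerance = 1e-8)
  expect_equal(mine$t, fit2$t[, 1], tolerance = 1e-8, ignore_attr = TRUE)
  expect_equal(mine$p_value, fit2$p.value[, 1], tolerance = 1e-8,
               ignore_attr = TRUE)
})

test_that("infinite prior df collapses the posterior variance to the prior", {
  design <- toy_design(per_cell = 2)
  n <- nrow(design$samples)
  set.seed(67)
  # equal true variances -> moment estimator pushes d0 to infinity
  E <- matrix(rnorm(30 * n, 0, 1), 30, n,
              dimnames = list(paste0("g", 1:30), design$samples$sample))
  cfit <- fit_contrast(E, matrix(1, 30, n), design,
                       make_contrast(design, "evolved_unsprayed"))
  res <- ebayes_moderate(cfit)
  d0 <- attr(res, "prior_df")
  if (is.infinite(d0)) {
    expect_equal(res$p_value, 2 * pnorm(-abs(res$t)), tolerance = 1e-12)
  } else {
    expect_gt(d0, 20)  # strong shrinkage even if finite
  }
  expect_equal(sign(res$t), sign(res$log2_fc))
})

test_that("bh_fdr reproduces the step-up procedure and its properties", {
  expect_equal(bh_fdr(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(bh_fdr(0.37), 0.37)
  expect_equal(bh_fdr(c(0.005, 0.009, 0.05, 0.5, 1.0)),
               c(0.0225, 0.0225, 0.05 * 5 / 3, 0.625, 1.0),
               tolerance = 1e-12)
  set.seed(71)
  for (i in 1:5) {
    p <- runif(200)^2
    q <- bh_fdr(p)
    expect_equal(q, oracle_bh(p), tolerance = 1e-12)
    expect_equal(q, p.adjust(p, "BH"), tolerance = 1e-12)
    expect_true(all(q >= p - 1e-15))
    expect_true(all(diff(q[order(p)]) >= -1e-15))  # monotone in p
  }
  expect_error(bh_fdr(c(0.5, 1.2)), "\\[0, 1\\]")
})

# -- standard contrasts -----------------------------------------------------

test_that("swapping treatment labels flips every plastic log2 fold change", {
  sim <- simulate_experiment(sim_config(n_genes = 400, samples_per_cell = 2,
                                        seed = 73))
  f <- filter_by_expression(sim$counts, sim$design)
  res <- run_standard_contrasts(f, sim$design,
                                contrasts = c("plastic_control_pooled",
                                              "evolved_unsprayed"))
  swapped <- sim$design$samples
  swapped$treatment <- c(unsprayed = "sprayed",
                         sprayed = "unsprayed")[swapped$treatment]
  res2 <- run_standard_contrasts(f, sample_design(swapped),
                                 contrasts = c("plastic_control_pooled",
                                               "evolved_unsprayed"))
  expect_equal(res2$plastic_control_pooled$log2_fc,
               -res$plastic_control_pooled$log2_fc, tolerance = 1e-10)
  expect_equal(res2$plastic_control_pooled$p_value,
               res$plastic_control_pooled$p_value, tolerance = 1e-10)
})

test_that("planted plastic-only genes surface in plastic, not evolved, contrasts", {
  sim <- simulate_experiment(sim_config(n_genes = 2000, samples_per_cell = 6,
                                        effect_lfc_mean = 2, seed = 79,
                                        amplification = 1))
  f <- filter_by_expression(sim$counts, sim$design)
  res <- run_standard_contrasts(f, sim$design,
                                contrasts = c("plastic_control_pooled",
                                              "evolved_unsprayed"))
  truth <- sim$truth[match(res[[1]]$gene, sim$truth$gene), ]
  po <- truth$class_label == "plastic_only"
  hit_plastic <- res$plastic_control_pooled$fdr < 0.1
  hit_evolved <- res$evolved_unsprayed$fdr < 0.1
  expect_gt(mean(hit_plastic[po]), 0.8)
  expect_lt(mean(hit_evolved[po]), 0.05)
})

test_that("requesting a contrast with an empty cell names the cell", {
  design <- toy_design(per_cell = 2)
  keep <- design$samples$timepoint == 8 | design$samples$treatment == "unsprayed"
  sub <- sample_design(design$samples[keep, ])
  m <- matrix(rpois(20 * sum(keep), 100), 20, sum(keep),
              dimnames = list(paste0("g", 1:20), sub$samples$sample))
  expect_error(make_contrast(sub, "plastic_control_32h"),
               "control.sprayed.32")
  expect_error(
    run_standard_contrasts(count_matrix(m), sub,
                           contrasts = "plastic_resistant_32h"),
    "resistant.sprayed.32")
})

test_that("contrasts demand both line types and both treatments", {
  design <- toy_design(per_cell = 2)
  keep <- design$samples$line_type == "control"
  sub <- sample_design(design$samples[keep, ])
  m <- matrix(rpois(20 * sum(keep), 100), 20, sum(keep),
              dimnames = list(paste0("g", 1:20), sub$samples$sample))
  expect_error(run_standard_contrasts(count_matrix(m), sub),
               "both line types")
})
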