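#' Configuration for the synthetic count experiment
#'
#' Defines a 2 line x 2 treatment x 2 timepoint bulk RNA-seq experiment
#' with negative-binomial counts, a mean-dispersion trend, and planted
#' plastic / evolved expression effects with a controlled sign-concordance
#' fraction. The defaults describe the study conditions the package is
#' validated under: 8 samples per cell (64 samples), library sizes
#' log-normal around 28 million reads, moderate (about two-fold) planted
#' effects, 10% plastic-only, 3% evolved-only and 5% doubly affected
#' genes of which 72% are sign-concordant, and a 1.5x amplification of
#' the plastic response in resistance-selected lines.
#'
#' @param n_genes number of genes
#' @param samples_per_cell samples per design cell (scalar, or a named
#'   vector over the eight `line.treatment.timepoint` cells to emulate
#'   unbalanced designs); every cell needs at least 2 samples
#' @param baseline_log2cpm_mean,baseline_log2cpm_sd distribution of
#'   baseline expression (log2 CPM)
#' @param libsize_log_mean,libsize_log_sd log-normal library-size
#'   parameters (natural log of reads)
#' @param dispersion_a0,dispersion_a1 dispersion trend
#'   `phi_g = a1 + a0 / mu_g`, with `mu_g` the gene's expected baseline
#'   count at the typical library size; Var = mu + phi mu^2
#' @param frac_plastic,frac_evolved,frac_both proportions of genes with a
#'   plastic effect only, an evolved effect only, or both (must sum to
#'   at most 1)
#' @param prob_concordant probability that a doubly affected gene has
#'   same-signed plastic and evolved effects (adaptive plasticity)
#' @param effect_lfc_mean,effect_lfc_sd effect-magnitude distribution:
#'   |log2 fold change| is drawn as |N(mean, sd)|, signs are symmetric
#' @param amplification multiplier (>= 0) applied to the plastic effect in
#'   resistance-selected lines
#' @param seed integer RNG seed; the same seed and configuration
#'   reproduce the experiment bit-exactly
#' @return validated list of class `sim_config`
#' @export
sim_config <- function(n_genes = 5000,
                       samples_per_cell = 8,
                       baseline_log2cpm_mean = 5,
                       baseline_log2cpm_sd = 2,
                       libsize_log_mean = log(28e6),
                       libsize_log_sd = 0.25,
                       dispersion_a0 = 3,
                       dispersion_a1 = 0.05,
                       frac_plastic = 0.10,
                       frac_evolved = 0.03,
                       frac_both = 0.05,
                       prob_concordant = 0.72,
                       effect_lfc_mean = 1,
                       effect_lfc_sd = 0.5,
                       amplification = 1.5,
                       seed = 1L) {
  cfg <- list(n_genes = n_genes, samples_per_cell = samples_per_cell,
              baseline_log2cpm_mean = baseline_log2cpm_mean,
              baseline_log2cpm_sd = baseline_log2cpm_sd,
              libsize_log_mean = libsize_log_mean,
              libsize_log_sd = libsize_log_sd,
              dispersion_a0 = dispersion_a0, dispersion_a1 = dispersion_a1,
              frac_plastic = frac_plastic, frac_evolved = frac_evolved,
              frac_both = frac_both, prob_concordant = prob_concordant,
              effect_lfc_mean = effect_lfc_mean, effect_lfc_sd = effect_lfc_sd,
              amplification = amplification, seed = seed)
  .validate_sim_config(cfg)
  structure(cfg, class = "sim_config")
}

.sim_cell_labels <- function() {
  as.vector(outer(c("8", "32"),
                  outer(c("unsprayed", "sprayed"), c("control", "resistant"),
                        function(tr, lt) paste(lt, tr, sep = ".")),
                  function(tp, base) paste(base, tp, sep = ".")))
}

.validate_sim_config <- function(cfg) {
  with(cfg, {
    if (n_genes != round(n_genes) || n_genes < 1)
      stop("n_genes must be a positive integer")
    spc <- samples_per_cell
    if (any(spc != round(spc)) || any(spc < 2))
      stop("samples_per_cell must be integers >= 2")
    if (!length(spc) %in% c(1L, 8L))
      stop("samples_per_cell must be a scalar or one value per design cell")
    if (length(spc) == 8L && !is.null(names(spc)) &&
        !setequal(names(spc), .sim_cell_labels()))
      stop("named samples_per_cell must cover the eight design cells")
    props <- c(frac_plastic, frac_evolved, frac_both, prob_concordant)
    if (any(props < 0 | props > 1))
      stop("proportions must lie in [0, 1]")
    if (frac_plastic + frac_evolved + frac_both > 1)
      stop("frac_plastic + frac_evolved + frac_both must not exceed 1")
    if (dispersion_a0 < 0 || dispersion_a1 <= 0)
      stop("dispersion parameters must be positive")
    if (amplification < 0) stop("amplification must be >= 0")
    if (effect_lfc_sd < 0 || baseline_log2cpm_sd < 0 || libsize_log_sd < 0)
      stop("standard deviations must be >= 0")
    if (seed != round(seed)) stop("seed must be an integer")
  })
  invisible(cfg)
}

#' Simulate a count experiment with known plasticity ground truth
#'
#' Draws gene-and-sample-wise negative-binomial counts with mean
#' `mu_gi = 2^(b_g + x_i' beta_g) * L_i / 1e6` and gene-wise dispersion
#' from the configured trend. The plastic effect applies to sprayed
#' samples (multiplied by `amplification` in resistant lines, identically
#' at both timepoints); the evolved effect applies to resistant samples
#' in both treatments. Ground-truth class labels follow the sign pattern
#' of the two planted effects: same nonzero signs = adaptive, opposite =
#' maladaptive, one effect = plastic_only / evolved_only, none = null.
#'
#' @param config a [sim_config()]
#' @return list with elements `counts` ([count_matrix()]), `design`
#'   ([sample_design()]) and `truth` (data.frame of class `sim_truth`
#'   with gene, class_label, true_plastic_lfc, true_evolved_lfc,
#'   amplified, baseline_log2cpm). Baselines are shifted so that the
#'   unsprayed-control expression profile sums to exactly one million CPM,
#'   making the stored baseline the realized log2 CPM.
#' @export
simulate_experiment <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  .validate_sim_config(config)
  old_seed <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit(if (!is.null(old_seed))
    assign(".Random.seed", old_seed, envir = globalenv()))
  set.seed(config$seed, kind = "Mersenne-Twister",
           normal.kind = "Inversion", sample.kind = "Rejection")

  cells <- .sim_cell_labels()
  spc <- config$samples_per_cell
  if (length(spc) == 1L) spc <- stats::setNames(rep(spc, 8L), cells)
  if (is.null(names(spc))) names(spc) <- cells
  spc <- spc[cells]

  parts <- strsplit(cells, ".", fixed = TRUE)
  samples <- do.call(rbind, lapply(seq_along(cells), function(i) {
    data.frame(line_type = parts[[i]][1], treatment = parts[[i]][2],
               timepoint = as.integer(parts[[i]][3]),
               replicate = seq_len(spc[i]), stringsAsFactors = FALSE)
  }))
  samples$sample <- sprintf("s%02d", seq_len(nrow(samples)))
  samples <- samples[, c("sample", "line_type", "treatment", "timepoint",
                         "replicate")]
  design <- sample_design(samples)
  n_s <- nrow(samples)
  G <- config$n_genes

  lib <- stats::rlnorm(n_s, config$libsize_log_mean, config$libsize_log_sd)
  # baseline shape is drawn on the configured log2-CPM scale, then shifted
  # so the baseline expression of all genes is a valid CPM composition
  # (sums to 1e6); realized log2 CPM then matches the stored baseline
  b <- stats::rnorm(G, config$baseline_log2cpm_mean, config$baseline_log2cpm_sd)
  b <- b + log2(1e6) - log2(sum(2^b))

  cls <- sample(c("plastic", "evolved", "both", "null"), G, replace = TRUE,
                prob = c(config$frac_plastic, config$frac_evolved,
                         config$frac_both,
                         1 - config$frac_plastic - config$frac_evolved -
                           config$frac_both))
  mag_p <- abs(stats::rnorm(G, config$effect_lfc_mean, config$effect_lfc_sd))
  mag_e <- abs(stats::rnorm(G, config$effect_lfc_mean, config$effect_lfc_sd))
  sign_p <- sample(c(-1, 1), G, replace = TRUE)
  sign_e_free <- sample(c(-1, 1), G, replace = TRUE)
  concord <- stats::runif(G) < config$prob_concordant
  sign_e <- ifelse(cls == "both",
                   ifelse(concord, sign_p, -sign_p), sign_e_free)

  plastic_lfc <- ifelse(cls %in% c("plastic", "both"), sign_p * mag_p, 0)
  evolved_lfc <- ifelse(cls %in% c("evolved", "both"), sign_e * mag_e, 0)
  class_label <- .plasticity_truth_label(plastic_lfc, evolved_lfc)

  sprayed <- samples$treatment == "sprayed"
  resistant <- samples$line_type == "resistant"
  plastic_scale <- ifelse(resistant, config$amplification, 1)
  # per-gene, per-sample log2 CPM
  logcpm <- matrix(b, G, n_s) +
    outer(plastic_lfc, as.numeric(sprayed) * plastic_scale) +
    outer(evolved_lfc, as.numeric(resistant))
  mu <- sweep(2^logcpm, 2, lib / 1e6, "*")

  mu_bar <- 2^b * exp(config$libsize_log_mean) / 1e6
  phi <- config$dispersion_a1 + config$dispersion_a0 / mu_bar
  counts <- matrix(stats::rnbinom(G * n_s, mu = mu, size = rep(1 / phi, n_s)),
                   G, n_s,
                   dimnames = list(sprintf("gene%05d", seq_len(G)),
                                   samples$sample))
  truth <- data.frame(gene = rownames(counts), class_label = class_label,
                      true_plastic_lfc = plastic_lfc,
                      true_evolved_lfc = evolved_lfc,
                      amplified = cls %in% c("plastic", "both"),
                      baseline_log2cpm = b,
                      row.names = NULL, stringsAsFactors = FALSE)
  list(counts = count_matrix(counts),
       design = design,
       truth = structure(truth, class = c("sim_truth", "data.frame")))
}

.plasticity_truth_label <- function(plastic_lfc, evolved_lfc) {
  s <- sign(plastic_lfc) * sign(evolved_lfc)
  ifelse(s > 0, "adaptive",
    ifelse(s < 0, "maladaptive",
      ifelse(plastic_lfc != 0, "plastic_only",
        ifelse(evolved_lfc != 0, "evolved_only", "null"))))
}

#' Write / read the ground-truth table
#'
#' Plain TSV, one row per gene; round-trips losslessly.
#' @param truth `sim_truth` data.frame from [simulate_experiment()]
#' @param path file path
#' @export
write_truth <- function(truth, path) {
  stopifnot(is.data.frame(truth))
  utils::write.table(truth, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @rdname write_truth
#' @export
read_truth <- function(path) {
  truth <- utils::read.delim(path, stringsAsFactors = FALSE,
                             colClasses = c(gene = "character"))
  structure(truth, class = c("sim_truth", "data.frame"))
}
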