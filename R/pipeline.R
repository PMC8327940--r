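#' Assemble and validate a pipeline configuration
#'
#' A configuration holds either input paths (`counts`, `samples`,
#' optionally `annotation`) or a `simulate` block of [sim_config()]
#' arguments, plus the tunable settings of every stage. It round-trips
#' losslessly through YAML via [read_pipeline_config()] /
#' [write_pipeline_config()].
#'
#' @param output_dir directory for all pipeline outputs
#' @param counts,samples,annotation optional input paths
#' @param simulate optional named list of [sim_config()] arguments
#' @param cpm_min,min_prop expression-filter settings
#' @param trim_m,trim_a TMM trim fractions
#' @param span voom lowess span
#' @param fdr_alpha FDR threshold used throughout (default 0.1)
#' @param seed integer seed forwarded to the simulation block
#' @param log_level "quiet" or "info" (cosmetic only)
#' @return validated list of class `pipeline_config`
#' @export
pipeline_config <- function(output_dir,
                            counts = NULL, samples = NULL, annotation = NULL,
                            simulate = NULL,
                            cpm_min = 10, min_prop = 1,
                            trim_m = 0.30, trim_a = 0.05,
                            span = 0.5, fdr_alpha = 0.1,
                            seed = 1L, log_level = "info") {
  if (is.null(simulate) && (is.null(counts) || is.null(samples)))
    stop("config needs either input paths (counts + samples) or a ",
         "simulate block")
  if (fdr_alpha <= 0 || fdr_alpha >= 1) stop("fdr_alpha must be in (0, 1)")
  if (!log_level %in% c("quiet", "info"))
    stop("log_level must be 'quiet' or 'info'")
  structure(list(output_dir = output_dir, counts = counts, samples = samples,
                 annotation = annotation, simulate = simulate,
                 cpm_min = cpm_min, min_prop = min_prop,
                 trim_m = trim_m, trim_a = trim_a, span = span,
                 fdr_alpha = fdr_alpha, seed = as.integer(seed),
                 log_level = log_level),
            class = "pipeline_config")
}

#' @rdname pipeline_config
#' @param path YAML file
#' @export
read_pipeline_config <- function(path) {
  raw <- yaml::read_yaml(path)
  do.call(pipeline_config, raw)
}

#' @rdname pipeline_config
#' @param config a `pipeline_config`
#' @export
write_pipeline_config <- function(config, path) {
  stopifnot(inherits(config, "pipeline_config"))
  yaml::write_yaml(Filter(Negate(is.null), unclass(config)), path)
  invisible(path)
}

.plog <- function(config, ...) {
  if (identical(config$log_level, "info"))
    message("[adaplast] ", ...)
  invisible(NULL)
}

#' Run the full plasticity pipeline
#'
#' Executes simulate (or load) -> expression filter -> TMM factors ->
#' precision weights -> standard contrasts -> plasticity classification,
#' writing every intermediate table, a `summary.json` with the headline
#' numbers, and a `manifest.json` recording the configuration, software
#' version, input checksums, per-stage row counts and timings. Identical
#' configurations and seeds reproduce identical outputs.
#'
#' @param config a [pipeline_config()]
#' @return the run manifest (list), invisibly; the summary list is
#'   attached as attribute `summary`.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(config$output_dir, recursive = TRUE, showWarnings = FALSE)
  t0 <- proc.time()[["elapsed"]]
  timings <- c()
  stage <- function(name, expr) {
    s <- proc.time()[["elapsed"]]
    out <- tryCatch(force(expr), error = function(e)
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE))
    timings[[name]] <<- round(proc.time()[["elapsed"]] - s, 3)
    out
  }
  op <- function(f) file.path(config$output_dir, f)

  truth <- NULL
  if (!is.null(config$simulate)) {
    .plog(config, "simulating experiment")
    sim_args <- config$simulate
    sim_args$seed <- config$seed
    sim <- stage("simulate", simulate_experiment(do.call(sim_config, sim_args)))
    counts <- sim$counts; design <- sim$design; truth <- sim$truth
    write_counts(counts, op("counts.tsv"))
    write_samples(design, op("samples.tsv"))
    write_truth(truth, op("truth.tsv"))
  } else {
    .plog(config, "reading inputs")
    counts <- stage("read_counts", read_counts(config$counts))
    design <- stage("read_samples", read_samples(config$samples))
    if (!identical(colnames(counts$counts),
                   as.character(design$samples$sample)))
      stop("sample sheet samples do not match count matrix columns")
  }

  .plog(config, "filtering: ", nrow(counts$counts), " genes in")
  filtered <- stage("filter",
    filter_by_expression(counts, design, cpm_min = config$cpm_min,
                         min_prop = config$min_prop))
  .plog(config, "filtering: ", nrow(filtered$counts), " genes kept")

  factors <- stage("normalize",
    tmm_factors(filtered, trim_m = config$trim_m, trim_a = config$trim_a))
  write_norm_factors(factors, op("norm_factors.tsv"))

  .plog(config, "fitting standard contrasts")
  res <- stage("contrasts",
    run_standard_contrasts(filtered, design, norm_factors = factors,
                           span = config$span))
  for (nm in names(res))
    write_dge_result(res[[nm]], op(paste0("dge_", nm, ".tsv")))

  .plog(config, "classifying plasticity")
  calls <- stage("classify",
    classify_genes(res$plastic_control_pooled, res$evolved_unsprayed,
                   alpha = config$fdr_alpha))
  write_calls(calls, op("calls.tsv"))
  conc <- concordance_test(calls)
  tc <- timepoint_concordance(res$plastic_control_8h, res$plastic_control_32h,
                              alpha = config$fdr_alpha)
  amp <- plasticity_amplification(res$plastic_control_pooled,
                                  res$plastic_resistant_pooled,
                                  alpha = config$fdr_alpha)

  summary <- list(n_genes_in = nrow(counts$counts),
                  n_genes_filtered = nrow(filtered$counts),
                  n_both = conc$n_both,
                  n_adaptive = conc$n_concordant,
                  n_maladaptive = conc$n_both - conc$n_concordant,
                  p_binomial = conc$p_two_sided,
                  fraction_greater = amp$fraction_greater,
                  n_sig_control = amp$n_sig_control,
                  n_sig_resistant = amp$n_sig_resistant,
                  r_timepoints = tc$pearson_r,
                  n_direction_changed = tc$n_direction_changed)
  .write_json_atomic(summary, op("summary.json"))

  outputs <- list.files(config$output_dir, pattern = "\\.(tsv|json)$",
                        full.names = TRUE)
  outputs <- setdiff(outputs, op("manifest.json"))
  manifest <- list(
    package_version = as.character(utils::packageVersion("adaplast")),
    config = Filter(Negate(is.null), unclass(config)),
    checksums = as.list(tools::md5sum(sort(outputs))),
    stage_rows = list(input = nrow(counts$counts),
                      filtered = nrow(filtered$counts),
                      calls = nrow(calls)),
    timings_sec = as.list(timings),
    total_sec = round(proc.time()[["elapsed"]] - t0, 3))
  .write_json_atomic(manifest, op("manifest.json"))
  .plog(config, "done in ", manifest$total_sec, " s")
  invisible(structure(manifest, summary = summary, calls = calls))
}

# write JSON to a temp file in the same directory, then rename into place
.write_json_atomic <- function(x, path) {
  tmp <- tempfile(tmpdir = dirname(path), fileext = ".json.tmp")
  jsonlite::write_json(x, tmp, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, na = "null")
  file.rename(tmp, path)
  invisible(path)
}
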