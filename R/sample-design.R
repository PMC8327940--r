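#' Experimental design for the two-line, two-treatment, two-timepoint study
#'
#' Encodes the factorial structure of the selection experiment: each sample
#' belongs to one cell of line_type (control / resistant) x treatment
#' (unsprayed / sprayed) x timepoint (8 / 32 hours after application).
#' The derived design matrix uses the group-means (cell-means)
#' parameterization: one coefficient per occupied cell, no intercept.
#' Contrasts over cell means then express every comparison of interest,
#' with "pooled" contrasts averaging the two timepoints.
#'
#' @param samples data.frame with columns `sample`, `line_type`,
#'   `treatment`, `timepoint` (and optionally `replicate`). Levels are
#'   validated against the closed vocabularies.
#' @return An object of class `sample_design`: list with `samples` (the
#'   validated sheet), `cell` (factor of cell labels per sample), `matrix`
#'   (samples x occupied-cells design matrix), `cell_sizes` (named counts).
#' @export
sample_design <- function(samples) {
  samples <- as.data.frame(samples)
  required <- c("sample", "line_type", "treatment", "timepoint")
  missing_cols <- setdiff(required, names(samples))
  if (length(missing_cols))
    stop("sample sheet is missing column(s): ", paste(missing_cols, collapse = ", "))
  if (anyDuplicated(samples$sample))
    stop("duplicate sample id in sheet: ",
         paste(unique(samples$sample[duplicated(samples$sample)]), collapse = ", "))
  .check_levels(samples$line_type, c("control", "resistant"), "line_type")
  .check_levels(samples$treatment, c("unsprayed", "sprayed"), "treatment")
  .check_levels(as.character(samples$timepoint), c("8", "32"), "timepoint")

  line_type <- factor(samples$line_type, levels = c("control", "resistant"))
  treatment <- factor(samples$treatment, levels = c("unsprayed", "sprayed"))
  timepoint <- factor(as.character(samples$timepoint), levels = c("8", "32"))
  cell <- factor(paste(line_type, treatment, timepoint, sep = "."))
  X <- stats::model.matrix(~ 0 + cell)
  colnames(X) <- levels(cell)
  rownames(X) <- as.character(samples$sample)
  if (qr(X)$rank < ncol(X))
    stop("design matrix is not full column rank over the occupied cells")
  structure(list(samples = samples, cell = cell, matrix = X,
                 cell_sizes = table(cell)),
            class = "sample_design")
}

.check_levels <- function(x, allowed, what) {
  bad <- setdiff(unique(as.character(x)), allowed)
  if (length(bad))
    stop("unknown ", what, " level(s): ", paste(bad, collapse = ", "),
         "; allowed values are: ", paste(allowed, collapse = ", "))
}

#' @export
print.sample_design <- function(x, ...) {
  cat("sample_design:", nrow(x$samples), "samples in",
      nlevels(x$cell), "cells\n")
  print(x$cell_sizes)
  invisible(x)
}

.cell_label <- function(line_type, treatment, timepoint)
  paste(line_type, treatment, timepoint, sep = ".")

#' Build a named contrast over design-cell coefficients
#'
#' A contrast is a zero-sum weight vector over the columns of the
#' group-means design matrix. The standard contrast names are:
#'
#' * `plastic_control_pooled`, `plastic_resistant_pooled`: sprayed minus
#'   unsprayed within one line, averaged over timepoints (positive log2
#'   fold change = higher expression when sprayed).
#' * `plastic_control_8h`, `plastic_control_32h`, `plastic_resistant_8h`,
#'   `plastic_resistant_32h`: the same within a single timepoint.
#' * `evolved_unsprayed`, `evolved_sprayed`: resistant minus control within
#'   one treatment, averaged over timepoints (positive = higher in the
#'   resistance-selected lines).
#'
#' @param design a [sample_design()]
#' @param name one of the standard contrast names above
#' @return object of class `dge_contrast`: named numeric weight vector over
#'   design columns with attribute `contrast` = name.
#' @export
make_contrast <- function(design, name) {
  stopifnot(inherits(design, "sample_design"))
  spec <- .standard_contrast_cells(name)
  w <- numeric(ncol(design$matrix))
  names(w) <- colnames(design$matrix)
  for (side in c("plus", "minus")) {
    cells <- spec[[side]]
    missing_cells <- setdiff(cells, names(w))
    if (length(missing_cells))
      stop("contrast '", name, "' needs empty design cell(s): ",
           paste(missing_cells, collapse = ", "))
    w[cells] <- w[cells] + (if (side == "plus") 1 else -1) / length(cells)
  }
  if (abs(sum(w)) > 1e-12 || sum(w != 0) < 2)
    stop("invalid contrast weights for '", name, "'")
  structure(w, class = "dge_contrast", contrast = name)
}

.standard_contrast_cells <- function(name) {
  tp <- c("8", "32")
  switch(name,
    plastic_control_pooled = list(
      plus  = .cell_label("control", "sprayed", tp),
      minus = .cell_label("control", "unsprayed", tp)),
    plastic_control_8h = list(
      plus  = .cell_label("control", "sprayed", "8"),
      minus = .cell_label("control", "unsprayed", "8")),
    plastic_control_32h = list(
      plus  = .cell_label("control", "sprayed", "32"),
      minus = .cell_label("control", "unsprayed", "32")),
    plastic_resistant_pooled = list(
      plus  = .cell_label("resistant", "sprayed", tp),
      minus = .cell_label("resistant", "unsprayed", tp)),
    plastic_resistant_8h = list(
      plus  = .cell_label("resistant", "sprayed", "8"),
      minus = .cell_label("resistant", "unsprayed", "8")),
    plastic_resistant_32h = list(
      plus  = .cell_label("resistant", "sprayed", "32"),
      minus = .cell_label("resistant", "unsprayed", "32")),
    evolved_unsprayed = list(
      plus  = .cell_label("resistant", "unsprayed", tp),
      minus = .cell_label("control", "unsprayed", tp)),
    evolved_sprayed = list(
      plus  = .cell_label("resistant", "sprayed", tp),
      minus = .cell_label("control", "sprayed", tp)),
    stop("unknown contrast name: ", name)
  )
}

#' Names of the contrasts run by default
#' @return character vector of standard contrast names
#' @export
standard_contrast_names <- function()
  c("plastic_control_pooled", "plastic_control_8h", "plastic_control_32h",
    "plastic_resistant_pooled", "plastic_resistant_8h", "plastic_resistant_32h",
    "evolved_unsprayed", "evolved_sprayed")
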