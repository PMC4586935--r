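#' Construct a pattern dataset
#'
#' The unit of all pattern analyses: one t-value (or t-like) pattern per run
#' and per trial configuration, for one sensory modality. Values are stored as
#' a 3-way array `[run, configuration, voxel]`. Volumetric datasets
#' additionally carry a 3D logical `mask` and a 4x4 `affine`; the voxel
#' dimension then corresponds to `which(mask)` in R's column-major order.
#'
#' @param values Numeric array `[run, configuration, voxel]`, no missing
#'   values.
#' @param modality `"visual"` or `"somaesthetic"`.
#' @param run_ids Optional run identifiers (default `run-01` ...).
#' @param config_labels Configuration labels for the second dimension
#'   (default the canonical four).
#' @param mask Optional 3D logical array (volumetric datasets).
#' @param affine Optional 4x4 voxel-to-world affine (volumetric datasets).
#' @return An object of class `fl_patterns`.
#' @export
pattern_dataset <- function(values, modality = c("visual", "somaesthetic"),
                            run_ids = NULL, config_labels = CONFIG_LABELS,
                            mask = NULL, affine = NULL) {
  modality <- match.arg(modality)
  if (length(dim(values)) != 3L)
    stop("values must be a [run x configuration x voxel] array")
  if (anyNA(values) || any(!is.finite(values)))
    stop("values must be finite with no missing entries")
  if (dim(values)[2] != length(config_labels))
    stop("second dimension must match the configuration labels")
  if (is.null(run_ids)) run_ids <- sprintf("run-%02d", seq_len(dim(values)[1]))
  if (length(run_ids) != dim(values)[1]) stop("run_ids length mismatch")
  if (!is.null(mask)) {
    if (length(dim(mask)) != 3L) stop("mask must be a 3D logical array")
    if (sum(mask) != dim(values)[3])
      stop("voxel dimension must equal the number of in-mask voxels")
    if (is.null(affine)) affine <- diag(4)
  }
  structure(list(values = values, modality = modality, run_ids = run_ids,
                 config_labels = config_labels, mask = mask, affine = affine),
            class = "fl_patterns")
}

#' @export
print.fl_patterns <- function(x, ...) {
  d <- dim(x$values)
  cat(sprintf("<fl_patterns> %s modality: %d runs x %d configurations x %d voxels%s\n",
              x$modality, d[1], d[2], d[3],
              if (!is.null(x$mask)) " (volumetric)" else ""))
  invisible(x)
}

#' @export
dim.fl_patterns <- function(x) dim(x$values)

n_runs <- function(dataset) dim(dataset$values)[1]
n_voxels <- function(dataset) dim(dataset$values)[3]

# restrict a dataset to a subset of voxels (e.g. one searchlight sphere)
subset_voxels <- function(dataset, voxels) {
  dataset$values <- dataset$values[, , voxels, drop = FALSE]
  dataset$mask <- NULL
  dataset
}

# patterns of a given configuration label as a [run x voxel] matrix
config_matrix <- function(dataset, label) {
  i <- match(label, dataset$config_labels)
  if (is.na(i)) stop("unknown configuration label: ", label)
  dataset$values[, i, , drop = FALSE][, 1, , drop = TRUE]
}
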