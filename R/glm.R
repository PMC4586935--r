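#' Canonical double-gamma hemodynamic response function
#'
#' The conventional two-gamma shape: a positive response gamma (shape 6,
#' rate 1; peak near 5-6 s) minus a 1/6-scaled undershoot gamma (shape 16,
#' rate 1; trough near 15-16 s).
#'
#' @param t Time in seconds (vector).
#' @return HRF values at `t`.
#' @export
canonical_hrf <- function(t) {
  h <- stats::dgamma(t, shape = 6, rate = 1) -
    stats::dgamma(t, shape = 16, rate = 1) / 6
  h[t < 0] <- 0
  h
}

# convolve a microtime neural signal with the HRF and sample at scan onsets
convolve_sample <- function(u, dt, n_scans, tr_s) {
  h <- canonical_hrf(seq(0, 32, by = dt))
  conv <- stats::convolve(u, rev(h), type = "open")[seq_along(u)] * dt
  scan_bins <- pmin(length(u), floor(((seq_len(n_scans) - 1) * tr_s) / dt) + 1L)
  conv[scan_bins]
}

#' Build a per-run design matrix
#'
#' Implements the full regressor recipe for one run: four planning regressors
#' (boxcars spanning cue onset to Go cue, one per trial configuration), four
#' movement regressors (boxcars from Go to the hand's return), three spike
#' regressors (stimulus cues, saccade cues, run onset), and optionally 12
#' motion plus 5 image-compartment nuisance regressors — 28 columns in all.
#' All hemodynamic columns (boxcars and spikes) are convolved with the same
#' canonical HRF at microtime resolution `tr_s/16` and sampled at scan
#' onsets. Nuisance columns are taken as supplied or simulated as
#' small-amplitude AR(1) series.
#'
#' A configuration absent from the run yields an all-zero planning column,
#' recorded in the `empty_columns` field.
#'
#' @param events Single-run event table ([simulate_schedule()] columns).
#' @param n_scans Number of scans in the run.
#' @param tr_s Repetition time (s).
#' @param include_nuisance Append the 17 nuisance columns?
#' @param nuisance Optional `[scan x 17]` matrix of nuisance values.
#' @param nuisance_seed Seed for simulated nuisance series.
#' @param config_labels Configuration labels (canonical four).
#' @return A list of class `fl_design`: `matrix` `[scan x regressor]`,
#'   `names`, `tr_s`, `empty_columns`, and `boxcar_integral_s` (pre-convolution
#'   planning boxcar areas, seconds).
#' @export
build_design <- function(events, n_scans, tr_s, include_nuisance = TRUE,
                         nuisance = NULL, nuisance_seed = 1L,
                         config_labels = CONFIG_LABELS) {
  if (tr_s <= 0) stop("tr_s must be positive")
  run_len <- n_scans * tr_s
  if (any(events$onset < 0) || any(events$onset > run_len) ||
      any(events$go_onset + events$movement_duration > run_len))
    stop("events fall outside the run")
  if (!all(events$trial_type %in% config_labels))
    stop("unknown configuration label: ",
         paste(setdiff(events$trial_type, config_labels), collapse = ", "))

  dt <- tr_s / 16
  nb <- ceiling(run_len / dt)
  bin_of <- function(t) pmin(nb, floor(t / dt) + 1L)
  box <- function(from, to) {
    u <- numeric(nb)
    for (i in seq_along(from)) {
      b <- bin_of(from[i]):bin_of(to[i] - 1e-9)
      u[b] <- u[b] + 1
    }
    u
  }
  spike <- function(at) {
    u <- numeric(nb)
    u[bin_of(at)] <- u[bin_of(at)] + 1 / dt      # unit-area impulse
    u
  }

  cols <- list(); names_out <- character(0); integrals <- numeric(0)
  empty <- character(0)
  for (lab in config_labels) {
    ev <- events[events$trial_type == lab, , drop = FALSE]
    u <- if (nrow(ev)) box(ev$onset, ev$go_onset) else numeric(nb)
    if (!nrow(ev)) empty <- c(empty, paste0("planning_", lab))
    cols[[length(cols) + 1L]] <- convolve_sample(u, dt, n_scans, tr_s)
    names_out <- c(names_out, paste0("planning_", lab))
    integrals <- c(integrals, sum(u) * dt)
  }
  for (lab in config_labels) {
    ev <- events[events$trial_type == lab, , drop = FALSE]
    u <- if (nrow(ev)) box(ev$go_onset, ev$go_onset + ev$movement_duration)
         else numeric(nb)
    if (!nrow(ev)) empty <- c(empty, paste0("movement_", lab))
    cols[[length(cols) + 1L]] <- convolve_sample(u, dt, n_scans, tr_s)
    names_out <- c(names_out, paste0("movement_", lab))
  }
  sacc <- c(events$saccade1, events$saccade2)
  spikes <- list(stimulus_spike = events$onset,
                 saccade_spike = sacc[!is.na(sacc)],
                 run_onset_spike = 0)
  for (nm in names(spikes)) {
    u <- Reduce(`+`, lapply(spikes[[nm]], spike), numeric(nb))
    cols[[length(cols) + 1L]] <- convolve_sample(u, dt, n_scans, tr_s)
    names_out <- c(names_out, nm)
  }
  if (include_nuisance) {
    if (is.null(nuisance)) {
      set.seed(nuisance_seed)
      nuisance <- sapply(1:17, function(i) {
        e <- rnorm(n_scans, sd = 0.1)
        as.numeric(stats::filter(e, 0.95, method = "recursive"))
      })
    }
    if (nrow(nuisance) != n_scans || ncol(nuisance) != 17)
      stop("nuisance must be a [scan x 17] matrix")
    for (i in 1:12) cols[[length(cols) + 1L]] <- nuisance[, i]
    for (i in 1:5) cols[[length(cols) + 1L]] <- nuisance[, 12 + i]
    names_out <- c(names_out, sprintf("motion_%02d", 1:12),
                   sprintf("compartment_%02d", 1:5))
  }
  X <- do.call(cbind, cols)
  colnames(X) <- names_out
  structure(list(matrix = X, names = names_out, tr_s = tr_s,
                 empty_columns = empty,
                 boxcar_integral_s = setNames(integrals,
                                              paste0("planning_", config_labels))),
            class = "fl_design")
}

#' High-pass filter by discrete-cosine drift removal
#'
#' Regresses out a discrete cosine basis of all components with period longer
#' than `cutoff_s` (k = 1 .. floor(2 N tr / cutoff)). The constant component
#' is not in the basis, so the series mean (the implicit baseline) is
#' retained. If the run is too short for any drift term the input is returned
#' unchanged with a warning.
#'
#' @param timeseries `[scan x voxel]` matrix (or vector).
#' @param cutoff_s Cutoff period in seconds (default 128).
#' @param tr_s Repetition time (s).
#' @return Filtered matrix of the same shape.
#' @export
highpass <- function(timeseries, cutoff_s = 128, tr_s = 1.63) {
  Y <- as.matrix(timeseries)
  N <- nrow(Y)
  if (cutoff_s <= 2 * tr_s) stop("cutoff_s must exceed 2 * tr_s")
  K <- floor(2 * N * tr_s / cutoff_s)
  if (K < 1) {
    warning("run shorter than the cutoff period; returning input unchanged")
    return(timeseries)
  }
  n <- seq_len(N) - 0.5
  B <- sapply(seq_len(K), function(k) cos(pi * k * n / N))
  B <- qr.Q(qr(B))
  out <- Y - B %*% (crossprod(B, Y))
  if (is.vector(timeseries)) out <- drop(out)
  out
}

#' Fit an ordinary least squares GLM and contrast t-statistics
#'
#' Per-voxel OLS with rank-aware degrees of freedom. Contrast t-values are
#' `t = c'b / sqrt(s2 * c'(X'X)^- c)` with the Moore-Penrose pseudoinverse;
#' a contrast outside the estimable space of a rank-deficient design is an
#' error.
#'
#' @param timeseries `[scan x voxel]` matrix.
#' @param design An `fl_design` (or bare matrix).
#' @param contrasts `[contrast x regressor]` weight matrix (rows optionally
#'   named), or a single weight vector.
#' @return A list of class `fl_glmfit`: `betas` `[regressor x voxel]`,
#'   `t_map` `[contrast x voxel]`, `dof`, `sigma2`.
#' @export
fit_glm <- function(timeseries, design, contrasts) {
  X <- if (inherits(design, "fl_design")) design$matrix else as.matrix(design)
  Y <- as.matrix(timeseries)
  if (nrow(Y) != nrow(X)) stop("timeseries and design disagree on scan count")
  if (is.vector(contrasts)) contrasts <- matrix(contrasts, nrow = 1)
  if (ncol(contrasts) != ncol(X)) stop("contrast length must match regressors")
  sv <- svd(X)
  pos <- sv$d > max(sv$d) * 1e-10
  rank <- sum(pos)
  dof <- nrow(X) - rank
  if (dof < 1) stop("need at least rank(design) + 1 scans")
  dinv <- ifelse(pos, 1 / sv$d, 0)
  # minimum-norm betas and pinv(X'X)
  betas <- sv$v %*% (dinv * crossprod(sv$u, Y))
  xtx_pinv <- sv$v %*% (dinv^2 * t(sv$v))
  # estimability: c must lie in the row space of X
  proj <- sv$v[, pos, drop = FALSE] %*% t(sv$v[, pos, drop = FALSE])
  for (i in seq_len(nrow(contrasts))) {
    ci <- contrasts[i, ]
    if (sqrt(sum((proj %*% ci - ci)^2)) > 1e-8 * max(1, sqrt(sum(ci^2))))
      stop("contrast ", i, " is not estimable under the rank-deficient design")
  }
  res <- Y - X %*% betas
  sigma2 <- colSums(res^2) / dof
  cb <- contrasts %*% betas
  cvc <- rowSums((contrasts %*% xtx_pinv) * contrasts)
  t_map <- cb / sqrt(outer(pmax(cvc, 0), sigma2))
  t_map[, sigma2 == 0] <- ifelse(abs(cb[, sigma2 == 0, drop = FALSE]) < 1e-12,
                                 0, Inf * sign(cb[, sigma2 == 0, drop = FALSE]))
  rownames(t_map) <- rownames(contrasts)
  rownames(betas) <- colnames(X)
  structure(list(betas = betas, t_map = t_map, dof = dof, sigma2 = sigma2),
            class = "fl_glmfit")
}

#' Planning-versus-baseline contrast weights
#'
#' One row per configuration, selecting its planning regressor against the
#' implicit (unmodeled fixation) baseline.
#'
#' @param design An `fl_design`.
#' @return `[4 x regressor]` matrix with configuration-labelled rows.
#' @export
planning_contrasts <- function(design) {
  p <- length(design$names)
  idx <- grep("^planning_", design$names)
  C <- matrix(0, length(idx), p)
  C[cbind(seq_along(idx), idx)] <- 1
  rownames(C) <- sub("^planning_", "", design$names[idx])
  C
}

#' GLM stage: per-run t-patterns from BOLD runs
#'
#' Runs are modeled separately: each run's series is high-pass filtered, a
#' full design is built from its events, the GLM is fit, and the four
#' planning-versus-baseline t-values per voxel form that run's patterns.
#'
#' @param bold_runs List of `[scan x voxel]` matrices, one per run.
#' @param schedule Multi-run event table ([simulate_schedule()]).
#' @param tr_s Repetition time (s).
#' @param cutoff_s High-pass cutoff (s); `NULL` skips filtering.
#' @param include_nuisance Use the full 28-regressor recipe?
#' @param modality Modality tag for the resulting dataset.
#' @return An [pattern_dataset()] of t-patterns `[run x configuration x voxel]`.
#' @export
glm_patterns <- function(bold_runs, schedule, tr_s = 1.63, cutoff_s = 128,
                         include_nuisance = TRUE,
                         modality = c("visual", "somaesthetic")) {
  modality <- match.arg(modality)
  runs <- sort(unique(schedule$run))
  if (length(bold_runs) != length(runs))
    stop("one BOLD matrix per run is required")
  V <- ncol(bold_runs[[1]])
  vals <- array(0, dim = c(length(runs), length(CONFIG_LABELS), V))
  for (i in seq_along(runs)) {
    Y <- as.matrix(bold_runs[[i]])
    ev <- schedule[schedule$run == runs[i], , drop = FALSE]
    des <- build_design(ev, n_scans = nrow(Y), tr_s = tr_s,
                        include_nuisance = include_nuisance,
                        nuisance_seed = i)
    if (!is.null(cutoff_s)) {            # filter data and design alike
      Y <- highpass(Y, cutoff_s, tr_s)
      des$matrix <- highpass(des$matrix, cutoff_s, tr_s)
    }
    fit <- fit_glm(Y, des, planning_contrasts(des))
    vals[i, , ] <- fit$t_map
  }
  pattern_dataset(vals, modality)
}
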