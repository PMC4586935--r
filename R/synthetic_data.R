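#' Specify a synthetic pattern simulation
#'
#' Describes a ground-truth coding scheme for a pair of pattern datasets (one
#' per sensory modality). Each voxel receives one tuning prototype per coded
#' level; which level a configuration maps to depends on the scheme:
#' \describe{
#'   \item{gaze_centered}{prototype depends only on the target side relative
#'     to gaze (2 levels).}
#'   \item{body_centered}{only on the target side relative to the body
#'     midline (2 levels).}
#'   \item{gaze_direction}{only on the gaze position itself (3 levels).}
#'   \item{mixed}{convex combination of the gaze- and body-centered signals
#'     with weight `mix_weight` on the gaze-centered share.}
#'   \item{null}{no signal at all.}
#' }
#' Prototypes are i.i.d. standard Gaussian per voxel per level; noise is
#' spherical Gaussian with SD 1, and the prototype signal is scaled by `snr`
#' (so `snr` is signal SD over noise SD, and `snr = 0` yields
#' label-independent data).
#'
#' The `modality_model` controls how the two modalities relate:
#' `"shared"` reuses identical prototypes, `"independent"` draws fresh ones,
#' and `"switching"` gives the visual modality gaze-centered and the
#' somaesthetic modality body-centered tuning (the signature expected in
#' anterior intraparietal cortex).
#'
#' @param coding_scheme One of `"gaze_centered"`, `"body_centered"`,
#'   `"gaze_direction"`, `"mixed"`, `"null"`. Ignored (forced per modality)
#'   when `modality_model = "switching"`.
#' @param mix_weight Gaze-centered share in `[0, 1]` for `"mixed"`.
#' @param modality_model `"shared"`, `"independent"` or `"switching"`.
#' @param n_voxels Number of voxels.
#' @param n_runs_per_modality Runs per modality (default 8).
#' @param snr Signal SD / noise SD, nonnegative.
#' @param run_jitter_sd SD of per-run prototype jitter (between-run pattern
#'   variability; 0 disables).
#' @param seed Integer seed; fixed seed gives bit-identical output.
#' @return A list of class `fl_simspec`.
#' @export
simulation_spec <- function(coding_scheme = c("gaze_centered", "body_centered",
                                              "gaze_direction", "mixed", "null"),
                            mix_weight = 0.5,
                            modality_model = c("shared", "independent", "switching"),
                            n_voxels = 50, n_runs_per_modality = 8,
                            snr = 1, run_jitter_sd = 0, seed = 1L) {
  coding_scheme <- match.arg(coding_scheme)
  modality_model <- match.arg(modality_model)
  if (n_voxels < 1 || n_runs_per_modality < 1)
    stop("n_voxels and n_runs_per_modality must be positive")
  if (snr < 0) stop("snr must be nonnegative")
  if (mix_weight < 0 || mix_weight > 1) stop("mix_weight must be in [0, 1]")
  structure(list(coding_scheme = coding_scheme, mix_weight = mix_weight,
                 modality_model = modality_model, n_voxels = as.integer(n_voxels),
                 n_runs_per_modality = as.integer(n_runs_per_modality),
                 snr = snr, run_jitter_sd = run_jitter_sd, seed = as.integer(seed)),
            class = "fl_simspec")
}

# per-configuration level index under each elementary scheme
config_levels <- function(configs, scheme) {
  switch(scheme,
         gaze_centered = match(configs$target_side_gaze, c("left", "right")),
         body_centered = match(configs$target_side_body, c("left", "right")),
         gaze_direction = match(configs$gaze_label, c("L", "C", "R")),
         stop("no levels for scheme: ", scheme))
}

# [configuration x voxel] noise-free signal for one elementary/mixed scheme.
# protos: list of level-indexed prototype matrices drawn by the caller.
scheme_signal <- function(scheme, configs, protos, mix_weight, n_voxels) {
  if (scheme == "null") return(matrix(0, nrow(configs), n_voxels))
  if (scheme == "mixed") {
    gc <- protos$gaze_centered[config_levels(configs, "gaze_centered"), , drop = FALSE]
    bc <- protos$body_centered[config_levels(configs, "body_centered"), , drop = FALSE]
    return(mix_weight * gc + (1 - mix_weight) * bc)
  }
  protos[[scheme]][config_levels(configs, scheme), , drop = FALSE]
}

draw_protos <- function(n_voxels) {
  list(gaze_centered = matrix(rnorm(2 * n_voxels), 2),
       body_centered = matrix(rnorm(2 * n_voxels), 2),
       gaze_direction = matrix(rnorm(3 * n_voxels), 3))
}

#' Simulate pattern datasets with known ground-truth coding
#'
#' Draws one dataset per modality according to a [simulation_spec()]. The
#' noise-free prototype signal (scaled by `snr`) is shared, redrawn, or
#' scheme-swapped across modalities per the spec's `modality_model`; i.i.d.
#' standard Gaussian noise is added per run.
#'
#' @param spec A [simulation_spec()].
#' @param configs Trial configurations (default [make_configurations()]).
#' @return A list with elements `visual` and `somaesthetic`, each an
#'   [pattern_dataset()], plus the spec as attribute `"spec"`.
#' @examples
#' sim <- simulate_patterns(simulation_spec("gaze_centered", snr = 5, seed = 2))
#' dim(sim$visual)
#' @export
simulate_patterns <- function(spec, configs = make_configurations()) {
  stopifnot(inherits(spec, "fl_simspec"))
  set.seed(spec$seed)
  V <- spec$n_voxels; R <- spec$n_runs_per_modality
  n_cfg <- nrow(configs)

  scheme_for <- function(modality) {
    if (spec$modality_model == "switching")
      return(if (modality == "visual") "gaze_centered" else "body_centered")
    spec$coding_scheme
  }
  protos_vis <- draw_protos(V)
  protos_som <- if (spec$modality_model == "shared") protos_vis else draw_protos(V)

  make_one <- function(modality, protos) {
    sig <- scheme_signal(scheme_for(modality), configs, protos, spec$mix_weight, V)
    vals <- array(0, dim = c(R, n_cfg, V))
    for (r in seq_len(R)) {
      run_sig <- sig
      if (spec$run_jitter_sd > 0)
        run_sig <- sig + spec$run_jitter_sd * matrix(rnorm(n_cfg * V), n_cfg)
      vals[r, , ] <- spec$snr * run_sig + matrix(rnorm(n_cfg * V), n_cfg)
    }
    pattern_dataset(vals, modality, config_labels = configs$label)
  }
  out <- list(visual = make_one("visual", protos_vis),
              somaesthetic = make_one("somaesthetic", protos_som))
  attr(out, "spec") <- spec
  out
}

#' Simulate a counterbalanced event schedule
#'
#' Emits per-run event tables for the instructed-delay task: an auditory cue
#' announces the target, a variable delay (uniform within `delay_range_s`)
#' follows, then a Go cue triggers the movement, after which the fixation
#' point changes position twice (two saccade cues). Runs begin with 20 s and
#' end with 10 s of fixation. Trials are divided among the four
#' configurations as evenly as possible (the remainder rotates across runs so
#' overall counts balance), and the order approximates first-order
#' counterbalancing greedily: each next configuration minimizes the running
#' count of the (previous, next) transition.
#'
#' @param n_runs Number of runs.
#' @param trials_per_run Trials per run (default 22).
#' @param delay_range_s Length-2 delay bounds in seconds (default `c(3, 6)`).
#' @param seed Integer seed.
#' @param movement_duration_s Go-to-return duration in seconds.
#' @param configs Trial configurations.
#' @return A data.frame of class `fl_schedule` with columns `run`, `trial`,
#'   `trial_type`, `onset` (cue, s), `delay`, `go_onset`,
#'   `movement_duration`, `saccade1`, `saccade2`, and attribute
#'   `run_duration_s` (named per run).
#' @export
simulate_schedule <- function(n_runs, trials_per_run = 22,
                              delay_range_s = c(3, 6), seed = 1L,
                              movement_duration_s = 2,
                              configs = make_configurations()) {
  if (delay_range_s[1] > delay_range_s[2]) stop("delay bounds inverted")
  if (n_runs < 1 || trials_per_run < 1) stop("n_runs and trials_per_run must be positive")
  set.seed(seed)
  labels <- configs$label; K <- length(labels)
  base <- trials_per_run %/% K; rem <- trials_per_run %% K
  trans <- matrix(0L, K, K)                 # running transition counts
  prev <- 0L                                # 0 = run start
  rows <- list(); run_durs <- numeric(n_runs)
  extra_off <- 0L
  for (run in seq_len(n_runs)) {
    quota <- rep(base, K)
    if (rem > 0) {                          # rotate the remainder across runs
      idx <- ((extra_off + seq_len(rem) - 1L) %% K) + 1L
      quota[idx] <- quota[idx] + 1L
      extra_off <- (extra_off + rem) %% K
    }
    order_k <- integer(trials_per_run)
    for (t in seq_len(trials_per_run)) {
      avail <- which(quota > 0)
      cost <- if (prev == 0L) rep(0L, length(avail)) else trans[prev, avail]
      cand <- avail[cost == min(cost)]
      cand <- cand[quota[cand] == max(quota[cand])]   # tie: largest remaining quota
      k <- cand[1L]                                   # then label order
      order_k[t] <- k
      if (prev != 0L) trans[prev, k] <- trans[prev, k] + 1L
      quota[k] <- quota[k] - 1L
      prev <- k
    }
    delays <- runif(trials_per_run, delay_range_s[1], delay_range_s[2])
    onset <- numeric(trials_per_run)
    tcur <- 20                                         # initial fixation
    for (t in seq_len(trials_per_run)) {
      onset[t] <- tcur
      go <- tcur + delays[t]
      # two post-movement gaze shifts, then 0.5 s to the next cue
      tcur <- go + movement_duration_s + 1 + 0.5
    }
    go_onset <- onset + delays
    rows[[run]] <- data.frame(run = run, trial = seq_len(trials_per_run),
                              trial_type = labels[order_k], onset = onset,
                              delay = delays, go_onset = go_onset,
                              movement_duration = movement_duration_s,
                              saccade1 = go_onset + movement_duration_s,
                              saccade2 = go_onset + movement_duration_s + 1,
                              stringsAsFactors = FALSE)
    run_durs[run] <- tcur + 10                         # final fixation
  }
  sched <- do.call(rbind, rows)
  attr(sched, "run_duration_s") <- run_durs
  class(sched) <- c("fl_schedule", "data.frame")
  sched
}

#' Write a schedule as a BIDS-style events TSV
#'
#' Columns `onset`, `duration` (the delay period), `trial_type`, `run`.
#'
#' @param schedule Result of [simulate_schedule()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_events_tsv <- function(schedule, path) {
  out <- data.frame(onset = schedule$onset, duration = schedule$delay,
                    trial_type = schedule$trial_type, run = schedule$run)
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Simulate BOLD time series from a schedule
#'
#' Builds delay-period boxcars per configuration, convolves them with the
#' canonical double-gamma hemodynamic response, scales by the supplied
#' per-configuration amplitudes, and adds Gaussian noise and (optionally) a
#' slow cosine drift. Movement-period regressors can be driven too, so the
#' full GLM recipe can be exercised.
#'
#' @param schedule One run of an [simulate_schedule()] table (or a table with
#'   a single `run` value).
#' @param true_betas `[configuration x voxel]` planning amplitudes.
#' @param noise_sd Gaussian noise SD.
#' @param tr_s Repetition time in seconds (default 1.63).
#' @param seed Integer seed.
#' @param movement_betas Optional `[configuration x voxel]` movement
#'   amplitudes (default zero).
#' @param drift_amp Amplitude of an additive 256 s cosine drift (default 0).
#' @param run_duration_s Run length in seconds; defaults to the schedule's
#'   recorded duration.
#' @return A `[scan x voxel]` matrix with attribute `tr_s`.
#' @export
simulate_bold <- function(schedule, true_betas, noise_sd, tr_s = 1.63,
                          seed = 1L, movement_betas = NULL, drift_amp = 0,
                          run_duration_s = NULL) {
  if (tr_s <= 0) stop("tr_s must be positive")
  runs <- unique(schedule$run)
  if (length(runs) != 1L) stop("simulate_bold expects a single-run schedule")
  if (is.null(run_duration_s)) {
    rd <- attr(schedule, "run_duration_s")
    run_duration_s <- if (!is.null(rd)) rd[runs] else max(schedule$go_onset) +
      max(schedule$movement_duration) + 11.5
  }
  labels <- unique(schedule$trial_type)
  if (!is.matrix(true_betas) || nrow(true_betas) != length(CONFIG_LABELS))
    stop("true_betas must be a [configuration x voxel] matrix (4 rows)")
  n_scans <- ceiling(run_duration_s / tr_s)
  des <- build_design(schedule, n_scans = n_scans, tr_s = tr_s,
                      include_nuisance = FALSE)
  Xp <- des$matrix[, grep("^planning_", des$names), drop = FALSE]
  Y <- Xp %*% true_betas
  if (!is.null(movement_betas)) {
    Xm <- des$matrix[, grep("^movement_", des$names), drop = FALSE]
    Y <- Y + Xm %*% movement_betas
  }
  set.seed(seed)
  if (drift_amp > 0) {
    tt <- (seq_len(n_scans) - 1) * tr_s
    Y <- Y + drift_amp * cos(2 * pi * tt / 256)
  }
  if (noise_sd > 0) Y <- Y + noise_sd * matrix(rnorm(length(Y)), nrow(Y))
  attr(Y, "tr_s") <- tr_s
  Y
}

#' Simulate a volumetric pattern dataset with planted coding regions
#'
#' Places non-overlapping rectangular regions with specified coding schemes
#' into a 3D grid whose background voxels carry no signal (null coding).
#' Returns volumetric datasets (one per modality) on a full-grid mask with a
#' diagonal affine.
#'
#' @param grid_shape Integer vector of 3 grid dimensions.
#' @param region_specs List of regions, each `list(bbox =, spec =)` where
#'   `bbox` is a 3x2 matrix of inclusive voxel index ranges (rows x, y, z)
#'   and `spec` a [simulation_spec()]. Region specs' `n_voxels` is ignored
#'   (taken from the box).
#' @param n_runs_per_modality Runs per modality.
#' @param voxel_size_mm Isotropic voxel size for the affine (default 3.5).
#' @param seed Integer seed (region seeds are derived from it).
#' @return List with `visual` and `somaesthetic` volumetric
#'   [pattern_dataset()]s and attribute `"regions"` holding, per region, the
#'   linear voxel indices it occupies.
#' @export
simulate_volume <- function(grid_shape, region_specs = list(),
                            n_runs_per_modality = 8, voxel_size_mm = 3.5,
                            seed = 1L) {
  stopifnot(length(grid_shape) == 3L)
  mask <- array(TRUE, dim = grid_shape)
  N <- prod(grid_shape); R <- n_runs_per_modality
  occupied <- logical(N)
  region_idx <- list()
  for (i in seq_along(region_specs)) {
    bbox <- region_specs[[i]]$bbox
    if (any(bbox[, 1] < 1) || any(bbox[, 2] > grid_shape) || any(bbox[, 1] > bbox[, 2]))
      stop("region ", i, " bounding box outside the grid")
    idx_grid <- as.matrix(expand.grid(x = bbox[1, 1]:bbox[1, 2],
                                      y = bbox[2, 1]:bbox[2, 2],
                                      z = bbox[3, 1]:bbox[3, 2]))
    lin <- idx_grid[, 1] + (idx_grid[, 2] - 1L) * grid_shape[1] +
      (idx_grid[, 3] - 1L) * grid_shape[1] * grid_shape[2]
    if (any(occupied[lin])) stop("region ", i, " overlaps an earlier region")
    occupied[lin] <- TRUE
    region_idx[[i]] <- lin
  }
  set.seed(seed)
  vis <- array(rnorm(R * 4 * N), dim = c(R, 4, N))      # null background
  som <- array(rnorm(R * 4 * N), dim = c(R, 4, N))
  for (i in seq_along(region_specs)) {
    rspec <- region_specs[[i]]$spec
    rspec$n_voxels <- length(region_idx[[i]])
    rspec$n_runs_per_modality <- R
    rspec$seed <- as.integer((seed + 1000L * i) %% .Machine$integer.max)
    sim <- simulate_patterns(rspec)
    vis[, , region_idx[[i]]] <- sim$visual$values
    som[, , region_idx[[i]]] <- sim$somaesthetic$values
  }
  affine <- diag(c(rep(voxel_size_mm, 3), 1))
  out <- list(visual = pattern_dataset(vis, "visual", mask = mask, affine = affine),
              somaesthetic = pattern_dataset(som, "somaesthetic",
                                             mask = mask, affine = affine))
  attr(out, "regions") <- region_idx
  out
}
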