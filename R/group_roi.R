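#' Build the group-level design
#'
#' Observations are the full crossing of subjects, modalities, condition
#' pairs and tests (classification vs cross-classification); with 18
#' subjects, 2 modalities, 6 pairs and 2 tests that is 432 observations. The
#' design holds one intercept per subject plus one regressor per
#' modality-by-pair-by-test cell (42 regressors at that scale).
#' The subject intercepts are collinear with the condition set, so the rank
#' is one less than the column count and the residual degrees of freedom are
#' `observations - (regressors - 1)` (391 in the full-scale design).
#'
#' @param obs_info Data.frame with columns `subject`, `modality`, `pair`,
#'   `test`, one row per observation.
#' @return A list of class `fl_group_design`: `X`, `subjects`, `cells`
#'   (data.frame describing the condition columns), `n_subject_cols`.
#' @export
build_group_design <- function(obs_info) {
  need <- c("subject", "modality", "pair", "test")
  if (!all(need %in% names(obs_info)))
    stop("obs_info must have columns: ", paste(need, collapse = ", "))
  subj <- factor(obs_info$subject)
  cell <- interaction(obs_info$modality, obs_info$pair, obs_info$test,
                      sep = ":", drop = FALSE)
  tab <- table(subj, cell)
  if (any(tab != 1L))
    stop("observations must be the full subject x modality x pair x test crossing")
  Xs <- stats::model.matrix(~ 0 + subj)
  Xc <- stats::model.matrix(~ 0 + cell)
  colnames(Xs) <- paste0("subject_", levels(subj))
  colnames(Xc) <- paste0("cond_", levels(cell))
  cells <- do.call(rbind, strsplit(levels(cell), ":", fixed = TRUE))
  cells <- data.frame(modality = cells[, 1], pair = cells[, 2],
                      test = cells[, 3], column = colnames(Xc),
                      stringsAsFactors = FALSE)
  structure(list(X = cbind(Xs, Xc), subjects = levels(subj), cells = cells,
                 n_subject_cols = ncol(Xs)),
            class = "fl_group_design")
}

#' Build a group contrast vector
#'
#' Selects condition cells by modality/pair/test and weights them `1/n`
#' each; with a second selection, the contrast is the difference of the two
#' cell means (subject intercepts cancel). For a single selection (a mean
#' against zero) the subject intercepts are included at `1/S` each, which
#' makes the otherwise inestimable cell mean estimable as "condition mean at
#' the average subject".
#'
#' @param gdesign An `fl_group_design`.
#' @param select,against Named lists with any of `modality`, `pair`, `test`
#'   (values to match; NULL matches all).
#' @return Contrast vector over the design's columns.
#' @export
group_contrast <- function(gdesign, select, against = NULL) {
  pick <- function(sel) {
    keep <- rep(TRUE, nrow(gdesign$cells))
    for (f in c("modality", "pair", "test"))
      if (!is.null(sel[[f]])) keep <- keep & gdesign$cells[[f]] %in% sel[[f]]
    if (!any(keep)) stop("contrast selection matches no condition cell")
    keep
  }
  nc <- ncol(gdesign$X); S <- gdesign$n_subject_cols
  w <- numeric(nc)
  k1 <- pick(select)
  w[S + which(k1)] <- 1 / sum(k1)
  if (!is.null(against)) {
    k2 <- pick(against)
    w[S + which(k2)] <- w[S + which(k2)] - 1 / sum(k2)
  } else {
    w[seq_len(S)] <- 1 / S
  }
  w
}

#' Frame-aggregate contrast over the group design
#'
#' Weights the four condition cells that make up a frame's aggregate (the
#' frame's two predicted-common pairs under cross-classification and its two
#' predicted-distinct pairs under classification) at 1/4 each, within one
#' modality. With `against_frame`/`against_modality` the mirror cells are
#' subtracted (subject intercepts cancel); otherwise the contrast tests the
#' aggregate against chance and includes the subject intercepts at 1/S.
#'
#' @param gdesign An `fl_group_design`.
#' @param frame `"gc"` or `"bc"`.
#' @param modality `"visual"` or `"somaesthetic"`.
#' @param against_frame,against_modality Optional frame/modality whose
#'   aggregate cells are subtracted.
#' @return Contrast vector over the design's columns.
#' @export
aggregate_contrast <- function(gdesign, frame = c("gc", "bc"),
                               modality = c("visual", "somaesthetic"),
                               against_frame = NULL, against_modality = NULL) {
  frame <- match.arg(frame)
  modality <- match.arg(modality)
  cell_weights <- function(frame, modality) {
    gaze <- c("left_wrt_gaze", "right_wrt_gaze")
    body <- c("left_wrt_body", "right_wrt_body")
    xc_pairs <- if (frame == "gc") gaze else body
    cl_pairs <- if (frame == "gc") body else gaze
    k <- (gdesign$cells$modality == modality) &
      ((gdesign$cells$pair %in% xc_pairs &
          gdesign$cells$test == "cross_classification") |
         (gdesign$cells$pair %in% cl_pairs &
            gdesign$cells$test == "classification"))
    stopifnot(sum(k) == 4L)
    k / 4
  }
  S <- gdesign$n_subject_cols
  w <- numeric(ncol(gdesign$X))
  w[S + seq_len(nrow(gdesign$cells))] <- cell_weights(frame, modality)
  if (is.null(against_frame) && is.null(against_modality)) {
    w[seq_len(S)] <- 1 / S
  } else {
    w[S + seq_len(nrow(gdesign$cells))] <-
      w[S + seq_len(nrow(gdesign$cells))] -
      cell_weights(if (is.null(against_frame)) frame else against_frame,
                   if (is.null(against_modality)) modality else against_modality)
  }
  w
}

#' Group-level GLM over subject evidence maps
#'
#' Per-voxel OLS on the full-crossing design of [build_group_design()].
#' Accuracy values are chance-centred (`chance` subtracted) before fitting,
#' so a single-cell contrast directly tests exceedance of chance.
#'
#' @param evidence `[observation x voxel]` matrix of evidence values
#'   (accuracies), rows aligned with `obs_info`.
#' @param obs_info Observation labels (see [build_group_design()]).
#' @param contrasts `[contrast x regressor]` matrix (build rows with
#'   [group_contrast()]), or a single vector.
#' @param chance Value subtracted from the evidence (default 0.5; use 0 for
#'   already-centred inputs).
#' @return A list of class `fl_group_fit`: `t_map` `[contrast x voxel]`,
#'   `dof`, `design`, the underlying `fit`.
#' @export
group_glm <- function(evidence, obs_info, contrasts, chance = 0.5) {
  gdesign <- if (inherits(obs_info, "fl_group_design")) obs_info
             else build_group_design(obs_info)
  evidence <- as.matrix(evidence)
  if (nrow(evidence) != nrow(gdesign$X))
    stop("evidence rows must match the observations")
  bsv <- apply(evidence, 2, stats::sd)
  fit <- fit_glm(evidence - chance, gdesign$X, contrasts)
  flagged <- which(fit$sigma2 < 1e-20 & bsv < 1e-12)
  structure(list(t_map = fit$t_map, dof = fit$dof, design = gdesign,
                 fit = fit, degenerate_voxels = flagged),
            class = "fl_group_fit")
}

#' Threshold a t-map and extract clusters
#'
#' Voxels with one-tailed `p < alpha` under the t distribution with `dof`
#' degrees of freedom are retained; connected components strictly larger
#' than `min_cluster_voxels` survive. Connectivity is 26-neighborhood by
#' default (configurable to 6).
#'
#' @param t_map 3D t-value array (NA outside the mask) or per-voxel vector
#'   with `mask`.
#' @param dof Degrees of freedom.
#' @param alpha Voxelwise significance level (default 0.05).
#' @param min_cluster_voxels Strict lower bound on surviving cluster size
#'   (default 250).
#' @param connectivity 26 or 6.
#' @param mask Mask when `t_map` is a vector.
#' @param affine Optional affine for peak world coordinates.
#' @return List: `map` (logical 3D array of surviving voxels), `clusters`
#'   (data.frame with `id`, `size`, `peak_t`, peak voxel indices and, with
#'   an affine, peak mm coordinates).
#' @export
cluster_threshold <- function(t_map, dof, alpha = 0.05,
                              min_cluster_voxels = 250, connectivity = 26,
                              mask = NULL, affine = NULL) {
  if (alpha <= 0 || alpha >= 1) stop("alpha must be in (0, 1)")
  if (!is.array(t_map) || length(dim(t_map)) != 3L) {
    if (is.null(mask)) stop("vector t_map requires a mask")
    t_map <- as_volume(drop(t_map), mask = mask)
  }
  thr <- qt(1 - alpha, dof)
  supra <- !is.na(t_map) & t_map > thr
  lab <- label_components(supra, connectivity)
  keep_map <- array(FALSE, dim(t_map))
  rows <- list()
  if (max(lab) > 0) {
    id_out <- 0L
    for (id in seq_len(max(lab))) {
      vox <- which(lab == id)
      if (length(vox) > min_cluster_voxels) {
        id_out <- id_out + 1L
        keep_map[vox] <- TRUE
        peak <- vox[which.max(t_map[vox])]
        pc <- arrayInd(peak, dim(t_map))
        row <- data.frame(id = id_out, size = length(vox),
                          peak_t = t_map[peak],
                          peak_i = pc[1], peak_j = pc[2], peak_k = pc[3])
        if (!is.null(affine)) {
          mm <- affine %*% c(pc - 1, 1)
          row$peak_x_mm <- mm[1]; row$peak_y_mm <- mm[2]; row$peak_z_mm <- mm[3]
        }
        rows[[length(rows) + 1L]] <- row
      }
    }
  }
  clusters <- if (length(rows)) do.call(rbind, rows)
  else data.frame(id = integer(0), size = integer(0), peak_t = numeric(0),
                  peak_i = integer(0), peak_j = integer(0), peak_k = integer(0))
  list(map = keep_map, clusters = clusters, threshold_t = thr)
}

# connected-component labeling by iterative flood fill
label_components <- function(binary, connectivity = 26) {
  dims <- dim(binary)
  stopifnot(connectivity %in% c(6, 26))
  off <- as.matrix(expand.grid(-1:1, -1:1, -1:1))
  off <- off[rowSums(abs(off)) > 0, , drop = FALSE]
  if (connectivity == 6) off <- off[rowSums(abs(off)) == 1, , drop = FALSE]
  lab <- array(0L, dims)
  nxt <- 0L
  todo <- which(binary)
  for (start in todo) {
    if (lab[start] != 0L) next
    nxt <- nxt + 1L
    queue <- start; lab[start] <- nxt
    while (length(queue)) {
      v <- queue[[1]]; queue <- queue[-1]
      vc <- arrayInd(v, dims)
      nb <- off + matrix(vc, nrow(off), 3, byrow = TRUE)
      ok <- nb[, 1] >= 1 & nb[, 1] <= dims[1] & nb[, 2] >= 1 &
        nb[, 2] <= dims[2] & nb[, 3] >= 1 & nb[, 3] <= dims[3]
      nl <- nb[ok, 1] + (nb[ok, 2] - 1L) * dims[1] +
        (nb[ok, 3] - 1L) * dims[1] * dims[2]
      nl <- nl[binary[nl] & lab[nl] == 0L]
      lab[nl] <- nxt
      queue <- c(queue, nl)
    }
  }
  lab
}

#' Define a spherical ROI at the local maximum nearest a reference
#'
#' Finds all local maxima of an *independent* evidence t-map (voxels
#' strictly greater than every in-mask neighbor, 26-connectivity), picks the
#' one with the smallest Euclidean world distance to the reference
#' coordinate (ties broken lexicographically by voxel coordinate), and
#' returns a sphere of `radius_mm` around it. The map must come from the
#' independent pairs (center/outer sides) so that ROI placement does not
#' bias frame evidence.
#'
#' @param t_map 3D array (NA outside mask) or per-voxel vector with `mask`.
#' @param reference_mm Length-3 world coordinate.
#' @param mask 3D logical mask.
#' @param affine 4x4 voxel-to-world affine.
#' @param radius_mm ROI radius (default 7).
#' @param name ROI name.
#' @return A list of class `fl_roi`: `name`, `reference_mm`, `center_mm`,
#'   `center_vox`, `radius_mm`, `voxels` (in-mask voxel indices inside the
#'   sphere).
#' @export
define_roi <- function(t_map, reference_mm, mask, affine = NULL,
                       radius_mm = 7, name = "roi") {
  if (is.null(affine)) affine <- diag(4)
  if (!is.array(t_map) || length(dim(t_map)) != 3L)
    t_map <- as_volume(drop(t_map), mask = mask)
  dims <- dim(mask)
  off <- as.matrix(expand.grid(-1:1, -1:1, -1:1))
  off <- off[rowSums(abs(off)) > 0, , drop = FALSE]
  cand <- which(mask)
  is_max <- logical(length(cand))
  for (i in seq_along(cand)) {
    vc <- arrayInd(cand[i], dims)
    nb <- off + matrix(vc, nrow(off), 3, byrow = TRUE)
    ok <- nb[, 1] >= 1 & nb[, 1] <= dims[1] & nb[, 2] >= 1 &
      nb[, 2] <= dims[2] & nb[, 3] >= 1 & nb[, 3] <= dims[3]
    nl <- nb[ok, 1] + (nb[ok, 2] - 1L) * dims[1] +
      (nb[ok, 3] - 1L) * dims[1] * dims[2]
    nl <- nl[mask[nl]]
    is_max[i] <- length(nl) == 0L || all(t_map[cand[i]] > t_map[nl])
  }
  peaks <- cand[is_max]
  if (!length(peaks)) stop("no local maximum inside the mask")
  pc <- arrayInd(peaks, dims)
  mm <- t(affine %*% rbind(t(pc - 1), 1))[, 1:3, drop = FALSE]
  d <- sqrt(rowSums(sweep(mm, 2, reference_mm, "-")^2))
  ord <- order(d, pc[, 1], pc[, 2], pc[, 3])   # lexicographic tie-break
  best <- ord[1]
  center_vox <- pc[best, ]
  center_mm <- mm[best, ]
  all_vox <- which(mask)
  ac <- arrayInd(all_vox, dims)
  amm <- t(affine %*% rbind(t(ac - 1), 1))[, 1:3, drop = FALSE]
  inside <- sqrt(rowSums(sweep(amm, 2, center_mm, "-")^2)) <= radius_mm + 1e-9
  structure(list(name = name, reference_mm = reference_mm,
                 center_mm = center_mm, center_vox = center_vox,
                 radius_mm = radius_mm, voxels = which(inside)),
            class = "fl_roi")
}

#' ROI-level statistics across a subject cohort
#'
#' Given per-subject, per-modality frame aggregates inside an ROI, runs the
#' standard battery: one-sample tests of each aggregate against chance
#' (one-tailed), paired GC-vs-BC tests per modality, paired
#' visual-vs-somaesthetic tests per frame, and the (GC - BC) x modality
#' interaction (all paired tests two-tailed). Optionally, per-pair scores
#' yield group-level significance flags and the conjunction / gaze-direction
#' calls per modality.
#'
#' @param roi_evidence Data.frame with columns `subject`, `modality`,
#'   `aggregate_gc`, `aggregate_bc` (one row per subject x modality).
#' @param pair_scores Optional data.frame with columns `subject`,
#'   `modality`, `pair`, `a`, `o` for group-level conjunction flags.
#' @param alpha Significance level for the flags.
#' @return List of class `fl_roi_stats`: `tests` (data.frame test,
#'   estimate, t, df, p) and, when `pair_scores` is given, `conjunction`
#'   and `gazedir` per modality.
#' @export
roi_stats <- function(roi_evidence, pair_scores = NULL, alpha = 0.05) {
  need <- c("subject", "modality", "aggregate_gc", "aggregate_bc")
  if (!all(need %in% names(roi_evidence)))
    stop("roi_evidence must have columns: ", paste(need, collapse = ", "))
  subjects <- sort(unique(roi_evidence$subject))
  if (length(subjects) < 3) stop("at least 3 subjects are required")
  get <- function(mod, col) {
    d <- roi_evidence[roi_evidence$modality == mod, ]
    d[[col]][match(subjects, d$subject)]
  }
  rows <- list()
  add <- function(test, x, mu = 0, alternative = "two.sided") {
    ok <- is.finite(x)
    tt <- if (stats::sd(x[ok]) < 1e-12) {
      # zero-variance battery: p is 0 or 1 depending on whether the constant
      # effect matches the null
      hit <- if (alternative == "greater") mean(x[ok]) > mu
             else abs(mean(x[ok]) - mu) > 1e-12
      list(estimate = mean(x[ok]), statistic = NA_real_,
           parameter = sum(ok) - 1, p.value = if (hit) 0 else 1)
    } else stats::t.test(x[ok], mu = mu, alternative = alternative)
    rows[[length(rows) + 1L]] <<- data.frame(
      test = test, estimate = unname(mean(x[ok]) - mu),
      t = unname(tt$statistic), df = unname(tt$parameter),
      p = tt$p.value, stringsAsFactors = FALSE)
  }
  for (mod in c("visual", "somaesthetic")) {
    add(paste0("gc_vs_chance_", mod), get(mod, "aggregate_gc"), 0.5, "greater")
    add(paste0("bc_vs_chance_", mod), get(mod, "aggregate_bc"), 0.5, "greater")
    add(paste0("gc_vs_bc_", mod),
        get(mod, "aggregate_gc") - get(mod, "aggregate_bc"))
  }
  add("gc_vis_vs_som",
      get("visual", "aggregate_gc") - get("somaesthetic", "aggregate_gc"))
  add("bc_vis_vs_som",
      get("visual", "aggregate_bc") - get("somaesthetic", "aggregate_bc"))
  dvis <- get("visual", "aggregate_gc") - get("visual", "aggregate_bc")
  dsom <- get("somaesthetic", "aggregate_gc") - get("somaesthetic", "aggregate_bc")
  add("gc_bc_by_modality_interaction", dvis - dsom)
  out <- list(tests = do.call(rbind, rows))
  if (!is.null(pair_scores)) {
    out$conjunction <- list(); out$gazedir <- list()
    for (mod in unique(pair_scores$modality)) {
      d <- pair_scores[pair_scores$modality == mod, ]
      flags <- do.call(rbind, lapply(split(d, d$pair), function(g) {
        data.frame(pair = g$pair[1],
                   sig_a = acc_ttest_p(g$a) < alpha,
                   sig_o = acc_ttest_p(g$o) < alpha,
                   stringsAsFactors = FALSE)
      }))
      rownames(flags) <- flags$pair
      out$conjunction[[mod]] <- conjunction(flags)
      out$gazedir[[mod]] <- gaze_direction_test(flags)
    }
  }
  class(out) <- "fl_roi_stats"
  out
}
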