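pipeline_defaults <- function() {
  list(
    geometry = list(gaze_angles_deg = c(-11, 0, 11),
                    target_offsets_deg = c(-5, 5)),
    simulation = list(grid_shape = c(8, 8, 4), n_subjects = 6,
                      n_runs_per_modality = 8, snr = 2, voxel_size_mm = 3.5,
                      regions = list()),
    glm = list(tr_s = 1.63, cutoff_s = 128),
    decoding = list(zscore = "all_patterns", xmode = "replacement"),
    searchlight = list(radius_mm = 7),
    group = list(alpha = 0.05, min_cluster = 250),
    roi = list(radius_mm = 7),
    seed = NULL,
    out_dir = NULL)
}

#' Load and validate a pipeline configuration
#'
#' Accepts a JSON file path or a nested list; unknown keys are rejected and
#' missing keys fall back to documented defaults, except `out_dir` and at
#' least one simulation region, which are required for [run_pipeline()].
#' Each region is a list with `name`, `scheme` (a [simulation_spec()]
#' coding scheme), `modality_model` and `bbox` (3x2 inclusive voxel ranges).
#'
#' @param x Path to a JSON config, or a list.
#' @return A validated config list of class `fl_config`.
#' @export
pipeline_config <- function(x = list()) {
  if (is.character(x)) x <- jsonlite::read_json(x, simplifyVector = TRUE,
                                                simplifyDataFrame = FALSE)
  if (!is.list(x)) stop("config must be a list or a JSON file path")
  defaults <- pipeline_defaults()
  unknown <- setdiff(names(x), names(defaults))
  if (length(unknown))
    stop("unknown config key(s): ", paste(unknown, collapse = ", "))
  cfg <- modifyList(defaults, x)
  # modifyList drops unnamed list elements; region lists are unnamed
  if (!is.null(x$simulation$regions))
    cfg$simulation$regions <- x$simulation$regions
  for (key in c("seed", "out_dir"))
    if (is.null(cfg[[key]])) stop("config key missing: ", key)
  if (!length(cfg$simulation$regions))
    stop("config key missing: simulation.regions (at least one region)")
  for (i in seq_along(cfg$simulation$regions)) {
    r <- cfg$simulation$regions[[i]]
    for (key in c("name", "scheme", "bbox"))
      if (is.null(r[[key]]))
        stop("config key missing: simulation.regions[", i, "].", key)
    if (is.null(r$modality_model)) cfg$simulation$regions[[i]]$modality_model <- "shared"
    bbox <- r$bbox
    if (!is.matrix(bbox)) bbox <- do.call(rbind, lapply(bbox, unlist))
    if (!all(dim(bbox) == c(3, 2)))
      stop("simulation.regions[", i, "].bbox must be a 3x2 range matrix")
    cfg$simulation$regions[[i]]$bbox <- bbox
  }
  class(cfg) <- c("fl_config", "list")
  cfg
}

# tiny FNV-1a hash so outputs can be traced back to their configuration
config_hash <- function(cfg) {
  s <- jsonlite::toJSON(unclass(cfg), auto_unbox = TRUE, digits = NA,
                        force = TRUE)
  bytes <- utf8ToInt(as.character(s))
  h <- 2166136261
  for (b in bytes) h <- (bitwXor(as.integer(h %% 2^31), b) * 16777619) %% 2^31
  sprintf("%08x", as.integer(h))
}

region_center_mm <- function(bbox, voxel_size_mm) {
  (colMeans(t(bbox)) - 1) * voxel_size_mm
}

#' Run the full synthetic pipeline
#'
#' End to end: simulate a volumetric cohort with planted coding regions,
#' decode every searchlight sphere (per-pair classification and
#' cross-classification, both modalities), average scores back onto voxels,
#' fit the full-crossing group GLM, threshold the frame maps by cluster
#' extent, define ROIs at the local maxima of the independent-pair map
#' nearest each region's center, and run the ROI statistics battery.
#' Outputs (pair table, per-subject maps, group t-maps as NIfTI, cluster and
#' ROI tables as TSV, a JSON report) are written under `config$out_dir`,
#' each traceable to the config hash.
#'
#' @param config An `fl_config` (see [pipeline_config()]).
#' @param verbose Log stage progress?
#' @return The report, invisibly: a list with `group` (t-maps, dof),
#'   `clusters`, `rois`, `roi_stats`, `hash`, `out_dir`.
#' @export
run_pipeline <- function(config, verbose = TRUE) {
  if (!inherits(config, "fl_config")) config <- pipeline_config(config)
  hash <- config_hash(config)
  out_dir <- config$out_dir
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  say <- function(...) if (verbose) message(sprintf("[framelight %s] ", hash), ...)
  stage <- function(name, expr) {
    t0 <- Sys.time()
    res <- tryCatch(expr, error = function(e)
      stop("stage '", name, "' failed: ", conditionMessage(e), call. = FALSE))
    say(sprintf("%s done in %.1f s", name, as.numeric(Sys.time() - t0, units = "secs")))
    res
  }

  cfg_sim <- config$simulation
  configs <- do.call(make_configurations, config$geometry)
  pairs <- enumerate_pairs(configs)
  write_pair_table(pairs, file.path(out_dir, "pairs.tsv"))
  say("seed ", config$seed, "; ", cfg_sim$n_subjects, " subjects; grid ",
      paste(cfg_sim$grid_shape, collapse = "x"))

  region_specs <- lapply(cfg_sim$regions, function(r)
    list(bbox = r$bbox,
         spec = simulation_spec(r$scheme, modality_model = r$modality_model,
                                n_runs_per_modality = cfg_sim$n_runs_per_modality,
                                snr = cfg_sim$snr)))

  subj_vols <- stage("simulate", {
    lapply(seq_len(cfg_sim$n_subjects), function(s)
      simulate_volume(cfg_sim$grid_shape, region_specs,
                      n_runs_per_modality = cfg_sim$n_runs_per_modality,
                      voxel_size_mm = cfg_sim$voxel_size_mm,
                      seed = config$seed + 97L * s))
  })

  subj_maps <- stage("searchlight", {
    idx <- build_spheres(subj_vols[[1]]$visual$mask,
                         config$searchlight$radius_mm,
                         affine = subj_vols[[1]]$visual$affine)
    scoring <- searchlight_measures(pairs, zscore = config$decoding$zscore,
                                    xmode = config$decoding$xmode,
                                    detail = "full")
    lapply(subj_vols, function(vols)
      voxelwise_average(run_searchlight(vols, idx, scoring), idx))
  })
  mask <- subj_maps[[1]]$mask
  affine <- subj_maps[[1]]$affine

  group <- stage("group", {
    measures <- subj_maps[[1]]$measures
    obs <- expand.grid(test = c("classification", "cross_classification"),
                       pair = pairs$pair,
                       modality = c("visual", "somaesthetic"),
                       subject = sprintf("sub-%02d", seq_along(subj_maps)),
                       stringsAsFactors = FALSE)
    col_of <- paste0(ifelse(obs$test == "classification", "a_", "o_"),
                     obs$pair, "_", obs$modality)
    ev <- do.call(rbind, lapply(seq_len(nrow(obs)), function(i) {
      s <- match(obs$subject[i], sprintf("sub-%02d", seq_along(subj_maps)))
      subj_maps[[s]]$values[, match(col_of[i], measures)]
    }))
    gdesign <- build_group_design(obs)
    cmat <- rbind(
      gc_visual = aggregate_contrast(gdesign, "gc", "visual"),
      bc_visual = aggregate_contrast(gdesign, "bc", "visual"),
      gc_somaesthetic = aggregate_contrast(gdesign, "gc", "somaesthetic"),
      bc_somaesthetic = aggregate_contrast(gdesign, "bc", "somaesthetic"),
      gc_vs_bc_visual = aggregate_contrast(gdesign, "gc", "visual",
                                           against_frame = "bc"),
      gc_vs_bc_somaesthetic = aggregate_contrast(gdesign, "gc", "somaesthetic",
                                                 against_frame = "bc"),
      interaction = aggregate_contrast(gdesign, "gc", "visual",
                                       against_frame = "bc") -
        aggregate_contrast(gdesign, "gc", "somaesthetic", against_frame = "bc"),
      independent = group_contrast(gdesign,
                                   list(pair = c("outer_sides", "center_sides"),
                                        test = "classification")))
    fit <- group_glm(ev, gdesign, cmat)
    for (nm in rownames(fit$t_map)) {
      p <- file.path(out_dir, paste0("group_t_", nm, ".nii"))
      write_nifti(as_volume(fit$t_map[nm, ], mask = mask), p, affine)
      write_sidecar(list(contrast = nm, dof = fit$dof, config_hash = hash), p)
    }
    fit
  })

  clusters <- stage("clusters", {
    cl <- lapply(c("gc_vs_bc_visual", "gc_vs_bc_somaesthetic", "independent"),
                 function(nm) {
      res <- cluster_threshold(as_volume(group$t_map[nm, ], mask = mask),
                               group$dof, alpha = config$group$alpha,
                               min_cluster_voxels = config$group$min_cluster,
                               affine = affine)
      if (nrow(res$clusters)) cbind(contrast = nm, res$clusters) else NULL
    })
    tab <- do.call(rbind, cl[!vapply(cl, is.null, TRUE)])
    if (is.null(tab)) tab <- data.frame()
    if (nrow(tab)) write.table(tab, file.path(out_dir, "clusters.tsv"),
                               sep = "\t", quote = FALSE, row.names = FALSE)
    tab
  })

  roi_results <- stage("roi", {
    indep_map <- as_volume(group$t_map["independent", ], mask = mask)
    res <- list()
    for (i in seq_along(cfg_sim$regions)) {
      r <- cfg_sim$regions[[i]]
      ref <- region_center_mm(r$bbox, cfg_sim$voxel_size_mm)
      roi <- define_roi(indep_map, ref, mask, affine,
                        radius_mm = config$roi$radius_mm, name = r$name)
      ev_rows <- list()
      for (s in seq_len(cfg_sim$n_subjects)) {
        vols <- subj_vols[[s]]
        for (mod in c("visual", "somaesthetic")) {
          ds <- subset_voxels(vols[[mod]], roi$voxels)
          tbl <- evidence_table(ds, pairs, zscore = config$decoding$zscore,
                                xmode = config$decoding$xmode)
          agg <- aggregate_evidence(tbl)
          ev_rows[[length(ev_rows) + 1L]] <-
            data.frame(subject = sprintf("sub-%02d", s), modality = mod,
                       aggregate_gc = agg$aggregate_gc,
                       aggregate_bc = agg$aggregate_bc)
        }
      }
      stats <- roi_stats(do.call(rbind, ev_rows))
      res[[r$name]] <- list(roi = roi, evidence = do.call(rbind, ev_rows),
                            tests = stats$tests)
    }
    all_tests <- do.call(rbind, lapply(names(res), function(nm)
      cbind(roi = nm, res[[nm]]$tests)))
    write.table(all_tests, file.path(out_dir, "roi_stats.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
    res
  })

  report <- list(hash = hash, out_dir = out_dir, seed = config$seed,
                 group = list(dof = group$dof,
                              contrasts = rownames(group$t_map)),
                 clusters = clusters,
                 rois = lapply(roi_results, function(r)
                   list(center_vox = r$roi$center_vox, tests = r$tests)),
                 config = unclass(config))
  jsonlite::write_json(report, file.path(out_dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       force = TRUE)
  structure(c(report, list(roi_results = roi_results, group_fit = group,
                           subject_maps = subj_maps, mask = mask,
                           affine = affine)),
            class = "fl_report")
}
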