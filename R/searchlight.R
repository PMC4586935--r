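#' Build a searchlight sphere index
#'
#' For every in-mask voxel (each one is a sphere center), lists the in-mask
#' voxels whose center-to-center world distance is at most `radius_mm`
#' (inclusive; the center voxel is always a member). Distances use the
#' affine's voxel sizes, so anisotropic grids are handled; spheres are
#' truncated at the mask border rather than zero-padded. With 3.5 mm voxels
#' and a 7 mm (two-voxel) radius an interior sphere has 33 members.
#'
#' @param mask 3D logical array.
#' @param radius_mm Sphere radius in mm.
#' @param affine 4x4 voxel-to-world affine; default diagonal with
#'   `voxel_size_mm`.
#' @param voxel_size_mm Isotropic voxel size used when `affine` is NULL.
#' @return A list of class `fl_spheres`: `membership` (per center, integer
#'   indices into the in-mask voxel ordering), `centers` (grid coordinates),
#'   `sizes`, `mask`, `affine`, `radius_mm`.
#' @export
build_spheres <- function(mask, radius_mm = 7, affine = NULL,
                          voxel_size_mm = 3.5) {
  if (length(dim(mask)) != 3L) stop("mask must be a 3D logical array")
  if (is.null(affine)) affine <- diag(c(rep(voxel_size_mm, 3), 1))
  vs <- sqrt(colSums(affine[1:3, 1:3]^2))
  if (radius_mm < min(vs)) stop("radius must be at least one voxel size")
  dims <- dim(mask)
  lin <- which(mask)
  if (!length(lin)) stop("empty mask")
  vox_of_lin <- integer(prod(dims)); vox_of_lin[lin] <- seq_along(lin)
  coords <- arrayInd(lin, dims)

  rng <- floor(radius_mm / vs)
  off <- as.matrix(expand.grid(dx = -rng[1]:rng[1], dy = -rng[2]:rng[2],
                               dz = -rng[3]:rng[3]))
  keep <- (off[, 1] * vs[1])^2 + (off[, 2] * vs[2])^2 + (off[, 3] * vs[3])^2 <=
    radius_mm^2 + 1e-9
  off <- off[keep, , drop = FALSE]

  center_idx <- integer(0); member_idx <- integer(0)
  for (k in seq_len(nrow(off))) {
    cand <- coords + matrix(off[k, ], nrow(coords), 3, byrow = TRUE)
    ok <- cand[, 1] >= 1 & cand[, 1] <= dims[1] &
      cand[, 2] >= 1 & cand[, 2] <= dims[2] &
      cand[, 3] >= 1 & cand[, 3] <= dims[3]
    cl <- cand[ok, 1] + (cand[ok, 2] - 1L) * dims[1] +
      (cand[ok, 3] - 1L) * dims[1] * dims[2]
    mv <- vox_of_lin[cl]
    inmask <- mv > 0
    center_idx <- c(center_idx, which(ok)[inmask])
    member_idx <- c(member_idx, mv[inmask])
  }
  membership <- split(member_idx, center_idx)
  membership <- membership[order(as.integer(names(membership)))]
  names(membership) <- NULL
  stopifnot(length(membership) == length(lin))
  structure(list(membership = membership, centers = coords,
                 sizes = lengths(membership), mask = mask, affine = affine,
                 radius_mm = radius_mm),
            class = "fl_spheres")
}

#' @export
print.fl_spheres <- function(x, ...) {
  cat(sprintf("<fl_spheres> %d centers, radius %.1f mm, mean size %.1f voxels\n",
              length(x$membership), x$radius_mm, mean(x$sizes)))
  invisible(x)
}

#' Run a scoring operation over all searchlight spheres
#'
#' Applies `scoring` to the datasets restricted to each sphere's voxels.
#' Centers are processed independently (no state is shared), so results are
#' identical regardless of processing order.
#'
#' @param datasets A single [pattern_dataset()] or a named list of them
#'   (e.g. `list(visual = ..., somaesthetic = ...)`); all must live on the
#'   index's grid.
#' @param index An `fl_spheres` index.
#' @param scoring Function taking the restricted dataset (or list) and
#'   returning a numeric scalar or named vector of measures.
#' @return `[center x measure]` matrix of scores.
#' @export
run_searchlight <- function(datasets, index, scoring) {
  single <- inherits(datasets, "fl_patterns")
  dlist <- if (single) list(datasets) else datasets
  nv <- length(index$sizes) # centers == in-mask voxels
  for (d in dlist)
    if (n_voxels(d) != sum(index$mask))
      stop("dataset voxel grid does not match the sphere index mask")
  out <- NULL
  for (ci in seq_along(index$membership)) {
    members <- index$membership[[ci]]
    sub <- lapply(dlist, subset_voxels, voxels = members)
    s <- scoring(if (single) sub[[1]] else sub)
    if (is.null(out))
      out <- matrix(NA_real_, nv, length(s),
                    dimnames = list(NULL, names(s)))
    out[ci, ] <- s
  }
  out
}

#' Average sphere scores back onto voxels
#'
#' The value at a voxel is the mean score of all spheres that *contain* it
#' (not the score of the sphere centered on it). Because every in-mask voxel
#' is itself a center, every voxel is contained in at least one sphere.
#'
#' @param scores `[center x measure]` matrix (or per-center vector) from
#'   [run_searchlight()].
#' @param index The `fl_spheres` index used to compute the scores.
#' @return A list of class `fl_map`: `values` `[voxel x measure]`, `counts`
#'   (spheres containing each voxel), `mask`, `affine`.
#' @export
voxelwise_average <- function(scores, index) {
  if (is.vector(scores)) scores <- matrix(scores, ncol = 1)
  nv <- length(index$membership)
  if (nrow(scores) != nv) stop("one score row per sphere center is required")
  sums <- matrix(0, nv, ncol(scores))
  counts <- integer(nv)
  for (ci in seq_len(nv)) {
    m <- index$membership[[ci]]
    sums[m, ] <- sums[m, ] + matrix(scores[ci, ], length(m), ncol(scores),
                                    byrow = TRUE)
    counts[m] <- counts[m] + 1L
  }
  stopifnot(all(counts > 0))
  structure(list(values = sums / counts, counts = counts,
                 measures = colnames(scores), mask = index$mask,
                 affine = index$affine),
            class = "fl_map")
}

#' Expand an evidence map measure to a 3D volume
#'
#' @param map An `fl_map` (or a per-voxel vector plus `mask`).
#' @param measure Column index or name (default first).
#' @param mask Mask when `map` is a bare vector.
#' @return 3D array with `NA` outside the mask.
#' @export
as_volume <- function(map, measure = 1L, mask = NULL) {
  if (inherits(map, "fl_map")) {
    v <- map$values[, measure]
    mask <- map$mask
  } else v <- map
  if (is.null(mask)) stop("mask required")
  vol <- array(NA_real_, dim(mask))
  vol[mask] <- v
  vol
}

#' Standard searchlight measures for the reference-frame pipeline
#'
#' Returns a scoring function for [run_searchlight()] computing, per sphere
#' and per modality, the frame aggregates and their contrast, plus the
#' independent-pair score (mean classification accuracy of the outer- and
#' center-sides pairs) used for ROI definition.
#'
#' @param pairs Condition pairs.
#' @param zscore,xmode Decoding options (see [evidence_table()]).
#' @param detail `"aggregates"` for the summary measures only, `"full"` to
#'   also emit every pair's `a` and `o` (columns `a_<pair>_<modality>`,
#'   `o_<pair>_<modality>`), as needed by the full-crossing group GLM.
#' @return Function mapping `list(visual =, somaesthetic =)` to a named
#'   vector of measures.
#' @export
searchlight_measures <- function(pairs = NULL, zscore = "all_patterns",
                                 xmode = "replacement",
                                 detail = c("aggregates", "full")) {
  detail <- match.arg(detail)
  if (is.null(pairs)) pairs <- enumerate_pairs(make_configurations())
  indep <- pairs$pair[pairs$independent]
  function(dsl) {
    out <- c()
    for (mod in names(dsl)) {
      tbl <- evidence_table(dsl[[mod]], pairs, zscore = zscore, xmode = xmode)
      agg <- aggregate_evidence(tbl)
      out <- c(out, setNames(c(agg$aggregate_gc, agg$aggregate_bc, agg$contrast,
                               mean(tbl[indep, "a"])),
                             paste0(c("aggregate_gc_", "aggregate_bc_",
                                      "contrast_", "independent_"), mod)))
      if (detail == "full")
        out <- c(out,
                 setNames(tbl$a, paste0("a_", tbl$pair, "_", mod)),
                 setNames(tbl$o, paste0("o_", tbl$pair, "_", mod)))
    }
    out
  }
}
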