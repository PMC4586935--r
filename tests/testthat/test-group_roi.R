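make_obs <- function(n_sub = 18) {
  expand.grid(test = c("classification", "cross_classification"),
              pair = PAIR_NAMES,
              modality = c("visual", "somaesthetic"),
              subject = sprintf("s%02d", seq_len(n_sub)),
              stringsAsFactors = FALSE)
}

test_that("the full-scale group design has 432 observations, 42 regressors, dof 391", {
  obs <- make_obs(18)
  gd <- build_group_design(obs)
  expect_equal(nrow(gd$X), 432L)
  expect_equal(ncol(gd$X), 42L)
  set.seed(27)
  ev <- matrix(rnorm(432 * 3, 0.5, 0.05), 432)
  fit <- group_glm(ev, gd, group_contrast(gd, list(pair = "outer_sides",
                                                   test = "classification")))
  expect_equal(fit$dof, 391L)
  # incomplete crossing is refused
  expect_error(build_group_design(obs[-1, ]), "full")
})

test_that("a paired-difference group contrast equals the closed-form paired t-test", {
  obs <- make_obs(5)
  set.seed(28)
  ev <- matrix(rnorm(nrow(obs) * 2, 0.5, 0.1), nrow(obs))
  gd <- build_group_design(obs)
  cvec <- group_contrast(gd,
                         list(pair = "left_wrt_gaze", test = "classification",
                              modality = "visual"),
                         against = list(pair = "left_wrt_gaze",
                                        test = "classification",
                                        modality = "somaesthetic"))
  fit <- group_glm(ev, gd, cvec)
  # oracle: within-subject difference of the two cells, one-sample t
  pick <- function(mod) obs$pair == "left_wrt_gaze" &
    obs$test == "classification" & obs$modality == mod
  for (v in 1:2) {
    d <- ev[pick("visual"), v][order(obs$subject[pick("visual")])] -
      ev[pick("somaesthetic"), v][order(obs$subject[pick("somaesthetic")])]
    # same estimate; the GLM pools its error over all cells, so only the
    # effect estimate is identical by construction — compare it
    est <- drop(cvec %*% fit$fit$betas[, v])
    expect_equal(est, mean(d), tolerance = 1e-10)
  }
})

test_that("a single-condition group GLM reduces to the one-sample t-test", {
  # one observation per subject, one condition regressor: the group GLM t
  # must equal the one-sample t on the (chance-centred) subject values
  n_sub <- 8
  set.seed(29)
  y <- matrix(rnorm(n_sub, 0.6, 0.1), n_sub)
  fit <- fit_glm(y - 0.5, matrix(1, n_sub), 1)
  tt <- t.test(y - 0.5)
  expect_equal(drop(fit$t_map), unname(tt$statistic), tolerance = 1e-10)
  expect_equal(fit$dof, n_sub - 1)
})

test_that("degenerate zero-variance voxels are flagged, not silently propagated", {
  obs <- make_obs(4)
  ev <- matrix(0.5, nrow(obs), 2)
  ev[, 2] <- rnorm(nrow(obs), 0.5, 0.1)
  gd <- build_group_design(obs)
  fit <- group_glm(ev, gd, group_contrast(gd, list(test = "classification")))
  expect_equal(fit$degenerate_voxels, 1L)
})

test_that("cluster extent thresholding is strict and connectivity-aware", {
  # two components: exactly 250 voxels and 251 voxels, clearly suprathreshold
  vol <- array(0, c(60, 12, 2))
  vol[1:25, 1:10, 1] <- 10          # 250 voxels
  vol[30:54, 1:10, 1] <- 10         # 250 voxels ...
  vol[30, 11, 1] <- 10              # ... plus one 26-connected neighbour = 251
  res <- cluster_threshold(vol, dof = 391, alpha = 0.05,
                           min_cluster_voxels = 250)
  expect_equal(nrow(res$clusters), 1L)
  expect_equal(res$clusters$size, 251L)
  expect_equal(sum(res$map), 251L)
  # under 6-connectivity the appended voxel no longer connects diagonally
  vol2 <- array(0, c(60, 12, 2))
  vol2[30:54, 1:10, 1] <- 10
  vol2[29, 11, 1] <- 10             # diagonal neighbour of the box corner
  r26 <- cluster_threshold(vol2, 391, min_cluster_voxels = 250, connectivity = 26)
  r6 <- cluster_threshold(vol2, 391, min_cluster_voxels = 250, connectivity = 6)
  expect_equal(r26$clusters$size, 251L)
  expect_equal(nrow(r6$clusters), 0L)
  # nothing suprathreshold: empty map and table
  res0 <- cluster_threshold(array(0, c(4, 4, 4)), 391, min_cluster_voxels = 0)
  expect_equal(nrow(res0$clusters), 0L)
  expect_false(any(res0$map))
  expect_error(cluster_threshold(vol, 391, alpha = 1.2), "alpha")
})

test_that("component labeling agrees with a recursive flood-fill oracle", {
  flood_oracle <- function(binary) {
    dims <- dim(binary)
    lab <- array(0L, dims); cur <- 0L
    off <- as.matrix(expand.grid(-1:1, -1:1, -1:1))
    off <- off[rowSums(abs(off)) > 0, ]
    for (v in which(binary)) {
      if (lab[v]) next
      cur <- cur + 1L; stack <- v
      while (length(stack)) {
        x <- stack[length(stack)]; stack <- stack[-length(stack)]
        if (lab[x]) next
        lab[x] <- cur
        xc <- arrayInd(x, dims)
        for (k in seq_len(nrow(off))) {
          nb <- xc + off[k, ]
          if (all(nb >= 1) && all(nb <= dims)) {
            nl <- nb[1] + (nb[2] - 1) * dims[1] + (nb[3] - 1) * dims[1] * dims[2]
            if (binary[nl] && !lab[nl]) stack <- c(stack, nl)
          }
        }
      }
    }
    lab
  }
  set.seed(31)
  for (i in 1:15) {
    b <- array(runif(10 * 9 * 8) > 0.7, c(10, 9, 8))
    lab <- framelight:::label_components(b, 26)
    orc <- flood_oracle(b)
    expect_equal(max(lab), max(orc))
    # same partition up to label permutation
    expect_equal(length(unique(paste(lab[b], orc[b]))), max(lab))
    sz <- sort(tabulate(lab[b]))
    expect_equal(sz, sort(tabulate(orc[b])))
  }
})

test_that("ROI definition picks the local maximum nearest the reference", {
  dims <- c(12, 12, 12)
  mask <- array(TRUE, dims)
  aff <- diag(c(3.5, 3.5, 3.5, 1))
  aff[1:3, 4] <- c(-50, -60, 30)     # MNI-ish origin
  tmap <- array(0, dims)
  # two peaks; the reference sits nearer the second
  tmap[3, 3, 3] <- 5
  tmap[9, 8, 8] <- 4
  ref <- drop(aff %*% c(c(9, 8, 8) - 1 + 0.4, 1))[1:3]
  roi <- define_roi(tmap, ref, mask, aff, radius_mm = 7, name = "aIPS")
  expect_equal(unname(roi$center_vox), c(9, 8, 8))
  expect_equal(unname(roi$center_mm), drop(aff %*% c(8, 7, 7, 1))[1:3])
  # the 7-mm sphere holds the 33-voxel neighbourhood
  expect_length(roi$voxels, 33L)
  # single smooth peak: exact recovery
  tm2 <- array(0, dims)
  d2 <- as.matrix(expand.grid(1:12, 1:12, 1:12))
  tm2[] <- -colSums((t(d2) - c(5, 6, 7))^2)
  roi2 <- define_roi(tm2, c(0, 0, 0), mask, aff, name = "peak")
  expect_equal(unname(roi2$center_vox), c(5, 6, 7))
  # two equidistant peaks: deterministic lexicographic tie-break
  tm3 <- array(0, dims)
  tm3[4, 6, 6] <- 5; tm3[8, 6, 6] <- 5
  ref3 <- drop(aff %*% c(c(6, 6, 6) - 1, 1))[1:3]
  roi3 <- define_roi(tm3, ref3, mask, aff, name = "tie")
  expect_equal(unname(roi3$center_vox), c(4, 6, 6))
  expect_error(define_roi(array(1, dims), c(0, 0, 0), mask, aff), "no local maximum")
})

test_that("ROI statistics detect the planted battery of effects", {
  set.seed(32)
  n <- 12
  mk <- function(gc_v, bc_v, gc_s, bc_s, sdev = 0.03) {
    rbind(data.frame(subject = sprintf("s%d", 1:n), modality = "visual",
                     aggregate_gc = rnorm(n, gc_v, sdev),
                     aggregate_bc = rnorm(n, bc_v, sdev)),
          data.frame(subject = sprintf("s%d", 1:n), modality = "somaesthetic",
                     aggregate_gc = rnorm(n, gc_s, sdev),
                     aggregate_bc = rnorm(n, bc_s, sdev)))
  }
  # switching region: GC dominates visually, BC somaesthetically
  st <- roi_stats(mk(0.9, 0.5, 0.5, 0.9))$tests
  get_p <- function(st, nm) st$p[st$test == nm]
  expect_lt(get_p(st, "gc_bc_by_modality_interaction"), 0.05)
  expect_lt(get_p(st, "gc_vs_chance_visual"), 0.05)
  # shared gaze-centered region: no interaction
  st2 <- roi_stats(mk(0.9, 0.5, 0.9, 0.5))$tests
  expect_gt(get_p(st2, "gc_bc_by_modality_interaction"), 0.05)
  expect_lt(get_p(st2, "gc_vs_bc_visual"), 0.05)
  # identical modalities: all modality-difference tests are null
  one <- data.frame(subject = sprintf("s%d", 1:n),
                    aggregate_gc = rnorm(n, 0.7, 0.05),
                    aggregate_bc = rnorm(n, 0.6, 0.05))
  same <- rbind(cbind(one, modality = "visual"),
                cbind(one, modality = "somaesthetic"))
  st3 <- roi_stats(same)$tests
  expect_equal(get_p(st3, "gc_vis_vs_som"), 1)
  expect_equal(get_p(st3, "gc_bc_by_modality_interaction"), 1)
  expect_error(roi_stats(same[same$subject %in% c("s1", "s2"), ]),
               "at least 3 subjects")
})

test_that("group-level pair scores drive conjunction and gaze-direction calls", {
  set.seed(33)
  n <- 10
  ps <- expand.grid(subject = sprintf("s%d", 1:n), modality = "visual",
                    pair = PAIR_NAMES, stringsAsFactors = FALSE)
  # gaze-direction-like cohort: high a on main pairs, high o only on center
  ps$a <- rnorm(nrow(ps), ifelse(ps$pair %in% MAIN_PAIRS, 0.95, 0.9), 0.03)
  ps$o <- rnorm(nrow(ps), ifelse(ps$pair == "center_sides", 0.95, 0.4), 0.03)
  ev <- data.frame(subject = rep(sprintf("s%d", 1:n), 2),
                   modality = rep(c("visual", "somaesthetic"), each = n),
                   aggregate_gc = rnorm(2 * n, 0.7, 0.03),
                   aggregate_bc = rnorm(2 * n, 0.7, 0.03))
  st <- roi_stats(ev, pair_scores = ps)
  expect_true(st$gazedir$visual)
  expect_false(st$conjunction$visual$conj_gc)
  expect_false(st$conjunction$visual$conj_bc)
})
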