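test_that("the compiled SVM solver matches the pure-R reference", {
  set.seed(13)
  for (i in 1:5) {
    n <- sample(6:16, 1); p <- sample(c(2, 10, 40), 1)
    X <- matrix(rnorm(n * p), n)
    y <- sample(c(-1, 1), n, replace = TRUE)
    if (length(unique(y)) < 2) y[1] <- -y[1]
    fc <- linsvm_fit(X, y)
    fr <- framelight:::linsvm_fit_r(X, y)
    expect_equal(fc$w, fr$w, tolerance = 1e-10)
    expect_equal(fc$b, fr$b, tolerance = 1e-10)
  }
  expect_error(linsvm_fit(matrix(1:4, 2), c(1, 2)), "labels")
})

test_that("the SVM separates well-separated clusters and ties score half", {
  set.seed(14)
  X <- rbind(matrix(rnorm(14, 10), 7, 2), matrix(rnorm(14, -10), 7, 2))
  y <- rep(c(1, -1), each = 7)
  fit <- linsvm_fit(X, y)
  expect_true(all(linsvm_decision(fit, X) * y > 0))
  expect_equal(framelight:::svm_credit(0, 1), 0.5)
})

test_that("z-scoring standardizes per voxel and handles degenerate voxels", {
  ds <- tiny_dataset(n_runs = 8)
  ds$values[, , 3] <- 7  # constant voxel
  z <- zscore_patterns(ds, "all_patterns")
  m <- matrix(z$values, ncol = dim(z$values)[3])
  expect_equal(colMeans(m), rep(0, ncol(m)), tolerance = 1e-12)
  expect_equal(apply(m[, -3], 2, sd), rep(1, ncol(m) - 1), tolerance = 1e-12)
  expect_equal(attr(z, "zero_variance_voxels"), 3L)
  expect_true(all(m[, 3] == 0))
  # train-only moments differ from all-pattern moments on held-out runs
  zt <- zscore_patterns(ds, "train_only", train_runs = 1:7)
  expect_false(isTRUE(all.equal(zt$values[8, , 1], z$values[8, , 1])))
  expect_error(zscore_patterns(ds, "train_only"), "train_runs")
})

test_that("leave-one-run-out bookkeeping matches the paradigm arithmetic", {
  ds <- tiny_dataset(n_runs = 8)
  trained <- train_pair_classifiers(ds, canonical_pairs)
  expect_length(trained$folds, 8L)
  expect_equal(trained$n_train_patterns, 14L)  # 7 runs x 2 configurations
  res <- classify_pair(ds, "left_wrt_body", trained = trained)
  expect_length(res$fold_acc, 8L)
  expect_equal(res$a, mean(res$fold_acc))
  expect_error(train_pair_classifiers(
    pattern_dataset(ds$values[1, , , drop = FALSE], "visual")), "2 runs")
})

test_that("classification is invariant to swapping the pair's class labels", {
  ds <- tiny_dataset(n_runs = 6, seed = 15)
  pairs_swapped <- canonical_pairs
  pairs_swapped[, c("member_1", "member_2")] <-
    pairs_swapped[, c("member_2", "member_1")]
  a1 <- evidence_table(ds, canonical_pairs)$a
  a2 <- evidence_table(ds, pairs_swapped)$a
  expect_equal(a1, a2, tolerance = 1e-10)
})

test_that("permuting labels within runs drives accuracy to chance", {
  ds <- tiny_dataset(n_runs = 6, n_voxels = 10, snr = 8, seed = 16)
  i <- match(c("GL-TL", "GC-TL"), ds$config_labels)
  set.seed(16)
  a_perm <- replicate(400, {
    perm <- ds
    for (r in 1:6) if (runif(1) < 0.5)
      perm$values[r, i, ] <- perm$values[r, rev(i), ]
    classify_pair(perm, "left_wrt_body", zscore = "none")$a
  })
  expect_lt(abs(mean(a_perm) - 0.5), 0.02)
})

test_that("cross-classification routes replacements to the pair they describe", {
  ds <- tiny_dataset(n_runs = 4)
  xc <- cross_classify(ds, scoring_mode = "replacement")
  routes <- xc$routes
  # the worked example: train left w.r.t. body, replace GC-TL by GR-TR,
  # evidence goes to left w.r.t. gaze
  ex <- routes[routes$classifier == "left_wrt_body" &
                 routes$replaced == "GC-TL" & routes$replacement == "GR-TR", ]
  expect_true(nrow(ex) > 0)
  expect_true(all(ex$receiving == "left_wrt_gaze"))
  # each classifier feeds exactly 4 receiving pairs; each receiving pair
  # aggregates exactly 4 routed scores per fold
  per_clf <- tapply(routes$receiving, routes$classifier,
                    function(x) length(unique(x)))
  expect_true(all(per_clf == 4))
  per_recv <- table(routes$receiving, routes$fold)
  expect_true(all(per_recv == 4))
  # a receiving pair never receives evidence from a classifier trained on it
  expect_true(all(routes$receiving != routes$classifier))
})

test_that("replacement-only scores from one classifier are exactly complementary", {
  ds <- tiny_dataset(n_runs = 5, seed = 17)
  routes <- cross_classify(ds, scoring_mode = "replacement")$routes
  # for classifier {A,B} and non-trained C: C is assigned to exactly one of
  # the two classes, so score(A->C) + score(B->C) = 1 (fold by fold)
  for (clf in unique(routes$classifier)) {
    rc <- routes[routes$classifier == clf, ]
    for (f in unique(rc$fold)) for (repl in unique(rc$replacement)) {
      s <- rc$score[rc$fold == f & rc$replacement == repl]
      expect_length(s, 2L)
      expect_equal(sum(s), 1)
    }
  }
})

test_that("pair-mode scoring also credits the retained configuration", {
  ds <- tiny_dataset(n_runs = 4, seed = 18)
  trained <- train_pair_classifiers(ds, canonical_pairs)
  o_rep <- cross_classify(trained = trained, scoring_mode = "replacement")$o
  o_pair <- cross_classify(trained = trained, scoring_mode = "pair")$o
  # with strong gaze-centered signal the retained pattern is almost always
  # classified correctly, pulling pair-mode scores toward (x + 1) / 2
  expect_true(all(o_pair >= o_rep - 1e-9))
  expect_error(cross_classify(trained = trained, scoring_mode = "both"))
})

test_that("evidence tables carry both scores for every pair in [0, 1]", {
  ds <- tiny_dataset(n_runs = 6, seed = 19)
  tbl <- evidence_table(ds, canonical_pairs)
  expect_setequal(tbl$pair, PAIR_NAMES)
  expect_true(all(tbl$a >= 0 & tbl$a <= 1 & tbl$o >= 0 & tbl$o <= 1))
  expect_true(all(tbl$n_folds == 6L))
  expect_equal(dim(attr(tbl, "fold_a")), c(6L, 6L))
  expect_equal(dim(attr(tbl, "fold_o")), c(6L, 6L))
  path <- tempfile(fileext = ".tsv")
  write_evidence_tsv(tbl, path)
  expect_equal(read.table(path, header = TRUE, sep = "\t")$a, tbl$a)
})

test_that("distinct and common evidence are anticorrelated on the same pair", {
  # gaze-centered truth: gaze pairs cross-classify near 1 but classify near
  # chance; body pairs the opposite
  res <- sapply(1:8, function(s) {
    sim <- simulate_patterns(simulation_spec("gaze_centered", snr = 5, seed = s))
    tbl <- evidence_table(sim$visual, canonical_pairs)
    c(o_gaze = mean(tbl[GAZE_PAIRS, "o"]), a_gaze = mean(tbl[GAZE_PAIRS, "a"]),
      a_body = mean(tbl[BODY_PAIRS, "a"]))
  })
  expect_gt(mean(res["o_gaze", ]), 0.9)
  expect_lt(mean(res["a_gaze", ]), 0.6)
  expect_gt(mean(res["a_body", ]), 0.9)
})

test_that("cross-modal transfer dissociates shared from independent codes", {
  within_a <- function(sim) mean(evidence_table(sim$visual,
                                                canonical_pairs)[BODY_PAIRS, "a"])
  cross_a <- function(sim) mean(cross_modal_evidence(sim$visual,
                                                     sim$somaesthetic,
                                                     canonical_pairs)[BODY_PAIRS, "a"])
  sh <- sapply(1:5, function(s) {
    sim <- simulate_patterns(simulation_spec("gaze_centered", snr = 5,
                                             modality_model = "shared", seed = s))
    c(w = within_a(sim), x = cross_a(sim))
  })
  expect_lt(mean(abs(sh["w", ] - sh["x", ])), 0.1)
  ind <- sapply(1:5, function(s) {
    sim <- simulate_patterns(simulation_spec("gaze_centered", snr = 5,
                                             modality_model = "independent",
                                             seed = s))
    c(w = within_a(sim), x = cross_a(sim))
  })
  expect_gt(mean(ind["w", ]), 0.9)
  expect_lt(abs(mean(ind["x", ]) - 0.5), 0.1)
})

test_that("identical modalities make cross-modal accuracy a resubstitution test", {
  ds <- tiny_dataset(n_runs = 4, seed = 20)
  tbl <- cross_modal_evidence(ds, ds, canonical_pairs)
  # oracle: train on all runs and test on the same patterns directly
  z <- zscore_patterns(ds, "all_patterns")$values
  for (i in seq_len(nrow(canonical_pairs))) {
    ai <- match(canonical_pairs$member_1[i], ds$config_labels)
    bi <- match(canonical_pairs$member_2[i], ds$config_labels)
    X <- rbind(matrix(z[, ai, ], 4), matrix(z[, bi, ], 4))
    y <- rep(c(1, -1), each = 4)
    fit <- linsvm_fit(X, y)
    resub <- mean(framelight:::svm_credit(linsvm_decision(fit, X), y))
    expect_equal(tbl$a[i], resub, tolerance = 1e-10)
  }
  expect_error(cross_modal_evidence(ds, tiny_dataset(n_voxels = 5)),
               "voxel count")
})
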