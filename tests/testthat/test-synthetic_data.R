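test_that("simulation specs validate their fields", {
  expect_error(simulation_spec(snr = -1), "nonnegative")
  expect_error(simulation_spec(n_voxels = 0), "positive")
  expect_error(simulation_spec(mix_weight = 1.5), "mix_weight")
  expect_s3_class(simulation_spec("null", snr = 0), "fl_simspec")
})

test_that("fixed seeds give bit-identical datasets", {
  s1 <- simulate_patterns(simulation_spec("mixed", seed = 7))
  s2 <- simulate_patterns(simulation_spec("mixed", seed = 7))
  expect_identical(s1$visual$values, s2$visual$values)
  expect_identical(s1$somaesthetic$values, s2$somaesthetic$values)
})

test_that("coding schemes put the signal where the hypothesis says", {
  # gaze-centered: GC-TL and GR-TR share the left-of-gaze prototype
  sim <- simulate_patterns(simulation_spec("gaze_centered", snr = 10,
                                           n_voxels = 80, seed = 3))
  mpat <- apply(sim$visual$values, c(2, 3), mean)
  rownames(mpat) <- sim$visual$config_labels
  expect_gt(cor(mpat["GC-TL", ], mpat["GR-TR", ]), 0.9)
  expect_gt(cor(mpat["GL-TL", ], mpat["GC-TR", ]), 0.9)
  expect_lt(cor(mpat["GC-TL", ], mpat["GL-TL", ]), 0.5)
  # body-centered: GL-TL and GC-TL share the left-of-body prototype
  sim <- simulate_patterns(simulation_spec("body_centered", snr = 10,
                                           n_voxels = 80, seed = 3))
  mpat <- apply(sim$visual$values, c(2, 3), mean)
  rownames(mpat) <- sim$visual$config_labels
  expect_gt(cor(mpat["GL-TL", ], mpat["GC-TL", ]), 0.9)
  # gaze-direction: the two center-gaze configurations share a prototype
  sim <- simulate_patterns(simulation_spec("gaze_direction", snr = 10,
                                           n_voxels = 80, seed = 3))
  mpat <- apply(sim$visual$values, c(2, 3), mean)
  rownames(mpat) <- sim$visual$config_labels
  expect_gt(cor(mpat["GC-TL", ], mpat["GC-TR", ]), 0.9)
  expect_lt(abs(cor(mpat["GL-TL", ], mpat["GR-TR", ])), 0.5)
})

test_that("modality models share, redraw or swap the prototypes", {
  mean_pat <- function(ds) {
    m <- apply(ds$values, c(2, 3), mean)
    rownames(m) <- ds$config_labels
    m
  }
  shared <- simulate_patterns(simulation_spec("gaze_centered", snr = 10,
                                              modality_model = "shared",
                                              n_voxels = 80, seed = 5))
  expect_gt(cor(mean_pat(shared$visual)["GC-TL", ],
                mean_pat(shared$somaesthetic)["GC-TL", ]), 0.9)
  indep <- simulate_patterns(simulation_spec("gaze_centered", snr = 10,
                                             modality_model = "independent",
                                             n_voxels = 80, seed = 5))
  expect_lt(abs(cor(mean_pat(indep$visual)["GC-TL", ],
                    mean_pat(indep$somaesthetic)["GC-TL", ])), 0.5)
  # switching: visual gaze-centered, somaesthetic body-centered
  sw <- simulate_patterns(simulation_spec(modality_model = "switching",
                                          snr = 10, n_voxels = 80, seed = 5))
  expect_gt(cor(mean_pat(sw$visual)["GC-TL", ],
                mean_pat(sw$visual)["GR-TR", ]), 0.9)
  expect_gt(cor(mean_pat(sw$somaesthetic)["GL-TL", ],
                mean_pat(sw$somaesthetic)["GC-TL", ]), 0.9)
})

test_that("snr = 0 yields label-independent data (chance decoding)", {
  a <- replicate(10, {
    sim <- simulate_patterns(simulation_spec("gaze_centered", snr = 0,
                                             seed = sample.int(1e6, 1)))
    mean(evidence_table(sim$visual, canonical_pairs)$a)
  })
  expect_lt(abs(mean(a) - 0.5), 0.1)
})

test_that("schedules are balanced, counterbalanced and correctly timed", {
  sched <- simulate_schedule(16, 22, seed = 11)
  # full-scale arithmetic: 88 trials per configuration overall
  expect_equal(as.vector(table(sched$trial_type)), rep(88L, 4))
  expect_true(all(sched$delay >= 3 & sched$delay <= 6))
  # runs start after 20 s fixation; ends include 10 s fixation
  first <- sched[!duplicated(sched$run), ]
  expect_true(all(first$onset == 20))
  durs <- attr(sched, "run_duration_s")
  last <- sched[rev(!duplicated(rev(sched$run))), ]
  expect_equal(durs,
               unname(last$go_onset + last$movement_duration + 1.5 + 10))
  # greedy first-order counterbalancing: all 16 transition types occur and
  # counts stay nearly uniform
  trans <- table(head(sched$trial_type, -1), tail(sched$trial_type, -1))
  expect_true(all(trans > 0))
  expect_lte(max(trans) - min(trans), 5)
})

test_that("minimal schedules and invalid delays behave", {
  s <- simulate_schedule(1, 4, seed = 1)
  expect_equal(sort(s$trial_type), sort(CONFIG_LABELS))
  expect_error(simulate_schedule(2, 8, delay_range_s = c(6, 3)), "inverted")
  path <- tempfile(fileext = ".tsv")
  write_events_tsv(s, path)
  ev <- read.table(path, header = TRUE, sep = "\t")
  expect_named(ev, c("onset", "duration", "trial_type", "run"))
  expect_equal(ev$duration, s$delay)
})

test_that("simulated BOLD is deterministic and linear in the amplitudes", {
  sched <- simulate_schedule(1, 8, seed = 2)
  betas <- matrix(rnorm(4 * 3), 4)
  y1 <- simulate_bold(sched, betas, noise_sd = 0, seed = 9)
  y2 <- simulate_bold(sched, betas, noise_sd = 0, seed = 9)
  expect_identical(y1, y2)
  y3 <- simulate_bold(sched, 2 * betas, noise_sd = 0, seed = 9)
  expect_equal(y3, 2 * y1, tolerance = 1e-12)
  expect_error(simulate_bold(sched, betas[1:3, , drop = FALSE], 0), "4 rows")
})

test_that("volumetric simulation places regions and rejects overlap", {
  grid <- c(6, 6, 4)
  reg <- list(list(bbox = rbind(c(1, 2), c(1, 2), c(1, 2)),
                   spec = simulation_spec("gaze_centered", snr = 10)),
              list(bbox = rbind(c(4, 6), c(4, 6), c(3, 4)),
                   spec = simulation_spec("body_centered", snr = 10)))
  vols <- simulate_volume(grid, reg, n_runs_per_modality = 4, seed = 21)
  expect_equal(dim(vols$visual$values), c(4L, 4L, prod(grid)))
  regions <- attr(vols, "regions")
  expect_length(regions, 2L)
  # in-region voxels carry the scheme's structure, background does not
  mpat <- apply(vols$visual$values, c(2, 3), mean)
  gc_cor <- cor(mpat[2, regions[[1]]], mpat[4, regions[[1]]])  # GC-TL vs GR-TR
  expect_gt(gc_cor, 0.8)
  bg <- setdiff(seq_len(prod(grid)), unlist(regions))
  expect_lt(abs(cor(mpat[2, bg], mpat[4, bg])), 0.4)
  # overlapping regions are refused
  reg_bad <- list(reg[[1]], list(bbox = rbind(c(2, 3), c(2, 3), c(2, 3)),
                                 spec = simulation_spec("null")))
  expect_error(simulate_volume(grid, reg_bad, seed = 1), "overlaps")
  expect_error(simulate_volume(grid, list(list(bbox = rbind(c(0, 2), c(1, 2), c(1, 2)),
                                               spec = simulation_spec("null"))),
                               seed = 1), "outside the grid")
})
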