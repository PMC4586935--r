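# shared fixtures, all built in code

canonical_configs <- make_configurations()
canonical_pairs <- enumerate_pairs(canonical_configs)

MAIN_PAIRS <- c("left_wrt_gaze", "right_wrt_gaze", "left_wrt_body", "right_wrt_body")
GAZE_PAIRS <- c("left_wrt_gaze", "right_wrt_gaze")
BODY_PAIRS <- c("left_wrt_body", "right_wrt_body")

# a tiny deterministic dataset with distinguishable structure for routing /
# bookkeeping tests: strong configuration-specific prototypes
tiny_dataset <- function(n_runs = 4, n_voxels = 12, snr = 8, seed = 42,
                         scheme = "gaze_centered") {
  simulate_patterns(simulation_spec(scheme, n_voxels = n_voxels,
                                    n_runs_per_modality = n_runs,
                                    snr = snr, seed = seed))$visual
}

# hand-built evidence table for arithmetic tests
manual_evidence <- function(a, o) {
  tbl <- data.frame(pair = canonical_pairs$pair, a = a, o = o, n_folds = 8L,
                    modality_context = "visual", stringsAsFactors = FALSE)
  rownames(tbl) <- tbl$pair
  class(tbl) <- c("fl_evidence", "data.frame")
  tbl
}

manual_flags <- function(sig_a, sig_o) {
  out <- data.frame(pair = canonical_pairs$pair, sig_a = sig_a, sig_o = sig_o)
  rownames(out) <- out$pair
  out
}
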