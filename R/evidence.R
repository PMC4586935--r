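#' Aggregate evidence per reference frame
#'
#' Each frame's aggregate is the mean of the four scores its hypothesis
#' predicts to be high: for gaze-centered coding the cross-classification
#' scores of the left/right-w.r.t.-gaze pairs (predicted common) and the
#' classification scores of the left/right-w.r.t.-body pairs (predicted
#' distinct); for body-centered coding the mirror image. Both aggregates mix
#' exactly two classification and two cross-classification scores, so any
#' systematic offset between the two measure types — including a pure
#' gaze-direction effect, which inflates classification on all four main
#' pairs equally — cancels in the contrast `aggregate_gc - aggregate_bc`.
#'
#' @param table An `fl_evidence` table ([evidence_table()]).
#' @return List with `aggregate_gc`, `aggregate_bc` and `contrast`
#'   (`aggregate_gc - aggregate_bc`).
#' @export
aggregate_evidence <- function(table) {
  need <- c("left_wrt_gaze", "right_wrt_gaze", "left_wrt_body", "right_wrt_body")
  if (!all(need %in% table$pair))
    stop("missing pair(s): ", paste(setdiff(need, table$pair), collapse = ", "))
  a <- setNames(table$a, table$pair)
  o <- setNames(table$o, table$pair)
  agg_gc <- mean(c(o["left_wrt_gaze"], o["right_wrt_gaze"],
                   a["left_wrt_body"], a["right_wrt_body"]))
  agg_bc <- mean(c(a["left_wrt_gaze"], a["right_wrt_gaze"],
                   o["left_wrt_body"], o["right_wrt_body"]))
  list(aggregate_gc = agg_gc, aggregate_bc = agg_bc,
       contrast = agg_gc - agg_bc)
}

# one-tailed p-value for accuracy scores above chance; degenerate SD handled
# deterministically (constant above chance -> 0, otherwise 1)
acc_ttest_p <- function(scores, chance = 0.5) {
  scores <- scores[is.finite(scores)]
  if (length(scores) < 2 || stats::sd(scores) < 1e-12)
    return(if (mean(scores) > chance) 0 else 1)
  stats::t.test(scores, mu = chance, alternative = "greater")$p.value
}

#' Per-pair significance flags from fold scores
#'
#' Single-dataset significance: a one-tailed t-test of the per-fold scores
#' against chance (0.5) for both the classification and cross-classification
#' score of every pair. At group level, use the group module's t-maps
#' instead.
#'
#' @param table An `fl_evidence` table with fold attributes.
#' @param alpha Per-flag significance level (default 0.05).
#' @return A data.frame (rownames = pair) with `sig_a`, `sig_o`, `p_a`,
#'   `p_o`.
#' @export
significance_flags <- function(table, alpha = 0.05) {
  fold_a <- attr(table, "fold_a"); fold_o <- attr(table, "fold_o")
  if (is.null(fold_a) || is.null(fold_o))
    stop("table lacks per-fold scores; build it with evidence_table()")
  p_a <- apply(fold_a, 2, acc_ttest_p)
  p_o <- apply(fold_o, 2, acc_ttest_p)
  out <- data.frame(pair = table$pair, sig_a = p_a < alpha, sig_o = p_o < alpha,
                    p_a = p_a, p_o = p_o, stringsAsFactors = FALSE)
  rownames(out) <- out$pair
  out
}

#' Conjunction of two-sided evidence per reference frame
#'
#' A frame is flagged only when both sides of its prediction hold: for
#' gaze-centered coding, significant cross-classification on at least one
#' gaze-frame pair AND significant classification on at least one body-frame
#' pair; for body-centered coding the mirror. Both flags may be true
#' (evidence for both frames). Unlike the aggregate, the conjunction is
#' immune to pure gaze-direction coding, which never produces the required
#' cross-classification.
#'
#' @param flags Data.frame from [significance_flags()] (or any data.frame
#'   with rownames per pair and logical `sig_a`, `sig_o`).
#' @return List with logicals `conj_gc` and `conj_bc`.
#' @export
conjunction <- function(flags) {
  need <- c("left_wrt_gaze", "right_wrt_gaze", "left_wrt_body", "right_wrt_body")
  if (!all(need %in% rownames(flags)))
    stop("missing flags for pair(s): ",
         paste(setdiff(need, rownames(flags)), collapse = ", "))
  s_a <- setNames(flags$sig_a, rownames(flags))
  s_o <- setNames(flags$sig_o, rownames(flags))
  list(conj_gc = (s_o["left_wrt_gaze"] || s_o["right_wrt_gaze"]) &&
         (s_a["left_wrt_body"] || s_a["right_wrt_body"]),
       conj_bc = (s_a["left_wrt_gaze"] || s_a["right_wrt_gaze"]) &&
         (s_o["left_wrt_body"] || s_o["right_wrt_body"]))
}

#' Gaze-direction control test
#'
#' True only when classification is significant on all four main pairs
#' (every main pair differs in gaze position) AND cross-classification is
#' significant on the center-sides pair — the only pair predicted common
#' under gaze-direction coding but distinct under either reference frame.
#'
#' @param flags Data.frame from [significance_flags()].
#' @return Logical.
#' @export
gaze_direction_test <- function(flags) {
  main <- c("left_wrt_gaze", "right_wrt_gaze", "left_wrt_body", "right_wrt_body")
  if (!all(c(main, "center_sides") %in% rownames(flags)))
    stop("flags must cover the four main pairs and center_sides")
  all(flags[main, "sig_a"]) && flags["center_sides", "sig_o"]
}

#' Full frame-evidence summary for one dataset
#'
#' Convenience wrapper: aggregates, contrast, conjunction flags and the
#' gaze-direction control, from one evidence table.
#'
#' @param table An `fl_evidence` table.
#' @param alpha Significance level for the single-dataset flags.
#' @return A list of class `fl_frame_evidence`.
#' @export
frame_evidence <- function(table, alpha = 0.05) {
  agg <- aggregate_evidence(table)
  flags <- significance_flags(table, alpha)
  conj <- conjunction(flags)
  structure(c(agg, conj, list(gazedir = gaze_direction_test(flags),
                              flags = flags, alpha = alpha)),
            class = "fl_frame_evidence")
}

#' @export
print.fl_frame_evidence <- function(x, ...) {
  cat(sprintf("<fl_frame_evidence> GC %.3f  BC %.3f  contrast %+.3f | conj GC=%s BC=%s | gaze-direction=%s\n",
              x$aggregate_gc, x$aggregate_bc, x$contrast,
              x$conj_gc, x$conj_bc, x$gazedir))
  invisible(x)
}
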