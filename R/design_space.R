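#' Canonical configuration labels
#'
#' The four tested gaze/target configurations in canonical order:
#' gaze left-target left, gaze center-target left, gaze center-target right,
#' gaze right-target right.
#'
#' @format Character vector of length 4.
#' @export
CONFIG_LABELS <- c("GL-TL", "GC-TL", "GC-TR", "GR-TR")

#' Canonical condition-pair names
#'
#' @format Character vector of length 6.
#' @export
PAIR_NAMES <- c("left_wrt_gaze", "right_wrt_gaze",
                "left_wrt_body", "right_wrt_body",
                "outer_sides", "center_sides")

#' Build the tested trial configurations
#'
#' Crosses three gaze fixation angles with two lateral target positions and
#' keeps only the combinations actually tested: for each gaze position, the
#' target(s) closest in angle to the gaze line. With the default geometry
#' (gaze at -11/0/+11 degrees, targets at -5/+5 degrees) this yields the four
#' canonical configurations; the two combinations with the target further
#' separated from the gaze line (gaze left-target right, gaze right-target
#' left) are excluded.
#'
#' Each configuration carries its target side in both reference frames:
#' `target_side_body` is the sign of the target offset from the body midline,
#' `target_side_gaze` the sign of target angle minus gaze angle. The latter is
#' always derived from the angles, never set independently.
#'
#' @param gaze_angles_deg Three strictly increasing gaze angles (degrees of
#'   visual angle), interpreted as left, center, right.
#' @param target_offsets_deg Two target angles, one negative (left of body
#'   midline) and one positive (right).
#' @return A data.frame of class `fl_configurations` with one row per tested
#'   configuration (columns `label`, `gaze_label`, `gaze_angle_deg`,
#'   `target_offset_deg`, `target_side_body`, `target_side_gaze`), ordered
#'   canonically.
#' @examples
#' make_configurations()
#' @export
make_configurations <- function(gaze_angles_deg = c(-11, 0, 11),
                                target_offsets_deg = c(-5, 5)) {
  if (length(gaze_angles_deg) != 3L || is.unsorted(gaze_angles_deg, strictly = TRUE))
    stop("gaze_angles_deg must be three strictly increasing angles (left < center < right)")
  if (length(target_offsets_deg) != 2L)
    stop("target_offsets_deg must have length 2")
  target_offsets_deg <- sort(target_offsets_deg)
  if (!(target_offsets_deg[1] < 0 && target_offsets_deg[2] > 0))
    stop("target_offsets_deg must contain one negative and one positive offset")
  if (any(outer(target_offsets_deg, gaze_angles_deg, "-") == 0))
    stop("degenerate geometry: a target angle equals a gaze angle, ",
         "so its side with respect to gaze is undefined")

  gaze_labels <- c("L", "C", "R")
  rows <- list()
  for (g in seq_along(gaze_angles_deg)) {
    d <- abs(target_offsets_deg - gaze_angles_deg[g])
    keep <- which(d == min(d))          # drop targets further from the gaze line
    for (t in keep) {
      body_side <- if (target_offsets_deg[t] < 0) "left" else "right"
      gaze_side <- if (target_offsets_deg[t] - gaze_angles_deg[g] < 0) "left" else "right"
      rows[[length(rows) + 1L]] <- data.frame(
        label = sprintf("G%s-T%s", gaze_labels[g],
                        if (body_side == "left") "L" else "R"),
        gaze_label = gaze_labels[g],
        gaze_angle_deg = gaze_angles_deg[g],
        target_offset_deg = target_offsets_deg[t],
        target_side_body = body_side,
        target_side_gaze = gaze_side,
        stringsAsFactors = FALSE)
    }
  }
  configs <- do.call(rbind, rows)
  if (nrow(configs) != 4L || !setequal(configs$label, CONFIG_LABELS))
    stop("geometry does not yield the four tested configurations; got: ",
         paste(configs$label, collapse = ", "))
  configs <- configs[match(CONFIG_LABELS, configs$label), , drop = FALSE]
  rownames(configs) <- NULL
  class(configs) <- c("fl_configurations", "data.frame")
  configs
}

#' Enumerate the six condition pairs with per-hypothesis predictions
#'
#' The four configurations define the six unordered pairs (all C(4,2)
#' combinations). Four "main" pairs group configurations by target side in one
#' frame: `left/right_wrt_gaze` share the gaze-frame side (predicted common
#' under gaze-centered coding, distinct under body-centered), and
#' `left/right_wrt_body` the body-frame side (the mirror image). The two
#' "independent" pairs, `outer_sides` and `center_sides`, are distinct under
#' both frames and carry no frame-specific prediction (`independent = TRUE`);
#' they are used for ROI definition. `center_sides` is the only pair whose
#' members share a gaze position, hence the only pair predicted common under
#' pure gaze-direction coding.
#'
#' @param configs Result of [make_configurations()].
#' @return A data.frame of class `fl_pairs` with columns `pair`, `member_1`,
#'   `member_2`, `pred_gc`, `pred_bc`, `pred_gazedir`, `independent`.
#' @examples
#' enumerate_pairs(make_configurations())
#' @export
enumerate_pairs <- function(configs) {
  if (!inherits(configs, "fl_configurations"))
    configs <- make_configurations_from_df(configs)
  if (nrow(configs) != 4L || anyDuplicated(configs$label))
    stop("exactly four distinct configurations are required")

  members_by <- function(col, side) configs$label[configs[[col]] == side]
  pair_row <- function(name, members, gc, bc, independent = FALSE) {
    stopifnot(length(members) == 2L)
    members <- members[order(match(members, configs$label))]
    same_gaze <- configs$gaze_label[match(members[1], configs$label)] ==
      configs$gaze_label[match(members[2], configs$label)]
    data.frame(pair = name, member_1 = members[1], member_2 = members[2],
               pred_gc = gc, pred_bc = bc,
               pred_gazedir = if (same_gaze) "common" else "distinct",
               independent = independent, stringsAsFactors = FALSE)
  }

  pairs <- rbind(
    pair_row("left_wrt_gaze",  members_by("target_side_gaze", "left"),
             gc = "common", bc = "distinct"),
    pair_row("right_wrt_gaze", members_by("target_side_gaze", "right"),
             gc = "common", bc = "distinct"),
    pair_row("left_wrt_body",  members_by("target_side_body", "left"),
             gc = "distinct", bc = "common"),
    pair_row("right_wrt_body", members_by("target_side_body", "right"),
             gc = "distinct", bc = "common"),
    pair_row("outer_sides",
             configs$label[configs$gaze_label %in% c("L", "R")],
             gc = "distinct", bc = "distinct", independent = TRUE),
    pair_row("center_sides", configs$label[configs$gaze_label == "C"],
             gc = "distinct", bc = "distinct", independent = TRUE))

  keys <- apply(pairs[, c("member_1", "member_2")], 1L,
                function(m) paste(sort(m), collapse = "|"))
  all_keys <- apply(utils::combn(configs$label, 2L), 2L,
                    function(m) paste(sort(m), collapse = "|"))
  if (anyDuplicated(keys) || !setequal(keys, all_keys))
    stop("pair enumeration failed to partition the C(4,2) combinations")
  rownames(pairs) <- pairs$pair
  class(pairs) <- c("fl_pairs", "data.frame")
  pairs
}

# coerce a plain data.frame of configurations (validated minimally)
make_configurations_from_df <- function(df) {
  need <- c("label", "gaze_label", "target_side_body", "target_side_gaze")
  if (!all(need %in% names(df)))
    stop("configurations must have columns: ", paste(need, collapse = ", "))
  class(df) <- c("fl_configurations", "data.frame")
  df
}

#' Look up a pair's two member configurations
#'
#' Membership is unordered: the pair containing configurations A and B is
#' found whichever order they are given in.
#'
#' @param pairs Result of [enumerate_pairs()].
#' @param members Character vector of two configuration labels, or a single
#'   pair name.
#' @return The matching row of `pairs`.
#' @export
find_pair <- function(pairs, members) {
  if (length(members) == 1L) {
    row <- pairs[pairs$pair == members, , drop = FALSE]
  } else {
    key <- paste(sort(members), collapse = "|")
    keys <- apply(pairs[, c("member_1", "member_2")], 1L,
                  function(m) paste(sort(m), collapse = "|"))
    row <- pairs[keys == key, , drop = FALSE]
  }
  if (nrow(row) != 1L) stop("no unique pair matching: ", paste(members, collapse = ", "))
  row
}

#' Write the pair table as TSV
#'
#' Columns: pair, member_1, member_2, pred_gc, pred_bc, pred_gazedir.
#'
#' @param pairs Result of [enumerate_pairs()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_pair_table <- function(pairs, path) {
  write.table(pairs[, c("pair", "member_1", "member_2",
                        "pred_gc", "pred_bc", "pred_gazedir")],
              path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
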