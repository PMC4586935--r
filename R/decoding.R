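#' Z-score patterns per voxel
#'
#' Standardizes every voxel to mean 0 and SD 1 over a scoping set of
#' patterns. `"all_patterns"` uses all runs-by-configurations patterns of the
#' dataset (the literal reading of z-scoring t-values per voxel before
#' classification); `"train_only"` computes the moments on the training runs
#' only and applies them to every pattern, avoiding any statistical leakage
#' from held-out runs. Voxels with zero variance over the scoping set are set
#' to zero and flagged in the `"zero_variance_voxels"` attribute.
#'
#' @param dataset An [pattern_dataset()].
#' @param scope `"all_patterns"` or `"train_only"`.
#' @param train_runs Run indices defining the moments when
#'   `scope = "train_only"`.
#' @return The z-scored dataset.
#' @export
zscore_patterns <- function(dataset, scope = c("all_patterns", "train_only"),
                            train_runs = NULL) {
  scope <- match.arg(scope)
  vals <- dataset$values
  d <- dim(vals)
  if (d[1] * d[2] < 2) stop("need at least 2 patterns per voxel")
  src <- if (scope == "train_only") {
    if (is.null(train_runs)) stop("train_runs required for train_only scope")
    vals[train_runs, , , drop = FALSE]
  } else vals
  m <- matrix(src, ncol = d[3])            # [pattern x voxel]
  mu <- colMeans(m)
  sdv <- sqrt(colMeans(m * m) - mu^2) * sqrt(nrow(m) / (nrow(m) - 1))
  flagged <- which(sdv < 1e-12)
  sdv[flagged] <- 1
  out <- sweep(sweep(vals, 3, mu, "-"), 3, sdv, "/")
  dataset$values <- out
  attr(dataset, "zero_variance_voxels") <- flagged
  dataset
}

# internal: train the six per-pair classifiers for one leave-one-run-out fold
fold_classifiers <- function(vals, pairs_idx, test_run) {
  R <- dim(vals)[1]
  train_runs <- setdiff(seq_len(R), test_run)
  lapply(seq_len(nrow(pairs_idx)), function(i) {
    a <- pairs_idx[i, 1]; b <- pairs_idx[i, 2]
    X <- rbind(matrix(vals[train_runs, a, ], length(train_runs)),
               matrix(vals[train_runs, b, ], length(train_runs)))
    y <- rep(c(1, -1), each = length(train_runs))
    linsvm_fit(X, y)
  })
}

#' Train the six pair classifiers per leave-one-run-out fold
#'
#' One binary linear SVM per condition pair per fold, trained on all runs but
#' one (14 patterns with 8 runs). The returned object feeds both
#' [classify_pair()] and [cross_classify()], guaranteeing that distinct- and
#' common-evidence scores use the very same classifiers.
#'
#' @param dataset An [pattern_dataset()].
#' @param pairs Condition pairs ([enumerate_pairs()]).
#' @param zscore Z-scoring scope: `"all_patterns"`, `"train_only"` or
#'   `"none"`.
#' @return A list of class `fl_trained` with per-fold classifiers and the
#'   z-scored values each fold must be tested on.
#' @export
train_pair_classifiers <- function(dataset, pairs = NULL,
                                   zscore = c("all_patterns", "train_only", "none")) {
  zscore <- match.arg(zscore)
  if (is.null(pairs)) pairs <- enumerate_pairs(make_configurations())
  R <- n_runs(dataset)
  if (R < 2) stop("at least 2 runs are required for leave-one-run-out folds")
  labels <- dataset$config_labels
  pairs_idx <- cbind(match(pairs$member_1, labels), match(pairs$member_2, labels))
  if (anyNA(pairs_idx)) stop("pair members missing from the dataset")
  shared_vals <- if (zscore == "all_patterns")
    zscore_patterns(dataset, "all_patterns")$values else dataset$values
  folds <- lapply(seq_len(R), function(r) {
    vals <- if (zscore == "train_only")
      zscore_patterns(dataset, "train_only",
                      train_runs = setdiff(seq_len(R), r))$values
    else shared_vals
    list(test_run = r, values = vals,
         clf = fold_classifiers(vals, pairs_idx, r))
  })
  structure(list(folds = folds, pairs = pairs, pairs_idx = pairs_idx,
                 zscore = zscore, n_runs = R, labels = labels,
                 n_train_patterns = 2L * (R - 1L)),
            class = "fl_trained")
}

#' Classification score (a) for one condition pair
#'
#' Leave-one-run-out accuracy of the pair's binary linear SVM: per fold the
#' classifier trained on the other runs is tested on the held-out run's two
#' member patterns; `a` is the mean accuracy across folds. Evidence that the
#' two representations are distinct.
#'
#' @param dataset An [pattern_dataset()] (ignored when `trained` is given).
#' @param pair A pair name or a row of the pair table.
#' @param trained Optional [train_pair_classifiers()] result to reuse.
#' @param zscore Z-scoring scope.
#' @return List with `a` (mean accuracy), `fold_acc` (per fold) and `pair`.
#' @export
classify_pair <- function(dataset, pair, trained = NULL,
                          zscore = "all_patterns") {
  if (is.null(trained)) trained <- train_pair_classifiers(dataset, zscore = zscore)
  name <- if (is.character(pair)) pair else pair$pair
  i <- match(name, trained$pairs$pair)
  if (is.na(i)) stop("unknown pair: ", name)
  a <- pairs_fold_accuracy(trained)
  list(pair = name, fold_acc = a[, i], a = mean(a[, i]))
}

# [fold x pair] classification accuracies from trained classifiers
pairs_fold_accuracy <- function(trained) {
  R <- trained$n_runs
  np <- nrow(trained$pairs_idx)
  acc <- matrix(0, R, np)
  for (r in seq_len(R)) {
    f <- trained$folds[[r]]
    for (i in seq_len(np)) {
      a <- trained$pairs_idx[i, 1]; b <- trained$pairs_idx[i, 2]
      X <- rbind(f$values[r, a, ], f$values[r, b, ])
      dec <- linsvm_decision(f$clf[[i]], X)
      acc[r, i] <- mean(svm_credit(dec, c(1, -1)))
    }
  }
  colnames(acc) <- trained$pairs$pair
  acc
}

#' Cross-classification scores (o) via replacement routing
#'
#' For the classifier trained on pair `{A, B}`, one trained configuration is
#' replaced by one of the two non-trained configurations (`A -> C`,
#' `A -> D`, `B -> C`, `B -> D`). The held-out run's pattern of the
#' replacement is scored correct when the classifier assigns it the replaced
#' configuration's class; the resulting score is ascribed to the *receiving*
#' pair `{replaced, replacement}`. Every trained classifier thus feeds four
#' receiving pairs, and every receiving pair aggregates exactly four routed
#' scores per fold; `o` is their mean over folds. High `o` is evidence that
#' the replaced and replacement configurations share a representation.
#'
#' `scoring_mode = "replacement"` (default) scores only the replacement
#' pattern. `"pair"` additionally scores the retained configuration's
#' held-out pattern against its own class and averages the two, mimicking a
#' test on the full substituted pair.
#'
#' @param dataset An [pattern_dataset()] (ignored when `trained` is given).
#' @param trained Optional [train_pair_classifiers()] result to reuse.
#' @param scoring_mode `"replacement"` or `"pair"`.
#' @param zscore Z-scoring scope (when training here).
#' @param keep_routes Keep the per-route bookkeeping table? (Disable inside
#'   tight searchlight loops.)
#' @return List with `o` (named per receiving pair), `fold_o`
#'   `[fold x pair]`, and `routes` (one row per routed score, or NULL).
#' @export
cross_classify <- function(dataset = NULL, trained = NULL,
                           scoring_mode = c("replacement", "pair"),
                           zscore = "all_patterns", keep_routes = TRUE) {
  scoring_mode <- match.arg(scoring_mode)
  if (is.null(trained)) trained <- train_pair_classifiers(dataset, zscore = zscore)
  pairs <- trained$pairs
  np <- nrow(pairs); R <- trained$n_runs
  pair_key <- function(m) paste(sort(m), collapse = "|")
  keys <- apply(pairs[, c("member_1", "member_2")], 1L, pair_key)
  labels <- trained$labels
  fold_sum <- matrix(0, R, np); fold_n <- matrix(0L, R, np)
  routes <- list()
  for (r in seq_len(R)) {
    f <- trained$folds[[r]]
    for (i in seq_len(np)) {
      ai <- trained$pairs_idx[i, 1]; bi <- trained$pairs_idx[i, 2]
      others <- setdiff(seq_along(labels), c(ai, bi))
      for (rep_from in c(ai, bi)) {
        retained <- if (rep_from == ai) bi else ai
        y_rep <- if (rep_from == ai) 1 else -1
        for (rep_to in others) {
          dec <- linsvm_decision(f$clf[[i]], f$values[r, rep_to, ])
          score <- svm_credit(dec, y_rep)
          if (scoring_mode == "pair") {
            dec2 <- linsvm_decision(f$clf[[i]], f$values[r, retained, ])
            score <- mean(c(score, svm_credit(dec2, -y_rep)))
          }
          recv <- match(pair_key(labels[c(rep_from, rep_to)]), keys)
          fold_sum[r, recv] <- fold_sum[r, recv] + score
          fold_n[r, recv] <- fold_n[r, recv] + 1L
          if (keep_routes)
            routes[[length(routes) + 1L]] <-
              data.frame(fold = r, classifier = pairs$pair[i],
                         replaced = labels[rep_from], replacement = labels[rep_to],
                         receiving = pairs$pair[recv], score = score,
                         stringsAsFactors = FALSE)
        }
      }
    }
  }
  stopifnot(all(fold_n == 4L))
  fold_o <- fold_sum / fold_n
  colnames(fold_o) <- pairs$pair
  list(o = colMeans(fold_o), fold_o = fold_o,
       routes = if (keep_routes) do.call(rbind, routes) else NULL)
}

#' Full within-modality evidence table
#'
#' Computes, from one set of leave-one-run-out classifiers, the
#' classification score `a` and the replacement-routed cross-classification
#' score `o` for every condition pair.
#'
#' @param dataset An [pattern_dataset()].
#' @param pairs Condition pairs (default canonical six).
#' @param zscore Z-scoring scope.
#' @param xmode Cross-classification scoring mode (see [cross_classify()]).
#' @return A data.frame of class `fl_evidence` (columns `pair`, `a`, `o`,
#'   `n_folds`, `modality_context`) with per-fold score matrices in
#'   attributes `fold_a` and `fold_o`.
#' @export
evidence_table <- function(dataset, pairs = NULL,
                           zscore = c("all_patterns", "train_only", "none"),
                           xmode = c("replacement", "pair")) {
  zscore <- match.arg(zscore)
  xmode <- match.arg(xmode)
  trained <- train_pair_classifiers(dataset, pairs, zscore)
  fold_a <- pairs_fold_accuracy(trained)
  xc <- cross_classify(trained = trained, scoring_mode = xmode,
                       keep_routes = FALSE)
  tbl <- data.frame(pair = trained$pairs$pair, a = colMeans(fold_a),
                    o = xc$o, n_folds = trained$n_runs,
                    modality_context = dataset$modality,
                    stringsAsFactors = FALSE)
  rownames(tbl) <- tbl$pair
  attr(tbl, "fold_a") <- fold_a
  attr(tbl, "fold_o") <- xc$fold_o
  class(tbl) <- c("fl_evidence", "data.frame")
  tbl
}

#' Cross-modal evidence table
#'
#' Tests whether the spatial code is shared across sensory modalities:
#' classifiers are trained on all runs of one modality and tested on all runs
#' of the other, in both directions, and the two directions are averaged.
#' Z-scoring is performed within each modality separately. Routing of
#' cross-classification evidence works exactly as within modality; the
#' "fold" dimension of the result indexes the two transfer directions.
#'
#' @param dataset_vis,dataset_som The two modality datasets (matched voxels).
#' @param pairs Condition pairs.
#' @param zscore `"all_patterns"` (per modality) or `"none"`.
#' @param xmode Cross-classification scoring mode.
#' @return An `fl_evidence` data.frame with `modality_context =
#'   "cross_modal"` and `n_folds = 2`.
#' @export
cross_modal_evidence <- function(dataset_vis, dataset_som, pairs = NULL,
                                 zscore = c("all_patterns", "none"),
                                 xmode = c("replacement", "pair")) {
  zscore <- match.arg(zscore)
  xmode <- match.arg(xmode)
  if (n_voxels(dataset_vis) != n_voxels(dataset_som))
    stop("voxel count mismatch between modalities")
  if (is.null(pairs)) pairs <- enumerate_pairs(make_configurations())
  labels <- dataset_vis$config_labels
  pairs_idx <- cbind(match(pairs$member_1, labels), match(pairs$member_2, labels))
  zs <- function(ds) if (zscore == "none") ds$values
                     else zscore_patterns(ds, "all_patterns")$values
  v_vis <- zs(dataset_vis); v_som <- zs(dataset_som)
  np <- nrow(pairs)
  pair_key <- function(m) paste(sort(m), collapse = "|")
  keys <- apply(pairs[, c("member_1", "member_2")], 1L, pair_key)

  one_direction <- function(tr_vals, te_vals) {
    Rtr <- dim(tr_vals)[1]; Rte <- dim(te_vals)[1]
    a <- numeric(np); o_sum <- numeric(np); o_n <- integer(np)
    for (i in seq_len(np)) {
      ai <- pairs_idx[i, 1]; bi <- pairs_idx[i, 2]
      X <- rbind(matrix(tr_vals[, ai, ], Rtr), matrix(tr_vals[, bi, ], Rtr))
      fit <- linsvm_fit(X, rep(c(1, -1), each = Rtr))
      Xte <- rbind(matrix(te_vals[, ai, ], Rte), matrix(te_vals[, bi, ], Rte))
      a[i] <- mean(svm_credit(linsvm_decision(fit, Xte),
                              rep(c(1, -1), each = Rte)))
      others <- setdiff(seq_along(labels), c(ai, bi))
      for (rep_from in c(ai, bi)) {
        retained <- if (rep_from == ai) bi else ai
        y_rep <- if (rep_from == ai) 1 else -1
        for (rep_to in others) {
          dec <- linsvm_decision(fit, matrix(te_vals[, rep_to, ], Rte))
          score <- mean(svm_credit(dec, y_rep))
          if (xmode == "pair") {
            dec2 <- linsvm_decision(fit, matrix(te_vals[, retained, ], Rte))
            score <- mean(c(score, mean(svm_credit(dec2, -y_rep))))
          }
          recv <- match(pair_key(labels[c(rep_from, rep_to)]), keys)
          o_sum[recv] <- o_sum[recv] + score
          o_n[recv] <- o_n[recv] + 1L
        }
      }
    }
    stopifnot(all(o_n == 4L))
    list(a = a, o = o_sum / o_n)
  }
  d1 <- one_direction(v_vis, v_som)
  d2 <- one_direction(v_som, v_vis)
  tbl <- data.frame(pair = pairs$pair, a = (d1$a + d2$a) / 2,
                    o = (d1$o + d2$o) / 2, n_folds = 2L,
                    modality_context = "cross_modal", stringsAsFactors = FALSE)
  rownames(tbl) <- tbl$pair
  attr(tbl, "fold_a") <- rbind(d1$a, d2$a)
  attr(tbl, "fold_o") <- rbind(d1$o, d2$o)
  class(tbl) <- c("fl_evidence", "data.frame")
  tbl
}

#' Write an evidence table as TSV
#'
#' @param table An `fl_evidence` data.frame.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_evidence_tsv <- function(table, path) {
  write.table(as.data.frame(table), path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(path)
}
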