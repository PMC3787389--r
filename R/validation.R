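# Cross-validated ROC evaluation of the screening pipeline.

#' Receptor eligibility for cross-validation
#'
#' A receptor qualifies when its training panel contains at least one very
#' strongly activating odor (> `very_strong` spikes/s) and at least
#' `n_strong` strongly activating odors (> `strong` spikes/s; the very
#' strong odor counts among them), so every test fold can be backed by at
#' least one training active.
#'
#' @param activity odor-by-receptor response matrix.
#' @param receptor receptor id.
#' @param very_strong spikes/s cutoff for the very strong activator
#'   (default 150, strict `>`).
#' @param strong spikes/s cutoff for strong activators (default 100,
#'   strict `>`).
#' @param n_strong minimum number of strong activators (default 5).
#' @return logical.
#' @export
check_eligibility <- function(activity, receptor, very_strong = 150,
                              strong = 100, n_strong = 5) {
  a <- receptor_responses(activity, receptor)
  sum(a > very_strong) >= 1 && sum(a > strong) >= n_strong
}

#' ROC points by standard step construction
#'
#' Scores are sorted decreasing; compounds sharing a score move together,
#' giving one ROC vertex per distinct score. The curve runs from (0, 0) to
#' (1, 1) and is invariant under any monotone transform of the scores.
#'
#' @param scores numeric vector (higher = more positive).
#' @param labels logical vector of true positives.
#' @return data.frame with columns `fpr`, `tpr`.
#' @export
roc_points <- function(scores, labels) {
  stopifnot(length(scores) == length(labels))
  if (!any(labels) || all(labels)) {
    stop("ROC needs both positive and negative labels", call. = FALSE)
  }
  ord <- order(scores, decreasing = TRUE)
  s <- scores[ord]; l <- labels[ord]
  last <- cumsum(rle(s)$lengths)  # threshold steps: ties move together
  tp <- cumsum(l)[last]
  fp <- cumsum(!l)[last]
  data.frame(fpr = c(0, fp / sum(!l)), tpr = c(0, tp / sum(l)))
}

#' Trapezoidal area under a ROC curve
#'
#' @param roc data.frame from [roc_points()].
#' @return scalar AUC in \[0, 1\].
#' @export
roc_auc <- function(roc) {
  sum(diff(roc$fpr) * (roc$tpr[-1] + roc$tpr[-nrow(roc)]) / 2)
}

# interpolated TPR at fixed FPR values (vertical averaging support);
# vertical ROC segments collapse to their upper point
roc_at <- function(roc, fpr_grid) {
  tpr_max <- tapply(roc$tpr, roc$fpr, max)
  fpr <- as.numeric(names(tpr_max))
  stats::approx(fpr, as.numeric(tpr_max), xout = fpr_grid, rule = 2)$y
}

#' Cross-validated ROC analysis of ligand prediction
#'
#' Runs independent repeated k-fold cross-validations of the whole
#' pipeline. Within each trial the compounds are randomly partitioned into
#' `folds` near-equal folds (sizes differing by at most one); for every
#' fold the descriptor table is re-normalized on the training split only,
#' actives are re-classified and the descriptor multiset re-selected on the
#' training split only, and each withheld compound is scored by its
#' weighted distance to the nearest training active. Scores are pooled
#' across folds and receptors within a trial and a ROC curve is computed
#' with score = negative distance, positive labels being membership in the
#' receptor's full-data active set (a fixed ground truth independent of the
#' training procedure). The mean ROC curve averages the trial curves
#' vertically on a fixed 101-point false-positive-rate grid.
#'
#' @param activity odor-by-receptor response matrix.
#' @param descriptors raw compound-by-descriptor matrix.
#' @param receptors receptor ids to pool; all must pass
#'   [check_eligibility()].
#' @param trials number of independent cross-validations (default 5).
#' @param folds folds per trial (default 5).
#' @param seed integer seed governing all fold assignments.
#' @param strong_cutoff activator cutoff in spikes/s for active
#'   classification (default 50).
#' @param max_iter per-fold cap on descriptor selections (default
#'   unlimited).
#' @return object of class `or_cv`: list with `trials`, `folds`, `seed`,
#'   `pooled` (per-trial score/label data frames), `roc` (per-trial ROC
#'   point sets), `auc` (per-trial AUCs), `mean_auc`, `mean_roc`
#'   (101-point averaged curve) and `skipped` (receptor-folds without
#'   training actives).
#' @export
crossvalidate <- function(activity, descriptors, receptors, trials = 5,
                          folds = 5, seed, strong_cutoff = 50,
                          max_iter = Inf) {
  check_activity_table(activity)
  check_descriptor_table(descriptors)
  if (missing(seed)) stop("a seed is required for reproducible folds", call. = FALSE)
  descriptors <- descriptors[rownames(activity), , drop = FALSE]
  for (r in receptors) {
    if (!check_eligibility(activity, r)) {
      stop("receptor not eligible for cross-validation: ", r, call. = FALSE)
    }
  }
  truth <- lapply(stats::setNames(receptors, receptors), function(r) {
    classify_actives(activity, r, strong_cutoff = strong_cutoff)$members
  })

  n <- nrow(activity)
  ids <- rownames(activity)
  sizes <- rep(n %/% folds, folds)
  if (n %% folds > 0) sizes[seq_len(n %% folds)] <- sizes[seq_len(n %% folds)] + 1

  old_seed <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, globalenv()))
  set.seed(seed)

  skipped <- character(0)
  pooled <- vector("list", trials)
  for (t in seq_len(trials)) {
    assignment <- sample(rep(seq_len(folds), times = sizes))
    rows <- list()
    for (f in seq_len(folds)) {
      test_ids <- ids[assignment == f]
      train_ids <- ids[assignment != f]
      train_norm <- normalize_descriptors(descriptors[train_ids, , drop = FALSE])
      test_norm <- project_library(descriptors[test_ids, , drop = FALSE], train_norm)
      for (r in receptors) {
        fold_act <- tryCatch(
          classify_actives(activity[train_ids, , drop = FALSE], r,
                           strong_cutoff = strong_cutoff),
          no_actives_error = function(e) NULL)
        if (is.null(fold_act) || length(fold_act$members) == 0) {
          warning(sprintf("trial %d fold %d: no training actives for %s; skipped",
                          t, f, r), call. = FALSE)
          skipped <- c(skipped, sprintf("trial%d/fold%d/%s", t, f, r))
          next
        }
        trace <- sfs_select(train_norm, activity[train_ids, , drop = FALSE], r,
                            actives = fold_act, max_iter = max_iter)
        pred <- rank_library(test_norm, fold_act, train_norm, trace$multiset)
        rows[[length(rows) + 1]] <- data.frame(
          receptor = r, id = pred$id, score = -pred$distance,
          label = pred$id %in% truth[[r]], stringsAsFactors = FALSE)
      }
    }
    if (length(rows) == 0) stop("all receptor-folds skipped", call. = FALSE)
    pooled[[t]] <- do.call(rbind, rows)
  }

  roc <- lapply(pooled, function(p) roc_points(p$score, p$label))
  auc <- vapply(roc, roc_auc, numeric(1))
  grid <- seq(0, 1, length.out = 101)
  tpr_mat <- vapply(roc, roc_at, numeric(101), fpr_grid = grid)
  structure(list(trials = trials, folds = folds, seed = seed,
                 pooled = pooled, roc = roc, auc = auc,
                 mean_auc = mean(auc),
                 mean_roc = data.frame(fpr = grid, tpr = rowMeans(tpr_mat)),
                 skipped = skipped),
            class = "or_cv")
}

#' @export
print.or_cv <- function(x, ...) {
  cat(sprintf("%d x %d-fold cross-validation (seed %d)\n", x$trials, x$folds, x$seed))
  cat("per-trial AUC:", paste(sprintf("%.3f", x$auc), collapse = ", "), "\n")
  cat(sprintf("mean AUC: %.3f\n", x$mean_auc))
  if (length(x$skipped) > 0) cat(sprintf("skipped receptor-folds: %d\n", length(x$skipped)))
  invisible(x)
}

#' @export
plot.or_cv <- function(x, ...) {
  graphics::plot(x$mean_roc$fpr, x$mean_roc$tpr, type = "l", lwd = 2,
                 xlab = "false positive rate", ylab = "true positive rate",
                 main = sprintf("mean ROC (AUC %.3f)", x$mean_auc), ...)
  for (r in x$roc) graphics::lines(r$fpr, r$tpr, col = "grey70")
  graphics::lines(x$mean_roc$fpr, x$mean_roc$tpr, lwd = 2)
  graphics::abline(0, 1, lty = 3)
  invisible(x)
}
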