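# Central model object: a receptor-optimized descriptor model fitted from
# an activity panel and a raw descriptor table.

#' Fit a receptor-optimized descriptor model
#'
#' End-to-end fit for one receptor: normalizes the raw training descriptor
#' table (z-scores, zero-variance descriptors dropped), classifies the
#' receptor's active odors by dendrogram branch selection, and runs
#' sequential forward selection of the descriptor multiset maximizing the
#' activity-distance correlation objective. The fitted object predicts
#' ligands for untested compounds by their weighted descriptor distance to
#' the nearest known active.
#'
#' @param activity odor-by-receptor response matrix in spikes/s (see
#'   [read_activity_table()]).
#' @param descriptors raw compound-by-descriptor matrix for the training
#'   odors (row ids matching `activity`).
#' @param receptor receptor id (column of `activity`).
#' @param strong_cutoff spikes/s cutoff defining strong activators for the
#'   active classification (default 50).
#' @param max_iter maximum number of descriptor selections (default
#'   unlimited; selection halts when the objective stops improving).
#' @return object of class `or_fit` with components `receptor`, `actives`
#'   (`active_set`), `trace` (`sfs_trace`), `multiset`, `objective`,
#'   `training` (normalized descriptor matrix) and `activity` (response
#'   vector).
#' @seealso [predict.or_fit()], [apoa_curve()], [crossvalidate()]
#' @examples
#' panel <- generate_panel(synthetic_config(seed = 1))
#' fit <- or_fit(panel$activity, panel$descriptors, receptor = "Or1")
#' fit
#' head(coef(fit))
#' @export
or_fit <- function(activity, descriptors, receptor, strong_cutoff = 50,
                   max_iter = Inf) {
  check_activity_table(activity)
  check_descriptor_table(descriptors)
  if (!setequal(rownames(activity), rownames(descriptors))) {
    stop("activity and descriptor tables cover different compounds", call. = FALSE)
  }
  descriptors <- descriptors[rownames(activity), , drop = FALSE]
  training <- normalize_descriptors(descriptors)
  actives <- classify_actives(activity, receptor, strong_cutoff = strong_cutoff)
  trace <- sfs_select(training, activity, receptor, actives = actives,
                      max_iter = max_iter)
  structure(list(receptor = receptor,
                 actives = actives,
                 trace = trace,
                 multiset = trace$multiset,
                 objective = trace$objective,
                 training = training,
                 activity = receptor_responses(activity, receptor),
                 strong_cutoff = strong_cutoff),
            class = "or_fit")
}

#' @export
print.or_fit <- function(x, ...) {
  cat(sprintf("receptor-optimized descriptor model for %s\n", x$receptor))
  cat(sprintf("  training compounds : %d\n", nrow(x$training)))
  cat(sprintf("  active odors       : %d (threshold %.4g spikes/s)\n",
              length(x$actives$members), x$actives$threshold))
  cat(sprintf("  selections         : %d (%d distinct descriptors)\n",
              length(x$multiset), length(unique(unclass(x$multiset)))))
  cat(sprintf("  final objective    : %.4f\n", x$objective))
  invisible(x)
}

#' Model coefficients: descriptor weights
#'
#' @param object `or_fit`.
#' @param ... unused.
#' @return named integer vector of selection multiplicities, ordered by
#'   decreasing weight.
#' @export
coef.or_fit <- function(object, ...) {
  m <- multiplicity(object$multiset)
  m[order(-m, names(m))]
}

#' @export
summary.or_fit <- function(object, ...) {
  curve <- apoa_curve(pairwise_distance(object$training, object$multiset),
                      object$actives)
  structure(list(fit = object, apoa = curve, apoa_auc = apoa_auc(curve)),
            class = "summary.or_fit")
}

#' @export
print.summary.or_fit <- function(x, ...) {
  print(x$fit)
  cat(sprintf("  training APoA AUC  : %.4f\n", x$apoa_auc))
  cat("  top descriptor weights:\n")
  print(utils::head(coef(x$fit), 8))
  invisible(x)
}

#' Rank new compounds by predicted affinity for the receptor
#'
#' Projects a raw screening library into the model's training coordinate
#' frame and ranks every compound by its weighted descriptor distance to
#' the nearest known active (ascending; ties broken by compound id).
#'
#' @param object fitted `or_fit`.
#' @param newdata raw compound-by-descriptor matrix for the screening
#'   library; must contain every descriptor retained in training.
#' @param top_n optional cap on the number of rows returned.
#' @param ... unused.
#' @return data.frame with columns `rank`, `id`, `distance`.
#' @export
predict.or_fit <- function(object, newdata, top_n = NULL, ...) {
  lib <- project_library(newdata, object$training)
  rank_library(lib, object$actives, object$training, object$multiset,
               top_n = top_n)
}

#' Plot the selection trace and training enrichment of a fitted model
#'
#' Left panel: objective value per selection iteration. Right panel: mean
#' APoA curve of the training compounds under the optimized multiset.
#'
#' @param x `or_fit`.
#' @param ... passed to [graphics::plot()].
#' @export
plot.or_fit <- function(x, ...) {
  op <- graphics::par(mfrow = c(1, 2))
  on.exit(graphics::par(op))
  graphics::plot(x$trace$iterations$iteration, x$trace$iterations$objective,
                 type = "b", pch = 16, xlab = "iteration",
                 ylab = "objective correlation",
                 main = sprintf("%s: SFS trace", x$receptor), ...)
  curve <- apoa_curve(pairwise_distance(x$training, x$multiset), x$actives)
  plot(curve, main = sprintf("%s: training APoA", x$receptor))
  invisible(x)
}
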