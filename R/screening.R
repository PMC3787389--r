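# Library screening: nearest-active ranking and breadth-of-tuning
# distribution profiles.

#' Rank a screening library by distance to the nearest known active
#'
#' Each library compound is scored by the minimum weighted descriptor
#' distance to any active training compound, measured in the training
#' coordinate frame with the receptor's optimized multiset. Compounds are
#' returned in ascending score order, ties broken by compound id.
#'
#' @param library normalized library matrix from [project_library()]
#'   (training coordinate frame).
#' @param actives `active_set` or character vector of active training
#'   compound ids.
#' @param training normalized training descriptor matrix containing the
#'   active compounds.
#' @param multiset `descriptor_multiset` (or character vector) of
#'   descriptor selections; NULL for uniform weights.
#' @param top_n optional cap on the number of rows returned (the paper's
#'   screens keep the top 500 per receptor).
#' @return data.frame of class `ranked_predictions` with columns `rank`,
#'   `id`, `distance`.
#' @export
rank_library <- function(library, actives, training, multiset = NULL,
                         top_n = NULL) {
  check_descriptor_table(library)
  check_descriptor_table(training)
  if (!identical(colnames(library), colnames(training))) {
    stop("library and training descriptor columns differ; project the library first",
         call. = FALSE)
  }
  act <- if (inherits(actives, "active_set")) actives$members else as.character(actives)
  if (length(act) == 0) stop("empty active set", call. = FALSE)
  if (!all(act %in% rownames(training))) {
    stop("active id(s) absent from training table", call. = FALSE)
  }
  if (is.null(multiset)) {
    w <- stats::setNames(rep(1L, ncol(training)), colnames(training))
  } else {
    w <- multiplicity(multiset)
    unknown <- setdiff(names(w), colnames(training))
    if (length(unknown) > 0) {
      stop("multiset references unknown descriptor(s): ",
           paste(unknown, collapse = ", "), call. = FALSE)
    }
  }
  A <- sweep(training[act, names(w), drop = FALSE], 2, sqrt(w), "*")
  L <- sweep(library[, names(w), drop = FALSE], 2, sqrt(w), "*")
  d2 <- outer(rowSums(L^2), rowSums(A^2), "+") - 2 * L %*% t(A)
  score <- sqrt(pmax(0, apply(d2, 1, min)))
  ord <- order(score, rownames(library))
  out <- data.frame(rank = seq_along(score),
                    id = rownames(library)[ord],
                    distance = score[ord],
                    row.names = NULL, stringsAsFactors = FALSE)
  if (!is.null(top_n)) out <- out[seq_len(min(top_n, nrow(out))), , drop = FALSE]
  class(out) <- c("ranked_predictions", "data.frame")
  out
}

#' Breadth-of-tuning distribution profile
#'
#' Summarizes how a receptor's predicted ligands are distributed in a large
#' library, using each compound's distance from the receptor's single
#' strongest activating compound. Extreme outliers are removed first
#' (distance above `mean + extreme_k * SD`, a handful of compounds in a
#' large library), then ordinary outliers (distance above
#' `mean + outlier_k * SD` of the remaining distances). Retained distances
#' are expressed as a percentage of the maximum retained distance, and the
#' compounds in the top `top_pct` percent are binned at 1% resolution.
#'
#' @param distances named vector of library-compound distances from the
#'   strongest active (>= 10 compounds).
#' @param outlier_k SD multiplier for the outlier stage (default 3).
#' @param extreme_k SD multiplier for the extreme-outlier stage (default 6;
#'   `Inf` disables the stage).
#' @param top_pct percentage window profiled (default 15).
#' @return object of class `breadth_profile`: list with
#'   `removed_extreme_ids`, `removed_outlier_ids`, `percent` (named vector
#'   in \[0, 100\]) and `histogram` (data.frame `bin_upper_pct`, `count`,
#'    1%-wide bins covering (0, top_pct]).
#' @export
breadth_distribution <- function(distances, outlier_k = 3, extreme_k = 6,
                                 top_pct = 15) {
  d <- distances
  if (length(d) < 10) stop("need at least 10 compounds for a distribution profile", call. = FALSE)
  if (is.null(names(d))) names(d) <- as.character(seq_along(d))
  if (any(d < 0) || anyNA(d)) stop("distances must be nonnegative and complete", call. = FALSE)

  cut1 <- mean(d) + extreme_k * stats::sd(d)
  extreme <- names(d)[d > cut1]
  d1 <- d[d <= cut1]
  if (length(d1) == 0) stop("all compounds removed as extreme outliers", call. = FALSE)

  cut2 <- mean(d1) + outlier_k * stats::sd(d1)
  outlier <- names(d1)[d1 > cut2]
  d2 <- d1[d1 <= cut2]
  if (length(d2) == 0 || max(d2) == 0) {
    stop("no usable distance spread after outlier removal", call. = FALSE)
  }

  pct <- 100 * d2 / max(d2)
  in_top <- pct <= top_pct
  bin <- pmax(1, ceiling(pct[in_top]))  # percent 0 falls in the first bin
  counts <- tabulate(bin, nbins = top_pct)
  structure(list(removed_extreme_ids = extreme,
                 removed_outlier_ids = outlier,
                 percent = pct,
                 histogram = data.frame(bin_upper_pct = seq_len(top_pct),
                                        count = counts)),
            class = "breadth_profile")
}

#' @export
print.breadth_profile <- function(x, ...) {
  cat(sprintf("breadth-of-tuning profile: %d compounds retained, %d extreme + %d outlier removed\n",
              length(x$percent), length(x$removed_extreme_ids),
              length(x$removed_outlier_ids)))
  cat(sprintf("compounds within top %d%%: %d\n",
              nrow(x$histogram), sum(x$histogram$count)))
  invisible(x)
}

#' @export
plot.breadth_profile <- function(x, ...) {
  graphics::barplot(x$histogram$count, names.arg = x$histogram$bin_upper_pct,
                    xlab = "% of maximum distance from strongest active",
                    ylab = "compounds", ...)
  invisible(x)
}
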