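# Sequential forward selection of receptor-optimized descriptor multisets.
#
# The selection objective correlates two compound-by-compound distance
# matrices over the rows of the receptor's active compounds: the activity
# distance matrix (CbCA, |spikes/s difference|) and the weighted descriptor
# distance matrix (CbCD) implied by the growing multiset. Descriptors may
# be re-selected; a repeated selection doubles that descriptor's weight.

# Pair bookkeeping shared by the objective and the optimizer: for each
# active i (sorted id order) every other compound j != i (sorted id order),
# diagonal excluded.
active_pairs <- function(compound_ids, active_ids) {
  ids <- sort(compound_ids)
  act <- sort(intersect(active_ids, ids))
  if (length(act) == 0) stop("no active compounds among the table ids", call. = FALSE)
  i <- rep(act, each = length(ids) - 1)
  j <- unlist(lapply(act, function(a) ids[ids != a]), use.names = FALSE)
  list(i = i, j = j)
}

pearson_vs <- function(cand, y) {
  # correlation of each column of cand with y; zero-variance -> -Inf sentinel
  cc <- suppressWarnings(stats::cor(cand, y))
  cc[!is.finite(cc)] <- -Inf
  unname(drop(cc))
}

#' Correlation objective for a descriptor multiset
#'
#' Builds the weighted descriptor distance matrix from `descriptors` and
#' `multiset`, extracts for every active compound its distances to all
#' other compounds (diagonal excluded), concatenates those rows in fixed
#' (sorted active id) x (sorted compound id) order, and returns the Pearson
#' correlation with the identically indexed activity-distance entries.
#'
#' If either concatenated vector has zero variance the correlation is
#' undefined and the sentinel `-Inf` is returned (treated as "worst
#' possible" by the optimizer).
#'
#' @param descriptors normalized compound-by-descriptor matrix.
#' @param multiset `descriptor_multiset` or character vector of descriptor
#'   ids with repetition.
#' @param cbca compound-by-compound activity distance matrix (see
#'   [activity_distance()]).
#' @param actives `active_set` or character vector of active compound ids.
#' @return Pearson correlation in \[-1, 1\], or `-Inf` if undefined.
#' @export
objective_correlation <- function(descriptors, multiset, cbca, actives) {
  check_descriptor_table(descriptors)
  act <- if (inherits(actives, "active_set")) actives$members else as.character(actives)
  if (length(act) == 0) stop("empty active set", call. = FALSE)
  if (!all(act %in% rownames(descriptors))) {
    stop("active id(s) absent from descriptor table", call. = FALSE)
  }
  if (!all(rownames(descriptors) %in% rownames(cbca))) {
    stop("activity distance matrix does not cover all compounds", call. = FALSE)
  }
  cbcd <- pairwise_distance(descriptors, multiset)
  p <- active_pairs(rownames(descriptors), act)
  pearson_vs(cbind(cbcd[cbind(p$i, p$j)]), cbca[cbind(p$i, p$j)])
}

#' Sequential forward selection of an optimized descriptor multiset
#'
#' Greedy growth of a descriptor multiset for one receptor. The first
#' iteration evaluates every single descriptor and keeps the best; each
#' later iteration evaluates the current multiset extended by every
#' descriptor (including ones already chosen, so re-selection acts as
#' weighting) and keeps the extension with the highest objective. Selection
#' halts when no extension strictly improves the objective; the multiset
#' from the previous step is returned. Objective ties are broken by the
#' smallest descriptor id in sorted order.
#'
#' @param descriptors normalized compound-by-descriptor matrix for the
#'   training compounds (>= 2 descriptors unless the pool is deliberately
#'   degenerate).
#' @param activity odor-by-receptor response matrix.
#' @param receptor receptor id.
#' @param actives `active_set` from [classify_actives()]; computed from
#'   `activity` when NULL.
#' @param max_iter maximum number of selections (default unlimited).
#' @return object of class `sfs_trace`: list with `receptor`, `iterations`
#'   (data.frame of chosen descriptor and objective per iteration),
#'   `multiset` (`descriptor_multiset`) and `objective`.
#' @export
sfs_select <- function(descriptors, activity, receptor, actives = NULL,
                       max_iter = Inf) {
  check_descriptor_table(descriptors)
  if (ncol(descriptors) < 1) stop("empty descriptor table", call. = FALSE)
  if (is.null(actives)) actives <- classify_actives(activity, receptor)
  act <- actives$members
  if (!all(act %in% rownames(descriptors))) {
    stop("active id(s) absent from descriptor table", call. = FALSE)
  }
  cbca <- activity_distance(activity, receptor)
  prs <- active_pairs(rownames(descriptors), act)
  y <- cbca[cbind(prs$i, prs$j)]

  # per-descriptor squared coordinate differences on the fixed pair list;
  # adding descriptor k to the multiset adds column k to the running sum
  sq <- (descriptors[prs$i, , drop = FALSE] - descriptors[prs$j, , drop = FALSE])^2
  desc_ids <- colnames(descriptors)
  ord <- order(desc_ids)  # tie-break: smallest id in sorted order

  base <- numeric(length(y))
  sel <- character(0)
  objs <- numeric(0)
  best_obj <- -Inf
  while (length(sel) < max_iter) {
    cc <- pearson_vs(sqrt(base + sq), y)
    k <- ord[which.max(cc[ord])]
    if (!is.finite(cc[k]) && length(sel) == 0) {
      stop("selection objective undefined for every descriptor (no activity variance?)",
           call. = FALSE)
    }
    if (!(cc[k] > best_obj)) break
    best_obj <- cc[k]
    sel <- c(sel, desc_ids[k])
    objs <- c(objs, best_obj)
    base <- base + sq[, k]
  }

  structure(list(receptor = receptor,
                 iterations = data.frame(iteration = seq_along(sel),
                                         descriptor = sel,
                                         objective = objs,
                                         stringsAsFactors = FALSE),
                 multiset = descriptor_multiset(sel, receptor = receptor),
                 objective = best_obj),
            class = "sfs_trace")
}

#' @export
print.sfs_trace <- function(x, ...) {
  cat(sprintf("SFS trace for %s: %d selection(s), final objective %.4f\n",
              x$receptor, nrow(x$iterations), x$objective))
  print(utils::head(x$iterations, 10))
  if (nrow(x$iterations) > 10) cat("...\n")
  invisible(x)
}

#' Serialize an SFS trace to JSON
#'
#' @param trace `sfs_trace`.
#' @param path output JSON file.
#' @export
write_sfs_trace <- function(trace, path) {
  jsonlite::write_json(list(receptor_id = trace$receptor,
                            iterations = trace$iterations,
                            final_objective = trace$objective),
                       path, auto_unbox = TRUE, digits = NA, dataframe = "rows")
  invisible(path)
}
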