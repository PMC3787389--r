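# Active-compound classification by dendrogram branch selection.

#' Classify a receptor's active training odors
#'
#' Clusters the training odors of one receptor by their pairwise activity
#' distance (|spikes/s difference|, complete linkage) and selects, among all
#' dendrogram nodes, the branch containing the largest number of strong
#' activators (response strictly above `strong_cutoff`). Ties go to the
#' branch with fewer total leaves, then to the deeper (lower-height) node,
#' then to stable id order. The receptor's activity threshold is the lowest
#' response of any odor in the selected branch, and every odor at or above
#' that threshold is classified active.
#'
#' Odors are canonicalized to id order before clustering so the result does
#' not depend on input row order.
#'
#' @param activity odor-by-receptor response matrix (>= 3 odors).
#' @param receptor receptor id.
#' @param strong_cutoff spikes/s defining a strong activator (default 50,
#'   strict `>`).
#' @return object of class `active_set`: list with `receptor`, `threshold`
#'   (spikes/s), `members` (odor ids), `strong_cutoff`, `responses`.
#'   If no odor exceeds `strong_cutoff` an error of class
#'   `no_actives_error` is signalled so callers can skip the receptor.
#' @export
classify_actives <- function(activity, receptor, strong_cutoff = 50) {
  a <- receptor_responses(activity, receptor)
  if (length(a) < 3) stop("need at least 3 odors to classify actives", call. = FALSE)
  if (!any(a > strong_cutoff)) {
    stop(errorCondition(
      sprintf("receptor %s has no odor above %g spikes/s", receptor, strong_cutoff),
      class = c("no_actives_error", "error", "condition")))
  }
  a <- a[order(names(a))]
  n <- length(a)
  hc <- stats::hclust(stats::dist(a), method = "complete")

  # leaf sets for every node: n singletons plus n-1 internal merges
  leafsets <- c(as.list(seq_len(n)), vector("list", n - 1))
  heights <- c(rep(0, n), hc$height)
  for (k in seq_len(n - 1)) {
    kids <- hc$merge[k, ]
    get <- function(v) if (v < 0) -v else leafsets[[n + v]]
    leafsets[[n + k]] <- c(get(kids[1]), get(kids[2]))
  }

  strong <- a > strong_cutoff
  best <- NULL
  for (i in seq_along(leafsets)) {
    leaves <- leafsets[[i]]
    cand <- list(count = sum(strong[leaves]), size = length(leaves),
                 height = heights[i], leaves = leaves)
    if (is.null(best) ||
        cand$count > best$count ||
        (cand$count == best$count && cand$size < best$size) ||
        (cand$count == best$count && cand$size == best$size &&
           cand$height < best$height) ||
        (cand$count == best$count && cand$size == best$size &&
           cand$height == best$height &&
           paste(sort(names(a)[cand$leaves]), collapse = ",") <
             paste(sort(names(a)[best$leaves]), collapse = ","))) {
      best <- cand
    }
  }

  threshold <- min(a[best$leaves])
  members <- names(a)[a >= threshold]
  structure(list(receptor = receptor, threshold = threshold,
                 members = members, strong_cutoff = strong_cutoff,
                 responses = a),
            class = "active_set")
}

#' @export
print.active_set <- function(x, ...) {
  cat(sprintf("active set for %s: %d member(s), threshold %.4g spikes/s (strong cutoff > %g)\n",
              x$receptor, length(x$members), x$threshold, x$strong_cutoff))
  cat("members:", paste(x$members, collapse = ", "), "\n")
  invisible(x)
}

#' Serialize an active set to JSON
#'
#' @param actives `active_set`.
#' @param path output JSON file.
#' @export
write_active_set <- function(actives, path) {
  jsonlite::write_json(list(receptor_id = actives$receptor,
                            threshold = actives$threshold,
                            strong_cutoff = actives$strong_cutoff,
                            member_ids = actives$members),
                       path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
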