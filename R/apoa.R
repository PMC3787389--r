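# Accumulative percentage of actives (APoA) enrichment curves.

#' Accumulative-percentage-of-actives curve
#'
#' For each active compound c, all other compounds are ranked by distance
#' from c (ascending, ties broken by compound id); at rank m the APoA is
#' the fraction of actives among the m nearest compounds. Curves are
#' averaged over all active queries. The query compound is excluded from
#' its own ranking, so the final-rank value is exactly
#' `(|A| - 1) / (N - 1)`.
#'
#' @param distances symmetric compound-by-compound distance matrix.
#' @param actives `active_set` or character vector of active compound ids
#'   (at least 2 — each query must have another active to find).
#' @return object of class `apoa_curve`: data.frame with columns `rank`
#'   (1..N-1) and `mean_apoa`, with attributes `n_compounds`, `n_actives`.
#' @export
apoa_curve <- function(distances, actives) {
  act <- if (inherits(actives, "active_set")) actives$members else as.character(actives)
  ids <- rownames(distances)
  validate_distances(distances, tol = 1e-8)
  act <- intersect(ids, act)
  if (length(act) < 2) stop("need at least 2 active compounds for an APoA curve", call. = FALSE)
  n <- length(ids)
  is_active <- ids %in% act
  acc <- numeric(n - 1)
  for (c_id in sort(act)) {
    others <- setdiff(ids, c_id)
    d <- distances[c_id, others]
    ord <- order(d, others)  # stable id order on ties
    hits <- cumsum(is_active[match(others[ord], ids)])
    acc <- acc + hits / seq_len(n - 1)
  }
  out <- data.frame(rank = seq_len(n - 1), mean_apoa = acc / length(act))
  attr(out, "n_compounds") <- n
  attr(out, "n_actives") <- length(act)
  class(out) <- c("apoa_curve", "data.frame")
  out
}

#' Area under an APoA curve
#'
#' Trapezoidal integral over the normalized rank axis `x = m/(N-1)` in
#' (0, 1], with the leading interval (0, 1/(N-1)] treated as constant at
#' the rank-1 value, so a constant curve at value c has AUC exactly c.
#'
#' @param curve `apoa_curve`.
#' @return scalar AUC.
#' @export
apoa_auc <- function(curve) {
  v <- curve$mean_apoa
  if (length(v) == 0) stop("empty APoA curve", call. = FALSE)
  k <- length(v)
  x <- curve$rank / k
  lead <- v[1] * x[1]
  if (k == 1) return(lead)
  lead + sum((v[-1] + v[-k]) / 2 * diff(x))
}

#' @export
plot.apoa_curve <- function(x, ...) {
  args <- list(...)
  if (is.null(args$main)) args$main <- "mean APoA"
  do.call(graphics::plot,
          c(list(x = x$rank, y = x$mean_apoa, type = "l",
                 xlab = "rank", ylab = "mean APoA", ylim = c(0, 1)), args))
  graphics::abline(h = attr(x, "n_actives") / attr(x, "n_compounds"),
                   lty = 3, col = "grey50")
  invisible(x)
}

#' Write an APoA curve to CSV
#'
#' @param curve `apoa_curve`.
#' @param path output file.
#' @export
write_apoa_curve <- function(curve, path) {
  utils::write.csv(as.data.frame(curve), path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
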