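# Descriptor-table preparation and distance computation.
#
# Descriptor tables are compound-by-descriptor numeric matrices. A
# normalized table carries attributes:
#   norm_stats - data.frame(descriptor, mean, sd) of the *raw* training
#                statistics for every retained descriptor
#   dropped    - ids of zero-variance descriptors removed
# Standard deviation uses the sample (n-1) denominator throughout.

#' Z-score a raw descriptor table
#'
#' Centers and scales each descriptor to standard scores and removes
#' descriptors with no variation across compounds (raw sample SD below
#' 1e-12). The raw per-descriptor mean and SD are retained so screening
#' libraries can later be projected into the same coordinate frame.
#'
#' @param descriptors raw compound-by-descriptor matrix (>= 2 compounds).
#' @return normalized matrix with `norm_stats` and `dropped` attributes.
#' @export
normalize_descriptors <- function(descriptors) {
  check_descriptor_table(descriptors)
  if (nrow(descriptors) < 2) stop("need at least 2 compounds to normalize", call. = FALSE)
  mu <- colMeans(descriptors)
  sd <- apply(descriptors, 2, stats::sd)
  keep <- sd >= 1e-12
  if (!any(keep)) stop("all descriptors have zero variance", call. = FALSE)
  dropped <- colnames(descriptors)[!keep]
  if (length(dropped) > 0) {
    message(sprintf("dropping %d zero-variance descriptor(s): %s",
                    length(dropped), paste(utils::head(dropped, 5), collapse = ", ")))
  }
  x <- sweep(sweep(descriptors[, keep, drop = FALSE], 2, mu[keep], "-"),
             2, sd[keep], "/")
  attr(x, "norm_stats") <- data.frame(descriptor = colnames(descriptors)[keep],
                                      mean = unname(mu[keep]), sd = unname(sd[keep]),
                                      stringsAsFactors = FALSE)
  attr(x, "dropped") <- dropped
  x
}

#' Project a raw library into a training coordinate frame
#'
#' Applies the training set's per-descriptor mean/SD (not statistics pooled
#' with the library) so that library-to-training distances are measured in
#' the training frame. The result is restricted to the descriptors retained
#' by the training normalization, in training order.
#'
#' @param library raw compound-by-descriptor matrix for the screening
#'   library; must contain every retained training descriptor.
#' @param stats_from a normalized training table from
#'   [normalize_descriptors()], or its `norm_stats` data frame.
#' @return normalized library matrix carrying the training `norm_stats`.
#' @export
project_library <- function(library, stats_from) {
  ns <- if (is.data.frame(stats_from)) stats_from else attr(stats_from, "norm_stats")
  if (is.null(ns)) stop("'stats_from' carries no normalization statistics", call. = FALSE)
  check_descriptor_table(library)
  missing <- setdiff(ns$descriptor, colnames(library))
  if (length(missing) > 0) {
    stop("library lacks descriptor column(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  x <- library[, ns$descriptor, drop = FALSE]
  x <- sweep(sweep(x, 2, ns$mean, "-"), 2, ns$sd, "/")
  attr(x, "norm_stats") <- ns
  x
}

#' Descriptor selection multiset
#'
#' An ordered record of descriptor selections with repetition allowed; the
#' order is the greedy selection sequence and the repetition count of a
#' descriptor is its integer weight in distance computations.
#'
#' @param selections character vector of descriptor ids in selection order.
#' @param receptor optional receptor id the multiset was optimized for.
#' @return object of class `descriptor_multiset`.
#' @export
descriptor_multiset <- function(selections, receptor = NA_character_) {
  selections <- as.character(selections)
  if (length(selections) == 0) stop("empty descriptor multiset", call. = FALSE)
  structure(selections, receptor = as.character(receptor),
            class = "descriptor_multiset")
}

#' @export
print.descriptor_multiset <- function(x, ...) {
  cat(sprintf("descriptor multiset (%s): %d selections, %d distinct\n",
              attr(x, "receptor"), length(x), length(unique(unclass(x)))))
  m <- multiplicity(x)
  print(m[order(-m, names(m))])
  invisible(x)
}

#' Multiplicity (integer weights) of a descriptor multiset
#'
#' @param multiset `descriptor_multiset` or plain character vector.
#' @return named integer vector of repetition counts.
#' @export
multiplicity <- function(multiset) {
  tab <- table(as.character(multiset))
  stats::setNames(as.integer(tab), names(tab))
}

#' Serialize a descriptor multiset to JSON
#'
#' @param multiset `descriptor_multiset`.
#' @param path output JSON file.
#' @export
write_multiset <- function(multiset, path) {
  jsonlite::write_json(list(receptor_id = attr(multiset, "receptor"),
                            selections = as.character(multiset)),
                       path, auto_unbox = TRUE)
  invisible(path)
}

#' Read a descriptor multiset from JSON
#'
#' @param path JSON file written by [write_multiset()].
#' @return `descriptor_multiset`.
#' @export
read_multiset <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  descriptor_multiset(obj$selections, receptor = obj$receptor_id)
}

#' Weighted Euclidean compound-by-compound descriptor distances
#'
#' Distance between compounds i and j is
#' `sqrt(sum_k m(k) * (X[i,k] - X[j,k])^2)` with `m(k)` the multiplicity of
#' descriptor k in the multiset — identical to the unweighted Euclidean
#' distance on a table whose columns are physically repeated per selection.
#' With `weights = NULL` every descriptor of the table enters once.
#'
#' @param descriptors normalized compound-by-descriptor matrix.
#' @param weights `descriptor_multiset`, character vector with repetition,
#'   or NULL for uniform weights over all columns.
#' @return symmetric compound-by-compound distance matrix with zero
#'   diagonal and `provenance` attribute `"descriptor"`.
#' @export
pairwise_distance <- function(descriptors, weights = NULL) {
  check_descriptor_table(descriptors)
  if (is.null(weights)) {
    w <- stats::setNames(rep(1L, ncol(descriptors)), colnames(descriptors))
  } else {
    sel <- as.character(weights)
    if (length(sel) == 0) stop("empty descriptor multiset", call. = FALSE)
    unknown <- setdiff(sel, colnames(descriptors))
    if (length(unknown) > 0) {
      stop("multiset references unknown descriptor(s): ",
           paste(unique(unknown), collapse = ", "), call. = FALSE)
    }
    w <- multiplicity(sel)
  }
  x <- sweep(descriptors[, names(w), drop = FALSE], 2, sqrt(w), "*")
  m <- as.matrix(stats::dist(x))
  diag(m) <- 0
  dimnames(m) <- list(rownames(descriptors), rownames(descriptors))
  attr(m, "provenance") <- "descriptor"
  m
}

#' Compound-by-compound activity distances for one receptor
#'
#' The activity distance between two odors at a receptor is the absolute
#' difference of their responses in spikes/s.
#'
#' @param activity odor-by-receptor response matrix.
#' @param receptor receptor id (column of `activity`).
#' @return symmetric odor-by-odor distance matrix, `provenance`
#'   attribute `"activity"`.
#' @export
activity_distance <- function(activity, receptor) {
  a <- receptor_responses(activity, receptor)
  m <- abs(outer(a, a, "-"))
  dimnames(m) <- list(names(a), names(a))
  attr(m, "provenance") <- "activity"
  m
}

# --- internal validation helpers ---------------------------------------

check_descriptor_table <- function(x) {
  if (!is.matrix(x) || !is.numeric(x)) {
    stop("descriptor table must be a numeric matrix", call. = FALSE)
  }
  if (is.null(rownames(x)) || is.null(colnames(x))) {
    stop("descriptor table needs compound row names and descriptor column names", call. = FALSE)
  }
  if (any(!is.finite(x))) stop("non-finite descriptor values", call. = FALSE)
  invisible(x)
}

check_activity_table <- function(x) {
  if (!is.matrix(x) || !is.numeric(x)) {
    stop("activity table must be a numeric matrix", call. = FALSE)
  }
  if (is.null(rownames(x)) || is.null(colnames(x))) {
    stop("activity table needs odor row names and receptor column names", call. = FALSE)
  }
  if (anyNA(x)) stop("missing cells in activity table", call. = FALSE)
  invisible(x)
}

receptor_responses <- function(activity, receptor) {
  check_activity_table(activity)
  if (!receptor %in% colnames(activity)) {
    stop("unknown receptor id: ", receptor, call. = FALSE)
  }
  stats::setNames(activity[, receptor], rownames(activity))
}
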