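# Receptor-relationship trees and the receptor-ligand interaction network.

#' Receptor-by-feature matrices for receptor clustering
#'
#' Three views of receptor relationships:
#' \describe{
#'   \item{descriptor}{binary presence/absence of each receptor's first
#'     `first_n` descriptor selection events (duplicates collapse to
#'     presence), over the union of selected descriptors.}
#'   \item{activity}{raw receptor response vectors across the training
#'     odors (the activity table transposed).}
#'   \item{overlap}{per-receptor vector of pairwise percentage overlaps
#'     between top-N predicted ligand lists.}
#' }
#'
#' @param mode one of `"descriptor"`, `"activity"`, `"overlap"`.
#' @param traces named list of `sfs_trace` (or `descriptor_multiset`)
#'   objects, for descriptor mode.
#' @param activity odor-by-receptor response matrix, for activity mode.
#' @param predictions named list of `ranked_predictions` (or character id
#'   vectors) of equal length, for overlap mode.
#' @param first_n number of leading selection events used in descriptor
#'   mode (default 20; receptors with fewer selections use all available,
#'   with a warning).
#' @return receptor-by-feature numeric matrix.
#' @export
receptor_feature_matrix <- function(mode = c("descriptor", "activity", "overlap"),
                                    traces = NULL, activity = NULL,
                                    predictions = NULL, first_n = 20) {
  mode <- match.arg(mode)
  if (mode == "descriptor") {
    if (is.null(traces)) stop("descriptor mode needs 'traces'", call. = FALSE)
    firsts <- lapply(traces, function(tr) {
      sel <- if (inherits(tr, "sfs_trace")) as.character(tr$multiset) else as.character(tr)
      if (length(sel) < first_n) {
        warning(sprintf("receptor has only %d selection(s); using all", length(sel)),
                call. = FALSE)
      }
      unique(utils::head(sel, first_n))
    })
    pool <- sort(unique(unlist(firsts)))
    m <- t(vapply(firsts, function(s) as.numeric(pool %in% s), numeric(length(pool))))
    dimnames(m) <- list(names(traces), pool)
    return(m)
  }
  if (mode == "activity") {
    check_activity_table(activity)
    return(t(activity))
  }
  if (is.null(predictions)) stop("overlap mode needs 'predictions'", call. = FALSE)
  tops <- lapply(predictions, function(p) {
    if (inherits(p, "data.frame")) as.character(p$id) else as.character(p)
  })
  n <- length(tops[[1]])
  m <- outer(seq_along(tops), seq_along(tops),
             Vectorize(function(i, j) 100 * length(intersect(tops[[i]], tops[[j]])) / n))
  dimnames(m) <- list(names(tops), names(tops))
  m
}

#' Hierarchically cluster receptors
#'
#' Complete-linkage agglomeration of Euclidean distances between the rows
#' of a receptor-by-feature matrix. Rows are canonicalized to id order
#' first so the topology does not depend on input order.
#'
#' @param features receptor-by-feature matrix (>= 2 receptors).
#' @param mode optional label recording which feature space was used.
#' @return object of class `receptor_tree` wrapping the `hclust` result.
#' @export
cluster_receptors <- function(features, mode = NA_character_) {
  if (is.null(dim(features)) || nrow(features) < 2) {
    stop("need at least 2 receptors to cluster", call. = FALSE)
  }
  features <- features[order(rownames(features)), , drop = FALSE]
  hc <- stats::hclust(stats::dist(features), method = "complete")
  structure(list(hclust = hc, mode = mode), class = "receptor_tree")
}

#' @export
print.receptor_tree <- function(x, ...) {
  cat(sprintf("receptor tree (%s space): %d receptors\n",
              ifelse(is.na(x$mode), "unspecified", x$mode),
              length(x$hclust$labels)))
  cat("merge heights:", paste(sprintf("%.3g", x$hclust$height), collapse = ", "), "\n")
  invisible(x)
}

#' @export
plot.receptor_tree <- function(x, ...) {
  graphics::plot(x$hclust, main = sprintf("receptor tree (%s)", x$mode),
                 xlab = "", sub = "", ...)
  invisible(x)
}

#' Export a receptor tree as Newick
#'
#' @param tree `receptor_tree`.
#' @param path output file.
#' @export
write_tree_newick <- function(tree, path) {
  ape::write.tree(ape::as.phylo(tree$hclust), file = path)
  invisible(path)
}

#' Build the receptor-ligand interaction network
#'
#' Bipartite network of receptors and compounds. Known interactions are
#' activity-table cells strictly above `known_cutoff` spikes/s; predicted
#' interactions come from each receptor's top-N ranked predictions. A pair
#' that is both known and predicted carries a single edge with evidence
#' `"known"`.
#'
#' @param known odor-by-receptor response matrix of measured interactions
#'   (NULL for none).
#' @param predicted named list (by receptor) of `ranked_predictions` or
#'   character vectors of predicted compound ids (NULL for none).
#' @param known_cutoff spikes/s cutoff for a known interaction
#'   (default 50, strict `>`).
#' @return object of class `interaction_network` wrapping an igraph graph
#'   with vertex attribute `type` ("receptor"/"compound") and edge
#'   attribute `evidence` ("known"/"predicted").
#' @export
build_network <- function(known = NULL, predicted = NULL, known_cutoff = 50) {
  known_edges <- data.frame(receptor = character(), compound = character(),
                            stringsAsFactors = FALSE)
  receptors <- character(0); compounds <- character(0)
  if (!is.null(known)) {
    check_activity_table(known)
    hit <- which(known > known_cutoff, arr.ind = TRUE)
    known_edges <- data.frame(receptor = colnames(known)[hit[, 2]],
                              compound = rownames(known)[hit[, 1]],
                              stringsAsFactors = FALSE)
    receptors <- colnames(known); compounds <- rownames(known)
  }
  pred_edges <- data.frame(receptor = character(), compound = character(),
                           stringsAsFactors = FALSE)
  if (!is.null(predicted)) {
    ids <- lapply(predicted, function(p) {
      if (inherits(p, "data.frame")) as.character(p$id) else as.character(p)
    })
    pred_edges <- data.frame(receptor = rep(names(ids), lengths(ids)),
                             compound = unlist(ids, use.names = FALSE),
                             stringsAsFactors = FALSE)
    receptors <- union(receptors, names(ids))
    compounds <- union(compounds, unlist(ids, use.names = FALSE))
  }
  clash <- intersect(receptors, compounds)
  if (length(clash) > 0) {
    stop("receptor and compound id namespaces overlap: ",
         paste(utils::head(clash, 5), collapse = ", "), call. = FALSE)
  }
  known_key <- paste(known_edges$receptor, known_edges$compound, sep = "\r")
  pred_key <- paste(pred_edges$receptor, pred_edges$compound, sep = "\r")
  pred_edges <- pred_edges[!duplicated(pred_key) & !(pred_key %in% known_key), , drop = FALSE]
  edges <- rbind(cbind(known_edges, evidence = rep("known", nrow(known_edges))),
                 cbind(pred_edges, evidence = rep("predicted", nrow(pred_edges))))
  g <- igraph::graph_from_data_frame(
    edges[c("receptor", "compound", "evidence")], directed = FALSE,
    vertices = data.frame(name = c(receptors, compounds),
                          type = c(rep("receptor", length(receptors)),
                                   rep("compound", length(compounds)))))
  structure(list(graph = g), class = "interaction_network")
}

#' @export
print.interaction_network <- function(x, ...) {
  g <- x$graph
  ev <- igraph::E(g)$evidence
  cat(sprintf("receptor-ligand network: %d receptors, %d compounds, %d edges (%d known, %d predicted)\n",
              sum(igraph::V(g)$type == "receptor"),
              sum(igraph::V(g)$type == "compound"),
              igraph::ecount(g), sum(ev == "known"), sum(ev == "predicted")))
  invisible(x)
}

#' Export an interaction network as SIF
#'
#' One line per edge: `receptor <evidence> compound` (Cytoscape simple
#' interaction format).
#'
#' @param network `interaction_network`.
#' @param path output file.
#' @export
write_network_sif <- function(network, path) {
  e <- igraph::as_data_frame(network$graph, what = "edges")
  writeLines(sprintf("%s\t%s\t%s", e$from, e$evidence, e$to), path)
  invisible(path)
}

#' Export an interaction network as GraphML
#'
#' @param network `interaction_network`.
#' @param path output file.
#' @export
write_network_graphml <- function(network, path) {
  igraph::write_graph(network$graph, path, format = "graphml")
  invisible(path)
}
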