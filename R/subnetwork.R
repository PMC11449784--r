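# degree sequence from the edge table (each edge contributes one incidence
# to each endpoint, directions included as stored)
vertex_degrees <- function(network) {
  ids <- network$vertices$id
  deg <- table(factor(c(network$edges$from, network$edges$to), levels = ids))
  as.integer(deg)
}

subset_network <- function(network, keep_ids) {
  keep <- network$vertices$id %in% keep_ids
  vertices <- network$vertices[keep, , drop = FALSE]
  edges <- network$edges[network$edges$from %in% vertices$id &
                           network$edges$to %in% vertices$id, , drop = FALSE]
  # drop vertices isolated inside the induced subgraph
  touched <- unique(c(edges$from, edges$to))
  vertices <- vertices[vertices$id %in% touched, , drop = FALSE]
  rownames(vertices) <- NULL
  rownames(edges) <- NULL
  out <- new_network(vertices, edges, network$n_comparisons)
  idx <- match(vertices$id, rownames(network$fc))
  out$fc <- network$fc[idx, , drop = FALSE]
  out$sig <- network$sig[idx, , drop = FALSE]
  out$color <- network$color[idx, , drop = FALSE]
  out$clip <- network$clip
  out
}

#' Induce a pathway subnetwork
#'
#' Vertex-induced subgraph on the pathway members present in the network,
#' plus connector vertices bridging at least two retained members; all
#' internal edges are kept and isolated vertices dropped.
#'
#' @param network an `integrative_network`.
#' @param members character vector of pathway member ids.
#' @return the induced `integrative_network`.
#' @export
induce_pathway_subnetwork <- function(network, members) {
  stopifnot(inherits(network, "integrative_network"))
  kept <- intersect(network$vertices$id, members)
  conn <- network$vertices$id[network$vertices$vkind == "connector"]
  conn <- setdiff(conn, members)
  if (length(conn) && length(kept)) {
    e <- network$edges
    nb <- rbind(data.frame(v = e$from, o = e$to, stringsAsFactors = FALSE),
                data.frame(v = e$to, o = e$from, stringsAsFactors = FALSE))
    nb <- unique(nb[nb$v %in% conn & nb$o %in% kept, , drop = FALSE])
    bridge <- names(which(table(nb$v) >= 2L))
    kept <- c(kept, bridge)
  }
  subset_network(network, kept)
}

#' Degree-distribution distance between two networks
#'
#' Two-sample Kolmogorov-Smirnov statistic between the vertex degree
#' sequences of a subnetwork and its parent; always in `[0, 1]`.
#'
#' @param sub,parent non-empty `integrative_network`s.
#' @return the KS statistic (numeric scalar).
#' @export
degree_distance <- function(sub, parent) {
  d1 <- vertex_degrees(sub)
  d2 <- vertex_degrees(parent)
  if (!length(d1) || !length(d2)) {
    stop("both networks must be non-empty", call. = FALSE)
  }
  ks_statistic(d1, d2)
}

# exact two-sample KS statistic via ECDF evaluation at the pooled support
ks_statistic <- function(a, b) {
  pts <- sort(unique(c(a, b)))
  fa <- vapply(pts, function(p) mean(a <= p), 0)
  fb <- vapply(pts, function(p) mean(b <= p), 0)
  max(abs(fa - fb))
}

#' Score candidate pathway subnetworks
#'
#' For every pathway: counts the member vertices significant in at least
#' one of the five comparisons (`de_count`; connectors never count, and a
#' vertex counts once regardless of how many comparisons flag it) and
#' computes the degree-distribution distance of the induced subnetwork to
#' the parental network. Pathways are ranked by `de_count` (descending),
#' then `degree_distance` (ascending), then pathway id; pathways with no
#' member in the network rank last.
#'
#' @param network an `integrative_network` with fold changes attached.
#' @param pathways a `pathway_map`.
#' @param results optional differential table; when given it is attached via
#'   [attach_fold_changes()] first.
#' @return data frame with columns `pathway`, `de_count`, `degree_distance`,
#'   `n_vertices`, `n_edges`, sorted by rank.
#' @export
score_subnetworks <- function(network, pathways, results = NULL) {
  stopifnot(inherits(network, "integrative_network"))
  if (!is.null(results)) {
    network <- attach_fold_changes(network, results)
  }
  sig_any <- rowSums(network$sig, na.rm = TRUE) > 0
  rows <- lapply(names(pathways), function(p) {
    sub <- induce_pathway_subnetwork(network, pathways[[p]])
    if (n_vertices(sub) == 0L) {
      return(data.frame(pathway = p, de_count = 0L,
                        degree_distance = NA_real_, n_vertices = 0L,
                        n_edges = 0L, stringsAsFactors = FALSE))
    }
    member <- sub$vertices$id[sub$vertices$vkind != "connector"]
    data.frame(pathway = p,
               de_count = sum(sig_any[member]),
               degree_distance = degree_distance(sub, network),
               n_vertices = n_vertices(sub),
               n_edges = n_edges(sub),
               stringsAsFactors = FALSE)
  })
  scores <- do.call(rbind, rows)
  empty <- scores$n_vertices == 0L
  ord <- order(empty, -scores$de_count, scores$degree_distance,
               scores$pathway, na.last = TRUE)
  scores <- scores[ord, , drop = FALSE]
  rownames(scores) <- NULL
  class(scores) <- c("subnetwork_scores", "data.frame")
  scores
}

#' Select the top-ranked pathway subnetwork
#'
#' @param scores a `subnetwork_scores` table from [score_subnetworks()].
#' @param network the parental `integrative_network`.
#' @param pathways the `pathway_map` used for scoring.
#' @return the induced `integrative_network` of the top-ranked pathway, with
#'   attribute `"pathway"` naming it.
#' @export
select_subnetwork <- function(scores, network, pathways) {
  if (!nrow(scores)) stop("`scores` is empty", call. = FALSE)
  scores <- scores[scores$n_vertices > 0L, , drop = FALSE]
  if (!nrow(scores)) {
    stop("no pathway has members in the network", call. = FALSE)
  }
  top <- scores$pathway[1L]
  sub <- induce_pathway_subnetwork(network, pathways[[top]])
  attr(sub, "pathway") <- top
  sub
}

#' Write subnetwork scores as TSV
#'
#' @param scores a `subnetwork_scores` table.
#' @param path file path.
#' @return `path`, invisibly.
#' @export
write_scores_tsv <- function(scores, path) {
  utils::write.table(scores, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
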