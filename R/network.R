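#' Default currency-metabolite blocklist
#'
#' Ubiquitous cofactors excluded from network construction to avoid
#' biologically meaningless hub vertices. Fully configurable, including an
#' empty blocklist.
#'
#' @return character vector of metabolite ids.
#' @export
currency_metabolites <- function() {
  c("H2O", "water", "H+", "proton", "ATP", "ADP", "NAD", "NADH",
    "NADP", "NADPH", "CO2", "phosphate", "Pi")
}

# number of consecutive comparisons carried on every vertex
N_COMPARISONS <- 5L

new_network <- function(vertices, edges, n_comparisons = N_COMPARISONS) {
  k <- n_comparisons
  n <- nrow(vertices)
  mk <- function(what) {
    matrix(what, n, k, dimnames = list(vertices$id, paste0("c", seq_len(k))))
  }
  structure(list(vertices = vertices, edges = edges,
                 fc = mk(NA_real_), sig = mk(NA),
                 color = mk(NA_character_),
                 n_comparisons = as.integer(k)),
            class = "integrative_network")
}

#' @export
print.integrative_network <- function(x, ...) {
  tab <- table(factor(x$vertices$vkind,
                      levels = c("gene", "metabolite", "connector")))
  cat(sprintf(paste0("<integrative_network> %d vertices ",
                     "(%d genes, %d metabolites, %d connectors), %d edges\n"),
              nrow(x$vertices), tab[["gene"]], tab[["metabolite"]],
              tab[["connector"]], nrow(x$edges)))
  invisible(x)
}

#' @rdname assemble_network
#' @param network an `integrative_network`.
#' @export
n_vertices <- function(network) nrow(network$vertices)

#' @rdname assemble_network
#' @export
n_edges <- function(network) nrow(network$edges)

empty_edges <- function() {
  data.frame(from = character(), to = character(), provenance = character(),
             reaction_id = character(), directed = logical(),
             stringsAsFactors = FALSE)
}

# canonical edge ordering + duplicate collapse; undirected edges are stored
# with endpoints in lexical order so duplicates are recognized
normalize_edges <- function(edges) {
  if (!nrow(edges)) return(empty_edges())
  swap <- !edges$directed & edges$from > edges$to
  tmp <- edges$from[swap]
  edges$from[swap] <- edges$to[swap]
  edges$to[swap] <- tmp
  key <- paste(edges$from, edges$to, edges$provenance,
               ifelse(is.na(edges$reaction_id), "", edges$reaction_id),
               edges$directed, sep = "\r")
  edges <- edges[!duplicated(key), , drop = FALSE]
  edges <- edges[order(edges$provenance, edges$from, edges$to,
                       edges$reaction_id, na.last = TRUE), , drop = FALSE]
  rownames(edges) <- NULL
  edges
}

#' Extract reactions associated with measured genes
#'
#' @param model a `stoich_model`.
#' @param measured_genes character vector of measured gene ids.
#' @return list of `reaction` objects whose gene set intersects
#'   `measured_genes`.
#' @export
extract_reactions <- function(model, measured_genes) {
  stopifnot(inherits(model, "stoich_model"))
  Filter(function(r) length(intersect(r$genes, measured_genes)) > 0,
         model$reactions)
}

#' Filter reactions to measured entities
#'
#' Removes reactions not associated with any measured gene or metabolite.
#' Under the default `mode = "or"` a reaction survives with at least one
#' measured gene *or* one measured participating metabolite; `mode = "and"`
#' requires both.
#'
#' @param reactions list of `reaction` objects.
#' @param measured_genes,measured_metabolites measured id sets.
#' @param mode `"or"` or `"and"`.
#' @return the filtered reaction list (a subset of the input).
#' @export
filter_measured <- function(reactions, measured_genes, measured_metabolites,
                            mode = c("or", "and")) {
  mode <- match.arg(mode)
  Filter(function(r) {
    has_g <- length(intersect(r$genes, measured_genes)) > 0
    mets <- c(names(r$educts), names(r$products))
    has_m <- length(intersect(mets, measured_metabolites)) > 0
    if (mode == "or") has_g || has_m else has_g && has_m
  }, reactions)
}

#' Assemble the integrative gene-metabolite network
#'
#' Builds the parental network from a filtered reaction list. Per reaction,
#' the educt-product stoichiometry yields directed metabolite-to-metabolite
#' edges from every educt to every product (both directions for reversible
#' reactions), and every associated measured gene is linked by an undirected
#' edge to every participating non-blocked metabolite. Vertices are the
#' measured genes, the measured participating metabolites, and connector
#' vertices for unmeasured metabolites bridging at least
#' `connector_min_reactions` retained reactions. Currency metabolites on the
#' blocklist are excluded entirely, duplicate edges are collapsed, and
#' isolated vertices are dropped.
#'
#' @param reactions filtered list of `reaction` objects.
#' @param measured_genes,measured_metabolites measured id sets.
#' @param currency_blocklist metabolite ids excluded from the network
#'   (default [currency_metabolites()]).
#' @param connector_min_reactions minimum number of retained reactions an
#'   unmeasured metabolite must participate in to be kept as a connector.
#' @return an `integrative_network`.
#' @export
assemble_network <- function(reactions, measured_genes, measured_metabolites,
                             currency_blocklist = currency_metabolites(),
                             connector_min_reactions = 2L) {
  parts <- lapply(reactions, function(r) {
    setdiff(unique(c(names(r$educts), names(r$products))), currency_blocklist)
  })
  met_count <- table(unlist(lapply(parts, unique)))
  all_parts <- names(met_count)
  meas_mets <- intersect(all_parts, measured_metabolites)
  connectors <- setdiff(all_parts[met_count >= connector_min_reactions],
                        measured_metabolites)
  genes <- sort(unique(as.character(unlist(lapply(reactions, function(r) {
    intersect(r$genes, measured_genes)
  })))))
  vset <- as.character(c(genes, meas_mets, connectors))

  edges <- list()
  for (i in seq_along(reactions)) {
    r <- reactions[[i]]
    ed <- intersect(setdiff(names(r$educts), currency_blocklist), vset)
    pr <- intersect(setdiff(names(r$products), currency_blocklist), vset)
    if (length(ed) && length(pr)) {
      grid <- expand.grid(from = ed, to = pr, stringsAsFactors = FALSE)
      grid <- grid[grid$from != grid$to, , drop = FALSE]
      if (nrow(grid)) {
        e <- data.frame(grid, provenance = "reaction", reaction_id = r$id,
                        directed = TRUE, stringsAsFactors = FALSE)
        if (r$reversible) {
          e <- rbind(e, data.frame(from = grid$to, to = grid$from,
                                   provenance = "reaction",
                                   reaction_id = r$id, directed = TRUE,
                                   stringsAsFactors = FALSE))
        }
        edges[[length(edges) + 1L]] <- e
      }
    }
    g <- intersect(r$genes, measured_genes)
    m <- intersect(parts[[i]], vset)
    if (length(g) && length(m)) {
      grid <- expand.grid(from = g, to = m, stringsAsFactors = FALSE)
      edges[[length(edges) + 1L]] <-
        data.frame(grid, provenance = "reaction", reaction_id = r$id,
                   directed = FALSE, stringsAsFactors = FALSE)
    }
  }
  edges <- normalize_edges(if (length(edges)) do.call(rbind, edges)
                           else empty_edges())
  vertices <- data.frame(
    id = vset,
    vkind = c(rep("gene", length(genes)),
              rep("metabolite", length(meas_mets)),
              rep("connector", length(connectors))),
    measured = c(rep(TRUE, length(genes) + length(meas_mets)),
                 rep(FALSE, length(connectors))),
    stringsAsFactors = FALSE)
  touched <- unique(c(edges$from, edges$to))
  vertices <- vertices[vertices$id %in% touched, , drop = FALSE]
  if (nrow(vertices)) {
    vertices <- vertices[order(match(vertices$vkind,
                                     c("gene", "metabolite", "connector")),
                               vertices$id), , drop = FALSE]
  }
  rownames(vertices) <- NULL
  new_network(vertices, edges)
}

#' Enrich a network with protein-protein interaction edges
#'
#' Adds one undirected `ppi`-provenance edge per interaction whose both
#' endpoints are existing gene vertices; all other rows (absent endpoints,
#' self-interactions, malformed entries) are skipped and counted in the
#' returned network's `ppi_skipped` field. Duplicates are collapsed.
#'
#' @param network an `integrative_network`.
#' @param ppi data frame with columns `entity_a`, `entity_b`.
#' @return the enriched network.
#' @export
add_ppi <- function(network, ppi) {
  stopifnot(inherits(network, "integrative_network"))
  if (!all(c("entity_a", "entity_b") %in% colnames(ppi))) {
    stop("PPI table needs `entity_a` and `entity_b` columns", call. = FALSE)
  }
  gene_ids <- network$vertices$id[network$vertices$vkind == "gene"]
  a <- as.character(ppi$entity_a)
  b <- as.character(ppi$entity_b)
  ok <- !is.na(a) & !is.na(b) & nzchar(a) & nzchar(b) &
    a %in% gene_ids & b %in% gene_ids & a != b
  skipped <- sum(!ok)
  if (any(ok)) {
    new <- data.frame(from = a[ok], to = b[ok], provenance = "ppi",
                      reaction_id = NA_character_, directed = FALSE,
                      stringsAsFactors = FALSE)
    network$edges <- normalize_edges(rbind(network$edges, new))
  }
  network$ppi_skipped <- skipped
  network
}

#' Attach five-comparison fold-change vectors to vertices
#'
#' Fills, for every measured vertex, the per-comparison fold-change,
#' significance and display-color slots from a differential table. Slots
#' with no result stay empty and render gray; connector vertices are never
#' touched. Results for features absent from the network are ignored and
#' counted in the `unmatched_results` field.
#'
#' @param network an `integrative_network`.
#' @param results differential table with columns `feature`, `comparison`,
#'   `log2FC`, `significant`.
#' @param clip color saturation point; defaults to the 97.5th percentile of
#'   the attached absolute log2 fold changes.
#' @return the network with `fc`, `sig` and `color` slots filled.
#' @export
attach_fold_changes <- function(network, results, clip = NULL) {
  stopifnot(inherits(network, "integrative_network"))
  need <- c("feature", "comparison", "log2FC", "significant")
  if (!all(need %in% colnames(results))) {
    stop("`results` must have columns feature, comparison, log2FC, significant",
         call. = FALSE)
  }
  measured <- network$vertices$id[network$vertices$measured]
  known <- results$feature %in% measured &
    results$comparison >= 1L & results$comparison <= network$n_comparisons
  network$unmatched_results <- sum(!known)
  res <- results[known, , drop = FALSE]
  idx <- cbind(match(res$feature, rownames(network$fc)), res$comparison)
  network$fc[idx] <- res$log2FC
  network$sig[idx] <- res$significant
  filled <- !is.na(network$fc)
  if (is.null(clip)) {
    clip <- if (any(filled)) {
      stats::quantile(abs(network$fc[filled]), 0.975, names = FALSE)
    } else {
      1
    }
    clip <- max(clip, .Machine$double.eps)
  }
  network$clip <- clip
  col <- matrix(GRAY_HEX, nrow(network$fc), ncol(network$fc),
                dimnames = dimnames(network$fc))
  fill <- filled & !is.na(network$sig)
  col[fill] <- fc_to_color(network$fc[fill], network$sig[fill], clip = clip)
  # connectors carry no color vector at all
  col[!network$vertices$measured, ] <- NA_character_
  network$color <- col
  network
}

GRAY_HEX <- "#BEBEBE"

#' Map a log2 fold change to a display color
#'
#' Linear diverging scale on `[-clip, +clip]`: pure blue at `-clip`
#' (downregulation versus the previous time point), neutral white at 0,
#' pure red at `+clip` (upregulation); values beyond the clip saturate.
#' Non-significant values map to gray.
#'
#' @param log2fc numeric vector of log2 fold changes (finite).
#' @param significant logical vector.
#' @param clip positive saturation point.
#' @return character vector of hex colors.
#' @export
fc_to_color <- function(log2fc, significant, clip = 2) {
  if (clip <= 0) stop("`clip` must be > 0", call. = FALSE)
  if (any(!is.finite(log2fc))) {
    stop("log2 fold changes must be finite", call. = FALSE)
  }
  t <- pmin(pmax(log2fc / clip, -1), 1)
  up <- t >= 0
  r <- ifelse(up, 255, round(255 * (1 + t)))
  g <- round(255 * (1 - abs(t)))
  b <- ifelse(up, round(255 * (1 - t)), 255)
  out <- grDevices::rgb(r, g, b, maxColorValue = 255)
  out[!significant] <- GRAY_HEX
  out
}
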