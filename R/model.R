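#' Reactions and stoichiometric models
#'
#' A `reaction` holds educts (substrates) and products as named coefficient
#' vectors, a flattened set of associated genes, and a reversibility flag. A
#' `stoich_model` is a list of reactions plus the metabolite and gene
#' universes they reference.
#'
#' @param id reaction id (unique within a model).
#' @param educts,products named numeric vectors of positive stoichiometric
#'   coefficients; names are metabolite ids. Both sides must be non-empty.
#' @param genes character vector of associated gene ids (may be empty).
#' @param reversible logical flag.
#' @return `reaction()` returns a `reaction` object; `stoich_model()` a
#'   `stoich_model`.
#' @export
reaction <- function(id, educts, products, genes = character(),
                     reversible = FALSE) {
  if (!is.character(id) || length(id) != 1L || !nzchar(id)) {
    stop("reaction `id` must be a non-empty string", call. = FALSE)
  }
  for (side in list(educts = educts, products = products)) {
    if (length(side) == 0L || is.null(names(side)) || any(!nzchar(names(side)))) {
      stop(sprintf("reaction '%s': educt and product sets must be non-empty ",
                   id), "named vectors", call. = FALSE)
    }
    if (any(!is.finite(side)) || any(side <= 0)) {
      stop(sprintf("reaction '%s': coefficients must be positive", id),
           call. = FALSE)
    }
  }
  structure(list(id = id,
                 educts = educts[order(names(educts))],
                 products = products[order(names(products))],
                 genes = sort(unique(as.character(genes))),
                 reversible = isTRUE(reversible)),
            class = "reaction")
}

#' @rdname reaction
#' @param reactions list of `reaction` objects with unique ids.
#' @export
stoich_model <- function(reactions) {
  if (!length(reactions)) stop("model must contain reactions", call. = FALSE)
  ids <- vapply(reactions, `[[`, "", "id")
  if (anyDuplicated(ids)) {
    stop(sprintf("duplicate reaction id(s): %s",
                 paste(unique(ids[duplicated(ids)]), collapse = ", ")),
         call. = FALSE)
  }
  names(reactions) <- ids
  mets <- sort(unique(unlist(lapply(reactions, function(r) {
    c(names(r$educts), names(r$products))
  }))))
  genes <- sort(unique(unlist(lapply(reactions, `[[`, "genes"))))
  structure(list(reactions = reactions, metabolites = mets, genes = genes),
            class = "stoich_model")
}

#' @export
print.stoich_model <- function(x, ...) {
  cat(sprintf("<stoich_model> %d reactions, %d metabolites, %d genes\n",
              length(x$reactions), length(x$metabolites), length(x$genes)))
  invisible(x)
}

#' @export
print.reaction <- function(x, ...) {
  side <- function(v) paste(ifelse(v == 1, "", paste0(v, " ")), names(v),
                            sep = "", collapse = " + ")
  arrow <- if (x$reversible) "<=>" else "->"
  cat(sprintf("%s: %s %s %s [%s]\n", x$id, side(x$educts), arrow,
              side(x$products), paste(x$genes, collapse = ", ")))
  invisible(x)
}

# metabolite ids of the core glutamate/polyamine-to-GABA motif
core_motif_metabolites <- function() {
  c("glutamate", "GABA", "ornithine", "putrescine", "4-aminobutanal")
}

core_motif_genes <- function() {
  c("GAD1", "GAD2", "ODC1", "AOC2", "ALDH9A1", "SAT1", "ALDH1A1")
}

#' Toy stoichiometric model around the GABA biosynthetic routes
#'
#' Builds a small reaction model that always contains the canonical and
#' non-canonical GABA biosynthesis motif: decarboxylation of glutamate to
#' GABA (GAD1/GAD2), decarboxylation of ornithine to putrescine (ODC1),
#' oxidation of putrescine to 4-aminobutanal (AOC2) and on to GABA
#' (ALDH9A1), and the acetylation-dependent putrescine-to-GABA route
#' (SAT1/ALDH1A1). Additional random reactions over a small metabolite pool
#' can be appended to exercise network construction at scale.
#'
#' @param seed integer seed; the model is a pure function of
#'   `(seed, n_extra_reactions)`.
#' @param n_extra_reactions number of random decoy reactions to append.
#' @return a `stoich_model`.
#' @examples
#' make_toy_model(seed = 1, n_extra_reactions = 3)
#' @export
make_toy_model <- function(seed = 1, n_extra_reactions = 0) {
  if (!is.numeric(n_extra_reactions) || length(n_extra_reactions) != 1L ||
      is.na(n_extra_reactions) || n_extra_reactions < 0) {
    stop("`n_extra_reactions` must be a non-negative count", call. = FALSE)
  }
  n_extra_reactions <- as.integer(n_extra_reactions)
  core <- list(
    reaction("R_GAD", c(glutamate = 1), c(GABA = 1, CO2 = 1),
             genes = c("GAD1", "GAD2")),
    reaction("R_ODC", c(ornithine = 1), c(putrescine = 1, CO2 = 1),
             genes = "ODC1"),
    reaction("R_AOC", c(putrescine = 1), c(`4-aminobutanal` = 1),
             genes = "AOC2"),
    reaction("R_ABAL", c(`4-aminobutanal` = 1), c(GABA = 1),
             genes = "ALDH9A1"),
    reaction("R_SAT", c(putrescine = 1), c(GABA = 1),
             genes = c("SAT1", "ALDH1A1"))
  )
  extra <- list()
  if (n_extra_reactions > 0) {
    pool_m <- sprintf("M%02d", 1:12)
    pool_g <- sprintf("G%02d", 1:10)
    extra <- with_seed(seed, lapply(seq_len(n_extra_reactions), function(i) {
      mets <- sample(pool_m, sample(2:4, 1))
      n_ed <- sample(seq_len(length(mets) - 1L), 1)
      reaction(sprintf("RX%03d", i),
               educts = stats::setNames(rep(1, n_ed), mets[seq_len(n_ed)]),
               products = stats::setNames(rep(1, length(mets) - n_ed),
                                          mets[-seq_len(n_ed)]),
               genes = sample(pool_g, sample(1:2, 1)),
               reversible = stats::runif(1) < 0.2)
    }))
  }
  stoich_model(c(core, extra))
}

#' Synthetic protein-protein interaction table
#'
#' Draws unique unordered gene pairs from the model's gene universe, in the
#' three-column layout of curated interaction exports
#' (`entity_a`, `entity_b`, `effect`).
#'
#' @param model a `stoich_model` with at least two genes.
#' @param n_edges number of interactions to draw.
#' @param seed integer seed.
#' @return data frame with columns `entity_a`, `entity_b`, `effect`.
#' @export
make_ppi <- function(model, n_edges, seed = 1) {
  stopifnot(inherits(model, "stoich_model"))
  genes <- model$genes
  if (length(genes) < 2L) {
    stop("model must contain at least 2 genes", call. = FALSE)
  }
  max_pairs <- choose(length(genes), 2)
  if (n_edges > max_pairs) {
    stop(sprintf("n_edges = %d exceeds the %d possible gene pairs",
                 n_edges, max_pairs), call. = FALSE)
  }
  if (n_edges == 0L) {
    return(data.frame(entity_a = character(), entity_b = character(),
                      effect = character(), stringsAsFactors = FALSE))
  }
  pairs <- t(utils::combn(genes, 2))
  with_seed(seed, {
    idx <- sample(nrow(pairs), n_edges)
    data.frame(entity_a = pairs[idx, 1], entity_b = pairs[idx, 2],
               effect = sample(c("up-regulates", "down-regulates", "binds"),
                               n_edges, replace = TRUE),
               stringsAsFactors = FALSE)
  })
}

#' Synthetic pathway map
#'
#' Builds a pathway membership map containing one planted pathway,
#' `"polyamine_gaba"`, holding exactly the core-motif genes and metabolites
#' of [make_toy_model()], plus `n_decoy_pathways` decoy pathways drawing
#' random non-core members from the model.
#'
#' @param model a `stoich_model`.
#' @param n_decoy_pathways number of decoy pathways.
#' @param seed integer seed.
#' @param decoy_size number of members per decoy pathway (capped at the
#'   non-core pool size).
#' @return a named list of member-id character vectors, class `pathway_map`.
#' @export
make_pathway_map <- function(model, n_decoy_pathways = 0, seed = 1,
                             decoy_size = 8) {
  stopifnot(inherits(model, "stoich_model"))
  core <- c(core_motif_genes(), core_motif_metabolites())
  core <- intersect(core, c(model$genes, model$metabolites))
  map <- list(polyamine_gaba = core)
  if (n_decoy_pathways > 0) {
    pool <- setdiff(c(model$genes, model$metabolites), c(core, "CO2"))
    if (!length(pool)) {
      stop("model has no non-core members to build decoy pathways from",
           call. = FALSE)
    }
    decoys <- with_seed(seed, lapply(seq_len(n_decoy_pathways), function(i) {
      sample(pool, min(decoy_size, length(pool)))
    }))
    names(decoys) <- sprintf("decoy_%02d", seq_len(n_decoy_pathways))
    map <- c(map, decoys)
  }
  structure(map, class = "pathway_map")
}

#' Read and write pathway maps as GMT
#'
#' One pathway per line: id, description, then member ids, tab-separated.
#'
#' @param pathways a `pathway_map` (named list of member vectors).
#' @param path file path.
#' @return `read_gmt()` returns a `pathway_map`; the writer returns `path`
#'   invisibly.
#' @export
write_gmt <- function(pathways, path) {
  lines <- vapply(names(pathways), function(p) {
    paste(c(p, p, pathways[[p]]), collapse = "\t")
  }, "")
  writeLines(lines, path)
  invisible(path)
}

#' @rdname write_gmt
#' @export
read_gmt <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  parts <- strsplit(lines, "\t", fixed = TRUE)
  map <- lapply(parts, function(p) p[-(1:2)])
  names(map) <- vapply(parts, `[[`, "", 1L)
  structure(map, class = "pathway_map")
}

#' Write a PPI table as TSV
#'
#' @param ppi data frame with columns `entity_a`, `entity_b` (and optionally
#'   `effect`).
#' @param path file path.
#' @return `read_ppi_tsv()` returns the data frame; the writer returns
#'   `path` invisibly.
#' @export
write_ppi_tsv <- function(ppi, path) {
  utils::write.table(ppi, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_ppi_tsv
#' @export
read_ppi_tsv <- function(path) {
  utils::read.table(path, sep = "\t", header = TRUE, stringsAsFactors = FALSE)
}
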