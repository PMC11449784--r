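#' Build the parental integrative network from a model and measured sets
#'
#' Convenience wrapper chaining the reconstruction steps: extract the
#' reactions associated with measured genes, filter to measured entities,
#' assemble the gene-metabolite network, enrich with PPI edges, and attach
#' the five-comparison fold-change vectors.
#'
#' @param model a `stoich_model`.
#' @param measured_genes,measured_metabolites measured id sets.
#' @param ppi optional PPI data frame (`entity_a`, `entity_b`).
#' @param results optional differential table (gene and metabolite rows
#'   combined) to attach.
#' @param mode measured-entity filter mode, see [filter_measured()].
#' @param currency_blocklist see [assemble_network()].
#' @param connector_min_reactions see [assemble_network()].
#' @return an `integrative_network`.
#' @export
build_parental_network <- function(model, measured_genes,
                                   measured_metabolites,
                                   ppi = NULL, results = NULL,
                                   mode = "or",
                                   currency_blocklist = currency_metabolites(),
                                   connector_min_reactions = 2L) {
  rxns <- extract_reactions(model, measured_genes)
  rxns <- filter_measured(rxns, measured_genes, measured_metabolites,
                          mode = mode)
  net <- assemble_network(rxns, measured_genes, measured_metabolites,
                          currency_blocklist = currency_blocklist,
                          connector_min_reactions = connector_min_reactions)
  if (!is.null(ppi)) net <- add_ppi(net, ppi)
  if (!is.null(results)) net <- attach_fold_changes(net, results)
  net
}
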