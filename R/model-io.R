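#' Write a stoichiometric model as a JSON reaction table
#'
#' Schema: a top-level array of
#' `{id, educts: [{met, coef}], products: [{met, coef}], genes: [], reversible}`.
#'
#' @param model a `stoich_model`.
#' @param path file path.
#' @return `path`, invisibly.
#' @export
write_model_json <- function(model, path) {
  stopifnot(inherits(model, "stoich_model"))
  side_df <- function(v) {
    data.frame(met = names(v), coef = unname(v), stringsAsFactors = FALSE)
  }
  rxns <- lapply(model$reactions, function(r) {
    list(id = r$id, educts = side_df(r$educts), products = side_df(r$products),
         genes = r$genes, reversible = r$reversible)
  })
  jsonlite::write_json(unname(rxns), path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

# SBML species ids must match the SId grammar; metabolite names like
# "4-aminobutanal" are carried in the `name` attribute instead.
sbml_sid <- function(x) paste0("M_", gsub("[^A-Za-z0-9_]", "_", x))

#' Write a stoichiometric model as SBML (level 3)
#'
#' Species carry the metabolite id in their `name` attribute (ids are
#' sanitized to the SBML identifier grammar); gene associations are stored
#' as a `GENE_ASSOCIATION:` note on each reaction, the convention of
#' flux-model exchange files.
#'
#' @param model a `stoich_model`.
#' @param path file path.
#' @return `path`, invisibly.
#' @export
write_model_sbml <- function(model, path) {
  stopifnot(inherits(model, "stoich_model"))
  doc <- xml2::xml_new_root(
    "sbml", xmlns = "http://www.sbml.org/sbml/level3/version1/core",
    level = "3", version = "1")
  mod <- xml2::xml_add_child(doc, "model", id = "model")
  los <- xml2::xml_add_child(mod, "listOfSpecies")
  for (m in model$metabolites) {
    xml2::xml_add_child(los, "species", id = sbml_sid(m), name = m,
                        hasOnlySubstanceUnits = "false",
                        boundaryCondition = "false", constant = "false")
  }
  lor <- xml2::xml_add_child(mod, "listOfReactions")
  for (r in model$reactions) {
    rx <- xml2::xml_add_child(lor, "reaction", id = r$id,
                              reversible = tolower(as.character(r$reversible)),
                              fast = "false")
    if (length(r$genes)) {
      notes <- xml2::xml_add_child(rx, "notes")
      body <- xml2::xml_add_child(notes, "body",
                                  xmlns = "http://www.w3.org/1999/xhtml")
      xml2::xml_add_child(body, "p",
                          paste("GENE_ASSOCIATION:",
                                paste(r$genes, collapse = " or ")))
    }
    lre <- xml2::xml_add_child(rx, "listOfReactants")
    for (i in seq_along(r$educts)) {
      xml2::xml_add_child(lre, "speciesReference",
                          species = sbml_sid(names(r$educts)[i]),
                          stoichiometry = format(r$educts[[i]], digits = 17),
                          constant = "true")
    }
    lpr <- xml2::xml_add_child(rx, "listOfProducts")
    for (i in seq_along(r$products)) {
      xml2::xml_add_child(lpr, "speciesReference",
                          species = sbml_sid(names(r$products)[i]),
                          stoichiometry = format(r$products[[i]], digits = 17),
                          constant = "true")
    }
  }
  xml2::write_xml(doc, path)
  invisible(path)
}

# flatten a boolean gene-association string like "(A and B) or C" to the
# plain gene set {A, B, C}
flatten_gpr <- function(gpr) {
  tokens <- strsplit(gsub("[()]", " ", gpr), "[[:space:]]+")[[1]]
  tokens <- tokens[nzchar(tokens)]
  sort(unique(tokens[!tolower(tokens) %in% c("and", "or")]))
}

#' Parse a stoichiometric model file
#'
#' Reads either the JSON reaction schema written by [write_model_json()] or
#' an SBML level 3 file. Boolean gene-association rules are flattened to
#' plain gene sets; reversibility is read from the model. Reactions lacking
#' educts or products are rejected with a warning naming their ids.
#'
#' @param path file path (`.json` / `.xml` / `.sbml`; the format is sniffed
#'   from the content).
#' @return a `stoich_model`.
#' @export
parse_model <- function(path) {
  if (!file.exists(path)) stop(sprintf("no such file: %s", path),
                               call. = FALSE)
  head <- paste(readLines(path, n = 5L, warn = FALSE), collapse = "")
  if (grepl("^\\s*<", head)) parse_model_sbml(path) else parse_model_json(path)
}

parse_model_json <- function(path) {
  rxns <- tryCatch(jsonlite::read_json(path, simplifyVector = FALSE),
                   error = function(e) {
                     stop(sprintf("unparsable JSON model '%s': %s",
                                  path, conditionMessage(e)), call. = FALSE)
                   })
  build_reactions(lapply(rxns, function(r) {
    side <- function(s) {
      if (!length(s)) return(numeric())
      stats::setNames(vapply(s, function(e) as.numeric(e$coef), 0),
                      vapply(s, function(e) as.character(e$met), ""))
    }
    list(id = as.character(r$id), educts = side(r$educts),
         products = side(r$products),
         genes = as.character(unlist(r$genes)),
         reversible = isTRUE(r$reversible))
  }))
}

parse_model_sbml <- function(path) {
  doc <- tryCatch(xml2::read_xml(path), error = function(e) {
    stop(sprintf("unparsable SBML '%s': %s", path, conditionMessage(e)),
         call. = FALSE)
  })
  xml2::xml_ns_strip(doc)
  sp <- xml2::xml_find_all(doc, ".//listOfSpecies/species")
  sid <- xml2::xml_attr(sp, "id")
  sname <- xml2::xml_attr(sp, "name")
  met_of <- stats::setNames(ifelse(is.na(sname) | !nzchar(sname), sid, sname),
                            sid)
  rx <- xml2::xml_find_all(doc, ".//listOfReactions/reaction")
  build_reactions(lapply(rx, function(r) {
    side <- function(xpath) {
      refs <- xml2::xml_find_all(r, xpath)
      if (!length(refs)) return(numeric())
      ids <- xml2::xml_attr(refs, "species")
      coefs <- as.numeric(xml2::xml_attr(refs, "stoichiometry"))
      coefs[is.na(coefs)] <- 1
      mets <- ifelse(ids %in% names(met_of), met_of[ids], ids)
      stats::setNames(coefs, mets)
    }
    notes <- xml2::xml_text(xml2::xml_find_all(r, ".//notes//p"))
    ga <- notes[grepl("GENE_ASSOCIATION:", notes, fixed = TRUE)]
    genes <- if (length(ga)) {
      flatten_gpr(sub(".*GENE_ASSOCIATION:", "", ga[1]))
    } else {
      character()
    }
    list(id = xml2::xml_attr(r, "id"),
         educts = side("./listOfReactants/speciesReference"),
         products = side("./listOfProducts/speciesReference"),
         genes = genes,
         reversible = identical(xml2::xml_attr(r, "reversible"), "true"))
  }))
}

build_reactions <- function(specs) {
  bad <- vapply(specs, function(s) {
    length(s$educts) == 0L || length(s$products) == 0L
  }, TRUE)
  if (any(bad)) {
    warning(sprintf("rejected reaction(s) lacking a side: %s",
                    paste(vapply(specs[bad], `[[`, "", "id"),
                          collapse = ", ")))
    specs <- specs[!bad]
  }
  if (!length(specs)) stop("model contains no valid reactions", call. = FALSE)
  stoich_model(lapply(specs, function(s) {
    reaction(s$id, s$educts, s$products, genes = s$genes,
             reversible = s$reversible)
  }))
}

#' Map measured feature ids into a model universe
#'
#' Applies a two-column mapping table (`source`, `target`) to a list of
#' measured feature ids, reporting which features matched a model id and
#' why the others did not. Conflicting duplicate mappings (one source id to
#' several targets) are an error; many-to-one mappings (several sources onto
#' one target) collapse with a warning.
#'
#' @param features character vector of measured feature ids.
#' @param mapping data frame with columns `source` and `target`.
#' @param universe optional character vector of valid model ids; when given,
#'   targets outside it count as unmatched.
#' @return list with `matched` (data frame `source`, `target`) and
#'   `unmatched` (data frame `feature`, `reason`).
#' @export
map_identifiers <- function(features, mapping, universe = NULL) {
  if (!all(c("source", "target") %in% colnames(mapping))) {
    stop("mapping table needs `source` and `target` columns", call. = FALSE)
  }
  mapping <- unique(mapping[, c("source", "target")])
  dup <- unique(mapping$source[duplicated(mapping$source)])
  if (length(dup)) {
    stop(sprintf("conflicting mappings for source id(s): %s",
                 paste(dup, collapse = ", ")), call. = FALSE)
  }
  tgt <- stats::setNames(mapping$target, mapping$source)
  hit <- features %in% names(tgt)
  target <- unname(tgt[features[hit]])
  reason <- rep("no mapping", sum(!hit))
  unmatched <- data.frame(feature = features[!hit], reason = reason,
                          stringsAsFactors = FALSE)
  matched <- data.frame(source = features[hit], target = target,
                        stringsAsFactors = FALSE)
  if (!is.null(universe)) {
    out <- !matched$target %in% universe
    if (any(out)) {
      unmatched <- rbind(unmatched,
                         data.frame(feature = matched$source[out],
                                    reason = "target not in model universe",
                                    stringsAsFactors = FALSE))
      matched <- matched[!out, , drop = FALSE]
    }
  }
  collapsed <- unique(matched$target[duplicated(matched$target)])
  if (length(collapsed)) {
    warning(sprintf("many-to-one mapping collapsed onto target(s): %s",
                    paste(collapsed, collapse = ", ")))
  }
  rownames(matched) <- NULL
  rownames(unmatched) <- NULL
  list(matched = matched, unmatched = unmatched)
}
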