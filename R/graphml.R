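# GraphML interchange for integrative networks. Vertex attributes: vkind,
# measured, fc_k / sig_k / color_k for k = 1..5; edge attributes:
# provenance, reaction_id, directed. Empty fold-change slots are encoded by
# omitting the <data> element, so the round trip is lossless including NAs.

fmt_num <- function(x) formatC(x, digits = 17, format = "g")

#' Export an integrative network as GraphML
#'
#' The export is lossless: [parse_graphml()] reconstructs the vertex table,
#' edge table and all per-comparison fold-change, significance and color
#' slots exactly, including empty slots.
#'
#' @param network an `integrative_network`.
#' @param path file path.
#' @return `path`, invisibly.
#' @export
export_graphml <- function(network, path) {
  stopifnot(inherits(network, "integrative_network"))
  k <- network$n_comparisons
  doc <- xml2::xml_new_root(
    "graphml", xmlns = "http://graphml.graphdrawing.org/xmlns")
  key <- function(id, dom, name, type) {
    xml2::xml_add_child(doc, "key", id = id, `for` = dom,
                        attr.name = name, attr.type = type)
  }
  key("v_vkind", "node", "vkind", "string")
  key("v_measured", "node", "measured", "boolean")
  for (i in seq_len(k)) {
    key(sprintf("v_fc_%d", i), "node", sprintf("fc_%d", i), "double")
    key(sprintf("v_sig_%d", i), "node", sprintf("sig_%d", i), "boolean")
    key(sprintf("v_color_%d", i), "node", sprintf("color_%d", i), "string")
  }
  key("e_provenance", "edge", "provenance", "string")
  key("e_reaction_id", "edge", "reaction_id", "string")
  key("e_directed", "edge", "directed", "boolean")
  g <- xml2::xml_add_child(doc, "graph", id = "G", edgedefault = "undirected")
  dat <- function(node, keyid, value) {
    xml2::xml_add_child(node, "data", value, key = keyid)
  }
  v <- network$vertices
  for (i in seq_len(nrow(v))) {
    nd <- xml2::xml_add_child(g, "node", id = v$id[i])
    dat(nd, "v_vkind", v$vkind[i])
    dat(nd, "v_measured", tolower(as.character(v$measured[i])))
    for (j in seq_len(k)) {
      if (!is.na(network$fc[i, j])) {
        dat(nd, sprintf("v_fc_%d", j), fmt_num(network$fc[i, j]))
      }
      if (!is.na(network$sig[i, j])) {
        dat(nd, sprintf("v_sig_%d", j),
            tolower(as.character(network$sig[i, j])))
      }
      if (!is.na(network$color[i, j])) {
        dat(nd, sprintf("v_color_%d", j), network$color[i, j])
      }
    }
  }
  e <- network$edges
  for (i in seq_len(nrow(e))) {
    ed <- xml2::xml_add_child(g, "edge", source = e$from[i], target = e$to[i])
    dat(ed, "e_provenance", e$provenance[i])
    if (!is.na(e$reaction_id[i])) {
      dat(ed, "e_reaction_id", e$reaction_id[i])
    }
    dat(ed, "e_directed", tolower(as.character(e$directed[i])))
  }
  xml2::write_xml(doc, path)
  invisible(path)
}

#' @rdname export_graphml
#' @export
parse_graphml <- function(path) {
  doc <- xml2::read_xml(path)
  xml2::xml_ns_strip(doc)
  keys <- xml2::xml_find_all(doc, "./key")
  key_name <- stats::setNames(xml2::xml_attr(keys, "attr.name"),
                              xml2::xml_attr(keys, "id"))
  get_data <- function(node) {
    d <- xml2::xml_find_all(node, "./data")
    stats::setNames(xml2::xml_text(d),
                    unname(key_name[xml2::xml_attr(d, "key")]))
  }
  nodes <- xml2::xml_find_all(doc, "./graph/node")
  nd <- lapply(nodes, get_data)
  ids <- xml2::xml_attr(nodes, "id")
  pull <- function(data_list, name, default = NA_character_) {
    vapply(data_list, function(d) {
      if (name %in% names(d)) d[[name]] else default
    }, "")
  }
  vertices <- data.frame(
    id = ids,
    vkind = pull(nd, "vkind"),
    measured = pull(nd, "measured") == "true",
    stringsAsFactors = FALSE)
  edges_xml <- xml2::xml_find_all(doc, "./graph/edge")
  ed <- lapply(edges_xml, get_data)
  edges <- if (length(ed)) {
    data.frame(from = xml2::xml_attr(edges_xml, "source"),
               to = xml2::xml_attr(edges_xml, "target"),
               provenance = pull(ed, "provenance"),
               reaction_id = pull(ed, "reaction_id"),
               directed = pull(ed, "directed") == "true",
               stringsAsFactors = FALSE)
  } else {
    empty_edges()
  }
  fc_keys <- grep("^fc_", unname(key_name), value = TRUE)
  k <- max(c(length(fc_keys), N_COMPARISONS))
  net <- new_network(vertices, edges, n_comparisons = k)
  for (j in seq_len(k)) {
    fc <- pull(nd, sprintf("fc_%d", j))
    sig <- pull(nd, sprintf("sig_%d", j))
    col <- pull(nd, sprintf("color_%d", j))
    net$fc[, j] <- as.numeric(fc)
    net$sig[, j] <- ifelse(is.na(sig), NA, sig == "true")
    net$color[, j] <- col
  }
  net
}
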