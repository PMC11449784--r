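test_that("model files round-trip through JSON and SBML", {
  model <- make_toy_model(1, 7)
  fj <- tempfile(fileext = ".json")
  fs <- tempfile(fileext = ".xml")
  write_model_json(model, fj)
  write_model_sbml(model, fs)
  expect_identical(parse_model(fj), model)
  expect_identical(parse_model(fs), model)
  # sanitized SBML ids preserve metabolite names like 4-aminobutanal
  expect_true("4-aminobutanal" %in% parse_model(fs)$metabolites)
})

test_that("gene-association rules flatten to plain gene sets", {
  expect_identical(flatten_gpr("(A and B) or C"), c("A", "B", "C"))
  expect_identical(flatten_gpr("GAD1 or GAD2"), c("GAD1", "GAD2"))
  expect_identical(flatten_gpr("X"), "X")
})

test_that("one-sided reactions are rejected with their ids logged", {
  f <- tempfile(fileext = ".json")
  writeLines(paste0(
    '[{"id":"ok","educts":[{"met":"a","coef":1}],',
    '"products":[{"met":"b","coef":1}],"genes":["g1"],"reversible":false},',
    '{"id":"half","educts":[{"met":"a","coef":1}],',
    '"products":[],"genes":[],"reversible":false}]'), f)
  expect_warning(model <- parse_model(f), "half")
  expect_identical(names(model$reactions), "ok")
  expect_error(parse_model(tempfile()), "no such file")
})

test_that("identifier mapping reports matches, reasons and conflicts", {
  model <- make_toy_model(1, 0)
  # identity mapping over model ids matches everything
  idmap <- data.frame(source = model$genes, target = model$genes)
  res <- map_identifiers(model$genes, idmap, universe = model$genes)
  expect_equal(nrow(res$matched), length(model$genes))
  expect_equal(nrow(res$unmatched), 0L)
  # empty mapping: everything unmatched
  res0 <- map_identifiers(c("a", "b"),
                          data.frame(source = character(),
                                     target = character()))
  expect_equal(nrow(res0$matched), 0L)
  expect_equal(nrow(res0$unmatched), 2L)
  # 3 features, 2 mappable
  mp <- data.frame(source = c("hmdb1", "hmdb2"),
                   target = c("GABA", "putrescine"))
  res2 <- map_identifiers(c("hmdb1", "hmdb2", "hmdb3"), mp,
                          universe = model$metabolites)
  expect_equal(res2$matched$target, c("GABA", "putrescine"))
  expect_equal(res2$unmatched$feature, "hmdb3")
  # conflicting duplicate mapping errors; many-to-one warns
  expect_error(map_identifiers("a", data.frame(source = c("a", "a"),
                                               target = c("x", "y"))),
               "conflicting")
  expect_warning(map_identifiers(c("a", "b"),
                                 data.frame(source = c("a", "b"),
                                            target = c("x", "x"))),
                 "many-to-one")
})

test_that("reaction extraction and measured-entity filtering follow set rules", {
  model <- make_toy_model(1, 0)
  got <- extract_reactions(model, "GAD1")
  expect_length(got, 1L)
  expect_identical(got[[1]]$id, "R_GAD")
  expect_length(extract_reactions(model, character()), 0L)
  expect_length(extract_reactions(model, model$genes),
                length(model$reactions))
  rxns <- model$reactions
  # no measured gene, no measured metabolite: removed in both modes
  expect_length(filter_measured(rxns, character(), character(), "or"), 0L)
  expect_length(filter_measured(rxns, character(), character(), "and"), 0L)
  # measured gene only: kept under or, dropped under and
  expect_length(filter_measured(rxns["R_GAD"], "GAD1", character(), "or"), 1L)
  expect_length(filter_measured(rxns["R_GAD"], "GAD1", character(), "and"),
                0L)
})

test_that("a single reaction assembles into the contract's vertex/edge set", {
  r <- reaction("r1", c(E = 1), c(P = 1), genes = "G")
  net <- assemble_network(list(r), measured_genes = "G",
                          measured_metabolites = c("E", "P"))
  expect_setequal(net$vertices$id, c("G", "E", "P"))
  keys <- edge_keys(net)
  expect_setequal(keys, c("E|P|reaction|r1|TRUE",
                          "E|G|reaction|r1|FALSE",
                          "G|P|reaction|r1|FALSE"))
  # unmeasured metabolite in one reaction only: no connector
  net2 <- assemble_network(list(r), "G", "E")
  expect_false("P" %in% net2$vertices$id)
  # blocklisted educt disappears from vertices and edges
  net3 <- assemble_network(list(r), "G", c("E", "P"),
                           currency_blocklist = "E")
  expect_false("E" %in% net3$vertices$id)
  expect_false(any(net3$edges$from == "E" | net3$edges$to == "E"))
})

test_that("assembly equals the brute-force contract oracle on random models", {
  for (s in 1:100) {
    model <- random_model(s)
    set.seed(s + 5000)
    mg <- sample(model$genes, min(length(model$genes), sample(0:6, 1)))
    mm <- sample(model$metabolites,
                 min(length(model$metabolites), sample(0:6, 1)))
    rxns <- filter_measured(extract_reactions(model, mg), mg, mm)
    net <- assemble_network(rxns, mg, mm, currency_blocklist = character())
    oracle <- assemble_oracle(rxns, mg, mm, blocklist = character())
    expect_identical(sort(net$vertices$id), oracle$vertices)
    expect_identical(edge_keys(net), oracle$edges)
  }
})

test_that("enlarging the measured sets never removes vertices or edges", {
  model <- random_model(7, max_reactions = 15)
  mg1 <- model$genes[1:2]
  mm1 <- model$metabolites[1:3]
  rx1 <- filter_measured(extract_reactions(model, mg1), mg1, mm1)
  n1 <- assemble_network(rx1, mg1, mm1, currency_blocklist = character())
  mg2 <- model$genes
  mm2 <- model$metabolites
  rx2 <- filter_measured(extract_reactions(model, mg2), mg2, mm2)
  n2 <- assemble_network(rx2, mg2, mm2, currency_blocklist = character())
  expect_true(all(n1$vertices$id %in% n2$vertices$id))
  reaction_keys <- function(net) {
    k <- edge_keys(net)
    k[grepl("\\|reaction\\|", k)]
  }
  expect_true(all(reaction_keys(n1) %in% reaction_keys(n2)))
})

test_that("PPI enrichment adds only gene-gene edges between present vertices", {
  model <- make_toy_model(1, 0)
  rxns <- model$reactions
  net <- assemble_network(rxns, model$genes, model$metabolites)
  e0 <- n_edges(net)
  ok <- data.frame(entity_a = "GAD1", entity_b = "ODC1")
  net1 <- add_ppi(net, ok)
  expect_equal(n_edges(net1), e0 + 1L)
  expect_equal(net1$ppi_skipped, 0L)
  # absent endpoint: skipped and counted
  bad <- data.frame(entity_a = "GAD1", entity_b = "NOT_PRESENT")
  net2 <- add_ppi(net, bad)
  expect_equal(n_edges(net2), e0)
  expect_equal(net2$ppi_skipped, 1L)
  # duplicates (either orientation) collapse; self-loops dropped
  dup <- data.frame(entity_a = c("GAD1", "ODC1", "GAD1"),
                    entity_b = c("ODC1", "GAD1", "GAD1"))
  net3 <- add_ppi(net, dup)
  expect_equal(n_edges(net3), e0 + 1L)
  # empty table: identity
  net4 <- add_ppi(net, make_ppi(model, 0))
  expect_equal(n_edges(net4), e0)
  # metabolite endpoints never accepted
  met <- data.frame(entity_a = "GABA", entity_b = "GAD1")
  expect_equal(n_edges(add_ppi(net, met)), e0)
})

test_that("fold-change vectors attach to measured vertices only", {
  model <- make_toy_model(1, 0)
  net <- assemble_network(model$reactions, model$genes, model$metabolites)
  res <- data.frame(feature = rep("GABA", 5), comparison = 1:5,
                    log2FC = c(-2, -1, 0, 1, 2),
                    significant = c(TRUE, FALSE, TRUE, FALSE, TRUE))
  net1 <- attach_fold_changes(net, res, clip = 2)
  expect_equal(unname(net1$fc["GABA", ]), c(-2, -1, 0, 1, 2))
  expect_equal(unname(net1$color["GABA", 1]), "#0000FF")
  expect_equal(unname(net1$color["GABA", 2]), "#BEBEBE")
  expect_equal(unname(net1$color["GABA", 3]), "#FFFFFF")
  # untouched vertices keep empty slots and gray colors
  expect_true(all(is.na(net1$fc["GAD1", ])))
  expect_true(all(net1$color["GAD1", ] == "#BEBEBE"))
  # unknown features are ignored with a count
  res2 <- rbind(res, data.frame(feature = "nope", comparison = 1,
                                log2FC = 1, significant = TRUE))
  net2 <- attach_fold_changes(net, res2, clip = 2)
  expect_equal(net2$unmatched_results, 1L)
  # gene vertices are always measured; connectors carry no fold changes
  expect_true(all(net1$vertices$measured[net1$vertices$vkind == "gene"]))
  conn <- net1$vertices$vkind == "connector"
  expect_true(all(is.na(net1$fc[conn, ])))
})

test_that("fold-change colors form an odd-symmetric diverging scale", {
  expect_identical(fc_to_color(0, TRUE, clip = 2), "#FFFFFF")
  expect_identical(fc_to_color(-2, TRUE, clip = 2), "#0000FF")
  expect_identical(fc_to_color(2, TRUE, clip = 2), "#FF0000")
  # saturation beyond the clip
  expect_identical(fc_to_color(-7, TRUE, clip = 2), "#0000FF")
  expect_identical(fc_to_color(10, TRUE, clip = 2), "#FF0000")
  # non-significant is gray regardless of magnitude
  expect_identical(fc_to_color(3, FALSE, clip = 2), "#BEBEBE")
  # hue mirror: color(-x) swaps the red and blue channels of color(+x)
  for (x in c(0.3, 0.8, 1.5, 1.9)) {
    up <- grDevices::col2rgb(fc_to_color(x, TRUE, clip = 2))
    dn <- grDevices::col2rgb(fc_to_color(-x, TRUE, clip = 2))
    expect_equal(unname(up["red", ]), unname(dn["blue", ]))
    expect_equal(unname(up["green", ]), unname(dn["green", ]))
    expect_equal(unname(up["blue", ]), unname(dn["red", ]))
  }
  expect_error(fc_to_color(NaN, TRUE, 2), "finite")
  expect_error(fc_to_color(1, TRUE, clip = 0), "> 0")
})
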