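# Independent oracles and fixture builders used across the suite.

# Brute-force Benjamini-Hochberg step-up: sort, scale by n/rank, enforce
# monotonicity from the largest rank down, cap at 1, restore input order.
bh_oracle <- function(p) {
  n <- length(p)
  ord <- order(p)
  ranked <- (n / seq_len(n)) * p[ord]
  if (n > 1L) {
    for (i in (n - 1L):1L) {
      ranked[i] <- min(ranked[i], ranked[i + 1L])
    }
  }
  out <- numeric(n)
  out[ord] <- pmin(ranked, 1)
  out
}

# Brute-force enumeration of the network-assembly contract, written
# independently of assemble_network(): returns sorted vertex ids and a
# sorted edge key set.
assemble_oracle <- function(reactions, measured_genes, measured_metabolites,
                            blocklist = currency_metabolites(),
                            bridge_min = 2L) {
  parts <- lapply(reactions, function(r) {
    setdiff(unique(c(names(r$educts), names(r$products))), blocklist)
  })
  count <- table(unlist(parts))
  vset <- character()
  for (r in reactions) {
    vset <- union(vset, intersect(r$genes, measured_genes))
  }
  vset <- union(vset, intersect(names(count), measured_metabolites))
  unmeasured <- setdiff(names(count), measured_metabolites)
  vset <- union(vset, unmeasured[count[unmeasured] >= bridge_min])
  keys <- character()
  for (i in seq_along(reactions)) {
    r <- reactions[[i]]
    ed <- intersect(setdiff(names(r$educts), blocklist), vset)
    pr <- intersect(setdiff(names(r$products), blocklist), vset)
    for (a in ed) for (b in pr) {
      if (a != b) {
        keys <- c(keys, paste(a, b, "reaction", r$id, "TRUE", sep = "|"))
        if (r$reversible) {
          keys <- c(keys, paste(b, a, "reaction", r$id, "TRUE", sep = "|"))
        }
      }
    }
    for (g in intersect(r$genes, measured_genes)) {
      for (m in intersect(parts[[i]], vset)) {
        ends <- sort(c(g, m))
        keys <- c(keys, paste(ends[1], ends[2], "reaction", r$id, "FALSE",
                              sep = "|"))
      }
    }
  }
  keys <- sort(unique(keys))
  touched <- unlist(lapply(strsplit(keys, "|", fixed = TRUE), `[`, 1:2))
  if (is.null(touched)) touched <- character(0)
  list(vertices = sort(intersect(vset, unique(touched))), edges = keys)
}

edge_keys <- function(net) {
  sort(paste(net$edges$from, net$edges$to, net$edges$provenance,
             ifelse(is.na(net$edges$reaction_id), "NA",
                    net$edges$reaction_id),
             net$edges$directed, sep = "|"))
}

# random small models for property tests
random_model <- function(seed, max_reactions = 20) {
  set.seed(seed)
  mets <- sprintf("m%02d", 1:10)
  genes <- sprintf("g%02d", 1:8)
  n <- sample(1:max_reactions, 1)
  rxns <- lapply(seq_len(n), function(i) {
    pool <- sample(mets, sample(2:5, 1))
    ne <- sample(seq_len(length(pool) - 1L), 1)
    reaction(sprintf("r%03d", i),
             setNames(rep(1, ne), pool[seq_len(ne)]),
             setNames(rep(1, length(pool) - ne), pool[-seq_len(ne)]),
             genes = sample(genes, sample(0:3, 1)),
             reversible = runif(1) < 0.3)
  })
  stoich_model(rxns)
}

# crafted abundance fixture: explicit values/detection for QC unit tests
make_abund <- function(values, detected = NULL, lod = NULL,
                       kind = "metabolite", scale = "raw") {
  if (is.null(lod) && kind == "metabolite") {
    lod <- setNames(rep(1e-6, nrow(values)), rownames(values))
  }
  abundance_matrix(values, detected = detected, lod = lod, kind = kind,
                   scale = scale)
}

toy_sample_sheet <- function(n_per_tp = 4,
                             tps = c("d0", "d7", "d16", "d27", "d50", "d100"),
                             batches = c("B1", "B2")) {
  df <- expand.grid(rep = seq_len(n_per_tp), time_point = tps,
                    stringsAsFactors = FALSE)
  df$sample_id <- sprintf("%s_s%d", df$time_point, df$rep)
  df$condition <- "CTRL"
  df$batch <- batches[(df$rep - 1L) %% length(batches) + 1L]
  df$sex <- "F"
  df[, c("sample_id", "time_point", "condition", "batch", "sex")]
}
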