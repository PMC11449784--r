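#' Longitudinal two-condition study design
#'
#' Describes the sampling layout the synthetic generator emulates: an ordered
#' set of differentiation time points, case/control conditions, cell lines
#' nested in batches, and replicates per (time point, condition, line) cell.
#' The defaults mirror a cortical-differentiation study design with six time
#' points, two conditions and two culture batches.
#'
#' @param time_points ordered character vector of time-point labels.
#' @param conditions character vector of condition labels.
#' @param n_lines_per_condition number of cell lines per condition.
#' @param batches character vector of batch labels; lines are assigned to
#'   batches round-robin.
#' @param replicates_per_cell samples per line at each time point.
#' @return a `study_design` object.
#' @examples
#' design <- study_design(n_lines_per_condition = 3)
#' head(design_samples(design))
#' @export
study_design <- function(time_points = c("d0", "d7", "d16", "d27", "d50", "d100"),
                         conditions = c("CTRL", "SCZ"),
                         n_lines_per_condition = 4,
                         batches = c("B1", "B2"),
                         replicates_per_cell = 1) {
  if (length(time_points) < 2L) stop("need >= 2 time points", call. = FALSE)
  if (length(conditions) < 1L) stop("need >= 1 condition", call. = FALSE)
  if (n_lines_per_condition < 1L || replicates_per_cell < 1L) {
    stop("every (time point, condition) cell needs >= 1 sample",
         call. = FALSE)
  }
  if (length(batches) < 1L) stop("need >= 1 batch", call. = FALSE)
  structure(list(time_points = as.character(time_points),
                 conditions = as.character(conditions),
                 n_lines_per_condition = as.integer(n_lines_per_condition),
                 batches = as.character(batches),
                 replicates_per_cell = as.integer(replicates_per_cell)),
            class = "study_design")
}

#' @rdname study_design
#' @param design a `study_design`.
#' @return `design_samples()` returns the fully expanded sample sheet: one
#'   row per sample with columns `sample_id`, `time_point`, `condition`,
#'   `batch`, `sex`, `line`.
#' @export
design_samples <- function(design) {
  stopifnot(inherits(design, "study_design"))
  lines <- do.call(rbind, lapply(seq_along(design$conditions), function(ci) {
    cond <- design$conditions[ci]
    idx <- seq_len(design$n_lines_per_condition)
    data.frame(line = sprintf("%s_L%d", cond, idx),
               condition = cond,
               batch = design$batches[(idx - 1L) %% length(design$batches) + 1L],
               sex = c("F", "M")[(idx - 1L) %% 2L + 1L],
               stringsAsFactors = FALSE)
  }))
  grid <- expand.grid(rep = seq_len(design$replicates_per_cell),
                      line = lines$line,
                      time_point = design$time_points,
                      stringsAsFactors = FALSE)
  grid <- merge(grid, lines, by = "line", sort = FALSE)
  grid$sample_id <- sprintf("%s_%s_r%d", grid$line, grid$time_point, grid$rep)
  # stable ordering: time point, condition, line, replicate
  grid <- grid[order(match(grid$time_point, design$time_points),
                     match(grid$condition, design$conditions),
                     grid$line, grid$rep), ]
  rownames(grid) <- NULL
  grid[, c("sample_id", "time_point", "condition", "batch", "sex", "line")]
}

#' Planted differential effect
#'
#' Describes a log2 shift applied to one feature from a given consecutive
#' comparison onward (the shift is cumulative: a shift at comparison `k`
#' moves all time points after the k-th), optionally restricted to one
#' condition.
#'
#' @param feature feature id (gene or metabolite).
#' @param comparison consecutive-comparison index `k` in `1..(T-1)` for `T`
#'   time points.
#' @param shift log2 fold change planted at that transition.
#' @param condition condition label the effect is restricted to, or `NA`
#'   for all conditions.
#' @param kind `"gene"`, `"metabolite"`, or `NA` to match by feature id.
#' @return one-row data frame; rows can be `rbind`-ed into an effect table.
#' @export
planted_effect <- function(feature, comparison, shift, condition = NA,
                           kind = NA) {
  if (!is.finite(shift)) stop("`shift` must be finite", call. = FALSE)
  if (comparison < 1L) stop("`comparison` must be >= 1", call. = FALSE)
  data.frame(feature = as.character(feature),
             comparison = as.integer(comparison),
             shift = as.numeric(shift),
             condition = as.character(condition),
             kind = as.character(kind),
             stringsAsFactors = FALSE)
}

#' Default rosette-stage effect table for the toy model
#'
#' Plants condition-specific shifts of magnitude `shift` on the core-motif
#' genes and metabolites at the rosette-stage transitions (comparisons 2 and
#' 3): the canonical glutamate-decarboxylation route (GAD1, GAD2, GABA) goes
#' down while the compensatory ornithine/putrescine route (ODC1, AOC2,
#' ALDH9A1, SAT1, ALDH1A1, ornithine, putrescine) goes up.
#'
#' @param shift magnitude of the planted log2 shifts.
#' @param condition condition label the effects are restricted to.
#' @return effect table (data frame of [planted_effect()] rows).
#' @export
rosette_effects <- function(shift = 2, condition = "SCZ") {
  rbind(
    planted_effect("GAD1", 2, -shift, condition, "gene"),
    planted_effect("GAD2", 2, -shift, condition, "gene"),
    planted_effect("GABA", 3, -shift, condition, "metabolite"),
    planted_effect("glutamate", 3, shift, condition, "metabolite"),
    planted_effect("ODC1", 2, shift, condition, "gene"),
    planted_effect("AOC2", 2, shift, condition, "gene"),
    planted_effect("ALDH9A1", 2, shift, condition, "gene"),
    planted_effect("SAT1", 3, shift, condition, "gene"),
    planted_effect("ALDH1A1", 3, shift, condition, "gene"),
    planted_effect("ornithine", 2, shift, condition, "metabolite"),
    planted_effect("putrescine", 3, shift, condition, "metabolite")
  )
}

#' Simulate longitudinal two-condition omics matrices
#'
#' Generates a gene and a metabolite abundance matrix over the study design.
#' Each feature gets a lognormal baseline; on the log2 scale a sample value
#' is the baseline plus the cumulative planted shifts applying to its time
#' point and condition plus Gaussian noise of standard deviation `sigma`.
#' Metabolite concentrations are censored at a per-feature LOD set to the
#' `lod_quantile` quantile of the feature's marginal distribution; censored
#' cells are reported as below-detection (`NA` value, `detected = FALSE`),
#' never as zeros.
#'
#' @param model a `stoich_model`; its gene and metabolite universes become
#'   the simulated features.
#' @param design a `study_design`.
#' @param effects effect table ([planted_effect()] rows), or `NULL`.
#' @param lod_quantile quantile (in `[0, 1)`) of each metabolite's marginal
#'   distribution used as its LOD; `0` disables censoring.
#' @param sigma log2-scale noise standard deviation.
#' @param n_extra_genes,n_extra_metabolites additional unconnected features
#'   to simulate alongside the model members.
#' @param seed integer seed; output is a pure function of all arguments.
#' @return list with elements `genes` (`abund_mat`), `metabolites`
#'   (`abund_mat`), `samples` (sample sheet data frame).
#' @export
simulate_longitudinal <- function(model, design, effects = NULL,
                                  lod_quantile = 0.1, sigma = 0.5,
                                  n_extra_genes = 0, n_extra_metabolites = 0,
                                  seed = 1) {
  stopifnot(inherits(model, "stoich_model"), inherits(design, "study_design"))
  if (lod_quantile < 0 || lod_quantile >= 1) {
    stop("`lod_quantile` must be in [0, 1)", call. = FALSE)
  }
  sheet <- design_samples(design)
  gene_ids <- c(model$genes, if (n_extra_genes > 0)
    sprintf("EXG%03d", seq_len(n_extra_genes)))
  met_ids <- c(model$metabolites, if (n_extra_metabolites > 0)
    sprintf("EXM%03d", seq_len(n_extra_metabolites)))
  if (!is.null(effects) && nrow(effects)) {
    known <- c(gene_ids, met_ids)
    bad <- setdiff(effects$feature, known)
    if (length(bad)) {
      stop(sprintf("effect references unknown feature(s): %s",
                   paste(bad, collapse = ", ")), call. = FALSE)
    }
  }
  tp_index <- match(sheet$time_point, design$time_points)

  simulate_kind <- function(ids, kind, base_mean, base_sd) {
    n <- length(ids)
    m <- nrow(sheet)
    baseline <- stats::rnorm(n, base_mean, base_sd)
    log2val <- matrix(rep(baseline, m), n, m,
                      dimnames = list(ids, sheet$sample_id))
    if (!is.null(effects) && nrow(effects)) {
      eff <- effects[is.na(effects$kind) | effects$kind == kind, , drop = FALSE]
      eff <- eff[eff$feature %in% ids, , drop = FALSE]
      for (i in seq_len(nrow(eff))) {
        hit <- tp_index > eff$comparison[i]
        if (!is.na(eff$condition[i])) {
          hit <- hit & sheet$condition == eff$condition[i]
        }
        log2val[eff$feature[i], hit] <- log2val[eff$feature[i], hit] +
          eff$shift[i]
      }
    }
    log2val + matrix(stats::rnorm(n * m, 0, sigma), n, m)
  }

  with_seed(seed, {
    gene_log2 <- simulate_kind(gene_ids, "gene", base_mean = 8, base_sd = 2)
    met_log2 <- simulate_kind(met_ids, "metabolite", base_mean = 2,
                              base_sd = 1.5)
    met_raw <- 2^met_log2
    lod <- apply(met_raw, 1, stats::quantile, probs = lod_quantile,
                 names = FALSE)
    # keep LODs strictly positive even at quantile 0
    lod <- pmax(lod, .Machine$double.xmin)
    names(lod) <- met_ids
    detected <- met_raw >= lod[row(met_raw)]
    met_raw[!detected] <- NA_real_
    genes <- abundance_matrix(2^gene_log2, kind = "gene")
    mets <- abundance_matrix(met_raw, detected = detected, lod = lod,
                             kind = "metabolite")
    list(genes = genes, metabolites = mets, samples = sheet)
  })
}
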