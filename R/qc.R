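#' Group-wise 80 percent detection rule
#'
#' Retains a feature iff, in at least one sample group, the fraction of
#' detected samples reaches `threshold`. The grouping the rule is evaluated
#' over (typically time points) is a parameter; the boundary is inclusive
#' (a group at exactly the threshold retains the feature).
#'
#' @param x an `abund_mat`.
#' @param groups sample group labels: a vector aligned with the sample
#'   columns, or named by sample id.
#' @param threshold detection fraction required in at least one group
#'   (default 0.8).
#' @return the filtered `abund_mat`, feature order preserved.
#' @export
apply_80pct_rule <- function(x, groups, threshold = 0.8) {
  stopifnot(inherits(x, "abund_mat"))
  if (threshold <= 0 || threshold > 1) {
    stop("`threshold` must be in (0, 1]", call. = FALSE)
  }
  lv <- if (is.factor(groups)) levels(groups) else NULL
  groups <- resolve_labels(x, groups)
  counts <- table(factor(groups, levels = lv %||% unique(groups)))
  if (any(counts == 0)) {
    stop(sprintf("empty group(s): %s",
                 paste(names(counts)[counts == 0], collapse = ", ")),
         call. = FALSE)
  }
  frac <- vapply(unique(groups), function(g) {
    rowMeans(x$detected[, groups == g, drop = FALSE])
  }, numeric(n_features(x)))
  if (is.null(dim(frac))) frac <- matrix(frac, nrow = 1L)
  keep <- apply(frac, 1, max) >= threshold
  x[keep, ]
}

#' LOD-bounded random imputation
#'
#' Imputes below-detection cells of features that are detected at some
#' *other* time point with an independent uniform draw from
#' `[LOD/2, LOD]`; since every LOD is strictly positive, imputed values are
#' strictly positive. Detected cells are never altered; censored cells whose
#' feature is detected only within their own time point (or nowhere) are
#' left for [impute_class_mean()].
#'
#' @param x an `abund_mat` on raw scale.
#' @param groups sample time-point labels (vector aligned with columns or
#'   named by sample id); when `NULL`, any censored cell of a feature with at
#'   least one detected cell is eligible.
#' @param seed integer seed; imputation is reproducible under a fixed seed.
#' @return the `abund_mat` with eligible cells filled.
#' @export
impute_lod <- function(x, groups = NULL, seed = 1) {
  stopifnot(inherits(x, "abund_mat"))
  if (x$scale != "raw") {
    stop("LOD imputation applies to raw-scale matrices", call. = FALSE)
  }
  censored <- !x$detected & is.na(x$values)
  if (!any(censored)) return(x)
  eligible <- censored
  if (is.null(groups)) {
    has_det <- rowSums(x$detected) > 0
    eligible[] <- censored & has_det[row(censored)]
  } else {
    groups <- resolve_labels(x, groups)
    for (g in unique(groups)) {
      in_g <- groups == g
      # detected anywhere outside group g?
      det_elsewhere <- rowSums(x$detected[, !in_g, drop = FALSE]) > 0
      eligible[, in_g] <- censored[, in_g, drop = FALSE] &
        det_elsewhere[row(censored[, in_g, drop = FALSE])]
    }
  }
  idx <- which(eligible, arr.ind = TRUE)
  if (!nrow(idx)) return(x)
  feats <- rownames(x$values)[idx[, 1]]
  if (is.null(x$lod)) {
    stop(sprintf("LOD missing for eligible feature(s): %s",
                 paste(unique(feats), collapse = ", ")), call. = FALSE)
  }
  lod <- x$lod[feats]
  if (anyNA(lod)) {
    stop(sprintf("LOD missing for eligible feature(s): %s",
                 paste(unique(feats[is.na(lod)]), collapse = ", ")),
         call. = FALSE)
  }
  out <- x
  out$values[eligible] <- with_seed(seed, {
    stats::runif(nrow(idx), min = lod / 2, max = lod)
  })
  out
}

#' Class-mean imputation
#'
#' Fills each remaining missing cell with the arithmetic mean of the
#' non-missing values in its (feature, class) cell, where classes are
#' typically time points. Observed cells are unchanged.
#'
#' @param x an `abund_mat`.
#' @param classes sample class labels (vector aligned with columns or named
#'   by sample id).
#' @return the completed `abund_mat`.
#' @export
impute_class_mean <- function(x, classes) {
  stopifnot(inherits(x, "abund_mat"))
  classes <- resolve_labels(x, classes, what = "classes")
  out <- x
  miss <- is.na(x$values)
  if (!any(miss)) return(x)
  for (cl in unique(classes)) {
    in_cl <- classes == cl
    sub <- x$values[, in_cl, drop = FALSE]
    need <- which(rowSums(is.na(sub)) > 0)
    for (f in need) {
      obs <- sub[f, !is.na(sub[f, ])]
      if (!length(obs)) {
        stop(sprintf("feature '%s' has no observed value in class '%s'",
                     rownames(x$values)[f], cl), call. = FALSE)
      }
      fill <- mean(obs)
      cols <- which(in_cl)[is.na(sub[f, ])]
      out$values[f, cols] <- fill
    }
  }
  out
}

#' Batch centering within groups
#'
#' For each feature, subtracts the (group, batch) cell mean and adds back
#' the group mean, so that within every group all batch means coincide with
#' the group mean while each group's overall mean is preserved. Groups are
#' typically time points. Values are centered on the log2 scale by default
#' (raw-scale matrices are log2-transformed first); singleton (group, batch)
#' cells map onto the group mean.
#'
#' @param x a complete `abund_mat` (no missing values).
#' @param groups sample group (time point) labels.
#' @param batches sample batch labels.
#' @param scale `"log2"` (transform raw input, center, return log2 scale) or
#'   `"raw"` (center on the input scale).
#' @return the centered `abund_mat` (scale `"log2"` unless `scale = "raw"`).
#' @export
center_batches <- function(x, groups, batches, scale = c("log2", "raw")) {
  stopifnot(inherits(x, "abund_mat"))
  scale <- match.arg(scale)
  if (anyNA(x$values)) {
    stop("matrix has missing values; impute before centering", call. = FALSE)
  }
  groups <- resolve_labels(x, groups)
  batches <- resolve_labels(x, batches, what = "batches")
  out <- if (scale == "log2") as_log2(x) else x
  v <- out$values
  cell <- paste(groups, batches, sep = "\r")
  for (g in unique(groups)) {
    in_g <- groups == g
    gmean <- rowMeans(v[, in_g, drop = FALSE])
    for (cl in unique(cell[in_g])) {
      in_c <- cell == cl
      cmean <- rowMeans(v[, in_c, drop = FALSE])
      v[, in_c] <- v[, in_c, drop = FALSE] - cmean + gmean
    }
  }
  out$values <- v
  out
}

#' QC diagnostics: feature summaries and sample PCA
#'
#' Computes per-feature means and standard deviations (for the standard
#' mean-versus-SD normalization diagnostic) and a PCA of the samples
#' (observations = samples, variables = features, column-centered) via
#' singular value decomposition.
#'
#' @param x a complete `abund_mat`.
#' @param n_components number of principal components to report; at most
#'   `min(n_features, n_samples) - 1`.
#' @return a `qc_report`: list with `feature_means`, `feature_sds`, `scores`
#'   (samples x components), `explained_variance` (fractions, non-increasing)
#'   and `degenerate` (TRUE when the matrix carried no variance).
#' @export
qc_diagnostics <- function(x, n_components = 2) {
  stopifnot(inherits(x, "abund_mat"))
  if (anyNA(x$values)) {
    stop("matrix has missing values; impute before QC", call. = FALSE)
  }
  v <- x$values
  if (n_components > min(dim(v)) - 1L) {
    stop("`n_components` must be <= min(dim) - 1", call. = FALSE)
  }
  fm <- rowMeans(v)
  fs <- apply(v, 1, stats::sd)
  X <- scale(t(v), center = TRUE, scale = FALSE)
  total_var <- sum(X^2) / (nrow(X) - 1L)
  degenerate <- total_var < .Machine$double.eps
  if (degenerate) {
    warning("matrix is constant; PCA fractions undefined, returning zeros")
    scores <- matrix(0, nrow(X), n_components,
                     dimnames = list(rownames(X),
                                     paste0("PC", seq_len(n_components))))
    ev <- rep(0, n_components)
  } else {
    sv <- svd(X, nu = n_components, nv = 0)
    scores <- sv$u %*% diag(sv$d[seq_len(n_components)], n_components)
    dimnames(scores) <- list(rownames(X), paste0("PC", seq_len(n_components)))
    ev <- (sv$d^2 / sum(sv$d^2))[seq_len(n_components)]
  }
  structure(list(feature_means = fm, feature_sds = fs, scores = scores,
                 explained_variance = ev, degenerate = degenerate),
            class = "qc_report")
}

#' @export
print.qc_report <- function(x, ...) {
  cat(sprintf("<qc_report> %d features, %d samples, %d PC(s)\n",
              length(x$feature_means), nrow(x$scores), ncol(x$scores)))
  cat("  explained variance:",
      paste(sprintf("%.1f%%", 100 * x$explained_variance), collapse = ", "),
      "\n")
  invisible(x)
}

#' Full targeted-metabolomics preprocessing pipeline
#'
#' Applies, in fixed order: the group-wise 80 percent rule, LOD-bounded
#' random imputation, class-mean imputation, and batch centering within time
#' points. Groups and classes are the time points of the sample sheet.
#'
#' @param x a raw-scale metabolite `abund_mat`.
#' @param samples sample sheet data frame (`sample_id`, `time_point`,
#'   `batch`, ...).
#' @param threshold detection threshold for the 80 percent rule.
#' @param scale centering scale, see [center_batches()].
#' @param seed seed for the random imputation.
#' @return the processed `abund_mat`.
#' @export
preprocess_metabolomics <- function(x, samples, threshold = 0.8,
                                    scale = "log2", seed = 1) {
  tp <- stats::setNames(samples$time_point, samples$sample_id)
  batch <- stats::setNames(samples$batch, samples$sample_id)
  x <- apply_80pct_rule(x, tp, threshold = threshold)
  x <- impute_lod(x, groups = tp, seed = seed)
  x <- impute_class_mean(x, classes = tp)
  center_batches(x, groups = tp, batches = batch, scale = scale)
}
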