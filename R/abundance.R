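#' Abundance matrix with detection status
#'
#' A features-by-samples numeric matrix carrying, per cell, a detection flag
#' and, per metabolite feature, a limit of detection (LOD). Cells censored at
#' acquisition (below the LOD) hold `NA` in `values` with `detected = FALSE`;
#' the imputation steps ([impute_lod()], [impute_class_mean()]) later replace
#' the `NA`s while leaving the detection flags untouched, so the original
#' measurement status is never lost.
#'
#' @param values numeric matrix, features in rows, samples in columns; both
#'   dimensions must be named.
#' @param detected logical matrix of the same dimension; defaults to
#'   `!is.na(values)`.
#' @param lod named numeric vector of per-feature detection limits (strictly
#'   positive). Required when `kind = "metabolite"`.
#' @param kind `"metabolite"` or `"gene"`.
#' @param scale `"raw"` (concentrations / abundances) or `"log2"`.
#' @return An object of class `abund_mat`: a list with elements `values`,
#'   `detected`, `lod`, `kind`, `scale`.
#' @examples
#' m <- matrix(c(5, 10, NA, 8), 2, 2,
#'             dimnames = list(c("glu", "gaba"), c("s1", "s2")))
#' am <- abundance_matrix(m, lod = c(glu = 1, gaba = 2))
#' n_features(am)
#' @export
abundance_matrix <- function(values, detected = NULL, lod = NULL,
                             kind = c("metabolite", "gene"),
                             scale = c("raw", "log2")) {
  kind <- match.arg(kind)
  scale <- match.arg(scale)
  if (!is.matrix(values) || !is.numeric(values)) {
    stop("`values` must be a numeric matrix", call. = FALSE)
  }
  if (is.null(rownames(values)) || is.null(colnames(values))) {
    stop("`values` must have feature row names and sample column names",
         call. = FALSE)
  }
  if (anyDuplicated(rownames(values)) || anyDuplicated(colnames(values))) {
    stop("feature and sample ids must be unique", call. = FALSE)
  }
  if (is.null(detected)) detected <- !is.na(values)
  if (!is.logical(detected) || !identical(dim(detected), dim(values))) {
    stop("`detected` must be a logical matrix matching `values`",
         call. = FALSE)
  }
  dimnames(detected) <- dimnames(values)
  if (kind == "metabolite") {
    if (is.null(lod)) {
      stop("metabolite matrices require a per-feature `lod`", call. = FALSE)
    }
    missing <- setdiff(rownames(values), names(lod))
    if (length(missing)) {
      stop(sprintf("LOD missing for feature(s): %s",
                   paste(missing, collapse = ", ")), call. = FALSE)
    }
    lod <- lod[rownames(values)]
    if (any(!is.finite(lod)) || any(lod <= 0)) {
      stop("all LODs must be finite and > 0", call. = FALSE)
    }
    if (scale == "raw") {
      bad <- detected & !is.na(values) & values < lod[row(values)]
      if (any(bad)) {
        stop("detected cells must have value >= LOD", call. = FALSE)
      }
    }
  } else {
    lod <- lod %||% NULL
  }
  structure(list(values = values, detected = detected, lod = lod,
                 kind = kind, scale = scale),
            class = "abund_mat")
}

#' @export
print.abund_mat <- function(x, ...) {
  cat(sprintf("<abund_mat> %s matrix (%s scale): %d features x %d samples\n",
              x$kind, x$scale, nrow(x$values), ncol(x$values)))
  cat(sprintf("  below-detection cells: %d; unimputed (NA) cells: %d\n",
              sum(!x$detected), sum(is.na(x$values))))
  invisible(x)
}

#' @rdname abundance_matrix
#' @param x an `abund_mat`.
#' @export
n_features <- function(x) nrow(x$values)

#' @rdname abundance_matrix
#' @export
n_samples <- function(x) ncol(x$values)

#' @rdname abundance_matrix
#' @export
features <- function(x) rownames(x$values)

#' @rdname abundance_matrix
#' @export
samples <- function(x) colnames(x$values)

#' @export
`[.abund_mat` <- function(x, i, j, ...) {
  if (missing(i)) i <- seq_len(nrow(x$values))
  if (missing(j)) j <- seq_len(ncol(x$values))
  abundance_matrix(x$values[i, j, drop = FALSE],
                   detected = x$detected[i, j, drop = FALSE],
                   lod = x$lod, kind = x$kind, scale = x$scale)
}

#' Log2-transform an abundance matrix
#'
#' Requires a complete (fully imputed) raw-scale matrix; returns the same
#' object with `values` replaced by `log2(values)` and `scale = "log2"`.
#'
#' @param x an `abund_mat` on raw scale.
#' @return the log2-scale `abund_mat`.
#' @export
as_log2 <- function(x) {
  stopifnot(inherits(x, "abund_mat"))
  if (x$scale == "log2") return(x)
  if (anyNA(x$values)) {
    stop("matrix has unimputed cells; impute before log2 transform",
         call. = FALSE)
  }
  if (any(x$values <= 0)) {
    stop("all values must be > 0 for log2 transform", call. = FALSE)
  }
  out <- x
  out$values <- log2(x$values)
  out$scale <- "log2"
  out
}

# token used for below-detection cells in TSV interchange files
LOD_TOKEN <- "<LOD"

#' Read and write abundance matrices as TSV
#'
#' The interchange format is a TSV with features in rows and samples in
#' columns; below-detection cells are encoded as the literal token `"<LOD"`.
#' Per-feature LODs travel in a separate two-column TSV (`feature`, `lod`).
#'
#' @param x an `abund_mat`.
#' @param path file path.
#' @param lod optional named numeric LOD vector (or path to a LOD TSV) when
#'   reading a metabolite matrix.
#' @param kind,scale passed to [abundance_matrix()] when reading.
#' @return `read_abundance_tsv()` returns an `abund_mat`; the writers return
#'   `path` invisibly.
#' @export
write_abundance_tsv <- function(x, path) {
  stopifnot(inherits(x, "abund_mat"))
  vals <- matrix(as.character(x$values), nrow(x$values), ncol(x$values))
  vals[!x$detected & is.na(x$values)] <- LOD_TOKEN
  df <- data.frame(feature = features(x), vals, check.names = FALSE,
                   stringsAsFactors = FALSE)
  colnames(df) <- c("feature", samples(x))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_abundance_tsv
#' @export
read_abundance_tsv <- function(path, lod = NULL,
                               kind = c("metabolite", "gene"),
                               scale = c("raw", "log2")) {
  kind <- match.arg(kind)
  scale <- match.arg(scale)
  df <- utils::read.table(path, sep = "\t", header = TRUE,
                          check.names = FALSE, stringsAsFactors = FALSE,
                          colClasses = "character")
  if (!"feature" %in% colnames(df)) {
    stop("matrix TSV must have a `feature` column", call. = FALSE)
  }
  cells <- as.matrix(df[, setdiff(colnames(df), "feature"), drop = FALSE])
  rownames(cells) <- df$feature
  detected <- cells != LOD_TOKEN
  vals <- suppressWarnings(matrix(as.numeric(cells), nrow(cells), ncol(cells),
                                  dimnames = dimnames(cells)))
  vals[!detected] <- NA_real_
  if (is.character(lod) && length(lod) == 1L) lod <- read_lod_tsv(lod)
  abundance_matrix(vals, detected = detected, lod = lod, kind = kind,
                   scale = scale)
}

#' @rdname write_abundance_tsv
#' @export
write_lod_tsv <- function(x, path) {
  lod <- if (inherits(x, "abund_mat")) x$lod else x
  df <- data.frame(feature = names(lod), lod = unname(lod))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_abundance_tsv
#' @export
read_lod_tsv <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = TRUE,
                          stringsAsFactors = FALSE)
  stats::setNames(as.numeric(df$lod), df$feature)
}

#' Read and write the sample sheet
#'
#' The sample sheet is a CSV with columns `sample_id`, `time_point`,
#' `condition`, `batch`, `sex` (plus any extra columns, which are preserved).
#'
#' @param samples a data frame.
#' @param path file path.
#' @return `read_sample_sheet()` returns a data frame; the writer returns
#'   `path` invisibly.
#' @export
write_sample_sheet <- function(samples, path) {
  utils::write.csv(samples, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_sample_sheet
#' @export
read_sample_sheet <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("sample_id", "time_point", "condition", "batch", "sex")
  missing <- setdiff(need, colnames(df))
  if (length(missing)) {
    stop(sprintf("sample sheet is missing column(s): %s",
                 paste(missing, collapse = ", ")), call. = FALSE)
  }
  df
}
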