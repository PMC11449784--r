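#' Benjamini-Hochberg step-up adjustment
#'
#' Standard step-up adjusted p-values, capped at 1, aligned with the input
#' order (a thin validating wrapper around the stock BH adjustment).
#'
#' @param pvalues numeric vector of p-values in `[0, 1]`.
#' @return adjusted p-values in input order.
#' @export
bh_adjust <- function(pvalues) {
  if (!is.numeric(pvalues)) stop("p-values must be numeric", call. = FALSE)
  if (anyNA(pvalues) || any(pvalues < 0 | pvalues > 1)) {
    stop("all p-values must lie in [0, 1]", call. = FALSE)
  }
  stats::p.adjust(pvalues, method = "BH")
}

#' Consecutive time-point differential tables
#'
#' For every feature and every adjacent pair of time points, computes the
#' log2 fold change `mean(later) - mean(earlier)` on the log2 scale and a
#' Welch two-sample t-test p-value, then adjusts p-values by
#' Benjamini-Hochberg within each comparison (families are per comparison
#' and per feature kind; a single matrix holds one kind). Six time points
#' yield five comparisons per feature.
#'
#' @param x a complete `abund_mat` on log2 scale.
#' @param samples sample sheet data frame.
#' @param alpha significance level; `significant` is `padj < alpha`
#'   (strict).
#' @param condition optional condition label; when given, only samples of
#'   that condition enter the comparisons.
#' @return data frame with columns `feature`, `kind`, `comparison` (index
#'   `k`), `comparison_label`, `log2FC`, `p`, `padj`, `significant`,
#'   `degenerate` (TRUE where both groups had zero variance and `p` was set
#'   to 1).
#' @export
consecutive_comparisons <- function(x, samples, alpha = 0.1,
                                    condition = NULL) {
  stopifnot(inherits(x, "abund_mat"))
  if (x$scale != "log2") {
    stop("matrix must be on log2 scale (see `as_log2()`)", call. = FALSE)
  }
  if (anyNA(x$values)) {
    stop("matrix has missing values; impute first", call. = FALSE)
  }
  sheet <- samples[match(samples(x), samples$sample_id), , drop = FALSE]
  if (anyNA(sheet$sample_id)) {
    stop("sample sheet does not cover all matrix samples", call. = FALSE)
  }
  keep <- rep(TRUE, nrow(sheet))
  if (!is.null(condition)) keep <- sheet$condition == condition
  tps <- order_time_points(sheet$time_point[keep])
  if (length(tps) < 2L) stop("need >= 2 time points", call. = FALSE)
  v <- x$values
  out <- vector("list", length(tps) - 1L)
  for (k in seq_len(length(tps) - 1L)) {
    i1 <- which(keep & sheet$time_point == tps[k])
    i2 <- which(keep & sheet$time_point == tps[k + 1L])
    if (length(i1) < 2L || length(i2) < 2L) {
      stop(sprintf("time point '%s' has < 2 samples",
                   if (length(i1) < 2L) tps[k] else tps[k + 1L]),
           call. = FALSE)
    }
    g1 <- v[, i1, drop = FALSE]
    g2 <- v[, i2, drop = FALSE]
    m1 <- rowMeans(g1)
    m2 <- rowMeans(g2)
    s1 <- apply(g1, 1, stats::var)
    s2 <- apply(g2, 1, stats::var)
    degen <- s1 < .Machine$double.eps & s2 < .Machine$double.eps
    # Welch statistic computed in closed form for speed across features
    se2 <- s1 / length(i1) + s2 / length(i2)
    tstat <- (m2 - m1) / sqrt(se2)
    df <- se2^2 / (s1^2 / (length(i1)^2 * (length(i1) - 1L)) +
                   s2^2 / (length(i2)^2 * (length(i2) - 1L)))
    p <- 2 * stats::pt(abs(tstat), df, lower.tail = FALSE)
    p[degen] <- 1
    out[[k]] <- data.frame(feature = rownames(v),
                           kind = x$kind,
                           comparison = k,
                           comparison_label = paste(tps[k], "vs", tps[k + 1L]),
                           log2FC = m2 - m1,
                           p = p,
                           padj = bh_adjust(p),
                           degenerate = degen,
                           stringsAsFactors = FALSE,
                           row.names = NULL)
  }
  res <- do.call(rbind, out)
  res$significant <- res$padj < alpha
  res[, c("feature", "kind", "comparison", "comparison_label", "log2FC",
          "p", "padj", "significant", "degenerate")]
}

#' Load an externally computed differential table
#'
#' Accepts TSV exports in the common DE-table layout with columns `feature`
#' (or `gene` / first column), `log2FC` (alias `log2FoldChange`) and `padj`;
#' an optional `p` (alias `pvalue`) column is copied from `padj` when
#' absent. Rows with unparsable or missing `padj` are dropped with a message
#' naming their line numbers.
#'
#' @param path TSV file path.
#' @param kind `"gene"` or `"metabolite"`.
#' @param comparison comparison index `k` assigned to all rows.
#' @param alpha significance level applied to the loaded `padj`.
#' @return data frame in the [consecutive_comparisons()] layout.
#' @export
load_external_de <- function(path, kind = c("gene", "metabolite"),
                             comparison = 1L, alpha = 0.1) {
  kind <- match.arg(kind)
  df <- utils::read.table(path, sep = "\t", header = TRUE,
                          stringsAsFactors = FALSE, check.names = FALSE)
  if (nrow(df) == 0L) {
    warning("external DE table is empty")
    return(data.frame(feature = character(), kind = character(),
                      comparison = integer(), comparison_label = character(),
                      log2FC = numeric(), p = numeric(), padj = numeric(),
                      significant = logical(), degenerate = logical(),
                      stringsAsFactors = FALSE))
  }
  nm <- tolower(colnames(df))
  pick <- function(aliases, required = TRUE) {
    hit <- which(nm %in% aliases)
    if (!length(hit)) {
      if (required) {
        stop(sprintf("external DE table is missing column `%s`", aliases[1]),
             call. = FALSE)
      }
      return(NULL)
    }
    df[[hit[1]]]
  }
  feature <- pick(c("feature", "gene", "metabolite", "id"))
  log2fc <- suppressWarnings(as.numeric(pick(c("log2fc", "log2foldchange"))))
  padj <- suppressWarnings(as.numeric(pick(c("padj", "p.adjust", "fdr"))))
  p <- pick(c("p", "pvalue", "p.value"), required = FALSE)
  p <- if (is.null(p)) padj else suppressWarnings(as.numeric(p))
  bad <- which(is.na(padj) | is.na(log2fc))
  if (length(bad)) {
    # +1 for the header line
    message(sprintf("dropping %d malformed row(s) at line(s): %s",
                    length(bad), paste(bad + 1L, collapse = ", ")))
  }
  keep <- setdiff(seq_len(nrow(df)), bad)
  data.frame(feature = as.character(feature[keep]),
             kind = kind,
             comparison = as.integer(comparison),
             comparison_label = sprintf("external_%d", comparison),
             log2FC = log2fc[keep],
             p = ifelse(is.na(p[keep]), padj[keep], p[keep]),
             padj = padj[keep],
             significant = padj[keep] < alpha,
             degenerate = FALSE,
             stringsAsFactors = FALSE)
}

#' Re-flag significance at a new threshold
#'
#' Recomputes the `significant` column as `padj < alpha` (strict
#' inequality); nothing else is altered.
#'
#' @param results a differential table with a `padj` column.
#' @param alpha significance level.
#' @return the table with `significant` recomputed.
#' @export
flag_significant <- function(results, alpha) {
  if (!"padj" %in% colnames(results)) {
    stop("`results` must contain a `padj` column", call. = FALSE)
  }
  results$significant <- results$padj < alpha
  results
}

#' Write a differential table as TSV
#'
#' @param results differential table.
#' @param path file path.
#' @return `path`, invisibly.
#' @export
write_de_tsv <- function(results, path) {
  utils::write.table(results, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
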