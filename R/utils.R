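# internal helpers shared across modules

# Evaluate `code` under a fixed RNG state without disturbing the caller's
# stream; all generators route their randomness through this.
with_seed <- function(seed, code) {
  if (!is.numeric(seed) || length(seed) != 1L || !is.finite(seed)) {
    stop("`seed` must be a single finite number", call. = FALSE)
  }
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_old) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Resolve a sample -> label mapping given either a vector aligned with the
# matrix columns or a vector named by sample id.
resolve_labels <- function(x, labels, what = "groups") {
  ids <- samples(x)
  if (!is.null(names(labels))) {
    missing <- setdiff(ids, names(labels))
    if (length(missing)) {
      stop(sprintf("%s missing for sample(s): %s", what,
                   paste(missing, collapse = ", ")), call. = FALSE)
    }
    labels <- labels[ids]
  } else if (length(labels) != length(ids)) {
    stop(sprintf("`%s` must have one label per sample", what), call. = FALSE)
  }
  as.character(labels)
}

# Canonical ordering for time-point labels: numeric by their "d<n>" suffix
# when all labels follow that convention, otherwise order of appearance.
order_time_points <- function(tp) {
  u <- unique(as.character(tp))
  if (all(grepl("^d[0-9]+$", u))) {
    u[order(as.integer(sub("^d", "", u)))]
  } else {
    u
  }
}
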