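test_that("80% rule keeps and drops features by best group detection", {
  # 3 groups x 5 samples; crafted detection patterns with known fractions
  vals <- matrix(10, 4, 15,
                 dimnames = list(c("all", "none", "boundary", "partial"),
                                 sprintf("s%02d", 1:15)))
  groups <- rep(c("d0", "d7", "d16"), each = 5)
  det <- matrix(TRUE, 4, 15, dimnames = dimnames(vals))
  det["none", ] <- FALSE
  det["boundary", ] <- FALSE
  det["boundary", 1:4] <- TRUE            # 4/5 = 0.8 in group d0 only
  det["partial", ] <- FALSE
  det["partial", 6:8] <- TRUE             # 3/5 = 0.6 best
  vals[!det] <- NA
  x <- make_abund(vals, detected = det)
  kept <- apply_80pct_rule(x, groups)
  expect_identical(features(kept), c("all", "boundary"))
  # inclusive boundary: exactly 0.8 retains
  expect_true("boundary" %in% features(kept))
  # monotone filtering: raising the threshold never re-admits a feature
  for (th in c(0.5, 0.7, 0.9, 1)) {
    k_lo <- features(apply_80pct_rule(x, groups, threshold = th))
    for (th2 in seq(th, 1, by = 0.1)) {
      expect_true(all(features(apply_80pct_rule(x, groups, th2)) %in% k_lo))
    }
  }
  expect_error(apply_80pct_rule(x, factor(groups,
                                          levels = c("d0", "d7", "d16",
                                                     "d27"))),
               "empty group")
})

test_that("LOD imputation draws in [LOD/2, LOD] and spares detected cells", {
  vals <- matrix(c(20, NA, 30, 25,
                   5, 6, 7, 8), 2, 4, byrow = TRUE,
                 dimnames = list(c("m1", "m2"), sprintf("s%d", 1:4)))
  det <- !is.na(vals)
  groups <- c("d0", "d0", "d7", "d7")
  x <- make_abund(vals, detected = det, lod = c(m1 = 10, m2 = 1))
  out <- impute_lod(x, groups = groups, seed = 7)
  v <- out$values["m1", 2]
  expect_gte(v, 5)
  expect_lte(v, 10)
  expect_gt(v, 0)
  # detected measurements never altered
  expect_identical(out$values[det], x$values[det])
  # fully detected feature untouched
  expect_identical(out$values["m2", ], x$values["m2", ])
  # determinism
  expect_identical(impute_lod(x, groups = groups, seed = 7), out)
  # different seed, different draw (still in bounds)
  out2 <- impute_lod(x, groups = groups, seed = 8)
  expect_false(identical(out2$values["m1", 2], v))
  # missing LOD for an eligible feature is an error naming it
  x_nolod <- x
  x_nolod$lod <- c(m1 = NA_real_, m2 = 1)
  expect_error(impute_lod(x_nolod, groups = groups, seed = 1), "m1")
})

test_that("cells censored only within their own time point go to class mean", {
  # m1 detected at d0 only; its censored d0 cell is left for class-mean,
  # its d7 cells are LOD-imputed
  vals <- matrix(c(20, 30, NA, NA, NA, NA), 1, 6,
                 dimnames = list("m1", sprintf("s%d", 1:6)))
  det <- !is.na(vals)
  det[1, 3] <- FALSE
  groups <- c("d0", "d0", "d0", "d7", "d7", "d7")
  x <- make_abund(vals, detected = det, lod = c(m1 = 10))
  out <- impute_lod(x, groups = groups, seed = 1)
  expect_true(is.na(out$values[1, 3]))           # own-time-point censoring
  expect_true(all(!is.na(out$values[1, 4:6])))   # detected elsewhere
  done <- impute_class_mean(out, classes = groups)
  expect_equal(done$values[1, 3], 25)            # mean of {20, 30}
  expect_false(anyNA(done$values))
})

test_that("class-mean imputation fills with hand-computed means", {
  vals <- matrix(c(2, 4, NA,
                   10, NA, NA,
                   1, 2, 3), 3, 3, byrow = TRUE,
                 dimnames = list(c("a", "b", "c"), c("s1", "s2", "s3")))
  x <- make_abund(vals, lod = c(a = 0.1, b = 0.1, c = 0.1))
  out <- impute_class_mean(x, classes = rep("d0", 3))
  expect_equal(out$values["a", "s3"], 3)
  expect_equal(unname(out$values["b", c("s2", "s3")]), c(10, 10))
  expect_identical(out$values["c", ], x$values["c", ])
  # identity when complete
  expect_identical(impute_class_mean(out, rep("d0", 3)), out)
  # empty class errors, naming feature and class
  vals2 <- matrix(c(1, NA), 1, 2, dimnames = list("m", c("s1", "s2")))
  x2 <- make_abund(vals2, lod = c(m = 0.1))
  expect_error(impute_class_mean(x2, classes = c("d0", "d7")), "m.*d7")
})

test_that("batch centering equalizes batch means and preserves group means", {
  # hand fixture: one group, batches {1,3} and {5,7}; raw-scale centering
  vals <- matrix(c(1, 3, 5, 7), 1, 4,
                 dimnames = list("m", sprintf("s%d", 1:4)))
  x <- make_abund(vals, kind = "gene", scale = "log2")
  out <- center_batches(x, groups = rep("d0", 4),
                        batches = c("A", "A", "B", "B"), scale = "raw")
  expect_equal(mean(out$values[1, 1:2]), 4)
  expect_equal(mean(out$values[1, 3:4]), 4)
  expect_equal(mean(out$values), 4)
  # batch A {1,3} - 2 + 4 = {3,5}; batch B {5,7} - 6 + 4 = {3,5}
  expect_equal(unname(out$values[1, ]), c(3, 5, 3, 5))
  # one batch only: identity
  one <- center_batches(x, rep("d0", 4), rep("A", 4), scale = "raw")
  expect_equal(one$values, x$values)
  # idempotence and group-mean conservation on a random matrix
  set.seed(1)
  big <- matrix(2^rnorm(25 * 24, 4, 1), 25, 24,
                dimnames = list(sprintf("f%02d", 1:25),
                                sprintf("s%02d", 1:24)))
  groups <- rep(c("d0", "d7", "d16"), each = 8)
  batches <- rep(rep(c("B1", "B2"), each = 4), 3)
  xb <- make_abund(big, kind = "gene")
  c1 <- center_batches(xb, groups, batches)
  c2 <- center_batches(c1, groups, batches)
  expect_lt(max(abs(c1$values - c2$values)), 1e-12)
  for (g in unique(groups)) {
    pre <- rowMeans(log2(big)[, groups == g, drop = FALSE])
    post <- rowMeans(c1$values[, groups == g, drop = FALSE])
    expect_lt(max(abs(pre - post)), 1e-12)
    for (b in unique(batches)) {
      bm <- rowMeans(c1$values[, groups == g & batches == b, drop = FALSE])
      expect_lt(max(abs(bm - post)), 1e-12)
    }
  }
  # singleton (group, batch) cells map onto the group mean
  xs <- make_abund(matrix(c(1, 5, 9), 1, 3,
                          dimnames = list("m", c("s1", "s2", "s3"))),
                   kind = "gene", scale = "log2")
  cs <- center_batches(xs, rep("d0", 3), c("A", "A", "B"), scale = "raw")
  expect_equal(unname(cs$values[1, 3]), 5)
})

test_that("QC diagnostics match an independent eigendecomposition", {
  set.seed(42)
  vals <- matrix(rnorm(20 * 12), 20, 12,
                 dimnames = list(sprintf("f%02d", 1:20),
                                 sprintf("s%02d", 1:12)))
  x <- make_abund(vals, kind = "gene", scale = "log2")
  rep_ <- qc_diagnostics(x, n_components = 3)
  expect_equal(rep_$feature_means, rowMeans(vals))
  expect_equal(rep_$feature_sds, apply(vals, 1, sd))
  # oracle: eigendecomposition of the sample covariance
  X <- scale(t(vals), center = TRUE, scale = FALSE)
  eg <- eigen(stats::cov(X), symmetric = TRUE)
  scores_oracle <- X %*% eg$vectors[, 1:3]
  for (j in 1:3) {
    expect_lt(min(max(abs(rep_$scores[, j] - scores_oracle[, j])),
                  max(abs(rep_$scores[, j] + scores_oracle[, j]))), 1e-8)
  }
  ev_oracle <- eg$values / sum(eg$values)
  expect_equal(rep_$explained_variance, ev_oracle[1:3], tolerance = 1e-10)
  expect_true(all(diff(rep_$explained_variance) <= 1e-12))
  # rank-1 case: two perfectly correlated features explain everything
  v2 <- matrix(c(1, 2, 3, 4, 2, 4, 6, 8), 2, 4, byrow = TRUE,
               dimnames = list(c("a", "b"), sprintf("s%d", 1:4)))
  r2 <- qc_diagnostics(make_abund(v2, kind = "gene", scale = "log2"), 1)
  expect_equal(r2$explained_variance, 1)
  # constant matrix: zeros plus a warning flag
  vc <- matrix(5, 3, 4, dimnames = list(letters[1:3], sprintf("s%d", 1:4)))
  expect_warning(rc <- qc_diagnostics(make_abund(vc, kind = "gene",
                                                 scale = "log2"), 1),
                 "constant")
  expect_true(rc$degenerate)
  expect_equal(rc$explained_variance, 0)
})

test_that("full preprocessing pipeline yields a complete centered matrix", {
  model <- make_toy_model(1, 4)
  sim <- simulate_longitudinal(model, study_design(n_lines_per_condition = 3),
                               seed = 21, lod_quantile = 0.15)
  out <- preprocess_metabolomics(sim$metabolites, sim$samples, seed = 2)
  expect_false(anyNA(out$values))
  expect_identical(out$scale, "log2")
  expect_lte(n_features(out), n_features(sim$metabolites))
  # detected raw measurements reach the output as their log2 values
  common <- features(out)
  det <- sim$metabolites$detected[common, , drop = FALSE]
  # centering shifts values, but only by per-(group,batch) constants:
  # check that within each (feature, group, batch) cell the imputation
  # pipeline altered no detected cell before centering
  pre <- impute_class_mean(
    impute_lod(apply_80pct_rule(sim$metabolites,
                                setNames(sim$samples$time_point,
                                         sim$samples$sample_id)),
               groups = setNames(sim$samples$time_point,
                                 sim$samples$sample_id), seed = 2),
    classes = setNames(sim$samples$time_point, sim$samples$sample_id))
  expect_identical(pre$values[common, ][det],
                   sim$metabolites$values[common, ][det])
})
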