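# Median normalization, Dixon outlier exclusion, log + autoscale and KNN
# imputation, with hand-computed and brute-force oracles.

test_that("median normalization divides by the sample median and records it", {
  meta <- make_metadata(n_rep = 1, genotypes = "gA")[1:2, ]
  m <- rbind(c(2, 4, 8), c(5, 5, 5))
  dimnames(m) <- list(meta$sample_id, c("a", "b", "c"))
  out <- median_normalize(metab_table_from_matrix(m, "raw"))
  expect_equal(unname(abundance_matrix(out$table)[1, ]), c(0.5, 1, 2))
  expect_equal(unname(abundance_matrix(out$table)[2, ]), c(1, 1, 1))
  expect_equal(out$normalization_factors$median, c(4, 5))
  expect_null(names(out$normalization_factors$median))
  expect_identical(mt_state(out$table), "normalized")
  # second pass is a no-op: all medians of the normalized table are 1
  renorm <- median_normalize(
    metab_table_from_matrix(abundance_matrix(out$table), "raw"))
  expect_true(all(renorm$normalization_factors$median == 1))
})

test_that("median normalization rejects degenerate samples by name", {
  meta <- make_metadata(n_rep = 1, genotypes = "gA")[1:2, ]
  m <- rbind(c(NA, NA, NA), c(1, 2, 3))
  dimnames(m) <- list(meta$sample_id, c("a", "b", "c"))
  expect_error(median_normalize(metab_table_from_matrix(m, "raw")),
               meta$sample_id[1])
  m2 <- rbind(c(0, 0, 1), c(1, 2, 3))
  dimnames(m2) <- list(meta$sample_id, c("a", "b", "c"))
  expect_error(median_normalize(metab_table_from_matrix(m2, "raw")), "zero")
})

test_that("median normalization preserves within-sample rank order", {
  for (seed in 1:5) {
    meta <- make_metadata(n_rep = 2)
    tab <- make_table(meta, n_met = 12, seed = seed)
    out <- median_normalize(tab)$table
    before <- abundance_matrix(tab); after <- abundance_matrix(out)
    for (i in seq_len(nrow(before))) {
      expect_identical(order(before[i, ]), order(after[i, ]))
    }
  }
})

test_that("Dixon decisions match the hand-computed Q against the table", {
  meta <- make_metadata(n_rep = 4, genotypes = "gA",
                        times = 3)[1:4, ] # one group of 4
  m <- cbind(out_high = c(2.1, 2.2, 2.3, 5.0),   # Q = 2.7/2.9 = 0.931 > 0.829
             clean = c(2.1, 2.2, 2.3, 2.6),      # Q = 0.3/0.5 = 0.600
             constant = c(3, 3, 3, 3))           # range 0, never tested
  rownames(m) <- meta$sample_id
  res <- dixon_filter(metab_table_from_matrix(m, "raw"), meta, alpha = 0.05)
  expect_identical(res$outliers$metabolite_id, "out_high")
  expect_equal(res$outliers$q, 2.7 / 2.9, tolerance = 1e-12)
  expect_equal(res$outliers$critical, 0.829)
  expect_identical(res$outliers$value, 5.0)
  expect_true(is.na(abundance_matrix(res$table)["gA_norm_t3_r4", "out_high"]))
  expect_identical(sum(is.na(abundance_matrix(res$table))), 1L)
})

test_that("Dixon filter validates alpha and skips tiny groups with a warning", {
  meta <- make_metadata(n_rep = 2, genotypes = "gA", times = 3)[1:2, ]
  tab <- make_table(meta, n_met = 3)
  expect_error(dixon_filter(tab, meta, alpha = 1.2), "alpha")
  expect_error(dixon_filter(tab, meta, alpha = 0.03), "0.01")
  expect_warning(res <- dixon_filter(tab, meta), "fewer than 3")
  expect_identical(nrow(res$outliers), 0L)
})

test_that("Dixon removes at most one value per metabolite and group", {
  meta <- make_metadata(n_rep = 6, genotypes = "gA", times = 3)[1:6, ]
  m <- matrix(c(1, 1.1, 1.2, 1.05, 1.5, 90), ncol = 1,
              dimnames = list(meta$sample_id, "m1"))
  res <- dixon_filter(metab_table_from_matrix(m, "raw"), meta)
  expect_identical(nrow(res$outliers), 1L)
  expect_equal(res$outliers$value, 90)
  expect_true(all(res$outliers$q > res$outliers$critical))
})

test_that("log + autoscale matches the hand-computed column example", {
  meta <- make_metadata(n_rep = 1, genotypes = "gA")[1:2, ]
  m <- cbind(a = c(1, exp(2)), b = c(4, 4))
  rownames(m) <- meta$sample_id
  out <- log_autoscale(metab_table_from_matrix(m, "normalized"))
  sc <- abundance_matrix(out)
  expect_equal(unname(sc[, "a"]), c(-1, 1) / sqrt(2), tolerance = 1e-12)
  expect_equal(unname(sc[, "b"]), c(0, 0))  # constant column guard
  expect_identical(mt_state(out), "log_scaled")
})

test_that("autoscaled columns have mean 0 and unit sd; non-positive values error", {
  meta <- make_metadata(n_rep = 3)
  tab <- median_normalize(make_table(meta, n_met = 10, seed = 5))$table
  sc <- abundance_matrix(log_autoscale(tab))
  expect_true(all(abs(colMeans(sc)) < 1e-12))
  expect_true(all(abs(apply(sc, 2, sd) - 1) < 1e-12))
  bad <- abundance_matrix(tab); bad[3, 2] <- 0
  expect_error(log_autoscale(metab_table_from_matrix(bad, "normalized")),
               "Non-positive")
})

test_that("KNN imputation is a no-op without missing values and copies a twin row", {
  meta <- make_metadata(n_rep = 2)
  tab <- make_table(meta, n_met = 6, seed = 2)
  scaled <- log_autoscale(tab)
  out <- knn_impute(scaled, meta, k = 3)
  expect_equal(abundance_matrix(out$table), abundance_matrix(scaled))
  expect_identical(nrow(out$imputed), 0L)

  # duplicated metabolite rows: with k = 1 the imputed value equals the twin's
  m <- abundance_matrix(scaled)
  m[, 2] <- m[, 1]
  m[1, 1] <- NA
  out2 <- knn_impute(metab_table_from_matrix(m, "log_scaled"), meta, k = 1)
  expect_equal(abundance_matrix(out2$table)[1, 1], m[1, 2])
})

test_that("KNN imputation equals the brute-force neighbour search", {
  withr::with_seed(42, {
    meta <- make_metadata(n_rep = 2, times = c(3, 5, 7))[1:12, ]
    X <- matrix(rnorm(12 * 20), 12, 20,
                dimnames = list(meta$sample_id, sprintf("m%02d", 1:20)))
    X[4, 7] <- NA
    out <- knn_impute(metab_table_from_matrix(X, "log_scaled"), meta, k = 2)
    # brute force on metabolite rows: Euclidean over mutually observed samples
    xm <- t(X)
    target <- xm[7, ]
    cand <- setdiff(which(!is.na(X[4, ])), 7)
    d <- sapply(cand, function(i) {
      both <- !is.na(target) & !is.na(xm[i, ])
      sqrt(sum((target[both] - xm[i, both])^2) / sum(both) * 12)
    })
    nn <- cand[order(d)][1:2]
    expect_equal(abundance_matrix(out$table)[4, 7], mean(X[4, nn]))
    expect_identical(out$imputed$metabolite_id, "m07")
  })
})

test_that("imputation only fills group-supported cells and never edits observed ones", {
  withr::with_seed(9, {
    meta <- make_metadata(n_rep = 4, genotypes = "gA", times = 3)[1:4, ]
    X <- matrix(rnorm(4 * 6), 4, 6,
                dimnames = list(meta$sample_id, sprintf("m%d", 1:6)))
    X[, 6] <- NA          # missing across the whole group: must stay missing
    X[2, 3] <- NA         # supported by 3 replicates: imputed
    out <- knn_impute(metab_table_from_matrix(X, "log_scaled"), meta, k = 2)
    res <- abundance_matrix(out$table)
    expect_true(all(is.na(res[, 6])))
    expect_identical(out$left_missing$metabolite_id, rep("m6", 4))
    expect_false(is.na(res[2, 3]))
    obs <- !is.na(X)
    expect_identical(res[obs], X[obs])
    # imputed value lies within the donors' range
    expect_gte(res[2, 3], min(X[2, -c(3, 6)]))
    expect_lte(res[2, 3], max(X[2, -c(3, 6)]))
  })
})

test_that("the full pipeline runs the stages in order and is deterministic", {
  meta <- make_metadata(n_rep = 4)
  # a structurally clean table: per-sample scale times per-metabolite base,
  # so normalization leaves every replicate group constant — the Dixon test
  # has nothing to flag and no cell is missing
  base <- exp(seq(0.1, 1, length.out = 10))
  scale_j <- exp(seq(-0.3, 0.3, length.out = nrow(meta)))
  m0 <- outer(scale_j, base)
  dimnames(m0) <- list(meta$sample_id, sprintf("met_%02d", 1:10))
  tab <- metab_table_from_matrix(m0, "raw")
  p1 <- preprocess_pipeline(tab, meta)
  p2 <- preprocess_pipeline(tab, meta)
  expect_identical(mt_state(p1$table), "imputed")
  expect_identical(nrow(p1$report$outliers_removed), 0L)
  expect_identical(nrow(p1$report$imputed_cells), 0L)
  expect_equal(abundance_matrix(p1$table), abundance_matrix(p2$table))

  # a planted extreme value is flagged, removed and then imputed; spiking the
  # largest metabolite leaves the sample median (hence normalization) intact
  m <- abundance_matrix(tab)
  m[1, 10] <- m[1, 10] * 60
  p3 <- preprocess_pipeline(metab_table_from_matrix(m, "raw"), meta)
  expect_identical(p3$report$outliers_removed$metabolite_id, "met_10")
  expect_identical(p3$report$outliers_removed$sample_id, meta$sample_id[1])
  expect_identical(p3$report$imputed_cells$metabolite_id, "met_10")
  expect_identical(nrow(tidy(p3$report)), 2L)
})

test_that("pipeline recovers planted outliers at the generator's spike size", {
  # elevated outlier rate for a stable recall estimate; spike magnitude and
  # all other settings at the generator defaults
  sim <- simulate_dataset(simulate_config(seed = 101, outlier_prob = 0.01))
  prep <- preprocess_pipeline(sim$table, sim$metadata)
  planted <- paste(sim$truth$outlier_cells$sample_id,
                   sim$truth$outlier_cells$metabolite_id)
  masked <- paste(sim$truth$missing_cells$sample_id,
                  sim$truth$missing_cells$metabolite_id)
  detectable <- setdiff(planted, masked)
  removed <- paste(prep$report$outliers_removed$sample_id,
                   prep$report$outliers_removed$metabolite_id)
  expect_gte(mean(detectable %in% removed), 0.9)
  n_tests <- length(unique(sim$metadata$genotype)) * 2 * 3 *
    length(metabolite_ids(sim$table))
  fp_rate <- sum(!(removed %in% planted)) / (n_tests - length(detectable))
  expect_lte(fp_rate, 0.05 + 0.02)
})
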