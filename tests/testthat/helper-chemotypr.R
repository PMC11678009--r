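# Shared fixtures and independent oracles. Everything is built in code; no
# data files are stored.

# small balanced design: 2 genotypes x 2 conditions x `times` x n replicates
make_metadata <- function(n_rep = 4, times = 3, genotypes = c("gA", "gB")) {
  design <- expand.grid(replicate = seq_len(n_rep), time_das = times,
                        condition = c("normoxia", "hypoxia"),
                        genotype = genotypes, stringsAsFactors = FALSE)
  design$sample_id <- sprintf("%s_%s_t%d_r%d", design$genotype,
                              substr(design$condition, 1, 4), design$time_das,
                              design$replicate)
  tibble::as_tibble(design[, c("sample_id", "genotype", "condition",
                               "time_das", "replicate")])
}

# random positive table matching a metadata frame
make_table <- function(metadata, n_met = 8, seed = 1, state = "raw") {
  withr::with_seed(seed, {
    m <- matrix(exp(rnorm(nrow(metadata) * n_met, mean = 2, sd = 0.3)),
                nrow(metadata), n_met,
                dimnames = list(metadata$sample_id,
                                sprintf("met_%02d", seq_len(n_met))))
    metab_table_from_matrix(m, state = state)
  })
}

# an imputed-state table with a planted two-class difference along `shift`
make_two_class <- function(n_per_class = 12, n_met = 50, shift = NULL,
                           effect = 2, seed = 1) {
  withr::with_seed(seed, {
    meta <- make_metadata(n_rep = n_per_class / 2, times = c(3, 5),
                          genotypes = "gA")
    if (is.null(shift)) shift <- c(rep(1, 5), rep(0, n_met - 5))
    shift <- shift / sqrt(sum(shift^2))
    y <- ifelse(meta$condition == "hypoxia", 1, -1)
    X <- matrix(rnorm(nrow(meta) * n_met), nrow(meta), n_met)
    X <- X + (effect / 2) * outer(y, shift)
    dimnames(X) <- list(meta$sample_id, sprintf("met_%02d", seq_len(n_met)))
    list(table = metab_table_from_matrix(X, state = "imputed"),
         metadata = meta, direction = shift, y = y)
  })
}

# brute-force running-sum curve for the enrichment score
bf_enrichment_curve <- function(scores, hit, weight_exponent = 1) {
  N <- length(scores)
  m <- sum(hit)
  w <- abs(scores)^weight_exponent
  tot <- sum(w[hit])
  cum <- numeric(N)
  run <- 0
  for (i in seq_len(N)) {
    run <- run + if (hit[i]) {
      if (tot > 0) w[i] / tot else 1 / m
    } else {
      -1 / (N - m)
    }
    cum[i] <- run
  }
  cum
}

bf_enrichment_score <- function(scores, hit, weight_exponent = 1) {
  cum <- bf_enrichment_curve(scores, hit, weight_exponent)
  cum[which.max(abs(cum))]
}

# exhaustive Ward merge cost (Ward.D2 / Lance-Williams on squared distances)
bf_ward_first_merge <- function(d) {
  n <- nrow(d)
  best <- c(NA, NA); best_h <- Inf
  for (i in seq_len(n - 1)) {
    for (j in seq(i + 1, n)) {
      if (d[i, j] < best_h) { best_h <- d[i, j]; best <- c(i, j) }
    }
  }
  list(pair = best, height = best_h)
}

# AUROC of score for a binary label, by rank statistic
auroc <- function(score, label) {
  r <- rank(score)
  (mean(r[label]) - (sum(label) + 1) / 2) / sum(!label)
}

# mean 1-D silhouette width
silhouette_1d <- function(x, lab) {
  mean(vapply(seq_along(x), function(i) {
    a <- mean(abs(x[i] - x[-i][lab[-i] == lab[i]]))
    b <- mean(abs(x[i] - x[lab != lab[i]]))
    (b - a) / max(a, b)
  }, double(1)))
}

edge_keys <- function(net) {
  e <- net$edges
  if (!nrow(e)) return(character(0))
  paste(pmin(e$from, e$to), pmax(e$from, e$to), sep = "|")
}

true_block_pairs <- function(truth, condition) {
  b <- truth$blocks[truth$blocks$condition == condition, ]
  unlist(lapply(split(b$metabolite_id, b$factor), function(ids) {
    ids <- sort(ids)
    apply(utils::combn(ids, 2), 2, paste, collapse = "|")
  }), use.names = FALSE)
}
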