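# Correlation networks, graph metrics, dissimilarities and Ward clustering.

# build a metab_network by hand from an edge list over a node universe
toy_network <- function(edges, nodes, stratum = "toy", n_samples = 12) {
  e <- if (length(edges)) {
    tibble::tibble(from = vapply(edges, `[`, "", 1),
                   to = vapply(edges, `[`, "", 2),
                   r = vapply(edges, function(x) as.numeric(x[3]), 0),
                   p = 0.001, q = 0.01)
  } else {
    tibble::tibble(from = character(), to = character(), r = double(),
                   p = double(), q = double())
  }
  structure(list(edges = e, nodes = nodes, stratum = stratum,
                 n_samples = n_samples, q_threshold = 0.05),
            class = "metab_network")
}

k4 <- toy_network(list(c("a", "b", 1), c("a", "c", 1), c("a", "d", 1),
                       c("b", "c", 1), c("b", "d", 1), c("c", "d", 1)),
                  letters[1:4])
star4 <- toy_network(list(c("a", "b", 1), c("a", "c", 1), c("a", "d", -1)),
                     letters[1:4])

test_that("two proportional metabolites yield a perfect-correlation edge", {
  meta <- make_metadata(n_rep = 4, genotypes = "gA", times = 3)[1:4, ]
  withr::with_seed(2, {
    base <- rnorm(4)
    m <- cbind(x = base, y = 2 * base + 1, z = rnorm(4))
    rownames(m) <- meta$sample_id
  })
  net <- build_network(metab_table_from_matrix(m, "imputed"), meta,
                       list(genotype = "gA"))
  key <- edge_keys(net)
  expect_true("x|y" %in% key)
  expect_equal(net$edges$r[net$edges$from %in% c("x", "y") &
                             net$edges$to %in% c("x", "y")], 1)
})

test_that("independent Gaussians produce no edges after BH in most runs", {
  clean <- 0
  for (seed in 1:10) {
    withr::with_seed(seed, {
      meta <- make_metadata(n_rep = 3, genotypes = "gA", times = c(3, 5))
      m <- matrix(rnorm(12 * 50), 12, 50,
                  dimnames = list(meta$sample_id, sprintf("m%02d", 1:50)))
    })
    net <- build_network(metab_table_from_matrix(m, "imputed"), meta,
                         list(genotype = "gA"))
    clean <- clean + (nrow(net$edges) == 0)
  }
  expect_gte(clean, 9)
})

test_that("stratum selection and degenerate metabolites are handled", {
  meta <- make_metadata(n_rep = 2)
  tab <- make_table(meta, n_met = 5, seed = 4, state = "imputed")
  expect_error(build_network(tab, meta,
                             list(genotype = "gA", condition = "hypoxia",
                                  time_das = 3)),
               "fewer than 4")
  expect_error(build_network(tab, meta, list(cultivar = "gA")), "cultivar")
  m <- abundance_matrix(tab); m[, 2] <- 5
  expect_warning(net <- build_network(metab_table_from_matrix(m, "imputed"),
                                      meta, list(genotype = "gA")),
                 "zero-variance")
  expect_false("met_02" %in% net$nodes)
})

test_that("metrics on K4 and the 4-star match closed forms", {
  mk <- network_metrics(k4)
  expect_equal(mk$density, 1)
  expect_equal(mk$diameter, 1)
  expect_equal(mk$heterogeneity, 0)
  expect_equal(mk$centralization, 0)

  ms <- network_metrics(star4)
  expect_equal(ms$density, 0.5)
  expect_equal(ms$diameter, 2)
  expect_equal(ms$heterogeneity, sqrt(3) / 3, tolerance = 1e-9) # 0.577
  expect_equal(ms$centralization, 1.0)
  expect_equal(ms$n_edges_pos, 2L)
  expect_equal(ms$n_edges_neg, 1L)
  expect_equal(ms$pos_neg_ratio, 2)
})

test_that("an edgeless network uses the stated conventions", {
  empty <- toy_network(list(), letters[1:5])
  m <- network_metrics(empty)
  expect_equal(m$diameter, 0)
  expect_equal(m$heterogeneity, 0)
  expect_true(is.na(m$pos_neg_ratio))
  expect_equal(m$density, 0)
})

test_that("degree accounting: histogram, zero-degree nodes, handshake lemma", {
  h <- degree_histogram(star4)
  expect_identical(h$count[h$degree == 1], 3L)
  expect_identical(h$count[h$degree == 3], 1L)
  expect_identical(sum(h$count), length(star4$nodes))
  withiso <- toy_network(list(c("a", "b", 1)), letters[1:4])
  h2 <- degree_histogram(withiso)
  expect_identical(h2$count[h2$degree == 0], 2L)
  expect_identical(sum(node_degrees(k4)$degree), 2L * nrow(k4$edges))
})

test_that("metrics are invariant to node relabeling", {
  relab <- star4
  map <- c(a = "w", b = "x", c = "y", d = "z")
  relab$nodes <- unname(map[relab$nodes])
  relab$edges$from <- unname(map[relab$edges$from])
  relab$edges$to <- unname(map[relab$edges$to])
  expect_equal(network_metrics(relab)[, -1], network_metrics(star4)[, -1])
})

test_that("dissimilarities match hand computations and their bounds", {
  na <- toy_network(list(c("a", "b", 1), c("b", "c", 1), c("a", "c", 1)),
                    letters[1:3], "na")
  dup <- na; dup$stratum <- "dup"
  nb <- toy_network(list(c("a", "b", 1)), letters[1:3], "nb")
  nc_ <- toy_network(list(c("b", "c", -1)), letters[1:3], "nc")

  bc <- network_dissimilarity(list(x = na, y = dup), "bray_curtis_degrees")
  jc <- network_dissimilarity(list(x = na, y = dup), "jaccard_edges")
  expect_equal(unname(bc$dissimilarity["x", "y"]), 0)
  expect_equal(unname(jc$dissimilarity["x", "y"]), 0)

  # aligned degree vectors (2,2,3,1) vs (3,2,2,1): BC = 2/16
  da <- toy_network(list(c("a", "b", 1), c("b", "c", 1), c("c", "a", 1),
                         c("c", "d", 1)), letters[1:4], "da")
  db <- toy_network(list(c("a", "b", 1), c("a", "c", 1), c("a", "d", 1),
                         c("b", "c", 1)), letters[1:4], "db")
  expect_identical(node_degrees(da)$degree, c(2L, 2L, 3L, 1L))
  expect_identical(node_degrees(db)$degree, c(3L, 2L, 2L, 1L))
  hand <- sum(abs(c(2, 2, 3, 1) - c(3, 2, 2, 1))) / sum(c(2, 2, 3, 1) + c(3, 2, 2, 1))
  bc2 <- network_dissimilarity(list(a = da, b = db), "bray_curtis_degrees")
  expect_equal(unname(bc2$dissimilarity["a", "b"]), hand)
  expect_equal(hand, 2 / 16)
  expect_equal(unname(
    network_dissimilarity(
      list(u = toy_network(list(c("a","b",1), c("b","c",1), c("c","d",1)), letters[1:4]),
           v = toy_network(list(c("d","c",1), c("c","b",1), c("b","a",1)), letters[1:4])),
      "bray_curtis_degrees")$dissimilarity["u", "v"]), 0)

  # disjoint edge sets: Jaccard distance 1; sign-agnostic pair identity
  jd <- network_dissimilarity(list(b = nb, c = nc_), "jaccard_edges")
  expect_equal(unname(jd$dissimilarity["b", "c"]), 1)
  flip <- nb; flip$edges$r <- -flip$edges$r
  expect_equal(unname(network_dissimilarity(list(b = nb, f = flip),
                                            "jaccard_edges")$dissimilarity["b", "f"]), 0)

  for (cmp in list(bc2, jd)) {
    d <- cmp$dissimilarity
    expect_true(all(d >= 0 & d <= 1))
    expect_equal(d, t(d))
    expect_true(all(diag(d) == 0))
  }
  expect_warning(network_dissimilarity(
    list(e1 = toy_network(list(), "a"), e2 = toy_network(list(), "a")),
    "jaccard_edges"), "Edgeless")
})

test_that("Bray-Curtis on degree vectors agrees with the vegan reference", {
  skip_if_not_installed("vegan")
  withr::with_seed(8, {
    nets <- lapply(1:3, function(i) {
      edges <- lapply(1:6, function(j) {
        c(sample(letters[1:6], 2), 1)
      })
      edges <- edges[!duplicated(lapply(edges, function(e) sort(e[1:2])))]
      edges <- Filter(function(e) e[1] != e[2], edges)
      toy_network(edges, letters[1:6], paste0("n", i))
    })
    names(nets) <- paste0("n", 1:3)
    ours <- network_dissimilarity(nets, "bray_curtis_degrees")$dissimilarity
    degs <- t(vapply(nets, function(n) node_degrees(n)$degree, integer(6)))
    ref <- as.matrix(vegan::vegdist(degs, method = "bray"))
    expect_equal(unname(ours), unname(ref), tolerance = 1e-12)
  })
})

test_that("Ward clustering merges duplicates first and matches brute force", {
  n1 <- toy_network(list(c("a", "b", 1)), letters[1:4], "n1")
  n2 <- n1; n2$stratum <- "n2"
  n3 <- toy_network(list(c("c", "d", 1), c("b", "c", 1)), letters[1:4], "n3")
  n4 <- n3; n4$stratum <- "n4"
  cmp <- network_dissimilarity(list(n1 = n1, n2 = n2, n3 = n3, n4 = n4),
                               "jaccard_edges")
  hc <- ward_cluster(cmp)
  expect_equal(hc$height[1:2], c(0, 0))
  expect_identical(sort(cutree(hc, 2)), setNames(c(1L, 1L, 2L, 2L),
                                                 c("n1", "n2", "n3", "n4")))

  # first merge on a hand-made 3-item matrix equals the exhaustive minimum
  d <- matrix(c(0, 0.2, 0.9, 0.2, 0, 0.7, 0.9, 0.7, 0), 3,
              dimnames = list(c("p", "q", "r"), c("p", "q", "r")))
  cmp3 <- structure(list(dissimilarity = d, method = "jaccard_edges",
                         labels = c("p", "q", "r")),
                    class = "network_comparison")
  hc3 <- ward_cluster(cmp3)
  bf <- bf_ward_first_merge(d)
  expect_identical(sort(-hc3$merge[1, ]), sort(bf$pair))
  expect_equal(hc3$height[1], bf$height)

  bad <- cmp3; bad$dissimilarity[1, 2] <- 0.5
  expect_error(ward_cluster(bad), "symmetric")
})

test_that("edges only shrink as the q threshold tightens", {
  sim <- simulate_dataset(simulate_config(seed = 5, n_metabolites = 60,
                                          n_latent_factors = 2, n_dams = 6,
                                          n_genotype_mets = 5, set_size = 3,
                                          n_background_sets = 4))
  prep <- preprocess_pipeline(sim$table, sim$metadata)
  loose <- build_network(prep$table, sim$metadata,
                         list(genotype = "slow", condition = "normoxia"),
                         q_threshold = 0.05)
  tight <- build_network(prep$table, sim$metadata,
                         list(genotype = "slow", condition = "normoxia"),
                         q_threshold = 0.01)
  expect_true(all(edge_keys(tight) %in% edge_keys(loose)))
  expect_true(all(loose$edges$q < 0.05))
})
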