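# Correlation networks within experimental strata, NetworkAnalyzer-style
# metrics, degree distributions, Bray-Curtis / Jaccard comparison and Ward
# clustering of networks.

#' Build a correlation network within a stratum
#'
#' Pearson correlation with two-sided p-values (t approximation) for every
#' metabolite pair over the stratum's samples, Benjamini-Hochberg adjustment
#' across all pairs, and a signed edge wherever q falls below the threshold.
#' By default the stratum pools all time points of a genotype x condition cell
#' so that the per-edge tests have usable sample sizes; pass `time_das` in the
#' stratum to build per-timepoint networks instead.
#'
#' @param table An imputed-state `metab_tbl`.
#' @param metadata Sample metadata.
#' @param stratum Named list of metadata values selecting the samples, e.g.
#'   `list(genotype = "slow", condition = "hypoxia")`; must select at least 4
#'   samples.
#' @param q_threshold Edge threshold on the BH-adjusted p (default 0.05,
#'   strict `<`).
#' @return A `metab_network`: edge tibble (`from`, `to`, `r`, `p`, `q`), the
#'   node universe (metabolites tested), the stratum label and the sample
#'   count.
#' @export
build_network <- function(table, metadata, stratum, q_threshold = 0.05) {
  stopifnot(inherits(table, "metab_tbl"))
  if (mt_state(table) != "imputed") {
    abort("build_network() expects an imputed-state table.")
  }
  metadata <- validate_metadata(metadata, table)
  keep <- rep(TRUE, nrow(metadata))
  for (v in names(stratum)) {
    if (!v %in% names(metadata)) abort(paste0("Unknown stratum variable: ", v))
    keep <- keep & metadata[[v]] %in% stratum[[v]]
  }
  ids <- intersect(table$sample_id, metadata$sample_id[keep])
  if (length(ids) < 4) abort("Stratum selects fewer than 4 samples.")
  X <- abundance_matrix(subset_samples(table, ids))
  if (anyNA(X)) {
    drop <- colnames(X)[colSums(is.na(X)) > 0]
    warn(paste0(length(drop), " metabolite(s) with missing values in this ",
                "stratum excluded from correlation testing."))
    X <- X[, setdiff(colnames(X), drop), drop = FALSE]
  }
  v <- apply(X, 2, var)
  if (any(v == 0)) {
    warn(paste0(sum(v == 0), " zero-variance metabolite(s) excluded from ",
                "correlation testing."))
    X <- X[, v > 0, drop = FALSE]
  }
  n <- nrow(X)
  r <- cor(X)
  ut <- upper.tri(r)
  rv <- r[ut]
  rv_c <- pmin(pmax(rv, -1 + 1e-15), 1 - 1e-15)
  tt <- rv_c * sqrt((n - 2) / (1 - rv_c^2))
  pv <- 2 * pt(-abs(tt), df = n - 2)
  pv[abs(rv) >= 1] <- 0
  qv <- p.adjust(pv, method = "BH")
  idx <- which(ut, arr.ind = TRUE)
  sel <- qv < q_threshold
  edges <- tibble(from = colnames(r)[idx[sel, 1]],
                  to = colnames(r)[idx[sel, 2]],
                  r = rv[sel], p = pv[sel], q = qv[sel])
  label <- paste(unlist(stratum), collapse = ".")
  structure(list(edges = edges, nodes = colnames(X), stratum = label,
                 n_samples = n, q_threshold = q_threshold),
            class = "metab_network")
}

#' @export
print.metab_network <- function(x, ...) {
  cat(sprintf("Correlation network [%s]: %d nodes, %d edges (q < %g, n = %d)\n",
              x$stratum, length(x$nodes), nrow(x$edges), x$q_threshold,
              x$n_samples))
  invisible(x)
}

#' @export
tidy.metab_network <- function(x, ...) x$edges

net_igraph <- function(net) {
  g <- igraph::make_empty_graph(n = length(net$nodes), directed = FALSE)
  igraph::V(g)$name <- net$nodes
  if (nrow(net$edges)) {
    g <- igraph::add_edges(g, rbind(match(net$edges$from, net$nodes),
                                    match(net$edges$to, net$nodes)),
                           weight = net$edges$r)
  }
  g
}

#' Node degrees of a correlation network
#'
#' @param net A `metab_network`.
#' @return Tibble (`metabolite_id`, `degree`), including degree-0 nodes.
#' @export
node_degrees <- function(net) {
  stopifnot(inherits(net, "metab_network"))
  deg <- table(factor(c(net$edges$from, net$edges$to), levels = net$nodes))
  tibble(metabolite_id = net$nodes, degree = as.integer(deg))
}

#' NetworkAnalyzer-style summary metrics
#'
#' Density is 2E/(N(N-1)) over all N nodes of the metabolite universe;
#' diameter is the longest unweighted shortest path within the largest
#' connected component; heterogeneity is the coefficient of variation of the
#' degree distribution (population variance); centralization is Freeman
#' degree centralization, `(N/(N-2)) * (k_max/(N-1) - density)`. For an
#' edgeless network, diameter and heterogeneity are 0 by convention and the
#' positive:negative ratio is `NA`.
#'
#' @param net A `metab_network`.
#' @return A one-row tibble of metrics.
#' @export
network_metrics <- function(net) {
  stopifnot(inherits(net, "metab_network"))
  N <- length(net$nodes)
  deg <- node_degrees(net)$degree
  E <- nrow(net$edges)
  n_pos <- sum(net$edges$r > 0)
  n_neg <- E - n_pos
  density <- if (N > 1) 2 * E / (N * (N - 1)) else 0
  mean_deg <- mean(deg)
  het <- if (mean_deg > 0) sqrt(mean((deg - mean_deg)^2)) / mean_deg else 0
  centr <- if (N > 2) (N / (N - 2)) * (max(deg) / (N - 1) - density) else 0
  diam <- 0
  if (E > 0) {
    g <- net_igraph(net)
    comp <- igraph::components(g)
    big <- igraph::induced_subgraph(g, which(comp$membership ==
                                               which.max(comp$csize)))
    diam <- igraph::diameter(big, weights = NA)
  }
  tibble(stratum = net$stratum, n_samples = net$n_samples, n_nodes = N,
         n_edges = E, n_edges_pos = n_pos, n_edges_neg = n_neg,
         pos_neg_ratio = if (n_neg > 0) n_pos / n_neg else NA_real_,
         density = density, diameter = diam, heterogeneity = het,
         centralization = centr)
}

#' Degree histogram of a network
#'
#' Counts nodes per degree (or per bin when `bins` breaks are supplied),
#' including degree-0 nodes, so the counts always total the node universe.
#'
#' @param net A `metab_network`.
#' @param bins Optional numeric break points passed to [cut()].
#' @return Tibble (`degree` or `bin`, `count`).
#' @export
degree_histogram <- function(net, bins = NULL) {
  deg <- node_degrees(net)$degree
  if (is.null(bins)) {
    tab <- table(deg)
    tibble(degree = as.integer(names(tab)), count = as.integer(tab))
  } else {
    tab <- table(cut(deg, breaks = bins, include.lowest = TRUE))
    tibble(bin = names(tab), count = as.integer(tab))
  }
}

#' Bray-Curtis dissimilarity between two non-negative vectors
#'
#' `sum(|u - v|) / sum(u + v)`; 0 for identical vectors, 1 for vectors with
#' disjoint support. Used on aligned node-degree vectors.
#'
#' @param u,v Non-negative numeric vectors of equal length.
#' @return The dissimilarity, between 0 and 1; 0 by convention when both
#'   vectors are all zero.
#' @export
bray_curtis <- function(u, v) {
  stopifnot(length(u) == length(v))
  if (any(u < 0) || any(v < 0)) abort("Inputs must be non-negative.")
  tot <- sum(u + v)
  if (tot == 0) return(0)
  sum(abs(u - v)) / tot
}

#' Jaccard distance between two sets
#'
#' One minus intersection-over-union; 0 by convention when both sets are
#' empty.
#'
#' @param a,b Vectors treated as sets of keys.
#' @return The distance, between 0 and 1.
#' @export
jaccard_distance <- function(a, b) {
  un <- union(a, b)
  if (!length(un)) return(0)
  1 - length(intersect(a, b)) / length(un)
}

#' Pairwise dissimilarity between correlation networks
#'
#' Two comparison modes, both bounded between 0 and 1:
#' `"bray_curtis_degrees"` computes the Bray-Curtis dissimilarity
#' `sum|u - v| / sum(u + v)` on node-degree vectors aligned over the union of
#' node universes (absent nodes get degree 0); `"jaccard_edges"` computes one
#' minus the Jaccard index of the two sign-agnostic edge sets (a metabolite
#' pair counts once regardless of correlation sign).
#'
#' @param nets A named list of at least two `metab_network` objects.
#' @param method `"bray_curtis_degrees"` or `"jaccard_edges"`.
#' @return A `network_comparison`: symmetric dissimilarity matrix plus the
#'   method label, ready for [ward_cluster()].
#' @export
network_dissimilarity <- function(nets,
                                  method = c("bray_curtis_degrees",
                                             "jaccard_edges")) {
  method <- match.arg(method)
  if (length(nets) < 2) abort("Need at least 2 networks to compare.")
  stopifnot(all(vapply(nets, inherits, logical(1), "metab_network")))
  labels <- names(nets) %||% vapply(nets, function(n) n$stratum, character(1))
  if (is.null(names(nets))) names(nets) <- labels
  universe <- sort(unique(unlist(lapply(nets, function(n) n$nodes))))
  K <- length(nets)
  d <- matrix(0, K, K, dimnames = list(labels, labels))
  degv <- lapply(nets, function(n) {
    dg <- node_degrees(n)
    setNames(dg$degree, dg$metabolite_id)[universe] |>
      (\(v) ifelse(is.na(v), 0L, v))()
  })
  edgekeys <- lapply(nets, function(n) {
    if (!nrow(n$edges)) return(character(0))
    unique(paste(pmin(n$edges$from, n$edges$to),
                 pmax(n$edges$from, n$edges$to), sep = "|"))
  })
  warned <- FALSE
  for (i in seq_len(K - 1)) {
    for (j in seq(i + 1, K)) {
      degenerate <- if (method == "bray_curtis_degrees") {
        sum(degv[[i]]) + sum(degv[[j]]) == 0
      } else {
        !length(edgekeys[[i]]) && !length(edgekeys[[j]])
      }
      if (degenerate && !warned) {
        warn("Edgeless network pair; dissimilarity 0 by convention.")
        warned <- TRUE
      }
      val <- if (method == "bray_curtis_degrees") {
        bray_curtis(degv[[i]], degv[[j]])
      } else {
        jaccard_distance(edgekeys[[i]], edgekeys[[j]])
      }
      d[i, j] <- d[j, i] <- val
    }
  }
  structure(list(dissimilarity = d, method = method, labels = labels),
            class = "network_comparison")
}

#' @export
print.network_comparison <- function(x, ...) {
  cat(sprintf("Network comparison (%s), %d networks\n", x$method,
              length(x$labels)))
  print(round(x$dissimilarity, 3))
  invisible(x)
}

#' Ward clustering of networks
#'
#' Agglomerative clustering of the network dissimilarity matrix with the Ward
#' criterion (Ward.D2 semantics: squared distances inside the merge cost).
#' Leaf order and merge heights are deterministic.
#'
#' @param comparison A `network_comparison` from [network_dissimilarity()].
#' @return An [hclust] tree; export with [write_newick()].
#' @export
ward_cluster <- function(comparison) {
  stopifnot(inherits(comparison, "network_comparison"))
  d <- comparison$dissimilarity
  if (!isSymmetric(unname(d))) abort("Dissimilarity matrix must be symmetric.")
  if (nrow(d) < 2) abort("Need at least 2 items to cluster.")
  hclust(as.dist(d), method = "ward.D2")
}

#' Write a dendrogram as Newick
#'
#' Branch lengths encode the merge heights.
#'
#' @param hc An [hclust] tree.
#' @param path Output path.
#' @export
write_newick <- function(hc, path) {
  ape::write.tree(ape::as.phylo(hc), file = path)
  invisible(path)
}
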