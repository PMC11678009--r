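# Metabolite set enrichment analysis on a loading-ranked list, using the
# weighted Kolmogorov-Smirnov running-sum statistic with a random-set null
# (same-size member draws from the ranked universe), NES normalization by the
# mean same-sign null magnitude, and Benjamini-Hochberg adjustment.

#' Rank metabolites by predictive loading
#'
#' Sorts metabolites by the OPLS-DA predictive loading, descending, so that
#' the head of the list is "most up in the positive class". Ties are broken
#' id-lexicographically and flagged in an attribute.
#'
#' @param model A fitted `oplsda`.
#' @return A tibble (`metabolite_id`, `score`) sorted by score descending;
#'   ties, if any, are listed in `attr(, "ties")`.
#' @export
rank_from_loadings <- function(model) {
  if (!inherits(model, "oplsda")) abort("`model` must be a fitted oplsda object.")
  out <- tibble(metabolite_id = names(model$loadings),
                score = unname(model$loadings))
  out <- arrange(out, dplyr::desc(.data$score), .data$metabolite_id)
  dup <- out$score %in% out$score[duplicated(out$score)]
  attr(out, "ties") <- out$metabolite_id[dup]
  out
}

# signed running-sum extremum from hit positions; increments weighted by
# |score|^exponent, misses decrement 1/(N - m)
running_sum_es <- function(scores, hit, weight_exponent = 1) {
  N <- length(scores)
  m <- sum(hit)
  w <- abs(scores[hit])^weight_exponent
  tot <- sum(w)
  steps <- rep(-1 / (N - m), N)
  steps[hit] <- if (tot > 0) w / tot else 1 / m
  # plain sequential accumulation (not cumsum) so the running sum is
  # bit-reproducible against a position-by-position recomputation
  run <- 0
  best <- 0
  best_abs <- -1
  for (i in seq_len(N)) {
    run <- run + steps[i]
    if (abs(run) > best_abs) {
      best_abs <- abs(run)
      best <- run
    }
  }
  best
}

#' Weighted running-sum enrichment score
#'
#' Walks the ranked list accumulating `|score|^weight_exponent /
#' sum(hit weights)` at each set member and `-1/(N - m)` at each non-member;
#' the ES is the running-sum value of largest magnitude (signed). A set
#' concentrated at the top yields ES near +1, at the bottom near -1.
#'
#' @param ranked A ranked list from [rank_from_loadings()] (tibble with
#'   `metabolite_id`, `score`).
#' @param set_members Character vector of member metabolite ids; at least one
#'   must be present in the ranked list.
#' @param weight_exponent Weighting exponent on |score| (default 1; 0 gives
#'   the unweighted Kolmogorov-Smirnov statistic).
#' @return The enrichment score, between -1 and 1.
#' @export
enrichment_score <- function(ranked, set_members, weight_exponent = 1) {
  hit <- ranked$metabolite_id %in% set_members
  if (!any(hit)) abort("No set member is present in the ranked list.")
  if (all(hit)) return(1)
  running_sum_es(ranked$score, hit, weight_exponent)
}

#' Metabolite set enrichment analysis
#'
#' Computes the enrichment score of every set against the ranked list, builds
#' a null distribution from `n_perm` random same-size member draws out of the
#' ranked universe (seeded), normalizes ES by the mean magnitude of same-sign
#' null scores (NES), derives an add-one permutation p-value from the
#' same-sign null tail, and adjusts p across sets by Benjamini-Hochberg.
#'
#' @param ranked A ranked list from [rank_from_loadings()].
#' @param sets Named list of metabolite-id vectors, as from
#'   [load_metabolite_sets()]; members absent from the ranked list are
#'   dropped, and sets falling below `min_size` are skipped with a warning.
#' @param min_size Minimum surviving set size (default 3).
#' @param n_perm Random draws per set (default 10000).
#' @param weight_exponent Passed to [enrichment_score()].
#' @param seed Seed for the null draws.
#' @return A tibble (`set_id`, `size`, `es`, `nes`, `p`, `padj`,
#'   `direction`), one row per tested set, with the ranked universe stored in
#'   `attr(, "universe")`.
#' @export
msea_run <- function(ranked, sets, min_size = 3, n_perm = 10000,
                     weight_exponent = 1, seed = 1L) {
  universe <- ranked$metabolite_id
  trimmed <- lapply(sets, function(s) unique(s[s %in% universe]))
  sizes <- lengths(trimmed)
  drop <- names(trimmed)[sizes < min_size]
  if (length(drop)) {
    warn(paste0("Set(s) below min_size after filtering to the ranked universe: ",
                paste(drop, collapse = ", ")))
  }
  trimmed <- trimmed[sizes >= min_size]
  if (!length(trimmed)) {
    warn("No sets survive filtering; returning an empty result.")
    out <- tibble(set_id = character(), size = integer(), es = double(),
                  nes = double(), p = double(), padj = double(),
                  direction = character())
    attr(out, "universe") <- universe
    return(out)
  }
  N <- length(universe)
  scores <- ranked$score

  rows <- vector("list", length(trimmed))
  withr::with_seed(seed, {
    for (si in seq_along(trimmed)) {
      members <- trimmed[[si]]
      m <- length(members)
      hit <- universe %in% members
      es <- if (m == N) 1 else running_sum_es(scores, hit, weight_exponent)
      null_es <- vapply(seq_len(n_perm), function(i) {
        pos <- sample.int(N, m)
        h <- logical(N); h[pos] <- TRUE
        running_sum_es(scores, h, weight_exponent)
      }, double(1))
      same <- if (es >= 0) null_es[null_es >= 0] else null_es[null_es < 0]
      nes <- if (length(same)) es / mean(abs(same)) else NA_real_
      p <- if (es >= 0) {
        (1 + sum(same >= es)) / (1 + length(same))
      } else {
        (1 + sum(same <= es)) / (1 + length(same))
      }
      rows[[si]] <- tibble(set_id = names(trimmed)[si], size = m, es = es,
                           nes = nes, p = p)
    }
  })
  out <- bind_rows(rows)
  out$padj <- p.adjust(out$p, method = "BH")
  out$direction <- ifelse(out$nes < 0, "down", "up")
  out <- arrange(out, .data$padj, .data$p, .data$set_id)
  attr(out, "universe") <- universe
  attr(out, "params") <- list(min_size = min_size, n_perm = n_perm,
                              weight_exponent = weight_exponent, seed = seed)
  out
}

#' Pathway-overlap graph of enriched sets
#'
#' Builds the graph whose nodes are the sets passing the `padj_max` cutoff
#' and whose edges join any two sets sharing at least one member within the
#' ranked universe. Node attributes carry |NES| (size), padj (significance)
#' and direction, matching the usual enrichment-map rendering.
#'
#' @param result An enrichment result from [msea_run()].
#' @param sets The set collection used for the analysis.
#' @param padj_max Adjusted-p cutoff for inclusion (default 0.05); use 1 to
#'   include every tested set.
#' @return An `igraph` graph (possibly with zero nodes).
#' @export
pathway_overlap_graph <- function(result, sets, padj_max = 0.05) {
  universe <- attr(result, "universe")
  keep <- result[result$padj <= padj_max, , drop = FALSE]
  members <- lapply(sets[keep$set_id], function(s) {
    if (is.null(universe)) unique(s) else unique(s[s %in% universe])
  })
  ids <- keep$set_id
  edges <- list()
  if (length(ids) > 1) {
    for (i in seq_len(length(ids) - 1)) {
      for (j in seq(i + 1, length(ids))) {
        if (length(intersect(members[[i]], members[[j]]))) {
          edges[[length(edges) + 1]] <- c(ids[i], ids[j])
        }
      }
    }
  }
  g <- igraph::make_empty_graph(n = 0, directed = FALSE)
  g <- igraph::add_vertices(g, length(ids), name = ids,
                            abs_nes = abs(keep$nes), padj = keep$padj,
                            direction = keep$direction)
  if (length(edges)) {
    g <- igraph::add_edges(g, match(unlist(edges), ids))
  }
  g
}
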