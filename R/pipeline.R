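# End-to-end orchestration: preprocessing, PCA, per-timepoint hypoxia models,
# DAM tables, MSEA, intervarietal comparisons, correlation networks and their
# comparison — with every output written to a run directory and recorded in a
# manifest.

#' Group-mean heatmap matrix
#'
#' Mean preprocessed abundance per (genotype, condition, time) group per
#' metabolite, then each metabolite row centered and scaled across groups —
#' the matrix behind the usual group-mean heatmap. Rows are ordered by
#' chemical class when an annotation is supplied.
#'
#' @param table An imputed-state `metab_tbl`.
#' @param metadata Sample metadata.
#' @param annotation Optional annotation tibble with `chem_class`.
#' @return A tibble: `metabolite_id`, optional `chem_class`, one numeric
#'   column per group (named `genotype.condition.tTIME`). Each row has mean 0
#'   and, when non-constant, unit SD across groups.
#' @export
group_mean_matrix <- function(table, metadata, annotation = NULL) {
  stopifnot(inherits(table, "metab_tbl"))
  if (mt_state(table) != "imputed") {
    abort("group_mean_matrix() expects an imputed-state table.")
  }
  metadata <- validate_metadata(metadata, table)
  meta <- metadata[match(table$sample_id, metadata$sample_id), ]
  grp <- paste(meta$genotype, meta$condition, paste0("t", meta$time_das),
               sep = ".")
  m <- abundance_matrix(table)
  groups <- unique(grp)
  means <- vapply(groups, function(g) {
    colMeans(m[grp == g, , drop = FALSE], na.rm = TRUE)
  }, double(ncol(m)))
  if (any(!is.finite(means))) abort("A group has no samples with data.")
  ctr <- means - rowMeans(means)
  sdv <- apply(ctr, 1, sd)
  sdv[sdv == 0] <- 1
  scaled <- ctr / sdv
  out <- as_tibble(scaled)
  out <- dplyr::bind_cols(tibble(metabolite_id = colnames(m)), out)
  if (!is.null(annotation) && "chem_class" %in% names(annotation)) {
    out <- left_join(out, annotation[, c("metabolite_id", "chem_class")],
                     by = "metabolite_id")
    out <- arrange(out, .data$chem_class, .data$metabolite_id)
    out <- dplyr::relocate(out, "metabolite_id", "chem_class")
  }
  out
}

default_pipeline_config <- function() {
  list(simulate = list(seed = 1),
       dixon_alpha = 0.05, knn_k = 10,
       n_orthogonal = 1, folds = 7, n_perm = 199,
       vip_min = 1.0, loading_quantile = 0.75,
       msea_min_size = 3, msea_n_perm = 2000,
       network_q = 0.05, seed = 1, skip_stages = character())
}

#' Run the full chemotyping pipeline
#'
#' Executes, in order: data loading (or simulation), preprocessing, PCA,
#' per-timepoint hypoxia-vs-normoxia OPLS-DA for each genotype with DAM
#' selection and MSEA, per-timepoint intervarietal OPLS-DA under each
#' condition with loading comparisons, genotype-by-condition correlation
#' networks with metrics, dissimilarities and a Ward dendrogram, and the
#' group-mean heatmap matrix. All result tables are written under `out_dir`
#' and listed in a JSON manifest (config snapshot, seeds, input digests, stage
#' timings, output files).
#'
#' @param config A named list (or path to a YAML file) overriding
#'   the defaults: either a `simulate` block (generator settings) or an
#'   `input` block with `matrix`, `metadata`, `annotation`, `sets` paths,
#'   plus analysis settings (`dixon_alpha`, `knn_k`, `n_orthogonal`, `folds`,
#'   `n_perm`, `vip_min`, `loading_quantile`, `msea_min_size`, `msea_n_perm`,
#'   `network_q`, `seed`).
#' @param out_dir Output directory, created if needed.
#'
#' Stages downstream of preprocessing (`"pca"`, `"oplsda_hypoxia"`,
#' `"oplsda_intervarietal"`, `"loading_comparison"`, `"networks"`,
#' `"network_comparison"`, `"heatmap"`) can be disabled via the
#' `skip_stages` config entry; skipping a stage removes only its outputs.
#' @return The manifest, invisibly.
#' @export
run_pipeline <- function(config = list(), out_dir = tempfile("chemotypr_run")) {
  if (is.character(config) && length(config) == 1) {
    if (!file.exists(config)) abort(paste0("Config file not found: ", config))
    config <- yaml::read_yaml(config)
  }
  cfg <- utils::modifyList(default_pipeline_config(), config)
  if (!is.null(config$input)) cfg$simulate <- NULL
  if (!is.null(cfg$input)) {
    for (p in unlist(cfg$input)) {
      if (!file.exists(p)) abort(paste0("Input file not found: ", p))
    }
  }
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  manifest <- list(config = cfg, outputs = character(), timings = list())
  t_stage <- function(name, expr) {
    if (name %in% cfg$skip_stages) return(invisible(NULL))
    t0 <- proc.time()[["elapsed"]]
    res <- tryCatch(expr, error = function(e) {
      manifest$outputs <<- manifest$outputs
      abort(paste0("Pipeline stage '", name, "' failed: ",
                   conditionMessage(e)))
    })
    manifest$timings[[name]] <<- round(proc.time()[["elapsed"]] - t0, 3)
    res
  }
  emit <- function(x, name) {
    path <- file.path(out_dir, name)
    write_table(x, path)
    manifest$outputs <<- c(manifest$outputs, name)
    path
  }

  dat <- t_stage("load", {
    if (!is.null(cfg$input)) {
      d <- load_dataset(cfg$input$matrix, cfg$input$metadata,
                        cfg$input$annotation)
      d$sets <- if (!is.null(cfg$input$sets))
        load_metabolite_sets(cfg$input$sets) else NULL
      manifest$input_digests <- as.list(tools::md5sum(unlist(cfg$input)))
      d
    } else {
      sim_cfg <- do.call(simulate_config, cfg$simulate %||% list())
      d <- simulate_dataset(sim_cfg)
      emit(truth_summary(d$truth), "ground_truth.tsv")
      d
    }
  })

  prep <- t_stage("preprocess", preprocess_pipeline(
    dat$table, dat$metadata, dixon_alpha = cfg$dixon_alpha, knn_k = cfg$knn_k))
  emit(tidy(prep$report), "preprocess_report.tsv")
  norm <- median_normalize(dat$table)$table

  pca <- t_stage("pca", fit_pca(prep$table, n_components = 5))
  emit(tidy(pca, "scores"), "pca_scores.tsv")
  emit(tidy(pca, "eigenvalues"), "pca_variance.tsv")

  genotypes <- unique(dat$metadata$genotype)
  times <- sort(unique(dat$metadata$time_das))
  hyp_models <- list()
  t_stage("oplsda_hypoxia", {
    for (g in genotypes) {
      for (tt in times) {
        ids <- dat$metadata$sample_id[dat$metadata$genotype == g &
                                        dat$metadata$time_das == tt]
        sub <- subset_samples(prep$table, intersect(prep$table$sample_id, ids))
        meta_sub <- dat$metadata[dat$metadata$sample_id %in% sub$sample_id, ]
        mod <- fit_oplsda(sub, meta_sub, "condition",
                          c("hypoxia", "normoxia"),
                          n_orthogonal = cfg$n_orthogonal, folds = cfg$folds,
                          fold_seed = cfg$seed)
        key <- paste0(g, "_t", tt)
        hyp_models[[key]] <- mod
        emit(tidy(mod), paste0("oplsda_", key, "_loadings.tsv"))
        dams <- select_dams(mod, subset_samples(norm, mod$sample_ids),
                            meta_sub, vip_min = cfg$vip_min,
                            loading_quantile = cfg$loading_quantile)
        emit(dams, paste0("dams_", key, ".tsv"))
        if (!is.null(dat$sets)) {
          enr <- msea_run(rank_from_loadings(mod), dat$sets,
                          min_size = cfg$msea_min_size,
                          n_perm = cfg$msea_n_perm, seed = cfg$seed)
          emit(enr, paste0("msea_", key, ".tsv"))
        }
      }
    }
  })
  if (length(hyp_models)) {
    emit(bind_rows(lapply(names(hyp_models), function(k) {
      dplyr::mutate(glance(hyp_models[[k]]), model = k, .before = 1)
    })), "oplsda_hypoxia_summary.tsv")
  }

  t_stage("oplsda_intervarietal", {
    rows <- list()
    for (cond in unique(dat$metadata$condition)) {
      for (tt in times) {
        ids <- dat$metadata$sample_id[dat$metadata$condition == cond &
                                        dat$metadata$time_das == tt]
        sub <- subset_samples(prep$table, intersect(prep$table$sample_id, ids))
        meta_sub <- dat$metadata[dat$metadata$sample_id %in% sub$sample_id, ]
        mod <- fit_oplsda(sub, meta_sub, "genotype",
                          c(genotypes[1], genotypes[2]),
                          n_orthogonal = cfg$n_orthogonal, folds = cfg$folds,
                          fold_seed = cfg$seed)
        rows[[paste(cond, tt)]] <- dplyr::mutate(
          glance(mod), condition = cond, time_das = tt, .before = 1)
      }
    }
    emit(bind_rows(rows), "oplsda_intervarietal_summary.tsv")
  })

  if (!length(hyp_models)) cfg$skip_stages <- c(cfg$skip_stages, "loading_comparison")
  t_stage("loading_comparison", {
    comp <- list()
    for (tt in times) {
      a <- hyp_models[[paste0(genotypes[1], "_t", tt)]]
      b <- hyp_models[[paste0(genotypes[2], "_t", tt)]]
      comp[[as.character(tt)]] <- dplyr::mutate(
        compare_loadings(a, b), time_das = tt, .before = 1)
    }
    emit(bind_rows(comp), "loading_similarity.tsv")
  })

  nets <- t_stage("networks", {
    nets <- list()
    for (g in genotypes) {
      for (cond in unique(dat$metadata$condition)) {
        key <- paste(g, cond, sep = ".")
        nets[[key]] <- build_network(prep$table, dat$metadata,
                                     list(genotype = g, condition = cond),
                                     q_threshold = cfg$network_q)
        emit(nets[[key]]$edges, paste0("network_", g, "_", cond, ".tsv"))
      }
    }
    emit(bind_rows(lapply(nets, network_metrics)), "network_metrics.tsv")
    nets
  })

  if (is.null(nets)) cfg$skip_stages <- c(cfg$skip_stages, "network_comparison")
  t_stage("network_comparison", {
    for (method in c("bray_curtis_degrees", "jaccard_edges")) {
      cmp <- network_dissimilarity(nets, method = method)
      hc <- ward_cluster(cmp)
      nwk <- file.path(out_dir, paste0("dendrogram_", method, ".nwk"))
      write_newick(hc, nwk)
      manifest$outputs <- c(manifest$outputs, basename(nwk))
      d <- as_tibble(cmp$dissimilarity)
      d <- dplyr::bind_cols(tibble(network = cmp$labels), d)
      emit(d, paste0("dissimilarity_", method, ".tsv"))
    }
  })

  t_stage("heatmap", {
    emit(group_mean_matrix(prep$table, dat$metadata, dat$annotation),
         "group_mean_matrix.tsv")
  })

  manifest$outputs <- unique(manifest$outputs)
  manifest$output_digests <- as.list(
    tools::md5sum(file.path(out_dir, manifest$outputs)))
  names(manifest$output_digests) <- manifest$outputs
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA,
                       force = TRUE)
  invisible(manifest)
}
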