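# Synthetic GC-MS study generator. Emulates a 2-genotype x 2-oxygen-condition
# x 3-timepoint factorial with >= 4 replicates and ~370 metabolites: a
# dominant oxygen effect on a subset of metabolites, a genotype effect that
# shrinks geometrically over time under hypoxia, an age trend damped by
# hypoxia, latent-factor correlation blocks whose sign structure differs by
# condition, per-sample scale factors, sporadic single-value outliers and
# sparse missing values. Everything is drawn from one seeded stream and the
# planted structure is returned as machine-readable ground truth.

#' Configuration for the synthetic study generator
#'
#' Defaults reproduce the study conditions the package's analyses assume; see
#' the methods vignette for the reasoning behind each value. Effects live on
#' the natural-log scale, so the preprocessing chain (log + autoscale)
#' linearizes them.
#'
#' @param n_metabolites Number of metabolites (default 370).
#' @param n_replicates Biological replicates per design cell (default 4).
#' @param genotypes Two genotype labels (default `c("slow", "fast")`).
#' @param times Sampling times in days after sowing (default `c(3, 5, 7)`).
#' @param condition_effect_sd SD of the log-scale hypoxia effect on the
#'   planted DAMs (default 2).
#' @param genotype_effect_sd SD of the log-scale genotype effect on the
#'   `n_genotype_mets` genotype-responsive metabolites (default 0.5).
#' @param n_genotype_mets Number of metabolites carrying a genotype effect
#'   (default 25) — intervarietal differences are concentrated and weak
#'   relative to the oxygen effect.
#' @param genotype_shrink_rate Geometric decay of the genotype effect per
#'   time step under hypoxia only (default 0.45).
#' @param age_effect_sd SD of the per-metabolite linear age trend (default
#'   0.05) — ages separate along a minor component, not the leading one.
#' @param age_hypoxia_factor Damping of the age trend under hypoxia (default
#'   0.3), emulating developmental arrest.
#' @param n_dams Number of metabolites given a hypoxia effect (default 40).
#' @param n_enriched_sets,set_size Planted consistently-signed enriched sets
#'   built from the DAMs (default 4 sets of 10).
#' @param n_background_sets Random non-enriched sets added to the collection
#'   (default 20).
#' @param n_latent_factors,block_size Latent correlation blocks (default 6
#'   blocks of 12 metabolites).
#' @param factor_loading_sd Scale of the latent-factor loadings (default
#'   0.68); together with `noise_sd` this sets the within-block correlation
#'   (about 0.97 at the defaults).
#' @param sign_mixing_fraction Named pair: fraction of each block's loadings
#'   whose sign is flipped per condition (default normoxia 0.1, hypoxia 0.3);
#'   drives the positive:negative edge-ratio contrast.
#' @param rewire_fraction Named pair: fraction of each block's members swapped
#'   for condition-specific alternates (default normoxia 0, hypoxia 1/3), so
#'   hypoxia changes the composition of the co-regulated modules, not only
#'   their sign structure.
#' @param noise_sd Residual log-scale noise SD (default 0.12, a realistic
#'   residual CV for derivatized GC-MS with an internal standard).
#' @param missing_prob Per-cell missingness probability (default 0.02).
#' @param missing_mode `"mcar"` (default) or `"censor"` (lowest values per
#'   metabolite go missing).
#' @param outlier_prob,outlier_multiplier Sporadic single-value outliers:
#'   per-cell probability (default 0.002) and multiplicative spike (default
#'   20).
#' @param sample_scale_sd SD of the per-sample lognormal scale factor
#'   (default 0.2).
#' @param baseline_log_mean,baseline_log_sd Baseline log-abundance
#'   distribution across metabolites (default 10, 1).
#' @param seed Seed for the single random stream.
#' @return A validated `sim_config` list.
#' @export
simulate_config <- function(n_metabolites = 370, n_replicates = 4,
                            genotypes = c("slow", "fast"),
                            times = c(3, 5, 7),
                            condition_effect_sd = 2.0,
                            genotype_effect_sd = 0.5,
                            n_genotype_mets = 25,
                            genotype_shrink_rate = 0.45,
                            age_effect_sd = 0.05,
                            age_hypoxia_factor = 0.3,
                            n_dams = 40,
                            n_enriched_sets = 4, set_size = 10,
                            n_background_sets = 20,
                            n_latent_factors = 6, block_size = 12,
                            factor_loading_sd = 0.68,
                            sign_mixing_fraction = c(normoxia = 0.1,
                                                     hypoxia = 0.3),
                            rewire_fraction = c(normoxia = 0,
                                                hypoxia = 1 / 3),
                            noise_sd = 0.12,
                            missing_prob = 0.02, missing_mode = "mcar",
                            outlier_prob = 0.002, outlier_multiplier = 20,
                            sample_scale_sd = 0.2,
                            baseline_log_mean = 10, baseline_log_sd = 1,
                            seed = 1L) {
  cfg <- as.list(environment())
  cfg$missing_mode <- match.arg(missing_mode, c("mcar", "censor"))
  probs <- c(cfg$missing_prob, cfg$outlier_prob, cfg$sign_mixing_fraction,
             cfg$rewire_fraction)
  if (any(probs < 0 | probs > 1)) abort("Probabilities must lie in [0, 1].")
  if (length(genotypes) != 2) abort("Exactly 2 genotypes are supported.")
  for (fld in c("sign_mixing_fraction", "rewire_fraction")) {
    if (!all(c("normoxia", "hypoxia") %in% names(cfg[[fld]]))) {
      abort(paste0("`", fld, "` needs named entries for both conditions."))
    }
  }
  if (cfg$n_dams > cfg$n_metabolites) abort("n_dams exceeds n_metabolites.")
  if (cfg$n_genotype_mets > cfg$n_metabolites) {
    abort("n_genotype_mets exceeds n_metabolites.")
  }
  n_alt <- sum(round(cfg$rewire_fraction * cfg$block_size)) *
    cfg$n_latent_factors
  if (cfg$n_latent_factors * cfg$block_size + n_alt + cfg$n_dams >
        cfg$n_metabolites) {
    abort("Latent blocks, rewired alternates and DAMs exceed n_metabolites.")
  }
  if (cfg$n_enriched_sets > 0 && cfg$set_size > ceiling(cfg$n_dams / 2)) {
    abort("set_size exceeds the number of same-sign DAMs available.")
  }
  if (any(c(cfg$n_metabolites, cfg$n_replicates, cfg$n_latent_factors,
            cfg$block_size, cfg$set_size) < 1)) {
    abort("Counts and sizes must be positive.")
  }
  structure(cfg, class = "sim_config")
}

.chem_classes <- c("amino acid", "carboxylate", "sugar", "sugar phosphate",
                   "disaccharide", "sterol", "fatty acid", "phenolic",
                   "nitrogenous base", "unknown")

#' Generate a synthetic metabolomic study
#'
#' Draws abundance data under the factorial log-linear model described in the
#' methods vignette, injects outliers and missing values, and emits the
#' matching metadata, annotation, metabolite-set collection and ground truth.
#' The same seed always yields identical output.
#'
#' @param config A [simulate_config()].
#' @return A list: `table` (raw `metab_tbl`), `metadata`, `annotation`,
#'   `sets` (GMT-style named list), `truth` (planted DAMs, enriched sets,
#'   latent blocks, outlier and missing cells, scale factors).
#' @export
simulate_dataset <- function(config = simulate_config()) {
  stopifnot(inherits(config, "sim_config"))
  cfg <- config
  withr::with_seed(cfg$seed, {
    M <- cfg$n_metabolites
    met_ids <- sprintf("met_%03d", seq_len(M))

    design <- expand.grid(replicate = seq_len(cfg$n_replicates),
                          time_das = cfg$times,
                          condition = c("normoxia", "hypoxia"),
                          genotype = cfg$genotypes,
                          stringsAsFactors = FALSE)
    metadata <- as_tibble(design[, c("genotype", "condition", "time_das",
                                     "replicate")])
    metadata$sample_id <- sprintf("%s_%s_t%d_r%d", metadata$genotype,
                                  substr(metadata$condition, 1, 4),
                                  metadata$time_das, metadata$replicate)
    metadata <- dplyr::relocate(metadata, "sample_id")
    S <- nrow(metadata)

    # planted structure: latent blocks first, DAMs from the remainder
    block_ids <- matrix(met_ids[seq_len(cfg$n_latent_factors * cfg$block_size)],
                        ncol = cfg$n_latent_factors)
    remaining <- setdiff(met_ids, as.vector(block_ids))
    dam_ids <- sort(sample(remaining, cfg$n_dams))
    n_up <- ceiling(cfg$n_dams / 2)
    dam_sign <- rep(c(1, -1), c(n_up, cfg$n_dams - n_up))
    alpha <- setNames(rep(0, M), met_ids)
    alpha[dam_ids] <- dam_sign * abs(stats::rnorm(cfg$n_dams,
                                                  sd = cfg$condition_effect_sd))
    gamma <- stats::rnorm(M, sd = cfg$age_effect_sd)
    mu <- stats::rnorm(M, mean = cfg$baseline_log_mean,
                       sd = cfg$baseline_log_sd)

    # condition-specific block loadings: each condition keeps the block's
    # core members, swaps a rewired fraction for condition-specific
    # alternates, and flips the sign of a mixed fraction of the active
    # members — so oxygen deprivation changes both which metabolites are
    # co-regulated and the sign structure of their co-regulation
    alt_pool <- setdiff(remaining, dam_ids)
    lam_cond <- list(normoxia = matrix(0, M, cfg$n_latent_factors),
                     hypoxia = matrix(0, M, cfg$n_latent_factors))
    block_rows <- list()
    for (cond in c("normoxia", "hypoxia")) {
      n_rw <- round(cfg$rewire_fraction[[cond]] * cfg$block_size)
      for (f in seq_len(cfg$n_latent_factors)) {
        active <- block_ids[, f]
        if (n_rw > 0) {
          drop_ix <- sample.int(cfg$block_size, n_rw)
          alts <- sample(alt_pool, n_rw)
          alt_pool <- setdiff(alt_pool, alts)
          active[drop_ix] <- alts
        }
        rows <- match(active, met_ids)
        mag <- cfg$factor_loading_sd * exp(stats::rnorm(cfg$block_size,
                                                        sd = 0.1))
        n_flip <- round(cfg$sign_mixing_fraction[[cond]] * cfg$block_size)
        sgn <- rep(1, cfg$block_size)
        if (n_flip > 0) sgn[sample.int(cfg$block_size, n_flip)] <- -1
        lam_cond[[cond]][rows, f] <- mag * sgn
        block_rows[[paste(cond, f)]] <- tibble(
          condition = cond, factor = f, metabolite_id = active,
          loading = mag * sgn)
      }
    }

    # genotype-responsive metabolites: outside blocks, alternates and DAMs,
    # so the intervarietal signal is not masked by module variance
    beta <- numeric(M)
    geno_ids <- sort(sample(alt_pool, cfg$n_genotype_mets))
    beta[match(geno_ids, met_ids)] <- stats::rnorm(
      cfg$n_genotype_mets, sd = cfg$genotype_effect_sd)

    hyp <- as.numeric(metadata$condition == "hypoxia")
    gset <- ifelse(metadata$genotype == cfg$genotypes[2], 0.5, -0.5)
    tstep <- (metadata$time_das - min(cfg$times)) / 2
    shrink <- ifelse(hyp == 1, cfg$genotype_shrink_rate^tstep, 1)
    tcent <- (metadata$time_das - mean(range(cfg$times))) / 2
    agefac <- ifelse(hyp == 1, cfg$age_hypoxia_factor, 1)
    z <- matrix(stats::rnorm(S * cfg$n_latent_factors), S)

    logx <- matrix(rep(mu, each = S), S, M)
    logx <- logx + outer(hyp, alpha)
    logx <- logx + outer(gset * shrink, beta)
    logx <- logx + outer(tcent * agefac, gamma)
    for (cond in c("normoxia", "hypoxia")) {
      rows <- which(metadata$condition == cond)
      logx[rows, ] <- logx[rows, ] +
        z[rows, , drop = FALSE] %*% t(lam_cond[[cond]])
    }
    logx <- logx + matrix(stats::rnorm(S * M, sd = cfg$noise_sd), S)

    scale_fac <- exp(stats::rnorm(S, sd = cfg$sample_scale_sd))
    x <- exp(logx) * scale_fac
    dimnames(x) <- list(metadata$sample_id, met_ids)

    out_mask <- matrix(stats::runif(S * M) < cfg$outlier_prob, S)
    x[out_mask] <- x[out_mask] * cfg$outlier_multiplier
    out_cells <- which(out_mask, arr.ind = TRUE)

    if (cfg$missing_mode == "mcar") {
      miss_mask <- matrix(stats::runif(S * M) < cfg$missing_prob, S)
    } else {
      miss_mask <- apply(x, 2, function(v) {
        v <= quantile(v, cfg$missing_prob)
      })
      miss_mask <- miss_mask & matrix(stats::runif(S * M) < 0.8, S)
    }
    miss_cells <- which(miss_mask, arr.ind = TRUE)
    x[miss_mask] <- NA_real_

    annotation <- tibble(
      metabolite_id = met_ids,
      display_name = met_ids,
      chem_class = sample(.chem_classes, M, replace = TRUE),
      kegg_compound = ifelse(stats::runif(M) < 0.6,
                             sprintf("C%05d", seq_len(M)), NA_character_),
      retention_index = round(stats::runif(M, 1000, 3200), 1))

    # planted enriched sets (consistent sign) plus random background sets
    sets <- list()
    descs <- character()
    set_dir <- rep(c("up", "down"), length.out = cfg$n_enriched_sets)
    up_ids <- dam_ids[alpha[dam_ids] > 0]
    down_ids <- dam_ids[alpha[dam_ids] < 0]
    enr_rows <- list()
    for (e in seq_len(cfg$n_enriched_sets)) {
      pool <- if (set_dir[e] == "up") up_ids else down_ids
      id <- sprintf("path_enriched_%02d", e)
      sets[[id]] <- sort(sample(pool, cfg$set_size))
      descs[[id]] <- paste0("planted ", set_dir[e], "-regulated set")
      enr_rows[[e]] <- tibble(set_id = id, direction = set_dir[e],
                              size = cfg$set_size)
    }
    non_dam <- setdiff(met_ids, dam_ids)
    for (b in seq_len(cfg$n_background_sets)) {
      id <- sprintf("path_background_%02d", b)
      sz <- sample(5:15, 1)
      sets[[id]] <- sort(sample(non_dam, sz))
      descs[[id]] <- "background set"
    }
    attr(sets, "description") <- descs

    blocks <- bind_rows(block_rows)

    truth <- list(
      dams = {
        dam_alpha <- unname(alpha[dam_ids])
        tibble(metabolite_id = dam_ids, alpha = dam_alpha,
               direction = as.character(ifelse(dam_alpha > 0, "up", "down")))
      },
      genotype_mets = tibble(metabolite_id = geno_ids,
                             beta = beta[match(geno_ids, met_ids)]),
      enriched_sets = if (length(enr_rows)) bind_rows(enr_rows) else
        tibble(set_id = character(), direction = character(),
               size = numeric()),
      blocks = blocks,
      outlier_cells = tibble(sample_id = metadata$sample_id[out_cells[, 1]],
                             metabolite_id = met_ids[out_cells[, 2]]),
      missing_cells = tibble(sample_id = metadata$sample_id[miss_cells[, 1]],
                             metabolite_id = met_ids[miss_cells[, 2]]),
      scale_factors = tibble(sample_id = metadata$sample_id,
                             scale = scale_fac),
      config = cfg)

    list(table = metab_table_from_matrix(x, state = "raw"),
         metadata = metadata, annotation = annotation, sets = sets,
         truth = truth)
  })
}

#' Flatten generator ground truth for the test suite
#'
#' @param truth The `truth` element of [simulate_dataset()] output.
#' @return A flat tibble (`section`, `id`, `partner`, `direction`, `value`),
#'   one row per planted fact, suitable for [write_table()].
#' @export
truth_summary <- function(truth) {
  bind_rows(
    dplyr::transmute(truth$dams, section = "dam", id = .data$metabolite_id,
                     partner = NA_character_, direction = .data$direction,
                     value = .data$alpha),
    dplyr::transmute(truth$enriched_sets, section = "enriched_set",
                     id = .data$set_id, partner = NA_character_,
                     direction = .data$direction, value = as.numeric(.data$size)),
    dplyr::transmute(truth$blocks, section = "block",
                     id = .data$metabolite_id,
                     partner = paste(.data$condition, .data$factor, sep = ":"),
                     direction = ifelse(.data$loading > 0, "up", "down"),
                     value = .data$loading),
    dplyr::transmute(truth$outlier_cells, section = "outlier",
                     id = .data$metabolite_id, partner = .data$sample_id,
                     direction = NA_character_, value = NA_real_),
    dplyr::transmute(truth$missing_cells, section = "missing",
                     id = .data$metabolite_id, partner = .data$sample_id,
                     direction = NA_character_, value = NA_real_))
}
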