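# The preprocessing chain: sample-median normalization -> Dixon outlier
# exclusion -> natural log + autoscaling -> group-aware KNN imputation.

#' Normalize each sample to its median abundance
#'
#' Divides every sample's values by that sample's median over non-missing
#' metabolites, removing per-sample injection/extraction scale differences.
#'
#' @param table A raw-state `metab_tbl`.
#' @return A list with `table` (state `"normalized"`) and
#'   `normalization_factors`, a tibble of the medians used.
#' @export
median_normalize <- function(table) {
  stopifnot(inherits(table, "metab_tbl"))
  if (mt_state(table) != "raw") abort("median_normalize() expects a raw-state table.")
  m <- abundance_matrix(table)
  med <- apply(m, 1, median, na.rm = TRUE)
  dead <- rownames(m)[is.na(med)]
  if (length(dead)) {
    abort(paste0("Sample(s) with no non-missing values: ",
                 paste(dead, collapse = ", ")))
  }
  zero <- rownames(m)[med == 0]
  if (length(zero)) {
    abort(paste0("Sample median is zero for: ", paste(zero, collapse = ", ")))
  }
  out <- sweep(m, 1, med, "/")
  list(table = metab_table_from_matrix(out, state = "normalized"),
       normalization_factors = tibble(sample_id = rownames(m),
                                      median = unname(med)))
}

#' Natural log transform and autoscale each metabolite
#'
#' Applies `log()` elementwise (all non-missing values must be positive, so
#' normalization must come first), then centers every metabolite column to
#' mean 0 and scales it to unit sample standard deviation (n - 1 denominator)
#' over its non-missing entries. Constant columns are set to all zeros rather
#' than dropped, keeping metabolite indices aligned.
#'
#' @param table A `metab_tbl` in raw or normalized state.
#' @return A `metab_tbl` with state `"log_scaled"`.
#' @export
log_autoscale <- function(table) {
  stopifnot(inherits(table, "metab_tbl"))
  if (!mt_state(table) %in% c("raw", "normalized")) {
    abort("log_autoscale() expects a raw or normalized table.")
  }
  m <- abundance_matrix(table)
  bad <- which(!is.na(m) & m <= 0, arr.ind = TRUE)
  if (nrow(bad)) {
    abort(paste0("Non-positive value at [sample ", rownames(m)[bad[1, 1]],
                 ", metabolite ", colnames(m)[bad[1, 2]],
                 "]; normalize before log transform."))
  }
  lg <- log(m)
  mu <- colMeans(lg, na.rm = TRUE)
  sdv <- apply(lg, 2, sd, na.rm = TRUE)
  centered <- sweep(lg, 2, mu, "-")
  const <- is.na(sdv) | sdv == 0
  sdv[const] <- 1
  scaled <- sweep(centered, 2, sdv, "/")
  scaled[, const] <- ifelse(is.na(lg[, const, drop = FALSE]), NA_real_, 0)
  metab_table_from_matrix(scaled, state = "log_scaled")
}

#' Group-aware k-nearest-neighbour imputation
#'
#' Imputes a missing cell (metabolite i, sample j) only when metabolite i is
#' observed in at least one other replicate of sample j's (genotype,
#' condition, time) group — the "present in other replicates, so the gap is a
#' technical error" rule. The imputed value is the plain average of the k
#' nearest metabolite rows (Euclidean distance over mutually non-missing
#' samples, rescaled to the full sample count) at sample j, the classic
#' impute-by-similar-features KNN scheme. Metabolites missing across an
#' entire group are left missing and flagged.
#'
#' @param table A `metab_tbl`, log-scaled (default pipeline order) or
#'   normalized (when imputing before scaling).
#' @param metadata Sample metadata.
#' @param k Number of neighbour metabolites (default 10); when fewer complete
#'   candidates exist, all available are used with a warning.
#' @return A list with `table` (state `"imputed"`), `imputed` (tibble of
#'   imputed cells) and `left_missing` (cells not eligible for imputation).
#' @export
knn_impute <- function(table, metadata, k = 10) {
  stopifnot(inherits(table, "metab_tbl"))
  if (!mt_state(table) %in% c("log_scaled", "normalized")) {
    abort("knn_impute() expects a log_scaled (or normalized) table.")
  }
  if (k < 1) abort("`k` must be at least 1.")
  metadata <- validate_metadata(metadata, table)
  m <- abundance_matrix(table)
  meta <- metadata[match(rownames(m), metadata$sample_id), ]
  grp <- group_key(meta)
  xm <- t(m)   # metabolites x samples; imputed values written here
  orig <- xm   # all neighbours and distances use the original matrix only
  n_samp <- ncol(xm)
  miss <- which(is.na(orig), arr.ind = TRUE)

  imputed <- list()
  left <- list()
  warned_k <- FALSE
  for (r in seq_len(nrow(miss))) {
    i <- miss[r, 1]; j <- miss[r, 2]
    mates <- which(grp == grp[j])
    if (!any(!is.na(orig[i, setdiff(mates, j)]))) {
      left[[length(left) + 1]] <- tibble(metabolite_id = rownames(xm)[i],
                                         sample_id = colnames(xm)[j])
      next
    }
    cand <- setdiff(which(!is.na(orig[, j])), i) # rows observed at sample j
    target <- orig[i, ]
    d <- vapply(cand, function(ii) {
      both <- !is.na(target) & !is.na(orig[ii, ])
      if (!any(both)) return(Inf)
      sqrt(sum((target[both] - orig[ii, both])^2) / sum(both) * n_samp)
    }, double(1))
    cand <- cand[is.finite(d)]
    d <- d[is.finite(d)]
    if (!length(cand)) {
      left[[length(left) + 1]] <- tibble(metabolite_id = rownames(xm)[i],
                                         sample_id = colnames(xm)[j])
      next
    }
    kk <- min(k, length(cand))
    if (kk < k && !warned_k) {
      warn(paste0("Fewer than k = ", k, " candidate neighbours for some cells; ",
                  "using all available."))
      warned_k <- TRUE
    }
    nn <- cand[order(d, rownames(orig)[cand])][seq_len(kk)]
    val <- mean(orig[cbind(nn, j)])
    imputed[[length(imputed) + 1]] <- tibble(
      metabolite_id = rownames(xm)[i], sample_id = colnames(xm)[j],
      value = val, k_used = kk)
    xm[i, j] <- val
  }
  empty_cells <- tibble(metabolite_id = character(), sample_id = character())
  list(table = metab_table_from_matrix(t(xm), state = "imputed"),
       imputed = if (length(imputed)) bind_rows(imputed) else
         dplyr::mutate(empty_cells, value = double(0), k_used = integer(0)),
       left_missing = if (length(left)) bind_rows(left) else empty_cells)
}

#' Run the full preprocessing chain
#'
#' Applies [median_normalize()], [dixon_filter()], [log_autoscale()] and
#' [knn_impute()] in that order (a `impute_before_scale` flag swaps the last
#' two for sensitivity analysis) and consolidates the per-stage reports.
#'
#' @param table A raw-state `metab_tbl`.
#' @param metadata Sample metadata.
#' @param dixon_alpha Significance level for the Dixon filter.
#' @param knn_k Neighbour count for imputation.
#' @param impute_before_scale If `TRUE`, impute on the normalized scale before
#'   log/autoscaling.
#' @return A list with `table` (state `"imputed"`) and `report`, a
#'   `preprocess_report` holding normalization factors, removed outliers and
#'   imputed cells.
#' @export
preprocess_pipeline <- function(table, metadata, dixon_alpha = 0.05,
                                knn_k = 10, impute_before_scale = FALSE) {
  norm <- median_normalize(table)
  dx <- dixon_filter(norm$table, metadata, alpha = dixon_alpha)
  if (impute_before_scale) {
    imp <- knn_impute(dx$table, metadata, k = knn_k)
    out <- log_autoscale(set_state(imp$table, "normalized"))
    out <- set_state(out, "imputed")
  } else {
    scaled <- log_autoscale(dx$table)
    imp <- knn_impute(scaled, metadata, k = knn_k)
    out <- imp$table
  }
  report <- structure(
    list(normalization_factors = norm$normalization_factors,
         outliers_removed = dx$outliers,
         imputed_cells = imp$imputed,
         left_missing = imp$left_missing),
    class = "preprocess_report")
  list(table = out, report = report)
}

#' @export
print.preprocess_report <- function(x, ...) {
  cat("Preprocessing report\n")
  cat(sprintf("  samples normalized : %d\n", nrow(x$normalization_factors)))
  cat(sprintf("  outliers removed   : %d\n", nrow(x$outliers_removed)))
  cat(sprintf("  cells imputed      : %d\n", nrow(x$imputed_cells)))
  cat(sprintf("  cells left missing : %d\n", nrow(x$left_missing)))
  invisible(x)
}

#' Flatten a preprocessing report to one row per event
#'
#' @param x A `preprocess_report`.
#' @param ... Unused.
#' @return A tibble with columns `stage`, `metabolite_id`, `sample_id`,
#'   `value`, suitable for [write_table()].
#' @export
tidy.preprocess_report <- function(x, ...) {
  bind_rows(
    dplyr::transmute(x$outliers_removed, stage = "dixon_outlier",
                     .data$metabolite_id, .data$sample_id, .data$value),
    dplyr::transmute(x$imputed_cells, stage = "knn_imputed",
                     .data$metabolite_id, .data$sample_id, .data$value),
    dplyr::transmute(x$left_missing, stage = "left_missing",
                     .data$metabolite_id, .data$sample_id, value = NA_real_))
}
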