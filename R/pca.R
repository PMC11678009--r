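# SVD-based PCA of the preprocessed matrix, with per-group 95% confidence
# ellipses for score plots.

#' Principal component analysis of a preprocessed table
#'
#' Singular value decomposition of the column-centered abundance matrix.
#' Variance fractions are ratios of squared singular values over the full
#' spectrum, and each component's sign is fixed so that its largest-magnitude
#' loading is positive, making the orientation deterministic.
#'
#' @param table An imputed-state `metab_tbl` with no missing entries.
#' @param n_components Number of components to retain; at most
#'   `min(samples - 1, metabolites)`.
#' @return A `metab_pca` object with `scores` (samples x components),
#'   `loadings` (metabolites x components, orthonormal columns) and
#'   `variance_fraction`. Supports [tidy()], [glance()] and [autoplot()].
#' @export
fit_pca <- function(table, n_components = 5) {
  stopifnot(inherits(table, "metab_tbl"))
  m <- abundance_matrix(table)
  if (anyNA(m)) {
    abort("Table contains missing entries; run preprocess_pipeline() first.")
  }
  max_comp <- min(nrow(m) - 1, ncol(m))
  if (n_components < 1 || n_components > max_comp) {
    abort(paste0("`n_components` must be in 1..", max_comp, "."))
  }
  x <- sweep(m, 2, colMeans(m), "-")
  sv <- svd(x)
  ev <- sv$d^2
  keep <- seq_len(n_components)
  loadings <- sv$v[, keep, drop = FALSE]
  scores <- sv$u[, keep, drop = FALSE] %*% diag(sv$d[keep], n_components)
  # deterministic orientation: largest-|loading| element positive
  for (a in keep) {
    top <- which.max(abs(loadings[, a]))
    if (loadings[top, a] < 0) {
      loadings[, a] <- -loadings[, a]
      scores[, a] <- -scores[, a]
    }
  }
  dimnames(scores) <- list(rownames(m), paste0("PC", keep))
  dimnames(loadings) <- list(colnames(m), paste0("PC", keep))
  structure(list(scores = scores, loadings = loadings,
                 variance_fraction = ev[keep] / sum(ev),
                 sdev = sv$d[keep] / sqrt(nrow(m) - 1),
                 n_samples = nrow(m), n_metabolites = ncol(m)),
            class = "metab_pca")
}

#' @export
print.metab_pca <- function(x, ...) {
  cat(sprintf("PCA: %d samples, %d metabolites, %d components\n",
              x$n_samples, x$n_metabolites, ncol(x$scores)))
  cat("variance fractions:",
      paste(sprintf("%.1f%%", 100 * x$variance_fraction), collapse = " "), "\n")
  invisible(x)
}

#' @export
#' @rdname fit_pca
#' @param x,object A `metab_pca`.
#' @param matrix Which matrix to tidy: `"scores"`, `"loadings"` or
#'   `"eigenvalues"`.
#' @param ... Unused.
tidy.metab_pca <- function(x, matrix = c("scores", "loadings", "eigenvalues"), ...) {
  matrix <- match.arg(matrix)
  if (matrix == "eigenvalues") {
    return(tibble(component = seq_along(x$variance_fraction),
                  std_dev = x$sdev,
                  variance_fraction = x$variance_fraction))
  }
  m <- x[[matrix]]
  id_col <- if (matrix == "scores") "sample_id" else "metabolite_id"
  out <- as_tibble(m)
  out[[id_col]] <- rownames(m)
  dplyr::relocate(out, all_of(id_col))
}

#' @export
#' @rdname fit_pca
glance.metab_pca <- function(x, ...) {
  tibble(n_samples = x$n_samples, n_metabolites = x$n_metabolites,
         n_components = ncol(x$scores),
         cum_variance_fraction = sum(x$variance_fraction))
}

#' Per-group confidence ellipses for 2-D scores
#'
#' Data (covariance) confidence ellipses: per group, the ellipse whose squared
#' Mahalanobis radius equals the chi-square quantile at `level` with 2 degrees
#' of freedom — the region expected to contain `level` of that group's
#' population under normality.
#'
#' @param scores A data frame or matrix whose first two numeric columns are
#'   the component scores (e.g. `tidy(pca)[, c("PC1","PC2")]`).
#' @param groups Group label per row.
#' @param level Confidence level in (0, 1), default 0.95.
#' @return A tibble with one row per group: center, semi-axes, rotation angle
#'   (radians) and group size. Groups with fewer than 3 samples are skipped
#'   with a warning.
#' @export
group_ellipse <- function(scores, groups, level = 0.95) {
  if (!is.numeric(level) || length(level) != 1 || level <= 0 || level >= 1) {
    abort("`level` must be a single value in (0, 1).")
  }
  s <- as.matrix(as.data.frame(scores))
  if (ncol(s) < 2) abort("`scores` needs two columns.")
  s <- s[, 1:2, drop = FALSE]
  groups <- as.character(groups)
  stopifnot(length(groups) == nrow(s))
  r2 <- qchisq(level, df = 2)
  out <- list()
  for (g in unique(groups)) {
    rows <- which(groups == g)
    if (length(rows) < 3) {
      warn(paste0("Group '", g, "' has fewer than 3 samples; ellipse skipped."))
      next
    }
    cv <- cov(s[rows, , drop = FALSE])
    eg <- eigen(cv, symmetric = TRUE)
    out[[g]] <- tibble(
      group = g,
      center_x = mean(s[rows, 1]), center_y = mean(s[rows, 2]),
      semi_major = sqrt(pmax(eg$values[1], 0) * r2),
      semi_minor = sqrt(pmax(eg$values[2], 0) * r2),
      angle = atan2(eg$vectors[2, 1], eg$vectors[1, 1]),
      level = level, n = length(rows))
  }
  if (!length(out)) {
    return(tibble(group = character(), center_x = double(), center_y = double(),
                  semi_major = double(), semi_minor = double(), angle = double(),
                  level = double(), n = integer()))
  }
  bind_rows(out)
}

# polygon approximation of an ellipse row, for plotting
ellipse_path <- function(e, n = 120) {
  th <- seq(0, 2 * pi, length.out = n)
  x0 <- e$semi_major * cos(th)
  y0 <- e$semi_minor * sin(th)
  tibble(group = e$group,
         x = e$center_x + x0 * cos(e$angle) - y0 * sin(e$angle),
         y = e$center_y + x0 * sin(e$angle) + y0 * cos(e$angle))
}
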