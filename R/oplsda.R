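# Two-class OPLS-DA, written from first principles. The predictor variance is
# split into one class-predictive component and n_orthogonal class-orthogonal
# components: the initial PLS weight is w = X'y (normalized); each orthogonal
# weight is the part of the X-loading not aligned with w; X is deflated by the
# orthogonal component and the predictive component is then recomputed on the
# deflated matrix. With a single centered y, X'y is unchanged by the
# orthogonal deflation, so w ⊥ w_o and t ⊥ t_o hold exactly.

opls_core <- function(X, yc, n_orthogonal = 1) {
  ss_x0 <- sum(X^2)
  w0 <- crossprod(X, yc)
  if (sqrt(sum(w0^2)) < 1e-10 * sqrt(ss_x0 * sum(yc^2) + 1e-300)) {
    abort("Degenerate contrast: X'y is numerically zero.")
  }
  w <- w0 / sqrt(sum(w0^2))
  Xd <- X
  Wo <- To <- Po <- NULL
  r2x_ortho <- double(0)
  for (a in seq_len(n_orthogonal)) {
    t <- Xd %*% w
    p <- crossprod(Xd, t) / sum(t^2)
    wo <- p - as.numeric(crossprod(w, p)) * w
    nwo <- sqrt(sum(wo^2))
    if (nwo < 1e-12) break
    wo <- wo / nwo
    to <- Xd %*% wo
    po <- crossprod(Xd, to) / sum(to^2)
    Xd <- Xd - to %*% t(po)
    Wo <- cbind(Wo, wo); To <- cbind(To, to); Po <- cbind(Po, po)
    r2x_ortho <- c(r2x_ortho, sum((to %*% t(po))^2) / ss_x0)
  }
  w <- crossprod(Xd, yc)
  w <- w / sqrt(sum(w^2))
  t <- Xd %*% w
  p <- crossprod(Xd, t) / sum(t^2)
  cc <- sum(yc * t) / sum(t^2)
  list(w = as.numeric(w), t = as.numeric(t), p = as.numeric(p), c = cc,
       Wo = Wo, To = To, Po = Po,
       r2x_predictive = sum((t %*% t(p))^2) / ss_x0,
       r2x_orthogonal = r2x_ortho,
       r2y = 1 - sum((yc - t * cc)^2) / sum(yc^2))
}

opls_predict <- function(core, Xnew) {
  if (!is.null(core$Wo)) {
    for (a in seq_len(ncol(core$Wo))) {
      to <- Xnew %*% core$Wo[, a]
      Xnew <- Xnew - to %*% t(core$Po[, a])
    }
  }
  as.numeric(Xnew %*% core$w) * core$c
}

# ---- user-facing fitting ---------------------------------------------------

build_xy <- function(table, metadata, class_var, contrast) {
  stopifnot(inherits(table, "metab_tbl"))
  if (mt_state(table) != "imputed") {
    abort("fit_oplsda() expects an imputed-state table; run preprocess_pipeline().")
  }
  metadata <- validate_metadata(metadata, table)
  if (length(contrast) != 2 || contrast[1] == contrast[2]) {
    abort("`contrast` must be two distinct class labels.")
  }
  if (!class_var %in% names(metadata)) {
    abort(paste0("Unknown class variable: ", class_var))
  }
  meta <- metadata[match(table$sample_id, metadata$sample_id), ]
  keep <- which(meta[[class_var]] %in% contrast)
  if (!length(keep)) abort("No samples match the contrast labels.")
  cls <- as.character(meta[[class_var]][keep])
  n_pos <- sum(cls == contrast[1]); n_neg <- sum(cls == contrast[2])
  if (n_pos < 3 || n_neg < 3) {
    abort(paste0("Each class needs at least 3 samples (got ", n_pos, " '",
                 contrast[1], "', ", n_neg, " '", contrast[2], "')."))
  }
  X <- abundance_matrix(table)[keep, , drop = FALSE]
  if (anyNA(X)) abort("Table contains missing entries after subsetting.")
  y <- ifelse(cls == contrast[1], 1, -1)
  list(X = X, y = y, sample_ids = table$sample_id[keep], classes = cls)
}

#' Fit a two-class OPLS-DA model
#'
#' Orthogonal partial least squares discriminant analysis with one predictive
#' and `n_orthogonal` orthogonal components. The first contrast label is the
#' positive class (encoded +1), so positive predictive loadings mean "higher
#' in the first label". The model stores the predictive weights, scores and
#' loadings, the orthogonal components, R²X per component, R²Y, the
#' cross-validated Q²Y (stratified `folds`-fold CV with a deterministic,
#' seeded fold assignment) and VIP scores.
#'
#' @param table An imputed-state `metab_tbl`.
#' @param metadata Sample metadata.
#' @param class_var Metadata column holding the class labels.
#' @param contrast Character pair `c(positive, negative)`.
#' @param n_orthogonal Number of orthogonal components (default 1).
#' @param folds,fold_seed Cross-validation folds and the seed fixing fold
#'   membership.
#' @return An `oplsda` object; see [tidy.oplsda()], [glance.oplsda()],
#'   [vip()], [select_dams()].
#' @export
fit_oplsda <- function(table, metadata, class_var = "condition",
                       contrast = c("hypoxia", "normoxia"),
                       n_orthogonal = 1, folds = 7, fold_seed = 1L) {
  d <- build_xy(table, metadata, class_var, contrast)
  x_center <- colMeans(d$X)
  X <- sweep(d$X, 2, x_center, "-")
  yc <- d$y - mean(d$y)
  if (var(yc) == 0) abort("Zero-variance class vector.")
  core <- opls_core(X, yc, n_orthogonal)
  M <- ncol(X)
  vip <- sqrt(M) * abs(core$w) / sqrt(sum(core$w^2))
  q2 <- q2_core(d$X, d$y, n_orthogonal = n_orthogonal, folds = folds,
                fold_seed = fold_seed)
  structure(list(
    weights = setNames(core$w, colnames(X)),
    scores = setNames(core$t, d$sample_ids),
    loadings = setNames(core$p, colnames(X)),
    y_loading = core$c,
    orthogonal = list(weights = core$Wo, scores = core$To, loadings = core$Po),
    r2x_predictive = core$r2x_predictive,
    r2x_orthogonal = core$r2x_orthogonal,
    r2y = core$r2y, q2y = q2, permutation_p = NA_real_,
    vip = setNames(vip, colnames(X)),
    pcorr = setNames(as.numeric(cor(X, core$t)), colnames(X)),
    class_encoding = setNames(c(1, -1), contrast),
    class_var = class_var, classes = d$classes,
    sample_ids = d$sample_ids, y = d$y,
    x_center = x_center, n_orthogonal = n_orthogonal,
    folds = folds, fold_seed = fold_seed),
    class = "oplsda")
}

#' @export
print.oplsda <- function(x, ...) {
  cat(sprintf("OPLS-DA: %s (+1) vs %s (-1), %d samples x %d metabolites\n",
              names(x$class_encoding)[1], names(x$class_encoding)[2],
              length(x$y), length(x$weights)))
  cat(sprintf("  1 predictive + %d orthogonal component(s)\n",
              length(x$r2x_orthogonal)))
  cat(sprintf("  R2X(pred) = %.3f  R2Y = %.3f  Q2Y = %.3f\n",
              x$r2x_predictive, x$r2y, x$q2y))
  if (!is.na(x$permutation_p)) {
    cat(sprintf("  permutation p = %.4g\n", x$permutation_p))
  }
  invisible(x)
}

# stratified fold assignment, deterministic for a given seed
stratified_folds <- function(y, folds, fold_seed) {
  if (folds < 2) abort("`folds` must be at least 2.")
  if (folds > length(y)) abort("`folds` cannot exceed the number of samples.")
  fold <- integer(length(y))
  withr::with_seed(fold_seed, {
    for (cls in unique(y)) {
      idx <- sample(which(y == cls))
      fold[idx] <- rep_len(seq_len(folds), length(idx))
    }
  })
  fold
}

q2_core <- function(X, y, n_orthogonal = 1, folds = 7, fold_seed = 1L) {
  fold <- stratified_folds(y, folds, fold_seed)
  press <- 0
  for (f in unique(fold)) {
    test <- fold == f
    ytr <- y[!test]
    if (length(unique(ytr)) < 2) {
      abort("A training split lost an entire class; reduce `folds`.")
    }
    ctr <- colMeans(X[!test, , drop = FALSE])
    Xtr <- sweep(X[!test, , drop = FALSE], 2, ctr, "-")
    core <- opls_core(Xtr, ytr - mean(ytr), n_orthogonal)
    Xte <- sweep(X[test, , drop = FALSE], 2, ctr, "-")
    yhat <- opls_predict(core, Xte) + mean(ytr)
    press <- press + sum((y[test] - yhat)^2)
  }
  1 - press / sum((y - mean(y))^2)
}

#' Cross-validated predictive ability Q²Y
#'
#' Q²Y = 1 - PRESS/SS(y), with PRESS accumulated over held-out predictions
#' from OPLS-DA models refit on each training split of a stratified K-fold
#' partition. Fold membership is deterministic given `fold_seed`.
#'
#' @inheritParams fit_oplsda
#' @return Q²Y, a real number no larger than 1 (negative values mean the
#'   model predicts worse than the class mean).
#' @export
q2_cv <- function(table, metadata, class_var = "condition",
                  contrast = c("hypoxia", "normoxia"), n_orthogonal = 1,
                  folds = 7, fold_seed = 1L) {
  d <- build_xy(table, metadata, class_var, contrast)
  q2_core(d$X, d$y, n_orthogonal, folds, fold_seed)
}

#' Label-permutation test of the OPLS-DA model
#'
#' Recomputes Q²Y under `n_perm` random permutations of the class labels and
#' reports the add-one estimator p = (1 + #\{Q²Y_perm ≥ Q²Y_obs\}) / (1 +
#' n_perm), so p is never exactly zero.
#'
#' @inheritParams fit_oplsda
#' @param folds Cross-validation folds used for each Q²Y evaluation.
#' @param n_perm Number of label permutations (at least 99).
#' @param seed Seed for the permutation stream (fold seeds are drawn from it).
#' @return The p-value, with attributes `observed_q2` and `null_q2`.
#' @export
permutation_test <- function(table, metadata, class_var = "condition",
                             contrast = c("hypoxia", "normoxia"),
                             n_orthogonal = 1, folds = 7,
                             n_perm = 1000, seed = 1L) {
  if (n_perm < 99) abort("`n_perm` must be at least 99.")
  d <- build_xy(table, metadata, class_var, contrast)
  null_q2 <- double(n_perm)
  withr::with_seed(seed, {
    fold_seeds <- sample.int(.Machine$integer.max - 1L, n_perm + 1L)
    perms <- lapply(seq_len(n_perm), function(i) sample(d$y))
  })
  obs <- q2_core(d$X, d$y, n_orthogonal, folds, fold_seeds[1])
  for (i in seq_len(n_perm)) {
    null_q2[i] <- q2_core(d$X, perms[[i]], n_orthogonal, folds,
                          fold_seeds[i + 1])
  }
  p <- (1 + sum(null_q2 >= obs)) / (1 + n_perm)
  structure(p, observed_q2 = obs, null_q2 = null_q2)
}

#' Variable importance in projection
#'
#' Predictive-component VIP: with one predictive component and unit-norm
#' weights w, `VIP_j = sqrt(M) * |w_j|`, so that the VIP² values average to 1
#' over the M metabolites. (The classic multi-component PLS VIP reduces to
#' exactly this expression when there is a single predictive component.)
#'
#' @param model A fitted `oplsda`.
#' @return Named numeric vector of VIP scores.
#' @export
vip <- function(model) {
  if (!inherits(model, "oplsda")) abort("`model` must be a fitted oplsda object.")
  sqrt(length(model$weights)) * abs(model$weights) / sqrt(sum(model$weights^2))
}

#' Select differentially accumulating metabolites (DAMs)
#'
#' Retains metabolites whose VIP is at least `vip_min` and whose predictive
#' loading passes the loading rule. The default rule (`"pcorr"`) thresholds
#' the scaled loading — the correlation between a metabolite and the
#' predictive scores — at an absolute value (`loading_cor_min`), so the DAM
#' count genuinely tracks the strength of the class difference; a model with
#' no real signal selects few metabolites. The alternative `"quantile"` rule
#' keeps the metabolites in the upper `loading_quantile` tail of |loading|;
#' being relative, it selects a near-constant fraction regardless of signal
#' strength. Direction follows the loading sign under the class encoding
#' ("up" = higher in the positive class). The log2 fold change of group means
#' is computed from an abundance table on the normalized (pre-log) scale.
#'
#' @param model A fitted `oplsda`.
#' @param abundance A raw- or normalized-state `metab_tbl` covering the
#'   model's samples (fold changes are meaningless on autoscaled values).
#' @param metadata Sample metadata.
#' @param vip_min VIP threshold (default 1, the community convention).
#' @param loading_rule `"pcorr"` (default) or `"quantile"`.
#' @param loading_cor_min Absolute score-correlation threshold for the
#'   `"pcorr"` rule (default 0.5).
#' @param loading_quantile Quantile of |loading| a DAM must reach under the
#'   `"quantile"` rule (default 0.75).
#' @return A tibble with one row per DAM (`metabolite_id`, `loading`,
#'   `loading_cor`, `vip`, `direction`, `log2_fc`); the thresholds used are
#'   stored as attributes.
#' @export
select_dams <- function(model, abundance, metadata, vip_min = 1.0,
                        loading_rule = c("pcorr", "quantile"),
                        loading_cor_min = 0.5, loading_quantile = 0.75) {
  if (!inherits(model, "oplsda")) abort("`model` must be a fitted oplsda object.")
  loading_rule <- match.arg(loading_rule)
  if (!is.numeric(vip_min) || vip_min < 0) abort("`vip_min` must be >= 0.")
  if (!is.numeric(loading_quantile) || loading_quantile < 0 ||
      loading_quantile >= 1) {
    abort("`loading_quantile` must be in [0, 1).")
  }
  if (!is.numeric(loading_cor_min) || loading_cor_min < 0 ||
      loading_cor_min > 1) {
    abort("`loading_cor_min` must be in [0, 1].")
  }
  if (!mt_state(abundance) %in% c("raw", "normalized")) {
    abort("`abundance` must be on the raw or normalized scale for fold changes.")
  }
  # scaled loading: correlation of each metabolite with the predictive scores
  pcorr <- model$pcorr
  if (loading_rule == "pcorr") {
    thr <- loading_cor_min
    keep <- which(model$vip >= vip_min & abs(pcorr) >= thr)
  } else {
    thr <- quantile(abs(model$loadings), loading_quantile, names = FALSE)
    keep <- which(model$vip >= vip_min & abs(model$loadings) >= thr)
  }

  av <- abundance_matrix(subset_samples(abundance, model$sample_ids))
  pos <- model$classes == names(model$class_encoding)[1]
  mean_pos <- colMeans(av[pos, , drop = FALSE], na.rm = TRUE)
  mean_neg <- colMeans(av[!pos, , drop = FALSE], na.rm = TRUE)
  l2fc <- log2(mean_pos / mean_neg)

  ids <- names(model$loadings)[keep]
  out <- tibble(
    metabolite_id = ids,
    loading = unname(model$loadings[keep]),
    loading_cor = unname(pcorr[keep]),
    vip = unname(model$vip[keep]),
    direction = unname(ifelse(model$loadings[keep] > 0, "up", "down")),
    log2_fc = unname(l2fc[ids]))
  out <- arrange(out, dplyr::desc(abs(.data$loading)))
  attr(out, "vip_min") <- vip_min
  attr(out, "loading_rule") <- loading_rule
  attr(out, "loading_threshold") <- thr
  attr(out, "contrast") <- names(model$class_encoding)
  out
}

#' Spearman comparison of predictive loadings between two models
#'
#' Rank correlation of the predictive loadings over the metabolites shared by
#' the two models (matched by id; ties mid-ranked), with the p-value from the
#' large-sample t approximation.
#'
#' @param model_a,model_b Fitted `oplsda` objects sharing at least 10
#'   metabolites.
#' @return A one-row tibble: `rho`, `p_value`, `n_shared`.
#' @export
compare_loadings <- function(model_a, model_b) {
  shared <- intersect(names(model_a$loadings), names(model_b$loadings))
  if (length(shared) < 10) {
    abort("Models share fewer than 10 metabolites; comparison is unreliable.")
  }
  a <- rank(model_a$loadings[shared])
  b <- rank(model_b$loadings[shared])
  rho <- cor(a, b)
  n <- length(shared)
  tt <- rho * sqrt((n - 2) / pmax(1 - rho^2, .Machine$double.eps))
  tibble(rho = rho, p_value = 2 * pt(-abs(tt), df = n - 2), n_shared = n)
}

#' @export
#' @rdname fit_oplsda
#' @param x,object A fitted `oplsda`.
#' @param ... Unused.
tidy.oplsda <- function(x, ...) {
  tibble(metabolite_id = names(x$weights),
         weight = unname(x$weights),
         loading = unname(x$loadings),
         vip = unname(x$vip))
}

#' @export
#' @rdname fit_oplsda
glance.oplsda <- function(x, ...) {
  tibble(n_samples = length(x$y), n_metabolites = length(x$weights),
         n_orthogonal = length(x$r2x_orthogonal),
         r2x_predictive = x$r2x_predictive,
         r2x_orthogonal_total = sum(x$r2x_orthogonal),
         r2y = x$r2y, q2y = x$q2y, permutation_p = x$permutation_p)
}
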