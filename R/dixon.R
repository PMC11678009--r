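# Dixon's r10 ("Q") test for a single outlier in small replicate groups.
# Two-sided critical values from Rorabacher (1991), n = 3..30, packaged as a
# constant table so decisions are exactly reproducible. Q = gap/range for the
# most extreme value; one removal at most per metabolite x group.

.dixon_n <- 3:30
.dixon_crit <- list(
  "0.1" = c(0.941, 0.765, 0.642, 0.560, 0.507, 0.468, 0.437, 0.412,
            0.392, 0.376, 0.361, 0.349, 0.338, 0.329, 0.320, 0.313,
            0.306, 0.300, 0.295, 0.290, 0.285, 0.281, 0.277, 0.273,
            0.269, 0.266, 0.263, 0.260),
  "0.05" = c(0.970, 0.829, 0.710, 0.625, 0.568, 0.526, 0.493, 0.466,
             0.444, 0.426, 0.410, 0.396, 0.384, 0.374, 0.365, 0.356,
             0.349, 0.342, 0.337, 0.331, 0.326, 0.321, 0.317, 0.312,
             0.308, 0.305, 0.301, 0.298),
  "0.01" = c(0.994, 0.926, 0.821, 0.740, 0.680, 0.634, 0.598, 0.568,
             0.542, 0.522, 0.503, 0.488, 0.475, 0.463, 0.452, 0.442,
             0.433, 0.425, 0.418, 0.411, 0.404, 0.399, 0.393, 0.388,
             0.384, 0.380, 0.376, 0.372))

#' Two-sided critical value for Dixon's r10 statistic
#'
#' @param n Group size, 3 to 30.
#' @param alpha Significance level; one of the tabulated levels 0.01, 0.05, 0.1.
#' @return The critical value; the test flags an outlier when Q exceeds it.
#' @export
dixon_critical <- function(n, alpha = 0.05) {
  if (!is.numeric(alpha) || alpha <= 0 || alpha >= 1) {
    abort("`alpha` must be in (0, 1).")
  }
  key <- as.character(alpha)
  if (!key %in% names(.dixon_crit)) {
    abort("Tabulated critical values exist only for alpha in {0.01, 0.05, 0.1}.")
  }
  if (any(n < 3 | n > 30)) abort("Dixon's r10 table covers n = 3..30.")
  .dixon_crit[[key]][match(n, .dixon_n)]
}

# Q statistic and index of the most extreme value; NULL for a degenerate
# range (exactly constant, or spread at floating-point noise level).
dixon_q <- function(x) {
  x <- unname(x[!is.na(x)])
  n <- length(x)
  rng <- max(x) - min(x)
  if (rng <= max(abs(x)) * 1e-12) return(NULL)
  ord <- order(x)
  s <- x[ord]
  q_low <- (s[2] - s[1]) / rng
  q_high <- (s[n] - s[n - 1]) / rng
  if (q_high >= q_low) {
    list(q = q_high, which = ord[n], value = s[n])
  } else {
    list(q = q_low, which = ord[1], value = s[1])
  }
}

#' Exclude single-value outliers by Dixon's test within replicate groups
#'
#' For every metabolite within every (genotype, condition, time) replicate
#' group of 3 to 30 samples, tests the most extreme value with Dixon's
#' two-sided r10 statistic and, when Q exceeds the tabulated critical value,
#' marks that one value missing (it then becomes eligible for imputation).
#' At most one value is removed per metabolite per group. Groups smaller than
#' 3 are skipped with a warning.
#'
#' @param table A `metab_tbl` (raw or normalized state).
#' @param metadata Sample metadata; see [validate_metadata()].
#' @param alpha Significance level for the tabulated critical values.
#' @return A list with `table` (values with outliers set to missing, state
#'   unchanged) and `outliers`, a tibble logging each removal with its Q and
#'   critical value.
#' @export
dixon_filter <- function(table, metadata, alpha = 0.05) {
  stopifnot(inherits(table, "metab_tbl"))
  metadata <- validate_metadata(metadata, table)
  dixon_critical(3, alpha) # validates alpha up front
  m <- abundance_matrix(table)
  meta <- metadata[match(rownames(m), metadata$sample_id), ]
  grp <- group_key(meta)

  small <- unique(grp[ave(seq_along(grp), grp, FUN = length) < 3])
  if (length(small)) {
    warn(paste0("Group(s) with fewer than 3 replicates skipped by Dixon test: ",
                paste(small, collapse = ", ")))
  }

  removals <- list()
  for (g in unique(grp)) {
    rows <- which(grp == g)
    for (j in seq_len(ncol(m))) {
      v <- m[rows, j]
      ok <- !is.na(v)
      n <- sum(ok)
      if (n < 3 || n > 30) next
      qq <- dixon_q(v)
      if (is.null(qq)) next
      crit <- dixon_critical(n, alpha)
      if (qq$q > crit) {
        i <- rows[qq$which]
        removals[[length(removals) + 1]] <- tibble(
          metabolite_id = colnames(m)[j], sample_id = rownames(m)[i],
          group = g, value = m[i, j], q = qq$q, critical = crit, n = n)
        m[i, j] <- NA_real_
      }
    }
  }
  outliers <- if (length(removals)) bind_rows(removals) else
    tibble(metabolite_id = character(), sample_id = character(),
           group = character(), value = double(), q = double(),
           critical = double(), n = integer())
  list(table = metab_table_from_matrix(m, state = mt_state(table)),
       outliers = outliers)
}
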