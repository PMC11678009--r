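# Core container: a wide tibble of abundances (samples in rows) that carries a
# processing-state flag, so each pipeline stage can assert what it receives.

#' Metabolite abundance tables
#'
#' A `metab_tbl` is a wide tibble whose first column, `sample_id`, holds unique
#' sample identifiers and whose remaining columns are numeric metabolite
#' abundances (arbitrary peak-area units; `NA` marks a missing measurement).
#' The object carries a processing-state flag, one of `"raw"`, `"normalized"`,
#' `"log_scaled"` or `"imputed"`, which the preprocessing stages check and
#' advance; see [preprocess_pipeline()].
#'
#' @param x A data frame with a `sample_id` column (or row names) and one
#'   numeric column per metabolite.
#' @param state Processing state of the values, one of `"raw"`, `"normalized"`,
#'   `"log_scaled"`, `"imputed"`.
#' @return A `metab_tbl` (subclass of `tbl_df`).
#' @examples
#' tab <- metab_table(data.frame(sample_id = c("s1", "s2"),
#'                               met_a = c(1, 2), met_b = c(3, NA)))
#' mt_state(tab)
#' abundance_matrix(tab)
#' @export
metab_table <- function(x, state = "raw") {
  x <- as_tibble(x)
  if (!"sample_id" %in% names(x)) {
    abort("`x` must have a `sample_id` column.")
  }
  x <- dplyr::relocate(x, "sample_id")
  x$sample_id <- as.character(x$sample_id)
  out <- new_metab_tbl(x, state)
  validate_metab_tbl(out)
}

new_metab_tbl <- function(x, state) {
  state <- match.arg(state, c("raw", "normalized", "log_scaled", "imputed"))
  structure(x, state = state,
            class = c("metab_tbl", "tbl_df", "tbl", "data.frame"))
}

validate_metab_tbl <- function(x) {
  ids <- x$sample_id
  if (anyDuplicated(ids)) {
    abort(paste0("Duplicated sample id(s): ",
                 paste(unique(ids[duplicated(ids)]), collapse = ", ")))
  }
  mets <- setdiff(names(x), "sample_id")
  if (anyDuplicated(mets)) {
    abort(paste0("Duplicated metabolite id(s): ",
                 paste(unique(mets[duplicated(mets)]), collapse = ", ")))
  }
  not_num <- mets[!vapply(x[mets], is.numeric, logical(1))]
  if (length(not_num)) {
    abort(paste0("Non-numeric metabolite column(s): ",
                 paste(not_num, collapse = ", ")))
  }
  if (mt_state(x) == "raw") {
    m <- abundance_matrix(x)
    neg <- which(!is.na(m) & m < 0, arr.ind = TRUE)
    if (nrow(neg)) {
      abort(paste0("Negative abundance in raw table at [sample ",
                   rownames(m)[neg[1, 1]], ", metabolite ",
                   colnames(m)[neg[1, 2]], "]"))
    }
  }
  x
}

#' @rdname metab_table
#' @export
mt_state <- function(x) {
  stopifnot(inherits(x, "metab_tbl"))
  attr(x, "state")
}

set_state <- function(x, state) {
  new_metab_tbl(as_tibble(as.data.frame(x)), state)
}

#' @rdname metab_table
#' @export
abundance_matrix <- function(x) {
  stopifnot(inherits(x, "metab_tbl"))
  m <- as.matrix(as.data.frame(x)[setdiff(names(x), "sample_id")])
  rownames(m) <- x$sample_id
  m
}

#' @rdname metab_table
#' @param m A numeric matrix, samples in rows (row names = sample ids).
#' @export
metab_table_from_matrix <- function(m, state = "raw") {
  stopifnot(is.matrix(m), !is.null(rownames(m)), !is.null(colnames(m)))
  df <- as_tibble(m, .name_repair = "minimal")
  df <- dplyr::bind_cols(tibble(sample_id = rownames(m)), df)
  out <- new_metab_tbl(df, state)
  validate_metab_tbl(out)
}

#' @rdname metab_table
#' @export
metabolite_ids <- function(x) setdiff(names(x), "sample_id")

#' Keep a subset of samples, preserving class and state
#'
#' `dplyr` verbs strip the `metab_tbl` class, so row subsetting goes through
#' this helper.
#'
#' @param x A `metab_tbl`.
#' @param sample_ids Character vector of sample ids to keep, in this order.
#' @return A `metab_tbl` with the same state.
#' @export
subset_samples <- function(x, sample_ids) {
  stopifnot(inherits(x, "metab_tbl"))
  missing <- setdiff(sample_ids, x$sample_id)
  if (length(missing)) {
    abort(paste0("Unknown sample id(s): ", paste(missing, collapse = ", ")))
  }
  out <- as_tibble(as.data.frame(x))[match(sample_ids, x$sample_id), ]
  new_metab_tbl(out, mt_state(x))
}

#' @export
print.metab_tbl <- function(x, ...) {
  cat(sprintf("# A metab_tbl: %d samples x %d metabolites, state = %s\n",
              nrow(x), length(metabolite_ids(x)), mt_state(x)))
  NextMethod()
}

#' Validate a sample metadata table
#'
#' Checks the factorial design columns (`sample_id`, `genotype`, `condition`,
#' `time_das`, `replicate`), uniqueness of ids and of design tuples, and the
#' allowed oxygen conditions.
#'
#' @param metadata A data frame of per-sample factors.
#' @param table Optional `metab_tbl`; when given, every sample in the table
#'   must have exactly one metadata row.
#' @return The validated metadata as a tibble (invisibly usable in pipes).
#' @export
validate_metadata <- function(metadata, table = NULL) {
  metadata <- as_tibble(metadata)
  need <- c("sample_id", "genotype", "condition", "time_das", "replicate")
  miss <- setdiff(need, names(metadata))
  if (length(miss)) {
    abort(paste0("Metadata is missing column(s): ", paste(miss, collapse = ", ")))
  }
  metadata$sample_id <- as.character(metadata$sample_id)
  if (anyDuplicated(metadata$sample_id)) {
    dup <- unique(metadata$sample_id[duplicated(metadata$sample_id)])
    abort(paste0("Duplicated sample id(s) in metadata: ", paste(dup, collapse = ", ")))
  }
  bad <- setdiff(unique(metadata$condition), c("normoxia", "hypoxia"))
  if (length(bad)) {
    abort(paste0("`condition` must be 'normoxia' or 'hypoxia'; found: ",
                 paste(bad, collapse = ", ")))
  }
  key <- paste(metadata$genotype, metadata$condition, metadata$time_das,
               metadata$replicate)
  if (anyDuplicated(key)) {
    abort("Duplicated (genotype, condition, time_das, replicate) design tuple(s).")
  }
  if (!is.null(table)) {
    orphans <- setdiff(table$sample_id, metadata$sample_id)
    if (length(orphans)) {
      abort(paste0("Sample(s) present in abundance table but absent from ",
                   "metadata: ", paste(orphans, collapse = ", ")))
    }
  }
  metadata
}

# group key used by the Dixon filter and KNN imputation
group_key <- function(metadata) {
  paste(metadata$genotype, metadata$condition, metadata$time_das, sep = ".")
}
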