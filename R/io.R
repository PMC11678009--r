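# Reading and writing the tabular interchange formats: wide abundance TSV/CSV,
# sample metadata, metabolite annotations and GMT metabolite-set files.
# Delimiter is chosen from the file extension (.csv => comma, otherwise tab);
# empty cells and "NA" are both read as missing, and missing is written back as
# an empty cell.

delim_for <- function(path) if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"

read_wide <- function(path) {
  readr::read_delim(path, delim = delim_for(path), na = c("", "NA"),
                    show_col_types = FALSE, progress = FALSE,
                    name_repair = "minimal")
}

#' Load an abundance matrix with its metadata and annotations
#'
#' Reads a wide samples-by-metabolites table (first column = sample ids, header
#' row = metabolite ids), a sample metadata table and, optionally, a metabolite
#' annotation table, cross-validating identifiers. Blank cells and `"NA"` are
#' parsed as missing values, never as zero. A matrix whose row identifiers
#' match metabolite annotations while its column names match the metadata
#' samples is rejected with a transposition hint rather than silently
#' transposed.
#'
#' @param matrix_path Path to the abundance table (TSV, or CSV by extension).
#' @param metadata_path Path to the sample metadata table.
#' @param annotation_path Optional path to a metabolite annotation table with
#'   columns `metabolite_id`, `display_name`, `chem_class` and optionally
#'   `kegg_compound`, `retention_index`.
#' @return A list with elements `table` (a raw-state [metab_table()]),
#'   `metadata` (tibble) and `annotation` (tibble or `NULL`).
#' @export
load_dataset <- function(matrix_path, metadata_path, annotation_path = NULL) {
  for (p in c(matrix_path, metadata_path, annotation_path)) {
    if (!is.null(p) && !file.exists(p)) abort(paste0("File not found: ", p))
  }
  wide <- read_wide(matrix_path)
  names(wide)[1] <- "sample_id"
  metadata <- validate_metadata(read_wide(metadata_path))

  if (!any(wide$sample_id %in% metadata$sample_id) &&
      any(names(wide)[-1] %in% metadata$sample_id)) {
    abort(paste0("Abundance matrix appears transposed: its column names match ",
                 "metadata sample ids. Provide samples in rows."))
  }
  table <- metab_table(wide, state = "raw")
  validate_metadata(metadata, table)

  annotation <- NULL
  if (!is.null(annotation_path)) {
    annotation <- read_wide(annotation_path)
    if (!"metabolite_id" %in% names(annotation)) {
      abort("Annotation table must have a `metabolite_id` column.")
    }
    annotation$metabolite_id <- as.character(annotation$metabolite_id)
    if (anyDuplicated(annotation$metabolite_id)) {
      dup <- unique(annotation$metabolite_id[duplicated(annotation$metabolite_id)])
      abort(paste0("Duplicated metabolite id(s) in annotation: ",
                   paste(dup, collapse = ", ")))
    }
  }
  list(table = table, metadata = metadata, annotation = annotation)
}

#' Read a GMT metabolite-set file
#'
#' GMT lines are tab-separated: set id, description, then one or more member
#' metabolite ids. Membership order is preserved; members may be shared
#' between sets.
#'
#' @param path Path to a GMT file.
#' @return A named list of character vectors (one per set), with the set
#'   descriptions in `attr(, "description")`.
#' @export
load_metabolite_sets <- function(path) {
  if (!file.exists(path)) abort(paste0("File not found: ", path))
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (!length(lines)) abort("GMT file is empty.")
  sets <- list()
  descs <- character()
  for (i in seq_along(lines)) {
    parts <- strsplit(lines[[i]], "\t", fixed = TRUE)[[1]]
    if (length(parts) < 3 || !any(nzchar(parts[-(1:2)]))) {
      abort(paste0("Malformed GMT line ", i, ": need set id, description and ",
                   "at least one member."))
    }
    id <- parts[[1]]
    if (id %in% names(sets)) abort(paste0("Duplicated set id: ", id))
    sets[[id]] <- parts[-(1:2)][nzchar(parts[-(1:2)])]
    descs[[id]] <- parts[[2]]
  }
  attr(sets, "description") <- descs
  sets
}

#' Write metabolite sets as GMT
#'
#' @param sets Named list of character vectors, as from
#'   [load_metabolite_sets()].
#' @param path Output path.
#' @export
write_gmt <- function(sets, path) {
  descs <- attr(sets, "description") %||% setNames(names(sets), names(sets))
  lines <- vapply(names(sets), function(id) {
    paste(c(id, descs[[id]] %||% id, sets[[id]]), collapse = "\t")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

#' Write a tabular result deterministically
#'
#' Serializes any of the package's tabular results (including `metab_tbl`
#' objects) as TSV with a fixed column order and floating-point values
#' rendered at a fixed number of significant digits, so that two writes of the
#' same object are byte-identical. Missing values become empty cells.
#'
#' @param x A data frame.
#' @param path Output path.
#' @param digits Significant digits for numeric columns (default 6).
#' @return `path`, invisibly.
#' @export
write_table <- function(x, path, digits = 6) {
  df <- as_tibble(as.data.frame(x))
  df <- dplyr::mutate(df, dplyr::across(
    dplyr::where(is.numeric),
    function(v) {
      out <- ifelse(is.na(v), NA_character_,
                    formatC(signif(v, digits), digits = digits,
                            format = "g", flag = "-"))
      trimws(out)
    }))
  con <- tryCatch(file(path, "wb"), error = function(e) {
    abort(paste0("Cannot open path for writing: ", path))
  })
  close(con)
  readr::write_tsv(df, path, na = "", progress = FALSE)
  invisible(path)
}
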