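#' Read a samples-by-metabolites abundance matrix
#'
#' Reads a TSV or CSV file holding a two-group metabolomic matrix: first
#' column sample id, one designated group column, every remaining column a
#' metabolite. Empty cells and the literal string `NA` are treated as missing
#' values (to be handled by [impute_metabolites()]).
#'
#' @param path Path to the file.
#' @param format `"auto"` (from the file extension), `"tsv"` or `"csv"`.
#' @param group_col Name of the column holding the two group labels.
#' @param sample_col Name given to the sample-id column in the returned tibble
#'   (the file's first column is used regardless of its header).
#' @param transpose If `TRUE` the file is metabolites-by-samples and is
#'   transposed after reading; the group labels must then sit in a row named
#'   `group_col`.
#'
#' @return A tibble with columns `sample_col`, `group_col`, then one numeric
#'   column per metabolite, in file order.
#' @seealso [write_metabolite_matrix()], [impute_metabolites()]
#' @export
read_metabolite_matrix <- function(path, format = c("auto", "tsv", "csv"),
                                   group_col = "group",
                                   sample_col = "sample_id",
                                   transpose = FALSE) {
  format <- match.arg(format)
  if (!file.exists(path)) abort(sprintf("file '%s' does not exist", path))
  if (format == "auto") {
    format <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "csv" else "tsv"
  }
  reader <- if (format == "csv") readr::read_csv else readr::read_tsv
  raw <- reader(path,
    na = c("", "NA"), show_col_types = FALSE, progress = FALSE,
    col_types = readr::cols(.default = readr::col_guess()),
    name_repair = "minimal"
  )
  if (ncol(raw) < 2L) abort("matrix file needs at least an id column and one data column")

  if (transpose) {
    ids <- as.character(raw[[1L]])
    if (anyDuplicated(ids)) {
      abort(sprintf("duplicated row id '%s'", ids[duplicated(ids)][1L]))
    }
    body <- t(as.matrix(raw[-1L]))
    samples <- colnames(raw)[-1L]
    out <- tibble::as_tibble(as.data.frame(body, stringsAsFactors = FALSE),
      .name_repair = "minimal"
    )
    names(out) <- ids
    out <- tibble::add_column(out, !!sample_col := samples, .before = 1L)
    if (!group_col %in% ids) {
      abort(sprintf("no row named '%s' found to transpose into group labels", group_col))
    }
    mets <- setdiff(ids, group_col)
    out[mets] <- lapply(out[mets], as.numeric)
    raw <- out[c(sample_col, group_col, mets)]
  } else {
    names(raw)[1L] <- sample_col
    raw[[sample_col]] <- as.character(raw[[sample_col]])
  }

  if (!group_col %in% names(raw)) {
    abort(sprintf("group column '%s' not found", group_col))
  }
  dup_cols <- names(raw)[duplicated(names(raw))]
  if (length(dup_cols) > 0L) {
    abort(sprintf("duplicated metabolite column name '%s'", dup_cols[1L]))
  }
  ids <- raw[[sample_col]]
  if (anyDuplicated(ids)) {
    abort(sprintf("duplicated sample id '%s'", ids[duplicated(ids)][1L]))
  }
  check_two_groups(raw[[group_col]])

  mets <- setdiff(names(raw), c(sample_col, group_col))
  not_num <- mets[!vapply(raw[mets], is.numeric, logical(1L))]
  if (length(not_num) > 0L) {
    abort(sprintf("metabolite column '%s' is not numeric", not_num[1L]))
  }
  raw[c(sample_col, group_col, mets)]
}

#' Write a metabolite tibble back to TSV/CSV
#'
#' Inverse of [read_metabolite_matrix()]; missing values are written as empty
#' cells. The round trip is lossless for finite values (numbers are written
#' with full precision).
#'
#' @inheritParams read_metabolite_matrix
#' @param data Metabolite tibble (see [read_metabolite_matrix()]).
#' @return `path`, invisibly.
#' @export
write_metabolite_matrix <- function(data, path, format = c("auto", "tsv", "csv")) {
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "csv" else "tsv"
  }
  writer <- if (format == "csv") readr::write_csv else readr::write_tsv
  writer(data, path, na = "")
  invisible(path)
}
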