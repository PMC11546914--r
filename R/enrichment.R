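# Local pathway over-representation analysis (one-sided hypergeometric) and
# the primary/secondary marker-set combination logic.

#' Read / write GMT-style pathway annotations
#'
#' A GMT line is tab-separated: pathway id, description, then member
#' metabolite identifiers. Duplicate members within a line are dropped with a
#' warning; a line with no members is skipped with a warning.
#'
#' @param path File path.
#' @return `read_gmt()`: a tibble with columns `pathway_id`, `pathway_name`
#'   and `members` (list-column of character vectors).
#' @export
read_gmt <- function(path) {
  if (!file.exists(path)) abort(sprintf("file '%s' does not exist", path))
  lines <- readr::read_lines(path, progress = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  rows <- purrr::map(lines, function(ln) {
    parts <- strsplit(ln, "\t", fixed = TRUE)[[1L]]
    if (length(parts) < 3L) {
      warn(sprintf("pathway '%s' has no members; skipped", parts[1L]))
      return(NULL)
    }
    members <- parts[-(1:2)]
    members <- members[nzchar(members)]
    if (anyDuplicated(members)) {
      warn(sprintf("duplicated member(s) in pathway '%s'; deduplicated", parts[1L]))
      members <- unique(members)
    }
    if (length(members) == 0L) {
      warn(sprintf("pathway '%s' has no members; skipped", parts[1L]))
      return(NULL)
    }
    tibble::tibble(
      pathway_id = parts[1L], pathway_name = parts[2L], members = list(members)
    )
  })
  dplyr::bind_rows(rows)
}

#' @rdname read_gmt
#' @param annotation Tibble as returned by `read_gmt()`.
#' @export
write_gmt <- function(annotation, path) {
  lines <- purrr::pmap_chr(
    annotation[c("pathway_id", "pathway_name", "members")],
    function(pathway_id, pathway_name, members) {
      paste(c(pathway_id, pathway_name, members), collapse = "\t")
    }
  )
  readr::write_lines(lines, path)
  invisible(path)
}

#' Over-representation analysis of a marker set
#'
#' One-sided (upper tail) hypergeometric test per pathway: with a universe of
#' `N` measured metabolites, a pathway covering `K` of them and a marker set
#' of `n` draws, `p = P(X >= hits)` for `X ~ Hypergeometric(N, K, n)`.
#' Benjamini-Hochberg FDR across pathways. Pathway member sets are
#' intersected with the universe before testing, so annotation entries that
#' were never measured do not count. The defensible universe is the set of
#' metabolites actually measured (and mapped to the annotation namespace) —
#' web-tool universes are typically undocumented, which is why printed
#' enrichment p-values from such tools are not directly comparable.
#'
#' @param markers Character vector of marker ids (must lie in `universe`).
#' @param annotation Pathway tibble from [read_gmt()] (or of the same shape).
#' @param universe Character vector: all measured/mappable metabolite ids.
#' @return A tibble of class `ora_result`, one row per tested pathway:
#'   `pathway_id`, `pathway_name`, `total` (pathway size in the universe),
#'   `hits`, `p_value`, `fdr`, sorted by p.
#' @export
ora <- function(markers, annotation, universe) {
  universe <- unique(universe)
  if (length(universe) == 0L) abort("universe must be nonempty")
  markers <- unique(markers)
  stray <- setdiff(markers, universe)
  if (length(stray) > 0L) {
    abort(sprintf(
      "marker(s) outside the universe: %s", paste(stray, collapse = ", ")
    ))
  }
  n_draws <- length(markers)
  rows <- purrr::pmap(
    annotation[c("pathway_id", "pathway_name", "members")],
    function(pathway_id, pathway_name, members) {
      in_universe <- intersect(members, universe)
      total <- length(in_universe)
      if (total == 0L) return(NULL)
      hits <- length(intersect(markers, in_universe))
      p <- phyper(hits - 1L, total, length(universe) - total, n_draws,
        lower.tail = FALSE
      )
      tibble::tibble(
        pathway_id = pathway_id, pathway_name = pathway_name,
        total = total, hits = hits, p_value = p
      )
    }
  )
  out <- dplyr::bind_rows(rows)
  if (nrow(out) == 0L) abort("no pathway overlaps the universe")
  out$fdr <- adjust_bh(out$p_value)
  out <- dplyr::arrange(out, .data$p_value, .data$pathway_id)
  class(out) <- c("ora_result", class(out))
  out
}

#' Combine primary and secondary marker sets
#'
#' The union feeds a combined over-representation analysis (correlation-break
#' markers sharpen the pathway signal carried by concentration-shift
#' markers); the intersection is the dual-status set — metabolites that are
#' both primary and secondary markers.
#'
#' @param primary,secondary Character vectors of marker ids from the same
#'   namespace.
#' @return A list with `union`, `intersection`, and `table` (a tibble with
#'   one row per id and logical columns `in_primary`, `in_secondary`).
#' @export
combine_marker_sets <- function(primary, secondary) {
  primary <- unique(primary)
  secondary <- unique(secondary)
  ids <- sort(union(primary, secondary))
  list(
    union = ids,
    intersection = sort(intersect(primary, secondary)),
    table = tibble::tibble(
      metabolite = ids,
      in_primary = ids %in% primary,
      in_secondary = ids %in% secondary
    )
  )
}
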