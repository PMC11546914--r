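# Internal helpers shared across modules. The package-wide data contract is a
# "metabolite tibble": one row per sample, a sample-id column, a group column
# with exactly two labels, and all remaining numeric columns treated as
# metabolites.

metab_columns <- function(data, group_col = "group", sample_col = "sample_id") {
  setdiff(names(data), c(group_col, sample_col))
}

# Split the tidy tibble into a numeric matrix + metadata used internally.
metab_split <- function(data, group_col = "group", sample_col = "sample_id") {
  if (!sample_col %in% names(data)) {
    abort(sprintf("column '%s' (sample ids) not found", sample_col))
  }
  if (!group_col %in% names(data)) {
    abort(sprintf("column '%s' (group labels) not found", group_col))
  }
  mets <- metab_columns(data, group_col, sample_col)
  if (length(mets) == 0L) abort("no metabolite columns found")
  values <- as.matrix(data[mets])
  if (!is.numeric(values)) abort("metabolite columns must all be numeric")
  rownames(values) <- as.character(data[[sample_col]])
  list(
    values = values,
    group = as.character(data[[group_col]]),
    sample_id = as.character(data[[sample_col]]),
    metabolites = mets
  )
}

check_two_groups <- function(group) {
  labs <- unique(group[!is.na(group)])
  if (length(labs) != 2L) {
    abort(sprintf(
      "group column must contain exactly 2 labels, found %d: %s",
      length(labs), paste(labs, collapse = ", ")
    ))
  }
  sort(labs)
}

# Resolve which of the two group labels is the case (e.g. POD) group.
resolve_case <- function(group, case = NULL) {
  labs <- check_two_groups(group)
  if (is.null(case)) {
    hit <- labs[tolower(labs) %in% c("case", "pod")]
    if (length(hit) == 1L) return(hit)
    abort(paste0(
      "cannot infer the case label from groups {",
      paste(labs, collapse = ", "), "}; pass `case = ` explicitly"
    ))
  }
  if (!case %in% labs) {
    abort(sprintf("case label '%s' not present in group column", case))
  }
  case
}

# Derive a child seed from a master seed; stays well below .Machine$integer.max
# for master seeds up to ~2e6 and counters up to ~1000.
child_seed <- function(seed, counter) {
  as.integer((as.numeric(seed) * 1009 + counter) %% 2147483647)
}
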