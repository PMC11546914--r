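#' Mann-Whitney U test (two-sided)
#'
#' Rank-sum comparison of two samples. For small untied samples
#' (`min(n, m) <= exact_max_n` and no ties) the exact permutation distribution
#' is used; otherwise the normal approximation with tie and continuity
#' correction. `U` counts pairs `(x_i, y_j)` with `x_i > y_j` (midranks for
#' ties), so swapping the samples maps `U` to `n*m - U` and leaves `p`
#' unchanged.
#'
#' @param x,y Numeric vectors, each nonempty.
#' @param exact_max_n Largest `min(n, m)` for which the exact distribution is
#'   used when there are no ties.
#' @return A list with elements `u` and `p`.
#' @export
mann_whitney <- function(x, y, exact_max_n = 8) {
  if (length(x) < 1L || length(y) < 1L) abort("both samples must be nonempty")
  pooled <- c(x, y)
  if (all(pooled == pooled[1L])) {
    return(list(u = length(x) * length(y) / 2, p = 1))
  }
  ties <- anyDuplicated(pooled) > 0L
  exact <- !ties && min(length(x), length(y)) <= exact_max_n
  wt <- suppressWarnings(
    wilcox.test(x, y, alternative = "two.sided", exact = exact, correct = TRUE)
  )
  p <- wt$p.value
  if (is.nan(p)) p <- 1
  list(u = unname(wt$statistic), p = min(p, 1))
}

#' Step-up false-discovery-rate adjustments
#'
#' `adjust_bh()` is the Benjamini-Hochberg procedure; `adjust_by()` is
#' Benjamini-Yekutieli, which multiplies by the harmonic sum
#' `c(m) = 1 + 1/2 + ... + 1/m` and therefore remains valid under arbitrary
#' dependence. Both cap at 1 and are monotone in the sorted order, and
#' elementwise `adjust_by(p) >= adjust_bh(p) >= p`.
#'
#' @param p Vector of p-values in \[0, 1\].
#' @return Vector of adjusted p-values, same order as the input.
#' @export
adjust_bh <- function(p) {
  stopifnot(all(p >= 0 & p <= 1, na.rm = TRUE))
  p.adjust(p, method = "BH")
}

#' @rdname adjust_bh
#' @export
adjust_by <- function(p) {
  stopifnot(all(p >= 0 & p <= 1, na.rm = TRUE))
  p.adjust(p, method = "BY")
}

#' Per-metabolite two-group screen
#'
#' Runs a two-sided Mann-Whitney test for every metabolite (case vs control),
#' adjusts across metabolites by Benjamini-Yekutieli (default, the
#' conservative choice for a screen) or Benjamini-Hochberg, and flags rows
#' with adjusted p below `alpha`. In the postoperative-delirium study design
#' this screen is expected to come back empty: the interesting signal lives in
#' metabolite combinations and correlation structure, not single
#' concentrations.
#'
#' @param data Preprocessed metabolite tibble.
#' @param correction `"BY"` or `"BH"`.
#' @param alpha Significance level on the adjusted scale.
#' @param case Group label of the case group (auto-detected for labels
#'   `case`/`POD`).
#' @param group_col,sample_col Metadata column names.
#' @inheritParams mann_whitney
#'
#' @return A tibble with one row per metabolite: `metabolite`, `u_statistic`,
#'   `p_value`, `adjusted_p`, `direction` (sign of case median minus control
#'   median) and `significant`.
#' @export
screen_metabolites <- function(data, correction = c("BY", "BH"), alpha = 0.05,
                               case = NULL, group_col = "group",
                               sample_col = "sample_id", exact_max_n = 8) {
  correction <- match.arg(correction)
  sp <- metab_split(data, group_col, sample_col)
  case <- resolve_case(sp$group, case)
  is_case <- sp$group == case
  if (sum(is_case) < 2L || sum(!is_case) < 2L) {
    abort("each group needs at least 2 samples")
  }
  if (anyNA(sp$values)) abort("screen requires an imputed (complete) matrix")

  res <- purrr::map(sp$metabolites, function(m) {
    x <- sp$values[is_case, m]
    y <- sp$values[!is_case, m]
    mw <- mann_whitney(x, y, exact_max_n = exact_max_n)
    tibble::tibble(
      metabolite = m, u_statistic = mw$u, p_value = mw$p,
      direction = sign(median(x) - median(y))
    )
  })
  out <- dplyr::bind_rows(res)
  out$adjusted_p <- if (correction == "BY") adjust_by(out$p_value) else adjust_bh(out$p_value)
  out$significant <- out$adjusted_p < alpha
  out[c(
    "metabolite", "u_statistic", "p_value", "adjusted_p", "direction",
    "significant"
  )]
}
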