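#' Median-impute sparse metabolites, drop overly missing ones
#'
#' Applies the preprocessing rule used for targeted LC-MS/MS peak-area
#' matrices: a metabolite whose missing fraction is at most `max_missing`
#' (default 5%) has each missing cell replaced by the median of its observed
#' values; a metabolite above the threshold (or with no observed values at
#' all) is dropped. Observed cells are never altered, so the operation is
#' idempotent, and the keep/drop decision depends only on the missing count.
#'
#' @param data Metabolite tibble (see [read_metabolite_matrix()]).
#' @param max_missing Maximum tolerated missing fraction per metabolite.
#' @param group_col,sample_col Metadata column names.
#' @param quiet Suppress the message listing dropped metabolites.
#'
#' @return The tibble with no remaining missing values, with attributes
#'   `dropped` (character vector of removed metabolites) and `imputed`
#'   (named integer vector: cells imputed per kept metabolite).
#' @export
impute_metabolites <- function(data, max_missing = 0.05, group_col = "group",
                               sample_col = "sample_id", quiet = FALSE) {
  stopifnot(max_missing >= 0, max_missing < 1)
  mets <- metab_columns(data, group_col, sample_col)
  n <- nrow(data)
  n_missing <- vapply(data[mets], function(x) sum(is.na(x)), integer(1L))
  drop <- mets[n_missing / n > max_missing | n_missing == n]
  keep <- setdiff(mets, drop)

  imputed <- integer(0L)
  for (m in keep) {
    x <- data[[m]]
    miss <- is.na(x)
    if (any(miss)) {
      data[[m]][miss] <- median(x[!miss])
      imputed[m] <- sum(miss)
    }
  }
  if (length(drop) > 0L && !quiet) {
    inform(sprintf(
      "dropped %d metabolite(s) with > %.1f%% missing: %s",
      length(drop), 100 * max_missing, paste(drop, collapse = ", ")
    ))
  }
  out <- data[c(sample_col, group_col, keep)]
  attr(out, "dropped") <- drop
  attr(out, "imputed") <- imputed
  out
}

#' Log-transform metabolite abundances
#'
#' Elementwise logarithm of every metabolite column. Peak areas must be
#' strictly positive; a nonpositive cell is a hard error naming the offending
#' sample and metabolite. The base only rescales all downstream rank-, tree-
#' and network-based stages, so any fixed base is statistically equivalent;
#' the natural log is the default.
#'
#' @inheritParams impute_metabolites
#' @param base Logarithm base (default `exp(1)`).
#' @return The tibble with log-scale metabolite columns.
#' @export
log_transform_metabolites <- function(data, base = exp(1), group_col = "group",
                                      sample_col = "sample_id") {
  stopifnot(is.numeric(base), base > 0, base != 1)
  mets <- metab_columns(data, group_col, sample_col)
  for (m in mets) {
    x <- data[[m]]
    bad <- which(!is.na(x) & x <= 0)
    if (length(bad) > 0L) {
      abort(sprintf(
        "nonpositive value for metabolite '%s' in sample '%s'",
        m, as.character(data[[sample_col]][bad[1L]])
      ))
    }
    data[[m]] <- log(x, base = base)
  }
  data
}

#' Fit a per-metabolite min-max scaler
#'
#' Maps each metabolite to \[0, 1\] by the min and max of the supplied
#' (training) rows. The autoencoder stage uses a rectifier output layer, which
#' cannot emit negative values, so log-scale data must be brought into the
#' unit interval before training; the scaler is fitted on the control group
#' only and then applied to every sample.
#'
#' @inheritParams impute_metabolites
#' @return An object of class `minmax_scaler`.
#' @seealso [apply_scaler()], [invert_scaler()]
#' @export
fit_scaler <- function(data, group_col = "group", sample_col = "sample_id") {
  sp <- metab_split(data, group_col, sample_col)
  mins <- apply(sp$values, 2L, min)
  maxs <- apply(sp$values, 2L, max)
  const <- names(mins)[maxs == mins]
  if (length(const) > 0L) {
    warn(sprintf(
      "constant metabolite(s) mapped to 0.5: %s", paste(const, collapse = ", ")
    ))
  }
  structure(
    list(min = mins, max = maxs, metabolites = sp$metabolites),
    class = "minmax_scaler"
  )
}

#' @export
print.minmax_scaler <- function(x, ...) {
  cat(sprintf(
    "<minmax_scaler> %d metabolites (%d constant)\n",
    length(x$metabolites), sum(x$max == x$min)
  ))
  invisible(x)
}

#' Apply / invert a fitted min-max scaler
#'
#' `apply_scaler()` maps each metabolite through the affine transform fitted
#' by [fit_scaler()], clipping values outside the training range to \[0, 1\]
#' (the clipped-cell count is attached as attribute `n_clipped`). Constant
#' training metabolites map to 0.5. `invert_scaler()` undoes the transform on
#' the training range.
#'
#' @inheritParams impute_metabolites
#' @param scaler A `minmax_scaler` from [fit_scaler()].
#' @return The tibble with scaled (or unscaled) metabolite columns.
#' @export
apply_scaler <- function(data, scaler, group_col = "group",
                         sample_col = "sample_id") {
  stopifnot(inherits(scaler, "minmax_scaler"))
  mets <- metab_columns(data, group_col, sample_col)
  if (!setequal(mets, scaler$metabolites)) {
    abort("scaler metabolites do not match the data")
  }
  n_clipped <- 0L
  for (m in mets) {
    rng <- scaler$max[[m]] - scaler$min[[m]]
    if (rng == 0) {
      data[[m]] <- rep(0.5, nrow(data))
      next
    }
    z <- (data[[m]] - scaler$min[[m]]) / rng
    n_clipped <- n_clipped + sum(z < 0 | z > 1)
    data[[m]] <- pmin(pmax(z, 0), 1)
  }
  attr(data, "n_clipped") <- n_clipped
  data
}

#' @rdname apply_scaler
#' @export
invert_scaler <- function(data, scaler, group_col = "group",
                          sample_col = "sample_id") {
  stopifnot(inherits(scaler, "minmax_scaler"))
  mets <- metab_columns(data, group_col, sample_col)
  for (m in mets) {
    rng <- scaler$max[[m]] - scaler$min[[m]]
    data[[m]] <- data[[m]] * rng + scaler$min[[m]]
  }
  data
}

#' One-call preprocessing: impute, log-transform
#'
#' Convenience wrapper chaining [impute_metabolites()] and
#' [log_transform_metabolites()] with a JSON-serialisable report attached as
#' attribute `report`.
#'
#' @inheritParams impute_metabolites
#' @inheritParams log_transform_metabolites
#' @return Preprocessed tibble ready for screening and marker search.
#' @export
preprocess_metabolites <- function(data, max_missing = 0.05, base = exp(1),
                                   group_col = "group",
                                   sample_col = "sample_id", quiet = FALSE) {
  imp <- impute_metabolites(data, max_missing,
    group_col = group_col,
    sample_col = sample_col, quiet = quiet
  )
  out <- log_transform_metabolites(imp,
    base = base, group_col = group_col,
    sample_col = sample_col
  )
  attr(out, "report") <- list(
    n_samples = nrow(out),
    n_metabolites = length(metab_columns(out, group_col, sample_col)),
    dropped = attr(imp, "dropped"),
    imputed = as.list(attr(imp, "imputed")),
    log_base = base
  )
  out
}
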