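# Secondary-marker discovery: denoising-autoencoder ensemble trained on
# control profiles; metabolites whose reconstruction errors differ between
# case and control groups (rank test + FDR) are correlation-break candidates.

#' Generate noisy replicates of metabolomic profiles
#'
#' For each input profile, draws `replicates` corrupted copies by the
#' multiplicative-scale noise model `CN_n = CO_n + d * e`, where `e` is
#' normal with mean 0 and standard deviation equal to the original value
#' `CO_n`. The noise SD of metabolite `n` is therefore `d * CO_n`: large
#' abundances receive proportionally large noise, and a zero value receives
#' none. With `d = 0` every replicate equals its source exactly.
#'
#' @param x Numeric matrix (profiles in rows) or a single profile vector.
#' @param d Noise level factor (default 0.25).
#' @param replicates Noisy copies per input profile (default 500).
#' @param seed Integer seed; draws are reproducible.
#' @return A matrix with `nrow(x) * replicates` rows; attribute `source_row`
#'   maps each replicate to its input row.
#' @export
noisy_replicates <- function(x, d = 0.25, replicates = 500, seed = 1L) {
  stopifnot(d >= 0, replicates >= 1)
  if (is.vector(x)) x <- matrix(x, nrow = 1L)
  src <- rep(seq_len(nrow(x)), each = replicates)
  base <- x[src, , drop = FALSE]
  noisy <- withr::with_seed(seed, {
    base + d * matrix(
      rnorm(length(base), mean = 0, sd = abs(as.vector(base))),
      nrow = nrow(base)
    )
  })
  attr(noisy, "source_row") <- src
  noisy
}

# PyTorch-style Linear init: U(-1/sqrt(fan_in), 1/sqrt(fan_in)).
init_layer <- function(fan_in, fan_out) {
  bound <- 1 / sqrt(fan_in)
  list(
    W = matrix(runif(fan_in * fan_out, -bound, bound), fan_in, fan_out),
    b = runif(fan_out, -bound, bound)
  )
}

#' Train one denoising autoencoder on control profiles
#'
#' Fits a three-layer fully connected network (`p -> hidden -> p`, rectifier
#' activation on every layer, mean-squared-error loss, Adam optimiser,
#' minibatch training) that maps noise-corrupted profiles back to their clean
#' originals. Inputs must already be scaled to \[0, 1\] (see [fit_scaler()]):
#' the rectifier output layer cannot produce negative values. The control
#' rows are split `train_fraction` / rest; the held-out part only monitors
#' loss (no early stopping — the epoch count is fixed).
#'
#' @param x Numeric matrix of control profiles, scaled to \[0, 1\].
#' @param hidden Hidden-layer width (must be below `ncol(x)` to force a
#'   bottleneck).
#' @param epochs,batch_size,learning_rate Training settings (defaults 20, 8,
#'   0.001).
#' @param train_fraction Fraction of rows used for weight updates.
#' @param d,replicates Noise model passed to [noisy_replicates()].
#' @param seed Integer seed covering the split, the weight init, the noise
#'   draws and the minibatch shuffles; identical seeds give bit-identical
#'   weights.
#' @return An object of class `dae` holding the weights, the training
#'   configuration and per-epoch train/validation losses.
#' @export
train_dae <- function(x, hidden, epochs = 20, batch_size = 8,
                      learning_rate = 0.001, train_fraction = 0.8, d = 0.25,
                      replicates = 500, seed = 1L) {
  x <- as.matrix(x)
  p <- ncol(x)
  stopifnot(hidden >= 1, hidden < p, train_fraction > 0, train_fraction < 1)
  if (nrow(x) < 2L) abort("need at least 2 control profiles to train")

  fit <- withr::with_seed(seed, {
    n_train <- max(1L, round(train_fraction * nrow(x)))
    train_rows <- sort(sample.int(nrow(x), n_train))
    val_rows <- setdiff(seq_len(nrow(x)), train_rows)

    clean <- x[rep(train_rows, each = replicates), , drop = FALSE]
    noisy <- noisy_replicates(
      x[train_rows, , drop = FALSE],
      d = d, replicates = replicates,
      seed = sample.int(.Machine$integer.max, 1L)
    )

    l1 <- init_layer(p, hidden)
    l2 <- init_layer(hidden, p)
    n_obs <- nrow(noisy)
    perm <- vapply(
      seq_len(epochs), function(e) sample.int(n_obs) - 1L, integer(n_obs)
    )

    out <- .dae_train(
      noisy, clean, l1$W, l1$b, l2$W, l2$b, perm,
      as.integer(batch_size), learning_rate,
      x[val_rows, , drop = FALSE], x[val_rows, , drop = FALSE]
    )
    out$train_rows <- train_rows
    out$val_rows <- val_rows
    out
  })

  structure(
    list(
      W1 = fit$W1, b1 = as.vector(fit$b1), W2 = fit$W2, b2 = as.vector(fit$b2),
      n_features = p, hidden = hidden,
      train_loss = as.vector(fit$train_loss),
      val_loss = as.vector(fit$val_loss),
      train_rows = fit$train_rows, val_rows = fit$val_rows,
      config = list(
        epochs = epochs, batch_size = batch_size,
        learning_rate = learning_rate, train_fraction = train_fraction,
        d = d, replicates = replicates, seed = seed
      )
    ),
    class = "dae"
  )
}

#' @export
print.dae <- function(x, ...) {
  cat(sprintf(
    "<dae> %d -> %d -> %d; final train MSE %.3g%s\n",
    x$n_features, x$hidden, x$n_features,
    x$train_loss[length(x$train_loss)],
    if (length(x$val_rows) > 0) {
      sprintf(", val MSE %.3g", x$val_loss[length(x$val_loss)])
    } else {
      ""
    }
  ))
  invisible(x)
}

#' Reconstruct profiles through a trained autoencoder
#'
#' @param object A `dae` from [train_dae()].
#' @param newdata Matrix of scaled profiles (`ncol` must match the model).
#' @param ... Unused.
#' @return Matrix of reconstructed profiles.
#' @export
predict.dae <- function(object, newdata, ...) {
  newdata <- as.matrix(newdata)
  if (ncol(newdata) != object$n_features) {
    abort(sprintf(
      "model expects %d features, got %d", object$n_features, ncol(newdata)
    ))
  }
  out <- .dae_forward(newdata, object$W1, object$b1, object$W2, object$b2)
  dimnames(out) <- dimnames(newdata)
  out
}

#' Absolute reconstruction errors on clean profiles
#'
#' Feeds CLEAN (noise-free) scaled profiles through a trained autoencoder and
#' returns `|input - output|` per sample and metabolite. Rows are independent
#' (the network is applied samplewise), so errors are equivariant under row
#' permutation.
#'
#' @inheritParams predict.dae
#' @param model A `dae` from [train_dae()].
#' @param x Matrix of scaled profiles.
#' @return Matrix of nonnegative errors, same shape as `x`.
#' @export
reconstruction_errors <- function(model, x) {
  x <- as.matrix(x)
  abs(x - predict(model, x))
}

#' Per-metabolite anomaly test on reconstruction errors
#'
#' For each metabolite, compares the case samples' reconstruction errors with
#' the control samples' by a two-sided Mann-Whitney test, adjusts across
#' metabolites by Benjamini-Hochberg, and flags metabolites with adjusted p
#' below `fdr_alpha`. A metabolite whose errors are identical in both groups
#' gets p = 1 and is never flagged.
#'
#' @param case_errors,control_errors Error matrices from
#'   [reconstruction_errors()] for the two groups (same columns, same model).
#' @param fdr_alpha FDR threshold (default 0.05).
#' @return A tibble: `metabolite`, `p_value`, `adjusted_p`, `flagged`.
#' @export
detect_anomalies <- function(case_errors, control_errors, fdr_alpha = 0.05) {
  if (ncol(case_errors) != ncol(control_errors)) {
    abort("case and control error tables must share columns")
  }
  mets <- colnames(case_errors) %||% paste0("V", seq_len(ncol(case_errors)))
  p <- vapply(seq_len(ncol(case_errors)), function(j) {
    mann_whitney(case_errors[, j], control_errors[, j])$p
  }, numeric(1L))
  p_adj <- adjust_bh(p)
  tibble::tibble(
    metabolite = mets, p_value = p, adjusted_p = p_adj,
    flagged = p_adj < fdr_alpha
  )
}

#' Denoising-autoencoder ensemble for secondary markers
#'
#' Trains one autoencoder per hidden-layer width in `hidden_sizes` on the
#' control group's profiles (each model independently seeded), computes clean
#' reconstruction errors for every sample, runs [detect_anomalies()] per
#' model, and counts for each metabolite how many models flag it — the
#' consensus count. Metabolites flagged by at least `consensus_min` models
#' are selected as secondary markers: their relationships with other
#' metabolites, learned from controls, fail to reproduce in cases, even
#' though their marginal concentrations may be unchanged.
#'
#' The matrix is scaled internally to \[0, 1\] per metabolite by min-max
#' fitted on the control rows (the rectifier output layer requires
#' nonnegative targets); pass `scale = FALSE` if `data` is already scaled.
#'
#' @param data Preprocessed (imputed, log-scale) metabolite tibble.
#' @param hidden_sizes Integer vector, one autoencoder per entry (default
#'   `50:149`, i.e. 100 models spanning the bottleneck range).
#' @param consensus_min Minimum number of flagging models for selection;
#'   default `ceiling(0.97 * length(hidden_sizes))` (97 of 100 models).
#' @param fdr_alpha Per-model Benjamini-Hochberg threshold.
#' @param holdout_controls_only If `TRUE`, control errors in the test use
#'   only each model's held-out control rows (avoids in-sample bias at the
#'   cost of power; default `FALSE` uses all controls).
#' @param scale Min-max scale internally (default `TRUE`).
#' @param case Case group label (auto-detected for `case`/`POD`).
#' @param group_col,sample_col Metadata column names.
#' @param seed Master seed; model seeds are derived from it.
#' @inheritParams train_dae
#' @return An object of class `dae_ensemble`: list with `consensus` (tibble:
#'   `metabolite`, `consensus_count`, `n_models`, `median_adjusted_p`,
#'   `selected`), `flags` (metabolites x models logical matrix), `models`
#'   summary tibble and `config`.
#' @seealso [tidy.dae_ensemble()], [autoplot.dae_ensemble()]
#' @export
run_dae_ensemble <- function(data, hidden_sizes = 50:149,
                             consensus_min = ceiling(0.97 * length(hidden_sizes)),
                             fdr_alpha = 0.05, epochs = 20, batch_size = 8,
                             learning_rate = 0.001, train_fraction = 0.8,
                             d = 0.25, replicates = 500,
                             holdout_controls_only = FALSE, scale = TRUE,
                             case = NULL, group_col = "group",
                             sample_col = "sample_id", seed = 1L) {
  stopifnot(consensus_min <= length(hidden_sizes))
  sp <- metab_split(data, group_col, sample_col)
  case <- resolve_case(sp$group, case)
  is_case <- sp$group == case

  if (scale) {
    scaler <- fit_scaler(data[!is_case, ], group_col, sample_col)
    data_s <- apply_scaler(data, scaler, group_col, sample_col)
    sp <- metab_split(data_s, group_col, sample_col)
  }
  x_case <- sp$values[is_case, , drop = FALSE]
  x_ctrl <- sp$values[!is_case, , drop = FALSE]

  n_models <- length(hidden_sizes)
  flags <- matrix(FALSE, length(sp$metabolites), n_models,
    dimnames = list(sp$metabolites, NULL)
  )
  p_adj <- matrix(NA_real_, length(sp$metabolites), n_models)
  model_info <- vector("list", n_models)

  for (i in seq_len(n_models)) {
    model_seed <- child_seed(seed, i)
    model <- train_dae(
      x_ctrl,
      hidden = hidden_sizes[i], epochs = epochs,
      batch_size = batch_size, learning_rate = learning_rate,
      train_fraction = train_fraction, d = d, replicates = replicates,
      seed = model_seed
    )
    ctrl_rows <- if (holdout_controls_only) model$val_rows else seq_len(nrow(x_ctrl))
    res <- detect_anomalies(
      reconstruction_errors(model, x_case),
      reconstruction_errors(model, x_ctrl[ctrl_rows, , drop = FALSE]),
      fdr_alpha = fdr_alpha
    )
    flags[, i] <- res$flagged
    p_adj[, i] <- res$adjusted_p
    model_info[[i]] <- tibble::tibble(
      hidden = hidden_sizes[i], seed = model_seed,
      final_train_mse = model$train_loss[epochs],
      final_val_mse = model$val_loss[epochs],
      n_flagged = sum(res$flagged)
    )
  }

  consensus <- tibble::tibble(
    metabolite = sp$metabolites,
    consensus_count = unname(rowSums(flags)),
    n_models = n_models,
    median_adjusted_p = apply(p_adj, 1L, median)
  ) |>
    dplyr::mutate(selected = .data$consensus_count >= consensus_min) |>
    dplyr::arrange(
      dplyr::desc(.data$consensus_count), .data$median_adjusted_p
    )

  structure(
    list(
      consensus = consensus, flags = flags,
      models = dplyr::bind_rows(model_info),
      config = list(
        hidden_sizes = hidden_sizes, consensus_min = consensus_min,
        fdr_alpha = fdr_alpha, epochs = epochs, batch_size = batch_size,
        learning_rate = learning_rate, train_fraction = train_fraction,
        d = d, replicates = replicates,
        holdout_controls_only = holdout_controls_only, case = case,
        seed = seed
      )
    ),
    class = "dae_ensemble"
  )
}

#' @export
print.dae_ensemble <- function(x, ...) {
  cat(sprintf(
    "<dae_ensemble> %d models; %d metabolite(s) selected at consensus >= %d\n",
    nrow(x$models), sum(x$consensus$selected), x$config$consensus_min
  ))
  print(head(x$consensus, 5L))
  invisible(x)
}

#' Tidy a DAE ensemble result
#'
#' `tidy()` returns the per-metabolite consensus table; `glance()` a one-row
#' summary.
#'
#' @param x A `dae_ensemble` from [run_dae_ensemble()].
#' @param ... Unused.
#' @return A tibble.
#' @method tidy dae_ensemble
#' @export
tidy.dae_ensemble <- function(x, ...) x$consensus

#' @rdname tidy.dae_ensemble
#' @method glance dae_ensemble
#' @export
glance.dae_ensemble <- function(x, ...) {
  tibble::tibble(
    n_models = nrow(x$models),
    consensus_min = x$config$consensus_min,
    n_selected = sum(x$consensus$selected),
    median_final_train_mse = median(x$models$final_train_mse)
  )
}

#' Secondary marker ids from an ensemble
#'
#' @param x A `dae_ensemble`.
#' @return Character vector of selected metabolites.
#' @export
secondary_markers <- function(x) {
  stopifnot(inherits(x, "dae_ensemble"))
  x$consensus$metabolite[x$consensus$selected]
}
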