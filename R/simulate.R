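#' Simulate a two-group metabolomic matrix with planted markers
#'
#' Generates a samples-by-metabolites peak-area matrix with the statistical
#' structure the marker-discovery pipeline assumes: log-normal marginals,
#' equicorrelated blocks of metabolites in the control group, planted
#' mean-shift (primary) markers, and planted correlation-break (secondary)
#' markers whose case values are resampled independently from their marginal
#' — so their concentrations are unchanged but their coupling to the rest of
#' their block is destroyed, exactly the signature the autoencoder stage is
#' built to detect.
#'
#' On the log scale, metabolite `j` is `mu_j + sd_j * z_j` with `z` standard
#' normal; within a block `z = sqrt(r) f + sqrt(1-r) eps` shares a block
#' factor `f`, giving pairwise correlation `r`. A primary shift of `s` moves
#' the case-group `z` by `s`, i.e. `s` control-SD units on the log scale.
#' Default dimensions mirror a 27-control / 12-case, 210-metabolite targeted
#' LC-MS/MS study.
#'
#' @param n_control,n_case Group sizes (defaults 27 and 12).
#' @param n_metabolites Number of metabolites (default 210).
#' @param block_sizes Integer vector of correlated-block sizes occupying the
#'   first metabolites; default blocks of 10 covering about half the matrix.
#' @param within_block_correlation Pairwise correlation inside a block
#'   (default 0.6).
#' @param primary_idx Indices of planted mean-shift markers.
#' @param primary_shift Shift in control-SD units (recycled over
#'   `primary_idx`; default 2).
#' @param secondary_idx Indices of planted correlation-break markers (should
#'   lie inside blocks to have any correlation to break). A metabolite listed
#'   in both `primary_idx` and `secondary_idx` is allowed (dual-status) and
#'   reported with a message.
#' @param missing_rate Missing-completely-at-random knockout probability
#'   (default 0.02).
#' @param log_mean_range,log_sd_range Uniform ranges for per-metabolite
#'   log-scale means and SDs (defaults U(10, 16) and U(0.3, 0.8), i.e. peak
#'   areas around 2e4--9e6).
#' @param seed Integer seed; output is deterministic given the seed.
#' @return A list of class `metab_sim`: `data` (metabolite tibble with
#'   groups `case`/`control`) and `truth` (planted-marker manifest: tibbles
#'   `primary` and `secondary`, list `blocks`, and the generating config).
#' @seealso [write_fixture()]
#' @export
simulate_metabolome <- function(n_control = 27, n_case = 12,
                                n_metabolites = 210, block_sizes = NULL,
                                within_block_correlation = 0.6,
                                primary_idx = integer(0), primary_shift = 2,
                                secondary_idx = integer(0),
                                missing_rate = 0.02,
                                log_mean_range = c(10, 16),
                                log_sd_range = c(0.3, 0.8), seed = 1L) {
  if (is.null(block_sizes)) {
    block_sizes <- rep(10L, max(0L, n_metabolites %/% 20L))
  }
  r <- within_block_correlation
  stopifnot(
    r >= 0, r < 1, sum(block_sizes) <= n_metabolites,
    missing_rate >= 0, missing_rate < 1,
    all(primary_idx >= 1), all(primary_idx <= n_metabolites),
    all(secondary_idx >= 1), all(secondary_idx <= n_metabolites)
  )
  shifts <- rep_len(primary_shift, length(primary_idx))
  dual <- intersect(primary_idx, secondary_idx)
  if (length(dual) > 0L) {
    inform(sprintf(
      "%d metabolite(s) planted as both primary and secondary: %s",
      length(dual), paste(dual, collapse = ", ")
    ))
  }

  p <- n_metabolites
  blocks <- list()
  start <- 1L
  for (b in seq_along(block_sizes)) {
    blocks[[b]] <- seq.int(start, start + block_sizes[b] - 1L)
    start <- start + block_sizes[b]
  }

  draw_z <- function(n) {
    z <- matrix(rnorm(n * p), n, p)
    for (idx in blocks) {
      f <- rnorm(n)
      z[, idx] <- sqrt(r) * f + sqrt(1 - r) * z[, idx]
    }
    z
  }

  sim <- withr::with_seed(seed, {
    mu <- runif(p, log_mean_range[1L], log_mean_range[2L])
    sdv <- runif(p, log_sd_range[1L], log_sd_range[2L])
    z_ctrl <- draw_z(n_control)
    z_case <- draw_z(n_case)
    # correlation break: marginal-preserving independent resample in cases
    for (j in secondary_idx) z_case[, j] <- rnorm(n_case)
    # concentration shift in cases, in control-SD units
    for (i in seq_along(primary_idx)) {
      z_case[, primary_idx[i]] <- z_case[, primary_idx[i]] + shifts[i]
    }
    vals <- exp(sweep(
      sweep(rbind(z_case, z_ctrl), 2L, sdv, `*`), 2L, mu, `+`
    ))
    if (missing_rate > 0) {
      vals[matrix(runif(length(vals)) < missing_rate, nrow(vals))] <- NA_real_
    }
    vals
  })

  met_ids <- sprintf("met%03d", seq_len(p))
  colnames(sim) <- met_ids
  data <- tibble::as_tibble(as.data.frame(sim)) |>
    tibble::add_column(
      sample_id = c(
        sprintf("case%02d", seq_len(n_case)),
        sprintf("ctrl%02d", seq_len(n_control))
      ),
      group = rep(c("case", "control"), c(n_case, n_control)),
      .before = 1L
    )

  truth <- list(
    primary = tibble::tibble(
      index = as.integer(primary_idx),
      metabolite = met_ids[primary_idx], shift = shifts
    ),
    secondary = tibble::tibble(
      index = as.integer(secondary_idx),
      metabolite = met_ids[secondary_idx]
    ),
    blocks = purrr::map(blocks, ~ met_ids[.x]),
    config = list(
      n_control = n_control, n_case = n_case, n_metabolites = n_metabolites,
      block_sizes = as.integer(block_sizes),
      within_block_correlation = r, missing_rate = missing_rate,
      log_mean_range = log_mean_range, log_sd_range = log_sd_range,
      seed = seed
    )
  )
  structure(list(data = data, truth = truth), class = "metab_sim")
}

#' @export
print.metab_sim <- function(x, ...) {
  cfg <- x$truth$config
  cat(sprintf(
    "<metab_sim> %d case + %d control samples x %d metabolites; %d primary, %d secondary planted\n",
    cfg$n_case, cfg$n_control, cfg$n_metabolites,
    nrow(x$truth$primary), nrow(x$truth$secondary)
  ))
  invisible(x)
}

#' Write a simulated dataset as a plain-text fixture
#'
#' Emits `matrix.tsv` (readable by [read_metabolite_matrix()]), `truth.json`
#' (the planted-marker manifest) and `pathways.gmt` (a toy annotation with
#' one pathway per correlated block, so enrichment can be exercised against a
#' known ground truth). Files are byte-identical given the same simulation
#' seed.
#'
#' @param sim A `metab_sim` from [simulate_metabolome()].
#' @param dir Output directory (created if needed).
#' @return Named character vector of the written paths, invisibly.
#' @export
write_fixture <- function(sim, dir) {
  stopifnot(inherits(sim, "metab_sim"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- c(
    matrix = file.path(dir, "matrix.tsv"),
    truth = file.path(dir, "truth.json"),
    pathways = file.path(dir, "pathways.gmt")
  )
  write_metabolite_matrix(sim$data, paths[["matrix"]])
  jsonlite::write_json(
    list(
      primary = sim$truth$primary, secondary = sim$truth$secondary,
      blocks = sim$truth$blocks, config = sim$truth$config
    ),
    paths[["truth"]],
    auto_unbox = TRUE, digits = NA, pretty = TRUE
  )
  ann <- tibble::tibble(
    pathway_id = sprintf("BLOCK%02d", seq_along(sim$truth$blocks)),
    pathway_name = sprintf("Correlated block %d", seq_along(sim$truth$blocks)),
    members = sim$truth$blocks
  )
  write_gmt(ann, paths[["pathways"]])
  invisible(paths)
}
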