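# Primary-marker search: GA over fixed-size metabolite subsets, fitness = the
# minimum held-out-fold accuracy of a gradient-boosted tree classifier under
# stratified k-fold cross-validation.

# Stratified fold assignment: within each group, indices are shuffled and
# dealt round-robin into k folds.
make_folds <- function(group, n_folds, seed) {
  stopifnot(n_folds >= 2L)
  fold <- integer(length(group))
  withr::with_seed(seed, {
    for (g in unique(group)) {
      idx <- which(group == g)
      if (length(idx) < n_folds) {
        abort(sprintf(
          "group '%s' has %d samples, fewer than n_folds = %d",
          g, length(idx), n_folds
        ))
      }
      fold[idx] <- rep_len(seq_len(n_folds), length(idx))[sample.int(length(idx))]
    }
  })
  fold
}

# Out-of-fold case-probabilities for a metabolite subset under one fold plan.
oof_probabilities <- function(values, y, fold, booster_rounds, learning_rate,
                              max_depth) {
  probs <- numeric(length(y))
  for (f in sort(unique(fold))) {
    te <- fold == f
    probs[te] <- .gbt_train_predict(
      values[!te, , drop = FALSE], as.integer(y[!te]),
      values[te, , drop = FALSE],
      as.integer(booster_rounds), learning_rate, as.integer(max_depth),
      1.0, 1.0, 0.0, 0.5
    )
  }
  probs
}

#' Minimum cross-validation-fold accuracy of a metabolite subset
#'
#' The GA fitness function: a gradient-boosted tree classifier (logistic
#' loss, 1000 rounds at learning rate 0.05 by default, remaining booster
#' parameters at the library defaults) is trained on the subset's columns
#' within each of `n_folds` stratified splits, and the MINIMUM held-out-fold
#' accuracy is returned. Taking the minimum rather than the mean rewards
#' combinations that classify well uniformly, not just on average.
#'
#' @param data Preprocessed metabolite tibble.
#' @param subset Character vector of metabolite column names.
#' @param n_folds Number of stratified cross-validation folds.
#' @param booster_rounds,learning_rate,max_depth Booster hyperparameters.
#' @param case Case group label (auto-detected for `case`/`POD`).
#' @param group_col,sample_col Metadata column names.
#' @param seed Integer; fixes the fold assignment, making the value
#'   reproducible.
#' @return The minimum fold accuracy, a number in \[0, 1\].
#' @export
fitness_subset <- function(data, subset, n_folds = 5, booster_rounds = 1000,
                           learning_rate = 0.05, max_depth = 6, case = NULL,
                           group_col = "group", sample_col = "sample_id",
                           seed = 1L) {
  sp <- metab_split(data, group_col, sample_col)
  if (length(subset) == 0L) abort("subset must contain at least one metabolite")
  missing_ids <- setdiff(subset, sp$metabolites)
  if (length(missing_ids) > 0L) {
    abort(sprintf("unknown metabolite(s): %s", paste(missing_ids, collapse = ", ")))
  }
  case <- resolve_case(sp$group, case)
  y <- as.integer(sp$group == case)
  fold <- make_folds(sp$group, n_folds, seed)
  min_fold_accuracy(
    sp$values[, subset, drop = FALSE], y, fold, booster_rounds, learning_rate,
    max_depth
  )
}

min_fold_accuracy <- function(values, y, fold, booster_rounds, learning_rate,
                              max_depth) {
  probs <- oof_probabilities(values, y, fold, booster_rounds, learning_rate, max_depth)
  pred <- as.integer(probs >= 0.5)
  accs <- vapply(
    sort(unique(fold)),
    function(f) mean(pred[fold == f] == y[fold == f]), numeric(1L)
  )
  min(accs)
}

#' Cross-validated ROC AUC of a metabolite subset
#'
#' Pools the out-of-fold predicted case-probabilities over the same stratified
#' `n_folds` scheme used by [fitness_subset()] and returns the area under the
#' ROC curve of the pooled scores against the true labels (midrank / Wilcoxon
#' formulation, so ties are handled properly). In-sample AUC would be close
#' to 1 trivially for a boosted model; the cross-validated AUC is the honest
#' summary.
#'
#' @inheritParams fitness_subset
#' @return The AUC, a number in \[0, 1\].
#' @export
evaluate_auc <- function(data, subset, n_folds = 5, booster_rounds = 1000,
                         learning_rate = 0.05, max_depth = 6, case = NULL,
                         group_col = "group", sample_col = "sample_id",
                         seed = 1L) {
  sp <- metab_split(data, group_col, sample_col)
  case <- resolve_case(sp$group, case)
  y <- as.integer(sp$group == case)
  fold <- make_folds(sp$group, n_folds, seed)
  probs <- oof_probabilities(
    sp$values[, subset, drop = FALSE], y, fold, booster_rounds, learning_rate,
    max_depth
  )
  auc_from_scores(probs, y)
}

# Rank (Wilcoxon) AUC: P(score_case > score_control) + 0.5 P(tie).
auc_from_scores <- function(scores, y) {
  n1 <- sum(y == 1L)
  n0 <- sum(y == 0L)
  stopifnot(n1 > 0L, n0 > 0L)
  r <- rank(scores)
  (sum(r[y == 1L]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

# --- GA internals -----------------------------------------------------------

# One GA run at fixed subset size k. Chromosome = k distinct column indices.
# Tournament selection, uniform index crossover with duplicate repair, point
# mutation to a random unused index, elitism. Fitness values are cached per
# subset (order-free key) in `cache`, an environment.
ga_run <- function(values, y, k, population_size, generations, mutation_rate,
                   crossover_rate, tournament_size, elitism, fold,
                   booster_rounds, learning_rate, max_depth, cache) {
  p <- ncol(values)
  if (k > p) abort(sprintf("subset size %d exceeds %d metabolites", k, p))

  eval_subset <- function(idx) {
    key <- paste(sort(idx), collapse = ",")
    hit <- cache[[key]]
    if (!is.null(hit)) return(hit)
    fit <- min_fold_accuracy(
      values[, idx, drop = FALSE], y, fold, booster_rounds, learning_rate,
      max_depth
    )
    cache[[key]] <- fit
    fit
  }

  pop <- t(replicate(population_size, sample.int(p, k)))
  fit <- apply(pop, 1L, eval_subset)

  repair <- function(child) {
    dup <- duplicated(child)
    if (any(dup)) {
      child[dup] <- sample(setdiff(seq_len(p), child[!dup]), sum(dup))
    }
    child
  }

  for (gen in seq_len(generations)) {
    ord <- order(fit, decreasing = TRUE)
    new_pop <- pop[ord[seq_len(elitism)], , drop = FALSE]
    while (nrow(new_pop) < population_size) {
      pick <- function() {
        contenders <- sample.int(population_size, tournament_size)
        pop[contenders[which.max(fit[contenders])], ]
      }
      pa <- pick()
      pb <- pick()
      child <- if (runif(1) < crossover_rate) {
        repair(ifelse(runif(k) < 0.5, pa, pb))
      } else {
        pa
      }
      mut <- runif(k) < mutation_rate
      if (any(mut)) {
        child[mut] <- sample(setdiff(seq_len(p), child[!mut]), sum(mut))
      }
      new_pop <- rbind(new_pop, child)
    }
    pop <- new_pop
    fit <- apply(pop, 1L, eval_subset)
  }
  best <- which.max(fit)
  list(members = sort(pop[best, ]), fitness = fit[best])
}

#' Genetic-algorithm search for primary marker combinations
#'
#' Runs `n_runs` independent seeded GA searches for each subset size in
#' `subset_sizes`, retaining each run's best metabolite combination. Retained
#' combinations are deduplicated by member set, and each metabolite's
#' inclusion frequency (fraction of retained combinations containing it) is
#' reported — the ranking statistic for primary markers. Fitness is the
#' minimum cross-validation-fold accuracy from [fitness_subset()]; the fold
#' assignment is fixed per run so that subset comparisons within a run share
#' folds.
#'
#' @inheritParams fitness_subset
#' @param subset_sizes Integer vector of combination sizes to search
#'   (default `c(3, 4)`).
#' @param n_runs Independent GA runs per subset size.
#' @param population_size,generations,mutation_rate,crossover_rate,
#'   tournament_size,elitism GA operator settings.
#' @param seed Master seed; per-run seeds are derived from it.
#' @return An object of class `ga_markers`: list with `combinations`
#'   (tibble: members list-column, `k`, `fitness`, `n_runs` retaining it),
#'   `inclusion` (tibble: `metabolite`, `frequency`), `union` (character
#'   vector of all members) and `config`.
#' @seealso [tidy.ga_markers()], [autoplot.ga_markers()]
#' @export
ga_search <- function(data, subset_sizes = c(3, 4), n_runs = 100,
                      population_size = 50, generations = 100,
                      mutation_rate = 0.1, crossover_rate = 0.9,
                      tournament_size = 3, elitism = 2, n_folds = 5,
                      booster_rounds = 1000, learning_rate = 0.05,
                      max_depth = 6, case = NULL, group_col = "group",
                      sample_col = "sample_id", seed = 1L) {
  stopifnot(n_runs >= 1, all(subset_sizes >= 1))
  sp <- metab_split(data, group_col, sample_col)
  case <- resolve_case(sp$group, case)
  y <- as.integer(sp$group == case)

  retained <- list()
  counter <- 0L
  for (k in subset_sizes) {
    for (run in seq_len(n_runs)) {
      counter <- counter + 1L
      run_seed <- child_seed(seed, counter)
      cache <- new.env(parent = emptyenv())
      res <- withr::with_seed(run_seed, {
        fold <- make_folds(sp$group, n_folds, run_seed)
        ga_run(
          sp$values, y, k, population_size, generations, mutation_rate,
          crossover_rate, tournament_size, elitism, fold, booster_rounds,
          learning_rate, max_depth, cache
        )
      })
      retained[[counter]] <- tibble::tibble(
        k = k, run = run,
        members = list(sp$metabolites[res$members]),
        fitness = res$fitness
      )
    }
  }
  retained <- dplyr::bind_rows(retained)

  combos <- retained |>
    dplyr::mutate(key = purrr::map_chr(.data$members, paste, collapse = "|")) |>
    dplyr::group_by(.data$key) |>
    dplyr::summarise(
      members = .data$members[1L],
      k = .data$k[1L],
      fitness = max(.data$fitness),
      n_runs = dplyr::n(),
      .groups = "drop"
    ) |>
    dplyr::arrange(dplyr::desc(.data$fitness), dplyr::desc(.data$n_runs)) |>
    dplyr::select(!"key")

  all_members <- unlist(combos$members)
  inclusion <- tibble::tibble(metabolite = sp$metabolites) |>
    dplyr::mutate(
      frequency = purrr::map_dbl(
        .data$metabolite,
        ~ mean(purrr::map_lgl(combos$members, function(s) .x %in% s))
      )
    ) |>
    dplyr::filter(.data$frequency > 0) |>
    dplyr::arrange(dplyr::desc(.data$frequency))

  structure(
    list(
      combinations = combos,
      inclusion = inclusion,
      union = sort(unique(all_members)),
      config = list(
        subset_sizes = subset_sizes, n_runs = n_runs,
        population_size = population_size, generations = generations,
        mutation_rate = mutation_rate, crossover_rate = crossover_rate,
        tournament_size = tournament_size, elitism = elitism,
        n_folds = n_folds, booster_rounds = booster_rounds,
        learning_rate = learning_rate, max_depth = max_depth,
        case = case, seed = seed
      )
    ),
    class = "ga_markers"
  )
}

#' @export
print.ga_markers <- function(x, ...) {
  cat(sprintf(
    "<ga_markers> %d distinct combination(s) from %d run(s); union of %d metabolites\n",
    nrow(x$combinations), sum(x$combinations$n_runs), length(x$union)
  ))
  cat("Top inclusion frequencies:\n")
  print(head(x$inclusion, 5L))
  invisible(x)
}

#' Tidy a GA primary-marker search
#'
#' `tidy()` returns the per-metabolite inclusion-frequency table;
#' `glance()` returns a one-row summary.
#'
#' @param x A `ga_markers` object from [ga_search()].
#' @param ... Unused.
#' @return A tibble.
#' @method tidy ga_markers
#' @export
tidy.ga_markers <- function(x, ...) x$inclusion

#' @rdname tidy.ga_markers
#' @method glance ga_markers
#' @export
glance.ga_markers <- function(x, ...) {
  tibble::tibble(
    n_combinations = nrow(x$combinations),
    n_runs = sum(x$combinations$n_runs),
    union_size = length(x$union),
    best_fitness = max(x$combinations$fitness)
  )
}
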