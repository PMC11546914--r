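# Unit tests use a reduced booster (60 rounds) for speed; the full-scale
# defaults (1000 rounds) are exercised by the acceptance suite.

test_that("fitness is 1 for a perfect separator and bounded in [0, 1]", {
  d <- separable_tibble(seed = 21)
  f <- fitness_subset(d, "sep", booster_rounds = 60, seed = 1)
  expect_equal(f, 1)
  # separator plus noise still separates perfectly on every fold
  f3 <- fitness_subset(d, c("sep", "noise01", "noise02"),
    booster_rounds = 60, seed = 1
  )
  expect_gte(f3, f - 1e-12)  # monotone sanity on shared folds
  # pure-noise subsets stay within accuracy bounds
  withr::with_seed(8, {
    for (i in 1:5) {
      fn <- fitness_subset(d, c("noise01", "noise03"),
        booster_rounds = 60, seed = i
      )
      expect_gte(fn, 0)
      expect_lte(fn, 1)
    }
  })
  expect_error(fitness_subset(d, character(0)), "at least one")
  expect_error(fitness_subset(d, "nope"), "unknown metabolite")
})

test_that("fitness and AUC are deterministic given the seed", {
  d <- separable_tibble(seed = 4)
  a <- fitness_subset(d, c("sep", "noise01"), booster_rounds = 80, seed = 7)
  b <- fitness_subset(d, c("sep", "noise01"), booster_rounds = 80, seed = 7)
  expect_identical(a, b)
  u <- evaluate_auc(d, c("sep", "noise01"), booster_rounds = 80, seed = 7)
  v <- evaluate_auc(d, c("sep", "noise01"), booster_rounds = 80, seed = 7)
  expect_identical(u, v)
})

test_that("cross-validated AUC behaves like a rank statistic", {
  d <- separable_tibble(seed = 5)
  expect_equal(
    evaluate_auc(d, "sep", booster_rounds = 60, seed = 2), 1
  )
  # null AUC hovers around 0.5 over seeds
  aucs <- vapply(1:8, function(s) {
    evaluate_auc(d, c("noise02", "noise04"), booster_rounds = 60, seed = s)
  }, numeric(1))
  expect_gt(mean(aucs), 0.2)
  expect_lt(mean(aucs), 0.8)
})

test_that("score reversal maps AUC to 1 - AUC", {
  # direct check of the rank-AUC kernel used for pooled fold scores
  withr::with_seed(31, {
    for (i in 1:10) {
      y <- rep(c(1L, 0L), c(12, 27))
      s <- rnorm(39) + y * runif(1, 0, 2)
      a <- metabmarker:::auc_from_scores(s, y)
      b <- metabmarker:::auc_from_scores(-s, y)
      expect_equal(a, 1 - b, tolerance = 1e-12)
    }
  })
})

test_that("ga_search recovers a planted separator and respects contracts", {
  d <- separable_tibble(n_case = 10, n_control = 14, n_noise = 11, seed = 9)
  res <- ga_search(d,
    subset_sizes = 2, n_runs = 4, population_size = 12, generations = 8,
    booster_rounds = 60, n_folds = 4, seed = 5
  )
  expect_s3_class(res, "ga_markers")
  # the perfect separator is in every run's best pair
  expect_equal(
    res$inclusion$frequency[res$inclusion$metabolite == "sep"], 1
  )
  expect_true(all(res$combinations$fitness == 1))
  # tidy/glance accessors
  expect_identical(tidy(res), res$inclusion)
  expect_identical(glance(res)$union_size, length(res$union))

  # single run: inclusion frequencies are 0 or 1
  r1 <- ga_search(d,
    subset_sizes = 2, n_runs = 1, population_size = 8, generations = 4,
    booster_rounds = 60, n_folds = 4, seed = 2
  )
  expect_true(all(r1$inclusion$frequency %in% c(0, 1)))

  # infeasible subset size
  expect_error(
    ga_search(d,
      subset_sizes = 40, n_runs = 1, population_size = 6, generations = 2,
      booster_rounds = 30, n_folds = 4, seed = 1
    ),
    "exceeds"
  )
})

test_that("identical seed and config reproduce the search bit-identically", {
  d <- separable_tibble(n_case = 8, n_control = 10, n_noise = 6, seed = 14)
  args <- list(d,
    subset_sizes = 2, n_runs = 2, population_size = 8, generations = 5,
    booster_rounds = 40, n_folds = 4, seed = 99
  )
  a <- do.call(ga_search, args)
  b <- do.call(ga_search, args)
  expect_identical(a$combinations, b$combinations)
  expect_identical(a$inclusion, b$inclusion)
})

test_that("stratified folds keep both groups in every fold", {
  g <- rep(c("case", "control"), c(12, 27))
  f <- metabmarker:::make_folds(g, 5, seed = 3)
  for (k in 1:5) {
    expect_gte(sum(f == k & g == "case"), 2)
    expect_gte(sum(f == k & g == "control"), 5)
  }
  expect_error(metabmarker:::make_folds(rep(c("a", "b"), c(3, 30)), 5, 1), "fewer")
})
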