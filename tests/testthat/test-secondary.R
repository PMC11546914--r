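# DAE unit tests run on small matrices with reduced replicate counts; the
# spec-scale ensemble experiment lives in the acceptance suite.

test_that("noise model: d = 0 is the identity, SD follows the closed form", {
  x <- matrix(runif(30, 0, 1), 3, 10)
  z <- noisy_replicates(x, d = 0, replicates = 4, seed = 1)
  expect_equal(z, x[rep(1:3, each = 4), ], ignore_attr = TRUE)

  # Var(d * e) = d^2 * CO^2: CO = 4, d = 0.25 -> SD = 1
  reps <- noisy_replicates(rep(4, 1), d = 0.25, replicates = 10000, seed = 2)
  expect_equal(sd(reps[, 1]), 1, tolerance = 0.03)
  expect_equal(mean(reps[, 1]), 4, tolerance = 0.03)

  # default replicate count is 500 per input profile
  def <- noisy_replicates(matrix(runif(5), 1, 5))
  expect_identical(nrow(def), 500L)

  # a zero value receives no noise under the proportional-SD model
  z0 <- noisy_replicates(c(0, 1), d = 0.25, replicates = 50, seed = 3)
  expect_true(all(z0[, 1] == 0))

  # deterministic given seed
  expect_identical(
    noisy_replicates(x, replicates = 7, seed = 9),
    noisy_replicates(x, replicates = 7, seed = 9)
  )
})

test_that("train_dae learns correlated structure better than the mean baseline", {
  sim <- simulate_metabolome(
    n_control = 27, n_case = 2, n_metabolites = 30, block_sizes = rep(10, 3),
    missing_rate = 0, seed = 55
  )
  d <- preprocess_metabolites(sim$data, quiet = TRUE)
  ctrl <- d[d$group == "control", ]
  sc <- fit_scaler(ctrl)
  x <- as.matrix(apply_scaler(ctrl, sc)[, -(1:2)])

  m <- train_dae(x, hidden = 8, replicates = 200, seed = 6)
  # held-out clean reconstruction beats predicting each metabolite's
  # training-set mean
  val <- x[m$val_rows, , drop = FALSE]
  dae_mse <- mean(reconstruction_errors(m, val)^2)
  base_mse <- mean(sweep(val, 2, colMeans(x[m$train_rows, , drop = FALSE]))^2)
  expect_lt(dae_mse, base_mse)
  # loss trace shrinks over epochs
  expect_lt(m$train_loss[20], m$train_loss[1])
  # determinism contract
  m2 <- train_dae(x, hidden = 8, replicates = 200, seed = 6)
  expect_identical(m$W1, m2$W1)
  expect_identical(m$W2, m2$W2)
  # shape guards
  expect_error(predict(m, x[, 1:5]), "features")
  expect_error(train_dae(x[1, , drop = FALSE], hidden = 3), "at least 2")
})

test_that("reconstruction errors are nonnegative, row-local, permutation-equivariant", {
  withr::with_seed(77, x <- matrix(runif(80), 8, 10))
  m <- train_dae(x, hidden = 3, replicates = 30, epochs = 5, seed = 1)
  err <- reconstruction_errors(m, x)
  expect_true(all(err >= 0))
  # permuting rows permutes errors identically
  perm <- c(3, 1, 2, 8, 5, 4, 7, 6)
  expect_equal(reconstruction_errors(m, x[perm, ]), err[perm, ])
  # duplicated profile has identical error rows
  dup <- rbind(x[1, ], x[1, ])
  edup <- reconstruction_errors(m, dup)
  expect_equal(edup[1, ], edup[2, ])
})

test_that("an identity network yields zero errors", {
  # hand-built weights implementing the identity on [0, 1] inputs
  p <- 6
  m <- structure(
    list(
      W1 = diag(p), b1 = rep(0, p), W2 = diag(p), b2 = rep(0, p),
      n_features = p, hidden = p
    ),
    class = "dae"
  )
  x <- matrix(runif(30), 5, p)
  expect_equal(reconstruction_errors(m, x), matrix(0, 5, p), ignore_attr = TRUE)
})

test_that("detect_anomalies flags planted error shifts under FDR control", {
  # copied errors -> never flagged
  withr::with_seed(12, e <- matrix(abs(rnorm(60)), 6, 10))
  res0 <- detect_anomalies(e, e)
  expect_false(any(res0$flagged))
  expect_true(all(res0$p_value == 1 | res0$p_value > 0.9))

  # one metabolite's case errors shifted far up -> only it is flagged
  withr::with_seed(13, {
    ctrl <- matrix(abs(rnorm(270)), 27, 10)
    case <- matrix(abs(rnorm(120)), 12, 10)
  })
  case[, 4] <- case[, 4] + 10
  colnames(ctrl) <- colnames(case) <- sprintf("m%02d", 1:10)
  res <- detect_anomalies(case, ctrl)
  expect_true(res$flagged[res$metabolite == "m04"])
  expect_lte(sum(res$flagged[res$metabolite != "m04"]), 1)
  # flags are a subset of raw p < alpha (BH never helps a raw failure)
  expect_true(all(res$p_value[res$flagged] < 0.05))
  expect_error(detect_anomalies(case, ctrl[, 1:5]), "share columns")
})

test_that("ensemble consensus counts, selection threshold and accessors", {
  sim <- simulate_metabolome(
    n_control = 14, n_case = 8, n_metabolites = 16, block_sizes = rep(8, 2),
    secondary_idx = c(1, 9), missing_rate = 0, seed = 70
  )
  d <- preprocess_metabolites(sim$data, quiet = TRUE)
  ens <- run_dae_ensemble(d,
    hidden_sizes = c(4, 5, 6), replicates = 100, seed = 3
  )
  expect_s3_class(ens, "dae_ensemble")
  expect_identical(nrow(ens$models), 3L)
  cons <- tidy(ens)
  expect_true(all(cons$consensus_count >= 0 & cons$consensus_count <= 3))
  # consensus_count equals the column sums of the flag matrix
  expect_equal(
    sort(cons$consensus_count), sort(unname(rowSums(ens$flags)))
  )
  # selection at the threshold is consistent with the counts
  expect_identical(
    cons$selected, cons$consensus_count >= ens$config$consensus_min
  )
  expect_identical(secondary_markers(ens), cons$metabolite[cons$selected])
  expect_identical(glance(ens)$n_models, 3L)

  # consensus monotonicity: raising the threshold never enlarges selection
  sel1 <- sum(cons$consensus_count >= 1)
  sel2 <- sum(cons$consensus_count >= 2)
  sel3 <- sum(cons$consensus_count >= 3)
  expect_true(sel1 >= sel2 && sel2 >= sel3)

  # determinism of the full ensemble
  ens2 <- run_dae_ensemble(d,
    hidden_sizes = c(4, 5, 6), replicates = 100, seed = 3
  )
  expect_identical(ens$consensus, ens2$consensus)
})
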