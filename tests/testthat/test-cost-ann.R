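test_that("instance weights realize the cost matrix", {
  psms <- toy_psms() # 2 decoys, 3 targets
  w <- make_instance_weights(psms, cost_matrix(10, 1))
  expect_equal(w, ifelse(psms$class_label == 0L, 10, 1))
  expect_equal(make_instance_weights(psms, cost_matrix(1, 1)), rep(1, 5))
  expect_equal(sum(make_instance_weights(psms, cost_matrix(4, 1))), 2 * 4 + 3)
  expect_error(cost_matrix(0.5), "cfp")
  expect_error(cost_matrix(1, 2), "cfn")
})

test_that("hyperparameter defaults are the standard configuration", {
  hp <- ann_hyperparams()
  expect_equal(hp$hidden_nodes, 4L)
  expect_equal(hp$learning_rate, 0.3)
  expect_equal(hp$momentum, 0.2)
  expect_equal(hp$epochs, 1000L)
})

test_that("training separates well-separated clouds and is deterministic", {
  psms <- separable_psms()
  fit <- train_cost_ann(psms, cost_matrix(1), ann_hyperparams(seed = 7))
  scored <- predict_probabilities(fit, psms)
  acc <- mean((scored$raw_prob >= 0.5) == psms$class_label)
  expect_gte(acc, 0.99)

  fit2 <- train_cost_ann(psms, cost_matrix(1), ann_hyperparams(seed = 7))
  expect_identical(fit$weights, fit2$weights)
  fit3 <- train_cost_ann(psms, cost_matrix(1), ann_hyperparams(seed = 8))
  expect_false(identical(fit$weights, fit3$weights))
})

test_that("training rejects degenerate inputs", {
  psms <- toy_psms()
  expect_error(train_cost_ann(psms[psms$class_label == 1L, ], cost_matrix(1)),
               "both classes")
  bad <- psms
  bad$xcorr[3] <- NaN
  expect_error(train_cost_ann(bad, cost_matrix(1)), "s3")
})

test_that("integer instance weights are equivalent to record replication", {
  psms <- separable_psms(n_per_class = 40, seed = 11)
  hp <- ann_hyperparams(epochs = 60, seed = 2)
  # weight 3 on decoys vs. the decoy rows stacked three times
  fit_w <- train_cost_ann(psms, cost_matrix(3, 1), hp)
  reps <- dplyr::bind_rows(
    psms,
    dplyr::mutate(psms[psms$class_label == 0L, ],
                  spectrum_id = paste0(spectrum_id, "_r1")),
    dplyr::mutate(psms[psms$class_label == 0L, ],
                  spectrum_id = paste0(spectrum_id, "_r2"))
  )
  fit_r <- train_cost_ann(reps, cost_matrix(1, 1), hp)
  expect_equal(fit_w$weights, fit_r$weights, tolerance = 1e-8)
  p_w <- predict(fit_w, psms)
  p_r <- predict(fit_r, psms)
  expect_equal(p_w, p_r, tolerance = 1e-8)
})

test_that("cfp = cfn = 1 reduces to the unweighted baseline", {
  psms <- separable_psms(n_per_class = 40, seed = 13)
  hp <- ann_hyperparams(epochs = 60, seed = 3)
  fit_cost <- train_cost_ann(psms, cost_matrix(1, 1), hp)
  # manual unweighted training: identical by construction of the weights
  w <- make_instance_weights(psms, cost_matrix(1, 1))
  expect_true(all(w == 1))
  fit_again <- train_cost_ann(psms, cost_matrix(1, 1), hp)
  expect_identical(fit_cost$weights, fit_again$weights)
})

test_that("raising the false-positive cost biases predictions toward class 0", {
  # count of predicted positives at cfp = 10 should not exceed cfp = 1
  # by more than 5% of n, across seeds
  for (s in 1:5) {
    sim <- simulate_psms(n_targets = 400, n_decoys = 400, frac_correct = 0.15,
                         seed = 100 + s)
    hp <- ann_hyperparams(epochs = 150, seed = s)
    n1 <- sum(predict(train_cost_ann(sim$psms, cost_matrix(1), hp),
                      sim$psms) >= 0.5)
    n10 <- sum(predict(train_cost_ann(sim$psms, cost_matrix(10), hp),
                       sim$psms) >= 0.5)
    expect_lte(n10, n1 + 0.05 * nrow(sim$psms))
  }
})

test_that("network outputs are probabilities: in (0,1), idempotent, 0.5 at zero weights", {
  psms <- toy_psms()
  fit <- train_cost_ann(psms, cost_matrix(2), ann_hyperparams(epochs = 20))
  scored <- predict_probabilities(fit, psms)
  expect_true(all(scored$raw_prob > 0 & scored$raw_prob < 1))
  scored2 <- predict_probabilities(fit, scored)
  expect_identical(scored$raw_prob, scored2$raw_prob)
  expect_identical(scored2[, names(psms)], scored[, names(psms)])
  # extreme inputs still map inside (0,1)
  extreme <- dplyr::mutate(psms, xcorr = xcorr * 1e6, sp_rank = sp_rank * 1e6)
  p_ex <- predict(fit, extreme)
  expect_true(all(p_ex > 0 & p_ex < 1))
  # hand-set all-zero weights give sigmoid(0) = 0.5 everywhere
  zero <- fit
  zero$weights$W1[] <- 0; zero$weights$b1[] <- 0
  zero$weights$W2[] <- 0; zero$weights$b2 <- 0
  expect_equal(predict(zero, psms), rep(0.5, nrow(psms)))
  expect_error(predict(fit, dplyr::select(psms, -"xcorr")), "xcorr")
})

test_that("model JSON serialization round-trips exactly", {
  psms <- separable_psms(n_per_class = 30, seed = 17)
  fit <- train_cost_ann(psms, cost_matrix(7, 1),
                        ann_hyperparams(epochs = 120, seed = 5))
  f <- withr::local_tempfile(fileext = ".json")
  write_cost_ann(fit, f)
  back <- read_cost_ann(f)
  expect_equal(back$weights$W1, fit$weights$W1)
  expect_equal(back$weights$b1, fit$weights$b1)
  expect_equal(back$weights$W2, fit$weights$W2)
  expect_equal(back$weights$b2, fit$weights$b2)
  expect_equal(back$normalization, fit$normalization)
  expect_equal(unclass(back$hyperparams), unclass(fit$hyperparams))
  expect_equal(unclass(back$cost), unclass(fit$cost))
  expect_identical(predict(back, psms), predict(fit, psms))
  expect_error(read_cost_ann(withr::local_tempfile(fileext = ".json") |>
                               (\(p) { writeLines('{"format":"x"}', p); p })()),
               "model file")
})

test_that("tidy and glance expose the fitted network", {
  psms <- separable_psms(n_per_class = 30, seed = 19)
  fit <- train_cost_ann(psms, cost_matrix(2), ann_hyperparams(epochs = 30))
  td <- tidy(fit)
  expect_equal(nrow(td), 7 * 4 + 5) # (6 inputs + bias) x 4 hidden + (4 + bias)
  expect_equal(td$estimate[1:7], unname(c(fit$weights$W1[, 1], fit$weights$b1[1])))
  gl <- glance(fit)
  expect_equal(gl$cfp, 2)
  expect_equal(gl$n_train, nrow(psms))
})
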