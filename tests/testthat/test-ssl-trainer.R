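test_that("pre-training with zero epochs is the identity", {
  sim <- small_benchmark(seed = 1)
  cfg <- fast_config(epochs_pretrain = 0)
  params <- init_params(80, c(8, 4), 2, seed = 1)
  res <- pretrain(params, sim$labeled, cfg)
  expect_identical(res$params, params)
  expect_identical(nrow(res$history), 0L)
})

test_that("pre-training is deterministic and learns separable data", {
  # spec'd regime: 200 labelled samples, 50 features, strong effect
  sim <- generate_synthetic(synthetic_spec(
    n_classes = 2, n_cpgs = 50, n_informative_per_class = 15,
    n_labeled = 200, n_unlabeled = 0, n_test = 0, cohort_shift = 0,
    seed = 31))
  # the task must be genuinely separable: nearest-centroid oracle >= 0.95
  X <- t(unclass(sim$labeled$matrix))
  y <- unname(sim$labeled$labels)
  expect_gte(nearest_centroid_accuracy(X, y, X, y), 0.95)

  cfg <- training_config(lr_pretrain = 1e-3, epochs_pretrain = 300,
                         hidden_sizes = c(32, 16), seed = 7)
  params <- init_params(50, c(32, 16), 2, seed = 7)
  res <- pretrain(params, sim$labeled, cfg)
  pred <- predict_proba(res$params, X)
  expect_gte(mean(pred$predicted == y), 0.95)

  # bit-identical rerun under the same config and seed
  res2 <- pretrain(params, sim$labeled, cfg)
  expect_identical(res2$params, res$params)
  expect_identical(res2$history, res$history)

  # history contract: one row per epoch, alpha 0 throughout
  expect_identical(nrow(res$history), 300L)
  expect_true(all(res$history$phase == "pretrain"))
  expect_true(all(res$history$alpha == 0))
})

test_that("pre-training loss decreases from first to final epoch", {
  sim <- small_benchmark(seed = 5)
  cfg <- training_config(lr_pretrain = 1e-3, epochs_pretrain = 120,
                         dropout_rate = 0, hidden_sizes = c(8, 4), seed = 2)
  params <- init_params(80, c(8, 4), 2, seed = 2)
  h <- pretrain(params, sim$labeled, cfg)$history
  expect_lt(h$labeled_loss[nrow(h)], h$labeled_loss[1])
})

test_that("training rejects unimputed data and warns on unrepresented classes", {
  sim <- small_benchmark(seed = 3)
  holey <- labeled_dataset(inject_missing(sim$labeled$matrix, 0.1, seed = 1),
                           labels_tbl(sim$labeled), sim$vocabulary)
  params <- init_params(80, c(8, 4), 2, seed = 1)
  expect_error(pretrain(params, holey, fast_config()), "missing values")

  # vocabulary lists a third subtype with no labelled samples
  three <- labeled_dataset(sim$labeled$matrix, labels_tbl(sim$labeled),
                           c(sim$vocabulary, "subtype3"))
  p3 <- init_params(80, c(8, 4), 3, seed = 1)
  expect_warning(res <- pretrain(p3, three, fast_config(epochs_pretrain = 2)),
                 "subtype3")
  expect_match(attr(res$history, "warnings"), "subtype3")
})

test_that("fine-tuning without unlabelled data reduces to supervised training", {
  sim <- small_benchmark(seed = 11)
  params <- init_params(80, c(8, 4), 2, seed = 11)
  cfg <- fast_config(seed = 11)
  sup <- finetune(params, sim$labeled, NULL, cfg)
  # alpha_f = 0 with unlabelled data present: bit-identical trajectory
  cfg0 <- fast_config(seed = 11, ramp = ramp_schedule(5, 15, 0))
  off <- finetune(params, sim$labeled, sim$unlabeled, cfg0)
  expect_identical(off$params, sup$params)
  expect_identical(off$history$labeled_loss, sup$history$labeled_loss)
  # and the unlabelled term never contributes
  expect_true(all(off$history$alpha == 0))
})

test_that("fine-tuning history records the ramp and pseudo-label counts", {
  sim <- small_benchmark(seed = 13)
  params <- init_params(80, c(8, 4), 2, seed = 13)
  cfg <- training_config(lr_finetune = 1e-3, epochs_finetune = 250,
                         epochs_pretrain = 0, hidden_sizes = c(8, 4),
                         ramp = ramp_schedule(100, 200, 0.05), seed = 13)
  h <- finetune(params, sim$labeled, sim$unlabeled, cfg)$history
  expect_identical(nrow(h), 250L)
  expect_true(all(h$alpha[h$epoch < 100] == 0))
  ramp_part <- h$alpha[h$epoch >= 100 & h$epoch < 200]
  expect_true(all(diff(ramp_part) > 0))
  expect_equal(h$alpha[h$epoch >= 200], rep(0.05, 50))
  expect_equal(h$alpha, alpha_schedule(h$epoch, cfg$ramp))
  expect_true(all(h$n_pseudo_included == ncol(sim$unlabeled$matrix)))
})

test_that("pseudo-labels used at each epoch come from that epoch's parameters", {
  sim <- small_benchmark(seed = 23)
  params <- init_params(80, c(8, 4), 2, seed = 23)
  cfg <- fast_config(epochs_finetune = 12, seed = 23)
  full <- finetune(params, sim$labeled, sim$unlabeled, cfg,
                   pseudo_log = TRUE)
  plog <- attr(full$history, "pseudo_log")
  expect_length(plog, 12)
  # pseudo-labels at epoch t must equal argmax predictions under the
  # parameters obtained after exactly t epochs of the same run
  for (t in c(0L, 5L, 11L)) {
    cfg_t <- cfg
    cfg_t$epochs_finetune <- t
    part <- finetune(params, sim$labeled, sim$unlabeled, cfg_t)
    expected <- predict_proba(part$params,
                              t(unclass(sim$unlabeled$matrix)))$predicted
    expect_identical(plog[[t + 1]], expected)
  }
})

test_that("the confidence threshold masks low-posterior samples during training", {
  sim <- small_benchmark(seed = 29)
  params <- init_params(80, c(8, 4), 2, seed = 29)
  cfg <- fast_config(epochs_finetune = 30, seed = 29,
                     confidence_threshold = 0.9)
  h <- finetune(params, sim$labeled, sim$unlabeled, cfg)$history
  m <- ncol(sim$unlabeled$matrix)
  expect_true(all(h$n_pseudo_included <= m))
  expect_true(all(h$n_pseudo_included >= 0))
})

test_that("the full fit composes init, pretrain and finetune deterministically", {
  sim <- small_benchmark(seed = 41)
  cfg <- fast_config(seed = 41)
  fit1 <- methsemi_fit(sim$labeled, sim$unlabeled, cfg)
  fit2 <- methsemi_fit(sim$labeled, sim$unlabeled, cfg)
  expect_identical(fit1$params, fit2$params)
  expect_identical(tidy(fit1), tidy(fit2))
  expect_identical(nrow(tidy(fit1)), 80L)

  # finetune budget 0 equals pretraining alone
  cfg0 <- fast_config(seed = 41, epochs_finetune = 0)
  fit0 <- methsemi_fit(sim$labeled, sim$unlabeled, cfg0)
  pre <- pretrain(init_params(80, c(8, 4), 2, seed = 41), sim$labeled, cfg0)
  expect_identical(fit0$params, pre$params)

  # bundle carries the feature list and vocabulary for prediction
  expect_identical(fit1$cpg_ids, rownames(sim$labeled$matrix))
  expect_identical(fit1$vocabulary, sim$vocabulary)
  preds <- predict(fit1, sim$test$matrix)
  expect_identical(nrow(preds), 30L)
  expect_true(all(preds$predicted %in% sim$vocabulary))
  expect_equal(rowSums(as.matrix(preds[, paste0("p_", sim$vocabulary)])),
               rep(1, 30), tolerance = 1e-6)
})

test_that("mini-batch updates run deterministically when configured", {
  sim <- small_benchmark(seed = 43)
  cfg <- fast_config(seed = 43, batch_size = 8, epochs_pretrain = 10,
                     epochs_finetune = 10)
  fit1 <- methsemi_fit(sim$labeled, sim$unlabeled, cfg)
  fit2 <- methsemi_fit(sim$labeled, sim$unlabeled, cfg)
  expect_identical(fit1$params, fit2$params)
  # batching changes the trajectory relative to full batch
  full <- methsemi_fit(sim$labeled, sim$unlabeled,
                       fast_config(seed = 43, epochs_pretrain = 10,
                                   epochs_finetune = 10))
  expect_false(identical(fit1$params, full$params))
})

test_that("class oversampling replicates only the requested subtype", {
  sim <- small_benchmark(seed = 47)
  n0 <- table(labels_tbl(sim$labeled)$subtype)
  over <- oversample_classes(sim$labeled, c(subtype2 = 3L))
  n1 <- table(labels_tbl(over)$subtype)
  expect_identical(unname(n1["subtype1"]), unname(n0["subtype1"]))
  expect_identical(unname(n1["subtype2"]), unname(n0["subtype2"]) * 3L)
  expect_identical(over$vocabulary, sim$vocabulary)
})

test_that("saved models reload to bit-identical predictions", {
  sim <- small_benchmark(seed = 53)
  fit <- methsemi_fit(sim$labeled, sim$unlabeled,
                      fast_config(seed = 53, epochs_pretrain = 10,
                                  epochs_finetune = 10))
  path <- withr::local_tempfile(fileext = ".json")
  save_model(fit, path)
  back <- load_model(path)
  expect_identical(back$cpg_ids, fit$cpg_ids)
  expect_identical(back$vocabulary, fit$vocabulary)
  expect_identical(predict(back, sim$test$matrix),
                   predict(fit, sim$test$matrix))
})
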