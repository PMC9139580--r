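test_that("fold assignment partitions the cohort with near-equal folds", {
  a <- make_folds(20, k = 10, seed = 5)
  expect_equal(as.vector(table(a$fold)), rep(2L, 10))
  expect_identical(make_folds(20, k = 10, seed = 5)$fold, a$fold)
  expect_false(identical(make_folds(20, k = 10, seed = 6)$fold, a$fold))
  expect_error(make_folds(5, k = 10), "at least")
})

test_that("every sample is tested exactly once; roles are disjoint and exhaustive", {
  for (n in c(20, 37, 101)) {
    a <- make_folds(n, k = 10, seed = n)
    tested <- integer(0)
    for (i in 1:10) {
      r <- fold_roles(a, i)
      expect_length(intersect(r$train, r$val), 0)
      expect_length(intersect(r$train, r$test), 0)
      expect_length(intersect(r$val, r$test), 0)
      expect_setequal(c(r$train, r$val, r$test), seq_len(n))
      tested <- c(tested, r$test)
    }
    expect_setequal(tested, seq_len(n))
    expect_equal(length(tested), n)
  }
})

test_that("reduced 2-fold mode reuses the validation fold for training", {
  a <- make_folds(10, k = 2, seed = 1)
  r <- fold_roles(a, 1)
  expect_identical(r$train, r$val)
  expect_length(intersect(r$train, r$test), 0)
})

test_that("rank-based AUC matches the brute-force pairwise oracle", {
  expect_equal(roc_auc(c(0, 1, 0, 1), c(0.1, 0.9, 0.8, 0.4)), 0.75)
  expect_equal(roc_auc(c(0, 1, 0, 1), rep(0.3, 4)), 0.5)
  expect_equal(roc_auc(c(0, 0, 1, 1), c(0.1, 0.2, 0.8, 0.9)), 1.0)
  expect_error(roc_auc(c(1, 1, 1), c(0.2, 0.3, 0.1)), "single-class")
  set.seed(99)
  for (i in 1:100) {
    n <- sample(4:50, 1)
    y <- c(0, 1, sample(0:1, n - 2, replace = TRUE))
    s <- round(runif(n), sample(1:3, 1))   # rounding forces ties
    expect_equal(roc_auc(y, s), auc_brute(y, s), tolerance = 1e-12)
  }
})

test_that("mean ROC curve is pinned at the corners and averages fold TPRs", {
  folds <- list(list(labels = c(0, 1, 0, 1), scores = c(0.1, 0.9, 0.2, 0.8)),
                list(labels = c(0, 1, 1, 0), scores = c(0.4, 0.6, 0.7, 0.3)))
  mc <- mean_roc_curve(folds)
  expect_equal(mc$fpr, seq(0, 1, by = 0.01))
  expect_equal(mc$tpr_mean[1], 0)
  expect_equal(mc$tpr_mean[nrow(mc)], 1)
  expect_true(all(diff(mc$tpr_mean) >= -1e-12))
  # both folds are perfectly separated: mid-grid TPR is 1
  expect_equal(mc$tpr_mean[51], 1)
})

test_that("ensemble prediction is the exact arithmetic mean of member outputs", {
  co <- simulate_cohort(4, small_spec(noise_sigma = 0.5), seed = 8)
  cfg <- small_config(seed = 1)
  m1 <- build_model(cfg)
  m2 <- build_model(small_config(seed = 2))
  m1$params$head$w[] <- rnorm(8, 0, 0.5)
  m2$params$head$w[] <- rnorm(8, 0, 0.5)
  p1 <- predict(m1, co)$probability
  p2 <- predict(m2, co)$probability
  ens <- ensemble_model(list(m1$params, m2$params), config = cfg)
  pe <- predict(ens, co)$probability
  expect_identical(pe, (p1 + p2) / 2)
  expect_true(all(pe >= pmin(p1, p2) & pe <= pmax(p1, p2)))
  # identical members reproduce a single member exactly
  ens10 <- ensemble_model(rep(list(m1$params), 10), config = cfg)
  expect_identical(predict(ens10, co)$probability, p1)
})

test_that("train_fold restores the best checkpoint and stops on patience", {
  co <- simulate_cohort(8, small_spec(noise_sigma = 0.5),
                        lesion_law_separated(), seed = 12)
  a <- make_folds(8, k = 2, seed = 1)
  fr <- train_fold(small_config(seed = 2), co, a, 1,
                   spec = batch_spec(batch_size = 4),
                   max_epochs = 1, patience = 1, seed = 5)
  expect_s3_class(fr, "fold_result")
  expect_identical(fr$best_epoch, 1L)
  expect_true(fr$val_auc >= 0 && fr$val_auc <= 1)
  # reported test AUC equals recomputation from the restored checkpoint
  model <- build_model(small_config(seed = 2))
  model$params <- fr$checkpoint
  roles <- fold_roles(a, 1)
  p <- predict(model, co$samples[roles$test], batch_size = 4)
  y <- as.numeric(cohort_labels(co)[roles$test] == "large")
  expect_equal(fr$test_auc, roc_auc(y, p$probability))
  expect_equal(fr$scores, p$probability)
})

test_that("cross-validation bookkeeping covers every sample once and is recomputable", {
  co <- simulate_cohort(12, small_spec(noise_sigma = 0.5),
                        lesion_law_separated(), seed = 13)
  rep3 <- cross_validate(small_config(seed = 3), co, k = 3, seed = 2,
                         spec = batch_spec(batch_size = 6),
                         max_epochs = 2, patience = 2)
  ids <- unlist(lapply(rep3$folds, `[[`, "test_ids"))
  expect_setequal(ids, cohort_ids(co))
  expect_length(ids, 12)
  expect_equal(rep3$test_auc_mean,
               mean(vapply(rep3$folds, `[[`, numeric(1), "test_auc")))
  expect_equal(rep3$val_auc_sd,
               sd(vapply(rep3$folds, `[[`, numeric(1), "val_auc")))
})

test_that("ablation arms share fold assignments and emit a three-row table", {
  co <- simulate_cohort(12, small_spec(noise_sigma = 0.5),
                        lesion_law_separated(), seed = 14)
  ab <- run_ablation(small_config(seed = 4), co, k = 2, seed = 6,
                     spec = batch_spec(batch_size = 6),
                     max_epochs = 1, patience = 1)
  expect_equal(nrow(ab$table), 3)
  expect_setequal(ab$table$pathways, c("both", "global_only", "local_only"))
  f1 <- ab$reports$both$assignment$fold
  expect_identical(ab$reports$global_only$assignment$fold, f1)
  expect_identical(ab$reports$local_only$assignment$fold, f1)
  # reduced models have strictly fewer parameters
  np <- vapply(ab$reports, function(r)
    n_parameters(structure(list(config = r$config,
                                params = r$folds[[1]]$checkpoint),
                           class = "ctp_model")), numeric(1))
  expect_lt(np["global_only"], np["both"])
  expect_lt(np["local_only"], np["both"])
})
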