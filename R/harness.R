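#' Random fold assignment for k-fold cross-validation
#'
#' Randomly permutes `n` samples into `k` near-equal folds. In iteration `i`
#' fold `i` is the test fold, fold `(i mod k) + 1` is the validation fold and
#' the remaining folds train the model (the 8:1:1 pattern for k = 10; the
#' validation fold rotates so every fold serves every role). With `k = 2`
#' (a reduced desk-scale mode) no fold is left for training and the
#' validation fold doubles as the training set.
#'
#' @param n Number of samples (>= k).
#' @param k Number of folds.
#' @param seed Integer seed.
#' @return An object of class `fold_assignment`: `fold` (per-sample fold
#'   index) and `roles(i)` giving the train/val/test index sets of
#'   iteration `i`.
#' @export
make_folds <- function(n, k = 10, seed = 1L) {
  if (n < k) stop("'n' must be at least 'k'")
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(seed)
  fold <- rep_len(seq_len(k), n)[sample.int(n)]
  structure(list(n = as.integer(n), k = as.integer(k), fold = fold,
                 seed = as.integer(seed)),
            class = "fold_assignment")
}

#' @rdname make_folds
#' @param assignment A `fold_assignment`.
#' @param i Iteration index in `1..k`.
#' @export
fold_roles <- function(assignment, i) {
  k <- assignment$k
  stopifnot(i >= 1, i <= k)
  test_f <- i
  val_f <- (i %% k) + 1
  test <- which(assignment$fold == test_f)
  val <- which(assignment$fold == val_f)
  train <- which(!assignment$fold %in% c(test_f, val_f))
  if (length(train) == 0) train <- val    # reduced 2-fold mode
  list(train = train, val = val, test = test)
}

#' Rank-based ROC-AUC
#'
#' Area under the receiver operating characteristic curve by the
#' rank (Mann-Whitney) formulation; tied scores receive midranks, i.e. 0.5
#' credit per tied positive-negative pair.
#'
#' @param labels Binary labels (0/1, logical, or small/large strings).
#' @param scores Numeric scores, higher = more positive.
#' @return AUC in `[0, 1]`.
#' @export
roc_auc <- function(labels, scores) {
  y <- as_binary_labels(labels)
  n1 <- sum(y == 1); n0 <- sum(y == 0)
  if (n1 == 0 || n0 == 0) stop("ROC-AUC undefined: single-class labels")
  r <- rank(scores, ties.method = "average")
  (sum(r[y == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

as_binary_labels <- function(labels) {
  if (is.character(labels) || is.factor(labels))
    return(as.numeric(as.character(labels) == "large"))
  as.numeric(labels)
}

#' Empirical ROC curve and cross-fold mean ROC curve
#'
#' `roc_curve()` returns the empirical (FPR, TPR) staircase. `mean_roc_curve()`
#' interpolates each fold's TPR onto a common FPR grid (step 0.01, endpoints
#' pinned at (0,0) and (1,1)) and averages pointwise.
#'
#' @param labels,scores As in [roc_auc()].
#' @return `roc_curve()`: data frame `fpr`, `tpr`. `mean_roc_curve()`: data
#'   frame `fpr`, `tpr_mean`, `tpr_sd`.
#' @export
roc_curve <- function(labels, scores) {
  y <- as_binary_labels(labels)
  ord <- order(-scores)
  y <- y[ord]
  tpr <- c(0, cumsum(y) / sum(y))
  fpr <- c(0, cumsum(1 - y) / sum(1 - y))
  data.frame(fpr = fpr, tpr = tpr)
}

#' @rdname roc_curve
#' @param fold_results List of per-fold lists with `labels` and `scores` (a
#'   `cv_report$folds` works directly).
#' @param grid_step FPR grid step.
#' @export
mean_roc_curve <- function(fold_results, grid_step = 0.01) {
  grid <- seq(0, 1, by = grid_step)
  tprs <- vapply(fold_results, function(fr) {
    rc <- roc_curve(fr$labels, fr$scores)
    # staircase interpolation: best TPR available at each FPR
    vapply(grid, function(g) max(rc$tpr[rc$fpr <= g + 1e-12]), numeric(1))
  }, numeric(length(grid)))
  tprs <- as.matrix(tprs)
  tpr_mean <- rowMeans(tprs)
  tpr_sd <- apply(tprs, 1, sd)
  tpr_mean[1] <- 0; tpr_mean[length(grid)] <- 1
  data.frame(fpr = grid, tpr_mean = tpr_mean, tpr_sd = tpr_sd)
}

#' Train one cross-validation fold
#'
#' Trains for at most `max_epochs` epochs (one epoch = enough random batches
#' to cover the training role once), evaluating the validation loss after
#' every epoch. Training stops early once the validation loss has not reached
#' a new minimum for `patience` consecutive epochs; the weights with the
#' lowest validation loss are restored before the test fold is evaluated.
#'
#' @param config A [model_config()].
#' @param cohort A labeled `ctp_cohort`.
#' @param assignment A [make_folds()] assignment.
#' @param iteration Fold iteration in `1..k`.
#' @param spec A [batch_spec()].
#' @param max_epochs,patience Training-length controls (the clinical-scale
#'   protocol is 500 epochs, patience 200; desk-scale runs shrink both).
#' @param seed Integer seed for batch draws.
#' @param verbose Print per-epoch losses.
#' @return A `fold_result`: best epoch, validation/test AUC, test predictions
#'   and the trained checkpoint (parameter list).
#' @export
train_fold <- function(config, cohort, assignment, iteration,
                       spec = batch_spec(), max_epochs = 500, patience = 200,
                       seed = 1L, verbose = FALSE) {
  roles <- fold_roles(assignment, iteration)
  if (length(roles$train) == 0) stop("empty training role")
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(seed + 7919L * (iteration - 1L))
  # each fold's network starts from a fresh random initialization, as a
  # framework would reinitialize a newly built model per CV iteration
  cfg_i <- config
  cfg_i$seed <- config$seed + 104729L * (iteration - 1L)
  model <- build_model(cfg_i)
  opt <- adam_init(model$params, lr = config$lr)
  steps <- ceiling(length(roles$train) / spec$batch_size)
  val_samples <- cohort$samples[roles$val]
  y_val <- as.numeric(cohort_labels(cohort)[roles$val] == "large")
  best <- list(loss = Inf, epoch = 0L, params = model$params)
  wait <- 0L
  for (epoch in seq_len(max_epochs)) {
    tr_loss <- 0
    for (b in seq_len(steps)) {
      batch <- make_batch(cohort, spec, ids = roles$train)
      st <- train_step(model, opt, batch$x, batch$y)
      model <- st$model; opt <- st$state
      tr_loss <- tr_loss + st$loss / steps
    }
    p_val <- predict(model, val_samples, batch_size = spec$batch_size)
    val_loss <- bce_loss(p_val$probability, y_val)
    if (verbose)
      message(sprintf("fold %d epoch %d train %.4f val %.4f", iteration,
                      epoch, tr_loss, val_loss))
    if (val_loss < best$loss) {
      best <- list(loss = val_loss, epoch = epoch, params = model$params)
      wait <- 0L
    } else {
      wait <- wait + 1L
      if (wait >= patience) break
    }
  }
  model$params <- best$params            # restore best weights
  p_val <- predict(model, val_samples, batch_size = spec$batch_size)
  test_samples <- cohort$samples[roles$test]
  y_test <- as.numeric(cohort_labels(cohort)[roles$test] == "large")
  p_test <- predict(model, test_samples, batch_size = spec$batch_size)
  structure(list(fold = iteration, best_epoch = best$epoch,
                 val_loss = best$loss,
                 val_auc = roc_auc(y_val, p_val$probability),
                 test_auc = roc_auc(y_test, p_test$probability),
                 labels = y_test, scores = p_test$probability,
                 test_ids = cohort_ids(cohort)[roles$test],
                 checkpoint = model$params),
            class = "fold_result")
}

#' k-fold cross-validation
#'
#' Runs [train_fold()] for every iteration of the assignment and summarizes
#' validation and test ROC-AUC (mean and SD), the pooled per-sample test
#' predictions (each sample is tested exactly once) and the mean ROC curve.
#'
#' @inheritParams train_fold
#' @param assignment Optional pre-made [make_folds()] assignment (shared fold
#'   assignments make ablation arms directly comparable); built from `seed`
#'   when `NULL`.
#' @param k Folds, used when `assignment` is `NULL`.
#' @param checkpoint_dir Optional directory; per-fold checkpoints are saved as
#'   `fold<i>.rds`.
#' @return A `cv_report`.
#' @export
cross_validate <- function(config, cohort, k = 10, seed = 1L,
                           assignment = NULL, spec = batch_spec(),
                           max_epochs = 500, patience = 200,
                           checkpoint_dir = NULL, verbose = FALSE) {
  n <- length(cohort$samples)
  if (is.null(assignment)) assignment <- make_folds(n, k = k, seed = seed)
  folds <- vector("list", assignment$k)
  for (i in seq_len(assignment$k)) {
    folds[[i]] <- train_fold(config, cohort, assignment, i, spec = spec,
                             max_epochs = max_epochs, patience = patience,
                             seed = seed, verbose = verbose)
    if (!is.null(checkpoint_dir)) {
      if (!dir.exists(checkpoint_dir)) dir.create(checkpoint_dir,
                                                  recursive = TRUE)
      saveRDS(folds[[i]]$checkpoint,
              file.path(checkpoint_dir, sprintf("fold%d.rds", i)))
    }
  }
  val_auc <- vapply(folds, `[[`, numeric(1), "val_auc")
  test_auc <- vapply(folds, `[[`, numeric(1), "test_auc")
  structure(list(config = config, assignment = assignment, folds = folds,
                 val_auc_mean = mean(val_auc), val_auc_sd = sd(val_auc),
                 test_auc_mean = mean(test_auc), test_auc_sd = sd(test_auc),
                 mean_roc = mean_roc_curve(folds), seed = seed),
            class = "cv_report")
}

#' @export
print.cv_report <- function(x, ...) {
  cat(sprintf("<cv_report> %d-fold CV (%s, pathways=%s)\n", x$assignment$k,
              x$config$backbone, x$config$pathways))
  cat(sprintf("  validation ROC-AUC %.3f (%.3f)\n", x$val_auc_mean,
              x$val_auc_sd))
  cat(sprintf("  test       ROC-AUC %.3f (%.3f)\n", x$test_auc_mean,
              x$test_auc_sd))
  invisible(x)
}

#' Fold-ensemble model
#'
#' The final model of a cross-validation run: the k fold checkpoints, whose
#' predicted probabilities are averaged arithmetically.
#'
#' @param report A `cv_report`, or a list of checkpoints.
#' @param config A [model_config()] (taken from the report when omitted).
#' @return An `ensemble_model`.
#' @export
ensemble_model <- function(report, config = NULL) {
  if (inherits(report, "cv_report")) {
    checkpoints <- lapply(report$folds, `[[`, "checkpoint")
    config <- report$config
  } else checkpoints <- report
  if (is.null(config)) stop("'config' required with a bare checkpoint list")
  structure(list(checkpoints = checkpoints, config = config),
            class = "ensemble_model")
}

#' Predict with a fold ensemble
#'
#' The ensemble probability is the arithmetic mean of the member
#' probabilities, exactly.
#'
#' @param object An [ensemble_model()].
#' @param samples List of `ctp_sample`s or a `ctp_cohort`.
#' @param ... Passed to the member [predict.ctp_model()].
#' @return Data frame `sample_id`, `probability`.
#' @export
predict.ensemble_model <- function(object, samples, ...) {
  if (length(object$checkpoints) == 0) stop("no checkpoints in ensemble")
  member <- function(ck) {
    m <- structure(list(config = object$config, params = ck),
                   class = "ctp_model")
    predict(m, samples, ...)
  }
  preds <- lapply(object$checkpoints, member)
  out <- preds[[1]]
  out$probability <- rowMeans(vapply(preds, `[[`, numeric(nrow(out)),
                                     "probability"))
  out
}

#' Pathway ablation study
#'
#' Cross-validates the full model and the two reduced models (global pathway
#' alone, local pathway alone) on an identical fold assignment and seed, and
#' tabulates mean (SD) test ROC-AUC for the three arms. All three runs go
#' through the same [cross_validate()] path.
#'
#' @inheritParams cross_validate
#' @return List with `reports` (named list of three `cv_report`s) and `table`
#'   (three-row comparison data frame).
#' @export
run_ablation <- function(config, cohort, k = 10, seed = 1L,
                         spec = batch_spec(), max_epochs = 500,
                         patience = 200, verbose = FALSE) {
  assignment <- make_folds(length(cohort$samples), k = k, seed = seed)
  arms <- c("both", "global_only", "local_only")
  reports <- lapply(arms, function(p) {
    cfg <- config
    cfg$pathways <- p
    cross_validate(cfg, cohort, seed = seed, assignment = assignment,
                   spec = spec, max_epochs = max_epochs, patience = patience,
                   verbose = verbose)
  })
  names(reports) <- arms
  table <- data.frame(
    model = c("full", "global pathway alone", "local pathway alone"),
    pathways = arms,
    test_auc_mean = vapply(reports, `[[`, numeric(1), "test_auc_mean"),
    test_auc_sd = vapply(reports, `[[`, numeric(1), "test_auc_sd"),
    row.names = NULL)
  list(reports = reports, table = table)
}
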