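# Patient-hold-out cross-validation, early stopping, permutation null,
# model-selection grid and refit-then-test scoring.

#' Extract, encode and cache the features of every sample in a cohort
#'
#' Motif tables (with the per-sample top-k cap) and raw, un-normalized
#' feature matrices. Normalization is deliberately not applied here: its
#' statistics depend on which samples form the training set.
#'
#' @param cohort A `tcr_cohort`.
#' @param config A [model_config()].
#' @return A `tcr_cohort_features` list: `tables`, `X_raw`, `labels`,
#'   `sample_ids`, `config`.
#' @export
prepare_cohort_features <- function(cohort, config = model_config()) {
  check_config_supported(config)
  tables <- lapply(cohort$repertoires, build_motif_table, config = config)
  X_raw <- lapply(tables, encode_motif_table, config = config)
  structure(list(tables = tables, X_raw = X_raw,
                 labels = cohort_labels(cohort),
                 sample_ids = cohort_ids(cohort),
                 config = config),
            class = "tcr_cohort_features")
}

# Normalize a list of raw matrices with frozen stats and prepend nothing;
# mil_fit adds the intercept itself.
normalize_features <- function(X_raw_list, stats) {
  lapply(X_raw_list, apply_normalizer, stats = stats)
}

#' Pick the early-stopping step from a held-out loss curve
#'
#' @param loss_curve Mean held-out loss after each optimization step.
#' @return 0-based index of the minimizing step (earliest on ties), i.e.
#'   the loss after `step + 1` parameter updates.
#' @export
select_early_stopping <- function(loss_curve) {
  stopifnot(length(loss_curve) >= 1L)
  which.min(loss_curve) - 1L
}

#' Exhaustive patient-hold-out cross-validation
#'
#' For each sample, the model is fitted on the remaining samples and the
#' held-out sample scored along the whole optimization trajectory. The
#' same initial parameter draws are reused in every fold, so the only
#' variation between folds is the held-out patient. The normalizer is
#' refitted on each fold's training samples and frozen before scoring the
#' held-out sample. The early-stopping step minimizes the mean held-out
#' loss curve, and the reported probabilities, accuracy and loss are
#' taken at that step.
#'
#' @param cohort A `tcr_cohort` containing both classes.
#' @param config A [model_config()].
#' @param opt An [optimizer_config()].
#' @param features Optional precomputed [prepare_cohort_features()]
#'   result (labels may be overridden with `labels`).
#' @param labels Optional label vector overriding the cohort labels (used
#'   by the permutation test).
#' @param init Optional shared initial parameter matrix.
#' @return A `tcr_cv_result`: `per_sample` data frame (sample_id, label,
#'   probability, predicted, heldout_loss), `accuracy`, `mean_loss`
#'   (nats), `loss_curve`, `early_stop_step`, `config`, `opt`.
#' @export
leave_one_out_cv <- function(cohort, config = model_config(),
                             opt = optimizer_config(), features = NULL,
                             labels = NULL, init = NULL) {
  if (is.null(features)) features <- prepare_cohort_features(cohort, config)
  y <- if (is.null(labels)) features$labels else as.integer(labels)
  n <- length(y)
  if (length(unique(y)) < 2L) {
    stop("cross-validation requires both classes in the cohort",
         call. = FALSE)
  }
  d <- n_features(features$config)
  if (is.null(init)) init <- init_params(d, opt$n_restarts, seed = opt$seed)
  prob_by_step <- matrix(NA_real_, opt$n_steps, n)
  for (j in seq_len(n)) {
    stats <- fit_normalizer(features$X_raw[-j])
    Xtr <- normalize_features(features$X_raw[-j], stats)
    Xh <- apply_normalizer(features$X_raw[[j]], stats)
    if (nrow(Xh) == 0L) {
      warning("held-out sample ", features$sample_ids[j],
              " has no motifs; scored 0", call. = FALSE)
      prob_by_step[, j] <- 0
      next
    }
    fit <- mil_fit(Xtr, y[-j], opt, init = init, X_heldout = Xh)
    prob_by_step[, j] <- fit$heldout_prob_by_step
  }
  # per-step held-out loss, averaged over folds
  loss_by_step <- vapply(seq_len(opt$n_steps), function(t) {
    negative_log_likelihood(prob_by_step[t, ], y)
  }, numeric(1))
  step <- select_early_stopping(loss_by_step)
  prob <- prob_by_step[step + 1L, ]
  per_sample <- data.frame(
    sample_id = features$sample_ids,
    label = y,
    probability = prob,
    predicted = classify(prob),
    heldout_loss = vapply(seq_len(n), function(j) {
      negative_log_likelihood(prob[j], y[j])
    }, numeric(1)),
    stringsAsFactors = FALSE)
  structure(list(per_sample = per_sample,
                 accuracy = mean(per_sample$predicted == y),
                 mean_loss = loss_by_step[step + 1L],
                 loss_curve = loss_by_step,
                 early_stop_step = step,
                 config = features$config, opt = opt),
            class = "tcr_cv_result")
}

#' @export
print.tcr_cv_result <- function(x, ...) {
  cat(sprintf(paste0("<tcr_cv_result> %d folds: accuracy %.1f%%, held-out ",
                     "loss %.4f nats, early stop at step %d\n"),
              nrow(x$per_sample), 100 * x$accuracy, x$mean_loss,
              x$early_stop_step))
  invisible(x)
}

#' Label-permutation null analysis
#'
#' Each run draws a uniform random permutation of the label vector
#' (preserving the class counts), repeats the full patient-hold-out
#' cross-validation with early stopping, and records the accuracy, mean
#' held-out loss and chosen step. By default the same initial parameter
#' draws are reused in every run, mirroring the unpermuted analysis. The
#' empirical p-value for an observed accuracy uses the add-one estimator
#' `(1 + #\{runs >= observed\}) / (1 + n_perm)`.
#'
#' @param cohort A `tcr_cohort`.
#' @param config A [model_config()].
#' @param opt An [optimizer_config()].
#' @param n_perm Number of permutation runs.
#' @param seed Seed for the permutation draws (the initializations use
#'   `opt$seed`); defaults to `opt$seed + 1`.
#' @param observed_accuracy Accuracy of the unpermuted analysis; if `NA`,
#'   it is computed by running the cross-validation on the true labels.
#' @param features Optional precomputed [prepare_cohort_features()].
#' @return A `tcr_permutation_result`: `per_run` data frame (run,
#'   accuracy, mean_loss, early_stop_step), `permuted_labels` (list),
#'   `mean_accuracy`, `mean_loss`, `observed_accuracy`, `p_value`.
#' @export
permutation_test <- function(cohort, config = model_config(),
                             opt = optimizer_config(), n_perm = 20L,
                             seed = NULL, observed_accuracy = NA,
                             features = NULL) {
  stopifnot(n_perm >= 1L)
  if (is.null(features)) features <- prepare_cohort_features(cohort, config)
  if (is.na(observed_accuracy)) {
    observed_accuracy <- leave_one_out_cv(cohort, config, opt,
                                          features = features)$accuracy
  }
  if (is.null(seed)) seed <- opt$seed + 1L
  y <- features$labels
  perms <- withr_seed(seed, lapply(seq_len(n_perm), function(i) sample(y)))
  init <- init_params(n_features(features$config), opt$n_restarts,
                      seed = opt$seed)
  runs <- lapply(seq_len(n_perm), function(i) {
    cv <- leave_one_out_cv(cohort, config, opt, features = features,
                           labels = perms[[i]], init = init)
    data.frame(run = i, accuracy = cv$accuracy, mean_loss = cv$mean_loss,
               early_stop_step = cv$early_stop_step)
  })
  per_run <- do.call(rbind, runs)
  structure(list(per_run = per_run,
                 permuted_labels = perms,
                 mean_accuracy = mean(per_run$accuracy),
                 mean_loss = mean(per_run$mean_loss),
                 observed_accuracy = observed_accuracy,
                 p_value = (1 + sum(per_run$accuracy >= observed_accuracy)) /
                   (1 + n_perm)),
            class = "tcr_permutation_result")
}

# Evaluate an expression with a temporary RNG state seeded by `seed`.
withr_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv())) {
    get(".Random.seed", globalenv())
  }
  set.seed(seed)
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  expr
}

#' @export
print.tcr_permutation_result <- function(x, ...) {
  cat(sprintf(paste0("<tcr_permutation_result> %d runs: mean accuracy ",
                     "%.1f%%, mean loss %.4f nats; p = %.3f vs observed ",
                     "%.1f%%\n"),
              nrow(x$per_run), 100 * x$mean_accuracy, x$mean_loss,
              x$p_value, 100 * x$observed_accuracy))
  invisible(x)
}

#' Evaluate a grid of model configurations
#'
#' Runs the patient-hold-out cross-validation for every configuration and
#' ranks them by held-out loss (the model-selection criterion).
#' Configurations requesting unimplemented features (blood frequency,
#' batch normalization) are skipped with a notice, not an error.
#'
#' @param cohort A `tcr_cohort`.
#' @param configs List of [model_config()] objects.
#' @param opt An [optimizer_config()].
#' @return A `tcr_grid_result` with a ranked data frame `table` (one row
#'   per configuration: configuration columns, `cv_log_loss`,
#'   `cv_accuracy`, `early_stopping_step`, `n_restarts`, `skipped`,
#'   `note`) and `best` (index into `configs` of the lowest-loss row).
#' @export
run_model_grid <- function(cohort, configs, opt = optimizer_config()) {
  stopifnot(length(configs) >= 1L)
  rows <- lapply(seq_along(configs), function(i) {
    cf <- configs[[i]]
    row <- data.frame(
      config = i,
      motif_size = cf$motif_size,
      n_gap_positions = cf$n_gap_positions,
      gap_onehot = cf$gap_onehot,
      restrict_gap_to_position = if (is.null(cf$restrict_gap_to_position))
        NA_integer_ else cf$restrict_gap_to_position,
      use_blood_frequency = cf$use_blood_frequency,
      log_frequency = cf$log_frequency,
      second_order = cf$second_order,
      batch_norm = cf$batch_norm,
      cv_log_loss = NA_real_, cv_accuracy = NA_real_,
      early_stopping_step = NA_integer_,
      n_restarts = opt$n_restarts,
      skipped = FALSE, note = "", stringsAsFactors = FALSE)
    sup <- tryCatch({ check_config_supported(cf); TRUE },
                    error = function(e) conditionMessage(e))
    if (!isTRUE(sup)) {
      row$skipped <- TRUE
      row$note <- paste("skipped:", sup)
      message("config ", i, " skipped: ", sup)
      return(row)
    }
    cv <- leave_one_out_cv(cohort, cf, opt)
    row$cv_log_loss <- cv$mean_loss
    row$cv_accuracy <- cv$accuracy
    row$early_stopping_step <- cv$early_stop_step
    row
  })
  tab <- do.call(rbind, rows)
  ord <- order(tab$skipped, tab$cv_log_loss, tab$config)
  tab <- tab[ord, , drop = FALSE]
  rownames(tab) <- NULL
  structure(list(table = tab,
                 best = tab$config[which(!tab$skipped)[1L]]),
            class = "tcr_grid_result")
}

#' @export
print.tcr_grid_result <- function(x, ...) {
  cat("<tcr_grid_result> ranked by cross-validation log-loss:\n")
  print(x$table[, c("config", "motif_size", "n_gap_positions",
                    "log_frequency", "cv_log_loss", "cv_accuracy",
                    "early_stopping_step", "skipped")])
  invisible(x)
}

#' Refit on a full training cohort and score an unseen test cohort
#'
#' The normalizer and model parameters are fitted on all training samples
#' for `early_stop_step + 1` updates (the step count selected by
#' cross-validation), reusing the same random initializations, and the
#' frozen model then scores every test sample. The ROC is built by
#' sweeping the decision threshold over the observed repertoire scores
#' and the AUC computed by the trapezoid rule.
#'
#' @param train,test Disjoint `tcr_cohort`s.
#' @param config A [model_config()].
#' @param opt An [optimizer_config()].
#' @param early_stop_step 0-based step count from cross-validation; `NULL`
#'   runs [leave_one_out_cv()] on `train` to determine it.
#' @param init Optional initial parameter matrix (to reuse draws from the
#'   cross-validation).
#' @return A `tcr_test_result`: `per_sample` (test predictions),
#'   `accuracy`, `sensitivity`, `specificity`, `auc`, `roc` (threshold,
#'   fpr, tpr) and `model` (a `tcr_mil_model` usable with
#'   [score_cohort()]).
#' @export
refit_and_score_test <- function(train, test, config = model_config(),
                                 opt = optimizer_config(),
                                 early_stop_step = NULL, init = NULL) {
  overlap <- intersect(cohort_ids(train), cohort_ids(test))
  if (length(overlap) > 0L) {
    stop("training and test cohorts share sample ids: ",
         paste(overlap, collapse = ", "), call. = FALSE)
  }
  if (is.null(early_stop_step)) {
    early_stop_step <- leave_one_out_cv(train, config, opt)$early_stop_step
  }
  model <- fit_repertoire_model(train, config, opt,
                                n_steps = early_stop_step + 1L,
                                init = init)
  scores <- score_cohort(model, test)
  y <- cohort_labels(test)
  pred <- classify(scores)
  per_sample <- data.frame(sample_id = cohort_ids(test), label = y,
                           probability = scores, predicted = pred,
                           stringsAsFactors = FALSE)
  metrics <- classification_metrics(pred, y)
  roc <- roc_points(scores, y)
  structure(c(list(per_sample = per_sample),
              metrics,
              list(mean_loss = negative_log_likelihood(scores, y),
                   auc = auc_trapezoid(roc$fpr, roc$tpr),
                   roc = roc, early_stop_step = early_stop_step,
                   model = model)),
            class = "tcr_test_result")
}

#' @export
print.tcr_test_result <- function(x, ...) {
  cat(sprintf(paste0("<tcr_test_result> %d test samples: accuracy %.1f%%, ",
                     "sensitivity %.1f%%, specificity %.1f%%, AUC %.3f\n"),
              nrow(x$per_sample), 100 * x$accuracy, 100 * x$sensitivity,
              100 * x$specificity, x$auc))
  invisible(x)
}

# Accuracy, sensitivity = TP/(TP+FN) over tumor labels, specificity =
# TN/(TN+FP) over healthy labels.
classification_metrics <- function(predicted, labels) {
  list(accuracy = mean(predicted == labels),
       sensitivity = if (any(labels == 1)) {
         mean(predicted[labels == 1] == 1)
       } else NA_real_,
       specificity = if (any(labels == 0)) {
         mean(predicted[labels == 0] == 0)
       } else NA_real_)
}

#' ROC points from repertoire scores
#'
#' Sweeps the decision threshold over the observed scores (prediction
#' positive when score >= threshold) and returns one point per threshold
#' plus the (0, 0) endpoint.
#'
#' @param scores Repertoire probabilities.
#' @param labels Binary labels.
#' @return Data frame `threshold`, `fpr`, `tpr`, sorted by increasing
#'   false-positive rate.
#' @export
roc_points <- function(scores, labels) {
  stopifnot(length(scores) == length(labels), any(labels == 1),
            any(labels == 0))
  th <- sort(unique(scores))
  pts <- lapply(th, function(t) {
    pred <- as.integer(scores >= t)
    data.frame(threshold = t,
               fpr = mean(pred[labels == 0] == 1),
               tpr = mean(pred[labels == 1] == 1))
  })
  out <- rbind(do.call(rbind, pts),
               data.frame(threshold = Inf, fpr = 0, tpr = 0))
  out <- out[order(out$fpr, out$tpr), ]
  rownames(out) <- NULL
  out
}

#' Trapezoid-rule area under a ROC curve
#'
#' @param fpr,tpr ROC coordinates (any order; sorted internally).
#' @return AUC in `[0, 1]`.
#' @export
auc_trapezoid <- function(fpr, tpr) {
  ord <- order(fpr, tpr)
  x <- c(0, fpr[ord], 1)
  y <- c(0, tpr[ord], 1)
  sum(diff(x) * (utils::head(y, -1) + utils::tail(y, -1)) / 2)
}

#' Fit a deployable repertoire classifier
#'
#' Convenience wrapper: builds motif tables, fits the abundance-weighted
#' normalizer on all samples, runs the multi-restart Adam fit, and
#' bundles configuration, frozen normalization statistics and the best
#' parameters into a model object.
#'
#' @param cohort Training `tcr_cohort`.
#' @param config A [model_config()].
#' @param opt An [optimizer_config()].
#' @param n_steps Optional override of `opt$n_steps` (e.g. the
#'   early-stopping step count + 1).
#' @param init Optional initial parameter matrix.
#' @return A `tcr_mil_model`: `config`, `norm_stats`, `params`, `opt`,
#'   `fit` (the `tcr_fit_result`).
#' @export
fit_repertoire_model <- function(cohort, config = model_config(),
                                 opt = optimizer_config(), n_steps = NULL,
                                 init = NULL) {
  features <- prepare_cohort_features(cohort, config)
  if (!is.null(n_steps)) opt$n_steps <- as.integer(n_steps)
  stats <- fit_normalizer(features$X_raw)
  Xn <- normalize_features(features$X_raw, stats)
  if (is.null(init)) {
    init <- init_params(n_features(config), opt$n_restarts, seed = opt$seed)
  }
  fit <- mil_fit(Xn, features$labels, opt, init = init)
  structure(list(config = config, norm_stats = stats, params = fit$params,
                 opt = opt, fit = fit),
            class = "tcr_mil_model")
}

#' Score every repertoire of a cohort with a fitted model
#'
#' @param model A `tcr_mil_model`.
#' @param cohort A `tcr_cohort`.
#' @return Named numeric vector of repertoire probabilities.
#' @export
score_cohort <- function(model, cohort) {
  stopifnot(inherits(model, "tcr_mil_model"))
  features <- prepare_cohort_features(cohort, model$config)
  vapply(seq_along(features$X_raw), function(j) {
    X <- apply_normalizer(features$X_raw[[j]], model$norm_stats)
    if (nrow(X) == 0L) return(score_repertoire(numeric(0)))
    score_repertoire(score_motif(X, model$params))
  }, numeric(1)) |> setNames(features$sample_ids)
}

#' Serialize a fitted model to JSON
#'
#' @param model A `tcr_mil_model`.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_model_json <- function(model, path) {
  obj <- list(config = unclass(model$config),
              norm_stats = list(mean = model$norm_stats$mean,
                                var = model$norm_stats$var,
                                floor = model$norm_stats$floor),
              params = list(bias = model$params$bias,
                            weights = model$params$weights),
              seed = model$opt$seed,
              n_steps = model$opt$n_steps,
              n_restarts = model$opt$n_restarts,
              restart_index = model$fit$restart_index,
              training_loss = model$fit$training_loss)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                       null = "null", pretty = TRUE)
  invisible(path)
}
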