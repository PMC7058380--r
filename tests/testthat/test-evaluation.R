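test_that("early stopping picks the held-out loss minimum, earliest on ties", {
  expect_equal(select_early_stopping(seq(2, 0.1, length.out = 2500)), 2499)
  expect_equal(select_early_stopping(c(3, 2, 1, 0.5, 0.4, 0.3, 0.7, 0.35)), 5)
  expect_equal(select_early_stopping(rep(1, 10)), 0)
  expect_equal(select_early_stopping(c(5, 1, 1, 1)), 1)
})

test_that("hold-out cross-validation separates a planted cohort", {
  gen <- tiny_separable_cohort(4, 4, seed = 23)
  cv <- leave_one_out_cv(gen$cohort, model_config(), fast_opt(200, 32))
  expect_equal(nrow(cv$per_sample), 8)
  expect_equal(cv$accuracy, 1.0)
  expect_length(cv$loss_curve, 200)
  expect_equal(cv$mean_loss, cv$loss_curve[cv$early_stop_step + 1])
  # summary fields agree with per-sample records
  expect_equal(cv$accuracy,
               mean(cv$per_sample$predicted == cv$per_sample$label))
  expect_equal(cv$per_sample$predicted, classify(cv$per_sample$probability))
})

test_that("cross-validation is reproducible and needs both classes", {
  gen <- tiny_separable_cohort(2, 2, seed = 29)
  cv1 <- leave_one_out_cv(gen$cohort, model_config(), fast_opt(60, 8))
  cv2 <- leave_one_out_cv(gen$cohort, model_config(), fast_opt(60, 8))
  expect_identical(cv1$per_sample, cv2$per_sample)
  expect_identical(cv1$loss_curve, cv2$loss_curve)
  expect_error(leave_one_out_cv(gen$cohort, model_config(), fast_opt(),
                                labels = rep(1, 4)),
               "both classes")
  # n = 2 cohort: exactly two folds
  small <- cohort(gen$cohort$repertoires[c(1, 3)])
  cv3 <- leave_one_out_cv(small, model_config(), fast_opt(40, 4))
  expect_equal(nrow(cv3$per_sample), 2)
})

test_that("permutation runs preserve the label multiset and report p-values", {
  gen <- tiny_separable_cohort(3, 3, seed = 31)
  pt <- permutation_test(gen$cohort, model_config(), fast_opt(50, 8),
                         n_perm = 4, observed_accuracy = 1.0)
  expect_equal(nrow(pt$per_run), 4)
  for (perm in pt$permuted_labels) {
    expect_equal(sort(perm), sort(cohort_labels(gen$cohort)))
  }
  expect_equal(pt$p_value,
               (1 + sum(pt$per_run$accuracy >= 1.0)) / 5)
  expect_true(all(c("accuracy", "mean_loss", "early_stop_step") %in%
                    names(pt$per_run)))
})

test_that("the grid runner ranks configurations by held-out loss", {
  gen <- tiny_separable_cohort(3, 3, seed = 37)
  configs <- list(model_config(3, 1), model_config(3, 0),
                  model_config(3, 1, use_blood_frequency = TRUE))
  expect_message(grid <- run_model_grid(gen$cohort, configs, fast_opt(60, 8)),
                 "skipped")
  expect_equal(nrow(grid$table), 3)
  expect_true(grid$table$skipped[3])
  fitted <- grid$table[!grid$table$skipped, ]
  expect_false(is.unsorted(fitted$cv_log_loss))
  expect_equal(grid$best, fitted$config[1])
  # single-config grid: that config is best
  g1 <- run_model_grid(gen$cohort, list(model_config(3, 1)), fast_opt(40, 4))
  expect_equal(g1$best, 1)
})

test_that("ROC construction matches an independent implementation", {
  skip_if_not_installed("pROC")
  set.seed(41)
  scores <- runif(30)
  labels <- rbinom(30, 1, 0.5)
  roc <- roc_points(scores, labels)
  auc <- auc_trapezoid(roc$fpr, roc$tpr)
  ref <- suppressMessages(pROC::auc(pROC::roc(labels, scores)))
  expect_equal(auc, as.numeric(ref), tolerance = 1e-10)
  # perfectly separated scores
  expect_equal(auc_trapezoid(c(0, 0, 1), c(0, 1, 1)), 1)
  perfect <- roc_points(c(0.9, 0.8, 0.2, 0.1), c(1, 1, 0, 0))
  expect_equal(auc_trapezoid(perfect$fpr, perfect$tpr), 1)
})

test_that("refit-and-test scores an unseen cohort with frozen statistics", {
  train <- tiny_separable_cohort(4, 4, seed = 43)
  test <- tiny_separable_cohort(3, 3, seed = 44, id_prefix = "t_")
  res <- refit_and_score_test(train$cohort, test$cohort, model_config(),
                              fast_opt(200, 32), early_stop_step = 199)
  expect_equal(nrow(res$per_sample), 6)
  y <- res$per_sample$label
  pred <- res$per_sample$predicted
  expect_equal(res$accuracy, mean(pred == y))
  expect_equal(res$sensitivity, mean(pred[y == 1] == 1))
  expect_equal(res$specificity, mean(pred[y == 0] == 0))
  expect_gte(res$auc, 0.9)  # planted signal generalizes across seeds
  # self-consistency: the refitted model reproduces its training loss
  probs <- score_cohort(res$model, train$cohort)
  expect_equal(negative_log_likelihood(probs, cohort_labels(train$cohort)),
               res$model$fit$training_loss, tolerance = 1e-9)
  expect_error(refit_and_score_test(train$cohort, train$cohort),
               "share sample ids")
})

test_that("fitted models serialize to JSON and score cohorts", {
  gen <- tiny_separable_cohort(2, 2, seed = 47)
  model <- fit_repertoire_model(gen$cohort, model_config(), fast_opt(40, 4))
  path <- tempfile(fileext = ".json")
  write_model_json(model, path)
  obj <- jsonlite::read_json(path)
  expect_equal(obj$config$motif_size, 3)
  expect_equal(length(obj$params$weights), 16)
  expect_equal(obj$training_loss, model$fit$training_loss)
  scores <- score_cohort(model, gen$cohort)
  expect_named(scores, cohort_ids(gen$cohort))
  expect_true(all(scores >= 0 & scores <= 1))
})
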