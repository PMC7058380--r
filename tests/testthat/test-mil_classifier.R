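test_that("motif scoring reproduces the logistic closed forms", {
  p0 <- score_motif(rep(0, 16), c(0, rep(1, 16)))
  expect_equal(p0, 0.5)
  # logit = ln 3 -> P = 0.75
  expect_equal(score_motif(matrix(log(3)), c(0, 1)), 0.75)
  # numerically stable at extreme logits
  expect_equal(score_motif(matrix(800), c(0, 1)), 1)
  expect_equal(score_motif(matrix(-800), c(0, 1)), 0)
  expect_error(score_motif(matrix(NaN), c(0, 1)), "non-finite")
  # random instances vs direct high-precision evaluation
  set.seed(31)
  X <- matrix(rnorm(50 * 16), 50, 16)
  beta <- rnorm(17)
  expect_equal(score_motif(X, beta),
               1 / (1 + exp(-(beta[1] + X %*% beta[-1]))),
               tolerance = 1e-12, ignore_attr = TRUE)
})

test_that("repertoire aggregation is the max with monotone growth", {
  expect_equal(score_repertoire(c(0.1, 0.9, 0.3)), 0.9)
  expect_equal(score_repertoire(0.42), 0.42)
  expect_warning(z <- score_repertoire(numeric(0)), "no motifs")
  expect_equal(z, 0)
  set.seed(32)
  p <- runif(10)
  expect_gte(score_repertoire(c(p, runif(1))), score_repertoire(p))
})

test_that("classification threshold calls ties positive", {
  expect_equal(classify(0.5), 1L)
  expect_equal(classify(0.4999), 0L)
  expect_equal(classify(c(1, 0)), c(1L, 0L))
})

test_that("mean negative log-likelihood matches closed forms and oracle", {
  expect_equal(negative_log_likelihood(c(1, 0), c(1, 0)), 0,
               tolerance = 1e-10)
  expect_equal(negative_log_likelihood(rep(0.5, 8), rep(c(0, 1), 4)), log(2))
  expect_equal(negative_log_likelihood(rep(0.5, 8), rep(c(0, 1), 4),
                                       bits = TRUE), 1)
  set.seed(33)
  p <- runif(20, 0.01, 0.99)
  y <- rbinom(20, 1, 0.5)
  expect_equal(negative_log_likelihood(p, y),
               -mean(y * log(p) + (1 - y) * log(1 - p)), tolerance = 1e-12)
  expect_error(negative_log_likelihood(c(0.5, 0.5), 1), "length")
})

test_that("initial draws follow the stated two-scale scheme", {
  B <- init_params(16, n_restarts = 1e5, seed = 5)
  expect_true(all(B[1, ] == 0))
  atchley_w <- B[2, ]
  abundance_w <- B[17, ]
  expect_equal(var(atchley_w), 0.25 / 15, tolerance = 0.05)
  expect_equal(var(abundance_w), 0.25, tolerance = 0.05)
  # equal expected squared magnitude of the two blocks
  expect_equal(mean(colSums(B[2:16, ]^2)), mean(abundance_w^2),
               tolerance = 0.02)
  # draws consumed in fixed order: restart prefixes are stable
  expect_equal(init_params(16, 8, seed = 9)[, 1:3],
               init_params(16, 3, seed = 9))
  # alternative typographic reading: sd = 1/15
  Bsd <- init_params(16, n_restarts = 2e4, seed = 5, scheme = "sd")
  expect_equal(sd(Bsd[2, ]), 0.5 / 15, tolerance = 0.05)
})

test_that("zero parameters give score 0.5 and loss ln 2 exactly", {
  gen <- tiny_separable_cohort()
  feats <- prepare_cohort_features(gen$cohort)
  st <- fit_normalizer(feats$X_raw)
  X_list <- lapply(feats$X_raw, apply_normalizer, stats = st)
  beta <- rep(0, 17)
  probs <- vapply(X_list, function(X) score_repertoire(score_motif(X, beta)),
                  numeric(1))
  expect_equal(probs, rep(0.5, length(X_list)), ignore_attr = TRUE)
  expect_equal(negative_log_likelihood(probs, feats$labels), log(2))
  lg <- tcrmil:::mil_loss_grad(beta, X_list, feats$labels)
  expect_identical(lg$loss, log(2))
})

test_that("analytic subgradient matches central finite differences", {
  set.seed(34)
  X_list <- lapply(c(4, 6, 5), function(m) matrix(rnorm(m * 16), m, 16))
  y <- c(1, 0, 1)
  beta <- rnorm(17, sd = 0.3)
  lg <- tcrmil:::mil_loss_grad(beta, X_list, y)
  h <- 1e-6
  fd <- vapply(seq_along(beta), function(k) {
    e <- numeric(length(beta)); e[k] <- h
    (tcrmil:::mil_loss_grad(beta + e, X_list, y)$loss -
       tcrmil:::mil_loss_grad(beta - e, X_list, y)$loss) / (2 * h)
  }, numeric(1))
  expect_equal(lg$grad, fd, tolerance = 1e-5)
})

test_that("the compiled kernel reproduces the plain-R Adam trajectory", {
  set.seed(35)
  X_list <- lapply(c(3, 5, 4, 6), function(m) matrix(rnorm(m * 6), m, 6))
  y <- c(1, 0, 1, 0)
  init <- init_params(6, n_restarts = 3, n_atchley = 5, seed = 8)
  opt <- optimizer_config(n_steps = 40, n_restarts = 3, seed = 8)
  fit <- mil_fit(X_list, y, opt, init = init)
  ref <- lapply(1:3, function(r) reference_adam(init[, r], X_list, y, 40))
  ref_final <- vapply(ref, function(z) tail(z$loss_by_step, 1), numeric(1))
  expect_equal(fit$final_losses, ref_final, tolerance = 1e-10)
  best <- which.min(ref_final)
  expect_equal(fit$restart_index, best)
  expect_equal(fit$loss_by_step, ref[[best]]$loss_by_step, tolerance = 1e-10)
  expect_equal(c(fit$params$bias, fit$params$weights), ref[[best]]$beta,
               tolerance = 1e-10)
})

test_that("the best training loss is non-increasing in the restart count", {
  gen <- tiny_separable_cohort()
  feats <- prepare_cohort_features(gen$cohort)
  st <- fit_normalizer(feats$X_raw)
  X_list <- lapply(feats$X_raw, apply_normalizer, stats = st)
  init <- init_params(16, 12, seed = 2)
  opt <- function(R) optimizer_config(n_steps = 60, n_restarts = R, seed = 2)
  f4 <- mil_fit(X_list, feats$labels, opt(4), init = init[, 1:4])
  f12 <- mil_fit(X_list, feats$labels, opt(12), init = init)
  expect_lte(f12$training_loss, f4$training_loss)
  # the shared prefix of restarts yields identical losses
  expect_equal(f12$final_losses[1:4], f4$final_losses)
})

test_that("a separable planted signal is fitted to perfect training accuracy", {
  gen <- generate_cohort(synthetic_spec(n_pos = 4, n_neg = 4,
                                        seqs_per_sample = 12, seed = 17))
  feats <- prepare_cohort_features(gen$cohort)
  st <- fit_normalizer(feats$X_raw)
  X_list <- lapply(feats$X_raw, apply_normalizer, stats = st)
  fit <- mil_fit(X_list, feats$labels, fast_opt(n_steps = 200, n_restarts = 32))
  beta <- c(fit$params$bias, fit$params$weights)
  probs <- vapply(X_list, function(X) score_repertoire(score_motif(X, beta)),
                  numeric(1))
  expect_equal(classify(probs), feats$labels, ignore_attr = TRUE)
  # objective invariant to sample order
  ord <- sample(length(X_list))
  fit2 <- mil_fit(X_list[ord], feats$labels[ord],
                  fast_opt(n_steps = 200, n_restarts = 32))
  expect_equal(fit2$training_loss, fit$training_loss, tolerance = 1e-9)
})

test_that("samples without motifs are rejected before fitting", {
  X_list <- list(matrix(rnorm(8), 2, 4), matrix(numeric(0), 0, 4))
  expect_error(mil_fit(X_list, c(1, 0), fast_opt(10, 2)), "without motifs")
})
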