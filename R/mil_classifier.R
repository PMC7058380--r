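# Logistic scoring of motifs, max aggregation to repertoire probabilities,
# and multi-restart full-batch Adam fitting of the MIL objective.

#' Optimizer settings for the MIL fit
#'
#' Full-batch Adam, run independently from `n_restarts` random
#' initializations; the restart with the lowest final training loss wins.
#' Defaults follow the published fitting protocol (2,500 iterations, step
#' size 0.01, b1 = 0.9, b2 = 0.999, epsilon = 1e-8) except for the
#' restart count, which defaults to 256 for desk use; 131,072 restarts
#' reproduce the full protocol at matching compute cost.
#'
#' @param step_size Adam learning rate.
#' @param n_steps Number of gradient steps.
#' @param b1,b2,epsilon Adam moment decay rates and stabilizer.
#' @param n_restarts Number of random initializations fitted in parallel.
#' @param seed Master seed for the initial parameter draws.
#' @return A `tcr_optimizer_config` list.
#' @export
optimizer_config <- function(step_size = 0.01, n_steps = 2500L,
                             b1 = 0.9, b2 = 0.999, epsilon = 1e-8,
                             n_restarts = 256L, seed = 1L) {
  stopifnot(step_size > 0, n_steps >= 1L, b1 > 0, b2 > 0, epsilon > 0,
            n_restarts >= 1L)
  structure(list(step_size = step_size, n_steps = as.integer(n_steps),
                 b1 = b1, b2 = b2, epsilon = epsilon,
                 n_restarts = as.integer(n_restarts),
                 seed = as.integer(seed)),
            class = "tcr_optimizer_config")
}

#' Score motifs with the logistic model
#'
#' Computes the logit `l_i = beta0 + sum_j beta_j f_ij` and the sigmoid
#' probability `P_i = 1 / (1 + exp(-l_i))` for each motif; numerically
#' stable for extreme logits via [stats::plogis()].
#'
#' @param features Numeric feature vector, or matrix with one motif per
#'   row (normalized features, without an intercept column).
#' @param params A `tcr_model_params` list with `bias` and `weights`, or
#'   a plain numeric vector `c(bias, weights)`.
#' @return Probability (vector, one per motif).
#' @export
score_motif <- function(features, params) {
  beta <- as_param_vector(params)
  if (is.null(dim(features))) features <- matrix(features, ncol = length(features))
  if (!all(is.finite(features))) stop("non-finite feature values",
                                      call. = FALSE)
  if (ncol(features) != length(beta) - 1L) {
    stop("feature length ", ncol(features), " does not match parameter ",
         "length ", length(beta) - 1L, call. = FALSE)
  }
  drop(stats::plogis(beta[1L] + features %*% beta[-1L]))
}

as_param_vector <- function(params) {
  if (inherits(params, "tcr_model_params") || is.list(params)) {
    beta <- c(params$bias, params$weights)
  } else {
    beta <- as.numeric(params)
  }
  if (!all(is.finite(beta))) stop("non-finite model parameters",
                                  call. = FALSE)
  beta
}

new_model_params <- function(beta) {
  structure(list(bias = beta[1L], weights = beta[-1L]),
            class = "tcr_model_params")
}

#' Aggregate motif probabilities into a repertoire score
#'
#' The repertoire probability is the maximum over its motif
#' probabilities: under the standard multiple-instance assumption a
#' repertoire is tumor-derived iff at least one motif is.
#'
#' @param motif_probs Numeric vector of per-motif probabilities.
#' @return The maximum probability; an empty input returns 0 with a
#'   warning.
#' @export
score_repertoire <- function(motif_probs) {
  if (length(motif_probs) == 0L) {
    warning("repertoire has no motifs; scoring 0", call. = FALSE)
    return(0)
  }
  stopifnot(all(motif_probs >= 0), all(motif_probs <= 1))
  max(motif_probs)
}

#' Threshold a repertoire score into a class label
#'
#' @param score Repertoire probability in `[0, 1]`.
#' @param threshold Decision threshold; a score equal to the threshold is
#'   called positive, so at 0.5 a repertoire is predicted tumor-derived
#'   when at least one motif reaches probability 0.5.
#' @return Integer label, 1 (tumor) or 0 (healthy).
#' @export
classify <- function(score, threshold = 0.5) {
  stopifnot(all(score >= 0), all(score <= 1))
  as.integer(score >= threshold)
}

#' Mean negative log-likelihood of repertoire predictions
#'
#' `-(1/n) * sum_j [y_j ln P_j + (1 - y_j) ln(1 - P_j)]` in nats, with
#' probabilities clipped to `[1e-12, 1 - 1e-12]` before the logarithm.
#'
#' @param predictions Predicted repertoire probabilities.
#' @param labels Binary labels.
#' @param bits Report in bits (divide by `ln 2`) instead of nats.
#' @return Non-negative mean loss.
#' @export
negative_log_likelihood <- function(predictions, labels, bits = FALSE) {
  if (length(predictions) != length(labels)) {
    stop("predictions and labels differ in length", call. = FALSE)
  }
  p <- pmin(pmax(predictions, 1e-12), 1 - 1e-12)
  nll <- -mean(labels * log(p) + (1 - labels) * log(1 - p))
  if (bits) nll / log(2) else nll
}

#' Draw random initial parameters for the restarts
#'
#' The bias is initialized to 0. Weights on the Atchley block (the first
#' `5 * motif_size` features) are drawn as `0.5 * N(0, 1/k)` with `k` the
#' block size, and all remaining weights (abundance term, gap indicators,
#' second-order terms) as `0.5 * N(0, 1)`: the summed contribution of the
#' Atchley block then has the same expected magnitude as the abundance
#' term. Draws are consumed restart by restart in fixed order, so the
#' initializations of the first `r` restarts do not depend on
#' `n_restarts`.
#'
#' @param feature_length Number of features (16 for the default
#'   configuration).
#' @param n_restarts Number of initializations to draw.
#' @param n_atchley Size of the Atchley block; defaults to
#'   `feature_length - 1`, i.e. all but the abundance term, which is
#'   correct for configurations without extra features.
#' @param seed Seed; `NULL` uses the current RNG state.
#' @param scheme `"variance"` reads the initialization spread as a
#'   variance of `1/k` (default; the reading under which the
#'   equal-expected-magnitude property holds); `"sd"` reads it as a
#'   standard deviation of `1/k`.
#' @return Numeric matrix `(1 + feature_length) x n_restarts`; row 1 is
#'   the bias.
#' @export
init_params <- function(feature_length, n_restarts = 1L,
                        n_atchley = feature_length - 1L, seed = NULL,
                        scheme = c("variance", "sd")) {
  scheme <- match.arg(scheme)
  stopifnot(feature_length >= 1L, n_atchley <= feature_length)
  if (!is.null(seed)) set.seed(seed)
  sd_atchley <- if (scheme == "variance") sqrt(1 / n_atchley) else 1 / n_atchley
  n_other <- feature_length - n_atchley
  B <- matrix(0, 1L + feature_length, n_restarts)
  for (r in seq_len(n_restarts)) {
    B[1L + seq_len(n_atchley), r] <- 0.5 * rnorm(n_atchley, 0, sd_atchley)
    if (n_other > 0L) {
      B[1L + n_atchley + seq_len(n_other), r] <- 0.5 * rnorm(n_other, 0, 1)
    }
  }
  B
}

# MIL objective and analytic subgradient, pure R. `beta` includes the
# bias; each element of X_list is a sample's motifs-by-features matrix
# WITHOUT intercept column. The max over motif sigmoids is the sigmoid of
# the max logit; only the argmax motif (lowest index on ties) receives
# gradient. Used by tests as the reference for the compiled kernel.
mil_loss_grad <- function(beta, X_list, labels, clip = 1e-12) {
  n <- length(X_list)
  d <- length(beta)
  grad <- numeric(d)
  loss <- 0
  for (j in seq_len(n)) {
    l <- beta[1L] + drop(X_list[[j]] %*% beta[-1L])
    a <- which.max(l)
    p <- stats::plogis(l[a])
    pc <- min(max(p, clip), 1 - clip)
    y <- labels[j]
    loss <- loss - (y * log(pc) + (1 - y) * log(1 - pc))
    grad <- grad + (p - y) * c(1, X_list[[j]][a, ])
  }
  list(loss = loss / n, grad = grad / n)
}

#' Fit the MIL logistic model by multi-restart Adam
#'
#' Minimizes the mean negative log-likelihood of the max-aggregated
#' repertoire predictions by full-batch Adam, independently from each
#' random initialization, and returns the restart with the lowest final
#' training loss (ties to the lowest restart index). The max is
#' non-smooth; each step propagates a straight-through subgradient to the
#' argmax motif of each sample only, with ties broken by the lowest motif
#' index. All restarts are batched through one compiled kernel and the
#' result is bit-reproducible given the seed.
#'
#' @param X_list List of per-sample normalized feature matrices (motifs x
#'   features), one per repertoire; every sample must have at least one
#'   motif.
#' @param labels Binary labels, one per sample.
#' @param opt An [optimizer_config()].
#' @param init Optional `(1 + n_features) x n_restarts` matrix of initial
#'   parameters (e.g. to share initializations across cross-validation
#'   folds); drawn via [init_params()] with `opt$seed` when `NULL`.
#' @param X_heldout Optional feature matrix of a held-out sample; its
#'   max-logit trajectory is tracked after every step for early-stopping
#'   analysis.
#' @return A `tcr_fit_result`: `params` (best restart), `restart_index`,
#'   `training_loss`, `loss_by_step` (training loss of the best restart
#'   after each step), `final_losses` (all restarts) and, when
#'   `X_heldout` is given, `heldout_prob_by_step`.
#' @export
mil_fit <- function(X_list, labels, opt = optimizer_config(), init = NULL,
                    X_heldout = NULL) {
  n <- length(X_list)
  stopifnot(n >= 1L, length(labels) == n, all(labels %in% c(0, 1)))
  sizes <- vapply(X_list, nrow, integer(1))
  if (any(sizes == 0L)) {
    stop("sample(s) without motifs cannot be fitted: index ",
         paste(which(sizes == 0L), collapse = ", "), call. = FALSE)
  }
  d <- ncol(X_list[[1L]])
  X <- do.call(rbind, X_list)
  if (is.null(init)) {
    init <- init_params(d, opt$n_restarts, seed = opt$seed)
  }
  stopifnot(nrow(init) == d + 1L)
  grp <- rep.int(seq_len(n) - 1L, sizes)
  has_heldout <- !is.null(X_heldout) && nrow(X_heldout) > 0L
  Xh <- if (has_heldout) cbind(1, X_heldout) else matrix(0, 0L, d + 1L)
  res <- cpp_mil_fit(cbind(1, X), grp, n, as.numeric(labels), init,
                     opt$n_steps, opt$step_size, opt$b1, opt$b2,
                     opt$epsilon, Xh, has_heldout, 1e-12)
  final <- res$loss_by_step[opt$n_steps, ]
  ok <- is.finite(final)
  if (!all(ok)) {
    warning(sum(!ok), " restart(s) diverged to non-finite loss and were ",
            "excluded", call. = FALSE)
    if (!any(ok)) stop("all restarts produced non-finite loss",
                       call. = FALSE)
    final[!ok] <- Inf
  }
  best <- which.min(final)
  out <- list(params = new_model_params(res$B[, best]),
              restart_index = best,
              training_loss = final[best],
              loss_by_step = res$loss_by_step[, best],
              final_losses = res$loss_by_step[opt$n_steps, ],
              n_samples = n, opt = opt)
  if (has_heldout) {
    out$heldout_prob_by_step <- stats::plogis(res$heldout_logit_by_step[, best])
  }
  class(out) <- "tcr_fit_result"
  out
}

#' @export
print.tcr_fit_result <- function(x, ...) {
  cat(sprintf(paste0("<tcr_fit_result> %d samples, best of %d restart(s): ",
                     "training loss %.4f nats (restart %d)\n"),
              x$n_samples, length(x$final_losses), x$training_loss,
              x$restart_index))
  invisible(x)
}
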