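# Motif -> numeric feature vectors (Atchley factors + relative abundance)
# and abundance-weighted standardization.

#' Number of features implied by a configuration
#'
#' Five Atchley factors per motif residue, one abundance term, optional
#' gap one-hot indicators (one per motif position) and, with
#' `second_order`, a squared copy of every preceding feature.
#'
#' @param config A [model_config()].
#' @return Integer feature count (16 for the default configuration).
#' @export
n_features <- function(config = model_config()) {
  n <- 5L * config$motif_size + 1L +
    (if (config$gap_onehot) config$motif_size else 0L)
  if (config$second_order) n <- 2L * n
  n
}

feature_names <- function(config = model_config()) {
  nm <- c(paste0("f", seq_len(5L * config$motif_size)), "fq")
  if (config$gap_onehot) nm <- c(nm, paste0("gap", seq_len(config$motif_size)))
  if (config$second_order) nm <- c(nm, paste0(nm, "_sq"))
  nm
}

#' Encode a single motif as a feature vector
#'
#' Concatenation order is fixed: residue 1 factors F1-F5, residue 2
#' factors F1-F5, ... , then the abundance term (`f_q`, or `ln f_q` with
#' `log_frequency`), then optional gap indicators and squared copies.
#'
#' @param residues Motif residue string of length `motif_size`.
#' @param f_q Relative abundance in (0, 1].
#' @param config A [model_config()].
#' @param gap_pattern Comma-separated skipped motif positions (`""` for a
#'   contiguous motif); only used when `gap_onehot` is on.
#' @return Named numeric feature vector.
#' @export
encode_motif <- function(residues, f_q, config = model_config(),
                         gap_pattern = "") {
  stopifnot(nchar(residues) == config$motif_size, f_q > 0, f_q <= 1)
  at <- atchley_factors()
  chars <- strsplit(residues, "", fixed = TRUE)[[1L]]
  v <- as.numeric(t(at[chars, , drop = FALSE]))
  v <- c(v, if (config$log_frequency) log(f_q) else f_q)
  if (config$gap_onehot) {
    onehot <- numeric(config$motif_size)
    if (nzchar(gap_pattern)) {
      pos <- as.integer(strsplit(gap_pattern, ",", fixed = TRUE)[[1L]])
      onehot[pos] <- 1
    }
    v <- c(v, onehot)
  }
  if (config$second_order) v <- c(v, v^2)
  setNames(v, feature_names(config))
}

#' Encode all motifs of a table as a feature matrix
#'
#' @param table A `tcr_motif_table`.
#' @param config A [model_config()].
#' @return Numeric matrix (motifs x features, rownames = motif keys) with
#'   attribute `weights` holding each motif's `f_q` (used for weighted
#'   normalization and as each motif's influence on pooled statistics).
#' @export
encode_motif_table <- function(table, config = model_config()) {
  check_config_supported(config)
  mot <- table$motifs
  at <- atchley_factors()
  n <- nrow(mot)
  if (n == 0L) {
    X <- matrix(numeric(0), 0L, n_features(config),
                dimnames = list(NULL, feature_names(config)))
    attr(X, "weights") <- numeric(0)
    return(X)
  }
  size <- config$motif_size
  # residue-position-major Atchley block, vectorized over motifs
  chars <- matrix(unlist(strsplit(mot$residues, "", fixed = TRUE)),
                  nrow = size)
  blocks <- lapply(seq_len(size), function(p) at[chars[p, ], , drop = FALSE])
  X <- do.call(cbind, blocks)
  fq <- mot$rel_abundance
  X <- cbind(X, if (config$log_frequency) log(fq) else fq)
  if (config$gap_onehot) {
    onehot <- matrix(0, n, size)
    has <- nzchar(mot$gap_pattern)
    if (any(has)) {
      pos_list <- strsplit(mot$gap_pattern[has], ",", fixed = TRUE)
      ii <- rep(which(has), lengths(pos_list))
      onehot[cbind(ii, as.integer(unlist(pos_list)))] <- 1
    }
    X <- cbind(X, onehot)
  }
  if (config$second_order) X <- cbind(X, X^2)
  dimnames(X) <- list(mot$key, feature_names(config))
  attr(X, "weights") <- fq
  X
}

#' Fit abundance-weighted normalization statistics
#'
#' Per feature j, `mean_j = sum(w_i v_ij) / sum(w_i)` and
#' `var_j = sum(w_i (v_ij - mean_j)^2) / sum(w_i)`; the variance is
#' floored at `1e-8` so constant features (e.g. a one-hot column that
#' never fires) do not divide by zero. In the classification pipeline the
#' weights are the motifs' relative abundances `f_q`, so frequent motifs
#' dominate the statistics and each sample contributes total weight ~1.
#'
#' @param x Numeric matrix (observations x features) or list of such
#'   matrices (pooled by row-binding).
#' @param weights Positive weights, one per row of `x`; defaults to the
#'   `weights` attribute set by [encode_motif_table()].
#' @return A `tcr_norm_stats` list with `mean`, `var` and `floor`.
#' @export
fit_normalizer <- function(x, weights = NULL) {
  if (is.list(x) && !is.matrix(x)) {
    if (is.null(weights)) {
      weights <- unlist(lapply(x, function(m) attr(m, "weights")))
    }
    x <- do.call(rbind, x)
  }
  if (is.null(weights)) weights <- attr(x, "weights")
  if (is.null(dim(x))) x <- matrix(x, ncol = 1L)
  if (nrow(x) == 0L) stop("cannot fit normalizer on empty input",
                          call. = FALSE)
  if (is.null(weights)) weights <- rep(1, nrow(x))
  stopifnot(length(weights) == nrow(x), all(weights > 0))
  w <- weights / sum(weights)
  mu <- colSums(x * w)
  va <- colSums((x - matrix(mu, nrow(x), ncol(x), byrow = TRUE))^2 * w)
  floor_ <- 1e-8
  structure(list(mean = mu, var = pmax(va, floor_), floor = floor_),
            class = "tcr_norm_stats")
}

#' Standardize feature vectors with fitted statistics
#'
#' `z_j = (v_j - mean_j) / sqrt(var_j)`. Statistics fitted on the pooled
#' training samples are frozen and reused for held-out and test samples,
#' so no information leaks from evaluation data.
#'
#' @param x Numeric matrix or vector with the same feature length as the
#'   fitted statistics.
#' @param stats A `tcr_norm_stats` from [fit_normalizer()].
#' @return Standardized matrix (weights attribute preserved).
#' @export
apply_normalizer <- function(x, stats) {
  stopifnot(inherits(stats, "tcr_norm_stats"))
  vec <- is.null(dim(x))
  if (vec) x <- matrix(x, ncol = length(x))
  if (ncol(x) != length(stats$mean)) {
    stop("feature length ", ncol(x), " does not match fitted statistics (",
         length(stats$mean), ")", call. = FALSE)
  }
  z <- sweep(sweep(x, 2L, stats$mean, "-"), 2L, sqrt(stats$var), "/")
  if (vec) return(drop(z))
  attr(z, "weights") <- attr(x, "weights")
  z
}
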