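# Independent oracles and tiny fixtures, built in code.

AA <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]

random_cdr3 <- function(len) {
  paste(sample(AA, len, replace = TRUE), collapse = "")
}

# Brute-force motif oracle: all strictly increasing index tuples of
# `size` positions inside the trimmed string whose span implies at most
# `gaps` skipped interior residues (span - size <= gaps). Returns the
# multiset of residue strings (one per tuple).
naive_motifs <- function(cdr3, size, gaps) {
  m <- nchar(cdr3) - 6L
  if (m < size) return(character(0))
  chars <- strsplit(substr(cdr3, 4, nchar(cdr3) - 3), "")[[1]]
  ix <- utils::combn(seq_len(m), size)
  ix <- ix[, (ix[size, ] - ix[1, ] + 1L) - size <= gaps, drop = FALSE]
  if (ncol(ix) == 0) return(character(0))
  apply(ix, 2, function(t) paste(chars[t], collapse = ""))
}

# Direct-summation weighted moments.
naive_weighted_stats <- function(X, w) {
  w <- w / sum(w)
  mu <- apply(X, 2, function(col) sum(col * w))
  va <- vapply(seq_len(ncol(X)), function(j) sum(w * (X[, j] - mu[j])^2),
               numeric(1))
  list(mean = mu, var = va)
}

# Plain-R single-restart Adam on the MIL objective; reference for the
# compiled kernel. Returns the parameter vector after n_steps updates
# and the post-update loss trajectory.
reference_adam <- function(beta0, X_list, y, n_steps, lr = 0.01,
                           b1 = 0.9, b2 = 0.999, eps = 1e-8) {
  beta <- beta0
  m <- v <- numeric(length(beta))
  losses <- numeric(n_steps)
  lg <- function(beta) tcrmil:::mil_loss_grad(beta, X_list, y)
  for (t in seq_len(n_steps)) {
    g <- lg(beta)$grad
    m <- b1 * m + (1 - b1) * g
    v <- b2 * v + (1 - b2) * g^2
    beta <- beta - lr * (m / (1 - b1^t)) / (sqrt(v / (1 - b2^t)) + eps)
    losses[t] <- lg(beta)$loss
  }
  list(beta = beta, loss_by_step = losses)
}

# A tiny separable cohort: positives carry boosted CDR3s with planted
# interior triplets; all background counts are 1, so the planted motifs'
# relative abundance alone separates the classes even at this scale.
tiny_separable_cohort <- function(n_pos = 3, n_neg = 3, seed = 42,
                                  id_prefix = NULL) {
  gen <- generate_cohort(synthetic_spec(
    n_pos = n_pos, n_neg = n_neg, seqs_per_sample = 8,
    n_planted_per_pos = 2, planted_count_boost = 10, count_mean = 1,
    seed = seed))
  if (!is.null(id_prefix)) {
    gen$cohort$repertoires <- lapply(gen$cohort$repertoires, function(r) {
      r$sample_id <- paste0(id_prefix, r$sample_id)
      r
    })
  }
  gen
}

fast_opt <- function(n_steps = 150, n_restarts = 16, seed = 1) {
  optimizer_config(n_steps = n_steps, n_restarts = n_restarts, seed = seed)
}

write_tsv_fixture <- function(df, path = tempfile(fileext = ".tsv")) {
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}
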