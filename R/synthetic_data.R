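# Synthetic labeled repertoires with planted biophysicochemical motifs.
#
# Background CDR3s are drawn residue-wise between conserved "CAS"/"QYF"
# ends and rejection-resampled so that none of their extractable motifs
# equals a planted triplet. Positive samples additionally carry a few
# sequences whose interior contains a planted triplet with boosted
# template counts, giving a separable multiple-instance signal with known
# ground truth.

#' Specification of a synthetic cohort
#'
#' Defaults emulate the study design the package targets: two balanced
#' classes of 10 samples each, CDR3 lengths in the range typical of TCRB
#' junctions, geometric template counts, and a handful of planted
#' sequences per positive sample whose triplets share similar Atchley
#' profiles (acid/base residue, aromatic, aromatic-or-basic) and carry
#' boosted counts. Repertoire sizes are kept small so that fitting,
#' cross-validation and permutation analyses run in seconds to minutes.
#'
#' @param n_pos,n_neg Positive (tumor-like) and negative sample counts.
#' @param seqs_per_sample Unique CDR3s per sample (including planted).
#' @param length_distribution Named probability vector over CDR3 lengths
#'   (names = lengths, 9-25); default uniform over 12-16.
#' @param residue_frequencies Named 20-vector of background residue
#'   probabilities; default uniform.
#' @param planted_triplets Character vector of 3-mers planted in positive
#'   samples; must be absent (by rejection) from all background
#'   sequences.
#' @param n_planted_per_pos Planted sequences per positive sample.
#' @param planted_count_boost Multiplier applied to the template counts
#'   of planted sequences (>= 1).
#' @param count_mean Mean of the geometric template-count distribution on
#'   \{1, 2, ...\}.
#' @param gap_check Gap allowance used when rejecting background
#'   sequences containing a planted triplet; matches the default model.
#' @param sample_prefix Prefix for generated sample ids, so cohorts
#'   generated for train and test roles stay disjoint.
#' @param seed Seed making generation bit-reproducible.
#' @return A `tcr_synthetic_spec` list.
#' @export
synthetic_spec <- function(n_pos = 10L, n_neg = 10L,
                           seqs_per_sample = 20L,
                           length_distribution = NULL,
                           residue_frequencies = NULL,
                           planted_triplets = c("KWH", "EWH", "KYH"),
                           n_planted_per_pos = 3L,
                           planted_count_boost = 10L,
                           count_mean = 3,
                           gap_check = 1L,
                           sample_prefix = "",
                           seed = 0L) {
  if (is.null(length_distribution)) {
    length_distribution <- setNames(rep(1 / 5, 5), 12:16)
  }
  lens <- as.integer(names(length_distribution))
  stopifnot(all(lens >= 9L), all(lens <= 25L),
            abs(sum(length_distribution) - 1) < 1e-9)
  if (is.null(residue_frequencies)) {
    residue_frequencies <- setNames(rep(1 / 20, 20), AA_ALPHABET)
  }
  stopifnot(identical(sort(names(residue_frequencies)), AA_ALPHABET),
            abs(sum(residue_frequencies) - 1) < 1e-9)
  if (length(planted_triplets) > 0L) {
    stopifnot(all(nchar(planted_triplets) == 3L),
              all(is_canonical_aa(planted_triplets)))
  }
  stopifnot(n_pos >= 0L, n_neg >= 0L, seqs_per_sample >= 1L,
            n_planted_per_pos >= 0L, planted_count_boost >= 1,
            count_mean >= 1)
  structure(list(n_pos = as.integer(n_pos), n_neg = as.integer(n_neg),
                 seqs_per_sample = as.integer(seqs_per_sample),
                 length_distribution = length_distribution,
                 residue_frequencies =
                   residue_frequencies[AA_ALPHABET],
                 planted_triplets = planted_triplets,
                 n_planted_per_pos = as.integer(n_planted_per_pos),
                 planted_count_boost = planted_count_boost,
                 count_mean = count_mean,
                 gap_check = as.integer(gap_check),
                 sample_prefix = as.character(sample_prefix),
                 seed = as.integer(seed)),
            class = "tcr_synthetic_spec")
}

# One background CDR3 free of planted triplets (under the gap_check
# allowance), or error after bounded retries.
sample_background_cdr3 <- function(spec, check_config, max_tries = 100L) {
  lens <- as.integer(names(spec$length_distribution))
  for (i in seq_len(max_tries)) {
    L <- sample(lens, 1L, prob = spec$length_distribution)
    interior <- paste(sample(AA_ALPHABET, L - 6L, replace = TRUE,
                             prob = spec$residue_frequencies),
                      collapse = "")
    cdr3 <- paste0("CAS", interior, "QYF")
    if (length(spec$planted_triplets) == 0L) return(cdr3)
    occ <- extract_motifs(cdr3, check_config)
    if (!any(occ$residues %in% spec$planted_triplets)) return(cdr3)
  }
  stop("could not generate a background CDR3 free of planted triplets ",
       "after ", max_tries, " tries; try different planted_triplets",
       call. = FALSE)
}

sample_counts <- function(n, mean) {
  if (mean <= 1) return(rep(1L, n))
  1L + stats::rgeom(n, prob = 1 / mean)
}

#' Generate a labeled synthetic cohort with ground truth
#'
#' Negative samples hold background CDR3s only; rejection sampling
#' guarantees that no planted triplet is extractable from any of their
#' sequences. Positive samples hold the same kind of background plus
#' `n_planted_per_pos` sequences whose interior (at least three residues
#' from each end, so end-trimming never removes it) carries a planted
#' triplet, with template counts multiplied by `planted_count_boost`.
#' Deterministic given `spec$seed`.
#'
#' @param spec A [synthetic_spec()].
#' @return List with `cohort` (a `tcr_cohort`; positives first, labeled
#'   1) and `truth` (a `tcr_ground_truth`: data frame `planted` with
#'   sample_id, cdr3, triplet; `centroid`, the 15-dimensional Atchley
#'   centroid of the planted triplets).
#' @export
generate_cohort <- function(spec = synthetic_spec()) {
  stopifnot(inherits(spec, "tcr_synthetic_spec"))
  set.seed(spec$seed)
  check_config <- model_config(motif_size = 3L,
                               n_gap_positions = spec$gap_check)
  reps <- list()
  planted_rows <- list()
  make_sample <- function(sample_id, label, n_planted) {
    n_bg <- spec$seqs_per_sample - n_planted
    seqs <- character(0)
    while (length(seqs) < n_bg) {
      cand <- sample_background_cdr3(spec, check_config)
      if (!cand %in% seqs) seqs <- c(seqs, cand)
    }
    counts <- sample_counts(length(seqs), spec$count_mean)
    if (n_planted > 0L) {
      pl_seqs <- character(0)
      pl_trip <- character(0)
      while (length(pl_seqs) < n_planted) {
        base <- sample_background_cdr3(spec, check_config)
        trip <- sample(spec$planted_triplets, 1L)
        L <- nchar(base)
        start <- sample(4:(L - 5L), 1L)  # triplet stays inside the trimmed region
        cand <- paste0(substr(base, 1L, start - 1L), trip,
                       substr(base, start + 3L, L))
        if (!cand %in% c(seqs, pl_seqs)) {
          pl_seqs <- c(pl_seqs, cand)
          pl_trip <- c(pl_trip, trip)
        }
      }
      pl_counts <- as.integer(sample_counts(n_planted, spec$count_mean) *
                                spec$planted_count_boost)
      planted_rows[[length(planted_rows) + 1L]] <<-
        data.frame(sample_id = sample_id, cdr3 = pl_seqs,
                   triplet = pl_trip, stringsAsFactors = FALSE)
      seqs <- c(seqs, pl_seqs)
      counts <- c(counts, pl_counts)
    }
    repertoire(sample_id, label, seqs, counts)
  }
  for (i in seq_len(spec$n_pos)) {
    reps[[length(reps) + 1L]] <-
      make_sample(sprintf("%spos_%02d", spec$sample_prefix, i), 1L,
                  spec$n_planted_per_pos)
  }
  for (i in seq_len(spec$n_neg)) {
    reps[[length(reps) + 1L]] <-
      make_sample(sprintf("%sneg_%02d", spec$sample_prefix, i), 0L, 0L)
  }
  centroid <- if (length(spec$planted_triplets) > 0L) {
    trip_feats <- t(vapply(spec$planted_triplets, function(tr) {
      chars <- strsplit(tr, "", fixed = TRUE)[[1L]]
      as.numeric(t(atchley_factors()[chars, , drop = FALSE]))
    }, numeric(15)))
    colMeans(trip_feats)
  } else numeric(0)
  truth <- structure(
    list(planted = if (length(planted_rows)) do.call(rbind, planted_rows)
         else data.frame(sample_id = character(0), cdr3 = character(0),
                         triplet = character(0), stringsAsFactors = FALSE),
         centroid = centroid,
         spec = spec),
    class = "tcr_ground_truth")
  list(cohort = cohort(reps, name = sprintf("synthetic_seed%d", spec$seed)),
       truth = truth)
}

#' Write a cohort as AIRR Rearrangement TSVs plus a manifest
#'
#' One file per sample with columns `junction_aa` and `duplicate_count`,
#' and a `manifest.csv` (`path`, `dialect`, `label`, `sample_id`) so
#' synthetic data exercises the real I/O path end to end.
#'
#' @param cohort A `tcr_cohort`.
#' @param dir Output directory (created if needed).
#' @return Path to the manifest, invisibly.
#' @export
export_cohort_airr <- function(cohort, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  rows <- lapply(cohort$repertoires, function(r) {
    path <- file.path(dir, paste0(r$sample_id, ".tsv"))
    write.table(data.frame(junction_aa = r$records$cdr3_aa,
                           duplicate_count = r$records$template_count),
                path, sep = "\t", quote = FALSE, row.names = FALSE)
    data.frame(path = path, dialect = "airr", label = r$label,
               sample_id = r$sample_id, stringsAsFactors = FALSE)
  })
  manifest <- file.path(dir, "manifest.csv")
  write.table(do.call(rbind, rows), manifest, sep = ",", quote = FALSE,
              row.names = FALSE)
  invisible(manifest)
}

#' Report how well a fitted model recovers planted motifs
#'
#' Scores every motif of every sample with a fitted model, lists all
#' motifs with probability >= 0.5 in the context of their source CDR3s
#' and counts, and reports the fraction of positive samples whose
#' top-scoring motif is one of the planted triplets (the hit rate).
#'
#' @param model A `tcr_mil_model` from [fit_repertoire_model()] or
#'   [refit_and_score_test()].
#' @param cohort The `tcr_cohort` to examine.
#' @param truth A `tcr_ground_truth` from [generate_cohort()].
#' Because motifs overlap, a gapped variant sharing two residues with a
#' planted triplet (and the same boosted abundance, since it comes from
#' the same CDR3) can edge out the exact triplet by a hair; the report
#' therefore also records whether each top motif occurs within a planted
#' CDR3 (`hit_rate_context`), separating "found the planted signal" from
#' "ranked the exact triplet first".
#'
#' @return A `tcr_recovery_report`: `high_scoring` data frame
#'   (sample_id, motif, cdr3, count, probability, planted), `top_motif`
#'   per-sample data frame (with `in_planted_cdr3`), `hit_rate` (exact
#'   planted triplet on top) and `hit_rate_context` (top motif extracted
#'   from a planted CDR3).
#' @export
recovery_report <- function(model, cohort, truth) {
  stopifnot(inherits(model, "tcr_mil_model"),
            inherits(truth, "tcr_ground_truth"))
  config <- model$config
  planted <- unique(truth$planted$triplet)
  high <- list()
  top <- list()
  for (r in cohort$repertoires) {
    tab <- build_motif_table(r, config)
    X <- encode_motif_table(tab, config)
    if (nrow(X) == 0L) next
    Xn <- apply_normalizer(X, model$norm_stats)
    probs <- score_motif(Xn, model$params)
    best <- which.max(probs)
    own_planted <- truth$planted$cdr3[truth$planted$sample_id == r$sample_id]
    in_context <- any(vapply(own_planted, function(cd) {
      tab$motifs$key[best] %in%
        with(extract_motifs(cd, config), motif_key(residues, gap_pattern,
                                                   config))
    }, logical(1)))
    top[[length(top) + 1L]] <- data.frame(
      sample_id = r$sample_id, label = r$label,
      motif = tab$motifs$residues[best],
      probability = unname(probs[best]),
      planted = tab$motifs$residues[best] %in% planted,
      in_planted_cdr3 = in_context,
      stringsAsFactors = FALSE)
    hits <- which(probs >= 0.5)
    for (h in hits) {
      residues <- tab$motifs$residues[h]
      contains <- vapply(seq_len(nrow(r$records)), function(i) {
        occ <- extract_motifs(r$records$cdr3_aa[i], config)
        any(motif_key(occ$residues, occ$gap_pattern, config) ==
              tab$motifs$key[h])
      }, logical(1))
      high[[length(high) + 1L]] <- data.frame(
        sample_id = r$sample_id, motif = residues,
        cdr3 = r$records$cdr3_aa[contains],
        count = r$records$template_count[contains],
        probability = unname(probs[h]),
        planted = residues %in% planted,
        stringsAsFactors = FALSE)
    }
  }
  top_df <- if (length(top)) do.call(rbind, top) else
    data.frame(sample_id = character(0), label = integer(0),
               motif = character(0), probability = numeric(0),
               planted = logical(0), in_planted_cdr3 = logical(0),
               stringsAsFactors = FALSE)
  pos <- top_df$label == 1L
  structure(list(
    high_scoring = if (length(high)) do.call(rbind, high) else
      data.frame(sample_id = character(0), motif = character(0),
                 cdr3 = character(0), count = integer(0),
                 probability = numeric(0), planted = logical(0),
                 stringsAsFactors = FALSE),
    top_motif = top_df,
    hit_rate = if (any(pos)) mean(top_df$planted[pos]) else NA_real_,
    hit_rate_context = if (any(pos)) mean(top_df$in_planted_cdr3[pos])
    else NA_real_),
    class = "tcr_recovery_report")
}

#' @export
print.tcr_recovery_report <- function(x, ...) {
  cat(sprintf(paste0("<tcr_recovery_report> %d high-scoring motif/CDR3 ",
                     "pairs; planted-triplet hit rate %.2f\n"),
              nrow(x$high_scoring), x$hit_rate))
  invisible(x)
}
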