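# Gapped/contiguous motif enumeration and template-weighted counting.
#
# A motif is a short in-order subsequence (3 or 4 residues) of the CDR3
# after removing the first and last three residues, which rarely contact
# peptide. Gapped motifs skip up to `n_gap_positions` interior residues of
# a contiguous window; the first and last residue of the window are never
# skipped (a skip there would just shift the window).

#' Model configuration
#'
#' Collects the switches that define the motif representation and feature
#' set. The default (`motif_size = 3`, `n_gap_positions = 1`, raw
#' relative-abundance feature, triplet-only motif identity) is the
#' best-performing configuration for HGSOC repertoires.
#'
#' @param motif_size Number of residues per motif, 3 or 4.
#' @param n_gap_positions Maximum number of interior residues that may be
#'   skipped when assembling a motif (0-3); `g` skips are taken from a
#'   contiguous window of `motif_size + g` residues.
#' @param gap_onehot Add binary indicator features marking, per motif
#'   position, whether the CDR3 residue that would have occupied it was
#'   skipped. Forces `key_includes_gap = TRUE` because motifs with
#'   different gap patterns then carry different features.
#' @param restrict_gap_to_position If set, only skips whose skipped
#'   residue would occupy this motif position (1..`motif_size`) are
#'   allowed; contiguous motifs are always emitted.
#' @param use_blood_frequency Expected motif frequency in healthy blood as
#'   an extra feature. Not implemented (needs an external cohort); the
#'   flag exists so grid configurations can be declared and skipped.
#' @param log_frequency Use `ln(f_q)` instead of `f_q` as the abundance
#'   feature.
#' @param second_order Square every feature and append the squares.
#' @param batch_norm Batch-normalization model variant. Not implemented.
#' @param key_includes_gap Key motifs by (residues, gap pattern) instead
#'   of residues alone. With the default `FALSE`, a triplet reachable both
#'   contiguously and via a gap is a single motif: the features of that
#'   configuration encode only the residues and abundance, so separate
#'   keys would be indistinguishable to the classifier.
#' @param top_k Per-sample cap on the number of motifs kept (most
#'   abundant first); a runtime bound, not a probability model change.
#' @return A `tcr_model_config` list.
#' @export
model_config <- function(motif_size = 3L, n_gap_positions = 1L,
                         gap_onehot = FALSE,
                         restrict_gap_to_position = NULL,
                         use_blood_frequency = FALSE,
                         log_frequency = FALSE,
                         second_order = FALSE,
                         batch_norm = FALSE,
                         key_includes_gap = gap_onehot,
                         top_k = 65536L) {
  motif_size <- as.integer(motif_size)
  n_gap_positions <- as.integer(n_gap_positions)
  stopifnot(motif_size %in% c(3L, 4L), n_gap_positions %in% 0:3,
            top_k >= 1L)
  if (!is.null(restrict_gap_to_position)) {
    restrict_gap_to_position <- as.integer(restrict_gap_to_position)
    stopifnot(restrict_gap_to_position >= 1L,
              restrict_gap_to_position <= motif_size)
  }
  if (gap_onehot && !key_includes_gap) {
    stop("gap_onehot requires key_includes_gap = TRUE", call. = FALSE)
  }
  structure(
    list(motif_size = motif_size,
         n_gap_positions = n_gap_positions,
         gap_onehot = isTRUE(gap_onehot),
         restrict_gap_to_position = restrict_gap_to_position,
         use_blood_frequency = isTRUE(use_blood_frequency),
         log_frequency = isTRUE(log_frequency),
         second_order = isTRUE(second_order),
         batch_norm = isTRUE(batch_norm),
         key_includes_gap = isTRUE(key_includes_gap),
         top_k = as.integer(top_k)),
    class = "tcr_model_config")
}

# Stop if a configuration requests a feature the package does not provide.
check_config_supported <- function(config) {
  if (config$use_blood_frequency) {
    stop("use_blood_frequency is not implemented (requires an external ",
         "healthy-blood reference cohort)", call. = FALSE)
  }
  if (config$batch_norm) {
    stop("batch_norm model variant is not implemented", call. = FALSE)
  }
  invisible(config)
}

#' Enumerate motif occurrences in one CDR3
#'
#' The first and last three CDR3 residues are removed; every contiguous
#' window of `motif_size` residues of the remainder is a motif, and, when
#' gaps are allowed, every in-order subsequence obtained from a window of
#' `motif_size + g` residues (1 <= g <= `n_gap_positions`) by skipping
#' exactly `g` interior residues. Coordinates are 0-based half-open within
#' the trimmed CDR3.
#'
#' @param cdr3 A canonical CDR3 amino-acid string.
#' @param config A [model_config()].
#' @return Data frame with one row per occurrence: `residues`,
#'   `gap_pattern` (comma-separated motif positions whose would-be residue
#'   was skipped, `""` for contiguous), `start`, `end`. CDR3s shorter than
#'   `motif_size + 6` yield zero rows.
#' @export
extract_motifs <- function(cdr3, config = model_config()) {
  stopifnot(is.character(cdr3), length(cdr3) == 1L)
  if (!is_canonical_aa(cdr3)) {
    stop("CDR3 contains non-canonical residues: ", cdr3, call. = FALSE)
  }
  size <- config$motif_size
  m <- nchar(cdr3) - 6L
  out_res <- character(0)
  out_gap <- character(0)
  out_start <- integer(0)
  out_end <- integer(0)
  if (m >= size) {
    chars <- strsplit(substr(cdr3, 4L, nchar(cdr3) - 3L), "", fixed = TRUE)[[1L]]
    for (g in 0:config$n_gap_positions) {
      wlen <- size + g
      nw <- m - wlen + 1L
      if (nw < 1L) break
      combos <- if (g == 0L) list(integer(0)) else
        utils::combn(2:(wlen - 1L), g, simplify = FALSE)
      for (skip in combos) {
        kept <- setdiff(seq_len(wlen), skip)
        # motif position each skipped residue would have occupied:
        # one past the number of kept residues before it
        gap_pos <- vapply(skip, function(q) sum(kept < q) + 1L, integer(1))
        if (!is.null(config$restrict_gap_to_position) && g > 0L &&
            !all(gap_pos == config$restrict_gap_to_position)) next
        gap_str <- paste(gap_pos, collapse = ",")
        for (s in seq_len(nw)) {
          out_res <- c(out_res, paste(chars[s - 1L + kept], collapse = ""))
          out_gap <- c(out_gap, gap_str)
          out_start <- c(out_start, s - 1L)
          out_end <- c(out_end, s - 1L + wlen)
        }
      }
    }
  }
  data.frame(residues = out_res, gap_pattern = out_gap,
             start = out_start, end = out_end, stringsAsFactors = FALSE)
}

motif_key <- function(residues, gap_pattern, config) {
  if (config$key_includes_gap) {
    ifelse(gap_pattern == "", residues,
           paste0(residues, "|", gap_pattern))
  } else {
    residues
  }
}

#' Count motifs in a repertoire
#'
#' For each motif key, the count `C^motif` is the sum of template counts
#' `C^CDR3` over the unique CDR3 sequences that contain the motif at least
#' once — containment is boolean per sequence, so a CDR3 harboring the
#' same motif at several positions contributes its count once. The total
#' `T` sums `C^motif` over all keys, and each motif's relative abundance
#' is `f_q = C^motif / T`. The per-sample `top_k` cap of the
#' configuration is applied after abundances are computed (see
#' [truncate_top_k()]).
#'
#' @param rep A `tcr_repertoire`.
#' @param config A [model_config()].
#' @param apply_top_k Apply the configuration's per-sample motif cap.
#' @return A `tcr_motif_table`: list with `sample_id`, `motifs` (data
#'   frame `key`, `residues`, `gap_pattern`, `count`, `rel_abundance`,
#'   sorted by key) and `total`.
#' @export
build_motif_table <- function(rep, config = model_config(),
                              apply_top_k = TRUE) {
  check_config_supported(config)
  stopifnot(inherits(rep, "tcr_repertoire"), nrow(rep$records) > 0L)
  keys <- character(0); res <- character(0); gaps <- character(0)
  counts <- integer(0)
  for (i in seq_len(nrow(rep$records))) {
    occ <- extract_motifs(rep$records$cdr3_aa[i], config)
    if (nrow(occ) == 0L) next
    k <- motif_key(occ$residues, occ$gap_pattern, config)
    first <- !duplicated(k)
    keys <- c(keys, k[first])
    res <- c(res, occ$residues[first])
    gaps <- c(gaps, occ$gap_pattern[first])
    counts <- c(counts, rep.int(rep$records$template_count[i], sum(first)))
  }
  if (length(keys) == 0L) {
    warning("no motifs extractable from sample ", rep$sample_id,
            " (all CDR3s too short)", call. = FALSE)
    tab <- structure(
      list(sample_id = rep$sample_id,
           motifs = data.frame(key = character(0), residues = character(0),
                               gap_pattern = character(0), count = integer(0),
                               rel_abundance = numeric(0),
                               stringsAsFactors = FALSE),
           total = 0L),
      class = "tcr_motif_table")
    return(tab)
  }
  agg <- rowsum(counts, group = keys)
  key_u <- rownames(agg)
  count_u <- as.integer(agg[, 1L])
  first <- !duplicated(keys)
  meta <- data.frame(key = keys[first], residues = res[first],
                     gap_pattern = gaps[first], stringsAsFactors = FALSE)
  meta <- meta[match(key_u, meta$key), ]
  total <- sum(count_u)
  tab <- structure(
    list(sample_id = rep$sample_id,
         motifs = data.frame(key = key_u, residues = meta$residues,
                             gap_pattern = meta$gap_pattern,
                             count = count_u,
                             rel_abundance = count_u / total,
                             stringsAsFactors = FALSE),
         total = total),
    class = "tcr_motif_table")
  if (apply_top_k) tab <- truncate_top_k(tab, config$top_k)
  tab
}

#' Keep the k most abundant motifs of a table
#'
#' Ties on count are broken lexicographically by motif key so truncation
#' is deterministic. Relative abundances are not recomputed: the cap is a
#' runtime bound, not a renormalization.
#'
#' @param table A `tcr_motif_table`.
#' @param k Number of motifs to keep.
#' @return The truncated `tcr_motif_table` (`total` unchanged).
#' @export
truncate_top_k <- function(table, k = 65536L) {
  stopifnot(inherits(table, "tcr_motif_table"), k >= 1L)
  if (nrow(table$motifs) <= k) return(table)
  ord <- order(-table$motifs$count, table$motifs$key)
  keep <- sort(ord[seq_len(k)])
  table$motifs <- table$motifs[keep, , drop = FALSE]
  rownames(table$motifs) <- NULL
  table
}

#' Write a motif table as TSV
#'
#' @param table A `tcr_motif_table`.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_motif_table <- function(table, path) {
  out <- cbind(sample_id = table$sample_id, table$motifs)
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @export
print.tcr_motif_table <- function(x, ...) {
  cat(sprintf("<tcr_motif_table> %s: %d motifs, total count %d\n",
              x$sample_id, nrow(x$motifs), x$total))
  invisible(x)
}
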