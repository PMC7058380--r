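# Readers for TCRB rearrangement tables and labeled cohort assembly.
#
# Two tab-separated dialects are supported:
#   * AIRR Rearrangement: columns `junction_aa`, `duplicate_count`
#   * Adaptive immunoSEQ export: an amino-acid column (`aminoAcid` or
#     `amino_acid`) and a template column (`templates`, `count`,
#     `count (templates/reads)` or `count..templates.reads.`)
# Rows are deduplicated on the CDR3 amino-acid string (V/J calls are
# ignored: the classifier consumes only CDR3 residues and template counts)
# and template counts are summed.

IMMUNOSEQ_AA_COLS <- c("aminoAcid", "amino_acid")
IMMUNOSEQ_COUNT_COLS <- c("templates", "count (templates/reads)",
                          "count..templates.reads.", "count")

new_repertoire <- function(sample_id, label, cdr3_aa, template_count,
                           skipped = c(noncanonical = 0L, missing = 0L)) {
  stopifnot(length(label) == 1L, label %in% c(0L, 1L))
  ord <- order(cdr3_aa)
  structure(
    list(sample_id = as.character(sample_id),
         label = as.integer(label),
         records = data.frame(cdr3_aa = cdr3_aa[ord],
                              template_count = as.integer(template_count[ord]),
                              stringsAsFactors = FALSE),
         skipped = skipped),
    class = "tcr_repertoire")
}

#' Build a repertoire from vectors (mainly for tests and simulation)
#'
#' Rows sharing a CDR3 amino-acid string are merged with counts summed.
#'
#' @param sample_id Sample identifier.
#' @param label Binary class label (1 = tumor, 0 = healthy).
#' @param cdr3_aa Character vector of CDR3 amino-acid sequences.
#' @param template_count Integer template counts (`C^CDR3`), recycled if
#'   length 1.
#' @return A `tcr_repertoire` object.
#' @export
repertoire <- function(sample_id, label, cdr3_aa, template_count = 1L) {
  template_count <- rep_len(as.integer(template_count), length(cdr3_aa))
  if (any(!is_canonical_aa(cdr3_aa))) {
    stop("cdr3_aa contains non-canonical residues", call. = FALSE)
  }
  if (any(template_count < 1L)) stop("template_count must be >= 1",
                                     call. = FALSE)
  agg <- rowsum(template_count, group = cdr3_aa)
  new_repertoire(sample_id, label, rownames(agg), as.integer(agg[, 1L]))
}

#' Read one rearrangement file into a repertoire
#'
#' Reads a tab-separated rearrangement table, keeps the CDR3 amino-acid
#' and template-count columns of the requested dialect, drops rows whose
#' CDR3 is empty, missing, or contains non-canonical characters (stop
#' codons `*`, ambiguous `X`, frame-shift `_`), merges duplicate CDR3s by
#' summing counts, and returns a labeled repertoire. Missing or
#' non-positive counts default to 1 with a warning, preserving presence
#' information from survey-depth exports.
#'
#' @param path Path to a TSV file.
#' @param dialect `"airr"` or `"immunoseq"`.
#' @param label Binary label for the sample (1 = tumor, 0 = healthy).
#' @param sample_id Sample identifier; defaults to the file name.
#' @return A `tcr_repertoire`; the `skipped` element counts dropped rows.
#' @export
read_repertoire <- function(path, dialect = c("airr", "immunoseq"),
                            label, sample_id = basename(path)) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  tab <- read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  if (dialect == "airr") {
    aa_col <- "junction_aa"
    count_col <- "duplicate_count"
    if (!aa_col %in% names(tab)) {
      stop("AIRR file lacks required column 'junction_aa': ", path,
           call. = FALSE)
    }
  } else {
    aa_col <- intersect(IMMUNOSEQ_AA_COLS, names(tab))[1L]
    count_col <- intersect(IMMUNOSEQ_COUNT_COLS, names(tab))[1L]
    if (is.na(aa_col)) {
      stop("immunoSEQ file lacks an amino-acid column ",
           "('aminoAcid' or 'amino_acid'): ", path, call. = FALSE)
    }
  }
  cdr3 <- as.character(tab[[aa_col]])
  if (!is.na(count_col) && count_col %in% names(tab)) {
    counts <- suppressWarnings(as.numeric(tab[[count_col]]))
  } else {
    counts <- rep(NA_real_, length(cdr3))
    warning("no template-count column in ", basename(path),
            "; defaulting counts to 1", call. = FALSE)
  }
  bad_count <- is.na(counts) | counts < 1
  if (any(bad_count) && !is.na(count_col) && count_col %in% names(tab)) {
    warning(sum(bad_count), " row(s) with missing/zero counts in ",
            basename(path), " defaulted to 1", call. = FALSE)
  }
  counts[bad_count] <- 1
  missing_aa <- is.na(cdr3) | cdr3 == ""
  noncanon <- !missing_aa & !is_canonical_aa(cdr3)
  keep <- !missing_aa & !noncanon
  if (!any(keep)) {
    stop("no usable CDR3 rows in ", path, " (empty repertoire)",
         call. = FALSE)
  }
  agg <- rowsum(counts[keep], group = cdr3[keep])
  new_repertoire(sample_id, label, rownames(agg),
                 as.integer(round(agg[, 1L])),
                 skipped = c(noncanonical = sum(noncanon),
                             missing = sum(missing_aa)))
}

#' Assemble a labeled cohort from a manifest
#'
#' @param manifest Either a data frame or a path to a CSV/TSV file with
#'   columns `path`, `dialect`, `label`, `sample_id`. Relative paths are
#'   resolved against the manifest's directory when a file path is given.
#' @param name Cohort name.
#' @return A `tcr_cohort`: a list with `name` and `repertoires`.
#' @export
load_cohort <- function(manifest, name = "cohort") {
  if (is.character(manifest)) {
    sep <- if (grepl("\\.tsv$", manifest)) "\t" else ","
    dir <- dirname(manifest)
    manifest <- utils::read.table(manifest, sep = sep, header = TRUE,
                                  stringsAsFactors = FALSE)
    rel <- !file.exists(manifest$path) &
      file.exists(file.path(dir, manifest$path))
    manifest$path[rel] <- file.path(dir, manifest$path[rel])
  }
  req <- c("path", "dialect", "label", "sample_id")
  if (!all(req %in% names(manifest))) {
    stop("manifest must have columns: ", paste(req, collapse = ", "),
         call. = FALSE)
  }
  if (anyDuplicated(manifest$sample_id)) {
    stop("duplicate sample_id in manifest: ",
         paste(unique(manifest$sample_id[duplicated(manifest$sample_id)]),
               collapse = ", "), call. = FALSE)
  }
  reps <- lapply(seq_len(nrow(manifest)), function(i) {
    read_repertoire(manifest$path[i], manifest$dialect[i],
                    label = manifest$label[i],
                    sample_id = manifest$sample_id[i])
  })
  cohort(reps, name = name)
}

#' Construct a cohort from repertoires
#'
#' @param repertoires List of `tcr_repertoire` objects with unique sample
#'   ids.
#' @param name Cohort name.
#' @return A `tcr_cohort` object.
#' @export
cohort <- function(repertoires, name = "cohort") {
  ids <- vapply(repertoires, function(r) r$sample_id, character(1))
  if (anyDuplicated(ids)) {
    stop("duplicate sample_id in cohort: ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "),
         call. = FALSE)
  }
  structure(list(name = name, repertoires = repertoires),
            class = "tcr_cohort")
}

#' Labels and sample ids of a cohort
#'
#' @param x A `tcr_cohort`.
#' @return `cohort_labels()`: integer vector of binary labels;
#'   `cohort_ids()`: character vector of sample ids, in cohort order.
#' @export
cohort_labels <- function(x) {
  vapply(x$repertoires, function(r) r$label, integer(1))
}

#' @rdname cohort_labels
#' @export
cohort_ids <- function(x) {
  vapply(x$repertoires, function(r) r$sample_id, character(1))
}

#' Per-sample summary of a cohort
#'
#' @param x A `tcr_cohort`.
#' @return Data frame with sample id, label, number of unique CDR3s
#'   (comparable to the "Unique TCRBs" column of a patient table) and
#'   total template count.
#' @export
cohort_summary <- function(x) {
  data.frame(
    sample_id = cohort_ids(x),
    label = cohort_labels(x),
    unique_cdr3 = vapply(x$repertoires, function(r) nrow(r$records),
                         integer(1)),
    total_templates = vapply(x$repertoires,
                             function(r) sum(r$records$template_count),
                             integer(1)),
    stringsAsFactors = FALSE)
}

#' @export
print.tcr_repertoire <- function(x, ...) {
  cat(sprintf("<tcr_repertoire> %s  label=%d  %d unique CDR3s, %d templates\n",
              x$sample_id, x$label, nrow(x$records),
              sum(x$records$template_count)))
  invisible(x)
}

#' @export
print.tcr_cohort <- function(x, ...) {
  labs <- cohort_labels(x)
  cat(sprintf("<tcr_cohort> %s: %d samples (%d positive, %d negative)\n",
              x$name, length(labs), sum(labs == 1L), sum(labs == 0L)))
  invisible(x)
}
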