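#' @useDynLib tcrmil, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @importFrom stats rnorm setNames
#' @importFrom utils read.delim write.table
NULL

# The 20 canonical amino-acid one-letter codes, alphabetical.
AA_ALPHABET <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
                 "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")

.tcrmil_cache <- new.env(parent = emptyenv())

#' Atchley factor table
#'
#' Returns the five standardized biophysicochemical descriptors per amino
#' acid derived by Atchley and colleagues from factor analysis of ~50
#' physical properties. The factors correspond loosely to polarity (F1),
#' secondary-structure propensity (F2), molecular volume (F3), codon
#' diversity (F4) and electrostatic charge (F5). The table ships as a
#' plain-text file under `extdata/` so the values are auditable.
#'
#' @return A 20 x 5 numeric matrix with one row per canonical residue
#'   (rownames are one-letter codes) and columns `F1`..`F5`.
#' @export
#' @examples
#' atchley_factors()["A", ]
atchley_factors <- function() {
  if (is.null(.tcrmil_cache$atchley)) {
    path <- system.file("extdata", "atchley_factors.tsv", package = "tcrmil",
                        mustWork = TRUE)
    tab <- read.delim(path, stringsAsFactors = FALSE)
    mat <- as.matrix(tab[, c("F1", "F2", "F3", "F4", "F5")])
    rownames(mat) <- tab$residue
    stopifnot(identical(sort(rownames(mat)), AA_ALPHABET))
    .tcrmil_cache$atchley <- mat[AA_ALPHABET, , drop = FALSE]
  }
  .tcrmil_cache$atchley
}

#' Atchley factor values of a single residue
#'
#' @param residue A single canonical amino-acid letter.
#' @return A named numeric vector of the five factor values.
#' @export
#' @examples
#' atchley_vector("A")
atchley_vector <- function(residue) {
  if (!is.character(residue) || length(residue) != 1L ||
      !(residue %in% AA_ALPHABET)) {
    stop("'", residue, "' is not one of the 20 canonical amino-acid letters",
         call. = FALSE)
  }
  atchley_factors()[residue, ]
}

is_canonical_aa <- function(x) {
  grepl("^[ACDEFGHIKLMNPQRSTVWY]+$", x)
}
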