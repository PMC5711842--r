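#' Parameter schema for phenotypic vectors
#'
#' A phenotypic vector holds twelve ordinal scores in a fixed order: six
#' general-morphology parameters followed by six segmentation parameters.
#' The default codes follow the standard zebrafish segmentation-screen
#' scoring scheme: morphology E (embryonic development), H (head), Y (yolk),
#' D (dorsal-ventral development), A (axis elongation), T (tail shape);
#' segmentation S (secondary tail appendage), BD (myotome boundary defects),
#' AD/TD/PD (anterior/trunk/posterior axial position of defects) and BS
#' (segment shape). Every score is an integer between 0 (indistinguishable
#' from an untreated control of the same genotype) and \code{max_score}
#' (strong difference).
#'
#' @param morphology Character vector of 6 morphology parameter codes.
#' @param segmentation Character vector of 6 segmentation parameter codes.
#' @param max_score Maximum ordinal score (default 3).
#' @return An object of class \code{parameter_schema} with elements
#'   \code{morphology}, \code{segmentation}, \code{codes} (morphology first)
#'   and \code{max_score}.
#' @examples
#' sch <- parameter_schema()
#' sch$codes
#' @export
parameter_schema <- function(morphology = c("E", "H", "Y", "D", "A", "T"),
                             segmentation = c("S", "BD", "AD", "TD", "PD", "BS"),
                             max_score = 3L) {
  morphology <- as.character(morphology)
  segmentation <- as.character(segmentation)
  if (length(morphology) != 6L || length(segmentation) != 6L) {
    stop_config("schema requires exactly 6 morphology and 6 segmentation codes")
  }
  codes <- c(morphology, segmentation)
  if (anyDuplicated(codes)) {
    stop_config("schema parameter codes must be distinct")
  }
  max_score <- as.integer(max_score)
  if (is.na(max_score) || max_score < 1L) {
    stop_config("max_score must be a positive integer")
  }
  structure(
    list(morphology = morphology, segmentation = segmentation,
         codes = codes, max_score = max_score),
    class = "parameter_schema"
  )
}

#' @export
print.parameter_schema <- function(x, ...) {
  cat("<parameter_schema> 12 parameters, scores 0-", x$max_score, "\n", sep = "")
  cat("  morphology:  ", paste(x$morphology, collapse = " "), "\n", sep = "")
  cat("  segmentation:", paste(x$segmentation, collapse = " "), "\n", sep = "")
  invisible(x)
}

#' Coerce and validate a phenotypic vector
#'
#' @param x Numeric vector of length 12, optionally named by parameter code.
#'   If named, it is reordered to schema order; if unnamed, it is assumed to
#'   already be in schema order (morphology half first).
#' @param schema A \code{\link{parameter_schema}}.
#' @return A named integer vector of length 12 in schema order.
#' @examples
#' v <- as_phenotypic_vector(c(0,0,0,0,0,0, 0,3,0,0,2,0))
#' v[["BD"]]
#' @export
as_phenotypic_vector <- function(x, schema = parameter_schema()) {
  if (length(x) != 12L) {
    stop_validation(sprintf(
      "phenotypic vector must have length 12, got %d", length(x)))
  }
  if (!is.null(names(x))) {
    missing <- setdiff(schema$codes, names(x))
    if (length(missing)) {
      stop_validation(sprintf(
        "phenotypic vector is missing parameter code(s): %s",
        paste(missing, collapse = ", ")))
    }
    x <- x[schema$codes]
  }
  if (anyNA(x)) stop_validation("phenotypic vector contains missing scores")
  if (!all(is_whole(x))) {
    stop_validation("phenotypic vector scores must be integers (ordinal 0-3 scale)")
  }
  x <- as.integer(round(x))
  if (any(x < 0L | x > schema$max_score)) {
    bad <- schema$codes[which(x < 0L | x > schema$max_score)[1L]]
    stop_validation(sprintf(
      "score for parameter %s outside [0, %d]", bad, schema$max_score))
  }
  names(x) <- schema$codes
  x
}

# Column indices of the two halves within a score matrix in schema order.
morph_idx <- function(schema) match(schema$morphology, schema$codes)
seg_idx <- function(schema) match(schema$segmentation, schema$codes)
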