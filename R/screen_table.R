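# Screen-table data model: one row per treatment (compound x concentration x
# experiment) carrying metadata plus the 12-parameter phenotypic vector.
# A vector is "present" only when all 12 score cells are filled; any empty
# score cell marks the treatment as unscored (absent vector), which is
# deliberately distinct from an all-zero (scored-normal) vector.

META_COLUMNS <- c("compound_id", "plate", "well", "concentration_uM",
                  "experiment", "lethal", "n_embryos", "n_scoreable")

#' Construct a validated screen table
#'
#' A screen table is a data frame with one row per treatment and columns
#' \code{compound_id, plate, well, concentration_uM, experiment, lethal,
#' n_embryos, n_scoreable} followed by the 12 parameter score columns in
#' schema order. Rows are normalized to a deterministic order (compound, then
#' concentration, then experiment) so that all downstream ranking and
#' clustering tie-breaks are reproducible.
#'
#' @param df Data frame with the required columns.
#' @param schema A \code{\link{parameter_schema}}.
#' @param experiments Optional ordered character vector of expected
#'   experiment labels (defaults to the sorted labels observed).
#' @param concentrations Optional ordered numeric vector of screened
#'   concentrations in micromolar (defaults to sorted observed values).
#' @return A data frame of class \code{screen_table} with attributes
#'   \code{schema}, \code{experiments} and \code{concentrations}.
#' @export
screen_table <- function(df, schema = parameter_schema(),
                         experiments = NULL, concentrations = NULL) {
  df <- as.data.frame(df, stringsAsFactors = FALSE)
  missing_meta <- setdiff(META_COLUMNS, names(df))
  if (length(missing_meta)) {
    stop_format(sprintf("missing required column(s): %s",
                        paste(missing_meta, collapse = ", ")))
  }
  missing_par <- setdiff(schema$codes, names(df))
  if (length(missing_par)) {
    stop_format(sprintf("missing parameter column(s): %s",
                        paste(missing_par, collapse = ", ")))
  }
  dup_par <- schema$codes[schema$codes %in% names(df)[duplicated(names(df))]]
  if (length(dup_par)) {
    stop_format(sprintf("duplicated parameter column(s): %s",
                        paste(dup_par, collapse = ", ")))
  }

  df$compound_id <- as.character(df$compound_id)
  df$plate <- as.character(df$plate)
  df$well <- as.character(df$well)
  df$experiment <- as.character(df$experiment)
  df$concentration_uM <- as.numeric(df$concentration_uM)
  df$lethal <- parse_lethal(df$lethal)
  df$n_embryos <- as.integer(df$n_embryos)
  df$n_scoreable <- as.integer(df$n_scoreable)

  # Score columns: integers in [0, max_score] or NA (absent).
  for (code in schema$codes) {
    x <- df[[code]]
    if (is.character(x)) x[!nzchar(trimws(x))] <- NA
    x <- suppressWarnings(as.numeric(x))
    bad <- which(!is.na(x) & !is_whole(x))
    if (length(bad)) {
      stop_validation(sprintf(
        "non-integer score in column %s at row %d", code, bad[1L]))
    }
    oob <- which(!is.na(x) & (x < 0 | x > schema$max_score))
    if (length(oob)) {
      stop_validation(sprintf(
        "score outside [0, %d] in column %s at row %d",
        schema$max_score, code, oob[1L]))
    }
    df[[code]] <- as.integer(round(x))
  }

  key <- treatment_key(df$compound_id, df$concentration_uM, df$experiment)
  if (anyDuplicated(key)) {
    k <- key[duplicated(key)][1L]
    stop_duplicate(sprintf(
      "duplicate (compound, concentration, experiment): %s", k))
  }
  bad_n <- which(!is.na(df$n_scoreable) & !is.na(df$n_embryos) &
                   df$n_scoreable > df$n_embryos)
  if (length(bad_n)) {
    stop_validation(sprintf("n_scoreable > n_embryos at row %d", bad_n[1L]))
  }

  df <- df[c(META_COLUMNS, schema$codes)]
  ord <- order(df$compound_id, df$concentration_uM, df$experiment)
  df <- df[ord, , drop = FALSE]
  rownames(df) <- NULL

  if (is.null(experiments)) experiments <- sort(unique(df$experiment))
  if (is.null(concentrations)) concentrations <- sort(unique(df$concentration_uM))
  structure(df,
            schema = schema,
            experiments = as.character(experiments),
            concentrations = as.numeric(concentrations),
            class = c("screen_table", "data.frame"))
}

parse_lethal <- function(x) {
  if (is.logical(x)) return(x)
  if (is.numeric(x)) return(x != 0)
  x <- trimws(as.character(x))
  out <- rep(NA, length(x))
  out[x %in% c("1", "TRUE", "true", "T")] <- TRUE
  out[x %in% c("0", "FALSE", "false", "F")] <- FALSE
  if (anyNA(out)) stop_validation("lethal column must be 0/1 or TRUE/FALSE")
  out
}

#' @export
print.screen_table <- function(x, ...) {
  sch <- attr(x, "schema")
  cat(sprintf("<screen_table> %d treatments | %d compounds | conc: %s | experiments: %s\n",
              nrow(x), length(unique(x$compound_id)),
              paste(attr(x, "concentrations"), collapse = "/"),
              paste(attr(x, "experiments"), collapse = ", ")))
  cat(sprintf("  lethal: %d | unscored (non-lethal): %d\n",
              sum(x$lethal), sum(!x$lethal & !has_vector(x))))
  NextMethod()
}

# Logical: row has a complete phenotypic vector.
has_vector <- function(table, schema = attr(table, "schema")) {
  if (is.null(schema)) schema <- parameter_schema()
  m <- as.matrix(as.data.frame(table)[schema$codes])
  rowSums(is.na(m)) == 0L
}

# Score matrix (rows = treatments, 12 columns in schema order).
score_matrix <- function(table, schema = attr(table, "schema")) {
  if (is.null(schema)) schema <- parameter_schema()
  m <- as.matrix(as.data.frame(table)[schema$codes])
  storage.mode(m) <- "double"
  rownames(m) <- treatment_key(table$compound_id, table$concentration_uM,
                               table$experiment)
  m
}

#' Read a score table from TSV
#'
#' Expects a UTF-8 tab-separated file with a header row naming the metadata
#' columns (\code{compound_id, plate, well, concentration_uM, experiment,
#' lethal, n_embryos, n_scoreable}) and the 12 parameter codes. Score cells
#' may be empty, which marks the treatment as unscored (absent vector).
#'
#' @param path File path.
#' @param schema A \code{\link{parameter_schema}}.
#' @inheritParams screen_table
#' @return A \code{\link{screen_table}}.
#' @export
load_score_table <- function(path, schema = parameter_schema(),
                             experiments = NULL, concentrations = NULL) {
  if (!file.exists(path)) stop_format(sprintf("file not found: %s", path))
  df <- utils::read.delim(path, header = TRUE, sep = "\t", quote = "",
                          colClasses = "character", check.names = FALSE,
                          na.strings = NULL, fileEncoding = "UTF-8")
  screen_table(df, schema = schema, experiments = experiments,
               concentrations = concentrations)
}

#' Write a screen table to TSV
#'
#' The writer emits the canonical normalized form (deterministic column and
#' row order, \code{lethal} as 0/1, absent scores as empty cells) so that
#' \code{save_score_table(load_score_table(path))} round-trips byte-identically
#' for normalized files.
#'
#' @param table A \code{\link{screen_table}}.
#' @param path Output file path.
#' @return Invisibly, \code{path}.
#' @export
save_score_table <- function(table, path) {
  df <- as.data.frame(table)
  df$lethal <- as.integer(df$lethal)
  df$concentration_uM <- format(df$concentration_uM, trim = TRUE,
                                scientific = FALSE, drop0trailing = TRUE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     na = "", fileEncoding = "UTF-8")
  invisible(path)
}

#' Drop non-analyzable treatments
#'
#' Treatments that were lethal or that carry no score are removed before any
#' ranking, QC or clustering, mirroring standard screen practice: a dead well
#' has no phenotypic vector, and an unscored well is missing data rather than
#' scored-normal.
#'
#' @param table A \code{\link{screen_table}}.
#' @param quiet Suppress the removal message.
#' @return A \code{screen_table} containing exactly the records with
#'   \code{lethal = FALSE} and a complete vector. Idempotent.
#' @export
filter_analyzable <- function(table, quiet = FALSE) {
  keep <- !table$lethal & has_vector(table)
  removed <- sum(!keep)
  out <- table[keep, , drop = FALSE]
  rownames(out) <- NULL
  if (!quiet && removed > 0L) {
    message(sprintf("filter_analyzable: removed %d non-analyzable treatment(s) (%d lethal, %d unscored)",
                    removed, sum(table$lethal),
                    sum(!table$lethal & !has_vector(table))))
  }
  if (nrow(out) == 0L) warning("filter_analyzable: no analyzable treatments remain")
  attrs <- attributes(table)
  attributes(out) <- c(attributes(out)[c("names", "row.names")],
                       attrs[c("schema", "experiments", "concentrations")],
                       list(class = attrs$class))
  out
}

#' Per-parameter consensus score across embryos in a well
#'
#' The well-level score of a parameter is the largest ordinal value supported
#' by at least \code{min_embryos} embryos, i.e. the \code{min_embryos}-th
#' largest per-embryo score. With the default \code{min_embryos = 3} and five
#' embryos per well this reproduces the standard "phenotype shown by at least
#' three out of five embryos" rule. For wells with fewer than
#' \code{min_embryos} embryos the support requirement degrades gracefully to
#' \code{ceiling(0.6 * n_embryos)}.
#'
#' @param embryo_scores Matrix or data frame, one row per embryo, 12 columns
#'   in schema order (or named by parameter code).
#' @param min_embryos Minimum number of supporting embryos (default 3).
#' @param schema A \code{\link{parameter_schema}}.
#' @return A named integer phenotypic vector.
#' @examples
#' m <- rbind(c(3,3,3,0,0), c(3,3,0,0,0), c(2,2,3,3,0))
#' # one parameter per row here, transpose to embryos x parameters:
#' apply(m, 1, function(s) sort(s, decreasing = TRUE)[3])  # 3, 0, 2
#' @export
consensus_vector <- function(embryo_scores, min_embryos = 3L,
                             schema = parameter_schema()) {
  m <- as.matrix(embryo_scores)
  if (nrow(m) == 0L) stop_data("consensus_vector: empty well (no embryos)")
  if (ncol(m) != 12L) stop_validation("embryo scores must have 12 parameter columns")
  if (!is.null(colnames(m)) && all(schema$codes %in% colnames(m))) {
    m <- m[, schema$codes, drop = FALSE]
  }
  storage.mode(m) <- "integer"
  if (anyNA(m)) stop_validation("embryo scores contain missing values")
  if (any(m < 0L | m > schema$max_score)) {
    stop_validation(sprintf("embryo scores outside [0, %d]", schema$max_score))
  }
  min_embryos <- as.integer(min_embryos)
  if (min_embryos < 1L) stop_config("min_embryos must be >= 1")
  n <- nrow(m)
  support <- if (n < min_embryos) as.integer(ceiling(0.6 * n)) else min_embryos
  out <- as.integer(apply(m, 2, function(s) sort(s, decreasing = TRUE)[support]))
  names(out) <- schema$codes
  out
}

#' Read an embryo-level score table and collapse it to well consensus
#'
#' The embryo-level dialect carries the same columns as the treatment table
#' plus \code{embryo_index}, one row per embryo. All embryo rows of a well
#' must be fully scored.
#'
#' @param path TSV file path.
#' @param schema A \code{\link{parameter_schema}}.
#' @param min_embryos Consensus support threshold (see
#'   \code{\link{consensus_vector}}).
#' @return A \code{\link{screen_table}} with one consensus row per treatment.
#' @export
load_embryo_table <- function(path, schema = parameter_schema(),
                              min_embryos = 3L) {
  if (!file.exists(path)) stop_format(sprintf("file not found: %s", path))
  df <- utils::read.delim(path, header = TRUE, sep = "\t", quote = "",
                          check.names = FALSE, fileEncoding = "UTF-8")
  need <- c(META_COLUMNS, "embryo_index", schema$codes)
  missing <- setdiff(need, names(df))
  if (length(missing)) {
    stop_format(sprintf("missing column(s): %s", paste(missing, collapse = ", ")))
  }
  key <- treatment_key(df$compound_id, df$concentration_uM, df$experiment)
  wells <- split(seq_len(nrow(df)), key)
  rows <- lapply(wells, function(idx) {
    sub <- df[idx, , drop = FALSE]
    meta <- sub[1L, META_COLUMNS, drop = FALSE]
    if (isTRUE(parse_lethal(meta$lethal)[1L])) {
      meta[schema$codes] <- NA_integer_
    } else {
      cons <- consensus_vector(sub[schema$codes], min_embryos = min_embryos,
                               schema = schema)
      meta[schema$codes] <- as.list(cons)
    }
    meta$n_embryos <- nrow(sub)
    meta
  })
  screen_table(do.call(rbind, rows), schema = schema)
}

#' Validate a screen table without mutating it
#'
#' Runs the standard checks (score range and integrality, duplicate
#' treatments, schema conformity, design completeness against the expected
#' compound x concentration x experiment grid) and reports all findings
#' rather than throwing.
#'
#' @param table A \code{\link{screen_table}} (or plain data frame with the
#'   same columns).
#' @param schema A \code{\link{parameter_schema}}.
#' @param concentrations,experiments Expected design grid; defaults to the
#'   table attributes (or observed values).
#' @return A list of class \code{validation_report}: per-check \code{pass},
#'   offending row indices/details, and overall design \code{completeness}
#'   in [0, 1].
#' @export
validate_table <- function(table, schema = attr(table, "schema"),
                           concentrations = attr(table, "concentrations"),
                           experiments = attr(table, "experiments")) {
  if (is.null(schema)) schema <- parameter_schema()
  df <- as.data.frame(table)
  checks <- list()

  present <- intersect(schema$codes, names(df))
  missing_cols <- setdiff(schema$codes, names(df))
  checks$schema <- list(pass = length(missing_cols) == 0L,
                        missing_codes = missing_cols)

  bad_rows <- integer(0)
  for (code in present) {
    x <- suppressWarnings(as.numeric(df[[code]]))
    bad <- which(!is.na(x) & (!is_whole(x) | x < 0 | x > schema$max_score))
    bad_rows <- union(bad_rows, bad)
  }
  checks$score_range <- list(pass = length(bad_rows) == 0L,
                             rows = sort(bad_rows))

  key <- treatment_key(df$compound_id, df$concentration_uM, df$experiment)
  dup <- which(duplicated(key) | duplicated(key, fromLast = TRUE))
  checks$duplicates <- list(pass = length(dup) == 0L, rows = dup,
                            keys = unique(key[duplicated(key)]))

  if (is.null(concentrations)) concentrations <- sort(unique(df$concentration_uM))
  if (is.null(experiments)) experiments <- sort(unique(df$experiment))
  compounds <- sort(unique(df$compound_id))
  grid <- expand.grid(compound_id = compounds,
                      concentration_uM = concentrations,
                      experiment = experiments,
                      stringsAsFactors = FALSE)
  expected <- treatment_key(grid$compound_id, grid$concentration_uM,
                            grid$experiment)
  missing_cells <- setdiff(expected, key)
  completeness <- 1 - length(missing_cells) / length(expected)
  checks$design_completeness <- list(pass = length(missing_cells) == 0L,
                                     missing_cells = missing_cells,
                                     completeness = completeness)

  structure(list(checks = checks,
                 completeness = completeness,
                 n_records = nrow(df),
                 all_pass = all(vapply(checks, `[[`, logical(1), "pass"))),
            class = "validation_report")
}

#' @export
print.validation_report <- function(x, ...) {
  cat(sprintf("<validation_report> %d records, completeness %.1f%%, %s\n",
              x$n_records, 100 * x$completeness,
              if (x$all_pass) "all checks pass" else "FAILURES present"))
  for (nm in names(x$checks)) {
    cat(sprintf("  %-20s %s\n", nm,
                if (x$checks[[nm]]$pass) "pass" else "FAIL"))
  }
  invisible(x)
}

#' Serialize a validation report to JSON
#' @param report A \code{validation_report}.
#' @param path Optional output path; if \code{NULL} the JSON string is returned.
#' @return JSON string (invisibly if written to file).
#' @export
write_validation_report <- function(report, path = NULL) {
  json <- jsonlite::toJSON(unclass(report), auto_unbox = TRUE, pretty = TRUE,
                           digits = NA)
  if (is.null(path)) return(json)
  writeLines(json, path)
  invisible(json)
}
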