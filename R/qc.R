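# Replicate reproducibility metrics between two experiments of a screen.
# Pairing is on (compound, concentration, parameter); only treatments that
# are analyzable (non-lethal, scored) in BOTH experiments enter -- a
# treatment lost in one replicate is missing data, not disagreement.

# Paired score matrices for two experiments; rows = treatments analyzable in
# both, columns = the 12 parameters.
paired_scores <- function(table, exp_a, exp_b) {
  exps <- unique(table$experiment)
  for (e in c(exp_a, exp_b)) {
    if (!e %in% exps) stop_data(sprintf("experiment not present in table: %s", e))
  }
  tab <- filter_analyzable(table, quiet = TRUE)
  a <- tab[tab$experiment == exp_a, , drop = FALSE]
  b <- tab[tab$experiment == exp_b, , drop = FALSE]
  ka <- paste(a$compound_id, a$concentration_uM)
  kb <- paste(b$compound_id, b$concentration_uM)
  common <- intersect(ka, kb)
  schema <- attr(table, "schema")
  list(a = as.matrix(as.data.frame(a)[match(common, ka), schema$codes]),
       b = as.matrix(as.data.frame(b)[match(common, kb), schema$codes]),
       treatments = common)
}

#' Pointwise replicate correlation
#'
#' Pearson product-moment correlation over every paired (treatment,
#' parameter) score measured in both experiments, with the two-sided p-value
#' from the standard t transform. This is the screen-wide "each data point of
#' all scored parameters" comparison used to quantify technical
#' reproducibility between wild-type replicates.
#'
#' @param table A \code{\link{screen_table}}.
#' @param exp_a,exp_b Experiment labels.
#' @param method \code{"pearson"} (default) or \code{"spearman"}.
#' @return List with \code{r}, \code{p}, \code{n_pairs}.
#' @export
replicate_correlation <- function(table, exp_a, exp_b, method = c("pearson", "spearman")) {
  method <- match.arg(method)
  ps <- paired_scores(table, exp_a, exp_b)
  x <- as.numeric(ps$a)
  y <- as.numeric(ps$b)
  if (length(x) < 3L) {
    stop_data(sprintf("replicate_correlation: only %d paired measurements (need >= 3)",
                      length(x)))
  }
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    stop_undefined("replicate_correlation: zero variance in one experiment's scores; correlation undefined")
  }
  ct <- stats::cor.test(x, y, method = method, exact = FALSE)
  list(r = unname(ct$estimate), p = ct$p.value, n_pairs = length(x))
}

#' Normalized Hamming distance between replicates
#'
#' The proportion of paired (treatment, parameter) measurements whose integer
#' scores differ at all, in [0, 1] with 1 indicating maximum distance.
#' Mismatch is binary: a 0 vs 3 disagreement counts the same as 0 vs 1.
#'
#' @inheritParams replicate_correlation
#' @return List with \code{hamming} and \code{n_compared} (paired
#'   measurements).
#' @export
hamming_distance <- function(table, exp_a, exp_b) {
  ps <- paired_scores(table, exp_a, exp_b)
  n <- length(ps$a)
  if (n == 0L) stop_data("hamming_distance: no paired measurements")
  list(hamming = mean(ps$a != ps$b), n_compared = n,
       n_treatments = length(ps$treatments))
}

#' Correlation distance between two phenotypic vectors
#'
#' \code{1 - Pearson r} along the 12 parameter scores, in [0, 2]. Constant
#' vectors (zero variance, e.g. all-zero "no phenotype") have no defined
#' correlation and raise an error; callers such as
#' \code{\link{distance_matrix}} pre-filter them.
#'
#' @param v1,v2 Phenotypic vectors (length 12, schema order).
#' @return Correlation distance in [0, 2].
#' @export
vector_distance <- function(v1, v2) {
  v1 <- as.numeric(v1)
  v2 <- as.numeric(v2)
  if (length(v1) != length(v2)) stop_validation("vectors differ in length")
  if (stats::sd(v1) == 0 || stats::sd(v2) == 0) {
    stop_undefined("vector_distance: constant vector has undefined correlation")
  }
  1 - stats::cor(v1, v2)
}

#' Replicate QC report
#'
#' Bundles \code{\link{replicate_correlation}} and
#' \code{\link{hamming_distance}} for one replicate pair.
#'
#' @inheritParams replicate_correlation
#' @param path Optional path; when given, the report is written as JSON.
#' @return List of class \code{qc_report} with \code{correlation_r},
#'   \code{correlation_p}, \code{n_pairs}, \code{hamming}, \code{n_compared}.
#' @export
qc_report <- function(table, exp_a = "wt_A", exp_b = "wt_B", path = NULL) {
  rc <- replicate_correlation(table, exp_a, exp_b)
  hd <- hamming_distance(table, exp_a, exp_b)
  rep <- structure(list(exp_a = exp_a, exp_b = exp_b,
                        correlation_r = rc$r, correlation_p = rc$p,
                        n_pairs = rc$n_pairs,
                        hamming = hd$hamming, n_compared = hd$n_compared),
                   class = "qc_report")
  if (!is.null(path)) {
    writeLines(jsonlite::toJSON(unclass(rep), auto_unbox = TRUE, pretty = TRUE,
                                digits = NA), path)
  }
  rep
}

#' @export
print.qc_report <- function(x, ...) {
  cat(sprintf("<qc_report> %s vs %s\n  r = %.3f (p = %.3g, n = %d)\n  Hamming = %.3f (n = %d)\n",
              x$exp_a, x$exp_b, x$correlation_r, x$correlation_p, x$n_pairs,
              x$hamming, x$n_compared))
  invisible(x)
}
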