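# Hit selection on phenotypic vectors.
#
# Each treatment's 12 scores split into a segmentation half (the "specific"
# signal) and a morphology half (general toxicity). The modified SSMD,
#   SSMD = (mean_seg - mean_morph) / sqrt(var_seg + var_morph),
# with sample variances (n-1 denominator, n = 6 per half), and the plain
# mean difference mean_seg - mean_morph, both rank treatments by how
# segmentation-specific their phenotype is. The direct-segmentation
# predicate operationalizes "high segmentation, low morphology".

#' Ranking and hit-calling thresholds
#'
#' @param ssmd_exclude_seg_mean_below Exclude treatments from the SSMD
#'   ranking when the segmentation mean is below this (no specific signal);
#'   default 0.2.
#' @param ssmd_exclude_morph_mean_above Exclude when the morphology mean is
#'   above this (general toxicity); default 2.
#' @param exclusion_rule \code{"union"} (default: exclude if either condition
#'   holds) or \code{"conjunction"} (exclude only if both hold).
#' @param meandiff_morph_max Mean-difference ranking keeps treatments with
#'   morphology mean strictly below this; default 2.
#' @param predicate_min_seg_mean,predicate_morph_max Direct-segmentation
#'   predicate thresholds (defaults 0.2 and 2).
#' @return List of class \code{ranking_config}.
#' @export
ranking_config <- function(ssmd_exclude_seg_mean_below = 0.2,
                           ssmd_exclude_morph_mean_above = 2,
                           exclusion_rule = c("union", "conjunction"),
                           meandiff_morph_max = 2,
                           predicate_min_seg_mean = 0.2,
                           predicate_morph_max = 2) {
  exclusion_rule <- match.arg(exclusion_rule)
  vals <- c(ssmd_exclude_seg_mean_below, ssmd_exclude_morph_mean_above,
            meandiff_morph_max, predicate_min_seg_mean, predicate_morph_max)
  if (any(vals < 0)) stop_config("ranking thresholds must be >= 0")
  structure(list(ssmd_exclude_seg_mean_below = ssmd_exclude_seg_mean_below,
                 ssmd_exclude_morph_mean_above = ssmd_exclude_morph_mean_above,
                 exclusion_rule = exclusion_rule,
                 meandiff_morph_max = meandiff_morph_max,
                 predicate_min_seg_mean = predicate_min_seg_mean,
                 predicate_morph_max = predicate_morph_max),
            class = "ranking_config")
}

#' Summary statistics of one phenotypic vector
#'
#' Means and sample variances (n-1 denominator, n = 6) of the two halves,
#' the modified SSMD and the mean difference. When both variances are zero
#' the SSMD is 0 for a zero numerator and signed infinity otherwise, so
#' rankings stay well defined.
#'
#' @param vector Phenotypic vector (length 12; named or in schema order).
#' @param schema A \code{\link{parameter_schema}}.
#' @return List of class \code{treatment_summary}: \code{seg_mean},
#'   \code{morph_mean}, \code{seg_var}, \code{morph_var}, \code{ssmd},
#'   \code{mean_diff}.
#' @examples
#' v <- c(0,0,1,0,0,1, 3,2,3,2,3,2)  # morphology half first
#' summarize_treatment(v)$ssmd
#' @export
summarize_treatment <- function(vector, schema = parameter_schema()) {
  v <- as_phenotypic_vector(vector, schema)
  seg <- as.numeric(v[schema$segmentation])
  morph <- as.numeric(v[schema$morphology])
  seg_mean <- mean(seg)
  morph_mean <- mean(morph)
  seg_var <- stats::var(seg)
  morph_var <- stats::var(morph)
  num <- seg_mean - morph_mean
  denom <- seg_var + morph_var
  ssmd <- if (denom > 0) num / sqrt(denom) else if (num == 0) 0 else sign(num) * Inf
  structure(list(seg_mean = seg_mean, morph_mean = morph_mean,
                 seg_var = seg_var, morph_var = morph_var,
                 ssmd = ssmd, mean_diff = num),
            class = "treatment_summary")
}

#' Per-treatment summaries for a whole table
#'
#' Vectorized \code{\link{summarize_treatment}} over the analyzable rows.
#'
#' @param table A \code{\link{screen_table}}.
#' @return Data frame with treatment keys and \code{seg_mean, morph_mean,
#'   seg_var, morph_var, ssmd, mean_diff}.
#' @export
summarize_table <- function(table) {
  schema <- attr(table, "schema")
  if (is.null(schema)) schema <- parameter_schema()
  tab <- filter_analyzable(table, quiet = TRUE)
  m <- score_matrix(tab, schema)
  seg <- m[, schema$segmentation, drop = FALSE]
  morph <- m[, schema$morphology, drop = FALSE]
  seg_mean <- rowMeans(seg)
  morph_mean <- rowMeans(morph)
  seg_var <- (rowSums(seg^2) - 6 * seg_mean^2) / 5
  morph_var <- (rowSums(morph^2) - 6 * morph_mean^2) / 5
  # guard tiny negative values from floating cancellation
  seg_var <- pmax(seg_var, 0)
  morph_var <- pmax(morph_var, 0)
  num <- seg_mean - morph_mean
  denom <- seg_var + morph_var
  ssmd <- ifelse(denom > 0, num / sqrt(denom),
                 ifelse(num == 0, 0, sign(num) * Inf))
  data.frame(compound_id = tab$compound_id,
             concentration_uM = tab$concentration_uM,
             experiment = tab$experiment,
             seg_mean = seg_mean, morph_mean = morph_mean,
             seg_var = seg_var, morph_var = morph_var,
             ssmd = ssmd, mean_diff = num,
             stringsAsFactors = FALSE, row.names = NULL)
}

rank_order <- function(df, primary) {
  ord <- order(-df[[primary]], -df$mean_diff, df$compound_id,
               df$concentration_uM, df$experiment)
  df <- df[ord, , drop = FALSE]
  rownames(df) <- NULL
  df$rank <- seq_len(nrow(df))
  df
}

#' Rank treatments by modified SSMD
#'
#' Treatments with essentially no segmentation signal
#' (\code{seg_mean < ssmd_exclude_seg_mean_below}) or dominated by general
#' toxicity (\code{morph_mean > ssmd_exclude_morph_mean_above}) are excluded
#' before ranking (union of the two conditions by default; see
#' \code{\link{ranking_config}}). The remainder is sorted by SSMD descending
#' with deterministic tie-breaks (mean difference descending, then compound,
#' concentration, experiment).
#'
#' @param table A \code{\link{screen_table}} (non-analyzable rows dropped
#'   internally).
#' @param config A \code{\link{ranking_config}}.
#' @return Ranked data frame with summary columns and a \code{rank} column;
#'   attribute \code{"excluded"} holds the exclusion log (treatment keys and
#'   reason codes).
#' @export
rank_by_ssmd <- function(table, config = ranking_config()) {
  s <- summarize_table(table)
  low_seg <- s$seg_mean < config$ssmd_exclude_seg_mean_below
  high_morph <- s$morph_mean > config$ssmd_exclude_morph_mean_above
  excl <- if (config$exclusion_rule == "union") low_seg | high_morph
          else low_seg & high_morph
  reason <- character(nrow(s))
  reason[low_seg] <- sprintf("seg_mean below %g", config$ssmd_exclude_seg_mean_below)
  reason[high_morph] <- sprintf("morph_mean above %g", config$ssmd_exclude_morph_mean_above)
  reason[low_seg & high_morph] <- sprintf("seg_mean below %g; morph_mean above %g",
                                          config$ssmd_exclude_seg_mean_below,
                                          config$ssmd_exclude_morph_mean_above)
  excluded <- cbind(s[excl, c("compound_id", "concentration_uM", "experiment")],
                    reason = reason[excl])
  rownames(excluded) <- NULL
  out <- rank_order(s[!excl, , drop = FALSE], "ssmd")
  attr(out, "excluded") <- excluded
  out
}

#' Rank treatments by segmentation-morphology mean difference
#'
#' Keeps treatments with morphology mean strictly below
#' \code{meandiff_morph_max} and strictly positive mean difference, sorted by
#' mean difference descending with the same deterministic tie-breaks as
#' \code{\link{rank_by_ssmd}}.
#'
#' @inheritParams rank_by_ssmd
#' @return Ranked data frame with an \code{"excluded"} attribute.
#' @export
rank_by_mean_diff <- function(table, config = ranking_config()) {
  s <- summarize_table(table)
  high_morph <- s$morph_mean >= config$meandiff_morph_max
  nonpos <- s$mean_diff <= 0
  excl <- high_morph | nonpos
  reason <- character(nrow(s))
  reason[nonpos] <- "mean_diff not positive"
  reason[high_morph] <- sprintf("morph_mean not below %g", config$meandiff_morph_max)
  reason[high_morph & nonpos] <- sprintf("morph_mean not below %g; mean_diff not positive",
                                         config$meandiff_morph_max)
  excluded <- cbind(s[excl, c("compound_id", "concentration_uM", "experiment")],
                    reason = reason[excl])
  rownames(excluded) <- NULL
  out <- rank_order(s[!excl, , drop = FALSE], "mean_diff")
  attr(out, "excluded") <- excluded
  out
}

#' Spearman concordance between two rankings
#'
#' Rank correlation of the positions of the treatments common to both ranked
#' lists.
#'
#' @param rank_a,rank_b Outputs of \code{\link{rank_by_ssmd}} /
#'   \code{\link{rank_by_mean_diff}}.
#' @return List with \code{rho} and \code{n_common}.
#' @export
ranking_concordance <- function(rank_a, rank_b) {
  ka <- treatment_key(rank_a$compound_id, rank_a$concentration_uM, rank_a$experiment)
  kb <- treatment_key(rank_b$compound_id, rank_b$concentration_uM, rank_b$experiment)
  common <- intersect(ka, kb)
  if (length(common) < 3L) {
    stop_data(sprintf("ranking_concordance: only %d common treatments (need >= 3)",
                      length(common)))
  }
  rho <- stats::cor(match(common, ka), match(common, kb), method = "spearman")
  list(rho = rho, n_common = length(common))
}

#' Direct-segmentation predicate
#'
#' TRUE when a treatment shows a segmentation-specific phenotype: morphology
#' mean strictly below \code{predicate_morph_max}, strictly positive mean
#' difference, and segmentation mean at least \code{predicate_min_seg_mean}.
#'
#' @param summary A \code{treatment_summary} (or data frame of summaries).
#' @param config A \code{\link{ranking_config}}.
#' @return Logical (vector).
#' @export
direct_seg_predicate <- function(summary, config = ranking_config()) {
  summary$morph_mean < config$predicate_morph_max &
    summary$mean_diff > 0 &
    summary$seg_mean >= config$predicate_min_seg_mean
}

wt_experiments <- function(exps) intersect(c("wt_A", "wt_B"), exps)

#' Compound-level hit calling
#'
#' A compound's qualifying treatments are those passing the
#' direct-segmentation predicate. A compound is a hit when it has at least
#' one qualifying treatment and is not excluded as irreproducible: the
#' wild-type reproducibility filter rejects compounds whose qualifying
#' treatments all lie in exactly one wild-type replicate, with no support
#' from the other replicate or a mutant background.
#'
#' @param table A \code{\link{screen_table}}.
#' @param config A \code{\link{ranking_config}}.
#' @return Data frame of class \code{hit_calls}, one row per compound:
#'   \code{is_hit}, \code{n_qualifying}, \code{excluded_as_irreproducible},
#'   \code{genotype_class}, \code{active_concentrations} (comma-separated),
#'   \code{single_concentration}, \code{best_ssmd}, \code{best_mean_diff}.
#'   Attribute \code{"qualifying"} is the per-treatment qualifying table.
#' @export
call_hits <- function(table, config = ranking_config()) {
  s <- summarize_table(table)
  s$qualifies <- direct_seg_predicate(s, config)
  q <- s[s$qualifies, , drop = FALSE]
  compounds <- sort(unique(table$compound_id))
  wt <- wt_experiments(attr(table, "experiments") %||% unique(table$experiment))

  rows <- lapply(compounds, function(cid) {
    qi <- q[q$compound_id == cid, , drop = FALSE]
    nq <- nrow(qi)
    irre <- FALSE
    if (nq > 0L && length(wt) == 2L) {
      exps <- unique(qi$experiment)
      irre <- length(exps) == 1L && exps %in% wt
    }
    concs <- sort(unique(qi$concentration_uM))
    data.frame(compound_id = cid,
               is_hit = nq > 0L && !irre,
               n_qualifying = nq,
               excluded_as_irreproducible = irre,
               active_concentrations = paste(concs, collapse = ","),
               single_concentration = length(concs) == 1L,
               best_ssmd = if (nq) max(qi$ssmd) else NA_real_,
               best_mean_diff = if (nq) max(qi$mean_diff) else NA_real_,
               stringsAsFactors = FALSE)
  })
  hits <- do.call(rbind, rows)
  attr(hits, "qualifying") <- q
  attr(hits, "summaries") <- s
  class(hits) <- c("hit_calls", "data.frame")
  genotype_profile(hits, table)
}

#' Genotype class of each hit compound
#'
#' Classifies the genetic-background dependence of qualifying treatments:
#' \code{her1_only} (qualifies in the her1 mutant and nowhere else; the
#' sensitized background revealed the compound), \code{her1_enhanced}
#' (qualifies in her1 with strictly higher segmentation mean than the best
#' analyzable wild-type treatment at the same concentration),
#' \code{hes6_suppressed} (qualifies in wild type and/or her1 at some
#' concentration where the analyzable hes6 treatment does not qualify),
#' \code{wild_type_supported} (all qualifying treatments in the wild-type
#' replicates), else \code{mixed}. Rules apply in that order; compounds with
#' no qualifying treatment get \code{NA}.
#'
#' @param hits Output of \code{\link{call_hits}}.
#' @param table The same \code{\link{screen_table}}.
#' @return \code{hits} with the \code{genotype_class} column filled.
#' @export
genotype_profile <- function(hits, table) {
  q <- attr(hits, "qualifying")
  s <- attr(hits, "summaries")
  wt <- wt_experiments(unique(table$experiment))
  has_hes6 <- "hes6" %in% unique(table$experiment)

  cls <- vapply(hits$compound_id, function(cid) {
    qi <- q[q$compound_id == cid, , drop = FALSE]
    if (nrow(qi) == 0L) return(NA_character_)
    exps <- unique(qi$experiment)
    si <- s[s$compound_id == cid, , drop = FALSE]

    if (identical(exps, "her1")) return("her1_only")

    if ("her1" %in% exps) {
      enhanced <- FALSE
      for (cc in unique(qi$concentration_uM[qi$experiment == "her1"])) {
        h <- qi$seg_mean[qi$experiment == "her1" & qi$concentration_uM == cc]
        wrows <- si[si$experiment %in% wt & si$concentration_uM == cc, , drop = FALSE]
        if (nrow(wrows) && max(h) > max(wrows$seg_mean)) enhanced <- TRUE
      }
      if (enhanced) return("her1_enhanced")
    }

    if (has_hes6) {
      for (cc in unique(qi$concentration_uM[qi$experiment %in% c(wt, "her1")])) {
        hrow <- si[si$experiment == "hes6" & si$concentration_uM == cc, , drop = FALSE]
        # suppression requires an analyzable hes6 treatment that fails to qualify
        if (nrow(hrow) && !any(hrow$qualifies)) return("hes6_suppressed")
      }
    }

    if (all(exps %in% wt)) return("wild_type_supported")
    "mixed"
  }, character(1))

  hits$genotype_class <- unname(cls)
  hits
}

#' Concentration-masking summary of the hit list
#'
#' Fraction of hits active at a single concentration (the masking signature:
#' a compound's direct phenotype visible in one dose window only) and hit
#' counts per concentration.
#'
#' @param hits Output of \code{\link{call_hits}}.
#' @return List with \code{fraction_single}, \code{n_hits},
#'   \code{hits_per_concentration}.
#' @export
concentration_masking <- function(hits) {
  h <- hits[hits$is_hit, , drop = FALSE]
  if (nrow(h) == 0L) {
    warning("concentration_masking: no hits")
    return(list(fraction_single = NA_real_, n_hits = 0L,
                hits_per_concentration = integer(0)))
  }
  concs <- strsplit(h$active_concentrations, ",", fixed = TRUE)
  per_conc <- table(as.numeric(unlist(concs)))
  list(fraction_single = mean(h$single_concentration),
       n_hits = nrow(h),
       hits_per_concentration = per_conc)
}

#' Screen-level count arithmetic
#'
#' Derived statistics of a completed screen's hit bookkeeping: the primary
#' hit frequency over the library, the pulse-retest positive rate, and the
#' combined hit total after adding pulse-revealed hits.
#'
#' @param n_primary Primary hit compounds.
#' @param n_library Library size.
#' @param n_pulse_positive Pulse-retest positives.
#' @param n_pulse_tested Compounds retested with the short pulse.
#' @return List with \code{hit_frequency_pct}, \code{pulse_positive_pct},
#'   \code{total_hits}, \code{treatments_per_compound} given the design.
#' @export
screen_counts_summary <- function(n_primary, n_library,
                                  n_pulse_positive = 0L, n_pulse_tested = 0L) {
  list(hit_frequency_pct = 100 * n_primary / n_library,
       pulse_positive_pct = if (n_pulse_tested > 0)
         100 * n_pulse_positive / n_pulse_tested else NA_real_,
       total_hits = n_primary + n_pulse_positive)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
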