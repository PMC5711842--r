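# Synthetic screen generator.
#
# Ordinal scores arise from a latent-severity model: each compound carries a
# class-specific latent severity and a per-parameter weight pattern; dose
# activation is a threshold step (effects are absent below the activation
# concentration and saturate above it, matching the all-or-nothing activity
# windows seen in concentration-series screens); per-embryo scores are the
# latent value plus Gaussian noise discretized at fixed cutpoints and clamped
# to [0, 3]; well vectors are the 3-of-5 consensus; lethality is drawn per
# treatment with probability increasing in the morphology (toxicity) latent.
# wt_A and wt_B share all latent values and differ only through noise
# realizations (plus an optional batch shift for stress tests).

#' Simulation configuration
#'
#' Defaults encode the reference screen design: 243 compounds, three
#' concentrations (2, 10, 50 uM), four experiments (two wild-type replicates
#' plus the her1 and hes6 clock mutants), five embryos per well. Planted
#' compound classes: \code{direct_seg} (the true hits: segmentation effects
#' with near-normal morphology inside a dose window), \code{seg_plus_morph}
#' (segmentation plus strong morphology defects), \code{morph_only},
#' \code{secondary_tail} (secondary tail appendage plus tail-shape defect),
#' \code{toxic} and \code{inactive}.
#'
#' @param n_compounds Number of compounds (default 243).
#' @param concentrations Screened concentrations in micromolar.
#' @param experiments Experiment labels; must include the two wild-type
#'   replicates \code{wt_A}/\code{wt_B} and may include \code{her1}/\code{hes6}.
#' @param class_proportions Named probability vector over compound classes.
#' @param noise_sd Latent-scale Gaussian noise per embryo and parameter.
#' @param score_cutpoints Three increasing latent thresholds mapping severity
#'   to ordinal scores 1/2/3.
#' @param lethality_scale,lethality_onset Hazard-style lethality curve
#'   \code{p = 1 - exp(-scale * max(0, morph_latent - onset))}; scale 0
#'   disables lethality.
#' @param n_embryos_per_well Embryos scored per well (default 5).
#' @param min_embryos Consensus support threshold (default 3).
#' @param her1_only_frac Fraction of direct_seg compounds active only in the
#'   her1 mutant (sub-threshold wild-type severity amplified by
#'   \code{her1_multiplier}).
#' @param hes6_suppressed_frac Fraction of direct_seg compounds whose
#'   segmentation effect is suppressed in the hes6 mutant.
#' @param batch_shift Systematic latent shift added to wt_B (default 0; used
#'   to stress-test the reproducibility filter).
#' @param fixed_patterns If TRUE, all compounds of a class share the
#'   canonical class parameter pattern (well-separated classes, for
#'   clustering-recovery experiments); default FALSE draws per-compound
#'   patterns.
#' @param window_mode \code{"sampled"} draws direct_seg activity windows so
#'   that two-thirds of hits are active at a single concentration;
#'   \code{"full"} makes every direct_seg compound active at all
#'   concentrations (no masking).
#' @param seed Integer seed controlling every random draw.
#' @return A list of class \code{sim_config}.
#' @export
sim_config <- function(n_compounds = 243L,
                       concentrations = c(2, 10, 50),
                       experiments = c("wt_A", "wt_B", "her1", "hes6"),
                       class_proportions = c(inactive = 0.60,
                                             direct_seg = 0.10,
                                             seg_plus_morph = 0.12,
                                             morph_only = 0.08,
                                             secondary_tail = 0.05,
                                             toxic = 0.05),
                       noise_sd = 0.3,
                       score_cutpoints = c(0.5, 1.5, 2.5),
                       lethality_scale = 0.7,
                       lethality_onset = 2,
                       n_embryos_per_well = 5L,
                       min_embryos = 3L,
                       her1_only_frac = 0.3,
                       hes6_suppressed_frac = 0.6,
                       batch_shift = 0,
                       fixed_patterns = FALSE,
                       window_mode = c("sampled", "full"),
                       seed = 1L) {
  window_mode <- match.arg(window_mode)
  classes <- c("inactive", "direct_seg", "seg_plus_morph", "morph_only",
               "secondary_tail", "toxic")
  if (is.null(names(class_proportions)) ||
      !all(names(class_proportions) %in% classes)) {
    stop_config(sprintf("class_proportions must be named with classes among: %s",
                        paste(classes, collapse = ", ")))
  }
  if (abs(sum(class_proportions) - 1) > 1e-8) {
    stop_config("class_proportions must sum to 1")
  }
  if (any(diff(score_cutpoints) <= 0) || length(score_cutpoints) != 3L) {
    stop_config("score_cutpoints must be 3 strictly increasing thresholds")
  }
  if (!all(c("wt_A", "wt_B") %in% experiments)) {
    stop_config("experiments must include the wild-type replicates wt_A and wt_B")
  }
  structure(list(
    n_compounds = as.integer(n_compounds),
    concentrations = sort(as.numeric(concentrations)),
    experiments = as.character(experiments),
    class_proportions = class_proportions,
    noise_sd = noise_sd,
    score_cutpoints = as.numeric(score_cutpoints),
    lethality_scale = lethality_scale,
    lethality_onset = lethality_onset,
    n_embryos_per_well = as.integer(n_embryos_per_well),
    min_embryos = as.integer(min_embryos),
    her1_only_frac = her1_only_frac,
    hes6_suppressed_frac = hes6_suppressed_frac,
    batch_shift = batch_shift,
    fixed_patterns = fixed_patterns,
    window_mode = window_mode,
    seed = as.integer(seed),
    schema = parameter_schema()
  ), class = "sim_config")
}

#' Lethality probability curve
#'
#' \code{p = 1 - exp(-scale * max(0, morph_latent - onset))}: no lethality
#' below the onset severity, saturating hazard above it; \code{scale = 0}
#' disables lethality entirely.
#'
#' @param morph_latent Latent morphology (toxicity) severity.
#' @param scale,onset Curve parameters.
#' @return Probability in [0, 1].
#' @export
lethality_prob <- function(morph_latent, scale = 0.7, onset = 2) {
  1 - exp(-scale * pmax(0, morph_latent - onset))
}

# Discretize latent values at the cutpoints, clamped to [0, 3].
discretize_scores <- function(x, cutpoints) {
  matrix(findInterval(x, cutpoints), nrow = nrow(x), ncol = ncol(x))
}

# Canonical per-class weight patterns over the 12 parameters (schema order:
# E H Y D A T | S BD AD TD PD BS).
canonical_patterns <- function(schema) {
  zeros <- stats::setNames(numeric(12), schema$codes)
  pat <- function(...) {
    w <- zeros
    v <- c(...)
    w[names(v)] <- v
    w
  }
  list(
    inactive = zeros,
    direct_seg = pat(BD = 1, PD = 0.8, TD = 0.6),
    # strong-morphology compounds disrupt boundaries along the whole axis
    seg_plus_morph = pat(BD = 1, AD = 0.8, TD = 0.9, PD = 0.9),
    morph_only = zeros,
    secondary_tail = pat(S = 1),
    toxic = zeros
  )
}

# Morphology-half weight patterns (applied to the toxicity latent).
canonical_morph_patterns <- function(schema) {
  zeros <- stats::setNames(numeric(12), schema$codes)
  all_morph <- zeros
  all_morph[schema$morphology] <- 1
  tail_pat <- zeros
  tail_pat[c("T", "E", "A")] <- c(1.2, 0.3, 0.3)
  list(
    inactive = zeros,
    direct_seg = all_morph,       # masking toxicity above the window
    seg_plus_morph = all_morph,
    morph_only = all_morph,
    secondary_tail = tail_pat,
    toxic = all_morph
  )
}

#' Draw per-compound latent profiles
#'
#' Uses the R random stream in its current state; \code{\link{simulate_screen}}
#' seeds the stream from the config before calling this.
#'
#' @param config A \code{\link{sim_config}}.
#' @return Data frame with one row per compound: class, latent effect sizes,
#'   activation/toxicity thresholds, genotype multipliers, and the 12
#'   segmentation/morphology weight columns (\code{w_*} applied to the
#'   segmentation latent, \code{m_*} to the morphology latent).
#' @export
draw_compound_profiles <- function(config) {
  n <- config$n_compounds
  schema <- config$schema
  p <- config$class_proportions
  cls <- sample(names(p), n, replace = TRUE, prob = as.numeric(p))
  compound_id <- sprintf("C%03d", seq_len(n))
  concs <- config$concentrations

  seg_pat <- canonical_patterns(schema)
  morph_pat <- canonical_morph_patterns(schema)

  W <- matrix(0, n, 12, dimnames = list(NULL, paste0("w_", schema$codes)))
  M <- matrix(0, n, 12, dimnames = list(NULL, paste0("m_", schema$codes)))
  seg_effect <- numeric(n)
  morph_effect <- numeric(n)      # main toxicity latent, at >= toxicity_threshold
  morph_low <- numeric(n)         # small within-window morphology latent
  activity_threshold <- rep(Inf, n)
  toxicity_threshold <- rep(Inf, n)
  her1_multiplier <- rep(1, n)
  hes6_multiplier <- rep(1, n)
  her1_only <- logical(n)
  hes6_suppressed <- logical(n)

  seg_codes <- schema$segmentation
  extra_codes <- setdiff(seg_codes, c("S", "BD"))
  nc <- length(concs)
  # activation-concentration weights (low/mid/high); uniform if the
  # concentration set is not the standard 3-point series
  act_prob <- if (nc == 3L) c(1 / 6, 1 / 2, 1 / 3) else rep(1 / nc, nc)
  tox_prob <- if (nc == 3L) c(0.2, 0.4, 0.4) else rep(1 / nc, nc)

  for (i in seq_len(n)) {
    k <- cls[i]
    W[i, ] <- seg_pat[[k]]
    M[i, ] <- morph_pat[[k]]
    if (k == "inactive") next

    if (!config$fixed_patterns && k %in% c("direct_seg", "seg_plus_morph")) {
      # per-compound axial pattern: boundary defects always engaged, plus
      # further segmentation codes at partial weight (3 for the axis-wide
      # seg_plus_morph phenotype, 1-3 for direct_seg)
      w <- stats::setNames(numeric(12), schema$codes)
      w["BD"] <- 1
      n_extra <- if (k == "seg_plus_morph") 3L else sample(1:3, 1L)
      extra <- sample(extra_codes, n_extra)
      w[extra] <- stats::runif(n_extra, 0.6, 1)
      W[i, ] <- w
    }

    if (k == "direct_seg") {
      her1_only[i] <- stats::runif(1) < config$her1_only_frac
      hes6_suppressed[i] <- stats::runif(1) < config$hes6_suppressed_frac
      if (her1_only[i]) {
        seg_effect[i] <- stats::runif(1, 0.15, 0.30)
        her1_multiplier[i] <- stats::runif(1, 5, 8)
      } else {
        seg_effect[i] <- stats::runif(1, 1.2, 2.8)
      }
      if (hes6_suppressed[i]) hes6_multiplier[i] <- 0.1
      if (config$window_mode == "full") {
        activity_threshold[i] <- concs[1L]
        toxicity_threshold[i] <- Inf
      } else {
        # activation at 2/10/50 uM w.p. 1/6, 1/2, 1/3; windows sized so that
        # two-thirds of direct hits are active at a single concentration
        a <- sample(concs, 1L, prob = act_prob)
        end <- if (nc == 3L && a == concs[2L] && stats::runif(1) < 2 / 3)
          concs[3L] else a
        activity_threshold[i] <- a
        above <- concs[concs > end]
        toxicity_threshold[i] <- if (length(above)) above[1L] else Inf
      }
      morph_effect[i] <- if (is.finite(toxicity_threshold[i]))
        stats::runif(1, 2.2, 3.2) else 0
      morph_low[i] <- stats::runif(1, 0, 0.3)
    } else if (k == "seg_plus_morph") {
      seg_effect[i] <- stats::runif(1, 1.5, 2.5)
      morph_effect[i] <- stats::runif(1, 2.2, 3.0)
      a <- sample(concs, 1L, prob = tox_prob)
      activity_threshold[i] <- a
      toxicity_threshold[i] <- a
    } else if (k == "morph_only") {
      morph_effect[i] <- stats::runif(1, 0.8, 1.8)
      toxicity_threshold[i] <- sample(concs, 1L, prob = tox_prob)
      if (!config$fixed_patterns) {
        M[i, paste0("m_", schema$morphology)] <- stats::runif(6, 0.7, 1)
      }
    } else if (k == "secondary_tail") {
      sev <- stats::runif(1, 1.6, 2.4)
      seg_effect[i] <- sev
      morph_effect[i] <- sev
      upper <- utils::tail(concs, min(2L, nc))
      a <- upper[sample.int(length(upper), 1L)]
      activity_threshold[i] <- a
      toxicity_threshold[i] <- a
    } else if (k == "toxic") {
      morph_effect[i] <- stats::runif(1, 3, 5)
      upper <- utils::tail(concs, min(2L, nc))
      toxicity_threshold[i] <- upper[sample.int(length(upper), 1L,
        prob = if (length(upper) == 2L) c(0.4, 0.6) else NULL)]
    }
  }

  out <- data.frame(compound_id = compound_id, compound_class = cls,
                    seg_effect = seg_effect, morph_effect = morph_effect,
                    morph_low = morph_low,
                    activity_threshold = activity_threshold,
                    toxicity_threshold = toxicity_threshold,
                    her1_multiplier = her1_multiplier,
                    hes6_multiplier = hes6_multiplier,
                    her1_only = her1_only,
                    hes6_suppressed = hes6_suppressed,
                    stringsAsFactors = FALSE)
  cbind(out, as.data.frame(W), as.data.frame(M))
}

# Latent severities for a profile grid (one row per treatment).
# Returns list(seg_sev, morph_sev) of length nrow(grid).
latent_severities <- function(grid, config) {
  mult <- rep(1, nrow(grid))
  mult[grid$experiment == "her1"] <- grid$her1_multiplier[grid$experiment == "her1"]
  mult[grid$experiment == "hes6"] <- grid$hes6_multiplier[grid$experiment == "hes6"]
  act <- as.numeric(grid$concentration_uM >= grid$activity_threshold)
  tox <- as.numeric(grid$concentration_uM >= grid$toxicity_threshold)
  seg_sev <- grid$seg_effect * mult * act
  morph_sev <- grid$morph_effect * tox + grid$morph_low * act
  list(seg_sev = seg_sev, morph_sev = morph_sev)
}

# Vectorized treatment simulation core. `grid` has one row per treatment
# with profile columns joined in. Consumes the R random stream in a fixed
# order: embryo noise first, then lethality uniforms.
simulate_treatments_core <- function(grid, config) {
  schema <- config$schema
  n <- nrow(grid)
  nemb <- config$n_embryos_per_well
  sev <- latent_severities(grid, config)

  Wseg <- as.matrix(grid[paste0("w_", schema$codes)])
  Wmor <- as.matrix(grid[paste0("m_", schema$codes)])
  latent <- Wseg * sev$seg_sev + Wmor * sev$morph_sev   # n x 12
  if (config$batch_shift != 0) {
    wb <- grid$experiment == "wt_B"
    latent[wb, ] <- latent[wb, ] + config$batch_shift
  }

  noise <- array(stats::rnorm(n * 12L * nemb, sd = config$noise_sd),
                 dim = c(n, 12L, nemb))
  support <- if (nemb < config$min_embryos)
    as.integer(ceiling(0.6 * nemb)) else config$min_embryos

  # Per-parameter consensus = support-th largest embryo score; scores are a
  # monotone transform of the noisy latent, so take the support-th largest
  # noisy latent and discretize once. Streaming top-k keeps this fully
  # vectorized over the (treatment, parameter) grid.
  tops <- replicate(support, matrix(-Inf, n, 12L), simplify = FALSE)
  for (e in seq_len(nemb)) {
    v <- latent + noise[, , e]
    carry <- v
    for (j in seq_len(support)) {
      new_j <- pmax(tops[[j]], carry)
      carry <- pmin(tops[[j]], carry)
      tops[[j]] <- new_j
    }
  }
  kth <- tops[[support]]
  scores <- discretize_scores(kth, config$score_cutpoints)
  scores[scores > schema$max_score] <- schema$max_score

  p_lethal <- if (config$lethality_scale > 0) {
    lethality_prob(sev$morph_sev, config$lethality_scale, config$lethality_onset)
  } else rep(0, n)
  lethal <- stats::runif(n) < p_lethal
  scores[lethal, ] <- NA_integer_

  list(scores = scores, lethal = lethal, p_lethal = p_lethal,
       seg_sev = sev$seg_sev, morph_sev = sev$morph_sev)
}

#' Simulate a single treatment
#'
#' Runs the generator for one (compound profile, concentration, experiment)
#' cell using the R random stream in its current state. Mainly useful for
#' unit-level inspection of the dose-activation and lethality rules; whole
#' screens should use \code{\link{simulate_screen}}.
#'
#' @param profile One row of \code{\link{draw_compound_profiles}} output.
#' @param concentration Concentration in micromolar (must be in the config set).
#' @param experiment Experiment label.
#' @param config A \code{\link{sim_config}}.
#' @return List with the treatment record fields (\code{vector} is NULL for
#'   lethal treatments) and the latent record (\code{seg_sev},
#'   \code{morph_sev}, \code{p_lethal}).
#' @export
simulate_treatment <- function(profile, concentration, experiment, config) {
  if (!concentration %in% config$concentrations) {
    stop_config(sprintf("concentration %s not in the screened set", concentration))
  }
  if (!experiment %in% config$experiments) {
    stop_config(sprintf("unknown experiment: %s", experiment))
  }
  grid <- cbind(profile,
                data.frame(concentration_uM = concentration,
                           experiment = experiment,
                           stringsAsFactors = FALSE))
  res <- simulate_treatments_core(grid, config)
  vec <- if (res$lethal[1L]) NULL else {
    stats::setNames(as.integer(res$scores[1L, ]), config$schema$codes)
  }
  list(compound_id = profile$compound_id,
       concentration = concentration, experiment = experiment,
       lethal = res$lethal[1L], vector = vec,
       n_embryos = config$n_embryos_per_well,
       seg_sev = res$seg_sev[1L], morph_sev = res$morph_sev[1L],
       p_lethal = res$p_lethal[1L])
}

#' Simulate a full factorial screen with ground truth
#'
#' Generates the complete compound x concentration x experiment table in
#' deterministic order under the config seed: identical configs give
#' byte-identical serialized tables.
#'
#' @param config A \code{\link{sim_config}}.
#' @return List with \code{table} (a \code{\link{screen_table}}) and
#'   \code{truth} (class \code{ground_truth}): \code{$profiles} per compound
#'   and \code{$treatments} per treatment with realized lethality and latent
#'   severities, aligned row-for-row with the table.
#' @export
simulate_screen <- function(config = sim_config()) {
  schema <- config$schema
  out <- with_seed(config$seed, {
    profiles <- draw_compound_profiles(config)
    grid <- expand.grid(experiment = config$experiments,
                        concentration_uM = config$concentrations,
                        compound_id = profiles$compound_id,
                        stringsAsFactors = FALSE)[, 3:1]
    # canonical order: compound, then concentration, then experiment
    grid <- grid[order(grid$compound_id, grid$concentration_uM,
                       match(grid$experiment, config$experiments)), ]
    rownames(grid) <- NULL
    grid <- merge(grid, profiles, by = "compound_id", sort = FALSE)
    grid <- grid[order(grid$compound_id, grid$concentration_uM,
                       match(grid$experiment, config$experiments)), ]
    rownames(grid) <- NULL
    res <- simulate_treatments_core(grid, config)
    list(profiles = profiles, grid = grid, res = res)
  })
  grid <- out$grid
  res <- out$res

  cidx <- match(grid$compound_id, out$profiles$compound_id)
  plate <- sprintf("%s_c%g_p%02d", grid$experiment, grid$concentration_uM,
                   (cidx - 1L) %/% 96L + 1L)
  wi <- (cidx - 1L) %% 96L
  well <- sprintf("%s%02d", LETTERS[wi %% 8L + 1L], wi %/% 8L + 1L)

  df <- data.frame(compound_id = grid$compound_id, plate = plate, well = well,
                   concentration_uM = grid$concentration_uM,
                   experiment = grid$experiment, lethal = res$lethal,
                   n_embryos = config$n_embryos_per_well,
                   n_scoreable = ifelse(res$lethal, 0L, config$n_embryos_per_well),
                   stringsAsFactors = FALSE)
  df <- cbind(df, as.data.frame(res$scores))
  names(df)[(ncol(df) - 11L):ncol(df)] <- schema$codes
  table <- screen_table(df, schema = schema,
                        experiments = config$experiments,
                        concentrations = config$concentrations)

  treatments <- data.frame(compound_id = grid$compound_id,
                           concentration_uM = grid$concentration_uM,
                           experiment = grid$experiment,
                           compound_class = grid$compound_class,
                           seg_sev = res$seg_sev, morph_sev = res$morph_sev,
                           p_lethal = res$p_lethal, lethal = res$lethal,
                           stringsAsFactors = FALSE)
  # realign truth rows to the normalized screen_table order
  tkey <- treatment_key(table$compound_id, table$concentration_uM,
                        table$experiment)
  gkey <- treatment_key(treatments$compound_id, treatments$concentration_uM,
                        treatments$experiment)
  treatments <- treatments[match(tkey, gkey), ]
  rownames(treatments) <- NULL

  truth <- structure(list(profiles = out$profiles, treatments = treatments,
                          config = config),
                     class = "ground_truth")
  list(table = table, truth = truth)
}

#' Planted true-hit compounds of a ground truth
#'
#' The planted hits are the \code{direct_seg} compounds: every such compound
#' has a nonempty activity window in which it shows segmentation defects with
#' near-normal morphology in at least the her1 mutant (her1-only hits) or in
#' both wild-type replicates.
#'
#' @param truth A \code{ground_truth}.
#' @return Character vector of compound ids.
#' @export
truth_hits <- function(truth) {
  truth$profiles$compound_id[truth$profiles$compound_class == "direct_seg"]
}

#' Write ground truth companion TSVs
#' @param truth A \code{ground_truth}.
#' @param dir Output directory (created if needed).
#' @return Invisibly, the two file paths.
#' @export
save_ground_truth <- function(truth, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  pp <- file.path(dir, "ground_truth_compounds.tsv")
  tp <- file.path(dir, "ground_truth_treatments.tsv")
  utils::write.table(truth$profiles, pp, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  utils::write.table(truth$treatments, tp, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(c(pp, tp))
}
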