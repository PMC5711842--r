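# SSMD / mean-difference statistics, rankings, predicate and hit calling.

test_that("summarize_treatment matches the arithmetic oracle on the worked example", {
  v <- c(0,0,1,0,0,1, 3,2,3,2,3,2)   # morphology half first
  s <- summarize_treatment(v)
  expect_equal(s$seg_mean, 2.5)
  expect_equal(s$morph_mean, 1 / 3)
  expect_equal(s$seg_var, 0.3)
  expect_equal(s$morph_var, 4 / 15)
  expect_equal(s$mean_diff, 2.5 - 1 / 3)
  expect_equal(s$ssmd, (2.5 - 1 / 3) / sqrt(0.3 + 4 / 15))
  expect_equal(s$ssmd, 2.878, tolerance = 1e-3)

  z <- summarize_treatment(rep(0, 12))
  expect_equal(z$ssmd, 0)
  expect_equal(z$mean_diff, 0)

  same <- summarize_treatment(c(1,2,3,0,1,2, 1,2,3,0,1,2))
  expect_equal(same$ssmd, 0)
  expect_equal(same$mean_diff, 0)

  # both variances zero, nonzero numerator -> signed infinity
  inf_pos <- summarize_treatment(c(rep(0, 6), rep(2, 6)))
  expect_identical(inf_pos$ssmd, Inf)
  inf_neg <- summarize_treatment(c(rep(2, 6), rep(0, 6)))
  expect_identical(inf_neg$ssmd, -Inf)

  expect_error(summarize_treatment(rep(0, 11)),
               class = "segscreen_validation_error")
})

test_that("SSMD/mean-diff antisymmetry and within-half permutation invariance", {
  set.seed(13)
  for (rep in 1:50) {
    v <- random_vector()
    s <- summarize_treatment(v)
    swapped <- summarize_treatment(c(v[7:12], v[1:6]))
    expect_equal(swapped$ssmd, -s$ssmd)
    expect_equal(swapped$mean_diff, -s$mean_diff)

    perm <- c(sample(1:6), sample(7:12))
    sp <- summarize_treatment(v[perm])
    expect_equal(sp$ssmd, s$ssmd)
    expect_equal(sp$mean_diff, s$mean_diff)
  }
})

test_that("summarize_table agrees with summarize_treatment row by row", {
  sim <- simulate_screen(sim_config(n_compounds = 15, seed = 8))
  tab <- filter_analyzable(sim$table, quiet = TRUE)
  st <- summarize_table(tab)
  for (i in sample(nrow(tab), 20)) {
    s <- summarize_treatment(unlist(tab[i, SCH$codes]))
    expect_equal(st$ssmd[i], s$ssmd)
    expect_equal(st$seg_var[i], s$seg_var)
    expect_equal(st$mean_diff[i], s$mean_diff)
  }
})

test_that("ranking exclusion rules fire with the documented reasons", {
  low_seg <- c(rep(0, 6), 1, rep(0, 5))            # seg_mean 1/6 < 0.2
  high_morph <- c(rep(3, 5), 2, rep(3, 6))         # morph_mean ~2.83
  keeper <- c(0,0,1,0,0,1, 3,2,3,2,3,2)
  tab <- make_table(make_row("C001", 10, "wt_A", low_seg),
                    make_row("C002", 10, "wt_A", high_morph),
                    make_row("C003", 10, "wt_A", keeper),
                    make_row("C004", 10, "wt_A", rep(0, 12)))
  r <- rank_by_ssmd(tab)
  excl <- attr(r, "excluded")
  expect_setequal(excl$compound_id, c("C001", "C002", "C004"))
  expect_match(excl$reason[excl$compound_id == "C001"], "seg_mean below 0.2")
  expect_match(excl$reason[excl$compound_id == "C002"], "morph_mean above 2")
  expect_equal(r$compound_id[1], "C003")

  # conjunction switch: only rows failing BOTH conditions are dropped
  rc <- rank_by_ssmd(tab, ranking_config(exclusion_rule = "conjunction"))
  expect_setequal(attr(rc, "excluded")$compound_id, character(0))
  expect_equal(nrow(rc), 4L)
})

test_that("mean-diff ranking applies strict boundary rules", {
  boundary_md <- c(1,1,1,1,1,1, 1,1,1,1,1,1)       # mean_diff = 0
  boundary_morph <- c(2,2,2,2,2,2, 3,3,3,3,3,3)    # morph_mean = 2 exactly
  keeper <- c(0,0,1,0,0,1, 3,2,3,2,3,2)
  tab <- make_table(make_row("C001", 10, "wt_A", boundary_md),
                    make_row("C002", 10, "wt_A", boundary_morph),
                    make_row("C003", 10, "wt_A", keeper))
  r <- rank_by_mean_diff(tab)
  expect_equal(r$compound_id, "C003")
  expect_equal(r$mean_diff[1], 2.5 - 1 / 3)
  expect_setequal(attr(r, "excluded")$compound_id, c("C001", "C002"))
})

test_that("rankings match the exhaustive brute-force sorter on random tables", {
  set.seed(17)
  for (trial in 1:40) {
    rows <- lapply(1:20, function(i)
      make_row(sprintf("C%03d", sample(1:15, 1) ), sample(c(2, 10, 50), 1),
               sample(c("wt_A", "wt_B", "her1", "hes6"), 1), random_vector()))
    tab <- tryCatch(screen_table(do.call(rbind, rows)),
                    segscreen_duplicate_error = function(e) NULL)
    if (is.null(tab)) next
    expect_ranking_matches(rank_by_ssmd(tab), tab, "ssmd")
    expect_ranking_matches(rank_by_mean_diff(tab), tab, "meandiff")
  }
})

test_that("ranking_concordance identities and errors", {
  keeper <- function(top) c(0,0,0,0,0,0, top, 1, 0, 0, 0, 0)
  tab <- make_table(make_row("C001", 10, "wt_A", keeper(3)),
                    make_row("C002", 10, "wt_A", keeper(2)),
                    make_row("C003", 10, "wt_A", c(0,0,0,0,0,0, 2,2,2,1,0,0)))
  ra <- rank_by_ssmd(tab)
  expect_equal(ranking_concordance(ra, ra)$rho, 1)
  rev_ra <- ra[nrow(ra):1, , drop = FALSE]
  expect_equal(ranking_concordance(ra, rev_ra)$rho, -1)
  expect_error(ranking_concordance(ra[1:2, ], ra[1:2, ]),
               class = "segscreen_data_error")
})

test_that("direct_seg_predicate captures the qualitative control phenotypes", {
  # DAPT-like: posterior boundary defects, normal morphology
  dapt <- summarize_treatment(c(rep(0, 6), 0, 3, 0, 0, 3, 1))
  expect_true(direct_seg_predicate(dapt))
  # SU5402-like: axis/yolk reduction dominating (morph_mean >= 2)
  su <- summarize_treatment(c(3,2,3,2,3,1, 0,3,0,0,3,1))
  expect_false(direct_seg_predicate(su))
  expect_false(direct_seg_predicate(summarize_treatment(rep(0, 12))))
})

test_that("call_hits applies the wild-type reproducibility filter", {
  q <- c(rep(0, 6), 0, 3, 0, 0, 2, 0)     # qualifying vector
  z <- rep(0, 12)
  # C001 qualifies in wt_A only -> excluded as irreproducible
  # C002 qualifies in wt_A and wt_B at 10 uM -> hit at a single concentration
  # C003 never qualifies -> not a hit, not excluded
  tab <- make_table(
    make_row("C001", 10, "wt_A", q), make_row("C001", 10, "wt_B", z),
    make_row("C001", 10, "her1", z), make_row("C001", 10, "hes6", z),
    make_row("C002", 10, "wt_A", q), make_row("C002", 10, "wt_B", q),
    make_row("C002", 10, "her1", z), make_row("C002", 10, "hes6", z),
    make_row("C003", 10, "wt_A", z), make_row("C003", 10, "wt_B", z),
    make_row("C003", 10, "her1", z), make_row("C003", 10, "hes6", z),
    experiments = c("wt_A", "wt_B", "her1", "hes6"))
  hits <- call_hits(tab)
  h1 <- hits[hits$compound_id == "C001", ]
  expect_false(h1$is_hit)
  expect_true(h1$excluded_as_irreproducible)
  h2 <- hits[hits$compound_id == "C002", ]
  expect_true(h2$is_hit)
  expect_false(h2$excluded_as_irreproducible)
  expect_equal(h2$active_concentrations, "10")
  expect_true(h2$single_concentration)
  h3 <- hits[hits$compound_id == "C003", ]
  expect_false(h3$is_hit)
  expect_false(h3$excluded_as_irreproducible)
  expect_equal(h3$n_qualifying, 0L)
})

test_that("genotype classes follow the documented rule order", {
  q <- c(rep(0, 6), 0, 3, 0, 0, 2, 0)
  q_weak <- c(rep(0, 6), 0, 2, 0, 0, 1, 0)
  z <- rep(0, 12)
  tab <- make_table(
    # her1-only
    make_row("A1", 10, "wt_A", z), make_row("A1", 10, "wt_B", z),
    make_row("A1", 10, "her1", q), make_row("A1", 10, "hes6", z),
    # hes6-suppressed (qualifies in wt+her1, analyzable hes6 does not qualify)
    make_row("A2", 10, "wt_A", q), make_row("A2", 10, "wt_B", q),
    make_row("A2", 10, "her1", q), make_row("A2", 10, "hes6", z),
    # qualifies everywhere with equal strength -> mixed
    make_row("A3", 10, "wt_A", q), make_row("A3", 10, "wt_B", q),
    make_row("A3", 10, "her1", q), make_row("A3", 10, "hes6", q),
    # her1-enhanced: qualifies in wt and her1, her1 strictly stronger; hes6 too
    make_row("A4", 10, "wt_A", q_weak), make_row("A4", 10, "wt_B", q_weak),
    make_row("A4", 10, "her1", q), make_row("A4", 10, "hes6", q_weak),
    # wild-type supported only (hes6 lethal, so no suppression evidence)
    make_row("A5", 10, "wt_A", q), make_row("A5", 10, "wt_B", q),
    make_row("A5", 10, "her1", z), make_row("A5", 10, "hes6", NULL, lethal = TRUE),
    experiments = c("wt_A", "wt_B", "her1", "hes6"))
  hits <- call_hits(tab)
  cls <- setNames(hits$genotype_class, hits$compound_id)
  expect_equal(unname(cls["A1"]), "her1_only")
  expect_equal(unname(cls["A2"]), "hes6_suppressed")
  expect_equal(unname(cls["A3"]), "mixed")
  expect_equal(unname(cls["A4"]), "her1_enhanced")
  expect_equal(unname(cls["A5"]), "wild_type_supported")
})

test_that("concentration_masking summarizes single-concentration activity", {
  q <- c(rep(0, 6), 0, 3, 0, 0, 2, 0)
  z <- rep(0, 12)
  tab <- make_table(
    make_row("B1", 10, "wt_A", q), make_row("B1", 10, "wt_B", q),
    make_row("B1", 2, "wt_A", z), make_row("B1", 50, "wt_A", z),
    make_row("B2", 10, "wt_A", q), make_row("B2", 10, "wt_B", q),
    make_row("B2", 50, "wt_A", q), make_row("B2", 50, "wt_B", q),
    make_row("B3", 2, "wt_A", q), make_row("B3", 2, "wt_B", q),
    experiments = c("wt_A", "wt_B"))
  cm <- concentration_masking(call_hits(tab))
  expect_equal(cm$fraction_single, 2 / 3)
  expect_equal(cm$n_hits, 3L)
  expect_equal(unname(cm$hits_per_concentration[["10"]]), 2L)

  none <- make_table(make_row("B9", 10, "wt_A", z))
  expect_warning(cm0 <- concentration_masking(call_hits(none)), "no hits")
  expect_equal(cm0$n_hits, 0L)
})

test_that("noise-free screens are recovered perfectly; default noise nearly so", {
  cfg <- sim_config(n_compounds = 80, noise_sd = 0, lethality_scale = 0,
                    seed = 21)
  sim <- simulate_screen(cfg)
  hits <- call_hits(sim$table)
  called <- hits$compound_id[hits$is_hit]
  truth <- truth_hits(sim$truth)
  expect_setequal(called, truth)

  simn <- simulate_screen(sim_config(n_compounds = 80, seed = 22))
  hitsn <- call_hits(simn$table)
  calledn <- hitsn$compound_id[hitsn$is_hit]
  truthn <- truth_hits(simn$truth)
  if (length(calledn)) expect_gte(mean(calledn %in% truthn), 0.9)
  expect_gte(mean(truthn %in% calledn), 0.9)
})

test_that("screen count arithmetic", {
  s <- screen_counts_summary(22, 243, 7, 25)
  expect_equal(s$hit_frequency_pct, 100 * 22 / 243)
  expect_equal(s$pulse_positive_pct, 28)
  expect_equal(s$total_hits, 29)
})
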