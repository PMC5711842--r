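# Correlation distance, deterministic UPGMA, flat cuts, profiles, Newick.

test_that("distance_matrix computes 1 - Pearson and excludes constant vectors", {
  v1 <- c(0,0,0,0,0,0, 3,3,0,0,3,0)
  v2 <- v1
  v3 <- 3 - v1
  v4 <- c(1,0,2,0,1,0, 0,3,1,0,2,1)
  m <- rbind(a = v1, b = v2, c = v3, d = v4, e = rep(2, 12))
  d <- distance_matrix(m)
  expect_equal(attr(d, "excluded_constant"), "e")
  expect_equal(unname(d["a", "b"]), 0)
  expect_equal(unname(d["a", "c"]), 2)
  for (i in rownames(d)) for (j in rownames(d)) {
    expect_equal(d[i, j], 1 - oracle_pearson(m[i, ], m[j, ]),
                 tolerance = 1e-12)
  }
  expect_error(distance_matrix(rbind(rep(0, 12), rep(1, 12), v1)),
               class = "segscreen_data_error")
})

test_that("average_linkage handles the base cases by hand", {
  d2 <- matrix(c(0, 0.2, 0.2, 0), 2, 2, dimnames = list(c("A", "B"), c("A", "B")))
  dend <- average_linkage(d2)
  expect_equal(dend$height, 0.2)
  expect_equal(dend$merge, matrix(c(-1L, -2L), 1, 2))

  d3 <- matrix(1, 3, 3, dimnames = list(c("A", "B", "C"), c("A", "B", "C")))
  diag(d3) <- 0
  d3["A", "B"] <- d3["B", "A"] <- 0.1
  dend3 <- average_linkage(d3)
  expect_equal(dend3$height, c(0.1, 1.0))
  sets <- dendro_merge_sets(dend3)
  expect_equal(sets[[1]]$members, c("A", "B"))
  expect_equal(sets[[2]]$members, c("A", "B", "C"))

  bad <- d3; bad[1, 2] <- 5
  expect_error(average_linkage(bad), class = "segscreen_validation_error")
})

test_that("average_linkage matches the brute-force oracle on random instances", {
  set.seed(31)
  for (trial in 1:40) {
    n <- sample(3:7, 1)
    labs <- sprintf("L%02d", sample(1:20, n))
    d <- matrix(0, n, n, dimnames = list(labs, labs))
    d[upper.tri(d)] <- runif(n * (n - 1) / 2, 0.01, 2)
    d <- d + t(d)
    got <- dendro_merge_sets(average_linkage(d))
    want <- oracle_average_linkage(d)
    for (k in seq_along(want)) {
      expect_equal(got[[k]]$members, want[[k]]$members)
      expect_equal(got[[k]]$height, want[[k]]$height, tolerance = 1e-9)
    }
    # heights are monotone along the merge sequence
    expect_true(all(diff(dendro_merge_sets(average_linkage(d)) |>
                           vapply(`[[`, 0, "height")) >= -1e-12))
  }
})

test_that("average_linkage agrees with stats::hclust on tie-free instances", {
  set.seed(32)
  n <- 12
  labs <- sprintf("L%02d", 1:n)
  d <- matrix(0, n, n, dimnames = list(labs, labs))
  d[upper.tri(d)] <- runif(n * (n - 1) / 2, 0.01, 2)
  d <- d + t(d)
  dend <- average_linkage(d)
  hc <- stats::hclust(stats::as.dist(d), method = "average")
  expect_equal(sort(dend$height), sort(hc$height), tolerance = 1e-12)
  expect_equal(stats::cophenetic(as.hclust(dend)),
               stats::cophenetic(hc), tolerance = 1e-12)
})

test_that("cut_clusters recovers planted block structure at the 0.6 cutoff", {
  base1 <- c(0,0,0,0,0,0, 3,3,0,0,3,0)
  base2 <- c(3,0,3,0,3,0, 0,0,3,3,0,3)
  jitter_vec <- function(v) { w <- v; w[w == 3] <- sample(2:3, sum(w == 3), TRUE); w }
  set.seed(5)
  m <- rbind(g1a = base1, g1b = jitter_vec(base1), g1c = jitter_vec(base1),
             g2a = base2, g2b = jitter_vec(base2))
  d <- distance_matrix(m)
  cl <- cut_clusters(average_linkage(d), cutoff_correlation = 0.6)
  a <- cl$assignment
  expect_equal(length(unique(a$cluster[grepl("^g1", a$label)])), 1L)
  expect_equal(length(unique(a$cluster[grepl("^g2", a$label)])), 1L)
  expect_false(a$cluster[a$label == "g1a"] == a$cluster[a$label == "g2a"])

  # extreme cutoffs: one cluster / all singletons (on pairwise-distinct vectors)
  one <- cut_clusters(average_linkage(d), cutoff_correlation = -1)
  expect_equal(length(unique(one$assignment$cluster)), 1L)
  ms <- matrix(0, 4, 12, dimnames = list(sprintf("s%d", 1:4), NULL))
  for (i in 1:4) ms[i, 6 + i] <- 3
  ds <- distance_matrix(ms)
  sing <- cut_clusters(average_linkage(ds), cutoff_correlation = 1)
  expect_equal(length(unique(sing$assignment$cluster)), 4L)

  expect_error(cut_clusters(average_linkage(d), 1.5),
               class = "segscreen_config_error")
})

test_that("cluster assignment is invariant to input row order", {
  set.seed(41)
  m <- do.call(rbind, lapply(1:8, function(i) random_vector()))
  rownames(m) <- sprintf("t%02d", 1:8)
  m <- m[apply(m, 1, stats::sd) > 0, , drop = FALSE]
  d <- distance_matrix(m)
  a1 <- cut_clusters(average_linkage(d), 0.6)$assignment
  perm <- sample(nrow(m))
  d2 <- distance_matrix(m[perm, , drop = FALSE])
  a2 <- cut_clusters(average_linkage(d2), 0.6)$assignment
  part <- function(a) unname(split(a$label, a$cluster))
  expect_setequal(lapply(part(a1), sort), lapply(part(a2), sort))
})

test_that("planted classes are recovered and labeled from a well-separated screen", {
  cfg <- sim_config(n_compounds = 80,
                    class_proportions = c(inactive = 0.40, direct_seg = 0.20,
                                          secondary_tail = 0.20,
                                          seg_plus_morph = 0.20),
                    noise_sd = 0.1, lethality_scale = 0,
                    fixed_patterns = TRUE, window_mode = "full",
                    her1_only_frac = 0, hes6_suppressed_frac = 0,
                    seed = 51)
  sim <- simulate_screen(cfg)
  m <- treatment_vectors(sim$table)
  d <- distance_matrix(m)
  dend <- average_linkage(d)
  cl <- cut_clusters(dend, 0.6)
  a <- cl$assignment

  cid <- vapply(strsplit(a$label, "|", fixed = TRUE), `[[`, "", 1L)
  truth_class <- sim$truth$profiles$compound_class[
    match(cid, sim$truth$profiles$compound_id)]
  ari <- adjusted_rand(a$cluster, truth_class)
  expect_gte(ari, 0.9)

  prof <- cluster_profiles(cl, sim$table)
  lab_of <- function(klass) {
    cls <- a$cluster[truth_class == klass]
    main <- as.integer(names(sort(table(cls), decreasing = TRUE))[1])
    prof$label[prof$cluster == main]
  }
  expect_equal(lab_of("direct_seg"), "first_class")
  expect_equal(lab_of("secondary_tail"), "secondary_tail")
  expect_equal(lab_of("seg_plus_morph"), "seg_plus_morph")
})

test_that("low-signal clusters are labeled other", {
  m <- rbind(a = c(1, rep(0, 11)), b = c(1, rep(0, 10), 1),
             c = c(0, 1, rep(0, 10)))
  tabrows <- list(make_row("a", 10, "wt_A", m["a", ]),
                  make_row("b", 10, "wt_A", m["b", ]),
                  make_row("c", 10, "wt_A", m["c", ]))
  tab <- do.call(make_table, tabrows)
  d <- distance_matrix(treatment_vectors(tab))
  cl <- cut_clusters(average_linkage(d), 0)
  prof <- cluster_profiles(cl, tab)
  expect_true(all(prof$label %in% c("other", "first_class")))
  expect_true(all(prof$label[prof$size < 2] == "other"))
})

test_that("select_pulse_candidates samples uniformly and deterministically", {
  assign <- list(assignment = data.frame(
    label = treatment_key(sprintf("C%02d", 1:4), 10, "wt_A"),
    cluster = 1L, stringsAsFactors = FALSE))
  prof <- data.frame(cluster = 1L, label = "seg_plus_morph",
                     stringsAsFactors = FALSE)
  all4 <- select_pulse_candidates(assign, prof, "seg_plus_morph", 4, seed = 1)
  expect_setequal(all4, sprintf("C%02d", 1:4))
  expect_identical(select_pulse_candidates(assign, prof, "seg_plus_morph", 2, 7),
                   select_pulse_candidates(assign, prof, "seg_plus_morph", 2, 7))
  expect_error(select_pulse_candidates(assign, prof, "seg_plus_morph", 5, 1),
               class = "segscreen_data_error")
  expect_error(select_pulse_candidates(assign, prof, "first_class", 1, 1),
               class = "segscreen_data_error")

  # uniformity over pairs: 6 possible pairs of 4 compounds
  draws <- vapply(1:3000, function(i)
    paste(select_pulse_candidates(assign, prof, "seg_plus_morph", 2, i),
          collapse = "+"), "")
  freq <- table(draws) / 3000
  se <- sqrt((1 / 6) * (5 / 6) / 3000)
  expect_equal(length(freq), 6L)
  expect_true(all(abs(freq - 1 / 6) < 4 * se))
})

test_that("to_newick uses the ultrametric height-splitting convention and round-trips", {
  d2 <- matrix(c(0, 0.2, 0.2, 0), 2, 2, dimnames = list(c("A", "B"), c("A", "B")))
  expect_equal(to_newick(average_linkage(d2)), "(A:0.1,B:0.1);")

  set.seed(61)
  n <- 9
  labs <- sprintf("T%02d", 1:n)
  d <- matrix(0, n, n, dimnames = list(labs, labs))
  d[upper.tri(d)] <- runif(n * (n - 1) / 2, 0.05, 2)
  d <- d + t(d)
  dend <- average_linkage(d)
  tree <- ape::read.tree(text = to_newick(dend))
  coph_tree <- ape::cophenetic.phylo(tree)
  coph_dend <- as.matrix(stats::cophenetic(as.hclust(dend)))
  expect_equal(coph_tree[labs, labs], coph_dend[labs, labs], tolerance = 1e-6)
})

test_that("cluster outputs export to files", {
  sim <- simulate_screen(sim_config(n_compounds = 30, seed = 71))
  d <- distance_matrix(treatment_vectors(sim$table))
  dend <- average_linkage(d)
  cl <- cut_clusters(dend, 0.6)
  prof <- cluster_profiles(cl, sim$table)
  dir <- withr::local_tempdir()
  paths <- export_clusters(cl, prof, dend, dir)
  expect_true(all(file.exists(paths)))
  nwk <- readLines(file.path(dir, "dendrogram.nwk"))
  expect_match(nwk, ";$")
})
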