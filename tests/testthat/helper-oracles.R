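# Fixture builders and independent brute-force oracles used across tests.

SCH <- parameter_schema()

# One treatment row; `scores` is a length-12 vector in schema order or NULL
# for an unscored/lethal well.
make_row <- function(compound, conc, exp, scores = NULL, lethal = FALSE,
                     n_embryos = 5L) {
  row <- data.frame(compound_id = compound, plate = "P1", well = "A01",
                    concentration_uM = conc, experiment = exp,
                    lethal = lethal, n_embryos = n_embryos,
                    n_scoreable = if (lethal) 0L else n_embryos,
                    stringsAsFactors = FALSE)
  sc <- if (is.null(scores)) rep(NA_integer_, 12) else as.integer(scores)
  row[SCH$codes] <- as.list(sc)
  row
}

make_table <- function(..., experiments = NULL, concentrations = NULL) {
  screen_table(do.call(rbind, list(...)), schema = SCH,
               experiments = experiments, concentrations = concentrations)
}

random_vector <- function() sample(0:3, 12, replace = TRUE)

# --- textbook-formula oracles (kept independent of package internals) ------

oracle_pearson <- function(x, y) {
  mx <- sum(x) / length(x)
  my <- sum(y) / length(y)
  sum((x - mx) * (y - my)) /
    sqrt(sum((x - mx)^2) * sum((y - my)^2))
}

# SSMD / mean-diff summary by direct arithmetic (n-1 variances).
oracle_summary <- function(v) {
  morph <- as.numeric(v[1:6])
  seg <- as.numeric(v[7:12])
  sm <- sum(seg) / 6
  mm <- sum(morph) / 6
  sv <- sum((seg - sm)^2) / 5
  mv <- sum((morph - mm)^2) / 5
  num <- sm - mm
  den <- sv + mv
  ssmd <- if (den > 0) num / sqrt(den) else if (num == 0) 0 else sign(num) * Inf
  list(seg_mean = sm, morph_mean = mm, seg_var = sv, morph_var = mv,
       ssmd = ssmd, mean_diff = num)
}

# Exhaustive ranking oracle: per-row oracle summaries, rule-based exclusion,
# then a plain order() with the documented tie-break keys.
oracle_rank <- function(tab, method = c("ssmd", "meandiff")) {
  method <- match.arg(method)
  scores <- as.matrix(as.data.frame(tab)[SCH$codes])
  keep <- !tab$lethal & rowSums(is.na(scores)) == 0
  tab <- tab[keep, , drop = FALSE]
  scores <- scores[keep, , drop = FALSE]
  ss <- t(apply(scores, 1, function(v) unlist(oracle_summary(v))))
  df <- cbind(tab[c("compound_id", "concentration_uM", "experiment")],
              as.data.frame(ss))
  if (method == "ssmd") {
    keep2 <- !(df$seg_mean < 0.2 | df$morph_mean > 2)
    primary <- "ssmd"
  } else {
    keep2 <- df$morph_mean < 2 & df$mean_diff > 0
    primary <- "mean_diff"
  }
  df <- df[keep2, , drop = FALSE]
  df <- df[order(-df[[primary]], -df$mean_diff, df$compound_id,
                 df$concentration_uM, df$experiment), , drop = FALSE]
  rownames(df) <- NULL
  df
}

# Ranking oracle check robust to float ties: (1) the retained treatment set
# equals the oracle's, (2) every summary value matches the oracle within
# tolerance, (3) the returned order is a valid sort under the documented
# comparator applied to the returned values themselves (strict descent or
# documented tie-breaks). Mathematically equal ssmd values from different
# vectors can round differently under different formulas, so comparing raw
# list positions against the oracle is ill-posed at ties.
expect_ranking_matches <- function(got, tab, method) {
  want <- oracle_rank(tab, method)
  kg <- paste(got$compound_id, got$concentration_uM, got$experiment)
  kw <- paste(want$compound_id, want$concentration_uM, want$experiment)
  expect_setequal(kg, kw)
  idx <- match(kg, kw)
  expect_equal(got$ssmd, want$ssmd[idx], tolerance = 1e-9)
  expect_equal(got$mean_diff, want$mean_diff[idx], tolerance = 1e-9)
  primary <- if (method == "ssmd") got$ssmd else got$mean_diff
  n <- nrow(got)
  if (n > 1L) {
    ok <- vapply(seq_len(n - 1L), function(i) {
      if (primary[i] > primary[i + 1]) return(TRUE)
      if (primary[i] < primary[i + 1]) return(FALSE)
      if (got$mean_diff[i] > got$mean_diff[i + 1]) return(TRUE)
      if (got$mean_diff[i] < got$mean_diff[i + 1]) return(FALSE)
      if (got$compound_id[i] != got$compound_id[i + 1])
        return(got$compound_id[i] < got$compound_id[i + 1])
      if (got$concentration_uM[i] != got$concentration_uM[i + 1])
        return(got$concentration_uM[i] < got$concentration_uM[i + 1])
      got$experiment[i] < got$experiment[i + 1]
    }, logical(1))
    expect_true(all(ok))
  }
}

# Brute-force average linkage from the definition: inter-cluster distance is
# the mean of all pairwise leaf distances taken from the ORIGINAL matrix
# (no Lance-Williams recursion). Same tie-break rule as the implementation.
oracle_average_linkage <- function(d) {
  labels <- rownames(d)
  clusters <- as.list(seq_len(nrow(d)))
  merges <- list()
  while (length(clusters) > 1L) {
    best <- NULL
    for (i in seq_along(clusters)) {
      for (j in seq_along(clusters)) {
        if (j <= i) next
        dd <- mean(d[clusters[[i]], clusters[[j]]])
        reps <- sort(c(min(labels[clusters[[i]]]), min(labels[clusters[[j]]])))
        key <- paste(reps, collapse = "\r")
        if (is.null(best) || dd < best$d ||
            (dd == best$d && key < best$key)) {
          best <- list(i = i, j = j, d = dd, key = key)
        }
      }
    }
    members <- sort(c(clusters[[best$i]], clusters[[best$j]]))
    merges[[length(merges) + 1L]] <- list(members = sort(labels[members]),
                                          height = best$d)
    clusters[[best$i]] <- members
    clusters[[best$j]] <- NULL
  }
  merges
}

# Leaf-label sets of each merge of a seg_dendrogram, for comparison with the
# oracle's merge sequence.
dendro_merge_sets <- function(dend) {
  sets <- vector("list", nrow(dend$merge))
  for (k in seq_len(nrow(dend$merge))) {
    kids <- dend$merge[k, ]
    mem <- c(if (kids[1] < 0) -kids[1] else NULL,
             if (kids[2] < 0) -kids[2] else NULL)
    for (kid in kids[kids > 0]) mem <- c(mem, attr(sets[[kid]], "idx"))
    sets[[k]] <- structure(sort(dend$labels[mem]), idx = mem)
  }
  lapply(seq_along(sets), function(k)
    list(members = as.character(sets[[k]]), height = dend$height[k]))
}

# Adjusted Rand index between two labelings.
adjusted_rand <- function(a, b) {
  tab <- table(a, b)
  choose2 <- function(x) x * (x - 1) / 2
  sum_ij <- sum(choose2(tab))
  sum_i <- sum(choose2(rowSums(tab)))
  sum_j <- sum(choose2(colSums(tab)))
  n2 <- choose2(sum(tab))
  exp_idx <- sum_i * sum_j / n2
  max_idx <- (sum_i + sum_j) / 2
  if (max_idx == exp_idx) return(1)
  (sum_ij - exp_idx) / (max_idx - exp_idx)
}

# Hand sums-of-squares two-way ANOVA (no interaction, one obs per cell) for
# the concentration factor.
oracle_anova <- function(counts) {
  y <- counts$count
  a <- factor(counts$concentration_uM)
  b <- factor(counts$experiment)
  gm <- mean(y)
  ssa <- sum(tapply(y, a, function(v) length(v) * (mean(v) - gm)^2))
  ssb <- sum(tapply(y, b, function(v) length(v) * (mean(v) - gm)^2))
  sst <- sum((y - gm)^2)
  sse <- sst - ssa - ssb
  dfa <- nlevels(a) - 1
  dfb <- nlevels(b) - 1
  dfe <- length(y) - 1 - dfa - dfb
  f <- (ssa / dfa) / (sse / dfe)
  list(f_conc = f, p_conc = stats::pf(f, dfa, dfe, lower.tail = FALSE))
}
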