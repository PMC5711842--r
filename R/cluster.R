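# Hierarchical clustering of phenotypic vectors.
#
# Distance is 1 - Pearson correlation along the 12-score vector (range
# [0, 2]; not a metric -- no triangle inequality -- but a valid
# dissimilarity for average linkage, which is monotone). Agglomeration is
# deterministic: ties in the minimal inter-cluster distance are broken by
# the lexicographically earliest pair of cluster representative labels, so
# results are invariant to input row order and platform.

#' Score matrix of clusterable treatments
#'
#' Extracts analyzable treatments with at least one nonzero score and a
#' nonconstant vector (all-zero "no phenotype" rows carry no correlation
#' information), labeled \code{compound|concentration|experiment}.
#'
#' @param table A \code{\link{screen_table}}.
#' @param aggregate If \code{"treatment"} (default) one row per treatment;
#'   \code{"compound"} averages each compound's analyzable vectors first.
#' @return Numeric matrix with treatment (or compound) row labels.
#' @export
treatment_vectors <- function(table, aggregate = c("treatment", "compound")) {
  aggregate <- match.arg(aggregate)
  tab <- filter_analyzable(table, quiet = TRUE)
  m <- score_matrix(tab)
  if (aggregate == "compound") {
    m <- do.call(rbind, lapply(split(seq_len(nrow(m)), tab$compound_id),
                               function(i) colMeans(m[i, , drop = FALSE])))
  }
  m
}

#' Pairwise correlation-distance matrix
#'
#' Constant (zero-variance) vectors are excluded and listed rather than
#' silently given distance 0.
#'
#' @param vectors Numeric matrix, one labeled row per phenotypic vector.
#' @return Symmetric matrix of \code{1 - r} distances with zero diagonal and
#'   attribute \code{"excluded_constant"} (labels of dropped rows).
#' @export
distance_matrix <- function(vectors) {
  m <- as.matrix(vectors)
  if (is.null(rownames(m))) rownames(m) <- sprintf("v%03d", seq_len(nrow(m)))
  sds <- apply(m, 1, stats::sd)
  excluded <- rownames(m)[sds == 0]
  m <- m[sds > 0, , drop = FALSE]
  if (nrow(m) < 2L) {
    stop_data("distance_matrix: fewer than 2 nonconstant vectors")
  }
  d <- 1 - stats::cor(t(m))
  diag(d) <- 0
  d[abs(d) < 1e-15] <- 0
  structure(d, excluded_constant = excluded)
}

#' Agglomerative average-linkage clustering
#'
#' UPGMA-style agglomeration: at each step the pair of clusters with minimal
#' mean pairwise inter-cluster distance is merged; exact ties are broken by
#' the lexicographically earliest pair of cluster representatives (each
#' cluster represented by its smallest leaf label).
#'
#' @param dist Symmetric nonnegative distance matrix with row/column labels
#'   (e.g. from \code{\link{distance_matrix}}).
#' @return Object of class \code{seg_dendrogram}: \code{merge} (hclust
#'   convention: negative entries are leaves, positive entries earlier
#'   merges), \code{height}, \code{labels}, plus the
#'   \code{"excluded_constant"} attribute carried over from the input.
#' @export
average_linkage <- function(dist) {
  d <- unclass(as.matrix(dist))
  n <- nrow(d)
  if (n < 2L) stop_data("average_linkage: need at least 2 items")
  if (!isTRUE(all.equal(d, t(d), tolerance = 1e-12))) {
    stop_validation("average_linkage: distance matrix must be symmetric")
  }
  if (any(d < 0)) stop_validation("average_linkage: negative distances")
  labels <- rownames(d)
  if (is.null(labels)) labels <- sprintf("v%03d", seq_len(n))

  # active cluster bookkeeping
  id <- -seq_len(n)              # hclust convention entry for each cluster
  size <- rep(1L, n)
  rep_lab <- labels              # lexicographic representative
  active <- rep(TRUE, n)
  cd <- d                        # cluster-distance matrix (average linkage)
  merge <- matrix(0L, n - 1L, 2L)
  height <- numeric(n - 1L)

  for (step in seq_len(n - 1L)) {
    act <- which(active)
    sub <- cd[act, act, drop = FALSE]
    sub[lower.tri(sub, diag = TRUE)] <- Inf
    mn <- min(sub)
    cand <- which(sub == mn, arr.ind = TRUE)
    # tie-break: earliest (rep_i, rep_j) pair, each pair sorted
    keys <- apply(cand, 1, function(ij) {
      labs <- sort(c(rep_lab[act[ij[1]]], rep_lab[act[ij[2]]]))
      paste(labs, collapse = "\r")
    })
    pick <- cand[order(keys)[1L], ]
    i <- act[min(pick)]
    j <- act[max(pick)]

    # record merge (hclust convention: negative entries are singletons);
    # children ordered by representative label so exports are deterministic
    merge[step, ] <- if (rep_lab[i] <= rep_lab[j]) c(id[i], id[j]) else
      c(id[j], id[i])
    height[step] <- mn

    # Lance-Williams average-linkage update onto slot i
    others <- setdiff(act, c(i, j))
    if (length(others)) {
      newd <- (size[i] * cd[i, others] + size[j] * cd[j, others]) /
        (size[i] + size[j])
      cd[i, others] <- newd
      cd[others, i] <- newd
    }
    size[i] <- size[i] + size[j]
    rep_lab[i] <- min(rep_lab[i], rep_lab[j])
    id[i] <- step
    active[j] <- FALSE
  }

  structure(list(merge = merge, height = height, labels = labels, n = n),
            class = "seg_dendrogram",
            excluded_constant = attr(dist, "excluded_constant"))
}

#' @export
print.seg_dendrogram <- function(x, ...) {
  cat(sprintf("<seg_dendrogram> %d leaves, %d merges, heights [%.3g, %.3g]\n",
              x$n, length(x$height), min(x$height), max(x$height)))
  invisible(x)
}

# Leaf display order via depth-first traversal (for as.hclust).
dendro_order <- function(dend) {
  leaves <- function(node) {
    if (node < 0) return(-node)
    c(leaves(dend$merge[node, 1L]), leaves(dend$merge[node, 2L]))
  }
  leaves(nrow(dend$merge))
}

#' Convert to a base-R hclust object
#' @param x A \code{seg_dendrogram}.
#' @param ... Unused.
#' @return An \code{hclust} object (enables \code{plot}, \code{cutree}, ...).
#' @export
as.hclust.seg_dendrogram <- function(x, ...) {
  structure(list(merge = x$merge, height = x$height, order = dendro_order(x),
                 labels = x$labels, method = "average",
                 dist.method = "correlation"),
            class = "hclust")
}

#' Flat clusters at a correlation cutoff
#'
#' Cuts the dendrogram at distance threshold \code{1 - cutoff_correlation}
#' (the default cutoff 0.6 gives threshold 0.4): flat clusters are the
#' maximal subtrees whose merge heights all lie at or below the threshold;
#' unmerged leaves become singletons. Cluster ids are assigned in
#' lexicographic order of each cluster's smallest member label.
#'
#' @param dend A \code{seg_dendrogram}.
#' @param cutoff_correlation Correlation cutoff in [-1, 1] (default 0.6).
#' @return List of class \code{cluster_assignment}: \code{assignment} data
#'   frame (label, cluster), \code{cutoff_correlation}, \code{threshold},
#'   \code{excluded_constant}.
#' @export
cut_clusters <- function(dend, cutoff_correlation = 0.6) {
  if (cutoff_correlation < -1 || cutoff_correlation > 1) {
    stop_config("cutoff_correlation must be in [-1, 1]")
  }
  threshold <- 1 - cutoff_correlation
  n <- dend$n
  parent <- seq_len(n)
  find <- function(i) {
    while (parent[i] != i) i <- parent[i]
    i
  }
  node_root <- integer(nrow(dend$merge))
  for (k in seq_len(nrow(dend$merge))) {
    kids <- dend$merge[k, ]
    a <- if (kids[1] < 0) -kids[1] else node_root[kids[1]]
    b <- if (kids[2] < 0) -kids[2] else node_root[kids[2]]
    ra <- find(a); rb <- find(b)
    if (dend$height[k] <= threshold + 1e-12) parent[rb] <- ra
    node_root[k] <- ra
  }
  comp <- vapply(seq_len(n), find, integer(1))
  # order clusters by their smallest member label
  roots <- unique(comp)
  root_min <- vapply(roots, function(r) min(dend$labels[comp == r]), character(1))
  cluster <- match(comp, roots[order(root_min)])
  assignment <- data.frame(label = dend$labels, cluster = cluster,
                           stringsAsFactors = FALSE)
  structure(list(assignment = assignment,
                 cutoff_correlation = cutoff_correlation,
                 threshold = threshold,
                 excluded_constant = attr(dend, "excluded_constant") %||% character(0)),
            class = "cluster_assignment")
}

#' @export
print.cluster_assignment <- function(x, ...) {
  cat(sprintf("<cluster_assignment> %d treatments in %d clusters (correlation cutoff %.2f)\n",
              nrow(x$assignment), max(x$assignment$cluster),
              x$cutoff_correlation))
  invisible(x)
}

#' Characterize flat clusters
#'
#' Computes each cluster's elementwise mean vector and assigns a qualitative
#' label, mutually exclusively and in order: \code{first_class} for the
#' cluster (size >= 2) maximizing the segmentation-to-morphology ratio
#' \code{seg_mean / (morph_mean + 1)} -- the "best direct segmentation"
#' cluster; \code{secondary_tail} when the secondary-tail (S) and tail-shape
#' (T) means are the two dominant signals among the morphology+tail codes and
#' both reach \code{secondary_min}; \code{seg_plus_morph} when both halves
#' are strongly affected; else \code{other}.
#'
#' @param assign A \code{cluster_assignment}.
#' @param table The \code{\link{screen_table}} the assignment came from.
#' @param secondary_min Threshold for the secondary-tail signature (default 1.5).
#' @param spm_seg_min,spm_morph_min Thresholds for \code{seg_plus_morph}
#'   (defaults 1 and 2).
#' @return Data frame, one row per cluster: \code{cluster}, \code{size},
#'   \code{seg_mean}, \code{morph_mean}, \code{label}, plus the 12 mean
#'   scores.
#' @export
cluster_profiles <- function(assign, table, secondary_min = 1.5,
                             spm_seg_min = 1, spm_morph_min = 2) {
  schema <- attr(table, "schema")
  if (is.null(schema)) schema <- parameter_schema()
  m <- treatment_vectors(table)
  a <- assign$assignment
  idx <- match(a$label, rownames(m))
  if (anyNA(idx)) stop_data("cluster_profiles: assignment labels not found in table")

  rows <- lapply(sort(unique(a$cluster)), function(cl) {
    mem <- idx[a$cluster == cl]
    mv <- colMeans(m[mem, , drop = FALSE])
    data.frame(cluster = cl, size = length(mem),
               seg_mean = mean(mv[schema$segmentation]),
               morph_mean = mean(mv[schema$morphology]),
               t(mv), stringsAsFactors = FALSE, check.names = FALSE)
  })
  prof <- do.call(rbind, rows)

  ratio <- prof$seg_mean / (prof$morph_mean + 1)
  eligible <- prof$size >= 2L
  label <- rep("other", nrow(prof))
  if (any(eligible)) {
    fc <- which(eligible)[which.max(ratio[eligible])]
    label[fc] <- "first_class"
  }
  tail_codes <- c(schema$morphology, "S")
  for (i in seq_len(nrow(prof))) {
    if (label[i] != "other") next
    sig <- unlist(prof[i, tail_codes])
    top2 <- names(sort(sig, decreasing = TRUE))[1:2]
    if (prof$S[i] >= secondary_min && prof$T[i] >= secondary_min &&
        setequal(top2, c("S", "T"))) {
      label[i] <- "secondary_tail"
    } else if (prof$seg_mean[i] >= spm_seg_min &&
               prof$morph_mean[i] >= spm_morph_min) {
      label[i] <- "seg_plus_morph"
    }
  }
  prof$label <- label
  prof[c("cluster", "size", "seg_mean", "morph_mean", "label", schema$codes)]
}

#' Randomly select pulse-retest candidates from a labeled cluster
#'
#' Uniform sample without replacement of \code{k} distinct compounds from the
#' clusters carrying the requested label (typically \code{seg_plus_morph},
#' whose strong morphological defects may mask direct segmentation effects
#' that a short treatment pulse can reveal). Deterministic given the seed;
#' the caller's RNG state is untouched.
#'
#' @param assign A \code{cluster_assignment}.
#' @param profiles Output of \code{\link{cluster_profiles}}.
#' @param label Cluster label to sample from.
#' @param k Number of compounds.
#' @param seed Integer seed.
#' @return Character vector of k compound ids (sorted).
#' @export
select_pulse_candidates <- function(assign, profiles, label = "seg_plus_morph",
                                    k, seed = 1L) {
  cl <- profiles$cluster[profiles$label == label]
  if (!length(cl)) stop_data(sprintf("no cluster labeled '%s'", label))
  labs <- assign$assignment$label[assign$assignment$cluster %in% cl]
  compounds <- sort(unique(vapply(strsplit(labs, "|", fixed = TRUE), `[[`, "",
                                  1L)))
  if (k > length(compounds)) {
    stop_data(sprintf("k = %d exceeds cluster size %d", k, length(compounds)))
  }
  sort(with_seed(seed, sample(compounds, k)))
}

#' Export a dendrogram as a Newick string
#'
#' Ultrametric height-splitting convention: every internal node sits at half
#' its merge distance, so each child branch length is the node height minus
#' the child's height and all leaves lie at depth 0. Two leaves merged at
#' distance 0.2 give \code{"(A:0.1,B:0.1);"}. Labels are sanitized (Newick
#' structural characters replaced by \code{_}).
#'
#' @param dend A \code{seg_dendrogram}.
#' @param digits Branch-length digits (default 10).
#' @return A Newick string.
#' @export
to_newick <- function(dend, digits = 10) {
  san <- gsub("[ ,:;()\\[\\]']", "_", dend$labels)
  if (dend$n == 1L) return(paste0(san[1L], ";"))
  node_h <- dend$height / 2
  fmt <- function(x) format(x, digits = digits, trim = TRUE, scientific = FALSE)
  build <- function(node) {
    if (node < 0) return(list(str = san[-node], h = 0))
    kids <- dend$merge[node, ]
    a <- build(kids[1L])
    b <- build(kids[2L])
    h <- node_h[node]
    list(str = sprintf("(%s:%s,%s:%s)", a$str, fmt(h - a$h),
                       b$str, fmt(h - b$h)),
         h = h)
  }
  paste0(build(nrow(dend$merge))$str, ";")
}

#' Write cluster outputs to a directory
#'
#' Writes the assignment TSV (label, cluster, cluster label), the cluster
#' profile TSV and the Newick dendrogram.
#'
#' @param assign A \code{cluster_assignment}.
#' @param profiles Output of \code{\link{cluster_profiles}}.
#' @param dend The \code{seg_dendrogram}.
#' @param dir Output directory.
#' @return Invisibly, the written paths.
#' @export
export_clusters <- function(assign, profiles, dend, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  a <- assign$assignment
  a$label_class <- profiles$label[match(a$cluster, profiles$cluster)]
  pa <- file.path(dir, "cluster_assignment.tsv")
  pp <- file.path(dir, "cluster_profiles.tsv")
  pn <- file.path(dir, "dendrogram.nwk")
  utils::write.table(a, pa, sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(profiles, pp, sep = "\t", quote = FALSE, row.names = FALSE)
  writeLines(to_newick(dend), pn)
  invisible(c(pa, pp, pn))
}
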