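# Concentration-dependence summaries and bipartite compound-parameter
# networks for visualization tools (Cytoscape-readable SIF / GraphML).

#' Classify treatments as lethal / any-defect / no-defect
#'
#' @param table A \code{\link{screen_table}}.
#' @return Character vector along the rows of \code{table}: \code{"lethal"}
#'   when the lethal flag is set, else \code{"any_defect"} when any of the 12
#'   scores exceeds 0, else \code{"no_defect"}. Unscored non-lethal
#'   treatments are unclassifiable (\code{NA}, with a warning).
#' @export
classify_treatments <- function(table) {
  out <- rep(NA_character_, nrow(table))
  out[table$lethal] <- "lethal"
  scored <- !table$lethal & has_vector(table)
  m <- score_matrix(table)
  any_def <- rowSums(m > 0, na.rm = TRUE) > 0
  out[scored & any_def] <- "any_defect"
  out[scored & !any_def] <- "no_defect"
  if (anyNA(out)) {
    warning(sprintf("classify_treatments: %d unscored non-lethal treatment(s) unclassifiable",
                    sum(is.na(out))))
  }
  out
}

#' Two-way ANOVA on lethal counts
#'
#' Two-factor analysis (concentration + experiment, no interaction: one
#' observation per cell) of lethal-treatment counts. When every cell count is
#' identical all sums of squares vanish and F = 0, p = 1 by convention.
#'
#' @param counts Data frame with columns \code{experiment},
#'   \code{concentration_uM}, \code{count}.
#' @return List with \code{f_conc}, \code{p_conc}, \code{f_exp},
#'   \code{p_exp}, \code{df} (degrees of freedom) and the fitted
#'   \code{anova} table (NULL in the degenerate case).
#' @export
lethal_count_anova <- function(counts) {
  need <- c("experiment", "concentration_uM", "count")
  if (!all(need %in% names(counts))) {
    stop_format(sprintf("lethal_count_anova needs columns: %s",
                        paste(need, collapse = ", ")))
  }
  if (length(unique(counts$concentration_uM)) < 2L) {
    warning("lethal_count_anova: single concentration, ANOVA skipped")
    return(list(f_conc = NA_real_, p_conc = NA_real_,
                f_exp = NA_real_, p_exp = NA_real_, anova = NULL))
  }
  if (stats::var(counts$count) == 0) {
    return(list(f_conc = 0, p_conc = 1, f_exp = 0, p_exp = 1, anova = NULL))
  }
  fit <- stats::aov(count ~ factor(concentration_uM) + factor(experiment),
                    data = counts)
  at <- summary(fit)[[1L]]
  list(f_conc = at["factor(concentration_uM)", "F value"],
       p_conc = at["factor(concentration_uM)", "Pr(>F)"],
       f_exp = at["factor(experiment)", "F value"],
       p_exp = at["factor(experiment)", "Pr(>F)"],
       anova = at)
}

#' Concentration-dependence profile of a screen
#'
#' Counts lethal / any-defect / no-defect treatments per (experiment,
#' concentration) cell, summarizes each class per concentration as mean and
#' sample SD across experiments, and tests the concentration dependence of
#' lethal counts with a two-way ANOVA (see \code{\link{lethal_count_anova}}).
#'
#' @param table A \code{\link{screen_table}}.
#' @param path Optional path to write the profile as JSON.
#' @return List of class \code{concentration_profile}: \code{counts} (per
#'   cell), \code{summary} (per concentration and class: mean, sd),
#'   \code{anova_f}, \code{anova_p}, \code{anova}.
#' @export
concentration_profile <- function(table, path = NULL) {
  cls <- classify_treatments(table)
  exps <- attr(table, "experiments") %||% sort(unique(table$experiment))
  concs <- attr(table, "concentrations") %||% sort(unique(table$concentration_uM))
  classes <- c("lethal", "any_defect", "no_defect")

  grid <- expand.grid(experiment = exps, concentration_uM = concs,
                      class = classes, stringsAsFactors = FALSE)
  grid$count <- mapply(function(e, cc, k) {
    sum(table$experiment == e & table$concentration_uM == cc &
          !is.na(cls) & cls == k)
  }, grid$experiment, grid$concentration_uM, grid$class)

  summ <- do.call(rbind, lapply(concs, function(cc) {
    do.call(rbind, lapply(classes, function(k) {
      x <- grid$count[grid$concentration_uM == cc & grid$class == k]
      data.frame(concentration_uM = cc, class = k,
                 mean = mean(x), sd = stats::sd(x),
                 stringsAsFactors = FALSE)
    }))
  }))

  lethal_counts <- grid[grid$class == "lethal",
                        c("experiment", "concentration_uM", "count")]
  an <- lethal_count_anova(lethal_counts)

  out <- structure(list(counts = grid, summary = summ,
                        anova_f = an$f_conc, anova_p = an$p_conc,
                        anova = an),
                   class = "concentration_profile")
  if (!is.null(path)) {
    writeLines(jsonlite::toJSON(list(counts = grid, summary = summ,
                                     anova_f = an$f_conc, anova_p = an$p_conc),
                                auto_unbox = TRUE, pretty = TRUE, digits = NA),
               path)
  }
  out
}

#' @export
print.concentration_profile <- function(x, ...) {
  cat("<concentration_profile>\n")
  print(x$summary)
  cat(sprintf("  lethal counts ~ concentration: F = %.3g, p = %.3g\n",
              x$anova_f, x$anova_p))
  invisible(x)
}

#' Bipartite compound-parameter network of one screen slice
#'
#' For one (experiment, concentration) slice: parameter nodes (all 12, typed
#' morphology/segmentation) carry a frequency attribute counting the
#' treatments scoring > 0 on that parameter; compound nodes carry a lethal
#' flag; an edge links a compound to every parameter it scores > 0 on, with
#' the score (1-3) as weight. Lethal treatments contribute a flagged compound
#' node with no edges.
#'
#' @param table A \code{\link{screen_table}}.
#' @param experiment Experiment label.
#' @param concentration Concentration in micromolar.
#' @return List of class \code{parameter_network}: \code{parameters},
#'   \code{compounds}, \code{edges} data frames.
#' @export
build_network <- function(table, experiment, concentration) {
  schema <- attr(table, "schema")
  if (is.null(schema)) schema <- parameter_schema()
  sl <- table[table$experiment == experiment &
                table$concentration_uM == concentration, , drop = FALSE]
  if (nrow(sl) == 0L) warning("build_network: empty slice")

  scored <- !sl$lethal & has_vector(sl, schema)
  unclass_n <- sum(!sl$lethal & !has_vector(sl, schema))
  if (unclass_n > 0L) {
    warning(sprintf("build_network: %d unscored non-lethal treatment(s) excluded",
                    unclass_n))
  }
  m <- as.matrix(as.data.frame(sl)[schema$codes])

  edges <- NULL
  if (any(scored)) {
    idx <- which(scored)
    el <- lapply(idx, function(i) {
      pos <- which(m[i, ] > 0)
      if (!length(pos)) return(NULL)
      data.frame(compound_id = sl$compound_id[i],
                 parameter = schema$codes[pos],
                 weight = as.integer(m[i, pos]),
                 stringsAsFactors = FALSE)
    })
    edges <- do.call(rbind, el)
    if (!is.null(edges)) rownames(edges) <- NULL
  }
  if (is.null(edges)) {
    edges <- data.frame(compound_id = character(0), parameter = character(0),
                        weight = integer(0), stringsAsFactors = FALSE)
  }

  parameters <- data.frame(
    code = schema$codes,
    param_class = c(rep("morphology", 6), rep("segmentation", 6)),
    frequency = unname(vapply(schema$codes,
                              function(p) sum(edges$parameter == p), integer(1))),
    stringsAsFactors = FALSE, row.names = NULL
  )
  compounds <- data.frame(
    compound_id = sl$compound_id[sl$lethal | scored],
    lethal = sl$lethal[sl$lethal | scored],
    stringsAsFactors = FALSE, row.names = NULL
  )
  # invariant: every parameter node's frequency equals its degree
  stopifnot(identical(parameters$frequency,
                      unname(vapply(parameters$code,
                                    function(p) sum(edges$parameter == p),
                                    integer(1)))))
  structure(list(parameters = parameters, compounds = compounds,
                 edges = edges, experiment = experiment,
                 concentration = concentration),
            class = "parameter_network")
}

#' @export
print.parameter_network <- function(x, ...) {
  cat(sprintf("<parameter_network> %s @ %g uM: %d compounds (%d lethal), %d edges\n",
              x$experiment, x$concentration, nrow(x$compounds),
              sum(x$compounds$lethal), nrow(x$edges)))
  invisible(x)
}

#' Export a network as SIF or GraphML
#'
#' SIF: one line per edge, \code{compound<TAB>scores<TAB>parameter} (the
#' relation name is fixed to \code{scores}; SIF has no edge-attribute slot,
#' so score magnitude is carried in GraphML only). GraphML: node attributes
#' \code{node_type}, \code{param_class}, \code{frequency}, \code{lethal};
#' edge attribute \code{weight}. GraphML files round-trip through
#' \code{\link{read_network_graphml}}.
#'
#' @param net A \code{parameter_network}.
#' @param path Output file path.
#' @param format \code{"sif"} or \code{"graphml"}.
#' @return Invisibly, \code{path}.
#' @export
export_network <- function(net, path, format = c("sif", "graphml")) {
  format <- tryCatch(match.arg(format),
                     error = function(e) stop_format(
                       sprintf("unknown network format: %s", format[1])))
  if (format == "sif") {
    lines <- sprintf("%s\tscores\t%s", net$edges$compound_id, net$edges$parameter)
    writeLines(lines, path)
    return(invisible(path))
  }
  doc <- xml2::xml_new_root("graphml",
                            xmlns = "http://graphml.graphdrawing.org/xmlns")
  key <- function(id, dom, name, type) {
    xml2::xml_add_child(doc, "key", id = id, `for` = dom,
                        `attr.name` = name, `attr.type` = type)
  }
  key("d_type", "node", "node_type", "string")
  key("d_class", "node", "param_class", "string")
  key("d_freq", "node", "frequency", "int")
  key("d_lethal", "node", "lethal", "boolean")
  key("d_weight", "edge", "weight", "int")
  g <- xml2::xml_add_child(doc, "graph", id = "screen", edgedefault = "undirected")
  add_data <- function(node, k, v) {
    d <- xml2::xml_add_child(node, "data", key = k)
    xml2::xml_text(d) <- as.character(v)
  }
  for (i in seq_len(nrow(net$parameters))) {
    nd <- xml2::xml_add_child(g, "node", id = net$parameters$code[i])
    add_data(nd, "d_type", "parameter")
    add_data(nd, "d_class", net$parameters$param_class[i])
    add_data(nd, "d_freq", net$parameters$frequency[i])
  }
  for (i in seq_len(nrow(net$compounds))) {
    nd <- xml2::xml_add_child(g, "node", id = net$compounds$compound_id[i])
    add_data(nd, "d_type", "compound")
    add_data(nd, "d_lethal", tolower(as.character(net$compounds$lethal[i])))
  }
  for (i in seq_len(nrow(net$edges))) {
    ed <- xml2::xml_add_child(g, "edge",
                              source = net$edges$compound_id[i],
                              target = net$edges$parameter[i])
    add_data(ed, "d_weight", net$edges$weight[i])
  }
  xml2::write_xml(doc, path)
  invisible(path)
}

#' Read a GraphML network written by \code{\link{export_network}}
#'
#' @param path GraphML file path.
#' @return A \code{parameter_network} (without slice metadata).
#' @export
read_network_graphml <- function(path) {
  doc <- xml2::read_xml(path)
  xml2::xml_ns_strip(doc)
  nodes <- xml2::xml_find_all(doc, ".//node")
  get_data <- function(node, key) {
    d <- xml2::xml_find_first(node, sprintf("./data[@key='%s']", key))
    if (inherits(d, "xml_missing")) NA_character_ else xml2::xml_text(d)
  }
  ids <- xml2::xml_attr(nodes, "id")
  types <- vapply(nodes, get_data, "", key = "d_type")
  is_par <- types == "parameter"
  parameters <- data.frame(
    code = ids[is_par],
    param_class = vapply(nodes[is_par], get_data, "", key = "d_class"),
    frequency = as.integer(vapply(nodes[is_par], get_data, "", key = "d_freq")),
    stringsAsFactors = FALSE, row.names = NULL
  )
  compounds <- data.frame(
    compound_id = ids[!is_par],
    lethal = vapply(nodes[!is_par], get_data, "", key = "d_lethal") == "true",
    stringsAsFactors = FALSE, row.names = NULL
  )
  enodes <- xml2::xml_find_all(doc, ".//edge")
  edges <- data.frame(
    compound_id = xml2::xml_attr(enodes, "source"),
    parameter = xml2::xml_attr(enodes, "target"),
    weight = as.integer(vapply(enodes, get_data, "", key = "d_weight")),
    stringsAsFactors = FALSE, row.names = NULL
  )
  structure(list(parameters = parameters, compounds = compounds, edges = edges,
                 experiment = NA_character_, concentration = NA_real_),
            class = "parameter_network")
}
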