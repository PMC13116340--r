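# Rule-based node assignment and phenotype prediction: affinity-tier rules
# mapping compounds onto the SMO / CK1d / PINK1 signaling-node branches, a
# node -> phenotype catalog with developmental windows, and a decision-tree
# DAG from neural crest progenitor to terminal phenotype leaves.

#' Affinity-tier rule thresholds
#'
#' Binding tiers on docking scores (more negative = stronger): strong is
#' `score <= strong_cutoff`, moderate is
#' `strong_cutoff < score <= moderate_cutoff`, weak is
#' `score > moderate_cutoff`. `tie_tolerance` defines how close to the
#' compound's best score a node must be to count as dominant (scores are
#' reported to one decimal, so the default is half a reporting unit).
#'
#' @param strong_cutoff kcal/mol (default -8.0).
#' @param moderate_cutoff kcal/mol (default -7.0).
#' @param tie_tolerance kcal/mol (default 0.05).
#' @return An object of class `rule_thresholds`.
#' @export
rule_thresholds <- function(strong_cutoff = -8.0, moderate_cutoff = -7.0,
                            tie_tolerance = 0.05) {
  if (strong_cutoff >= moderate_cutoff) {
    config_error("strong_cutoff must be more negative than moderate_cutoff")
  }
  if (tie_tolerance < 0) config_error("tie_tolerance must be >= 0")
  structure(list(strong_cutoff = strong_cutoff,
                 moderate_cutoff = moderate_cutoff,
                 tie_tolerance = tie_tolerance),
            class = "rule_thresholds")
}

score_tier <- function(score, thresholds) {
  ifelse(score <= thresholds$strong_cutoff, "strong",
         ifelse(score <= thresholds$moderate_cutoff, "moderate", "weak"))
}

#' Assign a compound to signaling-node branches
#'
#' Applies the affinity-tier rules to a compound's scores at the three
#' nodes: (1) strong binding qualifies the compound for that branch
#' outright; (2) moderate binding qualifies only if the node is dominant
#' (within `tie_tolerance` of the compound's most negative score); (3) weak
#' binding excludes the node unless no stronger affinity exists anywhere --
#' i.e. all three nodes are weak -- in which case the dominant node(s) are
#' kept, guaranteeing every compound lands on at least one branch. Nodes
#' tied within tolerance are all included. With `mechanism_override`, the
#' annotated primary target is added regardless of the rules (a curation
#' overlay for reproducing hand-assigned layouts).
#'
#' @param scores named numeric: node -> docking score (kcal/mol); all
#'   finite, typically the three nodes SMO, CK1d, PINK1.
#' @param thresholds a [rule_thresholds()].
#' @param compound_id identifier carried into the result.
#' @param mechanism_override logical; add `annotated_primary_target`.
#' @param annotated_primary_target node name (required when overriding).
#' @return An object of class `node_assignment`: list with `compound_id`,
#'   `tiers`, `assigned_nodes`, `dominant_nodes`, `rule_trace`,
#'   `override_applied`.
#' @export
assign_nodes <- function(scores, thresholds = rule_thresholds(),
                         compound_id = "compound",
                         mechanism_override = FALSE,
                         annotated_primary_target = NULL) {
  if (is.null(names(scores)) || any(!nzchar(names(scores)))) {
    stop("scores must be named by node", call. = FALSE)
  }
  if (any(!is.finite(scores))) {
    stop(sprintf("missing or non-finite node score for %s", compound_id),
         call. = FALSE)
  }
  nodes <- names(scores)
  tiers <- stats::setNames(score_tier(scores, thresholds), nodes)
  best <- min(scores)
  dominant <- nodes[scores <= best + thresholds$tie_tolerance]
  all_weak <- all(tiers == "weak")
  assigned <- character(0)
  trace <- character(length(nodes))
  names(trace) <- nodes
  for (nd in nodes) {
    if (tiers[[nd]] == "strong") {
      assigned <- c(assigned, nd)
      trace[nd] <- sprintf("strong (%.2f <= %.1f): included",
                           scores[[nd]], thresholds$strong_cutoff)
    } else if (tiers[[nd]] == "moderate") {
      if (nd %in% dominant) {
        assigned <- c(assigned, nd)
        trace[nd] <- sprintf("moderate and dominant (%.2f): included", scores[[nd]])
      } else {
        trace[nd] <- sprintf("moderate but not dominant (%.2f): excluded", scores[[nd]])
      }
    } else {
      if (all_weak && nd %in% dominant) {
        assigned <- c(assigned, nd)
        trace[nd] <- sprintf("weak (%.2f) but no stronger affinity exists: included",
                             scores[[nd]])
      } else {
        trace[nd] <- sprintf("weak (%.2f > %.1f): excluded",
                             scores[[nd]], thresholds$moderate_cutoff)
      }
    }
  }
  override_applied <- FALSE
  if (isTRUE(mechanism_override) && !is.null(annotated_primary_target)) {
    if (!annotated_primary_target %in% nodes) {
      stop("annotated_primary_target is not one of the scored nodes", call. = FALSE)
    }
    if (!annotated_primary_target %in% assigned) {
      assigned <- c(assigned, annotated_primary_target)
      trace[annotated_primary_target] <- paste0(
        trace[annotated_primary_target], "; mechanism override: included")
      override_applied <- TRUE
    }
  }
  structure(list(
    compound_id = compound_id,
    scores = scores,
    tiers = tiers,
    assigned_nodes = nodes[nodes %in% assigned],
    dominant_nodes = dominant,
    rule_trace = trace,
    override_applied = override_applied
  ), class = "node_assignment")
}

#' @export
print.node_assignment <- function(x, ...) {
  cat(sprintf("%s -> {%s}%s\n", x$compound_id,
              paste(x$assigned_nodes, collapse = ", "),
              if (x$override_applied) " [override]" else ""))
  for (nd in names(x$rule_trace)) {
    cat(sprintf("  %-6s %s\n", nd, x$rule_trace[[nd]]))
  }
  invisible(x)
}

#' Assign every compound in an affinity matrix to node branches
#'
#' @param matrix an `affinity_matrix`.
#' @param node_targets named character vector mapping node name -> matrix
#'   target column (default identity over `c("SMO", "CK1d", "PINK1")`).
#' @param thresholds a [rule_thresholds()].
#' @return A named list of [assign_nodes()] results with a `node_counts`
#'   attribute (compounds per branch).
#' @export
assign_panel <- function(matrix,
                         node_targets = c(SMO = "SMO", CK1d = "CK1d",
                                          PINK1 = "PINK1"),
                         thresholds = rule_thresholds()) {
  sc <- matrix$scores
  if (!nrow(sc)) stop("empty affinity matrix", call. = FALSE)
  missing <- setdiff(unname(node_targets), colnames(sc))
  if (length(missing)) {
    stop(sprintf("node target(s) not in matrix: %s",
                 paste(missing, collapse = ", ")), call. = FALSE)
  }
  out <- lapply(rownames(sc), function(cmp) {
    scores <- stats::setNames(sc[cmp, node_targets], names(node_targets))
    assign_nodes(scores, thresholds, compound_id = cmp)
  })
  names(out) <- rownames(sc)
  counts <- table(unlist(lapply(out, `[[`, "assigned_nodes")))
  attr(out, "node_counts") <- counts
  out
}

#' Default node -> phenotype catalog
#'
#' Controlled phenotype terms per signaling node with anatomical region and
#' embryonic-day vulnerability window: SMO (midline patterning, E8.5--E10),
#' CK1d (bilateral symmetry, E9.5--E11), PINK1 (mandibular outgrowth,
#' E10--E12).
#'
#' @return A named list; each node holds a `data.frame` with columns
#'   `phenotype_term`, `anatomical_region`, and a `window` attribute
#'   `c(start, end)` in embryonic days.
#' @export
default_phenotype_catalog <- function() {
  catalog <- list(
    SMO = list(
      terms = data.frame(
        phenotype_term = c("cyclopia/holoprosencephaly", "frontal bossing/hypertelorism",
                           "midline defects/microform HPE"),
        anatomical_region = c("midline neurocranium", "frontonasal/supraorbital",
                              "nasal bridge/philtrum"),
        stringsAsFactors = FALSE),
      window = c(8.5, 10)
    ),
    CK1d = list(
      terms = data.frame(
        phenotype_term = c("asymmetry/craniosynostosis", "maxillofacial cleft",
                           "facial asymmetry"),
        anatomical_region = c("unilateral cranial vault", "maxilla/palate",
                              "unilateral lower face"),
        stringsAsFactors = FALSE),
      window = c(9.5, 11)
    ),
    PINK1 = list(
      terms = data.frame(
        phenotype_term = c("mandibular hypoplasia/micrognathia",
                           "Treacher Collins-like dysostosis",
                           "mandibular retrognathia"),
        anatomical_region = c("mandibular body/chin", "zygoma/mandible/ear",
                              "mandible (posterior displacement)"),
        stringsAsFactors = FALSE),
      window = c(10, 12)
    )
  )
  catalog
}

#' Predict composite phenotypes from a node assignment
#'
#' The composite phenotype is the union of the catalog terms of the
#' assigned nodes only, each term carrying node provenance and the node's
#' vulnerability window; unassigned nodes contribute nothing.
#'
#' @param assignment a [assign_nodes()] result.
#' @param catalog a catalog as from [default_phenotype_catalog()].
#' @return An object of class `phenotype_prediction`: list with
#'   `compound_id`, `terms` (data.frame `node`, `phenotype_term`,
#'   `anatomical_region`, `window_start`, `window_end`) and `windows`.
#' @export
predict_phenotypes <- function(assignment, catalog = default_phenotype_catalog()) {
  missing <- setdiff(assignment$assigned_nodes, names(catalog))
  if (length(missing)) {
    stop(sprintf("node(s) missing from catalog: %s",
                 paste(missing, collapse = ", ")), call. = FALSE)
  }
  rows <- lapply(assignment$assigned_nodes, function(nd) {
    entry <- catalog[[nd]]
    cbind(node = nd, entry$terms,
          window_start = entry$window[1], window_end = entry$window[2],
          stringsAsFactors = FALSE)
  })
  terms <- if (length(rows)) do.call(rbind, rows) else
    data.frame(node = character(0), phenotype_term = character(0),
               anatomical_region = character(0), window_start = numeric(0),
               window_end = numeric(0), stringsAsFactors = FALSE)
  windows <- lapply(assignment$assigned_nodes,
                    function(nd) catalog[[nd]]$window)
  names(windows) <- assignment$assigned_nodes
  structure(list(compound_id = assignment$compound_id, terms = terms,
                 windows = windows),
            class = "phenotype_prediction")
}

#' @export
print.phenotype_prediction <- function(x, ...) {
  cat(sprintf("Phenotype prediction for %s (%d term(s))\n",
              x$compound_id, nrow(x$terms)))
  if (nrow(x$terms)) {
    for (i in seq_len(nrow(x$terms))) {
      cat(sprintf("  [%s] %s (%s; E%g-E%g)\n", x$terms$node[i],
                  x$terms$phenotype_term[i], x$terms$anatomical_region[i],
                  x$terms$window_start[i], x$terms$window_end[i]))
    }
  }
  invisible(x)
}

#' Build the developmental decision tree
#'
#' A directed acyclic graph rooted at the neural crest progenitor, with one
#' internal branch per signaling node and one terminal leaf per (compound,
#' node, phenotype term), each leaf carrying the compound's docking
#' affinity at that node.
#'
#' @param assignments list of [assign_nodes()] results (see [assign_panel()]).
#' @param catalog phenotype catalog.
#' @param matrix the `affinity_matrix` providing leaf affinities.
#' @param root root-node label.
#' @return An object of class `decision_tree`: list with `nodes`
#'   (data.frame `id`, `type`, `label`) and `edges` (data.frame `from`,
#'   `to`), plus `leaves` (data.frame with compound, node, phenotype,
#'   affinity).
#' @export
build_decision_tree <- function(assignments, catalog = default_phenotype_catalog(),
                                matrix = NULL, root = "neural crest progenitor") {
  branch_nodes <- unique(unlist(lapply(assignments, `[[`, "assigned_nodes")))
  leaves <- list()
  for (a in assignments) {
    if (!is.null(matrix) && !a$compound_id %in% rownames(matrix$scores)) {
      stop(sprintf("assignment for '%s' has no row in the affinity matrix",
                   a$compound_id), call. = FALSE)
    }
    for (nd in a$assigned_nodes) {
      aff <- if (!is.null(matrix)) matrix$scores[a$compound_id, nd] else
        a$scores[[nd]]
      entry <- catalog[[nd]]
      if (is.null(entry)) {
        stop(sprintf("node '%s' missing from catalog", nd), call. = FALSE)
      }
      for (term in entry$terms$phenotype_term) {
        leaves[[length(leaves) + 1L]] <- data.frame(
          compound = a$compound_id, node = nd, phenotype_term = term,
          affinity = unname(aff), stringsAsFactors = FALSE)
      }
    }
  }
  leaves <- if (length(leaves)) do.call(rbind, leaves) else
    data.frame(compound = character(0), node = character(0),
               phenotype_term = character(0), affinity = numeric(0),
               stringsAsFactors = FALSE)
  leaves <- leaves[order(leaves$compound, leaves$node, leaves$phenotype_term), ,
                   drop = FALSE]
  rownames(leaves) <- NULL
  leaf_ids <- sprintf("leaf:%s|%s|%s", leaves$compound, leaves$node,
                      leaves$phenotype_term)
  nodes <- rbind(
    data.frame(id = "root", type = "root", label = root,
               stringsAsFactors = FALSE),
    if (length(branch_nodes)) data.frame(id = paste0("node:", sort(branch_nodes)),
                                         type = "node", label = sort(branch_nodes),
                                         stringsAsFactors = FALSE),
    if (nrow(leaves)) data.frame(id = leaf_ids, type = "leaf",
                                 label = sprintf("%s: %s (%.1f kcal/mol)",
                                                 leaves$compound,
                                                 leaves$phenotype_term,
                                                 leaves$affinity),
                                 stringsAsFactors = FALSE)
  )
  edges <- rbind(
    if (length(branch_nodes)) data.frame(from = "root",
                                         to = paste0("node:", sort(branch_nodes)),
                                         stringsAsFactors = FALSE),
    if (nrow(leaves)) data.frame(from = paste0("node:", leaves$node),
                                 to = leaf_ids, stringsAsFactors = FALSE)
  )
  if (is.null(edges)) edges <- data.frame(from = character(0), to = character(0),
                                          stringsAsFactors = FALSE)
  g <- igraph::graph_from_data_frame(edges, directed = TRUE,
                                     vertices = nodes$id)
  if (nrow(edges) && !igraph::is_dag(g)) {
    stop("constructed decision tree is not acyclic", call. = FALSE)
  }
  structure(list(nodes = nodes, edges = edges, leaves = leaves, root = root),
            class = "decision_tree")
}

#' @export
print.decision_tree <- function(x, ...) {
  cat(sprintf("Decision tree: root '%s', %d branch node(s), %d leaf/leaves\n",
              x$root, sum(x$nodes$type == "node"), sum(x$nodes$type == "leaf")))
  invisible(x)
}

#' Export a decision tree
#'
#' @param tree a `decision_tree`.
#' @param path output path.
#' @param format `"json"` (nodes/edges object) or `"dot"`
#'   (Graphviz-dialect text).
#' @return `path`, invisibly.
#' @export
write_decision_tree <- function(tree, path, format = c("json", "dot")) {
  format <- match.arg(format)
  if (format == "json") {
    jsonlite::write_json(list(nodes = tree$nodes, edges = tree$edges),
                         path, auto_unbox = TRUE, digits = NA)
  } else {
    esc <- function(x) gsub('"', '\\\\"', x)
    lines <- c("digraph decision_tree {",
               sprintf('  "%s" [label="%s"];', esc(tree$nodes$id),
                       esc(tree$nodes$label)),
               sprintf('  "%s" -> "%s";', esc(tree$edges$from),
                       esc(tree$edges$to)),
               "}")
    writeLines(lines, path)
  }
  invisible(path)
}
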