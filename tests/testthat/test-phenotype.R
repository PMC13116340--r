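test_that("node assignment follows the affinity-tier rules on hand-worked profiles", {
  # all three strong: every branch assigned (purmorphamine-like profile)
  a <- assign_nodes(c(SMO = -9.1, CK1d = -10.4, PINK1 = -10.4))
  expect_setequal(a$assigned_nodes, c("SMO", "CK1d", "PINK1"))
  expect_true(all(a$tiers == "strong"))
  expect_setequal(a$dominant_nodes, c("CK1d", "PINK1"))
  # moderate profile: only the dominant (most negative) node is kept
  b <- assign_nodes(c(SMO = -7.5, CK1d = -7.2, PINK1 = -6.8))
  expect_equal(b$assigned_nodes, "SMO")
  expect_equal(unname(b$tiers), c("moderate", "moderate", "weak"))
  # all weak: dominant node kept via the no-stronger-affinity fallback
  c_ <- assign_nodes(c(SMO = -6.0, CK1d = -6.5, PINK1 = -5.0))
  expect_equal(c_$assigned_nodes, "CK1d")
  # symmetric weak tie: all three included
  d <- assign_nodes(c(SMO = -6.0, CK1d = -6.0, PINK1 = -6.0))
  expect_setequal(d$assigned_nodes, c("SMO", "CK1d", "PINK1"))
  # boundary conventions: exactly -8.0 is strong, exactly -7.0 moderate
  e <- assign_nodes(c(SMO = -8.0, CK1d = -7.0, PINK1 = -6.0))
  expect_equal(unname(e$tiers), c("strong", "moderate", "weak"))
  expect_equal(e$assigned_nodes, "SMO")
  expect_error(assign_nodes(c(SMO = -8, CK1d = NA, PINK1 = -7)), "non-finite")
  expect_match(b$rule_trace[["PINK1"]], "excluded")
})

test_that("assignment is never empty and matches the brute-force rule oracle on a grid", {
  vals <- seq(-12, -5, by = 0.5)
  thr <- rule_thresholds()
  for (s1 in vals) for (s2 in vals) for (s3 in vals) {
    scores <- c(SMO = s1, CK1d = s2, PINK1 = s3)
    got <- assign_nodes(scores, thr)$assigned_nodes
    expect_identical(sort(got), sort(oracle_assign(scores)))
    expect_gt(length(got), 0)
  }
})

test_that("rules are monotone and strong nodes are always assigned", {
  set.seed(33)
  thr <- rule_thresholds()
  for (i in 1:200) {
    scores <- c(SMO = runif(1, -12, -5), CK1d = runif(1, -12, -5),
                PINK1 = runif(1, -12, -5))
    base <- assign_nodes(scores, thr)$assigned_nodes
    # strengthening one node never removes it
    nd <- sample(names(scores), 1)
    stronger <- scores
    stronger[nd] <- stronger[nd] - runif(1, 0, 3)
    after <- assign_nodes(stronger, thr)$assigned_nodes
    if (nd %in% base) expect_true(nd %in% after)
    # any strong node is assigned regardless of the others
    strong_nodes <- names(scores)[scores <= thr$strong_cutoff]
    expect_true(all(strong_nodes %in% base))
  }
})

test_that("mechanism override adds the annotated primary target and is flagged", {
  scores <- c(SMO = -7.6, CK1d = -8.2, PINK1 = -6.5) # cyclopamine-like
  pure <- assign_nodes(scores)
  expect_equal(pure$assigned_nodes, "CK1d") # strict rules exclude SMO
  over <- assign_nodes(scores, mechanism_override = TRUE,
                       annotated_primary_target = "SMO")
  expect_setequal(over$assigned_nodes, c("SMO", "CK1d"))
  expect_true(over$override_applied)
  # override of an already-assigned node changes nothing
  noop <- assign_nodes(scores, mechanism_override = TRUE,
                       annotated_primary_target = "CK1d")
  expect_false(noop$override_applied)
})

test_that("panel assignment is deterministic and respects custom node mapping", {
  m <- toy_matrix()
  asg <- assign_panel(m)
  expect_length(asg, 5)
  expect_identical(lapply(asg, `[[`, "assigned_nodes"),
                   lapply(assign_panel(m), `[[`, "assigned_nodes"))
  counts <- attr(asg, "node_counts")
  expect_true(all(counts >= 1))
  # a panel strong everywhere lands on all three branches
  allstrong <- affinity_matrix(matrix(-9, 2, 3, dimnames = list(c("x", "y"),
                                                                c("SMO", "CK1d", "PINK1"))))
  asg2 <- assign_panel(allstrong)
  expect_true(all(vapply(asg2, function(a) length(a$assigned_nodes) == 3, logical(1))))
  expect_error(assign_panel(affinity_matrix(m$scores[, 1:2])), "not in matrix")
})

test_that("phenotype prediction is the union over assigned nodes with windows", {
  catalog <- default_phenotype_catalog()
  pink_only <- assign_nodes(c(SMO = -6, CK1d = -6.5, PINK1 = -9.6))
  expect_equal(pink_only$assigned_nodes, "PINK1")
  pred <- predict_phenotypes(pink_only, catalog)
  expect_true(all(pred$terms$node == "PINK1"))
  expect_true(any(grepl("mandibular hypoplasia", pred$terms$phenotype_term)))
  expect_equal(unique(pred$terms$window_start), 10)
  expect_equal(unique(pred$terms$window_end), 12)
  # all three nodes: union of all catalog terms
  all3 <- assign_nodes(c(SMO = -9.1, CK1d = -10.4, PINK1 = -10.4))
  pred3 <- predict_phenotypes(all3, catalog)
  expect_equal(nrow(pred3$terms), sum(vapply(catalog, function(e) nrow(e$terms),
                                             integer(1))))
  # purity: identical assignments give identical predictions
  twin <- assign_nodes(c(SMO = -9.1, CK1d = -10.4, PINK1 = -10.4))
  pred_twin <- predict_phenotypes(twin, catalog)
  expect_equal(pred_twin$terms, pred3$terms)
  # node missing from the catalog is an error
  expect_error(predict_phenotypes(all3, catalog["SMO"]), "missing from catalog")
})

test_that("decision tree is an acyclic root-branch-leaf DAG carrying node affinities", {
  m <- toy_matrix()
  asg <- assign_panel(m)
  tree <- build_decision_tree(asg, matrix = m)
  expect_equal(sum(tree$nodes$type == "root"), 1)
  # every leaf affinity equals the matrix score at its branch node
  for (i in seq_len(nrow(tree$leaves))) {
    lf <- tree$leaves[i, ]
    expect_equal(lf$affinity, m$scores[lf$compound, lf$node])
  }
  g <- igraph::graph_from_data_frame(tree$edges, directed = TRUE,
                                     vertices = tree$nodes$id)
  expect_true(igraph::is_dag(g))
  # every leaf reachable from the root
  dist <- igraph::distances(g, v = "root", mode = "out")
  leaf_ids <- tree$nodes$id[tree$nodes$type == "leaf"]
  expect_true(all(is.finite(dist[1, leaf_ids])))
  # single compound on one node -> leaves only under that node
  solo <- list(assign_nodes(c(SMO = -6, CK1d = -6.5, PINK1 = -9.6),
                            compound_id = "cpdA"))
  t2 <- build_decision_tree(solo, matrix = m)
  expect_true(all(t2$leaves$node == "PINK1"))
  expect_equal(unique(t2$leaves$affinity), m$scores["cpdA", "PINK1"])
  # export stable under input reordering
  t3 <- build_decision_tree(rev(asg), matrix = m)
  expect_equal(t3$leaves, tree$leaves)
  expect_error(build_decision_tree(list(assign_nodes(
    c(SMO = -9, CK1d = -9, PINK1 = -9), compound_id = "ghost")), matrix = m),
    "no row")
})

test_that("decision tree exports JSON and Graphviz text", {
  m <- toy_matrix()
  tree <- build_decision_tree(assign_panel(m), matrix = m)
  j <- withr::local_tempfile(fileext = ".json")
  write_decision_tree(tree, j, "json")
  back <- jsonlite::read_json(j, simplifyVector = TRUE)
  expect_equal(nrow(back$edges), nrow(tree$edges))
  d <- withr::local_tempfile(fileext = ".dot")
  write_decision_tree(tree, d, "dot")
  txt <- readLines(d)
  expect_match(txt[1], "digraph")
  expect_true(any(grepl("root", txt)))
})
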