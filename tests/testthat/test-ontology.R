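# Ontology loading, DAG closures and disease-group expansion.

obograph_json <- function(nodes, edges) {
  doc <- list(graphs = list(list(nodes = nodes, edges = edges)))
  path <- tempfile(fileext = ".json")
  jsonlite::write_json(doc, path, auto_unbox = TRUE)
  path
}

obo_node <- function(curie, lbl = curie, deprecated = FALSE,
                     xrefs = NULL) {
  nd <- list(id = curie_to_iri(curie), lbl = lbl)
  meta <- list()
  if (deprecated) meta$deprecated <- TRUE
  if (!is.null(xrefs)) meta$xrefs <- lapply(xrefs, function(v) list(val = v))
  if (length(meta) > 0L) nd$meta <- meta
  nd
}

obo_edge <- function(child, parent, pred = "is_a") {
  list(sub = curie_to_iri(child), pred = pred, obj = curie_to_iri(parent))
}

test_that("load_obograph retains non-obsolete terms, is_a edges and xrefs", {
  ids <- sprintf("HP:%07d", 1:5)
  path <- obograph_json(
    nodes = c(lapply(ids, obo_node),
              list(obo_node("HP:0000099", deprecated = TRUE),
                   obo_node("MONDO:0000001"))), # wrong prefix, dropped
    edges = list(obo_edge(ids[2], ids[1]), obo_edge(ids[3], ids[1]),
                 obo_edge(ids[4], ids[2]), obo_edge(ids[5], ids[2]),
                 obo_edge(ids[5], ids[3], pred = "part_of"),
                 obo_edge("HP:0000099", ids[1])))
  g <- load_obograph(path, "HP")
  expect_setequal(g$terms, ids)
  expect_equal(nrow(g$edges), 4L)          # part_of and obsolete edges gone
  expect_false("HP:0000099" %in% g$terms)
  expect_false("HP:0000099" %in% descendants(g, ids[1]))
})

test_that("xrefs with allowed prefixes are mapped to flat disease ids", {
  path <- obograph_json(
    nodes = list(obo_node("MONDO:0000001"),
                 obo_node("MONDO:0007322",
                          xrefs = list("OMIM:118651", "Orphanet:79345"))),
    edges = list(obo_edge("MONDO:0007322", "MONDO:0000001")))
  g <- load_obograph(path, "MONDO")
  expect_equal(g$xrefs[["MONDO:0007322"]], "OMIM:118651")
})

test_that("malformed and empty inputs raise informative errors", {
  bad <- tempfile(fileext = ".json")
  writeLines("{not json", bad)
  expect_error(load_obograph(bad, "HP"), "malformed")
  empty <- obograph_json(nodes = list(obo_node("MONDO:0000001")),
                         edges = list())
  expect_error(load_obograph(empty, "HP"), "no non-obsolete 'HP' terms")
  expect_error(
    ontology_graph(c("HP:0000001", "HP:0000002"),
                   data.frame(child = c("HP:0000001", "HP:0000002"),
                              parent = c("HP:0000002", "HP:0000001"))),
    "cycle")
  expect_error(
    ontology_graph("HP:0000001",
                   data.frame(child = "HP:0000002", parent = "HP:0000001")),
    "not a known term")
})

test_that("descendant closure is reflexive and handles diamonds once", {
  g <- toy_hpo()
  expect_setequal(descendants(g, "HP:0000001"), g$terms)       # root: all 5
  expect_equal(descendants(g, "HP:0000005"), "HP:0000005")     # leaf: itself
  d <- diamond_hpo()
  got <- sort(descendants(d, "HP:0000001"))
  expect_equal(got, brute_descendants(d$edges, "HP:0000001"))
  expect_equal(sum(got == "HP:0000004"), 1L)                   # counted once
  expect_setequal(ancestors(d, "HP:0000004"), d$terms)         # both paths up
  expect_error(descendants(g, "HP:9999999"), "unknown term")
})

test_that("descendants is monotone along the DAG", {
  b <- synth_bundle()
  for (t1 in sample(b$hpo$terms, 8)) {
    for (t2 in descendants(b$hpo, t1)) {
      expect_true(all(descendants(b$hpo, t2) %in% descendants(b$hpo, t1)))
    }
  }
})

test_that("group expansion maps a group term to corpus disease ids", {
  mondo <- toy_mondo()
  corpus_ids <- c("OMIM:118651", "OMIM:100002", "OMIM:100003")
  expect_equal(group_to_diseases(mondo, "MONDO:0000100", corpus_ids),
               c("OMIM:100002", "OMIM:118651"))     # k = 2
  # xref absent from corpus is excluded by the intersection
  expect_equal(group_to_diseases(mondo, "MONDO:0000100", "OMIM:118651"),
               "OMIM:118651")
  # no xref among descendants -> empty set with a mapping-failure warning
  expect_warning(
    res <- group_to_diseases(mondo, "MONDO:0000100", "OMIM:999999"),
    "mapping failure")
  expect_length(res, 0L)
})

test_that("the root group over a fully xref'd corpus returns the whole corpus", {
  b <- synth_bundle()
  root <- "MONDO:0000001"
  expect_setequal(group_to_diseases(b$mondo, root, names(b$corpus)),
                  names(b$corpus))
})

test_that("load -> write -> load round-trips terms, edges and xrefs", {
  b <- synth_bundle()
  for (g in list(b$hpo, b$mondo)) {
    path <- tempfile(fileext = ".json")
    write_obograph(g, path)
    g2 <- load_obograph(path, g$prefix)
    expect_setequal(g2$terms, g$terms)
    expect_equal(
      g2$edges[order(g2$edges$child, g2$edges$parent), ],
      g$edges[order(g$edges$child, g$edges$parent), ],
      ignore_attr = TRUE)
    norm_xr <- function(x) {
      if (length(x) == 0L) list() else lapply(x, sort)[order(names(x))]
    }
    expect_equal(norm_xr(g2$xrefs), norm_xr(g$xrefs))
  }
})
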