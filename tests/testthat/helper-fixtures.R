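# Shared in-code fixtures: tiny hand-built ontologies and corpora with known
# structure, so every expected value can be derived by hand or brute force.

# 5-term phenotype tree: B, C children of A (root); D, E children of B.
toy_hpo <- function() {
  ontology_graph(
    terms = sprintf("HP:%07d", 1:5),
    edges = data.frame(
      child  = sprintf("HP:%07d", c(2, 3, 4, 5)),
      parent = sprintf("HP:%07d", c(1, 1, 2, 2)),
      stringsAsFactors = FALSE),
    prefix = "HP")
}

# Diamond: B and C children of A; D child of both B and C.
diamond_hpo <- function() {
  ontology_graph(
    terms = sprintf("HP:%07d", 1:4),
    edges = data.frame(
      child  = sprintf("HP:%07d", c(2, 3, 4, 4)),
      parent = sprintf("HP:%07d", c(1, 1, 2, 3)),
      stringsAsFactors = FALSE),
    prefix = "HP")
}

# Disease ontology: root, one group term with two disease leaves xref'd to
# OMIM ids, plus one ungrouped leaf.
toy_mondo <- function() {
  ontology_graph(
    terms = c("MONDO:0000001", "MONDO:0000100",
              "MONDO:0000101", "MONDO:0000102", "MONDO:0000103"),
    edges = data.frame(
      child  = c("MONDO:0000100", "MONDO:0000101", "MONDO:0000102",
                 "MONDO:0000103"),
      parent = c("MONDO:0000001", "MONDO:0000100", "MONDO:0000100",
                 "MONDO:0000001"),
      stringsAsFactors = FALSE),
    xrefs = list("MONDO:0000101" = "OMIM:118651",
                 "MONDO:0000102" = "OMIM:100002",
                 "MONDO:0000103" = "OMIM:100003"),
    prefix = "MONDO")
}

# Brute-force reflexive descendant closure by DFS over the edge list,
# independent of the package's closure construction.
brute_descendants <- function(edges, t) {
  kids <- split(edges$child, edges$parent)
  seen <- character(0)
  stack <- t
  while (length(stack) > 0L) {
    v <- stack[[1L]]; stack <- stack[-1L]
    if (v %in% seen) next
    seen <- c(seen, v)
    stack <- c(stack, kids[[v]])
  }
  sort(seen)
}

# Three diseases over toy_hpo() with disjoint annotation sets.
toy_corpus <- function() {
  list(
    "OMIM:100001" = disease_model("OMIM:100001", c("HP:0000002" = 1.0),
                                  name = "disease A"),
    "OMIM:100002" = disease_model("OMIM:100002",
                                  c("HP:0000004" = 1.0, "HP:0000005" = 0.9),
                                  name = "disease B"),
    "OMIM:100003" = disease_model("OMIM:100003", c("HP:0000003" = 1.0),
                                  name = "disease C")
  )
}

# Standard synthetic bundle used by several test files (small but nontrivial).
synth_bundle <- function(seed = 11, ...) {
  cfg <- synth_config(seed = seed, ...)
  s <- make_ontologies(cfg)
  corpus <- make_corpus(cfg, s$hpo, s$groups)
  bg <- background_frequencies(corpus, s$hpo)
  list(cfg = cfg, hpo = s$hpo, mondo = s$mondo, groups = s$groups,
       corpus = corpus, bg = bg)
}

# Brute-force one-sided signed-rank p-value by enumerating all 2^n sign
# assignments (zeros dropped, mid-ranks), independent of the package's
# convolution implementation.
brute_wilcoxon_p <- function(r_uniform, r_adjusted) {
  d <- r_uniform - r_adjusted
  d <- d[d != 0]
  n <- length(d)
  if (n == 0L) return(1.0)
  r <- rank(abs(d))
  w_obs <- sum(r[d > 0])
  hits <- 0L
  for (m in 0:(2^n - 1)) {
    signs <- as.integer(intToBits(m))[seq_len(n)]
    if (sum(r[signs == 1L]) >= w_obs) hits <- hits + 1L
  }
  hits / 2^n
}
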