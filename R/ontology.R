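# Ontology graphs: DAGs of terms connected by child -> parent "is_a" edges,
# with optional cross-references to flat disease identifiers (Mondo -> OMIM).
# Ancestor/descendant closures are reflexive: a term is its own ancestor and
# its own descendant. Group expansion ("a term and its descendants") relies on
# this convention.

#' Construct an ontology graph
#'
#' Builds a validated DAG of ontology terms. Most users will call
#' [load_obograph()] instead; this constructor is the programmatic entry point
#' used by the synthetic-data generator and by tests.
#'
#' @param terms Character vector of term identifiers (CURIEs).
#' @param edges Two-column data frame (`child`, `parent`) of `is_a` edges;
#'   both endpoints must appear in `terms`.
#' @param labels Named character vector of human-readable labels; names are
#'   term identifiers. Terms without a label get their identifier as label.
#' @param xrefs Named list mapping term identifiers to character vectors of
#'   cross-referenced identifiers (e.g. Mondo terms to OMIM ids). Only
#'   meaningful for disease ontologies.
#' @param prefix Namespace prefix shared by all terms (e.g. `"HP"`).
#' @return An object of class `ontology_graph` with components `terms`,
#'   `labels`, `edges`, `xrefs`, `prefix`, plus precomputed reflexive
#'   `ancestors` and `descendants` closures (named lists).
#' @export
ontology_graph <- function(terms, edges, labels = NULL, xrefs = NULL,
                           prefix = term_prefix(terms[1])) {
  terms <- as.character(terms)
  if (length(terms) == 0L) stop("ontology must contain at least one term")
  if (anyDuplicated(terms)) stop("duplicate term identifiers")
  if (!all(is_curie(terms))) {
    stop("malformed term identifier: ", terms[!is_curie(terms)][1])
  }
  edges <- as.data.frame(edges, stringsAsFactors = FALSE)
  if (nrow(edges) > 0L) {
    names(edges)[1:2] <- c("child", "parent")
    bad <- setdiff(c(edges$child, edges$parent), terms)
    if (length(bad) > 0L) stop("edge endpoint is not a known term: ", bad[1])
  } else {
    edges <- data.frame(child = character(), parent = character(),
                        stringsAsFactors = FALSE)
  }

  g <- igraph::graph_from_data_frame(
    edges[, c("child", "parent")],
    directed = TRUE,
    vertices = data.frame(name = terms, stringsAsFactors = FALSE)
  )
  if (!igraph::is_dag(g)) stop("ontology edge relation contains a cycle")

  lab <- stats::setNames(terms, terms)
  if (!is.null(labels) && length(labels) > 0L) {
    lab[names(labels)] <- unname(labels)
  }
  xr <- if (is.null(xrefs)) list() else xrefs[intersect(names(xrefs), terms)]

  clo <- .closures(terms, edges)
  structure(
    list(terms = terms, labels = lab, edges = edges, xrefs = xr,
         prefix = prefix, graph = g,
         ancestors = clo$ancestors, descendants = clo$descendants),
    class = "ontology_graph"
  )
}

# Reflexive transitive closures for all terms, computed once in topological
# order (parents before children for ancestors, the reverse for descendants).
.closures <- function(terms, edges) {
  parents_of <- split(edges$parent, factor(edges$child, levels = terms))
  children_of <- split(edges$child, factor(edges$parent, levels = terms))
  # Kahn topological order: roots first, so every parent is emitted before
  # any of its children.
  order_out <- character(0)
  npar <- stats::setNames(
    vapply(parents_of, length, integer(1))[terms], terms
  ) # parents not yet emitted
  queue <- terms[npar == 0L] # roots
  while (length(queue) > 0L) {
    v <- queue[[1L]]
    queue <- queue[-1L]
    order_out <- c(order_out, v)
    for (c in children_of[[v]]) {
      npar[[c]] <- npar[[c]] - 1L
      if (npar[[c]] == 0L) queue <- c(queue, c)
    }
  }
  anc <- vector("list", length(terms))
  names(anc) <- terms
  for (v in order_out) { # parents already done
    anc[[v]] <- unique(c(v, unlist(anc[parents_of[[v]]], use.names = FALSE)))
  }
  desc <- vector("list", length(terms))
  names(desc) <- terms
  for (v in rev(order_out)) { # children already done
    desc[[v]] <- unique(c(v, unlist(desc[children_of[[v]]], use.names = FALSE)))
  }
  list(ancestors = anc, descendants = desc)
}

#' @export
print.ontology_graph <- function(x, ...) {
  cat(sprintf("<ontology_graph> %s: %d terms, %d is_a edges, %d xref'd terms\n",
              x$prefix, length(x$terms), nrow(x$edges), length(x$xrefs)))
  invisible(x)
}

#' Load an ontology from OBO-Graph JSON
#'
#' Reads the OBO-Graph JSON dialect used by `hp.json` and `mondo.json`
#' (top-level `graphs` array with `nodes` and `edges`). Only non-obsolete
#' terms of the expected prefix and their `is_a` edges are retained; other
#' edge predicates (`part_of` etc.) are ignored because disease grouping is
#' subclass-based. Cross-references with an allowed prefix are kept for every
#' retained node.
#'
#' @param path Path to an OBO-Graph JSON file.
#' @param expected_prefix Namespace prefix of terms to retain (`"HP"`,
#'   `"MONDO"`, ...).
#' @param xref_prefixes Character vector of cross-reference prefixes to keep;
#'   defaults to `"OMIM"`, the flat identifiers of the annotation corpus.
#' @return An [ontology_graph()].
#' @export
load_obograph <- function(path, expected_prefix, xref_prefixes = "OMIM") {
  if (!file.exists(path)) stop("file not found: ", path)
  js <- tryCatch(
    jsonlite::fromJSON(path, simplifyVector = FALSE),
    error = function(e) stop("malformed OBO-Graph JSON in '", path, "': ",
                             conditionMessage(e), call. = FALSE)
  )
  if (is.null(js$graphs) || length(js$graphs) == 0L) {
    stop("malformed OBO-Graph JSON: missing top-level 'graphs' array")
  }
  gr <- js$graphs[[1L]]
  nodes <- gr$nodes
  if (is.null(nodes)) stop("malformed OBO-Graph JSON: graph has no 'nodes'")

  ids <- character(0); labels <- character(0)
  xrefs <- list(); obsolete <- character(0)
  for (nd in nodes) {
    if (is.null(nd$id)) stop("malformed OBO-Graph JSON: node without 'id'")
    id <- iri_to_curie(nd$id)
    if (term_prefix(id) != expected_prefix) next
    if (isTRUE(nd$meta$deprecated)) {
      obsolete <- c(obsolete, id)
      next
    }
    ids <- c(ids, id)
    labels[id] <- if (!is.null(nd$lbl)) nd$lbl else id
    xs <- vapply(nd$meta$xrefs, function(x) iri_to_curie(x$val), character(1))
    xs <- xs[term_prefix(xs) %in% xref_prefixes]
    if (length(xs) > 0L) xrefs[[id]] <- unique(unname(xs))
  }
  if (length(ids) == 0L) {
    stop("no non-obsolete '", expected_prefix, "' terms found in ", path)
  }

  ed <- data.frame(child = character(), parent = character(),
                   stringsAsFactors = FALSE)
  if (!is.null(gr$edges)) {
    ch <- character(0); pa <- character(0)
    for (e in gr$edges) {
      if (is.null(e$pred) || e$pred != "is_a") next
      s <- iri_to_curie(e$sub); o <- iri_to_curie(e$obj)
      if (s %in% ids && o %in% ids) {
        ch <- c(ch, s); pa <- c(pa, o)
      }
    }
    ed <- unique(data.frame(child = ch, parent = pa, stringsAsFactors = FALSE))
  }
  ontology_graph(ids, ed, labels = labels, xrefs = xrefs,
                 prefix = expected_prefix)
}

#' Write an ontology as OBO-Graph JSON
#'
#' Emits the same dialect [load_obograph()] consumes, with deterministic
#' node and edge ordering, so synthetic ontologies exercise the real parser
#' and `load -> write -> load` is the identity on terms, edges and xrefs.
#'
#' @param g An [ontology_graph()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_obograph <- function(g, path) {
  stopifnot(inherits(g, "ontology_graph"))
  nodes <- lapply(sort(g$terms), function(t) {
    nd <- list(id = curie_to_iri(t), lbl = unname(g$labels[[t]]),
               type = "CLASS")
    xs <- g$xrefs[[t]]
    if (!is.null(xs) && length(xs) > 0L) {
      nd$meta <- list(xrefs = lapply(sort(xs), function(v) list(val = v)))
    }
    nd
  })
  ed <- g$edges[order(g$edges$child, g$edges$parent), , drop = FALSE]
  edges <- lapply(seq_len(nrow(ed)), function(i) {
    list(sub = curie_to_iri(ed$child[i]), pred = "is_a",
         obj = curie_to_iri(ed$parent[i]))
  })
  doc <- list(graphs = list(list(nodes = nodes, edges = edges)))
  jsonlite::write_json(doc, path, auto_unbox = TRUE, pretty = FALSE,
                       digits = NA)
  invisible(path)
}

.check_term <- function(g, t) {
  if (!t %in% g$terms) stop("unknown term: ", t)
}

#' Reflexive descendant closure of a term
#'
#' Returns the term itself plus every term below it under child -> parent
#' `is_a` edges. Reflexivity matters for group expansion: a selected disease
#' group term may itself be a disease.
#'
#' @param g An [ontology_graph()].
#' @param t Term identifier.
#' @return Character vector of term identifiers, including `t`.
#' @export
descendants <- function(g, t) {
  stopifnot(inherits(g, "ontology_graph"))
  .check_term(g, t)
  g$descendants[[t]]
}

#' Reflexive ancestor closure of a term
#'
#' @inheritParams descendants
#' @return Character vector of term identifiers, including `t`.
#' @export
ancestors <- function(g, t) {
  stopifnot(inherits(g, "ontology_graph"))
  .check_term(g, t)
  g$ancestors[[t]]
}

#' Expand a disease-group term to corpus disease identifiers
#'
#' Maps an ontology-defined disease group (a Mondo term and its descendants)
#' to the flat disease identifiers of the annotation corpus via
#' cross-references. The size of the returned set is the `k` of the pretest
#' adjustment. Mapping failures (an empty result) raise a warning rather than
#' an error: cross-referencing between disease nomenclatures is known to be
#' incomplete.
#'
#' @param mondo Disease [ontology_graph()] with xrefs.
#' @param group Group term identifier within `mondo`.
#' @param known_diseases Character vector of flat disease identifiers present
#'   in the annotation corpus (e.g. OMIM ids).
#' @return Sorted character vector of disease identifiers (possibly empty).
#' @export
group_to_diseases <- function(mondo, group, known_diseases) {
  stopifnot(inherits(mondo, "ontology_graph"))
  .check_term(mondo, group)
  dd <- descendants(mondo, group)
  mapped <- unique(unlist(mondo$xrefs[dd], use.names = FALSE))
  res <- sort(intersect(mapped, known_diseases))
  if (length(res) == 0L) {
    warning("group '", group, "' maps to no disease in the corpus ",
            "(mapping failure)", call. = FALSE)
  }
  res
}
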