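# Synthetic-data generator: mini phenotype/disease ontologies, annotation
# corpora and simulated patients with the statistical structure the ranking
# method assumes. Everything is emitted in the real file dialects (OBO-Graph
# JSON, HPOA TSV, Phenopacket JSON) so the parsers are exercised end to end
# without any downloads.

# Run code under a temporary RNG seed, restoring global RNG state after.
.with_seed <- function(seed, code) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

#' Configuration for the synthetic-data generator
#'
#' Defaults describe a desk-scale cohort: a 40-term phenotype DAG of depth 4,
#' 50 diseases of 8 annotated terms each, three nested group chains
#' (narrow within broad), half of each group member's terms drawn from a
#' shared group core (phenotypic relatedness within groups), a 20% chance of
#' swapping each observed term for a random one (curation/phenotyping noise)
#' and two observed terms recorded imprecisely as a parent. Under these
#' conditions the correct disease is usually near but not at the top of the
#' uniform-pretest ranking — a diagnostically ambiguous cohort, which is the
#' situation the pretest boost exists for.
#'
#' @param seed Integer seed; identical seed and config give identical output.
#' @param n_phenotype_terms Number of phenotype terms including the root.
#' @param phenotype_depth Number of levels below the phenotype root.
#' @param n_diseases Number of diseases in the corpus.
#' @param terms_per_disease Annotated phenotype terms per disease.
#' @param groups List of strictly increasing integer vectors; each vector is
#'   one nested chain of disease-group sizes, narrowest first (e.g.
#'   `c(3, 10)`: a narrow group of 3 diseases inside a broad group of 10).
#' @param group_overlap Fraction of a group member's terms drawn from the
#'   group's shared core, in \[0, 1\].
#' @param noise Probability that an observed term is swapped for a random
#'   ontology term during patient simulation, in \[0, 1\].
#' @param n_imprecise Number of observed terms replaced by a parent term
#'   (imprecise phenotyping) during patient simulation.
#' @return A list of class `synth_config`.
#' @export
synth_config <- function(seed = 1, n_phenotype_terms = 40,
                         phenotype_depth = 4, n_diseases = 50,
                         terms_per_disease = 8,
                         groups = list(c(3, 10), c(4, 12), c(5, 15)),
                         group_overlap = 0.5, noise = 0.2,
                         n_imprecise = 2) {
  stopifnot(n_phenotype_terms >= 2, phenotype_depth >= 1, n_diseases >= 1,
            terms_per_disease >= 1, group_overlap >= 0, group_overlap <= 1,
            noise >= 0, noise <= 1, n_imprecise >= 0)
  for (ch in groups) {
    if (length(ch) > 1L && any(diff(ch) <= 0)) {
      stop("infeasible nesting: group sizes must be strictly increasing ",
           "within a chain")
    }
  }
  outer_total <- sum(vapply(groups, function(ch) ch[length(ch)], numeric(1)))
  if (outer_total > n_diseases) {
    stop("infeasible nesting: group chains need ", outer_total,
         " diseases but n_diseases is ", n_diseases)
  }
  structure(
    list(seed = as.integer(seed), n_phenotype_terms = n_phenotype_terms,
         phenotype_depth = phenotype_depth, n_diseases = n_diseases,
         terms_per_disease = terms_per_disease, groups = groups,
         group_overlap = group_overlap, noise = noise,
         n_imprecise = n_imprecise),
    class = "synth_config"
  )
}

#' Generate synthetic phenotype and disease ontologies
#'
#' The phenotype ontology is a layered DAG: the root plus
#' `phenotype_depth` levels, each non-root term with one random parent in
#' the level above, and (where the layer widths permit) at least one diamond
#' — a term with two parents — so multiple-inheritance code paths are
#' exercised. The disease ontology contains one subtree per group chain:
#' nested group terms (broadest under the root, narrowest innermost) whose
#' leaf diseases carry cross-references to flat OMIM-style identifiers;
#' diseases outside any chain hang directly off the root.
#'
#' @param cfg A [synth_config()].
#' @return A list: `hpo` and `mondo` ([ontology_graph()]s), `xrefs` (data
#'   frame mapping `mondo_id` to `disease_id`), and `groups` — one entry per
#'   chain with `nodes` (group term ids, narrowest first) and `members`
#'   (list of cumulative disease-id sets per node).
#' @export
make_ontologies <- function(cfg) {
  stopifnot(inherits(cfg, "synth_config"))
  .with_seed(cfg$seed, {
    ## ---- phenotype DAG ----
    n <- cfg$n_phenotype_terms
    hp_ids <- sprintf("HP:%07d", seq_len(n))
    root <- hp_ids[1L]
    level <- c(0L, ((seq_len(n - 1L) - 1L) %% cfg$phenotype_depth) + 1L)
    child <- character(0); parent <- character(0)
    for (i in 2:n) {
      cands <- hp_ids[level == level[i] - 1L]
      p <- if (length(cands) == 1L) cands else sample(cands, 1L)
      child <- c(child, hp_ids[i]); parent <- c(parent, p)
    }
    # add a diamond where some term's parent level has >= 2 nodes
    for (i in 2:n) {
      cands <- setdiff(hp_ids[level == level[i] - 1L], parent[i - 1L])
      if (length(cands) > 0L) {
        p2 <- if (length(cands) == 1L) cands else sample(cands, 1L)
        child <- c(child, hp_ids[i]); parent <- c(parent, p2)
        break
      }
    }
    hpo <- ontology_graph(
      hp_ids, data.frame(child = child, parent = parent,
                         stringsAsFactors = FALSE),
      labels = stats::setNames(paste("Synthetic phenotype", seq_len(n)),
                               hp_ids),
      prefix = "HP")

    ## ---- disease ontology with nested groups and xrefs ----
    disease_ids <- sprintf("OMIM:%06d", 600000 + seq_len(cfg$n_diseases))
    mondo_root <- "MONDO:0000001"
    leaf_ids <- sprintf("MONDO:%07d", 1000000 + seq_len(cfg$n_diseases))
    m_terms <- c(mondo_root, leaf_ids)
    m_labels <- stats::setNames(
      c("synthetic disease root",
        paste("Synthetic disease", seq_len(cfg$n_diseases))),
      m_terms)
    m_child <- character(0); m_parent <- character(0)
    xrefs <- stats::setNames(as.list(disease_ids), leaf_ids)

    next_leaf <- 1L
    next_group <- 1L
    groups_out <- list()
    for (ch in cfg$groups) {
      sizes <- ch
      gids <- sprintf("MONDO:%07d", 2000000 + next_group - 1L +
                        seq_along(sizes))
      next_group <- next_group + length(sizes)
      # broadest under root; each narrower group under the next broader one
      for (j in rev(seq_along(sizes))) {
        p <- if (j == length(sizes)) mondo_root else gids[j + 1L]
        m_terms <- c(m_terms, gids[j])
        m_labels[gids[j]] <- sprintf("synthetic disease group (%d diseases)",
                                     sizes[j])
        m_child <- c(m_child, gids[j]); m_parent <- c(m_parent, p)
      }
      members <- vector("list", length(sizes))
      chain_start <- next_leaf
      prev <- 0L
      for (j in seq_along(sizes)) {
        take <- sizes[j] - prev
        leaves <- leaf_ids[next_leaf:(next_leaf + take - 1L)]
        m_child <- c(m_child, leaves)
        m_parent <- c(m_parent, rep(gids[j], take))
        next_leaf <- next_leaf + take
        prev <- sizes[j]
        # cumulative: group j contains every leaf of groups 1..j in the chain
        members[[j]] <- disease_ids[chain_start:(chain_start + sizes[j] - 1L)]
      }
      groups_out[[length(groups_out) + 1L]] <-
        list(nodes = gids, members = members)
    }
    if (next_leaf <= cfg$n_diseases) {
      rest <- leaf_ids[next_leaf:cfg$n_diseases]
      m_child <- c(m_child, rest)
      m_parent <- c(m_parent, rep(mondo_root, length(rest)))
    }
    mondo <- ontology_graph(
      m_terms, data.frame(child = m_child, parent = m_parent,
                          stringsAsFactors = FALSE),
      labels = m_labels, xrefs = xrefs, prefix = "MONDO")

    list(hpo = hpo, mondo = mondo,
         xrefs = data.frame(mondo_id = leaf_ids, disease_id = disease_ids,
                            stringsAsFactors = FALSE),
         groups = groups_out)
  })
}

#' Generate a synthetic annotation corpus
#'
#' Each disease receives `terms_per_disease` annotated phenotype terms with
#' frequencies drawn from the HPO frequency-term midpoints
#' (1.0, 0.895, 0.545, 0.17). Members of a disease group draw a
#' `group_overlap` fraction of their terms from a core set shared by the
#' group (its narrowest containing group when chains are nested), which
#' makes group members phenotypically related, as real disease families are.
#'
#' @param cfg A [synth_config()].
#' @param hpo Phenotype [ontology_graph()] from [make_ontologies()].
#' @param groups Optional `groups` component of [make_ontologies()]; when
#'   supplied, group members share core terms.
#' @return Named list of [disease_model()] objects keyed by disease id.
#' @export
make_corpus <- function(cfg, hpo, groups = NULL) {
  stopifnot(inherits(cfg, "synth_config"), inherits(hpo, "ontology_graph"))
  pool <- setdiff(hpo$terms, hpo$terms[1L]) # all non-root terms
  if (cfg$terms_per_disease > length(pool)) {
    stop("terms_per_disease exceeds the number of available phenotype terms")
  }
  freqs <- c(1.0, 0.895, 0.545, 0.17)
  disease_ids <- sprintf("OMIM:%06d", 600000 + seq_len(cfg$n_diseases))

  .with_seed(cfg$seed + 1L, {
    n_core <- round(cfg$group_overlap * cfg$terms_per_disease)
    # narrowest containing group per disease, with that group's core terms
    core_of <- stats::setNames(vector("list", cfg$n_diseases), disease_ids)
    if (!is.null(groups) && n_core > 0L) {
      for (ch in groups) {
        cores <- lapply(ch$nodes, function(g) sample(pool, n_core))
        seen <- character(0)
        for (j in seq_along(ch$nodes)) { # narrowest first
          fresh <- setdiff(ch$members[[j]], seen)
          for (d in fresh) core_of[[d]] <- cores[[j]]
          seen <- c(seen, fresh)
        }
      }
    }
    out <- list()
    for (i in seq_along(disease_ids)) {
      id <- disease_ids[i]
      core <- core_of[[id]]
      n_own <- cfg$terms_per_disease - length(core)
      own <- sample(setdiff(pool, core), n_own)
      terms <- c(core, own)
      ann <- stats::setNames(sample(freqs, length(terms), replace = TRUE),
                             terms)
      out[[id]] <- disease_model(id, ann,
                                 name = paste("Synthetic disease", i))
    }
    out
  })
}

#' Simulate a patient from a disease model
#'
#' Each annotated term is observed with probability equal to its frequency;
#' `n_imprecise` observed terms are then replaced by a parent term
#' (imprecise phenotyping), and every observed term is independently swapped
#' for a random ontology term with probability `noise` (curation error).
#' If the observed set comes out empty the draw is repeated, up to 10 times.
#'
#' @param disease A [disease_model()].
#' @param cfg A [synth_config()] (supplies `noise` and `n_imprecise`).
#' @param hpo Phenotype [ontology_graph()].
#' @param seed Integer seed for this patient.
#' @param subject_id Subject identifier for the profile.
#' @return A [patient_profile()] with `true_diagnosis` set to the disease.
#' @export
simulate_patient <- function(disease, cfg, hpo, seed,
                             subject_id = paste0("sim-", seed)) {
  stopifnot(inherits(disease, "disease_model"),
            inherits(cfg, "synth_config"))
  parents_of <- split(hpo$edges$parent, hpo$edges$child)
  pool <- setdiff(hpo$terms, hpo$terms[1L])
  .with_seed(seed, {
    obs <- character(0)
    for (attempt in seq_len(10L)) {
      terms <- names(disease$annotations)
      obs <- terms[stats::runif(length(terms)) < disease$annotations]
      if (length(obs) > 0L) break
    }
    if (length(obs) == 0L) {
      stop("failed to simulate a non-empty phenotype profile for ",
           disease$disease_id)
    }
    if (cfg$n_imprecise > 0L && length(obs) > 0L) {
      idx <- sample(seq_along(obs), min(cfg$n_imprecise, length(obs)))
      for (i in idx) {
        ps <- parents_of[[obs[i]]]
        if (!is.null(ps) && length(ps) > 0L) {
          obs[i] <- if (length(ps) == 1L) ps else sample(ps, 1L)
        }
      }
    }
    if (cfg$noise > 0) {
      swap <- stats::runif(length(obs)) < cfg$noise
      if (any(swap)) {
        obs[swap] <- sample(pool, sum(swap), replace = TRUE)
      }
    }
    patient_profile(observed = unique(obs), subject_id = subject_id,
                    true_diagnosis = disease$disease_id)
  })
}

#' Simulate a benchmark cohort over the synthetic group structure
#'
#' Draws `n_patients` patients from diseases belonging to narrow groups
#' (cycling through the chains) and pairs each with its chain's narrowest
#' and broadest group terms as the narrow/broad intuition.
#'
#' @param synth Output of [make_ontologies()].
#' @param corpus Output of [make_corpus()].
#' @param cfg A [synth_config()].
#' @param n_patients Number of patients to simulate.
#' @param seed Integer base seed (per-patient seeds are derived from it).
#' @return List of [benchmark_case()] objects.
#' @export
synth_benchmark_cases <- function(synth, corpus, cfg, n_patients,
                                  seed = cfg$seed) {
  stopifnot(length(synth$groups) > 0L)
  cases <- vector("list", n_patients)
  n_chain <- length(synth$groups)
  for (i in seq_len(n_patients)) {
    ch <- synth$groups[[((i - 1L) %% n_chain) + 1L]]
    narrow_members <- ch$members[[1L]]
    pick <- narrow_members[((i - 1L) %/% n_chain) %% length(narrow_members) + 1L]
    pat <- simulate_patient(corpus[[pick]], cfg, synth$hpo,
                            seed = seed + 1000L + i,
                            subject_id = sprintf("sim-%04d", i))
    cases[[i]] <- benchmark_case(
      pat, narrow_group = ch$nodes[1L],
      broad_group = ch$nodes[length(ch$nodes)])
  }
  cases
}

#' Write a complete synthetic data set to a directory
#'
#' Emits `hp.json` and `mondo.json` (OBO-Graph JSON), `corpus.hpoa` (HPOA
#' TSV) and, if `n_patients > 0`, a `phenopackets/` directory of Phenopacket
#' v2 JSON files plus `benchmark_cases.tsv` (phenopacket path, narrow group
#' id, broad group id) — the same formats the loaders consume.
#'
#' @param cfg A [synth_config()].
#' @param dir Output directory (created if needed).
#' @param n_patients Number of simulated patients to write.
#' @return `dir`, invisibly.
#' @export
write_synth_dir <- function(cfg, dir, n_patients = 0L) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  synth <- make_ontologies(cfg)
  corpus <- make_corpus(cfg, synth$hpo, synth$groups)
  write_obograph(synth$hpo, file.path(dir, "hp.json"))
  write_obograph(synth$mondo, file.path(dir, "mondo.json"))
  write_hpoa(corpus, file.path(dir, "corpus.hpoa"))
  if (n_patients > 0L) {
    ppdir <- file.path(dir, "phenopackets")
    dir.create(ppdir, showWarnings = FALSE)
    cases <- synth_benchmark_cases(synth, corpus, cfg, n_patients)
    rows <- character(0)
    for (i in seq_along(cases)) {
      pp <- file.path(ppdir, sprintf("patient-%04d.json", i))
      write_phenopacket(cases[[i]]$patient, pp, hpo = synth$hpo)
      rows <- c(rows, paste(pp, cases[[i]]$narrow_group,
                            cases[[i]]$broad_group, sep = "\t"))
    }
    writeLines(c("phenopacket\tnarrow_group\tbroad_group", rows),
               file.path(dir, "benchmark_cases.tsv"))
  }
  invisible(dir)
}
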