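# Disease models: frequency-weighted phenotype annotations per disease, parsed
# from the HPOA tab-separated dialect (phenotype.hpoa), plus corpus-wide
# background phenotype frequencies that estimate Pr(x | not-D).

# Midpoints of the HPO frequency-term ranges.
.HPO_FREQ_TERMS <- c(
  "HP:0040280" = 1.0,    # Obligate (100%)
  "HP:0040281" = 0.895,  # Very frequent (80-99%)
  "HP:0040282" = 0.545,  # Frequent (30-79%)
  "HP:0040283" = 0.17,   # Occasional (5-29%)
  "HP:0040284" = 0.025   # Very rare (1-4%)
)

#' Construct a disease model
#'
#' One flat-identifier disease (e.g. an OMIM entry) with frequency-weighted
#' phenotype annotations and explicitly excluded phenotypes. Annotation
#' frequencies are Pr(phenotype | disease), the sensitivity side of the
#' likelihood ratio.
#'
#' @param disease_id Flat disease identifier (CURIE, e.g. `"OMIM:118651"`).
#' @param annotations Named numeric vector: phenotype term id -> frequency in
#'   (0, 1].
#' @param excluded Character vector of phenotype term ids asserted absent in
#'   the disease. Must be disjoint from `names(annotations)`.
#' @param name Human-readable disease name.
#' @return An object of class `disease_model`.
#' @export
disease_model <- function(disease_id, annotations, excluded = character(),
                          name = disease_id) {
  stopifnot(is_curie(disease_id))
  annotations <- unlist(annotations)
  if (length(annotations) > 0L) {
    if (is.null(names(annotations)) || any(names(annotations) == "")) {
      stop("annotations must be a named vector (phenotype term -> frequency)")
    }
    if (any(annotations <= 0 | annotations > 1)) {
      stop("annotation frequencies must lie in (0, 1]")
    }
  } else {
    annotations <- stats::setNames(numeric(0), character(0))
  }
  overlap <- intersect(names(annotations), excluded)
  if (length(overlap) > 0L) {
    stop("term both annotated and excluded for ", disease_id, ": ", overlap[1])
  }
  structure(
    list(disease_id = disease_id, name = name,
         annotations = annotations, excluded = unique(excluded)),
    class = "disease_model"
  )
}

#' @export
print.disease_model <- function(x, ...) {
  cat(sprintf("<disease_model> %s (%s): %d annotations, %d excluded\n",
              x$disease_id, x$name, length(x$annotations), length(x$excluded)))
  invisible(x)
}

# Parse one HPOA frequency field to a numeric frequency, or NA if unparseable.
# Accepted dialects: empty (-> default), HPO frequency term, "m/n" ratio,
# percentage ("45%" / "4.5%").
.parse_frequency <- function(s, default = 1.0) {
  s <- trimws(s)
  if (is.na(s) || s == "") return(default)
  if (s %in% names(.HPO_FREQ_TERMS)) return(unname(.HPO_FREQ_TERMS[[s]]))
  if (grepl("^[0-9]+/[0-9]+$", s)) {
    mn <- as.numeric(strsplit(s, "/", fixed = TRUE)[[1L]])
    if (mn[2L] == 0) return(NA_real_)
    return(mn[1L] / mn[2L])
  }
  if (grepl("^[0-9.]+%$", s)) {
    return(as.numeric(sub("%$", "", s)) / 100)
  }
  NA_real_
}

#' Parse HPOA disease-phenotype annotations
#'
#' Reads the tab-separated `phenotype.hpoa` dialect: comment lines starting
#' with `#`, a header, and one row per disease-phenotype assertion. Rows with
#' qualifier `"NOT"` (or a frequency of exactly zero) populate the excluded
#' set. The frequency column accepts HPO frequency terms (mapped to range
#' midpoints), `m/n` ratios and percentages; an empty field defaults to
#' `default_frequency` since the presence of an annotation asserts the
#' feature is characteristic. If a term is asserted both present and absent
#' for one disease, the absence assertion wins and a warning is raised.
#'
#' @param path Path to an HPOA file.
#' @param databases Database prefixes to retain (default `"OMIM"`).
#' @param default_frequency Frequency used when the field is empty or
#'   unparseable (default 1.0).
#' @return Named list of [disease_model()] objects, keyed and sorted by
#'   disease identifier.
#' @export
parse_hpoa <- function(path, databases = "OMIM", default_frequency = 1.0) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- utils::read.delim(path, sep = "\t", comment.char = "#", quote = "",
                          stringsAsFactors = FALSE,
                          colClasses = "character")
  required <- c("database_id", "disease_name", "qualifier", "hpo_id",
                "frequency")
  missing <- setdiff(required, names(df))
  if (length(missing) > 0L) {
    stop("HPOA file lacks mandatory column(s): ",
         paste(missing, collapse = ", "))
  }
  df <- df[term_prefix(df$database_id) %in% databases, , drop = FALSE]

  out <- list()
  for (id in sort(unique(df$database_id))) {
    rows <- df[df$database_id == id, , drop = FALSE]
    ann <- numeric(0)
    excl <- character(0)
    for (i in seq_len(nrow(rows))) {
      t <- rows$hpo_id[i]
      if (identical(toupper(trimws(rows$qualifier[i])), "NOT")) {
        excl <- c(excl, t)
        next
      }
      f <- .parse_frequency(rows$frequency[i], default_frequency)
      if (is.na(f)) {
        warning("unparseable frequency '", rows$frequency[i], "' for ",
                id, " / ", t, "; using default ", default_frequency,
                call. = FALSE)
        f <- default_frequency
      }
      if (f <= 0) { # a 0/n or 0% assertion is an absence statement
        excl <- c(excl, t)
        next
      }
      ann[t] <- min(f, 1.0)
    }
    both <- intersect(names(ann), excl)
    if (length(both) > 0L) {
      warning("terms both asserted and NOT for ", id, " (NOT wins): ",
              paste(both, collapse = ", "), call. = FALSE)
      ann <- ann[setdiff(names(ann), both)]
    }
    out[[id]] <- disease_model(id, ann, excluded = unique(excl),
                               name = rows$disease_name[1L])
  }
  out
}

#' Write disease models in the HPOA dialect
#'
#' Inverse of [parse_hpoa()]. Frequencies matching an HPO frequency-term
#' midpoint are written as that term so `parse -> write -> parse` round-trips
#' exactly for synthetic corpora; other values are written as percentages.
#'
#' @param corpus List of [disease_model()] objects.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_hpoa <- function(corpus, path) {
  inv <- stats::setNames(names(.HPO_FREQ_TERMS), as.character(.HPO_FREQ_TERMS))
  lines <- c(
    "#description: disease-phenotype annotations",
    paste("database_id", "disease_name", "qualifier", "hpo_id", "reference",
          "evidence", "onset", "frequency", sep = "\t")
  )
  for (d in corpus[order(names(corpus))]) {
    for (t in sort(names(d$annotations))) {
      f <- d$annotations[[t]]
      key <- as.character(f)
      fs <- if (!is.na(inv[key])) unname(inv[key]) else sprintf("%.17g%%", f * 100)
      lines <- c(lines, paste(d$disease_id, d$name, "", t, "", "TAS", "", fs,
                              sep = "\t"))
    }
    for (t in sort(d$excluded)) {
      lines <- c(lines, paste(d$disease_id, d$name, "NOT", t, "", "TAS", "",
                              "", sep = "\t"))
    }
  }
  writeLines(lines, path)
  invisible(path)
}

#' Background phenotype frequencies across a disease corpus
#'
#' Estimates Pr(phenotype | not-disease) for every ontology term as the
#' fraction of corpus diseases annotated with the term or any of its
#' descendants (annotation propagation along `is_a`). Frequencies are floored
#' at `1/(2N)` so that no likelihood ratio becomes infinite; the phenotype
#' root reaches 1 whenever every disease has at least one annotation.
#'
#' @param corpus List of [disease_model()] objects.
#' @param hpo Phenotype [ontology_graph()].
#' @return An object of class `background_frequencies` with components
#'   `freq` (named numeric over all ontology terms) and `n_diseases`.
#' @export
background_frequencies <- function(corpus, hpo) {
  stopifnot(inherits(hpo, "ontology_graph"))
  n <- length(corpus)
  if (n == 0L) stop("empty corpus")
  counts <- stats::setNames(integer(length(hpo$terms)), hpo$terms)
  for (d in corpus) {
    terms <- names(d$annotations)
    known <- terms %in% hpo$terms
    if (any(!known)) {
      warning("annotated term(s) absent from ontology, skipped: ",
              paste(terms[!known], collapse = ", "), call. = FALSE)
      terms <- terms[known]
    }
    reached <- unique(unlist(hpo$ancestors[terms], use.names = FALSE))
    counts[reached] <- counts[reached] + 1L
  }
  floor_ <- 1 / (2 * n)
  freq <- pmax(counts / n, floor_)
  structure(list(freq = freq, n_diseases = n),
            class = "background_frequencies")
}

#' @export
print.background_frequencies <- function(x, ...) {
  cat(sprintf("<background_frequencies> %d terms over %d diseases\n",
              length(x$freq), x$n_diseases))
  invisible(x)
}
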