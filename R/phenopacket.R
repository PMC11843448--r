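# Minimal GA4GH Phenopacket v2 JSON reader/writer: phenotypicFeatures,
# subject.id and the disease diagnosis are all the phenotype-only engine
# needs. Onset, measurements and variant records are ignored.

#' Construct a patient profile
#'
#' The observed and explicitly excluded phenotype terms of one individual —
#' the test-result vector the likelihood-ratio engine scores — plus an
#' optional known diagnosis used in benchmarking. Duplicates are removed
#' preserving first occurrence (the composite LR must not double-count);
#' a term listed both observed and excluded is kept as excluded, with a
#' warning.
#'
#' @param observed Character vector of observed phenotype term ids.
#' @param excluded Character vector of explicitly excluded phenotype term ids.
#' @param subject_id Identifier for the individual.
#' @param true_diagnosis Optional flat disease identifier (e.g. OMIM) of the
#'   known diagnosis; `NA` if unknown.
#' @return An object of class `patient_profile`.
#' @export
patient_profile <- function(observed, excluded = character(),
                            subject_id = "patient",
                            true_diagnosis = NA_character_) {
  observed <- unique(as.character(observed))
  excluded <- unique(as.character(excluded))
  both <- intersect(observed, excluded)
  if (length(both) > 0L) {
    warning("term(s) both observed and excluded (excluded wins): ",
            paste(both, collapse = ", "), call. = FALSE)
    observed <- setdiff(observed, both)
  }
  structure(
    list(subject_id = subject_id, observed = observed, excluded = excluded,
         true_diagnosis = true_diagnosis),
    class = "patient_profile"
  )
}

#' @export
print.patient_profile <- function(x, ...) {
  cat(sprintf("<patient_profile> %s: %d observed, %d excluded%s\n",
              x$subject_id, length(x$observed), length(x$excluded),
              if (!is.na(x$true_diagnosis))
                paste0(", diagnosis ", x$true_diagnosis) else ""))
  invisible(x)
}

#' Read a GA4GH Phenopacket v2 JSON file
#'
#' Parses the subset needed for analysis: `subject.id`,
#' `phenotypicFeatures[].type.id` with the optional `excluded` flag, and the
#' first OMIM disease identifier found in `diseases[]` or
#' `interpretations[].diagnosis`. Features whose term id is not an HP CURIE
#' are skipped with a warning.
#'
#' @param path Path to a phenopacket JSON file.
#' @return A [patient_profile()].
#' @export
read_phenopacket <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  js <- tryCatch(
    jsonlite::fromJSON(path, simplifyVector = FALSE),
    error = function(e) stop("malformed phenopacket JSON in '", path, "': ",
                             conditionMessage(e), call. = FALSE)
  )
  subject_id <- if (!is.null(js$subject$id)) js$subject$id else
    if (!is.null(js$id)) js$id else "patient"

  obs <- character(0); excl <- character(0)
  for (f in js$phenotypicFeatures) {
    id <- f$type$id
    if (is.null(id)) next
    if (term_prefix(id) != "HP") {
      warning("skipping feature with non-HP term id: ", id, call. = FALSE)
      next
    }
    if (isTRUE(f$excluded)) excl <- c(excl, id) else obs <- c(obs, id)
  }

  diag <- NA_character_
  for (d in js$diseases) {
    id <- d$term$id
    if (!is.null(id) && term_prefix(id) == "OMIM") { diag <- id; break }
  }
  if (is.na(diag)) {
    for (it in js$interpretations) {
      id <- it$diagnosis$disease$id
      if (!is.null(id) && term_prefix(id) == "OMIM") { diag <- id; break }
    }
  }
  patient_profile(observed = obs, excluded = excl, subject_id = subject_id,
                  true_diagnosis = diag)
}

#' Write a patient profile as Phenopacket v2 JSON
#'
#' Emits the same subset [read_phenopacket()] consumes, so synthetic patients
#' exercise the real parser and write -> read round-trips.
#'
#' @param patient A [patient_profile()].
#' @param path Output path.
#' @param hpo Optional phenotype [ontology_graph()] used to fill feature
#'   labels.
#' @return `path`, invisibly.
#' @export
write_phenopacket <- function(patient, path, hpo = NULL) {
  stopifnot(inherits(patient, "patient_profile"))
  lab <- function(t) {
    if (!is.null(hpo) && t %in% names(hpo$labels)) unname(hpo$labels[[t]])
    else t
  }
  feats <- c(
    lapply(patient$observed, function(t)
      list(type = list(id = t, label = lab(t)))),
    lapply(patient$excluded, function(t)
      list(type = list(id = t, label = lab(t)), excluded = TRUE))
  )
  doc <- list(
    id = patient$subject_id,
    subject = list(id = patient$subject_id),
    phenotypicFeatures = feats,
    metaData = list(phenopacketSchemaVersion = "2.0")
  )
  if (!is.na(patient$true_diagnosis)) {
    doc$diseases <- list(list(term = list(id = patient$true_diagnosis,
                                          label = patient$true_diagnosis)))
  }
  jsonlite::write_json(doc, path, auto_unbox = TRUE, pretty = TRUE,
                       digits = NA)
  invisible(path)
}
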