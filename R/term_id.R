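# Term identifiers are plain character CURIEs, "PREFIX:localid"
# (e.g. "HP:0000118", "MONDO:0007322", "OMIM:118651"). Comparison is by the
# canonical rendering, case-sensitive in the prefix.

#' Validate CURIE-style term identifiers
#'
#' A term identifier is a compact URI of the form `"PREFIX:localid"`, e.g.
#' `"HP:0000118"` or `"OMIM:118651"`.
#'
#' @param x Character vector.
#' @return Logical vector, `TRUE` where the element is a well-formed CURIE.
#' @examples
#' is_curie(c("HP:0000001", "not a curie"))
#' @export
is_curie <- function(x) {
  grepl("^[A-Za-z][A-Za-z0-9_.]*:[A-Za-z0-9]+$", x)
}

#' Extract the namespace prefix of a term identifier
#'
#' @param x Character vector of CURIEs.
#' @return Character vector of prefixes (the part before the first `":"`).
#' @examples
#' term_prefix("MONDO:0007322")
#' @export
term_prefix <- function(x) sub(":.*$", "", x)

#' Extract the local part of a term identifier
#'
#' @param x Character vector of CURIEs.
#' @return Character vector of local identifiers (the part after the prefix).
#' @export
term_local <- function(x) sub("^[^:]*:", "", x)

#' Convert OBO-style IRIs to CURIEs
#'
#' Takes the IRI fragment after the last `"/"` or `"#"` and replaces the first
#' underscore with a colon, so `"http://purl.obolibrary.org/obo/MONDO_0007322"`
#' becomes `"MONDO:0007322"`. Inputs that already look like CURIEs pass through
#' unchanged.
#'
#' @param iri Character vector of IRIs or CURIEs.
#' @return Character vector of CURIEs.
#' @examples
#' iri_to_curie("http://purl.obolibrary.org/obo/HP_0000118")
#' @export
iri_to_curie <- function(iri) {
  out <- ifelse(is_curie(iri), iri, sub("_", ":", sub("^.*[/#]", "", iri)))
  out
}

#' Convert CURIEs to OBO purl IRIs
#'
#' Inverse of [iri_to_curie()] for the OBO purl convention.
#'
#' @param curie Character vector of CURIEs.
#' @return Character vector of IRIs.
#' @export
curie_to_iri <- function(curie) {
  paste0("http://purl.obolibrary.org/obo/", sub(":", "_", curie))
}
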