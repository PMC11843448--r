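# Pretest probability distributions over the disease corpus, and the
# intuition-driven group boost: each of the k diseases in the chosen group is
# raised from 1/N to (1+a)/N and the distribution renormalized, giving the
# exact closed form
#   boosted:     (1+a) / (N + k a)
#   non-boosted:     1 / (N + k a)
# so the boosted / non-boosted ratio is exactly 1+a, and a = 0 reproduces the
# uniform distribution bit for bit.

#' Construct a pretest distribution
#'
#' Low-level constructor; prefer [uniform_pretest()], [adjust_pretest()] or
#' [build_adjusted()].
#'
#' @param probs Named numeric vector of probabilities over all diseases;
#'   must be positive and sum to 1 (tolerance 1e-12 relative to N).
#' @param boosted Character vector of boosted disease ids (subset of
#'   `names(probs)`).
#' @param adjustment Adjustment factor a >= 0.
#' @return An object of class `pretest_distribution` with components `probs`,
#'   `n_diseases`, `boosted`, `adjustment`.
#' @export
pretest_distribution <- function(probs, boosted = character(),
                                 adjustment = 0) {
  if (length(probs) == 0L) stop("empty disease corpus")
  if (is.null(names(probs)) || any(names(probs) == "")) {
    stop("probs must be named by disease id")
  }
  if (any(probs <= 0)) stop("all pretest probabilities must be positive")
  if (abs(sum(probs) - 1) > 1e-9) {
    stop(sprintf("pretest probabilities sum to %.12g, not 1", sum(probs)))
  }
  bad <- setdiff(boosted, names(probs))
  if (length(bad) > 0L) stop("boosted disease outside corpus: ", bad[1])
  if (adjustment < 0) stop("adjustment must be >= 0")
  structure(
    list(probs = probs, n_diseases = length(probs),
         boosted = sort(boosted), adjustment = adjustment),
    class = "pretest_distribution"
  )
}

#' @export
print.pretest_distribution <- function(x, ...) {
  cat(sprintf(
    "<pretest_distribution> N=%d, k=%d boosted, a=%g (boosted p=%.4g)\n",
    x$n_diseases, length(x$boosted), x$adjustment,
    if (length(x$boosted) > 0L) x$probs[[x$boosted[1L]]] else NA_real_))
  invisible(x)
}

#' Uniform pretest distribution
#'
#' Every disease receives 1/N, the default in the absence of clinical
#' intuition.
#'
#' @param corpus_ids Character vector of disease identifiers.
#' @return A [pretest_distribution()] with empty boosted set and a = 0.
#' @examples
#' uniform_pretest(sprintf("OMIM:%06d", 1:4))
#' @export
uniform_pretest <- function(corpus_ids) {
  corpus_ids <- unique(as.character(corpus_ids))
  if (length(corpus_ids) == 0L) stop("empty disease corpus")
  n <- length(corpus_ids)
  pretest_distribution(stats::setNames(rep(1 / n, n), corpus_ids))
}

#' Boost a disease group's pretest probability and renormalize
#'
#' Sets each of the k boosted diseases to (1+a)/N and renormalizes, which in
#' closed form gives (1+a)/(N + k a) for boosted and 1/(N + k a) for
#' non-boosted diseases. With a = 0 this is exactly [uniform_pretest()].
#'
#' @param corpus_ids Character vector of all disease identifiers (size N).
#' @param boosted Character vector of boosted disease ids (size k), a subset
#'   of `corpus_ids`.
#' @param a Adjustment factor, >= 0; encodes the strength of the clinical
#'   intuition.
#' @return A [pretest_distribution()].
#' @examples
#' # the boosted probability for N = 8307, k = 2, a = 5 is 6/8317 ~ 7.2e-4
#' d <- adjust_pretest(sprintf("D:%d", 1:10), sprintf("D:%d", 1:2), a = 4)
#' d$probs[1:3]  # 5/18, 5/18, 1/18
#' @export
adjust_pretest <- function(corpus_ids, boosted, a) {
  corpus_ids <- unique(as.character(corpus_ids))
  if (length(corpus_ids) == 0L) stop("empty disease corpus")
  boosted <- unique(as.character(boosted))
  bad <- setdiff(boosted, corpus_ids)
  if (length(bad) > 0L) stop("boosted disease outside corpus: ", bad[1])
  if (length(a) != 1L || is.na(a) || a < 0) stop("adjustment must be >= 0")
  n <- length(corpus_ids)
  k <- length(boosted)
  denom <- n + k * a
  probs <- stats::setNames(rep(1 / denom, n), corpus_ids)
  probs[boosted] <- (1 + a) / denom
  pretest_distribution(probs, boosted = boosted, adjustment = a)
}

#' Build an adjusted pretest distribution from an intuition specification
#'
#' Composes [group_to_diseases()] (expand the chosen disease-group term and
#' its descendants to corpus disease ids via cross-references) with
#' [adjust_pretest()]. If the group maps to no corpus disease, a warning is
#' raised and the uniform distribution is returned.
#'
#' @param mondo Disease [ontology_graph()].
#' @param group_term Disease-group term identifier within `mondo`.
#' @param adjustment Adjustment factor a >= 0.
#' @param corpus_ids Character vector of all corpus disease identifiers.
#' @return A [pretest_distribution()].
#' @export
build_adjusted <- function(mondo, group_term, adjustment, corpus_ids) {
  boosted <- group_to_diseases(mondo, group_term, corpus_ids)
  if (length(boosted) == 0L) {
    return(uniform_pretest(corpus_ids))
  }
  adjust_pretest(corpus_ids, boosted, adjustment)
}

#' Save a pretest distribution as a text file
#'
#' Tab-separated format: a header line `#adjustment=<a>` followed by rows of
#' `disease_id  probability  boosted_flag`. Probabilities are written with 17
#' significant digits so save/load round-trips exactly.
#'
#' @param d A [pretest_distribution()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
save_pretest <- function(d, path) {
  stopifnot(inherits(d, "pretest_distribution"))
  ids <- names(d$probs)
  lines <- c(
    sprintf("#adjustment=%.17g", d$adjustment),
    sprintf("%s\t%.17g\t%d", ids, unname(d$probs),
            as.integer(ids %in% d$boosted))
  )
  writeLines(lines, path)
  invisible(path)
}

#' Load a pretest distribution from a text file
#'
#' Inverse of [save_pretest()]. Files whose probabilities do not sum to 1
#' within 1e-9 are rejected. Whether the disease ids match the corpus in use
#' is checked at ranking time, not at load time.
#'
#' @param path Path to a file written by [save_pretest()].
#' @return A [pretest_distribution()].
#' @export
load_pretest <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path)
  a <- 0
  hdr <- grepl("^#adjustment=", lines)
  if (any(hdr)) {
    a <- as.numeric(sub("^#adjustment=", "", lines[hdr][1L]))
    if (is.na(a)) stop("unparseable adjustment header")
  }
  rows <- lines[!grepl("^#", lines) & nzchar(lines)]
  parts <- strsplit(rows, "\t", fixed = TRUE)
  if (any(lengths(parts) < 3L)) stop("malformed pretest file row")
  ids <- vapply(parts, `[[`, character(1), 1L)
  probs <- as.numeric(vapply(parts, `[[`, character(1), 2L))
  flags <- vapply(parts, `[[`, character(1), 3L) == "1"
  if (anyNA(probs)) stop("unparseable probability in pretest file")
  if (abs(sum(probs) - 1) > 1e-9) {
    stop(sprintf("pretest file probabilities sum to %.12g, not 1",
                 sum(probs)))
  }
  pretest_distribution(stats::setNames(probs, ids), boosted = ids[flags],
                       adjustment = a)
}
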