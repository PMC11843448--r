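# Likelihood-ratio engine. For each phenotype term x in a patient profile and
# each candidate disease D, LR(x) = Pr(x | D) / Pr(x | not-D). Per-term LRs
# are multiplied into a composite LR under an explicit independence
# assumption (accumulated in log space), and converted to a posttest
# probability via Bayes' rule in odds form:
#   Pr(D | X) = p LR(X) / (1 - p + p LR(X)).

#' Likelihood-ratio model options
#'
#' Tunable constants of the per-term matching model. The matching model is a
#' deliberately simple, monotone reconstruction of phenotype-likelihood-ratio
#' scoring: the pretest-adjustment machinery this package exists for is
#' agnostic to the LR internals, needing only positive, finite per-term LRs.
#'
#' @param no_match_lr LR assigned to an observed term with no exact, ancestor
#'   or descendant match among the disease's annotations (default 0.01 — a
#'   strong but bounded penalty).
#' @param excluded_cap Upper cap on the LR reward when a patient-excluded term
#'   is also absent from the disease model (default 2.0).
#' @param ancestor_match_factor Multiplier applied to the annotation frequency
#'   when the observed term is more specific than (a descendant of) the
#'   annotated term (default 0.5: a more specific presentation is compatible
#'   but not guaranteed).
#' @return A list of class `lr_options`.
#' @export
lr_options <- function(no_match_lr = 0.01, excluded_cap = 2.0,
                       ancestor_match_factor = 0.5) {
  stopifnot(no_match_lr > 0, excluded_cap >= 1, ancestor_match_factor > 0,
            ancestor_match_factor <= 1)
  structure(list(no_match_lr = no_match_lr, excluded_cap = excluded_cap,
                 ancestor_match_factor = ancestor_match_factor),
            class = "lr_options")
}

.bg_freq <- function(bg, t) {
  f <- bg$freq[t]
  if (is.na(f)) stop("unknown term: ", t)
  unname(f)
}

#' Likelihood ratio for one phenotype term against one disease
#'
#' For an observed term the numerator Pr(x | D) depends on how the term
#' relates to the disease's annotations: an exact annotation contributes its
#' frequency f; an annotated ancestor of the observed term contributes
#' f * `ancestor_match_factor` (the patient is more specific than the model);
#' an annotated descendant contributes its frequency f (the patient is less
#' specific); with no related annotation the LR is the fixed `no_match_lr`
#' penalty. The denominator is always the background frequency of the
#' observed term. When several annotations match, the one yielding the
#' highest LR wins, ties broken by smallest term id.
#'
#' For an excluded term: if the disease is annotated with it at frequency f,
#' the LR is (1 - f) / max(1 - bg, 1/(2N)) (exclusion contradicts the model);
#' if not, the LR is 1 / (1 - bg), capped at `excluded_cap`.
#'
#' @param t Phenotype term identifier.
#' @param observed `TRUE` if the term was observed in the patient, `FALSE`
#'   if explicitly excluded.
#' @param disease A [disease_model()].
#' @param bg [background_frequencies()] built over the same corpus.
#' @param hpo Phenotype [ontology_graph()].
#' @param opts [lr_options()].
#' @return A list of class `term_lr` with fields `query_term`, `match_type`,
#'   `matched_term`, `numerator`, `denominator`, `lr`.
#' @export
term_lr <- function(t, observed, disease, bg, hpo, opts = lr_options()) {
  .check_term(hpo, t)
  ann <- disease$annotations
  n_dis <- bg$n_diseases
  bgf <- .bg_freq(bg, t)

  if (observed) {
    if (t %in% names(ann)) {
      num <- unname(ann[[t]])
      res <- list(match_type = "EXACT", matched_term = t, numerator = num,
                  denominator = bgf)
    } else {
      anc <- intersect(setdiff(ancestors(hpo, t), t), names(ann))
      des <- intersect(setdiff(descendants(hpo, t), t), names(ann))
      cand <- data.frame(
        term = c(anc, des),
        type = c(rep("QUERY_DESCENDANT_OF_ANNOTATION", length(anc)),
                 rep("QUERY_ANCESTOR_OF_ANNOTATION", length(des))),
        num = c(unname(ann[anc]) * opts$ancestor_match_factor,
                unname(ann[des])),
        stringsAsFactors = FALSE
      )
      if (nrow(cand) == 0L) {
        res <- list(match_type = "NO_MATCH", matched_term = NA_character_,
                    numerator = opts$no_match_lr * bgf, denominator = bgf)
      } else {
        cand <- cand[order(-cand$num, cand$term), , drop = FALSE]
        res <- list(match_type = cand$type[1L], matched_term = cand$term[1L],
                    numerator = cand$num[1L], denominator = bgf)
      }
    }
  } else {
    if (t %in% names(ann)) {
      f <- unname(ann[[t]])
      num <- max(1 - f, 1 / (2 * n_dis))
      den <- max(1 - bgf, 1 / (2 * n_dis))
      res <- list(match_type = "EXCLUDED_VIOLATED", matched_term = t,
                  numerator = num, denominator = den)
    } else {
      den <- max(1 - bgf, 1 / (2 * n_dis))
      lr <- min(1 / den, opts$excluded_cap)
      res <- list(match_type = "EXCLUDED_CONFIRMED", matched_term = NA_character_,
                  numerator = lr * den, denominator = den)
    }
  }
  structure(c(list(query_term = t), res,
              list(lr = res$numerator / res$denominator)),
            class = "term_lr")
}

#' @export
print.term_lr <- function(x, ...) {
  cat(sprintf("<term_lr> %s %s LR=%.4g (%.4g / %.4g)\n", x$query_term,
              x$match_type, x$lr, x$numerator, x$denominator))
  invisible(x)
}

# Precompute per-term quantities shared by all diseases for one patient:
# background denominators and the annotated-ancestor/descendant candidate
# sets only depend on the term, not the disease.
.patient_context <- function(patient, bg, hpo) {
  obs <- patient$observed
  if (length(obs) == 0L) stop("patient has no observed phenotype terms")
  unknown <- setdiff(c(obs, patient$excluded), hpo$terms)
  if (length(unknown) > 0L) stop("unknown term: ", unknown[1])
  list(
    observed = obs,
    excluded = patient$excluded,
    bg_obs = vapply(obs, function(t) .bg_freq(bg, t), numeric(1)),
    bg_excl = vapply(patient$excluded, function(t) .bg_freq(bg, t), numeric(1)),
    anc = lapply(stats::setNames(obs, obs),
                 function(t) setdiff(hpo$ancestors[[t]], t)),
    des = lapply(stats::setNames(obs, obs),
                 function(t) setdiff(hpo$descendants[[t]], t)),
    n_diseases = bg$n_diseases
  )
}

# log composite LR of one disease given a precomputed patient context.
.composite_loglr <- function(ctx, disease, opts) {
  ann <- disease$annotations
  ann_names <- names(ann)
  total <- 0
  half <- 1 / (2 * ctx$n_diseases)
  for (i in seq_along(ctx$observed)) {
    t <- ctx$observed[[i]]
    bgf <- ctx$bg_obs[[i]]
    if (t %in% ann_names) {
      num <- ann[[t]]
    } else {
      a <- intersect(ctx$anc[[t]], ann_names)
      d <- intersect(ctx$des[[t]], ann_names)
      nums <- c(ann[a] * opts$ancestor_match_factor, ann[d])
      num <- if (length(nums) == 0L) opts$no_match_lr * bgf else max(nums)
    }
    total <- total + log(num) - log(bgf)
  }
  for (i in seq_along(ctx$excluded)) {
    t <- ctx$excluded[[i]]
    bgf <- ctx$bg_excl[[i]]
    den <- max(1 - bgf, half)
    if (t %in% ann_names) {
      lr <- max(1 - ann[[t]], half) / den
    } else {
      lr <- min(1 / den, opts$excluded_cap)
    }
    total <- total + log(lr)
  }
  total
}

#' Composite likelihood ratio of a patient profile for one disease
#'
#' Product of per-term likelihood ratios over all observed and excluded terms
#' (independence assumption), accumulated in log space to avoid
#' under/overflow.
#'
#' @param patient A [patient_profile()] with at least one observed term.
#' @param disease A [disease_model()].
#' @param bg [background_frequencies()].
#' @param hpo Phenotype [ontology_graph()].
#' @param opts [lr_options()].
#' @return Positive composite LR (may be `Inf`-free but very large; use
#'   [lr_breakdown()] for per-term detail).
#' @export
composite_lr <- function(patient, disease, bg, hpo, opts = lr_options()) {
  ctx <- .patient_context(patient, bg, hpo)
  exp(.composite_loglr(ctx, disease, opts))
}

#' Per-term likelihood-ratio breakdown for one disease
#'
#' @inheritParams composite_lr
#' @return Data frame with one row per observed/excluded term: `query_term`,
#'   `status`, `match_type`, `matched_term`, `numerator`, `denominator`,
#'   `lr`, `log10_lr`.
#' @export
lr_breakdown <- function(patient, disease, bg, hpo, opts = lr_options()) {
  terms <- c(patient$observed, patient$excluded)
  obs_flag <- c(rep(TRUE, length(patient$observed)),
                rep(FALSE, length(patient$excluded)))
  out <- do.call(rbind, lapply(seq_along(terms), function(i) {
    x <- term_lr(terms[i], obs_flag[i], disease, bg, hpo, opts)
    data.frame(query_term = x$query_term,
               status = if (obs_flag[i]) "observed" else "excluded",
               match_type = x$match_type,
               matched_term = x$matched_term,
               numerator = x$numerator, denominator = x$denominator,
               lr = x$lr, log10_lr = log10(x$lr),
               stringsAsFactors = FALSE)
  }))
  out
}

#' Posttest probability from pretest probability and composite LR
#'
#' Bayes' rule in odds form: posttest odds equal pretest odds times the
#' likelihood ratio, i.e. Pr(D | X) = p LR / (1 - p + p LR). Monotone
#' increasing in both arguments.
#'
#' @param p Pretest probability in \[0, 1\] (vectorized).
#' @param lr Composite likelihood ratio, >= 0 (vectorized).
#' @return Posttest probability in \[0, 1\].
#' @examples
#' posttest_probability(0.5, 1)    # 0.5: an uninformative test
#' posttest_probability(1/8297, 1000)
#' @export
posttest_probability <- function(p, lr) {
  if (any(p < 0 | p > 1)) stop("pretest probability outside [0, 1]")
  if (any(lr < 0)) stop("likelihood ratio must be non-negative")
  p * lr / (1 - p + p * lr)
}

# Posttest probabilities from log LRs via log-odds, numerically safe for
# huge composite LRs; equals the naive formula where that formula is finite.
.posttest_from_loglr <- function(p, loglr) {
  ifelse(p == 0, 0,
         ifelse(p == 1, 1, stats::plogis(log(p) - log1p(-p) + loglr)))
}

#' Rank all corpus diseases for one patient
#'
#' Computes the composite LR for every disease, converts it to a posttest
#' probability using that disease's pretest probability, and sorts by
#' posttest probability (descending), breaking ties by composite LR
#' (descending) and then disease id (ascending). Ranks are assigned 1..N
#' without gaps.
#'
#' @param patient A [patient_profile()] with at least one observed term.
#' @param corpus Named list of [disease_model()] objects.
#' @param pretest A [pretest_distribution()] covering every corpus disease.
#' @param bg [background_frequencies()].
#' @param hpo Phenotype [ontology_graph()].
#' @param opts [lr_options()].
#' @return Data frame of class `ranked_result` with columns `rank`,
#'   `disease_id`, `disease_name`, `pretest`, `composite_lr`, `log10_lr`,
#'   `posttest`.
#' @export
rank_diseases <- function(patient, corpus, pretest, bg, hpo,
                          opts = lr_options()) {
  stopifnot(inherits(pretest, "pretest_distribution"))
  ids <- names(corpus)
  missing_p <- setdiff(ids, names(pretest$probs))
  if (length(missing_p) > 0L) {
    stop("pretest distribution does not cover disease: ", missing_p[1])
  }
  ctx <- .patient_context(patient, bg, hpo)
  loglr <- vapply(corpus, function(d) .composite_loglr(ctx, d, opts),
                  numeric(1))
  p <- unname(pretest$probs[ids])
  post <- .posttest_from_loglr(p, loglr)
  ord <- order(-post, -loglr, ids)
  out <- data.frame(
    rank = seq_along(ids),
    disease_id = ids[ord],
    disease_name = vapply(corpus[ord], function(d) d$name, character(1)),
    pretest = p[ord],
    composite_lr = exp(loglr[ord]),
    log10_lr = loglr[ord] / log(10),
    posttest = post[ord],
    stringsAsFactors = FALSE, row.names = NULL
  )
  class(out) <- c("ranked_result", "data.frame")
  attr(out, "subject_id") <- patient$subject_id
  out
}

#' Competition rank of one disease in a ranked result
#'
#' Uses "1224" competition ranking on the posttest probability: tied diseases
#' share the lowest rank of their tie block. This is the rank statistic used
#' in benchmarking.
#'
#' @param result A `ranked_result` from [rank_diseases()].
#' @param disease_id Disease identifier to look up.
#' @return Integer rank (>= 1).
#' @export
competition_rank <- function(result, disease_id) {
  i <- match(disease_id, result$disease_id)
  if (is.na(i)) stop("disease not present in result: ", disease_id)
  sum(result$posttest > result$posttest[i]) + 1L
}
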