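# Benchmarking harness: rank each case's true diagnosis under uniform vs
# group-adjusted pretest probabilities across a sweep of adjustment values
# and two intuition widths (narrow: a group closely related to the true
# diagnosis; broad: a larger umbrella group), then test rank improvement
# with a one-sided Wilcoxon signed-rank test per (width, adjustment) cell.

#' Construct a benchmark case
#'
#' @param patient A [patient_profile()] with a known `true_diagnosis`.
#' @param narrow_group Disease-group term identifier encoding a narrow (close
#'   to the true diagnosis) clinical intuition.
#' @param broad_group Disease-group term identifier encoding a broad
#'   intuition; its mapped disease set normally contains the narrow one.
#' @return An object of class `benchmark_case`.
#' @export
benchmark_case <- function(patient, narrow_group, broad_group) {
  stopifnot(inherits(patient, "patient_profile"))
  if (is.na(patient$true_diagnosis)) {
    stop("benchmark case requires a true diagnosis")
  }
  structure(list(patient = patient, narrow_group = narrow_group,
                 broad_group = broad_group),
            class = "benchmark_case")
}

# Competition rank of the true disease from per-disease log LRs and pretest
# probabilities, avoiding a full rank_diseases() per pretest configuration:
# the composite LR does not depend on the pretest, so one LR pass per case
# serves every point of the adjustment sweep.
.rank_from_loglr <- function(loglr, probs, true_id) {
  post <- .posttest_from_loglr(unname(probs[names(loglr)]), loglr)
  i <- match(true_id, names(loglr))
  sum(post > post[i]) + 1L
}

#' Run the rank-improvement benchmark
#'
#' For every case, ranks the true diagnosis under the uniform pretest and
#' under group-boosted pretests for each adjustment value and both intuition
#' widths, computes per-case rank improvements (uniform rank minus adjusted
#' rank; positive is better), and tests each (width, adjustment) cell with
#' [wilcoxon_one_sided()]. Cases whose true diagnosis is absent from the
#' corpus are excluded with a logged count; cases whose group term maps to no
#' corpus disease are excluded from that width only.
#'
#' @param cases List of [benchmark_case()] objects.
#' @param corpus Named list of [disease_model()] objects.
#' @param bg [background_frequencies()] over `corpus`.
#' @param hpo Phenotype [ontology_graph()].
#' @param mondo Disease [ontology_graph()].
#' @param adjustments Numeric vector of adjustment values to sweep
#'   (default `c(1, 5, 10, 15, 20)`).
#' @param opts [lr_options()].
#' @return A list of class `benchmark_result`: `results` (long data frame
#'   with columns `case`, `width`, `adjustment`, `rank_uniform`,
#'   `rank_adjusted`, `improvement`), `summary` (mean/median improvement and
#'   Wilcoxon p-value per width x adjustment), `n_excluded_missing_diagnosis`
#'   and `n_excluded_mapping` (width-tagged).
#' @export
run_benchmark <- function(cases, corpus, bg, hpo, mondo,
                          adjustments = c(1, 5, 10, 15, 20),
                          opts = lr_options()) {
  corpus_ids <- names(corpus)
  usable <- vapply(cases, function(cs) cs$patient$true_diagnosis %in%
                     corpus_ids, logical(1))
  n_missing <- sum(!usable)
  if (n_missing > 0L) {
    warning(n_missing, " case(s) excluded: true diagnosis not in corpus",
            call. = FALSE)
  }
  cases <- cases[usable]
  uni <- uniform_pretest(corpus_ids)

  rows <- list()
  n_map_fail <- c(narrow = 0L, broad = 0L)
  for (ci in seq_along(cases)) {
    cs <- cases[[ci]]
    ctx <- .patient_context(cs$patient, bg, hpo)
    loglr <- vapply(corpus, function(d) .composite_loglr(ctx, d, opts),
                    numeric(1))
    true_id <- cs$patient$true_diagnosis
    r0 <- .rank_from_loglr(loglr, uni$probs, true_id)
    for (width in c("narrow", "broad")) {
      grp <- if (width == "narrow") cs$narrow_group else cs$broad_group
      boosted <- suppressWarnings(group_to_diseases(mondo, grp, corpus_ids))
      if (length(boosted) == 0L) {
        n_map_fail[[width]] <- n_map_fail[[width]] + 1L
        next
      }
      for (a in adjustments) {
        pt <- adjust_pretest(corpus_ids, boosted, a)
        ra <- .rank_from_loglr(loglr, pt$probs, true_id)
        rows[[length(rows) + 1L]] <- data.frame(
          case = cs$patient$subject_id, width = width, adjustment = a,
          rank_uniform = r0, rank_adjusted = ra, improvement = r0 - ra,
          stringsAsFactors = FALSE)
      }
    }
  }
  results <- if (length(rows) > 0L) do.call(rbind, rows) else
    data.frame(case = character(), width = character(),
               adjustment = numeric(), rank_uniform = integer(),
               rank_adjusted = integer(), improvement = integer(),
               stringsAsFactors = FALSE)

  cells <- unique(results[, c("width", "adjustment")])
  summ <- do.call(rbind, lapply(seq_len(nrow(cells)), function(i) {
    sel <- results$width == cells$width[i] &
      results$adjustment == cells$adjustment[i]
    imp <- results$improvement[sel]
    wt <- wilcoxon_one_sided(results$rank_uniform[sel],
                             results$rank_adjusted[sel])
    data.frame(width = cells$width[i], adjustment = cells$adjustment[i],
               n = sum(sel), mean_improvement = mean(imp),
               median_improvement = stats::median(imp),
               p_value = wt$p_value, stringsAsFactors = FALSE)
  }))
  if (is.null(summ)) {
    summ <- data.frame(width = character(), adjustment = numeric(),
                       n = integer(), mean_improvement = numeric(),
                       median_improvement = numeric(), p_value = numeric(),
                       stringsAsFactors = FALSE)
  } else {
    summ <- summ[order(summ$width, summ$adjustment), , drop = FALSE]
    row.names(summ) <- NULL
  }
  structure(
    list(results = results, summary = summ,
         n_excluded_missing_diagnosis = n_missing,
         n_excluded_mapping = n_map_fail),
    class = "benchmark_result"
  )
}

#' @export
print.benchmark_result <- function(x, ...) {
  cat(sprintf("<benchmark_result> %d rank comparisons\n", nrow(x$results)))
  print(x$summary)
  invisible(x)
}

#' Write benchmark results as TSV files
#'
#' @param bm A `benchmark_result` from [run_benchmark()].
#' @param results_path Path for the long per-case table.
#' @param summary_path Path for the per-cell summary table.
#' @return `results_path`, invisibly.
#' @export
write_benchmark_tsv <- function(bm, results_path, summary_path) {
  stopifnot(inherits(bm, "benchmark_result"))
  utils::write.table(bm$results, results_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  summ <- bm$summary
  summ$mean_improvement <- signif(summ$mean_improvement, 6)
  summ$p_value <- signif(summ$p_value, 6)
  utils::write.table(summ, summary_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(results_path)
}
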