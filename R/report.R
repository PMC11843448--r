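# Result writers: TSV (primary) and a plain single-file HTML report whose
# per-term bars are signed log10 likelihood ratios — features supporting a
# candidate point up (positive), features speaking against it point down
# (negative).

#' Write a ranked result as TSV
#'
#' Columns: rank, disease_id, disease_name, pretest, log10_composite_lr,
#' posttest. Floating-point values are printed with 6 significant digits
#' for stable diffs.
#'
#' @param result A `ranked_result` from [rank_diseases()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_ranked_tsv <- function(result, path) {
  stopifnot(inherits(result, "ranked_result"))
  df <- data.frame(
    rank = result$rank,
    disease_id = result$disease_id,
    disease_name = result$disease_name,
    pretest = sprintf("%.6g", result$pretest),
    log10_composite_lr = sprintf("%.6g", result$log10_lr),
    posttest = sprintf("%.6g", result$posttest),
    stringsAsFactors = FALSE
  )
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write per-term LR breakdowns for the top candidates as TSV
#'
#' @param patient A [patient_profile()].
#' @param result A `ranked_result` from [rank_diseases()].
#' @param corpus Named list of [disease_model()] objects.
#' @param bg [background_frequencies()].
#' @param hpo Phenotype [ontology_graph()].
#' @param path Output path.
#' @param top Number of top-ranked diseases to break down (default 10).
#' @param opts [lr_options()].
#' @return `path`, invisibly.
#' @export
write_breakdown_tsv <- function(patient, result, corpus, bg, hpo, path,
                                top = 10, opts = lr_options()) {
  ids <- utils::head(result$disease_id, top)
  rows <- do.call(rbind, lapply(ids, function(id) {
    bd <- lr_breakdown(patient, corpus[[id]], bg, hpo, opts)
    cbind(data.frame(disease_id = id, stringsAsFactors = FALSE), bd)
  }))
  rows$numerator <- sprintf("%.6g", rows$numerator)
  rows$denominator <- sprintf("%.6g", rows$denominator)
  rows$lr <- sprintf("%.6g", rows$lr)
  rows$log10_lr <- sprintf("%.6g", rows$log10_lr)
  utils::write.table(rows, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

.html_escape <- function(x) {
  x <- gsub("&", "&amp;", x, fixed = TRUE)
  x <- gsub("<", "&lt;", x, fixed = TRUE)
  gsub(">", "&gt;", x, fixed = TRUE)
}

#' Write a plain single-file HTML report
#'
#' For each of the top candidates, lists posttest probability and a per-term
#' bar chart of signed log10 LR values: green bars (positive) for features
#' supporting the candidate, red bars (negative) for features speaking
#' against it.
#'
#' @inheritParams write_breakdown_tsv
#' @return `path`, invisibly.
#' @export
write_html_report <- function(patient, result, corpus, bg, hpo, path,
                              top = 10, opts = lr_options()) {
  ids <- utils::head(result$disease_id, top)
  out <- c(
    "<!DOCTYPE html><html><head><meta charset='utf-8'>",
    "<title>Disease ranking report</title><style>",
    "body{font-family:sans-serif;margin:2em} .bar{height:12px;display:inline-block}",
    ".pos{background:#2a7} .neg{background:#c33} td{padding:2px 8px}",
    "</style></head><body>",
    sprintf("<h1>Disease ranking for %s</h1>",
            .html_escape(patient$subject_id)),
    sprintf("<p>%d observed, %d excluded phenotype terms.</p>",
            length(patient$observed), length(patient$excluded))
  )
  for (id in ids) {
    row <- result[result$disease_id == id, ]
    bd <- lr_breakdown(patient, corpus[[id]], bg, hpo, opts)
    out <- c(out, sprintf(
      "<h2>%d. %s (%s)</h2><p>posttest %.4g, pretest %.4g, log10 LR %.4g</p><table>",
      row$rank, .html_escape(row$disease_name), .html_escape(id),
      row$posttest, row$pretest, row$log10_lr))
    for (i in seq_len(nrow(bd))) {
      v <- bd$log10_lr[i]
      w <- max(1, round(abs(v) * 40))
      cls <- if (v >= 0) "pos" else "neg"
      out <- c(out, sprintf(
        "<tr><td>%s</td><td>%s</td><td>%+.2f</td><td><span class='bar %s' style='width:%dpx'></span></td></tr>",
        .html_escape(bd$query_term[i]), bd$match_type[i], v, cls, w))
    }
    out <- c(out, "</table>")
  }
  out <- c(out, "</body></html>")
  writeLines(out, path)
  invisible(path)
}
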