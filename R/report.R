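# Cohort-level aggregation: deletion events, tumor/cell-line matching,
# score distribution, druggability fractions, and report writers.

#' Distinct deletion events behind a set of vulnerabilities
#'
#' One event per distinct (set_id, deleted gene) pair; vulnerabilities with
#' several deleted genes fan out into one event per gene. Sample lists are
#' deduplicated and partitioned by sample class. An alternative key on the
#' deleted gene alone is available for sensitivity analysis.
#'
#' @param vulns a \code{vuln_set}.
#' @param key \code{"set_gene"} (default) or \code{"gene"}.
#' @return data frame with columns \code{set_id}, \code{deleted_gene},
#'   \code{tumor_samples}, \code{cell_line_samples} (";"-joined),
#'   \code{n_tumor}, \code{n_cell_line}.
#' @export
deletion_events <- function(vulns, key = c("set_gene", "gene")) {
  key <- match.arg(key)
  empty <- data.frame(set_id = character(0), deleted_gene = character(0),
                      tumor_samples = character(0),
                      cell_line_samples = character(0),
                      n_tumor = integer(0), n_cell_line = integer(0),
                      stringsAsFactors = FALSE)
  if (nrow(vulns) == 0L) return(empty)
  long <- do.call(rbind, lapply(seq_len(nrow(vulns)), function(i) {
    genes <- .split(vulns$deleted_genes[i])
    data.frame(set_id = vulns$set_id[i], deleted_gene = genes,
               sample = paste(vulns$study_id[i], vulns$sample_id[i],
                              sep = "/"),
               sample_class = vulns$sample_class[i],
               stringsAsFactors = FALSE)
  }))
  k <- if (key == "set_gene") paste(long$set_id, long$deleted_gene,
                                    sep = "\r") else long$deleted_gene
  out <- lapply(unique(k), function(kk) {
    rows <- long[k == kk, , drop = FALSE]
    tum <- sort(unique(rows$sample[rows$sample_class == "tumor"]))
    cl <- sort(unique(rows$sample[rows$sample_class == "cell_line"]))
    data.frame(set_id = if (key == "set_gene") rows$set_id[1] else "",
               deleted_gene = rows$deleted_gene[1],
               tumor_samples = .join(tum), cell_line_samples = .join(cl),
               n_tumor = length(tum), n_cell_line = length(cl),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  out <- out[order(out$set_id, out$deleted_gene), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Tumor-to-cell-line matching rate of deletion events
#'
#' Among deletion events observed in at least one tumor sample, the
#' fraction also observed in at least one cell line. Undefined (NA) when no
#' tumor event exists.
#'
#' @param events output of \code{\link{deletion_events}}.
#' @return fraction in [0, 1], or \code{NA} if there are no tumor events.
#' @export
match_rate <- function(events) {
  tum <- events[events$n_tumor > 0L, , drop = FALSE]
  if (nrow(tum) == 0L) return(NA_real_)
  mean(tum$n_cell_line > 0L)
}

#' Summarize a cohort's vulnerabilities
#'
#' @param vulns a scored \code{vuln_set}.
#' @param event_key passed to \code{\link{deletion_events}}.
#' @return list of class \code{cohort_summary}: counts, score histogram
#'   (0..4), druggability fractions and per-study breakdown.
#' @export
summarize_cohort <- function(vulns, event_key = "set_gene") {
  events <- deletion_events(vulns, key = event_key)
  sample_key <- paste(vulns$study_id, vulns$sample_id, sep = "/")
  uniq <- !duplicated(sample_key)
  hist <- as.integer(table(factor(vulns$score, levels = 0:4)))
  names(hist) <- as.character(0:4)
  per_study <- if (nrow(vulns)) {
    do.call(rbind, lapply(sort(unique(vulns$study_id)), function(st) {
      v <- vulns[vulns$study_id == st, , drop = FALSE]
      data.frame(study_id = st, n_vulnerabilities = nrow(v),
                 n_vulnerable_samples = length(unique(v$sample_id)),
                 stringsAsFactors = FALSE)
    }))
  } else {
    data.frame(study_id = character(0), n_vulnerabilities = integer(0),
               n_vulnerable_samples = integer(0), stringsAsFactors = FALSE)
  }
  structure(list(
    n_vulnerabilities = nrow(vulns),
    n_vulnerable_tumor_samples =
      sum(uniq & vulns$sample_class == "tumor"),
    n_vulnerable_cell_lines =
      sum(uniq & vulns$sample_class == "cell_line"),
    n_deletion_events = nrow(events),
    n_tumor_events = sum(events$n_tumor > 0L),
    fraction_tumor_events_with_cell_line_match = match_rate(events),
    score_histogram = hist,
    fraction_with_fda_drug =
      if (nrow(vulns)) mean(vulns$has_fda_drug) else NA_real_,
    fraction_with_cancer_drug =
      if (nrow(vulns)) mean(vulns$has_cancer_drug) else NA_real_,
    fraction_targeting_essential =
      if (nrow(vulns)) mean(!vulns$nonessential_target) else NA_real_,
    per_study = per_study),
    class = "cohort_summary")
}

#' @export
print.cohort_summary <- function(x, ...) {
  cat("cohort_summary\n")
  cat(sprintf("  vulnerabilities: %d (%d tumor samples, %d cell lines)\n",
              x$n_vulnerabilities, x$n_vulnerable_tumor_samples,
              x$n_vulnerable_cell_lines))
  cat(sprintf("  distinct deletion events: %d (%d in tumors; %s%% with cell-line match)\n",
              x$n_deletion_events, x$n_tumor_events,
              ifelse(is.na(x$fraction_tumor_events_with_cell_line_match),
                     "-", format(
                       100 * x$fraction_tumor_events_with_cell_line_match,
                       digits = 3))))
  cat("  score histogram:",
      paste(names(x$score_histogram), x$score_histogram, sep = "=",
            collapse = ", "), "\n")
  fmt_pct <- function(f) ifelse(is.na(f), "-",
                                paste0(format(100 * f, digits = 3), "%"))
  cat(sprintf("  with FDA drug: %s; with cancer drug: %s; targeting an essential gene: %s\n",
              fmt_pct(x$fraction_with_fda_drug),
              fmt_pct(x$fraction_with_cancer_drug),
              fmt_pct(x$fraction_targeting_essential)))
  invisible(x)
}

#' Write cohort reports
#'
#' Emits \code{vulnerabilities.tsv} (one row per vulnerability),
#' \code{summary.json} (fractions to 4 decimals) and
#' \code{per_study.tsv} under \code{out_dir}.
#'
#' @param summary a \code{cohort_summary}.
#' @param vulns the \code{vuln_set} it was computed from.
#' @param out_dir output directory (created if needed).
#' @return invisibly, the paths written.
#' @export
write_reports <- function(summary, vulns, out_dir) {
  if (!dir.exists(out_dir)) {
    ok <- dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    if (!ok) stop("cannot create output directory: ", out_dir)
  }
  paths <- c(vulns = file.path(out_dir, "vulnerabilities.tsv"),
             summary = file.path(out_dir, "summary.json"),
             per_study = file.path(out_dir, "per_study.tsv"))
  write_vulnerabilities(vulns, paths[["vulns"]])
  js <- unclass(summary)
  js$per_study <- NULL
  round4 <- function(f) if (is.na(f)) NULL else round(f, 4)
  js$fraction_tumor_events_with_cell_line_match <-
    round4(js$fraction_tumor_events_with_cell_line_match)
  js$fraction_with_fda_drug <- round4(js$fraction_with_fda_drug)
  js$fraction_with_cancer_drug <- round4(js$fraction_with_cancer_drug)
  js$fraction_targeting_essential <- round4(js$fraction_targeting_essential)
  js$score_histogram <- as.list(js$score_histogram)
  jsonlite::write_json(js, paths[["summary"]], auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  utils::write.table(summary$per_study, paths[["per_study"]], sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(paths)
}

#' Write / read the vulnerabilities table
#'
#' Tab-separated, one row per vulnerability; reading back reproduces the
#' \code{vuln_set} (and hence its summary) exactly.
#'
#' @param vulns a \code{vuln_set}.
#' @param path TSV path.
#' @export
write_vulnerabilities <- function(vulns, path) {
  utils::write.table(as.data.frame(vulns), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @rdname write_vulnerabilities
#' @export
read_vulnerabilities <- function(path) {
  df <- utils::read.delim(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE,
                          colClasses = c(
                            study_id = "character",
                            sample_id = "character",
                            sample_class = "character",
                            set_id = "character",
                            reaction_name = "character",
                            deleted_genes = "character",
                            intact_members = "character",
                            expected_expressed_partners = "character",
                            exploit_map = "character",
                            suggested_drugs = "character",
                            single_drug_covers_all = "logical",
                            underexpressed_deletion = "logical",
                            has_fda_drug = "logical",
                            has_cancer_drug = "logical",
                            nonessential_target = "logical",
                            score = "integer"))
  for (col in c("reaction_name", "deleted_genes", "intact_members",
                "expected_expressed_partners", "exploit_map",
                "suggested_drugs")) {
    df[[col]][is.na(df[[col]])] <- ""
  }
  class(df) <- c("vuln_set", "data.frame")
  df
}
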