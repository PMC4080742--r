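# Vulnerability engine: per sample x gene set, detect homozygous
# deletions, determine exploitable intact partners, attach drugs, score.
#
# A call is made for (sample, gene set) when at least one member is
# homozygously deleted, at least one expected-expressed member is intact,
# and (under the default "all" partner rule) every expected-expressed
# intact member can be hit by at least one selective drug that leaves part
# of the set uninhibited in a normal cell.

.join <- function(x) paste(x, collapse = ";")
.split <- function(x) {
  if (is.na(x) || !nzchar(x)) character(0) else strsplit(x, ";", fixed = TRUE)[[1]]
}

.exploit_map_string <- function(partners, exploit) {
  # exploit: named list partner -> drug ids
  if (length(partners) == 0L) return("")
  paste(vapply(partners, function(p) {
    paste0(p, ":", paste(exploit[[p]], collapse = "|"))
  }, character(1)), collapse = ";")
}

#' Parse an exploit-map string
#'
#' Inverse of the serialized \code{exploit_map} column
#' (\code{"partner:drug1|drug2;partner2:drug3"}).
#'
#' @param s exploit-map string.
#' @return named list partner -> character vector of drug ids.
#' @export
parse_exploit_map <- function(s) {
  if (is.na(s) || !nzchar(s)) return(list())
  parts <- strsplit(s, ";", fixed = TRUE)[[1]]
  out <- list()
  for (p in parts) {
    kv <- strsplit(p, ":", fixed = TRUE)[[1]]
    out[[kv[1]]] <- if (length(kv) > 1L && nzchar(kv[2])) {
      strsplit(kv[2], "|", fixed = TRUE)[[1]]
    } else character(0)
  }
  out
}

.empty_vulns <- function() {
  df <- data.frame(
    study_id = character(0), sample_id = character(0),
    sample_class = character(0), set_id = character(0),
    reaction_name = character(0), deleted_genes = character(0),
    intact_members = character(0),
    expected_expressed_partners = character(0),
    exploit_map = character(0), suggested_drugs = character(0),
    single_drug_covers_all = logical(0),
    underexpressed_deletion = logical(0), has_fda_drug = logical(0),
    has_cancer_drug = logical(0), nonessential_target = logical(0),
    score = integer(0), stringsAsFactors = FALSE)
  class(df) <- c("vuln_set", "data.frame")
  df
}

#' Classify a drug as a selective exploit for a partner
#'
#' A drug selectively exploits an intact partner isoenzyme when (a) it has
#' no more than \code{max_drug_targets} unique targets, (b) the partner is
#' among its targets, and (c) its targets do not cover every member of the
#' gene set -- in a normal cell at least one isoenzyme must remain
#' uninhibited, otherwise the drug is toxic regardless of the deletion
#' (the methotrexate/DHFR/DHFRL1 situation).
#'
#' @param drug_id drug identifier present in \code{drugs}.
#' @param drugs a \code{drug_catalog}.
#' @param set a \code{gene_set} (or character vector of member symbols).
#' @param deleted_genes symbols deleted in the sample.
#' @param partner the intact member to exploit; must be a set member not in
#'   \code{deleted_genes}.
#' @param thresholds a \code{vuln_thresholds}.
#' @return list with \code{drug_id}, \code{is_selective_exploit} and
#'   \code{reason} (one of \code{ok}, \code{too_many_targets},
#'   \code{misses_partner}, \code{covers_all_members}).
#' @export
classify_exploit <- function(drug_id, drugs, set, deleted_genes, partner,
                             thresholds = vuln_thresholds()) {
  members <- if (inherits(set, "gene_set")) set$genes else
    normalize_symbols(set)
  partner <- normalize_symbols(partner)
  deleted_genes <- normalize_symbols(deleted_genes)
  if (!(partner %in% setdiff(members, deleted_genes))) {
    stop("partner '", partner, "' is not an intact member of the set")
  }
  tg <- drugs$targets[[drug_id]]
  if (is.null(tg)) stop("unknown drug_id '", drug_id, "'")
  verdict <- function(ok, reason) {
    list(drug_id = drug_id, is_selective_exploit = ok, reason = reason)
  }
  if (length(tg) > thresholds$max_drug_targets) {
    return(verdict(FALSE, "too_many_targets"))
  }
  if (!(partner %in% tg)) return(verdict(FALSE, "misses_partner"))
  if (all(members %in% tg)) return(verdict(FALSE, "covers_all_members"))
  verdict(TRUE, "ok")
}

# selective exploit drug ids for one partner within one set
.exploits_for_partner <- function(drugs, members, deleted, partner,
                                  thresholds, selective_ids) {
  hits <- character(0)
  for (d in selective_ids) {
    tg <- drugs$targets[[d]]
    if (partner %in% tg && !all(members %in% tg)) hits <- c(hits, d)
  }
  sort(hits)
}

#' Call vulnerabilities for one sample
#'
#' For each gene set: members with CNA code -2 are deleted, the rest are
#' intact; intact members expected to be expressed in the study tissue are
#' the partners that must be inhibited. A vulnerability is emitted when at
#' least one member is deleted, at least one expected-expressed partner
#' remains, and the partner rule is satisfied: under \code{"all"} (default)
#' every expected-expressed partner needs at least one selective exploit
#' drug; under \code{"any"} one covered partner suffices. Suggested drugs
#' then include every drug -- selective or not -- that targets any
#' expected-expressed partner.
#'
#' @param sample sample id present in the bundle.
#' @param catalog a \code{geneset_catalog}.
#' @param drugs a \code{drug_catalog}.
#' @param tmap a \code{tissue_map}.
#' @param bundle a \code{profile_bundle} (carries the study config).
#' @param thresholds a \code{vuln_thresholds}.
#' @param partner_rule \code{"all"} or \code{"any"}.
#' @return a \code{vuln_set} data frame (unscored: criteria NA, score NA).
#' @export
call_sample <- function(sample, catalog, drugs, tmap, bundle,
                        thresholds = vuln_thresholds(),
                        partner_rule = c("all", "any")) {
  partner_rule <- match.arg(partner_rule)
  if (!(sample %in% bundle$samples)) {
    stop("sample '", sample, "' not in study '",
         bundle$study$study_id, "'")
  }
  study <- bundle$study
  selective_ids <- selective_ids_cached(drugs, thresholds)
  rows <- list()
  set_ids <- sort(names(catalog$sets))
  for (sid in set_ids) {
    set <- catalog$sets[[sid]]
    members <- set$genes
    del <- members[vapply(members, function(g)
      is_homdel(bundle, g, sample, thresholds), logical(1))]
    if (length(del) == 0L) next
    intact <- setdiff(members, del)
    if (length(intact) == 0L) next  # complete loss: nothing left to target
    partners <- intact[vapply(intact, function(g)
      expected_expressed(g, study$tissue, tmap), logical(1))]
    if (length(partners) == 0L) next
    exploit <- lapply(partners, function(p)
      .exploits_for_partner(drugs, members, del, p, thresholds,
                            selective_ids))
    names(exploit) <- partners
    covered <- vapply(exploit, function(e) length(e) > 0L, logical(1))
    ok <- if (partner_rule == "all") all(covered) else any(covered)
    if (!ok) next
    exploit <- exploit[covered]
    # one selective drug covering all expected-expressed partners?
    common <- Reduce(intersect, exploit)
    suggested <- sort(unique(unlist(lapply(partners, function(p)
      names(drugs$targets)[vapply(drugs$targets, function(tg)
        p %in% tg, logical(1))]))))
    rows[[length(rows) + 1L]] <- data.frame(
      study_id = study$study_id, sample_id = sample,
      sample_class = study$sample_class, set_id = sid,
      reaction_name = set$reaction_name,
      deleted_genes = .join(sort(del)),
      intact_members = .join(sort(intact)),
      expected_expressed_partners = .join(sort(partners)),
      exploit_map = .exploit_map_string(sort(names(exploit)), exploit),
      suggested_drugs = .join(suggested),
      single_drug_covers_all = length(partners) == length(exploit) &&
        length(common) > 0L,
      underexpressed_deletion = NA, has_fda_drug = NA,
      has_cancer_drug = NA, nonessential_target = NA,
      score = NA_integer_, stringsAsFactors = FALSE)
  }
  out <- if (length(rows)) do.call(rbind, rows) else .empty_vulns()
  class(out) <- c("vuln_set", "data.frame")
  out
}

# memoized selective subset per (catalog, thresholds) pair
selective_ids_cached <- function(drugs, thresholds) {
  if (thresholds$max_drug_targets == drugs$max_targets_for_selective) {
    selective_drugs(drugs)
  } else {
    with(drugs$drugs,
         sort(drug_id[n_targets >= 1L &
                        n_targets <= thresholds$max_drug_targets]))
  }
}

#' Score a called vulnerability
#'
#' Four criteria, one point each (score 0-4):
#' \enumerate{
#'   \item every homozygously deleted gene is underexpressed (strict
#'     cutoff) or not expected to be expressed in the study tissue;
#'     unknown expression counts as unmet;
#'   \item at least one suggested drug is FDA-approved;
#'   \item at least one suggested drug is a cancer drug (FDA-approved and
#'     used in cancer treatment);
#'   \item at least one selective exploit drug hits only non-essential
#'     expected-expressed partners.
#' }
#'
#' @param vulns a \code{vuln_set} from \code{\link{call_sample}}.
#' @param bundle the \code{profile_bundle} the calls came from.
#' @param emap an \code{essential_map}.
#' @param drugs a \code{drug_catalog}.
#' @param tmap a \code{tissue_map}.
#' @param thresholds a \code{vuln_thresholds}.
#' @return the \code{vuln_set} with criteria columns and \code{score}
#'   filled in.
#' @export
score_vulnerability <- function(vulns, bundle, emap, drugs, tmap,
                                thresholds = vuln_thresholds()) {
  if (nrow(vulns) == 0L) return(vulns)
  tissue <- bundle$study$tissue
  for (i in seq_len(nrow(vulns))) {
    sample <- vulns$sample_id[i]
    del <- .split(vulns$deleted_genes[i])
    crit1 <- all(vapply(del, function(g) {
      if (!expected_expressed(g, tissue, tmap)) return(TRUE)
      isTRUE(is_underexpressed(bundle, g, sample, thresholds))
    }, logical(1)))
    sugg <- .split(vulns$suggested_drugs[i])
    rec <- drugs$drugs[match(sugg, drugs$drugs$drug_id), , drop = FALSE]
    crit2 <- any(rec$fda_approved, na.rm = TRUE)
    crit3 <- any(rec$cancer_drug, na.rm = TRUE)
    partners <- .split(vulns$expected_expressed_partners[i])
    emapped <- parse_exploit_map(vulns$exploit_map[i])
    exploit_ids <- unique(unlist(emapped, use.names = FALSE))
    crit4 <- any(vapply(exploit_ids, function(d) {
      hit <- intersect(drugs$targets[[d]], partners)
      !any(vapply(hit, is_essential, logical(1), emap = emap))
    }, logical(1)))
    vulns$underexpressed_deletion[i] <- crit1
    vulns$has_fda_drug[i] <- crit2
    vulns$has_cancer_drug[i] <- crit3
    vulns$nonessential_target[i] <- crit4
    vulns$score[i] <- sum(crit1, crit2, crit3, crit4)
  }
  vulns
}

#' Run the caller over a whole cohort
#'
#' Loads every study's profile bundle, calls and scores each sample, and
#' concatenates the results in deterministic (study, sample, set) order.
#'
#' @param studies list of \code{study_config}.
#' @param catalog a \code{geneset_catalog}.
#' @param drugs a \code{drug_catalog}.
#' @param tmap a \code{tissue_map}.
#' @param emap an \code{essential_map}.
#' @param thresholds a \code{vuln_thresholds}.
#' @param partner_rule \code{"all"} or \code{"any"}.
#' @return a scored \code{vuln_set}; attribute \code{"study_log"} carries
#'   per-study sample and call counts.
#' @export
run_cohort <- function(studies, catalog, drugs, tmap, emap,
                       thresholds = vuln_thresholds(),
                       partner_rule = c("all", "any")) {
  partner_rule <- match.arg(partner_rule)
  # fail fast on missing files before any calling starts
  for (st in studies) {
    paths <- c(st$cna_path, if (st$expression_mode != "none") st$expr_path)
    missing <- paths[!file.exists(paths)]
    if (length(missing)) {
      stop("study '", st$study_id, "': missing input file(s): ",
           paste(missing, collapse = ", "))
    }
  }
  ord <- order(vapply(studies, function(s) s$study_id, character(1)))
  studies <- studies[ord]
  pieces <- list()
  log <- data.frame(study_id = character(0), n_samples = integer(0),
                    n_vulnerabilities = integer(0),
                    stringsAsFactors = FALSE)
  for (st in studies) {
    bundle <- load_profile_bundle(st)
    n_st <- 0L
    for (sample in sort(bundle$samples)) {
      v <- call_sample(sample, catalog, drugs, tmap, bundle, thresholds,
                       partner_rule)
      v <- score_vulnerability(v, bundle, emap, drugs, tmap, thresholds)
      n_st <- n_st + nrow(v)
      if (nrow(v)) pieces[[length(pieces) + 1L]] <- v
    }
    log <- rbind(log, data.frame(study_id = st$study_id,
                                 n_samples = length(bundle$samples),
                                 n_vulnerabilities = n_st,
                                 stringsAsFactors = FALSE))
  }
  out <- if (length(pieces)) do.call(rbind, pieces) else .empty_vulns()
  out <- out[order(out$study_id, out$sample_id, out$set_id), ,
             drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("vuln_set", "data.frame")
  attr(out, "study_log") <- log
  out
}

#' @export
print.vuln_set <- function(x, ...) {
  cat(sprintf("vuln_set: %d vulnerabilities in %d samples across %d studies\n",
              nrow(x), length(unique(paste(x$study_id, x$sample_id))),
              length(unique(x$study_id))))
  if (nrow(x) && !all(is.na(x$score))) {
    tab <- table(factor(x$score, levels = 0:4))
    cat("  scores: ", paste(names(tab), tab, sep = "=", collapse = ", "),
        "\n")
  }
  if (nrow(x)) {
    print.data.frame(utils::head(
      as.data.frame(x)[, c("study_id", "sample_id", "set_id",
                           "deleted_genes",
                           "expected_expressed_partners", "score")], 10L))
    if (nrow(x) > 10L) cat("  ... and", nrow(x) - 10L, "more rows\n")
  }
  invisible(x)
}

#' @export
summary.vuln_set <- function(object, ...) {
  summarize_cohort(object)
}
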