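# Independent brute-force enumerator, written directly against the raw
# input files. Deliberately shares no code with the package: GMT lines are
# split by hand, matrices read with read.delim, and every
# (sample, set, member, drug) quadruple is enumerated with plain loops.

oracle_cohort <- function(dir, partner_rule = "all") {
  cfg <- yaml::read_yaml(file.path(dir, "cohort.yaml"))
  loc <- function(p) file.path(dir, p)

  gmt <- readLines(loc(cfg$genesets))
  gmt <- gmt[nzchar(gmt)]
  set_genes <- list()
  for (l in gmt) {
    f <- strsplit(l, "\t", fixed = TRUE)[[1]]
    set_genes[[f[1]]] <- unique(toupper(trimws(f[-(1:2)])))
  }

  dd <- read.delim(loc(cfg$drugs), colClasses = "character")
  dd$target_gene <- toupper(trimws(dd$target_gene))
  targets <- lapply(split(dd$target_gene, dd$drug_id), unique)
  fda <- tapply(as.integer(dd$fda_approved) != 0 |
                  as.integer(dd$cancer_drug) != 0,
                dd$drug_id, any)
  cancer <- tapply(as.integer(dd$cancer_drug) != 0, dd$drug_id, any)

  tt <- read.delim(loc(cfg$tissue), colClasses = "character")
  tspec <- lapply(split(tt$tissue, toupper(tt$gene_symbol)), unique)
  ee <- read.delim(loc(cfg$essential), colClasses = "character")
  essential <- unique(toupper(ee$gene_symbol))

  read_mat <- function(p) {
    df <- read.delim(loc(p), check.names = FALSE)
    m <- as.matrix(df[, -1, drop = FALSE])
    rownames(m) <- toupper(df[[1]])
    m
  }

  rows <- list()
  for (st in cfg$studies) {
    cna <- read_mat(st$cna)
    mode <- if (is.null(st$expression_mode)) "none" else st$expression_mode
    expr <- if (mode != "none") read_mat(st$expr) else NULL
    tissue <- if (is.null(st$tissue)) NA_character_ else st$tissue
    cutoff <- if (mode == "zscore") -2 else if (mode == "ccle_log2") 5
              else NA
    exp_expr <- function(g) {
      ts <- tspec[[g]]
      if (is.null(ts)) return(TRUE)
      if (is.na(tissue)) return(TRUE)
      tissue %in% ts
    }
    for (smp in colnames(cna)) {
      for (sid in names(set_genes)) {
        genes <- set_genes[[sid]]
        del <- character(0)
        for (g in genes) {
          if (g %in% rownames(cna) && !is.na(cna[g, smp]) &&
              cna[g, smp] == -2) {
            del <- c(del, g)
          }
        }
        if (length(del) == 0) next
        intact <- setdiff(genes, del)
        if (length(intact) == 0) next
        partners <- intact[vapply(intact, exp_expr, logical(1))]
        if (length(partners) == 0) next
        exploit <- list()
        for (p in partners) {
          hits <- character(0)
          for (d in names(targets)) {
            tg <- targets[[d]]
            if (length(tg) <= 5 && p %in% tg && !all(genes %in% tg)) {
              hits <- c(hits, d)
            }
          }
          exploit[[p]] <- sort(hits)
        }
        ncov <- sum(vapply(exploit, length, integer(1)) > 0)
        ok <- if (partner_rule == "all") ncov == length(partners)
              else ncov > 0
        if (!ok) next
        suggested <- character(0)
        for (d in names(targets)) {
          if (any(partners %in% targets[[d]])) suggested <- c(suggested, d)
        }
        suggested <- sort(suggested)
        # score
        c1 <- TRUE
        for (g in del) {
          if (!exp_expr(g)) next
          known <- !is.null(expr) && g %in% rownames(expr) &&
            smp %in% colnames(expr) && !is.na(expr[g, smp])
          if (!known || !(expr[g, smp] < cutoff)) c1 <- FALSE
        }
        c2 <- any(fda[suggested])
        c3 <- any(cancer[suggested])
        exploit_ids <- unique(unlist(exploit))
        c4 <- FALSE
        for (d in exploit_ids) {
          hit <- intersect(targets[[d]], partners)
          if (!any(hit %in% essential)) c4 <- TRUE
        }
        rows[[length(rows) + 1L]] <- data.frame(
          study_id = st$study_id, sample_id = smp, set_id = sid,
          deleted_genes = paste(sort(del), collapse = ";"),
          expected_expressed_partners = paste(sort(partners),
                                              collapse = ";"),
          suggested_drugs = paste(suggested, collapse = ";"),
          score = sum(c1, c2, c3, c4), stringsAsFactors = FALSE)
      }
    }
  }
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(study_id = character(0), sample_id = character(0),
               set_id = character(0), deleted_genes = character(0),
               expected_expressed_partners = character(0),
               suggested_drugs = character(0), score = integer(0),
               stringsAsFactors = FALSE)
  out <- out[order(out$study_id, out$sample_id, out$set_id), ,
             drop = FALSE]
  rownames(out) <- NULL
  out
}

# compare an engine vuln_set with the oracle on shared columns
expect_matches_oracle <- function(vulns, oracle) {
  cols <- c("study_id", "sample_id", "set_id", "deleted_genes",
            "expected_expressed_partners", "suggested_drugs", "score")
  got <- as.data.frame(vulns)[, cols]
  rownames(got) <- NULL
  got$score <- as.integer(got$score)
  oracle$score <- as.integer(oracle$score)
  expect_equal(got, oracle)
}
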