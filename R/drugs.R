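# Drug-target catalog: loading, selective-drug subset, per-gene lookups.

#' Read a drug-target table
#'
#' Loads a TSV with one row per (drug, target) pair and groups rows into
#' drug records. Flag conflicts across a drug's rows are resolved by logical
#' OR with a warning; a drug flagged as a cancer drug is by definition
#' FDA-approved (a cancer drug is one currently FDA-approved and used in
#' cancer treatment), so \code{cancer_drug = 1} with \code{fda_approved = 0}
#' is coerced with a warning.
#'
#' @param path TSV with columns \code{drug_id}, \code{drug_name},
#'   \code{target_gene}, \code{fda_approved} (0/1), \code{cancer_drug}
#'   (0/1).
#' @param max_targets_for_selective target-count cap defining the selective
#'   subset (default 5; drugs with more targets are considered
#'   non-specific).
#' @return an object of class \code{drug_catalog} with components
#'   \code{drugs} (data frame: drug_id, name, fda_approved, cancer_drug,
#'   n_targets), \code{targets} (named list drug_id -> target symbols) and
#'   \code{max_targets_for_selective}.
#' @export
read_drug_targets <- function(path, max_targets_for_selective = 5L) {
  df <- utils::read.delim(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE,
                          colClasses = "character")
  need <- c("drug_id", "drug_name", "target_gene", "fda_approved",
            "cancer_drug")
  missing <- setdiff(need, names(df))
  if (length(missing)) {
    stop("drug table missing column(s): ", paste(missing, collapse = ", "))
  }
  drug_table(df, max_targets_for_selective)
}

#' Build a drug catalog from a long-format data frame
#'
#' @param df data frame with the columns of \code{\link{read_drug_targets}}.
#' @param max_targets_for_selective see \code{\link{read_drug_targets}}.
#' @return a \code{drug_catalog}.
#' @export
drug_table <- function(df, max_targets_for_selective = 5L) {
  if (nrow(df) == 0L) {
    return(structure(
      list(drugs = data.frame(drug_id = character(0), name = character(0),
                              fda_approved = logical(0),
                              cancer_drug = logical(0),
                              n_targets = integer(0),
                              stringsAsFactors = FALSE),
           targets = list(),
           max_targets_for_selective = max_targets_for_selective),
      class = "drug_catalog"))
  }
  df$drug_id <- as.character(df$drug_id)
  df$target_gene <- normalize_symbols(df$target_gene)
  df$fda_approved <- as.integer(df$fda_approved) != 0L
  df$cancer_drug <- as.integer(df$cancer_drug) != 0L

  ids <- sort(unique(df$drug_id))
  targets <- vector("list", length(ids))
  names(targets) <- ids
  rec <- data.frame(drug_id = ids, name = "", fda_approved = FALSE,
                    cancer_drug = FALSE, n_targets = 0L,
                    stringsAsFactors = FALSE)
  conflicts <- character(0)
  for (i in seq_along(ids)) {
    rows <- df[df$drug_id == ids[i], , drop = FALSE]
    tg <- unique(rows$target_gene)
    tg <- sort(tg[nzchar(tg)])
    targets[[i]] <- tg
    rec$name[i] <- rows$drug_name[1]
    if (length(unique(rows$fda_approved)) > 1L ||
        length(unique(rows$cancer_drug)) > 1L) {
      conflicts <- c(conflicts, ids[i])
    }
    rec$fda_approved[i] <- any(rows$fda_approved)
    rec$cancer_drug[i] <- any(rows$cancer_drug)
    rec$n_targets[i] <- length(tg)
  }
  if (length(conflicts)) {
    warning("conflicting approval flags for drug(s) ",
            paste(conflicts, collapse = ", "), "; resolved by logical OR")
  }
  coerce <- rec$cancer_drug & !rec$fda_approved
  if (any(coerce)) {
    warning("drug(s) ", paste(rec$drug_id[coerce], collapse = ", "),
            " flagged cancer_drug but not fda_approved; ",
            "fda_approved coerced to TRUE")
    rec$fda_approved[coerce] <- TRUE
  }
  keep <- rec$n_targets > 0L
  structure(list(drugs = rec[keep, , drop = FALSE],
                 targets = targets[keep],
                 max_targets_for_selective = max_targets_for_selective),
            class = "drug_catalog")
}

#' @export
print.drug_catalog <- function(x, ...) {
  cat(sprintf(
    "drug_catalog: %d drugs, %d drug-target pairs, %d targetable genes\n",
    nrow(x$drugs), sum(x$drugs$n_targets), length(targetable_genes(x))))
  cat(sprintf("  selective (<= %d targets): %d; FDA-approved: %d; cancer drugs: %d\n",
              x$max_targets_for_selective, length(selective_drugs(x)),
              sum(x$drugs$fda_approved), sum(x$drugs$cancer_drug)))
  invisible(x)
}

#' Selective-drug subset
#'
#' Drugs with at least one and at most \code{max_targets_for_selective}
#' unique targets; drugs with more known targets are considered
#' non-specific and excluded from selective exploitation.
#'
#' @param catalog a \code{drug_catalog}.
#' @return character vector of drug ids (sorted).
#' @export
selective_drugs <- function(catalog) {
  with(catalog$drugs,
       sort(drug_id[n_targets >= 1L &
                      n_targets <= catalog$max_targets_for_selective]))
}

#' All genes targetable by at least one drug
#'
#' @param catalog a \code{drug_catalog}.
#' @param selective_only restrict to the selective subset.
#' @return sorted character vector of gene symbols.
#' @export
targetable_genes <- function(catalog, selective_only = FALSE) {
  tg <- catalog$targets
  if (selective_only) tg <- tg[selective_drugs(catalog)]
  sort(unique(unlist(tg, use.names = FALSE)))
}

#' Drugs targeting a gene
#'
#' @param catalog a \code{drug_catalog}.
#' @param gene gene symbol (normalized internally).
#' @param selective_only restrict to the selective subset.
#' @return data frame of matching drug records, ordered by drug_id.
#' @export
drugs_for_gene <- function(catalog, gene, selective_only = FALSE) {
  gene <- normalize_symbols(gene)
  hit <- vapply(catalog$targets, function(tg) gene %in% tg, logical(1))
  ids <- names(catalog$targets)[hit]
  if (selective_only) ids <- intersect(ids, selective_drugs(catalog))
  out <- catalog$drugs[match(sort(ids), catalog$drugs$drug_id), ,
                       drop = FALSE]
  rownames(out) <- NULL
  out
}
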