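# Tissue-specificity and gene-essentiality annotations.

#' Read a tissue-specificity map
#'
#' Genes listed in the file are tissue-specific: expressed only in the
#' tissues given. Genes absent from the file are implicitly ubiquitous.
#'
#' @param path TSV with columns \code{gene_symbol}, \code{tissue}; multiple
#'   rows per gene allowed.
#' @return named list gene -> character vector of tissues, class
#'   \code{tissue_map}.
#' @export
read_tissue_map <- function(path) {
  df <- utils::read.delim(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE,
                          colClasses = "character")
  need <- c("gene_symbol", "tissue")
  missing <- setdiff(need, names(df))
  if (length(missing)) {
    stop("tissue table missing column(s): ", paste(missing, collapse = ", "))
  }
  tissue_map(df$gene_symbol, df$tissue)
}

#' Build a tissue map from vectors
#'
#' @param genes gene symbols (repeated per tissue row).
#' @param tissues tissue labels, parallel to \code{genes}.
#' @return a \code{tissue_map}.
#' @export
tissue_map <- function(genes = character(0), tissues = character(0)) {
  genes <- normalize_symbols(genes)
  keep <- nzchar(genes) & nzchar(tissues)
  m <- lapply(split(tissues[keep], genes[keep]), unique)
  structure(m, class = "tissue_map")
}

#' Is a gene expected to be expressed in a study's tissue?
#'
#' Ubiquitous genes (absent from the map) are always expected. A
#' tissue-specific gene is expected only in its annotated tissues. When the
#' study tissue is unknown (\code{NA}), the answer is conservatively
#' \code{TRUE}: without tissue information a gene cannot be excluded.
#'
#' @param gene gene symbol.
#' @param study_tissue tissue label or \code{NA} for unknown.
#' @param tmap a \code{tissue_map}.
#' @return logical.
#' @export
expected_expressed <- function(gene, study_tissue, tmap) {
  gene <- normalize_symbols(gene)
  tissues <- tmap[[gene]]
  if (is.null(tissues)) return(TRUE)
  if (is.null(study_tissue) || is.na(study_tissue)) return(TRUE)
  study_tissue %in% tissues
}

#' Read an essential-gene map
#'
#' Lists human genes whose direct annotation or model-organism homologue is
#' essential for viability; the organism labels are retained for reference.
#'
#' @param path TSV with columns \code{gene_symbol}, \code{organism}.
#' @return named list gene -> organisms, class \code{essential_map}.
#' @export
read_essential_map <- function(path) {
  df <- utils::read.delim(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE,
                          colClasses = "character")
  need <- c("gene_symbol", "organism")
  missing <- setdiff(need, names(df))
  if (length(missing)) {
    stop("essential table missing column(s): ",
         paste(missing, collapse = ", "))
  }
  essential_map(df$gene_symbol, df$organism)
}

#' Build an essential map from vectors
#'
#' @param genes gene symbols.
#' @param organisms organism labels, parallel to \code{genes}.
#' @return an \code{essential_map}.
#' @export
essential_map <- function(genes = character(0), organisms = character(0)) {
  genes <- normalize_symbols(genes)
  keep <- nzchar(genes) & nzchar(organisms)
  m <- lapply(split(organisms[keep], genes[keep]), unique)
  structure(m, class = "essential_map")
}

#' Is a gene essential in any model organism?
#'
#' @param gene gene symbol.
#' @param emap an \code{essential_map}.
#' @return logical: \code{TRUE} iff the gene has at least one organism
#'   entry.
#' @export
is_essential <- function(gene, emap) {
  !is.null(emap[[normalize_symbols(gene)]])
}
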