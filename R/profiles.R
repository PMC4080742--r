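# Per-study genomic profiles: discrete copy-number categories and
# expression matrices, with deletion / underexpression classification.

#' Calling thresholds
#'
#' Fixed defaults matching the discrete-CNA conventions: code -2 is a
#' homozygous deletion; expression Z-scores strictly below -2 (or log2
#' probe levels strictly below 5 in CCLE-style data, the upper limit of the
#' lower quartile) mean underexpressed; gene sets larger than 5 and drugs
#' with more than 5 targets are excluded.
#'
#' @param zscore_cutoff underexpression cutoff on Z-scores (strict less-than).
#' @param ccle_log2_cutoff underexpression cutoff on log2 probe levels
#'   (strict less-than).
#' @param homdel_code CNA category meaning homozygous deletion.
#' @param max_set_size largest retained gene-set size.
#' @param max_drug_targets largest target count for a selective drug.
#' @return list of class \code{vuln_thresholds}.
#' @export
vuln_thresholds <- function(zscore_cutoff = -2, ccle_log2_cutoff = 5,
                            homdel_code = -2L, max_set_size = 5L,
                            max_drug_targets = 5L) {
  structure(list(zscore_cutoff = zscore_cutoff,
                 ccle_log2_cutoff = ccle_log2_cutoff,
                 homdel_code = homdel_code,
                 max_set_size = max_set_size,
                 max_drug_targets = max_drug_targets),
            class = "vuln_thresholds")
}

#' Per-study configuration
#'
#' @param study_id study identifier.
#' @param tissue tissue-of-origin label, or \code{NA} if unknown (no tissue
#'   filtering is applied then).
#' @param sample_class \code{"tumor"} or \code{"cell_line"}.
#' @param expression_mode \code{"zscore"}, \code{"ccle_log2"} or
#'   \code{"none"}.
#' @param cna_path path to the CNA matrix TSV.
#' @param expr_path path to the expression matrix TSV (required unless
#'   \code{expression_mode = "none"}).
#' @return list of class \code{study_config}.
#' @export
study_config <- function(study_id, tissue = NA_character_,
                         sample_class = c("tumor", "cell_line"),
                         expression_mode = c("zscore", "ccle_log2", "none"),
                         cna_path, expr_path = NA_character_) {
  sample_class <- match.arg(sample_class)
  expression_mode <- match.arg(expression_mode)
  if (expression_mode == "none" && !is.na(expr_path)) {
    stop("study '", study_id,
         "': expression_mode 'none' excludes an expression matrix path")
  }
  if (expression_mode != "none" && is.na(expr_path)) {
    stop("study '", study_id, "': expression_mode '", expression_mode,
         "' requires expr_path")
  }
  structure(list(study_id = as.character(study_id),
                 tissue = if (is.null(tissue)) NA_character_ else tissue,
                 sample_class = sample_class,
                 expression_mode = expression_mode,
                 cna_path = cna_path, expr_path = expr_path),
            class = "study_config")
}

#' Read a gene-by-sample profile matrix
#'
#' cBioPortal-style export dialect: tab-separated, first column
#' \code{gene_symbol}, remaining columns one per sample; cells numeric or
#' NA. Duplicate gene rows keep the first occurrence with a warning.
#'
#' @param path TSV path.
#' @return numeric matrix, rownames = normalized gene symbols, colnames =
#'   sample ids.
#' @export
read_profile_matrix <- function(path) {
  df <- utils::read.delim(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE, check.names = FALSE,
                          colClasses = "character")
  if (ncol(df) < 2L) stop("profile matrix needs a gene column plus samples")
  genes <- normalize_symbols(df[[1]])
  df <- df[, -1, drop = FALSE]
  mat <- matrix(NA_real_, nrow = nrow(df), ncol = ncol(df),
                dimnames = list(genes, colnames(df)))
  for (j in seq_len(ncol(df))) {
    cell <- trimws(df[[j]])
    blank <- is.na(cell) | !nzchar(cell) | cell %in% c("NA", "NaN", "na")
    val <- suppressWarnings(as.numeric(cell))
    bad <- is.na(val) & !blank
    if (any(bad)) {
      i <- which(bad)[1]
      stop(sprintf(
        "non-numeric value '%s' at gene %s, sample %s in %s",
        cell[i], genes[i], colnames(df)[j], path))
    }
    mat[, j] <- val
  }
  if (anyDuplicated(rownames(mat))) {
    dup <- unique(rownames(mat)[duplicated(rownames(mat))])
    warning("duplicate gene row(s) ", paste(dup, collapse = ", "),
            "; first occurrence kept")
    mat <- mat[!duplicated(rownames(mat)), , drop = FALSE]
  }
  mat
}

#' Load the profile bundle for one study
#'
#' @param study a \code{study_config}.
#' @return list of class \code{profile_bundle}: \code{cna} matrix,
#'   \code{expr} matrix or NULL, \code{samples}, \code{study}.
#' @export
load_profile_bundle <- function(study) {
  cna <- read_profile_matrix(study$cna_path)
  bad <- cna[!is.na(cna) & !(cna %in% -2:2)]
  if (length(bad)) {
    stop("CNA matrix for study '", study$study_id,
         "' contains values outside -2..2: ",
         paste(utils::head(unique(bad)), collapse = ", "))
  }
  expr <- NULL
  if (study$expression_mode != "none") {
    expr <- read_profile_matrix(study$expr_path)
    extra <- setdiff(colnames(expr), colnames(cna))
    if (length(extra)) {
      stop("expression samples absent from CNA matrix: ",
           paste(utils::head(extra), collapse = ", "))
    }
  }
  structure(list(cna = cna, expr = expr, samples = colnames(cna),
                 study = study),
            class = "profile_bundle")
}

#' @export
print.profile_bundle <- function(x, ...) {
  cat(sprintf(
    "profile_bundle [%s]: %d genes x %d samples (%s, tissue %s, expression %s)\n",
    x$study$study_id, nrow(x$cna), length(x$samples),
    x$study$sample_class,
    ifelse(is.na(x$study$tissue), "unknown", x$study$tissue),
    x$study$expression_mode))
  invisible(x)
}

#' Is a gene homozygously deleted in a sample?
#'
#' \code{TRUE} iff the CNA category equals the homozygous-deletion code
#' (-2). Heterozygous loss (-1) is insufficient. A gene or sample missing
#' from the matrix, or an NA cell, yields \code{FALSE}: absence of evidence
#' is never a deletion call.
#'
#' @param bundle a \code{profile_bundle}.
#' @param gene gene symbol.
#' @param sample sample id.
#' @param thresholds a \code{vuln_thresholds}.
#' @return logical.
#' @export
is_homdel <- function(bundle, gene, sample, thresholds = vuln_thresholds()) {
  gene <- normalize_symbols(gene)
  if (!(gene %in% rownames(bundle$cna)) ||
      !(sample %in% colnames(bundle$cna))) {
    return(FALSE)
  }
  v <- bundle$cna[gene, sample]
  !is.na(v) && v == thresholds$homdel_code
}

#' Is a gene underexpressed in a sample?
#'
#' Strict comparisons: Z-scores must be < -2, CCLE-style log2 levels < 5;
#' boundary values are not underexpressed. When the study carries no
#' expression data, or the value is missing, the answer is \code{NA}
#' (unknown) -- unknown never counts as underexpressed downstream.
#'
#' @inheritParams is_homdel
#' @return \code{TRUE}, \code{FALSE} or \code{NA} (unknown).
#' @export
is_underexpressed <- function(bundle, gene, sample,
                              thresholds = vuln_thresholds()) {
  mode <- bundle$study$expression_mode
  if (mode == "none" || is.null(bundle$expr)) return(NA)
  gene <- normalize_symbols(gene)
  if (!(gene %in% rownames(bundle$expr)) ||
      !(sample %in% colnames(bundle$expr))) {
    return(NA)
  }
  v <- bundle$expr[gene, sample]
  if (is.na(v)) return(NA)
  cutoff <- switch(mode, zscore = thresholds$zscore_cutoff,
                   ccle_log2 = thresholds$ccle_log2_cutoff)
  v < cutoff
}

#' Upper limit of the lower quartile
#'
#' The 25th percentile of the pooled expression values, using the linear
#' interpolation convention of \code{stats::quantile} type 7. Provided as a
#' diagnostic to justify or recompute a data-driven log2 cutoff.
#'
#' @param values numeric vector with at least 4 finite values.
#' @return numeric scalar.
#' @export
lower_quartile_upper_limit <- function(values) {
  values <- values[is.finite(values)]
  if (length(values) < 4L) {
    stop("need at least 4 finite values, got ", length(values))
  }
  unname(stats::quantile(values, probs = 0.25, type = 7))
}
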