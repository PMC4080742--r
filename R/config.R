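# Cohort configuration: YAML loading, validation, loading of all inputs,
# and the run manifest.

#' Read a cohort configuration file
#'
#' YAML with top-level keys \code{genesets} (GMT), \code{drugs},
#' \code{tissue}, \code{essential} (TSVs), optional \code{thresholds}
#' overrides, optional \code{partner_rule} (\code{all}/\code{any}), and
#' \code{studies}: a list of entries with \code{study_id}, optional
#' \code{tissue}, \code{sample_class}, \code{expression_mode}, \code{cna}
#' and (unless mode is \code{none}) \code{expr}. Relative paths are
#' resolved against the config file's directory.
#'
#' @param path YAML path.
#' @return list of class \code{cohort_config}.
#' @export
read_cohort_config <- function(path) {
  raw <- yaml::read_yaml(path)
  base <- dirname(normalizePath(path))
  resolve <- function(p) {
    if (is.null(p) || is.na(p)) return(NA_character_)
    if (grepl("^/", p)) p else file.path(base, p)
  }
  raw$genesets <- resolve(raw$genesets)
  raw$drugs <- resolve(raw$drugs)
  raw$tissue <- resolve(raw$tissue)
  raw$essential <- resolve(raw$essential)
  if (is.null(raw$partner_rule)) raw$partner_rule <- "all"
  raw$studies <- lapply(raw$studies, function(st) {
    st[["cna"]] <- resolve(st[["cna"]])
    st[["expr"]] <- if (is.null(st[["expr"]])) NA_character_ else
      resolve(st[["expr"]])
    if (is.null(st[["tissue"]])) st[["tissue"]] <- NA_character_
    st
  })
  raw$config_path <- path
  structure(raw, class = "cohort_config")
}

#' Validate a cohort configuration
#'
#' Checks every referenced path, header-validates each study's matrices,
#' checks cross-field rules (an expression mode requires an expression
#' matrix) and threshold sanity. All failures are collected, not only the
#' first.
#'
#' @param config a \code{cohort_config}.
#' @return data frame with columns \code{field}, \code{message}; zero rows
#'   when the config is valid.
#' @export
validate_config <- function(config) {
  fails <- list()
  add <- function(field, msg) {
    fails[[length(fails) + 1L]] <<- data.frame(
      field = field, message = msg, stringsAsFactors = FALSE)
  }
  check_file <- function(field, p) {
    if (is.null(p) || is.na(p)) {
      add(field, "path not set")
      FALSE
    } else if (!file.exists(p)) {
      add(field, paste("file not found:", p))
      FALSE
    } else TRUE
  }
  check_matrix_header <- function(field, p) {
    hdr <- strsplit(readLines(p, n = 1L), "\t", fixed = TRUE)[[1]]
    if (length(hdr) < 2L || hdr[1] != "gene_symbol") {
      add(field,
          "matrix header must start with 'gene_symbol' plus sample columns")
    }
  }
  check_file("genesets", config$genesets)
  check_file("drugs", config$drugs)
  check_file("tissue", config$tissue)
  check_file("essential", config$essential)
  if (!config$partner_rule %in% c("all", "any")) {
    add("partner_rule", "must be 'all' or 'any'")
  }
  th <- config$thresholds
  if (!is.null(th)) {
    for (k in c("zscore_cutoff", "ccle_log2_cutoff")) {
      if (!is.null(th[[k]]) && !is.numeric(th[[k]])) {
        add(paste0("thresholds.", k), "must be numeric")
      }
    }
    for (k in c("max_set_size", "max_drug_targets")) {
      if (!is.null(th[[k]]) &&
          (!is.numeric(th[[k]]) || th[[k]] < 1)) {
        add(paste0("thresholds.", k), "must be a positive integer")
      }
    }
  }
  if (length(config$studies) == 0L) add("studies", "no studies configured")
  for (st in config$studies) {
    id <- if (is.null(st$study_id)) "<unnamed>" else st$study_id
    pre <- paste0("studies.", id)
    if (is.null(st$study_id)) add(pre, "study_id missing")
    if (!is.null(st$sample_class) &&
        !st$sample_class %in% c("tumor", "cell_line")) {
      add(paste0(pre, ".sample_class"), "must be 'tumor' or 'cell_line'")
    }
    mode <- if (is.null(st$expression_mode)) "none" else st$expression_mode
    if (!mode %in% c("zscore", "ccle_log2", "none")) {
      add(paste0(pre, ".expression_mode"),
          "must be 'zscore', 'ccle_log2' or 'none'")
      mode <- "none"
    }
    if (check_file(paste0(pre, ".cna"), st[["cna"]])) {
      check_matrix_header(paste0(pre, ".cna"), st[["cna"]])
    }
    if (mode != "none") {
      if (is.na(st[["expr"]])) {
        add(paste0(pre, ".expr"),
            paste0("expression_mode '", mode,
                   "' requires an expression matrix path"))
      } else if (check_file(paste0(pre, ".expr"), st[["expr"]])) {
        check_matrix_header(paste0(pre, ".expr"), st[["expr"]])
      }
    } else if (!is.na(st[["expr"]])) {
      add(paste0(pre, ".expr"),
          "expression_mode 'none' excludes an expression matrix path")
    }
  }
  if (length(fails)) do.call(rbind, fails) else
    data.frame(field = character(0), message = character(0),
               stringsAsFactors = FALSE)
}

#' Load all inputs referenced by a cohort configuration
#'
#' @param config a validated \code{cohort_config}.
#' @return list with \code{studies} (list of \code{study_config}),
#'   \code{catalog}, \code{drugs}, \code{tmap}, \code{emap},
#'   \code{thresholds}, \code{partner_rule}.
#' @export
load_cohort_inputs <- function(config) {
  th_args <- config$thresholds
  thresholds <- if (is.null(th_args)) vuln_thresholds() else
    do.call(vuln_thresholds, th_args)
  studies <- lapply(config$studies, function(st) {
    study_config(st$study_id, tissue = st[["tissue"]],
                 sample_class = if (is.null(st$sample_class)) "tumor" else
                   st$sample_class,
                 expression_mode = if (is.null(st$expression_mode)) "none"
                 else st$expression_mode,
                 cna_path = st[["cna"]], expr_path = st[["expr"]])
  })
  list(studies = studies,
       catalog = geneset_catalog(read_gmt(config$genesets)),
       drugs = read_drug_targets(config$drugs,
                                 thresholds$max_drug_targets),
       tmap = read_tissue_map(config$tissue),
       emap = read_essential_map(config$essential),
       thresholds = thresholds,
       partner_rule = config$partner_rule)
}

#' Run the full pipeline from a cohort configuration
#'
#' @param config a \code{cohort_config} or path to one.
#' @return a scored \code{vuln_set}.
#' @export
run_cohort_config <- function(config) {
  if (is.character(config)) config <- read_cohort_config(config)
  fails <- validate_config(config)
  if (nrow(fails)) {
    stop("invalid cohort config:\n",
         paste(" -", fails$field, ":", fails$message, collapse = "\n"))
  }
  inp <- load_cohort_inputs(config)
  run_cohort(inp$studies, inp$catalog, inp$drugs, inp$tmap, inp$emap,
             inp$thresholds, inp$partner_rule)
}

#' Write a run manifest
#'
#' Records MD5 hashes of every input file, the thresholds in force and the
#' package version, so that identical inputs are recognizably identical
#' across runs.
#'
#' @param out_dir directory to write \code{manifest.json} into.
#' @param inputs named character vector of input paths.
#' @param thresholds a \code{vuln_thresholds}.
#' @return the manifest path, invisibly.
#' @export
write_manifest <- function(out_dir, inputs, thresholds = vuln_thresholds()) {
  inputs <- inputs[!is.na(inputs)]
  if (is.null(names(inputs)) || any(!nzchar(names(inputs)))) {
    names(inputs) <- basename(inputs)
  }
  hashes <- as.list(unname(tools::md5sum(inputs)))
  names(hashes) <- names(inputs)
  manifest <- list(
    tool = "isovuln",
    version = as.character(utils::packageVersion("isovuln")),
    hash_algorithm = "md5",
    inputs = hashes,
    thresholds = unclass(thresholds))
  path <- file.path(out_dir, "manifest.json")
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}
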