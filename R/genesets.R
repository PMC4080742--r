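# Isoenzyme gene-set catalog: construction from BioPAX / EC tables / GMT,
# priority merging and size/targetability filtering.

#' Normalize gene symbols
#'
#' Uppercases and strips surrounding whitespace. No alias resolution is
#' attempted; inputs are expected to carry HGNC-style symbols already.
#'
#' @param x character vector of gene symbols.
#' @return normalized character vector.
#' @keywords internal
normalize_symbols <- function(x) {
  toupper(trimws(as.character(x)))
}

#' Create an isoenzyme gene set
#'
#' A gene set groups the genes whose products catalyze the same biochemical
#' reaction (isoenzymes). Genes are normalized to uppercase symbols and
#' deduplicated, preserving first-seen order.
#'
#' @param set_id unique identifier within a catalog.
#' @param genes character vector of gene symbols (non-empty after dedup).
#' @param source one of \code{"KEGG"}, \code{"REACTOME"}, \code{"HUMANCYC"},
#'   \code{"USER"}.
#' @param reaction_name free-text reaction name.
#' @param pathway_name free-text pathway name, may be empty.
#' @return an object of class \code{gene_set}.
#' @export
gene_set <- function(set_id, genes, source = "USER",
                     reaction_name = "", pathway_name = "") {
  genes <- normalize_symbols(genes)
  genes <- genes[nzchar(genes)]
  genes <- genes[!duplicated(genes)]
  if (length(genes) == 0L) {
    stop("gene_set '", set_id, "': no genes after normalization")
  }
  source <- toupper(source)
  structure(
    list(set_id = as.character(set_id), genes = genes, source = source,
         reaction_name = as.character(reaction_name),
         pathway_name = as.character(pathway_name)),
    class = "gene_set"
  )
}

#' @export
print.gene_set <- function(x, ...) {
  cat(sprintf("<gene_set %s [%s] %s: %s>\n", x$set_id, x$source,
              x$reaction_name, paste(x$genes, collapse = ", ")))
  invisible(x)
}

#' Assemble a gene-set catalog
#'
#' @param sets list of \code{gene_set} objects.
#' @param provenance optional named character vector mapping set_id to the
#'   source file it came from.
#' @return an object of class \code{geneset_catalog}.
#' @export
geneset_catalog <- function(sets, provenance = NULL) {
  stopifnot(is.list(sets))
  ids <- vapply(sets, function(s) s$set_id, character(1))
  if (anyDuplicated(ids)) {
    ids <- make.unique(ids, sep = "_")
    for (i in seq_along(sets)) sets[[i]]$set_id <- ids[i]
  }
  names(sets) <- ids
  structure(list(sets = sets, provenance = provenance),
            class = "geneset_catalog")
}

#' @export
length.geneset_catalog <- function(x) length(x$sets)

#' @export
print.geneset_catalog <- function(x, ...) {
  sizes <- vapply(x$sets, function(s) length(s$genes), integer(1))
  cat(sprintf("geneset_catalog: %d sets, %d distinct genes\n",
              length(x$sets),
              length(unique(unlist(lapply(x$sets, `[[`, "genes"))))))
  if (length(sizes)) {
    cat("  set sizes: ", paste(names(table(sizes)), table(sizes),
                               sep = "x", collapse = ", "), "\n")
  }
  invisible(x)
}

# strip a URI or "#frag" reference down to its fragment / local id
.ref_local_id <- function(ref) {
  sub(".*#", "", ref)
}

.bp_local_name <- function(nodes) {
  vapply(nodes, function(n) xml2::xml_name(n), character(1))
}

.bp_node_id <- function(node) {
  id <- xml2::xml_attr(node, "ID")
  if (is.na(id)) id <- .ref_local_id(xml2::xml_attr(node, "about"))
  id
}

#' Extract isoenzyme gene sets from a BioPAX Level 3 document
#'
#' Walks every \code{BiochemicalReaction} that has at least one
#' \code{Catalysis}/\code{Control} controller, resolves each controller
#' protein to HGNC gene symbols through its \code{ProteinReference} xrefs
#' (any xref whose \code{db} field names HGNC), and emits one gene set per
#' reaction. \code{Complex} controllers contribute the symbols of all member
#' proteins. Reactions with no resolvable symbol are skipped. Only the
#' classes \code{BiochemicalReaction}, \code{Catalysis}, \code{Control},
#' \code{Protein}, \code{ProteinReference}, \code{Complex} and xref classes
#' are interpreted; everything else in the document is ignored.
#'
#' @param path path to a BioPAX Level 3 OWL (RDF/XML) file, or a string of
#'   XML content.
#' @param source source label attached to the resulting sets
#'   (e.g. \code{"REACTOME"}, \code{"HUMANCYC"}).
#' @return list of \code{gene_set} objects.
#' @export
parse_biopax_isoenzymes <- function(path, source = "REACTOME") {
  doc <- xml2::read_xml(path)  # malformed XML -> xml2 error with position
  all_nodes <- xml2::xml_find_all(doc, "//*")
  lname <- .bp_local_name(all_nodes)

  # index every element carrying an rdf:ID / rdf:about
  ids <- vapply(all_nodes, .bp_node_id, character(1))
  keep <- !is.na(ids) & nzchar(ids)
  index <- all_nodes[keep]
  names(index) <- ids[keep]

  node_class <- function(node) xml2::xml_name(node)

  # children of `node` named `field` (local name), either inline or by
  # rdf:resource reference; returns resolved nodes, warning on dangling refs
  resolve_children <- function(node, field) {
    kids <- xml2::xml_children(node)
    kids <- kids[.bp_local_name(kids) == field]
    out <- list()
    for (k in kids) {
      res <- xml2::xml_attr(k, "resource")
      if (!is.na(res)) {
        id <- .ref_local_id(res)
        tgt <- index[[id]]
        if (is.null(tgt)) {
          warning("dangling reference '", id, "' in <", field,
                  "> of ", node_class(node), "; entity skipped",
                  call. = FALSE)
        } else {
          out[[length(out) + 1L]] <- tgt
        }
      } else {
        inner <- xml2::xml_children(k)
        for (n in inner) out[[length(out) + 1L]] <- n
      }
    }
    out
  }

  child_text <- function(node, field) {
    kids <- xml2::xml_children(node)
    kids <- kids[.bp_local_name(kids) == field]
    if (length(kids) == 0L) return("")
    trimws(xml2::xml_text(kids[[1]]))
  }

  hgnc_symbols_from_xrefs <- function(node) {
    xrefs <- resolve_children(node, "xref")
    syms <- character(0)
    for (x in xrefs) {
      db <- child_text(x, "db")
      if (grepl("hgnc", db, ignore.case = TRUE)) {
        id <- child_text(x, "id")
        if (nzchar(id)) syms <- c(syms, id)
      }
    }
    syms
  }

  protein_symbols <- function(node) {
    syms <- hgnc_symbols_from_xrefs(node)
    for (er in resolve_children(node, "entityReference")) {
      syms <- c(syms, hgnc_symbols_from_xrefs(er))
    }
    syms
  }

  controller_symbols <- function(node) {
    cls <- node_class(node)
    if (cls == "Complex") {
      syms <- character(0)
      for (comp in resolve_children(node, "component")) {
        syms <- c(syms, controller_symbols(comp))
      }
      c(syms, hgnc_symbols_from_xrefs(node))
    } else {
      # Protein or any other physical entity: use its own / its reference xrefs
      protein_symbols(node)
    }
  }

  # map reaction id -> list of controller nodes, via Catalysis/Control
  controls <- index[vapply(index, node_class, character(1)) %in%
                      c("Catalysis", "Control")]
  controllers_of <- list()
  for (ctl in controls) {
    controlled <- resolve_children(ctl, "controlled")
    ctrls <- resolve_children(ctl, "controller")
    for (rx in controlled) {
      if (node_class(rx) != "BiochemicalReaction") next
      rid <- .bp_node_id(rx)
      controllers_of[[rid]] <- c(controllers_of[[rid]], ctrls)
    }
  }

  reactions <- index[vapply(index, node_class, character(1)) ==
                       "BiochemicalReaction"]
  sets <- list()
  for (rid in names(reactions)) {
    ctrls <- controllers_of[[rid]]
    if (is.null(ctrls) || length(ctrls) == 0L) next
    syms <- unlist(lapply(ctrls, controller_symbols))
    syms <- normalize_symbols(syms)
    syms <- syms[nzchar(syms)]
    if (length(syms) == 0L) next
    rx <- reactions[[rid]]
    rname <- child_text(rx, "displayName")
    if (!nzchar(rname)) rname <- child_text(rx, "name")
    sets[[length(sets) + 1L]] <- gene_set(
      set_id = rid, genes = syms, source = source,
      reaction_name = rname
    )
  }
  sets
}

#' Build gene sets from an EC-number to gene-symbol table
#'
#' One gene set per EC number, pooling all gene rows of that EC. An optional
#' third column supplies the primary enzyme name used as reaction name;
#' otherwise the EC number itself is used.
#'
#' @param table data frame with columns \code{ec_number},
#'   \code{gene_symbol} and optionally \code{enzyme_name}, or a path to a
#'   TSV with those columns.
#' @param resource_label source label for the resulting sets
#'   (default \code{"KEGG"}).
#' @return list of \code{gene_set} objects.
#' @export
parse_ec_table <- function(table, resource_label = "KEGG") {
  if (is.character(table) && length(table) == 1L) {
    table <- utils::read.delim(table, header = TRUE, sep = "\t",
                               stringsAsFactors = FALSE)
  }
  need <- c("ec_number", "gene_symbol")
  if (!all(need %in% names(table))) {
    stop("EC table must have columns: ", paste(need, collapse = ", "))
  }
  if (nrow(table) == 0L) return(list())
  empty <- !nzchar(trimws(as.character(table$gene_symbol)))
  if (any(empty)) {
    warning(sum(empty), " EC table row(s) with empty gene symbol dropped")
    table <- table[!empty, , drop = FALSE]
  }
  if (nrow(table) == 0L) return(list())
  has_name <- "enzyme_name" %in% names(table)
  sets <- list()
  for (ec in unique(as.character(table$ec_number))) {
    rows <- table[table$ec_number == ec, , drop = FALSE]
    rname <- ec
    if (has_name) {
      nm <- trimws(as.character(rows$enzyme_name))
      nm <- nm[nzchar(nm)]
      if (length(nm)) rname <- nm[1]
    }
    sets[[length(sets) + 1L]] <- gene_set(
      set_id = ec, genes = rows$gene_symbol, source = resource_label,
      reaction_name = rname
    )
  }
  sets
}

#' Read gene sets from a GMT file
#'
#' Standard GMT dialect: one set per line, \code{name TAB description TAB
#' gene1 TAB gene2 ...}. The description field encodes metadata as
#' \code{"source|reaction_name|pathway_name"}; a free-text description is
#' accepted and stored as the reaction name with source \code{USER}.
#'
#' @param path path to a GMT file.
#' @return list of \code{gene_set} objects.
#' @export
read_gmt <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(lines)]
  sets <- list()
  for (i in seq_along(lines)) {
    fields <- strsplit(lines[i], "\t", fixed = TRUE)[[1]]
    if (length(fields) < 3L) {
      stop("GMT line ", i, ": expected >= 3 tab-separated fields, got ",
           length(fields))
    }
    meta <- strsplit(fields[2], "|", fixed = TRUE)[[1]]
    if (length(meta) >= 2L) {
      src <- meta[1]
      rname <- meta[2]
      pname <- if (length(meta) >= 3L) meta[3] else ""
    } else {
      src <- "USER"
      rname <- fields[2]
      pname <- ""
    }
    sets[[length(sets) + 1L]] <- gene_set(
      set_id = fields[1], genes = fields[-(1:2)], source = src,
      reaction_name = rname, pathway_name = pname
    )
  }
  sets
}

#' Write a gene-set catalog to a GMT file
#'
#' The inverse of \code{\link{read_gmt}}: metadata is packed into the
#' description field so that write-then-read reproduces compositions and
#' metadata exactly.
#'
#' @param catalog a \code{geneset_catalog} or list of \code{gene_set}.
#' @param path output path.
#' @export
write_gmt <- function(catalog, path) {
  sets <- if (inherits(catalog, "geneset_catalog")) catalog$sets else catalog
  lines <- vapply(sets, function(s) {
    desc <- paste(s$source, s$reaction_name, s$pathway_name, sep = "|")
    paste(c(s$set_id, desc, s$genes), collapse = "\t")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

.composition_key <- function(genes) paste(sort(genes), collapse = "|")

#' Merge gene-set catalogs with resource priority
#'
#' Sets with identical gene composition (as unordered symbol sets) collapse
#' to a single survivor: the copy from the highest-priority source, including
#' its metadata. Sets with distinct compositions are all kept, even when they
#' overlap. Merging is idempotent.
#'
#' @param catalogs list of gene-set lists (or \code{geneset_catalog}s).
#' @param priority character vector of sources from highest to lowest
#'   priority; must cover every source present.
#' @return a \code{geneset_catalog}.
#' @export
merge_catalogs <- function(catalogs,
                           priority = c("KEGG", "REACTOME", "HUMANCYC",
                                        "USER")) {
  priority <- toupper(priority)
  sets <- list()
  for (cat_i in catalogs) {
    if (inherits(cat_i, "geneset_catalog")) cat_i <- cat_i$sets
    sets <- c(sets, cat_i)
  }
  srcs <- vapply(sets, function(s) s$source, character(1))
  unknown <- setdiff(unique(srcs), priority)
  if (length(unknown)) {
    stop("source(s) not in priority list: ", paste(unknown, collapse = ", "))
  }
  rank <- match(srcs, priority)
  keys <- vapply(sets, function(s) .composition_key(s$genes), character(1))
  # stable: first occurrence wins among equal ranks
  ord <- order(match(keys, unique(keys)), rank)
  sets <- sets[ord]
  keys <- keys[ord]
  survivors <- sets[!duplicated(keys)]
  geneset_catalog(survivors)
}

#' Filter a catalog by set size and targetability
#'
#' Retains only sets with at most \code{max_set_size} genes (large sets do
#' not add exploitable calls) and at least one gene that is targetable by
#' some drug (any drug, not only selective ones). Removal counts by reason
#' are reported via \code{message()} and attached as the
#' \code{"filter_log"} attribute.
#'
#' @param catalog a \code{geneset_catalog}.
#' @param targetable_genes character vector of targetable gene symbols,
#'   typically \code{\link{targetable_genes}} of a drug catalog.
#' @param max_set_size maximum retained set size (default 5, inclusive).
#' @return filtered \code{geneset_catalog}.
#' @export
filter_catalog <- function(catalog, targetable_genes, max_set_size = 5L) {
  targetable_genes <- normalize_symbols(targetable_genes)
  sizes <- vapply(catalog$sets, function(s) length(s$genes), integer(1))
  too_big <- sizes > max_set_size
  has_target <- vapply(catalog$sets, function(s) {
    any(s$genes %in% targetable_genes)
  }, logical(1))
  removed_size <- sum(too_big)
  removed_nontarg <- sum(!too_big & !has_target)
  keep <- !too_big & has_target
  message(sprintf(
    "filter_catalog: kept %d/%d sets (removed %d with > %d genes, %d with no targetable gene)",
    sum(keep), length(keep), removed_size, max_set_size, removed_nontarg))
  out <- geneset_catalog(catalog$sets[keep], provenance = catalog$provenance)
  attr(out, "filter_log") <- c(removed_size = removed_size,
                               removed_nontargetable = removed_nontarg)
  out
}
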