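# Programmatic fixture builders shared across tests.

# Minimal BioPAX Level 3 RDF/XML document builder.
# reactions: list of list(id, name, controllers = list of controller ids)
# proteins:  list of list(id, hgnc = symbol or NULL, ref = protein-ref id)
# complexes: list of list(id, components = protein ids)
# dangling:  character vector of controller ids referenced but not defined
make_biopax <- function(reactions, proteins = list(), complexes = list()) {
  esc <- function(x) gsub("&", "&amp;", x)
  out <- c(
    '<?xml version="1.0" encoding="UTF-8"?>',
    paste0('<rdf:RDF xmlns:rdf="http://www.w3.org/1999/02/22-rdf-syntax-ns#"',
           ' xmlns:bp="http://www.biopax.org/release/biopax-level3.owl#"',
           ' xml:base="http://example.org/biopax#">'))
  k <- 0L
  for (rx in reactions) {
    out <- c(out,
             sprintf('<bp:BiochemicalReaction rdf:ID="%s">', rx$id),
             sprintf('<bp:displayName>%s</bp:displayName>', esc(rx$name)),
             '</bp:BiochemicalReaction>')
    for (ctrl in rx$controllers) {
      k <- k + 1L
      out <- c(out,
               sprintf('<bp:Catalysis rdf:ID="cat%d">', k),
               sprintf('<bp:controlled rdf:resource="#%s"/>', rx$id),
               sprintf('<bp:controller rdf:resource="#%s"/>', ctrl),
               '</bp:Catalysis>')
    }
  }
  for (p in proteins) {
    ref <- if (is.null(p$ref)) paste0(p$id, "_ref") else p$ref
    out <- c(out,
             sprintf('<bp:Protein rdf:ID="%s">', p$id),
             sprintf('<bp:entityReference rdf:resource="#%s"/>', ref),
             '</bp:Protein>',
             sprintf('<bp:ProteinReference rdf:ID="%s">', ref))
    if (!is.null(p$hgnc)) {
      out <- c(out,
               sprintf('<bp:xref rdf:resource="#%s_x"/>', p$id),
               '</bp:ProteinReference>',
               sprintf('<bp:RelationshipXref rdf:ID="%s_x">', p$id),
               '<bp:db>HGNC Symbol</bp:db>',
               sprintf('<bp:id>%s</bp:id>', p$hgnc),
               '</bp:RelationshipXref>')
    } else {
      out <- c(out, '</bp:ProteinReference>')
    }
  }
  for (cx in complexes) {
    out <- c(out, sprintf('<bp:Complex rdf:ID="%s">', cx$id))
    for (cp in cx$components) {
      out <- c(out, sprintf('<bp:component rdf:resource="#%s"/>', cp))
    }
    out <- c(out, '</bp:Complex>')
  }
  paste(c(out, '</rdf:RDF>'), collapse = "\n")
}

write_tmp <- function(text, ext = ".owl") {
  path <- tempfile(fileext = ext)
  writeLines(text, path)
  path
}

# long-format drug table -> TSV path
write_drug_tsv <- function(df, path = tempfile(fileext = ".tsv")) {
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  path
}

drug_row <- function(id, target, fda = 0L, cancer = 0L, name = id) {
  data.frame(drug_id = id, drug_name = name, target_gene = target,
             fda_approved = fda, cancer_drug = cancer,
             stringsAsFactors = FALSE)
}

# micro-cohort: set {GA, GB}, GA homozygously deleted, GB the partner with
# one dedicated selective drug; criteria are wired through flags/annotations
make_scenario <- function(crit_i = TRUE, fda = TRUE, cancer = FALSE,
                          partner_essential = FALSE, with_expr = TRUE) {
  catalog <- geneset_catalog(list(gene_set("PAIR", c("GA", "GB"), "KEGG")))
  drugs <- suppressWarnings(drug_table(
    drug_row("sel", "GB", fda = as.integer(fda),
             cancer = as.integer(cancer))))
  emap <- if (partner_essential) essential_map("GB", "S. cerevisiae")
          else essential_map()
  cna <- matrix(c(-2, 0), nrow = 2, dimnames = list(c("GA", "GB"), "S1"))
  expr <- if (with_expr) {
    matrix(c(if (crit_i) -3 else -2, 0.5), nrow = 2,
           dimnames = list(c("GA", "GB"), "S1"))
  } else NULL
  bundle <- make_bundle(cna, expr = expr, tissue = "lung")
  list(catalog = catalog, drugs = drugs, tmap = tissue_map(),
       emap = emap, bundle = bundle)
}

call_and_score <- function(sc) {
  v <- call_sample("S1", sc$catalog, sc$drugs, sc$tmap, sc$bundle)
  score_vulnerability(v, sc$bundle, sc$emap, sc$drugs, sc$tmap)
}

# in-memory micro-study: build a profile bundle without touching disk
make_bundle <- function(cna, expr = NULL, study_id = "st",
                        tissue = NA_character_, sample_class = "tumor",
                        expression_mode = if (is.null(expr)) "none"
                        else "zscore") {
  dir <- tempfile("bundle")
  dir.create(dir)
  cna_path <- file.path(dir, "cna.tsv")
  write.table(cbind(gene_symbol = rownames(cna),
                    as.data.frame(cna, check.names = FALSE)),
              cna_path, sep = "\t", quote = FALSE, row.names = FALSE)
  expr_path <- NA_character_
  if (!is.null(expr)) {
    expr_path <- file.path(dir, "expr.tsv")
    write.table(cbind(gene_symbol = rownames(expr),
                      as.data.frame(expr, check.names = FALSE)),
                expr_path, sep = "\t", quote = FALSE, row.names = FALSE)
  }
  st <- study_config(study_id, tissue = tissue,
                     sample_class = sample_class,
                     expression_mode = expression_mode,
                     cna_path = cna_path, expr_path = expr_path)
  load_profile_bundle(st)
}
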