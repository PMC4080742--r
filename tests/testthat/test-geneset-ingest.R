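# Gene-set catalog construction: BioPAX extraction, EC tables, GMT I/O,
# priority merging, size/targetability filtering.

test_that("BioPAX extraction resolves reaction controllers to HGNC symbols", {
  owl <- make_biopax(
    reactions = list(
      list(id = "rxn1", name = "phosphopyruvate hydratase",
           controllers = c("p1", "p2", "p3")),
      list(id = "rxn2", name = "orphan reaction", controllers = list())),
    proteins = list(list(id = "p1", hgnc = "ENO1"),
                    list(id = "p2", hgnc = "ENO2"),
                    list(id = "p3", hgnc = "ENO3")))
  sets <- parse_biopax_isoenzymes(write_tmp(owl), source = "REACTOME")
  expect_length(sets, 1L)  # the controller-less reaction emits nothing
  expect_setequal(sets[[1]]$genes, c("ENO1", "ENO2", "ENO3"))
  expect_equal(sets[[1]]$reaction_name, "phosphopyruvate hydratase")
  expect_equal(sets[[1]]$source, "REACTOME")
})

test_that("complex controllers contribute all member-protein symbols", {
  owl <- make_biopax(
    reactions = list(list(id = "rxn1", name = "lipid transport",
                          controllers = "cplx1")),
    proteins = list(list(id = "pa", hgnc = "A2M"),
                    list(id = "pb", hgnc = "BMP1")),
    complexes = list(list(id = "cplx1", components = c("pa", "pb"))))
  sets <- parse_biopax_isoenzymes(write_tmp(owl))
  expect_length(sets, 1L)
  expect_setequal(sets[[1]]$genes, c("A2M", "BMP1"))
})

test_that("BioPAX extraction matches a hand-enumerated walk of the tree", {
  # two reactions sharing one protein; one protein without an HGNC xref
  owl <- make_biopax(
    reactions = list(
      list(id = "r1", name = "reaction one", controllers = c("p1", "p2")),
      list(id = "r2", name = "reaction two", controllers = c("p2", "p3"))),
    proteins = list(list(id = "p1", hgnc = "GCK"),
                    list(id = "p2", hgnc = "HK1"),
                    list(id = "p3", hgnc = NULL)))
  sets <- parse_biopax_isoenzymes(write_tmp(owl))
  got <- lapply(sets, function(s) sort(s$genes))
  names(got) <- vapply(sets, function(s) s$set_id, character(1))
  # oracle: reaction -> catalysis -> protein -> xref, walked by hand
  expect_equal(got[order(names(got))],
               list(r1 = c("GCK", "HK1"), r2 = "HK1"))
})

test_that("dangling references are skipped with a warning", {
  owl <- make_biopax(
    reactions = list(list(id = "rxn1", name = "rx",
                          controllers = c("p1", "ghost"))),
    proteins = list(list(id = "p1", hgnc = "TK1")))
  expect_warning(sets <- parse_biopax_isoenzymes(write_tmp(owl)),
                 "dangling")
  expect_length(sets, 1L)
  expect_equal(sets[[1]]$genes, "TK1")
})

test_that("malformed XML is a parse error", {
  path <- write_tmp("<rdf:RDF><unclosed>")
  expect_error(suppressWarnings(parse_biopax_isoenzymes(path)))
})

test_that("EC tables group genes per EC number", {
  tab <- data.frame(
    ec_number = rep("EC 4.2.1.11", 3),
    gene_symbol = c("ENO1", "ENO2", "ENO3"),
    enzyme_name = "phosphopyruvate hydratase",
    stringsAsFactors = FALSE)
  sets <- parse_ec_table(tab)
  expect_length(sets, 1L)
  expect_setequal(sets[[1]]$genes, c("ENO1", "ENO2", "ENO3"))
  expect_equal(sets[[1]]$reaction_name, "phosphopyruvate hydratase")
  expect_equal(sets[[1]]$source, "KEGG")

  expect_length(parse_ec_table(tab[0, ]), 0L)

  expect_warning(
    dropped <- parse_ec_table(data.frame(
      ec_number = c("EC 1.1.1.1", "EC 1.1.1.1"),
      gene_symbol = c("ADH1B", ""), stringsAsFactors = FALSE)),
    "empty")
  expect_equal(dropped[[1]]$genes, "ADH1B")
})

test_that("EC grouping equals a brute-force group-by, shared genes allowed", {
  tab <- data.frame(
    ec_number = rep(paste0("EC ", 1:4), each = 2),
    gene_symbol = c("G1", "SHARED", "G2", "SHARED", "G3", "G4",
                    "G5", "G6"),
    stringsAsFactors = FALSE)
  sets <- parse_ec_table(tab)
  expect_length(sets, 4L)
  got <- lapply(sets, `[[`, "genes")
  names(got) <- vapply(sets, `[[`, character(1), "set_id")
  oracle <- lapply(split(tab$gene_symbol, tab$ec_number), unique)
  expect_equal(got[order(names(got))], oracle[order(names(oracle))])
  expect_equal(sum(vapply(got, function(g) "SHARED" %in% g, logical(1))),
               2L)
})

test_that("GMT round-trips compositions and metadata", {
  one <- tempfile(fileext = ".gmt")
  writeLines("pair\tKEGG|some reaction|glycolysis\tGCK\tHK1", one)
  sets <- read_gmt(one)
  expect_length(sets, 1L)
  expect_equal(sets[[1]]$genes, c("GCK", "HK1"))
  expect_equal(sets[[1]]$source, "KEGG")
  expect_equal(sets[[1]]$pathway_name, "glycolysis")

  # 10-set fixture: write(read(f)) reproduces read(f)
  set.seed(42)
  sets10 <- lapply(1:10, function(i) {
    gene_set(paste0("S", i), paste0("G", sample(100, sample(2:5, 1))),
             source = sample(c("KEGG", "REACTOME", "HUMANCYC"), 1),
             reaction_name = paste("rx", i), pathway_name = paste("pw", i))
  })
  f1 <- tempfile(fileext = ".gmt")
  f2 <- tempfile(fileext = ".gmt")
  write_gmt(sets10, f1)
  write_gmt(read_gmt(f1), f2)
  expect_identical(readLines(f1), readLines(f2))
})

test_that("GMT duplicate genes are deduplicated preserving order", {
  f <- tempfile(fileext = ".gmt")
  writeLines("dup\tUSER|rx|\tTK2\tTK1\tTK2\tTK1", f)
  expect_equal(read_gmt(f)[[1]]$genes, c("TK2", "TK1"))
})

test_that("GMT lines with fewer than 3 fields name the line number", {
  f <- tempfile(fileext = ".gmt")
  writeLines(c("ok\tUSER|rx|\tGCK\tHK1", "broken\tonly-description"), f)
  expect_error(read_gmt(f), "line 2")
})

test_that("merging collapses identical compositions by source priority", {
  kegg <- list(gene_set("k1", c("ENO1", "ENO2", "ENO3"), "KEGG",
                        "enolase (KEGG)"))
  reac <- list(gene_set("r1", c("ENO3", "ENO1", "ENO2"), "REACTOME",
                        "enolase (Reactome)"),
               gene_set("r2", c("GCK", "HK1"), "REACTOME"))
  merged <- merge_catalogs(list(kegg, reac))
  expect_length(merged, 2L)
  eno <- Filter(function(s) "ENO1" %in% s$genes, merged$sets)[[1]]
  expect_equal(eno$source, "KEGG")
  expect_equal(eno$reaction_name, "enolase (KEGG)")
})

test_that("merge is idempotent and keys on unordered composition", {
  catalogs <- list(
    list(gene_set("a1", c("A", "B"), "KEGG"),
         gene_set("a2", c("C", "D", "E"), "KEGG")),
    list(gene_set("b1", c("B", "A"), "REACTOME"),
         gene_set("b2", c("C", "D"), "REACTOME")),
    list(gene_set("c1", c("E", "D", "C"), "HUMANCYC"),
         gene_set("c2", c("F", "G"), "HUMANCYC")))
  merged <- merge_catalogs(catalogs)
  # brute-force: 5 distinct unordered compositions
  comps <- unique(lapply(unlist(catalogs, recursive = FALSE),
                         function(s) sort(s$genes)))
  expect_length(merged, length(comps))
  dup_srcs <- vapply(merged$sets, function(s) s$source, character(1))
  expect_equal(sum(dup_srcs == "KEGG"), 2L)  # duplicated ones keep KEGG

  again <- merge_catalogs(list(merged))
  expect_equal(lapply(again$sets, `[[`, "genes"),
               lapply(merged$sets, `[[`, "genes"))

  # single catalog in -> identical compositions out
  single <- merge_catalogs(list(catalogs[[1]]))
  expect_equal(unname(lapply(single$sets, `[[`, "genes")),
               lapply(catalogs[[1]], `[[`, "genes"))

  expect_error(
    merge_catalogs(list(list(gene_set("x", "A", "MYSTERY")))),
    "MYSTERY")
})

test_that("filtering enforces set size and targetability", {
  catalog <- geneset_catalog(list(
    gene_set("six", paste0("G", 1:6), "KEGG"),
    gene_set("five_ok", paste0("H", 1:5), "KEGG"),
    gene_set("untargetable", c("X1", "X2"), "KEGG")))
  kept <- suppressMessages(
    filter_catalog(catalog, targetable_genes = c("H3", "G1")))
  expect_equal(names(kept$sets), "five_ok")  # 6-gene out, no-target out
  log <- attr(kept, "filter_log")
  expect_equal(unname(log["removed_size"]), 1L)
  expect_equal(unname(log["removed_nontargetable"]), 1L)
})

test_that("post-merge catalogs never repeat a composition and filters never grow", {
  set.seed(7)
  for (rep in 1:5) {
    sets <- lapply(1:20, function(i) {
      gene_set(paste0("s", i), paste0("G", sample(12, sample(2:6, 1))),
               source = sample(c("KEGG", "REACTOME", "HUMANCYC"), 1))
    })
    merged <- merge_catalogs(list(sets))
    keys <- vapply(merged$sets,
                   function(s) paste(sort(s$genes), collapse = "|"),
                   character(1))
    expect_equal(anyDuplicated(keys), 0L)
    targ <- paste0("G", 1:6)
    kept <- suppressMessages(filter_catalog(merged, targ))
    expect_lte(length(kept), length(merged))
    for (s in kept$sets) {
      expect_lte(length(s$genes), 5L)
      expect_true(any(s$genes %in% targ))
    }
  }
})
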