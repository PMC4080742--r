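# The vulnerability caller and the 0-4 score.

test_that("exploit classification distinguishes the selectivity failures", {
  drugs <- drug_table(rbind(
    drug_row("methotrexate", "DHFR", fda = 1L, cancer = 1L),
    drug_row("methotrexate", "DHFRL1", fda = 1L, cancer = 1L),
    drug_row("dhfrl1_inh", "DHFRL1"),
    drug_row("wide", paste0("T", 1:5)),
    drug_row("wide", "DHFRL1")))
  set <- gene_set("pair", c("DHFR", "DHFRL1"), "KEGG")

  # covers both members of the pair: suggested, but not selective
  v <- classify_exploit("methotrexate", drugs, set, "DHFR", "DHFRL1")
  expect_false(v$is_selective_exploit)
  expect_equal(v$reason, "covers_all_members")

  v <- classify_exploit("dhfrl1_inh", drugs, set, "DHFR", "DHFRL1")
  expect_true(v$is_selective_exploit)
  expect_equal(v$reason, "ok")

  # six unique targets: too promiscuous
  v <- classify_exploit("wide", drugs, set, "DHFR", "DHFRL1")
  expect_false(v$is_selective_exploit)
  expect_equal(v$reason, "too_many_targets")

  v <- classify_exploit("dhfrl1_inh", drugs,
                        gene_set("trio", c("DHFR", "DHFRL1", "OTHER"),
                                 "KEGG"),
                        "DHFR", "OTHER")
  expect_equal(v$reason, "misses_partner")

  expect_error(classify_exploit("dhfrl1_inh", drugs, set, "DHFR", "DHFR"),
               "intact")
})

test_that("a drug targeting one of three enolases is a selective exploit", {
  drugs <- drug_table(drug_row("eno2_inh", "ENO2"))
  set <- gene_set("eno", c("ENO1", "ENO2", "ENO3"), "KEGG")
  v <- classify_exploit("eno2_inh", drugs, set, "ENO1", "ENO2")
  expect_true(v$is_selective_exploit)
})

test_that("the glioblastoma-like enolase case calls on ENO2 only", {
  catalog <- geneset_catalog(list(
    gene_set("eno", c("ENO1", "ENO2", "ENO3"), "KEGG")))
  drugs <- drug_table(drug_row("eno2_inh", "ENO2"))
  tmap <- tissue_map("ENO3", "muscle")
  cna <- matrix(c(-2, 0, 0), nrow = 3,
                dimnames = list(c("ENO1", "ENO2", "ENO3"), "S1"))
  bundle <- make_bundle(cna, tissue = "brain")
  v <- call_sample("S1", catalog, drugs, tmap, bundle)
  expect_equal(nrow(v), 1L)
  expect_equal(v$deleted_genes, "ENO1")
  expect_equal(v$expected_expressed_partners, "ENO2")  # ENO3 filtered out
  expect_equal(parse_exploit_map(v$exploit_map), list(ENO2 = "eno2_inh"))
})

test_that("no deletions or no selective coverage yields no call", {
  catalog <- geneset_catalog(list(
    gene_set("eno", c("ENO1", "ENO2", "ENO3"), "KEGG")))
  tmap <- tissue_map()
  drugs <- drug_table(drug_row("eno2_inh", "ENO2"))

  quiet <- make_bundle(matrix(c(0, -1, 1), nrow = 3,
                              dimnames = list(c("ENO1", "ENO2", "ENO3"),
                                              "S1")))
  expect_equal(nrow(call_sample("S1", catalog, drugs, tmap, quiet)), 0L)

  # ENO1 deleted but partners ENO2+ENO3 both expected: ENO3 uncovered
  del <- make_bundle(matrix(c(-2, 0, 0), nrow = 3,
                            dimnames = list(c("ENO1", "ENO2", "ENO3"),
                                            "S1")))
  expect_equal(nrow(call_sample("S1", catalog, drugs, tmap, del)), 0L)
  # under the "any"-partner rule the same sample does call
  v <- call_sample("S1", catalog, drugs, tmap, del, partner_rule = "any")
  expect_equal(nrow(v), 1L)
  expect_equal(names(parse_exploit_map(v$exploit_map)), "ENO2")
})

test_that("complete loss of a set emits no vulnerability", {
  catalog <- geneset_catalog(list(gene_set("pair", c("GA", "GB"), "KEGG")))
  drugs <- drug_table(drug_row("d", "GB"))
  b <- make_bundle(matrix(c(-2, -2), nrow = 2,
                          dimnames = list(c("GA", "GB"), "S1")))
  expect_equal(nrow(call_sample("S1", catalog, drugs, tissue_map(), b)), 0L)
})

test_that("score equals the boolean sum over the full criteria truth table", {
  # all 16 requested combinations; a cancer drug is FDA-approved by
  # definition, so combos with (fda = FALSE, cancer = TRUE) collapse onto
  # fda = TRUE -- the realized flags are asserted accordingly
  for (i in c(FALSE, TRUE)) {
    for (fda in c(FALSE, TRUE)) {
      for (cancer in c(FALSE, TRUE)) {
        for (noness in c(FALSE, TRUE)) {
          sc <- make_scenario(crit_i = i, fda = fda, cancer = cancer,
                              partner_essential = !noness)
          v <- call_and_score(sc)
          expect_equal(nrow(v), 1L)
          realized_fda <- fda || cancer
          expect_equal(v$underexpressed_deletion, i)
          expect_equal(v$has_fda_drug, realized_fda)
          expect_equal(v$has_cancer_drug, cancer)
          expect_equal(v$nonessential_target, noness)
          expect_equal(v$score, sum(i, realized_fda, cancer, noness))
        }
      }
    }
  }
})

test_that("missing expression caps the score at 3", {
  sc <- make_scenario(fda = TRUE, cancer = TRUE, partner_essential = FALSE,
                      with_expr = FALSE)
  v <- call_and_score(sc)
  expect_false(v$underexpressed_deletion)  # unknown never counts as met
  expect_equal(v$score, 3L)
})

test_that("a deleted gene that is not expected in the tissue satisfies criterion one", {
  # muscle-specific gene deleted in a brain study: no expression needed
  catalog <- geneset_catalog(list(gene_set("pair", c("GA", "GB"), "KEGG")))
  drugs <- drug_table(drug_row("d", "GB"))
  tmap <- tissue_map("GA", "muscle")
  b <- make_bundle(matrix(c(-2, 0), nrow = 2,
                          dimnames = list(c("GA", "GB"), "S1")),
                   tissue = "brain")
  v <- call_sample("S1", catalog, drugs, tmap, b)
  v <- score_vulnerability(v, b, essential_map(), drugs, tmap)
  expect_true(v$underexpressed_deletion)
})

test_that("adding an FDA cancer drug on an exploited partner never lowers the score", {
  for (i in c(FALSE, TRUE)) {
    for (fda in c(FALSE, TRUE)) {
      sc <- make_scenario(crit_i = i, fda = fda, partner_essential = TRUE)
      before <- call_and_score(sc)
      sc$drugs <- drug_table(rbind(
        drug_row("sel", "GB", fda = as.integer(fda)),
        drug_row("new_cancer_drug", "GB", fda = 1L, cancer = 1L)))
      after <- call_and_score(sc)
      expect_gte(after$score, before$score)
    }
  }
})

test_that("removing a drug never creates a vulnerability", {
  sim <- generate_cohort(sim_config(seed = 31, samples_per_study = 10L,
                                    planted_vulnerability_count = 4L))
  full <- run_cohort(sim$studies, sim$catalog, sim$drugs, sim$tmap,
                     sim$emap)
  ids <- sim$drugs$drugs$drug_id
  drop <- ids[seq(1, length(ids), by = 3)]
  keep_targets <- sim$drugs$targets[setdiff(ids, drop)]
  rows <- do.call(rbind, lapply(names(keep_targets), function(d) {
    rec <- sim$drugs$drugs[sim$drugs$drugs$drug_id == d, ]
    drug_row(d, keep_targets[[d]], fda = as.integer(rec$fda_approved),
             cancer = as.integer(rec$cancer_drug))
  }))
  pruned <- drug_table(rows)
  fewer <- run_cohort(sim$studies, sim$catalog, pruned, sim$tmap,
                      sim$emap)
  key <- function(v) paste(v$study_id, v$sample_id, v$set_id)
  expect_true(all(key(fewer) %in% key(full)))
})

test_that("every called deletion is a -2 in the source matrix", {
  sim <- generate_cohort(sim_config(seed = 13, planted_vulnerability_count
                                    = 6L))
  v <- run_cohort(sim$studies, sim$catalog, sim$drugs, sim$tmap, sim$emap)
  expect_gt(nrow(v), 0L)
  bundles <- lapply(sim$studies, load_profile_bundle)
  names(bundles) <- vapply(sim$studies, `[[`, character(1), "study_id")
  for (r in seq_len(nrow(v))) {
    b <- bundles[[v$study_id[r]]]
    for (g in strsplit(v$deleted_genes[r], ";")[[1]]) {
      expect_equal(unname(b$cna[g, v$sample_id[r]]), -2)
    }
  }
})

test_that("cohort runs are deterministic and ordered", {
  sim <- generate_cohort(sim_config(seed = 21, planted_vulnerability_count
                                    = 5L))
  v1 <- run_cohort(sim$studies, sim$catalog, sim$drugs, sim$tmap,
                   sim$emap)
  v2 <- run_cohort(sim$studies, sim$catalog, sim$drugs, sim$tmap,
                   sim$emap)
  expect_identical(as.data.frame(v1), as.data.frame(v2))
  ord <- order(v1$study_id, v1$sample_id, v1$set_id)
  expect_equal(ord, seq_len(nrow(v1)))
  log <- attr(v1, "study_log")
  expect_equal(sum(log$n_vulnerabilities), nrow(v1))
})

test_that("a study pointing at missing files fails before calling", {
  st <- study_config("ghost", cna_path = "/nonexistent/cna.tsv",
                     expression_mode = "none")
  expect_error(run_cohort(list(st), geneset_catalog(list()),
                          drug_table(drug_row("d", "G")[0, ]),
                          tissue_map(), essential_map()),
               "missing input")
})
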