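# Deterministic synthetic cohorts with planted ground-truth
# vulnerabilities, plus hand-built canonical mini-cohorts.
#
# Design: gene sets are pairwise disjoint and split into "armed" sets
# (every member carries a dedicated single-target selective drug, so a
# deletion of any one member always leaves every partner coverable) and
# "unarmed" sets (no selective drug touches any member, so no deletion in
# them can ever satisfy the calling rule). Planted deletions go only into
# armed sets; background homozygous deletions go only into unarmed-set
# genes and background genes. The planted list is therefore exhaustive by
# construction.

#' Simulation configuration
#'
#' Defaults describe a small two-study cohort: one tumor study with
#' expression Z-scores and one cell-line-style study without expression and
#' without a tissue label. Z-scores are standard normal for diploid genes
#' and shifted to mean -3 (sd 0.5) for homozygously deleted genes;
#' deliberate boundary cases (Z exactly -2) are planted to pin the strict
#' underexpression cutoff.
#'
#' @param seed integer seed; all randomness flows from it.
#' @param n_studies number of studies.
#' @param samples_per_study samples in each study.
#' @param n_gene_sets number of isoenzyme gene sets.
#' @param set_size_range inclusive range of set sizes (min >= 2).
#' @param n_background_genes genes outside any set.
#' @param deletion_rate per-gene per-sample background homozygous-deletion
#'   probability (confined to unarmed-set and background genes).
#' @param planted_vulnerability_count planted true vulnerabilities.
#' @param n_background_drugs drugs targeting only background genes.
#' @param fda_prob,cancer_prob,nonessential_prob probabilities of the
#'   drug-availability / essentiality criteria profiles of armed sets.
#' @param underexpressed_prob probability that a planted deletion in an
#'   expression study is also underexpressed (criterion i).
#' @param tissue_specific_fraction fraction of armed sets (size >= 3) given
#'   one member specific to an unused tissue.
#' @param expression_modes recycled over studies:
#'   \code{"zscore"}, \code{"ccle_log2"} or \code{"none"}.
#' @return list of class \code{sim_config}.
#' @export
sim_config <- function(seed = 1L, n_studies = 2L, samples_per_study = 20L,
                       n_gene_sets = 10L, set_size_range = c(2L, 5L),
                       n_background_genes = 40L, deletion_rate = 0.02,
                       planted_vulnerability_count = 5L,
                       n_background_drugs = 15L, fda_prob = 0.5,
                       cancer_prob = 0.25, nonessential_prob = 0.6,
                       underexpressed_prob = 0.7,
                       tissue_specific_fraction = 0.3,
                       expression_modes = c("zscore", "none")) {
  cfg <- list(seed = as.integer(seed), n_studies = as.integer(n_studies),
              samples_per_study = as.integer(samples_per_study),
              n_gene_sets = as.integer(n_gene_sets),
              set_size_range = as.integer(set_size_range),
              n_background_genes = as.integer(n_background_genes),
              deletion_rate = deletion_rate,
              planted_vulnerability_count =
                as.integer(planted_vulnerability_count),
              n_background_drugs = as.integer(n_background_drugs),
              fda_prob = fda_prob, cancer_prob = cancer_prob,
              nonessential_prob = nonessential_prob,
              underexpressed_prob = underexpressed_prob,
              tissue_specific_fraction = tissue_specific_fraction,
              expression_modes = expression_modes)
  stopifnot(cfg$n_studies >= 1L, cfg$samples_per_study >= 1L,
            cfg$n_gene_sets >= 2L, cfg$set_size_range[1] >= 2L,
            cfg$set_size_range[2] >= cfg$set_size_range[1],
            cfg$deletion_rate >= 0, cfg$deletion_rate <= 1)
  n_slots <- cfg$n_studies * cfg$samples_per_study
  if (cfg$planted_vulnerability_count > n_slots) {
    stop("infeasible config: ", cfg$planted_vulnerability_count,
         " planted vulnerabilities but only ", n_slots, " samples")
  }
  structure(cfg, class = "sim_config")
}

.write_matrix_tsv <- function(mat, path, digits = NULL) {
  df <- as.data.frame(mat, check.names = FALSE)
  if (!is.null(digits)) {
    for (j in seq_along(df)) {
      df[[j]] <- ifelse(is.na(df[[j]]), NA,
                        sprintf(paste0("%.", digits, "f"), df[[j]]))
    }
  }
  df <- cbind(gene_symbol = rownames(mat), df)
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
}

# truncated draw: mean -3, sd 0.5, strictly below `upper`
.r_under <- function(n, mean, sd, upper) {
  v <- stats::rnorm(n, mean, sd)
  while (any(v >= upper)) {
    v[v >= upper] <- stats::rnorm(sum(v >= upper), mean, sd)
  }
  v
}

#' Generate a synthetic cohort with planted ground truth
#'
#' Writes the full pipeline input tree (gene-set GMT, drug TSV, tissue TSV,
#' essential TSV, per-study CNA/expression matrices, cohort YAML,
#' ground-truth TSV) under \code{out_dir}, and returns the loaded objects
#' plus the ground-truth table. Identical seeds yield byte-identical files.
#'
#' @param config a \code{\link{sim_config}}.
#' @param out_dir output directory (created).
#' @return list with \code{dir}, \code{paths}, \code{studies},
#'   \code{catalog}, \code{drugs}, \code{tmap}, \code{emap},
#'   \code{ground_truth} and \code{config}.
#' @export
generate_cohort <- function(config, out_dir = tempfile("cohort")) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)

  ## ---- gene universe -------------------------------------------------
  sizes <- sample(seq(config$set_size_range[1], config$set_size_range[2]),
                  config$n_gene_sets, replace = TRUE)
  set_ids <- sprintf("SET%03d", seq_len(config$n_gene_sets))
  set_genes <- lapply(seq_len(config$n_gene_sets), function(i) {
    sprintf("IS%03d%s", i, LETTERS[seq_len(sizes[i])])
  })
  names(set_genes) <- set_ids
  bg_genes <- sprintf("BG%04d", seq_len(config$n_background_genes))
  all_genes <- c(unlist(set_genes, use.names = FALSE), bg_genes)

  n_armed <- max(1L, config$n_gene_sets %/% 2L)
  armed <- set_ids[seq_len(n_armed)]
  unarmed <- setdiff(set_ids, armed)

  sets <- lapply(set_ids, function(sid) {
    gene_set(sid, set_genes[[sid]], source = "KEGG",
             reaction_name = paste("reaction", sid))
  })
  catalog <- geneset_catalog(sets)

  ## ---- per-armed-set criteria profiles and drugs ---------------------
  profile <- data.frame(set_id = armed, stringsAsFactors = FALSE)
  profile$cancer <- stats::runif(n_armed) < config$cancer_prob
  profile$fda <- profile$cancer | (stats::runif(n_armed) < config$fda_prob)
  profile$nonessential <- stats::runif(n_armed) < config$nonessential_prob
  # deletable member is fixed per set; never the tissue-marked member
  profile$deleted_gene <- vapply(armed, function(sid)
    set_genes[[sid]][1], character(1))

  drug_rows <- list()
  add_drug <- function(id, name, targets, fda, cancer) {
    drug_rows[[length(drug_rows) + 1L]] <<- data.frame(
      drug_id = id, drug_name = name, target_gene = targets,
      fda_approved = as.integer(fda), cancer_drug = as.integer(cancer),
      stringsAsFactors = FALSE)
  }
  for (i in seq_len(n_armed)) {
    sid <- armed[i]
    for (g in set_genes[[sid]]) {
      add_drug(sprintf("D_%s", g), sprintf("inhibitor of %s", g), g,
               profile$fda[i], profile$cancer[i])
    }
  }
  # one wide-spectrum drug making unarmed sets targetable but never
  # selectively exploitable (> 5 targets)
  if (length(unarmed)) {
    wide <- vapply(unarmed, function(sid) set_genes[[sid]][1], character(1))
    pad <- max(0L, 6L - length(wide))
    wide <- c(wide, bg_genes[seq_len(pad)])
    add_drug("D_WIDE", "broad-spectrum compound", wide, 1L, 0L)
  }
  for (k in seq_len(config$n_background_drugs)) {
    nt <- sample(1:8, 1L)
    tg <- sample(bg_genes, min(nt, length(bg_genes)))
    ca <- stats::runif(1) < config$cancer_prob
    fd <- ca || stats::runif(1) < config$fda_prob
    add_drug(sprintf("D_BG%03d", k), sprintf("compound %d", k), tg, fd, ca)
  }
  drug_df <- do.call(rbind, drug_rows)
  drugs <- drug_table(drug_df)

  ## ---- annotations ---------------------------------------------------
  tissue_pool <- c("brain", "lung", "colon", "breast", "ovary")
  t_genes <- character(0); t_tissues <- character(0)
  for (i in seq_len(n_armed)) {
    sid <- armed[i]
    if (sizes[match(sid, set_ids)] >= 3L &&
        stats::runif(1) < config$tissue_specific_fraction) {
      marked <- set_genes[[sid]][2]  # never the deletable member
      t_genes <- c(t_genes, marked)
      t_tissues <- c(t_tissues, "muscle")  # unused by any study
    }
  }
  n_ts_bg <- max(1L, length(bg_genes) %/% 10L)
  t_genes <- c(t_genes, bg_genes[seq_len(n_ts_bg)])
  t_tissues <- c(t_tissues, sample(tissue_pool, n_ts_bg, replace = TRUE))
  tmap <- tissue_map(t_genes, t_tissues)

  organisms <- c("H. sapiens", "M. musculus", "S. cerevisiae",
                 "C. elegans", "D. melanogaster")
  e_genes <- character(0); e_org <- character(0)
  for (i in seq_len(n_armed)) {
    if (!profile$nonessential[i]) {
      gg <- set_genes[[armed[i]]]
      e_genes <- c(e_genes, gg)
      e_org <- c(e_org, sample(organisms, length(gg), replace = TRUE))
    }
  }
  n_e_bg <- max(1L, length(bg_genes) %/% 8L)
  e_genes <- c(e_genes, bg_genes[seq_len(n_e_bg)])
  e_org <- c(e_org, sample(organisms, n_e_bg, replace = TRUE))
  emap <- essential_map(e_genes, e_org)

  ## ---- studies and planted slots -------------------------------------
  modes <- rep_len(config$expression_modes, config$n_studies)
  study_ids <- sprintf("study%02d", seq_len(config$n_studies))
  sample_ids <- lapply(seq_len(config$n_studies), function(s)
    sprintf("%s_S%03d", study_ids[s], seq_len(config$samples_per_study)))
  classes <- rep("tumor", config$n_studies)
  if (config$n_studies >= 2L) classes[config$n_studies] <- "cell_line"
  tissues <- rep_len(tissue_pool, config$n_studies)
  tissues[classes == "cell_line"] <- NA_character_

  slots <- expand.grid(study = seq_len(config$n_studies),
                       sample = seq_len(config$samples_per_study))
  picked <- slots[sample(nrow(slots), config$planted_vulnerability_count), ,
                  drop = FALSE]
  plant <- data.frame(
    study_id = study_ids[picked$study],
    sample_id = vapply(seq_len(nrow(picked)), function(r)
      sample_ids[[picked$study[r]]][picked$sample[r]], character(1)),
    set_id = if (nrow(picked)) sample(armed, nrow(picked), replace = TRUE)
             else character(0),
    stringsAsFactors = FALSE)
  plant$deleted_gene <- profile$deleted_gene[match(plant$set_id,
                                                   profile$set_id)]
  plant$mode <- modes[match(plant$study_id, study_ids)]
  plant$underexpressed_deletion <- ifelse(
    plant$mode == "none", FALSE,
    stats::runif(nrow(plant)) < config$underexpressed_prob)
  plant$has_fda_drug <- profile$fda[match(plant$set_id, profile$set_id)]
  plant$has_cancer_drug <- profile$cancer[match(plant$set_id,
                                                profile$set_id)]
  plant$nonessential_target <- profile$nonessential[match(plant$set_id,
                                                          profile$set_id)]
  plant$expected_score <- with(plant, underexpressed_deletion +
                                 has_fda_drug + has_cancer_drug +
                                 nonessential_target)

  ## ---- matrices ------------------------------------------------------
  armed_genes <- unlist(set_genes[armed], use.names = FALSE)
  deletable <- setdiff(all_genes, armed_genes)
  studies <- vector("list", config$n_studies)
  paths <- list(sets = file.path(out_dir, "sets.gmt"),
                drugs = file.path(out_dir, "drugs.tsv"),
                tissue = file.path(out_dir, "tissue.tsv"),
                essential = file.path(out_dir, "essential.tsv"),
                ground_truth = file.path(out_dir, "ground_truth.tsv"),
                config = file.path(out_dir, "cohort.yaml"))
  for (s in seq_len(config$n_studies)) {
    sid <- study_ids[s]
    samples <- sample_ids[[s]]
    n <- length(samples)
    cna <- matrix(sample(c(-1L, 0L, 1L, 2L), length(all_genes) * n,
                         replace = TRUE,
                         prob = c(0.05, 0.85, 0.07, 0.03)),
                  nrow = length(all_genes),
                  dimnames = list(all_genes, samples))
    # background homozygous deletions only where they cannot create calls
    bgdel <- matrix(stats::runif(length(deletable) * n) <
                      config$deletion_rate,
                    nrow = length(deletable))
    sub <- cna[deletable, , drop = FALSE]
    sub[bgdel] <- -2L
    cna[deletable, ] <- sub
    # planted deletions
    pl <- plant[plant$study_id == sid, , drop = FALSE]
    for (r in seq_len(nrow(pl))) {
      cna[pl$deleted_gene[r], pl$sample_id[r]] <- -2L
    }
    cna_path <- file.path(out_dir, sprintf("cna_%s.tsv", sid))
    .write_matrix_tsv(cna, cna_path)

    expr_path <- NA_character_
    if (modes[s] != "none") {
      if (modes[s] == "zscore") {
        expr <- matrix(stats::rnorm(length(all_genes) * n),
                       nrow = length(all_genes),
                       dimnames = list(all_genes, samples))
        hd <- cna == -2L
        expr[hd] <- .r_under(sum(hd), -3, 0.5, -2)
        boundary <- -2
      } else {
        expr <- matrix(stats::rnorm(length(all_genes) * n, 7, 1.5),
                       nrow = length(all_genes),
                       dimnames = list(all_genes, samples))
        hd <- cna == -2L
        expr[hd] <- .r_under(sum(hd), 4, 0.5, 5)
        boundary <- 5
      }
      # planted not-underexpressed cases sit exactly on the boundary,
      # pinning the strict-inequality contract
      for (r in which(!pl$underexpressed_deletion)) {
        expr[pl$deleted_gene[r], pl$sample_id[r]] <- boundary
      }
      expr_path <- file.path(out_dir, sprintf("expr_%s.tsv", sid))
      .write_matrix_tsv(expr, expr_path, digits = 6)
    }
    studies[[s]] <- study_config(sid, tissue = tissues[s],
                                 sample_class = classes[s],
                                 expression_mode = modes[s],
                                 cna_path = cna_path,
                                 expr_path = expr_path)
  }

  ## ---- files ---------------------------------------------------------
  write_gmt(catalog, paths$sets)
  utils::write.table(drug_df, paths$drugs, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  utils::write.table(
    data.frame(gene_symbol = t_genes, tissue = t_tissues),
    paths$tissue, sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(
    data.frame(gene_symbol = e_genes, organism = e_org),
    paths$essential, sep = "\t", quote = FALSE, row.names = FALSE)
  gt <- plant[order(plant$study_id, plant$sample_id, plant$set_id),
              c("study_id", "sample_id", "set_id", "deleted_gene",
                "underexpressed_deletion", "has_fda_drug",
                "has_cancer_drug", "nonessential_target",
                "expected_score")]
  rownames(gt) <- NULL
  utils::write.table(gt, paths$ground_truth, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  write_cohort_yaml(studies, paths, out_dir)

  list(dir = out_dir, paths = paths, studies = studies, catalog = catalog,
       drugs = drugs, tmap = tmap, emap = emap, ground_truth = gt,
       config = config)
}

# cohort config YAML referencing the generated inputs (relative paths)
write_cohort_yaml <- function(studies, paths, out_dir) {
  rel <- function(p) if (is.na(p)) NULL else basename(p)
  cfg <- list(
    genesets = rel(paths$sets), drugs = rel(paths$drugs),
    tissue = rel(paths$tissue), essential = rel(paths$essential),
    partner_rule = "all",
    studies = lapply(studies, function(st) {
      x <- list(study_id = st$study_id,
                sample_class = st$sample_class,
                expression_mode = st$expression_mode,
                cna = rel(st$cna_path))
      if (!is.na(st$tissue)) x$tissue <- st$tissue
      if (!is.na(st$expr_path)) x$expr <- rel(st$expr_path)
      x
    }))
  yaml::write_yaml(cfg, paths$config)
  invisible(paths$config)
}

#' Canonical hand-built mini-cohorts
#'
#' Three textbook cases wired as tiny studies:
#' \describe{
#'   \item{enolase}{a brain-tissue sample with ENO1 homozygously deleted;
#'     ENO3 is muscle-specific so the only partner that must (and can) be
#'     drugged is ENO2.}
#'   \item{DHFR}{a sample with DHFR deleted; methotrexate targets both
#'     DHFR and DHFRL1, so it is suggested but is not a selective exploit
#'     (it covers every member); a DHFRL1-only inhibitor makes the call.}
#'   \item{TOP2}{two samples with reciprocal TOP2A / TOP2B deletions, each
#'     exploitable through the intact paralog.}
#' }
#'
#' @param dir directory where the fixture files are written.
#' @return list with \code{studies}, \code{catalog}, \code{drugs},
#'   \code{tmap}, \code{emap} and \code{dir}.
#' @export
canonical_fixtures <- function(dir = tempfile("canonical")) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  catalog <- geneset_catalog(list(
    gene_set("ENOLASE", c("ENO1", "ENO2", "ENO3"), source = "KEGG",
             reaction_name = "Phosphopyruvate hydratase"),
    gene_set("DHFR_SET", c("DHFR", "DHFRL1"), source = "KEGG",
             reaction_name = "Dihydrofolate reductase"),
    gene_set("TOP2_SET", c("TOP2A", "TOP2B"), source = "REACTOME",
             reaction_name = "DNA topoisomerase (ATP-hydrolysing)")))
  drug_df <- data.frame(
    drug_id = c("eno2_inh", "methotrexate", "methotrexate", "dhfrl1_inh",
                "top2a_inh", "top2b_inh"),
    drug_name = c("phosphoglycolate analog", "Methotrexate",
                  "Methotrexate", "DHFRL1 inhibitor", "TOP2A poison",
                  "TOP2B poison"),
    target_gene = c("ENO2", "DHFR", "DHFRL1", "DHFRL1", "TOP2A", "TOP2B"),
    fda_approved = c(0L, 1L, 1L, 0L, 1L, 1L),
    cancer_drug = c(0L, 1L, 1L, 0L, 1L, 1L),
    stringsAsFactors = FALSE)
  drugs <- drug_table(drug_df)
  tmap <- tissue_map("ENO3", "muscle")
  emap <- essential_map(character(0), character(0))

  write_study <- function(study_id, genes, samples, cna, expr, tissue) {
    cna_path <- file.path(dir, sprintf("cna_%s.tsv", study_id))
    dimnames(cna) <- list(genes, samples)
    .write_matrix_tsv(cna, cna_path)
    expr_path <- file.path(dir, sprintf("expr_%s.tsv", study_id))
    dimnames(expr) <- list(genes, samples)
    .write_matrix_tsv(expr, expr_path, digits = 2)
    study_config(study_id, tissue = tissue, sample_class = "tumor",
                 expression_mode = "zscore", cna_path = cna_path,
                 expr_path = expr_path)
  }
  eno <- write_study(
    "gbm", c("ENO1", "ENO2", "ENO3"), c("G1", "G2"),
    matrix(c(-2L, 0L, 0L, 0L, 0L, 0L), nrow = 3),
    matrix(c(-3.1, 0.2, 0.1, 0.4, -0.3, 0.5), nrow = 3),
    tissue = "brain")
  dhfr <- write_study(
    "folate", c("DHFR", "DHFRL1"), c("F1", "F2"),
    matrix(c(-2L, 0L, 0L, 0L), nrow = 2),
    matrix(c(-2.8, 0.1, 0.3, -0.2), nrow = 2),
    tissue = "colon")
  top2 <- write_study(
    "topo", c("TOP2A", "TOP2B"), c("T1", "T2"),
    matrix(c(0L, -2L, -2L, 0L), nrow = 2),
    matrix(c(0.2, -3.4, -2.9, 0.1), nrow = 2),
    tissue = "lung")
  studies <- list(eno, dhfr, top2)
  paths <- list(sets = file.path(dir, "sets.gmt"),
                drugs = file.path(dir, "drugs.tsv"),
                tissue = file.path(dir, "tissue.tsv"),
                essential = file.path(dir, "essential.tsv"),
                config = file.path(dir, "cohort.yaml"))
  write_gmt(catalog, paths$sets)
  utils::write.table(drug_df, paths$drugs, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  utils::write.table(data.frame(gene_symbol = "ENO3", tissue = "muscle"),
                     paths$tissue, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  utils::write.table(
    data.frame(gene_symbol = character(0), organism = character(0)),
    paths$essential, sep = "\t", quote = FALSE, row.names = FALSE)
  write_cohort_yaml(studies, paths, dir)
  list(studies = studies, catalog = catalog, drugs = drugs,
       tmap = tmap, emap = emap, dir = dir, paths = paths)
}
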