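# isovuln

Sample-specific collateral-lethality vulnerabilities from cancer
copy-number profiles.

## The problem

Tumor genomes carry many homozygous deletions that are passengers rather
than drivers: a locus is lost alongside an oncogenic event and the cell
survives because a partner gene carries the load. When the deleted gene is
one of several **isoenzymes** — distinct genes whose products catalyze the
same biochemical reaction — the tumor becomes fully dependent on the
remaining partners, while normal cells are not. Inhibiting an intact
partner is then selectively lethal to the deleted cells (synthetic /
collateral lethality). The textbook case is enolase in glioblastoma: ENO1
is homozygously deleted as a passenger, and the tumor cells become
uniquely sensitive to loss of ENO2, while ENO3 is irrelevant in brain
because its expression is muscle-specific.

`isovuln` is for computational oncologists who want to screen cohorts of
copy-number-profiled samples (tumors or cell lines) for such
vulnerabilities and rank them by how actionable they are.

## The method

For each sample *s*, study tissue *t* and isoenzyme gene set
*G = {g₁, …, gₖ}* (k ≤ 5):

- **Deleted members** D = { g ∈ G : CNA(g, s) = −2 } (discrete GISTIC/RAE
  category −2 = homozygous deletion; −1, heterozygous loss, never counts).
- **Partners** P = intact members of G expected to be expressed in tissue
  *t* (tissue-specific genes annotated to other tissues are excluded;
  unknown tissue excludes nothing).
- A drug *d* is a **selective exploit** of partner *p* when it has ≤ 5
  known targets, targets *p*, and does **not** cover all of *G* — a drug
  hitting every member of the set (methotrexate on the DHFR/DHFRL1 pair)
  would also poison normal cells and is only listed as "suggested".
- A **vulnerability** is called when D ≠ ∅, P ≠ ∅ and every partner in P
  has at least one selective exploit drug (a config switch relaxes this to
  "at least one partner").

Each call gets a 0–4 **score**, one point per criterion:

1. every deleted gene is underexpressed (expression Z < −2, or
   median-normalized log2 probe level < 5 in CCLE-style data; strict
   inequalities) or not expected to be expressed in the study tissue;
2. some suggested drug is FDA-approved;
3. some suggested drug is a cancer drug (FDA-approved and used in cancer
   therapy);
4. some selective exploit drug hits only non-essential partners
   (essentiality = the gene or its model-organism homologue is essential).

Cohort-level reports aggregate distinct deletion events (keyed on
gene set × deleted gene), tumor-to-cell-line matching rates, score
distributions and druggability fractions.

Gene-set catalogs are built from BioPAX Level 3 pathway exports
(reaction → catalysis → controller → HGNC xref), EC-number tables and GMT
files, merged with source priority KEGG > Reactome > HumanCyc and
filtered to ≤ 5 genes with ≥ 1 drug-targetable member.

## Worked example

The package ships hand-built mini-cohorts for the three canonical cases
(enolase, DHFR/methotrexate, TOP2A/TOP2B):

```r
library(isovuln)
fx <- canonical_fixtures()
v <- run_cohort(fx$studies, fx$catalog, fx$drugs, fx$tmap, fx$emap)
print(v)
#> vuln_set: 4 vulnerabilities in 4 samples across 3 studies
#>   scores:  0=0, 1=0, 2=1, 3=0, 4=3
#>   study_id sample_id   set_id deleted_genes expected_expressed_partners score
#> 1   folate        F1 DHFR_SET          DHFR                      DHFRL1     4
#> 2      gbm        G1  ENOLASE          ENO1                        ENO2     2
#> 3     topo        T1 TOP2_SET         TOP2B                       TOP2A     4
#> 4     topo        T2 TOP2_SET         TOP2A                       TOP2B     4

summarize_cohort(v)
#> cohort_summary
#>   vulnerabilities: 4 (4 tumor samples, 0 cell lines)
#>   distinct deletion events: 4 (4 in tumors; 0% with cell-line match)
#>   score histogram: 0=0, 1=0, 2=1, 3=0, 4=3
#>   with FDA drug: 75%; with cancer drug: 75%; targeting an essential gene: 0%
```

Reading the output: in the brain-tissue `gbm` study, ENO1 is deleted and
the only partner that must be drugged is ENO2 (ENO3 is muscle-specific);
the score is 2 because the ENO2 inhibitor in the fixture is not
FDA-approved. In the `folate` study, methotrexate appears among the
suggested drugs for the DHFR deletion but is not a selective exploit — it
targets both members of the pair. The two `topo` samples carry reciprocal
TOP2A/TOP2B deletions, each exploitable through the intact paralog.

The same pipeline runs from the shell:

```sh
inst/cli/isovuln simulate --seed 7 --planted 5 --out cohort/
inst/cli/isovuln run --config cohort/cohort.yaml --out cohort/vulns.tsv
inst/cli/isovuln summarize --vulns cohort/vulns.tsv --out cohort/reports
```

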