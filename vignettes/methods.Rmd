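---
title: "Calling collateral-lethality vulnerabilities: model, parameters and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Calling collateral-lethality vulnerabilities: model, parameters and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(isovuln)
```

## The model

`isovuln` predicts per-sample therapeutic vulnerabilities created by
homozygous passenger deletions of metabolic isoenzymes. The underlying
biological assumption is deliberately simple: genes catalyzing the same
biochemical reaction form a synthetic-lethal group, because the reaction
itself is taken to be required for viability. If a sample has lost one
member of such a group to homozygous deletion, the remaining members carry
the full load, and a drug that selectively inhibits an intact member
should kill the deleted cells while sparing normal cells (which still
have the deleted isoenzyme).

The calling rule, per sample × gene set, is:

1. **Deletion.** At least one member has discrete copy-number category −2.
   Only −2 counts; heterozygous loss (−1) leaves one functional allele and
   is never treated as loss of function. A gene absent from the
   copy-number matrix, or an `NA` cell, is *not deleted* — absence of
   evidence never makes a call.
2. **Intact partners.** At least one member is not deleted, and among the
   intact members at least one is *expected to be expressed* in the study
   tissue. Tissue-specific genes (from a tissue-annotation table) are
   excluded as partners in studies of other tissues; genes not in the
   table are treated as ubiquitous. When a study has no tissue annotation,
   no partner is excluded — wrongly assuming non-expression would silently
   destroy true calls, whereas the cost of keeping a partner is only an
   extra drug requirement.
3. **Selective coverage.** Every expected-expressed partner must have at
   least one *selective exploit* drug: ≤ 5 unique known targets, targeting
   the partner, and not covering every member of the set. The
   all-members exclusion encodes why methotrexate is not a selective
   exploit for a DHFR-deleted sample — it inhibits both DHFR and DHFRL1,
   so normal cells would lose the whole reaction too.

Once a vulnerability is called, the reported drug list widens to *all*
drugs targeting any expected-expressed partner, selective or not; the
selective subset remains separately visible in the exploit map.

### The partner rule

The requirement that *every* expected-expressed partner be coverable is
one of two defensible readings of "the other expressed isoenzymes can be
selectively targeted by at least one drug". We default to the
all-partners reading because killing the cell requires removing the whole
residual activity: if one expressed partner has no drug, the intervention
cannot work even when another partner is drugged. The `partner_rule =
"any"` switch in `call_sample()`/`run_cohort()` gives the permissive
reading for sensitivity analyses. A per-call flag
(`single_drug_covers_all`) additionally records whether one selective
drug covers all partners at once.

### The score

Each call is scored 0–4, one point per criterion: (i) every deleted gene
is underexpressed or tissue-excluded, (ii) a suggested drug is
FDA-approved, (iii) a suggested drug is a cancer drug, (iv) some
selective exploit drug hits only non-essential partners. Three
interpretation choices deserve note:

- **Multiple deleted genes.** Criterion (i) requires *all* deleted genes
  to be underexpressed. The singular phrasing of the criterion does not
  cover multi-deletion calls; we chose the conservative conjunction, since
  one well-supported deletion does not validate a second, unsupported one.
- **Unknown expression.** When a study carries no expression data, or the
  deleted gene is missing from the matrix, criterion (i) is *unmet*, not
  undefined — so such calls cap at score 3. Unknown never counts as
  evidence.
- **Criterion (iv) with multi-target drugs.** A drug satisfies (iv) when
  all of the expected-expressed partners it targets are non-essential;
  the criterion holds if at least one exploit drug qualifies. The
  alternative (any non-essential target anywhere) would let an irrelevant
  bystander target rescue an essential-partner drug.

A cancer drug is by definition FDA-approved; the drug-catalog loader
enforces this (coercing the FDA flag with a warning), so criterion (iii)
never holds without (ii).

## Thresholds and tunable parameters

| parameter | default | units | rationale |
|---|---|---|---|
| `homdel_code` | −2 | CNA category | discrete GISTIC/RAE convention for homozygous deletion |
| `zscore_cutoff` | −2 | expression Z-score | standard two-SD underexpression call; **strict** `<` |
| `ccle_log2_cutoff` | 5 | log2 probe level | upper limit of the lower quartile of pooled CCLE-style expression; **strict** `<` |
| `max_set_size` | 5 | genes | larger sets rarely add exploitable calls and dilute the synthetic-lethality assumption |
| `max_drug_targets` | 5 | unique target genes | drugs with more targets are considered non-specific |

All comparisons against the expression cutoffs are strict: a Z-score of
exactly −2.0 or a log2 level of exactly 5.0 is *not* underexpressed. The
boundary convention follows the `<` wording of the cutoff definitions,
and the synthetic-data generator plants exact-boundary values so the test
suite pins it. `lower_quartile_upper_limit()` recomputes a data-driven
log2 cutoff as the 25th percentile of pooled values, using the linear
interpolation convention of `stats::quantile` type 7 (stated here because
quartile conventions differ across software).

Set-size and target-count boundaries are inclusive: a 5-gene set passes
the size filter, a 5-target drug is selective.

## Gene-set catalog construction

BioPAX Level 3 extraction walks `BiochemicalReaction` →
`Catalysis`/`Control` → controller → HGNC xref. Only six classes are
interpreted (`BiochemicalReaction`, `Catalysis`, `Control`, `Protein`,
`ProteinReference`, `Complex`, plus xref leaves); everything else in a
document is ignored silently, because the extraction rule touches nothing
else. `Complex` controllers contribute all member-protein symbols.
Restricting a resource to a sub-pathway (e.g. only the metabolism branch
of a pathway database) is the caller's responsibility via input
selection, not a parser flag. Symbols are uppercased and
whitespace-stripped; no alias resolution is attempted, since pathway
exports normalized to HGNC xrefs make it unnecessary and silent alias
mapping can merge distinct genes.

Catalogs merge by *unordered gene composition*: two sets with the same
genes collapse to one, the survivor (including its reaction metadata)
taken from the highest-priority source — KEGG, then Reactome, then
HumanCyc. Overlapping-but-unequal sets are all kept as distinct
hypotheses; collapsing them by reaction identity would require a reaction
ontology we do not have. Merging is idempotent.

## What the synthetic generator emulates — and what it does not

`generate_cohort()` produces a full input tree (GMT, drug/tissue/essential
TSVs, per-study CNA and expression matrices, cohort YAML) with planted
ground truth. Its defaults describe a small cohort: 2 studies × 20
samples, 10 disjoint gene sets of 2–5 genes, 40 background genes, a 2%
per-gene background homozygous-deletion rate, one tumor study with
Z-score expression and one cell-line study without expression or tissue
annotation (mirroring a cell-line panel's missing tissue label).
Expression is standard normal for diploid genes and shifted to mean −3
(sd 0.5, truncated below the cutoff) for deleted genes; planted
"not-underexpressed" cases sit exactly on the cutoff boundary.

Exhaustiveness of the ground truth is a construction guarantee: gene sets
are pairwise disjoint and split into *armed* sets (every member has a
dedicated single-target selective drug; deleted only at planted
positions) and *unarmed* sets (no selective drug touches any member, so
no deletion in them can ever complete the calling rule; a shared
6-target drug keeps them targetable but unexploitable). Background
deletions are confined to unarmed-set and background genes. The test
suite independently cross-checks this with a brute-force enumerator
written directly against the raw files.

The generator does **not** emulate: genomic coordinates or segment-level
deletion structure (deletions are independent per gene, whereas real
passenger deletions are spatially correlated with driver loci),
expression correlation beyond the deletion shift, overlapping gene sets,
noisy or conflicting drug annotations, or miscalled CNAs. Passing the
recovery tests therefore shows the *logic* is exact, not that the method
is robust to real-data noise — on real cohorts, false-positive deletion
calls propagate directly into false-positive vulnerability calls, which
is exactly why criterion (i) exists.

All randomness flows from the single `seed`; file formats use fixed
number formatting, so identical seeds give byte-identical trees.

## Cohort aggregation choices

Distinct deletion events are keyed on (gene set, deleted gene): the same
gene deleted in two different sets is two events, matching the
one-gene-per-row layout used when reporting recurrent vulnerabilities.
A `key = "gene"` alternative exists for sensitivity analysis. The
tumor-to-cell-line match rate is computed among events observed in at
least one tumor sample: the fraction also observed in some cell line; it
is `NA` (reported as missing) when no tumor events exist. The
"targeting essential" fraction counts vulnerabilities where *every*
exploit option hits at least one essential partner — the complement of
criterion (iv).

Output ordering is lexicographic in (study, sample, set) throughout, and
reports round-trip: re-reading a written vulnerabilities TSV reproduces
the summary exactly.

## Degenerate inputs and numerical corner cases

- Sets whose members are *all* deleted emit nothing — there is no partner
  left to drug.
- Empty catalogs, empty cohorts and studies without expression all
  produce well-defined empty/NA results rather than errors.
- Duplicate gene rows in a matrix keep the first occurrence with a
  warning; conflicting drug flags OR together with a warning.
- CNA matrices are validated to the −2..2 category alphabet at load.

## Verification scale

The test suite checks engine-vs-enumerator agreement on 50 seeded
synthetic cohorts (8–16 samples per study, 6–9 sets) and exact
planted-recovery on 20 cohorts with 5–50 planted vulnerabilities each;
`scripts/acceptance.R` re-runs the same measurements at slightly reduced
counts plus a 4-study × 50-sample summary cohort. These sizes were chosen
to exercise every code path (both partner rules, all score combinations,
boundary expression values, tissue-filtered partners, cell-line studies)
while keeping a full run in well under a minute; agreement is exact, so
larger cohorts add replication rather than power.

## Known limitations

- Loss of function is read from homozygous deletion only; mutations,
  methylation and fusions are out of scope.
- The synthetic-lethal-group assumption treats every catalyzed reaction
  as essential; groups around dispensable reactions yield plausible-looking
  but unfounded calls.
- Drug-target catalogs are taken at face value; potency, direction of
  effect and pharmacokinetics are not modeled.
- Tissue filtering is binary and list-based; per-sample expression of the
  partner is not consulted when deciding expected expression.
- Homolog-based essentiality is consumed pre-mapped; no homology mapping
  is performed here.
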