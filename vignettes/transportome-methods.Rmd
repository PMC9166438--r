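---
title: "Methods: transportome profiling from bulk RNA-seq"
author: "transportome package"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: transportome profiling from bulk RNA-seq}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(transportome)
```

# Scope and model

The package reconstructs a transcriptome-to-transportome analysis for a
secretory epithelium such as the choroid plexus: from gene-level
abundance tables to ranked transport-protein discovery tables,
cross-sample overlap statistics, solute-carrier (SLC) supercategory
summaries, and bipartite transporter–regulator association networks.
Everything downstream of quantification is in scope; read QC, alignment
and RSEM/STAR themselves are not — the package consumes their tabular
outputs, but implements TPM normalization from counts so restricted
universes can be re-normalized:

$$\mathrm{TPM}_i = 10^6 \cdot \frac{c_i/\ell_i}{\sum_j c_j/\ell_j}$$

with expected counts $c$ and effective lengths $\ell$ (bases). The output
sums to $10^6$ by construction (asserted to a relative tolerance of
$10^{-9}$); all-zero counts or non-positive lengths are rejected as
degenerate/domain errors rather than silently propagated.

## Assumptions

- **Gene identity** is the stable `gene_id` (e.g. an Ensembl accession);
  symbols and aliases are matching/display metadata. Symbol resolution
  tries symbol, then pipe-separated aliases, case-insensitively, and
  reports unresolved symbols instead of inventing genes.
- **Presence/absence, not quantitative cross-sample comparison**: overlap
  statistics say whether a gene is transcribed on each side, never that
  its level is comparable across species or tissues.
- Annotation (biotypes, seqnames, GO terms, family/group/EC memberships)
  comes from user-supplied files and is taken as-is; no live database
  queries, no alias re-curation.

# Tunable parameters

| Parameter | Default | Units | Rationale |
|---|---|---|---|
| expression cutoff | 0.5 | TPM | study-wide presence threshold; genes **at** the cutoff are kept (the literal reading of excluding genes *below* it) |
| transporter score interval | [0.6, 1] | STRING combined score | closed at both ends — "0.6–1" read inclusively |
| channel score interval | [0.7, 1] | STRING combined score | as above |
| transporter node bins | (10, 200) | TPM | boundary values go to the outer bins ("≤ 10", "≥ 200") |
| channel node bins | (10, 50) | TPM | as above |
| evidence channels | experiments, databases | — | an edge needs **any** required channel > 0, matching "curated in a database **or** demonstrated experimentally" |
| discovery table length | 20 | genes | the printed-table convention |

All of these are `runConfig()` fields; the defaults are the study
conditions.

# Category construction

Each of the eight categories (transporters/pumps, water and ion
channels, GPCRs, RTKs, kinases, phosphatases, PDEs, cyclases) is a
declarative `CategoryRule`: source lists → family-prefix exclusions →
GO filters → optional plasma-membrane filter → manual exclusions →
symbol resolution, with per-member provenance. Decisions where the
procedure was genuinely open:

- **Plasma-membrane filter boolean structure.** The rule sentence admits
  two parses; it is implemented as
  $(A \lor B) \land (C \lor D) \land \lnot E$ — both positive conjuncts
  required, any exclusion term fatal. The alternative reading (second
  conjunct applying to only one branch) is noted here and not
  implemented.
- **Exact GO label matching**, case-insensitive, never substring:
  substring matching would conflate `plasma membrane` with
  `integral component of plasma membrane`. A consequence worth knowing:
  single-word exclusion labels such as `endoplasmic` only match a
  stand-alone label, not `endoplasmic reticulum`; an optional GO-ID →
  label equivalence table (`go_aliases`) lets users normalise their
  annotation before matching.
- **SLC25/ATP5/ATP6V prefix exclusion runs first** ("initially"), before
  GO filtering.
- **PDE selection** is the symbol regex `^PDE` followed by a digit, so
  PDZ-domain genes and PDE-like non-family symbols are not admitted even
  though the loose instruction is "starting with PDE".
- **EC selectors include sub-categories** by dotted-prefix matching:
  `EC 2.7.11` admits `EC 2.7.11.x` but not `EC 2.7.112` or `EC 2.7.1.1`.
- **Kinases "involved solely with transcription or cell cycle" are a
  configuration list** (`kinase_exclusions`, default empty): the
  exclusion names no gene list, so it is data, not code.

# Overlap statistics

A left gene is shared when its symbol (uppercased) equals a right-side
symbol or an ortholog pair bridges it to one; matching is per side, each
gene counted once, so many-to-many orthology cannot double-count. The
Venn-center percentage is reported from each side's perspective
separately. "Total transcripts" denominators are TPM sums over the
**cutoff-filtered** table of the relevant side — the cutoff is applied
before any overlap denominator. The annotation fraction over non-shared
genes is computed for a designated side (both can be requested); both
TPM shares are always computed. Display rounding is half-away-from-zero,
whole percents for figure-style output and one decimal for text-style
output, while the `OverlapResult` object keeps full precision.
An empty side (e.g. after restriction to a category) yields an explicit
degenerate marker with `NA` percentages, never a silent 0/0.

# SLC supercategories

Families are parsed from symbols (`SLC<k>...` → `SLC<k>`; `SLCO...` →
the organic-anion family `SLCO`, the Bioparadigms name for historic
SLC21). The family → supercategory grouping is **shipped as
configuration** (`inst/extdata/slc_supercategories.tsv`), a
reconstructed 11-supercategory assignment by transported substrate;
users can replace it, and families without an entry land in an explicit
`ungrouped` bucket with a warning. A family counts as detected when at
least one member gene is at or above the cutoff. Bubble-layout areas are
proportional to accumulated TPM and normalized to sum to 1 (radius
$\sqrt{a/\pi}$).

# Association networks

Edge tables are STRING `protein.links.detailed`-style; scores on the
0–1000 scale are divided by 1000, self-edges dropped, duplicate
undirected edges collapsed keeping the maximum combined score (that
row's channel scores travel with it). Construction applies three
independent filters — evidence, closed score interval, bipartiteness
(exactly one endpoint in the target set, one in the regulator union) —
and prunes isolated nodes; tests verify equality with a brute-force
enumeration of the three rules on random graphs. Two documented edge
cases:

- Genes in both a target and a regulator set are treated as targets (with
  a warning); edges between two such genes then fall under the
  target–target rule.
- The strict bipartite reading discards target–target pairs, yet
  published renderings of such networks sometimes show cotransporter
  clusters; an opt-in `keep_target_target` flag retains them, off by
  default.

Regulator nodes carry the first matching category in the fixed
precedence GPCR > RTK > kinase > phosphatase > PDE > cyclase — an
arbitrary but stable choice affecting only node metadata. GraphML export
is lossless (round-trip asserted); SIF/TSV exports carry a sidecar node
attribute table.

# Discovery tables

Ranking is TPM-descending with ties broken by ascending symbol (the
sources never specify tie handling; an alphabetical rule keeps reruns
diffable). Cross-ranks are computed against the other sample's **full**
category ranking, not its printed truncation — required for genes that
sit in the other sample's tail — and are `NA` when the gene is below the
cutoff there, mirroring the "N/A" convention of printed tables.
`topNContainment()` summarises the first *n* rows: the maximum
cross-rank among the genes present, and the count absent. Printed tables
round-trip through a TSV layout (`Gene`, `Alias`, `TPM`, `Rank`,
`<Label>_rank`) and are shipped as fixtures.

# Synthetic data: what it emulates, what it does not

The generator plants ground truth that downstream stages must recover
**exactly**:

- Gene universes are partitioned explicitly (shared block, ortholog-only
  bridges, side-only blocks, sub-threshold decoys), so the planted
  shared fraction is constructed, not sampled; the default 89% at
  13,500 left-side genes mirrors a rat-vs-human protein-coding
  comparison, and the log-normal TPM (meanlog 1, sdlog 2) reproduces the
  heavy-tailed 0.5–~2400 TPM range of real tissue tables. Expressed
  TPMs are floored at the cutoff and renormalized so every table sums to
  $10^6$; emitted `expected_count`/`effective_length` columns are
  consistent with the TPMs.
- Annotation sources are built so the eight rules recover the planted
  memberships, with decoys exercising every exclusion branch (SLC25/
  ATP5/ATP6V prefixes, plasma-membrane near-misses, organelle terms, a
  `PDEX1` symbol, EC and GO near-miss kinases/phosphatases).
- The edge table plants bipartite edges inside the score interval with
  valid evidence, plus distractors violating exactly one rule each, a
  self-edge and reversed lower-score duplicates.

It does **not** emulate: read-level artifacts, count overdispersion or
replicate noise, annotation incompleteness (real GO vocabularies are
messier than the exact-label world the filter assumes), many-to-many
orthology tangles, or quantitative cross-species effects. Passing the
recovery tests therefore demonstrates correctness of the pipeline's set
logic and arithmetic on well-posed inputs, not robustness to noisy
annotation.

Test and acceptance runs use scaled problem sizes chosen for exactness
rather than realism where speed matters: 1,000/950-gene samples for the
recovery suite, the full 13,500/13,000-gene defaults in the acceptance
script, 200-node random graphs for the network oracle.

# Numerical and degenerate-input choices

- Strict numeric parsing (no locale decimal commas); malformed cells are
  errors naming the column and row, never zeros.
- Duplicate `gene_id`s are integrity errors; duplicate undirected edges
  are collapsed by rule.
- Cutoff idempotence and monotonicity are asserted as properties.
- Sub-interval checks: score intervals must be closed sub-intervals of
  [0, 1]; bin edges strictly increasing; violations are config errors
  before any work happens.
- The pipeline validates its whole configuration before any I/O, labels
  every stage failure with the stage name, writes outputs only under its
  output directory, and logs in/out gene counts per filter.

# Known limitations

- Exact-label GO matching (see above) under-excludes against compound
  organelle labels unless a `go_aliases` table normalises them.
- The shipped SLC grouping is a reconstruction; analyses of real data
  should substitute the grouping actually used for that data set.
- Cross-species overlap depends entirely on the supplied ortholog map;
  genes absent from it count as non-shared, so sharing percentages are
  lower bounds.
- Reproducing published full-data percentages requires the original
  expression matrices (GEO series GSE194236, GSE137619, GSE66312),
  protein-coding-only references and ortholog exports; the package ships
  only desk-scale fixtures and the synthetic generator.
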