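---
title: "Compartment-aware pathway analysis with functional homolog expansion"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Compartment-aware pathway analysis with functional homolog expansion}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(funhop)
library(dplyr)
```

## The problem

KEGG pathway maps collapse alternative enzymes — functional homologs able to
catalyse the same reaction — into a single node, and viewers display only the
first gene of each node. Two consequences follow. First, regulation of the
hidden homologs is invisible: a node can look downregulated because its
displayed gene is, while a hidden homolog is strongly upregulated. Second,
the hidden homologs often live in different subcellular compartments (a
classic example is the malate dehydrogenase pair, with one cytosolic and one
mitochondrial enzyme), so any compartment-level reading of the map based on
one gene per node is unreliable.

`funhop` addresses both. It expands every multi-gene KGML node into one
display row per gene, assigns each gene product a consensus subcellular
localization from three heterogeneous sources, overlays signed
differential-expression scores, and splits each pathway into a mitochondrial
and a non-mitochondrial variant with connectivity diagnostics. Outputs are
KGML, GraphML and node-attribute tables that Cytoscape can load.

## Node expansion

`expand_nodes()` gives every gene entry with $k > 1$ genes exactly $k$
single-gene children; the parent entry is kept as the structural node that
anchors reactions and relations, so expansion never changes the reaction
substrate/product structure and is idempotent. Group entries are flattened
into their members first, with relations re-targeted to each member.
Because standard KGML has no nesting, children are written as ordinary
`<entry>` elements with synthetic ids (`<parent>_<n>`) and a `funhop_parent`
attribute; any generic KGML reader can load the output, and `read_kgml()`
restores the structure losslessly. Children are stacked vertically from the
parent's box, one box height apart — KGML gives no guidance on placing the
extra rows, so a deterministic stack that cannot overlap within a node was
chosen.

## Localization consensus

Three sources vote, each first reduced to one of four categories
(mitochondria, cytoplasm, nucleus, secretory) per gene:

* **SubCellBarCode** reports one localization neighborhood per cell line
  (A431, MCF7, H322, U251, HCC827). `Unassign` calls are dropped; the rest
  are put to a *strict plurality* vote — the winner must occur strictly more
  often than the runner-up, an exact tie gives `uncertain`, all-`Unassign`
  gives `unknown`. The vote operates on labels harmonized to the shared
  vocabulary: SubCell's four neighborhoods map 1:1 onto the four categories,
  so the harmonized and raw votes coincide; harmonizing first simply makes
  the reduction's output directly comparable across sources.
* **Human Protein Atlas** annotates up to 35 locations per protein. Each
  label is mapped through a bundled 35-to-4 grouping table
  (`inst/extdata/hpa_category_map.tsv`) that follows HPA's organelle-proteome
  grouping with mitochondria kept as its own group, then the same strict
  plurality vote applies. The grouping table ships as data, not code: HPA's
  web grouping changes over time, and users can point `simplify_hpa()` at
  their own table.
* **BUSCA** predicts a single compartment per protein sequence.
  Extracellular and membrane classes are grouped with `secretory`; BUSCA has
  no `uncertain`.

`build_consensus()` then applies a fixed hierarchy per gene, treating
`uncertain` and `unknown` as absent votes:

1. two or three usable votes agree → that category (`majority`/`unanimous`),
   *even against* the prediction;
2. all usable votes differ → BUSCA casts the deciding vote
   (`busca_casting_vote`);
3. exactly one usable vote → it stands (`single_source`);
4. no usable vote → `unknown`.

Rule 1 encodes the experimental override: when both experimental sources
call a protein cytoplasmic and the prediction says mitochondrial, the
consensus is cytoplasmic. Rule 2 reflects that a sequence-based prediction
exists for every gene and is the only opinion available for much of the
genome. One genuinely open case is a *single* experimental vote that
disagrees with the prediction: the default lets the prediction win
(consistent with "casting vote when no two sources agree"), and
`prefer = "experimental"` flips it. Two usable experimental votes that
disagree with no usable prediction fall through to `unknown` — there is no
principled tie-break left.

Cross-source reliability is quantified by `agreement()`: categories are
binarized as mitochondria vs the rest and a confusion matrix, sensitivity
and specificity are computed over genes usable in both sources, with
`agreement_average()` for pooling comparisons.

## Differential-expression overlay

Significant genes (p strictly below `alpha`, default 0.05) receive the score

$$\mathrm{score} = \log_2(p) \times (-10) \times \mathrm{regulation},$$

with regulation $+1$ for positive and $-1$ for negative fold-changes. The
score is 0 at $p = 1$, $\pm 10$ at $p = 0.5$, and grows in magnitude as $p$
shrinks; its sign carries the direction, so a single continuous attribute
drives a red(down)/gray(0)/green(up) Cytoscape gradient. `colorize()` clamps
$|\mathrm{score}|$ at a configurable cap (default 100, i.e. $p = 2^{-10}$)
before linear interpolation — the underlying study specifies color *ranges*,
not breakpoints, so the endpoints are deliberately configurable. The p-value
column is used exactly as supplied (raw by default); pointing `read_de_table()`
at an adjusted-p column switches the filtering basis.

## Compartment splitting

`split_pathway()` keeps, in the mitochondrial variant, the per-gene nodes
whose consensus is mitochondria, and in the non-mitochondrial variant all
other *known* categories pooled (the binary split is the analysis target;
the per-category breakdown is still reported by `compartment_fractions()`).
Entries emptied of genes are deleted with their incident relations;
reactions whose catalysing entry vanished are flagged as **broken links**
and removed; compounds and maps stay in both variants. Connectivity is
assessed on the undirected reaction/relation graph — "the pathway falls
apart into three pieces" is a visual, direction-free notion — via
`connectivity_report()`, which also lists compound pairs connected in the
original but separated in a variant.

Genes with unknown consensus are retained in *both* variants and flagged by
default (`unknown_policy = "both"`): missing localization data should be
visible, not silently turned into broken paths. `"drop"` removes them, which
is also what the partition invariants in the test-suite check
(disjointness and union over the known-localization genes).

Percentages in the fraction table are rounded half-to-even: for a 19/21
split this yields the 48%/52% pair (47.5 rounds up, 52.5 rounds down), and
the two rounded percentages always sum to 100.

## The synthetic generators

`fixture_spec()` + `make_pathway()` / `make_localization_tables()` /
`make_de_table()` generate a linear-plus-branches reaction chain with
multi-gene entries, the three source tables in their native dialects, and a
DE table, all byte-deterministic under a seed and accompanied by a
ground-truth table. Defaults mirror the real study conditions: 61% / 53%
experimental coverage with full prediction coverage, roughly 4% SubCell and
15% HPA forced-tie (uncertain) rates, cytosol dominating the
non-mitochondrial categories (59/25/16 weights), and upregulation odds of
3:1 for mitochondrial genes versus 1:1 elsewhere, so Fig-1-style enrichment
is recoverable. Test problem sizes were chosen to exercise the statistics at
negligible cost: 300-600 genes for the binomial and noisy-recovery checks,
dozens of small pathways for the partition properties.

What the generators do *not* emulate: correlated errors between the two
experimental sources (real "unknowns" overlap heavily between SubCell and
HPA), multi-compartment proteins, protein complexes spanning membranes, and
any KEGG-release drift in pathway membership. Passing the synthetic
recovery tests therefore demonstrates that the machinery is correct, not
that real localization calls are — on real data the consensus quality is
bounded by the sources themselves.

## Reproducing published-style numbers

`reproduce_published_tables()` recomputes, from a user-downloaded combined
per-gene assignment table and KEGG KGML files, the agreement statistics, the
cytosol share among non-mitochondrial calls, and the per-pathway
mitochondrial fractions. These inputs are external databases and supplements
that cannot be redistributed here; a small *synthetic* stand-in with the
same layout ships as `inst/extdata/synthetic_s2_localizations.tsv` for
format reference and testing. When comparing pathway fractions against
published counts, expect ±1-2 gene deviations from KEGG release drift and
from manual judgment calls in hand-edited pathway files; the split report
itemizes every removed gene so such differences can be traced per gene.

## Limitations

* Metabolite transport between compartments is not modelled; a path broken
  in a variant may be biologically rescued by a transporter.
* Expansion only covers genes already listed in the KGML `name` attribute;
  no external homolog database is consulted.
* The KEGG-id/symbol mapping is explicit user input (a bundled fixture
  mapping serves the tests); no ID-mapping service is called.
* Localization is treated as a single compartment per protein, ignoring
  dual-localized pools.
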