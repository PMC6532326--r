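---
title: "Methods: the herbnet inference chain, its parameters and its synthetic testbed"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: the herbnet inference chain}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(herbnet)
```

## The inference chain

herbnet implements the standard network-pharmacology workflow for multi-herb
formulas as a chain of deterministic stages. Each stage is a pure function of
its input tables and thresholds; no stage uses randomness, so identical
inputs and settings are bit-identical on rerun.

**Ingredient screening.** Systems-pharmacology exports carry two ADME scores
per compound: oral bioavailability (OB, in percent) and a unitless
drug-likeness score (DL, in [0,1]). `screen_tcmsp()` keeps compounds with
OB ≥ 30 and DL ≥ 0.18 by default. Published descriptions of this screen vary
between strict (">") and inclusive ("≥") wording, so the comparison is a
flag (`inclusive`, default `TRUE`) and both boundaries are unit-tested.
Curated literature sources carry no ADME scores and bypass the screen; they
are merged afterwards with `merge_sources()`.

**Ingredient identity.** The two sources share no stable accession, so
merging is keyed on the canonicalized compound name (trimmed, internal
whitespace collapsed, lower-cased). This is the one genuinely open design
point in the assembly: name-keyed merging under-merges synonyms
("(+)-catechin" vs "catechin") and never over-merges; we prefer that
direction because a false merge silently pools target sets. No synonym
resolution is attempted — it would require an external chemical dictionary
and would make runs irreproducible as that dictionary evolves.

**Target compendium.** Two association routes feed `build_compendium()`:
literature-validated pairs, and structure-based predictions filtered by
`filter_predicted()` at similarity > 1.0 and prediction score > 0 (strict
bounds; the upstream 3D-similarity score can exceed 1, so a strict lower
bound of 1.0 is meaningful and deliberately harsh). Duplicate
(ingredient, gene) pairs keep the validated copy: curated evidence should
not be downgraded by a prediction of the same pair.

**Disease genes.** `call_degs()` performs a per-gene two-sided two-sample t
test on log2 intensities, case vs control. The fold change is computed from
the group means on the linear scale, `fc = 2^(mean_case − mean_ctrl)`, and
the magnitude criterion is `max(fc, 1/fc) ≥ 1.5` — equivalently
`|log2fc| ≥ log2 1.5 ≈ 0.585`. Reading "|FC| ≥ 1.5" on the log2 scale
instead would amount to a 2.8-fold cut, the less common convention; both
readings are reachable through `fc_min`. The significance cut is on the raw
p (`p < 0.05`, strict), as conventional for this style of screening;
Benjamini–Hochberg q-values are reported alongside in the output but do not
drive the call. DEG genes are merged with curated per-source disease lists
by `merge_disease_genes()`, every gene keeping its full set of source tags.

**Candidates and interactors.** `map_candidates()` is the set intersection
of the target universe with the disease genes; each candidate inherits the
best evidence class reaching it. `expand_interactors()` keeps PPI edges with
combined confidence strictly above 0.9 that touch at least one candidate;
non-candidate endpoints become interactors. Edges between two interactors
are kept by default (`include_interactor_interactor = TRUE`), matching how
interaction-neighborhood exports behave; the flag exists because the
alternative (candidate-incident edges only) is also defensible.

**Network and key nodes.** `build_network()` assembles a simple undirected
tripartite graph: ingredients with ≥ 1 candidate target, the candidates, and
the interactors; edges are ingredient→candidate associations plus the kept
PPI edges. Ingredients with no candidate target are excluded — as isolated
nodes they would only depress the mean degree and thereby the key threshold.
A node is *key* when its degree strictly exceeds twice the mean degree
(`2·E/N`). Two numerical points: (i) the threshold is used exactly, not
rounded to an integer; (ii) on a simple graph the mean degree is identically
`2E/N`, whereas GUI network tools sometimes report a multigraph "average
neighbours" statistic that differs — both conventions cannot be satisfied at
once, and we use the simple-graph identity, asserted by the handshake lemma
on every constructed network.

**Enrichment.** `hypergeom_enrich()` computes the upper-tail hypergeometric
p, `P[X ≥ k]` for `X ~ Hypergeom(N, K, n)`, for each term after intersecting
it with the background; terms with `k = 0` are omitted, and BH adjustment is
applied within each category (pathways and molecular functions are separate
term systems with separate multiplicities). The background defaults to the
analysis universe — the compendium's target universe plus the interactors —
because that is the gene space the query (the pooled key targets) was drawn
from; testing against "all annotated genes" would overstate enrichment.
`kappa_group()` reproduces the ClueGO-style grouping convention: binary term
memberships over the union of query-hit genes, pairwise Cohen's kappa,
linking at κ ≥ 0.4, groups as connected components, each group named by its
lowest-p member. Degenerate kappa cases are pinned down: identical
membership vectors give κ = 1 (including all-in/all-out vectors, where
chance agreement is 1), and a chance-agreement denominator of zero with
non-identical vectors gives κ = 0.

## Tunable parameters

| Parameter | Default | Units / scale | Why this default |
|---|---|---|---|
| `ob_min` | 30 | percent | conventional oral-bioavailability screen |
| `dl_min` | 0.18 | unitless [0,1] | conventional drug-likeness screen |
| `inclusive` | TRUE | — | published wording varies between ≥ and > |
| `sim_min` | 1.0 | similarity score (can exceed 1) | strict structural-similarity cut |
| `pred_score_min` | 0 | score | keep any positive prediction |
| `p_max` | 0.05 | probability | raw-p screening convention |
| `fc_min` | 1.5 | linear fold change | standard microarray cut |
| `var_equal` | FALSE | — | Welch default; Student reachable |
| `ppi_score_min` | 0.9 | combined confidence [0,1] | "highest confidence" PPI tier |
| `q_max` | 0.05 | BH-adjusted p | grouping only clearly enriched terms |
| `kappa_min` | 0.4 | Cohen's kappa | ClueGO's default linking threshold |

## The synthetic testbed

The generator (`synth_params()`, `gen_*()`, `gen_all()`) emulates every
input the chain consumes, with planted ground truth so recovery is
measurable. Defaults describe one fixed study design, chosen once at a
realistic scale:

* **Knowledgebase** — 12 herbs with uneven ingredient weights; 480 scored
  ingredient rows with OB ~ U(0, 60) and DL ~ U(0, 0.4), straddling the
  screen thresholds so ~130 pass; 39 curated ingredients without scores;
  a 1100-gene reachable universe of which ~900 distinct genes end up
  targeted; predicted associations include sub-threshold decoy rows that
  `filter_predicted()` must remove. One planted hub ingredient always passes
  the screen, targets 60% of a 45-gene disease core plus a fan-out ten times
  the typical ingredient's — the "promiscuous flavonoid" pattern seen in
  real formulas, where the top compounds reach a third of the universe.
* **Expression** — 6 case vs 6 control arrays; per-gene baseline
  N(7, 1.5²) log2 intensity, iid noise sd 0.3, and 23 up + 28 down planted
  DEGs at |log2FC| = 1; a subset of planted DEGs falls inside the disease
  core so DEG evidence feeds the candidate set, the rest are
  expression-only symbols.
* **Disease lists** — 59 distinct curated genes across five sources with
  overlapping membership, 28 of them in the disease core.
* **PPI and annotation** — edge confidences from a Beta mixture
  (Beta(2,6) background, Beta(14,1.2) high mode with substantial mass above
  0.9); core genes get Poisson numbers of partners from a 300-protein pool;
  one pathway and one molecular-function term are planted by over-sampling
  core genes (18/25 and 8/15 of their memberships), the remaining terms are
  uniform decoys.

Seed handling: every generator derives an independent 32-bit substream from
the master seed, so adding a generator never shifts the draws of existing
ones, and `gen_all()` with the same seed is byte-identical on disk. The
ground truth (planted hubs, DEG effects, enriched terms, all parameters) is
serialized beside every generated dataset.

**What the testbed does not emulate.** Real intensity distributions
(heteroskedasticity, probe effects, batch structure), correlated genes,
hub-and-spoke PPI topology, synonymous compound names, and annotation
redundancy beyond the planted terms. Passing recovery tests therefore shows
the chain's logic and calibration are correct under the stated model — not
that any particular biological conclusion from real exports is right.

## Statistical calibration

Two properties are checked by simulation at fixed problem sizes (50 seeds ×
2000 genes for the null; 100 seeds for recall; 100 and 50 seeds for hub and
pathway recovery — sizes chosen to give tight Monte-Carlo error while the
whole suite stays fast):

* Under a pure null, the Student's t variant is exact: its pooled type-I
  rate at p < 0.05 falls inside the exact binomial 99% band. The default
  Welch variant at n = 6/6 is mildly **conservative** under equal variances
  (empirical rate ≈ 0.046) because its estimated degrees of freedom are at
  most 2(n−1); conservative is the safe direction for a screening cut, and
  the suite asserts Welch never exceeds the nominal rate.
* With planted |log2FC| = 1, noise sd 0.3 and 6 vs 6 samples, pooled recall
  of planted DEGs exceeds 0.95 (recall is limited by the fold-change
  criterion, not the test: the observed mean difference must also clear
  0.585).

Degenerate inputs are defined, not crashed on: zero-variance genes get
p = 1 (`ns`); an empty candidate intersection warns and propagates empty
downstream sets; an empty significant-term set yields an empty summary with
a warning.

## Known limitations

* Name-keyed ingredient merging under-merges synonyms (by design, see
  above).
* Gene identity is the upper-cased symbol; no cross-release symbol mapping.
* The hypergeometric test treats genes as exchangeable; correlated gene sets
  (nested pathway hierarchies) inflate the kappa groups rather than the
  p-values.
* The degree > 2×mean rule is scale-sensitive: adding isolated or weakly
  connected nodes lowers the threshold. The pipeline's exclusion of
  zero-candidate ingredients is the one place this is actively managed.
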