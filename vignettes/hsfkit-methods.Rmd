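---
title: "Methods: gene-family cataloguing, reconciliation and network analysis with hsfkit"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: gene-family cataloguing, reconciliation and network analysis with hsfkit}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hsfkit)
library(ape)
```

hsfkit implements a comparative-genomics pipeline for the plant heat shock
transcription factor (Hsf) family and its downstream chaperone (Hsp)
families: family cataloguing from profile-domain hits, conserved-motif
gain/loss trajectories, gene-tree/species-tree reconciliation, duplicate-type
classification with collinear block chaining, regulatory and co-expression
network assembly with term enrichment, promoter scanning for the heat shock
element (HSE), and subgenome retention bookkeeping for a triplicated
pan-genome. This vignette explains the models and procedures, the parameters
that matter, and the design choices behind them.

## Family cataloguing

Hsf proteins are defined by the HSF-type DNA-binding domain (Pfam PF00447).
A genome's family catalog is built in three steps:

1. **Isoform deduplication** (`dedupe_isoforms`). Annotation releases list
   several splice forms per locus; statistics must count loci. The longest
   protein per locus is retained; exact length ties are broken by the
   lexicographically smallest gene id so the output is reproducible
   regardless of input order.
2. **Membership** (`select_family_members`). A gene is a member iff it has
   at least one domain hit with the family accession and e-value strictly
   below `e_max = 1e-4`. The inequality is strict, so a hit at exactly
   1e-4 is excluded. The threshold applies to the per-domain
   (independent) e-value of HMMER's `--domtblout` output; full-sequence
   filtering can be emulated by pre-filtering the hit table. A secondary
   validation hit table (e.g. from SMART/CDD profiles run locally) can be
   supplied and is combined by intersection.
3. **Summaries** (`summarize_catalog`). Per species: member count, count
   ratio (members / genome genes), log2 member count and log10 genome size
   (counts of zero are reported as missing rather than −Inf, so downstream
   plots do not inherit infinities), and the mean-length ratio between
   family and genome proteins. Ratios are kept on a 0–1 scale internally;
   percent formatting belongs to the reporting layer and uses R's
   round-half-to-even.

## Motif states and Dollo trajectories

Conserved-motif analysis distinguishes, per species and motif, three states:
*complete* (all family genes carry the motif), *partial* (some do) and
*absent* (none). For trajectory inference on the species tree, a motif is
treated as present in a species when its state is complete **or** partial:
partial loss is a within-family event, reported separately in the state
table, while the trajectory tracks whether the motif existed in the lineage
at all. Under Dollo parsimony a motif is gained exactly once — on the branch
above the most recent common ancestor of all carrier species — and lost any
number of times; the loss set is one loss on the root branch of each maximal
carrier-free clade below the gain, which is the provably minimal single-gain
explanation (the test suite checks this against exhaustive enumeration on
small trees). Polytomies in the species tree are honoured as given; no
fractional presence cutoff is introduced beyond all/some/none.

## LCA reconciliation

`lca_reconcile` maps every gene-tree node to the lowest common ancestor (in
the species tree) of the species below it. A node that maps to the same
species node as one of its children is a duplication; otherwise it is a
speciation. For a gene-tree edge whose endpoint mappings are `d` species
branches apart, the implied loss count is `d − 1` below a speciation and `d`
below a duplication. Each loss is attributed to the branch where the lineage
disappeared: at every species node the mapping path passes through (plus the
starting node when the parent is a duplication), one loss is charged to each
child branch off the path. On a binary species tree this reproduces the
`d − 1` / `d` totals exactly; at a polytomy each off-path child counts one
loss, the natural generalization (each of those subtrees independently lost
the gene). Duplications are charged to the branch above the node they map
to, so a family-wide expansion appears on the stem branch, mirroring the
`+n/−n` branch annotations used in published reconciliation figures.

LCA mapping gives the most parsimonious (minimum duplications + losses)
reconciliation; the tests verify this against a brute-force minimum over all
valid node mappings on trees small enough to enumerate. Gene trees must be
rooted and strictly binary — the loss arithmetic assumes binary gene trees —
while species trees may be multifurcating. No automated rooting heuristic is
applied: rooting changes event counts, so it must be an explicit caller
decision. Transfer-aware (DTL) reconciliation and bootstrap-aware
rearrangement are out of scope.

## Duplicate-type classification

Gene duplicates are classified from gene order (rank along the chromosome,
not bp — rank semantics make gap thresholds assembly-independent and the
synthetic ground truth exact):

* `chain_collinear_blocks` chains homologous anchor pairs by dynamic
  programming within each chromosome pair: consecutive anchors must advance
  1–`max_rank_gap` ranks on both chromosomes, monotonically (increasing, or
  decreasing on the second chromosome for inverted blocks). Chains are
  extracted best-first, each anchor joins at most one block, and blocks with
  fewer than `min_pairs` anchors are dropped. Defaults `min_pairs = 5`,
  `max_rank_gap = 25` mirror the de-facto standard collinearity-scan
  defaults; both are exposed.
* `classify_duplicates` applies a fixed precedence so every gene gets
  exactly one class: **WGD/segmental** (anchors any block) >
  **tandem** (homolog at rank distance 1 on the same chromosome) >
  **proximal** (within `proximal_max_gap = 10` ranks) > **dispersed** (any
  other homolog) > **singleton** (no homolog).
* `type_enrichment_chi2` compares one type's share in the family against the
  genome with a 2×2 Pearson chi-square (no continuity correction, 1 df,
  upper tail), flagged at `p < .01`; Bonferroni-adjusted values over the
  tested types are reported alongside for the conservative reading. A zero
  expected cell raises an error recommending an exact test rather than
  returning an unstable statistic.

## Regulatory and co-expression networks

`build_target_network` filters a scored, directed regulator→target edge
table at `score ≥ 0.60` (the customary cutoff for integrated
gene-regulatory-network confidence scores, treated as a 0–1 scale) and
splits the family neighbourhood into downstream genes (targets of family
regulators), upstream genes (regulators of family targets) and the feedback
set (their intersection).

`pcc_network` computes the Pearson correlation coefficient between every
pair of genes across the sample columns (sample, `n − 1` normalization) and
keeps pairs with `pcc > 0.95` (positive regulatory edge) or `pcc < −0.95`
(negative), strict inequalities as printed in the source thresholds.
Correlations are meant to be computed over the heat-treatment series
(control, T1, T4, T8, T12); the caller chooses the sample columns, so a
tissue panel can be included deliberately. Genes with zero sample variance
have no defined correlation and are excluded with a warning; fewer than 3
samples is an error, since a 2-point correlation is ±1 by construction.
Both within-family and cross-family edges are reported by default
(`cross_family_only` restricts to Hsf–Hsp style pairs). `hub_ranking`
breaks degree ties by gene id so top-k tables are stable.

`term_enrichment` uses the upper-tail hypergeometric probability
P(X ≥ k | N, K, n) — equivalent to a one-sided Fisher test — over the
*annotated* background (N) and annotated targets (n), since genes without
any annotation are uninformative for term frequencies. Bonferroni correction
uses m = number of terms actually tested (those with k ≥ 1), which keeps q
well-defined and matches common practice; a term is significant when
`q < .05` **and** fold change `(k/n)/(K/N) > 2`.

## Promoter HSE scanning

Promoters are the 2 kb upstream of the translation initiation site (CDS
start, not transcript start), truncated at chromosome edges and reported
5′→3′ relative to the gene (minus-strand promoters are
reverse-complemented). `scan_hse` matches the HSE consensus
`GAAnnTTnnnGAA` in every (possibly overlapping) 13-nt window; windows
containing N never match. Both strands are scanned by default — the minus
strand via the reverse-complement pattern `TTCnnnAAnnTTC` on the forward
sequence, reported with forward-coordinate offsets — with a single-strand
mode for a stricter reading. All overlapping matches are reported; the
downstream HSE-positive predicate is "≥ 1 hit", so overlap handling cannot
change gene-level conclusions. Offsets are 0-based internally and 1-based
inclusive in written reports. Under an i.i.d. uniform background the
expected hit count is 2·(L−12)/4⁸ per promoter of length L (8 fixed
positions over both strands), which the tests verify by Monte Carlo.

`hse_subnetwork` restricts a co-expression network to edges whose Hsp
endpoints all carry at least one promoter HSE (Hsf endpoints are always
kept), reconstructing the promoter-supported heat-response subnetwork.

## Pan-genome retention

After a whole-genome triplication, each reference (e.g. *Arabidopsis*) gene
has up to one syntenic copy in each of the three subgenomes — the least
fractionated (LF) and the more fractionated MF1 and MF2 — of every
accession, so retention per (reference gene, accession) is an integer 0–3.
`count_retention` enforces this structure: two copies in one subgenome slot
are rejected rather than silently collapsed. Syntenic assignment itself
(which copy pairs with which reference gene) is an input table — producible
by running the collinearity chaining cross-species — so the triplication
bookkeeping stays independently testable. `retention_summary` and
`detect_losses` give per-accession syntenic ratios and the zero-copy pairs,
including genes lost in every accession.

## Synthetic data: what it emulates, and what it does not

The `simulate_*` generators produce seeded, bit-reproducible inputs with
machine-readable truth tables for every stage, so the full pipeline runs and
is validated without any downloads:

* `simulate_family_evolution` runs a linear birth–death process (duplication
  rate λ, loss rate μ per unit branch length) along a species tree rescaled
  to unit root-to-tip depth, so rates are interpretable per tree depth. The
  event log records the true branch of every event. With μ = 0 every
  duplication is recoverable and LCA reconciliation must return the log
  exactly; with λ = 0 the per-branch loss probability has the closed form
  1 − e^(−μt), which the tests check by Monte Carlo.
* `simulate_genome_with_duplicates` plants tandem, proximal, segmental and
  dispersed structures in rank windows separated by ≥ 30 ranks, beyond the
  default chaining gap, so the planted truth is provably the only signal and
  noise-free classification must be exact.
* `simulate_expression` uses a block design on the log2 scale (shared block
  profile + gene baseline + N(0, σ) noise), exponentiated to mimic FPKM
  positivity and right skew. At σ = 0 within-block correlations are exactly
  1 on either scale (genes of a block are positive scalings of each other).
  Co-expression PCC should be computed on **log2-transformed** values, the
  scale expression analyses and heat maps use: on the raw exponentiated
  scale a single high-expression sample dominates both vectors of a pair and
  can push unrelated genes past |0.95|, whereas on the log2 scale
  cross-block profiles are independent Gaussians and spurious edges are
  vanishingly rare with the 11-sample heat+tissue design. The default design
  mirrors the study conditions: a 5-point 38 °C heat series (control, T1,
  T4, T8, T12) and a 6-tissue panel (root, stem, leaf, flower, silique,
  callus).
* `simulate_promoters` plants HSE instances (with the free `n` positions
  drawn uniformly) at recorded offsets/strands in uniform background, with
  an optional disrupting substitution at the first pattern position.
* `simulate_regulatory_edges` produces scored directed edges with decoys
  below the 0.60 cutoff and designated feedback genes.

These generators emulate the *statistical structure* each method assumes —
not real data. Real genomes have fragmented assemblies, unequal family
sizes, correlated noise across samples, GC-biased promoter composition and
incomplete annotations; passing the synthetic suites therefore demonstrates
algorithmic correctness (the right sets, counts and statistics on inputs
with known truth), not field performance on any particular genome.

## Numerical choices and problem sizes

Determinism is enforced everywhere results could depend on input order:
sorted outputs, canonical unordered pairs, explicit tie-breaks (longest
isoform then smallest id; hub degree then gene id; chain length then
smallest starting rank). Thresholds are strict or inclusive exactly as the
conventions they follow print them (`e < 1e-4`, `score ≥ 0.60`,
`|pcc| > 0.95`, `q < .05`, fold `> 2`, `p < .01`).

The validation suites run at desk scale, chosen to exercise every code path
while keeping the whole suite fast: exhaustive reconciliation oracles on
species trees with ≤ 4 tips and gene trees with ≤ 6 tips plus 500
birth-only replicate families; a 1000-gene planted genome for the
classifier; 10⁵ random 200-nt sequences for the HSE background rate; full
enumeration of C(20, n) draws for the hypergeometric oracle. Published
genome-scale figures that depend on external databases (111 proteomes, the
integrated regulatory-network service, the *B. rapa* pan-genome) are
represented by their printed summary counts, used as inputs to the same
summary functions.

## Known limitations

* Loss attribution at species-tree polytomies generalizes the binary
  formula (one loss per off-path child); other conventions exist.
* The chaining DP is O(n²) per chromosome pair — ample for gene-family
  anchor sets, not tuned for whole-genome all-vs-all anchor lists.
* `term_enrichment` tests terms independently; hierarchical term structure
  (e.g. ontology DAGs) is not modelled.
* The birth–death simulator draws waiting times per lineage segment;
  it does not model rate variation across branches or gene conversion.
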