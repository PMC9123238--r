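# hsfkit

Comparative-genomics toolkit for the plant **heat shock transcription
factor (Hsf)** gene family and the chaperone (**Hsp**) families it
regulates. Hsfs are the master switches of the plant heat-stress response:
they are defined by the HSF-type DNA-binding domain (Pfam **PF00447**), bind
the heat shock element (HSE, consensus `GAAnnTTnnnGAA`) in Hsp promoters,
and have expanded and contracted through whole-genome duplication and
triplication across the plant kingdom. hsfkit provides the full analysis
chain used in large-scale Hsf family studies as tested, reusable R
functions, for anyone cataloguing a transcription-factor family across many
genomes and asking how it evolved and what it regulates.

## What it computes

| Stage | Functions | Method |
|---|---|---|
| Family catalog | `dedupe_isoforms`, `select_family_members`, `summarize_catalog` | longest isoform per locus; membership iff a PF00447 hit with e-value < 1e-4 (strict); per-species counts, count ratios, length ratios |
| Motif trajectories | `species_motif_state`, `dollo_trajectory` | complete/partial/absent states; single-gain, minimum-loss (Dollo) placement on the species tree |
| Reconciliation | `lca_reconcile`, `aggregate_reconciliations` | LCA mapping; duplication where a node maps with its child; losses `d−1` (speciation) / `d` (duplication) charged to off-path branches; most-parsimonious by construction |
| Duplicate types | `chain_collinear_blocks`, `classify_duplicates`, `type_enrichment_chi2` | DP collinearity chaining (≥5 anchors, rank gap ≤25); precedence WGD/segmental > tandem > proximal > dispersed > singleton; 2×2 χ² (no continuity correction, p < .01) |
| Networks | `build_target_network`, `pcc_network`, `hub_ranking`, `summarize_coexpression`, `term_enrichment`, `venn_partition` | score ≥ 0.60 regulatory edges, downstream/upstream/feedback split; PCC > .95 / < −.95 co-expression edges; hypergeometric upper tail, Bonferroni, significant iff q < .05 and fold > 2 |
| Promoters | `extract_promoters`, `scan_hse`, `hse_subnetwork` | 2 kb upstream of the CDS start; all overlapping `GAAnnTTnnnGAA` windows on both strands; HSE-restricted heat-response subnetwork |
| Pan-genome | `count_retention`, `retention_summary`, `detect_losses` | 0–3 syntenic copies per reference gene across LF/MF1/MF2 subgenomes; retention ratios and complete losses |
| Synthetic truth | `simulate_family_evolution`, `simulate_genome_with_duplicates`, `simulate_expression`, `simulate_promoters`, `simulate_regulatory_edges` | seeded generators with machine-readable ground truth for every stage |

## Worked example

```r
library(hsfkit)
library(ape)

# 1. catalog a small family from domain hits
records <- data.frame(
  gene_id = c("Ath1.1", "Ath1.2", "Ath2.1", "Osa1.1", "Osa2.1"),
  species_id = c("Ath", "Ath", "Ath", "Osa", "Osa"),
  locus_id = c("L1", "L1", "L2", "L3", "L4"),
  protein_length = c(310L, 495L, 420L, 380L, 300L))
hits <- data.frame(
  gene_id = c("Ath1.2", "Ath2.1", "Osa1.1", "Osa2.1"),
  domain_accession = "PF00447",
  e_value = c(1e-30, 2e-12, 4e-9, 5e-3))
catalog <- select_family_members(hits, dedupe_isoforms(records), "PF00447")
summarize_catalog(catalog)$species
#>   species_id member_count genome_gene_count count_ratio log2_member_count
#> 1        Ath            2                 2         1.0                 1
#> 2        Osa            1                 2         0.5                 0
#>   log10_genome_count length_ratio
#> 1            0.30103     1.000000
#> 2            0.30103     1.117647
```

The two isoforms of locus `L1` collapse to the 495-aa one; `Osa2.1` is
rejected because 5e-3 is above the e-value cutoff, so rice keeps 1 member of
its 2 loci (count ratio 0.5).

```r
# 2. reconcile a gene tree against the species tree
stree <- read.tree(text = "((Ath,Osa),Ppa);")
gtree <- read.tree(text = "(((a1,o1),(a2,o2)),p1);")
rec <- lca_reconcile(gtree, stree,
                     c(a1 = "Ath", o1 = "Osa", a2 = "Ath", o2 = "Osa",
                       p1 = "Ppa"))
rec$branches
#>   branch duplications losses annotation
#> 1    Ath            0      0      +0/-0
#> 2    Osa            0      0      +0/-0
#> 3    Ppa            0      0      +0/-0
#> 4     N1            0      0      +0/-0
#> 5     N2            1      0      +1/-0
```

The duplicated (Ath, Osa) pair is explained by one duplication on the branch
above the Ath–Osa ancestor (`N2`), no losses — the `+1/-0` annotation
mirrors how reconciliation figures label branches.

```r
# 3. scan a promoter for heat shock elements
scan_hse(c(BraA01g027780 = "TTGAACATTCCCGAATTTTAGCGAACCTTAAAGAAGT"))
#>         gene_id offset strand       matched
#> 1 BraA01g027780      2      + GAACATTCCCGAA
#> 2 BraA01g027780     12      + GAATTTTAGCGAA
#> 3 BraA01g027780     22      + GAACCTTAAAGAA
```

Three overlapping-window HSE matches, all on the forward strand, with
0-based offsets; any gene with ≥ 1 hit is HSE-positive for
`hse_subnetwork`.

## Package layout

* `R/` — implementation (one file per stage, plus tree utilities).
* `tests/testthat/` — unit, property and end-to-end suites; brute-force
  oracles live in `helper-oracles.R`.
* `inst/fixtures/` — deterministic builders that assemble data objects from
  published summary counts.
* `vignettes/hsfkit-methods.Rmd` — models, parameters, design decisions and
  limitations.
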