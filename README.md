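# lrrfam

Genome-wide characterization of plant LRR receptor-like kinase (LRR-RLK)
gene families in R.

LRR-RLKs — proteins with an extracellular leucine-rich repeat region and a
cytoplasmic kinase domain — form the largest receptor kinase family in
plant genomes, and surveys of the family follow a standard recipe:
identify members by domain architecture, classify them against reference
subgroups on a phylogeny, summarize gene structure, reconstruct and date
duplication history, scan promoters for cis-regulatory elements, and
profile expression. `lrrfam` implements the whole recipe as composable
functions plus an end-to-end pipeline, together with a seeded
synthetic-genome generator whose machine-readable ground truth makes
every stage testable offline.

## What it does

* **Identification** — E-value screen (`E < 0.001`, strict) over
  Pfam-style domain hit tables, union with a similarity-rescue list, the
  LRR + kinase architecture rule with overlapping-LRR-envelope merging,
  and patristic-distance pruning against reference leaves.
* **Classification** — p-distance neighbor joining (exact on additive
  matrices, deterministic tie-breaking), seeded bootstrap supports, and
  reference-anchored assignment into the 24 canonical RLK-Pelle LRR
  subgroups (smallest supported clade whose references agree).
* **Gene structure** — per-subgroup exon statistics (n, min, max, mean,
  sample SD) from primary transcripts.
* **Duplication & dating** — tandem clusters by the 200-kb rule,
  collinear blocks by rank-space anchor chaining (≥ 3 anchors, same or
  inverted orientation), NG86 Ka/Ks with Jukes–Cantor correction,
  selection classes, and `T = Ks/(2γ)` dating (γ = 1.5e-8).
* **Promoters** — strand-aware 2-kb upstream extraction and IUPAC motif
  scanning against a packaged cis-element library.
* **Expression** — replicate-aware matrices, tau tissue-specificity
  calls, genotype × time peak calls, heatmap ordering, and 2^−ΔΔCt.
* **Synthetic genome** — `simulate_genome()` writes a 3-chromosome
  genome (FASTA/GFF3/proteins/CDS/domain hits/expression) with a planted
  40-member family and `truth/` tables stating exactly what was planted;
  `evolve_cds()` calibrates divergence so NG86 recovers target Ks by
  construction.

## Worked example

```r
library(lrrfam)
bundle <- simulate_genome(sim_config(seed = 101), "bundle")
res <- run_pipeline(bundle, "results")
cat(res$summary, sep = "\n")
```

```
family members: 40
protein length range: 300-300 aa (mean 300.0)
members with two or more kinase domains: 2
members assigned to subgroups: 40 / 40
tandem clusters: 3 (7 duplicate pairs, largest 5 genes)
collinear blocks: 2 (7 anchor pairs)
duplicate pairs dated: 14 (mean Ks 0.345, mean Ka/Ks 0.198)
promoter elements found: 232 occurrences of 6 element types
tissue-specific members: 8
infection-responsive members (fold >= 2 over baseline): 38
```

All of this matches the planted truth exactly: the three tandem clusters
(3 + 5 + 2 genes, planted gaps 20–150 kb, with a deliberate 250-kb
near-miss pair correctly left out), both segmental blocks with all 7
planted anchor pairs, and every subgroup assignment. Dating lands on
target — e.g. the first tandem pairs, planted at Ks = 0.15, Ka/Ks = 0.2:

```r
head(res$kaks[, c("gene_a", "gene_b", "ka", "ks", "ratio", "t_mya")], 4)
#     gene_a    gene_b         ka        ks     ratio    t_mya
#  mt1g00070 mt1g00080 0.03009431 0.1490030 0.2019711 4.966767
#  mt1g00080 mt1g00090 0.03013210 0.1483868 0.2030645 4.946228
#  mt2g00070 mt2g00080 0.02932925 0.1510461 0.1941742 5.034870
#  mt2g00080 mt2g00090 0.02930060 0.1515931 0.1932845 5.053105
```

Stage tables (`family_members.tsv`, `subgroup_assignments.tsv`,
`exon_stats.tsv`, `tandem_clusters.tsv`, `collinear_blocks.tsv`,
`kaks_pairs.tsv`, `promoter_counts.tsv`, `specificity_calls.tsv`,
`peak_calls.tsv`, `family_tree.nwk`, `report.txt`) are written to the
output directory. Real data goes through the same interface as a named
list of file paths, or via the CLI wrapper
`inst/scripts/lrrfam-pipeline.R`.

## Reproduce the headline numbers

```sh
Rscript scripts/acceptance.R --seed 42 --out acceptance.json
```

regenerates a bundle from the seed, reruns the pipeline, and writes the
headline quantities as JSON (e.g. at seed 42: 40/40 members recovered,
100% subgroup assignment at support ≥ 51, mean tandem Ks 0.1494 against a
0.15 target, maximum segmental Ks error 0.0138, mean Ka/Ks 0.1999, all
promoter scans and planted expression sets recovered exactly). Every
stochastic step derives from `--seed`; the run takes about a minute.

See the vignette (`vignettes/lrr-rlk-family-analysis.Rmd`) for methods
details and the generator's design rationale and limitations.
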