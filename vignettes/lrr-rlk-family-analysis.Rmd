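---
title: "Genome-wide LRR-RLK family characterization: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Genome-wide LRR-RLK family characterization: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

Leucine-rich repeat receptor-like kinases (LRR-RLKs) are the largest plant
receptor kinase family: an extracellular leucine-rich repeat region, a
transmembrane segment, and a cytoplasmic protein kinase domain. Surveys of
this family in a plant genome follow a well-worn path: identify members by
domain architecture, classify them against reference subgroups on a
phylogeny, characterize gene structure, map duplication history and date
it with synonymous divergence, scan promoters for cis-regulatory elements,
and profile expression across tissues and stress time courses. `lrrfam`
implements that entire path as composable R functions plus an end-to-end
pipeline, and ships a seeded synthetic-genome generator whose ground truth
makes every stage machine-checkable.

# Identification

Candidates come from two routes that are merged as a set union:

* **Domain screen.** Pfam-style hit tables are filtered at a strict
  E-value threshold (`filter_domain_hits()`, default `E < 0.001`); genes
  carrying an LRR-class hit form the screen set. Kinase hit E-values do
  not gate candidacy — the kinase requirement is enforced by the
  architecture rule below, which mirrors how LRR-profile-driven searches
  are normally run.
* **Similarity rescue.** A caller-provided list of ids recovered by
  sequence similarity despite weak domain hits.

`call_architecture()` then requires at least one LRR and one kinase
domain per protein. Overlapping LRR envelopes (different LRR-clan profiles
matching the same residues) are merged with `IRanges::reduce()` before
counting, so one repeat region is never double-counted; kinase hits are
counted as-is, so tandem-kinase receptors report `n_kinase = 2`.
`merge_candidates()` records provenance (`hmm_search`, `rescue`, `both`)
and lists architecture failures in `removed`. Finally `prune_by_tree()`
drops members whose patristic distance to every reference leaf exceeds a
ceiling (default 1.0 substitutions/site) — the manual-curation analogue
for divergent false positives.

# Classification

`p_distance_matrix()` computes amino-acid p-distances (pairwise or
complete gap deletion) and `nj_tree()` performs textbook Saitou–Nei
neighbor joining with deterministic tie-breaking (smallest `(i, j)` in
current taxon order) and zero-clamped branch lengths. On an additive
matrix the generating tree is recovered exactly; this is a test invariant
(tolerance 1e-9), not an aspiration. `bootstrap_supports()` resamples
alignment columns (seeded, hence reproducible) and labels internal edges
with bipartition support percentages.

`assign_subgroups()` anchors classification on labeled reference leaves
from the 24-subgroup RLK-Pelle LRR vocabulary: each query receives the
label of the *smallest* sufficiently supported clade (default support
≥ 50) containing it together with at least one reference, provided all
references in that clade agree; clades with conflicting references are
skipped in favor of larger ones, and queries with no qualifying clade are
reported `unclassified` rather than guessed.

# Gene structure, duplication, and dating

`exon_counts()` counts exons on the primary transcript (explicit
`primary` flag, else longest CDS, else lexicographic id).
`subgroup_stats()` reproduces the classic per-subgroup table: n, min,
max, mean, and sample SD (n−1 denominator; statistics are kept at full
precision and rounded only for display).

Tandem duplication uses the 200-kb rule: family genes on one chromosome
chained by consecutive end-to-start distance ≤ 200 kb (inclusive) form a
cluster of ≥ 2 genes; a k-gene cluster contributes k−1 duplicate pairs.
Segmental duplication chains protein-similarity anchors
(`find_anchor_pairs()`, local alignment, BLOSUM62, score ≥ 100) in gene
rank space: a block is a maximal strictly monotonic run (same or inverted
orientation) with per-step rank gaps ≤ 25 and ≥ 3 anchors, extracted
greedily by dynamic programming. In `run_pipeline()` the chaining input is
restricted to inter-chromosomal anchors; intra-chromosomal proximal
duplicates are the tandem step's jurisdiction (the same division of labor
as MCScanX's tandem-anchor exclusion).

Duplicate pairs are dated with Nei–Gojobori (NG86): per-codon synonymous
site fractions by single-mutation enumeration, substitution counts
averaged over all minimal mutational pathways (stop-passing pathways
excluded, with an all-pathways fallback), Jukes–Cantor correction
`d = -3/4 log(1 - 4p/3)`, saturation flagged at `p ≥ 3/4`. Divergence
time is `T = Ks / (2γ)` with `γ = 1.5e-8` substitutions/site/year, the
rate conventionally used for nuclear genes of dicots. Ks histograms use
half-open bins `[kw, (k+1)w)` with a small tolerance so edge values land
in the upper bin deterministically.

# Promoters and expression

`extract_upstream()` returns the 2-kb window upstream of the translation
start (strand-aware, reverse-complemented for minus-strand genes,
truncated with a warning at chromosome ends). `scan_elements()` matches a
packaged IUPAC cis-element library (W-box, MBS, P-box, LTR, GARE-motif,
AuxRR-core, ABRE, and others) on both strands where the motif definition
calls for it, counting a palindromic match at one locus once.

Expression matrices carry explicit replicate structure;
`replicate_means()` condenses them. Tissue specificity uses the tau
score, `tau = Σ(1 - x_i/x_max) / (N-1)`. A gene is *specific* when
`tau ≥ 0.8` and the called conditions (those within 2-fold of the
maximum) stand at least 2-fold above every other condition. This is a
deliberate generalization of the naive "top exceeds 2 × second" rule:
genes genuinely specific to two conditions (e.g. root **and** nodule)
would fail the naive rule because their second condition is necessarily
within 2-fold of the top — the separation criterion between the called
set and the rest is what the biology means. Infection time courses use
`genotype:time` condition labels; `peak_time_calls()` reports the
peak condition (ties to the earliest time, then genotype order) and calls
genes with peak ≥ 2-fold over baseline. `delta_delta_ct()` implements
2^−ΔΔCt with replicate pairing.

# The synthetic genome generator

`simulate_genome(sim_config(seed), out_dir)` writes a complete input set
(genome FASTA, GFF3, proteins, CDS, domain hit table, rescue list,
reference proteins and labels, tissue/infection/Ct matrices) plus
`truth/` tables that state exactly what was planted. Design points:

* **Sequence evolution is estimator-calibrated.** `evolve_cds()` places
  `round(p*·S)` synonymous changes with
  `p* = 3/4(1 - exp(-4/3·Ks))`, at most one change per codon, never
  creating stops, so NG86+JC recovers the target Ks up to rounding — by
  construction, not by luck. A Poisson substitution process was rejected
  because back-mutations at 2-fold sites bias NG86 noticeably by Ks 0.6.
* **Tandem truth is geometric.** Chromosomes are laid out as units
  (tandem clusters with exact planned gaps ≤ 200 kb, segmental anchor
  runs, a deliberate near-miss pair at 250 kb, singles) separated by
  filler background genes plus a terminal gap keeping family genes of
  different units > 205 kb apart — the planted clusters are exactly what
  the 200-kb rule can find.
* **Chain safety.** Anchors only arise within subgroups (cross-subgroup
  alignment scores sit far below the threshold). Every non-segmental
  subgroup lives on a single chromosome and segmental subgroups appear
  only inside their planted blocks, so the planted blocks are the only
  chainable inter-chromosomal anchor sets; leftover cross anchors cannot
  reach the 3-anchor minimum. This was derived from first principles
  before the pipeline ever ran, not tuned afterward.
* **Capacity honesty.** The 3 Mb default chromosome length exists because
  > 205 kb separations between ~10 units plus 160 background genes do not
  fit in less; impossible plans fail fast with clear errors rather than
  silently bending gaps.
* **Known limitations.** Family proteins are equal-length and indel-free
  (alignment is trivial by design, since MSA construction is out of
  scope); background genes are random sense-codon ORFs with no
  inter-genic repeat structure; domain hits are planted rather than
  produced by a real HMM search; expression noise is Gaussian on linear
  scale. The generator is a test harness with exact truth, not a genome
  simulator for benchmarking aligners.

Determinism is strict: every stochastic choice flows from the single
seed, and two runs with the same seed produce byte-identical files.

# Running everything

```{r pipeline}
library(lrrfam)
bundle <- simulate_genome(sim_config(seed = 101), "bundle")
res <- run_pipeline(bundle, "results")
res$summary
```

`run_pipeline()` also accepts a named list of file paths for real data
(`genome`, `gff`, `proteins`, `cds`, `domains`, `ref_proteins`,
`ref_labels`, optional `rescue`, `tissues`, `infection`), and the same
interface is exposed on the command line via
`inst/scripts/lrrfam-pipeline.R`. The repository-level
`scripts/acceptance.R --seed <int> --out <json>` regenerates a bundle,
reruns the pipeline, and emits the headline quantities as JSON.
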