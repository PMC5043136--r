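---
title: "Methods: reconstructing gene family duplication histories"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: reconstructing gene family duplication histories}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(duphist)
```

## The problem

Plant genomes carry the scars of repeated whole-genome duplications
(WGDs): the ancient hexaploidy (γ) shared by the rosids, the α/β
duplications of the *Arabidopsis* lineage, and the "salicoid" (p)
duplication of *Populus*. A gene family observed today in several related
genomes is the net result of those genome-wide events, of local tandem
duplications, and of extensive gene loss. `duphist` reconstructs that
history for one focal family: which present-day genes are paralogs or
orthologs, under what selective regime they diverged, which pairs sit on
duplicated chromosome segments, which duplication era each segment dates
to, and how many copies of each ancestral locus each genome has retained.

Every stage is a tibble-in/tibble-out function, so the pipeline can be run
end to end with `run_pipeline()` or stage by stage with the pipe.

## Homology and pair calling

All searches run on CDS nucleotide sequences. `local_align()` computes the
single best local alignment per pair by full affine-gap dynamic programming
(match +2, mismatch −3, gap open 5, gap extend 2 — the classic BLASTN-like
scheme; no heuristic seeding, since family-scale inputs are small).
Identity is identical columns over *all* alignment columns, gaps included.

Two genes of one species are **paralogs** when identity exceeds 40% and
the alignment spans more than 300 bp — both strict inequalities. Two genes
of different species are **orthologs** when they are reciprocal best hits
and both alignments span at least 300 columns (ties broken by identity,
then gene id, for determinism). `all_vs_all()` reports hits above a score
floor of 50; the calling thresholds are applied downstream so they remain
visible and configurable.

## Ka/Ks (NG86) and selection regimes

For each pair the proteins are aligned globally (BLOSUM62, gap open 10 /
extend 1), the alignment is back-translated to codons (gapped columns
dropped and counted), and Ka/Ks is estimated with the Nei–Gojobori (1986)
counting method:

* **Sites.** For each codon position the three single-nucleotide neighbors
  are enumerated; mutations creating a stop codon are excluded from both
  numerator and denominator at that position. Each position contributes
  exactly one site, so N + S = 3L.
* **Differences.** Codons differing at k positions are averaged uniformly
  over all k! substitution orders; pathways through stop codons are
  excluded (if every pathway is blocked, the k differences are split
  equally). A brute-force pathway enumerator in the test suite checks all
  61 × 61 sense-codon pairs exactly.
* **Correction.** Jukes–Cantor, `d = −¾ log(1 − 4p/3)`. Proportions at or
  beyond the p = ¾ ceiling are reported as saturated (`Ks = NA`, flagged),
  never dropped silently.

ω = Ka/Ks is classified as strong purifying (< 0.5), relaxed purifying
(0.5 ≤ ω < 1), neutral (ω = 1 within 1e−9), or positive (> 1); the 0.5
split mirrors the band commonly highlighted in family-wide selection
scans.

NG86 was fixed as the counting model because it is fully specifiable and
oracle-testable; other counting or ML estimators (YN00, GY94) are out of
scope. Estimates from different models can differ by a few hundredths at
moderate divergence, which is why downstream era intervals are broad.

## Microsynteny, tandem arrays, and ancestral groups

A pair of family genes anchors a **syntenic block** when, among the k
genes upstream and downstream of each anchor (default k = 50, truncated at
chromosome ends), at least three flanking pairs are homologous. Flank
matching is a greedy best-score one-to-one matching, so one repetitive
flanking gene cannot satisfy the rule by itself. Flank hits use a relaxed
floor (identity > 40%, > 150 bp) because background genes are often
shorter than family genes. Block **quality** is
`2 × matches / (size_a + size_b) × 100`, with the anchor pair counted as a
match.

A pair is a **tandem duplication** when both genes are family members on
one chromosome, their nearest span boundaries lie within 60 kb, and at
most five non-family gene loci sit strictly between them; intervening
family members extend the chain instead of counting toward the limit, and
passing pairs are merged transitively into maximal clusters. When a pair
satisfies both the tandem rule and the block rule, tandem wins — the two
classes are treated as disjoint.

Block anchor pairs, within and across species, form a graph whose
connected components are the **ancestral groups** ("A", "B", …, ordered by
size then smallest gene id; invariant to input order).

## Dating and the retention matrix

Each within-species block is dated by the **median Ks** over its anchor
and flank pairs (saturated pairs excluded, contributing count reported)
and assigned to a duplication era by pure interval lookup in an
`era_config()`. The shipped rosid-like defaults place the literature
medians inside padded intervals — e.g. Populus p: reference 0.27 in
[0.1, 0.6]; Populus γ: 1.54 in [1.2, 2.6]; Arabidopsis α: 0.86 in
[0.5, 1.3] with β merged into the γ interval (the two are nearly
indistinguishable by Ks); Vitis γ: 1.22 in [0.8, 2.2]; Carica γ: 1.76 in
[0.8, 2.6]. The sources give medians, not boundaries, so the intervals are
midpoint-padded and fully configurable; values outside every interval are
labeled `unassigned` rather than forced into an era.

The **retention matrix** has one row per ancestral group and, per species,
`1 + extra` duplicate slots where the slot count is the product of the
species' era multipliers (post-γ benchmark: 4:2:1:1 for an
At/Pt/Vv/Cp-like clade). Slots are filled with retained family genes;
collinear counterparts that are no longer family members are recorded as
sub-functionalized ("N" loci); empty slots are losses. When one species
contributes more genes than slots (tandem expansion), the extras share the
last slot so the cell count stays conserved.
`expected_multiplicity_check()` reports observed versus expected counts
and count ratios normalized to a benchmark species.

## Phylogeny

Protein distances use the p-distance with pairwise gap deletion (Poisson
correction by flag); trees are built by neighbor joining — additive
matrices are recovered exactly, and negative branch estimates are clamped
to zero with a flag. Bootstrap support resamples alignment columns
(default 1000 replicates; seeded, so support values are reproducible) and
reports the percentage of replicate trees containing each original
bipartition. `clade_mean_distance()` summarizes within-subfamily
divergence; subfamily membership is a user-supplied label (there is no
computable sequence rule for, e.g., 9-LOX vs 13-LOX positional
specificity), defaulting in simulations to the founder lineage.
Minimum-evolution search is not implemented; on these data NJ and ME are
reported in the literature to give identical topologies.

Multiple alignment: simulated homologs are colinear (the simulator never
inserts indels), so their "alignment" is the identity; length-divergent
real inputs go through the mafft command-line aligner.

## The synthetic-genome simulator

The simulator is the package's ground-truth instrument, not a fixture. It
emulates what the analysis consumes: multi-chromosome ordered gene
catalogs (GFF3 + CDS/protein FASTA) with a focal family among background
genes, and planted events recorded in a truth table.

* **Sequence evolution.** `evolve_cds_pair()` proposes uniform random
  single-nucleotide changes; synonymous proposals are accepted, whereas
  nonsynonymous ones are accepted with probability ω, and proposals creating
  stops are rejected. The number of synonymous substitutions to accumulate
  is Poisson with mean `target_ks × S(input)`, which makes the NG86
  estimator approximately unbiased at low divergence (the recovery checks
  measure a mean estimate within ~2% of the target at Ks 0.5 for
  1000-codon genes).
* **Events.** `apply_wgd()` duplicates every chromosome and retains each
  duplicate independently (losses logged); `apply_tandem_array()` inserts
  diverged copies downstream of a gene at a controlled boundary gap with
  optional intervening background loci; `apply_speciation()` derives a
  daughter genome, keeping a shared core id as the ortholog truth map.
* **Study design.** `simulate_rosid_clade()` is the flagship condition: an
  ancestor of 2 chromosomes × 20 genes with 2 family founders; background
  genes of 110–150 codons and family genes of 780–880 codons (family ORFs
  of ~2.4–2.8 kb match the real inventories this kind of analysis is run
  on, and keep deep anchors alignable); a shared γ-like WGD at Ks 1.5 with
  retention 0.8; speciation into four lineages at Ks 0.05; a recent WGD
  (Ks 0.3, retention 0.8) in the second lineage; one tandem array in the
  third. Analysis of these clades uses window k = 6 — on 20-gene
  chromosomes that is already a third of the chromosome, and it keeps a
  20-replicate recovery experiment a few minutes long.

What the simulator does **not** emulate: intron/intergenic sequence
content (coordinates only), strand variation (single-strand by default),
inversions/translocations, assembly or annotation error, and rate
variation across sites. Passing recovery tests therefore demonstrate the
correctness of the calling rules under clean annotations, not robustness
to noisy real genomes.

## Numerical and design choices

* Strict vs inclusive thresholds follow the stated rules literally:
  paralogs > 40% and > 300 bp (strict), orthologs ≥ 300 bp.
* Gene-to-gene distance for the tandem rule is the nearest-boundary gap,
  which is what makes published neighbor-pair coordinates (e.g. two family
  genes 12.3 kb apart on one supercontig) pass the 60 kb rule.
* Best-hit and flank-matching ties break deterministically (score, then
  identity, then lexicographic id).
* All stochastic steps (simulator, bootstrap) take explicit integer seeds;
  identical seeds give byte-identical exports.
* Era intervals are configuration, not inference: a block median falling
  outside every interval stays `unassigned`.

## Problem sizes used by the checks

The shipped tests and the acceptance script use: all 61 × 61 codon pairs
for the NG86 oracle; 100 replicate 1000-codon pairs at (Ks 0.5, ω 0.2)
for estimator recovery; 20 seeded clades of the flagship design for
planted-event recovery; and 50 random additive 8-taxon trees for NJ. These
sizes give binomial-scale standard errors well inside the asserted bands.

## Known limitations

* A single counting model (NG86); saturated pairs are flagged, not
  rescued by ML.
* One best local alignment per pair (no multi-HSP tiling), as the calling
  rules reference a single identity/length per pair.
* The block detector anchors only on family-member pairs; a family gene
  whose collinear counterpart left the family enters the retention matrix
  as an "N" locus only if that counterpart appears among supplied group
  members.
* Cross-species blocks are not era-dated (speciation, not duplication,
  separates those anchors).
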