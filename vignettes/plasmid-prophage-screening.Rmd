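---
title: "Screening plasmid sequences for putative plasmid prophages"
author: "prophageScreen"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Screening plasmid sequences for putative plasmid prophages}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

## The problem

Temperate bacteriophages can lysogenize a host either by integrating into
its chromosome or by replicating as an autonomous circular plasmid in the
cytoplasm. In whole-genome sequencing archives such plasmid prophages are
routinely deposited as ordinary plasmids, because nothing in a circular
contig announces that it is a phage. Their genomes, however, carry a
recognizable signature: DNA-packaging and head genes (a terminase and a
major capsid protein), tail genes (in siphovirus-like elements a long
tape measure protein, in myovirus-like elements additionally a tail
sheath), and the maintenance machinery of a plasmid — a partitioning
system (a ParA Walker-ATPase, ParM actin-like or TubZ tubulin-like motor
with a small DNA-binding adapter encoded immediately downstream) and/or a
site-specific recombinase (XerC-like tyrosine recombinases, or serine
recombinases whose function tracks their length: roughly 200-aa
resolvases/invertases versus 400-aa-plus integrases).

`prophageScreen` turns this signature into a reproducible pipeline:
deduplicate the plasmid set, screen every proteome with marker profile
HMMs, keep genomes carrying at least a terminase and a major capsid
protein, cluster the selected proteomes into homologous gene families,
group genomes by shared protein content, and classify every genome into
one of four states — putative active plasmid prophage, putative
degenerated plasmid prophage (split or truncated key genes), putative
virulent phage (head/tail genes but no maintenance machinery), or
ordinary plasmid — together with a tail morphotype.

## Pipeline stages and their parameters

All thresholds live in a single `ScreenConfig` object
(`screenConfig()`); the defaults are:

* **Size filter.** Plasmids of 15--500 kbp, bounds inclusive. Smaller
  replicons cannot hold a complete tailed-phage gene complement; larger
  ones are chromids or megaplasmids.
* **Genome deduplication.** Greedy incremental clustering at 99%
  identity and 99% bidirectional coverage on global nucleotide
  alignments, the representative being the longest (then
  lexicographically first) member. Identity is counted over all
  alignment columns, gaps included.
* **Marker profiles.** Reference protein sets for each of the marker
  families (terminase, major capsid protein, tape measure protein, XerC,
  ParA, ParM, TubZ, plus auxiliary sheath and serine-recombinase
  families) are clustered at 20% identity / 80% coverage (local mode);
  clusters of 10 or more sequences are aligned with a center-star
  multiple alignment and compiled into profile HMMs. Match states are
  alignment columns with a majority (>50%) of residues; emissions and
  transitions are Laplace(+1)-smoothed counts; insert states emit the
  background.
* **Screen.** Every protein is scored against every profile with a local
  Viterbi log-odds algorithm (free entry/exit at any match state,
  cost-free flanks). The default acceptance rule is a 25-bit score
  threshold; alternatively profiles can be calibrated on shuffled decoys
  (Gumbel fit by the method of moments) and an E-value cutoff in the
  1e-1..1e-3 range applied, with the database size set to the number of
  proteins searched in the run. A genome is selected when it has
  qualifying hits for *both* terminase and major capsid protein.
* **Orthology.** All-vs-all Smith--Waterman between the selected
  proteomes with Karlin--Altschul statistics (BLOSUM62, gap open/extend
  -11/-1, gapped lambda = 0.267, K = 0.041); directed hits need E <=
  1e-5 and 75% query coverage. Bidirectional best hits (ties broken by
  coverage, then identifier) seed COGtriangles clustering: triangles of
  pairwise-BBH proteins from three distinct genomes are merged when they
  share an edge. Proteins in no triangle stay singletons.
* **Grouping.** From the genome-by-cluster presence/absence matrix
  (exported as a bipartite GraphML network), genome pairs are connected
  when they share at least 50% of the smaller genome's clusters;
  connected components are the groups, size-1 components the singletons.
* **Classification.** A pure rule cascade over per-genome features:
  R1 no terminase or no major capsid protein -> ordinary plasmid;
  R2 head markers but neither motor nor recombinase -> putative virulent
  phage; R3 truncated terminase or non-intact tape measure protein ->
  putative degenerated plasmid prophage; R4 otherwise -> putative active
  plasmid prophage. Morphotype: sheath -> myovirus-like, else tape
  measure protein -> siphovirus-like, else undetermined.

### Classifier feature thresholds

The expert judgments behind published calls are formalized as
configurable thresholds: a tape measure protein is *intact* when its
best hit lies on a single CDS of at least 900 aa — comfortably above
reported split fragments (up to ~790 aa) and below intact examples
(1,200--2,200 aa); a terminase is *truncated* below 80% profile
match-state coverage; a partitioning *adapter* is a CDS of at most
150 aa within two genes downstream of the motor on the same strand;
serine recombinases of at most 250 aa are called
resolvases/invertases, of at least 400 aa integrase-like. Split genes
that might stem from frameshifting sequencing errors are *not*
second-guessed: the genome is called degenerated and the caveat recorded
in the report.

## The synthetic world

Real inputs (GenBank plasmid records) are not redistributable and not
reproducible over time, so validation runs on a generator
(`generatorSpec()`, `makeGenomes()`) whose defaults are a fixed, stated
world: 40 unique genomes of 15--120 kbp — 12 active / 6 degenerated /
2 virulent-like / 20 non-phage — with three planted groups sharing
diverged cargo repertoires, marker family members at 20% i.i.d.
substitution divergence (expected pairwise identity
$(1-d)^2 + d^2/19 \approx 0.64$), two active genomes carrying a sheath
gene, and three planted duplicate pairs: one exact copy, one at 99.5%
nucleotide identity, one at 98% (the last must *survive*
deduplication). Genes are reverse-translated with uniform codon choice;
intergenic DNA is random. Duplicate point mutations are placed in
intergenic DNA only, so CDS translations stay consistent with the
emitted protein FASTA while whole-genome identity equals the planted
value.

What the generator does *not* emulate — and hence what a green test does
not establish — includes: realistic phage gene order and operon
structure, codon usage, nucleotide-level indels and recombination,
intra-genome paralogs, and circular-permutation effects (genomes are
emitted linearized from a fixed origin; rotation-invariant deduplication
is out of scope). Marker families never share ancestry, so cross-family
hits in tests diagnose scoring bugs, not remote homology; real marker
families are not this cleanly separated.

## Numerical and algorithmic choices

* **Exact DP instead of heuristic search.** BLAST-style heuristics are
  replaced by full Needleman--Wunsch / Smith--Waterman with affine gaps
  (first gap residue `gapOpen`, further residues `gapExtend`);
  traceback ties break diagonal > up > left, making alignments
  deterministic. Scores are checked in the test suite against exhaustive
  alignment enumeration (short pairs) and against an independent aligner.
* **Banded deduplication alignments.** Whole-genome global alignment at
  120 kbp is infeasible unbanded. Any alignment reaching identity $t$
  has at most $(1-t)\cdot\mathrm{cols}$ non-identical columns, so its
  path stays within a diagonal band of that width; the dedup aligner
  therefore uses a band of $(1-t)L + |\Delta L| + 32$ columns, which is
  exact for every pair that could pass the threshold. Two further exact
  rejects: a length ratio below $t$ caps identity below $t$, and a pair
  reaching identity $t$ must share an exact run of at least
  $t/(1-t) \approx 99$ columns, so pairs sharing no 64-mer are rejected
  without alignment.
* **Profile HMM.** A Krogh-style architecture (match/insert/delete, no
  plan7 flanking states); local alignment is implemented as free entry
  and exit at match states with cost-free flanking residues. Viterbi and
  Forward are verified against exhaustive state-path enumeration; Forward
  is never below Viterbi.
* **COGtriangles merging.** Merging is strictly by shared *edge* (a
  common BBH pair); merging by shared vertex over-merges and is
  rejected. On adversarial instances edge-merging can leave one protein
  in two clusters; to keep the output a partition such overlaps are
  resolved by merging the affected clusters — a conflict-resolution
  step, not a primary merge rule. The brute-force oracle in the tests
  implements the identical two-phase rule.
* **Group similarity.** Min-normalized shared-cluster count rather than
  Jaccard, so a gene-poor degenerated prophage still groups with its
  intact relatives. The 0.5 default threshold cleanly separates the
  generator's within-group similarity (~1.0) from the between-genome
  marker-only overlap (<=0.47); with real data this threshold is the
  first parameter to revisit, since published groupings also weighed
  genome length, tRNAs and synteny, which are out of scope here.
* **E-value calibration.** Bit scores of background decoys follow an
  extreme-value distribution; a Gumbel is fitted by the method of
  moments (beta = sd * sqrt(6)/pi, mu = mean - gamma * beta). The fit is
  a tail approximation: the suite checks monotonicity and that the
  false-hit count at a 1e-2 per-sequence tail probability on 1,000
  fresh decoys stays within a 3-sigma binomial bound of the expected 10.
* **Determinism.** Every source of randomness flows from a single seed;
  logs carry no timestamps; two runs with the same configuration are
  byte-identical, and the suite checks this over the whole output tree.
* **Configuration.** A flat `key: value` text file (no YAML dependency
  is available in the target environment) mirrors the generator and
  screen parameters; `inst/scripts/prophage-pipeline.R` provides `synth`
  and `run` subcommands, and every stage is an exported function.

## Degenerate inputs and edge cases

Empty sequences are input errors; residues absent from the substitution
matrix are reported by symbol. Ambiguous amino acids emit the background
distribution in profile search (log-odds 0). A genome with no proteins
appears in the marker table as an all-absent row and classifies as an
ordinary plasmid. An empty local alignment (no positive-scoring pair)
has score 0, empty spans and identity 0. Profiles require at least one
alignment column with a residue majority. Six-frame ORF scanning
translates codons containing non-ACGT symbols as `X` rather than
discarding the ORF.

## Known limitations

The screen cannot distinguish a *bona fide* plasmid prophage from a
prophage integrated into a resident plasmid; no claim about inducibility
or biological activity is made — degeneration calls are structural.
Packaging strategy (cos/headful/terminal repeats), replication-module
annotation and taxonomy are out of scope. The acceptance criteria
validate internal consistency and planted-truth recovery on synthetic
data; they do not validate recall on real GenBank plasmids, for which
the profile quality of the marker reference sets is the binding
constraint.
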