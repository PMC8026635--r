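# prophageScreen

Detection and classification of putative **plasmid prophages** —
temperate bacteriophages that lysogenize their host as autonomous
circular plasmids instead of integrating into the chromosome — among
bacterial plasmid sequences.

In sequencing archives such molecules are deposited as ordinary
plasmids, yet their genomes carry a recognizable signature: phage
DNA-packaging and head genes (terminase, major capsid protein), tail
genes (tape measure protein; a tail sheath in myovirus-like elements),
and plasmid maintenance machinery — a partitioning system (ParA / ParM /
TubZ motor with a small DNA-binding adapter encoded immediately
downstream) and/or site-specific recombinases (XerC-like tyrosine
recombinases; small serine recombinases). `prophageScreen` turns this
signature into a reproducible pipeline:

1. **Deduplicate** plasmid genomes (greedy clustering, 99% identity /
   99% coverage, banded global nucleotide alignment);
2. **Build profile HMMs** for the marker families (greedy family
   clustering at 20% identity / 80% coverage, center-star multiple
   alignment, Krogh-style profiles with Viterbi/Forward scoring and
   optional shuffled-decoy Gumbel E-value calibration);
3. **Screen** every proteome, keeping genomes with hits for at least a
   terminase **and** a major capsid protein (size window 15–500 kbp);
4. **Cluster** the selected proteomes into homologous gene families
   (all-vs-all Smith–Waterman with Karlin–Altschul statistics,
   E ≤ 1e-5 and ≥ 75% query coverage; bidirectional best hits;
   COGtriangles triangle merging) and build the genome × cluster
   **pangenome matrix**, exported as a bipartite protein-sharing
   network (GraphML);
5. **Group** genomes by shared protein content (min-normalized
   similarity ≥ 0.5, connected components; ungrouped genomes are
   singletons);
6. **Classify** each genome by a deterministic rule cascade:
   - **R1** no terminase or no major capsid protein → `non_phage_plasmid`
   - **R2** head markers but neither partitioning motor nor recombinase →
     `putative_virulent_phage`
   - **R3** truncated terminase, or tape measure protein present but not
     intact (split/short) → `putative_degenerated_plasmid_prophage`
   - **R4** otherwise → `putative_active_plasmid_prophage`

   with a morphotype call (`myovirus_like` if a sheath is present, else
   `siphovirus_like` if a tape measure protein is present, else
   `undetermined`) and machine-readable evidence per genome.

A synthetic-data generator (`generatorSpec()` / `makeGenomes()`) emits
plasmid genomes with planted marker families, prophage states,
duplicates, near-duplicates, split/truncated genes and group structure,
plus a truth table, so the whole pipeline can be validated end to end
without network access.

## Worked example

A self-contained run on a reduced synthetic world (12 genomes: 4 planted
active prophages, 2 degenerated, 1 virulent-like, 5 ordinary plasmids,
2 planted groups):

```r
library(prophageScreen)
spec <- generatorSpec(seed = 5, nGenomes = 12,
                      stateMix = c(active = 4, degenerated = 2,
                                   virulent = 1, non_phage = 5),
                      nGroups = 2, genomeLengthRange = c(15000, 25000))
res <- runPipeline("out", seed = 5, spec = spec)
res$report$counts
```

```
                                  state n percent
1      putative_active_plasmid_prophage 4    33.3
2 putative_degenerated_plasmid_prophage 2    16.7
3               putative_virulent_phage 1     8.3
4                     non_phage_plasmid 5    41.7
```

Every planted state is recovered: the 7 phage-bearing genomes pass the
two-marker screen, the 5 ordinary plasmids are rejected at rule R1, the
split-TMP and truncated-terminase genomes are called degenerated at R3,
and the motor-less, recombinase-less genome is called a putative
virulent phage at R2. The two planted genome groups come back as the two
connected components of the protein-sharing network:

```r
res$groups
```

```
  group_id genome_id is_singleton
1        1       G01        FALSE
2        1       G02        FALSE
3        1       G03        FALSE
4        2       G04        FALSE
5        2       G05        FALSE
6        2       G06        FALSE
7        3       G07         TRUE
```

`out/` now holds every stage artifact: `dedup_clusters.tsv`,
`profiles/*.json`, `marker_table.tsv`, `selected.txt`,
`homology_hits.tsv`, `clusters.tsv`, `pangenome.tsv`,
`network.graphml`, `groups.tsv`, `calls.tsv`, `counts.tsv` and a
deterministic `log.txt`. Reruns with the same seed are byte-identical.

A thin command-line wrapper is provided at
`inst/scripts/prophage-pipeline.R` (`synth` and `run` subcommands);
every stage is also an exported function (`greedyCluster()`,
`buildMarkerProfiles()`, `screenGenomes()`, `allVsAll()`, `bbhPairs()`,
`cogTriangles()`, `buildPangenome()`, `makeGroups()`,
`extractFeatures()`, `classifyFeatures()`).

## Acceptance script

`scripts/acceptance.R` re-runs the complete pipeline from scratch on the
default synthetic world (40 unique genomes: 12 active / 6 degenerated /
2 virulent-like / 20 non-phage, 3 planted groups, planted exact /
99.5% / 98% duplicate pairs) and writes its JSON report:

```sh
Rscript scripts/acceptance.R --seed 1 --out results/acceptance.json
```

The substantive validation lives in the test suite
(`tests/testthat/test-acceptance.R`): exhaustive-enumeration oracles for
the alignment and profile-HMM kernels, a brute-force COGtriangles
oracle, planted-duplicate deduplication behavior, exact recovery of the
planted selection, states, groups and morphotypes, single-gene
perturbation sensitivity, decoy-calibration sanity and byte-level
determinism of the output tree.

See the vignette (`vignettes/plasmid-prophage-screening.Rmd`) for the
model, its assumptions, every tunable threshold and the known
limitations.
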