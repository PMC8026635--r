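#' @include io.R
NULL

#' Build profile HMMs from marker reference families
#'
#' For each family the reference sequences are clustered greedily (local
#' mode, 20% identity / 80% coverage by default); the largest cluster with
#' at least `minSize` members is aligned by [centerStarMSA()] and turned
#' into a [ProfileHMM]. Families whose clusters all fall below `minSize`
#' are skipped.
#'
#' @param familySets named list of named character vectors (one per
#'   family), e.g. from [makeMarkerFamilies()] or [readMarkerFamilies()].
#' @param minSize minimum cluster size (default 10).
#' @param identity,coverage family clustering thresholds.
#' @param scheme protein [ScoringScheme].
#' @return named list of [ProfileHMM] objects.
#' @export
buildMarkerProfiles <- function(familySets, minSize = 10L,
                                identity = 0.2, coverage = 0.8,
                                scheme = proteinScheme()) {
  profiles <- list()
  for (f in names(familySets)) {
    cl <- greedyCluster(familySets[[f]], minIdentity = identity,
                        minCoverage = coverage, mode = "local", scheme = scheme)
    cl <- selectFamilyClusters(cl, minSize)
    if (!length(cl)) next
    sizes <- vapply(cl, function(x) length(x$members), integer(1))
    members <- familySets[[f]][cl[[which.max(sizes)]]$members]
    msa <- centerStarMSA(members, scheme)
    profiles[[f]] <- buildProfile(msa, f)
  }
  profiles
}

.logLine <- function(lines, fmt, ...) c(lines, sprintf(fmt, ...))

#' Run the plasmid-prophage screening pipeline end to end
#'
#' Stage order: genome deduplication (greedy clustering at 99%/99%);
#' marker family clustering, center-star alignment and profile building
#' (or loading pre-built profiles); plasmid size filter; two-marker
#' profile-HMM screen; all-vs-all protein comparison of the selected
#' genomes; bidirectional best hits; COGtriangles ortholog clustering;
#' pangenome matrix; bipartite network export; shared-content genome
#' grouping; feature extraction; prophage-state classification; reports.
#' Every stage writes its artifact into `outDir` and a deterministic log
#' line with input/output counts; reruns with an identical configuration
#' and seed are byte-identical.
#'
#' @param outDir output directory (created if needed).
#' @param seed integer seed; drives the synthetic generator when no input
#'   data are supplied.
#' @param spec a [GeneratorSpec] for self-contained synthetic runs
#'   (defaults to `generatorSpec(seed = seed)`).
#' @param cfg a [ScreenConfig].
#' @param dataset optional pre-built `syntheticPlasmidSet` (overrides
#'   `spec`).
#' @param genomesFasta,proteinsFasta optional real input files (genome
#'   nucleotide FASTA plus protein FASTA with coordinate headers); used
#'   instead of the generator when both are given.
#' @param markerFastaDir directory of per-family reference multi-FASTA
#'   files (required with `genomesFasta`), or `NULL` to use the
#'   generator's families.
#' @param profiles optional pre-built named list of [ProfileHMM]s,
#'   bypassing family clustering.
#' @param configFile optional flat key/value configuration file parsed by
#'   [readPipelineConfig()]; its values override `spec` and `cfg`.
#' @return Invisibly, a list with all stage artifacts: `dataset`, `dedup`,
#'   `profiles`, `markerTable`, `selected`, `hits`, `bbh`, `clusters`,
#'   `pangenome`, `groups`, `calls`, `report`, `outDir`.
#' @export
runPipeline <- function(outDir, seed = 1L, spec = NULL, cfg = screenConfig(),
                        dataset = NULL, genomesFasta = NULL,
                        proteinsFasta = NULL, markerFastaDir = NULL,
                        profiles = NULL, configFile = NULL) {
  if (!is.null(configFile)) {
    if (!file.exists(configFile)) stop("config file not found: ", configFile)
    conf <- readPipelineConfig(configFile)
    spec <- conf$spec; cfg <- conf$cfg
    seed <- spec@seed
  }
  dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
  log <- character(0)
  log <- .logLine(log, "seed: %d", as.integer(seed))

  familySets <- NULL
  if (!is.null(genomesFasta) || !is.null(proteinsFasta)) {
    if (is.null(genomesFasta) || is.null(proteinsFasta))
      stop("both genomesFasta and proteinsFasta are required for file input")
    genomes <- readGenomesFasta(genomesFasta)
    proteins <- readProteinsFasta(proteinsFasta)
    truth <- NULL
    if (is.null(profiles)) {
      if (is.null(markerFastaDir))
        stop("markerFastaDir (or profiles) is required with file input")
      familySets <- readMarkerFamilies(markerFastaDir)
    }
  } else {
    if (is.null(dataset)) {
      if (is.null(spec)) spec <- generatorSpec(seed = seed)
      dataset <- makeGenomes(spec)
    }
    writeSyntheticData(dataset, file.path(outDir, "inputs"))
    genomes <- dataset$genomes
    proteins <- dataset$proteins
    truth <- dataset$truth
    familySets <- dataset$families$members[PROFILED_MARKERS]
  }
  log <- .logLine(log, "stage input: genomes=%d proteins=%d",
                  length(genomes), nrow(proteins))

  ## 1. genome deduplication
  dedup <- greedyCluster(setNames(as.character(genomes), names(genomes)),
                         minIdentity = cfg@dedupIdentity,
                         minCoverage = cfg@dedupCoverage,
                         mode = "global", scheme = nucleotideScheme())
  writeClustersTsv(dedup, file.path(outDir, "dedup_clusters.tsv"))
  reps <- vapply(dedup, `[[`, "", "representative")
  log <- .logLine(log, "stage dedup: in=%d unique=%d", length(genomes), length(reps))
  genomes <- genomes[names(genomes) %in% reps]

  ## 2. marker profiles
  if (is.null(profiles)) {
    profiles <- buildMarkerProfiles(familySets, minSize = cfg@familyMinSize)
  }
  profDir <- file.path(outDir, "profiles")
  dir.create(profDir, showWarnings = FALSE)
  for (f in names(profiles))
    writeProfileJson(profiles[[f]], file.path(profDir, paste0(f, ".json")))
  log <- .logLine(log, "stage profiles: families=%d profiles=%d",
                  length(familySets), length(profiles))

  ## 3. size filter
  before <- length(genomes)
  genomes <- sizeFilter(genomes, cfg)
  proteins <- proteins[proteins$genome_id %in% names(genomes), , drop = FALSE]
  log <- .logLine(log, "stage size_filter: in=%d out=%d", before, length(genomes))

  ## 4. two-marker screen
  screen <- screenGenomes(proteins, profiles, cfg,
                          genomeUniverse = names(genomes))
  write.table(screen$markerTable, file.path(outDir, "marker_table.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  writeLines(sort(screen$selected), file.path(outDir, "selected.txt"))
  write.table(screen$hits, file.path(outDir, "marker_hits.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  log <- .logLine(log, "stage screen: genomes=%d selected=%d",
                  length(genomes), length(screen$selected))

  ## 5-8. orthology on the selected genomes
  selProteins <- proteins[proteins$genome_id %in% screen$selected, , drop = FALSE]
  if (length(screen$selected) >= 2 && nrow(selProteins)) {
    hits <- allVsAll(selProteins, cfg)
    bbh <- bbhPairs(hits)
    clusters <- cogTriangles(bbh, selProteins)
    pangenome <- buildPangenome(clusters, sort(screen$selected))
  } else {
    hits <- bbh <- clusters <- NULL
    pangenome <- buildPangenome(
      data.frame(cluster_id = integer(), genome_id = character(),
                 protein_id = character()), sort(screen$selected))
  }
  if (!is.null(hits))
    write.table(hits, file.path(outDir, "homology_hits.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
  if (!is.null(clusters))
    write.table(clusters, file.path(outDir, "clusters.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
  pm <- presenceMatrix(pangenome)
  write.table(cbind(genome_id = rownames(pm), as.data.frame(pm * 1L)),
              file.path(outDir, "pangenome.tsv"), sep = "\t", quote = FALSE,
              row.names = FALSE)
  log <- .logLine(log, "stage orthology: proteins=%d hits=%d bbh=%d clusters=%d",
                  nrow(selProteins), if (is.null(hits)) 0L else nrow(hits),
                  if (is.null(bbh)) 0L else nrow(bbh),
                  if (is.null(clusters)) 0L else length(unique(clusters$cluster_id)))

  exportBipartiteNetwork(pangenome, file.path(outDir, "network.graphml"),
                         file.path(outDir, "network_edges.tsv"))

  ## 9. grouping
  groups <- makeGroups(pangenome, cfg@groupThreshold)
  write.table(groups, file.path(outDir, "groups.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  nGroups <- length(unique(groups$group_id[!groups$is_singleton]))
  log <- .logLine(log, "stage grouping: selected=%d groups=%d singletons=%d",
                  length(screen$selected), nGroups, sum(groups$is_singleton))

  ## 10. classification of every unique, size-filtered genome
  calls <- lapply(sort(names(genomes)), function(g) {
    feats <- extractFeatures(g, proteins, screen$hits, cfg,
                             genomeLength = Biostrings::width(genomes)[
                               match(g, names(genomes))])
    classifyFeatures(feats)
  })
  report <- reportCalls(calls, groups, dir = outDir)
  log <- .logLine(log, "stage classify: genomes=%d active=%d degenerated=%d virulent=%d non_phage=%d",
                  length(calls),
                  sum(report$calls$state == "putative_active_plasmid_prophage"),
                  sum(report$calls$state == "putative_degenerated_plasmid_prophage"),
                  sum(report$calls$state == "putative_virulent_phage"),
                  sum(report$calls$state == "non_phage_plasmid"))

  writeLines(log, file.path(outDir, "log.txt"))
  invisible(list(dataset = dataset, dedup = dedup, profiles = profiles,
                 markerTable = screen$markerTable, selected = screen$selected,
                 markerHits = screen$hits, hits = hits, bbh = bbh,
                 clusters = clusters, pangenome = pangenome, groups = groups,
                 calls = calls, report = report, truth = truth,
                 outDir = outDir))
}
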