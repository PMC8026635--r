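#' @include profile.R
NULL

#' Marker families profiled by the screen
#'
#' The seven core markers (terminase, major capsid protein, tape measure
#' protein, XerC-like tyrosine recombinase, ParA/ParM/TubZ partitioning
#' motors) plus the auxiliary tail sheath and serine recombinase profiles
#' used for morphotype and recombinase calls.
#'
#' @format character vector of family names.
#' @export
PROFILED_MARKERS <- c("terminase", "mcp", "tmp", "xerC", "parA", "parM",
                      "tubZ", "sheath", "serine_recombinase")

#' Motor (partitioning-system) marker names
#' @format character vector.
#' @export
MOTOR_MARKERS <- c("parA", "parM", "tubZ")

#' Construct a screening configuration
#'
#' Defaults encode the screen thresholds: plasmid size window 15-500 kbp
#' (inclusive), required markers terminase + major capsid protein, 25-bit
#' profile hit threshold, protein families of 10 or more members used for
#' profile building, genome deduplication at 99% identity / 99% coverage,
#' orthology at 75% query coverage and E-value 1e-5, genome grouping at 0.5
#' shared-content similarity, an intact tape measure protein of at least
#' 900 aa, terminase truncation below 80% profile coverage, a partitioning
#' adapter of at most 150 aa, and serine recombinase classes at <= 250 aa
#' (resolvase/invertase) and >= 400 aa (integrase-like).
#'
#' @param minLenBp,maxLenBp inclusive genome size window.
#' @param requiredMarkers markers a genome must hit to be selected.
#' @param hitBits profile bit-score threshold.
#' @param hitEvalue E-value cutoff for calibrated profiles (`NA` = use bits).
#' @param familyMinSize minimum family cluster size for profiles.
#' @param dedupIdentity,dedupCoverage genome dedup thresholds.
#' @param orthoQueryCoverage,orthoEvalue all-vs-all homology thresholds.
#' @param groupThreshold genome grouping similarity threshold.
#' @param tmpMinAa,terminaseCovMin,adapterMaxAa,serineSmallMaxAa,serineLargeMinAa
#'   classifier feature thresholds.
#' @return A [ScreenConfig].
#' @export
screenConfig <- function(minLenBp = 15000, maxLenBp = 500000,
                         requiredMarkers = c("terminase", "mcp"),
                         hitBits = 25, hitEvalue = NA_real_,
                         familyMinSize = 10L,
                         dedupIdentity = 0.99, dedupCoverage = 0.99,
                         orthoQueryCoverage = 0.75, orthoEvalue = 1e-5,
                         groupThreshold = 0.5,
                         tmpMinAa = 900, terminaseCovMin = 0.8,
                         adapterMaxAa = 150,
                         serineSmallMaxAa = 250, serineLargeMinAa = 400) {
  new("ScreenConfig", minLenBp = minLenBp, maxLenBp = maxLenBp,
      requiredMarkers = requiredMarkers, hitBits = hitBits,
      hitEvalue = hitEvalue, familyMinSize = as.integer(familyMinSize),
      dedupIdentity = dedupIdentity, dedupCoverage = dedupCoverage,
      orthoQueryCoverage = orthoQueryCoverage, orthoEvalue = orthoEvalue,
      groupThreshold = groupThreshold, tmpMinAa = tmpMinAa,
      terminaseCovMin = terminaseCovMin, adapterMaxAa = adapterMaxAa,
      serineSmallMaxAa = serineSmallMaxAa, serineLargeMinAa = serineLargeMinAa)
}

#' Filter plasmid genomes by size
#'
#' Retains genomes whose length lies inside the inclusive
#' `[minLenBp, maxLenBp]` window of the configuration.
#'
#' @param genomes a [Biostrings::DNAStringSet] of plasmid genomes.
#' @param cfg a [ScreenConfig].
#' @return The filtered `DNAStringSet`.
#' @export
sizeFilter <- function(genomes, cfg = screenConfig()) {
  w <- Biostrings::width(genomes)
  genomes[w >= cfg@minLenBp & w <= cfg@maxLenBp]
}

#' Search whole proteomes against a set of marker profiles
#'
#' Runs every protein against every profile and collects accepted hits.
#'
#' @param proteins protein table: a `data.frame` with columns `protein_id`,
#'   `genome_id`, `seq` (and coordinate columns, which are carried along).
#' @param profiles named list of [ProfileHMM] objects.
#' @param cfg a [ScreenConfig] supplying the acceptance threshold.
#' @return `data.frame` with one row per accepted hit: `protein_id`,
#'   `genome_id`, `profile`, `bit_score`, `evalue`, `coverage`, `start`,
#'   `end`.
#' @export
searchProteome <- function(proteins, profiles, cfg = screenConfig()) {
  eCutoff <- if (is.na(cfg@hitEvalue)) NULL else cfg@hitEvalue
  dbSize <- nrow(proteins)
  hits <- vector("list", length(profiles) * nrow(proteins))
  n <- 0L
  for (p in profiles) {
    for (i in seq_len(nrow(proteins))) {
      h <- searchProfile(p, proteins$seq[i], bits = cfg@hitBits,
                         eCutoff = eCutoff, dbSize = dbSize)
      if (!is.null(h)) {
        n <- n + 1L
        hits[[n]] <- cbind(data.frame(protein_id = proteins$protein_id[i],
                                      genome_id = proteins$genome_id[i],
                                      stringsAsFactors = FALSE), h)
      }
    }
  }
  if (n == 0L)
    return(data.frame(protein_id = character(), genome_id = character(),
                      profile = character(), bit_score = numeric(),
                      evalue = numeric(), coverage = numeric(),
                      start = integer(), end = integer(),
                      stringsAsFactors = FALSE))
  do.call(rbind, hits[seq_len(n)])
}

#' Two-marker genome screen
#'
#' Applies the genome-level selection rule: a genome is selected when it
#' has a qualifying profile hit for every required marker (by default
#' terminase and major capsid protein). The marker table records the best
#' hit per genome per marker for all profiled markers, required or not;
#' genomes with no proteins appear with an all-absent row.
#'
#' @param proteins protein table (see [searchProteome()]), or a
#'   precomputed hit table via `hits`.
#' @param profiles named list of [ProfileHMM] objects; must include every
#'   required marker.
#' @param cfg a [ScreenConfig].
#' @param genomeUniverse genome identifiers to report on (defaults to the
#'   genomes present in `proteins`).
#' @param hits optional precomputed hit table from [searchProteome()].
#' @return list with `markerTable` (`data.frame`, one row per genome and
#'   marker with `NA` bits where absent), `selected` (character vector of
#'   genome ids) and `hits` (the full hit table).
#' @export
screenGenomes <- function(proteins, profiles, cfg = screenConfig(),
                          genomeUniverse = NULL, hits = NULL) {
  missing <- setdiff(cfg@requiredMarkers, names(profiles))
  if (length(missing))
    stop("required marker profile(s) missing: ", paste(missing, collapse = ", "))
  if (is.null(genomeUniverse)) genomeUniverse <- unique(proteins$genome_id)
  if (is.null(hits)) hits <- searchProteome(proteins, profiles, cfg)

  markerNames <- names(profiles)
  grid <- expand.grid(genome_id = genomeUniverse, marker = markerNames,
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  best <- lapply(seq_len(nrow(grid)), function(i) {
    h <- hits[hits$genome_id == grid$genome_id[i] &
              hits$profile == grid$marker[i], , drop = FALSE]
    if (!nrow(h)) return(data.frame(protein_id = NA_character_,
                                    bit_score = NA_real_, evalue = NA_real_,
                                    coverage = NA_real_, stringsAsFactors = FALSE))
    h <- h[order(-h$bit_score, h$protein_id), , drop = FALSE]
    data.frame(protein_id = h$protein_id[1], bit_score = h$bit_score[1],
               evalue = h$evalue[1], coverage = h$coverage[1],
               stringsAsFactors = FALSE)
  })
  markerTable <- cbind(grid, do.call(rbind, best))

  selected <- vapply(genomeUniverse, function(g) {
    all(vapply(cfg@requiredMarkers, function(mk) {
      any(!is.na(markerTable$bit_score[markerTable$genome_id == g &
                                       markerTable$marker == mk]))
    }, logical(1)))
  }, logical(1))
  list(markerTable = markerTable,
       selected = genomeUniverse[selected],
       hits = hits)
}

#' Six-frame open reading frame scan
#'
#' Nucleotide-only fallback when no annotation is available: finds ORFs on
#' both strands in all three frames, taking each stretch between stop
#' codons, starting at the first ATG (optionally also GTG/TTG, translation
#' table 11 style) and ending at the stop. Coordinates are 1-based
#' inclusive on the forward strand, including the stop codon when present.
#'
#' @param genome a character string or [Biostrings::DNAString] genome.
#' @param genomeId genome identifier for the output table.
#' @param minAa minimum protein length in amino acids (>= 20).
#' @param altStarts also accept GTG and TTG start codons.
#' @return protein table `data.frame`: `protein_id`, `genome_id`, `start`,
#'   `end`, `strand`, `seq`, `length_aa`.
#' @export
orfScan <- function(genome, genomeId = "genome", minAa = 50L,
                    altStarts = FALSE) {
  if (minAa < 20) stop("minAa must be at least 20")
  s <- toupper(as.character(genome))
  L <- nchar(s)
  starts <- if (altStarts) c("ATG", "GTG", "TTG") else "ATG"
  stops <- c("TAA", "TAG", "TGA")
  rows <- list()
  for (strand in c("+", "-")) {
    str <- if (strand == "+") s else
      as.character(Biostrings::reverseComplement(Biostrings::DNAString(s)))
    for (frame in 0:2) {
      nc <- (nchar(str) - frame) %/% 3
      if (nc < 1) next
      codons <- substring(str, frame + 1 + 3 * (seq_len(nc) - 1),
                          frame + 3 * seq_len(nc))
      isStop <- codons %in% stops
      bounds <- c(0L, which(isStop), nc + 1L)
      for (b in seq_len(length(bounds) - 1L)) {
        lo <- bounds[b] + 1L; hi <- bounds[b + 1L] - 1L
        if (hi < lo) next
        seg <- codons[lo:hi]
        st <- which(seg %in% starts)
        if (!length(st)) next
        first <- lo + st[1] - 1L
        aaLen <- hi - first + 1L
        if (aaLen < minAa) next
        hasStop <- bounds[b + 1L] <= nc
        cdsEndCodon <- if (hasStop) bounds[b + 1L] else hi
        p1 <- frame + 1L + 3L * (first - 1L)          # on current strand
        p2 <- frame + 3L * cdsEndCodon
        if (strand == "+") { fs <- p1; fe <- p2 } else {
          fs <- nchar(str) - p2 + 1L; fe <- nchar(str) - p1 + 1L
        }
        aa <- .translateCodons(seg[st[1]:length(seg)])
        rows[[length(rows) + 1L]] <-
          data.frame(genome_id = genomeId, start = fs, end = fe,
                     strand = strand, seq = aa, length_aa = aaLen,
                     stringsAsFactors = FALSE)
      }
    }
  }
  if (!length(rows))
    return(data.frame(protein_id = character(), genome_id = character(),
                      start = integer(), end = integer(), strand = character(),
                      seq = character(), length_aa = integer(),
                      stringsAsFactors = FALSE))
  out <- do.call(rbind, rows)
  out <- out[order(out$start, out$end, out$strand), , drop = FALSE]
  out <- cbind(protein_id = sprintf("%s_orf%03d", genomeId, seq_len(nrow(out))),
               out, stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

.translateCodons <- function(codons) {
  gc <- Biostrings::GENETIC_CODE
  aa <- gc[codons]
  aa[is.na(aa)] <- "X"  # codons containing non-ACGT symbols
  paste(aa, collapse = "")
}
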