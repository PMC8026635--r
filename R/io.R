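#' @include synthetic.R
NULL

#' Read and write plasmid genome FASTA
#'
#' Thin wrappers over Biostrings with 60-column wrapping on output.
#'
#' @param path FASTA file.
#' @param genomes a [Biostrings::DNAStringSet].
#' @return `readGenomesFasta()` a `DNAStringSet`; writers return `path`
#'   invisibly.
#' @export
readGenomesFasta <- function(path) Biostrings::readDNAStringSet(path)

#' @rdname readGenomesFasta
#' @export
writeGenomesFasta <- function(genomes, path) {
  Biostrings::writeXStringSet(genomes, path, width = 60L)
  invisible(path)
}

#' Read and write protein FASTA with coordinate headers
#'
#' Headers follow `genome_id|protein_id|start|end|strand`; coordinates are
#' 1-based inclusive on the forward strand.
#'
#' @param path FASTA file.
#' @param proteins protein table with `protein_id`, `genome_id`, `start`,
#'   `end`, `strand`, `seq`.
#' @return `readProteinsFasta()` a protein table; writers return `path`
#'   invisibly.
#' @export
readProteinsFasta <- function(path) {
  aa <- Biostrings::readAAStringSet(path)
  parts <- strsplit(names(aa), "|", fixed = TRUE)
  bad <- which(lengths(parts) != 5L)
  if (length(bad))
    stop("malformed protein FASTA header at record ", bad[1],
         " (expected genome_id|protein_id|start|end|strand)")
  df <- data.frame(
    protein_id = vapply(parts, `[`, "", 2L),
    genome_id = vapply(parts, `[`, "", 1L),
    start = as.integer(vapply(parts, `[`, "", 3L)),
    end = as.integer(vapply(parts, `[`, "", 4L)),
    strand = vapply(parts, `[`, "", 5L),
    seq = as.character(aa), stringsAsFactors = FALSE)
  df$length_aa <- nchar(df$seq)
  rownames(df) <- NULL
  df
}

#' @rdname readProteinsFasta
#' @export
writeProteinsFasta <- function(proteins, path) {
  aa <- Biostrings::AAStringSet(setNames(
    proteins$seq,
    sprintf("%s|%s|%d|%d|%s", proteins$genome_id, proteins$protein_id,
            proteins$start, proteins$end, proteins$strand)))
  Biostrings::writeXStringSet(aa, path, width = 60L)
  invisible(path)
}

#' Write and read CDS annotations as GFF3
#'
#' @param gff a [GenomicRanges::GRanges] with `type`, `ID` and `family`
#'   metadata columns.
#' @param path GFF3 file.
#' @return `writeGff3()` returns `path` invisibly; `readGff3()` a
#'   `GRanges`.
#' @export
writeGff3 <- function(gff, path) {
  rtracklayer::export(gff, path, format = "gff3")
  invisible(path)
}

#' @rdname writeGff3
#' @export
readGff3 <- function(path) {
  gr <- rtracklayer::import(path, format = "gff3")
  if (any(GenomicRanges::end(gr) < GenomicRanges::start(gr)))
    stop("GFF3 record with end < start")
  gr
}

#' Write a synthetic dataset to disk
#'
#' Emits `genomes.fna`, `proteins.faa` (coordinate headers),
#' `annotations.gff3`, `truth.tsv` and one reference multi-FASTA per marker
#' family under `families/`.
#'
#' @param dataset a `syntheticPlasmidSet` from [makeGenomes()].
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
writeSyntheticData <- function(dataset, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  writeGenomesFasta(dataset$genomes, file.path(dir, "genomes.fna"))
  writeProteinsFasta(dataset$proteins, file.path(dir, "proteins.faa"))
  writeGff3(dataset$gff, file.path(dir, "annotations.gff3"))
  write.table(dataset$truth, file.path(dir, "truth.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  famDir <- file.path(dir, "families")
  dir.create(famDir, showWarnings = FALSE)
  for (f in names(dataset$families$members)) {
    aa <- Biostrings::AAStringSet(dataset$families$members[[f]])
    Biostrings::writeXStringSet(aa, file.path(famDir, paste0(f, ".faa")),
                                width = 60L)
  }
  invisible(dir)
}

#' Read marker reference families from a directory of multi-FASTA files
#'
#' @param dir directory with one `<family>.faa` per marker family.
#' @return named list of named character vectors.
#' @export
readMarkerFamilies <- function(dir) {
  files <- list.files(dir, pattern = "\\.faa$", full.names = TRUE)
  fams <- lapply(files, function(f) {
    aa <- Biostrings::readAAStringSet(f)
    setNames(as.character(aa), names(aa))
  })
  names(fams) <- sub("\\.faa$", "", basename(files))
  fams
}

#' Parse a flat key/value pipeline configuration file
#'
#' The configuration is a plain text file of `key: value` lines (with `#`
#' comments) covering the generator and screen parameters, e.g. `seed: 7`,
#' `n_genomes: 40`, `min_len_bp: 15000`, `hit_bits: 25`,
#' `group_threshold: 0.5`.
#'
#' @param path configuration file.
#' @return list with elements `spec` (a [GeneratorSpec]) and `cfg`
#'   (a [ScreenConfig]).
#' @export
readPipelineConfig <- function(path) {
  lines <- readLines(path)
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  kv <- list()
  for (ln in lines) {
    m <- regmatches(ln, regexec("^([A-Za-z0-9_]+)\\s*:\\s*(.+)$", ln))[[1]]
    if (length(m) != 3L) stop("malformed config line: '", ln, "'")
    kv[[m[2]]] <- m[3]
  }
  num <- function(key, default) if (!is.null(kv[[key]])) as.numeric(kv[[key]]) else default
  int <- function(key, default) as.integer(num(key, default))
  spec <- generatorSpec(
    seed = int("seed", 1L),
    nGenomes = int("n_genomes", 40L),
    stateMix = c(active = int("active", 12L),
                 degenerated = int("degenerated", 6L),
                 virulent = int("virulent", 2L),
                 non_phage = int("non_phage", 20L)),
    nGroups = int("n_groups", 3L),
    familyDivergence = num("family_divergence", 0.2),
    genomeLengthRange = c(num("genome_min_bp", 15000), num("genome_max_bp", 120000)),
    cargoPerGenome = int("cargo_per_genome", 8L))
  cfg <- screenConfig(
    minLenBp = num("min_len_bp", 15000),
    maxLenBp = num("max_len_bp", 500000),
    hitBits = num("hit_bits", 25),
    dedupIdentity = num("dedup_identity", 0.99),
    dedupCoverage = num("dedup_coverage", 0.99),
    orthoQueryCoverage = num("ortho_query_coverage", 0.75),
    orthoEvalue = num("ortho_evalue", 1e-5),
    groupThreshold = num("group_threshold", 0.5))
  list(spec = spec, cfg = cfg)
}
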