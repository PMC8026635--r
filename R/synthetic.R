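#' @include classifier.R
NULL

# family-typical ancestor lengths (aa)
.FAMILY_LEN <- c(terminase = 420L, mcp = 350L, tmp = 1200L, xerC = 300L,
                 parA = 260L, parM = 330L, tubZ = 420L, adapter = 90L,
                 sheath = 480L, serine_recombinase = 195L)

.DNA <- c("A", "C", "G", "T")

.deriveSeed <- function(seed, k) {
  as.integer((as.numeric(seed) * 48271 + 7919 * k) %% 2147483647)
}

#' Construct a synthetic dataset specification
#'
#' Defaults describe the generator's stated world: 40 unique plasmid
#' genomes of 15-120 kbp (12 planted active plasmid prophages, 6
#' degenerated, 2 virulent-phage-like, 20 ordinary plasmids), three genome
#' groups sharing cargo repertoires, marker family members diverged by 20%
#' substitutions, an exact duplicate, a 99.5%-identity near-duplicate and a
#' 98%-identity relative pair for the deduplication tests, and two active
#' genomes carrying a tail sheath (myovirus-like morphotype).
#'
#' @param seed integer seed driving all generator randomness.
#' @param nGenomes number of unique genomes.
#' @param stateMix named integer counts (`active`, `degenerated`,
#'   `virulent`, `non_phage`) summing to `nGenomes`.
#' @param nGroups planted groups among the phage-like genomes.
#' @param familyDivergence substitution fraction for family members.
#' @param withinGroupDivergence substitution fraction for within-group
#'   cargo copies.
#' @param duplicatePairs number of planted duplicate pairs.
#' @param nearDuplicateIdentity,distantPairIdentity planted nucleotide
#'   identities (see [GeneratorSpec]).
#' @param genomeLengthRange genome length window (bp).
#' @param intergenicMean mean intergenic spacer (bp).
#' @param cargoPerGenome cargo genes per phage-like genome.
#' @param familyMembers reference sequences per marker family.
#' @param nMyovirus active genomes additionally carrying a sheath gene.
#' @return A [GeneratorSpec].
#' @export
generatorSpec <- function(seed = 1L, nGenomes = 40L,
                          stateMix = c(active = 12L, degenerated = 6L,
                                       virulent = 2L, non_phage = 20L),
                          nGroups = 3L, familyDivergence = 0.2,
                          withinGroupDivergence = 0.05,
                          duplicatePairs = 3L,
                          nearDuplicateIdentity = 0.995,
                          distantPairIdentity = 0.98,
                          genomeLengthRange = c(15000, 120000),
                          intergenicMean = 120,
                          cargoPerGenome = 8L, familyMembers = 12L,
                          nMyovirus = 2L) {
  new("GeneratorSpec", seed = as.integer(seed), nGenomes = as.integer(nGenomes),
      stateMix = setNames(as.integer(stateMix), names(stateMix)),
      nGroups = as.integer(nGroups), familyDivergence = familyDivergence,
      withinGroupDivergence = withinGroupDivergence,
      duplicatePairs = as.integer(duplicatePairs),
      nearDuplicateIdentity = nearDuplicateIdentity,
      distantPairIdentity = distantPairIdentity,
      genomeLengthRange = genomeLengthRange, intergenicMean = intergenicMean,
      cargoPerGenome = as.integer(cargoPerGenome),
      familyMembers = as.integer(familyMembers),
      nMyovirus = as.integer(nMyovirus))
}

.randomProtein <- function(len) paste(sample(AA20, len, replace = TRUE), collapse = "")

.randomDna <- function(len) paste(sample(.DNA, len, replace = TRUE), collapse = "")

#' Mutate a protein by i.i.d. substitutions
#'
#' Each position is substituted with probability `rate` by a uniformly
#' chosen different residue (so two members mutated at rate d from a common
#' ancestor have expected identity `(1 - d)^2 + d^2 / 19`).
#'
#' @param seq protein sequence.
#' @param rate substitution probability per site.
#' @return mutated sequence.
#' @export
mutateProtein <- function(seq, rate) {
  ch <- strsplit(seq, "", fixed = TRUE)[[1]]
  hit <- which(runif(length(ch)) < rate)
  for (i in hit) ch[i] <- sample(setdiff(AA20, ch[i]), 1L)
  paste(ch, collapse = "")
}

.codonTable <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      gc <- Biostrings::GENETIC_CODE
      cache <<- split(names(gc), unname(gc))
    }
    cache
  }
})

.reverseTranslate <- function(aa) {
  tab <- .codonTable()
  ch <- strsplit(aa, "", fixed = TRUE)[[1]]
  paste(vapply(ch, function(a) {
    cods <- tab[[a]]
    if (is.null(cods)) cods <- tab[["X"]]
    if (is.null(cods)) return("NNN")
    cods[sample.int(length(cods), 1L)]
  }, character(1)), collapse = "")
}

.stopCodon <- function() sample(c("TAA", "TAG", "TGA"), 1L)

#' Generate the marker reference protein families
#'
#' For each marker family an ancestor of family-typical length (terminase
#' 420 aa, major capsid protein 350, tape measure protein 1200, XerC 300,
#' ParA 260, ParM 330, TubZ 420, adapter 90, sheath 480, serine recombinase
#' 195) is sampled from the background residue distribution, and
#' `familyMembers` reference sequences are derived by i.i.d. substitutions
#' at rate `familyDivergence`. Families never share ancestors, so
#' cross-family profile hits would indicate scoring bugs rather than
#' homology.
#'
#' @param spec a [GeneratorSpec].
#' @return list with `ancestors` (named character) and `members` (named
#'   list of named character vectors, one per family).
#' @export
makeMarkerFamilies <- function(spec) {
  set.seed(.deriveSeed(spec@seed, 1L))
  ancestors <- vapply(names(.FAMILY_LEN), function(f)
    .randomProtein(.FAMILY_LEN[[f]]), character(1))
  members <- lapply(names(.FAMILY_LEN), function(f) {
    v <- vapply(seq_len(spec@familyMembers), function(i)
      mutateProtein(ancestors[[f]], spec@familyDivergence), character(1))
    names(v) <- sprintf("%s_ref%02d", f, seq_along(v))
    v
  })
  names(members) <- names(.FAMILY_LEN)
  list(ancestors = ancestors, members = members)
}

# planted gene layout for one genome: data.frame(family, aa, strand)
.planGenome <- function(state, motor, recombinase, degenMode, sheath,
                        cargoSeqs, families, spec) {
  anc <- families$ancestors
  d <- spec@familyDivergence
  genes <- list()
  addGene <- function(family, aa, strand = "+")
    genes[[length(genes) + 1L]] <<- list(family = family, aa = aa, strand = strand)
  marker <- function(f) mutateProtein(anc[[f]], d)

  if (state %in% c("active", "degenerated", "virulent")) {
    term <- marker("terminase")
    if (state == "degenerated" && degenMode == "terminase_truncated")
      term <- substr(term, 1L, floor(0.7 * nchar(term)))
    addGene("terminase", term)
    addGene("mcp", marker("mcp"))
    if (sheath) addGene("sheath", marker("sheath"))
    tmp <- marker("tmp")
    if (state == "degenerated" && degenMode == "tmp_split") {
      addGene("tmp", substr(tmp, 1L, 313L))        # 5' fragment
      addGene("tmp", substr(tmp, 315L, nchar(tmp)))  # 3' fragment (886 aa)
    } else {
      addGene("tmp", tmp)
    }
    if (state != "virulent") {
      addGene(motor, marker(motor))
      addGene("adapter", marker("adapter"))  # immediately downstream, same strand
      addGene(recombinase, marker(recombinase))
    }
  } else {  # non_phage plasmid: partitioning/recombination but no head genes
    addGene(motor, marker(motor))
    addGene("adapter", marker("adapter"))
    addGene(recombinase, marker(recombinase))
  }
  for (i in seq_along(cargoSeqs)) {
    strand <- if (i == length(cargoSeqs)) "-" else "+"
    addGene("cargo", cargoSeqs[[i]], strand)
  }
  genes
}

.assembleGenome <- function(genes, targetLen, intergenicMean, genomeId) {
  parts <- character(0)
  pos <- 0L
  lead <- 300L + sample.int(400L, 1L)
  parts <- c(parts, .randomDna(lead)); pos <- pos + lead
  prot <- list()
  for (gi in seq_along(genes)) {
    g <- genes[[gi]]
    dna <- paste0(.reverseTranslate(g$aa), .stopCodon())
    if (g$strand == "-")
      dna <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(dna)))
    start <- pos + 1L
    end <- pos + nchar(dna)
    prot[[gi]] <- data.frame(
      protein_id = sprintf("%s_p%03d", genomeId, gi), genome_id = genomeId,
      start = start, end = end, strand = g$strand, seq = g$aa,
      length_aa = nchar(g$aa), family = g$family, stringsAsFactors = FALSE)
    parts <- c(parts, dna); pos <- end
    spacer <- max(2L, rpois(1L, intergenicMean))
    parts <- c(parts, .randomDna(spacer)); pos <- pos + spacer
  }
  if (pos < targetLen) {
    parts <- c(parts, .randomDna(targetLen - pos))
    pos <- targetLen
  }
  list(seq = paste(parts, collapse = ""), proteins = do.call(rbind, prot))
}

.mutateIntergenic <- function(seq, proteins, identity) {
  L <- nchar(seq)
  nMut <- round((1 - identity) * L)
  inCds <- rep(FALSE, L)
  for (r in seq_len(nrow(proteins)))
    inCds[proteins$start[r]:proteins$end[r]] <- TRUE
  candidates <- which(!inCds)
  posn <- sort(sample(candidates, min(nMut, length(candidates))))
  ch <- strsplit(seq, "", fixed = TRUE)[[1]]
  for (p in posn) ch[p] <- sample(setdiff(.DNA, ch[p]), 1L)
  paste(ch, collapse = "")
}

#' Generate synthetic plasmid genomes with planted truth
#'
#' Emits the genomes described by the specification: active prophages carry
#' terminase + major capsid protein + intact tape measure protein + a
#' partitioning motor with its adapter immediately downstream on the same
#' strand + a recombinase + cargo genes; degenerated prophages carry a TMP
#' split into two CDSs (313 and 886 aa) or a terminase truncated to 70%
#' length; virulent-phage-like genomes carry the head/tail genes but no
#' motor, adapter or recombinase; ordinary plasmids carry
#' motor/adapter/recombinase and cargo but never terminase or MCP. Group
#' members share diverged copies of a common cargo repertoire. Genes are
#' reverse-translated with uniform codon choice; duplicates are copied
#' exactly and near-duplicates receive intergenic point mutations down to
#' the planted identity.
#'
#' @param spec a [GeneratorSpec].
#' @param families marker families from [makeMarkerFamilies()] (built from
#'   `spec` when `NULL`).
#' @return list of class `"syntheticPlasmidSet"` with `genomes`
#'   ([Biostrings::DNAStringSet] with `circular`/`organism` metadata),
#'   `proteins` (protein table), `gff` ([GenomicRanges::GRanges] of CDS
#'   features), `truth` (truth table) and `families`.
#' @export
makeGenomes <- function(spec, families = NULL) {
  if (sum(spec@stateMix) != spec@nGenomes)
    stop("stateMix counts must sum to nGenomes")
  if (is.null(families)) families <- makeMarkerFamilies(spec)
  set.seed(.deriveSeed(spec@seed, 2L))

  nA <- spec@stateMix[["active"]]; nD <- spec@stateMix[["degenerated"]]
  nV <- spec@stateMix[["virulent"]]; nN <- spec@stateMix[["non_phage"]]
  states <- c(rep("active", nA), rep("degenerated", nD),
              rep("virulent", nV), rep("non_phage", nN))
  n <- length(states)
  ids <- sprintf("G%02d", seq_len(n))

  # group assignment: interleave actives and degens, round-robin over groups
  selIdx <- which(states %in% c("active", "degenerated"))
  aIdx <- which(states == "active"); dIdx <- which(states == "degenerated")
  pool <- integer(0)
  for (i in seq_len(max(length(aIdx), length(dIdx)))) {
    if (i <= length(aIdx)) pool <- c(pool, aIdx[i])
    if (i <= length(dIdx)) pool <- c(pool, dIdx[i])
  }
  nGroupMembers <- 0L
  if (spec@nGroups > 0L) {
    perGroup <- max(3L, floor(length(pool) * 0.6 / spec@nGroups))
    nGroupMembers <- min(length(pool), perGroup * spec@nGroups)
  }
  groupOf <- rep(NA_integer_, n)
  if (nGroupMembers >= spec@nGroups && spec@nGroups > 0L)
    groupOf[pool[seq_len(nGroupMembers)]] <-
      rep(seq_len(spec@nGroups), length.out = nGroupMembers)

  # motor/recombinase per genome: fixed per group, cycled for singletons
  motorOf <- character(n); recombOf <- character(n)
  for (i in seq_len(n)) {
    g <- groupOf[i]
    if (!is.na(g)) {
      motorOf[i] <- MOTOR_MARKERS[(g - 1L) %% 3L + 1L]
      recombOf[i] <- if (g %% 2L == 0L) "serine_recombinase" else "xerC"
    } else {
      motorOf[i] <- MOTOR_MARKERS[(i - 1L) %% 3L + 1L]
      recombOf[i] <- if (i %% 2L == 0L) "serine_recombinase" else "xerC"
    }
  }

  # sheath carriers: last nMyovirus active genomes (planted myovirus-like)
  sheathOf <- rep(FALSE, n)
  if (spec@nMyovirus > 0L && length(aIdx))
    sheathOf[utils::tail(aIdx, spec@nMyovirus)] <- TRUE

  # degeneration modes alternate across degenerated genomes
  degenOf <- rep("none", n)
  degenOf[dIdx] <- rep(c("tmp_split", "terminase_truncated"),
                       length.out = length(dIdx))

  # cargo repertoires
  cargoLen <- function() 150L + sample.int(451L, 1L)
  groupCargo <- lapply(seq_len(max(spec@nGroups, 1L)), function(g)
    vapply(seq_len(spec@cargoPerGenome), function(i)
      .randomProtein(cargoLen()), character(1)))
  cargoFor <- function(i) {
    g <- groupOf[i]
    if (!is.na(g))
      lapply(groupCargo[[g]], mutateProtein, rate = spec@withinGroupDivergence)
    else if (states[i] == "non_phage")
      lapply(seq_len(5L), function(k) .randomProtein(cargoLen()))
    else
      lapply(seq_len(spec@cargoPerGenome), function(k) .randomProtein(cargoLen()))
  }

  lenRange <- spec@genomeLengthRange
  genomeSeqs <- character(n)
  protList <- vector("list", n)
  for (i in seq_len(n)) {
    genes <- .planGenome(states[i], motorOf[i], recombOf[i], degenOf[i],
                         sheathOf[i], cargoFor(i), families, spec)
    targetLen <- round(runif(1L, lenRange[1], lenRange[2]))
    asm <- .assembleGenome(genes, targetLen, spec@intergenicMean, ids[i])
    genomeSeqs[i] <- asm$seq
    protList[[i]] <- asm$proteins
  }

  truth <- data.frame(
    genome_id = ids, planted_state = states, planted_group = groupOf,
    planted_morphotype = ifelse(states == "non_phage", NA_character_,
                                ifelse(sheathOf, "myovirus_like", "siphovirus_like")),
    degeneration = degenOf,
    motor = ifelse(states == "virulent", "none", motorOf),
    recombinase = ifelse(states == "virulent", "none", recombOf),
    duplicate_of = NA_character_, planted_identity = NA_real_,
    stringsAsFactors = FALSE)

  # distant 98%-identity relative pair inside the non-phage set
  if (spec@duplicatePairs >= 3L && nN >= 2L) {
    src <- which(states == "non_phage")[nN - 1L]
    dst <- which(states == "non_phage")[nN]
    genomeSeqs[dst] <- .mutateIntergenic(genomeSeqs[src], protList[[src]],
                                         spec@distantPairIdentity)
    p <- protList[[src]]
    p$genome_id <- ids[dst]
    p$protein_id <- sub(ids[src], ids[dst], p$protein_id, fixed = TRUE)
    protList[[dst]] <- p
    for (col in c("planted_state", "planted_group", "planted_morphotype",
                  "degeneration", "motor", "recombinase"))
      truth[[col]][dst] <- truth[[col]][src]
    truth$duplicate_of[dst] <- ids[src]
    truth$planted_identity[dst] <- spec@distantPairIdentity
  }

  # extra copies: one exact duplicate of an active genome, one
  # near-duplicate of a non-phage genome
  extra <- list()
  if (spec@duplicatePairs >= 1L && nA >= 1L) {
    src <- aIdx[1]
    extra[[length(extra) + 1L]] <- list(src = src, identity = 1)
  }
  if (spec@duplicatePairs >= 2L && nN >= 1L) {
    src <- which(states == "non_phage")[1]
    extra[[length(extra) + 1L]] <- list(src = src,
                                        identity = spec@nearDuplicateIdentity)
  }
  for (e in extra) {
    newId <- sprintf("G%02d", length(genomeSeqs) + 1L)
    s <- genomeSeqs[e$src]
    if (e$identity < 1)
      s <- .mutateIntergenic(s, protList[[e$src]], e$identity)
    genomeSeqs <- c(genomeSeqs, s)
    p <- protList[[e$src]]
    p$genome_id <- newId
    p$protein_id <- sub(ids[e$src], newId, p$protein_id, fixed = TRUE)
    protList[[length(protList) + 1L]] <- p
    ids <- c(ids, newId)
    truth <- rbind(truth, data.frame(
      genome_id = newId, planted_state = truth$planted_state[e$src],
      planted_group = truth$planted_group[e$src],
      planted_morphotype = truth$planted_morphotype[e$src],
      degeneration = truth$degeneration[e$src], motor = truth$motor[e$src],
      recombinase = truth$recombinase[e$src],
      duplicate_of = truth$genome_id[e$src], planted_identity = e$identity,
      stringsAsFactors = FALSE))
  }

  genomes <- Biostrings::DNAStringSet(setNames(genomeSeqs, ids))
  S4Vectors::mcols(genomes) <- S4Vectors::DataFrame(
    organism = sprintf("synthetic Bacillus sp. %s", ids), circular = TRUE)
  proteins <- do.call(rbind, protList)
  rownames(proteins) <- NULL

  gff <- GenomicRanges::GRanges(
    seqnames = proteins$genome_id,
    ranges = IRanges::IRanges(start = proteins$start, end = proteins$end),
    strand = proteins$strand)
  gff$type <- "CDS"
  gff$phase <- 0L
  gff$ID <- proteins$protein_id
  gff$family <- proteins$family

  out <- list(spec = spec, genomes = genomes, proteins = proteins, gff = gff,
              truth = truth, families = families)
  class(out) <- "syntheticPlasmidSet"
  out
}

#' @export
print.syntheticPlasmidSet <- function(x, ...) {
  cat(sprintf("syntheticPlasmidSet: %d genomes (%d unique), %d proteins\n",
              length(x$genomes), sum(is.na(x$truth$duplicate_of) |
                                     x$truth$planted_identity < 0.99),
              nrow(x$proteins)))
  invisible(x)
}

#' Corrupt a planted marker gene
#'
#' Models prophage degeneration in place: `"split"` replaces the codon at
#' the gene's midpoint with a stop codon, turning the CDS into two adjacent
#' CDSs whose lengths sum to the original minus one codon; `"truncate"`
#' stops the gene at 70% of its length, removing the 3' 30% from the
#' annotation. The truth table entry is updated to a degenerated state.
#' Only forward-strand marker genes (as planted by [makeGenomes()]) are
#' supported.
#'
#' @param dataset a `syntheticPlasmidSet`.
#' @param genomeId genome to corrupt.
#' @param marker marker family name carried intact by the genome.
#' @param mode `"split"` or `"truncate"`.
#' @param seed unused placeholder for interface stability.
#' @return The modified dataset.
#' @export
corruptGene <- function(dataset, genomeId, marker,
                        mode = c("split", "truncate"), seed = 1L) {
  mode <- match.arg(mode)
  pr <- dataset$proteins
  sel <- which(pr$genome_id == genomeId & pr$family == marker)
  if (length(sel) != 1L)
    stop("genome ", genomeId, " does not carry a single intact '", marker, "' gene")
  row <- pr[sel, ]
  if (row$strand != "+") stop("only forward-strand genes can be corrupted")
  L <- row$length_aa
  seqs <- as.character(dataset$genomes)
  g <- seqs[[genomeId]]

  replaceCodon <- function(seq, cdsStart, codonIdx, with) {
    at <- cdsStart + 3L * (codonIdx - 1L)
    paste0(substr(seq, 1L, at - 1L), with, substr(seq, at + 3L, nchar(seq)))
  }

  if (mode == "split") {
    mid <- ceiling(L / 2)
    g <- replaceCodon(g, row$start, mid, "TAA")
    aa <- row$seq
    p1 <- row; p2 <- row
    p1$protein_id <- paste0(row$protein_id, "a")
    p1$end <- row$start + 3L * mid - 1L
    p1$seq <- substr(aa, 1L, mid - 1L); p1$length_aa <- mid - 1L
    p2$protein_id <- paste0(row$protein_id, "b")
    p2$start <- row$start + 3L * mid
    p2$seq <- substr(aa, mid + 1L, L); p2$length_aa <- L - mid
    pr <- rbind(pr[-sel, ], p1, p2)
    dataset$truth$degeneration[dataset$truth$genome_id == genomeId] <-
      paste0(marker, "_split")
  } else {
    keep <- floor(0.7 * L)
    g <- replaceCodon(g, row$start, keep + 1L, "TAA")
    row$end <- row$start + 3L * (keep + 1L) - 1L
    row$seq <- substr(row$seq, 1L, keep); row$length_aa <- keep
    pr <- rbind(pr[-sel, ], row)
    dataset$truth$degeneration[dataset$truth$genome_id == genomeId] <-
      paste0(marker, "_truncated")
  }
  seqs[[genomeId]] <- g
  mc <- S4Vectors::mcols(dataset$genomes)
  dataset$genomes <- Biostrings::DNAStringSet(seqs)
  S4Vectors::mcols(dataset$genomes) <- mc
  pr <- pr[order(pr$genome_id, pr$start), ]
  rownames(pr) <- NULL
  dataset$proteins <- pr
  tsel <- dataset$truth$genome_id == genomeId
  if (dataset$truth$planted_state[tsel] == "active")
    dataset$truth$planted_state[tsel] <- "degenerated"
  dataset$gff <- GenomicRanges::GRanges(
    seqnames = pr$genome_id,
    ranges = IRanges::IRanges(start = pr$start, end = pr$end),
    strand = pr$strand)
  dataset$gff$type <- "CDS"
  dataset$gff$phase <- 0L
  dataset$gff$ID <- pr$protein_id
  dataset$gff$family <- pr$family
  dataset
}
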