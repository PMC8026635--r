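#' @include grouping.R
NULL

#' Prophage state labels assigned by the classifier
#' @format character vector of the four states.
#' @export
PROPHAGE_STATES <- c("putative_active_plasmid_prophage",
                     "putative_degenerated_plasmid_prophage",
                     "putative_virulent_phage",
                     "non_phage_plasmid")

#' Extract classifier features from a genome's marker hits
#'
#' Turns the per-protein profile hits of one genome into the boolean and
#' categorical features the prophage-state rules consume: marker presence,
#' tape measure protein (TMP) integrity and fragmentation, terminase
#' truncation, partitioning motor type and downstream adapter, recombinase
#' families, and tail sheath presence.
#'
#' Feature rules: the TMP is intact when its best hit lies on a single CDS
#' of at least `tmpMinAa` (default 900 aa); the TMP fragment count is the
#' largest number of TMP-hit CDSs within a window of three consecutive
#' genes; the terminase is truncated when its best-hit CDS covers less than
#' `terminaseCovMin` (80%) of the profile match states; an adapter is a CDS
#' of at most `adapterMaxAa` (150 aa) within two genes downstream of the
#' motor on the same strand; a serine recombinase on a CDS of at most
#' 250 aa is a small resolvase/invertase, of at least 400 aa an
#' integrase-like enzyme.
#'
#' @param genomeId genome identifier.
#' @param proteins protein table rows for this genome (`protein_id`,
#'   `start`, `end`, `strand`, `length_aa`).
#' @param hits profile hit table rows for this genome (from
#'   [searchProteome()]).
#' @param cfg a [ScreenConfig].
#' @param genomeLength optional genome length for coordinate validation.
#' @return A named list of class `"GeneFeatureSet"`.
#' @export
extractFeatures <- function(genomeId, proteins, hits, cfg = screenConfig(),
                            genomeLength = NULL) {
  proteins <- proteins[proteins$genome_id == genomeId, , drop = FALSE]
  hits <- hits[hits$genome_id == genomeId, , drop = FALSE]
  if (!is.null(genomeLength) && nrow(proteins) &&
      any(proteins$end > genomeLength | proteins$start < 1))
    stop("CDS coordinates outside genome ", genomeId)
  proteins <- proteins[order(proteins$start, proteins$end), , drop = FALSE]
  geneIndex <- setNames(seq_len(nrow(proteins)), proteins$protein_id)
  aaLen <- setNames(proteins$length_aa, proteins$protein_id)

  hitsFor <- function(marker) hits[hits$profile == marker, , drop = FALSE]
  bestHit <- function(marker) {
    h <- hitsFor(marker)
    if (!nrow(h)) return(NULL)
    h[order(-h$bit_score, h$protein_id), , drop = FALSE][1, , drop = FALSE]
  }

  tmpHits <- hitsFor("tmp")
  tmpCds <- unique(tmpHits$protein_id)
  hasTmp <- length(tmpCds) > 0
  tmpBest <- bestHit("tmp")
  tmpIntact <- hasTmp && aaLen[tmpBest$protein_id] >= cfg@tmpMinAa
  tmpFragments <- 0L
  if (hasTmp) {
    idx <- sort(unname(geneIndex[tmpCds]))
    tmpFragments <- max(vapply(idx, function(w)
      sum(idx >= w & idx <= w + 2L), integer(1)))
  }

  termBest <- bestHit("terminase")
  hasTerminase <- !is.null(termBest)
  terminaseTruncated <- hasTerminase && termBest$coverage < cfg@terminaseCovMin

  motorBest <- NULL
  motorType <- "none"
  for (mk in MOTOR_MARKERS) {
    h <- bestHit(mk)
    if (!is.null(h) && (is.null(motorBest) || h$bit_score > motorBest$bit_score)) {
      motorBest <- h; motorType <- mk
    }
  }
  adapterDownstream <- FALSE
  if (motorType != "none") {
    mi <- geneIndex[motorBest$protein_id]
    mstrand <- proteins$strand[mi]
    cand <- if (mstrand == "+") mi + c(1L, 2L) else mi - c(1L, 2L)
    cand <- cand[cand >= 1 & cand <= nrow(proteins)]
    for (ci in cand) {
      if (proteins$strand[ci] == mstrand &&
          proteins$length_aa[ci] <= cfg@adapterMaxAa) {
        adapterDownstream <- TRUE
        break
      }
    }
  }

  serBest <- bestHit("serine_recombinase")
  serClass <- "none"
  if (!is.null(serBest)) {
    l <- aaLen[serBest$protein_id]
    serClass <- if (l <= cfg@serineSmallMaxAa) "small_resolvase_invertase"
    else if (l >= cfg@serineLargeMinAa) "large_integrase_like"
    else "none_classified"
  }

  out <- list(
    genome_id = genomeId,
    has_terminase = hasTerminase,
    has_mcp = !is.null(bestHit("mcp")),
    has_tmp = hasTmp,
    tmp_intact = tmpIntact,
    tmp_fragment_count = as.integer(tmpFragments),
    terminase_truncated = terminaseTruncated,
    motor_type = motorType,
    has_adapter_downstream = adapterDownstream,
    has_tyrosine_recombinase = !is.null(bestHit("xerC")),
    has_serine_recombinase = !is.null(serBest),
    serine_recombinase_class = serClass,
    has_sheath = !is.null(bestHit("sheath")))
  class(out) <- "GeneFeatureSet"
  out
}

#' Classify a genome's prophage state from its features
#'
#' Deterministic rule cascade (first match wins):
#' \describe{
#'   \item{R1}{no terminase or no major capsid protein: not a phage --
#'     `non_phage_plasmid`.}
#'   \item{R2}{both head markers but neither a partitioning motor nor any
#'     recombinase: nothing maintains it as a plasmid --
#'     `putative_virulent_phage`.}
#'   \item{R3}{a truncated terminase, or a TMP present but not intact
#'     (split/short): `putative_degenerated_plasmid_prophage`.}
#'   \item{R4}{otherwise `putative_active_plasmid_prophage`.}
#' }
#' Morphotype: `myovirus_like` when a tail sheath is present, else
#' `siphovirus_like` when any tail marker (TMP) is present, else
#' `undetermined`.
#'
#' @param features a `GeneFeatureSet` from [extractFeatures()].
#' @return list of class `"ProphageCall"` with `genome_id`, `state`,
#'   `morphotype`, `rules` (rule ids in firing order) and `evidence` (the
#'   feature set).
#' @export
classifyFeatures <- function(features) {
  f <- features
  rules <- character(0)
  state <- NULL
  if (!(f$has_terminase && f$has_mcp)) {
    state <- "non_phage_plasmid"; rules <- "R1"
  } else if (f$motor_type == "none" &&
             !f$has_tyrosine_recombinase && !f$has_serine_recombinase) {
    state <- "putative_virulent_phage"; rules <- "R2"
  } else if (f$terminase_truncated || (f$has_tmp && !f$tmp_intact)) {
    state <- "putative_degenerated_plasmid_prophage"; rules <- "R3"
  } else {
    state <- "putative_active_plasmid_prophage"; rules <- "R4"
  }
  morphotype <- if (f$has_sheath) "myovirus_like"
  else if (f$has_tmp) "siphovirus_like"
  else "undetermined"
  out <- list(genome_id = f$genome_id, state = state, morphotype = morphotype,
              rules = rules, evidence = f)
  class(out) <- "ProphageCall"
  out
}

#' @export
print.ProphageCall <- function(x, ...) {
  cat(sprintf("%s: %s (%s; rule %s)\n", x$genome_id, x$state, x$morphotype,
              paste(x$rules, collapse = ",")))
  invisible(x)
}

#' Tabulate and write prophage calls
#'
#' Produces the per-genome call table (state, morphotype, group membership
#' and evidence flags) and a per-state count summary with percentages over
#' the unique genomes reported. Split genes possibly caused by frameshift
#' sequencing errors are still called degenerated; the caveat is recorded
#' in the table's `note` column.
#'
#' @param calls list of `ProphageCall` objects covering all genomes.
#' @param groups optional group table from [makeGroups()].
#' @param dir optional output directory; writes `calls.tsv` and
#'   `counts.tsv` when given.
#' @return list with `calls` and `counts` data frames.
#' @export
reportCalls <- function(calls, groups = NULL, dir = NULL) {
  groupOf <- if (!is.null(groups))
    setNames(groups$group_id, groups$genome_id) else integer(0)
  df <- do.call(rbind, lapply(calls, function(cl) {
    f <- cl$evidence
    data.frame(genome_id = cl$genome_id, state = cl$state,
               morphotype = cl$morphotype,
               group_id = if (cl$genome_id %in% names(groupOf))
                 groupOf[[cl$genome_id]] else NA_integer_,
               rule = paste(cl$rules, collapse = ","),
               has_terminase = f$has_terminase, has_mcp = f$has_mcp,
               has_tmp = f$has_tmp, tmp_intact = f$tmp_intact,
               tmp_fragment_count = f$tmp_fragment_count,
               terminase_truncated = f$terminase_truncated,
               motor_type = f$motor_type,
               has_adapter_downstream = f$has_adapter_downstream,
               has_tyrosine_recombinase = f$has_tyrosine_recombinase,
               has_serine_recombinase = f$has_serine_recombinase,
               serine_recombinase_class = f$serine_recombinase_class,
               has_sheath = f$has_sheath,
               note = if (cl$state == "putative_degenerated_plasmid_prophage")
                 "split/truncated genes may reflect frameshifting sequencing errors"
               else "",
               stringsAsFactors = FALSE)
  }))
  df <- df[order(df$genome_id), , drop = FALSE]
  rownames(df) <- NULL
  counts <- data.frame(state = PROPHAGE_STATES,
                       n = vapply(PROPHAGE_STATES, function(s)
                         sum(df$state == s), integer(1)),
                       stringsAsFactors = FALSE)
  counts$percent <- round(100 * counts$n / nrow(df), 1)
  rownames(counts) <- NULL
  if (!is.null(dir)) {
    write.table(df, file.path(dir, "calls.tsv"), sep = "\t", quote = FALSE,
                row.names = FALSE)
    write.table(counts, file.path(dir, "counts.tsv"), sep = "\t", quote = FALSE,
                row.names = FALSE)
  }
  list(calls = df, counts = counts)
}
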