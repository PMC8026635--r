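#' @include prophageScreen-package.R
NULL

#' Scoring scheme for pairwise alignment
#'
#' Bundles a substitution matrix, affine gap penalties and Karlin-Altschul
#' statistical parameters. Protein schemes default to BLOSUM62 with gap
#' open/extend -11/-1 and gapped statistics lambda = 0.267, K = 0.041;
#' nucleotide schemes default to match/mismatch +1/-2 with gaps -5/-2.
#'
#' @slot type `"protein"` or `"nucleotide"`.
#' @slot matrix symmetric substitution matrix with residue dimnames.
#' @slot gapOpen cost of the first residue of a gap (negative).
#' @slot gapExtend cost of each further gap residue (negative,
#'   `gapOpen <= gapExtend < 0`).
#' @slot lambda,k Karlin-Altschul parameters; the bit score of a raw score S
#'   is `(lambda * S - log(k)) / log(2)` and the E-value of an alignment of
#'   sequences of lengths m, n is `m * n * 2^-bits`.
#' @seealso [proteinScheme()], [nucleotideScheme()], [alignGlobal()]
#' @exportClass ScoringScheme
setClass("ScoringScheme",
  representation(type = "character", matrix = "matrix",
                 gapOpen = "numeric", gapExtend = "numeric",
                 lambda = "numeric", k = "numeric"))

setValidity("ScoringScheme", function(object) {
  msg <- character()
  m <- object@matrix
  if (is.null(rownames(m)) || !identical(rownames(m), colnames(m)))
    msg <- c(msg, "substitution matrix must have identical row and column names")
  else if (!isTRUE(all.equal(m, t(m))))
    msg <- c(msg, "substitution matrix must be symmetric")
  if (!(object@gapOpen <= object@gapExtend && object@gapExtend < 0))
    msg <- c(msg, "gap penalties must satisfy gapOpen <= gapExtend < 0")
  if (object@lambda <= 0 || object@k <= 0)
    msg <- c(msg, "lambda and k must be positive")
  if (!object@type %in% c("protein", "nucleotide"))
    msg <- c(msg, "type must be 'protein' or 'nucleotide'")
  if (length(msg)) msg else TRUE
})

setMethod("show", "ScoringScheme", function(object) {
  cat("ScoringScheme (", object@type, ")\n", sep = "")
  cat("  alphabet: ", paste(head(rownames(object@matrix), 8), collapse = ""),
      if (nrow(object@matrix) > 8) "..." else "", "\n", sep = "")
  cat(sprintf("  gapOpen %d, gapExtend %d; lambda %.3f, K %.3f\n",
              as.integer(object@gapOpen), as.integer(object@gapExtend),
              object@lambda, object@k))
})

#' Pairwise alignment result
#'
#' Result of [alignGlobal()] or [alignLocal()]. Identity is the fraction of
#' identical columns over all alignment columns including gap columns;
#' coverage is the aligned span divided by the full sequence length,
#' computed separately for query and target.
#'
#' @slot queryId,targetId sequence identifiers.
#' @slot mode `"global"` or `"local"`.
#' @slot rawScore integer DP score.
#' @slot bitScore,evalue Karlin-Altschul statistics (see [ScoringScheme]).
#' @slot identity fraction in `[0, 1]`.
#' @slot queryCoverage,targetCoverage fractions in `[0, 1]`.
#' @slot queryRange,targetRange 1-based inclusive aligned spans.
#' @slot alignedPairs two-column integer matrix of aligned residue positions
#'   (1-based; gap columns omitted).
#' @slot nColumns,nIdentical alignment column counts.
#' @exportClass PairAlignment
setClass("PairAlignment",
  representation(queryId = "character", targetId = "character", mode = "character",
                 rawScore = "integer", bitScore = "numeric", evalue = "numeric",
                 identity = "numeric", queryCoverage = "numeric",
                 targetCoverage = "numeric", queryRange = "integer",
                 targetRange = "integer", alignedPairs = "matrix",
                 nColumns = "integer", nIdentical = "integer"))

setValidity("PairAlignment", function(object) {
  msg <- character()
  fr <- c(object@identity, object@queryCoverage, object@targetCoverage)
  if (any(fr < 0 | fr > 1)) msg <- c(msg, "identity and coverages must lie in [0, 1]")
  if (object@evalue < 0) msg <- c(msg, "evalue must be non-negative")
  if (length(msg)) msg else TRUE
})

setMethod("show", "PairAlignment", function(object) {
  cat(sprintf("PairAlignment (%s): %s vs %s\n", object@mode,
              object@queryId, object@targetId))
  cat(sprintf("  raw %d | bits %.1f | E %.3g | identity %.3f | cov %.2f/%.2f\n",
              object@rawScore, object@bitScore, object@evalue, object@identity,
              object@queryCoverage, object@targetCoverage))
})

#' Profile hidden Markov model for a marker protein family
#'
#' A Krogh-style profile HMM with match, insert and delete states built from
#' a multiple alignment by [buildProfile()]. Insert states emit the
#' background distribution. The optional calibration slot holds Gumbel
#' location/scale fitted to shuffled-decoy bit scores by
#' [calibrateEvalues()].
#'
#' @slot name marker family name.
#' @slot M number of match states.
#' @slot matchEmissions `M x 20` matrix of match emission probabilities.
#' @slot insertEmissions background emission probabilities (length 20).
#' @slot transitions `(M + 1) x 7` matrix of transition probabilities with
#'   columns MM, MI, MD, IM, II, DM, DD, row `k + 1` holding transitions out
#'   of node `k` (row 1 is the begin node).
#' @slot background length-20 background distribution.
#' @slot calibration numeric; empty, or `c(mu, beta, decoys)` after
#'   calibration.
#' @slot trainingLengths ungapped lengths of the training sequences.
#' @exportClass ProfileHMM
setClass("ProfileHMM",
  representation(name = "character", M = "integer",
                 matchEmissions = "matrix", insertEmissions = "numeric",
                 transitions = "matrix", background = "numeric",
                 calibration = "numeric", trainingLengths = "integer"))

setValidity("ProfileHMM", function(object) {
  msg <- character()
  if (object@M < 1) msg <- c(msg, "profile must have at least one match state")
  if (nrow(object@matchEmissions) != object@M)
    msg <- c(msg, "matchEmissions must have M rows")
  if (any(abs(rowSums(object@matchEmissions) - 1) > 1e-9))
    msg <- c(msg, "match emission rows must sum to 1")
  if (abs(sum(object@background) - 1) > 1e-9)
    msg <- c(msg, "background must sum to 1")
  if (abs(sum(object@insertEmissions) - 1) > 1e-9)
    msg <- c(msg, "insert emissions must sum to 1")
  tr <- object@transitions
  if (nrow(tr) != object@M + 1 || ncol(tr) != 7)
    msg <- c(msg, "transitions must be (M + 1) x 7")
  else {
    groups <- list(c("MM", "MI", "MD"), c("IM", "II"), c("DM", "DD"))
    for (g in groups)
      if (any(abs(rowSums(tr[, g, drop = FALSE]) - 1) > 1e-9))
        msg <- c(msg, sprintf("transition group (%s) rows must sum to 1",
                              paste(g, collapse = ",")))
  }
  if (length(msg)) msg else TRUE
})

setMethod("show", "ProfileHMM", function(object) {
  cat(sprintf("ProfileHMM '%s': %d match states, %d training sequences%s\n",
              object@name, object@M, length(object@trainingLengths),
              if (length(object@calibration))
                sprintf(" (calibrated: mu %.2f, beta %.2f)",
                        object@calibration[1], object@calibration[2]) else ""))
})

#' Genome-by-cluster presence/absence matrix
#'
#' Boolean pangenome matrix: `presence[i, j]` is `TRUE` when genome `i`
#' contributes at least one protein to ortholog cluster `j`. Built by
#' [buildPangenome()]; exported as a bipartite protein-sharing network by
#' [exportBipartiteNetwork()].
#'
#' @slot presence logical matrix with genome rownames and cluster colnames.
#' @exportClass PangenomeMatrix
setClass("PangenomeMatrix", representation(presence = "matrix"))

setValidity("PangenomeMatrix", function(object) {
  p <- object@presence
  if (!is.logical(p)) return("presence must be a logical matrix")
  if (is.null(rownames(p)) || is.null(colnames(p)))
    return("presence must carry genome rownames and cluster colnames")
  TRUE
})

setMethod("show", "PangenomeMatrix", function(object) {
  p <- object@presence
  cat(sprintf("PangenomeMatrix: %d genomes x %d clusters, %d presences\n",
              nrow(p), ncol(p), sum(p)))
})

#' Screening and orthology thresholds
#'
#' Holds every numeric threshold of the screen: the plasmid size window, the
#' markers a genome must hit to be selected, profile-HMM acceptance, family
#' cluster size for profile building, genome deduplication thresholds and
#' the orthology coverage/E-value cutoffs.
#'
#' @slot minLenBp,maxLenBp inclusive genome size window in bp (15-500 kbp).
#' @slot requiredMarkers markers a genome must hit to be selected.
#' @slot hitBits profile-HMM bit score acceptance threshold.
#' @slot hitEvalue E-value cutoff used instead of `hitBits` when profiles are
#'   calibrated (`NA` disables).
#' @slot familyMinSize minimum cluster size used to build a profile.
#' @slot dedupIdentity,dedupCoverage genome deduplication thresholds.
#' @slot orthoQueryCoverage,orthoEvalue all-vs-all homology thresholds.
#' @slot groupThreshold shared-protein-content similarity threshold for
#'   genome grouping.
#' @slot tmpMinAa minimum CDS length (aa) for an intact tape measure protein.
#' @slot terminaseCovMin minimum profile match-state coverage below which the
#'   terminase is called truncated.
#' @slot adapterMaxAa maximum length of a partitioning adapter protein.
#' @slot serineSmallMaxAa,serineLargeMinAa serine recombinase class bounds.
#' @exportClass ScreenConfig
setClass("ScreenConfig",
  representation(minLenBp = "numeric", maxLenBp = "numeric",
                 requiredMarkers = "character", hitBits = "numeric",
                 hitEvalue = "numeric", familyMinSize = "integer",
                 dedupIdentity = "numeric", dedupCoverage = "numeric",
                 orthoQueryCoverage = "numeric", orthoEvalue = "numeric",
                 groupThreshold = "numeric", tmpMinAa = "numeric",
                 terminaseCovMin = "numeric", adapterMaxAa = "numeric",
                 serineSmallMaxAa = "numeric", serineLargeMinAa = "numeric"))

setValidity("ScreenConfig", function(object) {
  msg <- character()
  if (!(object@minLenBp < object@maxLenBp))
    msg <- c(msg, "minLenBp must be smaller than maxLenBp")
  if (!length(object@requiredMarkers))
    msg <- c(msg, "requiredMarkers must be non-empty")
  if (!(object@groupThreshold > 0 && object@groupThreshold <= 1))
    msg <- c(msg, "groupThreshold must lie in (0, 1]")
  if (length(msg)) msg else TRUE
})

setMethod("show", "ScreenConfig", function(object) {
  cat("ScreenConfig\n")
  cat(sprintf("  size window: %d-%d bp; required markers: %s\n",
              as.integer(object@minLenBp), as.integer(object@maxLenBp),
              paste(object@requiredMarkers, collapse = " + ")))
  cat(sprintf("  hit >= %.0f bits; dedup %.2f/%.2f; orthology qcov >= %.2f, E <= %g; grouping >= %.2f\n",
              object@hitBits, object@dedupIdentity, object@dedupCoverage,
              object@orthoQueryCoverage, object@orthoEvalue, object@groupThreshold))
})

#' Synthetic plasmid dataset specification
#'
#' Describes the synthetic world the generator emits: how many plasmid
#' genomes of which planted prophage state, how many genome groups share a
#' cargo-gene repertoire, how diverged marker family members are, and which
#' duplicate/near-duplicate pairs are planted for the deduplication tests.
#'
#' @slot seed integer seed; all generator randomness flows from it.
#' @slot nGenomes number of unique genomes.
#' @slot stateMix named counts (`active`, `degenerated`, `virulent`,
#'   `non_phage`) summing to `nGenomes`.
#' @slot nGroups planted genome groups sharing cargo repertoires.
#' @slot familyDivergence per-sequence substitution fraction for marker
#'   family members (0-0.6).
#' @slot withinGroupDivergence substitution fraction for within-group cargo
#'   copies.
#' @slot duplicatePairs planted duplicate pairs: one exact copy, one copy at
#'   `nearDuplicateIdentity`, one within-set pair at `distantPairIdentity`.
#' @slot nearDuplicateIdentity,distantPairIdentity nucleotide identities of
#'   the planted near-duplicate (merges at 0.99) and the distant pair
#'   (stays distinct).
#' @slot genomeLengthRange genome length window in bp.
#' @slot intergenicMean mean intergenic spacer length in bp.
#' @slot cargoPerGenome cargo genes per phage-like genome.
#' @slot familyMembers reference sequences emitted per marker family.
#' @slot nMyovirus number of active genomes additionally carrying a tail
#'   sheath gene (myovirus-like morphotype).
#' @exportClass GeneratorSpec
setClass("GeneratorSpec",
  representation(seed = "integer", nGenomes = "integer", stateMix = "integer",
                 nGroups = "integer", familyDivergence = "numeric",
                 withinGroupDivergence = "numeric", duplicatePairs = "integer",
                 nearDuplicateIdentity = "numeric", distantPairIdentity = "numeric",
                 genomeLengthRange = "numeric", intergenicMean = "numeric",
                 cargoPerGenome = "integer", familyMembers = "integer",
                 nMyovirus = "integer"))

setValidity("GeneratorSpec", function(object) {
  msg <- character()
  if (sum(object@stateMix) != object@nGenomes)
    msg <- c(msg, "stateMix counts must sum to nGenomes")
  if (!all(c("active", "degenerated", "virulent", "non_phage") %in%
           names(object@stateMix)))
    msg <- c(msg, "stateMix must name active, degenerated, virulent, non_phage")
  if (object@familyDivergence < 0 || object@familyDivergence > 0.6)
    msg <- c(msg, "familyDivergence must lie in [0, 0.6]")
  if (object@genomeLengthRange[1] >= object@genomeLengthRange[2])
    msg <- c(msg, "genomeLengthRange must be increasing")
  if (length(msg)) msg else TRUE
})

setMethod("show", "GeneratorSpec", function(object) {
  cat(sprintf("GeneratorSpec: %d genomes (%s), %d groups, divergence %.2f, seed %d\n",
              object@nGenomes,
              paste(sprintf("%d %s", object@stateMix, names(object@stateMix)),
                    collapse = " / "),
              object@nGroups, object@familyDivergence, object@seed))
})
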