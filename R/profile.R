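#' @include msa.R
NULL

#' The 20 standard amino acids, in the emission column order used by
#' [ProfileHMM] objects.
#' @format character vector of single-letter residue codes.
#' @export
AA20 <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]

.TRCOLS <- c("MM", "MI", "MD", "IM", "II", "DM", "DD")

#' Build a profile HMM from a multiple alignment
#'
#' Columns with more than 50% non-gap residues become match states; all
#' other columns are treated as insertions relative to the profile. Match
#' emissions and state transitions are Laplace(+1)-smoothed observed counts;
#' insert states emit the background distribution (uniform 1/20 by
#' default).
#'
#' @param msa named character vector of equal-length gapped rows, as
#'   returned by [centerStarMSA()] or [readMsa()].
#' @param name marker family name stored on the profile.
#' @param background length-20 emission background (sums to 1).
#' @return A [ProfileHMM].
#' @examples
#' buildProfile(c(a = "AC-E", b = "ACDE", c = "AC-E"), "toy")
#' @export
buildProfile <- function(msa, name, background = rep(1 / 20, 20)) {
  if (length(msa) < 1) stop("empty alignment")
  mat <- do.call(rbind, strsplit(msa, "", fixed = TRUE))
  if (is.null(rownames(mat))) rownames(mat) <- names(msa)
  ncols <- ncol(mat)
  nongap <- colMeans(mat != "-")
  isMatch <- nongap > 0.5
  M <- sum(isMatch)
  if (M == 0) stop("alignment has no column with a residue majority; cannot build a profile")

  # emissions
  em <- matrix(1, nrow = M, ncol = 20, dimnames = list(NULL, AA20))  # +1 pseudocount
  matchCols <- which(isMatch)
  for (k in seq_len(M)) {
    res <- mat[, matchCols[k]]
    res <- res[res %in% AA20]
    if (length(res)) {
      tab <- table(factor(res, levels = AA20))
      em[k, ] <- em[k, ] + as.numeric(tab)
    }
  }
  em <- em / rowSums(em)

  # transitions: walk each row through its state path
  trCounts <- matrix(1, nrow = M + 1, ncol = 7, dimnames = list(NULL, .TRCOLS))
  colState <- ifelse(isMatch, "M", "I")
  nodeOfCol <- cumsum(isMatch)  # node index after this column
  for (r in seq_len(nrow(mat))) {
    prev <- "B"; prevNode <- 0L
    for (c in seq_len(ncols)) {
      if (colState[c] == "M") {
        cur <- if (mat[r, c] == "-") "D" else "M"
        node <- nodeOfCol[c]
      } else {
        if (mat[r, c] == "-") next
        cur <- "I"
        node <- nodeOfCol[c]
      }
      key <- paste0(if (prev == "B") "M" else prev, cur)  # begin counted as M0
      trCounts[prevNode + 1L, key] <- trCounts[prevNode + 1L, key] + 1
      prev <- cur; prevNode <- node
    }
    # exit: from final state into the end node, counted as an M-type move
    key <- paste0(if (prev == "B") "M" else prev, "M")
    trCounts[prevNode + 1L, key] <- trCounts[prevNode + 1L, key] + 1
  }
  tr <- trCounts
  tr[, c("MM", "MI", "MD")] <- tr[, c("MM", "MI", "MD")] /
    rowSums(tr[, c("MM", "MI", "MD")])
  tr[, c("IM", "II")] <- tr[, c("IM", "II")] / rowSums(tr[, c("IM", "II")])
  tr[, c("DM", "DD")] <- tr[, c("DM", "DD")] / rowSums(tr[, c("DM", "DD")])

  lens <- as.integer(nchar(gsub("-", "", msa, fixed = TRUE)))
  new("ProfileHMM", name = name, M = as.integer(M), matchEmissions = em,
      insertEmissions = background, transitions = tr, background = background,
      calibration = numeric(0), trainingLengths = lens)
}

.profileLogOdds <- function(profile) {
  list(mlo = log2(sweep(profile@matchEmissions, 2, profile@background, "/")),
       tlo = log2(profile@transitions))
}

.encodeAA <- function(x) {
  code <- match(strsplit(x, "", fixed = TRUE)[[1]], AA20)
  code[is.na(code)] <- 0L  # ambiguous -> background (emits log-odds 0)
  code - 1L
}

#' Search a protein sequence with a profile HMM
#'
#' Computes the optimal local Viterbi log-odds score in bits, with free
#' entry/exit at any match state and cost-free flanking residues. A hit is
#' returned when the bit score reaches `bits` or, for a calibrated profile
#' with `eCutoff` set, when the E-value is at most `eCutoff`; otherwise
#' `NULL`.
#'
#' @param profile a [ProfileHMM].
#' @param sequence protein sequence (ambiguous residues emit background).
#' @param bits bit score acceptance threshold (default 25).
#' @param eCutoff optional E-value cutoff; requires a calibrated profile.
#' @param dbSize database size multiplying the Gumbel tail probability when
#'   E-values are computed (number of proteins searched in the run).
#' @return `NULL` or a one-row `data.frame` with `profile`, `bit_score`,
#'   `evalue`, `coverage` (fraction of match states spanned), `start`,
#'   `end` (1-based region on the protein).
#' @export
searchProfile <- function(profile, sequence, bits = 25, eCutoff = NULL,
                          dbSize = 1) {
  if (!nzchar(sequence)) stop("protein sequence must be non-empty")
  lo <- .profileLogOdds(profile)
  code <- .encodeAA(sequence)
  score <- cpp_phmm_score(code, lo$mlo, lo$tlo)
  if (is.na(score)) return(NULL)
  ev <- profileEvalue(profile, score, dbSize)
  accept <- if (!is.null(eCutoff)) {
    if (is.na(ev)) stop("eCutoff requires a calibrated profile; run calibrateEvalues()")
    ev <= eCutoff
  } else score >= bits
  if (!accept) return(NULL)
  res <- cpp_phmm(code, lo$mlo, lo$tlo, FALSE)  # full pass for the region
  data.frame(profile = profile@name, bit_score = res$score, evalue = ev,
             coverage = (res$kend - res$kstart + 1) / profile@M,
             start = res$jstart, end = res$jend, stringsAsFactors = FALSE)
}

#' Viterbi and Forward scores of a profile HMM
#'
#' Lower-level scoring interface used by tests and diagnostics:
#' `profileViterbi()` returns the optimal local path log-odds in bits
#' (with region and match-state span), `profileForward()` the log2-summed
#' odds over all local paths (always at least the Viterbi score).
#'
#' @inheritParams searchProfile
#' @return `profileViterbi()`: list with `score`, `jstart`, `jend`,
#'   `kstart`, `kend`; `profileForward()`: numeric score.
#' @export
profileViterbi <- function(profile, sequence) {
  lo <- .profileLogOdds(profile)
  cpp_phmm(.encodeAA(sequence), lo$mlo, lo$tlo, FALSE)
}

#' @rdname profileViterbi
#' @export
profileForward <- function(profile, sequence) {
  lo <- .profileLogOdds(profile)
  cpp_phmm(.encodeAA(sequence), lo$mlo, lo$tlo, TRUE)$score
}

#' Gumbel E-value of a bit score under a calibrated profile
#'
#' `E(s) = dbSize * P(S >= s)` with `P` the Gumbel survival function fitted
#' by [calibrateEvalues()]. Returns `NA` for uncalibrated profiles.
#'
#' @param profile a [ProfileHMM].
#' @param bits bit score(s).
#' @param dbSize database size (number of proteins searched).
#' @return numeric E-value(s).
#' @export
profileEvalue <- function(profile, bits, dbSize = 1) {
  if (!length(profile@calibration)) return(NA_real_)
  mu <- profile@calibration[1]; beta <- profile@calibration[2]
  dbSize * (-expm1(-exp(-(bits - mu) / beta)))
}

#' Calibrate profile E-values on shuffled decoys
#'
#' Scores `decoys` background-composition decoy sequences (lengths sampled
#' with replacement from the profile's training lengths) and fits a Gumbel
#' distribution to the bit scores by the method of moments
#' (`beta = sd * sqrt(6) / pi`, `mu = mean - gamma * beta`). The fitted
#' parameters are stored on the returned profile and drive
#' [profileEvalue()].
#'
#' @param profile a [ProfileHMM].
#' @param decoys number of decoy sequences (at least 100).
#' @param seed integer seed for decoy generation.
#' @return The calibrated [ProfileHMM].
#' @export
calibrateEvalues <- function(profile, decoys = 500L, seed = 1L) {
  if (decoys < 100) stop("at least 100 decoys are required for calibration")
  scores <- decoyScores(profile, decoys, seed)
  beta <- sd(scores) * sqrt(6) / pi
  mu <- mean(scores) - 0.5772156649 * beta
  profile@calibration <- c(mu = mu, beta = beta, decoys = as.numeric(decoys))
  validObject(profile)
  profile
}

#' @rdname calibrateEvalues
#' @return `decoyScores()`: numeric vector of decoy bit scores.
#' @export
decoyScores <- function(profile, decoys, seed = 1L) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  lens <- sample(profile@trainingLengths, decoys, replace = TRUE)
  lo <- .profileLogOdds(profile)
  vapply(lens, function(l) {
    s <- sample.int(20L, l, replace = TRUE, prob = profile@background) - 1L
    cpp_phmm_score(s, lo$mlo, lo$tlo)
  }, numeric(1))
}

#' Read and write profile HMMs as JSON
#'
#' Plain-text JSON serialization of a [ProfileHMM] with full numeric
#' precision.
#'
#' @param profile a [ProfileHMM].
#' @param path file path.
#' @return `writeProfileJson()` returns `path` invisibly;
#'   `readProfileJson()` returns a [ProfileHMM].
#' @export
writeProfileJson <- function(profile, path) {
  obj <- list(name = profile@name, M = profile@M,
              match_emissions = profile@matchEmissions,
              insert_emissions = profile@insertEmissions,
              transitions = profile@transitions,
              transition_names = .TRCOLS,
              background = profile@background,
              calibration = profile@calibration,
              training_lengths = profile@trainingLengths)
  jsonlite::write_json(obj, path, digits = NA, auto_unbox = TRUE)
  invisible(path)
}

#' @rdname writeProfileJson
#' @export
readProfileJson <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  em <- obj$match_emissions
  dimnames(em) <- list(NULL, AA20)
  tr <- obj$transitions
  dimnames(tr) <- list(NULL, .TRCOLS)
  new("ProfileHMM", name = obj$name, M = as.integer(obj$M),
      matchEmissions = em, insertEmissions = as.numeric(obj$insert_emissions),
      transitions = tr, background = as.numeric(obj$background),
      calibration = if (length(obj$calibration)) {
        cal <- as.numeric(obj$calibration)
        names(cal) <- c("mu", "beta", "decoys")[seq_along(cal)]
        cal
      } else numeric(0),
      trainingLengths = as.integer(obj$training_lengths))
}

#' Read a multiple alignment from aligned FASTA or Stockholm
#'
#' Thin wrapper over [Biostrings::readAAMultipleAlignment()] returning the
#' named gapped rows used by [buildProfile()].
#'
#' @param path alignment file.
#' @param format `"fasta"` or `"stockholm"`.
#' @return named character vector of gapped rows.
#' @export
readMsa <- function(path, format = c("fasta", "stockholm")) {
  format <- match.arg(format)
  aln <- Biostrings::readAAMultipleAlignment(path, format = format)
  rows <- as.character(aln)
  gsub("[.]", "-", rows)
}
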