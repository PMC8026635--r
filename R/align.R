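#' @include AllGenerics.R
NULL

.blosum62 <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      e <- new.env()
      data("BLOSUM62", package = "Biostrings", envir = e)
      cache <<- e$BLOSUM62
    }
    cache
  }
})

#' Protein and nucleotide scoring schemes
#'
#' `proteinScheme()` returns the default protein scheme (BLOSUM62,
#' gap open/extend -11/-1, gapped Karlin-Altschul parameters
#' lambda = 0.267, K = 0.041). `nucleotideScheme()` returns a
#' match/mismatch scheme (+1/-2, gaps -5/-2) over A, C, G, T, N, with N
#' scoring as a mismatch against everything. A gap of length L costs
#' `gapOpen + (L - 1) * gapExtend`.
#'
#' @param gapOpen,gapExtend negative gap penalties,
#'   `gapOpen <= gapExtend < 0`.
#' @param lambda,k Karlin-Altschul parameters used for bit scores and
#'   E-values.
#' @param substitutionMatrix optional symmetric matrix overriding the
#'   default.
#' @param match,mismatch nucleotide match/mismatch scores.
#' @return A [ScoringScheme] object.
#' @examples
#' proteinScheme()
#' nucleotideScheme()
#' @export
proteinScheme <- function(gapOpen = -11, gapExtend = -1,
                          lambda = 0.267, k = 0.041,
                          substitutionMatrix = NULL) {
  m <- if (is.null(substitutionMatrix)) .blosum62() else substitutionMatrix
  new("ScoringScheme", type = "protein", matrix = m,
      gapOpen = gapOpen, gapExtend = gapExtend, lambda = lambda, k = k)
}

#' @rdname proteinScheme
#' @export
nucleotideScheme <- function(match = 1, mismatch = -2,
                             gapOpen = -5, gapExtend = -2,
                             lambda = 1.28, k = 0.46) {
  ab <- c("A", "C", "G", "T", "N")
  m <- matrix(mismatch, 5, 5, dimnames = list(ab, ab))
  diag(m) <- match
  m["N", "N"] <- mismatch
  new("ScoringScheme", type = "nucleotide", matrix = m,
      gapOpen = gapOpen, gapExtend = gapExtend, lambda = lambda, k = k)
}

.encodeSeq <- function(x, scheme, what = "sequence") {
  if (!nzchar(x)) stop(what, " must be non-empty")
  ch <- strsplit(x, "", fixed = TRUE)[[1]]
  code <- match(ch, rownames(scheme@matrix))
  if (anyNA(code)) {
    bad <- unique(ch[is.na(code)])
    stop(sprintf("symbol '%s' in %s is absent from the substitution matrix",
                 bad[1], what))
  }
  code - 1L
}

#' Karlin-Altschul bit scores and E-values
#'
#' `bitScoreOf()` converts a raw alignment score to bits,
#' `(lambda * S - log(K)) / log(2)`; `evalueOf()` converts bits to the
#' expected number of chance alignments in an `m x n` search space,
#' `m * n * 2^-bits`.
#'
#' @param rawScore raw alignment score(s).
#' @param scheme a [ScoringScheme].
#' @param bits bit score(s).
#' @param m,n sequence lengths spanning the search space.
#' @return numeric vector.
#' @export
bitScoreOf <- function(rawScore, scheme) {
  (scheme@lambda * rawScore - log(scheme@k)) / log(2)
}

#' @rdname bitScoreOf
#' @export
evalueOf <- function(bits, m, n) {
  as.numeric(m) * as.numeric(n) * 2^(-bits)
}

.alignPair <- function(a, b, scheme, local, band, queryId, targetId) {
  ca <- .encodeSeq(a, scheme, "query")
  cb <- .encodeSeq(b, scheme, "target")
  n <- length(ca); m <- length(cb)
  if (is.null(band)) {
    if (as.numeric(n) * m > 4e8)
      stop("sequences too long for unbanded alignment; supply a band width")
    band <- 0L
  }
  res <- cpp_align(ca, cb, scheme@matrix, as.integer(scheme@gapOpen),
                   as.integer(scheme@gapExtend), local, as.integer(band))
  ops <- res$ops
  nCols <- res$ncols
  empty <- nCols == 0L
  qspan <- if (empty) 0L else res$qend - res$qstart + 1L
  tspan <- if (empty) 0L else res$tend - res$tstart + 1L
  pairs <- if (empty) matrix(integer(), 0, 2) else {
    qi <- res$qstart - 1L + cumsum(ops != 2L)
    ti <- res$tstart - 1L + cumsum(ops != 1L)
    keep <- ops == 0L
    cbind(query = qi[keep], target = ti[keep])
  }
  bits <- bitScoreOf(res$score, scheme)
  new("PairAlignment",
      queryId = queryId, targetId = targetId,
      mode = if (local) "local" else "global",
      rawScore = as.integer(res$score), bitScore = bits,
      evalue = evalueOf(bits, n, m),
      identity = if (empty) 0 else res$nident / nCols,
      queryCoverage = qspan / n, targetCoverage = tspan / m,
      queryRange = c(res$qstart, res$qend), targetRange = c(res$tstart, res$tend),
      alignedPairs = pairs, nColumns = nCols, nIdentical = res$nident)
}

#' Optimal pairwise alignment with affine gaps
#'
#' `alignGlobal()` computes the optimal Needleman-Wunsch global alignment,
#' `alignLocal()` the optimal Smith-Waterman local alignment, both under
#' affine gap costs with deterministic tie-breaking (diagonal over up over
#' left). Bit scores and E-values follow the Karlin-Altschul convention of
#' the scheme.
#'
#' For very long, near-identical sequences (genome deduplication)
#' `alignGlobal()` accepts a `band` half-width: the dynamic program is
#' restricted to diagonals within `band` of the main band spanned by the
#' length difference. Any alignment whose gap columns fit in the band is
#' scored exactly, so a band of `(1 - minIdentity) * maxLength` columns is
#' sufficient to decide identity thresholds of `minIdentity` or more.
#'
#' @param a,b character strings (query and target).
#' @param scheme a [ScoringScheme]; defaults to [proteinScheme()].
#' @param band optional integer band half-width (global only); `NULL` for
#'   the full matrix.
#' @param queryId,targetId identifiers stored in the result.
#' @return A [PairAlignment].
#' @examples
#' alignGlobal("ACGT", "ACGT", nucleotideScheme())
#' alignLocal("HEAGAWGHEE", "PAWHEAE")
#' @export
alignGlobal <- function(a, b, scheme = proteinScheme(), band = NULL,
                        queryId = "query", targetId = "target") {
  .alignPair(a, b, scheme, local = FALSE, band = band,
             queryId = queryId, targetId = targetId)
}

#' @rdname alignGlobal
#' @export
alignLocal <- function(a, b, scheme = proteinScheme(),
                       queryId = "query", targetId = "target") {
  .alignPair(a, b, scheme, local = TRUE, band = 0L,
             queryId = queryId, targetId = targetId)
}
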