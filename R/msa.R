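#' @include align.R
NULL

#' Center-star multiple sequence alignment
#'
#' Builds a multiple alignment by the center-star method: the center is the
#' member maximizing the summed pairwise local alignment score to all other
#' members (ties broken by length, then identifier); every member is then
#' aligned globally to the center and the pairwise alignments are merged
#' under the once-a-gap-always-a-gap rule.
#'
#' @param members named character vector of at least two sequences.
#' @param scheme a [ScoringScheme] (default [proteinScheme()]).
#' @return Named character vector of equal-length gapped rows (gap `"-"`),
#'   with the center identifier in attribute `"center"`.
#' @examples
#' centerStarMSA(c(s1 = "ACDE", s2 = "ACE"))
#' @export
centerStarMSA <- function(members, scheme = proteinScheme()) {
  if (length(members) < 2) stop("at least two sequences are required")
  ids <- names(members)
  n <- length(members)
  sums <- numeric(n)
  for (i in seq_len(n - 1)) {
    for (j in seq(i + 1, n)) {
      s <- alignLocal(members[[i]], members[[j]], scheme)@rawScore
      sums[i] <- sums[i] + s
      sums[j] <- sums[j] + s
    }
  }
  ord <- order(-sums, -nchar(members), ids, method = "radix")
  center <- ord[1]
  Lc <- nchar(members[[center]])
  others <- setdiff(seq_len(n), center)

  # ops per member against the center (a = center, b = member):
  # 0 diag, 1 center residue vs gap, 2 member insertion
  opsList <- vector("list", n)
  insAt <- function(ops) {
    # insertions indexed by number of center residues consumed (0..Lc)
    ins <- integer(Lc + 1)
    pos <- 0L
    for (op in ops) {
      if (op == 2L) ins[pos + 1L] <- ins[pos + 1L] + 1L
      else pos <- pos + 1L
    }
    ins
  }
  maxIns <- integer(Lc + 1)
  for (i in others) {
    ca <- .encodeSeq(members[[center]], scheme)
    cb <- .encodeSeq(members[[i]], scheme)
    res <- cpp_align(ca, cb, scheme@matrix, as.integer(scheme@gapOpen),
                     as.integer(scheme@gapExtend), FALSE, 0L)
    opsList[[i]] <- res$ops
    maxIns <- pmax(maxIns, insAt(res$ops))
  }

  buildRow <- function(seqChars, ops) {
    out <- character(0)
    pos <- 0L  # center residues consumed
    bpos <- 0L # member residues consumed
    emitSlot <- function(insChars) {
      pad <- maxIns[pos + 1L] - length(insChars)
      c(insChars, rep("-", pad))
    }
    insBuf <- character(0)
    for (op in ops) {
      if (op == 2L) {
        bpos <- bpos + 1L
        insBuf <- c(insBuf, seqChars[bpos])
      } else {
        out <- c(out, emitSlot(insBuf)); insBuf <- character(0)
        if (op == 0L) {
          bpos <- bpos + 1L
          out <- c(out, seqChars[bpos])
        } else {
          out <- c(out, "-")
        }
        pos <- pos + 1L
      }
    }
    out <- c(out, emitSlot(insBuf))
    paste(out, collapse = "")
  }

  rows <- character(n); names(rows) <- ids
  centerChars <- strsplit(members[[center]], "")[[1]]
  centerOps <- rep(0L, Lc)
  rows[center] <- buildRow(centerChars, centerOps)
  for (i in others) {
    rows[i] <- buildRow(strsplit(members[[i]], "")[[1]], opsList[[i]])
  }
  out <- rows[ids]
  attr(out, "center") <- ids[center]
  out
}
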