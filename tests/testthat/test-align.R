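# pairwise alignment: scoring schemes, identity/coverage conventions,
# Karlin-Altschul statistics, and agreement with exhaustive enumeration
# and with an independent aligner.

test_that("scheme construction enforces its invariants", {
  expect_error(nucleotideScheme(gapOpen = 1), "gapOpen")
  expect_error(proteinScheme(lambda = -1), "positive")
  m <- matrix(c(1, 2, 3, 1), 2, 2, dimnames = list(c("A", "B"), c("A", "B")))
  expect_error(proteinScheme(substitutionMatrix = m), "symmetric")
})

test_that("global alignment handles identity and near-identity cases", {
  nt <- nucleotideScheme()
  a <- alignGlobal("ACGT", "ACGT", nt)
  expect_equal(a@rawScore, 4L)
  expect_equal(a@identity, 1)
  expect_equal(a@queryCoverage, 1)

  b <- alignGlobal("AAAA", "AAAT", nt)
  expect_equal(b@identity, 0.75)

  expect_error(alignGlobal("", "ACGT", nt), "non-empty")
  expect_error(alignGlobal("ACGU", "ACGT", nt), "U")
})

test_that("classic protein pair matches an independent aligner", {
  a <- alignGlobal("HEAGAWGHEE", "PAWHEAE")
  l <- alignLocal("HEAGAWGHEE", "PAWHEAE")
  # independent route: Biostrings pairwiseAlignment with the equivalent
  # gap parameterization (opening excludes the first extension there)
  bg <- Biostrings::pairwiseAlignment(
    "HEAGAWGHEE", "PAWHEAE", substitutionMatrix = "BLOSUM62",
    gapOpening = 10, gapExtension = 1, type = "global", scoreOnly = TRUE)
  bl <- Biostrings::pairwiseAlignment(
    "HEAGAWGHEE", "PAWHEAE", substitutionMatrix = "BLOSUM62",
    gapOpening = 10, gapExtension = 1, type = "local", scoreOnly = TRUE)
  expect_equal(a@rawScore, as.integer(bg))
  expect_equal(l@rawScore, as.integer(bl))
})

test_that("local self-alignment covers the full sequence with the diagonal score", {
  sch <- proteinScheme()
  for (s in c("MKV", "ACDEFGHIKLMNPQRSTVWY", "WWAWW")) {
    a <- alignLocal(s, s, sch)
    expect_equal(a@queryCoverage, 1)
    expect_equal(a@targetCoverage, 1)
    diagScore <- sum(diag(sch@matrix[strsplit(s, "")[[1]],
                                     strsplit(s, "")[[1]], drop = FALSE]))
    expect_equal(a@rawScore, as.integer(diagScore))
    expect_equal(a@identity, 1)
  }
})

test_that("DP scores equal exhaustive enumeration on random short pairs", {
  set.seed(101)
  nt <- nucleotideScheme()
  for (rep in seq_len(60)) {
    a <- randomSeq(sample(1:6, 1), c("A", "C", "G", "T"))
    b <- randomSeq(sample(1:6, 1), c("A", "C", "G", "T"))
    expect_equal(alignGlobal(a, b, nt)@rawScore, as.integer(enumGlobalScore(a, b, nt)),
                 info = paste(a, b, "global"))
    expect_equal(alignLocal(a, b, nt)@rawScore, as.integer(enumLocalScore(a, b, nt)),
                 info = paste(a, b, "local"))
  }
})

test_that("alignment score is symmetric in its arguments", {
  set.seed(7)
  sch <- proteinScheme()
  for (rep in seq_len(20)) {
    a <- randomSeq(sample(3:12, 1), AA20)
    b <- randomSeq(sample(3:12, 1), AA20)
    expect_equal(alignGlobal(a, b, sch)@rawScore, alignGlobal(b, a, sch)@rawScore)
    expect_equal(alignLocal(a, b, sch)@rawScore, alignLocal(b, a, sch)@rawScore)
  }
})

test_that("E-values decrease strictly with bit score at fixed search space", {
  sch <- proteinScheme()
  scores <- c(10, 20, 40, 80)
  bits <- bitScoreOf(scores, sch)
  ev <- evalueOf(bits, 300, 400)
  expect_true(all(diff(bits) > 0))
  expect_true(all(diff(ev) < 0))
  expect_equal(bits, (sch@lambda * scores - log(sch@k)) / log(2))
  expect_equal(ev, 300 * 400 * 2^(-bits))
})

test_that("the score-only local kernel agrees with the traceback kernel", {
  set.seed(77)
  sch <- proteinScheme()
  for (rep in seq_len(40)) {
    a <- randomSeq(sample(1:50, 1), AA20)
    b <- randomSeq(sample(1:50, 1), AA20)
    full <- alignLocal(a, b, sch)@rawScore
    fast <- prophageScreen:::cpp_align_score_local(
      prophageScreen:::.encodeSeq(a, sch), prophageScreen:::.encodeSeq(b, sch),
      sch@matrix, -11L, -1L)
    expect_identical(full, as.integer(fast))
  }
})

test_that("banded global alignment is exact for near-identical long sequences", {
  set.seed(23)
  dna <- c("A", "C", "G", "T")
  s <- randomSeq(4000, dna)
  ch <- strsplit(s, "")[[1]]
  mut <- sample(4000, 30)
  for (i in mut) ch[i] <- sample(setdiff(dna, ch[i]), 1)
  s2 <- paste(ch, collapse = "")
  full <- alignGlobal(s, s2, nucleotideScheme())
  banded <- alignGlobal(s, s2, nucleotideScheme(), band = 80L)
  expect_equal(banded@rawScore, full@rawScore)
  expect_equal(banded@identity, full@identity)
  expect_equal(banded@identity, 1 - 30 / 4000)
})
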