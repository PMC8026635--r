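# center-star MSA, profile construction, Viterbi/Forward correctness
# against exhaustive path enumeration, and decoy calibration.

test_that("center-star alignment handles the canonical small cases", {
  msa <- centerStarMSA(c(s1 = "ACDE", s2 = "ACE"))
  expect_equal(unname(nchar(msa)), c(4L, 4L))
  expect_equal(sum(strsplit(msa[["s2"]], "")[[1]] == "-"), 1L)
  expect_equal(attr(msa, "center"), "s1")

  same <- centerStarMSA(c(a = "MKVLL", b = "MKVLL"))
  expect_false(any(grepl("-", same, fixed = TRUE)))

  expect_error(centerStarMSA(c(a = "MKV")), "two sequences")
})

test_that("MSA columns never drop below the longest member", {
  set.seed(5)
  for (rep in 1:10) {
    members <- setNames(vapply(1:4, function(i)
      randomSeq(sample(8:20, 1), AA20), character(1)), paste0("m", 1:4))
    msa <- centerStarMSA(members)
    expect_true(all(nchar(msa) == nchar(msa)[1]))
    expect_gte(nchar(msa)[[1]], max(nchar(members)))
    # rows reproduce their sequences after degapping
    expect_equal(gsub("-", "", msa[names(members)], fixed = TRUE),
                 members)
  }
})

test_that("profile construction follows the +1 pseudocount rule", {
  p <- buildProfile(c(a = "A", b = "A", c = "A"), "tiny")
  expect_equal(p@M, 1L)
  expect_equal(unname(p@matchEmissions[1, "A"]), 4 / 23)
  expect_equal(sum(p@matchEmissions[1, ]), 1)

  # all-gap and minority columns never become match states
  p2 <- buildProfile(c(a = "A-C", b = "A-C", c = "A--"), "tiny2")
  expect_equal(p2@M, 2L)

  expect_error(buildProfile(c(a = "--", b = "--"), "bad"), "majority")
})

test_that("Viterbi equals exhaustive path enumeration on tiny instances", {
  set.seed(13)
  for (rep in 1:12) {
    M <- sample(2:6, 1)
    p <- randomTinyProfile(M)
    s <- randomSeq(sample(2:8, 1), AA20)
    scores <- enumHmmScores(p, s)
    v <- profileViterbi(p, s)
    f <- profileForward(p, s)
    expect_equal(v$score, max(scores), tolerance = 1e-9)
    lse <- function(x) { m <- max(x); m + log2(sum(2^(x - m))) }
    expect_equal(f, lse(scores), tolerance = 1e-9)
    expect_gte(f + 1e-12, v$score)  # Forward >= Viterbi always
  }
})

test_that("a profile scores its own training sequence above point mutants", {
  set.seed(21)
  s <- randomSeq(40, AA20)
  rows <- setNames(rep(s, 3), paste0("r", 1:3))
  p <- buildProfile(rows, "self")
  self <- profileViterbi(p, s)$score
  for (rep in 1:5) {
    ch <- strsplit(s, "")[[1]]
    i <- sample(40, 1)
    ch[i] <- sample(setdiff(AA20, ch[i]), 1)
    expect_gte(self, profileViterbi(p, paste(ch, collapse = ""))$score)
  }
})

test_that("family profiles retrieve members and reject unrelated sequences", {
  profs <- smallProfiles()
  ds <- smallDataset()
  fam <- ds$families$members
  # every reference member of each profiled family is found at >= 25 bits
  for (f in c("terminase", "mcp", "adapter")) {
    hitScores <- vapply(fam[[f]], function(s)
      profileViterbi(profs[[f]], s)$score, numeric(1))
    expect_true(all(hitScores >= 25))
  }
  # unrelated random proteins are not hits at the default threshold
  set.seed(99)
  for (rep in 1:10) {
    r <- randomSeq(sample(100:500, 1), AA20)
    expect_null(searchProfile(profs$terminase, r, bits = 25))
  }
  # cross-family searches are not hits either
  expect_null(searchProfile(profs$mcp, fam$terminase[[1]]))
})

test_that("decoy calibration is deterministic and E-values behave", {
  p <- smallProfiles()$adapter
  cal1 <- calibrateEvalues(p, decoys = 150, seed = 4)
  cal2 <- calibrateEvalues(p, decoys = 150, seed = 4)
  expect_identical(cal1@calibration, cal2@calibration)
  expect_error(calibrateEvalues(p, decoys = 50), "at least 100")

  bits <- seq(0, 60, by = 5)
  ev <- profileEvalue(cal1, bits, dbSize = 1000)
  expect_true(all(diff(ev) < 0))          # monotone decreasing
  expect_true(all(ev >= 0))

  # the median decoy score maps to a tail probability near one half
  sc <- decoyScores(cal1, 150, seed = 4)
  pMed <- profileEvalue(cal1, median(sc), dbSize = 1)
  expect_lt(abs(pMed - 0.5), 0.1)
})

test_that("profiles survive a JSON round trip", {
  p <- calibrateEvalues(smallProfiles()$adapter, decoys = 120, seed = 2)
  f <- tempfile(fileext = ".json")
  writeProfileJson(p, f)
  q <- readProfileJson(f)
  expect_equal(q@M, p@M)
  expect_equal(q@matchEmissions, p@matchEmissions)
  expect_equal(q@transitions, p@transitions)
  expect_equal(unname(q@calibration), unname(p@calibration))
  s <- smallDataset()$families$members$adapter[[1]]
  expect_equal(profileViterbi(q, s)$score, profileViterbi(p, s)$score)
})

test_that("aligned FASTA and Stockholm alignments are accepted as input", {
  msa <- c(seq1 = "MK-VL", seq2 = "MKAVL")
  fa <- tempfile(fileext = ".afa")
  writeLines(c(">seq1", msa[[1]], ">seq2", msa[[2]]), fa)
  got <- readMsa(fa, "fasta")
  expect_equal(unname(got), unname(msa))
  sto <- tempfile(fileext = ".sto")
  writeLines(c("# STOCKHOLM 1.0", "seq1 MK.VL", "seq2 MKAVL", "//"), sto)
  gotSto <- readMsa(sto, "stockholm")
  expect_equal(unname(gotSto), unname(msa))
  p <- buildProfile(got, "ext")
  # the half-gapped column is not a residue majority, so it is an insert
  expect_equal(p@M, 4L)
})
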