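# greedy identity/coverage clustering: representative choice, thresholds,
# partition property, and agreement with an independently-aligned oracle.

test_that("identical sequences merge and the representative is deterministic", {
  cl <- greedyCluster(c(b = "MKVLATGE", a = "MKVLATGE"),
                      minIdentity = 0.9, minCoverage = 0.9, mode = "local")
  expect_length(cl, 1)
  expect_equal(cl[[1]]$representative, "a")  # tie broken lexicographically
  expect_setequal(cl[[1]]$members, c("a", "b"))
})

test_that("sub-threshold identity keeps sequences apart", {
  s1 <- paste(rep("A", 100), collapse = "")
  s2 <- paste(c(rep("A", 98), "T", "T"), collapse = "")
  cl <- greedyCluster(c(x = s1, y = s2), minIdentity = 0.99,
                      minCoverage = 0.99, mode = "global",
                      scheme = nucleotideScheme())
  expect_length(cl, 2)
})

test_that("empty input and duplicate names are rejected", {
  expect_error(greedyCluster(character(0), 0.9, 0.9), "no sequences")
  expect_error(greedyCluster(setNames(c("AC", "AC"), c("a", "a")), 0.9, 0.9),
               "unique")
})

test_that("greedy clustering matches an independently-aligned oracle", {
  set.seed(31)
  # 30 proteins: several diverged families plus isolated sequences
  seqs <- character(0)
  for (f in 1:5) {
    anc <- randomSeq(sample(40:80, 1), AA20)
    for (m in 1:4) {
      ch <- strsplit(anc, "")[[1]]
      mut <- which(runif(length(ch)) < 0.15)
      for (i in mut) ch[i] <- sample(setdiff(AA20, ch[i]), 1)
      seqs[sprintf("f%d_m%d", f, m)] <- paste(ch, collapse = "")
    }
  }
  for (k in 1:10) seqs[sprintf("solo%02d", k)] <- randomSeq(sample(40:80, 1), AA20)

  got <- greedyCluster(seqs, minIdentity = 0.5, minCoverage = 0.8,
                       mode = "local", scheme = proteinScheme())

  # oracle: identical greedy rule, alignments via Biostrings
  oracleAlign <- function(a, b) {
    aln <- Biostrings::pairwiseAlignment(
      a, b, substitutionMatrix = "BLOSUM62", gapOpening = 10,
      gapExtension = 1, type = "local")
    cols <- nchar(as.character(Biostrings::alignedPattern(aln)))
    qsp <- Biostrings::width(Biostrings::pattern(aln))
    tsp <- Biostrings::width(Biostrings::subject(aln))
    list(identity = Biostrings::nmatch(aln) / cols,
         qcov = qsp / nchar(a), tcov = tsp / nchar(b))
  }
  ord <- order(-nchar(seqs), names(seqs), method = "radix")
  ss <- seqs[ord]
  reps <- character(0); mem <- list()
  for (i in seq_along(ss)) {
    placed <- FALSE
    for (ci in seq_along(reps)) {
      o <- oracleAlign(ss[[i]], ss[[reps[ci]]])
      if (o$identity >= 0.5 && o$qcov >= 0.8 && o$tcov >= 0.8) {
        mem[[ci]] <- c(mem[[ci]], names(ss)[i]); placed <- TRUE; break
      }
    }
    if (!placed) { reps <- c(reps, names(ss)[i]); mem <- c(mem, list(names(ss)[i])) }
  }
  gotSig <- sort(vapply(got, function(cl) paste(sort(cl$members), collapse = ","),
                        character(1)))
  oraSig <- sort(vapply(mem, function(m) paste(sort(m), collapse = ","),
                        character(1)))
  expect_equal(gotSig, oraSig)
})

test_that("clustering is a partition and cluster count is monotone in identity", {
  set.seed(57)
  seqs <- setNames(vapply(1:15, function(i) randomSeq(30, c("A", "C", "G", "T")),
                          character(1)), sprintf("s%02d", 1:15))
  # make some related pairs
  seqs[2] <- seqs[1]; seqs[4] <- sub("A", "C", seqs[3])
  prev <- -1L
  for (thr in c(0.3, 0.6, 0.9)) {
    cl <- greedyCluster(seqs, minIdentity = thr, minCoverage = 0.5,
                        mode = "global", scheme = nucleotideScheme())
    members <- unlist(lapply(cl, `[[`, "members"))
    expect_setequal(members, names(seqs))
    expect_equal(anyDuplicated(members), 0L)
    expect_gte(length(cl), prev)
    prev <- length(cl)
  }
})

test_that("family-size selection keeps clusters of min size, preserving order", {
  mk <- function(n, tag) list(representative = paste0(tag, 1),
                              members = paste0(tag, seq_len(n)))
  cl <- list(mk(12, "a"), mk(9, "b"), mk(10, "c"))
  class(cl) <- "sequenceClusters"
  kept <- selectFamilyClusters(cl, 10)
  expect_equal(vapply(kept, function(x) length(x$members), integer(1)), c(12L, 10L))
  expect_length(selectFamilyClusters(cl, 1), 3)
  expect_length(selectFamilyClusters(cl, 13), 0)
  expect_error(selectFamilyClusters(cl, 0), "at least 1")
})
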