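# Independent oracles used across the test suite.
#
# The alignment and HMM oracles enumerate every admissible path explicitly
# (no dynamic programming), so they share no code path with the Rcpp
# kernels they check. The orthology oracles are brute-force double loops.

# ---- exhaustive alignment enumeration ----------------------------------

# Enumerates every monotone global alignment path and scores it with the
# affine rule (first gap residue gapOpen, further residues gapExtend).
enumGlobalScore <- function(a, b, scheme) {
  ca <- strsplit(a, "")[[1]]; cb <- strsplit(b, "")[[1]]
  n <- length(ca); m <- length(cb)
  sub <- scheme@matrix
  go <- scheme@gapOpen; ge <- scheme@gapExtend
  best <- -Inf
  rec <- function(i, j, last, score) {
    if (i == n && j == m) {
      if (score > best) best <<- score
      return(invisible())
    }
    if (i < n && j < m)
      rec(i + 1, j + 1, "M", score + sub[ca[i + 1], cb[j + 1]])
    if (i < n)
      rec(i + 1, j, "X", score + if (last == "X") ge else go)
    if (j < m)
      rec(i, j + 1, "Y", score + if (last == "Y") ge else go)
  }
  rec(0L, 0L, "S", 0)
  best
}

# Enumerates every local alignment that starts and ends with an aligned
# residue pair; the empty alignment scores 0.
enumLocalScore <- function(a, b, scheme) {
  ca <- strsplit(a, "")[[1]]; cb <- strsplit(b, "")[[1]]
  n <- length(ca); m <- length(cb)
  sub <- scheme@matrix
  go <- scheme@gapOpen; ge <- scheme@gapExtend
  best <- 0
  rec <- function(i, j, last, score) {
    # (i, j) consumed so far; path currently ends after an op `last`
    if (last == "M" && score > best) best <<- score
    if (i < n && j < m)
      rec(i + 1, j + 1, "M", score + sub[ca[i + 1], cb[j + 1]])
    if (i < n)
      rec(i + 1, j, "X", score + if (last == "X") ge else go)
    if (j < m)
      rec(i, j + 1, "Y", score + if (last == "Y") ge else go)
  }
  for (i0 in seq_len(n)) for (j0 in seq_len(m))
    rec(i0, j0, "M", sub[ca[i0], cb[j0]])
  best
}

randomSeq <- function(len, alphabet) {
  paste(sample(alphabet, len, replace = TRUE), collapse = "")
}

# ---- exhaustive profile-HMM path enumeration ---------------------------

# Enumerates every local path through the profile (entry at any match
# state, exit at any match state, free flanks) and returns all path
# log2-odds scores. Viterbi = max, Forward = log2 sum of 2^scores.
enumHmmScores <- function(profile, sequence) {
  code <- match(strsplit(sequence, "")[[1]], prophageScreen::AA20)
  L <- length(code); M <- profile@M
  mlo <- log2(sweep(profile@matchEmissions, 2, profile@background, "/"))
  tlo <- log2(profile@transitions)
  em <- function(k, j) if (is.na(code[j])) 0 else mlo[k, code[j]]
  scores <- numeric(0)
  # state: "M", "I", "D"; k = node, j = last consumed sequence position
  rec <- function(state, k, j, score) {
    if (state == "M") scores[length(scores) + 1L] <<- score  # exit here
    if (state == "M") {
      if (k < M && j < L)
        rec("M", k + 1L, j + 1L, score + tlo[k + 1L, "MM"] + em(k + 1L, j + 1L))
      if (j < L)
        rec("I", k, j + 1L, score + tlo[k + 1L, "MI"])
      if (k < M)
        rec("D", k + 1L, j, score + tlo[k + 1L, "MD"])
    } else if (state == "I") {
      if (j < L)
        rec("I", k, j + 1L, score + tlo[k + 1L, "II"])
      if (k < M && j < L)
        rec("M", k + 1L, j + 1L, score + tlo[k + 1L, "IM"] + em(k + 1L, j + 1L))
    } else {
      if (k < M)
        rec("D", k + 1L, j, score + tlo[k + 1L, "DD"])
      if (k < M && j < L)
        rec("M", k + 1L, j + 1L, score + tlo[k + 1L, "DM"] + em(k + 1L, j + 1L))
    }
  }
  for (j0 in seq_len(L)) for (k0 in seq_len(M))
    rec("M", k0, j0, em(k0, j0))
  scores
}

randomTinyProfile <- function(M, nseq = 4L) {
  rows <- vapply(seq_len(nseq), function(i)
    randomSeq(M, prophageScreen::AA20), character(1))
  names(rows) <- paste0("s", seq_len(nseq))
  prophageScreen::buildProfile(rows, "tiny")
}

# ---- brute-force BBH and triangle clustering ---------------------------

oracleBbh <- function(hits) {
  out <- list()
  ids <- unique(c(hits$query_id, hits$target_id))
  for (p in ids) {
    ph <- hits[hits$query_id == p, , drop = FALSE]
    for (tg in unique(ph$target_genome)) {
      cand <- ph[ph$target_genome == tg, , drop = FALSE]
      cand <- cand[order(-cand$bit_score, -cand$query_coverage, cand$target_id), ,
                   drop = FALSE]
      q <- cand$target_id[1]
      # reciprocal check
      qh <- hits[hits$query_id == q & hits$target_genome == cand$query_genome[1], ,
                 drop = FALSE]
      if (!nrow(qh)) next
      qh <- qh[order(-qh$bit_score, -qh$query_coverage, qh$target_id), , drop = FALSE]
      if (qh$target_id[1] == p && p < q)
        out[[length(out) + 1L]] <- c(p, q)
    }
  }
  if (!length(out)) return(data.frame(p = character(), q = character()))
  df <- unique(do.call(rbind, lapply(out, function(x)
    data.frame(p = x[1], q = x[2], stringsAsFactors = FALSE))))
  df[order(df$p, df$q), , drop = FALSE]
}

# All-triples triangle test, edge-union, then vertex-overlap merge;
# singletons for everything else. Returns a canonical partition signature.
oracleTriangleClusters <- function(bbhs, proteins) {
  genomeOf <- setNames(proteins$genome_id, proteins$protein_id)
  pairKey <- function(x, y) paste(min(x, y), max(x, y))
  bbhSet <- if (nrow(bbhs)) paste(pmin(bbhs$p, bbhs$q), pmax(bbhs$p, bbhs$q)) else character(0)
  isBbh <- function(x, y) pairKey(x, y) %in% bbhSet
  ids <- sort(proteins$protein_id)
  triangles <- list()
  nid <- length(ids)
  if (nid >= 3) {
    for (i in 1:(nid - 2)) for (j in (i + 1):(nid - 1)) for (k in (j + 1):nid) {
      trio <- c(ids[i], ids[j], ids[k])
      if (length(unique(genomeOf[trio])) != 3) next
      if (isBbh(trio[1], trio[2]) && isBbh(trio[1], trio[3]) &&
          isBbh(trio[2], trio[3]))
        triangles[[length(triangles) + 1L]] <- trio
    }
  }
  clusters <- list()
  if (length(triangles)) {
    edgeSets <- lapply(triangles, function(tr)
      c(pairKey(tr[1], tr[2]), pairKey(tr[1], tr[3]), pairKey(tr[2], tr[3])))
    nt <- length(triangles)
    parent <- seq_len(nt)
    find <- function(x) { while (parent[x] != x) x <- parent[x]; x }
    for (i in seq_len(nt)) for (j in seq_len(nt)) {
      if (i < j && length(intersect(edgeSets[[i]], edgeSets[[j]])))
        parent[find(i)] <- find(j)
    }
    comp <- vapply(seq_len(nt), find, integer(1))
    for (cid in unique(comp)) {
      clusters[[length(clusters) + 1L]] <-
        sort(unique(unlist(triangles[comp == cid])))
    }
    # vertex-overlap conflict resolution, as in the implementation
    repeat {
      merged <- FALSE
      if (length(clusters) > 1) {
        for (i in seq_len(length(clusters) - 1L)) {
          for (j in seq(i + 1L, length(clusters))) {
            if (length(intersect(clusters[[i]], clusters[[j]]))) {
              clusters[[i]] <- sort(unique(c(clusters[[i]], clusters[[j]])))
              clusters[[j]] <- NULL
              merged <- TRUE
              break
            }
          }
          if (merged) break
        }
      }
      if (!merged) break
    }
  }
  singles <- setdiff(ids, unlist(clusters))
  allCl <- c(clusters, as.list(singles))
  sig <- sort(vapply(allCl, function(x) paste(sort(x), collapse = ","), character(1)))
  sig
}

clusterSignature <- function(clusterDf) {
  unname(sort(vapply(split(clusterDf$protein_id, clusterDf$cluster_id),
                     function(x) paste(sort(x), collapse = ","), character(1)),
              method = "radix"))
}

# random directed hit tables for orthology oracle tests
randomHitInstance <- function(nProteins, nGenomes) {
  genomes <- paste0("g", seq_len(nGenomes))
  proteins <- data.frame(
    protein_id = sprintf("p%02d", seq_len(nProteins)),
    genome_id = sample(genomes, nProteins, replace = TRUE),
    stringsAsFactors = FALSE)
  rows <- list()
  for (i in seq_len(nProteins)) for (j in seq_len(nProteins)) {
    if (i == j) next
    if (proteins$genome_id[i] == proteins$genome_id[j]) next
    if (runif(1) < 0.45) {
      rows[[length(rows) + 1L]] <- data.frame(
        query_id = proteins$protein_id[i], target_id = proteins$protein_id[j],
        query_genome = proteins$genome_id[i], target_genome = proteins$genome_id[j],
        bit_score = round(runif(1, 30, 60), 1),
        query_coverage = round(runif(1, 0.75, 1), 2),
        stringsAsFactors = FALSE)
    }
  }
  hits <- if (length(rows)) do.call(rbind, rows) else
    data.frame(query_id = character(), target_id = character(),
               query_genome = character(), target_genome = character(),
               bit_score = numeric(), query_coverage = numeric())
  list(proteins = proteins, hits = hits)
}

# small shared dataset for unit tests (built once per test run)
.testDataEnv <- new.env()
smallDataset <- function() {
  if (is.null(.testDataEnv$ds)) {
    spec <- generatorSpec(seed = 11L, nGenomes = 12L,
                          stateMix = c(active = 4L, degenerated = 2L,
                                       virulent = 1L, non_phage = 5L),
                          nGroups = 2L,
                          genomeLengthRange = c(15000, 22000))
    .testDataEnv$spec <- spec
    .testDataEnv$ds <- makeGenomes(spec)
  }
  .testDataEnv$ds
}
smallSpec <- function() { smallDataset(); .testDataEnv$spec }
smallProfiles <- function() {
  if (is.null(.testDataEnv$profiles)) {
    ds <- smallDataset()
    # all reference families, including the adapter (not screened in the
    # pipeline, but convenient as a small fast profile in unit tests)
    .testDataEnv$profiles <- buildMarkerProfiles(ds$families$members)
  }
  .testDataEnv$profiles
}
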