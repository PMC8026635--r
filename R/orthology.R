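#' @include screen.R
NULL


#' All-against-all protein homology search
#'
#' Aligns every inter-genome protein pair with Smith-Waterman and keeps
#' directed hits passing the orthology thresholds (query coverage >= 75%,
#' E-value <= 1e-5 by default). Scores and aligned spans are symmetric, so
#' each unordered pair is aligned once and both directed hits are derived
#' from the same alignment; intra-genome pairs are excluded.
#'
#' A shared-4-mer prefilter (on by default) skips unordered pairs that have
#' no amino-acid 4-mer in common; such pairs cannot produce a qualifying
#' hit at the default thresholds, and tests verify the prefilter leaves
#' fixture results unchanged.
#'
#' @param proteins protein table with `protein_id`, `genome_id`, `seq`.
#' @param cfg a [ScreenConfig].
#' @param scheme protein [ScoringScheme].
#' @param kmerPrefilter logical; apply the shared-4-mer skip.
#' @return `data.frame` of directed hits: `query_id`, `target_id`,
#'   `query_genome`, `target_genome`, `raw_score`, `bit_score`, `evalue`,
#'   `identity`, `query_coverage`, `target_coverage`.
#' @export
allVsAll <- function(proteins, cfg = screenConfig(), scheme = proteinScheme(),
                     kmerPrefilter = TRUE) {
  if (length(unique(proteins$genome_id)) < 2)
    stop("at least two genomes are required for all-vs-all comparison")
  proteins <- proteins[order(proteins$protein_id), , drop = FALSE]
  n <- nrow(proteins)
  codes <- lapply(proteins$seq, .encodeSeq, scheme = scheme)
  km <- if (kmerPrefilter) lapply(codes, .kmerCodesInt) else NULL
  lens <- nchar(proteins$seq)
  go <- as.integer(scheme@gapOpen); ge <- as.integer(scheme@gapExtend)
  qid <- tid <- qg <- tg <- character(0)
  raw <- qs <- qe <- ts <- te <- ni <- nc <- integer(0)
  cnt <- 0L
  add <- function(i, j, r) {
    cnt <<- cnt + 1L
    qid[cnt] <<- proteins$protein_id[i]; tid[cnt] <<- proteins$protein_id[j]
    qg[cnt] <<- proteins$genome_id[i]; tg[cnt] <<- proteins$genome_id[j]
    raw[cnt] <<- r$score
    qs[cnt] <<- r$qstart; qe[cnt] <<- r$qend
    ts[cnt] <<- r$tstart; te[cnt] <<- r$tend
    ni[cnt] <<- r$nident; nc[cnt] <<- r$ncols
  }
  for (i in seq_len(n - 1L)) {
    for (j in seq(i + 1L, n)) {
      if (proteins$genome_id[i] == proteins$genome_id[j]) next
      if (kmerPrefilter && !.anyShared(km[[i]], km[[j]])) next
      sc <- cpp_align_score_local(codes[[i]], codes[[j]], scheme@matrix, go, ge)
      if (evalueOf(bitScoreOf(sc, scheme), lens[i], lens[j]) > cfg@orthoEvalue)
        next
      r <- cpp_align(codes[[i]], codes[[j]], scheme@matrix, go, ge,
                     TRUE, 0L, FALSE)
      # scores and spans are symmetric: derive both directed hits
      add(i, j, r)
      add(j, i, list(score = r$score, qstart = r$tstart, qend = r$tend,
                     tstart = r$qstart, tend = r$qend,
                     nident = r$nident, ncols = r$ncols))
    }
  }
  if (!cnt)
    return(data.frame(query_id = character(), target_id = character(),
                      query_genome = character(), target_genome = character(),
                      raw_score = integer(), bit_score = numeric(),
                      evalue = numeric(), identity = numeric(),
                      query_coverage = numeric(), target_coverage = numeric(),
                      stringsAsFactors = FALSE))
  qlen <- lens[match(qid, proteins$protein_id)]
  tlen <- lens[match(tid, proteins$protein_id)]
  bits <- bitScoreOf(raw, scheme)
  res <- data.frame(
    query_id = qid, target_id = tid, query_genome = qg, target_genome = tg,
    raw_score = raw, bit_score = bits, evalue = evalueOf(bits, qlen, tlen),
    identity = ifelse(nc > 0, ni / nc, 0),
    query_coverage = (qe - qs + 1) / qlen,
    target_coverage = (te - ts + 1) / tlen,
    stringsAsFactors = FALSE)
  res <- res[res$query_coverage >= cfg@orthoQueryCoverage, , drop = FALSE]
  res <- res[order(res$query_id, res$target_id), , drop = FALSE]
  rownames(res) <- NULL
  res
}

.kmerCodesInt <- function(code, k = 4L) {
  n <- length(code) - k + 1L
  if (n < 1L) return(integer(0))
  v <- integer(n)
  for (off in 0:(k - 1L)) v <- v * 25L + code[(1L + off):(n + off)]
  sort(unique(v))
}

.anyShared <- function(a, b) {
  # both are unique vectors, so any duplicate in the union is shared
  anyDuplicated(c(a, b)) > 0L
}

#' Bidirectional best hits
#'
#' `(p, q)` is a BBH when `q` is `p`'s best-scoring hit in `q`'s genome and
#' `p` is `q`'s best-scoring hit in `p`'s genome. Score ties are broken by
#' higher query coverage, then lexicographic target identifier.
#'
#' @param hits directed hit table from [allVsAll()].
#' @return `data.frame` with columns `p`, `q` (`p < q` lexicographically)
#'   and the genomes of each.
#' @export
bbhPairs <- function(hits) {
  if (!nrow(hits))
    return(data.frame(p = character(), q = character(),
                      p_genome = character(), q_genome = character(),
                      stringsAsFactors = FALSE))
  key <- paste(hits$query_id, hits$target_genome, sep = "\r")
  ord <- order(key, -hits$bit_score, -hits$query_coverage, hits$target_id,
               method = "radix")
  h <- hits[ord, , drop = FALSE]
  bestRows <- h[!duplicated(paste(h$query_id, h$target_genome, sep = "\r")), ,
                drop = FALSE]
  bestOf <- setNames(bestRows$target_id,
                     paste(bestRows$query_id, bestRows$target_genome, sep = "\r"))
  pairs <- list(); cnt <- 0L
  for (r in seq_len(nrow(bestRows))) {
    p <- bestRows$query_id[r]; q <- bestRows$target_id[r]
    if (p >= q) next  # handle each unordered pair once
    back <- bestOf[paste(q, bestRows$query_genome[r], sep = "\r")]
    if (!is.na(back) && back == p) {
      cnt <- cnt + 1L
      pairs[[cnt]] <- data.frame(p = p, q = q,
                                 p_genome = bestRows$query_genome[r],
                                 q_genome = bestRows$target_genome[r],
                                 stringsAsFactors = FALSE)
    }
  }
  if (!cnt)
    return(data.frame(p = character(), q = character(),
                      p_genome = character(), q_genome = character(),
                      stringsAsFactors = FALSE))
  res <- do.call(rbind, pairs[seq_len(cnt)])
  res[order(res$p, res$q), , drop = FALSE]
}

#' COGtriangles ortholog clustering
#'
#' Seeds clusters from triangles: three proteins from three distinct
#' genomes that are pairwise bidirectional best hits. Triangles sharing an
#' edge (a common BBH pair) are merged into one cluster; if the edge-merge
#' leaves a protein in more than one cluster the overlapping clusters are
#' merged so that the output is a partition. Proteins in no triangle become
#' singleton clusters. Cluster identifiers are assigned in order of each
#' cluster's smallest member protein id.
#'
#' @param bbhs BBH table from [bbhPairs()].
#' @param proteins protein table with `protein_id`, `genome_id` covering
#'   every protein to place (singletons included).
#' @return `data.frame` with `cluster_id`, `genome_id`, `protein_id`.
#' @export
cogTriangles <- function(bbhs, proteins) {
  genomeOf <- setNames(proteins$genome_id, proteins$protein_id)
  nE <- nrow(bbhs)
  clustersOf <- list()
  if (nE) {
    g <- igraph::graph_from_data_frame(bbhs[, c("p", "q")], directed = FALSE)
    tri <- igraph::triangles(g)
    vn <- igraph::V(g)$name
    parent <- seq_len(nE)
    find <- function(x) { while (parent[x] != x) { parent[x] <<- parent[parent[x]]; x <- parent[x] }; x }
    unite <- function(x, y) { rx <- find(x); ry <- find(y); if (rx != ry) parent[rx] <<- ry }
    edgeKey <- paste(pmin(bbhs$p, bbhs$q), pmax(bbhs$p, bbhs$q), sep = "\r")
    edgeIdx <- setNames(seq_len(nE), edgeKey)
    inTriangle <- rep(FALSE, nE)
    if (length(tri)) {
      tm <- matrix(vn[as.integer(tri)], ncol = 3, byrow = TRUE)
      for (r in seq_len(nrow(tm))) {
        trio <- tm[r, ]
        if (length(unique(genomeOf[trio])) != 3L) next
        e12 <- edgeIdx[paste(min(trio[1], trio[2]), max(trio[1], trio[2]), sep = "\r")]
        e13 <- edgeIdx[paste(min(trio[1], trio[3]), max(trio[1], trio[3]), sep = "\r")]
        e23 <- edgeIdx[paste(min(trio[2], trio[3]), max(trio[2], trio[3]), sep = "\r")]
        inTriangle[c(e12, e13, e23)] <- TRUE
        unite(e12, e13); unite(e12, e23)
      }
    }
    comp <- vapply(seq_len(nE), find, integer(1))
    for (cid in unique(comp[inTriangle])) {
      es <- which(comp == cid & inTriangle)
      clustersOf[[length(clustersOf) + 1L]] <-
        unique(c(bbhs$p[es], bbhs$q[es]))
    }
    # resolve any vertex shared between edge-components (partition guarantee)
    if (length(clustersOf) > 1L) {
      repeat {
        merged <- FALSE
        for (i in seq_len(length(clustersOf) - 1L)) {
          for (j in seq(i + 1L, length(clustersOf))) {
            if (length(intersect(clustersOf[[i]], clustersOf[[j]]))) {
              clustersOf[[i]] <- unique(c(clustersOf[[i]], clustersOf[[j]]))
              clustersOf[[j]] <- NULL
              merged <- TRUE
              break
            }
          }
          if (merged) break
        }
        if (!merged) break
      }
    }
  }
  clustered <- unlist(clustersOf)
  singles <- setdiff(proteins$protein_id, clustered)
  allClusters <- c(clustersOf, as.list(singles))
  minId <- vapply(allClusters, min, character(1))
  allClusters <- allClusters[order(minId, method = "radix")]
  do.call(rbind, lapply(seq_along(allClusters), function(k) {
    ids <- sort(allClusters[[k]])
    data.frame(cluster_id = k, genome_id = unname(genomeOf[ids]),
               protein_id = ids, stringsAsFactors = FALSE)
  }))
}

#' Build the genome-by-cluster pangenome matrix
#'
#' @param clusters cluster table from [cogTriangles()].
#' @param genomes ordered genome identifiers (matrix row order).
#' @return A [PangenomeMatrix] with `TRUE` wherever a genome contributes at
#'   least one protein to a cluster.
#' @export
buildPangenome <- function(clusters, genomes) {
  cids <- sort(unique(clusters$cluster_id))
  p <- matrix(FALSE, nrow = length(genomes), ncol = length(cids),
              dimnames = list(genomes, paste0("C", cids)))
  for (r in seq_len(nrow(clusters))) {
    g <- clusters$genome_id[r]
    if (g %in% genomes)
      p[g, paste0("C", clusters$cluster_id[r])] <- TRUE
  }
  new("PangenomeMatrix", presence = p)
}
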