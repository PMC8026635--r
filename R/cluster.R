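#' @include align.R
NULL

#' Greedy identity/coverage sequence clustering
#'
#' Incremental clustering in the style of MMseqs2/CD-HIT, used for plasmid
#' genome deduplication (global mode, 0.99 identity / 0.99 coverage) and for
#' marker protein-family construction (local mode, 0.20 identity / 0.80
#' coverage). Sequences are sorted by decreasing length (ties by identifier);
#' each sequence joins the first existing cluster whose representative
#' alignment reaches `minIdentity` and `minCoverage` on both query and
#' target, otherwise it founds a new cluster. Because of the processing
#' order the representative is always the longest (then lexicographically
#' first) member.
#'
#' In global mode two exact prefilters are applied before aligning: a pair
#' whose length ratio already caps identity below the threshold
#' (`min(la, lb) / max(la, lb) < minIdentity`) is rejected without
#' alignment, and long sequences are aligned inside a band wide enough to
#' contain any alignment that could reach the identity threshold.
#'
#' @param sequences named character vector of sequences (unique names).
#' @param minIdentity,minCoverage thresholds in `[0, 1]`.
#' @param mode `"global"` or `"local"` alignment of candidates against
#'   representatives.
#' @param scheme a [ScoringScheme]; defaults to [proteinScheme()] or
#'   [nucleotideScheme()] according to `mode == "global"` heuristics --
#'   pass one explicitly for clarity.
#' @return A list of clusters, each `list(representative =, members =)`,
#'   in founding order; class `"sequenceClusters"`.
#' @examples
#' greedyCluster(c(a = "MKVLAT", b = "MKVLAT", c = "WWRRFF"),
#'               minIdentity = 0.9, minCoverage = 0.9, mode = "local")
#' @export
greedyCluster <- function(sequences, minIdentity, minCoverage,
                          mode = c("local", "global"), scheme = NULL) {
  mode <- match.arg(mode)
  if (length(sequences) == 0) stop("no sequences to cluster")
  if (is.null(names(sequences)) || anyDuplicated(names(sequences)))
    stop("sequences must carry unique names")
  if (is.null(scheme)) {
    nt <- all(grepl("^[ACGTN]+$", sequences))
    scheme <- if (nt) nucleotideScheme() else proteinScheme()
  }
  ord <- order(-nchar(sequences), names(sequences), method = "radix")
  sequences <- sequences[ord]
  lens <- nchar(sequences)
  reps <- character(); repLen <- integer()
  members <- list()
  for (i in seq_along(sequences)) {
    id <- names(sequences)[i]; s <- sequences[[i]]; l <- lens[i]
    placed <- FALSE
    for (ci in seq_along(reps)) {
      rl <- repLen[ci]
      if (mode == "global") {
        # identical columns <= min(l, rl); columns >= max(l, rl)
        if (min(l, rl) / max(l, rl) < minIdentity) next
        # exact-substring reject: an alignment with identity >= t has at
        # most (1 - t) * cols non-identical columns, so its longest exact
        # run spans at least t / (1 - t) columns; with t >= 0.985 a pair
        # sharing no 64-mer can never reach the threshold
        if (minIdentity >= 0.985 && max(l, rl) > 5000L &&
            !cpp_shared_kmer(s, sequences[[reps[ci]]], 64L)) next
        band <- if (max(l, rl) > 10000L)
          as.integer(ceiling((1 - minIdentity) * max(l, rl)) + abs(l - rl) + 32L)
        else NULL
        aln <- alignGlobal(s, sequences[[reps[ci]]], scheme, band = band,
                           queryId = id, targetId = reps[ci])
      } else {
        aln <- alignLocal(s, sequences[[reps[ci]]], scheme,
                          queryId = id, targetId = reps[ci])
      }
      if (aln@identity >= minIdentity &&
          aln@queryCoverage >= minCoverage &&
          aln@targetCoverage >= minCoverage) {
        members[[ci]] <- c(members[[ci]], id)
        placed <- TRUE
        break
      }
    }
    if (!placed) {
      reps <- c(reps, id); repLen <- c(repLen, l)
      members <- c(members, list(id))
    }
  }
  out <- lapply(seq_along(reps), function(ci)
    list(representative = reps[ci], members = members[[ci]]))
  class(out) <- "sequenceClusters"
  out
}

#' @export
print.sequenceClusters <- function(x, ...) {
  cat(sprintf("%d clusters over %d sequences\n",
              length(x), sum(lengths(lapply(x, `[[`, "members")))))
  invisible(x)
}

#' Keep clusters large enough to train a profile
#'
#' Retains clusters with at least `minSize` members (default 10, the size
#' from which a family alignment and profile HMM are built), preserving
#' order.
#'
#' @param clusters result of [greedyCluster()].
#' @param minSize minimum member count (`>= 1`).
#' @return Filtered cluster list.
#' @export
selectFamilyClusters <- function(clusters, minSize = 10L) {
  if (minSize < 1) stop("minSize must be at least 1")
  out <- clusters[vapply(clusters, function(cl)
    length(cl$members) >= minSize, logical(1))]
  class(out) <- "sequenceClusters"
  out
}

#' Write cluster membership as a two-column TSV
#'
#' @param clusters result of [greedyCluster()].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
writeClustersTsv <- function(clusters, path) {
  df <- do.call(rbind, lapply(clusters, function(cl)
    data.frame(member_id = cl$members, representative_id = cl$representative,
               stringsAsFactors = FALSE)))
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
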