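#' @include orthology.R
NULL

#' Export the bipartite protein-sharing network
#'
#' Writes the pangenome matrix as a bipartite network with genome nodes and
#' protein-cluster nodes and an edge wherever a genome harbors a
#' representative of a cluster, in GraphML (and optionally an edge-list
#' TSV). The `nodeType` attribute distinguishes the two parts.
#'
#' @param pangenome a [PangenomeMatrix].
#' @param graphmlPath output GraphML path.
#' @param edgeTsvPath optional edge-list TSV path.
#' @return `graphmlPath`, invisibly.
#' @export
exportBipartiteNetwork <- function(pangenome, graphmlPath, edgeTsvPath = NULL) {
  p <- presenceMatrix(pangenome)
  idx <- which(p, arr.ind = TRUE)
  edges <- data.frame(from = rownames(p)[idx[, 1]],
                      to = colnames(p)[idx[, 2]], stringsAsFactors = FALSE)
  verts <- data.frame(name = c(rownames(p), colnames(p)),
                      nodeType = c(rep("genome", nrow(p)),
                                   rep("cluster", ncol(p))),
                      type = c(rep(FALSE, nrow(p)), rep(TRUE, ncol(p))),
                      stringsAsFactors = FALSE)
  g <- igraph::graph_from_data_frame(edges, directed = FALSE, vertices = verts)
  igraph::write_graph(g, graphmlPath, format = "graphml")
  if (!is.null(edgeTsvPath))
    write.table(edges, edgeTsvPath, sep = "\t", quote = FALSE, row.names = FALSE,
                col.names = c("genome_id", "cluster_id"))
  invisible(graphmlPath)
}

#' Read a bipartite protein-sharing network back into a pangenome matrix
#'
#' Round-trip companion of [exportBipartiteNetwork()].
#'
#' @param graphmlPath GraphML file written by [exportBipartiteNetwork()].
#' @return A [PangenomeMatrix].
#' @export
readBipartiteNetwork <- function(graphmlPath) {
  g <- igraph::read_graph(graphmlPath, format = "graphml")
  nodeType <- igraph::vertex_attr(g, "nodeType")
  name <- igraph::vertex_attr(g, "name")
  genomes <- name[nodeType == "genome"]
  clusters <- name[nodeType == "cluster"]
  p <- matrix(FALSE, length(genomes), length(clusters),
              dimnames = list(genomes, clusters))
  el <- igraph::as_edgelist(g)
  for (r in seq_len(nrow(el))) {
    a <- el[r, 1]; b <- el[r, 2]
    if (a %in% genomes) p[a, b] <- TRUE else p[b, a] <- TRUE
  }
  new("PangenomeMatrix", presence = p)
}

#' Shared-protein-content similarity between two genomes
#'
#' The number of protein clusters shared by genomes `i` and `j` divided by
#' the smaller of their cluster counts (min-normalization, so that a
#' gene-poor degenerated prophage still scores high against its intact
#' relatives). Genomes with no clusters have similarity 0 to everything.
#'
#' @param pangenome a [PangenomeMatrix].
#' @param i,j distinct genome identifiers.
#' @return similarity in `[0, 1]`.
#' @export
genomeSimilarity <- function(pangenome, i, j) {
  p <- presenceMatrix(pangenome)
  if (!i %in% rownames(p)) stop("unknown genome id: ", i)
  if (!j %in% rownames(p)) stop("unknown genome id: ", j)
  if (identical(i, j)) stop("i and j must differ")
  ni <- sum(p[i, ]); nj <- sum(p[j, ])
  if (ni == 0 || nj == 0) return(0)
  sum(p[i, ] & p[j, ]) / min(ni, nj)
}

#' Group genomes by shared protein content
#'
#' Builds a graph over genomes with an edge wherever the min-normalized
#' shared-cluster similarity reaches `threshold`, and returns its connected
#' components ordered by decreasing size (ties by smallest member id).
#' Size-1 components are singletons: genomes not grouped with any others.
#'
#' @param pangenome a [PangenomeMatrix].
#' @param threshold similarity threshold in `(0, 1]` (default 0.5).
#' @return `data.frame` with `group_id`, `genome_id`, `is_singleton`.
#' @export
makeGroups <- function(pangenome, threshold = 0.5) {
  if (!(threshold > 0 && threshold <= 1)) stop("threshold must lie in (0, 1]")
  p <- presenceMatrix(pangenome)
  genomes <- rownames(p)
  n <- length(genomes)
  cross <- (p %*% t(p))              # shared-cluster counts
  counts <- rowSums(p)
  edges <- list(); cnt <- 0L
  if (n >= 2) {
    for (i in seq_len(n - 1)) {
      for (j in seq(i + 1, n)) {
        if (counts[i] == 0 || counts[j] == 0) next
        sim <- cross[i, j] / min(counts[i], counts[j])
        if (sim >= threshold) {
          cnt <- cnt + 1L
          edges[[cnt]] <- c(genomes[i], genomes[j])
        }
      }
    }
  }
  g <- igraph::make_empty_graph(directed = FALSE) + igraph::vertices(genomes)
  if (cnt) g <- g + igraph::edges(unlist(edges))
  comp <- igraph::components(g)
  byComp <- split(genomes, comp$membership)
  sizes <- lengths(byComp)
  minIds <- vapply(byComp, min, character(1))
  ord <- order(-sizes, minIds, method = "radix")
  do.call(rbind, lapply(seq_along(ord), function(k) {
    mem <- sort(byComp[[ord[k]]])
    data.frame(group_id = k, genome_id = mem,
               is_singleton = length(mem) == 1L, stringsAsFactors = FALSE)
  }))
}
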