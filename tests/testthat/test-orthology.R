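# all-vs-all homology thresholds, BBH definition, COGtriangles clustering
# vs brute-force oracles, and the pangenome matrix.

test_that("all-vs-all enforces coverage and E-value thresholds", {
  ds <- smallDataset()
  fam <- ds$families$members
  prot <- data.frame(
    protein_id = c("gA_t", "gB_t", "gA_junk", "gB_junk"),
    genome_id = c("gA", "gB", "gA", "gB"),
    seq = c(fam$terminase[[1]], fam$terminase[[2]],
            prophageScreen:::.randomProtein(200),
            prophageScreen:::.randomProtein(200)),
    stringsAsFactors = FALSE)
  set.seed(1)
  hits <- allVsAll(prot, screenConfig())
  # the homologous terminase pair is reciprocally retained with high identity
  th <- hits[hits$query_id == "gA_t" & hits$target_id == "gB_t", ]
  expect_equal(nrow(th), 1L)
  expect_gt(th$identity, 0.5)
  expect_lt(th$evalue, 1e-5)
  expect_true(any(hits$query_id == "gB_t" & hits$target_id == "gA_t"))
  # random proteins do not pass
  expect_false(any(grepl("junk", hits$query_id)))
  expect_error(allVsAll(prot[prot$genome_id == "gA", ]), "two genomes")
})

test_that("k-mer prefilter does not change all-vs-all results", {
  ds <- smallDataset()
  fam <- ds$families$members
  set.seed(8)
  prot <- data.frame(
    protein_id = sprintf("p%02d", 1:9),
    genome_id = rep(c("g1", "g2", "g3"), each = 3),
    seq = c(fam$mcp[[1]], fam$adapter[[1]], prophageScreen:::.randomProtein(150),
            fam$mcp[[2]], fam$adapter[[2]], prophageScreen:::.randomProtein(180),
            fam$mcp[[3]], fam$adapter[[3]], prophageScreen:::.randomProtein(160)),
    stringsAsFactors = FALSE)
  withFilter <- allVsAll(prot, kmerPrefilter = TRUE)
  without <- allVsAll(prot, kmerPrefilter = FALSE)
  expect_equal(withFilter, without)
})

test_that("identical proteins across genomes are reciprocal hits at identity 1", {
  s <- prophageScreen:::.randomProtein(120)
  prot <- data.frame(protein_id = c("x", "y"), genome_id = c("g1", "g2"),
                     seq = c(s, s), stringsAsFactors = FALSE)
  hits <- allVsAll(prot)
  expect_equal(nrow(hits), 2L)
  expect_true(all(hits$identity == 1))
  expect_true(all(hits$query_coverage == 1))
})

test_that("BBH pairs match the brute-force double-loop oracle", {
  set.seed(19)
  for (rep in 1:20) {
    inst <- randomHitInstance(sample(8:16, 1), sample(2:4, 1))
    if (!nrow(inst$hits)) next
    got <- bbhPairs(inst$hits)
    ora <- oracleBbh(inst$hits)
    expect_equal(got[, c("p", "q")], ora,
                 ignore_attr = TRUE)
  }
})

test_that("BBH requires reciprocity", {
  hits <- data.frame(
    query_id = c("a1", "b1", "b1"), target_id = c("b1", "a2", "a1"),
    query_genome = c("A", "B", "B"), target_genome = c("B", "A", "A"),
    bit_score = c(50, 60, 40), query_coverage = c(1, 1, 1),
    stringsAsFactors = FALSE)
  # a1's best in B is b1, but b1's best in A is a2
  expect_equal(nrow(bbhPairs(hits)), 0L)
})

test_that("COGtriangles clusters equal the brute-force oracle on random instances", {
  set.seed(41)
  for (rep in 1:40) {
    inst <- randomHitInstance(sample(10:30, 1), sample(3:6, 1))
    bbh <- bbhPairs(inst$hits)
    got <- clusterSignature(cogTriangles(bbh, inst$proteins))
    ora <- oracleTriangleClusters(bbh, inst$proteins)
    expect_equal(got, ora)
  }
})

test_that("triangle seeding and edge merging behave on constructed cases", {
  prot <- data.frame(protein_id = c("a", "b", "c", "d"),
                     genome_id = c("g1", "g2", "g3", "g4"),
                     stringsAsFactors = FALSE)
  # one triangle
  bbh1 <- data.frame(p = c("a", "a", "b"), q = c("b", "c", "c"),
                     stringsAsFactors = FALSE)
  cl1 <- cogTriangles(bbh1, prot)
  expect_equal(sort(cl1$protein_id[cl1$cluster_id == 1]), c("a", "b", "c"))
  expect_equal(cl1$protein_id[cl1$cluster_id == 2], "d")

  # two triangles sharing the a-b edge -> one 4-member cluster
  bbh2 <- rbind(bbh1, data.frame(p = c("a", "b"), q = c("d", "d")))
  cl2 <- cogTriangles(bbh2, prot)
  expect_equal(sort(cl2$protein_id[cl2$cluster_id == 1]), c("a", "b", "c", "d"))

  # a BBH pair in no triangle stays two singletons
  bbh3 <- data.frame(p = "a", q = "b", stringsAsFactors = FALSE)
  cl3 <- cogTriangles(bbh3, prot)
  expect_equal(max(cl3$cluster_id), 4L)
  expect_true(all(table(cl3$cluster_id) == 1))
})

test_that("clustering is a partition of the input proteins", {
  set.seed(67)
  inst <- randomHitInstance(25, 5)
  cl <- cogTriangles(bbhPairs(inst$hits), inst$proteins)
  expect_setequal(cl$protein_id, inst$proteins$protein_id)
  expect_equal(anyDuplicated(cl$protein_id), 0L)
})

test_that("pangenome matrix counts are consistent with the cluster table", {
  clusters <- data.frame(
    cluster_id = c(1, 1, 1, 2, 2, 3),
    genome_id = c("g1", "g2", "g3", "g1", "g2", "g2"),
    protein_id = paste0("p", 1:6), stringsAsFactors = FALSE)
  pg <- buildPangenome(clusters, c("g1", "g2", "g3", "g4"))
  p <- presenceMatrix(pg)
  expect_equal(dim(p), c(4L, 3L))
  expect_equal(unname(rowSums(p)), c(2, 3, 1, 0))  # g4 all-false row
  # true cells equal sum over clusters of distinct genomes represented
  expect_equal(sum(p), length(unique(paste(clusters$cluster_id,
                                           clusters$genome_id))))
})
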