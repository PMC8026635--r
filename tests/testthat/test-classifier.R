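# feature extraction from marker hits and the prophage-state rule cascade.

featureSet <- function(...) {
  base <- list(genome_id = "g", has_terminase = TRUE, has_mcp = TRUE,
               has_tmp = TRUE, tmp_intact = TRUE, tmp_fragment_count = 1L,
               terminase_truncated = FALSE, motor_type = "parM",
               has_adapter_downstream = TRUE, has_tyrosine_recombinase = TRUE,
               has_serine_recombinase = FALSE,
               serine_recombinase_class = "none", has_sheath = FALSE)
  mod <- list(...)
  base[names(mod)] <- mod
  class(base) <- "GeneFeatureSet"
  base
}

test_that("the rule cascade reproduces the canonical calls", {
  # complete head + partitioning system + recombinase: active prophage
  call <- classifyFeatures(featureSet())
  expect_equal(call$state, "putative_active_plasmid_prophage")
  expect_equal(call$morphotype, "siphovirus_like")
  expect_equal(call$rules, "R4")

  # head markers but no maintenance machinery: likely a virulent phage
  call <- classifyFeatures(featureSet(motor_type = "none",
                                      has_tyrosine_recombinase = FALSE,
                                      has_adapter_downstream = FALSE))
  expect_equal(call$state, "putative_virulent_phage")
  expect_equal(call$rules, "R2")

  # split tape measure protein: degenerated
  call <- classifyFeatures(featureSet(tmp_intact = FALSE,
                                      tmp_fragment_count = 2L))
  expect_equal(call$state, "putative_degenerated_plasmid_prophage")
  expect_equal(call$rules, "R3")

  # truncated terminase: degenerated even with an intact tail
  call <- classifyFeatures(featureSet(terminase_truncated = TRUE))
  expect_equal(call$state, "putative_degenerated_plasmid_prophage")

  # no terminase: not a phage at all
  call <- classifyFeatures(featureSet(has_terminase = FALSE))
  expect_equal(call$state, "non_phage_plasmid")
  expect_equal(call$rules, "R1")
})

test_that("morphotype is driven by the sheath, then by the tail marker", {
  expect_equal(classifyFeatures(featureSet(has_sheath = TRUE))$morphotype,
               "myovirus_like")
  expect_equal(classifyFeatures(featureSet(has_sheath = FALSE))$morphotype,
               "siphovirus_like")
  expect_equal(classifyFeatures(featureSet(has_tmp = FALSE,
                                           tmp_intact = FALSE))$morphotype,
               "undetermined")
})

test_that("classification is a pure total function over random feature sets", {
  set.seed(55)
  for (rep in 1:200) {
    f <- featureSet(
      has_terminase = sample(c(TRUE, FALSE), 1),
      has_mcp = sample(c(TRUE, FALSE), 1),
      has_tmp = sample(c(TRUE, FALSE), 1),
      tmp_intact = sample(c(TRUE, FALSE), 1),
      terminase_truncated = sample(c(TRUE, FALSE), 1),
      motor_type = sample(c("none", "parA", "parM", "tubZ"), 1),
      has_tyrosine_recombinase = sample(c(TRUE, FALSE), 1),
      has_serine_recombinase = sample(c(TRUE, FALSE), 1),
      has_sheath = sample(c(TRUE, FALSE), 1))
    f$tmp_intact <- f$tmp_intact && f$has_tmp       # type invariant
    f$has_adapter_downstream <- f$motor_type != "none" && runif(1) < 0.5
    call1 <- classifyFeatures(f)
    call2 <- classifyFeatures(f)
    expect_true(call1$state %in% PROPHAGE_STATES)
    expect_identical(call1$state, call2$state)
    expect_length(call1$rules, 1)
  }
})

test_that("feature extraction reads gene architecture from hits and coordinates", {
  cfg <- screenConfig()
  # gene order: terminase, tmp fragment a, tmp fragment b, motor, adapter,
  # serine recombinase; coordinates in gene order on the forward strand
  proteins <- data.frame(
    protein_id = c("p1", "p2", "p3", "p4", "p5", "p6", "p7"),
    genome_id = "g",
    start = c(1, 2000, 3000, 6000, 7000, 7500, 9000),
    end = c(1500, 2900, 5900, 6900, 7400, 8200, 9800),
    strand = c("+", "+", "+", "+", "+", "+", "+"),
    length_aa = c(420, 313, 669, 330, 90, 195, 250),
    stringsAsFactors = FALSE)
  hits <- data.frame(
    protein_id = c("p1", "p2", "p3", "p4", "p6", "p7"),
    genome_id = "g",
    profile = c("terminase", "tmp", "tmp", "parM", "serine_recombinase", "mcp"),
    bit_score = c(200, 100, 220, 150, 90, 180),
    evalue = NA_real_, coverage = c(0.97, 0.26, 0.55, 0.95, 0.9, 0.95),
    start = 1L, end = 1L, stringsAsFactors = FALSE)
  f <- extractFeatures("g", proteins, hits, cfg)
  expect_true(f$has_terminase)
  expect_false(f$terminase_truncated)
  expect_true(f$has_tmp)
  expect_false(f$tmp_intact)               # best TMP CDS is 669 aa < 900
  expect_equal(f$tmp_fragment_count, 2L)   # two TMP CDSs within 3 genes
  expect_equal(f$motor_type, "parM")
  expect_true(f$has_adapter_downstream)    # 90-aa CDS right after the motor
  expect_equal(f$serine_recombinase_class, "small_resolvase_invertase")
  expect_false(f$has_tyrosine_recombinase)

  # terminase truncation keys on profile match-state coverage
  hits2 <- hits; hits2$coverage[1] <- 0.7
  expect_true(extractFeatures("g", proteins, hits2, cfg)$terminase_truncated)

  # adapter must lie downstream on the same strand
  proteins3 <- proteins; proteins3$strand[5] <- "-"
  expect_false(extractFeatures("g", proteins3, hits, cfg)$has_adapter_downstream)

  # a large serine recombinase is integrase-like
  proteins4 <- proteins; proteins4$length_aa[6] <- 450
  expect_equal(extractFeatures("g", proteins4, hits, cfg)$serine_recombinase_class,
               "large_integrase_like")

  # no motor hit: no adapter by construction
  f5 <- extractFeatures("g", proteins, hits[hits$profile != "parM", ], cfg)
  expect_equal(f5$motor_type, "none")
  expect_false(f5$has_adapter_downstream)

  # CDS outside the genome is a coordinate error
  expect_error(extractFeatures("g", proteins, hits, cfg, genomeLength = 5000),
               "coordinates")
})

test_that("report percentages and counts are consistent", {
  calls <- list(
    classifyFeatures(featureSet(genome_id = "g1")),
    classifyFeatures(featureSet(genome_id = "g2", has_terminase = FALSE)),
    classifyFeatures(featureSet(genome_id = "g3", has_terminase = FALSE)),
    classifyFeatures(featureSet(genome_id = "g4", terminase_truncated = TRUE)))
  rep <- reportCalls(calls)
  expect_equal(sum(rep$counts$n), 4L)
  expect_equal(sum(rep$counts$percent), 100)
  for (s in PROPHAGE_STATES)
    expect_equal(rep$counts$n[rep$counts$state == s], sum(rep$calls$state == s))
  d <- tempfile(); dir.create(d)
  rep2 <- reportCalls(calls, dir = d)
  expect_true(file.exists(file.path(d, "calls.tsv")))
  back <- read.table(file.path(d, "counts.tsv"), header = TRUE, sep = "\t")
  expect_equal(back$n, rep$counts$n)
})
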