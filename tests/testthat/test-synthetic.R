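# synthetic generator: determinism, family divergence statistics, planted
# architecture, duplicates, and gene corruption.

test_that("generation is deterministic under a fixed seed", {
  spec <- generatorSpec(seed = 77L, nGenomes = 6L,
                        stateMix = c(active = 2L, degenerated = 1L,
                                     virulent = 1L, non_phage = 2L),
                        nGroups = 1L, genomeLengthRange = c(15000, 17000))
  a <- makeGenomes(spec)
  b <- makeGenomes(spec)
  expect_identical(as.character(a$genomes), as.character(b$genomes))
  expect_identical(a$proteins, b$proteins)
  expect_identical(a$truth, b$truth)
  expect_identical(a$families$members, b$families$members)
})

test_that("family divergence matches the closed-form expectation", {
  spec <- generatorSpec(seed = 9L)
  fam <- makeMarkerFamilies(spec)
  d <- spec@familyDivergence
  expected <- (1 - d)^2 + d^2 / 19
  for (f in c("terminase", "tmp", "adapter")) {
    members <- fam$members[[f]]
    idents <- c()
    for (i in 1:5) for (j in (i + 1):6) {
      a <- strsplit(members[[i]], "")[[1]]
      b <- strsplit(members[[j]], "")[[1]]
      idents <- c(idents, mean(a == b))
    }
    expect_lt(abs(mean(idents) - expected), 0.05)
  }
  # the serine recombinase family respects its class boundary
  expect_true(all(nchar(fam$members$serine_recombinase) <= 250))
})

test_that("planted genomes carry the architecture of their state", {
  ds <- smallDataset()
  tr <- ds$truth
  prots <- split(ds$proteins$family, ds$proteins$genome_id)
  for (i in seq_len(nrow(tr))) {
    fams <- prots[[tr$genome_id[i]]]
    st <- tr$planted_state[i]
    if (st %in% c("active", "degenerated", "virulent")) {
      expect_true(all(c("terminase", "mcp", "tmp") %in% fams), info = tr$genome_id[i])
    } else {
      expect_false(any(c("terminase", "mcp", "tmp") %in% fams))
    }
    if (st == "virulent") {
      expect_false(any(c("parA", "parM", "tubZ", "xerC",
                         "serine_recombinase", "adapter") %in% fams))
    }
    if (st %in% c("active", "degenerated", "non_phage")) {
      expect_true(any(c("parA", "parM", "tubZ") %in% fams))
      expect_true("adapter" %in% fams)
    }
  }
  # genome lengths respect the configured window and the screening window
  w <- Biostrings::width(ds$genomes)
  expect_true(all(w >= 15000 & w <= 500000))
  # truth state counts equal the requested mix for unique genomes
  uniq <- tr[is.na(tr$duplicate_of) | tr$planted_identity < 0.99, ]
  expect_equal(unname(table(uniq$planted_state)[c("active", "degenerated",
                                                  "virulent", "non_phage")]),
               unname(smallSpec()@stateMix[c("active", "degenerated",
                                             "virulent", "non_phage")]),
               ignore_attr = TRUE)
})

test_that("annotated CDS translations equal the protein records", {
  ds <- smallDataset()
  pr <- ds$proteins
  idx <- sample(nrow(pr), 25)
  for (i in idx) {
    dna <- substr(as.character(ds$genomes[[pr$genome_id[i]]]),
                  pr$start[i], pr$end[i])
    if (pr$strand[i] == "-")
      dna <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(dna)))
    aa <- as.character(Biostrings::translate(Biostrings::DNAString(dna)))
    expect_equal(sub("\\*$", "", aa), pr$seq[i], info = pr$protein_id[i])
  }
  # GFF3 round trip preserves the coordinates
  f <- tempfile(fileext = ".gff3")
  writeGff3(ds$gff, f)
  expect_true(any(grepl("^##gff-version 3", readLines(f, n = 5))))
  back <- readGff3(f)
  expect_equal(length(back), length(ds$gff))
  expect_equal(sort(back$ID), sort(ds$gff$ID))
})

test_that("planted duplicates have the advertised identities", {
  ds <- smallDataset()
  tr <- ds$truth
  dups <- tr[!is.na(tr$duplicate_of), ]
  expect_equal(nrow(dups), 3L)
  expect_setequal(round(dups$planted_identity, 3), c(1, 0.995, 0.98))
  for (i in seq_len(nrow(dups))) {
    a <- strsplit(as.character(ds$genomes[[dups$genome_id[i]]]), "")[[1]]
    b <- strsplit(as.character(ds$genomes[[dups$duplicate_of[i]]]), "")[[1]]
    expect_equal(length(a), length(b))
    expect_lt(abs(mean(a == b) - dups$planted_identity[i]), 0.002)
  }
})

test_that("corruptGene splits and truncates as advertised", {
  ds <- smallDataset()
  active <- ds$truth$genome_id[ds$truth$planted_state == "active" &
                               is.na(ds$truth$duplicate_of)][1]
  orig <- ds$proteins[ds$proteins$genome_id == active &
                      ds$proteins$family == "tmp", ]
  expect_equal(nrow(orig), 1L)

  split <- corruptGene(ds, active, "tmp", "split")
  frags <- split$proteins[split$proteins$genome_id == active &
                          split$proteins$family == "tmp", ]
  expect_equal(nrow(frags), 2L)
  expect_equal(sum(frags$length_aa), orig$length_aa - 1L)  # one codon -> stop
  expect_equal(split$truth$planted_state[split$truth$genome_id == active],
               "degenerated")
  # translations still consistent after corruption
  for (i in seq_len(2)) {
    dna <- substr(as.character(split$genomes[[active]]), frags$start[i], frags$end[i])
    aa <- as.character(Biostrings::translate(Biostrings::DNAString(dna)))
    expect_equal(sub("\\*$", "", aa), frags$seq[i])
  }

  trunc <- corruptGene(ds, active, "terminase", "truncate")
  t2 <- trunc$proteins[trunc$proteins$genome_id == active &
                       trunc$proteins$family == "terminase", ]
  expect_equal(t2$length_aa, floor(0.7 * 420))  # terminase ancestors are 420 aa

  expect_error(corruptGene(ds, active, "sheath", "split"), "does not carry")
})
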