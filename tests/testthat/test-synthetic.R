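test_that("hairpin planting is deterministic and honours the spec counts", {
  spec <- small_spec(seed = 42)
  t1 <- plant_hairpins(spec)
  t2 <- plant_hairpins(spec)
  expect_identical(t1$genome, t2$genome)
  expect_identical(t1$loci, t2$loci)
  expect_equal(sum(t1$loci$type == "known_mirna"), 6)
  expect_equal(sum(t1$loci$type == "novel_mirna"), 5)
  expect_equal(sum(t1$loci$type == "decoy"), 10)
  ## planted loci never overlap and avoid the unplaced chromosome
  expect_false(any(t1$loci$chrom == "chr1_random"))
  by_chr <- split(t1$loci, t1$loci$chrom)
  for (b in by_chr) {
    b <- b[order(b$start), ]
    if (nrow(b) > 1) expect_true(all(b$start[-1] >= b$end[-nrow(b)]))
  }
  ## novel loci are absent from every annotation tier
  novel_seqs <- t1$loci$mature_seq[t1$loci$type == "novel_mirna"]
  for (tier in t1$tiers) expect_false(any(novel_seqs %in% tier$sequences))
  ## the genome carries each planted mature sequence at its recorded interval
  for (i in seq_len(nrow(t1$loci))) {
    lc <- t1$loci[i, ]
    g <- substr(t1$genome[[lc$chrom]], lc$mature_start + 1, lc$mature_end)
    if (lc$strand == "-") g <- revcomp(g)
    expect_equal(g, lc$mature_seq)
  }
})

test_that("planted hairpins pass the structure filters in at least one window", {
  truth <- plant_hairpins(small_spec(seed = 43))
  cfg <- cluster_config()
  loci <- truth$loci[truth$loci$type != "decoy", ][1:4, ]
  for (i in seq_len(nrow(loci))) {
    lc <- loci[i, ]
    cl <- data.frame(cluster_id = "c", chrom = lc$chrom,
                     start = lc$mature_start - 1L, end = lc$mature_end + 1L,
                     strand = lc$strand,
                     span = lc$mature_end - lc$mature_start + 2L,
                     total_count = 50L, stringsAsFactors = FALSE)
    cl$members <- list(data.frame())
    prec <- generate_precursors(cl, truth$genome, cfg)
    folded <- fold_precursors(prec)
    expect_true(any(folded$pass), info = lc$locus_id)
    expect_true(min(folded$mfe[folded$pass]) <= -25, info = lc$locus_id)
  }
})

test_that("read simulation is deterministic, Poisson-consistent and length-correct", {
  spec <- small_spec(seed = 44)
  truth <- plant_hairpins(spec)
  s1 <- simulate_reads(truth, "control")
  s2 <- simulate_reads(truth, "control")
  expect_identical(unname(s1$reads), unname(s2$reads))
  expect_true(all(nchar(s1$reads) <= 25))
  st <- simulate_reads(truth, "treated")
  expect_true(all(nchar(st$reads) <= 35))
  expect_gt(median(nchar(st$reads)), median(nchar(s1$reads)))
  ## observed per-locus counts stay within 3 sigma of the Poisson expectation
  e <- s1$expected
  expect_true(all(abs(e$observed_mature - e$expected_mature) <=
                    3 * sqrt(e$expected_mature) + 1))
})

test_that("treated counts fall for repressed loci by construction", {
  spec <- synthetic_spec(genome_length = 40000, n_known_mirnas = 3,
                         n_novel_mirnas = 4, n_decoy_rnas = 4,
                         reads_per_sample = 8000, repression_fraction = 1,
                         seed = 45)
  truth <- plant_hairpins(spec)
  expect_true(all(truth$loci$direction[truth$loci$type != "decoy"] == "repressed"))
  ec <- simulate_reads(truth, "control")$expected
  et <- simulate_reads(truth, "treated")$expected
  mir <- ec$type != "decoy"
  expect_true(all(et$expected_mature[mir] < ec$expected_mature[mir]))
})

test_that("the conservation track separates miRNA loci from background", {
  truth <- plant_hairpins(small_spec(seed = 46))
  track <- make_conservation_track(truth)
  for (i in which(truth$loci$type != "decoy")) {
    lc <- truth$loci[i, ]
    expect_gte(conservation_mean(track, lc$chrom, lc$start, lc$end), 0.8)
  }
  for (i in which(truth$loci$type == "decoy")) {
    lc <- truth$loci[i, ]
    expect_lte(conservation_mean(track, lc$chrom, lc$start, lc$end), 0.2)
  }
  ## a random unplanted window scores low
  expect_lte(conservation_mean(track, "chr1_random", 1000, 1200), 0.2)
  ## empty truth -> a track with no high-scoring blocks
  empty <- plant_hairpins(synthetic_spec(genome_length = 30000,
                                         n_known_mirnas = 0,
                                         n_novel_mirnas = 0, n_decoy_rnas = 0,
                                         reads_per_sample = 1000, seed = 47))
  tr0 <- make_conservation_track(empty)
  expect_true(all(tr0$score <= 0.2))
})

test_that("background-only simulations never reach the test expression cutoff", {
  spec <- synthetic_spec(genome_length = 40000, n_known_mirnas = 0,
                         n_novel_mirnas = 0, n_decoy_rnas = 0,
                         reads_per_sample = 3000, background_fraction = 1,
                         seed = 48)
  truth <- plant_hairpins(spec)
  expect_equal(nrow(truth$loci), 0)
  reads <- simulate_reads(truth, "control")$reads
  col <- collapse_reads(suppressMessages(trim_reads(reads)))
  hits <- align_reads(col, truth$genome)
  clusters <- suppressMessages(build_clusters(hits))
  if (nrow(clusters) > 0) expect_lt(max(clusters$total_count), 11)
})

test_that("simulated expression matrices carry their planted DE truth", {
  sim <- simulate_expression_matrix(n_probes = 100, n_de = 10, seed = 49)
  expect_equal(dim(sim$mat), c(100, 6))
  expect_equal(sum(sim$de_truth$is_de), 10)
  sim2 <- simulate_expression_matrix(n_probes = 100, n_de = 10, seed = 49)
  expect_identical(sim$mat, sim2$mat)
  d <- rowMeans(sim$mat[, sim$groups == "treated"]) -
    rowMeans(sim$mat[, sim$groups == "control"])
  expect_gt(mean(abs(d[sim$de_truth$is_de])),
            5 * mean(abs(d[!sim$de_truth$is_de])))
})
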