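test_that("a unique exact match yields one zero-mismatch hit", {
  set.seed(101)
  genome <- c(chr1 = random_dna(5000))
  read <- substr(genome[["chr1"]], 1001, 1020)
  h <- align_read(read, genome)
  expect_equal(nrow(h), 1)
  expect_equal(h$start, 1000)
  expect_equal(h$end, 1020)
  expect_equal(h$strand, "+")
  expect_equal(h$seed_mismatches, 0)
})

test_that("reads exceeding the seed mismatch budget are rejected", {
  set.seed(102)
  genome <- c(chr1 = random_dna(3000))
  read <- substr(genome[["chr1"]], 501, 520)
  ## plant 3 mismatches inside the 17-nt seed
  mut <- read
  for (p in c(2, 8, 14)) {
    old <- substr(mut, p, p)
    substr(mut, p, p) <- setdiff(c("A", "C", "G", "T"), old)[1]
  }
  expect_equal(nrow(align_read(mut, genome)), 0)
  ## 2 seed mismatches are still allowed
  mut2 <- read
  for (p in c(2, 8)) {
    old <- substr(mut2, p, p)
    substr(mut2, p, p) <- setdiff(c("A", "C", "G", "T"), old)[1]
  }
  h <- align_read(mut2, genome)
  expect_true(nrow(h) >= 1)
  expect_true(all(h$seed_mismatches <= 2))
  ## mismatches in the 3 trailing bases are unrestricted
  mut3 <- read
  for (p in 18:20) {
    old <- substr(mut3, p, p)
    substr(mut3, p, p) <- setdiff(c("A", "C", "G", "T"), old)[1]
  }
  h3 <- align_read(mut3, genome)
  expect_true(any(h3$start == 500 & h3$seed_mismatches == 0))
})

test_that("a read at 8 identical loci is suppressed by the alignment cap", {
  set.seed(103)
  core <- random_dna(20)
  copies <- replicate(8, paste0(core, paste(sample(c("A", "C"), 30, TRUE),
                                            collapse = "")))
  genome <- c(chrX = paste(copies, collapse = ""))
  h <- align_read(core, genome)
  expect_equal(nrow(h), 0)
  expect_true(attr(h, "suppressed"))
  ## 5 copies stay under the cap of 6
  genome5 <- c(chrX = paste(copies[1:5], collapse = ""))
  h5 <- align_read(core, genome5)
  expect_equal(nrow(h5), 5)
})

test_that("internal aligner equals the brute-force position scan", {
  set.seed(104)
  genome <- c(chrA = random_dna(6000), chrB = random_dna(4000))
  p <- align_params()
  for (i in 1:20) {
    if (i <= 14) {
      ch <- sample(names(genome), 1)
      pos <- sample(nchar(genome[[ch]]) - 20, 1)
      rd <- substr(genome[[ch]], pos, pos + 19)
      if (i %% 3 == 0) {
        q <- sample(17, 1)
        substr(rd, q, q) <- setdiff(c("A", "C", "G", "T"), substr(rd, q, q))[1]
      }
      if (i %% 4 == 0) rd <- revcomp(rd)
    } else {
      rd <- random_dna(20)
    }
    expect_true(same_as_oracle(align_read(rd, genome, p), brute_align(rd, genome)),
                info = paste("read", i, rd))
  }
})

test_that("aligning the reverse complement swaps strands and nothing else", {
  set.seed(105)
  genome <- c(chr1 = random_dna(4000))
  rd <- substr(genome[["chr1"]], 2001, 2020)
  h_fwd <- align_read(rd, genome)
  h_rev <- align_read(revcomp(rd), genome)
  expect_equal(nrow(h_fwd), nrow(h_rev))
  expect_equal(h_fwd$start, h_rev$start)
  expect_equal(h_fwd$end, h_rev$end)
  expect_equal(chartr("+-", "-+", h_fwd$strand), h_rev$strand)
})

test_that("tier assignment removes reads at their first matching tier", {
  set.seed(106)
  genome <- c(chr1 = random_dna(20000))
  mature <- vapply(1:10, function(i) random_dna(22), "")
  rrna <- vapply(1:10, function(i) random_dna(60), "")
  ## plant rRNA-like decoys and intergenic reads in the genome
  for (i in 1:10) {
    substr(genome[["chr1"]], 1000 * i, 1000 * i + 59) <- rrna[i]
  }
  intergenic <- vapply(1:10, function(i) {
    substr(genome[["chr1"]], 12000 + 37 * i, 12000 + 37 * i + 19)
  }, "")
  reads <- c(substr(mature, 1, 20), substr(rrna, 3, 22), intergenic)
  col <- collapse_reads(reads)
  tiers <- list(reference_tier("mature", mature),
                reference_tier("star", character(0)),
                reference_tier("star_unobserved", character(0)),
                reference_tier("hairpin", character(0)),
                reference_tier("refseq_mrna", character(0)),
                reference_tier("rfam", rrna),
                reference_tier("genome", genome))
  ta <- assign_tiers(col, tiers)
  tab <- table(ta$assignment$tier)
  expect_equal(as.integer(tab[c("mature", "rfam", "genome")]), c(10, 10, 10))
  ## partition property: every read in exactly one category
  expect_equal(sum(tab), nrow(col))
  expect_false(any(is.na(ta$assignment$tier)))
  ## a read matching the mature tier is never tested downstream
  expect_false(any(ta$tier_hits$rfam$read_sequence %in% substr(mature, 1, 20)))
  ## empty tier list errors
  expect_error(assign_tiers(col, list()), "empty")
  ## final tier must be the genome
  expect_error(assign_tiers(col, tiers[1:2]), "genome")
})

test_that("unobserved star derivation follows the 2-nt overhang duplex geometry", {
  ## perfect inverted repeat with a 3' tail so the shifted interval stays
  ## inside the hairpin
  mature <- "GCGGCATCGATCGGACCGGCAT"
  hairpin <- paste0(mature, "AACCAACCAACC", revcomp(mature), "ACACA")
  star <- derive_unobserved_star(hairpin, 1, nchar(mature))
  ## oracle: pair-table lookup with the +2 shift applied in test code
  s <- fold_rna(hairpin)
  partners <- s$pair_table[1:nchar(mature)]
  expect_true(mean(partners > 0) >= 0.5)
  rng <- range(partners[partners > 0]) + 2L
  expect_equal(star, substr(hairpin, rng[1], rng[2]))
  ## the star of a perfect duplex is the reverse complement shifted 2 nt
  expect_equal(star, substr(paste0(revcomp(mature), "ACACA"), 3, nchar(mature) + 2))
  ## mature placed in the terminal loop is unpaired -> empty result
  lp <- paste0(strrep("C", 20), strrep("A", 12), strrep("G", 20))
  expect_equal(derive_unobserved_star(lp, 22, 8), "")
  ## mature outside the hairpin errors
  expect_error(derive_unobserved_star(lp, 50, 20), "outside")
})
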