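## a fully controlled candidate: perfect 25-bp stem planted in a genomic
## window, cluster on the 5' arm, star reads planted on the 3' arm
make_feature_fixture <- function(seed = 401, strand = "+") {
  set.seed(seed)
  stem <- perfect_stem(25, loop = "AACAA")   # 55 nt hairpin
  ## A-only flanks cannot pair with the C/G stem, so every window containing
  ## the full stem folds to exactly its 25 pairs
  insert <- if (strand == "+") stem else revcomp(stem)
  genome <- c(chr1 = paste0(strrep("A", 150), insert, strrep("A", 150)))
  ## five reads of counts 3,2,1,1,1 on the cluster arm
  mk <- function(starts, counts, strand) {
    data.frame(read_sequence = paste0("r", seq_along(starts), "_", strand),
               ref_id = "chr1", start = starts, end = starts + 20L,
               strand = strand, seed_mismatches = 0L, total_mismatches = 0L,
               count = counts, stringsAsFactors = FALSE)
  }
  if (strand == "+") {
    cl_hits <- mk(c(150, 150, 151, 152, 152), c(3, 2, 1, 1, 1), "+")
    star_hits <- mk(c(182, 184), c(4, 2), "+")  # inside the 3' arm
  } else {
    cl_hits <- mk(c(185, 185, 184, 183, 183), c(3, 2, 1, 1, 1), "-")
    star_hits <- mk(c(153, 151), c(4, 2), "-")
  }
  clusters <- build_clusters(cl_hits)
  prec <- generate_precursors(clusters, genome, cluster_config())
  folded <- fold_precursors(prec)
  list(genome = genome, clusters = clusters, folded = folded,
       hits = rbind(cl_hits, star_hits))
}

test_that("feature values match hand-computable quantities on a planted hairpin", {
  fx <- make_feature_fixture()
  cand <- fx$folded[fx$folded$pass, ][1, ]
  fv <- compute_features(cand, cand$structure[[1]], fx$hits, cons = NULL)
  expect_named(fv, mirforge:::FEATURE_NAMES)
  ## f5: counting oracle on the planted counts 3+2+1+1+1
  expect_equal(unname(fv["f5_cluster_tag_count"]), 8)
  ## f3: cluster span from the planted hit coordinates
  expect_equal(unname(fv["f3_cluster_length"]), 22)
  ## f7 is exactly f6 / window length
  expect_equal(unname(fv["f7_norm_energy"]),
               unname(fv["f6_mfe"]) / nchar(cand$window_sequence))
  expect_equal(sign(fv[["f7_norm_energy"]]), sign(fv[["f6_mfe"]]))
  ## perfect stem: no bulges, symmetric arms
  expect_equal(unname(fv["f8_arm_unpaired_diff"]), 0)
  ## f1 cannot exceed cluster length nor twice the pair count
  expect_lte(fv[["f1_pairs_in_cluster"]], fv[["f3_cluster_length"]])
  expect_lte(fv[["f1_pairs_in_cluster"]], 2 * fv[["f2_pairs_in_precursor"]])
  ## f4: star reads planted fully within the partner interval
  expect_equal(unname(fv["f4_star_expression"]), 6)
  ## conservation defaults to zero without a track
  expect_equal(unname(fv["f9_conservation"]), 0)
})

test_that("star expression is found on the minus strand as well", {
  fx <- make_feature_fixture(seed = 402, strand = "-")
  cand <- fx$folded[fx$folded$pass, ][1, ]
  fv <- compute_features(cand, cand$structure[[1]], fx$hits, cons = NULL)
  expect_equal(unname(fv["f4_star_expression"]), 6)
  expect_equal(unname(fv["f5_cluster_tag_count"]), 8)
})

test_that("normalized energy follows the worked example", {
  ## MFE -30 over a 100-nt precursor gives -0.30
  cand <- data.frame(candidate_id = "x", chrom = "chr1", start = 0, end = 100,
                     strand = "+", cluster_off_start = 40, cluster_off_end = 62,
                     cluster_start = 40, cluster_end = 62, total_count = 12,
                     stringsAsFactors = FALSE)
  s <- structure(list(sequence = strrep("A", 100),
                      dotbracket = strrep(".", 100), mfe = -30,
                      pair_table = integer(100), n_hairpin_loops = 0L),
                 class = "rna_structure")
  fv <- compute_features(cand, s, NULL, NULL)
  expect_equal(unname(fv["f7_norm_energy"]), -0.30)
})

test_that("conservation means come from the track with absent regions at zero", {
  track <- data.frame(chrom = "chr1", start = c(100, 200), end = c(150, 210),
                      score = c(0.9, 0.4), stringsAsFactors = FALSE)
  expect_equal(conservation_mean(track, "chr1", 100, 150), 0.9)
  expect_equal(conservation_mean(track, "chr1", 100, 200), 0.9 * 50 / 100)
  expect_equal(conservation_mean(track, "chr1", 300, 350), 0)
  expect_equal(conservation_mean(track, "chr2", 100, 150), 0)
  expect_equal(conservation_mean(NULL, "chr1", 100, 150), 0)
  ## bedGraph round trip
  path <- withr::local_tempfile(fileext = ".bedGraph")
  write_bedgraph(track, path)
  back <- read_conservation(path)
  expect_equal(back$start, track$start)
  expect_equal(back$score, track$score)
})

test_that("feature matrices are stable, complete and duplicate-safe", {
  fx <- make_feature_fixture()
  cands <- fx$folded[fx$folded$pass, , drop = FALSE]
  fm <- feature_matrix(cands, fx$hits, NULL, label = "test")
  expect_equal(nrow(fm), nrow(cands))
  expect_equal(colnames(fm), c("candidate_id", mirforge:::FEATURE_NAMES, "label"))
  expect_false(anyNA(fm[, mirforge:::FEATURE_NAMES]))
  ## permuting candidate order permutes rows only
  fm2 <- feature_matrix(cands[rev(seq_len(nrow(cands))), ], fx$hits, NULL, "test")
  expect_equal(fm2[rev(seq_len(nrow(fm2))), -1], fm[, -1],
               ignore_attr = TRUE)
  ## duplicated ids error
  dup <- rbind(cands, cands)
  expect_error(feature_matrix(dup, fx$hits, NULL, "test"), "duplicated")
  ## absent conservation track leaves f9 at zero
  expect_true(all(fm$f9_conservation == 0))
})
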