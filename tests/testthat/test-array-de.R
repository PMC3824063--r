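test_that("signal-to-noise statistic matches hand arithmetic", {
  expect_equal(snr_statistic(c(3, 4, 5), c(1, 2, 3)), 1.0)
  expect_equal(snr_statistic(c(2, 2, 2), c(2, 2, 2)), 0.0)
  ## identical replicates: sd floor of 0.01 engages
  expect_equal(snr_statistic(c(10, 10), c(2, 2)), 8 / 0.02)
  ## anti-symmetry under group swap
  set.seed(701)
  a <- rnorm(4, 5); b <- rnorm(4, 3)
  expect_equal(snr_statistic(a, b), -snr_statistic(b, a))
  ## disabled floor with zero sds errors
  expect_error(snr_statistic(c(1, 1), c(2, 2), eps = 0), "denominator")
})

test_that("quantile normalization equalizes column distributions", {
  set.seed(702)
  raw <- matrix(2^rnorm(300, 8), nrow = 50)
  norm <- normalize_expression(raw)
  sorted <- apply(norm, 2, sort)
  for (j in 2:ncol(sorted)) expect_equal(sorted[, j], sorted[, 1])
  ## identical columns are a fixed point
  same <- matrix(rep(2^seq(1, 5, length.out = 20), 3), ncol = 3)
  expect_equal(unname(normalize_expression(same)), unname(log2(same)))
  ## non-positive intensities error
  expect_error(normalize_expression(matrix(c(-1, 2, 3, 4), 2)), "positive")
})

test_that("median polish summarization matches a hand-iterated oracle", {
  ## 3 spots x 2 samples for one probe, plus a singleton probe
  sub <- matrix(c(10, 12, 11, 20, 22, 21), nrow = 3)
  oracle <- medpolish(sub, eps = 1e-6, maxiter = 10, trace.iter = FALSE)
  expected <- oracle$overall + oracle$col
  raw <- 2^rbind(sub, c(5, 6))
  norm <- normalize_expression(raw, probe_ids = c("p1", "p1", "p1", "p2"),
                               log2_transform = TRUE)
  ## quantile normalization across these 2 columns changes values, so build
  ## the oracle from the same normalized matrix instead
  qn <- limma::normalizeQuantiles(log2(raw))
  mp <- medpolish(qn[1:3, ], eps = 1e-6, maxiter = 10, trace.iter = FALSE)
  expect_equal(unname(norm["p1", ]), unname(mp$overall + mp$col))
  expect_equal(unname(norm["p2", ]), unname(qn[4, ]))
})

test_that("permutation p-values equal exhaustive enumeration on a 3v3 design", {
  set.seed(703)
  mat <- matrix(rnorm(60, 8, 1), nrow = 10)
  mat[1, 4:6] <- mat[1, 4:6] + 3   # one strongly shifted probe
  rownames(mat) <- paste0("g", 1:10)
  groups <- rep(c("control", "treated"), each = 3)
  pv <- permutation_pvalues(mat, groups, exhaustive = TRUE, pool_probes = FALSE)
  ## independent oracle: enumerate all 20 relabelings with plain arithmetic
  combos <- combn(6, 3)
  for (i in c(1, 4, 7)) {
    obs <- (mean(mat[i, 4:6]) - mean(mat[i, 1:3])) /
      (max(sd(mat[i, 4:6]), 0.01) + max(sd(mat[i, 1:3]), 0.01))
    null <- apply(combos, 2, function(tr) {
      co <- setdiff(1:6, tr)
      (mean(mat[i, tr]) - mean(mat[i, co])) /
        (max(sd(mat[i, tr]), 0.01) + max(sd(mat[i, co]), 0.01))
    })
    expect_equal(pv$p_right[i], mean(null >= obs))
    expect_equal(pv$p_left[i], mean(null <= obs))
  }
  ## the shifted probe is at the extreme tail
  expect_equal(pv$p_right[1], 1 / 20)
})

test_that("random-permutation p-values are deterministic and near 1 for null snr", {
  set.seed(704)
  mat <- matrix(rnorm(120, 8), nrow = 20)
  groups <- rep(c("control", "treated"), each = 3)
  p1 <- permutation_pvalues(mat, groups, n_perm = 200, seed = 31)
  p2 <- permutation_pvalues(mat, groups, n_perm = 200, seed = 31)
  expect_identical(p1, p2)
  ## a probe with snr ~ 0 has two-sided p near 1
  mat0 <- mat
  mat0[5, ] <- rep(c(8, 9, 10), 2)
  p0 <- permutation_pvalues(mat0, groups, n_perm = 400, seed = 32)
  expect_gt(p0$p_two[5], 0.8)
  expect_error(permutation_pvalues(mat, groups, n_perm = 0), "n_perm")
})

test_that("null permutation p-values are approximately uniform", {
  set.seed(705)
  mat <- matrix(rnorm(100 * 6, 8), nrow = 100)
  groups <- rep(c("control", "treated"), each = 3)
  pv <- permutation_pvalues(mat, groups, n_perm = 1000, seed = 33,
                            pool_probes = TRUE)
  ks <- suppressWarnings(stats::ks.test(pv$p_right, "punif"))
  expect_gt(ks$p.value, 0.01)
})

test_that("significance gate requires both the p-value and fold-change thresholds", {
  stats <- data.frame(probe = c("g1", "g2", "g3", "g4"),
                      snr = c(2, 2, 2, 0.1),
                      fold_change = c(1.25, 1.1, -1.3, 1.25),
                      p_two = c(0.009, 0.009, 0.01, 0.011),
                      stringsAsFactors = FALSE)
  g <- gate_and_intersect(stats, list(A = c("g1", "g2"), B = c("g2", "g3")))
  expect_setequal(g$significant, c("g1", "g3"))   # g3: boundary p = 0.01 passes
  expect_equal(g$intersections$A, "g1")
  expect_equal(g$intersections$B, "g3")
  ## |FC| >= 1.2 boundary behaviour
  stats$fold_change <- c(1.2, 1.19, -1.2, 2)
  g2 <- gate_and_intersect(stats, list())
  expect_setequal(g2$significant, c("g1", "g3"))
})

test_that("the full DE wrapper flags planted effects in simulated arrays", {
  sim <- simulate_expression_matrix(n_probes = 120, n_de = 12,
                                    effect_log2 = c(1.2, 2), seed = 706)
  de <- de_stats(sim$mat, sim$groups, n_perm = 400, seed = 41)
  expect_true(all(de$p_two >= 0 & de$p_two <= 1))
  planted <- sim$de_truth$is_de
  ## planted effects have systematically larger |snr| and most gate through
  expect_gt(mean(abs(de$snr[planted])), 3 * mean(abs(de$snr[!planted])))
  expect_gt(mean(de$significant[planted]), 0.7)
  expect_lt(mean(de$significant[!planted]), 0.1)
  ## fold-change sign tracks the planted direction
  up <- sim$de_truth$direction == "induced"
  expect_true(all(de$fold_change[up & de$significant] > 0))
})
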