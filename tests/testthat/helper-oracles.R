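## Independent oracles used by the test suite. These deliberately share no
## code with the package implementation: the aligner oracle is a plain
## vectorised position scan, and the folding oracle enumerates every valid
## secondary structure and scores it from its pair set.

## ---- brute-force alignment oracle -----------------------------------------

## scan every position of every chromosome on both strands, apply the
## seed/stratum/cap rules, return a hit table comparable to align_read()
## (NULL when the read is unaligned or suppressed by the multi-mapper cap)
brute_align <- function(read, genome, seed_len = 17, max_mm = 2, max_aln = 6) {
  hits <- list()
  for (chrom in names(genome)) {
    g <- strsplit(genome[[chrom]], "")[[1]]
    for (strand in c("+", "-")) {
      q <- if (strand == "+") read else revcomp(read)
      qc <- strsplit(q, "")[[1]]
      rl <- length(qc)
      if (length(g) < rl) next
      seed_pos <- if (strand == "+") 1:seed_len else (rl - seed_len + 1):rl
      npos <- length(g) - rl + 1
      mmv <- integer(npos); tot <- integer(npos)
      for (k in 1:rl) {
        ne <- g[k:(length(g) - rl + k)] != qc[k]
        tot <- tot + ne
        if (k %in% seed_pos) mmv <- mmv + ne
      }
      for (s in which(mmv <= max_mm)) {
        hits[[length(hits) + 1]] <- data.frame(
          ref_id = chrom, start = s - 1L, end = s - 1L + rl, strand = strand,
          seed_mismatches = mmv[s], total_mismatches = tot[s],
          stringsAsFactors = FALSE)
      }
    }
  }
  if (!length(hits)) return(NULL)
  h <- do.call(rbind, hits)
  h <- h[h$seed_mismatches == min(h$seed_mismatches), , drop = FALSE]
  if (nrow(h) > max_aln) return(NULL)
  h <- h[order(h$ref_id, h$start, h$strand), , drop = FALSE]
  rownames(h) <- NULL
  h
}

## compare an align_read() result with the oracle
same_as_oracle <- function(mine, oracle) {
  if (is.null(oracle)) return(nrow(mine) == 0)
  if (nrow(mine) != nrow(oracle)) return(FALSE)
  cols <- c("ref_id", "start", "end", "strand", "seed_mismatches",
            "total_mismatches")
  isTRUE(all.equal(oracle[, cols], mine[, cols], check.attributes = FALSE))
}

## ---- exhaustive folding oracle --------------------------------------------

## same energy parameters as the internal model, applied to complete pair
## sets; every valid structure (non-crossing, complementary pairs, minimum
## loop 3) is generated and scored, so this is enumeration, not DP
ORACLE_PAIR_E <- c(GC = -3, CG = -3, AT = -2, TA = -2, GT = -1, TG = -1,
                   GU = -1, UG = -1, AU = -2, UA = -2)
ORACLE_STACK <- -1
oracle_hairpin_pen <- function(loop) 3.0 + 0.1 * (loop - 3)

## enumerate all structures of seq and return the minimum energy; per
## structure the recursion tracks the energy, whether the interval is empty
## and whether its two boundary positions pair with each other (needed for
## the parent's hairpin-loop and stacking terms)
enum_fold_mfe <- function(seq) {
  ch <- strsplit(toupper(seq), "")[[1]]
  n <- length(ch)
  memo <- new.env(parent = emptyenv())
  rec <- function(i, j) {
    if (j - i < 4) {
      return(list(E = 0, empty = TRUE, bp = FALSE))
    }
    key <- paste0(i, ":", j)
    got <- memo[[key]]
    if (!is.null(got)) return(got)
    res_E <- numeric(0); res_empty <- logical(0); res_bp <- logical(0)
    sub <- rec(i + 1, j)  # structures leaving position i unpaired
    res_E <- c(res_E, sub$E)
    res_empty <- c(res_empty, sub$empty)
    res_bp <- c(res_bp, rep(FALSE, length(sub$E)))
    for (k in (i + 4):j) {
      pe <- ORACLE_PAIR_E[paste0(ch[i], ch[k])]
      if (is.na(pe)) next
      inner <- rec(i + 1, k - 1)
      right <- rec(k + 1, j)
      inner_adj <- inner$E + pe +
        ifelse(inner$empty, oracle_hairpin_pen(k - i - 1), 0) +
        ifelse(inner$bp, ORACLE_STACK, 0)
      comb <- as.numeric(outer(inner_adj, right$E, `+`))
      res_E <- c(res_E, comb)
      res_empty <- c(res_empty, rep(FALSE, length(comb)))
      res_bp <- c(res_bp, rep(k == j, length(comb)))
    }
    out <- list(E = res_E, empty = res_empty, bp = res_bp)
    memo[[key]] <- out
    out
  }
  min(0, min(rec(1, n)$E))
}

## ---- small fixture builders ------------------------------------------------

## a perfect stem of n C-G pairs around an unpairable A-loop: the C arm and
## the A loop cannot pair internally, so the fold has exactly n pairs
perfect_stem <- function(n_pairs, loop = "AAA") {
  paste0(strrep("C", n_pairs), loop, strrep("G", n_pairs))
}

random_dna <- function(n) paste(sample(c("A", "C", "G", "T"), n, TRUE), collapse = "")

## separable two-class feature simulation used by the forest tests: features
## f2 (precursor pairs) and f6 (MFE) carry all the signal, everything else is
## label-independent noise
make_separable <- function(n_per_class, seed) {
  set.seed(seed)
  n <- 2 * n_per_class
  x <- as.data.frame(matrix(runif(n * 10), ncol = 10))
  names(x) <- paste0("f", 1:10)
  y <- rep(c(TRUE, FALSE), each = n_per_class)
  x$f2 <- ifelse(y, runif(n, 25, 35), runif(n, 5, 15))
  x$f6 <- ifelse(y, runif(n, -45, -30), runif(n, -15, -5))
  list(x = x, y = y)
}

## small synthetic study used by unit-scale pipeline tests
small_spec <- function(seed = 42) {
  synthetic_spec(genome_length = 60000, n_known_mirnas = 6,
                 n_novel_mirnas = 5, n_decoy_rnas = 10,
                 reads_per_sample = 10000, seed = seed)
}

## overlap bookkeeping between a call table and planted loci
calls_overlapping <- function(calls, loci) {
  if (nrow(calls) == 0) return(logical(0))
  vapply(seq_len(nrow(calls)), function(i) {
    any(loci$chrom == calls$chrom[i] & loci$strand == calls$strand[i] &
          pmin(loci$end, calls$end[i]) - pmax(loci$start, calls$start[i]) > 0)
  }, TRUE)
}

loci_recovered <- function(loci, calls) {
  if (nrow(loci) == 0) return(logical(0))
  vapply(seq_len(nrow(loci)), function(i) {
    nrow(calls) > 0 &&
      any(calls$chrom == loci$chrom[i] & calls$strand == loci$strand[i] &
            pmin(calls$end, loci$end[i]) - pmax(calls$start, loci$start[i]) > 0)
  }, TRUE)
}
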