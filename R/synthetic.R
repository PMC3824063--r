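#' Specification for a synthetic small-RNA experiment
#'
#' Defines the study conditions the generator emulates: a multi-chromosome
#' toy genome (including one unplaced "_random" chromosome), planted known
#' and novel miRNA hairpins, decoy structured RNAs assigned to the
#' mRNA/ncRNA-family tiers, two sequencing conditions (untreated control and
#' glucocorticoid-treated) in which most miRNA loci are repressed, and a
#' conservation track elevated over miRNA loci.
#'
#' @param genome_length total genome length in nt (default 200000, split over
#'   chr1/chr2/chr3/chr1_random at 35/30/25/10%).
#' @param n_known_mirnas planted miRNAs present in the annotation tiers
#'   (default 20).
#' @param n_novel_mirnas planted miRNAs absent from every tier (default 15).
#' @param n_decoy_rnas planted decoy RNAs present in the refseq/rfam tiers
#'   (default 30).
#' @param reads_per_sample approximate raw reads per condition (default 50000).
#' @param repression_fraction fraction of planted miRNA loci repressed in the
#'   treated condition (default 0.8).
#' @param fold_range range of per-locus fold changes (default 2-10).
#' @param background_fraction fraction of reads drawn uniformly from the
#'   genome (default 0.04).
#' @param star_fraction fraction of a locus's reads originating from the star
#'   arm (default 0.05).
#' @param raw_read_length raw read length per condition before trimming
#'   (control 25 nt, treated 35 nt).
#' @param seed master RNG seed; every generator call derives from it.
#' @return an object of class `synthetic_spec`.
#' @export
synthetic_spec <- function(genome_length = 200000L, n_known_mirnas = 20L,
                           n_novel_mirnas = 15L, n_decoy_rnas = 30L,
                           reads_per_sample = 50000L,
                           repression_fraction = 0.8,
                           fold_range = c(2, 10),
                           background_fraction = 0.04,
                           star_fraction = 0.05,
                           raw_read_length = c(control = 25L, treated = 35L),
                           seed = 1L) {
  stopifnot(genome_length >= 20000, repression_fraction >= 0,
            repression_fraction <= 1, fold_range[1] >= 1)
  chrom_lengths <- round(genome_length * c(chr1 = 0.35, chr2 = 0.30,
                                           chr3 = 0.25, chr1_random = 0.10))
  structure(list(genome_length = as.integer(genome_length),
                 chrom_lengths = chrom_lengths,
                 n_known_mirnas = as.integer(n_known_mirnas),
                 n_novel_mirnas = as.integer(n_novel_mirnas),
                 n_decoy_rnas = as.integer(n_decoy_rnas),
                 reads_per_sample = as.integer(reads_per_sample),
                 repression_fraction = repression_fraction,
                 fold_range = fold_range,
                 background_fraction = background_fraction,
                 star_fraction = star_fraction,
                 raw_read_length = raw_read_length,
                 seed = as.integer(seed)),
            class = "synthetic_spec")
}

rand_seq <- function(n, alphabet = c("A", "C", "G", "T"), prob = NULL) {
  paste(sample(alphabet, n, replace = TRUE, prob = prob), collapse = "")
}

mutate_seq <- function(s, k) {
  ch <- strsplit(s, "")[[1]]
  pos <- sample(length(ch), k)
  for (p in pos) ch[p] <- sample(setdiff(c("A", "C", "G", "T"), ch[p]), 1)
  paste(ch, collapse = "")
}

## A planted hairpin: mature arm + loop + (im)perfect reverse complement,
## flanked by A/C-only spacers (A and C cannot pair with each other, keeping
## the immediate flanks from forming competing helices with each other).
## `strong` controls stem composition (GC-rich, 1-2 mutations) vs weak decoys
## (AT-leaning, 3-4 mutations). Rejection-samples until at least one default
## precursor window around the mature cluster passes the structure filters
## (and, for strong hairpins, reaches MFE <= -26).
make_planted_locus <- function(strong = TRUE, spacer = 75L,
                               filt = structure_filter_config(),
                               clus = cluster_config()) {
  for (attempt in 1:50) {
    if (strong) {
      mature <- rand_seq(22, prob = c(0.2, 0.3, 0.3, 0.2))
      loop <- rand_seq(12, alphabet = c("A", "C"))
      star <- mutate_seq(revcomp(mature), sample(1:2, 1))
    } else {
      mature <- rand_seq(24, prob = c(0.32, 0.18, 0.18, 0.32))
      loop <- rand_seq(15, alphabet = c("A", "C"))
      star <- mutate_seq(revcomp(mature), sample(3:4, 1))
    }
    hairpin <- paste0(mature, loop, star)
    left <- rand_seq(spacer, alphabet = c("A", "C"))
    right <- rand_seq(spacer, alphabet = c("A", "C"))
    locus_seq <- paste0(left, hairpin, right)
    ## the read cluster covers the mature arm with 1 nt of end wobble; a
    ## window passes only when it contains enough of both stem arms, so the
    ## requirement is that at least one of the flank geometries passes (the
    ## pipeline keeps whichever windows fold well)
    c_start <- spacer - 1L
    c_end <- spacer + nchar(mature) + 1L
    ok <- FALSE
    mfe_best <- 0
    for (fl in clus$window_flanks) {
      ws <- c_start - fl[1]; we <- c_end + fl[2]
      ws <- max(0L, ws); we <- min(nchar(locus_seq), we)
      wseq <- substr(locus_seq, ws + 1L, we)
      s <- fold_rna(wseq)
      f <- passes_structure_filters(s, c(c_start - ws, c_end - ws), filt)
      if (f$pass) {
        ok <- TRUE
        mfe_best <- min(mfe_best, s$mfe)
      }
    }
    if (ok && (!strong || mfe_best <= -26)) {
      ## tier record with 10 nt of flank so end-wobble reads stay contained
      tier_seq <- substr(locus_seq, spacer - 10L + 1L,
                         spacer + nchar(hairpin) + 10L)
      return(list(mature = mature, star = star, hairpin = hairpin,
                  tier_seq = tier_seq, locus_seq = locus_seq, spacer = spacer,
                  mature_off = spacer, star_off = spacer + nchar(mature) +
                    nchar(loop)))
    }
  }
  stop("failed to generate a filter-passing hairpin after 50 attempts")
}

#' Plant hairpins and decoys in a synthetic genome
#'
#' Builds the genome, the annotation tier FASTAs and the ground truth. Known
#' miRNAs appear in the mature/star (or unobserved-star)/hairpin tiers; novel
#' miRNAs appear only in the genome; decoys appear in the refseq/rfam tiers
#' and the genome. Planted loci are non-overlapping and avoid the unplaced
#' chromosome so that truth loci are never removed by the chromosome
#' post-filter. Deterministic given `spec$seed`.
#'
#' @param spec a [synthetic_spec()].
#' @return an object of class `mirforge_truth`: list with `genome` (named
#'   character), `tiers` (ordered list of [reference_tier()]), `loci`
#'   (data frame of planted loci with type, coordinates, strand, sequences,
#'   expression and direction truth) and `spec`.
#' @export
plant_hairpins <- function(spec = synthetic_spec()) {
  with_seed(spec$seed, {
    genome <- vapply(spec$chrom_lengths, rand_seq, "")
    names(genome) <- names(spec$chrom_lengths)
    n_total <- spec$n_known_mirnas + spec$n_novel_mirnas + spec$n_decoy_rnas
    empty_loci <- data.frame(
      locus_id = character(0), type = character(0), chrom = character(0),
      strand = character(0), start = integer(0), end = integer(0),
      mature_start = integer(0), mature_end = integer(0),
      star_start = integer(0), star_end = integer(0),
      mature_seq = character(0), star_seq = character(0),
      hairpin_seq = character(0), tier_seq = character(0),
      rel_expression = numeric(0), direction = character(0),
      fold = numeric(0), stringsAsFactors = FALSE)
    types <- c(rep("known_mirna", spec$n_known_mirnas),
               rep("novel_mirna", spec$n_novel_mirnas),
               rep("decoy", spec$n_decoy_rnas))
    ## placement slots on the regular chromosomes, proportional to length
    host <- c("chr1", "chr2", "chr3")
    slots <- do.call(rbind, lapply(host, function(ch) {
      starts <- seq(200L, spec$chrom_lengths[[ch]] - 500L, by = 320L)
      data.frame(chrom = ch, pos = starts, stringsAsFactors = FALSE)
    }))
    if (nrow(slots) < n_total) stop("cannot place non-overlapping loci: genome too small")
    slots <- slots[sample(nrow(slots), n_total), , drop = FALSE]
    order_types <- sample(n_total)  # interleave types across chromosomes
    types <- types[order(order_types)]
    fold_rng <- spec$fold_range
    n_mir <- spec$n_known_mirnas + spec$n_novel_mirnas
    mir_idx <- which(types != "decoy")
    repressed <- rep(FALSE, n_total)
    n_rep <- round(spec$repression_fraction * n_mir)
    repressed[mir_idx[sample.int(length(mir_idx), n_rep)]] <- TRUE
    rows <- list()
    for (i in seq_len(n_total)) {
      pl <- make_planted_locus(strong = types[i] != "decoy")
      strand <- sample(c("+", "-"), 1)
      chrom <- slots$chrom[i]; pos <- slots$pos[i]
      insert <- if (strand == "+") pl$locus_seq else revcomp(pl$locus_seq)
      substr(genome[[chrom]], pos + 1L, pos + nchar(insert)) <- insert
      L <- nchar(pl$locus_seq); hp_len <- nchar(pl$hairpin)
      if (strand == "+") {
        hp_start <- pos + pl$spacer
        mat_start <- pos + pl$mature_off
        star_start <- pos + pl$star_off
      } else {
        hp_start <- pos + (L - pl$spacer - hp_len)
        mat_start <- pos + (L - pl$mature_off - nchar(pl$mature))
        star_start <- pos + (L - pl$star_off - nchar(pl$star))
      }
      is_mir <- types[i] != "decoy"
      rows[[i]] <- data.frame(
        locus_id = sprintf("%s_%d", types[i], i), type = types[i],
        chrom = chrom, strand = strand,
        start = hp_start, end = hp_start + hp_len,
        mature_start = mat_start, mature_end = mat_start + nchar(pl$mature),
        star_start = star_start, star_end = star_start + nchar(pl$star),
        mature_seq = pl$mature, star_seq = pl$star, hairpin_seq = pl$hairpin,
        tier_seq = pl$tier_seq,
        rel_expression = runif(1, 0.5, 2),
        direction = if (!is_mir) "unchanged" else
          if (repressed[i]) "repressed" else "induced",
        fold = if (is_mir) runif(1, fold_rng[1], fold_rng[2]) else 1,
        stringsAsFactors = FALSE)
    }
    loci <- if (n_total == 0) empty_loci else do.call(rbind, rows)
    rownames(loci) <- NULL
    known <- loci[loci$type == "known_mirna", , drop = FALSE]
    decoy <- loci[loci$type == "decoy", , drop = FALSE]
    half <- seq_len(nrow(known)) %% 2 == 0
    dhalf <- seq_len(nrow(decoy)) %% 2 == 0
    tiers <- list(
      reference_tier("mature", setNames(known$mature_seq, known$locus_id)),
      reference_tier("star", setNames(known$star_seq[half],
                                      known$locus_id[half])),
      reference_tier("star_unobserved", setNames(known$star_seq[!half],
                                                 known$locus_id[!half])),
      reference_tier("hairpin", setNames(known$tier_seq, known$locus_id)),
      reference_tier("refseq_mrna", setNames(decoy$tier_seq[dhalf],
                                             decoy$locus_id[dhalf])),
      reference_tier("rfam", setNames(decoy$tier_seq[!dhalf],
                                      decoy$locus_id[!dhalf])))
    structure(list(genome = genome, tiers = tiers, loci = loci, spec = spec),
              class = "mirforge_truth")
  })
}

## substring of the genome oriented along `strand`, reading `len` nt starting
## at 0-based position `start` in transcription order
oriented_read <- function(genome, chrom, start, len, strand) {
  chrom_seq <- genome[[chrom]]
  n <- nchar(chrom_seq)
  if (strand == "+") {
    e <- min(n, start + len)
    substr(chrom_seq, start + 1L, e)
  } else {
    s <- max(0L, start - len)
    revcomp(substr(chrom_seq, s + 1L, start))
  }
}

#' Simulate raw reads for one condition
#'
#' Reads are drawn from mature arms (with 1-nt end wobble at weights
#' 0.2/0.6/0.2), star arms at a low rate, decoy arms, and a uniform genomic
#' background; per-variant counts are Poisson so collapsing is exercised.
#' In the treated condition, expected counts of repressed loci are divided
#' by the planted fold and induced loci are multiplied by it. Raw reads are
#' longer than the mature sequence (25 nt control / 35 nt treated) and read
#' through into downstream sequence, emulating adapter read-through removed
#' later by trimming.
#'
#' @param truth a `mirforge_truth` from [plant_hairpins()].
#' @param condition "control" or "treated".
#' @return list with `reads` (named character vector of raw reads, shuffled)
#'   and `expected` (data frame of per-locus expected and realized mature
#'   read counts).
#' @export
simulate_reads <- function(truth, condition = c("control", "treated")) {
  condition <- match.arg(condition)
  spec <- truth$spec
  with_seed(spec$seed + ifelse(condition == "control", 1000L, 2000L), {
    loci <- truth$loci
    raw_len <- spec$raw_read_length[[condition]]
    n_locus_reads <- round(spec$reads_per_sample * (1 - spec$background_fraction))
    w <- loci$rel_expression
    expect_total <- n_locus_reads * w / sum(w)
    if (condition == "treated") {
      expect_total <- ifelse(loci$direction == "repressed",
                             expect_total / loci$fold,
                      ifelse(loci$direction == "induced",
                             expect_total * loci$fold, expect_total))
    }
    reads <- character(0)
    exp_rows <- list()
    offsets <- c(-1L, 0L, 1L)
    offw <- c(0.2, 0.6, 0.2)
    for (i in seq_len(nrow(loci))) {
      lc <- loci[i, ]
      e_mat <- expect_total[i] * (1 - spec$star_fraction)
      e_star <- expect_total[i] * spec$star_fraction
      obs_mat <- 0L
      for (k in seq_along(offsets)) {
        ## mature-arm reads with end wobble
        cnt <- rpois(1, e_mat * offw[k])
        if (cnt > 0) {
          start0 <- if (lc$strand == "+") lc$mature_start + offsets[k]
                    else lc$mature_end - offsets[k]
          s <- oriented_read(truth$genome, lc$chrom, start0, raw_len, lc$strand)
          reads <- c(reads, rep(s, cnt))
          obs_mat <- obs_mat + cnt
        }
        cnt <- rpois(1, e_star * offw[k])
        if (cnt > 0) {
          start0 <- if (lc$strand == "+") lc$star_start + offsets[k]
                    else lc$star_end - offsets[k]
          s <- oriented_read(truth$genome, lc$chrom, start0, raw_len, lc$strand)
          reads <- c(reads, rep(s, cnt))
        }
      }
      exp_rows[[i]] <- data.frame(locus_id = lc$locus_id, type = lc$type,
                                  condition = condition,
                                  expected_mature = e_mat,
                                  observed_mature = obs_mat,
                                  stringsAsFactors = FALSE)
    }
    n_bg <- round(spec$reads_per_sample * spec$background_fraction)
    chroms <- sample(names(truth$genome), n_bg, replace = TRUE,
                     prob = spec$chrom_lengths / sum(spec$chrom_lengths))
    for (ch in unique(chroms)) {
      m <- sum(chroms == ch)
      pos <- sample.int(spec$chrom_lengths[[ch]] - raw_len, m)
      st <- sample(c("+", "-"), m, replace = TRUE)
      bg <- vapply(seq_len(m), function(j) {
        if (st[j] == "+") oriented_read(truth$genome, ch, pos[j] - 1L, raw_len, "+")
        else oriented_read(truth$genome, ch, pos[j] - 1L + raw_len, raw_len, "-")
      }, "")
      reads <- c(reads, bg)
    }
    reads <- reads[sample(length(reads))]
    names(reads) <- sprintf("%s_read%d", condition, seq_along(reads))
    list(reads = reads, expected = do.call(rbind, exp_rows))
  })
}

#' Build the synthetic conservation track
#'
#' Planted miRNA loci (known and novel) receive high per-base scores
#' (0.85-0.98); decoys and scattered background blocks receive low scores
#' (0-0.15). Deterministic given the spec seed.
#'
#' @param truth a `mirforge_truth`.
#' @return conservation data frame (`chrom`, `start`, `end`, `score`).
#' @export
make_conservation_track <- function(truth) {
  spec <- truth$spec
  with_seed(spec$seed + 7L, {
    loci <- truth$loci
    rows <- list()
    for (i in seq_len(nrow(loci))) {
      hi <- loci$type[i] != "decoy"
      rows[[length(rows) + 1L]] <- data.frame(
        chrom = loci$chrom[i], start = loci$start[i], end = loci$end[i],
        score = if (hi) runif(1, 0.85, 0.98) else runif(1, 0, 0.15),
        stringsAsFactors = FALSE)
    }
    for (b in 1:100) {
      ch <- sample(names(truth$genome), 1)
      s <- sample.int(spec$chrom_lengths[[ch]] - 200L, 1)
      rows[[length(rows) + 1L]] <- data.frame(
        chrom = ch, start = s, end = s + sample(50:200, 1),
        score = runif(1, 0, 0.15), stringsAsFactors = FALSE)
    }
    tr <- do.call(rbind, rows)
    tr[order(tr$chrom, tr$start), , drop = FALSE]
  })
}

#' Simulate a synthetic probe x sample expression matrix
#'
#' Supports the microarray differential-expression module: log-scale
#' intensities for two groups of replicates with a planted set of
#' differentially expressed probes.
#'
#' @param n_probes number of probes (default 500).
#' @param n_de number of DE probes (default 50; half induced, half repressed).
#' @param n_per_group replicates per group (default 3).
#' @param effect_log2 log2 effect size range for DE probes (default 0.6-1.6).
#' @param noise_sd replicate noise sd on the log2 scale (default 0.25).
#' @param seed RNG seed.
#' @return list with `mat` (log2 expression, probes x samples), `groups`,
#'   and `de_truth` (data frame: probe, is_de, direction).
#' @export
simulate_expression_matrix <- function(n_probes = 500L, n_de = 50L,
                                       n_per_group = 3L,
                                       effect_log2 = c(0.6, 1.6),
                                       noise_sd = 0.25, seed = 1L) {
  with_seed(seed, {
    base <- runif(n_probes, 6, 12)
    effect <- numeric(n_probes)
    de_idx <- sample.int(n_probes, n_de)
    up <- de_idx[seq_len(floor(n_de / 2))]
    dn <- setdiff(de_idx, up)
    effect[up] <- runif(length(up), effect_log2[1], effect_log2[2])
    effect[dn] <- -runif(length(dn), effect_log2[1], effect_log2[2])
    ns <- 2L * n_per_group
    groups <- rep(c("control", "treated"), each = n_per_group)
    mat <- matrix(rnorm(n_probes * ns, sd = noise_sd), n_probes, ns) + base
    mat[, groups == "treated"] <- mat[, groups == "treated"] + effect
    rownames(mat) <- sprintf("probe%d", seq_len(n_probes))
    colnames(mat) <- sprintf("%s_%d", groups, rep(seq_len(n_per_group), 2))
    list(mat = mat, groups = groups,
         de_truth = data.frame(probe = rownames(mat), is_de = effect != 0,
                               direction = ifelse(effect > 0, "induced",
                                           ifelse(effect < 0, "repressed", "none")),
                               stringsAsFactors = FALSE))
  })
}
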