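FEATURE_NAMES <- c("f1_pairs_in_cluster", "f2_pairs_in_precursor",
                   "f3_cluster_length", "f4_star_expression",
                   "f5_cluster_tag_count", "f6_mfe", "f7_norm_energy",
                   "f8_arm_unpaired_diff", "f9_conservation",
                   "f10_overhang_unpaired")

#' Read a per-base conservation track from bedGraph
#'
#' @param path bedGraph file (0-based half-open intervals, one score column).
#' @return data frame with columns `chrom`, `start`, `end`, `score`.
#' @export
read_conservation <- function(path) {
  gr <- as.data.frame(rtracklayer::import(path, format = "bedGraph"))
  data.frame(chrom = as.character(gr$seqnames), start = gr$start - 1L,
             end = gr$end, score = gr$score, stringsAsFactors = FALSE)
}

#' Mean per-base conservation over an interval
#'
#' Positions absent from the track score 0.
#'
#' @param track conservation data frame (as from [read_conservation()]), or
#'   NULL for an absent track (returns 0).
#' @param chrom,start,end interval (0-based half-open).
#' @return mean score over the interval.
#' @export
conservation_mean <- function(track, chrom, start, end) {
  if (is.null(track) || nrow(track) == 0 || end <= start) return(0)
  sub <- track[track$chrom == chrom, , drop = FALSE]
  if (nrow(sub) == 0) return(0)
  ol <- overlap_len(start, end, sub$start, sub$end)
  sum(ol * sub$score) / (end - start)
}

## arm decomposition of a (single-stem) structure: outermost paired positions
## o1/o2 and the innermost pair a/b of the first hairpin loop
stem_arms <- function(pt) {
  paired <- which(pt > 0)
  if (length(paired) == 0) return(NULL)
  o1 <- min(paired); o2 <- max(paired)
  opens <- which(pt > seq_along(pt))
  a <- max(opens); b <- pt[a]
  list(o1 = o1, o2 = o2, loop5 = a, loop3 = b)
}

#' Compute the ten molecular features for one candidate precursor
#'
#' Features: (f1) paired positions within the read cluster; (f2) base pairs in
#' the whole precursor structure; (f3) cluster length; (f4) mature-star
#' expression — summed counts of reads falling entirely within the cluster's
#' pairing-partner interval (2-nt 3' overhang geometry) widened by
#' `star_tolerance` nt; (f5) total tag count in the cluster; (f6) minimum free
#' energy; (f7) normalized energy, MFE divided by precursor length; (f8)
#' absolute difference in unpaired nucleotides between the two stem arms;
#' (f9) mean per-base conservation over the cluster; (f10) unpaired
#' nucleotides outside the outermost base pair (the overhang region).
#'
#' @param candidate one row of a folded candidate table (see
#'   [fold_precursors()]).
#' @param s the candidate's `rna_structure`.
#' @param genome_hits genome hit table used to look up star-arm expression.
#' @param cons conservation track data frame or NULL.
#' @param star_tolerance widening of the star interval in nt (default 3),
#'   allowing for Drosha/Dicer processing heterogeneity.
#' @return named numeric vector of the ten features.
#' @export
compute_features <- function(candidate, s, genome_hits = NULL, cons = NULL,
                             star_tolerance = 3L) {
  if (is.null(s)) stop("missing structure for candidate ", candidate$candidate_id)
  pt <- s$pair_table
  n <- length(pt)
  cpos <- (candidate$cluster_off_start + 1L):candidate$cluster_off_end
  cpos <- cpos[cpos >= 1 & cpos <= n]
  f1 <- sum(pt[cpos] > 0)
  f2 <- sum(pt > 0) %/% 2L
  f3 <- candidate$cluster_end - candidate$cluster_start
  f5 <- candidate$total_count
  f6 <- s$mfe
  f7 <- s$mfe / n
  arms <- stem_arms(pt)
  if (is.null(arms)) {
    f8 <- 0; f10 <- 0
  } else {
    up5 <- sum(pt[arms$o1:arms$loop5] == 0)
    up3 <- sum(pt[arms$loop3:arms$o2] == 0)
    f8 <- abs(up5 - up3)
    f10 <- (arms$o1 - 1L) + (n - arms$o2)
  }
  ## f4: star expression on the partner interval of the cluster
  f4 <- 0
  iv <- star_interval_from_pt(pt, min(cpos), max(cpos))
  if (!is.null(iv) && !is.null(genome_hits) && nrow(genome_hits) > 0) {
    ## map strand-oriented window coordinates to the genome
    if (candidate$strand == "+") {
      gs <- candidate$start + iv[1] - 1L
      ge <- candidate$start + iv[2]
    } else {
      gs <- candidate$end - iv[2]
      ge <- candidate$end - iv[1] + 1L
    }
    gs <- gs - star_tolerance
    ge <- ge + star_tolerance
    sub <- genome_hits[genome_hits$ref_id == candidate$chrom &
                       genome_hits$strand == candidate$strand &
                       genome_hits$start >= gs & genome_hits$end <= ge, , drop = FALSE]
    f4 <- sum(sub$count)
  }
  f9 <- conservation_mean(cons, candidate$chrom, candidate$cluster_start,
                          candidate$cluster_end)
  setNames(c(f1, f2, f3, f4, f5, f6, f7, f8, f9, f10), FEATURE_NAMES)
}

#' Build the labeled feature matrix for a set of candidates
#'
#' @param candidates folded candidate table ([fold_precursors()]), normally
#'   restricted to filter-passing rows.
#' @param genome_hits genome hit table for star-expression lookup.
#' @param cons conservation track or NULL (feature f9 defaults to 0).
#' @param label label to attach ("positive", "negative", "test", or NA).
#' @param star_tolerance see [compute_features()].
#' @return data frame: `candidate_id`, the ten feature columns in fixed
#'   order, and `label`.
#' @export
feature_matrix <- function(candidates, genome_hits = NULL, cons = NULL,
                           label = NA_character_, star_tolerance = 3L) {
  if (anyDuplicated(candidates$candidate_id)) stop("duplicated candidate ids")
  n <- nrow(candidates)
  m <- matrix(0, nrow = n, ncol = length(FEATURE_NAMES),
              dimnames = list(NULL, FEATURE_NAMES))
  for (i in seq_len(n)) {
    m[i, ] <- compute_features(candidates[i, ], candidates$structure[[i]],
                               genome_hits, cons, star_tolerance)
  }
  out <- data.frame(candidate_id = candidates$candidate_id, m,
                    stringsAsFactors = FALSE, check.names = FALSE)
  out$label <- rep(label, length.out = n)
  rownames(out) <- NULL
  out
}
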