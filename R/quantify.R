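#' Quantify locus expression as reads per million
#'
#' Raw counts sum the collapsed counts of all reads aligned at the locus
#' (same strand, at least `min_overlap_frac` of the read overlapping the
#' locus interval); multi-mapped reads contribute their full count at every
#' alignment unless `fractional = TRUE`, which down-weights each hit by the
#' read's number of retained alignments. For the stringent signal
#' calculation the hits should come from `align_params(stringent = TRUE)`
#' (at most 3 alignments, 1 seed mismatch).
#'
#' @param loci data frame with `chrom`, `start`, `end`, `strand` (0-based
#'   half-open) and optionally `locus_id`.
#' @param hits genome hit table carrying `count`.
#' @param total_aligned total aligned read count for the sample (RPM
#'   denominator); must be positive.
#' @param min_overlap_frac minimum fraction of the read overlapping the locus
#'   (default 0.5).
#' @param fractional divide each hit's count by the read's alignment
#'   multiplicity (default FALSE).
#' @param sample sample name stored in the output.
#' @return data frame: `locus_id`, `chrom`, `start`, `end`, `strand`,
#'   `raw_count`, `rpm`, `sample`.
#' @export
quantify_loci <- function(loci, hits, total_aligned, min_overlap_frac = 0.5,
                          fractional = FALSE, sample = NA_character_) {
  if (total_aligned <= 0) stop("total_aligned must be positive")
  w <- if (nrow(hits) == 0) numeric(0) else hits$count
  if (fractional && nrow(hits) > 0) {
    mult <- table(hits$read_sequence)
    w <- hits$count / as.integer(mult[hits$read_sequence])
  }
  ids <- loci$locus_id %||%
    sprintf("%s:%d-%d:%s", loci$chrom, loci$start, loci$end, loci$strand)
  raw <- vapply(seq_len(nrow(loci)), function(i) {
    if (nrow(hits) == 0) return(0)
    sel <- hits$ref_id == loci$chrom[i] & hits$strand == loci$strand[i]
    if (!any(sel)) return(0)
    h <- hits[sel, , drop = FALSE]
    ol <- overlap_len(loci$start[i], loci$end[i], h$start, h$end)
    keep <- ol >= min_overlap_frac * (h$end - h$start)
    sum(w[sel][keep])
  }, 0)
  data.frame(locus_id = ids, chrom = loci$chrom, start = loci$start,
             end = loci$end, strand = loci$strand, raw_count = raw,
             rpm = raw / total_aligned * 1e6, sample = sample,
             stringsAsFactors = FALSE)
}

#' Call induced/repressed direction between conditions
#'
#' The ratio is treated/control RPM: above 1 is induced, below 1 repressed,
#' exactly 1 unchanged. Loci with zero control signal but positive treated
#' signal are reported as `undefined` (the ratio is not computable); loci
#' silent in both samples are reported unchanged.
#'
#' @param treated,control expression tables from [quantify_loci()], matched
#'   row-for-row on the same loci.
#' @return data frame: locus columns plus `rpm_treated`, `rpm_control`,
#'   `ratio`, `direction`.
#' @export
call_direction <- function(treated, control) {
  stopifnot(nrow(treated) == nrow(control),
            all(treated$locus_id == control$locus_id))
  ratio <- ifelse(control$rpm > 0, treated$rpm / control$rpm, NA_real_)
  direction <- rep("unchanged", nrow(treated))
  direction[!is.na(ratio) & ratio > 1] <- "induced"
  direction[!is.na(ratio) & ratio < 1] <- "repressed"
  direction[control$rpm == 0 & treated$rpm > 0] <- "undefined"
  data.frame(locus_id = treated$locus_id, chrom = treated$chrom,
             start = treated$start, end = treated$end,
             strand = treated$strand, rpm_treated = treated$rpm,
             rpm_control = control$rpm, ratio = ratio,
             direction = direction, stringsAsFactors = FALSE)
}

#' Percent-control signal
#'
#' @param treated,control RPM values (or matched expression records).
#' @return `100 * treated / control`.
#' @export
percent_control <- function(treated, control) {
  t <- if (is.data.frame(treated)) treated$rpm else treated
  c_ <- if (is.data.frame(control)) control$rpm else control
  if (any(c_ <= 0)) stop("control signal must be positive for percent control")
  100 * t / c_
}
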