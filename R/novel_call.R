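#' Post-prediction call filter configuration
#'
#' @param mfe_max maximum (least negative) allowed minimum free energy in
#'   kcal/mol; candidates with MFE strictly greater than this are discarded
#'   (default -25, so exactly -25 is retained).
#' @param excluded_chrom_patterns glob patterns of chromosomes whose calls
#'   are discarded (default unplaced/random assemblies: `chrUn*`, `*_random`).
#' @return an object of class `call_filter_config`.
#' @export
call_filter_config <- function(mfe_max = -25,
                               excluded_chrom_patterns = c("chrUn*", "*_random")) {
  stopifnot(mfe_max < 0)
  structure(list(mfe_max = mfe_max,
                 excluded_chrom_patterns = excluded_chrom_patterns),
            class = "call_filter_config")
}

chrom_excluded <- function(chrom, patterns) {
  if (length(patterns) == 0) return(rep(FALSE, length(chrom)))
  hit <- rep(FALSE, length(chrom))
  for (p in patterns) hit <- hit | grepl(utils::glob2rx(p), chrom)
  hit
}

#' Convert positive classifications into novel miRNA calls
#'
#' Candidates predicted positive are discarded when they localize to an
#' excluded chromosome or when their MFE exceeds (is greater than) `mfe_max`.
#' Each surviving candidate yields one call whose mature sequence is the
#' parent cluster sequence and whose locus is the cluster interval.
#'
#' @param predicted candidate table (rows predicted positive) carrying
#'   `chrom`, `strand`, `cluster_start`, `cluster_end`, `cluster_sequence`,
#'   `total_count`, `mfe` and `vote_fraction`.
#' @param cfg a [call_filter_config()].
#' @return call table: `chrom`, `start`, `end`, `strand`,
#'   `mature_sequence`, `mfe`, `vote_fraction`, `total_count`,
#'   `n_candidates`.
#' @export
postfilter <- function(predicted, cfg = call_filter_config()) {
  keep <- !chrom_excluded(predicted$chrom, cfg$excluded_chrom_patterns) &
    predicted$mfe <= cfg$mfe_max
  p <- predicted[keep, , drop = FALSE]
  out <- data.frame(chrom = p$chrom, start = p$cluster_start,
                    end = p$cluster_end, strand = p$strand,
                    mature_sequence = p$cluster_sequence, mfe = p$mfe,
                    vote_fraction = p$vote_fraction,
                    total_count = p$total_count,
                    n_candidates = rep(1L, nrow(p)),
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

#' Merge overlapping novel miRNA calls
#'
#' Same-strand calls with overlapping coordinates are replaced by a single
#' call spanning their union; the merged call keeps the best (lowest) MFE,
#' the maximum vote fraction, and the mature sequence of the
#' highest-total-count source cluster. Merging is idempotent and
#' order-invariant, and no two emitted calls overlap on the same strand.
#'
#' @param calls call table from [postfilter()].
#' @return merged call table sorted by (chrom, start, strand).
#' @export
merge_overlapping <- function(calls) {
  if (nrow(calls) == 0) return(calls)
  out <- list()
  for (key in unique(paste(calls$chrom, calls$strand, sep = "\r"))) {
    parts <- strsplit(key, "\r", fixed = TRUE)[[1]]
    sub <- calls[calls$chrom == parts[1] & calls$strand == parts[2], , drop = FALSE]
    ir <- IRanges::IRanges(start = sub$start + 1L, end = sub$end)
    red <- IRanges::reduce(ir)
    grp <- S4Vectors::subjectHits(IRanges::findOverlaps(ir, red))
    for (g in seq_along(red)) {
      mem <- sub[grp == g, , drop = FALSE]
      best <- mem[order(-mem$total_count, mem$start), , drop = FALSE][1, ]
      out[[length(out) + 1L]] <- data.frame(
        chrom = parts[1], start = IRanges::start(red)[g] - 1L,
        end = IRanges::end(red)[g], strand = parts[2],
        mature_sequence = best$mature_sequence, mfe = min(mem$mfe),
        vote_fraction = max(mem$vote_fraction),
        total_count = best$total_count,
        n_candidates = sum(mem$n_candidates),
        stringsAsFactors = FALSE)
    }
  }
  res <- do.call(rbind, out)
  res <- res[order(res$chrom, res$start, res$strand), , drop = FALSE]
  rownames(res) <- NULL
  res
}

#' Compare novel miRNA call sets between two conditions
#'
#' Loci are compared by same-strand coordinate overlap on the merged union of
#' both call sets; the partition into condition-unique and common loci is
#' exhaustive and disjoint.
#'
#' @param calls_a,calls_b merged call tables from the two conditions.
#' @return list with counts `unique_a`, `unique_b`, `common` and `loci`, the
#'   merged union loci annotated with `in_a`/`in_b`.
#' @export
compare_conditions <- function(calls_a, calls_b) {
  cols <- c("chrom", "start", "end", "strand", "mature_sequence", "mfe",
            "vote_fraction", "total_count", "n_candidates")
  u <- merge_overlapping(rbind(calls_a[, cols], calls_b[, cols]))
  flag <- function(set) {
    if (nrow(set) == 0) return(rep(FALSE, nrow(u)))
    vapply(seq_len(nrow(u)), function(i) {
      s <- set[set$chrom == u$chrom[i] & set$strand == u$strand[i], , drop = FALSE]
      nrow(s) > 0 && any(overlap_len(u$start[i], u$end[i], s$start, s$end) > 0)
    }, TRUE)
  }
  u$in_a <- flag(calls_a)
  u$in_b <- flag(calls_b)
  list(unique_a = sum(u$in_a & !u$in_b),
       unique_b = sum(u$in_b & !u$in_a),
       common = sum(u$in_a & u$in_b),
       loci = u)
}

#' Write a call catalog as BED6 plus mature FASTA
#'
#' BED scores encode `1000 * vote_fraction`.
#'
#' @param calls merged call table.
#' @param prefix output path prefix; writes `<prefix>.bed` and `<prefix>.fa`.
#' @export
write_call_catalog <- function(calls, prefix) {
  ids <- sprintf("novel_mir_%d", seq_len(nrow(calls)))
  bed <- data.frame(calls$chrom, calls$start, calls$end, ids,
                    round(1000 * calls$vote_fraction), calls$strand)
  write.table(bed, paste0(prefix, ".bed"), quote = FALSE, sep = "\t",
              row.names = FALSE, col.names = FALSE)
  write_fasta(setNames(calls$mature_sequence, ids), paste0(prefix, ".fa"))
  invisible(prefix)
}
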