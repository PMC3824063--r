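#' Cluster and precursor-window configuration
#'
#' @param min_span,max_span allowed cluster span (union interval length) in
#'   nt; clusters outside 20-27 nt are treated as non-miRNA-like and dropped.
#' @param min_test_count minimum raw read count for test-set clusters
#'   (default 11); training clusters are not expression-filtered.
#' @param window_flanks list of (upstream, downstream) flank pairs in nt used
#'   to expand a cluster into candidate precursor windows; the defaults place
#'   the cluster on the 5' arm, centre, or 3' arm of a ~110-115 nt window.
#' @param min_window minimum window length after truncation at chromosome
#'   edges (default 60 nt); shorter candidates are dropped.
#' @return an object of class `cluster_config`.
#' @export
cluster_config <- function(min_span = 20L, max_span = 27L, min_test_count = 11L,
                           window_flanks = list(c(70L, 20L), c(45L, 45L), c(20L, 70L)),
                           min_window = 60L) {
  stopifnot(min_span <= max_span,
            all(vapply(window_flanks, function(f) length(f) == 2 && all(f > 0), TRUE)))
  structure(list(min_span = as.integer(min_span), max_span = as.integer(max_span),
                 min_test_count = as.integer(min_test_count),
                 window_flanks = lapply(window_flanks, as.integer),
                 min_window = as.integer(min_window)),
            class = "cluster_config")
}

#' Group overlapping genome hits into read clusters
#'
#' Clusters are maximal connected components of interval overlap per
#' (chromosome, strand); the cluster interval is the union of its members.
#' Clusters whose span falls outside `[min_span, max_span]` are discarded.
#'
#' @param hits genome hit table from [align_reads()] (must carry `count`).
#' @param cfg a [cluster_config()].
#' @return data frame with columns `cluster_id`, `chrom`, `start`, `end`
#'   (0-based half-open), `strand`, `span`, `total_count` and a list-column
#'   `members` holding each cluster's member hits; sorted by
#'   (chrom, start, strand).
#' @export
build_clusters <- function(hits, cfg = cluster_config()) {
  empty <- data.frame(cluster_id = character(0), chrom = character(0),
                      start = integer(0), end = integer(0), strand = character(0),
                      span = integer(0), total_count = integer(0),
                      stringsAsFactors = FALSE)
  empty$members <- list()
  if (nrow(hits) == 0) return(empty)
  out <- list()
  for (key in unique(paste(hits$ref_id, hits$strand, sep = "\r"))) {
    parts <- strsplit(key, "\r", fixed = TRUE)[[1]]
    sub <- hits[hits$ref_id == parts[1] & hits$strand == parts[2], , drop = FALSE]
    ir <- IRanges::IRanges(start = sub$start + 1L, end = sub$end)
    red <- IRanges::reduce(ir)
    ov <- IRanges::findOverlaps(ir, red)
    grp <- S4Vectors::subjectHits(ov)[order(S4Vectors::queryHits(ov))]
    for (g in seq_along(red)) {
      mem <- sub[grp == g, , drop = FALSE]
      st <- IRanges::start(red)[g] - 1L
      en <- IRanges::end(red)[g]
      out[[length(out) + 1L]] <- data.frame(
        cluster_id = sprintf("%s:%d-%d:%s", parts[1], st, en, parts[2]),
        chrom = parts[1], start = st, end = en, strand = parts[2],
        span = en - st, total_count = sum(mem$count),
        stringsAsFactors = FALSE)
      out[[length(out)]]$members <- list(mem)
    }
  }
  cl <- do.call(rbind, out)
  drop <- cl$span < cfg$min_span | cl$span > cfg$max_span
  if (any(drop)) {
    message(sum(drop), " cluster(s) with span outside [", cfg$min_span, ",",
            cfg$max_span, "] nt discarded")
    cl <- cl[!drop, , drop = FALSE]
  }
  cl <- cl[order(cl$chrom, cl$start, cl$strand), , drop = FALSE]
  rownames(cl) <- NULL
  cl
}

#' Expression-filter test-set clusters
#'
#' Test clusters with raw read count below `min_test_count` (default 11) are
#' removed so that only moderately-to-highly expressed loci are classified;
#' training clusters pass through this function unfiltered by convention
#' (simply do not call it on them).
#'
#' @param clusters cluster table from [build_clusters()].
#' @param cfg a [cluster_config()].
#' @return filtered cluster table.
#' @export
filter_test_clusters <- function(clusters, cfg = cluster_config()) {
  clusters[clusters$total_count >= cfg$min_test_count, , drop = FALSE]
}

#' Expand clusters into candidate precursor windows
#'
#' One candidate per configured flank pair: the window covers the cluster plus
#' `up` nt of strand-upstream and `down` nt of strand-downstream flank.
#' Window sequences are strand-oriented (reverse-complemented for minus-strand
#' clusters). Windows are truncated at chromosome edges and dropped when
#' shorter than `min_window` nt.
#'
#' @param clusters cluster table from [build_clusters()].
#' @param genome named character vector of chromosome sequences.
#' @param cfg a [cluster_config()].
#' @return data frame of candidates: `candidate_id`, `cluster_id`, `chrom`,
#'   `start`, `end`, `strand`, `flank_up`, `flank_down`, `window_sequence`,
#'   `cluster_off_start`, `cluster_off_end` (0-based cluster interval in
#'   strand-oriented window coordinates), `cluster_start`, `cluster_end`,
#'   `cluster_sequence` (strand-oriented), `total_count`.
#' @export
generate_precursors <- function(clusters, genome, cfg = cluster_config()) {
  rows <- list()
  for (i in seq_len(nrow(clusters))) {
    cl <- clusters[i, ]
    if (!cl$chrom %in% names(genome)) stop("chromosome missing from genome: ", cl$chrom)
    chrom_len <- nchar(genome[[cl$chrom]])
    if (cl$end > chrom_len) stop("cluster beyond chromosome end: ", cl$cluster_id)
    cseq <- substr(genome[[cl$chrom]], cl$start + 1L, cl$end)
    if (cl$strand == "-") cseq <- revcomp(cseq)
    for (fl in cfg$window_flanks) {
      up <- fl[1]; down <- fl[2]
      if (cl$strand == "+") {
        ws <- max(0L, cl$start - up); we <- min(chrom_len, cl$end + down)
      } else {
        ws <- max(0L, cl$start - down); we <- min(chrom_len, cl$end + up)
      }
      if (we - ws < cfg$min_window) next
      wseq <- substr(genome[[cl$chrom]], ws + 1L, we)
      if (cl$strand == "-") wseq <- revcomp(wseq)
      off_start <- if (cl$strand == "+") cl$start - ws else we - cl$end
      rows[[length(rows) + 1L]] <- data.frame(
        candidate_id = sprintf("%s:f%d_%d", cl$cluster_id, up, down),
        cluster_id = cl$cluster_id, chrom = cl$chrom,
        start = ws, end = we, strand = cl$strand,
        flank_up = up, flank_down = down,
        window_sequence = wseq,
        cluster_off_start = off_start,
        cluster_off_end = off_start + cl$span,
        cluster_start = cl$start, cluster_end = cl$end,
        cluster_sequence = cseq, total_count = cl$total_count,
        stringsAsFactors = FALSE)
    }
  }
  if (length(rows) == 0) {
    return(data.frame(candidate_id = character(0), cluster_id = character(0),
                      chrom = character(0), start = integer(0), end = integer(0),
                      strand = character(0), flank_up = integer(0),
                      flank_down = integer(0), window_sequence = character(0),
                      cluster_off_start = integer(0), cluster_off_end = integer(0),
                      cluster_start = integer(0), cluster_end = integer(0),
                      cluster_sequence = character(0), total_count = integer(0),
                      stringsAsFactors = FALSE))
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Strand-aware overlap of candidates with known miRNA loci
#'
#' Used to vet the positive training set: a candidate qualifies as a true
#' positive only when its genomic window overlaps a known miRNA locus on the
#' same strand.
#'
#' @param candidates candidate table from [generate_precursors()] (or any
#'   data frame with `chrom`, `start`, `end`, `strand`).
#' @param known_loci data frame with `chrom`, `start`, `end`, `strand`
#'   (0-based half-open).
#' @return logical vector, one element per candidate.
#' @export
label_positive <- function(candidates, known_loci) {
  if (nrow(candidates) == 0) return(logical(0))
  if (is.null(known_loci) || nrow(known_loci) == 0) return(rep(FALSE, nrow(candidates)))
  vapply(seq_len(nrow(candidates)), function(i) {
    k <- known_loci[known_loci$chrom == candidates$chrom[i] &
                    known_loci$strand == candidates$strand[i], , drop = FALSE]
    if (nrow(k) == 0) return(FALSE)
    any(overlap_len(candidates$start[i], candidates$end[i], k$start, k$end) > 0)
  }, TRUE)
}
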