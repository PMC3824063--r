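#' Alignment parameters
#'
#' Seed-restricted mismatch semantics: mismatches are counted and capped only
#' within the first `seed_length` bases of the read (read orientation); the
#' trailing bases may mismatch freely. Only best-stratum hits (minimum seed
#' mismatch count among all valid hits for the read) are kept, and a read with
#' more than `max_alignments` best-stratum hits is suppressed entirely as an
#' ambiguous repetitive mapper.
#'
#' @param seed_length seed length in nt (default 17).
#' @param max_seed_mismatches maximum mismatches tolerated in the seed
#'   (default 2).
#' @param max_alignments maximum number of retained alignments per read
#'   (default 6); more hits suppress the read.
#' @param stringent logical; TRUE switches to the stringent quantification
#'   criteria (at most 3 alignments, at most 1 seed mismatch).
#' @return an object of class `align_params`.
#' @export
align_params <- function(seed_length = 17L, max_seed_mismatches = 2L,
                         max_alignments = 6L, stringent = FALSE) {
  if (isTRUE(stringent)) {
    max_seed_mismatches <- 1L
    max_alignments <- 3L
  }
  seed_length <- as.integer(seed_length)
  stopifnot(seed_length >= 1L, max_seed_mismatches >= 0L, max_alignments >= 1L)
  structure(list(seed_length = seed_length,
                 max_seed_mismatches = as.integer(max_seed_mismatches),
                 max_alignments = as.integer(max_alignments),
                 stringent = isTRUE(stringent)),
            class = "align_params")
}

#' Create a reference tier
#'
#' @param name one of "mature", "star", "star_unobserved", "hairpin",
#'   "refseq_mrna", "rfam", "genome".
#' @param sequences named character vector of reference sequences (uppercase
#'   ACGT, N allowed; N never matches).
#' @return an object of class `reference_tier`.
#' @export
reference_tier <- function(name, sequences) {
  name <- match.arg(name, c("mature", "star", "star_unobserved", "hairpin",
                            "refseq_mrna", "rfam", "genome"))
  sequences <- toupper(unlist(sequences))
  if (length(sequences) > 0 && is.null(names(sequences))) {
    names(sequences) <- paste0(name, "_", seq_along(sequences))
  }
  structure(list(name = name, sequences = sequences), class = "reference_tier")
}

## Build a search index: all reference sequences concatenated with N spacers
## (N counts as a mismatch so nothing aligns across a boundary undetected;
## boundary-crossing candidates are discarded explicitly below).
build_subject_index <- function(sequences, spacer = 25L) {
  stopifnot(length(sequences) > 0)
  lens <- nchar(sequences)
  gaps <- strrep("N", spacer)
  concat <- paste(sequences, collapse = gaps)
  offs <- cumsum(c(0L, head(lens + spacer, -1L)))  # 0-based start of each ref
  list(subject = Biostrings::DNAString(concat),
       ref_id = names(sequences), offset = offs, len = lens)
}

as_ref_sequences <- function(ref) {
  if (inherits(ref, "reference_tier")) ref$sequences
  else if (is.character(ref)) toupper(ref)
  else stop("reference must be a reference_tier or a named character vector")
}

## Core scan of one read against an index. Returns the full hit table
## (pre-strata): candidate positions found by seed matching on both strands,
## validated to lie entirely within one reference sequence.
scan_read <- function(read_seq, idx, params) {
  rl <- nchar(read_seq)
  sl <- params$seed_length
  mm <- params$max_seed_mismatches
  hits <- list()
  collect <- function(starts, strand, seed_pat, query_pat, qoff) {
    ## starts: subject positions (1-based) of the seed match; qoff = offset of
    ## the full query start relative to the seed match start
    if (length(starts) == 0) return(NULL)
    full_start <- starts - qoff
    keep <- full_start >= 1 & (full_start + rl - 1L) <= length(idx$subject)
    starts <- starts[keep]; full_start <- full_start[keep]
    if (length(starts) == 0) return(NULL)
    ridx <- findInterval(full_start - 1L, idx$offset)
    inside <- (full_start - 1L) >= idx$offset[ridx] &
      (full_start - 1L + rl) <= (idx$offset[ridx] + idx$len[ridx])
    starts <- starts[inside]; full_start <- full_start[inside]; ridx <- ridx[inside]
    if (length(starts) == 0) return(NULL)
    seed_mm <- Biostrings::neditStartingAt(seed_pat, idx$subject,
                                           starting.at = starts,
                                           with.indels = FALSE)
    tot_mm <- Biostrings::neditStartingAt(query_pat, idx$subject,
                                          starting.at = full_start,
                                          with.indels = FALSE)
    data.frame(
      read_sequence = read_seq,
      ref_id = idx$ref_id[ridx],
      start = full_start - 1L - idx$offset[ridx],
      end = full_start - 1L - idx$offset[ridx] + rl,
      strand = strand,
      seed_mismatches = as.integer(seed_mm),
      total_mismatches = as.integer(tot_mm),
      stringsAsFactors = FALSE
    )
  }
  ## plus strand: seed is the first sl bases of the read
  q_fwd <- Biostrings::DNAString(read_seq)
  seed_fwd <- Biostrings::subseq(q_fwd, 1L, sl)
  st_fwd <- Biostrings::start(Biostrings::matchPattern(
    seed_fwd, idx$subject, max.mismatch = mm, with.indels = FALSE))
  hits$fwd <- collect(st_fwd, "+", seed_fwd, q_fwd, 0L)
  ## minus strand: search the reverse complement of the read on the forward
  ## reference; the read's 5' seed occupies the *last* sl bases of the query
  q_rev <- Biostrings::reverseComplement(q_fwd)
  seed_rev <- Biostrings::subseq(q_rev, rl - sl + 1L, rl)
  st_rev <- Biostrings::start(Biostrings::matchPattern(
    seed_rev, idx$subject, max.mismatch = mm, with.indels = FALSE))
  hits$rev <- collect(st_rev, "-", seed_rev, q_rev, rl - sl)
  out <- do.call(rbind, hits[!vapply(hits, is.null, TRUE)])
  if (is.null(out)) empty_hits() else out
}

## apply best-stratum retention and the multi-mapper cap
apply_strata <- function(hits, params) {
  if (nrow(hits) == 0) return(hits)
  hits <- hits[hits$seed_mismatches <= params$max_seed_mismatches, , drop = FALSE]
  if (nrow(hits) == 0) return(hits)
  ## duplicates can arise when forward and reverse seed scans land on the
  ## same locus (palindromes); keep one record per (ref,start,strand)
  hits <- hits[!duplicated(hits[, c("ref_id", "start", "strand")]), , drop = FALSE]
  best <- min(hits$seed_mismatches)
  hits <- hits[hits$seed_mismatches == best, , drop = FALSE]
  if (nrow(hits) > params$max_alignments) {
    out <- empty_hits()
    attr(out, "suppressed") <- TRUE
    return(out)
  }
  hits <- hits[order(hits$ref_id, hits$start, hits$strand), , drop = FALSE]
  rownames(hits) <- NULL
  attr(hits, "suppressed") <- FALSE
  hits
}

#' Align one read against a reference
#'
#' Searches both strands for full-length hits whose seed (first
#' `seed_length` read bases) carries at most `max_seed_mismatches`
#' mismatches; mismatches outside the seed are unrestricted. Only the best
#' stratum (minimum seed mismatches) is returned, capped at
#' `max_alignments` hits — beyond the cap the read is suppressed (zero rows,
#' attribute `suppressed = TRUE`).
#'
#' @param read_seq a single read sequence (length >= `seed_length`).
#' @param ref a [reference_tier()] or named character vector (e.g. a genome).
#' @param params an [align_params()].
#' @return data frame of hits with 0-based half-open coordinates:
#'   `read_sequence`, `ref_id`, `start`, `end`, `strand`, `seed_mismatches`,
#'   `total_mismatches`.
#' @export
align_read <- function(read_seq, ref, params = align_params()) {
  stopifnot_scalar_chr(read_seq, "read_seq")
  if (nchar(read_seq) < params$seed_length) {
    warning("read shorter than seed length; no alignment attempted")
    return(empty_hits())
  }
  idx <- build_subject_index(as_ref_sequences(ref))
  apply_strata(scan_read(toupper(read_seq), idx, params), params)
}

#' Align a set of collapsed reads against a reference
#'
#' @param collapsed data frame with columns `sequence` and `count`
#'   (see [collapse_reads()]).
#' @param ref a [reference_tier()] or named character vector.
#' @param params an [align_params()].
#' @return data frame of hits as in [align_read()] with an added `count`
#'   column; suppressed and unaligned reads contribute no rows. The attribute
#'   `aligned_sequences` lists sequences with >= 1 retained hit and
#'   `suppressed_sequences` those removed by the multi-mapper cap.
#' @export
align_reads <- function(collapsed, ref, params = align_params()) {
  idx <- build_subject_index(as_ref_sequences(ref))
  res <- vector("list", nrow(collapsed))
  suppressed <- logical(nrow(collapsed))
  for (i in seq_len(nrow(collapsed))) {
    s <- collapsed$sequence[i]
    if (nchar(s) < params$seed_length) next
    h <- apply_strata(scan_read(s, idx, params), params)
    suppressed[i] <- isTRUE(attr(h, "suppressed"))
    if (nrow(h) > 0) {
      h$count <- collapsed$count[i]
      res[[i]] <- h
    }
  }
  keep <- !vapply(res, is.null, TRUE)
  out <- if (any(keep)) do.call(rbind, res[keep]) else cbind(empty_hits(), count = integer(0))
  rownames(out) <- NULL
  attr(out, "aligned_sequences") <- unique(out$read_sequence)
  attr(out, "suppressed_sequences") <- collapsed$sequence[suppressed]
  out
}

#' Sequentially assign reads to annotation tiers
#'
#' Reads are tested against each tier in order; a read is removed from the
#' candidate pool at the first tier where it aligns (or where it is
#' suppressed as a multi-mapper). Reads whose first alignment is the final
#' genome tier form the "test" pool; reads aligning nowhere are flagged
#' unaligned.
#'
#' @param collapsed data frame of collapsed reads.
#' @param tiers ordered list of [reference_tier()] objects, ending with the
#'   genome tier.
#' @param params an [align_params()].
#' @return list with `assignment` (data frame: `sequence`, `count`, `tier`,
#'   `suppressed`) and `tier_hits` (named list of hit tables per tier).
#' @export
assign_tiers <- function(collapsed, tiers, params = align_params()) {
  if (length(tiers) == 0) stop("empty tier list")
  tier_names <- vapply(tiers, function(t) t$name, "")
  if (anyDuplicated(tier_names)) stop("tier names must be unique")
  if (tier_names[length(tier_names)] != "genome") {
    stop("the final tier must be the genome")
  }
  assignment <- data.frame(sequence = collapsed$sequence,
                           count = collapsed$count,
                           tier = NA_character_, suppressed = FALSE,
                           stringsAsFactors = FALSE)
  tier_hits <- setNames(vector("list", length(tiers)), tier_names)
  pool <- collapsed
  for (t in seq_along(tiers)) {
    if (nrow(pool) == 0) {
      tier_hits[[t]] <- cbind(empty_hits(), count = integer(0))
      next
    }
    if (length(tiers[[t]]$sequences) == 0) {
      tier_hits[[t]] <- cbind(empty_hits(), count = integer(0))
      next
    }
    h <- align_reads(pool, tiers[[t]], params)
    tier_hits[[t]] <- h
    hit_seqs <- attr(h, "aligned_sequences")
    sup_seqs <- attr(h, "suppressed_sequences")
    assignment$tier[assignment$sequence %in% c(hit_seqs, sup_seqs)] <- tier_names[t]
    assignment$suppressed[assignment$sequence %in% sup_seqs] <- TRUE
    pool <- pool[!(pool$sequence %in% c(hit_seqs, sup_seqs)), , drop = FALSE]
  }
  assignment$tier[is.na(assignment$tier)] <- "unaligned"
  list(assignment = assignment, tier_hits = tier_hits)
}

## Star interval from a pair table: partner positions of the mature interval
## shifted by the canonical 2-nt 3' overhang of the Dicer duplex. Returns
## c(start, end) 1-based inclusive in the folded sequence, or NULL when fewer
## than half of the mature bases are paired.
star_interval_from_pt <- function(pt, m_start, m_end) {
  n <- length(pt)
  pos <- m_start:m_end
  partners <- pt[pos]
  paired <- partners > 0
  if (mean(paired) < 0.5) return(NULL)
  partners <- partners[paired]
  on_5p_arm <- mean(partners > pos[paired]) >= 0.5
  raw <- range(partners)
  shift <- if (on_5p_arm) 2L else -2L
  c(max(1L, raw[1] + shift), min(n, raw[2] + shift))
}

#' Derive the unobserved mature-star sequence from a hairpin
#'
#' Folds the hairpin, looks up the stem positions pairing with the mature
#' interval and applies the canonical Dicer duplex geometry (2-nt 3'
#' overhangs) to obtain the star sequence on the opposite arm.
#'
#' @param hairpin hairpin precursor sequence.
#' @param mature_start 1-based start of the mature sequence in the hairpin.
#' @param mature_len mature length in nt.
#' @param fold_fun folding function; defaults to [fold_rna()].
#' @return the star sequence, or `""` when fewer than 50% of mature bases are
#'   paired (e.g. a mature placed in the terminal loop).
#' @export
derive_unobserved_star <- function(hairpin, mature_start, mature_len,
                                   fold_fun = fold_rna) {
  m_end <- mature_start + mature_len - 1L
  if (mature_start < 1L || m_end > nchar(hairpin)) {
    stop("mature interval outside hairpin")
  }
  s <- fold_fun(hairpin)
  iv <- star_interval_from_pt(s$pair_table, mature_start, m_end)
  if (is.null(iv)) return("")
  substr(hairpin, iv[1], iv[2])
}
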