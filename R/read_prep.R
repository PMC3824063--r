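#' Read preparation configuration
#'
#' Small-RNA reads are trimmed from the 3' end to a uniform length before any
#' alignment, which removes adapter read-through without needing the adapter
#' sequence itself. Reads shorter than the trim length carry no mature-miRNA
#' signal at this scale and are dropped rather than padded.
#'
#' @param trim_length target read length in nt (default 20, minimum 15).
#' @param drop_short drop reads shorter than `trim_length` (default TRUE).
#' @param drop_with_n drop reads containing N (default TRUE); downstream
#'   alignment treats N as a mismatch everywhere, so such reads only add noise.
#' @return an object of class `prep_config`.
#' @export
prep_config <- function(trim_length = 20L, drop_short = TRUE, drop_with_n = TRUE) {
  trim_length <- as.integer(trim_length)
  if (is.na(trim_length) || trim_length < 15L) stop("trim_length must be >= 15")
  structure(list(trim_length = trim_length, drop_short = isTRUE(drop_short),
                 drop_with_n = isTRUE(drop_with_n)),
            class = "prep_config")
}

#' Read small-RNA reads from FASTA or FASTQ
#'
#' @param path input file; gzip is handled transparently. Format is guessed
#'   from the extension unless given.
#' @param format "auto", "fasta" or "fastq".
#' @return named character vector of read sequences.
#' @export
read_small_rna <- function(path, format = c("auto", "fasta", "fastq")) {
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (grepl("\\.(fq|fastq)(\\.gz)?$", path, ignore.case = TRUE))
      "fastq" else "fasta"
  }
  x <- Biostrings::readDNAStringSet(path, format = format)
  setNames(as.character(x), names(x))
}

#' Trim reads to a fixed length from the 3' end
#'
#' Keeps the first `trim_length` bases of every read. Reads with characters
#' outside A/C/G/T/N are rejected per read with a warning; short reads and
#' reads containing N are dropped according to the configuration.
#'
#' @param reads character vector of read sequences (names preserved).
#' @param cfg a [prep_config()].
#' @return character vector of trimmed reads.
#' @export
trim_reads <- function(reads, cfg = prep_config()) {
  stopifnot(inherits(cfg, "prep_config"))
  if (length(reads) == 0) return(character(0))
  reads <- toupper(reads)
  bad <- grepl("[^ACGTN]", reads)
  if (any(bad)) {
    warning(sum(bad), " read(s) with non-nucleotide characters rejected")
    reads <- reads[!bad]
  }
  if (cfg$drop_short) {
    short <- nchar(reads) < cfg$trim_length
    if (any(short)) {
      message(sum(short), " read(s) shorter than ", cfg$trim_length, " nt dropped")
      reads <- reads[!short]
    }
  } else {
    reads <- reads[nchar(reads) >= cfg$trim_length]
  }
  out <- substr(reads, 1L, cfg$trim_length)
  names(out) <- names(reads)
  if (cfg$drop_with_n) {
    hasn <- grepl("N", out, fixed = TRUE)
    if (any(hasn)) {
      message(sum(hasn), " read(s) containing N dropped")
      out <- out[!hasn]
    }
  }
  out
}

#' Collapse identical reads into unique sequences with counts
#'
#' @param reads character vector of (trimmed) read sequences.
#' @return data frame with columns `sequence` and `count`, ordered by
#'   descending count then lexicographic sequence; the counts sum to
#'   `length(reads)`.
#' @export
collapse_reads <- function(reads) {
  if (length(reads) == 0) {
    return(data.frame(sequence = character(0), count = integer(0),
                      stringsAsFactors = FALSE))
  }
  tab <- table(reads)
  out <- data.frame(sequence = names(tab), count = as.integer(tab),
                    stringsAsFactors = FALSE)
  out <- out[order(-out$count, out$sequence), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Write collapsed reads as FASTA with counts in the header
#'
#' Headers follow the common small-RNA convention `>seq{i}_x{count}` so the
#' duplicate count survives a round trip through the file.
#'
#' @param collapsed data frame from [collapse_reads()].
#' @param path output FASTA path.
#' @export
write_collapsed_fasta <- function(collapsed, path) {
  ids <- sprintf("seq%d_x%d", seq_len(nrow(collapsed)), collapsed$count)
  write_fasta(setNames(collapsed$sequence, ids), path)
}

#' Read a collapsed FASTA written by [write_collapsed_fasta()]
#'
#' @param path input FASTA path.
#' @return data frame with columns `sequence` and `count`.
#' @export
read_collapsed_fasta <- function(path) {
  x <- Biostrings::readDNAStringSet(path)
  if (length(x) == 0) {
    return(data.frame(sequence = character(0), count = integer(0),
                      stringsAsFactors = FALSE))
  }
  m <- regmatches(names(x), regexec("_x(\\d+)$", names(x)))
  cnt <- vapply(m, function(g) if (length(g) == 2) as.integer(g[2]) else NA_integer_, 1L)
  if (anyNA(cnt)) stop("malformed collapsed FASTA header (expected >id_x<count>)")
  out <- data.frame(sequence = unname(as.character(x)), count = cnt,
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}
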