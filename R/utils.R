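#' @useDynLib mirforge, .registration = TRUE
#' @importFrom Rcpp evalCpp
#' @importFrom stats rpois runif rnorm sd setNames predict p.adjust medpolish
#' @importFrom utils head read.table write.table
NULL

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Reverse-complement a DNA string
#'
#' @param x character vector of DNA sequences (A/C/G/T/N).
#' @return character vector of reverse complements.
#' @export
revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

## run `code` under a fixed RNG seed and restore the caller's RNG state
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = .GlobalEnv, inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = .GlobalEnv) else NULL
  on.exit({
    if (had) {
      assign(".Random.seed", old, envir = .GlobalEnv)
    } else if (exists(".Random.seed", envir = .GlobalEnv, inherits = FALSE)) {
      rm(".Random.seed", envir = .GlobalEnv)
    }
  })
  set.seed(seed)
  code
}

## 0-based half-open interval overlap length
overlap_len <- function(s1, e1, s2, e2) {
  pmax(0L, pmin(e1, e2) - pmax(s1, s2))
}

stopifnot_scalar_chr <- function(x, what) {
  if (!is.character(x) || length(x) != 1L || is.na(x)) {
    stop(what, " must be a single character string", call. = FALSE)
  }
}

## empty hit table shared by the alignment functions
empty_hits <- function() {
  data.frame(
    read_sequence = character(0), ref_id = character(0),
    start = integer(0), end = integer(0), strand = character(0),
    seed_mismatches = integer(0), total_mismatches = integer(0),
    stringsAsFactors = FALSE
  )
}

#' Write sequences to a FASTA file
#'
#' @param seqs named character vector of sequences.
#' @param path output path.
#' @export
write_fasta <- function(seqs, path) {
  Biostrings::writeXStringSet(Biostrings::DNAStringSet(seqs), path)
  invisible(path)
}

#' Write reads to a FASTQ file with uniform placeholder qualities
#'
#' @param reads named character vector of read sequences.
#' @param path output path (".gz" suffix writes gzip).
#' @export
write_fastq <- function(reads, path) {
  ids <- names(reads) %||% paste0("read", seq_along(reads))
  if (is.null(names(reads))) names(reads) <- ids
  x <- Biostrings::DNAStringSet(reads)
  q <- Biostrings::BStringSet(vapply(nchar(reads), function(n) strrep("I", n), ""))
  Biostrings::writeXStringSet(x, path, format = "fastq", qualities = q,
                              compress = grepl("\\.gz$", path))
  invisible(path)
}

#' Write a conservation track as bedGraph
#'
#' @param track data frame with columns `chrom`, `start` (0-based), `end`, `score`.
#' @param path output path.
#' @export
write_bedgraph <- function(track, path) {
  write.table(track[, c("chrom", "start", "end", "score")], path,
              quote = FALSE, sep = "\t", row.names = FALSE, col.names = FALSE)
  invisible(path)
}
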