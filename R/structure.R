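#' Fold an RNA sequence into its minimum-free-energy secondary structure
#'
#' The default backend is a dynamic-programming fold under a simplified
#' nearest-neighbour energy model (base-pair energies GC -3 / AU -2 / GU -1
#' kcal/mol, -1 per stacked pair, hairpin-loop penalty 3.0 + 0.1 per unpaired
#' nt beyond the 3-nt minimum loop; lonely pairs allowed). The "vienna"
#' backend shells out to RNAfold for full thermodynamic parameters; both
#' return the same structure contract.
#'
#' @param sequence nucleotide string (ACGU; T is read as U).
#' @param backend "internal" (default) or "vienna".
#' @return an object of class `rna_structure`: list with `sequence`,
#'   `dotbracket`, `mfe` (kcal/mol), `pair_table` (integer vector; 0 =
#'   unpaired, otherwise 1-based partner) and `n_hairpin_loops`.
#' @export
fold_rna <- function(sequence, backend = c("internal", "vienna")) {
  backend <- match.arg(backend)
  stopifnot_scalar_chr(sequence, "sequence")
  sequence <- toupper(sequence)
  if (grepl("[^ACGUT]", sequence)) stop("non-nucleotide characters in sequence")
  if (backend == "internal") {
    r <- .rna_fold_internal(sequence)
    db <- r$dotbracket; mfe <- r$mfe; pt <- r$pair_table
  } else {
    out <- system2("RNAfold", c("--noPS"), input = sequence, stdout = TRUE)
    line <- out[length(out)]
    m <- regexec("^([().]+)\\s+\\(\\s*(-?[0-9.]+)\\)", line)
    g <- regmatches(line, m)[[1]]
    if (length(g) != 3) stop("could not parse RNAfold output: ", line)
    db <- g[2]; mfe <- as.numeric(g[3]); pt <- dotbracket_to_pairs(db)
  }
  structure(list(sequence = sequence, dotbracket = db, mfe = mfe,
                 pair_table = pt, n_hairpin_loops = count_hairpin_loops(db)),
            class = "rna_structure")
}

#' @export
print.rna_structure <- function(x, ...) {
  cat(x$sequence, "\n", x$dotbracket, " (", sprintf("%.2f", x$mfe), ")\n", sep = "")
  invisible(x)
}

#' Convert dot-bracket notation to a pair table
#'
#' @param db dot-bracket string.
#' @return integer vector: 0 for unpaired positions, otherwise the 1-based
#'   partner index.
#' @export
dotbracket_to_pairs <- function(db) {
  ch <- strsplit(db, "")[[1]]
  pt <- integer(length(ch))
  stack <- integer(0)
  for (i in seq_along(ch)) {
    if (ch[i] == "(") {
      stack <- c(stack, i)
    } else if (ch[i] == ")") {
      if (length(stack) == 0) stop("unbalanced brackets")
      j <- stack[length(stack)]
      stack <- stack[-length(stack)]
      pt[i] <- j; pt[j] <- i
    } else if (ch[i] != ".") {
      stop("invalid dot-bracket character: ", ch[i])
    }
  }
  if (length(stack) > 0) stop("unbalanced brackets")
  pt
}

#' Convert a pair table back to dot-bracket notation
#'
#' @param pt integer pair table as from [dotbracket_to_pairs()].
#' @return dot-bracket string.
#' @export
pairs_to_dotbracket <- function(pt) {
  ch <- rep(".", length(pt))
  ch[pt > seq_along(pt)] <- "("
  ch[pt > 0 & pt < seq_along(pt)] <- ")"
  paste(ch, collapse = "")
}

#' Count hairpin (terminal) loops in a structure
#'
#' A hairpin loop is a base pair with no pair nested inside it; a canonical
#' pre-miRNA stem-loop has exactly one.
#'
#' @param x an `rna_structure` or a dot-bracket string.
#' @return integer count.
#' @export
count_hairpin_loops <- function(x) {
  db <- if (inherits(x, "rna_structure")) x$dotbracket else x
  m <- gregexpr("\\(\\.*\\)", db)[[1]]
  if (m[1] == -1L) 0L else length(m)
}

#' Structure-filter configuration
#'
#' @param min_pairs_precursor minimum number of base pairs in the whole
#'   precursor structure (default 19).
#' @param min_pairs_cluster minimum number of paired nucleotide positions
#'   within the read-cluster interval (default 11). Paired *positions* are
#'   counted here because a 20-27 nt cluster lies on one arm: its pairing
#'   partners sit on the other arm, so it cannot contain 11 full pairs.
#' @param require_single_stem require exactly one hairpin loop (default TRUE).
#' @return an object of class `structure_filter_config`.
#' @export
structure_filter_config <- function(min_pairs_precursor = 19L,
                                    min_pairs_cluster = 11L,
                                    require_single_stem = TRUE) {
  stopifnot(min_pairs_precursor > 0, min_pairs_cluster > 0)
  structure(list(min_pairs_precursor = as.integer(min_pairs_precursor),
                 min_pairs_cluster = as.integer(min_pairs_cluster),
                 require_single_stem = isTRUE(require_single_stem)),
            class = "structure_filter_config")
}

#' Apply the hairpin structure filters to a folded precursor
#'
#' A precursor is discarded when any of these holds: it is not a single-stem
#' hairpin; it has fewer than `min_pairs_precursor` base pairs; or fewer than
#' `min_pairs_cluster` paired positions fall within the cluster interval.
#'
#' @param s an `rna_structure` for the candidate window.
#' @param cluster_offset integer pair: 0-based half-open cluster interval in
#'   window coordinates.
#' @param cfg a [structure_filter_config()].
#' @return list with `pass` (logical) and `reason` — `""` on pass, otherwise
#'   the first failed rule: "single_stem", "min_pairs_precursor" or
#'   "min_pairs_cluster".
#' @export
passes_structure_filters <- function(s, cluster_offset,
                                     cfg = structure_filter_config()) {
  stopifnot(inherits(s, "rna_structure"))
  pt <- s$pair_table
  if (cfg$require_single_stem && s$n_hairpin_loops != 1L) {
    return(list(pass = FALSE, reason = "single_stem"))
  }
  if (sum(pt > 0) %/% 2L < cfg$min_pairs_precursor) {
    return(list(pass = FALSE, reason = "min_pairs_precursor"))
  }
  cpos <- (cluster_offset[1] + 1L):cluster_offset[2]
  cpos <- cpos[cpos >= 1 & cpos <= length(pt)]
  if (sum(pt[cpos] > 0) < cfg$min_pairs_cluster) {
    return(list(pass = FALSE, reason = "min_pairs_cluster"))
  }
  list(pass = TRUE, reason = "")
}

#' Fold candidate precursors and apply the structure filters
#'
#' @param candidates candidate table from [generate_precursors()].
#' @param cfg a [structure_filter_config()].
#' @param backend folding backend passed to [fold_rna()].
#' @return the candidate table with added columns `mfe`, `dotbracket`,
#'   `n_pairs`, `pass`, `fail_reason` and a list-column `structure`.
#' @export
fold_precursors <- function(candidates, cfg = structure_filter_config(),
                            backend = "internal") {
  n <- nrow(candidates)
  structs <- vector("list", n)
  mfe <- numeric(n); db <- character(n); np <- integer(n)
  pass <- logical(n); reason <- character(n)
  for (i in seq_len(n)) {
    s <- fold_rna(candidates$window_sequence[i], backend = backend)
    structs[[i]] <- s
    mfe[i] <- s$mfe; db[i] <- s$dotbracket
    np[i] <- sum(s$pair_table > 0) %/% 2L
    f <- passes_structure_filters(
      s, c(candidates$cluster_off_start[i], candidates$cluster_off_end[i]), cfg)
    pass[i] <- f$pass; reason[i] <- f$reason
  }
  candidates$mfe <- mfe
  candidates$dotbracket <- db
  candidates$n_pairs <- np
  candidates$pass <- pass
  candidates$fail_reason <- reason
  candidates$structure <- structs
  candidates
}

#' Serialize folded structures as Vienna-style three-line records
#'
#' @param candidates folded candidate table from [fold_precursors()].
#' @param path output path.
#' @export
write_structures <- function(candidates, path) {
  con <- file(path, "w")
  on.exit(close(con))
  for (i in seq_len(nrow(candidates))) {
    writeLines(c(paste0(">", candidates$candidate_id[i]),
                 candidates$window_sequence[i],
                 sprintf("%s (%.2f)", candidates$dotbracket[i], candidates$mfe[i])),
               con)
  }
  invisible(path)
}
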