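#' Full pipeline configuration
#'
#' Aggregates every stage configuration with the defaults of the discovery
#' protocol: 20-nt trim; seed 17 / <=2 seed mismatches / <=6 alignments
#' (stringent quantification: <=3 alignments / <=1 seed mismatch); cluster
#' span 20-27 nt and test-set count >= 11; >= 19 precursor pairs and >= 11
#' paired cluster positions; 1000 trees / 66% bags / 3 features per tree;
#' MFE <= -25 and unplaced-chromosome exclusion for calls.
#'
#' @param prep a [prep_config()].
#' @param align an [align_params()].
#' @param stringent stringent [align_params()] for quantification.
#' @param cluster a [cluster_config()].
#' @param structure a [structure_filter_config()].
#' @param forest a [forest_config()].
#' @param call a [call_filter_config()].
#' @param backend folding backend ("internal" or "vienna").
#' @param seed global seed (also seeds the forest unless it was configured
#'   explicitly).
#' @return an object of class `pipeline_config`.
#' @export
pipeline_config <- function(prep = prep_config(), align = align_params(),
                            stringent = align_params(stringent = TRUE),
                            cluster = cluster_config(),
                            structure = structure_filter_config(),
                            forest = NULL, call = call_filter_config(),
                            backend = "internal", seed = 1L) {
  forest <- forest %||% forest_config(seed = seed)
  structure(list(prep = prep, align = align, stringent = stringent,
                 cluster = cluster, structure = structure, forest = forest,
                 call = call, backend = backend, seed = as.integer(seed)),
            class = "pipeline_config")
}

#' Run the novel-miRNA discovery pipeline on one sample
#'
#' Executes the full workflow: trim and collapse; sequential tier alignment
#' ending at the genome; genomic re-alignment of annotation-assigned reads;
#' strand-specific clustering (with the expression filter on the test set
#' only); precursor window generation; folding and structure filtering;
#' feature computation; per-sample random-forest training on the
#' positive/negative sets with out-of-bag evaluation and permutation
#' importance; classification of test candidates; post-filtering and merging
#' into novel miRNA calls; stringent re-alignment for quantification.
#'
#' @param reads named character vector of raw reads (or a FASTA/FASTQ path).
#' @param genome named character vector of chromosome sequences.
#' @param tiers ordered list of annotation [reference_tier()]s (without the
#'   genome; it is appended internally).
#' @param known_loci data frame of known miRNA loci (`chrom`, `start`, `end`,
#'   `strand`) used to vet the positive training set.
#' @param conservation conservation track data frame or NULL.
#' @param config a [pipeline_config()].
#' @param sample_name label recorded in outputs.
#' @return an object of class `mirforge_run`: list with `manifest` (named
#'   stage counts), `assignment`, `clusters` (list: positive/negative/test),
#'   `candidates` (folded, filter-annotated), `features` (list of labeled
#'   feature matrices), `model`, `importance`, `predictions`, `calls`
#'   (merged novel miRNA calls), `stringent` (hits and total aligned count)
#'   and `config`.
#' @export
run_discovery <- function(reads, genome, tiers, known_loci = NULL,
                          conservation = NULL, config = pipeline_config(),
                          sample_name = "sample") {
  if (is.character(reads) && length(reads) == 1 && file.exists(reads)) {
    reads <- read_small_rna(reads)
  }
  genome <- toupper(genome)
  n_raw <- length(reads)
  trimmed <- trim_reads(reads, config$prep)
  collapsed <- collapse_reads(trimmed)
  genome_tier <- reference_tier("genome", genome)
  ta <- assign_tiers(collapsed, c(tiers, list(genome_tier)), config$align)
  tier_counts <- table(ta$assignment$tier)
  pick <- function(tier_names) {
    collapsed[collapsed$sequence %in%
              ta$assignment$sequence[ta$assignment$tier %in% tier_names &
                                     !ta$assignment$suppressed], , drop = FALSE]
  }
  realign <- function(sub) {
    if (nrow(sub) == 0) return(cbind(empty_hits(), count = integer(0)))
    align_reads(sub, genome, config$align)
  }
  pos_hits <- realign(pick("mature"))
  neg_hits <- realign(pick(c("refseq_mrna", "rfam")))
  star_hits <- realign(pick(c("star", "star_unobserved", "hairpin")))
  test_hits <- ta$tier_hits$genome
  all_hits <- rbind(pos_hits, neg_hits, star_hits, test_hits)

  pos_clusters <- build_clusters(pos_hits, config$cluster)
  neg_clusters <- build_clusters(neg_hits, config$cluster)
  test_clusters_all <- build_clusters(test_hits, config$cluster)
  test_clusters <- filter_test_clusters(test_clusters_all, config$cluster)

  pos_prec <- generate_precursors(pos_clusters, genome, config$cluster)
  if (nrow(pos_prec) > 0 && !is.null(known_loci)) {
    pos_prec <- pos_prec[label_positive(pos_prec, known_loci), , drop = FALSE]
  }
  neg_prec <- generate_precursors(neg_clusters, genome, config$cluster)
  test_prec <- generate_precursors(test_clusters, genome, config$cluster)

  fold_set <- function(prec) {
    if (nrow(prec) == 0) return(prec)
    fold_precursors(prec, config$structure, backend = config$backend)
  }
  pos_f <- fold_set(pos_prec); neg_f <- fold_set(neg_prec); test_f <- fold_set(test_prec)
  keep_pass <- function(x) if (nrow(x) == 0) x else x[x$pass, , drop = FALSE]
  pos_k <- keep_pass(pos_f); neg_k <- keep_pass(neg_f); test_k <- keep_pass(test_f)

  feats <- list(
    positive = feature_matrix(pos_k, all_hits, conservation, "positive"),
    negative = feature_matrix(neg_k, all_hits, conservation, "negative"),
    test = feature_matrix(test_k, all_hits, conservation, "test"))
  train <- rbind(feats$positive, feats$negative)
  x <- train[, FEATURE_NAMES, drop = FALSE]
  y <- train$label == "positive"
  model <- rf_train(x, y, config$forest)
  importance <- rf_importance(model, x, y)
  preds <- rf_classify(model, feats$test[, FEATURE_NAMES, drop = FALSE])
  test_k$vote_fraction <- preds$vote_fraction
  test_k$predicted <- preds$predicted

  calls <- postfilter(test_k[test_k$predicted, , drop = FALSE], config$call)
  calls <- merge_overlapping(calls)

  str_hits <- align_reads(collapsed, genome, config$stringent)
  aligned_seqs <- attr(str_hits, "aligned_sequences")
  total_aligned <- sum(collapsed$count[collapsed$sequence %in% aligned_seqs])

  manifest <- c(
    list(sample = sample_name, n_raw_reads = n_raw,
         n_trimmed_reads = length(trimmed),
         n_collapsed_reads = nrow(collapsed)),
    as.list(setNames(as.integer(tier_counts),
                     paste0("reads_tier_", names(tier_counts)))),
    list(n_positive_clusters = nrow(pos_clusters),
         n_negative_clusters = nrow(neg_clusters),
         n_test_clusters_all = nrow(test_clusters_all),
         n_test_clusters_expressed = nrow(test_clusters),
         n_positive_precursors = nrow(pos_prec),
         n_negative_precursors = nrow(neg_prec),
         n_test_precursors = nrow(test_prec),
         n_positive_filtered = nrow(pos_k),
         n_negative_filtered = nrow(neg_k),
         n_test_filtered = nrow(test_k),
         oob_accuracy = model$oob_accuracy,
         n_predicted_positive = sum(preds$predicted),
         n_novel_calls = nrow(calls),
         total_stringent_aligned = total_aligned))
  structure(list(sample = sample_name, manifest = manifest,
                 assignment = ta$assignment,
                 clusters = list(positive = pos_clusters,
                                 negative = neg_clusters,
                                 test = test_clusters),
                 candidates = list(positive = pos_f, negative = neg_f,
                                   test = test_k),
                 features = feats, model = model, importance = importance,
                 predictions = preds, calls = calls,
                 stringent = list(hits = str_hits,
                                  total_aligned = total_aligned),
                 config = config),
            class = "mirforge_run")
}

#' @export
print.mirforge_run <- function(x, ...) {
  cat("mirforge discovery run:", x$sample, "\n")
  m <- x$manifest
  for (k in setdiff(names(m), "sample")) cat(sprintf("  %-28s %s\n", k, m[[k]]))
  invisible(x)
}

#' Compare two discovery runs and quantify differential expression
#'
#' Intersects the two call catalogs by same-strand locus overlap and
#' computes stringent-criteria RPM signals and induced/repressed calls for
#' every union locus (treated / control ratio).
#'
#' @param run_treated,run_control `mirforge_run` objects for the two
#'   conditions.
#' @return list with `comparison` (see [compare_conditions()]) and `de`
#'   (per-locus DE table from [call_direction()]).
#' @export
compare_runs <- function(run_treated, run_control) {
  cmp <- compare_conditions(run_treated$calls, run_control$calls)
  loci <- cmp$loci[, c("chrom", "start", "end", "strand")]
  loci$locus_id <- sprintf("%s:%d-%d:%s", loci$chrom, loci$start, loci$end,
                           loci$strand)
  qt <- quantify_loci(loci, run_treated$stringent$hits,
                      run_treated$stringent$total_aligned,
                      sample = run_treated$sample)
  qc <- quantify_loci(loci, run_control$stringent$hits,
                      run_control$stringent$total_aligned,
                      sample = run_control$sample)
  list(comparison = cmp, de = call_direction(qt, qc))
}
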