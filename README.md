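# mirforge

Discovery of novel microRNAs from small RNA deep-sequencing data, with a
fully synthetic validation harness.

## The problem

Small RNA-seq of a treated/control pair (here modeled on
glucocorticoid-treated vs untreated primary lymphocytes) captures reads
from annotated miRNAs, other structured RNAs, and — most interestingly —
unannotated loci that behave exactly like miRNAs: a tight 20–27 nt read
cluster on one arm of a stable genomic hairpin, a weaker star-arm signal
offset by the 2-nt 3′ overhangs of the Dicer duplex, and elevated sequence
conservation. mirforge turns that signature into a classifier-based
discovery pipeline for researchers analysing small-RNA libraries without a
reference catalog of every miRNA in their system.

## The method

1. **Prepare** — trim reads to 20 nt from the 3′ end, collapse to unique
   sequences with counts (`>seq{i}_x{count}` headers).
2. **Tiered alignment** — align sequentially to mature miRNA → mature-star →
   unobserved star → hairpin → mRNA → ncRNA families → genome. Semantics:
   full-length hits, ≤2 mismatches in the 17-nt seed, best stratum only,
   ≤6 alignments per read (more ⇒ the read is suppressed). Reads first
   matching the mature tier seed the **positive** training pool, other-RNA
   reads the **negative** pool, genome-only reads the **test** pool.
3. **Cluster & window** — overlapping same-strand genome hits form clusters
   (span 20–27 nt; test clusters need raw counts ≥ 11); each cluster is
   expanded into three candidate precursor windows with flanks
   (70,20)/(45,45)/(20,70) nt.
4. **Fold & filter** — each window is folded (internal simplified
   nearest-neighbour MFE model by default; ViennaRNA adapter available) and
   kept only if it is a single-stem hairpin with ≥ 19 base pairs and ≥ 11
   paired positions under the cluster.
5. **Classify** — ten features per candidate (pairing counts, cluster
   length, star expression, tag count, MFE, normalized energy, arm
   asymmetry, conservation, overhang size) train a random forest of 1000
   trees, each built from a 66% no-replacement sample bag and 3 features
   drawn per tree, with out-of-bag vote evaluation and permutation feature
   importance. Test candidates with a positive vote majority are calls.
6. **Post-filter & quantify** — calls on `chrUn*`/`*_random` chromosomes or
   with MFE > −25 kcal/mol are dropped; overlapping calls merge (the mature
   sequence is the parent cluster sequence). Expression is reads-per-million
   under stringent criteria (≤3 alignments, ≤1 seed mismatch) and the
   treated/control ratio labels each locus induced or repressed.

A companion module implements the matching microarray analysis: quantile
normalization + median-polish summarization, a signal-to-noise statistic
with permutation p-values, and the p ≤ 0.01 & |FC| ≥ 1.2 gate with gene-list
intersection. A synthetic-data module plants ground-truth hairpins, decoys,
two-condition reads and a conservation track so every stage is verifiable.

## Worked example

A self-contained run on a small synthetic study (60 kb genome, 6 known +
5 novel + 10 decoy loci, 10k reads per condition):

```r
library(mirforge)
spec  <- synthetic_spec(genome_length = 60000, n_known_mirnas = 6,
                        n_novel_mirnas = 5, n_decoy_rnas = 10,
                        reads_per_sample = 10000, seed = 42)
truth <- plant_hairpins(spec)
cons  <- make_conservation_track(truth)
known <- truth$loci[truth$loci$type == "known_mirna",
                    c("chrom", "start", "end", "strand")]
run_control <- run_discovery(simulate_reads(truth, "control")$reads,
                             truth$genome, truth$tiers, known_loci = known,
                             conservation = cons,
                             config = pipeline_config(seed = 5),
                             sample_name = "control")
run_treated <- run_discovery(simulate_reads(truth, "treated")$reads,
                             truth$genome, truth$tiers, known_loci = known,
                             conservation = cons,
                             config = pipeline_config(seed = 6),
                             sample_name = "treated")
print(run_control)
```

```
mirforge discovery run: control
  n_raw_reads                  9899
  n_collapsed_reads            526
  reads_tier_genome            423
  reads_tier_mature            24
  ...
  n_test_clusters_expressed    9
  n_test_filtered              18
  oob_accuracy                 1
  n_novel_calls                9
```

The manifest mirrors the workflow: 526 unique sequences partition over the
tiers, 9 expressed test clusters yield 18 filter-passing windows, the
forest separates the planted positives and negatives perfectly (OOB
accuracy 1.0), and 9 merged loci are called novel — the 5 planted novel
hairpins, most contributing both a mature-arm and a star-arm cluster.
Comparing conditions:

```r
cmp <- compare_runs(run_treated, run_control)
cat(cmp$comparison$unique_a, cmp$comparison$unique_b, cmp$comparison$common)
#> 1 3 6
head(cmp$de[order(cmp$de$ratio), c("locus_id", "rpm_treated", "rpm_control", "ratio", "direction")])
#>           locus_id rpm_treated rpm_control     ratio direction
#> 8   chr3:628-650:+    300.3304    2323.467 0.1292596 repressed
#> 4 chr2:8308-8330:+    500.5506    3434.690 0.1457338 repressed
#> 1   chr1:594-616:+   7308.0388   37781.594 0.1934285 repressed
```

The ratio column is treated/control RPM; values below 1 are repressed loci,
matching the planted fold changes. Feature importance puts conservation on
top, as expected for this signature:

```r
head(run_control$importance, 3)
#>                 feature mean_decrease rank
#> 1       f9_conservation     0.4566025    1
#> 2     f3_cluster_length     0.3475897    2
#> 3 f10_overhang_unpaired     0.2287130    3
```

A thin CLI over the same functions lives at `inst/scripts/mirforge`
(`mirforge simulate`, `mirforge run`).

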