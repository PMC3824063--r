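---
title: "Discovering novel miRNAs from small RNA-seq: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Discovering novel miRNAs from small RNA-seq: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

mirforge implements a discovery pipeline for novel microRNAs from small-RNA
deep-sequencing data, in the style of classifier-based miRNA discovery tools:
reads are partitioned by a tiered annotation alignment into positive
(known-miRNA), negative (other structured RNA) and test (unannotated) pools;
genomic read clusters are expanded into candidate precursor windows; windows
are folded and filtered on hairpin structure; ten molecular features per
surviving candidate train a random forest that then classifies the test
candidates; and positive predictions are post-filtered, merged and quantified
between a treated and a control condition. This vignette documents the model
choices, tunable parameters, and the limits of what the synthetic validation
demonstrates.

## The discovery model

A mature miRNA leaves a characteristic signature in small RNA-seq: a tight
pile-up of ~20-27 nt reads on one arm of a genomic hairpin, usually with a
weaker pile-up on the opposite arm (the star strand, offset by the 2-nt 3'
overhangs of the Dicer duplex), strong predicted secondary-structure
stability, and elevated sequence conservation. The pipeline encodes exactly
this signature and lets a classifier learn the joint distribution from loci
that are already annotated.

### Read preparation

Reads are trimmed to a uniform 20 nt from the 3' end (`prep_config()`),
which removes adapter read-through without requiring the adapter sequence,
then collapsed to unique sequences with duplicate counts
(`collapse_reads()`). Reads shorter than the trim length are dropped rather
than padded — nothing shorter carries the mature-miRNA signal sought here —
and reads containing N are dropped by default because the aligner treats N
as a mismatch at every position, so they only dilute the seed budget.
Collapsed FASTA headers use the common `>seq{i}_x{count}` small-RNA dialect.

### Tiered alignment

Collapsed reads are aligned sequentially to mature miRNA, mature-star,
unobserved star, hairpin, mRNA and ncRNA-family references, and finally to
the genome (`assign_tiers()`); a read is removed from the pool at the first
tier it matches. Alignment semantics (`align_params()`): full-length hits
only, at most 2 mismatches within the 17-nt seed (unrestricted in the 3
trailing bases), best-stratum retention (only hits with the minimal seed
mismatch count), and at most 6 alignments per read. A read exceeding the
cap is suppressed entirely as an ambiguous repetitive mapper — retaining an
arbitrary 6 of, say, 8 hits would bias cluster counts; suppressed reads are
considered consumed by the tier where they multimapped and are not passed
further down the cascade. The same semantics are applied at every tier.
The quantification step uses a stringent variant (at most 3 alignments,
1 seed mismatch; `align_params(stringent = TRUE)`).

Coordinates are 0-based half-open internally and in BED output. The engine
scans the seed with `Biostrings::matchPattern` over an N-spacer concatenated
reference and recounts mismatches exactly; a brute-force position scan in
the test suite verifies the two agree on desk-scale genomes.

### Clusters and precursor windows

Genome hits overlapping on the same strand form clusters
(`build_clusters()`); maximal connected components of interval overlap.
Since reads are uniformly 20 nt, a mature-miRNA pile-up with end wobble
spans 20-27 nt, and clusters outside that span are treated as
non-miRNA-like and dropped. Test-set clusters with raw counts below 11 are
removed so only moderately expressed loci are classified; training clusters
are not expression-filtered. Each cluster is expanded into three candidate
windows (`generate_precursors()`) with (upstream, downstream) flanks of
(70,20), (45,45) and (20,70) nt: a precursor hairpin is ~60-120 nt and the
cluster may sit on either arm, so the three geometries let whichever arm
hosts the mature sequence fall inside a well-formed window. Windows are
strand-oriented, truncated at chromosome ends, and dropped below 60 nt.

The negative training set is built by re-aligning reads assigned to the
mRNA/ncRNA tiers back to the genome under identical parameters, because all
downstream features are defined on genomic windows. Positive-set candidates
must additionally overlap a known miRNA locus on the same strand
(`label_positive()`).

### Folding and structure filters

Each window is folded (`fold_rna()`). The default backend is an internal
dynamic program over a simplified nearest-neighbour model: pair energies
GC -3, AU -2, GU -1 kcal/mol; -1 kcal/mol per stacked pair; hairpin-loop
closing penalty 3.0 + 0.1 kcal/mol per unpaired nucleotide beyond the 3-nt
minimum loop; lonely pairs allowed; no interior/multibranch penalties. The
total energy of a structure is therefore a function of its pair set alone,
which makes the model exhaustively enumerable — the test suite checks the
DP against complete enumeration for sequences up to 25 nt. A ViennaRNA
adapter (`backend = "vienna"`) provides full thermodynamic parameters when
MFE values on the physical scale matter; the energy threshold used by the
call filter applies to whichever backend is active and is config-exposed
for that reason.

Candidates are discarded (`passes_structure_filters()`) unless the window
folds into a single-stem hairpin (exactly one terminal loop), carries at
least 19 base pairs, and has at least 11 *paired nucleotide positions*
within the cluster interval. The cluster-level rule counts paired positions
rather than pairs: a 20-27 nt cluster sits on one arm and its pairing
partners lie on the other, so it cannot contain 11 full pairs — reading
"11 bindings" as positions is the only self-consistent interpretation.

### The ten features

Per candidate (`compute_features()`): f1 paired positions in the cluster;
f2 base pairs in the precursor; f3 cluster length; f4 star-arm expression —
the summed counts of reads falling entirely within the cluster's pairing
partner interval under the 2-nt 3' overhang geometry, widened by ±3 nt for
Drosha/Dicer processing heterogeneity; f5 total cluster tag count; f6 MFE;
f7 normalized energy (MFE / window length); f8 absolute difference in
unpaired nucleotides between the two stem arms; f9 mean per-base
conservation over the cluster from a user-supplied bedGraph (0 when absent);
f10 unpaired nucleotides outside the outermost pair (the overhangs).

Feature 9 deserves a note: the source protocol names this feature only as
the "expression of overlapping conserved region", which could be read
either as a conservation score or as read expression within conserved
regions. The feature-ranking evidence labels it simply "conservation", so
mirforge implements the conservation-score reading (mean per-base score
over the cluster; a sum variant is a config switch away in
`conservation_mean` semantics, with the mean chosen as default so the
magnitude is independent of cluster span). f8 uses the absolute difference
since the arm order carries no meaning for the classifier.

### The forest protocol

`rf_train()` grows 1000 binary classification trees. Each tree sees a bag
of `floor(0.66 n)` training candidates drawn *without* replacement and a
subset of exactly 3 features drawn once *per tree* — not per split. Both
choices follow the stated protocol literally rather than conventional
bootstrap/mtry defaults (a per-split variant would be a small change but is
deliberately not the default). Individual trees are CART fits (Gini
impurity, grown to purity, no pruning) via rpart. Out-of-bag votes for each
training sample aggregate only over trees whose bag excluded it; OOB
accuracy and the confusion matrix come from those votes, and permutation
importance is the mean decrease in per-tree OOB accuracy after permuting a
feature among that tree's OOB samples. Ties at the 0.5 vote threshold are
classified negative — conservative for a discovery tool. All sampling is
integer-indexed and seeded, so results are exactly reproducible.

With 3-of-10 features per tree, roughly half the trees see neither
informative feature on a two-feature signal; those trees vote near chance
and the ensemble still separates cleanly — the protocol's redundancy is
part of why 1000 trees are used.

### Calls, merging, and quantification

Positive test predictions are discarded if they localize to unplaced
chromosomes (`chrUn*`, `*_random`) or if their MFE is greater than
-25 kcal/mol (exactly -25 is retained). The mature sequence of a call is
its parent cluster sequence. Overlapping same-strand calls merge into one
locus keeping the best MFE, the maximum vote fraction and the mature
sequence of the strongest cluster; because the several windows of one
cluster necessarily overlap, this merge also unifies them. Cross-condition
comparison counts merged union loci by same-strand overlap.

Expression is reads-per-million under the stringent alignment criteria:
raw counts sum collapsed counts of reads with at least half their length on
the locus, multi-mapped reads contribute at every retained alignment (the
simplest consistent reading; fractional weighting is available via
`fractional = TRUE`), and the denominator is the sample's total
stringently-aligned read count. The treated/control RPM ratio calls each
locus induced (>1), repressed (<1) or unchanged (=1); a locus silent in
control but expressed in treated is reported `undefined` rather than given
an infinite ratio.

### Microarray differential expression

`normalize_expression()` log2-transforms, quantile-normalizes (limma) and
summarizes replicate probe rows by median polish (overall + column effects,
tolerance 1e-6, ≤10 iterations). The test statistic is signal-to-noise:
group mean difference over the sum of group standard deviations, with each
sd floored at 0.01 so identical replicates stay finite. P-values come from
sample-label permutations; the default pools null statistics across probes
(10,000 permutations would otherwise resolve little at per-probe level with
3v3 designs), with pure per-probe permutation and exhaustive enumeration as
flags. Random-sampling p-values use the add-one estimator to avoid zero;
exhaustive enumeration reports exact tail proportions. Significance
requires p ≤ 0.01 and |linear fold change| ≥ 1.2, fold change being
2^(mean log2 difference), sign-folded.

## The synthetic study

The generator (`synthetic_spec()`, `plant_hairpins()`, `simulate_reads()`)
emulates the structure of a two-condition thymocyte experiment at desk
scale: a 200 kb genome over four chromosomes (including one `chr1_random`
to exercise the chromosome filter), 20 known miRNA hairpins present in the
annotation tiers, 15 novel hairpins present only in the genome, 30 decoy
structured RNAs in the mRNA/ncRNA tiers, 50,000 reads per condition with
raw lengths 25 nt (control) and 35 nt (treated), 80% of miRNA loci
repressed in the treated condition with per-locus folds of 2-10, a 4%
uniform genomic background, 5% star-arm reads per locus, and a conservation
track scoring ~0.9 over miRNA loci and ~0.1 elsewhere.

Hairpins are built as a random mature arm + loop + imperfect reverse
complement (1-2 mutations for miRNA-like loci; weaker, AT-leaning stems
with 3-4 mutations for decoys) and rejection-sampled until at least one of
the three precursor-window geometries passes the structure filters (strong
hairpins additionally must reach MFE ≤ -26 so they survive the call filter
with margin). Planted loci are flanked by A/C-composition spacers whose
bases cannot pair each other, keeping the immediate flanks from spawning
competing stems; loci avoid `chr1_random` so ground truth is never consumed
by the chromosome filter (that filter is exercised by unit fixtures
instead). Annotation tier records include 10 nt of flanking sequence so
that end-wobble reads remain contained in their tier instead of leaking
into the test pool — mirroring how real annotation records include
precursor context. Per-variant read counts are Poisson around the planted
expectation with 1-nt end wobble (weights 0.2/0.6/0.2), so read collapsing,
cluster spans and the count filter are all exercised realistically.

Because a window must contain both stem arms to fold, only a subset of the
three flank geometries passes the filters for any given cluster — the
generator requires at least one passing window per planted hairpin, which
is exactly the property the pipeline relies on.

What passing on this synthetic study does *not* show: performance on real
genomes with repeats, isomiR spectra beyond ±1 nt wobble, sequencing error,
RNA editing, or thermodynamically marginal hairpins — the planted stems are
cleaner than many genuine pre-miRNAs, and real annotation tiers are far
larger. The synthetic result validates the machinery (every stage's
contract, determinism, and the end-to-end recovery logic), not a biological
sensitivity estimate.

## Problem sizes and numerical choices

The bundled validation runs at these scales, chosen to keep a full check
comfortably interactive on a laptop-class machine: aligner-oracle
comparison on 100 reads over 50 kb; folding-oracle comparison on 50
sequences of 12-25 nt (exhaustive enumeration grows near-exponentially with
length; 25 nt is ~10^5 structures); forest protocol at 200 training
candidates per class; and the full pipeline at the default synthetic spec
(two conditions, ~50k reads each, ≈5 minutes total). Folding uses
double-precision energies with a 1e-9 traceback tolerance; ties in the DP
traceback resolve toward fewer pairs first, which only affects degenerate
equal-energy structures, never the MFE. Interval arithmetic is integer
throughout.

## Known limitations

- The internal energy model is intentionally simple; its MFE scale differs
  from full thermodynamic parameter sets. The -25 kcal/mol call threshold is
  config-exposed (`call_filter_config()`) and should be recalibrated if the
  ViennaRNA backend is used on real data.
- "Unobserved star" derivation assumes the canonical 2-nt 3' overhang; loci
  with non-canonical processing will get an offset star interval (mitigated
  by the ±3 nt tolerance in f4).
- Clusters longer than 27 nt are dropped, not re-segmented; a locus with a
  broad isomiR spectrum could be lost.
- One library per condition: no replicate variance model for sequencing
  counts — differential calls are ratio-based by design, and the
  permutation machinery applies to the array module only.
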