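---
title: "Methods: gonadal piRNA discovery and sex-biased expression"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: gonadal piRNA discovery and sex-biased expression}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(eval = FALSE, collapse = TRUE, comment = "#>")
```

## Scope

`gonadpi` analyses gonadal small-RNA sequencing libraries for
Piwi-interacting RNAs (piRNAs): 26-32 nt germline small RNAs whose
biogenesis leaves a characteristic sequence signature — a uridine at the
5'-most position (1U) and an adenine at position 10 (10A), the "ping-pong"
signature. The pipeline takes raw FASTQ libraries from ovaries and testes,
collapses them to unique reads, maps them to a transcriptome with zero
mismatches, pushes mapped reads through a priority-ordered annotation
cascade, classifies the surviving 26-32 nt candidates with a k-mer
discriminant, summarises the sequence signatures, calls sex-specific and
sex-biased expression on read counts and on replicated microarray
intensities, and summarises piRNA-generating genes with hypergeometric term
enrichment. A fully seeded synthetic-data generator with ground-truth labels
accompanies every stage, so each claim the pipeline makes is testable as a
recovery experiment.

## Ingestion and mapping

Reads are cleaned per library: optional 3' adapter trimming (everything from
the first exact adapter occurrence is removed), then removal of reads
containing N, reads whose mean Phred quality falls below `min_quality`
(default Q20), and reads outside the retained length window (default
18-35 nt, which covers the miRNA and piRNA ranges of a 50 bp single-end
run). Survivors collapse to a unique-read table carrying per-library counts;
per-library QC reports the mean per-base error rate
$\overline{10^{-Q/10}}$, the Q30 fraction and GC content on the raw reads.

Mapping is exact: a read maps where it equals the reference substring
(sense) or its reverse complement (antisense). This is implemented with
Aho-Corasick dictionaries (Biostrings `PDict`, one variable-width dictionary
with a trusted band) scanned over the reference concatenated with `N`
separators and over its reverse complement; ACGT-only patterns cannot cross
a separator, so concatenated coordinates map back uniquely. The test suite
holds this equivalent to a brute-force substring scan on random instances.
End-to-end zero-mismatch mapping makes exact substring search a faithful
implementation of the mapping contract, not an approximation to a heuristic
aligner.

## Annotation cascade

Only transcriptome-mapped reads are annotated. Each mapped read receives
exactly one label, by database priority:

1. `conserved_miRNA` — occurs in the mature-miRNA set;
2. `rRNA` / `tRNA` / `snRNA` / `snoRNA` — occurs in the structural-ncRNA set;
3. `repeat` — occurs in the repeat set;
4. `novel_miRNA` — 18-25 nt, passes the hairpin filter below;
5. `piRNA_candidate` — remaining reads of 26-32 nt;
6. `other` — everything else.

Membership is an exact occurrence (either strand) in the user-supplied FASTA
set; the package does not re-implement covariance models or repeat
alignment. The per-library accounting table reports counts and percentages
of the mapped total, rounded half-up to two decimals — the convention that
reproduces standard published accounting tables cell for cell.

The novel-miRNA filter is a deliberately simple precursor test: take ±70 nt
of transcript context around the hit, compute the Nussinov maximum base
pairing (Watson-Crick plus G-U wobble, minimum loop 3) by dynamic
programming, and accept when the window reaches 18 pairs and the read lies
wholly within one arm of the optimal traceback (it does not cross the
innermost paired region). The 18-pair floor and ±70 nt window emulate
miRNA-precursor geometry (a canonical pre-miRNA stem pairs ~20-30 bases
within a ~70-90 nt hairpin); both are configurable. Random RNA of this
window length pairs promiscuously under Nussinov scoring, so the arm
condition, not the pair count, carries most of the specificity; dedicated
precursor scanners remain stricter, which is why the filter is applied only
to reads already unexplained by every reference set.

## k-mer classifier

Candidates are classified by a Fisher-discriminant over k-mer frequencies,
k = 1..5: for each of the 1,364 k-mers (4 + 16 + 64 + 256 + 1024,
lexicographic order), the feature is occurrences divided by valid windows.
Training on piRNA and non-piRNA sets gives per-feature Fisher ratios
$F_j = (m^+_j - m^-_j)^2 / (v^+_j + v^-_j + \varepsilon)$ with
$\varepsilon = 10^{-9}$, signed by the class-mean difference; a sequence's
score is the weighted sum, and the decision threshold maximises Youden's J
on the training scores (smallest optimal score on ties, so the rule is
deterministic). The published k-mer approach this follows does not fix its
weighting or threshold in print; Fisher weights with a linear score and a
Youden threshold are this package's fully specified, testable choice. A
position-specific "static" comparator is provided: smoothed base frequencies
at positions 1-20 (pseudocount 1, uniform 0.25 background) scored as summed
log-odds; the benchmarking helpers report held-out AUROC for both schemes on
the same split.

Predicted piRNAs are scanned against a known-piRNA set by exact full-sequence
identity (the zero-mismatch homolog rule). In the synthetic study this is a
planted-truth experiment: the generator hides a configurable number of true
pool sequences (default 93) among letter-shuffled decoys, and the search
must recover exactly the planted ones.

## Signature statistics

Position-specific base usage is computed over positions 1-32, in both
unique-sequence and count-weighted modes (published base-utility figures do
not always say which; both are one flag apart). A position draws only on
reads long enough to reach it, so every defined row of the matrix sums to 1.
The derived scalars are the 1U fraction and the 10A fraction, always counted
on the read's own 5'→3' sequence regardless of mapping strand (standard
ping-pong convention). Length histograms are reported as percentages per
group; strand composition counts each piRNA once via its primary hit — the
lexicographically smallest (transcript, start, strand) — a deterministic
multi-mapping tie-break. Genic-feature assignment overlaps the read interval
with the transcript's 5' UTR / CDS / 3' UTR spans and takes the majority,
breaking ties CDS > 3' UTR > 5' UTR; transcripts without a model are
`unannotated`.

## Expression calling

**Sequencing.** The two libraries of each sex are pooled. A piRNA is
`ovary_specific` when testis detection is exactly zero and the ovary pool
reaches the count floor (default 10; symmetric for testis), `shared` when
detected in both, and `low_count` otherwise. log2 fold change uses
library-size-normalised pools with a 0.5 pseudocount. With two libraries per
sex, a count-model fit has no usable replication, so differential expression
is a two-sided Fisher's exact test on the 2×2 table
[piRNA count, library remainder] × [ovary, testis], computed by direct
hypergeometric enumeration with the customary $1+10^{-7}$ relative slack on
the two-sided comparison, BH-corrected across piRNAs. This is a documented
stand-in: it is exact, deterministic and assumption-light at n = 2 + 2, but
treats pooled counts as independent draws. Probe selection for validation is
the union of the differential set (|log2FC| ≥ 1.5, P ≤ 0.01, Padj ≤ 0.05,
pooled counts > 10) and the high-expression set (pool within 50-4,646 for
ovary or 50-8,177 for testis, inclusive).

**Microarray.** Steps follow the order of the platform protocol: subtract
the background matrix (negatives floored at zero with a warning); drop
probes whose replicate-spot CV (sd/mean) reaches 0.3 in *any* sample — the
protocol states the filter but not the aggregation rule, and any-sample
failure is the conservative reading; quantile-normalize the spot columns of
the retained probes (limma, rank-wise sorted-value means, ties averaged);
take per-sample replicate medians; one-way ANOVA across the two groups of
three sample medians (closed-form two-group decomposition, identical to the
pooled-variance t test, F = t²); log2FC of the group medians with a 0.01
pseudo-intensity. Categories: `ovary_up`/`testis_up` at |log2FC| ≥ 1 and
P ≤ 0.05, `co_expressed` when both group medians exceed 1 with P > 0.05
(the threshold lives on the normalized-intensity scale as emitted and is
configurable, since that scale's units are platform-dependent), else
`nonsignificant`. Sex-biased probes are clustered into clades (default 10)
by average-linkage hierarchical clustering on correlation distance of
z-scored sample medians; platform concordance is the Pearson correlation of
sequencing and array log2FC.

## Genes and enrichment

A transcript is piRNA-generating when at least one predicted piRNA maps to
it; a multi-gene piRNA counts once per gene. Genes partition into
ovary / testis / both by the sex-specific piRNAs they host — note this
partition is disjoint by construction, which is stricter than summaries that
double-count the overlap. Term enrichment is the upper-tail hypergeometric
P(X ≥ k) with BH correction and an adjusted-P 0.05 flag; the background
universe is the annotated subset of the supplied background (genes with at
least one term), a choice that has to be made explicitly because enrichment
against unannotatable genes is vacuous. Term-to-gene maps are plain TSV
inputs; producing them (domain scanners, BLAST-based annotation) is upstream
of this package.

## The synthetic-data generator

The generator exists so the pipeline can be tested against known truth at
desk scale; it emulates the statistical structure the analysis assumes, not
any particular organism:

* **Reference.** A uniform-random transcriptome (default 300 transcripts,
  500-2,500 nt — matching assembled-transcript scale); gene models partition
  each annotated transcript (default 80% of them) into 5' UTR / CDS / 3' UTR
  at configurable fractions.
* **Planting.** Every simulated element — mature miRNAs (20-24 nt, 5' U
  biased), structural ncRNAs (70-120 nt), repeats, hairpin precursors,
  piRNAs, decoy and "other" fragments — is written *into* the transcriptome
  at non-overlapping loci. This guarantees perfect mapping and makes origin
  coordinates a checkable invariant (re-extraction reproduces the read,
  after reverse complement on the antisense strand).
* **piRNA sequence model.** Lengths 26-32 nt with the mass on 26-30;
  composition is A/U-rich (A 0.30, C 0.17, G 0.18, T 0.35), reflecting the
  A/U richness of piRNA populations and their source loci; the 5' base is U
  with total probability `p_5prime_U` (default 0.8) and base 10 is A with
  total probability `p_pos10_A` (default 0.5), so the configured values are
  exactly the recoverable fractions. The compositional component is what a
  k-mer classifier can legitimately learn; a generator with positional bias
  only would make any composition-based classifier near-powerless by
  construction, which would test nothing. Antisense fraction defaults to
  0.57, the sense/antisense balance reported for gonadal piRNA populations.
* **Expression.** Sex classes default to 44% ovary-only, 44% testis-only,
  6% biased (|log2FC| = 2), 6% shared, echoing the heavily sex-specific
  composition of gonadal piRNA sets. Counts are negative binomial around
  sex-dependent means (lognormal abundance weights, dispersion 0.2, Poisson
  in the dispersion→0 limit); one-sex classes have literally zero mean in
  the other sex.
* **Microarray.** Three samples per sex, three replicate spots per probe:
  intensity = per-sample background (a gain factor constant across the
  sample's spots) + signal × 2^(±log2FC/2) × lognormal noise (CV 0.1). A
  configurable probe fraction receives inflated replicate noise so the CV
  filter has true positives. One-sex piRNAs are given a ±4 log2 presence
  effect on the array scale — hybridisation of an absent piRNA still yields
  background, so the effect is strong but finite.
* **Truth semantics.** Each pool row records a biological class *and* the
  cascade-level expected label. The two differ for degradation decoys:
  unbiased 26-32 nt transcript fragments are, by definition of the cascade,
  piRNA candidates (expected label), while biologically "other" (class).
  Cascade recovery is judged against expected labels; classifier
  sensitivity/specificity against biological class. Conflating the two
  would make the cascade and the classifier answer for each other's job.

What the generator does **not** emulate: sequencing errors beyond a uniform
quality-degradation option, adapter chemistry (reads are emitted pre-trimmed
unless an adapter suffix is requested), multi-copy gene families and
paralogy (random sequences make multi-mapping rare), library-level abundance
calibrated to any real species, and spatial artefacts on the array. Passing
recovery tests therefore demonstrates the pipeline's internal correctness
under its own assumptions, not field performance on real gonadal libraries.

## Numerical and design choices

* Coordinates are 1-based and closed everywhere, matching R/Bioconductor
  and emitted GFF3; no internal convention switch.
* Percentages are rounded half-up to 2 decimals (`round_half_up`), the
  convention that reproduces published accounting tables; a small absolute
  epsilon guards binary-representation artefacts at exact halves.
* All randomness derives from one config seed through stage-tagged
  sub-seeds, so any stage can be re-run in isolation and full runs are
  byte-identical; the RNG state of the caller is restored after every
  generator call.
* Classifier models serialise to JSON with 17 significant digits, which
  round-trips doubles bit-exactly.
* Degenerate inputs are defined, not accidental: empty FASTQ libraries flow
  through to a zero-count report; zero mapped reads report 0.00% with a
  warning; a constant vector makes concordance NA with a note; fewer biased
  probes than clades reduces k with a warning; zero within-group variance
  with a between-group difference yields F = ∞, P = 0.
* Problem sizes in the test suite (≈5,000 unique reads for cascade
  recovery, 2,000 sequences per class for classifier benchmarks, 20,000
  piRNAs for parameter recovery, 1,000 probes for array detection) are
  chosen so that 3-standard-error recovery bands are tight enough to be
  meaningful while the whole suite stays desk-scale.

## Limitations

The Fisher/k-mer classifier is a fully specified stand-in for a published
scheme whose exact weights are not in print; absolute accuracies depend on
the (synthetic or user-supplied) training sets. The sequencing DE test
treats pooled counts as the unit of evidence and will be anticonservative
under strong overdispersion between same-sex libraries. The hairpin filter
is far weaker than dedicated miRNA-precursor scanners. Exact matching is
faithful to a zero-mismatch contract but unforgiving of sequencing errors —
reads with errors simply drop out as unmapped.
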