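# gonadpi

Discovery of Piwi-interacting RNAs (piRNAs) in gonadal small-RNA sequencing
libraries and analysis of their sex-specific and sex-biased expression.

piRNAs are 26–32 nt germline small RNAs that guide Piwi proteins in
transposon silencing and gonadal development. Their biogenesis leaves a
recognisable sequence signature — a 5′ uridine (1U) and an adenine at
position 10 (10A), the "ping-pong" signature — and in gonads they are
typically the dominant small-RNA class, with most individual piRNAs detected
in only one sex. `gonadpi` implements the complete analysis path from raw
reads to sex-biased piRNA calls for a two-ovary / two-testis sequencing
design with microarray validation:

* FASTQ cleaning, QC and collapsing to unique reads with per-library counts;
* zero-mismatch transcriptome mapping (exact substring search on both
  strands, held equivalent to a brute-force scan by the test suite);
* a priority-ordered annotation cascade
  (miRNA → rRNA/tRNA/snRNA/snoRNA → repeat → novel-miRNA hairpin filter →
  piRNA candidate → other);
* a Fisher-discriminant **k-mer classifier** for 26–32 nt candidates: k-mer
  frequencies for k = 1..5 (1,364 features), per-feature weights
  `w_j = sign(m⁺_j − m⁻_j)(m⁺_j − m⁻_j)² / (v⁺_j + v⁻_j + ε)`, linear score,
  Youden-J threshold; plus a position-specific log-odds comparator and an
  exact-identity known-piRNA homolog search;
* ping-pong signature statistics: positional base usage (1U/10A fractions),
  length, strand and 5′UTR/CDS/3′UTR feature distributions;
* expression calling: sex-specific categories and Fisher-exact/BH
  differential tests on pooled counts; a microarray pipeline (background
  subtraction → replicate-CV filter → quantile normalization → replicate
  medians → one-way ANOVA → |log2FC| ≥ 1, P ≤ 0.05 calls → clade
  clustering → cross-platform concordance);
* piRNA-generating gene summaries with hypergeometric GO/KEGG-style term
  enrichment (BH-corrected);
* a seeded synthetic-data generator that plants every simulated element into
  the transcriptome with full ground truth, so each stage is testable as a
  recovery experiment.

See `vignettes/gonadal-pirna-methods.Rmd` for the methods account and the
design rationale.

## Worked example

Simulate a default study (four libraries, ~3,000 planted piRNAs among
miRNA/ncRNA/repeat/decoy reads) and run the full pipeline:

```r
library(gonadpi)
cfg    <- sim_config(seed = 1)
report <- run_pipeline(cfg, out_dir = "demo")
```

Selected report fields, as printed by the run above:

```
unique reads: 5401
cascade agreement: 100 %
candidates: 3528  predicted piRNAs: 2551
1U: 79.6 %  10A: 50.3 %
sense/antisense: 44.18 / 55.82 %
known homolog hits: 75 of 93 planted
array: 592 ovary-up, 554 testis-up, concordance r = 0.986
piRNA-generating genes: 300  mean piRNAs/gene: 8.5
```

Reading this: every unique read with a truth record received its expected
cascade label (100% agreement); the classifier kept 2,551 of 3,528
candidates, and the recovered 1U/10A fractions (79.6%/50.3%) match the
generator's configured biases (0.8/0.5). The homolog search finds the
planted known piRNAs that survived classification (75 of 93 planted in the
pool; running `match_known` on the full pool recovers all 93 exactly). The
microarray stage calls sex-biased probes with sequencing/array log2FC
concordance r ≈ 0.99 on this noise level. Stage outputs (unique-read table,
annotation summary, expression tables, enrichment results) are written as
TSV under `demo/`, with a machine-readable `report.json` whose every
percentage is stored alongside its numerator and denominator.

A thin command-line wrapper is included at `inst/cli/gonadpi.R`
(`Rscript gonadpi.R simulate|run --config cfg.yaml --out dir`).

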