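# nmdpipe

Annotation of putative nonsense-mediated mRNA decay (NMD) targets from
transcript models, and the downstream statistics used in insulin/IGF-1
longevity transcriptomics — as a tested, offline-reproducible R pipeline.

## What it computes, and for whom

NMD degrades transcripts that terminate translation in a suspicious
context. Three operational marks identify a putative target on an
annotated transcript:

* **PTC (50-nt rule).** Let `j` be the mRNA coordinate of the first base
  after the final exon–exon junction and `e` the first base after the stop
  codon. The transcript is PTC-positive iff `j − e > 50` (strict). Single-
  exon transcripts are never PTC-positive.
* **uORF.** A complete ORF (ATG…stop, stop included) contained entirely in
  the 5′ UTR of the main CDS (itself the longest complete ORF, ties
  5′-most).
* **3′ UTR class.** short ≤ 350 nt < medium < 1,500 nt ≤ long.

Around this core, the package provides the statistics such a study runs:

* χ² fraction tests (Pearson, no continuity correction) for feature
  enrichment among down-regulated transcripts (`down`: log2fc ≤ −1,
  p ≤ 0.1, inclusive);
* rank-sum tests of fold-change by 3′ UTR class (tie + continuity
  corrected normal approximation; exact permutation at n ≤ 10);
* restoration analysis across a WT / `daf-2`-like / `smg-2`-like / double
  design (down in the single mutant, rescued in the double);
* hypergeometric overrepresentation with the conservative EASE variant
  (`p_ease = P(X ≥ k−1) ≥ p_fisher`);
* mRNA half-lives from transcription-shutoff time courses
  (`ln A = −k t`, `t½ = ln 2 / k`), comparative-Ct quantification, and
  two-way ANOVA genotype comparisons;
* Kaplan–Meier / log-rank (Mantel–Cox) lifespan statistics with the
  worm-assay censoring policy.

A synthetic-data module generates every input — genome FASTA, GTF,
expression tables, decay curves, survival tables — with planted ground
truth, so the whole pipeline runs and is tested with no downloads. It is
aimed at computational biologists who want these classification rules and
tests as auditable, seed-reproducible code rather than a one-off script.

## Worked example

```r
library(nmdpipe)

spec <- synthetic_spec(seed = 42, n_transcripts = 300, n_nmd_targets = 60)
g <- gen_genome_and_transcripts(spec, dir = "demo")   # genome.fa, annotation.gtf, truth.tsv
e <- gen_expression(spec, g$truth, dir = "demo")

feats <- cmd_annotate("demo/annotation.gtf", "demo/genome.fa", "demo/features.tsv")
#> biotype filter removed: ncRNA=5, pseudogene=5, rRNA=7, snoRNA=7, tRNA=6
head(feats[c("transcript_id", "n_exons", "utr3_len", "utr3_category",
             "has_ptc", "stop_to_last_junction", "has_uorf")])
#>   transcript_id n_exons utr3_len utr3_category has_ptc stop_to_last_junction has_uorf
#> 1         t0001       4      226         short   FALSE                    50     TRUE
#> 2         t0002       1      157         short   FALSE                    NA    FALSE
#> 3         t0003       3     1041        medium    TRUE                    51    FALSE
#> 4         t0004       3       89         short    TRUE                    84    FALSE
#> 5         t0005       3     1524          long    TRUE                   397    FALSE
#> 6         t0006       3     1138        medium   FALSE                    31     TRUE
```

Note the planted boundary pair: t0001 terminates exactly 50 nt upstream of
its final junction (PTC-negative, strict rule), t0003 exactly 51 nt
(PTC-positive).

```r
de <- classify_de(filter_expression(e), "daf2_vs_WT")
feature_fraction_test(de, feats, "ptc")
#> <nmd_enrichment> ptc vs DE class (daf2_vs_WT)
#>           de
#> feature    down not_down
#>   feature+   25       30
#>   feature-   35      180
#> chi2 = 21.57, p = 3.413e-06; fraction down = 0.4167, not-down = 0.1429
```

41.7% of down-regulated transcripts carry a PTC versus 14.3% of the rest —
the planted depletion of NMD targets in the `daf-2`-like genotype is
detected. Restoration in the double mutant (`fraction_restored = 1` on this
noise level), half-lives and lifespans behave accordingly:

```r
dc <- gen_decay(spec)
fit_decay(dc[dc$gene == "rpl-12.ptc" & dc$genotype == "WT", ])
#> <halflife_estimate> rpl-12.ptc / WT: k = 0.012243 /min, t1/2 = 56.62 min (se_k 0.000386, R2 0.986)
fit_decay(dc[dc$gene == "rpl-12.ptc" & dc$genotype == "daf2", ])
#> <halflife_estimate> rpl-12.ptc / daf2: k = 0.021735 /min, t1/2 = 31.89 min (se_k 0.000561, R2 0.991)

sv <- gen_survival(spec)
logrank_test(sv, "WT", "daf2")
#> <logrank_result> chi2 = 159.5 (df 1), p = 1.422e-36
#>        n observed  expected
#> WT   100       84  30.14908
#> daf2 100       88 141.85092
```

The fitted half-lives recover the planted 60 vs 30 min (shorter under the
`daf-2`-like genotype, as NMD is enhanced), and the log-rank test sees the
roughly doubled lifespan of the `daf-2`-like group.

One command runs everything (byte-reproducible per seed):

```r
cmd_demo(seed = 1, out_dir = "demo_full")   # writes demo_summary.json
```

or from a shell via the bundled launcher:

```sh
Rscript inst/cli/nmdpipe demo --seed 1 --out-dir demo_full
Rscript inst/cli/nmdpipe annotate --gtf demo/annotation.gtf --fasta demo/genome.fa --out features.tsv
```

## Layout

* `R/` — transcript models & GTF/FASTA I/O, ORF annotation, NMD features,
  expression statistics, decay kinetics, survival analysis, synthetic-data
  generators, pipeline/CLI.
* `tests/testthat/` — unit, property and acceptance suites with
  independent brute-force oracles (`helper-oracles.R`).
* `vignettes/nmd-target-annotation.Rmd` — the model, parameter and design
  discussion.
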