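---
title: "Classifying NMD-target transcripts and the longevity assay statistics behind it"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Classifying NMD-target transcripts and the longevity assay statistics behind it}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(nmdpipe)
```

## The problem

Nonsense-mediated mRNA decay (NMD) is an RNA surveillance pathway that
degrades aberrant transcripts and a sizeable minority of normal ones. Three
transcript features mark a putative NMD target:

* a **premature termination codon (PTC)**, operationally a stop codon lying
  more than 50 nt upstream of the final exon–exon junction (the "50-nt
  rule": termination that far upstream leaves an exon-junction complex on
  the mRNA, which recruits the SMG/UPF machinery);
* an **upstream open reading frame (uORF)** — a complete ATG…stop ORF
  contained in the 5′ UTR;
* a **long 3′ UTR**, using the standard three-class convention
  short ≤ 350 nt, medium 350–1,500 nt, long ≥ 1,500 nt.

In *C. elegans*, reduced insulin/IGF-1 signalling (`daf-2` mutants) extends
lifespan, and transcripts bearing these features are preferentially depleted
in `daf-2` animals in an `smg-2`(UPF1)-dependent manner. `nmdpipe`
re-implements the computational side of that analysis as a reusable
pipeline: feature annotation from transcript models, the four-genotype
enrichment and restoration statistics, mRNA half-life estimation from
transcription-shutoff time courses, and lifespan survival statistics — all
exercisable end-to-end on synthetic data with planted ground truth.

## Feature annotation

### Coordinates and the PTC rule

All internal coordinates are 0-based and half-open; GTF input is converted
from 1-based inclusive on read. A junction is represented by the mRNA
coordinate of the first base *after* it, so the stop-to-junction distance is
the plain subtraction `last_junction − cds_end`. The PTC call is strict:
distance 51 is PTC-positive, distance 50 is not, and both boundary cases are
pinned by tests and planted in every synthetic fixture set. Only the 3′-most
junction is consulted, and single-exon transcripts are never PTC-positive
(there is no junction to leave a complex on). A transcript whose stop lies
*downstream* of the final junction gets a negative distance and a negative
call rather than an error, since that is the normal topology.

### ORF discovery and CDS selection

`find_complete_orfs()` scans the three forward frames of the spliced mRNA
and reports only *complete* ORFs — ATG through an in-frame stop, stop
included. The default reports one ORF per (frame, stop) pair anchored at the
5′-most ATG, mirroring start-to-stop region reporting of classic ORF
finders; nested-ATG enumeration is available for uORF bookkeeping. The
minimum length default is 3 nt (the `-minsize 3` convention), which for a
complete ORF is vacuous (≥ 6 nt); it is configurable. Codons containing N
never count as start or stop codons — ambiguity is handled conservatively.

The main CDS is the **longest complete ORF, ties broken 5′-most**. Published
analyses of this kind delegate CDS selection to a Markov-model coding-score
tool; reimplementing that scorer is out of scope, and the selection rule had
to be decided here. The longest-ORF rule is reproducible, oracle-checkable,
and exact on the synthetic data, whose generator guarantees the planted CDS
is uniquely longest (see below). On real transcriptomes it will occasionally
pick a different ORF than a coding-score model would; that is a documented
stand-in, not an inference about the original tooling.

### uORFs

A uORF must start *and* terminate within `[0, cds_start)`. ORFs that start
in the 5′ UTR but overlap the CDS start are counted separately
(`n_overlapping_orfs`) and never set `has_uorf`. Whether a uORF must share
the CDS reading frame is genuinely ambiguous in the source description;
both readings are implemented. The default records the longest uORF and a
frame-match flag without requiring the match; `uorf_frame_match = TRUE`
(CLI `--uorf-frame-match`) switches to the strict reading.

## Expression statistics

Expression tables carry per-condition FPKM, a cuffdiff-style status column,
and per-contrast log2 fold-changes with p-values; the p-values are inputs
(or synthetic), never recomputed from counts — the upstream dispersion model
is out of scope. Filtering keeps status `OK` with FPKM > 0 in every
condition, logging removal counts per reason.

* **DE classes.** `down` means log2fc ≤ −1 and p ≤ 0.1, boundaries
  inclusive; `up` symmetric. The gene-ontology input lists use the relaxed
  cutoff log2fc ≤ −0.4. Both are configurable.
* **Fraction tests.** Enrichment of PTC+ (or uORF+) among down-regulated
  transcripts uses Pearson's χ² on the 2×2 table without continuity
  correction, two-sided, df = 1. The comparator is *all other tested
  transcripts* (fractions "per total transcripts"), not down-vs-up. A table
  with a zero margin is reported as untestable rather than given a fake p.
* **Rank-sum tests by 3′ UTR class.** Pairwise two-sided Mann–Whitney tests
  with tie **and continuity** corrections in the normal approximation. The
  continuity correction is a deliberate choice: at n = 4 vs 4 the
  uncorrected approximation deviates from the exhaustive permutation p by up
  to 0.12, the corrected one by at most 0.03, and it matches the common
  implementation default. When both samples have n ≤ 10 the test switches to
  exact enumeration of all label assignments.
* **Restoration.** Transcripts down in the `daf-2`-like contrast are called
  restored when the double-mutant-vs-single log2fc is ≥ 0 (any increase);
  the threshold is configurable because the original cutoff is unstated.
  With the default on symmetric noise, the null false-positive rate is 0.5 —
  a property the acceptance suite checks rather than assumes.
* **Overrepresentation.** One-sided hypergeometric tails; the EASE score
  recomputes the tail after decrementing the overlap by one, which can only
  enlarge it, so `p_ease ≥ p_fisher` is asserted as an invariant. Raw
  p-values are reported to mirror the primary convention; Benjamini–Hochberg
  columns are available but off by default.

## Decay kinetics

Relative qPCR quantification uses the comparative Ct method,
`2^(−ΔΔCt)`, which is invariant to shifting all Ct values — a property
under test. Half-lives come from the log-linear fit
`ln(abundance) = −k·t` with the intercept fixed at 0, because each
replicate is normalized to the reference RNA and then to its own t = 0
value; a free-intercept variant exists as a robustness check. The
log-linear (rather than nonlinear exponential) fit is variance-stabilizing
under multiplicative noise and has a closed form; no fitting method was
specified by the source, so this choice is the package's own. Zero or
negative abundances are replaced by half the smallest positive observation
(configurable drop policy) so the log transform stays defined; the count of
adjusted points is reported. `t_half·k = ln 2` holds to machine precision by
construction, and a non-decaying series (k ≤ 0) is flagged rather than given
a negative half-life. Genotype comparison is a fixed-effects two-way ANOVA
(genotype × time as factors) on a balanced design, where type I and type II
sums of squares coincide; unbalanced cells are an error naming the cell.

## Survival analysis

Kaplan–Meier curves and the log-rank (Mantel–Cox) test are computed via the
`survival` package behind this package's record contract, with hand-computed
product-limit oracles and an exhaustive permutation oracle pinning the
conventions: deaths are processed before censorings tied on the same day,
and the variance is the hypergeometric one at each death time. Mean
lifespans average death events only; censored animals are counted
separately and remain in risk sets until removal. Days are integers (worms
are scored on transfer days); fractional input is accepted.

## The synthetic-data generator

The generator is first-class, tested code, and its defaults *are* the
stated world of the design it emulates:

* four genotypes (WT, `daf-2`-like, `smg-2`-like, double), **duplicate**
  samples, matching the duplicate RNA collections of the emulated design;
* target effects: −2 log2 units in the `daf-2`-like mutant, +1 in the
  `smg-2`-like mutant (targets accumulate when decay is lost), +2 in the
  double relative to the single (restoration); replicate noise s.d. 0.25
  log2 units. These magnitudes are not printed anywhere in the source; they
  were chosen once as what a transcriptomicist would call a strong,
  comfortably detectable NMD effect at duplicate sampling, and are not
  revisited;
* decay curves at half-lives of 60/30 and 80/40 min (WT vs `daf-2`-like),
  5 timepoints over 2 h, 3 replicates, lognormal noise s.d. 0.1 —
  NMD-target half-lives shorten under reduced insulin/IGF-1 signalling;
* Weibull lifespans (shape 4) with scale 17 vs 35 days and 10% censoring,
  i.e. wild-type-like mean lifespan near 15 days and a roughly doubled
  `daf-2`-like lifespan at 20 °C.

Transcripts are constructed **feature-first**: the CDS length, the planted
uORF, the 3′ UTR class and the stop-to-junction distance are placed to
satisfy the requested label, and the sequence outside the planted elements
is scrubbed so that no stray ATG exists anywhere (including across every
junction and element boundary). Consequently the ORF set of each synthetic
mRNA is exactly {CDS} or {CDS, uORF}, the planted CDS is uniquely longest,
and feature recovery is exactly 100% — which is what makes "accuracy = 1"
a meaningful oracle rather than a tautology. Boundary transcripts with
distances exactly 50 and 51 nt are forced into every fixture set.

What the generator does **not** emulate: realistic *C. elegans* sequence
composition, alternative isoforms sharing exons, read-level noise (no
FASTQ), cuffdiff's dispersion model (p-values come from small-replicate
t-tests, which is enough to exercise threshold logic), or
expression-dependent censoring. A green planted-recovery test therefore
establishes the correctness of the coordinate arithmetic and classification
logic, not robustness to ambiguous real-world gene models — transcripts
whose CDS a coding-score model would call differently are outside what
these tests can certify.

## Numerical and degenerate-input choices

* Strict inequality at the 50-nt boundary, pinned by tests on both sides.
* χ² tables with a zero margin → untestable, p = NA (never 0 or 1).
* Rank-sum classes with fewer than 2 members → comparison skipped with a
  warning.
* No-decay series → flagged, `t_half = NA`; all-nonpositive abundances →
  error.
* Zero total deaths → log-rank result flagged with `note = "no deaths"`.
* Unknown biotypes (including annotation-less novel transcripts) are
  filtered and logged, never silently kept.
* Every writer stamps a provenance line (seed + config hash); outputs are
  byte-identical across reruns of the same seed, with timestamps off by
  default.

## Known limitations

* CDS selection is longest-ORF, not coding-score-based (above).
* Read-based alternative 3′ UTR calling is out of scope; 3′ UTR lengths are
  annotation-derived only.
* DE p-values are never recomputed from fragment counts.
* The log-rank test is two-group; multi-group designs are handled pairwise.
* EASE/Fisher p-values ignore gene-length or expression-level bias in term
  membership, as does the convention they mirror.
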