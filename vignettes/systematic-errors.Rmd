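---
title: "Detecting and correcting systematic base-call errors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting and correcting systematic base-call errors}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(syserr)
library(data.table)
```

## The problem

Short-read sequencers make individual base-call errors at rates that
depend on read position and local sequence.  Beyond those effects, some
*genomic* positions accumulate errors from many independent reads far
in excess of any per-read model — often with every erroneous call on
one read orientation, in a GG(T) sequence context, as a T>G
substitution, and with locally depressed quality scores.  Such
*systematic errors* occur at roughly 1 in 1000 covered positions in
deep Illumina-type data and are easily mistaken for heterozygous sites,
rare variants, or RNA edits, especially when the expected variant
allele fraction is not 0.5 (RNA-Seq, pooled samples).

`syserr` implements, end to end: detection statistics for such sites,
characterization summaries, a logistic-regression classifier that
separates them from true heterozygous sites, and a read simulator that
makes the whole pipeline testable without any external dataset.

## Overlapping mate pairs as an error oracle

When a fragment is shorter than twice the read length, its two mates
overlap and each overlapped position receives two calls sequenced from
the *same molecule* in opposite directions.  At a position with
reference base $r$ and calls $(b_f, b_r)$:

* both equal $r$: **reference-pair**;
* both differ from $r$ and agree: **SNP-pair** (a real variant travels
  with the molecule);
* exactly one differs: **error-pair** — the differing call is a
  verified base-call error;
* both differ and disagree: **discordant** (two independent errors).

Discordant pairs are excluded from all counts.  The corresponding
double-error SNP-pair (both mates wrong, identically) has probability
on the order of $\epsilon^2/3$ per pair and is ignored, as is standard.
The background per-pair error rate is

$$p = \frac{\#\text{error-pairs}}{\#\text{pairs}}$$

over positions with at least `min_coverage = 10` analysis pairs (the
deep methyl-Seq-like dataset this design emulates gives
$p \approx 0.0026$).

## Detection statistics

**Binomial site test.** With background rate $p$, the error count $K$
at a position with $n$ pairs is Binomial$(n, p)$ under the null; the
site p-value is the exact upper tail $P(K \ge i \mid n)$, including the
observed count.  Significance is declared under Bonferroni control at
level $\alpha / m$ with $m$ the number of tested sites, which bounds
the probability of *any* false positive by $\alpha$ — the annotated
set is deliberately conservative because it is used to characterize
the phenomenon.  `expected_proportion_histogram()` gives the
complementary genome-wide view: from the coverage spectrum $c_j$ it
computes the expected number of sites at each error proportion,
$E[B_i] = \sum_j c_j \binom{j}{k_{ij}} p^{k_{ij}} (1-p)^{j-k_{ij}}$;
an observed excess in the high-proportion bins is the signature of
systematic error.

**Quality-conditioned test.** Conditioning on each call's
quality-implied error probability $e_i = 10^{-q_i/10}$, $K$ is
Poisson-binomial; `quality_dp_pvalue()` computes the exact tail by the
recurrence
$P(K_n = k) = e_n P(K_{n-1} = k-1) + (1-e_n) P(K_{n-1} = k)$
in $O(n^2)$ time and $O(n)$ space.  This asks a sharper question: are
the errors surprising *given the qualities the machine itself
reported*?

**Directionality screen.** Without overlapping mates (single-end data),
error-pairs cannot be observed.  `scan_directionality()` instead tests
each position covered by at least 10 forward and 10 reverse reads for
association between mismatch occurrence and read orientation with a
Pearson chi-square (2x2, 1 df, no continuity correction by default; a
flag enables Yates, and expected cells below 5 raise a warning).  This
screen is statistically weak — strongly affected sites can be missed —
which is the motivation for the classifier below.

## The classifier

For a candidate site $l$ with at least one mismatching call, the
direction (forward/reverse read orientation) with the larger mismatch
proportion is chosen ($q_1 \ge q_2$, ties to forward, an uncovered
direction counts as 0).  The feature vector is

$$x_l = (b_{-2},\; b_{-1},\; b_0,\; q_1 - q_2,\; q_1,\; PT(w_0, w_1))$$

where $b_i$ is the reference base $i$ places from $l$ walking in the
chosen direction (read off the reverse complement when that direction
is reverse), and $PT$ is the paired t statistic between the quality
scores at the site ($w_0$) and one position onward ($w_1$), paired by
read over all reads covering both positions regardless of orientation.
Quality scores at systematic-error sites sit well below their
neighbours', so $PT$ is strongly negative there and near zero at true
heterozygous sites.

A logistic regression (systematic_error = 0, heterozygous = 1) is fit
by maximum likelihood over the one-hot-encoded design (reference level
A; 13 coefficients with the intercept).  Training labels come from
overlapping-pair evidence: sites with pair coverage of at least 40 and
forward-strand mismatch fraction between 10% and 90% are labelled
heterozygous if *every* difference from the reference is a SNP-pair
and systematic errors if every difference is an error-pair; mixed
sites are excluded and the larger class is randomly downsampled so
predictions are feature-based only.  Because the two classes are
nearly separable in $PT$, perfect separation is common; the fit then
falls back to a small ridge penalty ($\lambda = 10^{-4}$, intercept
unpenalized) and is flagged.

Coverage changes which features carry information, so
`train_bank()` retrains after subsampling 20/40/60/80/100% of the
reads (single-end reduced first) and keys each model by its realized
mean training coverage; `classify_sites()` picks the model closest to
the dataset's mean coverage (ties to the higher coverage) and
partitions the candidate list at posterior 0.5, with ties labelled
heterozygous.  Candidates default to positions with at least 10% and
at least 5 mismatching calls.  Rejected sites (no coverage, no
mismatch, contig edge) are reported with reasons.

## The simulator: a stated world

The generator emulates the kind of dataset in which overlapping-pair
labelling is possible — a methyl-Seq-like library:

* 76 bp paired reads from 50-300 bp fragments;
* fragments drawn at *discrete loci* (restriction-digest libraries
  concentrate coverage at fragment sites rather than spreading it
  uniformly), one locus per planted site with its mate-overlap region
  containing the site, plus background loci every 400 bp; per-locus
  copy numbers are negative binomial with mean `coverage` (default 35)
  and size 3, reproducing the heavy-tailed site coverage such data
  shows.  This concentration is also what keeps deep pair coverage
  affordable in tests — uniform fragment placement would need roughly
  an order of magnitude more reads for the same pair coverage;
* baseline per-base error rate calibrated so the per-pair rate is
  0.0026 (`base_error_for_pair_rate()`; an error-pair needs exactly
  one of two calls wrong, so $\epsilon = (1 - \sqrt{1-2p})/2$);
* heterozygous sites at variant allele fraction 0.5, alleles assigned
  per fragment (mates are consistent);
* systematic-error sites: errors only on the affected read
  orientation, at rate `eps_sys` = 0.4 per call; half the sites are
  placed at GGT-context T positions (the genome itself is generated
  with 4-fold GGT enrichment); the wrong call is drawn once per site
  from a substitution matrix concentrated on calls to G and then
  reused — the error is systematic, not random; erroneous calls carry
  quality depressed by 10 below the Phred(32, 3) truncated-normal
  quality model.

Reads are emitted pre-aligned (SAM with exact coordinates); alignment
is out of scope, and an optional FASTQ export exists for integration
with real aligners.  Everything derives from one mandatory seed;
outputs are byte-identical across runs, and a separate reads-stage
seed allows replicate experiments over the same genome and truth.

What the simulator does *not* model: bisulfite chemistry, true
restriction-site fragment boundaries, PCR duplicates, indels,
position-in-read error gradients, or multi-mapping.  A green test
therefore establishes that the statistics and the classifier behave as
designed on data with the stated error structure — not that they are
robust to alignment artifacts or library chemistry these modules never
see.

## Numerical and design choices

* Coordinates are 0-based half-open internally, 1-based in all output
  files (stated in their headers).
* p-values are clipped to $[10^{-320}, 1]$; posteriors to
  $[10^{-12}, 1-10^{-12}]$ (ridge fits under separation can saturate
  the logistic in double precision).
* Histogram bins are fixed width (default 0.02), right-open except the
  last; exact proportions $k/j$ are pooled into bins.
* Paired-t degeneracies use bounded sentinels: fewer than 2 pairs
  gives 0 (flagged), zero-variance differences give $\pm 100$ —
  keeping design matrices finite without discarding sites.
* Mate quality scores are kept separate; only the quality-DP
  annotation of pair data combines them, as
  $e_f(1-e_r) + e_r(1-e_f)$, the probability that exactly one call of
  the pair is wrong.
* The GGT-restricted annotation uses the motif-site count as its
  Bonferroni family and, by default, the error rate measured at the
  motif sites themselves as its background.
* The "directionality-only" ablation model uses only $q_1 - q_2$ (plus
  intercept) and is the comparison baseline in the benchmark.
* Unmapped, secondary, supplementary, QC-fail and duplicate records
  are excluded at ingestion (mask overridable); insertions have no
  reference coordinate and contribute nothing, deletion gaps
  contribute no call, reference-N positions are dropped.

## Benchmark protocol

`benchmark_classifier()` reproduces the coverage-stratified
evaluation: label sites from full-coverage pairs, cap each class at
338 sites, reduce to single-end, then per read fraction
(0.2/0.4/0.6/0.8) refine the labelled sites to those retaining a
mismatch, train on a random half of each class and score the held-out
half, for the full model and the ablation.  On the packaged
acceptance-scale dataset the full model reaches ~0.97 accuracy at the
lowest fraction, is non-decreasing in coverage, and strictly dominates
the ablation at every fraction (the acceptance suite computes these
numbers; this vignette states no result the tests do not themselves
compute).  One caveat on coverage labels: planted loci overlap at the
test density, so the realized read coverage at labelled sites is
higher than `fraction x 35`; the fraction, not a nominal coverage
label, is the protocol variable.

## Known limitations

* The directionality screen needs both strands covered; amplicon-like
  single-strand data cannot be screened that way.
* Training requires overlapping-pair data (classification does not).
* The classifier inherits the candidate filter's blind spots: sites
  with fewer than 5 mismatching calls are never candidates.
* Chi-square p-values are asymptotic; small strand coverages near the
  10-read floor are only warned about, not exactified.
* The simulator's planted truth makes labels unambiguous; real
  training data contains mislabelled sites at some rate, which would
  soften the separation the ridge fallback handles here.
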