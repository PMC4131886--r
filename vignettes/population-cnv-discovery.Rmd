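---
title: "Population-scale CNV discovery from SNP-array signals: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Population-scale CNV discovery from SNP-array signals: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(popcnv)
```

## The problem

Genome-wide SNP genotyping arrays measure, at every probe, a normalized
total-intensity ratio (Log R Ratio, LRR — approximately 0 at diploid copy
number, negative in deletions, positive in duplications) and a normalized
allelic ratio (B Allele Frequency, BAF — clustering at 0, 1/2 and 1 for the
three diploid genotypes). Copy number variants (CNVs) leave a joint
signature in both tracks: a one-copy deletion depresses LRR and removes the
heterozygote BAF band; a homozygous deletion drives LRR far negative and
destroys allelic signal entirely; a duplication raises LRR and splits the
heterozygote band towards 1/3 and 2/3.

Building a reliable population reference catalogue of CNVs from thousands
of array samples requires more than a caller: sample- and probe-level
quality control, agreement between two algorithmically independent callers,
a ledger of size/density/region filters, merging of per-sample calls into
copy number variable regions (CNVRs) with per-population frequencies, and
statistical machinery to compare those frequencies across populations.
`popcnv` implements that whole workflow, plus a synthetic signal generator
so every stage is testable without access to genotyping data.

## The two callers

### Four-state hidden Markov model

The HMM has states HOMDEL (copy number 0), HETDEL (1), NORMAL (2) and DUP
(3 or more), decoded per chromosome by the Viterbi algorithm over probes
ordered by position.

*Emissions.* Each state emits LRR from a Normal distribution and BAF from a
genotype-cluster mixture whose weights depend on the probe's population
frequency of the B allele (PFB): for NORMAL the clusters \{0, 1/2, 1\} carry
Hardy–Weinberg weights $(1-p)^2, 2p(1-p), p^2$; HETDEL has clusters
\{0, 1\} with weights $(1-p, p)$; DUP has \{0, 1/3, 2/3, 1\} with trisomic
weights; HOMDEL BAF is uniform noise. BAF values exactly 0 or 1 are treated
as truncated-cluster point masses (all mixture mass at or beyond the
boundary), which is how clipped array exports behave.

*Transitions.* At inter-probe distance $d$ the probability of leaving the
current state is $p_{\mathrm{off}}\,(1 - e^{-d/D})$, split evenly among the
other three states. Defaults $p_{\mathrm{off}} = 10^{-4}$ and $D = 100$ kb
make the expected number of spurious segments on a null genome well below
one; both are exposed via `hmm_params()`. The emission means/SDs default to
canonical Illumina-like values — LRR means $(-3.5, -0.66, 0, +0.40)$ and SDs
$(1.3, 0.25, 0.18, 0.20)$ for copy numbers 0–3 — which are surrogates for
the unpublished model files of the array-calling tools of that era; they
are deliberately shared with the signal generator's defaults so that
recovery tests measure algorithmic behaviour, not parameter mismatch.

Ties in the dynamic program are broken toward NORMAL, so a flat stretch of
evidence never produces a call. Each maximal run of non-NORMAL states
becomes one call spanning the first to the last probe of the run (no
midpoint extension), scored by the summed per-probe log-likelihood margin
over NORMAL.

### Circular binary segmentation

The second caller ignores the genotype model and asks only where the LRR
mean changes. For an ordered vector the circular max-T statistic scans
every arc $(i, j]$ against its wrapped complement with a pooled-variance
two-sample t statistic (`max_t_statistic()`, exhaustive $O(n^2)$ scan in
C++). A split is accepted when its permutation p-value
$(b+1)/(R+1)$ — permuting values within the tested stretch — is at most
`alpha`, then the procedure recurses into the resulting pieces
(`cbs_segment()`). Defaults `alpha = 0.01`, `n_perm = 1000`, minimum arm
width 2; the $(b+1)/(R+1)$ estimator avoids zero p-values. The permutation
loop stops early once the exceedance count already forces $p >$ `alpha`;
the accept/reject decision is unchanged, but because early stopping
consumes a different amount of the RNG stream, exact-reproducibility
comparisons across `alpha` values should set `early_stop = FALSE` (the
invariant "smaller `alpha` never adds breakpoints" holds exactly in that
mode).

Segments are classified from their mean LRR and BAF distribution
(`classify_segment()`): HOMDEL below $-2.0$; HETDEL below $-0.3$ with an
empty 0.5-centred BAF band; DUP above $+0.2$ with an empty 0.5 band; else
NORMAL. Two design points deserve note:

* The *mid-band* used for classification is $(0.4, 0.6)$, not the wider
  $(0.25, 0.75)$ band reported descriptively per segment. A duplication's
  heterozygote clusters sit at 1/3 and 2/3 — inside $(0.25, 0.75)$ — so a
  het-band-emptiness test on the wide band can never accept a true
  duplication; the $(0.4, 0.6)$ band separates all four states cleanly.
* The HETDEL band-emptiness cutoff defaults to 0.10 rather than a stricter
  0.05: segment boundaries from max-T splits are accurate only to one or
  two probes, and a single diploid heterozygote dragged into a 10–40-probe
  deletion segment should not veto it. A diploid segment's mid-band
  fraction is ≈ 0.36 on average, many standard deviations above either
  cutoff. All five thresholds are configurable.

Adjacent same-class segments are merged before calls are emitted.

## Consensus and quality control

Per sample, the two call sets are intersected (`consensus_calls()`): a pair
must share chromosome and direction (DEL vs DUP) and each call must be
covered by the intersection for at least 60% of its own length — reciprocal
overlap, the stricter of the two readings of "60% overlapping length".
Matching is greedy one-to-one by descending intersection length with a
leftmost-start tie-break, so replication counts are well defined. The
consensus call is the *intersection* interval, its copy-number class taken
from the HMM call (the model-based caller distinguishes one- from two-copy
losses more reliably), and its probe count recounted inside the
intersection. Concordance is reported with the segmentation-based call set
as denominator.

The filter ledger then rejects, in order, with every rejection tagged:
calls on sex chromosomes; probe density below 1 probe / 30 kb; deletions
with fewer than 5 probes or length ≤ 5 kb; duplications with fewer than 10
probes or length ≤ 10 kb; calls more than 50% inside centromere/telomere
intervals; and finally every call of any sample retaining more than 100
calls (an array-failure signature). Boundary semantics are strict
inequalities exactly as stated; kept + rejected always equals input
(conservation is tested).

## CNVRs and population comparison

Filtered calls from all samples merge transitively into discrete CNVRs
(closed-coordinate interval union via `IRanges::reduce`; sharing a single
base merges, a one-base gap does not). A CNVR is DEL, DUP, or COMPLEX when
member directions mix. Frequencies count each individual once per CNVR,
divided by the population's manifest size; regions at ≥ 5% are flagged
common, and `singleton_filter()` drops regions seen in one individual
before cross-catalog comparison (`degree_of_match()`, binned at 1/5/10/20%
frequency edges).

Cross-population comparison works on gene-overlapping loci: a sample
carries a gene when any filtered call overlaps it. For each locus and
population pair, the observed statistic is the absolute carrier-frequency
difference; the null permutes group labels over the pooled carrier vector —
implemented by the equivalent hypergeometric draw, cross-validated against
the exact hypergeometric tail — with empirical p-value $(b+1)/(R+1)$ at
$R = 5000$. The nominal significance cut of 0.0002 equals $1/5001$ only at
the attainable floor, so the significance flag fires at
$p \le 1/(R+1)$ *or* $p < 0.0002$. Per pair, the 10 most positive and 10
most negative significant signed differences are selected and the union
deduplicated. Frequencies of the selected loci are row-scaled to mean 0,
variance 1 (constant rows flagged, left centred), and populations are
clustered by Ward's minimum-variance criterion on Euclidean distances
(`stats::hclust(method = "ward.D2")`; a from-definition brute-force Ward is
the test oracle). Homozygous-deletion bookkeeping splits a locus's carriers
by zygosity and reports homozygous/total proportions to 3 decimals.

## The synthetic generator

`simulate_cohort()` emulates a multi-population array experiment:

* **Genome.** 22 autosomes + X, each 1.085 Mb, 217 probes per chromosome —
  5 kb spacing, the density of a ~600k array. Miniature chromosomes at
  realistic *density* (rather than full-length chromosomes at sparse
  density) keep the probe-density and size filters meaningful.
* **Signals.** Outside CNVs: LRR $\sim N(0, 0.18)$; BAF genotype clusters
  (SD 0.03) with Hardy–Weinberg weights from per-probe PFB
  $\sim U(0.05, 0.95)$. Inside spiked CNVs the state-specific emissions
  above apply. 0.5% of genotypes are emitted as no-calls to drive
  call-rate QC; X is emitted hemizygous for males so sex inference has
  signal. Homozygous-deletion probes are emitted as no-calls, as array
  software does.
* **Truth.** The bundled scenario spikes 10 loci (15–40 probes; copy
  numbers 0, 1, 3) into 3 populations × 50 samples, with carrier
  frequencies covering \{0.01, 0.05, 0.2, 0.5\} and several loci strongly
  differentiated between populations. Carriers are independent Bernoulli
  draws at the target frequency, so realized frequencies are Binomial.
  The two copy-number-0 loci are kept to 15 probes: their extreme LRR
  (mean −3.5, SD 1.3) occupies a 100-fold larger *fraction* of a miniature
  genome than of a real array, and larger homozygous loci would push
  carriers over the 0.3 LRR-SD sample-QC bound — an artefact of scale, not
  of biology.

What the generator does **not** model: GC waves and batch effects in LRR,
linkage disequilibrium between probes, family structure, multiallelic
loci, mosaic (non-integer) states, and platform mixtures. Passing recovery
tests therefore demonstrate algorithmic correctness under the stated noise
model, not performance on any particular array product.

## Numerical and procedural choices

* Coordinates are 1-based closed everywhere; lengths are
  $end - start + 1$; BED input is converted on read and nowhere else.
* HWE probe filtering uses the 1-df chi-square goodness-of-fit test
  (deterministic, standard GWAS-QC practice) at $10^{-5}$, computed per
  population label; a probe failing in any population is removed for all.
  Monomorphic probes return p = 1.
* Sex inference calls female at X heterozygote fraction ≥ 0.10, male
  below 0.02, unknown between or with fewer than 50 X probes.
* The sample-QC LRR SD is the plain SD of autosomal LRR, threshold 0.3
  strictly; call-rate threshold 0.98 strictly.
* Ties in ranking (top-gene selection) break by smaller p-value then
  genome order; chromosome order is numeric with X last.
* `run_pipeline()` derives per-sample CBS seeds from the global seed, so a
  run is reproducible end to end; rerunning with the same configuration
  and seed produces byte-identical output files.
* Genome coverage uses the summed supplied autosome lengths as
  denominator; when run through `run_pipeline()` the per-chromosome
  maximum probe position stands in for unknown chromosome lengths.

## Problem sizes used in validation

The packaged validation exercises the full pipeline on the bundled
3 × 50-sample scenario (~5,000 probes), checks the Viterbi decoder against
exhaustive path enumeration at up to 8 probes, the max-T scan against a
brute-force double loop at up to 50 values, Ward linkage against
from-definition merging at up to 6 populations, the HWE statistic against
a hand-built formula for every genotype triple up to 30 samples, the
permutation test's type-I error on 1,000 null loci of 200 + 200 samples,
and structure recovery on 20 replicates of a 12-population, 35-locus
frequency matrix. These sizes were chosen so the complete validation runs
in minutes on a laptop while every stochastic check retains comfortable
statistical margin.

## Known limitations

* The callers assume integer copy number ≤ 3+; high-amplitude
  amplifications and mosaic events are out of scope.
* The CBS permutation test shuffles within the tested stretch only, which
  is slightly anticonservative for heavy-tailed noise.
* Consensus requires both callers; a CNV seen by only one caller is
  discarded by design, trading sensitivity for specificity exactly as the
  dual-algorithm workflow intends.
* The association test treats samples as unrelated; family structure
  would invalidate the permutation null.
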