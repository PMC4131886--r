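# popcnv

Population-scale copy number variant (CNV) discovery and comparison from
SNP-array intensity signals.

Genotyping arrays report, per probe, a Log R Ratio (LRR; ≈ 0 at diploid
copy number, negative in deletions, positive in duplications) and a
B Allele Frequency (BAF; clustering at 0, ½, 1 for diploid genotypes).
`popcnv` is for researchers building population reference CNV catalogues
from such data — the kind of resource used to judge whether a CNV seen in a
patient is a benign population polymorphism or a candidate pathogenic
variant. It implements the complete workflow:

1. **Quality control** — sample-level (autosomal LRR SD > 0.3, call rate
   < 98%, reported/genotypic sex mismatch) and probe-level
   (Hardy–Weinberg chi-square, p < 10⁻⁵) exclusion.
2. **Dual-algorithm calling** — a four-state hidden Markov model
   (HOMDEL/HETDEL/NORMAL/DUP) with PFB-weighted BAF-mixture emissions and
   distance-decay transitions, decoded by Viterbi; and circular binary
   segmentation of LRR with permutation-validated breakpoints, segments
   classified from mean LRR and the BAF band structure.
3. **Consensus + filters** — per-sample reciprocal-overlap (≥ 60% of both
   calls) intersection of the two call sets, then the filter ledger:
   ≥ 1 probe/30 kb density, ≥ 5 probes & > 5 kb for deletions, ≥ 10 probes
   & > 10 kb for duplications, ≤ 50% centromere/telomere overlap, autosomes
   only, ≤ 100 calls per sample.
4. **CNVR catalogue** — transitive interval merging of calls across
   individuals into copy number variable regions, per-population carrier
   frequencies, common-region flag (≥ 5%), genome-wide summary, gene and
   syndrome-region annotation, cross-catalogue degree of match by
   frequency bin.
5. **Population comparison** — per-locus permutation association
   (statistic |f₁ − f₂|, empirical p = (b+1)/(R+1), R = 5000,
   significance at p < 2×10⁻⁴), top-10-up/top-10-down gene selection per
   population pair, row scaling to mean 0 / variance 1, and Ward
   hierarchical clustering of populations on Euclidean distances, with
   Newick export.

A synthetic multi-population signal generator (`simulate_cohort()`) with
spiked ground-truth CNVs makes the whole pipeline testable end to end; see
the methods vignette (`vignettes/population-cnv-discovery.Rmd`) for the
model, parameter defaults and design rationale.

## Worked example

Simulate two populations of 20 samples (120 probes per chromosome here to
keep it quick), run the full pipeline, and inspect the catalogue:

```r
library(popcnv)

co  <- simulate_cohort(populations = c(POP_A = 20L, POP_B = 20L),
                       n_probes_per_chrom = 120L, seed = 7)
res <- run_pipeline(co$signals, co$map, co$manifest,
                    config = pipeline_config(cbs_n_perm = 500L, seed = 8))
res
#> popcnv pipeline result
#>   samples passing QC : 38 / 40
#>   HMM / CBS calls    : 85 / 86
#>   consensus (kept)   : 84 (68)
#>   CBS concordance    : 0.977
#>   CNVRs              : 9 (del 6, dup 3, complex 0)
#>   median calls/genome: 1
```

Two samples failed QC (inflated LRR SD), the callers agreed on 97.7% of
segmentation calls, and 68 consensus calls survived the filter ledger.
The catalogue rows carry per-population frequencies:

```r
head(res$cnvrs[, c("cnvr_id", "chrom", "start", "end", "type",
                   "n_carriers", "freq_POP_A", "freq_POP_B", "common")])
#>    cnvr_id chrom  start    end type n_carriers freq_POP_A freq_POP_B common
#>  CNVR_0001     1 193285 392970  DEL         19 0.63157895  0.3684211   TRUE
#>  CNVR_0002     2 648260 783575  DEL          1 0.05263158  0.0000000   TRUE
#>  CNVR_0003     3 146658 292538  DUP         10 0.31578947  0.2105263   TRUE
#>  CNVR_0004     4 294986 363852  DEL          4 0.05263158  0.1578947   TRUE
#>  CNVR_0005     5 635664 833708  DUP          4 0.21052632  0.0000000   TRUE
#>  CNVR_0006     6  95164 209842  DEL          4 0.00000000  0.2105263   TRUE
```

CNVR_0001 recovers a deletion locus spiked at 50% in POP_A and 37% realized
in POP_B; CNVR_0005 a duplication absent from POP_B. A frequency contrast
of 26/40 vs 3/40 carriers at a locus is highly significant under the
permutation test — its p-value sits at the attainable floor 1/5001:

```r
a <- permutation_association(26, 40, 3, 40, n_perm = 5000, seed = 9)
sprintf("stat=%.3f  p=%.3g  significant=%s", a$statistic, a$p_value, a$significant)
#> "stat=0.575  p=0.0002  significant=TRUE"
```

A thin command-line interface over the same functions is installed as
`exec/popcnv` (verbs `simulate`, `qc`, `call-hmm`, `call-cbs`, `consensus`,
`cnvr`, `run`).

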