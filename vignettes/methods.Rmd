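---
title: "Detecting batch-biased somatic variant calls: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting batch-biased somatic variant calls: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(batchbias)
```

## The detection model

A somatic variant call is *batch-biased* when its carriers concentrate in
one processing batch beyond what carrier frequency alone explains. For a
cohort of $N$ tumor samples, a variant site $v$ with $K$ carriers, and a
batch $B$ of size $n$, the null hypothesis is that carriers are
exchangeable across batches, so the number of carriers inside $B$ is
$X \sim \mathrm{Hypergeometric}(N, K, n)$. With $a$ observed carriers in
$B$ the one-sided Fisher exact P-value is $P = \Pr[X \ge a]$. Counting is
sample-level: a sample listed twice for the same site is one carrier,
because the contingency table counts samples, not MAF rows.

The test is one-sided (enrichment) by default, because a processing
artifact produces carriers *inside* the affected batch; a two-sided
variant (summing the probabilities of all tables with point probability
at most that of the observed table, within relative tolerance $10^{-7}$
to absorb floating-point ties) is available via
`detection_params(alternative = "two_sided")`.

### Filters and multiplicity

Three screening rules bound the test set (defaults in
`detection_params()`):

* `min_batch_size = 6` — batches of more than 5 samples are testable;
  smaller batches cannot reach informative configurations.
* `min_carriers_in_batch = 3` — a variant needs at least 3 carriers
  inside the tested batch; with 2 carriers even complete concentration is
  unremarkable, and singleton calls are dominated by private mutations.
* `p_threshold = 1e-5` — a stringent fixed cut appropriate for screening
  $10^3$–$10^5$ tests per dataset.

Benjamini–Hochberg q-values are computed per dataset over all tests
actually performed (all batch variables together); the `biased` flag
itself uses the raw-P threshold so that the call set does not depend on
how many other variants happened to be testable. Both numbers are
reported so either convention can be applied downstream.

### Representative batches

Batch variables alias each other (a plate often maps onto one shipment
date or one center), so the same artifact surfaces under several batch
IDs. `select_representative_batches()` links two IDs when they share more
than 75% of their biased variants and keeps, per linked component, the ID
with the most biased variants. The overlap denominator is the *smaller*
set (containment), because aliased IDs can have very different set sizes;
Jaccard is available by flag. Ties break lexicographically so results are
reproducible.

## Sequence-context characterization

* **Flanks.** `extract_flanks()` takes the $w$ reference bases 5' of the
  variant start and 3' of the variant end (1-based inclusive
  coordinates). For deletions the windows lie outside the deleted
  interval; for insertions the left window ends at the insertion point.
  The two sides are scanned separately so a homopolymer run never spans
  the variant itself — the variant base is the uncertain call.
* **GC content** is computed on 10 bases per side by default (20 flanking
  bases total; `gc_w` is configurable since "20 flanking nucleotides"
  admits both the per-side and the total reading), excluding `N` from
  numerator and denominator.
* **Homopolymer runs.** Per nucleotide, the maximum run length within
  each side; `long_run_fraction()` reports the fraction of variants whose
  maximum run strictly exceeds 5 within windows of 10–50 bp. Long runs
  mark polymerase-slippage-prone loci, the classic indel-error context.
  Distribution shifts between biased and unbiased variants are tested
  with a two-sided Mann–Whitney U (`rank_shift_test()`; exact enumeration
  when $|x||y| \le 400$ without ties, otherwise normal approximation with
  tie and continuity correction). The Mann–Whitney choice is a design
  decision — a location-shift test on an ordinal quantity with heavy
  ties; Kolmogorov–Smirnov would also serve and the raw per-variant
  features are exported so any test can be re-run.
* **Regions.** A deliberately simple gene-model classifier replaces
  transcript-level annotation: `splicing` within `splice_window = 2`
  bases of an internal exon boundary on the intron side, then `exonic`,
  `intronic`, `intergenic`, with precedence splicing > exonic > intronic
  across overlapping genes. Functional classes (frameshift, stop-loss,
  ...) are taken from the MAF's classification column rather than
  recomputed — consequence prediction is out of scope.
* **Motifs.** `build_pfm()` tallies per-position nucleotide counts over
  aligned windows (`N` excluded per column); information content is
  $IC = 2 + \sum_n f_n \log_2 f_n$ bits with the optional small-sample
  correction $3/(2 n \ln 2)$. Consensus strings use a majority threshold
  (default 0.7) and IUPAC degenerate codes for mixed positions. k-mer
  enrichment is exhaustive: every k-mer present in the foreground is
  tested by presence/absence per sequence with the same one-sided Fisher
  machinery and BH adjustment. This is a desk-scale replacement for EM
  motif finders: on windows of ~20 bp with dozens of foreground
  sequences, exhaustive testing recovers planted motifs directly.
  Minus-strand contexts are reverse-complemented before PFM building so
  acceptor `AG` dinucleotides align in transcript orientation.

## Phylogeny and the clustering score

Binary per-sample mutation profiles (sample × site presence/absence) are
compared by Hamming distance — the natural metric for 0/1 profiles, with
a normalized variant available. Neighbor-Joining follows Saitou–Nei with
two reproducibility conventions: ties in the $Q$ criterion break
deterministically, and a negative branch length is clipped to zero with
the deficit transferred to its sister edge so the joined pair's path
length is preserved. On additive matrices the algorithm recovers the
generating topology and branch lengths to floating-point precision
(branch lengths are serialized at 17 significant digits).

The batch effect on clustering is summarized without tree inspection:
`batch_clustering_score()` is the fraction of samples whose nearest
neighbor shares their batch label (ties broken by lexicographic sample
ID). Removing biased variants from the profiles should drive the score
from above chance back toward the label frequency.

## What the generator emulates — and what it does not

`sim_config()` defaults define the reference study conditions:

| parameter | default | rationale |
|---|---|---|
| `genome_length` | 100 kb | smallest size with hundreds of genes/runs at desk scale |
| `homopolymer_boost` | 1 | repeat probability 0.2; run-length tail resembles non-repetitive genome |
| `n_samples`, `n_plates` | 200, 10 | mid-size cohort, plate size 20 |
| `background_rate` | 30/sample | mutation loads within the range seen in exome MAFs |
| `spectrum_weights` | C>T/G>A 0.45 ... T>G/A>C 0.04, indels 0.15 | transition-dominated spectrum with the C>T/G>A class heaviest and T>G/A>C lightest |
| `sharing_range` | 1–3 carriers | background variants mostly private, plate-agnostic |
| `n_planted`, `planted_enrichment` | 50, (10, 0) | all carriers on one plate — the clean artifact signature |

Background carriers are drawn uniformly over samples regardless of plate,
so every batch variable is null by construction; the null calibration is
checked empirically (carriers are not i.i.d. across batches once drawn
without replacement). Planted variants are placed in one of three
contexts: uniform (`random`), immediately 5' of a run longer than 5
(`homopolymer`), or at the acceptor `A` of an internal splice junction
(`splice_acceptor`). In the acceptor case the genome is rewritten in
transcript orientation as an 8-nt stochastic pyrimidine tract (T 0.75 /
C 0.25) followed by `TTAG|TT` (acceptor dinucleotide, then the first two
exonic bases), reverse-complemented for minus-strand genes. The tract is
stochastic on purpose: with a fixed tract every k-mer tiling the
junction would be present in 100% of foreground windows and the
top-ranked k-mer would be decided by background noise; with a variable
tract the junction-spanning `TTAGTT` is the unique always-present k-mer
and motif recovery is well-defined.

The generator does **not** model read-level error processes, coverage,
mappability, caller idiosyncrasies, contamination, or correlated batch
structure (e.g. plates confounded with collection date). Passing tests
therefore demonstrate that the statistics behave correctly under their
own assumptions — exchangeable null carriers, planted enrichment — not
that any particular real cohort is artifact-free.

## Numerical and degenerate-input conventions

* Fisher P-values are computed from hypergeometric tail sums
  (vectorized); the two-sided mass comparison uses a $1 + 10^{-7}$
  relative guard at ties. Zero-carrier tables give $P = 1$.
* `bh_fdr()` delegates to `stats::p.adjust(method = "BH")`; empty input
  returns empty output.
* A zero pooled variance makes the t statistic degenerate: $p = 1$ when
  means agree, else $p = 0$, flagged `degenerate`.
* All-`N` flank contexts give `NA` GC and are excluded from comparisons;
  `N` breaks homopolymer runs.
* Contig-edge variants get truncated flanks; motif windows refuse
  truncated contexts (they would misalign columns).
* Datasets in which no batch passes the size filter return an empty
  result with a warning rather than an error, so multi-dataset runs
  continue.

## Scope of the pipeline interface

The pipeline stages are plain functions (`run_simulate`, `run_detect`,
`run_characterize`, `run_phylo`) writing self-describing TSVs; an R
package interface serves this analysis better than a shell wrapper, and
`scripts/acceptance.R` shows the end-to-end composition. Logged counts at
each filter stage (tests performed, significant, post-collapse) make the
screening funnel auditable.

## Problem sizes in the shipped tests

The test suite simulates cohorts of 100–200 samples with 5–10 plates and
2,500–22,000 variant records; null calibration uses 20 cohorts sharing
each background variant among 3–12 samples (~2,000 testable variants per
cohort), motif recovery uses 10 splice-planted cohorts, and NJ is checked
on 100 random additive matrices of up to 8 taxa. These sizes keep the
full suite around three minutes while leaving every statistical contract
detectable with wide margins.

## Known limitations

* The carrier filter interprets "fewer than 3 mutations" as *carriers
  inside the tested batch*; a cohort-wide reading is configurable.
* Clinical or shipment-date batch variables must be supplied as custom
  assignments; continuous covariates need discretization by the caller.
* Gene-level aggregation uses the MAF's gene symbols; overlapping genes
  resolve to the first model hit in strand assignment, with ambiguous
  overlaps excluded and counted.
* The clustering score is a nearest-neighbor summary, not a tree-shape
  statistic; with weak planted signal relative to per-sample
  mutation-count variance, individual cohorts can score near chance even
  before variant removal.
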