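# batchbias

Detection and characterization of **batch-biased somatic variant calls**
in MAF-format tumor cohorts.

## The problem

Somatic mutation calls in large multi-center cohorts carry technical
signal: some "mutations" are sequencing or processing artifacts whose
carriers concentrate in a single processing batch — a sample plate, a
tissue source site (TSS), or a sequencing center — rather than being
spread across the cohort as real somatic events are. Because TCGA-style
sample barcodes encode these batch variables positionally
(`TCGA-AA-1234-01A-01D-0886-08` → TSS `AA`, plate `0886`, center `08`),
the association between a variant and a batch is directly testable.
Undetected batch-biased variants inflate gene-level mutation frequencies,
distort mutation spectra, and make samples cluster by plate instead of by
biology.

`batchbias` implements the full screening workflow:

1. **Detect** — for every variant site *v* and batch value *B*, build the
   sample-level 2×2 table

   |            | in *B* | not in *B* |
   |------------|--------|------------|
   | carrier    | *a*    | *c*        |
   | non-carrier| *b*    | *d*        |

   and test carrier enrichment with Fisher's exact test (one-sided,
   *P* = P[X ≥ a] with X ~ Hypergeometric(N, a+c, a+b)). Only batches
   with more than 5 samples and at least 3 carriers inside the batch are
   tested; significance is called at *P* < 10⁻⁵ with Benjamini–Hochberg
   q-values reported over all tests in the dataset. Batch IDs sharing
   more than 75% of their biased variants (containment) are collapsed to
   one representative ID.
2. **Characterize** — compare biased and unbiased variants by mutation
   spectrum (strand-collapsed substitution classes and AT/GC indel
   classes), flanking GC content, per-nucleotide maximum homopolymer runs
   in 10–50 bp windows (artifact-prone loci), gene-region distribution
   with splice-site enrichment, position frequency matrices /
   information content / IUPAC consensus, and exhaustive k-mer
   enrichment against background flanks (recovering e.g. the
   splice-acceptor `AG` with its upstream polypyrimidine tract).
3. **Phylogeny** — Neighbor-Joining trees (Saitou–Nei) on Hamming
   distances between binary mutation profiles, before and after removing
   biased variants, scored by the fraction of samples whose nearest
   neighbor shares their batch label.
4. **Simulate** — a deterministic generator for reference genomes with
   tunable homopolymer content, multi-exon gene models, barcoded
   plate/TSS cohorts, background variants with a realistic spectrum, and
   planted plate-biased variants with a ground-truth table, so the whole
   pipeline is testable end to end without external data.

## Worked example

```r
library(batchbias)

cfg <- sim_config(seed = 42)        # 200 samples, 10 plates, 50 planted
sim <- simulate_cohort(cfg)         # plate-biased variants (10 carriers
sim$dataset                         # on one plate, none outside)
#> maf_dataset 'sim' (synthetic): 6466 variant records, 200 samples, 1216 indel records

res <- detect_batch_biased(sim$dataset)
head(res[, c("variable", "batch_value", "key", "a", "b", "c", "d", "p")], 3)
#>   variable batch_value            key  a  b c   d            p
#> 1    plate        A001 chr1:10965:T>A 10 10 0 180 8.229298e-12
#> 2    plate        A001 chr1:14109:T>A 10 10 0 180 8.229298e-12
#> 3    plate        A001 chr1:56117:->C 10 10 0 180 8.229298e-12

rep <- select_representative_batches(res)
evaluate_detection(unique(rep$key), sim$truth)
#>   tp fp fn sensitivity precision
#> 1 50  0  0           1         1
```

Of 1,247 (variant, batch) tests, exactly the 50 planted variants are
flagged (*P* ≈ 8 × 10⁻¹² each: 10 of 10 carriers on a 20-sample plate in
a cohort of 200) and recovered with sensitivity and precision 1 against
the generator's truth table. `run_characterize()` and `run_phylo()` then
write the context comparisons and the before/after trees:

```r
ch <- run_characterize(sim$dataset, unique(rep$key), sim$genome,
                       sim$models, "out")
ph <- run_phylo(sim$dataset, unique(rep$key), "out")
```

Real MAF files are read with `read_maf()` (standard TCGA headers or the
minimal lower-case dialect), screened with `qc_filter_datasets()`
(drops datasets with > 500,000 indels, no indels, or fewer than 100
samples), and fed to the same functions.

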