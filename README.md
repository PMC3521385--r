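# mitocount

Mitochondrial DNA copy-number estimation from paired-end whole-genome
sequencing (WGS) reads.

Human cells carry one diploid nuclear genome (2N bases) and many copies of a
~16.5 kb circular mitochondrial genome (mtDNA, length M). Because shotgun
sequencing samples molecules roughly in proportion to their base content,
the fraction of sequenced bases that are mitochondrial estimates
`kM / (2N + kM)`, where k is the average mtDNA copy number per cell — a
quantity of interest in aging and mitochondrial-disease research, where
reduced copy numbers have been reported repeatedly. Inverting the relation
gives the estimator at the core of this package:

```
k = mtBases * 2N / ((allBases - mtBases) * M)
```

Measuring `mtBases` honestly is the actual work, and `mitocount` implements
the full assay:

1. **Typing** (`type_consensus()`): guided greedy-overlap assembly of the
   sample's own homoplasmic circular mtDNA consensus against a reference
   mitochondrial genome, with majority-vote base calling and data-driven
   circle closure.
2. **Separation** (`build_index()`, `classify_pairs()`, `count_run()`):
   error-tolerant seed-and-verify mapping of every read pair against the
   typed consensus, gated by opposite-strand placement and a circular
   insert-size window; per-run totals are written to CSV.
3. **Estimation** (`estimate_copies()`, `aggregate_runs()`,
   `oneway_anova()`): the copy-number estimate from pooled counts, plus
   one-way ANOVA across groups of per-run ratios.

A truth-labelled read simulator (`sim_spec()`, `simulate_dataset()`) makes
the whole chain testable end-to-end without any external data, and a CLI
(`mitocount type|count|estimate|simulate|compare`) binds the stages into a
pipeline.

## Worked example

Simulate a planted world — a 100 kb nuclear stand-in, a 3 kb "mitochondrial"
circle at 120 copies per cell, 4,000 read pairs at 1% substitution error,
8 substitutions between the reference and the sample's true mtDNA — then run
the three-stage assay:

```r
library(mitocount)

spec <- sim_spec(nuclear_length = 1e5, mito_length = 3000, true_k = 120,
                 n_pairs = 4000, error_rate = 0.01, mito_divergence = 8,
                 seed = 42)
sim <- simulate_dataset(spec, "data")
manifest <- run_manifest("demo", data.frame(run_id = "run1",
                                            r1 = sim$r1, r2 = sim$r2))
res <- run_pipeline(manifest, sim$reference, "out", N = 1e5)
#> [type] reference reference_mito: 3000 bp
#> [type] pooled 8000 reads from 1 run(s)
#> [type] consensus 3000 bp, mean support 71.5x
#> [count] run run1: 5086/8000 reads mitochondrial
#> [estimate] k = 116.36 over 1 run(s)

print(res$estimate)
#> mtDNA copy number estimate: k = 116.36 (1 runs, pooled ratio 0.6358)
```

The consensus is recovered exactly (all 8 planted variants, no spurious
calls), 5,086 of 8,000 reads are classified mitochondrial, and the estimate
k = 116.36 sits within binomial sampling error of the planted 120 (the
3-standard-deviation band at this depth is about ±12). Two files mirror the
assay's tabular outputs:

```
run_id,total_reads,mito_reads,all_bases,mt_bases,mt_ratio
run1,8000,5086,800000,508600,0.63575

sample,runs,all_bases,mt_bases,mt_ratio,k
demo,1,800000,508600,0.63575,116.36
```

On real WGS data the mitochondrial ratio is a few parts in a thousand
(0.18–0.26% in the published benchmark samples, giving 630–760 copies for
B-lymphocyte-derived DNA), not 64% — the simulator's small nuclear stand-in
only rescales the ratio, which is all the estimator consumes. N must be
supplied explicitly (e.g. `nuclear_size_from_fasta()` on a nuclear
reference); M is taken from the typed consensus length.

The same pipeline from the shell:

```sh
mitocount simulate --out-dir data --mito-length 3000 --true-k 120 --n-pairs 4000 --seed 42
mitocount type --reference data/sim_reference.fasta \
    --r1 data/sim_R1.fastq.gz --r2 data/sim_R2.fastq.gz --out-prefix cons
mitocount count --consensus cons.fasta --out runs.csv \
    run1=data/sim_R1.fastq.gz,data/sim_R2.fastq.gz
mitocount estimate --runs runs.csv --nuclear-bases 100000 --mito-length 3000
mitocount compare groupA_runs.csv groupB_runs.csv   # one-way ANOVA
```

(the executable lives at `system.file("cli", "mitocount", package = "mitocount")`).

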