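---
title: "Estimating mtDNA copy number from whole-genome sequencing"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Estimating mtDNA copy number from whole-genome sequencing}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mitocount)
```

## The model

A human cell carries one diploid nuclear genome (2N bases, N ≈ haploid base
count) and many copies of a ~16.5 kb circular mitochondrial genome of length
M. If whole-genome shotgun sequencing samples nuclear and mitochondrial
molecules in proportion to their base content — a reasonable assumption for
PCR-light Illumina libraries — then the expected fraction of sequenced bases
that are mitochondrial is

$$\frac{\mathrm{mtBases}}{\mathrm{allBases}} = \frac{kM}{2N + kM},$$

where k is the average mtDNA copy number per cell. Solving for k gives the
estimator this package computes:

$$k = \frac{\mathrm{mtBases} \cdot 2N}{(\mathrm{allBases} - \mathrm{mtBases}) \cdot M}.$$

Everything else in the package exists to measure `mtBases` and `allBases`
honestly: the mitochondrial fraction is a few parts in a thousand of a real
WGS run, so both the consensus used for read separation and the separation
itself must be accurate.

The assay has three stages:

1. **Typing** — reconstruct the sample's own homoplasmic mtDNA consensus by
   guided assembly, because classifying reads against a mismatched reference
   haplotype costs sensitivity exactly where the sample diverges.
2. **Separation** — classify every read pair as mitochondrial or not with an
   error-tolerant seed-and-verify mapper plus a paired-end insert-distance
   gate, accumulating per-run totals.
3. **Estimation** — pool runs, apply the estimator, and (optionally) compare
   groups of per-run ratios by one-way ANOVA.

This model is not suitable for plant material: plant organellar genomes
exchange segments with the nuclear genome and co-occur with plastid and
plasmid DNA, which breaks the two-compartment sampling assumption.

## Typing: guided greedy-overlap assembly

`select_anchor_reads()` maps the read pool (both orientations,
error-tolerantly) against the circular reference and picks a *beginning*
read anchored inside the reference start window and an *ending* read whose
alignment ends within the same window-width upstream of the beginning anchor
on the circle. `assemble_consensus()` then extends the beginning read
rightward: at each step the candidate read with the longest verified overlap
against the contig tail is incorporated (ties: fewest overlap mismatches,
then input order, forward orientation before reverse). Candidates are found
by exact match of a read's leading 31-mer against the contig tail and
verified over the whole overlap at the configured mismatch rate.

Two details matter for robustness and were chosen after measurement:

* **The working contig is the running majority vote.** Appending raw read
  bases leaves ~1 error per 100 bp in the tail, which breaks the exact
  31-mer candidate lookup often enough to stall roughly one assembly in six
  at 1% error. Re-calling the contig from accumulated votes after each
  incorporation washes errors out as depth builds.
* **The circle is closed by self-alignment.** Once the contig length enters
  the window `reference length ± length_tol`, the tail is aligned against
  the contig head; agreement over at least `min_overlap` bases fixes the
  circle length exactly. Requiring instead that the ending read align flush
  with the junction truncates the circle whenever no read ends exactly
  there. After closure, assembly continues one read-length past the junction
  so reads spanning the origin vote on the consensus start, then the votes
  are folded modulo the circle length. The consensus is reported linearized
  at reference coordinate 0.

Per-position consensus bases are the majority over all incorporated reads;
N never votes, ties resolve alphabetically (a deterministic, documented
rule — at any realistic depth ties essentially never occur). Failure modes
are classed errors: no anchor within tolerance ("insufficient mitochondrial
coverage"), a coverage hole ("assembly gap" with the stall coordinate), and
exceeding the maximum length before closure ("runaway assembly").

Defaults: `min_overlap = 31` bp and a 5% overlap mismatch rate (long enough
that a chance 31-mer overlap is ~4^-31), `anchor_window = 200` bp,
`length_tol = 500` bp. All configurable via `typing_params()`.

## Separation: seed-and-verify classification

`build_index()` hashes all M circular k-mers of the consensus.
`map_read()` extracts seeds from a read at every offset (stride 1, plus the
window flush with the read end), looks them up, and verifies each candidate
placement by a full-read circular Hamming comparison on both strands. This
makes a provable guarantee possible: *any read with at least one error-free
seed-length window is examined at its true position*, so the seeded mapper
returns exactly what an exhaustive scan over all positions and strands
returns (the acceptance suite checks this equivalence against an
independent Biostrings oracle).

`classify_pair()` accepts a pair as mitochondrial iff both mates place on
opposite strands and a circular insert distance lies within
`[insert_min, insert_max]` (defaults 50–1000 bp). On a circle the two mates
bound two arcs, and the physical fragment is whichever arc the window
admits; testing both arcs keeps verdicts invariant under
reverse-complementing and swapping the mates, and — unlike a "shorter arc"
rule — does not reject legitimately short inserts whose mate-overlap arc is
smaller than the fragment arc.

Numerical defaults, with reasons:

* `seed_length = 15`, `stride = 1`. A 100 bp read at 1% error has ≥3 errors
  with probability 8%; with 31-mer seeds at stride 31 those errors often
  leave no clean window, and every missed mitochondrial pair both shrinks
  the numerator and inflates the nuclear denominator of the estimator —
  a 0.6–5% downward bias on k in measurement. 15-mers need ≥6 tightly
  clustered errors to fail while 4^15 ≫ M keeps lookups specific.
* `max_mismatch_rate = 0.10` per read. At 1% error the probability of a
  100 bp read exceeding 10 mismatches is ~1e-8, so the error tail costs
  nothing, while verification still demands 90% identity (a chance
  placement on a random background averages 75% mismatches).

With these defaults the classifier achieves 100% sensitivity and zero false
positives on the package's noise-free and 1%-error benchmark worlds. The
known systematic bias that no single-genome filter can remove is NUMTs
(nuclear-embedded mitochondrial segments): read pairs from a NUMT are
indistinguishable from mitochondrial pairs without a nuclear alignment and
are counted as mitochondrial. The simulator can plant a synthetic NUMT
(`numt_length`) to exercise this.

`count_run()` totals `all_bases` (every read, orphans included) and
`mt_bases` (full read lengths of accepted pairs — the model speaks of total
sequenced bases, not aligned bases). Orphan single-end reads can never
contribute to `mt_bases`. `pileup_alleles()` stacks the placed mates of
accepted pairs and flags positions whose minor-allele fraction reaches a
threshold — plumbing for heteroplasmy screening, not a genotyper: it
ignores base qualities and strand balance.

## Estimation and group comparison

`estimate_copies()` is the closed-form estimator above; `aggregate_runs()`
pools base counts across runs (equivalent to base-weighted averaging of
per-run ratios) and keeps the per-run ratios. N is a *required* input: the
published benchmark table never prints it, but inverting the estimator on
the three self-consistent family rows implies the authors used a diploid
total of ≈ 5.79 × 10⁹ bases (the three rows agree to 0.065%); the package
treats N as configuration (`genome_params()`, or
`nuclear_size_from_fasta()` to count non-N bases of a nuclear reference).
M is taken from the typed consensus length per sample, not a constant.

`oneway_anova()` is the classical fixed-effects decomposition on per-run
mitochondrial ratios, with the p-value from the F distribution. Ratios
differ from per-run k values only by a constant factor within a sample
group, so F is identical either way. Degenerate inputs are handled
explicitly: zero within-group variance with unequal means reports F = ∞ and
p = 0; identical constant groups report F = 0.

## The synthetic-data generator

`sim_spec()` describes a planted world; `simulate_genome()` and
`simulate_reads()` realize it reproducibly from a seed. Each pair's origin
is mitochondrial with probability `kM / (2N + kM)` — the generator *is* the
sampling premise of the estimator, which is the point: it validates the
measurement chain, not the premise. Fragment starts are uniform (circular
for mtDNA, linear for the nuclear stand-in), inserts are normal, truncated
to `[read_length, 4·insert_mean]`, mates read inward with either mate as R1,
and substitution errors are i.i.d. per base.

Defaults state the validation world used throughout: a 2 Mbp haploid
nuclear stand-in (the estimator consumes only base-count *ratios*, so
nuclear realism is irrelevant and a full-size genome would only cost time),
M = 16,569, k = 650, 100 bp reads, 300 ± 30 bp inserts, 1% error, 20
substitutions between reference and sample. What a green end-to-end test
establishes: the assay recovers a planted copy number to within binomial
sampling error under substitution noise and reference divergence. What it
does not establish: robustness to indels and structural variants (the
overlap model is substitution-only), quality-score–dependent error
patterns, GC/coverage bias, duplicates, real NUMT landscapes, or
contamination.

## Known limitations

* Substitution-only world: indel sequencing errors or a sample with
  insertions/deletions relative to the reference shift coordinates and
  would degrade both typing and classification.
* Repetitive or near-palindromic mtDNA regions could in principle confuse
  the head–tail closure test; the `length_tol` window and the
  longest-circle-first rule guard against short spurious closures.
* NUMT inflation of k is inherent to a single-genome filter and is
  documented rather than corrected.
* The ANOVA assumes independent, homoscedastic per-run ratios; runs from
  one flow cell violate independence in ways the package does not model.
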