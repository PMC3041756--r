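---
title: "Models and methods behind phenoscreen"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind phenoscreen}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(phenoscreen)
```

`phenoscreen` models forward-genetic screens analysed by pooled sequencing:
S independent mutant strains, each mutagenized to a density of θ mutations
per genome, pass a phenotype screen and are sequenced in pools. The
statistical question is how many of the T genes capable of causing the
phenotype ("target genes") can be read off from the per-gene mutation
counts, and how to design the sequencing to do so cheaply. This vignette
records the models, the tunable parameters, and the numerical and design
choices the implementation makes.

## The screened-strain model

Mutations are Poisson. We work in units of mutations per gene per strain,
μ = θ/G for G genes; the target region receives λ_T = Tμ expected
mutations per strain. Passing the screen conditions on at least one
target-region mutation, giving the zero-truncated Poisson

$$P(m \mid m \ge 1) = \frac{e^{-\lambda_T}\lambda_T^m / m!}{1 - e^{-\lambda_T}},\qquad m \ge 1.$$

`conditional_target_distribution()` truncates the support at the smallest
count whose remaining tail mass is below `tail_mass_cutoff` (default
`1e-10` — small enough that truncation is invisible at double precision
against the 1000-replicate sampling noise used throughout) and renormalizes
so the vector sums to exactly 1. The sum over S strains is realized as a
*single* multinomial draw of S counts over that support
(`sample_target_counts()`), which is O(support size) rather than O(S);
totals are then allocated to individual target genes by a second
multinomial — uniform probabilities for the uniform-size model,
probabilities proportional to effective size otherwise. Non-target genes
are independent Poissons with mean Sλ_g (`sample_nontarget_histogram()`).

Conservative assumptions are deliberate: exactly one causal mutation is
required per strain, and the causal signal is split equally (or by size)
over all T targets. Real screens, where one gene dominates, are easier; the
model's yields are therefore lower bounds in that respect.

Two-sided accounting: all K conditioned target-region mutations are
allocated among the T targets, and non-target genes draw independently —
background mutations landing in target genes are absorbed into the target
allocation rather than drawn separately, mirroring the conditional
construction.

## Variable gene sizes and GC bias

"Size" here is anything that changes a gene's chance of mutation. A gene's
effective size is n_GC·μ_GC + n_AT·μ_AT (`effective_gene_size()`), with
per-base rates measured genome-wide; chemical mutagens such as NTG are
strongly GC-biased (observed GC/AT rate ratios around 36). Rather than one
Poisson per gene, non-target genes are sorted by effective size and split
into B equal bins (`bin_genes_by_size()`, default B = 10; remainder genes
join the last, largest-size bin, slightly inflating it — the conservative
direction). Ten bins approximate the exact size distribution closely (see
the calibration check below).

## p-values, Bonferroni, and yield at an FDR

A gene with m observed hits and null mean Sλ_g scores the Poisson upper
tail P(X ≥ m); `gene_pvalue(0, ·)` is exactly 1. The Bonferroni multiplier
defaults to the number of genes observed mutated at least once — the
quantity actually reported by a screen — with `bonferroni = "all"`
available since either convention is defensible; corrected values cap at 1.

The yield at a false discovery rate is computed two ways, matching the two
modelling regimes:

* `yield_from_counts()` (uniform sizes): the smallest count threshold m*
  such that for *every* m ≥ m*, the non-target fraction among genes with
  ≥ m hits stays strictly below the FDR; the yield is the number of targets
  with ≥ m* hits.
* `yield_from_scores()` (variable sizes): genes sorted by p-value; the
  largest cutoff whose reported set keeps the non-target fraction below
  the FDR.

With equal gene sizes the two agree on typical samples, since ranking by p
is ranking by count. They are not identical in the tail: the count rule
also requires the FDR bound at every threshold *above* m*, so on rare
samples whose sparse non-target tail briefly violates the bound it reports
one gene fewer. Both contracts are implemented exactly; the score rule
never reports less than the count rule. Ties in ranked output break by
p-value, then hit count (descending), then gene id, so tables are
deterministic. FDR comparison is strict (< FDR).

## Calibration of the null p-values

`calibration_curve()` samples non-target hit counts under the null
(defaults mirror a heavily mutagenized screen: 50 mutations/genome, 4244
genes, 80 strains, 1000 replicates), computes p-values, and pairs each
−log p with the −log empirical survival fraction of its rank. Poisson
p-values are discrete and tie in large blocks; a p-value's realized
frequency is the fraction of the sample *at or below it*, i.e. the last
rank of its tie block, and the curve is evaluated there (mid-block ranks
sit off the diagonal by construction, not through miscalibration). For the
uniform model the curve lies on the y = x diagonal to within sampling
noise; with variable gene sizes it sits on or above it — the p-values are
slightly conservative, because a large gene's p-value overstates how often
small genes produce the same score. The ten-bin approximation tracks the
exact-size curve within plotting tolerance, which is why ten bins are the
default.

## Pooled sequencing error

For coverage c (rounded to the nearest integer when used as binomial
trials — c is an average), pooling factor P, error rate ε and call
threshold k:

* detection failure (false negative): P(X < k), X ~ Bin(c, (1−ε)/P);
* false positive per site: P(X ≥ k), X ~ Bin(c, ε).

ε is the probability of reading one *specific* wrong nucleotide — a third
of the total miscall probability under a uniform error spectrum — exactly
as the rates are defined; no ×3 factor is applied anywhere. Both rates are
deterministic given the design and are computed once per design
(`error_profile()`).

`apply_sequencing_effects()` injects these into the screen model: target
allocation probabilities are rescaled by (1 − fail) with an appended
discard category of mass fail, and every gene accrues spurious events.
False calls arise independently in each of the S/P sequenced libraries, so
over a whole experiment a gene of length ν expects ν·fp·(S/P) false events;
equivalently each non-target gene's per-strain rate becomes
λ_g(1 − fail) + ν·fp/P. Target and non-target genes are treated
symmetrically. For target-gene false positives the full gene span is used
for ν (coding-only lengths would change the rates by the coding fraction,
a few percent). Local coverage variation is not modelled: above- and
below-average sites largely cancel in the genome-wide expectations, and
that residual optimism is a documented limitation rather than a parameter.

At c = 75, P = 4, ε = 0.01 there is a non-empty window of thresholds
(k = 9–11) where a 4 Mb genome expects fewer than one false positive *and*
fewer than one missed mutation among ~50 per genome; `scan_thresholds()`
maps the mean yield over (P, k) grids and shows the characteristic
collapse at permissive thresholds, the plateau, and the slow decline as k
approaches c. At their optimal thresholds, pooling levels 2–5 retain the
unpooled yield to within a few percent.

## Experiment design and cost

`coverage_per_library()` divides lane capacity (default 1.5 Gb) by genome
size times the tag-pooling level; `experiment_cost()` books libraries at
`lib_cost` (default $50) and lanes at `lane_cost` (default $700), with
fractional lanes allowed (a `whole_lanes` flag bills whole lanes), and
`ceiling(S/P)` libraries; mixed pool sizes (e.g. eight pools of 3 plus two
of 4 for 32 strains) are expressed through explicit layouts
(`pool_layout()`). `optimize_design()` operationalizes "maintains a high
yield" as ≥ 90% of the unpooled (P = 1) mean yield at the per-P optimal
threshold; the floor is configurable since it is a judgment call, not a
measured constant. Candidate thresholds are pre-filtered to the workable
window (expected genome-wide false calls ≤ 10, failure rate ≤ 50%) purely
to avoid simulating grid cells whose yield is provably negligible.

## The VCF pipeline

`read_snv_vcfs()` consumes one VCF per (library, lane) from a manifest,
splitting multi-allelic records and keeping biallelic SNVs (indels and
symbolic alleles are counted and skipped; substitutions are the only event
type modelled). Filters mirror pooled-screen practice: allele frequency at
most 0.5 (a pooled single-strain mutation sits near 1/P) with identical
calls — same (library, position, alt) — required in at least 2 of 3
replicate lanes; single-lane analyses apply only the frequency filter.
Variants at ≥ 95% frequency in *every* library are ancestral (present in
the parent strain) and are removed; the 0.95 floor rather than literal
100% tolerates caller noise and is configurable. Both filters are
idempotent.

Coordinates are 1-based inclusive throughout the user-facing tables (VCF
and annotation conventions); reverse-strand CDS are translated from the
reverse complement with amino-acid changes reported in protein
coordinates. A SNP inside overlapping CDS counts once per gene by default
(`all_overlaps = FALSE` keeps the first). CDS whose length is not a
multiple of 3 are skipped with a warning.

Scoring normalizes each gene's null mean to the realized mutagenesis
intensity: expected count = total filtered SNPs × (gene effective size /
genome effective size), with per-base GC/AT rates measured genome-wide
from the data (`gc_mutation_rates()`). This makes the null self-calibrated
— no externally supplied mutation rate is needed. The caller's allele
frequency is read from a configurable INFO field (default `AF`), since
different callers encode it differently.

`subset_yield_analysis()` re-scores every non-empty subset of the tagged
libraries (2^L − 1 of them; beyond 20 libraries subsets are Monte-Carlo
sampled with a stated seed) by summing per-library gene counts and
rescaling the null to the subset's SNP total, then reports how many
validated targets appear in the top 20 (the reporting convention) per
subset size, with costs prorated at the layout's per-strain cost.

## The synthetic-data generator

`make_toy_genome()` builds a small annotated genome: non-overlapping CDS
(ATG start, in-frame stop-free body, stop codon, length divisible by 3) on
both strands at a controlled GC fraction, with intergenic spacers. A body
codon drawn as a stop is replaced by a random non-stop permutation of the
same three letters, so the fix-up cannot bias composition.
`simulate_strains()` forward-simulates GC-biased Poisson mutagenesis with
rejection until each strain carries a target-gene mutation — the screen
condition realized mechanically rather than through the conditional
distribution, which is what makes it a genuine cross-check of the screen
model. `write_pooled_vcfs()` emulates the sequencing model exactly as
specified: fixed depth c at every site (no depth variance, matching the
model; a site is emitted when its alternate-read count, Bin(c,
carriers·(1−ε)/P), reaches the call threshold), spurious sites planted at
the binomial false-positive rate with conditional read counts, and
optional parental markers at 100% frequency everywhere. Alt bases are
uniform over the three alternatives by default, with an optional
transition-bias weight. Everything is deterministic under a fixed seed.

The generator emulates the *model*, not a sequencer: no read-level
artifacts, no mapping bias, no base-quality structure, no depth variation,
and single-replicon genomes only. Tests passing on synthetic data
therefore validate the statistical machinery and the pipeline plumbing,
not robustness to real-world alignment pathologies.

## Problem sizes used in the test-suite

Simulated checks run at the study conditions (4244 genes; 1000 replicates
for yield averages and threshold scans) where those are stated, and on
deliberately small instances elsewhere: goodness-of-fit against brute-force
rejection sampling uses a 20-gene genome where the oracle is exact and
fast, and the end-to-end recovery check uses 50 synthetic 32-strain
experiments on 40-gene toy genomes whose *per-gene* mutation density
matches the 50-per-4244-gene regime, so per-gene statistics — and hence
the comparison against the model's predicted yield — carry over while the
full pipeline (VCF round-trip included) stays fast.

## Randomness

Every stochastic function takes `seed = NULL`; a supplied seed runs the
computation in an isolated RNG scope (`withr::with_seed`), so calls are
reproducible without mutating the caller's RNG stream, and omitted seeds
draw from the session stream in the usual R way.

## Known limitations

* Substitutions only: indels, IS insertions and structural variants are out
  of scope end to end.
* Average-coverage error rates; systematically low-coverage regions (e.g.
  AT-rich repeats on some platforms) would degrade yields beyond the model.
* Strain independence is assumed; shared ancestry inflates per-gene counts
  and would need phylogeny-aware scoring.
* The conditional model plants exactly one required causal mutation per
  strain; multi-hit phenotypes have proportionally stronger signal than
  predicted here.
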