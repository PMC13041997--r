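---
title: "Methods: cohort SV callsets and cell-type-resolved expression effects"
author: "svcellreg"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: cohort SV callsets and cell-type-resolved expression effects}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette documents the models, algorithms and numerical choices behind
`svcellreg`, in the spirit of the long-form methods sections that accompany
expression-analysis packages. It states no empirical result that the test
suite and `scripts/acceptance.R` do not themselves compute.

## 1. The problem

Long-read sequencing makes structural variants (SVs) callable at scale, but
single callers have systematic blind spots, breakpoints are reported with
positional uncertainty, and raw callsets carry artefacts concentrated in
repetitive sequence. Downstream, connecting an SV to gene regulation in a
specific cell type requires pseudobulk expression per cell type, covariate
control, and — for direct evidence within heterozygous carriers —
haplotype-resolved expression. `svcellreg` implements this chain for
case/control cohorts with three diagnosis groups (HC, ILBD, PD), matching
the design of a ~100-donor brain cohort with two sampled regions.

## 2. Coordinates and containers

VCF fields are 1-based; every internal interval computation uses 0-based
half-open coordinates, converting only at the I/O boundary. A single
convention prevents off-by-one drift across the many overlap computations
(masks, windows, read spans). SV callsets are plain data frames with a
genotype-string matrix column; intervals are handled by
GenomicRanges/IRanges. Deletions carry negative `SVLEN` (the identifier
`chr17_46237501_DEL_-724` encodes chromosome, position, type, signed
length); wherever a "size" is meant, the absolute value is used. The strand
pair of insertions and deletions is frequently unreported by callers, so an
unknown strand (`*`) acts as a wildcard that matches any strand during
merging.

## 3. Ensemble merge

Records failing FILTER or shorter than 40 bp are removed before matching;
records shorter than 50 bp are excluded at the merge itself (the 40 bp
pre-filter keeps near-threshold calls available for cross-caller matching
before the final 50 bp floor applies). Calls are split by type so that,
e.g., a deletion can never merge with an inversion.

Within a type, two records link when they share a chromosome, their
breakpoint *start* positions lie within 1 kb, and their strands are
compatible. Clusters are the transitive closure of this predicate
(single-linkage). Chaining behaviour is deliberate and documented: merging
tools behave similarly, and transitive closure makes the result independent
of input order, which we verify against a brute-force label-propagation
oracle on every acceptance run. Link distance uses start breakpoints only;
END agreement is enforced indirectly through the type split and the size
floor. The cluster representative is the record with lexicographically
smallest (position, caller label, sample label); callers and support are
unioned. Genotype conflicts within a cluster resolve by caller priority
(the representative's caller first, then the remaining callers
alphabetically), taking the first non-missing call — in a production run
these genotypes are later superseded by re-genotyping, so the policy only
needs to be deterministic.

Insertion/duplication reconciliation links a DUP to an INS when their
breakpoints lie within 500 bp and size similarity `min/max ≥ 0.7` — the
lenient similarity regime; the linked pair emits a single insertion flagged
`POSSIBLE_DUP`. One caller profile in the simulator reports duplications
but no insertions precisely to exercise this path.

## 4. QC metrics and the confidence filter

Masked-region exclusion drops any SV whose query span overlaps a mask by
at least 1 bp; insertions count as their single breakpoint base. Sex
chromosomes are dropped wholesale (hemizygous genotype models are out of
scope). Carriers are samples with dosage 1 or 2; HC forms the control
group, ILBD+PD the case group.

Read metrics count primary (non-supplementary) alignments from carrier
samples overlapping the SV query interval; for insertions the read must
fully contain the breakpoint base, since a read ending at the breakpoint
carries no information about inserted sequence. Supplementary alignments
are excluded for consistency with the read-partitioning stage.

LD metrics use genotypic r² — the squared Pearson correlation between SNP
and SV dosage vectors over samples non-missing in both — for SNPs within
10 kb of *either* breakpoint. Zero-variance SNPs have undefined r²: they
stay in `TOTAL_SNPS_NEARBY` but cannot enter `LD_SNPS_COUNT` (a choice the
spec leaves open; it is logged and configurable through the returned r²
vector).

The low-confidence filter removes SVs with `TOTAL_READS < 5`,
`AVG_READS_PER_SAMPLE < 5`, `AVG_MAP_QUALITY < 20`, or cohort alternate
allele count `< 1`. All four removals are strict less-thans, so exact
boundary values survive — the test suite pins the boundary record
(5, 5.0, 20.0, AC = 1). The AC < 1 rule is applied literally (AC = 0
removal); it is distinct from the later selection filter's AC > 1
requirement.

## 5. Functional selection

Candidate pairs are SVs whose span (insertions: breakpoint base) overlaps
an eGene's span expanded by 100 kb on both sides; SVs inside the gene body
are included. The window anchors to the full gene span rather than the TSS
— the choice is configurable, and anchoring to the body is the more
inclusive reading. Cohort filters then require missingness ≤ 0.95 (≥5
valid genotypes in a 100-sample cohort), allele frequency < 0.99 over
non-missing alleles, and at least two alternate alleles among PD samples
or among ILBD samples — which removes variants carried only by healthy
controls.

## 6. Matching and benchmarking

A pair of records matches when types are compatible (equal, or INS~DUP
when enabled), breakpoints lie within `refdist`, size similarity
`min(|len|)/max(|len|)` meets `pctsize`, reciprocal span overlap meets
`pctovl` (span types only), and edit-distance sequence similarity
`1 − d/max(len)` meets `pctseq` (only when both records carry sequence).
The strict regime is refdist 1 bp with all similarities at 0.99. The
lenient regime is refdist 500 bp with sequence and size similarity at 0.7
and **no reciprocal-overlap requirement** (`pctovl = 0`): this matches the
benchmark tool's actual relaxed defaults, and is the only reading under
which a 100 bp deletion offset by 300 bp can match leniently — requiring
70% reciprocal overlap at a 300 bp offset would contradict the regime's
intent. Strict matches are provably nested within lenient matches.

Benchmarking scores candidate pairs by mean available similarity and
accepts them greedily best-first under a one-to-one constraint, ties broken
by (position, id) for determinism. On instances whose similarities are
effectively 0/1, greedy matching attains the optimal assignment size; the
test suite checks this against an augmenting-path maximum-matching oracle.

## 7. Permutation enrichment

The allowed universe is the genome minus masks, kept as maximal disjoint
blocks. Each SV is placed independently: a block is drawn with probability
proportional to `block length − width + 1` (its number of valid
placements), then a uniform offset — this makes every valid genomic
position equally likely while preserving widths exactly. Placements are
sampled independently per SV with no mutual-exclusion constraint, matching
per-region randomisation. Empirical p-values use the add-one correction
`(1 + #{null ≥ obs})/(n_perm + 1)`, preventing p = 0 artefacts; both
one-sided values (enrichment and depletion) are returned, and the expected
fraction is the *mean* of the null distribution.

## 8. Read phasing and phased SV genotypes

Only heterozygous phased SNPs are informative. For each non-supplementary
read, bases are compared to the two haplotype alleles at overlapped SNPs;
sites matching neither allele (sequencing errors, third alleles) are not
counted in the denominator. A read is assigned when the matching fraction
strictly exceeds 0.95 (19/20 = 0.95 is *unassigned*), and retained in an
allele set only when its allele-match counter strictly exceeds 3 — the
counter filter mirrors a `[AL]>3 || [AM]>3` read-tag filter and guards
against assignments based on one or two SNPs. SNP calls within 5 bp of an
SV breakpoint can be excluded as indel-adjacent artefacts (off by
default in the simulator, which produces clean calls).

SV presence on an allele is decided from reads fully spanning the query
interval: PRESENT needs ≥2 supporting reads at a supporting fraction
≥0.5; ABSENT needs ≥2 spanning reads at a fraction <0.5; everything else
is AMBIGUOUS. These thresholds stand in for an external re-genotyper's
internal logic and are exposed as arguments. Allele calls combine as
`(absent, present) → 0|1`, `(present, absent) → 1|0`, all else `./.` —
any ambiguity propagates to an unphaseable genotype rather than a guess.
Swapping haplotype labels provably flips `0|1`↔`1|0` and fixes `./.`.

## 9. Expression processing

Cell-level normalisation is `ln(1 + count/cell_total × 10⁴)`. Pseudobulk
is the per-sample mean over cells of one type; samples with zero cells of
a type become missing columns (never imputed) and are excluded before
scaling. Two screens feed the specificity classifier: a gene is
*confidently expressed* in a cell type when strictly more than 50% of
samples (among samples with ≥1 cell of the type) have mean UMI strictly
above 0.1, and a cell type is *adequately sampled* when the median cell
count across individuals is at least 9 (boundary inclusive).

Covariate adjustment has three deterministic stages: (1) per gene and
batch, mean-centering with rescaling to the pooled standard deviation — a
location/scale batch adjustment *without* empirical-Bayes shrinkage (the
exact empirical-Bayes machinery is intentionally out of scope; the
adjustment is specified by its contract: planted batch shifts reduced to
<5% explained variance, which the acceptance run measures); (2) surrogate
variables as the top `k = min(30, n − p − 2)` principal components of the
expression residualised on known covariates (age, sex, PMI, RIN), with
sign fixed by the largest-magnitude loading so reruns are bit-identical;
(3) residualisation on known covariates plus surrogates. The cap on `k`
matters at cohort scale: a fixed 30 dimensions can exceed the residual
degrees of freedom at n ≈ 94.

A scale caveat the tests make explicit: with only tens of genes, a single
strong planted effect dominates the residual principal components and is
absorbed by the surrogate variables. At transcriptome scale (15–20k genes)
one gene's cis effect contributes negligibly to global PCs. Demonstrations
and calibration runs on small gene panels therefore use small `k_sva` (or
0), and the adjustment's acceptance checks target its contract (batch
variance removal, covariate orthogonality within 1e-8), not equivalence
with any external implementation.

## 10. Association models

**cis-eQTL.** Ordinary least squares of scaled pseudobulk expression on SV
dosage, optionally with covariate columns (e.g. genotype PCs). The effect
size is the dosage slope; p comes from the slope's t statistic. Samples
missing either value are dropped pairwise; pairs monomorphic among used
samples are skipped rather than reported with meaningless slopes. Slopes
are verified against a normal-equations oracle to 1e-10. Genotype PCs
follow the conventional recipe: MAF ≥ 0.05, missingness ≤ 0.05, greedy LD
pruning at |r| > √0.1 within 10 Mb windows, mean imputation,
standardisation, PCA, six components by default.

**Allelic imbalance.** For each SV–gene–cell-type trio, per-sample
alternate/total phased UMI counts (alternate haplotype = haplotype 2 under
`0|1`, haplotype 1 under `1|0`) are modelled as beta-binomial with mean μ
and overdispersion φ shared across samples, parameterised
`a = μ(1−φ)/φ`, `b = (1−μ)(1−φ)/φ`. The null fixes μ = 0.5 with free φ;
the alternative frees both; p comes from the likelihood-ratio statistic
against χ²(1). The effect size is `logit(μ̂)`, clamped with a half-count
offset at the boundary. Optimisation starts from the pooled moment
estimate and a mid-range φ, with the 1-d null profile solved by golden
search. One behaviour of this prescription is worth knowing: because the
null's φ is free, a *perfectly consistent* extreme imbalance (every sample
all-alternate) is partially absorbed by a bimodal null, so the
likelihood-ratio grows roughly linearly in the number of samples (~2·log 2
each) rather than in total read count; five all-alternate samples give
p ≈ 0.008, twenty give p < 1e-6. The simulated type-I error of the test at
(μ = 0.5, φ = 0.02) sits within [0.03, 0.07] at α = 0.05, and power at
μ = 0.8 exceeds 95% at realistic depths — both recomputed by the
acceptance script. Preconditions: ≥2 samples with nonzero totals and
pooled totals ≥10.

**Multiple testing and specificity.** Benjamini–Hochberg within
region × test (pooling cell types), significance at adjusted p ≤ 0.05;
the cutoff is read as `p_adj ≤ 0.05` (the natural reading of an "FDR 0.05
cutoff"). For pairs significant in exactly one cell type, with E the other
cell types expressing the gene confidently and C the other cell types
passing the cell-count screen: some type in E∩C ⇒ potential regulatory
specificity; E empty, C non-empty ⇒ low expression; E non-empty, E∩C
empty ⇒ low cell number; both empty ⇒ low expression and cell number.
ASE effect sizes are reported on the logit scale, so eQTL/ASE concordance
is summarised scale-free by correlation and sign agreement.

## 11. The synthetic-data generator

The generator defines the study conditions under which every guarantee is
tested; its defaults were chosen once to mirror the cohort design and are
not tuned against outcomes:

- cohort of 100 samples split 34 HC / 31 ILBD / 35 PD; covariates age
  ~N(78, 7), sex Bernoulli, PMI ~N(6, 2) h, RIN ~N(7, 0.8), two batches;
- SV sizes from a three-component lognormal mixture with modes near 60,
  300 and 6000 bp (weights 0.5/0.35/0.15) — the characteristic size peaks
  of real SV catalogues (Alu-scale, LINE/SVA-scale, and large events);
- allele frequencies Beta(0.8, 3.2) clipped to [0.02, 0.8], genotypes
  Hardy–Weinberg with phased haplotypes retained as truth;
- three caller profiles: 5% false negatives, Gaussian breakpoint jitter
  (σ = 20 bp), 5% multiplicative length noise, 5% genotype error
  (pairwise genotype concordance ≈ 90%), and one caller that reports
  duplications but never insertions;
- tag SNPs constructed by copying SV haplotypes and redrawing each
  haplotype with probability `1 − √(r²_target)`, giving genotype
  correlation ≈ √r² by construction; background SNPs independent;
- reads: Poisson depth 20–30 per locus, length 8 kb, MAPQ ~N(60, 3),
  haplotype chosen fairly, per-SNP base calls with error ε, SV support
  consistent with the read's haplotype;
- expression: Poisson cell counts per sample/cell type, negative-binomial
  UMIs with log-linear planted effects `exp(β·dosage)`, and beta-binomial
  allelic splits (per-sample alternate fraction drawn from Beta(μ, φ)).

Genome sizes are scaled to tens of megabases so that each property check
runs in seconds to minutes on one CPU; all statistical checks are
scale-free (calibration, bias, exactness against oracles), so the reduced
genome changes problem sizes, not the properties under test. What the
simulator does *not* emulate: realistic HiFi error profiles and repeat
structure, reference bias, mapping artefacts concentrated in segmental
duplications, doublets and ambient RNA in snRNA-seq. Passing tests
demonstrate the pipeline's logic and statistical calibration under the
generative model, not robustness to those real-data pathologies.

## 12. Degenerate inputs and tie-breaks

Empty callsets round-trip as header-only VCFs; merges of empty lists
return empty tables. Mixed-type input to the within-type merge is a fatal
error (the type split precedes it). Unknown SV types are quarantined with
a warning, not dropped silently. ID collisions after concatenation get
numeric suffixes with a warning. Zero-variance genes scale to zero and
are flagged. An SV wider than every universe block is skipped with a
warning during permutation. Greedy matching ties break by (position, id);
representative selection by (position, caller, sample); both make reruns
bit-identical.

## 13. Known limitations

- Breakend/translocation records and multi-allelic sites are out of scope.
- The batch adjustment is location/scale only; cohorts with very small
  batches would benefit from empirical-Bayes shrinkage that this package
  deliberately does not implement.
- The beta-binomial LRT's free-φ null damps perfectly consistent extreme
  imbalance (Section 10); users who prefer a binomial-anchored null can
  inspect `phi_hat` and the boundary flag.
- Genotype merging during the ensemble stage is a deterministic
  placeholder for downstream re-genotyping, not a genotype integrator.
- The simulator plants SV support flags on reads rather than emitting
  base-level alignments; CIGAR-level SV evidence extraction is therefore
  exercised only through the tabular path.
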