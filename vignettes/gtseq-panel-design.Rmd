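---
title: "Designing and QC-ing GT-seq microhaplotype panels for temporal genetic monitoring"
author: "GTseqPanel"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Designing and QC-ing GT-seq microhaplotype panels}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(GTseqPanel)
```

## The problem this package addresses

Long-term genetic monitoring programmes genotype hundreds of individuals
per year, year after year, and their value lies in *continuity*: the same
genomic regions must be interrogated across decades so that temporal
shifts in diversity and allele frequencies are comparable. Genome-wide
reduced-representation sequencing discovers thousands of variable loci
but is too expensive to repeat annually; Genotyping-in-Thousands by
sequencing (GT-seq) multiplexes a few hundred PCR amplicons in one
reaction and is cheap enough for routine monitoring. The transition
problem is therefore: given an archived, time-stamped microhaplotype
dataset (individuals x loci, with collection years) and a reference
genome, choose and validate a panel of ~300 amplicons that *tracks
temporal genetic change the way the full dataset does* — not a panel of
maximally divergent outlier loci, which is the usual target when panels
are built for stock identification.

`GTseqPanel` implements that workflow end to end:

1. **Locus filtering** — depth, individual missingness, Hardy-Weinberg
   equilibrium (HWE) across all temporal collections, linkage
   disequilibrium (LD).
2. **Assay compatibility** — iterative SNP-position trimming so every
   retained SNP has clear flanks for primers and probes; a template
   length gate; per-SNP allele probes; exact-match primer specificity
   screening against the reference with candidate iteration.
3. **Panel selection** — per-locus temporal F~ST~; five candidate subset
   schemes mixing top-F~ST~ and random loci; diversity statistics,
   permutation-tested pairwise F~ST~ and DAPC; ranking by Euclidean
   distance between subset and complete-dataset DAPC year centroids.
4. **Multiplex QC** — classification of amplicon reads into on-target /
   primer-interaction / unknown; probe-based allele counting;
   maximum-likelihood microhaplotype genotyping; concordance against the
   reference dataset; removal recommendations; a stopping rule; sex
   assignment from a two-SNP sex-linked locus.
5. **Synthetic data** — a Wright-Fisher simulator for temporal genotype
   series, reference genomes with embedded loci, and amplicon read pools
   with per-read truth, so the whole pipeline is testable without any
   external data.

## The statistical machinery

### Weir–Cockerham variance components

All F-statistics are Weir & Cockerham (1984) estimators computed on
microhaplotype alleles, with multi-allelic loci handled by summing the
a (among-population), b (among-individual) and c (within-individual)
variance components over alleles; per-locus
$\hat\theta = \sum_u a_u / \sum_u (a_u+b_u+c_u)$ and multilocus
estimates are ratios of summed components. Loci monomorphic across all
collections have a zero denominator and are flagged undefined rather
than reported as zero. Permutation tests for pairwise temporal
$F_{ST}$ shuffle individuals between the pair of collections and count
$\theta^* \ge \hat\theta$ one-sidedly, with the $+1/(n+1)$ correction;
confidence intervals bootstrap over loci.

A useful closed form for validation: two populations that drifted $t$
generations each since splitting from a common ancestor have
$E[\hat\theta] \approx 1-(1-\tfrac{1}{2N_e})^t$. Two samples of *one*
lineage $t$ generations apart are genealogically one-sided, and the
among-sample variance is half that of the two-branch case, so
$E[\hat\theta] \approx \tfrac12\bigl(1-(1-\tfrac{1}{2N_e})^t\bigr)$.
Both identities are verified by simulation in the test suite; the
factor of two matters when interpreting temporal $F_{ST}$ against
textbook divergence formulas.

### Diversity statistics

Per collection: observed heterozygosity $H_O$; Nei's unbiased expected
heterozygosity $H_E = \frac{2n}{2n-1}(1-\sum_u p_u^2)$; allelic
richness $A_R$ by *exact* hypergeometric rarefaction to $g$ gene copies
($\sum_u 1 - \binom{N-N_u}{g}/\binom{N}{g}$, not resampling); and the
multilocus inbreeding coefficient $F_{IS} = 1 - \sum_l H_{O,l} / \sum_l
H_{E,l}$ over loci polymorphic in that collection (monomorphic loci
carry no information on heterozygote deficit and are excluded, which is
also why collections with many monomorphic loci have noisier $F_{IS}$).
95% CIs come from a percentile bootstrap over loci (1,000 iterations by
default); bootstrapping over loci rather than individuals is a
documented choice — the sampling unit of the panel-selection question
is the locus.

### DAPC and subset ranking

Genotypes are expanded to an allele-dosage table (one column per locus
allele, values 0/1/2), missing entries are imputed within group (mean
by default; a random-forest option fits per-column regression forests
within group), principal components are computed *without* scaling, and
a linear discriminant analysis on the retained PCs yields year
centroids in discriminant space. For wide data the PCA is computed from
the n x n Gram matrix, which is exact and much faster when loci far
outnumber individuals. The number of retained PCs is either fixed or
chosen by the a-score (observed reassignment rate minus its mean under
permuted labels, maximized over 1..min(50, n - groups)).

Candidate subsets are scored by the per-year Euclidean distance *d*
between the subset's DAPC centroids and the complete dataset's. Because
independently fitted DAPCs have arbitrary axis orientation, centroid
sets are aligned by orthogonal Procrustes (translation + rotation +
reflection, *no scaling*) before distances are taken; raw-coordinate
comparison is available (`alignment = "none"`) to replicate analyses
that skipped alignment, but its distances are sensitive to arbitrary
sign flips of the discriminant axes. The scheme with the smallest mean
*d* wins.

### Read classification and ML genotyping

A read is **on-target(i)** when its leading bases exactly match the
forward primer of locus *i* and it contains any allele probe of *i*;
it is an **interaction(i, j)** when it matches fwd(*i*) but contains a
primer sequence of another pair *j* — forward, reverse, or a reverse
complement of either, anywhere downstream (the containment rule is this
package's concrete definition of a chimeric primer product); with a
forward-primer match but neither evidence it is **unknown**. Probes are
the SNP allele plus 8 nt of template on each side, with neighbouring
SNPs inside the window encoded as IUPAC degenerate bases that match
their expansion set.

Genotypes are called per locus from haplotype-allele read counts (all
SNPs of a locus sit on one single-end read, so phase is read directly).
For a locus with $k$ alleles, genotype $g$ has expected allele-read
proportions $p_u = (1-\varepsilon)\,w_u(g) + \varepsilon/k$ with
$w_u$ = 1 (homozygote), 0.5/0.5 (heterozygote), 0 otherwise; the caller
maximizes the multinomial likelihood over unordered pairs. The
mis-assignment rate $\varepsilon$ (default 0.01) and the depth gate
(default 10 reads) are configurable; neither value is dictated by the
underlying publication describing the genotyper, so both are explicit
parameters and are recorded in run manifests. The call is invariant to
scaling all counts, and at depth 50 with $\varepsilon = 0.01$ the
caller exceeds 99% accuracy on simulated counts.

### The optimization loop and its stopping rule

Each multiplex round classifies the read pool, genotypes the
individuals, and measures mean genotype accuracy against the reference
dataset over individuals with less than 30% missing data. Primer pairs
are ranked by their involvement in interaction reads and removed
greedily until the removed set covers 90% of interaction reads; a pair
that interacts predominantly (>50%) with one single partner is treated
as a duo, and only the member whose locus has the *lower* temporal
F~ST~ is removed. SNPs with accuracy below 0.9 are dropped, their locus
surviving if another SNP passes; loci with more than 10x (less than
0.1x) the mean on-target share are flagged over- (under-) amplifying —
the fold thresholds are package defaults for a criterion the source
protocol leaves qualitative. The loop stops when the proportion of
interaction reads is below one third *and* accuracy exceeds 95%; an
inestimable accuracy (e.g. a first round drowned in interactions) never
stops the loop.

## The synthetic-data generator

`DriftParams()` defaults encode the study conditions the package was
built around: 2,983 microhaplotype loci (2-4 alleles each, built on 1-2
SNP sites), 12 temporal collections spanning 1999-2018 with per-year
sample sizes of 27-42, one generation per year (a short-lived,
1-3-year species), i.i.d. 3% missing calls, and an effective-size
schedule with baseline $N_e = 1500$ and a two-year bottleneck at
$N_e = 250$ in 2013-2014. The baseline/bottleneck values were
calibrated so that simulated pairwise temporal $F_{ST}$ falls in the
~0.001-0.007 range reported for the monitored population; they are the
package's definition of "realistic drift" for this system. Allele
frequencies evolve by multinomial resampling of $2N_e$ gene copies
(frequency-based Wright-Fisher, not individual-based — sufficient for
drift statistics and orders of magnitude faster); genotypes are drawn
under Hardy-Weinberg proportions at the sampled year's frequencies.

The read simulator emits 150 bp single-end reads: on-target reads are
the forward primer plus the haplotype-substituted template with
substitution errors downstream of the primer; interaction reads are
fwd(*i*) + filler + a primer of pair *j*, with per-pair chimera
propensities so a designated subset of pairs can drive most
interactions. Every read carries a truth label.

**What the generator does not emulate** — and hence what passing tests
do and do not show: there is no selection, migration or overlapping
generations; no genotyping error, null alleles, or depth-dependent
miscalls in the *temporal genotype* data (the read simulator has
sequencing errors, but the upstream discovery genotypes are clean); no
linkage between loci; and missingness is independent of genotype and
depth. One practical consequence is documented honestly here: on real
monitoring data, mixed panels (e.g. 250 top-F~ST~ + 250 random loci)
have been observed to track the complete dataset's DAPC structure
better than pure top-F~ST~ panels. Under this generator that ordering
does not emerge — with exchangeable neutral loci, ranking by realized
$\hat\theta$ selects exactly the loci whose drift realizations dominate
the complete dataset's discriminant structure, so the pure top-F~ST~
subset tracks it at least as well in the large majority of replicates
(we verified this across pool fractions, retained-PC counts and drift
intensities). The real-data advantage of mixing in random loci
plausibly reflects locus-specific artifacts that inflate apparent
F~ST~ (depth-dependent genotyping error, null alleles, or selection) —
all deliberately outside this simulator. The corresponding acceptance
check is left failing rather than redefining the generator to force the
ordering; users applying the package to real data should still prefer
mixed schemes for the reasons above.

## Numerical and design choices

- **Coordinates** are 0-based half-open everywhere internally; 1-based
  only at VCF and reference-report boundaries. SNP trimming reads
  "within the first or last 33 bp" as 0-based offsets 0..32: a SNP at
  1-based position 33 has only 32 bases before it, which cannot host a
  25 bp primer plus 8 bp probe flank.
- **Trimming** runs the 5' pass to fixpoint, then the 3' pass; the two
  passes commute for this rule (property-tested), so the order is
  presentational.
- **Missing data** is a dedicated sentinel (`"-"` in tables, paired
  `NA` internally), never an allele index.
- **HWE testing** uses the classic chi-square on genotype classes
  (df = classes − alleles), per collection, Bonferroni-corrected across
  loci within each collection; a locus falls only if significant in
  *every* collection. A collection with no called genotypes cannot
  reject.
- **LD pruning** selects one SNP per locus (seeded per locus id, so the
  choice is stable under re-runs on subsets), uses the squared Pearson
  correlation of diploid dosages over individuals called at both loci
  (a composite, phase-free estimator computed from called genotypes;
  a sequencing-aware likelihood estimator would need read data the
  genotype matrix no longer carries), tests $n r^2$ against
  $\chi^2_1$ with $n$ = individuals, and removes from each significant
  pair the locus with higher missingness (ties: lexicographically
  larger id), cascading until no significant pair remains.
- **Primer specificity** is exact full-length matching on both strands
  ("100% coverage and identity", which exact search reproduces);
  ambiguous IUPAC bases in the genome never match. The on-target hit is
  identified by the source locus's coordinates.
- **Primer design itself is delegated**: candidates come from an
  external designer's table (`readPrimerCandidates()`), or from
  `makeNaivePrimerCandidates()` for simulation, which involves no
  thermodynamics. The package's contribution is the surrounding logic
  (trimming, screening, iteration), not oligo design.
- **Probe-table dialect**: the eight columns are
  `locus, ploidy, alleles, probes, fwd_primer, snp_offset,
  allele_correction, notes`; a strict flag on the reader rejects other
  layouts. The companion primer table carries the template and trim
  record so panels round-trip losslessly.
- **Degenerate inputs**: loci with fewer than two collections, a pair
  with fewer than two individuals per side, monomorphic loci in
  F~ST~/F~IS~, zero-read loci in representation flags, and empty read
  pools all have defined, tested behaviour (undefined entries, flags or
  no-ops rather than silent zeros).

## Problem sizes used in the checks

The test-suite and the acceptance script scale the study down so a
complete run finishes in minutes on one core: the heaviest checks use
the full 2,983-locus default only where the proportion structure
matters (subset selection: a 675-locus primer-compatible pool and
500-locus schemes, 50 replicates); elsewhere 60-1,500 loci, 6-40
individuals per collection, read depths of 20-60 and 2,000-10,000-read
pools are representative. The acceptance script
(`scripts/acceptance.R`) runs the whole pipeline at 1,500 loci.

## Known limitations

- Single-end, single-read phasing only: microhaplotypes longer than one
  read and paired-end merging are out of scope.
- The LD estimator ignores genotype uncertainty.
- The ML genotyper is this package's multinomial formulation; the
  published genotyper it stands in for does not print its exact
  likelihood, so equivalence should be verified before cross-tool
  comparisons.
- The diplotype-to-sex mapping is configuration: which genotype means
  which sex is marker- and species-specific knowledge that ships with
  the user, not the package.
- No index-hopping correction, UMI handling, or PCR-duplicate
  modelling.
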